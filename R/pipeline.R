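# Genome composition accounting and the orchestration layer producing the
# full report bundle (repeat table and summary, pseudogene scan, sharing
# report, gene-order distances, intron scan, rates, composition).

#' Round half away from zero
#'
#' Fixed-decimal rounding with ties going up (the convention of printed
#' percentage tables), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Genome composition from an annotation
#'
#' Exact three-way partition of the genome into coding (exons of protein
#' genes plus tRNA/rRNA), intron and intergenic space, with overlaps
#' resolved by precedence coding > intron > intergenic. Percentages are
#' rounded to one decimal, half up.
#'
#' @param annotation Annotation tibble.
#' @param genome_length Genome length (bp).
#' @param genome Optional DNA string for GC content.
#' @return A one-row `mm_composition` tibble: `genome_bp`, `gc_pct`,
#'   `coding_bp`, `intron_bp`, `intergenic_bp` and the three percentages.
#' @export
partition_genome <- function(annotation, genome_length, genome = NULL) {
  stopifnot(genome_length > 0)
  bad <- annotation$start < 1 | annotation$end > genome_length |
    annotation$end < annotation$start
  if (any(bad)) {
    stop(sprintf("annotation intervals out of bounds: rows %s",
                 paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  coding <- filter(annotation, .data$type %in% c("exon", "tRNA", "rRNA"))
  coding_iv <- reduce_intervals(tibble(start = coding$start,
                                       end = coding$end))
  intron <- filter(annotation, .data$type == "intron")
  intron_ir <- BiocGenerics::setdiff(as_iranges(
    reduce_intervals(tibble(start = intron$start, end = intron$end))),
    as_iranges(coding_iv))
  coding_bp <- intervals_width(coding_iv)
  intron_bp <- sum(IRanges::width(intron_ir))
  intergenic_bp <- genome_length - coding_bp - intron_bp
  composition_from_bp(genome_length, coding_bp, intron_bp, intergenic_bp,
                      gc_pct = if (!is.null(genome)) {
                        round_half_up(100 * gc_fraction(genome), 1)
                      } else NA_real_)
}

composition_from_bp <- function(genome_bp, coding_bp, intron_bp,
                                intergenic_bp, gc_pct = NA_real_) {
  stopifnot(coding_bp + intron_bp + intergenic_bp == genome_bp)
  out <- tibble(
    genome_bp = genome_bp, gc_pct = gc_pct,
    coding_bp = coding_bp, intron_bp = intron_bp,
    intergenic_bp = intergenic_bp,
    coding_pct = round_half_up(100 * coding_bp / genome_bp, 1),
    intron_pct = round_half_up(100 * intron_bp / genome_bp, 1),
    intergenic_pct = round_half_up(100 * intergenic_bp / genome_bp, 1))
  structure(out, class = c("mm_composition", class(tibble())))
}

#' Genome composition from published totals
#'
#' Derives the three-way partition from the totals a genome report
#' typically prints: total length, gene bp (exons plus introns), intron bp
#' and protein-exon bp. Coding bp is gene bp minus intron bp; intergenic
#' bp is the remainder.
#'
#' @param genome_bp Total genome length (bp).
#' @param gene_bp Total gene length including introns (bp).
#' @param intron_bp Total intron length (bp).
#' @param protein_exon_bp Optional protein-coding exon total (bp), reported
#'   as an additional percentage.
#' @return A one-row `mm_composition` tibble (with `protein_exon_bp` /
#'   `protein_exon_pct` when supplied).
#' @export
composition_from_totals <- function(genome_bp, gene_bp, intron_bp,
                                    protein_exon_bp = NA_integer_) {
  coding_bp <- gene_bp - intron_bp
  out <- composition_from_bp(genome_bp, coding_bp, intron_bp,
                             genome_bp - gene_bp)
  out$protein_exon_bp <- protein_exon_bp
  out$protein_exon_pct <- round_half_up(100 * protein_exon_bp / genome_bp, 1)
  out
}

#' Genome trait table of eight Faboideae mitogenomes
#'
#' Published genome-level totals (length, GC, gene/intron/exon bp, repeat
#' coverage) for the S. japonica 'JinhuaiJ2' mitogenome and seven
#' Faboideae comparators, keyed by GenBank accession.
#'
#' @return Tibble, one row per genome.
#' @export
mt_genome_traits <- function() {
  readr::read_tsv(system.file("extdata", "faboideae_mt_traits.tsv",
                              package = "mitomosaic"),
                  show_col_types = FALSE, comment = "#")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages the package implements; stages whose inputs are
#' missing from the config are skipped with a logged reason. Deterministic
#' given the config (all stage functions are deterministic; generator
#' seeds live in the config).
#'
#' @param config A list. Recognised entries: `genome` (DNA string),
#'   `annotation` (tibble), `genome_b` (second genome for sharing),
#'   `gene_seqs` (named vector for the pseudogene scan), `reads` (named
#'   vector), `repeat_for_reads` (row index into the repeat table for the
#'   recombination stage, default: largest repeat), `orders` (list of
#'   [gene_order()]), `intron_alignments` (named list of alignments),
#'   `codon_alignment` (named vector of in-frame coding sequences), and
#'   stage parameter lists `repeat_params`, `pseudo_params`,
#'   `share_params`, `recomb_params`.
#' @param out_dir Optional directory; when given, every stage report is
#'   written as TSV with a parameter-recording header.
#' @param quiet Suppress the stage log (messages)?
#' @return Named list of stage reports (class `mm_bundle`): any of
#'   `composition`, `repeats`, `repeat_summary`, `pseudogenes`, `sharing`,
#'   `gene_order`, `introns`, `intron_lengths`, `rates`, `recombination`,
#'   plus `log` (tibble of stages run/skipped).
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  bundle <- list()
  log <- list()
  note <- function(stage, status, detail = "") {
    log[[length(log) + 1]] <<- tibble(stage = stage, status = status,
                                      detail = detail)
    say("[%s] %s %s", stage, status, detail)
  }
  has <- function(nm) !is.null(config[[nm]])

  if (has("genome") && has("annotation")) {
    bundle$composition <- partition_genome(config$annotation,
                                           nchar(config$genome),
                                           genome = config$genome)
    note("composition", "run")
  } else note("composition", "skipped", "needs genome + annotation")

  if (has("genome")) {
    rp <- do.call(find_repeats,
                  c(list(genome = config$genome),
                    config$repeat_params %||% list()))
    bundle$repeats <- rp
    bundle$repeat_summary <- summarize_repeats(rp)
    note("repeats", "run", sprintf("%d pairs", nrow(rp)))
  } else note("repeats", "skipped", "needs genome")

  if (has("genome") && has("annotation")) {
    gseqs <- config$gene_seqs %||%
      gene_sequences(config$genome, config$annotation)
    ps <- do.call(scan_pseudogenes,
                  c(list(genome = config$genome,
                         annotation = config$annotation,
                         gene_seqs = gseqs),
                    config$pseudo_params %||% list()))
    if (!is.null(bundle$repeats)) {
      ps <- flag_repeat_association(ps, bundle$repeats)
    }
    bundle$pseudogenes <- ps
    note("pseudogenes", "run", sprintf("%d fragments", nrow(ps)))
  } else note("pseudogenes", "skipped", "needs genome + annotation")

  if (has("genome") && has("genome_b")) {
    bundle$sharing <- do.call(shared_content,
                              c(list(genome_a = config$genome,
                                     genome_b = config$genome_b),
                                config$share_params %||% list()))
    note("sharing", "run")
  } else note("sharing", "skipped", "needs genome + genome_b")

  if (has("orders")) {
    bundle$gene_order <- pairwise_dcj(config$orders)
    note("gene_order", "run")
  } else note("gene_order", "skipped", "needs orders")

  if (has("intron_alignments")) {
    bundle$intron_lengths <- intron_length_table(config$intron_alignments)
    bundle$introns <- purrr::imap_dfr(config$intron_alignments,
      function(aln, nm) {
        b <- find_deletion_blocks(aln)
        if (nrow(b)) mutate(b, intron = nm, .before = 1) else b
      })
    note("introns", "run")
  } else note("introns", "skipped", "needs intron_alignments")

  if (has("codon_alignment")) {
    bundle$rates <- ng86_pairwise_all(config$codon_alignment)
    note("rates", "run")
  } else note("rates", "skipped", "needs codon_alignment")

  if (has("genome") && has("reads")) {
    if (is.null(bundle$repeats) || !nrow(bundle$repeats)) {
      note("recombination", "skipped", "no repeats found")
    } else {
      idx <- config$repeat_for_reads %||% which.max(bundle$repeats$size)
      calls <- do.call(classify_spanning_reads,
                       c(list(reads = config$reads,
                              genome = config$genome,
                              repeat_pair = bundle$repeats[idx, ]),
                         config$recomb_params %||% list()))
      bundle$recombination <- summarize_recombination(calls)
      bundle$read_calls <- calls
      note("recombination", "run",
           sprintf("%d spanning reads", nrow(calls)))
    }
  } else note("recombination", "skipped", "needs genome + reads")

  bundle$log <- bind_rows(log)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, config)
  }
  structure(bundle, class = "mm_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_bundle <- function(bundle, out_dir, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# mitomosaic %s | %s",
                 as.character(utils::packageVersion("mitomosaic")),
                 paste(names(config), collapse = ","))
  for (nm in setdiff(names(bundle), c("log"))) {
    x <- bundle[[nm]]
    if (inherits(x, "mm_dcj")) x <- tidy(x)
    if (!is.data.frame(x)) next
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    writeLines(hdr, path)
    suppressWarnings(readr::write_tsv(as_tibble(x), path, append = TRUE,
                                      col_names = TRUE))
  }
  readr::write_tsv(bundle$log, file.path(out_dir, "log.tsv"))
  invisible(out_dir)
}
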