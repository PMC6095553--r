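# Pseudogene-fragment detection in intergenic spacers, shared-mtDNA
# accounting between genome pairs, and the known/anonymous sequence
# partition.

#' Scan intergenic spacers for pseudogene fragments
#'
#' Aligns each functional gene sequence against the genome and reports hits
#' lying wholly outside annotated genic space (genes including their
#' introns, plus tRNA/rRNA features). Overlapping hits from the same source
#' gene are merged and re-validated by exact local realignment. Default
#' thresholds (28 bp, 92 percent) reflect the detection envelope typical of
#' plant mitochondrial pseudogene fragments.
#'
#' @param genome DNA string.
#' @param annotation Annotation tibble defining genic space.
#' @param gene_seqs Named character vector of functional gene sequences.
#' @param min_len Minimum fragment length (bp).
#' @param min_identity Minimum identity (fraction).
#' @param word_size Seed word size (7 by default: gene-versus-genome search
#'   spaces are small enough for exhaustive short seeding).
#' @param scoring An [align_scoring()] scheme.
#' @return A `mm_pseudogenes` tibble: `gene`, `start`, `end`, `length`,
#'   `identity` (percent), `strand`, `inside_repeat` (`NA` until
#'   [flag_repeat_association()] is applied).
#' @export
scan_pseudogenes <- function(genome, annotation, gene_seqs,
                             min_len = 28L, min_identity = 0.92,
                             word_size = 7L, scoring = align_scoring()) {
  check_dna(c(genome = genome))
  genic <- genic_intervals(annotation)
  genic_ir <- as_iranges(genic)
  # sensitive first pass: thresholds relaxed so that fragments split by
  # mismatch clusters during extension are still collected; the exact
  # realignment below applies the real thresholds
  search_len <- max(20L, min_len - 8L)
  search_identity <- max(0.75, min_identity - 0.10)
  pad <- 40L
  gaps_ir <- BiocGenerics::setdiff(IRanges::IRanges(1L, nchar(genome)),
                                   genic_ir)
  res <- purrr::imap_dfr(gene_seqs, function(gseq, gname) {
    if (is.na(gseq) || !nzchar(gseq)) {
      warning(sprintf("gene %s absent from gene_seqs; skipped", gname))
      return(tibble())
    }
    h <- align_hits(gseq, genome, k = word_size, scoring = scoring,
                    min_len = search_len, min_identity = search_identity)
    if (!nrow(h)) return(tibble())
    # pad, merge, and clip to intergenic space: candidate segments are
    # wholly intergenic by construction (the gene's own locus vanishes
    # here), then re-validate each by exact realignment
    padded <- reduce_intervals(tibble(
      start = pmax(1L, h$s_start - pad),
      end = pmin(nchar(genome), h$s_end + pad)))
    clipped <- BiocGenerics::intersect(as_iranges(padded), gaps_ir)
    merged <- tibble(start = BiocGenerics::start(clipped),
                     end = BiocGenerics::end(clipped))
    merged <- filter(merged, .data$end - .data$start + 1L >= min_len)
    if (!nrow(merged)) return(tibble())
    purrr::map_dfr(seq_len(nrow(merged)), function(i) {
      seg <- substr(genome, merged$start[i], merged$end[i])
      val <- local_align(seg, gseq, scoring = scoring,
                         max_cells = 4e7)
      if (!nrow(val)) return(tibble())
      # the score-optimal alignment may carry a few chance-matching bases
      # beyond the fragment that dilute identity below threshold: trim to
      # the longest window meeting the thresholds (ungapped case)
      if (val$gaps == 0 && val$identity < min_identity) {
        qs <- strsplit(substr(seg, val$q_start, val$q_end), "")[[1]]
        sref <- substr(gseq, val$s_start, val$s_end)
        if (val$strand == "-") sref <- revcomp(sref)
        ss <- strsplit(sref, "")[[1]]
        win <- longest_identity_window(qs == ss, min_len, min_identity)
        if (!is.null(win)) {
          val$q_end <- val$q_start + win[2] - 1L
          val$q_start <- val$q_start + win[1] - 1L
          val$length <- win[2] - win[1] + 1L
          val$matches <- win[3]
          val$identity <- win[3] / val$length
        }
      }
      tibble(gene = gname,
             start = merged$start[i] + val$q_start - 1L,
             end = merged$start[i] + val$q_end - 1L,
             length = val$length,
             identity = round(val$identity * 100, 2),
             strand = val$strand)
    })
  })
  if (!nrow(res)) {
    res <- tibble(gene = character(), start = integer(), end = integer(),
                  length = integer(), identity = double(),
                  strand = character())
  }
  res <- filter(res, .data$length >= min_len,
                .data$identity >= min_identity * 100)
  res$inside_repeat <- NA
  res <- arrange(res, .data$start)
  structure(res, class = c("mm_pseudogenes", class(tibble())))
}

# longest window meeting the identity threshold obtainable by trimming at
# most max_trim positions from each alignment end (end-trimming only: a
# diverged fragment must not qualify through a short high-identity core);
# returns c(start, end, matches) relative to the match vector, or NULL
longest_identity_window <- function(is_match, min_len, min_id,
                                    max_trim = 20L) {
  n <- length(is_match)
  if (n < min_len) return(NULL)
  cm <- c(0L, cumsum(is_match))
  best <- NULL
  for (i in seq_len(min(max_trim + 1L, n - min_len + 1L))) {
    j_lo <- max(n - max_trim, i + min_len - 1L)
    if (j_lo > n) break
    for (j in seq(n, j_lo)) {
      w <- j - i + 1L
      if (w < min_len) next
      matches <- cm[j + 1L] - cm[i]
      if (matches / w >= min_id &&
          (is.null(best) || w > best[2] - best[1] + 1L)) {
        best <- c(i, j, matches)
      }
    }
  }
  best
}

#' Flag pseudogene hits that fall inside repeat copies
#'
#' @param hits A `mm_pseudogenes` tibble.
#' @param repeats An `mm_repeats` tibble from [find_repeats()] on the same
#'   genome.
#' @param mode `"containment"` (default; the hit interval must lie wholly
#'   inside the union of repeat copy intervals) or `"overlap"` (any
#'   overlap).
#' @return `hits` with `inside_repeat` set.
#' @export
flag_repeat_association <- function(hits, repeats,
                                    mode = c("containment", "overlap")) {
  mode <- match.arg(mode)
  cover <- reduce_intervals(tibble(
    start = c(repeats$copy1_start, repeats$copy2_start),
    end = c(repeats$copy1_end, repeats$copy2_end)))
  cov_ir <- as_iranges(cover)
  hit_ir <- IRanges::IRanges(start = hits$start, end = hits$end)
  hits$inside_repeat <- if (mode == "overlap") {
    IRanges::countOverlaps(hit_ir, cov_ir) > 0
  } else {
    IRanges::countOverlaps(hit_ir, cov_ir, type = "within") > 0
  }
  hits
}

#' Shared sequence content between two genomes
#'
#' Coverage accounting over seed-and-extend hits: the shared amount on each
#' genome is the width of the union of its intervals across all qualifying
#' hits, both strands. A deterministic, threshold-driven approximation to
#' collinear-block-based sharing estimates; thresholds are recorded in the
#' output.
#'
#' @param genome_a,genome_b DNA strings.
#' @param min_len Minimum hit length (bp).
#' @param min_identity Minimum hit identity (fraction).
#' @param word_size Seed word size.
#' @param ids Length-2 character vector naming the pair.
#' @param scoring An [align_scoring()] scheme.
#' @return A one-row `mm_sharing` tibble: ids, genome lengths, shared bp and
#'   fraction per genome, unshared (species-specific) bp and fraction per
#'   genome, and the thresholds used.
#' @export
shared_content <- function(genome_a, genome_b, min_len = 100L,
                           min_identity = 0.70, word_size = 13L,
                           ids = c("A", "B"), scoring = align_scoring()) {
  check_dna(c(a = genome_a, b = genome_b))
  h <- align_hits(genome_a, genome_b, k = word_size, scoring = scoring,
                  min_len = min_len, min_identity = min_identity)
  la <- nchar(genome_a)
  lb <- nchar(genome_b)
  bp_a <- intervals_width(tibble(start = h$q_start, end = h$q_end))
  bp_b <- intervals_width(tibble(start = h$s_start, end = h$s_end))
  out <- tibble(
    id_a = ids[1], id_b = ids[2],
    length_a = la, length_b = lb,
    shared_bp_a = bp_a, shared_frac_a = bp_a / la,
    shared_bp_b = bp_b, shared_frac_b = bp_b / lb,
    unshared_bp_a = la - bp_a, unshared_frac_a = (la - bp_a) / la,
    unshared_bp_b = lb - bp_b, unshared_frac_b = (lb - bp_b) / lb,
    min_len = as.integer(min_len), min_identity = min_identity)
  structure(out, class = c("mm_sharing", class(tibble())))
}

#' Anonymous sequence content of a genome
#'
#' Anonymous content is what remains after subtracting the known sequence
#' content (the union of the supplied intervals) from the total genome
#' length.
#'
#' @param genome_length Total genome length (bp).
#' @param known_intervals Tibble with `start`, `end` (1-based inclusive)
#'   columns of known-content intervals; overlaps are counted once.
#' @return One-row tibble: `genome_length`, `known_bp`, `anonymous_bp`,
#'   `anonymous_frac`.
#' @export
anonymous_content <- function(genome_length, known_intervals) {
  stopifnot(genome_length > 0)
  if (nrow(known_intervals)) {
    if (any(known_intervals$start < 1) ||
        any(known_intervals$end > genome_length) ||
        any(known_intervals$end < known_intervals$start)) {
      stop("known intervals out of genome bounds")
    }
  }
  known <- intervals_width(known_intervals)
  tibble(genome_length = genome_length, known_bp = known,
         anonymous_bp = genome_length - known,
         anonymous_frac = (genome_length - known) / genome_length)
}

#' Export shared/unshared intervals of a genome pair as BED
#'
#' @param genome_a,genome_b DNA strings (as passed to [shared_content()]).
#' @param path Output path (BED: 0-based half-open).
#' @param which `"shared"` or `"unshared"`, accounted on genome A.
#' @inheritParams shared_content
#' @return `path`, invisibly.
#' @export
write_shared_bed <- function(genome_a, genome_b, path,
                             which = c("shared", "unshared"),
                             min_len = 100L, min_identity = 0.70,
                             word_size = 13L, ids = c("A", "B")) {
  which <- match.arg(which)
  h <- align_hits(genome_a, genome_b, k = word_size,
                  min_len = min_len, min_identity = min_identity)
  shared <- reduce_intervals(tibble(start = h$q_start, end = h$q_end))
  ivs <- if (which == "shared") shared else {
    gaps <- BiocGenerics::setdiff(
      IRanges::IRanges(1L, nchar(genome_a)), as_iranges(shared))
    tibble(start = BiocGenerics::start(gaps), end = BiocGenerics::end(gaps))
  }
  out <- tibble(chrom = ids[1], start = ivs$start - 1L, end = ivs$end)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}
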