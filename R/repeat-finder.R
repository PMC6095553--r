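# Self-comparison repeat detection on circular genomes: unique-pair
# deduplication, direct/inverted orientation, size-tier classification
# (small < 100 bp, medium 100-1000 bp, large >= 1000 bp) and coverage
# summaries.

#' Find repeated sequence pairs in a (circular) genome
#'
#' Aligns the genome against itself with the seed-and-extend kernel and
#' reports every repeat pair with unique start and end coordinates. For
#' circular genomes the sequence is doubled before self-comparison, hits are
#' capped at the genome length and deduplicated modulo the genome length.
#' The trivial full-length self-match and any pair whose two copies are the
#' same interval are excluded; nested and overlapping pairs with distinct
#' coordinates are all retained.
#'
#' @param genome DNA string (a single circular or linear molecule).
#' @param min_len Minimum alignment length reported (bp).
#' @param min_identity Minimum identity (fraction) reported.
#' @param word_size Seed word size. The default (13) trades sensitivity at
#'   the shortest, most diverged end of the spectrum for speed; lower it
#'   towards 7 for exhaustive small-repeat scans of short genomes.
#' @param scoring An [align_scoring()] scheme.
#' @param circular Treat the genome as circular?
#' @return A `mm_repeats` tibble, one row per repeat pair: `repeat_id`,
#'   `identity` (percent), `copy1_start`, `copy1_end`, `copy2_start`,
#'   `copy2_end` (1-based inclusive, ascending; ends may exceed the genome
#'   length for pairs spanning the origin), `size` (alignment length, bp),
#'   `orientation` (`"DR"`/`"IR"`), `size_class`, `score`, `self_overlap`.
#'   Rows are sorted by `copy1_start`; copy 1 precedes copy 2
#'   lexicographically. The genome length is attached as attribute
#'   `genome_length`.
#' @export
find_repeats <- function(genome, min_len = 20L, min_identity = 0.80,
                         word_size = 13L, scoring = align_scoring(),
                         circular = TRUE) {
  if (length(genome) != 1 || !nzchar(genome)) {
    stop("genome must be a single non-empty sequence")
  }
  check_dna(c(genome = genome))
  L <- nchar(genome)
  if (L < 2 * min_len) stop("genome shorter than twice min_len")
  seq2 <- if (circular) paste0(genome, genome) else genome
  excl <- if (circular) c(0L, L, -L) else 0L
  hits <- align_hits(seq2, seq2, k = word_size, scoring = scoring,
                     min_len = min_len, min_identity = min_identity,
                     exclude_diagonals = excl,
                     self_length = if (circular) L else NULL)
  hits <- filter(hits, .data$length <= L)
  if (circular && nrow(hits)) {
    # drop residual echoes of the trivial self-match (plus-strand hits whose
    # two intervals coincide modulo L)
    same <- hits$strand == "+" &
      ((hits$q_start - hits$s_start) %% L == 0) &
      ((hits$q_end - hits$s_end) %% L == 0)
    hits <- hits[!same, ]
  }
  pairs <- canonicalize_repeat_pairs(hits, L, circular)
  pairs <- mutate(pairs,
    size_class = classify_repeat_size(.data$size),
    repeat_id = sprintf("R%02d", row_number()))
  pairs <- select(pairs, "repeat_id", "identity", "copy1_start", "copy1_end",
                  "copy2_start", "copy2_end", "size", "orientation",
                  "size_class", "score", "self_overlap")
  new_mm_repeats(pairs, L)
}

new_mm_repeats <- function(x, genome_length) {
  structure(x, genome_length = genome_length,
            class = c("mm_repeats", class(tibble())))
}

# Reduce raw self-comparison hits to canonical unique repeat pairs:
# shift both intervals into [1, L] starts, order the two copies
# lexicographically, drop self-pairs and duplicates. Idempotent.
canonicalize_repeat_pairs <- function(hits, L, circular = TRUE) {
  empty <- tibble(identity = double(), copy1_start = integer(),
                  copy1_end = integer(), copy2_start = integer(),
                  copy2_end = integer(), size = integer(),
                  orientation = character(), score = integer(),
                  self_overlap = logical())
  if (!nrow(hits)) return(empty)
  shift <- function(s, e) {
    if (circular) {
      off <- ((s - 1) %/% L) * L
      cbind(s - off, e - off)
    } else cbind(s, e)
  }
  a <- shift(hits$q_start, hits$q_end)
  b <- shift(hits$s_start, hits$s_end)
  first_a <- (a[, 1] < b[, 1]) | (a[, 1] == b[, 1] & a[, 2] <= b[, 2])
  c1 <- ifelse(first_a, a[, 1], b[, 1])
  c1e <- ifelse(first_a, a[, 2], b[, 2])
  c2 <- ifelse(first_a, b[, 1], a[, 1])
  c2e <- ifelse(first_a, b[, 2], a[, 2])
  out <- tibble(
    identity = round(hits$identity * 100, 2),
    copy1_start = as.integer(c1), copy1_end = as.integer(c1e),
    copy2_start = as.integer(c2), copy2_end = as.integer(c2e),
    size = hits$length,
    orientation = ifelse(hits$strand == "+", "DR", "IR"),
    score = hits$score,
    self_overlap = pmax(c1, c2) <= pmin(c1e, c2e))
  out <- filter(out, !(.data$copy1_start == .data$copy2_start &
                         .data$copy1_end == .data$copy2_end))
  out <- distinct(out, .data$copy1_start, .data$copy1_end, .data$copy2_start,
                  .data$copy2_end, .data$orientation, .keep_all = TRUE)
  arrange(out, .data$copy1_start, .data$copy1_end, .data$copy2_start)
}

#' Classify repeat sizes into tiers
#'
#' Small repeats are `[20, 100)` bp, medium `[100, 1000)` bp and large
#' `>= 1000` bp (the explicit inequality for large resolves the shared
#' 1000-bp boundary).
#'
#' @param size Integer vector of repeat sizes (bp), all >= 20.
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
classify_repeat_size <- function(size) {
  if (any(size < 20)) {
    stop("repeat size below the 20 bp reporting threshold")
  }
  cut(size, breaks = c(20, 100, 1000, Inf), labels =
        c("small", "medium", "large"), right = FALSE,
      include.lowest = TRUE)
}

#' Orientation of a repeat pair from raw (possibly descending) coordinates
#'
#' Repeat tables conventionally print the second copy with descending
#' coordinates when the two copies lie on opposite strands. Copies running
#' in the same direction are direct repeats (DR); opposite directions are
#' inverted repeats (IR).
#'
#' @param copy1_start,copy1_end,copy2_start,copy2_end Raw coordinates with
#'   direction encoded by start/end order. Degenerate (1 bp) intervals are
#'   rejected.
#' @return Character vector of `"DR"`/`"IR"`.
#' @export
orient_repeat <- function(copy1_start, copy1_end, copy2_start, copy2_end) {
  d1 <- sign(copy1_end - copy1_start)
  d2 <- sign(copy2_end - copy2_start)
  if (any(d1 == 0 | d2 == 0)) {
    stop("degenerate (single-position) repeat interval")
  }
  ifelse(d1 == d2, "DR", "IR")
}

#' Summarise a repeat set
#'
#' @param repeats An `mm_repeats` tibble (or any tibble in its layout).
#' @param genome_length Genome length in bp; taken from the `genome_length`
#'   attribute when missing.
#' @param count Coverage accounting: `"union"` (default) counts every
#'   genome position covered by any repeat copy once; `"copy1"` counts only
#'   the first copy's spans (still merged).
#' @return One-row tibble: pair counts per size class, `repeat_bp` and
#'   `repeat_frac`.
#' @export
summarize_repeats <- function(repeats, genome_length = NULL,
                              count = c("union", "copy1")) {
  count <- match.arg(count)
  if (is.null(genome_length)) {
    genome_length <- attr(repeats, "genome_length")
  }
  if (is.null(genome_length) || genome_length <= 0) {
    stop("genome_length must be a positive integer")
  }
  ivs <- tibble(start = repeats$copy1_start, end = repeats$copy1_end)
  if (count == "union") {
    ivs <- bind_rows(ivs, tibble(start = repeats$copy2_start,
                                 end = repeats$copy2_end))
  }
  bp <- if (nrow(ivs)) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = ivs$start, end = ivs$end))))
  } else 0L
  cls <- table(factor(repeats$size_class,
                      levels = c("small", "medium", "large")))
  tibble(n_pairs = nrow(repeats),
         n_small = as.integer(cls[["small"]]),
         n_medium = as.integer(cls[["medium"]]),
         n_large = as.integer(cls[["large"]]),
         repeat_bp = as.integer(bp),
         repeat_frac = bp / genome_length)
}

#' Write a repeat table as TSV
#'
#' @param repeats An `mm_repeats` tibble.
#' @param path Output path.
#' @param style `"ascending"` keeps both copies ascending with the
#'   orientation column; `"report"` prints the second copy of inverted
#'   repeats with descending coordinates, the convention of printed repeat
#'   tables.
#' @return `path`, invisibly.
#' @export
write_repeat_table <- function(repeats, path,
                               style = c("ascending", "report")) {
  style <- match.arg(style)
  out <- as_tibble(repeats)
  if (style == "report") {
    ir <- out$orientation == "IR"
    tmp <- out$copy2_start[ir]
    out$copy2_start[ir] <- out$copy2_end[ir]
    out$copy2_end[ir] <- tmp
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Export repeat pairs as Circos-style link records
#'
#' @param repeats An `mm_repeats` tibble.
#' @param path Output path.
#' @param chr Chromosome/molecule label.
#' @return `path`, invisibly.
#' @export
write_repeat_links <- function(repeats, path, chr = "mt") {
  out <- tibble(chr1 = chr, start1 = repeats$copy1_start,
                end1 = repeats$copy1_end, chr2 = chr,
                start2 = repeats$copy2_start, end2 = repeats$copy2_end)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Curated repeat table of the Sophora japonica 'JinhuaiJ2' mitogenome
#'
#' The 21 repeat pairs of at least 100 bp annotated on the S. japonica
#' 'JinhuaiJ2' mitochondrial genome (GenBank MG757109), with the second
#' copy of inverted repeats printed in descending coordinates. Shipped as a
#' worked example for [orient_repeat()] and [classify_repeat_size()].
#'
#' @return Tibble with columns `repeat_id`, `identity`, `copy1_start`,
#'   `copy1_end`, `copy2_start`, `copy2_end`, `size`, `type`.
#' @export
mt_repeat_table <- function() {
  readr::read_tsv(system.file("extdata", "sophora_mt_repeats.tsv",
                              package = "mitomosaic"),
                  show_col_types = FALSE, comment = "#")
}
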