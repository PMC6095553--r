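# Seed-and-extend local alignment: the blastn-like kernel behind repeat
# detection, pseudogene scanning, shared-DNA accounting and read placement.
# Coordinates are 1-based inclusive throughout; minus-strand hits are
# reported with ascending coordinates on both sequences plus a strand flag.

#' Alignment scoring scheme
#'
#' Blastn-like defaults: match +2, mismatch -3, affine gaps costing
#' `gap_open + gap_extend * length`, and an x-drop of 20 terminating
#' extension. `N` never matches anything, including `N`.
#'
#' @param match Match reward (> 0).
#' @param mismatch Mismatch penalty (< 0).
#' @param gap_open Gap opening penalty (> 0, subtracted).
#' @param gap_extend Gap extension penalty (> 0, subtracted per column).
#' @param xdrop Score drop-off terminating seed extension.
#' @return A list with class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                          gap_extend = 2L, xdrop = 20L) {
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0, xdrop > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop = as.integer(xdrop)),
            class = "align_scoring")
}

#' Exact k-mer seed matches between two sequences
#'
#' Finds every position pair where a query k-mer equals a subject k-mer
#' exactly, on the plus strand and (via reverse complement) the minus
#' strand. k-mers containing `N` never match. A `k` longer than either
#' sequence yields an empty result.
#'
#' @param query,subject DNA strings.
#' @param k Word size (>= 4).
#' @param strands Strands to search, a subset of `c("+", "-")`.
#' @return Tibble with columns `q_start`, `s_start`, `strand`; `s_start` is
#'   the ascending subject start of the matched window on both strands.
#' @export
find_seeds <- function(query, subject, k = 7L, strands = c("+", "-")) {
  check_dna(c(q = query, s = subject))
  if (k < 4) stop("word size k must be >= 4")
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  out <- list()
  if ("+" %in% strands) {
    m <- cpp_find_seeds(query, subject, as.integer(k))
    out$plus <- tibble(q_start = m[, 1], s_start = m[, 2], strand = "+")
  }
  if ("-" %in% strands) {
    ns <- nchar(subject)
    m <- cpp_find_seeds(query, revcomp(subject), as.integer(k))
    out$minus <- tibble(q_start = m[, 1],
                        s_start = ns - m[, 2] - as.integer(k) + 2L,
                        strand = "-")
  }
  res <- bind_rows(out)
  attr(res, "k") <- as.integer(k)
  arrange(res, .data$strand, .data$q_start, .data$s_start)
}

# shared post-processing of an extension on the (possibly revcomp'ed)
# subject: map minus-strand subject coordinates back to ascending originals
map_hit_strand <- function(hits, ns, strand) {
  if (strand == "-" && nrow(hits)) {
    s1 <- ns - hits$s_end + 1L
    s2 <- ns - hits$s_start + 1L
    hits$s_start <- s1
    hits$s_end <- s2
  }
  hits$strand <- strand
  hits
}

#' Extend a single seed into a local alignment hit
#'
#' Two-phase extension emulating blastn: an ungapped x-drop extension from
#' the exact seed, then (when `gapped = TRUE` and the window is tractable)
#' an exact affine-gap local realignment of the extended window, anchored so
#' the reported hit contains the seed.
#'
#' @param query,subject DNA strings.
#' @param q_start,s_start Seed start positions (ascending, 1-based).
#' @param strand `"+"` or `"-"`.
#' @param k Seed length.
#' @param scoring An [align_scoring()] scheme.
#' @param gapped Run the gapped polish phase?
#' @param max_polish_cells Skip the gapped polish when the window DP would
#'   exceed this many cells (the ungapped hit is returned instead).
#' @return One-row tibble: `q_start`, `q_end`, `s_start`, `s_end`, `strand`,
#'   `length`, `matches`, `identity` (fraction), `score`, `gaps`.
#' @export
extend_seed <- function(query, subject, q_start, s_start, strand = "+",
                        k = 7L, scoring = align_scoring(), gapped = TRUE,
                        max_polish_cells = 2.5e7) {
  ns <- nchar(subject)
  sub2 <- if (strand == "-") revcomp(subject) else subject
  s0 <- if (strand == "-") ns - s_start - k + 2L else s_start
  e <- cpp_ungapped_extend(query, sub2, as.integer(q_start), as.integer(s0),
                           as.integer(k), scoring$match, scoring$mismatch,
                           scoring$xdrop)
  hit <- tibble(q_start = e[["q_start"]], q_end = e[["q_end"]],
                s_start = e[["s_start"]], s_end = e[["s_end"]],
                length = e[["length"]], matches = e[["matches"]],
                score = e[["score"]], gaps = 0L)
  if (gapped) {
    hit <- polish_hit(hit, query, sub2, scoring, max_polish_cells,
                      seed_q = c(q_start, q_start + k - 1L))
  }
  hit$identity <- hit$matches / hit$length
  hit <- map_hit_strand(hit, ns, strand)
  select(hit, "q_start", "q_end", "s_start", "s_end", "strand",
         "length", "matches", "identity", "score", "gaps")
}

# Gapped polish: exact local DP over the ungapped extent plus a margin.
# Falls back to the ungapped hit when the window is too large or the polished
# alignment no longer overlaps the seed.
polish_hit <- function(hit, query, sub2, scoring, max_polish_cells,
                       seed_q = NULL, margin = 50L) {
  qa <- max(1L, hit$q_start - margin)
  qb <- min(nchar(query), hit$q_end + margin)
  sa <- max(1L, hit$s_start - margin)
  sb <- min(nchar(sub2), hit$s_end + margin)
  if (as.double(qb - qa + 1) * as.double(sb - sa + 1) > max_polish_cells) {
    return(hit)
  }
  r <- cpp_sw_local(substr(query, qa, qb), substr(sub2, sa, sb),
                    scoring$match, scoring$mismatch, scoring$gap_open,
                    scoring$gap_extend)
  if (r[["score"]] < hit$score) return(hit)
  pol <- tibble(q_start = qa + r[["a_start"]] - 1L,
                q_end = qa + r[["a_end"]] - 1L,
                s_start = sa + r[["b_start"]] - 1L,
                s_end = sa + r[["b_end"]] - 1L,
                length = r[["length"]], matches = r[["matches"]],
                score = r[["score"]], gaps = r[["gaps"]])
  if (!is.null(seed_q) &&
      (pol$q_end < seed_q[1] || pol$q_start > seed_q[2])) {
    return(hit) # polished alignment drifted off the seed; keep the anchor
  }
  pol
}

#' Exact best local alignment (dynamic-programming oracle)
#'
#' Full affine-gap Smith-Waterman over both strands. Intended as the exact
#' reference for the seed-and-extend path on small inputs; refuses problems
#' larger than `max_cells` DP cells.
#'
#' @param a,b DNA strings.
#' @param scoring An [align_scoring()] scheme.
#' @param strands Strands to search.
#' @param max_cells Refusal threshold on `nchar(a) * nchar(b)`.
#' @return One-row tibble in the same layout as [extend_seed()] (query = `a`,
#'   subject = `b`), or a zero-row tibble if no positive-scoring alignment
#'   exists.
#' @export
local_align <- function(a, b, scoring = align_scoring(),
                        strands = c("+", "-"), max_cells = 1e7) {
  check_dna(c(a = a, b = b))
  if (as.double(nchar(a)) * as.double(nchar(b)) > max_cells) {
    stop(sprintf(
      "refusing exact local alignment: %d x %d exceeds max_cells = %g",
      nchar(a), nchar(b), max_cells))
  }
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  nb <- nchar(b)
  best <- NULL
  for (st in strands) {
    b2 <- if (st == "-") revcomp(b) else b
    r <- cpp_sw_local(a, b2, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    if (r[["score"]] <= 0) next
    hit <- tibble(q_start = r[["a_start"]], q_end = r[["a_end"]],
                  s_start = r[["b_start"]], s_end = r[["b_end"]],
                  length = r[["length"]], matches = r[["matches"]],
                  score = r[["score"]], gaps = r[["gaps"]])
    hit$identity <- hit$matches / hit$length
    hit <- map_hit_strand(hit, nb, st)
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  if (is.null(best)) {
    return(tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), length = integer(),
                  matches = integer(), identity = double(),
                  score = integer(), gaps = integer()))
  }
  select(best, "q_start", "q_end", "s_start", "s_end", "strand",
         "length", "matches", "identity", "score", "gaps")
}

#' Seed-and-extend local alignment between two sequences
#'
#' The workhorse search: exact k-mer seeding on both strands, batched
#' ungapped x-drop extension with per-diagonal pruning, optional gapped
#' polish, then length/identity filtering. These deterministic thresholds
#' replace an e-value cutoff.
#'
#' @param query,subject DNA strings.
#' @param k Word size.
#' @param scoring An [align_scoring()] scheme.
#' @param min_len Minimum alignment length reported.
#' @param min_identity Minimum identity (fraction) reported.
#' @param strands Strands to search.
#' @param gapped Run the gapped polish on candidate hits?
#' @param exclude_diagonals Integer offsets `s_start - q_start` of plus-strand
#'   diagonals to drop before extension (used by the repeat finder to remove
#'   the trivial self-match of a genome against itself).
#' @param max_polish_cells See [extend_seed()].
#' @return Tibble of hits in [extend_seed()] layout, deduplicated (hits whose
#'   query and subject intervals are both contained in another hit on the
#'   same strand are dropped), sorted by strand, `q_start`, `s_start`.
#' @export
align_hits <- function(query, subject, k = 11L, scoring = align_scoring(),
                       min_len = 20L, min_identity = 0.80,
                       strands = c("+", "-"), gapped = TRUE,
                       exclude_diagonals = integer(),
                       max_polish_cells = 2.5e7, self_length = NULL) {
  check_dna(c(q = query, s = subject))
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  ns <- nchar(subject)
  out <- list()
  for (st in strands) {
    sub2 <- if (st == "-") revcomp(subject) else subject
    m <- cpp_find_seeds(query, sub2, as.integer(k))
    if (!nrow(m)) next
    diag <- m[, 2] - m[, 1]
    if (st == "+" && length(exclude_diagonals)) {
      keep <- !(diag %in% as.integer(exclude_diagonals))
      m <- m[keep, , drop = FALSE]
      diag <- diag[keep]
    }
    if (!is.null(self_length)) {
      # self-comparison of a doubled circular sequence: every repeat pair
      # has a representative with the query copy starting in the first
      # period and the subject copy not before it -- keep only those
      keep <- m[, 1] <= self_length & m[, 2] >= m[, 1]
      m <- m[keep, , drop = FALSE]
      diag <- diag[keep]
    }
    if (!nrow(m)) next
    o <- order(diag, m[, 1])
    e <- cpp_extend_seeds(query, sub2, m[o, 1], m[o, 2], as.integer(k),
                          scoring$match, scoring$mismatch, scoring$xdrop)
    h <- as_tibble(e)
    h$gaps <- 0L
    # cheap pre-filter before the gapped polish
    h <- filter(h, .data$length >= min_len | .data$length >= 2L * k)
    h <- filter(h, .data$matches / .data$length >= min_identity * 0.9)
    if (gapped && nrow(h)) {
      # perfect ungapped hits cannot gain from a gapped realignment
      h <- purrr::map_dfr(seq_len(nrow(h)), function(i) {
        if (h$matches[i] == h$length[i]) return(h[i, ])
        polish_hit(h[i, ], query, sub2, scoring, max_polish_cells)
      })
    }
    if (!nrow(h)) next
    h$identity <- h$matches / h$length
    out[[st]] <- map_hit_strand(h, ns, st)
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  strand = character(), length = integer(),
                  matches = integer(), identity = double(),
                  score = integer(), gaps = integer()))
  }
  res <- filter(res, .data$length >= min_len, .data$identity >= min_identity)
  res <- distinct(res, .data$q_start, .data$q_end, .data$s_start,
                  .data$s_end, .data$strand, .keep_all = TRUE)
  res <- drop_contained_hits(res)
  res <- select(res, "q_start", "q_end", "s_start", "s_end", "strand",
                "length", "matches", "identity", "score", "gaps")
  arrange(res, .data$strand, .data$q_start, .data$s_start)
}

# drop hits contained (query AND subject interval) in a higher-scoring hit
# on the same strand
drop_contained_hits <- function(h) {
  if (nrow(h) < 2) return(h)
  h <- arrange(h, dplyr::desc(.data$score), dplyr::desc(.data$length))
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    j <- which(keep & seq_len(nrow(h)) > i)
    if (!length(j)) next
    contained <- h$strand[j] == h$strand[i] &
      h$q_start[j] >= h$q_start[i] & h$q_end[j] <= h$q_end[i] &
      h$s_start[j] >= h$s_start[i] & h$s_end[j] <= h$s_end[i]
    keep[j[contained]] <- FALSE
  }
  h[keep, ]
}

#' Write alignment hits as tab-separated text
#'
#' Columns mirror the tabular blastn output ordering: query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, score.
#'
#' @param hits Tibble from [align_hits()].
#' @param path Output path.
#' @param query_id,subject_id Labels for the first two columns.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, query_id = "query",
                           subject_id = "subject") {
  out <- tibble(
    qseqid = query_id, sseqid = subject_id,
    pident = round(hits$identity * 100, 2), length = hits$length,
    mismatch = hits$length - hits$matches - hits$gaps,
    gaps = hits$gaps,
    qstart = hits$q_start, qend = hits$q_end,
    sstart = ifelse(hits$strand == "-", hits$s_end, hits$s_start),
    send = ifelse(hits$strand == "-", hits$s_start, hits$s_end),
    score = hits$score)
  readr::write_tsv(out, path)
  invisible(path)
}
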