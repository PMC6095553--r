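# Long-read evidence for repeat-mediated homologous recombination: reads
# spanning a full repeat copy plus flanking sequence on both sides are
# classified as parental (both flanks from one copy's genomic context) or
# recombined (flanks from different copies' contexts).

# contexts of both repeat copies, oriented so each reads like copy 1:
# list(L1, R1, L2, R2), each `flank + pad` bp (circular)
repeat_contexts <- function(genome, rp, flank, pad = 50L) {
  L <- nchar(genome)
  a1 <- rp$copy1_start
  b1 <- rp$copy1_end
  a2 <- rp$copy2_start
  b2 <- rp$copy2_end
  f <- flank + pad
  left_of <- function(p) circ_substr(genome, p - f, p - 1L)
  right_of <- function(p) circ_substr(genome, p + 1L, p + f)
  if (rp$orientation == "DR") {
    list(L1 = left_of(a1), R1 = right_of(b1),
         L2 = left_of(a2), R2 = right_of(b2))
  } else {
    list(L1 = left_of(a1), R1 = right_of(b1),
         L2 = revcomp(right_of(b2)), R2 = revcomp(left_of(a2)))
  }
}

#' Find reads spanning the total length of a repeat copy
#'
#' A read spans the repeat when the repeat sequence aligns within the read
#' over (essentially) its full length with at least `min_flank` additional
#' bases on both sides.
#'
#' @param reads Named character vector of read sequences.
#' @param genome DNA string (circular).
#' @param repeat_pair One row of an `mm_repeats` tibble.
#' @param min_flank Minimum flanking bases required on each side (>= 100).
#' @param word_size Seed word size for placing the repeat in reads.
#' @param edge_slack Tolerated shortfall (bp) at each repeat end.
#' @param scoring An [align_scoring()] scheme.
#' @return Tibble: `read_id`, `strand` (of the repeat within the read),
#'   `rep_start`, `rep_end` (repeat footprint in read coordinates). Empty,
#'   with a warning, when the repeat plus flanks exceeds every read length.
#' @export
find_spanning_reads <- function(reads, genome, repeat_pair,
                                min_flank = 500L, word_size = 15L,
                                edge_slack = 10L,
                                scoring = align_scoring()) {
  stopifnot(min_flank >= 100)
  rp <- as.list(repeat_pair)
  rep_seq <- circ_substr(genome, rp$copy1_start, rp$copy1_end)
  need <- nchar(rep_seq) + 2L * min_flank
  if (!length(reads) || max(nchar(reads)) < need) {
    warning("repeat plus flanks longer than the longest read; no spanning reads")
    return(tibble(read_id = character(), strand = character(),
                  rep_start = integer(), rep_end = integer()))
  }
  purrr::imap_dfr(reads, function(rd, id) {
    if (nchar(rd) < need) return(tibble())
    h <- align_hits(rep_seq, rd, k = word_size, scoring = scoring,
                    min_len = min(100L, nchar(rep_seq)),
                    min_identity = 0.80)
    if (!nrow(h)) return(tibble())
    h <- h[which.max(h$score), ]
    covered <- h$q_end - h$q_start + 1L
    if (covered < nchar(rep_seq) - 2L * edge_slack) return(tibble())
    if (h$s_start - 1L < min_flank) return(tibble())
    if (nchar(rd) - h$s_end < min_flank) return(tibble())
    tibble(read_id = id, strand = h$strand,
           rep_start = h$s_start, rep_end = h$s_end)
  })
}

#' Classify spanning reads as parental or recombined
#'
#' Each flank of a spanning read is aligned against the corresponding
#' genomic context of both repeat copies and assigned to the context with
#' the higher identity when the margin exceeds `margin`; otherwise the
#' flank is ambiguous. A read is `recombined` when both flanks are
#' unambiguous and point to different copies' contexts, `parental` when
#' both point to the same copy, and `uninformative` otherwise.
#'
#' @param reads Named character vector of read sequences.
#' @param genome DNA string (circular).
#' @param repeat_pair One row of an `mm_repeats` tibble.
#' @param min_flank Flank length compared on each side (bp).
#' @param margin Minimum identity difference to resolve a flank (fraction).
#' @param spanning Optional precomputed [find_spanning_reads()] result.
#' @param scoring An [align_scoring()] scheme.
#' @inheritParams find_spanning_reads
#' @return A `mm_read_calls` tibble: `read_id`, `left_copy`, `right_copy`
#'   (`"copy1"`/`"copy2"`/`"ambiguous"`), left/right identities against both
#'   contexts, and `call`.
#' @export
classify_spanning_reads <- function(reads, genome, repeat_pair,
                                    min_flank = 500L, margin = 0.02,
                                    word_size = 15L,
                                    spanning = NULL,
                                    scoring = align_scoring()) {
  rp <- as.list(repeat_pair)
  if (is.null(spanning)) {
    spanning <- find_spanning_reads(reads, genome, repeat_pair,
                                    min_flank = min_flank,
                                    word_size = word_size,
                                    scoring = scoring)
  }
  ctx <- repeat_contexts(genome, rp, min_flank)
  flank_id <- function(flank, context) {
    r <- cpp_sw_local(flank, context, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
    r[["matches"]] / nchar(flank)
  }
  assign_copy <- function(id1, id2) {
    if (abs(id1 - id2) < margin) "ambiguous"
    else if (id1 > id2) "copy1" else "copy2"
  }
  out <- purrr::map_dfr(seq_len(nrow(spanning)), function(i) {
    s <- spanning[i, ]
    rd <- reads[[s$read_id]]
    if (s$strand == "-") {
      n <- nchar(rd)
      rd <- revcomp(rd)
      rs <- n - s$rep_end + 1L
      re <- n - s$rep_start + 1L
    } else {
      rs <- s$rep_start
      re <- s$rep_end
    }
    lf <- substr(rd, rs - min_flank, rs - 1L)
    rf <- substr(rd, re + 1L, re + min_flank)
    li1 <- flank_id(lf, ctx$L1)
    li2 <- flank_id(lf, ctx$L2)
    ri1 <- flank_id(rf, ctx$R1)
    ri2 <- flank_id(rf, ctx$R2)
    lc <- assign_copy(li1, li2)
    rc <- assign_copy(ri1, ri2)
    call <- if (lc == "ambiguous" || rc == "ambiguous") "uninformative"
    else if (lc == rc) "parental" else "recombined"
    tibble(read_id = s$read_id, left_copy = lc, right_copy = rc,
           left_id1 = li1, left_id2 = li2, right_id1 = ri1,
           right_id2 = ri2, call = call)
  })
  if (!nrow(out)) {
    out <- tibble(read_id = character(), left_copy = character(),
                  right_copy = character(), left_id1 = double(),
                  left_id2 = double(), right_id1 = double(),
                  right_id2 = double(), call = character())
  }
  structure(out, class = c("mm_read_calls", class(tibble())))
}

# Wilson score interval for a binomial proportion
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Summarise recombination evidence at a repeat
#'
#' The reported statistic is recombined / spanning, with a Wilson 95
#' percent interval.
#'
#' @param calls A `mm_read_calls` tibble.
#' @return One-row tibble: `n_spanning`, `n_parental`, `n_recombined`,
#'   `n_uninformative`, `recomb_frac`, `recomb_lower`, `recomb_upper`.
#' @export
summarize_recombination <- function(calls) {
  n <- nrow(calls)
  nr <- sum(calls$call == "recombined")
  ci <- wilson_interval(nr, n)
  tibble(n_spanning = n,
         n_parental = sum(calls$call == "parental"),
         n_recombined = nr,
         n_uninformative = sum(calls$call == "uninformative"),
         recomb_frac = if (n > 0) nr / n else NA_real_,
         recomb_lower = ci[["lower"]], recomb_upper = ci[["upper"]])
}
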