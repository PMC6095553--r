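# broom-style tidiers for the package's result objects.

#' Tidy a repeat table
#'
#' @param x An `mm_repeats` object.
#' @param ... Unused.
#' @return The underlying tibble, one row per repeat pair.
#' @exportS3Method generics::tidy
tidy.mm_repeats <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a repeat scan
#'
#' @param x An `mm_repeats` object.
#' @param ... Unused.
#' @return One-row tibble: pair counts per size tier, repeat coverage and
#'   genome fraction.
#' @exportS3Method generics::glance
glance.mm_repeats <- function(x, ...) {
  summarize_repeats(x)
}

#' Tidy a pairwise DCJ matrix into a long pair table
#'
#' @param x An `mm_dcj` object.
#' @param ... Unused.
#' @return Tibble: `genome_a`, `genome_b`, `distance`, `n_shared`.
#' @exportS3Method generics::tidy
tidy.mm_dcj <- function(x, ...) {
  attr(x, "pairs")
}

#' One-row summary of a pairwise DCJ matrix
#'
#' @param x An `mm_dcj` object.
#' @param ... Unused.
#' @return One-row tibble: `n_genomes`, `mean_distance`, `max_distance`.
#' @exportS3Method generics::glance
glance.mm_dcj <- function(x, ...) {
  p <- attr(x, "pairs")
  tibble(n_genomes = nrow(unclass(x)),
         mean_distance = mean(p$distance),
         max_distance = max(p$distance))
}

#' Tidy a sharing report into per-genome rows
#'
#' @param x An `mm_sharing` object.
#' @param ... Unused.
#' @return Tibble with one row per genome of the pair.
#' @exportS3Method generics::tidy
tidy.mm_sharing <- function(x, ...) {
  bind_rows(
    tibble(genome = x$id_a, partner = x$id_b, length = x$length_a,
           shared_bp = x$shared_bp_a, shared_frac = x$shared_frac_a,
           unshared_bp = x$unshared_bp_a,
           unshared_frac = x$unshared_frac_a),
    tibble(genome = x$id_b, partner = x$id_a, length = x$length_b,
           shared_bp = x$shared_bp_b, shared_frac = x$shared_frac_b,
           unshared_bp = x$unshared_bp_b,
           unshared_frac = x$unshared_frac_b))
}

#' One-row summary of read-level recombination evidence
#'
#' @param x An `mm_read_calls` object.
#' @param ... Unused.
#' @return See [summarize_recombination()].
#' @exportS3Method generics::glance
glance.mm_read_calls <- function(x, ...) {
  summarize_recombination(x)
}
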