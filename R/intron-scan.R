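# Taxon-specific deletion blocks in orthologous intron alignments, and the
# search for short direct repeats at the deletion edges -- the signature of
# repeat-mediated recombination collapse, which leaves a single repeat copy
# at the deletion junction.

# alignment = named character vector of equal-length gapped sequences
check_alignment <- function(alignment) {
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    stop("alignment sequences must be named by taxon")
  }
  if (anyDuplicated(names(alignment))) {
    stop("duplicate taxon in alignment")
  }
  if (length(unique(nchar(alignment))) != 1) {
    stop("aligned sequences must have equal length")
  }
  invisible(alignment)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return Named character vector of gapped sequences.
#' @export
read_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  check_alignment(out)
}

#' Per-taxon, per-intron length table
#'
#' The ungapped length of each taxon in each alignment; a quantity that
#' depends only on per-taxon gap counts, so it is invariant to any column
#' permutation preserving residues. Taxa missing from an alignment
#' (relative to the union over all alignments) are flagged.
#'
#' @param alignments Named list of alignments (named character vectors).
#' @return A `mm_intron_lengths` tibble: `intron`, `taxon`, `length`
#'   (`NA` when absent), `present`.
#' @export
intron_length_table <- function(alignments) {
  stopifnot(length(alignments) >= 1, !is.null(names(alignments)))
  purrr::walk(alignments, check_alignment)
  taxa <- unique(unlist(lapply(alignments, names)))
  out <- purrr::imap_dfr(alignments, function(aln, intron) {
    len <- nchar(gsub("-", "", aln, fixed = TRUE))
    tibble(intron = intron, taxon = taxa,
           length = as.integer(len[match(taxa, names(aln))]),
           present = taxa %in% names(aln))
  })
  structure(out, class = c("mm_intron_lengths", class(tibble())))
}

#' Find taxon-specific deletion blocks in an alignment
#'
#' Maximal per-taxon gap runs (adjacent runs separated by fewer than
#' `merge_gap` columns are merged) whose length in reference bp -- columns
#' where at least one other taxon retains sequence -- reaches `min_del`.
#' Gaps shared by every taxon yield no block.
#'
#' @param alignment Named character vector of gapped sequences (>= 2 taxa).
#' @param min_del Minimum deletion length in reference bp.
#' @param merge_gap Merge gap runs separated by fewer than this many
#'   columns.
#' @return Tibble: `taxon`, `col_start`, `col_end` (alignment columns),
#'   `length_ref` (bp retained by at least one reference taxon),
#'   `affected_taxa` (comma-separated taxa whose gaps cover the block).
#' @export
find_deletion_blocks <- function(alignment, min_del = 50L, merge_gap = 10L) {
  check_alignment(alignment)
  if (length(alignment) < 2) stop("need at least 2 taxa")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  isgap <- m == "-"
  out <- purrr::map_dfr(rownames(m), function(tx) {
    g <- isgap[tx, ]
    r <- rle(g)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- tibble(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) return(tibble())
    # merge runs separated by < merge_gap columns
    merged <- runs[1, ]
    if (nrow(runs) > 1) {
      for (i in 2:nrow(runs)) {
        last <- nrow(merged)
        if (runs$start[i] - merged$end[last] - 1L < merge_gap) {
          merged$end[last] <- runs$end[i]
        } else {
          merged <- bind_rows(merged, runs[i, ])
        }
      }
    }
    others <- isgap[setdiff(rownames(m), tx), , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(merged)), function(i) {
      cols <- seq(merged$start[i], merged$end[i])
      ref_cols <- cols[colSums(!others[, cols, drop = FALSE]) > 0]
      if (length(ref_cols) < min_del) return(tibble())
      covered <- rownames(others)[
        rowSums(!others[, cols, drop = FALSE]) == 0]
      tibble(taxon = tx, col_start = merged$start[i],
             col_end = merged$end[i],
             length_ref = length(ref_cols),
             affected_taxa = paste(sort(c(tx, covered)), collapse = ","))
    })
  })
  if (!nrow(out)) {
    out <- tibble(taxon = character(), col_start = integer(),
                  col_end = integer(), length_ref = integer(),
                  affected_taxa = character())
  }
  arrange(out, .data$taxon, .data$col_start)
}

#' Map a deletion block to coordinates on a retaining taxon
#'
#' @param alignment Named character vector of gapped sequences.
#' @param block One row of [find_deletion_blocks()] output.
#' @param taxon A taxon retaining sequence across the block.
#' @return Named integer vector `c(del_start, del_end)`: the deleted
#'   interval in the retaining taxon's ungapped coordinates.
#' @export
deletion_in_retained <- function(alignment, block, taxon) {
  check_alignment(alignment)
  chars <- strsplit(alignment[[taxon]], "")[[1]]
  pos <- cumsum(chars != "-")
  cols <- seq(block$col_start, block$col_end)
  keep <- cols[chars[cols] != "-"]
  if (!length(keep)) {
    stop(sprintf("taxon %s retains no sequence across the block", taxon))
  }
  c(del_start = pos[keep[1]], del_end = pos[keep[length(keep)]])
}

#' Search for direct repeats at the edges of a deletion
#'
#' Looks for a direct repeat pair with one copy within `window` bp of each
#' deletion edge in the retaining taxon's (ungapped) sequence: the expected
#' footprint when recombination between the two copies collapsed the region
#' and left a single copy in the deleted lineage. A copy covering or
#' abutting an edge has offset 0; positive offsets run inward from the
#' edge. Only direct repeats are searched by default (set
#' `inverted = TRUE` to also screen the reverse complement).
#'
#' @param retained_seq Ungapped sequence of a taxon retaining the region.
#' @param del_start,del_end Deleted interval on `retained_seq` (1-based
#'   inclusive), e.g. from [deletion_in_retained()].
#' @param min_rep,max_rep Repeat length range searched (bp).
#' @param window Maximum offset of a copy from its deletion edge (bp).
#' @param max_mismatch Maximum mismatches between the two copies.
#' @param inverted Also search for inverted (reverse-complement) copies?
#' @return Tibble sorted by length descending: `seq`, `length`,
#'   `left_start`, `right_start` (copy starts on `retained_seq`),
#'   `left_offset`, `right_offset`, `mismatches`, `orientation`.
#' @export
edge_repeat_search <- function(retained_seq, del_start, del_end,
                               min_rep = 10L, max_rep = 40L, window = 5L,
                               max_mismatch = 0L, inverted = FALSE) {
  n <- nchar(retained_seq)
  if (del_start < 1 || del_end > n || del_end < del_start) {
    stop("deletion interval outside the retained sequence span")
  }
  if (window < 0) stop("window must be >= 0")
  chars <- strsplit(retained_seq, "")[[1]]
  hits <- list()
  # candidate left copies start near del_start; right copies end near del_end
  for (len in seq(max_rep, min_rep)) {
    p_range <- seq(max(1L, del_start - len - window),
                   min(n - len + 1L, del_start + window))
    q_range <- seq(max(1L, del_end - window - len + 1L),
                   min(n - len + 1L, del_end + window + 1L))
    for (p in p_range) {
      lo <- edge_offset(p, p + len - 1L, del_start, left = TRUE)
      if (lo > window) next
      left <- chars[p:(p + len - 1L)]
      for (q in q_range) {
        if (q <= p + len - 1L) next # copies must not overlap
        ro <- edge_offset(q, q + len - 1L, del_end, left = FALSE)
        if (ro > window) next
        right <- chars[q:(q + len - 1L)]
        mm <- sum(left != right)
        ori <- "direct"
        if (mm > max_mismatch && inverted) {
          rc <- rev(chartr("ACGT", "TGCA", right))
          mm2 <- sum(left != rc)
          if (mm2 <= max_mismatch) {
            mm <- mm2
            ori <- "inverted"
          }
        }
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1]] <- tibble(
            seq = paste(left, collapse = ""), length = len,
            left_start = p, right_start = q,
            left_offset = lo, right_offset = ro,
            mismatches = mm, orientation = ori)
        }
      }
    }
  }
  out <- bind_rows(hits)
  if (!nrow(out)) {
    return(tibble(seq = character(), length = integer(),
                  left_start = integer(), right_start = integer(),
                  left_offset = integer(), right_offset = integer(),
                  mismatches = integer(), orientation = character()))
  }
  # keep only maximal hits per copy-pair diagonal
  out <- mutate(out, .diag = .data$right_start - .data$left_start)
  out <- arrange(out, dplyr::desc(.data$length))
  out <- distinct(out, .data$.diag, .keep_all = TRUE)
  out <- select(out, -".diag")
  arrange(out, dplyr::desc(.data$length), .data$left_start)
}

# distance of copy [s, e] from a deletion edge: 0 when the copy covers or
# abuts the edge position, otherwise the gap inward/outward
edge_offset <- function(s, e, edge, left = TRUE) {
  if (left) {
    if (s > edge) return(s - edge)        # shifted inward
    if (e >= edge - 1L) return(0L)        # covers or abuts the edge
    (edge - 1L) - e                       # entirely outside, gap to edge
  } else {
    if (e < edge) return(edge - e)        # shifted inward
    if (s <= edge + 1L) return(0L)        # covers or abuts the edge
    s - (edge + 1L)                       # entirely outside
  }
}
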