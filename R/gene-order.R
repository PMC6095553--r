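# Signed gene orders and double-cut-and-join (DCJ) rearrangement distances.
# For circular single-chromosome genomes the DCJ distance is N - C, with N
# the number of shared genes and C the number of cycles in the adjacency
# graph; it is 0 exactly when the orders agree up to rotation and
# whole-genome reflection (the orientation of a circle is arbitrary).

#' Construct a signed gene order
#'
#' @param genes Character vector of gene symbols, in genomic order.
#' @param signs Integer vector of +1/-1 strands (or a character vector of
#'   `"+"`/`"-"`).
#' @param id Genome identifier.
#' @param topology `"circular"` or `"linear"`.
#' @return A `gene_order` object.
#' @export
gene_order <- function(genes, signs = rep(1L, length(genes)),
                       id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  signs <- as.integer(sign(signs))
  stopifnot(length(genes) == length(signs), all(signs != 0))
  if (!length(genes)) stop("empty gene order")
  if (anyDuplicated(genes)) stop("duplicated gene symbols in gene order")
  structure(list(id = id, genes = as.character(genes), signs = signs,
                 topology = topology),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s, %d genes)\n", x$id, x$topology,
              length(x$genes)))
  cat(paste0(ifelse(x$signs > 0, "+", "-"), x$genes, collapse = " "), "\n")
  invisible(x)
}

#' Extract the signed gene order from an annotation
#'
#' Gene features are sorted by start coordinate; the sign is the strand.
#' Trans-spliced genes (multiple `gene` rows sharing a symbol with
#' `trans_spliced = TRUE`) are collapsed to a single marker at their first
#' exon (`part == 1` when present, otherwise the lowest start). Other
#' duplicated symbols are resolved by the dedup policy with a warning.
#'
#' @param annotation Annotation tibble with `gene`-type rows.
#' @param id Genome identifier.
#' @param dedup Duplicate policy: `"drop-all"` removes every copy of a
#'   multi-copy gene; `"keep-first"` keeps the copy with the lowest start.
#' @param topology Genome topology.
#' @return A [gene_order()] object.
#' @export
extract_gene_order <- function(annotation, id = "genome",
                               dedup = c("drop-all", "keep-first"),
                               topology = c("circular", "linear")) {
  dedup <- match.arg(dedup)
  topology <- match.arg(topology)
  g <- filter(annotation, .data$type == "gene")
  if (!nrow(g)) stop("annotation contains no gene features")
  ts <- if (!is.null(g[["trans_spliced"]])) {
    ifelse(is.na(g[["trans_spliced"]]), FALSE, g[["trans_spliced"]])
  } else rep(FALSE, nrow(g))
  # collapse trans-spliced fragments to the first exon's fragment
  tsg <- unique(g$gene[ts])
  if (length(tsg)) {
    keep <- rep(TRUE, nrow(g))
    for (sym in tsg) {
      idx <- which(g$gene == sym)
      first <- if (!is.null(g[["part"]]) && !all(is.na(g[["part"]][idx]))) {
        idx[which.min(g[["part"]][idx])]
      } else idx[which.min(g$start[idx])]
      keep[setdiff(idx, first)] <- FALSE
    }
    g <- g[keep, ]
  }
  dup <- unique(g$gene[duplicated(g$gene)])
  if (length(dup)) {
    warning(sprintf("duplicated gene symbols (%s) resolved by policy '%s'",
                    paste(dup, collapse = ", "), dedup))
    if (dedup == "drop-all") {
      g <- filter(g, !(.data$gene %in% dup))
    } else {
      g <- g[order(g$start), ]
      g <- g[!duplicated(g$gene), ]
    }
  }
  g <- g[order(g$start), ]
  gene_order(g$gene, ifelse(g$strand == "-", -1L, 1L), id = id,
             topology = topology)
}

# restrict two orders to their shared gene set, preserving order/signs
restrict_shared <- function(a, b) {
  shared <- intersect(a$genes, b$genes)
  if (!length(shared)) stop("empty shared gene set")
  ka <- a$genes %in% shared
  kb <- b$genes %in% shared
  list(a = gene_order(a$genes[ka], a$signs[ka], a$id, a$topology),
       b = gene_order(b$genes[kb], b$signs[kb], b$id, b$topology))
}

# signed integer vector of order `x` relative to the gene indexing of `ref`
signed_relative <- function(x, ref) {
  idx <- match(x$genes, ref$genes)
  idx * x$signs
}

# adjacency matching over gene extremities (tail 2g-1, head 2g) of a
# circular signed order given as +-index vector
adjacency_matching <- function(perm) {
  n <- length(perm)
  partner <- integer(2L * n)
  for (i in seq_len(n)) {
    gi <- perm[i]
    gj <- perm[if (i == n) 1L else i + 1L]
    e1 <- if (gi > 0) 2L * gi else 2L * (-gi) - 1L          # right extremity
    e2 <- if (gj > 0) 2L * gj - 1L else 2L * (-gj)          # left extremity
    partner[e1] <- e2
    partner[e2] <- e1
  }
  partner
}

#' DCJ distance between two gene orders
#'
#' Orders are restricted to their shared gene set; the distance is
#' `N - C` over the adjacency-graph cycles. Only circular,
#' single-chromosome orders are supported.
#'
#' @param a,b [gene_order()] objects.
#' @return Non-negative integer DCJ distance.
#' @export
dcj_distance <- function(a, b) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  if (a$topology != "circular" || b$topology != "circular") {
    stop("DCJ distance is implemented for circular genomes")
  }
  r <- restrict_shared(a, b)
  pa <- adjacency_matching(signed_relative(r$a, r$a))
  pb <- adjacency_matching(signed_relative(r$b, r$a))
  n <- length(r$a$genes)
  # orbits of pb∘pa: each adjacency-graph cycle with 2k extremities splits
  # into exactly two orbits of size k, so C = orbits / 2
  seen <- rep(FALSE, 2L * n)
  orbits <- 0L
  for (e0 in seq_len(2L * n)) {
    if (seen[e0]) next
    orbits <- orbits + 1L
    e <- e0
    repeat {
      seen[e] <- TRUE
      e <- pb[pa[e]]
      if (e == e0) break
    }
  }
  as.integer(n - orbits %/% 2L)
}

#' Exhaustive BFS oracle for the DCJ distance
#'
#' Breadth-first search over all double-cut-and-join moves (including
#' intermediate multi-circular genomes) from the identity genome; exact by
#' construction and independent of the adjacency-graph cycle formula.
#' Limited to at most 8 shared genes.
#'
#' @param a,b [gene_order()] objects (circular).
#' @return Minimal number of DCJ operations.
#' @export
dcj_distance_bfs <- function(a, b) {
  r <- restrict_shared(a, b)
  if (length(r$a$genes) > 8) stop("BFS oracle supports at most 8 genes")
  # express b in a's coordinates so that a becomes the identity
  pa <- signed_relative(r$a, r$a) # identity by construction
  pb <- signed_relative(r$b, r$a)
  stopifnot(identical(pa, seq_along(pa) * 1L))
  as.integer(cpp_dcj_bfs(matrix(as.integer(pb), nrow = 1)))
}

# vectorized BFS distances from the identity for rows of signed circular
# permutations (internal; one shared BFS per call)
dcj_bfs_from_identity <- function(perms) {
  storage.mode(perms) <- "integer"
  as.integer(cpp_dcj_bfs(perms))
}

#' Pairwise DCJ rearrangement matrix
#'
#' @param orders List of [gene_order()] objects.
#' @return A `mm_dcj` object: the symmetric integer distance matrix with a
#'   `pairs` attribute holding the long-format pair table
#'   (`genome_a`, `genome_b`, `distance`, `n_shared`).
#' @export
pairwise_dcj <- function(orders) {
  stopifnot(length(orders) >= 2)
  ids <- vapply(orders, function(o) o$id, character(1))
  if (anyDuplicated(ids)) stop("duplicated genome ids")
  n <- length(orders)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- dcj_distance(orders[[i]], orders[[j]])
      m[i, j] <- m[j, i] <- d
      pairs[[length(pairs) + 1]] <- tibble(
        genome_a = ids[i], genome_b = ids[j], distance = d,
        n_shared = length(intersect(orders[[i]]$genes, orders[[j]]$genes)))
    }
  }
  structure(m, pairs = bind_rows(pairs), class = c("mm_dcj", "matrix"))
}

#' @export
print.mm_dcj <- function(x, ...) {
  cat("<mm_dcj> pairwise DCJ rearrangement distances\n")
  print(unclass(structure(x, pairs = NULL)))
  invisible(x)
}

#' Read gene orders from a UniMoG-style text file
#'
#' One genome per pair of lines: a `>id` header line (or `id:` prefix)
#' followed by signed gene symbols, terminated by `)` for circular or `|`
#' for linear genomes.
#'
#' @param path Input path.
#' @return List of [gene_order()] objects.
#' @export
read_gene_orders <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  cur_id <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur_id <- trimws(sub("^>", "", ln))
      next
    }
    if (grepl(":", ln, fixed = TRUE) && is.null(cur_id)) {
      cur_id <- trimws(sub(":.*$", "", ln))
      ln <- sub("^[^:]*:", "", ln)
    }
    if (is.null(cur_id)) stop("gene order line without a genome id")
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    topo <- "circular"
    if (length(toks) && toks[length(toks)] %in% c(")", "|")) {
      topo <- if (toks[length(toks)] == ")") "circular" else "linear"
      toks <- toks[-length(toks)]
    }
    signs <- ifelse(startsWith(toks, "-"), -1L, 1L)
    genes <- sub("^[+-]", "", toks)
    out[[length(out) + 1]] <- gene_order(genes, signs, id = cur_id,
                                         topology = topo)
    cur_id <- NULL
  }
  out
}

#' Write gene orders in the UniMoG-style dialect
#'
#' @param orders List of [gene_order()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- unlist(lapply(orders, function(o) {
    body <- paste0(ifelse(o$signs > 0, "", "-"), o$genes, collapse = " ")
    term <- if (o$topology == "circular") ")" else "|"
    c(paste0(">", o$id), paste(body, term))
  }))
  writeLines(lines, path)
  invisible(path)
}
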