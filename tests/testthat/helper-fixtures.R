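# shared fixtures and oracles, all built in code

# overwrite genome[tgt_start..] with a (possibly mutated / reverse
# complemented) copy of genome[src_start..src_end]
plant_copy <- function(genome, src_start, src_end, tgt_start,
                       ir = FALSE, identity = 100, seed = NULL) {
  copy <- substr(genome, src_start, src_end)
  if (identity < 100) {
    copy <- mitomosaic:::with_local_seed(seed %||% 1L,
      mitomosaic:::mutate_to_identity(copy, identity))
  }
  if (ir) copy <- revcomp(copy)
  substr(genome, tgt_start, tgt_start + nchar(copy) - 1L) <- copy
  genome
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# match planted repeat pairs against found pairs with coordinate slack
# (extension may run a few bases into flanking sequence that matches by
# chance); returns precision/recall over the >= 100 bp tier
match_repeat_pairs <- function(truth, found, slack = 10L) {
  if (!nrow(truth)) {
    return(list(precision = as.numeric(!nrow(found)), recall = 1))
  }
  hit <- function(t, f) {
    abs(f$copy1_start - t$copy1_start) <= slack &
      abs(f$copy1_end - t$copy1_end) <= slack &
      abs(f$copy2_start - t$copy2_start) <= slack &
      abs(f$copy2_end - t$copy2_end) <= slack &
      f$orientation == t$orientation
  }
  matched_t <- vapply(seq_len(nrow(truth)), function(i) {
    any(hit(truth[i, ], found))
  }, logical(1))
  matched_f <- vapply(seq_len(nrow(found)), function(j) {
    any(vapply(seq_len(nrow(truth)), function(i) {
      hit(truth[i, ], found[j, ])
    }, logical(1)))
  }, logical(1))
  list(precision = mean(matched_f), recall = mean(matched_t))
}

# brute-force k-mer seed enumeration (independent oracle for find_seeds)
brute_seeds <- function(query, subject, k) {
  res <- list()
  for (st in c("+", "-")) {
    s2 <- if (st == "-") revcomp(subject) else subject
    for (i in seq_len(nchar(query) - k + 1)) {
      qk <- substr(query, i, i + k - 1)
      if (grepl("N", qk)) next
      for (j in seq_len(nchar(s2) - k + 1)) {
        if (qk == substr(s2, j, j + k - 1) &&
            !grepl("N", substr(s2, j, j + k - 1))) {
          sj <- if (st == "-") nchar(subject) - j - k + 2L else j
          res[[length(res) + 1]] <- data.frame(q_start = i, s_start = sj,
                                               strand = st)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(q_start = integer(), s_start = integer(),
                      strand = character())
  }
  out[order(out$strand, out$q_start, out$s_start), , drop = FALSE]
}

# random signed circular permutations relative to the identity, as an
# integer matrix (one row each)
random_signed_perms <- function(n_perms, n_genes) {
  t(replicate(n_perms, {
    p <- sample(n_genes)
    s <- sample(c(-1L, 1L), n_genes, replace = TRUE)
    as.integer(p * s)
  }))
}

# all signed circular permutations of n genes with gene 1 fixed at +1
# (one representative per rotation class)
all_signed_perms <- function(n) {
  if (n < 2) return(matrix(1L, 1, 1))
  perms <- mitomosaic:::perms_of(2:n)
  rows <- list()
  for (p in perms) {
    for (mask in 0:(2^(n - 1) - 1)) {
      signs <- ifelse(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0, -1L, 1L)
      rows[[length(rows) + 1]] <- c(1L, as.integer(p * signs))
    }
  }
  do.call(rbind, rows)
}

# signed-permutation row -> gene_order on letters
order_from_row <- function(row, id = "x") {
  gene_order(letters[abs(row)], sign(row), id = id)
}

# fixture: genome with one clean repeat pair for read-evidence tests
recomb_fixture <- function(L = 30000L, rep_len = 2000L, ir = FALSE,
                           seed = 21L) {
  g <- random_dna(L, 0.45, seed = seed)
  g <- plant_copy(g, 5000L, 5000L + rep_len - 1L, 20000L, ir = ir)
  rp <- find_repeats(g, min_len = 1000L)
  stopifnot(nrow(rp) == 1)
  list(genome = g, repeat_pair = rp[1, ])
}
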