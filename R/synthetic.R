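# Seeded generator of circular mitogenome-like test data: random background
# at a target GC with an annotated gene complement, planted repeat pairs,
# pseudogene fragments, derived genome pairs, intron alignments with
# repeat-flanked deletions, codon alignments at known divergence, and
# simulated long reads -- each with machine-readable ground truth.

#' Default gene roster for synthetic genomes
#'
#' A plant-mitochondrial-style complement: ~30 protein-coding genes (a few
#' with cis-spliced introns, two trans-spliced), three rRNAs and five
#' tRNAs. Lengths are typical CDS/structural-RNA lengths.
#'
#' @return Tibble: `gene`, `type`, `length` (total exon bp), `strand`,
#'   `introns` (list-column of intron lengths), `trans_spliced`.
#' @export
default_gene_roster <- function() {
  protein <- tibble(
    gene = c("atp1", "atp4", "atp6", "atp8", "atp9", "ccmB", "ccmC",
             "ccmFc", "ccmFn", "cob", "cox1", "cox2", "cox3", "matR",
             "mttB", "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5",
             "nad6", "nad7", "nad9", "rpl5", "rpl16", "rps3", "rps4",
             "rps10", "rps12", "rps14"),
    type = "gene",
    length = c(1530L, 600L, 720L, 480L, 225L, 621L, 753L, 1320L, 1740L,
               1182L, 1584L, 780L, 798L, 1950L, 750L, 978L, 1467L, 357L,
               1488L, 303L, 2010L, 618L, 1185L, 573L, 555L, 540L, 1680L,
               1050L, 360L, 378L, 300L),
    strand = c("+", "-", "+", "+", "-", "+", "+", "+", "-", "+", "+",
               "-", "+", "+", "-", "+", "-", "+", "+", "-", "+", "-",
               "+", "+", "-", "+", "+", "-", "+", "+", "-"))
  protein$introns <- rep(list(integer()), nrow(protein))
  protein$introns[protein$gene == "ccmFc"] <- list(900L)
  protein$introns[protein$gene == "cox2"] <- list(800L)
  protein$introns[protein$gene == "nad4"] <- list(1000L)
  protein$introns[protein$gene == "nad7"] <- list(900L)
  protein$introns[protein$gene == "rps3"] <- list(800L)
  protein$introns[protein$gene == "rps10"] <- list(750L)
  protein$trans_spliced <- protein$gene %in% c("nad1", "nad5")
  rrna <- tibble(gene = c("rrn5", "rrn18", "rrn26"), type = "rRNA",
                 length = c(118L, 1935L, 3500L), strand = "+",
                 introns = list(integer(), integer(), integer()),
                 trans_spliced = FALSE)
  trna <- tibble(gene = paste0("trn", c("M", "W", "P", "fM", "D")),
                 type = "tRNA", length = c(73L, 74L, 75L, 74L, 74L),
                 strand = c("+", "-", "+", "+", "-"),
                 introns = rep(list(integer()), 5), trans_spliced = FALSE)
  bind_rows(protein, rrna, trna)
}

#' Default planted-repeat spectrum
#'
#' One large direct repeat of 2,160 bp plus twenty medium repeats whose
#' sizes, orientations and identities follow the repeat spectrum annotated
#' on the S. japonica mitogenome (see [mt_repeat_table()]), including the
#' one borderline pair below 80 percent identity.
#'
#' @return Tibble: `size`, `orientation`, `identity` (percent).
#' @export
default_repeat_spec <- function() {
  tb <- mt_repeat_table()
  tibble(size = tb$size, orientation = tb$type, identity = tb$identity)
}

#' Default planted pseudogene-fragment spec
#'
#' Fragments below 100 bp so that planted pseudogenes and planted repeats
#' occupy disjoint size tiers in the default blueprint (dedicated
#' pseudogene blueprints may span the full 28-182 bp envelope).
#'
#' @return Tibble: `gene`, `length`, `identity` (percent).
#' @export
default_pseudogene_spec <- function() {
  tibble(gene = c("atp6", "rpl5", "cox2", "nad9", "rps4", "atp1"),
         length = c(28L, 45L, 60L, 75L, 88L, 95L),
         identity = c(100, 98, 96, 95, 93, 92))
}

#' Blueprint for a synthetic circular mitogenome
#'
#' The defaults define the generator's standard conditions: a 100 kb
#' circular molecule (a 5x scale-down keeping the full gene complement) at
#' GC 0.454, carrying the default repeat spectrum and pseudogene set.
#'
#' @param seed Integer seed; every feature of the realised genome is
#'   reproducible from it.
#' @param length Genome length (bp).
#' @param gc Target GC fraction.
#' @param genes Gene roster tibble ([default_gene_roster()] layout).
#' @param repeats Planted-repeat tibble (`size`, `orientation`,
#'   `identity`), or `NULL` for none.
#' @param pseudogenes Planted pseudogene tibble (`gene`, `length`,
#'   `identity`), or `NULL` for none.
#' @return A `genome_blueprint` list.
#' @export
genome_blueprint <- function(seed = 1L, length = 100000L, gc = 0.454,
                             genes = default_gene_roster(),
                             repeats = default_repeat_spec(),
                             pseudogenes = default_pseudogene_spec()) {
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 gc = gc, genes = genes, repeats = repeats,
                 pseudogenes = pseudogenes),
            class = "genome_blueprint")
}

# sample a placement interval of `width` from the free-interval set,
# removing it (plus a margin) from the set; NULL when nothing fits
take_free_interval <- function(free, width, margin = 2L) {
  ok <- which(free$end - free$start + 1L >= width)
  if (!length(ok)) return(NULL)
  w <- (free$end[ok] - free$start[ok] + 1L) - width + 1L
  gi <- ok[sample.int(length(ok), 1, prob = w)]
  off <- sample.int(free$end[gi] - free$start[gi] + 2L - width, 1) - 1L
  start <- free$start[gi] + off
  end <- start + width - 1L
  cut_lo <- max(free$start[gi], start - margin)
  cut_hi <- min(free$end[gi], end + margin)
  left <- if (cut_lo > free$start[gi]) {
    tibble(start = free$start[gi], end = cut_lo - 1L)
  } else tibble()
  right <- if (cut_hi < free$end[gi]) {
    tibble(start = cut_hi + 1L, end = free$end[gi])
  } else tibble()
  list(interval = c(start, end),
       free = bind_rows(free[-gi, ], left, right))
}

# place at the start of a (randomly chosen, capacity-weighted) gap:
# keeps fragmentation low while leaving gap remainders for later features
take_free_at_start <- function(free, width, margin = 2L) {
  ok <- which(free$end - free$start + 1L >= width)
  if (!length(ok)) return(NULL)
  w <- (free$end[ok] - free$start[ok] + 1L) - width + 1L
  gi <- ok[sample.int(length(ok), 1, prob = w)]
  start <- free$start[gi]
  end <- start + width - 1L
  cut_hi <- min(free$end[gi], end + margin)
  right <- if (cut_hi < free$end[gi]) {
    tibble(start = cut_hi + 1L, end = free$end[gi])
  } else tibble()
  list(interval = c(start, end), free = bind_rows(free[-gi, ], right))
}

mutate_to_identity <- function(seq, identity) {
  n <- nchar(seq)
  # floor: the realised identity is never below the requested one
  k <- floor(n * (1 - identity / 100))
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic circular genome with planted features
#'
#' Background bases are i.i.d. at the requested GC. Genes (with introns;
#' trans-spliced genes as two separated fragments) are placed in random
#' order with random spacer widths; repeat pairs and pseudogene fragments
#' are then planted into unoccupied spacer sequence. Identical seeds give
#' byte-identical outputs.
#'
#' @param blueprint A [genome_blueprint()].
#' @return List with class `mm_synth_genome`: `genome` (DNA string),
#'   `annotation` (tibble), `truth` (list of tibbles: `repeats`,
#'   `pseudogenes`), `blueprint`.
#' @export
generate_genome <- function(blueprint = genome_blueprint()) {
  bp <- blueprint
  with_local_seed(bp$seed, {
    L <- bp$length
    # expand roster into placement units (trans-spliced genes: 2 fragments)
    units <- list()
    for (i in seq_len(nrow(bp$genes))) {
      g <- bp$genes[i, ]
      introns <- g$introns[[1]]
      if (isTRUE(g$trans_spliced)) {
        half <- g$length %/% 2L
        units[[length(units) + 1]] <- list(
          gene = g$gene, type = g$type, strand = g$strand, part = 1L,
          trans = TRUE, exons = half, introns = integer())
        units[[length(units) + 1]] <- list(
          gene = g$gene, type = g$type, strand = g$strand, part = 2L,
          trans = TRUE, exons = g$length - half, introns = integer())
      } else {
        n_ex <- length(introns) + 1L
        ex <- rep(g$length %/% n_ex, n_ex)
        ex[n_ex] <- g$length - sum(ex[-n_ex])
        units[[length(units) + 1]] <- list(
          gene = g$gene, type = g$type, strand = g$strand, part = NA_integer_,
          trans = FALSE, exons = ex, introns = introns)
      }
    }
    unit_len <- vapply(units, function(u) sum(u$exons) + sum(u$introns),
                       integer(1))
    total_units <- sum(unit_len)
    if (total_units >= L) {
      stop(sprintf(
        "blueprint unsatisfiable: gene complement (%d bp) exceeds genome length (%d bp)",
        total_units, L))
    }
    ord <- sample.int(length(units))
    units <- units[ord]
    unit_len <- unit_len[ord]
    genome <- random_dna(L, bp$gc)
    free <- tibble(start = 1L, end = L)
    # plant repeats first (largest first: they need the longest gaps)
    truth_rep <- tibble()
    if (!is.null(bp$repeats) && nrow(bp$repeats)) {
      spec <- arrange(bp$repeats, dplyr::desc(.data$size))
      for (i in seq_len(nrow(spec))) {
        size <- spec$size[i]
        src <- take_free_interval(free, size)
        if (is.null(src)) stop(sprintf(
          "blueprint unsatisfiable: no room for a %d bp repeat copy", size))
        free <- src$free
        tgt <- take_free_interval(free, size)
        if (is.null(tgt)) stop(sprintf(
          "blueprint unsatisfiable: no room for the second %d bp repeat copy",
          size))
        free <- tgt$free
        seq1 <- substr(genome, src$interval[1], src$interval[2])
        seq2 <- mutate_to_identity(seq1, spec$identity[i])
        if (spec$orientation[i] == "IR") seq2 <- revcomp(seq2)
        substr(genome, tgt$interval[1], tgt$interval[2]) <- seq2
        ivs <- rbind(src$interval, tgt$interval)
        ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
        truth_rep <- bind_rows(truth_rep, tibble(
          copy1_start = ivs[1, 1], copy1_end = ivs[1, 2],
          copy2_start = ivs[2, 1], copy2_end = ivs[2, 2],
          size = size, orientation = spec$orientation[i],
          identity = spec$identity[i]))
      }
      truth_rep <- arrange(truth_rep, .data$copy1_start)
    }
    # place gene units largest-first as [spacer][unit] blocks anchored at
    # gap starts: realistic variable spacers, and the spacer shrinks to
    # zero when space gets tight so packing stays feasible
    ord2 <- order(unit_len, decreasing = TRUE)
    units <- units[ord2]
    unit_len <- unit_len[ord2]
    slack <- sum(free$end - free$start + 1L) - sum(unit_len)
    mean_sp <- max(10, slack / (2 * (length(units) + 1)))
    ann <- list()
    for (i in seq_along(units)) {
      u <- units[[i]]
      sp <- min(round(stats::rexp(1, 1 / mean_sp)), round(3 * mean_sp))
      placed <- take_free_at_start(free, unit_len[i] + sp)
      if (is.null(placed)) {
        sp <- 0L
        placed <- take_free_at_start(free, unit_len[i])
      }
      if (is.null(placed)) {
        stop(sprintf(
          "blueprint unsatisfiable: no room for gene %s (%d bp)",
          u$gene, unit_len[i]))
      }
      free <- placed$free
      gstart <- placed$interval[1] + sp
      piece_types <- c(rbind(rep("exon", length(u$exons)),
                             c(rep("intron", length(u$introns)), NA)))
      piece_types <- piece_types[!is.na(piece_types)]
      piece_len <- c(rbind(u$exons, c(u$introns, NA)))
      piece_len <- piece_len[!is.na(piece_len)]
      p <- gstart
      for (j in seq_along(piece_types)) {
        ann[[length(ann) + 1]] <- tibble(
          type = piece_types[j], start = p, end = p + piece_len[j] - 1L,
          strand = u$strand, gene = u$gene, part = u$part,
          trans_spliced = u$trans)
        p <- p + piece_len[j]
      }
      ann[[length(ann) + 1]] <- tibble(
        type = if (u$type == "gene") "gene" else u$type,
        start = gstart, end = p - 1L, strand = u$strand, gene = u$gene,
        part = u$part, trans_spliced = u$trans)
    }
    annotation <- arrange(bind_rows(ann), .data$start, .data$end)
    # plant pseudogene fragments
    truth_pseudo <- tibble()
    if (!is.null(bp$pseudogenes) && nrow(bp$pseudogenes)) {
      gseqs <- gene_sequences(genome, annotation)
      for (i in seq_len(nrow(bp$pseudogenes))) {
        ps <- bp$pseudogenes[i, ]
        gs <- gseqs[[ps$gene]]
        if (is.null(gs) || nchar(gs) < ps$length) {
          stop(sprintf("blueprint unsatisfiable: pseudogene source %s too short",
                       ps$gene))
        }
        off <- sample.int(nchar(gs) - ps$length + 1L, 1)
        frag <- mutate_to_identity(substr(gs, off, off + ps$length - 1L),
                                   ps$identity)
        tgt <- take_free_interval(free, ps$length)
        if (is.null(tgt)) stop(sprintf(
          "blueprint unsatisfiable: no room for a %d bp pseudogene fragment",
          ps$length))
        free <- tgt$free
        substr(genome, tgt$interval[1], tgt$interval[2]) <- frag
        truth_pseudo <- bind_rows(truth_pseudo, tibble(
          gene = ps$gene, start = tgt$interval[1], end = tgt$interval[2],
          length = ps$length, identity = ps$identity))
      }
      truth_pseudo <- arrange(truth_pseudo, .data$start)
    }
    structure(list(genome = genome, annotation = annotation,
                   truth = list(repeats = truth_rep,
                                pseudogenes = truth_pseudo),
                   blueprint = bp),
              class = "mm_synth_genome")
  })
}

#' @export
print.mm_synth_genome <- function(x, ...) {
  cat(sprintf(
    "<mm_synth_genome> %d bp, GC %.3f, %d gene features, %d planted repeat pairs, %d pseudogene fragments\n",
    nchar(x$genome), gc_fraction(x$genome),
    sum(x$annotation$type %in% c("gene", "tRNA", "rRNA")),
    nrow(x$truth$repeats), nrow(x$truth$pseudogenes)))
  invisible(x)
}

#' Spliced gene sequences from a genome and annotation
#'
#' Exon sequences are concatenated in genomic order (fragments of
#' trans-spliced genes by `part` rank) and reverse-complemented for
#' minus-strand genes. Features without exon rows (tRNA/rRNA) use their
#' full span.
#'
#' @param genome DNA string.
#' @param annotation Annotation tibble.
#' @return Named character vector of gene sequences.
#' @export
gene_sequences <- function(genome, annotation) {
  genes <- filter(annotation, .data$type %in% c("gene", "tRNA", "rRNA"))
  syms <- unique(genes$gene)
  out <- setNames(character(length(syms)), syms)
  for (sym in syms) {
    ex <- filter(annotation, .data$type == "exon", .data$gene == sym)
    if (!nrow(ex)) {
      ex <- filter(genes, .data$gene == sym)
    }
    ex <- ex[order(ex$start), ]
    pieces <- substring(genome, ex$start, ex$end)
    strand <- genes$strand[genes$gene == sym][1]
    seq <- paste(pieces, collapse = "")
    out[[sym]] <- if (strand == "-") revcomp(seq) else seq
  }
  out
}

#' Derive a diverged companion genome
#'
#' Applies uniform substitutions and inserts unique random segments; the
#' ground truth records every inserted interval (on the derived
#' coordinates), so the expected shared fraction is available in closed
#' form (`L / (L + total insertion)` at zero substitution divergence).
#'
#' @param genome DNA string.
#' @param substitution_rate Per-base substitution probability.
#' @param n_insertions Number of inserted unique segments.
#' @param insertion_length Length of each inserted segment (bp).
#' @param gc GC fraction of inserted sequence.
#' @param seed Integer seed.
#' @return List: `genome` (derived), `truth` (tibble of inserted intervals
#'   on the derived genome, plus `n_substitutions`).
#' @export
derive_genome <- function(genome, substitution_rate = 0,
                          n_insertions = 0L, insertion_length = 10000L,
                          gc = 0.454, seed = 1L) {
  with_local_seed(seed, {
    L <- nchar(genome)
    g <- genome
    nsub <- 0L
    if (substitution_rate > 0) {
      pos <- which(runif(L) < substitution_rate)
      nsub <- length(pos)
      if (nsub) {
        chars <- strsplit(g, "")[[1]]
        for (p in pos) {
          chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
        }
        g <- paste(chars, collapse = "")
      }
    }
    ins_truth <- tibble(start = integer(), end = integer())
    if (n_insertions > 0) {
      at <- sort(sample.int(nchar(g), n_insertions))
      segs <- vapply(seq_len(n_insertions), function(i) {
        random_dna(insertion_length, gc)
      }, character(1))
      parts <- character(0)
      prev <- 1L
      shift <- 0L
      starts <- integer(n_insertions)
      for (i in seq_len(n_insertions)) {
        parts <- c(parts, substr(g, prev, at[i]), segs[i])
        starts[i] <- at[i] + shift + 1L
        shift <- shift + insertion_length
        prev <- at[i] + 1L
      }
      parts <- c(parts, substr(g, prev, nchar(g)))
      g <- paste(parts, collapse = "")
      ins_truth <- tibble(start = starts,
                          end = starts + insertion_length - 1L)
    }
    list(genome = g,
         truth = list(insertions = ins_truth, n_substitutions = nsub))
  })
}

#' Apply random non-overlapping segment inversions to a gene order
#'
#' Inverted segments are separated by at least one untouched gene so every
#' inversion breaks distinct adjacencies.
#'
#' @param order A [gene_order()].
#' @param k Number of inversions.
#' @param seed Integer seed.
#' @return List: `order` (evolved [gene_order()]), `truth` (tibble of
#'   inverted index ranges on the original order).
#' @export
evolve_gene_order <- function(order, k, seed = 1L) {
  with_local_seed(seed, {
    n <- length(order$genes)
    if (3 * k + 1 > n) stop("too many inversions for this gene count")
    # choose k disjoint segments, each flanked by >= 1 untouched gene,
    # and never covering position 1 (keeps the circular frame fixed)
    repeat {
      bounds <- sort(sample(2:n, 2L * k))
      starts <- bounds[seq(1, 2 * k, 2)]
      ends <- bounds[seq(2, 2 * k, 2)]
      if (all(starts[-1] - ends[-k] >= 2)) break
    }
    genes <- order$genes
    signs <- order$signs
    for (i in seq_len(k)) {
      idx <- seq(starts[i], ends[i])
      genes[idx] <- rev(genes[idx])
      signs[idx] <- -rev(signs[idx])
    }
    list(order = gene_order(genes, signs, id = paste0(order$id, "_inv"),
                            topology = order$topology),
         truth = tibble(start = starts, end = ends))
  })
}

#' Simulate long reads from a circular genome
#'
#' Read start positions are uniform on the circle (sampling from the
#' doubled sequence); read lengths are normal around `mean_length`
#' (sd 10 percent, floored at 200 bp); half the reads are
#' reverse-complemented; sequencing errors are uniform substitutions.
#'
#' @param genome DNA string.
#' @param coverage Target mean coverage depth.
#' @param mean_length Mean read length (bp).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List: `reads` (named character vector), `truth` (tibble:
#'   `read_id`, `start`, `end` on the circle, `strand`).
#' @export
simulate_reads <- function(genome, coverage = 15, mean_length = 14389L,
                           error_rate = 0, seed = 1L) {
  with_local_seed(seed, {
    L <- nchar(genome)
    n <- max(1L, round(coverage * L / mean_length))
    lens <- pmax(200L, pmin(2L * mean_length,
                            round(stats::rnorm(n, mean_length,
                                               0.1 * mean_length))))
    lens <- pmin(lens, L)
    starts <- sample.int(L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("read_%04d", seq_len(n))
    reads <- vapply(seq_len(n), function(i) {
      s <- circ_substr(genome, starts[i], starts[i] + lens[i] - 1L)
      s <- apply_read_errors(s, error_rate)
      if (strands[i] == "-") revcomp(s) else s
    }, character(1))
    names(reads) <- ids
    list(reads = reads,
         truth = tibble(read_id = ids, start = starts,
                        end = starts + lens - 1L, strand = strands))
  })
}

apply_read_errors <- function(seq, error_rate) {
  if (error_rate <= 0) return(seq)
  n <- nchar(seq)
  pos <- which(runif(n) < error_rate)
  if (!length(pos)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate reads spanning a repeat pair, with a recombined fraction
#'
#' Parental reads are contiguous genome substrings across one repeat copy;
#' recombined reads swap the right flank for the other copy's genomic
#' context (the product of homologous recombination between the copies).
#' Truth labels are emitted per read.
#'
#' @param genome DNA string (circular).
#' @param repeat_pair One row of an `mm_repeats` tibble (or the truth
#'   layout of [generate_genome()]).
#' @param n_reads Number of spanning reads.
#' @param recombined_fraction Probability that a read is recombined.
#' @param flank Minimum genomic flank on each side of the repeat (bp).
#' @param extra Additional random flank length (uniform 0..extra bp).
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return List: `reads` (named character vector), `truth` (tibble:
#'   `read_id`, `origin_left`, `origin_right`, `strand`, `label`).
#' @export
simulate_spanning_reads <- function(genome, repeat_pair, n_reads = 30L,
                                    recombined_fraction = 0, flank = 1000L,
                                    extra = 500L, error_rate = 0,
                                    seed = 1L) {
  rp <- as.list(repeat_pair)
  if (is.null(rp$orientation)) rp$orientation <- "DR"
  with_local_seed(seed, {
    rep_seq <- circ_substr(genome, rp$copy1_start, rp$copy1_end)
    pad <- flank + extra
    ctx <- repeat_contexts(genome, rp, flank = pad, pad = 0L)
    ids <- sprintf("span_%04d", seq_len(n_reads))
    labels <- ifelse(runif(n_reads) < recombined_fraction,
                     "recombined", "parental")
    lefts <- sample(c("copy1", "copy2"), n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    reads <- character(n_reads)
    rights <- character(n_reads)
    for (i in seq_len(n_reads)) {
      lf <- flank + sample.int(extra + 1L, 1) - 1L
      rf <- flank + sample.int(extra + 1L, 1) - 1L
      rights[i] <- if (labels[i] == "recombined") {
        setdiff(c("copy1", "copy2"), lefts[i])
      } else lefts[i]
      lctx <- if (lefts[i] == "copy1") ctx$L1 else ctx$L2
      rctx <- if (rights[i] == "copy1") ctx$R1 else ctx$R2
      rd <- paste0(substr(lctx, nchar(lctx) - lf + 1L, nchar(lctx)),
                   rep_seq,
                   substr(rctx, 1L, rf))
      rd <- apply_read_errors(rd, error_rate)
      reads[i] <- if (strands[i] == "-") revcomp(rd) else rd
    }
    names(reads) <- ids
    list(reads = reads,
         truth = tibble(read_id = ids, origin_left = lefts,
                        origin_right = rights, strand = strands,
                        label = labels))
  })
}

#' Simulate an orthologous intron alignment with a repeat-flanked deletion
#'
#' Builds an ancestral intron, optionally plants a direct repeat pair at
#' the edges of a deletion block (offsets measured inward from the edges),
#' and deletes the block from the chosen taxa. Substitutions, when
#' requested, avoid a 20 bp guard zone around the block so the planted
#' signal stays exact.
#'
#' @param taxa Character vector of taxon names.
#' @param deleted_taxa Taxa carrying the deletion.
#' @param intron_length Ancestral intron length (columns).
#' @param deletion_length Deleted block length (bp).
#' @param edge_repeat_length Planted repeat length, or `NULL`/0 to plant
#'   none (edges are then screened to be repeat-free).
#' @param edge_offset Length-2 inward offsets of the two copies from the
#'   block edges.
#' @param sub_rate Per-base substitution probability per taxon (outside
#'   the guard zone).
#' @param gc GC fraction of the ancestral sequence.
#' @param seed Integer seed.
#' @param min_screen Minimum repeat length screened away for repeat-free
#'   edges.
#' @return List: `alignment` (named character vector with `-` gaps),
#'   `truth` (list: `del_start`, `del_end` in retained/column coordinates,
#'   `repeat_length`, `offsets`, planted copy starts, `deleted_taxa`).
#' @export
simulate_intron_alignment <- function(taxa = c("t1", "t2", "t3", "t4"),
                                      deleted_taxa = "t4",
                                      intron_length = 2000L,
                                      deletion_length = 800L,
                                      edge_repeat_length = 15L,
                                      edge_offset = c(0L, 0L),
                                      sub_rate = 0, gc = 0.45,
                                      seed = 1L, min_screen = 10L) {
  stopifnot(all(deleted_taxa %in% taxa),
            length(setdiff(taxa, deleted_taxa)) >= 1)
  if (length(edge_offset) == 1) edge_offset <- rep(edge_offset, 2)
  with_local_seed(seed, {
    M <- intron_length
    d1 <- (M - deletion_length) %/% 2L + 1L
    d2 <- d1 + deletion_length - 1L
    plant <- !is.null(edge_repeat_length) && edge_repeat_length >= 1
    tries <- 0L
    repeat {
      tries <- tries + 1L
      base <- random_dna(M, gc)
      if (plant) {
        ell <- edge_repeat_length
        o1 <- edge_offset[1]
        o2 <- edge_offset[2]
        stopifnot(d1 + o1 + ell - 1L < d2 - o2 - ell + 1L)
        copy <- random_dna(ell, gc)
        substr(base, d1 + o1, d1 + o1 + ell - 1L) <- copy
        substr(base, d2 - o2 - ell + 1L, d2 - o2) <- copy
        # the planted pair must be the unique maximal edge repeat
        found <- edge_repeat_search(base, d1, d2, min_rep = min_screen,
                                    max_rep = ell + 5L, window =
                                      max(edge_offset) + 1L)
        if (nrow(found) && found$length[1] == ell &&
            found$left_start[1] == d1 + o1) break
      } else {
        found <- edge_repeat_search(base, d1, d2, min_rep = min_screen,
                                    max_rep = 40L, window = 5L)
        if (!nrow(found)) break
      }
      if (tries > 100) stop("could not realise the requested edge structure")
    }
    aln <- setNames(character(length(taxa)), taxa)
    for (tx in taxa) {
      s <- base
      if (sub_rate > 0) {
        guard <- seq(max(1L, d1 - 20L), min(M, d2 + 20L))
        pos <- setdiff(which(runif(M) < sub_rate), guard)
        if (length(pos)) {
          chars <- strsplit(s, "")[[1]]
          for (p in pos) {
            chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
          }
          s <- paste(chars, collapse = "")
        }
      }
      if (tx %in% deleted_taxa) {
        substr(s, d1, d2) <- strrep("-", deletion_length)
      }
      aln[[tx]] <- s
    }
    truth <- list(del_start = d1, del_end = d2,
                  repeat_length = if (plant) edge_repeat_length else 0L,
                  offsets = if (plant) edge_offset else c(NA, NA),
                  left_copy_start = if (plant) d1 + edge_offset[1] else NA,
                  right_copy_start = if (plant) {
                    d2 - edge_offset[2] - edge_repeat_length + 1L
                  } else NA,
                  deleted_taxa = deleted_taxa)
    list(alignment = aln, truth = truth)
  })
}

#' Simulate a codon-alignment pair at known divergence
#'
#' One lineage evolves from a uniform-sense-codon ancestor by explicit
#' substitution events: Poisson numbers of synonymous and nonsynonymous
#' events with expectations `dS * S` and `dN * N` (S, N the ancestor's
#' counting sites), each event a uniform draw among the eligible
#' single-nucleotide changes of the current sequence (changes to stops are
#' never drawn).
#'
#' @param n_codons Number of codons.
#' @param dS,dN Target synonymous / nonsynonymous divergence (per-site).
#' @param seed Integer seed.
#' @return List: `a`, `b` (codon character vectors), `truth` (tibble with
#'   targets, realised event counts and ancestor site counts).
#' @export
simulate_codon_pair <- function(n_codons = 1000L, dS = 0.2, dN = 0.02,
                                seed = 1L) {
  tab <- codon_tables()
  nb <- codon_neighbors()
  with_local_seed(seed, {
    anc <- sample(tab$sense, n_codons, replace = TRUE)
    S <- sum(tab$syn_sites[anc])
    N <- 3 * n_codons - S
    n_s <- rpois(1, dS * S)
    n_n <- rpois(1, dN * N)
    events <- sample(c(rep("s", n_s), rep("n", n_n)))
    cur <- anc
    for (ev in events) {
      w <- if (ev == "s") nb$n_syn[cur] else nb$n_nonsyn[cur]
      if (sum(w) == 0) next
      i <- sample.int(n_codons, 1, prob = w)
      opts <- if (ev == "s") nb$syn[[cur[i]]] else nb$nonsyn[[cur[i]]]
      cur[i] <- opts[sample.int(length(opts), 1)]
    }
    list(a = anc, b = cur,
         truth = tibble(dS_target = dS, dN_target = dN,
                        syn_events = n_s, nonsyn_events = n_n,
                        S_sites = S, N_sites = N))
  })
}

# single-nucleotide synonymous / nonsynonymous (non-stop) neighbours of
# every sense codon (cached)
codon_neighbors <- function() {
  if (!is.null(codon_env$nb)) return(codon_env$nb)
  tab <- codon_tables()
  bases <- c("A", "C", "G", "T")
  syn <- list()
  nonsyn <- list()
  for (cd in tab$sense) {
    sp <- strsplit(cd, "")[[1]]
    s_nb <- character(0)
    n_nb <- character(0)
    for (p in 1:3) {
      for (b in bases[bases != sp[p]]) {
        x <- sp
        x[p] <- b
        ncd <- paste(x, collapse = "")
        if (tab$gc[[ncd]] == "*") next
        if (tab$gc[[ncd]] == tab$gc[[cd]]) s_nb <- c(s_nb, ncd)
        else n_nb <- c(n_nb, ncd)
      }
    }
    syn[[cd]] <- s_nb
    nonsyn[[cd]] <- n_nb
  }
  codon_env$nb <- list(
    syn = syn, nonsyn = nonsyn,
    n_syn = vapply(syn, length, integer(1)),
    n_nonsyn = vapply(nonsyn, length, integer(1)))
  codon_env$nb
}
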