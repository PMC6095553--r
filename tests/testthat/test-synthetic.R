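# the synthetic-genome generator and its ground truth

test_that("generation is byte-identical for identical seeds", {
  a <- generate_genome(genome_blueprint(seed = 7, length = 70000))
  b <- generate_genome(genome_blueprint(seed = 7, length = 70000))
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  d <- generate_genome(genome_blueprint(seed = 8, length = 70000))
  expect_false(identical(a$genome, d$genome))

  # emitted files digest identically too
  dir <- withr::local_tempdir()
  for (x in list(a = a, b = b)) {
    write_fasta(c(g = x$genome), file.path(dir, paste0(x$blueprint$seed,
                                                       "_tmp.fa")))
  }
  f1 <- file.path(dir, "a.fa")
  f2 <- file.path(dir, "b.fa")
  write_fasta(c(g = a$genome), f1)
  write_fasta(c(g = b$genome), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("realised GC tracks the request within one percent", {
  g <- generate_genome(genome_blueprint(seed = 9, length = 50000,
                                        repeats = NULL,
                                        pseudogenes = NULL))
  expect_lt(abs(gc_fraction(g$genome) - 0.454), 0.01)
})

test_that("the default blueprint plants the full printed repeat spectrum", {
  sg <- generate_genome(genome_blueprint(seed = 2))
  tr <- sg$truth$repeats
  expect_equal(nrow(tr), 21L)
  cls <- classify_repeat_size(tr$size)
  expect_equal(sum(cls == "large"), 1L)
  expect_equal(sum(cls == "medium"), 20L)
  expect_equal(max(tr$size), 2160L)
  # planted copies really are at the recorded coordinates
  big <- tr[which.max(tr$size), ]
  c1 <- substr(sg$genome, big$copy1_start, big$copy1_end)
  c2 <- substr(sg$genome, big$copy2_start, big$copy2_end)
  if (big$orientation == "IR") c2 <- revcomp(c2)
  expect_equal(c1, c2)
})

test_that("unsatisfiable blueprints raise a packing error", {
  expect_error(
    generate_genome(genome_blueprint(
      seed = 1, length = 4000,
      genes = default_gene_roster()[35, ],
      repeats = tibble::tibble(size = 5000L, orientation = "DR",
                               identity = 100),
      pseudogenes = NULL)),
    "unsatisfiable")
})

test_that("annotations are internally consistent", {
  sg <- generate_genome(genome_blueprint(seed = 4, length = 60000,
                                         repeats = NULL))
  ann <- sg$annotation
  expect_true(all(ann$start >= 1 & ann$end <= 60000))
  # every exon/intron lies inside its gene's span
  genes <- dplyr::filter(ann, type %in% c("gene", "tRNA", "rRNA"))
  for (i in seq_len(nrow(genes))) {
    inner <- dplyr::filter(ann, type %in% c("exon", "intron"),
                           gene == genes$gene[i],
                           start >= genes$start[i], end <= genes$end[i])
    span <- sum(inner$end - inner$start + 1L)
    expect_equal(span, genes$end[i] - genes$start[i] + 1L)
  }
  # trans-spliced genes appear as two parts
  ts <- dplyr::filter(ann, type == "gene", trans_spliced)
  expect_setequal(unique(ts$gene), c("nad1", "nad5"))
  expect_equal(nrow(ts), 4L)
})

test_that("derived genomes honour the divergence spec", {
  g <- random_dna(20000, 0.45, seed = 12)
  same <- derive_genome(g, seed = 1)
  expect_identical(same$genome, g)
  ins <- derive_genome(g, n_insertions = 3, insertion_length = 1000,
                       seed = 2)
  expect_equal(nchar(ins$genome), 23000L)
  expect_equal(nrow(ins$truth$insertions), 3L)
  # recorded insertion intervals carry the inserted (novel) sequence;
  # removing them restores the original genome
  kept <- ins$genome
  for (i in rev(seq_len(3))) {
    iv <- ins$truth$insertions[i, ]
    kept <- paste0(substr(kept, 1, iv$start - 1),
                   substr(kept, iv$end + 1, nchar(kept)))
  }
  expect_identical(kept, g)
})

test_that("simulated error-free reads are substrings of the circle", {
  g <- random_dna(20000, 0.45, seed = 13)
  sim <- simulate_reads(g, coverage = 3, mean_length = 2000,
                        error_rate = 0, seed = 3)
  doubled <- paste0(g, g)
  for (i in seq_along(sim$reads)) {
    rd <- sim$reads[[i]]
    fwd <- grepl(rd, doubled, fixed = TRUE)
    rev <- grepl(revcomp(rd), doubled, fixed = TRUE)
    expect_true(fwd || rev)
  }
})

test_that("read counts follow the coverage arithmetic", {
  g <- random_dna(100000, 0.45, seed = 14)
  sim <- simulate_reads(g, coverage = 15, mean_length = 14000, seed = 4)
  expect_lte(abs(length(sim$reads) - 107), 6)
})

test_that("recombined truth labels follow the requested binomial fraction", {
  g <- recomb_fixture(seed = 28)
  sim <- simulate_spanning_reads(g$genome, g$repeat_pair, n_reads = 600,
                                 recombined_fraction = 1 / 3, seed = 5)
  n_rec <- sum(sim$truth$label == "recombined")
  expect_gte(n_rec, stats::qbinom(0.0005, 600, 1 / 3))
  expect_lte(n_rec, stats::qbinom(0.9995, 600, 1 / 3))
})

test_that("codon simulation records its realised event counts", {
  sim <- simulate_codon_pair(2000, dS = 0.2, dN = 0.02, seed = 6)
  expect_length(sim$a, 2000L)
  expect_length(sim$b, 2000L)
  gc <- Biostrings::GENETIC_CODE
  expect_false(any(gc[sim$b] == "*"))
  # realised counts near the Poisson expectations
  expect_lt(abs(sim$truth$syn_events - 0.2 * sim$truth$S_sites),
            4 * sqrt(0.2 * sim$truth$S_sites))
})

test_that("the full pipeline recovers the planted truth end to end", {
  # noise-free blueprint: everything planted at 100 percent identity
  reps <- tibble::tibble(size = c(1500L, 400L, 250L, 120L),
                         orientation = c("DR", "IR", "DR", "IR"),
                         identity = 100)
  sg <- generate_genome(genome_blueprint(
    seed = 31, length = 40000,
    genes = default_gene_roster()[c(1, 3, 12, 25, 27, 29), ],
    repeats = reps, pseudogenes = NULL))
  found <- find_repeats(sg$genome, min_len = 100)
  pr <- match_repeat_pairs(sg$truth$repeats, found)
  expect_equal(pr$precision, 1)
  expect_equal(pr$recall, 1)

  # pseudogene envelope blueprint
  ps <- tibble::tibble(gene = c("atp1", "cox2", "rpl5"),
                       length = c(28L, 100L, 182L),
                       identity = c(100, 95, 92))
  sg2 <- generate_genome(genome_blueprint(
    seed = 32, length = 20000,
    genes = default_gene_roster()[c(1, 12, 25), ],
    repeats = NULL, pseudogenes = ps))
  hits <- scan_pseudogenes(sg2$genome, sg2$annotation,
                           gene_sequences(sg2$genome, sg2$annotation))
  tr <- sg2$truth$pseudogenes
  recall <- mean(vapply(seq_len(nrow(tr)), function(i) {
    any(hits$gene == tr$gene[i] & abs(hits$start - tr$start[i]) <= 10)
  }, logical(1)))
  expect_equal(recall, 1)
})
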