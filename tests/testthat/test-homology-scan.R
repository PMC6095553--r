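# pseudogene scanning, shared-mtDNA accounting, anonymous content

# compact genome with a handful of genes for scan tests
scan_fixture <- function(seed = 3) {
  roster <- default_gene_roster()[c(1, 3, 12, 25, 27, 29), ]
  generate_genome(genome_blueprint(seed = seed, length = 20000,
                                   genes = roster, repeats = NULL,
                                   pseudogenes = NULL))
}

test_that("planted pseudogene fragments are found with their source gene", {
  sg <- scan_fixture(seed = 3)
  gs <- gene_sequences(sg$genome, sg$annotation)
  g <- sg$genome
  frag <- substr(gs[["atp1"]], 201, 350) # 150 bp
  frag <- mitomosaic:::with_local_seed(4,
    mitomosaic:::mutate_to_identity(frag, 95))
  spot <- 18500L
  substr(g, spot, spot + 149L) <- frag
  hits <- scan_pseudogenes(g, sg$annotation, gs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene, "atp1")
  expect_lte(abs(hits$start - spot), 5)
  expect_gte(hits$identity, 92)

  # the same fragment at 85 percent identity stays below threshold
  g2 <- sg$genome
  frag85 <- mitomosaic:::with_local_seed(5,
    mitomosaic:::mutate_to_identity(substr(gs[["atp1"]], 201, 350), 85))
  substr(g2, spot, spot + 149L) <- frag85
  hits2 <- scan_pseudogenes(g2, sg$annotation, gs)
  expect_equal(nrow(hits2), 0L)
})

test_that("fragments inside annotated features are not pseudogenes", {
  sg <- scan_fixture(seed = 7)
  gs <- gene_sequences(sg$genome, sg$annotation)
  g <- sg$genome
  # plant a perfect fragment of atp1 inside cox2's intron
  intr <- dplyr::filter(sg$annotation, type == "intron", gene == "cox2")
  expect_gte(nrow(intr), 1L)
  frag <- substr(gs[["atp1"]], 101, 200)
  substr(g, intr$start[1] + 50L, intr$start[1] + 149L) <- frag
  hits <- scan_pseudogenes(g, sg$annotation, gs)
  expect_equal(nrow(hits), 0L)
})

test_that("missing gene sequences are skipped with a warning", {
  sg <- scan_fixture(seed = 11)
  gs <- gene_sequences(sg$genome, sg$annotation)
  gs[["atp1"]] <- NA_character_
  expect_warning(scan_pseudogenes(sg$genome, sg$annotation, gs),
                 "skipped")
})

test_that("repeat association distinguishes containment from overlap", {
  reps <- tibble::tibble(
    repeat_id = "R01", identity = 100,
    copy1_start = 1000L, copy1_end = 1499L,
    copy2_start = 5000L, copy2_end = 5499L,
    size = 500L, orientation = "DR",
    size_class = factor("medium", levels = c("small", "medium", "large")))
  hits <- tibble::tibble(
    gene = c("a", "b", "c"),
    start = c(1100L, 1600L, 1400L), end = c(1199L, 1699L, 1599L),
    length = 100L, identity = 95, strand = "+", inside_repeat = NA)
  contained <- flag_repeat_association(hits, reps, mode = "containment")
  expect_equal(contained$inside_repeat, c(TRUE, FALSE, FALSE))
  overlapping <- flag_repeat_association(hits, reps, mode = "overlap")
  expect_equal(overlapping$inside_repeat, c(TRUE, FALSE, TRUE))
})

test_that("a genome shares all of itself and little with a stranger", {
  g <- random_dna(20000, 0.45, seed = 31)
  self <- shared_content(g, g)
  expect_equal(self$shared_frac_a, 1)
  expect_equal(self$shared_frac_b, 1)
  other <- random_dna(20000, 0.45, seed = 32)
  unrelated <- shared_content(g, other)
  expect_lt(unrelated$shared_frac_a, 0.05)
})

test_that("an insertion changes sharing by the closed-form amount", {
  g <- random_dna(50000, 0.45, seed = 11)
  d <- derive_genome(g, n_insertions = 1, insertion_length = 10000,
                     seed = 2)
  sh <- shared_content(g, d$genome)
  expect_equal(sh$shared_frac_a, 1)
  expect_equal(sh$shared_bp_b, 50000L)
  expect_equal(sh$shared_frac_b, 50000 / 60000)
  expect_equal(sh$unshared_bp_b, 10000L)
})

test_that("raising thresholds never increases shared coverage", {
  g <- random_dna(30000, 0.45, seed = 41)
  d <- derive_genome(g, substitution_rate = 0.05, n_insertions = 2,
                     insertion_length = 2000, seed = 42)
  base <- shared_content(g, d$genome, min_len = 100, min_identity = 0.70)
  stricter_id <- shared_content(g, d$genome, min_len = 100,
                                min_identity = 0.90)
  stricter_len <- shared_content(g, d$genome, min_len = 500,
                                 min_identity = 0.70)
  expect_lte(stricter_id$shared_bp_a, base$shared_bp_a)
  expect_lte(stricter_len$shared_bp_a, base$shared_bp_a)
})

test_that("anonymous content is total length minus known coverage", {
  r <- anonymous_content(484916, tibble::tibble(start = 1L,
                                                end = 363687L))
  expect_equal(r$anonymous_bp, 121229L)
  expect_equal(round(100 * r$anonymous_frac), 25)

  whole <- anonymous_content(1000, tibble::tibble(start = 1L, end = 1000L))
  expect_equal(whole$anonymous_bp, 0L)

  # overlapping intervals count once
  ovl <- anonymous_content(1000, tibble::tibble(start = c(1L, 50L),
                                                end = c(100L, 150L)))
  expect_equal(ovl$known_bp, 150L)
  expect_error(anonymous_content(1000, tibble::tibble(start = 0L,
                                                      end = 10L)),
               "bounds")
})

test_that("known plus anonymous always reconstructs the genome length", {
  set.seed(51)
  for (i in 1:10) {
    L <- sample(1000:5000, 1)
    n <- sample(0:8, 1)
    ivs <- if (n > 0) {
      s <- sort(sample.int(L, n))
      tibble::tibble(start = s, end = pmin(L, s + sample(10:500, n,
                                                         replace = TRUE)))
    } else tibble::tibble(start = integer(), end = integer())
    r <- anonymous_content(L, ivs)
    expect_equal(r$known_bp + r$anonymous_bp, L)
  }
})
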