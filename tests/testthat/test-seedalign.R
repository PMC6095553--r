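# seed finding, x-drop extension and the exact local-alignment oracle

test_that("find_seeds enumerates exact k-mer matches on both strands", {
  s <- find_seeds("ACGTACGT", "ACGTACGT", k = 7)
  plus <- s[s$strand == "+", ]
  expect_equal(plus$q_start, c(1L, 2L))
  expect_equal(plus$s_start, c(1L, 2L))
  # full enumeration oracle, both strands
  expect_equal(as.data.frame(s),
               brute_seeds("ACGTACGT", "ACGTACGT", 7),
               ignore_attr = TRUE)

  m <- find_seeds("AAAAAAA", "TTTTTTT", k = 7)
  expect_equal(nrow(m), 1L)
  expect_equal(m$strand, "-")
  expect_equal(unname(c(m$q_start, m$s_start)), c(1L, 1L))

  # random pair with a planted shared 50-mer
  set.seed(7)
  q <- random_dna(1000, 0.5)
  s2 <- random_dna(1000, 0.5)
  substr(s2, 401, 450) <- substr(q, 201, 250)
  k <- 11
  seeds <- find_seeds(q, s2, k = k)
  inside <- seeds[seeds$strand == "+" &
                    seeds$q_start >= 201 & seeds$q_start <= 250 - k + 1 &
                    seeds$s_start - seeds$q_start == 200, ]
  expect_gte(nrow(inside), 50 - k + 1)
})

test_that("find_seeds validates input and degenerates gracefully", {
  expect_error(find_seeds("ACGTX", "ACGT", k = 4), "outside")
  expect_error(find_seeds("ACGTACGT", "ACGTACGT", k = 3), "k must be >= 4")
  expect_equal(nrow(find_seeds("ACGT", "ACGT", k = 7)), 0L)
  # N never matches, including N-vs-N
  expect_equal(nrow(find_seeds("ACGNACG", "ACGNACG", k = 7)), 0L)
})

test_that("extend_seed recovers planted homologies", {
  set.seed(11)
  core <- random_dna(200, 0.5)
  h <- extend_seed(core, core, 90, 90, "+", k = 11)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 200, 1, 200))
  expect_equal(h$identity, 1)

  # planted 100 bp copy with 5 scattered substitutions
  q <- random_dna(400, 0.5)
  s <- random_dna(400, 0.5)
  copy <- substr(q, 151, 250)
  for (p in c(10, 30, 55, 70, 92)) {
    substr(copy, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(copy, p, p))[1]
  }
  substr(s, 101, 200) <- copy
  seeds <- find_seeds(q, s, k = 11)
  seeds <- seeds[seeds$strand == "+" & seeds$s_start - seeds$q_start == -50, ]
  h <- extend_seed(q, s, seeds$q_start[1], seeds$s_start[1], "+", k = 11)
  expect_lte(h$q_start, 151)
  expect_gte(h$q_end, 250 - 2) # x-drop may stop just short of a mismatch
  expect_gte(h$identity, 0.95)
  # score agrees with the exact DP on the local windows
  oracle <- local_align(substr(q, 120, 280), substr(s, 70, 230))
  expect_equal(h$score, oracle$score)

  # a seed in unrelated random sequence stays short
  set.seed(12)
  a <- random_dna(300, 0.5)
  b <- paste0(random_dna(100, 0.5), substr(a, 50, 60), random_dna(100, 0.5))
  h2 <- extend_seed(a, b, 50, 101, "+", k = 11)
  expect_lt(h2$length, 2 * 11 + 10)
})

test_that("local_align is exact and refuses oversized problems", {
  h <- local_align("ACGT", "ACGT")
  expect_equal(h$score, 8L)
  expect_equal(h$identity, 1)
  # reverse complement found as a full-length minus hit
  h2 <- local_align("ACGT", "ACGT", strands = "-")
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$length, 4L)
  # planted 40 bp shared core inside random 150-mers
  set.seed(3)
  a <- random_dna(150, 0.5)
  b <- random_dna(150, 0.5)
  substr(b, 61, 100) <- substr(a, 41, 80)
  h3 <- local_align(a, b)
  expect_lte(h3$q_start, 41)
  expect_gte(h3$q_end, 80)
  expect_error(local_align(random_dna(4000, 0.5), random_dna(4000, 0.5)),
               "refusing")
})

test_that("local_align matches an independent dynamic-programming oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(17)
  for (i in 1:10) {
    a <- random_dna(120, 0.5)
    b <- random_dna(120, 0.5)
    core <- substr(a, 31, 70)
    substr(b, 51, 90) <- core
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
    expect_equal(local_align(a, b, strands = "+")$score,
                 Biostrings::score(pa))
  }
})

test_that("hits are symmetric under query/subject swap", {
  set.seed(23)
  for (i in 1:5) {
    a <- random_dna(300, 0.5)
    b <- random_dna(300, 0.5)
    substr(b, 101, 180) <- substr(a, 51, 130)
    h_ab <- align_hits(a, b, k = 11, min_len = 30)
    h_ba <- align_hits(b, a, k = 11, min_len = 30)
    expect_equal(nrow(h_ab), nrow(h_ba))
    swapped <- h_ba[, c("s_start", "s_end", "q_start", "q_end", "strand",
                        "score")]
    names(swapped) <- c("q_start", "q_end", "s_start", "s_end", "strand",
                        "score")
    expect_equal(
      dplyr::arrange(h_ab[, names(swapped)], q_start, s_start),
      dplyr::arrange(swapped, q_start, s_start))
  }
})

test_that("extension equals the exact oracle on planted-homology pairs", {
  set.seed(29)
  for (i in 1:15) {
    n <- sample(150:300, 1)
    a <- random_dna(n, 0.5)
    b <- random_dna(n, 0.5)
    w <- sample(40:90, 1)
    qa <- sample(seq_len(n - w), 1)
    sb <- sample(seq_len(n - w), 1)
    core <- substr(a, qa, qa + w - 1)
    nm <- sample(0:3, 1)
    if (nm > 0) {
      core <- mitomosaic:::with_local_seed(i,
        mitomosaic:::mutate_to_identity(core, 100 * (1 - nm / w)))
    }
    substr(b, sb, sb + w - 1) <- core
    # seed inside the planted block, on its diagonal
    seeds <- find_seeds(a, b, k = 9)
    seeds <- seeds[seeds$strand == "+" &
                     seeds$s_start - seeds$q_start == sb - qa &
                     seeds$q_start >= qa &
                     seeds$q_start <= qa + w - 9, ]
    expect_gt(nrow(seeds), 0)
    h <- extend_seed(a, b, seeds$q_start[1], seeds$s_start[1], "+", k = 9)
    oracle <- local_align(a, b)
    expect_equal(h$score, oracle$score)
  }
})

test_that("minus-strand hits carry ascending coordinates plus a flag", {
  set.seed(31)
  a <- random_dna(400, 0.5)
  b <- random_dna(400, 0.5)
  substr(b, 201, 280) <- revcomp(substr(a, 101, 180))
  h <- align_hits(a, b, k = 11, min_len = 40)
  h <- h[h$strand == "-", ]
  expect_gt(nrow(h), 0)
  expect_true(all(h$q_start < h$q_end))
  expect_true(all(h$s_start < h$s_end))
})

test_that("hit export mirrors tabular blast ordering", {
  set.seed(37)
  a <- random_dna(300, 0.5)
  b <- a
  h <- align_hits(a, b, k = 11, min_len = 100)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, path, query_id = "qx", subject_id = "sx")
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back)[1:6],
               c("qseqid", "sseqid", "pident", "length", "mismatch", "gaps"))
  expect_equal(back$qseqid[1], "qx")
  expect_equal(back$length[1], 300)
})
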