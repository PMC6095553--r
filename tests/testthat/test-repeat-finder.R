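# self-comparison repeat detection, classification and summaries

test_that("a planted large direct repeat is recovered at its coordinates", {
  g <- random_dna(10000, 0.45, seed = 5)
  g <- plant_copy(g, 1000, 3159, 6000)
  rp <- find_repeats(g, min_len = 100)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "DR")
  expect_equal(as.character(rp$size_class), "large")
  expect_equal(rp$identity, 100)
  expect_lte(abs(rp$copy1_start - 1000), 5)
  expect_lte(abs(rp$copy2_start - 6000), 5)
  expect_gte(rp$size, 2160)
})

test_that("a planted medium inverted repeat is recovered", {
  g <- random_dna(10000, 0.45, seed = 6)
  g <- plant_copy(g, 2000, 2445, 7000, ir = TRUE)
  rp <- find_repeats(g, min_len = 100)
  expect_equal(nrow(rp), 1L)
  expect_equal(rp$orientation, "IR")
  expect_equal(as.character(rp$size_class), "medium")
  expect_lte(abs(rp$size - 446), 10)
})

test_that("random genomes yield no medium pairs and only re-validatable hits", {
  g <- random_dna(2000, 0.5, seed = 8)
  rp <- find_repeats(g, min_len = 20)
  expect_equal(sum(rp$size >= 100), 0L)
  if (nrow(rp)) {
    for (i in seq_len(nrow(rp))) {
      a <- substr(g, rp$copy1_start[i], min(rp$copy1_end[i], 2000))
      b <- substr(g, rp$copy2_start[i], min(rp$copy2_end[i], 2000))
      val <- local_align(a, b)
      expect_gte(val$identity, 0.80)
    }
  }
})

test_that("size classification follows the printed tier boundaries", {
  cls <- classify_repeat_size(c(2160, 795, 99, 100, 999, 1000, 20))
  expect_equal(as.character(cls),
               c("large", "medium", "small", "medium", "medium", "large",
                 "small"))
  expect_error(classify_repeat_size(19), "threshold")
})

test_that("orientation derives from printed coordinate directions", {
  # descending copy-2 coordinates mark inverted repeats
  expect_equal(orient_repeat(131028, 131822, 199473, 198679), "IR")
  expect_equal(orient_repeat(150477, 152636, 323868, 326027), "DR")
  expect_error(orient_repeat(5, 5, 10, 20), "degenerate")
})

test_that("the curated 21-pair repeat table reproduces its printed labels", {
  tb <- mt_repeat_table()
  expect_equal(nrow(tb), 21L)
  called <- orient_repeat(tb$copy1_start, tb$copy1_end,
                          tb$copy2_start, tb$copy2_end)
  expect_equal(called, tb$type)
  expect_equal(sum(called == "DR"), 8L)
  expect_equal(sum(called == "IR"), 13L)
  cls <- classify_repeat_size(tb$size)
  expect_equal(sum(cls == "medium"), 20L)
  expect_equal(sum(cls == "large"), 1L)
  expect_equal(max(tb$size), 2160L)
})

test_that("summaries count merged coverage once", {
  reps <- tibble::tibble(
    repeat_id = c("R01", "R02"),
    identity = c(100, 100),
    copy1_start = c(100L, 150L), copy1_end = c(299L, 349L),
    copy2_start = c(700L, 1200L), copy2_end = c(899L, 1399L),
    size = c(200L, 200L), orientation = c("DR", "DR"),
    size_class = factor(c("medium", "medium"),
                        levels = c("small", "medium", "large")))
  s <- summarize_repeats(reps, genome_length = 2000)
  # position-by-position union oracle
  covered <- rep(FALSE, 2000)
  for (i in 1:2) {
    covered[reps$copy1_start[i]:reps$copy1_end[i]] <- TRUE
    covered[reps$copy2_start[i]:reps$copy2_end[i]] <- TRUE
  }
  expect_equal(s$repeat_bp, sum(covered))
  expect_equal(s$repeat_frac, sum(covered) / 2000)
  expect_equal(s$n_medium, 2L)

  empty <- reps[0, ]
  s0 <- summarize_repeats(empty, genome_length = 2000)
  expect_equal(s0$repeat_bp, 0L)
  expect_equal(s0$repeat_frac, 0)
  expect_error(summarize_repeats(reps, genome_length = 0), "positive")
})

test_that("canonicalization is idempotent and deterministically ordered", {
  g <- random_dna(8000, 0.45, seed = 9)
  g <- plant_copy(g, 500, 799, 4000)
  g <- plant_copy(g, 1500, 1799, 6000, ir = TRUE)
  rp <- find_repeats(g, min_len = 100)
  hits_like <- tibble::tibble(
    q_start = rp$copy1_start, q_end = rp$copy1_end,
    s_start = rp$copy2_start, s_end = rp$copy2_end,
    strand = ifelse(rp$orientation == "DR", "+", "-"),
    identity = rp$identity / 100, length = rp$size, score = rp$score)
  once <- mitomosaic:::canonicalize_repeat_pairs(hits_like, 8000)
  again_in <- tibble::tibble(
    q_start = once$copy1_start, q_end = once$copy1_end,
    s_start = once$copy2_start, s_end = once$copy2_end,
    strand = ifelse(once$orientation == "DR", "+", "-"),
    identity = once$identity / 100, length = once$size,
    score = once$score)
  twice <- mitomosaic:::canonicalize_repeat_pairs(again_in, 8000)
  expect_equal(twice[, names(once)], once)
  expect_false(is.unsorted(rp$copy1_start))
})

test_that("the repeat set is invariant under genome rotation", {
  g <- random_dna(8000, 0.45, seed = 10)
  g <- plant_copy(g, 500, 799, 4000)
  g <- plant_copy(g, 1500, 1699, 6200, ir = TRUE)
  base <- find_repeats(g, min_len = 100)
  key <- function(rp, shift, L) {
    rot <- function(p) ((p - 1 + shift) %% L) + 1
    k <- paste(pmin(rot(rp$copy1_start), rot(rp$copy2_start)),
               pmax(rot(rp$copy1_start), rot(rp$copy2_start)),
               rp$size, rp$orientation)
    sort(k)
  }
  for (off in c(1234, 4321)) {
    rotated <- paste0(substr(g, off + 1, 8000), substr(g, 1, off))
    rp2 <- find_repeats(rotated, min_len = 100)
    expect_equal(nrow(rp2), nrow(base))
    expect_equal(key(rp2, off, 8000), key(base, 0, 8000))
  }
})

test_that("planted repeats are recovered with full precision and recall", {
  for (s in 1:3) {
    sizes <- c(1500L, 600L, 300L, 150L, 120L)
    ir <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
    g <- random_dna(20000, 0.45, seed = 100 + s)
    pos <- cbind(src = c(500, 3000, 5500, 7500, 9000),
                 tgt = c(11000, 13500, 15500, 17000, 18500))
    truth <- list()
    for (i in seq_along(sizes)) {
      g <- plant_copy(g, pos[i, 1], pos[i, 1] + sizes[i] - 1L, pos[i, 2],
                      ir = ir[i])
      truth[[i]] <- tibble::tibble(
        copy1_start = pos[i, 1], copy1_end = pos[i, 1] + sizes[i] - 1L,
        copy2_start = pos[i, 2], copy2_end = pos[i, 2] + sizes[i] - 1L,
        orientation = ifelse(ir[i], "IR", "DR"))
    }
    truth <- dplyr::bind_rows(truth)
    found <- find_repeats(g, min_len = 100)
    pr <- match_repeat_pairs(truth, found)
    expect_equal(pr$precision, 1)
    expect_equal(pr$recall, 1)
  }
})
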