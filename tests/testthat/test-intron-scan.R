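# intron length tables, deletion blocks and edge-repeat detection

test_that("intron length tables count non-gap characters only", {
  aln <- c(t1 = paste0(strrep("A", 50), strrep("-", 30), strrep("G", 20)),
           t2 = strrep("A", 100), t3 = strrep("C", 100))
  tb <- intron_length_table(list(i1 = aln))
  expect_equal(tb$length[tb$taxon == "t1"], 70L)
  expect_equal(tb$length[tb$taxon == "t2"], 100L)

  same <- c(a = "ACGTACGT", b = "ACGTACGT")
  tb2 <- intron_length_table(list(i1 = same))
  expect_equal(unique(tb2$length), 8L)

  # missing taxa flagged across alignments
  tb3 <- intron_length_table(list(i1 = same, i2 = c(a = "ACGT")))
  expect_false(tb3$present[tb3$intron == "i2" & tb3$taxon == "b"])
  expect_true(is.na(tb3$length[tb3$intron == "i2" & tb3$taxon == "b"]))

  expect_error(intron_length_table(list(i1 = c(a = "AC", a = "AC"))),
               "duplicate")
})

test_that("bimodal intron lengths are recovered from a long deletion", {
  sim <- simulate_intron_alignment(
    taxa = c("s1", "s2", "s3", "s4"), deleted_taxa = c("s1", "s2"),
    intron_length = 4000, deletion_length = 3050,
    edge_repeat_length = 15, seed = 13)
  tb <- intron_length_table(list(ccmFci829 = sim$alignment))
  short <- tb$length[tb$taxon %in% c("s1", "s2")]
  long <- tb$length[tb$taxon %in% c("s3", "s4")]
  expect_true(all(short == 950))
  expect_true(all(long == 4000))
})

test_that("deletion blocks respect the merge rule and the reference rule", {
  gap <- function(n) strrep("-", n)
  base <- strrep("A", 300)
  one <- c(x = paste0(strrep("A", 100), gap(100), strrep("A", 100)),
           y = strrep("A", 300))
  b1 <- find_deletion_blocks(one, min_del = 50)
  expect_equal(nrow(b1), 1L)
  expect_equal(c(b1$col_start, b1$col_end, b1$length_ref),
               c(101L, 200L, 100L))

  # two 60-column gaps separated by 5 columns merge into one block
  two <- c(x = paste0(strrep("A", 50), gap(60), strrep("A", 5), gap(60),
                      strrep("A", 125)),
           y = base)
  b2 <- find_deletion_blocks(two, min_del = 50, merge_gap = 10)
  expect_equal(nrow(b2), 1L)
  expect_equal(c(b2$col_start, b2$col_end), c(51L, 175L))
  # with merging disabled they stay separate
  b2b <- find_deletion_blocks(two, min_del = 50, merge_gap = 1)
  expect_equal(nrow(b2b), 2L)

  # a gap shared by every taxon is not a deletion
  all_gap <- c(x = paste0(strrep("A", 100), gap(100), strrep("A", 100)),
               y = paste0(strrep("C", 100), gap(100), strrep("C", 100)))
  expect_equal(nrow(find_deletion_blocks(all_gap, min_del = 50)), 0L)
})

test_that("length tables depend only on gap counts, not column order", {
  sim <- simulate_intron_alignment(seed = 19)
  aln <- sim$alignment
  set.seed(19)
  perm <- sample(nchar(aln[1]))
  shuffled <- vapply(aln, function(s) {
    paste(strsplit(s, "")[[1]][perm], collapse = "")
  }, character(1))
  t1 <- intron_length_table(list(i = aln))
  t2 <- intron_length_table(list(i = shuffled))
  expect_equal(t1$length, t2$length)
})

test_that("deletion blocks are unchanged by removing all-gap columns", {
  gap <- function(n) strrep("-", n)
  aln <- c(x = paste0(strrep("A", 80), gap(120), strrep("A", 100)),
           y = paste0(strrep("A", 80), gap(20), strrep("C", 100),
                      strrep("A", 100)))
  b <- find_deletion_blocks(aln, min_del = 50)
  # columns 81..100 are gap in every taxon; drop them
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  allgap <- Reduce(`&`, lapply(chars, function(x) x == "-"))
  stripped <- vapply(chars, function(x) {
    paste(x[!allgap], collapse = "")
  }, character(1))
  b2 <- find_deletion_blocks(stripped, min_del = 50)
  expect_equal(b$length_ref, b2$length_ref)
  expect_equal(nrow(b), nrow(b2))
})

test_that("edge repeats are found at their planted offsets", {
  sim <- simulate_intron_alignment(seed = 9) # 15-mer at offsets 0/0
  ret <- gsub("-", "", sim$alignment[["t1"]])
  er <- edge_repeat_search(ret, sim$truth$del_start, sim$truth$del_end)
  expect_gte(nrow(er), 1L)
  expect_equal(er$length[1], 15L)
  expect_equal(c(er$left_offset[1], er$right_offset[1]), c(0L, 0L))
  expect_equal(er$left_start[1], sim$truth$left_copy_start)

  sim2 <- simulate_intron_alignment(edge_repeat_length = 13,
                                    edge_offset = c(3, 3), seed = 10)
  ret2 <- gsub("-", "", sim2$alignment[["t1"]])
  er2 <- edge_repeat_search(ret2, sim2$truth$del_start,
                            sim2$truth$del_end, window = 5)
  expect_equal(er2$length[1], 13L)
  expect_equal(c(er2$left_offset[1], er2$right_offset[1]), c(3L, 3L))
  # a strict window misses offset-3 copies
  er2s <- edge_repeat_search(ret2, sim2$truth$del_start,
                             sim2$truth$del_end, window = 0)
  expect_equal(nrow(er2s), 0L)

  expect_error(edge_repeat_search(ret, 1, nchar(ret) + 10), "outside")
})

test_that("screened repeat-free deletions yield no edge repeats", {
  sim <- simulate_intron_alignment(edge_repeat_length = NULL, seed = 23)
  ret <- gsub("-", "", sim$alignment[["t1"]])
  er <- edge_repeat_search(ret, sim$truth$del_start, sim$truth$del_end)
  expect_equal(nrow(er), 0L)
})

test_that("planted edge repeats are always recalled; negatives stay rare", {
  hits <- 0L
  for (s in 1:8) {
    len <- sample(10:20, 1)
    off <- sample(0:3, 2, replace = TRUE)
    sim <- simulate_intron_alignment(edge_repeat_length = len,
                                     edge_offset = off, seed = 200 + s)
    ret <- gsub("-", "", sim$alignment[["t1"]])
    er <- edge_repeat_search(ret, sim$truth$del_start, sim$truth$del_end,
                             window = 5, max_rep = 25)
    expect_gte(nrow(er), 1L)
    expect_equal(er$length[1], len)
  }
  # negatives: the expected number of chance >= 10 bp exact direct repeats
  # in the searched window set is far below one per alignment
  for (s in 1:10) {
    sim <- simulate_intron_alignment(edge_repeat_length = NULL,
                                     seed = 300 + s)
    ret <- gsub("-", "", sim$alignment[["t1"]])
    er <- edge_repeat_search(ret, sim$truth$del_start, sim$truth$del_end)
    hits <- hits + nrow(er)
  }
  expect_lte(hits, 1L)
})

test_that("deletion blocks map to retained-taxon coordinates", {
  sim <- simulate_intron_alignment(seed = 29)
  blocks <- find_deletion_blocks(sim$alignment, min_del = 50)
  coords <- deletion_in_retained(sim$alignment, blocks[1, ], "t1")
  expect_equal(unname(coords),
               c(sim$truth$del_start, sim$truth$del_end))
})
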