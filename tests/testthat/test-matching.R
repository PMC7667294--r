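test_that("length keywords render in Mb/Kb report style", {
  expect_equal(render_length(50e6), "50 Mb")
  expect_equal(render_length(1.26e6), "1.26 Mb")
  expect_equal(render_length(1e6), "1 Mb")
  expect_equal(render_length(1.5e6), "1.5 Mb")
  expect_equal(render_length(480e3), "480 Kb")
  expect_equal(render_length(999999), "1000 Kb")
})

test_that("relation score components carry the printed 5/2/1/1 weights", {
  cb <- toy_cytobands()
  cnv <- cnv_calls("1", 101, 700, "heterozygous_deletion",
                   validate_length = FALSE)[1, ]
  len_kw <- render_length(cnv$length_bp)
  all_kw <- sprintf("a %s heterozygous deletion on chr1 band q11", len_kw)
  expect_equal(relation_score(cnv, all_kw, cb)$total, 9L)
  none <- "nothing informative here"
  expect_equal(relation_score(cnv, none, cb)$total, 0L)
  expect_equal(relation_score(cnv, "seen on chr1 only", cb)$total, 5L)
  expect_equal(relation_score(cnv, "a deletion was seen", cb)$total, 2L)
  expect_equal(relation_score(cnv, "band q11 was involved", cb)$total, 1L)
  expect_equal(relation_score(cnv, sprintf("a %s event", len_kw), cb)$total,
               1L)
  # total always equals the weighted component sum
  rs <- relation_score(cnv, sprintf("a %s deletion near band q11", len_kw),
                       cb)
  expect_equal(rs$total, 5L * rs$chr_score + 2L * rs$type_score +
                 rs$cyto_score + rs$length_score)
})

test_that("chromosome keywords match as tokens, not prefixes", {
  cb <- synthetic_cytobands()
  cnv1 <- cnv_calls("1", 1e6, 2e6, "duplication")[1, ]
  # chr17 must not satisfy a chr1 query
  expect_equal(relation_score(cnv1, "event on chr17", cb)$chr_score, 0L)
  expect_equal(relation_score(cnv1, "event on chr1", cb)$chr_score, 1L)
  expect_equal(relation_score(cnv1, "chromosome 1 involved", cb)$chr_score, 1L)
  expect_equal(relation_score(cnv1, "位于1号染色体", cb)$chr_score, 1L)
  # the CJK form must not match 21号 for chromosome 1
  expect_equal(relation_score(cnv1, "位于21号染色体", cb)$chr_score, 0L)
})

test_that("case-insensitive unit matching for length keywords", {
  cb <- toy_cytobands()
  cnv <- cnv_calls("1", 101, 700, "duplication", validate_length = FALSE)[1, ]
  len_kw <- render_length(cnv$length_bp)
  expect_equal(relation_score(
    cnv, sprintf("a %s gain", toupper(len_kw)), cb)$length_score, 1L)
  expect_equal(relation_score(
    cnv, sprintf("a %s gain", tolower(len_kw)), cb)$length_score, 1L)
})

test_that("matching takes the argmax with first-index ties", {
  m <- matrix(c(9, 0, 0, 9), nrow = 2, byrow = TRUE)
  expect_equal(match_cnvs(score_matrix = m), c(1L, 2L))
  # equal scores pick the first sub-paragraph
  expect_equal(match_cnvs(score_matrix = matrix(c(3, 3), nrow = 1)), 1L)
  expect_error(match_cnvs(score_matrix = matrix(numeric(0), nrow = 1)),
               "no sub-paragraphs")
})

test_that("matching equals the brute-force oracle on exhaustive and random matrices", {
  # exhaustive: every achievable score value in every cell of small matrices
  vals <- c(0, 1, 2, 3, 5, 9)
  for (n in 1:2) {
    grids <- expand.grid(rep(list(vals), n * 2))
    for (g in seq_len(nrow(grids))) {
      m <- matrix(as.numeric(grids[g, ]), nrow = n)
      expect_identical(match_cnvs(score_matrix = m), brute_match(m))
    }
  }
  # random larger matrices up to 6x6 over all component combinations
  set.seed(11)
  combos <- expand.grid(chr = 0:1, type = 0:1, cyto = 0:1, len = 0:1)
  achievable <- unique(5 * combos$chr + 2 * combos$type + combos$cyto +
                         combos$len)
  for (rep in 1:200) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    m <- matrix(sample(achievable, nr * nc, replace = TRUE), nrow = nr)
    expect_identical(match_cnvs(score_matrix = m), brute_match(m))
  }
})

test_that("CNV call validation enforces coordinates and minimum length", {
  expect_error(cnv_calls("1", 200, 100, "duplication"), "exceed")
  expect_error(cnv_calls("1", 100, 500, "duplication"), "minimum reportable")
  ok <- cnv_calls("1", 100, 500, "duplication", validate_length = FALSE)
  expect_equal(ok$length_bp, 401)
  expect_error(cnv_calls("27", 1, 2e5, "duplication"))
  expect_error(cnv_calls("1", 1e6, 2e6, "gain"))
})
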