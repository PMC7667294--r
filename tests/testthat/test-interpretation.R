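# hand-built KB exercising every evidence route
toy_kbs <- function() {
  knowledge_base_set(
    polymorphism = data.frame(
      chrom = "1", start = 900000, end = 2200000, frequency = 0.08,
      sample_size = 5000, source = "dgv-like", stringsAsFactors = FALSE),
    syndrome = data.frame(
      chrom = c("2", "2"), start = c(1.05e6, 8e6), end = c(1.95e6, 9e6),
      syndrome_name = c("toy syndrome", "other syndrome"),
      dosage_mechanism = c("deletion", "duplication"),
      corpus = c("deletion of this region causes toy syndrome",
                 "duplication syndrome text"),
      source = "test", stringsAsFactors = FALSE),
    gene = data.frame(
      gene_symbol = "TOY1", chrom = "3", start = 1.2e6, end = 1.4e6,
      dosage_sensitivity = "haploinsufficient",
      corpus = "TOY1 is dosage sensitive", source = "clingen-like",
      stringsAsFactors = FALSE),
    paper = data.frame(
      chrom = "4", start = 1e6, end = 2e6, plp_case_count = 7,
      citation = "ref1", corpus = "seven cases were described",
      stringsAsFactors = FALSE),
    patient = data.frame(
      chrom = "1", start = 1e6, end = 2e6, phenotype = "normal carrier",
      reported_classification = "benign", source = "open_access",
      stringsAsFactors = FALSE),
    aneuploid = data.frame(
      chrom = "21", event = "gain",
      description = "trisomy 21 detected, consistent with Down syndrome",
      source = "test", stringsAsFactors = FALSE))
}

test_that("overlap fractions follow the printed definitions", {
  f <- overlap_fractions("1", 101, 200, "1", 151, 250)
  expect_equal(f$overlap_bp, 50)
  expect_equal(f$overlap_db, 0.5)
  expect_equal(f$overlap_query, 0.5)
  # identical intervals
  f2 <- overlap_fractions("1", 101, 200, "1", 101, 200)
  expect_equal(f2, list(overlap_bp = 100, overlap_db = 1, overlap_query = 1))
  # record nested in query at 10% of its length
  f3 <- overlap_fractions("1", 1, 1000, "1", 101, 200)
  expect_equal(f3$overlap_db, 1)
  expect_equal(f3$overlap_query, 0.1)
  # different chromosomes: zeros, not an error
  expect_equal(overlap_fractions("1", 1, 100, "2", 1, 100)$overlap_bp, 0)
})

test_that("annotation applies the per-store filters", {
  cb <- synthetic_cytobands()
  kbs <- toy_kbs()
  # CNV covering the toy syndrome region
  del2 <- cnv_calls("2", 1e6, 2e6, "heterozygous_deletion")
  ann <- annotate_cnv(del2[1, ], kbs, annotation_filters(), cb)
  expect_equal(nrow(ann$syndrome), 1)
  expect_equal(ann$syndrome$syndrome_name, "toy syndrome")
  expect_gte(ann$syndrome$overlap_db, 0.9)
  # polymorphism below the sample-size filter is excluded
  small <- kbs
  small$polymorphism$sample_size <- 500
  cnv1 <- cnv_calls("1", 1e6, 2e6, "heterozygous_deletion")
  ann_small <- annotate_cnv(cnv1[1, ], small, annotation_filters(), cb)
  expect_equal(nrow(ann_small$polymorphism), 0)
  ann_ok <- annotate_cnv(cnv1[1, ], kbs, annotation_filters(), cb)
  expect_equal(nrow(ann_ok$polymorphism), 1)
  # patient hits are annotated for display
  expect_equal(nrow(ann_ok$patient), 1)
})

test_that("surviving hits equal a brute-force filter application on random KBs", {
  set.seed(23)
  cb <- synthetic_cytobands()
  filters <- annotation_filters()
  store <- data.frame(
    chrom = sample(c("1", "2"), 50, replace = TRUE),
    start = sample.int(5e7, 50), stringsAsFactors = FALSE)
  store$end <- store$start + sample.int(5e6, 50)
  store$syndrome_name <- sprintf("s%d", 1:50)
  store$dosage_mechanism <- sample(c("deletion", "duplication", "both"),
                                   50, replace = TRUE)
  store$corpus <- "x"; store$source <- "x"
  kbs <- knowledge_base_set(syndrome = store)
  for (q in 1:25) {
    chrom <- sample(c("1", "2"), 1)
    qs <- sample.int(5e7, 1); qe <- qs + sample.int(8e6, 1) + 1e5
    cnv <- cnv_calls(chrom, qs, qe, "heterozygous_deletion")[1, ]
    ann <- annotate_cnv(cnv, kbs, filters, cb)
    want <- brute_overlaps(store, chrom, qs, qe)
    want_db <- want$overlap_bp / (want$end - want$start + 1)
    want <- want[want_db >= filters$syndrome_min_overlap_db, ]
    expect_setequal(ann$syndrome$syndrome_name, want$syndrome_name)
  }
})

test_that("evidence scores implement the documented default rules", {
  cb <- synthetic_cytobands()
  kbs <- toy_kbs()
  filters <- annotation_filters()
  # empty annotation -> all zeros, no flag
  vous <- cnv_calls("6", 1e6, 2e6, "duplication")
  s0 <- evidence_scores(annotate_cnv(vous[1, ], kbs, filters, cb))
  expect_equal(s0$benign_score, 0)
  expect_equal(s0$syndrome_score, 0)
  expect_equal(s0$gene_score, 0)
  expect_equal(s0$paper_score, 0)
  expect_false(s0$aneuploid_flag)
  # paper case count passes through
  pap <- cnv_calls("4", 1e6, 2e6, "heterozygous_deletion")
  sp <- evidence_scores(annotate_cnv(pap[1, ], kbs, filters, cb))
  expect_equal(sp$paper_score, 7)
  # duplication over a haploinsufficient-only gene contributes nothing
  dup3 <- cnv_calls("3", 1e6, 2e6, "duplication")
  sd <- evidence_scores(annotate_cnv(dup3[1, ], kbs, filters, cb))
  expect_equal(sd$gene_score, 0)
  del3 <- cnv_calls("3", 1e6, 2e6, "heterozygous_deletion")
  expect_equal(evidence_scores(annotate_cnv(del3[1, ], kbs, filters,
                                            cb))$gene_score, 1)
  # syndrome mechanism must match the variant type
  dup2 <- cnv_calls("2", 1e6, 2e6, "duplication")
  expect_equal(evidence_scores(annotate_cnv(dup2[1, ], kbs, filters,
                                            cb))$syndrome_score, 0)
})

test_that("the classification ladder maps evidence to the five-tier scale", {
  mk <- function(benign = 0, syndrome = 0, gene = 0, paper = 0,
                 flag = FALSE) {
    structure(list(benign_score = benign, syndrome_score = syndrome,
                   gene_score = gene, paper_score = paper,
                   aneuploid_flag = flag,
                   patient_annotations = data.frame()),
              class = "evidence_scores")
  }
  expect_equal(classify_variant(mk(flag = TRUE)), "pathogenic")
  # an aneuploidy is pathogenic regardless of benign evidence
  expect_equal(classify_variant(mk(benign = 0.5, flag = TRUE)), "pathogenic")
  expect_equal(classify_variant(mk()), "VOUS")
  expect_equal(classify_variant(mk(benign = 0.05)), "benign")
  expect_equal(classify_variant(mk(syndrome = 0.8)), "pathogenic")
  expect_equal(classify_variant(mk(syndrome = 0.6)), "likely_pathogenic")
  expect_equal(classify_variant(mk(gene = 1)), "likely_pathogenic")
  expect_equal(classify_variant(mk(gene = 3)), "pathogenic")
  expect_equal(classify_variant(mk(paper = 5)), "likely_pathogenic")
  expect_equal(classify_variant(mk(paper = 12)), "pathogenic")
  # pathogenic evidence outranks benign evidence
  expect_equal(classify_variant(mk(benign = 0.5, syndrome = 0.8)),
               "pathogenic")
})

test_that("whole-chromosome detection respects the span-fraction threshold", {
  cb <- synthetic_cytobands()
  len21 <- chromosome_lengths(cb)["21"]
  full <- is_whole_chromosome_event("21", 1, len21, "duplication", cb)
  expect_true(full$is_event)
  expect_match(full$descriptor, "gain")
  expect_match(full$descriptor, "21")
  inter <- is_whole_chromosome_event("21", 1e6, 11e6,
                                     "heterozygous_deletion", cb)
  expect_false(inter$is_event)
  # 98.5% of the chromosome: below the 0.99 default, above 0.98
  e985 <- round(0.985 * len21)
  expect_false(is_whole_chromosome_event("21", 1, e985, "duplication",
                                         cb)$is_event)
  expect_true(is_whole_chromosome_event("21", 1, e985, "duplication", cb,
                                        min_fraction = 0.98)$is_event)
})

test_that("incomplete-penetrance hits are annotated but never scored", {
  cb <- synthetic_cytobands()
  kbs <- toy_kbs()
  block <- data.frame(chrom = "2", start = 1e6, end = 2e6,
                      stringsAsFactors = FALSE)
  filters <- annotation_filters(incomplete_penetrance = block)
  del2 <- cnv_calls("2", 1e6, 2e6, "heterozygous_deletion")
  ann <- annotate_cnv(del2[1, ], kbs, filters, cb)
  expect_equal(nrow(ann$syndrome), 1)      # still reviewable
  expect_true(ann$syndrome$excluded)
  sc <- evidence_scores(ann)
  expect_equal(sc$syndrome_score, 0)       # but not scored
  expect_equal(classify_variant(sc), "VOUS")
})

test_that("evidence scores are monotone in overlap, frequency and counts", {
  cb <- synthetic_cytobands()
  filters <- annotation_filters()
  base_poly <- data.frame(chrom = "1", start = 1e6, end = 1.8e6,
                          frequency = 0.05, sample_size = 2000,
                          source = "x", stringsAsFactors = FALSE)
  cnv <- cnv_calls("1", 1e6, 2e6, "duplication")[1, ]
  score_with <- function(poly = base_poly, paper = NULL) {
    kbs <- knowledge_base_set(polymorphism = poly, paper = paper)
    evidence_scores(annotate_cnv(cnv, kbs, filters, cb))
  }
  s_base <- score_with()
  # larger overlap
  bigger <- base_poly; bigger$end <- 2e6
  expect_gte(score_with(bigger)$benign_score, s_base$benign_score)
  # higher frequency
  freq <- base_poly; freq$frequency <- 0.2
  expect_gte(score_with(freq)$benign_score, s_base$benign_score)
  # more literature cases
  pap1 <- data.frame(chrom = "1", start = 1e6, end = 2e6,
                     plp_case_count = 2, citation = "a", corpus = "c",
                     stringsAsFactors = FALSE)
  pap2 <- pap1; pap2$plp_case_count <- 6
  expect_gte(score_with(paper = pap2)$paper_score,
             score_with(paper = pap1)$paper_score)
})

test_that("interpretation is deterministic and order-invariant", {
  sim <- simulate_interpretation_fixtures(interp_sim_config(n_cnvs = 30,
                                                            seed = 5))
  r1 <- interpret_cnvs(sim$cnvs, sim$kbs, sim$cytobands)
  r2 <- interpret_cnvs(sim$cnvs, sim$kbs, sim$cytobands)
  expect_identical(r1$classification, r2$classification)
  perm <- sample(nrow(sim$cnvs))
  r3 <- interpret_cnvs(sim$cnvs[perm, ], sim$kbs, sim$cytobands)
  expect_identical(r3$classification, r1$classification[perm])
})

test_that("patient records carry no score field into classification", {
  # by construction: the patient store is routed to a display-only list
  cb <- synthetic_cytobands()
  kbs <- toy_kbs()
  cnv <- cnv_calls("1", 1e6, 2e6, "duplication")[1, ]
  # with vs without the patient store: identical scores and call
  kbs_nopat <- kbs
  kbs_nopat$patient <- kbs_nopat$patient[0, ]
  f <- annotation_filters()
  s_with <- evidence_scores(annotate_cnv(cnv, kbs, f, cb))
  s_without <- evidence_scores(annotate_cnv(cnv, kbs_nopat, f, cb))
  expect_equal(nrow(s_with$patient_annotations), 1)
  for (fld in c("benign_score", "syndrome_score", "gene_score",
                "paper_score", "aneuploid_flag")) {
    expect_identical(s_with[[fld]], s_without[[fld]])
  }
  expect_identical(classify_variant(s_with), classify_variant(s_without))
})
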