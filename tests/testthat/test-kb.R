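test_that("corpus sentences route into the correct stores with matched regions", {
  labeled <- data.frame(
    report_id = c("R1", "R1", "R1", "R2", "R2"),
    sub_index = c(1, 1, 1, 1, 1),
    sent_index = 0:4 %% 3,
    text = c("basic location text", "syndrome description here",
             "published in the literature", "gene dosage text",
             "patient phenotype note"),
    category = c("Basic", "Syndrome", "Paper", "Gene", "Patient"),
    stringsAsFactors = FALSE)
  matched <- data.frame(
    report_id = c("R1", "R2"), sub_index = c(1, 1),
    chrom = c("7", "3"), start = c(1e6, 2e6), end = c(2e6, 4e6),
    variation_type = c("heterozygous_deletion", "duplication"),
    stringsAsFactors = FALSE)
  kbs <- build_knowledge_bases(labeled, matched)
  expect_s3_class(kbs, "knowledge_base_set")
  expect_equal(nrow(kbs$syndrome), 1)
  expect_equal(kbs$syndrome$chrom, "7")
  expect_equal(kbs$syndrome$dosage_mechanism, "deletion")
  expect_equal(nrow(kbs$paper), 1)
  expect_equal(nrow(kbs$gene), 1)
  expect_equal(kbs$gene$dosage_sensitivity, "triplosensitive")
  expect_equal(nrow(kbs$patient), 1)
  # Basic sentences are not stored as evidence anywhere
  expect_equal(nrow(kbs$polymorphism), 0)
  all_corpus <- c(kbs$syndrome$corpus, kbs$gene$corpus, kbs$paper$corpus,
                  kbs$patient$phenotype)
  expect_false(any(grepl("basic location", all_corpus)))
})

test_that("sub-paragraphs without a matched CNV are skipped with a warning", {
  labeled <- data.frame(report_id = "R9", sub_index = 1, sent_index = 0,
                        text = "syndrome text", category = "Syndrome",
                        stringsAsFactors = FALSE)
  matched <- data.frame(report_id = "R9", sub_index = 2, chrom = "1",
                        start = 1, end = 2, variation_type = "duplication",
                        stringsAsFactors = FALSE)
  expect_warning(kbs <- build_knowledge_bases(labeled, matched),
                 "no matched CNV")
  expect_equal(nrow(kbs$syndrome), 0)
})

test_that("store sizes equal planted category counts on a synthetic corpus", {
  sim <- simulate_corpus(corpus_sim_config(n_reports = 30, seed = 4,
                                           multi_cnv_fraction = 0))
  truth <- sim$truth
  matched <- sim$cnv_truth
  for (i in seq_len(nrow(sim$cnv_truth))) {
    r <- sim$reports[[match(matched$report_id[i],
                            vapply(sim$reports, `[[`, "", "report_id"))]]
    matched$chrom[i] <- r$cnvs$chrom[matched$cnv_index[i]]
    matched$start[i] <- r$cnvs$start[matched$cnv_index[i]]
    matched$end[i] <- r$cnvs$end[matched$cnv_index[i]]
    matched$variation_type[i] <- r$cnvs$variation_type[matched$cnv_index[i]]
  }
  kbs <- build_knowledge_bases(truth, matched)
  # one record per sub-paragraph containing >=1 sentence of the category
  # (regions are distinct across reports, so no merging applies)
  key <- paste(truth$report_id, truth$sub_index)
  for (spec in list(c("Syndrome", "syndrome"), c("Gene", "gene"),
                    c("Paper", "paper"), c("Patient", "patient"))) {
    n_subs_with <- length(unique(key[truth$category == spec[1]]))
    expect_equal(nrow(kbs[[spec[2]]]), n_subs_with)
  }
})

test_that("region queries agree with the brute-force all-pairs oracle", {
  set.seed(17)
  store <- data.frame(
    chrom = sample(c("1", "2"), 200, replace = TRUE),
    start = sample.int(10000, 200, replace = TRUE),
    stringsAsFactors = FALSE)
  store$end <- store$start + sample.int(800, 200, replace = TRUE)
  store$frequency <- runif(200)
  store$sample_size <- 100
  store$source <- "x"
  store$id <- seq_len(200)
  for (q in 1:50) {
    chrom <- sample(c("1", "2", "3"), 1)
    qs <- sample.int(10000, 1); qe <- qs + sample.int(1500, 1)
    got <- query_region(store, chrom, qs, qe)
    want <- brute_overlaps(store, chrom, qs, qe)
    expect_setequal(got$id, want$id)
    expect_equal(sort(got$overlap_bp, decreasing = TRUE), got$overlap_bp)
    if (nrow(got)) {
      expect_equal(got$overlap_bp[order(got$id)],
                   want$overlap_bp[order(want$id)])
    }
  }
  # printed example: [100,200] vs [150,250] overlap 51 bp, 1-based inclusive
  one <- data.frame(chrom = "1", start = 150, end = 250, frequency = 0.1,
                    sample_size = 10, source = "x")
  expect_equal(query_region(one, "1", 100, 200)$overlap_bp, 51)
  expect_equal(nrow(query_region(one, "1", 300, 400)), 0)
})

test_that("evidence stores refuse five-tier classification columns", {
  bad <- data.frame(chrom = "1", start = 1, end = 10,
                    syndrome_name = "s", dosage_mechanism = "deletion",
                    corpus = "c", source = "x",
                    classification = "pathogenic",
                    stringsAsFactors = FALSE)
  expect_error(knowledge_base_set(syndrome = bad), "evidence")
  # the patient store legitimately carries reported_classification
  pat <- data.frame(chrom = "1", start = 1, end = 10, phenotype = "p",
                    reported_classification = "benign",
                    source = "open_access", stringsAsFactors = FALSE)
  expect_s3_class(knowledge_base_set(patient = pat), "knowledge_base_set")
})

test_that("knowledge bases round-trip through TSV + manifest serialization", {
  sim <- simulate_interpretation_fixtures(interp_sim_config(n_cnvs = 40,
                                                            seed = 3))
  dir <- withr::local_tempdir()
  write_kb(sim$kbs, dir)
  back <- read_kb(dir)
  expect_equal(back$version, sim$kbs$version)
  # identical query results before and after
  for (i in c(1, 5, 10)) {
    cnv <- sim$cnvs[i, ]
    for (s in c("polymorphism", "syndrome", "gene", "paper")) {
      a <- query_region(sim$kbs[[s]], cnv$chrom, cnv$start, cnv$end)
      b <- query_region(back[[s]], cnv$chrom, cnv$start, cnv$end)
      expect_equal(nrow(a), nrow(b))
      expect_equal(a$overlap_bp, b$overlap_bp)
    }
  }
})

test_that("duplicate regions merge corpus and sum distinct-citation case counts", {
  labeled <- data.frame(
    report_id = c("A", "B"), sub_index = c(1, 1), sent_index = c(0, 0),
    text = c("five cases in the literature", "three cases published"),
    category = c("Paper", "Paper"), stringsAsFactors = FALSE)
  matched <- data.frame(report_id = c("A", "B"), sub_index = c(1, 1),
                        chrom = "5", start = 1e6, end = 2e6,
                        variation_type = "duplication",
                        stringsAsFactors = FALSE)
  kbs <- build_knowledge_bases(labeled, matched)
  expect_equal(nrow(kbs$paper), 1)
  expect_equal(kbs$paper$plp_case_count, 2)  # one per distinct citation
  expect_match(kbs$paper$corpus, "five cases")
  expect_match(kbs$paper$corpus, "three cases")
})
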