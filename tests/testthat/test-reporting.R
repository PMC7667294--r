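# build a small end-to-end interpreted set from the benchmark generator
report_fixture <- function(n = 40, seed = 11) {
  sim <- simulate_interpretation_fixtures(interp_sim_config(n_cnvs = n,
                                                            seed = seed))
  res <- interpret_cnvs(sim$cnvs, sim$kbs, sim$cytobands)
  list(sim = sim, res = res,
       report = compose_report(list(sample_id = "S1",
                                    sample_type = "prenatal"),
                               res, sim$kbs, sim$cytobands))
}

test_that("benign and VOUS blocks contain the exact template sentence", {
  fx <- report_fixture()
  tiers <- vapply(fx$report$blocks, `[[`, "", "reported_classification")
  for (i in which(tiers %in% c("benign", "VOUS"))) {
    cls <- tiers[i]
    expect_match(
      fx$report$blocks[[i]]$special_explanation,
      sprintf("according to DGV, DECIPHER, OMIM, UCSC and PubMed databases and ACMG guidelines, this is a %s CNV",
              cls), fixed = TRUE)
  }
  expect_gt(sum(tiers %in% c("benign", "VOUS")), 0)
})

test_that("aneuploidy blocks pass the Aneuploid store description through", {
  fx <- report_fixture()
  flags <- vapply(seq_len(nrow(fx$res)), function(i)
    fx$res$aneuploid_flag[i], TRUE)
  expect_gt(sum(flags), 0)
  for (i in which(flags)) {
    chrom <- fx$res$chrom[i]
    desc <- fx$sim$kbs$aneuploid$description[
      fx$sim$kbs$aneuploid$chrom == chrom]
    block <- fx$report$blocks[[i]]
    expect_true(any(vapply(desc, grepl, TRUE,
                           x = block$special_explanation, fixed = TRUE)))
  }
})

test_that("pCNV blocks carry location, type and length strings plus evidence corpus", {
  fx <- report_fixture()
  tiers <- vapply(fx$report$blocks, `[[`, "", "reported_classification")
  pcnv <- which(tiers %in% c("pathogenic", "likely_pathogenic") &
                !fx$res$aneuploid_flag)
  expect_gt(length(pcnv), 0)
  for (i in pcnv) {
    b <- fx$report$blocks[[i]]
    txt <- paste(b$basic_description, b$special_explanation)
    expect_match(txt, b$cytoband, fixed = TRUE)
    expect_match(txt, cnvreporter:::variation_keyword(b$variation_type),
                 fixed = TRUE)
    expect_match(txt, render_length(b$length_bp), fixed = TRUE)
    # the special explanation cites at least one knowledge-base sentence
    expect_gt(nchar(b$special_explanation),
              nchar("This copy number variant"))
  }
})

test_that("every block round-trips to a full relation score of 9", {
  fx <- report_fixture()
  for (i in seq_along(fx$report$blocks)) {
    b <- fx$report$blocks[[i]]
    cnv <- fx$res[i, ]
    rs <- relation_score(cnv, paste(b$basic_description,
                                    b$special_explanation),
                         fx$sim$cytobands)
    expect_equal(rs$total, 9L)
  }
})

test_that("report composition is pure and benign blocks are suppressed in text", {
  fx <- report_fixture()
  rep2 <- compose_report(list(sample_id = "S1", sample_type = "prenatal"),
                         fx$res, fx$sim$kbs, fx$sim$cytobands)
  expect_identical(report_to_json(fx$report), report_to_json(rep2))
  txt_default <- render_report_text(fx$report)
  txt_all <- render_report_text(fx$report, include_suppressed = TRUE)
  tiers <- vapply(fx$report$blocks, `[[`, "", "reported_classification")
  flags <- fx$res$aneuploid_flag
  if (any(tiers == "benign" & !flags)) {
    expect_gt(length(txt_all), length(txt_default))
    expect_false(any(grepl("this is a benign CNV", txt_default,
                           fixed = TRUE)))
  }
})

test_that("a pCNV without evidence corpus is an inconsistency error", {
  sim <- simulate_interpretation_fixtures(interp_sim_config(n_cnvs = 30,
                                                            seed = 2))
  res <- interpret_cnvs(sim$cnvs, sim$kbs, sim$cytobands)
  pcnv <- which(res$classification %in% c("pathogenic",
                                          "likely_pathogenic") &
                !res$aneuploid_flag)
  expect_gt(length(pcnv), 0)
  # blank out the annotation corpus behind one pCNV
  anns <- attr(res, "annotations")
  i <- pcnv[1]
  for (s in c("syndrome", "gene", "paper")) {
    if (nrow(anns[[i]][[s]])) anns[[i]][[s]]$corpus <- ""
  }
  attr(res, "annotations") <- anns
  expect_error(compose_report(list(sample_id = "X"), res, sim$kbs,
                              sim$cytobands),
               "no evidence corpus")
})
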