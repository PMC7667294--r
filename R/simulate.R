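# vocabulary pools for the synthetic pseudo-clinical prose. The *primary*
# keywords are the ones the programming-label rule table keys on; the
# secondary pools are category-correlated vocabulary that survives keyword
# dropout, which is what lets a trained classifier beat the rule labels.
sim_vocab <- list(
  openers = c("copy number analysis identified", "sequencing detected",
              "the sample harbors", "chromosomal analysis revealed"),
  primary = list(
    Aneuploid = c("trisomy", "monosomy", "aneuploidy", "mosaicism"),
    Syndrome = c("syndrome"),
    Gene = c("haploinsufficiency", "gene", "triplosensitivity"),
    Paper = c("literature", "published", "pubmed"),
    Patient = c("patient", "proband")),
  secondary = list(
    Basic = c("coordinates", "interval", "segment", "copy", "state"),
    Aneuploid = c("nondisjunction", "meiotic", "karyotype", "whole"),
    Syndrome = c("dysmorphic", "congenital", "malformation", "anomalies"),
    Gene = c("transcript", "exon", "protein", "expression"),
    Paper = c("cohort", "journal", "authors", "citation"),
    Patient = c("phenotype", "pregnancy", "ultrasound", "follow")),
  filler = c("the", "was", "this", "with", "and", "for", "region",
             "result", "finding", "observed"))

#' Configuration for the synthetic report-corpus generator
#'
#' Shapes the simulated historical-report corpus: `n_reports` reports, a
#' `multi_cnv_fraction` of which (default 0.19, the multi-variant share of
#' real report archives) carry 2–`max_cnvs` variants; each variant is
#' explained by a sub-paragraph of `sentences_range` sentences whose
#' non-opening sentences draw categories from `category_mixture`. Noise:
#' each matching/category keyword is independently dropped with probability
#' `keyword_dropout`, and with probability `keyword_confusion` a sentence
#' additionally carries a misleading keyword of another category —
#' emulating the linguistic diversity of real reports that makes weak
#' labels imperfect.
#'
#' @param n_reports number of reports.
#' @param multi_cnv_fraction fraction of reports with more than one CNV.
#' @param max_cnvs maximum CNVs per multi-CNV report.
#' @param sentences_range length-2 integer range of sentences per
#'   sub-paragraph.
#' @param category_mixture named probabilities over the six categories for
#'   non-opening sentences; must sum to 1.
#' @param keyword_dropout per-keyword dropout probability.
#' @param keyword_confusion per-sentence misleading-keyword probability.
#' @param secondary_dropout per-word dropout probability for the
#'   category-correlated (non-keyword) vocabulary; with both the keyword
#'   and all secondary words dropped a sentence is unresolvable in
#'   isolation.
#' @param seed integer seed.
#' @return a `corpus_sim_config` list.
#' @export
corpus_sim_config <- function(n_reports = 500, multi_cnv_fraction = 0.19,
                              max_cnvs = 3, sentences_range = c(3, 6),
                              category_mixture = c(Basic = 0.15,
                                                   Aneuploid = 0.10,
                                                   Syndrome = 0.20,
                                                   Gene = 0.15,
                                                   Paper = 0.20,
                                                   Patient = 0.20),
                              keyword_dropout = 0.15,
                              keyword_confusion = 0.10,
                              secondary_dropout = 0.4,
                              seed = 1L) {
  stopifnot(n_reports >= 1,
            multi_cnv_fraction >= 0, multi_cnv_fraction <= 1,
            keyword_dropout >= 0, keyword_dropout <= 1,
            keyword_confusion >= 0, keyword_confusion <= 1,
            length(sentences_range) == 2,
            sentences_range[1] >= 2)
  if (!setequal(names(category_mixture), SENTENCE_CATEGORIES) ||
      any(category_mixture < 0) ||
      abs(sum(category_mixture) - 1) > 1e-8 ||
      sum(category_mixture > 0) < 2) {
    stop("degenerate category mixture: need probabilities over the six categories summing to 1 with at least two positive")
  }
  structure(list(n_reports = as.integer(n_reports),
                 multi_cnv_fraction = multi_cnv_fraction,
                 max_cnvs = as.integer(max_cnvs),
                 sentences_range = as.integer(sentences_range),
                 category_mixture = category_mixture[SENTENCE_CATEGORIES],
                 keyword_dropout = keyword_dropout,
                 keyword_confusion = keyword_confusion,
                 secondary_dropout = secondary_dropout,
                 seed = as.integer(seed)),
            class = "corpus_sim_config")
}

# one non-opening sentence of a given category, with planted-noise metadata.
# Category-correlated secondary words are themselves subject to dropout, and
# a "confused" sentence borrows the other category's vocabulary too, so a
# fraction of sentences is ambiguous or misleading in isolation and only
# resolvable from neighbouring sentences — the property that makes sequence
# context worth modelling.
sim_category_sentence <- function(category, config) {
  keep <- stats::runif(1) >= config$keyword_dropout
  confuse <- stats::runif(1) < config$keyword_confusion
  filler <- sample(sim_vocab$filler, 2)
  sec <- sample(sim_vocab$secondary[[category]], 2)
  sec <- sec[stats::runif(2) >= config$secondary_dropout]
  primary <- NULL
  if (category != "Basic" && keep) {
    primary <- sample(sim_vocab$primary[[category]], 1)
  }
  confuser <- NULL
  confuse_cat <- NA_character_
  if (confuse) {
    confuse_cat <- sample(setdiff(names(sim_vocab$primary), category), 1)
    confuser <- c(sample(sim_vocab$primary[[confuse_cat]], 1),
                  sample(sim_vocab$secondary[[confuse_cat]], 1))
  }
  text <- paste(c(filler[1], primary, sec, confuser, filler[2]),
                collapse = " ")
  list(text = text, category = category,
       primary_kept = !is.null(primary) || category == "Basic",
       confuse_cat = confuse_cat)
}

# opening (begin) sentence: basic description with independently dropped
# matching keywords
sim_begin_sentence <- function(cnv, band, config) {
  keep <- stats::runif(4) >= config$keyword_dropout
  parts <- c(sample(sim_vocab$openers, 1), "a")
  if (keep[4]) parts <- c(parts, render_length(cnv$length_bp))
  parts <- c(parts, if (keep[2]) gsub("_", " ", cnv$variation_type)
                    else "variant")
  if (keep[1]) parts <- c(parts, "on", paste0("chr", cnv$chrom))
  if (keep[3]) parts <- c(parts, "band", band)
  paste(parts, collapse = " ")
}

#' Simulate a historical-report corpus with ground truth
#'
#' Generates a seeded corpus of pseudo-clinical reports shaped like the
#' archives the corpus-mining pipeline targets: each report carries 1..k
#' CNV calls and a single explanation paragraph built by concatenating one
#' sub-paragraph per CNV. Every sub-paragraph opens with a begin sentence
#' embedding the CNV's chromosome / variant-type / cytoband / length
#' keywords (each independently subject to dropout) followed by
#' category-bearing sentences (Basic first, Patient last, mirroring real
#' report structure). The returned ground truth records begin labels, the
#' CNV-to-sub-paragraph mapping and per-sentence categories, so every
#' pipeline stage can be scored without re-deriving labels.
#'
#' @param config a [corpus_sim_config()].
#' @return a `corpus_simulation` list: `reports` (list of report objects),
#'   `truth` (per-sentence data.frame), `cnv_truth` (per-CNV data.frame
#'   with the planted sub-paragraph index), `cytobands`, `config`.
#' @export
simulate_corpus <- function(config = corpus_sim_config()) {
  stopifnot(inherits(config, "corpus_sim_config"))
  set.seed(config$seed)
  cytobands <- synthetic_cytobands()
  chrom_lens <- chromosome_lengths(cytobands)
  mix <- config$category_mixture
  reports <- vector("list", config$n_reports)
  truth_rows <- list()
  cnv_rows <- list()
  for (r in seq_len(config$n_reports)) {
    rid <- sprintf("R%05d", r)
    n_cnv <- if (stats::runif(1) < config$multi_cnv_fraction && config$max_cnvs >= 2) {
      sample(2:config$max_cnvs, 1)
    } else {
      1L
    }
    chroms <- sample(CHROMS, n_cnv)
    len <- round(exp(stats::runif(n_cnv, log(2e5), log(4e7))))
    start <- vapply(seq_len(n_cnv), function(i) {
      floor(stats::runif(1, 1, chrom_lens[chroms[i]] - len[i]))
    }, numeric(1))
    vt <- sample(VARIATION_TYPES, n_cnv, replace = TRUE,
                 prob = c(0.05, 0.45, 0.45, 0.05))
    gender <- sample(c("male", "female"), 1)
    stype <- sample(c("prenatal", "POC"), 1, prob = c(0.4, 0.6))
    cnvs <- cnv_calls(chroms, start, start + len - 1, vt, gender, stype)
    sent_idx <- 0L
    sentences <- character(0)
    for (ci in seq_len(n_cnv)) {
      band <- cytoband_label(cnvs$chrom[ci], cnvs$start[ci], cnvs$end[ci],
                             cytobands)
      n_sent <- sample(config$sentences_range[1]:config$sentences_range[2], 1)
      cats <- sample(SENTENCE_CATEGORIES, n_sent - 1, replace = TRUE,
                     prob = mix)
      # realistic ordering: Basic follows the opener, Patient closes
      cats <- c(cats[cats == "Basic"],
                cats[!cats %in% c("Basic", "Patient")],
                cats[cats == "Patient"])
      stexts <- sim_begin_sentence(cnvs[ci, ], band, config)
      scats <- "Basic"
      kept <- TRUE
      conf <- NA_character_
      for (cat in cats) {
        s <- sim_category_sentence(cat, config)
        stexts <- c(stexts, s$text)
        scats <- c(scats, s$category)
        kept <- c(kept, s$primary_kept)
        conf <- c(conf, s$confuse_cat)
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        report_id = rid, cnv_index = ci, sub_index = ci,
        sent_index = sent_idx + seq_along(stexts) - 1L,
        text = stexts, begin = seq_along(stexts) == 1,
        category = scats, primary_kept = kept, confused_as = conf,
        stringsAsFactors = FALSE)
      cnv_rows[[length(cnv_rows) + 1]] <- data.frame(
        report_id = rid, cnv_index = ci, sub_index = ci,
        begin_sent_index = sent_idx, stringsAsFactors = FALSE)
      sent_idx <- sent_idx + length(stexts)
      sentences <- c(sentences, stexts)
    }
    delims <- sample(c(", ", ". "), length(sentences), replace = TRUE)
    delims[length(delims)] <- "."
    paragraph <- paste0(sentences, delims, collapse = "")
    paragraph <- sub("[.,] ?$", ".", paragraph)
    reports[[r]] <- list(report_id = rid, sample_type = stype,
                         gender = gender, cnvs = cnvs,
                         paragraph = paragraph)
  }
  structure(list(reports = reports,
                 truth = do.call(rbind, truth_rows),
                 cnv_truth = do.call(rbind, cnv_rows),
                 cytobands = cytobands, config = config),
            class = "corpus_simulation")
}

#' Configuration for the interpretation benchmark generator
#'
#' @param n_cnvs number of benchmark CNVs.
#' @param tier_mixture named probabilities over planted outcomes:
#'   pathogenic, likely_pathogenic, benign, VOUS, plus `aneuploid`
#'   (whole-chromosome events, always pathogenic).
#' @param n_distractors unrelated knowledge-base records added per store.
#' @param seed integer seed.
#' @return an `interp_sim_config` list.
#' @export
interp_sim_config <- function(n_cnvs = 200,
                              tier_mixture = c(pathogenic = 0.18,
                                               likely_pathogenic = 0.17,
                                               benign = 0.25,
                                               VOUS = 0.30,
                                               aneuploid = 0.10),
                              n_distractors = 30, seed = 7L) {
  stopifnot(n_cnvs >= 1, abs(sum(tier_mixture) - 1) < 1e-8,
            all(tier_mixture >= 0),
            setequal(names(tier_mixture),
                     c("pathogenic", "likely_pathogenic", "benign", "VOUS",
                       "aneuploid")))
  structure(list(n_cnvs = as.integer(n_cnvs), tier_mixture = tier_mixture,
                 n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "interp_sim_config")
}

#' Simulate an interpretation benchmark with planted truth
#'
#' Co-designs CNV calls and knowledge-base records so the documented
#' default evidence rules should recover the planted five-tier outcomes:
#' pathogenic CNVs sit on well-covered syndrome regions or heavy literature
#' case counts, likely-pathogenic ones on single dosage-matched genes,
#' moderate syndrome coverage or few literature cases, benign ones inside
#' common high-frequency population CNVs, VOUS CNVs overlap nothing
#' informative, and aneuploidies span whole chromosomes with an Aneuploid
#' knowledge-base description. Distractor records on other chromosomes
#' exercise the filters. The truth table carries the planted tier for every
#' CNV.
#'
#' @param config an [interp_sim_config()].
#' @return an `interp_simulation` list: `cnvs`, `kbs`, `truth`,
#'   `cytobands`, `config`.
#' @export
simulate_interpretation_fixtures <- function(config = interp_sim_config()) {
  stopifnot(inherits(config, "interp_sim_config"))
  set.seed(config$seed)
  cytobands <- synthetic_cytobands()
  chrom_lens <- chromosome_lengths(cytobands)
  n <- config$n_cnvs
  planted <- sample(names(config$tier_mixture), n, replace = TRUE,
                    prob = config$tier_mixture)
  poly <- list(); synd <- list(); gene <- list(); pap <- list()
  aneu <- list(); pat <- list()
  rows <- vector("list", n)
  mechanisms <- character(n)
  for (i in seq_len(n)) {
    tier <- planted[i]
    chrom <- sample(CHROMS, 1)
    if (tier == "aneuploid") {
      vt <- sample(c("duplication", "heterozygous_deletion"), 1)
      start <- 1; end <- chrom_lens[chrom]
      ev <- if (vt == "duplication") "gain" else "loss"
      aneu[[length(aneu) + 1]] <- data.frame(
        chrom = chrom, event = ev,
        description = sprintf(
          "%s of chromosome %s detected, consistent with a clinically significant aneuploidy",
          if (ev == "gain") "trisomy" else "monosomy", chrom),
        source = "synthetic", stringsAsFactors = FALSE)
    } else {
      vt <- sample(VARIATION_TYPES, 1, prob = c(0.05, 0.45, 0.45, 0.05))
      len <- round(exp(stats::runif(1, log(5e5), log(2e7))))
      start <- floor(stats::runif(1, 1, chrom_lens[chrom] - len))
      end <- start + len - 1
    }
    del <- grepl("deletion", vt)
    mech <- if (del) "deletion" else "duplication"
    sens <- if (del) "haploinsufficient" else "triplosensitive"
    mechanisms[i] <- mech
    if (tier == "pathogenic") {
      if (stats::runif(1) < 0.5) {
        # syndrome region ~90% covered by the CNV
        len <- end - start + 1
        synd[[length(synd) + 1]] <- data.frame(
          chrom = chrom, start = start + round(0.05 * len),
          end = end - round(0.05 * len),
          syndrome_name = sprintf("synthetic syndrome %d", i),
          dosage_mechanism = mech,
          corpus = sprintf(
            "%s of this region causes synthetic syndrome %d with congenital anomalies",
            mech, i),
          source = "synthetic", stringsAsFactors = FALSE)
      } else {
        pap[[length(pap) + 1]] <- data.frame(
          chrom = chrom, start = start, end = end, plp_case_count = 12,
          citation = sprintf("synthetic:%d", i),
          corpus = sprintf(
            "twelve pathogenic cases with similar %ss are described in the literature",
            mech),
          stringsAsFactors = FALSE)
      }
    } else if (tier == "likely_pathogenic") {
      pick <- stats::runif(1)
      if (pick < 1 / 3) {
        len <- end - start + 1
        gene[[length(gene) + 1]] <- data.frame(
          gene_symbol = sprintf("SYN%03d", i), chrom = chrom,
          start = start + round(0.2 * len), end = end - round(0.2 * len),
          dosage_sensitivity = sens,
          corpus = sprintf(
            "the dosage-sensitive gene SYN%03d lies within this region", i),
          source = "synthetic", stringsAsFactors = FALSE)
      } else if (pick < 2 / 3) {
        len <- end - start + 1
        synd[[length(synd) + 1]] <- data.frame(
          chrom = chrom, start = start + round(0.2 * len),
          end = end + round(0.35 * len),  # ~0.57 of record covered
          syndrome_name = sprintf("synthetic syndrome %d", i),
          dosage_mechanism = mech,
          corpus = sprintf(
            "partial overlap with synthetic syndrome %d region is reported", i),
          source = "synthetic", stringsAsFactors = FALSE)
      } else {
        pap[[length(pap) + 1]] <- data.frame(
          chrom = chrom, start = start, end = end, plp_case_count = 5,
          citation = sprintf("synthetic:%d", i),
          corpus = "five pathogenic carrier cases appear in published reports",
          stringsAsFactors = FALSE)
      }
    } else if (tier == "benign") {
      len <- end - start + 1
      poly[[length(poly) + 1]] <- data.frame(
        chrom = chrom, start = max(1, start - round(0.05 * len)),
        end = end + round(0.05 * len),
        frequency = stats::runif(1, 0.05, 0.3),
        sample_size = round(stats::runif(1, 2000, 10000)),
        source = "synthetic", stringsAsFactors = FALSE)
      if (stats::runif(1) < 0.3) {
        pat[[length(pat) + 1]] <- data.frame(
          chrom = chrom, start = start, end = end,
          phenotype = "normal phenotype reported for a carrier",
          reported_classification = "benign", source = "open_access",
          stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- data.frame(chrom = chrom, start = start, end = end,
                            variation_type = vt, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  cnvs <- cnv_calls(calls$chrom, calls$start, calls$end,
                    calls$variation_type,
                    gender = sample(c("male", "female"), n, replace = TRUE),
                    sample_type = sample(c("prenatal", "POC"), n,
                                         replace = TRUE),
                    validate_length = FALSE)
  # distractors: sub-threshold or off-target records exercising the filters.
  # Syndrome distractors are deliberately broad regions (30-60 Mb) that no
  # benchmark CNV can cover to the 0.5 overlap_db threshold; polymorphism
  # distractors sit below the frequency and sample-size filters.
  for (d in seq_len(config$n_distractors)) {
    chrom <- sample(CHROMS, 1)
    start <- floor(stats::runif(1, 1, chrom_lens[chrom] * 0.5))
    end <- min(start + round(stats::runif(1, 3e7, 6e7)), chrom_lens[chrom])
    synd[[length(synd) + 1]] <- data.frame(
      chrom = chrom, start = start, end = end,
      syndrome_name = sprintf("distractor %d", d),
      dosage_mechanism = sample(c("deletion", "duplication"), 1),
      corpus = "distractor record", source = "synthetic",
      stringsAsFactors = FALSE)
    poly[[length(poly) + 1]] <- data.frame(
      chrom = chrom, start = start, end = end,
      frequency = stats::runif(1, 0, 0.005),   # below frequency filter
      sample_size = round(stats::runif(1, 10, 500)),
      source = "synthetic", stringsAsFactors = FALSE)
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  kbs <- knowledge_base_set(
    polymorphism = bind(poly),
    aneuploid = merge_aneuploid_store(bind(aneu)),
    syndrome = bind(synd), gene = bind(gene), paper = bind(pap),
    patient = bind(pat),
    version = sprintf("synthetic-seed%d", config$seed))
  truth <- cbind(as.data.frame(cnvs),
                 data.frame(planted_tier = ifelse(planted == "aneuploid",
                                                  "pathogenic", planted),
                            planted_aneuploid = planted == "aneuploid",
                            planted_pcnv = planted %in%
                              c("pathogenic", "likely_pathogenic",
                                "aneuploid")))
  structure(list(cnvs = cnvs, kbs = kbs, truth = truth,
                 cytobands = cytobands, config = config),
            class = "interp_simulation")
}
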