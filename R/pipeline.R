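#' Mine a report archive into a labeled corpus
#'
#' Runs the three-step corpus-mining pipeline over a list of historical
#' reports: (1) sentence splitting and begin/not-begin segmentation with a
#' classifier trained on the archive itself, (2) relation-score matching of
#' each report's CNVs to its sub-paragraphs, and (3, optional) weak
#' category labels from the keyword rule table.
#'
#' @param reports list of report objects (see [read_reports_jsonl()]).
#' @param cytobands a `cytoband_table`.
#' @param config a [training_config()].
#' @param rules a [keyword_rules()] table or NULL to skip weak labeling.
#' @param tokenizer tokenizer function.
#' @return a `mined_corpus` list: `corpus` (per-sentence data.frame with
#'   `report_id`, `sub_index`, `sent_index`, `text`, `begin_label`, and
#'   `category` when rules were given), `assignments` (per-CNV data.frame
#'   with the matched `sub_index` and relation score), `matched_subs`
#'   (per-sub data.frame with the best-scoring CNV for knowledge-base
#'   construction), and the fitted `begin_model`.
#' @export
mine_corpus <- function(reports, cytobands, config = training_config(),
                        rules = default_keyword_rules(),
                        tokenizer = tokenize) {
  model <- train_begin_classifier(reports, config, tokenizer)
  corpus_rows <- list()
  assign_rows <- list()
  sub_rows <- list()
  for (r in reports) {
    sents <- split_sentences(r$paragraph)
    if (!length(sents)) next
    seg <- segment_paragraph(sents, model)
    subs <- subparagraph_texts(seg)
    sm <- relation_score_matrix(r$cnvs, subs, cytobands)
    assignment <- match_cnvs(r$cnvs, subs, cytobands, score_matrix = sm)
    corpus_rows[[length(corpus_rows) + 1]] <- data.frame(
      report_id = r$report_id, sub_index = seg$sub_index,
      sent_index = seg$sent_index, text = seg$text,
      begin_label = ifelse(seg$begin, "begin", "not_begin"),
      stringsAsFactors = FALSE)
    assign_rows[[length(assign_rows) + 1]] <- data.frame(
      report_id = r$report_id, cnv_index = seq_len(nrow(r$cnvs)),
      sub_index = assignment,
      score = sm[cbind(seq_len(nrow(r$cnvs)), assignment)],
      stringsAsFactors = FALSE)
    # per sub-paragraph, the best-scoring CNV (for region assignment)
    best_cnv <- max.col(t(sm), ties.method = "first")
    sub_rows[[length(sub_rows) + 1]] <- data.frame(
      report_id = r$report_id, sub_index = seq_along(subs),
      chrom = r$cnvs$chrom[best_cnv], start = r$cnvs$start[best_cnv],
      end = r$cnvs$end[best_cnv],
      variation_type = r$cnvs$variation_type[best_cnv],
      score = sm[cbind(best_cnv, seq_along(subs))],
      stringsAsFactors = FALSE)
  }
  corpus <- do.call(rbind, corpus_rows)
  if (!is.null(rules)) {
    corpus$category <- generate_programming_labels(corpus$text, rules)
  }
  structure(list(corpus = corpus,
                 assignments = do.call(rbind, assign_rows),
                 matched_subs = do.call(rbind, sub_rows),
                 begin_model = model),
            class = "mined_corpus")
}

#' Score CNV-to-sub-paragraph pair recovery against planted truth
#'
#' Evaluates the combined segmentation + matching stage on a simulated
#' corpus: a planted pair is counted recovered when the predicted
#' sub-paragraph matched to the CNV contains that CNV's true begin sentence
#' and no other CNV's begin sentence — merged or split segmentations
#' therefore count against recovery even when the argmax matching is
#' locally right.
#'
#' @param mined a `mined_corpus` from [mine_corpus()].
#' @param sim a `corpus_simulation` from [simulate_corpus()].
#' @return list with `recovered`, `total`, `rate`.
#' @export
pair_recovery <- function(mined, sim) {
  stopifnot(inherits(mined, "mined_corpus"),
            inherits(sim, "corpus_simulation"))
  truth <- sim$cnv_truth
  corpus <- mined$corpus
  assignments <- mined$assignments
  ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    rid <- truth$report_id[i]
    a <- assignments[assignments$report_id == rid &
                     assignments$cnv_index == truth$cnv_index[i], ]
    if (nrow(a) != 1) next
    sents <- corpus$sent_index[corpus$report_id == rid &
                               corpus$sub_index == a$sub_index]
    begins <- truth$begin_sent_index[truth$report_id == rid]
    own <- truth$begin_sent_index[i]
    ok[i] <- own %in% sents && !any(setdiff(begins, own) %in% sents)
  }
  list(recovered = sum(ok), total = nrow(truth),
       rate = sum(ok) / nrow(truth))
}
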