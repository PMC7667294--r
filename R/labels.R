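#' Six sentence categories of the labeled corpus
#'
#' Basic (cytogenetic location, size, copy-number state — key indices, not
#' scoring evidence), Aneuploid (whole-chromosome events, always
#' pathogenic), Syndrome, Gene and Paper (the evidence classes driving
#' classification and report text), and Patient (previously reported
#' carriers, annotation display only).
#'
#' @format character vector of length 6.
#' @export
SENTENCE_CATEGORIES <- c("Basic", "Aneuploid", "Syndrome", "Gene",
                         "Paper", "Patient")

#' Default keyword rule table for programming labels
#'
#' Ordered keyword-to-category rules used to produce the weak
#' ("programming") training labels: the first rule whose keyword occurs in a
#' sentence wins, and sentences matching no rule fall back to the default
#' category (Basic). Keywords are matched case-insensitively as substrings.
#'
#' @return a `keyword_rules` data.frame with columns `keyword`, `category`.
#' @export
default_keyword_rules <- function() {
  keyword_rules(
    keyword = c("trisomy", "monosomy", "aneuploid", "mosaic", "heteroploid",
                "syndrome",
                "haploinsufficien", "triplosensitiv", "dosage-sensitive",
                "gene",
                "literature", "pubmed", "published",
                "patient", "proband"),
    category = c(rep("Aneuploid", 5), "Syndrome", rep("Gene", 4),
                 rep("Paper", 3), rep("Patient", 2)))
}

#' Construct a keyword rule table
#'
#' @param keyword character vector of keywords (substring patterns).
#' @param category category assigned by each rule; must be one of the six
#'   sentence categories.
#' @return a `keyword_rules` data.frame; row order is rule priority.
#' @export
keyword_rules <- function(keyword, category) {
  stopifnot(length(keyword) == length(category), length(keyword) >= 1,
            all(category %in% SENTENCE_CATEGORIES))
  structure(data.frame(keyword = keyword, category = category,
                       stringsAsFactors = FALSE),
            class = c("keyword_rules", "data.frame"))
}

#' Weak labels for sentences by keyword string matching
#'
#' Assigns each sentence the category of the first matching rule in the rule
#' table (first-matching-rule-wins); sentences matching no rule receive
#' `default_category`. The labels are deliberately cheap and possibly
#' inaccurate — they bootstrap the trained classifier and the
#' active-learning loop.
#'
#' @param sentences character vector.
#' @param rules a [keyword_rules()] table.
#' @param default_category fallback category (default "Basic").
#' @return character vector of categories, one per sentence.
#' @export
#' @examples
#' generate_programming_labels("described in the literature",
#'                             default_keyword_rules())
generate_programming_labels <- function(sentences,
                                        rules = default_keyword_rules(),
                                        default_category = "Basic") {
  stopifnot(nrow(rules) >= 1, default_category %in% SENTENCE_CATEGORIES)
  low <- tolower(sentences)
  out <- rep(default_category, length(sentences))
  undecided <- rep(TRUE, length(sentences))
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & grepl(tolower(rules$keyword[i]), low, fixed = TRUE)
    out[hit] <- rules$category[i]
    undecided[hit] <- FALSE
  }
  out
}

#' Select sub-paragraphs for expert labeling (active learning)
#'
#' Flags sub-paragraphs whose predicted sentence categories look implausible
#' and should be sent to a clinical laboratory geneticist: trigger A fires
#' when some window of three consecutive sentences carries three distinct
#' categories; trigger B fires when the number of distinct categories in the
#' sub-paragraph exceeds three. In well-formed explanations a category
#' change every sentence is unlikely, so these patterns indicate label
#' noise. The two triggers are combined with OR by default (more inclusive,
#' so more candidates reach the expert); both are reported separately.
#'
#' @param labels_by_sub list of character vectors: predicted categories of
#'   each sub-paragraph's sentences, in order.
#' @param combine `"or"` (default) or `"and"`.
#' @return data.frame with columns `sub` (index into the input list),
#'   `trigger_window`, `trigger_count`, `selected`.
#' @export
select_for_active_labeling <- function(labels_by_sub,
                                       combine = c("or", "and")) {
  combine <- match.arg(combine)
  if (is.character(labels_by_sub)) labels_by_sub <- list(labels_by_sub)
  trig_a <- vapply(labels_by_sub, function(lab) {
    n <- length(lab)
    if (n < 3) return(FALSE)
    any(vapply(seq_len(n - 2),
               function(i) length(unique(lab[i:(i + 2)])) == 3, TRUE))
  }, TRUE)
  trig_b <- vapply(labels_by_sub,
                   function(lab) length(unique(lab)) > 3, TRUE)
  sel <- if (combine == "or") trig_a | trig_b else trig_a & trig_b
  data.frame(sub = seq_along(labels_by_sub), trigger_window = trig_a,
             trigger_count = trig_b, selected = sel)
}
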