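#' Report template strings
#'
#' Locale-indexed template sentences used when composing diagnostic
#' reports. The English benign/VOUS template is the sentence printed for
#' variants without pathogenic evidence; the Chinese strings are
#' translations of the English ones provided for bilingual deployments.
#'
#' @param locale `"en"` (default) or `"zh"`.
#' @return named list of template strings; `%s` slots are filled by
#'   [compose_report()].
#' @export
report_templates <- function(locale = c("en", "zh")) {
  locale <- match.arg(locale)
  templates <- list(
    en = list(
      benign_vous = "according to DGV, DECIPHER, OMIM, UCSC and PubMed databases and ACMG guidelines, this is a %s CNV",
      significance = "This copy number variant is classified as %s and should be reviewed together with the clinical findings.",
      basic = "Cytogenetic location %s%s (chr%s:%s-%s), %s of %s."),
    zh = list(
      benign_vous = "\u6839\u636EDGV\u3001DECIPHER\u3001OMIM\u3001UCSC\u53CAPubMed\u6570\u636E\u5E93\u548CACMG\u6307\u5357\uFF0C\u8BE5CNV\u4E3A%s",
      significance = "\u8BE5\u62F7\u8D1D\u6570\u53D8\u5F02\u5206\u7C7B\u4E3A%s\uFF0C\u8BF7\u7ED3\u5408\u4E34\u5E8A\u8868\u73B0\u5BA1\u9605\u3002",
      basic = "\u7EC6\u80DE\u9057\u4F20\u5B66\u5B9A\u4F4D%s%s\uFF08chr%s:%s-%s\uFF09\uFF0C%s\uFF0C\u5927\u5C0F%s\u3002"))
  templates[[locale]]
}

#' Compose a structured diagnostic report
#'
#' Builds one report block per classified variant:
#' * basic description — cytogenetic location, variation type, CNV length
#'   (always present, so every block carries all four matching keywords);
#' * special explanation — for whole-chromosome aneuploidies, the
#'   description from the Aneuploid knowledge base verbatim; for pCNVs
#'   (pathogenic / likely pathogenic), the knowledge-base corpus sentences
#'   in Syndrome, Gene, Paper order followed by the clinical-significance
#'   statement; for benign or VOUS calls, the fixed database/guideline
#'   template sentence with the class substituted.
#'
#' Reported classes collapse likely_benign into benign. A pCNV whose
#' annotation carries no corpus evidence at all is a classification /
#' evidence inconsistency and raises an error. Benign blocks are kept in
#' the structured output but flagged `suppressed` (default on), reflecting
#' reporting practice of not printing benign findings.
#'
#' @param sample list of sample metadata (e.g. `sample_id`, `sample_type`,
#'   `gender`); stored verbatim.
#' @param interpreted output of [interpret_cnvs()] (calls + classifications
#'   with annotations attached).
#' @param kbs the `knowledge_base_set` used for interpretation.
#' @param cytobands a `cytoband_table`.
#' @param templates a [report_templates()] list.
#' @param suppress_benign flag benign blocks as suppressed in rendering.
#' @return a `diagnostic_report`.
#' @export
compose_report <- function(sample, interpreted, kbs, cytobands,
                           templates = report_templates("en"),
                           suppress_benign = TRUE) {
  anns <- attr(interpreted, "annotations")
  stopifnot(!is.null(anns), nrow(interpreted) == length(anns))
  blocks <- lapply(seq_len(nrow(interpreted)), function(i) {
    row <- interpreted[i, ]
    ann <- anns[[i]]
    band <- cytoband_label(row$chrom, row$start, row$end, cytobands)
    basic <- sprintf(templates$basic, row$chrom, band, row$chrom,
                     format(row$start, scientific = FALSE, trim = TRUE),
                     format(row$end, scientific = FALSE, trim = TRUE),
                     gsub("_", " ", row$variation_type),
                     render_length(row$length_bp))
    reported <- if (row$classification %in% c("benign", "likely_benign")) {
      "benign"
    } else {
      row$classification
    }
    if (isTRUE(row$aneuploid_flag)) {
      special <- if (nrow(ann$aneuploid)) {
        paste(ann$aneuploid$description, collapse = " ")
      } else {
        ann$whole_chromosome$descriptor
      }
    } else if (reported %in% c("pathogenic", "likely_pathogenic")) {
      corpus <- c(ann$syndrome$corpus, ann$gene$corpus, ann$paper$corpus)
      corpus <- corpus[!is.na(corpus) & nzchar(corpus)]
      if (!length(corpus)) {
        stop(sprintf(
          "pCNV at %s:%s-%s classified %s but has no evidence corpus",
          row$chrom, row$start, row$end, row$classification))
      }
      special <- paste(c(corpus,
                         sprintf(templates$significance,
                                 gsub("_", " ", reported))),
                       collapse = " ")
    } else {
      special <- sprintf(templates$benign_vous, reported)
    }
    list(chrom = row$chrom, start = row$start, end = row$end,
         variation_type = row$variation_type, length_bp = row$length_bp,
         cytoband = band,
         reported_classification = reported,
         basic_description = basic,
         special_explanation = special,
         suppressed = suppress_benign && reported == "benign" &&
           !isTRUE(row$aneuploid_flag))
  })
  structure(list(sample = sample, blocks = blocks,
                 review_status = "pending_review"),
            class = "diagnostic_report")
}

#' Render a diagnostic report as plain text
#'
#' @param report a `diagnostic_report`.
#' @param include_suppressed also render blocks flagged suppressed.
#' @return character vector of lines.
#' @export
render_report_text <- function(report, include_suppressed = FALSE) {
  stopifnot(inherits(report, "diagnostic_report"))
  lines <- c(sprintf("Sample: %s",
                     paste(unlist(report$sample), collapse = " / ")),
             sprintf("Review status: %s", report$review_status), "")
  for (b in report$blocks) {
    if (b$suppressed && !include_suppressed) next
    lines <- c(lines,
               sprintf("[%s] %s", gsub("_", " ", b$reported_classification),
                       b$basic_description),
               b$special_explanation, "")
  }
  lines
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(render_report_text(x, include_suppressed = TRUE), sep = "\n")
  invisible(x)
}

#' Serialize a diagnostic report to JSON
#'
#' @param report a `diagnostic_report`.
#' @param file optional path; when NULL the JSON string is returned.
#' @export
report_to_json <- function(report, file = NULL) {
  stopifnot(inherits(report, "diagnostic_report"))
  x <- unclass(report)
  if (is.null(file)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    jsonlite::write_json(x, file, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(file)
  }
}
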