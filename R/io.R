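#' Read / write report archives as JSON-lines
#'
#' One report per line:
#' `{"report_id": ..., "sample_type": ..., "cnvs": [...], "paragraph": ...}`
#' with `cnvs` an array of `{chrom, start, end, variation_type}` objects
#' (optional `gender` kept when present).
#'
#' @param file path or connection.
#' @return list of report objects (`report_id`, `sample_type`, `cnvs` as a
#'   `cnv_calls` table, `paragraph`).
#' @export
read_reports_jsonl <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyDataFrame = TRUE)
    cn <- as.data.frame(x$cnvs)
    x$cnvs <- cnv_calls(cn$chrom, cn$start, cn$end, cn$variation_type,
                        gender = if (!is.null(x$gender)) x$gender
                                 else "unknown",
                        sample_type = x$sample_type,
                        validate_length = FALSE)
    x
  })
}

#' @rdname read_reports_jsonl
#' @param reports list of report objects.
#' @export
write_reports_jsonl <- function(reports, file) {
  lines <- vapply(reports, function(r) {
    jsonlite::toJSON(list(
      report_id = r$report_id, sample_type = r$sample_type,
      gender = if (!is.null(r$gender)) r$gender else "unknown",
      cnvs = r$cnvs[c("chrom", "start", "end", "variation_type")],
      paragraph = r$paragraph), auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Read / write a labeled corpus as TSV
#'
#' Columns: `report_id`, `sub_index`, `sent_index`, `text`, `begin_label`,
#' `category`.
#'
#' @param file path.
#' @return data.frame in the labeled-corpus schema.
#' @export
read_labeled_corpus <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  need <- c("report_id", "sub_index", "sent_index", "text", "begin_label",
            "category")
  stopifnot(all(need %in% names(df)))
  df
}

#' @rdname read_labeled_corpus
#' @param corpus labeled-corpus data.frame.
#' @export
write_labeled_corpus <- function(corpus, file) {
  need <- c("report_id", "sub_index", "sent_index", "text", "begin_label",
            "category")
  stopifnot(all(need %in% names(corpus)))
  utils::write.table(corpus[need], file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' Read CNV calls from a TSV/BED-like table
#'
#' Expects columns `chrom`, `start`, `end`, `variation_type` and optionally
#' `gender`, `sample_type`.
#'
#' @param file path.
#' @param ... passed to [cnv_calls()] (e.g. `validate_length`).
#' @return a `cnv_calls` table.
#' @export
read_cnv_calls <- function(file, ...) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cnv_calls(df$chrom, df$start, df$end, df$variation_type,
            gender = if ("gender" %in% names(df)) df$gender else "unknown",
            sample_type = if ("sample_type" %in% names(df)) df$sample_type
                          else "prenatal", ...)
}
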