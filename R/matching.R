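#' Supported copy-number states
#'
#' @format character vector of the four copy-number states reported by the
#'   CNV-seq platform.
#' @export
VARIATION_TYPES <- c("homozygous_deletion", "heterozygous_deletion",
                     "duplication", "triplication")

CHROMS <- c(as.character(1:22), "X", "Y")

#' Construct a validated CNV call table
#'
#' CNV calls use the clinical 1-based inclusive convention. Copy-number
#' states follow the four-level scheme used in prenatal/POC CNV-seq
#' reporting: homozygous deletion, heterozygous deletion, duplication,
#' triplication. Calls shorter than `min_length` (default 100 kb, the
#' platform's minimum reportable CNV length) are rejected unless
#' `validate_length = FALSE` (whole-chromosome aneuploidies always pass).
#'
#' @param chrom chromosome names (1..22, X, Y; "chr" prefix tolerated).
#' @param start,end 1-based inclusive coordinates.
#' @param variation_type one of `r paste(VARIATION_TYPES, collapse=", ")`.
#' @param gender "male", "female" or "unknown".
#' @param sample_type "prenatal" or "POC".
#' @param min_length minimum CNV length in bp.
#' @param validate_length enforce `min_length`.
#' @return a `cnv_calls` data.frame with a derived `length_bp` column.
#' @export
cnv_calls <- function(chrom, start, end, variation_type,
                      gender = "unknown", sample_type = "prenatal",
                      min_length = 1e5, validate_length = TRUE) {
  chrom <- sub("^chr", "", as.character(chrom))
  stopifnot(all(chrom %in% CHROMS),
            all(variation_type %in% VARIATION_TYPES),
            all(gender %in% c("male", "female", "unknown")),
            all(sample_type %in% c("prenatal", "POC")))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start > end)) stop("CNV start must not exceed end")
  if (any(start < 1)) stop("coordinates are 1-based; start must be >= 1")
  len <- end - start + 1
  if (validate_length && any(len < min_length)) {
    stop(sprintf("CNV shorter than the %s bp minimum reportable length",
                 format(min_length, scientific = FALSE)))
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   variation_type = rep_len(variation_type, length(chrom)),
                   gender = rep_len(gender, length(chrom)),
                   sample_type = rep_len(sample_type, length(chrom)),
                   length_bp = len, stringsAsFactors = FALSE)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

#' Render a CNV length as its report keyword
#'
#' Lengths of at least 1 Mb are printed in Mb with up to two decimals and
#' trailing zeros trimmed ("50 Mb", "1.26 Mb"); shorter CNVs in integer kb
#' ("480 Kb"). Matching against report text is case-insensitive on the unit.
#'
#' @param length_bp CNV length in bp.
#' @return character, e.g. `"1.26 Mb"`.
#' @export
render_length <- function(length_bp) {
  vapply(length_bp, function(l) {
    if (l >= 1e6) {
      v <- sprintf("%.2f", l / 1e6)
      v <- sub("0+$", "", v)
      v <- sub("\\.$", "", v)
      paste(v, "Mb")
    } else {
      paste(round(l / 1e3), "Kb")
    }
  }, character(1))
}

variation_keyword <- function(variation_type) {
  c(homozygous_deletion = "deletion", heterozygous_deletion = "deletion",
    duplication = "duplication", triplication = "triplication")[variation_type]
}

#' @keywords internal
chrom_keyword_patterns <- function(chrom) {
  c(sprintf("chr%s(?![0-9])", chrom),
    sprintf("chromosome %s(?![0-9])", chrom),
    sprintf("(?<![0-9])%s\u53F7", chrom))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Relation score between a CNV and a sub-paragraph
#'
#' Computes the keyword-based relation score used to match a CNV against a
#' candidate explanation sub-paragraph:
#' \deqn{score = 5 \cdot chr + 2 \cdot type + cyto + length}
#' Each component is 1 iff its rendered keyword occurs in the sub-paragraph
#' text: the chromosome token ("chr7", "chromosome 7", or the CJK "7号"
#' form), the variant-type word ("deletion", "duplication", "triplication"),
#' the cytoband label (e.g. "p11.32"), and the formatted length (e.g.
#' "50 Mb"). The empirical weights make the chromosome decisive, the variant
#' type next, and cytoband/length tie-breakers; the maximum is 9.
#'
#' @param cnv single-row `cnv_calls` (or list with chrom/start/end/
#'   variation_type/length_bp).
#' @param sub_text sub-paragraph text: character vector of sentences (they
#'   are concatenated) or a single string.
#' @param cytobands a `cytoband_table` for the cytoband keyword.
#' @return a `relation_score` list: chr_score, type_score, cyto_score,
#'   length_score (0/1 each) and total (0..9).
#' @export
relation_score <- function(cnv, sub_text, cytobands) {
  text <- paste(sub_text, collapse = " ")
  chr_score <- as.integer(any(vapply(
    chrom_keyword_patterns(cnv$chrom),
    function(p) grepl(p, text, perl = TRUE, ignore.case = TRUE), TRUE)))
  type_score <- as.integer(grepl(variation_keyword(cnv$variation_type), text,
                                 fixed = TRUE, ignore.case = FALSE))
  band <- cytoband_label(cnv$chrom, cnv$start, cnv$end, cytobands)
  cyto_score <- as.integer(grepl(band, text, fixed = TRUE))
  len_kw <- render_length(cnv$end - cnv$start + 1)
  length_score <- as.integer(grepl(escape_regex(len_kw), text,
                                   perl = TRUE, ignore.case = TRUE))
  total <- 5L * chr_score + 2L * type_score + cyto_score + length_score
  structure(list(chr_score = chr_score, type_score = type_score,
                 cyto_score = cyto_score, length_score = length_score,
                 total = total),
            class = "relation_score")
}

#' @export
print.relation_score <- function(x, ...) {
  cat(sprintf("relation score %d = 5*%d + 2*%d + %d + %d (chr/type/cyto/length)\n",
              x$total, x$chr_score, x$type_score, x$cyto_score, x$length_score))
  invisible(x)
}

#' Relation-score matrix between CNVs and sub-paragraphs
#'
#' @param cnvs a `cnv_calls` table.
#' @param subs list of sub-paragraphs (character vectors of sentences).
#' @param cytobands a `cytoband_table`.
#' @return integer matrix, CNVs in rows, sub-paragraphs in columns.
#' @export
relation_score_matrix <- function(cnvs, subs, cytobands) {
  m <- matrix(0L, nrow = nrow(cnvs), ncol = length(subs))
  for (i in seq_len(nrow(cnvs))) {
    for (j in seq_along(subs)) {
      m[i, j] <- relation_score(cnvs[i, ], subs[[j]], cytobands)$total
    }
  }
  m
}

#' Match CNVs to sub-paragraphs by maximum relation score
#'
#' Each CNV is independently assigned the sub-paragraph with the highest
#' relation score; when several sub-paragraphs tie, the first (lowest index)
#' is chosen. The assignment is not forced to be injective.
#'
#' @param cnvs a `cnv_calls` table (or a precomputed score matrix via
#'   `score_matrix`).
#' @param subs list of sub-paragraphs (character vectors of sentences).
#' @param cytobands a `cytoband_table`.
#' @param score_matrix optionally, a precomputed CNV-by-sub score matrix.
#' @return integer vector: for each CNV, the matched sub-paragraph index.
#' @export
match_cnvs <- function(cnvs, subs, cytobands, score_matrix = NULL) {
  if (is.null(score_matrix)) {
    if (length(subs) == 0) stop("no sub-paragraphs to match against")
    score_matrix <- relation_score_matrix(cnvs, subs, cytobands)
  }
  if (ncol(score_matrix) == 0) stop("no sub-paragraphs to match against")
  max.col(score_matrix, ties.method = "first")
}
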