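#' Tokenize clinical text
#'
#' Default tokenizer used throughout the corpus-mining pipeline: lower-cases,
#' splits on whitespace and punctuation (internal dots are kept so tokens such
#' as \code{"q11.23"} or \code{"1.26"} survive), and segments runs of CJK
#' characters into single-character tokens. The tokenizer argument of the
#' higher-level functions is pluggable, so a dictionary-based CJK segmenter
#' can be substituted for corpora where single-character segmentation is too
#' coarse.
#'
#' @param text character vector of sentences.
#' @return list of character vectors, one per input element.
#' @export
#' @examples
#' tokenize("A 1.26 Mb deletion at 7q11.23")
tokenize <- function(text) {
  text <- tolower(as.character(text))
  out <- vector("list", length(text))
  for (i in seq_along(text)) {
    # protect CJK runs by spacing each character
    x <- gsub("([\u4e00-\u9fff])", " \\1 ", text[i], perl = TRUE)
    toks <- strsplit(x, "[^a-z0-9.\u4e00-\u9fff]+", perl = TRUE)[[1]]
    toks <- gsub("^\\.+|\\.+$", "", toks)
    out[[i]] <- toks[nzchar(toks)]
  }
  out
}

# --- TF-IDF -----------------------------------------------------------------
# Hand-rolled because no text-mining package is a dependency. Semantics follow
# the common library defaults: raw term counts, idf = log((1+n)/(1+df)) + 1
# (smoothed), L2 row normalisation, sublinear tf off.

tfidf_fit <- function(token_lists) {
  vocab <- sort(unique(unlist(token_lists)))
  n <- length(token_lists)
  df <- integer(length(vocab))
  names(df) <- vocab
  for (toks in token_lists) {
    u <- unique(toks)
    df[u] <- df[u] + 1L
  }
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocab = vocab, idf = idf), class = "tfidf_encoder")
}

tfidf_transform <- function(encoder, token_lists) {
  vocab <- encoder$vocab
  m <- matrix(0, nrow = length(token_lists), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(token_lists)) {
    toks <- token_lists[[i]]
    toks <- toks[toks %in% vocab]
    if (length(toks)) {
      tab <- table(toks)
      m[i, names(tab)] <- as.numeric(tab) * encoder$idf[names(tab)]
    }
  }
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  m / nrm
}

# --- Multinomial naive Bayes ------------------------------------------------
# Standard text-classification NB with Laplace smoothing on (weighted) feature
# totals; operates directly on the TF-IDF matrix.

nb_fit <- function(x, y, alpha = 1) {
  y <- as.factor(y)
  classes <- levels(y)
  k <- length(classes)
  log_prior <- log(as.numeric(table(y)[classes]) / length(y))
  log_theta <- matrix(0, nrow = k, ncol = ncol(x),
                      dimnames = list(classes, colnames(x)))
  for (j in seq_len(k)) {
    s <- colSums(x[y == classes[j], , drop = FALSE]) + alpha
    log_theta[j, ] <- log(s / sum(s))
  }
  structure(list(classes = classes, log_prior = log_prior,
                 log_theta = log_theta), class = "multinomial_nb")
}

nb_predict <- function(model, x) {
  scores <- x %*% t(model$log_theta)
  scores <- sweep(scores, 2, model$log_prior, "+")
  model$classes[max.col(scores, ties.method = "first")]
}

#' Split a paragraph into sentences
#'
#' Splits free-text explanation paragraphs on sentence delimiters. ASCII
#' delimiters (comma, period, semicolon) split only when followed by
#' whitespace or end-of-string, so decimals ("1.26 Mb") and cytoband names
#' ("q11.23") are never broken; CJK full-width delimiters split anywhere.
#' Delimiters are consumed, sentences are trimmed, and empty fragments are
#' dropped, so joining the result with single delimiters reproduces the
#' paragraph's token content.
#'
#' @param paragraph single character string (may be empty).
#' @param delimiters character vector of single-character delimiters; the
#'   default covers ASCII and CJK comma/period/semicolon.
#' @return character vector of sentences, in original order (empty input
#'   yields \code{character(0)}).
#' @export
#' @examples
#' split_sentences("A, B. C")
split_sentences <- function(paragraph,
                            delimiters = c(",", ".", ";",
                                           "\uFF0C", "\u3002", "\uFF1B")) {
  stopifnot(length(paragraph) == 1, !is.na(paragraph))
  if (!nzchar(paragraph)) return(character(0))
  ascii <- delimiters[vapply(delimiters, function(d) utf8ToInt(d) < 128, TRUE)]
  cjk <- setdiff(delimiters, ascii)
  parts <- character(0)
  if (length(ascii)) {
    esc <- paste(vapply(ascii, function(d) paste0("\\", d), ""), collapse = "")
    parts <- c(parts, sprintf("[%s](?=\\s|$)", esc))
  }
  if (length(cjk)) parts <- c(parts, sprintf("[%s]", paste(cjk, collapse = "")))
  rx <- paste(parts, collapse = "|")
  out <- strsplit(paragraph, rx, perl = TRUE)[[1]]
  out <- trimws(out)
  out[nzchar(out)]
}
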