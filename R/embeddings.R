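# token-level hash so vectors depend only on (token, seed), not vocab order
token_hash <- function(token) {
  h <- 0
  for (c in utf8ToInt(token)) h <- (h * 31 + c) %% 2147483647
  h
}

#' Build a deterministic token embedding table
#'
#' Generates fixed random token vectors for a vocabulary: each token's
#' vector is drawn from N(0, 1/d) with an RNG stream seeded by a hash of the
#' token and the table seed, so the table is a pure function of (vocabulary,
#' dim, seed) and independent of vocabulary order. Random projections of
#' this kind preserve token identity, which is what the downstream averaged
#' sentence vectors need; a pretrained 200-dimensional table (e.g. GloVe
#' vectors in the same text format) can be supplied instead via
#' [read_embedding_table()].
#'
#' @param vocab character vector of tokens.
#' @param dim embedding dimension (default 200).
#' @param seed integer seed.
#' @return an `embedding_table`: numeric matrix, one row per token.
#' @export
build_embedding_table <- function(vocab, dim = 200L, seed = 1L) {
  vocab <- unique(vocab)
  m <- matrix(0, nrow = length(vocab), ncol = dim,
              dimnames = list(vocab, NULL))
  for (i in seq_along(vocab)) {
    s <- (as.numeric(seed) * 7919 + token_hash(vocab[i])) %% 2147483647
    set.seed(as.integer(s))
    m[i, ] <- stats::rnorm(dim, sd = 1 / sqrt(dim))
  }
  class(m) <- c("embedding_table", "matrix", "array")
  m
}

#' Read / write token embeddings in text format
#'
#' One token per line: `token<TAB>v1<TAB>...<TAB>vd`.
#'
#' @param file path or connection.
#' @return an `embedding_table` matrix with tokens as rownames.
#' @export
read_embedding_table <- function(file) {
  lines <- readLines(file, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  dims <- unique(lengths(parts))
  if (length(dims) != 1) stop("ragged embedding file: unequal vector lengths")
  toks <- vapply(parts, `[[`, "", 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dims - 1)))
  rownames(m) <- toks
  class(m) <- c("embedding_table", "matrix", "array")
  m
}

#' @rdname read_embedding_table
#' @param table an `embedding_table`.
#' @export
write_embedding_table <- function(table, file) {
  lines <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i], format(table[i, ], digits = 17)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, file, useBytes = FALSE)
  invisible(file)
}

#' Sentence vector as the mean of token vectors
#'
#' A sentence is embedded as the element-wise mean of its tokens' vectors.
#' Out-of-vocabulary tokens contribute the zero vector (the deterministic
#' OOV policy), so an all-OOV or empty sentence maps to the zero vector; the
#' empty case is flagged via the `"empty"` attribute.
#'
#' @param sentence a single sentence (character) or a token vector.
#' @param table an `embedding_table`.
#' @param tokenizer tokenizer function used when `sentence` is raw text.
#' @return numeric vector of length `ncol(table)`.
#' @export
embed_sentence <- function(sentence, table, tokenizer = tokenize) {
  toks <- if (length(sentence) == 1 && !inherits(sentence, "AsIs")) {
    tokenizer(sentence)[[1]]
  } else {
    as.character(sentence)
  }
  d <- ncol(table)
  if (!length(toks)) {
    return(structure(numeric(d), empty = TRUE))
  }
  m <- matrix(0, nrow = length(toks), ncol = d)
  known <- toks %in% rownames(table)
  if (any(known)) m[known, ] <- table[toks[known], , drop = FALSE]
  colMeans(m)
}

# matrix of sentence vectors
embed_sentences <- function(sentences, table, tokenizer = tokenize) {
  toks <- tokenizer(sentences)
  t(vapply(toks, function(tk) embed_sentence(I(tk), table),
           numeric(ncol(table))))
}
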