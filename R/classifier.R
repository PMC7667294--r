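#' Train the six-category sentence classifier
#'
#' Trains the corpus-classification model that assigns every sentence of a
#' sub-paragraph one of the six categories (Basic, Aneuploid, Syndrome,
#' Gene, Paper, Patient). Sentences are embedded as averaged token vectors;
#' a probability forest supplies per-sentence emission probabilities; the
#' `"sequence"` engine additionally estimates a CRF-style category
#' transition matrix from the training sub-paragraphs (add-one smoothing)
#' and decodes each sub-paragraph jointly by Viterbi, so neighbouring
#' sentences inform each other; a transition weight balancing the
#' transition scale against the emission scale is selected on the forest's
#' out-of-bag training predictions. The `"baseline"` engine is contract-
#' identical but decodes each sentence independently from the same
#' emissions; comparing the two isolates the value of sequence context.
#' Training is deterministic given `config$seed`.
#'
#' @param labeled data.frame with at least `sub_id` (grouping key giving the
#'   sub-paragraph and sentence order), `text`, `category`. Every sentence
#'   must be labeled.
#' @param config a [training_config()]; `num_units` is the emission-forest
#'   ensemble size, `embedding_dim` must match the table.
#' @param embeddings an `embedding_table`; by default one is built from the
#'   training vocabulary with [build_embedding_table()].
#' @param engine `"sequence"` (default) or `"baseline"`.
#' @param tokenizer tokenizer function.
#' @return a `corpus_classifier` with a [predict][predict.corpus_classifier]
#'   method.
#' @export
train_corpus_classifier <- function(labeled, config = training_config(),
                                    embeddings = NULL,
                                    engine = c("sequence", "baseline"),
                                    tokenizer = tokenize) {
  engine <- match.arg(engine)
  stopifnot(all(c("sub_id", "text", "category") %in% names(labeled)))
  if (anyNA(labeled$category)) {
    stop("unlabeled sentence in training data")
  }
  stopifnot(all(labeled$category %in% SENTENCE_CATEGORIES))
  if (is.null(embeddings)) {
    vocab <- sort(unique(unlist(tokenizer(labeled$text))))
    embeddings <- build_embedding_table(vocab, dim = config$embedding_dim,
                                        seed = config$seed)
  }
  stopifnot(ncol(embeddings) == config$embedding_dim)
  x <- embed_sentences(labeled$text, embeddings, tokenizer)
  y <- factor(labeled$category, levels = SENTENCE_CATEGORIES)
  present <- levels(droplevels(y))
  fit <- ranger::ranger(
    y = droplevels(y), x = as.data.frame(x),
    probability = TRUE, num.trees = config$num_units,
    seed = config$seed, num.threads = 1)
  k <- length(SENTENCE_CATEGORIES)
  trans <- matrix(1, k, k, dimnames = list(SENTENCE_CATEGORIES,
                                           SENTENCE_CATEGORIES))
  start <- rep(1, k); names(start) <- SENTENCE_CATEGORIES
  seqs <- split(as.character(y), labeled$sub_id)
  for (lab in seqs) {
    start[lab[1]] <- start[lab[1]] + 1
    if (length(lab) > 1) {
      for (t in seq_len(length(lab) - 1)) {
        trans[lab[t], lab[t + 1]] <- trans[lab[t], lab[t + 1]] + 1
      }
    }
  }
  log_trans <- log(trans / rowSums(trans))
  log_start <- log(start / sum(start))
  # The transition weight balances the generatively estimated transition
  # log-probabilities against the forest's emission scale (a jointly
  # trained CRF calibrates this implicitly). It is selected on the
  # forest's out-of-bag predictions for the training sub-paragraphs:
  # weight 0 reduces to per-sentence decoding, so the sequence decoder
  # can never be chosen when context carries no usable signal.
  trans_weight <- 0
  if (engine == "sequence") {
    oob <- fit$predictions
    full <- matrix(1e-12, nrow = nrow(oob), ncol = k,
                   dimnames = list(NULL, SENTENCE_CATEGORIES))
    full[, colnames(oob)] <- full[, colnames(oob)] + oob
    bad <- !is.finite(rowSums(full))
    full[bad, ] <- 1 / k
    log_oob <- log(full)
    idx <- split(seq_len(nrow(labeled)), labeled$sub_id)
    best_acc <- -1
    for (w in c(0, 0.125, 0.25, 0.5, 1)) {
      correct <- 0
      for (s in seq_along(idx)) {
        path <- viterbi_decode(log_oob[idx[[s]], , drop = FALSE],
                               w * log_start, w * log_trans)
        correct <- correct + sum(SENTENCE_CATEGORIES[path] == seqs[[s]])
      }
      if (correct > best_acc) {
        best_acc <- correct
        trans_weight <- w
      }
    }
  }
  structure(list(engine = engine, forest = fit, present = present,
                 log_trans = log_trans, log_start = log_start,
                 trans_weight = trans_weight,
                 embeddings = embeddings, config = config,
                 tokenizer = tokenizer),
            class = "corpus_classifier")
}

# first-tie Viterbi over log-domain scores
viterbi_decode <- function(log_emit, log_start, log_trans) {
  n <- nrow(log_emit); k <- ncol(log_emit)
  delta <- matrix(-Inf, n, k)
  back <- matrix(0L, n, k)
  delta[1, ] <- log_start + log_emit[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (j in seq_len(k)) {
        cand <- delta[t - 1, ] + log_trans[, j]
        b <- which.max(cand)
        back[t, j] <- b
        delta[t, j] <- cand[b] + log_emit[t, j]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

# emission log-probabilities for a block of sentences, over all six classes
emission_logprob <- function(model, texts) {
  x <- embed_sentences(texts, model$embeddings, model$tokenizer)
  p <- stats::predict(model$forest, data = as.data.frame(x),
                      num.threads = 1)$predictions
  full <- matrix(1e-12, nrow = nrow(p), ncol = length(SENTENCE_CATEGORIES),
                 dimnames = list(NULL, SENTENCE_CATEGORIES))
  full[, colnames(p)] <- full[, colnames(p)] + p
  log(full)
}

#' Classify sub-paragraph sentences into the six categories
#'
#' Applies a trained [train_corpus_classifier()] model. Sub-paragraphs
#' longer than `max_sequence_length` are chunked into consecutive windows,
#' each window is decoded, and the labels are concatenated, so every
#' sentence always receives exactly one label. Deterministic given the
#' model.
#'
#' @param subs list of character vectors (one per sub-paragraph), or a
#'   single character vector treated as one sub-paragraph.
#' @param model a `corpus_classifier`.
#' @return list of character vectors of categories, parallel to `subs`.
#' @export
classify_corpus <- function(subs, model) {
  stopifnot(inherits(model, "corpus_classifier"))
  if (is.character(subs)) subs <- list(subs)
  if (!length(subs)) return(list())
  maxlen <- model$config$max_sequence_length
  lapply(subs, function(sents) {
    if (!length(sents)) return(character(0))
    chunks <- split(sents, (seq_along(sents) - 1) %/% maxlen)
    out <- lapply(chunks, function(ch) {
      le <- emission_logprob(model, ch)
      if (model$engine == "sequence") {
        w <- model$trans_weight
        SENTENCE_CATEGORIES[viterbi_decode(le, w * model$log_start,
                                           w * model$log_trans)]
      } else {
        SENTENCE_CATEGORIES[max.col(le, ties.method = "first")]
      }
    })
    unname(unlist(out))
  })
}

#' @rdname classify_corpus
#' @param object a `corpus_classifier`.
#' @param subs list of sub-paragraphs, as in [classify_corpus()].
#' @param ... unused.
#' @export
predict.corpus_classifier <- function(object, subs, ...) {
  classify_corpus(subs, object)
}

#' @export
print.corpus_classifier <- function(x, ...) {
  cat(sprintf("corpus classifier (%s engine): %d-tree emission forest on %d-dim sentence embeddings, %d-class CRF-style transitions\n",
              x$engine, x$config$num_units, x$config$embedding_dim,
              length(SENTENCE_CATEGORIES)))
  invisible(x)
}
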