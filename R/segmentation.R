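#' Hyperparameter configuration for corpus models
#'
#' Carries the standard sequence-model hyperparameters used across the
#' corpus-mining pipeline. Defaults: batch_size 64, num_epochs 50,
#' dropout_rate 0.1, learning_rate 0.001, max_sequence_length 100 sentences,
#' num_units 200, optimizer "Adam", embedding_dim 200, seed 1. The bundled
#' trainers consume `max_sequence_length`, `embedding_dim`, `num_units`
#' (ensemble size of the emission forest) and `seed`; the remaining fields
#' parameterise gradient-trained sequence models plugged in behind the same
#' contract and are retained for configuration compatibility.
#'
#' @param batch_size,num_epochs,dropout_rate,learning_rate,max_sequence_length,num_units,optimizer,embedding_dim,seed
#'   see description; all overridable.
#' @return a `training_config` list.
#' @export
training_config <- function(batch_size = 64L, num_epochs = 50L,
                            dropout_rate = 0.1, learning_rate = 0.001,
                            max_sequence_length = 100L, num_units = 200L,
                            optimizer = "Adam", embedding_dim = 200L,
                            seed = 1L) {
  stopifnot(max_sequence_length >= 1, embedding_dim >= 1, num_units >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 num_epochs = as.integer(num_epochs),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 max_sequence_length = as.integer(max_sequence_length),
                 num_units = as.integer(num_units), optimizer = optimizer,
                 embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train the sentence-begin classifier
#'
#' Learns to recognise sentences that open the explanation of a new variant.
#' Training data are constructed from the reports themselves: the first
#' sentence of every report is a positive ("begin") example, and all
#' remaining sentences of single-CNV reports are negatives ("not_begin") —
#' in a one-CNV report only the first sentence can open an explanation.
#' The pipeline is tokenise, TF-IDF encode (encoder fit on the training
#' sentences only), multinomial naive Bayes.
#'
#' @param reports list of report objects (`list(report_id, sample_type,
#'   cnvs, paragraph)`, see [read_reports_jsonl()]).
#' @param config a [training_config()] (reserved; the NB stage has no
#'   stochastic hyperparameters).
#' @param tokenizer tokenizer function, defaults to [tokenize()].
#' @param delimiters sentence delimiters, see [split_sentences()].
#' @return a `begin_classifier` with a [predict][predict.begin_classifier]
#'   method.
#' @export
train_begin_classifier <- function(reports, config = training_config(),
                                   tokenizer = tokenize,
                                   delimiters = NULL) {
  stopifnot(length(reports) >= 2)
  split1 <- function(p) if (is.null(delimiters)) split_sentences(p)
                        else split_sentences(p, delimiters)
  pos <- character(0); neg <- character(0)
  n_single <- 0L
  for (r in reports) {
    sents <- split1(r$paragraph)
    if (!length(sents)) next
    pos <- c(pos, sents[1])
    if (nrow(r$cnvs) == 1) {
      n_single <- n_single + 1L
      if (length(sents) > 1) neg <- c(neg, sents[-1])
    }
  }
  if (n_single == 0 || !length(neg)) {
    stop("no single-CNV reports: cannot construct the negative class")
  }
  y <- c(rep("begin", length(pos)), rep("not_begin", length(neg)))
  toks <- tokenizer(c(pos, neg))
  enc <- tfidf_fit(toks)
  nb <- nb_fit(tfidf_transform(enc, toks), y)
  structure(list(encoder = enc, nb = nb, tokenizer = tokenizer,
                 n_positive = length(pos), n_negative = length(neg)),
            class = "begin_classifier")
}

#' Predict begin/not_begin for sentences
#'
#' @param object a `begin_classifier`.
#' @param sentences character vector of sentences.
#' @param ... unused.
#' @return character vector of `"begin"` / `"not_begin"`.
#' @export
predict.begin_classifier <- function(object, sentences, ...) {
  if (!length(sentences)) return(character(0))
  x <- tfidf_transform(object$encoder, object$tokenizer(sentences))
  nb_predict(object$nb, x)
}

#' @export
print.begin_classifier <- function(x, ...) {
  cat(sprintf("begin classifier (TF-IDF + multinomial NB): %d positive / %d negative training sentences, vocabulary %d\n",
              x$n_positive, x$n_negative, length(x$encoder$vocab)))
  invisible(x)
}

#' Segment a paragraph's sentences into sub-paragraphs
#'
#' Every sentence predicted "begin" opens a new sub-paragraph; the first
#' sentence is always forced to "begin" so the result is a partition: the
#' concatenation of the sub-paragraphs restores the original sentence
#' sequence with no loss or duplication.
#'
#' @param sentences character vector of sentences (from [split_sentences()]).
#' @param model a `begin_classifier`, or a logical/character vector of
#'   precomputed begin predictions (for testing the rule in isolation).
#' @return data.frame with columns `sub_index` (1-based), `sent_index`
#'   (0-based within the paragraph), `text`, `begin`.
#' @export
segment_paragraph <- function(sentences, model) {
  stopifnot(length(sentences) >= 1)
  if (inherits(model, "begin_classifier")) {
    pred <- predict(model, sentences) == "begin"
  } else if (is.character(model)) {
    pred <- model == "begin"
  } else {
    pred <- as.logical(model)
  }
  stopifnot(length(pred) == length(sentences))
  pred[1] <- TRUE
  data.frame(sub_index = cumsum(pred),
             sent_index = seq_along(sentences) - 1L,
             text = sentences, begin = pred, stringsAsFactors = FALSE)
}

#' Split a segmentation into a list of sub-paragraphs
#'
#' @param segmentation output of [segment_paragraph()].
#' @return list of character vectors, one per sub-paragraph.
#' @export
subparagraph_texts <- function(segmentation) {
  unname(split(segmentation$text, segmentation$sub_index))
}
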