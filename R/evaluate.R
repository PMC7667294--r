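#' Round half away from zero
#'
#' Display rounding used for percentage metrics (half-up at one decimal),
#' matching clinical-report formatting rather than IEEE round-half-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # pre-round at high precision so binary representation error (86.05
  # stored as 86.0499...) cannot push a half-case down
  sign(x) * floor(round(abs(x) * p, 6) + 0.5) / p
}

#' Diagnostic performance metrics from a confusion matrix
#'
#' Computes the eight binary classification statistics for pCNV detection
#' (positive class = pathogenic or likely pathogenic CNV): accuracy, PPV,
#' NPV, sensitivity, specificity, FPR, FNR and Cohen's kappa, as
#' percentages. Ratios with a zero denominator are reported as `NA`
#' (undefined), never silently as 0. Kappa uses the chance agreement
#' expected from the marginals: with po the observed agreement and
#' pe = (P_pred * P_gold + N_pred * N_gold) / total^2,
#' kappa = (po - pe) / (1 - pe); the degenerate all-agree case with one
#' class (pe = 1) is returned as 100%.
#'
#' @param tp,fp,fn,tn non-negative confusion counts.
#' @return a `binary_metrics` list with `counts`, `raw` (proportions) and
#'   `percent` (half-up, one decimal).
#' @export
#' @examples
#' confusion_metrics(tp = 846, fp = 197, fn = 20, tn = 3988)
confusion_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  total <- sum(counts)
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  po <- (tp + tn) / total
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / total^2
  kappa <- if (pe == 1) {
    if (po == 1) 1 else NA_real_
  } else {
    (po - pe) / (1 - pe)
  }
  raw <- c(accuracy = po,
           ppv = ratio(tp, tp + fp),
           npv = ratio(tn, tn + fn),
           sensitivity = ratio(tp, tp + fn),
           specificity = ratio(tn, tn + fp),
           fpr = ratio(fp, fp + tn),
           fnr = ratio(fn, fn + tp),
           kappa = kappa)
  structure(list(counts = counts, total = total, raw = raw,
                 percent = round_half_up(raw * 100, 1)),
            class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  cat(sprintf("n = %d (TP %d, FP %d, FN %d, TN %d)\n", x$total,
              x$counts["tp"], x$counts["fp"], x$counts["fn"],
              x$counts["tn"]))
  for (m in names(x$percent)) {
    cat(sprintf("  %-12s %s\n", toupper(m),
                ifelse(is.na(x$percent[m]), "undefined",
                       paste0(x$percent[m], "%"))))
  }
  invisible(x)
}

#' Per-class precision / recall / F1 with macro averages
#'
#' One-vs-rest precision, recall and F1 for each class plus the macro
#' (unweighted) average over classes. Classes absent from both the
#' predictions and the gold labels are excluded from the macro average with
#' a warning. A class with no predicted positives has undefined precision;
#' it is treated as 0 in F1 (the usual convention) but reported as `NA` in
#' the table.
#'
#' @param pred,gold equal-length label vectors.
#' @param classes class set; defaults to the six sentence categories when
#'   the labels are drawn from them, else the union of observed labels.
#' @return data.frame with one row per class and a `"macro"` row.
#' @export
per_class_prf <- function(pred, gold, classes = NULL) {
  stopifnot(length(pred) == length(gold))
  pred <- as.character(pred); gold <- as.character(gold)
  if (is.null(classes)) {
    obs <- union(pred, gold)
    classes <- if (all(obs %in% SENTENCE_CATEGORIES)) {
      SENTENCE_CATEGORIES
    } else {
      sort(obs)
    }
  }
  rows <- lapply(classes, function(cl) {
    tp <- sum(pred == cl & gold == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(pred != cl & gold == cl)
    present <- (tp + fp + fn) > 0 || cl %in% c(pred, gold)
    precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    p0 <- if (is.na(precision)) 0 else precision
    r0 <- if (is.na(recall)) 0 else recall
    f1 <- if (p0 + r0 == 0) 0 else 2 * p0 * r0 / (p0 + r0)
    data.frame(class = cl, support = tp + fn, precision = precision,
               recall = recall, f1 = f1, present = present,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  absent <- !tab$present
  if (any(absent)) {
    warning(sprintf("class(es) absent from both pred and gold excluded from macro average: %s",
                    paste(tab$class[absent], collapse = ", ")))
  }
  used <- tab[!absent, , drop = FALSE]
  macro <- data.frame(class = "macro", support = sum(tab$support),
                      precision = mean(used$precision, na.rm = TRUE),
                      recall = mean(used$recall, na.rm = TRUE),
                      f1 = mean(used$f1), present = TRUE,
                      stringsAsFactors = FALSE)
  out <- rbind(tab, macro)
  out$present <- NULL
  rownames(out) <- NULL
  out
}

#' Macro F1 convenience accessor
#'
#' @param pred,gold label vectors, see [per_class_prf()].
#' @param classes optional class set.
#' @return the macro-averaged F1 score.
#' @export
macro_f1 <- function(pred, gold, classes = NULL) {
  tab <- per_class_prf(pred, gold, classes)
  tab$f1[tab$class == "macro"]
}
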