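# rank (Mann-Whitney) AUC with midrank tie correction
auc_rank <- function(probs, is_pos) {
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: one class absent")
  }
  r <- rank(probs)                      # midranks handle ties
  (sum(r[is_pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate binary class probabilities
#'
#' AUC by the rank (Mann-Whitney) formulation with midrank tie correction;
#' sensitivity at the smallest threshold whose specificity reaches
#' `spec_target` (a sample is called positive when its probability is at or
#' above the threshold); F1 score and confusion matrix at `threshold`.
#'
#' @param probs positive-class probabilities.
#' @param labels class labels aligned with `probs`.
#' @param positive name of the positive class.
#' @param threshold cutoff for the confusion matrix and F1.
#' @param spec_target specificity at which sensitivity is read.
#' @return object of class `cfepi_eval`: `auc`, `sens_at_spec`,
#'   `spec_target`, `f1`, `threshold`, `confusion` (2x2 table, rows =
#'   truth), `n`, `roc` (data frame of threshold/sens/spec).
#' @export
evaluate <- function(probs, labels, positive, threshold = 0.5,
                     spec_target = 0.90) {
  labels <- as.character(labels)
  if (!positive %in% labels || all(labels == positive)) {
    stop("AUC undefined: one class absent")
  }
  if (length(probs) != length(labels)) stop("probs/labels length mismatch")
  is_pos <- labels == positive
  npos <- sum(is_pos); nneg <- sum(!is_pos)
  auc <- auc_rank(probs, is_pos)
  # ROC over candidate thresholds (every observed probability, plus one
  # above the maximum where nothing is called positive)
  ts <- c(sort(unique(probs)), max(probs) + 1)
  sens <- vapply(ts, function(t) sum(probs[is_pos] >= t) / npos, numeric(1))
  spec <- vapply(ts, function(t) sum(probs[!is_pos] < t) / nneg, numeric(1))
  roc <- data.frame(threshold = ts, sens = sens, spec = spec)
  ok <- which(spec >= spec_target)
  sens_at_spec <- if (length(ok)) sens[ok[1]] else 0
  pred_pos <- probs >= threshold
  tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos); tn <- sum(!pred_pos & !is_pos)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  neg_name <- paste0("not_", positive)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2,
                      dimnames = list(truth = c(positive, neg_name),
                                      predicted = c(positive, neg_name)))
  structure(list(auc = auc, sens_at_spec = sens_at_spec,
                 spec_target = spec_target, f1 = f1, threshold = threshold,
                 confusion = as.table(confusion), n = length(probs),
                 roc = roc),
            class = "cfepi_eval")
}

#' @export
print.cfepi_eval <- function(x, ...) {
  cat(sprintf("AUC %.4f | sensitivity at %.0f%% specificity %.4f | F1 %.4f (threshold %.2f), n = %d\n",
              x$auc, 100 * x$spec_target, x$sens_at_spec, x$f1,
              x$threshold, x$n))
  invisible(x)
}

argmax_class <- function(prob) {
  cls <- sort(colnames(prob))           # ties -> lexicographically first
  prob <- prob[, cls, drop = FALSE]
  cls[apply(prob, 1, which.max)]
}

#' Evaluate multiclass probability vectors
#'
#' The predicted class is the argmax of the per-class probabilities (ties
#' broken by the lexicographically first class name). Reports overall
#' accuracy and the full confusion matrix; accuracy replaces AUC as the
#' headline metric in three-class mode.
#'
#' @param prob matrix of per-class probabilities (columns named by class,
#'   rows summing to 1).
#' @param labels true labels; every label must be a column of `prob`.
#' @return object of class `cfepi_eval_multiclass`: `accuracy`, `confusion`
#'   (rows = truth, columns = predicted), `n`.
#' @export
evaluate_multiclass <- function(prob, labels) {
  prob <- as.matrix(prob)
  labels <- as.character(labels)
  if (any(!labels %in% colnames(prob))) {
    stop("label outside declared class set: ",
         paste(setdiff(labels, colnames(prob)), collapse = ", "))
  }
  if (any(abs(rowSums(prob) - 1) > 1e-6)) {
    stop("per-class probabilities must sum to 1")
  }
  pred <- argmax_class(prob)
  cls <- sort(colnames(prob))
  confusion <- table(truth = factor(labels, levels = cls),
                     predicted = factor(pred, levels = cls))
  structure(list(accuracy = mean(pred == labels), confusion = confusion,
                 n = length(labels)),
            class = "cfepi_eval_multiclass")
}

#' @export
print.cfepi_eval_multiclass <- function(x, ...) {
  cat(sprintf("accuracy %.4f, n = %d\n", x$accuracy, x$n))
  print(x$confusion)
  invisible(x)
}

#' Pairwise rank correlation of per-modality probabilities
#'
#' Symmetric matrix of Spearman correlations between the predicted
#' probabilities of the single-modality models (diagonal 1). A pair
#' involving a constant probability vector is reported as `NA`.
#'
#' @param probs matrix or data frame, samples x modalities.
#' @export
probability_correlations <- function(probs) {
  probs <- as.matrix(probs)
  m <- ncol(probs)
  out <- matrix(NA_real_, m, m,
                dimnames = list(colnames(probs), colnames(probs)))
  diag(out) <- 1
  if (m < 2) return(out)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (stats::sd(probs[, i]) == 0 || stats::sd(probs[, j]) == 0) next
      out[i, j] <- out[j, i] <-
        stats::cor(probs[, i], probs[, j], method = "spearman")
    }
  }
  out
}
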