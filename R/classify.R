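#' Model configuration
#'
#' Tunables of the selection + stacking protocol. Defaults follow the
#' training protocol: top 100 features per modality, tenfold inner CV,
#' 500-tree random forests, ridge-logistic meta-classifier, probability
#' threshold 0.5 and operating point at 90% specificity.
#'
#' @param top_k features kept per modality after ranking.
#' @param inner_k inner cross-validation folds for stacking.
#' @param num_trees trees per random forest.
#' @param boruta_max_iter,boruta_alpha shadow-selection iteration cap and
#'   per-test significance level (Bonferroni-corrected across features).
#' @param var_threshold training-variance cutoff (inclusive) below which a
#'   feature is dropped; the default removes only (near-)constant features.
#' @param meta meta-classifier family: `"logistic"` (L2-regularized, the
#'   low-variance default for a 4-column input) or `"rf"`.
#' @param meta_lambda ridge penalty for the logistic meta-classifier.
#' @param threshold probability cutoff for the confusion matrix / F1.
#' @param spec_target specificity at which sensitivity is reported.
#' @param positive name of the positive class (default: `"cancer"` when
#'   present, otherwise the last factor level).
#' @param skip_boruta_when_small when the post-filter feature count is at
#'   most `top_k`, skip the shadow iterations: every feature is selected
#'   either way (ranking cannot change the selected set), so the fitted
#'   models are identical and the run is much faster.
#' @export
model_config <- function(top_k = 100L, inner_k = 10L, num_trees = 500L,
                         boruta_max_iter = 100L, boruta_alpha = 0.05,
                         var_threshold = 1e-8,
                         meta = c("logistic", "rf"), meta_lambda = 0.01,
                         threshold = 0.5, spec_target = 0.90,
                         positive = NULL, skip_boruta_when_small = TRUE) {
  list(top_k = as.integer(top_k), inner_k = as.integer(inner_k),
       num_trees = as.integer(num_trees),
       boruta_max_iter = as.integer(boruta_max_iter),
       boruta_alpha = boruta_alpha, var_threshold = var_threshold,
       meta = match.arg(meta), meta_lambda = meta_lambda,
       threshold = threshold, spec_target = spec_target,
       positive = positive,
       skip_boruta_when_small = isTRUE(skip_boruta_when_small))
}

# deterministic 31-bit seed derived from a base seed and context indices
derive_seed <- function(seed, ...) {
  ids <- c(...)
  h <- as.numeric(seed) %% 2147483587
  for (v in ids) h <- (h * 48271 + as.numeric(v) + 1) %% 2147483587
  as.integer(h + 1)
}

default_positive <- function(levels, positive = NULL) {
  if (!is.null(positive)) {
    if (!positive %in% levels) stop("positive class not among labels")
    return(positive)
  }
  if ("cancer" %in% levels) "cancer" else levels[length(levels)]
}

# training-side feature processing + base model for one modality.
# Selection (NA filter, variance filter, shadow selection) sees only the
# training rows; medians for predict-time imputation are training medians.
fit_base_model <- function(fm, train_ids, cfg, seed) {
  fm <- drop_na_features(fm, train_ids)
  fm <- drop_low_variance(fm, train_ids, cfg$var_threshold)
  y <- fm$labels[match(train_ids, rownames(fm$values))]
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("training split lost a class")
  p <- ncol(fm$values)
  selection <- NULL
  if (p == 0L) {
    pri <- as.numeric(table(y) / length(y))
    return(list(type = "prior", prior = stats::setNames(pri, levels(y)),
                features = character(), levels = levels(y)))
  }
  feats <- colnames(fm$values)
  if (p > cfg$top_k || !cfg$skip_boruta_when_small) {
    selection <- boruta_select(fm$values[train_ids, , drop = FALSE], y,
                               k = cfg$top_k,
                               max_iter = cfg$boruta_max_iter,
                               alpha = cfg$boruta_alpha,
                               num_trees = cfg$num_trees,
                               seed = derive_seed(seed, 7L))
    feats <- selection$selected
  }
  xtr <- fm$values[train_ids, feats, drop = FALSE]
  med <- apply(xtr, 2, stats::median, na.rm = TRUE)
  fit <- ranger::ranger(x = xtr, y = y,
                        num.trees = cfg$num_trees, probability = TRUE,
                        num.threads = 1L, seed = derive_seed(seed, 11L))
  list(type = "ranger", model = fit, features = feats, medians = med,
       levels = levels(y), selection = selection)
}

# class-probability matrix (rows = newdata rows, cols = model levels)
predict_base_model <- function(base, newx) {
  if (base$type == "prior") {
    return(matrix(rep(base$prior, each = nrow(newx)), nrow(newx),
                  dimnames = list(rownames(newx), base$levels)))
  }
  x <- newx[, base$features, drop = FALSE]
  for (j in seq_along(base$features)) {
    na <- is.na(x[, j])
    if (any(na)) x[na, j] <- base$medians[j]
  }
  pr <- stats::predict(base$model, data = x, num.threads = 1L)$predictions
  pr[, base$levels, drop = FALSE]
}

# stratified fold assignment; refolds (new sub-seed) until every fold's
# training complement contains all classes, erroring after max_attempts
make_stratified_folds <- function(y, k, seed, max_attempts = 10L) {
  n <- length(y)
  if (k > n) stop("more folds than samples")
  for (attempt in seq_len(max_attempts)) {
    set.seed(derive_seed(seed, attempt))
    fold <- integer(n)
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(j) {
      nlevels(droplevels(y[fold != j])) == nlevels(droplevels(y))
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build stratified folds with all classes in every ",
       "training split after ", max_attempts, " attempts")
}

check_modalities <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("x must be a named list of feature matrices (one per modality)")
  }
  ids <- rownames(x[[1]]$values)
  for (fm in x) {
    if (!identical(rownames(fm$values), ids)) {
      stop("all modalities must cover the same samples in the same order")
    }
    if (!identical(as.character(fm$labels), as.character(x[[1]]$labels))) {
      stop("labels disagree across modalities")
    }
  }
  ids
}

#' Out-of-fold base predictions by inner cross-validation
#'
#' Stratified k-fold CV inside a training set: per modality and fold, the
#' full selection pipeline is re-run on the in-fold training part, a forest
#' is fit, and the held-in-fold-out samples are predicted, so every training
#' sample receives exactly one out-of-fold probability per modality.
#'
#' @param x named list of `feature_matrix` objects (the training samples).
#' @param k folds (default 10).
#' @param cfg [model_config()].
#' @param seed RNG seed; runs are deterministic given (x, k, cfg, seed).
#' @return for two-class labels, an n x M matrix of positive-class
#'   probabilities (columns = modalities); for more classes, an
#'   n x (M*C) matrix with columns `<modality>.<class>`.
#' @export
inner_cv_base_predictions <- function(x, k = 10L, cfg = model_config(),
                                      seed = 1L) {
  ids <- check_modalities(x)
  y <- droplevels(x[[1]]$labels)
  positive <- default_positive(levels(y), cfg$positive)
  binary <- nlevels(y) == 2L
  fold <- make_stratified_folds(y, k, derive_seed(seed, 1L))
  mods <- names(x)
  cols <- if (binary) mods else {
    as.vector(t(outer(mods, levels(y), paste, sep = ".")))
  }
  oof <- matrix(NA_real_, length(ids), length(cols),
                dimnames = list(ids, cols))
  for (j in seq_len(k)) {
    tr <- ids[fold != j]
    te <- ids[fold == j]
    if (!length(te)) next
    for (m in seq_along(mods)) {
      base <- fit_base_model(x[[mods[m]]], tr, cfg,
                             derive_seed(seed, j, m))
      pr <- predict_base_model(base, x[[mods[m]]]$values[te, , drop = FALSE])
      if (binary) {
        oof[te, mods[m]] <- pr[, positive]
      } else {
        oof[te, paste(mods[m], colnames(pr), sep = ".")] <- pr
      }
    }
  }
  oof
}

fit_meta <- function(oof, y, cfg) {
  binary <- nlevels(y) == 2L
  if (cfg$meta == "rf") {
    fit <- ranger::ranger(x = oof, y = y, num.trees = cfg$num_trees,
                          probability = TRUE, num.threads = 1L, seed = 1L)
    return(list(family = "rf", model = fit, levels = levels(y)))
  }
  if (ncol(oof) >= 2L) {
    fam <- if (binary) "binomial" else "multinomial"
    # glmnet warns about small class counts at LOOCV scale; expected here
    fit <- suppressWarnings(glmnet::glmnet(oof, y, family = fam, alpha = 0,
                                           lambda = cfg$meta_lambda))
    list(family = fam, model = fit, levels = levels(y))
  } else {
    # single base column: plain logistic
    df <- data.frame(p = oof[, 1], y = y)
    fit <- stats::glm(y ~ p, data = df, family = stats::binomial())
    list(family = "glm", model = fit, levels = levels(y))
  }
}

predict_meta <- function(meta, newoof) {
  if (meta$family == "rf") {
    pr <- stats::predict(meta$model, data = newoof,
                         num.threads = 1L)$predictions
    return(pr[, meta$levels, drop = FALSE])
  }
  if (meta$family == "glm") {
    p2 <- stats::predict(meta$model, data.frame(p = newoof[, 1]),
                         type = "response")
    return(cbind(1 - p2, p2, deparse.level = 0) |>
             `colnames<-`(meta$levels))
  }
  pr <- stats::predict(meta$model, newx = newoof, type = "response")
  if (meta$family == "binomial") {
    p2 <- as.numeric(pr)
    out <- cbind(1 - p2, p2)
    colnames(out) <- meta$levels
    out
  } else {
    out <- pr[, , 1]
    if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                         dimnames = list(NULL, dimnames(pr)[[2]]))
    out[, meta$levels, drop = FALSE]
  }
}

#' Fit the stacked multimodal classifier
#'
#' The central fitting function. For each modality the full training-side
#' pipeline is run (NA filter, low-variance filter, shadow-feature
#' selection, random forest), inner stratified k-fold CV produces
#' out-of-fold base probabilities for every training sample, and a
#' meta-classifier is fit on the stacked base probabilities. Prediction for
#' a new sample feeds the per-modality base probabilities (from the models
#' refit on the full training set) through the meta-classifier.
#'
#' @param x named list of `feature_matrix` objects, one per modality, over
#'   the same samples.
#' @param cfg [model_config()].
#' @param seed RNG seed (fits are deterministic given data, cfg and seed).
#' @return object of class `cfepi_fit` with elements `bases` (per-modality
#'   base models), `meta`, `oof` (inner-CV base probabilities), `levels`,
#'   `positive`, `modalities`, `cfg`, `seed`.
#' @seealso [predict.cfepi_fit()], [loocv_multimodal()], [cross_cohort()]
#' @export
stacked_fit <- function(x, cfg = model_config(), seed = 1L) {
  ids <- check_modalities(x)
  y <- droplevels(x[[1]]$labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  positive <- default_positive(levels(y), cfg$positive)
  oof <- inner_cv_base_predictions(x, k = min(cfg$inner_k, length(ids)),
                                   cfg = cfg, seed = derive_seed(seed, 2L))
  meta <- fit_meta(oof, y, cfg)
  bases <- lapply(seq_along(x), function(m) {
    fit_base_model(x[[m]], ids, cfg, derive_seed(seed, 3L, m))
  })
  names(bases) <- names(x)
  structure(list(bases = bases, meta = meta, oof = oof,
                 levels = levels(y), positive = positive,
                 modalities = names(x), n = length(ids),
                 cfg = cfg, seed = seed),
            class = "cfepi_fit")
}

base_prob_row <- function(object, newx) {
  binary <- length(object$levels) == 2L
  mods <- object$modalities
  if (binary) {
    out <- matrix(NA_real_, nrow(newx[[1]]), length(mods),
                  dimnames = list(rownames(newx[[1]]), mods))
  } else {
    cols <- as.vector(t(outer(mods, object$levels, paste, sep = ".")))
    out <- matrix(NA_real_, nrow(newx[[1]]), length(cols),
                  dimnames = list(rownames(newx[[1]]), cols))
  }
  for (m in mods) {
    pr <- predict_base_model(object$bases[[m]], newx[[m]])
    if (binary) out[, m] <- pr[, object$positive]
    else out[, paste(m, colnames(pr), sep = ".")] <- pr
  }
  out
}

#' Predict from a stacked fit
#'
#' @param object a `cfepi_fit`.
#' @param newdata named list (by modality) of numeric matrices or
#'   `feature_matrix` objects holding the new samples' features.
#' @param type `"prob"` for final class probabilities, `"base"` for the
#'   per-modality base probabilities, `"class"` for hard labels (argmax,
#'   ties to the lexicographically first class).
#' @param ... unused.
#' @export
predict.cfepi_fit <- function(object, newdata,
                              type = c("prob", "base", "class"), ...) {
  type <- match.arg(type)
  missing_mod <- setdiff(object$modalities, names(newdata))
  if (length(missing_mod)) {
    stop("newdata missing modality column(s): ",
         paste(missing_mod, collapse = ", "))
  }
  newx <- lapply(newdata[object$modalities], function(z) {
    if (inherits(z, "feature_matrix")) z$values else as.matrix(z)
  })
  base <- base_prob_row(object, newx)
  if (type == "base") return(base)
  prob <- predict_meta(object$meta, base)
  if (type == "prob") return(prob)
  argmax_class(prob)
}

#' @export
print.cfepi_fit <- function(x, ...) {
  cat(sprintf("cfepi_fit: stacked %s model, %d training samples\n",
              paste(x$modalities, collapse = "+"), x$n))
  cat(sprintf("classes: %s (positive: %s); meta: %s\n",
              paste(x$levels, collapse = "/"), x$positive, x$meta$family))
  for (m in x$modalities) {
    cat(sprintf("  %-12s %d features\n", m, length(x$bases[[m]]$features)))
  }
  invisible(x)
}

#' @export
summary.cfepi_fit <- function(object, ...) {
  oof_eval <- if (length(object$levels) == 2L) {
    y <- factor(ifelse(rowSums(is.na(object$oof)) > 0, NA, 1))
    NULL
  } else NULL
  print(object)
  cat("\ninner-CV out-of-fold base probabilities (head):\n")
  print(utils::head(round(object$oof, 3)))
  if (length(object$levels) == 2L) {
    cm <- coef(object)
    if (!is.null(cm)) {
      cat("\nmeta-classifier coefficients:\n")
      print(round(cm, 4))
    }
  }
  invisible(object)
}

#' @export
coef.cfepi_fit <- function(object, ...) {
  if (object$meta$family == "binomial") {
    as.matrix(stats::coef(object$meta$model))
  } else if (object$meta$family == "glm") {
    as.matrix(stats::coef(object$meta$model))
  } else NULL
}

#' Leave-one-out cross-validation of one modality
#'
#' For each of the n iterations the held-out sample is removed, the
#' training-side pipeline (NA filter, low-variance filter, shadow-feature
#' selection) is re-run on the n-1 remaining samples, a random forest is
#' fit, and the held-out sample's class probability is recorded. The n
#' held-out probabilities are aggregated into a single evaluation (one ROC
#' curve), not averaged over folds.
#'
#' @param fm `feature_matrix` of one modality.
#' @param cfg [model_config()].
#' @param seed RNG seed.
#' @return object of class `cfepi_cv`: `probs` (per-sample data frame),
#'   `eval` (see [evaluate()] / [evaluate_multiclass()]), `seed`.
#' @export
loocv_single_modality <- function(fm, cfg = model_config(), seed = 1L) {
  ids <- rownames(fm$values)
  n <- length(ids)
  y <- droplevels(fm$labels)
  if (nlevels(y) < 2L) stop("need >= 2 classes")
  binary <- nlevels(y) == 2L
  positive <- default_positive(levels(y), cfg$positive)
  probs <- matrix(NA_real_, n, nlevels(y), dimnames = list(ids, levels(y)))
  for (i in seq_len(n)) {
    tr <- ids[-i]
    if (nlevels(droplevels(y[-i])) < 2L) {
      stop("training split lost a class at iteration ", i)
    }
    base <- fit_base_model(fm, tr, cfg, derive_seed(seed, i))
    pr <- predict_base_model(base, fm$values[ids[i], , drop = FALSE])
    probs[i, colnames(pr)] <- pr
  }
  ev <- if (binary) {
    evaluate(probs[, positive], y, positive = positive,
             threshold = cfg$threshold, spec_target = cfg$spec_target)
  } else {
    evaluate_multiclass(probs, y)
  }
  out <- data.frame(sample_id = ids, label = as.character(y),
                    stringsAsFactors = FALSE)
  if (binary) out$prob <- probs[, positive] else out <- cbind(out, probs)
  structure(list(probs = out, eval = ev, positive = positive,
                 modalities = "single", seed = seed),
            class = "cfepi_cv")
}

#' Leave-one-out cross-validation of the stacked multimodal model
#'
#' Outer LOOCV with leakage-free stacking: in each iteration the full
#' [stacked_fit()] pipeline (per-modality selection, inner tenfold CV for
#' out-of-fold base probabilities, meta-classifier) runs on the n-1 training
#' samples only, then emits the held-out sample's base and final
#' probabilities. Per-modality holdout probabilities are also aggregated so
#' the single-modality performance of the identical base pipeline is
#' reported alongside the stacked model.
#'
#' @param x named list of `feature_matrix` objects, one per modality.
#' @param cfg [model_config()].
#' @param seed RNG seed; inner folds use a seed derived from (seed,
#'   iteration) so the run is fully reproducible.
#' @return object of class `cfepi_cv`: `probs` has one row per sample with
#'   per-modality base probabilities and the final stacked probability;
#'   `eval` is the stacked-model evaluation; `modality_auc` the per-modality
#'   AUCs of the holdout base probabilities (two-class mode);
#'   `prob_correlations` the pairwise Spearman matrix of per-modality
#'   probabilities.
#' @export
loocv_multimodal <- function(x, cfg = model_config(), seed = 1L) {
  ids <- check_modalities(x)
  n <- length(ids)
  y <- droplevels(x[[1]]$labels)
  binary <- nlevels(y) == 2L
  positive <- default_positive(levels(y), cfg$positive)
  mods <- names(x)
  base_cols <- if (binary) mods else {
    as.vector(t(outer(mods, levels(y), paste, sep = ".")))
  }
  base_probs <- matrix(NA_real_, n, length(base_cols),
                       dimnames = list(ids, base_cols))
  final <- matrix(NA_real_, n, nlevels(y), dimnames = list(ids, levels(y)))
  for (i in seq_len(n)) {
    tr_x <- lapply(x, subset_samples, sample_ids = ids[-i])
    fit <- stacked_fit(tr_x, cfg, seed = derive_seed(seed, i))
    new_x <- lapply(x, function(fm) fm$values[ids[i], , drop = FALSE])
    b <- base_prob_row(fit, new_x)
    base_probs[i, ] <- b
    final[i, ] <- predict_meta(fit$meta, b)[1, ]
  }
  ev <- if (binary) {
    evaluate(final[, positive], y, positive = positive,
             threshold = cfg$threshold, spec_target = cfg$spec_target)
  } else {
    evaluate_multiclass(final, y)
  }
  modality_auc <- if (binary) {
    vapply(mods, function(m) auc_rank(base_probs[, m], y == positive),
           numeric(1))
  } else NULL
  corr_in <- if (binary) base_probs else {
    sapply(mods, function(m) base_probs[, paste(m, positive, sep = ".")])
  }
  out <- data.frame(sample_id = ids, label = as.character(y),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(base_probs))
  if (binary) out$final <- final[, positive] else out <- cbind(out, final)
  structure(list(probs = out, eval = ev, positive = positive,
                 modalities = mods, modality_auc = modality_auc,
                 prob_correlations = probability_correlations(corr_in),
                 seed = seed),
            class = "cfepi_cv")
}

#' Cross-cohort validation
#'
#' Fits the full selection + stacking pipeline once on the training cohort
#' and applies it unchanged to the test cohort; only features present in
#' both cohorts (per modality) are used, and the evaluation covers the test
#' cohort only.
#'
#' @param train_x,test_x named lists of `feature_matrix` objects.
#' @param cfg [model_config()].
#' @param seed RNG seed.
#' @return `cfepi_cv` over the test cohort, with the fitted model attached
#'   as `fit`.
#' @export
cross_cohort <- function(train_x, test_x, cfg = model_config(), seed = 1L) {
  mods <- names(train_x)
  if (!setequal(mods, names(test_x))) stop("modalities differ between cohorts")
  for (m in mods) {
    shared <- intersect(colnames(train_x[[m]]$values),
                        colnames(test_x[[m]]$values))
    if (!length(shared)) stop("empty feature intersection for modality ", m)
    train_x[[m]] <- subset_features(train_x[[m]], shared)
    test_x[[m]] <- subset_features(test_x[[m]], shared)
  }
  fit <- stacked_fit(train_x, cfg, seed)
  yte <- droplevels(test_x[[1]]$labels)
  binary <- length(fit$levels) == 2L
  new_x <- lapply(test_x, function(fm) fm$values)
  b <- base_prob_row(fit, new_x)
  final <- predict_meta(fit$meta, b)
  ev <- if (binary) {
    evaluate(final[, fit$positive], yte, positive = fit$positive,
             threshold = cfg$threshold, spec_target = cfg$spec_target)
  } else {
    evaluate_multiclass(final, yte)
  }
  out <- data.frame(sample_id = rownames(test_x[[1]]$values),
                    label = as.character(yte), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(b))
  if (binary) out$final <- final[, fit$positive] else out <- cbind(out, final)
  structure(list(probs = out, eval = ev, positive = fit$positive,
                 modalities = mods, fit = fit, seed = seed),
            class = "cfepi_cv")
}

#' @export
print.cfepi_cv <- function(x, ...) {
  cat(sprintf("cfepi_cv: %d samples, modalities: %s\n",
              nrow(x$probs), paste(x$modalities, collapse = ", ")))
  print(x$eval)
  invisible(x)
}

#' @export
summary.cfepi_cv <- function(object, ...) {
  print(object)
  if (!is.null(object$modality_auc)) {
    cat("per-modality holdout AUC:\n")
    print(round(object$modality_auc, 4))
  }
  if (!is.null(object$prob_correlations)) {
    cat("probability Spearman correlations:\n")
    print(round(object$prob_correlations, 3))
  }
  invisible(object)
}

#' ROC curve of a cross-validated model
#'
#' @param x a `cfepi_cv` from a two-class run.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cfepi_cv <- function(x, ...) {
  if (is.null(x$eval$roc)) stop("no ROC curve for multiclass results")
  r <- x$eval$roc
  graphics::plot(1 - r$spec, r$sens, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.4f", x$eval$auc))
  invisible(x)
}
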