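#' Construct a feature matrix
#'
#' A rectangular samples-by-features table for one or more modalities, with
#' per-feature modality tags and per-sample class labels. Missing values are
#' allowed and handled by the training-side NA filter.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids, unique).
#' @param modality single modality name or per-feature character vector,
#'   each in `c("methylation", "occupancy", "fuzziness", "wps")`.
#' @param labels class labels aligned with the rows (factor or character).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, modality, labels) {
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values must have sample rownames and feature colnames")
  }
  if (ncol(values) == 0L) colnames(values) <- character()
  if (anyDuplicated(colnames(values))) stop("feature ids must be unique")
  modality <- rep_len(as.character(modality), ncol(values))
  known <- c("methylation", "occupancy", "fuzziness", "wps")
  if (!all(modality %in% known)) {
    stop("unknown modality tag; must be one of ", paste(known, collapse = ", "))
  }
  if (length(labels) != nrow(values)) stop("labels must match sample count")
  structure(list(values = values,
                 modality = stats::setNames(modality, colnames(values)),
                 labels = factor(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$modality), collapse = ", ")))
  cat("labels:", paste(sprintf("%s=%d", levels(x$labels),
                               tabulate(x$labels)), collapse = ", "), "\n")
  nas <- sum(is.na(x$values))
  if (nas) cat("missing cells:", nas, "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

subset_features <- function(fm, feature_ids) {
  feature_matrix(fm$values[, feature_ids, drop = FALSE],
                 fm$modality[feature_ids], fm$labels)
}

subset_samples <- function(fm, sample_ids) {
  structure(list(values = fm$values[sample_ids, , drop = FALSE],
                 modality = fm$modality,
                 labels = factor(fm$labels[match(sample_ids, rownames(fm$values))],
                                 levels = levels(fm$labels))),
            class = "feature_matrix")
}

#' Assemble per-sample feature tables into a feature matrix
#'
#' @param per_sample named list (by sample id) of named numeric vectors;
#'   all samples share one feature universe, missing entries become `NA`.
#' @param sample_sheet sample sheet with `sample_id` and `label`; every
#'   sheet sample must appear in `per_sample`.
#' @param modality modality tag(s) for the features.
#' @return `feature_matrix` with samples in sheet order and features in
#'   lexicographic order (canonical layout, invariant to input order).
#' @export
assemble_features <- function(per_sample, sample_sheet, modality) {
  missing <- setdiff(sample_sheet$sample_id, names(per_sample))
  if (length(missing)) {
    stop("sample(s) in sheet without feature data: ",
         paste(missing, collapse = ", "))
  }
  feats <- sort(unique(unlist(lapply(per_sample, names))))
  vals <- matrix(NA_real_, nrow(sample_sheet), length(feats),
                 dimnames = list(sample_sheet$sample_id, feats))
  for (s in sample_sheet$sample_id) {
    v <- per_sample[[s]]
    vals[s, names(v)] <- unname(v)
  }
  feature_matrix(vals, modality, sample_sheet$label)
}

#' Drop features with missing training values
#'
#' Removes every feature with at least one missing value among the training
#' samples. This runs inside each cross-validation iteration on the training
#' split only -- never on the full cohort -- so held-out samples cannot
#' influence the feature set. A feature missing only in held-out samples is
#' retained (its held-out value is imputed with the training median at
#' predict time).
#'
#' @param fm feature matrix.
#' @param train_ids training sample ids (subset of rownames).
#' @export
drop_na_features <- function(fm, train_ids) {
  stopifnot(all(train_ids %in% rownames(fm$values)))
  keep <- colSums(is.na(fm$values[train_ids, , drop = FALSE])) == 0L
  subset_features(fm, colnames(fm$values)[keep])
}

#' Drop low-variance features
#'
#' Removes features whose variance over the training samples is at or below
#' `var_threshold`; constant features are always removed. The default
#' threshold 1e-8 is effectively constant-only.
#'
#' @inheritParams drop_na_features
#' @param var_threshold variance cutoff (inclusive).
#' @export
drop_low_variance <- function(fm, train_ids, var_threshold = 1e-8) {
  if (var_threshold < 0) stop("var_threshold must be >= 0")
  v <- apply(fm$values[train_ids, , drop = FALSE], 2,
             function(x) stats::var(x[!is.na(x)]))
  v[is.na(v)] <- 0
  subset_features(fm, colnames(fm$values)[v > var_threshold])
}

#' Low-coverage occupancy feature filter
#'
#' For sparse (low-coverage whole-genome) data, removes occupancy features
#' whose value is lower than the mean of all feature values in at least one
#' sample -- keeping only regions with consistently above-average signal.
#'
#' @param fm feature matrix (occupancy modality).
#' @param sample_ids samples over which the per-sample means are taken
#'   (default: all).
#' @export
drop_low_occupancy <- function(fm, sample_ids = rownames(fm$values)) {
  x <- fm$values[sample_ids, , drop = FALSE]
  row_means <- rowMeans(x, na.rm = TRUE)
  below <- sweep(x, 1, row_means, `<`)
  keep <- colSums(below, na.rm = TRUE) == 0L
  subset_features(fm, colnames(fm$values)[keep])
}

#' Shadow-feature (Boruta) selection
#'
#' All-relevant feature selection by the shadow-feature procedure: at each
#' iteration every original feature is copied and its values permuted
#' ("shadows"), a random forest is fit on the combined real+shadow matrix,
#' and a real feature scores a "hit" when its Gini importance exceeds the
#' maximum shadow importance. After each iteration, two-sided binomial
#' tests of the hit counts against Binomial(iterations, 1/2) with
#' Bonferroni correction across all features promote features to
#' "confirmed" or demote them to "rejected". Rejected features are
#' eliminated from further consideration (they leave the real half of the
#' forest), but the shadow pool is always rebuilt from the full original
#' feature set, so the importance bar stays the maximum over p fresh
#' permutations throughout -- letting the contrast pool shrink with the
#' rejections makes the late bar trivially low and spuriously confirms
#' chance-correlated noise. Iteration stops when every feature is decided
#' or at `max_iter`.
#' Features are ranked confirmed first, then tentative, then rejected,
#' within status by decreasing mean importance (ties by feature id), and
#' the top `k` are selected.
#'
#' @param x numeric matrix (samples x features, no missing values).
#' @param y class labels (factor, >= 2 classes).
#' @param k number of features selected (k >= ncol(x) selects all, ranked).
#' @param max_iter maximum shadow iterations.
#' @param alpha significance level before Bonferroni correction.
#' @param num_trees trees per forest.
#' @param seed RNG seed; results are reproducible given (x, y, seed).
#' @return list of class `boruta_result`: `ranking` (data.frame with
#'   `feature`, `status`, `mean_importance`, `hits`, `rank`), `selected`,
#'   `iterations`, `seed`.
#' @export
boruta_select <- function(x, y, k = 100L, max_iter = 100L, alpha = 0.05,
                          num_trees = 500L, seed = 1L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("labels must contain >= 2 classes")
  p <- ncol(x)
  feats <- colnames(x)
  if (is.null(feats)) stop("x must have feature colnames")
  set.seed(seed)
  active <- rep(TRUE, p)
  hits <- integer(p)
  imp_sum <- numeric(p)
  imp_n <- integer(p)
  status <- rep("tentative", p)
  iter <- 0L
  while (iter < max_iter && any(status == "tentative")) {
    iter <- iter + 1L
    ai <- which(active)
    xa <- x[, ai, drop = FALSE]
    shadow <- apply(x, 2, sample)          # permute every original feature
    colnames(shadow) <- paste0(".shadow.", feats)
    fit <- ranger::ranger(x = cbind(xa, shadow), y = y,
                          num.trees = num_trees, importance = "impurity",
                          num.threads = 1L,
                          seed = sample.int(.Machine$integer.max, 1L))
    imp <- fit$variable.importance
    real_imp <- imp[colnames(xa)]
    max_shadow <- max(imp[colnames(shadow)])
    hit <- real_imp > max_shadow
    hits[ai] <- hits[ai] + as.integer(hit)
    imp_sum[ai] <- imp_sum[ai] + real_imp
    imp_n[ai] <- imp_n[ai] + 1L
    # two-sided binomial decisions, Bonferroni across all p features
    a_adj <- alpha / (2 * p)
    tent <- which(status == "tentative")
    p_hi <- stats::pbinom(hits[tent] - 1L, iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits[tent], iter, 0.5)
    status[tent[p_hi < a_adj]] <- "confirmed"
    status[tent[p_lo < a_adj]] <- "rejected"
    active <- status != "rejected"
  }
  mean_imp <- ifelse(imp_n > 0, imp_sum / imp_n, 0)
  status_rank <- match(status, c("confirmed", "tentative", "rejected"))
  ord <- order(status_rank, -mean_imp, feats)
  ranking <- data.frame(feature = feats[ord], status = status[ord],
                        mean_importance = mean_imp[ord], hits = hits[ord],
                        rank = seq_len(p), stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 selected = utils::head(ranking$feature, k),
                 iterations = iter, seed = seed),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$ranking$status,
                      levels = c("confirmed", "tentative", "rejected")))
  cat(sprintf("boruta_result: %d iterations; %d confirmed, %d tentative, %d rejected; %d selected\n",
              x$iterations, tab[1], tab[2], tab[3], length(x$selected)))
  invisible(x)
}
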