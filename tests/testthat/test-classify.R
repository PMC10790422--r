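test_that("evaluation metrics match hand-enumerated cases", {
  ev <- evaluate(c(0.9, 0.8, 0.1, 0.2),
                 c("cancer", "cancer", "control", "control"), "cancer")
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$sens_at_spec, 1.0)
  expect_equal(ev$f1, 1.0)

  ev2 <- evaluate(c(0.6, 0.4, 0.5, 0.3),
                  c("cancer", "cancer", "control", "control"), "cancer")
  expect_equal(ev2$auc, 0.75)              # 3 of 4 concordant pairs

  ev3 <- evaluate(rep(0.4, 6), rep(c("cancer", "control"), 3), "cancer")
  expect_equal(ev3$auc, 0.5)               # all tied -> 0.5 under midranks

  expect_error(evaluate(c(0.1, 0.2), c("cancer", "cancer"), "cancer"),
               "one class absent")
})

test_that("AUC equals brute-force concordant-pair counting on random fixtures", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    lab <- sample(c("cancer", "control"), n, replace = TRUE,
                  prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    probs <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse grids force ties
    ev <- evaluate(probs, lab, "cancer")
    expect_equal(ev$auc, bf_auc(probs, lab == "cancer"))
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  lab <- sample(c("cancer", "control"), 80, replace = TRUE)
  probs <- round(runif(80), 2)
  ev <- evaluate(probs, lab, "cancer")
  ref <- as.numeric(pROC::auc(pROC::roc(lab, probs, levels = c("control", "cancer"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ev$auc, ref)
})

test_that("sensitivity at 90% specificity reads the first qualifying threshold", {
  # 10 controls: one above 0.65 -> specificity hits 0.9 at t = 0.65
  probs <- c(seq(0.05, 0.45, length.out = 9), 0.7,   # controls
             0.6, 0.65, 0.8, 0.9, 0.3)               # cancers
  lab <- rep(c("control", "cancer"), c(10, 5))
  ev <- evaluate(probs, lab, "cancer")
  expect_equal(ev$sens_at_spec, 4 / 5)
  # threshold 0.5 confusion: TP = 4, FP = 1, FN = 1 -> F1 = 8/10
  expect_equal(ev$f1, 2 * 4 / (2 * 4 + 1 + 1))
  expect_equal(as.vector(ev$confusion), c(4, 1, 1, 9))
})

test_that("multiclass evaluation uses argmax with lexicographic tie-break", {
  P <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(P) <- c("control", "hcc", "pdac")
  ev <- evaluate_multiclass(P, c("control", "hcc", "pdac"))
  expect_equal(ev$accuracy, 1.0)

  Pu <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("hcc", "control", "pdac")))
  labs <- rep(c("control", "hcc", "pdac"), 2)
  evu <- evaluate_multiclass(Pu, labs)
  expect_equal(evu$accuracy, 1 / 3)        # everything goes to "control"
  expect_true(all(evu$confusion[, "control"] == 2))

  P6 <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6),
              c(0.5, 0.4, 0.1), c(0.1, 0.6, 0.3), c(0.3, 0.3, 0.4))
  colnames(P6) <- c("control", "hcc", "pdac")
  lab6 <- c("control", "hcc", "pdac", "hcc", "control", "pdac")
  ev6 <- evaluate_multiclass(P6, lab6)
  expect_equal(ev6$accuracy, 4 / 6)
  expect_equal(as.vector(ev6$confusion),
               c(1, 1, 0, 1, 1, 0, 0, 0, 2))
  expect_error(evaluate_multiclass(P6, c(lab6[-6], "other")), "outside")
  expect_error(evaluate_multiclass(P6 * 2, lab6), "sum to 1")
})

test_that("probability correlations form a symmetric rank-correlation matrix", {
  set.seed(43)
  x <- runif(30)
  m <- cbind(a = x, b = x, c = 1 - x)
  pc <- probability_correlations(m)
  expect_equal(pc["a", "b"], 1.0)
  expect_equal(pc["a", "c"], -1.0)
  expect_equal(diag(pc), c(a = 1, b = 1, c = 1))
  expect_identical(pc, t(pc))

  mc <- cbind(a = x, b = rep(0.5, 30))
  pcc <- probability_correlations(mc)
  expect_true(is.na(pcc["a", "b"]))

  null_rho <- replicate(40, {
    probability_correlations(cbind(a = runif(100), b = runif(100)))["a", "b"]
  })
  expect_gte(mean(abs(null_rho) < 0.3), 0.95)
})

test_that("single-modality LOOCV separates a perfectly informative feature", {
  fm <- toy_matrix(40, 5, planted = TRUE, seed = 44)
  cv <- loocv_single_modality(fm, study_config(), seed = 2)
  expect_equal(cv$eval$auc, 1.0)
  expect_equal(nrow(cv$probs), 40L)
  expect_equal(cv$probs$sample_id, rownames(fm$values))
})

test_that("inner CV yields one out-of-fold probability per sample per modality", {
  set.seed(45)
  x <- list(occupancy = toy_matrix(40, 6, planted = TRUE, seed = 45),
            wps = toy_matrix(40, 6, seed = 46))
  x$wps$labels <- x$occupancy$labels
  oof <- inner_cv_base_predictions(x, k = 10, study_config(), seed = 3)
  expect_equal(dim(oof), c(40L, 2L))
  expect_false(anyNA(oof))
  oof2 <- inner_cv_base_predictions(x, k = 10, study_config(), seed = 3)
  expect_identical(oof, oof2)              # deterministic given the seed
  # k = n reduces to inner LOOCV and still covers every sample
  oof3 <- inner_cv_base_predictions(x, k = 40, study_config(), seed = 4)
  expect_false(anyNA(oof3))
})

test_that("meta-classifier is monotone when all base columns agree", {
  set.seed(46)
  p <- runif(60)
  y <- factor(ifelse(p + rnorm(60, 0, 0.2) > 0.5, "cancer", "control"))
  oof <- cbind(m1 = p, m2 = p, m3 = p)
  meta <- cfepi:::fit_meta(oof, y, model_config())
  grid <- cbind(m1 = seq(0, 1, 0.1), m2 = seq(0, 1, 0.1),
                m3 = seq(0, 1, 0.1))
  pr <- cfepi:::predict_meta(meta, grid)[, "cancer"]
  expect_true(all(diff(pr) > 0))
})

test_that("stacking tracks an informative column despite noise columns", {
  set.seed(47)
  n <- 200
  y <- rep(c("cancer", "control"), each = n / 2)
  informative <- plogis(ifelse(y == "cancer", 1, -1) + rnorm(n))
  oof <- cbind(a = informative, b = runif(n), c = runif(n), d = runif(n))
  meta <- cfepi:::fit_meta(oof, factor(y), model_config())
  pr <- cfepi:::predict_meta(meta, oof)[, "cancer"]
  auc_base <- bf_auc(informative, y == "cancer")
  auc_meta <- bf_auc(pr, y == "cancer")
  expect_gte(auc_meta, auc_base - 0.05)

  # two complementary half-informative columns beat either alone
  s1 <- ifelse(y == "cancer", 0.7, -0.7) + rnorm(n)
  s2 <- ifelse(y == "cancer", 0.7, -0.7) + rnorm(n)
  oof2 <- cbind(a = plogis(s1), b = plogis(s2))
  meta2 <- cfepi:::fit_meta(oof2, factor(y), model_config())
  pr2 <- cfepi:::predict_meta(meta2, oof2)[, "cancer"]
  expect_gt(bf_auc(pr2, y == "cancer"),
            max(bf_auc(oof2[, 1], y == "cancer"),
                bf_auc(oof2[, 2], y == "cancer")))
})

test_that("stacked fit predicts new samples and exposes coefficients", {
  set.seed(48)
  x <- list(occupancy = toy_matrix(30, 6, planted = TRUE, seed = 48),
            wps = toy_matrix(30, 6, planted = TRUE, seed = 49))
  x$wps$labels <- x$occupancy$labels
  fit <- stacked_fit(x, study_config(), seed = 5)
  expect_s3_class(fit, "cfepi_fit")
  expect_equal(sort(colnames(fit$oof)), c("occupancy", "wps"))
  newd <- list(occupancy = x$occupancy$values[1:3, ],
               wps = x$wps$values[1:3, ])
  pr <- predict(fit, newd)
  expect_equal(dim(pr), c(3L, 2L))
  expect_equal(unname(rowSums(pr)), rep(1, 3), tolerance = 1e-9)
  expect_true(is.matrix(coef(fit)))
  expect_error(predict(fit, newd["wps"]), "missing modality")
})

test_that("LOOCV probabilities come from models never trained on the held-out sample", {
  # leakage guard: mutating the held-out sample's features must not change
  # that iteration's selection, base models or prediction of other samples
  set.seed(50)
  n <- 16
  lab <- rep(c("cancer", "control"), each = n / 2)
  x <- matrix(rnorm(n * 120), n, 120,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%03d", 1:120)))
  x[, 1] <- (lab == "cancer") + rnorm(n, 0, 0.3)
  fm <- feature_matrix(x, "methylation", lab)     # p > top_k: selection runs
  cfg <- model_config(num_trees = 100, top_k = 20, boruta_max_iter = 15)
  train <- rownames(x)[-1]
  base_a <- cfepi:::fit_base_model(fm, train, cfg, seed = 77)
  fm_mut <- fm
  fm_mut$values[1, ] <- 999                        # corrupt held-out row
  base_b <- cfepi:::fit_base_model(fm_mut, train, cfg, seed = 77)
  expect_identical(base_a$features, base_b$features)
  expect_identical(base_a$selection$ranking, base_b$selection$ranking)
  expect_identical(base_a$medians, base_b$medians)
  expect_equal(cfepi:::predict_base_model(base_a, fm$values[2, , drop = FALSE]),
               cfepi:::predict_base_model(base_b, fm$values[2, , drop = FALSE]))
})

test_that("null labels give chance-level LOOCV performance", {
  set.seed(51)
  aucs <- replicate(5, {
    fm <- toy_matrix(24, 6, seed = sample.int(1e6, 1))
    loocv_single_modality(fm, study_config(), seed = sample.int(1e6, 1))$eval$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("multimodal LOOCV emits one final probability per sample", {
  set.seed(52)
  x <- list(occupancy = toy_matrix(12, 5, planted = TRUE, seed = 52),
            wps = toy_matrix(12, 5, seed = 53))
  x$wps$labels <- x$occupancy$labels
  cv <- loocv_multimodal(x, study_config(inner_k = 5), seed = 6)
  expect_equal(nrow(cv$probs), 12L)
  expect_false(anyNA(cv$probs$final))
  expect_equal(colnames(cv$prob_correlations), c("occupancy", "wps"))
  cv2 <- loocv_multimodal(x, study_config(inner_k = 5), seed = 6)
  expect_identical(cv$probs, cv2$probs)     # full determinism
})

test_that("cross-cohort validation fits once and generalizes to shared features", {
  set.seed(54)
  mk <- function(seed, n = 24) {
    a <- toy_matrix(n, 6, planted = TRUE, seed = seed)
    b <- toy_matrix(n, 6, planted = TRUE, seed = seed + 1)
    b$labels <- a$labels
    list(occupancy = a, wps = b)
  }
  tr <- mk(100)
  # resubstitution sanity bound: test == train is at least as good as LOOCV
  res <- cross_cohort(tr, tr, study_config(), seed = 7)
  cvh <- loocv_multimodal(tr, study_config(), seed = 7)
  expect_gte(res$eval$auc, cvh$eval$auc)
  te <- mk(200)
  out <- cross_cohort(tr, te, study_config(), seed = 7)
  expect_gte(out$eval$auc, 0.85)
  # permuted test labels give chance performance
  te_perm <- te
  set.seed(55)
  perm <- sample(length(te_perm$occupancy$labels))
  te_perm$occupancy$labels <- te_perm$occupancy$labels[perm]
  te_perm$wps$labels <- te_perm$wps$labels[perm]
  outp <- cross_cohort(tr, te_perm, study_config(), seed = 7)
  expect_lt(abs(outp$eval$auc - 0.5), 0.25)
  # empty feature intersection errors
  te2 <- te
  colnames(te2$occupancy$values) <- paste0("other_", colnames(te2$occupancy$values))
  expect_error(cross_cohort(tr, te2, study_config(), seed = 7),
               "empty feature intersection")
})

test_that("three-class mode stacks per-class probability vectors", {
  set.seed(56)
  n <- 30
  lab <- rep(c("control", "hcc", "pdac"), each = 10)
  mk3 <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(sprintf("s%02d", 1:n), sprintf("f%d", 1:5)))
    x[, 1] <- c(control = 0, hcc = 2, pdac = 4)[lab] + rnorm(n, 0, 0.5)
    feature_matrix(x, "occupancy", lab)
  }
  x <- list(occupancy = mk3(1), wps = mk3(2))
  cv <- loocv_multimodal(x, study_config(inner_k = 5), seed = 8)
  expect_s3_class(cv$eval, "cfepi_eval_multiclass")
  expect_gte(cv$eval$accuracy, 0.8)
  expect_equal(sum(cv$eval$confusion), n)
})
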