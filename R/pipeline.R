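run_config_defaults <- function() {
  list(
    sample_dir = NULL,        # directory with sample_sheet.tsv + panel.bed
    out_dir = NULL,
    min_len = 80L, max_len = 200L,          # fragment size filter (bp)
    qc_max_lambda = 0.01,                   # spike-in QC threshold
    window_mode = FALSE,
    wps_k = 120L,
    modalities = c("methylation", "occupancy", "fuzziness", "wps"),
    top_k = 100L, inner_k = 10L, num_trees = 500L,
    meta = "logistic", threshold = 0.5, spec_target = 0.90,
    min_fuzziness_support = 20,
    seed = 1L
  )
}

#' Pipeline run configuration
#'
#' Flat-key configuration with every protocol constant defaulted: 80/200 bp
#' fragment bounds, 1% lambda QC threshold, top 100 features, tenfold inner
#' CV, 90% specificity operating point. Unknown keys are rejected by name.
#' Round-trips losslessly through YAML via [read_run_config()] /
#' [write_run_config()].
#'
#' @param ... overrides of the defaults (see `run_config_defaults`
#'   internals / the pipeline vignette).
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg$min_len <- as.integer(cfg$min_len)
  cfg$max_len <- as.integer(cfg$max_len)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param cfg configuration list from [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full pipeline
#'
#' Orchestrates QC, feature extraction, selection, stacked LOOCV modeling
#' and reporting into a deterministic directory layout (`qc/`,
#' `features/<modality>/`, `selection/`, `models/`, `reports/`). Re-running
#' with the same config and seed reproduces bit-identical reports.
#'
#' @param cfg [run_config()].
#' @param cohort optional in-memory cohort (e.g. from [simulate_cohort()]);
#'   when `NULL` the cohort is read from `cfg$sample_dir`.
#' @return (invisibly) the output directory; `reports/metrics.json` holds
#'   the headline metrics.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (is.null(cohort)) {
    if (is.null(cfg$sample_dir)) stop("config must set sample_dir or pass a cohort")
    cohort <- read_cohort(cfg$sample_dir)
  }
  out <- cfg$out_dir
  for (d in c("qc", "selection", "models", "reports")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  # --- QC ---------------------------------------------------------------
  qc <- cohort_qc(cohort, max_ratio = cfg$qc_max_lambda)
  utils::write.table(qc, file.path(out, "qc", "qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  keep <- qc$sample_id[qc$passed]
  for (i in seq_len(nrow(qc))) {
    message(sprintf("QC %s: %s (lambda methylation %.4f)", qc$sample_id[i],
                    qc$status[i], qc$lambda_meth_ratio[i]))
  }
  if (length(keep) < nrow(qc)) {
    message(nrow(qc) - length(keep), " sample(s) removed by spike-in QC")
  }
  cohort$sample_sheet <- cohort$sample_sheet[
    cohort$sample_sheet$sample_id %in% keep, , drop = FALSE]
  # --- features ---------------------------------------------------------
  fms <- extract_cohort_features(
    cohort, window_mode = cfg$window_mode, min_len = cfg$min_len,
    max_len = cfg$max_len, wps_k = cfg$wps_k,
    min_fuzziness_support = cfg$min_fuzziness_support)
  fms <- fms[intersect(cfg$modalities, names(fms))]
  for (m in names(fms)) {
    d <- file.path(out, "features", m)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(fms[[m]]$values),
                 label = as.character(fms[[m]]$labels),
                 fms[[m]]$values, check.names = FALSE),
      file.path(d, "matrix.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  # --- model ------------------------------------------------------------
  mcfg <- model_config(top_k = cfg$top_k, inner_k = cfg$inner_k,
                       num_trees = cfg$num_trees, meta = cfg$meta,
                       threshold = cfg$threshold,
                       spec_target = cfg$spec_target)
  cv <- loocv_multimodal(fms, mcfg, seed = cfg$seed)
  final_fit <- stacked_fit(fms, mcfg, seed = cfg$seed)
  for (m in names(fms)) {
    sel <- final_fit$bases[[m]]$selection
    tab <- if (!is.null(sel)) sel$ranking else {
      data.frame(feature = final_fit$bases[[m]]$features,
                 status = "selected_all", mean_importance = NA_real_,
                 hits = NA_integer_,
                 rank = seq_along(final_fit$bases[[m]]$features))
    }
    utils::write.table(tab, file.path(out, "selection", paste0(m, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(utils::capture.output(print(final_fit)),
             file.path(out, "models", "stacked_model.txt"))
  # --- reports ----------------------------------------------------------
  utils::write.table(cv$probs, file.path(out, "reports", "probabilities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- list(n = nrow(cv$probs),
                  auc = cv$eval$auc,
                  sens_at_spec = cv$eval$sens_at_spec,
                  spec_target = cv$eval$spec_target,
                  f1 = cv$eval$f1,
                  threshold = cv$eval$threshold,
                  modality_auc = as.list(cv$modality_auc),
                  seed = cfg$seed)
  jsonlite::write_json(metrics, file.path(out, "reports", "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(cv$eval$roc, file.path(out, "reports", "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cv$eval$confusion),
                     file.path(out, "reports", "confusion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  corr <- cv$prob_correlations
  utils::write.table(data.frame(modality = rownames(corr), corr,
                                check.names = FALSE),
                     file.path(out, "reports", "probability_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("cfepi")),
                   n_samples_input = nrow(qc),
                   n_samples_passed_qc = length(keep))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
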