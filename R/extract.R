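# per-sample feature vectors for the four modalities.
# frags must already be size-filtered; nuc_regions anchored; calls are the
# sample's CpG calls. Window mode emits one feature per 1 kb / 10 bp
# sliding window instead of one per region.
extract_sample <- function(frags, calls, nuc_regions, cpg_regions,
                           window_mode = FALSE, meth_mode = "site",
                           wps_k = 120L, min_summit_occ = 0.5,
                           min_spacing = 147L, smooth_width = 73L) {
  nf <- panel_norm_factor(frags, nuc_regions)
  occ <- fuzz <- wps <- numeric(0)
  support <- numeric(0)        # supporting fragments per region
  for (i in seq_len(nrow(nuc_regions))) {
    r <- nuc_regions[i, ]
    prof <- compute_occupancy(frags, r,
                              norm_factor = if (is.na(nf)) 1 else nf)
    peaks <- call_nucleosomes(frags, prof, min_summit_occ, min_spacing,
                              smooth_width)
    wprof <- compute_wps(frags, r, wps_k)
    support <- c(support, sum(peaks$n_support))
    if (window_mode) {
      wins <- make_windows(r)
      co <- cumsum(c(0, prof$values))
      cw <- cumsum(c(0, wprof$values))
      lo <- wins$start - r$start
      hi <- wins$end - r$start
      width <- hi - lo
      ov <- (co[hi + 1L] - co[lo + 1L]) / width
      wv <- (cw[hi + 1L] - cw[lo + 1L]) / width
      names(ov) <- names(wv) <- wins$name
      fz <- vapply(seq_len(nrow(wins)), function(j) {
        region_fuzziness_feature(peaks, wins[j, ])
      }, numeric(1))
      names(fz) <- wins$name
      occ <- c(occ, ov); wps <- c(wps, wv); fuzz <- c(fuzz, fz)
    } else {
      occ[r$name] <- mean(prof$values)
      wps[r$name] <- mean(wprof$values)
      fuzz[r$name] <- region_fuzziness_feature(peaks, r)
    }
  }
  if (meth_mode == "region") {
    rm <- region_methylation(calls, cpg_regions)
    meth <- stats::setNames(rm$ratio, rm$name)
  } else {
    sm <- site_methylation(calls)
    in_panel <- logical(nrow(sm))
    reg_of <- character(nrow(sm))
    for (i in seq_len(nrow(cpg_regions))) {
      r <- cpg_regions[i, ]
      hit <- sm$chrom == r$chrom & sm$pos >= r$start & sm$pos < r$end
      in_panel <- in_panel | hit
      reg_of[hit] <- r$name
    }
    meth <- stats::setNames(sm$ratio[in_panel],
                            sprintf("%s:%d", reg_of[in_panel],
                                    sm$pos[in_panel]))
  }
  list(methylation = meth, occupancy = occ, fuzziness = fuzz, wps = wps,
       mean_peak_support = if (length(support)) mean(support) else NA_real_)
}

#' Extract the four feature matrices from a cohort
#'
#' Runs the full per-sample feature extraction: fragment size filtering,
#' panel-normalized occupancy, nucleosome peak calling with fuzziness,
#' per-bp WPS, and per-CpG methylation ratios; assembles one
#' `feature_matrix` per modality over all samples. Nucleosome features are
#' one per region by default, or one per 1 kb / 10 bp sliding window with
#' `window_mode = TRUE`.
#'
#' The fuzziness modality is dropped automatically (with a message) when
#' the cohort's mean per-region supporting-fragment count falls below
#' `min_fuzziness_support`: at low sequencing depth the positional SD is
#' too noisy to be a usable feature, as in low-coverage whole-genome mode.
#'
#' @param cohort a `cfepi_cohort` (or a list with the same shape: `regions`,
#'   per-sample `fragments` and `methylation` lists, `sample_sheet`).
#' @param window_mode emit sliding-window features for the 2 kb regions.
#' @param meth_mode `"site"` for one feature per CpG site (the default for
#'   CpG-marker panels) or `"region"` for the count-pooled per-region ratio
#'   (the convention of the low-coverage whole-genome mode).
#' @param min_len,max_len fragment size filter (bp).
#' @param wps_k WPS window (bp, even).
#' @param min_summit_occ,min_spacing,smooth_width peak-calling parameters
#'   (see [call_peaks()]).
#' @param min_fuzziness_support minimum mean supporting fragments per
#'   region for the fuzziness modality to be emitted.
#' @return named list of `feature_matrix` objects (methylation, occupancy,
#'   fuzziness when reliable, wps).
#' @export
extract_cohort_features <- function(cohort, window_mode = FALSE,
                                    meth_mode = c("site", "region"),
                                    min_len = 80L, max_len = 200L,
                                    wps_k = 120L, min_summit_occ = 0.5,
                                    min_spacing = 147L, smooth_width = 73L,
                                    min_fuzziness_support = 20) {
  meth_mode <- match.arg(meth_mode)
  regions <- cohort$regions
  nuc <- regions[regions$region_type %in% c("tss", "pas"), , drop = FALSE]
  cpg <- regions[regions$region_type == "cpg_marker", , drop = FALSE]
  sheet <- cohort$sample_sheet
  per <- lapply(sheet$sample_id, function(s) {
    fr <- filter_fragments(cohort$fragments[[s]], min_len, max_len)
    extract_sample(fr, cohort$methylation[[s]], nuc, cpg,
                   window_mode = window_mode, meth_mode = meth_mode,
                   wps_k = wps_k, min_summit_occ = min_summit_occ,
                   min_spacing = min_spacing, smooth_width = smooth_width)
  })
  names(per) <- sheet$sample_id
  grab <- function(what) lapply(per, `[[`, what)
  out <- list(
    methylation = assemble_features(grab("methylation"), sheet, "methylation"),
    occupancy = assemble_features(grab("occupancy"), sheet, "occupancy"),
    fuzziness = assemble_features(grab("fuzziness"), sheet, "fuzziness"),
    wps = assemble_features(grab("wps"), sheet, "wps")
  )
  support <- mean(unlist(grab("mean_peak_support")), na.rm = TRUE)
  if (is.finite(support) && support < min_fuzziness_support) {
    message(sprintf(
      "mean per-region nucleosome support %.1f < %s fragments: fuzziness modality disabled",
      support, format(min_fuzziness_support)))
    out$fuzziness <- NULL
  }
  attr(out, "mean_peak_support") <- support
  out
}

#' Run spike-in QC over a cohort
#'
#' @param cohort a `cfepi_cohort` (or compatible list with a per-sample
#'   `lambda` list).
#' @param max_ratio maximum tolerated pooled lambda methylation ratio.
#' @param allow_missing see [spike_in_qc()].
#' @return data frame with one QC row per sample.
#' @export
cohort_qc <- function(cohort, max_ratio = 0.01, allow_missing = FALSE) {
  rows <- lapply(cohort$sample_sheet$sample_id, function(s) {
    spike_in_qc(cohort$lambda[[s]], s, max_ratio, allow_missing)
  })
  do.call(rbind, rows)
}

#' Read a cohort from files written by [write_cohort()]
#'
#' @param dir directory holding `sample_sheet.tsv`, `panel.bed` and the
#'   per-sample fragment/methylation/lambda files it references.
#' @return list with the `cfepi_cohort` shape, usable by
#'   [extract_cohort_features()] and [cohort_qc()].
#' @export
read_cohort <- function(dir) {
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  regions <- read_regions(file.path(dir, "panel.bed"))
  frags <- meth <- lambda <- list()
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample_id[i]
    fmt <- if (grepl("\\.bedpe$", sheet$fragments[i])) "bedpe" else "bed"
    frags[[s]] <- read_fragments(file.path(dir, sheet$fragments[i]), fmt, s)
    meth[[s]] <- read_methylation(file.path(dir, sheet$methylation[i]))
    if (!is.null(sheet$lambda)) {
      lambda[[s]] <- read_methylation(file.path(dir, sheet$lambda[i]))
    }
  }
  list(regions = regions, fragments = frags, methylation = meth,
       lambda = lambda, sample_sheet = sheet)
}
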