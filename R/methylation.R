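#' Read per-CpG methylation calls
#'
#' Tab-separated table of per-cytosine counts in the shape produced by
#' methylation-ratio callers: columns `chrom`, `pos` (0-based), optional
#' `strand`, `n_meth`, `n_total`. A header row is detected automatically.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `chrom`, `pos`, `n_meth`, `n_total`.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("chrom", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  if (!header) {
    names(tab) <- if (ncol(tab) >= 5) {
      c("chrom", "pos", "strand", "n_meth", "n_total")[seq_len(ncol(tab))]
    } else c("chrom", "pos", "n_meth", "n_total")
  }
  cpg_calls(tab$chrom, tab$pos, tab$n_meth, tab$n_total)
}

#' Construct validated CpG site calls
#'
#' @param chrom,pos site coordinates (0-based position of the cytosine).
#' @param n_meth,n_total methylated and total call counts,
#'   `0 <= n_meth <= n_total`.
#' @export
cpg_calls <- function(chrom, pos, n_meth, n_total) {
  n_meth <- as.integer(n_meth); n_total <- as.integer(n_total)
  chrom <- rep_len(as.character(chrom), length(pos))
  if (any(n_meth < 0 | n_total < 0)) stop("counts must be non-negative")
  bad <- which(n_meth > n_total)
  if (length(bad)) {
    stop("validation error: n_meth > n_total at row ", bad[1])
  }
  data.frame(chrom = chrom, pos = as.integer(pos),
             n_meth = n_meth, n_total = n_total, stringsAsFactors = FALSE)
}

#' Per-site methylation ratio
#'
#' The conventional methylation ratio `n_meth / n_total` per cytosine.
#' Zero-coverage sites get `NA`, which downstream feature filtering treats
#' as a missing feature value.
#'
#' @param calls CpG call table from [cpg_calls()].
#' @return the call table with a `ratio` column appended.
#' @export
site_methylation <- function(calls) {
  calls <- cpg_calls(calls$chrom, calls$pos, calls$n_meth, calls$n_total)
  calls$ratio <- ifelse(calls$n_total > 0, calls$n_meth / calls$n_total,
                        NA_real_)
  calls
}

#' Region-pooled methylation ratio
#'
#' Count-weighted pooling: the number of methylated calls divided by the
#' total number of calls over all sites inside each region
#' (sum(n_meth) / sum(n_total)), not the mean of per-site ratios. This is
#' coverage-robust and is the convention used for region-level methylation
#' features in both the targeted and the low-coverage whole-genome modes.
#'
#' @param calls CpG call table.
#' @param regions target-region table; a site belongs to a region when
#'   `start <= pos < end` on the same chromosome.
#' @return `data.frame` with columns `name`, `n_meth`, `n_total`, `ratio`
#'   (one row per region; `ratio` is `NA` where no calls were observed).
#' @export
region_methylation <- function(calls, regions) {
  out <- data.frame(name = regions$name,
                    n_meth = 0L, n_total = 0L, ratio = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    in_r <- calls$chrom == r$chrom & calls$pos >= r$start & calls$pos < r$end
    out$n_meth[i] <- sum(calls$n_meth[in_r])
    out$n_total[i] <- sum(calls$n_total[in_r])
  }
  out$ratio <- ifelse(out$n_total > 0, out$n_meth / out$n_total, NA_real_)
  out
}

#' Spike-in conversion QC
#'
#' Each library carries fully unmethylated lambda phage DNA; residual
#' apparent methylation on the spike-in measures incomplete C-to-T
#' conversion. The pooled lambda methylation ratio is
#' sum(n_meth)/sum(n_total) over all spike-in sites; a sample fails QC when
#' that ratio exceeds `max_ratio` (default 1%, i.e. conversion below 99%),
#' and failed samples must be excluded from every downstream analysis.
#' A ratio exactly at the threshold passes.
#'
#' @param lambda_calls CpG call table restricted to the spike-in contig.
#' @param sample_id sample key for the report.
#' @param max_ratio maximum tolerated pooled lambda methylation ratio.
#' @param allow_missing if `TRUE`, a sample with no lambda calls is retained
#'   with status `"indeterminate"` (and a warning); otherwise it is failed.
#' @return one-row `data.frame`: `sample_id`, `lambda_meth_ratio`,
#'   `conversion_rate`, `passed`, `status`.
#' @export
spike_in_qc <- function(lambda_calls, sample_id = NA_character_,
                        max_ratio = 0.01, allow_missing = FALSE) {
  tot <- sum(lambda_calls$n_total)
  if (tot == 0) {
    warning("no spike-in calls for sample ", sample_id,
            "; conversion rate indeterminate")
    return(data.frame(sample_id = sample_id,
                      lambda_meth_ratio = NA_real_,
                      conversion_rate = NA_real_,
                      passed = allow_missing,
                      status = "indeterminate",
                      stringsAsFactors = FALSE))
  }
  ratio <- sum(lambda_calls$n_meth) / tot
  data.frame(sample_id = sample_id,
             lambda_meth_ratio = ratio,
             conversion_rate = 1 - ratio,
             passed = ratio <= max_ratio,
             status = if (ratio <= max_ratio) "pass" else "fail",
             stringsAsFactors = FALSE)
}
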