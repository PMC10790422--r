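#' Synthetic cfDNA cohort configuration
#'
#' Defines the generative model of the synthetic cohorts: nucleosome-
#' protected fragments (modal length 167 bp) sampled from a lattice of
#' nucleosome positions with a nucleosome-depleted region (NDR) at each
#' TSS/PAS anchor, positional jitter controlling fuzziness, class-dependent
#' NDR depth controlling occupancy, a class-dependent sub-nucleosomal
#' fragment fraction controlling WPS, binomial per-CpG methylation with
#' class-dependent rates, and an unmethylated lambda spike-in with a
#' configurable conversion rate. Class effects are planted only in the
#' configured informative regions of each modality; everywhere else both
#' classes share the baseline parameters.
#'
#' Biological and technical between-sample variability has two layers.
#' Subject-level heterogeneity -- one draw per sample, shared by all its
#' regions -- shifts the NDR depth additively (`ndr_sample_sd`), the jitter
#' multiplicatively (`jitter_sample_cv`, lognormal), and the methylation
#' rate and sub-nucleosomal fraction on the logit scale (`meth_sample_sd`,
#' `short_sample_sd`). Because these shifts are shared across a sample's
#' regions they do not average away over the panel, which keeps class
#' overlap realistic. Region-level noise adds a lognormal depth multiplier
#' per sample and region (`sample_cv`) and a Beta-distributed per-region
#' methylation rate (`meth_dispersion` is the Beta concentration).
#'
#' @param n_cancer,n_control samples per class.
#' @param n_cpg_regions CpG-marker regions (150 bp) in the methylation panel.
#' @param cpgs_per_region CpG sites per marker region.
#' @param n_tss,n_pas TSS/PAS regions (anchor +/- 1 kb) in the
#'   nucleosome-organization panel.
#' @param frag_len_mean,frag_len_sd fragment length Normal parameters (bp);
#'   lengths are rounded and rejected outside [50, 250].
#' @param nucleosome_spacing lattice spacing of nucleosome centers (bp).
#' @param ndr_width width of the depleted window at the anchor (bp).
#' @param jitter_sd,cancer_jitter_sd positional SD (bp) of fragment
#'   midpoints around their nucleosome center (baseline / cancer value in
#'   fuzziness-informative regions).
#' @param ndr_depth,cancer_ndr_depth sampling weight of lattice positions
#'   inside the NDR relative to 1 outside (baseline / cancer value in
#'   occupancy-informative regions).
#' @param meth_rate,cancer_meth_rate per-CpG methylation probability
#'   (baseline / cancer value in methylation-informative regions).
#' @param short_frac,cancer_short_frac fraction of sub-nucleosomal
#'   (~105 bp) fragments (baseline / cancer value in WPS-informative
#'   regions).
#' @param depth expected fragments per nucleosome region per sample.
#' @param meth_coverage expected calls per CpG site (Poisson).
#' @param sample_cv lognormal sigma of the per-sample, per-region depth
#'   multiplier.
#' @param meth_dispersion Beta concentration of the per-sample, per-region
#'   methylation rate.
#' @param ndr_sample_sd,jitter_sample_cv,meth_sample_sd,short_sample_sd
#'   subject-level heterogeneity of the four modality parameters (see
#'   Details).
#' @param lambda_sites,lambda_coverage spike-in site count and coverage.
#' @param lambda_conversion C-to-T conversion rate of the spike-in; apparent
#'   lambda methylation is `1 - lambda_conversion`.
#' @param informative list with integer index vectors `methylation`
#'   (into CpG regions), `occupancy`, `fuzziness`, `wps` (into nucleosome
#'   regions) naming where class effects are planted.
#' @param seed RNG seed; cohorts are byte-identical given (config, seed).
#' @return list of class `sim_config`.
#' @seealso [sim_preset()], [simulate_cohort()]
#' @export
sim_config <- function(n_cancer = 30L, n_control = 30L,
                       n_cpg_regions = 40L, cpgs_per_region = 5L,
                       n_tss = 24L, n_pas = 16L,
                       frag_len_mean = 167, frag_len_sd = 9,
                       nucleosome_spacing = 185L, ndr_width = 600L,
                       jitter_sd = 4, cancer_jitter_sd = 4.4,
                       ndr_depth = 0.5, cancer_ndr_depth = 0.3,
                       meth_rate = 0.25, cancer_meth_rate = 0.30,
                       short_frac = 0.10, cancer_short_frac = 0.30,
                       depth = 300L, meth_coverage = 50,
                       sample_cv = 0.05, meth_dispersion = 300,
                       ndr_sample_sd = 0.1, jitter_sample_cv = 0.12,
                       meth_sample_sd = 0.2, short_sample_sd = 0.2,
                       lambda_sites = 200L, lambda_coverage = 100,
                       lambda_conversion = 0.998,
                       informative = list(methylation = integer(),
                                          occupancy = integer(),
                                          fuzziness = integer(),
                                          wps = integer()),
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(cfg$ndr_depth, cfg$cancer_ndr_depth, cfg$meth_rate,
             cfg$cancer_meth_rate, cfg$short_frac, cfg$cancer_short_frac,
             cfg$lambda_conversion)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$jitter_sd < 0 || cfg$cancer_jitter_sd < 0) {
    stop("jitter_sd must be >= 0")
  }
  if (any(c(cfg$n_cancer, cfg$n_control, cfg$depth) < 1)) {
    stop("counts must be >= 1")
  }
  if (cfg$ndr_width >= 2000L) stop("NDR wider than the 2 kb region")
  structure(cfg, class = "sim_config")
}

#' Named simulation presets
#'
#' * `"null"` -- identical class parameters everywhere; pipeline AUCs
#'   should calibrate to 0.5.
#' * `"strong"` -- a deep occupancy NDR effect planted in a quarter of the
#'   nucleosome panel (regions 1-10; per-feature standardized effect
#'   around 2). Effects in only part of the panel survive the panel-mean
#'   depth normalization, which would cancel a uniform shift.
#' * `"complementary"` -- disjoint informative regions per modality
#'   (occupancy regions 1-10, fuzziness 11-20, WPS 21-30 of the nucleosome
#'   panel; CpG regions 1-10 for methylation), so each modality carries its
#'   own signal and stacking can exceed every single modality.
#' * `"jitter"` -- identical classes; use the `jitter_sd` override to study
#'   fuzziness recovery across jitter levels.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @param ... overrides passed to [sim_config()].
#' @export
sim_preset <- function(name = c("null", "strong", "complementary", "jitter"),
                       seed = 1L, ...) {
  name <- match.arg(name)
  over <- list(...)
  base <- list(seed = seed)
  inf0 <- list(methylation = integer(), occupancy = integer(),
               fuzziness = integer(), wps = integer())
  inf <- switch(name,
    null = inf0,
    jitter = inf0,
    strong = utils::modifyList(inf0, list(occupancy = 1:10)),
    complementary = list(methylation = 1:10, occupancy = 1:10,
                         fuzziness = 11:20, wps = 21:30)
  )
  if (name == "strong") {
    base <- c(base, list(cancer_ndr_depth = 0.1, ndr_width = 800L))
  }
  args <- utils::modifyList(c(base, list(informative = inf)), over)
  do.call(sim_config, args)
}

# panel layout on an artificial mini-genome: nucleosome regions on contig
# "sim_nuc" (anchors every 4 kb), CpG regions on "sim_cpg"
sim_regions <- function(cfg) {
  n_nuc <- cfg$n_tss + cfg$n_pas
  anchors <- 5000L + (seq_len(n_nuc) - 1L) * 4000L
  nuc <- target_regions(
    chrom = "sim_nuc", start = anchors - 1000L, end = anchors + 1000L,
    name = sprintf("nuc%02d", seq_len(n_nuc)),
    region_type = rep(c("tss", "pas"), c(cfg$n_tss, cfg$n_pas)),
    anchor = anchors
  )
  starts <- 1000L + (seq_len(cfg$n_cpg_regions) - 1L) * 1000L
  cpg <- target_regions(
    chrom = "sim_cpg", start = starts, end = starts + 150L,
    name = sprintf("cpg%02d", seq_len(cfg$n_cpg_regions)),
    region_type = "cpg_marker"
  )
  list(nuc = nuc, cpg = cpg)
}

sim_cpg_sites <- function(cfg, cpg_regions) {
  pieces <- lapply(seq_len(nrow(cpg_regions)), function(i) {
    r <- cpg_regions[i, ]
    pos <- r$start + round(seq(15, (r$end - r$start) - 15,
                               length.out = cfg$cpgs_per_region))
    data.frame(chrom = r$chrom, pos = as.integer(pos), region = r$name,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# lengths ~ round(Normal(mean, sd)) truncated to [50, 250]
sim_frag_lengths <- function(n, mean, sd) {
  len <- round(stats::rnorm(n, mean, sd))
  bad <- which(len < 50 | len > 250)
  while (length(bad)) {
    len[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[len[bad] < 50 | len[bad] > 250]
  }
  as.integer(len)
}

#' Simulate fragments for one region
#'
#' Nucleosome centers sit on a lattice; lattice positions within
#' `ndr_width / 2` of the anchor have their sampling weight multiplied by
#' `ndr_depth`. The realized fragment count is Poisson with mean
#' `depth * mean(lattice weights)`, so a deeper NDR yields fewer protected
#' fragments from the region, not just a reshaped profile. Each molecule
#' draws a lattice center, adds Normal(0, `jitter_sd`) positional jitter
#' (rounded), draws its length (a fraction `short_frac` from the ~105 bp
#' sub-nucleosomal component, the rest from Normal(`frag_len_mean`,
#' `frag_len_sd`)), and is placed with its midpoint at the jittered center.
#' Uses the current RNG stream.
#'
#' @param region one-row region table (anchored for tss/pas).
#' @param depth expected fragments at full lattice occupancy.
#' @param jitter_sd,ndr_depth,short_frac per-class parameters.
#' @param cfg [sim_config()] for the shared fragment-model constants.
#' @param sample_id sample key.
#' @export
simulate_region_fragments <- function(region, depth, jitter_sd, ndr_depth,
                                      short_frac, cfg, sample_id = NA) {
  anchored <- region$region_type %in% c("tss", "pas")
  phase <- if (anchored) region$anchor else {
    (region$start + region$end) %/% 2L
  }
  span <- 250L
  # lattice phased to the anchor so the NDR sits symmetrically on it
  m <- ceiling(((region$end - region$start) / 2 + span) /
                 cfg$nucleosome_spacing)
  lattice <- phase + seq.int(-m, m) * cfg$nucleosome_spacing
  lattice <- lattice[lattice >= region$start - span &
                     lattice <= region$end + span]
  w <- rep(1, length(lattice))
  if (anchored) {
    w[abs(lattice - region$anchor) < cfg$ndr_width / 2] <- ndr_depth
  }
  n <- stats::rpois(1, depth * mean(w))
  if (n < 1) return(empty_fragments())
  centers <- lattice[sample.int(length(lattice), n, replace = TRUE, prob = w)]
  mid <- centers + round(stats::rnorm(n, 0, jitter_sd))
  is_short <- stats::runif(n) < short_frac
  len <- integer(n)
  if (any(!is_short)) {
    len[!is_short] <- sim_frag_lengths(sum(!is_short), cfg$frag_len_mean,
                                       cfg$frag_len_sd)
  }
  if (any(is_short)) {
    len[is_short] <- sim_frag_lengths(sum(is_short), 105, 8)
  }
  start <- mid - (len - 1L) %/% 2L     # exact midpoint-at-center placement
  fragments(region$chrom, start, start + len, sample_id)
}

#' Simulate per-CpG methylation calls
#'
#' Coverage is Poisson(`coverage`); methylated counts are Binomial with the
#' site's rate. With `dispersion < Inf` each region draws one
#' Beta(rate * dispersion, (1 - rate) * dispersion) per-sample rate shared
#' by its sites (between-sample biological variability); rates of exactly
#' 0 or 1 are kept exact. Uses the current RNG stream.
#'
#' @param sites data frame with `chrom`, `pos`, `region`.
#' @param rate_by_region named per-region methylation rates.
#' @param coverage expected calls per site.
#' @param dispersion Beta concentration (larger = less variable).
#' @export
simulate_methylation <- function(sites, rate_by_region, coverage = 50,
                                 dispersion = 150) {
  n <- nrow(sites)
  rate <- unname(rate_by_region[sites$region])
  if (is.finite(dispersion)) {
    for (rg in unique(sites$region)) {
      i <- sites$region == rg
      r0 <- rate_by_region[[rg]]
      if (r0 > 0 && r0 < 1) {
        rate[i] <- stats::rbeta(1, r0 * dispersion, (1 - r0) * dispersion)
      }
    }
  }
  n_total <- stats::rpois(n, coverage)
  n_meth <- stats::rbinom(n, n_total, rate)
  cpg_calls(sites$chrom, sites$pos, n_meth, n_total)
}

sim_lambda_calls <- function(cfg) {
  n_total <- stats::rpois(cfg$lambda_sites, cfg$lambda_coverage)
  n_meth <- stats::rbinom(cfg$lambda_sites, n_total,
                          1 - cfg$lambda_conversion)
  cpg_calls("lambda", seq_len(cfg$lambda_sites) * 50L, n_meth, n_total)
}

#' Simulate a full multi-sample cohort
#'
#' Generates fragments, methylation calls and lambda spike-in calls for
#' every sample, a sample sheet with true labels, and a ground-truth record
#' of the informative regions per modality. Reproducible (byte-identical)
#' given the config's seed.
#'
#' @param cfg [sim_config()] or [sim_preset()].
#' @param dir optional directory: when given, all standard input files are
#'   written (per-sample BEDPE fragments, methylation and lambda TSVs,
#'   panel BEDs, sample sheet, `ground_truth.json`).
#' @return list of class `cfepi_cohort`: `config`, `regions` (nucleosome +
#'   CpG panels combined), `cpg_sites`, `fragments` / `methylation` /
#'   `lambda` (named per-sample lists), `sample_sheet`, `ground_truth`.
#' @export
simulate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  panels <- sim_regions(cfg)
  nuc <- panels$nuc; cpg <- panels$cpg
  sites <- sim_cpg_sites(cfg, cpg)
  inf <- cfg$informative
  for (nm in names(inf)) {
    top <- if (nm == "methylation") nrow(cpg) else nrow(nuc)
    if (length(inf[[nm]]) && (min(inf[[nm]]) < 1 || max(inf[[nm]]) > top)) {
      stop("informative index out of range for ", nm)
    }
  }
  ids <- c(sprintf("cancer%02d", seq_len(cfg$n_cancer)),
           sprintf("control%02d", seq_len(cfg$n_control)))
  labels <- rep(c("cancer", "control"), c(cfg$n_cancer, cfg$n_control))
  frags <- meth <- lambda <- stats::setNames(vector("list", length(ids)), ids)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  logit_shift <- function(p, d) {
    ifelse(p <= 0 | p >= 1, p, stats::plogis(stats::qlogis(p) + d))
  }
  for (s in seq_along(ids)) {
    cancer <- labels[s] == "cancer"
    # subject-level heterogeneity, shared across the sample's regions
    ndr_shift <- stats::rnorm(1, 0, cfg$ndr_sample_sd)
    jitter_mult <- exp(stats::rnorm(1, 0, cfg$jitter_sample_cv))
    meth_shift <- stats::rnorm(1, 0, cfg$meth_sample_sd)
    short_shift <- stats::rnorm(1, 0, cfg$short_sample_sd)
    parts <- vector("list", nrow(nuc))
    for (i in seq_len(nrow(nuc))) {
      depth_mult <- exp(stats::rnorm(1, -cfg$sample_cv^2 / 2, cfg$sample_cv))
      jit <- if (cancer && i %in% inf$fuzziness)
        cfg$cancer_jitter_sd else cfg$jitter_sd
      nd <- if (cancer && i %in% inf$occupancy)
        cfg$cancer_ndr_depth else cfg$ndr_depth
      sf <- if (cancer && i %in% inf$wps)
        cfg$cancer_short_frac else cfg$short_frac
      parts[[i]] <- simulate_region_fragments(
        nuc[i, ], cfg$depth * depth_mult,
        jitter_sd = jit * jitter_mult,
        ndr_depth = clamp01(nd + ndr_shift),
        short_frac = logit_shift(sf, short_shift),
        cfg = cfg, sample_id = ids[s]
      )
    }
    f <- do.call(rbind, parts)
    frags[[s]] <- f[order(f$chrom, f$start, f$end), , drop = FALSE]
    rate <- stats::setNames(rep(cfg$meth_rate, nrow(cpg)), cpg$name)
    if (cancer && length(inf$methylation)) {
      rate[inf$methylation] <- cfg$cancer_meth_rate
    }
    rate <- stats::setNames(logit_shift(rate, meth_shift), cpg$name)
    meth[[s]] <- simulate_methylation(sites, rate, cfg$meth_coverage,
                                      cfg$meth_dispersion)
    lambda[[s]] <- sim_lambda_calls(cfg)
  }
  sheet <- data.frame(sample_id = ids, label = labels, cohort = "sim",
                      fragments = paste0(ids, ".bedpe"),
                      methylation = paste0(ids, ".meth.tsv"),
                      lambda = paste0(ids, ".lambda.tsv"),
                      stringsAsFactors = FALSE)
  truth <- list(methylation = cpg$name[inf$methylation],
                occupancy = nuc$name[inf$occupancy],
                fuzziness = nuc$name[inf$fuzziness],
                wps = nuc$name[inf$wps])
  cohort <- structure(list(config = cfg, regions = rbind(nuc, cpg),
                           cpg_sites = sites, fragments = frags,
                           methylation = meth, lambda = lambda,
                           sample_sheet = sheet, ground_truth = truth),
                      class = "cfepi_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.cfepi_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("cfepi_cohort: %d cancer + %d control samples\n",
              cfg$n_cancer, cfg$n_control))
  cat(sprintf("panels: %d nucleosome regions (tss/pas), %d CpG regions x %d sites\n",
              sum(x$regions$region_type != "cpg_marker"),
              cfg$n_cpg_regions, cfg$cpgs_per_region))
  ninf <- vapply(x$ground_truth, length, integer(1))
  cat("informative regions:",
      paste(sprintf("%s=%d", names(ninf), ninf), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated cohort as standard input files
#'
#' @param cohort a `cfepi_cohort`.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- cohort$sample_sheet
  for (s in sheet$sample_id) {
    write_fragments(cohort$fragments[[s]], file.path(dir, paste0(s, ".bedpe")),
                    format = "bedpe")
    write_calls <- function(calls, path) {
      utils::write.table(calls, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
    }
    write_calls(cohort$methylation[[s]],
                file.path(dir, paste0(s, ".meth.tsv")))
    write_calls(cohort$lambda[[s]],
                file.path(dir, paste0(s, ".lambda.tsv")))
  }
  write_regions(cohort$regions, file.path(dir, "panel.bed"))
  utils::write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Generate the artificial mini-genome
#'
#' Random-sequence contigs matching the simulated panel layout, for the
#' dinucleotide diagnostic; no external reference is required anywhere in
#' the package.
#'
#' @param lengths named contig lengths (bp).
#' @param seed RNG seed.
#' @return a `Biostrings::DNAStringSet`.
#' @export
simulate_genome <- function(lengths = c(sim_nuc = 200000L, sim_cpg = 50000L),
                            seed = 1L) {
  set.seed(seed)
  seqs <- vapply(lengths, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(lengths)))
}
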