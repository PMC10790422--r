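#' Per-bp nucleosome occupancy
#'
#' Raw occupancy at base b is the number of kept (size-filtered) fragments
#' covering b -- the full-fragment pileup that underlies nucleosome-position
#' quantification of mononucleosome-length fragments. With
#' `norm_factor != 1` the profile is scaled so samples become comparable;
#' use [panel_norm_factor()] to scale a sample's panel-wide mean occupancy
#' to 1.
#'
#' @param frags fragment table (already size-filtered).
#' @param region a single target region.
#' @param norm_factor scalar multiplier applied to the raw counts.
#' @return list with `region`, `values` (length = region length, clipped to
#'   region bounds) and `norm_factor`.
#' @export
compute_occupancy <- function(frags, region, norm_factor = 1) {
  if (nrow(region) != 1L) stop("region must be a single region")
  S <- region$start; E <- region$end
  if (E <= S) stop("region of zero length")
  L <- E - S
  f <- frags[frags$chrom == region$chrom & frags$end > S & frags$start < E, ,
             drop = FALSE]
  if (nrow(f)) {
    lo <- pmax(f$start, S) - S + 1L
    hi <- pmin(f$end, E) - S + 1L
    delta <- tabulate(lo, L + 1L) - tabulate(hi, L + 1L)
  } else {
    delta <- integer(L + 1L)
  }
  list(region = region, values = cumsum(delta[seq_len(L)]) * norm_factor,
       norm_factor = norm_factor)
}

#' Panel-wide depth normalization factor
#'
#' Returns the scalar by which raw per-bp occupancy must be multiplied so
#' that the sample's mean occupancy over all panel regions equals 1.
#'
#' @param frags fragment table for one sample.
#' @param regions panel regions over which the mean is taken.
#' @export
panel_norm_factor <- function(frags, regions) {
  # sum of raw occupancy over a region equals the summed fragment-overlap
  # lengths, so no pileup is needed
  tot <- 0; nbp <- 0
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    f <- frags[frags$chrom == r$chrom & frags$end > r$start &
                 frags$start < r$end, , drop = FALSE]
    tot <- tot + sum(pmin(f$end, r$end) - pmax(f$start, r$start))
    nbp <- nbp + (r$end - r$start)
  }
  if (tot == 0) return(NA_real_)
  nbp / tot
}

# centered moving average with truncated windows at the profile edges
smooth_profile <- function(values, width = 73L) {
  if (width <= 1L) return(values)
  half <- (width - 1L) %/% 2L
  n <- length(values)
  cs <- cumsum(c(0, values))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call nucleosome peaks on an occupancy profile
#'
#' The profile is smoothed with a centered moving average (default width
#' 73 bp, half a nucleosome) and local maxima with smoothed value at least
#' `min_summit_occ` become candidate summits; for a plateau the leftmost
#' base is the summit. Candidates closer than `min_spacing` are merged
#' keeping the higher summit (ties: leftmost). Each peak spans
#' `[summit - 73, summit + 74)` -- the 147 bp of nucleosomal DNA.
#'
#' @param profile occupancy profile from [compute_occupancy()].
#' @param min_summit_occ minimum smoothed summit occupancy (in the profile's
#'   normalized units; default 0.5 assumes panel-mean-1 normalization).
#' @param min_spacing minimum distance between retained summits, bp.
#' @param smooth_width moving-average width in bp.
#' @return `data.frame` of peaks sorted by summit: `summit` (genomic bp),
#'   `summit_occ` (smoothed value), `span_start`, `span_end`.
#' @export
call_peaks <- function(profile, min_summit_occ = 0.5, min_spacing = 147L,
                       smooth_width = 73L) {
  v <- smooth_profile(profile$values, smooth_width)
  n <- length(v)
  empty <- data.frame(summit = integer(), summit_occ = numeric(),
                      span_start = integer(), span_end = integer())
  if (n == 0L) return(empty)
  # plateau-aware local maxima: leftmost base of each maximal run that is
  # strictly above both flanking values (edges count as -Inf)
  runs <- rle(v)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- length(runs$values)
  left <- c(-Inf, runs$values[-k])
  right <- c(runs$values[-1L], -Inf)
  is_max <- runs$values > left & runs$values > right &
    runs$values >= min_summit_occ
  if (!any(is_max)) return(empty)
  cand_pos <- starts[is_max]
  cand_val <- runs$values[is_max]
  # merge: greedily keep the higher summit, ties to the leftmost
  ord <- order(-cand_val, cand_pos)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(cand_pos[kept] - cand_pos[j]) >= min_spacing)) {
      kept <- c(kept, j)
    }
  }
  kept <- kept[order(cand_pos[kept])]
  summit <- profile$region$start + cand_pos[kept] - 1L
  data.frame(summit = summit, summit_occ = cand_val[kept],
             span_start = summit - 73L, span_end = summit + 74L)
}

#' Fragment midpoints
#'
#' Midpoint of the half-open fragment `[s, e)` is `floor((s + e - 1) / 2)`.
#'
#' @param frags fragment table.
#' @export
fragment_midpoints <- function(frags) {
  (frags$start + frags$end - 1L) %/% 2L
}

#' Nucleosome fuzziness of one peak
#'
#' Fuzziness is the dispersion of nucleosome positions within a region
#' across the contributing cell population, measured as the population
#' standard deviation (divisor n) of the midpoints of the fragments
#' supporting the peak -- those whose midpoint falls inside the peak span
#' `[summit - 73, summit + 74)`. Identical midpoints give exactly 0; fewer
#' than two supporting fragments give `NA`.
#'
#' @param frags fragment table for the sample (same chromosome as the peak's
#'   region, or the full sample).
#' @param peak one row of the [call_peaks()] output.
#' @param chrom chromosome of the peak (used to subset `frags`).
#' @return fuzziness in bp, or `NA`.
#' @export
peak_fuzziness <- function(frags, peak, chrom = NULL) {
  f <- if (is.null(chrom)) frags else frags[frags$chrom == chrom, , drop = FALSE]
  m <- fragment_midpoints(f)
  m <- m[m >= peak$span_start & m < peak$span_end]
  if (length(m) < 2L) return(NA_real_)
  mu <- mean(m)
  sqrt(mean((m - mu)^2))
}

#' Call peaks and score fuzziness for one region
#'
#' Convenience wrapper: peaks from [call_peaks()] with `fuzziness` and
#' `n_support` (supporting-fragment count) columns appended.
#'
#' @inheritParams call_peaks
#' @param frags fragment table used for midpoint support.
#' @export
call_nucleosomes <- function(frags, profile, min_summit_occ = 0.5,
                             min_spacing = 147L, smooth_width = 73L) {
  peaks <- call_peaks(profile, min_summit_occ, min_spacing, smooth_width)
  chrom <- profile$region$chrom
  f <- frags[frags$chrom == chrom, , drop = FALSE]
  m <- fragment_midpoints(f)
  peaks$fuzziness <- NA_real_
  peaks$n_support <- 0L
  for (i in seq_len(nrow(peaks))) {
    mi <- m[m >= peaks$span_start[i] & m < peaks$span_end[i]]
    peaks$n_support[i] <- length(mi)
    if (length(mi) >= 2L) {
      mu <- mean(mi)
      peaks$fuzziness[i] <- sqrt(mean((mi - mu)^2))
    }
  }
  peaks
}

#' Mean occupancy over a region or window
#'
#' @param profile occupancy profile.
#' @param window optional sub-region; defaults to the whole profiled region.
#' @export
region_occupancy_feature <- function(profile, window = NULL) {
  r <- profile$region
  if (is.null(window)) return(mean(profile$values))
  idx <- (window$start - r$start + 1L):(window$end - r$start)
  if (min(idx) < 1L || max(idx) > length(profile$values)) {
    stop("window outside profiled region")
  }
  mean(profile$values[idx])
}

#' Mean fuzziness of nucleosomes centered in a region or window
#'
#' @param peaks peak table with a `fuzziness` column
#'   (see [call_nucleosomes()]).
#' @param region region/window; peaks qualify when
#'   `start <= summit < end`.
#' @return mean fuzziness over qualifying peaks (missing fuzziness values
#'   dropped), or `NA` when no peak qualifies.
#' @export
region_fuzziness_feature <- function(peaks, region) {
  inside <- peaks$summit >= region$start & peaks$summit < region$end
  f <- peaks$fuzziness[inside]
  f <- f[!is.na(f)]
  if (!length(f)) return(NA_real_)
  mean(f)
}

#' Fragment length histogram
#'
#' Exact integer counts per fragment length with the modal length attached
#' (`attr(x, "mode")`). Intended as the usual cfDNA diagnostic: the unfiltered
#' distribution peaks near 167 bp, the length of DNA bound by a nucleosome
#' plus linker histone.
#'
#' @param frags fragment table (typically unfiltered).
#' @return `data.frame` with `length` and `count`, ascending in length.
#' @export
fragment_length_histogram <- function(frags) {
  if (!nrow(frags)) {
    out <- data.frame(length = integer(), count = integer())
    attr(out, "mode") <- NA_integer_
    return(out)
  }
  tab <- table(frags$length)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab))
  attr(out, "mode") <- out$length[which.max(out$count)]
  out
}

#' Dinucleotide fraction profile across fragments
#'
#' For fragments of exactly `frag_len` bp, computes at every offset (from
#' `-flank` upstream of the fragment start to `flank - 1` past the end) the
#' fraction of fragments whose genomic dinucleotide at that offset belongs
#' to `dinucs` (default: the A/T-containing class, whose ~10 bp periodicity
#' across 147 bp fragments is the classic signature of nucleosomal DNA).
#' Periodicity is summarized by the dominant period of the detrended
#' within-fragment profile: the inverse of the frequency with maximal
#' periodogram power inside `period_range` (the band around the ~10 bp
#' helical repeat; restricting to the band keeps harmonics of an impulse-
#' like repeat from masquerading as the period), reported with its
#' signal-to-noise ratio (band maximum / in-band median power). Periods are
#' reported as `NA` when the SNR is below `snr_min` (no dominant period
#' above the noise floor).
#'
#' @param frags fragment table.
#' @param fasta reference sequences: a `Biostrings::DNAStringSet` or a path
#'   to a FASTA file.
#' @param frag_len fragment length selected for the profile (bp).
#' @param flank flanking bp on each side.
#' @param dinucs character vector of dinucleotides counted as a class.
#' @param snr_min minimum spectral signal-to-noise for a period call.
#' @param period_range candidate period band in bp.
#' @return list: `profile` (`data.frame` of `offset`, `fraction`), `period`,
#'   `snr`, `n_fragments`.
#' @export
dinucleotide_profile <- function(frags, fasta, frag_len = 147L, flank = 50L,
                                 dinucs = c("AA", "AT", "TA", "TT"),
                                 snr_min = 15, period_range = c(6, 30)) {
  genome <- if (inherits(fasta, "DNAStringSet")) fasta else {
    Biostrings::readDNAStringSet(fasta)
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  f <- frags[frags$length == frag_len, , drop = FALSE]
  if (!nrow(f)) stop("no fragments of length ", frag_len)
  miss <- setdiff(unique(f$chrom), names(genome))
  if (length(miss)) {
    stop("contig(s) missing from FASTA: ", paste(miss, collapse = ", "))
  }
  offsets <- seq.int(-flank, frag_len + flank - 2L)
  # drop fragments whose flanked window leaves the contig
  clen <- Biostrings::width(genome)[match(f$chrom, names(genome))]
  ok <- f$start - flank >= 0L & f$start + frag_len + flank <= clen
  f <- f[ok, , drop = FALSE]
  if (!nrow(f)) stop("no fragments with complete flanks")
  seqs <- as.character(Biostrings::subseq(
    genome[f$chrom], start = f$start - flank + 1L,
    width = frag_len + 2L * flank))
  hit <- matrix(FALSE, nrow(f), length(offsets))
  for (j in seq_along(offsets)) {
    di <- substr(seqs, j, j + 1L)
    hit[, j] <- di %in% dinucs
  }
  frac <- colMeans(hit)
  profile <- data.frame(offset = offsets, fraction = frac)
  # periodicity over the fragment body only
  body <- frac[offsets >= 0 & offsets < frag_len - 1L]
  detr <- body - smooth_profile(body, 21L)
  pw <- Mod(stats::fft(detr))^2
  n <- length(detr)
  idx <- 2:floor(n / 2)            # nonzero frequencies
  freq <- (idx - 1) / n
  band <- freq >= 1 / period_range[2] & freq <= 1 / period_range[1]
  if (!any(band) || stats::median(pw[idx][band]) <= 0) {
    period <- NA_real_; snr <- 0
  } else {
    pb <- pw[idx][band]
    snr <- max(pb) / stats::median(pb)
    period <- if (snr >= snr_min) 1 / freq[band][which.max(pb)] else NA_real_
  }
  list(profile = profile, period = period, snr = snr, n_fragments = nrow(f))
}

#' Aggregate occupancy around TSS/PAS anchors
#'
#' Averages anchor-centered occupancy over regions (and samples) to
#' reproduce the aggregate nucleosome-depleted-region diagnostic: occupancy
#' dips at active TSS and PAS anchors relative to the flanking signal.
#'
#' @param frags fragment table (pooled or single sample).
#' @param regions tss/pas regions with anchors.
#' @param halfwidth bp plotted on each side of the anchor.
#' @return list: `offset` (-halfwidth..halfwidth-1), `occupancy` (mean
#'   relative occupancy, normalized to mean 1 over the plotted span) and
#'   `anchor_ratio` -- mean occupancy within +/-50 bp of the anchor divided
#'   by the mean over the rest of the span.
#' @export
aggregate_anchor_profile <- function(frags, regions, halfwidth = 1000L) {
  regions <- regions[regions$region_type %in% c("tss", "pas"), , drop = FALSE]
  if (!nrow(regions)) stop("no anchored (tss/pas) regions")
  acc <- numeric(2L * halfwidth)
  n_used <- 0L
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    win <- data.frame(chrom = r$chrom, start = r$anchor - halfwidth,
                      end = r$anchor + halfwidth, name = r$name,
                      region_type = r$region_type, anchor = r$anchor,
                      stringsAsFactors = FALSE)
    p <- compute_occupancy(frags, win)
    acc <- acc + p$values
    n_used <- n_used + 1L
  }
  prof <- acc / n_used
  if (mean(prof) > 0) prof <- prof / mean(prof)
  offset <- seq.int(-halfwidth, halfwidth - 1L)
  core <- abs(offset) <= 50L
  anchor_ratio <- mean(prof[core]) / mean(prof[!core])
  list(offset = offset, occupancy = prof, anchor_ratio = anchor_ratio)
}
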