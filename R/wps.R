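#' Windowed protection score (WPS)
#'
#' For each base p of the region, with the even window
#' W(p) = [p - k/2, p + k/2 - 1] (inclusive, k = `window_k`), the WPS is the
#' number of fragments completely spanning W(p) minus the number of
#' fragments with at least one endpoint (start s, or last covered base
#' e - 1) inside W(p). High values indicate nucleosome protection; fragments
#' shorter than the window can only contribute non-positive values. All
#' fragments of the sample on the region's chromosome contribute (fragments
#' are not clipped to the region), so scores at the region edges are exact.
#'
#' @param frags size-filtered fragment table (whole sample).
#' @param region a single target region (one-row data.frame).
#' @param window_k protection window width in bp; must be even. 120 bp is
#'   the long-fraction window of the fragmentomics literature.
#' @return list with `region`, `window_k` and integer `values` of length
#'   `region$end - region$start` (position `region$start` first).
#' @export
compute_wps <- function(frags, region, window_k = 120L) {
  if (window_k %% 2L != 0L) stop("window_k must be even")
  if (nrow(region) != 1L) stop("region must be a single region")
  S <- region$start; E <- region$end
  L <- E - S
  h <- window_k %/% 2L
  f <- frags[frags$chrom == region$chrom, , drop = FALSE]
  s <- f$start; e <- f$end; len <- e - s
  # per-fragment position intervals (inclusive genomic coordinates):
  #   +1 where the fragment spans W(p):      p in [s + h, e - h]  (len >= k)
  #   -1 where an endpoint falls in W(p): s in W(p) <=> p in [s-h+1, s+h],
  #      e-1 in W(p) <=> p in [e-h, e+h-1]; a fragment counts once, so the
  #      two endpoint intervals are merged when they overlap (len <= k)
  sp <- len >= window_k
  mg <- len <= window_k
  pos_a <- s[sp] + h;              pos_b <- e[sp] - h
  neg_a <- c(s[mg] - h + 1L,       s[!mg] - h + 1L, e[!mg] - h)
  neg_b <- c(e[mg] + h - 1L,       s[!mg] + h,      e[!mg] + h - 1L)
  acc <- function(a, b) {
    a <- pmax(a, S); b <- pmin(b, E - 1L)
    keep <- a <= b
    tabulate(a[keep] - S + 1L, L + 1L) -
      tabulate(b[keep] - S + 2L, L + 1L)
  }
  delta <- acc(pos_a, pos_b) - acc(neg_a, neg_b)
  list(region = region, window_k = window_k,
       values = cumsum(delta[seq_len(L)]))
}

#' Average WPS over a region or window
#'
#' @param profile WPS profile from [compute_wps()].
#' @param window optional sub-region (one row); defaults to the profile's
#'   full region.
#' @return arithmetic mean of the per-bp WPS values.
#' @export
region_wps_feature <- function(profile, window = NULL) {
  r <- profile$region
  if (is.null(window)) return(mean(profile$values))
  idx <- (window$start - r$start + 1L):(window$end - r$start)
  if (min(idx) < 1L || max(idx) > length(profile$values)) {
    stop("window outside profiled region")
  }
  mean(profile$values[idx])
}
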