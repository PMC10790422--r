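# independent brute-force oracles used across the suite

# per-position fragment pileup
bf_pileup <- function(frags, region) {
  vapply(region$start:(region$end - 1L), function(b) {
    sum(frags$start <= b & frags$end > b)
  }, numeric(1))
}

# per-position windowed protection score: loop over positions x fragments
bf_wps <- function(frags, region, k = 120L) {
  h <- k %/% 2L
  f <- frags[frags$chrom == region$chrom, , drop = FALSE]
  vapply(region$start:(region$end - 1L), function(p) {
    wlo <- p - h; whi <- p + h - 1L
    span <- sum(f$start <= wlo & f$end - 1L >= whi)
    endp <- sum((f$start >= wlo & f$start <= whi) |
                  (f$end - 1L >= wlo & f$end - 1L <= whi))
    span - endp
  }, numeric(1))
}

# concordant-pair AUC with half-credit ties
bf_auc <- function(probs, is_pos) {
  pp <- probs[is_pos]; pn <- probs[!is_pos]
  conc <- 0
  for (a in pp) conc <- conc + sum(a > pn) + 0.5 * sum(a == pn)
  conc / (length(pp) * length(pn))
}

# two-pass population SD
bf_pop_sd <- function(x) {
  mu <- sum(x) / length(x)
  sqrt(sum((x - mu)^2) / length(x))
}

empty_fragments_for_test <- function() {
  fragments(character(), integer(), integer())
}

random_fragments <- function(n, chrom = "c", lo = 0L, hi = 5000L,
                             len_lo = 60L, len_hi = 250L) {
  s <- sample(lo:hi, n, replace = TRUE)
  fragments(chrom, s, s + sample(len_lo:len_hi, n, replace = TRUE))
}

# small two-class feature matrix with an optional planted feature
toy_matrix <- function(n = 20, p = 5, planted = FALSE, seed = 1) {
  set.seed(seed)
  lab <- rep(c("cancer", "control"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p)))
  if (planted) x[, 1] <- (lab == "cancer") + rnorm(n, 0, 0.01)
  feature_matrix(x, "occupancy", lab)
}

# model configuration used by the simulation studies: 200-tree forests
# (selection behaviour is unchanged; see the methods vignette)
study_config <- function(...) model_config(num_trees = 200L, ...)
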