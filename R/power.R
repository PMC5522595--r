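#' Configuration for relationship-inference power
#'
#' @param alpha significance level for the likelihood-ratio test
#' @param error_rate genotyping error rate entering the dyad likelihoods
#'   (typical values: 1e-5 for SNPs, 0.015 for STRs)
#' @param bin_width discretization width of the log-likelihood-ratio grid
#'   used by the exact convolution
#' @return a `power_config` list
#' @export
power_config <- function(alpha = 0.05, error_rate = 1e-5, bin_width = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (error_rate < 0 || error_rate >= 1) stop("error rate must be in [0, 1)")
  if (bin_width <= 0) stop("bin width must be positive")
  structure(list(alpha = alpha, error_rate = error_rate,
                 bin_width = bin_width), class = "power_config")
}

# Per-locus distribution of the log-likelihood ratio log L(R1)/L(R2) over
# unordered genotype pairs, under each hypothesis. Returns bin indices
# (round(llr / width)) and the two probability vectors.
locus_llr_dist <- function(p, k1, k2, e, width) {
  gs <- genotype_space(length(p))
  ng <- nrow(gs)
  bins <- integer(0); pr1 <- numeric(0); pr2 <- numeric(0)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    l1 <- dyad_likelihood(gs[i, ], gs[j, ], p, k1, e)
    l2 <- dyad_likelihood(gs[i, ], gs[j, ], p, k2, e)
    if (l1 <= 0 && l2 <= 0) next
    if (l1 <= 0 || l2 <= 0)
      stop("infinite log-likelihood ratio; use a positive error rate")
    bins <- c(bins, as.integer(round(log(l1 / l2) / width)))
    pr1 <- c(pr1, l1); pr2 <- c(pr2, l2)
  }
  agg1 <- tapply(pr1, bins, sum)
  agg2 <- tapply(pr2, bins, sum)
  list(bins = as.integer(names(agg1)), p1 = as.numeric(agg1),
       p2 = as.numeric(agg2))
}

# dist = list(offset = bin index of first element, p = probabilities)
convolve_dist <- function(dist, bins, probs) {
  span <- max(bins) - min(bins)
  out <- numeric(length(dist$p) + span)
  base <- min(bins)
  for (k in seq_along(bins)) {
    sh <- bins[k] - base
    idx <- seq_along(dist$p) + sh
    out[idx] <- out[idx] + dist$p * probs[k]
  }
  list(offset = dist$offset + base, p = out)
}

#' Power for relationship inference of a marker panel
#'
#' Exact multi-locus power of the likelihood-ratio test discriminating two
#' candidate relationships. Per locus, the distribution of
#' `log L(R1)/L(R2)` over genotype pairs is computed exactly under each
#' hypothesis; multi-locus distributions follow by discretized convolution
#' on a grid of width `config$bin_width`. The critical value `c` is the
#' smallest grid value with `P(S > c | R2) <= alpha` (conservative,
#' non-randomized) and `PWR = P(S > c | R1)`.
#'
#' @param freqs list of allele-frequency vectors (or numeric vector of
#'   biallelic allele-1 frequencies) for the panel loci
#' @param r1,r2 IBD coefficient vectors `c(k0, k1, k2)` of the two candidate
#'   relationships (see [relationship_models()]); `r1` is the relationship
#'   the test must detect
#' @param config a [power_config()]
#' @return list with `pwr`, `critical`, `alpha_realized`
#' @export
pwr_panel <- function(freqs, r1, r2, config = power_config()) {
  if (is.numeric(freqs)) freqs <- lapply(freqs, function(q) c(q, 1 - q))
  freqs <- Filter(function(p) max(p) < 1 - 1e-12, freqs)
  if (!length(freqs)) stop("no polymorphic loci in panel")
  w <- config$bin_width
  d1 <- list(offset = 0L, p = 1)
  d2 <- list(offset = 0L, p = 1)
  for (p in freqs) {
    ld <- locus_llr_dist(p, r1, r2, config$error_rate, w)
    d1 <- convolve_dist(d1, ld$bins, ld$p1)
    d2 <- convolve_dist(d2, ld$bins, ld$p2)
  }
  # align supports
  lo <- min(d1$offset, d2$offset)
  hi <- max(d1$offset + length(d1$p), d2$offset + length(d2$p)) - 1
  grid <- lo:hi
  f1 <- numeric(length(grid)); f2 <- numeric(length(grid))
  f1[d1$offset - lo + seq_along(d1$p)] <- d1$p
  f2[d2$offset - lo + seq_along(d2$p)] <- d2$p
  # P(S > c): exceedance just above each grid point
  tail2 <- rev(cumsum(rev(f2))) # P(S >= grid)
  exceed2 <- c(tail2[-1], 0)    # P(S > grid)
  ci <- which(exceed2 <= config$alpha + 1e-12)[1]
  tail1 <- rev(cumsum(rev(f1)))
  exceed1 <- c(tail1[-1], 0)
  list(pwr = exceed1[ci], critical = grid[ci] * w,
       alpha_realized = exceed2[ci])
}
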