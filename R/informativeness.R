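check_simplex <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("allele frequencies must be non-negative and sum to 1")
  p
}

power_sums <- function(p, upto = 6) {
  vapply(seq_len(upto), function(n) sum(p^n), 0)
}

#' Probability of identity at one locus
#'
#' `PID` is the probability that two individuals drawn at random from a
#' Hardy-Weinberg population share the same genotype; `PIDsibs` is the same
#' probability for a pair of full siblings, the conservative variant used
#' when samples contain relatives. Both accept any number of alleles. In
#' power sums `a_n = sum(p_i^n)`:
#' `PID = 2 a2^2 - a4`,
#' `PIDsibs = 0.25 + 0.5 a2 + 0.5 a2^2 - 0.25 a4`.
#'
#' @param p allele frequency vector (sums to 1)
#' @return named vector `c(pid, pid_sibs)`
#' @export
pid_locus <- function(p) {
  check_simplex(p)
  a <- power_sums(p, 4)
  c(pid = 2 * a[2]^2 - a[4],
    pid_sibs = 0.25 + 0.5 * a[2] + 0.5 * a[2]^2 - 0.25 * a[4])
}

#' Parentage exclusion probabilities at one locus
#'
#' Jamieson & Taylor closed forms in power sums `a_n = sum(p_i^n)`:
#' * `PE1` — probability of excluding a random non-parent when the other
#'   true parent's genotype is known:
#'   `1 - 2a2 + a3 + 2a4 - 3a5 - 2a2^2 + 3 a2 a3`
#' * `PE2` — the same with the other parent unknown:
#'   `1 - 4a2 + 2a2^2 + 4a3 - 3a4`
#' * `PE3` — probability of excluding a random non-parental pair:
#'   `1 + 4a4 - 4a5 - 3a6 - 8a2^2 + 8 a2 a3 + 2 a3^2`
#'
#' The mapping of each closed form to its label is pinned by an exhaustive
#' genotype-enumeration oracle in the test suite (the literature's labels
#' are frequently permuted).
#'
#' @param p allele frequency vector (sums to 1)
#' @return named vector `c(pe1, pe2, pe3)`
#' @export
pe_locus <- function(p) {
  check_simplex(p)
  a <- power_sums(p, 6)
  c(pe1 = 1 - 2 * a[2] + a[3] + 2 * a[4] - 3 * a[5] - 2 * a[2]^2 + 3 * a[2] * a[3],
    pe2 = 1 - 4 * a[2] + 2 * a[2]^2 + 4 * a[3] - 3 * a[4],
    pe3 = 1 + 4 * a[4] - 4 * a[5] - 3 * a[6] - 8 * a[2]^2 + 8 * a[2] * a[3] +
      2 * a[3]^2)
}

# All unordered genotypes for k alleles as a 2-column matrix (i <= j)
genotype_space <- function(k) {
  gs <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  cbind(gs[, "row"], gs[, "col"])
}

hwe_prob <- function(g, p) {
  ifelse(g[, 1] == g[, 2], p[g[, 1]]^2, 2 * p[g[, 1]] * p[g[, 2]])
}

# T(g2 | g1): genotype distribution of a relative sharing exactly one
# allele IBD with g1 (the shared allele is a uniform pick from g1, the
# other allele is a population draw)
ibd1_transition <- function(g1, g2, p) {
  share_from <- function(x) { # P(g2 | transmitted allele x)
    u <- g2[1]; v <- g2[2]
    if (u == v) (x == u) * p[u]
    else (x == u) * p[v] + (x == v) * p[u]
  }
  0.5 * share_from(g1[1]) + 0.5 * share_from(g1[2])
}

#' Joint genotype probability of a dyad under an IBD relationship
#'
#' `P(g1, g2) = k0 P(g1)P(g2) + k1 P(g1)T(g2|g1) + k2 P(g1) 1[g2 = g1]`
#' under Hardy-Weinberg frequencies `p`, where `(k0, k1, k2)` are the
#' probabilities that the pair shares 0/1/2 alleles identical by descent
#' and `T` is the one-allele-shared transition. With genotyping error rate
#' `e`, each observed genotype is independently a random Hardy-Weinberg
#' draw with probability `e`, so the likelihood mixes to
#' `(1-e)^2 P(g1,g2) + (2e - e^2) P(g1)P(g2)`.
#'
#' @param g1,g2 genotypes as length-2 vectors of allele indices (unordered)
#' @param p allele frequency vector
#' @param k IBD coefficients `c(k0, k1, k2)` summing to 1
#' @param e genotyping error rate in `[0, 1)`
#' @return joint probability
#' @export
dyad_likelihood <- function(g1, g2, p, k, e = 0) {
  check_simplex(p)
  if (abs(sum(k) - 1) > 1e-9 || any(k < 0)) stop("invalid IBD coefficients")
  if (e >= 1 || e < 0) stop("error rate must be in [0, 1)")
  g1 <- sort(g1); g2 <- sort(g2)
  pg <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  base <- k[1] * pg(g1) * pg(g2) +
    k[2] * pg(g1) * ibd1_transition(g1, g2, p) +
    k[3] * pg(g1) * as.numeric(all(g1 == g2))
  (1 - e)^2 * base + (2 * e - e^2) * pg(g1) * pg(g2)
}

#' Canonical IBD relationship models
#'
#' Unrelated `(1,0,0)`, parent-offspring `(0,1,0)`, full siblings
#' `(0.25,0.5,0.25)`, half siblings `(0.5,0.5,0)`.
#'
#' @return named list of `c(k0, k1, k2)` vectors
#' @export
relationship_models <- function() {
  list(UR = c(1, 0, 0), PO = c(0, 1, 0),
       FS = c(0.25, 0.5, 0.25), HS = c(0.5, 0.5, 0))
}

#' Informativeness for relatedness at one locus
#'
#' Fisher information about the relatedness coefficient `r` along the
#' non-inbred path `k(r) = ((1-r)^2, 2r(1-r), r^2)`. Writing `A0`, `A1`,
#' `A2` for the joint dyad genotype distributions with IBD weight fully on
#' `k0`, `k1`, `k2`, the joint distribution at relatedness `r` is
#' `P_r = (1-r)^2 A0 + 2r(1-r) A1 + r^2 A2` and the information is
#' `I(r) = sum over ordered genotype pairs of (dP_r/dr)^2 / P_r`.
#'
#' By default `I_r` is `I(r)` averaged over a uniform prior on
#' `r in (0, 1)` (a flat prior over the path, in the spirit of the
#' `{1,1,1}` prior used by relationship-informativeness software), which
#' makes it strictly increasing in diversity; a point evaluation is
#' available via `at`. At `r = 0` the information reduces to
#' `sum 4 (A1 - A0)^2 / A0`, which equals 1 for every polymorphic
#' biallelic locus — a degenerate ranking criterion, which is why the
#' averaged form is the default. Monomorphic loci carry no information
#' (`I_r = 0`).
#'
#' @param p allele frequency vector
#' @param at optional relatedness value at which to evaluate the
#'   information instead of averaging
#' @return scalar `I_r`
#' @export
ir_locus <- function(p, at = NULL) {
  check_simplex(p)
  if (max(p) >= 1 - 1e-12) return(0)
  gs <- genotype_space(length(p))
  ng <- nrow(gs)
  A0 <- A1 <- A2 <- matrix(0, ng, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    A0[i, j] <- dyad_likelihood(gs[i, ], gs[j, ], p, c(1, 0, 0))
    A1[i, j] <- dyad_likelihood(gs[i, ], gs[j, ], p, c(0, 1, 0))
    A2[i, j] <- dyad_likelihood(gs[i, ], gs[j, ], p, c(0, 0, 1))
  }
  info <- function(r) {
    P <- (1 - r)^2 * A0 + 2 * r * (1 - r) * A1 + r^2 * A2
    D <- -2 * (1 - r) * A0 + (2 - 4 * r) * A1 + 2 * r * A2
    sum(ifelse(P > 1e-300, D^2 / P, 0))
  }
  if (!is.null(at)) return(info(at))
  # fixed midpoint quadrature over the uniform prior on r
  mean(vapply(seq(0.005, 0.995, by = 0.01), info, 0))
}

#' Per-locus informativeness table
#'
#' Computes every per-locus panel-design statistic for a list of loci.
#'
#' @param freqs list of allele-frequency vectors (or a numeric vector of
#'   biallelic allele-1 frequencies)
#' @param marker_ids optional marker names
#' @return data.frame `marker`, `he`, `pid`, `pid_sibs`, `pe1`, `pe2`,
#'   `pe3`, `ir`
#' @export
informativeness_table <- function(freqs, marker_ids = NULL) {
  if (is.numeric(freqs)) freqs <- lapply(freqs, function(q) c(q, 1 - q))
  n <- length(freqs)
  if (is.null(marker_ids)) marker_ids <- sprintf("locus%03d", seq_len(n))
  rows <- lapply(freqs, function(p) {
    pid <- pid_locus(p); pe <- pe_locus(p)
    c(he = 1 - sum(p^2), pid, pe, ir = ir_locus(p))
  })
  out <- data.frame(marker = marker_ids, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

criterion_direction <- c(pid = 1, pid_sibs = 1, # smaller is better
                         pe1 = -1, pe2 = -1, pe3 = -1,
                         ir = -1, he = -1, fst = -1) # larger is better

#' Rank loci and cut nested panels
#'
#' Sorts loci best-first by one criterion (ties broken by marker id) and
#' cuts nested prefix panels of the requested sizes, reporting for each
#' panel the global (product) statistics: multi-locus PID and PIDsibs and
#' the three non-exclusion probabilities `PnE = prod(1 - PE)`. Requested
#' sizes larger than the number of available loci are clamped with a
#' warning.
#'
#' @param tab an [informativeness_table()] (a custom criterion column such
#'   as `fst` may be added by the caller)
#' @param criterion column to rank by
#' @param sizes panel sizes, largest first by convention
#' @return list with `ranking` (marker ids best-first) and `panels`
#'   (data.frame `size`, `pid_global`, `pid_sibs_global`, `pne1`, `pne2`,
#'   `pne3`) plus `panel_markers` (list of id vectors)
#' @export
rank_and_nest <- function(tab, criterion = "pid",
                          sizes = c(343, 192, 96, 48, 24, 12)) {
  if (!criterion %in% names(tab)) stop("unknown criterion: ", criterion)
  dir <- criterion_direction[[criterion]]
  if (is.null(dir)) dir <- -1
  ord <- order(dir * tab[[criterion]], tab$marker)
  ranked <- tab[ord, , drop = FALSE]
  if (any(sizes > nrow(ranked))) {
    warning("panel size clamped to ", nrow(ranked), " available loci")
    sizes <- pmin(sizes, nrow(ranked))
  }
  sizes <- sort(unique(sizes), decreasing = TRUE)
  panels <- lapply(sizes, function(s) ranked[seq_len(s), , drop = FALSE])
  ev <- data.frame(
    size = sizes,
    pid_global = vapply(panels, function(d) prod(d$pid), 0),
    pid_sibs_global = vapply(panels, function(d) prod(d$pid_sibs), 0),
    pne1 = vapply(panels, function(d) prod(1 - d$pe1), 0),
    pne2 = vapply(panels, function(d) prod(1 - d$pe2), 0),
    pne3 = vapply(panels, function(d) prod(1 - d$pe3), 0))
  list(ranking = ranked$marker, panels = ev,
       panel_markers = lapply(panels, `[[`, "marker"))
}

#' Kendall rank correlations between ranking criteria
#'
#' Tie-corrected Kendall tau-b between each pair of columns.
#'
#' @param ranks data.frame or matrix of per-locus criterion values (already
#'   oriented so that larger = better, or raw — tau is sign-sensitive)
#' @return symmetric tau matrix
#' @export
kendall_tau <- function(ranks) {
  m <- as.matrix(ranks)
  cor(m, method = "kendall")
}
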