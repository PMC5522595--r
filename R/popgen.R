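#' Per-locus descriptive statistics within a pool
#'
#' Allele frequencies, minor allele frequency, observed and expected
#' heterozygosity from non-missing calls. At X-linked markers males are
#' hemizygous: they contribute a single allele to the frequencies and are
#' excluded from the heterozygosity fractions.
#'
#' @param gm a [genotype_matrix()]
#' @param pool pool label
#' @return a `marker_stats` data.frame: `marker`, `is_x`, `n_typed`
#'   (individuals with a call), `p1` (frequency of the first declared
#'   allele), `maf`, `ho`, `he`; all-missing markers carry `NA` statistics.
#' @export
per_locus_stats <- function(gm, pool) {
  idx <- pool_samples(gm, pool)
  male <- gm$samples$sex[idx] == "male"
  nm <- n_markers(gm)
  out <- data.frame(marker = gm$markers$id, is_x = gm$markers$is_x,
                    n_typed = 0L, p1 = NA_real_, maf = NA_real_,
                    ho = NA_real_, he = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(nm)) {
    a1 <- gm$a1[idx, j]; a2 <- gm$a2[idx, j]
    ok <- !is.na(a1)
    out$n_typed[j] <- sum(ok)
    if (!any(ok)) next
    hemi <- gm$markers$is_x[j] & male
    dip <- ok & !hemi
    alle <- c(a1[dip], a2[dip], a1[ok & hemi]) # males count one X allele
    k <- length(gm$markers$alleles[[j]])
    cnt <- tabulate(alle, nbins = k)
    p <- cnt / sum(cnt)
    out$p1[j] <- p[1]
    out$maf[j] <- 1 - max(p)
    out$he[j] <- 1 - sum(p^2)
    out$ho[j] <- if (any(dip)) mean(a1[dip] != a2[dip]) else NA_real_
  }
  attr(out, "pool") <- pool
  class(out) <- c("marker_stats", "data.frame")
  out
}

#' Weir-Cockerham differentiation between two pools
#'
#' Per-locus variance components (a, b, c) of the Weir & Cockerham (1984)
#' theta estimator for two populations, and the weighted multi-locus
#' estimate `sum(a) / sum(a + b + c)` (ratio of sums). Loci monomorphic in
#' both pools, with a typed sample missing in either pool, or with a zero
#' total variance are skipped. X-linked markers are evaluated on females
#' only (the diploid estimator does not apply to hemizygous males).
#'
#' @param gm a [genotype_matrix()]
#' @param pool1,pool2 pool labels
#' @return list with `per_locus` data.frame (`marker`, `a`, `b`, `c`,
#'   `theta`), `theta_weighted`, `n_loci_used`
#' @export
wc_fst <- function(gm, pool1 = "pool1", pool2 = "pool2") {
  i1 <- pool_samples(gm, pool1); i2 <- pool_samples(gm, pool2)
  nm <- n_markers(gm)
  comp <- matrix(NA_real_, nm, 3, dimnames = list(gm$markers$id, c("a", "b", "c")))
  for (j in seq_len(nm)) {
    use1 <- i1; use2 <- i2
    if (gm$markers$is_x[j]) {
      use1 <- i1[gm$samples$sex[i1] == "female"]
      use2 <- i2[gm$samples$sex[i2] == "female"]
    }
    g1 <- cbind(gm$a1[use1, j], gm$a2[use1, j])
    g2 <- cbind(gm$a1[use2, j], gm$a2[use2, j])
    g1 <- g1[!is.na(g1[, 1]), , drop = FALSE]
    g2 <- g2[!is.na(g2[, 1]), , drop = FALSE]
    n1 <- nrow(g1); n2 <- nrow(g2)
    if (n1 < 1 || n2 < 1) next
    p1 <- mean(g1 == 1L); p2 <- mean(g2 == 1L)
    if ((p1 %in% c(0, 1)) && (p2 %in% c(0, 1)) && p1 == p2) next # monomorphic
    h1 <- mean(g1[, 1] != g1[, 2]); h2 <- mean(g2[, 1] != g2[, 2])
    r <- 2
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) next
    comp[j, ] <- c(a, b, cc)
  }
  used <- !is.na(comp[, 1])
  if (!any(used)) stop("no usable loci for differentiation")
  per_locus <- data.frame(marker = gm$markers$id[used],
                          a = comp[used, 1], b = comp[used, 2],
                          c = comp[used, 3],
                          theta = comp[used, 1] / rowSums(comp[used, , drop = FALSE]),
                          stringsAsFactors = FALSE)
  list(per_locus = per_locus,
       theta_weighted = sum(per_locus$a) / sum(per_locus$a + per_locus$b + per_locus$c),
       n_loci_used = sum(used))
}

#' Within-pool inbreeding coefficient F_IS
#'
#' Ratio-of-averages form over polymorphic loci:
#' `1 - sum(H_O) / sum(H_E)`.
#'
#' @param stats a [per_locus_stats()] table
#' @return scalar F_IS
#' @export
fis <- function(stats) {
  use <- !is.na(stats$he) & stats$he > 0 & !is.na(stats$ho)
  if (!any(use)) stop("no polymorphic loci: F_IS undefined")
  1 - sum(stats$ho[use]) / sum(stats$he[use])
}

#' Hardy-Weinberg z-test for an autosomal biallelic locus
#'
#' The fixation-index z-test: `Fhat = 1 - H_O/H_E`, `z = sqrt(n) * Fhat`,
#' two-sided p-value `2 * pnorm(-|z|)`. `z^2` equals the classical 1-df HWE
#' chi-square statistic.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts
#' @return list with `fhat`, `z`, `p`
#' @export
hwe_z_test <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  p <- (2 * n_hom1 + n_het) / (2 * n)
  he <- 2 * p * (1 - p)
  if (he == 0) stop("monomorphic locus: z-test undefined")
  fhat <- 1 - (n_het / n) / he
  z <- sqrt(n) * fhat
  list(fhat = fhat, z = z, p = 2 * pnorm(-abs(z)))
}

#' Exact Hardy-Weinberg test for an X-linked locus
#'
#' Joint exact test conditioning on the total allele count across female
#' genotypes and hemizygous male alleles (Graffelman-Weir construction):
#' under the null (random union of gametes and equal male/female allele
#' frequencies) the probability of observing `m_A` copies of allele A among
#' males together with female genotype counts `(n_AA, n_AB, n_BB)` is
#' `choose(n_m, m_A) * n_f!/(n_AA! n_AB! n_BB!) * 2^n_AB * n_A! n_B! / t!`
#' with `t = 2 n_f + n_m` gene copies. The two-sided p-value sums the
#' probabilities of all outcomes no more probable than the observed one.
#' With no males this reduces to the autosomal (Levene) exact test.
#'
#' @param female_counts genotype counts `c(n_AA, n_AB, n_BB)`
#' @param male_counts allele counts `c(n_A, n_B)` among males
#' @return list with `p` and `prob_observed`
#' @export
hwe_x_exact_test <- function(female_counts, male_counts = c(0, 0)) {
  stopifnot(length(female_counts) == 3, length(male_counts) == 2)
  nf <- sum(female_counts); nmale <- sum(male_counts)
  if (nf == 0) stop("no females: X exact test undefined")
  nA <- 2 * female_counts[1] + female_counts[2] + male_counts[1]
  t_copies <- 2 * nf + nmale
  nB <- t_copies - nA
  if (nA == 0 || nB == 0) stop("monomorphic locus: exact test undefined")
  logprob <- function(mA, h) {
    nAA <- (nA - mA - h) / 2
    nBB <- nf - nAA - h
    if (nAA < 0 || nBB < 0 || nAA != round(nAA)) return(-Inf)
    lchoose(nmale, mA) +
      lgamma(nf + 1) - lgamma(nAA + 1) - lgamma(h + 1) - lgamma(nBB + 1) +
      h * log(2) +
      lgamma(nA + 1) + lgamma(nB + 1) - lgamma(t_copies + 1)
  }
  obs <- logprob(male_counts[1], female_counts[2])
  space <- expand.grid(mA = max(0, nA - 2 * nf):min(nmale, nA), h = 0:nf)
  lp <- mapply(logprob, space$mA, space$h)
  pr <- exp(lp[is.finite(lp)])
  p_obs <- exp(obs)
  list(p = min(1, sum(pr[pr <= p_obs * (1 + 1e-9)])), prob_observed = p_obs)
}

#' Hardy-Weinberg tests across markers within a pool
#'
#' Applies [hwe_z_test()] to autosomal markers (genotype counts in the pool)
#' and [hwe_x_exact_test()] to X-linked markers (female genotype counts plus
#' male allele counts), with Benjamini-Hochberg adjustment within each
#' marker family. Markers monomorphic in the pool are excluded.
#'
#' @param gm a [genotype_matrix()]
#' @param pool pool label
#' @return data.frame `marker`, `is_x`, `statistic` (z, `NA` for exact
#'   tests), `p`, `q`
#' @export
hwe_test <- function(gm, pool) {
  idx <- pool_samples(gm, pool)
  male <- gm$samples$sex[idx] == "male"
  rows <- lapply(seq_len(n_markers(gm)), function(j) {
    a1 <- gm$a1[idx, j]; a2 <- gm$a2[idx, j]
    ok <- !is.na(a1)
    if (!any(ok)) return(NULL)
    if (length(gm$markers$alleles[[j]]) != 2) return(NULL)
    if (gm$markers$is_x[j]) {
      fok <- ok & !male; mok <- ok & male
      fc <- c(sum(a1[fok] == 1 & a2[fok] == 1),
              sum(a1[fok] != a2[fok]),
              sum(a1[fok] == 2 & a2[fok] == 2))
      mc <- c(sum(a1[mok] == 1), sum(a1[mok] == 2))
      if (sum(fc) == 0) return(NULL)
      tot <- 2 * fc[1] + fc[2] + mc[1]
      if (tot == 0 || tot == 2 * sum(fc) + sum(mc)) return(NULL) # monomorphic
      r <- hwe_x_exact_test(fc, mc)
      data.frame(marker = gm$markers$id[j], is_x = TRUE,
                 statistic = NA_real_, p = r$p, stringsAsFactors = FALSE)
    } else {
      cnt <- c(sum(a1[ok] == 1 & a2[ok] == 1),
               sum(a1[ok] != a2[ok]),
               sum(a1[ok] == 2 & a2[ok] == 2))
      if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[2] == 0) return(NULL)
      r <- hwe_z_test(cnt[1], cnt[2], cnt[3])
      data.frame(marker = gm$markers$id[j], is_x = FALSE,
                 statistic = r$z, p = r$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable loci in pool ", pool)
  out$q <- NA_real_
  out$q[!out$is_x] <- bh_adjust(out$p[!out$is_x])
  out$q[out$is_x] <- bh_adjust(out$p[out$is_x])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values
#' @return vector of BH q-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pairwise linkage disequilibrium (r-squared) within a pool
#'
#' Squared Pearson correlation of allele-1 dosages over pairwise-complete
#' samples, computed on a subset of (ideally unrelated) individuals.
#' Markers monomorphic in the subset are excluded, mirroring the pool-wise
#' monomorphism filter. Entries with fewer than 2 complete pairs, or where
#' either dosage is constant over the complete pairs, are `NA`.
#'
#' @param gm a [genotype_matrix()]
#' @param pool pool label
#' @param sample_subset optional vector of sample ids (default: all pool
#'   members)
#' @return an `ld_matrix` list: `r2` (symmetric matrix, diagonal 1), `n`
#'   (complete pairs per entry), `markers`, `maf` (within the subset)
#' @export
ld_r2_matrix <- function(gm, pool, sample_subset = NULL) {
  idx <- pool_samples(gm, pool)
  if (!is.null(sample_subset)) {
    idx <- match(sample_subset, gm$samples$id)
    if (anyNA(idx)) stop("unknown sample id in subset")
  }
  if (!length(idx)) stop("empty sample subset")
  sub <- gm_subset(gm, samples = idx)
  mono <- detect_monomorphic(sub)
  drop <- union(mono$monomorphic, mono$all_missing)
  keep <- setdiff(sub$markers$id, drop)
  if (!length(keep)) stop("all markers monomorphic in subset")
  sub <- gm_subset(sub, markers = keep)
  dos <- dosage(sub)
  r <- suppressWarnings(cor(dos, use = "pairwise.complete.obs"))
  r2 <- r^2
  nmat <- crossprod(!is.na(dos))
  r2[nmat < 2] <- NA
  diag(r2) <- 1
  st <- per_locus_stats(sub, pool = sub$samples$pool[1])
  structure(list(r2 = r2, n = nmat, markers = sub$markers$id,
                 maf = setNames(st$maf, st$marker)),
            class = "ld_matrix")
}

#' Greedy all-pairs LD pruning
#'
#' While any retained pair has `r2` strictly above the threshold, removes
#' one member of the currently worst (highest `r2`) pair: the lower-MAF
#' member, ties broken by removing the lexicographically later marker id.
#' On exit no retained pair exceeds the threshold.
#'
#' @param ld an [ld_r2_matrix()] result
#' @param threshold `r2` ceiling in `(0, 1]`
#' @return character vector of retained marker ids, in input order
#' @export
ld_prune <- function(ld, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  r2 <- ld$r2
  maf <- ld$maf[ld$markers]
  keep <- ld$markers
  repeat {
    m <- r2[keep, keep, drop = FALSE]
    m[lower.tri(m, diag = TRUE)] <- NA
    worst <- suppressWarnings(max(m, na.rm = TRUE))
    if (!is.finite(worst) || worst <= threshold) break
    cand <- which(m == worst, arr.ind = TRUE)
    # deterministic pair choice: order pairs by sorted member ids
    pair_ids <- t(apply(cand, 1, function(rc) sort(c(keep[rc[1]], keep[rc[2]]))))
    o <- order(pair_ids[, 1], pair_ids[, 2])[1]
    a <- pair_ids[o, 1]; b <- pair_ids[o, 2]
    drop_id <- if (maf[a] < maf[b]) a
               else if (maf[b] < maf[a]) b
               else max(a, b)
    keep <- setdiff(keep, drop_id)
  }
  keep
}

#' Intersect retained marker panels across pools
#'
#' @param retained_pool1,retained_pool2 marker id vectors
#' @return markers retained in both, in `retained_pool1` order; warns when
#'   empty
#' @export
intersect_panels <- function(retained_pool1, retained_pool2) {
  out <- retained_pool1[retained_pool1 %in% retained_pool2]
  if (!length(out)) warning("panel intersection is empty")
  out
}

#' Compare per-locus diversity between pools
#'
#' Two-sided paired Wilcoxon signed-rank test on the per-locus expected
#' heterozygosities of the two pools (identical vectors give p = 1).
#'
#' @param stats1,stats2 [per_locus_stats()] tables over the same markers
#' @return two-sided p-value
#' @export
compare_pool_diversity <- function(stats1, stats2) {
  stopifnot(identical(stats1$marker, stats2$marker))
  ok <- !is.na(stats1$he) & !is.na(stats2$he)
  d <- stats1$he[ok] - stats2$he[ok]
  if (all(d == 0)) return(1)
  suppressWarnings(wilcox.test(stats1$he[ok], stats2$he[ok],
                               paired = TRUE)$p.value)
}
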