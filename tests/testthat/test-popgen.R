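test_that("per-locus statistics count alleles and heterozygotes correctly", {
  gm <- make_gm(rbind("AA", "AB", "BB"))
  st <- per_locus_stats(gm, "pool1")
  expect_equal(st$p1, 0.5)
  expect_equal(st$ho, 1 / 3)
  expect_equal(st$he, 0.5)
  expect_equal(st$maf, 0.5)
  mono <- per_locus_stats(make_gm(rbind("AA", "AA")), "pool1")
  expect_equal(mono$maf, 0)
  expect_equal(mono$he, 0)
  # X marker: 1 male (hemizygous A) + 1 female AB -> p_A = 2/3
  gx <- make_gm(rbind("AA", "AB"), sex = c("male", "female"), is_x = TRUE)
  stx <- per_locus_stats(gx, "pool1")
  expect_equal(stx$p1, 2 / 3)
  expect_equal(stx$ho, 1) # females only
})

test_that("Weir-Cockerham components reproduce hand-evaluated cases", {
  # fixed difference, n = 20 per pool: a = 0.5, b = c = 0, theta = 1
  calls <- rbind(matrix("AA", 20, 1), matrix("BB", 20, 1))
  gm <- make_gm(calls, pool = rep(c("pool1", "pool2"), each = 20))
  f <- wc_fst(gm)
  expect_equal(f$per_locus$a, 0.5)
  expect_equal(f$per_locus$b, 0)
  expect_equal(f$per_locus$c, 0)
  expect_equal(f$per_locus$theta, 1)
  expect_equal(f$theta_weighted, 1)
  # identical genotype counts in both pools -> near-zero weighted theta
  set.seed(31)
  pf <- make_pf(runif(300, 0.2, 0.8))
  g1 <- simulate_population(pf, "pool1", 50)
  g2 <- g1; g2$samples$pool <- "pool2"
  g2$samples$id <- paste0("b_", g2$samples$id)
  gm2 <- genotype_matrix(rbind(g1$a1, g2$a1), rbind(g1$a2, g2$a2),
                         rbind(g1$samples, g2$samples), g1$markers)
  expect_lt(abs(wc_fst(gm2)$theta_weighted), 0.02)
  # loci monomorphic in both pools are skipped
  gm3 <- make_gm(cbind(rep("AA", 10), rep(c("AA", "AB"), 5)),
                 pool = rep(c("pool1", "pool2"), each = 5))
  expect_equal(wc_fst(gm3)$n_loci_used, 1)
})

test_that("F_IS uses the ratio-of-sums over polymorphic loci", {
  st <- data.frame(marker = c("a", "b"), ho = c(0.5, 0.3), he = c(0.5, 0.3))
  expect_equal(fis(st), 0)
  # all heterozygotes at one p = 0.5 locus: 1 - 1/0.5 = -1
  gm <- make_gm(rbind("AB", "AB"))
  expect_equal(fis(per_locus_stats(gm, "pool1")), -1)
  # HWE-simulated pool is close to zero
  set.seed(32)
  pf <- make_pf(runif(400, 0.2, 0.8))
  g <- simulate_population(pf, "pool1", 500)
  expect_lt(abs(fis(per_locus_stats(g, "pool1"))), 0.05)
  expect_error(fis(data.frame(ho = 0, he = 0)), "polymorphic")
})

test_that("the HWE z-test matches its closed form and the chi-square identity", {
  r <- hwe_z_test(25, 50, 25)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)
  r2 <- hwe_z_test(30, 40, 30)
  expect_equal(r2$fhat, 0.2)
  expect_equal(r2$z, 2)
  expect_equal(r2$p, 2 * pnorm(-2))
  # z^2 equals the 1-df HWE chi-square on random tables
  set.seed(33)
  for (i in 1:25) {
    n <- sample(50:500, 1)
    p <- runif(1, 0.1, 0.9)
    cnt <- as.vector(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    if (cnt[1] + cnt[2] == 0 || cnt[3] + cnt[2] == 0) next
    ph <- (2 * cnt[1] + cnt[2]) / (2 * n)
    exp_cnt <- n * c(ph^2, 2 * ph * (1 - ph), (1 - ph)^2)
    chi2 <- sum((cnt - exp_cnt)^2 / exp_cnt)
    z <- hwe_z_test(cnt[1], cnt[2], cnt[3])$z
    expect_equal(z^2, chi2, tolerance = 1e-9)
  }
})

test_that("z-test p-values are uniform under Hardy-Weinberg sampling", {
  set.seed(34)
  nloci <- 1000; n <- 500
  pvals <- vapply(seq_len(nloci), function(i) {
    p <- runif(1, 0.2, 0.8)
    cnt <- as.vector(rmultinom(1, n, c(p^2, 2 * p * (1 - p), (1 - p)^2)))
    hwe_z_test(cnt[1], cnt[2], cnt[3])$p
  }, 0)
  # occasional tied p-values from identical counts: KS still applies
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the X-linked exact test reduces to Levene and handles males", {
  # no males, females (1 AA, 0 AB, 1 BB): P(h=0) = 1/3
  r <- hwe_x_exact_test(c(1, 0, 1), c(0, 0))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_x_exact_test(c(0, 2, 0), c(0, 0))$p, 1, tolerance = 1e-12)
  # outcome probabilities sum to one over the conditional sample space
  probs <- function(fc, mc) {
    nf <- sum(fc); nm <- sum(mc)
    nA <- 2 * fc[1] + fc[2] + mc[1]
    tot <- 0
    for (mA in 0:nm) for (h in 0:nf) {
      nAA <- (nA - mA - h) / 2
      if (nAA < 0 || nAA != round(nAA) || nf - nAA - h < 0) next
      tot <- tot + exp(lchoose(nm, mA) + lgamma(nf + 1) - lgamma(nAA + 1) -
                       lgamma(h + 1) - lgamma(nf - nAA - h + 1) +
                       h * log(2) + lgamma(nA + 1) +
                       lgamma(2 * nf + nm - nA + 1) - lgamma(2 * nf + nm + 1))
    }
    tot
  }
  expect_equal(probs(c(3, 4, 2), c(3, 2)), 1, tolerance = 1e-12)
  # males at the female allele frequency do not make a balanced female
  # configuration more significant than the females-only test
  p_f <- hwe_x_exact_test(c(2, 4, 2), c(0, 0))$p
  p_fm <- hwe_x_exact_test(c(2, 4, 2), c(4, 4))$p
  expect_gte(p_fm, p_f - 1e-12)
  expect_error(hwe_x_exact_test(c(0, 0, 0), c(3, 2)), "no females")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("hwe_test runs both marker families with BH within each", {
  set.seed(35)
  cfg <- simulation_config(n_markers = 60, n_x_markers = 10,
                           divergence_F = 0.1)
  pf <- simulate_pool_frequencies(cfg)
  gm <- simulate_population(pf, "pool1", 80)
  ht <- hwe_test(gm, "pool1")
  expect_true(all(ht$p >= 0 & ht$p <= 1))
  expect_true(all(ht$q >= ht$p - 1e-12))
  expect_equal(ht$q[!ht$is_x], bh_adjust(ht$p[!ht$is_x]))
  expect_true(any(ht$is_x))
})

test_that("LD r2 is the squared dosage correlation over complete pairs", {
  set.seed(36)
  pf <- make_pf(runif(40, 0.3, 0.7))
  gm <- simulate_population(pf, "pool1", 200)
  # duplicated marker -> r2 = 1
  gm$a1[, 2] <- gm$a1[, 1]; gm$a2[, 2] <- gm$a2[, 1]
  ld <- ld_r2_matrix(gm, "pool1")
  expect_equal(ld$r2["snp0001", "snp0002"], 1)
  expect_true(isSymmetric(ld$r2))
  expect_true(all(diag(ld$r2) == 1))
  # independent loci: mean off-diagonal r2 ~ 1/(n-1)
  off <- ld$r2[upper.tri(ld$r2)]
  off <- off[ld$r2[upper.tri(ld$r2)] < 0.9] # drop the planted duplicate
  expect_lt(abs(mean(off) - 1 / 199), 0.002)
  # constant-dosage (monomorphic) markers are skipped
  gmono <- make_gm(cbind(rep("AA", 4), rep(c("AB", "BB"), 2)))
  ld2 <- ld_r2_matrix(gmono, "pool1")
  expect_equal(ld2$markers, "m02")
})

test_that("greedy pruning removes the lower-MAF member and is order-invariant", {
  # construct dosages with a planted correlated pair
  set.seed(37)
  n <- 60
  base <- rbinom(n, 2, 0.5)
  noisy <- base; flip <- sample(n, 6)
  noisy[flip] <- sample(0:2, 6, TRUE)
  rare <- rbinom(n, 2, 0.15) # lower MAF, correlated with nothing
  calls <- function(d) c("AA", "AB", "BB")[d + 1]
  cm <- cbind(hi = calls(base), lo = calls(pmin(noisy + rare, 2)), c = calls(noisy))
  # simpler deterministic construction: duplicate a marker, vary MAF
  d1 <- rbinom(n, 2, 0.5)
  d2 <- d1 # r2 = 1 with d1
  d3 <- rbinom(n, 2, 0.25)
  cm <- cbind(m_a = calls(d1), m_b = calls(d2), m_c = calls(d3))
  gm <- make_gm(cm)
  ld <- ld_r2_matrix(gm, "pool1")
  kept <- ld_prune(ld, 0.5)
  expect_length(kept, 2)
  expect_true("m_c" %in% kept)
  # equal MAF tie: the lexicographically later id of the pair is removed
  expect_setequal(kept, c("m_a", "m_c"))
  # chain A-B, B-C correlated, A-C not: removing B suffices
  b <- rbinom(200, 2, 0.5)
  a <- b; a[1:40] <- rbinom(40, 2, 0.5)
  c3 <- b; c3[161:200] <- rbinom(40, 2, 0.5)
  gm2 <- make_gm(cbind(A = calls(a), B = calls(b), C = calls(c3)))
  ld2 <- ld_r2_matrix(gm2, "pool1")
  if (ld2$r2["A", "B"] > 0.5 && ld2$r2["B", "C"] > 0.5 &&
      ld2$r2["A", "C"] < 0.5) {
    kept2 <- ld_prune(ld2, 0.5)
    expect_setequal(kept2, c("A", "C"))
  }
  # permutation invariance
  perm <- c(3, 1, 2)
  gm3 <- gm_subset(gm2, markers = perm)
  kept3 <- ld_prune(ld_r2_matrix(gm3, "pool1"), 0.5)
  expect_setequal(kept3, ld_prune(ld2, 0.5))
  # all pairs below threshold -> identity
  expect_setequal(ld_prune(ld2, 1), c("A", "B", "C"))
})

test_that("panel intersection preserves order and warns when empty", {
  expect_equal(intersect_panels(c("A", "B", "C"), c("B", "C", "D")),
               c("B", "C"))
  expect_warning(out <- intersect_panels(c("A"), c("B")), "empty")
  expect_length(out, 0)
})

test_that("pool diversity comparison is a paired Wilcoxon signed-rank test", {
  st <- function(he) data.frame(marker = sprintf("m%02d", seq_along(he)),
                                he = he)
  expect_equal(compare_pool_diversity(st(rep(0.4, 10)), st(rep(0.4, 10))), 1)
  set.seed(38)
  he1 <- runif(50, 0.1, 0.4)
  expect_lt(compare_pool_diversity(st(he1), st(he1 + 0.1)), 1e-8)
  # antisymmetric differences -> large p
  d <- rep(c(-0.05, 0.05), 25)
  expect_gt(compare_pool_diversity(st(he1), st(he1 + d)), 0.5)
})
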