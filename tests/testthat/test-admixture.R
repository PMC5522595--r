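test_that("the hybrid class table encodes the cross algebra", {
  tab <- hybrid_class_table()
  expect_equal(tab$class, c("P1", "P2", "F1", "F2", "Bc1", "Bc2",
                            "2Bc1", "2Bc2"))
  phi <- as.matrix(tab[, -1])
  expect_equal(unname(rowSums(phi)), rep(1, 8))
  expect_equal(unname(phi[tab$class == "F2", ]), c(0.25, 0.5, 0.25))
  expect_equal(unname(phi[tab$class == "2Bc1", ]), c(0.75, 0.25, 0))
  expect_equal(unname(phi[tab$class == "Bc2", ]), c(0, 0.5, 0.5))
})

test_that("hybrid simulation follows the gene-origin mixture", {
  # diagnostic locus: F1 individuals are always heterozygous
  pf <- make_pf(p1 = rep(1, 10), p2 = rep(0, 10))
  set.seed(61)
  f1 <- simulate_hybrids(pf, "F1", 30)
  expect_true(all(f1$a1 == 1L & f1$a2 == 2L))
  # P1 genotypes are Hardy-Weinberg at pool1 frequencies (chi-square GOF)
  pf2 <- make_pf(p1 = 0.35, p2 = 0.9)
  set.seed(62)
  p1g <- simulate_hybrids(pf2, "P1", 10000)
  cnt <- table(factor(p1g$a1 + p1g$a2, levels = c(2, 3, 4)))
  expected <- 10000 * c(0.35^2, 2 * 0.35 * 0.65, 0.65^2)
  chi2 <- sum((cnt - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 2))
  # seed reproducibility
  set.seed(63); a <- simulate_hybrids(pf2, "Bc1", 20)
  set.seed(63); b <- simulate_hybrids(pf2, "Bc1", 20)
  expect_identical(a, b)
  expect_error(simulate_hybrids(pf2, "F3", 5), "unknown hybrid class")
  # marginal genotype frequencies match the phi-mixture closed form
  set.seed(64)
  pfm <- make_pf(p1 = 0.8, p2 = 0.2)
  bc1 <- simulate_hybrids(pfm, "Bc1", 10000)
  g <- bc1$a1 + bc1$a2 - 2L # allele-2 dosage (0, 1, 2) of allele B
  het_theory <- 0.5 * (2 * 0.8 * 0.2) + 0.5 * (0.8 * 0.8 + 0.2 * 0.2)
  expect_lt(abs(mean(g == 1L) - het_theory), 4 * sqrt(0.25 / 10000) + 0.01)
})

test_that("Gibbs posteriors with known frequencies match hand Bayes", {
  # 10 diagnostic loci, uniform class prior.
  # All-heterozygous individual: P(data|F1)=1, P(|F2)=P(|Bc1)=P(|Bc2)=0.5^10,
  # P(|2Bc1)=P(|2Bc2)=0.25^10, P(|P1)=P(|P2)=0.
  pf <- make_pf(p1 = rep(1, 10), p2 = rep(0, 10))
  n <- 6
  a1 <- matrix(1L, n, 10); a2 <- matrix(2L, n, 10)
  a1[2, ] <- 1L; a2[2, ] <- 1L # all hom pool1 allele
  samples <- data.frame(id = sprintf("i%d", 1:n), sex = "unknown",
                        pool = "unknown", replicate_group = NA)
  gm <- genotype_matrix(a1, a2, samples, {
    mk <- data.frame(id = pf$marker, chrom = "1", pos = pf$pos, is_x = FALSE)
    mk$alleles <- rep(list(c("A", "B")), 10); mk
  })
  set.seed(65)
  res <- gibbs_classify(gm, iterations = 4000, burn_in = 500,
                        known_frequencies = pf)
  post_f1 <- 1 / (1 + 3 * 0.5^10 + 2 * 0.25^10)
  expect_equal(res$posterior[1, "F1"], post_f1, tolerance = 0.005)
  expect_gt(res$posterior[1, "F1"], 0.99)
  expect_equal(unname(res$classes[which.max(res$posterior[2, ])]), "P1")
  # uninformative loci: posteriors stay at the uniform prior
  pfu <- make_pf(p1 = rep(0.5, 10), p2 = rep(0.5, 10))
  set.seed(66)
  g2 <- simulate_hybrids(pfu, "F1", 8)
  res2 <- gibbs_classify(g2, iterations = 4000, burn_in = 500,
                         known_frequencies = pfu)
  expect_lt(max(abs(res2$posterior - 1 / 8)), 0.08)
})

test_that("assignment applies the strict 60% rule", {
  fake <- structure(list(
    posterior = rbind(c(0.61, rep(0.39 / 7, 7)),
                      c(0.60, rep(0.40 / 7, 7)),
                      rep(0.125, 8)),
    classes = hybrid_class_table()$class), class = "classification_result")
  rownames(fake$posterior) <- c("a", "b", "c")
  asg <- assign_categories(fake, 0.60)
  expect_equal(asg$assigned, c("P1", "AMBIGUOUS", "AMBIGUOUS"))
})

test_that("confusion matrices tabulate counts, rates and ambiguity", {
  lev <- hybrid_class_table()$class
  cm <- confusion_matrix(lev, lev)
  expect_equal(unname(diag(cm$counts[, lev])), rep(1L, 8))
  expect_equal(unname(rowSums(cm$rates)), rep(1, 8))
  cm2 <- confusion_matrix(rep("F1", 4), rep("AMBIGUOUS", 4))
  expect_equal(unname(cm2$counts["F1", "AMBIGUOUS"]), 4L)
  expect_error(confusion_matrix("F9", "P1"), "unknown true class")
  expect_error(confusion_matrix(c("P1", "P2"), "P1"), "length")
})

test_that("classification recovers classes on a differentiated panel", {
  # study-shaped pools; panel = the 48 most differentiated of 300 loci,
  # mirroring the FST-ranked panel construction
  set.seed(67)
  cfg <- simulation_config(n_markers = 300, n_x_markers = 0)
  pf <- simulate_pool_frequencies(cfg)
  panel <- pf$marker[order(-abs(pf$p1 - pf$p2))][1:48]
  ev <- suppressWarnings(
    evaluate_panel_admixture(pf, panel, n_per_class = 15,
                             iterations = 3000, burn_in = 500))
  rates <- ev$confusion$rates
  # pure classes and F1 classify well; labels are correctly anchored
  expect_gt(rates["P1", "P1"], 0.8)
  expect_gt(rates["P2", "P2"], 0.8)
  expect_gt(rates["F1", "F1"], 0.8)
  expect_equal(unname(rowSums(ev$confusion$counts)), rep(15L, 8))
  # backcross classes are the hardest: their correct rate never exceeds
  # the pure/F1 average
  easy <- mean(diag(rates[c("P1", "P2", "F1"), c("P1", "P2", "F1")]))
  hard <- mean(diag(rates[c("Bc1", "Bc2", "2Bc1", "2Bc2"),
                          c("Bc1", "Bc2", "2Bc1", "2Bc2")]))
  expect_lte(hard, easy + 0.05)
})
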