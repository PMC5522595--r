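test_that("pool frequency simulation honours divergence and the seed", {
  cfg0 <- simulation_config(n_markers = 50, n_x_markers = 5, divergence_F = 0)
  set.seed(5); pf0 <- simulate_pool_frequencies(cfg0)
  expect_equal(pf0$p1, pf0$p_anc)
  expect_equal(pf0$p2, pf0$p_anc)
  expect_true(all(pf0$p_anc >= 0.4 & pf0$p_anc <= 0.6))
  expect_error(simulation_config(divergence_F = 1), "divergence_F")
  cfg <- simulation_config(n_markers = 50, n_x_markers = 5)
  set.seed(9); a <- simulate_pool_frequencies(cfg)
  set.seed(9); b <- simulate_pool_frequencies(cfg)
  expect_identical(a, b) # bitwise under a fixed seed
})

test_that("population sampling is Hardy-Weinberg with hemizygous male X", {
  pf <- make_pf(p1 = c(1, 0.5), is_x = c(FALSE, FALSE))
  set.seed(2)
  gm <- simulate_population(pf, "pool1", n = 10000)
  expect_true(all(gm$a1[, 1] == 1L & gm$a2[, 1] == 1L)) # p = 1: all hom
  het <- mean(gm$a1[, 2] != gm$a2[, 2])
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 4 * se)
  # male X calls homozygous-coded
  pfx <- make_pf(p1 = rep(0.5, 4), is_x = TRUE)
  set.seed(3)
  gx <- simulate_population(pfx, "pool1", n = 200, sex_ratio = 1)
  expect_true(all(gx$a1 == gx$a2))
  expect_error(simulate_population(pf, "pool1", n = 0), "positive")
})

test_that("gamete dropping respects Mendel and X transmission", {
  # sire AA x dam AA -> child always AA
  pf <- make_pf(p1 = rep(1, 3))
  ped <- pedigree(data.frame(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
                             dam = c(NA, NA, "D"),
                             sex = c("male", "female", "male")))
  set.seed(4)
  gm <- simulate_pedigree_genotypes(pf, ped)
  expect_true(all(gm$a1 == 1L & gm$a2 == 1L))
  # error-free gamete-dropped data have zero Mendelian inconsistencies
  cfg <- simulation_config(n_markers = 120, n_x_markers = 10,
                           n_founders = 12, n_dyads = 10, n_triads = 15)
  set.seed(5)
  pf2 <- simulate_pool_frequencies(cfg)
  ped2 <- make_study_pedigree(cfg)
  gm2 <- simulate_pedigree_genotypes(pf2, ped2)
  mr <- mendel_check(gm2, ped2)
  expect_equal(sum(mr$per_marker$n_inconsistent[!gm2$markers$is_x]), 0)
  # a recorded but ungenotyped parent is an error
  ped3 <- pedigree(data.frame(id = "K", sire = "GHOST", dam = NA,
                              sex = "male"))
  expect_error(simulate_pedigree_genotypes(pf, ped3), "missing parent")
})

test_that("sons never inherit the sire's X allele", {
  pfx <- make_pf(p1 = 0.5, is_x = TRUE)
  n <- 1000
  ped <- pedigree(data.frame(
    id = c("S", "D", sprintf("C%03d", seq_len(n))),
    sire = c(NA, NA, rep("S", n)),
    dam = c(NA, NA, rep("D", n)),
    sex = c("male", "female", rep("male", n))))
  set.seed(6)
  gm <- simulate_pedigree_genotypes(pfx, ped)
  dam <- c(gm$a1["D", 1], gm$a2["D", 1])
  sons <- grep("^C", gm$samples$id)
  expect_true(all(gm$a1[sons, 1] %in% dam)) # every son call is a dam allele
  expect_true(all(gm$a1[sons, 1] == gm$a2[sons, 1])) # hemizygote-coded
  # with a heterozygous dam, both dam alleles appear (transmission random)
  if (dam[1] != dam[2]) expect_equal(sort(unique(gm$a1[sons, 1])), c(1L, 2L))
})

test_that("degradation injects error, missingness and replicates as configured", {
  set.seed(7)
  pf <- make_pf(runif(30, 0.2, 0.8))
  gm <- simulate_population(pf, "pool1", 20)
  clean <- degrade_dataset(gm, e = 0, m = 0, n_replicates = 2)
  expect_equal(n_samples(clean), 22)
  expect_identical(clean$a1[1:20, ], gm$a1) # identity apart from replicates
  expect_identical(clean$a1[21, ], gm$a1[1, ])
  expect_equal(clean$samples$replicate_group[21], gm$samples$id[1])
  expect_equal(clean$samples$replicate_group[1], gm$samples$id[1])
  allmiss <- degrade_dataset(gm, e = 0, m = 1)
  expect_true(all(is.na(allmiss$a1)))
  expect_error(degrade_dataset(gm, e = -0.1, m = 0), "rates")
})

test_that("replicate discordance matches the collision-corrected expectation", {
  # P(discordant) per valid comparison = (2e - e^2) * (1 - sum_g P(g)^2)
  set.seed(8)
  e <- 0.01
  p <- runif(100, 0.2, 0.8)
  pf <- make_pf(p)
  gm <- simulate_population(pf, "pool1", 500)
  deg <- degrade_dataset(gm, e = e, m = 0, n_replicates = 500, freq = p)
  rc <- replicate_concordance(deg)
  hwe2 <- function(q) ((1 - q)^2)^2 + (2 * q * (1 - q))^2 + (q^2)^2
  d_expect <- (2 * e - e^2) * (1 - hwe2(p)) # per marker
  mu <- sum(500 * d_expect) # 500 pairs per marker
  sdev <- sqrt(sum(500 * d_expect * (1 - d_expect)))
  expect_equal(rc$n_valid, 500 * 100)
  expect_lt(abs(rc$n_discordant - mu), 4 * sdev)
})
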