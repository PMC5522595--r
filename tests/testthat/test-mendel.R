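test_that("dyad and triad checks agree with gamete enumeration for 2-4 alleles", {
  for (k in 2:4) {
    gs <- oracle_gspace(k)
    ng <- nrow(gs)
    geno_str <- apply(gs, 1, function(g)
      paste0(c("A", "B", "C", "D")[g], collapse = ""))
    # triads: every (sire, dam, child) configuration
    for (si in seq_len(ng)) for (di in seq_len(ng)) {
      calls <- cbind(c(geno_str[si], geno_str[di], geno_str))
      rownames(calls) <- c("S", "D", sprintf("C%02d", seq_len(ng)))
      gm <- make_gm(calls, sex = c("male", "female", rep("male", ng)))
      ped <- pedigree(data.frame(
        id = rownames(calls),
        sire = c(NA, NA, rep("S", ng)), dam = c(NA, NA, rep("D", ng)),
        sex = gm$samples$sex))
      mr <- mendel_check(gm, ped)
      expected <- !vapply(seq_len(ng), function(ci)
        oracle_mendel_consistent(gs[ci, ], sire = gs[si, ], dam = gs[di, ]),
        TRUE)
      expect_equal(unname(mr$flags[, 1]), expected,
                   info = sprintf("k=%d sire=%s dam=%s", k,
                                  geno_str[si], geno_str[di]))
    }
    # dyads: every (parent, child) configuration
    for (pi in seq_len(ng)) {
      calls <- cbind(c(geno_str[pi], geno_str))
      rownames(calls) <- c("P", sprintf("C%02d", seq_len(ng)))
      gm <- make_gm(calls, sex = c("female", rep("male", ng)))
      ped <- pedigree(data.frame(
        id = rownames(calls), sire = NA_character_,
        dam = c(NA, rep("P", ng)), sex = gm$samples$sex))
      mr <- mendel_check(gm, ped)
      expected <- !vapply(seq_len(ng), function(ci)
        oracle_mendel_consistent(gs[ci, ], dam = gs[pi, ]), TRUE)
      expect_equal(unname(mr$flags[, 1]), expected)
    }
  }
})

test_that("missing calls never count as inconsistent", {
  calls <- rbind(S = "AA", D = "--", C1 = "BB", C2 = "--")
  gm <- make_gm(calls, sex = c("male", "female", "male", "male"))
  ped <- pedigree(data.frame(id = c("S", "D", "C1", "C2"),
                             sire = c(NA, NA, "S", "S"),
                             dam = c(NA, NA, "D", "D"),
                             sex = gm$samples$sex))
  mr <- mendel_check(gm, ped)
  # C1 vs sire AA with dam untyped -> dyad check, AA vs BB inconsistent;
  # C2 has no call -> nothing to flag
  fam <- setNames(mr$per_family$n_inconsistent, mr$per_family$offspring)
  expect_equal(fam[["C1"]], 1)
  expect_equal(fam[["C2"]], 0)
  expect_equal(mr$per_marker$n_inconsistent, 1)
  # the inconsistency is a sire-son one
  expect_equal(mr$per_marker$n_sire_son, 1)
})

test_that("triad-only inconsistencies are not attributed to sire-son pairs", {
  # sire AB, dam AA, child BB: child shares B with sire but the dam cannot
  # have transmitted B -> triad inconsistent, not a sire-son mismatch
  calls <- rbind(S = "AB", D = "AA", C = "BB")
  gm <- make_gm(calls, sex = c("male", "female", "male"))
  ped <- pedigree(data.frame(id = c("S", "D", "C"), sire = c(NA, NA, "S"),
                             dam = c(NA, NA, "D"), sex = gm$samples$sex))
  mr <- mendel_check(gm, ped)
  expect_equal(mr$per_marker$n_inconsistent, 1)
  expect_equal(mr$per_marker$n_sire_son, 0)
})

test_that("X-linked markers are flagged from sire-son patterns, autosomal are not", {
  set.seed(21)
  cfg <- simulation_config(n_markers = 150, n_x_markers = 12,
                           divergence_F = 0.1, n_founders = 30,
                           n_dyads = 40, n_triads = 60)
  pf <- simulate_pool_frequencies(cfg)
  ped <- make_study_pedigree(cfg)
  gm <- simulate_pedigree_genotypes(pf, ped)
  mr <- mendel_check(gm, ped)
  flagged <- flag_x_linked(mr, gm)
  expect_setequal(flagged, gm$markers$id[gm$markers$is_x])
  # an autosomal marker with a couple of injected errors stays unflagged
  gm2 <- gm
  auto1 <- which(!gm2$markers$is_x)[1]
  sons <- which(gm2$samples$sex == "male" & grepl("^tri", gm2$samples$id))
  gm2$a1[sons[1:2], auto1] <- 3L - gm2$a1[sons[1:2], auto1]
  gm2$a2[sons[1:2], auto1] <- gm2$a1[sons[1:2], auto1]
  mr2 <- mendel_check(gm2, ped)
  expect_false(gm2$markers$id[auto1] %in% flag_x_linked(mr2, gm2))
})

test_that("inconsistency counts grow monotonically with the error rate", {
  set.seed(22)
  cfg <- simulation_config(n_markers = 200, n_x_markers = 0,
                           divergence_F = 0.1, n_founders = 20,
                           n_dyads = 20, n_triads = 40)
  pf <- simulate_pool_frequencies(cfg)
  ped <- make_study_pedigree(cfg)
  gm <- simulate_pedigree_genotypes(pf, ped)
  totals <- vapply(c(0, 0.005, 0.02), function(e) {
    deg <- degrade_dataset(gm, e = e, m = 0, freq = pf$p1)
    sum(mendel_check(deg, ped)$per_marker$n_inconsistent)
  }, 0)
  expect_equal(totals[1], 0)
  expect_true(all(diff(totals) > 0))
})

test_that("sex-association Fisher tests match the hypergeometric by hand", {
  # males 10 A alleles / 0 B vs females 0 A / 10 B: p = 2 / choose(20, 10)
  calls <- rbind(matrix("AA", 5, 1), matrix("BB", 5, 1))
  gm <- make_gm(calls, sex = rep(c("male", "female"), each = 5))
  res <- sex_association_tests(gm, "pool1")
  expect_equal(res$p_allele, 2 / choose(20, 10), tolerance = 1e-12)
  # identical counts in both sexes -> p = 1
  calls2 <- cbind(rep(c("AA", "AB", "BB"), 2))
  gm2 <- make_gm(calls2, sex = rep(c("male", "female"), each = 3))
  res2 <- sex_association_tests(gm2, "pool1")
  expect_equal(res2$p_allele, 1)
  expect_equal(res2$p_genotype, 1)
  # q-values are the BH adjustment of the same p-vector
  set.seed(23)
  pf <- make_pf(runif(20, 0.3, 0.7))
  g3 <- simulate_population(pf, "pool1", 40)
  res3 <- sex_association_tests(g3, "pool1")
  expect_equal(res3$q_allele, bh_adjust(res3$p_allele))
  # monomorphic marker -> p = 1 by convention
  g4 <- make_gm(rbind("AA", "AA"), sex = c("male", "female"))
  expect_equal(sex_association_tests(g4, "pool1")$p_allele, 1)
})
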