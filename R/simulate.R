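#' Simulation configuration for the two-pool study design
#'
#' Bundles the parameters of the synthetic dataset generator, whose defaults
#' emulate the study design the package targets: ~1500 ascertained SNPs
#' (discovery minor-allele frequency at least 0.4), a minority of X-linked
#' markers, two genetic pools of contrasting diversity descended from a
#' common ancestral population, a pedigree of dyads and triads, replicated
#' samples, and low genotyping error and missingness.
#'
#' The two pools diverge from the ancestral allele frequency under a
#' Balding-Nichols model with pool-specific divergence `F`. Defaults
#' `c(0.524, 0.193)` give expected pool heterozygosities of about 0.235 and
#' 0.398 (`E[H_E] = E[2p(1-p)](1 - F)` with `p ~ U(0.4, 0.6)`, so
#' `E[2p(1-p)] = 0.4933`).
#'
#' @param n_markers total number of markers
#' @param n_x_markers how many of them are X-linked
#' @param divergence_F per-pool Balding-Nichols divergence on `[0,1)`;
#'   length 1 (shared) or 2 (pool1, pool2)
#' @param ancestral_maf_min ascertainment floor for the ancestral minor
#'   allele frequency
#' @param pool_n samples per pool, named or ordered `(pool1, pool2)`
#' @param n_founders,n_dyads,n_triads pedigree shape: unrelated founders
#'   from which single-parent (dyad) and two-parent (triad) offspring are
#'   generated
#' @param error_rate probability a call is replaced by a random
#'   Hardy-Weinberg draw
#' @param missing_rate probability a call is set missing
#' @param n_replicates number of samples duplicated as internal controls
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_markers = 1500,
                              n_x_markers = 21,
                              divergence_F = c(0.524, 0.193),
                              ancestral_maf_min = 0.4,
                              pool_n = c(pool1 = 91, pool2 = 165),
                              n_founders = 40,
                              n_dyads = 108,
                              n_triads = 77,
                              error_rate = 1e-5,
                              missing_rate = 0.02,
                              n_replicates = 20) {
  if (length(divergence_F) == 1) divergence_F <- rep(divergence_F, 2)
  stopifnot(length(divergence_F) == 2)
  if (any(divergence_F < 0) || any(divergence_F >= 1))
    stop("divergence_F must be in [0, 1)")
  if (ancestral_maf_min < 0 || ancestral_maf_min > 0.5)
    stop("ancestral_maf_min must be in [0, 0.5]")
  for (r in c(error_rate, missing_rate))
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  structure(list(n_markers = n_markers, n_x_markers = n_x_markers,
                 divergence_F = divergence_F,
                 ancestral_maf_min = ancestral_maf_min,
                 pool_n = pool_n, n_founders = n_founders,
                 n_dyads = n_dyads, n_triads = n_triads,
                 error_rate = error_rate, missing_rate = missing_rate,
                 n_replicates = n_replicates),
            class = "simulation_config")
}

#' Simulate per-pool allele frequencies (Balding-Nichols)
#'
#' For each marker an ancestral frequency `p` of the reference allele is
#' drawn uniformly on `[maf_min, 1 - maf_min]`; each pool's frequency is an
#' independent `Beta(p(1-F)/F, (1-p)(1-F)/F)` draw with that pool's
#' divergence `F` (mean `p`, variance `p(1-p)F`). `F = 0` returns the
#' ancestral frequency exactly. All draws are governed by the session RNG;
#' call `set.seed()` beforehand for reproducibility.
#'
#' @param config a [simulation_config()]
#' @return a `pool_frequencies` data.frame with columns `marker`, `chrom`,
#'   `pos`, `is_x`, `p_anc`, `p1`, `p2` (frequencies of allele "A")
#' @export
simulate_pool_frequencies <- function(config) {
  nm <- config$n_markers; nx <- config$n_x_markers
  stopifnot(nx <= nm)
  Fd <- config$divergence_F
  p_anc <- runif(nm, config$ancestral_maf_min, 1 - config$ancestral_maf_min)
  draw_pool <- function(Fk) {
    if (Fk == 0) return(p_anc)
    s <- (1 - Fk) / Fk
    rbeta(nm, p_anc * s, (1 - p_anc) * s)
  }
  p1 <- draw_pool(Fd[1]); p2 <- draw_pool(Fd[2])
  n_auto <- nm - nx
  chrom <- c(rep(as.character(1 + (seq_len(n_auto) - 1) %% 18), length.out = n_auto),
             rep("X", nx))
  # markers spaced > 0.6 Mb apart on each chromosome, as in the ascertainment
  pos <- integer(nm)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- 700000L * seq_along(i)
  }
  structure(data.frame(marker = sprintf("snp%04d", seq_len(nm)),
                       chrom = chrom, pos = pos, is_x = chrom == "X",
                       p_anc = p_anc, p1 = p1, p2 = p2,
                       stringsAsFactors = FALSE),
            class = c("pool_frequencies", "data.frame"))
}

pf_markers <- function(pf) {
  mk <- data.frame(id = pf$marker, chrom = pf$chrom, pos = pf$pos,
                   is_x = pf$is_x, stringsAsFactors = FALSE)
  mk$alleles <- rep(list(c("A", "B")), nrow(pf))
  mk
}

pf_freq <- function(pf, pool) {
  switch(pool, pool1 = pf$p1, pool2 = pf$p2,
         stop("unknown pool: ", pool))
}

# one HWE genotype row per frequency vector p (freq of allele 1);
# returns list(a1, a2) integer vectors with 1 = "A", 2 = "B"
draw_hwe_calls <- function(p) {
  c1 <- ifelse(runif(length(p)) < p, 1L, 2L)
  c2 <- ifelse(runif(length(p)) < p, 1L, 2L)
  list(a1 = pmin(c1, c2), a2 = pmax(c1, c2))
}

#' Simulate an unrelated population sample from pool frequencies
#'
#' Autosomal genotypes are Hardy-Weinberg draws from the pool's allele
#' frequencies. At X-linked markers females receive two draws and males a
#' single draw stored as a homozygous pair (hemizygote convention).
#'
#' @param pf a [simulate_pool_frequencies()] table
#' @param pool `"pool1"` or `"pool2"`
#' @param n number of individuals
#' @param sex_ratio probability an individual is male
#' @param id_prefix prefix for generated sample ids
#' @return a [genotype_matrix()]
#' @export
simulate_population <- function(pf, pool, n, sex_ratio = 0.5,
                                id_prefix = pool) {
  if (n <= 0) stop("n must be positive")
  p <- pf_freq(pf, pool)
  nm <- nrow(pf)
  sex <- ifelse(runif(n) < sex_ratio, "male", "female")
  a1 <- matrix(NA_integer_, n, nm); a2 <- a1
  xi <- which(pf$is_x)
  for (i in seq_len(n)) {
    g <- draw_hwe_calls(p)
    if (sex[i] == "male" && length(xi)) {
      hemi <- ifelse(runif(length(xi)) < p[xi], 1L, 2L)
      g$a1[xi] <- hemi; g$a2[xi] <- hemi
    }
    a1[i, ] <- g$a1; a2[i, ] <- g$a2
  }
  samples <- data.frame(id = sprintf("%s_%03d", id_prefix, seq_len(n)),
                        sex = sex, pool = pool,
                        replicate_group = NA_character_,
                        stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, samples, pf_markers(pf))
}

#' Build the study-shaped pedigree
#'
#' Founders are unrelated pool members; each triad offspring has a sire and
#' a dam drawn from the founders, each dyad offspring has a single recorded
#' parent (alternating dam and sire; the other parent is an unsampled
#' population member). Offspring sexes alternate so both sexes are well
#' represented (X-linkage screening needs sons).
#'
#' @param config a [simulation_config()]
#' @param pool pool label the founders belong to
#' @return a [pedigree()] with a `pool` attribute
#' @export
make_study_pedigree <- function(config, pool = "pool1") {
  nf <- config$n_founders
  if (nf < 2) stop("need at least 2 founders")
  fid <- sprintf("fnd_%03d", seq_len(nf))
  fsex <- rep(c("male", "female"), length.out = nf)
  sires <- fid[fsex == "male"]; dams <- fid[fsex == "female"]
  rec <- data.frame(id = fid, sire = NA_character_, dam = NA_character_,
                    sex = fsex, stringsAsFactors = FALSE)
  nt <- config$n_triads
  if (nt > 0) {
    rec <- rbind(rec, data.frame(
      id = sprintf("tri_%03d", seq_len(nt)),
      sire = sires[1 + (seq_len(nt) - 1) %% length(sires)],
      dam = dams[1 + (seq_len(nt) - 1) %% length(dams)],
      sex = rep(c("male", "female"), length.out = nt)))
  }
  nd <- config$n_dyads
  if (nd > 0) {
    # the recorded parent alternates between dam and sire
    dam_known <- seq_len(nd) %% 2 == 1
    rec <- rbind(rec, data.frame(
      id = sprintf("dya_%03d", seq_len(nd)),
      sire = ifelse(dam_known, NA_character_,
                    sires[1 + (seq_len(nd) - 1) %% length(sires)]),
      dam = ifelse(dam_known, dams[1 + (seq_len(nd) - 1) %% length(dams)],
                   NA_character_),
      sex = rep(c("male", "female"), length.out = nd)))
  }
  out <- pedigree(rec)
  attr(out, "pool") <- pool
  out
}

#' Gamete-drop genotypes down a pedigree
#'
#' Founders are drawn as in [simulate_population()]. Each non-founder
#' receives one uniformly chosen allele from each parent per autosomal
#' marker; an unrecorded (unknown) parent contributes a random allele from
#' the pool frequencies. At X-linked markers sons receive one dam allele
#' only (stored homozygous-coded) and daughters receive the sire's single X
#' allele plus one dam allele. A recorded parent that has no genotype is an
#' error.
#'
#' @param pf a [simulate_pool_frequencies()] table
#' @param ped a [pedigree()]; its `pool` attribute (default `"pool1"`)
#'   fixes the founder pool
#' @return a [genotype_matrix()] in pedigree order
#' @export
simulate_pedigree_genotypes <- function(pf, ped) {
  pool <- attr(ped, "pool")
  if (is.null(pool)) pool <- "pool1"
  p <- pf_freq(pf, pool)
  nm <- nrow(pf); n <- nrow(ped)
  xi <- pf$is_x
  a1 <- matrix(NA_integer_, n, nm); a2 <- a1
  rownames(a1) <- rownames(a2) <- ped$id
  pick <- function(h1, h2) ifelse(runif(nm) < 0.5, h1, h2)
  pop_allele <- function() ifelse(runif(nm) < p, 1L, 2L)
  for (i in seq_len(n)) {
    sire <- ped$sire[i]; dam <- ped$dam[i]
    if (is.na(sire) && is.na(dam)) { # founder
      g <- draw_hwe_calls(p)
      if (ped$sex[i] == "male" && any(xi)) {
        hemi <- ifelse(runif(sum(xi)) < p[xi], 1L, 2L)
        g$a1[xi] <- hemi; g$a2[xi] <- hemi
      }
      a1[i, ] <- g$a1; a2[i, ] <- g$a2
      next
    }
    gam <- function(par) {
      if (is.na(par)) return(pop_allele())
      if (!par %in% rownames(a1) || anyNA(a1[par, ]))
        stop("missing parent genotype for ", par)
      pick(a1[par, ], a2[par, ])
    }
    from_sire <- gam(sire); from_dam <- gam(dam)
    h1 <- from_sire; h2 <- from_dam
    if (any(xi)) {
      if (ped$sex[i] == "male") {
        h1[xi] <- h2[xi] # sons: dam allele only, hemizygote-coded
      } else if (!is.na(sire)) {
        h1[xi] <- a1[sire, xi] # sire transmits his single X allele
      }
    }
    a1[i, ] <- pmin(h1, h2); a2[i, ] <- pmax(h1, h2)
  }
  samples <- data.frame(id = ped$id, sex = ped$sex, pool = pool,
                        replicate_group = NA_character_,
                        stringsAsFactors = FALSE)
  genotype_matrix(a1, a2, samples, pf_markers(pf))
}

#' Inject genotyping error, missingness and replicate samples
#'
#' Each call is independently replaced, with probability `e`, by a fresh
#' draw from the marker's Hardy-Weinberg genotype distribution (which may
#' coincide with the true call), then set missing with probability `m`.
#' Before degradation, `n_replicates` samples are duplicated; original and
#' duplicate receive independent error/missingness draws and share a
#' `replicate_group`. Error draws for hemizygous male X calls replace the
#' single allele, preserving the homozygous coding.
#'
#' @param gm a [genotype_matrix()] of true genotypes
#' @param e error rate in `[0,1]`
#' @param m missing rate in `[0,1]`
#' @param n_replicates number of samples to duplicate (first
#'   `n_replicates` samples)
#' @param freq optional per-marker frequency of allele 1 used for the error
#'   model; defaults to the frequencies observed in `gm`
#' @return a degraded [genotype_matrix()]
#' @export
degrade_dataset <- function(gm, e, m, n_replicates = 0, freq = NULL) {
  for (r in c(e, m)) if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  if (n_replicates > n_samples(gm)) stop("more replicates than samples")
  if (n_replicates > 0) {
    ri <- seq_len(n_replicates)
    rep_ids <- gm$samples$id[ri]
    dup <- gm$samples[ri, , drop = FALSE]
    dup$id <- paste0(rep_ids, "_rep")
    dup$replicate_group <- rep_ids
    samples <- gm$samples
    samples$replicate_group[ri] <- rep_ids
    samples <- rbind(samples, dup)
    a1 <- rbind(gm$a1, gm$a1[ri, , drop = FALSE])
    a2 <- rbind(gm$a2, gm$a2[ri, , drop = FALSE])
    gm <- genotype_matrix(a1, a2, samples, gm$markers)
  }
  n <- n_samples(gm); nm <- n_markers(gm)
  if (is.null(freq)) {
    freq <- colMeans(dosage(gm), na.rm = TRUE) / 2
    freq[is.nan(freq)] <- 0.5
  }
  a1 <- gm$a1; a2 <- gm$a2
  if (e > 0) {
    err <- matrix(runif(n * nm) < e, n, nm) & !is.na(a1)
    if (any(err)) {
      idx <- which(err, arr.ind = TRUE)
      pm <- freq[idx[, 2]]
      hemi <- gm$markers$is_x[idx[, 2]] &
        gm$samples$sex[idx[, 1]] == "male"
      d1 <- ifelse(runif(nrow(idx)) < pm, 1L, 2L)
      d2 <- ifelse(hemi, d1, ifelse(runif(nrow(idx)) < pm, 1L, 2L))
      a1[idx] <- pmin(d1, d2); a2[idx] <- pmax(d1, d2)
    }
  }
  if (m > 0) {
    miss <- matrix(runif(n * nm) < m, n, nm)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  }
  genotype_matrix(a1, a2, gm$samples, gm$markers)
}

#' Generate a complete synthetic study dataset
#'
#' Convenience wrapper producing everything a full pipeline run needs: pool
#' frequencies, two unrelated pool samples, a pedigreed cohort gamete-dropped
#' from pool1 frequencies, replicates, and injected error/missingness. The
#' pedigree cohort is appended to the pool samples (founders and offspring
#' are labelled with their pool).
#'
#' @param config a [simulation_config()]
#' @param seed integer seed fixing every draw
#' @return list with elements `truth` (clean [genotype_matrix()]),
#'   `genotypes` (degraded matrix with replicates), `pedigree`, `pool_freq`
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  pf <- simulate_pool_frequencies(config)
  g1 <- simulate_population(pf, "pool1", config$pool_n[[1]])
  g2 <- simulate_population(pf, "pool2", config$pool_n[[2]])
  ped <- make_study_pedigree(config, pool = "pool1")
  gped <- simulate_pedigree_genotypes(pf, ped)
  truth <- genotype_matrix(rbind(g1$a1, g2$a1, gped$a1),
                           rbind(g1$a2, g2$a2, gped$a2),
                           rbind(g1$samples, g2$samples, gped$samples),
                           pf_markers(pf))
  degraded <- degrade_dataset(truth, config$error_rate, config$missing_rate,
                              config$n_replicates,
                              freq = (pf$p1 + pf$p2) / 2)
  list(truth = truth, genotypes = degraded, pedigree = ped, pool_freq = pf)
}
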