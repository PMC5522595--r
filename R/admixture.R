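#' The eight hybrid ancestry classes
#'
#' Each class is defined by `phi = (phi11, phi12, phi22)`: the probabilities
#' that an individual's two gene copies at a locus derive from
#' (pool1, pool1), (one from each pool), (pool2, pool2). The table follows
#' from cross composition: pure classes P1/P2, first filial F1, second
#' filial F2 = F1 x F1, first backcrosses Bc1 = F1 x P1 and Bc2 = F1 x P2,
#' and second backcrosses 2Bc1 = Bc1 x P1 and 2Bc2 = Bc2 x P2.
#'
#' @return data.frame with columns `class`, `phi11`, `phi12`, `phi22`
#' @export
hybrid_class_table <- function() {
  data.frame(
    class = c("P1", "P2", "F1", "F2", "Bc1", "Bc2", "2Bc1", "2Bc2"),
    phi11 = c(1, 0, 0, 0.25, 0.5, 0, 0.75, 0),
    phi12 = c(0, 0, 1, 0.5, 0.5, 0.5, 0.25, 0.25),
    phi22 = c(0, 1, 0, 0.25, 0, 0.5, 0, 0.75),
    stringsAsFactors = FALSE)
}

#' Simulate genotypes of one hybrid ancestry class
#'
#' Per individual and locus, the gene-origin pair is drawn from the class's
#' `phi` and each allele is then drawn from its origin pool's allele
#' frequency; loci are independent (frequency-based hybrid simulation, no
#' linkage). All simulated individuals are diploid at every locus and of
#' unknown sex; panels are expected to be autosomal.
#'
#' @param pf a [simulate_pool_frequencies()] table (possibly subset to a
#'   panel)
#' @param class class name from [hybrid_class_table()]
#' @param n individuals to simulate
#' @param id_prefix prefix for sample ids
#' @return a [genotype_matrix()] with pool label `"admixed"` (`"pool1"` /
#'   `"pool2"` for the pure classes)
#' @export
simulate_hybrids <- function(pf, class, n, id_prefix = class) {
  if (n <= 0) stop("n must be positive")
  tab <- hybrid_class_table()
  row <- tab[tab$class == class, ]
  if (nrow(row) != 1) stop("unknown hybrid class: ", class)
  phi <- c(row$phi11, row$phi12, row$phi22)
  nm <- nrow(pf)
  a1 <- matrix(NA_integer_, n, nm); a2 <- a1
  for (i in seq_len(n)) {
    w <- sample.int(3, nm, replace = TRUE, prob = phi)
    pa <- ifelse(w == 3, pf$p2, pf$p1)      # first copy origin
    pb <- ifelse(w == 1, pf$p1, pf$p2)      # second copy origin
    c1 <- ifelse(runif(nm) < pa, 1L, 2L)
    c2 <- ifelse(runif(nm) < pb, 1L, 2L)
    a1[i, ] <- pmin(c1, c2); a2[i, ] <- pmax(c1, c2)
  }
  pool <- switch(class, P1 = "pool1", P2 = "pool2", "admixed")
  samples <- data.frame(id = sprintf("%s_%03d", id_prefix, seq_len(n)),
                        sex = "unknown", pool = pool,
                        replicate_group = NA_character_,
                        stringsAsFactors = FALSE)
  mk <- pf_markers(pf)
  mk$is_x <- FALSE # hybrid simulation is diploid throughout
  genotype_matrix(a1, a2, samples, mk)
}

#' Bayesian classification into hybrid ancestry classes
#'
#' Gibbs sampler over each individual's latent class (uniform prior over
#' the classes), the per-locus latent gene-origin pairs given the class
#' `phi`, and the two pools' per-locus allele frequencies under Jeffreys
#' `Beta(1/2, 1/2)` priors. The per-locus genotype likelihood given the
#' origin pair is the product of origin-pool allele probabilities; missing
#' genotypes contribute nothing. Posterior class probabilities are the
#' post-burn-in occupancies of the latent class.
#'
#' By default allele frequencies are estimated jointly from the sample; the
#' pool labelling of such a run is arbitrary (the model is symmetric under
#' swapping pools and mirroring classes), so either supply
#' `known_frequencies` or `anchor` frequencies used only to orient the
#' labels of the result. If the posterior class probabilities of the two
#' half-chains differ by more than 0.1 for any individual, a non-mixing
#' warning is recorded (and signalled).
#'
#' @param gm a [genotype_matrix()] of biallelic loci
#' @param iterations total Gibbs iterations
#' @param burn_in iterations discarded
#' @param known_frequencies optional [simulate_pool_frequencies()] table (or
#'   data.frame with `marker`, `p1`, `p2`): fixes the pool allele
#'   frequencies instead of estimating them
#' @param anchor optional frequency table of the same form used only to
#'   resolve the pool-label symmetry of a joint-estimation run
#' @return a `classification_result` list: `posterior` (individuals x
#'   classes), `classes`, `iterations`, `burn_in`, `mixing_ok`,
#'   `max_half_chain_diff`
#' @export
gibbs_classify <- function(gm, iterations = 11000, burn_in = 1000,
                           known_frequencies = NULL, anchor = NULL) {
  if (n_samples(gm) < 2) stop("need at least 2 individuals")
  if (any(vapply(gm$markers$alleles, length, 0L) != 2))
    stop("classifier requires biallelic loci")
  if (burn_in >= iterations) stop("burn_in must be smaller than iterations")
  tab <- hybrid_class_table()
  phi <- as.matrix(tab[, c("phi11", "phi12", "phi22")])
  geno <- dosage(gm)            # counts of allele 1
  geno[is.na(geno)] <- -1L
  storage.mode(geno) <- "integer"
  update_freq <- is.null(known_frequencies)
  if (!update_freq) {
    fq <- known_frequencies[match(gm$markers$id, known_frequencies$marker), ]
    if (anyNA(fq$p1)) stop("known_frequencies must cover every marker")
    p1 <- fq$p1; p2 <- fq$p2
  } else {
    p1 <- rep(0.5, n_markers(gm)); p2 <- p1
  }
  fit <- gibbs_core(geno, phi, p1, p2, update_freq,
                    as.integer(iterations), as.integer(burn_in))
  post <- fit$posterior
  theta1 <- fit$theta1_mean; theta2 <- fit$theta2_mean
  half1 <- fit$half1; half2 <- fit$half2
  if (update_freq && !is.null(anchor)) {
    aq <- anchor[match(gm$markers$id, anchor$marker), ]
    straight <- sum((theta1 - aq$p1)^2 + (theta2 - aq$p2)^2)
    swapped <- sum((theta1 - aq$p2)^2 + (theta2 - aq$p1)^2)
    if (swapped < straight) {
      perm <- match(c("P2", "P1", "F1", "F2", "Bc2", "Bc1", "2Bc2", "2Bc1"),
                    tab$class)
      post <- post[, perm, drop = FALSE]
      half1 <- half1[, perm, drop = FALSE]
      half2 <- half2[, perm, drop = FALSE]
      tmp <- theta1; theta1 <- theta2; theta2 <- tmp
    }
  }
  colnames(post) <- colnames(half1) <- colnames(half2) <- tab$class
  rownames(post) <- gm$samples$id
  maxdiff <- max(abs(half1 - half2))
  if (maxdiff > 0.1)
    warning(sprintf("possible non-mixing: half-chain posteriors differ by %.2f",
                    maxdiff))
  structure(list(posterior = post, classes = tab$class,
                 iterations = iterations, burn_in = burn_in,
                 theta1 = theta1, theta2 = theta2,
                 mixing_ok = maxdiff <= 0.1,
                 max_half_chain_diff = maxdiff),
            class = "classification_result")
}

#' Assign individuals to ancestry categories
#'
#' The highest-posterior class, provided its posterior strictly exceeds the
#' threshold; otherwise `"AMBIGUOUS"`.
#'
#' @param result a [gibbs_classify()] result
#' @param threshold posterior probability an assignment must exceed
#' @return data.frame `id`, `assigned`, `posterior`
#' @export
assign_categories <- function(result, threshold = 0.60) {
  post <- result$posterior
  best <- max.col(post, ties.method = "first")
  bestp <- post[cbind(seq_len(nrow(post)), best)]
  data.frame(id = rownames(post),
             assigned = ifelse(bestp > threshold,
                               result$classes[best], "AMBIGUOUS"),
             posterior = bestp, stringsAsFactors = FALSE)
}

#' Confusion matrix of true versus inferred ancestry
#'
#' @param true_classes character vector of simulated classes
#' @param assignments [assign_categories()] output (or a character vector
#'   of assigned classes incl. `"AMBIGUOUS"`)
#' @return a `confusion_matrix` list: `counts` (true x inferred incl. an
#'   AMBIGUOUS column), `rates` (row-normalized)
#' @export
confusion_matrix <- function(true_classes, assignments) {
  if (is.data.frame(assignments)) assignments <- assignments$assigned
  if (length(true_classes) != length(assignments))
    stop("true classes and assignments differ in length")
  lev <- hybrid_class_table()$class
  if (!all(true_classes %in% lev)) stop("unknown true class label")
  if (!all(assignments %in% c(lev, "AMBIGUOUS")))
    stop("unknown assigned class label")
  counts <- table(factor(true_classes, lev),
                  factor(assignments, c(lev, "AMBIGUOUS")))
  counts <- unclass(counts)
  rates <- counts / pmax(rowSums(counts), 1)
  structure(list(counts = counts, rates = rates), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rates):\n")
  print(round(x$rates, 3))
  invisible(x)
}

#' Simulate, classify and tabulate one panel's admixture power
#'
#' Simulates `n_per_class` individuals for each of the eight ancestry
#' classes on the given marker panel, classifies them jointly with
#' [gibbs_classify()] (frequencies estimated from the mixed sample,
#' labels anchored to the true pool frequencies), applies the assignment
#' threshold and returns the confusion matrix.
#'
#' @param pf a [simulate_pool_frequencies()] table
#' @param panel marker ids (subset of `pf$marker`)
#' @param n_per_class simulated individuals per class
#' @param iterations,burn_in Gibbs settings
#' @param threshold assignment threshold
#' @param known_frequencies if TRUE, classify with the true pool
#'   frequencies instead of estimating them
#' @return list with `confusion` ([confusion_matrix()]), `assignments`,
#'   `result` (the [gibbs_classify()] output)
#' @export
evaluate_panel_admixture <- function(pf, panel, n_per_class = 100,
                                     iterations = 11000, burn_in = 1000,
                                     threshold = 0.60,
                                     known_frequencies = FALSE) {
  if (!length(panel)) stop("panel is empty")
  if (!all(panel %in% pf$marker)) stop("panel contains unknown markers")
  sub <- pf[match(panel, pf$marker), , drop = FALSE]
  classes <- hybrid_class_table()$class
  sims <- lapply(classes, function(cl)
    simulate_hybrids(sub, cl, n_per_class, id_prefix = cl))
  gm <- genotype_matrix(do.call(rbind, lapply(sims, `[[`, "a1")),
                        do.call(rbind, lapply(sims, `[[`, "a2")),
                        do.call(rbind, lapply(sims, `[[`, "samples")),
                        sims[[1]]$markers)
  truth <- rep(classes, each = n_per_class)
  res <- gibbs_classify(gm, iterations = iterations, burn_in = burn_in,
                        known_frequencies = if (known_frequencies) sub else NULL,
                        anchor = if (!known_frequencies) sub else NULL)
  asg <- assign_categories(res, threshold)
  list(confusion = confusion_matrix(truth, asg),
       assignments = asg, result = res)
}
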