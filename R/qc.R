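#' Filter markers and samples by missingness
#'
#' Removes markers whose fraction of missing calls exceeds `threshold`
#' (strictly), then samples whose missingness over the retained markers
#' exceeds it. The marker-first order makes the filter idempotent.
#'
#' @param gm a [genotype_matrix()]
#' @param threshold maximum tolerated missingness, in `(0, 1]`
#' @return list with `genotypes` (filtered matrix), `marker_missingness` and
#'   `sample_missingness` (named vectors, pre-filter), `removed_markers`,
#'   `removed_samples`
#' @export
filter_missingness <- function(gm, threshold = 0.20) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  mm <- colMeans(is.na(gm$a1))
  names(mm) <- gm$markers$id
  keep_m <- mm <= threshold
  g2 <- gm_subset(gm, markers = keep_m)
  sm <- rowMeans(is.na(g2$a1))
  names(sm) <- g2$samples$id
  keep_s <- sm <= threshold
  out <- gm_subset(g2, samples = keep_s)
  if (n_markers(out) == 0 || n_samples(out) == 0)
    warning("matrix is empty after missingness filtering")
  list(genotypes = out,
       marker_missingness = mm,
       sample_missingness = sm,
       removed_markers = gm$markers$id[!keep_m],
       removed_samples = g2$samples$id[!keep_s])
}

#' Detect monomorphic markers
#'
#' Flags markers showing a single observed allele among non-missing calls,
#' either over the whole sample or within one pool. Markers with no
#' non-missing call at all are reported separately as monomorphic by
#' vacuity.
#'
#' @param gm a [genotype_matrix()]
#' @param within_pool optional pool label restricting the samples examined
#' @return list with character vectors `monomorphic` and `all_missing`
#' @export
detect_monomorphic <- function(gm, within_pool = NULL) {
  if (!is.null(within_pool)) gm <- gm_subset(gm, samples = pool_samples(gm, within_pool))
  n_distinct <- vapply(seq_len(n_markers(gm)), function(j) {
    length(unique(c(gm$a1[, j], gm$a2[, j])[!is.na(c(gm$a1[, j], gm$a2[, j]))]))
  }, 0L)
  list(monomorphic = gm$markers$id[n_distinct == 1L],
       all_missing = gm$markers$id[n_distinct == 0L])
}

#' Assay validation summary
#'
#' @param n_assayed markers attempted
#' @param n_failed markers that yielded no genotypes
#' @param n_monomorphic markers discarded as monomorphic
#' @return list with `n_assayed`, `n_failed`, `n_monomorphic`, `n_retained`
#'   and `validation_rate` (percent, one decimal)
#' @export
validation_summary <- function(n_assayed, n_failed, n_monomorphic) {
  if (any(c(n_assayed, n_failed, n_monomorphic) < 0))
    stop("counts must be non-negative")
  if (n_failed + n_monomorphic > n_assayed)
    stop("discarded markers exceed markers assayed")
  n_retained <- n_assayed - n_failed - n_monomorphic
  list(n_assayed = n_assayed, n_failed = n_failed,
       n_monomorphic = n_monomorphic, n_retained = n_retained,
       validation_rate = round(100 * n_retained / n_assayed, 1))
}

#' Replicate concordance and genotyping error rate
#'
#' Compares replicated samples (same `replicate_group`). A pair is first
#' identity-checked: if the fraction of identical non-missing genotype pairs
#' falls below `identity_threshold` the pair is flagged as a probable sample
#' mix-up and excluded from the error tally. Across confirmed pairs, the
#' error rate is the number of discordant genotypes over the number of valid
#' (both-called) comparisons; with zero discordances an upper bound of
#' 1/valid is reported to three significant figures. Triplicates contribute
#' all three pairs.
#'
#' @param gm a [genotype_matrix()] containing replicate groups
#' @param identity_threshold minimum concordance for a pair to count as the
#'   same individual
#' @return list with `n_pairs_compared`, `n_valid`, `n_discordant`,
#'   `error_rate`, `is_bound` (TRUE when the rate is the zero-discordance
#'   upper bound), `flagged_pairs` (data.frame of suspected mix-ups) and
#'   `pairs` (per-pair detail)
#' @export
replicate_concordance <- function(gm, identity_threshold = 0.95) {
  grp <- gm$samples$replicate_group
  groups <- split(seq_len(n_samples(gm))[!is.na(grp)], grp[!is.na(grp)])
  groups <- groups[lengths(groups) >= 2]
  if (!length(groups)) stop("no replicate groups of size >= 2")
  detail <- do.call(rbind, lapply(groups, function(idx) {
    prs <- utils::combn(idx, 2)
    do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      i <- prs[1, k]; j <- prs[2, k]
      ok <- !is.na(gm$a1[i, ]) & !is.na(gm$a1[j, ])
      same <- gm$a1[i, ] == gm$a1[j, ] & gm$a2[i, ] == gm$a2[j, ]
      data.frame(sample1 = gm$samples$id[i], sample2 = gm$samples$id[j],
                 n_valid = sum(ok), n_discordant = sum(ok & !same),
                 concordance = if (sum(ok)) mean(same[ok]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(detail) <- NULL
  confirmed <- !is.na(detail$concordance) &
    detail$concordance >= identity_threshold
  flagged <- detail[!confirmed, , drop = FALSE]
  valid <- sum(detail$n_valid[confirmed])
  disc <- sum(detail$n_discordant[confirmed])
  if (valid == 0) stop("no valid genotype comparisons among confirmed pairs")
  if (disc == 0) {
    rate <- signif(1 / valid, 3); bound <- TRUE
  } else {
    rate <- disc / valid; bound <- FALSE
  }
  list(n_pairs_compared = sum(confirmed), n_valid = valid,
       n_discordant = disc, error_rate = rate, is_bound = bound,
       flagged_pairs = flagged, pairs = detail)
}
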