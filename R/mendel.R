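#' Mendelian-inconsistency screening of dyads and triads
#'
#' For every pedigree record whose offspring is genotyped, checks each
#' marker for Mendelian consistency. A dyad (one typed parent) is
#' inconsistent when parent and offspring share no allele; a triad (both
#' parents typed) is inconsistent when no assignment of one allele from each
#' parent reproduces the offspring genotype. Missing calls never produce an
#' inconsistency (a triad with one missing parent call is checked as a
#' dyad). Pedigree members absent from the genotype matrix are skipped with
#' a message.
#'
#' For X-linkage screening, each inconsistency is additionally classified as
#' a sire-son inconsistency when the offspring is male and the sire-offspring
#' pair alone shares no allele.
#'
#' @param gm a [genotype_matrix()]
#' @param ped a [pedigree()]
#' @return a `mendel_report` list: `per_marker` data.frame (`marker`,
#'   `n_checked`, `n_inconsistent`, `n_sire_son`, `sire_son_fraction`),
#'   `per_family` data.frame (`offspring`, `kind`, `n_inconsistent`),
#'   `n_families_checked`, `flags` (logical families x markers matrix)
#' @export
mendel_check <- function(gm, ped) {
  ids <- gm$samples$id
  off <- ped[!(is.na(ped$sire) & is.na(ped$dam)), , drop = FALSE]
  typed <- off$id %in% ids &
    ((!is.na(off$sire) & off$sire %in% ids) |
     (!is.na(off$dam) & off$dam %in% ids))
  skipped <- off$id[!typed]
  if (length(skipped))
    message("skipping ", length(skipped),
            " pedigree record(s) without typed members")
  off <- off[typed, , drop = FALSE]
  nm <- n_markers(gm)
  nfam <- nrow(off)
  flags <- matrix(FALSE, nfam, nm,
                  dimnames = list(off$id, gm$markers$id))
  sire_son <- matrix(FALSE, nfam, nm,
                     dimnames = list(off$id, gm$markers$id))
  checked <- matrix(FALSE, nfam, nm)
  kind <- character(nfam)
  share <- function(ci, pi) { # per-marker: child and parent share an allele
    gm$a1[ci, ] == gm$a1[pi, ] | gm$a1[ci, ] == gm$a2[pi, ] |
    gm$a2[ci, ] == gm$a1[pi, ] | gm$a2[ci, ] == gm$a2[pi, ]
  }
  for (f in seq_len(nfam)) {
    ci <- match(off$id[f], ids)
    si <- if (!is.na(off$sire[f])) match(off$sire[f], ids) else NA_integer_
    di <- if (!is.na(off$dam[f])) match(off$dam[f], ids) else NA_integer_
    kind[f] <- if (!is.na(si) && !is.na(di)) "triad" else "dyad"
    cmiss <- is.na(gm$a1[ci, ])
    smiss <- if (is.na(si)) rep(TRUE, nm) else is.na(gm$a1[si, ])
    dmiss <- if (is.na(di)) rep(TRUE, nm) else is.na(gm$a1[di, ])
    sh_s <- if (!is.na(si)) share(ci, si) else rep(NA, nm)
    sh_d <- if (!is.na(di)) share(ci, di) else rep(NA, nm)
    # triad compatibility: exists one-allele-from-each-parent assignment
    tri_ok <- rep(NA, nm)
    both <- !cmiss & !smiss & !dmiss
    if (any(both)) {
      c1 <- gm$a1[ci, ]; c2 <- gm$a2[ci, ]
      s_has <- function(x) gm$a1[si, ] == x | gm$a2[si, ] == x
      d_has <- function(x) gm$a1[di, ] == x | gm$a2[di, ] == x
      tri_ok <- (s_has(c1) & d_has(c2)) | (s_has(c2) & d_has(c1))
    }
    bad <- rep(FALSE, nm)
    bad[both] <- !tri_ok[both]
    dy_s <- !cmiss & !smiss & dmiss
    bad[dy_s] <- !sh_s[dy_s]
    dy_d <- !cmiss & !dmiss & smiss
    bad[dy_d] <- !sh_d[dy_d]
    flags[f, ] <- bad
    checked[f, ] <- both | dy_s | dy_d
    if (off$sex[f] == "male" && !is.na(si)) {
      ss <- bad & !smiss & !cmiss & !sh_s
      sire_son[f, ] <- ss
    }
  }
  per_marker <- data.frame(
    marker = gm$markers$id,
    n_checked = colSums(checked),
    n_inconsistent = colSums(flags),
    n_sire_son = colSums(sire_son),
    stringsAsFactors = FALSE)
  per_marker$sire_son_fraction <-
    ifelse(per_marker$n_inconsistent > 0,
           per_marker$n_sire_son / per_marker$n_inconsistent, NA_real_)
  per_family <- data.frame(offspring = off$id, kind = kind,
                           n_inconsistent = rowSums(flags),
                           stringsAsFactors = FALSE)
  structure(list(per_marker = per_marker, per_family = per_family,
                 n_families_checked = nfam, flags = flags),
            class = "mendel_report")
}

#' Flag X-linked markers from sire-son incompatibility patterns
#'
#' A marker is flagged X-linked when it shows at least `min_mismatches`
#' Mendelian inconsistencies of which at least `sire_son_fraction` occur in
#' sire-male-offspring pairs — the segregation signature of a hemizygous
#' locus coded as a diploid genotype.
#'
#' @param report a [mendel_check()] report
#' @param gm the [genotype_matrix()] the report was computed from
#' @param min_mismatches minimum total inconsistencies
#' @param sire_son_fraction minimum fraction of them in sire-son pairs
#' @return character vector of flagged marker ids
#' @export
flag_x_linked <- function(report, gm, min_mismatches = 5,
                          sire_son_fraction = 0.9) {
  pm <- report$per_marker
  fams <- report$per_family
  sexed_sons <- any(gm$samples$sex[match(fams$offspring, gm$samples$id)] %in%
                    c("male", "female"))
  if (!sexed_sons) stop("no sexed offspring: X-linkage flagging undefined")
  hit <- pm$n_inconsistent >= min_mismatches &
    !is.na(pm$sire_son_fraction) &
    pm$sire_son_fraction >= sire_son_fraction
  pm$marker[hit]
}

#' Sex-association exact tests
#'
#' Per marker within one pool, two-sided Fisher exact tests on (i) the
#' allele-count x sex table and (ii) the genotype-count x sex table, with
#' Benjamini-Hochberg adjustment across markers for each table family.
#' Significant markers suggest sex linkage (or a sex-biased genotyping
#' artefact). Markers monomorphic in the pool get `p = 1` by convention.
#'
#' @param gm a [genotype_matrix()]
#' @param pool pool label to test within
#' @return data.frame with `marker`, `p_allele`, `p_genotype`, `q_allele`,
#'   `q_genotype`
#' @export
sex_association_tests <- function(gm, pool) {
  idx <- pool_samples(gm, pool)
  sex <- gm$samples$sex[idx]
  if (!all(c("male", "female") %in% sex))
    stop("both sexes must be present in pool ", pool)
  keep <- sex %in% c("male", "female")
  idx <- idx[keep]; sex <- sex[keep]
  res <- lapply(seq_len(n_markers(gm)), function(j) {
    a1 <- gm$a1[idx, j]; a2 <- gm$a2[idx, j]
    ok <- !is.na(a1)
    if (!any(ok)) return(c(1, 1))
    al <- sort(unique(c(a1[ok], a2[ok])))
    if (length(al) < 2) return(c(1, 1))
    at <- vapply(al, function(a) c(
      sum((a1[ok & sex == "male"] == a) + (a2[ok & sex == "male"] == a)),
      sum((a1[ok & sex == "female"] == a) + (a2[ok & sex == "female"] == a))),
      numeric(2))
    gcode <- paste(a1, a2)[ok]
    gt <- table(factor(sex[ok], c("male", "female")), gcode)
    c(fisher.test(at)$p.value, fisher.test(gt)$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(marker = gm$markers$id,
             p_allele = res[, 1], p_genotype = res[, 2],
             q_allele = bh_adjust(res[, 1]),
             q_genotype = bh_adjust(res[, 2]),
             stringsAsFactors = FALSE)
}
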