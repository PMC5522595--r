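#' @useDynLib panelkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom runif rbeta cor pnorm fisher.test wilcox.test
#'   p.adjust setNames complete.cases quantile
#' @importFrom utils read.table write.table head packageVersion
"_PACKAGE"

SEXES <- c("male", "female", "unknown")
POOLS <- c("pool1", "pool2", "admixed", "unknown")

#' Construct a genotype matrix
#'
#' The central container of the package: unphased diploid calls for a set of
#' samples at a set of markers. Calls are stored as two parallel integer
#' matrices of allele indices (1-based into each marker's allele vector),
#' normalized so that `a1 <= a2` within a call (genotypes are unordered).
#' Missing calls have `NA` in both matrices; partial calls are rejected.
#' Males at X-linked markers are hemizygous and stored by convention as
#' homozygous pairs of their single allele.
#'
#' @param a1,a2 integer matrices (samples x markers) of allele indices;
#'   `NA` = missing. `a1 > a2` entries are swapped on construction.
#' @param samples data.frame with columns `id`, `sex` (one of
#'   `"male"/"female"/"unknown"`), `pool` (one of
#'   `"pool1"/"pool2"/"admixed"/"unknown"`) and optionally `replicate_group`
#'   (NA for non-replicated samples).
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based bp),
#'   `is_x` (logical) and `alleles` (list column of character allele codes,
#'   length >= 2 each).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, samples, markers) {
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (is.null(samples$replicate_group)) samples$replicate_group <- NA_character_
  if (is.null(markers$is_x)) markers$is_x <- FALSE
  # normalize unordered calls
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  gm <- structure(list(a1 = a1, a2 = a2, samples = samples, markers = markers),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
}

validate_genotype_matrix <- function(gm) {
  a1 <- gm$a1; a2 <- gm$a2
  n <- nrow(gm$samples); m <- nrow(gm$markers)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices have different dimensions")
  if (nrow(a1) != n || ncol(a1) != m)
    stop(sprintf("call matrix is %d x %d but there are %d samples and %d markers",
                 nrow(a1), ncol(a1), n, m))
  if (anyDuplicated(gm$samples$id))
    stop("duplicate sample id: ",
         paste(unique(gm$samples$id[duplicated(gm$samples$id)]), collapse = ", "))
  if (anyDuplicated(gm$markers$id))
    stop("duplicate marker id: ",
         paste(unique(gm$markers$id[duplicated(gm$markers$id)]), collapse = ", "))
  if (!all(gm$samples$sex %in% SEXES)) stop("invalid sex code")
  if (!all(gm$samples$pool %in% POOLS)) stop("invalid pool label")
  if (any(is.na(a1) != is.na(a2)))
    stop("partial calls (one allele missing) are malformed")
  if (any(gm$markers$pos < 0, na.rm = TRUE)) stop("negative marker position")
  n_all <- vapply(gm$markers$alleles, length, 0L)
  if (any(n_all < 2L)) stop("markers must declare at least 2 alleles")
  if (any(vapply(gm$markers$alleles, anyDuplicated, 0L) > 0L))
    stop("duplicate allele codes within a marker")
  maxidx <- suppressWarnings(apply(a2, 2, max, na.rm = TRUE))
  bad <- which(is.finite(maxidx) & maxidx > n_all)
  if (length(bad))
    stop("allele index out of range at marker ", gm$markers$id[bad[1]])
  # hemizygote convention: male X calls homozygous-coded
  xm <- which(gm$markers$is_x)
  males <- which(gm$samples$sex == "male")
  if (length(xm) && length(males)) {
    h1 <- a1[males, xm, drop = FALSE]; h2 <- a2[males, xm, drop = FALSE]
    if (any(h1 != h2, na.rm = TRUE))
      stop("heterozygous male call at X-linked marker violates hemizygote convention")
  }
  dimnames(gm$a1) <- dimnames(gm$a2) <- list(gm$samples$id, gm$markers$id)
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d X-linked)\n",
              n_samples(x), n_markers(x), sum(x$markers$is_x)))
  cat(sprintf("  pools: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$pool)),
                            table(x$samples$pool)), collapse = " ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' @rdname genotype_matrix
#' @export
n_markers <- function(gm) nrow(gm$markers)

#' Subset a genotype matrix
#'
#' @param gm a `genotype_matrix`
#' @param samples sample ids or logical/integer index (default: keep all)
#' @param markers marker ids or logical/integer index (default: keep all)
#' @return the subsetted `genotype_matrix`
#' @export
gm_subset <- function(gm, samples = NULL, markers = NULL) {
  si <- seq_len(n_samples(gm)); mi <- seq_len(n_markers(gm))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples$id) else si[samples]
    if (anyNA(si)) stop("unknown sample id")
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, gm$markers$id) else mi[markers]
    if (anyNA(mi)) stop("unknown marker id")
  }
  structure(list(a1 = gm$a1[si, mi, drop = FALSE],
                 a2 = gm$a2[si, mi, drop = FALSE],
                 samples = gm$samples[si, , drop = FALSE],
                 markers = gm$markers[mi, , drop = FALSE]),
            class = "genotype_matrix")
}

#' Allele-1 dosage matrix
#'
#' Counts of the first declared allele per call (0, 1 or 2; `NA` when
#' missing). For biallelic markers this is the usual additive SNP dosage.
#' Male calls at X markers count their single allele twice under the
#' hemizygote storage convention; use [per_locus_stats()] for sex-aware
#' allele frequencies.
#'
#' @param gm a `genotype_matrix`
#' @return integer matrix samples x markers
#' @export
dosage <- function(gm) {
  (gm$a1 == 1L) + (gm$a2 == 1L)
}

pool_samples <- function(gm, pool) {
  if (!pool %in% gm$samples$pool)
    stop("pool '", pool, "' has no samples")
  which(gm$samples$pool == pool)
}

#' Mark markers as X-linked
#'
#' Sets the `is_x` flag; verifies that male calls at the newly flagged
#' markers obey the hemizygote (homozygous-coded) convention.
#'
#' @param gm a `genotype_matrix`
#' @param marker_ids markers to flag
#' @return the updated `genotype_matrix`
#' @export
set_x_linked <- function(gm, marker_ids) {
  mi <- match(marker_ids, gm$markers$id)
  if (anyNA(mi)) stop("unknown marker id")
  gm$markers$is_x[mi] <- TRUE
  validate_genotype_matrix(gm)
}

#' Construct a pedigree
#'
#' @param df data.frame with columns `id`, `sire`, `dam` (NA = unknown) and
#'   `sex`. Each individual appears at most once as a record subject; links
#'   must be acyclic and no individual may be its own ancestor.
#' @return a `pedigree` data.frame, rows sorted so that parents precede
#'   offspring (topological order).
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam", "sex")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  df$sire[df$sire %in% c("", "0")] <- NA
  df$dam[df$dam %in% c("", "0")] <- NA
  if (anyDuplicated(df$id)) stop("individual appears more than once in pedigree")
  if (any(df$id == df$sire | df$id == df$dam, na.rm = TRUE))
    stop("individual recorded as its own parent")
  if (!all(df$sex %in% SEXES)) stop("invalid sex code in pedigree")
  ord <- pedigree_toposort(df)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("pedigree", "data.frame"))
}

# Kahn topological sort over parent->offspring edges; errors on cycles,
# reporting the individuals involved.
pedigree_toposort <- function(df) {
  ids <- df$id
  parents <- cbind(match(df$sire, ids), match(df$dam, ids)) # NA = founder/external
  indeg <- rowSums(!is.na(parents))
  ord <- integer(0)
  ready <- which(indeg == 0)
  indeg[ready] <- -1L
  while (length(ready)) {
    ord <- c(ord, ready)
    done <- ids[ord]
    newly <- which(indeg >= 0 &
                   (is.na(parents[, 1]) | df$sire %in% done) &
                   (is.na(parents[, 2]) | df$dam %in% done))
    ready <- newly
    indeg[ready] <- -1L
  }
  if (length(ord) < length(ids)) {
    stop("pedigree contains a cycle involving: ",
         paste(setdiff(ids, ids[ord]), collapse = ", "))
  }
  ord
}
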