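# Independent brute-force oracles used to pin the analytical results.
# Everything here enumerates genotype configurations from first principles
# and never calls the package's closed-form implementations.

# all unordered genotypes for k alleles, rows (i, j) with i <= j
oracle_gspace <- function(k) {
  g <- NULL
  for (i in seq_len(k)) for (j in i:k) g <- rbind(g, c(i, j))
  g
}

oracle_hwe_prob <- function(g, p) {
  if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
}

# offspring genotype distribution (k x k upper matrix) given two parents
oracle_child_dist <- function(gm, gf, k) {
  d <- matrix(0, k, k)
  for (a in gm) for (b in gf) {
    i <- min(a, b); j <- max(a, b)
    d[i, j] <- d[i, j] + 0.25
  }
  d
}

# PID, PIDsibs, PE1, PE2, PE3 by exhaustive enumeration under HWE
oracle_identity_exclusion <- function(p) {
  k <- length(p)
  gs <- oracle_gspace(k)
  pg <- apply(gs, 1, oracle_hwe_prob, p = p)
  pid <- sum(pg^2)
  pids <- 0
  for (mi in seq_len(nrow(gs))) for (fi in seq_len(nrow(gs))) {
    cd <- oracle_child_dist(gs[mi, ], gs[fi, ], k)
    pids <- pids + pg[mi] * pg[fi] * sum(cd^2)
  }
  pe1 <- 0; pe2 <- 0
  for (mi in seq_len(nrow(gs))) for (ui in seq_len(nrow(gs))) {
    gm <- gs[mi, ]; gu <- gs[ui, ]
    for (ma in gm) for (fa in seq_len(k)) {
      ci <- sort(c(ma, fa))
      wt <- pg[mi] * 0.5 * p[fa] * oracle_hwe_prob(gu, p)
      # alleles the true father could have passed, given mother and child
      pat <- unique(c(if (ci[1] %in% gm) ci[2], if (ci[2] %in% gm) ci[1]))
      pe1 <- pe1 + wt * !any(gu %in% pat)
      pe2 <- pe2 + wt * !any(gu %in% ci)
    }
  }
  pe3 <- 0
  for (ci in seq_len(nrow(gs))) for (u1 in seq_len(nrow(gs))) for (u2 in seq_len(nrow(gs))) {
    cc <- gs[ci, ]; a <- gs[u1, ]; b <- gs[u2, ]
    compat <- any(outer(a, b, function(x, y)
      pmin(x, y) == cc[1] & pmax(x, y) == cc[2]))
    pe3 <- pe3 + pg[ci] * pg[u1] * pg[u2] * !compat
  }
  c(pid = pid, pid_sibs = pids, pe1 = pe1, pe2 = pe2, pe3 = pe3)
}

# Mendelian consistency by gamete enumeration. Genotypes are length-2
# integer vectors; NULL parent = untyped. Missing child -> consistent.
oracle_mendel_consistent <- function(child, sire = NULL, dam = NULL) {
  if (is.null(child)) return(TRUE)
  child <- sort(child)
  if (!is.null(sire) && !is.null(dam)) {
    for (a in sire) for (b in dam)
      if (identical(sort(c(a, b)), child)) return(TRUE)
    return(FALSE)
  }
  par <- if (!is.null(sire)) sire else dam
  if (is.null(par)) return(TRUE)
  any(par %in% child)
}

# random allele-frequency simplex bounded away from the boundary
oracle_random_simplex <- function(k) {
  x <- runif(k, 0.05, 1)
  x / sum(x)
}

# --- small fixture builders -------------------------------------------

# genotype matrix from a character matrix of calls like "AB", "AA", "--"
make_gm <- function(calls, sex = NULL, pool = "pool1", is_x = FALSE,
                    replicate_group = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  code <- function(ch) match(ch, c("A", "B", "C", "D"))
  a1 <- matrix(code(substr(calls, 1, 1)), n, m)
  a2 <- matrix(code(substr(calls, 2, 2)), n, m)
  if (is.null(sex)) sex <- rep("unknown", n)
  if (is.null(replicate_group)) replicate_group <- rep(NA_character_, n)
  samples <- data.frame(
    id = if (!is.null(rownames(calls))) rownames(calls)
         else sprintf("s%02d", seq_len(n)),
    sex = rep(sex, length.out = n),
    pool = rep(pool, length.out = n),
    replicate_group = replicate_group,
    stringsAsFactors = FALSE)
  mid <- if (!is.null(colnames(calls))) colnames(calls)
         else sprintf("m%02d", seq_len(m))
  k <- suppressWarnings(pmax(apply(rbind(a1, a2), 2, max, na.rm = TRUE), 2))
  k[!is.finite(k)] <- 2
  markers <- data.frame(id = mid, chrom = "1", pos = seq_len(m) * 1000L,
                        is_x = rep(is_x, length.out = m),
                        stringsAsFactors = FALSE)
  markers$alleles <- lapply(k, function(kk) c("A", "B", "C", "D")[seq_len(kk)])
  genotype_matrix(a1, a2, samples, markers)
}

# pool_frequencies table from explicit biallelic frequencies
make_pf <- function(p1, p2 = p1, is_x = FALSE) {
  nm <- length(p1)
  structure(data.frame(marker = sprintf("snp%04d", seq_len(nm)),
                       chrom = ifelse(rep(is_x, length.out = nm), "X", "1"),
                       pos = seq_len(nm) * 700000L,
                       is_x = rep(is_x, length.out = nm),
                       p_anc = (p1 + p2) / 2, p1 = p1, p2 = p2,
                       stringsAsFactors = FALSE),
            class = c("pool_frequencies", "data.frame"))
}

# Monte-Carlo PWR: simulate dyads under each relationship and apply the
# multi-locus log-likelihood-ratio test at the exact critical value
mc_pwr <- function(freqs, r1, r2, alpha, e = 1e-5, nrep = 2000) {
  if (is.numeric(freqs)) freqs <- lapply(freqs, function(q) c(q, 1 - q))
  draw_geno <- function(p) sort(sample.int(length(p), 2, TRUE, prob = p))
  draw_dyad <- function(p, k) {
    ibd <- sample.int(3, 1, prob = k) - 1L
    g1 <- draw_geno(p)
    g2 <- if (ibd == 2) g1
          else if (ibd == 1) sort(c(g1[sample.int(2, 1)],
                                    sample.int(length(p), 1, prob = p)))
          else draw_geno(p)
    list(g1 = g1, g2 = g2)
  }
  score <- function(k_true) {
    replicate(nrep, {
      s <- 0
      for (p in freqs) {
        d <- draw_dyad(p, k_true)
        s <- s + log(dyad_likelihood(d$g1, d$g2, p, r1, e) /
                     dyad_likelihood(d$g1, d$g2, p, r2, e))
      }
      s
    })
  }
  s2 <- score(r2)
  crit <- unname(quantile(s2, 1 - alpha, type = 1))
  s1 <- score(r1)
  list(pwr = mean(s1 > crit),
       pwr_at = function(crit_exact) mean(s1 > crit_exact),
       null_scores = s2, alt_scores = s1)
}
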