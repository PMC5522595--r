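#' Read genotypes from PED/MAP text files
#'
#' Reads the whitespace-separated PED/MAP text dialect (PLINK-style).
#' The MAP file has four columns (chromosome, marker id, genetic distance,
#' 1-based bp position); a chromosome of `"X"` marks a marker X-linked.
#' Each PED line has `6 + 2*M` fields: family id, sample id, father, mother,
#' sex (1 = male, 2 = female, other = unknown), phenotype, then two allele
#' codes per marker with `"0"` meaning missing. A call with exactly one
#' missing allele is rejected as malformed. The family-id column is used as
#' the pool label when it matches a known label (`pool1/pool2/admixed`),
#' otherwise the pool is `unknown`.
#'
#' @param ped_path,map_path input file paths
#' @param sample_info optional path to a TSV with columns `id`, `pool`,
#'   `replicate_group` overriding PED-derived sample metadata (PED cannot
#'   carry replicate groups).
#' @return a [genotype_matrix()]
#' @export
read_ped_map <- function(ped_path, map_path, sample_info = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- lapply(strsplit(map_lines, "[ \t]+"), function(f) f[nzchar(f)])
  nf <- lengths(map)
  if (length(map) && !all(nf == 4))
    stop("MAP parse error at line ", which(nf != 4)[1], ": expected 4 fields")
  chrom <- vapply(map, `[`, "", 1)
  mid <- vapply(map, `[`, "", 2)
  pos <- as.integer(vapply(map, `[`, "", 4))
  m <- length(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix(NA_integer_, n, m)
  a2 <- matrix(NA_integer_, n, m)
  allele_codes <- rep(list(character(0)), m)
  sid <- character(n); fid <- character(n); sex <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(ped_lines[i], "[ \t]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) != 6 + 2 * m)
      stop(sprintf("PED parse error at line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(f)))
    fid[i] <- f[1]; sid[i] <- f[2]
    sex[i] <- switch(f[5], "1" = "male", "2" = "female", "unknown")
    g <- matrix(f[-(1:6)], nrow = 2)
    miss1 <- g[1, ] == "0"; miss2 <- g[2, ] == "0"
    if (any(miss1 != miss2))
      stop(sprintf("partial call at PED line %d, marker %s",
                   i, mid[which(miss1 != miss2)[1]]))
    for (j in which(!miss1)) {
      for (al in c(g[1, j], g[2, j])) {
        if (!al %in% allele_codes[[j]])
          allele_codes[[j]] <- c(allele_codes[[j]], al)
      }
      a1[i, j] <- match(g[1, j], allele_codes[[j]])
      a2[i, j] <- match(g[2, j], allele_codes[[j]])
    }
  }
  if (anyDuplicated(sid))
    stop("duplicate sample id in PED: ", sid[duplicated(sid)][1])
  # every marker must declare >= 2 alleles even if fewer were observed
  allele_codes <- lapply(allele_codes, function(al) {
    if (length(al) >= 2) al else c(al, setdiff(c("A", "B"), al))[1:2]
  })
  pool <- ifelse(fid %in% POOLS, fid, "unknown")
  samples <- data.frame(id = sid, sex = sex, pool = pool,
                        replicate_group = NA_character_,
                        stringsAsFactors = FALSE)
  if (!is.null(sample_info)) {
    si <- read.table(sample_info, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
    idx <- match(samples$id, si$id)
    if (anyNA(idx)) stop("sample_info is missing ids present in PED")
    if (!is.null(si$pool)) samples$pool <- si$pool[idx]
    if (!is.null(si$replicate_group))
      samples$replicate_group <- si$replicate_group[idx]
  }
  markers <- data.frame(id = mid, chrom = chrom, pos = pos,
                        is_x = chrom %in% c("X", "x"),
                        stringsAsFactors = FALSE)
  markers$alleles <- allele_codes
  genotype_matrix(a1, a2, samples, markers)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_ped_map()]: missing calls are written as `"0 0"`, sex as
#' 1/2/0, the pool label as family id. If `sample_info` is given, a TSV with
#' `id`, `pool`, `replicate_group` is written alongside so that a round trip
#' preserves replicate structure.
#'
#' @param gm a [genotype_matrix()]
#' @param ped_path,map_path output paths
#' @param sample_info optional path for the sample metadata TSV
#' @return invisibly, the paths written
#' @export
write_ped_map <- function(gm, ped_path, map_path, sample_info = NULL) {
  mk <- gm$markers
  map <- sprintf("%s\t%s\t0\t%d",
                 ifelse(mk$is_x, "X", mk$chrom), mk$id, mk$pos)
  writeLines(map, map_path)
  sexcode <- c(male = "1", female = "2", unknown = "0")[gm$samples$sex]
  n <- n_samples(gm); m <- n_markers(gm)
  geno <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    al <- mk$alleles[[j]]
    c1 <- al[gm$a1[, j]]; c2 <- al[gm$a2[, j]]
    geno[, 2 * j - 1] <- ifelse(is.na(c1), "0", c1)
    geno[, 2 * j] <- ifelse(is.na(c2), "0", c2)
  }
  if (n == 0) {
    writeLines(character(0), ped_path)
  } else {
    lead <- cbind(gm$samples$pool, gm$samples$id, "0", "0", sexcode, "0")
    writeLines(apply(cbind(lead, geno), 1, paste, collapse = " "), ped_path)
  }
  if (!is.null(sample_info)) {
    write.table(gm$samples[, c("id", "pool", "replicate_group")],
                sample_info, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a pedigree from a TSV file
#'
#' Expects a header with columns `individual`, `sire`, `dam`, `sex`
#' (1 = male, 2 = female, otherwise unknown; blanks or `"0"` = unknown
#' parent). Cycles and self-parenting are rejected.
#'
#' @param tsv_path input path
#' @return a [pedigree()] in topological (parents-first) order
#' @export
read_pedigree <- function(tsv_path) {
  df <- read.table(tsv_path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("individual", "sire", "dam", "sex")
  if (!all(need %in% names(df)))
    stop("pedigree TSV needs columns: ", paste(need, collapse = ", "))
  sex <- as.character(df$sex)
  sex <- ifelse(sex %in% c("1", "male"), "male",
                ifelse(sex %in% c("2", "female"), "female", "unknown"))
  pedigree(data.frame(id = as.character(df$individual),
                      sire = as.character(df$sire),
                      dam = as.character(df$dam),
                      sex = sex, stringsAsFactors = FALSE))
}

#' Write a pedigree to a TSV file
#'
#' @param ped a [pedigree()]
#' @param tsv_path output path
#' @return invisibly, the path
#' @export
write_pedigree <- function(ped, tsv_path) {
  out <- data.frame(individual = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    sex = c(male = 1, female = 2, unknown = 0)[ped$sex])
  write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsv_path)
}
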