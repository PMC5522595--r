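#' Run configuration for the full panel-design workflow
#'
#' @param out_dir run directory (created if absent)
#' @param seed master seed; per-stage substreams are derived from it so each
#'   stage is independently reproducible
#' @param sim a [simulation_config()] (or a list of its arguments) for the
#'   synthetic input; alternatively supply `ped_path`/`map_path`/
#'   `pedigree_path` to run on existing files
#' @param missingness_threshold marker/sample missingness ceiling
#' @param r2_threshold LD pruning ceiling
#' @param hwe_alpha BH-adjusted significance level for HWE exclusion
#' @param assignment_threshold posterior threshold for ancestry assignment
#' @param panel_sizes nested panel sizes
#' @param hybrid_n_per_class simulated individuals per ancestry class
#' @param gibbs_iterations,gibbs_burn_in classifier run length
#' @param stages character vector of stages to run, a prefix-closed subset
#'   of `c("simulate", "qc", "mendel", "popgen", "prune", "rank", "power",
#'   "hybrids")`
#' @return a `run_config` list
#' @export
run_config <- function(out_dir, seed = 1, sim = simulation_config(),
                       ped_path = NULL, map_path = NULL, pedigree_path = NULL,
                       missingness_threshold = 0.20, r2_threshold = 0.5,
                       hwe_alpha = 0.05, assignment_threshold = 0.60,
                       panel_sizes = c(343, 192, 96, 48, 24, 12),
                       hybrid_n_per_class = 100,
                       gibbs_iterations = 11000, gibbs_burn_in = 1000,
                       stages = c("simulate", "qc", "mendel", "popgen",
                                  "prune", "rank", "power", "hybrids")) {
  if (is.list(sim) && !inherits(sim, "simulation_config"))
    sim <- do.call(simulation_config, sim)
  all_stages <- c("simulate", "qc", "mendel", "popgen", "prune", "rank",
                  "power", "hybrids")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage: ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, seed = seed, sim = sim,
                 ped_path = ped_path, map_path = map_path,
                 pedigree_path = pedigree_path,
                 missingness_threshold = missingness_threshold,
                 r2_threshold = r2_threshold, hwe_alpha = hwe_alpha,
                 assignment_threshold = assignment_threshold,
                 panel_sizes = panel_sizes,
                 hybrid_n_per_class = hybrid_n_per_class,
                 gibbs_iterations = gibbs_iterations,
                 gibbs_burn_in = gibbs_burn_in,
                 stages = match.arg(stages, all_stages, several.ok = TRUE)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; a `sim` mapping holds
#' [simulation_config()] arguments.
#'
#' @param path YAML file
#' @param out_dir overrides the configured run directory if given
#' @return a `run_config`
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

tsv_out <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full panel-design pipeline
#'
#' Executes the configured stages in order — synthetic data generation (or
#' file input), missingness/monomorphism QC with replicate concordance,
#' Mendelian screening with X-linkage flagging, per-pool statistics and
#' differentiation, HWE filtering, LD pruning and cross-pool intersection,
#' informativeness ranking with nested panels, relationship-inference
#' power, and hybrid-ancestry simulation + classification — writing each
#' stage's tables as TSV into the run directory together with a JSON
#' manifest (package version, seeds, parameters, input hashes). Identical
#' config and seed give byte-identical outputs.
#'
#' @param config a [run_config()]
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage_seed <- setNames(sample.int(.Machine$integer.max %/% 2, 8),
                         c("simulate", "qc", "mendel", "popgen", "prune",
                           "rank", "power", "hybrids"))
  stages <- config$stages
  manifest <- list(package_version = as.character(packageVersion("panelkit")),
                   seed = config$seed, stage_seeds = as.list(stage_seed),
                   parameters = config[setdiff(names(config),
                                               c("out_dir", "sim"))],
                   sim = unclass(config$sim),
                   outputs = list())
  out <- function(df, name) {
    manifest$outputs[[name]] <<- tsv_out(df, config$out_dir, name)
  }

  # -- inputs -----------------------------------------------------------
  pf <- NULL
  if ("simulate" %in% stages) {
    ds <- simulate_dataset(config$sim, seed = stage_seed[["simulate"]])
    gm <- ds$genotypes; ped <- ds$pedigree; pf <- ds$pool_freq
    write_ped_map(gm, file.path(config$out_dir, "genotypes.ped"),
                  file.path(config$out_dir, "genotypes.map"),
                  sample_info = file.path(config$out_dir, "samples.tsv"))
    write_pedigree(ped, file.path(config$out_dir, "pedigree.tsv"))
    out(pf, "true_pool_frequencies")
  } else {
    if (is.null(config$ped_path))
      stop("stage 'simulate' disabled but no input files configured")
    gm <- read_ped_map(config$ped_path, config$map_path)
    ped <- read_pedigree(config$pedigree_path)
    manifest$input_hashes <- as.list(tools::md5sum(
      c(config$ped_path, config$map_path, config$pedigree_path)))
  }

  # -- qc ----------------------------------------------------------------
  if ("qc" %in% stages) {
    set.seed(stage_seed[["qc"]])
    fm <- filter_missingness(gm, config$missingness_threshold)
    rep_rep <- if (any(!is.na(gm$samples$replicate_group)))
      replicate_concordance(fm$genotypes) else NULL
    mono <- detect_monomorphic(fm$genotypes)
    vs <- validation_summary(n_markers(gm),
                             length(fm$removed_markers),
                             length(mono$monomorphic))
    keep <- setdiff(fm$genotypes$markers$id,
                    c(mono$monomorphic, mono$all_missing))
    gm <- gm_subset(fm$genotypes, markers = keep)
    # replicates served their purpose; analyse one copy per individual
    gm <- gm_subset(gm, samples = !grepl("_rep$", gm$samples$id))
    qc_tab <- data.frame(metric = c("n_assayed", "n_failed_missingness",
                                    "n_monomorphic", "n_retained",
                                    "validation_rate"),
                         value = c(vs$n_assayed, vs$n_failed,
                                   vs$n_monomorphic, vs$n_retained,
                                   vs$validation_rate))
    if (!is.null(rep_rep)) {
      qc_tab <- rbind(qc_tab, data.frame(
        metric = c("replicate_pairs", "replicate_valid",
                   "replicate_discordant", "error_rate_or_bound"),
        value = c(rep_rep$n_pairs_compared, rep_rep$n_valid,
                  rep_rep$n_discordant, rep_rep$error_rate)))
    }
    out(qc_tab, "qc_report")
  }

  # -- mendel ------------------------------------------------------------
  if ("mendel" %in% stages) {
    set.seed(stage_seed[["mendel"]])
    mr <- mendel_check(gm, ped)
    xm <- flag_x_linked(mr, gm)
    if (length(xm)) gm <- set_x_linked(gm, xm)
    out(mr$per_marker, "mendel_per_marker")
    out(mr$per_family, "mendel_per_family")
    out(data.frame(marker = xm), "x_linked_markers")
  }

  # -- popgen ------------------------------------------------------------
  stats1 <- stats2 <- NULL
  if ("popgen" %in% stages) {
    set.seed(stage_seed[["popgen"]])
    stats1 <- per_locus_stats(gm, "pool1")
    stats2 <- per_locus_stats(gm, "pool2")
    fst <- wc_fst(gm, "pool1", "pool2")
    hwe1 <- hwe_test(gm, "pool1"); hwe2 <- hwe_test(gm, "pool2")
    wil_p <- compare_pool_diversity(stats1, stats2)
    out(cbind(stats1, pool = "pool1"), "stats_pool1")
    out(cbind(stats2, pool = "pool2"), "stats_pool2")
    out(fst$per_locus, "fst_per_locus")
    out(hwe1, "hwe_pool1"); out(hwe2, "hwe_pool2")
    out(data.frame(metric = c("theta_weighted", "fis_pool1", "fis_pool2",
                              "he_wilcoxon_p"),
                   value = c(fst$theta_weighted, fis(stats1), fis(stats2),
                             wil_p)),
        "differentiation_summary")
    fail <- union(hwe1$marker[hwe1$q < config$hwe_alpha],
                  hwe2$marker[hwe2$q < config$hwe_alpha])
    gm <- gm_subset(gm, markers = setdiff(gm$markers$id, fail))
  }

  # -- prune -------------------------------------------------------------
  panel <- NULL
  if ("prune" %in% stages) {
    set.seed(stage_seed[["prune"]])
    auto <- gm_subset(gm, markers = !gm$markers$is_x)
    # unrelated subsets: founders only in synthetic runs
    unrel <- function(pool) {
      ids <- auto$samples$id[auto$samples$pool == pool]
      fo <- ids[grepl("^(fnd|pool)", ids)]
      if (length(fo) >= 10) fo else ids
    }
    keep1 <- ld_prune(ld_r2_matrix(auto, "pool1", unrel("pool1")),
                      config$r2_threshold)
    keep2 <- ld_prune(ld_r2_matrix(auto, "pool2", unrel("pool2")),
                      config$r2_threshold)
    panel <- intersect_panels(
      intersect_panels(auto$markers$id, keep1), keep2)
    out(data.frame(marker = panel), "pruned_panel")
  } else {
    panel <- gm$markers$id[!gm$markers$is_x]
  }

  # -- rank --------------------------------------------------------------
  ranking <- NULL
  if ("rank" %in% stages) {
    set.seed(stage_seed[["rank"]])
    stats_all <- per_locus_stats(gm_subset(gm, markers = panel), "pool1")
    freqs <- lapply(stats_all$p1, function(q) c(q, 1 - q))
    tab <- informativeness_table(freqs, marker_ids = panel)
    sizes <- pmin(config$panel_sizes, nrow(tab))
    ranking <- rank_and_nest(tab, "pid", sizes = sizes)
    out(tab, "informativeness")
    out(ranking$panels, "panel_evaluation")
    tau <- kendall_tau(tab[, c("he", "pid", "pid_sibs", "pe1", "pe2",
                               "pe3", "ir")])
    out(data.frame(criterion = rownames(tau), tau), "kendall_tau")
  }

  # -- power -------------------------------------------------------------
  if ("power" %in% stages && !is.null(ranking)) {
    set.seed(stage_seed[["power"]])
    models <- relationship_models()
    contrasts <- list(FS_UR = c("FS", "UR"), FS_HS = c("FS", "HS"),
                      HS_UR = c("HS", "UR"))
    stats_all <- per_locus_stats(gm_subset(gm, markers = panel), "pool1")
    pw <- do.call(rbind, lapply(ranking$panel_markers, function(mk) {
      q <- stats_all$p1[match(mk, stats_all$marker)]
      row <- vapply(contrasts, function(ct)
        pwr_panel(q, models[[ct[1]]], models[[ct[2]]])$pwr, 0)
      data.frame(size = length(mk), t(row))
    }))
    out(pw, "relationship_power")
  }

  # -- hybrids -----------------------------------------------------------
  if ("hybrids" %in% stages) {
    if (is.null(pf))
      stop("hybrid evaluation requires stage 'simulate' (pool frequencies)")
    set.seed(stage_seed[["hybrids"]])
    fst <- wc_fst(gm_subset(gm, markers = panel), "pool1", "pool2")
    ord <- fst$per_locus$marker[order(-fst$per_locus$theta,
                                      fst$per_locus$marker)]
    top <- ord[seq_len(min(96, length(ord)))]
    ev <- evaluate_panel_admixture(
      pf, top, n_per_class = config$hybrid_n_per_class,
      iterations = config$gibbs_iterations,
      burn_in = config$gibbs_burn_in,
      threshold = config$assignment_threshold)
    out(as.data.frame(ev$confusion$counts), "hybrid_confusion_counts")
    out(data.frame(true = rownames(ev$confusion$rates),
                   round(ev$confusion$rates, 4), check.names = FALSE),
        "hybrid_confusion_rates")
  }

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
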