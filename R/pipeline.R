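# ---------------------------------------------------------------------------
# End-to-end orchestration: simulate/load -> validate -> annotate -> stats
# -> SFS -> DFE fit -> alpha, writing report tables, fit JSON and a log.
# All randomness flows from one top-level seed via named substreams, so
# e.g. changing bootstrap_reps does not perturb the simulated data.
# ---------------------------------------------------------------------------

#' Pipeline run configuration
#'
#' Exactly one input mode: `input_dir` (FASTA + BED on disk) or `sim`
#' (a [sim_config()]; the simulated data are also written out).
#'
#' @param input_dir directory with `<locus>.fa` files and `features.bed`.
#' @param sim a [sim_config()].
#' @param neutral_reference "4fold" or "intron".
#' @param outgroup "close" or "far".
#' @param cpg_filter restrict analyses to non-CpG-prone sites.
#' @param bootstrap_reps bootstrap replicates for CIs/SEs.
#' @param mu mutation rate per site per generation for the Ne estimate.
#' @param grid_2N,n_quadrature DFE-fit settings (see [fit_dfe_ml()]).
#' @param seed master seed (mandatory when bootstrap_reps > 0).
#' @param out_dir output directory.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, sim = NULL,
                       neutral_reference = "4fold", outgroup = "close",
                       cpg_filter = FALSE, bootstrap_reps = 200L,
                       mu = 3.4e-9, grid_2N = 200L, n_quadrature = 24L,
                       seed = 1L, out_dir = tempfile("popdfe_run_")) {
  if (is.null(input_dir) == is.null(sim))
    stop("exactly one of input_dir or sim must be given")
  if (bootstrap_reps > 0 && is.null(seed))
    stop("seed is mandatory when bootstrap_reps > 0")
  stopifnot(neutral_reference %in% c("4fold", "intron"),
            outgroup %in% c("close", "far"))
  structure(list(input_dir = input_dir, sim = sim,
                 neutral_reference = neutral_reference, outgroup = outgroup,
                 cpg_filter = cpg_filter,
                 bootstrap_reps = as.integer(bootstrap_reps), mu = mu,
                 grid_2N = as.integer(grid_2N),
                 n_quadrature = as.integer(n_quadrature),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Validate an on-disk input bundle
#'
#' Checks FASTA/BED consistency: every locus has a feature entry and vice
#' versa, all sequences within a locus have equal length, sampled alleles
#' pair up two per individual, CDS lengths are divisible by 3, and
#' features stay within the alignment.  Problems are split into `errors`
#' and `warnings`.
#'
#' @param dir input directory.
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(dir) {
  errors <- character(); warnings <- character()
  bed_path <- file.path(dir, "features.bed")
  if (!dir.exists(dir)) return(list(errors = "input directory missing",
                                    warnings = warnings))
  if (!file.exists(bed_path))
    return(list(errors = "features.bed missing", warnings = warnings))
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("locus", "start", "end",
                                         "feature", "frame"))
  fastas <- list.files(dir, pattern = "\\.fa$", full.names = TRUE)
  ids <- sub("\\.fa$", "", basename(fastas))
  for (lid in setdiff(unique(bed$locus), ids))
    errors <- c(errors, paste0(lid, ": features but no FASTA"))
  for (i in seq_along(fastas)) {
    ss <- tryCatch(Biostrings::readDNAStringSet(fastas[i]),
                   error = function(e) NULL)
    if (is.null(ss)) {
      errors <- c(errors, paste0(ids[i], ": unreadable FASTA")); next
    }
    if (length(unique(Biostrings::width(ss))) != 1L)
      errors <- c(errors, paste0(ids[i], ": unequal sequence lengths"))
    special <- c("reference", "outgroup_close", "outgroup_far")
    if (!all(special %in% names(ss)))
      errors <- c(errors, paste0(ids[i], ": missing reference/outgroup records"))
    n_samp <- length(setdiff(names(ss), special))
    if (n_samp %% 2L != 0L)
      errors <- c(errors, paste0(ids[i], ": odd number of sampled alleles"))
    bl <- bed[bed$locus == ids[i], , drop = FALSE]
    if (!nrow(bl)) {
      warnings <- c(warnings, paste0(ids[i], ": no features"))
    } else {
      if (max(bl$end) > Biostrings::width(ss)[1L])
        errors <- c(errors, paste0(ids[i], ": feature beyond alignment end"))
      cds_len <- sum(bl$end[bl$feature == "CDS"] -
                       bl$start[bl$feature == "CDS"])
      if (cds_len %% 3L != 0L)
        errors <- c(errors,
                    paste0(ids[i], ": CDS length ", cds_len,
                           " not divisible by 3"))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full inference pipeline
#'
#' simulate/load -> validate -> annotate -> summary statistics -> folded
#' SFSs -> DFE maximum likelihood -> alpha (model-based and FWW), writing
#' TSV reports, a fit JSON and a plain-text log into `out_dir`.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `loci`, `stats`, `fit`, `alpha_model`,
#'   `alpha_fww_all`, `alpha_fww_gt10`, `fis`, `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("popDFE pipeline run ", format(Sys.time())),
                 paste0("R version: ", R.version.string),
                 paste0("master seed: ", config$seed),
                 paste0("neutral_reference: ", config$neutral_reference,
                        "; outgroup: ", config$outgroup,
                        "; cpg_filter: ", config$cpg_filter),
                 paste0("bootstrap_reps: ", config$bootstrap_reps))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- input ------------------------------------------------------------
  if (!is.null(config$sim)) {
    data_dir <- file.path(out, "data")
    gen <- stage("simulate", generate_locus_set(config$sim, data_dir))
    loci <- gen$loci
    log_lines <- c(log_lines, paste0("stage simulate: ", length(loci),
                                     " loci written to ", data_dir))
  } else {
    data_dir <- config$input_dir
    diag <- stage("validate", validate_inputs(data_dir))
    if (length(diag$errors))
      stop("pipeline stage [validate] failed: ",
           paste(diag$errors, collapse = "; "), call. = FALSE)
    loci <- stage("annotate", read_locus_set(data_dir))
    log_lines <- c(log_lines, paste0("stage load: ", length(loci),
                                     " loci from ", data_dir))
  }
  write_annotation_tsv(loci, file.path(out, "annotation.tsv"))

  # -- summary statistics ----------------------------------------------
  stats_tab <- stage("stats", class_summary_stats(
    loci, cpg_filter = config$cpg_filter, n_boot = config$bootstrap_reps,
    seed = substream_seed(config$seed, "stats")))
  utils::write.table(stats_tab, file.path(out, "summary_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  theta4 <- stats_tab$theta_pi_pct[stats_tab$site_class == "4fold"] / 100
  ne_tab <- data.frame(statistic = "theta_pi_4fold", theta_pi = theta4,
                       mu = config$mu,
                       ne = ne_from_diversity(theta4, config$mu))
  utils::write.table(ne_tab, file.path(out, "ne_estimate.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_lines <- c(log_lines, "stage stats: summary_stats.tsv, ne_estimate.tsv")

  # -- SFS + DFE fit ----------------------------------------------------
  sel_sfs <- stage("sfs", build_grouped_folded_sfs(loci, "0fold",
                                                   config$cpg_filter))
  neu_sfs <- stage("sfs", build_grouped_folded_sfs(
    loci, config$neutral_reference, config$cpg_filter))
  write_sfs_tsv(sel_sfs, file.path(out, "sfs_0fold.tsv"))
  write_sfs_tsv(neu_sfs, file.path(out, paste0(
    "sfs_", config$neutral_reference, ".tsv")))
  fit <- stage("fit-dfe", fit_dfe_ml(
    neu_sfs, sel_sfs, grid_2N = config$grid_2N,
    n_quadrature = config$n_quadrature,
    seed = substream_seed(config$seed, "fit")))
  log_lines <- c(log_lines, paste0(
    "stage fit-dfe: shape = ", signif(fit$dfe$shape, 4), ", mean Ne*s = ",
    signif(fit$dfe$mean_S, 5), ", N2/N1 = ",
    signif(fit$demog$n2 / fit$demog$n1, 4), ", t = ", fit$demog$t,
    ", f0 = ", signif(fit$f0, 4), ", loglik = ", signif(fit$loglik, 10)))

  # -- alpha ------------------------------------------------------------
  am <- stage("alpha", estimate_alpha_model(
    loci, fit, config$outgroup, config$neutral_reference,
    config$cpg_filter, n_boot = config$bootstrap_reps,
    seed = substream_seed(config$seed, "alpha_model")))
  af0 <- stage("alpha", estimate_alpha_fww(
    loci, config$outgroup, config$neutral_reference, freq_threshold = 0,
    cpg_filter = config$cpg_filter, n_boot = config$bootstrap_reps,
    seed = substream_seed(config$seed, "alpha_fww")))
  af10 <- stage("alpha", estimate_alpha_fww(
    loci, config$outgroup, config$neutral_reference, freq_threshold = 0.10,
    cpg_filter = config$cpg_filter, n_boot = config$bootstrap_reps,
    seed = substream_seed(config$seed, "alpha_fww")))
  alpha_tab <- data.frame(
    method = c("model_based", "fww_all", "fww_gt10"),
    outgroup = config$outgroup, neutral_ref = config$neutral_reference,
    cpg_filter = config$cpg_filter,
    alpha = c(am$alpha, af0$alpha, af10$alpha),
    ci_lo = c(am$ci[1L], af0$ci[1L], af10$ci[1L]),
    ci_hi = c(am$ci[2L], af0$ci[2L], af10$ci[2L]),
    se = c(am$se, af0$se, af10$se))
  utils::write.table(alpha_tab, file.path(out, "alpha_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # -- F_IS -------------------------------------------------------------
  fis <- stage("fis", fis_by_snp(loci))
  utils::write.table(fis, file.path(out, "fis_by_snp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # -- fit JSON + dfe table --------------------------------------------
  fit_json <- list(
    dfe = list(shape = fit$dfe$shape, mean_S = fit$dfe$mean_S),
    demography = list(n1 = fit$demog$n1, n2 = fit$demog$n2, t = fit$demog$t,
                      weighted_n = fit$weighted_n,
                      weighted_n_convention = paste(
                        "pair-coalescence weighting (package convention;",
                        "see methods vignette)")),
    f0 = fit$f0, loglik = fit$loglik,
    nes_class_props = as.list(stats::setNames(
      fit$nes_class_props, c("lt1", "1to10", "gt10"))),
    alpha = alpha_tab)
  jsonlite::write_json(fit_json, file.path(out, "dfe_fit.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  log_lines <- c(log_lines,
                 paste0("stage alpha: model = ", signif(am$alpha, 4),
                        ", fww_all = ", signif(af0$alpha, 4),
                        ", fww_gt10 = ", signif(af10$alpha, 4)),
                 paste0("stage fis: ", nrow(fis), " SNPs"))
  writeLines(log_lines, file.path(out, "run.log"))

  invisible(list(loci = loci, stats = stats_tab, fit = fit,
                 alpha_model = am, alpha_fww_all = af0,
                 alpha_fww_gt10 = af10, fis = fis,
                 paths = list(out_dir = out)))
}

#' Load a run configuration from YAML
#'
#' Keys mirror [run_config()]; a `sim:` block mirrors [sim_config()].
#' CLI flags override YAML values.
#'
#' @param path YAML file.
#' @param overrides named list of values overriding the file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  for (nm in names(overrides)) y[[nm]] <- overrides[[nm]]
  sim <- NULL
  if (!is.null(y$sim)) {
    sim_args <- y$sim
    if (!is.null(sim_args$demog)) sim_args$demog <- as.list(sim_args$demog)
    sim <- do.call(sim_config, sim_args)
  }
  run_config(input_dir = y$input_dir, sim = sim,
             neutral_reference = y$neutral_reference %||% "4fold",
             outgroup = y$outgroup %||% "close",
             cpg_filter = isTRUE(y$cpg_filter),
             bootstrap_reps = y$bootstrap_reps %||% 200L,
             mu = y$mu %||% 3.4e-9,
             grid_2N = y$grid_2N %||% 200L,
             n_quadrature = y$n_quadrature %||% 24L,
             seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("popdfe_run_"))
}
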