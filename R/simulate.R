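# ---------------------------------------------------------------------------
# Seeded synthetic datasets with the statistical structure the inference
# assumes: population folded SFSs drawn from Wright-Fisher step-change
# expectations, and per-locus FASTA alignments with polymorphism,
# divergence to two outgroups, missing data and inbreeding.
#
# Divergence is collapsed onto one lineage per outgroup comparison: the
# sample keeps the ancestral state and each outgroup accumulates
# substitutions at the class-specific target rate, so the observed
# pairwise divergence is calibrated directly and degeneracy classes never
# drift away from the annotation (substitutions on the sample lineage
# would relabel codon positions mid-simulation).  The estimators only
# consume pairwise divergence, so which lineage carries it is
# unidentifiable anyway.  Adaptive 0-fold substitutions are injected as
# instantaneous fixations so that the adaptive fraction of 0-fold
# divergence equals alpha_true; they contribute nothing to polymorphism,
# matching the assumption of the estimators.
# ---------------------------------------------------------------------------

#' @keywords internal
sim_demog_model <- function(cfg) {
  g <- sim_grid_sizes(cfg)
  demographic_model(g$pop2N1 / 2, g$pop2N2 / 2, g$t_gens)
}

#' Draw population minor/derived counts for a block of sites
#'
#' For each site, decides whether it currently segregates in the population
#' (probability `lambda * V(gamma)`, with V the total segregating density
#' for that site's scaled selection strength) and, if so, draws the derived
#' population count from the Wright-Fisher density.  Selection strengths
#' are binned onto a fixed log grid so densities are computed once per bin.
#'
#' @param gammas per-site scaled selection strengths (0 = neutral).
#' @param demog a [demographic_model()] on the generator grid.
#' @param lambda per-site mutational influx per generation (theta / 2).
#' @return integer vector of derived population counts (0 = not
#'   segregating), with attribute `pop2N` (current grid size).
#' @keywords internal
draw_population_counts <- function(gammas, demog, lambda, n_bins = 48L) {
  g <- demog_grid(demog)
  L <- length(gammas)
  j <- integer(L)
  nw <- weighted_recent_n(demog)
  grid <- dfe_quadrature_grid(n_bins, gamma_max = 0.98 * nw)
  bin <- findInterval(gammas, grid$edges)     # 0 = below grid -> neutral
  bin[gammas <= grid$edges[1L]] <- 0L
  bin[bin > n_bins] <- n_bins + 1L            # above grid -> effectively lethal
  pop2N_cur <- g$pop2N2
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    if (b > n_bins) next                      # lethal: never segregates
    gam <- if (b == 0L) 0 else grid$nodes[b]
    s <- gamma_to_s(gam, demog)
    dens <- cached_stepchange_density(g$pop2N1, g$pop2N2, g$t_gens, s)
    pop2N_cur <- attr(dens, "pop2N")
    v <- sum(dens)
    seg <- idx[stats::runif(length(idx)) < lambda * v]
    if (length(seg))
      j[seg] <- sample.int(length(dens), length(seg), replace = TRUE,
                           prob = dens)
  }
  attr(j, "pop2N") <- pop2N_cur
  j
}

#' @keywords internal
sim_class_site_counts <- function(cfg) {
  fr <- codon_class_fractions()
  coding <- cfg$n_loci * cfg$exon_len
  intron_usable <- cfg$n_loci * max(cfg$intron_len - 22L, 0L)
  c("0fold" = round(coding * fr[1L]), "2fold" = round(coding * fr[2L]),
    "4fold" = round(coding * fr[3L]), "intron" = intron_usable)
}

#' Simulate grouped folded SFSs for all site classes
#'
#' Neutral classes (2-fold, 4-fold, intron) draw population frequencies
#' from the neutral step-change density; 0-fold sites draw a per-site
#' scaled effect gamma from the configured gamma DFE.  Finite samples are
#' drawn binomially per site, with the per-site allele number varying
#' through `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return list with one [grouped_folded_sfs()] per site class, plus a
#'   `truth` record of generator-side quantities.
#' @export
simulate_population_sfs <- function(config) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "population_sfs"))
  demog <- sim_demog_model(config)
  lambda <- config$theta_neutral / 2
  n_alleles <- 2L * config$n_individuals
  counts <- sim_class_site_counts(config)
  out <- list()
  for (cls in names(counts)) {
    L <- as.integer(counts[[cls]])
    gammas <- if (cls == "0fold" && config$dfe_mean_S > 0)
      stats::rgamma(L, shape = config$dfe_shape,
                    scale = config$dfe_mean_S / config$dfe_shape)
    else numeric(L)
    j <- draw_population_counts(gammas, demog, lambda)
    pop2N <- attr(j, "pop2N")
    n_i <- stats::rbinom(L, n_alleles, 1 - config$missing_rate)
    i_cnt <- integer(L)
    seg <- j > 0L & n_i >= 2L
    i_cnt[seg] <- stats::rbinom(sum(seg), n_i[seg], j[seg] / pop2N)
    k <- pmin(i_cnt, pmax(n_i - i_cnt, 0L))
    spectra <- list()
    for (n in sort(unique(n_i[n_i >= 2L]))) {
      idx <- n_i == n
      spectra[[as.character(n)]] <-
        as.numeric(tabulate(k[idx] + 1L, nbins = n %/% 2L + 1L))
    }
    out[[cls]] <- grouped_folded_sfs(cls, spectra)
  }
  out$truth <- list(config = unclass(config), demog = unclass(demog),
                    lambda = lambda,
                    weighted_n = weighted_recent_n(demog),
                    class_sites = counts)
  out
}

#' @keywords internal
random_sense_codons <- function(n_codons) {
  gc <- .codon_table()
  sense <- names(gc)[gc != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' @keywords internal
flip_base <- function(base) {
  vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

#' Generate a synthetic locus set with ground truth
#'
#' Writes (optionally) per-locus FASTA alignments of 2 alleles x
#' n_individuals plus reference and two outgroups, and a BED feature file,
#' and returns the annotated loci together with the generator's ground
#' truth.  Polymorphism is consistent with the simulated Wright-Fisher
#' site frequency spectra; divergence matches the configured targets
#' (with adaptive 0-fold substitutions at fraction `alpha_true`);
#' missing bases and identical-by-descent allele pairs are injected at the
#' configured rates.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory to write `<locus>.fa`, `features.bed`
#'   and `ground_truth.json`.
#' @return list with `loci` (list of `annotated_locus`) and `truth`.
#' @export
generate_locus_set <- function(config, out_dir = NULL) {
  validate_sim_config(config)
  set.seed(substream_seed(config$seed, "locus_set"))
  cfg <- config
  demog <- sim_demog_model(cfg)
  g <- demog_grid(demog)
  lambda <- cfg$theta_neutral / 2
  n_ind <- cfg$n_individuals

  # class-specific divergence targets (JC scale), then raw flip rates
  e_r <- if (cfg$dfe_mean_S > 0)
    dfe_mean_fixation_ratio(gamma_dfe(cfg$dfe_shape, cfg$dfe_mean_S)) else 1
  sel_factor <- e_r / (1 - cfg$alpha_true)
  d_close <- c("0fold" = cfg$div_neutral_close * sel_factor,
               other = cfg$div_neutral_close)
  d_far <- c("0fold" = cfg$div_neutral_far * sel_factor,
             other = cfg$div_neutral_far)
  p_close <- vapply(d_close, jc_uncorrect, numeric(1))
  p_far <- vapply(d_far, jc_uncorrect, numeric(1))

  # exon split at a codon boundary: exon A, intron, exon B
  ea <- 3L * ((cfg$exon_len / 3L) %/% 2L)
  eb <- cfg$exon_len - ea
  has_intron <- cfg$intron_len > 0L
  feats <- data.frame(
    start = c(0L, if (has_intron) ea, ea + cfg$intron_len),
    end = c(ea, if (has_intron) ea + cfg$intron_len,
            ea + cfg$intron_len + eb),
    feature = c("CDS", if (has_intron) "intron", "CDS"),
    frame = c(0L, if (has_intron) NA_integer_, 0L))
  feats <- feats[feats$end > feats$start, , drop = FALSE]
  l_tot <- cfg$exon_len + cfg$intron_len

  loci <- vector("list", cfg$n_loci)
  bed_rows <- vector("list", cfg$n_loci)
  truth_subs <- numeric(0)
  for (lc in seq_len(cfg$n_loci)) {
    locus_id <- sprintf("locus%03d", lc)
    anc <- character(l_tot)
    if (ea > 0L)
      anc[1:ea] <- strsplit(random_sense_codons(ea / 3L), "")[[1L]]
    if (eb > 0L)
      anc[(ea + cfg$intron_len + 1L):l_tot] <-
        strsplit(random_sense_codons(eb / 3L), "")[[1L]]
    if (has_intron)
      anc[(ea + 1L):(ea + cfg$intron_len)] <-
        sample(DNA_BASES, cfg$intron_len, replace = TRUE)

    cls_anc <- site_classes_from_reference(anc, feats, locus_id)
    is0 <- cls_anc == "0fold"
    ref <- anc                               # sample lineage keeps ancestor
    og_close <- anc
    sub <- stats::runif(l_tot) < ifelse(is0, p_close[["0fold"]],
                                        p_close[["other"]])
    if (any(sub)) og_close[sub] <- flip_base(anc[sub])
    og_far <- anc
    farflip <- stats::runif(l_tot) < ifelse(is0, p_far[["0fold"]],
                                            p_far[["other"]])
    if (any(farflip)) og_far[farflip] <- flip_base(anc[farflip])

    gammas <- numeric(l_tot)
    sel_sites <- is0 & cfg$dfe_mean_S > 0
    if (any(sel_sites))
      gammas[sel_sites] <- stats::rgamma(sum(sel_sites),
                                         shape = cfg$dfe_shape,
                                         scale = cfg$dfe_mean_S / cfg$dfe_shape)
    j <- draw_population_counts(gammas, demog, lambda)
    pop2N <- attr(j, "pop2N")

    alleles <- matrix(rep(ref, 2L * n_ind), nrow = l_tot)
    colnames(alleles) <- paste0(rep(sprintf("ind%02d", seq_len(n_ind)),
                                    each = 2L), c("_a", "_b"))
    ibd <- stats::runif(n_ind) < cfg$inbreeding_F
    for (pos in which(j > 0L)) {
      q <- j[pos] / pop2N
      derived <- flip_base(ref[pos])
      d1 <- stats::runif(n_ind) < q
      d2 <- ifelse(ibd, d1, stats::runif(n_ind) < q)
      alleles[pos, 2L * seq_len(n_ind) - 1L][d1] <- derived
      alleles[pos, 2L * seq_len(n_ind)][d2] <- derived
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(l_tot * 2L * n_ind) < cfg$missing_rate,
                     nrow = l_tot)
      alleles[miss] <- "N"
    }
    # occasional masked stretch in an outgroup (unsequenced amplicon ends)
    for (og in c("og_close", "og_far")) {
      if (stats::runif(1) < 0.25) {
        w <- max(1L, round(0.1 * l_tot))
        st <- sample.int(l_tot - w + 1L, 1L)
        v <- get(og)
        v[st:(st + w - 1L)] <- "N"
        assign(og, v)
      }
    }

    seqs <- cbind(alleles, reference = ref, outgroup_close = og_close,
                  outgroup_far = og_far)
    loci[[lc]] <- annotate_locus(locus_id, seqs, feats)
    bed_rows[[lc]] <- cbind(locus = locus_id, feats)
    truth_subs <- truth_subs + sum(sub)
  }
  names(loci) <- vapply(loci, `[[`, character(1), "locus_id")

  truth <- list(config = unclass(cfg), demog = unclass(demog),
                lambda = lambda, weighted_n = weighted_recent_n(demog),
                expected_fixation_ratio = e_r,
                d_target_close = as.list(d_close),
                d_target_far = as.list(d_far),
                n_substitutions_close = truth_subs,
                class_counts = as.list(table(factor(
                  unlist(lapply(loci, `[[`, "site_class")),
                  levels = SITE_CLASSES))))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (locus in loci) {
      seqs <- cbind(locus$alleles, reference = locus$reference,
                    outgroup_close = locus$outgroup_close,
                    outgroup_far = locus$outgroup_far)
      ss <- Biostrings::DNAStringSet(apply(seqs, 2L, paste, collapse = ""))
      Biostrings::writeXStringSet(
        ss, file.path(out_dir, paste0(locus$locus_id, ".fa")))
    }
    bed <- do.call(rbind, bed_rows)
    utils::write.table(bed, file.path(out_dir, "features.bed"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(loci = loci, truth = truth)
}
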