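# ---------------------------------------------------------------------------
# Diversity, skew, divergence, inbreeding and correlation statistics per
# site class, with per-locus bootstrap uncertainty.  theta_pi and theta_w
# use each site's own allele number; only Tajima's D requires a fixed n and
# is computed after downsampling every site to exactly fixed_n alleles.
# ---------------------------------------------------------------------------

#' Nucleotide diversity (theta_pi) from per-site base counts
#'
#' Per site, the unbiased average heterozygosity
#' `(n / (n - 1)) * (1 - sum(p_k^2))` with that site's own allele number n;
#' the statistic is the mean over usable sites (coverage >= 2).
#'
#' @param counts 4 x L matrix of per-site base counts (rows A, C, G, T).
#' @return list with `theta` (per-site diversity), `n_sites` (usable L),
#'   `sum_het` (summed heterozygosity).
#' @export
theta_pi <- function(counts) {
  n <- colSums(counts)
  use <- n >= 2L
  if (!any(use)) return(list(theta = NA_real_, n_sites = 0L, sum_het = 0))
  cc <- counts[, use, drop = FALSE]
  nn <- n[use]
  het <- (nn / (nn - 1)) * (1 - colSums((t(t(cc) / nn))^2))
  list(theta = sum(het) / sum(use), n_sites = sum(use), sum_het = sum(het))
}

#' Watterson's diversity (theta_W) from per-site base counts
#'
#' Per site, `I(segregating) / a_n` with `a_n = sum_{i=1}^{n-1} 1/i` using
#' that site's own n; the statistic is the mean over usable sites.
#'
#' @inheritParams theta_pi
#' @return list with `theta`, `n_sites`, `seg_sites`.
#' @export
theta_w <- function(counts) {
  n <- colSums(counts)
  use <- n >= 2L
  if (!any(use)) return(list(theta = NA_real_, n_sites = 0L, seg_sites = 0L))
  cc <- counts[, use, drop = FALSE]
  seg <- colSums(cc > 0L) >= 2L
  contrib <- ifelse(seg, 1 / watterson_a(n[use]), 0)
  list(theta = sum(contrib) / sum(use), n_sites = sum(use),
       seg_sites = sum(seg))
}

#' Tajima's D with fixed-n downsampling
#'
#' Every usable site is downsampled to exactly `fixed_n` alleles, drawn
#' uniformly without replacement (sites with fewer than `fixed_n` called
#' alleles are rejected).  D is then computed from the resampled totals of
#' segregating sites and mean pairwise differences with the standard
#' Tajima (1989) variance constants.
#'
#' @param loci list of `annotated_locus`.
#' @param site_class site class label.
#' @param fixed_n alleles per site after downsampling (default 20).
#' @param seed integer seed for the downsampling draws.
#' @param cpg_filter if TRUE, use only non-CpG-prone sites.
#' @return list with `d`, `n_sites`, `seg_sites`, `pi_total`; `d` is
#'   `NA` when no site segregates after resampling.
#' @export
tajima_d <- function(loci, site_class, fixed_n = 20L, seed = 1L,
                     cpg_filter = FALSE) {
  set.seed(substream_seed(seed, paste0("tajima_", site_class)))
  s_total <- 0L
  pi_total <- 0
  l_used <- 0L
  for (locus in loci) {
    keep <- which(class_site_filter(locus, site_class, cpg_filter) &
                    locus$coverage >= fixed_n)
    if (!length(keep)) next
    counts <- site_base_counts(locus)[, keep, drop = FALSE]
    sub <- downsample_counts_matrix(counts, fixed_n)
    l_used <- l_used + ncol(sub)
    seg <- colSums(sub > 0L) >= 2L
    s_total <- s_total + sum(seg)
    if (any(seg)) {
      pairs_same <- colSums(choose(sub[, seg, drop = FALSE], 2))
      pi_total <- pi_total +
        sum((choose(fixed_n, 2) - pairs_same) / choose(fixed_n, 2))
    }
  }
  if (s_total == 0L)
    return(list(d = NA_real_, n_sites = l_used, seg_sites = 0L, pi_total = 0))
  # pi_total is in units of mean pairwise differences summed over sites
  pi_sum <- pi_total * 1
  list(d = tajima_d_from_totals(s_total, pi_sum, fixed_n),
       n_sites = l_used, seg_sites = s_total, pi_total = pi_sum)
}

#' Tajima's D from totals of S and mean pairwise differences
#'
#' @param s number of segregating sites.
#' @param pi_sum sum over sites of mean pairwise differences.
#' @param n fixed number of alleles.
#' @export
tajima_d_from_totals <- function(s, pi_sum, n) {
  if (s == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - s / a1) / sqrt(e1 * s + e2 * s * (s - 1))
}

#' Jukes-Cantor multiple-hit correction
#'
#' `d = -(3/4) * log(1 - 4 p / 3)` for an observed proportion of differing
#' sites `p < 0.75`.
#'
#' @param p proportion of sites that differ.
#' @return corrected divergence (substitutions per site).
#' @export
jc_correct <- function(p) {
  stopifnot(all(p >= 0))
  if (any(p >= 0.75))
    stop("proportion of differences >= 0.75: Jukes-Cantor correction undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Inverse of the Jukes-Cantor correction
#' @param d corrected divergence.
#' @export
jc_uncorrect <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Divergence to an outgroup for a site class
#'
#' A site is usable when the outgroup base is called and at least one
#' sampled allele is called; it counts as divergent when the outgroup base
#' differs from every called sampled allele (a polymorphic-and-divergent
#' site counts once).  The pooled proportion is Jukes-Cantor corrected.
#'
#' @param loci list of `annotated_locus`.
#' @param outgroup "close" or "far".
#' @param site_class site class label.
#' @param cpg_filter if TRUE, use only non-CpG-prone sites.
#' @return list with `d` (JC-corrected), `p_raw`, `n_sites`, `n_div`.
#' @export
jc_divergence <- function(loci, outgroup = c("close", "far"), site_class,
                          cpg_filter = FALSE) {
  outgroup <- match.arg(outgroup)
  field <- paste0("outgroup_", outgroup)
  n_div <- 0L; n_use <- 0L
  for (locus in loci) {
    keep <- which(class_site_filter(locus, site_class, cpg_filter))
    if (!length(keep)) next
    og <- locus[[field]][keep]
    counts <- site_base_counts(locus)[, keep, drop = FALSE]
    cov <- colSums(counts)
    usable <- og %in% DNA_BASES & cov >= 1L
    if (!any(usable)) next
    idx <- which(usable)
    n_use <- n_use + length(idx)
    og_count <- counts[cbind(match(og[idx], DNA_BASES), idx)]
    n_div <- n_div + sum(og_count == 0L)
  }
  if (n_use == 0L)
    return(list(d = NA_real_, p_raw = NA_real_, n_sites = 0L, n_div = 0L))
  p <- n_div / n_use
  list(d = jc_correct(p), p_raw = p, n_sites = n_use, n_div = n_div)
}

#' Bootstrap a statistic by locus
#'
#' Resamples loci with replacement, recomputes the statistic, and reports
#' the percentile 95% CI and the bootstrap-SD standard error.
#'
#' @param statistic function taking a list of loci and returning a scalar.
#' @param loci list of `annotated_locus`.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `est`, `se`, `ci` (length 2), `n_failed`, and
#'   `flagged` (TRUE when the statistic was undefined in more than half the
#'   replicates).
#' @export
bootstrap_by_locus <- function(statistic, loci, n_boot = 1000L, seed = 1L) {
  est <- statistic(loci)
  set.seed(substream_seed(seed, "bootstrap_by_locus"))
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(loci), replace = TRUE)
    as.numeric(statistic(loci[idx]))
  }, numeric(1))
  ok <- is.finite(reps)
  list(est = est,
       se = if (sum(ok) >= 2) stats::sd(reps[ok]) else NA_real_,
       ci = if (sum(ok) >= 2)
         unname(stats::quantile(reps[ok], c(0.025, 0.975))) else c(NA, NA),
       n_failed = sum(!ok), flagged = sum(!ok) > n_boot / 2,
       replicates = reps)
}

#' Weir & Cockerham (1984) within-population inbreeding coefficient
#'
#' Small-sample single-locus estimator of f (F_IS) for a biallelic SNP from
#' genotype tallies in one population.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return f estimate in `[-1, 1]`, or `NA` for monomorphic SNPs or fewer
#'   than 2 genotyped individuals.
#' @export
fis_weir_cockerham <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 2L) return(NA_real_)
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  q <- 1 - p
  if (p == 0 || p == 1) return(NA_real_)
  h <- n_het / n
  b <- (n / (n - 1)) * (p * q - (2 * n - 1) / (4 * n) * h)
  cc <- h / 2
  if (b + cc <= 0) return(NA_real_)
  1 - cc / (b + cc)
}

#' Per-SNP F_IS table for a locus set
#'
#' Scans all biallelic SNPs in the given site classes with at least
#' `min_individuals` fully genotyped individuals and returns the
#' Weir-Cockerham f for each.
#'
#' @param loci list of `annotated_locus`.
#' @param site_classes site classes to scan.
#' @param min_individuals minimum fully genotyped individuals.
#' @return data.frame with snp_id, locus, pos, n_ind, f_is.
#' @export
fis_by_snp <- function(loci, site_classes = c("4fold", "intron"),
                       min_individuals = 2L) {
  rows <- list()
  for (locus in loci) {
    a <- locus$alleles
    n_ind <- ncol(a) / 2L
    keep <- which(locus$site_class %in% site_classes & locus$coverage >= 4L)
    for (pos in keep) {
      b1 <- a[pos, 2L * seq_len(n_ind) - 1L]
      b2 <- a[pos, 2L * seq_len(n_ind)]
      ok <- b1 %in% DNA_BASES & b2 %in% DNA_BASES
      if (sum(ok) < min_individuals) next
      bases <- unique(c(b1[ok], b2[ok]))
      if (length(bases) != 2L) next
      ref <- bases[1L]
      g <- (b1[ok] == ref) + (b2[ok] == ref)   # copies of ref per individual
      f <- fis_weir_cockerham(sum(g == 2L), sum(g == 1L), sum(g == 0L))
      rows[[length(rows) + 1L]] <-
        data.frame(snp_id = paste0(locus$locus_id, ":", pos),
                   locus = locus$locus_id, pos = pos,
                   n_ind = sum(ok), f_is = f)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(), locus = character(),
                      pos = integer(), n_ind = integer(),
                      f_is = numeric()))
  do.call(rbind, rows)
}

#' Effective population size from nucleotide diversity
#'
#' `Ne = theta_pi / (4 mu)`, reported to two significant figures.
#'
#' @param theta_pi per-site nucleotide diversity.
#' @param mu mutation rate per site per generation (> 0).
#' @export
ne_from_diversity <- function(theta_pi, mu) {
  if (mu <= 0) stop("mu must be > 0")
  stopifnot(theta_pi >= 0)
  signif(theta_pi / (4 * mu), 2)
}

#' Spearman correlation between per-locus diversity and divergence
#'
#' @param dn per-locus nonsynonymous divergence.
#' @param theta per-locus neutral diversity.
#' @return list with `rho` and `p` (two-sided, mid-rank ties).
#' @export
diversity_divergence_correlation <- function(dn, theta) {
  stopifnot(length(dn) == length(theta))
  if (length(dn) < 5L) stop("need at least 5 loci")
  if (stats::sd(dn) == 0 || stats::sd(theta) == 0)
    stop("constant vector: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(dn, theta, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' @keywords internal
pooled_counts_for_class <- function(loci, site_class, cpg_filter = FALSE) {
  mats <- lapply(loci, function(locus) {
    keep <- which(class_site_filter(locus, site_class, cpg_filter) &
                    locus$coverage >= 2L)
    if (!length(keep)) return(NULL)
    site_base_counts(locus)[, keep, drop = FALSE]
  })
  mats <- mats[!vapply(mats, is.null, logical(1))]
  if (!length(mats)) return(matrix(0L, nrow = 4L, ncol = 0L))
  do.call(cbind, mats)
}

#' Per-class summary statistics table
#'
#' Diversities, Tajima's D and JC-corrected divergences per site class,
#' with per-locus bootstrap standard errors (diversities and divergences in
#' percent, matching the conventional presentation).
#'
#' @param loci list of `annotated_locus`.
#' @param classes site classes to summarise.
#' @param cpg_filter if TRUE, restrict to non-CpG-prone sites.
#' @param n_boot bootstrap replicates per statistic (0 disables SEs).
#' @param seed integer seed.
#' @param fixed_n alleles for the Tajima's D downsampling.
#' @return data.frame, one row per class.
#' @export
class_summary_stats <- function(loci, classes = c("0fold", "2fold", "4fold",
                                                  "intron"),
                                cpg_filter = FALSE, n_boot = 0L, seed = 1L,
                                fixed_n = 20L) {
  one_class <- function(cls) {
    counts <- pooled_counts_for_class(loci, cls, cpg_filter)
    tp <- theta_pi(counts)
    tw <- theta_w(counts)
    td <- tajima_d(loci, cls, fixed_n = fixed_n, seed = seed,
                   cpg_filter = cpg_filter)
    dc <- jc_divergence(loci, "close", cls, cpg_filter)
    df <- jc_divergence(loci, "far", cls, cpg_filter)
    row <- data.frame(site_class = cls, n_sites = tp$n_sites,
                      seg_sites = tw$seg_sites,
                      theta_pi_pct = 100 * tp$theta,
                      theta_w_pct = 100 * tw$theta,
                      tajima_d = td$d,
                      d_close_pct = 100 * dc$d, d_far_pct = 100 * df$d)
    if (n_boot > 0L) {
      boots <- list(
        theta_pi_se = function(l) {
          cm <- pooled_counts_for_class(l, cls, cpg_filter)
          100 * theta_pi(cm)$theta
        },
        theta_w_se = function(l) {
          cm <- pooled_counts_for_class(l, cls, cpg_filter)
          100 * theta_w(cm)$theta
        },
        tajima_d_se = function(l)
          tajima_d(l, cls, fixed_n = fixed_n, seed = seed,
                   cpg_filter = cpg_filter)$d,
        d_close_se = function(l)
          100 * jc_divergence(l, "close", cls, cpg_filter)$d,
        d_far_se = function(l)
          100 * jc_divergence(l, "far", cls, cpg_filter)$d)
      for (nm in names(boots))
        row[[nm]] <- bootstrap_by_locus(boots[[nm]], loci, n_boot,
                                        substream_seed(seed, nm))$se
    }
    row
  }
  do.call(rbind, lapply(classes, one_class))
}
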