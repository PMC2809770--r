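# ---------------------------------------------------------------------------
# Folded site frequency spectra grouped by per-site sampled allele number.
# Index 1 of every spectrum vector is the monomorphic class (minor count 0);
# the cell at exactly n/2 for even n is counted once.
# ---------------------------------------------------------------------------

#' Grouped folded SFS container
#'
#' @param site_class label of the site class the spectra summarise.
#' @param spectra named list, name = sample size n (alleles), value =
#'   numeric vector of length `floor(n/2) + 1` indexed by minor-allele
#'   count 0..floor(n/2) (index 1 = monomorphic sites).
#' @param n_excluded number of sites dropped (e.g. triallelic).
#' @return object of class `grouped_folded_sfs`.
#' @export
grouped_folded_sfs <- function(site_class, spectra, n_excluded = 0L) {
  stopifnot(is.list(spectra), length(spectra) == 0L || !is.null(names(spectra)))
  for (nm in names(spectra)) {
    n <- as.integer(nm)
    v <- spectra[[nm]]
    if (length(v) != n %/% 2L + 1L)
      stop("spectrum for n = ", nm, " has wrong length")
    if (any(v < 0)) stop("negative spectrum entries for n = ", nm)
  }
  structure(list(site_class = site_class, spectra = spectra,
                 total_sites = sum(unlist(spectra)),
                 n_excluded = n_excluded),
            class = "grouped_folded_sfs")
}

#' @export
print.grouped_folded_sfs <- function(x, ...) {
  seg <- sum(unlist(lapply(x$spectra, function(v) sum(v[-1L]))))
  cat("<grouped_folded_sfs> class", x$site_class, ":", x$total_sites,
      "sites in", length(x$spectra), "allele-number group(s),", seg,
      "segregating\n")
  invisible(x)
}

#' Number of segregating sites recorded in a grouped SFS
#' @param sfs a [grouped_folded_sfs()].
#' @export
sfs_segregating <- function(sfs)
  sum(unlist(lapply(sfs$spectra, function(v) sum(v[-1L]))))

#' Per-site base counts for one locus
#'
#' @param locus an `annotated_locus`.
#' @return 4 x n_sites integer matrix of A/C/G/T counts among sampled
#'   alleles.
#' @keywords internal
site_base_counts <- function(locus) {
  if (!is.null(locus$base_counts)) return(locus$base_counts)
  m <- locus$alleles
  out <- matrix(0L, nrow = 4L, ncol = nrow(m),
                dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) out[b, ] <- as.integer(rowSums(m == b))
  out
}

#' Vectorised multivariate-hypergeometric downsampling of base counts
#'
#' Draws `m` alleles per site without replacement from each column of a
#' 4 x L base-count matrix (all columns must sum to >= m).
#' @keywords internal
downsample_counts_matrix <- function(counts, m) {
  n <- colSums(counts)
  stopifnot(all(n >= m))
  L <- ncol(counts)
  out <- matrix(0L, nrow = 4L, ncol = L, dimnames = dimnames(counts))
  left <- rep.int(as.integer(m), L)
  pool <- n
  for (b in 1:3) {
    x <- stats::rhyper(L, counts[b, ], pool - counts[b, ], left)
    out[b, ] <- x
    left <- left - x
    pool <- pool - counts[b, ]
  }
  out[4L, ] <- left
  out
}

#' @keywords internal
class_site_filter <- function(locus, site_class, cpg_filter = FALSE) {
  keep <- locus$site_class == site_class
  if (cpg_filter) keep <- keep & !locus$cpg_prone
  keep
}

#' Build a grouped folded SFS for a site class
#'
#' Each site with coverage >= 2 contributes its minor-allele count at that
#' site's own allele number n to `spectra[[n]]`; monomorphic sites go to
#' index 0.  Sites with more than two segregating bases are excluded (and
#' counted in `n_excluded`).  Allele-number groups holding fewer than
#' `min_group_sites` sites are merged into the nearest smaller retained n
#' by hypergeometric projection, which stabilises the per-group likelihood.
#'
#' @param loci list of `annotated_locus`.
#' @param site_class one of "0fold", "2fold", "4fold", "intron".
#' @param cpg_filter if TRUE, use only non-CpG-prone sites.
#' @param min_group_sites merge threshold for small allele-number groups
#'   (0 disables merging).
#' @return a [grouped_folded_sfs()].
#' @export
build_grouped_folded_sfs <- function(loci, site_class, cpg_filter = FALSE,
                                     min_group_sites = 50L) {
  tallies <- list()
  n_excl <- 0L
  for (locus in loci) {
    keep <- which(class_site_filter(locus, site_class, cpg_filter) &
                    locus$coverage >= 2L)
    if (!length(keep)) next
    counts <- site_base_counts(locus)[, keep, drop = FALSE]
    n <- colSums(counts)
    n_bases <- colSums(counts > 0L)
    tri <- n_bases > 2L
    n_excl <- n_excl + sum(tri)
    # biallelic (or monomorphic): minor count = n - largest base count
    k <- n - pmax(counts[1L, ], counts[2L, ], counts[3L, ], counts[4L, ])
    k <- pmin(k, n - k)
    ok <- !tri
    for (nn in unique(n[ok])) {
      idx <- ok & n == nn
      nm <- as.character(nn)
      add <- tabulate(k[idx] + 1L, nbins = nn %/% 2L + 1L)
      if (is.null(tallies[[nm]])) tallies[[nm]] <- numeric(nn %/% 2L + 1L)
      tallies[[nm]] <- tallies[[nm]] + add
    }
  }
  if (min_group_sites > 0L && length(tallies) > 1L)
    tallies <- merge_small_groups(tallies, min_group_sites)
  tallies <- tallies[order(as.integer(names(tallies)))]
  grouped_folded_sfs(site_class, tallies, n_excluded = n_excl)
}

#' @keywords internal
merge_small_groups <- function(tallies, min_group_sites) {
  ns <- sort(as.integer(names(tallies)), decreasing = TRUE)
  sizes <- vapply(as.character(ns), function(nm) sum(tallies[[nm]]),
                  numeric(1))
  big <- ns[sizes >= min_group_sites]
  if (!length(big)) return(tallies)        # nothing stable to merge into
  out <- tallies[as.character(big)]
  for (n in ns[sizes < min_group_sites]) {
    targets <- big[big <= n]
    if (!length(targets)) { out[[as.character(n)]] <- tallies[[as.character(n)]]; next }
    m <- max(targets)
    proj <- downsample_sfs(tallies[[as.character(n)]], n, m)
    out[[as.character(m)]] <- out[[as.character(m)]] + proj
  }
  out
}

#' Hypergeometric projection of a folded spectrum to a smaller sample size
#'
#' Deterministic expectation of drawing `m` alleles without replacement
#' from each site's `n`, refolded.  Projected entries are generally
#' fractional expected counts.
#'
#' @param spectrum folded spectrum at sample size `n` (length
#'   `floor(n/2) + 1`, index 1 = monomorphic).
#' @param n current sample size.
#' @param m target sample size, `2 <= m <= n`.
#' @return folded spectrum at `m` (length `floor(m/2) + 1`).
#' @export
downsample_sfs <- function(spectrum, n, m) {
  stopifnot(m >= 2, m <= n, length(spectrum) == n %/% 2L + 1L)
  if (m == n) return(spectrum)
  pm <- folded_projection_matrix(n, m)
  as.vector(pm %*% spectrum)
}

#' @keywords internal
folded_projection_matrix <- function(n, m) {
  kmax_n <- n %/% 2L
  kmax_m <- m %/% 2L
  pm <- matrix(0, nrow = kmax_m + 1L, ncol = kmax_n + 1L)
  for (k in 0:kmax_n) {
    pr <- stats::dhyper(0:m, k, n - k, m)     # minor copies drawn
    for (x in 0:m) {
      kk <- min(x, m - x)
      pm[kk + 1L, k + 1L] <- pm[kk + 1L, k + 1L] + pr[x + 1L]
    }
  }
  pm
}

#' One-allele-per-individual composite datasets
#'
#' For each of `n_datasets` replicates, and for every individual and every
#' site, randomly picks one of the individual's two alleles (taking the
#' called one when exactly one is missing), producing composite sequences
#' that break within-individual allele pairing.  Downstream statistics are
#' averaged over the replicates to guard against inbreeding-induced
#' pseudo-replication.
#'
#' @param loci list of `annotated_locus` (alleles paired as consecutive
#'   columns per individual).
#' @param n_datasets number of composite datasets (default 20).
#' @param seed integer seed.
#' @return list of `n_datasets` locus sets whose alleles matrices have one
#'   column per individual.
#' @export
one_allele_resample <- function(loci, n_datasets = 20L, seed) {
  set.seed(substream_seed(seed, "one_allele"))
  n_ind <- ncol(loci[[1L]]$alleles) / 2L
  if (n_ind != round(n_ind)) stop("alleles are not paired (odd column count)")
  lapply(seq_len(n_datasets), function(d) {
    lapply(loci, function(locus) {
      a <- locus$alleles
      n_sites <- nrow(a)
      comp <- matrix(NA_character_, nrow = n_sites, ncol = n_ind)
      colnames(comp) <- sprintf("ind%02d", seq_len(n_ind))
      for (i in seq_len(n_ind)) {
        b1 <- a[, 2L * i - 1L]; b2 <- a[, 2L * i]
        pick <- stats::runif(n_sites) < 0.5
        chosen <- ifelse(pick, b1, b2)
        only1 <- b1 %in% DNA_BASES & !(b2 %in% DNA_BASES)
        only2 <- b2 %in% DNA_BASES & !(b1 %in% DNA_BASES)
        chosen[only1] <- b1[only1]
        chosen[only2] <- b2[only2]
        comp[, i] <- chosen
      }
      out <- locus
      out$alleles <- comp
      out$base_counts <- NULL
      out$base_counts <- site_base_counts(out)
      out$coverage <- as.integer(colSums(out$base_counts))
      out
    })
  })
}

#' Write a grouped folded SFS as TSV
#'
#' Columns: class, n, minor_count, n_sites.
#' @param sfs a [grouped_folded_sfs()].
#' @param path output path.
#' @export
write_sfs_tsv <- function(sfs, path) {
  rows <- do.call(rbind, lapply(names(sfs$spectra), function(nm) {
    v <- sfs$spectra[[nm]]
    data.frame(class = sfs$site_class, n = as.integer(nm),
               minor_count = seq_along(v) - 1L, n_sites = v)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
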