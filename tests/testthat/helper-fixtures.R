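# Shared fixtures: tiny hand-built loci and a small cached simulated set.

# Build an annotated_locus from a character matrix of sampled alleles plus
# optional outgroups/reference; default features mark everything intron-free
# CDS or plain intron.
toy_locus <- function(alleles, reference = NULL, outgroup_close = NULL,
                      outgroup_far = NULL, features = NULL,
                      locus_id = "toy") {
  n_sites <- nrow(alleles)
  if (is.null(reference)) reference <- alleles[, 1L]
  if (is.null(outgroup_close)) outgroup_close <- reference
  if (is.null(outgroup_far)) outgroup_far <- reference
  if (is.null(colnames(alleles)))
    colnames(alleles) <- paste0(rep(sprintf("ind%02d",
                                            seq_len(ncol(alleles) / 2)),
                                    each = 2L), c("_a", "_b"))
  if (is.null(features))
    features <- data.frame(start = 0L, end = n_sites, feature = "intron",
                           frame = NA_integer_)
  seqs <- cbind(alleles, reference = reference,
                outgroup_close = outgroup_close, outgroup_far = outgroup_far)
  annotate_locus(locus_id, seqs, features)
}

# A locus whose sites are all intronic; 6 leading and 16 trailing pad
# sites are swallowed exactly by the splice windows, so the usable sites
# are `patterns` (a list of per-site base vectors) at positions 7, 8, ...
toy_intron_locus <- function(patterns, ...) {
  n_alleles <- length(patterns[[1L]])
  n_sites <- length(patterns) + 22L
  alleles <- matrix("A", nrow = n_sites, ncol = n_alleles)
  for (i in seq_along(patterns))
    alleles[6L + i, ] <- patterns[[i]]
  toy_locus(alleles,
            features = data.frame(start = 0L, end = n_sites,
                                  feature = "intron", frame = NA_integer_),
            ...)
}

# Small simulated locus set shared across test files (built once per run).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_loci = 20L, exon_len = 120L, intron_len = 120L,
                        grid_2N = 80L, seed = 402L)
      cache <<- generate_locus_set(cfg)
    }
    cache
  }
})

expect_close <- function(object, expected, tol = 1e-6) {
  expect_true(all(abs(object - expected) <= tol),
              label = paste0(deparse(substitute(object)), " = ",
                             paste(signif(object, 6), collapse = ", ")))
}
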