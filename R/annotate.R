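# ---------------------------------------------------------------------------
# Site annotation: codon degeneracy, splice-window exclusion, CpG-prone
# status, per-site allele coverage.  Coordinates are BED-style 0-based
# half-open internally; reports are 1-based.
# ---------------------------------------------------------------------------

SITE_CLASSES <- c("0fold", "2fold", "4fold", "intron", "excluded")

.codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

#' Degeneracy class of a codon position
#'
#' Counts how many of the three alternative bases at `position` preserve the
#' encoded amino acid: 0 alternatives gives "0fold" (nonsynonymous), 3 gives
#' "4fold" (fully synonymous).  The three 3-fold degenerate isoleucine sites
#' are binned with "2fold", so 1 or 2 synonymous alternatives give "2fold".
#'
#' @param codon three-letter string of A/C/G/T.
#' @param position codon position, 1 to 3.
#' @return one of "0fold", "2fold", "4fold", or `NA_character_` when the
#'   codon is a stop codon or contains a non-ACGT character (such sites are
#'   excluded from analysis).
#' @export
classify_degeneracy <- function(codon, position) {
  stopifnot(position %in% 1:3)
  codon <- toupper(codon)
  bases <- strsplit(codon, "")[[1]]
  if (length(bases) != 3L || !all(bases %in% c("A", "C", "G", "T")))
    return(NA_character_)
  gc <- .codon_table()
  aa <- gc[[codon]]
  if (aa == "*") return(NA_character_)
  alts <- setdiff(c("A", "C", "G", "T"), bases[position])
  n_syn <- 0L
  for (b in alts) {
    alt <- bases; alt[position] <- b
    if (gc[[paste(alt, collapse = "")]] == aa) n_syn <- n_syn + 1L
  }
  if (n_syn == 0L) "0fold" else if (n_syn == 3L) "4fold" else "2fold"
}

#' Degeneracy classes for a whole coding sequence
#'
#' @param cds_seq character vector of bases in transcript orientation; the
#'   length need not be a multiple of 3 (trailing partial codons are
#'   excluded).
#' @return character vector the same length: "0fold"/"2fold"/"4fold" or
#'   "excluded" (stop codons, ambiguity codes, gaps, partial codons).
#' @export
classify_cds <- function(cds_seq) {
  n <- length(cds_seq)
  out <- rep("excluded", n)
  n_full <- (n %/% 3L) * 3L
  if (n_full == 0L) return(out)
  for (i in seq(1L, n_full, by = 3L)) {
    codon <- paste(cds_seq[i:(i + 2L)], collapse = "")
    cls <- vapply(1:3, function(p) classify_degeneracy(codon, p), character(1))
    if (anyNA(cls)) next                   # stop codon or ambiguity: excluded
    out[i:(i + 2L)] <- cls
  }
  out
}

#' Splice-window exclusion flags for an intron
#'
#' The first 6 bp and last 16 bp of each intron are potential splice signal
#' and are excluded; introns shorter than 22 bp are excluded entirely.
#'
#' @param intron_len intron length in bases.
#' @return logical vector of length `intron_len`; `TRUE` marks excluded
#'   positions.
#' @export
mark_splice_window <- function(intron_len) {
  stopifnot(intron_len >= 0)
  if (intron_len < 22L) return(rep(TRUE, intron_len))
  excl <- rep(FALSE, intron_len)
  excl[seq_len(6L)] <- TRUE
  excl[(intron_len - 15L):intron_len] <- TRUE
  excl
}

#' CpG-prone status for every alignment column
#'
#' A site is CpG-prone when it is preceded by a C or followed by a G in any
#' aligned sequence (sampled alleles, outgroups, or reference).  Sites at
#' the alignment edge, whose context is unknown, are conservatively scored
#' prone.
#'
#' @param seq_mat character matrix, sites in rows, sequences in columns.
#' @return logical vector, one entry per site.
#' @export
cpg_prone_status <- function(seq_mat) {
  n <- nrow(seq_mat)
  prone <- rep(FALSE, n)
  if (n >= 2L) {
    prev_c <- rowSums(seq_mat[1:(n - 1L), , drop = FALSE] == "C") > 0
    next_g <- rowSums(seq_mat[2:n, , drop = FALSE] == "G") > 0
    prone[2:n] <- prone[2:n] | prev_c
    prone[1:(n - 1L)] <- prone[1:(n - 1L)] | next_g
  }
  prone[1L] <- TRUE
  prone[n] <- TRUE
  prone
}

#' Per-site count of non-missing sampled alleles
#'
#' @param allele_mat character matrix of sampled alleles (sites x alleles);
#'   outgroups and the reference are not counted.
#' @return integer vector of coverage per site.
#' @export
per_site_coverage <- function(allele_mat) {
  as.integer(rowSums(matrix(allele_mat %in% c("A", "C", "G", "T"),
                            nrow = nrow(allele_mat))))
}

#' Per-site degeneracy classes from a reference sequence and features
#'
#' CDS chunks are concatenated in feature order to reconstruct codons in
#' transcript orientation; degeneracy is taken from the reference codon.
#' Intron positions get splice-window exclusion; positions covered by no
#' feature are excluded.
#'
#' @param reference character vector of reference bases.
#' @param features data.frame with `start`, `end` (0-based half-open) and
#'   `feature` columns.
#' @param locus_id label used in error messages.
#' @return character vector of site classes.
#' @export
site_classes_from_reference <- function(reference, features,
                                        locus_id = "locus") {
  site_class <- rep("excluded", length(reference))
  cds_rows <- which(features$feature == "CDS")
  if (length(cds_rows)) {
    cds_pos <- unlist(lapply(cds_rows, function(i)
      (features$start[i] + 1L):features$end[i]))
    site_class[cds_pos] <- classify_cds(reference[cds_pos])
  }
  for (i in which(features$feature == "intron")) {
    if (features$end[i] <= features$start[i]) next
    pos <- (features$start[i] + 1L):features$end[i]
    if (any(site_class[pos] %in% c("0fold", "2fold", "4fold")))
      stop("locus ", locus_id, ": intron feature overlaps CDS")
    excl <- mark_splice_window(length(pos))
    site_class[pos] <- ifelse(excl, "excluded", "intron")
  }
  site_class
}

#' Annotate a locus alignment
#'
#' Combines degeneracy classification (from the reference sequence, so that
#' amino-acid polymorphism among sampled alleles does not shift the class),
#' splice-window exclusion, CpG-prone scoring and coverage into an
#' `annotated_locus` object.
#'
#' @param locus_id label.
#' @param seqs character matrix (sites x sequences) with column names; the
#'   sampled alleles are all columns except `reference`, `outgroup_close`
#'   and `outgroup_far`.
#' @param features data.frame with columns `start`, `end` (0-based
#'   half-open), `feature` ("CDS" or "intron"); CDS chunks are concatenated
#'   in order for codon reconstruction.
#' @return an object of class `annotated_locus`: list with `locus_id`,
#'   `alleles`, `reference`, `outgroup_close`, `outgroup_far`, `site_class`,
#'   `cpg_prone`, `coverage`, `features`.
#' @export
annotate_locus <- function(locus_id, seqs, features) {
  stopifnot(is.matrix(seqs), !is.null(colnames(seqs)))
  special <- c("reference", "outgroup_close", "outgroup_far")
  stopifnot(all(special %in% colnames(seqs)))
  n_sites <- nrow(seqs)
  if (any(features$end > n_sites))
    stop("locus ", locus_id, ": feature beyond alignment end")
  alleles <- seqs[, setdiff(colnames(seqs), special), drop = FALSE]
  if (ncol(alleles) %% 2L != 0L)
    stop("locus ", locus_id, ": odd number of sampled alleles")

  site_class <- site_classes_from_reference(seqs[, "reference"], features,
                                            locus_id = locus_id)

  base_counts <- matrix(0L, nrow = 4L, ncol = n_sites,
                        dimnames = list(c("A", "C", "G", "T"), NULL))
  for (b in rownames(base_counts))
    base_counts[b, ] <- as.integer(rowSums(alleles == b))

  structure(list(
    locus_id = locus_id,
    alleles = alleles,
    base_counts = base_counts,
    reference = seqs[, "reference"],
    outgroup_close = seqs[, "outgroup_close"],
    outgroup_far = seqs[, "outgroup_far"],
    site_class = site_class,
    cpg_prone = cpg_prone_status(seqs),
    coverage = as.integer(colSums(base_counts)),
    features = features
  ), class = "annotated_locus")
}

#' @export
print.annotated_locus <- function(x, ...) {
  cat("<annotated_locus> ", x$locus_id, ": ", length(x$site_class),
      " sites, ", ncol(x$alleles), " sampled alleles\n", sep = "")
  print(table(factor(x$site_class, levels = SITE_CLASSES)))
  invisible(x)
}

#' Read a locus set from FASTA alignments and a BED feature file
#'
#' Expects one FASTA per locus (`<locus_id>.fa`) holding the aligned sampled
#' alleles plus `reference`, `outgroup_close` and `outgroup_far` records,
#' and a single BED file (0-based half-open) with columns locus, start,
#' end, feature, frame.
#'
#' @param dir directory containing the FASTA files and `features.bed`.
#' @return list of `annotated_locus`.
#' @export
read_locus_set <- function(dir) {
  bed_path <- file.path(dir, "features.bed")
  stopifnot(dir.exists(dir), file.exists(bed_path))
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("locus", "start", "end",
                                         "feature", "frame"))
  fastas <- sort(list.files(dir, pattern = "\\.fa$", full.names = TRUE))
  loci <- lapply(fastas, function(f) {
    id <- sub("\\.fa$", "", basename(f))
    ss <- Biostrings::readDNAStringSet(f)
    seqs <- do.call(cbind, lapply(as.character(ss), function(s)
      strsplit(s, "")[[1]]))
    colnames(seqs) <- names(ss)
    annotate_locus(id, seqs, bed[bed$locus == id, , drop = FALSE])
  })
  names(loci) <- vapply(loci, `[[`, character(1), "locus_id")
  loci
}

#' Write a per-site annotation table
#'
#' @param loci list of `annotated_locus`.
#' @param path output TSV path (columns: locus, pos (1-based), class,
#'   cpg_prone, coverage).
#' @export
write_annotation_tsv <- function(loci, path) {
  tab <- do.call(rbind, lapply(loci, function(lc)
    data.frame(locus = lc$locus_id, pos = seq_along(lc$site_class),
               class = lc$site_class, cpg_prone = lc$cpg_prone,
               coverage = lc$coverage)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fractions of coding sites per degeneracy class under the standard code
#'
#' Averaged over the 61 sense codons with equal weight; used by the
#' synthetic-data generator to size site classes.
#' @keywords internal
codon_class_fractions <- function() {
  gc <- .codon_table()
  sense <- names(gc)[gc != "*"]
  cls <- unlist(lapply(sense, function(cd)
    vapply(1:3, function(p) classify_degeneracy(cd, p), character(1))))
  tab <- table(factor(cls, levels = c("0fold", "2fold", "4fold")))
  as.vector(tab) / sum(tab)
}
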