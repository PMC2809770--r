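Package: popDFE
Title: Selection on Protein-Coding Genes from Polymorphism and Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the strength of negative and positive selection acting on
    protein-coding genes from within-species nucleotide polymorphism and
    between-species divergence. Implements site degeneracy annotation
    (0-fold/2-fold/4-fold/intron with splice-window exclusion and CpG-prone
    scoring), standard diversity statistics (Watterson's theta, nucleotide
    diversity, Tajima's D with fixed-n downsampling, Jukes-Cantor divergence,
    Weir-Cockerham F_IS) with per-locus bootstrap intervals, maximum-likelihood
    fitting of a gamma distribution of deleterious fitness effects together
    with a step-change demographic model on folded site frequency spectra via
    Wright-Fisher transition matrices, and estimation of the fraction of
    adaptive amino acid substitutions (alpha) both from fixation probabilities
    under the fitted model and by the Fay-Wyckoff-Wu extension of the
    McDonald-Kreitman test. A seeded synthetic-data generator emulating a
    multi-locus Sanger resequencing study of a wild house mouse population,
    with a forward Wright-Fisher simulator, provides ground-truth datasets
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
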