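---
title: "Models and methods behind popDFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popDFE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`popDFE` estimates the strength of purifying selection on amino acid
mutations (a distribution of fitness effects, DFE) and the fraction of
adaptive amino acid substitutions (α) from two ingredients: the folded
site frequency spectrum (SFS) of a population sample, contrasted between
selected (0-fold degenerate) and putatively neutral (4-fold degenerate or
intronic) sites, and the divergence of the same sites to one or two
outgroup species. This vignette records the model, its assumptions, the
tunable parameters, and the numerical and design choices, so that a reader
can judge exactly what a passing test establishes.

## The population-genetic model

**Selection scheme.** A mutant allele with selection coefficient `s` has
genotype fitnesses 1, 1 − s/2 and 1 − s (wild-type homozygote,
heterozygote, mutant homozygote): semidominant, additive on the allele
scale with per-copy effect s/2. Deleterious effects are unconditionally
deleterious and scaled as γ = N·s with N the diploid population size; the
diffusion-limit fixation probability of a new semidominant mutation,
relative to a neutral one, is R(S) = S/(1 − e^{−S}) with S = −2γ
(`relative_fixation_rate()`). The discrete Wright–Fisher chain converges
to this value as the grid grows; at 2N = 100 and |S| = 10 the chain is
~30% below the diffusion value because s = 0.1 is not small — the test
suite asserts the convergence behaviour, not a fictitious sub-percent
agreement at small grids.

**DFE.** Deleterious effects of new amino acid mutations follow a gamma
distribution over γ with shape `b` and mean E[N_e s]. The shape
parameter is the quantity of scientific interest (low shape = strongly
leptokurtic: many nearly-neutral and many strongly deleterious mutations);
the mean is notoriously weakly identified because every effect beyond
γ ≈ N_w contributes no polymorphism at all — the data bound the DFE's
lower tail and the gamma form extrapolates the rest. Summaries therefore
emphasise the three N_e·s classes [0,1), [1,10), [10,∞)
(`nes_class_proportions()`).

**Demography.** A single step change: ancestral size N₁, current size N₂,
`t` generations ago, all in transition-matrix grid units (only the ratio
N₂/N₁ and the scaled time are identifiable). Expected population
allele-frequency densities come from iterating the Wright–Fisher
transition matrix from the N₁ equilibrium for t generations at N₂, with
one new mutation entering per generation (`wf_stepchange_density()`);
binomial sampling to the per-site allele number and folding give expected
sample spectra. At t = 0 the ancestral equilibrium is returned unchanged
— the change has not yet acted — which makes the constant-size case exact
for any N₂.

**Weighted recent size.** When t ≫ N₂ or t ≪ N₂ the two sizes are barely
distinguishable; a single effective scale is needed to express γ. We use
pair-coalescence weighting, N_w = N₁·e^{−t/(2N₂)} + N₂·(1 − e^{−t/(2N₂)}):
the weight on the current size is the probability that two lineages
coalesce after the change. Limits: t = 0 gives N₁, t → ∞ gives N₂. The
original description of this quantity is not rendered in our source
material, so this convention is the package's own documented stand-in;
every output that reports N_w labels it as such.

**Mutation and f₀.** Sites are independent (free recombination between
sites, no recombination needed within the model), biallelic, and at most
one mutation segregates per site (infinite-sites thinking on a per-site
basis). The nuisance parameter f₀ is the fraction of sites carrying no
currently segregating mutation; it fixes the mutational influx
λ = (1 − f₀)/V where V is the total neutral segregating density per unit
influx. The same λ applies to the selected class (equal mutability), which
is exactly what lets the *reduction* in the number of 0-fold polymorphisms
— not just the shape of their spectrum — inform the DFE.

**Likelihood.** For each per-site allele number n present in the data, the
folded spectrum (monomorphic class included) is multinomial with the
f₀-scaled expected proportions; log-likelihoods are summed over n-groups
and over the neutral and selected classes. The multinomial coefficient is
dropped throughout (it cancels in every comparison the package makes).

## Fitting: staged maximum likelihood

A joint 5-parameter search (shape, mean, N₂/N₁, t, f₀) would recompute
~25 transition-matrix spectra per likelihood evaluation. Because the
neutral SFS alone carries the demographic information, the fit is staged:

1. **Demography + f₀ on the neutral SFS.** The ratio is searched on
   [0.1, 5] and t on [0, 5·grid] — outside that box the folded spectrum at
   these sample sizes is essentially flat, and unbounded searches run to
   the boundary at great computational cost. A coarse (r, t) grid with f₀
   profiled in 1-D seeds a local Nelder–Mead refinement (t quantised to
   4-generation steps so the optimiser re-hits cached densities; this is
   far below the statistical resolution of t).
2. **DFE + f₀ with the demography fixed.** The gamma integral uses a
   *fixed* log-spaced grid over γ from 10⁻⁴ to 0.98·N_w (n_quadrature
   nodes, default 24; ≥ 16 enforced), weighted by exact gamma-CDF bin
   masses, plus an effectively neutral node for lower-tail mass and an
   effectively lethal node (no polymorphism, no fixation) for mass beyond
   the representable maximum s = 0.98. Because the node positions do not
   depend on (shape, mean), node spectra are computed once per demography
   and cached; optimising the DFE parameters and re-fitting under
   bootstrap then costs microseconds per evaluation. Multi-start
   Nelder–Mead (5 starts spanning shape 0.15–1, mean 10–10⁴) guards
   against the shape/mean ridge.

Bootstrap confidence intervals resample loci with replacement and re-run
the chain — SFS construction, stage-2 DFE refit, divergences. Because t
and N₂/N₁ are the least identified quantities in the model, holding the
demography at the point estimate understates the interval; by default each
α bootstrap replicate therefore re-selects the demography from the coarse
candidate grid (ranked by the replicate's neutral likelihood at the
point-estimate f₀ — the cached node spectra make this nearly free) before
the DFE refit (`refit_demography = "grid"`). A full Nelder–Mead demography
refit per replicate would multiply cost by ~100 for little further gain.

## α estimation

*Model-based*: α = (d_N − d_S·E[R])/d_N with E[R] the mean relative
fixation rate under the fitted DFE, computed by probability-integral-
transform quadrature of R(−2γ) over the fitted gamma (smooth and bounded
for any shape, including shape < 1 where the density diverges at zero).
Negative estimates are reported, never truncated. The estimator assumes
adaptive mutations contribute negligibly to polymorphism and is evaluated
per outgroup (close/far) and neutral reference (4-fold/intron), with an
optional non-CpG-prone filter.

*Fay–Wyckoff–Wu*: α_FWW = 1 − (D_S·ΣP_N)/(D_N·ΣP_S) on per-locus counts
after downsampling every site to exactly 20 alleles (multivariate
hypergeometric, seeded; sites with lower coverage or no called outgroup
base are ignored). "Excluding variants at 10% or less" keeps sites whose
minor variant is strictly above 0.10 after downsampling, i.e. minor count
≥ 3 of 20. Divergence and polymorphism counts are raw (McDonald–Kreitman
tables are count-based); a site whose outgroup base differs from every
sampled allele counts once as divergent even if also polymorphic.

*Bias relation*: if the current N_e differs from the long-term N_e by a
factor λ and the DFE is gamma with shape b, then
α_est = 1 − (1 − α_true)·λ^{−b}; the package provides both directions.
The functional form was reconstructed from the four published worked
values (which it reproduces to two decimals — see the acceptance tests);
outputs using it are labelled accordingly.

*Contrasts* between datasets use two bootstrap distributions paired by
replicate: p = 2·min(Pr(Δ ≤ 0), Pr(Δ ≥ 0)) with +1 continuity correction,
capped at 1 — the granularity matches the replicate count, so 1,000
replicates can resolve p ≈ 0.002 at best.

## The synthetic-data generator

`generate_locus_set()` emulates the statistical structure of the target
study: 77 amplicons of exon+intron sequence, 15 diploid individuals
(30 alleles), per-site missing data (default 5%), a close outgroup at 3%
neutral divergence and a distant one at 19% (4-fold sites), a gamma DFE on
0-fold sites (shape 0.3, mean N_e·s 10³), a recent 2-fold expansion, an
adaptive fraction α_true of 0-fold divergence (default 0.57), and
per-individual inbreeding F (default 0.2, chosen to give the clear excess
of positive per-SNP F_IS values that motivates the one-allele-per-individual
resampling; the study reports the signature but no F value). Inbreeding
matters: with F > 0 the two alleles of an individual are not independent
draws, the folded SFS is overdispersed, and a 30-allele fit reads this as
a (spurious) population contraction. `one_allele_resample()` implements
the protocol remedy — composite sequences with one randomly chosen allele
per individual — at the cost of roughly halving the number of segregating
sites; at the 77-locus scale that trade is unfavourable for a single
composite (the DFE fit noise grows more than the inbreeding bias shrinks),
so the validation harness (`recovery_run()`) analyses the full 30-allele
data and instead (i) uses the intronic class as the neutral reference —
five times more neutral sites than 4-fold, stabilising the demography, f₀
and d_S — and (ii) propagates demographic uncertainty through the
bootstrap (below). Analyses of real data with strong F_IS should report
the one-allele-resampled estimates alongside. Polymorphism
is drawn site-by-site from the same Wright–Fisher densities the fitter
uses (segregation probability λ·V(γ), then a population frequency from the
density, then binomial sampling into the 30 alleles, with
identical-by-descent allele pairs per individual at rate F).

Two deliberate simplifications:

- **Divergence lives on the outgroup lineages.** Substitutions on the
  sample lineage would change codon degeneracy classes mid-simulation (a
  substitution at codon position 1 can turn a 4-fold third position into
  2-fold), dragging realised class-specific divergences off their targets
  and decoupling the generator's ground truth from the annotation. Since
  every estimator in scope consumes only pairwise divergence, the
  generator keeps the sample at the ancestral state and lets each outgroup
  accumulate the class-specific substitution rate directly — the observed
  pairwise divergence is then calibrated exactly, and 2-fold/4-fold sites
  annotated from the reference are identical to the generator's truth.
- **Adaptive substitutions are instantaneous fixations** at the rate that
  makes the adaptive fraction of 0-fold divergence equal α_true,
  contributing nothing to polymorphism — precisely the assumption of the
  model-based estimator, so recovery tests validate the inference
  machinery, not that assumption.

Not emulated (hence not established by green tests): recombination and
linkage within loci, selective sweeps and background selection, migration
and population structure, codon usage bias, CpG hypermutability (CpG
status is annotated but not differentially mutated), real amplicon length
variation, and sequencing error.

## Numerical choices and degenerate inputs

- **Grids.** Transition matrices default to 2N₁ = 200 (`grid_2N`), with
  N₂ as a ratio; validation harnesses use 2N₁ = 100 to stay inside
  runtime budgets (documented wherever used). Densities beyond 8·2N₂
  generations are replaced by the new equilibrium (relative error < e⁻⁸).
- **Degeneracy conventions.** The three 3-fold degenerate isoleucine
  positions are binned with 2-fold (only 0/2/4-fold classes are
  reported). Stop codons, codons with gaps or ambiguity codes, and
  partial codons at feature boundaries are excluded. Classes come from
  the reference codon, so amino acid polymorphism does not reassign
  classes. Alignment-edge sites with unknown CpG context count as
  CpG-prone (conservative for non-CpG analyses).
- **Folding.** The exact-half cell at even n is counted once; minor
  counts at a site's own coverage n go into that n's spectrum, monomorphic
  sites into index 0 of their own n-group. Triallelic sites are excluded
  and counted. Allele-number groups below 50 sites (configurable) are
  merged into the nearest smaller retained group by hypergeometric
  projection; a small group with no smaller stable neighbour is kept.
- **Divergence.** A site needs a called outgroup base and at least one
  called allele; p ≥ 0.75 makes the Jukes–Cantor correction undefined and
  raises an error. Tajima's D is NA when no site segregates after
  downsampling; diversity skips sites with coverage < 2 and records them.
- **Optimiser tolerances.** Nelder–Mead relative tolerance 10⁻⁸–10⁻⁹;
  stage-2 starts dispersed over two decades of mean and one of shape;
  quadrature self-convergence (doubling nodes moves expected cells by
  < 10⁻⁴) is asserted in the tests.
- **Seeding.** Every stochastic step draws from a named substream of one
  master seed (`substream_seed()`), so adding bootstrap replicates never
  perturbs the simulated data, and identical configurations are
  byte-identical end to end.

## Known limitations

The demography is at most two epochs and is weakly identified from folded
spectra at 30 alleles — the bounded search and the weighted-N reduction
are honest about this rather than pretending precision. The DFE mean is
reported but should be interpreted through the class proportions. The
model-based α inherits any misfit of the DFE's nearly-neutral tail, and
α_FWW is known to be downward-biased when slightly deleterious variants
segregate (the ≥10% threshold only mitigates this); both behaviours are
asserted as directional properties in the test suite. Positively selected
polymorphism, multi-epoch histories, and unfolded/polarised spectra are
out of scope.
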