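---
title: "Simulating intercrop breeding programs with genomic selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating intercrop breeding programs with genomic selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intercropping grows two component crops (here labelled A and B) together in
one field. Breeding for it requires improving both crops *for the mixture*:
a variety is valuable not for its monocrop yield per se but for its
**general intercropping ability (GIA)** — its average intercrop yield across
partners from the other crop — and ultimately for the **specific
intercropping ability (SIA)** of one released pair. `icbreedsim` simulates
five closed breeding programs for this problem over a shared 20-year
phenotypic-selection burn-in and a 20-year future phase, at equal annual
operating cost, and measures genetic gain, genetic variance and selection
accuracy for intercrop yield:

* **Pheno** — phenotypic selection throughout (the comparison baseline);
* **Baseline-GS**, **PYT-GS**, **DH-GS** — "Conventional" programs that
  keep the Pheno pipeline (DH, PYT, GIA1, GIA2, SIA1, SIA2) but replace
  phenotypic selection with genomic prediction of GIA at progressively
  earlier stages, shortening the generation interval from 5 years (Pheno,
  Baseline-GS) to 3 (PYT-GS) and 2 (DH-GS);
* **Grid-GS** — replaces the PYT/GIA stages with a single "grid" stage in
  which genomic predictions rank all pairwise combinations of the selected
  DH lines of the two crops and only a random sample of pairs is
  field-tested.

## Genomes, founders and traits

Each crop has 10 chromosomes of 1.43 Morgans and 8×10⁸ bp, so the per-base
recombination rate is 1.43/8×10⁸ ≈ 1.8×10⁻⁹; the per-base mutation rate is
2×10⁻⁹. Founder haplotypes are drawn from a neutral coalescent whose
effective population size ramps linearly from 50 at present to 32,000 at
100,000 generations ago. Because the ramp rises steeply near the present,
the piecewise-constant discretization supplied to the coalescent engine
uses a log-spaced time grid (default 150 epochs); a coarse linear grid
visibly under-resolves the recent history and halves the number of
segregating sites. The two crops' genomes are independent draws with
identical parameters. Per chromosome, 1,000 QTN and 2,000 SNP-array sites
are sampled uniformly without replacement among the segregating sites
(disjoint sets), and the 100 founders per crop are converted to doubled
haploids (DH).

Meiosis uses Poisson crossover counts with mean equal to the chromosome's
genetic length and uniform crossover placement — no interference, the
standard simulator default; nothing in the modelled quantities depends on
an interference model.

Two additive traits are simulated per crop: monocrop grain yield and
intercrop grain yield. QTN effects are drawn from a bivariate standard
normal with correlation 0.4, 0.7 or 0.9 (the study's axis of interest) and
rescaled per trait so the founder additive variance is exactly 1. DH
genotypes are dosage-coded ±1 (centered); the affine choice of coding is
absorbed by the scaling. The intercrop yield of a pair (i from A, j from B)
is `(a_ic_A_i + a_ic_B_j)/2 + e`.

Stage phenotypes use the entry-mean heritability definition
`h² = σ²_A / (σ²_A + σ²_e/r)`, inverted to give the stage error variance.
Heritabilities and effective replications per stage are DH 0.10/1,
PYT 0.33/4, GIA1 0.33/4, GIA2 0.50/24, SIA1 0.67/16, SIA2 0.80/32 and
Grid 0.10/1. Error variances are fixed from the *founder* σ²_A = 1, so
realized heritability drifts downward as genetic variance erodes — the
convention of entry-mean parameterization in the founder population. GIA
trials evaluate each crop's candidates against the *other* crop's probe
varieties (1 probe in GIA1, 3 in GIA2; the four best GIA2 performers become
next year's probes); the probe contribution is a within-year constant and
is absorbed by the year-by-stage fixed effects of the genomic models. GIA
means over probes are simulated as one error draw at the stage's
effective-replication variance rather than per-plot draws — the two are
equivalent for every quantity the package reports.

## Genomic models

Both genomic models are RR-BLUP mixed models solved exactly by a direct
dense solve of the mixed-model equations (no iterative solver is needed at
the sizes involved; the test suite checks the solutions against an
independent generalized-least-squares/BLUP oracle to 10⁻⁸).

The **Conventional model** (per crop) fits monocrop yield records from the
PYT stage together with intercrop yield records from GIA1 and GIA2:
year-by-stage fixed effects per stream; per-SNP correlated effects
`(a_m, a_ic)` with prior (co)variance `G / Σ 2p_k q_k`, where `G` is the
2×2 additive (co)variance of the true genetic values of the current
training genotypes (variances assumed known rather than REML-estimated)
and the divisor is computed in the current training genotypes — the
standard RR-BLUP/GBLUP equivalence; and residual variances `σ²_e/r` per
record. `G` is pooled *within year*: because year-by-stage is a fixed
effect, marker effects only ever explain within-cohort contrasts, and
pooling raw genetic values across the window would let genetic trend and
selection-set differences between cohorts inflate the prior variance,
under-shrink the effects and degrade accuracy (the Grid initialization
sets, whose year means bounce under selection on a still-noisy model, can
inflate it several-fold).
Because a GIA record is a candidate-plus-probe pair mean, it carries half
of the candidate's genetic signal; its design row therefore loads the
centered dosages with coefficient ½, keeping `a_ic` on the genetic-value
scale and the cross-trait covariance correctly specified. The same ½
convention defines the **Grid model**, which regresses intercrop records
(grid, SIA1, SIA2 stages; each indexed by one genotype per crop) on both
crops' markers simultaneously with independent per-crop marker-variance
priors. gGIA predictions carry no intercept — every use is a ranking, so
any constant shift is immaterial.

Training sets are 5-year sliding windows. For the Conventional model the
genotype block is the last five PYT cohorts and records whose genotype has
left the block (through the 1- and 2-year stage lags of GIA1/GIA2) leave
with it: at steady state 2,500 genotypes with 2,500 + 4×50 + 3×13 = 2,739
records. For the Grid model the genotype block is the last five grid-stage
cohorts (500 per crop per year) and all grid/SIA records of the window are
kept — 4,790 at steady state — with dosages of the few SIA genotypes from
just-older cohorts fetched from the genotype store. The Grid training
population is initialized during the last five burn-in years: 23 genotypes
per crop per year (chosen by PYT monocrop phenotype in the first year, by
gGIA from the accumulating grid model afterwards) are crossed in all
23² = 529 combinations, giving 115 genotypes per crop and 2,645 records at
branch time. The burn-in's own SIA trials are not part of that
initialization set. Model fitting happens at the start of each year on the
window ending the previous year, and all of that year's selections use it.

## Program orchestration

One calendar year advances every stage by one step. Crosses decided at the
end of year *t* produce a DH cohort in year *t+2* (one season for crossing,
one for DH production), reproducing the printed stage calendar. Parents
selected on GIA1 results (Pheno, Baseline-GS) enter the crossing block the
*following* season — their GIA2 year — which is what makes those programs'
generation interval 5 years while PYT-GS (parents from PYT ∪ last block,
ranked jointly) and DH-GS/Grid-GS (parents from the DH stage) use new
parents immediately, giving intervals 3 and 2. In the oldest-replacement
scheme, 20 of 80 parents are replaced per year, so each parent serves four
crossing cycles.

DH-GS and Grid-GS select 80 parents by gGIA under a **maximum-avoidance**
constraint: every bi-parental family contributes equally (its best members
by gGIA), and crossing pairs families on a circle with a rotation offset
that increments each generation, so the least related families meet and no
within-family cross ever occurs. When more crosses are needed than family
pairs, additional rotations run with a least-used-member rule that keeps
parent contributions equal within one. Truncation selection without this
constraint exhausts variance quickly; the constraint trades a little
selection intensity for sustained variance.

The Grid-GS year: gGIA from the current model selects the top 500 DH per
crop; 900 of the 250,000 candidate pairs are sampled uniformly without
replacement for field testing (feeding the training set); the top 50 pairs
of the full 250,000 by predicted pair gGIA — the mean of the two
components' gGIA — advance to SIA1; SIA selections are always phenotypic.
At the branch from burn-in, the first SIA1 set is the best-predicted pairs
of the last initialization grid, and the first future year has no SIA2
cohort — a one-year transition edge with no effect on the reported
metrics, which are DH-stage quantities.

Selection ties are broken by genotype id, making every run reproducible
from its seeds.

## Costing

Annual cost uses unit costs of $20 per monocrop plot, $50 per intercrop
plot, $35 per DH line and $20 per genotyped sample. The accounting that
reproduces all five printed totals exactly (493,200 / 492,200 / 492,200 /
495,200 / 493,800) is: DH production and PYT plots per crop (×2), GIA
plots per crop (×2, because each crop's candidates are tested against the
other crop's probes), SIA and grid combinations shared (×1), DH-stage
single plants unpriced, and genotyping of 2×500 PYT entries (Baseline-GS,
PYT-GS) or 2×all DH lines (DH-GS, Grid-GS). `budget_scale()` re-sizes DH
lines per cross — the designs' own budget lever — rounding to the nearest
integer, which recovers the printed 47/47/80/90 from the Pheno total.

## Comparison metrics

Per year and program the package records, at the DH stage: the mean
intercrop genetic value `(ā_ic_A + ā_ic_B)/2`, centered at the end-of-burn-in
value; the intercrop genetic variance, taken as the population variance
(divide by n) of the individual intercrop genetic values of the pooled DH
cohorts — the phrase "variance of the mean intercrop genetic values" is
ambiguous between individual- and replicate-level dispersion, and the
individual-level reading is adopted; and prediction accuracy, the Pearson
correlation between gGIA (or the DH monocrop phenotype, for Pheno) and the
true intercrop genetic values. Program contrasts are reported as
back-transformed paired log-ratios over seed-paired replicates, with the
paired-t confidence interval on the log scale; replicates with non-positive
gain cannot be log-transformed and are excluded with a logged count (none
are excluded in the shipped configurations).

Replicates are paired by common random numbers: founders per replicate,
one architecture and one burn-in per (replicate, correlation), and each
program arm branched from that identical burn-in snapshot on its own
derived stream.

## The desk preset

Full-scale runs (10,000 QTN, 5,000 DH per crop, 30 replicates) are not the
package's test vehicle. The replicated comparisons use a **desk preset**
chosen once as a one-tenth scaling that preserves the design contrasts:

* genome: 2 chromosomes × (100 QTN + 200 SNP), same map lengths, rates and
  demography;
* Pheno: 20 crosses × 25 DH, block 20 (5 replaced/year), PYT 50, GIA1 10,
  GIA2 5, 3 SIA lines (9 SIA1 pairs), 3 SIA2 pairs, 4 probes;
* GS arms: stage sizes scaled the same way (DH-GS/Grid-GS keep the
  2-parents-per-family geometry with a 40-parent block from 20 crosses;
  Grid keeps 50/crop, field-tests 90 pairs, advances 5, SIA2 2,
  initialization 8 per crop) and DH-per-cross set by `budget_scale()`
  against the desk Pheno total, exactly as the full designs are matched at
  the full budget;
* 20 + 20 years, 10 seed-paired replicates.

What desk-scale results do and do not show: the count, cost, window and
solver properties are scale-free and are checked exactly. The stochastic
gain/variance/accuracy contrasts reproduce the direction and rough
magnitude of the full-scale comparison, but training populations of a few
hundred genotypes give genomic accuracies well below full scale, and the
budget lever leaves DH-GS with only 16 DH per cross (against 80 at full
scale), so within-family selection intensity — and with it part of the
DH-GS and Grid-GS advantage — is compressed. Monte-Carlo error with 10
replicates on ratio statistics is roughly ±10–15%.

The synthetic founder generator emulates the stated demography, map and
marker density; it does not emulate sequence content, structural variation,
population substructure, genotyping error, or non-additive gene action
(dominance, epistasis, genotype-by-environment, genotype-by-genotype
between the crops) — all outside the simulated model, and the last group
deliberately so.

## Numerical choices and degenerate inputs

* Mixed-model equations are solved with a dense Cholesky-backed `solve()`;
  if `G` becomes numerically singular (perfectly correlated traits, or a
  variance-depleted population) its diagonal is jittered by 10⁻⁸ of its
  mean before inversion, and a singular system falls back to a
  pseudo-inverse with a warning.
* `G` must be positive semi-definite (eigenvalue check at 10⁻⁸ relative
  tolerance); non-PSD input is an error.
* Founder-variance scaling and the h² inversion are exact (tolerances
  10⁻¹⁰ and 10⁻¹² in the tests).
* Zero-variance inputs to accuracy return `NA` with a warning rather than
  an error, since late-program cohorts can be variance-depleted.
* Seeds are derived from one base seed by a 31-bit polynomial hash over
  (replicate, correlation, arm) so every stream is independent and below
  2³¹.

## Known limitations

* The coalescent backend runs through the system `python` (msprime); the
  package fails with a clear error if none is available.
* The burn-in's Grid training initialization is executed retrospectively at
  branch time from archived burn-in cohorts. This keeps the burn-in state
  bit-identical across arms, at the price that the initialization's
  529-combination trials do not consume burn-in field capacity — consistent
  with treating them as a bookkeeping device for the starting training set.
* Replacing both pending cross cohorts at the branch applies the new
  design's crossing scheme to the inherited block one year earlier than a
  strict reading of the calendar would; the effect is a one-year transient.
* Costs are operating costs only (no land, labor, discounting), and the
  'large'/'small' budget scenarios, selection indices, optimal-contribution
  selection and non-additive genetic models are out of scope.
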