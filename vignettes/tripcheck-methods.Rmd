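---
title: "Verifying ploidy and chromosomal aberrations in pressure-induced triploid salmon"
author: "tripcheck"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying ploidy and chromosomal aberrations in pressure-induced triploid salmon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Commercial triploid Atlantic salmon are produced by applying a hydrostatic
pressure shock shortly after fertilization. The shock suppresses extrusion of
the second polar body during meiosis II, so the embryo keeps two maternal
chromosome sets and one paternal set. When the shock is applied at a
sub-optimal pressure, retention can fail completely (a diploid "failed
triploid"), fail partially (aneuploidy: a mixture of disomic and trisomic
chromosomes), or go wrong in rarer ways — loss of maternal material at many
loci (uniparental disomy, UPD), or androgenetic development with no maternal
genome at all. These outcomes matter both economically (mortality) and for
biocontainment (non-triploid escapees are fertile).

`tripcheck` implements a microsatellite-based workflow for quantifying these
outcomes, plus a forward simulator of the half-sibling, pressure-gradient
breeding design that such studies use, so that every analysis stage can be
validated against known latent truth.

## Allele dosage from peak heights (MAC-PR)

Fragment analysis reports, for each individual and microsatellite marker, the
detected allele lengths and their peak heights. For a heterozygous marker the
*relative* heights carry copy-number information: a disomic AB genotype gives
a height ratio near 1:1, while trisomic AAB and ABB give near 2:1 and 1:2,
and a three-allele ABC call is trisomic outright. The classifier computes
`r = height(smaller allele) / height(larger allele)` and maps it through
three disjoint bands:

| band | default interval | call | copies |
|------|------------------|------|--------|
| 1:2  | (0.38, 0.63) | ABB | 1;2 |
| 1:1  | (0.75, 1.40) | AB  | 1;1 |
| 2:1  | (1.60, 2.60) | AAB | 2;1 |

Ratios in the guard gaps between bands — or exactly on a boundary — are
*unresolved* and flagged, never guessed. The bands are centred on the
theoretical ratios with deliberate gaps; they are configurable
(`dosage_calibration()`) because real assays differ in amplification balance.
Peaks below 100 RFU are discarded, and a peak exactly one repeat motif below
a retained peak at under 15% of its height is treated as PCR stutter. An
optional multiplicative size-bias correction (shorter fragments amplify
slightly better) is available but off by default.

Homozygous markers give a single peak whose copy number fragment analysis
cannot resolve, so their somy is unknown; they still inform family assignment
and aberration checks. Markers whose heterozygous calls are frequently
unresolved, or whose alleles often sit one motif apart (so stutter merges
with true-allele signal), fail the informativeness screen and are excluded
from somy aggregation.

## Ploidy classification

For each individual, over the informative heterozygous markers with resolved
somy, the trisomic proportion `p = n_trisomic / n_informative_het` determines
the class: diploid at `p = 0`, triploid at `p = 1`, aneuploid in between, and
undetermined when no informative heterozygous marker was resolved (e.g. an
individual homozygous at every locus). Individuals scoring fewer than 50% of
the informative panel are excluded beforehand; the boundary is strict
(exactly 50% is retained) and configurable. Aneuploids deviating at exactly
one locus (one trisomic locus in an otherwise diploid genotype, or one
disomic locus in an otherwise triploid one) are distinguished from
intermediate forms, which matters because viability selection acts most
strongly on the intermediate class.

## Family assignment and aberration typing

Offspring are assigned to half-sib families by exclusion: for each candidate
dam (the sire is shared), a locus is compatible if the offspring multiset can
be built from one dam and one sire allele (diploid), from a maternal dyad —
any pair of the dam's two alleles, since recombination before polar-body
retention permits heterozygous dyads — plus one sire allele (triploid), or,
when dosage is unresolved, if every allele occurs in the parental pool.
A family survives with at most `tolerance` (default 1) incompatible loci;
assignment requires exactly one surviving family, ties are reported, never
broken randomly. A locus explicable only by moving one *non-parental* allele
1–2 repeat motifs is a slippage candidate and is excused (one per offspring
by default) rather than counted as an exclusion, because repeat slippage is
a common, benign mutation process that should not exclude the true family.

Against the assigned (or hatchery-known) parents, each locus is then typed:
`ok`; `ambiguous` when a normal gamete combination explains the call but a
single-parent explanation exists too (shared parental alleles — reported,
never counted as an error); `maternal_allele_missing` /
`paternal_allele_missing` when only a single-parent combination fits;
`double_paternal` for a trisomy with two copies only the sire can supply
(impossible under polar-body retention); and `bp_shift_candidate`, which
takes precedence over missing-parent explanations at a locus. Maternal
absence across more than 3 loci collapses into one UPD event; an individual
with maternal-missing loci and *no* dam-only allele anywhere is flagged
`total_maternal_absence` — possibly an androgenetic haploid or doubled
haploid, which fragment-length genotyping cannot resolve, so the package
flags and never resolves it. Trisomic loci in mostly-diploid individuals are
origin-typed by gamete enumeration (maternal / paternal / ambiguous).

## Incidence models

Triploidy and aneuploidy are Bernoulli responses modelled on the logit scale
with pressure treatment, family and developmental stage as categorical fixed
effects. Designs with replicate rearing units add a Gaussian random intercept
per unit. The marginal likelihood of the random-intercept model is computed
in the package by adaptive Gauss–Hermite quadrature: each group's integrand
is centred at its conditional mode (found by Newton iteration) and scaled by
the curvature there, then integrated on a 15-node Hermite grid (1 node
recovers the Laplace approximation; 7 vs 31 nodes move the log-likelihood by
under 1e-3 on study-sized data, so 15 is comfortably converged). When the
likelihood at the zero-variance boundary is not measurably worse than the
interior optimum, the fit is reported as the boundary solution — the plain
GLM with σ = 0 — mirroring how mixed-model software reports singular fits.

Fixed effects are evaluated by refitting without each term and comparing
AIC (`2k − 2·logLik`); the random intercept is never dropped. Quasi-complete
separation — a factor level whose responses are constant, e.g. no triploids
in the untreated control — is detected up front, flagged (standard errors
are then unreliable), and remedied by refitting without the offending level,
with both fits reported side by side. Mortality rates are computed per
rearing unit and stage interval as deaths/starters, and aggregated by
pooling counts before dividing, never by averaging rates.

With 10 groups of 200 observations, the maximum-likelihood estimate of the
random-intercept SD carries the usual O(1/G) downward bias of
variance-component MLEs (a few percent at these sizes, identical in other
mixed-model software); recovery tests allow for that documented bias rather
than asserting exact unbiasedness.

## The synthetic study design

The simulator reproduces the structure the analysis assumes, with every
latent variable retained:

* **Crosses.** Twelve dams by one shared sire; parents diploid, drawn from
  per-marker allele frequency models. The default 30-marker panel makes
  markers 1–20 dosage-informative (5–8 alleles spaced two motifs apart, so
  stutter never overlaps a true allele) and markers 21–30 deliberately
  stutter-conflicted (2–3 alleles one motif apart), mimicking the fraction
  of a real panel that fails dosage screening.
* **Designs.** Experiment 1: 3 families × 5 pressures (0, 6500, 7500, 8500,
  9500 PSI) × 2 replicates, 15 eggs sampled and 100 reared per unit (450
  sampled eggs, 3000 reared). Experiment 2: 12 families × {0, 9500} PSI, 20
  eggs sampled and 100 reared per unit (480 and 2400).
* **Retention.** Polar-body retention is logistic in pressure with midpoint
  7500 PSI and scale 400, giving ≈0 at 0 PSI, ≈7.6% at 6500, 50% at 7500,
  ≈92% at 8500 and ≈99% at 9500 — the qualitative success gradient reported
  for sub-optimal shocks. Illustrative, not fitted.
* **Aberration channels.** Two channels are kept distinct in the truth
  labels. (1) *Treatment failure*: in retained embryos each duplicated
  maternal copy is lost per locus with a probability decreasing in pressure
  (5% × logistic, midpoint 7000 PSI), producing partially-triploid
  aneuploids at intermediate pressures. (2) *Spontaneous nondisjunction*:
  per-locus extra copies at a family-specific base rate (0.002–0.010,
  placing control aneuploidy in the 12–17% range over ~16 informative
  heterozygous loci) plus a pressure-stress term peaking near 6800 PSI
  (max 0.015), reflecting that sub-optimal shocks disturb meiosis even when
  retention fails. Extra copies are maternal or paternal with equal odds,
  paternal only without retention — so paternally derived trisomies appear
  only at low pressures; in retained embryos nondisjunction sheds a maternal
  copy, since paternal-allele loss was not part of the observed spectrum.
* **Rare whole-genome events.** UPD blocks (maternal alleles replaced by
  duplicated paternal ones at 4–8 loci, rate 0.004/individual) and
  androgenesis (no maternal genome, 0.002), both only in non-retained
  embryos. Repeat slippage moves one inherited copy by one motif (90%) or
  two (10%) in 2.5% of individuals.
* **Observation model.** Peak height = 1000 RFU × copy number × lognormal
  noise (sdlog 0.07, a clean single-injection assay); stutter at 10% of the
  parent peak one motif below, merged when it coincides with a real allele;
  2% locus dropout.
* **Viability.** Survival from eyed egg to parr: 0.93 for clean diploids and
  triploids, 0.20 for single-locus deviants, 0.04 for intermediate
  aneuploids, 0.03 for maternal-DNA-loss and 0.02 for androgenetic
  individuals. These encode the reported egg→parr depletion (intermediate
  aneuploidy nearly absent among survivors; pooled aneuploid relative
  survival ≈0.15 of baseline at the most affected pressure). Deaths split
  70/30 between the eyed-egg→start-feed and start-feed→parr intervals,
  mortality peaking just after the eyed-egg stage. A treatment-dependent
  fertilization→eyed-egg mortality (2–6%) is recorded for the ledger.

All parameters sit in `sim_params()` and were chosen once from the study
conditions described above; a single seed drives every stage through derived
substreams, so stages can be regenerated independently and runs are
bit-reproducible.

### What the simulator does not emulate

Chromosome linkage (markers are independent, while a real genome has 29
chromosome pairs and markers do not cover all of them), mosaicism
(a locus call is one configuration per individual), PCR competition between
multiplexed markers, allele-size-dependent amplification bias (available in
the calibration but off in the generator), and any physiological effect of
pressure beyond the retention/nondisjunction probabilities. Passing recovery
tests therefore demonstrates that the inference machinery is correct under
the stated generative assumptions — not that those assumptions exhaust real
fragment-analysis data.

## Numerical and design choices

* Band boundaries are open intervals: a ratio exactly on a boundary is
  unresolved (conservative tie-break).
* The bp-shift explanation considers only non-parental alleles and offsets
  of exactly 1–2 motifs; it takes precedence over missing-parent typing at
  a locus because slippage is common and benign.
* The UPD collapse threshold is strictly more than 3 loci.
* The genotyping-success filter reads "below 50%" strictly; whether an
  individual at exactly 50% was retained in any given study is usually
  unstated, so the boundary and the panel it is computed over (informative
  set vs whole panel) are both configurable.
* Individuals with a single informative heterozygous locus are classified
  but flagged low-confidence rather than dropped.
* Assignment requires exactly one family within tolerance; two candidate
  families — even with different mismatch counts — leave the individual
  flagged rather than assigned.
* Degenerate inputs (zero usable peaks, more than three peaks, empty call
  sets, zero-start mortality cells, rank-deficient designs, all-constant
  responses) produce flagged no-calls or classed errors, never silent
  results.

## Problem sizes

The bundled tests run the full Experiment 1 study (3,450 individuals, ~30
markers) through the entire pipeline once, 10,000 synthetic loci per
configuration for dosage round-trips, 200 seeded viability replicates, 50
seeded family-rate recovery cohorts and 200 mixed-model recovery replicates
at 10 groups × 200 observations. These sizes give Monte-Carlo standard
errors well inside the asserted tolerances while keeping a full check run in
minutes on one core.

## Known limitations

Homozygous loci veto somy information, so ploidy in fully homozygous
individuals is undetermined — as in any fragment-length protocol. Aneuploidy
detected over ~20 markers is a minimum estimate of genome-wide aneuploidy.
Parental allele sharing makes some extra-allele origins irrecoverably
ambiguous; the package reports ambiguity rather than guessing. The
mixed-model fitter supports a single random intercept (the designs analysed
here have one nesting level); crossed or nested multi-level structures are
out of scope.
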