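---
title: "Quantifying parallel evolution of colour vision from opsin expression"
author: "OpsinShift authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parallel evolution of colour vision from opsin expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OpsinShift)
```

## The biological problem

Cichlid fishes tune their colour vision largely by regulating which of
seven cone opsin paralogs they express (*sws1*, *sws2b*, *sws2a*,
*rh2b*, *rh2aβ*, *rh2aα*, *lws*, ordered from UV- to red-sensitive) and
by *cyp27c1*-mediated exchange of the A1 chromophore for the red-shifted
A2. When several species independently colonize the same novel photic
environment — say, a clear crater lake after a history in turbid rivers
and lakes — each lineage can adjust either lever. OpsinShift asks, and
tests, whether those adjustments are *parallel*: similar in direction and
magnitude across species.

## From counts to phenotypes

The input is a per-sample table of read counts for the seven cone opsins,
*cyp27c1*, and the total sequenced reads, with species and environment
metadata (`OpsinExperiment`, a `SummarizedExperiment`). Two phenotype
axes are derived per individual:

* **Predicted sensitivity index** `X = Σ PE_i · λmax_i`, where
  `PE_i` is each opsin's share of summed cone opsin counts and `λmax_i`
  its peak absorbance. λmax values are data, not constants: the packaged
  default (360/425/456/472/517/527/560 nm) carries Midas cichlid values
  with Nile tilapia for *sws1*, and a different taxon just needs a
  different TSV. Because `X` is linear in `PE`, the mean of individual
  indices equals the index of the mean profile; population summaries use
  the mean of individual indices and a test asserts the equality.
* ***cyp27c1* expression**, either reads per million total reads
  (absolute) or relative to the species maximum (default for the
  parallelism analysis, since species differ strongly in overall level
  and convergence concerns within-species change). The per-million
  denominator is the sample's total post-QC read count; whether total or
  mapped reads are used upstream is the caller's choice and should be
  kept consistent.

Secondary measures — single-cone fraction (*sws* share), the
*rh2aβ/(rh2aβ+rh2aα)* ratio (undefined when neither paralog is expressed;
such samples are dropped from ratio tests only), and the *lws* fraction —
feed the rank statistics.

## Rank-based statistics

Environment and species effects are tested non-parametrically.
`scheirerRayHare()` is the rank analogue of two-way ANOVA: observations
are replaced by mid-ranks, sequential sums of squares are computed for
species, environment and interaction, and each is divided by the total
mean square of the realized ranks, `SS_total/(N-1)`, which absorbs tie
correction; the statistics are referred to chi-square. Sequential SS
coincide with the classical construction for balanced designs; with
mildly unbalanced designs (one population of three) the decomposition is
order-dependent in the usual way, which we accept and document rather
than silently switching to another SS type. Per-species environment
effects use Kruskal–Wallis tests, corrected with Benjamini–Hochberg
within each measure across the seven species (one family per measure;
a global family is available). Whether reported significance survives
either family choice is worth checking in practice — the per-measure
default mirrors how per-measure significance is usually annotated.

`rankMaintenance()` asks whether among-species differences persist across
an environment transition: Spearman's ρ between species means in the two
environments, with a one-sided exact p-value from full enumeration of all
n! orderings for n ≤ 8 (7 species → 5040), since maintenance means
positive association. A two-sided variant is a flag away; beyond n = 8
the asymptotic approximation of `cor.test()` is used.

## The parallelism permutation test

For each colonization event (river → great lake, great lake → crater
lake) and species, a 2-D vector connects the population mean in the
ancestral environment to the mean in the derived environment in the
(sensitivity index, relative *cyp27c1*) plane. Because nanometres and
relative expression are incommensurable and angles are scale-dependent,
each axis is divided by the standard deviation of its population means
before vectors are built (`scale = "sd"`, the default; `scale = "none"`
keeps raw axes). Parallelism is summarised by the sums over all
species pairs (21 for 7 species) of between-vector angles and of absolute
length differences; the combined scope adds the sums of both events.

The null randomizes species identity within each environment: in each of
`nPerm` pseudo-datasets one individual per pseudo-species is drawn per
environment, vectors connect those individuals, and the same sums are
computed. The p-value is the add-one fraction of permuted sums *strictly
smaller* than the observed sum — small sums mean parallel change, and
ties count against rejection. p can never be 0 and never falls below
`1/(nPerm + 1)`. Zero-length observed vectors are excluded from angle
sums (their direction is undefined) but kept in length sums.

Two deliberate asymmetries deserve note. First, observed vectors use
population means while null vectors use single individuals; we keep that
asymmetry because it is how the procedure is defined, and provide
`nullMeans = TRUE` (pseudo-species means) as a sensitivity mode. The
asymmetry has a measurable cost: conditional on a dataset, the mean-based
observed sum is less dispersed than the single-individual permutation
distribution, so the default test is mildly conservative — on fully
exchangeable simulated data its angle-test rejection rate at α = 0.05 is
about 0.02–0.03 rather than the attainable 0.045, whereas the
`nullMeans` mode is exactly calibrated by exchangeability. We verified
this is a property of the procedure, not of the code: the conservatism
persists on ideal iid Gaussian phenotypes with scaling on or off, the
observed statistic matches an independent re-derivation exactly, and the
Monte-Carlo p matches exhaustive enumeration of the full null space on a
toy dataset (3 species × 2 individuals, 14 400 states). Second, within a
permuted dataset one individual per pseudo-species per *environment* is
drawn, so in the combined scope the great-lake endpoint is shared between
the two events — mirroring how the observed great-lake mean is shared.

## What the simulator emulates — and what it does not

`generateCounts()` draws, per individual: a library size (log-normal,
median 1.4 × 10⁶ reads, typical of the retinal RNA-seq depth this
analysis assumes); an opsin composition from a Dirichlet centred on the
population composition (species baseline + environment shift, combined
on the centred log-ratio scale so shifts compose additively and remain
on the simplex; concentration 150 by default, giving individual
proportion SDs of a few percent); multinomial opsin counts given an
opsin read budget (0.5% of the library by default — the absolute budget
is arbitrary and affects no proportion-based statistic); and a
negative-binomial *cyp27c1* count with an environment-specific mean rate
(highest in the turbid great lake) and size 5.

Presets fix the study conditions: `null` shares one baseline across
species with zero shift and equal *cyp27c1* means — fully exchangeable
data for calibration; `parallel_weak`/`parallel_strong` give seven
distinct species baselines plus a common shift toward short-wavelength
opsins (cumulative CLR magnitudes 0.25/0.6 and 1.2/2.4 for great and
crater lake; the strong preset also tightens individual noise to
concentration 400). "Strong" is defined by alignment: species mean
vectors lie within 30° of the preset direction, which the test suite
checks against stored ground truth. `paper_like` uses 5–6 individuals
per population with one population of three, and one species that swaps
*sws2a* for *sws2b* and gains *rh2b* in the crater lake — a qualitative
paralog switch layered on the graded shift.

The simulator does not emulate several features of real retinal RNA-seq:
no mapping ambiguity between the gene-converted *rh2aα/rh2aβ* paralogs
(real quantification must restrict to the 5′ segment that distinguishes
them), no ontogenetic or diurnal expression variation, no batch or lane
effects, and no phylogenetic correlation among species baselines.
Passing tests therefore demonstrate that the statistics behave correctly
under the model the analysis assumes, not that the model captures every
property of field data.

## Consensus calling

`callConsensus()` works per site on A/C/G/T counts: coverage below 10×
masks to `N`; otherwise a site is a heterozygote (IUPAC two-base code)
when the minor allele frequency exceeds 0.35, else the majority base.
Only two-allele heterozygotes are scored (diploid assumption); a
three-way tie for the major allele gives `N` with a warning. The
thresholds are arguments, and calls depend only on frequencies above the
coverage floor. Translation expands heterozygous codons into both
resolved codons (all combinations when a codon carries more than one
ambiguity, since phase is unknown), masks `N`-containing codons to `X`,
and flags internal stops without truncating. A site is "variable within
species" when conspecific individuals — pooled across populations, with
heterozygotes contributing both states — carry at least two amino-acid
states; both states are always reported rather than collapsed to one.
Residue numbers are reported against bovine RH1 through a user-supplied
per-gene alignment table; unmapped positions keep their raw index with a
flag. Pileups are assumed gap-free against the reference CDS — indels
are out of scope.

## Numerical choices and degenerate inputs

* Proportional expression requires at least one non-zero cone opsin
  count; the sensitivity index requires `|ΣPE − 1| ≤ 10⁻⁶`.
* Fractional counts in input tables are rejected, never rounded: counting
  pipelines emit integers, and silent rounding hides upstream errors.
* A species with all-zero *cyp27c1* gets relative values of 0 with a
  warning (not NaN).
* Angle computations clamp cosines to [−1, 1] before `acos`.
* Exact Spearman enumeration treats equal ρ values as ties in favour of
  the null (≥ with an ε guard of 10⁻¹²).
* Every stochastic entry point (`generateCounts()`, `generatePileup()`,
  `parallelismTest()`, `runPipeline()`) requires an explicit seed; the
  pipeline records it in its manifest.

## Problem sizes used in the test suite

The suite exercises the statistics at the scale the design implies:
calibration of the parallelism test uses 500 simulated datasets
(7 species × 3 environments × 5 individuals) at 199 permutations;
power uses 200 datasets of the strong preset; Scheirer–Ray–Hare
calibration uses 400 null datasets of the 7 × 3 × 5 design;
Kruskal–Wallis calibration uses 10⁴ simulations; the permutation oracle
enumerates the complete 14 400-state null of a 3-species toy. Larger
permutation counts (the conventional 999) are the default for real
analyses.

## Known limitations

* The Scheirer–Ray–Hare decomposition uses sequential SS (see above).
* The parallelism test's default mode is mildly conservative by
  construction (see above); interpret marginal p-values near α
  accordingly, or consult `nullMeans = TRUE` as a calibrated companion.
* The sensitivity index ignores chromophore state; *cyp27c1* is carried
  as a separate axis precisely because A1/A2 spectral modelling is out
  of scope.
* Exact rank-maintenance p-values are limited to n ≤ 8 species.
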