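---
title: "Methods and design notes for cpglyco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cpglyco}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpglyco)
```

`cpglyco` implements the computational analyses used to map plastid-targeted
lower glycolysis–gluconeogenesis enzymes (cpEnolase, cpPGAM) across algal
sequence collections and ocean meta-omics, and to quantify knockout
physiology. This vignette documents the models, the parameters that matter,
the numerical choices, and the places where the design was genuinely open.

## The localization screen

A candidate protein is judged plastid-targeted only after three ordered
gates.

**Domain completeness.** Coverage of a Pfam model is the union of the
`[hmm_from, hmm_to]` intervals (1-based inclusive) divided by the model
length; overlapping envelopes are merged, never summed, so a repeated
partial hit cannot inflate coverage past 1. Enolase requires coverage
strictly above 0.90 on *both* Enolase_N and Enolase_C; PGAM requires
strictly above 0.50 on His_Phos. The inequalities are strict, so a coverage
of exactly 0.90 fails: the thresholds are phrased as exceedances and the
boundary case is resolved conservatively.

**Presequence room.** Plastid-targeting presequences (signal plus transit
peptide in secondary plastids) need roughly 20 or more residues upstream of
the mature protein. A sequence whose earliest domain alignment starts at
position ≤ 20 (1-based) therefore cannot carry a credible presequence and
fails the gate regardless of predictor output.

**Predictor consensus.** The qualifying predictors depend on lineage:
TargetP or PredAlgo for primary plastids (plants, green/red algae,
glaucophytes); HECTAR or ASAFind for secondary plastids. A single plastid
call on either the complete or the Met-trimmed variant suffices.
Met-trimming takes the suffix from the first methionine at position ≥ 2
(trimming a sequence already starting with Met to itself would be vacuous);
sequences without an internal Met simply have no trimmed variant.
Mitochondrial consensus comes from a HECTAR mitochondrion call or a
MitoFates presequence probability at or above 0.35 (the tool's recommended
operating point; we read "threshold" inclusively). Two open points were
resolved here as package decisions: conflicting plastid and mitochondrial
calls on the same protein resolve to plastid (the screen exists to find
plastid isoforms, and a false mitochondrion call is the cheaper error — the
evidence column preserves the firing calls so users can revisit); and
WoLFPSORT output is accepted in input tables but never drives the
consensus, since the decision rule is defined over the four predictors
above. Prokaryotic sequences are always `other`: they have no organelles to
target.

**Reciprocal best hit.** The best hit per query is the maximal bitscore,
with ties broken by minimal e-value and then lexicographic subject id. BLAST
run with `-max_target_seqs 1` leaves tie behaviour undefined; fixing the
tie-break makes retention deterministic and shuffle-invariant.

## The environmental sieve

Candidate meta-genes pass, in order: an hmmer e-value gate at 10⁻¹⁰
(inclusive — the cut is quoted without strictness, and e-values are
continuous so the boundary is measure-zero); a reciprocal-best-hit filter
against the reference genome (best hit must be an enolase/PGAM gene); a
reciprocal-best-hit filter against the curated alignment (best hit must be a
diatom plastid-targeted isoform); and a tree filter.

**Midpoint rooting.** The root is placed halfway along the longest
tip-to-tip path. This point minimises the maximum root-to-tip distance over
all possible placements, which the test suite verifies against an exhaustive
edge-placement oracle. Ties for the diameter are broken by the
lexicographically smallest sorted tip pair, so rooting is reproducible
across runs and platforms. If the midpoint falls exactly on an internal
node, that node becomes the root and its basal multifurcation is retained —
inserting a zero-length edge would create an arbitrary bifurcation that
downstream clade logic would have to special-case. Zero-length internal
branches elsewhere are honoured as written in the newick; a tree whose
branch lengths are all zero has no defined midpoint and is an error.

**Monophyletic retention.** For each environmental tip we walk rootward to
the smallest ancestral clade containing at least one reference tip and
retain the tip iff every reference in that clade is a diatom
plastid-targeted reference. This topological reading operationalises
"positions closer to diatom plastid-targeted proteins than to any
non-diatom or non-plastid sequence": on a rooted tree the minimal
reference-containing ancestor is exactly the set of references the tip is
"with". A patristic-distance mode (`mode = "patristic"`: nearest reference
by path length must be a diatom plastid reference) is exposed for
sensitivity analysis, since branch-length-based readings can differ on
trees with strong rate heterogeneity. Branch support values are ignored —
retention is purely topological. A tree with environmental tips but no
surviving diatom-plastid references is an error rather than a silent empty
result, because it means the curation upstream failed.

## Abundance normalisation and correlation

Two normalisations proxy different quantities: 10⁶ (Σ metaT / Σ DiatomT) is
the share of the diatom meta-transcriptome occupied by the gene family
(invariant under joint rescaling of numerator and denominator), and
log₁₀(1 + Σ metaT) − log₁₀(1 + Σ metaG) proxies per-gene expression level
while admitting stations with zero meta-genome counts. Size-fraction labels
"3-20" and "5-20" are both mapped to "3/5-20" because Arctic and non-Arctic
campaigns used different lower filters for the same nominal fraction.

Correlations (Pearson, or Spearman on average ranks) take significance from
F = r²(n−2)/(1−r²) on (1, n−2) df. One-tailed tests take the upper tail in
a *declared* direction — positive for |latitude| and day length, negative
for temperature, or whatever the user configures — never a direction
inferred from the data, which would make the test liberal. Spearman
significance uses the same t/F approximation, adequate at the station
counts involved (n ≳ 20). Stations with missing values are dropped pairwise
and n is reported per test; no multiple-testing correction is applied, and
all raw p-values are exported so users can apply their own. Genome-bin
(MAG) coverage is compared to absolute latitude with a two-tailed t-test;
latitude always enters as |latitude| since the hypotheses are polar-vs-
temperate, not hemispheric.

## Enrichment statistics

The 2×2 chi-squared uses no continuity correction; at the printed table
sizes (hundreds to thousands) the correction changes nothing material, and
omitting it keeps the one-tailed construction exact: the one-tailed p is
the upper normal tail of z = sign(k₁/n₁ − k₂/n₂)·√χ², which halves the
two-tailed p in the enriched direction and returns 0.5 at zero deviation.
Tails are a required argument — both one- and two-tailed versions are used
in different analyses and silently defaulting would invite misreading.
The DEG intersection uses strict thresholds (fold-change > 2, p < 0.05) in
*both* knockout comparisons, and the localization-enrichment background
includes the DEG genes (denominators 239 and 11,514 overlap); a
`disjoint_background` switch is provided for users who prefer
non-overlapping sets.

The two-group summary ANOVA computes the pooled-variance F (equal to the
squared equal-variance t) from (n, mean, SD) alone. Printed SDs are
ambiguous: with the sample convention (n−1 divisor, matching `sd()` and a
raw-data `aov`, the default) the latitude contrast (n = 81, 45.6°, 13.5°)
vs (n = 10, 38.9°, 24.3°) gives p = 0.185; treating them as population SDs
(n divisor, the spreadsheet `STDEVP` convention) gives p = 0.193. The
`sd_type` argument exposes both; only the population reading reproduces the
reported two-decimal value of 0.19, which is why the acceptance script uses
it for that quantity.

## Physiology

**Growth.** The rate is the least-squares slope of log₂(density) against
time in days over the in-window points, i.e. divisions per day. The window
is all consecutive measurements with density in [5×10⁴, 4×10⁶] cells/mL —
below that, cytometer particle noise dominates; above it, medium exhaustion
bends the curve — and when several disjoint runs qualify the longest (then
earliest) is used. Linearity is gated at r > 0.95 on the same points. The
quantity is sometimes written Δlog₂(density)/Δlog₂(time); read literally
(slope against log₂ time) it would not carry units of divisions/day, so the
linear-time reading is the default and the literal one is available behind
`log2_time = TRUE` for comparison.

**Light curves.** rETR = ϕPSII·E is fitted to
rETR_M (1 − e^(−αE/rETR_M)) using only steps with E ≤ 450 µmol photons
m⁻² s⁻¹ (the 600 and 750 steps are too noisy to constrain the plateau), and
NPQ to the sigmoid NPQ_M Eⁿ/(E50ⁿ + Eⁿ) on all steps. Both fits use
Levenberg–Marquardt least squares with deterministic, data-derived starts
(initial slope and series maximum for the rETR model; series maximum,
half-max step and n = 1 for the sigmoid), positivity bounds, and step
tolerances of 10⁻¹⁵, giving noiseless-recovery accuracy near machine
precision across rETR_M ∈ [20, 200], α ∈ [0.05, 1], NPQ_M ∈ [0.5, 4].
Non-convergence is flagged in the returned object, never thrown, so batch
fits over many cell lines do not abort. E_K = rETR_M/α and
ϕPSII at 50 µmol photons m⁻² s⁻¹ are derived from the fitted parameters.
σPSII and single-turnover Fv/Fm are instrument-internal measurements and
are only ever carried as data.

## What the synthetic data emulate — and what they do not

Every generator is a pure function of its seed, ships a truth table
sufficient to score downstream decisions without re-simulation, and writes
the exact text formats the consuming parsers read (FASTA, newick, hmmscan
`--domtblout`, BLAST outfmt 6, TSV).

* `simulate_labeled_tree()` joins a diatom-plastid reference clade and an
  other-reference clade by two long stems (length 10 against exponential
  mean-0.2 clade edges) and *grafts* environmental tips onto edges strictly
  inside one clade. Grafting (rather than evolving sequences) makes
  retention truth exact, isolating the filter logic from phylogenetic
  error, which real pipelines delegate to the tree inference step. The long
  stems guarantee the diameter midpoint lands on a stem, so midpoint
  rooting never breaks the reference clades.
* `simulate_predictor_table()` draws calls conditioned on true
  localization with per-call sensitivity/specificity; at
  sensitivity = specificity = 1 the consensus must reproduce truth exactly.
* `simulate_station_abundances()` draws latitudes uniformly, meta-genome
  counts negative-binomially (overdispersion is the norm in meta-omics
  counts; Poisson is the large-dispersion limit), and meta-transcript means
  as metaG·10^(β|lat|/90 + ε), ε ~ N(0, 0.2²) in log₁₀ units — a poleward
  expression increase without a commensurate gene-abundance increase.
  Default n = 40 stations and β = 1 give the correlation test ≥ 95% power
  while β = 0 recovers the nominal 5% one-tailed false-positive rate.
* `simulate_growth()` is logistic with N₀ = 10⁴ cells/mL, 1 division/day,
  K = 2×10⁷ cells/mL (a realistic stationary density for diatom batch
  culture) and lognormal noise of CV 0.05. Note the logistic bend inside
  the upper density window biases the estimated rate ~3% low even at zero
  noise; `K = Inf` gives the pure exponential for exactness checks.
* `simulate_light_curve()` back-computes Fs and FM′ from the generating
  rETR and NPQ models (FM′ = FM/(1+NPQ), Fs = FM′(1−ϕPSII)) on a 35-then-
  six-steps-to-750 protocol grid, so the derived parameters invert exactly
  at zero noise.

None of the generators emulate sequence evolution, oceanographic covariance
between environmental variables, or phylogenetic reconstruction error.
Passing tests therefore demonstrate that the *decision logic and estimators*
are correct under the stated statistical models, not that upstream tools
(aligners, tree inference, targeting predictors) are reliable on real data.

## Problem sizes and verification

The test suite cross-checks midpoint rooting against an exhaustive
edge-placement oracle on 500 random trees of up to 12 tips and the
retention filter against a clade-enumeration oracle on 500 random labeled
trees of up to 16 tips; fit recovery uses a 3×3(×3) noiseless parameter
grid plus 200-seed noise studies at 5% multiplicative noise (growth: CV
0.05); and test calibration/power use 500 and 200 simulated station sets.
These sizes give binomial standard errors below one percentage point on the
agreement rates while keeping the whole suite around half a minute.

## Known limitations

* The consensus screen emits a single localization; dual-targeted proteins
  are not represented as a category.
* Spearman p-values use the t approximation, which is anti-conservative
  below n ≈ 10.
* The patristic retention mode ignores within-clade reference density; it
  is a sensitivity check, not the primary criterion.
* The growth-rate estimator assumes the density window captures clean
  exponential phase; cultures that saturate inside the window are biased
  low, as quantified above.
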