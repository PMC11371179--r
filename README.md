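# cpglyco

Diatoms and several other algal lineages carry a complete lower half of
glycolysis–gluconeogenesis inside the chloroplast: plastid-targeted isoforms
of enolase (cpEnolase) and phosphoglycerate mutase (cpPGAM). `cpglyco` is an
R toolkit for the computational side of characterising this pathway: deciding
which candidate proteins in large sequence collections are genuinely
plastid-targeted, sieving ocean meta-omics data for environmental homologs of
the diatom plastid isoforms, relating their abundance to latitude and other
environmental drivers, and quantifying knockout physiology (growth rates,
PSII light-response curves) and expression enrichment. Every stage can be
exercised end-to-end on seeded synthetic data with known ground truth, so the
package tests itself without any external downloads.

It is written for molecular phycologists and comparative genomicists working
with targeting predictions, single-gene phylogenies and *Tara* Oceans-style
meta-omics tables.

## What it computes

**Localization screen** (`screen_proteins()` and friends). A candidate is
plastid-targeted only if it passes three gates in order:

1. *Domain completeness* — union coverage of the Pfam model coordinates must
   exceed 90% for both Enolase_N and Enolase_C (enolase) or 50% for His_Phos
   (PGAM);
2. *Presequence room* — the earliest domain alignment must begin after
   residue 20, leaving room for a plastid-targeting presequence;
3. *Predictor consensus* — TargetP or PredAlgo (primary plastids) or HECTAR
   or ASAFind (secondary plastids) must call a plastid presequence on the
   complete or Met-trimmed sequence. Mitochondrial calls come from HECTAR or
   a MitoFates score ≥ 0.35, with plastid taking precedence.

**Environmental sieve** (`run_sieve()`). Meta-genes pass an hmmer e-value
gate (≤ 10⁻¹⁰), two reciprocal-best-hit filters (against the reference
genome, then the curated alignment), and finally a tree filter: on a
midpoint-rooted single-gene tree (`midpoint_root()`), an environmental tip is
retained iff its smallest reference-containing ancestral clade holds only
diatom plastid-targeted references (`retain_env_tips()`).

**Abundance and correlation** (`normalize_abundances()`,
`correlate_env()`). Meta-transcript sums are normalised per million diatom
reads, 10⁶ (Σ metaT / Σ DiatomT), and expression level is proxied by
log₁₀(1 + Σ metaT) − log₁₀(1 + Σ metaG). Pearson/Spearman correlations
against |latitude|, temperature, day length etc. use the regression F
statistic, F = r²(n−2)/(1−r²), with explicit one- or two-tailed p-values.

**Enrichment statistics** (`chi2_enrichment()`, `shared_degs()`,
`anova_two_group_summary()`). 2×2 chi-squared without continuity correction
(one-tailed via the signed normal deviate), strict DEG thresholds
(fold-change > 2, p < 0.05 in both knockout comparisons), and a pooled
two-group one-way ANOVA computable from printed (n, mean, SD) summaries.

**Physiology** (`log_phase_rate()`, `fit_light_curve()`). Growth rate is the
slope of log₂(density) vs time inside the 5×10⁴–4×10⁶ cells/mL window with
an r > 0.95 linearity gate. Light curves fit
rETR = rETR_M (1 − e^(−αE/rETR_M)) on steps with E ≤ 450 µmol photons
m⁻² s⁻¹ (E_K = rETR_M/α) and NPQ = NPQ_M Eⁿ/(E50ⁿ + Eⁿ).

## Worked example

```r
library(cpglyco)

# Enrichment of chloroplast-targeted proteins among shared upregulated DEGs
chi2_enrichment(90, 239, 1585, 11514, tails = "one")
#>      k1    n1    k2    n2 statistic tails  p_value
#>      90   239  1585 11514      109. one   6.77e-26

# Fit a rapid light curve simulated with instrument noise
lc <- simulate_light_curve(noise_sd = 2, seed = 4)   # truth: rETR_M 60, alpha 0.3
fits <- fit_light_curve(lc$trace)
glance(fits$retr)
#>   rETR_M alpha   E_K phi_psii_50   rss     n converged
#>     67.7 0.276  245.       0.250  19.2     6 TRUE
autoplot(fits$retr)   # points + fitted saturation curve

# Log-phase growth rate from a noisy logistic curve (truth: 1 division/day)
g <- simulate_growth(seed = 4)
log_phase_rate(g$curve)
#>    rate     r window_start window_end n_points passes_linearity
#>   0.967 0.999            4          9        6 TRUE

# Latitude correlation of simulated meta-gene expression (truth: positive)
sim <- simulate_station_abundances(seed = 4)
j <- normalize_abundances(sim$abundances, sim$stations)
correlate_env(j$log_expression_ratio, abs(j$latitude),
              tails = "one", direction = "positive")
#>   method      r r_squared p_value tails direction     n
#>   pearson 0.441     0.195 0.00218 one   positive     40
```

The chi-squared row says 38% (90/239) of shared upregulated genes are
predicted chloroplast-targeted against a 14% genome-wide background — a
massive enrichment. The rETR fit recovers the generating parameters to
within the noise level, the growth estimate sits 3% under the generating
rate (the logistic flattens slightly near the top of the density window),
and the simulated poleward expression signal is detected at p ≈ 0.002.

A full demo workspace with every fixture type and its truth tables can be
written with `simulate_workspace("workspace/", seed = 1)`.

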