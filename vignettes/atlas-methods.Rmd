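---
title: "Modeling environment- and background-dependent variant effects with mavatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling environment- and background-dependent variant effects with mavatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Most rare missense variants in clinically important genes cannot be
classified from population data alone, and a variant's impact can depend
both on the environment and on other variants carried in cis. MTHFR
(5,10-methylenetetrahydrofolate reductase) is the archetype: deficiency is
recessive, caused mostly by rare missense alleles, and the common
polymorphism p.Ala222Val — carried by half of humanity — is a hypomorph
whose effect depends on folate availability and which modifies the effect
of rare variants on the same allele.

`mavatlas` implements the analysis layer of a multiplexed yeast
complementation assay (a MAVE read out by TileSeq) that measures every
possible MTHFR amino-acid substitution across a folinate gradient
(12.5, 25, 100, 200 µg/mL) in two genetic backgrounds (wild-type and
p.Ala222Val), and turns the resulting sequencing counts into:

1. calibrated **functionality scores** with regularized errors,
2. per-variant linear **dose-response models** (base functionality `b`,
   folinate response `r`) with likelihood-ratio evidence,
3. **genetic-interaction models** against a polynomial double-mutant
   expectation (folinate-independent `eps_b` and -dependent `eps_r`
   deviations), including suppressor calls,
4. screening statistics (Welch, Mann–Whitney, Fisher, all BH-FDR
   controlled), and
5. clinical calibration of scores into **log-likelihood ratios of
   pathogenicity (LLRp)** with balanced precision–recall evaluation of
   diploid genotype models (M1–M3).

A first-class synthetic-data module replaces the wet-lab experiment, so
every stage is testable against a known ground truth without downloads.

# The measurement model

## From counts to scores

For each variant, condition (nonselect or select at folinate `c`),
replicate and tile, the allele frequency is `count / depth`. The
error-subtracted enrichment ratio is

    phi = max(0, f_sel - f_ctrl_sel) / (f_non - f_ctrl_non),

undefined when the denominator is non-positive. Control frequencies come
from a wild-type-only strain sequenced alongside; they capture the base
caller's residual error (a pair-consensus miscall requires both reads to
miscall the same base, rate ≈ `(e/3)^2` per single-nucleotide path).

Raw ratios are rescaled per mutagenesis region so that the mode of the
nonsense-variant ratios maps to 0 and the mode of the synonymous ratios to
1 (`estimate_mode()`: Gaussian KDE, Silverman bandwidth, 512-point grid —
reproducible with no tuning). Scores are therefore relative to the
*background of the map*: in the p.Ala222Val background a score of 1 means
"as functional as p.Ala222Val alone".

## Errors, in three layers

* A count-propagated (Poisson delta-method) prior
  `sigma_prior ≈ phi * sqrt(1/k_sel + 1/k_non)`, rescaled to score units.
* Regularization of the between-replicate scatter toward that prior,
  `sigma^2 = (nu * sigma_prior^2 + (n-1) * s_obs^2) / (nu + n - 1)` with
  `nu = 2` pseudo-replicates and a floor of 0.005 score units.
* **Empirical calibration against the synonymous population**
  (`calibrate_errors = TRUE`): whatever variance the neutral variants show
  beyond their claimed errors is shared noise every score carries, and it
  is added to every claimed variance per (background, map, region).

The third layer matters because both replicates of a map derive from the
same transformant pool: clone-composition ("library") noise — the
finite number of independent clones carrying a variant, each with its own
background mutations — is invisible to replicate scatter. On simulated
data this component is ~0.06 score units at 300,000 clones per region,
which replicate-based errors would miss entirely.

## Shared variance components

Two components do not average out the way independent errors would, and
the fitters account for this explicitly:

* the **nonselect library** is sequenced once per replicate and shared by
  all four concentration maps (`var_non`), and
* the **clone-composition noise** is one draw per (variant, background),
  shared across replicates *and* maps (`var_shared`).

Both cancel exactly in any slope over concentration but not in intercepts;
`fit_dose_response()` and `fit_interaction()` therefore inflate `se_b` and
`se_eb` by the shared component scaled by `(1/g - 1/n)`, where `g` is the
number of independent groups the component is shared within. Without this,
the folinate-independent interaction test is anticonservative by a factor
of ~2 in variance (verified on strict-null simulations, where the corrected
z-statistics have unit spread).

# Dose-response and interaction models

Each variant's scores are modeled as `s(c) = b + r*c` by closed-form
weighted least squares with the per-measurement errors treated as known —
no iterative optimizer, and the Gaussian likelihoods are exact. The null
model fixes `r = 0` (the inverse-variance weighted mean), and
`LLR = logL_full - logL_null` (natural log) feeds a chi-square(1) test,
Benjamini–Hochberg FDR across variants, plus an effect floor
(`|r| * (c_max - c_min) >= 0.1` by default): a response must be both
statistically supported and large enough to matter over the tested range.
The linear model is deliberately parsimonious and is never extrapolated
outside the tested 0–200 µg/mL range ("virtual maps" via
`predict_score()` interpolate within it).

Genetic interaction is a deviation from what the double mutant *should*
score given its single-mutant behavior. The expectation is a weighted
polynomial (degree 3 by default, configurable 1–5) of the double-mutant on
the single-mutant score, pooled over concentration-matched pairs. Because
the curve must describe *non-interacting* variants, the fit is robustified
by iterated residual trimming (2.5 robust SDs, 2 passes): a third of
variants genuinely interact, and without trimming they drag the curve away
from the majority and bias every deviation estimate. Predictions are
clipped to the training range.

With `(b, r)` fixed from the wild-type fit, the deviations
`y(c) = s_av(c) - P(b + r*c)` are fitted as `eps_b + eps_r * c` (again
closed-form WLS), with the wild-type fit's uncertainty propagated through
the curve's derivative. Three nested fits give `LLRg` (any interaction)
and the folinate-dependence test; posteriors use the Gaussian
approximation `P(eps > 0) = pnorm(eps_hat / se)`.

Suppressor calls follow the published rule: a good interaction-model fit
(total natural-log likelihood above −8), posterior probability of a
positive interaction above 0.95, and model-predicted double-mutant scores
above the 95th percentile of synonymous scores in the polymorphism
background — at all concentrations (folinate-independent), only at the
lowest (low-folinate) or only at the highest (high-folinate). Each call is
annotated with single-nucleotide accessibility.

# Screens

Background comparisons use Welch's t from summary statistics per
(variant, concentration), two-sided, FDR per concentration family.
Hypercomplementation tests missense variants with base functionality
strictly above 1, one-sided against the pooled synonymous distribution.
Because the per-variant variances are regularized and calibrated, each
group's variance estimate carries more information than its raw replicate
count; the tests credit `nu` extra degrees of freedom per group (the
moderated-statistics convention). Even so, with honestly calibrated errors
the between-background Welch screen is *conservative*: the shared library
noise differs between the two background pools and genuinely confounds
per-variant comparisons at this design's replication level, so atlas-level
flag counts are smaller than they would be with purely replicate-based
errors. Structural comparisons (buried vs exposed, ligand-proximal vs
surface) use Mann–Whitney U on per-position median scores; enrichments use
Fisher's exact test with both the conditional-MLE and sample odds ratios
reported.

# Clinical calibration

Positive reference sets come from a curated case table: variants seen
strictly more often in early-onset than late-onset cases (ties excluded);
the random reference set keeps population missense variants with global
allele frequency above 1 in 10,000 or at least one observed homozygote.
Per protein domain (catalytic ≤ position 356, regulatory above — the
boundary is configurable), Gaussian KDEs of the positive and random score
distributions give `LLRp(s) = log(f_pos(s)/f_rand(s))`, floored at 1e-3 of
each density's peak so the transform stays finite; the package falls back
to a pooled fit when a domain has fewer than 10 reference scores.

Diploid genotypes are scored under three models: M1 scores each allele's
rare variant as if in the wild-type background; M2 substitutes the
interaction-model prediction when the polymorphism is in cis; M3
additionally multiplies in the functionality of an in-cis p.Glu429Ala
(product rule, default 0.95). Reflecting recessiveness, a genotype gets
the *minimum* (least pathogenic) LLRp of its two alleles; variant-free
alleles sit at a benign floor (the 5th percentile of random-reference
LLRp values). Classifier quality is the area under the balanced
precision–recall curve (precision recomputed at a 50/50 class prior),
with R90P the maximum recall at balanced precision ≥ 0.9, and paired
bootstrap (10,000 resamples) for comparisons.

# The simulator: what it emulates, and what it does not

The generator's defaults are the published experiment's stated scale:
300,000 clones per mutagenesis region with Poisson codon-change loads of
0.93/0.86/0.80/0.71 for regions 1–4, two replicates, 5.5 doublings of
selection, four folinate levels in two backgrounds, and 2 million read
pairs per tile across 19 tiles (4/4/5/6 per region). Ground truth plants:

* bimodal missense functionality (30% null, 15% hypomorph, 50%
  wild-type-like, 5% hypercomplementing, reweighted by structural
  context: buried/ligand-proximal catalytic positions toward null,
  regulatory and SAM-pocket positions toward hypercomplementation);
* 7% folinate-responsive variants, preferentially hypomorphs (6-fold
  odds), with slopes of 0.0015–0.003 score units per µg/mL bracketing the
  published example fits, ~15% negative;
* 33% genetic interactions, about one in six folinate-dependent
  (`|eps_r|` 0.002–0.005 per µg/mL), 75% negative, plus ~4% dedicated
  suppressors split independent/low-/high-folinate. Suppressor truth
  labels are then assigned *definitionally*: any positively interacting
  variant whose true double-mutant trajectory crosses 1.15 (the truth-side
  analogue of the synonymous 95th percentile) is labeled by the
  concentrations at which it crosses;
* a recessive clinical cohort (100 case-stream, 77 population-stream
  individuals): phased diploid genotypes, rare case alleles carrying the
  polymorphism in cis with probability 1/3, onset classes from the
  *most functional* allele (the recessive rule) plus Gaussian noise, and a
  population allele-summary table arranged so the benign pool largely
  passes the frequency/homozygote filter while case alleles do not.

Selection uses the growth factor `G(w) = 1 + w * (2^d − 1)` per clone
(product fitness over a clone's variants), which agrees with exponential
doubling at `w ∈ {0, 1}`, is monotone in fitness, and makes the calibrated
enrichment score an unbiased estimator of the planted score — so recovery
can be assessed on one scale. Multi-variant clones contribute their full
product fitness to every constituent variant's marginal frequency, which
is precisely the background-averaging premise marginal scoring relies on.
Sequencing is binomial (beta-binomial overdispersion available, off by
default); read-pair emission with per-base miscalls feeds the consensus
caller.

Deliberately not simulated: real Illumina error profiles, PCR jackpots,
alignment artifacts, position-level coverage unevenness (simulated
coverage is therefore near 100%, higher than the ~90% typical of real
maps), batch effects between replicates, and any nonlinearity between
growth rate and enzymatic activity. Passing recovery tests on this
simulator shows the *estimators* are correct and calibrated under the
stated noise model — not that real data meet that model.

# Problem sizes and numerical choices

The bundled analyses run the full 13,776-outcome atlas (about half a
minute for simulation plus scoring on one core); unit tests use a
30-residue protein where only rule semantics matter. Degenerate inputs:
enrichment ratios with non-positive denominators are `NA` and filtered
records carry missing scores (never zero); mode calibration aborts loudly
if the synonymous mode does not exceed the nonsense mode; fits require two
distinct concentrations; rank-deficient expectation fits reduce the
polynomial degree with a warning; zero-margin Fisher tables are flagged
degenerate. All randomness flows through explicit seeds; identical
config + seed reproduces byte-identical score tables (checksummed in the
pipeline manifest).

# Known limitations

* Scores are relative to each background's own synonymous/nonsense modes;
  cross-background comparisons therefore measure *relative* shifts, and
  the linear dose-response is a local approximation valid only across the
  tested folinate range.
* The posterior of a positive interaction uses a flat-prior Gaussian
  approximation; with strongly non-Gaussian errors the 0.95 cutoff is
  nominal.
* Atlas-level screen counts are not comparable to published counts from
  real data: they depend on the error model, and this package's calibrated
  errors are deliberately more conservative than replicate-only errors.
* The clinical module assumes phased genotypes and at most one rare
  missense variant per allele.
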