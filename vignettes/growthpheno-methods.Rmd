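---
title: "Growth-trajectory deviations, startle psychophysics, and phenotype mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-trajectory deviations, startle psychophysics, and phenotype mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthpheno)
```

## The scientific problem

Mouse models of neurodevelopmental disorders often pair volumetric MRI
at two developmental ages — neonatal (P7) and adult (P60), necessarily
in *different* animals because imaging is terminal — with a battery of
behavioral assays. The question this package operationalizes: which
brain regions depart from their expected developmental growth in the
mutant, is region-to-region growth coordination preserved, and do the
departures predict which behaviors are abnormal?

## Growth model

All volumetric statistics run on either **absolute** volumes (mm³) or
**relative** volumes (percent of whole brain,
`region/whole_brain × 100`). Relative volumes factor out global brain
overgrowth, which matters for macrocephalic mutants; both bases are
always available and reported.

Because P7 and P60 cohorts are different animals, subject-matched
growth is unobservable. All baselines are therefore genotype means:

- **Growth index** (per adult subject, per region):
  $(y_{P60} - \bar{y}_{P7,g}) / \bar{y}_{P7,g}$ where
  $\bar{y}_{P7,g}$ is the subject's genotype mean at P7. Zero means
  no growth; negative values (shrinkage) are allowed.
- **WT trajectory** $w = \bar{y}_{P60,WT}/\bar{y}_{P7,WT}$: the
  expected fold-growth of a region under normal development.
- **Predicted mutant adult volume** $\hat{y} = \bar{y}_{P7,MUT}\,w$:
  the mutant P7 baseline carried forward along the normal trajectory.
- **Percent deviation** $x = (y - \hat{y})/\hat{y} \times 100$ per
  mutant adult, tested against zero per region with a two-sided
  one-sample t test.

Two algebraic properties anchor the implementation and its tests.
First, applying the deviation machinery to the WT adults themselves
gives mean zero per region *identically* (their $\hat{y}$ equals their
own P60 mean), which the suite asserts at $10^{-9}$. Second, all
statistics are invariant to global unit rescaling.

Significance is reported with the conventional star categories and a
trend band ($+$, $0.05 \le p < 0.10$). Benjamini–Hochberg q values
across regions are **off by default** — the region-wise presentation
this mirrors uses raw-p stars, with FDR reserved for voxel-wise maps —
and can be enabled with `fdr = TRUE`. One caveat worth stating: the
BH step-up is a fixed point only on vectors it has already flattened
(ties, single elements); re-applying it to a general q vector inflates
the values further, so "apply once" is part of the contract.

## Correlation divergence

Growth indices are correlated across regions within each genotype
(Pearson, two-sided p, n = adult subjects of that genotype). Each
region pair is classified at level $\alpha$:
`shared` (significant in both), `WT_only`, `MUT_only`, `neither`.
Defaults: $\alpha = 0.05$ per pair, uncorrected, with a BH option
across pairs; pairs undefined through zero variance are excluded
rather than coerced. The classification is deliberately simple — it is
a descriptive map, not a formal test of correlation-matrix equality,
which is out of scope.

## Startle psychophysics

Per-mouse analysis starts from per-intensity means over the 8 trial
presentations. The mean (not the individual trials) is
log10-transformed, floored at $\epsilon = 0.01$ accelerometer units to
keep no-stimulus cells finite; base 10 is the psychophysics
convention and the floor only matters for silent cells, which are
flagged. The response curve is modeled as a logistic in stimulus
intensity $s$ (dB above background):

$$N(s) = \frac{m_{max}}{1 + e^{-r (s - s_0)}}$$

with saturation $m_{max}$ (log10-amplitude units), midpoint $s_0$ (dB)
and slope $r$ (per dB). Fitting minimizes the RMSE between $N$ and the
log-normalized means over the observed intensities. Numerical choices:

- multi-start bounded quasi-Newton (L-BFGS-B on the sum of squares
  with its analytic gradient), starts at
  $m_{max}^0 = \max(y)$, $s_0^0 \in \{15, 25, 35\}$,
  $r^0 \in \{0.1, 0.3\}$, followed by a tight-tolerance polish of the
  winner;
- bounds $m_{max} > 0$, $r \in (0, 5]$, $s_0 \in [-20, 80]$, chosen to
  bracket the stimulus range generously;
- a curve whose log-amplitude range is below $10^{-3}$ is declared
  unconverged (flat); the constant-model RMSE is reported instead of
  parameters. By construction the fit RMSE never exceeds that
  constant-model RMSE.

The test suite verifies the optimizer against a brute-force
$60^3$ parameter-grid oracle and recovers noiseless curves to
$10^{-4}$. Derived measures are closed forms: the intensity producing
fraction $f$ of saturation is $s_0 - \ln((1-f)/f)/r$, so the midpoint
is exact at $f = 0.5$ and the 5 % threshold is $s_0 - \ln(19)/r$;
symmetry $t(f) + t(1-f) = 2 s_0$ holds identically. Because the
loudest stimulus (50 dB above background) may not reach true
saturation, $m_{max}$ is an extrapolation; the observed maximum
(highest per-intensity mean, ties resolved to the lower intensity and
flagged) is always reported alongside.

All 11 intensity points, including the 0-dB control, enter the fit by
default; the 0-dB rows also serve as the paired baseline for the
**traditional threshold**: per intensity, a paired t of the group's
per-subject means against baseline, threshold = lowest significant
intensity. Significance need not be monotone in intensity with real
animals, so the *monotone* threshold (lowest intensity from which all
higher ones are significant) is reported alongside; the two differ
exactly in the ambiguous cases.

**dB modules.** The intensity range splits into a low (0–25 dB above
background) and high (30–50) module, each analyzed with a two-way
mixed ANOVA (genotype between, intensity within) via the standard
balanced error-stratum decomposition; subjects missing any
within-subject level are excluded and listed. Sidak-adjusted
($p_{adj} = 1-(1-p)^k$) per-intensity genotype contrasts are added
when the interaction is significant.

**PPI and habituation** are the printed ratio formulas. Habituation is
scored per mouse with phase I as the denominator (the alternative
phase III normalization, which appears in some presentations, is
available via `denominator = "phase3"` but is not the default — the
two conventions are not interchangeable and the package does not guess
between them). Because individual mice can habituate negatively, the
mean of per-mouse scores differs from the score of group means;
`habituation_group_summary()` reports both rather than choosing.

## Behavioral indices

Discrimination index, preference index, percent-of-maximum-time and
the quadrant-vs-25 % utility are direct formula implementations with
explicit degenerate-input policy: zero total investigation or chamber
time yields a flagged undefined score (not NaN), puzzle-box
non-completers are clamped to 100 % and flagged. The preference index
is reported ×100 by default for comparability with the usual figure
scale; `scale100 = FALSE` gives the raw −1..1 index. The social
preference *dichotomy* is group-level — a paired t between chamber-time
vectors with more time on the social side — not a per-mouse call.

## Phenotype concordance

Regions are classified `increased`/`decreased`/`unchanged` from the
relative-basis deviation tests (sign of the mean deviation gated by
p < α; untestable regions are `unchanged` with a flag). A behavior is
predicted abnormal when its associated regions satisfy the prediction
rule — `any` increased by default, the weakest faithful formalization
of "enlarged regions predict phenotypes"; `majority` and `all` are
available for sensitivity analysis. The 2×2 predicted × observed tally
over tested behaviors carries an exploratory Fisher exact p; it is
labeled exploratory because the underlying mapping is a qualitative
literature exercise, not a pre-registered test.

## Synthetic data: what it emulates and what it does not

`simulate_volume_study()` draws P7 volumes lognormally around
region baselines (default CV 5 %, a typical between-animal volumetric
spread) and P60 volumes as baseline × genotype growth multiplier ×
$e^{\text{factors} + \text{noise}}$. Latent per-subject factors with
loading $L$ on a region set induce growth-index correlations of about
$L^2/(L^2 + s^2)$ (log-noise sd $s$) in the genotypes carrying the
factor — planting `shared` or genotype-specific coordination. The
default manifest is 12 named regions spanning hindbrain to forebrain
with plausible neonatal baselines and region-specific fold-growth of
1.8–2.6; the mutant P7 baseline is shifted +10 % to emulate early
overgrowth. Whole brain is the sum of regions. Defaults for the study
size are n = 10 per genotype per age.

`simulate_startle_study()` draws per-mouse sigmoid parameters around
group truth (default saturation 2.0 log units, midpoint 25 dB, slope
0.3/dB, with between-mouse SDs) and trial amplitudes as
$10^{N(s) + \varepsilon}$, $\varepsilon \sim N(0, 0.1)$ — noise on the
log scale, matching the log-normalization applied downstream.
`simulate_ppi_session()` attenuates pulse-alone amplitudes by the
configured inhibition fraction per prepulse intensity and by a
habituation fraction in phase III, so the measured %PPI and
%habituation recover the planted fractions in expectation.

These generators reproduce the statistical *structure* the analyses
assume — multiplicative volumetric noise, factor-induced growth
correlation, sigmoidal intensity-response with log-normal trial noise.
They do not emulate litter effects, sex differences, registration or
segmentation error, startle-chamber drift, or non-sigmoid response
shapes; passing recovery tests therefore validates the estimators
under the model, not robustness to those real-world violations.

## Problem sizes and reproducibility

The recovery studies used by the test suite and `scripts/acceptance.R`
were sized for stable Monte-Carlo estimates at desk scale: 500
replicate studies for deviation recovery (binomial SE on a 95 % power
estimate ≈ 1 %), 200 for divergence-class and sigmoid-midpoint
recovery, and 10,000 null replicates for type-I calibration (SE ≈
0.002 around 0.05). Every simulation takes an explicit seed; the same
seed reproduces a study bit-exactly, and the pipeline embeds a config
fingerprint in its run log so reports from identical configurations
are byte-identical.

## Known limitations

- The trajectory prediction uses genotype means at P7, so uncertainty
  in $w$ and $\hat{y}$ propagates into the deviation scores but is
  not formally decomposed; with the default study sizes this inflates
  the between-seed spread of the recovered mean deviation by a few
  percentage points.
- The divergence map classifies marginal significance, so pairs near
  the alpha boundary flip class across seeds; the class-recovery rate,
  not any single map, is the meaningful quantity on noisy data.
- The mixed ANOVA assumes a balanced complete design after exclusion
  and classical sphericity; no correction (Greenhouse–Geisser) is
  applied, matching the analysis it reproduces.
- Pooled-variance independent t is the default (Welch via
  `welch = TRUE`), matching the legacy-stats convention the analyses
  follow.
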