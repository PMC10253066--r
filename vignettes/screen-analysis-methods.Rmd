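---
title: "Models and methods behind epscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epscreen)
```

# The problem

Electroporation transiently permeabilizes cell membranes, and the
permeabilized state in living cells lasts far longer than pure lipid-pore
physics predicts, implicating membrane proteins. An arrayed CRISPR knockout
(KO) screen probes this: populations of cells each lacking one
membrane-protein gene are exposed to a train of nanosecond electric pulses
(nsEP), and membrane permeabilization is read out as the per-cell uptake of
the otherwise impermeant dye Yo-Pro-1 (YP). KOs that raise uptake point to
proteins that support membrane resilience or repair; KOs that lower uptake
point to proteins that themselves conduct or assist the field-induced leak.

`epscreen` implements the complete analysis of such a screen — from per-cell
fluorescence tables to replicated hit lists — together with a synthetic-data
generator with known ground truth, a model of the T7EI genomic cleavage
validation assay, dose bookkeeping, and a final stage correlating gene
expression with nsEP lethality across cell lines.

# The quantification pipeline

Each variant (KO or non-targeting "SCR" control) is measured as a matched
pair: one exposed cuvette and one sham-exposed cuvette, with 400–2000 cells
quantified per sample. The analysis proceeds in four steps, each a package
function:

1. **Per-sample summary** (`summarize_sample`): the mean and, in parallel,
   the median of per-cell YP fluorescence. The median pipeline is carried
   through everywhere because it resists the handful of saturated
   (typically dead) cells present in any sample.
2. **Sham correction** (`compute_delta_f`): ΔF = exposed summary − sham
   summary removes spontaneous dye uptake.
3. **Plate normalization** (`normalize_plate`): within each plate and
   experiment, all ΔF values are expressed as a percentage of the mean ΔF
   of that plate's SCR samples, which is 100% by construction. This absorbs
   multiplicative plate-to-plate differences (illumination, dye lots,
   culture state) exactly — a property the test suite asserts.
4. **Pooling** (`pool_variants`): per variant, the normalized ΔF values
   from the 3–8 independent experiments give a mean
   $\bar{\Delta F}$ and its squared standard error
   $S^2 = \mathrm{var}/n$.

Replicates are experiment-level normalized ΔF values for both KO and
control arms; all SCR samples on a plate are pooled into a single control
group. This is the natural reading of "screens with unpaired replicates":
the independent unit is the experiment, not the cell.

# Hit calling

Two complementary criteria are computed on the same pooled values:

**SSMD** (`ssmd`), the strictly standardized mean difference for unpaired
groups with unequal variance:

$$\mathrm{SSMD} = \frac{\bar{\Delta F}_{KO} - \bar{\Delta F}_{SCR}}
  {\sqrt{S^2_{KO} + S^2_{SCR}}}$$

with the conservative convention that only |SSMD| > 1 ("strong effect")
counts.

**Dunnett's many-to-one test** (`dunnett_test`): each KO on a plate is
compared with the plate group's shared control, with a pooled error
variance across all groups and a family-wise adjusted two-sided p value.
The adjusted p is
$1 - P\!\left(\max_j |T_j| \le |t|\right)$ under the equicorrelated
multivariate-t null induced by the shared control. We evaluate that
probability by conditioning on the control deviate $z$ and the pooled
standard-deviation ratio $u = S/\sigma$, reducing it to a smooth 2-D
integral evaluated by a composite Simpson rule (81 × 61 nodes reproduces a
401 × 401 reference to ~1e-13, and agrees with `multcomp`'s stochastic
integration to a few 1e-4). The quadrature is fully deterministic, so
results are bit-reproducible. With one comparison the test is special-cased
to the exact two-sided two-sample pooled t test. For the typical design —
19 KOs and a 3-sample control at n = 3 — the α = 0.05 critical value is
≈ 3.04, i.e. "t > 3 corresponds to p < 0.05".

A variant is a **hit** when it passes both criteria (`classify_hits`), a
**possible hit** when SSMD crosses the threshold without significance, and
a variant qualifies as a candidate if *either* the mean or the median
pipeline qualifies. We chose classical pooled-variance Dunnett even though
the SSMD uses per-group variances: the test and the effect-size measure
serve different roles (error control vs. magnitude), and both operate on
the same experiment-level values. Dunnett's family is the plate group; no
further cross-plate correction is applied, matching how arrayed screens
treat each co-processed group as one family.

**Replication** (`replication_concordance`): because a single series cannot
prove a hit, hits must recur in an independently re-generated series. A
final hit needs the dual criterion in at least one series plus
same-direction support in the other — SSMD beyond threshold, or a
normalized ΔF excess of at least 20 percentage points (the "confirmed to a
minimum of 120%" reading). Any opposite-direction estimate demotes the
variant. This codifies a narrative judgment; it is a reasonable
formalization, not a claim of exact equivalence to any manual curation.

`screen_summary` tabulates the screen's up/down asymmetry: counts above
110%/120% and below 90%/80%, SSMD beyond ±1, and significant calls by
direction.

# The synthetic screen generator

No raw screen data accompany the analysis the package models, so the
generator (`screen_config`, `simulate_screen`) is a first-class module that
embodies the statistical structure the pipeline assumes, with every
parameter exposed:

- **Sham fluorescence**: per-cell YP is log-normal with mean `sham_mean`
  (30 a.u.) and CV `sham_cv` (0.5) — non-negative, right-skewed, unimodal,
  matching the observed bell-shaped histograms. No per-cell law is published,
  so the log-normal is a modeling choice.
- **Exposure increment**: exposed cells add an increment with mean
  `slope_per_pulse × pulses` (linear dose response through the origin up to
  `linear_limit` = 50 pulses), per-cell CV `uptake_cv` (0.4), and a
  per-sample log-normal factor with CV `sample_cv` (0.15) modeling
  day-to-day biological variability. The 0.15 value was chosen to match the
  magnitude of the standard-error bars typical of such screens' control
  samples (roughly 10–15 percentage points at n = 3); it is the main driver
  of the pipeline's power characteristics.
- **KO effects and mosaicism**: a KO's multiplicative effect applies only
  to the edited fraction of its cells (`editing_fraction`); unedited cells
  respond as controls. The closed-form expectation,
  `slope × pulses × (f·effect + 1 − f)`, is exported as
  `expected_delta_f` and used as the oracle in tests.
- **Divergence above 50 pulses**: a fraction (0.3) of cells is reassigned
  to a broad component with mean and CV scaled by `divergence_scatter` (3),
  a proxy for swelling/rupture. This both degrades the histogram peak and
  lifts the mean off the linear fit, which is what the dose-response
  divergence detector flags.
- **Plate scale and outliers**: each (experiment, plate) gets a log-normal
  multiplicative scale factor (log-SD 0.15) applied to all fluorescence;
  saturating dead-cell outliers appear at rate 0.005 with mean 2000 a.u. in
  both conditions.
- **Reproducibility**: the master seed is expanded by a deterministic hash
  of (experiment, plate, variant, condition) into per-sample substreams, so
  any single sample can be regenerated independently of the rest of the
  screen.

`simulate_replication` regenerates a screen with every editing fraction
multiplied by (1 − attenuation), modeling effect fade between de-novo
generated KO series, under a fresh derived seed.

What the generator does *not* emulate: uptake kinetics over the 50-minute
incubation (endpoint only), well-position effects, gRNA off-target
structure, and any correlation between neighboring wells. Tests passing on
synthetic screens therefore validate the statistical machinery and its
calibration — not the biology of any particular gene list.

# Image front end

The optional imaging module mirrors the automated microscopy step:
`render_field` draws cells as Gaussian spots in a nuclear (Hoechst) channel
and a wider spot in the YP channel whose integral equals the cell's ground
truth; `identify_cells` segments Hoechst-positive nuclei (global Otsu
threshold + connected components, minimum area 9 px); `measure_yp` expands
each nucleus by a fixed dilation radius into a "cell region" (contested
pixels go to the nearest region), subtracts the outside-region median as
background, and integrates YP per cell. Otsu-plus-dilation is a simplified,
documented stand-in for proprietary commercial segmentation; nuclei closer
than about one spot sigma can merge, and a blank field is recognized by an
implausibly large foreground fraction (> 0.3) and returns no objects.

# Cleavage assay model

Editing is validated by the T7EI assay: `cleaved_fraction` computes
CF = (B + C)/(A + B + C) from gel band intensities (mass-proportional,
no length correction; one cut gives two equal-mass fragments).
`expected_mismatch_fraction` gives the re-annealing model: a random duplex
is cleavable with probability $1 - \sum_i p_i^2$ over allele-class
frequencies. For wild type + one indel class this is maximized at exactly
50% — the assay's detection ceiling — while pools with several distinct
indel classes can exceed it. `simulate_reannealing` closes the loop by
drawing duplexes and scoring the resulting virtual gel.

# Dose bookkeeping

`adiabatic_heating` evaluates ΔT = σE²τN/(ρc), the maximum heating with
dissipation disregarded. Defaults (σ = 1.4 S/m, ρc = 4.18×10⁶ J·m⁻³·K⁻¹)
are typical growth-medium/water values — the source analyses do not print
the constants they used — and give 0.98 K for the standard 20-pulse
treatment and exactly twice that for 40 pulses, below the 1 °C and 2 °C
bookkeeping bounds. `fit_dose_response` fits OLS to mean ΔF over 0–50
pulses and flags above-limit doses outside the extrapolated 95% *prediction*
band (each judged point is a single measurement, so the prediction band,
not the confidence band, is the right reference).

# Expression vs. LD50

`gene_ld50_correlation` computes Pearson R between a gene's expression
across cell lines and each line's LD50 (the nsEP dose killing 50% of
cells), with the two-sided p from the t transform on n − 2 degrees of
freedom. `select_and_pool` keeps genes with R ≥ 0.9 and p ≤ 0.02 and pools
the selected genes by concatenating their baseline-shifted (expression,
LD50) pairs; the shift (subtracting the most sensitive line's expression)
does not change any correlation — Pearson R is translation-invariant — but
anchors the pooled display scale. LD50 enters untransformed. The packaged
synthetic panel plants 8 LD50-linear genes among 52 null genes over six
lines whose LD50 spans an 80-fold range; planted noise is 0.14 of the
signal SD (true R ≈ 0.99), consistent with the near-perfect pooled
correlations such selections produce. No multiplicity correction is applied
over the candidate genes, matching the source procedure; at these
thresholds roughly one false positive per 52 null genes is expected.

# Numerical choices and problem sizes

- Simpson-rule grids for the Dunnett integral: 81 (control deviate, range
  ±8.5) × 61 (variance ratio, χ quantile range 1e-14 to 1−1e-12); verified
  against a 401 × 401 reference and against `multcomp`.
- Critical values are found by `uniroot` on the adjusted-p function over
  |t| ∈ [1, 12], tolerance 1e-7.
- Normalization failure (SCR mean ΔF ≤ 0, pathological) drops the plate
  with a warning rather than producing sign-flipped percentages.
- Zero-variance SSMD is reported as signed infinity with a warning and is
  never classified as a hit.
- The test suite exercises the full design at reduced problem sizes (one
  plate of 6–20 variants, 3–4 experiments, 300–1000 cells per sample; 200
  screens for null calibration; 10⁶ draws for the Monte-Carlo check of the
  Dunnett critical value; 100 panels for the expression stage), keeping the
  whole suite within a few minutes while staying inside the study's stated
  design ranges.

# Known limitations

- The generator's dispersion parameters are calibrated qualitatively (no
  per-cell dispersion at fixed dose is published); absolute power estimates
  from simulation should be read as indicative.
- Plate normalization assumes at least one well-behaved SCR sample per
  plate per experiment; designs without on-plate controls are out of scope.
- The replication-concordance rule is a codification of a narrative
  procedure; borderline variants can legitimately be judged differently.
- The image quantifier handles isolated-to-moderately-dense fields; heavy
  clumping, illumination gradients and tile stitching are not modeled.
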