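---
title: "Estimating nephron number from biopsy morphometry: models, assumptions and design choices"
author: "nephest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating nephron number from biopsy morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephest)
```

## The problem

The number of nephrons a person is born with varies enormously between
individuals — reported autopsy extremes span roughly an eight-fold range —
and a low endowment (strongly associated with low birth weight) is thought
to drive chronic kidney disease progression through single-nephron
hyperfiltration. No routine clinical measurement of nephron number exists.
`nephest` implements a practical estimator that combines two quantities a
CKD work-up can actually produce: glomerular density measured on a needle
biopsy, and the renal cortex volume measured (or predicted) from axial
tomography. Around the estimator it provides the supporting clinical
computations of a prospective CKD cohort — eGFR, endpoint construction,
eGFR slope — and the two-group log-rank sample-size design such a study
rests on, each validated against simulation oracles.

## The stereological model

Glomeruli are idealised as spheres of one common in-vivo radius $r$
(a cohort constant, estimated once from a random ~5% patient subsample),
distributed homogeneously in the cortex, the only compartment that
contains them. A needle core of internal diameter $d_b$ is sectioned; on
a section we observe circular glomerular profiles.

**Shrinkage.** Fixation and paraffin embedding shrink the tissue by about
31% in volume, and glomeruli by about 43% (they additionally lose arterial
pressure). Volume shrinkage $s$ corresponds to the isotropic linear factor
$(1-s)^{1/3}$, giving $0.8837$ for tissue and $0.8291$ for glomeruli
(conventionally printed as 0.883 and 0.829). The factors are always
*computed* from the configured fractions; on-slide lengths are divided by
the tissue factor, profile radii by the glomerular factor.

**Detection cutoff.** Profiles under 5 µm in diameter cannot be counted.
A sphere of radius $r$ produces a countable profile only when the cutting
plane passes within $h = \sqrt{r^2 - r_o^2}$ of its centre
($r_o = 2.5$ µm). Averaging the circle area $\pi(r^2 - x^2)$ over a
uniform offset $x \in (-h, h)$ gives the mean observed profile area

$$A_h = \pi\!\left(r^2 - \tfrac{h^2}{3}\right)
      = \pi\!\left(\tfrac{2}{3} r^2 + \tfrac{1}{3} r_o^2\right),$$

which reduces to the classical $\tfrac{2}{3}\pi r^2$ when $r_o = 0$. The
package checks this closed form against a Monte-Carlo sphere-sectioning
oracle (uniform plane offsets, $10^6$ draws) in its test suite.

**From counts to a number.** With $N_s$ observed profiles over a usable
cortex area $A_{cortex} = L_{a+b} \cdot d_b$ (total cortex length between
outermost and innermost glomerulus, corrected to in-vivo scale), the
Delesse principle equates area and volume fractions:

$$VF_{glom/cortex} = \frac{N_s \, A_h}{A_{cortex}}, \qquad
  N_{total} = \frac{VF_{glom/cortex} \cdot V_{cortex}}{\tfrac{4}{3}\pi r^3}.$$

```{r chain}
sp <- biopsy_specimen(biopsy_section(10, 10), needle_gauge = 16)
estimate_nephrons(sp, v_cortex = 100,
                  geometry = glomerular_geometry(r = 100, r_o = 2.5))
```

### Data-quality rules

A section containing exactly one glomerulus is ignored entirely — both
its count and its cortex length. A specimen whose total observed count
over all obtained sections is under 8 is flagged `insufficient`. The flag
travels with the numeric estimate rather than suppressing it, so cohort
filtering is an explicit, auditable step. Whether the dropped section's
length should still count toward the cortex area is genuinely open; we
drop it (the count rule reads as distrust of the whole section), and the
choice is isolated in `assess_adequacy()` should a lab prefer otherwise.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| tissue volume shrinkage | 0.31 | — | on-slide → in-vivo lengths |
| glomerular volume shrinkage | 0.43 | — | on-slide → in-vivo radii |
| detection cutoff diameter | 5 | µm | truncates observable profiles |
| `cutoff_space` | `in_vivo` | — | scale on which the cutoff is read |
| needle gauge table | ISO 9626 nominal | mm | core width $d_b$ |
| cohort radius $r$ | measured | µm | mean glomerular radius |

Two of these deserve comment. The cutoff is specified as an observed
diameter, and the source convention does not say whether "observed" means
on the slide or after shrinkage correction; we default to the in-vivo
scale (the geometry in which the whole derivation lives) and expose
`cutoff_space = "on_slide"`, which divides $r_o$ by the glomerular
factor first. The difference in $A_h$ is well under 0.1% at $r = 100$ µm,
so nothing downstream hinges on it. The needle's internal diameter is
treated as an in-vivo width (the core is cut before shrinkage); only the
gauge *number* is recorded clinically, so the mapping to millimetres is
shipped as an editable configuration table of nominal regular-wall
dimensions.

## Cortex volume

Whole-kidney and cortex volumes are plain Riemann sums of per-slice
cross-sectional areas times slice spacing — deliberately so, with no
trapezoid or end-cap correction, because that is exactly how the volumes
are read off an axial tomogram. The ellipsoid phantom
(`mri_phantom()`) provides the convergence check: the summed volume
approaches the closed-form $\tfrac{4}{3}\pi abc$ monotonically as spacing
halves, and is within 1% at 0.05 cm spacing for the unit sphere.

Because tomography cannot be performed on every patient, a sub-cohort
with measured volumes supports an ordinary least-squares estimating
equation (`fit_cortex_volume_model()`) on clinically available features
(ultrasound axes, sex, eGFR, birth weight, body weight, ...). The feature
set is configurable and no automatic selection is attempted — which
equation is right, and whether it should be disease-specific, is an open
scientific question the data will have to answer; stratified fitting is a
matter of subsetting the input. Negative predictions are floored at zero
and flagged.

## Clinical computations

eGFR uses the 3-coefficient Japanese serum-creatinine equation
($194 \cdot \mathrm{Age}^{-0.287} \cdot \mathrm{Cre}^{-1.094}$, ×0.739
for women). CKD stages follow the guideline eGFR bands (configurable),
with stages 1–2 requiring a kidney-damage marker. Low birth weight is
strictly `< 2500` g, with categorical interview answers passing through
for patients who only know whether their weight was "normal".

The composite endpoint is the first of: death, renal death (maintenance
dialysis or transplantation), an adjudicated cerebro-cardiovascular
event, or a 50% reduction of eGFR from enrollment. Adjudication encodes
the study definitions (MI: ≥2 of chest symptoms / ECG changes / enzymes;
angina: all of ECG abnormality, symptoms, intervention; stroke: >24 h
neuropathy with imaging lesion, excluding TIA and asymptomatic
infarcts). Two open points are resolved as follows and flagged in the
API: a *single* sub-50% eGFR measurement triggers the endpoint (the
source states no confirmation rule; `confirm_egfr = TRUE` requires a
consecutive confirmation), and the baseline for the 50% rule is the
enrollment value. When an adjudicated event and an eGFR halving fall on
the same day the eGFR component is reported — an arbitrary but fixed
tie-break mirrored by the synthetic-cohort truth tables. The eGFR decline
rate is the OLS slope over all available annual values; mixed-model
shrinkage is out of scope.

## The log-rank design

The design assumes exponential event times, uniform entry over a 2-year
accrual interval, 3 further years of follow-up (so individual follow-up
is uniform on 3–5 years), a low-birth-weight prevalence of 0.095 fixing
the allocation, event rates 0.1 vs 0.2, two-sided α = 0.05 and power
0.80. "Event rate" is ambiguous; both readings are implemented
(`rate_interpretation`), with per-year hazard as the default — under the
cumulative reading the implied hazard difference is so small that no
plausible cohort size results, which is itself evidence for the hazard
reading.

Classical sample-size approximations disagree substantially at a 0.095 /
0.905 allocation with a hazard ratio of 2, so `required_sample_size()`
implements four published variants side by side (null-variance
hazard-difference formula; Schoenfeld events; a binomial events form;
per-group expected events) and reports every intermediate. The default,
`"protocol"`, is the variant that reproduces protocol-style calculations
of this era exactly: the null-variance two-sample exponential formula

$$N = \frac{(z_{\alpha/2} + z_\beta)^2 \; \bar\lambda^2 / E(\bar\lambda)}
          {Q_1 Q_0 (\lambda_1 - \lambda_0)^2},
  \qquad E(\lambda) = 1 - \frac{1 - e^{-\lambda T}}{\lambda T},$$

with enrolment spread uniformly over the whole study window $T$, the
resulting $N$ assigned to the majority (normal-birth-weight) group and
the minority group sized by the allocation odds $Q_1/Q_0$, rounded to
the nearest integer (this variant rounds to nearest precisely because
that is the arithmetic it reproduces; the other variants round up). Its
strict reading ($N$ as the total, split by $Q_1/Q_0$ and rounded up) is
returned alongside in the intermediates rather than silently discarded.

```{r design}
spec <- design_spec()
required_sample_size(spec, variant = "protocol")
```

Monte-Carlo verification (`simulate_power()`) simulates the trial as
stated — uniform entry, exponential events, administrative censoring —
and applies the package's own log-rank test, which is in turn checked
against `survival::survdiff` and a brute-force 2×2 tabulation in the
suite. Two facts emerge and are asserted by the acceptance tests: the
test's type-I error is correctly calibrated at these very unequal group
sizes, and the design *over*-attains its nominal power (the simulated
power at the protocol's group sizes is near 0.89 rather than 0.80,
because the textbook approximations are conservative-to-crude at extreme
allocation; the suite therefore asserts that the target power is
*reached*, not that it is matched as an equality). Replicates use
seeds drawn upfront from the master seed, one per replicate, so results
are reproducible regardless of how many random draws a replicate
consumes.

## What the synthetic-data engine emulates — and what it does not

`virtual_kidney()` + `sample_biopsy()` realise the estimator's own
model: Poisson-distributed sphere centres at intensity
$N_{true}/V_{cortex}$, a section observing every sphere whose centre
lies within $\pm h$ of the plane, profile radii $\sqrt{r^2 - x^2}$,
forward shrinkage applied so specimens arrive in on-slide units. The
simulation volume is implicitly buffered so sampling is edge-effect
free. Defaults (700 000 glomeruli of radius 100 µm in 100 cm³ of cortex,
16G needle, three 10-mm sections) give roughly 17 expected profiles per
section. Parameter recovery on 500 simulated biopsies is the headline
acceptance property (relative bias of the mean estimate under 5%).

`generate_cohort()` draws birth weights from a two-component Gaussian
mixture whose mixing weight is solved in closed form so the realised
< 2500 g prevalence equals the configured 0.095; nephron numbers are
linear in birth weight (250 glomeruli/g over an intercept of 130 000,
noise SD 180 000 — placing a 3.2 kg newborn near 930 000 and spanning
the published extremes); event times are exponential with the group
rates; eGFR declines linearly with a slope that steepens as nephron
number falls, observed with Gaussian noise at annual visits and
serialised through the *inverse* eGFR equation into serum creatinine, so
the clinical module must reconstruct everything from raw registry
columns. With noise set to zero the pipeline identity is exact and is
asserted row-for-row.

The engine deliberately does **not** emulate: glomerular size
heterogeneity within a kidney (the estimator itself assumes a single
$r$; a radius-variability switch would test sensitivity, not
correctness), non-homogeneous glomerular placement (cortical depth
gradients), measurement error in lengths and areas, informative dropout,
competing risks, or anatomically realistic kidney shapes and imaging
noise. Passing tests therefore demonstrate internal consistency of the
method under its own assumptions — not robustness to their violation in
real tissue.

## Numerical and degenerate-input choices

* All internal geometry is in micrometres; cortex volumes carry explicit
  unit tags (`cm3`/`mm3`/`um3`) and unknown units are an error, never a
  guess.
* Volume fractions above 1 are clipped to 1 with a warning and a
  `clipped` attribute (they indicate unit mistakes, not biology).
* A specimen whose every section is unusable yields a zero estimate with
  the `insufficient` flag, not an error.
* `event_probability_under_accrual()` is continuous at λ = 0 (returns 0)
  and degenerates to fixed follow-up when the accrual interval is 0.
* The log-rank test handles ties through the hypergeometric variance; a
  degenerate variance of 0 yields statistic 0 rather than NaN.
* The random-sampling operations (`cohort_mean_radius()`,
  `sample_biopsy()`, `generate_cohort()`, `simulate_power()`) restore
  the caller's RNG state.

## Validation problem sizes

The shipped suite runs the Monte-Carlo profile-area oracle at $10^6$
draws (10 random geometries), nephron recovery at 500 biopsies, power
and type-I error at 5000 simulated trials each, calibration checks of
the cohort generator at 20 000 patients, and the noiseless endpoint
identity at 400 patients — sizes chosen so each check's Monte-Carlo
error is comfortably below the tolerance it asserts while the whole
suite stays interactive.

## Known limitations

* The estimator inherits every assumption of its derivation: common
  spherical glomeruli, homogeneous placement, unbiased uniform
  sectioning. Real cortices violate all three to some degree.
* $r$ is a cohort constant by design; per-patient glomerular volume is
  deliberately out of scope.
* The cortex-volume estimating equation is a generic linear predictor;
  its clinical adequacy is exactly what a sub-cohort study must
  establish.
* The sample-size module reproduces and cross-examines classical
  approximations; if a design must hit a simulated power exactly, size
  it with `simulate_power()` directly.
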