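---
title: "Right-ventricular PV-loop, myofilament and molecular analysis with pvloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Right-ventricular PV-loop, myofilament and molecular analysis with pvloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvloop)
```

## Scope

`pvloop` implements the quantitative analysis chain of an invasive
hemodynamic study of right-ventricular (RV) function in large-animal chronic
thromboembolic pulmonary hypertension (CTEPH): conductance-catheter
pressure-volume (PV) loops with thermodilution/saline calibration and
caval-occlusion family fits; skinned-cardiomyocyte force–pCa and
sarcomere-length/passive-tension mechanics with hierarchical statistics; and
molecular quantification (2^−ΔΔCT qPCR, Western-blot densitometry, histology
morphometry). Because animal recordings cannot ship with a package, every
stage is paired with a synthetic-data generator whose ground truth is known
in closed form, so the whole pipeline is verifiable by parameter recovery.

## The beat-level elastance model

The generator does not integrate a closed-loop circulation ODE. Each beat is
rendered directly from the quantities the analyzers estimate, which gives
closed-form truth for every recovery test:

* **Coupling.** Given end-systolic elastance $E_{es}$ (slope of the ESPVR
  $P = E_{es}(V - V_0)$), effective arterial elastance $E_a = ESP/SV$, and a
  prescribed end-diastolic volume, the end-systolic volume is the analytic
  coupling solution
  $$ESV = \frac{E_a\,EDV + E_{es}\,V_0}{E_a + E_{es}},$$
  so $ESP = E_{es}(ESV - V_0) = E_a(EDV - ESV)$ holds exactly.
* **Four phases per cycle** (default fractions 0.08 / 0.30 / 0.12 / 0.50 of
  the RR interval at a default 1 kHz sampling rate): isovolumic contraction
  at $V = EDV$ (half-cosine ramp EDP→ESP); ejection $EDV \to ESV$ with a
  half-sine pressure through the rendered peak and endpoint ESP; isovolumic
  relaxation at $V = ESV$ following the logistic decay
  $$P(t) = \frac{P_A}{1 + e^{t/\tau}} + P_B,\qquad P_B = 2\ \mathrm{mmHg},\;
  P_A = 2(ESP - P_B);$$
  and filling $ESV \to EDV$ along the exponential-with-asymptote EDPVR
  $P = P_\infty + A e^{\beta V}$, plus a quadratically vanishing continuity
  term that joins the logistic tail and is exactly zero at end-diastole.
* **Occlusion runs** prescribe a linearly falling EDV per beat with fixed
  $E_{es}, E_a, V_0$: all end-systolic points are collinear on the ESPVR to
  machine precision and all end-diastolic points lie exactly on the EDPVR.
* **PA channel.** A two-segment sinusoid that hits the preset systolic and
  diastolic pressures exactly. A waveform's time-average depends on its
  shape, so the preset *mean* PA pressure travels as metadata and is the
  value used for PVR.

Rendering the relaxation with the same logistic family the analyzer fits is
deliberate: it makes $\tau$ recovery well-posed and lets the round-trip test
detect analyzer bugs rather than model mismatch.

Two presets encode a severe-CTEPH and a sham RV phenotype
(`make_preset("cteph")`, `make_preset("sham")`): EF 35% vs 51%, $E_{es}$
2.0 vs 0.47 mmHg/mL, $\tau$ 20 vs 13 ms, $\beta$ 0.038 vs 0.015 /mL, PA
(s/m/d) 70/51/38 vs 32/24/14 mmHg, CO 4.2 vs 6.0 L/min. The CTEPH preset's
heart rate (96 bpm) and LV end-diastolic pressure (9 mmHg) are chosen so
that the derived indices are mutually consistent: $CO = SV \cdot HR$ gives
exactly 4.2 L/min and $PVR = (mPAP - LVEDP)/CO$ exactly 10.0 Wood units.

What the generator does **not** emulate: respiratory modulation (the study
design it mirrors suspends ventilation at end-expiration), ECG, catheter
artifacts, afterload changes during occlusion, or beat-to-beat variability
beyond additive Gaussian pressure noise. Passing recovery tests therefore
demonstrate correctness of the estimators under the model's assumptions, not
robustness to every artifact of real catheter data.

## Beat segmentation and landmarks

Cycles are delimited at the onset of isovolumic contraction: the upward
crossing of dP/dt through **+10% of its running maximum**, computed on a
zero-phase 25 Hz low-pass (Butterworth, reflect-padded) trace so that
additive noise cannot create false triggers; a 200 ms refractory period and
an RR-based ectopy rule (deviation > 20% from the running median RR) guard
the occlusion analysis. Each crossing is then walked back while dP/dt stays
above 1% of the running maximum, so the beat onset sits at the foot of the
upstroke and the ED landmark (first maximum-volume sample) reads the true
end-diastolic pressure rather than a value part-way up the ramp.

Conventions chosen where the field has several:

* **ES is the minimum-volume point**, not the maximum-P/V-ratio point; this
  avoids a circular dependence on $V_0$ inside beat analysis.
* **$\tau$ window**: from dP/dt$_{min}$ to the sample where pressure first
  falls to the beat's own EDP (the Matsubara-style window), $t = 0$ at
  dP/dt$_{min}$. This window is a package convention — the logistic model is
  the prescribed form, the window is not.
* **Stroke work** is the shoelace area of the sampled loop polygon; at 1 kHz
  it agrees with the analytic loop area to well under 1%.
* Sample indices are 1-based with closed `[start, end]` windows.

## Calibration

The conductance channel is modelled as $U(t) = \alpha\,(V(t) + V_p)$ with
field-inhomogeneity gain $\alpha$ and parallel-conductance volume $V_p$.

* $\alpha$ comes first, from stroke volumes: $\alpha = SV_{uncal} /
  (CO_{TD} \cdot 1000 / HR)$ — the offset $V_p$ cancels out of any SV.
* $V_p$ comes from the hypertonic-saline transient. Saline raises blood
  conductivity but not the parallel (tissue) term, so on $\alpha$-corrected
  volumes $V'_{es} = m V'_{ed} + b$ with $m = ESV/EDV < 1$, and the
  intersection with the identity line gives $V_p = b/(1-m)$. The generator
  implements wash-in as a per-beat multiplicative gain on the blood-volume
  term (apparent ED volume rising by `drift_per_beat` mL per beat, true SV
  constant), which is the physical mechanism that makes this extrapolation
  identifiable; a slope $m \ge 1$ is a hard error, and a transient whose
  ED-volume span is below 2 mL is flagged low-confidence rather than used
  silently. Estimating $V_p$ after $\alpha$-scaling keeps it in mL.

## Occlusion-family fits

* **ESPVR**: OLS of ESP on ESV. A quadratic fit runs alongside and its
  fractional curvature contribution $|c_2|(\Delta ESV)^2 / \mathrm{range}(ESP)$
  is always reported; "negligible quadratic term" is operationalized as
  ≤ 5% (no threshold exists in the source convention), and a linear fit is
  returned regardless, with a warning above it.
* **EDPVR**: $P = P_\infty + A e^{\beta V}$ by Levenberg–Marquardt with a
  deterministic start ($P_{\infty,0} = \min P - 0.5$, then a log-linear
  regression for $A_0, \beta_0$) and the asymptote bounded below at
  −20 mmHg. The optimizer is called directly (`minpack.lm::nls.lm`) because
  the $A$ and $\beta$ gradient columns are nearly collinear on narrow volume
  spans and trip `nls()`'s singular-gradient check even at the optimum.
* **PRSW**: OLS of stroke work on EDV; slope $M_w$ (mmHg), volume intercept
  $V_w$.
* **Derived indices**: $E_a = ESP/SV$ over steady beats; coupling
  $VVC = E_{es}/E_a$, computed per animal and averaged afterwards (mean of
  ratios, matching how a group-mean VVC relates to the group's $E_{es}$ and
  $E_a$ summaries); $PVR = (mPAP - LVEDP)/CO$ in Wood units, with LV EDP as
  the documented surrogate for wedge pressure and negative gradients flagged
  rather than clipped.

All fits are deterministic: fixed initialization rules, no stochastic
restarts.

## Myofilament mechanics

Force is normalized by the elliptical cross-section $CSA = \pi w d / 4$;
passive tension comes from the slack test (force drop on shortening to 80%
length); active tension is total minus passive. The force–pCa relation is
the Hill curve
$$AT = \frac{AT_{max}}{1 + (EC_{50}/[\mathrm{Ca}^{2+}])^{n_H}},$$
parameterized internally in $pCa_{50} = -\log_{10} EC_{50}$ and fitted with
a free Hill coefficient; SL–PT uses $PT = a e^{b\,SL}$ without offset (an
offset variant would add a parameter the 6-point design cannot support).
Confidence bands are cluster bootstraps that resample **myocytes**, not
points, preserving within-cell correlation; 5,000 resamples is the
production default, tests use fewer.

One identifiability fact shapes the recovery expectations, and we derived it
from the Fisher information of the design rather than from simulation: with
six pCa points (5.0–6.0), homoscedastic residual noise of 5% of $AT_{max}$
and a free $n_H$, the Cramér–Rao bound puts the best attainable median
relative error of $AT_{max}$ at ≈ 3.7% (the least-squares fit sits on that
bound); $pCa_{50}$ is an order of magnitude better determined (≈ 0.4%).
Similarly the SL–PT amplitude $a$ is the curve extrapolated to $SL = 0$,
two full sarcomere lengths below the data, and is intrinsically poorly
determined; the exponent $b$ and the in-range prediction $PT(2.2\,\mu m)$
are the recoverable quantities. The myocyte generator's default residual
noise is 0.5 kN/m² on active tension and 2% of the cell's 2.2-µm passive
tension on PT, reflecting force-transducer precision that is small relative
to between-myocyte spread.

## Molecular quantification

Relative expression uses 2^−ΔΔCT with dual housekeepers (GAPDH, RPL4):
replicate Cts are averaged; ΔCt subtracts the *arithmetic mean* of the
housekeeper Cts, which is exactly the geometric mean of the linear
housekeeper quantities when efficiencies are equal (the efficiency check
must pass first — dilution-series slope, $E = 10^{-1/slope} - 1$, flagged
when a target differs from the housekeepers by more than 5 percentage
points); ΔΔCt subtracts the reference-group mean ΔCt, so the reference
group's geometric-mean fold is 1 by construction. The reference is the
sham-group mean (not a paired calibrator sample) — an assumption, recorded
here. Densitometry averages duplicates, forms target/normalizer ratios and
rescales to a reference-group mean of 1. Morphometry treats the **animal**
as the statistical unit (cell- or vessel-level values are averaged within
animal first) and warns below the design minimums (60 cardiomyocytes, 10
arterioles, 10 fields per animal). Percent wall thickness is
$100(D_{ext} - D_{lumen})/D_{ext}$ — the convention must be stated because
a 2×medial-thickness variant exists; the ratio is scale-invariant.

## Statistics layer

* **Two-group dispatcher**: Shapiro–Wilk per group at α = 0.05; both normal
  → F-test of variances → Student (homogeneous) or Welch; otherwise
  Mann–Whitney U. Descriptives follow the decision (mean ± SEM vs median
  (range)), and the full decision trace is returned so every test choice is
  reproducible. No multiple-testing correction is applied — single
  pre-specified comparisons per variable, at two-tailed α = 0.05;
  this mirrors the analysis design it reimplements and is stated here
  prominently.
* **ANCOVA for fit-derived parameters**: `response ~ group + covariates`
  where the covariates are the co-fitted parameters ($V_0$ for $E_{es}$;
  $A$ and $P_\infty$ for $\beta$) — the natural reading of "accounting for
  other fit parameters"; the response is log-transformed when residual
  normality fails and all values are positive, and the transformation is
  recorded.
* **Nested mixed model** for myocyte data:
  `response ~ group + (1 | animal) + (1 | animal:myocyte)`, REML. The group
  test uses Satterthwaite degrees of freedom: at 6 + 7 animals a plain Wald
  z-test is anticonservative, and the Satterthwaite t keeps the null
  rejection rate at ≈ 0.05 (verified over 200 simulated null datasets in
  the test suite).
* **Report rendering**: a fixed-shape summary table (mean ± SEM or median
  (range) per the dispatcher, test name, p, significance marker at
  p < 0.05) with deterministic decimal rules — integers for pressures and
  volumes, one decimal for elastances and ratios, three for $\beta$ — and a
  TSV round trip that re-reads bit-exactly at printed precision.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
the sizes the study design implies: 5-beat steady acquisitions and 12-beat
occlusions at 1 kHz, 8-beat saline transients, 100-seed noise sweeps for
calibration and ESPVR, 200 myocytes for fit-recovery sweeps, and 200
simulated null datasets for mixed-model calibration. Every stochastic
routine takes an explicit seed and is bit-reproducible; all fits use fixed
deterministic initializations.

## Known limitations

* The beat model shares its relaxation and EDPVR families with the
  analyzers; robustness to model mismatch (e.g. a mono-exponential
  relaxation) is not what the recovery tests measure.
* $AT_{max}$ recovery at 5%-of-scale noise is bounded at ≈ 3.7% median
  error by the design itself (see above); tighter claims require more pCa
  points or saturating activation levels.
* Single-beat (non-occlusion) $E_{es}$ estimation, ECG-gated segmentation,
  Baan's full conductance equation (blood resistivity, electrode spacing)
  and pixel-level image analysis are out of scope; inputs to morphometry
  are measurement tables.
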