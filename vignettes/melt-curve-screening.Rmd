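---
title: "Thermal shift screening from melt curves: model, statistics and design"
author: "meltscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal shift screening from melt curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltscreen)
```

## The measurement

Membrane transporters rarely come with a convenient activity assay, but
their thermal stability responds to ligand binding: a substrate that binds
the folded state makes unfolding harder, so the population melts at a
higher temperature. In the CPM flavour of the assay, a thiol-reactive
coumarin dye becomes fluorescent when it reaches cysteines that are buried
in the folded protein and become exposed during thermal unfolding over a
25–90 °C ramp. The read-out per well is therefore a rising fluorescence
curve F(T), and the *apparent melting temperature* (Tm) is the temperature
at which the rate of unfolding of the population is highest — operationally,
the peak of the derivative dF/dT.

A screen compares each compound well against no-ligand control wells of the
same instrument run. The temperature shift

\[\Delta T_m = T_m(\text{compound}) - \overline{T_m}(\text{controls, same run})\]

is the quantity of interest: positive shifts indicate stabilizing
(candidate-substrate) binding, negative shifts destabilization. A shift of
a condition contrast, \(\Delta\Delta T_m\), compares the same compound
between two buffers (pH 6 vs pH 8, Na⁺ vs K⁺) and probes whether a coupling
ion or proton participates in binding.

## The simulator

No public raw fluorescence data exist for screens of this kind, so the
package ships a generative model whose defaults define the study
conditions used in all tests and in `scripts/acceptance.R`.

Each well is a two-state van't Hoff unfolding transition with linear
baselines:

\[\Delta G(T) = \Delta H_{vH}\left(1 - \frac{T}{T_m}\right),\qquad
  K = e^{-\Delta G/RT},\qquad f_u = \frac{K}{1+K}\]

\[F(T) = (a_n + b_n T)(1-f_u) + (a_u + b_u T)f_u + \varepsilon,\qquad
  \varepsilon \sim N(0, \sigma)\]

with temperatures in kelvin inside the thermodynamic formulas only
(R = 8.314 J mol⁻¹ K⁻¹, ΔCp = 0). Ligand binding to the folded state moves
the midpoint to the root of
\(\Delta H_{vH}(1 - T^*/T_{m0}) + R\,T^*\ln(1 + [L]/K_d) = 0\),
found by bracketed root finding on [Tm₀, Tm₀ + 40 °C]; the shift is zero at
zero concentration, grows with \([L]/K_d\), and needs concentrations well
above \(K_d\) to become appreciable, which is why such screens are run at
millimolar compound concentrations. Screen fixtures encode compounds by
their *true shift* directly (screens report shifts, not affinities); the
`LigandSpec` route exists for dose–response demonstrations.

Defaults, chosen once:

* **ΔH_vH = 500 kJ/mol** — a sharp transition (10–90 % width ≈ 8 °C) of the
  kind detergent-solubilised transporters show in this assay.
* **Baselines** a_n = 10, b_n = 0.05, a_u = 110, b_u = −0.2 AU: transition
  amplitude ≈ 85 AU with a gently declining post-transition baseline, as
  dye assays often show.
* **Noise σ = 1.7 AU**, i.e. 2 % of the transition amplitude.
* **Between-run jitter 0.3 °C** on the apo midpoint: independent protein
  batches melt at slightly different temperatures; 0.3 °C is the scale of
  the replicate scatter such assays report.
* **Replicates**: each biological repeat of each condition arm is one run
  with 3 technical control wells and one well per compound; screens use 3
  or 5 biological repeats.

Together these defaults reproduce replicate standard deviations of ΔTm of
roughly 0.15–0.35 °C, the lower end of what published screens of this type
show. What the simulator deliberately does **not** model: irreversible dye
labelling kinetics and scan-rate dependence, aggregation, dye depletion,
multi-domain (multi-transition) unfolding, and plate-position effects.
Passing the packaged recovery tests therefore shows the pipeline is
correct and calibrated *under two-state assumptions with Gaussian noise*,
not that every real curve will be well-behaved — which is exactly what the
QC flags are for.

## Tm calling

The caller is `smoothCurve()` → `derivativeCurve()` → peak refinement:

1. Savitzky–Golay smoothing (window 7, order 3): a local least-squares
   cubic, which passes polynomials of degree ≤ 3 through unchanged, so the
   transition shape is preserved while reading noise is suppressed. A
   non-uniform temperature grid (beyond 10⁻⁶ °C) is an error directing the
   user to resample: the filter and derivative both assume the 1 °C grid.
2. Central-difference derivative (one-sided at the ends).
3. Global maximum of +dF/dT; downward slopes (post-transition signal
   decline) are ignored. Ties resolve to the lower temperature.
4. Sub-grid refinement: a least-squares parabola over ±3 grid points
   around the maximum; its vertex is the reported Tm. The wider fit
   (rather than the minimal 3-point vertex) roughly triples the noise
   averaging while remaining exact for locally quadratic peaks; the vertex
   is clamped to the fit window as a guard against pathological fits.

Baseline slopes are *not* fitted or subtracted: for monotone curves of
modest baseline slope the derivative peak is insensitive to them, and this
matches how such screens read their instruments directly.

Two numerical facts matter for interpretation. First, on the 1 °C grid at
zero noise the caller reproduces the continuous derivative-peak location to
better than 0.02 °C across midpoints 35–80 °C and enthalpies 200–600
kJ/mol. Second, the derivative peak of a van't Hoff sigmoid is *not* the
thermodynamic midpoint: it sits below it by approximately
\(4R^2T^3/\Delta H_{vH}^2\) — about 0.04 °C at 500 kJ/mol but 0.25 °C at
200 kJ/mol. The apparent Tm is therefore defined operationally (as the
assay defines it), and the accuracy contract of the caller is against the
exact derivative-peak location. Control subtraction cancels this offset in
ΔTm to well below 0.01 °C, which is why shifts are the robust quantity.

Quality control is expressed as flags, never errors: `no_transition`
(transition rise, the baseline-corrected positive derivative integrated
around the peak, below 20 % of the signal range), `edge_peak` (maximum
within 2 grid points of a ramp end — the transition is truncated and the
vertex would extrapolate), `multi_peak` (secondary peak ≥ 5 °C away
reaching 60 % of the main peak). Flagged wells keep their Tm but are
excluded from statistics by default; they reduce n and are never imputed.

## Screen statistics

Per run, the control Tm is the arithmetic mean of unflagged control wells
(technical repeats); per compound and run, ΔTm subtracts it from the test
well of the same run. The per-compound sample is then the per-repeat ΔTm
values across biological repeats.

The null hypothesis is that a compound's ΔTm is zero. Two test forms are
implemented:

* **`one_sample`** (default): one-sample t on the per-run shifts. Because
  control subtraction is within-run, batch-to-batch midpoint variation
  cancels exactly, and the per-run shifts are independent; under the
  generative model the test holds its nominal level (the packaged
  calibration suite measures the starred fraction of null screens at
  α = 0.05 against the exact binomial interval).
* **`welch`**: the two-sample unequal-variance (Welch/Satterthwaite) t of
  test-well Tm against per-run control means, the form screening papers
  conventionally quote. With no between-run variation it tests the same
  null and the two forms agree. With real batch effects, however, both
  samples carry the *same* run effects; the two-sample form ignores that
  pairing, inflates both variances, and becomes conservative — with the
  default 0.3 °C jitter its realized type-I rate is far below nominal.
  That is why the run-paired form is the default, and why the package
  documents rather than hides the distinction. Whether the technical
  control repeats should also count as t-test observations is a genuine
  ambiguity in this assay tradition; here they are averaged within run,
  and the test's units are biological repeats.

Stars follow the screening convention (`*` < 0.05, `**` < 0.01, `***`
< 0.001, `****` < 0.0001, boundaries to the less significant class). No
multiple-testing correction is applied by default — hit lists of this
assay type are conventionally reported uncorrected, and at α = 0.05 a
132-compound null screen is *expected* to star about 6–7 compounds, which
is visible in the fixtures' decoys; Benjamini–Hochberg adjustment is one
flag away (`correction = "bh"`) and can only shrink the hit list.
Compounds with fewer than two usable repeats are reported with `n`, no
p-value, and `ns`.

`conditionContrast()` subtracts a compound's mean shift between two
conditions, propagates the standard error as the root sum of squares, and
applies the Welch test to the two per-repeat shift samples — appropriate
here because the two conditions are separate runs, so no pairing exists to
exploit.

## Fixtures and what the acceptance run recomputes

`builtinScenarios()` encodes six published screen outcomes as ground
truth: the GalP sugar screen (apo 57.6 °C; D-glucosamine 5.7, D-glucose
4.2, D-galactose 2.1 °C; L-isoform decoys null), the Mhp1 hydantoin screen
(apo 51.3 °C; L-NMH 15.6, L-IMH 14.1, L-BH 13.6, BVH 11.9 °C), the
ADP/ATP-carrier nucleotide screen (ATP 7.2, ADP 6.0, dADP 1.8, AMP 0 °C;
the apo midpoint 60 °C is a synthetic choice, as only shifts were
published), the 132-compound mitochondrial library against the
*T. thermophila* phosphate carrier (apo 56.0 °C; phosphate 4.6,
glyoxylate 3.6, acetyl-phosphate 3.2, phosphoenolpyruvate 2.3 °C, 128
null decoys), its pH 6/pH 8 contrast (phosphate 4.6 vs 2.6 °C), and the
Mhp1 ion panel (large hydantoin stabilization only with 140 mM Na⁺; the
small 1.0 °C non-coupling-ion shifts are a synthetic choice).

`scripts/acceptance.R` simulates these scenarios at the given seed, runs
the full pipeline (simulate → call Tm → aggregate), and reports the
recovered apo midpoints and mean shifts — a parameter-recovery experiment
whose targets are the published values. The problem sizes are the
scenarios' own (70–405 curves each, seconds per scenario); the calibration
suite in the tests uses 200 ten-compound null screens.

## Worked example

```{r example}
res <- screenScenario("aac", seed = 42)
records(res$report)[, c("compound", "n", "mean_delta_tm_C",
                        "sd_delta_tm_C", "p_value", "stars")]
rankHits(res$report)$compound
```

```{r contrast}
ph <- screenScenario("tt_pic_ph", seed = 42)
conditionContrast(ph$report, "pH6;Na=50", "pH8;Na=50")[,
  c("compound", "delta_delta_tm_C", "se_delta_delta_tm_C", "stars")]
```

## Known limitations

* The caller assumes a single dominant transition; genuinely multiphasic
  curves are flagged, not deconvolved.
* Apparent Tm is kinetic in real dye assays (irreversible labelling, fixed
  scan rate); values are comparable within a protocol, not absolute
  thermodynamic midpoints.
* ΔTm magnitudes are not converted to affinities: the mapping depends on
  ΔH and concentration, and stabilizers may be inhibitors or regulators
  rather than substrates — binding candidates still need transport assays.
* The pH and ion contrasts compare shifts, which isolates the effect of
  the condition on *binding*; the condition may also change protein
  stability and dye chemistry, which the control subtraction absorbs.
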