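---
title: "Biionic permeability ratios and voltage-dependent block: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biionic permeability ratios and voltage-dependent block: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biionic)
```

## The measurement problem

Two-electrode voltage clamp (TEVC) of *Xenopus laevis* oocytes is the
workhorse assay for characterizing heterologously expressed glutamate-gated
channels, in particular NMDA-receptor diheteromers whose pore properties —
Ca^2+^ permeability and voltage-dependent Mg^2+^ block — are set by the
residues at the tip of the pore loop. Two numbers summarize those
properties:

* **P~Ca~/P~mono~** — the permeability of Ca^2+^ relative to the lumped
  intracellular monovalent cations, obtained from the reversal potential of
  agonist-evoked current recorded under *biionic* conditions (extracellular
  monovalents replaced by impermeant NMDG, leaving Ca^2+^ as the only
  putatively permeant cation outside).
* **Percent Mg^2+^ block** — the fractional reduction of the agonist-evoked
  current when Mg^2+^ is added to the bath at a negative holding potential.

This package implements the complete analysis path for both, plus a
generative TEVC simulator so every stage can be validated against known
ground truth without laboratory data.

## The biionic GHK equation

With only monovalent cations (concentration $[Mono^+]_i$, equal
permeabilities) inside and only Ca^2+^ (concentration $[Ca^{2+}]_o$)
permeant outside, setting the sum of the constant-field (GHK) currents for
the two species to zero at the reversal potential $E_{rev}$ gives

$$
\frac{P_{Ca}}{P_{mono}}
  = \frac{[Mono^+]_i \; e^{x}\,(e^{x}+1)}{4\,[Ca^{2+}]_o},
  \qquad x = \frac{E_{rev} F}{R T}.
$$

`ghk_permeability_ratio()` evaluates this expression;
`ghk_current()` provides the underlying single-species GHK currents, and
the package's tests verify that the zero crossing of the summed currents
coincides with the inversion of the formula above — the two routes are kept
distinct precisely so that one can check the other.

The equation is strictly increasing and convex in $E_{rev}$. Convexity
matters for reporting: the mean of per-cell ratios exceeds the ratio
evaluated at the mean reversal potential whenever the per-cell reversal
potentials are dispersed. `build_permeability_table()` reports the mean of
per-cell ratios (consistent with per-cell SEMs) and exposes the
ratio-at-mean-E~rev~ alongside, so the difference is always visible.

### Calibration of the intracellular monovalent concentration

$[Mono^+]_i$ is not measured directly. Following standard practice, it is
obtained per oocyte batch by recording a reference channel whose
P~Ca~/P~mono~ is known from the literature (classically the GluR6(Q)
kainate receptor) and inverting the equation
(`calibrate_mono_i()`, wrapped in `calibration_record()`). The reference
ratio is deliberately *not* defaulted in the package: it is a per-batch
input. The inversion is algebraic, and the round trip
forward∘inverse is the identity to better than $10^{-9}$ relative error
across the physiologically meaningful range (tested on a $10^3$-point
grid).

A useful consistency check, which the test suite encodes: calibrating from
a conventional wild-type operating point ($E_{rev} = -29.3$ mV, ratio 2.3,
4 mM Ca^2+^, 293.15 K) yields $[Mono^+]_i \approx 89.4$ mM, and forward
evaluation at five other published-style operating points reproduces their
one-decimal ratios exactly. Three rows do *not* reproduce under that single
shared calibration (forward values 1.8, 0.9 and 0.5 against printed 1.7,
0.4 and 0.2). The regression suite asserts these discrepancies rather than
hiding them; the plausible causes are (i) per-batch calibration — each
batch has its own $[Mono^+]_i$, while the recomputation necessarily uses
one shared value — and (ii) mean-of-ratios versus ratio-of-means
aggregation of per-cell values, which diverges strongly for the
high-variance glycine-condition rows.

## Reversal-potential estimation

`ramp_to_iv()` bins a 2-s, −150→+50 mV command ramp (sampled at ≥ 1 kHz in
the default protocol) onto a regular 1-mV grid by within-bin averaging; the
oversampled ramp makes this lossless in practice while giving all sweeps a
common grid. `subtract_background()` removes leak and endogenous
conductances by subtracting the mean of two agonist-free control IVs
bracketing the agonist sweep — the subtraction is exact for any ohmic leak,
which the simulator-based tests confirm to numerical precision.
`estimate_reversal_potential()` then takes the zero crossing by linear
interpolation between the bracketing grid points. Numerical choices:

* **Search window** −120…0 mV by default: every reversal potential this
  assay produces lies well inside it, and it excludes the noise-dominated
  extremes of the ramp.
* **Multiple crossings** (possible under noise) resolve to the crossing
  closest to the point of minimal current magnitude, and the multiplicity
  is flagged on the result (`n_crossings` attribute) rather than silently
  discarded.
* **No crossing** raises a typed error (`biionic_no_reversal`): a cell
  without a measurable reversal is reported, never guessed.
* **Junction potential.** Measured command potentials are offset from the
  true membrane potential by the liquid junction potential (−4.5 mV for
  these solutions). `correct_junction_potential()` *adds* the junction
  value (so corrected potentials are 4.5 mV more negative under the
  default) and marks the result, making double correction an error. The
  simulator applies the same offset generatively, so end-to-end recovery
  tests exercise the bookkeeping.

## Voltage-dependent block and its quantification

The simulator represents Mg^2+^ block with the Woodhull model: a blocker
binding at fractional electrical depth $\delta$ sees a voltage-dependent
dissociation constant $K_d(V) = K_d(0)\,e^{z\delta F V/RT}$, giving an
unblocked fraction $K_d(V) / (K_d(V) + [B])$
(`woodhull_unblocked_fraction()`). This is a generative device: the
published-style measurements report percent block, not block-model
parameters, so the package measures block exactly as an experimenter does —
within a single application sweep, comparing the agonist-evoked plateau
before the Mg^2+^ pulse with the plateau during it (`percent_block()`,
`application_measurements()`).

Responses are quantified as the baseline-subtracted plateau mean over the
last 25 % of each segment (configurable to the extremum): 20-s applications
reach steady state, and the plateau mean is far more noise-robust than a
pointwise extremum.

**Apparent block above 100 %.** If Mg^2+^ also suppresses part of the
oocyte's leak conductance, the within-sweep measurement attributes that
leak suppression to the agonist-evoked current, and the apparent block is

$$
\text{block}_{app} = 100\cdot\frac{f_{ch}\,IC + f_{leak}\,LC}{IC},
$$

which exceeds 100 % whenever $f_{leak} LC > (1-f_{ch})\,IC$ — i.e. for
small agonist-induced currents (IC) riding on a large, partly
Mg^2+^-sensitive leak (LC). `apparent_block_decomposition()` implements
the identity, the oocyte model's `leak_mg_sensitivity` reproduces the
phenomenon generatively, and a property test confirms that the measured
block on leak-free simulator output reduces exactly to the channel term.

## What the simulator emulates — and what it does not

`simulate_ramp_sweep()`, `simulate_application_sweep()` and
`generate_batch()` generate:

* agonist-gated channel current as the permeability-weighted sum of GHK
  currents (monovalent reference permeability 1, Ca^2+^ scaled by the
  channel's `pca_over_pmono`), multiplied by the agonist-set efficacy
  (`gly` vs `glu_gly`, encoding the conventional-receptor vs
  glycine-receptor agonist profiles) and the Woodhull unblocked fraction;
* ohmic leak with its own reversal potential, optionally partly
  Mg^2+^-sensitive;
* optional endogenous contamination: a small conventional-like,
  glutamate-requiring, Mg^2+^-blockable component mimicking oocyte-native
  NR2B-like subunits (off by default);
* per-cell log-normal expression scaling with configurable coefficient of
  variation (default 0.5 — a deliberately moderate value; real oocyte
  batches are often more variable), white Gaussian current noise, the
  junction-potential offset, and first-order solution exchange with a 1-s
  default time constant (superfusion at a few ml/min is not instantaneous;
  the exact kinetics are not critical as long as segments reach plateau);
* optional single-exponential desensitization sag from agonist onset
  (off by default; the post-wash rebound "off-peak" seen for some mutants
  is not modelled).

Randomness is hierarchical: one root seed, with per-cell and per-sweep
child seeds derived arithmetically, so a single sweep can be regenerated in
isolation and identical seeds give bit-identical traces.

Deliberately **not** modelled: Markov gating kinetics, stochastic
single-channel noise, capacitive transients, 50-Hz pickup,
series-resistance error, Ca^2+^-activated chloride currents (EGTA
pretreatment is assumed effective and recorded as metadata), and proton
inhibition (pH is metadata only). Passing recovery tests therefore show
that the *analysis* is correct for data whose noise is white and whose leak
is ohmic; they do not certify robustness against structured artifacts that
real recordings may contain.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| Temperature | K | 293.15 | Room-temperature oocyte recordings; the reference table is self-consistent at this value. Configurable via `phys_constants()`. |
| $[Ca^{2+}]_o$ for permeability | mM | 4 | The 4 mM CaR recipe (108.6 mM NMDG); only this choice makes the printed operating points mutually consistent at $[Mono^+]_i \approx 89$ mM. 8 mM CaR is supported as an alternate condition. |
| Junction potential | mV | −4.5 | Solution pair's liquid junction; added once, provenance-flagged. |
| IV grid step | mV | 1 | 2-s ramp at 1 kHz gives ~10 samples per 1-mV bin. |
| Zero-crossing window | mV | −120…0 | Brackets all plausible biionic reversals. |
| Plateau fraction | — | 0.25 | Last quarter of a 20-s segment is at steady state for a 1-s exchange constant. |
| Expression CV | — | 0.5 | Moderate per-cell variability for recovery tests. |
| t test | — | pooled variance | The classical unpaired Student form; Welch available via `var_equal = FALSE`. |

## Problem sizes in the test suite

The suite validates at sizes chosen to give tight statistical checks while
running in well under a minute: 1000-point calibration grids; 100-seed
Monte-Carlo reversal recovery with four averaged sweeps per replicate at
2 % noise; 20 generative ratios log-spaced over [0.1, 5] recovered through
the full simulate → subtract → estimate → correct → GHK pipeline with 5
cells per ratio at 1 % noise (median absolute relative error below 5 %);
and batches of 200–500 cells for the expression-variability and
law-of-large-numbers checks.

## Known limitations

* The GHK framework treats all intracellular monovalents as one species
  with equal permeabilities and ignores ion–ion interactions in the pore;
  multi-ion (Eyring-type) effects, anomalous mole-fraction behaviour, and
  fractional Ca^2+^ currents are out of scope.
* The Woodhull description of block is a single-site, non-permeant-blocker
  model; permeating blocker behaviour at extreme hyperpolarization is not
  represented.
* Group reversal potentials are aggregated per cell; the package does not
  attempt to resolve which aggregation convention produced any given
  published table, it only makes both conventions visible.
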