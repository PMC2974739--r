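# biionic

Analysis and simulation of two-electrode voltage-clamp (TEVC) recordings
from *Xenopus laevis* oocytes expressing glutamate-gated ion channels —
the assay used to characterize how pore-loop residues of NMDA-receptor
diheteromers set Ca²⁺ permeability and voltage-dependent Mg²⁺ block.

The package is for electrophysiologists (and their reviewers) who want the
quantitative path from raw sweeps to the two headline numbers of such a
study to be explicit, tested, and reproducible:

* **Ca²⁺/monovalent permeability ratio.** Under biionic conditions
  (extracellular monovalents replaced by impermeant NMDG, Ca²⁺ the only
  putatively permeant cation outside), the reversal potential of the
  agonist-evoked current gives

  $$\frac{P_{Ca}}{P_{mono}} = \frac{[Mono^+]_i\,e^{x}(e^{x}+1)}{4\,[Ca^{2+}]_o},
    \qquad x = \frac{E_{rev}F}{RT},$$

  with `[Mono⁺]ᵢ` calibrated per oocyte batch from a reference channel of
  known ratio.
* **Percent Mg²⁺ block**, measured within a single agonist application as
  the fractional drop of the plateau current during a Mg²⁺ pulse, with the
  leak-current decomposition that explains apparent block above 100 %.

Around these sit the standard processing steps (voltage-ramp binning,
background subtraction with bracketing controls, normalization to +20 mV,
averaging, junction-potential correction, pooled-variance *t* statistics)
and a generative TEVC simulator — GHK channel currents, Woodhull block,
ohmic leak, per-cell expression variability, measurement noise — that
provides ground truth for every stage.

## Worked example

Calibrate the intracellular monovalent concentration from a reference
operating point, then recompute permeability ratios from measured reversal
potentials:

```r
library(biionic)

mono_i <- calibrate_mono_i(erev_ref_mv = -29.3, p_ref = 2.3, ca_o = 4)
mono_i
#> [1] 89.38345

ghk_permeability_ratio(c(-44.7, -68.4), mono_i, ca_o = 4)
#> [1] 1.1138407 0.3971893
```

The −44.7 mV cell has a ratio of 1.1 (a weakly Ca²⁺-permeable channel);
−68.4 mV gives 0.4 (essentially Ca²⁺-impermeable).

The same numbers can be recovered end to end from simulated raw data.
Here a channel with a known generative ratio of 1.5 is recorded in 4 mM
Ca²⁺ Ringer's, background-subtracted against bracketing controls, and
pushed through the full pipeline:

```r
channel <- channel_model(pca_over_pmono = 1.5, gain = 300,
                         agonist_efficacy = c(gly = 0.06, glu_gly = 1))
oocyte  <- oocyte_model(leak_conductance_us = 1, noise_sd_na = 5,
                        junction_potential_mv = -4.5, mono_i = 89.4)
car     <- solution_car(4)
agonist <- with_agonists(car, glycine_um = 10, glutamate_um = 100)
ramp    <- ramp_protocol()   # -150 to +50 mV in 2 s

agonist_sweep <- simulate_ramp_sweep(channel, oocyte, ramp, agonist, seed = 1)
ctrl_before   <- simulate_ramp_sweep(channel, oocyte, ramp, car, seed = 2)
ctrl_after    <- simulate_ramp_sweep(channel, oocyte, ramp, car, seed = 3)

erev <- estimate_cell_erev(agonist_sweep, ctrl_before, ctrl_after,
                           junction_potential_mv = -4.5)
as.numeric(erev)
#> [1] -37.87074

compute_permeability_per_cell(erev, calibration_record(mono_i = 89.4), ca_o = 4)
#> [1] 1.525922
```

The recovered ratio (1.53) matches the generative 1.5 to within the noise
of a single cell; averaging across a batch tightens it further (the test
suite quantifies this).

A complete simulate → process → summarize run, from a YAML experiment
configuration to tab-separated amplitude/block and permeability tables, is
one call:

```r
run_pipeline(read_experiment_config(), out_dir = "biionic-run", seed = 1)
```

`vignettes/biionic-methods.Rmd` documents the models, the numerical
choices, and the simulator's scope; `inst/scripts/run-pipeline.R` wraps
`run_pipeline()` for shell use.

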