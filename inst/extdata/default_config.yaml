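# Default experiment configuration: two reference channel phenotypes
# (a conventional glutamate/glycine-gated, Mg2+-blocked, Ca2+-permeable
# NR1/NR2B-like receptor and a glycine-gated, Mg2+-insensitive, weakly
# Ca2+-permeable NR1/NR3B-like receptor) recorded with the standard TEVC
# protocols: 2-s voltage ramps from -150 to +50 mV in Ca2+ Ringer's, and
# 60-s agonist applications with a 20-s Mg2+ pulse at -70 mV in NFR.
seed: 1
n_cells: 3
output_dir: biionic-run

constants:
  temperature_K: 293.15

# One calibration source per batch: either a direct intracellular monovalent
# concentration (mM), or erev_ref_mV + p_ref of a reference channel.
calibration:
  batch_id: batch1
  mono_i_mM: 89.4
  ca_o_mM: 4

oocyte:
  leak_conductance_uS: 1
  leak_reversal_mV: -20
  mono_i_mM: 89.4
  expression_cv: 0.5
  noise_sd_nA: 5
  junction_potential_mV: -4.5
  leak_mg_sensitivity: 0.3
  endogenous_fraction: 0

agonists:
  glycine_uM: 10
  glutamate_uM: 100

blocker:
  mg_mM: 0.5

protocols:
  ramp:
    v_from_mV: -150
    v_to_mV: 50
    duration_s: 2
    sample_rate_hz: 1000
  application:
    hold_mV: -70
    sample_rate_hz: 100
    exchange_tau_s: 1
    pre_s: 10
    segment_s: 20
    post_s: 10

permeability:
  ca_mM: 4
  window_mV: [-120, 0]

conditions:
  NR1/NR2B-like:
    pca_over_pmono: 2.3
    gain: 500
    agonist_efficacy: {gly: 0.06, glu_gly: 1.0}
    block: {kd0_mM: 1.0893, zdelta: 1.0}
  NR1/NR3B-like:
    pca_over_pmono: 0.4
    gain: 100
    agonist_efficacy: {gly: 1.0, glu_gly: 1.0}
    block: null

condition_order: [NR1/NR2B-like, NR1/NR3B-like]
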