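# Shared fixtures, built in code.

# An oocyte with no leak, no noise, no junction offset, and no expression
# variability: the cleanest background for parameter-recovery checks.
quiet_oocyte <- function(...) {
  args <- list(leak_conductance_us = 0, noise_sd_na = 0,
               junction_potential_mv = 0, expression_cv = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(oocyte_model, args)
}

# Hand-rolled bisection, used as the independent root oracle.
bisect_zero <- function(f, lo, hi, tol = 1e-9) {
  flo <- f(lo)
  fhi <- f(hi)
  stopifnot(flo * fhi < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (flo * f(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# The Ca2+ permeability that places the biionic reversal at `erev_mv`.
pca_for_erev <- function(erev_mv, mono_i = 89.4, ca_o = 4,
                         constants = phys_constants()) {
  ghk_permeability_ratio(erev_mv, mono_i, ca_o, constants)
}

# Simulate one biionic cell: an agonist ramp bracketed by two control ramps
# in Ca2+ Ringer's.
sim_biionic_cell <- function(pca, oocyte, gain = 300, seed = 1, ca_mm = 4,
                             protocol = ramp_protocol()) {
  ch <- channel_model(pca_over_pmono = pca, gain = gain,
                      agonist_efficacy = c(gly = 0.06, glu_gly = 1))
  car <- solution_car(ca_mm)
  agonist <- with_agonists(car, glycine_um = 10, glutamate_um = 100)
  list(
    agonist = simulate_ramp_sweep(ch, oocyte, protocol, agonist, seed = seed),
    ctrl_before = simulate_ramp_sweep(ch, oocyte, protocol, car,
                                      seed = seed + 1000L),
    ctrl_after = simulate_ramp_sweep(ch, oocyte, protocol, car,
                                     seed = seed + 2000L)
  )
}

# A small experiment configuration that runs the full pipeline quickly.
tiny_config <- function(n_cells = 2, seed = 1) {
  cfg <- yaml::read_yaml(default_config_path())
  cfg$n_cells <- n_cells
  cfg$seed <- seed
  cfg$protocols$ramp$sample_rate_hz <- 500
  cfg$protocols$application <- list(hold_mV = -70, sample_rate_hz = 100,
                                    exchange_tau_s = 0.5, pre_s = 4,
                                    segment_s = 6, post_s = 2)
  cfg$conditions <- cfg$conditions["NR1/NR2B-like"]
  cfg$condition_order <- "NR1/NR2B-like"
  cfg
}
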