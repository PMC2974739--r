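test_that("a channel-free cell produces an exactly ohmic ramp", {
  ch <- channel_model(gain = 0)
  oc <- quiet_oocyte(leak_conductance_us = 1, leak_reversal_mv = -20)
  tr <- simulate_ramp_sweep(ch, oc, ramp_protocol(), solution_nfr(), seed = 1)
  expect_equal(tr$current_nA, tr$voltage_mV + 20, tolerance = 1e-12)
})

test_that("ramp simulation is deterministic under a fixed seed", {
  ch <- channel_model()
  oc <- oocyte_model(noise_sd_na = 10)
  sol <- with_agonists(solution_nfr(), 10, 100)
  a <- simulate_ramp_sweep(ch, oc, ramp_protocol(), sol, seed = 42)
  b <- simulate_ramp_sweep(ch, oc, ramp_protocol(), sol, seed = 42)
  expect_identical(a$current_nA, b$current_nA)
  d <- simulate_ramp_sweep(ch, oc, ramp_protocol(), sol, seed = 43)
  expect_false(identical(a$current_nA, d$current_nA))
})

test_that("a solution without permeant ions is rejected", {
  sol <- solution_spec("NMDG only", ions = c(NMDG = 110))
  expect_error(
    simulate_ramp_sweep(channel_model(), quiet_oocyte(), ramp_protocol(),
                        sol, seed = 1),
    class = "biionic_invalid_input"
  )
})

test_that("noiseless biionic ramps reverse at the analytic reversal potential", {
  # permeability chosen to put the reversal at -30 mV
  oc <- quiet_oocyte(mono_i = 89.4)
  pca <- pca_for_erev(-30)
  ch <- channel_model(pca_over_pmono = pca, gain = 300,
                      agonist_efficacy = c(gly = 0.06, glu_gly = 1))
  sol <- with_agonists(solution_car(4), 10, 100)
  # bisection on the generative current confirms the construction
  root <- bisect_zero(
    function(v) predict_membrane_current(v, ch, oc, sol), -120, 20
  )
  expect_equal(root, -30, tolerance = 1e-6)
  # the estimate recovered from the simulated sweep agrees
  tr <- simulate_ramp_sweep(ch, oc, ramp_protocol(), sol, seed = 5)
  erev <- estimate_reversal_potential(ramp_to_iv(tr))
  expect_equal(as.numeric(erev), -30, tolerance = 0.1)
})

test_that("ohmic leak does not shift the background-subtracted reversal potential", {
  pca <- pca_for_erev(-55)
  ests <- vapply(c(0, 0.5, 3), function(leak) {
    oc <- quiet_oocyte(leak_conductance_us = leak, leak_reversal_mv = -15)
    cell <- sim_biionic_cell(pca, oc, seed = 9)
    as.numeric(estimate_cell_erev(cell$agonist, cell$ctrl_before,
                                  cell$ctrl_after,
                                  junction_potential_mv = 0))
  }, numeric(1))
  # leak cancels exactly in the subtraction: estimates are leak-independent
  expect_lt(max(ests) - min(ests), 1e-9)
  # and sit at the analytic reversal up to the interpolation grid
  expect_equal(ests, rep(-55, 3), tolerance = 1e-4)
})

test_that("application sweeps report near-zero block for block-insensitive channels", {
  ch <- channel_model(pca_over_pmono = 0.4, gain = 100,
                      agonist_efficacy = c(gly = 1, glu_gly = 1))
  prot <- mg_block_protocol(agonist_label = "NFR + glycine",
                            mg_label = "NFR + glycine + Mg")
  # amplitude first, then noise at 1% of it (SNR 100)
  clean <- simulate_application_sweep(ch, quiet_oocyte(), prot, seed = 1)
  amp <- application_measurements(clean)$i_response_nA
  oc <- quiet_oocyte(noise_sd_na = amp / 100)
  m <- application_measurements(
    simulate_application_sweep(ch, oc, prot, seed = 2)
  )
  expect_lt(abs(m$percent_block), 3)
})

test_that("percent block recovers the generative Woodhull unblocked fraction", {
  constants <- phys_constants()
  b <- constants$faraday / (constants$gas_constant * constants$temperature)
  # kd0 set so the unblocked fraction at -70 mV with 0.5 mM Mg2+ is 0.12
  kd_target <- 0.5 * 0.12 / 0.88
  kd0 <- kd_target / exp(1 * b * (-70 / 1000))
  ch <- channel_model(pca_over_pmono = 2.3, gain = 500,
                      agonist_efficacy = c(gly = 0.06, glu_gly = 1),
                      block = woodhull_params(kd0, 1))
  tr <- simulate_application_sweep(ch, quiet_oocyte(), mg_block_protocol(),
                                   seed = 3)
  m <- application_measurements(tr)
  expect_equal(m$percent_block, 88, tolerance = 1 / 88)
})

test_that("glycine-receptor-like efficacy gives equal responses to both agonist sets", {
  ch <- channel_model(pca_over_pmono = 0.4, gain = 120,
                      agonist_efficacy = c(gly = 0.85, glu_gly = 0.85))
  oc <- quiet_oocyte(noise_sd_na = 1)
  i <- vapply(c("glycine", "glutamate/glycine"), function(ag) {
    prot <- mg_block_protocol(agonist_label = paste0("NFR + ", ag),
                              mg_label = NULL)
    application_measurements(
      simulate_application_sweep(ch, oc, prot, seed = 4)
    )$i_response_nA
  }, numeric(1))
  expect_equal(unname(i[1]), unname(i[2]), tolerance = 0.02)
})

test_that("batches have the requested size, structure, and determinism", {
  prot <- mg_block_protocol(agonist_label = "NFR + glycine", mg_label = NULL,
                            pre_s = 2, seg_s = 2, post_s = 1,
                            exchange_tau_s = 0.2)
  config <- list(
    channel = channel_model(agonist_efficacy = c(gly = 1, glu_gly = 1)),
    oocyte = oocyte_model(noise_sd_na = 2),
    protocols = list(app = list(protocol = prot),
                     ramp = list(protocol = ramp_protocol(sample_rate_hz = 100),
                                 solution = solution_nfr()))
  )
  b <- generate_batch(config, n_cells = 5, seed = 11)
  expect_equal(length(unique(b$cell_id)), 5)
  expect_equal(nrow(b), 10) # every protocol on every cell
  expect_true(all(table(b$cell_id) == 2))
  b2 <- generate_batch(config, n_cells = 5, seed = 11)
  expect_identical(
    purrr::map(b$trace, "current_nA"), purrr::map(b2$trace, "current_nA")
  )
  expect_error(generate_batch(config, n_cells = 0, seed = 1),
               class = "biionic_invalid_input")
})

test_that("expression variability and batch means match their configuration", {
  prot <- mg_block_protocol(agonist_label = "NFR + glycine", mg_label = NULL,
                            pre_s = 2, seg_s = 2, post_s = 1,
                            exchange_tau_s = 0.2)
  make_config <- function(cv) list(
    channel = channel_model(gain = 300,
                            agonist_efficacy = c(gly = 1, glu_gly = 1)),
    oocyte = oocyte_model(noise_sd_na = 1, expression_cv = cv,
                          junction_potential_mv = 0)
  , protocols = list(app = list(protocol = prot)))
  # configured CV 0.5 recovered empirically at n = 200
  b <- generate_batch(make_config(0.5), n_cells = 200, seed = 21)
  peaks <- vapply(b$trace, function(tr) {
    application_measurements(tr)$i_response_nA
  }, numeric(1))
  cv_hat <- sd(peaks) / mean(peaks)
  expect_gt(cv_hat, 0.4)
  expect_lt(cv_hat, 0.6)
  # law of large numbers: mean peak converges to the unit-expression peak
  b500 <- generate_batch(make_config(0.5), n_cells = 500, seed = 22)
  peaks500 <- vapply(b500$trace, function(tr) {
    application_measurements(tr)$i_response_nA
  }, numeric(1))
  expected <- application_measurements(simulate_application_sweep(
    channel_model(gain = 300, agonist_efficacy = c(gly = 1, glu_gly = 1)),
    quiet_oocyte(), prot, seed = 1
  ))$i_response_nA
  se <- sd(peaks500) / sqrt(length(peaks500))
  expect_lt(abs(mean(peaks500) - expected), 3 * se)
})
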