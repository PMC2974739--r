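test_that("the reversal potential of a straight line is its zero crossing", {
  iv <- iv_relation(c(-50, 0), c(-10, 15))
  erev <- estimate_reversal_potential(iv)
  expect_equal(as.numeric(erev), -30)
  expect_equal(attr(erev, "n_crossings"), 1)
})

test_that("a window without sign change is a reported error, not a guess", {
  iv <- iv_relation(seq(-100, 0, by = 5), seq(-100, 0, by = 5) * 0 + 4)
  expect_error(estimate_reversal_potential(iv),
               class = "biionic_no_reversal")
})

test_that("multiple crossings resolve to the one near the current minimum", {
  v <- seq(-100, 0, by = 1)
  # genuine crossing at -50 on a shallow line, spurious bump crossing near -95
  i <- 0.2 * (v + 50) + 12 * exp(-((v + 95) / 2)^2)
  iv <- iv_relation(v, i)
  erev <- estimate_reversal_potential(iv)
  expect_gt(attr(erev, "n_crossings"), 1)
  expect_equal(as.numeric(erev), -50, tolerance = 0.5)
})

test_that("noiseless simulated biionic IVs reproduce the bisection oracle", {
  oc <- quiet_oocyte()
  for (target in c(-64.9, -29.3, -44.7)) {
    pca <- pca_for_erev(target)
    ch <- channel_model(pca_over_pmono = pca, gain = 300,
                        agonist_efficacy = c(gly = 0.06, glu_gly = 1))
    sol <- with_agonists(solution_car(4), 10, 100)
    oracle <- bisect_zero(
      function(v) predict_membrane_current(v, ch, oc, sol), -120, 10
    )
    tr <- simulate_ramp_sweep(ch, oc, ramp_protocol(), sol, seed = 2)
    est <- estimate_reversal_potential(ramp_to_iv(tr))
    expect_equal(as.numeric(est), oracle, tolerance = 0.1 / abs(oracle))
  }
})

test_that("noisy replicate ramps recover the reversal potential within 1 mV", {
  target <- -40
  pca <- pca_for_erev(target)
  # noise at 2% of the largest ramp current
  ref <- sim_biionic_cell(pca, quiet_oocyte(), seed = 1)
  noise <- 0.02 * max(abs(ref$agonist$current_nA))
  ests <- vapply(1:30, function(s) {
    oc <- quiet_oocyte(leak_conductance_us = 1, noise_sd_na = noise)
    cell <- sim_biionic_cell(pca, oc, seed = 100 + s)
    as.numeric(estimate_cell_erev(cell$agonist, cell$ctrl_before,
                                  cell$ctrl_after,
                                  junction_potential_mv = 0))
  }, numeric(1))
  expect_lt(abs(mean(ests) - target), 1)
  expect_gt(sd(ests), 0) # dispersion is reported, not suppressed
})

test_that("junction correction shifts once and only once", {
  expect_equal(as.numeric(correct_junction_potential(-24.8, -4.5)), -29.3)
  expect_equal(as.numeric(correct_junction_potential(-24.8, 0)), -24.8)
  once <- correct_junction_potential(-24.8)
  expect_error(correct_junction_potential(once),
               class = "biionic_invalid_input")
})

test_that("per-cell permeability reproduces reference operating points", {
  cal <- calibration_record(mono_i = 89.4)
  expect_equal(compute_permeability_per_cell(-29.3, cal, 4), 2.3,
               tolerance = 0.05 / 2.3)
  expect_equal(compute_permeability_per_cell(-68.4, cal, 4), 0.40,
               tolerance = 0.03 / 0.40)
})

test_that("calibration records accept exactly one source", {
  expect_error(calibration_record(), class = "biionic_config_error")
  expect_error(calibration_record(mono_i = 89, erev_ref_mv = -29.3,
                                  p_ref = 2.3),
               class = "biionic_config_error")
  ref <- calibration_record(erev_ref_mv = -29.3, p_ref = 2.3, ca_o = 4)
  expect_equal(ref$mono_i, calibrate_mono_i(-29.3, 2.3, 4))
})

test_that("the full per-cell pipeline recovers a generative permeability ratio", {
  oc <- quiet_oocyte(leak_conductance_us = 1, junction_potential_mv = -4.5)
  cell <- sim_biionic_cell(1.5, oc, seed = 77)
  erev <- estimate_cell_erev(cell$agonist, cell$ctrl_before, cell$ctrl_after,
                             junction_potential_mv = -4.5)
  p <- compute_permeability_per_cell(erev, calibration_record(mono_i = 89.4), 4)
  expect_equal(p, 1.5, tolerance = 0.02 / 1.5)
})

test_that("a more negative corrected reversal potential always lowers the ratio", {
  cal <- calibration_record(mono_i = 89.4)
  e <- seq(-120, 10, by = 2)
  p <- compute_permeability_per_cell(e, cal, 4)
  expect_true(all(diff(p) > 0))
})

test_that("group statistics match hand-computed SEM and pooled t", {
  g <- group_statistics(c(2, 4, 6))
  expect_equal(g$mean, 4)
  expect_equal(g$sem, 2 / sqrt(3))
  # identical groups: t = 0, p = 1
  same <- group_statistics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unique(same$t), 0)
  expect_equal(unique(same$p_value), 1)
  expect_equal(unique(same$signif), "ns")
  # shift by 10 with unit pooled SD: |t| = 10 * sqrt(3/2)
  shift <- group_statistics(c(1, 2, 3), c(11, 12, 13))
  expect_equal(abs(unique(shift$t)), 10 * sqrt(3 / 2))
  expect_equal(unique(shift$signif), "***")
  expect_error(group_statistics(c(1)), class = "biionic_insufficient_data")
  expect_error(group_statistics(c(1, 2), c(3)),
               class = "biionic_insufficient_data")
})

test_that("significance tiers follow the 0.05 / 0.01 / 0.005 convention", {
  expect_equal(signif_stars(c(0.04, 0.009, 0.004, 0.2)),
               c("*", "**", "***", "ns"))
})

test_that("the permeability table aggregates per cell and exposes both estimators", {
  cal <- calibration_record(mono_i = 89.4)
  per_cell <- tibble::tibble(
    condition = "wt", cell_id = sprintf("c%d", 1:5), agonist = "glu_gly",
    erev_mV = c(-25, -28, -30, -32, -60) # one skewed cell
  )
  fit <- analyze_permeability(per_cell, cal, ca_o = 4)
  tab <- fit$table
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_glu_gly, 5)
  expect_equal(tab$erev_mean_glu_gly, -35)
  # mean of per-cell ratios is reported; the ratio at the mean Erev differs
  # under skew (convexity of the GHK expression in Erev)
  expect_equal(tab$p_mean_glu_gly,
               mean(ghk_permeability_ratio(per_cell$erev_mV, 89.4, 4)))
  expect_equal(tab$p_from_mean_erev_glu_gly,
               ghk_permeability_ratio(-35, 89.4, 4))
  expect_gt(tab$p_mean_glu_gly, tab$p_from_mean_erev_glu_gly)
  # a missing agonist subgroup is rendered missing, not zero
  expect_false("erev_mean_gly" %in% names(tab))
  expect_error(
    build_permeability_table(fit$per_cell, cal, conditions = "mutant"),
    class = "biionic_config_error"
  )
})

test_that("tidy and glance summarize a permeability analysis", {
  cal <- calibration_record(mono_i = 89.4)
  per_cell <- tidyr::expand_grid(condition = c("a", "b"),
                                 cell_id = sprintf("c%d", 1:4)) |>
    dplyr::mutate(agonist = "gly",
                  erev_mV = c(-20, -22, -24, -26, -60, -62, -64, -66))
  fit <- analyze_permeability(per_cell, cal, conditions = c("a", "b"))
  td <- tidy(fit)
  expect_setequal(unique(td$quantity), c("erev_mV", "p_ratio"))
  expect_equal(nrow(td), 4) # 2 conditions x 2 quantities
  expect_true(all(td$n == 4))
  gl <- glance(fit)
  expect_equal(gl$n_cells, 4L)
  expect_equal(gl$n_conditions, 2L)
  expect_equal(gl$mono_i_mM, 89.4)
})

test_that("simulated condition groups reproduce their generative ratios", {
  # a two-condition replica at generative ratios 2.3 and 0.4, n = 9 cells
  cal <- calibration_record(mono_i = 89.4)
  per_cell <- purrr::imap(c(wt = 2.3, gly_receptor = 0.4), function(p, lab) {
    purrr::map(1:9, function(k) {
      oc <- quiet_oocyte(leak_conductance_us = 1,
                         noise_sd_na = 6, junction_potential_mv = -4.5)
      cell <- sim_biionic_cell(p, oc, seed = 5000 + 100 * match(lab, c("wt", "gly_receptor")) + k)
      tibble::tibble(
        condition = lab, cell_id = sprintf("c%d", k), agonist = "glu_gly",
        erev_mV = as.numeric(estimate_cell_erev(
          cell$agonist, cell$ctrl_before, cell$ctrl_after,
          junction_potential_mv = -4.5
        ))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  fit <- analyze_permeability(per_cell, cal,
                              conditions = c("wt", "gly_receptor"))
  tab <- fit$table
  expect_equal(tab$condition, c("wt", "gly_receptor"))
  for (i in 1:2) {
    truth <- c(2.3, 0.4)[i]
    expect_lt(abs(tab$p_mean_glu_gly[i] - truth),
              2 * max(tab$p_sem_glu_gly[i], 0.02))
  }
})
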