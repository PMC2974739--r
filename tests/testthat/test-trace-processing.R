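step_trace <- function(baseline_na, plateau_na, noise_sd = 0, seed = 1,
                       rate = 100, t_step = 5, t_end = 20) {
  n <- t_end * rate
  t <- seq_len(n) / rate
  i <- ifelse(t < t_step, baseline_na, plateau_na)
  if (noise_sd > 0) {
    i <- i + withr::with_seed(seed, rnorm(n, 0, noise_sd))
  }
  tibble::tibble(time_s = t, voltage_mV = rep(-70, n), current_nA = i)
}

test_that("peak current is the baseline-subtracted inward magnitude", {
  flat <- step_trace(-50, -50)
  expect_equal(peak_current(flat, c(5, 20), c(0, 4)), 0)
  tr <- step_trace(-10, -2132)
  expect_equal(peak_current(tr, c(5, 20), c(0, 4)), 2122)
  expect_equal(peak_current(tr, c(5, 20), c(0, 4), method = "extremum"), 2122)
  expect_error(peak_current(tr, c(30, 40), c(0, 4)),
               class = "biionic_invalid_input")
  expect_error(peak_current(tr, c(5, 20), c(0, 6)),
               class = "biionic_invalid_input")
})

test_that("peak current recovers a known step amplitude under noise", {
  amp <- 500
  errs <- vapply(1:100, function(s) {
    tr <- step_trace(-10, -10 - amp, noise_sd = amp / 100, seed = s)
    peak_current(tr, c(5, 20), c(0, 4)) - amp
  }, numeric(1))
  expect_true(all(abs(errs) / amp < 0.03))
})

test_that("background subtraction is pointwise and linear", {
  v <- seq(-100, 40, by = 2)
  a <- iv_relation(v, rep(20, length(v)))
  c1 <- iv_relation(v, rep(5, length(v)))
  c2 <- iv_relation(v, rep(7, length(v)))
  out <- subtract_background(a, c1, c2)
  expect_equal(out$current_nA, rep(14, length(v)))
  # self-subtraction gives the zero curve
  z <- subtract_background(a, a, a)
  expect_equal(z$current_nA, rep(0, length(v)))
  # linearity: subtracting summed agonist signals = summing subtractions
  a2 <- iv_relation(v, sin(v / 20) * 10)
  sum_iv <- iv_relation(v, a$current_nA + a2$current_nA)
  lhs <- subtract_background(sum_iv, c1, c2)
  rhs1 <- subtract_background(a, c1, c2)
  rhs2 <- subtract_background(a2, iv_relation(v, rep(0, length(v))),
                              iv_relation(v, rep(0, length(v))))
  expect_equal(lhs$current_nA, rhs1$current_nA + rhs2$current_nA)
  # disjoint voltage ranges are rejected
  far <- iv_relation(v + 500, rep(1, length(v)))
  expect_error(subtract_background(a, far, far),
               class = "biionic_invalid_input")
})

test_that("subtracting simulated leak-only controls recovers the pure channel IV", {
  pca <- pca_for_erev(-40)
  noise <- 2
  oc <- quiet_oocyte(leak_conductance_us = 1.5, leak_reversal_mv = -25,
                     noise_sd_na = noise)
  cell <- sim_biionic_cell(pca, oc, seed = 31)
  sub <- subtract_background(ramp_to_iv(cell$agonist),
                             ramp_to_iv(cell$ctrl_before),
                             ramp_to_iv(cell$ctrl_after))
  pure <- predict_membrane_current(
    sub$voltage_mV,
    channel_model(pca_over_pmono = pca, gain = 300,
                  agonist_efficacy = c(gly = 0.06, glu_gly = 1)),
    quiet_oocyte(),
    with_agonists(solution_car(4), 10, 100)
  )
  rms <- sqrt(mean((sub$current_nA - pure)^2))
  expect_lt(rms, 2 * noise)
})

test_that("normalization fixes the reference current to one and is scale invariant", {
  v <- seq(-120, 40, by = 1)
  iv <- iv_relation(v, (v + 30) * 12.5) # 500 nA at +10... arbitrary line
  norm <- normalize_iv(iv, reference_voltage_mv = 20)
  expect_equal(approx(norm$voltage_mV, norm$current_nA, xout = 20)$y, 1)
  scaled <- normalize_iv(iv_relation(v, iv$current_nA * 3.7), 20)
  expect_equal(norm$current_nA, scaled$current_nA)
  # idempotence
  expect_equal(normalize_iv(norm, 20)$current_nA, norm$current_nA)
  # degenerate normalization is refused
  flatzero <- iv_relation(v, v * 0)
  expect_error(normalize_iv(flatzero, 20),
               class = "biionic_degenerate_normalization")
  expect_error(normalize_iv(iv, 200), class = "biionic_invalid_input")
})

test_that("averaging four normalized replicates halves the RMS deviation", {
  pca <- pca_for_erev(-35)
  make_norm <- function(seed, noise) {
    oc <- quiet_oocyte(noise_sd_na = noise)
    cell <- sim_biionic_cell(pca, oc, seed = seed)
    normalize_iv(ramp_to_iv(cell$agonist), 20)
  }
  clean <- make_norm(1, 0)
  rms_vs_clean <- function(iv) {
    common <- intersect(iv$voltage_mV, clean$voltage_mV)
    sqrt(mean((approx(iv$voltage_mV, iv$current_nA, common)$y -
                 approx(clean$voltage_mV, clean$current_nA, common)$y)^2))
  }
  singles <- purrr::map(2:9, make_norm, noise = 8)
  rms1 <- mean(vapply(singles[1:4], rms_vs_clean, numeric(1)))
  rms4 <- rms_vs_clean(average_ivs(singles[1:4]))
  expect_gt(rms1 / rms4, 1.5)
  expect_lt(rms1 / rms4, 2.8)
})

test_that("IV averaging behaves as a pointwise mean", {
  v <- seq(-50, 30, by = 1)
  a <- iv_relation(v, sin(v / 10))
  expect_equal(average_ivs(list(a))$current_nA, a$current_nA)
  b <- iv_relation(v, -sin(v / 10))
  expect_equal(average_ivs(list(a, b))$current_nA, rep(0, length(v)))
  same <- average_ivs(list(a, a, a, a, a))
  expect_equal(same$current_nA, a$current_nA)
  expect_equal(attr(same, "n_averaged"), 5L)
  expect_error(average_ivs(list()), class = "biionic_invalid_input")
})

test_that("percent block follows its defining identity", {
  expect_equal(percent_block(100, 12), 88)
  expect_equal(percent_block(100, 103), -3) # potentiation
  expect_equal(percent_block(100, -25), 125) # leak-block artifact
  for (i in c(0.5, 10, 1234)) {
    expect_equal(percent_block(i, i), 0)
    expect_equal(percent_block(i, 0), 100)
  }
  expect_error(percent_block(0, 10), class = "biionic_undefined_block")
})

test_that("response ratio is computed per cell, not from mean amplitudes", {
  expect_equal(response_ratio(50, 1000), 0.05)
  expect_equal(response_ratio(42, 42), 1)
  expect_error(response_ratio(10, 0), class = "biionic_invalid_input")
  # amplitude-correlated ratio variability biases the ratio of means
  withr::with_seed(7, {
    n <- 30
    z <- rnorm(n)
    scale <- exp(0.8 * z - 0.32) # lognormal expression
    ratio_cell <- 0.06 * exp(0.4 * z - 0.08) # co-varies with expression
    i_glu_gly <- 2000 * scale
    i_gly <- ratio_cell * i_glu_gly
    mean_of_ratios <- mean(response_ratio(i_gly, i_glu_gly))
    ratio_of_means <- mean(i_gly) / mean(i_glu_gly)
    expect_equal(mean_of_ratios, 0.06, tolerance = 0.01 / 0.06)
    expect_gt(abs(ratio_of_means - mean_of_ratios), 0.005)
  })
})

test_that("apparent block decomposes into channel and leak contributions", {
  expect_equal(apparent_block_decomposition(100, 0, 0.7, 0.5), 70)
  expect_equal(apparent_block_decomposition(100, 400, 0.7, 0), 70)
  expect_equal(apparent_block_decomposition(50, 40, 1, 0.5), 140)
  expect_error(apparent_block_decomposition(0, 10, 0.5, 0.5),
               class = "biionic_invalid_input")
  expect_error(apparent_block_decomposition(10, 10, 1.5, 0.5),
               class = "biionic_invalid_input")
})

test_that("measured block equals the decomposition on leak-free simulator output", {
  constants <- phys_constants()
  withr::with_seed(13, {
    for (k in 1:20) {
      kd0 <- exp(runif(1, log(0.05), log(5)))
      zdelta <- runif(1, 0.3, 1.5)
      ch <- channel_model(pca_over_pmono = 2.3, gain = runif(1, 100, 800),
                          agonist_efficacy = c(gly = 0.06, glu_gly = 1),
                          block = woodhull_params(kd0, zdelta))
      tr <- simulate_application_sweep(ch, quiet_oocyte(),
                                       mg_block_protocol(), seed = k)
      m <- application_measurements(tr)
      f_channel <- 1 - woodhull_unblocked_fraction(
        -70, woodhull_params(kd0, zdelta, 0.5), constants
      )
      expected <- apparent_block_decomposition(m$i_response_nA, 0,
                                               f_channel, 0)
      expect_equal(m$percent_block, expected, tolerance = 0.005)
    }
  })
})

test_that("the block table aggregates per-cell values with mean and SEM", {
  per_cell <- tidyr::expand_grid(
    condition = "wt", cell_id = sprintf("c%d", 1:5),
    agonist = c("gly", "glu_gly")
  )
  per_cell$i_response_nA <- rep(c(100, 2000), 5) + rep(0:4, each = 2)
  per_cell$percent_block <- rep(c(120, 88), 5)
  tab <- build_block_table(per_cell)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$i_n_gly, 5)
  expect_equal(tab$block_mean_glu_gly, 88)
  expect_equal(tab$block_mean_gly, 120)
  expect_equal(tab$ratio_gly_gluGly, mean((100:104) / (2000:2004)))
  expect_error(build_block_table(per_cell, conditions = "other"),
               class = "biionic_config_error")
})
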