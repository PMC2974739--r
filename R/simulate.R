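# Synthetic TEVC sweep generation. Channel current is the permeability-
# weighted sum of GHK currents for the lumped intracellular monovalent
# species and Ca2+, gated by agonist efficacy and scaled by a Woodhull
# unblocked fraction; the oocyte adds ohmic leak, junction-potential offset,
# expression scaling, and white Gaussian noise.

# Raw GHK fluxes with mM concentrations are O(1e7); the gain is defined per
# 1e7 flux units so that default gains are O(100) and currents land in nA.
DRIVE_SCALE <- 1e7

agonist_mode <- function(solution) {
  ag <- solution$agonists
  glu <- if ("glutamate" %in% names(ag)) ag[["glutamate"]] else 0
  gly <- if ("glycine" %in% names(ag)) ag[["glycine"]] else 0
  if (glu > 0 && gly > 0) "glu_gly" else if (gly > 0) "gly" else "none"
}

mg_concentration <- function(solution) {
  bl <- solution$blockers
  if ("Mg" %in% names(bl)) bl[["Mg"]] else 0
}

solution_mono_out <- function(solution) {
  ions <- solution$ions
  sum(ions[names(ions) %in% PERMEANT_MONOVALENTS])
}

solution_ca_out <- function(solution) {
  ions <- solution$ions
  if ("Ca" %in% names(ions)) ions[["Ca"]] else 0
}

# Summed GHK flux (per unit gain) of a channel with relative monovalent
# permeability 1 and Ca2+ permeability pca, at true membrane potential v.
ghk_drive <- function(v_true_mv, pca, oocyte, solution, constants) {
  mono_out <- solution_mono_out(solution)
  ca_out <- solution_ca_out(solution)
  d <- ghk_current(v_true_mv, charge = 1, conc_in = oocyte$mono_i,
                   conc_out = mono_out, constants = constants)
  if (pca > 0 && (oocyte$ca_i > 0 || ca_out > 0)) {
    d <- d + ghk_current(v_true_mv, charge = 2, conc_in = oocyte$ca_i,
                         conc_out = ca_out, permeability = pca,
                         constants = constants)
  }
  d / DRIVE_SCALE
}

endogenous_channel <- function() {
  channel_model(pca_over_pmono = 2.3, gain = 1,
                agonist_efficacy = c(gly = 0, glu_gly = 1),
                block = woodhull_params(kd0 = 1.0893, zdelta = 1))
}

channel_component <- function(v_true_mv, channel, oocyte, solution,
                              constants) {
  mode <- agonist_mode(solution)
  eff <- if (mode == "none") 0 else channel$agonist_efficacy[[mode]]
  if (eff == 0) return(rep(0, length(v_true_mv)))
  unblocked <- rep(1, length(v_true_mv))
  mg <- mg_concentration(solution)
  if (!is.null(channel$block) && mg > 0) {
    p <- channel$block
    unblocked <- woodhull_unblocked_fraction(
      v_true_mv, woodhull_params(p$kd0, p$zdelta, mg), constants
    )
  }
  channel$gain * eff *
    ghk_drive(v_true_mv, channel$pca_over_pmono, oocyte, solution, constants) *
    unblocked
}

#' Predicted noiseless membrane current of the generative model
#'
#' Deterministic current (nA) at given command potentials for a channel /
#' oocyte / solution combination: expression-scaled gated channel current
#' (including any endogenous contamination) plus ohmic leak. This is the
#' mean function of the simulator; [simulate_ramp_sweep()] adds noise on top
#' of it. Useful as the generative ground truth when validating
#' reversal-potential estimation.
#'
#' @param v_command_mv Command potential(s) in mV. The membrane sees
#'   `v_command_mv + junction_potential_mv`.
#' @param channel A [channel_model()].
#' @param oocyte An [oocyte_model()].
#' @param solution A [solution_spec()].
#' @param constants A [phys_constants()] object.
#' @param expression_scale Per-cell multiplicative expression factor.
#' @return Numeric vector of currents in nA (inward negative).
#' @export
predict_membrane_current <- function(v_command_mv, channel, oocyte, solution,
                                     constants = phys_constants(),
                                     expression_scale = 1) {
  check_numeric_vector(v_command_mv, "v_command_mv")
  stopifnot(inherits(channel, "channel_model"),
            inherits(oocyte, "oocyte_model"),
            inherits(solution, "solution_spec"))
  constants <- as_phys_constants(constants)
  v_true <- v_command_mv + oocyte$junction_potential_mv
  chan <- channel_component(v_true, channel, oocyte, solution, constants)
  if (oocyte$endogenous_fraction > 0) {
    endo <- endogenous_channel()
    endo$gain <- channel$gain * oocyte$endogenous_fraction
    chan <- chan + channel_component(v_true, endo, oocyte, solution, constants)
  }
  mg_leak_scale <- if (mg_concentration(solution) > 0) {
    1 - oocyte$leak_mg_sensitivity
  } else {
    1
  }
  leak <- oocyte$leak_conductance_us * mg_leak_scale *
    (v_true - oocyte$leak_reversal_mv)
  expression_scale * chan + leak
}

new_tevc_trace <- function(time_s, voltage_mv, current_na, metadata) {
  tr <- tibble::tibble(time_s = time_s, voltage_mV = voltage_mv,
                       current_nA = current_na)
  attr(tr, "metadata") <- metadata
  class(tr) <- c("tevc_trace", class(tr))
  tr
}

#' Metadata of a simulated or loaded sweep
#'
#' @param trace A `tevc_trace` tibble.
#' @return The metadata list (protocol kind, solution labels, cell id, seed,
#'   segment table for applications).
#' @export
trace_metadata <- function(trace) {
  attr(trace, "metadata")
}

#' Simulate a voltage-ramp sweep
#'
#' Generates one current-voltage ramp recording: command voltage ramps
#' linearly over the protocol span while the model current
#' ([predict_membrane_current()]) is sampled and white Gaussian noise of the
#' oocyte's `noise_sd_na` is added. Identical seeds give bit-identical
#' traces.
#'
#' @param channel A [channel_model()].
#' @param oocyte An [oocyte_model()].
#' @param protocol A [ramp_protocol()].
#' @param solution A [solution_spec()]; must contain at least one permeant
#'   extracellular ion.
#' @param seed Integer seed for the noise draw.
#' @param cell_id Cell identifier stored in the metadata.
#' @param expression_scale Per-cell expression factor.
#' @param constants A [phys_constants()] object.
#' @return A `tevc_trace` tibble with columns `time_s`, `voltage_mV`,
#'   `current_nA` and a metadata attribute.
#' @export
simulate_ramp_sweep <- function(channel, oocyte, protocol, solution,
                                seed = 1L, cell_id = "cell1",
                                expression_scale = 1,
                                constants = phys_constants()) {
  stopifnot(inherits(protocol, "tevc_protocol"))
  if (protocol$kind != "ramp") {
    abort_invalid("`protocol` must be a ramp protocol.")
  }
  if (solution_mono_out(solution) == 0 && solution_ca_out(solution) == 0) {
    abort_invalid(sprintf(
      "solution '%s' contains no permeant extracellular ion.", solution$label
    ))
  }
  n <- max(2L, round(protocol$duration_s * protocol$sample_rate_hz))
  time_s <- seq(0, protocol$duration_s, length.out = n)
  v_cmd <- seq(protocol$v_from_mv, protocol$v_to_mv, length.out = n)
  mean_i <- predict_membrane_current(v_cmd, channel, oocyte, solution,
                                     constants, expression_scale)
  noise <- if (oocyte$noise_sd_na > 0) {
    withr::with_seed(seed, rnorm(n, 0, oocyte$noise_sd_na))
  } else {
    numeric(n)
  }
  new_tevc_trace(time_s, v_cmd, mean_i + noise, metadata = list(
    kind = "ramp", solution = solution$label, cell_id = cell_id, seed = seed,
    hold_mv = protocol$hold_mv, sample_rate_hz = protocol$sample_rate_hz,
    expression_scale = expression_scale
  ))
}

#' Simulate a timed solution-application sweep
#'
#' Holds the command potential fixed while the bath steps through the
#' protocol timeline. The target current in each segment is the model's
#' steady-state current in that segment's solution (Mg2+ segments scale the
#' channel current by the Woodhull unblocked fraction at the holding
#' potential, and the leak by `1 - leak_mg_sensitivity`); the recorded
#' current relaxes toward the target with the protocol's solution-exchange
#' time constant. An optional desensitization rate makes the agonist-gated
#' component sag single-exponentially from agonist onset.
#'
#' @inheritParams simulate_ramp_sweep
#' @param protocol An [application_protocol()].
#' @return A `tevc_trace` tibble; its metadata carries a `segments` table
#'   (label, start/end time, agonist mode, Mg2+ concentration) used by
#'   [application_measurements()].
#' @export
simulate_application_sweep <- function(channel, oocyte, protocol, seed = 1L,
                                       cell_id = "cell1",
                                       expression_scale = 1,
                                       constants = phys_constants()) {
  stopifnot(inherits(protocol, "tevc_protocol"))
  if (protocol$kind != "application") {
    abort_invalid("`protocol` must be an application protocol.")
  }
  constants <- as_phys_constants(constants)
  tl <- protocol$timeline
  rate <- protocol$sample_rate_hz
  seg_n <- pmax(1L, round(tl$duration_s * rate))
  n <- sum(seg_n)
  dt <- 1 / rate
  time_s <- seq_len(n) * dt
  seg_idx <- rep(seq_len(nrow(tl)), seg_n)
  seg_start <- c(0, cumsum(tl$duration_s))[seq_len(nrow(tl))]

  v_cmd <- rep(protocol$hold_mv, n)
  v_true <- protocol$hold_mv + oocyte$junction_potential_mv

  # Per-segment steady-state channel and leak currents at the hold.
  seg_chan <- vapply(seq_len(nrow(tl)), function(k) {
    sol <- protocol$solutions[[tl$solution[k]]]
    ch <- channel_component(v_true, channel, oocyte, sol, constants)
    if (oocyte$endogenous_fraction > 0) {
      endo <- endogenous_channel()
      endo$gain <- channel$gain * oocyte$endogenous_fraction
      ch <- ch + channel_component(v_true, endo, oocyte, sol, constants)
    }
    expression_scale * ch
  }, numeric(1))
  seg_leak <- vapply(seq_len(nrow(tl)), function(k) {
    sol <- protocol$solutions[[tl$solution[k]]]
    scale <- if (mg_concentration(sol) > 0) 1 - oocyte$leak_mg_sensitivity else 1
    oocyte$leak_conductance_us * scale * (v_true - oocyte$leak_reversal_mv)
  }, numeric(1))
  seg_mode <- vapply(seq_len(nrow(tl)), function(k) {
    agonist_mode(protocol$solutions[[tl$solution[k]]])
  }, character(1))

  # Time since uninterrupted agonist exposure, for the desensitization sag.
  desens <- rep(1, n)
  if (channel$desensitization_rate > 0) {
    onset <- NA_real_
    t_on <- numeric(n)
    for (i in seq_len(n)) {
      if (seg_mode[seg_idx[i]] != "none") {
        if (is.na(onset)) onset <- time_s[i]
        t_on[i] <- time_s[i] - onset
      } else {
        onset <- NA_real_
      }
    }
    desens <- ifelse(t_on > 0, exp(-channel$desensitization_rate * t_on), 1)
  }

  target <- seg_chan[seg_idx] * desens + seg_leak[seg_idx]
  current <- target
  if (protocol$exchange_tau_s > 0) {
    alpha <- 1 - exp(-dt / protocol$exchange_tau_s)
    current <- numeric(n)
    current[1] <- target[1]
    for (i in 2:n) {
      current[i] <- current[i - 1] + alpha * (target[i] - current[i - 1])
    }
  }
  if (oocyte$noise_sd_na > 0) {
    current <- current +
      withr::with_seed(seed, rnorm(n, 0, oocyte$noise_sd_na))
  }

  segments <- tibble::tibble(
    solution = tl$solution, start_s = seg_start,
    end_s = seg_start + tl$duration_s, agonist = seg_mode,
    mg_mM = vapply(seq_len(nrow(tl)), function(k) {
      mg_concentration(protocol$solutions[[tl$solution[k]]])
    }, numeric(1))
  )
  new_tevc_trace(time_s, v_cmd, current, metadata = list(
    kind = "application", solution = paste(tl$solution, collapse = " | "),
    cell_id = cell_id, seed = seed, hold_mv = protocol$hold_mv,
    sample_rate_hz = rate, expression_scale = expression_scale,
    segments = segments
  ))
}

#' Simulate a batch of cells
#'
#' Runs every protocol of an experiment description on `n_cells` simulated
#' oocytes. Each cell draws a log-normal expression scale (mean 1,
#' coefficient of variation `oocyte$expression_cv`); every sweep gets a
#' deterministic child seed derived from the root seed and the cell and
#' sweep indices, so the whole batch — and any single sweep in isolation —
#' is reproducible.
#'
#' @param config A list with elements `channel` ([channel_model()]),
#'   `oocyte` ([oocyte_model()]), and `protocols`: a named list in which
#'   each entry is either a list `list(protocol = , solution = )` for a ramp
#'   or `list(protocol = )` for an application, plus optionally `constants`.
#' @param n_cells Number of cells (>= 1).
#' @param seed Root integer seed.
#' @return A tibble of class `tevc_batch` with one row per sweep: `cell_id`,
#'   `sweep`, `expression_scale`, `seed`, and a `trace` list-column of
#'   `tevc_trace` objects.
#' @export
generate_batch <- function(config, n_cells = 5, seed = 1L) {
  if (!is.list(config) ||
      !all(c("channel", "oocyte", "protocols") %in% names(config))) {
    abort_config("`config` needs elements `channel`, `oocyte`, `protocols`.")
  }
  if (!is.numeric(n_cells) || n_cells < 1) {
    abort_invalid("`n_cells` must be >= 1.")
  }
  n_cells <- as.integer(n_cells)
  constants <- as_phys_constants(config$constants %||% phys_constants())
  oocyte <- config$oocyte
  cv <- oocyte$expression_cv
  sdlog <- sqrt(log(1 + cv^2))
  scales <- withr::with_seed(derive_seed(seed), {
    exp(rnorm(n_cells, mean = -sdlog^2 / 2, sd = sdlog))
  })
  prot_names <- names(config$protocols)
  if (is.null(prot_names) || any(!nzchar(prot_names))) {
    abort_config("`config$protocols` must be a named list.")
  }
  rows <- purrr::map(seq_len(n_cells), function(ci) {
    cell_id <- sprintf("cell%02d", ci)
    purrr::imap(config$protocols, function(entry, pname) {
      si <- match(pname, prot_names)
      sweep_seed <- derive_seed(seed, cell = ci, sweep = si)
      prot <- entry$protocol
      tr <- if (prot$kind == "ramp") {
        simulate_ramp_sweep(config$channel, oocyte, prot, entry$solution,
                            seed = sweep_seed, cell_id = cell_id,
                            expression_scale = scales[ci],
                            constants = constants)
      } else {
        simulate_application_sweep(config$channel, oocyte, prot,
                                   seed = sweep_seed, cell_id = cell_id,
                                   expression_scale = scales[ci],
                                   constants = constants)
      }
      tibble::tibble(cell_id = cell_id, sweep = pname,
                     expression_scale = scales[ci], seed = sweep_seed,
                     trace = list(tr))
    }) |> purrr::list_rbind()
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("tevc_batch", class(out))
  out
}
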