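# The Ca2+-permeability pipeline: reversal potentials from background-
# subtracted biionic IV relations, junction-potential correction, batch
# calibration of the intracellular monovalent concentration, per-cell GHK
# ratios, and group statistics.

#' Estimate the reversal potential of an IV relation
#'
#' Finds the zero crossing of the current within a search window by linear
#' interpolation between the bracketing grid points. If several crossings
#' exist (noise can produce spurious ones), the crossing closest to the
#' voltage of minimal current magnitude is returned and the multiplicity is
#' recorded in the `n_crossings` attribute. The default window −120..0 mV
#' brackets every reversal potential this kind of biionic measurement
#' produces while excluding noise-dominated extremes.
#'
#' @param iv An [iv_relation()] (normally background-subtracted).
#' @param window Two-element numeric search window in mV.
#' @return The reversal potential in mV (a length-1 numeric with attribute
#'   `n_crossings`). If no sign change exists in the window, an error of
#'   class `biionic_no_reversal` is thrown — the condition is reported, not
#'   guessed around.
#' @export
estimate_reversal_potential <- function(iv, window = c(-120, 0)) {
  stopifnot(inherits(iv, "iv_relation"))
  check_numeric_vector(window, "window")
  keep <- iv$voltage_mV >= window[1] & iv$voltage_mV <= window[2]
  v <- iv$voltage_mV[keep]
  i <- iv$current_nA[keep]
  if (length(v) < 2L) {
    abort("search window contains fewer than two grid points.",
          class = c("biionic_no_reversal", "biionic_error"))
  }
  crossing_idx <- which(i[-length(i)] * i[-1] < 0)
  crossings <- (v[crossing_idx] -
                  i[crossing_idx] * (v[crossing_idx + 1] - v[crossing_idx]) /
                  (i[crossing_idx + 1] - i[crossing_idx]))
  crossings <- c(crossings, v[i == 0])
  if (!length(crossings)) {
    abort(sprintf(
      "current does not change sign within [%g, %g] mV; no reversal found.",
      window[1], window[2]
    ), class = c("biionic_no_reversal", "biionic_error"))
  }
  v_min <- v[which.min(abs(i))]
  erev <- crossings[which.min(abs(crossings - v_min))]
  attr(erev, "n_crossings") <- length(crossings)
  erev
}

#' Correct a measured reversal potential for the liquid junction potential
#'
#' Adds the junction potential (default −4.5 mV, i.e. corrected values are
#' 4.5 mV more negative than measured) and flags the result so the pipeline
#' can guarantee the correction is applied exactly once: correcting an
#' already-corrected value is an error.
#'
#' @param erev_measured_mv Measured reversal potential(s), mV.
#' @param junction_potential_mv Junction potential, mV.
#' @return Corrected reversal potential(s) carrying the attribute
#'   `junction_corrected = TRUE`.
#' @export
correct_junction_potential <- function(erev_measured_mv,
                                       junction_potential_mv = -4.5) {
  check_numeric_vector(erev_measured_mv, "erev_measured_mv")
  check_number(junction_potential_mv, "junction_potential_mv")
  if (isTRUE(attr(erev_measured_mv, "junction_corrected"))) {
    abort_invalid("junction potential has already been applied to this value.")
  }
  out <- as.numeric(erev_measured_mv) + junction_potential_mv
  attr(out, "junction_corrected") <- TRUE
  out
}

#' Batch calibration record
#'
#' Holds the intracellular monovalent concentration used for a batch of
#' oocytes. Either supply `mono_i` directly, or supply the reference
#' channel's junction-corrected reversal potential and known permeability
#' ratio, from which `mono_i` is computed via [calibrate_mono_i()]. The
#' reference ratio is deliberately not defaulted: it comes from the
#' literature for the reference construct and must be stated per batch.
#'
#' @param batch_id Identifier for the oocyte batch.
#' @param mono_i Intracellular monovalent concentration in mM, if known
#'   directly.
#' @param erev_ref_mv,p_ref Reference-channel reversal potential (mV,
#'   junction-corrected) and known permeability ratio.
#' @param ca_o Extracellular Ca2+ of the reference measurement, mM.
#' @param constants A [phys_constants()] object.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(batch_id = "batch1", mono_i = NULL,
                               erev_ref_mv = NULL, p_ref = NULL, ca_o = 4,
                               constants = phys_constants()) {
  direct <- !is.null(mono_i)
  from_ref <- !is.null(erev_ref_mv) && !is.null(p_ref)
  if (direct == from_ref) {
    abort_config(
      "supply exactly one calibration source: `mono_i`, or `erev_ref_mv` + `p_ref`."
    )
  }
  if (from_ref) {
    mono_i <- calibrate_mono_i(erev_ref_mv, p_ref, ca_o, constants)
  }
  check_number(mono_i, "mono_i", positive = TRUE)
  structure(
    list(batch_id = batch_id, mono_i = mono_i,
         erev_ref_mv = erev_ref_mv, p_ref = p_ref, ca_o = ca_o),
    class = "calibration_record"
  )
}

#' Per-cell Ca2+/monovalent permeability ratio
#'
#' Applies the biionic GHK equation to one cell's junction-corrected
#' reversal potential using the batch's calibrated intracellular monovalent
#' concentration.
#'
#' @param erev_corrected_mv Junction-corrected reversal potential(s), mV.
#' @param calibration A [calibration_record()].
#' @param ca_o Extracellular Ca2+ concentration of the measurement, mM.
#' @param constants A [phys_constants()] object.
#' @return Permeability ratio(s), dimensionless.
#' @export
compute_permeability_per_cell <- function(erev_corrected_mv, calibration,
                                          ca_o = 4,
                                          constants = phys_constants()) {
  stopifnot(inherits(calibration, "calibration_record"))
  ghk_permeability_ratio(as.numeric(erev_corrected_mv), calibration$mono_i,
                         ca_o, constants)
}

#' Group mean, SEM, and unpaired two-group comparison
#'
#' Mean +/- SEM per group (SEM = sample SD / sqrt(n)); when two groups are
#' given, an unpaired two-sided Student's t test (classical pooled-variance
#' form by default, Welch optional) with significance tiers
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.005.
#'
#' @param values Numeric vector for group A.
#' @param values_b Optional numeric vector for group B.
#' @param var_equal Use the pooled-variance Student form (default) rather
#'   than Welch.
#' @return A tibble with one row per group (`group`, `n`, `mean`, `sem`);
#'   with two groups, columns `t`, `df`, `p_value`, `signif` are attached to
#'   both rows.
#' @export
group_statistics <- function(values, values_b = NULL, var_equal = TRUE) {
  check_numeric_vector(values, "values")
  if (length(values) < 2L) {
    abort("at least 2 values per group are required for SEM.",
          class = c("biionic_insufficient_data", "biionic_error"))
  }
  out <- tibble::tibble(
    group = "A", n = length(values), mean = mean(values),
    sem = sd(values) / sqrt(length(values))
  )
  if (is.null(values_b)) {
    return(out)
  }
  check_numeric_vector(values_b, "values_b")
  if (length(values_b) < 2L) {
    abort("at least 2 values per group are required for the t test.",
          class = c("biionic_insufficient_data", "biionic_error"))
  }
  out <- dplyr::bind_rows(out, tibble::tibble(
    group = "B", n = length(values_b), mean = mean(values_b),
    sem = sd(values_b) / sqrt(length(values_b))
  ))
  tt <- t.test(values, values_b, var.equal = var_equal)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out$signif <- signif_stars(tt$p.value)
  out
}

#' Significance tiers
#'
#' @param p P-value(s).
#' @return `"***"` for p < 0.005, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   otherwise `"ns"`.
#' @export
signif_stars <- function(p) {
  dplyr::case_when(p < 0.005 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   .default = "ns")
}

#' Reversal potential of one cell from its agonist and control ramps
#'
#' Convenience composition of the per-cell IV pipeline: bin the three ramps
#' onto a voltage grid, background-subtract, estimate the reversal
#' potential, and apply the junction correction exactly once.
#'
#' @param agonist_trace,control_before,control_after `tevc_trace` ramps from
#'   the same cell in the same Ca2+ Ringer's.
#' @param grid_step_mv Voltage bin width, mV.
#' @param window Zero-crossing search window, mV.
#' @param junction_potential_mv Junction potential, mV.
#' @return Junction-corrected reversal potential (mV).
#' @export
estimate_cell_erev <- function(agonist_trace, control_before, control_after,
                               grid_step_mv = 1, window = c(-120, 0),
                               junction_potential_mv = -4.5) {
  iv <- subtract_background(ramp_to_iv(agonist_trace, grid_step_mv),
                            ramp_to_iv(control_before, grid_step_mv),
                            ramp_to_iv(control_after, grid_step_mv))
  erev <- estimate_reversal_potential(iv, window = window)
  correct_junction_potential(erev, junction_potential_mv)
}

#' Condition-level permeability table
#'
#' Aggregates per-cell reversal potentials and permeability ratios into one
#' row per condition with mean +/- SEM and n for each agonist condition —
#' the standard reporting shape. The table reports the mean of per-cell
#' ratios; because the GHK equation is convex in the reversal potential,
#' this generally differs from the ratio computed at the mean reversal
#' potential, which is exposed alongside for comparison.
#'
#' @param per_cell Tibble with columns `condition`, `cell_id`, `agonist`
#'   (`"gly"` / `"glu_gly"`), `erev_mV` (junction-corrected), `p_ratio`.
#' @param calibration A [calibration_record()]; its `mono_i` is recorded and
#'   used for the ratio-at-mean-Erev columns.
#' @param ca_o Extracellular Ca2+, mM.
#' @param constants A [phys_constants()] object.
#' @param conditions Optional character vector fixing row order; labels
#'   outside it are a configuration error.
#' @return A tibble, one row per condition: for each agonist,
#'   `erev_*_mean/sem/n`, `p_*_mean/sem`, and `p_*_from_mean_erev`; plus
#'   `ca_o_mM` and `mono_i_mM`.
#' @export
build_permeability_table <- function(per_cell, calibration, ca_o = 4,
                                     constants = phys_constants(),
                                     conditions = NULL) {
  needed <- c("condition", "cell_id", "agonist", "erev_mV", "p_ratio")
  if (!all(needed %in% names(per_cell))) {
    abort_invalid(sprintf("`per_cell` needs columns: %s.",
                          paste(needed, collapse = ", ")))
  }
  stopifnot(inherits(calibration, "calibration_record"))
  per_cell <- check_condition_order(per_cell, conditions)
  sem <- function(x) if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  out <- per_cell |>
    dplyr::summarise(
      erev_mean = mean(.data$erev_mV), erev_sem = sem(.data$erev_mV),
      p_mean = mean(.data$p_ratio), p_sem = sem(.data$p_ratio),
      p_from_mean_erev = ghk_permeability_ratio(
        mean(.data$erev_mV), calibration$mono_i, ca_o, constants
      ),
      n = dplyr::n(),
      .by = c("condition", "agonist")
    ) |>
    tidyr::pivot_wider(
      names_from = "agonist",
      values_from = c("erev_mean", "erev_sem", "p_mean", "p_sem",
                      "p_from_mean_erev", "n")
    )
  out$ca_o_mM <- ca_o
  out$mono_i_mM <- calibration$mono_i
  order_levels <- conditions %||% unique(per_cell$condition)
  dplyr::arrange(out, match(.data$condition, order_levels))
}

#' Full permeability analysis of per-cell measurements
#'
#' Takes junction-corrected per-cell reversal potentials, computes per-cell
#' GHK ratios with the batch calibration, and wraps the per-cell table and
#' its condition-level summary into a single analysis object with
#' [tidy()], [glance()], and [autoplot()] methods.
#'
#' @param per_cell Tibble with columns `condition`, `cell_id`, `agonist`,
#'   `erev_mV` (junction-corrected).
#' @inheritParams build_permeability_table
#' @return An object of class `perm_analysis`.
#' @export
analyze_permeability <- function(per_cell, calibration, ca_o = 4,
                                 constants = phys_constants(),
                                 conditions = NULL) {
  needed <- c("condition", "cell_id", "agonist", "erev_mV")
  if (!all(needed %in% names(per_cell))) {
    abort_invalid(sprintf("`per_cell` needs columns: %s.",
                          paste(needed, collapse = ", ")))
  }
  per_cell <- tibble::as_tibble(per_cell)
  per_cell$p_ratio <- compute_permeability_per_cell(per_cell$erev_mV,
                                                    calibration, ca_o,
                                                    constants)
  tab <- build_permeability_table(per_cell, calibration, ca_o, constants,
                                  conditions)
  structure(
    list(per_cell = per_cell, table = tab, calibration = calibration,
         ca_o = ca_o, constants = as_phys_constants(constants)),
    class = "perm_analysis"
  )
}

#' @export
print.perm_analysis <- function(x, ...) {
  cat(sprintf(
    "<perm_analysis> %d cells, %d condition(s); [Mono+]i = %.1f mM, [Ca2+]o = %g mM, T = %g K\n",
    length(unique(x$per_cell$cell_id)),
    length(unique(x$per_cell$condition)),
    x$calibration$mono_i, x$ca_o, x$constants$temperature
  ))
  print(x$table)
  invisible(x)
}

#' Tidy and summarize a permeability analysis
#'
#' `tidy()` returns the condition-level summary in long form (one row per
#' condition, agonist, and quantity); `glance()` returns a one-row overview.
#'
#' @param x A `perm_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.perm_analysis <- function(x, ...) {
  sem <- function(v) if (length(v) < 2L) NA_real_ else sd(v) / sqrt(length(v))
  x$per_cell |>
    tidyr::pivot_longer(c("erev_mV", "p_ratio"), names_to = "quantity",
                        values_to = "value") |>
    dplyr::summarise(
      estimate = mean(.data$value), std_error = sem(.data$value),
      n = dplyr::n(),
      .by = c("condition", "agonist", "quantity")
    )
}

#' @rdname tidy.perm_analysis
#' @export
glance.perm_analysis <- function(x, ...) {
  tibble::tibble(
    n_cells = length(unique(x$per_cell$cell_id)),
    n_conditions = length(unique(x$per_cell$condition)),
    mono_i_mM = x$calibration$mono_i,
    ca_o_mM = x$ca_o,
    temperature_K = x$constants$temperature
  )
}
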