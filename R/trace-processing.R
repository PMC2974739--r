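# From raw sweeps to the quantities the downstream tables are built from:
# peak currents, binned and background-subtracted IV relations, normalized
# averages, percent block, agonist-response ratios, and the leak/induced
# current decomposition of apparent block.

#' Construct an IV relation
#'
#' @param voltage_mv Strictly increasing voltage grid in mV.
#' @param current_na Currents in nA, same length.
#' @param n_averaged Number of sweeps averaged into this relation.
#' @param normalized Whether currents have been normalized to a reference
#'   voltage.
#' @return A tibble of class `iv_relation` with columns `voltage_mV`,
#'   `current_nA`.
#' @export
iv_relation <- function(voltage_mv, current_na, n_averaged = 1L,
                        normalized = FALSE) {
  check_numeric_vector(voltage_mv, "voltage_mv")
  check_numeric_vector(current_na, "current_na")
  if (length(voltage_mv) != length(current_na)) {
    abort_invalid("voltage and current must have equal length.")
  }
  if (any(diff(voltage_mv) <= 0)) {
    abort_invalid("`voltage_mv` must be strictly increasing.")
  }
  iv <- tibble::tibble(voltage_mV = voltage_mv, current_nA = current_na)
  attr(iv, "n_averaged") <- as.integer(n_averaged)
  attr(iv, "normalized") <- isTRUE(normalized)
  class(iv) <- c("iv_relation", class(iv))
  iv
}

iv_meta <- function(iv) {
  list(n_averaged = attr(iv, "n_averaged") %||% 1L,
       normalized = attr(iv, "normalized") %||% FALSE)
}

#' Convert a voltage ramp sweep to an IV relation
#'
#' Bins the oversampled ramp onto a regular voltage grid by within-bin
#' averaging of both voltage and current. The regular grid makes pointwise
#' subtraction and averaging across sweeps well defined.
#'
#' @param trace A `tevc_trace` from a ramp protocol (columns `voltage_mV`,
#'   `current_nA`).
#' @param grid_step_mv Bin width in mV (default 1).
#' @return An [iv_relation()].
#' @export
ramp_to_iv <- function(trace, grid_step_mv = 1) {
  check_number(grid_step_mv, "grid_step_mv", positive = TRUE)
  if (!all(c("voltage_mV", "current_nA") %in% names(trace))) {
    abort_invalid("`trace` needs columns `voltage_mV` and `current_nA`.")
  }
  binned <- tibble::tibble(
    bin = grid_step_mv * round(trace$voltage_mV / grid_step_mv),
    v = trace$voltage_mV, i = trace$current_nA
  ) |>
    dplyr::summarise(v = mean(.data$v), i = mean(.data$i),
                     .by = "bin") |>
    dplyr::arrange(.data$v)
  iv_relation(binned$v, binned$i)
}

resample_iv <- function(iv, grid) {
  approx(iv$voltage_mV, iv$current_nA, xout = grid, rule = 1)$y
}

#' Background-subtract an agonist IV relation
#'
#' Subtracts, pointwise, the mean of two control (agonist-free) IV relations
#' recorded before and after the agonist sweep — the standard TEVC leak and
#' endogenous-conductance correction. Controls are resampled onto the
#' agonist grid by linear interpolation; the output is restricted to the
#' voltage range all three relations share.
#'
#' @param agonist_iv,control_before,control_after [iv_relation()] objects.
#' @return An [iv_relation()] on the common grid.
#' @export
subtract_background <- function(agonist_iv, control_before, control_after) {
  for (iv in list(agonist_iv, control_before, control_after)) {
    if (!inherits(iv, "iv_relation")) {
      abort_invalid("all inputs must be iv_relation objects.")
    }
  }
  lo <- max(min(agonist_iv$voltage_mV), min(control_before$voltage_mV),
            min(control_after$voltage_mV))
  hi <- min(max(agonist_iv$voltage_mV), max(control_before$voltage_mV),
            max(control_after$voltage_mV))
  keep <- agonist_iv$voltage_mV >= lo & agonist_iv$voltage_mV <= hi
  if (!any(keep)) {
    abort_invalid("voltage ranges of agonist and control IVs do not overlap.")
  }
  grid <- agonist_iv$voltage_mV[keep]
  bg <- (resample_iv(control_before, grid) +
           resample_iv(control_after, grid)) / 2
  iv_relation(grid, agonist_iv$current_nA[keep] - bg,
              n_averaged = iv_meta(agonist_iv)$n_averaged)
}

#' Normalize an IV relation to a reference voltage
#'
#' Divides the whole relation by the (linearly interpolated) current at the
#' reference voltage, so different cells can be averaged on a common scale;
#' +20 mV is the conventional reference for NMDA-receptor IV curves, safely
#' depolarized past both reversal and Mg2+ block.
#'
#' @param iv An [iv_relation()].
#' @param reference_voltage_mv Reference voltage in mV (must lie inside the
#'   grid).
#' @param epsilon Smallest admissible magnitude of the reference current;
#'   below it normalization is refused as degenerate.
#' @return A normalized [iv_relation()] whose value at the reference is 1.
#' @export
normalize_iv <- function(iv, reference_voltage_mv = 20, epsilon = 1e-9) {
  stopifnot(inherits(iv, "iv_relation"))
  check_number(reference_voltage_mv, "reference_voltage_mv")
  if (reference_voltage_mv < min(iv$voltage_mV) ||
      reference_voltage_mv > max(iv$voltage_mV)) {
    abort_invalid("reference voltage lies outside the IV grid.")
  }
  iref <- approx(iv$voltage_mV, iv$current_nA,
                 xout = reference_voltage_mv)$y
  if (abs(iref) < epsilon) {
    abort(sprintf(
      "current at %g mV is %.3g nA; normalization is degenerate.",
      reference_voltage_mv, iref
    ), class = c("biionic_degenerate_normalization", "biionic_error"))
  }
  m <- iv_meta(iv)
  iv_relation(iv$voltage_mV, iv$current_nA / iref,
              n_averaged = m$n_averaged, normalized = TRUE)
}

#' Average IV relations
#'
#' Pointwise mean of several IV relations on the grid of the first input,
#' restricted to the voltage range all inputs share; inputs on different
#' grids are resampled by linear interpolation.
#'
#' @param ivs A list of [iv_relation()] objects (at least one).
#' @return An [iv_relation()] with `n_averaged` set to the number of inputs.
#' @export
average_ivs <- function(ivs) {
  if (!is.list(ivs) || length(ivs) < 1L ||
      !all(vapply(ivs, inherits, TRUE, "iv_relation"))) {
    abort_invalid("`ivs` must be a non-empty list of iv_relation objects.")
  }
  lo <- max(vapply(ivs, function(x) min(x$voltage_mV), numeric(1)))
  hi <- min(vapply(ivs, function(x) max(x$voltage_mV), numeric(1)))
  grid <- ivs[[1]]$voltage_mV
  grid <- grid[grid >= lo & grid <= hi]
  if (!length(grid)) {
    abort_invalid("IV relations share no common voltage range.")
  }
  mat <- vapply(ivs, resample_iv, numeric(length(grid)), grid = grid)
  mat <- matrix(mat, nrow = length(grid))
  iv_relation(grid, rowMeans(mat), n_averaged = length(ivs),
              normalized = all(vapply(ivs, function(x) iv_meta(x)$normalized,
                                      TRUE)))
}

#' Baseline-subtracted response amplitude of an application sweep
#'
#' Quantifies the agonist response as the baseline-subtracted current in a
#' response window, reported as a positive magnitude for inward responses
#' (the sign convention of amplitude tables). By default the response is the
#' plateau mean over the last quarter of the window — 20-s applications
#' reach steady state — with the extremum available as an alternative.
#'
#' @param trace A `tevc_trace` (columns `time_s`, `current_nA`).
#' @param window Two-element numeric, response window in s.
#' @param baseline_window Two-element numeric, baseline window in s; must end
#'   before the response window begins.
#' @param method `"plateau"` (mean over the last `plateau_fraction` of the
#'   window) or `"extremum"` (largest baseline deviation).
#' @param plateau_fraction Final fraction of the window averaged by the
#'   plateau method.
#' @return Response magnitude in nA (positive for inward responses).
#' @export
peak_current <- function(trace, window, baseline_window,
                         method = c("plateau", "extremum"),
                         plateau_fraction = 0.25) {
  method <- match.arg(method)
  if (!all(c("time_s", "current_nA") %in% names(trace))) {
    abort_invalid("`trace` needs columns `time_s` and `current_nA`.")
  }
  check_numeric_vector(window, "window")
  check_numeric_vector(baseline_window, "baseline_window")
  if (length(window) != 2L || length(baseline_window) != 2L) {
    abort_invalid("windows must be two-element numeric vectors (s).")
  }
  if (baseline_window[2] > window[1]) {
    abort_invalid("the baseline window must precede the response window.")
  }
  t <- trace$time_s
  in_b <- t >= baseline_window[1] & t <= baseline_window[2]
  w_start <- if (method == "plateau") {
    window[2] - plateau_fraction * (window[2] - window[1])
  } else {
    window[1]
  }
  in_w <- t >= w_start & t <= window[2]
  if (!any(in_b) || !any(in_w)) {
    abort_invalid("empty baseline or response window.")
  }
  baseline <- mean(trace$current_nA[in_b])
  resp <- if (method == "plateau") {
    mean(trace$current_nA[in_w])
  } else {
    i <- trace$current_nA[in_w]
    i[which.max(abs(i - baseline))]
  }
  # inward (negative) deflections reported as positive magnitudes
  baseline - resp
}

#' Percent block of a response by a blocker
#'
#' `100 * (i_control - i_with_blocker) / i_control`, both inputs being
#' baseline-subtracted response magnitudes from the same sweep. Negative
#' values indicate potentiation; values above 100 arise when the blocker
#' also suppresses leak current (see [apparent_block_decomposition()]).
#'
#' @param i_control Response magnitude without blocker, nA (nonzero).
#' @param i_with_blocker Response magnitude with blocker, nA.
#' @return Percent block (vectorized).
#' @export
percent_block <- function(i_control, i_with_blocker) {
  check_numeric_vector(i_control, "i_control")
  check_numeric_vector(i_with_blocker, "i_with_blocker")
  if (any(i_control == 0)) {
    abort("percent block is undefined for a zero control current.",
          class = c("biionic_undefined_block", "biionic_error"))
  }
  100 * (i_control - i_with_blocker) / i_control
}

#' Ratio of glycine- to glutamate/glycine-evoked current
#'
#' Computed per cell; group summaries should average the per-cell ratios
#' rather than take the ratio of mean amplitudes, which is biased when
#' amplitude and ratio vary together across cells.
#'
#' @param i_gly Glycine-evoked response magnitude, nA.
#' @param i_glu_gly Glutamate/glycine-evoked response magnitude, nA (> 0).
#' @return Dimensionless ratio (vectorized).
#' @export
response_ratio <- function(i_gly, i_glu_gly) {
  check_numeric_vector(i_gly, "i_gly")
  check_numeric_vector(i_glu_gly, "i_glu_gly")
  if (any(i_glu_gly <= 0)) {
    abort_invalid("`i_glu_gly` must be > 0.")
  }
  i_gly / i_glu_gly
}

#' Decompose apparent percent block into channel and leak contributions
#'
#' Measured block relates the blocker-induced current drop to the
#' agonist-induced current (IC). If the blocker also suppresses a leak
#' current (LC), the apparent block is
#' `100 * (f_channel * IC + f_leak * LC) / IC`, which exceeds 100 percent
#' whenever `f_leak * LC > (1 - f_channel) * IC` — the situation for small
#' agonist responses riding on a large, partly blocker-sensitive leak.
#'
#' @param ic Agonist-induced current magnitude, nA (> 0).
#' @param lc Leak current magnitude, nA (>= 0).
#' @param f_channel Blocked fraction of the channel current, in \[0, 1\].
#' @param f_leak Blocked fraction of the leak current, in \[0, 1\].
#' @return Apparent percent block.
#' @export
apparent_block_decomposition <- function(ic, lc, f_channel, f_leak) {
  check_number(ic, "ic", positive = TRUE)
  check_number(lc, "lc", non_negative = TRUE)
  check_number(f_channel, "f_channel", non_negative = TRUE)
  check_number(f_leak, "f_leak", non_negative = TRUE)
  if (f_channel > 1 || f_leak > 1) {
    abort_invalid("`f_channel` and `f_leak` must lie in [0, 1].")
  }
  100 * (f_channel * ic + f_leak * lc) / ic
}

#' Response amplitude and percent block of an application sweep
#'
#' Reads the segment table a simulated (or loaded) application sweep
#' carries, and measures: the baseline from the plateau of the last
#' agonist-free segment preceding the application, the control response from
#' the agonist segment immediately before the Mg2+ pulse, and the blocked
#' response from the Mg2+ segment. Block is computed within the single
#' sweep via [percent_block()]. Sweeps without an Mg2+ segment yield
#' `percent_block = NA`.
#'
#' @param trace A `tevc_trace` from [simulate_application_sweep()] (or
#'   [read_trace_bundle()]) whose metadata carries a `segments` table.
#' @param plateau_fraction Final fraction of each segment averaged.
#' @return A one-row tibble: `agonist`, `i_response_nA`, `i_with_mg_nA`,
#'   `percent_block`.
#' @export
application_measurements <- function(trace, plateau_fraction = 0.25) {
  md <- trace_metadata(trace)
  seg <- md$segments
  if (is.null(seg)) {
    abort_invalid("`trace` metadata has no `segments` table.")
  }
  plateau <- function(k) {
    t0 <- seg$end_s[k] - plateau_fraction * (seg$end_s[k] - seg$start_s[k])
    mean(trace$current_nA[trace$time_s >= t0 & trace$time_s <= seg$end_s[k]])
  }
  agonist_rows <- which(seg$agonist != "none")
  if (!length(agonist_rows)) {
    abort_invalid("application sweep contains no agonist segment.")
  }
  pre_rows <- which(seg$agonist == "none" & seq_len(nrow(seg)) < min(agonist_rows))
  if (!length(pre_rows)) {
    abort_invalid("no agonist-free baseline segment precedes the application.")
  }
  baseline <- plateau(max(pre_rows))
  mg_rows <- intersect(agonist_rows, which(seg$mg_mM > 0))
  ctrl_rows <- setdiff(agonist_rows, mg_rows)
  ctrl <- if (length(mg_rows)) {
    prior <- ctrl_rows[ctrl_rows < min(mg_rows)]
    if (!length(prior)) {
      abort_invalid("no blocker-free agonist segment precedes the Mg2+ pulse.")
    }
    max(prior)
  } else {
    max(ctrl_rows)
  }
  i_resp <- baseline - plateau(ctrl)
  i_mg <- if (length(mg_rows)) baseline - plateau(min(mg_rows)) else NA_real_
  pb <- if (length(mg_rows)) percent_block(i_resp, i_mg) else NA_real_
  tibble::tibble(agonist = seg$agonist[ctrl], i_response_nA = i_resp,
                 i_with_mg_nA = i_mg, percent_block = pb)
}

#' Summarize per-cell amplitudes and block into a condition table
#'
#' Aggregates per-cell measurements into one row per condition with
#' mean +/- SEM and n for glycine- and glutamate/glycine-evoked amplitudes
#' and their percent Mg2+ block (the shape of an amplitude-and-block
#' summary table). Aggregation is mean of per-cell values throughout; the
#' mean per-cell glycine to glutamate/glycine response ratio is included.
#'
#' @param per_cell Tibble with columns `condition`, `cell_id`, `agonist`
#'   (`"gly"` or `"glu_gly"`), `i_response_nA`, `percent_block`.
#' @param conditions Optional character vector fixing row order; labels in
#'   `per_cell` that it does not contain are a configuration error.
#' @return A tibble, one row per condition.
#' @export
build_block_table <- function(per_cell, conditions = NULL) {
  needed <- c("condition", "cell_id", "agonist", "i_response_nA",
              "percent_block")
  if (!all(needed %in% names(per_cell))) {
    abort_invalid(sprintf("`per_cell` needs columns: %s.",
                          paste(needed, collapse = ", ")))
  }
  per_cell <- check_condition_order(per_cell, conditions)
  sem <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2L) NA_real_ else sd(x) / sqrt(length(x))
  }
  nfin <- function(x) sum(is.finite(x))
  stats <- per_cell |>
    dplyr::summarise(
      i_mean = mean(.data$i_response_nA),
      i_sem = sem(.data$i_response_nA),
      i_n = dplyr::n(),
      block_mean = mean(.data$percent_block[is.finite(.data$percent_block)]),
      block_sem = sem(.data$percent_block),
      block_n = nfin(.data$percent_block),
      .by = c("condition", "agonist")
    ) |>
    tidyr::pivot_wider(names_from = "agonist",
                       values_from = c("i_mean", "i_sem", "i_n",
                                       "block_mean", "block_sem", "block_n"))
  ratios <- per_cell |>
    dplyr::select("condition", "cell_id", "agonist", "i_response_nA") |>
    tidyr::pivot_wider(names_from = "agonist",
                       values_from = "i_response_nA") |>
    dplyr::filter(!is.na(.data$gly), !is.na(.data$glu_gly)) |>
    dplyr::summarise(
      ratio_gly_gluGly = mean(response_ratio(.data$gly, .data$glu_gly)),
      ratio_sem = sem(response_ratio(.data$gly, .data$glu_gly)),
      .by = "condition"
    )
  out <- dplyr::left_join(stats, ratios, by = "condition")
  dplyr::arrange(out, match(.data$condition, levels(factor(
    per_cell$condition, levels = conditions %||% unique(per_cell$condition)
  ))))
}

check_condition_order <- function(per_cell, conditions) {
  if (!is.null(conditions)) {
    unknown <- setdiff(unique(per_cell$condition), conditions)
    if (length(unknown)) {
      abort_config(sprintf("unknown condition label(s): %s",
                           paste(unknown, collapse = ", ")))
    }
    per_cell$condition <- factor(per_cell$condition, levels = conditions)
    per_cell <- dplyr::arrange(per_cell, .data$condition)
    per_cell$condition <- as.character(per_cell$condition)
  }
  per_cell
}
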