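# Generative model descriptions: bath solutions, channel phenotypes, oocyte
# (cell) properties, and stimulation protocols. These are plain classed lists;
# the tabular surfaces of the package start at the simulated sweeps.

PERMEANT_MONOVALENTS <- c("Na", "K", "Cs", "Li")

#' Describe a bath solution
#'
#' @param label Short text label used in protocols and output tables.
#' @param ions Named numeric vector of cation concentrations in mM
#'   (e.g. `c(Na = 115, K = 2.5, Ca = 1.8)`). NMDG and HEPES are treated as
#'   impermeant; Na, K, Cs, Li as permeant monovalents; Ca as the permeant
#'   divalent.
#' @param agonists Named numeric vector of agonist concentrations in uM
#'   (names among "glutamate", "glycine").
#' @param blockers Named numeric vector of blocker concentrations in mM
#'   (name "Mg" is recognised by the simulator).
#' @param pH Bath pH, recorded as metadata only.
#'
#' @return An object of class `solution_spec`.
#' @export
solution_spec <- function(label, ions = c(), agonists = c(), blockers = c(),
                          pH = 7.2) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_invalid("`label` must be a non-empty string.")
  }
  for (v in list(ions = ions, agonists = agonists, blockers = blockers)) {
    if (length(v) && (any(v < 0) || is.null(names(v)) || any(!nzchar(names(v))))) {
      abort_invalid("solution concentrations must be named and >= 0.")
    }
  }
  check_number(pH, "pH", positive = TRUE)
  structure(list(label = label, ions = ions, agonists = agonists,
                 blockers = blockers, pH = pH),
            class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  fmt <- function(v, unit) {
    if (!length(v)) return("none")
    paste(sprintf("%s %g %s", names(v), v, unit), collapse = ", ")
  }
  cat(sprintf("<solution_spec> %s (pH %g)\n  ions: %s\n  agonists: %s\n  blockers: %s\n",
              x$label, x$pH, fmt(x$ions, "mM"), fmt(x$agonists, "uM"),
              fmt(x$blockers, "mM")))
  invisible(x)
}

#' Standard recording solutions
#'
#' `solution_nfr()` is normal frog Ringer's (115 mM NaCl, 2.5 mM KCl,
#' 1.8 mM CaCl2, HEPES). `solution_car()` is the biionic Ca2+ Ringer's in
#' which extracellular monovalents are replaced by impermeant NMDG
#' (108.6 mM NMDG / 4 mM CaCl2, or 114.2 mM NMDG / 8 mM CaCl2), leaving Ca2+
#' as the only putatively permeant extracellular cation.
#'
#' @param ca_mm Extracellular CaCl2 concentration for `solution_car()`,
#'   4 or 8 mM.
#' @param pH Bath pH.
#' @return A [solution_spec()].
#' @export
solution_nfr <- function(pH = 7.2) {
  solution_spec("NFR", ions = c(Na = 115, K = 2.5, Ca = 1.8), pH = pH)
}

#' @rdname solution_nfr
#' @export
solution_car <- function(ca_mm = 4, pH = 7.2) {
  if (!ca_mm %in% c(4, 8)) {
    abort_invalid("`ca_mm` must be 4 or 8 (the two CaR recipes).")
  }
  nmdg <- if (ca_mm == 4) 108.6 else 114.2
  solution_spec(sprintf("%d mM CaR", ca_mm),
                ions = c(NMDG = nmdg, Ca = ca_mm), pH = pH)
}

#' Add agonists or blockers to a solution
#'
#' Returns a copy of the solution with agonist/blocker concentrations set and
#' the label suffixed accordingly, mirroring how working solutions are made
#' up from a Ringer's base.
#'
#' @param solution A [solution_spec()].
#' @param glycine_um,glutamate_um Agonist concentrations in uM.
#' @param mg_mm Mg2+ concentration in mM.
#' @return A [solution_spec()].
#' @export
with_agonists <- function(solution, glycine_um = 0, glutamate_um = 0) {
  stopifnot(inherits(solution, "solution_spec"))
  ag <- c(glutamate = glutamate_um, glycine = glycine_um)
  ag <- ag[ag > 0]
  tag <- paste(names(ag), collapse = "/")
  solution$agonists <- ag
  if (length(ag)) solution$label <- paste0(solution$label, " + ", tag)
  solution
}

#' @rdname with_agonists
#' @export
with_blocker <- function(solution, mg_mm) {
  stopifnot(inherits(solution, "solution_spec"))
  check_number(mg_mm, "mg_mm", non_negative = TRUE)
  solution$blockers <- c(Mg = mg_mm)
  if (mg_mm > 0) solution$label <- paste0(solution$label, " + Mg")
  solution
}

#' Default named solution set
#'
#' The working solutions of a typical oocyte TEVC session: NFR and 4/8 mM
#' CaR bases, each with glycine alone (10 uM) or glutamate/glycine
#' (100/10 uM), and NFR agonist solutions with 0.5 mM Mg2+.
#'
#' @param glycine_um,glutamate_um,mg_mm Working concentrations.
#' @return A named list of [solution_spec()] objects, keyed by label.
#' @export
default_solutions <- function(glycine_um = 10, glutamate_um = 100,
                              mg_mm = 0.5) {
  sols <- list(
    solution_nfr(),
    with_agonists(solution_nfr(), glycine_um = glycine_um),
    with_agonists(solution_nfr(), glycine_um = glycine_um,
                  glutamate_um = glutamate_um),
    with_blocker(with_agonists(solution_nfr(), glycine_um = glycine_um),
                 mg_mm),
    with_blocker(with_agonists(solution_nfr(), glycine_um = glycine_um,
                               glutamate_um = glutamate_um), mg_mm),
    solution_car(4),
    with_agonists(solution_car(4), glycine_um = glycine_um),
    with_agonists(solution_car(4), glycine_um = glycine_um,
                  glutamate_um = glutamate_um),
    solution_car(8),
    with_agonists(solution_car(8), glycine_um = glycine_um),
    with_agonists(solution_car(8), glycine_um = glycine_um,
                  glutamate_um = glutamate_um)
  )
  setNames(sols, vapply(sols, `[[`, "", "label"))
}

#' Generative channel description
#'
#' Biophysical phenotype of a receptor population used by the sweep
#' simulator: relative Ca2+ permeability, overall conductance gain, the
#' fraction of maximal activation reached by each agonist set, optional
#' Woodhull block parameters, and an optional desensitization rate.
#'
#' @param pca_over_pmono Ca2+ permeability relative to the lumped monovalent
#'   reference (>= 0).
#' @param gain Conductance scale converting the summed GHK flux to nA; the
#'   default gives glutamate/glycine currents on the order of 1-2 uA at
#'   -70 mV in NFR for a cell with unit expression.
#' @param agonist_efficacy Named numeric vector with entries `gly` and
#'   `glu_gly`, each in \[0, 1\]: fraction of maximal activation under
#'   glycine alone and under glutamate + glycine. NR1/NR2-like channels have
#'   small `gly`; NR1/NR3-like glycine receptors have `gly` close to
#'   `glu_gly`.
#' @param block A [woodhull_params()] object (blocker concentration may be
#'   `NA`; it is taken from the bath), or `NULL` for a block-insensitive
#'   channel.
#' @param desensitization_rate Exponential sag rate of the agonist-gated
#'   current in s^-1; 0 (default) disables desensitization.
#'
#' @return An object of class `channel_model`.
#' @export
channel_model <- function(pca_over_pmono = 2.3, gain = 500,
                          agonist_efficacy = c(gly = 0.06, glu_gly = 1),
                          block = NULL, desensitization_rate = 0) {
  check_number(pca_over_pmono, "pca_over_pmono", non_negative = TRUE)
  check_number(gain, "gain", non_negative = TRUE)
  if (is.null(names(agonist_efficacy)) ||
      !all(c("gly", "glu_gly") %in% names(agonist_efficacy)) ||
      any(agonist_efficacy < 0) || any(agonist_efficacy > 1)) {
    abort_invalid(
      "`agonist_efficacy` needs named entries `gly` and `glu_gly` in [0, 1]."
    )
  }
  if (!is.null(block)) {
    stopifnot(inherits(block, "woodhull_params"))
  }
  check_number(desensitization_rate, "desensitization_rate",
               non_negative = TRUE)
  structure(
    list(pca_over_pmono = pca_over_pmono, gain = gain,
         agonist_efficacy = agonist_efficacy, block = block,
         desensitization_rate = desensitization_rate),
    class = "channel_model"
  )
}

#' Oocyte (recording cell) description
#'
#' Everything about the cell and recording that is not the channel: ohmic
#' leak, intracellular ion content, expression variability across cells,
#' current noise, the liquid junction potential offsetting command voltages,
#' Mg2+ sensitivity of the leak (the mechanism behind apparent block
#' exceeding 100 percent), and an optional endogenous glutamate-gated
#' contamination mimicking oocyte-native NR2B-like subunits.
#'
#' @param leak_conductance_us Ohmic leak conductance in uS (>= 0).
#' @param leak_reversal_mv Leak reversal potential in mV.
#' @param mono_i Intracellular monovalent cation concentration in mM.
#' @param ca_i Intracellular free Ca2+ in mM (default 0: buffered, as after
#'   EGTA injection).
#' @param expression_cv Coefficient of variation of the log-normal per-cell
#'   expression scale used by [generate_batch()].
#' @param noise_sd_na Standard deviation of white Gaussian current noise, nA.
#' @param junction_potential_mv Liquid junction potential in mV; the membrane
#'   sees `command + junction`, and analysis must add the same value back via
#'   [correct_junction_potential()].
#' @param leak_mg_sensitivity Fraction of the leak conductance suppressed
#'   while Mg2+ is in the bath, in \[0, 1\].
#' @param endogenous_fraction Gain fraction of an endogenous
#'   glutamate-requiring, Mg2+-blockable, Ca2+-permeable conventional-like
#'   channel population, in \[0, 1\].
#'
#' @return An object of class `oocyte_model`.
#' @export
oocyte_model <- function(leak_conductance_us = 1, leak_reversal_mv = -20,
                         mono_i = 89.4, ca_i = 0, expression_cv = 0.5,
                         noise_sd_na = 5, junction_potential_mv = -4.5,
                         leak_mg_sensitivity = 0, endogenous_fraction = 0) {
  check_number(leak_conductance_us, "leak_conductance_us", non_negative = TRUE)
  check_number(leak_reversal_mv, "leak_reversal_mv")
  check_number(mono_i, "mono_i", positive = TRUE)
  check_number(ca_i, "ca_i", non_negative = TRUE)
  check_number(expression_cv, "expression_cv", non_negative = TRUE)
  check_number(noise_sd_na, "noise_sd_na", non_negative = TRUE)
  check_number(junction_potential_mv, "junction_potential_mv")
  check_number(leak_mg_sensitivity, "leak_mg_sensitivity", non_negative = TRUE)
  check_number(endogenous_fraction, "endogenous_fraction", non_negative = TRUE)
  if (leak_mg_sensitivity > 1 || endogenous_fraction > 1) {
    abort_invalid("`leak_mg_sensitivity` and `endogenous_fraction` lie in [0, 1].")
  }
  structure(
    list(leak_conductance_us = leak_conductance_us,
         leak_reversal_mv = leak_reversal_mv, mono_i = mono_i, ca_i = ca_i,
         expression_cv = expression_cv, noise_sd_na = noise_sd_na,
         junction_potential_mv = junction_potential_mv,
         leak_mg_sensitivity = leak_mg_sensitivity,
         endogenous_fraction = endogenous_fraction),
    class = "oocyte_model"
  )
}

#' Voltage-ramp protocol
#'
#' A linear command-voltage ramp used to record current-voltage relations;
#' the default spans -150 to +50 mV in 2 s.
#'
#' @param v_from_mv,v_to_mv Ramp limits in mV.
#' @param duration_s Ramp duration in s (> 0).
#' @param sample_rate_hz Sampling rate in Hz (>= 100).
#' @param hold_mv Holding potential in mV (metadata; the ramp itself defines
#'   the command).
#' @return An object of class `tevc_protocol` with `kind = "ramp"`.
#' @export
ramp_protocol <- function(v_from_mv = -150, v_to_mv = 50, duration_s = 2,
                          sample_rate_hz = 1000, hold_mv = -70) {
  check_number(duration_s, "duration_s", positive = TRUE)
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (sample_rate_hz < 100) {
    abort_invalid("`sample_rate_hz` must be >= 100.")
  }
  check_number(v_from_mv, "v_from_mv")
  check_number(v_to_mv, "v_to_mv")
  structure(
    list(kind = "ramp", v_from_mv = v_from_mv, v_to_mv = v_to_mv,
         duration_s = duration_s, sample_rate_hz = sample_rate_hz,
         hold_mv = hold_mv),
    class = "tevc_protocol"
  )
}

#' Timed solution-application protocol
#'
#' A voltage-clamp sweep at a fixed holding potential during which the bath
#' is switched through an ordered timeline of solutions, e.g. a 60-s agonist
#' application with a 20-s Mg2+ pulse in the middle. Solution exchange is
#' modelled as first-order relaxation with time constant `exchange_tau_s`.
#'
#' @param timeline Data frame with columns `solution` (labels resolving in
#'   `solutions`) and `duration_s` (> 0).
#' @param solutions Named list of [solution_spec()] objects the timeline may
#'   reference.
#' @param hold_mv Holding potential in mV.
#' @param sample_rate_hz Sampling rate in Hz (>= 100).
#' @param exchange_tau_s Solution-exchange time constant in s.
#' @return An object of class `tevc_protocol` with `kind = "application"`.
#' @export
application_protocol <- function(timeline, solutions = default_solutions(),
                                 hold_mv = -70, sample_rate_hz = 100,
                                 exchange_tau_s = 1) {
  timeline <- tibble::as_tibble(timeline)
  if (!all(c("solution", "duration_s") %in% names(timeline)) ||
      nrow(timeline) < 1L) {
    abort_config("`timeline` needs columns `solution` and `duration_s`.")
  }
  if (any(timeline$duration_s <= 0)) {
    abort_config("all timeline durations must be > 0.")
  }
  missing <- setdiff(timeline$solution, names(solutions))
  if (length(missing)) {
    abort_config(sprintf("timeline references undefined solution(s): %s",
                         paste(missing, collapse = ", ")))
  }
  check_number(sample_rate_hz, "sample_rate_hz", positive = TRUE)
  if (sample_rate_hz < 100) {
    abort_invalid("`sample_rate_hz` must be >= 100.")
  }
  check_number(exchange_tau_s, "exchange_tau_s", non_negative = TRUE)
  structure(
    list(kind = "application", timeline = timeline, solutions = solutions,
         hold_mv = hold_mv, sample_rate_hz = sample_rate_hz,
         exchange_tau_s = exchange_tau_s),
    class = "tevc_protocol"
  )
}

#' Standard agonist application with an Mg2+ pulse
#'
#' Builds the block-measurement timeline: baseline Ringer's, agonist
#' application, Mg2+ added during the application, agonist again, wash.
#' Defaults follow a 60-s application with a 20-s Mg2+ pulse.
#'
#' @param agonist_label Label of the agonist solution.
#' @param mg_label Label of the agonist + Mg2+ solution (NULL for a
#'   block-free application; the agonist segment is then extended).
#' @param base_label Label of the plain Ringer's used before and after.
#' @param pre_s,seg_s,post_s Baseline duration, duration of each of the
#'   three application segments, and wash duration (s).
#' @inheritParams application_protocol
#' @return A [application_protocol()] object.
#' @export
mg_block_protocol <- function(agonist_label = "NFR + glutamate/glycine",
                              mg_label = "NFR + glutamate/glycine + Mg",
                              base_label = "NFR",
                              solutions = default_solutions(),
                              pre_s = 10, seg_s = 20, post_s = 10,
                              hold_mv = -70, sample_rate_hz = 100,
                              exchange_tau_s = 1) {
  mid <- if (is.null(mg_label)) agonist_label else mg_label
  timeline <- tibble::tibble(
    solution = c(base_label, agonist_label, mid, agonist_label, base_label),
    duration_s = c(pre_s, seg_s, seg_s, seg_s, post_s)
  )
  application_protocol(timeline, solutions = solutions, hold_mv = hold_mv,
                       sample_rate_hz = sample_rate_hz,
                       exchange_tau_s = exchange_tau_s)
}
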