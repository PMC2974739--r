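#' Biionic GHK permeability ratio from a reversal potential
#'
#' Computes the permeability of Ca2+ relative to lumped intracellular
#' monovalent cations from the reversal potential measured under biionic
#' conditions, i.e. with Ca2+ as the only putatively permeant cation outside
#' (monovalents replaced by impermeant NMDG) and only monovalent cations,
#' assumed equally permeant, inside:
#'
#' \deqn{\frac{P_{Ca}}{P_{mono}} =
#'   \frac{[Mono^+]_i \, e^{x} (e^{x} + 1)}{4\,[Ca^{2+}]_o}, \qquad
#'   x = \frac{E_{rev} F}{R T}}
#'
#' This is the reversal condition of the summed GHK current equations for one
#' divalent and one lumped monovalent species; see [ghk_current()].
#'
#' @param erev_mv Reversal potential(s) in mV (junction-corrected).
#' @param mono_i Intracellular monovalent cation concentration in mM.
#' @param ca_o Extracellular Ca2+ concentration in mM.
#' @param constants A [phys_constants()] object.
#'
#' @return A strictly positive numeric vector, one ratio per element of
#'   `erev_mv`. The ratio is strictly increasing in `erev_mv`.
#'
#' @seealso [calibrate_mono_i()] for the algebraic inverse used to obtain
#'   `mono_i` from a reference channel with known ratio.
#'
#' @examples
#' # At 0 mV both exponentials are 1: 100 * 1 * 2 / (4 * 4) = 12.5
#' ghk_permeability_ratio(0, mono_i = 100, ca_o = 4)
#'
#' # A typical NR1/NR2B-like operating point
#' ghk_permeability_ratio(-29.3, mono_i = 89.4, ca_o = 4)
#' @export
ghk_permeability_ratio <- function(erev_mv, mono_i, ca_o,
                                   constants = phys_constants()) {
  check_numeric_vector(erev_mv, "erev_mv")
  check_number(mono_i, "mono_i", positive = TRUE)
  check_number(ca_o, "ca_o", positive = TRUE)
  constants <- as_phys_constants(constants)
  x <- erev_mv / 1000 * beta_per_volt(constants)
  mono_i * exp(x) * (exp(x) + 1) / (4 * ca_o)
}

#' Calibrate the intracellular monovalent concentration from a reference channel
#'
#' Inverts the biionic GHK permeability equation: given the reversal potential
#' of a reference channel whose Ca2+/monovalent permeability ratio is known
#' from the literature (in oocyte work, typically GluR6(Q) measured in the
#' same batch), returns the effective intracellular monovalent cation
#' concentration that makes the forward equation reproduce that ratio.
#'
#' @param erev_ref_mv Junction-corrected reversal potential of the reference
#'   channel, in mV.
#' @param p_ref Known permeability ratio of the reference channel
#'   (dimensionless, > 0).
#' @param ca_o Extracellular Ca2+ concentration in mM.
#' @param constants A [phys_constants()] object.
#'
#' @return The intracellular monovalent concentration in mM. The round trip
#'   `ghk_permeability_ratio(erev_ref_mv, calibrate_mono_i(...), ca_o)`
#'   reproduces `p_ref` to better than 1e-9 relative error.
#'
#' @examples
#' calibrate_mono_i(erev_ref_mv = 0, p_ref = 12.5, ca_o = 4) # 100 mM
#' @export
calibrate_mono_i <- function(erev_ref_mv, p_ref, ca_o,
                             constants = phys_constants()) {
  check_number(erev_ref_mv, "erev_ref_mv")
  check_number(p_ref, "p_ref", positive = TRUE)
  check_number(ca_o, "ca_o", positive = TRUE)
  constants <- as_phys_constants(constants)
  x <- erev_ref_mv / 1000 * beta_per_volt(constants)
  4 * ca_o * p_ref / (exp(x) * (exp(x) + 1))
}

#' GHK current for a single ion species
#'
#' Constant-field (Goldman-Hodgkin-Katz) current carried by one ion species
#' at a given membrane potential. Used generatively by the sweep simulator;
#' the sum over permeant species defines the channel current, and its zero
#' crossing under biionic conditions is exactly the reversal potential of
#' [ghk_permeability_ratio()].
#'
#' \deqn{I = P z^2 \frac{F^2 V}{R T}
#'   \frac{[X]_i - [X]_o e^{-u}}{1 - e^{-u}}, \qquad u = \frac{z F V}{R T}}
#'
#' The singularity at \eqn{V = 0} is handled by the analytic limit
#' \eqn{I \to P z F ([X]_i - [X]_o)}. Sign convention: outward current is
#' positive, inward current negative; depolarized potentials are positive.
#'
#' @param v_mv Membrane potential(s) in mV.
#' @param charge Ion valence, +1 or +2.
#' @param conc_in,conc_out Intracellular / extracellular concentrations in mM
#'   (non-negative, not both zero).
#' @param permeability Relative permeability scale (dimensionless here; the
#'   simulator applies a gain that converts to nA).
#' @param constants A [phys_constants()] object.
#'
#' @return Numeric vector of currents in arbitrary (permeability-scaled)
#'   units, one per element of `v_mv`. Vanishes exactly at the ion's Nernst
#'   potential.
#'
#' @examples
#' # equilibrium: equal concentrations, 0 mV
#' ghk_current(0, charge = 1, conc_in = 100, conc_out = 100)
#' @export
ghk_current <- function(v_mv, charge, conc_in, conc_out, permeability = 1,
                        constants = phys_constants()) {
  check_numeric_vector(v_mv, "v_mv")
  if (!charge %in% c(1, 2)) {
    abort_invalid("`charge` must be +1 or +2.")
  }
  check_number(conc_in, "conc_in", non_negative = TRUE)
  check_number(conc_out, "conc_out", non_negative = TRUE)
  if (conc_in == 0 && conc_out == 0) {
    abort_invalid("`conc_in` and `conc_out` must not both be zero.")
  }
  check_number(permeability, "permeability", non_negative = TRUE)
  constants <- as_phys_constants(constants)

  f <- constants$faraday
  v <- v_mv / 1000
  u <- charge * beta_per_volt(constants) * v
  out <- numeric(length(v))
  small <- abs(u) < 1e-6
  # second-order expansion around u = 0; exact at u = 0
  out[small] <- permeability * charge * f *
    ((conc_in - conc_out) + u[small] * (conc_in + conc_out) / 2)
  ub <- u[!small]
  out[!small] <- permeability * charge * f * ub *
    (conc_in - conc_out * exp(-ub)) / (1 - exp(-ub))
  out
}

#' Woodhull unblocked fraction for voltage-dependent open-channel block
#'
#' Fraction of channels not occupied by a blocking ion that binds at
#' fractional electrical depth delta within the pore (Woodhull model). The
#' voltage-dependent dissociation constant is
#' \eqn{K_d(V) = K_d(0)\, e^{z\delta F V / R T}}, so for an extracellular
#' cationic blocker (`zdelta > 0`) block deepens with hyperpolarization and
#' the unblocked fraction is strictly increasing in voltage — the behaviour
#' of Mg2+ block of NMDA receptor channels.
#'
#' @param v_mv Membrane potential(s) in mV.
#' @param params A [woodhull_params()] object (or a list with `kd0`,
#'   `zdelta`, `blocker_conc`).
#' @param constants A [phys_constants()] object.
#'
#' @return Numeric vector of fractions in \[0, 1\].
#'
#' @examples
#' p <- woodhull_params(kd0 = 1, zdelta = 1, blocker_conc = 0.5)
#' woodhull_unblocked_fraction(c(-150, -70, 0), p)
#' @export
woodhull_unblocked_fraction <- function(v_mv, params,
                                        constants = phys_constants()) {
  check_numeric_vector(v_mv, "v_mv")
  params <- as_woodhull_params(params)
  constants <- as_phys_constants(constants)
  if (params$blocker_conc == 0) {
    return(rep(1, length(v_mv)))
  }
  kd <- params$kd0 *
    exp(params$zdelta * beta_per_volt(constants) * v_mv / 1000)
  kd / (kd + params$blocker_conc)
}

#' Parameters of the Woodhull block model
#'
#' @param kd0 Zero-voltage dissociation constant in mM (> 0).
#' @param zdelta Effective valence times fractional electrical distance,
#'   dimensionless, in \[0, 2\].
#' @param blocker_conc Blocker concentration in mM (>= 0). May be left `NA`
#'   in a channel description; the simulator fills it in from the bath
#'   solution.
#'
#' @return An object of class `woodhull_params`.
#' @export
woodhull_params <- function(kd0, zdelta, blocker_conc = NA_real_) {
  check_number(kd0, "kd0", positive = TRUE)
  check_number(zdelta, "zdelta", non_negative = TRUE)
  if (zdelta > 2) {
    abort_invalid("`zdelta` must lie in [0, 2].")
  }
  if (!is.na(blocker_conc)) {
    check_number(blocker_conc, "blocker_conc", non_negative = TRUE)
  }
  structure(list(kd0 = kd0, zdelta = zdelta, blocker_conc = blocker_conc),
            class = "woodhull_params")
}

as_woodhull_params <- function(x) {
  if (inherits(x, "woodhull_params")) {
    if (is.na(x$blocker_conc)) {
      abort_invalid("`blocker_conc` is NA; supply the bath concentration.")
    }
    return(x)
  }
  if (is.list(x) && all(c("kd0", "zdelta") %in% names(x))) {
    return(woodhull_params(x$kd0, x$zdelta, x$blocker_conc %||% NA_real_))
  }
  abort_invalid("`params` must be created with woodhull_params().")
}
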