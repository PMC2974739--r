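# ggplot2 displays for the main result types.

#' Plot a voltage-clamp trace
#'
#' Ramp sweeps are shown as current against command voltage; application
#' sweeps as current against time with solution segments shaded.
#'
#' @param object A `tevc_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tevc_trace <- function(object, ...) {
  md <- trace_metadata(object)
  if (identical(md$kind, "ramp")) {
    return(
      ggplot2::ggplot(object,
                      ggplot2::aes(x = .data$voltage_mV, y = .data$current_nA)) +
        ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
        ggplot2::geom_line() +
        ggplot2::labs(x = "Command voltage (mV)", y = "Current (nA)",
                      title = md$solution %||% NULL)
    )
  }
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$time_s, y = .data$current_nA)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Current (nA)")
  seg <- md$segments
  if (!is.null(seg)) {
    shade <- seg[seg$agonist != "none" | seg$mg_mM > 0, , drop = FALSE]
    if (nrow(shade)) {
      p <- p + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf, fill = .data$solution),
        alpha = 0.15, inherit.aes = FALSE
      )
    }
  }
  p
}

#' Plot an IV relation
#'
#' @param object An [iv_relation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_relation <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "normalized"))) {
    "Current (normalized to +20 mV)"
  } else {
    "Current (nA)"
  }
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$voltage_mV, y = .data$current_nA)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Voltage (mV)", y = ylab)
}

#' Plot a permeability analysis
#'
#' Group mean +/- SEM of the Ca2+/monovalent permeability ratio per
#' condition and agonist.
#'
#' @param object A `perm_analysis` from [analyze_permeability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.perm_analysis <- function(object, ...) {
  dat <- tidy(object)
  dat <- dat[dat$quantity == "p_ratio", , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$condition, y = .data$estimate,
                                    fill = .data$agonist)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$estimate - .data$std_error,
                   ymax = .data$estimate + .data$std_error),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "P(Ca2+)/P(mono)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
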