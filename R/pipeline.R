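# One reproducible run: simulate -> process -> permeability/block -> report,
# driven by the YAML experiment configuration. Every artifact is plain
# tab-separated text with units in the header, stamped with the
# configuration hash and seed in the run log.

condition_dir <- function(label) gsub("[^A-Za-z0-9]+", "_", label)

pipeline_solutions <- function(cfg) {
  default_solutions(
    glycine_um = cfg$agonists$glycine_uM %||% 10,
    glutamate_um = cfg$agonists$glutamate_uM %||% 100,
    mg_mm = cfg$blocker$mg_mM %||% 0.5
  )
}

pipeline_protocols <- function(cfg, solutions) {
  rp <- cfg$protocols$ramp %||% list()
  ap <- cfg$protocols$application %||% list()
  ramp <- ramp_protocol(
    v_from_mv = rp$v_from_mV %||% -150, v_to_mv = rp$v_to_mV %||% 50,
    duration_s = rp$duration_s %||% 2,
    sample_rate_hz = rp$sample_rate_hz %||% 1000
  )
  ca <- cfg$permeability$ca_mM %||% 4
  car <- sprintf("%d mM CaR", ca)
  app <- function(agonist_suffix) {
    mg_block_protocol(
      agonist_label = paste0("NFR + ", agonist_suffix),
      mg_label = paste0("NFR + ", agonist_suffix, " + Mg"),
      base_label = "NFR", solutions = solutions,
      pre_s = ap$pre_s %||% 10, seg_s = ap$segment_s %||% 20,
      post_s = ap$post_s %||% 10, hold_mv = ap$hold_mV %||% -70,
      sample_rate_hz = ap$sample_rate_hz %||% 100,
      exchange_tau_s = ap$exchange_tau_s %||% 1
    )
  }
  list(
    ramp_ctrl_before = list(protocol = ramp, solution = solutions[[car]]),
    ramp_gly = list(protocol = ramp,
                    solution = solutions[[paste0(car, " + glycine")]]),
    ramp_glu_gly = list(protocol = ramp,
                        solution = solutions[[paste0(car, " + glutamate/glycine")]]),
    ramp_ctrl_after = list(protocol = ramp, solution = solutions[[car]]),
    app_gly = list(protocol = app("glycine")),
    app_glu_gly = list(protocol = app("glutamate/glycine"))
  )
}

log_line <- function(out_dir, ...) {
  readr::write_lines(sprintf(...), file.path(out_dir, "run_log.txt"),
                     append = TRUE)
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path)) {
    abort_ordering(sprintf(
      "stage '%s' requires '%s'; run stage '%s' first.",
      needed_by, basename(path), stage
    ))
  }
}

#' Run the simulate / process / summarize pipeline
#'
#' Executes the requested stages in their canonical order on one experiment
#' configuration:
#' \describe{
#'   \item{simulate}{generate a batch of cells per condition (ramps in Ca2+
#'     Ringer's, agonist/Mg2+ applications in NFR) and write trace bundles.}
#'   \item{process}{read the bundles and reduce each cell to its measured
#'     quantities (response amplitudes, percent block, uncorrected reversal
#'     potentials), written as a long tab-separated measurement table.}
#'   \item{permeability}{junction-correct reversal potentials once, apply
#'     the batch calibration, and write the condition-level permeability
#'     table.}
#'   \item{block}{write the condition-level amplitude / percent-block
#'     table.}
#'   \item{report}{record completion; the run log carries the configuration
#'     hash, seed, and per-stage row counts throughout.}
#' }
#' Running a stage whose inputs have not been produced is an ordering error.
#' Identical configuration and seed give byte-identical result tables.
#'
#' @param config An `experiment_config` (from [read_experiment_config()]) or
#'   a path to a YAML configuration.
#' @param stages Subset of `c("simulate", "process", "permeability",
#'   "block", "report")`.
#' @param out_dir Output directory; defaults to the configuration's
#'   `output_dir`.
#' @param seed Root seed; defaults to the configuration's `seed`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "process", "permeability",
                                    "block", "report"),
                         out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  cfg <- validate_experiment_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- out_dir %||% cfg$output_dir %||% "biionic-run"
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  constants <- config_constants(cfg)
  oocyte <- config_oocyte(cfg)
  solutions <- pipeline_solutions(cfg)
  protocols <- pipeline_protocols(cfg, solutions)
  conditions <- cfg$condition_order %||% names(cfg$conditions)
  cfg_hash <- rlang::hash(unclass(cfg))
  paths <- list(
    traces = file.path(out_dir, "traces"),
    measurements = file.path(out_dir, "measurements.tsv"),
    permeability = file.path(out_dir, "permeability_table.tsv"),
    block = file.path(out_dir, "block_table.tsv"),
    log = file.path(out_dir, "run_log.txt")
  )

  if ("simulate" %in% stages) {
    for (k in seq_along(conditions)) {
      label <- conditions[k]
      batch <- generate_batch(
        list(channel = config_channel(cfg, label), oocyte = oocyte,
             protocols = protocols, constants = constants),
        n_cells = cfg$n_cells, seed = derive_seed(seed, sweep = k)
      )
      batch$trace <- purrr::map(batch$trace, function(tr) {
        md <- trace_metadata(tr)
        md$condition <- label
        attr(tr, "metadata") <- md
        tr
      })
      write_trace_bundle(batch, file.path(paths$traces, condition_dir(label)))
      log_line(out_dir, "stage=simulate config=%s seed=%d condition=%s sweeps=%d",
               cfg_hash, seed, label, nrow(batch))
    }
  }

  if ("process" %in% stages) {
    require_artifact(paths$traces, "simulate", "process")
    junction_declared <- oocyte$junction_potential_mv
    rows <- purrr::map(conditions, function(label) {
      bundle_dir <- file.path(paths$traces, condition_dir(label))
      require_artifact(bundle_dir, "simulate", "process")
      batch <- read_trace_bundle(bundle_dir)
      by_cell <- split(seq_len(nrow(batch)), batch$cell_id)
      purrr::map(names(by_cell), function(cell) {
        idx <- by_cell[[cell]]
        sw <- setNames(batch$trace[idx], batch$sweep[idx])
        meas <- list()
        for (ag in c("gly", "glu_gly")) {
          app <- sw[[paste0("app_", ag)]]
          if (!is.null(app)) {
            m <- application_measurements(app)
            meas <- c(meas, list(
              tibble::tibble(quantity = paste0("i_", ag),
                             value = m$i_response_nA, units = "nA"),
              tibble::tibble(quantity = paste0("block_", ag),
                             value = m$percent_block, units = "%")
            ))
          }
          agr <- sw[[paste0("ramp_", ag)]]
          if (!is.null(agr)) {
            iv <- subtract_background(ramp_to_iv(agr),
                                      ramp_to_iv(sw$ramp_ctrl_before),
                                      ramp_to_iv(sw$ramp_ctrl_after))
            erev <- tryCatch(
              as.numeric(estimate_reversal_potential(
                iv, window = cfg$permeability$window_mV %||% c(-120, 0)
              )),
              biionic_no_reversal = function(e) NA_real_
            )
            meas <- c(meas, list(
              tibble::tibble(quantity = paste0("erev_measured_", ag),
                             value = erev, units = "mV")
            ))
          }
        }
        out <- purrr::list_rbind(meas)
        out$condition <- label
        out$cell_id <- cell
        out
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
    measurements <- dplyr::select(rows, "condition", "cell_id", "quantity",
                                  "value", "units")
    readr::write_tsv(measurements, paths$measurements, progress = FALSE)
    log_line(out_dir, "stage=process config=%s seed=%d rows=%d junction_declared_mV=%g",
             cfg_hash, seed, nrow(measurements), junction_declared)
  }

  if (any(c("permeability", "block") %in% stages)) {
    require_artifact(paths$measurements, "process",
                     if ("permeability" %in% stages) "permeability" else "block")
    measurements <- readr::read_tsv(paths$measurements,
                                    show_col_types = FALSE, progress = FALSE)
  }

  if ("permeability" %in% stages) {
    per_cell <- measurements |>
      dplyr::filter(grepl("^erev_measured_", .data$quantity),
                    is.finite(.data$value)) |>
      dplyr::mutate(agonist = sub("^erev_measured_", "", .data$quantity)) |>
      dplyr::select("condition", "cell_id", "agonist", erev_measured = "value")
    # junction correction applied exactly once, here
    per_cell$erev_mV <- as.numeric(correct_junction_potential(
      per_cell$erev_measured, oocyte$junction_potential_mv
    ))
    fit <- analyze_permeability(
      dplyr::select(per_cell, "condition", "cell_id", "agonist", "erev_mV"),
      calibration = config_calibration(cfg, constants),
      ca_o = cfg$permeability$ca_mM %||% 4, constants = constants,
      conditions = conditions
    )
    readr::write_tsv(fit$table, paths$permeability, progress = FALSE)
    log_line(out_dir, "stage=permeability config=%s seed=%d rows=%d mono_i_mM=%g",
             cfg_hash, seed, nrow(fit$table), fit$calibration$mono_i)
  }

  if ("block" %in% stages) {
    per_cell <- measurements |>
      dplyr::filter(.data$quantity %in% c("i_gly", "i_glu_gly", "block_gly",
                                          "block_glu_gly")) |>
      tidyr::separate_wider_regex(
        "quantity", c(kind = "^(?:i|block)", "_", agonist = ".*$")
      ) |>
      tidyr::pivot_wider(names_from = "kind", values_from = "value",
                         id_cols = c("condition", "cell_id", "agonist")) |>
      dplyr::rename(i_response_nA = "i", percent_block = "block")
    tab <- build_block_table(per_cell, conditions = conditions)
    readr::write_tsv(tab, paths$block, progress = FALSE)
    log_line(out_dir, "stage=block config=%s seed=%d rows=%d", cfg_hash, seed,
             nrow(tab))
  }

  if ("report" %in% stages) {
    require_artifact(paths$permeability, "permeability", "report")
    require_artifact(paths$block, "block", "report")
    log_line(out_dir, "stage=report config=%s seed=%d status=complete",
             cfg_hash, seed)
  }

  invisible(paths)
}
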