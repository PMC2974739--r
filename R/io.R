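# On-disk formats: columnar sweep files with a YAML metadata sidecar per
# sweep, and the YAML experiment configuration. All numeric columns carry
# their unit in the header name; re-ingestion converts explicitly and never
# silently rescales.

TIME_COLS <- c(time_s = 1, time_ms = 1e-3)
VOLT_COLS <- c(voltage_mV = 1, command_mV = 1, voltage_V = 1e3)
CURR_COLS <- c(current_nA = 1, current_uA = 1e3, current_pA = 1e-3)

#' Write a batch of sweeps to a trace bundle
#'
#' One tab-separated file per sweep with unit-bearing column headers
#' (`time_s`, `voltage_mV`, `current_nA`) and a YAML sidecar of the same
#' stem carrying the sweep metadata (cell id, protocol kind, solution
#' labels, seed, segment table for applications).
#'
#' @param batch A `tevc_batch` tibble from [generate_batch()] (or any tibble
#'   with `cell_id`, `sweep`, and a `trace` list-column).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written sweep files.
#' @export
write_trace_bundle <- function(batch, dir) {
  if (!all(c("cell_id", "sweep", "trace") %in% names(batch))) {
    abort_invalid("`batch` needs columns `cell_id`, `sweep`, `trace`.")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(seq_len(nrow(batch)), function(i) {
    tr <- batch$trace[[i]]
    md <- trace_metadata(tr)
    stem <- sprintf("%s__%s", batch$cell_id[i], gsub("[^A-Za-z0-9_.-]+", "-",
                                                     batch$sweep[i]))
    data_path <- file.path(dir, paste0(stem, ".tsv"))
    readr::write_tsv(
      tibble::tibble(time_s = tr$time_s, voltage_mV = tr$voltage_mV,
                     current_nA = tr$current_nA),
      data_path, progress = FALSE
    )
    side <- md
    side$sweep <- batch$sweep[i]
    side$units <- list(time = "s", voltage = "mV", current = "nA")
    if (!is.null(side$segments)) {
      side$segments <- as.list(as.data.frame(side$segments))
    }
    yaml::write_yaml(side, file.path(dir, paste0(stem, ".yaml")))
    data_path
  })
  invisible(paths)
}

read_sweep_file <- function(data_path) {
  side_path <- sub("\\.tsv$", ".yaml", data_path)
  if (!file.exists(side_path)) {
    abort_format(sprintf("missing metadata sidecar for sweep file '%s'.",
                         basename(data_path)))
  }
  md <- yaml::read_yaml(side_path)
  # parsing problems are escalated to format errors below, so readr's own
  # warning is redundant
  dat <- tryCatch(
    suppressWarnings(
      readr::read_tsv(data_path, show_col_types = FALSE, progress = FALSE,
                      col_types = readr::cols(.default = readr::col_double()))
    ),
    error = function(e) abort_format(sprintf("cannot parse sweep file '%s': %s",
                                             basename(data_path),
                                             conditionMessage(e)))
  )
  probs <- readr::problems(dat)
  if (nrow(probs) > 0) {
    abort_format(sprintf(
      "malformed sweep file '%s' (first problem at line %d: %s).",
      basename(data_path), probs$row[1] + 1L, probs$expected[1]
    ))
  }
  pick <- function(known, what) {
    hit <- intersect(names(known), names(dat))
    if (length(hit) != 1L) {
      abort_format(sprintf(
        "sweep file '%s' must have exactly one %s column (one of: %s).",
        basename(data_path), what, paste(names(known), collapse = ", ")
      ))
    }
    dat[[hit]] * known[[hit]]
  }
  time_s <- pick(TIME_COLS, "time")
  volt <- pick(VOLT_COLS, "voltage")
  curr <- pick(CURR_COLS, "current")
  if (any(is.na(time_s)) || any(is.na(volt)) || any(is.na(curr))) {
    abort_format(sprintf("sweep file '%s' has missing values (truncated row?).",
                         basename(data_path)))
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    abort_format(sprintf("time is not strictly increasing in '%s'.",
                         basename(data_path)))
  }
  if (!is.null(md$segments)) {
    md$segments <- tibble::as_tibble(md$segments)
  }
  new_tevc_trace(time_s, volt, curr, metadata = md)
}

#' Read a trace bundle from disk
#'
#' Reads every `*.tsv` sweep in a directory written by
#' [write_trace_bundle()], enforcing the sidecar-and-units contract:
#' a missing sidecar, an unknown or ambiguous unit column, a truncated row,
#' or non-monotonic time is a format error naming the offending file.
#' Currents in uA or pA and time in ms are converted to the canonical
#' nA / s on ingestion.
#'
#' @param dir Directory containing sweep files and sidecars.
#' @return A `tevc_batch` tibble (`cell_id`, `sweep`, `seed`, `trace`).
#' @export
read_trace_bundle <- function(dir) {
  if (!dir.exists(dir)) {
    abort_format(sprintf("trace bundle directory '%s' does not exist.", dir))
  }
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (!length(files)) {
    abort_format(sprintf("no sweep files (*.tsv) found in '%s'.", dir))
  }
  rows <- purrr::map(files, function(f) {
    tr <- read_sweep_file(f)
    md <- trace_metadata(tr)
    tibble::tibble(
      cell_id = md$cell_id %||% NA_character_,
      sweep = md$sweep %||% sub("\\.tsv$", "", basename(f)),
      expression_scale = md$expression_scale %||% NA_real_,
      seed = md$seed %||% NA_integer_,
      trace = list(tr)
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("tevc_batch", class(out))
  out
}

#' Read and validate an experiment configuration
#'
#' The experiment configuration is a single YAML file describing physical
#' constants, the oocyte model, the calibration source, simulated sample
#' size, protocol timing, and the channel phenotype of each condition. A
#' bundled default reproducing the standard solutions (NFR, 4/8 mM CaR),
#' agonist concentrations (100 uM glutamate / 10 uM glycine), 0.5 mM Mg2+,
#' −70 mV hold, and 2-s ramps ships with the package.
#'
#' @param path Path to a YAML configuration; default the bundled one.
#' @return A validated config list of class `experiment_config`.
#' @export
read_experiment_config <- function(path = default_config_path()) {
  if (!file.exists(path)) {
    abort_config(sprintf("configuration file '%s' does not exist.", path))
  }
  validate_experiment_config(yaml::read_yaml(path))
}

#' @rdname read_experiment_config
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "biionic",
              mustWork = TRUE)
}

validate_experiment_config <- function(cfg) {
  for (field in c("conditions", "calibration", "n_cells")) {
    if (is.null(cfg[[field]])) {
      abort_config(sprintf("configuration is missing required field `%s`.",
                           field))
    }
  }
  cal <- cfg$calibration
  direct <- !is.null(cal$mono_i_mM)
  from_ref <- !is.null(cal$erev_ref_mV) && !is.null(cal$p_ref)
  if (direct == from_ref) {
    abort_config(
      "calibration must name exactly one source: mono_i_mM, or erev_ref_mV + p_ref."
    )
  }
  if (!length(cfg$conditions) || is.null(names(cfg$conditions))) {
    abort_config("`conditions` must be a named mapping of channel phenotypes.")
  }
  for (label in names(cfg$conditions)) {
    cc <- cfg$conditions[[label]]
    if (is.null(cc$pca_over_pmono) || is.null(cc$agonist_efficacy)) {
      abort_config(sprintf(
        "condition '%s' needs `pca_over_pmono` and `agonist_efficacy`.", label
      ))
    }
  }
  if (!is.null(cfg$condition_order)) {
    unknown <- setdiff(cfg$condition_order, names(cfg$conditions))
    if (length(unknown)) {
      abort_config(sprintf("condition_order names undefined condition(s): %s",
                           paste(unknown, collapse = ", ")))
    }
  }
  structure(cfg, class = c("experiment_config", "list"))
}

config_constants <- function(cfg) {
  phys_constants(temperature = cfg$constants$temperature_K %||% 293.15)
}

config_oocyte <- function(cfg) {
  oc <- cfg$oocyte %||% list()
  oocyte_model(
    leak_conductance_us = oc$leak_conductance_uS %||% 1,
    leak_reversal_mv = oc$leak_reversal_mV %||% -20,
    mono_i = oc$mono_i_mM %||% 89.4,
    expression_cv = oc$expression_cv %||% 0.5,
    noise_sd_na = oc$noise_sd_nA %||% 5,
    junction_potential_mv = oc$junction_potential_mV %||% -4.5,
    leak_mg_sensitivity = oc$leak_mg_sensitivity %||% 0,
    endogenous_fraction = oc$endogenous_fraction %||% 0
  )
}

config_channel <- function(cfg, label) {
  cc <- cfg$conditions[[label]]
  if (is.null(cc)) {
    abort_config(sprintf("undefined condition label: %s", label))
  }
  block <- if (!is.null(cc$block)) {
    woodhull_params(cc$block$kd0_mM, cc$block$zdelta)
  }
  channel_model(
    pca_over_pmono = cc$pca_over_pmono,
    gain = cc$gain %||% 500,
    agonist_efficacy = c(gly = cc$agonist_efficacy$gly,
                         glu_gly = cc$agonist_efficacy$glu_gly),
    block = block,
    desensitization_rate = cc$desensitization_rate %||% 0
  )
}

config_calibration <- function(cfg, constants) {
  cal <- cfg$calibration
  if (!is.null(cal$mono_i_mM)) {
    calibration_record(batch_id = cal$batch_id %||% "batch1",
                       mono_i = cal$mono_i_mM,
                       ca_o = cal$ca_o_mM %||% 4, constants = constants)
  } else {
    calibration_record(batch_id = cal$batch_id %||% "batch1",
                       erev_ref_mv = cal$erev_ref_mV, p_ref = cal$p_ref,
                       ca_o = cal$ca_o_mM %||% 4, constants = constants)
  }
}
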