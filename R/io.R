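## Flat key/value configuration files (YAML), deterministic CSV/JSON output.
## All files use the package's fixed units: mV, ms, uA/cm2, mS/cm2, uF/cm2,
## energies in J/cm2; numeric output is serialised at 12 significant digits.

membrane_keys <- c("C_m", "g_Na", "g_K", "g_l", "E_Na", "E_K", "E_l", "V_r",
                   "lambda_ATP", "e_charge", "N_A", "na_per_atp")
protocol_keys <- c("amplitude", "onset", "duration", "t_total", "dt")
emit_flags <- c("trace", "power", "summary", "sweep")

#' Assemble a run configuration
#'
#' @param membrane A [membrane_params()] object.
#' @param protocol A [stimulus_protocol()] object.
#' @param output Output directory for [write_run_outputs()].
#' @param emit Artifact flags, a subset of
#'   `c("trace", "power", "summary", "sweep")`.
#'
#' @return An object of class `run_config`.
#' @export
run_config <- function(membrane = membrane_params(),
                       protocol = stimulus_protocol(),
                       output = ".",
                       emit = c("trace", "power", "summary")) {
  check_params(membrane)
  check_protocol(protocol)
  if (!is.character(output) || length(output) != 1) {
    abort("output must be a single path", class = "hh_config_error")
  }
  emit <- unique(as.character(emit))
  bad <- setdiff(emit, emit_flags)
  if (length(bad) > 0) {
    abort(paste0("unknown emit flag(s): ", paste(bad, collapse = ", ")),
          class = "hh_config_error")
  }
  structure(list(membrane = membrane, protocol = protocol,
                 output = output, emit = emit),
            class = "run_config")
}

#' Canonical and degenerate example configurations
#'
#' Ready-made configurations for the package's reference operating points:
#' `"suprathreshold"` (3 uA/cm2 for 5 ms: fires one action potential),
#' `"subthreshold"` (2.5 uA/cm2 for 3 ms: a ~5 mV depolarisation that decays
#' without firing) and `"resting"` (no stimulus). All use the default
#' membrane and a 30 ms window at dt = 0.005 ms.
#'
#' @param name One of `"suprathreshold"`, `"subthreshold"`, `"resting"`.
#' @return A [run_config()].
#' @examples
#' fixture_config("subthreshold")$protocol
#' @export
fixture_config <- function(name = c("suprathreshold", "subthreshold", "resting")) {
  name <- match.arg(name)
  proto <- switch(name,
    suprathreshold = stimulus_protocol(amplitude = 3, duration = 5),
    subthreshold = stimulus_protocol(amplitude = 2.5, duration = 3),
    resting = stimulus_protocol(amplitude = 0, duration = 0)
  )
  run_config(protocol = proto)
}

#' Load a run configuration from a flat YAML file
#'
#' Keys are the field names of [membrane_params()] and
#' [stimulus_protocol()], plus `output` (a directory) and `emit` (a list of
#' artifact flags). Missing keys take the documented defaults; an empty file
#' yields the all-defaults configuration; unknown keys are an error, so
#' typos never pass silently.
#'
#' @param path Path to a YAML (or flat JSON) config file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "hh_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("cannot parse config file ", path, ": ", conditionMessage(e)),
          class = "hh_config_error", parent = e)
  })
  raw <- raw %||% list()
  if (!is.list(raw)) {
    abort("config must be a flat key/value mapping", class = "hh_config_error")
  }
  known <- c(membrane_keys, protocol_keys, "output", "emit")
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "hh_config_error")
  }
  membrane <- do.call(membrane_params, raw[intersect(names(raw), membrane_keys)])
  protocol <- do.call(stimulus_protocol, raw[intersect(names(raw), protocol_keys)])
  run_config(membrane = membrane, protocol = protocol,
             output = raw$output %||% ".",
             emit = unlist(raw$emit) %||% c("trace", "power", "summary"))
}

#' Write a run configuration as a flat YAML file
#'
#' Inverse of [load_run_config()]: `load_run_config(write_run_config(cfg, f))`
#' reproduces `cfg` exactly.
#'
#' @param config A [run_config()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (!inherits(config, "run_config")) {
    abort("`config` must be a run_config", class = "hh_config_error")
  }
  flat <- c(unclass(config$membrane), unclass(config$protocol),
            list(output = config$output, emit = as.list(config$emit)))
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

fmt12 <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 12, format = "g") else as.character(x)
}

#' Write the artifacts of one run to disk
#'
#' Emits, per the config's `emit` flags, a trace CSV (`trace.csv`; power
#' columns appended when `"power"` is requested) and a JSON summary
#' (`summary.json`) embedding the fully resolved parameter set, so every
#' output is self-describing. Files are deterministic: fixed column order,
#' 12-significant-digit formatting, and a units comment line, so re-running
#' the same configuration reproduces byte-identical files.
#'
#' @param run An `hh_run` from [run_experiment()].
#' @param dir Output directory (created if needed); defaults to `"."`.
#' @param emit Artifact flags (see [run_config()]).
#' @return Named character vector of the files written, invisibly.
#' @export
write_run_outputs <- function(run, dir = ".",
                              emit = c("trace", "power", "summary")) {
  if (!inherits(run, "hh_run")) {
    abort("`run` must be an hh_run", class = "hh_invalid_input")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character()

  if ("trace" %in% emit) {
    df <- as.data.frame(run$trace)
    if ("power" %in% emit) {
      df <- cbind(df, as.data.frame(run$power)[, c("p_Na", "p_K", "p_l", "p_stim", "p_total")])
    }
    out <- as.data.frame(lapply(df, fmt12), stringsAsFactors = FALSE)
    names(out) <- names(df)
    path <- file.path(dir, "trace.csv")
    readr::write_lines(
      "# units: t ms; V_m mV; n,m,h dimensionless; i_* uA/cm2; p_* nW/cm2",
      path)
    readr::write_csv(out, path, append = TRUE, col_names = TRUE)
    written["trace"] <- path
  }

  if ("summary" %in% emit) {
    path <- file.path(dir, "summary.json")
    payload <- list(
      membrane = unclass(run$params),
      protocol = unclass(run$protocol),
      results = as.list(glance(run)),
      spike_times = run$spikes$time,
      units = list(charge = "C/cm2", energy = "J/cm2", eta = "percent",
                   psi = "degrees")
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE, null = "null")
    written["summary"] <- path
  }

  invisible(written)
}

#' Write a sweep result as CSV plus JSON summary
#'
#' @param sweep An `hh_sweep` from [sweep_stimulus()].
#' @param dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
write_sweep_outputs <- function(sweep, dir = ".") {
  if (!inherits(sweep, "hh_sweep")) {
    abort("`sweep` must be an hh_sweep", class = "hh_invalid_input")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  df <- as.data.frame(sweep)
  out <- as.data.frame(lapply(df, fmt12), stringsAsFactors = FALSE)
  csv <- file.path(dir, "sweep.csv")
  readr::write_csv(out, csv)
  js <- file.path(dir, "sweep.json")
  ti <- threshold_index(sweep)
  jsonlite::write_json(
    list(varied = attr(sweep, "varied"),
         threshold_index = if (is.na(ti)) NULL else ti,
         threshold_value = if (is.na(ti)) NULL else sweep$value[ti],
         n = nrow(sweep)),
    js, auto_unbox = TRUE, digits = 12, pretty = TRUE, null = "null")
  invisible(c(csv = csv, json = js))
}
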