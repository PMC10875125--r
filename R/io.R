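# Configuration round-trip, result serialization and run manifests.

#' Write a model configuration
#'
#' Flat key-value serialization (YAML or JSON) of kinetic parameters,
#' controlled species and geometry under their ASCII symbol names. Units
#' follow the package convention (mM, uM for Ca2+/IP3 pools, mV, s).
#'
#' @inheritParams validate_model_inputs
#' @param path output path; format from extension (`.yaml`/`.yml`/`.json`)
#' @return invisibly `path`.
#' @export
write_model_config <- function(path, p = mito_parameters(),
                               ctrl = mito_controls(),
                               geom = mito_geometry()) {
  cfg <- list(parameters = unclass(p), controls = unclass(ctrl),
              geometry = unclass(geom))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 17)
  }
  invisible(path)
}

#' Read a model configuration
#'
#' Inverse of [write_model_config()]. Unknown keys are rejected with the
#' offending names; missing keys fall back to reference values.
#'
#' @param path configuration file (YAML or JSON)
#' @return list with `p`, `ctrl`, `geom`.
#' @export
read_model_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (part in c("parameters", "controls", "geometry")) {
    if (!is.null(cfg[[part]]) && !is.list(cfg[[part]])) {
      stop("config section `", part, "` is not a key-value map", call. = FALSE)
    }
  }
  list(
    p = do.call(mito_parameters, cfg$parameters %||% list()),
    ctrl = do.call(mito_controls, cfg$controls %||% list()),
    geom = do.call(mito_geometry, cfg$geometry %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory as CSV with a JSON manifest
#'
#' One row per time point (state and flux columns); the sidecar manifest
#' records solver settings, parameter/control values and the package
#' version, sufficient to re-execute the run.
#'
#' @param traj a `mito_trajectory`
#' @param path CSV path; the manifest goes to `<path>.manifest.json`
#' @param seed optional seed to record
#' @return invisibly `path`.
#' @export
export_trajectory_csv <- function(traj, path, seed = NULL) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  man <- list(
    kind = "trajectory",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("camito")),
    solver = attr(traj, "solver"),
    parameters = unclass(attr(traj, "p")),
    controls = unclass(attr(traj, "ctrl")),
    geometry = unclass(attr(traj, "geom")),
    seed = seed,
    n_rows = nrow(traj),
    t_range = range(traj$time)
  )
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a scan as CSV with a JSON manifest
#'
#' One row per grid point including regime, oscillation metrics and the
#' full work ledger; bifurcation brackets are embedded in the manifest.
#'
#' @param scan a `mito_scan`
#' @param path CSV path; manifest at `<path>.manifest.json`
#' @param seed optional seed to record
#' @return invisibly `path`.
#' @export
export_scan_csv <- function(scan, path, seed = NULL) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  man <- list(
    kind = "scan",
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package_version = as.character(utils::packageVersion("camito")),
    parameter = scan$param[1],
    grid = scan$value,
    bifurcations = as.data.frame(attr(scan, "bifurcations")),
    parameters = unclass(attr(scan, "p")),
    controls = unclass(attr(scan, "ctrl")),
    seed = seed
  )
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
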