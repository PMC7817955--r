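#' Station processing configuration
#'
#' Collects every tunable of the processing chain with defaults equal to the
#' station's operating values: 0.006 deg angular step over an 87 x 151 deg
#' window (vertical span centred on the horizon), 138 m maximum range,
#' 0.10 m voxel edge, isolated-point filter of 3 neighbours within 5 cm,
#' 5 mm subsampling, weather gate of 3 m/s wind and 0 mm precipitation over
#' a 21-minute scan, and cluster tracking with 100-point minimum size and
#' 0.15 m maximum diameter. Override any field via `...` or load overrides
#' from a YAML/JSON `file`.
#'
#' @param ... named overrides of default fields.
#' @param file optional YAML (or JSON) file of overrides.
#' @return object of class `station_config` (a validated named list).
#' @export
station_config <- function(..., file = NULL) {
  cfg <- list(
    alpha = 0.006,
    theta_min = 46.5, theta_max = 133.5,   # 87 deg vertical window
    phi_min = 0, phi_max = 151,            # 151 deg horizontal window
    max_range = 138,
    scan_duration_min = 21,
    filter_radius = 0.05, filter_min_neighbors = 3L,
    subsample_d_min = 0.005,
    gate_wind_limit = 3, gate_precip_limit = 0, gate_stat = "max",
    voxel_edge = 0.10,
    dbh_center = 1.3, dbh_tol = 0.30, dbh_inlier_tol = 0.01,
    dbh_iterations = 2000L,
    tracker_min_size = 100L, tracker_max_diameter = 0.15,
    quicklook_low = 5, quicklook_high = 139,
    rng_seed = 1L)
  if (!is.null(file)) {
    overrides <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(file)
    }
    cfg[names(overrides)] <- overrides
  }
  dots <- list(...)
  if (length(dots) > 0L) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown config field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "station_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$alpha > 0, cfg$theta_max > cfg$theta_min,
            cfg$phi_max > cfg$phi_min, cfg$max_range > 0,
            cfg$filter_radius > 0, cfg$filter_min_neighbors >= 1,
            cfg$subsample_d_min > 0, cfg$gate_wind_limit > 0,
            cfg$voxel_edge > 0, cfg$dbh_tol > 0,
            cfg$tracker_min_size >= 1, cfg$tracker_max_diameter > 0)
  invisible(cfg)
}

#' Raster geometry of a station configuration
#' @param config a [station_config()].
#' @return the corresponding [raster_geometry()].
#' @export
config_geometry <- function(config) {
  raster_geometry(config$alpha, config$theta_min, config$theta_max,
                  config$phi_min, config$phi_max)
}

#' @export
print.station_config <- function(x, ...) {
  cat("station_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm,
                                   paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# stable hash of a config for provenance blocks
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(js, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
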