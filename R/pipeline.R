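#' Run the daily processing workflow over a scan project
#'
#' The station's per-day pre-processing chain: for every scan of the project
#' — ingest (CSV table or LAS), enrich with spherical/raster attributes,
#' write the analysis-ready LAS, rasterize range/reflectance/deviation
#' stacks to TIFF, and (when the project carries a weather file) compute the
#' scan's calm-weather quality flag. Products and their MD5 checksums are
#' listed in a JSON manifest; re-runs skip scans whose products already
#' exist and verify, so completed projects are idempotent. A failing scan is
#' logged in the manifest as `failed` and does not abort the project.
#'
#' @param project a [scan_project()].
#' @param config a [station_config()].
#' @param out_dir output directory (created; one subdirectory per day).
#' @return the manifest (list), invisibly written to `manifest.json`.
#' @export
run_daily <- function(project, config = station_config(), out_dir) {
  stopifnot(inherits(project, "scan_project"),
            inherits(config, "station_config"))
  day_dir <- file.path(out_dir, format(project$date))
  dir.create(day_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- config_geometry(config)
  log_path <- file.path(day_dir, "processing.jsonl")

  weather <- if (!is.null(project$weather_file)) {
    read_weather(project$weather_file)
  } else {
    NULL
  }

  manifest_path <- file.path(day_dir, "manifest.json")
  old <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    NULL
  }

  entries <- vector("list", length(project$scan_files))
  for (i in seq_along(project$scan_files)) {
    src <- project$scan_files[i]
    stamp <- format(project$timestamps[i], "%H%M")
    products <- c(
      las = file.path(day_dir, paste0(stamp, ".las")),
      range = file.path(day_dir, paste0(stamp, "_range.tif")),
      reflectance = file.path(day_dir, paste0(stamp, "_reflectance.tif")),
      deviation = file.path(day_dir, paste0(stamp, "_deviation.tif")))
    prev <- find_manifest_entry(old, src)
    if (!is.null(prev) && identical(prev$status, "ok") &&
        all(file.exists(products))) {
      prev$skipped <- TRUE
      entries[[i]] <- prev
      next
    }
    entries[[i]] <- tryCatch({
      cloud <- if (grepl("\\.las$", src, ignore.case = TRUE)) {
        read_las(src)
      } else {
        ingest_table(src)
      }
      if (is.null(cloud$timestamp)) cloud$timestamp <- project$timestamps[i]
      cloud <- enrich(cloud, geom)
      write_las(cloud, products["las"])
      for (attr_name in c("range", "reflectance", "deviation")) {
        if (attr_name %in% names(cloud$points)) {
          stk <- rasterize(cloud, geom, attribute = attr_name)
          write_tiff(stk, products[[attr_name]])
        }
      }
      flag <- NULL
      if (!is.null(weather)) {
        flags <- gate_scans(weather, project$timestamps[i],
                            duration = config$scan_duration_min,
                            wind_limit = config$gate_wind_limit,
                            precip_limit = config$gate_precip_limit,
                            stat = config$gate_stat)
        flag <- list(passed = flags$passed[1], wind_max = flags$wind_max[1],
                     precip_total_mm = flags$precip_total_mm[1])
      }
      append_log(log_path, list(event = "scan_processed", source = src,
                                points = npoints(cloud)))
      existing <- products[file.exists(products)]
      list(source = src, timestamp = format(project$timestamps[i]),
           status = "ok", points = npoints(cloud),
           products = as.list(existing),
           checksums = as.list(unname(tools::md5sum(existing))),
           quality = flag, skipped = FALSE)
    }, error = function(e) {
      append_log(log_path, list(event = "scan_failed", source = src,
                                error = conditionMessage(e)))
      list(source = src, timestamp = format(project$timestamps[i]),
           status = "failed", error = conditionMessage(e), skipped = FALSE)
    })
  }

  manifest <- list(date = format(project$date),
                   config_hash = config_hash(config),
                   n_scans = length(entries),
                   n_failed = sum(vapply(entries, function(e)
                     identical(e$status, "failed"), logical(1))),
                   scans = entries)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

find_manifest_entry <- function(manifest, src) {
  if (is.null(manifest)) return(NULL)
  for (e in manifest$scans) {
    if (identical(e$source, src)) return(e)
  }
  NULL
}

append_log <- function(path, record) {
  line <- jsonlite::toJSON(c(list(time = format(Sys.time(), usetz = TRUE)),
                             record), auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = path, append = TRUE)
}

#' Run a forest-dynamics analysis on enriched scans
#'
#' Dispatches to the analysis modules with the configuration's parameters
#' and writes CSV/JSON products plus a provenance block (config hash, seed):
#' \describe{
#'   \item{`voxel-diff`}{two inputs; voxelizes both on a shared origin and
#'     writes the [compare_epochs()] summary.}
#'   \item{`dbh`}{one input per epoch plus `dates`; writes the
#'     [fit_dbh_series()] CSV.}
#'   \item{`track`}{a time-ordered scan sequence; cleans each scan, seeds
#'     clusters on the first, and writes the [displacement_series()] CSV.}
#' }
#'
#' @param kind `"voxel-diff"`, `"dbh"` or `"track"`.
#' @param inputs list of [scan_cloud()]s (or file paths to LAS/CSV scans).
#' @param config a [station_config()].
#' @param out_dir output directory.
#' @param dates epoch dates for `"dbh"`.
#' @return the analysis result object, invisibly; products land in
#'   `out_dir`.
#' @export
run_analysis <- function(kind, inputs, config = station_config(), out_dir,
                         dates = NULL) {
  kinds <- c("voxel-diff", "dbh", "track")
  if (!kind %in% kinds) {
    stop("unknown analysis kind '", kind, "' (use ",
         paste(kinds, collapse = ", "), ")", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  clouds <- lapply(inputs, function(x) {
    if (inherits(x, "scan_cloud")) return(x)
    if (grepl("\\.las$", x, ignore.case = TRUE)) read_las(x) else
      ingest_table(x)
  })
  provenance <- list(kind = kind, config_hash = config_hash(config),
                     rng_seed = config$rng_seed,
                     n_inputs = length(clouds))

  result <- switch(
    kind,
    "voxel-diff" = {
      stopifnot(length(clouds) == 2L)
      org <- voxel_origin(clouds[[1]], clouds[[2]],
                          edge = config$voxel_edge)
      ga <- voxelize(clouds[[1]], edge = config$voxel_edge, origin = org)
      gb <- voxelize(clouds[[2]], edge = config$voxel_edge, origin = org)
      summary <- compare_epochs(ga, gb)
      jsonlite::write_json(unclass(summary),
                           file.path(out_dir, "voxel_diff.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      summary
    },
    "dbh" = {
      if (is.null(dates)) dates <- seq_along(clouds)
      series <- fit_dbh_series(clouds, dates, seed = config$rng_seed,
                               inlier_tol = config$dbh_inlier_tol,
                               iterations = config$dbh_iterations)
      utils::write.csv(as.data.frame(series),
                       file.path(out_dir, "dbh_series.csv"),
                       row.names = FALSE)
      series
    },
    "track" = {
      cleaned <- lapply(clouds, function(cl) {
        clean_scan(cl, radius = config$filter_radius,
                   min_neighbors = config$filter_min_neighbors,
                   d_min = config$subsample_d_min)$cloud
      })
      model <- seed_clusters(cleaned[[1]],
                             min_size = config$tracker_min_size,
                             max_diameter = config$tracker_max_diameter,
                             rng_seed = config$rng_seed)
      labels <- propagate_labels(model, cleaned[-1])
      series <- displacement_series(cleaned, labels)
      write_displacement_csv(series,
                             file.path(out_dir, "displacements.csv"))
      series
    })

  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
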