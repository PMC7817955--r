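#' Construct a scan cloud
#'
#' A `scan_cloud` is the package's point-cloud container: a list holding a
#' data frame of per-point attributes plus the acquisition timestamp and scan
#' metadata. Mandatory columns are `X`, `Y`, `Z` (metres, scanner-centric
#' frame). Recognised optional columns: `return_number`,
#' `number_of_returns` (1--15), `intensity` (normalized 0--1), `reflectance`
#' (dB), `deviation` (pulse-shape figure), `range` (m), `theta`, `phi`
#' (degrees), `row`, `col` (0-based pixel indices), `in_window` (logical),
#' `gps_time` (s).
#'
#' @param points data frame of per-point attributes with at least X, Y, Z.
#' @param timestamp scan acquisition time (`POSIXct`), optional.
#' @param meta named list of scan metadata (scanner id, config hash, ...).
#' @return object of class `scan_cloud`.
#' @export
scan_cloud <- function(points, timestamp = NULL, meta = list()) {
  points <- as.data.frame(points)
  missing <- setdiff(c("X", "Y", "Z"), names(points))
  if (length(missing) > 0L) {
    stop("missing coordinate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lens <- vapply(points, length, integer(1))
  if (length(unique(lens)) > 1L) {
    stop("per-point arrays differ in length", call. = FALSE)
  }
  if (all(c("return_number", "number_of_returns") %in% names(points)) &&
      nrow(points) > 0L &&
      any(points$return_number > points$number_of_returns, na.rm = TRUE)) {
    stop("return_number exceeds number_of_returns", call. = FALSE)
  }
  structure(list(points = points, timestamp = timestamp, meta = meta),
            class = "scan_cloud")
}

#' @export
print.scan_cloud <- function(x, ...) {
  cat(sprintf("scan_cloud: %d points, %d attributes", nrow(x$points),
              ncol(x$points)))
  if (!is.null(x$timestamp)) cat(", ", format(x$timestamp, usetz = TRUE))
  cat("\n columns:", paste(names(x$points), collapse = ", "), "\n")
  invisible(x)
}

#' Number of points in a scan cloud
#' @param cloud a [scan_cloud()].
#' @return integer point count.
#' @export
npoints <- function(cloud) {
  stopifnot(inherits(cloud, "scan_cloud"))
  nrow(cloud$points)
}

#' Enrich a scan cloud with spherical and raster attributes
#'
#' Computes, from the Cartesian coordinates, the derived per-point columns
#' the station's analysis-ready products carry: `range`, `theta`, `phi` (via
#' [spherical_from_cartesian()]) and the 0-based raster indices `row`, `col`
#' (via [pixel_of()]). Points outside the angular window are flagged in the
#' logical `in_window` column and retained. Enrichment is idempotent: the
#' derived columns are recomputed from X, Y, Z each call.
#'
#' @param cloud a [scan_cloud()] with at least X, Y, Z.
#' @param geom a [raster_geometry()] defining the fixed scan window.
#' @param tol_pixels border tolerance passed to [pixel_of()].
#' @return the enriched `scan_cloud`.
#' @export
enrich <- function(cloud, geom, tol_pixels = 0) {
  stopifnot(inherits(cloud, "scan_cloud"), inherits(geom, "raster_geometry"))
  p <- cloud$points
  if (nrow(p) == 0L) {
    for (nm in c("range", "theta", "phi")) p[[nm]] <- numeric(0)
    for (nm in c("row", "col")) p[[nm]] <- integer(0)
    p$in_window <- logical(0)
    cloud$points <- p
    return(cloud)
  }
  sph <- spherical_from_cartesian(p[, c("X", "Y", "Z")])
  px <- pixel_of(sph$theta, sph$phi, geom, tol_pixels = tol_pixels)
  p$range <- sph$rho
  p$theta <- sph$theta
  p$phi <- sph$phi
  p$row <- px$row
  p$col <- px$col
  p$in_window <- px$inside
  cloud$points <- p
  cloud$meta$geometry <- unclass(geom)
  cloud
}

#' Delineate a scan cloud by coordinate, range and angle thresholds
#'
#' Keeps the points satisfying the conjunction of all supplied predicates
#' (each a length-2 `c(min, max)` closed interval). Used to cut individual
#' trees out of a full scan, mirroring a manually optimized bounding box.
#' Point order is preserved; an empty result triggers a warning, not an
#' error.
#'
#' @param cloud a [scan_cloud()].
#' @param xlim,ylim,zlim,range_lim,theta_lim,phi_lim optional `c(min, max)`
#'   intervals in metres / degrees.
#' @return the filtered `scan_cloud` (metadata notes the selection count).
#' @export
delineate <- function(cloud, xlim = NULL, ylim = NULL, zlim = NULL,
                      range_lim = NULL, theta_lim = NULL, phi_lim = NULL) {
  stopifnot(inherits(cloud, "scan_cloud"))
  lims <- list(X = xlim, Y = ylim, Z = zlim, range = range_lim,
               theta = theta_lim, phi = phi_lim)
  lims <- Filter(Negate(is.null), lims)
  if (length(lims) == 0L) stop("at least one threshold required", call. = FALSE)
  p <- cloud$points
  keep <- rep(TRUE, nrow(p))
  for (nm in names(lims)) {
    if (!nm %in% names(p)) {
      stop("column '", nm, "' absent from cloud (enrich first?)",
           call. = FALSE)
    }
    lim <- lims[[nm]]
    stopifnot(length(lim) == 2L)
    keep <- keep & p[[nm]] >= lim[1] & p[[nm]] <= lim[2]
  }
  if (nrow(p) > 0L && !any(keep)) {
    warning("delineation selected no points", call. = FALSE)
  }
  cloud$points <- p[keep, , drop = FALSE]
  rownames(cloud$points) <- NULL
  cloud$meta$delineation <- list(kept = sum(keep), of = length(keep))
  cloud
}

#' Verify a file copy
#'
#' Confirms that a copy succeeded by comparing byte sizes, and (by default)
#' MD5 checksums as a stronger guarantee than the station's plain size
#' comparison.
#'
#' @param src,dst file paths; both must exist.
#' @param checksum compare MD5 checksums as well (default `TRUE`).
#' @return `TRUE` iff sizes (and checksums, when enabled) agree.
#' @export
verify_copy <- function(src, dst, checksum = TRUE) {
  for (f in c(src, dst)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  if (file.info(src)$size != file.info(dst)$size) return(FALSE)
  if (checksum) {
    sums <- tools::md5sum(c(src, dst))
    return(unname(sums[1]) == unname(sums[2]))
  }
  TRUE
}

#' Ingest a tabular scan into a scan cloud
#'
#' Reads a plain-text point table (CSV, or any delimited file readable by
#' `utils::read.csv`) with at least X, Y, Z columns — the simulator's text
#' output format — into a [scan_cloud()].
#'
#' @param path CSV file path, or a data frame.
#' @param timestamp scan acquisition time, optional; when `NULL` and `path`
#'   follows the daily-project naming `YYYY-MM-DD/HHMM.*`, the timestamp is
#'   parsed from the path.
#' @param meta metadata list.
#' @return a `scan_cloud`.
#' @export
ingest_table <- function(path, timestamp = NULL, meta = list()) {
  if (is.character(path)) {
    if (is.null(timestamp)) timestamp <- timestamp_from_path(path)
    points <- utils::read.csv(path)
  } else {
    points <- path
  }
  scan_cloud(points, timestamp = timestamp, meta = meta)
}

# parse 'YYYY-MM-DD/HHMM.ext' into POSIXct (UTC); NULL when not matching
timestamp_from_path <- function(path) {
  day <- basename(dirname(path))
  hm <- sub("\\..*$", "", basename(path))
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", day) && grepl("^\\d{4}$", hm)) {
    return(as.POSIXct(paste0(day, " ", substr(hm, 1, 2), ":",
                             substr(hm, 3, 4), ":00"), tz = "UTC"))
  }
  NULL
}

#' Assemble a daily scan project
#'
#' The station initializes one data-collection project per calendar day;
#' scans live under `YYYY-MM-DD/HHMM.<ext>` and are paired with that day's
#' weather file. This constructor validates the convention.
#'
#' @param date project day (`Date` or `YYYY-MM-DD` string).
#' @param scan_files character vector of scan file paths.
#' @param weather_file optional path to the day's weather CSV.
#' @return object of class `scan_project` with files ordered by timestamp.
#' @export
scan_project <- function(date, scan_files, weather_file = NULL) {
  date <- as.Date(date)
  ts <- lapply(scan_files, timestamp_from_path)
  if (any(vapply(ts, is.null, logical(1)))) {
    stop("scan files must follow the YYYY-MM-DD/HHMM.<ext> convention",
         call. = FALSE)
  }
  ts <- as.POSIXct(unlist(lapply(ts, as.numeric)), origin = "1970-01-01",
                   tz = "UTC")
  if (any(as.Date(ts) != date)) {
    stop("scan timestamps fall outside project day ", format(date),
         call. = FALSE)
  }
  o <- order(ts)
  ts <- ts[o]
  scan_files <- scan_files[o]
  if (any(duplicated(ts))) {
    stop("scan timestamps must be strictly increasing", call. = FALSE)
  }
  structure(list(date = date, scan_files = scan_files, timestamps = ts,
                 weather_file = weather_file),
            class = "scan_project")
}

#' @export
print.scan_project <- function(x, ...) {
  cat(sprintf("scan_project %s: %d scans%s\n", format(x$date),
              length(x$scan_files),
              if (is.null(x$weather_file)) "" else ", weather attached"))
  invisible(x)
}
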