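#' Remove isolated points
#'
#' The short-term monitoring noise filter: a point is kept iff at least
#' `min_neighbors` *other* points lie within `radius` of it (3-D Euclidean).
#' The defaults are the station's settings: at least 3 neighbours within a
#' 5 cm neighbourhood. The query point is not counted as its own neighbour
#' (a fully isolated point trivially contains itself, which would defeat the
#' filter); set `count_self = TRUE` for the self-inclusive reading.
#'
#' @param cloud a [scan_cloud()].
#' @param radius neighbourhood radius in metres (default 0.05).
#' @param min_neighbors minimum neighbour count (default 3).
#' @param count_self count the point itself as a neighbour (default `FALSE`).
#' @return list with `cloud` (filtered, order preserved) and `report`
#'   (a `filter_report`).
#' @export
remove_isolated <- function(cloud, radius = 0.05, min_neighbors = 3L,
                            count_self = FALSE) {
  stopifnot(inherits(cloud, "scan_cloud"), radius > 0)
  p <- cloud$points
  n_in <- nrow(p)
  if (n_in == 0L) {
    return(list(cloud = cloud,
                report = filter_report("remove_isolated", 0L, 0L,
                                       list(radius = radius,
                                            min_neighbors = min_neighbors))))
  }
  counts <- cpp_count_within(as_xyz_matrix(p[, c("X", "Y", "Z")]), radius)
  if (count_self) counts <- counts + 1L
  keep <- counts >= min_neighbors
  cloud$points <- p[keep, , drop = FALSE]
  rownames(cloud$points) <- NULL
  list(cloud = cloud,
       report = filter_report("remove_isolated", n_in, sum(keep),
                              list(radius = radius,
                                   min_neighbors = min_neighbors,
                                   count_self = count_self)))
}

#' Minimum-distance subsampling
#'
#' Greedy sequential thinning used to homogenize point density before
#' cluster tracking: scanning points in a deterministic order, a point is
#' kept iff it lies at least `d_min` from every previously kept point, so
#' the output's minimum pairwise distance is >= `d_min`. The default 5 mm is
#' the station's setting. The result depends on scan order; for
#' reproducibility the cloud is first sorted by (`row`, `col`) when those
#' raster indices are present, otherwise the stored order is used.
#'
#' @param cloud a [scan_cloud()].
#' @param d_min minimum spacing in metres (default 0.005).
#' @param sort_by_pixel sort by (row, col) before the greedy pass when the
#'   columns exist (default `TRUE`).
#' @return list with `cloud` and `report` as in [remove_isolated()].
#' @export
subsample_min_distance <- function(cloud, d_min = 0.005,
                                   sort_by_pixel = TRUE) {
  stopifnot(inherits(cloud, "scan_cloud"), d_min > 0)
  p <- cloud$points
  n_in <- nrow(p)
  if (n_in == 0L) {
    return(list(cloud = cloud,
                report = filter_report("subsample_min_distance", 0L, 0L,
                                       list(d_min = d_min))))
  }
  if (sort_by_pixel && all(c("row", "col") %in% names(p))) {
    o <- order(p$row, p$col)
    p <- p[o, , drop = FALSE]
  }
  keep <- cpp_greedy_subsample(as_xyz_matrix(p[, c("X", "Y", "Z")]), d_min)
  cloud$points <- p[keep, , drop = FALSE]
  rownames(cloud$points) <- NULL
  list(cloud = cloud,
       report = filter_report("subsample_min_distance", n_in, sum(keep),
                              list(d_min = d_min)))
}

#' Filter report
#'
#' Logging record for one cleanup step: counts in/out, removal count and the
#' parameters used. Serialized to the JSON-lines processing log by the
#' pipeline.
#'
#' @param filter filter name.
#' @param points_in,points_out point counts before/after.
#' @param parameters named list of filter parameters.
#' @return object of class `filter_report`.
#' @export
filter_report <- function(filter, points_in, points_out, parameters) {
  stopifnot(points_out <= points_in)
  structure(list(filter = filter,
                 points_in = as.integer(points_in),
                 points_out = as.integer(points_out),
                 removed = as.integer(points_in - points_out),
                 parameters = parameters),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s: %d -> %d points (removed %d)\n", x$filter, x$points_in,
              x$points_out, x$removed))
  invisible(x)
}

#' Standard cleanup chain for short-term monitoring
#'
#' Applies [remove_isolated()] then [subsample_min_distance()] with the
#' station defaults and returns the cleaned cloud plus both reports.
#'
#' @param cloud a [scan_cloud()].
#' @param radius,min_neighbors isolated-point filter parameters.
#' @param d_min subsampling minimum spacing.
#' @return list with `cloud` and `reports` (list of `filter_report`s).
#' @export
clean_scan <- function(cloud, radius = 0.05, min_neighbors = 3L,
                       d_min = 0.005) {
  a <- remove_isolated(cloud, radius = radius, min_neighbors = min_neighbors)
  b <- subsample_min_distance(a$cloud, d_min = d_min)
  list(cloud = b$cloud, reports = list(a$report, b$report))
}
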