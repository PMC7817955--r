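#' Voxelize a scan cloud
#'
#' Bins points into a cubic grid with the given edge length: voxel index
#' `(i, j, k) = floor((coordinate - origin)/edge)` per axis. The station's
#' crown-densification analysis uses a 0.10 m voxel. Counts conserve the
#' total number of points.
#'
#' @param cloud a [scan_cloud()] (or a data frame / matrix of XYZ).
#' @param edge voxel edge length in metres (default 0.10).
#' @param origin grid origin, length-3 numeric. Defaults to the floor of the
#'   cloud's bounding-box minimum snapped to an edge multiple; pass a shared
#'   origin (see [voxel_origin()]) when grids are to be compared.
#' @return object of class `voxel_grid`: data frame `voxels` with integer
#'   `i`, `j`, `k` and `count`, plus `edge`, `origin`, `total_points`.
#' @export
voxelize <- function(cloud, edge = 0.10, origin = NULL) {
  stopifnot(edge > 0)
  xyz <- if (inherits(cloud, "scan_cloud")) {
    as_xyz_matrix(cloud$points[, c("X", "Y", "Z")])
  } else {
    as_xyz_matrix(cloud)
  }
  if (is.null(origin)) origin <- voxel_origin(xyz, edge)
  stopifnot(length(origin) == 3L)
  if (nrow(xyz) == 0L) {
    vox <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      count = integer(0))
    return(structure(list(voxels = vox, edge = edge, origin = origin,
                          total_points = 0L), class = "voxel_grid"))
  }
  ijk <- floor(sweep(sweep(xyz, 2, origin), 2, edge, "/"))
  key <- paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ":")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  vox <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                    k = as.integer(parts[, 3]),
                    count = as.integer(tab))
  rownames(vox) <- NULL
  structure(list(voxels = vox, edge = edge, origin = as.numeric(origin),
                 total_points = nrow(xyz)),
            class = "voxel_grid")
}

#' Shared voxel-grid origin for a set of clouds
#'
#' Grid anchor for epoch comparison: the floor of the union bounding-box
#' minimum, snapped down to an edge multiple, so that compared grids bin
#' identically.
#'
#' @param ... scan clouds, data frames or XYZ matrices.
#' @param edge voxel edge length in metres.
#' @return length-3 numeric origin.
#' @export
voxel_origin <- function(..., edge = 0.10) {
  args <- list(...)
  mins <- sapply(args, function(a) {
    xyz <- if (inherits(a, "scan_cloud")) {
      as_xyz_matrix(a$points[, c("X", "Y", "Z")])
    } else {
      as_xyz_matrix(a)
    }
    if (nrow(xyz) == 0L) rep(Inf, 3) else apply(xyz, 2, min)
  })
  m <- apply(matrix(mins, nrow = 3), 1, min)
  floor(m / edge) * edge
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel_grid: %d occupied voxels (edge %g m), %d points\n",
              nrow(x$voxels), x$edge, x$total_points))
  invisible(x)
}

#' Construct a voxel grid from explicit counts
#'
#' Builds a `voxel_grid` directly from per-voxel counts — useful when only
#' the occupancy summary of an epoch is known (e.g. totals printed in a
#' report) rather than the raw points.
#'
#' @param counts integer vector of per-voxel point counts (all >= 1).
#' @param edge,origin grid geometry.
#' @param ijk optional integer matrix of voxel indices (defaults to a line
#'   of voxels along i).
#' @return a `voxel_grid`.
#' @export
voxel_grid <- function(counts, edge = 0.10, origin = c(0, 0, 0),
                       ijk = NULL) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 1))
  if (is.null(ijk)) {
    ijk <- cbind(seq_along(counts) - 1L, 0L, 0L)
  }
  vox <- data.frame(i = as.integer(ijk[, 1]), j = as.integer(ijk[, 2]),
                    k = as.integer(ijk[, 3]), count = counts)
  structure(list(voxels = vox, edge = edge, origin = as.numeric(origin),
                 total_points = sum(counts)),
            class = "voxel_grid")
}

#' Compare two voxelized epochs
#'
#' Quantifies crown densification between two epochs sharing a grid: total
#' point counts, occupied-voxel counts, mean points per occupied voxel, and
#' the relative changes `(b - a)/a * 100` (%). An increase in total points
#' and mean voxel density between spring epochs is the leaf-sprout signal.
#'
#' @param grid_a,grid_b [voxelize()] results with identical edge and origin.
#' @param digits decimals for the reported percent changes (default 1).
#' @return object of class `change_summary`.
#' @export
compare_epochs <- function(grid_a, grid_b, digits = 1) {
  stopifnot(inherits(grid_a, "voxel_grid"), inherits(grid_b, "voxel_grid"))
  if (!isTRUE(all.equal(grid_a$edge, grid_b$edge)) ||
      !isTRUE(all.equal(grid_a$origin, grid_b$origin))) {
    stop("voxel grids differ in edge or origin; rebuild with a shared origin",
         call. = FALSE)
  }
  pct <- function(a, b) if (a == 0) NA_real_ else (b - a) / a * 100
  mean_a <- if (nrow(grid_a$voxels) > 0L) {
    grid_a$total_points / nrow(grid_a$voxels)
  } else {
    NA_real_
  }
  mean_b <- if (nrow(grid_b$voxels) > 0L) {
    grid_b$total_points / nrow(grid_b$voxels)
  } else {
    NA_real_
  }
  structure(list(
    edge = grid_a$edge,
    points = c(a = grid_a$total_points, b = grid_b$total_points),
    occupied_voxels = c(a = nrow(grid_a$voxels), b = nrow(grid_b$voxels)),
    mean_points_per_voxel = c(a = mean_a, b = mean_b),
    point_change_pct = round(pct(grid_a$total_points, grid_b$total_points),
                             digits),
    voxel_change_pct = round(pct(nrow(grid_a$voxels), nrow(grid_b$voxels)),
                             digits),
    density_change_pct = round(pct(mean_a, mean_b), digits)),
    class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "change_summary (voxel edge %g m)\n",
    "  points:           %d -> %d (%+.1f%%)\n",
    "  occupied voxels:  %d -> %d (%+.1f%%)\n",
    "  mean pts/voxel:   %.1f -> %.1f (%+.1f%%)\n"),
    x$edge, x$points["a"], x$points["b"], x$point_change_pct,
    x$occupied_voxels["a"], x$occupied_voxels["b"], x$voxel_change_pct,
    x$mean_points_per_voxel["a"], x$mean_points_per_voxel["b"],
    x$density_change_pct))
  invisible(x)
}

#' Select the scanner-facing half of a tree cloud
#'
#' The station sees only the near side of each crown; for epoch comparisons
#' the analysis keeps the nearest points — implemented as the points whose
#' range is at or below the cloud's median range, a reproducible proxy for
#' "the half of the tree facing the scanner".
#'
#' @param cloud an enriched [scan_cloud()] (needs the `range` column).
#' @return the filtered `scan_cloud`.
#' @export
near_half_selection <- function(cloud) {
  stopifnot(inherits(cloud, "scan_cloud"))
  if (!"range" %in% names(cloud$points)) {
    stop("cloud lacks 'range'; enrich() it first", call. = FALSE)
  }
  if (nrow(cloud$points) == 0L) return(cloud)
  med <- stats::median(cloud$points$range)
  keep <- cloud$points$range <= med + 1e-9 # tolerance for tied ranges
  cloud$points <- cloud$points[keep, , drop = FALSE]
  rownames(cloud$points) <- NULL
  cloud$meta$near_half <- list(median_range = med, kept = sum(keep))
  cloud
}

#' Export a voxel grid as a CSV of (i, j, k, count)
#' @param grid a `voxel_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_csv <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  utils::write.csv(grid$voxels, path, row.names = FALSE)
  invisible(path)
}
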