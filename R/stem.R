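#' Extract a breast-height stem slab
#'
#' Cuts the points within `center +/- tol` metres above the ground reference
#' (defaults: 1.3 m +/- 0.30 m, the band used for DBH estimation) and drops
#' non-stem returns by keeping only the largest connected component of the
#' slab in the horizontal (XY) plane at the given linkage radius — an
#' automated stand-in for the manual foliage cleanup such slabs otherwise
#' need.
#'
#' @param tree a [scan_cloud()] of a single tree.
#' @param ground_z ground elevation in the cloud's frame (metres); when
#'   `NULL`, estimated as the 1st percentile of Z.
#' @param center slab centre height above ground (default 1.3 m).
#' @param tol half-height of the slab (default 0.30 m).
#' @param linkage XY single-linkage radius used to isolate the stem cluster
#'   (default 0.05 m).
#' @param min_points minimum acceptable slab size (default 50).
#' @return object of class `stem_slab`: the slab `cloud`, `ground_z`, and
#'   the height band used.
#' @export
extract_slab <- function(tree, ground_z = NULL, center = 1.3, tol = 0.30,
                         linkage = 0.05, min_points = 50L) {
  stopifnot(inherits(tree, "scan_cloud"))
  if (npoints(tree) == 0L) stop("empty tree cloud", call. = FALSE)
  p <- tree$points
  if (is.null(ground_z)) {
    ground_z <- unname(stats::quantile(p$Z, 0.01, names = FALSE))
  }
  h <- p$Z - ground_z
  band <- h >= center - tol & h <= center + tol
  p <- p[band, , drop = FALSE]
  if (nrow(p) >= 2L) {
    # stem isolation: largest XY-connected cluster
    xy <- cbind(p$X, p$Y, 0)
    labels <- cpp_cluster_components(xy, linkage)
    main <- as.integer(names(which.max(table(labels))))
    p <- p[labels == main, , drop = FALSE]
  }
  if (nrow(p) < min_points) {
    stop(sprintf("insufficient slab points (%d < %d)", nrow(p),
                 as.integer(min_points)), call. = FALSE)
  }
  rownames(p) <- NULL
  cloud <- tree
  cloud$points <- p
  structure(list(cloud = cloud, ground_z = ground_z, center = center,
                 tol = tol),
            class = "stem_slab")
}

#' @export
print.stem_slab <- function(x, ...) {
  cat(sprintf("stem_slab: %d points, %g +/- %g m above ground (z = %.3f)\n",
              npoints(x$cloud), x$center, x$tol, x$ground_z))
  invisible(x)
}

#' RANSAC cylinder fit of a stem slab
#'
#' Robustly fits a cylinder to a breast-height slab. Candidate circles are
#' generated from minimal samples of 3 points projected on the plane normal
#' to the axis (initialized vertical, since stems are near-plumb at breast
#' height); the consensus set at `inlier_tol` picks the winner, which is then
#' refined by least squares on its inliers: a Gauss-Newton geometric circle
#' fit, optionally extended with two axis-tilt parameters when
#' `axis = "free"`. The reported `sigma` is the standard deviation of the
#' inlier point-to-surface residuals. The fit is deterministic given `seed`.
#'
#' @param slab a [extract_slab()] result (or a `scan_cloud` of slab points).
#' @param inlier_tol inlier distance to the cylinder surface in metres
#'   (default 0.01).
#' @param iterations RANSAC iterations (default 2000).
#' @param seed RNG seed for the minimal samples.
#' @param axis `"vertical"` (fixed, default) or `"free"` (small tilts
#'   refined by least squares).
#' @param min_inlier_frac minimum consensus fraction for a valid fit
#'   (default 0.3).
#' @param date optional date label carried into the fit.
#' @return object of class `stem_fit`: `axis_point`, `axis_direction`,
#'   `radius` (m), `sigma` (m), `n_inliers`, `n_points`, `date`.
#' @export
ransac_cylinder <- function(slab, inlier_tol = 0.01, iterations = 2000L,
                            seed = 1L, axis = c("vertical", "free"),
                            min_inlier_frac = 0.3, date = NULL) {
  axis <- match.arg(axis)
  cloud <- if (inherits(slab, "stem_slab")) slab$cloud else slab
  stopifnot(inherits(cloud, "scan_cloud"))
  p <- cloud$points
  n <- nrow(p)
  if (n < 9L) stop("too few points for a cylinder fit", call. = FALSE)
  x <- p$X
  y <- p$Y
  z <- p$Z

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  best <- list(count = -1L)
  samples <- matrix(sample.int(n, 3L * iterations, replace = TRUE),
                    nrow = 3L)
  for (it in seq_len(iterations)) {
    s <- samples[, it]
    if (length(unique(s)) < 3L) next
    circ <- circle_through3(x[s], y[s])
    if (is.null(circ)) next
    r_i <- sqrt((x - circ[1])^2 + (y - circ[2])^2)
    resid <- abs(r_i - circ[3])
    count <- sum(resid <= inlier_tol)
    if (count > best$count) {
      best <- list(count = count, center = circ[1:2], radius = circ[3])
    }
  }
  if (best$count < min_inlier_frac * n) {
    stop(sprintf(
      "cylinder consensus too small (%d of %d points, need %.0f%%)",
      max(best$count, 0L), n, 100 * min_inlier_frac), call. = FALSE)
  }

  # least-squares refinement on the consensus set
  inl <- abs(sqrt((x - best$center[1])^2 + (y - best$center[2])^2) -
               best$radius) <= inlier_tol
  fit <- refine_cylinder(x[inl], y[inl], z[inl], best$center, best$radius,
                         free_axis = (axis == "free"))
  # re-evaluate inliers once under the refined model and refit
  resid_all <- cylinder_residuals(x, y, z, fit)
  inl <- abs(resid_all) <= inlier_tol
  fit <- refine_cylinder(x[inl], y[inl], z[inl], fit$center, fit$radius,
                         free_axis = (axis == "free"))
  resid_in <- cylinder_residuals(x[inl], y[inl], z[inl], fit)

  structure(list(
    axis_point = c(fit$center[1], fit$center[2], mean(z[inl])),
    axis_direction = fit$axis,
    radius = fit$radius,
    sigma = stats::sd(resid_in),
    n_inliers = sum(inl),
    n_points = n,
    inlier_tol = inlier_tol,
    date = date),
    class = "stem_fit")
}

#' @export
print.stem_fit <- function(x, ...) {
  cat(sprintf(
    "stem_fit: radius %.1f mm (sigma %.1f mm), %d/%d inliers%s\n",
    x$radius * 1000, x$sigma * 1000, x$n_inliers, x$n_points,
    if (is.null(x$date)) "" else paste0(", ", format(x$date))))
  invisible(x)
}

# circle through three points in the plane; NULL when nearly collinear
circle_through3 <- function(x, y) {
  ax <- x[1]; ay <- y[1]; bx <- x[2]; by <- y[2]; cx <- x[3]; cy <- y[3]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  r <- sqrt((ax - ux)^2 + (ay - uy)^2)
  c(ux, uy, r)
}

# signed point-to-surface distance for a (possibly tilted) cylinder
cylinder_residuals <- function(x, y, z, fit) {
  a <- fit$axis
  px <- x - fit$center[1]
  py <- y - fit$center[2]
  pz <- z - fit$z0
  t <- px * a[1] + py * a[2] + pz * a[3]
  dx <- px - t * a[1]
  dy <- py - t * a[2]
  dz <- pz - t * a[3]
  sqrt(dx^2 + dy^2 + dz^2) - fit$radius
}

# Gauss-Newton style refinement via stats::optim on the residual sum of
# squares; vertical-axis mode optimizes (cx, cy, r), free mode adds two
# small tilt angles.
refine_cylinder <- function(x, y, z, center0, r0, free_axis = FALSE) {
  z0 <- mean(z)
  make_fit <- function(par) {
    if (free_axis) {
      ax <- par[4]; ay <- par[5]
      axis <- c(ax, ay, 1)
      axis <- axis / sqrt(sum(axis^2))
    } else {
      axis <- c(0, 0, 1)
    }
    list(center = par[1:2], radius = par[3], axis = axis, z0 = z0)
  }
  obj <- function(par) {
    if (par[3] <= 0) return(1e12)
    sum(cylinder_residuals(x, y, z, make_fit(par))^2)
  }
  par0 <- c(center0, r0, if (free_axis) c(0, 0))
  opt <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  make_fit(opt$par)
}

#' Diameter at breast height from a cylinder fit
#'
#' DBH is twice the fitted radius, reported in millimetres to one decimal.
#'
#' @param fit a [ransac_cylinder()] result.
#' @return DBH in mm.
#' @export
#' @examples
#' fit <- structure(list(radius = 0.0824), class = "stem_fit")
#' dbh_from_fit(fit) # 164.8
dbh_from_fit <- function(fit) {
  stopifnot(inherits(fit, "stem_fit"), fit$radius > 0)
  round(2 * fit$radius * 1000, 1)
}

#' Fit a DBH time series over scan epochs
#'
#' Runs [extract_slab()] and [ransac_cylinder()] on each epoch's tree cloud
#' and assembles the DBH series.
#'
#' @param clouds list of [scan_cloud()]s, one per epoch.
#' @param dates vector of epoch dates (same length).
#' @param ground_z ground elevation passed to [extract_slab()] (scalar or
#'   per-epoch vector); `NULL` to estimate per epoch.
#' @param seed RANSAC seed (incremented per epoch for independence).
#' @param ... further arguments to [ransac_cylinder()].
#' @return object of class `dbh_series`: data frame with `date`, `dbh_mm`,
#'   `sigma_mm`, `radius_m`, `n_inliers`.
#' @export
fit_dbh_series <- function(clouds, dates, ground_z = NULL, seed = 1L, ...) {
  stopifnot(length(clouds) == length(dates))
  gz <- if (is.null(ground_z)) rep(list(NULL), length(clouds)) else
    as.list(rep_len(ground_z, length(clouds)))
  rows <- vector("list", length(clouds))
  fits <- vector("list", length(clouds))
  for (i in seq_along(clouds)) {
    slab <- extract_slab(clouds[[i]], ground_z = gz[[i]])
    fit <- ransac_cylinder(slab, seed = seed + i - 1L, date = dates[i], ...)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(date = dates[i],
                            dbh_mm = dbh_from_fit(fit),
                            sigma_mm = round(fit$sigma * 1000, 1),
                            radius_m = fit$radius,
                            n_inliers = fit$n_inliers)
  }
  series <- do.call(rbind, rows)
  o <- order(series$date)
  series <- series[o, , drop = FALSE]
  rownames(series) <- NULL
  structure(series, fits = fits[o], class = c("dbh_series", "data.frame"))
}

#' Compare a DBH series against caliper reference measurements
#'
#' The reference is the arithmetic mean of the caliper values (the field
#' protocol averages consecutive manual measurements). Reports per-date
#' discrepancies (estimate minus reference) and the caliper dispersion as
#' both the population and the sample standard deviation, labelled — with a
#' single caliper value the dispersion is reported as absent (`NA`).
#'
#' @param series a [fit_dbh_series()] result (or data frame with `date` and
#'   `dbh_mm`).
#' @param caliper_mm numeric vector of caliper DBH measurements in mm.
#' @return list with `reference_mm`, `caliper_sd_population_mm`,
#'   `caliper_sd_sample_mm`, and `discrepancies` (data frame).
#' @export
compare_to_reference <- function(series, caliper_mm) {
  stopifnot(length(caliper_mm) >= 1L)
  reference <- mean(caliper_mm)
  m <- length(caliper_mm)
  sd_pop <- if (m > 1L) sqrt(sum((caliper_mm - reference)^2) / m) else
    NA_real_
  sd_samp <- if (m > 1L) stats::sd(caliper_mm) else NA_real_
  disc <- data.frame(date = series$date,
                     dbh_mm = series$dbh_mm,
                     discrepancy_mm = round(series$dbh_mm - reference, 1))
  list(reference_mm = reference,
       caliper_n = m,
       caliper_sd_population_mm = sd_pop,
       caliper_sd_sample_mm = sd_samp,
       discrepancies = disc)
}
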