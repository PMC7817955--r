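#' Spherical coordinates of scanner-frame points
#'
#' Converts Cartesian coordinates in the scanner-centric frame (origin at the
#' scanner optical centre, Z up) to spherical coordinates: range `rho` (m),
#' polar angle `theta` measured from +Z (degrees, 0--180) and azimuth `phi`
#' (degrees). The azimuth is the four-quadrant arctangent of (Y, X) wrapped
#' to \[0, 360) so that a scan window spanning several quadrants maps to a
#' single contiguous interval.
#'
#' @param xyz numeric matrix or data frame with columns X, Y, Z (metres).
#' @return data frame with columns `rho`, `theta`, `phi`, one row per input
#'   point, order preserved.
#' @export
#' @examples
#' spherical_from_cartesian(cbind(3, 4, 0)) # rho 5, theta 90, phi ~53.13
spherical_from_cartesian <- function(xyz) {
  xyz <- as_xyz_matrix(xyz)
  rho <- sqrt(rowSums(xyz^2))
  bad <- which(rho <= 0 | !is.finite(rho))
  if (length(bad) > 0L) {
    stop("degenerate zero-norm point(s) at index ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         ": range must be > 0", call. = FALSE)
  }
  theta <- acos(pmin(1, pmax(-1, xyz[, 3] / rho))) * 180 / pi
  phi <- atan2(xyz[, 2], xyz[, 1]) * 180 / pi
  phi <- phi %% 360
  data.frame(rho = rho, theta = theta, phi = phi)
}

#' Cartesian coordinates from spherical coordinates
#'
#' Inverse of [spherical_from_cartesian()]: `rho` in metres, `theta` polar
#' angle from +Z and `phi` azimuth, both in degrees.
#'
#' @param sph data frame or matrix with columns `rho`, `theta`, `phi`.
#' @return data frame with columns `X`, `Y`, `Z` (metres).
#' @export
cartesian_from_spherical <- function(sph) {
  sph <- as.data.frame(sph)
  stopifnot(all(c("rho", "theta", "phi") %in% names(sph)))
  if (any(sph$rho < 0)) stop("rho must be >= 0", call. = FALSE)
  th <- sph$theta * pi / 180
  ph <- sph$phi * pi / 180
  data.frame(X = sph$rho * sin(th) * cos(ph),
             Y = sph$rho * sin(th) * sin(ph),
             Z = sph$rho * cos(th))
}

#' Angular raster geometry of the scan window
#'
#' Describes the equirectangular image frame of a scan: the fixed angular
#' window (polar angle `theta`, azimuth `phi`, degrees) and the pixel angular
#' size `alpha`. Image dimensions are `n_rows = ceiling((theta_max -
#' theta_min)/alpha)` and `n_cols = ceiling((phi_max - phi_min)/alpha)` (a
#' 1e-9 relative guard absorbs floating-point excess when the span is an
#' exact multiple of `alpha`).
#'
#' @param alpha pixel angular size in degrees (> 0).
#' @param theta_min,theta_max polar-angle window bounds in degrees.
#' @param phi_min,phi_max azimuth window bounds in degrees.
#' @return object of class `raster_geometry`.
#' @export
raster_geometry <- function(alpha, theta_min, theta_max, phi_min, phi_max) {
  stopifnot(alpha > 0, theta_max > theta_min, phi_max > phi_min)
  g <- list(alpha = alpha,
            theta_min = theta_min, theta_max = theta_max,
            phi_min = phi_min, phi_max = phi_max,
            n_rows = as.integer(ceiling((theta_max - theta_min) / alpha - 1e-9)),
            n_cols = as.integer(ceiling((phi_max - phi_min) / alpha - 1e-9)))
  class(g) <- "raster_geometry"
  g
}

#' @export
print.raster_geometry <- function(x, ...) {
  cat(sprintf(
    "raster_geometry: %d x %d px, alpha = %g deg, theta [%g, %g], phi [%g, %g]\n",
    x$n_rows, x$n_cols, x$alpha, x$theta_min, x$theta_max, x$phi_min,
    x$phi_max))
  invisible(x)
}

#' Pixel indices of spherical directions on the angular grid
#'
#' Maps polar/azimuth angles to 0-based (row, col) pixel indices of the
#' equirectangular frame: `row = floor((theta - theta_min)/alpha)`,
#' `col = floor((phi - phi_min)/alpha)`. Pixels are half-open intervals
#' `[k*alpha, (k+1)*alpha)`; angles exactly on the upper window bound fall in
#' the last pixel. Points outside the window are flagged in the `inside`
#' column (never clamped); their raw indices are still returned.
#'
#' @param theta,phi angles in degrees (vectors of equal length).
#' @param geom a [raster_geometry()].
#' @param tol_pixels border tolerance in pixels: points up to this many
#'   pixels outside the window still count as inside (default 0).
#' @return data frame with integer columns `row`, `col` and logical `inside`.
#' @export
pixel_of <- function(theta, phi, geom, tol_pixels = 0) {
  stopifnot(inherits(geom, "raster_geometry"), length(theta) == length(phi))
  row <- floor((theta - geom$theta_min) / geom$alpha)
  # azimuth offsets wrap modulo 360 so a window may sit across the 0/360
  # seam (phi_min < 0); for ordinary windows this changes nothing
  dphi <- (phi - geom$phi_min) %% 360
  col <- floor(dphi / geom$alpha)
  # upper-bound closure: the window's top edge belongs to the last pixel
  row[theta == geom$theta_max] <- geom$n_rows - 1L
  col[dphi == geom$phi_max - geom$phi_min] <- geom$n_cols - 1L
  inside <- row >= -tol_pixels & row <= geom$n_rows - 1L + tol_pixels &
    col >= -tol_pixels & col <= geom$n_cols - 1L + tol_pixels
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Point spacing on a target at a given range
#'
#' Arc length subtended by one angular step at a given range:
#' `range * alpha * pi/180`. At the station's 0.006 deg step this gives the
#' ~0.01 m point spacing at 100 m that the scan configuration was designed
#' around.
#'
#' @param alpha angular step in degrees (>= 0).
#' @param range range in metres (> 0).
#' @return spacing in metres.
#' @export
#' @examples
#' point_spacing_at_range(0.006, 100) # ~0.0105 m
point_spacing_at_range <- function(alpha, range) {
  stopifnot(alpha >= 0, range > 0)
  range * alpha * pi / 180
}

# coerce matrix/data.frame input to an n x 3 numeric matrix, tolerating
# either unnamed 3-column input or named X/Y/Z columns
as_xyz_matrix <- function(xyz) {
  if (is.data.frame(xyz)) {
    missing <- setdiff(c("X", "Y", "Z"), names(xyz))
    if (length(missing) == 0L) {
      xyz <- as.matrix(xyz[, c("X", "Y", "Z")])
    } else if (ncol(xyz) == 3L) {
      xyz <- as.matrix(xyz)
    } else {
      stop("missing coordinate column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("expected 3 coordinate columns", call. = FALSE)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  xyz
}
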