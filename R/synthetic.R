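#' Parametric tree specification for the scene simulator
#'
#' Describes one synthetic tree: a vertical (optionally tapered) stem
#' cylinder, thin branch cylinders, and point-bearing foliage discs around
#' the branch tips. The defaults emulate a mature birch-like deciduous tree
#' of the boreal stand the station monitors; `species = "conifer"` gives a
#' spruce/pine-like tree whose foliage does not respond to [sprout()].
#'
#' @param base length-2 or -3 stem base position (m, world frame, ground
#'   z = 0); a 2-vector is placed on the ground.
#' @param height tree height (m).
#' @param radius stem radius at 1.3 m (m).
#' @param n_branches number of branches.
#' @param foliage_density foliage return density (points per m^2 of leaf
#'   disc).
#' @param foliage_radius `c(min, max)` range of the foliage disc radii (m).
#' @param species `"deciduous"` or `"conifer"`.
#' @param taper stem radius shrink factor from base to tip (0 = cylinder).
#' @return object of class `tree_spec`.
#' @export
tree_spec <- function(base = c(6, 0), height = 19, radius = 0.0865,
                      n_branches = 12L, foliage_density = 3000,
                      foliage_radius = c(0.25, 0.45),
                      species = c("deciduous", "conifer"), taper = 0.4) {
  species <- match.arg(species)
  stopifnot(height > 0, radius > 0, foliage_density >= 0,
            length(foliage_radius) == 2L, all(foliage_radius > 0))
  if (length(base) == 2L) base <- c(base, 0)
  structure(list(base = as.numeric(base), height = height, radius = radius,
                 n_branches = as.integer(n_branches),
                 foliage_density = foliage_density,
                 foliage_radius = as.numeric(foliage_radius),
                 species = species, taper = taper),
            class = "tree_spec")
}

#' Scanner specification for the scene simulator
#'
#' The station's scanner constants: a sensor ~30 m above ground sampling a
#' fixed angular window on a regular (theta, phi) grid. Defaults follow the
#' station configuration: 0.006 deg angular step, 138 m maximum range, up to
#' 8 returns per pulse, 3 mm range noise (the scanner's nominal distance
#' precision). The full 87 x 151 deg window at 0.006 deg is enormous;
#' simulations normally pass a small `window` around the target or let
#' [scan_scene()] fit one automatically.
#'
#' @param position scanner position in the world frame (m).
#' @param alpha angular step in degrees.
#' @param window optional `c(theta_min, theta_max, phi_min, phi_max)` (deg).
#' @param max_range maximum detection range (m).
#' @param max_returns returns per emitted pulse (<= 8).
#' @param range_noise_sd Gaussian range noise sd (m).
#' @param epoch reference time of the simulated campaign (`POSIXct`).
#' @return object of class `scanner_spec`.
#' @export
scanner_spec <- function(position = c(0, 0, 30), alpha = 0.006,
                         window = NULL, max_range = 138, max_returns = 8L,
                         range_noise_sd = 0.003,
                         epoch = as.POSIXct("2020-04-30 00:00:00",
                                            tz = "UTC")) {
  stopifnot(alpha > 0, max_range > 0, max_returns >= 1, max_returns <= 15,
            range_noise_sd >= 0)
  structure(list(position = as.numeric(position), alpha = alpha,
                 window = window, max_range = max_range,
                 max_returns = as.integer(max_returns),
                 range_noise_sd = range_noise_sd, epoch = epoch),
            class = "scanner_spec")
}

#' Branch/foliage displacement law
#'
#' Sinusoidal displacement applied to branch and foliage primitives only —
#' the simulator's stand-in for circadian branch movement:
#' `d(t) = amplitude * sin(2*pi*t/period_h + phase) * axis` with `t` in
#' hours.
#'
#' @param amplitude displacement amplitude (m, >= 0).
#' @param period_h period in hours (default 24).
#' @param phase phase offset in radians.
#' @param axis direction of motion (unit-normalized; default vertical).
#' @return object of class `motion_spec`.
#' @export
motion_spec <- function(amplitude = 0.05, period_h = 24, phase = 0,
                        axis = c(0, 0, 1)) {
  stopifnot(amplitude >= 0, period_h > 0)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(amplitude = amplitude, period_h = period_h, phase = phase,
                 axis = axis),
            class = "motion_spec")
}

motion_offset <- function(motion, time_h) {
  if (is.null(motion)) return(c(0, 0, 0))
  motion$amplitude * sin(2 * pi * time_h / motion$period_h + motion$phase) *
    motion$axis
}

#' Build a synthetic forest scene
#'
#' Expands tree specifications into a primitive set: stems and branches as
#' finite cylinders (opaque), foliage as porous discs at branch tips.
#' Branch geometry is drawn from the seeded RNG, so the same (specs, seed)
#' pair always yields the identical scene. Overlapping stem bases only
#' trigger a warning.
#'
#' @param trees a `tree_spec` or list of them.
#' @param rng_seed integer seed.
#' @return object of class `scene`: data frame `primitives` with geometry
#'   columns (`bx/by/bz` base or centre, `ax/ay/az` unit axis or normal,
#'   `len`, `radius`), `material` (stem/branch/foliage), `density`,
#'   `species`, `tree`, and logical `moving`.
#' @export
build_scene <- function(trees, rng_seed = 1L) {
  if (inherits(trees, "tree_spec")) trees <- list(trees)
  stopifnot(all(vapply(trees, inherits, logical(1), "tree_spec")))
  bases <- t(vapply(trees, function(t) t$base[1:2], numeric(2)))
  if (nrow(bases) > 1L && min(stats::dist(bases)) < 0.5) {
    warning("overlapping stem bases in scene", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)

  prim <- list()
  add <- function(material, b, a, len, radius, density, species, tree,
                  moving) {
    prim[[length(prim) + 1L]] <<- data.frame(
      material = material, bx = b[1], by = b[2], bz = b[3],
      ax = a[1], ay = a[2], az = a[3], len = len, radius = radius,
      density = density, species = species, tree = tree, moving = moving)
  }
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    add("stem", tr$base, c(0, 0, 1), tr$height, tr$radius, NA_real_,
        tr$species, i, FALSE)
    if (tr$n_branches > 0L) {
      h <- stats::runif(tr$n_branches, 0.35, 0.95) * tr$height
      az <- stats::runif(tr$n_branches, 0, 2 * pi)
      el <- stats::runif(tr$n_branches, -0.1, 0.45)
      len <- stats::runif(tr$n_branches, 0.5, 1.5) * 0.12 * tr$height
      for (b in seq_len(tr$n_branches)) {
        dir <- c(cos(az[b]) * cos(el[b]), sin(az[b]) * cos(el[b]),
                 sin(el[b]))
        org <- tr$base + c(0, 0, h[b])
        add("branch", org, dir, len[b], 0.02, NA_real_, tr$species, i, TRUE)
        tip <- org + dir * len[b]
        nrm <- stats::rnorm(3)
        nrm <- nrm / sqrt(sum(nrm^2))
        add("foliage", tip, nrm, 0,
            stats::runif(1, tr$foliage_radius[1], tr$foliage_radius[2]),
            tr$foliage_density, tr$species, i, TRUE)
      }
    }
  }
  primitives <- do.call(rbind, prim)
  rownames(primitives) <- NULL
  structure(list(primitives = primitives, trees = trees,
                 rng_seed = rng_seed),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  tab <- table(x$primitives$material)
  cat("scene:", paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
      sprintf("(%d trees)\n", length(x$trees)))
  invisible(x)
}

#' Add an opaque wall to a scene
#'
#' A large opaque disc facing the scanner — a planar calibration target used
#' to verify point spacing and occlusion behaviour.
#'
#' @param scene a [build_scene()] result (or `NULL` for a wall-only scene).
#' @param center disc centre (m, world frame).
#' @param normal disc normal.
#' @param radius disc radius (m).
#' @return the extended `scene`.
#' @export
add_wall <- function(scene = NULL, center = c(100, 0, 15),
                     normal = c(-1, 0, 0), radius = 50) {
  normal <- normal / sqrt(sum(normal^2))
  wall <- data.frame(material = "wall", bx = center[1], by = center[2],
                     bz = center[3], ax = normal[1], ay = normal[2],
                     az = normal[3], len = 0, radius = radius,
                     density = NA_real_, species = "none", tree = 0L,
                     moving = FALSE)
  if (is.null(scene)) {
    scene <- structure(list(primitives = wall, trees = list(),
                            rng_seed = NA_integer_), class = "scene")
  } else {
    scene$primitives <- rbind(scene$primitives, wall)
  }
  scene
}

#' Scale foliage density (leaf sprout)
#'
#' Multiplies the foliage density of deciduous trees by `f >= 1`, leaving
#' conifers unchanged — the simulator's leaf-sprout densification control.
#'
#' @param scene a [build_scene()] result.
#' @param f density factor (>= 1; use a pruning flag, not f < 1).
#' @return the modified `scene`.
#' @export
sprout <- function(scene, f) {
  stopifnot(inherits(scene, "scene"))
  if (f < 1) stop("sprout factor must be >= 1", call. = FALSE)
  sel <- scene$primitives$material == "foliage" &
    scene$primitives$species == "deciduous"
  scene$primitives$density[sel] <- scene$primitives$density[sel] * f
  scene
}

# --- ray casting -----------------------------------------------------------

# angular bounding box (theta/phi deg) of a primitive seen from the origin,
# from a cage of sample points inflated by the primitive radius
prim_angular_bbox <- function(pr, origin) {
  b <- c(pr$bx, pr$by, pr$bz) - origin
  a <- c(pr$ax, pr$ay, pr$az)
  centres <- rbind(b, b + a * pr$len)
  offs <- rbind(diag(3), -diag(3)) * pr$radius
  pts <- do.call(rbind, lapply(seq_len(nrow(centres)), function(i) {
    sweep(offs, 2, centres[i, ], "+")
  }))
  sph <- spherical_from_cartesian(pts)
  phi <- sph$phi
  if (diff(range(phi)) > 180) {
    # primitive straddles the 0/360 azimuth seam: use (-180, 180] instead
    phi <- ifelse(phi > 180, phi - 360, phi)
  }
  list(theta = range(sph$theta), phi = range(phi))
}

# exact first intersections of grid rays with one primitive; ray directions
# given as unit-vector components. Returns parameter t (NA when missed).
ray_hits <- function(pr, dx, dy, dz) {
  b <- c(pr$bx, pr$by, pr$bz)
  a <- c(pr$ax, pr$ay, pr$az)
  if (pr$material %in% c("foliage", "wall")) {
    dn <- dx * a[1] + dy * a[2] + dz * a[3]
    t <- sum(b * a) / dn
    d2 <- (dx * t - b[1])^2 + (dy * t - b[2])^2 + (dz * t - b[3])^2
    t[!(is.finite(t) & t > 0 & d2 <= pr$radius^2)] <- NA_real_
    t
  } else {
    # finite cylinder: |(t d - b) - (((t d - b).a) a)|^2 = r^2
    da <- dx * a[1] + dy * a[2] + dz * a[3]
    ba <- sum(b * a)
    px <- dx - da * a[1]
    py <- dy - da * a[2]
    pz <- dz - da * a[3]
    bp <- b - ba * a
    A <- px * px + py * py + pz * pz
    B <- -2 * (px * bp[1] + py * bp[2] + pz * bp[3])
    C <- sum(bp * bp) - pr$radius^2
    disc <- B * B - 4 * A * C
    ok <- !is.na(disc) & disc >= 0 & A > 1e-12
    t <- rep(NA_real_, length(dx))
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-B[ok] - sq) / (2 * A[ok])
      t2 <- (-B[ok] + sq) / (2 * A[ok])
      tt <- ifelse(t1 > 1e-6, t1, ifelse(t2 > 1e-6, t2, NA_real_))
      s <- tt * da[ok] - ba
      tt[!is.na(tt) & (s < 0 | s > pr$len)] <- NA_real_
      t[ok] <- tt
    }
    t
  }
}

#' Simulate one scan of a scene
#'
#' Casts rays on the scanner's regular (theta, phi) grid and builds an
#' enriched [scan_cloud()]. Stems, branches and walls are opaque: the first
#' such hit terminates the ray. Foliage discs are porous: a ray crossing one
#' registers an echo with probability `min(1, density * spacing^2)` — where
#' `spacing` is the beam spacing at that range — and always continues, so a
#' pulse can yield several returns (capped at the scanner's maximum; return
#' numbers increase along the ray). Gaussian range noise perturbs each echo
#' along its ray; reflectance and deviation are drawn per material class.
#' Ground truth (primitive id, material, tree, true range and the motion
#' displacement applied) is attached as the `truth` attribute.
#'
#' @param scene a [build_scene()] result.
#' @param scanner a [scanner_spec()].
#' @param time_h scan time in hours since the scanner epoch (drives motion
#'   and the scan timestamp).
#' @param motion optional [motion_spec()] applied to moving primitives.
#' @param rng_seed seed for echo sampling and noise.
#' @param window optional `c(theta_min, theta_max, phi_min, phi_max)` (deg)
#'   overriding the scanner's; when both are `NULL` the window is fitted to
#'   the scene with a 2-pixel margin.
#' @return an enriched `scan_cloud` (in the scanner-centric frame) with a
#'   `truth` attribute and the [raster_geometry()] used in `meta`.
#' @export
scan_scene <- function(scene, scanner, time_h = 0, motion = NULL,
                       rng_seed = 1L, window = NULL) {
  stopifnot(inherits(scene, "scene"), inherits(scanner, "scanner_spec"))
  prims <- scene$primitives
  origin <- scanner$position
  disp <- motion_offset(motion, time_h)
  moved <- prims$moving
  prims$bx[moved] <- prims$bx[moved] + disp[1]
  prims$by[moved] <- prims$by[moved] + disp[2]
  prims$bz[moved] <- prims$bz[moved] + disp[3]
  # shift world frame to scanner-centric
  prims$bx <- prims$bx - origin[1]
  prims$by <- prims$by - origin[2]
  prims$bz <- prims$bz - origin[3]

  if (is.null(window)) window <- scanner$window
  if (is.null(window)) {
    bb <- lapply(seq_len(nrow(prims)), function(i) {
      prim_angular_bbox(prims[i, ], c(0, 0, 0))
    })
    th <- range(unlist(lapply(bb, `[[`, "theta")))
    ph_iv <- lapply(bb, `[[`, "phi")
    # keep the azimuth frame coherent around the 0/360 seam: when any
    # primitive was wrapped to negative azimuths, wrap the far side too
    if (any(vapply(ph_iv, function(v) v[1] < 0, logical(1)))) {
      ph_iv <- lapply(ph_iv, function(v) if (mean(v) > 180) v - 360 else v)
    }
    ph <- range(unlist(ph_iv))
    m <- 2 * scanner$alpha
    window <- c(th[1] - m, th[2] + m, ph[1] - m, ph[2] + m)
  }
  geom <- raster_geometry(scanner$alpha, window[1], window[2], window[3],
                          window[4])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)

  # per-row/col direction trig cached once for the whole window
  th <- (geom$theta_min + (seq_len(geom$n_rows) - 0.5) * geom$alpha) *
    pi / 180
  ph <- (geom$phi_min + (seq_len(geom$n_cols) - 0.5) * geom$alpha) *
    pi / 180
  th_s <- sin(th); th_c <- cos(th)
  ph_c <- cos(ph); ph_s <- sin(ph)

  # candidate rays of one angular bbox, as packed ray ids (row * n_cols + col)
  bbox_rays <- function(bb) {
    # express the bbox azimuth in the window's (possibly negative) frame
    if (bb$phi[1] > geom$phi_max) bb$phi <- bb$phi - 360
    if (bb$phi[2] < geom$phi_min) bb$phi <- bb$phi + 360
    r0 <- max(0L, floor((bb$theta[1] - geom$theta_min) / geom$alpha) - 1L)
    r1 <- min(geom$n_rows - 1L,
              ceiling((bb$theta[2] - geom$theta_min) / geom$alpha))
    c0 <- max(0L, floor((bb$phi[1] - geom$phi_min) / geom$alpha) - 1L)
    c1 <- min(geom$n_cols - 1L,
              ceiling((bb$phi[2] - geom$phi_min) / geom$alpha))
    if (r1 < r0 || c1 < c0) return(integer(0))
    outer((r0:r1) * geom$n_cols, c0:c1, "+")
  }

  # gather candidate hits per primitive; long thin cylinders are subdivided
  # for candidate selection (their one-piece angular bbox is mostly empty)
  prl <- lapply(seq_len(nrow(prims)), function(i) as.list(prims[i, ]))
  hits <- vector("list", nrow(prims))
  for (i in seq_along(prl)) {
    pr <- prl[[i]]
    seg_len <- max(8 * pr$radius, 0.4)
    n_seg <- if (pr$len > seg_len) ceiling(pr$len / seg_len) else 1L
    rays <- unlist(lapply(seq_len(n_seg), function(s) {
      seg <- pr
      seg$bx <- pr$bx + pr$ax * (s - 1) * pr$len / n_seg
      seg$by <- pr$by + pr$ay * (s - 1) * pr$len / n_seg
      seg$bz <- pr$bz + pr$az * (s - 1) * pr$len / n_seg
      seg$len <- pr$len / n_seg
      bbox_rays(prim_angular_bbox(seg, c(0, 0, 0)))
    }))
    if (n_seg > 1L) rays <- unique(rays)
    if (length(rays) == 0L) next
    ir <- rays %/% geom$n_cols
    ic <- rays %% geom$n_cols
    dx <- th_s[ir + 1L] * ph_c[ic + 1L]
    dy <- th_s[ir + 1L] * ph_s[ic + 1L]
    dz <- th_c[ir + 1L]
    t <- ray_hits(pr, dx, dy, dz)
    ok <- which(!is.na(t) & t <= scanner$max_range)
    if (length(ok) == 0L) next
    hits[[i]] <- data.frame(ray = rays[ok], t = t[ok], prim = i)
  }
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0L) {
    cloud <- scan_cloud(data.frame(X = numeric(0), Y = numeric(0),
                                   Z = numeric(0)),
                        timestamp = scanner$epoch + time_h * 3600)
    cloud <- enrich(cloud, geom)
    attr(cloud, "truth") <- data.frame(prim = integer(0))
    return(cloud)
  }

  # walk each ray front-to-back: porous foliage echoes, opaque termination
  o <- order(hits$ray, hits$t)
  hits <- hits[o, , drop = FALSE]
  mat <- prims$material[hits$prim]
  opaque <- mat %in% c("stem", "branch", "wall")
  spacing <- point_spacing_at_range(scanner$alpha, hits$t)
  p_echo <- ifelse(opaque, 1,
                   pmin(1, prims$density[hits$prim] * spacing^2))
  registered <- stats::runif(nrow(hits)) < p_echo

  ray <- hits$ray
  nh <- length(ray)
  new_ray <- c(TRUE, ray[-1] != ray[-nh])
  start <- which(new_ray)
  len <- diff(c(start, nh + 1L))
  # grouped cumulative sums via global cumsum minus each ray's offset
  grouped_cumsum <- function(v) {
    cs <- cumsum(v)
    cs - rep(cs[start] - v[start], len)
  }
  # a hit is reachable while no opaque hit precedes it on the same ray
  opaque_before <- grouped_cumsum(as.integer(opaque)) - as.integer(opaque)
  keep <- opaque_before == 0L & registered
  # return numbering among kept echoes of each ray, capped at max_returns
  rn <- grouped_cumsum(as.integer(keep))
  keep <- keep & rn <= scanner$max_returns
  rn <- rn[keep]
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    cloud <- scan_cloud(data.frame(X = numeric(0), Y = numeric(0),
                                   Z = numeric(0)),
                        timestamp = scanner$epoch + time_h * 3600)
    cloud <- enrich(cloud, geom)
    attr(cloud, "truth") <- data.frame(prim = integer(0))
    return(cloud)
  }
  # rn increases within a ray, so each ray's return count is its last rn
  kray <- ray[keep]
  kn <- length(kray)
  last_of_ray <- c(kray[-1] != kray[-kn], TRUE)
  klen <- diff(c(0L, which(last_of_ray)))
  nret <- rep(rn[last_of_ray], klen)

  t_noisy <- h$t + stats::rnorm(nrow(h), 0, scanner$range_noise_sd)
  rowi <- h$ray %/% geom$n_cols
  coli <- h$ray %% geom$n_cols
  th <- (geom$theta_min + (rowi + 0.5) * geom$alpha) * pi / 180
  ph <- (geom$phi_min + (coli + 0.5) * geom$alpha) * pi / 180
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  xyz <- dirs * t_noisy

  m <- prims$material[h$prim]
  refl_base <- c(stem = -8, branch = -9, foliage = -13, wall = -5)[m]
  reflectance <- refl_base + stats::rnorm(nrow(h), 0, 0.5)
  deviation <- ifelse(m == "foliage", 15 + 5 * rn, 2) +
    abs(stats::rnorm(nrow(h), 0, 1))
  intensity <- pmin(1, pmax(0, (reflectance + 20) / 20))

  cloud <- scan_cloud(
    data.frame(X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3],
               return_number = as.integer(rn),
               number_of_returns = as.integer(nret),
               intensity = intensity, reflectance = reflectance,
               deviation = deviation),
    timestamp = scanner$epoch + time_h * 3600,
    meta = list(scanner = unclass(scanner), time_h = time_h))
  cloud <- enrich(cloud, geom)
  attr(cloud, "truth") <- data.frame(
    prim = h$prim, material = m, tree = prims$tree[h$prim],
    true_range = h$t,
    disp_x = ifelse(prims$moving[h$prim], disp[1], 0),
    disp_y = ifelse(prims$moving[h$prim], disp[2], 0),
    disp_z = ifelse(prims$moving[h$prim], disp[3], 0))
  cloud
}

# --- direct surface samplers ----------------------------------------------

#' Sample scene surfaces directly into a point set
#'
#' Fast alternative to ray casting for analyses that only need point
#' positions: foliage discs receive `Poisson(density * area)` points
#' uniform on the disc, stems and branches `Poisson(wood_density * lateral
#' area)` points uniform on the cylinder surface. The draw is fixed by
#' `rng_seed`, so the same call yields the same base geometry — per-scan
#' measurement noise and motion are applied afterwards by
#' [simulate_scan_sequence()].
#'
#' @param scene a [build_scene()] result.
#' @param rng_seed integer seed.
#' @param wood_density stem/branch surface density (points per m^2).
#' @param materials which materials to sample (default all).
#' @return data frame with `X`, `Y`, `Z` (world frame), `material`, `tree`,
#'   `prim`, `moving`.
#' @export
sample_scene_points <- function(scene, rng_seed = 1L, wood_density = 4000,
                                materials = c("stem", "branch",
                                              "foliage")) {
  stopifnot(inherits(scene, "scene"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  prims <- scene$primitives
  out <- list()
  for (i in seq_len(nrow(prims))) {
    pr <- prims[i, ]
    if (!pr$material %in% materials) next
    if (pr$material == "foliage") {
      n <- stats::rpois(1, pr$density * pi * pr$radius^2)
      if (n == 0L) next
      # uniform on the disc, in an orthonormal frame of its plane
      a <- c(pr$ax, pr$ay, pr$az)
      u <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * a) * a
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      rr <- pr$radius * sqrt(stats::runif(n))
      an <- stats::runif(n, 0, 2 * pi)
      pts <- cbind(pr$bx, pr$by, pr$bz) [rep(1, n), , drop = FALSE] +
        outer(rr * cos(an), e1) + outer(rr * sin(an), e2)
    } else {
      area <- 2 * pi * pr$radius * pr$len
      n <- stats::rpois(1, wood_density * area)
      if (n == 0L) next
      a <- c(pr$ax, pr$ay, pr$az)
      u <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- u - sum(u * a) * a
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      s <- stats::runif(n, 0, pr$len)
      an <- stats::runif(n, 0, 2 * pi)
      pts <- cbind(pr$bx + a[1] * s, pr$by + a[2] * s, pr$bz + a[3] * s) +
        pr$radius * (outer(cos(an), e1) + outer(sin(an), e2))
    }
    out[[length(out) + 1L]] <- data.frame(
      X = pts[, 1], Y = pts[, 2], Z = pts[, 3], material = pr$material,
      tree = pr$tree, prim = i, moving = pr$moving)
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(X = numeric(0), Y = numeric(0), Z = numeric(0),
               material = character(0), tree = integer(0),
               prim = integer(0), moving = logical(0))
  rownames(res) <- NULL
  res
}

#' Simulate a scan sequence over fixed scene geometry
#'
#' Re-observes the same base surface points (from [sample_scene_points()])
#' at a series of times: moving points are displaced by the motion law and
#' every coordinate receives fresh iid Gaussian measurement noise per scan —
#' the "same target, resampled noise" regime of a fixed scanner revisiting
#' its angular grid.
#'
#' @param base_points a [sample_scene_points()] data frame.
#' @param times_h numeric vector of scan times (hours since epoch).
#' @param motion optional [motion_spec()].
#' @param noise_sd per-coordinate measurement noise sd (m, default 0.001).
#' @param rng_seed seed; scan t uses sub-stream `rng_seed + t`.
#' @param epoch campaign reference time (`POSIXct`).
#' @return list of [scan_cloud()]s with timestamps `epoch + times_h`.
#' @export
simulate_scan_sequence <- function(base_points, times_h, motion = NULL,
                                   noise_sd = 0.001, rng_seed = 1L,
                                   epoch = as.POSIXct("2020-04-30 00:00:00",
                                                      tz = "UTC")) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  n <- nrow(base_points)
  lapply(seq_along(times_h), function(t) {
    set.seed(rng_seed + t)
    disp <- motion_offset(motion, times_h[t])
    p <- base_points
    p$X <- p$X + ifelse(p$moving, disp[1], 0) + stats::rnorm(n, 0, noise_sd)
    p$Y <- p$Y + ifelse(p$moving, disp[2], 0) + stats::rnorm(n, 0, noise_sd)
    p$Z <- p$Z + ifelse(p$moving, disp[3], 0) + stats::rnorm(n, 0, noise_sd)
    # per-point provenance columns (material, tree, prim, moving) ride along
    scan_cloud(p, timestamp = epoch + times_h[t] * 3600,
               meta = list(time_h = times_h[t],
                           truth_displacement = disp))
  })
}

#' Sample a breast-height cylinder slab directly
#'
#' Generates stem-surface points on a visibility arc with radial Gaussian
#' surface noise — the controlled fixture for cylinder-fit validation. A
#' half-visible stem (the scanner sees one side) is `arc_deg = 180`, the
#' default facing +X.
#'
#' @param radius cylinder radius (m).
#' @param center axis position `c(x, y)` (m).
#' @param z_range slab height interval (m).
#' @param n number of points.
#' @param arc_deg visible azimuth arc width in degrees (default 180).
#' @param facing_deg azimuth of the arc centre (default 0 = +X).
#' @param noise_sd radial surface noise sd (m).
#' @param outlier_frac fraction of gross outliers displaced radially by up
#'   to 5 cm (default 0).
#' @param rng_seed seed.
#' @return a [scan_cloud()] of the slab points.
#' @export
sample_cylinder_slab <- function(radius = 0.0824, center = c(0, 0),
                                 z_range = c(1.0, 1.6), n = 3000L,
                                 arc_deg = 180, facing_deg = 0,
                                 noise_sd = 0.003, outlier_frac = 0,
                                 rng_seed = 1L) {
  stopifnot(radius > 0, n > 0, arc_deg > 0, noise_sd >= 0)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  half <- arc_deg / 2 * pi / 180
  az <- stats::runif(n, -half, half) + facing_deg * pi / 180
  r <- radius + stats::rnorm(n, 0, noise_sd)
  n_out <- round(outlier_frac * n)
  if (n_out > 0L) {
    idx <- sample.int(n, n_out)
    r[idx] <- r[idx] + stats::runif(n_out, 0.01, 0.05) *
      sample(c(-1, 1), n_out, replace = TRUE)
  }
  z <- stats::runif(n, z_range[1], z_range[2])
  scan_cloud(data.frame(X = center[1] + r * cos(az),
                        Y = center[2] + r * sin(az),
                        Z = z),
             meta = list(true_radius = radius, noise_sd = noise_sd,
                         arc_deg = arc_deg, outlier_frac = outlier_frac))
}

#' Synthesize a per-minute weather series
#'
#' Emulates the 1-minute weather records the gate consumes: hour blocks are
#' independently calm with probability `calm_fraction` (wind with a mild
#' diurnal cycle plus noise, strictly below 3 m/s, no rain) or disturbed
#' (gusts at or above 3 m/s, sometimes with a rain episode). A scan started
#' on the hour therefore passes the default gate iff its block is calm.
#'
#' @param days number of days (>= 1).
#' @param rng_seed integer seed.
#' @param calm_fraction probability that an hour block is calm.
#' @param start first day (`Date` or string).
#' @return a `weather_series` (see [read_weather()]).
#' @export
synth_weather <- function(days, rng_seed = 1L, calm_fraction = 0.5,
                          start = "2020-04-01") {
  stopifnot(days >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  n_min <- days * 24 * 60
  ts <- t0 + (seq_len(n_min) - 1L) * 60
  hour_of <- as.integer((seq_len(n_min) - 1L) %/% 60)
  n_hours <- days * 24
  calm <- stats::runif(n_hours) < calm_fraction
  rainy <- !calm & stats::runif(n_hours) < 0.3
  # diurnal base: calmer at night, windier mid-afternoon
  hod <- (hour_of %% 24)
  base <- 1.2 + 0.8 * sin(2 * pi * (hod - 9) / 24)
  wind <- ifelse(calm[hour_of + 1L],
                 pmin(2.9, pmax(0.1, base + stats::rnorm(n_min, 0, 0.25))),
                 3.2 + abs(stats::rnorm(n_min, 1.5, 1.2)))
  precip <- ifelse(rainy[hour_of + 1L],
                   round(stats::runif(n_min, 0.2, 4), 1), 0)
  w <- data.frame(timestamp = ts,
                  wind_speed = wind,
                  wind_direction = stats::runif(n_min, 0, 360),
                  temperature = 2 + 6 * sin(2 * pi * (hod - 6) / 24) +
                    stats::rnorm(n_min, 0, 0.5),
                  precipitation = precip,
                  relative_humidity = pmin(100, pmax(
                    20, 70 + stats::rnorm(n_min, 0, 10))))
  read_weather(w)
}
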