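#' Seed compact clusters on an initial scan
#'
#' First stage of the short-term (circadian) movement tracker. Cluster seeds
#' are drawn by random rejection from the (cleaned, subsampled) initial
#' cloud: points are visited in a seeded random order and accepted as seeds
#' when at least `max_diameter` from every previously accepted seed. Every
#' point is then assigned to its nearest seed provided it lies within
#' `max_diameter` of it (farther points stay unassigned, enforcing the
#' maximum initial cluster diameter). Clusters smaller than `min_size` are
#' dissolved and their points reassigned to the nearest surviving seed
#' within `max_diameter`, cascading until all surviving clusters meet the
#' minimum size. Station defaults: 100-point minimum size, 0.15 m maximum
#' diameter. Deterministic given `rng_seed`.
#'
#' @param cloud the initial [scan_cloud()] (preprocessed).
#' @param min_size minimum accepted cluster size (default 100).
#' @param max_diameter maximum initial cluster diameter in metres
#'   (default 0.15).
#' @param rng_seed RNG seed for the random seed draw.
#' @return object of class `cluster_model`: `seeds` (matrix of surviving
#'   seed coordinates, rownames are cluster ids), `labels` (integer per
#'   point, 0 = unassigned), `parameters`, `rng_seed`, and the initial
#'   `cloud`.
#' @export
seed_clusters <- function(cloud, min_size = 100L, max_diameter = 0.15,
                          rng_seed = 1L) {
  stopifnot(inherits(cloud, "scan_cloud"), max_diameter > 0, min_size >= 1)
  xyz <- as_xyz_matrix(cloud$points[, c("X", "Y", "Z")])
  n <- nrow(xyz)
  if (n == 0L) stop("empty initial cloud", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(rng_seed)
  perm <- sample.int(n)

  # random rejection: greedy spacing filter over the permuted order
  is_seed <- cpp_greedy_subsample(xyz[perm, , drop = FALSE], max_diameter)
  seed_idx <- perm[is_seed]
  seeds <- xyz[seed_idx, , drop = FALSE]

  assign_pts <- function(active) {
    nn <- cpp_nn1(xyz, seeds[active, , drop = FALSE], max_diameter)
    lab <- integer(n)
    hit <- nn$index > 0L
    lab[hit] <- which(active)[nn$index[hit]]
    lab
  }

  active <- rep(TRUE, nrow(seeds))
  labels <- assign_pts(active)
  repeat {
    sizes <- tabulate(labels, nbins = nrow(seeds))
    small <- active & sizes < min_size
    if (!any(small)) break
    active[small] <- FALSE
    if (!any(active)) {
      stop(paste("no cluster reaches the minimum size;",
                 "reduce min_size or increase max_diameter"), call. = FALSE)
    }
    labels <- assign_pts(active)
  }

  # renumber surviving clusters 1..K in seed-draw order
  survivors <- which(active)
  remap <- integer(nrow(seeds))
  remap[survivors] <- seq_along(survivors)
  labels <- c(0L, remap)[labels + 1L] # 0 stays unassigned
  seeds <- seeds[survivors, , drop = FALSE]
  rownames(seeds) <- seq_along(survivors)

  structure(list(seeds = seeds, labels = labels, cloud = cloud,
                 parameters = list(min_size = as.integer(min_size),
                                   max_diameter = max_diameter),
                 rng_seed = rng_seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "cluster_model: %d clusters over %d points (%d unassigned), seed %d\n",
    nrow(x$seeds), length(x$labels), sum(x$labels == 0L), x$rng_seed))
  invisible(x)
}

#' Propagate cluster labels through a scan sequence
#'
#' Labels each point of scan t+1 with the label of its nearest neighbour in
#' scan t, chained through the time-ordered sequence starting from the
#' initial cluster model. A match-radius cap (default: the model's maximum
#' cluster diameter) prevents labels from bleeding across branches: points
#' farther than the cap from every point of the previous scan stay
#' unassigned, and unassigned labels propagate as unassigned.
#'
#' @param model a [seed_clusters()] result; its cloud is the first scan.
#' @param clouds time-ordered list of the subsequent [scan_cloud()]s
#'   (scans 2..T; do not repeat the initial scan).
#' @param match_radius nearest-neighbour cap in metres (default
#'   `model$parameters$max_diameter`).
#' @return list of integer label vectors, one per scan including the initial
#'   one (length `length(clouds) + 1`).
#' @export
propagate_labels <- function(model, clouds, match_radius = NULL) {
  stopifnot(inherits(model, "cluster_model"))
  if (is.null(match_radius)) match_radius <- model$parameters$max_diameter
  labels <- list(model$labels)
  prev_xyz <- as_xyz_matrix(model$cloud$points[, c("X", "Y", "Z")])
  prev_lab <- model$labels
  for (t in seq_along(clouds)) {
    cl <- clouds[[t]]
    stopifnot(inherits(cl, "scan_cloud"))
    if (npoints(cl) == 0L) {
      stop("empty scan in sequence at position ", t,
           if (!is.null(cl$timestamp)) paste0(" (", format(cl$timestamp), ")")
           else "", call. = FALSE)
    }
    xyz <- as_xyz_matrix(cl$points[, c("X", "Y", "Z")])
    nn <- cpp_nn1(xyz, prev_xyz, match_radius)
    lab <- integer(nrow(xyz))
    hit <- nn$index > 0L
    lab[hit] <- prev_lab[nn$index[hit]]
    labels[[length(labels) + 1L]] <- lab
    prev_xyz <- xyz
    prev_lab <- lab
  }
  labels
}

#' Cluster-median displacement series
#'
#' For each scan and cluster, computes the component-wise median of the
#' member coordinates and the displacement of that median from its position
#' in the initial scan; the Euclidean norm is the movement amplitude and the
#' Z component the vertical movement. Clusters whose membership drops below
#' `min_membership` (default 20%) of the initial count are flagged; a
#' cluster absent from a scan yields a flagged row with `NA` medians rather
#' than an error, truncating its usable series.
#'
#' @param clouds time-ordered list of [scan_cloud()]s, first = initial scan.
#' @param labels per-scan label vectors from [propagate_labels()].
#' @param timestamps optional per-scan timestamps (defaults to the clouds'
#'   own, else the scan index).
#' @param min_membership flag threshold as a fraction of initial cluster
#'   size (default 0.2).
#' @return data frame of class `displacement_series`: `cluster`, `scan`,
#'   `timestamp`, medians `mx/my/mz`, displacement `dx/dy/dz`, `amplitude`,
#'   `vertical`, `n_points`, `flagged`.
#' @export
displacement_series <- function(clouds, labels, timestamps = NULL,
                                min_membership = 0.2) {
  stopifnot(length(clouds) == length(labels))
  n_scan <- length(clouds)
  if (is.null(timestamps)) {
    ts <- lapply(clouds, `[[`, "timestamp")
    timestamps <- if (any(vapply(ts, is.null, logical(1)))) {
      seq_len(n_scan)
    } else {
      as.POSIXct(vapply(ts, as.numeric, 0), origin = "1970-01-01",
                 tz = "UTC")
    }
  }
  k <- max(labels[[1]])
  init_size <- tabulate(labels[[1]], nbins = k)
  med3 <- function(xyz, lab) {
    # component-wise (marginal) median per cluster
    out <- matrix(NA_real_, k, 3)
    cnt <- tabulate(lab, nbins = k)
    assigned <- lab > 0L
    groups <- split(which(assigned), lab[assigned])
    for (g in names(groups)) {
      sel <- groups[[g]]
      c <- as.integer(g)
      out[c, ] <- c(stats::median(xyz[sel, 1]), stats::median(xyz[sel, 2]),
                    stats::median(xyz[sel, 3]))
    }
    list(med = out, count = cnt)
  }
  init <- med3(as_xyz_matrix(clouds[[1]]$points[, c("X", "Y", "Z")]),
               labels[[1]])
  rows <- vector("list", n_scan)
  for (t in seq_len(n_scan)) {
    m <- if (t == 1L) init else
      med3(as_xyz_matrix(clouds[[t]]$points[, c("X", "Y", "Z")]),
           labels[[t]])
    d <- m$med - init$med
    rows[[t]] <- data.frame(
      cluster = seq_len(k), scan = t, timestamp = timestamps[t],
      mx = m$med[, 1], my = m$med[, 2], mz = m$med[, 3],
      dx = d[, 1], dy = d[, 2], dz = d[, 3],
      amplitude = sqrt(rowSums(d^2)),
      vertical = d[, 3],
      n_points = m$count,
      flagged = m$count < min_membership * init_size)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("displacement_series", "data.frame")
  out
}

#' Write a displacement series to CSV
#' @param series a [displacement_series()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_displacement_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
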