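#' Specification of a Bernoulli co-activation generator
#'
#' Each homotopic pair draws, per experiment, one of the four joint
#' activation states with probabilities `(theta1, theta2, theta3, theta4)` =
#' P(both), P(left only), P(right only), P(neither) — the generative side of
#' the Bernoulli model that Patel's kappa estimates.
#'
#' @param theta Probability 4-vector, or an `n_pairs` x 4 matrix with one row
#'   per pair. Each row must be nonnegative and sum to 1 (tolerance 1e-9).
#' @param n_experiments Number of experiments to simulate.
#' @param foci_per_active_region Foci placed in each active region (one focus
#'   group per active region per experiment).
#' @param seed Integer seed.
#' @return A `coactivation_spec`.
#' @export
coactivation_spec <- function(theta, n_experiments,
                              foci_per_active_region = 1L, seed = 1L) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  stopifnot(ncol(theta) == 4L, n_experiments >= 1L,
            foci_per_active_region >= 1L)
  if (any(theta < 0)) stop("theta probabilities must be nonnegative",
                           call. = FALSE)
  if (any(abs(rowSums(theta) - 1) > 1e-9)) {
    stop("each theta vector must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(list(theta = theta, n_experiments = as.integer(n_experiments),
                 foci_per_active_region = as.integer(foci_per_active_region),
                 seed = as.integer(seed)),
            class = "coactivation_spec")
}

#' Synthetic symmetric atlas of mirrored spherical parcels
#'
#' Hosts `n_pairs` left-hemisphere spherical blobs on a deterministic lattice
#' (seeded jitter optional through `jitter_vox`) and mirrors them exactly
#' onto the right hemisphere, yielding `2 * n_pairs` labels with an explicit
#' pair table. Centres are spaced at least `spacing` mm apart so parcels are
#' disjoint.
#'
#' @param grid A mirror-closed `volume_grid`.
#' @param n_pairs Number of homotopic pairs (>= 1).
#' @param radius Parcel radius in mm.
#' @param spacing Minimum centre-to-centre distance in mm; default keeps
#'   parcels disjoint with a one-voxel gap.
#' @param seed Integer seed (controls the jitter; the layout is otherwise
#'   deterministic).
#' @param jitter_vox Integer jitter (in voxels, per axis) applied to each
#'   centre; 0 for a fully deterministic layout.
#' @return A `parcellation` with labels 1..n_pairs (left) and
#'   n_pairs+1..2*n_pairs (right).
#' @export
gen_synthetic_atlas <- function(grid, n_pairs, radius = 6,
                                spacing = 2 * radius + max(grid$voxel_size),
                                seed = 1L, jitter_vox = 0L) {
  stopifnot(n_pairs >= 1L)
  perm <- mirror_linear_perm(grid)
  xs <- grid_axis_coords(grid, 1L)
  ys <- grid_axis_coords(grid, 2L)
  zs <- grid_axis_coords(grid, 3L)
  step <- pmax(1L, as.integer(ceiling(spacing / grid$voxel_size)))
  cx <- xs[xs <= -radius]
  if (!length(cx)) stop("grid too narrow to host parcels of radius ", radius,
                        call. = FALSE)
  cx <- cx[seq(1L, length(cx), by = step[1])]
  margin_y <- ys[ys >= min(ys) + radius & ys <= max(ys) - radius]
  margin_z <- zs[zs >= min(zs) + radius & zs <= max(zs) - radius]
  cy <- margin_y[seq(1L, length(margin_y), by = step[2])]
  cz <- margin_z[seq(1L, length(margin_z), by = step[3])]
  if (!length(cy) || !length(cz)) {
    stop("grid too small to host parcels of radius ", radius, call. = FALSE)
  }
  centers <- as.matrix(expand.grid(x = cx, y = cy, z = cz))
  if (nrow(centers) < n_pairs) {
    stop("grid can host only ", nrow(centers), " parcels of radius ", radius,
         " at spacing ", spacing, "; ", n_pairs, " requested", call. = FALSE)
  }
  centers <- centers[seq_len(n_pairs), , drop = FALSE]
  if (jitter_vox > 0L) {
    local_seed(seed, {
      centers <- centers + matrix(
        sample(seq(-jitter_vox, jitter_vox), 3L * n_pairs, replace = TRUE),
        ncol = 3) * rep(grid$voxel_size, each = n_pairs)
    })
  }
  labels <- array(0L, dim = grid$dims)
  idx <- as.matrix(expand.grid(i = seq_along(xs), j = seq_along(ys),
                               k = seq_along(zs)))
  w <- cbind(xs[idx[, 1]], ys[idx[, 2]], zs[idx[, 3]])
  for (p in seq_len(n_pairs)) {
    d2 <- (w[, 1] - centers[p, 1])^2 + (w[, 2] - centers[p, 2])^2 +
      (w[, 3] - centers[p, 3])^2
    blob <- d2 <= radius^2 & w[, 1] < 0
    if (!any(blob)) stop("parcel ", p, " is empty", call. = FALSE)
    lin <- (idx[blob, 3] - 1L) * grid$dims[1] * grid$dims[2] +
      (idx[blob, 2] - 1L) * grid$dims[1] + idx[blob, 1]
    if (any(labels[lin] != 0L)) stop("parcels overlap; increase spacing",
                                     call. = FALSE)
    labels[lin] <- p
    labels[perm[lin]] <- n_pairs + p
  }
  nm <- stats::setNames(c(paste0("L", seq_len(n_pairs)),
                          paste0("R", seq_len(n_pairs))),
                        c(seq_len(n_pairs), n_pairs + seq_len(n_pairs)))
  res <- parcellation(grid, labels, names = nm,
                      provenance = sprintf(
                        "synthetic atlas: %d pairs, radius %g mm, seed %d",
                        n_pairs, radius, seed))
  res$pairs <- tibble::tibble(pair_id = seq_len(n_pairs),
                              left = seq_len(n_pairs),
                              right = n_pairs + seq_len(n_pairs),
                              n_voxels = vapply(seq_len(n_pairs), function(p)
                                sum(labels == p), integer(1)))
  res
}

#' Simulate experiments under a known co-activation structure
#'
#' For every experiment and homotopic pair, draws one of the four joint
#' states with the pair's `(theta1..theta4)`; each active region receives
#' `foci_per_active_region` foci placed uniformly over its voxel centres.
#' Empirical joint-state frequencies converge to theta as the number of
#' experiments grows, so the generator is the exact inverse of the kappa
#' estimator's model.
#'
#' @param atlas A paired `parcellation` (e.g. from [gen_synthetic_atlas()]).
#' @param spec A [coactivation_spec()].
#' @return A `foci_collection`; experiments with no active region anywhere
#'   are retained in the experiment index through attribute
#'   `"all_experiments"` (they simply contribute no rows).
#' @export
gen_coactivation_experiments <- function(atlas, spec) {
  stopifnot(inherits(atlas, "parcellation"),
            inherits(spec, "coactivation_spec"))
  if (is.null(atlas$pairs)) atlas$pairs <- homotopic_pairs(atlas)
  n_pairs <- nrow(atlas$pairs)
  theta <- spec$theta
  if (nrow(theta) == 1L) theta <- theta[rep(1L, n_pairs), , drop = FALSE]
  stopifnot(nrow(theta) == n_pairs)
  n <- spec$n_experiments
  k <- spec$foci_per_active_region
  region_vox <- lapply(c(atlas$pairs$left, atlas$pairs$right),
                       function(l) which(atlas$labels == l))
  names(region_vox) <- c(atlas$pairs$left, atlas$pairs$right)
  ids <- sprintf("exp_%05d", seq_len(n))
  out <- local_seed(spec$seed, {
    rows <- vector("list", n_pairs)
    for (p in seq_len(n_pairs)) {
      states <- sample.int(4L, n, replace = TRUE, prob = theta[p, ])
      left_on <- states %in% c(1L, 2L)
      right_on <- states %in% c(1L, 3L)
      pick <- function(on, label) {
        vox <- region_vox[[as.character(label)]]
        e <- which(on)
        if (!length(e)) return(NULL)
        sel <- vox[sample.int(length(vox), length(e) * k, replace = TRUE)]
        w <- voxel_to_world(atlas$grid, arrayInd(sel, atlas$grid$dims))
        tibble::tibble(experiment_id = rep(ids[e], each = k),
                       x = w[, 1], y = w[, 2], z = w[, 3])
      }
      rows[[p]] <- dplyr::bind_rows(pick(left_on, atlas$pairs$left[p]),
                                    pick(right_on, atlas$pairs$right[p]))
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) == 0L) {
    stop("no foci generated: all pairs drew the 'neither' state throughout",
         call. = FALSE)
  }
  out <- out[order(out$experiment_id), , drop = FALSE]
  res <- foci_collection(out, space = "TAL",
                         provenance = sprintf(
                           "synthetic Bernoulli co-activation, seed %d",
                           spec$seed))
  attr(res, "all_experiments") <- ids
  res
}

#' Specification of a planted-correlation resting-state simulation
#'
#' @param n_timepoints Number of volumes (the emulated acquisition default is
#'   225 timepoints).
#' @param rho Target Pearson correlation between each mirror-voxel pair, in
#'   \\[-1, 1\\]; a scalar or an array over the grid (the left voxel's value
#'   is used per pair).
#' @param noise_sd Marginal standard deviation of every voxel series.
#' @param ar AR(1) coefficient for temporal autocorrelation (0 = white).
#' @param seed Integer seed.
#' @return A `rest_spec`.
#' @export
rest_spec <- function(n_timepoints = 225L, rho = 0, noise_sd = 1, ar = 0,
                      seed = 1L) {
  if (any(abs(rho) > 1)) stop("|rho| must be <= 1", call. = FALSE)
  stopifnot(n_timepoints >= 3L, noise_sd > 0, abs(ar) < 1)
  structure(list(n_timepoints = as.integer(n_timepoints), rho = rho,
                 noise_sd = noise_sd, ar = ar, seed = as.integer(seed)),
            class = "rest_spec")
}

#' Simulate 4-D rest data with planted homotopic correlation
#'
#' Each mirror-voxel pair receives series built from a shared Gaussian
#' factor plus independent noise, with the mixing chosen so the population
#' Pearson correlation between the pair equals the planted rho at that voxel
#' and the marginal variance is constant (`noise_sd^2`). Temporal structure
#' is white by default; an AR(1) option filters all sources with unit
#' marginal variance preserved.
#'
#' @param grid A mirror-closed `volume_grid`.
#' @param spec A [rest_spec()].
#' @return A `rest_series`.
#' @export
gen_rest_timeseries <- function(grid, spec) {
  stopifnot(inherits(spec, "rest_spec"))
  perm <- mirror_linear_perm(grid)
  nvox <- prod(grid$dims)
  xs <- grid_axis_coords(grid, 1L)
  xw <- as.vector(xs[slice.index(array(0L, grid$dims), 1L)])
  left <- which(xw < 0)
  mid <- which(abs(xw) < 1e-9)
  rho <- if (length(spec$rho) == 1L) rep(spec$rho, nvox) else {
    stopifnot(length(spec$rho) == nvox)
    as.numeric(spec$rho)
  }
  TT <- spec$n_timepoints
  innov <- function(nr) {
    m <- matrix(stats::rnorm(nr * TT), nr, TT)
    if (spec$ar != 0) {
      m <- t(apply(m, 1L, function(x)
        as.numeric(stats::filter(x * sqrt(1 - spec$ar^2), spec$ar,
                                 method = "recursive"))))
    }
    m
  }
  data <- local_seed(spec$seed, {
    f <- innov(length(left))
    e1 <- innov(length(left))
    e2 <- innov(length(left))
    r <- rho[left]
    a <- sqrt(abs(r)); b <- sqrt(1 - abs(r))
    s_left <- a * f + b * e1
    s_right <- sign(r) * a * f + b * e2
    s_right[r == 0, ] <- e2[r == 0, ]     # pure noise when rho = 0
    arr <- array(0, dim = c(nvox, TT))
    arr[left, ] <- s_left
    arr[perm[left], ] <- s_right
    if (length(mid)) arr[mid, ] <- innov(length(mid))
    arr * spec$noise_sd
  })
  rest_series(grid, array(data, dim = c(grid$dims, TT)))
}
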