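#' Gaussian kernel width from FWHM
#'
#' The modeled-activation kernel is an isotropic 3-D Gaussian whose standard
#' deviation derives from the full-width half-maximum:
#' sigma = FWHM / sqrt(8 ln 2).
#'
#' @param fwhm Full-width half-maximum in mm (> 0).
#' @return Standard deviation sigma in mm.
#' @examples
#' sigma_from_fwhm(sqrt(8 * log(2)))  # exactly 1
#' @export
sigma_from_fwhm <- function(fwhm) {
  if (any(fwhm <= 0)) stop("fwhm must be > 0", call. = FALSE)
  fwhm / sqrt(8 * log(2))
}

#' Modeled-activation kernel specification
#'
#' @param fwhm Full-width half-maximum in mm. The default 10 mm gives a
#'   Gaussian cloud whose effective extent is around 12 mm around the focus,
#'   the scale typical of the spatial uncertainty of coordinate-based
#'   meta-analytic data.
#' @param truncation Truncation radius in multiples of sigma. At the default
#'   5, the per-focus probability mass lost is below 1e-5 of the peak.
#' @return A `kernel_spec` with fields `fwhm`, `sigma`, `truncation_radius`.
#' @export
kernel_spec <- function(fwhm = 10, truncation = 5) {
  sigma <- sigma_from_fwhm(fwhm)
  structure(list(fwhm = fwhm, sigma = sigma,
                 truncation_radius = truncation * sigma),
            class = "kernel_spec")
}

#' Midline offset-adjustment band
#'
#' Foci near the midline spread modeled activation into the opposite
#' hemisphere, inflating apparent co-activation there. Within a band of
#' `2 * half_width` mm along the midline, contributions from foci in the
#' opposite hemisphere are attenuated by a weight w(|x|) that is 0 at the
#' midline and reaches 1 at the band edge, so voxels further from the midline
#' receive progressively less interference. `"linear_ramp"` (default) uses
#' w = |x| / half_width; `"inverse_distance"` uses the affine-in-1/d form
#' w = (1/eps - 1/|x|) / (1/eps - 1/half_width), clamped to \\[0, 1\\].
#'
#' @param half_width Band half-width in mm (default 12, a 24-mm band).
#' @param mode `"linear_ramp"` or `"inverse_distance"`.
#' @param eps Inner guard distance in mm for the inverse-distance mode.
#' @return A `midline_band` object.
#' @export
midline_band <- function(half_width = 12,
                         mode = c("linear_ramp", "inverse_distance"),
                         eps = 1) {
  mode <- match.arg(mode)
  if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
  structure(list(half_width = half_width, mode = mode, eps = eps),
            class = "midline_band")
}

band_weight <- function(band, d) {
  d <- abs(d)
  w <- if (band$mode == "linear_ramp") {
    d / band$half_width
  } else {
    (1 / band$eps - 1 / pmax(d, band$eps)) /
      (1 / band$eps - 1 / band$half_width)
  }
  w[d >= band$half_width] <- 1
  pmin(pmax(w, 0), 1)
}

#' Modeled-activation (MA) map of one experiment
#'
#' Places a truncated isotropic 3-D Gaussian probability kernel around every
#' focus — per-focus value at distance d is
#' `g(d) = V_voxel * exp(-d^2 / (2 sigma^2)) / ((2 pi)^{3/2} sigma^3)`, zero
#' beyond the truncation radius — and combines foci by probabilistic union
#' `MA = 1 - prod(1 - g)`, so MA values lie in \\[0, 1). With a
#' [midline_band()], cross-hemisphere contributions near the midline are
#' attenuated per focus before the union.
#'
#' @param foci An n x 3 matrix of world mm coordinates, or a
#'   `foci_collection` restricted to one experiment.
#' @param grid A `volume_grid` (axis-aligned).
#' @param kernel A [kernel_spec()].
#' @param band Optional [midline_band()] for the offset adjustment.
#' @return A `voxel_map` of kind `"MA_probability"` with the kernel attached
#'   as attribute `"kernel"`.
#' @export
ma_map <- function(foci, grid, kernel = kernel_spec(), band = NULL) {
  xyz <- foci_matrix(foci)
  if (nrow(xyz) == 0L) stop("experiment has zero foci", call. = FALSE)
  acc <- ma_accumulate(xyz, grid, kernel, band)
  m <- voxel_map(grid, -expm1(acc), kind = "MA_probability")
  attr(m, "kernel") <- kernel
  attr(m, "band") <- band
  m
}

foci_matrix <- function(foci) {
  if (inherits(foci, "foci_collection") || is.data.frame(foci)) {
    cbind(foci$x, foci$y, foci$z)
  } else {
    matrix(as.numeric(foci), ncol = 3)
  }
}

# Accumulates sum(log(1 - g_f)) over foci into a 3-D array. Foci outside the
# grid bounding box are dropped with a warning.
ma_accumulate <- function(xyz, grid, kernel, band = NULL) {
  stopifnot(axis_aligned(grid))
  d <- grid$dims
  xs <- grid_axis_coords(grid, 1L)
  ys <- grid_axis_coords(grid, 2L)
  zs <- grid_axis_coords(grid, 3L)
  R <- kernel$truncation_radius
  R2 <- R^2
  two_s2 <- 2 * kernel$sigma^2
  c0 <- prod(grid$voxel_size) / ((2 * pi)^1.5 * kernel$sigma^3)
  if (c0 >= 1) {
    warning("kernel peak >= 1 at this voxel size; values capped below 1",
            call. = FALSE)
  }
  half_vox <- grid$voxel_size / 2
  inside <- xyz[, 1] >= min(xs) - half_vox[1] &
    xyz[, 1] <= max(xs) + half_vox[1] &
    xyz[, 2] >= min(ys) - half_vox[2] &
    xyz[, 2] <= max(ys) + half_vox[2] &
    xyz[, 3] >= min(zs) - half_vox[3] &
    xyz[, 3] <= max(zs) + half_vox[3]
  if (!all(inside)) {
    warning(sum(!inside), " foci outside the grid bounding box dropped",
            call. = FALSE)
    xyz <- xyz[inside, , drop = FALSE]
  }
  acc <- array(0, dim = d)
  for (f in seq_len(nrow(xyz))) {
    fx <- xyz[f, 1]; fy <- xyz[f, 2]; fz <- xyz[f, 3]
    ii <- which(abs(xs - fx) <= R)
    jj <- which(abs(ys - fy) <= R)
    kk <- which(abs(zs - fz) <= R)
    if (!length(ii) || !length(jj) || !length(kk)) next
    dx2 <- (xs[ii] - fx)^2
    dy2 <- (ys[jj] - fy)^2
    dz2 <- (zs[kk] - fz)^2
    n1 <- length(ii); n2 <- length(jj); n3 <- length(kk)
    D2 <- dx2 + rep(dy2, each = n1)
    D2 <- D2 + rep(dz2, each = n1 * n2)
    g <- c0 * exp(-D2 / two_s2)
    g[D2 > R2] <- 0
    if (!is.null(band)) {
      xv <- xs[ii]
      cross <- sign(xv) * sign(fx) <= 0 & abs(xv) < band$half_width
      if (any(cross)) {
        w <- rep(1, n1)
        w[cross] <- band_weight(band, xv[cross])
        g <- g * w                      # recycles along the x (fastest) dim
      }
    }
    g <- pmin(g, 1 - 1e-12)
    acc[ii, jj, kk] <- acc[ii, jj, kk] + log1p(-g)
  }
  acc
}

#' Apply the midline offset adjustment to an MA map
#'
#' The probabilistic union is not decomposable after the fact, so the map is
#' rebuilt from its foci with the band applied to every per-focus
#' contribution. Voxels with |x| at or beyond the band half-width are
#' untouched, as are maps whose foci and voxels share a hemisphere.
#'
#' @param ma A `voxel_map` produced by [ma_map()].
#' @param band A [midline_band()].
#' @param foci The foci the map was built from.
#' @param kernel Kernel used for `ma`; defaults to the one attached to it.
#' @return The adjusted MA `voxel_map`.
#' @export
midline_adjust <- function(ma, band, foci, kernel = attr(ma, "kernel")) {
  stopifnot(inherits(ma, "voxel_map"), inherits(band, "midline_band"))
  if (is.null(kernel)) kernel <- kernel_spec()
  ma_map(foci, ma$grid, kernel, band = band)
}

#' Probabilistic union of modeled-activation maps
#'
#' Voxel-wise `ALE = 1 - prod(1 - MA_e)` over experiments; commutative and
#' associative, with the all-zero map as the neutral element. A voxel-wise
#' maximum variant is available for compatibility with max-based ALE
#' implementations.
#'
#' @param mas List of `voxel_map`s on one grid, values in \\[0, 1).
#' @param mode `"probabilistic"` (default) or `"max"`.
#' @return A `voxel_map` of kind `"ALE"`.
#' @export
ale_union <- function(mas, mode = c("probabilistic", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(mas) >= 1L)
  g0 <- mas[[1]]$grid
  for (m in mas) stop_if_grid_mismatch(g0, m$grid)
  vals <- if (mode == "probabilistic") {
    1 - Reduce(`*`, lapply(mas, function(m) 1 - m$values))
  } else {
    Reduce(pmax, lapply(mas, function(m) m$values))
  }
  voxel_map(g0, pmin(vals, 1 - 1e-15), kind = "ALE")
}

#' ALE map of a foci collection
#'
#' Convenience wrapper: one MA map per experiment, then the probabilistic
#' union across experiments.
#'
#' @param foci A `foci_collection`.
#' @inheritParams ma_map
#' @param mode Union mode passed to [ale_union()].
#' @return A `voxel_map` of kind `"ALE"`.
#' @export
ale <- function(foci, grid, kernel = kernel_spec(), band = NULL,
                mode = "probabilistic") {
  stopifnot(inherits(foci, "foci_collection"))
  by_exp <- split(seq_len(nrow(foci)), foci$experiment_id)
  mas <- lapply(by_exp, function(idx)
    ma_map(foci[idx, , drop = FALSE], grid, kernel, band))
  ale_union(mas, mode = mode)
}

#' Cluster-level significance for an ALE map
#'
#' Builds a null by redrawing each experiment's foci uniformly at in-mask
#' voxel centres (foci-per-experiment counts preserved) and recomputing the
#' ALE map. The cluster-forming threshold is the `1 - cluster_forming_p`
#' quantile of the pooled permuted ALE scores; the null distribution of the
#' maximum suprathreshold 6-connected cluster size is recorded per
#' permutation, and an observed cluster is kept when its empirical cluster
#' p-value `mean(null max size >= size)` is at most `alpha`.
#'
#' @param ale_map Observed ALE `voxel_map`.
#' @param foci The `foci_collection` the map came from (defines the null).
#' @param kernel,band Kernel and optional midline band used for `ale_map`.
#' @param n_permutations Number of simulated experiment series (>= 100
#'   recommended; fewer triggers a warning about unstable quantiles).
#' @param cluster_forming_p Voxel-level tail probability forming clusters.
#' @param alpha Cluster-level significance threshold.
#' @param seed Integer seed; the null is reproducible for a fixed seed.
#' @return A list with `mask` (binary `voxel_map` of significant voxels),
#'   `clusters` (tibble: id, size, p_cluster, kept), and `null` (a
#'   `cluster_null` with the forming threshold, max-size distribution and
#'   parameters).
#' @export
ale_cluster_threshold <- function(ale_map, foci, kernel = kernel_spec(),
                                  band = NULL, n_permutations = 1000,
                                  cluster_forming_p = 0.001, alpha = 0.05,
                                  seed = 1L) {
  stopifnot(inherits(ale_map, "voxel_map"))
  grid <- ale_map$grid
  mask <- grid_mask(grid)
  vox <- which(mask)
  if (!length(vox)) stop("empty mask", call. = FALSE)
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: null quantiles will be unstable",
            call. = FALSE)
  }
  counts <- table(foci$experiment_id)
  centers <- voxel_to_world(grid, arrayInd(vox, grid$dims))
  null_vals <- matrix(0, length(vox), n_permutations)
  local_seed(seed, {
    for (p in seq_len(n_permutations)) {
      acc <- array(0, dim = grid$dims)
      for (nf in as.integer(counts)) {
        pick <- centers[sample.int(length(vox), nf, replace = TRUE), ,
                        drop = FALSE]
        mam <- -expm1(ma_accumulate(pick, grid, kernel, band))
        acc <- acc + log1p(-pmin(mam, 1 - 1e-15))
      }
      null_vals[, p] <- -expm1(acc[vox])
    }
  })
  thr <- stats::quantile(null_vals, 1 - cluster_forming_p, names = FALSE)
  max_sizes <- apply(null_vals > thr, 2L, function(v) {
    cl <- label_clusters(vox[v], grid$dims)
    if (length(cl$sizes)) max(cl$sizes) else 0L
  })
  obs_vox <- vox[ale_map$values[vox] > thr]
  cl <- label_clusters(obs_vox, grid$dims)
  keep_vox <- logical(length(obs_vox))
  clusters <- tibble::tibble(id = integer(), size = integer(),
                             p_cluster = numeric(), kept = logical())
  if (length(cl$sizes)) {
    p_cl <- vapply(cl$sizes, function(s) mean(max_sizes >= s), numeric(1))
    kept <- p_cl <= alpha
    clusters <- tibble::tibble(id = seq_along(cl$sizes),
                               size = as.integer(cl$sizes),
                               p_cluster = p_cl, kept = kept)
    keep_vox <- kept[cl$membership]
  }
  out <- array(0, dim = grid$dims)
  out[obs_vox[keep_vox]] <- 1
  null <- structure(list(n_permutations = n_permutations,
                         cluster_forming_p = cluster_forming_p,
                         alpha = alpha, forming_threshold = thr,
                         max_cluster_sizes = as.integer(max_sizes),
                         seed = seed),
                    class = "cluster_null")
  list(mask = voxel_map(grid, out, kind = "mask"), clusters = clusters,
       null = null)
}

#' @export
print.cluster_null <- function(x, ...) {
  cat(sprintf(
    "<cluster_null> %d permutations, forming threshold %.4g (p=%g), alpha %g\n",
    x$n_permutations, x$forming_threshold, x$cluster_forming_p, x$alpha))
  invisible(x)
}

# 6-connected components over suprathreshold voxel linear indices.
label_clusters <- function(vox, dims) {
  if (!length(vox)) return(list(membership = integer(), sizes = integer()))
  pos <- integer(prod(dims)); pos[vox] <- seq_along(vox)
  nb <- neighbours6(vox, dims)
  from <- rep(seq_along(vox), 6L)
  to <- as.vector(nb)
  ok <- !is.na(to)
  from <- from[ok]; to <- pos[to[ok]]
  ok <- to > 0L
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (any(ok)) {
    g <- igraph::add_edges(g, rbind(from[ok], to[ok]))
  }
  comp <- igraph::components(g)
  list(membership = comp$membership, sizes = comp$csize)
}
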