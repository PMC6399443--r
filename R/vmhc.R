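#' Voxel-mirrored homotopic connectivity
#'
#' For every in-mask voxel, the Pearson correlation between its time series
#' and that of its x-mirror voxel, Fisher z-transformed (atanh, with |r|
#' clipped at 1 - 1e-7 and the clip counted in attribute `"n_clipped"`). The
#' input must already be preprocessed and normalised to a symmetric template;
#' no smoothing is applied before or after. The output map is symmetric by
#' construction: the value at a voxel equals the value at its mirror.
#'
#' @param series A `rest_series` on a mirror-closed grid (>= 3 timepoints).
#' @param mask Optional logical array; defaults to the grid mask.
#' @return A `voxel_map` of kind `"fisher_z"`. Voxels with a constant series
#'   at either end of the pair are `NA`.
#' @export
vmhc <- function(series, mask = NULL) {
  stopifnot(inherits(series, "rest_series"))
  grid <- series$grid
  if (!is.null(mask)) grid$mask <- array(as.logical(mask), dim = grid$dims)
  perm <- mirror_linear_perm(grid)
  d4 <- dim(series$data)
  TT <- d4[4]
  if (TT < 3L) stop("need at least 3 timepoints", call. = FALSE)
  X <- matrix(series$data, prod(grid$dims), TT)
  xc <- X - rowMeans(X)
  ss <- rowSums(xc^2)
  num <- rowSums(xc * xc[perm, , drop = FALSE])
  den <- sqrt(ss * ss[perm])
  r <- ifelse(den > 0, num / den, NA_real_)
  clip <- 1 - 1e-7
  n_clipped <- sum(abs(r) > clip, na.rm = TRUE)
  z <- atanh(pmin(pmax(r, -clip), clip))
  m <- grid_mask(grid)
  z[!as.vector(m)] <- 0
  z[as.vector(m) & !as.vector(m)[perm]] <- NA_real_  # mirror outside mask
  out <- voxel_map(grid, array(z, grid$dims), kind = "fisher_z")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Voxel-wise average of z maps
#'
#' Arithmetic mean over maps, excluding missing values per voxel; the number
#' of contributing maps per voxel is kept in attribute `"n_valid"`.
#'
#' @param maps Non-empty list of `voxel_map`s on one grid.
#' @return A `voxel_map` of the same kind as the inputs.
#' @export
group_average <- function(maps) {
  if (!length(maps)) stop("no maps to average", call. = FALSE)
  g0 <- maps[[1]]$grid
  for (m in maps) stop_if_grid_mismatch(g0, m$grid)
  sums <- array(0, dim = g0$dims)
  ns <- array(0L, dim = g0$dims)
  for (m in maps) {
    ok <- !is.na(m$values)
    sums[ok] <- sums[ok] + m$values[ok]
    ns <- ns + ok
  }
  avg <- ifelse(ns > 0, sums / ns, NA_real_)
  out <- voxel_map(g0, array(avg, g0$dims), kind = maps[[1]]$kind)
  attr(out, "n_valid") <- ns
  out
}

#' Standardise a map to z-points over the mask
#'
#' `(value - in-mask mean) / in-mask SD`; the output has mean 0 and SD 1 over
#' the mask and is invariant to positive affine transforms of the input.
#'
#' @param m A `voxel_map`.
#' @param mask Optional logical array overriding the grid mask.
#' @return A `voxel_map` of kind `"zscore"`.
#' @export
zscore_map <- function(m, mask = NULL) {
  msk <- if (is.null(mask)) grid_mask(m$grid) else
    array(as.logical(mask), dim = m$grid$dims)
  v <- m$values[msk]
  v <- v[!is.na(v)]
  if (length(v) < 2L) stop("need at least 2 in-mask voxels", call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("zero variance over the mask: cannot z-score",
                   call. = FALSE)
  z <- (m$values - mean(v)) / s
  z[!msk] <- 0
  out <- voxel_map(m$grid, z, kind = "zscore")
  out$grid$mask <- msk
  out
}

shared_mask_values <- function(a, b, mask = NULL) {
  stop_if_grid_mismatch(a$grid, b$grid)
  msk <- if (is.null(mask)) grid_mask(a$grid) & grid_mask(b$grid) else
    array(as.logical(mask), dim = a$grid$dims)
  ok <- msk & !is.na(a$values) & !is.na(b$values)
  list(mask = ok, x = a$values[ok], y = b$values[ok], idx = which(ok))
}

#' Pearson correlation between two maps over a mask
#'
#' Non-brain voxels (outside the mask) and missing values are excluded from
#' the calculation; the statistic is symmetric in its arguments.
#'
#' @param a,b `voxel_map`s on one grid.
#' @param mask Optional logical array; default is the grids' shared mask.
#' @return Pearson r (scalar).
#' @export
map_correlation <- function(a, b, mask = NULL) {
  s <- shared_mask_values(a, b, mask)
  if (length(s$x) < 3L) stop("need at least 3 shared in-mask voxels",
                             call. = FALSE)
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) {
    stop("zero variance in one of the maps over the mask", call. = FALSE)
  }
  stats::cor(s$x, s$y)
}

#' Leave-one-voxel-out contribution to correlation (VCC)
#'
#' Removes each in-mask voxel pair from both maps and recomputes the Pearson
#' correlation, via exact sufficient-statistic downdating (one observation
#' removed from the running sums). The per-voxel difference
#' `r_global - r_without_i` is then z-scored over the mask, preserving sign:
#' positive values mark voxels driving the maps' convergence, negative values
#' divergence.
#'
#' @param a,b `voxel_map`s on one grid (>= 4 shared in-mask voxels).
#' @param mask Optional logical array.
#' @param normalize Z-score the differences (default); `FALSE` returns raw
#'   `r_global - r_without_i`.
#' @return A `voxel_map` of kind `"vcc"` with attributes `"r_global"` and
#'   `"normalization"`. Voxels whose removal makes a remaining variance zero
#'   are `NA`.
#' @export
vcc <- function(a, b, mask = NULL, normalize = TRUE) {
  s <- shared_mask_values(a, b, mask)
  x <- s$x; y <- s$y
  n <- length(x)
  if (n < 4L) stop("need at least 4 shared in-mask voxels", call. = FALSE)
  Sx <- sum(x); Sy <- sum(y)
  Sxx <- sum(x^2); Syy <- sum(y^2); Sxy <- sum(x * y)
  r_global <- (n * Sxy - Sx * Sy) / sqrt((n * Sxx - Sx^2) * (n * Syy - Sy^2))
  m <- n - 1
  num <- m * (Sxy - x * y) - (Sx - x) * (Sy - y)
  vx <- m * (Sxx - x^2) - (Sx - x)^2
  vy <- m * (Syy - y^2) - (Sy - y)^2
  tol <- 1e-12 * max(1, Sxx, Syy)
  r_i <- ifelse(vx > tol & vy > tol, num / sqrt(pmax(vx, 0) * pmax(vy, 0)),
                NA_real_)
  delta <- r_global - r_i
  if (normalize) {
    mu <- mean(delta, na.rm = TRUE)
    sdd <- stats::sd(delta[!is.na(delta)])
    delta <- if (isTRUE(sdd > 0)) (delta - mu) / sdd else delta * 0
  }
  vals <- array(NA_real_, dim = a$grid$dims)
  vals[s$idx] <- delta
  vals[!s$mask] <- 0
  g <- a$grid; g$mask <- s$mask
  out <- voxel_map(g, vals, kind = "vcc")
  attr(out, "r_global") <- r_global
  attr(out, "normalization") <- if (normalize)
    "z-score over mask, sign preserved" else "raw r_global - r_removed"
  out
}

#' Z-standardised difference of two maps
#'
#' Both maps are z-scored over the shared mask and subtracted voxel-wise
#' (`a - b`): positive values mark voxels where the first map dominates,
#' negative where the second does. Antisymmetric in its arguments.
#'
#' @param a,b `voxel_map`s on one grid.
#' @param mask Optional logical array.
#' @return A `voxel_map` of kind `"difference"`.
#' @export
difference_map <- function(a, b, mask = NULL) {
  s <- shared_mask_values(a, b, mask)
  ga <- a; gb <- b
  ga$grid$mask <- s$mask; gb$grid$mask <- s$mask
  za <- zscore_map(ga); zb <- zscore_map(gb)
  voxel_map(za$grid, za$values - zb$values, kind = "difference")
}

#' Threshold a map into a region of interest
#'
#' Keeps voxels with value strictly greater than the cutoff, optionally
#' intersected with a manually drawn mask.
#'
#' @param m A `voxel_map`.
#' @param cutoff Strict lower cutoff (default 1, for z-point maps).
#' @param manual_mask Optional logical array to intersect with.
#' @return A binary `voxel_map` of kind `"mask"`; empty results warn.
#' @export
threshold_to_roi <- function(m, cutoff = 1, manual_mask = NULL) {
  sel <- !is.na(m$values) & m$values > cutoff & grid_mask(m$grid)
  if (!is.null(manual_mask)) {
    sel <- sel & array(as.logical(manual_mask), dim = m$grid$dims)
  }
  if (!any(sel)) warning("threshold produced an empty ROI", call. = FALSE)
  voxel_map(m$grid, array(as.numeric(sel), m$grid$dims), kind = "mask")
}

#' Behavioral-domain enrichment of an ROI
#'
#' Given foci labelled with behavioral domains, compares each domain's hit
#' rate inside the ROI against the all-domain base rate with a binomial
#' z-score: `z_d = (k_d - n_d p0) / sqrt(n_d p0 (1 - p0))` where `p0` is the
#' fraction of all foci falling inside the ROI.
#'
#' @param roi A binary `voxel_map` (e.g. from [threshold_to_roi()]).
#' @param foci A data frame with columns `x`, `y`, `z`, `domain` (map-space
#'   mm coordinates).
#' @param z_cutoff Significance line reported alongside the table.
#' @return A tibble (`domain`, `n_foci`, `n_inside`, `expected`, `z`,
#'   `significant`), sorted by z descending, with attribute `"z_cutoff"`.
#' @export
domain_enrichment <- function(roi, foci, z_cutoff = 3) {
  stopifnot(inherits(roi, "voxel_map"), all(c("x", "y", "z", "domain")
                                            %in% names(foci)))
  if (!any(roi$values > 0)) stop("ROI is empty", call. = FALSE)
  u <- round(world_to_voxel(roi$grid, cbind(foci$x, foci$y, foci$z)))
  d <- roi$grid$dims
  on_grid <- u[, 1] >= 1 & u[, 1] <= d[1] & u[, 2] >= 1 & u[, 2] <= d[2] &
    u[, 3] >= 1 & u[, 3] <= d[3]
  inside <- logical(nrow(foci))
  lin <- (u[on_grid, 3] - 1) * d[1] * d[2] + (u[on_grid, 2] - 1) * d[1] +
    u[on_grid, 1]
  inside[on_grid] <- roi$values[lin] > 0
  p0 <- mean(inside)
  if (p0 <= 0 || p0 >= 1) {
    stop("base rate is degenerate (all or no foci inside the ROI)",
         call. = FALSE)
  }
  tab <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(domain = as.character(foci$domain),
                                   inside = inside), .data$domain),
    n_foci = dplyr::n(), n_inside = sum(.data$inside), .groups = "drop")
  tab$expected <- tab$n_foci * p0
  tab$z <- (tab$n_inside - tab$expected) /
    sqrt(tab$n_foci * p0 * (1 - p0))
  tab$significant <- tab$z >= z_cutoff
  out <- dplyr::arrange(tab, dplyr::desc(.data$z))
  attr(out, "z_cutoff") <- z_cutoff
  out
}

#' Compare an MHC map with a VMHC map
#'
#' Bundles the comparison machinery: the global Pearson
#' correlation over the shared brain mask, the leave-one-voxel-out VCC map,
#' and the z-standardised difference map (first argument minus second).
#'
#' @param map_a MHC `voxel_map` (kappa values).
#' @param map_b VMHC `voxel_map` (Fisher-z values).
#' @param mask Optional logical array (non-brain voxels excluded).
#' @return A `map_comparison` object with elements `r_global`, `vcc`,
#'   `difference`, `n_voxels`.
#' @export
compare_maps <- function(map_a, map_b, mask = NULL) {
  r <- map_correlation(map_a, map_b, mask)
  v <- vcc(map_a, map_b, mask)
  d <- difference_map(map_a, map_b, mask)
  structure(list(r_global = r, vcc = v, difference = d,
                 n_voxels = length(shared_mask_values(map_a, map_b,
                                                      mask)$x)),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  cat(sprintf("<map_comparison> r = %.4f over %d voxels\n", x$r_global,
              x$n_voxels))
  invisible(x)
}

#' @rdname compare_maps
#' @param x A `map_comparison`.
#' @param ... Unused.
#' @export
glance.map_comparison <- function(x, ...) {
  tibble::tibble(r_global = x$r_global, n_voxels = x$n_voxels)
}

#' @rdname compare_maps
#' @export
tidy.map_comparison <- function(x, ...) {
  vt <- as_tibble.voxel_map(x$vcc, mask_only = TRUE)
  dt <- as_tibble.voxel_map(x$difference, mask_only = TRUE)
  tibble::tibble(vt[, c("i", "j", "k", "x", "y", "z")],
                 vcc = vt$value, difference = dt$value)
}

#' @rdname compare_maps
#' @param object A `map_comparison`.
#' @export
autoplot.map_comparison <- function(object, ...) {
  df <- tidy.map_comparison(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$difference, y = .data$vcc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "z(MHC) - z(VMHC)", y = "normalised VCC",
                  title = sprintf("Contribution vs difference (r_global = %.2f)",
                                  object$r_global)) +
    ggplot2::theme_minimal()
}
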