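#' Scalar fields on a voxel grid
#'
#' A `voxel_map` pairs a [volume_grid()] with one scalar value per voxel and a
#' `kind` tag recording what the values are (modeled-activation probability,
#' ALE score, Patel's kappa, Fisher z, z-score, voxel contribution to
#' correlation, or a map difference). It is the carrier for every volumetric
#' result in the package.
#'
#' @param grid A `volume_grid`.
#' @param values Numeric array of dimension `grid$dims` (a scalar is
#'   recycled).
#' @param kind One of `"MA_probability"`, `"ALE"`, `"kappa"`, `"fisher_z"`,
#'   `"zscore"`, `"vcc"`, `"difference"`, `"label"`, `"mask"`, `"other"`.
#' @return A `voxel_map`.
#' @export
voxel_map <- function(grid, values, kind = "other") {
  stopifnot(inherits(grid, "volume_grid"))
  kind <- match.arg(kind, c("MA_probability", "ALE", "kappa", "fisher_z",
                            "zscore", "vcc", "difference", "label", "mask",
                            "other"))
  if (length(values) == 1L) values <- array(values, dim = grid$dims)
  values <- array(as.numeric(values), dim = grid$dims)
  m <- grid_mask(grid)
  inside <- values[m]
  if (any(!is.finite(inside) & !is.na(inside))) {
    stop("voxel_map values must be finite (or NA) inside the mask",
         call. = FALSE)
  }
  if (kind %in% c("MA_probability", "ALE")) {
    ok <- is.na(inside) | (inside >= 0 & inside < 1)
    if (!all(ok)) stop(kind, " values must lie in [0, 1)", call. = FALSE)
  }
  structure(list(grid = grid, values = values, kind = kind),
            class = "voxel_map")
}

#' @export
print.voxel_map <- function(x, ...) {
  v <- x$values[grid_mask(x$grid)]
  cat(sprintf("<voxel_map:%s> %d x %d x %d, in-mask range [%.4g, %.4g]\n",
              x$kind, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' Long tibble view of a voxel map
#'
#' One row per voxel with 1-based indices, world mm coordinates, value and
#' mask membership; convenient for dplyr/ggplot2 pipelines.
#'
#' @param x A `voxel_map`.
#' @param mask_only Keep in-mask voxels only.
#' @param ... Unused.
#' @return A tibble with columns `i, j, k, x, y, z, value, in_mask`.
#' @export
as_tibble.voxel_map <- function(x, ..., mask_only = FALSE) {
  d <- x$grid$dims
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  w <- voxel_to_world(x$grid, idx)
  vals <- as.vector(x$values)
  msk <- as.vector(grid_mask(x$grid))
  out <- tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    x = w[, 1], y = w[, 2], z = w[, 3],
    value = vals, in_mask = msk
  )
  if (mask_only) out <- out[out$in_mask, , drop = FALSE]
  out
}

mask_values <- function(m) m$values[grid_mask(m$grid)]

#' Reflect a map about the midsagittal plane
#'
#' Returns the map whose value at world (x, y, z) is the input value at
#' (-x, y, z). Requires a mirror-closed grid, on which the operation is an
#' exact involution.
#'
#' @param m A `voxel_map` (or a bare 3-D array with `grid` supplied).
#' @param ... Passed to methods.
#' @return An object of the same class as `m`.
#' @export
mirror_x <- function(m, ...) UseMethod("mirror_x")

#' @rdname mirror_x
#' @export
mirror_x.voxel_map <- function(m, ...) {
  p <- mirror_index_perm(m$grid)
  out <- m
  out$values <- m$values[p, , , drop = FALSE]
  if (!is.null(m$grid$mask)) {
    out$grid$mask <- m$grid$mask[p, , , drop = FALSE]
  }
  out
}

#' @rdname mirror_x
#' @param grid The `volume_grid` the array lives on.
#' @export
mirror_x.array <- function(m, grid, ...) {
  p <- mirror_index_perm(grid)
  m[p, , , drop = FALSE]
}

#' Plot an axial slice of a voxel map
#'
#' @param object A `voxel_map`.
#' @param k Axial slice index (1-based); defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.voxel_map <- function(object, k = NULL, ...) {
  if (is.null(k)) k <- ceiling(object$grid$dims[3] / 2)
  df <- as_tibble.voxel_map(object)
  df <- df[df$k == k & df$in_mask, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s map, axial slice k = %d", object$kind, k),
                  x = "x (mm)", y = "y (mm)", fill = object$kind) +
    ggplot2::theme_minimal()
}
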