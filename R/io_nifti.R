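#' Read and write voxel maps as NIfTI-1 volumes
#'
#' Volumes are stored as float32 (the neuroimaging standard; all computation
#' in the package is double precision), with the grid affine in the sform and
#' the map's `kind` recorded in the header description field so that a
#' written map reads back with its semantics intact.
#'
#' @param m A `voxel_map`.
#' @param path `.nii` or `.nii.gz` path.
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `voxel_map`.
#' @export
write_volume <- function(m, path) {
  stopifnot(inherits(m, "voxel_map"))
  img <- RNifti::asNifti(m$values, datatype = "float")
  RNifti::sform(img) <- structure(m$grid$affine, code = 2L)
  img$descrip <- paste0("kind=", m$kind)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param mask Optional logical array attached to the grid on read.
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop("expected a 3-D volume, got ", length(d), "-D: ", path,
         call. = FALSE)
  }
  grid <- grid_from_nifti(img, mask)
  hdr <- RNifti::niftiHeader(img)
  kind <- sub("^kind=", "", hdr$descrip)
  kinds <- c("MA_probability", "ALE", "kappa", "fisher_z", "zscore", "vcc",
             "difference", "label", "mask")
  voxel_map(grid, array(as.numeric(img), d),
            kind = if (kind %in% kinds) kind else "other")
}

grid_from_nifti <- function(img, mask = NULL) {
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  d <- dim(img)[1:3]
  # derive the voxel size from the affine columns; header pixdim can lag
  # behind the sform for files written by other tools
  volume_grid(d, voxel_size = sqrt(colSums(aff[1:3, 1:3]^2)),
              affine = aff, mask = mask)
}

#' Read and write parcellations (integer NIfTI + TSV sidecar)
#'
#' The label volume goes to `path` and a sidecar table
#' (`label`, `name`, `hemi`, `pair_id`, `n_voxels`) to `sidecar`.
#'
#' @param x A `parcellation`.
#' @param path NIfTI path for the label volume.
#' @param sidecar TSV path; defaults to `path` with a `.tsv` extension.
#' @return `write_parcellation()` returns `path` invisibly;
#'   `read_parcellation()` a `parcellation`.
#' @export
write_parcellation <- function(x, path, sidecar = default_sidecar(path)) {
  stopifnot(inherits(x, "parcellation"))
  img <- RNifti::asNifti(x$labels, datatype = "int32")
  RNifti::sform(img) <- structure(x$grid$affine, code = 2L)
  img$descrip <- "kind=label"
  RNifti::writeNifti(img, path)
  readr::write_tsv(tidy.parcellation(x), sidecar)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path, sidecar = default_sidecar(path)) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("parcellation volume must be 3-D",
                                   call. = FALSE)
  grid <- grid_from_nifti(img)
  labels <- array(as.integer(img), dim(img))
  names <- NULL; pairs <- NULL
  if (file.exists(sidecar)) {
    key <- readr::read_tsv(sidecar, show_col_types = FALSE)
    names <- stats::setNames(key$name, key$label)
    if (!all(is.na(key$pair_id))) {
      lk <- key[key$hemi == "L" & !is.na(key$pair_id), ]
      rk <- key[key$hemi == "R" & !is.na(key$pair_id), ]
      pairs <- tibble::tibble(pair_id = lk$pair_id, left = lk$label,
                              right = rk$label[match(lk$pair_id, rk$pair_id)],
                              n_voxels = lk$n_voxels)
    }
  }
  parcellation(grid, labels, names = names, pairs = pairs,
               provenance = paste0("read from ", path))
}

default_sidecar <- function(path) {
  sub("\\.nii(\\.gz)?$", ".tsv", path)
}

#' 4-D resting-state series I/O
#'
#' @param data A `rest_series` (see [rest_series()]).
#' @param path `.nii` or `.nii.gz` path.
#' @return `read_rest()` returns a `rest_series`; `write_rest()` the path,
#'   invisibly.
#' @export
write_rest <- function(data, path) {
  stopifnot(inherits(data, "rest_series"))
  img <- RNifti::asNifti(data$data, datatype = "float")
  RNifti::sform(img) <- structure(data$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_rest
#' @param mask Optional logical array attached to the grid on read.
#' @export
read_rest <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D series, got ", length(d), "-D",
                            call. = FALSE)
  grid <- grid_from_nifti(img, mask)
  rest_series(grid, array(as.numeric(img), d))
}

#' Bundle a 4-D array with its grid
#'
#' @param grid A `volume_grid` for the spatial dimensions.
#' @param data Numeric 4-D array, last dimension time.
#' @return A `rest_series` object.
#' @export
rest_series <- function(grid, data) {
  stopifnot(inherits(grid, "volume_grid"), length(dim(data)) == 4L,
            identical(dim(data)[1:3], as.integer(grid$dims)))
  structure(list(grid = grid, data = data), class = "rest_series")
}

#' @export
print.rest_series <- function(x, ...) {
  cat(sprintf("<rest_series> %d x %d x %d voxels, %d timepoints\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              dim(x$data)[4]))
  invisible(x)
}
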