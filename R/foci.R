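#' Collections of activation foci
#'
#' A `foci_collection` is a tibble with one row per reported activation peak
#' (focus), columns `experiment_id`, `x`, `y`, `z` (world mm, RAS) and
#' `n_subjects`, plus attributes `space` (`"TAL"` or `"MNI"`) and free-text
#' `provenance`. Experiments group rows; all foci of a collection share one
#' stereotaxic space.
#'
#' @param foci A data frame with columns `experiment_id`, `x`, `y`, `z` and
#'   optionally `n_subjects`.
#' @param space `"TAL"` or `"MNI"`.
#' @param provenance Free-text metadata.
#' @return A `foci_collection` tibble.
#' @export
foci_collection <- function(foci, space = c("TAL", "MNI"), provenance = "") {
  space <- match.arg(space)
  foci <- tibble::as_tibble(foci)
  stopifnot(all(c("experiment_id", "x", "y", "z") %in% names(foci)))
  if (!"n_subjects" %in% names(foci)) foci$n_subjects <- NA_integer_
  foci <- foci[, c("experiment_id", "x", "y", "z", "n_subjects")]
  foci$experiment_id <- as.character(foci$experiment_id)
  if (nrow(foci) == 0L) stop("foci collection is empty", call. = FALSE)
  if (!all(is.finite(foci$x) & is.finite(foci$y) & is.finite(foci$z))) {
    stop("all focus coordinates must be finite", call. = FALSE)
  }
  structure(foci,
            class = c("foci_collection", class(tibble::tibble())),
            space = space, provenance = provenance)
}

#' @rdname foci_collection
#' @param x A `foci_collection`.
#' @export
foci_space <- function(x) attr(x, "space", exact = TRUE)

#' @export
print.foci_collection <- function(x, ...) {
  cat(sprintf("<foci_collection> %d foci in %d experiments, space %s\n",
              nrow(x), length(unique(x$experiment_id)), foci_space(x)))
  NextMethod()
}

#' Summaries per experiment
#' @param x A `foci_collection`.
#' @param ... Unused.
#' @return Tibble with one row per experiment: id, focus count, subjects.
#' @export
tidy.foci_collection <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$experiment_id),
                   n_foci = dplyr::n(),
                   n_subjects = .data$n_subjects[1], .groups = "drop")
}

#' Read a Sleuth-style foci text export
#'
#' Parses the plain-text format produced by BrainMap foci exports: metadata
#' lines start with `//`; the first `// Reference=` line fixes the stereotaxic
#' space for the whole file; experiments are blocks of whitespace-separated
#' `x y z` lines separated by one or more blank lines. A `// Subjects=n` line
#' inside a block records the experiment's subject count, and the first other
#' `//` line names the experiment.
#'
#' @param path Path to the text file.
#' @return A [foci_collection()].
#' @export
read_sleuth <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  ref <- grep("^//\\s*Reference\\s*=", trimmed, ignore.case = TRUE, value = TRUE)
  if (length(ref) == 0L) {
    stop("no '// Reference=' header line: stereotaxic space is undeclared",
         call. = FALSE)
  }
  ref_val <- toupper(trimws(sub("^//\\s*Reference\\s*=", "", ref[1],
                                ignore.case = TRUE)))
  space <- if (grepl("^TAL", ref_val)) "TAL"
           else if (grepl("^MNI", ref_val)) "MNI"
           else stop("unrecognised reference space: ", ref_val, call. = FALSE)

  blank <- trimmed == ""
  block_id <- cumsum(blank)
  keep <- !blank
  rows <- list(); auto <- 0L; skipped <- 0L
  for (b in unique(block_id[keep])) {
    ln <- which(block_id == b & keep)
    meta <- ln[startsWith(trimmed[ln], "//")]
    coords <- setdiff(ln, meta)
    meta_txt <- trimmed[meta]
    meta_txt <- meta_txt[!grepl("^//\\s*Reference\\s*=", meta_txt,
                                ignore.case = TRUE)]
    subj_line <- grep("^//\\s*Subjects\\s*=", meta_txt, ignore.case = TRUE)
    n_subj <- NA_integer_
    if (length(subj_line)) {
      n_subj <- as.integer(sub("^//\\s*Subjects\\s*=", "",
                               meta_txt[subj_line[1]], ignore.case = TRUE))
      meta_txt <- meta_txt[-subj_line]
    }
    if (length(coords) == 0L) {
      if (length(meta_txt)) {   # experiment header with no foci
        warning("skipping block with no coordinate lines near line ",
                if (length(ln)) ln[1] else NA, call. = FALSE)
        skipped <- skipped + 1L
      }
      next
    }
    id <- if (length(meta_txt)) sub("^//\\s*", "", meta_txt[1]) else {
      auto <- auto + 1L
      sprintf("experiment_%03d", auto)
    }
    xyz <- lapply(coords, function(i) {
      parts <- strsplit(trimmed[i], "[\\s,;]+", perl = TRUE)[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) < 3L || anyNA(vals[1:3])) {
        stop(sprintf("non-numeric coordinate line %d: '%s'", i, trimmed[i]),
             call. = FALSE)
      }
      vals[1:3]
    })
    m <- do.call(rbind, xyz)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      experiment_id = id, x = m[, 1], y = m[, 2], z = m[, 3],
      n_subjects = n_subj)
  }
  if (!length(rows)) stop("no experiments found in ", path, call. = FALSE)
  out <- dplyr::bind_rows(rows)
  ids <- unique(out$experiment_id)
  if (anyDuplicated(ids) > 0L) stop("duplicate experiment ids", call. = FALSE)
  foci_collection(out, space = space, provenance = paste0("read from ", path))
}

#' Write a foci collection in the Sleuth text dialect
#'
#' Round-trips through [read_sleuth()]: coordinates are preserved to 1e-6 mm.
#'
#' @param x A `foci_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleuth <- function(x, path) {
  stopifnot(inherits(x, "foci_collection"))
  ref <- if (foci_space(x) == "TAL") "Talairach" else "MNI"
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("// Reference=%s", ref), con)
  writeLines("", con)
  for (id in unique(x$experiment_id)) {
    e <- x[x$experiment_id == id, , drop = FALSE]
    writeLines(sprintf("// %s", id), con)
    if (!is.na(e$n_subjects[1])) {
      writeLines(sprintf("// Subjects=%d", e$n_subjects[1]), con)
    }
    writeLines(sprintf("%.6f\t%.6f\t%.6f", e$x, e$y, e$z), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Stereotaxic-space transform constant sets
#'
#' Affine constants mapping MNI (ICBM-152) coordinates into Talairach space
#' and back. The `"spm"` and `"fsl"` sets are the published icbm2tal pooled
#' matrices for SPM- and FSL-normalised data; `"identity"` is provided for
#' testing and for data already in the target space.
#'
#' @param flavor `"spm"` (default), `"fsl"`, or `"identity"`.
#' @return A named list with 4x4 matrices `mni_to_tal` and `tal_to_mni`.
#' @export
icbm_transform <- function(flavor = c("spm", "fsl", "identity")) {
  flavor <- match.arg(flavor)
  m <- switch(flavor,
    spm = matrix(c(0.9254,  0.0024, -0.0118, -1.0207,
                   -0.0048, 0.9316, -0.0871, -1.7667,
                   0.0152,  0.0883,  0.8924,  4.0926,
                   0, 0, 0, 1), 4, 4, byrow = TRUE),
    fsl = matrix(c(0.9464,  0.0034, -0.0026, -1.0680,
                   -0.0083, 0.9479, -0.0580, -1.0239,
                   0.0053,  0.0617,  0.9010,  3.1883,
                   0, 0, 0, 1), 4, 4, byrow = TRUE),
    identity = diag(4))
  list(name = paste0("icbm2tal_", flavor), mni_to_tal = m,
       tal_to_mni = solve(m))
}

#' Convert a foci collection between stereotaxic spaces
#'
#' Maps every focus through the affine constants of `transform`. Converting a
#' collection to its own space is the identity.
#'
#' @param x A `foci_collection`.
#' @param to Target space, `"TAL"` or `"MNI"`.
#' @param transform A constant set from [icbm_transform()].
#' @return A `foci_collection` in the target space.
#' @export
convert_space <- function(x, to = c("TAL", "MNI"),
                          transform = icbm_transform("spm")) {
  stopifnot(inherits(x, "foci_collection"))
  to <- match.arg(to)
  from <- foci_space(x)
  if (from == to) return(x)
  key <- paste0(tolower(from), "_to_", tolower(to))
  if (!key %in% names(transform)) {
    stop("transform set has no constants for ", from, " -> ", to,
         call. = FALSE)
  }
  A <- transform[[key]]
  pts <- cbind(x$x, x$y, x$z, 1)
  new <- pts %*% t(A)
  out <- x
  out$x <- new[, 1]; out$y <- new[, 2]; out$z <- new[, 3]
  attr(out, "space") <- to
  attr(out, "provenance") <- paste0(attr(x, "provenance"), "; ",
                                    transform$name, " ", from, "->", to)
  out
}
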