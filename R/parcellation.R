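#' Labeled brain parcellations with homotopic pair bookkeeping
#'
#' A `parcellation` is an integer label field on a [volume_grid()] (0 =
#' background) together with a label key (name, hemisphere) and, for symmetric
#' atlases, an explicit homotopic pair table matching each left-hemisphere
#' label to the right-hemisphere label occupying its mirrored voxel set.
#'
#' @param grid A `volume_grid`.
#' @param labels Integer array of dimension `grid$dims`; 0 is background.
#' @param names Optional named character vector, `names(names)` = label ids.
#' @param pairs Optional tibble with columns `pair_id`, `left`, `right`.
#' @param provenance Free text describing how the parcellation was built.
#' @return A `parcellation` object.
#' @export
parcellation <- function(grid, labels, names = NULL, pairs = NULL,
                         provenance = "") {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- array(as.integer(labels), dim = grid$dims)
  ids <- sort(unique(labels[labels > 0L]))
  nm <- stats::setNames(paste0("region_", ids), ids)
  if (!is.null(names)) nm[names(names)[names(names) %in% ids]] <-
      names[names(names) %in% ids]
  if (!is.null(pairs)) pairs <- tibble::as_tibble(pairs)
  structure(list(grid = grid, labels = labels, names = nm, pairs = pairs,
                 provenance = provenance),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d labels on %d x %d x %d grid%s\n",
              length(region_ids(x)), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3],
              if (is.null(x$pairs)) "" else
                sprintf(", %d homotopic pairs", nrow(x$pairs))))
  invisible(x)
}

#' @rdname parcellation
#' @param x A `parcellation`.
#' @export
region_ids <- function(x) sort(unique(x$labels[x$labels > 0L]))

#' @rdname parcellation
#' @export
region_sizes <- function(x) {
  ids <- region_ids(x)
  stats::setNames(tabulate(x$labels, nbins = max(ids))[ids], ids)
}

#' Region summary table
#' @param x A `parcellation`.
#' @param ... Unused.
#' @return Tibble with columns `label`, `name`, `hemi`, `pair_id`, `n_voxels`.
#' @export
tidy.parcellation <- function(x, ...) {
  ids <- region_ids(x)
  xs <- grid_axis_coords(x$grid, 1L)
  xw <- xs[slice.index(x$labels, 1L)]
  hemi <- vapply(ids, function(id) {
    mx <- mean(xw[x$labels == id])
    if (mx < -1e-9) "L" else if (mx > 1e-9) "R" else "mid"
  }, character(1))
  pair_id <- rep(NA_integer_, length(ids))
  if (!is.null(x$pairs)) {
    pair_id[match(x$pairs$left, ids)] <- x$pairs$pair_id
    pair_id[match(x$pairs$right, ids)] <- x$pairs$pair_id
  }
  tibble::tibble(label = ids, name = unname(x$names[as.character(ids)]),
                 hemi = hemi, pair_id = pair_id,
                 n_voxels = unname(region_sizes(x)))
}

# 6-connected neighbour lists for a set of linear voxel indices.
neighbour_offsets <- function(dims) {
  c(-1L, 1L, -dims[1], dims[1], -dims[1] * dims[2], dims[1] * dims[2])
}

# For voxel linear indices `v` on grid dims, return matrix of 6-neighbour
# linear indices (NA when off-grid). Guards the x/y wrap-around at borders.
neighbours6 <- function(v, dims) {
  ijk <- arrayInd(v, dims)
  out <- matrix(NA_integer_, length(v), 6L)
  shift <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                 c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (s in 1:6) {
    nb <- sweep(ijk, 2L, shift[s, ], `+`)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] & nb[, 2] >= 1L &
      nb[, 2] <= dims[2] & nb[, 3] >= 1L & nb[, 3] <= dims[3]
    lin <- rep(NA_integer_, length(v))
    lin[ok] <- (nb[ok, 3] - 1L) * dims[1] * dims[2] +
      (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    out[, s] <- lin
  }
  out
}

#' Match left-hemisphere labels to their mirror right-hemisphere labels
#'
#' For a symmetric parcellation, each left label's voxel set, mirrored about
#' x = 0, must coincide exactly with the voxel set of a single right label;
#' the matching is geometric, independent of label numbering.
#'
#' @param x A symmetric `parcellation` on a mirror-closed grid.
#' @return Tibble with columns `pair_id`, `left`, `right`, `n_voxels`.
#' @export
homotopic_pairs <- function(x) {
  perm <- mirror_linear_perm(x$grid)
  lab <- as.integer(x$labels)
  mlab <- lab[perm]              # label of the mirror voxel, per voxel
  key <- tidy.parcellation(`[[<-`(x, "pairs", NULL))
  left <- key$label[key$hemi == "L"]
  rows <- lapply(left, function(l) {
    vox <- lab == l
    partner <- unique(mlab[vox])
    if (length(partner) != 1L || partner == 0L) {
      stop("label ", l, " has no single mirror partner: atlas not symmetric",
           call. = FALSE)
    }
    if (sum(lab == partner) != sum(vox)) {
      stop("label ", l, " and its partner differ in size: atlas not symmetric",
           call. = FALSE)
    }
    tibble::tibble(left = l, right = partner, n_voxels = sum(vox))
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$right) > 0L) {
    stop("pairing is not a bijection: atlas not symmetric", call. = FALSE)
  }
  tibble::tibble(pair_id = seq_len(nrow(out)), out)
}

#' Symmetrize an atlas about the midsagittal plane
#'
#' Makes the label field invariant under [mirror_x()] up to left/right label
#' exchange. Under the `"intersection"` policy (default) a voxel keeps its
#' anatomical label only if its mirror voxel carries the same label (after
#' canonicalising right labels through an existing pair table); under
#' `"left_dominant"` the left hemisphere is mirrored onto the right. Labels
#' shared across hemispheres are split into a left/right pair; unpaired
#' voxels become background.
#'
#' @param x A `parcellation` on a mirror-closed grid.
#' @param policy `"intersection"` or `"left_dominant"`.
#' @return A symmetric `parcellation` with a rebuilt pair table.
#' @export
symmetrize_atlas <- function(x, policy = c("intersection", "left_dominant")) {
  policy <- match.arg(policy)
  perm <- mirror_linear_perm(x$grid)
  lab <- as.integer(x$labels)
  canon <- seq_len(max(c(lab, 1L)))
  if (!is.null(x$pairs)) canon[x$pairs$right] <- x$pairs$left
  clab <- ifelse(lab > 0L, canon[pmax(lab, 1L)], 0L)
  xs <- grid_axis_coords(x$grid, 1L)
  xw <- xs[slice.index(array(0L, x$grid$dims), 1L)]
  out <- lab
  if (policy == "intersection") {
    keep <- clab > 0L & clab == clab[perm]
    out[!keep] <- 0L
  } else {
    mirrored <- lab[perm]
    right <- as.vector(xw) > 0
    out[right] <- mirrored[right]          # left voxel's label, mirrored
    out[as.vector(abs(xw)) < 1e-9 & clab != clab[perm]] <- 0L
  }
  # Split labels that span both hemispheres into explicit left/right ids.
  ids <- sort(unique(out[out > 0L]))
  spans <- vapply(ids, function(id) {
    s <- sign(as.vector(xw)[out == id])
    any(s < 0) && any(s > 0)
  }, logical(1))
  offset <- max(ids)
  relab <- out
  for (id in ids[spans]) {
    relab[out == id & as.vector(xw) > 0] <- id + offset
  }
  nm <- x$names
  for (id in ids[spans]) {
    nm[as.character(id + offset)] <- paste0(x$names[as.character(id)], "_R")
  }
  res <- parcellation(x$grid, array(relab, x$grid$dims), names = nm,
                      provenance = paste0(x$provenance, "; symmetrized (",
                                          policy, ")"))
  res$pairs <- homotopic_pairs(res)
  res
}

#' Homogeneous equal-size random parcellation
#'
#' Splits every left-hemisphere region of a symmetric atlas into
#' `floor(size / k)` random 6-connected parcels of exactly `k` voxels by
#' seeded region growing, then mirrors the left partition onto the right so
#' homotopic pairs stay voxel-exact. Remainder voxels (region size mod k) are
#' merged into an adjacent parcel of the same region (default) or dropped.
#'
#' @param x A symmetric `parcellation` with a pair table (see
#'   [symmetrize_atlas()], [homotopic_pairs()]).
#' @param k Target voxels per parcel (>= 8).
#' @param seed Integer seed; fixed seed gives a bit-identical parcellation.
#' @param remainder `"merge_to_nearest"` or `"drop"`.
#' @param contiguous Grow 6-connected parcels (default); `FALSE` partitions
#'   region voxels at random without contiguity (sensitivity checks only).
#' @param max_restarts Region-growing restarts before giving up.
#' @return A `parcellation` of equal-size paired parcels.
#' @export
homogeneous_parcellation <- function(x, k, seed = 1L,
                                     remainder = c("merge_to_nearest", "drop"),
                                     contiguous = TRUE, max_restarts = 50L) {
  remainder <- match.arg(remainder)
  stopifnot(k >= 8)
  if (is.null(x$pairs)) x$pairs <- homotopic_pairs(x)
  perm <- mirror_linear_perm(x$grid)
  dims <- x$grid$dims
  lab <- as.integer(x$labels)
  out <- integer(length(lab))
  next_label <- 1L
  pair_rows <- list()
  local_seed(seed, {
    for (p in seq_len(nrow(x$pairs))) {
      lvox <- which(lab == x$pairs$left[p])
      n_parcels <- floor(length(lvox) / k)
      if (n_parcels == 0L) {
        warning("region ", x$pairs$left[p], " smaller than k = ", k,
                "; dropped", call. = FALSE)
        next
      }
      assign_l <- grow_parcels(lvox, dims, k, n_parcels, contiguous,
                               remainder, max_restarts)
      new_left <- next_label + seq_len(n_parcels) - 1L
      new_right <- new_left + n_parcels
      keep <- assign_l > 0L
      out[lvox[keep]] <- new_left[assign_l[keep]]
      rvox <- perm[lvox]           # mirror voxel of each left voxel
      out[rvox[keep]] <- new_right[assign_l[keep]]
      pair_rows[[p]] <- tibble::tibble(
        left = new_left, right = new_right,
        parent = x$pairs$left[p],
        n_voxels = tabulate(assign_l[keep], n_parcels))
      next_label <- next_label + 2L * n_parcels
    }
  })
  pairs <- dplyr::bind_rows(pair_rows)
  if (nrow(pairs) == 0L) {
    pairs <- tibble::tibble(left = integer(), right = integer(),
                            parent = integer(), n_voxels = integer())
  }
  pairs <- tibble::tibble(pair_id = seq_len(nrow(pairs)), pairs)
  res <- parcellation(x$grid, array(out, dims),
                      provenance = sprintf(
                        "%s; homogeneous k=%d seed=%d remainder=%s",
                        x$provenance, k, seed, remainder))
  res$pairs <- pairs[, c("pair_id", "left", "right", "n_voxels")]
  res
}

# Partition the voxel set `vox` (linear indices) into n_parcels groups of k
# by random 6-connected growth; returns assignment in 1..n_parcels (0 =
# dropped remainder). Remainder merged into an adjacent parcel unless "drop".
grow_parcels <- function(vox, dims, k, n_parcels, contiguous, remainder,
                         max_restarts) {
  n <- length(vox)
  pos <- integer(max(vox)); pos[vox] <- seq_len(n)  # linear index -> local id
  if (!contiguous) {
    assign <- integer(n)
    ord <- sample.int(n)
    assign[ord[seq_len(n_parcels * k)]] <- rep(seq_len(n_parcels), each = k)
    return(merge_remainder(assign, vox, dims, pos, remainder))
  }
  nb <- neighbours6(vox, dims)
  nb_local <- matrix(0L, n, 6L)
  ok <- !is.na(nb) & nb <= length(pos)
  nb_local[ok] <- pos[nb[ok]]                       # 0 = outside region
  # free-degree-guided ("peeling") growth: seeding and growing at free
  # voxels with the fewest unassigned neighbours avoids stranding fragments
  # when the packing is dense; tie-breaks are randomised by the seed.
  free_degree <- function(v, assign) {
    vapply(v, function(i) {
      nn <- nb_local[i, ]
      sum(nn > 0L & assign[pmax(nn, 1L)] == 0L)
    }, integer(1))
  }
  pick_min <- function(cand, assign) {
    deg <- free_degree(cand, assign)
    best <- cand[deg == min(deg)]
    best[sample.int(length(best), 1L)]
  }
  for (try in seq_len(max_restarts)) {
    assign <- integer(n)
    stuck <- FALSE
    for (pcl in seq_len(n_parcels)) {
      free <- which(assign == 0L)
      seed_v <- pick_min(free, assign)
      assign[seed_v] <- pcl
      members <- 1L
      frontier <- nb_local[seed_v, ]
      frontier <- frontier[frontier > 0L]
      frontier <- frontier[assign[frontier] == 0L]
      while (members < k) {
        if (!length(frontier)) { stuck <- TRUE; break }
        pick <- pick_min(frontier, assign)
        assign[pick] <- pcl
        members <- members + 1L
        new_nb <- nb_local[pick, ]
        new_nb <- new_nb[new_nb > 0L]
        frontier <- unique(c(frontier, new_nb))
        frontier <- frontier[assign[frontier] == 0L]
      }
      if (stuck) break
    }
    if (!stuck) return(merge_remainder(assign, vox, dims, pos, remainder))
  }
  stop("region growing failed to place ", n_parcels, " parcels of ", k,
       " voxels after ", max_restarts, " restarts", call. = FALSE)
}

merge_remainder <- function(assign, vox, dims, pos, remainder) {
  left <- which(assign == 0L)
  if (!length(left)) return(assign)
  if (remainder == "drop") {
    warning(length(left), " remainder voxels dropped", call. = FALSE)
    return(assign)
  }
  nb <- neighbours6(vox[left], dims)
  # iterative passes: attach remainder voxels to an adjacent parcel
  repeat {
    progress <- FALSE
    for (r in seq_along(left)) {
      if (assign[left[r]] > 0L) next
      cand <- nb[r, ]
      cand <- cand[!is.na(cand) & cand <= length(pos)]
      cand <- pos[cand]; cand <- cand[cand > 0L]
      lab <- assign[cand]; lab <- lab[lab > 0L]
      if (length(lab)) { assign[left[r]] <- lab[1]; progress <- TRUE }
    }
    if (all(assign[left] > 0L)) break
    if (!progress) {
      # isolated remainder: attach to parcel of the nearest assigned voxel
      for (r in which(assign[left] == 0L)) {
        a <- which(assign > 0L)
        dd <- rowSums((arrayInd(vox[a], dims) -
                         matrix(arrayInd(vox[left[r]], dims), length(a), 3,
                                byrow = TRUE))^2)
        assign[left[r]] <- assign[a[which.min(dd)]]
      }
      break
    }
  }
  assign
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
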