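#' Experiments-by-regions activation matrix
#'
#' Binarises modeled activation against a parcellation: entry (e, r) is 1
#' when the fraction of region r's voxels that are MA-significant for
#' experiment e reaches `fraction_threshold` (boundary inclusive, so 10 of 50
#' voxels passes at 0.20). A threshold of 0 means "at least one significant
#' voxel". The default significance predicate is MA > 0 under the truncated
#' kernel, i.e. the voxel lies within the truncation radius of some focus;
#' `sig_cutoff` sets an absolute MA cutoff instead.
#'
#' @param x A list of MA `voxel_map`s (one per experiment) or a
#'   `foci_collection` (maps are then built on the fly and discarded, which
#'   is the memory-friendly route for thousands of experiments).
#' @param atlas A `parcellation` on the same grid.
#' @param fraction_threshold Fraction of region voxels required, in
#'   \\[0, 1\\]; default 0.20.
#' @param sig_cutoff MA significance cutoff (default 0: any positive MA).
#' @param ... Passed to methods.
#' @return An `activation_matrix`: integer matrix, experiments x regions,
#'   with the threshold and rule recorded as attributes.
#' @export
activation_matrix <- function(x, atlas, fraction_threshold = 0.2,
                              sig_cutoff = 0, ...) {
  UseMethod("activation_matrix")
}

#' @rdname activation_matrix
#' @export
activation_matrix.list <- function(x, atlas, fraction_threshold = 0.2,
                                   sig_cutoff = 0, ...) {
  stopifnot(length(x) >= 1L)
  for (m in x) stop_if_grid_mismatch(atlas$grid, m$grid)
  ids <- region_ids(atlas)
  sizes <- region_sizes(atlas)
  rows <- t(vapply(x, function(m) {
    region_active(m$values > sig_cutoff, atlas$labels, ids, sizes,
                  fraction_threshold)
  }, integer(length(ids))))
  nm <- names(x)
  if (is.null(nm)) nm <- sprintf("exp_%05d", seq_along(x))
  new_activation_matrix(rows, nm, ids, fraction_threshold, sig_cutoff)
}

#' @rdname activation_matrix
#' @param kernel,band Kernel and optional midline band used to build the
#'   per-experiment MA maps.
#' @param experiments Character vector of experiment ids defining the rows;
#'   defaults to the collection's experiments (including, for synthetic
#'   collections, experiments that drew no activation anywhere).
#' @export
activation_matrix.foci_collection <- function(x, atlas,
                                              fraction_threshold = 0.2,
                                              sig_cutoff = 0,
                                              kernel = kernel_spec(),
                                              band = NULL,
                                              experiments = NULL, ...) {
  stop_if_fraction_invalid(fraction_threshold)
  grid <- atlas$grid
  ids <- region_ids(atlas)
  sizes <- region_sizes(atlas)
  if (is.null(experiments)) {
    experiments <- attr(x, "all_experiments", exact = TRUE)
    if (is.null(experiments)) experiments <- unique(x$experiment_id)
  }
  by_exp <- split(seq_len(nrow(x)), factor(x$experiment_id,
                                           levels = experiments))
  rows <- matrix(0L, length(experiments), length(ids))
  labels <- atlas$labels
  for (e in seq_along(experiments)) {
    idx <- by_exp[[e]]
    if (!length(idx)) next
    acc <- ma_accumulate(cbind(x$x[idx], x$y[idx], x$z[idx]), grid, kernel,
                         band)
    sig <- if (sig_cutoff == 0) acc < 0 else -expm1(acc) > sig_cutoff
    rows[e, ] <- region_active(sig, labels, ids, sizes, fraction_threshold)
  }
  new_activation_matrix(rows, experiments, ids, fraction_threshold,
                        sig_cutoff)
}

region_active <- function(sig, labels, ids, sizes, fraction_threshold) {
  counts <- tabulate(labels[sig], nbins = max(ids))[ids]
  if (fraction_threshold > 0) {
    as.integer(counts / sizes >= fraction_threshold)
  } else {
    as.integer(counts > 0L)
  }
}

stop_if_fraction_invalid <- function(f) {
  if (f < 0 || f > 1) stop("fraction_threshold must be in [0, 1]",
                           call. = FALSE)
}

new_activation_matrix <- function(rows, exp_ids, region_ids,
                                  fraction_threshold, sig_cutoff) {
  stop_if_fraction_invalid(fraction_threshold)
  dimnames(rows) <- list(exp_ids, as.character(region_ids))
  structure(rows, class = c("activation_matrix", class(rows)),
            fraction_threshold = fraction_threshold,
            ma_significance_rule = if (sig_cutoff == 0)
              "MA > 0 under truncated kernel" else
              sprintf("MA > %g", sig_cutoff))
}

#' @export
print.activation_matrix <- function(x, ...) {
  cat(sprintf(
    "<activation_matrix> %d experiments x %d regions, threshold %.0f%% (%s)\n",
    nrow(x), ncol(x), 100 * attr(x, "fraction_threshold"),
    attr(x, "ma_significance_rule")))
  invisible(x)
}

#' @export
tidy.activation_matrix <- function(x, ...) {
  tibble::tibble(experiment_id = rep(rownames(x), ncol(x)),
                 region = rep(as.integer(colnames(x)), each = nrow(x)),
                 active = as.integer(x))
}

#' Joint activation contingency of a homotopic pair
#'
#' Tallies the four joint states over experiments and derives the Bernoulli
#' probabilities theta1..theta4 = P(both), P(a only), P(b only), P(neither),
#' the expected co-activation under independence E = (theta1 + theta2) *
#' (theta1 + theta3), and the attainable bounds on theta1 given the
#' marginals.
#'
#' @param m An `activation_matrix`.
#' @param pair Length-2 vector of region labels (a = left, b = right).
#' @return A `contingency` object.
#' @export
pair_contingency <- function(m, pair) {
  stopifnot(inherits(m, "activation_matrix"), length(pair) == 2L)
  key <- as.character(pair)
  if (!all(key %in% colnames(m))) {
    stop("pair regions not present in the activation matrix", call. = FALSE)
  }
  a <- m[, key[1]] == 1L
  b <- m[, key[2]] == 1L
  n <- length(a)
  if (n == 0L) stop("activation matrix has no experiments", call. = FALSE)
  counts <- c(n11 = sum(a & b), n10 = sum(a & !b),
              n01 = sum(!a & b), n00 = sum(!a & !b))
  contingency(counts, pair = pair)
}

#' @rdname pair_contingency
#' @param counts Named or positional integer vector (n11, n10, n01, n00).
#' @export
contingency <- function(counts, pair = c(NA, NA)) {
  stopifnot(length(counts) == 4L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0L) stop("contingency has zero experiments", call. = FALSE)
  th <- as.numeric(counts) / n
  E <- (th[1] + th[2]) * (th[1] + th[3])
  structure(list(counts = stats::setNames(as.integer(counts),
                                          c("n11", "n10", "n01", "n00")),
                 thetas = stats::setNames(th, paste0("theta", 1:4)),
                 E = E,
                 theta1_max = min(th[1] + th[2], th[1] + th[3]),
                 theta1_min = max(0, 2 * th[1] + th[2] + th[3] - 1),
                 D = as.integer(th[1] >= E),
                 pair = pair),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf(
    "<contingency> n=(%d,%d,%d,%d) theta=(%.3f,%.3f,%.3f,%.3f) E=%.4f\n",
    x$counts[1], x$counts[2], x$counts[3], x$counts[4],
    x$thetas[1], x$thetas[2], x$thetas[3], x$thetas[4], x$E))
  invisible(x)
}

#' Patel's kappa
#'
#' The excess of joint activation probability over independence, normalised
#' by the attainable range given the marginals:
#' `kappa = (theta1 - E) / (D * (max(theta1) - E) + (1 - D) * (E - min(theta1)))`
#' with `E = (theta1 + theta2) * (theta1 + theta3)`,
#' `max(theta1) = min(theta1 + theta2, theta1 + theta3)`,
#' `min(theta1) = max(0, 2 theta1 + theta2 + theta3 - 1)` and the indicator
#' `D = 1` when `theta1 >= E`. Kappa lies in \\[-1, 1\\]: 1 at the maximal
#' attainable co-activation, 0 at exact independence, -1 at the minimal.
#' When either region is never or always active the denominator vanishes and
#' kappa is undefined: the result is `NA` flagged `"degenerate"`, never a
#' number.
#'
#' @param x A `contingency` (see [pair_contingency()]).
#' @return Kappa, or flagged `NA` for degenerate marginals.
#' @examples
#' patel_kappa(contingency(c(30, 10, 10, 50)))  # 0.14 / 0.24
#' @export
patel_kappa <- function(x) {
  stopifnot(inherits(x, "contingency"))
  th <- x$thetas
  k <- kappa_stat(th[1], th[2], th[3], th[4])
  if (is.na(k)) attr(k, "degenerate") <- TRUE
  unname(k)
}

#' @rdname patel_kappa
#' @param theta1,theta2,theta3,theta4 Joint state probabilities (vectorised).
#' @export
kappa_stat <- function(theta1, theta2, theta3, theta4) {
  pa <- theta1 + theta2
  pb <- theta1 + theta3
  E <- pa * pb
  mx <- pmin(pa, pb)
  mn <- pmax(0, pa + pb - 1)
  D <- theta1 >= E
  denom <- ifelse(D, mx - E, E - mn)
  k <- ifelse(denom > 0, (theta1 - E) / denom, NA_real_)
  degen <- pa <= 0 | pa >= 1 | pb <= 0 | pb >= 1
  k[degen] <- NA_real_
  pmin(pmax(k, -1), 1)
}

#' @rdname patel_kappa
#' @param theta Probability 4-vector; closed-form kappa of a generating
#'   model, used as ground truth for synthetic collections.
#' @export
kappa_from_theta <- function(theta) {
  stopifnot(length(theta) == 4L, abs(sum(theta) - 1) < 1e-9)
  kappa_stat(theta[1], theta[2], theta[3], theta[4])
}

#' Monte-Carlo significance of Patel's kappa
#'
#' Samples the posterior of (theta1..theta4) under a flat prior —
#' Dirichlet(counts + 1) — computes kappa per draw, and reports the posterior
#' probability that kappa exceeds the threshold `e`. The pair is declared
#' significant when that probability reaches the credibility level.
#' Degenerate-marginal draws are skipped and counted; if more than half are
#' skipped the result is flagged unreliable.
#'
#' @param x A `contingency`.
#' @param e Connectivity threshold (default 0).
#' @param n_mc Number of Monte-Carlo draws (>= 1000 recommended).
#' @param credibility Posterior probability required for significance.
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @return A `kappa_result` with fields `kappa`, `posterior_prob_exceeds`,
#'   `e`, `n_mc`, `seed`, `significant`, `n_skipped`, `unreliable`.
#' @export
kappa_significance <- function(x, e = 0, n_mc = 10000L, credibility = 0.95,
                               seed = 1L) {
  stopifnot(inherits(x, "contingency"), n_mc >= 1L)
  alpha <- x$counts + 1
  draws <- local_seed(seed, {
    g <- matrix(stats::rgamma(n_mc * 4L, shape = rep(alpha, each = n_mc)),
                n_mc, 4L)
    g / rowSums(g)
  })
  ks <- kappa_stat(draws[, 1], draws[, 2], draws[, 3], draws[, 4])
  skipped <- sum(is.na(ks))
  p <- if (skipped < n_mc) mean(ks[!is.na(ks)] > e) else NA_real_
  structure(list(kappa = patel_kappa(x),
                 posterior_prob_exceeds = p, e = e, n_mc = as.integer(n_mc),
                 seed = as.integer(seed),
                 significant = isTRUE(p >= credibility),
                 credibility = credibility,
                 n_skipped = skipped,
                 unreliable = skipped > n_mc / 2),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<kappa_result> kappa=%.4f P(kappa > %g | data)=%.4f %s\n",
    x$kappa, x$e, x$posterior_prob_exceeds,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Meta-analytic homotopic connectivity
#'
#' The full estimator: per-experiment modeled-activation maps (with midline
#' offset adjustment), the experiments-by-regions activation matrix under the
#' fractional rule, and Patel's kappa with Dirichlet Monte-Carlo significance
#' for every homotopic pair of the atlas.
#'
#' @param foci A `foci_collection` in the atlas space.
#' @param atlas A paired symmetric `parcellation`.
#' @param kernel A [kernel_spec()].
#' @param band Optional [midline_band()]; the default applies the 24-mm
#'   offset adjustment.
#' @param fraction_threshold Activation-matrix threshold (default 0.20).
#' @param sig_cutoff MA significance cutoff (default 0).
#' @param e,n_mc,credibility,seed Monte-Carlo significance parameters, see
#'   [kappa_significance()].
#' @return An `mhc` object: `table` (one row per pair, sorted by kappa
#'   descending), `matrix` (the activation matrix), `atlas`, `params`.
#' @export
mhc <- function(foci, atlas, kernel = kernel_spec(), band = midline_band(),
                fraction_threshold = 0.2, sig_cutoff = 0, e = 0,
                n_mc = 10000L, credibility = 0.95, seed = 1L) {
  if (is.null(atlas$pairs)) atlas$pairs <- homotopic_pairs(atlas)
  m <- activation_matrix(foci, atlas, fraction_threshold = fraction_threshold,
                         sig_cutoff = sig_cutoff, kernel = kernel,
                         band = band)
  tbl <- kappa_table(m, atlas, e = e, n_mc = n_mc, credibility = credibility,
                     seed = seed)
  structure(list(table = tbl, matrix = m, atlas = atlas,
                 params = list(kernel = kernel, band = band,
                               fraction_threshold = fraction_threshold,
                               sig_cutoff = sig_cutoff, e = e, n_mc = n_mc,
                               credibility = credibility, seed = seed)),
            class = "mhc")
}

# Kappa + significance for every atlas pair; one tibble row per pair.
kappa_table <- function(m, atlas, e = 0, n_mc = 10000L, credibility = 0.95,
                        seed = 1L) {
  pairs <- atlas$pairs
  rows <- lapply(seq_len(nrow(pairs)), function(p) {
    ct <- pair_contingency(m, c(pairs$left[p], pairs$right[p]))
    kr <- kappa_significance(ct, e = e, n_mc = n_mc,
                             credibility = credibility,
                             seed = seed + p)
    tibble::tibble(
      pair_id = pairs$pair_id[p],
      left = pairs$left[p], right = pairs$right[p],
      left_name = unname(atlas$names[as.character(pairs$left[p])]),
      right_name = unname(atlas$names[as.character(pairs$right[p])]),
      n11 = ct$counts[["n11"]], n10 = ct$counts[["n10"]],
      n01 = ct$counts[["n01"]], n00 = ct$counts[["n00"]],
      theta1 = ct$thetas[[1]], theta2 = ct$thetas[[2]],
      theta3 = ct$thetas[[3]], theta4 = ct$thetas[[4]],
      E = ct$E, theta1_min = ct$theta1_min, theta1_max = ct$theta1_max,
      kappa = kr$kappa, posterior_prob_exceeds = kr$posterior_prob_exceeds,
      significant = kr$significant, unreliable = kr$unreliable)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$kappa))
}

#' @export
print.mhc <- function(x, ...) {
  cat(sprintf(
    "<mhc> %d pairs over %d experiments; %d significant; kappa range [%.3f, %.3f]\n",
    nrow(x$table), nrow(x$matrix), sum(x$table$significant),
    suppressWarnings(min(x$table$kappa, na.rm = TRUE)),
    suppressWarnings(max(x$table$kappa, na.rm = TRUE))))
  invisible(x)
}

#' @rdname mhc
#' @param x An `mhc` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-pair kappa table; `glance()` a one-row
#'   summary.
#' @export
tidy.mhc <- function(x, ...) x$table

#' @rdname mhc
#' @export
glance.mhc <- function(x, ...) {
  tibble::tibble(n_experiments = nrow(x$matrix),
                 n_pairs = nrow(x$table),
                 n_significant = sum(x$table$significant, na.rm = TRUE),
                 mean_kappa = mean(x$table$kappa, na.rm = TRUE),
                 n_undefined = sum(is.na(x$table$kappa)),
                 fraction_threshold = x$params$fraction_threshold)
}

#' @rdname mhc
#' @param object An `mhc` object.
#' @export
autoplot.mhc <- function(object, ...) {
  tbl <- object$table
  tbl$pair <- factor(paste(tbl$left_name, tbl$right_name, sep = "|"),
                     levels = rev(paste(tbl$left_name, tbl$right_name,
                                        sep = "|")))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$kappa, y = .data$pair,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Patel's kappa", y = NULL,
                  title = "Homotopic co-activation strength per pair") +
    ggplot2::theme_minimal()
}

#' Render a kappa table as a symmetric voxel map
#'
#' Every voxel of both regions of a pair carries that pair's kappa, so the
#' map equals its own mirror by construction. Pairs with undefined kappa are
#' rendered as background (0); `significant_only` masks non-significant
#' pairs to background as well. The map never clamps negative kappa values.
#'
#' @param x An `mhc` object or its `tidy()` table.
#' @param atlas The `parcellation` used (taken from the object if omitted).
#' @param significant_only Render Monte-Carlo-significant pairs only.
#' @return A `voxel_map` of kind `"kappa"`.
#' @export
mhc_map <- function(x, atlas = NULL, significant_only = FALSE) {
  if (inherits(x, "mhc")) {
    if (is.null(atlas)) atlas <- x$atlas
    x <- x$table
  }
  stopifnot(!is.null(atlas))
  vals <- array(0, dim = atlas$grid$dims)
  for (p in seq_len(nrow(x))) {
    k <- x$kappa[p]
    if (is.na(k)) next
    if (significant_only && !isTRUE(x$significant[p])) next
    vals[atlas$labels == x$left[p]] <- k
    vals[atlas$labels == x$right[p]] <- k
  }
  voxel_map(atlas$grid, vals, kind = "kappa")
}

#' Write / read a per-pair kappa table as TSV
#'
#' Values round-trip at full double precision.
#'
#' @param x An `mhc` object or kappa table tibble.
#' @param path TSV path.
#' @return `write_kappa_table()` returns `path` invisibly;
#'   `read_kappa_table()` the tibble.
#' @export
write_kappa_table <- function(x, path) {
  if (inherits(x, "mhc")) x <- x$table
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_kappa_table
#' @export
read_kappa_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
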