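ma_with_fraction <- function(grid, atlas, region, frac) {
  # MA map marking exactly `frac` of `region`'s voxels as active
  vox <- which(atlas$labels == region)
  n <- max(0L, round(frac * length(vox)))
  vals <- array(0, grid$dims)
  if (n > 0) vals[vox[seq_len(n)]] <- 0.5
  voxel_map(grid, vals, "MA_probability")
}

test_that("the fractional activation rule has an inclusive boundary", {
  g <- tiny_grid(c(20, 16, 16), 2)
  at <- gen_synthetic_atlas(g, 1, radius = 5.5, spacing = 13)
  # make the left region exactly 50 voxels by trimming the label field
  lv <- which(at$labels == 1L)
  expect_gte(length(lv), 50L)
  at$labels[lv[-seq_len(50)]] <- 0L
  rv <- which(at$labels == 2L)
  at$labels[rv[-seq_len(50)]] <- 0L
  m10 <- activation_matrix(list(e1 = ma_with_fraction(g, at, 1L, 10 / 50)),
                           at, fraction_threshold = 0.2)
  expect_equal(unname(m10["e1", "1"]), 1L)   # 10 of 50 = exactly 20%
  m9 <- activation_matrix(list(e1 = ma_with_fraction(g, at, 1L, 9 / 50)),
                          at, fraction_threshold = 0.2)
  expect_equal(unname(m9["e1", "1"]), 0L)
})

test_that("threshold 0 means at least one significant voxel", {
  g <- tiny_grid(c(20, 16, 16), 2)
  at <- gen_synthetic_atlas(g, 1, radius = 5.5, spacing = 13)
  one <- ma_with_fraction(g, at, 1L, 1 / sum(at$labels == 1L))
  expect_equal(sum(one$values > 0), 1L)
  m <- activation_matrix(list(e1 = one), at, fraction_threshold = 0)
  expect_equal(unname(m["e1", "1"]), 1L)
  expect_equal(unname(m["e1", "2"]), 0L)
  expect_error(activation_matrix(list(e1 = one), at,
                                 fraction_threshold = 1.5), "0, 1")
})

test_that("foci-collection and map-list activation matrices agree", {
  g <- tiny_grid(c(16, 12, 12), 4)
  at <- gen_synthetic_atlas(g, 2, radius = 5, spacing = 14)
  fc <- gen_coactivation_experiments(
    at, coactivation_spec(c(0.4, 0.2, 0.2, 0.2), 40, seed = 6))
  k <- kernel_spec(8)
  m1 <- activation_matrix(fc, at, kernel = k)
  ids <- attr(fc, "all_experiments")
  mas <- lapply(ids, function(id) {
    rows <- fc[fc$experiment_id == id, , drop = FALSE]
    if (nrow(rows) == 0) return(voxel_map(g, 0, "MA_probability"))
    ma_map(rows, g, k)
  })
  names(mas) <- ids
  m2 <- activation_matrix(mas, at)
  expect_equal(unclass(m1)[, ], unclass(m2)[, ], ignore_attr = TRUE)
})

test_that("contingency arithmetic matches the direct oracle", {
  counts <- c(30, 10, 10, 50)
  ct <- contingency(counts)
  expect_equal(unname(ct$thetas), c(0.30, 0.10, 0.10, 0.50))
  expect_equal(ct$E, 0.16)
  expect_equal(ct$theta1_max, 0.40)
  expect_equal(ct$theta1_min, 0)
  expect_equal(ct$D, 1L)
})

test_that("contingency of identical and complementary columns", {
  g <- tiny_grid(c(16, 12, 12), 4)
  at <- gen_synthetic_atlas(g, 1, radius = 5, spacing = 12)
  rows <- matrix(c(1L, 1L, 0L, 0L,
                   1L, 1L, 0L, 0L), 4, 2)
  m <- homokappa:::new_activation_matrix(rows, paste0("e", 1:4), c(1L, 2L),
                                         0.2, 0)
  ct <- pair_contingency(m, c(1, 2))
  expect_equal(unname(ct$counts[c("n10", "n01")]), c(0L, 0L))
  rows2 <- matrix(c(1L, 1L, 0L, 0L,
                    0L, 0L, 1L, 1L), 4, 2)
  m2 <- homokappa:::new_activation_matrix(rows2, paste0("e", 1:4), c(1L, 2L),
                                          0.2, 0)
  ct2 <- pair_contingency(m2, c(1, 2))
  expect_equal(unname(ct2$counts[c("n11", "n00")]), c(0L, 0L))
})

test_that("Patel's kappa on reference tables", {
  expect_equal(kappa_from_theta(c(0.5, 0, 0, 0.5)), 1)
  expect_equal(kappa_from_theta(c(0.16, 0.24, 0.24, 0.36)), 0)
  expect_equal(patel_kappa(contingency(c(30, 10, 10, 50))),
               (0.30 - 0.16) / (0.40 - 0.16), tolerance = 1e-12)
  expect_equal(kappa_from_theta(c(0, 0.4, 0.4, 0.2)), -1)
})

test_that("degenerate marginals yield flagged NA, never a number", {
  k <- patel_kappa(contingency(c(10, 0, 5, 0)))   # region a always active
  expect_true(is.na(k))
  expect_true(is.na(patel_kappa(contingency(c(0, 0, 5, 5)))))
  expect_error(contingency(c(0, 0, 0, 0)), "zero experiments")
})

test_that("closed-form kappa equals the brute-force transcription to 1e-12", {
  tabs <- random_tables(2000, n = 100, seed = 13)
  th <- tabs / rowSums(tabs)
  mine <- kappa_stat(th[, 1], th[, 2], th[, 3], th[, 4])
  ref <- vapply(seq_len(nrow(th)), function(i)
    kappa_oracle(th[i, 1], th[i, 2], th[i, 3], th[i, 4]), numeric(1))
  ok <- !is.na(ref)
  expect_equal(is.na(mine), is.na(ref))
  expect_lt(max(abs(mine[ok] - ref[ok])), 1e-12)
  # bounds hold for every valid table
  expect_true(all(mine[ok] >= -1 & mine[ok] <= 1))
  t1 <- th[ok, 1]
  mx <- pmin(t1 + th[ok, 2], t1 + th[ok, 3])
  mn <- pmax(0, 2 * t1 + th[ok, 2] + th[ok, 3] - 1)
  expect_true(all(t1 >= mn - 1e-12 & t1 <= mx + 1e-12))
})

test_that("kappa spans [-1, 1] over tables with fixed marginals", {
  # marginals P(a)=P(b)=0.4: theta1 ranges over [0, 0.4]
  t1s <- seq(0, 0.4, by = 0.004)
  ks <- vapply(t1s, function(t1)
    kappa_stat(t1, 0.4 - t1, 0.4 - t1, 0.2 + t1), numeric(1))
  expect_equal(min(ks), -1)
  expect_equal(max(ks), 1)
  expect_true(all(diff(ks) > 0))        # monotone in theta1
})

test_that("posterior probability concentrates and is seed-reproducible", {
  strong <- kappa_significance(contingency(c(500, 0, 0, 500)), e = 0.5,
                               n_mc = 4000, seed = 3)
  expect_gt(strong$posterior_prob_exceeds, 0.99)
  expect_true(strong$significant)

  indep <- kappa_significance(contingency(c(160, 240, 240, 360)), e = 0,
                              n_mc = 4000, seed = 3)
  expect_lt(abs(indep$posterior_prob_exceeds - 0.5), 0.1)
  expect_false(indep$significant)

  again <- kappa_significance(contingency(c(500, 0, 0, 500)), e = 0.5,
                              n_mc = 4000, seed = 3)
  expect_identical(strong$posterior_prob_exceeds,
                   again$posterior_prob_exceeds)
})

test_that("the mhc driver produces a coherent fit object", {
  g <- tiny_grid(c(16, 16, 24), 4)
  at <- gen_synthetic_atlas(g, 4, radius = 6, spacing = 16)
  theta <- rbind(c(0.45, 0.05, 0.05, 0.45),
                 c(0.30, 0.10, 0.10, 0.50),
                 c(0.16, 0.24, 0.24, 0.36),
                 c(0.05, 0.35, 0.35, 0.25))
  fc <- gen_coactivation_experiments(
    at, coactivation_spec(theta, 400, seed = 17))
  fit <- mhc(fc, at, kernel = kernel_spec(8), n_mc = 2000, seed = 5)
  tbl <- tidy(fit)
  expect_equal(nrow(tbl), 4L)
  expect_true(all(diff(tbl$kappa) <= 0))          # sorted descending
  expect_equal(tbl$n11 + tbl$n10 + tbl$n01 + tbl$n00, rep(400L, 4))
  # strongest pair should be the theta with the largest true kappa
  true_k <- apply(theta, 1, kappa_from_theta)
  expect_equal(tbl$pair_id[1], which.max(true_k))
  gl <- glance(fit)
  expect_equal(gl$n_pairs, 4L)
  expect_equal(gl$n_experiments, 400L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("the MHC map is piecewise constant, symmetric, maskable", {
  g <- tiny_grid(c(16, 12, 12), 4)
  at <- gen_synthetic_atlas(g, 2, radius = 5, spacing = 14)
  tbl <- tibble::tibble(pair_id = 1:2, left = 1:2, right = 3:4,
                        kappa = c(0.8, 0.1),
                        significant = c(TRUE, FALSE))
  m <- mhc_map(tbl, at)
  vals <- setdiff(unique(as.vector(m$values)), 0)
  expect_setequal(vals, c(0.8, 0.1))
  expect_identical(mirror_x(m)$values, m$values)
  expect_equal(mean(m$values[at$labels == 1L]), 0.8)
  expect_equal(mean(m$values[at$labels == 3L]), 0.8)
  only_sig <- mhc_map(tbl, at, significant_only = TRUE)
  expect_setequal(setdiff(unique(as.vector(only_sig$values)), 0), 0.8)
  # missing kappa renders as background
  tbl$kappa[2] <- NA
  m2 <- mhc_map(tbl, at)
  expect_setequal(setdiff(unique(as.vector(m2$values)), 0), 0.8)
})

test_that("kappa tables round-trip through TSV at full precision", {
  g <- tiny_grid(c(16, 16, 24), 4)
  at <- gen_synthetic_atlas(g, 4, radius = 6, spacing = 16)
  fc <- gen_coactivation_experiments(
    at, coactivation_spec(c(0.3, 0.1, 0.1, 0.5), 200, seed = 23))
  fit <- mhc(fc, at, kernel = kernel_spec(8), n_mc = 1000, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_kappa_table(fit, f)
  back <- read_kappa_table(f)
  expect_equal(back$kappa, fit$table$kappa, tolerance = 1e-12)
  expect_equal(back$posterior_prob_exceeds,
               fit$table$posterior_prob_exceeds, tolerance = 1e-12)
  expect_equal(back$left_name, fit$table$left_name)
})
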