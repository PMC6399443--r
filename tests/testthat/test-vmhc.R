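test_that("vmhc recovers a planted correlation and its Fisher z", {
  g <- tiny_grid(c(10, 10, 10), 2)
  ser <- gen_rest_timeseries(g, rest_spec(2000, rho = 0.5, seed = 12))
  vm <- vmhc(ser)
  left <- world_x_field(g) < 0
  r <- tanh(vm$values[left])
  expect_lt(abs(mean(r) - 0.5), 0.03)
  expect_lt(abs(mean(vm$values[left]) - atanh(0.5)), 0.05)
  expect_identical(vm$values, mirror_x(vm)$values)
})

test_that("a series equal to its mirror clips r at 1 - 1e-7 and is flagged", {
  g <- tiny_grid(c(6, 6, 6), 2)
  ser <- gen_rest_timeseries(g, rest_spec(60, rho = 1, seed = 2))
  vm <- vmhc(ser)
  expect_equal(max(vm$values), atanh(1 - 1e-7))
  expect_gt(attr(vm, "n_clipped"), 0)
})

test_that("constant series produce missing values at both pair ends", {
  g <- tiny_grid(c(6, 6, 6), 2)
  ser <- gen_rest_timeseries(g, rest_spec(40, rho = 0.3, seed = 3))
  ser$data[2, 3, 3, ] <- 5            # constant voxel
  vm <- vmhc(ser)
  expect_true(is.na(vm$values[2, 3, 3]))
  mirror_i <- which(abs(grid_axis_coords(g, 1) +
                          grid_axis_coords(g, 1)[2]) < 1e-9)
  expect_true(is.na(vm$values[mirror_i, 3, 3]))
  short <- rest_series(g, ser$data[, , , 1:2, drop = FALSE])
  expect_error(vmhc(short), "3 timepoints")
})

test_that("group averaging: identity, cancellation, brute-force oracle", {
  g <- tiny_grid(c(8, 8, 8), 2)
  m <- random_unit_map(g, 4, kind = "fisher_z")
  expect_equal(group_average(list(m, m))$values, m$values)
  neg <- voxel_map(g, -m$values, "fisher_z")
  expect_true(all(group_average(list(m, neg))$values == 0))
  maps <- lapply(5:9, function(s) random_unit_map(g, s, kind = "fisher_z"))
  brute <- Reduce(`+`, lapply(maps, `[[`, "values")) / 5
  expect_equal(group_average(maps)$values, brute, tolerance = 1e-15)
  expect_error(group_average(list()), "no maps")
})

test_that("group averaging skips missing values with per-voxel counts", {
  g <- tiny_grid(c(6, 6, 6), 2)
  a <- voxel_map(g, 1, "fisher_z")
  bv <- array(3, g$dims); bv[1, 1, 1] <- NA
  b <- voxel_map(g, bv, "fisher_z")
  avg <- group_average(list(a, b))
  expect_equal(avg$values[1, 1, 1], 1)      # only the first map contributes
  expect_equal(avg$values[2, 2, 2], 2)
  expect_equal(attr(avg, "n_valid")[1, 1, 1], 1L)
})

test_that("z-scoring standardises and is affine-invariant", {
  g <- tiny_grid(c(8, 8, 8), 2)
  m <- random_unit_map(g, 21, kind = "kappa")
  z <- zscore_map(m)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(z$values)), 1, tolerance = 1e-12)
  aff <- voxel_map(g, 3.7 * m$values + 11, "kappa")
  expect_equal(zscore_map(aff)$values, z$values, tolerance = 1e-12)
  expect_error(zscore_map(voxel_map(g, 2, "kappa")), "zero variance")
})

test_that("map correlation: self, negation, textbook oracle, mask restriction", {
  g <- tiny_grid(c(8, 8, 8), 2)
  a <- random_unit_map(g, 31, kind = "kappa")
  b <- random_unit_map(g, 32, kind = "fisher_z")
  expect_equal(map_correlation(a, a), 1)
  neg <- voxel_map(g, -a$values, "kappa")
  expect_equal(map_correlation(a, neg), -1)
  expect_equal(map_correlation(a, b),
               pearson_oracle(as.vector(a$values), as.vector(b$values)),
               tolerance = 1e-12)
  expect_equal(map_correlation(a, b), map_correlation(b, a))
  # out-of-mask voxels never influence the statistic
  msk <- array(TRUE, g$dims); msk[1:2, , ] <- FALSE
  r_masked <- map_correlation(a, b, mask = msk)
  a2 <- a; a2$values[1:2, , ] <- 99
  expect_equal(map_correlation(a2, b, mask = msk), r_masked)
  expect_error(map_correlation(a, voxel_map(g, 1, "kappa")),
               "zero variance")
})

test_that("VCC downdating equals naive leave-one-out recomputation", {
  # 5-point toy example, exact check
  x <- c(1, 2, 3, 4, 10); y <- c(2, 1, 4, 3, -6)
  v <- vcc(vector_map(x), vector_map(y), normalize = FALSE)
  naive <- vapply(seq_along(x), function(i)
    pearson_oracle(x, y) - pearson_oracle(x[-i], y[-i]), numeric(1))
  expect_lt(max(abs(as.vector(v$values) - naive)), 1e-12)
  expect_equal(attr(v, "r_global"), pearson_oracle(x, y), tolerance = 1e-15)
})

test_that("VCC on perfectly correlated maps is identically zero", {
  x <- rnorm(50)
  v <- vcc(vector_map(x), vector_map(2 * x + 3), normalize = FALSE)
  expect_lt(max(abs(as.vector(v$values))), 1e-12)
})

test_that("an extreme discordant voxel has the most negative normalized VCC", {
  set.seed(41)
  x <- rnorm(99); y <- x + rnorm(99, sd = 0.2)
  x <- c(x, 4); y <- c(y, -4)           # one strongly discordant pair
  v <- vcc(vector_map(x), vector_map(y))
  expect_equal(which.min(as.vector(v$values)), 100L)
  expect_lt(as.vector(v$values)[100], 0)
  # sign convention: removal of the discordant voxel raises r
  raw <- vcc(vector_map(x), vector_map(y), normalize = FALSE)
  expect_lt(as.vector(raw$values)[100], 0)
})

test_that("normalized VCC is z-scored over the mask", {
  set.seed(42)
  x <- rnorm(200); y <- 0.4 * x + rnorm(200)
  v <- vcc(vector_map(x), vector_map(y))
  expect_equal(mean(as.vector(v$values)), 0, tolerance = 1e-12)
  expect_equal(stats::sd(as.vector(v$values)), 1, tolerance = 1e-12)
})

test_that("difference map: zeros, doubling, antisymmetry", {
  g <- tiny_grid(c(8, 8, 8), 2)
  a <- random_unit_map(g, 51, kind = "kappa")
  b <- random_unit_map(g, 52, kind = "fisher_z")
  expect_true(all(abs(difference_map(a, a)$values) < 1e-12))
  neg <- voxel_map(g, -a$values, "kappa")
  expect_equal(difference_map(a, neg)$values, 2 * zscore_map(a)$values,
               tolerance = 1e-12)
  expect_equal(difference_map(a, b)$values, -difference_map(b, a)$values,
               tolerance = 1e-12)
})

test_that("threshold-to-ROI uses a strict cutoff and intersects masks", {
  g <- volume_grid(c(3, 1, 1), 1)
  m <- voxel_map(g, array(c(0.5, 1.0, 1.5), c(3, 1, 1)), "zscore")
  roi <- threshold_to_roi(m, 1)
  expect_equal(as.vector(roi$values), c(0, 0, 1))   # 1.0 excluded: strict
  low <- voxel_map(g, array(c(0.1, 0.5, 0.9), c(3, 1, 1)), "zscore")
  expect_warning(empty <- threshold_to_roi(low, 1), "empty")
  expect_true(all(empty$values == 0))
  disjoint <- array(c(TRUE, TRUE, FALSE), c(3, 1, 1))
  expect_warning(both <- threshold_to_roi(m, 1, manual_mask = disjoint),
                 "empty")
  expect_true(all(both$values == 0))
})

test_that("domain enrichment ranks a planted domain on top", {
  g <- tiny_grid(c(10, 10, 10), 2)
  roi_vals <- array(0, g$dims); roi_vals[3:4, 3:4, 3:4] <- 1
  roi <- voxel_map(g, roi_vals, "mask")
  set.seed(61)
  inside_w <- voxel_to_world(g, which(roi_vals == 1, arr.ind = TRUE))
  unif <- function(n) cbind(runif(n, -9, 9), runif(n, -9, 9),
                            runif(n, -9, 9))
  bg <- unif(200)
  foci <- rbind(
    data.frame(x = inside_w[rep(1:8, 5), 1], y = inside_w[rep(1:8, 5), 2],
               z = inside_w[rep(1:8, 5), 3], domain = "speech"),
    data.frame(x = bg[, 1], y = bg[, 2], z = bg[, 3], domain = "other"))
  tab <- domain_enrichment(roi, foci)
  expect_equal(tab$domain[1], "speech")
  expect_gt(tab$z[1], 3)
  expect_true(tab$significant[1])
  # the uniform background falls below the planted-enriched base rate
  expect_lt(tab$z[tab$domain == "other"], 0)
})

test_that("domains hitting the ROI at the common base rate score near zero", {
  g <- tiny_grid(c(10, 10, 10), 2)
  roi_vals <- array(0, g$dims); roi_vals[3:6, 3:6, 3:6] <- 1
  roi <- voxel_map(g, roi_vals, "mask")
  set.seed(62)
  unif <- function(n, dom) data.frame(x = runif(n, -9, 9),
                                      y = runif(n, -9, 9),
                                      z = runif(n, -9, 9), domain = dom)
  tab <- domain_enrichment(roi, rbind(unif(800, "a"), unif(800, "b")))
  expect_true(all(abs(tab$z) < 3))
  expect_false(any(tab$significant))
})

test_that("domain enrichment degenerate base rates error out", {
  g <- tiny_grid(c(6, 6, 6), 2)
  roi <- voxel_map(g, 1, "mask")          # whole grid: p0 = 1
  foci <- data.frame(x = 0.5, y = 0.5, z = 0.5, domain = "a")
  expect_error(domain_enrichment(roi, foci), "degenerate")
  empty <- voxel_map(g, 0, "mask")
  expect_error(domain_enrichment(empty, foci), "empty")
})

test_that("compare_maps bundles r, VCC and difference coherently", {
  g <- tiny_grid(c(10, 10, 10), 2)
  set.seed(71)
  base <- array(rnorm(prod(g$dims)), g$dims)
  a <- voxel_map(g, base + rnorm(prod(g$dims), sd = 0.5), "kappa")
  b <- voxel_map(g, base + rnorm(prod(g$dims), sd = 0.5), "fisher_z")
  cmp <- compare_maps(a, b)
  expect_equal(cmp$r_global, map_correlation(a, b))
  expect_gt(cmp$r_global, 0.5)
  expect_equal(attr(cmp$vcc, "r_global"), cmp$r_global)
  gl <- glance(cmp)
  expect_equal(gl$n_voxels, prod(g$dims))
  td <- tidy(cmp)
  expect_equal(nrow(td), prod(g$dims))
  expect_s3_class(autoplot(cmp), "ggplot")
})

test_that("regional discordance drives VCC down where difference is large", {
  # planted structure: one region disagrees between the maps
  g <- tiny_grid(c(10, 10, 10), 2)
  set.seed(81)
  base <- array(rnorm(prod(g$dims)), g$dims)
  a_vals <- base + rnorm(prod(g$dims), sd = 0.3)
  b_vals <- base + rnorm(prod(g$dims), sd = 0.3)
  region <- array(FALSE, g$dims); region[7:10, 7:10, 7:10] <- TRUE
  b_vals[region] <- -base[region] + rnorm(sum(region), sd = 0.3)
  a <- voxel_map(g, a_vals, "kappa"); b <- voxel_map(g, b_vals, "fisher_z")
  cmp <- compare_maps(a, b)
  d <- abs(cmp$difference$values)
  v <- cmp$vcc$values
  expect_lt(pearson_oracle(as.vector(d), as.vector(v)), 0)
  expect_lt(mean(v[region]), mean(v[!region]))
})
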