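test_that("smoothness of unsmoothed white noise is about one voxel", {
  set.seed(41)
  mask <- spherical_mask(c(20, 20, 20))
  res <- matrix(rnorm(20 * sum(mask$data)), 20)
  est <- estimate_smoothness(res, mask)
  # gradient estimator gives d * sqrt(2 ln 2) ~ 1.18 voxels for white noise
  expect_true(all(abs(est$fwhm_mm - 2 * sqrt(2 * log(2))) /
                    (2 * sqrt(2 * log(2))) < 0.2))
})

test_that("FWHM scales with voxel size", {
  set.seed(42)
  mask2 <- spherical_mask(c(16, 16, 16), voxel_size = c(2, 2, 2))
  mask4 <- spherical_mask(c(16, 16, 16), voxel_size = c(4, 4, 4))
  res <- matrix(rnorm(10 * sum(mask2$data)), 10)
  e2 <- estimate_smoothness(res, mask2)
  e4 <- estimate_smoothness(res, mask4)
  expect_equal(e4$fwhm_mm, 2 * e2$fwhm_mm, tolerance = 1e-12)
  expect_error(estimate_smoothness(matrix(1, 3, sum(mask2$data)), mask2),
               "constant")
})

test_that("cluster-null thresholds are monotone, seeded and bounded", {
  mask <- spherical_mask(c(16, 16, 16))
  tab <- simulate_cluster_null(mask, fwhm_mm = 6,
                               voxel_p = c(0.01, 0.005),
                               alpha = c(0.05, 0.10, 1.0),
                               n_iter = 300, seed = 7)
  tt <- tab$table
  k <- function(p, a) tt$k_voxels[tt$voxel_p == p & tt$alpha == a]
  expect_equal(k(0.01, 1.0), 1L)                    # alpha = 1: anything
  expect_gte(k(0.01, 0.05), k(0.01, 0.10))          # monotone in alpha
  expect_gte(k(0.01, 0.05), k(0.005, 0.05))         # monotone in voxel p
  expect_equal(tt$k_mm3, tt$k_voxels * 8)           # exact mm^3

  tab2 <- simulate_cluster_null(mask, 6, c(0.01, 0.005),
                                c(0.05, 0.10, 1.0), 300, seed = 7)
  expect_identical(tab$table, tab2$table)           # determinism
  expect_error(simulate_cluster_null(
    volume_image(array(FALSE, c(4, 4, 4))), 6, 0.01, 0.05, 10, 1),
    "empty mask")
})

test_that("smoothing inflates the null cluster extent", {
  mask <- spherical_mask(c(16, 16, 16))
  t0 <- simulate_cluster_null(mask, 0, 0.01, 0.05, 300, seed = 3)
  t6 <- simulate_cluster_null(mask, 6, 0.01, 0.05, 300, seed = 3)
  m0 <- t0$max_sizes[, 1]; m6 <- t6$max_sizes[, 1]
  sep <- (mean(m6) - mean(m0)) /
    sqrt(var(m6) / length(m6) + var(m0) / length(m0))
  expect_gt(sep, 3)                                  # 3-SE separation
  expect_gt(t6$table$k_voxels, t0$table$k_voxels)
})

test_that("cluster extraction: sizes, units and connectivity semantics", {
  d <- c(8, 8, 8)
  a <- array(0, d)
  a[2, 2, 2] <- 5
  cs <- extract_clusters(volume_image(a), 2.5, array(TRUE, d))
  expect_equal(nrow(cs$clusters), 1L)
  expect_equal(cs$clusters$n_voxels, 1L)
  expect_equal(cs$clusters$mm3, 8)                   # 2 mm isotropic

  # two voxels sharing only a corner
  b <- array(0, d); b[3, 3, 3] <- 4; b[4, 4, 4] <- -4
  cs6 <- extract_clusters(volume_image(b), 3, array(TRUE, d),
                          connectivity = 6)
  cs26 <- extract_clusters(volume_image(b), 3, array(TRUE, d),
                           connectivity = 26)
  expect_equal(nrow(cs6$clusters), 2L)
  expect_equal(nrow(cs26$clusters), 1L)

  # 140 contiguous voxels at 2 mm iso = 1120 mm^3
  cc <- array(0, c(10, 10, 10)); cc[1:5, 1:7, 1:4] <- 3  # 140 voxels
  cs140 <- extract_clusters(volume_image(cc), 2, array(TRUE, c(10, 10, 10)))
  expect_equal(cs140$clusters$n_voxels, 140L)
  expect_equal(cs140$clusters$mm3, 1120)
  expect_equal(cs140$clusters$peak_value, 3)
})

test_that("cluster correction keeps >= threshold and errors off-table", {
  d <- c(10, 10, 10)
  mask <- array(TRUE, d)
  tab <- structure(list(
    table = data.frame(voxel_p = 0.01, alpha = 0.05, k_voxels = 8L,
                       k_mm3 = 64),
    n_iter = 1000, seed = 1, connectivity = 6, fwhm_mm = 6,
    two_tailed = TRUE, voxel_size = c(2, 2, 2)),
    class = "cluster_threshold_table")

  z <- array(0, d)
  z[1:2, 1:2, 1:2] <- 4        # exactly 8 voxels: retained (>= semantics)
  z[8, 8, 8] <- 4              # 1 voxel: removed
  m <- stat_map(z, mask, "z", 100)
  out <- apply_cluster_correction(m, tab, 0.01, 0.05)
  expect_equal(sum(out$mask$data), 8)
  expect_equal(nrow(out$clusters$clusters), 1L)
  expect_equal(out$k_voxels, 8L)

  empty <- apply_cluster_correction(stat_map(array(0, d), mask, "z", 100),
                                    tab, 0.01, 0.05)
  expect_equal(sum(empty$mask$data), 0)
  expect_error(apply_cluster_correction(m, tab, 0.005, 0.05), "no entry")
})

test_that("threshold tables survive a JSON round trip", {
  mask <- spherical_mask(c(12, 12, 12))
  tab <- simulate_cluster_null(mask, 4, 0.01, 0.05, 50, seed = 2)
  f <- tempfile(fileext = ".json")
  write_cluster_table(tab, f)
  back <- read_cluster_table(f)
  expect_equal(back$table, tab$table)
  expect_equal(back$connectivity, tab$connectivity)
  unlink(f)
})
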