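test_that("feature rows are centered and scaled to unit norm", {
  X <- rbind(c(1, -1, 0), c(2, 5, -1))
  Xn <- row_normalize_features(X)
  expect_equal(Xn[1, ], c(1, -1, 0) / sqrt(2))
  expect_true(all(abs(rowMeans(Xn)) < 1e-12))
  expect_true(all(abs(rowSums(Xn^2) - 1) < 1e-12))
  expect_error(row_normalize_features(rbind(c(2, 2, 2))), "zero-variance")
  expect_error(row_normalize_features(cbind(1:4)), "K >= 2")

  set.seed(3)
  Xr <- row_normalize_features(matrix(rnorm(200), 20))
  expect_true(all(abs(rowMeans(Xr)) < 1e-12))
  expect_true(all(abs(sqrt(rowSums(Xr^2)) - 1) < 1e-12))
})

test_that("center initialization follows the lattice geometry", {
  mask <- random_mask(c(9, 9, 9), p = 0.8, seed = 5)
  c1 <- init_centers(mask, 1L)
  ctr <- colMeans(mask$vox)
  d2 <- rowSums(sweep(mask$vox, 2, ctr, "-")^2)
  expect_equal(c1, which.min(d2))

  # cubes on a 10x10x10 full mask with K = 8: the 2x2x2 grid of
  # 5x5x5-cube centers, i.e. voxel indices {2,7} per axis
  full10 <- full_mask(c(10, 10, 10))
  c8 <- init_centers(full10, 8L, scheme = "cubes")
  expect_length(c8, 8L)
  got <- full10$vox[c8, ]
  want <- as.matrix(expand.grid(c(2, 7), c(2, 7), c(2, 7)))
  expect_equal(pairs3_sorted(got), pairs3_sorted(want))

  # spheres on a 20x20x20 full mask with K = 64: count within 15 percent
  full20 <- full_mask(c(20, 20, 20))
  c64 <- init_centers(full20, 64L)
  expect_true(abs(length(c64) - 64) <= 0.15 * 64)
  expect_error(init_centers(full10, 2000L), "exceeds")
})

test_that("the unified distance combines feature and spatial terms", {
  expect_equal(unified_distance(c(1, 2), c(1, 2), c(0, 0, 0), c(0, 0, 0),
                                m = 2, S = 3), 0)
  expect_equal(unified_distance(c(1, 2), c(1, 2), c(0, 0, 0), c(3, 0, 0),
                                m = 1, S = 3), 1)
  set.seed(9)
  x1 <- rnorm(5); x2 <- rnorm(5); u1 <- rnorm(3); u2 <- rnorm(3)
  expect_equal(unified_distance(x1, x2, u1, u2, m = 2, S = 3),
               sum((x1 - x2)^2) / 4 + sum((u1 - u2)^2) / 9,
               tolerance = 1e-12)
})

test_that("SLIC labels every voxel and terminates deterministically", {
  mask <- full_mask(c(8, 8, 4))
  set.seed(2)
  X <- row_normalize_features(matrix(rnorm(mask$n * 4), mask$n))
  cen <- init_centers(mask, 6L)
  ctrl <- slic_control(max_iter = 40L)
  p1 <- slic_assign_update(X, mask$mm, cen, mask, K_init = 6L, ctrl)
  p2 <- slic_assign_update(X, mask$mm, cen, mask, K_init = 6L, ctrl)
  expect_identical(p1$labels, p2$labels)
  expect_true(all(p1$labels >= 1L))
  expect_length(p1$labels, mask$n)
  expect_lte(p1$iterations, 40L)

  # K = 1: everything in one cluster after one sweep
  pk1 <- slic_assign_update(X, mask$mm, init_centers(mask, 1L), mask,
                            K_init = 1L, ctrl)
  expect_true(all(pk1$labels == 1L))
})

test_that("two separated blobs with orthogonal features are recovered", {
  inside <- array(FALSE, c(11, 4, 4))
  inside[1:4, , ] <- TRUE
  inside[8:11, , ] <- TRUE
  mask <- gm_mask(inside)
  blob <- (mask$vox[, 1] >= 7) + 1L
  X <- cbind(ifelse(blob == 1L, 1, -1), ifelse(blob == 1L, -1, 1))
  X <- row_normalize_features(X + matrix(rnorm(mask$n * 2, sd = 0.01),
                                         mask$n))
  cen <- c(which(blob == 1L)[1L], which(blob == 2L)[1L])
  p <- slic_assign_update(X, mask$mm, cen, mask, K_init = 2L,
                          slic_control(S = 6))
  expect_equal(p$k_actual, 2L)
  expect_true(all(tapply(p$labels, blob, function(l) length(unique(l))) == 1))
  expect_lte(p$iterations, 3L)
})

test_that("an 8-parcel cube phantom is recovered from indicator features", {
  spec <- phantom_spec(dims = c(20L, 20L, 20L), K_true = 8L, seed = 0L)
  planted <- plant_parcellation(spec)
  mask <- planted$mask
  set.seed(0)
  X <- diag(8)[planted$labels, ] + matrix(rnorm(mask$n * 8, sd = 0.05),
                                          mask$n)
  X <- row_normalize_features(X)
  p <- slic_cluster(X, mask, 8L)
  expect_gte(dice_adjacency(p, planted), 0.95)
})

test_that("constant features give near-even geometric tiles", {
  mask <- full_mask(c(16, 16, 8))
  X <- matrix(0, mask$n, 3)
  cen <- init_centers(mask, 16L)
  p <- slic_assign_update(X, mask$mm, cen, mask, K_init = 16L)
  sizes <- tabulate(p$labels)
  expect_lt(sd(sizes) / mean(sizes), 0.5)
  expect_true(all(p$labels >= 1L))
})

test_that("parcellate_subject composes the pipeline and reports K drift", {
  co <- tiny_phantom(dims = c(14L, 14L, 8L), K_true = 6L, n_time = 100L,
                     n_subjects = 1L, seed = 3L)
  W <- apply_weighting(normalize_timecourses(co$subjects[[1L]]),
                       support_ss1(co$mask))
  p <- parcellate_subject(W, co$mask, 6L)
  expect_equal(p$k_init, 6L)
  expect_equal(p$k_difference, p$k_actual - 6L)
  expect_gte(dice_adjacency(p, co$planted), 0.7)

  p1 <- parcellate_subject(W, co$mask, 1L)
  expect_equal(p1$k_actual, 1L)
  expect_equal(p1$k_difference, 0L)
})

test_that("four disconnected blobs with a block weight matrix give one cluster each", {
  inside <- array(FALSE, c(9, 9, 2))
  inside[1:3, 1:3, ] <- TRUE; inside[7:9, 1:3, ] <- TRUE
  inside[1:3, 7:9, ] <- TRUE; inside[7:9, 7:9, ] <- TRUE
  mask <- gm_mask(inside)
  blob <- 1L + (mask$vox[, 1] >= 6) + 2L * (mask$vox[, 2] >= 6)
  m <- outer(blob, blob, "==") * 0.8
  diag(m) <- 0
  W <- slicparc:::sparse_w(Matrix::drop0(methods::as(m, "CsparseMatrix")))
  p <- parcellate_subject(W, mask, 4L,
                          slic_control(coupling = 0.01, S = 5))
  expect_equal(p$k_actual, 4L)
  expect_true(all(tapply(p$labels, blob,
                         function(l) length(unique(l))) == 1))
})
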