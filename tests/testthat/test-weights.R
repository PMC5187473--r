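test_that("SS1 support equals brute-force 26-neighborhood enumeration", {
  mask <- full_mask(c(3, 3, 3))
  s <- support_ss1(mask)
  r <- mask$row_of_voxel
  # corner neighbor (0,0,0)-(1,1,1) in, (0,0,0)-(2,0,0) out
  i1 <- r[1, 1, 1]; j1 <- r[2, 2, 2]; j2 <- r[3, 1, 1]
  m <- as_pair_matrix(s)
  expect_true(any(m[, 1] == min(i1, j1) & m[, 2] == max(i1, j1)))
  expect_false(any(m[, 1] == min(i1, j2) & m[, 2] == max(i1, j2)))

  rmask <- random_mask(c(8, 8, 8), p = 0.5, seed = 9)
  got <- pairs_sorted(as_pair_matrix(support_ss1(rmask)))
  want <- pairs_sorted(oracle_neighbor_pairs(rmask))
  expect_equal(got, unname(want))
})

test_that("SS2 support equals dense row/column top-k union with ties kept", {
  mask3 <- full_mask(c(3, 1, 1))
  ts3 <- random_ts(mask3, n_time = 10L, seed = 2)
  s <- support_ss2(ts3, k_reserve = 2L)
  expect_equal(nrow(as_pair_matrix(s)), 3L)  # k >= N-1 keeps all pairs

  # one hub voxel that is everyone's best match
  mask4 <- full_mask(c(4, 1, 1))
  set.seed(31)
  base <- rnorm(20)
  d <- rbind(base, base + 0.2 * rnorm(20), base + 0.2 * rnorm(20),
             base + 0.2 * rnorm(20))
  ts4 <- normalize_timecourses(masked_ts(d, mask4))
  s1 <- support_ss2(ts4, k_reserve = 1L)
  want <- pairs_sorted(oracle_topk_support(ts4$data, 1L))
  expect_equal(pairs_sorted(as_pair_matrix(s1)), unname(want))

  mask30 <- full_mask(c(30, 1, 1))
  ts30 <- random_ts(mask30, n_time = 15L, seed = 4)
  got <- pairs_sorted(as_pair_matrix(support_ss2(ts30, k_reserve = 5L,
                                                 block_size = 7L)))
  want <- pairs_sorted(oracle_topk_support(ts30$data, 5L))
  expect_equal(got, unname(want))
  expect_error(support_ss2(ts30, k_reserve = 30L), "< N")
})

test_that("SS3 support matches a global sort-and-cut at the target rate", {
  mask <- full_mask(c(40, 1, 1))
  ts <- random_ts(mask, n_time = 25L, seed = 8)
  n <- mask$n
  npairs <- n * (n - 1) / 2

  # extreme quantile: keep exactly the single largest pair
  s1 <- support_ss3(ts, target_sparse_rate = 1 - 1 / npairs)
  C <- tcrossprod(ts$data); diag(C) <- -Inf
  top <- which(C == max(C), arr.ind = TRUE)[1, ]
  expect_equal(as_pair_matrix(s1),
               cbind(min(top), max(top)), ignore_attr = TRUE)

  # rate 0 keeps everything
  s0 <- support_ss3(ts, target_sparse_rate = 0)
  expect_equal(nrow(as_pair_matrix(s0)), npairs)

  # SS1-derived rate matches the dense oracle
  rate <- support_sparse_rate(support_ss1(mask))
  got <- pairs_sorted(as_pair_matrix(support_ss3(ts, rate)))
  want <- pairs_sorted(oracle_threshold_support(ts$data, rate))
  expect_equal(got, unname(want))
  achieved <- support_sparse_rate(support_ss3(ts, rate))
  expect_lt(abs(achieved - rate), 1 / n)

  # identical rows -> all off-diagonal weights equal -> degenerate
  const <- normalize_timecourses(
    masked_ts(matrix(rnorm(10), 5, 10, byrow = TRUE), full_mask(c(5, 1, 1))))
  expect_error(support_ss3(const, 0.5), "degenerate")
})

test_that("weighting functions implement the stated formulas", {
  mask <- full_mask(c(4, 1, 1))
  set.seed(5)
  d <- matrix(rnorm(40), 4)
  d[2, ] <- d[1, ]  # identical pair
  ts <- normalize_timecourses(masked_ts(d, mask))
  sup <- support_ss1(mask)

  wc <- apply_weighting(ts, sup, weighting_config("correlation"))
  expect_equal(wc$W[1, 2], 1)
  wg <- apply_weighting(ts, sup, weighting_config("gaussian", sigma = 0.8))
  expect_equal(wg$W[1, 2], 1)  # exp(0)

  # gaussian weight equals exp(-2 (1 - corr) / sigma^2)
  r34 <- ts_correlation(ts, 3, 4)
  expect_equal(wg$W[3, 4], exp(-2 * (1 - r34) / 0.8^2), tolerance = 1e-12)

  wcst <- apply_weighting(ts, sup, weighting_config("constant"))
  expect_true(all(wcst$W@x == 1))

  # shimalik: spatial cutoff removes far pairs, formula holds inside
  cfg <- weighting_config("shimalik", sigma_v = 1.2, sigma_u = 2,
                          radius_r = 1.5)
  wsm <- apply_weighting(ts, sup, cfg)
  expect_equal(wsm$W[1, 3], 0)  # 2 mm apart under SS1? not in support
  d2 <- sum((ts$data[1, ] - ts$data[2, ])^2)
  expect_equal(wsm$W[1, 2], exp(-d2 / 1.2^2 - 1 / 2^2), tolerance = 1e-12)

  expect_error(apply_weighting(masked_ts(d, mask), sup), "normalized")
})

test_that("weight matrices are exactly symmetric with repaired diagonals", {
  mask <- random_mask(c(6, 6, 6), p = 0.6, seed = 13)
  ts <- random_ts(mask, n_time = 20L, seed = 13)
  for (cfg in list(weighting_config("correlation"),
                   weighting_config("gaussian"),
                   weighting_config("constant"))) {
    W <- apply_weighting(ts, support_ss1(mask), cfg)
    expect_equal(max(abs(W$W - Matrix::t(W$W))), 0)
    expect_true(all(Matrix::diag(W$W) == 0))
  }
  # SS3 at a harsh rate leaves empty rows; they get diagonal ones
  s3 <- support_ss3(ts, 0.995)
  W3 <- apply_weighting(ts, s3, weighting_config("correlation"))
  empty <- which(Matrix::rowSums(W3$W != 0) == 0)
  expect_true(length(empty) > 0)
  expect_true(all(empty %in% W3$diag_ones))
})

test_that("constant weighting on SS1 equals the 26-neighborhood indicator", {
  mask <- random_mask(c(7, 7, 7), p = 0.7, seed = 17)
  sup <- support_ss1(mask)
  tsA <- random_ts(mask, n_time = 15L, seed = 1)
  tsB <- random_ts(mask, n_time = 15L, seed = 2)
  WA <- apply_weighting(tsA, sup, weighting_config("constant"))
  WB <- apply_weighting(tsB, sup, weighting_config("constant"))
  expect_equal(WA$W, WB$W)  # independent of the data
  m <- as_pair_matrix(sup)
  ind <- Matrix::sparseMatrix(i = c(m[, 1], m[, 2]), j = c(m[, 2], m[, 1]),
                              x = 1, dims = c(mask$n, mask$n))
  expect_equal(max(abs(WA$W - ind)), 0)
})

test_that("sparse_rate counts zero off-diagonal entries", {
  mask <- full_mask(c(10, 1, 1))
  ts <- random_ts(mask, n_time = 10L, seed = 3)
  sup <- support_ss1(mask)  # path: 9 adjacent pairs
  W <- apply_weighting(ts, sup, weighting_config("constant"))
  expect_equal(sparse_rate(W), 1 - 18 / 90)
  empty <- slicparc:::sparse_w(
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(10, 10)), diag_ones = 1:10)
  expect_equal(sparse_rate(empty), 1)
  full_sup <- support_ss3(ts, 0)
  Wf <- apply_weighting(ts, full_sup, weighting_config("constant"))
  expect_equal(sparse_rate(Wf), 0)
})

test_that("fisher_mean averages on the z scale and is idempotent", {
  mask <- full_mask(c(5, 1, 1))
  tsA <- random_ts(mask, n_time = 12L, seed = 21)
  tsB <- random_ts(mask, n_time = 12L, seed = 22)
  sup <- support_ss1(mask)
  WA <- apply_weighting(tsA, sup)
  WB <- apply_weighting(tsB, sup)
  same <- fisher_mean(list(WA, WA, WA))
  expect_lt(max(abs(same$W - WA$W)), 1e-12)
  avg <- fisher_mean(list(WA, WB))
  expect_equal(avg$W[1, 2],
               tanh((atanh(WA$W[1, 2]) + atanh(WB$W[1, 2])) / 2),
               tolerance = 1e-12)
  expect_error(fisher_mean(list()), "empty")
})

test_that("parcellation adjacency and averaging match dense arithmetic", {
  mask <- full_mask(c(4, 1, 1))
  one <- parcellation(mask, rep(1L, 4))
  A1 <- adjacency_from_parcellation(one)
  expect_equal(Matrix::nnzero(A1$W), 12)
  singl <- parcellation(mask, 1:4)
  expect_equal(Matrix::nnzero(adjacency_from_parcellation(singl)$W), 0)

  mask25 <- full_mask(c(25, 1, 1))
  set.seed(23)
  labs <- sample.int(5, 25, replace = TRUE)
  parc <- parcellation(mask25, labs)
  A <- as.matrix(adjacency_from_parcellation(parc)$W)
  want <- outer(parc$labels, parc$labels, "==") * 1
  diag(want) <- 0
  expect_equal(A, want, ignore_attr = TRUE)

  A2 <- adjacency_from_parcellation(parcellation(mask25,
                                                 rep(1:5, each = 5)))
  A3 <- adjacency_from_parcellation(parcellation(mask25,
                                                 rep(1:5, times = 5)))
  avg <- average_adjacency(list(A2, A3, A2))
  dense <- (2 * as.matrix(A2$W) + as.matrix(A3$W)) / 3
  expect_equal(as.matrix(avg$W), dense, ignore_attr = TRUE)
  expect_error(average_adjacency(list()), "empty")
})

test_that("weight matrices round-trip through Matrix Market files", {
  mask <- random_mask(c(5, 5, 5), p = 0.6, seed = 25)
  ts <- random_ts(mask, n_time = 10L, seed = 25)
  W <- apply_weighting(ts, support_ss3(ts, 0.99))
  f <- tempfile(fileext = ".mtx")
  write_weights_mtx(W, f)
  back <- read_weights_mtx(f)
  expect_lt(max(abs(W$W - back$W)), 1e-12)
  expect_equal(sort(back$diag_ones), sort(W$diag_ones))
})
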