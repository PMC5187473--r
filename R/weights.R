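# 26-connectivity offsets.  half = one representative per unordered pair.
neighbor_offsets <- function(half = FALSE) {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0L, , drop = FALSE]
  if (half)
    o <- o[o[, 3] > 0L | (o[, 3] == 0L & o[, 2] > 0L) |
             (o[, 3] == 0L & o[, 2] == 0L & o[, 1] > 0L), , drop = FALSE]
  o
}

# All unordered 26-neighbour in-mask row pairs, vectorized over offsets.
neighbor_pairs <- function(mask) {
  dims <- mask$grid$dims
  offs <- neighbor_offsets(half = TRUE)
  ii <- vector("list", nrow(offs)); jj <- ii
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(mask$vox, 2L, offs[k, ], "+")
    ok <- nb[, 1] >= 0L & nb[, 1] < dims[1] &
          nb[, 2] >= 0L & nb[, 2] < dims[2] &
          nb[, 3] >= 0L & nb[, 3] < dims[3]
    r <- mask$row_of_voxel[nb[ok, , drop = FALSE] + 1L]
    hit <- r > 0L
    ii[[k]] <- which(ok)[hit]
    jj[[k]] <- r[hit]
  }
  i <- unlist(ii); j <- unlist(jj)
  list(i = pmin(i, j), j = pmax(i, j))
}

# Canonicalize a pair list into a pair_support: i < j, sorted, unique.
pair_support <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(i == j)) { keep <- i != j; i <- i[keep]; j <- j[keep] }
  ii <- pmin(i, j); jj <- pmax(i, j)
  key <- (ii - 1) * as.double(n) + jj  # exact for n well below 2^26
  o <- order(key)
  ii <- ii[o]; jj <- jj[o]; key <- key[o]
  keep <- !duplicated(key)
  structure(list(i = ii[keep], j = jj[keep], n = as.integer(n)),
            class = "pair_support")
}

#' @export
print.pair_support <- function(x, ...) {
  cat(sprintf("Support set: %d voxel pairs on %d voxels (sparse rate %.4f)\n",
              length(x$i), x$n, support_sparse_rate(x)))
  invisible(x)
}

#' Sparse rate of a support set
#'
#' Fraction of zero off-diagonal entries, `1 - 2P / (N(N-1))` for P retained
#' pairs.
#'
#' @param support a support set from [support_ss1()], [support_ss2()] or
#'   [support_ss3()].
#' @return Sparse rate in \[0, 1\].
#' @export
support_sparse_rate <- function(support) {
  stopifnot(inherits(support, "pair_support"))
  n <- as.double(support$n)
  1 - 2 * length(support$i) / (n * (n - 1))
}

#' Sparsifying scheme 1: 26-connected spatial constraint
#'
#' Retains exactly the pairs of in-mask voxels whose indices differ by at
#' most one on every axis (the 26-connected neighborhood).
#'
#' @param mask a [gm_mask()].
#' @return A support set (class `pair_support`).
#' @export
support_ss1 <- function(mask) {
  stopifnot(inherits(mask, "gm_mask"))
  p <- neighbor_pairs(mask)
  pair_support(p$i, p$j, mask$n)
}

# Dense correlation rows for a block of voxels: block x N matrix.
corr_block <- function(V, rows) {
  tcrossprod(V[rows, , drop = FALSE], V)
}

# k-th largest value via ascending partial sort (base sort() does not
# support partial together with decreasing).
kth_largest <- function(v, k) {
  n <- length(v)
  sort(v, partial = n - k + 1L)[n - k + 1L]
}

#' Sparsifying scheme 2: per-row/column top-k retention
#'
#' Keeps pair (i, j) iff the correlation w_ij is among the `k_reserve`
#' largest off-diagonal values of row i or of row j of the full correlation
#' matrix (symmetric union; ties at the k-th value are all kept).  The full
#' matrix is scanned blockwise and never materialized at once.
#'
#' @param ts_norm normalized [masked_ts()].
#' @param k_reserve number of largest values reserved per row/column
#'   (default 17).
#' @param block_size rows per dense block.
#' @return A support set.
#' @export
support_ss2 <- function(ts_norm, k_reserve = 17L, block_size = 1024L) {
  stopifnot(inherits(ts_norm, "masked_ts"))
  if (!ts_norm$normalized) stop("time courses must be normalized first")
  n <- nrow(ts_norm$data)
  k_reserve <- as.integer(k_reserve)
  if (k_reserve < 1L) stop("'k_reserve' must be >= 1")
  if (k_reserve >= n) stop("'k_reserve' must be < N = ", n)
  ii <- list(); jj <- list(); b <- 0L
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    B <- corr_block(ts_norm$data, rows)
    B[cbind(seq_along(rows), rows)] <- -Inf
    th <- apply(B, 1L, kth_largest, k = k_reserve)
    hit <- which(B >= matrix(th, nrow(B), ncol(B)), arr.ind = TRUE)
    b <- b + 1L
    ii[[b]] <- rows[hit[, 1L]]
    jj[[b]] <- hit[, 2L]
  }
  pair_support(unlist(ii), unlist(jj), n)
}

# Collect all off-diagonal upper-triangle correlations (exact for
# n <= exact_limit, seeded subsample of `sample_pairs` pairs above).
collect_pair_corrs <- function(V, exact_limit = 20000L,
                               sample_pairs = 1e7, sample_seed = 760613L,
                               block_size = 1024L) {
  n <- nrow(V)
  if (n <= exact_limit) {
    out <- vector("list", ceiling(n / block_size)); b <- 0L
    for (start in seq(1L, n, by = block_size)) {
      rows <- start:min(start + block_size - 1L, n)
      B <- corr_block(V, rows)
      keep <- which(col(B) > rows[row(B)])  # strict upper triangle
      b <- b + 1L
      out[[b]] <- B[keep]
    }
    unlist(out)
  } else {
    with_preserved_seed({
      set.seed(sample_seed)
      i <- sample.int(n, sample_pairs, replace = TRUE)
      j <- sample.int(n - 1L, sample_pairs, replace = TRUE)
      j <- j + (j >= i)
      rowSums(V[i, , drop = FALSE] * V[j, , drop = FALSE])
    })
  }
}

# Run code with the global RNG state preserved.
with_preserved_seed <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Sparsifying scheme 3: global quantile threshold
#'
#' Chooses the threshold t as the `target_sparse_rate` quantile of all
#' off-diagonal correlations and keeps pairs with w_ij >= t, so the achieved
#' sparse rate matches the target up to ties.  The target is typically the
#' sparse rate of [support_ss1()] on the same mask, which makes the three
#' schemes comparable.
#'
#' @param ts_norm normalized [masked_ts()].
#' @param target_sparse_rate desired fraction of zero off-diagonal entries,
#'   in \[0, 1).
#' @return A support set.
#' @export
support_ss3 <- function(ts_norm, target_sparse_rate) {
  stopifnot(inherits(ts_norm, "masked_ts"))
  if (!ts_norm$normalized) stop("time courses must be normalized first")
  if (!is.numeric(target_sparse_rate) || target_sparse_rate < 0 ||
      target_sparse_rate >= 1)
    stop("'target_sparse_rate' must lie in [0, 1)")
  V <- ts_norm$data
  n <- nrow(V)
  vals <- collect_pair_corrs(V)
  if (max(vals) - min(vals) <= .Machine$double.eps * 100)
    stop("degenerate weight matrix: all off-diagonal weights are equal")
  npairs <- n * (n - 1) / 2
  keep_n <- max(1L, min(length(vals),
                        as.integer(round((1 - target_sparse_rate) *
                                         length(vals)))))
  thr <- kth_largest(vals, keep_n)
  ii <- list(); jj <- list(); b <- 0L
  block_size <- 1024L
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    B <- corr_block(V, rows)
    hit <- which(B >= thr & col(B) > rows[row(B)], arr.ind = TRUE)
    b <- b + 1L
    ii[[b]] <- rows[hit[, 1L]]
    jj[[b]] <- hit[, 2L]
  }
  pair_support(unlist(ii), unlist(jj), n)
}

#' Weighting-function configuration
#'
#' @param kind one of `"correlation"` (Pearson correlation of time
#'   courses, the default), `"gaussian"` (`exp(-d^2/sigma^2)` of the
#'   functional distance d), `"constant"` (all retained edges weight 1; the
#'   purely geometric "trivial matrix" mode) or `"shimalik"`
#'   (`exp(-d^2/sigma_v^2 - du^2/sigma_u^2)` with a hard spatial cutoff at
#'   `radius_r` mm).
#' @param sigma Gaussian width, or `"median"` to use the median functional
#'   distance over all voxel pairs.
#' @param sigma_v,sigma_u,radius_r Shi-Malik functional width, spatial width
#'   and spatial cutoff (mm); required only for `kind = "shimalik"`.
#' @return An object of class `weighting_config`.
#' @export
weighting_config <- function(kind = c("correlation", "gaussian", "constant",
                                      "shimalik"),
                             sigma = "median", sigma_v = NULL,
                             sigma_u = NULL, radius_r = NULL) {
  kind <- match.arg(kind)
  if (kind == "gaussian" && !identical(sigma, "median") &&
      (!is.numeric(sigma) || sigma <= 0))
    stop("'sigma' must be positive or \"median\"")
  if (kind == "shimalik") {
    for (nm in c("sigma_v", "sigma_u", "radius_r")) {
      v <- get(nm)
      if (!is.numeric(v) || length(v) != 1L || v <= 0)
        stop("'", nm, "' must be a positive real for shimalik weighting")
    }
  }
  structure(list(kind = kind, sigma = sigma, sigma_v = sigma_v,
                 sigma_u = sigma_u, radius_r = radius_r),
            class = "weighting_config")
}

# sparse_w: symmetric sparse weight matrix with an explicitly zero diagonal
# plus the indices whose diagonal is set to one (empty-row repair).
sparse_w <- function(W, diag_ones = integer(0)) {
  structure(list(W = W, diag_ones = as.integer(diag_ones), n = nrow(W)),
            class = "sparse_w")
}

#' @export
print.sparse_w <- function(x, ...) {
  cat(sprintf(
    "Sparse weight matrix: %d x %d, %d stored entries (sparse rate %.4f)%s\n",
    x$n, x$n, Matrix::nnzero(x$W), sparse_rate(x),
    if (length(x$diag_ones))
      sprintf(", %d repaired diagonal entries", length(x$diag_ones))
    else ""))
  invisible(x)
}

# Diagonal repair rule: a row that is empty, or whose weights sum to a
# non-positive value (possible with retained negative correlations), gets
# its diagonal entry set to one so the degree matrix stays positive.
repair_rows <- function(W) {
  which(as.numeric(Matrix::rowSums(W)) <= 0)
}

# Build a symmetric sparse matrix from pair weights, dropping zeros, and
# apply the diagonal repair rule.
build_sparse_w <- function(i, j, w, n) {
  keep <- w != 0
  i <- i[keep]; j <- j[keep]; w <- w[keep]
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  sparse_w(W, diag_ones = repair_rows(W))
}

#' Apply a weighting function on a support set
#'
#' Computes edge weights for every retained pair under the chosen weighting
#' function, yielding a symmetric sparse weight matrix with zero diagonal.
#' Rows left empty by the sparsification (possible under the global
#' threshold scheme) or whose weights sum to a non-positive value (possible
#' when negative correlations are retained) have their diagonal entry set
#' to one so that the degree matrix stays positive definite.
#'
#' @param ts_norm normalized [masked_ts()].
#' @param support a support set.
#' @param cfg a [weighting_config()].
#' @return An object of class `sparse_w`.
#' @export
apply_weighting <- function(ts_norm, support,
                            cfg = weighting_config("correlation")) {
  stopifnot(inherits(ts_norm, "masked_ts"), inherits(support, "pair_support"))
  if (!ts_norm$normalized) stop("time courses must be normalized first")
  V <- ts_norm$data
  n <- nrow(V)
  if (support$n != n) stop("support and time series sizes differ")
  i <- support$i; j <- support$j
  if (cfg$kind == "shimalik") {
    du2 <- rowSums((ts_norm$coords_mm[i, , drop = FALSE] -
                    ts_norm$coords_mm[j, , drop = FALSE])^2)
    keep <- sqrt(du2) <= cfg$radius_r
    i <- i[keep]; j <- j[keep]; du2 <- du2[keep]
  }
  co <- pair_dots(V, i, j)
  d2 <- pmax(0, 2 * (1 - co))  # ||v_i - v_j||^2 for unit-norm rows
  w <- switch(cfg$kind,
    correlation = pmin(1, pmax(-1, co)),
    constant = rep(1, length(i)),
    gaussian = {
      sigma <- cfg$sigma
      if (identical(sigma, "median")) sigma <- median_functional_distance(V)
      exp(-d2 / sigma^2)
    },
    shimalik = exp(-d2 / cfg$sigma_v^2 - du2 / cfg$sigma_u^2))
  build_sparse_w(i, j, w, n)
}

# Chunked row-pair dot products (avoids a pairs x T temporary blow-up).
pair_dots <- function(V, i, j, chunk = 500000L) {
  out <- numeric(length(i))
  for (start in seq(1L, length(i), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(i))
    out[idx] <- rowSums(V[i[idx], , drop = FALSE] * V[j[idx], , drop = FALSE])
  }
  out
}

#' Median functional distance between normalized time courses
#'
#' The median of `||v_i - v_j||_2` over all voxel pairs, used as the default
#' Gaussian width (`sigma = "median"`).  Exact for moderate N, computed from
#' a seeded pair subsample at whole-brain scale.
#'
#' @param V normalized time-course matrix (or a normalized [masked_ts()]).
#' @return The median distance (a positive scalar).
#' @export
median_functional_distance <- function(V) {
  if (inherits(V, "masked_ts")) {
    if (!V$normalized) stop("time courses must be normalized first")
    V <- V$data
  }
  co <- collect_pair_corrs(V)
  stats::median(sqrt(pmax(0, 2 * (1 - co))))
}

#' Sparse rate of a weight matrix
#'
#' Fraction of zero off-diagonal entries among the N(N-1) off-diagonal
#' positions.
#'
#' @param W a `sparse_w`.
#' @return Sparse rate in \[0, 1\].
#' @export
sparse_rate <- function(W) {
  stopifnot(inherits(W, "sparse_w"))
  n <- as.double(W$n)
  nnz_off <- sum(W$W@x != 0)  # dgCMatrix stores both triangles; diag is zero
  1 - nnz_off / (n * (n - 1))
}

#' Fisher r-to-z average of weight matrices
#'
#' Entrywise `tanh(mean(atanh(w)))` over the union of supports (absent
#' entries contribute z = 0); entries are clipped to +/-(1 - 1e-7) before
#' the transform.  This is how per-subject correlation matrices are averaged
#' into a group matrix.
#'
#' @param Ws list of `sparse_w` of identical order.
#' @return The group-averaged `sparse_w`.
#' @export
fisher_mean <- function(Ws) {
  if (length(Ws) == 0L) stop("empty matrix list")
  stopifnot(all(vapply(Ws, inherits, logical(1), "sparse_w")))
  n <- Ws[[1L]]$n
  if (!all(vapply(Ws, function(w) w$n, integer(1)) == n))
    stop("matrices have different orders")
  bound <- 1 - 1e-7
  zsum <- NULL
  for (w in Ws) {
    M <- w$W
    M@x <- atanh(pmin(bound, pmax(-bound, M@x)))
    zsum <- if (is.null(zsum)) M else zsum + M
  }
  zsum <- zsum / length(Ws)
  zsum@x <- tanh(zsum@x)
  zsum <- Matrix::drop0(zsum)
  sparse_w(zsum, diag_ones = repair_rows(zsum))
}

#' Same-cluster adjacency matrix of a parcellation
#'
#' `a_ij = 1` iff voxels i and j carry the same label (i != j); symmetric
#' 0/1 with zero diagonal.
#'
#' @param parc a [parcellation()].
#' @return A `sparse_w` with binary entries.
#' @export
adjacency_from_parcellation <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  n <- parc$mask$n
  rows_by_label <- split(seq_len(n), parc$labels)
  ii <- list(); jj <- list(); b <- 0L
  for (idx in rows_by_label) {
    m <- length(idx)
    if (m < 2L) next
    b <- b + 1L
    ii[[b]] <- rep(idx, each = m)
    jj[[b]] <- rep(idx, times = m)
  }
  if (b == 0L)
    return(sparse_w(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, n)),
                    diag_ones = seq_len(n)))
  i <- unlist(ii); j <- unlist(jj)
  keep <- i != j
  W <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1, dims = c(n, n))
  sparse_w(W, diag_ones = repair_rows(W))
}

#' Average binary adjacency matrices across subjects
#'
#' Entrywise mean of same-cluster adjacency matrices; no further
#' sparsification is applied.  The result serves as the second-level weight
#' matrix of the two-level group pipeline.
#'
#' @param As list of binary `sparse_w` of identical order.
#' @return A `sparse_w` with entries in \[0, 1\].
#' @export
average_adjacency <- function(As) {
  if (length(As) == 0L) stop("empty adjacency list")
  stopifnot(all(vapply(As, inherits, logical(1), "sparse_w")))
  n <- As[[1L]]$n
  if (!all(vapply(As, function(a) a$n, integer(1)) == n))
    stop("adjacency matrices have different orders")
  for (a in As)
    if (length(a$W@x) && any(a$W@x != 1))
      stop("adjacency matrices must be binary")
  M <- NULL
  for (a in As) M <- if (is.null(M)) a$W else M + a$W
  M <- M / length(As)
  sparse_w(M, diag_ones = repair_rows(M))
}

#' Export / import a sparse weight matrix in Matrix Market format
#'
#' Plain-text interchange for debugging and cross-language checks.  The
#' repaired-diagonal convention is preserved by writing the diagonal ones
#' explicitly and re-deriving them on read.
#'
#' @param W a `sparse_w`.
#' @param path `.mtx` file path.
#' @return `path` (write) or a `sparse_w` (read).
#' @export
write_weights_mtx <- function(W, path) {
  stopifnot(inherits(W, "sparse_w"))
  M <- W$W
  if (length(W$diag_ones))
    M <- M + Matrix::sparseMatrix(i = W$diag_ones, j = W$diag_ones, x = 1,
                                  dims = c(W$n, W$n))
  Matrix::writeMM(M, path)
  invisible(path)
}

#' @rdname write_weights_mtx
#' @export
read_weights_mtx <- function(path) {
  M <- methods::as(Matrix::readMM(path), "CsparseMatrix")
  M <- methods::as(M, "generalMatrix")
  d <- Matrix::diag(M)
  diag_ones <- which(d != 0)
  Matrix::diag(M) <- 0
  sparse_w(Matrix::drop0(M * 1), diag_ones = diag_ones)
}
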