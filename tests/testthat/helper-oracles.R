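# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (O(N^2) loops, dense matrices) so that they cannot
# share a defect with the implementation paths they check.

# All unordered in-mask pairs with Chebyshev distance 1, by full O(N^2) scan.
oracle_neighbor_pairs <- function(mask) {
  out <- list(); b <- 0L
  for (i in seq_len(mask$n - 1L)) {
    for (j in (i + 1L):mask$n) {
      if (max(abs(mask$vox[i, ] - mask$vox[j, ])) == 1L) {
        b <- b + 1L
        out[[b]] <- c(i, j)
      }
    }
  }
  if (b == 0L) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# Top-k per row/column union support on the dense correlation matrix.
oracle_topk_support <- function(V, k) {
  n <- nrow(V)
  C <- tcrossprod(V)
  diag(C) <- -Inf
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    th <- sort(C[i, ], decreasing = TRUE)[k]
    keep[i, C[i, ] >= th] <- TRUE
  }
  keep <- keep | t(keep)
  which(keep & upper.tri(keep), arr.ind = TRUE)
}

# Pairs kept by a global sort-and-cut at the target sparse rate.
oracle_threshold_support <- function(V, rate) {
  n <- nrow(V)
  C <- tcrossprod(V)
  vals <- C[upper.tri(C)]
  keep_n <- max(1L, round((1 - rate) * length(vals)))
  thr <- sort(vals, decreasing = TRUE)[keep_n]
  which(C >= thr & upper.tri(C), arr.ind = TRUE)
}

as_pair_matrix <- function(support) {
  cbind(support$i, support$j)
}

pairs3_sorted <- function(m) {
  m <- unname(as.matrix(m))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

pairs_sorted <- function(m) {
  if (nrow(m) == 0L) return(m)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Flood-fill 26-connected component count per label, plain BFS over rows.
oracle_component_count <- function(parc) {
  mask <- parc$mask
  visited <- logical(mask$n)
  comp <- 0L
  for (start in seq_len(mask$n)) {
    if (visited[start]) next
    comp <- comp + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in seq_len(mask$n)) {
        if (!visited[w] && parc$labels[w] == parc$labels[v] &&
            max(abs(mask$vox[v, ] - mask$vox[w, ])) == 1L) {
          visited[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# Generalized eigenproblem (D - W) y = lambda D y solved densely and
# non-symmetrically (independent route from the normalized-Laplacian one).
oracle_generalized_eig <- function(Wobj, nev) {
  W <- as.matrix(Wobj$W)
  if (length(Wobj$diag_ones))
    diag(W)[Wobj$diag_ones] <- 1
  d <- rowSums(W)
  M <- diag(1 / d) %*% (diag(d) - W)
  ed <- eigen(M)
  ord <- order(Re(ed$values))
  list(values = Re(ed$values[ord])[seq_len(nev)],
       vectors = Re(ed$vectors[, ord, drop = FALSE])[, seq_len(nev),
                                                     drop = FALSE])
}

# Brute-force homogeneity: double loop over within-cluster pairs.
oracle_homogeneity <- function(parc, ts) {
  aks <- c()
  for (k in seq_len(parc$k_actual)) {
    idx <- which(parc$labels == k)
    if (length(idx) < 2L) next
    s <- 0; cnt <- 0L
    for (i in idx) for (j in idx) if (i != j) {
      s <- s + sum(ts$data[i, ] * ts$data[j, ])
      cnt <- cnt + 1L
    }
    aks <- c(aks, s / cnt)
  }
  mean(aks)
}

# Fixture builders -----------------------------------------------------

full_mask <- function(dims, voxel_size = c(1, 1, 1)) {
  gm_mask(array(TRUE, dims), volume_grid(dims, voxel_size))
}

random_mask <- function(dims, p = 0.5, seed = 1L) {
  set.seed(seed)
  arr <- array(runif(prod(dims)) < p, dims)
  if (!any(arr)) arr[1, 1, 1] <- TRUE
  gm_mask(arr, volume_grid(dims))
}

random_ts <- function(mask, n_time = 12L, seed = 1L, normalize = TRUE) {
  set.seed(seed)
  ts <- masked_ts(matrix(rnorm(mask$n * n_time), mask$n), mask)
  if (normalize) normalize_timecourses(ts) else ts
}

# A small random sparse symmetric weight matrix (connected by adding a path).
random_sparse_w <- function(n, density = 0.1, seed = 1L, positive = TRUE) {
  set.seed(seed)
  m <- matrix(0, n, n)
  npair <- round(density * n * (n - 1) / 2)
  pick <- sample.int(n * (n - 1) / 2, npair)
  ut <- which(upper.tri(m))
  m[ut[pick]] <- if (positive) runif(npair, 0.1, 1) else runif(npair, -1, 1)
  for (i in seq_len(n - 1L)) m[i, i + 1L] <- max(m[i, i + 1L], 0.5)
  m <- m + t(m)
  W <- Matrix::drop0(methods::as(m, "CsparseMatrix"))
  slicparc:::sparse_w(W, diag_ones = slicparc:::repair_rows(W))
}

# Tiny phantom cohort used across SLIC/group/evaluation tests.
tiny_phantom <- function(dims = c(10L, 10L, 10L), K_true = 4L,
                         n_subjects = 2L, n_time = 60L, seed = 0L, ...) {
  spec <- phantom_spec(dims = dims, K_true = K_true, n_time = n_time,
                       n_subjects = n_subjects, seed = seed, ...)
  suppressMessages(simulate_cohort(spec))
}
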