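# Degree vector D(i,i) = sum_j w_ij including repaired diagonal ones.
weight_degrees <- function(W) {
  deg <- as.numeric(Matrix::rowSums(W$W))
  if (length(W$diag_ones)) deg[W$diag_ones] <- deg[W$diag_ones] + 1
  deg
}

ncut_features <- function(X, eigenvalues) {
  structure(list(X = X, eigenvalues = eigenvalues, K = ncol(X),
                 row_normalized = FALSE),
            class = "ncut_features")
}

#' @export
print.ncut_features <- function(x, ...) {
  cat(sprintf("Ncut feature matrix: %d voxels x %d indicator vectors\n",
              nrow(x$X), x$K))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = " "), "\n")
  invisible(x)
}

#' Normalized-cut spectral embedding of a sparse weight matrix
#'
#' Solves the generalized eigenproblem `(D - W) y = lambda D y` through the
#' regularized normalized Laplacian `D^(-1/2)(D - W)D^(-1/2) + reg I`,
#' discards trivial eigenvalues (raw value <= `trivial_tol`, one per
#' connected component), back-transforms the surviving eigenvectors z to
#' indicator vectors `y = D^(-1/2) z` and scales each to unit L2 norm.  The
#' K columns corresponding to the K smallest non-trivial eigenvalues form
#' the feature matrix handed to SLIC.
#'
#' For small problems a dense symmetric eigendecomposition is used; larger
#' problems go through ARPACK (Lanczos on the spectrum-flipped operator),
#' requesting extra pairs so that K survive the trivial filter.
#'
#' @param W a `sparse_w` (symmetric, zero diagonal, repaired empty rows).
#' @param K number of non-trivial indicator vectors to return.
#' @param reg regularization added to the Laplacian diagonal.
#' @param trivial_tol eigenvalues at or below this raw value are trivial.
#' @param coupling optional uniform-affinity regularization: every voxel
#'   pair receives an extra weight `coupling * mean(degree) / N`.  The
#'   global constant vector stays exactly trivial, but indicator vectors of
#'   otherwise disconnected components move to small positive eigenvalues
#'   above `trivial_tol` instead of being discarded with the trivial ones.
#'   Use a small value (e.g. 0.01) when the graph may be disconnected, as
#'   consensus (averaged-adjacency) graphs can be; 0 (default) leaves the
#'   graph untouched.
#' @return An object of class `ncut_features` with fields `X` (N x K),
#'   `eigenvalues` (ascending, all > `trivial_tol`) and `K`.
#' @export
ncut_embedding <- function(W, K, reg = 1e-8, trivial_tol = 1e-4,
                           coupling = 0) {
  stopifnot(inherits(W, "sparse_w"))
  K <- as.integer(K)
  n <- W$n
  if (K < 1L) stop("'K' must be >= 1")
  if (reg <= 0) stop("'reg' must be positive")
  deg <- weight_degrees(W)
  if (any(!is.finite(deg))) stop("non-finite degree in the weight matrix")
  if (any(deg <= 0))
    stop("non-positive degree at row ", which(deg <= 0)[1L],
         "; repair the weight matrix diagonal first")
  tau <- if (coupling > 0) coupling * mean(deg) / n else 0
  if (tau > 0) deg <- deg + tau * (n - 1)
  dhalf <- 1 / sqrt(deg)
  Wfull <- W$W
  if (length(W$diag_ones))
    Wfull <- Wfull + Matrix::sparseMatrix(i = W$diag_ones, j = W$diag_ones,
                                          x = 1, dims = c(n, n))
  Dh <- Matrix::Diagonal(n, dhalf)
  A <- Dh %*% Wfull %*% Dh  # D^{-1/2} W D^{-1/2}, still sparse
  extra <- max(10L, as.integer(ceiling(K / 5)))
  repeat {
    nev <- min(K + extra, n)
    ep <- laplacian_smallest(A, n, reg, nev, tau = tau, dhalf = dhalf)
    lam_raw <- ep$values - reg
    keep <- which(lam_raw > trivial_tol)
    if (length(keep) >= K) { keep <- keep[seq_len(K)]; break }
    if (nev >= n)
      stop("fewer than K = ", K, " non-trivial eigenvalues obtainable (",
           length(keep), " found)")
    extra <- extra * 2L
  }
  Z <- ep$vectors[, keep, drop = FALSE]
  Y <- Z * dhalf
  nrm <- sqrt(colSums(Y * Y))
  Y <- sweep(Y, 2L, nrm, "/")
  # deterministic sign: largest-magnitude entry positive
  for (c in seq_len(ncol(Y))) {
    p <- which.max(abs(Y[, c]))
    if (Y[p, c] < 0) Y[, c] <- -Y[, c]
  }
  ncut_features(Y, lam_raw[keep])
}

# Smallest `nev` eigenpairs of L_reg = (1+reg) I - A', ascending, where
# A' adds the uniform coupling tau (off-diagonal) in normalized form.
laplacian_smallest <- function(A, n, reg, nev, tau = 0, dhalf = NULL) {
  ncv <- min(n, max(2L * nev + 10L, 40L))
  if (n < 150L || ncv >= n - 1L || nev >= n - 1L) {
    Lreg <- Matrix::Diagonal(n, 1 + reg) - A
    if (tau > 0)
      Lreg <- Lreg - tau * (tcrossprod(dhalf) - Matrix::Diagonal(n, dhalf^2))
    ed <- eigen(as.matrix(Lreg), symmetric = TRUE)
    ix <- order(ed$values)[seq_len(nev)]
    return(list(values = ed$values[ix],
                vectors = ed$vectors[, ix, drop = FALSE]))
  }
  cshift <- 2 + 2 * reg  # >= max eigenvalue of L_reg (Laplacian spectrum <= 2)
  fn <- function(x, extra) {
    y <- (cshift - 1 - reg) * x + as.numeric(extra %*% x)
    if (tau > 0)
      y <- y + tau * (dhalf * sum(dhalf * x) - dhalf^2 * x)
    y
  }
  # ARPACK draws its starting vector from R's RNG; pin it so identical
  # matrices give bitwise-identical bases (matters for degenerate
  # eigenspaces), without disturbing the caller's RNG state
  res <- with_preserved_seed({
    set.seed(171717L)
    igraph::arpack(fn, extra = A, sym = TRUE,
                   options = list(n = n, nev = nev, ncv = ncv,
                                  which = "LA", maxiter = 100000L,
                                  tol = 0))
  })
  vals <- cshift - res$values
  ix <- order(vals)
  list(values = vals[ix], vectors = res$vectors[, ix, drop = FALSE])
}
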