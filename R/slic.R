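#' SLIC control parameters
#'
#' @param m compactness parameter; the feature distance is divided by m^2 in
#'   the unified distance.  Features are row-normalized beforehand, so m = 1
#'   balances the two terms.
#' @param S grid interval in mm; `NULL` (default) computes the average
#'   cluster linear size `(N/K * voxel volume)^(1/3)`.
#' @param max_iter maximum assignment/update sweeps.
#' @param move_tol total L2 center movement (feature + mm, summed over
#'   centers) below which iteration stops.
#' @param init_scheme `"spheres"` (hexagonal-close-packed sphere lattice,
#'   default) or `"cubes"` (cubic grid).
#' @param lattice_offsets list of fractional lattice-origin shifts (each a
#'   triple in \[0, 1)).  The initialization lattice has an arbitrary
#'   origin; [parcellate_subject()] runs the SLIC iterations once per
#'   offset and keeps the solution with the lowest mean unified distance
#'   (a deterministic multi-start, standard for K-means-family
#'   algorithms).  Use `list(c(0, 0, 0))` for a single run.
#' @param reg,trivial_tol,coupling passed to [ncut_embedding()] by
#'   [parcellate_subject()].
#' @return An object of class `slic_control`.
#' @export
slic_control <- function(m = 1, S = NULL, max_iter = 100L, move_tol = 1e-4,
                         init_scheme = c("spheres", "cubes"),
                         lattice_offsets = list(c(0, 0, 0), c(0.5, 0, 0),
                                                c(0, 0.5, 0), c(0, 0, 0.5),
                                                c(0.5, 0.5, 0.5)),
                         reg = 1e-8, trivial_tol = 1e-4, coupling = 0) {
  init_scheme <- match.arg(init_scheme)
  stopifnot(is.numeric(m), m > 0, is.null(S) || (is.numeric(S) && S > 0),
            max_iter >= 1, move_tol > 0, coupling >= 0,
            is.list(lattice_offsets), length(lattice_offsets) >= 1L)
  structure(list(m = m, S = S, max_iter = as.integer(max_iter),
                 move_tol = move_tol, init_scheme = init_scheme,
                 lattice_offsets = lattice_offsets,
                 reg = reg, trivial_tol = trivial_tol, coupling = coupling),
            class = "slic_control")
}

default_grid_interval <- function(mask, K) {
  (mask$n / K * prod(mask$grid$voxel_size))^(1 / 3)
}

#' Row-normalize Ncut features
#'
#' Each feature vector (row) is centered to zero mean across its K
#' components and scaled to unit L2 norm, as required before the unified
#' distance with m = 1.
#'
#' @param feat an `ncut_features` (or plain matrix) with K >= 2 columns.
#' @return The object with normalized rows and `row_normalized = TRUE`.
#' @export
row_normalize_features <- function(feat) {
  X <- if (inherits(feat, "ncut_features")) feat$X else as.matrix(feat)
  if (ncol(X) < 2L)
    stop("row normalization needs K >= 2 feature components")
  Xc <- X - rowMeans(X)
  nrm <- sqrt(rowSums(Xc * Xc))
  bad <- which(nrm <= .Machine$double.eps * ncol(X) * 10)
  if (length(bad))
    stop("zero-variance feature row at mask row ", bad[1L])
  Xn <- Xc / nrm
  if (inherits(feat, "ncut_features")) {
    feat$X <- Xn
    feat$row_normalized <- TRUE
    feat
  } else Xn
}

#' Unified SLIC distance between a voxel and a cluster center
#'
#' `||x_i - x_c||^2 / m^2 + ||u_i - u_c||^2 / S^2`: squared feature distance
#' normalized by the compactness parameter plus squared spatial distance
#' (mm) normalized by the grid interval.
#'
#' @param x_i,x_c feature vectors.
#' @param u_i,u_c spatial coordinates in mm.
#' @param m,S compactness parameter and grid interval.
#' @return Nonnegative scalar.
#' @export
unified_distance <- function(x_i, x_c, u_i, u_c, m = 1, S = 1) {
  sum((x_i - x_c)^2) / m^2 + sum((u_i - u_c)^2) / S^2
}

# Nearest in-mask voxel row for each query point (voxel-index space), or
# NA when none lies within max_dist.  Local box search around each site.
snap_to_mask <- function(mask, pts_vox, max_dist) {
  dims <- mask$grid$dims
  h <- as.integer(ceiling(max_dist))
  out <- rep(NA_integer_, nrow(pts_vox))
  for (s in seq_len(nrow(pts_vox))) {
    p <- pts_vox[s, ]
    lo <- pmax(0L, as.integer(floor(p)) - h)
    hi <- pmin(dims - 1L, as.integer(ceiling(p)) + h)
    if (any(lo > hi)) next
    sub <- mask$row_of_voxel[(lo[1] + 1L):(hi[1] + 1L),
                             (lo[2] + 1L):(hi[2] + 1L),
                             (lo[3] + 1L):(hi[3] + 1L), drop = FALSE]
    rows <- sub[sub > 0L]
    if (!length(rows)) next
    d2 <- rowSums(sweep(mask$vox[rows, , drop = FALSE], 2L, p, "-")^2)
    best <- which.min(d2)
    if (sqrt(d2[best]) <= max_dist) out[s] <- rows[best]
  }
  out
}

# Hexagonal-close-packed lattice sites covering a bounding box (voxel
# units), sphere radius r.
hcp_sites <- function(lo, hi, r) {
  dx <- 2 * r
  dy <- sqrt(3) * r
  dz <- 2 * sqrt(6) / 3 * r
  zs <- seq(lo[3], hi[3] + dz, by = dz)
  sites <- list(); b <- 0L
  for (iz in seq_along(zs)) {
    ys <- seq(lo[2], hi[2] + dy, by = dy)
    for (iy in seq_along(ys)) {
      xoff <- ((iy - 1L) %% 2L) * r + ((iz - 1L) %% 2L) * r
      yoff <- ((iz - 1L) %% 2L) * (dy / 3)
      xs <- seq(lo[1] + xoff, hi[1] + dx, by = dx)
      b <- b + 1L
      sites[[b]] <- cbind(xs, ys[iy] + yoff, zs[iz])
    }
  }
  do.call(rbind, sites)
}

#' Initialize SLIC cluster centers over a mask
#'
#' Sphere scheme: sites of a hexagonal-close-packed sphere lattice whose
#' radius is tuned so that about K sites fall inside the mask.  Cube scheme:
#' centers of side-S cubes tiling the mask bounding box.  Sites are snapped
#' to the nearest in-mask voxel within one lattice spacing, otherwise
#' dropped; duplicates are merged.  The realized number of centers may
#' differ from K (the actual cluster number is reported alongside the
#' initialized one downstream).
#'
#' @param mask a [gm_mask()].
#' @param K requested cluster number (1 <= K <= N).
#' @param scheme `"spheres"` or `"cubes"`.
#' @param offset fractional lattice-origin shift, a triple in \[0, 1).
#' @return Integer vector of center voxel rows.
#' @export
init_centers <- function(mask, K, scheme = c("spheres", "cubes"),
                         offset = c(0, 0, 0)) {
  scheme <- match.arg(scheme)
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  if (K > mask$n) stop("'K' exceeds the number of mask voxels")
  if (K == 1L) {
    ctr <- colMeans(mask$vox)
    return(snap_to_mask(mask, rbind(ctr), max_dist = max(mask$grid$dims)))
  }
  lo <- apply(mask$vox, 2L, min)
  hi <- apply(mask$vox, 2L, max)
  if (scheme == "cubes") {
    s <- (mask$n / K)^(1 / 3)
    centers <- as.matrix(expand.grid(
      cube_axis_centers(lo[1], hi[1], s, offset[1]),
      cube_axis_centers(lo[2], hi[2], s, offset[2]),
      cube_axis_centers(lo[3], hi[3], s, offset[3])))
    rows <- snap_to_mask(mask, centers, max_dist = s)
    rows <- unique(rows[!is.na(rows)])
    if (!length(rows)) stop("no cube center could be snapped into the mask")
    return(sort(rows))
  }
  # spheres: tune r so the in-mask site count approaches K
  r <- (mask$n / (4 * sqrt(2) * K))^(1 / 3)
  best_rows <- NULL
  best_gap <- Inf
  for (it in 1:10) {
    sh <- offset * c(2 * r, sqrt(3) * r, 2 * sqrt(6) / 3 * r)
    sites <- hcp_sites(lo - sh, hi, r)
    rows <- snap_to_mask(mask, sites, max_dist = 2 * r)
    rows <- unique(rows[!is.na(rows)])
    cnt <- length(rows)
    gap <- abs(cnt - K)
    if (cnt > 0L && gap < best_gap) { best_gap <- gap; best_rows <- rows }
    if (gap == 0L) break
    if (cnt == 0L) { r <- r / 2; next }
    r <- r * (cnt / K)^(1 / 3)
  }
  if (is.null(best_rows)) stop("sphere initialization produced no centers")
  sort(best_rows)
}

cube_axis_centers <- function(lo, hi, s, offset = 0) {
  extent <- hi - lo + 1
  ncube <- max(1L, as.integer(round(extent / s)))
  ctr <- lo + s * (seq_len(ncube) - 0.5) - 0.5 + offset * s
  ctr[ctr <= hi + s / 2]
}

#' SLIC assignment/update iterations
#'
#' Runs the windowed K-means sweeps: for each center, every in-mask voxel
#' inside the axis-aligned 3S x 3S x 3S mm window around its spatial
#' centroid is reassigned when the unified distance beats the voxel's
#' stored best distance.  Stored distances are reset at the start of each
#' sweep (they are non-increasing within a sweep; labels persist across
#' sweeps), and ties keep the incumbent with centers visited in label
#' order, so the result is deterministic.  Centers are then
#' recomputed as the mean feature and mean mm coordinate of their members.
#' Iteration stops when the total center movement drops below `move_tol`
#' or after `max_iter` sweeps.  Voxels never covered by any window are
#' assigned post hoc to the globally nearest center; empty clusters are
#' removed and labels compacted.
#'
#' @param X row-normalized feature matrix (N x K_feat).
#' @param coords_mm N x 3 voxel coordinates in mm.
#' @param center_rows integer vector of initial center voxel rows (from
#'   [init_centers()]).
#' @param mask a [gm_mask()].
#' @param K_init the requested cluster number (recorded on the result).
#' @param control a [slic_control()].
#' @return A [parcellation()] with fields `iterations` and `converged`.
#' @export
slic_assign_update <- function(X, coords_mm, center_rows, mask,
                               K_init = length(center_rows),
                               control = slic_control()) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite features")
  n <- nrow(X)
  nc <- length(center_rows)
  if (nc == 0L) stop("no cluster centers")
  S <- if (is.null(control$S)) default_grid_interval(mask, K_init)
       else control$S
  m2 <- control$m^2
  S2 <- S^2
  cf <- X[center_rows, , drop = FALSE]
  cs <- coords_mm[center_rows, , drop = FALSE]
  lab <- integer(n)
  dist <- rep(Inf, n)
  xx <- rowSums(X * X)
  uu <- rowSums(coords_mm * coords_mm)
  half <- 1.5 * S
  iterations <- 0L
  converged <- FALSE
  for (it in seq_len(control$max_iter)) {
    iterations <- it
    dist[] <- Inf  # stored distances are per sweep; labels persist
    for (k in seq_len(nc)) {
      idx <- which(abs(coords_mm[, 1] - cs[k, 1]) <= half &
                   abs(coords_mm[, 2] - cs[k, 2]) <= half &
                   abs(coords_mm[, 3] - cs[k, 3]) <= half)
      if (!length(idx)) next
      df <- xx[idx] + sum(cf[k, ]^2) -
        2 * as.numeric(X[idx, , drop = FALSE] %*% cf[k, ])
      du <- uu[idx] + sum(cs[k, ]^2) -
        2 * as.numeric(coords_mm[idx, , drop = FALSE] %*% cs[k, ])
      d <- pmax(df, 0) / m2 + pmax(du, 0) / S2
      upd <- d < dist[idx]
      if (any(upd)) {
        lab[idx[upd]] <- k
        dist[idx[upd]] <- d[upd]
      }
    }
    assigned <- lab > 0L
    counts <- tabulate(lab[assigned], nbins = nc)
    live <- counts > 0L
    newf <- cf; news <- cs
    sf <- rowsum(X[assigned, , drop = FALSE], lab[assigned])
    ss <- rowsum(coords_mm[assigned, , drop = FALSE], lab[assigned])
    ks <- as.integer(rownames(sf))
    newf[ks, ] <- sf / counts[ks]
    news[ks, ] <- ss / counts[ks]
    movement <- sqrt(sum((newf - cf)^2) + sum((news - cs)^2))
    cf <- newf; cs <- news
    if (movement < control$move_tol) { converged <- TRUE; break }
  }
  orphan <- which(lab == 0L)
  if (length(orphan)) {
    # globally nearest center by unified distance
    best <- rep(Inf, length(orphan)); bk <- integer(length(orphan))
    for (k in seq_len(nc)) {
      df <- xx[orphan] + sum(cf[k, ]^2) -
        2 * as.numeric(X[orphan, , drop = FALSE] %*% cf[k, ])
      du <- uu[orphan] + sum(cs[k, ]^2) -
        2 * as.numeric(coords_mm[orphan, , drop = FALSE] %*% cs[k, ])
      d <- pmax(df, 0) / m2 + pmax(du, 0) / S2
      upd <- d < best
      best[upd] <- d[upd]; bk[upd] <- k
    }
    lab[orphan] <- bk
  }
  out <- parcellation(mask, lab, k_init = K_init,
                      iterations = iterations, converged = converged,
                      grid_interval = S)
  # objective: mean unified distance to the final centroid of the own
  # cluster (used to select among lattice-offset restarts)
  counts <- tabulate(out$labels, nbins = out$k_actual)
  fcent <- rowsum(X, out$labels) / counts
  scent <- rowsum(coords_mm, out$labels) / counts
  out$objective <- mean(
    rowSums((X - fcent[out$labels, , drop = FALSE])^2) / m2 +
    rowSums((coords_mm - scent[out$labels, , drop = FALSE])^2) / S2)
  out
}

#' SLIC supervoxel clustering of a feature matrix over a mask
#'
#' Initializes centers on the configured lattice once per offset in
#' `control$lattice_offsets`, runs the assignment/update iterations from
#' each, and returns the solution with the lowest mean unified distance.
#' Because the mean within-cluster distance scales like
#' `K_actual^(-2/3)` for even tiles, the comparison uses the objective
#' multiplied by `(K_actual / K)^(2/3)`; otherwise restarts that happen to
#' seed more centers would always win and inflate the actual cluster
#' number.
#'
#' @param X row-normalized feature matrix (N x K_feat).
#' @param mask a [gm_mask()].
#' @param K initialized cluster number.
#' @param control a [slic_control()].
#' @return A [parcellation()].
#' @export
slic_cluster <- function(X, mask, K, control = slic_control()) {
  offsets <- control$lattice_offsets
  if (is.null(offsets)) offsets <- list(c(0, 0, 0))
  best <- NULL
  best_score <- Inf
  for (off in offsets) {
    centers <- init_centers(mask, K, control$init_scheme, offset = off)
    p <- slic_assign_update(X, mask$mm, centers, mask, K_init = K,
                            control = control)
    score <- p$objective * (p$k_actual / K)^(2 / 3)
    if (is.null(best) || score < best_score) { best <- p; best_score <- score }
  }
  best
}

#' Parcellate one weight matrix: Ncut features + SLIC supervoxels
#'
#' The full single-matrix pipeline: spectral embedding of the sparse weight
#' matrix ([ncut_embedding()]), row normalization of the features, lattice
#' center initialization ([init_centers()]) and SLIC iterations
#' ([slic_assign_update()]).
#'
#' @param W a `sparse_w` built on the mask.
#' @param mask the [gm_mask()] the matrix rows refer to.
#' @param K initialized cluster number.
#' @param control a [slic_control()].
#' @return A [parcellation()]; `k_actual` may differ from `K` (the
#'   difference is recorded in `k_difference`).
#' @export
parcellate_subject <- function(W, mask, K, control = slic_control()) {
  stopifnot(inherits(W, "sparse_w"), inherits(mask, "gm_mask"))
  if (W$n != mask$n) stop("weight matrix order does not match the mask")
  K <- as.integer(K)
  if (K == 1L)  # single center, features are irrelevant
    return(parcellation(mask, rep(1L, mask$n), k_init = 1L,
                        iterations = 1L, converged = TRUE))
  feat <- ncut_embedding(W, K, reg = control$reg,
                         trivial_tol = control$trivial_tol,
                         coupling = if (is.null(control$coupling)) 0
                                    else control$coupling)
  feat <- row_normalize_features(feat)
  slic_cluster(feat$X, mask, K, control)
}
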