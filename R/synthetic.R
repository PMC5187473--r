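#' Specification of a synthetic phantom cohort
#'
#' Describes a masked 4D cohort with planted spatially contiguous parcels:
#' each parcel has a latent smoothed-Gaussian time course; each subject
#' perturbs the latents (`subject_sd`) and each voxel adds white noise
#' (`noise_sd`).  The expected within-parcel correlation is
#' `(1 + subject_sd^2) / (1 + subject_sd^2 + noise_sd^2)`; by default
#' `noise_sd` is derived from `within_corr` so that this ratio equals the
#' requested value.
#'
#' @param dims grid dimensions (voxels per axis); voxels are 1 mm.
#' @param mask_shape `"cuboid"` (full grid) or `"ellipsoid"` (inscribed).
#' @param K_true number of planted parcels.
#' @param n_time timepoints per subject.
#' @param within_corr target expected within-parcel correlation, used to
#'   derive `noise_sd` when the latter is `NULL`.
#' @param noise_sd voxelwise white-noise standard deviation, or `NULL`.
#' @param subject_sd between-subject perturbation of the latent signals.
#' @param n_subjects number of subjects in the cohort.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the spec including the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(20L, 20L, 20L),
                         mask_shape = c("cuboid", "ellipsoid"),
                         K_true = 20L, n_time = 150L, within_corr = 0.7,
                         noise_sd = NULL, subject_sd = 0.3,
                         n_subjects = 12L, seed = 0L) {
  mask_shape <- match.arg(mask_shape)
  stopifnot(length(dims) == 3L, all(dims >= 1), K_true >= 1L, n_time >= 2L,
            subject_sd >= 0, n_subjects >= 1L)
  if (is.null(noise_sd)) {
    stopifnot(within_corr > 0, within_corr <= 1)
    noise_sd <- noise_sd_for_correlation(within_corr, subject_sd)
  }
  stopifnot(noise_sd >= 0)
  structure(list(dims = as.integer(dims), mask_shape = mask_shape,
                 K_true = as.integer(K_true), n_time = as.integer(n_time),
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Noise level for a target within-parcel correlation
#'
#' Inverts `rho = (1 + subject_sd^2) / (1 + subject_sd^2 + noise_sd^2)`.
#'
#' @param rho target within-parcel correlation in (0, 1\].
#' @param subject_sd between-subject latent perturbation.
#' @return The voxel noise standard deviation.
#' @export
noise_sd_for_correlation <- function(rho, subject_sd = 0.3) {
  stopifnot(rho > 0, rho <= 1)
  sqrt((1 + subject_sd^2) * (1 - rho) / rho)
}

phantom_mask <- function(spec) {
  dims <- spec$dims
  if (spec$mask_shape == "cuboid") {
    inside <- array(TRUE, dims)
  } else {
    ctr <- (dims - 1) / 2
    semi <- pmax(dims / 2 - 0.5, 0.5)
    idx <- arrayInd(seq_len(prod(dims)), dims) - 1L
    inside <- array(rowSums(sweep(sweep(idx, 2L, ctr, "-"), 2L, semi,
                                  "/")^2) <= 1, dims)
  }
  gm_mask(inside, volume_grid(dims))
}

#' Plant a contiguous ground-truth parcellation
#'
#' Seeds `K_true` parcels by farthest-point sampling over the mask (the
#' first seed is drawn from the seeded RNG), evens the seed positions out
#' with a few Lloyd (centroidal Voronoi) relaxation steps so parcel
#' volumes are roughly balanced, and grows labels by multi-source
#' breadth-first search over 26-connectivity, so every parcel is
#' 26-connected by construction.  Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return A [parcellation()] with `k_init = K_true`.
#' @export
plant_parcellation <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- phantom_mask(spec)
  if (spec$K_true > mask$n) stop("'K_true' exceeds the mask voxel count")
  with_preserved_seed({
    set.seed(spec$seed)
    K <- spec$K_true
    seeds <- integer(K)
    seeds[1L] <- sample.int(mask$n, 1L)
    if (K > 1L) {
      dmin <- rowSums(sweep(mask$mm, 2L, mask$mm[seeds[1L], ], "-")^2)
      for (k in 2L:K) {
        seeds[k] <- which.max(dmin)
        dmin <- pmin(dmin, rowSums(sweep(mask$mm, 2L,
                                         mask$mm[seeds[k], ], "-")^2))
      }
      # Lloyd relaxation: farthest-point seeds concentrate at the mask
      # boundary; a few centroidal-Voronoi steps balance parcel volumes
      for (it in 1:10) {
        d2 <- matrix(0, K, mask$n)
        for (k in seq_len(K))
          d2[k, ] <- rowSums(sweep(mask$mm, 2L, mask$mm[seeds[k], ],
                                   "-")^2)
        assign <- max.col(-t(d2), ties.method = "first")
        cent <- rowsum(mask$mm, assign) / tabulate(assign, K)
        for (k in seq_len(K))
          seeds[k] <- which.min(rowSums(sweep(mask$mm, 2L, cent[k, ],
                                              "-")^2))
      }
      seeds <- unique(seeds)
      K <- length(seeds)
    }
    labels <- integer(mask$n)
    labels[seeds] <- seq_len(K)
    offs <- neighbor_offsets()
    dims <- mask$grid$dims
    while (any(labels == 0L)) {
      proposal <- integer(mask$n)
      un <- which(labels == 0L)
      for (o in seq_len(nrow(offs))) {
        open <- un[proposal[un] == 0L]
        if (!length(open)) break
        nb <- sweep(mask$vox[open, , drop = FALSE], 2L, offs[o, ], "+")
        ok <- nb[, 1] >= 0L & nb[, 1] < dims[1] &
              nb[, 2] >= 0L & nb[, 2] < dims[2] &
              nb[, 3] >= 0L & nb[, 3] < dims[3]
        if (!any(ok)) next
        r <- mask$row_of_voxel[nb[ok, , drop = FALSE] + 1L]
        hit <- r > 0L & labels[pmax(r, 1L)] > 0L
        proposal[open[ok][hit]] <- labels[r[hit]]
      }
      if (!any(proposal > 0L)) stop("BFS growth stalled (disconnected mask?)")
      labels[proposal > 0L] <- proposal[proposal > 0L]
    }
    parcellation(mask, labels, k_init = spec$K_true)
  })
}

# Empirically decorrelate latent rows (symmetric/ZCA whitening), then mix
# in a weak global component and a little idiosyncratic drift so that
# between-parcel correlations are small but predominantly positive, as in
# resting-state data without global-signal regression.  Purely independent
# draws at finite T carry sample cross-correlations of either sign that
# are coherent over whole parcel boundaries; their negative part pushes
# parcel-indicator eigenvalues of the correlation-weighted Laplacian below
# the trivial-eigenvalue threshold, which no parcellation method can
# recover from.
shared_latents <- function(k, n_time, global_sd = 0.2, jitter_sd = 0.1) {
  U <- latent_courses(k, n_time)
  if (k > 1L) {
    C <- tcrossprod(U) / n_time
    E <- eigen(C, symmetric = TRUE)
    U <- (E$vectors %*% diag(1 / sqrt(pmax(E$values, 1e-12)), k) %*%
            t(E$vectors)) %*% U
    U <- U - rowMeans(U)
    U <- U / apply(U, 1L, stats::sd)
  }
  g <- latent_courses(1L, n_time)
  L <- U + global_sd * matrix(rep(g, each = k), k) +
    jitter_sd * latent_courses(k, n_time)
  L <- L - rowMeans(L)
  L / apply(L, 1L, stats::sd)
}

# Smoothed, standardized latent time courses: k x T.
latent_courses <- function(k, n_time, window = 5L) {
  raw <- matrix(stats::rnorm(k * (n_time + 2L * window)), k)
  sm <- t(apply(raw, 1L, function(x)
    stats::filter(x, rep(1 / window, window), sides = 2L)))
  sm <- sm[, seq.int(window + 1L, window + n_time), drop = FALSE]
  sm <- sm - rowMeans(sm)
  sm / apply(sm, 1L, stats::sd)
}

#' Simulate one subject of a phantom cohort
#'
#' Voxel time courses are the subject's parcel latent (shared latent plus
#' `subject_sd` times an independent smoothed perturbation) plus
#' `noise_sd` times white noise.  The shared latents depend only on
#' `spec$seed`; the subject stream is derived from seed and subject index,
#' so cohorts are reproducible bit for bit.
#'
#' @param planted the [plant_parcellation()] ground truth.
#' @param spec the [phantom_spec()].
#' @param subject_index 1-based subject number.
#' @return A raw (unnormalized) [masked_ts()].
#' @export
simulate_subject <- function(planted, spec, subject_index) {
  stopifnot(inherits(planted, "parcellation"), inherits(spec, "phantom_spec"))
  subject_index <- as.integer(subject_index)
  stopifnot(subject_index >= 1L)
  k <- planted$k_actual
  with_preserved_seed({
    set.seed(spec$seed)
    shared <- shared_latents(k, spec$n_time)
    set.seed((spec$seed + 100003L * subject_index) %% 2147483647L)
    subj <- shared
    if (spec$subject_sd > 0)
      subj <- shared + spec$subject_sd * latent_courses(k, spec$n_time)
    n <- planted$mask$n
    data <- subj[planted$labels, , drop = FALSE]
    if (spec$noise_sd > 0)
      data <- data + spec$noise_sd * matrix(stats::rnorm(n * spec$n_time),
                                            n)
    var_latent <- 1 + spec$subject_sd^2
    message(sprintf(
      "phantom subject %d: expected within-parcel correlation %.3f",
      subject_index, var_latent / (var_latent + spec$noise_sd^2)))
    masked_ts(data, planted$mask)
  })
}

#' Simulate a whole phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @param planted optionally a precomputed ground truth (so two cohorts can
#'   share one planted structure).
#' @param subject_offset added to the subject index of every subject; use
#'   it to draw a second, disjoint cohort from the same planted structure.
#' @return A list with elements `spec`, `mask`, `planted` and `subjects`
#'   (list of raw [masked_ts()]).
#' @export
simulate_cohort <- function(spec, planted = NULL, subject_offset = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(planted)) planted <- plant_parcellation(spec)
  subjects <- lapply(seq_len(spec$n_subjects), function(s)
    simulate_subject(planted, spec, s + subject_offset))
  list(spec = spec, mask = planted$mask, planted = planted,
       subjects = subjects)
}

#' Write a phantom cohort to disk as NIfTI plus a JSON sidecar
#'
#' Writes `mask.nii.gz`, `planted_labels.nii.gz`, one 4D
#' `subject_NN.nii.gz` per subject, and `cohort.json` recording the spec.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mask <- cohort$mask
  vol <- array(0L, mask$grid$dims)
  vol[mask$lin] <- 1L
  write_label_volume(vol, mask$grid, file.path(dir, "mask.nii.gz"))
  write_parcellation(cohort$planted,
                     file.path(dir, "planted_labels.nii.gz"))
  for (s in seq_along(cohort$subjects)) {
    ts <- cohort$subjects[[s]]
    arr <- array(0, c(mask$grid$dims, ncol(ts$data)))
    flat <- matrix(arr, prod(mask$grid$dims), ncol(ts$data))
    flat[mask$lin, ] <- ts$data
    arr <- array(flat, c(mask$grid$dims, ncol(ts$data)))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- mask$grid$voxel_size
    aff <- diag(c(mask$grid$voxel_size, 1))
    aff[1:3, 4] <- mask$grid$origin
    img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
    img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
    RNifti::writeNifti(img, file.path(dir, sprintf("subject_%02d.nii.gz",
                                                   s)))
  }
  sidecar <- unclass(cohort$spec)
  sidecar$n_voxels <- mask$n
  sidecar$k_actual_planted <- cohort$planted$k_actual
  jsonlite::write_json(sidecar, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
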