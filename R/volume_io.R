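#' Construct a volume grid
#'
#' Describes the discrete spatial frame shared by a mask, its time series and
#' any label volume: grid dimensions, voxel size in mm, and the translation
#' from voxel-index space to world (scanner/MNI) space.  Only diagonal
#' voxel-to-world mappings are supported; world coordinates are
#' `index * voxel_size + origin` with 0-based indices.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size positive numeric vector of length 3, voxel edge lengths
#'   in mm.
#' @param origin numeric vector of length 3, world-space position (mm) of the
#'   voxel with index (0, 0, 0).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(dims, voxel_size = c(1, 1, 1), origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("'dims' must be three integers >= 1")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be three positive reals (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be three finite reals (mm)")
  structure(list(dims = dims, voxel_size = voxel_size, origin = origin),
            class = "volume_grid")
}

#' Construct a gray-matter mask from a logical array
#'
#' Establishes the deterministic voxel-to-row mapping used by every
#' downstream stage: in-mask voxels are numbered 1..N in lexicographic
#' order with the first (x) axis varying fastest.
#'
#' @param inside logical (or coercible) 3D array; `TRUE`/positive marks
#'   in-mask voxels.
#' @param grid a [volume_grid()]; defaults to unit voxels at the origin.
#' @return An object of class `gm_mask` with fields `grid`, `inside`,
#'   `n`, `vox` (N x 3 matrix of 0-based voxel indices), `mm` (N x 3 world
#'   coordinates) and `row_of_voxel` (array mapping voxels to rows, 0
#'   outside the mask).
#' @export
gm_mask <- function(inside, grid = NULL) {
  if (is.null(dim(inside)) || length(dim(inside)) != 3L)
    stop("'inside' must be a 3D array")
  if (!is.logical(inside)) inside <- inside > 0
  inside[is.na(inside)] <- FALSE
  if (is.null(grid)) grid <- volume_grid(dim(inside))
  if (!identical(as.integer(dim(inside)), grid$dims))
    stop("mask array dimensions do not match the grid")
  lin <- which(inside)  # column-major order == lexicographic, x fastest
  n <- length(lin)
  if (n == 0L) stop("empty mask: no voxel has a positive value")
  vox <- arrayInd(lin, grid$dims) - 1L
  mm <- sweep(vox %*% diag(grid$voxel_size), 2L, grid$origin, "+")
  row_of_voxel <- array(0L, grid$dims)
  row_of_voxel[lin] <- seq_len(n)
  structure(list(grid = grid, inside = inside, n = n, vox = vox, mm = mm,
                 row_of_voxel = row_of_voxel, lin = lin),
            class = "gm_mask")
}

#' @export
print.gm_mask <- function(x, ...) {
  cat(sprintf("Gray-matter mask: %d voxels on a %s grid (%s mm voxels)\n",
              x$n, paste(x$grid$dims, collapse = "x"),
              paste(format(x$grid$voxel_size), collapse = "x")))
  invisible(x)
}

same_mask <- function(a, b) {
  identical(a$grid$dims, b$grid$dims) && a$n == b$n &&
    identical(a$lin, b$lin)
}

# Extract the diagonal-affine geometry of a NIfTI image, rejecting rotated
# or sheared voxel-to-world mappings.
nifti_geometry <- function(img) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(xf))
    return(list(voxel_size = rep(1, 3), origin = rep(0, 3)))
  rot <- xf[1:3, 1:3, drop = FALSE]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot)), 1))
    stop("non-diagonal voxel-to-world affine; resample the image to a ",
         "grid-aligned orientation before use")
  list(voxel_size = abs(diag(rot)), origin = xf[1:3, 4])
}

#' Read a gray-matter mask from a NIfTI file
#'
#' Voxels with value > 0 are taken as in-mask.  The voxel-to-row mapping is
#' deterministic (lexicographic, x fastest), so two reads of the same file
#' always produce the same ordering.
#'
#' @param path path to a 3D NIfTI (`.nii` / `.nii.gz`) volume.
#' @return A [gm_mask()] object.
#' @export
read_mask <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI mask '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { dim(arr) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L)
    stop("mask must be a 3D volume, got ", length(d), " dimensions")
  geo <- nifti_geometry(img)
  gm_mask(arr > 0, volume_grid(d, geo$voxel_size, geo$origin))
}

#' Extract in-mask voxel time courses from a 4D NIfTI volume
#'
#' @param path4d path to a 4D NIfTI volume whose spatial dimensions match
#'   the mask grid.
#' @param mask a [gm_mask()].
#' @return A [masked_ts()] object with one row per mask voxel (in mask row
#'   order) and one column per timepoint.
#' @export
extract_timeseries <- function(path4d, mask) {
  stopifnot(inherits(mask, "gm_mask"))
  img <- tryCatch(RNifti::readNifti(path4d),
                  error = function(e) stop("cannot read NIfTI volume '",
                                           path4d, "': ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L)
    stop("expected a 4D volume, got ", length(d), " dimensions")
  if (!identical(as.integer(d[1:3]), mask$grid$dims))
    stop("spatial dimensions ", paste(d[1:3], collapse = "x"),
         " do not match the mask grid ",
         paste(mask$grid$dims, collapse = "x"))
  nt <- d[4]
  if (nt < 2L) stop("need at least 2 timepoints, got ", nt)
  m <- matrix(arr, nrow = prod(d[1:3]), ncol = nt)[mask$lin, , drop = FALSE]
  masked_ts(m, mask)
}

# Write an integer label array (0 = background) with the grid's geometry.
write_label_volume <- function(labels_vol, grid, path) {
  img <- RNifti::asNifti(labels_vol)
  RNifti::pixdim(img) <- grid$voxel_size
  aff <- diag(c(grid$voxel_size, 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' Write a parcellation as a NIfTI label volume
#'
#' In-mask voxels carry their cluster label (1..K), out-of-mask voxels 0.
#' Labels are stored as 32-bit integers so a round trip through
#' [read_parcellation()] reproduces them exactly.
#'
#' @param parc a [parcellation()] object.
#' @param path output path (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  vol <- array(0L, parc$mask$grid$dims)
  vol[parc$mask$lin] <- as.integer(parc$labels)
  write_label_volume(vol, parc$mask$grid, path)
}

#' Read a parcellation from a NIfTI label volume
#'
#' Positive voxels define the mask; their values define the labels.  Labels
#' are compacted to consecutive 1..K preserving their numeric order.
#'
#' @param path path to an integer 3D NIfTI label volume.
#' @return A [parcellation()] object (`k_init` taken equal to the number of
#'   distinct labels found).
#' @export
read_parcellation <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI volume '",
                                           path, "': ",
                                           conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { dim(arr) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L) stop("label volume must be 3D")
  geo <- nifti_geometry(img)
  mask <- gm_mask(arr > 0, volume_grid(d, geo$voxel_size, geo$origin))
  raw <- as.integer(round(arr[mask$lin]))
  labs <- match(raw, sort(unique(raw)))
  parcellation(mask, labs, k_init = length(unique(labs)))
}

#' Construct a parcellation object
#'
#' A parcellation assigns every in-mask voxel exactly one integer label;
#' labels are compacted to consecutive 1..K_actual (first-occurrence order
#' is preserved through compaction by numeric label value).
#'
#' @param mask a [gm_mask()].
#' @param labels integer vector, one label per mask row.
#' @param k_init the initialized (requested) cluster number.
#' @param ... further fields stored on the object (e.g. iteration counts).
#' @return An object of class `parcellation` with fields `mask`, `labels`,
#'   `k_init`, `k_actual` and `k_difference = k_actual - k_init`.
#' @export
parcellation <- function(mask, labels, k_init = NULL, ...) {
  stopifnot(inherits(mask, "gm_mask"))
  labels <- as.integer(labels)
  if (length(labels) != mask$n)
    stop("need exactly one label per mask voxel (", mask$n, "), got ",
         length(labels))
  if (anyNA(labels) || any(labels < 1L))
    stop("labels must be positive integers")
  u <- sort(unique(labels))
  if (!identical(u, seq_along(u))) labels <- match(labels, u)
  k_actual <- length(u)
  if (is.null(k_init)) k_init <- k_actual
  structure(c(list(mask = mask, labels = labels,
                   k_init = as.integer(k_init),
                   k_actual = as.integer(k_actual),
                   k_difference = as.integer(k_actual) - as.integer(k_init)),
              list(...)),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf(
    "Parcellation: %d clusters over %d voxels (initialized K = %d)\n",
    x$k_actual, x$mask$n, x$k_init))
  if (!is.null(x$iterations))
    cat(sprintf("  SLIC iterations: %d (%s)\n", x$iterations,
                if (isTRUE(x$converged)) "converged" else "max_iter reached"))
  invisible(x)
}

#' @export
summary.parcellation <- function(object, ...) {
  sizes <- tabulate(object$labels, nbins = object$k_actual)
  out <- list(k_init = object$k_init, k_actual = object$k_actual,
              k_difference = object$k_difference, n_voxels = object$mask$n,
              size_summary = summary(sizes), n_singletons = sum(sizes == 1L))
  class(out) <- "summary.parcellation"
  out
}

#' @export
print.summary.parcellation <- function(x, ...) {
  cat(sprintf("Parcellation of %d voxels into %d clusters (K_init = %d, difference %+d)\n",
              x$n_voxels, x$k_actual, x$k_init, x$k_difference))
  cat("Cluster sizes:\n"); print(x$size_summary)
  cat(sprintf("Singleton clusters: %d\n", x$n_singletons))
  invisible(x)
}

#' Plot axial slices of a parcellation
#'
#' @param x a [parcellation()].
#' @param slices z indices (1-based) to display; defaults to three evenly
#'   spaced in-mask slices.
#' @param ... passed to [graphics::image()].
#' @export
plot.parcellation <- function(x, slices = NULL, ...) {
  vol <- array(NA_integer_, x$mask$grid$dims)
  vol[x$mask$lin] <- x$labels
  zs <- unique(x$mask$vox[, 3]) + 1L
  if (is.null(slices))
    slices <- zs[unique(pmax(1L, round(length(zs) * c(0.25, 0.5, 0.75))))]
  old <- graphics::par(mfrow = c(1, length(slices)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  cols <- grDevices::hcl.colors(max(x$k_actual, 2L), "Spectral")
  for (z in slices)
    graphics::image(vol[, , z], col = cols, axes = FALSE,
                    main = sprintf("z = %d", z), useRaster = TRUE, ...)
  invisible(x)
}
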