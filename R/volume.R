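## Volume I/O, intensity normalization and the degradation operator that
## emulates the acquisition protocol: per-axis downsampling in image space
## followed by nearest-neighbour pre-upsampling back onto the original
## grid, so HR and LR share a pixel grid.

#' Load a NIfTI-1 volume
#'
#' Reads a volume plus its voxel spacing in millimetres. Arrays are indexed
#' (row, column, slice); spacing is carried separately.
#'
#' @param path path to a readable NIfTI-1 file.
#' @return List with `data` (3D array), `spacing` (length-3, mm) and
#'   `orientation` (xform code string).
#' @export
load_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("unreadable NIfTI volume (header/magic): ",
                                           conditionMessage(e)))
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  structure(list(data = arr, spacing = as.numeric(spacing),
                 orientation = RNifti::orientation(img)),
            class = "srdiff_volume")
}

#' Save a volume as NIfTI-1
#'
#' @param vol 3D array (or `srdiff_volume`).
#' @param path output path (`.nii` for byte-stable uncompressed output).
#' @param spacing voxel spacing in mm.
#' @return The path, invisibly.
#' @export
save_volume <- function(vol, path, spacing = c(1, 1, 1)) {
  if (inherits(vol, "srdiff_volume")) {
    spacing <- vol$spacing
    vol <- vol$data
  }
  attr(vol, "pixdim") <- spacing
  img <- RNifti::asNifti(vol, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Normalize intensities to \[0, 1\]
#'
#' Min-max scaling computed over masked voxels after clipping to the
#' \[0.5, 99.5\] percentile range; background (unmasked) voxels are forced
#' to exactly 0. The clip bounds are attached as the `"norm"` attribute so
#' [denormalize_volume()] can invert the scaling up to clipping loss.
#'
#' @param vol numeric array.
#' @param mask logical/0-1 array of the same shape (default: all voxels).
#' @param probs clipping percentiles.
#' @return Array in \[0, 1\] with attribute `norm = list(lo, hi)`.
#' @export
normalize_volume <- function(vol, mask = NULL, probs = c(0.005, 0.995)) {
  if (is.null(mask)) mask <- array(TRUE, dim(vol)) else mask <- mask != 0
  if (!any(mask)) stop("mask is empty")
  v <- vol[mask]
  q <- stats::quantile(v, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) {
    warning("constant masked region; returning zeros")
    out <- array(0, dim(vol))
    attr(out, "norm") <- list(lo = q[1], hi = q[2])
    return(out)
  }
  out <- (pmin(pmax(vol, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  out[!mask] <- 0
  attr(out, "norm") <- list(lo = q[1], hi = q[2])
  out
}

#' @rdname normalize_volume
#' @param norm the `norm` attribute from [normalize_volume()].
#' @export
denormalize_volume <- function(vol, norm) {
  vol * (norm$hi - norm$lo) + norm$lo
}

## --- separable resampling -------------------------------------------------

## Resamples along one axis to n_out samples. Output sample i (1-based)
## maps to input continuous index (i - 1) * (n_in / n_out) + 1 (shared
## origin at the first voxel centre, spacing scaled by the factor), the
## convention of spacing-driven resamplers.
resample_axis <- function(A, axis, n_out, method) {
  d <- dim(A)
  n_in <- d[axis]
  if (n_out == n_in) return(A)
  perm <- c(axis, setdiff(seq_along(d), axis))
  B <- aperm(A, perm)
  db <- dim(B)
  x <- (seq_len(n_out) - 1) * (n_in / n_out) + 1
  take <- function(i) {
    i <- pmin(pmax(i, 1L), n_in)
    Bi <- B[i, , , drop = FALSE]
    dim(Bi) <- c(length(i), db[2L], db[3L])
    Bi
  }
  wmul <- function(Bi, w) Bi * as.vector(w)   # recycles along axis 1
  out <- switch(method,
    nearest = take(as.integer(round(x))),
    linear = {
      lo <- floor(x); w <- x - lo
      wmul(take(as.integer(lo)), 1 - w) + wmul(take(as.integer(lo) + 1L), w)
    },
    cubic = {
      ## Keys/Catmull-Rom cubic (a = -0.5); weights sum to 1, so constants
      ## are fixed points.
      lo <- floor(x); s <- x - lo
      w0 <- ((-0.5 * s + 1) * s - 0.5) * s
      w1 <- ((1.5 * s - 2.5) * s) * s + 1
      w2 <- ((-1.5 * s + 2) * s + 0.5) * s
      w3 <- (0.5 * s - 0.5) * s * s
      wmul(take(as.integer(lo) - 1L), w0) + wmul(take(as.integer(lo)), w1) +
        wmul(take(as.integer(lo) + 1L), w2) + wmul(take(as.integer(lo) + 2L), w3)
    },
    stop("unknown interpolation method: ", method))
  aperm(out, order(perm))
}

#' Resample a volume to a target shape
#'
#' Separable per-axis resampling with nearest, linear or Keys-cubic
#' interpolation (no anti-alias prefilter by default, matching the plain
#' image-space resampler convention; set `presmooth_sigma` for an optional
#' Gaussian presmooth before downsampling).
#'
#' @param vol 3D array.
#' @param new_dims target dimensions (length 3).
#' @param method `"nearest"`, `"linear"` or `"cubic"`.
#' @param presmooth_sigma optional Gaussian presmooth s.d. in voxels.
#' @return Resampled array.
#' @export
resample_volume <- function(vol, new_dims, method = "linear",
                            presmooth_sigma = NULL) {
  d <- dim(vol)
  stopifnot(length(new_dims) == 3L)
  if (!is.null(presmooth_sigma) && presmooth_sigma > 0)
    vol <- gaussian_smooth3(vol, presmooth_sigma)
  for (axis in 1:3)
    vol <- resample_axis(vol, axis, as.integer(new_dims[axis]), method)
  vol
}

gaussian_smooth3 <- function(vol, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-0.5 * ((-r:r) / sigma)^2); g <- g / sum(g)
  smooth_axis <- function(A, axis) {
    d <- dim(A)
    perm <- c(axis, setdiff(1:3, axis))
    B <- aperm(A, perm)
    db <- dim(B)
    out <- array(0, db)
    for (k in -r:r) {
      i <- pmin(pmax(seq_len(db[1L]) + k, 1L), db[1L])
      out <- out + g[k + r + 1L] * B[i, , , drop = FALSE]
    }
    aperm(out, order(perm))
  }
  for (axis in 1:3) vol <- smooth_axis(vol, axis)
  vol
}

## --- degradation protocol -------------------------------------------------

#' Degradation specification
#'
#' Per-axis downsampling factors plus the interpolators. The `"brain"`
#' preset is an isotropic 4x4x4 reduction (0.8 mm to 3.2 mm); the
#' `"prostate"` preset is spacing-driven, 0.66 mm to 2 mm in-plane and
#' 1.5 mm to 3 mm through-plane (about 3x3x2). Pre-upsampling back to the
#' original grid is always nearest-neighbour.
#'
#' @param preset `"brain"`, `"prostate"`, or `NULL` with explicit factors.
#' @param factors per-axis factors (>= 1), used when `preset` is NULL.
#' @param interp_down interpolation for the downsampling pass.
#' @param presmooth_sigma optional Gaussian presmooth (voxels) before
#'   downsampling; off by default.
#' @return An object of class `srdiff_degrade_spec`.
#' @export
degrade_spec <- function(preset = NULL, factors = c(4, 4, 4),
                         interp_down = "linear", presmooth_sigma = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("brain", "prostate"))
    factors <- switch(preset,
      brain = c(4, 4, 4),
      prostate = c(2 / 0.66, 2 / 0.66, 3 / 1.5))
  }
  if (any(factors < 1)) stop("all degradation factors must be >= 1")
  structure(list(preset = preset, factors = as.numeric(factors),
                 interp_down = interp_down,
                 presmooth_sigma = presmooth_sigma),
            class = "srdiff_degrade_spec")
}

#' Degrade a volume onto its own grid
#'
#' Resamples down by the per-axis factors (image-space interpolation), then
#' nearest-neighbour pre-upsamples back onto the exact original grid, so
#' the returned low-resolution volume is aligned voxel-for-voxel with the
#' input. Constants are fixed points of the operator.
#'
#' @param vol 3D array (2D matrices are treated as single-slice volumes).
#' @param spec a [degrade_spec()].
#' @return Degraded array with `dim(vol)` unchanged.
#' @export
degrade <- function(vol, spec = degrade_spec("brain")) {
  was2d <- is.matrix(vol)
  if (was2d) dim(vol) <- c(dim(vol), 1L)
  d <- dim(vol)
  f <- spec$factors
  if (length(f) == 2L) f <- c(f, 1)
  nd <- pmax(1L, as.integer(round(d / f)))
  if (any(f > d))
    stop(sprintf("degradation factor (%s) exceeds volume dimension (%s)",
                 paste(signif(f, 3), collapse = "x"),
                 paste(d, collapse = "x")))
  low <- resample_volume(vol, nd, spec$interp_down, spec$presmooth_sigma)
  out <- resample_volume(low, d, "nearest")
  if (was2d) dim(out) <- d[1:2]
  out
}

#' Bicubic comparator
#'
#' The simplest baseline: recover the decimated grid from the
#' nearest-neighbour pre-upsampled LR image and upsample it back with
#' Keys-cubic interpolation.
#'
#' @param x_lr pre-upsampled LR image (matrix).
#' @param factors per-axis in-plane factors used by the degradation.
#' @return Bicubic restoration (matrix, same shape).
#' @export
bicubic_upsample <- function(x_lr, factors = c(4, 4)) {
  d <- dim(x_lr)
  nd <- pmax(1L, as.integer(round(d / factors[1:2])))
  v <- x_lr
  dim(v) <- c(d, 1L)
  low <- resample_volume(v, c(nd, 1L), "nearest")
  up <- resample_volume(low, c(d, 1L), "cubic")
  dim(up) <- d
  up
}
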