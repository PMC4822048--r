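#' SUV volume
#'
#' Construct a 3D grid of standardized uptake values (SUV, g/ml) with
#' physical voxel spacing. This is the raw input to every feature
#' computation in the package. A 2D image is represented with a third
#' axis of length 1, under which the 26-neighbourhood degenerates to the
#' usual 8-neighbourhood.
#'
#' Voxel indices are conceptually 0-based: the physical position of the
#' voxel at (R) index \code{(i, j, k)} is \code{(i-1, j-1, k-1) * spacing},
#' so the first voxel sits at the origin. Only relative distances ever
#' enter the computed features, so the origin convention is unobservable;
#' it is fixed here for reproducibility.
#'
#' @param values numeric array of SUV values; a matrix is promoted to
#'   shape \code{c(nrow, ncol, 1)}. All values must be finite and >= 0.
#' @param spacing numeric vector of length 3 (or 1, recycled), physical
#'   voxel size per axis in mm; strictly positive.
#' @return an object of class \code{suv_volume}: the value array with a
#'   \code{spacing} attribute.
#' @examples
#' v <- suv_volume(array(2, dim = c(4, 4, 4)), spacing = c(4, 4, 3.27))
#' dim(v)
#' @export
suv_volume <- function(values, spacing = c(1, 1, 1)) {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_validation("'values' must be a 3D array (or a matrix, promoted to nx x ny x 1)")
  if (any(dim(values) < 1L))
    stop_validation("every axis of the volume must have length >= 1")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop_validation("SUV values must all be finite (no NA/NaN/Inf)")
  if (any(values < 0))
    stop_validation("SUV values must be non-negative")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop_validation("'spacing' must be 3 strictly positive finite numbers (mm)")
  structure(values, spacing = spacing, class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x)
  sp <- attr(x, "spacing")
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(sp), collapse = " x ")))
  cat(sprintf("  SUV range [%.3g, %.3g] g/ml\n", min(x), max(x)))
  invisible(x)
}

#' Voxel spacing of an SUV volume
#' @param volume an \code{suv_volume}.
#' @return numeric length-3 vector of voxel sizes (mm).
#' @export
suv_spacing <- function(volume) {
  sp <- attr(volume, "spacing")
  if (is.null(sp)) rep(1, 3L) else sp
}

#' Tumor mask
#'
#' A binary voxel set over an SUV volume, marking the segmented
#' tumor/region of interest.
#'
#' @param member logical array, same shape as the paired volume; a matrix
#'   is promoted to shape \code{c(nrow, ncol, 1)}.
#' @param volume optional \code{suv_volume} to check the shape against.
#' @return object of class \code{tumor_mask} (logical array).
#' @export
tumor_mask <- function(member, volume = NULL) {
  if (is.matrix(member)) member <- array(member, dim = c(dim(member), 1L))
  if (!is.array(member) || length(dim(member)) != 3L)
    stop_validation("'member' must be a logical 3D array")
  if (!is.logical(member)) {
    if (!all(member %in% c(0, 1)))
      stop_validation("'member' must be logical (or 0/1)")
    member <- array(as.logical(member), dim = dim(member))
  }
  if (anyNA(member)) stop_validation("mask may not contain NA")
  if (!is.null(volume) && !identical(dim(member), dim(unclass(volume))))
    stop_validation("mask shape does not match the volume shape")
  structure(member, class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat(sprintf("Tumor mask: %d of %d voxels (grid %s)\n",
              sum(x), length(x), paste(dim(x), collapse = " x ")))
  invisible(x)
}

#' Number of voxels in a mask
#' @param mask a \code{tumor_mask}.
#' @return integer count M of in-mask voxels.
#' @export
mask_size <- function(mask) sum(mask)

# physical positions (mm) of the in-mask voxels, one row per voxel,
# in the order arrayInd() over which(mask) returns them
voxel_positions <- function(mask, spacing = c(1, 1, 1)) {
  idx <- arrayInd(which(mask), dim(mask))
  sweep(idx - 1, 2L, spacing, `*`)
}

check_pair <- function(volume, mask) {
  if (!identical(dim(unclass(volume)), dim(unclass(mask))))
    stop_validation("volume and mask have different shapes")
  invisible(NULL)
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("het_validation_error", "error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("het_io_error", "error")))
}
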