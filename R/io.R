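#' Read an SUV volume from a NIfTI file
#'
#' Loads a 3D scalar NIfTI volume (values assumed to already be SUV in
#' g/ml) with its voxel spacing. 2D images load with a third axis of
#' length 1. Computing SUV from raw DICOM activity/weight/time fields is
#' out of scope: inputs must already be SUV.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return an \code{\link{suv_volume}}.
#' @export
read_suv_volume <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_io(sprintf("cannot read '%s': %s",
                                                      path, conditionMessage(e))))
  d <- dim(img)
  sp <- RNifti::pixdim(img)
  if (length(d) == 2L) {
    img <- array(as.numeric(img), dim = c(d, 1L))
    d <- dim(img)
    sp <- c(sp[1:2], 1)          # single-slice: unit thickness
  }
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[1:3])
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop_io(sprintf(
      "'%s' is %dD; a single 3D SUV volume is required (split 4D/time-series input first)",
      path, length(d)))
  sp <- sp[1:3]
  if (anyNA(sp) || any(!is.finite(sp)) || any(sp <= 0))
    stop_io(sprintf("'%s' has no usable voxel spacing (pixdim); set pixdim and retry", path))
  vals <- array(as.numeric(img), dim = d)
  if (!all(is.finite(vals)))
    stop_validation(sprintf("'%s' contains non-finite voxel values", path))
  suv_volume(vals, spacing = as.numeric(sp))
}

#' Write an SUV volume (or mask) to a NIfTI file
#'
#' @param volume an \code{\link{suv_volume}} or \code{\link{tumor_mask}}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_suv_volume <- function(volume, path) {
  sp <- suv_spacing(volume)
  vals <- array(as.numeric(unclass(volume)), dim = dim(unclass(volume)))
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- sp
  tryCatch(RNifti::writeNifti(img, path),
           error = function(e) stop_io(sprintf("cannot write '%s': %s",
                                               path, conditionMessage(e))))
  invisible(path)
}

#' Read a mask volume from a NIfTI file
#'
#' Any strictly positive voxel is treated as in-mask.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param volume optional \code{\link{suv_volume}} to check the shape
#'   against.
#' @return a \code{\link{tumor_mask}}.
#' @export
read_tumor_mask <- function(path, volume = NULL) {
  v <- read_suv_volume(path)
  tumor_mask(array(unclass(v) > 0, dim = dim(unclass(v))), volume)
}

#' Write a feature table to CSV
#'
#' Full double precision is preserved (values round-trip exactly through
#' \code{\link{read_features}}).
#'
#' @param records data frame of feature records (e.g. from
#'   \code{\link{sweep_phantoms}} or rbind-ed \code{het_features}
#'   records).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(records, path) {
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by \code{\link{write_features}}
#' @param path CSV path.
#' @return data frame.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
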