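#' SUV-weighted tumor centroid
#'
#' The SUV-based tumor centre: the uptake-weighted mean of the in-mask
#' voxel positions, coordinate-wise
#' \deqn{x_{nc} = \sum_i SUV_i x_{ni} / \sum_i SUV_i ,}
#' summing over the M segmented voxels.
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param mask a \code{\link{tumor_mask}} over the volume.
#' @param use_physical_spacing positions in mm (\code{TRUE}, default) or
#'   voxel-index units.
#' @return numeric triple, the centroid position.
#' @export
suv_centroid <- function(volume, mask, use_physical_spacing = TRUE) {
  check_pair(volume, mask)
  if (mask_size(mask) < 1L) stop_validation("empty mask: centroid undefined")
  w <- unclass(volume)[unclass(mask)]
  if (all(w == 0))
    stop_validation("all in-mask SUV are zero: centroid undefined")
  sp <- if (use_physical_spacing) suv_spacing(volume) else c(1, 1, 1)
  pos <- voxel_positions(unclass(mask), sp)
  as.numeric(colSums(pos * w) / sum(w))
}

#' Centroid distances and peripheral weights
#'
#' For every in-mask voxel, the Euclidean distance d_i from its position
#' to the tumor centre, the maximum d_max over the mask, and the weight
#' w_i = d_i / d_max in [0, 1] that up-weights peripheral voxels in the
#' H index. A single-voxel mask has d_max = 0 and, by convention, all
#' weights 0.
#'
#' @inheritParams suv_centroid
#' @param centroid numeric triple from \code{\link{suv_centroid}} (same
#'   units as the positions).
#' @return list with per-voxel \code{d} and \code{w} (ordered as
#'   \code{which(mask)}) and the scalar \code{d_max}.
#' @export
distance_weights <- function(volume, mask, centroid, use_physical_spacing = TRUE) {
  check_pair(volume, mask)
  if (mask_size(mask) < 1L) stop_validation("empty mask")
  sp <- if (use_physical_spacing) suv_spacing(volume) else c(1, 1, 1)
  pos <- voxel_positions(unclass(mask), sp)
  d <- sqrt(rowSums(sweep(pos, 2L, centroid, `-`)^2))
  d_max <- max(d)
  w <- if (d_max > 0) d / d_max else rep(0, length(d))
  list(d = d, w = w, d_max = d_max)
}

#' Sign of the H index
#'
#' The sign compares the volume-averaged SUV of the whole tumor with that
#' of an inner region, the mask shrunk from the periphery toward the
#' centre: voxels with d_i <= inner_fraction * d_max (default half the
#' maximal centroid distance). If the whole-tumor mean is less than or
#' equal to the inner mean the SUV profile descends from centre to
#' periphery and the sign is +1; otherwise it ascends and the sign is -1.
#' Ties (e.g. a constant tumor) take the + branch.
#'
#' @inheritParams suv_centroid
#' @param dw distances/weights from \code{\link{distance_weights}}.
#' @param inner_fraction fraction of d_max bounding the inner region,
#'   in (0, 1); default 0.5.
#' @return +1 or -1.
#' @export
h_sign <- function(volume, mask, dw, inner_fraction = 0.5) {
  suv <- unclass(volume)[unclass(mask)]
  inner <- dw$d <= inner_fraction * dw$d_max
  if (mean(suv) <= mean(suv[inner])) 1 else -1
}

#' Signed H index of intratumor heterogeneity
#'
#' A single dimensionless parameter summarizing the voxel-wise
#' differential SUV distribution of a segmented tumor:
#' \deqn{|H| = \frac{1}{M} \sum_{i=1}^{M} \frac{d_i}{d_{max}}
#'   \cdot \frac{1}{N_i} \sum_{j=1}^{N_i}
#'   \frac{|\Delta SUV|_{ij}}{SUV_{th}} ,}
#' where M is the number of tumor voxels, N_i the number of in-mask
#' voxels adjacent to voxel i (26-connectivity; at most 26 in 3D, 8 in a
#' single slice), |ΔSUV|_ij the absolute SUV difference between voxel i
#' and its j-th in-mask neighbour, SUV_th the segmentation threshold used
#' as the normalizing SUV scale, and d_i the distance of voxel i from the
#' SUV-weighted tumor centre with d_max its maximum. The distance weight
#' d_i/d_max amplifies peripheral heterogeneity, which is the clinically
#' adverse pattern. Voxels with no in-mask neighbour contribute 0.
#'
#' The sign (\code{\link{h_sign}}) encodes a descending (+) or ascending
#' (-) volume-averaged SUV from centre to periphery. A constant tumor has
#' H = 0; a single-voxel tumor is defined as H = 0 (no neighbour
#' differences and no distance scale).
#'
#' @inheritParams suv_centroid
#' @param suv_th normalizing threshold SUV (g/ml), > 0; default 2.5.
#' @param inner_fraction inner-region fraction for the sign rule,
#'   in (0, 1); default 0.5.
#' @param use_physical_spacing compute centroid distances in mm
#'   (\code{TRUE}, default) or voxel-index units. The weight is a ratio,
#'   so with isotropic voxels the two agree.
#' @return object of class \code{h_index}: a list with the signed index
#'   \code{h}, \code{magnitude}, \code{sign}, \code{centroid},
#'   \code{d_max}, \code{mean_suv_whole}, \code{mean_suv_inner} and the
#'   voxel count \code{m}.
#' @examples
#' # 3-voxel row, SUV (4, 2, 4): centroid at the middle voxel,
#' # magnitude (1/3)(0.8 + 0 + 0.8), ascending profile so sign is -1
#' v <- suv_volume(array(c(4, 2, 4), dim = c(3, 1, 1)))
#' m <- tumor_mask(array(TRUE, dim = c(3, 1, 1)))
#' h_index(v, m)
#' @export
h_index <- function(volume, mask, suv_th = 2.5, inner_fraction = 0.5,
                    use_physical_spacing = TRUE) {
  check_pair(volume, mask)
  if (!is.numeric(suv_th) || length(suv_th) != 1L || !is.finite(suv_th) || suv_th <= 0)
    stop_validation("'suv_th' must be a single positive number (g/ml)")
  if (!is.numeric(inner_fraction) || length(inner_fraction) != 1L ||
      inner_fraction <= 0 || inner_fraction >= 1)
    stop_validation("'inner_fraction' must lie strictly between 0 and 1")
  m <- mask_size(mask)
  if (m < 1L) stop_validation("empty mask: H undefined")

  centroid <- suv_centroid(volume, mask, use_physical_spacing)
  dw <- distance_weights(volume, mask, centroid, use_physical_spacing)
  sgn <- h_sign(volume, mask, dw, inner_fraction)

  ns <- neighbor_sums(volume, mask)
  n_i <- ns$n[unclass(mask)]
  sum_abs <- ns$sum_abs[unclass(mask)]
  local_mean <- ifelse(n_i > 0L, sum_abs / pmax(n_i, 1L), 0)
  magnitude <- sum(dw$w * local_mean / suv_th) / m

  suv <- unclass(volume)[unclass(mask)]
  inner <- dw$d <= inner_fraction * dw$d_max
  structure(list(
    h = sgn * magnitude,
    magnitude = magnitude,
    sign = sgn,
    centroid = centroid,
    d_max = dw$d_max,
    mean_suv_whole = mean(suv),
    mean_suv_inner = mean(suv[inner]),
    m = m,
    suv_th = suv_th,
    inner_fraction = inner_fraction
  ), class = "h_index")
}

#' @export
print.h_index <- function(x, digits = 4, ...) {
  cat(sprintf("H index: %s (magnitude %s, sign %s)\n",
              format(x$h, digits = digits), format(x$magnitude, digits = digits),
              ifelse(x$sign > 0, "+", "-")))
  cat(sprintf("  M = %d voxels; centroid (%s); d_max = %s\n",
              x$m, paste(format(x$centroid, digits = digits), collapse = ", "),
              format(x$d_max, digits = digits)))
  cat(sprintf("  mean SUV whole %s, inner (d <= %s d_max) %s -> %s profile\n",
              format(x$mean_suv_whole, digits = digits), format(x$inner_fraction),
              format(x$mean_suv_inner, digits = digits),
              ifelse(x$sign > 0, "descending", "ascending")))
  invisible(x)
}
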