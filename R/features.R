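#' Heterogeneity feature extraction for one tumor
#'
#' The package's main entry point: given an SUV volume and a tumor mask
#' (or a segmentation threshold from which to derive one), compute the
#' signed H index together with the four GLCM texture features and basic
#' tumor statistics, returned as a single classed object.
#'
#' @param volume an \code{\link{suv_volume}} (or a 3D array, promoted
#'   with unit spacing).
#' @param mask a \code{\link{tumor_mask}}; if \code{NULL} the tumor is
#'   segmented by thresholding at \code{suv_th}.
#' @param suv_th segmentation/normalizing threshold SUV (g/ml);
#'   default 2.5.
#' @param inner_fraction inner-region fraction for the H sign rule;
#'   default 0.5.
#' @param glcm_levels number of gray levels G for the co-occurrence
#'   matrix; default 64.
#' @param entropy_base \code{"e"} (nats, default) or \code{"2"} (bits).
#' @param keep_largest_component passed to \code{\link{segment_suv}} when
#'   segmenting internally.
#' @param tumor_id identifier carried into the feature record.
#' @return object of class \code{het_features}: list with the
#'   \code{h_index} result, \code{glcm} features, \code{record} (one-row
#'   data frame: tumor_id, m_voxels, volume_ml, mean_suv, max_suv,
#'   h_index, h_sign, energy, contrast, local_homogeneity, entropy) and
#'   the call parameters. \code{coef()} extracts the numeric feature
#'   vector; \code{as.data.frame()} the record row.
#' @examples
#' spec <- phantom_spec("single_sphere", R = 12, grid_shape = c(64, 64, 64))
#' f <- het_features(build_phantom(spec), phantom_mask(spec))
#' coef(f)
#' @export
het_features <- function(volume, mask = NULL, suv_th = 2.5,
                         inner_fraction = 0.5, glcm_levels = 64L,
                         entropy_base = c("e", "2"),
                         keep_largest_component = FALSE,
                         tumor_id = "tumor") {
  entropy_base <- match.arg(entropy_base)
  if (!inherits(volume, "suv_volume")) volume <- suv_volume(volume)
  if (is.null(mask)) {
    mask <- segment_suv(volume, suv_th, keep_largest_component)
    if (mask_size(mask) < 1L)
      stop_validation(sprintf("threshold segmentation at %g g/ml yields an empty mask",
                              suv_th))
  } else if (!inherits(mask, "tumor_mask")) {
    mask <- tumor_mask(mask, volume)
  }
  check_pair(volume, mask)
  if (mask_size(mask) < 1L) stop_validation("empty mask")

  h <- h_index(volume, mask, suv_th = suv_th, inner_fraction = inner_fraction)
  suv <- unclass(volume)[unclass(mask)]
  m <- mask_size(mask)
  pairs <- 0L
  tex <- if (m >= 2L) {
    q <- quantize_suv(volume, mask, glcm_levels)
    p <- tryCatch(cooccurrence(q$levels, mask, q$map$n_levels),
                  het_validation_error = function(e) NULL)
    if (is.null(p)) rep(NA_real_, 4L) else {
      pairs <- p$total_pairs
      glcm_features(p, entropy_base)
    }
  } else rep(NA_real_, 4L)
  names(tex) <- c("energy", "contrast", "local_homogeneity", "entropy")

  voxel_ml <- prod(suv_spacing(volume)) / 1000   # mm^3 -> ml
  record <- data.frame(
    tumor_id = tumor_id, m_voxels = m, volume_ml = m * voxel_ml,
    mean_suv = mean(suv), max_suv = max(suv),
    h_index = h$h, h_sign = h$sign,
    energy = unname(tex["energy"]), contrast = unname(tex["contrast"]),
    local_homogeneity = unname(tex["local_homogeneity"]),
    entropy = unname(tex["entropy"]),
    stringsAsFactors = FALSE)

  structure(list(h = h, glcm = tex, glcm_pairs = pairs, record = record,
                 params = list(suv_th = suv_th, inner_fraction = inner_fraction,
                               glcm_levels = as.integer(glcm_levels),
                               entropy_base = entropy_base)),
            class = "het_features")
}

#' @export
print.het_features <- function(x, digits = 4, ...) {
  r <- x$record
  cat(sprintf("Heterogeneity features for '%s' (M = %d voxels, %.3g ml)\n",
              r$tumor_id, r$m_voxels, r$volume_ml))
  cat(sprintf("  H index: %s (%s profile)\n", format(r$h_index, digits = digits),
              ifelse(r$h_sign > 0, "descending", "ascending")))
  cat(sprintf("  GLCM (G = %d): energy %s, contrast %s, local homogeneity %s, entropy %s\n",
              x$params$glcm_levels,
              format(r$energy, digits = digits), format(r$contrast, digits = digits),
              format(r$local_homogeneity, digits = digits),
              format(r$entropy, digits = digits)))
  invisible(x)
}

#' @export
summary.het_features <- function(object, ...) {
  print(object, ...)
  h <- object$h
  cat(sprintf("  centroid (%s), d_max %s\n",
              paste(format(h$centroid, digits = 4), collapse = ", "),
              format(h$d_max, digits = 4)))
  cat(sprintf("  mean SUV: whole %s, inner %s; SUV range [%s, %s] g/ml\n",
              format(h$mean_suv_whole, digits = 4),
              format(h$mean_suv_inner, digits = 4),
              format(object$record$mean_suv, digits = 4),
              format(object$record$max_suv, digits = 4)))
  invisible(object)
}

#' @export
coef.het_features <- function(object, ...) {
  r <- object$record
  c(h_index = r$h_index, energy = r$energy, contrast = r$contrast,
    local_homogeneity = r$local_homogeneity, entropy = r$entropy)
}

#' @export
as.data.frame.het_features <- function(x, ...) x$record

#' Feature sweep over phantom families
#'
#' Build each phantom in a list of specs, compute its features on the
#' sphere-interior (or full-grid, for 2D) mask, and return one
#' feature-record row per phantom. Deterministic: phantom generation
#' involves no randomness.
#'
#' @param specs list of \code{\link{phantom_spec}} objects (an empty list
#'   yields an empty table), or \code{NULL} for the standard validation
#'   suite: single spheres R in \{0, 4, 8, 12\}; N in \{1, 2, 3, 4\} small
#'   spheres (r_s = 6, D = 15); centre distance D in \{10, 15, 19\}
#'   (r_s = 6); small-sphere radius r_s in \{6, 8, 12\} (D = 15).
#' @param ids character labels, one per spec (defaults derived from the
#'   specs).
#' @param ... passed to \code{\link{het_features}}.
#' @return data frame of feature records, one row per phantom, with a
#'   \code{family} and \code{sweep_value} column describing the varied
#'   parameter.
#' @export
sweep_phantoms <- function(specs = NULL, ids = NULL, ...) {
  if (is.null(specs)) specs <- standard_sweep_specs()
  if (length(specs) == 0L)
    return(data.frame())
  bad <- !vapply(specs, inherits, logical(1), "phantom_spec")
  if (any(bad))
    stop_validation(sprintf("invalid phantom spec at position(s) %s",
                            paste(which(bad), collapse = ", ")))
  rows <- vector("list", length(specs))
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    id <- if (!is.null(ids)) ids[[k]] else spec_label(s)
    f <- het_features(build_phantom(s), phantom_mask(s), tumor_id = id, ...)
    r <- f$record
    r$family <- s$family
    r$sweep_value <- sweep_value(s)
    rows[[k]] <- r
  }
  do.call(rbind, rows)
}

#' Standard phantom validation suite
#'
#' The list of phantom specs behind the default \code{\link{sweep_phantoms}}
#' run: single spheres over R, small-sphere count N, centre distance D and
#' small-sphere radius r_s sweeps.
#'
#' @param grid_shape integer triple, grid for every phantom; default 80^3.
#' @return list of \code{\link{phantom_spec}} objects.
#' @export
standard_sweep_specs <- function(grid_shape = c(80L, 80L, 80L)) {
  c(lapply(c(0, 4, 8, 12), function(R)
      phantom_spec("single_sphere", R = R, grid_shape = grid_shape)),
    lapply(1:4, function(N)
      phantom_spec("multi_sphere_N", N = N, r_s = 6, D = 15,
                   grid_shape = grid_shape)),
    lapply(c(10, 15, 19), function(D)
      phantom_spec("two_sphere_D", D = D, r_s = 6, grid_shape = grid_shape)),
    lapply(c(6, 8, 12), function(rs)
      phantom_spec("two_sphere_rs", r_s = rs, D = 15, grid_shape = grid_shape)))
}

spec_label <- function(s) {
  switch(s$family,
         homogeneous = "homogeneous",
         single_sphere = sprintf("single_R%g", s$R),
         multi_sphere_N = sprintf("multi_N%d", s$N),
         two_sphere_D = sprintf("two_D%g", s$D),
         two_sphere_rs = sprintf("two_rs%g", s$r_s),
         pattern2d = sprintf("pattern_%d", s$pattern_id))
}

sweep_value <- function(s) {
  switch(s$family,
         single_sphere = s$R, multi_sphere_N = as.numeric(s$N),
         two_sphere_D = s$D, two_sphere_rs = s$r_s,
         pattern2d = as.numeric(s$pattern_id), NA_real_)
}

#' Univariate feature-outcome correlation
#'
#' Coefficient of determination R^2 of an ordinary univariate linear fit
#' of the outcome on each feature column: a generic utility for relating
#' image features to, e.g., post-treatment tumor volume change on
#' user-supplied tables.
#'
#' @param features data frame (or matrix) of numeric feature columns.
#' @param outcome numeric vector, one value per row of \code{features}.
#' @return named numeric vector of R^2 values in [0, 1], one per
#'   feature column.
#' @export
correlate_features <- function(features, outcome) {
  features <- as.data.frame(features)
  num <- vapply(features, is.numeric, logical(1))
  features <- features[num]
  if (ncol(features) == 0L) stop_validation("no numeric feature columns")
  outcome <- as.numeric(outcome)
  if (length(outcome) != nrow(features))
    stop_validation("'outcome' length must match the number of feature rows")
  if (length(outcome) < 3L)
    stop_validation("need at least 3 paired observations")
  vapply(features, function(x) {
    if (stats::var(x) == 0) stop_validation("zero-variance feature column")
    fit <- stats::lm(outcome ~ x)
    1 - sum(stats::residuals(fit)^2) / sum((outcome - mean(outcome))^2)
  }, numeric(1))
}
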