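#' Digital lesion phantom specification
#'
#' Parameter record for the deterministic validation phantoms: a large
#' sphere of radius \code{r_max} voxels whose SUV follows a modified
#' Gaussian profile pinned to \code{suv_max} at the centre and
#' \code{suv_surface} at the surface, optionally hosting N smaller
#' high-uptake spheres of radius \code{r_s} at centre distance D, plus a
#' homogeneous baseline and a family of 2D patterns. Phantom generation
#' involves no randomness: the same spec always yields the same volume.
#'
#' @param family one of \code{"homogeneous"}, \code{"single_sphere"},
#'   \code{"multi_sphere_N"}, \code{"two_sphere_D"},
#'   \code{"two_sphere_rs"}, \code{"pattern2d"}.
#' @param grid_shape integer triple, the voxel grid; default 80^3
#'   (2D patterns default to 32 x 32 x 1).
#' @param r_max large-sphere radius in voxels; default 30.
#' @param R Gaussian size parameter of the large sphere in voxels
#'   (\code{R = 0} gives the homogeneous baseline: constant
#'   \code{suv_surface} inside the sphere). For the multi-sphere families
#'   the host default is \code{R = r_max}.
#' @param suv_max peak SUV at each sphere centre (g/ml); default 40.
#' @param suv_surface SUV at the large-sphere surface (g/ml); default 2.
#' @param N number of small spheres (1..4), placed at distance D from
#'   the host centre along +x, -x, +y, -y in that order.
#' @param D centre-to-centre distance of small spheres (voxels).
#' @param r_s small-sphere radius (voxels); the small spheres use the
#'   same modified-Gaussian form with size parameter equal to r_s,
#'   peaking at \code{suv_max} and blending continuously into the host
#'   profile at their surface.
#' @param background_suv SUV outside the large sphere; default 0 so that
#'   threshold segmentation at 2.5 g/ml recovers a sphere-interior mask.
#' @param pattern_id for \code{family = "pattern2d"}: integer 1..6, see
#'   \code{\link{build_pattern2d}}.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(family = c("homogeneous", "single_sphere",
                                    "multi_sphere_N", "two_sphere_D",
                                    "two_sphere_rs", "pattern2d"),
                         grid_shape = NULL, r_max = 30, R = NULL,
                         suv_max = 40, suv_surface = 2, N = 1, D = 15,
                         r_s = 6, background_suv = 0, pattern_id = 1L) {
  family <- match.arg(family)
  if (is.null(grid_shape))
    grid_shape <- if (family == "pattern2d") c(32L, 32L, 1L) else c(80L, 80L, 80L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 2L) grid_shape <- c(grid_shape, 1L)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop_validation("'grid_shape' must be a positive integer triple")
  if (!(suv_max > suv_surface) || suv_surface <= 0)
    stop_validation("need suv_max > suv_surface > 0")
  if (family == "homogeneous") R <- 0
  if (is.null(R)) R <- if (family == "single_sphere") 12 else r_max
  if (R < 0) stop_validation("'R' must be >= 0")
  has_subspheres <- family %in% c("multi_sphere_N", "two_sphere_D", "two_sphere_rs")
  if (family %in% c("two_sphere_D", "two_sphere_rs")) N <- 1L
  if (has_subspheres) {
    N <- as.integer(N)
    if (N < 1L || N > 4L) stop_validation("'N' must be 1..4")
    if (r_s <= 0 || D < 0) stop_validation("need r_s > 0 and D >= 0")
    if (r_s + D > r_max)
      stop_validation(sprintf(
        "small sphere extends beyond the host: r_s + D = %g > r_max = %g", r_s + D, r_max))
  }
  if (family != "pattern2d" && any(grid_shape[1:2] < 2 * r_max + 1))
    stop_validation(sprintf(
      "grid too small for the sphere: need >= %d voxels per axis", 2 * r_max + 1))
  if (family == "pattern2d" && !(pattern_id %in% 1:6))
    stop_validation("'pattern_id' must be in 1..6")
  structure(list(family = family, grid_shape = grid_shape, r_max = r_max,
                 R = R, suv_max = suv_max, suv_surface = suv_surface,
                 N = N, D = D, r_s = r_s, background_suv = background_suv,
                 pattern_id = as.integer(pattern_id)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  extra <- switch(x$family,
    single_sphere = sprintf(", R = %g", x$R),
    multi_sphere_N = sprintf(", N = %d, r_s = %g, D = %g", x$N, x$r_s, x$D),
    two_sphere_D = sprintf(", r_s = %g, D = %g", x$r_s, x$D),
    two_sphere_rs = sprintf(", r_s = %g, D = %g", x$r_s, x$D),
    pattern2d = sprintf(", pattern %d", x$pattern_id),
    "")
  cat(sprintf("Phantom spec: %s (grid %s%s)\n", x$family,
              paste(x$grid_shape, collapse = " x "), extra))
  invisible(x)
}

#' Modified-Gaussian radial SUV profile
#'
#' The spherical lesion profile \eqn{SUV(d) = B + A e^{-d^2/R^2}} with A
#' and B solved so that SUV(0) = \code{suv_max} and SUV(\code{r_max}) =
#' \code{suv_surface}; strictly decreasing in d for R > 0. \code{R = 0}
#' is the homogeneous special case: constant \code{suv_surface} inside
#' the sphere. Distances beyond \code{r_max} return
#' \code{background_suv}.
#'
#' @param d distance(s) from the sphere centre, voxels.
#' @param R Gaussian size parameter, voxels, >= 0.
#' @param r_max sphere radius, voxels.
#' @param suv_max centre SUV; default 40.
#' @param suv_surface surface SUV; default 2.
#' @param background_suv value returned for d > r_max; default 0.
#' @return numeric vector of SUV values.
#' @export
gaussian_sphere_profile <- function(d, R, r_max, suv_max = 40,
                                    suv_surface = 2, background_suv = 0) {
  out <- rep(background_suv, length(d))
  inside <- d <= r_max
  if (R == 0) {
    out[inside] <- suv_surface
  } else {
    A <- (suv_max - suv_surface) / (1 - exp(-r_max^2 / R^2))
    B <- suv_max - A
    out[inside] <- B + A * exp(-d[inside]^2 / R^2)
  }
  out
}

# position grid (voxel units, 0-based) and distance-from-centre array
grid_distance <- function(grid_shape, center) {
  x <- (seq_len(grid_shape[1]) - 1) - center[1]
  y <- (seq_len(grid_shape[2]) - 1) - center[2]
  z <- (seq_len(grid_shape[3]) - 1) - center[3]
  sqrt(outer(outer(x^2, y^2, `+`), z^2, `+`))
}

#' Build a spherical phantom volume
#'
#' Deterministically realize a \code{\link{phantom_spec}} as an
#' \code{\link{suv_volume}} (voxel spacing 1): the large sphere is
#' centred in the grid with the modified-Gaussian profile; each small
#' sphere peaks at \code{suv_max} at its own centre and decreases along
#' its radius to the host sphere's SUV at its boundary (evaluated at the
#' radial boundary point, so the blend is continuous), overwriting host
#' values inside.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return an \code{\link{suv_volume}}.
#' @examples
#' v <- build_phantom(phantom_spec("single_sphere", R = 12,
#'                                 grid_shape = c(64, 64, 64), r_max = 30))
#' max(v)  # 40 at the centre
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_validation("'spec' must be a phantom_spec")
  if (spec$family == "pattern2d")
    return(build_pattern2d(spec$pattern_id, spec$grid_shape))
  gs <- spec$grid_shape
  c0 <- (gs - 1) / 2
  d0 <- grid_distance(gs, c0)
  vals <- array(
    gaussian_sphere_profile(d0, spec$R, spec$r_max, spec$suv_max,
                            spec$suv_surface, spec$background_suv),
    dim = gs)

  if (spec$family %in% c("multi_sphere_N", "two_sphere_D", "two_sphere_rs")) {
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
    centers <- sweep(dirs[seq_len(spec$N), , drop = FALSE] * spec$D, 2L, c0, `+`)
    if (spec$N > 1L) {
      cd <- as.matrix(stats::dist(centers))
      if (any(cd[upper.tri(cd)] < 2 * spec$r_s))
        stop_validation("small spheres overlap: increase D or reduce r_s")
    }
    for (k in seq_len(spec$N))
      vals <- add_subsphere(vals, gs, c0, centers[k, ], spec)
  }
  suv_volume(vals, spacing = c(1, 1, 1))
}

# overwrite host values inside one small sphere with a modified-Gaussian
# bump: suv_max at its centre, host SUV at its radial boundary point
add_subsphere <- function(vals, gs, c0, cs, spec) {
  r_s <- spec$r_s
  ds <- grid_distance(gs, cs)
  inside <- which(ds <= r_s)
  if (length(inside) == 0L) return(vals)
  idx <- arrayInd(inside, gs)
  pos <- idx - 1
  rel <- sweep(pos, 2L, cs, `-`)
  dd <- ds[inside]
  # radial boundary point on the small-sphere surface; centre voxel maps
  # to the surface value along +x (any direction works: it only sets the
  # boundary SUV used to pin the profile there)
  u <- rel / ifelse(dd > 0, dd, 1)
  u[dd == 0, ] <- rep(c(1, 0, 0), each = sum(dd == 0))
  bnd <- sweep(u * r_s, 2L, cs - c0, `+`)   # boundary point relative to host centre
  db <- sqrt(rowSums(bnd^2))
  hb <- gaussian_sphere_profile(pmin(db, spec$r_max), spec$R, spec$r_max,
                                spec$suv_max, spec$suv_surface,
                                spec$background_suv)
  # size parameter of the small-sphere Gaussian equals its radius
  decay <- exp(-dd^2 / r_s^2)
  A <- (spec$suv_max - hb) / (1 - exp(-1))
  vals[inside] <- (spec$suv_max - A) + A * decay
  vals
}

#' Sphere-interior mask of a spherical phantom
#'
#' The geometric mask of voxels within \code{r_max} of the grid centre.
#' This is the natural analysis region for the phantom sweeps: it equals
#' the threshold segmentation up to a thin surface shell (the profile
#' surface value 2.0 sits below the 2.5 threshold) and, unlike
#' thresholding, is non-empty for the homogeneous R = 0 baseline. For 2D
#' patterns the full grid is returned.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a \code{\link{tumor_mask}}.
#' @export
phantom_mask <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_validation("'spec' must be a phantom_spec")
  gs <- spec$grid_shape
  if (spec$family == "pattern2d")
    return(tumor_mask(array(TRUE, dim = gs)))
  d0 <- grid_distance(gs, (gs - 1) / 2)
  tumor_mask(array(d0 <= spec$r_max, dim = gs))
}

#' 2D test patterns
#'
#' Six deterministic single-slice SUV distributions exercising the
#' heterogeneity index and texture features. The exact pixel images these
#' patterns emulate exist only as published figures, so these are
#' parameterized analogs reproducing every stated constraint, not pixel
#' reproductions:
#' \enumerate{
#'   \item smooth horizontal ramp 2..8 g/ml (mean exactly 5);
#'   \item 2/8 checkerboard (mean exactly 5; strictly more heterogeneous
#'     than pattern 1 in mean absolute neighbour difference and |H|);
#'   \item centre-peaked modified-Gaussian disk (descending profile,
#'     positive H);
#'   \item concentric alternating rings;
#'   \item four constant quadrants;
#'   \item ascending cone, low centre to high rim (negative H).
#' }
#'
#' @param pattern_id integer 1..6.
#' @param grid_shape grid, default 32 x 32 x 1; the first two axes must
#'   be equal and even.
#' @return a single-slice \code{\link{suv_volume}}.
#' @export
build_pattern2d <- function(pattern_id, grid_shape = c(32L, 32L, 1L)) {
  if (!(pattern_id %in% 1:6)) stop_validation("'pattern_id' must be in 1..6")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) == 2L) grid_shape <- c(grid_shape, 1L)
  n <- grid_shape[1]
  if (grid_shape[2] != n || grid_shape[3] != 1L || n %% 2L != 0L || n < 4L)
    stop_validation("2D patterns need an even square single-slice grid")
  xi <- seq_len(n) - 1
  cx <- (n - 1) / 2
  r <- sqrt(outer((xi - cx)^2, (xi - cx)^2, `+`))
  r_edge <- cx
  vals <- switch(pattern_id,
    # 1: ramp, symmetric about the centre column -> mean exactly 5
    matrix(rep(2 + 6 * xi / (n - 1), times = n), n, n),
    # 2: checkerboard of 2 and 8; even n -> equal counts, mean exactly 5
    outer(seq_len(n), seq_len(n), function(i, j) ifelse((i + j) %% 2 == 0, 8, 2)),
    # 3: centre-peaked modified Gaussian, 40 centre -> 2 at the inscribed edge
    matrix(gaussian_sphere_profile(pmin(r, r_edge), R = n / 4, r_max = r_edge),
           n, n),
    # 4: concentric rings alternating 3 / 7 g/ml, 4-voxel period
    matrix(ifelse(floor(r / 4) %% 2 == 0, 7, 3), n, n),
    # 5: four constant quadrants
    outer(seq_len(n), seq_len(n),
          function(i, j) 2 + 2 * ((i > n / 2) + 2 * (j > n / 2))),
    # 6: ascending cone: 2 at the centre rising to 40 at the rim
    matrix(2 + 38 * pmin(r, r_edge) / r_edge, n, n))
  suv_volume(array(vals, dim = c(n, n, 1L)), spacing = c(1, 1, 1))
}
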