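#' Gray-level quantization of in-mask SUV
#'
#' Map in-mask SUV to integer gray levels 1..G with equal-width bins over
#' the in-mask min-max range (the dominant radiomics convention; the top
#' bin is right-closed so the maximum maps to level G). A constant region
#' maps everything to level 1.
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param mask a \code{\link{tumor_mask}}.
#' @param n_levels number of gray levels G >= 2; default 64.
#' @return list: \code{levels}, an integer array (0 outside the mask,
#'   1..G inside), and the \code{map} (G, range, bin edges).
#' @export
quantize_suv <- function(volume, mask, n_levels = 64L) {
  check_pair(volume, mask)
  if (mask_size(mask) < 1L) stop_validation("empty mask: nothing to quantize")
  G <- as.integer(n_levels)
  if (is.na(G) || G < 2L) stop_validation("'n_levels' must be an integer >= 2")
  v <- unclass(volume)
  m <- unclass(mask)
  lo <- min(v[m]); hi <- max(v[m])
  lev <- array(0L, dim = dim(v))
  if (hi > lo) {
    width <- (hi - lo) / G
    l <- pmin(pmax(floor((v[m] - lo) / width) + 1, 1L), G)
    lev[m] <- as.integer(l)
  } else {
    lev[m] <- 1L
  }
  list(levels = lev,
       map = list(n_levels = G, range = c(lo, hi),
                  edges = seq(lo, hi, length.out = G + 1L)))
}

#' Gray-level co-occurrence matrix over all nearest-neighbour offsets
#'
#' Accumulate one count for every ordered pair of in-mask voxels (i, j)
#' with j adjacent to i (all 26 offsets at distance 1 in 3D; 8 on a
#' single-slice grid) and normalize to probabilities P(g, h). Because
#' every offset and its negation are both accumulated, P is symmetric by
#' construction; pairs with either endpoint outside the mask are
#' discarded, so the texture is computed strictly within the tumor.
#'
#' @param levels integer array of gray levels from
#'   \code{\link{quantize_suv}} (0 outside the mask).
#' @param mask a \code{\link{tumor_mask}}.
#' @param n_levels number of gray levels G (rows/cols of P); defaults to
#'   \code{max(levels)}.
#' @return object of class \code{glcm}: list with the G x G probability
#'   matrix \code{p} and \code{total_pairs}, the ordered pair count.
#' @export
cooccurrence <- function(levels, mask, n_levels = NULL) {
  m <- unclass(mask)
  if (!identical(dim(levels), dim(m)))
    stop_validation("levels grid and mask have different shapes")
  G <- if (is.null(n_levels)) max(levels) else as.integer(n_levels)
  if (G < 1L) stop_validation("no gray levels present")
  d <- dim(m)
  counts <- numeric(G * G)
  for (r in seq_len(26L)) {
    off <- .offset_table[r, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    ma <- m[rng$ax, rng$ay, rng$az, drop = FALSE]
    mb <- m[rng$bx, rng$by, rng$bz, drop = FALSE]
    both <- ma & mb
    if (!any(both)) next
    la <- levels[rng$ax, rng$ay, rng$az, drop = FALSE][both]
    lb <- levels[rng$bx, rng$by, rng$bz, drop = FALSE][both]
    counts <- counts + tabulate((lb - 1L) * G + la, nbins = G * G)
  }
  total <- sum(counts)
  if (total == 0)
    stop_validation("no in-mask voxel adjacencies: co-occurrence matrix undefined")
  structure(list(p = matrix(counts / total, G, G), total_pairs = total),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d gray levels, %d ordered co-occurring pairs\n",
              nrow(x$p), x$total_pairs))
  invisible(x)
}

#' Haralick texture features of a co-occurrence matrix
#'
#' The four second-order texture statistics used alongside the H index:
#' \describe{
#'   \item{energy}{\eqn{\sum_{g,h} P(g,h)^2} — image uniformity; 1 for a
#'     constant image.}
#'   \item{contrast}{\eqn{\sum_{g,h} (g-h)^2 P(g,h)} — favours
#'     off-diagonal mass, i.e. large local gray-level differences.}
#'   \item{local_homogeneity}{\eqn{\sum_{g,h} P(g,h)/(1+(g-h)^2)} —
#'     favours near-diagonal mass.}
#'   \item{entropy}{\eqn{-\sum_{g,h} P(g,h)\log P(g,h)} (0 log 0 = 0) —
#'     randomness of the gray-level pairing; maximal for uniform P.}
#' }
#'
#' @param glcm a \code{glcm} object (or bare probability matrix).
#' @param entropy_base logarithm base for the entropy, \code{"e"} (nats,
#'   default) or \code{"2"} (bits).
#' @return named numeric vector \code{energy}, \code{contrast},
#'   \code{local_homogeneity}, \code{entropy}.
#' @export
glcm_features <- function(glcm, entropy_base = c("e", "2")) {
  entropy_base <- match.arg(entropy_base)
  p <- if (inherits(glcm, "glcm")) glcm$p else as.matrix(glcm)
  G <- nrow(p)
  g <- row(p); h <- col(p)
  pos <- p > 0
  logp <- if (entropy_base == "e") log(p[pos]) else log2(p[pos])
  c(energy = sum(p^2),
    contrast = sum((g - h)^2 * p),
    local_homogeneity = sum(p / (1 + (g - h)^2)),
    entropy = -sum(p[pos] * logp))
}
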