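#' Threshold-based tumor segmentation
#'
#' Segment a tumor from an SUV volume by thresholding: a voxel belongs to
#' the mask iff its SUV is greater than or equal to \code{suv_th}. The
#' comparison is inclusive, so a lesion whose minimum uptake equals the
#' threshold is kept intact. The conventional clinical threshold of
#' 2.5 g/ml is the default.
#'
#' The returned mask may be empty (M = 0); feature computations reject
#' empty masks, so callers should check \code{\link{mask_size}} first.
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param suv_th threshold SUV (g/ml), > 0; default 2.5.
#' @param keep_largest_component if \code{TRUE}, retain only the largest
#'   26-connected component of the thresholded set (useful for multifocal
#'   uptake); default \code{FALSE}.
#' @return a \code{\link{tumor_mask}}.
#' @examples
#' v <- suv_volume(array(c(2.4, 2.5, 2.6, 1), dim = c(4, 1, 1)))
#' sum(segment_suv(v, suv_th = 2.5))  # 2: comparison is inclusive
#' @export
segment_suv <- function(volume, suv_th = 2.5, keep_largest_component = FALSE) {
  if (!is.numeric(suv_th) || length(suv_th) != 1L || !is.finite(suv_th) || suv_th <= 0)
    stop_validation("'suv_th' must be a single positive number (g/ml)")
  m <- unclass(volume) >= suv_th
  if (keep_largest_component && any(m)) m <- largest_component(m)
  tumor_mask(array(m, dim = dim(unclass(volume))))
}

# largest 26-connected component of a logical array, via igraph
largest_component <- function(m) {
  d <- dim(m)
  ids <- array(0L, dim = d)
  vox <- which(m)
  ids[vox] <- seq_along(vox)
  edges <- integer(0)
  for (r in seq_len(13L)) {          # half the offsets; edges are undirected
    off <- .offset_table[r, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    a <- ids[rng$ax, rng$ay, rng$az, drop = FALSE]
    b <- ids[rng$bx, rng$by, rng$bz, drop = FALSE]
    both <- a > 0L & b > 0L
    if (any(both)) edges <- c(edges, rbind(a[both], b[both]))
  }
  if (length(edges) == 0L) {
    # no adjacencies: every in-mask voxel is its own component; keep the first
    keep <- vox[1L]
    out <- array(FALSE, dim = d)
    out[keep] <- TRUE
    return(out)
  }
  g <- igraph::make_graph(edges, n = length(vox), directed = FALSE)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  out <- array(FALSE, dim = d)
  out[vox[comp$membership == biggest]] <- TRUE
  out
}
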