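# 26-connectivity (Chebyshev radius 1) in index space. Adjacency is
# defined on indices, ignoring anisotropic spacing: the neighbour count
# per voxel is at most 26 in 3D and degenerates to at most 8 on a
# single-slice grid.

neighbor_offsets <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
}

#' In-mask neighbours of a voxel
#'
#' Enumerate the voxels adjacent to a given voxel (differing by at most 1
#' on every index axis, not identical) that also lie inside the mask.
#' The count N_i is at most 26 in 3D, at most 8 for single-slice grids.
#'
#' @param index integer triple, 1-based voxel index.
#' @param mask a \code{tumor_mask}.
#' @return integer matrix with one row per in-mask neighbour (1-based
#'   indices), possibly zero rows.
#' @export
neighbors <- function(index, mask) {
  index <- as.integer(index)
  if (length(index) != 3L) stop_validation("'index' must be an integer triple")
  d <- dim(mask)
  if (any(index < 1L) || any(index > d))
    stop_validation("voxel index lies outside the grid")
  if (!mask[index[1], index[2], index[3]])
    stop_validation("voxel index is not inside the mask")
  off <- neighbor_offsets()
  cand <- sweep(off, 2L, index, `+`)
  ok <- cand[, 1] >= 1L & cand[, 1] <= d[1] &
        cand[, 2] >= 1L & cand[, 2] <= d[2] &
        cand[, 3] >= 1L & cand[, 3] <= d[3]
  cand <- cand[ok, , drop = FALSE]
  inmask <- mask[cand]
  cand[inmask, , drop = FALSE]
}

# Vectorized accumulation over all 26 offsets. For every in-grid voxel
# returns N_i (count of in-mask neighbours) and the sum over those
# neighbours of |SUV_i - SUV_j|. Out-of-mask voxels get 0s. One pass per
# offset, each fully vectorized over the overlapping sub-grids.
neighbor_sums <- function(values, mask) {
  d <- dim(mask)
  values <- unclass(values)
  mask <- unclass(mask)
  n <- array(0L, dim = d)
  sum_abs <- array(0, dim = d)
  for (r in seq_len(26L)) {
    off <- .offset_table[r, ]
    rng <- offset_ranges(d, off)
    if (is.null(rng)) next
    ma <- mask[rng$ax, rng$ay, rng$az, drop = FALSE]
    mb <- mask[rng$bx, rng$by, rng$bz, drop = FALSE]
    both <- ma & mb
    if (!any(both)) next
    va <- values[rng$ax, rng$ay, rng$az, drop = FALSE]
    vb <- values[rng$bx, rng$by, rng$bz, drop = FALSE]
    dv <- abs(va - vb)
    dv[!both] <- 0
    n[rng$ax, rng$ay, rng$az] <- n[rng$ax, rng$ay, rng$az, drop = FALSE] + both
    sum_abs[rng$ax, rng$ay, rng$az] <- sum_abs[rng$ax, rng$ay, rng$az, drop = FALSE] + dv
  }
  n[!mask] <- 0L
  sum_abs[!mask] <- 0
  list(n = n, sum_abs = sum_abs)
}

# overlapping index ranges for source (a) and shifted target (b = a + off);
# NULL when the shift leaves no overlap (axis of length 1 with off != 0)
offset_ranges <- function(d, off) {
  lo <- pmax(1L, 1L - off)
  hi <- pmin(d, d - off)
  if (any(lo > hi)) return(NULL)
  ax <- seq.int(lo[1], hi[1]); ay <- seq.int(lo[2], hi[2]); az <- seq.int(lo[3], hi[3])
  list(ax = ax, ay = ay, az = az,
       bx = ax + off[1], by = ay + off[2], bz = az + off[3])
}

.offset_table <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), , drop = FALSE])
})
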