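# Naive reference implementations and fixture generators, kept deliberately
# independent of the package internals: per-voxel scalar loops over the 26
# explicit offsets.

all_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
all_offsets <- all_offsets[rowSums(all_offsets != 0) > 0, , drop = FALSE]

# brute-force signed H index
oracle_h <- function(values, mask, suv_th = 2.5, inner_fraction = 0.5,
                     spacing = c(1, 1, 1)) {
  values <- unclass(values); mask <- unclass(mask)
  d <- dim(mask)
  vox <- which(mask)
  M <- length(vox)
  idx <- arrayInd(vox, d)
  pos <- sweep(idx - 1, 2L, spacing, `*`)
  suv <- values[vox]
  centroid <- colSums(pos * suv) / sum(suv)
  di <- sqrt(rowSums(sweep(pos, 2L, centroid, `-`)^2))
  d_max <- max(di)
  w <- if (d_max > 0) di / d_max else rep(0, M)
  local <- numeric(M)
  for (k in seq_len(M)) {
    i <- idx[k, ]
    s <- 0; n <- 0L
    for (r in seq_len(nrow(all_offsets))) {
      j <- i + all_offsets[r, ]
      if (any(j < 1L) || any(j > d)) next
      if (!mask[j[1], j[2], j[3]]) next
      n <- n + 1L
      s <- s + abs(values[i[1], i[2], i[3]] - values[j[1], j[2], j[3]])
    }
    if (n > 0L) local[k] <- s / n
  }
  magnitude <- sum(w * local / suv_th) / M
  inner <- di <= inner_fraction * d_max
  sgn <- if (mean(suv) <= mean(suv[inner])) 1 else -1
  sgn * magnitude
}

# brute-force ordered co-occurrence counts over all 26 offsets
oracle_glcm_counts <- function(levels, mask, G) {
  mask <- unclass(mask)
  d <- dim(mask)
  counts <- matrix(0, G, G)
  for (k in which(mask)) {
    i <- arrayInd(k, d)[1, ]
    for (r in seq_len(nrow(all_offsets))) {
      j <- i + all_offsets[r, ]
      if (any(j < 1L) || any(j > d)) next
      if (!mask[j[1], j[2], j[3]]) next
      g <- levels[i[1], i[2], i[3]]
      h <- levels[j[1], j[2], j[3]]
      counts[g, h] <- counts[g, h] + 1
    }
  }
  counts
}

# random small volume + mask, guaranteed non-empty with positive in-mask SUV
random_case <- function(max_dim = 8L, p_mask = 0.6) {
  d <- sample(2:max_dim, 3L, replace = TRUE)
  vals <- array(round(stats::runif(prod(d), 0, 12), 2), dim = d)
  m <- array(stats::runif(prod(d)) < p_mask, dim = d)
  if (!any(m)) m[sample.int(length(m), 1L)] <- TRUE
  if (all(vals[m] == 0)) vals[which(m)[1L]] <- 1
  list(volume = suv_volume(vals), mask = tumor_mask(m))
}

# small centre-peaked sphere phantom shared across tests
small_sphere <- function(R = 8, r_max = 14, n = 33L) {
  spec <- phantom_spec("single_sphere", R = R, r_max = r_max,
                       grid_shape = rep(n, 3L))
  list(spec = spec, volume = build_phantom(spec), mask = phantom_mask(spec))
}
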