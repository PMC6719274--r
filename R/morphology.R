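# Internal grid primitives: separable Gaussian smoothing, binary morphology
# with mm-sized ellipsoidal structuring elements, 26-connected components and
# slice-wise hole filling. Grids are small (head CT at desk scale), so these
# are vectorised base-R implementations.

# Apply an n x n linear operator along one axis of a 3D array.
apply_axis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  a <- M %*% matrix(a, nrow = dp[1])
  dim(a) <- dp
  aperm(a, order(perm))
}

# Truncated, row-normalised Gaussian convolution matrix (handles edges by
# renormalisation).
gauss_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 1e-8) return(diag(n))
  i <- seq_len(n)
  K <- outer(i, i, function(a, b) exp(-(a - b)^2 / (2 * sigma_vox^2)))
  K[K < 1e-8] <- 0
  K / rowSums(K)
}

# Separable 3D Gaussian smoothing with a sigma given in mm.
smooth3d <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    sv <- sigma_mm / spacing[ax]
    if (sv > 1e-8) arr <- apply_axis(arr, gauss_matrix(d[ax], sv), ax)
  }
  arr
}

# Normalised smoothing of a field defined only on a mask: values outside the
# mask do not contribute, and the result extrapolates smoothly beyond it.
# Voxels out of reach of any mask voxel get 0.
smooth_masked <- function(values, mask, sigma_mm, spacing) {
  m <- array(as.numeric(mask), dim = dim(mask))
  v <- values
  v[!mask] <- 0
  num <- smooth3d(v, sigma_mm, spacing)
  den <- smooth3d(m, sigma_mm, spacing)
  out <- num / pmax(den, 1e-12)
  out[den < 1e-8] <- 0
  out
}

# Integer voxel offsets whose mm displacement lies within radius_mm
# (ellipsoidal ball under anisotropic spacing). Excludes the origin.
ball_offsets <- function(radius_mm, spacing) {
  r <- pmax(floor(radius_mm / spacing), 0)
  g <- expand.grid(di = -r[1]:r[1], dj = -r[2]:r[2], dk = -r[3]:r[3])
  dist2 <- (g$di * spacing[1])^2 + (g$dj * spacing[2])^2 + (g$dk * spacing[3])^2
  g <- g[dist2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  as.matrix(g[!(g$di == 0 & g$dj == 0 & g$dk == 0), , drop = FALSE])
}

# Shift a logical array by an integer offset, padding with `fill`.
shift_mask <- function(mask, off, fill = FALSE) {
  d <- dim(mask)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      if (o >= d[ax]) return(out)
      src[[ax]] <- 1:(d[ax] - o); dst[[ax]] <- (1 + o):d[ax]
    } else {
      if (-o >= d[ax]) return(out)
      src[[ax]] <- (1 - o):d[ax]; dst[[ax]] <- 1:(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

erode_mm <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  if (nrow(offs) == 0) return(out)
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mask(mask, offs[i, ], fill = TRUE)
  out
}

dilate_mm <- function(mask, radius_mm, spacing) {
  offs <- ball_offsets(radius_mm, spacing)
  out <- mask
  if (nrow(offs) == 0) return(out)
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mask(mask, offs[i, ], fill = FALSE)
  out
}

# Label 26-connected components; returns integer array (0 = background).
# Vectorised breadth-first flood fill over coordinate frontiers.
label_components_26 <- function(mask) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  labels <- array(0L, dim = d)
  remaining <- which(mask)
  lab <- 0L
  while (length(remaining) > 0) {
    lab <- lab + 1L
    seed <- remaining[1]
    labels[seed] <- lab
    frontier <- arrayInd(seed, d)
    while (nrow(frontier) > 0) {
      cand <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(frontier, 2, offs[i, ], `+`)))
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
            cand[, 2] >= 1 & cand[, 2] <= d[2] &
            cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      keep <- !duplicated(lin)
      lin <- lin[keep]; cand <- cand[keep, , drop = FALSE]
      new <- mask[lin] & labels[lin] == 0L
      lin <- lin[new]
      labels[lin] <- lab
      frontier <- cand[new, , drop = FALSE]
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  labels
}

largest_component_26 <- function(mask) {
  labels <- label_components_26(mask)
  if (max(labels) == 0L) return(mask & FALSE)
  sizes <- tabulate(labels[labels > 0L])
  labels == which.max(sizes)
}

# Fill holes independently in each axial (third-axis) slice: background
# pixels not 4-connected to the slice border become foreground.
fill_holes_slicewise <- function(mask) {
  d <- dim(mask)
  out <- mask
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    bg <- !sl
    reach <- matrix(FALSE, d[1], d[2])
    # seed: border background pixels
    reach[1, ] <- bg[1, ]; reach[d[1], ] <- bg[d[1], ]
    reach[, 1] <- reach[, 1] | bg[, 1]; reach[, d[2]] <- reach[, d[2]] | bg[, d[2]]
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-d[1], ]
      grown[-d[1], ] <- grown[-d[1], ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -d[2]]
      grown[, -d[2]] <- grown[, -d[2]] | reach[, -1]
      grown <- grown & bg
      if (all(grown == reach)) break
      reach <- grown
    }
    out[, , k] <- sl | (bg & !reach)
  }
  out
}
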