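#' Histogram-sharpening intensity-inhomogeneity correction (N4-style backend)
#'
#' Non-segmentation correction: the observed log-intensity histogram is
#' modelled as the true tissue histogram convolved with a Gaussian bias
#' distribution of width `sharpen_fwhm`. Per multiresolution level the
#' backend iterates: (a) histogram of the current corrected log intensities
#' (`hist_bins` bins); (b) sharpened histogram by Wiener deconvolution with
#' the Gaussian and regulariser `wiener_noise`; (c) per-voxel expected true
#' intensity under the sharpened distribution; (d) the residual
#' (current - expected) fitted with a separable cubic B-spline field, knot
#' spacing `smooth_scale_mm / 2^(level-1)`, mean-centred; (e) field
#' accumulation. Levels run from coarse to fine, each until the maximum
#' field update falls below `tol` or `max_iters` iterations.
#'
#' A degenerate histogram (single occupied bin) yields the identity
#' correction with `converged = TRUE`.
#'
#' @inheritParams correct_em_seg
#' @param params an [iic_params] with `backend = "hist_sharpen"`.
#' @return an `iic_result`; see [correct_em_seg] for the field conventions.
#' @export
correct_hist_sharpen <- function(vol, mask, params = iic_params("hist_sharpen")) {
  if (params$backend != "hist_sharpen")
    stop("correct_hist_sharpen: params$backend must be 'hist_sharpen'")
  y <- iic_setup(vol, mask, params)
  if (length(y) < 20)
    stop("correct_hist_sharpen: mask too small")
  m <- mask$mask
  sigma_g <- params$sharpen_fwhm / (2 * sqrt(2 * log(2)))
  b <- rep(0, length(y))
  resid_arr <- array(0, dim = dim(vol$data))
  total_iters <- 0L
  converged <- TRUE
  for (level in seq_len(params$levels)) {
    knot_mm <- params$smooth_scale_mm / 2^(level - 1)
    if (knot_mm <= max(vol$spacing)) break   # finer than the grid: stop
    level_done <- FALSE
    it <- 0L
    while (it < params$max_iters) {
      it <- it + 1L
      total_iters <- total_iters + 1L
      x <- y - b
      u_exp <- expected_true_intensity(x, params$hist_bins, sigma_g,
                                       params$wiener_noise)
      if (is.null(u_exp)) { level_done <- TRUE; break }  # degenerate histogram
      resid_arr[m] <- x - u_exp
      db <- fit_spline_field(resid_arr, m, vol$spacing, knot_mm)[m]
      b <- b + db
      b <- b - mean(b)
      if (max(abs(db)) < params$tol) { level_done <- TRUE; break }
    }
    if (!level_done) converged <- FALSE
  }
  iic_finalize(vol, mask, b, total_iters, converged, params)
}

# Expected true (sharpened) intensity for each voxel value, via Wiener
# deconvolution of the binned histogram. Returns NULL when the histogram is
# degenerate (single occupied bin), meaning: nothing to sharpen.
expected_true_intensity <- function(x, nbins, sigma_g, wiener_noise) {
  rng <- range(x)
  if (diff(rng) < 1e-9) return(NULL)
  width <- diff(rng) / nbins
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  centers <- (breaks[-1] + breaks[-(nbins + 1)]) / 2
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nbins)
  h <- tabulate(idx, nbins)
  if (sum(h > 0) < 2) return(NULL)
  p <- h / sum(h)

  # circular Wiener deconvolution on a padded grid
  npad <- stats::nextn(2L * nbins, 2)
  pp <- c(p, rep(0, npad - nbins))
  d <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) * width
  g <- exp(-d^2 / (2 * sigma_g^2))
  g <- g / sum(g)
  G <- stats::fft(g)
  FF <- Conj(G) / (Mod(G)^2 + wiener_noise)
  ph <- Re(stats::fft(stats::fft(pp) * FF, inverse = TRUE)) / npad
  ph <- ph[1:nbins]
  ph[ph < 0] <- 0
  if (sum(ph) <= 0) return(NULL)
  ph <- ph / sum(ph)

  # E[u | v] = sum_u u phat(u) G(v - u) / sum_u phat(u) G(v - u)
  G2 <- exp(-outer(centers, centers, `-`)^2 / (2 * sigma_g^2))
  den <- as.numeric(G2 %*% ph)
  num <- as.numeric(G2 %*% (ph * centers))
  ev <- ifelse(den > 1e-300, num / den, centers)
  stats::approx(centers, ev, xout = x, rule = 2)$y
}

# --- separable cubic B-spline field fitting -------------------------------

.spline_proj_cache <- new.env(parent = emptyenv())

# Projection matrix onto cubic B-splines with knot spacing h (voxels) along
# an axis of length n; small ridge for conditioning.
spline_proj_matrix <- function(n, h_vox) {
  key <- paste(n, signif(h_vox, 8))
  hit <- .spline_proj_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- max(h_vox, 1)
  knots <- seq(1 - 3 * h, n + 3 * h, by = h)
  B <- splines::splineDesign(knots, x = seq_len(n), ord = 4, outer.ok = TRUE)
  P <- B %*% solve(crossprod(B) + 1e-8 * diag(ncol(B)), t(B))
  .spline_proj_cache[[key]] <- P
  P
}

# Fit a smooth separable B-spline field to values defined on a mask: the
# masked residual is first extrapolated by normalised Gaussian smoothing
# (so the unweighted separable fit is well posed off-mask), then projected
# axis-by-axis onto the spline space.
fit_spline_field <- function(values_arr, mask, spacing, knot_mm) {
  ext <- smooth_masked(values_arr, mask, knot_mm / 4, spacing)
  d <- dim(ext)
  for (ax in 1:3) {
    h_vox <- knot_mm / spacing[ax]
    ext <- apply_axis(ext, spline_proj_matrix(d[ax], h_vox), ax)
  }
  ext
}
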