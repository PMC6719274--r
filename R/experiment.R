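#' Specification of a lesion-recovery simulation grid
#'
#' The simulation study sweeps spherical lesion size and fractional density
#' reduction over both correction backends: one fresh phantom per cell with
#' a single right-sided spherical lesion, full pipeline, measured infarct
#' volume recorded. Default volumes follow the quantitative anchor
#' (122, 45, 17 cc) and reductions span 30% down to 5%.
#'
#' @param volumes_cc true lesion volumes in cc (default `c(122, 45, 17)`).
#' @param reductions fractional density reductions in (0, 0.5]
#'   (default `c(0.30, 0.20, 0.10, 0.05)`).
#' @param backends correction backends (default both).
#' @param phantom a [phantom_spec] for the lesion-free substrate.
#' @param replicates control-phantom noise replicates (default 1); all cells
#'   of a replicate share one control phantom.
#' @param seed integer base seed; the replicate-r control phantom uses seed
#'   `seed + r`, so replicates are independent yet the grid is reproducible.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(volumes_cc = c(122, 45, 17),
                      reductions = c(0.30, 0.20, 0.10, 0.05),
                      backends = c("em_seg", "hist_sharpen"),
                      phantom = phantom_spec(),
                      replicates = 1L, seed = 1L) {
  stopifnot(length(volumes_cc) > 0, all(volumes_cc > 0),
            length(reductions) > 0,
            all(reductions > 0), all(reductions <= 0.5),
            all(backends %in% c("em_seg", "hist_sharpen")),
            inherits(phantom, "phantom_spec"), replicates >= 1)
  structure(list(volumes_cc = as.numeric(volumes_cc),
                 reductions = as.numeric(reductions),
                 backends = backends, phantom = phantom,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "grid_spec")
}

# Common lesion centre for all sphere sizes: 34 mm lateral of the midline at
# mid-height -- a stand-in for the middle-cerebral-artery territory, and the
# lateral position at which the largest default sphere (122 cc, radius
# 30.8 mm) still fits inside the default brain without crossing the midline.
lesion_center_default <- function(side = "right") {
  c(if (side == "right") 34 else -34, 0, 0)
}

#' Run the lesion-recovery simulation grid
#'
#' Emulates the recovery study design: one control phantom per replicate
#' (seeded deterministically as `spec$seed + replicate`, so the whole grid is
#' reproducible), into which each (volume, reduction) lesion is inserted in
#' turn; every cell then runs brain extraction, inhomogeneity correction and
#' volumetry (forced to the known lesion side) and records the measured
#' infarct volume. Sharing the control scan across cells mirrors the use of
#' a single control head CT as substrate for all synthetic infarcts, and
#' makes within-substrate comparisons (recovery versus size or contrast)
#' independent of between-scan noise. Cell failures are recorded and the
#' grid continues; a grid with no successful cell is an error.
#'
#' @param spec a [grid_spec].
#' @param side lesion (and forced ipsilateral) side, default `"right"`.
#' @param upper_hu difference-map threshold, default -1.5 HU.
#' @param lesion_center mm coordinates of the common lesion centre (default
#'   34 mm lateral of the midline on `side`, at mid-height: an MCA-territory
#'   stand-in that accommodates every default sphere size).
#' @return an object of class `grid_result`: a data.frame `rows` with
#'   columns backend, true_cc, f, measured_cc, ratio_pct, seed, error; plus
#'   the grid specification used.
#' @export
run_grid <- function(spec, side = "right", upper_hu = -1.5,
                     lesion_center = lesion_center_default(side)) {
  stopifnot(inherits(spec, "grid_spec"))
  cells <- expand.grid(f = spec$reductions,
                       true_cc = spec$volumes_cc,
                       backend = spec$backends,
                       replicate = seq_len(spec$replicates),
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  substrate <- NULL       # control phantom shared within a replicate
  substrate_rep <- NA_integer_
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rep_seed <- spec$seed + cell$replicate
    res <- tryCatch({
      if (!identical(substrate_rep, cell$replicate)) {
        ph_spec <- spec$phantom
        ph_spec$seed <- rep_seed
        substrate <- make_head_phantom(ph_spec)
        substrate_rep <- cell$replicate
      }
      les <- lesion_spec("sphere",
                         center = lesion_center,
                         target_volume = cell$true_cc,
                         density_reduction = cell$f, side = side)
      truth <- insert_lesion(substrate, les)
      rep <- run_pipeline(truth$image, backend = cell$backend,
                          side_ipsi = side, upper_hu = upper_hu)
      data.frame(backend = cell$backend, true_cc = cell$true_cc,
                 f = cell$f, replicate = cell$replicate,
                 measured_cc = rep$infarct_cc,
                 ratio_pct = 100 * rep$infarct_cc / cell$true_cc,
                 seed = rep_seed, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(backend = cell$backend, true_cc = cell$true_cc,
                 f = cell$f, replicate = cell$replicate,
                 measured_cc = NA_real_, ratio_pct = NA_real_,
                 seed = rep_seed, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  rows <- do.call(rbind, rows)
  if (all(!is.na(rows$error)))
    stop("run_grid: every grid cell failed; first error: ", rows$error[1])
  structure(list(rows = rows, spec = spec), class = "grid_result")
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation with the preconditions of the recovery study:
#' equal lengths of at least 3 and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("pearson_r: x and y must be numeric vectors of equal length")
  if (length(x) < 3)
    stop("pearson_r: need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Recovery-ratio correlations per backend and density reduction
#'
#' Pearson r between measured and true volumes across lesion sizes, one
#' value per (backend, reduction); replicate means are used when
#' `replicates > 1`.
#'
#' @param result a `grid_result`.
#' @return data.frame with columns backend, f, r, n_sizes.
#' @export
grid_correlations <- function(result) {
  stopifnot(inherits(result, "grid_result"))
  rows <- result$rows[is.na(result$rows$error), ]
  agg <- stats::aggregate(measured_cc ~ backend + f + true_cc, rows, mean)
  combos <- unique(agg[, c("backend", "f")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- agg[agg$backend == combos$backend[i] & agg$f == combos$f[i], ]
    r <- if (nrow(sub) >= 3 && stats::sd(sub$true_cc) > 0 &&
             stats::sd(sub$measured_cc) > 0)
      pearson_r(sub$true_cc, sub$measured_cc) else NA_real_
    data.frame(backend = combos$backend[i], f = combos$f[i],
               r = r, n_sizes = nrow(sub), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Recovery-ratio table (volumes x reductions, per backend)
#'
#' Lays the grid out as the classic recovery table: one row per true volume
#' (largest first), one column per density reduction (largest first), cell
#' values `100 * measured / true` in percent. Missing cells are emitted as
#' NA with a warning.
#'
#' @param result a `grid_result`.
#' @param path optional CSV output path (one file per backend gets a
#'   `_<backend>` suffix); correlations are appended as extra rows.
#' @return named list of matrices, one per backend.
#' @export
summarize_ratios <- function(result, path = NULL) {
  stopifnot(inherits(result, "grid_result"))
  spec <- result$spec
  vols <- sort(spec$volumes_cc, decreasing = TRUE)
  reds <- sort(spec$reductions, decreasing = TRUE)
  rows <- result$rows
  cors <- grid_correlations(result)
  out <- list()
  for (bk in spec$backends) {
    tab <- matrix(NA_real_, length(vols), length(reds),
                  dimnames = list(sprintf("%gcc", vols),
                                  sprintf("%g%%", 100 * reds)))
    for (i in seq_along(vols)) for (j in seq_along(reds)) {
      sub <- rows[rows$backend == bk & rows$true_cc == vols[i] &
                    rows$f == reds[j] & is.na(rows$error), ]
      if (nrow(sub) > 0) tab[i, j] <- mean(sub$ratio_pct)
    }
    if (anyNA(tab))
      warning(sprintf("summarize_ratios: missing cells for backend %s", bk))
    out[[bk]] <- tab
    if (!is.null(path)) {
      stem <- sub("\\.csv$", "", path)
      df <- as.data.frame(tab)
      df <- cbind(volume = rownames(tab), df)
      rc <- cors[cors$backend == bk, ]
      extra <- data.frame(volume = sprintf("pearson_r_f_%g", rc$f))
      for (cn in colnames(tab)) extra[[cn]] <- NA_real_
      # correlations are per reduction; place each under its column
      for (k in seq_len(nrow(rc))) {
        col <- sprintf("%g%%", 100 * rc$f[k])
        if (col %in% colnames(tab)) extra[k, col] <- rc$r[k]
      }
      utils::write.csv(rbind(df, extra), sprintf("%s_%s.csv", stem, bk),
                       row.names = FALSE)
    }
  }
  out
}
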