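#' Difference map: input minus restored, on the brain mask
#'
#' The voxelwise HU correction applied by the inhomogeneity correction.
#' Baseline artifacts (cupping) appear symmetrically; an acute infarct
#' appears as a focal negative region in one hemisphere.
#'
#' @param input a [ct_volume].
#' @param result an `iic_result` computed on the same grid.
#' @param mask the [brain_mask] used for the correction.
#' @return an object of class `difference_map`: list with `values` (HU
#'   array, zero off-mask), `mask`, `spacing`.
#' @export
difference_map <- function(input, result, mask) {
  stopifnot(inherits(input, "ct_volume"), inherits(result, "iic_result"),
            inherits(mask, "brain_mask"))
  if (!identical(dim(input$data), dim(result$restored$data)) ||
      !identical(dim(input$data), dim(mask$mask)))
    stop("difference_map: grids do not match")
  values <- input$data - result$restored$data
  values[!mask$mask] <- 0
  structure(list(values = values, mask = mask, spacing = input$spacing),
            class = "difference_map")
}

#' Split a brain mask into hemispheres about the left-right midline
#'
#' The midline is the brain-mask centroid along the left--right grid axis,
#' rounded to a voxel index; the two hemispheres are the half-grids strictly
#' on either side of that plane, intersected with the mask. The midline
#' plane itself is assigned to neither hemisphere, which keeps the partition
#' unbiased.
#'
#' @param mask a [brain_mask].
#' @param vol the [ct_volume] the mask lives on (provides axis codes).
#' @param side_ipsi `"left"`, `"right"` or `"auto"` (resolution of `"auto"`
#'   is deferred to [estimate_infarct_volume]).
#' @return an object of class `hemisphere_split`: logical arrays `ipsi_mask`
#'   and `contra_mask`, `midline_index`, `side_ipsi`, and the voxel masks of
#'   the anatomical left/right halves.
#' @export
split_hemispheres <- function(mask, vol, side_ipsi = c("auto", "left", "right")) {
  side_ipsi <- match.arg(side_ipsi)
  stopifnot(inherits(mask, "brain_mask"), inherits(vol, "ct_volume"))
  ax <- lr_axis(vol)
  d <- dim(mask$mask)
  counts <- apply(mask$mask, ax, sum)
  if (sum(counts) == 0) stop("split_hemispheres: empty mask")
  centroid <- sum(seq_len(d[ax]) * counts) / sum(counts)
  midline <- round(centroid)
  idx_along <- slice.index(mask$mask, ax)
  if (abs(centroid - midline) <= 0.25) {
    # centroid on a voxel plane (odd mask extent): the plane belongs to
    # neither hemisphere, keeping the partition unbiased
    hi <- idx_along > midline & mask$mask   # increasing-index side
    lo <- idx_along < midline & mask$mask
  } else {
    # centroid between voxel planes (even extent): split at the gap
    hi <- idx_along >= ceiling(centroid) & mask$mask
    lo <- idx_along <= floor(centroid) & mask$mask
  }
  # polarity: does increasing index run toward the right?
  right_is_hi <- vol$axis_codes[ax] == "R"
  right_mask <- if (right_is_hi) hi else lo
  left_mask <- if (right_is_hi) lo else hi
  if (!any(right_mask) || !any(left_mask))
    stop("split_hemispheres: a hemisphere is empty")
  ipsi <- switch(side_ipsi, right = right_mask, left = left_mask, auto = NULL)
  contra <- switch(side_ipsi, right = left_mask, left = right_mask, auto = NULL)
  structure(list(ipsi_mask = ipsi, contra_mask = contra,
                 left_mask = left_mask, right_mask = right_mask,
                 midline_index = midline, side_ipsi = side_ipsi),
            class = "hemisphere_split")
}

#' Threshold a difference map at an upper HU value
#'
#' Selects on-mask voxels whose difference-map value is less than or equal
#' to `upper_hu` (closed at the threshold). The default -1.5 HU suppresses
#' residual inhomogeneity artifacts while keeping infarct-driven
#' corrections.
#'
#' @param dmap a [difference_map].
#' @param upper_hu negative HU threshold (default -1.5).
#' @return logical 3D array of selected voxels.
#' @export
threshold_map <- function(dmap, upper_hu = -1.5) {
  stopifnot(inherits(dmap, "difference_map"))
  if (!(is.numeric(upper_hu) && length(upper_hu) == 1 && upper_hu < 0))
    stop("threshold_map: upper_hu must be a negative HU value")
  dmap$values <= upper_hu & dmap$mask$mask
}

#' Volume of a voxel selection in cc
#'
#' @param selection logical 3D array.
#' @param spacing mm spacing triple.
#' @return volume in cc (`count * dx*dy*dz / 1000`).
#' @export
masked_volume_cc <- function(selection, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("masked_volume_cc: spacing must be positive")
  sum(selection) * voxel_mm3(spacing) / 1000
}

#' Estimate the infarct volume from a corrected volume
#'
#' Composes the volumetric stage of the pipeline: difference map (input
#' minus restored), hemisphere split about the brain-mask midline, the
#' upper -1.5 HU threshold, and the contralateral-volume subtraction that
#' normalises for baseline inhomogeneity artifacts. With
#' `side_ipsi = "auto"`, the ipsilateral side is the hemisphere with the
#' larger thresholded volume. The estimate is signed: a negative value under
#' a forced side is reported with a warning, not clamped, since the
#' lesion-free baseline is itself a diagnostic.
#'
#' @param input a [ct_volume].
#' @param mask a [brain_mask].
#' @param result an `iic_result` for `input` on `mask`.
#' @param side_ipsi `"auto"` (default), `"left"` or `"right"`.
#' @param upper_hu threshold, default -1.5 HU.
#' @return an object of class `volume_report`: `vol_ipsi_cc`,
#'   `vol_contra_cc`, `infarct_cc` (= ipsi - contra, signed), `threshold_hu`,
#'   `side_ipsi`, `backend`, `warnings`.
#' @export
estimate_infarct_volume <- function(input, mask, result,
                                    side_ipsi = c("auto", "left", "right"),
                                    upper_hu = -1.5) {
  side_ipsi <- match.arg(side_ipsi)
  dmap <- difference_map(input, result, mask)
  split <- split_hemispheres(mask, input, "auto")
  sel <- threshold_map(dmap, upper_hu)
  v_left <- masked_volume_cc(sel & split$left_mask, input$spacing)
  v_right <- masked_volume_cc(sel & split$right_mask, input$spacing)
  if (side_ipsi == "auto")
    side_ipsi <- if (v_right >= v_left) "right" else "left"
  vol_ipsi <- if (side_ipsi == "right") v_right else v_left
  vol_contra <- if (side_ipsi == "right") v_left else v_right
  infarct <- vol_ipsi - vol_contra
  warnings <- mask$warnings
  if (infarct < 0)
    warnings <- c(warnings,
                  sprintf("negative infarct estimate (%.2f cc) on forced side %s",
                          infarct, side_ipsi))
  structure(list(vol_ipsi_cc = vol_ipsi, vol_contra_cc = vol_contra,
                 infarct_cc = infarct, threshold_hu = upper_hu,
                 side_ipsi = side_ipsi, backend = result$backend,
                 warnings = warnings),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("<volume_report> backend %s, ipsi %s\n", x$backend, x$side_ipsi))
  cat(sprintf("  ipsi %.2f cc - contra %.2f cc = infarct %.2f cc (threshold %.1f HU)\n",
              x$vol_ipsi_cc, x$vol_contra_cc, x$infarct_cc, x$threshold_hu))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full volumetry pipeline on a CT volume
#'
#' Brain extraction, inhomogeneity correction with the chosen backend, and
#' infarct volume estimation, in one call.
#'
#' @param vol a [ct_volume].
#' @param backend `"em_seg"` or `"hist_sharpen"`.
#' @param params optional [iic_params]; defaults to the backend defaults.
#' @param side_ipsi `"auto"`, `"left"` or `"right"`.
#' @param upper_hu difference-map threshold, default -1.5 HU.
#' @param hu_high skull threshold for brain extraction, default 50 HU.
#' @return a `volume_report` (with the `iic_result` and `brain_mask`
#'   attached as attributes `"iic"` and `"mask"`).
#' @export
run_pipeline <- function(vol, backend = c("em_seg", "hist_sharpen"),
                         params = NULL, side_ipsi = "auto",
                         upper_hu = -1.5, hu_high = 50) {
  backend <- match.arg(backend)
  if (is.null(params)) params <- iic_params(backend)
  mask <- extract_brain(vol, hu_high = hu_high)
  corr <- switch(backend,
                 em_seg = correct_em_seg(vol, mask, params),
                 hist_sharpen = correct_hist_sharpen(vol, mask, params))
  rep <- estimate_infarct_volume(vol, mask, corr, side_ipsi, upper_hu)
  attr(rep, "iic") <- corr
  attr(rep, "mask") <- mask
  rep
}
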