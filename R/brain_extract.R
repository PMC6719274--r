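#' Extract the brain from a head CT by HU thresholding
#'
#' Skull and bone are removed by an upper Hounsfield threshold (50 HU by
#' default; bone is far denser than brain) and air/CSF-dominant voxels by a
#' lower threshold (0 HU). The candidate set is then cleaned by conventional
#' threshold-morphology: erosion (to cut thin scalp/skull bridges), selection
#' of the largest 26-connected component, dilation back, intersection with
#' the candidate set, and slice-wise hole filling (axial 2D filling, because
#' 5 mm slices make 3D hole filling unreliable on anisotropic grids).
#' Finally the largest connected component is kept again so the mask is a
#' single 26-connected component.
#'
#' @param vol a [ct_volume].
#' @param hu_low lower HU bound (inclusive), default 0.
#' @param hu_high upper HU bound (exclusive), default 50 -- the skull
#'   threshold.
#' @param erosion_mm erosion radius in mm (default 2).
#' @param dilation_mm dilation radius in mm (default 2).
#' @return an object of class `brain_mask`: list with logical array `mask`,
#'   `voxel_count`, `volume_cc`, `spacing`, and `warnings` (character).
#' @export
extract_brain <- function(vol, hu_low = 0, hu_high = 50,
                          erosion_mm = 2, dilation_mm = 2) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!(hu_low < hu_high))
    stop("extract_brain: hu_low must be < hu_high")
  cand <- vol$data >= hu_low & vol$data < hu_high
  if (!any(cand))
    stop("extract_brain: no voxels in the HU window; nothing to extract")
  core <- erode_mm(cand, erosion_mm, vol$spacing)
  if (!any(core))
    stop("extract_brain: candidate set vanished under erosion")
  core <- largest_component_26(core)
  mask <- dilate_mm(core, dilation_mm, vol$spacing) & cand
  mask <- fill_holes_slicewise(mask)
  # hole filling may re-admit >threshold voxels inside; keep the HU contract
  mask <- mask & (vol$data < hu_high)
  mask <- largest_component_26(mask)
  warnings <- character(0)
  vcc <- sum(mask) * voxel_mm3(vol$spacing) / 1000
  if (vcc < 100)
    warnings <- sprintf("extracted brain is only %.1f cc (< 100 cc) on this grid", vcc)
  brain_mask(mask, vol$spacing, warnings)
}

#' Construct a brain-mask object
#' @param mask logical 3D array.
#' @param spacing mm spacing triple.
#' @param warnings character vector of diagnostics.
#' @return an object of class `brain_mask`.
#' @export
brain_mask <- function(mask, spacing, warnings = character(0)) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  n <- sum(mask)
  structure(list(mask = mask, voxel_count = n,
                 volume_cc = n * voxel_mm3(spacing) / 1000,
                 spacing = as.numeric(spacing), warnings = warnings),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d voxels, %.1f cc\n", x$voxel_count, x$volume_cc))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
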