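#' In-memory CT volume with Hounsfield-unit semantics
#'
#' `ct_volume` is the image currency of the package: a 3D numeric array of
#' Hounsfield units (HU) plus the voxel spacing in mm and anatomical axis
#' labels. All pipeline stages (brain extraction, inhomogeneity correction,
#' volumetry) operate on this object. Volumes are kept in a canonical
#' orientation in which the first grid axis is the left--right axis, so that
#' the hemisphere split is a fixed-axis operation.
#'
#' @param data 3D numeric array of HU values. All values must be finite and
#'   lie within the physically meaningful CT range \[-1100, 3200\] HU
#'   (air is about -1000 HU, dense bone below about 3100 HU).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm; all
#'   strictly positive.
#' @param axis_codes character length-3 giving the anatomical direction of
#'   increasing index along each grid axis, one letter per axis from
#'   R/L (right/left), A/P (anterior/posterior), S/I (superior/inferior).
#'   Exactly one axis must be the left--right axis. Default `c("R","A","S")`.
#' @param origin numeric length-3 mm offset of the first voxel (informational;
#'   carried through I/O, not used by the algorithms).
#'
#' @return An object of class `ct_volume` with fields `data`, `spacing`,
#'   `axis_codes`, `origin`.
#' @export
ct_volume <- function(data, spacing, axis_codes = c("R", "A", "S"),
                      origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("ct_volume: `data` must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("ct_volume: all HU values must be finite")
  rng <- range(data)
  if (rng[1] < -1100 || rng[2] > 3200)
    stop(sprintf("ct_volume: HU values out of range [-1100, 3200] (got %.1f..%.1f)",
                 rng[1], rng[2]))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: `spacing` must be 3 strictly positive mm values")
  axis_codes <- toupper(as.character(axis_codes))
  valid <- c("R", "L", "A", "P", "S", "I")
  if (length(axis_codes) != 3L || !all(axis_codes %in% valid))
    stop("ct_volume: `axis_codes` must be 3 letters from R,L,A,P,S,I")
  if (sum(axis_codes %in% c("R", "L")) != 1L)
    stop("ct_volume: exactly one grid axis must be the left-right axis")
  structure(list(data = data, spacing = spacing, axis_codes = axis_codes,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm [%s]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              paste(x$axis_codes, collapse = "")))
  cat(sprintf("  HU range %.1f .. %.1f\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Index of the left-right grid axis
#' @param vol a `ct_volume`.
#' @return integer axis index (1..3).
#' @keywords internal
lr_axis <- function(vol) {
  which(vol$axis_codes %in% c("R", "L"))
}

#' Volume of one voxel in mm^3
#' @param spacing mm spacing triple.
#' @keywords internal
voxel_mm3 <- function(spacing) prod(spacing)

#' Reflect a volume about its left-right axis
#'
#' Reverses the data along the left--right grid axis while keeping the axis
#' code, i.e. the anatomy is mirrored (a right-sided lesion becomes
#' left-sided).
#'
#' @param vol a `ct_volume`.
#' @return the mirrored `ct_volume`.
#' @export
reflect_lr <- function(vol) {
  ax <- lr_axis(vol)
  idx <- rev(seq_len(dim(vol$data)[ax]))
  args <- list(vol$data, TRUE, TRUE, TRUE)
  args[[ax + 1L]] <- idx
  args$drop <- FALSE
  vol$data <- do.call(`[`, args)
  vol
}
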