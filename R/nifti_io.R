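#' Read a 3D head-CT volume from NIfTI-1
#'
#' Reads a scalar 3D NIfTI-1 image (`.nii` or `.nii.gz`), applies any stored
#' intensity scaling (`scl_slope`/`scl_inter`) so values are in Hounsfield
#' units, and reorients the grid to the canonical RAS orientation (first axis
#' left--right, increasing toward the patient's right). Axis codes are derived
#' from the image's qform/sform orientation metadata.
#'
#' @param path path to a NIfTI-1 file.
#' @return a [ct_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read_volume: file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    # degenerate singleton 4th dimension is tolerated
    img <- RNifti::asNifti(array(as.numeric(img), dim = d[1:3]), reference = img)
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop(sprintf("read_volume: %s is not a scalar 3D image (dim = %s)",
                 path, paste(d, collapse = "x")))
  hdr <- RNifti::niftiHeader(img)
  if (hdr$qform_code == 0L && hdr$sform_code == 0L)
    stop(sprintf("read_volume: %s has no orientation metadata (qform and sform codes are both zero)",
                 path))
  RNifti::orientation(img) <- "RAS"
  data <- array(as.numeric(img), dim = dim(img))
  spacing <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  ct_volume(data, spacing = spacing, axis_codes = c("R", "A", "S"),
            origin = xf[1:3, 4])
}

#' Write a CT volume to NIfTI-1
#'
#' Stores the volume as 32-bit float NIfTI-1 (difference maps need sub-HU
#' precision), with spacing in the qform and the canonical RAS orientation.
#' `read_volume(write_volume(v))` reproduces the data within float32
#' precision and the spacing exactly.
#'
#' @param vol a [ct_volume].
#' @param path output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @param datatype NIfTI storage type, default `"float"`; use `"uint8"` for
#'   masks.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("write_volume: directory does not exist: %s", dirname(path)))
  if (!identical(vol$axis_codes, c("R", "A", "S")))
    stop("write_volume: volume must be in canonical RAS orientation")
  a <- vol$data
  RNifti::pixdim(a) <- vol$spacing
  img <- RNifti::asNifti(a, datatype = datatype)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask as NIfTI-1 uint8
#'
#' @param mask logical 3D array.
#' @param like a [ct_volume] providing spacing/orientation.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, like, path) {
  stopifnot(is.logical(mask), identical(dim(mask), dim(like$data)))
  m <- array(as.numeric(mask), dim = dim(mask))
  write_volume(ct_volume(m, like$spacing, like$axis_codes, like$origin),
               path, datatype = "uint8")
}
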