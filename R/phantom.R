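#' Specification of a synthetic head-CT phantom
#'
#' Describes an ellipsoidal "brain" of uniform parenchymal density inside a
#' high-density skull shell surrounded by air, with a smooth left--right
#' symmetric "cupping" depression (the dominant beam-hardening artifact in
#' head CT) added inside the brain, and i.i.d. Gaussian noise everywhere.
#' The defaults emulate a clinical head protocol: 24 cm field of view and
#' 5 mm slices, at a 128 matrix (identical physical geometry to the clinical
#' 512 matrix; volumes in cc are unaffected by the matrix choice).
#'
#' Phantom coordinates are mm offsets from the grid centre; the brain is
#' centred on the grid, so the mid-sagittal plane is the x = 0 plane and
#' positive x is the patient's right (RAS orientation).
#'
#' @param grid integer triple, grid size in voxels (default 128 x 128 x 30).
#' @param spacing mm triple (default 1.875, 1.875, 5.0).
#' @param hu_air HU of air background (default -1000).
#' @param hu_brain HU of brain parenchyma (default 34).
#' @param hu_skull HU of the skull shell (default 800).
#' @param brain_semiaxes mm semi-axes of the ellipsoidal brain
#'   (default 70, 85, 62; about 1.5 litres).
#' @param skull_thickness mm thickness of the skull shell (default 6).
#' @param cupping_amplitude HU >= 0; depth of the central cupping depression
#'   (most negative at the brain centroid, zero at the brain edge; default 3).
#' @param noise_sigma HU >= 0; standard deviation of additive Gaussian noise
#'   (default 2).
#' @param seed integer RNG seed for the noise (default 1).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128L, 128L, 30L),
                         spacing = c(1.875, 1.875, 5.0),
                         hu_air = -1000, hu_brain = 34, hu_skull = 800,
                         brain_semiaxes = c(70, 85, 62),
                         skull_thickness = 6,
                         cupping_amplitude = 3, noise_sigma = 2,
                         seed = 1L) {
  grid <- as.integer(grid); spacing <- as.numeric(spacing)
  stopifnot(length(grid) == 3, all(grid > 0),
            length(spacing) == 3, all(spacing > 0),
            length(brain_semiaxes) == 3, all(brain_semiaxes > 0))
  if (!(hu_skull > 50 && 50 > hu_brain && hu_brain > hu_air))
    stop("phantom_spec: need hu_skull > 50 > hu_brain > hu_air")
  if (cupping_amplitude < 0 || noise_sigma < 0)
    stop("phantom_spec: cupping_amplitude and noise_sigma must be >= 0")
  extent <- grid * spacing
  if (any(2 * (brain_semiaxes + skull_thickness) >= extent))
    stop("phantom_spec: brain plus skull shell does not fit inside the grid")
  structure(list(grid = grid, spacing = spacing, hu_air = hu_air,
                 hu_brain = hu_brain, hu_skull = hu_skull,
                 brain_semiaxes = as.numeric(brain_semiaxes),
                 skull_thickness = skull_thickness,
                 cupping_amplitude = cupping_amplitude,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Specification of a synthetic hypodense lesion
#'
#' A lesion is a region of the phantom brain whose clean tissue density is
#' reduced by a fraction `density_reduction` (f = 0.10 on 34 HU tissue gives
#' a -3.4 HU lesion, the "approximately 3 HU" regime in which early ischemic
#' change is not visually evident). Spheres of a prescribed true volume are
#' the standard shape; a lateral wedge approximating a vascular territory is
#' also available.
#'
#' @param shape `"sphere"` or `"territory_wedge"`.
#' @param center mm coordinates of the lesion centre relative to the grid
#'   centre (sphere only); must place the lesion entirely inside the brain of
#'   the stated side.
#' @param target_volume true sphere volume in cc (sphere only).
#' @param density_reduction fraction f in (0, 0.5].
#' @param side `"left"` or `"right"`.
#' @param wedge_halfangle_deg azimuthal half-angle of the wedge about the
#'   lateral direction, degrees (wedge only; default 40).
#' @param wedge_rho_range fraction of the brain ellipsoid radius spanned by
#'   the wedge (wedge only; default c(0.35, 0.95)).
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("sphere", "territory_wedge"),
                        center = c(34, 0, 0), target_volume = 45,
                        density_reduction = 0.20,
                        side = c("right", "left"),
                        wedge_halfangle_deg = 40,
                        wedge_rho_range = c(0.35, 0.95)) {
  shape <- match.arg(shape)
  side <- match.arg(side)
  f <- density_reduction
  if (!(is.numeric(f) && length(f) == 1 && f > 0 && f <= 0.5))
    stop("lesion_spec: density_reduction must lie in (0, 0.5]")
  if (shape == "sphere" && target_volume <= 0)
    stop("lesion_spec: target_volume must be > 0")
  structure(list(shape = shape, center = as.numeric(center),
                 target_volume = target_volume, density_reduction = f,
                 side = side, wedge_halfangle_deg = wedge_halfangle_deg,
                 wedge_rho_range = as.numeric(wedge_rho_range)),
            class = "lesion_spec")
}

#' Radius of a sphere of given volume
#'
#' r = (3 * 1000 * v / (4 pi))^(1/3) mm for a volume in cc.
#'
#' @param v_cc volume in cc (> 0).
#' @return radius in mm.
#' @export
sphere_radius_from_volume <- function(v_cc) {
  if (!is.numeric(v_cc) || any(v_cc <= 0))
    stop("sphere_radius_from_volume: volume must be > 0")
  (3 * 1000 * v_cc / (4 * pi))^(1 / 3)
}

# mm coordinates of voxel centres along each axis, origin at the grid centre.
phantom_coords <- function(grid, spacing) {
  lapply(1:3, function(ax) (seq_len(grid[ax]) - (grid[ax] + 1) / 2) * spacing[ax])
}

# Squared ellipsoidal radius (rho^2) of every voxel centre w.r.t. semiaxes.
rho2_grid <- function(grid, spacing, semiaxes) {
  co <- phantom_coords(grid, spacing)
  x2 <- (co[[1]] / semiaxes[1])^2
  y2 <- (co[[2]] / semiaxes[2])^2
  z2 <- (co[[3]] / semiaxes[3])^2
  outer(outer(x2, y2, `+`), z2, `+`)
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a synthetic head-CT phantom
#'
#' Builds the lesion-free phantom: uniform ellipsoidal brain inside a skull
#' shell inside air, an additive radially quadratic cupping field inside the
#' brain (value `-cupping_amplitude * (1 - rho^2)`, i.e. most negative at the
#' brain centroid and zero at the brain edge), and seeded i.i.d. Gaussian
#' noise everywhere. The returned truth object records the ground-truth brain
#' mask, the (empty) lesion mask, and the clean (noise- and cupping-free)
#' tissue image, against which restoration accuracy can be measured.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom_truth`: list with `image`
#'   ([ct_volume]), `brain_mask_true`, `lesion_mask_true` (logical arrays),
#'   `lesion_volume_true` (cc), `lesion_delta_hu` (HU), `clean` and `cupping`
#'   (arrays), and `spec`.
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid; sp <- spec$spacing
  rho2 <- rho2_grid(g, sp, spec$brain_semiaxes)
  brain <- rho2 <= 1
  if (!any(brain)) stop("make_head_phantom: brain does not cover any voxel")
  rho2_out <- rho2_grid(g, sp, spec$brain_semiaxes + spec$skull_thickness)
  skull <- (rho2_out <= 1) & !brain
  clean <- array(spec$hu_air, dim = g)
  clean[skull] <- spec$hu_skull
  clean[brain] <- spec$hu_brain
  cupping <- array(0, dim = g)
  cupping[brain] <- -spec$cupping_amplitude * (1 - rho2[brain])
  noise <- with_seed(spec$seed,
                     array(stats::rnorm(prod(g), 0, spec$noise_sigma), dim = g))
  img <- clean + cupping + if (spec$noise_sigma > 0) noise else 0
  structure(list(image = ct_volume(img, sp),
                 brain_mask_true = brain,
                 lesion_mask_true = array(FALSE, dim = g),
                 lesion_volume_true = 0,
                 lesion_delta_hu = 0,
                 clean = clean, cupping = cupping, spec = spec),
            class = "phantom_truth")
}

# Voxel mask of a lesion geometry; voxel-centre inclusion rule (no
# partial-volume anti-aliasing), so the true volume is an exact voxel count.
lesion_mask_for <- function(truth, lesion) {
  spec <- truth$spec
  g <- spec$grid; sp <- spec$spacing
  co <- phantom_coords(g, sp)
  if (lesion$shape == "sphere") {
    r <- sphere_radius_from_volume(lesion$target_volume)
    cx <- lesion$center
    dx2 <- (co[[1]] - cx[1])^2
    dy2 <- (co[[2]] - cx[2])^2
    dz2 <- (co[[3]] - cx[3])^2
    outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
  } else {
    rho2 <- rho2_grid(g, sp, spec$brain_semiaxes)
    rho <- sqrt(rho2)
    nx <- g[1]; ny <- g[2]; nz <- g[3]
    x <- array(rep(co[[1]], times = ny * nz), dim = g)
    y <- array(rep(rep(co[[2]], each = nx), times = nz), dim = g)
    lateral <- if (lesion$side == "right") 0 else pi
    az <- atan2(y, if (lesion$side == "right") x else -x)
    half <- lesion$wedge_halfangle_deg * pi / 180
    m <- rho >= lesion$wedge_rho_range[1] & rho <= lesion$wedge_rho_range[2] &
      abs(az) <= half
    side_ok <- if (lesion$side == "right") x > 0 else x < 0
    m & side_ok
  }
}

# TRUE where voxel-centre x coordinate is on the stated side of the midline.
side_half_grid <- function(truth, side) {
  co <- phantom_coords(truth$spec$grid, truth$spec$spacing)
  x <- co[[1]]
  keep <- if (side == "right") x > 0 else x < 0
  array(rep(keep, times = prod(truth$spec$grid[2:3])), dim = truth$spec$grid)
}

# Shared insertion: subtract f * hu_brain from clean tissue inside the mask,
# rebuild the noisy image with the phantom's own seeded noise realisation.
insert_mask_lesion <- function(truth, lesion, mask) {
  spec <- truth$spec
  if (!any(mask)) stop("insert_lesion: lesion geometry covers no voxel centre")
  if (any(mask & !truth$brain_mask_true))
    stop("insert_lesion: lesion exits the brain")
  if (any(mask & !side_half_grid(truth, lesion$side)))
    stop(sprintf("insert_lesion: lesion crosses the midline (side = %s)", lesion$side))
  f <- lesion$density_reduction
  delta <- f * spec$hu_brain
  truth$clean[mask] <- truth$clean[mask] - delta
  img <- truth$image$data
  img[mask] <- img[mask] - delta
  truth$image$data <- img
  truth$lesion_mask_true <- truth$lesion_mask_true | mask
  truth$lesion_volume_true <-
    sum(truth$lesion_mask_true) * voxel_mm3(spec$spacing) / 1000
  truth$lesion_delta_hu <- delta
  truth
}

#' Insert a spherical hypodense lesion into a phantom
#'
#' Voxels whose centres fall inside the analytic sphere have their clean
#' tissue value reduced by `density_reduction * hu_brain` (equivalently,
#' tissue HU is multiplied by 1 - f relative to the noiseless, cupping-free
#' value). The recorded true volume is the voxel count times the voxel
#' volume.
#'
#' @param truth a [make_head_phantom] result.
#' @param lesion a [lesion_spec] with `shape = "sphere"`.
#' @return the updated `phantom_truth`.
#' @export
insert_lesion <- function(truth, lesion) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(lesion, "lesion_spec"))
  if (lesion$shape != "sphere")
    stop("insert_lesion: lesion shape must be 'sphere' (see insert_territory_lesion)")
  insert_mask_lesion(truth, lesion, lesion_mask_for(truth, lesion))
}

#' Insert a territory-like wedge lesion into a phantom
#'
#' The wedge is an azimuthal sector of the brain ellipsoid about the vertical
#' axis, opening laterally on the stated side -- a stand-in for a vascular
#' (MCA-like) territory. Density reduction is applied exactly as for spheres.
#'
#' @param truth a [make_head_phantom] result.
#' @param lesion a [lesion_spec] with `shape = "territory_wedge"`.
#' @return the updated `phantom_truth`.
#' @export
insert_territory_lesion <- function(truth, lesion) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(lesion, "lesion_spec"))
  if (lesion$shape != "territory_wedge")
    stop("insert_territory_lesion: lesion shape must be 'territory_wedge'")
  insert_mask_lesion(truth, lesion, lesion_mask_for(truth, lesion))
}

#' Serialise a phantom or lesion spec to YAML
#' @param spec a [phantom_spec] or [lesion_spec].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spec_yaml <- function(spec, path) {
  obj <- unclass(spec)
  obj$.class <- class(spec)[1]
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a phantom or lesion spec from YAML
#' @param path YAML file written by [write_spec_yaml] (or hand-written with
#'   a `.class` field of `phantom_spec` or `lesion_spec`).
#' @return the reconstructed spec object.
#' @export
read_spec_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.class
  obj$.class <- NULL
  ctor <- switch(cls,
                 phantom_spec = phantom_spec,
                 lesion_spec = lesion_spec,
                 stop("read_spec_yaml: unknown .class: ", cls))
  do.call(ctor, obj)
}
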