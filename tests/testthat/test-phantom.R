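test_that("unperturbed phantom brain is exactly uniform", {
  truth <- make_head_phantom(small_spec(noise_sigma = 0, cupping_amplitude = 0))
  expect_true(all(truth$image$data[truth$brain_mask_true] == 34))
  expect_true(all(truth$image$data[!truth$brain_mask_true] %in% c(-1000, 800)))
  expect_false(any(truth$lesion_mask_true))
  expect_equal(truth$lesion_volume_true, 0)
})

test_that("cupping field has the prescribed endpoints", {
  # odd grid so a voxel sits exactly at the brain centroid
  sp <- phantom_spec(grid = c(65L, 65L, 29L), spacing = c(3.75, 3.75, 5),
                     brain_semiaxes = c(60, 70, 55),
                     noise_sigma = 0, cupping_amplitude = 3)
  truth <- make_head_phantom(sp)
  expect_equal(truth$image$data[33, 33, 15], 34 - 3)
  # the outermost brain voxel carries (almost) no cupping
  rho2 <- ctiic:::rho2_grid(sp$grid, sp$spacing, sp$brain_semiaxes)
  edge <- which(truth$brain_mask_true & rho2 == max(rho2[truth$brain_mask_true]))
  expect_true(all(truth$image$data[edge] >= 34 - 0.1))
  expect_true(all(truth$cupping[truth$brain_mask_true] <= 0))
})

test_that("phantom generation is seed-deterministic", {
  a <- make_head_phantom(small_spec(seed = 7))
  b <- make_head_phantom(small_spec(seed = 7))
  expect_identical(a$image$data, b$image$data)
  c <- make_head_phantom(small_spec(seed = 8))
  expect_false(identical(a$image$data, c$image$data))
})

test_that("sphere radius follows the closed form", {
  expect_equal(sphere_radius_from_volume(17), 15.95, tolerance = 1e-3)
  expect_equal(sphere_radius_from_volume(45), 22.08, tolerance = 1e-3)
  expect_equal(sphere_radius_from_volume(122), 30.77, tolerance = 1e-3)
  expect_error(sphere_radius_from_volume(0), "> 0")
  expect_error(sphere_radius_from_volume(-5), "> 0")
})

test_that("spherical lesion insertion applies the fractional density drop", {
  truth <- make_head_phantom(small_spec(noise_sigma = 0, cupping_amplitude = 0))
  les <- small_lesion(f = 0.10)
  out <- insert_lesion(truth, les)
  expect_equal(out$lesion_delta_hu, 3.4)   # 10% of 34 HU, the ~3 HU regime
  expect_true(all(out$image$data[out$lesion_mask_true] == 34 - 3.4))
  expect_true(all(out$clean[out$lesion_mask_true] == 34 * 0.9))
  untouched <- truth$brain_mask_true & !out$lesion_mask_true
  expect_true(all(out$image$data[untouched] == 34))
  # degenerate input: zero reduction is rejected at spec construction
  expect_error(lesion_spec("sphere", density_reduction = 0), "0, 0.5")
})

test_that("voxelised lesion volume matches a brute-force sphere count", {
  truth <- make_head_phantom(phantom_spec(seed = 3))
  les <- lesion_spec("sphere", center = c(34, 0, 0), target_volume = 45,
                     density_reduction = 0.2, side = "right")
  out <- insert_lesion(truth, les)
  # independent oracle: count voxel centres inside the analytic sphere
  sp <- truth$spec
  co <- lapply(1:3, function(ax)
    (seq_len(sp$grid[ax]) - (sp$grid[ax] + 1) / 2) * sp$spacing[ax])
  r <- (3000 * 45 / (4 * pi))^(1 / 3)
  inside <- outer(outer((co[[1]] - 34)^2, co[[2]]^2, `+`), co[[3]]^2, `+`) <= r^2
  expect_equal(sum(out$lesion_mask_true), sum(inside))
  expect_lt(abs(out$lesion_volume_true - 45) / 45, 0.05)   # voxelisation error
})

test_that("lesions crossing the midline or exiting the brain are rejected", {
  truth <- make_head_phantom(small_spec())
  expect_error(insert_lesion(truth, lesion_spec("sphere", center = c(5, 0, 0),
                                                target_volume = 45,
                                                density_reduction = 0.2)),
               "midline")
  expect_error(insert_lesion(truth, lesion_spec("sphere", center = c(55, 0, 0),
                                                target_volume = 45,
                                                density_reduction = 0.2)),
               "brain")
})

test_that("territory wedge lesion is confined to its side and fully reduced", {
  truth <- make_head_phantom(small_spec(noise_sigma = 0))
  les <- lesion_spec("territory_wedge", density_reduction = 0.30, side = "right")
  out <- insert_territory_lesion(truth, les)
  wedge <- out$lesion_mask_true
  expect_gt(sum(wedge), 0)
  # all wedge voxels at 0.7 * hu_brain plus the cupping field
  expect_equal(out$image$data[wedge], 34 * 0.7 + truth$cupping[wedge])
  # volume is the voxel count times the voxel volume
  expect_equal(out$lesion_volume_true,
               sum(wedge) * prod(truth$spec$spacing) / 1000)
  # empty intersection with the contralateral half-grid
  left <- ctiic:::side_half_grid(truth, "left")
  expect_false(any(wedge & left))
})

test_that("lesion-free phantom is mirror-symmetric up to noise", {
  sp <- small_spec(seed = 5)
  truth <- make_head_phantom(sp)
  mirrored <- truth$image$data[rev(seq_len(sp$grid[1])), , ]
  d <- abs(truth$image$data - mirrored)[truth$brain_mask_true]
  # difference of two independent draws: sd sqrt(2)*sigma; allow extreme tail
  expect_lt(stats::quantile(d, 0.999), 6 * sp$noise_sigma)
  expect_lt(max(d), 8 * sp$noise_sigma)
})

test_that("lesion contrast against the mirrored region matches -f*hu_brain", {
  sp <- small_spec(seed = 9)
  truth <- insert_lesion(make_head_phantom(sp), small_lesion(f = 0.2))
  les <- truth$lesion_mask_true
  mir <- les[rev(seq_len(sp$grid[1])), , ]
  delta <- mean(truth$image$data[les]) - mean(truth$image$data[mir])
  se <- sp$noise_sigma * sqrt(2 / sum(les))
  expect_lt(abs(delta - (-0.2 * 34)), 3 * se)
})

test_that("phantom and lesion specs round-trip through YAML", {
  ps <- small_spec(seed = 3, noise_sigma = 1.5)
  f <- tempfile(fileext = ".yaml")
  write_spec_yaml(ps, f)
  expect_equal(read_spec_yaml(f), ps)
  ls <- small_lesion(f = 0.25)
  write_spec_yaml(ls, f)
  expect_equal(read_spec_yaml(f), ls)
})

test_that("ill-posed phantom specs are rejected", {
  expect_error(phantom_spec(hu_brain = 60), "hu_skull > 50")
  expect_error(phantom_spec(noise_sigma = -1), ">= 0")
  expect_error(phantom_spec(grid = c(32, 32, 10), spacing = c(1, 1, 1)),
               "fit")
})
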