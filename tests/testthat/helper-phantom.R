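# Desk-scale phantom used by the unit tests: same physical FOV and slice
# thickness as the default, coarser in-plane matrix and a slightly smaller
# brain, so per-test pipelines run in well under a second.
small_spec <- function(seed = 1L, ...) {
  phantom_spec(grid = c(64L, 64L, 28L), spacing = c(3.75, 3.75, 5),
               brain_semiaxes = c(60, 70, 55), seed = seed, ...)
}

# 45 cc sphere that fits the small brain, right side, clear of the midline.
small_lesion <- function(f = 0.2, v_cc = 45, side = "right") {
  lesion_spec("sphere", center = c(if (side == "right") 25 else -25, 0, 0),
              target_volume = v_cc, density_reduction = f, side = side)
}

# Construct an iic_result-shaped object directly (for volumetry unit tests
# that need a prescribed restored image rather than a fitted one).
fake_iic <- function(input, restored_data, backend = "em_seg") {
  restored <- input
  restored$data <- restored_data
  structure(list(restored = restored,
                 correction_field = input$data - restored_data,
                 iterations = 0L, converged = TRUE, backend = backend,
                 params = iic_params(backend)),
            class = "iic_result")
}
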