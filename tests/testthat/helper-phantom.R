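# Compact phantom geometry shared by the unit tests: same tissue model as
# the default spec, scaled to an 80 x 80 x 320 grid so a phantom builds in
# about a second.
small_phantom_spec <- function(...) {
  defaults <- list(
    shape = c(80L, 80L, 320L),
    spacing = c(8 / 300, 8 / 300, 0.008),
    anterior = list(apex_z = 40, apex_xy = c(3, -2), curv = 0.006),
    posterior = list(apex_z = 110, apex_xy = c(4, -3), curv = -0.009),
    pupil_radius_mm = 32 * 8 / 300,
    iris_offset_px = 30, iris_thickness_px = 10,
    n_fibers = 8, fiber_length_px = 60,
    n_lacunae = 1, lacuna_axes_px = c(6, 6, 15),
    slab_thickness_mm = 1.5,
    seed = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# a hand-built flat surface fit (for ROI arithmetic tests)
flat_surface_fit <- function(z0, shape) {
  structure(list(coef = c(c0 = z0, c1 = 0, c2 = 0, c3 = 0, c4 = 0),
                 shape = shape, cross_term = FALSE),
            class = "surface_fit")
}

# a hand-built pupil result
disc_pupil <- function(center_a, center_b, radius_px, shape) {
  mask <- outer((seq_len(shape[1]) - center_b)^2,
                (seq_len(shape[2]) - center_a)^2, "+") <= radius_px^2
  list(center = c(a = center_a, b = center_b), radius_px = radius_px,
       mask = mask, flag = "ok")
}

# relative L2 error of a coefficient vector
coef_relerr <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}
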