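mask_volume <- function(vals, shape = c(10, 10, 20)) {
  v <- oct_volume(array(db_to_linear(30), shape))
  mask <- array(FALSE, shape)
  mask[seq_along(vals)] <- TRUE
  v$intensity[mask] <- vals
  list(v = v, mask = mask)
}

test_that("optical density is the dB of the linear-scale ROI mean", {
  u <- mask_volume(rep(1584.9, 50))
  expect_equal(compute_vod(u$v, u$mask), 32.0, tolerance = 1e-3)
  two <- mask_volume(c(100, 300))
  expect_equal(compute_vod(two$v, two$mask), 10 * log10(200),
               tolerance = 1e-6)
  expect_identical(compute_vod(two$v, two$mask),
                   compute_lod(two$v, two$mask))
})

test_that("a lens/gel reflectivity ratio maps to the au difference", {
  ph <- make_phantom(small_phantom_spec(
    lens_db = 32 + 10 * log10(2.2), n_fibers = 0, n_lacunae = 0,
    speckle = FALSE, noise_floor_sd = 0, rolloff_db_per_mm = 0))
  lod <- compute_lod(ph$volume, ph$truth$lens_mask)
  vod <- compute_vod(ph$volume, ph$truth$slab_mask)
  expect_equal(lod - vod, 10 * log10(2.2), tolerance = 1e-5)
})

test_that("VOR saturates at its range endpoints and counts exactly", {
  hi <- mask_volume(rep(db_to_linear(80), 100))
  expect_equal(compute_vor(hi$v, hi$mask, 78), 1)
  lo <- mask_volume(rep(db_to_linear(30), 100))
  expect_equal(compute_vor(lo$v, lo$mask, 78), 0)
  mix <- mask_volume(c(rep(db_to_linear(80), 250), rep(db_to_linear(30), 750)))
  expect_equal(compute_vor(mix$v, mix$mask, 78), 0.250)
})

test_that("VOR is monotone non-increasing in the threshold", {
  ph <- make_phantom(small_phantom_spec(seed = 2))
  vors <- vapply(c(60, 70, 78, 85, 95), function(t)
    compute_vor(ph$volume, ph$truth$slab_mask, t), 1)
  expect_true(all(diff(vors) <= 0))
})

test_that("clean-phantom indices equal the ground truth", {
  ph <- make_phantom(small_phantom_spec(speckle = FALSE, noise_floor_sd = 0))
  expect_equal(compute_vod(ph$volume, ph$truth$slab_mask),
               ph$truth$vod_au, tolerance = 1e-6)
  expect_equal(compute_lod(ph$volume, ph$truth$lens_mask),
               ph$truth$lod_au, tolerance = 1e-6)
  expect_identical(compute_vor(ph$volume, ph$truth$slab_mask, 78),
                   ph$truth$vor)
})

test_that("empty masks and mismatched grids are errors", {
  v <- oct_volume(array(1, c(10, 10, 20)))
  expect_error(compute_vod(v, array(FALSE, c(10, 10, 20))), "empty")
  expect_error(compute_vor(v, array(TRUE, c(5, 5, 5))), "dimensions")
})

test_that("the depth MIP finds a single bright voxel at its true depth", {
  shape <- c(20L, 20L, 400L)
  dz <- 8 / 1200
  v <- oct_volume(array(db_to_linear(30), shape),
                  spacing = c(8 / 300, 8 / 300, dz))
  zp <- 50
  z_target <- zp + round(0.5 / dz)
  v$intensity[10, 12, z_target] <- db_to_linear(85)
  surfaces <- list(anterior = flat_surface_fit(20, shape[1:2]),
                   posterior = flat_surface_fit(zp, shape[1:2]))
  seg <- build_rois(v, surfaces, disc_pupil(10.5, 10.5, 8, shape),
                    slab_thickness_mm = 2.0)
  mip <- depth_mip(v, seg)
  expect_equal(mip$depth_mm[10, 12], 0.5, tolerance = dz)
  expect_equal(mip$intensity[10, 12], db_to_linear(85), tolerance = 1e-3)
})

test_that("MIP ties break at the shallowest maximum (uniform slab)", {
  shape <- c(16L, 16L, 200L)
  dz <- 0.01
  v <- oct_volume(array(1000, shape), spacing = c(0.027, 0.027, dz))
  surfaces <- list(anterior = flat_surface_fit(20, shape[1:2]),
                   posterior = flat_surface_fit(60, shape[1:2]))
  seg <- build_rois(v, surfaces, disc_pupil(8.5, 8.5, 6, shape),
                    slab_thickness_mm = 1.0)
  mip <- depth_mip(v, seg)
  got <- mip$depth_mm[!is.na(mip$depth_mm)]
  expect_true(all(abs(got - dz) < 1e-9))   # first slab voxel below capsule
  expect_true(all(mip$depth_mm <= seg$slab_thickness_mm + 1e-9, na.rm = TRUE))
})

test_that("replicate averaging is the arithmetic mean with a shared threshold", {
  mk <- function(vod, lod, vor, thr = 78)
    structure(list(VOD = vod, LOD = lod, VOR = vor, threshold_db = thr,
                   n_slab_voxels = 10, n_lens_voxels = 10),
              class = "opacity_indices")
  avg <- average_replicates(list(mk(32, 70, 0.1), mk(34, 72, 0.2),
                                 mk(33, 74, 0.3)))
  expect_equal(avg$VOR, 0.2)
  expect_equal(avg$VOD, 33)
  expect_equal(avg$LOD, 72)
  one <- average_replicates(list(mk(30, 60, 0.5)))
  expect_equal(one$VOD, 30)
  expect_error(average_replicates(list(mk(32, 70, 0.1),
                                       mk(32, 70, 0.1, thr = 75))),
               "different thresholds")
})
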