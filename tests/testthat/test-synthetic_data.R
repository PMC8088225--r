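test_that("feature-off phantom has a pure-gel slab and zero true VOR", {
  ph <- make_phantom(small_phantom_spec(n_fibers = 0, n_lacunae = 0,
                                        speckle = FALSE, noise_floor_sd = 0))
  expect_equal(ph$truth$vor, 0)
  slab_vals <- ph$truth$clean[ph$truth$slab_mask]
  gel <- db_to_linear(32)
  # gel reflectivity modulated only by depth roll-off
  expect_true(all(slab_vals > 0 & slab_vals <= gel))
})

test_that("gel raised above the threshold saturates true VOR at one", {
  ph <- suppressWarnings(
    make_phantom(small_phantom_spec(gel_db = 80, n_fibers = 5, n_lacunae = 0,
                                    speckle = FALSE, noise_floor_sd = 0,
                                    rolloff_db_per_mm = 0)))
  expect_equal(ph$truth$vor, 1)
})

test_that("slab speckle follows the exponential law (KS on strided sample)", {
  ph <- make_phantom(small_phantom_spec(seed = 3))
  sel <- which(ph$truth$slab_mask & ph$truth$clean > 0)
  set.seed(1)
  samp <- sample(sel, 1e4)
  ratio <- ph$volume$intensity[samp] / ph$truth$clean[samp]
  expect_gt(stats::ks.test(ratio, "pexp")$p.value, 0.01)
})

test_that("phantom generation is a pure function of (spec, seed)", {
  a <- make_phantom(small_phantom_spec(seed = 5))
  b <- make_phantom(small_phantom_spec(seed = 5))
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$vor, b$truth$vor)
  c <- make_phantom(small_phantom_spec(seed = 6))
  expect_false(identical(a$volume$intensity, c$volume$intensity))
})

test_that("true VOR increases strictly with fiber count", {
  vors <- vapply(c(0, 4, 8, 16), function(nf)
    make_phantom(small_phantom_spec(n_fibers = nf, n_lacunae = 0,
                                    speckle = FALSE,
                                    noise_floor_sd = 0))$truth$vor, 1)
  expect_true(all(diff(vors) > 0))
})

test_that("capsule geometry invariants are validated", {
  expect_error(small_phantom_spec(posterior = list(apex_z = 30,
                                                   apex_xy = c(0, 0),
                                                   curv = -0.009)),
               "intersect")
  expect_error(small_phantom_spec(fiber_db = 70), "exceed")
})

test_that("zero trace injection is the identity and -t inverts t inside", {
  ph <- make_phantom(small_phantom_spec(n_fibers = 0, n_lacunae = 0))
  v <- ph$volume
  zero <- motion_trace(rep(0L, 80))
  expect_identical(inject_motion(v, zero)$intensity, v$intensity)
  tr <- motion_trace(axial_px = rep(c(-4L, 3L), 40),
                     lateral_px = rep(c(2L, -5L), 40))
  back <- motion_trace(-tr$axial_px, -tr$lateral_px)
  v2 <- inject_motion(inject_motion(v, tr), back)
  inner_a <- 8:73; inner_z <- 8:313
  expect_identical(v2$intensity[, inner_a, inner_z],
                   v$intensity[, inner_a, inner_z])
})

test_that("a +5 px axial shift on one B-scan displaces its capsule ridge", {
  ph <- make_phantom(small_phantom_spec(n_fibers = 0, n_lacunae = 0,
                                        speckle = FALSE, noise_floor_sd = 0))
  tr <- motion_trace(c(rep(0L, 9), 5L, rep(0L, 70)))
  mv <- inject_motion(ph$volume, tr)
  a0 <- 40
  find_post <- function(vol, b) {
    col <- vol$intensity[b, a0, ]
    cand <- which(col > db_to_linear(85))
    max(cand)   # posterior capsule line is the deepest specular line
  }
  expect_equal(find_post(mv, 10) - find_post(ph$volume, 10), 5)
  expect_equal(find_post(mv, 11) - find_post(ph$volume, 11), 0)
})

test_that("trace injection validates shape and integer shifts", {
  ph <- make_phantom(small_phantom_spec(n_fibers = 0, n_lacunae = 0))
  expect_error(inject_motion(ph$volume, motion_trace(rep(0L, 10))),
               "does not match")
  expect_error(motion_trace(c(0.5, 1)), "integer")
})

test_that("noise-free cohort links are deterministic (R(age, LOD) = 1)", {
  spec <- cohort_spec(n = 30, seed = 9,
                      model = list(lod_sd = 0, vor_sd = 0, vod_sd = 0,
                                   osi_sd = 0, aulcsf_sd = 0),
                      eye_sd = list(VOD = 0, VOR = 0, LOD = 0, OSI = 0,
                                    AULCSF = 0),
                      rep_sd = list(VOD = 0, VOR = 0, LOD = 0))
  co <- make_cohort(spec)
  agg <- co$records[co$records$replicate == 1 & co$records$eye == "OD", ]
  expect_equal(stats::cor(agg$age, agg$LOD), 1, tolerance = 1e-12)
})

test_that("zero replicate noise gives ICC = 1 downstream", {
  co <- make_cohort(cohort_spec(n = 12, seed = 4,
                                rep_sd = list(VOD = 0, VOR = 0, LOD = 0)))
  rep <- analyze_cohort(co, seed = 1)
  for (v in c("VOD", "VOR", "LOD"))
    expect_equal(rep$icc[[v]]$icc, 1, tolerance = 1e-9)
})

test_that("cohort ages match the stated truncated-normal distribution", {
  means <- vapply(1:300, function(s)
    mean(attr(make_cohort(cohort_spec(n = 49, seed = s)), "latent")$age), 1)
  # per-cohort CLT band around the nominal mean
  expect_lt(abs(mean(means) - 40.0), 3 * 19.3 / sqrt(49))
  ages <- attr(make_cohort(cohort_spec(n = 49, seed = 1)), "latent")$age
  expect_true(all(ages >= 9 & ages <= 78))
})

test_that("cohort indices respect their ranges and AL its clip bounds", {
  co <- make_cohort(cohort_spec(n = 49, seed = 7))
  expect_true(all(co$records$VOR >= 0 & co$records$VOR <= 1))
  expect_true(all(co$records$AL >= 22.06 & co$records$AL <= 26.16))
  expect_true(all(co$records$OSI >= 0))
})

test_that("generated CSF samples integrate back to the recorded AULCSF", {
  co <- make_cohort(cohort_spec(n = 10, seed = 11))
  aul <- aulcsf_by_eye(co$csf)
  rec <- unique(co$records[, c("subject_id", "eye", "AULCSF")])
  m <- merge(aul, rec, by = c("subject_id", "eye"))
  expect_equal(m$AULCSF.x, m$AULCSF.y, tolerance = 1e-10)
})
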