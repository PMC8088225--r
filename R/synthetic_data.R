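#' Phantom specification
#'
#' Describes a synthetic anterior-segment OCT volume: lens-capsule geometry,
#' pupil/iris, tissue reflectivities, the retrolental morphology catalogue
#' (fibrous opacities, liquefied lacunae, laminar membranes, a Berger-space
#' gap), the speckle/noise model, depth roll-off and eye motion. Every
#' feature can be switched off independently, and generation is a pure
#' function of `(spec, seed)`.
#'
#' Capsule surfaces are axis-aligned paraboloids
#' `z = apex_z + curv * ((x - x0)^2 + (y - y0)^2)` in centred pixel
#' coordinates (`x = a - (n_a + 1)/2`, `y = b - (n_b + 1)/2`); the anterior
#' surface has positive curvature (apex closest to the instrument), the
#' posterior negative. Reflectivities are given in dB (`10*log10` of linear
#' intensity). Speckle is fully developed: multiplicative unit-mean
#' exponential intensity noise; the background noise floor is additive
#' half-normal.
#'
#' @param shape integer (n_b, n_a, n_z) grid dimensions.
#' @param spacing voxel pitch (dy, dx, dz) in mm.
#' @param anterior,posterior capsule paraboloids: lists with `apex_z` (px),
#'   `apex_xy` (px offsets of the apex from grid centre) and `curv`
#'   (px^-1, signed).
#' @param pupil_radius_mm pupil radius. `iris_db` iris band reflectivity;
#'   the band sits `iris_offset_px` above the anterior apex and is
#'   `iris_thickness_px` thick.
#' @param aqueous_db,lens_db,gel_db,capsule_db tissue reflectivities (dB).
#' @param n_fibers,fiber_radius_px,fiber_length_px,fiber_db fibrous-opacity
#'   model: smoothed 3-D random-walk tubes inside the retrolental slab.
#' @param n_lacunae,lacuna_axes_px,lacuna_shell_db liquefied lacunae:
#'   near-zero-intensity ellipsoids ringed by a bright fibrous shell.
#' @param lamina,lamina_shape,lamina_depth_mm,lamina_db,lamina_radius_frac
#'   retrolental laminar membrane (`shape` one of "flat", "plicated",
#'   "corrugated") covering `lamina_radius_frac` of the pupil.
#' @param berger_gap_mm thickness of the hyporeflective retrolental gap
#'   (Berger's space) behind the posterior capsule; 0 disables it.
#' @param speckle logical; multiplicative exponential speckle on/off.
#' @param speckle_grain_px speckle grain (correlation length of the
#'   underlying complex field) in px along the fast axis and depth;
#'   `c(0, 0)` gives voxel-white speckle. Marginals are Exp(1) either way.
#' @param noise_floor_sd sd of the additive half-normal background (linear).
#' @param rolloff_db_per_mm sensitivity decay with depth (default 6/11,
#'   i.e. -6 dB at 11 mm).
#' @param motion per-B-scan motion model: `axial_sd_px` (random-walk step
#'   sd), `n_jumps`/`jump_amp_px`/`jump_len_frac` (transient lateral
#'   saccades) and `detrend` (remove the quadratic slow-axis component of
#'   the axial walk, which is indistinguishable from lens shape).
#' @param vor_threshold_db opacity threshold used to define the ground-truth
#'   opacity voxel set (default 78).
#' @param slab_thickness_mm retrolental slab thickness (default 2).
#' @param seed RNG seed; same spec and seed give an identical phantom.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(150L, 150L, 600L),
                         spacing = c(8 / 300, 8 / 300, 8 / 1200),
                         anterior = list(apex_z = 60, apex_xy = c(4, -3),
                                         curv = 0.005),
                         posterior = list(apex_z = 250, apex_xy = c(6, -5),
                                          curv = -0.008),
                         pupil_radius_mm = 1.5,
                         iris_db = 55, iris_offset_px = 45,
                         iris_thickness_px = 15,
                         aqueous_db = 20, lens_db = 73, gel_db = 32,
                         capsule_db = 88,
                         n_fibers = 30, fiber_radius_px = 3,
                         fiber_length_px = 150, fiber_db = 82,
                         n_lacunae = 2, lacuna_axes_px = c(10, 10, 25),
                         lacuna_shell_db = 82,
                         lamina = FALSE, lamina_shape = "flat",
                         lamina_depth_mm = 0.35, lamina_db = 70,
                         lamina_radius_frac = 0.6,
                         berger_gap_mm = 0,
                         speckle = TRUE, speckle_grain_px = c(0, 1.0),
                         noise_floor_sd = 10,
                         rolloff_db_per_mm = 6 / 11,
                         motion = list(axial_sd_px = 0, n_jumps = 0,
                                       jump_amp_px = 8, jump_len_frac = 0.1,
                                       detrend = TRUE),
                         vor_threshold_db = 78,
                         slab_thickness_mm = 2,
                         seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               anterior = anterior, posterior = posterior,
               pupil_radius_mm = pupil_radius_mm,
               iris_db = iris_db, iris_offset_px = iris_offset_px,
               iris_thickness_px = iris_thickness_px,
               aqueous_db = aqueous_db, lens_db = lens_db, gel_db = gel_db,
               capsule_db = capsule_db,
               n_fibers = n_fibers, fiber_radius_px = fiber_radius_px,
               fiber_length_px = fiber_length_px, fiber_db = fiber_db,
               n_lacunae = n_lacunae, lacuna_axes_px = lacuna_axes_px,
               lacuna_shell_db = lacuna_shell_db,
               lamina = lamina,
               lamina_shape = match.arg(lamina_shape,
                                        c("flat", "plicated", "corrugated")),
               lamina_depth_mm = lamina_depth_mm, lamina_db = lamina_db,
               lamina_radius_frac = lamina_radius_frac,
               berger_gap_mm = berger_gap_mm,
               speckle = isTRUE(speckle),
               speckle_grain_px = as.numeric(speckle_grain_px),
               noise_floor_sd = noise_floor_sd,
               rolloff_db_per_mm = rolloff_db_per_mm,
               motion = utils::modifyList(
                 list(axial_sd_px = 0, n_jumps = 0, jump_amp_px = 8,
                      jump_len_frac = 0.1, detrend = TRUE), motion),
               vor_threshold_db = vor_threshold_db,
               slab_thickness_mm = slab_thickness_mm,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

# capsule depth matrices (n_b x n_a) and expanded paraboloid coefficients
capsule_surface <- function(surf, shape) {
  nb <- shape[1]; na_ <- shape[2]
  x <- seq_len(na_) - (na_ + 1) / 2
  y <- seq_len(nb) - (nb + 1) / 2
  x0 <- surf$apex_xy[1]; y0 <- surf$apex_xy[2]; k <- surf$curv
  z <- outer((y - y0)^2, (x - x0)^2, "+") * k + surf$apex_z
  coef <- c(c0 = surf$apex_z + k * (x0^2 + y0^2),
            c1 = -2 * k * x0, c2 = -2 * k * y0, c3 = k, c4 = k)
  list(z = z, coef = coef)
}

pupil_mask_matrix <- function(shape, radius_px, erode_px = 0) {
  nb <- shape[1]; na_ <- shape[2]
  x <- seq_len(na_) - (na_ + 1) / 2
  y <- seq_len(nb) - (nb + 1) / 2
  outer(y^2, x^2, "+") <= (radius_px - erode_px)^2
}

validate_phantom_spec <- function(spec) {
  if (any(spec$shape < c(8L, 8L, 16L)))
    stop("phantom grid too small")
  r_px <- spec$pupil_radius_mm / spec$spacing[2]
  za <- capsule_surface(spec$anterior, spec$shape)$z
  zp <- capsule_surface(spec$posterior, spec$shape)$z
  pup <- pupil_mask_matrix(spec$shape, r_px)
  if (any(zp[pup] <= za[pup]))
    stop("validation error: capsule surfaces intersect inside the pupil")
  dbs <- c(spec$aqueous_db, spec$lens_db, spec$gel_db, spec$capsule_db,
           spec$iris_db, spec$fiber_db, spec$lacuna_shell_db, spec$lamina_db)
  if (any(!is.finite(dbs)))
    stop("reflectivities must be finite dB values")
  if (spec$n_fibers > 0 && spec$fiber_db <= spec$vor_threshold_db)
    stop("fiber reflectivity must exceed the VOR threshold")
  if (spec$gel_db >= spec$vor_threshold_db && spec$n_fibers > 0)
    warning("gel reflectivity above the VOR threshold: ground-truth VOR ",
            "is saturated, not fiber-controlled")
  invisible(spec)
}

#' Per-B-scan eye-motion trace
#'
#' Integer per-B-scan shifts: `axial_px` along depth (positive = away from
#' the instrument) and `lateral_px` along the fast axis. An all-zero trace
#' is the identity.
#'
#' @param axial_px,lateral_px integer vectors, one entry per B-scan.
#' @param meta free-form list (estimation diagnostics, generator settings).
#' @return Object of class `motion_trace`.
#' @export
motion_trace <- function(axial_px, lateral_px = rep(0L, length(axial_px)),
                         meta = list()) {
  if (length(axial_px) != length(lateral_px))
    stop("axial and lateral traces must have equal length")
  if (any(axial_px != round(axial_px)) || any(lateral_px != round(lateral_px)))
    stop("motion shifts must be integer pixels")
  structure(list(axial_px = as.integer(round(axial_px)),
                 lateral_px = as.integer(round(lateral_px)),
                 meta = meta),
            class = "motion_trace")
}

# remove the component of v lying in span{1, b, b^2}: for axial motion this
# component is absorbed by the paraboloid fit and is not recoverable.
detrend_quadratic <- function(v) {
  b <- seq_along(v)
  stats::lm.fit(cbind(1, b, b^2), v)$residuals
}

#' Simulate a per-B-scan motion trace
#'
#' Axial motion is a Gaussian random walk (slow drift at the B-scan time
#' scale); with `detrend = TRUE` its quadratic slow-axis component — the part
#' a paraboloid capsule fit necessarily absorbs — is removed before rounding.
#' Transverse motion consists of `n_jumps` transient saccades of amplitude
#' `±jump_amp_px`, each lasting about `jump_len_frac` of the volume.
#'
#' @param n_bscans number of B-scans.
#' @param axial_sd_px random-walk step sd in pixels.
#' @param n_jumps,jump_amp_px,jump_len_frac lateral saccade model.
#' @param detrend remove the quadratic component of the axial walk.
#' @param seed RNG seed.
#' @return A [motion_trace()].
#' @export
simulate_motion_trace <- function(n_bscans, axial_sd_px = 0, n_jumps = 0,
                                  jump_amp_px = 8, jump_len_frac = 0.1,
                                  detrend = TRUE, seed = 1L) {
  set.seed(seed)
  ax <- rep(0, n_bscans)
  if (axial_sd_px > 0) {
    ax <- cumsum(stats::rnorm(n_bscans, 0, axial_sd_px))
    if (detrend) ax <- detrend_quadratic(ax)
  }
  lat <- rep(0, n_bscans)
  if (n_jumps > 0) {
    len <- max(2L, round(jump_len_frac * n_bscans))
    # saccades are discrete events with a refractory interval: draw
    # non-overlapping start positions at least `gap` B-scans apart
    gap <- 5L
    avail <- max(1L, n_bscans - (n_jumps + 1L) * (len + gap))
    starts <- sort(sample.int(avail, n_jumps)) +
      (seq_len(n_jumps) - 1L) * (len + gap)
    for (s in starts) {
      amp <- sample(c(-1, 1), 1) * jump_amp_px
      lat[s:min(n_bscans, s + len - 1L)] <-
        lat[s:min(n_bscans, s + len - 1L)] + amp
    }
  }
  motion_trace(round(ax), round(lat),
               meta = list(axial_sd_px = axial_sd_px, n_jumps = n_jumps,
                           jump_amp_px = jump_amp_px, detrend = detrend,
                           seed = seed))
}

#' Apply a motion trace to a volume
#'
#' Each B-scan is rolled by its integer trace entry: axially (content moves
#' deeper for positive shifts) and laterally along the fast axis. Voxels
#' shifted in from outside the grid are replaced by fresh background noise
#' (half-normal with the volume's recorded noise-floor sd). Injecting `t`
#' followed by `-t` restores all interior voxels exactly.
#'
#' @param volume an [oct_volume()].
#' @param trace a [motion_trace()] with one entry per B-scan.
#' @param noise_floor_sd fill-noise sd; defaults to the generating spec's
#'   value stored in `volume$meta`, else 0.
#' @return The shifted [oct_volume()].
#' @export
inject_motion <- function(volume, trace, noise_floor_sd = NULL) {
  stopifnot(inherits(volume, "oct_volume"), inherits(trace, "motion_trace"))
  d <- dim(volume$intensity)
  if (length(trace$axial_px) != d[1])
    stop("trace length (", length(trace$axial_px),
         ") does not match the B-scan count (", d[1], ")")
  if (is.null(noise_floor_sd))
    noise_floor_sd <- volume$meta$noise_floor_sd
  if (is.null(noise_floor_sd)) noise_floor_sd <- 0
  out <- volume$intensity
  for (b in seq_len(d[1])) {
    page <- out[b, , ]
    page <- roll_fill(page, trace$lateral_px[b], margin = 1,
                      sd = noise_floor_sd)
    page <- roll_fill(page, trace$axial_px[b], margin = 2,
                      sd = noise_floor_sd)
    out[b, , ] <- page
  }
  oct_volume(out, spacing = volume$spacing, scale = volume$scale,
             meta = c(volume$meta, list(motion_injected = TRUE)))
}

# shift a matrix by s along the given margin, filling vacated entries with
# half-normal noise
roll_fill <- function(mat, s, margin, sd) {
  if (s == 0) return(mat)
  n <- dim(mat)[margin]
  if (abs(s) >= n) {
    mat[] <- abs(stats::rnorm(length(mat), 0, sd))
    return(mat)
  }
  fill <- function(k) abs(stats::rnorm(k, 0, sd))
  if (margin == 2) {
    if (s > 0) mat <- cbind(matrix(fill(nrow(mat) * s), nrow(mat), s),
                            mat[, 1:(n - s), drop = FALSE])
    else       mat <- cbind(mat[, (1 - s):n, drop = FALSE],
                            matrix(fill(nrow(mat) * -s), nrow(mat), -s))
  } else {
    if (s > 0) mat <- rbind(matrix(fill(ncol(mat) * s), s, ncol(mat)),
                            mat[1:(n - s), , drop = FALSE])
    else       mat <- rbind(mat[(1 - s):n, , drop = FALSE],
                            matrix(fill(ncol(mat) * -s), -s, ncol(mat)))
  }
  mat
}

#' Generate a phantom OCT volume with ground truth
#'
#' Builds the clean (motion-free) anterior-segment volume described by a
#' [phantom_spec()] — iris, capsule lines, lens, gel vitreous and the
#' configured retrolental morphology — applies depth roll-off, speckle and
#' noise floor, and (when the motion model is non-trivial) a motion-corrupted
#' sibling obtained by injecting a simulated trace.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements
#'   \describe{
#'     \item{volume}{motion-free [oct_volume()] (speckled unless
#'       `spec$speckle = FALSE`).}
#'     \item{moving}{motion-corrupted sibling, or `NULL` when the motion
#'       model is all-zero.}
#'     \item{truth}{`phantom_truth`: injected [motion_trace()], true capsule
#'       coefficient vectors, pupil centre/radius (px), lens/slab/opacity
#'       masks, the clean pre-speckle volume, and the true index values
#'       VOD/LOD (au) and VOR.}
#'   }
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  nb <- spec$shape[1]; na_ <- spec$shape[2]; nz <- spec$shape[3]
  dz <- spec$spacing[3]
  ant <- capsule_surface(spec$anterior, spec$shape)
  pos <- capsule_surface(spec$posterior, spec$shape)
  r_px <- spec$pupil_radius_mm / spec$spacing[2]
  pupil <- pupil_mask_matrix(spec$shape, r_px)
  slab_px <- round(spec$slab_thickness_mm / dz)

  mu <- lapply(list(aq = spec$aqueous_db, lens = spec$lens_db,
                    gel = spec$gel_db, cap = spec$capsule_db,
                    iris = spec$iris_db, fiber = spec$fiber_db,
                    shell = spec$lacuna_shell_db, lam = spec$lamina_db),
               db_to_linear)
  za_r <- round(ant$z); zp_r <- round(pos$z)
  gap_px <- round(spec$berger_gap_mm / dz)
  iris_z1 <- max(1L, round(spec$anterior$apex_z - spec$iris_offset_px))
  iris_z2 <- min(nz, iris_z1 + spec$iris_thickness_px - 1L)

  Z <- matrix(seq_len(nz), na_, nz, byrow = TRUE)
  clean <- array(0, dim = c(nb, na_, nz))
  for (b in seq_len(nb)) {
    za_m <- matrix(za_r[b, ], na_, nz)
    zp_m <- matrix(zp_r[b, ], na_, nz)
    page <- mu$aq * (Z < za_m) +
      mu$cap * (Z == za_m | Z == zp_m) +
      mu$lens * (Z > za_m & Z < zp_m) +
      mu$gel * (Z > zp_m + gap_px) +
      mu$aq * (gap_px > 0) * (Z > zp_m & Z <= zp_m + gap_px)
    inp <- pupil[b, ]
    iris_page <- matrix(0, na_, nz)
    iris_page[, iris_z1:iris_z2] <- mu$iris
    page[!inp, ] <- iris_page[!inp, ]
    clean[b, , ] <- page
  }

  # slab bounds per lateral position (used to confine morphology)
  slab_lo <- zp_r + 1L
  slab_hi <- pmin(zp_r + slab_px, nz)

  if (isTRUE(spec$lamina)) {
    lam_r <- spec$lamina_radius_frac * r_px
    lam_mask <- pupil_mask_matrix(spec$shape, lam_r)
    depth_px <- round(spec$lamina_depth_mm / dz)
    xg <- seq_len(na_) - (na_ + 1) / 2
    yg <- seq_len(nb) - (nb + 1) / 2
    offs <- switch(spec$lamina_shape,
      flat = matrix(0, nb, na_),
      plicated = outer(rep(1, nb), round(4 * sin(2 * pi * xg / 30))),
      corrugated = round(3 * outer(sin(2 * pi * yg / 41),
                                   cos(2 * pi * xg / 23), "+")))
    zl <- zp_r + depth_px + offs
    idx <- which(lam_mask & zl >= slab_lo & zl <= slab_hi, arr.ind = TRUE)
    if (nrow(idx))
      clean[cbind(idx, zl[idx])] <- mu$lam
  }

  if (spec$n_lacunae > 0) {
    ax <- spec$lacuna_axes_px
    for (i in seq_len(spec$n_lacunae)) {
      cb <- round(stats::runif(1, (nb + 1) / 2 - 0.5 * r_px,
                               (nb + 1) / 2 + 0.5 * r_px))
      ca <- round(stats::runif(1, (na_ + 1) / 2 - 0.5 * r_px,
                               (na_ + 1) / 2 + 0.5 * r_px))
      cz <- round(stats::runif(1, zp_r[cb, ca] + ax[3] + 6,
                               min(zp_r[cb, ca] + slab_px, nz) - ax[3] - 6))
      bb <- max(1, cb - ax[1] - 2):min(nb, cb + ax[1] + 2)
      aa <- max(1, ca - ax[2] - 2):min(na_, ca + ax[2] + 2)
      zz <- max(1, cz - ax[3] - 2):min(nz, cz + ax[3] + 2)
      g <- expand.grid(b = bb, a = aa, z = zz)
      rho <- sqrt(((g$b - cb) / ax[1])^2 + ((g$a - ca) / ax[2])^2 +
                    ((g$z - cz) / ax[3])^2)
      core <- rho <= 1
      shell <- rho > 1 & rho <= 1 + 2 / min(ax)
      clean[as.matrix(g[core, ])] <- 0
      clean[as.matrix(g[shell, ])] <- mu$shell
    }
  }

  if (spec$n_fibers > 0) {
    off <- fiber_ball_offsets(spec$fiber_radius_px)
    n_steps <- max(2L, round(spec$fiber_length_px / 2))
    for (i in seq_len(spec$n_fibers)) {
      p <- c(stats::runif(1, (nb + 1) / 2 - 0.7 * r_px,
                          (nb + 1) / 2 + 0.7 * r_px),
             stats::runif(1, (na_ + 1) / 2 - 0.7 * r_px,
                          (na_ + 1) / 2 + 0.7 * r_px), 0)
      p[3] <- stats::runif(1, zp_r[round(p[1]), round(p[2])] + 10,
                           min(zp_r[round(p[1]), round(p[2])] + slab_px, nz) - 8)
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      pts <- matrix(0, n_steps, 3)
      for (s in seq_len(n_steps)) {
        pts[s, ] <- p
        v <- v + stats::rnorm(3, 0, 0.25); v <- v / sqrt(sum(v^2))
        p <- p + 2 * v
      }
      centers <- round(pts)
      vox <- unique(centers[rep(seq_len(n_steps), each = nrow(off)), ,
                            drop = FALSE] +
                      off[rep(seq_len(nrow(off)), times = n_steps), ,
                          drop = FALSE])
      keep <- vox[, 1] >= 1 & vox[, 1] <= nb &
        vox[, 2] >= 1 & vox[, 2] <= na_ &
        vox[, 3] >= slab_lo[cbind(pmin(pmax(vox[, 1], 1), nb),
                                  pmin(pmax(vox[, 2], 1), na_))] &
        vox[, 3] <= slab_hi[cbind(pmin(pmax(vox[, 1], 1), nb),
                                  pmin(pmax(vox[, 2], 1), na_))] &
        pupil[cbind(pmin(pmax(vox[, 1], 1), nb),
                    pmin(pmax(vox[, 2], 1), na_))]
      clean[vox[keep, , drop = FALSE]] <- mu$fiber
    }
  }

  # sensitivity roll-off with depth
  rz <- 10^(-spec$rolloff_db_per_mm * (seq_len(nz) - 1) * dz / 10)
  for (z in seq_len(nz)) clean[, , z] <- clean[, , z] * rz[z]

  # ground-truth ROIs (pupil eroded by 2 px, matching segmentation)
  pupil_roi <- pupil_mask_matrix(spec$shape, r_px, erode_px = 2)
  lens_mask <- array(FALSE, dim = spec$shape)
  slab_mask <- array(FALSE, dim = spec$shape)
  for (b in seq_len(nb)) {
    inp <- which(pupil_roi[b, ])
    for (a in inp) {
      l1 <- za_r[b, a] + 1L; l2 <- zp_r[b, a] - 1L
      if (l1 <= l2) lens_mask[b, a, l1:l2] <- TRUE
      s1 <- zp_r[b, a] + 1L; s2 <- min(zp_r[b, a] + slab_px, nz)
      if (s1 <= s2) slab_mask[b, a, s1:s2] <- TRUE
    }
  }
  thr_lin <- db_to_linear(spec$vor_threshold_db)
  opacity_mask <- slab_mask & clean > thr_lin
  true_vor <- sum(opacity_mask) / sum(slab_mask)
  true_vod <- linear_to_db(mean(clean[slab_mask]))
  true_lod <- linear_to_db(mean(clean[lens_mask]))

  signal <- clean
  if (spec$speckle)
    signal <- signal * speckle_field(spec$shape, spec$speckle_grain_px)
  if (spec$noise_floor_sd > 0)
    signal <- signal + abs(stats::rnorm(length(signal), 0,
                                        spec$noise_floor_sd))
  meta <- list(synthetic = TRUE, seed = spec$seed,
               noise_floor_sd = spec$noise_floor_sd,
               vor_threshold_db = spec$vor_threshold_db,
               slab_thickness_mm = spec$slab_thickness_mm)
  volume <- oct_volume(signal, spacing = spec$spacing, meta = meta)

  trace <- simulate_motion_trace(
    nb, axial_sd_px = spec$motion$axial_sd_px,
    n_jumps = spec$motion$n_jumps, jump_amp_px = spec$motion$jump_amp_px,
    jump_len_frac = spec$motion$jump_len_frac,
    detrend = isTRUE(spec$motion$detrend), seed = spec$seed + 1L)
  moving <- NULL
  if (any(trace$axial_px != 0L) || any(trace$lateral_px != 0L))
    moving <- inject_motion(volume, trace)

  truth <- structure(list(
    trace = trace,
    anterior_coef = ant$coef, posterior_coef = pos$coef,
    anterior_z = ant$z, posterior_z = pos$z,
    pupil_center_px = c(a = (na_ + 1) / 2, b = (nb + 1) / 2),
    pupil_radius_px = r_px,
    lens_mask = lens_mask, slab_mask = slab_mask,
    opacity_mask = opacity_mask,
    clean = clean,
    vor = true_vor, vod_au = true_vod, lod_au = true_lod),
    class = "phantom_truth")
  list(volume = volume, moving = moving, truth = truth)
}

# Fully developed speckle: unit-mean intensity of a smoothed complex
# Gaussian field. The squared modulus of a circular complex Gaussian is
# exponential whatever its spatial correlation, so the marginal law stays
# Exp(1) while the grain (correlation length, in px along fast axis and
# depth) matches the coherent PSF instead of being voxel white.
speckle_field <- function(shape, grain = c(0.8, 1.0)) {
  n <- prod(shape)
  g1 <- array(stats::rnorm(n), shape)
  g2 <- array(stats::rnorm(n), shape)
  if (any(grain > 0)) {
    g1 <- smooth_axis(smooth_axis(g1, grain[1], 2L), grain[2], 3L)
    g2 <- smooth_axis(smooth_axis(g2, grain[1], 2L), grain[2], 3L)
  }
  I <- g1^2 + g2^2
  I / mean(I)
}

# separable discrete Gaussian smoothing along one array axis (replicated
# edges), used for the speckle grain
smooth_axis <- function(x, sigma, axis) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(0:r)^2 / (2 * sigma^2))
  k <- k / (k[1] + 2 * sum(k[-1]))
  d <- dim(x)
  idx <- function(j) {
    s <- pmin(pmax(seq_len(d[axis]) + j, 1L), d[axis])
    switch(axis, x[s, , , drop = FALSE], x[, s, , drop = FALSE],
           x[, , s, drop = FALSE])
  }
  out <- k[1] * x
  for (j in seq_len(r))
    out <- out + k[j + 1] * (idx(j) + idx(-j))
  out
}

# integer offsets of a ball of given radius (for fiber tube voxelisation)
fiber_ball_offsets <- function(r) {
  s <- seq(-ceiling(r), ceiling(r))
  g <- as.matrix(expand.grid(s, s, s))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

#' Cohort specification
#'
#' Distributional model for a synthetic study cohort. Ages follow a
#' truncated normal (defaults: mean 40.0, sd 19.3, range 9–78 years), axial
#' length a clipped normal (23.90 ± 1.05 mm, range 22.06–26.16). The
#' structural model linking covariates to indices is deliberately simple and
#' monotone — a linear age trend for LOD, a logistic age trend for the
#' opacity fraction driving VOR and VOD, OSI linear in (VOR, AL) and AULCSF
#' linear in OSI, each with configurable noise — and its coefficients are
#' synthetic defaults, not estimates from any real cohort. Replicate and
#' between-eye noise sds control the reproducibility (ICC) of the indices.
#'
#' @param n number of subjects.
#' @param age_mean,age_sd,age_range,al_mean,al_sd,al_range,sphere_mean,sphere_sd,sphere_range,cyl_mean,cyl_sd,cyl_range
#'   covariate distributions.
#' @param k_replicates acquisitions per eye (default 3).
#' @param both_eyes generate OD and OS per subject (sharing subject-level
#'   latents plus between-eye noise).
#' @param model named list of structural coefficients (see Details in the
#'   methods vignette).
#' @param eye_sd,rep_sd named lists of between-eye and replicate noise sds.
#' @param csf_freqs,csf_shape spatial-frequency grid (cpd) and the unit
#'   log-CS curve shape scaled per subject to hit the target AULCSF.
#' @param seed RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 49L,
                        age_mean = 40.0, age_sd = 19.3, age_range = c(9, 78),
                        al_mean = 23.90, al_sd = 1.05,
                        al_range = c(22.06, 26.16),
                        sphere_mean = -1.0, sphere_sd = 2.2,
                        sphere_range = c(-9, 3.75),
                        cyl_mean = -0.6, cyl_sd = 0.55, cyl_range = c(-2, 0),
                        k_replicates = 3L, both_eyes = TRUE,
                        model = list(), eye_sd = list(), rep_sd = list(),
                        csf_freqs = c(3, 6, 12, 18, 24),
                        csf_shape = c(0.55, 0.65, 0.55, 0.35, 0.15),
                        seed = 1L) {
  model <- utils::modifyList(list(
    lod_intercept = 44.1, lod_age_slope = 0.652, lod_sd = 3,
    vor_max = 0.30, vor_age_mid = 55, vor_age_scale = 14, vor_sd = 0.03,
    vod_intercept = 31.5, vod_vor_slope = 8, vod_sd = 0.35,
    osi_intercept = 0.25, osi_vor_slope = 3.5, osi_al_slope = 0.18,
    osi_al_ref = 22, osi_sd = 0.25,
    aulcsf_intercept = 2.60, aulcsf_osi_slope = -0.45, aulcsf_sd = 0.10),
    model)
  eye_sd <- utils::modifyList(
    list(VOD = 0.15, VOR = 0.01, LOD = 1.0, OSI = 0.10, AULCSF = 0.05),
    eye_sd)
  rep_sd <- utils::modifyList(list(VOD = 0.18, VOR = 0.012, LOD = 0.6),
                              rep_sd)
  if (n < 2) stop("a cohort needs at least 2 subjects")
  structure(list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, al_mean = al_mean, al_sd = al_sd,
                 al_range = al_range, sphere_mean = sphere_mean,
                 sphere_sd = sphere_sd, sphere_range = sphere_range,
                 cyl_mean = cyl_mean, cyl_sd = cyl_sd, cyl_range = cyl_range,
                 k_replicates = as.integer(k_replicates),
                 both_eyes = isTRUE(both_eyes),
                 model = model, eye_sd = eye_sd, rep_sd = rep_sd,
                 csf_freqs = csf_freqs, csf_shape = csf_shape,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

rnorm_trunc <- function(n, mean, sd, range) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Generate a synthetic cohort table
#'
#' Draws `n` subjects from the distributions in a [cohort_spec()], applies
#' the structural model to obtain subject-level VOD/LOD/VOR/OSI/AULCSF,
#' adds between-eye and replicate noise, and emits the measurement records
#' plus consistent long-format CSF samples (the per-eye CSF curve is the
#' spec's unit shape scaled so that its trapezoidal log-log area equals the
#' eye's AULCSF).
#'
#' @param spec a [cohort_spec()].
#' @return A [cohort_table()]; the subject-level latent values are attached
#'   as `attr(, "latent")` for parameter-recovery tests.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  m <- spec$model
  n <- spec$n
  age <- rnorm_trunc(n, spec$age_mean, spec$age_sd, spec$age_range)
  al <- rnorm_trunc(n, spec$al_mean, spec$al_sd, spec$al_range)
  sphere <- rnorm_trunc(n, spec$sphere_mean, spec$sphere_sd,
                        spec$sphere_range)
  cyl <- rnorm_trunc(n, spec$cyl_mean, spec$cyl_sd, spec$cyl_range)
  lod <- m$lod_intercept + m$lod_age_slope * age +
    stats::rnorm(n, 0, m$lod_sd)
  vor <- m$vor_max / (1 + exp(-(age - m$vor_age_mid) / m$vor_age_scale)) +
    stats::rnorm(n, 0, m$vor_sd)
  vor <- pmin(pmax(vor, 0.001), 0.999)
  vod <- m$vod_intercept + m$vod_vor_slope * vor +
    stats::rnorm(n, 0, m$vod_sd)
  osi <- m$osi_intercept + m$osi_vor_slope * vor +
    m$osi_al_slope * (al - m$osi_al_ref) + stats::rnorm(n, 0, m$osi_sd)
  osi <- pmax(osi, 0.05)
  aulcsf <- m$aulcsf_intercept + m$aulcsf_osi_slope * osi +
    stats::rnorm(n, 0, m$aulcsf_sd)
  aulcsf <- pmin(pmax(aulcsf, 0.3), 3.5)
  latent <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                       age = age, AL = al, sphere = sphere, cylinder = cyl,
                       VOD = vod, VOR = vor, LOD = lod, OSI = osi,
                       AULCSF = aulcsf)

  eyes <- if (spec$both_eyes) c("OD", "OS") else "OD"
  base_area <- compute_aulcsf(cbind(spec$csf_freqs, 10^spec$csf_shape))
  rec <- list(); csf <- list()
  for (i in seq_len(n)) {
    for (eye in eyes) {
      e_vod <- vod[i] + stats::rnorm(1, 0, spec$eye_sd$VOD)
      e_vor <- min(max(vor[i] + stats::rnorm(1, 0, spec$eye_sd$VOR), 0), 1)
      e_lod <- lod[i] + stats::rnorm(1, 0, spec$eye_sd$LOD)
      e_osi <- max(osi[i] + stats::rnorm(1, 0, spec$eye_sd$OSI), 0.05)
      e_aul <- min(max(aulcsf[i] + stats::rnorm(1, 0, spec$eye_sd$AULCSF),
                       0.3), 3.5)
      for (r in seq_len(spec$k_replicates)) {
        rec[[length(rec) + 1L]] <- data.frame(
          subject_id = latent$subject_id[i], eye = eye, replicate = r,
          age = age[i], AL = al[i], sphere = sphere[i], cylinder = cyl[i],
          OSI = e_osi,
          VOD = e_vod + stats::rnorm(1, 0, spec$rep_sd$VOD),
          LOD = e_lod + stats::rnorm(1, 0, spec$rep_sd$LOD),
          VOR = min(max(e_vor + stats::rnorm(1, 0, spec$rep_sd$VOR), 0), 1),
          AULCSF = e_aul)
      }
      k_scale <- e_aul / base_area
      csf[[length(csf) + 1L]] <- data.frame(
        subject_id = latent$subject_id[i], eye = eye,
        frequency_cpd = spec$csf_freqs,
        cs = 10^(k_scale * spec$csf_shape))
    }
  }
  out <- cohort_table(do.call(rbind, rec), do.call(rbind, csf))
  attr(out, "latent") <- latent
  out
}
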