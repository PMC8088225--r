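# ---- shared edge machinery ------------------------------------------------

# Gaussian-blur a B-scan (rows = A-scans, cols = depth) and differentiate
# along depth with a Sobel kernel (smoothing across the fast axis,
# central difference along z). Returns both the blurred page (for
# sub-pixel line refinement) and the depth derivative.
depth_gradient <- function(page, sigma = 2) {
  blurred <- EBImage::gblur(page, sigma = sigma)
  # filter2 correlates with the flipped kernel; this orientation makes a
  # rising edge along z a positive derivative peak
  k <- outer(c(1, 2, 1), c(1, 0, -1))
  list(blur = blurred,
       deriv = EBImage::filter2(blurred, k, boundary = "replicate"))
}

# Locate a specular line per A-scan inside a depth window. mode
# "strongest": the maximal rising edge; mode "first": the first rising edge
# from the top that reaches `first_frac` of the window maximum (the
# anterior capsule is the first strong interface, not necessarily the
# brightest). The rising edge is paired with the subsequent falling edge,
# and the line depth is refined to sub-pixel precision by parabolic
# interpolation of the blurred intensity peak between the two edges.
# Returns depth (NA where no edge clears the gradient floor) and strength.
find_line <- function(dg, z_lo, z_hi, grad_floor = 6, pair_win = 8L,
                      mode = "strongest", first_frac = 0.3) {
  deriv <- dg$deriv; blur <- dg$blur; floor_ref <- dg$floor_ref
  na_ <- nrow(deriv); nz <- ncol(deriv)
  z_lo <- pmax(pmin(as.integer(round(z_lo)), nz), 1L)
  z_hi <- pmax(pmin(as.integer(round(z_hi)), nz), 1L)
  if (length(z_lo) == 1L) z_lo <- rep(z_lo, na_)
  if (length(z_hi) == 1L) z_hi <- rep(z_hi, na_)
  Z <- matrix(seq_len(nz), na_, nz, byrow = TRUE)
  masked <- deriv
  masked[Z < z_lo | Z > z_hi] <- -Inf
  zmax <- max.col(masked, ties.method = "first")
  peak <- masked[cbind(seq_len(na_), zmax)]
  if (is.null(floor_ref))
    floor_ref <- apply(abs(deriv), 1, stats::median)
  depth <- rep(NA_real_, na_)
  strength <- rep(-Inf, na_)
  for (a in seq_len(na_)) {
    if (!is.finite(peak[a]) || peak[a] <= 0 ||
        peak[a] <= grad_floor * floor_ref[a])
      next
    zr <- zmax[a]
    if (mode == "first") {
      cand <- which(masked[a, ] >= first_frac * peak[a])
      if (length(cand)) {
        z1 <- cand[1]
        # climb to the local maximum of this edge
        zr <- z1 - 1L + which.max(deriv[a, z1:min(nz, z1 + pair_win)])
      }
    }
    strength[a] <- deriv[a, zr]
    zf <- zr + which.min(deriv[a, zr:min(nz, zr + pair_win)]) - 1L
    zpk <- zr - 1L + which.max(blur[a, zr:zf])
    delta <- 0
    if (zpk > 1L && zpk < nz) {
      # a Gaussian-blurred specular line is parabolic in log intensity,
      # so the three-point parabola is interpolated on the log scale,
      # after removing the local background ramp (the tissue on either
      # side of the line differs in reflectivity and would pull the peak)
      y <- blur[a, (zpk - 1L):(zpk + 1L)]
      z1 <- max(1L, zr - pair_win); z2 <- min(nz, zf + pair_win)
      if (z2 > z1) {
        bg <- blur[a, z1] +
          (blur[a, z2] - blur[a, z1]) * ((zpk - 1L):(zpk + 1L) - z1) /
            (z2 - z1)
        if (all(y - bg > 0)) y <- y - bg
      }
      if (all(y > 0)) {
        ly <- log(y)
        den <- ly[1] - 2 * ly[2] + ly[3]
        if (den < 0)
          delta <- max(-0.5, min(0.5, 0.5 * (ly[1] - ly[3]) / den))
      }
    }
    depth[a] <- zpk + delta
  }
  list(depth = depth, strength = strength)
}

# Anterior + posterior capsule depth maps for every B-scan, in two passes.
# Pass 1: the anterior line is the first strong rising edge above
# `anterior_frac` of the depth range; the posterior is the strongest edge
# at least `min_sep_px` deeper. Pass 2: each surface is re-detected inside
# a narrow window (`refine_win_px`) around its trimmed paraboloid fit
# (shifted per B-scan by the median pass-1 residual, so uncorrected axial
# motion stays inside the window), which rejects bright off-surface
# structures such as fibrous opacities.
capsule_edges <- function(volume, pupil, params = list()) {
  p <- utils::modifyList(list(sigma = 2, min_sep_px = 40, grad_floor = 6,
                              anterior_frac = 0.6, pair_win = 8L,
                              refine_win_px = 6L, pupil_erode_px = 3L),
                         params)
  d <- dim(volume$intensity)
  # capsule detections inside the iris-shadow penumbra are biased and sit
  # at the high-leverage chord ends of the curvature fit: erode them away
  if (p$pupil_erode_px > 0) {
    br <- EBImage::makeBrush(2L * p$pupil_erode_px + 1L, "disc")
    eroded <- EBImage::erode(pupil, br) > 0
    if (sum(eroded) > 0.25 * sum(pupil)) pupil <- eroded
  }
  pages <- vector("list", d[1])
  ant <- matrix(NA_real_, d[1], d[2])
  post <- matrix(NA_real_, d[1], d[2])
  for (b in seq_len(d[1])) {
    if (!any(pupil[b, ])) next
    pages[[b]] <- depth_gradient(volume$intensity[b, , ], sigma = p$sigma)
    # per-A-scan gradient floor reference, computed once per page
    pages[[b]]$floor_ref <- apply(abs(pages[[b]]$deriv), 1, stats::median)
    fa <- find_line(pages[[b]], 3L, round(p$anterior_frac * d[3]),
                    grad_floor = p$grad_floor, pair_win = p$pair_win,
                    mode = "first")
    lo <- ifelse(is.na(fa$depth), d[3] + 1, fa$depth + p$min_sep_px)
    fp <- find_line(pages[[b]], lo, d[3] - 2L,
                    grad_floor = p$grad_floor, pair_win = p$pair_win)
    ant[b, pupil[b, ]] <- fa$depth[pupil[b, ]]
    post[b, pupil[b, ]] <- fp$depth[pupil[b, ]]
  }
  refine <- function(depth) {
    fit <- tryCatch(fit_paraboloid(depth, params), error = function(e) NULL)
    if (is.null(fit)) return(depth)
    surf <- predict_surface(fit, d[1:2])
    # Row-wise window centres from a LOW quantile of the residuals: the
    # capsule is the shallowest consistent interface, while everything
    # that can capture detections (fiber bundles, lacuna shells, laminae)
    # lies deeper, so the lower quartile tracks the capsule even on rows
    # whose pass-1 majority locked onto such a structure. The constant
    # quantile bias is absorbed by the surface gauge.
    res_map <- matrix(NA_real_, d[1], d[2])
    res_map[fit$idx[fit$inliers, , drop = FALSE]] <-
      fit$residuals[fit$inliers]
    n_det <- rowSums(!is.na(res_map))
    offs <- apply(res_map, 1, stats::quantile, probs = 0.25, na.rm = TRUE,
                  names = FALSE)
    offs[n_det < 8L | !is.finite(offs)] <- NA
    out <- matrix(NA_real_, d[1], d[2])
    for (b in seq_len(d[1])) {
      if (is.null(pages[[b]]) || is.na(offs[b])) next
      ctr <- surf[b, ] + offs[b]
      fl <- find_line(pages[[b]], ctr - p$refine_win_px,
                      ctr + p$refine_win_px, grad_floor = p$grad_floor,
                      pair_win = p$pair_win)
      out[b, pupil[b, ]] <- fl$depth[pupil[b, ]]
    }
    out
  }
  list(anterior = refine(ant), posterior = refine(post), params = p,
       pupil = pupil)
}

#' Delineate the posterior lens capsule
#'
#' Per A-scan depth of the posterior capsule interface, found as the
#' strongest depth-gradient edge (Sobel filter of Gaussian-blurred
#' cross-sections) below the anterior capsule, inside the pupil. A-scans
#' where no edge clears the gradient floor are returned as `NA`.
#'
#' @param volume linear-scale [oct_volume()].
#' @param params list; `sigma` (blur, px), `min_sep_px` (minimum
#'   anterior-posterior separation), `grad_floor` (edge strength floor as a
#'   multiple of the A-scan's median absolute gradient), `anterior_frac`
#'   (depth fraction searched for the anterior line), `pupil` (logical
#'   B x A mask; detected with [detect_pupil()] when omitted).
#' @return Numeric B x A matrix of capsule depths (px, `NA` = missing), with
#'   the in-pupil mask and detection fraction in attributes.
#' @export
delineate_posterior_capsule <- function(volume, params = list()) {
  stopifnot(inherits(volume, "oct_volume"))
  pupil <- params$pupil
  if (is.null(pupil)) pupil <- detect_pupil(volume)$mask
  edges <- capsule_edges(volume, pupil, params)
  pupil <- edges$pupil   # after penumbra erosion
  n_in <- sum(pupil)
  frac <- sum(!is.na(edges$posterior)) / max(n_in, 1L)
  if (frac < 0.10)
    stop(sprintf(paste0("delineation failure: only %.1f%% of in-pupil ",
                        "A-scans produced a capsule edge"), 100 * frac))
  structure(edges$posterior, pupil = pupil, anterior = edges$anterior,
            detected_fraction = frac)
}

# ---- paraboloid fitting ---------------------------------------------------

#' Fit a paraboloid surface to a detected depth map
#'
#' Least-squares fit of `z = c0 + c1 x + c2 y + c3 x^2 + c4 y^2` (centred
#' pixel coordinates; axis-aligned, no cross term unless `cross_term`) to
#' the non-missing entries of a depth map, with one round of
#' median-absolute-deviation trimming of residual outliers.
#'
#' @param depth numeric B x A matrix of detected depths (`NA` = missing).
#' @param params list; `mad_k` (trimming multiplier, default 3.5),
#'   `cross_term` (add a `c5 xy` term).
#' @return Object of class `surface_fit`: coefficients, per-point residuals,
#'   RMS residual over inliers, inlier mask, and the grid shape.
#' @export
fit_paraboloid <- function(depth, params = list()) {
  p <- utils::modifyList(list(mad_k = 3.5, cross_term = FALSE,
                              row_normalize = FALSE), params)
  nb <- nrow(depth); na_ <- ncol(depth)
  idx <- which(!is.na(depth), arr.ind = TRUE)
  if (nrow(idx) < 6)
    stop("fit error: need at least 6 detected points")
  x <- idx[, 2] - (na_ + 1) / 2
  y <- idx[, 1] - (nb + 1) / 2
  z <- depth[idx]
  # optional row-equalising weights: every B-scan contributes equally,
  # whatever its pupil chord length (used by the axial-motion fit so that
  # the surface absorbs the same per-B-scan gauge that is projected out
  # of the shift estimates)
  w <- rep(1, nrow(idx))
  if (isTRUE(p$row_normalize)) {
    n_per_row <- tabulate(idx[, 1], nbins = nb)
    w <- 1 / sqrt(n_per_row[idx[, 1]])
  }
  design <- cbind(1, x, y, x^2, y^2)
  if (p$cross_term) design <- cbind(design, x * y)
  qrd <- qr(design * w)
  if (qrd$rank < ncol(design))
    stop("fit error: rank-deficient design (points collinear in x, y)")
  beta <- qr.coef(qrd, z * w)
  res <- z - design %*% beta
  md <- stats::median(res); s <- stats::mad(res)
  keep <- abs(res - md) <= p$mad_k * s + 1e-9
  if (sum(keep) >= 6) {
    qrd2 <- qr((design * w)[keep, , drop = FALSE])
    if (qrd2$rank == ncol(design))
      beta <- qr.coef(qrd2, (z * w)[keep])
  }
  res <- as.vector(z - design %*% beta)
  names(beta) <- c("c0", "c1", "c2", "c3", "c4",
                   if (p$cross_term) "c5")
  structure(list(coef = beta, idx = idx, detected = z, residuals = res,
                 rms = sqrt(mean(res[keep]^2)), inliers = keep,
                 shape = c(nb, na_), cross_term = p$cross_term),
            class = "surface_fit")
}

#' Evaluate a fitted surface over the lateral grid
#'
#' @param fit a `surface_fit` from [fit_paraboloid()].
#' @param shape optional `(n_b, n_a)`; defaults to the fitted grid.
#' @return Numeric B x A matrix of fitted depths (px).
#' @export
predict_surface <- function(fit, shape = fit$shape) {
  nb <- shape[1]; na_ <- shape[2]
  x <- seq_len(na_) - (na_ + 1) / 2
  y <- seq_len(nb) - (nb + 1) / 2
  cf <- fit$coef
  z <- cf["c0"] + outer(cf["c2"] * y + cf["c4"] * y^2,
                        cf["c1"] * x + cf["c3"] * x^2, "+")
  if (isTRUE(fit$cross_term)) z <- z + cf["c5"] * outer(y, x)
  z
}

# Per-B-scan median residual offsets with outlier protection: rows with
# fewer than `min_det` detections are treated as missing, and offsets
# further than `jump_tol` px from their running median (motion is a walk,
# hence locally smooth) are replaced by it.
robust_row_offsets <- function(resid_map, min_det = 8L, jump_tol = 8) {
  n_det <- rowSums(!is.na(resid_map))
  offs <- apply(resid_map, 1, stats::median, na.rm = TRUE)
  offs[n_det < min_det | !is.finite(offs)] <- NA
  if (sum(!is.na(offs)) >= 7) {
    sm <- stats::runmed(fill_nearest(offs), 5, endrule = "median")
    out <- which(!is.na(offs) & abs(offs - sm) > jump_tol)
    offs[out] <- sm[out]
  }
  offs
}

# nearest-neighbour fill of NA entries in a vector
fill_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(rep(0, length(v)))
  idx <- vapply(seq_along(v), function(i) ok[which.min(abs(ok - i))], 1L)
  v[idx]
}

# ---- axial correction -----------------------------------------------------

#' Correct axial eye motion
#'
#' Delineates the posterior capsule, fits the best paraboloid, and shifts
#' each B-scan by the rounded median of (detected - fitted) depth over its
#' in-pupil A-scans. Shifts are integer pixels and intensities are never
#' interpolated, so ROI statistics of fully interior regions are unaffected.
#' B-scans without capsule detections inherit the shift of the nearest
#' estimated B-scan.
#'
#' @param volume linear-scale [oct_volume()].
#' @param params passed to [delineate_posterior_capsule()] and
#'   [fit_paraboloid()].
#' @return List with `volume` (corrected) and `trace` (a [motion_trace()];
#'   its `meta` carries the surface fit and the pre/post residual RMS).
#' @export
correct_axial <- function(volume, params = list()) {
  p <- utils::modifyList(list(min_det = 16L, mad_k = 3.5), params)
  depth <- delineate_posterior_capsule(volume, params)
  nb <- nrow(depth); na_ <- ncol(depth)
  bb <- cbind(1, seq_len(nb), seq_len(nb)^2)
  # Joint linear model: depth(b, a) = offset_b + c1 x + c3 x^2, solved by
  # within-B-scan demeaning (the offsets absorb the slow-axis terms of the
  # paraboloid). The component of the offsets quadratic in b is
  # indistinguishable from lens shape and is projected out as the gauge;
  # what remains is the per-B-scan axial motion the data identify.
  x <- seq_len(na_) - (na_ + 1) / 2
  X <- cbind(rep(1, na_), x, x^2)
  solve_rows <- function(depth) {
    ok_rows <- which(rowSums(!is.na(depth)) >= p$min_det)
    dml <- list(); xml <- list()
    for (b in ok_rows) {
      sel <- which(!is.na(depth[b, ]))
      Xb <- X[sel, 2:3, drop = FALSE]
      dml[[length(dml) + 1L]] <- depth[b, sel] - mean(depth[b, sel])
      xml[[length(xml) + 1L]] <- sweep(Xb, 2, colMeans(Xb))
    }
    cx <- stats::lm.fit(do.call(rbind, xml), unlist(dml))$coefficients
    o <- rep(NA_real_, nb)
    for (b in ok_rows) {
      sel <- which(!is.na(depth[b, ]))
      o[b] <- stats::median(depth[b, sel] -
                              X[sel, 2:3, drop = FALSE] %*% cx)
    }
    list(cx = cx, offsets = o, rows = ok_rows)
  }
  sol <- solve_rows(depth)
  # one robust re-pass: trim residual outliers, re-solve
  res_map <- depth - outer(ifelse(is.na(sol$offsets), 0, sol$offsets),
                           rep(1, na_)) -
    matrix(X[, 2:3] %*% sol$cx, nb, na_, byrow = TRUE)
  sc <- stats::mad(res_map, na.rm = TRUE)
  md <- stats::median(res_map, na.rm = TRUE)
  trimmed <- depth
  trimmed[!is.na(res_map) & abs(res_map - md) > p$mad_k * sc + 1e-9] <- NA
  sol <- solve_rows(trimmed)
  # quadratic gauge fitted on estimated B-scans only: the lens-shape
  # component of the offsets is exactly quadratic, so any subset fit
  # removes it without distortion from filled edge rows
  obs0 <- which(is.finite(sol$offsets))
  qc0 <- stats::lm.fit(bb[obs0, , drop = FALSE],
                       sol$offsets[obs0])$coefficients
  s_all <- rep(NA_real_, nb)
  s_all[obs0] <- sol$offsets[obs0] -
    as.vector(bb[obs0, , drop = FALSE] %*% qc0)
  s <- fill_nearest(s_all)
  # The estimated shifts are defined only up to a smooth quadratic gauge
  # (absorbed by the lens-shape fit), while physical shifts are whole
  # pixels. Choose the gauge that brings the estimates closest to the
  # integer lattice (alternating rounding with a quadratic refit), which
  # removes systematic off-by-one runs at rounding boundaries.
  q <- rep(0, nb)
  for (it2 in 1:8) {
    qc <- stats::lm.fit(bb, round(s + q) - s)$coefficients
    q_new <- as.vector(bb %*% qc)
    if (max(abs(q_new - q)) < 1e-9) break
    q <- q_new
  }
  sq <- s + q
  # any remaining slowly varying sub-pixel error shows up as a smooth
  # fractional part; physical shifts are whole pixels, so it is removed
  # before rounding (median over a 11-B-scan window)
  if (nb > 11) {
    fr <- sq - round(sq)
    sq <- sq - stats::runmed(fr, 11, endrule = "median")
  }
  shifts <- as.integer(round(sq))
  # B-scans without a capsule estimate inherit the nearest estimated
  # B-scan's shift (the gauge polynomials must not extrapolate there)
  obs <- which(is.finite(sol$offsets))
  if (length(obs) && length(obs) < nb) {
    near <- vapply(seq_len(nb),
                   function(i) obs[which.min(abs(obs - i))], 1L)
    shifts <- shifts[near]
  }
  # assemble the implied paraboloid (centred coordinates) for diagnostics
  m <- (nb + 1) / 2
  coef <- c(c0 = unname(qc0[1] + qc0[2] * m + qc0[3] * m^2),
            c1 = unname(sol$cx[1]), c2 = unname(qc0[2] + 2 * qc0[3] * m),
            c3 = unname(sol$cx[2]), c4 = unname(qc0[3]))
  fit <- structure(list(coef = coef, shape = c(nb, na_),
                        cross_term = FALSE), class = "surface_fit")
  resid_map <- depth - predict_surface(fit)
  rms_pre <- sqrt(mean(resid_map^2, na.rm = TRUE))
  rms_post <- sqrt(mean((resid_map - shifts)^2, na.rm = TRUE))
  d <- dim(volume$intensity)
  out <- volume$intensity
  fill_sd <- volume$meta$noise_floor_sd
  if (is.null(fill_sd)) fill_sd <- 0
  for (b in seq_len(d[1]))
    if (shifts[b] != 0L)
      out[b, , ] <- roll_fill(out[b, , ], -shifts[b], margin = 2,
                              sd = fill_sd)
  trace <- motion_trace(shifts, rep(0L, d[1]),
                        meta = list(kind = "axial", fit = fit,
                                    rms_pre = rms_pre, rms_post = rms_post))
  list(volume = oct_volume(out, volume$spacing, volume$scale, volume$meta),
       trace = trace)
}

# ---- transverse correction ------------------------------------------------

# 4-connectivity circularity of a logical mask: 4*pi*A / P^2 with P the
# count of mask/background edges (consistent before/after shifting).
mask_circularity <- function(mask) {
  A <- sum(mask)
  if (A == 0) return(0)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  nr <- nrow(pad); nc <- ncol(pad)
  P <- sum(pad[-1, ] != pad[-nr, ]) + sum(pad[, -1] != pad[, -nc])
  4 * pi * A / P^2
}

#' Correct transverse eye motion
#'
#' Detects the pupil in the en face projection, fits a circle to its
#' boundary, and shifts each B-scan along the fast axis so that the
#' per-B-scan pupil-chord midpoints align with the circle centre, restoring
#' a circular pupil. Raw midpoint offsets are denoised with a short running
#' median (saccadic motion is piecewise constant across B-scans). If the
#' estimated shifts would decrease pupil circularity the correction falls
#' back to the identity.
#'
#' @param volume linear-scale [oct_volume()].
#' @param params list; `smooth_window` (running-median width, odd, default
#'   5), `min_chord_px` (minimum pupil chord to estimate a midpoint), plus
#'   [detect_pupil()] parameters.
#' @return List with `volume`, `trace`, and the before/after circularity in
#'   `trace$meta`.
#' @export
correct_transverse <- function(volume, params = list()) {
  p <- utils::modifyList(list(smooth_window = 5L, min_chord_px = 5L), params)
  pup <- tryCatch(detect_pupil(volume, params),
                  error = function(e)
                    stop("pupil undetectable (", conditionMessage(e),
                         "); re-run with transverse correction disabled"))
  mask <- pup$mask
  d <- dim(volume$intensity)
  # midpoint of the largest contiguous pupil run per B-scan (robust to
  # stray dark pixels, e.g. shadow or fill noise at the volume edge)
  m <- rep(NA_real_, d[1])
  for (b in seq_len(d[1])) {
    r <- rle(mask[b, ])
    runs <- which(r$values)
    if (!length(runs)) next
    best <- runs[which.max(r$lengths[runs])]
    len <- r$lengths[best]
    if (len < p$min_chord_px) next
    end <- cumsum(r$lengths)[best]
    m[b] <- end - (len - 1) / 2
  }
  raw <- m - pup$center["a"]
  # a common lateral offset of all B-scans is unobservable (it only moves
  # the pupil in the field); fix the gauge at the majority baseline, which
  # the displaced B-scans would otherwise drag with them via the circle fit
  raw <- raw - stats::median(raw, na.rm = TRUE)
  w <- p$smooth_window
  sm <- fill_nearest(raw)
  if (w > 1L && length(sm) > w)
    sm <- stats::runmed(sm, k = w, endrule = "median")
  shifts <- as.integer(round(sm))
  # saccades last several B-scans: a single-B-scan excursion is midpoint
  # noise at a step boundary, not motion; snap it to the closer plateau
  for (b in 2:(d[1] - 1L))
    if (shifts[b] != shifts[b - 1L] && shifts[b] != shifts[b + 1L]) {
      cand <- c(shifts[b - 1L], shifts[b + 1L])
      shifts[b] <- cand[which.min(abs(cand - sm[b]))]
    }
  circ_before <- mask_circularity(mask)
  shifted_mask <- mask
  for (b in seq_len(d[1]))
    if (shifts[b] != 0L) {
      row <- rep(FALSE, d[2])
      src <- seq_len(d[2]) + shifts[b]
      ok <- src >= 1 & src <= d[2]
      row[ok] <- mask[b, src[ok]]
      shifted_mask[b, ] <- row
    }
  circ_after <- mask_circularity(shifted_mask)
  if (circ_after < circ_before) {
    shifts <- rep(0L, d[1])
    circ_after <- circ_before
  }
  out <- volume$intensity
  fill_sd <- volume$meta$noise_floor_sd
  if (is.null(fill_sd)) fill_sd <- 0
  for (b in seq_len(d[1]))
    if (shifts[b] != 0L)
      out[b, , ] <- roll_fill(out[b, , ], -shifts[b], margin = 1,
                              sd = fill_sd)
  trace <- motion_trace(rep(0L, d[1]), shifts,
                        meta = list(kind = "transverse",
                                    circularity_before = circ_before,
                                    circularity_after = circ_after,
                                    pupil = pup[c("center", "radius_px")]))
  list(volume = oct_volume(out, volume$spacing, volume$scale, volume$meta),
       trace = trace)
}

#' Full motion correction
#'
#' Applies transverse correction first — lateral B-scan shifts displace the
#' capsule surface laterally and would bias the paraboloid residuals by the
#' local surface slope — and axial correction second. Either stage can be
#' disabled.
#'
#' @param volume linear-scale [oct_volume()].
#' @param transverse,axial logical stage toggles.
#' @param axial_passes number of axial estimation/correction rounds. The
#'   second pass re-estimates on the corrected volume, where any residual
#'   shifts are near-integer steps that the quadratic gauge cannot hide;
#'   correction is idempotent, so further passes change nothing.
#' @param params forwarded to both stages.
#' @return List with `volume` and `trace`, a combined [motion_trace()].
#' @export
correct_motion <- function(volume, transverse = TRUE, axial = TRUE,
                           axial_passes = 2L, params = list()) {
  d1 <- dim(volume$intensity)[1]
  lat <- rep(0L, d1); ax <- rep(0L, d1); meta <- list()
  if (transverse) {
    ct <- correct_transverse(volume, params)
    volume <- ct$volume; lat <- ct$trace$lateral_px
    meta$transverse <- ct$trace$meta
  }
  if (axial) {
    for (pass in seq_len(axial_passes)) {
      ca <- correct_axial(volume, params)
      volume <- ca$volume; ax <- ax + ca$trace$axial_px
      meta$axial <- ca$trace$meta
      if (all(ca$trace$axial_px == 0L)) break
    }
  }
  list(volume = volume, trace = motion_trace(ax, lat, meta = meta))
}
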