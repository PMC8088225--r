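# ---- pupil detection ------------------------------------------------------

#' Detect the pupil in the en face projection
#'
#' The iris depth band is located from the mean depth profile of the
#' volume's lateral border (which always lies on the iris for an anterior
#' segment scan); the en face mean projection over that band shows the iris
#' as a bright annulus and the pupil as its dark interior. The projection is
#' thresholded (Otsu), the largest dark connected component is taken as the
#' pupil, and a circle is fitted to its boundary by least squares.
#'
#' @param volume linear-scale [oct_volume()].
#' @param params list; `ring_px` (border width used for the iris depth
#'   profile, default 2), `band_pad` (padding of the iris depth band, px),
#'   `min_frac` (minimum pupil area as a fraction of the en face area).
#' @return List with `center` (named `(a, b)` px), `radius_px`, `mask`
#'   (logical B x A), `band` (iris depth range used) and `flag`
#'   (`"ok"` or `"degenerate"` when the projection carries no contrast and
#'   the whole field is returned).
#' @export
detect_pupil <- function(volume, params = list()) {
  p <- utils::modifyList(list(ring_px = 2L, band_pad = 8L, min_frac = 0.01),
                         params)
  v <- volume$intensity
  d <- dim(v)
  ring_a <- c(seq_len(p$ring_px), d[2] - seq_len(p$ring_px) + 1L)
  # per-B-scan iris depth from the lateral border columns (always on the
  # iris), median-smoothed across B-scans so that uncorrected axial motion
  # cannot move the iris out of the projection band
  band_prof <- sapply(seq_len(d[1]), function(b)
    colMeans(v[b, ring_a, , drop = TRUE]))          # nz x nb
  peaks <- max.col(t(band_prof), ties.method = "first")
  if (d[1] > 9) peaks <- stats::runmed(peaks, 9, endrule = "median")
  prof <- band_prof[, ceiling(d[1] / 2)]
  pk <- peaks[ceiling(d[1] / 2)]
  above <- band_prof[, ceiling(d[1] / 2)] > 0.5 * band_prof[pk, ceiling(d[1] / 2)]
  lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- pk; while (hi < d[3] && above[hi + 1L]) hi <- hi + 1L
  half <- max(3L, ceiling((hi - lo) / 2) + p$band_pad)
  E <- matrix(0, d[1], d[2])
  for (b in seq_len(d[1])) {
    band_b <- max(1L, peaks[b] - half):min(d[3], peaks[b] + half)
    E[b, ] <- rowMeans(v[b, , band_b, drop = TRUE])
  }
  band <- c(max(1L, min(peaks) - half), min(d[3], max(peaks) + half))
  if (diff(range(E)) < 1e-12) {
    warning("en face projection carries no contrast; returning whole field")
    return(list(center = c(a = (d[2] + 1) / 2, b = (d[1] + 1) / 2),
                radius_px = sqrt(d[1] * d[2] / pi),
                mask = matrix(TRUE, d[1], d[2]), band = band,
                flag = "degenerate"))
  }
  En <- (E - min(E)) / diff(range(E))
  thr <- EBImage::otsu(En, range = c(0, 1))
  dark <- En < thr
  lab <- EBImage::bwlabel(dark)
  if (max(lab) == 0)
    stop("no dark en face component: pupil not found")
  sizes <- tabulate(lab[lab > 0])
  comp <- which.max(sizes)
  if (sizes[comp] < p$min_frac * d[1] * d[2])
    stop("no dark en face component covering at least ",
         round(100 * p$min_frac, 1), "% of the field")
  mask <- lab == comp
  bnd <- boundary_pixels(mask)
  # border pixels are truncation artifacts, not pupil boundary
  keep <- bnd[, 1] > 1 & bnd[, 1] < d[1] & bnd[, 2] > 1 & bnd[, 2] < d[2]
  if (sum(keep) >= 6) bnd <- bnd[keep, , drop = FALSE]
  fit <- fit_circle(bnd[, 2], bnd[, 1])
  list(center = c(a = fit$cx, b = fit$cy), radius_px = fit$r,
       mask = mask, band = band, flag = "ok")
}

# mask pixels with at least one 4-neighbour outside the mask
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
  inner <- pad[2:(nr + 1), 2:(nc + 1)]
  nb4 <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  which(inner & !nb4, arr.ind = TRUE)
}

# algebraic (Kasa) least-squares circle fit
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.coef(qr(A), b)
  list(cx = sol[1], cy = sol[2],
       r = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
}

# ---- lens interfaces ------------------------------------------------------

#' Segment the crystalline lens interfaces
#'
#' Delineates the anterior and posterior capsule lines in a motion-corrected
#' volume (anterior searched in the upper depth range, posterior below the
#' detected anterior surface) and fits a paraboloid to each. Errors if the
#' fitted surfaces cross anywhere inside the pupil.
#'
#' @param volume motion-corrected linear-scale [oct_volume()].
#' @param params edge/fit parameters, see
#'   [delineate_posterior_capsule()] and [fit_paraboloid()].
#' @return List with `anterior` and `posterior` (`surface_fit`s) and
#'   `pupil` (the [detect_pupil()] result used).
#' @export
segment_lens_interfaces <- function(volume, params = list()) {
  stopifnot(inherits(volume, "oct_volume"))
  pup <- if (is.null(params$pupil_result)) detect_pupil(volume, params)
         else params$pupil_result
  edges <- capsule_edges(volume, pup$mask, params)
  ant_fit <- fit_paraboloid(edges$anterior, params)
  post_fit <- fit_paraboloid(edges$posterior, params)
  za <- predict_surface(ant_fit)
  zp <- predict_surface(post_fit)
  if (any(zp[pup$mask] <= za[pup$mask]))
    stop("segmentation error: capsule surfaces cross inside the pupil")
  list(anterior = ant_fit, posterior = post_fit, pupil = pup)
}

# ---- ROI construction -----------------------------------------------------

#' Build the lens and retrolental-slab regions of interest
#'
#' The lens ROI is the space between the fitted capsule surfaces; the
#' vitreous ROI is the slab from one voxel below the posterior capsule down
#' to `slab_thickness_mm` behind it (`slab_px = round(slab_mm / dz_mm)`
#' voxels). Laterally both ROIs are limited to the fitted pupil circle
#' eroded by 2 px (the iris blocks deeper light propagation). Slab voxels
#' falling beyond the deep edge of the grid are excluded and reported as a
#' coverage fraction; coverage below 50% is an error (inadequate zero-delay
#' placement).
#'
#' @param volume linear-scale [oct_volume()].
#' @param surfaces result of [segment_lens_interfaces()] (or a list with
#'   `anterior`/`posterior` `surface_fit`s).
#' @param pupil a [detect_pupil()] result; defaults to `surfaces$pupil`.
#' @param slab_thickness_mm slab thickness (default 2.0).
#' @return Object of class `segmentation_result`: the two surface fits,
#'   pupil parameters, logical `lens_mask` and `slab_mask` 3-D grids,
#'   `slab_px` and `slab_coverage`.
#' @export
build_rois <- function(volume, surfaces, pupil = surfaces$pupil,
                       slab_thickness_mm = 2.0) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  dz <- volume$spacing[3]
  slab_px <- round(slab_thickness_mm / dz)
  r_eff <- pupil$radius_px - 2
  if (r_eff <= 0) stop("empty ROI: pupil radius too small")
  a_idx <- seq_len(d[2]); b_idx <- seq_len(d[1])
  lat <- outer((b_idx - pupil$center["b"])^2,
               (a_idx - pupil$center["a"])^2, "+") <= r_eff^2
  if (!any(lat)) stop("empty ROI: pupil circle outside the grid")
  za <- round(predict_surface(surfaces$anterior, d[1:2]))
  zp <- round(predict_surface(surfaces$posterior, d[1:2]))
  lens_mask <- array(FALSE, d)
  slab_mask <- array(FALSE, d)
  nominal <- 0L; included <- 0L
  for (b in b_idx) {
    for (a in which(lat[b, ])) {
      l1 <- za[b, a] + 1L; l2 <- zp[b, a] - 1L
      if (l1 >= 1L && l1 <= l2 && l2 <= d[3])
        lens_mask[b, a, l1:l2] <- TRUE
      s1 <- zp[b, a] + 1L; s2 <- zp[b, a] + slab_px
      nominal <- nominal + slab_px
      s2c <- min(s2, d[3])
      if (s1 >= 1L && s1 <= s2c) {
        slab_mask[b, a, s1:s2c] <- TRUE
        included <- included + (s2c - s1 + 1L)
      }
    }
  }
  coverage <- included / max(nominal, 1L)
  if (!any(slab_mask)) stop("empty ROI: slab mask is empty")
  if (coverage < 0.5)
    stop(sprintf(paste0("slab coverage %.0f%% < 50%%: zero-delay placement ",
                        "leaves too little vitreous in the grid"),
                 100 * coverage))
  structure(list(anterior = surfaces$anterior,
                 posterior = surfaces$posterior,
                 pupil = pupil[c("center", "radius_px")],
                 lens_mask = lens_mask, slab_mask = slab_mask,
                 slab_thickness_mm = slab_thickness_mm,
                 slab_px = slab_px, slab_coverage = coverage),
            class = "segmentation_result")
}

#' Segment a motion-corrected volume end to end
#'
#' Convenience wrapper: [detect_pupil()], [segment_lens_interfaces()],
#' [build_rois()].
#'
#' @inheritParams build_rois
#' @param params forwarded to the interface segmentation.
#' @return A `segmentation_result`.
#' @export
segment_volume <- function(volume, slab_thickness_mm = 2.0, params = list()) {
  surfaces <- segment_lens_interfaces(volume, params)
  build_rois(volume, surfaces, slab_thickness_mm = slab_thickness_mm)
}
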