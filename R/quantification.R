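# ---- opacification indices ------------------------------------------------

mean_db_over_mask <- function(volume, mask, what) {
  stopifnot(inherits(volume, "oct_volume"))
  if (!identical(dim(mask), dim(volume$intensity)))
    stop(what, ": mask dimensions do not match the volume")
  n <- sum(mask)
  if (n == 0) stop(what, ": empty ROI mask")
  vals <- volume$intensity[mask]
  if (any(vals < 0)) stop(what, ": negative linear intensities")
  linear_to_db(mean(vals))
}

#' Vitreous and lens optical density
#'
#' Mean of the linear-scale OCT signal over the ROI, reported on the dB
#' scale: `10 * log10(mean(I))` arbitrary units. Averaging is done in
#' linear scale and converted afterwards.
#'
#' @param volume linear-scale [oct_volume()].
#' @param slab_mask,lens_mask logical 3-D ROI masks (e.g. from
#'   [build_rois()]).
#' @return Optical density in au (a single number).
#' @export
compute_vod <- function(volume, slab_mask)
  mean_db_over_mask(volume, slab_mask, "VOD")

#' @rdname compute_vod
#' @export
compute_lod <- function(volume, lens_mask)
  mean_db_over_mask(volume, lens_mask, "LOD")

#' Vitreous opacification ratio
#'
#' Fraction of slab voxels whose signal exceeds the opacity threshold:
#' `VOR = |{v in slab : 10*log10(I_v) > threshold_dB}| / |slab|`, ranging
#' from 0 (no opacification above the threshold) to 1 (totally opacified).
#'
#' @inheritParams compute_vod
#' @param threshold_db opacity threshold in dB (default 78).
#' @return VOR in `[0, 1]`.
#' @export
compute_vor <- function(volume, slab_mask, threshold_db = 78) {
  if (!identical(dim(slab_mask), dim(volume$intensity)))
    stop("VOR: mask dimensions do not match the volume")
  if (sum(slab_mask) == 0) stop("VOR: empty ROI mask")
  vals <- volume$intensity[slab_mask]
  mean(vals > db_to_linear(threshold_db))
}

#' Opacification indices for one acquisition
#'
#' Bundles VOD, LOD and VOR computed from a segmented volume.
#'
#' @inheritParams compute_vor
#' @param seg a `segmentation_result` from [build_rois()].
#' @return Object of class `opacity_indices` with fields `VOD`, `LOD`,
#'   `VOR`, `threshold_db`, `n_slab_voxels`, `n_lens_voxels`.
#' @export
opacity_indices <- function(volume, seg, threshold_db = 78) {
  stopifnot(inherits(seg, "segmentation_result"))
  structure(list(VOD = compute_vod(volume, seg$slab_mask),
                 LOD = compute_lod(volume, seg$lens_mask),
                 VOR = compute_vor(volume, seg$slab_mask, threshold_db),
                 threshold_db = threshold_db,
                 n_slab_voxels = sum(seg$slab_mask),
                 n_lens_voxels = sum(seg$lens_mask)),
            class = "opacity_indices")
}

#' @export
print.opacity_indices <- function(x, ...) {
  cat(sprintf("VOD %.2f au | LOD %.2f au | VOR %.4f (>%g dB)\n",
              x$VOD, x$LOD, x$VOR, x$threshold_db))
  invisible(x)
}

#' Average replicate acquisitions
#'
#' Arithmetic mean of VOD, LOD (in au) and VOR over replicate
#' [opacity_indices()] of one eye. All replicates must share the threshold.
#'
#' @param replicates list of `opacity_indices` (length >= 1).
#' @return A single `opacity_indices` object.
#' @export
average_replicates <- function(replicates) {
  if (!length(replicates)) stop("need at least one replicate")
  stopifnot(all(vapply(replicates, inherits, TRUE, "opacity_indices")))
  thr <- unique(vapply(replicates, `[[`, 1, "threshold_db"))
  if (length(thr) != 1)
    stop("replicates computed with different thresholds: ",
         paste(thr, collapse = ", "))
  avg <- function(f) mean(vapply(replicates, `[[`, 1, f))
  structure(list(VOD = avg("VOD"), LOD = avg("LOD"), VOR = avg("VOR"),
                 threshold_db = thr,
                 n_slab_voxels = avg("n_slab_voxels"),
                 n_lens_voxels = avg("n_lens_voxels")),
            class = "opacity_indices")
}

# ---- depth-coded maximum intensity projection -----------------------------

#' Depth-coded maximum intensity projection of the retrolental slab
#'
#' Per lateral position, the maximum slab intensity along depth and the
#' depth of the maximising voxel measured from the local posterior capsule
#' surface (mm). Ties take the shallowest maximum. Lateral positions with
#' no slab voxels are `NA`.
#'
#' @param volume linear-scale [oct_volume()].
#' @param seg a `segmentation_result` (supplies the slab mask and the
#'   posterior capsule surface).
#' @return Object of class `depth_mip`: `intensity` (B x A), `depth_mm`
#'   (B x A, in `[0, slab_thickness_mm]`), `orientation` labels.
#' @export
depth_mip <- function(volume, seg) {
  stopifnot(inherits(volume, "oct_volume"),
            inherits(seg, "segmentation_result"))
  d <- dim(volume$intensity)
  dz <- volume$spacing[3]
  zp <- round(predict_surface(seg$posterior, d[1:2]))
  inten <- matrix(NA_real_, d[1], d[2])
  depth <- matrix(NA_real_, d[1], d[2])
  for (b in seq_len(d[1])) {
    cols <- which(apply(seg$slab_mask[b, , , drop = FALSE], 2, any))
    if (!length(cols)) next
    page <- volume$intensity[b, , ]
    msk <- seg$slab_mask[b, , ]
    page[!msk] <- -Inf
    zmax <- max.col(page, ties.method = "first")
    inten[b, cols] <- page[cbind(cols, zmax[cols])]
    depth[b, cols] <- (zmax[cols] - zp[b, cols]) * dz
  }
  structure(list(intensity = inten, depth_mm = depth,
                 slab_thickness_mm = seg$slab_thickness_mm,
                 orientation = c(left = "T", right = "N",
                                 top = "S", bottom = "I")),
            class = "depth_mip")
}
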