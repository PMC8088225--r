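#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> motion-correct -> segment -> quantify -> CSF ->
#' statistics from a single configuration, writing every stage's outputs
#' and a machine-readable run manifest (file hashes, seeds, versions) into
#' `out_dir`. Identical configuration and seed give byte-identical outputs.
#'
#' The configuration is a named list (or path to a JSON file with the same
#' structure): `out_dir`; `seed` (master seed; each stage derives its own
#' by a fixed offset); `phantom` and `cohort` (argument overrides for
#' [phantom_spec()] / [cohort_spec()]); `threshold_db`; `slab_thickness_mm`;
#' `stages` (subset of `c("simulate", "correct", "segment", "quantify",
#' "csf", "stats")`); `transverse` (logical, transverse correction on/off).
#'
#' @param config named list or path to a JSON config.
#' @return Invisibly, a list with the run `manifest` and the in-memory
#'   stage results (`indices`, `report`, paths). On error the failing stage
#'   is named and partial outputs are preserved.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(
    out_dir = tempfile("vitreoct_run_"), seed = 1L,
    phantom = list(), cohort = list(),
    threshold_db = 78, slab_thickness_mm = 2,
    stages = c("simulate", "correct", "segment", "quantify", "csf",
               "stats"),
    transverse = TRUE), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  outputs <- character(0)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial outputs in ", cfg$out_dir, ")", call. = FALSE))
  }
  `%has%` <- function(x, s) s %in% x

  volume <- NULL; seg <- NULL
  if (cfg$stages %has% "simulate") {
    stage("simulate", {
      pspec <- do.call(phantom_spec,
                       utils::modifyList(cfg$phantom,
                                         list(seed = seed,
                                              slab_thickness_mm =
                                                cfg$slab_thickness_mm),
                                         keep.null = TRUE))
      ph <- make_phantom(pspec)
      results$phantom_truth <- ph$truth
      volume <- if (!is.null(ph$moving)) ph$moving else ph$volume
      p <- file.path(cfg$out_dir, "volume_raw.tif")
      outputs <- c(outputs, write_volume(volume, p))
    })
  }
  if (cfg$stages %has% "correct") {
    stage("correct", {
      if (is.null(volume)) stop("no volume to correct")
      mc <- correct_motion(volume, transverse = isTRUE(cfg$transverse))
      volume <- mc$volume
      results$trace <- mc$trace
      tp <- file.path(cfg$out_dir, "trace.csv")
      utils::write.csv(data.frame(b = seq_along(mc$trace$axial_px),
                                  axial_px = mc$trace$axial_px,
                                  lateral_px = mc$trace$lateral_px),
                       tp, row.names = FALSE)
      vp <- file.path(cfg$out_dir, "volume_corrected.tif")
      outputs <- c(outputs, tp, write_volume(volume, vp))
    })
  }
  if (cfg$stages %has% "segment") {
    stage("segment", {
      if (is.null(volume)) stop("no volume to segment")
      seg <- segment_volume(volume,
                             slab_thickness_mm = cfg$slab_thickness_mm)
      results$segmentation <- seg
      sp <- file.path(cfg$out_dir, "segmentation.json")
      jsonlite::write_json(list(
        anterior_coef = as.list(seg$anterior$coef),
        posterior_coef = as.list(seg$posterior$coef),
        pupil_center_px = as.list(seg$pupil$center),
        pupil_radius_px = seg$pupil$radius_px,
        slab_px = seg$slab_px, slab_coverage = seg$slab_coverage),
        sp, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, sp)
    })
  }
  if (cfg$stages %has% "quantify") {
    stage("quantify", {
      if (is.null(seg)) stop("no segmentation to quantify")
      ind <- opacity_indices(volume, seg, threshold_db = cfg$threshold_db)
      results$indices <- ind
      ip <- file.path(cfg$out_dir, "indices.json")
      jsonlite::write_json(list(VOD_au = ind$VOD, LOD_au = ind$LOD,
                                VOR = ind$VOR,
                                threshold_dB = ind$threshold_db,
                                n_slab_voxels = ind$n_slab_voxels,
                                n_lens_voxels = ind$n_lens_voxels),
                           ip, auto_unbox = TRUE, digits = NA)
      mip <- depth_mip(volume, seg)
      results$mip <- mip
      outputs <- c(outputs, ip)
    })
  }
  cohort <- NULL
  if (cfg$stages %has% "csf" || cfg$stages %has% "stats") {
    stage("cohort", {
      cspec <- do.call(cohort_spec,
                       utils::modifyList(cfg$cohort,
                                         list(seed = seed + 1000L),
                                         keep.null = TRUE))
      cohort <- make_cohort(cspec)
      cp <- file.path(cfg$out_dir, "cohort.csv")
      outputs <- c(outputs, write_cohort(cohort, cp))
    })
  }
  if (cfg$stages %has% "csf") {
    stage("csf", {
      aul <- aulcsf_by_eye(cohort$csf)
      results$aulcsf <- aul
      ap <- file.path(cfg$out_dir, "aulcsf.csv")
      utils::write.csv(aul, ap, row.names = FALSE)
      outputs <- c(outputs, ap)
    })
  }
  if (cfg$stages %has% "stats") {
    stage("stats", {
      report <- analyze_cohort(cohort, seed = seed + 2000L)
      results$report <- report
      rp <- file.path(cfg$out_dir, "stats_report.json")
      jsonlite::write_json(report_to_list(report), rp, auto_unbox = TRUE,
                           digits = NA)
      outputs <- c(outputs, rp)
    })
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")], cfg_path,
                       auto_unbox = TRUE, digits = NA)
  outputs <- unique(c(outputs, cfg_path))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = seed,
    package_version = as.character(utils::packageVersion("vitreoct")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = as.list(tools::md5sum(sort(outputs))))
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(list(manifest = manifest, out_dir = cfg$out_dir), results))
}

# flatten a cohort_report into JSON-friendly lists
report_to_list <- function(report) {
  list(
    n = report$n,
    icc = lapply(report$icc, function(ic)
      list(icc = ic$icc, ci95 = ic$ci95, f = ic$f_stat, p = ic$p_value)),
    correlations = lapply(report$correlations, function(cr)
      list(r = cr$r, ci95 = cr$ci95, p = cr$p_value, n = cr$n)),
    al_groups = lapply(report$al_groups, function(g)
      list(test = g$test, p = g$p_value, summary = g$summary)),
    loess = report$loess,
    stepwise = lapply(report$stepwise, function(sw)
      list(selected = sw$selected, std_beta = as.list(sw$std_beta),
           adj_r2 = sw$adj_r2, p = sw$p_value)))
}
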