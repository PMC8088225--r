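#' OCT volume container
#'
#' An `oct_volume` holds a 3-D grid of OCT intensities indexed `[b, a, z]`
#' (b = B-scan / slow axis, a = A-scan / fast axis, z = depth pixel), together
#' with per-voxel spacing and acquisition metadata. Depth index z = 1
#' corresponds to the zero delay line; depth increases away from the
#' instrument. All modules in the package share this coordinate convention.
#'
#' Linear-scale intensities are snapped to 32-bit float precision on
#' construction, which is the precision the on-disk TIFF container stores;
#' write/read round trips are then bit-exact.
#'
#' @param intensity numeric 3-D array, dimensions `(n_b, n_a, n_z)`, all
#'   values non-negative when `scale = "linear"`.
#' @param spacing numeric length-3 vector `(dy_mm, dx_mm, dz_mm)`: voxel pitch
#'   along the slow, fast and depth axes in millimetres. Defaults to the
#'   8 mm / 300 lateral and 8 mm / 1200 axial pitch of the acquisition
#'   geometry this package targets.
#' @param scale `"linear"` or `"dB"`. dB volumes are accepted on input only;
#'   [read_volume()] converts them to linear via `I = 10^(dB/10)`.
#' @param meta free-form named list of acquisition metadata (seed, phantom
#'   parameters for synthetic volumes, provenance, ...).
#' @return An object of class `oct_volume`: a list with elements `intensity`,
#'   `spacing`, `scale`, `meta`.
#' @seealso [read_volume()], [write_volume()], [make_phantom()]
#' @export
oct_volume <- function(intensity,
                       spacing = c(8 / 300, 8 / 300, 8 / 1200),
                       scale = c("linear", "dB"),
                       meta = list()) {
  scale <- match.arg(scale)
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("'intensity' must be a 3-D array indexed [b, a, z]")
  d <- dim(intensity)
  if (any(d < c(8L, 8L, 16L)))
    stop("volume too small: grid dimensions must be at least (8, 8, 16)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive voxel pitches (mm)")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop("intensity grid contains non-finite values")
  if (scale == "linear" && any(intensity < 0))
    stop("negative intensities are invalid on the linear scale")
  intensity <- snap_float32(intensity)
  structure(list(intensity = intensity, spacing = spacing,
                 scale = scale, meta = meta),
            class = "oct_volume")
}

# Round doubles to the nearest IEEE 754 single-precision value (the stored
# precision of the TIFF container).
snap_float32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.vector(as.double(x)), raw(), size = 4L),
               what = "double", n = length(x), size = 4L)
  dim(y) <- d
  y
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("oct_volume: %d B-scans x %d A-scans x %d depth px (%s scale)\n",
              d[1], d[2], d[3], x$scale))
  cat(sprintf("  spacing (dy, dx, dz) mm: %.5f %.5f %.5f\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  field of view: %.2f x %.2f x %.2f mm\n",
              d[1] * x$spacing[1], d[2] * x$spacing[2], d[3] * x$spacing[3]))
  invisible(x)
}

# IEEE-754 float32 bit patterns as unsigned 32-bit numbers (held in
# doubles) and back
float32_to_u32 <- function(x) {
  ki <- readBin(writeBin(as.double(x), raw(), size = 4L), "integer",
                n = length(x), size = 4L)
  ifelse(ki < 0, ki + 2^32, ki)
}

u32_to_float32 <- function(k) {
  ki <- as.integer(ifelse(k >= 2^31, k - 2^32, k))
  readBin(writeBin(ki, raw(), size = 4L), "double",
          n = length(ki), size = 4L)
}

#' Write an OCT volume as a multi-page TIFF plus JSON sidecar
#'
#' One TIFF page per B-scan (rows = A-scans). Intensities are float32
#' (the precision [oct_volume()] snaps to); since the TIFF writer only
#' stores integer samples in `[0, 1]`, each float32 is written losslessly
#' as its IEEE-754 bit pattern split into two 16-bit words (the page is
#' twice as wide as the depth axis: high words first, then low words).
#' The round trip is therefore bit-exact.
#'
#' @param volume an [oct_volume()].
#' @param path path of the TIFF file to create; the sidecar is written next
#'   to it as `<path>.json`.
#' @return Invisibly, a character vector with the TIFF and sidecar paths.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  d <- dim(volume$intensity)
  pages <- lapply(seq_len(d[1]), function(b) {
    k <- float32_to_u32(volume$intensity[b, , , drop = TRUE])
    cbind(matrix(k %/% 65536, d[2], d[3]),
          matrix(k %% 65536, d[2], d[3])) / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE,
                        compression = "none")
  if (ok != d[1]) stop("failed to write all TIFF pages to ", path)
  sidecar <- list(shape = d,
                  spacing_mm = volume$spacing,
                  scale = volume$scale,
                  encoding = "ieee754_float32_hilo16",
                  z0 = "zero_delay_line",
                  meta = volume$meta)
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(c(tiff = path, sidecar = sidecar_path(path)))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read an OCT volume written by [write_volume()]
#'
#' dB-scale files are converted to linear intensity on load using the
#' package-wide convention `I_linear = 10^(dB/10)`.
#'
#' @param path path to the multi-page TIFF; the JSON sidecar is expected at
#'   `<path>.json`.
#' @return An [oct_volume()] on the linear scale.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata error: sidecar ", sp, " is missing")
  sc <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  shape <- as.integer(sc$shape)
  if (length(pages) != shape[1] ||
      !all(dim(pages[[1]]) == c(shape[2], 2L * shape[3])))
    stop(sprintf(
      "geometry error: sidecar declares %dx%dx%d but stack holds %d pages of %s",
      shape[1], shape[2], shape[3], length(pages),
      paste(dim(pages[[1]]), collapse = "x")))
  nz <- shape[3]
  intensity <- array(0, dim = shape)
  for (b in seq_len(shape[1])) {
    words <- round(pages[[b]] * 65535)
    k <- words[, seq_len(nz)] * 65536 + words[, nz + seq_len(nz)]
    page <- u32_to_float32(k)
    dim(page) <- c(shape[2], nz)
    intensity[b, , ] <- page
  }
  if (identical(sc$scale, "dB")) {
    intensity <- 10^(intensity / 10)
    sc$scale <- "linear"
  }
  if (any(intensity < 0))
    stop("validation error: negative linear intensities in ", path)
  meta <- if (is.null(sc$meta)) list() else sc$meta
  oct_volume(intensity, spacing = as.numeric(sc$spacing_mm),
             scale = "linear", meta = meta)
}

#' Cohort tables
#'
#' A cohort table bundles the per-acquisition measurement records with the
#' long-format contrast-sensitivity samples:
#' \describe{
#'   \item{records}{one row per subject / eye / replicate with columns
#'     `subject_id`, `eye` ("OD"/"OS"), `replicate`, `age` (years), `AL`
#'     (axial length, mm), `sphere` (D), `cylinder` (D), `OSI`
#'     (dimensionless), `VOD` (au), `LOD` (au), `VOR` (fraction), `AULCSF`.}
#'   \item{csf}{one row per subject / eye / spatial frequency with columns
#'     `subject_id`, `eye`, `frequency_cpd`, `cs`.}
#' }
#'
#' @param records data frame of measurement records (may have zero rows).
#' @param csf data frame of CSF samples (may have zero rows).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(records, csf) {
  records <- as.data.frame(records)
  csf <- as.data.frame(csf)
  if (nrow(records) > 0) {
    need <- c("subject_id", "eye", "replicate")
    miss <- setdiff(need, names(records))
    if (length(miss))
      stop("cohort records lack key columns: ", paste(miss, collapse = ", "))
    key <- interaction(records$subject_id, records$eye, records$replicate,
                       drop = TRUE)
    if (anyDuplicated(key))
      stop("duplicate subject/eye/replicate keys in cohort records")
    num <- setdiff(names(records), c("subject_id", "eye"))
    for (cn in num)
      if (!is.numeric(records[[cn]]))
        stop("non-numeric cohort field: ", cn)
  }
  structure(list(records = records, csf = csf), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d measurement rows (%d subjects), %d CSF rows\n",
              nrow(x$records),
              length(unique(x$records$subject_id)), nrow(x$csf)))
  invisible(x)
}

#' Write / read a cohort table as a pair of CSV files
#'
#' `write_cohort()` writes `<path>` (measurement records) and
#' `<path_prefix>_csf.csv` (long-format CSF samples). `read_cohort()` reads
#' them back; an empty records file yields an empty cohort, not an error.
#'
#' @param cohort a [cohort_table()].
#' @param path path of the records CSV.
#' @return `write_cohort()` invisibly returns the two paths; `read_cohort()`
#'   returns a [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(cohort$records, path, row.names = FALSE)
  utils::write.csv(cohort$csf, csf_path(path), row.names = FALSE)
  invisible(c(records = path, csf = csf_path(path)))
}

csf_path <- function(path) sub("\\.csv$", "", path) |> paste0("_csf.csv")

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such cohort file: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  csf <- if (file.exists(csf_path(path)))
    utils::read.csv(csf_path(path), stringsAsFactors = FALSE)
  else
    data.frame(subject_id = character(), eye = character(),
               frequency_cpd = numeric(), cs = numeric())
  cohort_table(records, csf)
}

#' Convert between linear intensity and decibels
#'
#' The package-wide convention is `dB = 10 * log10(I / reference)` with a
#' unit reference, so the opacification threshold (78 dB), VOD and LOD all
#' live on one scale.
#'
#' @param x numeric values to convert.
#' @param reference linear-scale reference intensity (default 1).
#' @return Converted numeric values.
#' @export
linear_to_db <- function(x, reference = 1) 10 * log10(x / reference)

#' @rdname linear_to_db
#' @export
db_to_linear <- function(x, reference = 1) reference * 10^(x / 10)
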