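#' Area under the log-log contrast sensitivity function
#'
#' Trapezoidal integral of `log10(CS)` over `log10(spatial frequency)`
#' across the measured frequency range. No parametric CSF model is fitted
#' and `log10(CS)` is not floored at zero: samples with CS below 1
#' contribute negatively, as measured.
#'
#' @param samples two-column matrix or data frame: spatial frequency (cpd)
#'   and contrast sensitivity. At least two distinct frequencies, all
#'   positive, with positive sensitivities.
#' @return AULCSF in (log10 cpd) x (log10 CS) units.
#' @export
compute_aulcsf <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) < 2) stop("'samples' needs (frequency, CS) columns")
  f <- as.numeric(samples[, 1]); cs <- as.numeric(samples[, 2])
  keep <- order(f)
  f <- f[keep]; cs <- cs[keep]
  if (length(f) < 2 || length(unique(f)) < 2)
    stop("need at least 2 samples at distinct spatial frequencies")
  if (any(!is.finite(f)) || any(f <= 0))
    stop("spatial frequencies must be positive and finite")
  if (any(!is.finite(cs)) || any(cs <= 0))
    stop("contrast sensitivities must be positive and finite")
  if (any(duplicated(f))) stop("duplicate spatial frequencies")
  lf <- log10(f); ls <- log10(cs)
  sum(diff(lf) * (ls[-length(ls)] + ls[-1]) / 2)
}

#' AULCSF per subject and eye
#'
#' Applies [compute_aulcsf()] to each subject/eye group of a long-format
#' CSF table.
#'
#' @param csf data frame with columns `subject_id`, `eye`, `frequency_cpd`,
#'   `cs` (the `csf` component of a [cohort_table()]).
#' @return Data frame with columns `subject_id`, `eye`, `AULCSF`.
#' @export
aulcsf_by_eye <- function(csf) {
  need <- c("subject_id", "eye", "frequency_cpd", "cs")
  miss <- setdiff(need, names(csf))
  if (length(miss)) stop("CSF table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(csf))
    return(data.frame(subject_id = character(), eye = character(),
                      AULCSF = numeric()))
  groups <- split(csf, interaction(csf$subject_id, csf$eye, drop = TRUE))
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(subject_id = g$subject_id[1], eye = g$eye[1],
               AULCSF = compute_aulcsf(g[, c("frequency_cpd", "cs")]))))
  rownames(out) <- NULL
  out
}
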