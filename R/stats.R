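# ---- reproducibility ------------------------------------------------------

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Reproducibility of a measurement repeated `k` times on each of `n`
#' subjects, from the one-way ANOVA mean squares:
#' `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`. The 95% confidence interval
#' and p value follow from the F statistic `MSB/MSW` with `(n - 1,
#' n(k - 1))` degrees of freedom (Searle bounds).
#'
#' @param data numeric n x k matrix (rows = subjects, columns = replicates),
#'   complete.
#' @param conf confidence level (default 0.95).
#' @return Object of class `icc_result`: `icc`, `ci95`, `f_stat`,
#'   `p_value`, `n`, `k`, `ms_between`, `ms_within`, and `degenerate`
#'   (TRUE when the total variance is zero and the ICC is undefined).
#' @export
icc_oneway <- function(data, conf = 0.95) {
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 replicates")
  if (anyNA(data)) stop("ICC needs a complete subject x replicate matrix")
  long <- data.frame(y = as.vector(data),
                     subject = factor(rep(seq_len(n), times = k)))
  tab <- withCallingHandlers(
    stats::anova(stats::aov(y ~ subject, data = long)),
    warning = function(w) {
      # perfect within-subject agreement is a legitimate input here (the
      # F statistic is recomputed below); silence the fitter's note
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  msb <- tab["subject", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  if (msb + msw < .Machine$double.eps)
    return(structure(list(icc = NA_real_, ci95 = c(NA_real_, NA_real_),
                          f_stat = NA_real_, p_value = NA_real_,
                          n = n, k = k, ms_between = msb, ms_within = msw,
                          degenerate = TRUE),
                     class = "icc_result"))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- msb / msw
  df1 <- n - 1; df2 <- n * (k - 1)
  alpha <- 1 - conf
  fl <- f / stats::qf(1 - alpha / 2, df1, df2)
  fu <- f * stats::qf(1 - alpha / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  structure(list(icc = icc, ci95 = ci, f_stat = f, p_value = p,
                 n = n, k = k, ms_between = msb, ms_within = msw,
                 degenerate = FALSE),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) cat("ICC undefined (zero total variance)\n")
  else cat(sprintf("ICC(1) = %.3f (95%% CI %.3f-%.3f), F = %.2f, p = %.3g\n",
                   x$icc, x$ci95[1], x$ci95[2], x$f_stat, x$p_value))
  invisible(x)
}

# ---- correlation ----------------------------------------------------------

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return Object of class `correlation_result`: `r`, `ci95`, `p_value`,
#'   `n`.
#' @export
pearson_ci <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in correlation input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in correlation input")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  ci <- if (is.null(ct$conf.int)) c(NA_real_, NA_real_)
        else as.numeric(ct$conf.int)
  structure(list(r = unname(ct$estimate), ci95 = ci,
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson R = %.3f [%.3f, %.3f], p = %.3g, n = %d\n",
              x$r, x$ci95[1], x$ci95[2], x$p_value, x$n))
  invisible(x)
}

#' Compare a straight-line fit with LOESS
#'
#' Residual standard error of the linear model versus a degree-2 LOESS
#' smoother with the given span. The linear RSE uses `n - 2` residual
#' degrees of freedom; the LOESS RSE uses `n` minus the trace of the
#' smoother matrix (the convention of the LOESS fitter itself).
#'
#' @param x,y numeric vectors, n >= 10.
#' @param span LOESS span as a fraction of the points, in (0, 1].
#' @return List with `linear_rse`, `loess_rse`, `loess_enp` (equivalent
#'   number of parameters).
#' @export
loess_compare <- function(x, y, span = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("LOESS comparison needs n >= 10")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  lin <- stats::lm(y ~ x)
  lo <- stats::loess(y ~ x, span = span, degree = 2,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  list(linear_rse = summary(lin)$sigma,
       loess_rse = lo$s,
       loess_enp = lo$enp)
}

# ---- group comparison -----------------------------------------------------

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk normality test on each group at alpha = 0.05; the
#' independent-samples t test (two-sided) is used when both groups are
#' normal, the Mann-Whitney U test otherwise. Summaries follow the same
#' gate: mean +/- sd when normal, median (Q1-Q3) otherwise.
#'
#' @param group_a,group_b numeric vectors, each n >= 3.
#' @param labels length-2 character vector naming the groups.
#' @return Object of class `group_comparison`: per-group `summary` strings
#'   and statistics, `test` ("t" or "mann-whitney"), `p_value`,
#'   `normality_p` per group.
#' @export
normality_gated_test <- function(group_a, group_b,
                                 labels = c("A", "B")) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs n >= 3")
  sw_p <- function(g) {
    if (stats::sd(g) == 0) return(0)   # constant: treat as non-normal
    stats::shapiro.test(g)$p.value
  }
  pa <- sw_p(group_a); pb <- sw_p(group_b)
  normal <- pa > 0.05 && pb > 0.05
  if (normal) {
    tt <- stats::t.test(group_a, group_b)
    test <- "t"; p <- tt$p.value
  } else {
    wt <- stats::wilcox.test(group_a, group_b, exact = FALSE)
    test <- "mann-whitney"; p <- wt$p.value
  }
  summarize <- function(g, normal_g) {
    if (normal_g) sprintf("%.3g ± %.3g", mean(g), stats::sd(g))
    else {
      q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
      sprintf("%.3g (%.3g-%.3g)", q[2], q[1], q[3])
    }
  }
  structure(list(labels = labels,
                 summary = c(summarize(group_a, pa > 0.05),
                             summarize(group_b, pb > 0.05)),
                 n = c(length(group_a), length(group_b)),
                 test = test, p_value = p,
                 normality_p = c(pa, pb)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s (n=%d) vs %s: %s (n=%d)\n  %s test, p = %.4g\n",
              x$labels[1], x$summary[1], x$n[1],
              x$labels[2], x$summary[2], x$n[2], x$test, x$p_value))
  invisible(x)
}

# ---- Tukey ladder of powers ----------------------------------------------

#' Tukey ladder-of-powers transformation
#'
#' Selects the power `lambda` from a grid that maximises the Shapiro-Wilk W
#' of the transformed sample. The transform is `x^lambda` for positive
#' `lambda`, `log(x)` at zero and `-x^lambda` for negative `lambda` — a
#' monotone increasing map in every case. Non-positive inputs are shifted
#' to `min(x) + 1` first (recorded in the result).
#'
#' @param x numeric vector, n >= 3, non-constant.
#' @param grid candidate powers (default `seq(-2, 2, 0.025)`).
#' @return List with `x` (transformed), `lambda`, `W`, `shift`.
#' @export
tukey_ladder <- function(x, grid = seq(-2, 2, by = 0.025)) {
  if (length(x) < 3) stop("Tukey ladder needs n >= 3")
  if (stats::sd(x) == 0) stop("constant input cannot be transformed")
  shift <- 0
  if (min(x) <= 0) {
    shift <- -min(x) + 1
    x <- x + shift
  }
  apply_lambda <- function(x, l) {
    if (l > 0) x^l else if (l == 0) log(x) else -(x^l)
  }
  w <- vapply(grid, function(l) {
    xt <- apply_lambda(x, l)
    if (stats::sd(xt) == 0) return(-Inf)
    tryCatch(stats::shapiro.test(xt)$statistic, error = function(e) -Inf)
  }, 1)
  best <- which.max(w)
  list(x = apply_lambda(x, grid[best]), lambda = grid[best],
       W = w[best], shift = shift)
}

# ---- forward stepwise regression ------------------------------------------

#' Forward stepwise linear regression with standardized coefficients
#'
#' Forward selection by AIC from the empty model over the given candidate
#' set, with standardized beta coefficients (`b * sd(x)/sd(y)`), adjusted
#' R-squared and the overall model F-test p value.
#'
#' @param data data frame with complete cases for response and candidates.
#' @param response name of the response column.
#' @param candidates character vector of candidate predictor names
#'   (defaults to every other numeric column).
#' @return Object of class `stepwise_model`: `response`, `selected`,
#'   `coef`, `std_beta`, `adj_r2`, `p_value`, `aic_path`, and the fitted
#'   `lm` in `$fit`.
#' @export
stepwise_forward <- function(data, response, candidates = NULL) {
  data <- as.data.frame(data)
  if (is.null(candidates)) {
    num <- names(data)[vapply(data, is.numeric, TRUE)]
    candidates <- setdiff(num, response)
  }
  cols <- c(response, candidates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[, cols]), cols]
  if (nrow(data) <= length(candidates) + 2)
    stop("too few complete cases for ", length(candidates), " candidates")
  if (length(candidates) >= 2) {
    cm <- stats::cor(data[, candidates])
    off <- which(abs(cm) >= 1 - 1e-12 & row(cm) < col(cm), arr.ind = TRUE)
    if (nrow(off))
      stop("collinear candidate pair: ",
           candidates[off[1, 1]], " and ", candidates[off[1, 2]])
  }
  null_fit <- stats::lm(stats::reformulate("1", response), data = data)
  scope <- stats::reformulate(candidates)
  fit <- MASS::stepAIC(null_fit, scope = list(lower = ~1, upper = scope),
                       direction = "forward", trace = 0)
  selected <- attr(stats::terms(fit), "term.labels")
  cf <- stats::coef(fit)
  std_beta <- if (length(selected))
    vapply(selected, function(v)
      cf[[v]] * stats::sd(data[[v]]) / stats::sd(data[[response]]), 1)
  else numeric(0)
  sm <- summary(fit)
  p_model <- if (length(selected)) {
    f <- sm$fstatistic
    stats::pf(f[1], f[2], f[3], lower.tail = FALSE)
  } else NA_real_
  structure(list(response = response, candidates = candidates,
                 selected = selected, coef = cf, std_beta = std_beta,
                 adj_r2 = sm$adj.r.squared, p_value = unname(p_model),
                 aic_path = fit$anova$AIC, fit = fit, n = nrow(data)),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise model for %s: %s\n", x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(empty)"))
  if (length(x$std_beta)) {
    cat("  standardized beta:",
        paste(sprintf("%s = %.3f", names(x$std_beta), x$std_beta),
              collapse = ", "), "\n")
  }
  cat(sprintf("  adjusted R2 = %.3f, model p = %.3g, n = %d\n",
              x$adj_r2, x$p_value, x$n))
  invisible(x)
}

# ---- cohort helpers -------------------------------------------------------

#' Select one eye per subject at random
#'
#' Avoids the bias of the bilateral-eye correlation: for subjects with both
#' eyes in the table, one eye is chosen uniformly at random (all its
#' replicate rows are kept); single-eye subjects pass through.
#'
#' @param cohort a [cohort_table()].
#' @param seed RNG seed for the selection.
#' @return A [cohort_table()] with one eye per subject (CSF table filtered
#'   to the same eyes).
#' @export
one_eye_per_subject <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  rec <- cohort$records
  if (!nrow(rec)) return(cohort)
  set.seed(seed)
  keep_key <- vapply(split(rec, rec$subject_id), function(g) {
    eyes <- unique(g$eye)
    paste(g$subject_id[1], sample(eyes, 1), sep = "\r")
  }, "")
  sel <- paste(rec$subject_id, rec$eye, sep = "\r") %in% keep_key
  csf <- cohort$csf
  if (nrow(csf))
    csf <- csf[paste(csf$subject_id, csf$eye, sep = "\r") %in% keep_key, ]
  cohort_table(rec[sel, ], csf)
}

#' Full statistical analysis of a cohort
#'
#' Runs the package's statistical layer on a cohort table: random one eye
#' per subject, replicate-reproducibility ICCs for VOD/VOR/LOD, the
#' pairwise Pearson correlation matrix with confidence intervals, the
#' axial-length stratified group comparison (nonmyopic AL < 23 mm vs
#' myopic AL > 25 mm) with normality gating, linear-vs-LOESS residual
#' comparisons for the age trends, and forward stepwise models for each
#' index (candidates restricted to VOD, VOR, LOD, age, AL and AULCSF;
#' non-normal variables are Tukey-transformed first).
#'
#' @param cohort a [cohort_table()].
#' @param seed RNG seed (eye selection).
#' @param loess_span span for the LOESS comparisons.
#' @return A list of class `cohort_report` with components `icc`,
#'   `correlations`, `al_groups`, `loess`, `stepwise`, `data` (the analysed
#'   per-eye table).
#' @export
analyze_cohort <- function(cohort, seed = 1L, loess_span = 1) {
  one <- one_eye_per_subject(cohort, seed = seed)
  rec <- one$records
  if (!nrow(rec)) stop("empty cohort")
  idx_cols <- c("VOD", "VOR", "LOD")
  # replicate matrices for ICC
  icc <- list()
  ksplit <- split(rec, rec$subject_id)
  k <- min(vapply(ksplit, nrow, 1L))
  if (k >= 2) {
    for (v in idx_cols) {
      m <- t(vapply(ksplit, function(g) g[[v]][seq_len(k)],
                    numeric(k)))
      icc[[v]] <- icc_oneway(m)
    }
  }
  # per-eye averages
  agg <- do.call(rbind, lapply(ksplit, function(g)
    data.frame(subject_id = g$subject_id[1], eye = g$eye[1],
               age = g$age[1], AL = g$AL[1], sphere = g$sphere[1],
               OSI = g$OSI[1], AULCSF = g$AULCSF[1],
               VOD = mean(g$VOD), VOR = mean(g$VOR), LOD = mean(g$LOD))))
  rownames(agg) <- NULL
  vars <- c("age", "AL", "OSI", "VOD", "VOR", "LOD", "AULCSF")
  vars <- vars[vapply(vars, function(v) stats::sd(agg[[v]]) > 0, TRUE)]
  correlations <- list()
  for (i in seq_along(vars)) for (j in seq_along(vars)) {
    if (i < j) {
      key <- paste(vars[i], vars[j], sep = "~")
      correlations[[key]] <- pearson_ci(agg[[vars[i]]], agg[[vars[j]]])
    }
  }
  # AL stratification
  al_groups <- list()
  nonmyopic <- agg$AL < 23; myopic <- agg$AL > 25
  if (sum(nonmyopic) >= 3 && sum(myopic) >= 3) {
    for (v in c("age", "sphere", "AL", "VOD", "VOR", "LOD", "OSI",
                "AULCSF"))
      al_groups[[v]] <- normality_gated_test(
        agg[[v]][nonmyopic], agg[[v]][myopic],
        labels = c("AL<23", "AL>25"))
  }
  lo <- list()
  if (nrow(agg) >= 10) {
    lo$age_VOD <- loess_compare(agg$age, agg$VOD, span = loess_span)
    lo$age_VOR <- loess_compare(agg$age, agg$VOR, span = loess_span)
  }
  # stepwise models on Tukey-transformed variables
  pool <- c("VOD", "VOR", "LOD", "age", "AL", "AULCSF")
  trans <- agg
  for (v in pool) {
    if (stats::sd(agg[[v]]) == 0) next
    if (stats::shapiro.test(agg[[v]])$p.value <= 0.05)
      trans[[v]] <- tukey_ladder(agg[[v]])$x
  }
  stepwise <- list()
  for (resp in c("VOD", "VOR", "LOD", "AULCSF"))
    stepwise[[resp]] <- stepwise_forward(trans, resp,
                                         setdiff(pool, resp))
  structure(list(icc = icc, correlations = correlations,
                 al_groups = al_groups, loess = lo,
                 stepwise = stepwise, data = agg, n = nrow(agg)),
            class = "cohort_report")
}
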