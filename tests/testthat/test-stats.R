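# literal sums-of-squares one-way ANOVA, independent of aov()
icc_by_hand <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_means <- rowMeans(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

test_that("ICC(1) equals the from-scratch ANOVA computation to 1e-10", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(40 * 3, rep(rnorm(40, 0, 3), 3)), 40, 3)
    expect_equal(icc_oneway(m)$icc, icc_by_hand(m), tolerance = 1e-10)
  }
})

test_that("identical replicates with distinct subjects give ICC = 1", {
  m <- matrix(rep(1:20, 3), 20, 3)
  r <- icc_oneway(m)
  expect_equal(r$icc, 1)
  expect_lt(r$p_value, 1e-10)
})

test_that("ICC is near zero when the subject effect is absent", {
  set.seed(21)
  iccs <- vapply(1:400, function(i)
    icc_oneway(matrix(rnorm(200 * 3), 200, 3))$icc, 1)
  expect_lt(abs(mean(iccs)), 0.02)
})

test_that("ICC recovers planted variance components with a covering CI", {
  set.seed(31)
  n <- 500; k <- 3
  subj <- rnorm(n, 0, 3)                      # sigma2_b = 9
  m <- matrix(rnorm(n * k, rep(subj, k), 1), n, k)  # sigma2_w = 1
  r <- icc_oneway(m)
  expect_equal(r$icc, 0.9, tolerance = 0.02)
  expect_true(r$ci95[1] <= r$icc && r$icc <= r$ci95[2])
  expect_true(-1 / (k - 1) <= r$icc && r$icc <= 1)
})

test_that("degenerate zero-variance data are flagged, not mangled", {
  r <- icc_oneway(matrix(5, 10, 3))
  expect_true(r$degenerate)
  expect_true(is.na(r$icc))
})

test_that("Pearson correlation matches the closed-form sums on 4 points", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 0)
  sxy <- sum(x * y) - 4 * mean(x) * mean(y)
  sxx <- sum(x^2) - 4 * mean(x)^2
  syy <- sum(y^2) - 4 * mean(y)^2
  r <- pearson_ci(x, y)
  expect_equal(r$r, sxy / sqrt(sxx * syy), tolerance = 1e-12)
  perfect <- pearson_ci(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
})

test_that("independent draws give near-zero correlation with valid CI", {
  set.seed(41)
  x <- rnorm(1000); y <- rnorm(1000)
  r <- pearson_ci(x, y)
  expect_lt(abs(r$r), 3 / sqrt(1000))
  expect_true(r$ci95[1] <= r$r && r$r <= r$ci95[2])
})

test_that("correlation is invariant to sign-preserving affine maps", {
  set.seed(43)
  x <- rnorm(60); y <- x + rnorm(60)
  r0 <- pearson_ci(x, y)$r
  expect_equal(pearson_ci(5 * x - 2, 0.1 * y + 7)$r, r0, tolerance = 1e-12)
  expect_error(pearson_ci(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("LOESS comparison behaves on linear, curved, and pure-noise data", {
  x <- seq(0, 10, length.out = 60)
  lin <- loess_compare(x, 2 * x + 1)
  expect_lt(lin$linear_rse, 1e-8)
  expect_lt(lin$loess_rse, 1e-6)
  set.seed(51)
  y_quad <- 0.5 * (x - 5)^2 + rnorm(60, 0, 0.3)
  quad <- loess_compare(x, y_quad)
  expect_lt(quad$loess_rse, quad$linear_rse)
  y_noise <- rnorm(200)
  xn <- seq_len(200)
  noise <- loess_compare(xn, y_noise)
  expect_lt(abs(noise$loess_rse / noise$linear_rse - 1), 0.1)
  expect_error(loess_compare(x, 2 * x, span = 1.5), "span")
})

test_that("the normality gate selects the right two-sample test", {
  set.seed(61)
  a <- rnorm(20); b <- rnorm(20, 5)
  g <- normality_gated_test(a, b)
  expect_equal(g$test, "t")
  expect_lt(g$p_value, 1e-6)
  expect_match(g$summary[1], "±")
  heavy_a <- rlnorm(100, sdlog = 1.5); heavy_b <- rlnorm(100, sdlog = 1.5)
  g2 <- normality_gated_test(heavy_a, heavy_b)
  expect_equal(g2$test, "mann-whitney")
  expect_match(g2$summary[1], "\\(")
  same <- c(1, 2, 3, 4, 5, 6)
  g3 <- normality_gated_test(same, same)
  expect_gt(g3$p_value, 0.95)
  expect_error(normality_gated_test(1:2, 1:5), "n >= 3")
})

test_that("the Tukey ladder finds near-identity and near-log powers", {
  set.seed(71)
  lam_norm <- vapply(1:150, function(i)
    tukey_ladder(rnorm(80, 50, 5))$lambda, 1)
  expect_true(median(lam_norm) >= 0.8 && median(lam_norm) <= 1.2)
  lam_ln <- vapply(1:150, function(i)
    tukey_ladder(rlnorm(80))$lambda, 1)
  expect_true(median(lam_ln) >= -0.2 && median(lam_ln) <= 0.2)
})

test_that("Tukey transforms preserve rank order and reject constants", {
  set.seed(73)
  x <- rlnorm(50)
  t1 <- tukey_ladder(x)
  expect_identical(rank(t1$x), rank(x))
  xs <- c(-3, rexp(30))    # non-positive values get shifted
  t2 <- tukey_ladder(xs)
  expect_identical(rank(t2$x), rank(xs))
  expect_gt(t2$shift, 0)
  expect_error(tukey_ladder(rep(2, 10)), "constant")
})

# exhaustive per-step forward AIC scan, independent of stepAIC
stepwise_by_hand <- function(data, response, candidates) {
  chosen <- character(0)
  current_aic <- stats::AIC(stats::lm(stats::reformulate("1", response),
                                      data = data))
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    aics <- vapply(remaining, function(v)
      stats::AIC(stats::lm(stats::reformulate(c(chosen, v), response),
                           data = data)), 1)
    if (min(aics) >= current_aic) break
    chosen <- c(chosen, remaining[which.min(aics)])
    current_aic <- min(aics)
  }
  chosen
}

test_that("forward stepwise recovers a planted predictor with its beta", {
  set.seed(81)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                  x4 = rnorm(n), x5 = rnorm(n))
  d$y <- 3 * d$x1 + rnorm(n)
  m <- stepwise_forward(d, "y", paste0("x", 1:5))
  expect_true("x1" %in% m$selected)
  true_beta <- 3 * stats::sd(d$x1) / stats::sd(d$y)
  expect_equal(unname(m$std_beta["x1"]), true_beta, tolerance = 0.1)
  expect_gt(m$adj_r2, 0.8)
})

test_that("selection agrees with the exhaustive per-step AIC scan", {
  set.seed(83)
  for (i in 1:10) {
    n <- 120
    d <- as.data.frame(matrix(rnorm(n * 6), n,
                              dimnames = list(NULL, paste0("x", 1:6))))
    d$y <- 1.5 * d$x2 - 1 * d$x5 + rnorm(n)
    m <- stepwise_forward(d, "y", paste0("x", 1:6))
    expect_setequal(m$selected, stepwise_by_hand(d, "y", paste0("x", 1:6)))
  }
})

test_that("pure-noise responses rarely earn explanatory power", {
  set.seed(85)
  ar2 <- vapply(1:100, function(i) {
    n <- 250
    d <- as.data.frame(matrix(rnorm(n * 5), n,
                              dimnames = list(NULL, paste0("x", 1:5))))
    d$y <- rnorm(n)
    stepwise_forward(d, "y", paste0("x", 1:5))$adj_r2
  }, 1)
  expect_gte(mean(ar2 <= 0.05, na.rm = TRUE), 0.9)
})

test_that("AIC never increases along the accepted path and collinearity errors", {
  set.seed(87)
  n <- 80
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  d$y <- d$x1 + rnorm(n)
  m <- stepwise_forward(d, "y", c("x1", "x2"))
  expect_true(all(diff(m$aic_path) <= 1e-9))
  d$x3 <- 2 * d$x1
  expect_error(stepwise_forward(d, "y", c("x1", "x3")), "collinear")
})

test_that("one eye per subject: deterministic, identity on single eyes, unbiased", {
  co <- make_cohort(cohort_spec(n = 8, seed = 3))
  a <- one_eye_per_subject(co, seed = 5)
  b <- one_eye_per_subject(co, seed = 5)
  expect_identical(a$records, b$records)
  expect_equal(length(unique(paste(a$records$subject_id, a$records$eye))), 8)
  single <- make_cohort(cohort_spec(n = 6, both_eyes = FALSE, seed = 4))
  expect_identical(one_eye_per_subject(single, seed = 1)$records,
                   single$records)
  picks <- vapply(1:300, function(s)
    one_eye_per_subject(co, seed = s)$records$eye[1], "")
  expect_true(abs(mean(picks == "OD") - 0.5) < 0.1)
})

test_that("the cohort report carries every analysis layer", {
  co <- make_cohort(cohort_spec(n = 20, seed = 12))
  rep <- analyze_cohort(co, seed = 2)
  expect_named(rep$icc, c("VOD", "VOR", "LOD"))
  expect_true(all(c("age~VOD", "VOR~AULCSF") %in% names(rep$correlations)))
  expect_named(rep$stepwise, c("VOD", "VOR", "LOD", "AULCSF"))
  expect_equal(rep$n, 20)
  expect_true(all(c("linear_rse", "loess_rse") %in%
                    names(rep$loess$age_VOD)))
})
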