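test_that("conception dates map to angles by day of year", {
  expect_equal(conception_angle(as.Date("2001-01-01")), 0)
  # 2 July of a 365-day year is day 183
  expect_equal(conception_angle(as.Date("2001-07-02")), 2 * pi * 182 / 365)
  expect_equal(conception_angle(as.Date("2001-07-02")), 3.1330, tolerance = 1e-4)
  expect_lt(conception_angle(as.Date("2001-12-31")), 2 * pi)
  expect_lt(conception_angle(as.Date("2000-12-31")), 2 * pi)  # leap year
  expect_equal(conception_angle(as.Date("2000-12-31")), 2 * pi * 365 / 366)
  # fixed convention divides by 365.25 regardless of year
  expect_equal(conception_angle(as.Date("2000-03-01"), "fixed"),
               2 * pi * 60 / 365.25)
  expect_error(conception_angle("not-a-date"))
})

test_that("Fourier basis has 2k bounded, named columns", {
  th <- seq(0, 2 * pi, length.out = 50)
  b <- fourier_basis(th, 3)
  expect_equal(dim(b), c(50, 6))
  expect_equal(colnames(b), c("sin1", "cos1", "sin2", "cos2", "sin3", "cos3"))
  expect_true(all(abs(b) <= 1))
  expect_equal(b[, "sin2"], sin(2 * th))
})

test_that("design matrix: dimensions, factor coding, complete cases", {
  rec <- make_seasonal_records(10, seed = 2, covariates = TRUE)
  d <- build_design(rec, k = 1)
  expect_equal(dim(d$X), c(10, 3))
  d2 <- build_design(rec, k = 1, covariates = c("age", "sex"))
  expect_equal(ncol(d2$X), 5)
  expect_true("sexmale" %in% colnames(d2$X))   # 'female' is the reference

  rec$maternal_bmi <- runif(10, 19, 23)
  rec$maternal_bmi[1:2] <- NA                  # 20% missing
  d3 <- build_design(rec, k = 1, covariates = "maternal_bmi")
  expect_equal(d3$n, 8)
  expect_equal(d3$n_dropped, 2)

  expect_error(build_design(rec, covariates = "nope"), "unknown covariate")
  rec$ltl_z <- NA_real_
  expect_error(build_design(rec, k = 1), "no complete cases")
})

test_that("Gaussian OLS agrees with the normal-equations oracle", {
  set.seed(8)
  X <- cbind(1, matrix(rnorm(60 * 3), 60, 3))
  colnames(X) <- c("(Intercept)", "a", "b", "c")
  y <- X %*% c(0.5, 1, -2, 0.3) + rnorm(60)
  fit <- fit_gaussian_lm(y, X)
  expect_equal(unname(fit$coefficients), ols_oracle(X, y), tolerance = 1e-9)
  expect_equal(fit$sigma2_mle, sum((y - fit$fitted)^2) / 60, tolerance = 1e-12)
  expect_equal(fit$loglik, -60 / 2 * (log(2 * pi * fit$sigma2_mle) + 1))
  # covariance equals unbiased sigma^2 (X'X)^-1
  expect_equal(fit$covariance,
               fit$rss / (60 - 4) * solve(crossprod(X)), tolerance = 1e-9)
})

test_that("intercept-only, degenerate and rank-deficient fits", {
  y <- c(2, 4, 6, 8)
  X <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_gaussian_lm(y, X)
  expect_equal(unname(fit$coefficients), mean(y))
  expect_equal(fit$sigma2_mle, mean((y - mean(y))^2))

  # exact linear response: RSS 0, flagged degenerate
  x <- 1:6
  fit2 <- fit_gaussian_lm(2 + 3 * x, cbind(`(Intercept)` = 1, x = x))
  expect_true(fit2$degenerate)
  expect_equal(unname(fit2$coefficients), c(2, 3), tolerance = 1e-10)

  X3 <- cbind(`(Intercept)` = 1, a = x, twice_a = 2 * x)
  expect_error(fit_gaussian_lm(rnorm(6), X3), "twice_a")
})

test_that("LRT: zero-improvement boundary, df bookkeeping, errors", {
  y <- c(1, 2, 3, 4, 2, 5)
  Xr <- matrix(1, 6, 1, dimnames = list(NULL, "(Intercept)"))
  # extra column orthogonal to both the intercept and the response:
  # its OLS coefficient is exactly 0, so the likelihood cannot improve
  set.seed(1)
  v <- rnorm(6)
  B <- cbind(1, y)
  c_extra <- v - B %*% solve(crossprod(B), crossprod(B, v))
  Xf <- cbind(Xr, extra = c_extra)
  lrt <- likelihood_ratio_test(fit_gaussian_lm(y, Xf), fit_gaussian_lm(y, Xr))
  expect_equal(lrt$chi2, 0, tolerance = 1e-10)
  expect_equal(lrt$p_value, 1, tolerance = 1e-10)
  expect_equal(lrt$df, 1)

  # one Fourier pair adds 2 df
  rec <- make_seasonal_records(50, amplitude = 1, seed = 3)
  res <- seasonal_lrt(rec, k = 1)
  expect_equal(res$lrt$df, 2)
  expect_equal(res$lrt$chi2,
               2 * (res$full$loglik - res$reduced$loglik), tolerance = 1e-12)

  f1 <- fit_gaussian_lm(rnorm(30), matrix(1, 30, 1))
  f2 <- fit_gaussian_lm(rnorm(20), matrix(1, 20, 1))
  expect_error(likelihood_ratio_test(f1, f2), "same observations")
})

test_that("LRT chi2 is invariant to affine rescaling of the response", {
  rec <- make_seasonal_records(80, amplitude = 0.6, seed = 12)
  r1 <- seasonal_lrt(rec, k = 1)
  rec$ltl_z <- 3.7 * rec$ltl_z - 1.2
  r2 <- seasonal_lrt(rec, k = 1)
  expect_equal(r2$lrt$chi2, r1$lrt$chi2, tolerance = 1e-8)
})

test_that("harmonic selection finds the generating order", {
  # strong pure first harmonic -> one pair suffices
  k1 <- vapply(1:10, function(s) {
    rec <- make_seasonal_records(300, amplitude = 2, sd = 0.5, seed = s)
    select_harmonics(rec, k_max = 3)$k
  }, numeric(1))
  expect_gte(mean(k1 == 1), 0.9)

  # strong two-harmonic signal -> two pairs
  set.seed(99)
  rec2 <- make_seasonal_records(300, amplitude = 0, sd = 0.2, seed = 99)
  th <- conception_angle(rec2$conception_date)
  rec2$ltl_z <- sin(th) + 0.8 * cos(2 * th) + rnorm(300, 0, 0.2)
  sel <- select_harmonics(rec2, k_max = 3)
  expect_equal(sel$k, 2)
  expect_true(all(c("chi2", "p_value") %in% names(sel$trail)))

  # pure noise still reports the minimal one-pair basis
  rec3 <- make_seasonal_records(100, amplitude = 0, seed = 5)
  expect_equal(select_harmonics(rec3, k_max = 3)$k, 1)
})

test_that("seasonal summary matches the k=1 closed form on the grid", {
  set.seed(4)
  for (i in 1:5) {
    a <- rnorm(1); b <- rnorm(1)
    rec <- make_seasonal_records(120, amplitude = 0, sd = 1, seed = i)
    th <- conception_angle(rec$conception_date)
    rec$ltl_z <- 0.2 + a * sin(th) + b * cos(th)   # exact signal
    res <- seasonal_lrt(rec, k = 1)
    sm <- seasonal_summary(res$full, k = 1)
    cf <- harmonic_closed_form(a, b)
    bound <- cf$amplitude * (1 - cos(pi / 366)) + 1e-8
    expect_lt(abs(sm$amplitude - cf$amplitude), bound)
    d <- abs(sm$peak_day - cf$peak_day)
    expect_lt(min(d, 366 - d), 1 + 1e-9)
    expect_equal(sm$curve[sm$peak_day] - sm$curve[sm$nadir_day], sm$amplitude)
  }
})

test_that("rotating the seasonal pattern rotates the peak, preserving fit", {
  # fixed-residual fixture: one record per day of a 365-day year; rotating
  # the response vector around the date grid is a pure relabelling, so
  # amplitude and LRT chi2 must be unchanged and the peak must shift by
  # the rotation
  set.seed(14)
  dates <- as.Date("2001-01-01") + 0:364
  th <- conception_angle(dates)
  e <- rnorm(365, 0, 0.5)
  y <- 0.4 * sin(th) + 0.1 * cos(th) + e
  shift <- 100
  rotate <- function(v, d) v[((seq_along(v) - 1 - d) %% length(v)) + 1]
  r0 <- seasonal_lrt(data.frame(conception_date = dates, ltl_z = y), k = 1)
  r1 <- seasonal_lrt(data.frame(conception_date = dates,
                                ltl_z = rotate(y, shift)), k = 1)
  expect_equal(r1$lrt$chi2, r0$lrt$chi2, tolerance = 1e-8)
  s0 <- seasonal_summary(r0$full, k = 1)
  s1 <- seasonal_summary(r1$full, k = 1)
  # the daily grid samples the rotated curve at a different phase offset,
  # so amplitudes agree only to the discretization bound
  expect_lt(abs(s1$amplitude - s0$amplitude),
            s0$amplitude * (1 - cos(pi / 366)) + 1e-10)
  d <- (s1$peak_day - s0$peak_day) %% 366
  expect_lt(abs(d - shift * 366 / 365), 2)
})

test_that("centering a covariate only moves the intercept", {
  rec <- make_seasonal_records(100, amplitude = 0.6, seed = 6,
                               covariates = TRUE)
  r0 <- seasonal_lrt(rec, k = 1, covariates = c("age", "sex"))
  rec$age <- rec$age + 5
  r1 <- seasonal_lrt(rec, k = 1, covariates = c("age", "sex"))
  cf0 <- r0$full$coefficients; cf1 <- r1$full$coefficients
  keep <- setdiff(names(cf0), "(Intercept)")
  expect_equal(cf1[keep], cf0[keep], tolerance = 1e-9)
  expect_equal(seasonal_summary(r1$full, k = 1)$amplitude,
               seasonal_summary(r0$full, k = 1)$amplitude, tolerance = 1e-9)
})

test_that("bootstrap intervals: determinism and zero-noise degeneracy", {
  rec <- make_seasonal_records(60, amplitude = 0, sd = 1, seed = 7)
  th <- conception_angle(rec$conception_date)
  rec$ltl_z <- 0.3 * sin(th)            # no noise at all
  b1 <- bootstrap_amplitude_ci(rec, B = 150, seed = 42)
  b2 <- bootstrap_amplitude_ci(rec, B = 150, seed = 42)
  expect_identical(b1$amplitude, b2$amplitude)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(unname(b1$amplitude["lower"]), unname(b1$amplitude["estimate"]),
               tolerance = 1e-8)
  expect_equal(unname(b1$amplitude["upper"]), unname(b1$amplitude["estimate"]),
               tolerance = 1e-8)
  b3 <- bootstrap_amplitude_ci(rec, B = 150, seed = 43)
  expect_false(identical(b3$replicates, b1$replicates))
})

test_that("per-predictor models recover effects and catch collinearity", {
  set.seed(31)
  n <- 400
  rec <- make_seasonal_records(n, amplitude = 0.4, sd = 0.8, seed = 31,
                               covariates = TRUE)
  bw <- rnorm(n)                               # standardized birthweight
  rec$birthweight <- bw
  rec$ltl_z <- rec$ltl_z + 0.3 * bw
  eff <- covariate_effect_models(rec, "birthweight")
  expect_equal(eff$estimate, 0.3, tolerance = 0.15)
  expect_true(eff$seasonal_adjusted)
  expect_lt(eff$p_value, 0.01)

  # non-seasonal predictors are not Fourier-adjusted
  rec$maternal_arm <- sample(c("A", "B"), n, replace = TRUE)
  eff2 <- covariate_effect_models(rec, "maternal_arm")
  expect_false(eff2$seasonal_adjusted)
  expect_equal(eff2$term, "maternal_armB")

  rec$clone <- sin(conception_angle(rec$conception_date))
  expect_error(covariate_effect_models(rec, "clone",
                                       seasonal_predictors = "clone"),
               "collinear")
  rec$flat <- 1
  expect_error(covariate_effect_models(rec, "flat"), "constant")
})
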