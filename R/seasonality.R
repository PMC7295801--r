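#' Map calendar dates to angular position within the year
#'
#' Converts a conception (or any) date to an angle
#' `theta = 2*pi*(doy - 1)/D`, where `doy` is the 1-based day of year and
#' `D` the number of days in that calendar year (365 or 366). January 1
#' maps to 0 and December 31 to strictly less than `2*pi`. The
#' `"fixed"` convention uses `D = 365.25` for every year instead.
#'
#' @param dates `Date` vector (or anything `as.Date()` accepts).
#' @param convention `"calendar"` (default, actual year length) or
#'   `"fixed"` (365.25).
#' @return numeric vector of angles in `[0, 2*pi)`.
#' @export
conception_angle <- function(dates, convention = c("calendar", "fixed")) {
  convention <- match.arg(convention)
  d <- as.Date(dates)
  if (anyNA(d) && !anyNA(dates)) stop("invalid date(s)")
  lt <- as.POSIXlt(d)
  doy <- lt$yday + 1L
  yr <- lt$year + 1900L
  D <- if (convention == "calendar") {
    365 + as.integer((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0)
  } else rep(365.25, length(d))
  2 * pi * (doy - 1) / D
}

#' Fourier (cosinor) basis for a cyclic time variable
#'
#' @param theta angles in radians.
#' @param k number of sine/cosine pairs (harmonics).
#' @return matrix with `2k` columns named `sin1, cos1, ..., sink, cosk`.
#' @export
fourier_basis <- function(theta, k) {
  stopifnot(k >= 1)
  cols <- lapply(seq_len(k), function(j) cbind(sin(j * theta), cos(j * theta)))
  m <- do.call(cbind, cols)
  colnames(m) <- as.vector(t(outer(seq_len(k), c("sin", "cos"),
                                   function(j, f) paste0(f, j))))
  m
}

expand_covariates <- function(records, covariates) {
  cols <- list(); factor_cols <- character()
  for (cv in covariates) {
    v <- records[[cv]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, cv))
    } else {
      f <- factor(v, levels = sort(unique(as.character(v[!is.na(v)]))))
      lev <- levels(f)
      if (length(lev) < 2L) {
        m <- matrix(numeric(length(v)), ncol = 1, dimnames = list(NULL, cv))
        m[] <- NA_real_; m[!is.na(v)] <- 0   # constant factor: caught by rank check
      } else {
        m <- vapply(lev[-1], function(l) as.numeric(f == l),
                    numeric(length(f)))
        colnames(m) <- paste0(cv, lev[-1])
        m[is.na(v), ] <- NA_real_
        factor_cols <- c(factor_cols, colnames(m))
      }
    }
    cols[[cv]] <- m
  }
  list(matrix = if (length(cols)) do.call(cbind, cols) else NULL,
       factor_cols = factor_cols)
}

#' Build the design matrix for a Fourier seasonal regression
#'
#' Columns are an intercept, `2k` Fourier terms of the conception-date
#' angle, and the requested covariates (categorical covariates expanded
#' to indicator columns against the alphabetically first reference
#' level). Rows with a missing outcome, date, or covariate are dropped
#' (complete-case analysis; the dropped count is recorded).
#'
#' @param records data frame with `ltl_z`, `conception_date`, and any
#'   covariate columns.
#' @param k number of Fourier pairs (0 gives a covariates-only baseline).
#' @param covariates character vector of covariate column names.
#' @param convention date-angle convention, see [conception_angle()].
#' @return list `X` (design matrix), `y` (response), `n`, `n_dropped`,
#'   `factor_cols`, `rows` (row indices of `records` used).
#' @export
build_design <- function(records, k = 1, covariates = character(),
                         convention = "calendar") {
  stopifnot(is.data.frame(records),
            all(c("ltl_z", "conception_date") %in% names(records)))
  unknown <- setdiff(covariates, names(records))
  if (length(unknown)) stop("unknown covariate(s): ",
                            paste(unknown, collapse = ", "))
  cv <- expand_covariates(records, covariates)
  theta <- conception_angle(records$conception_date, convention)
  fb <- if (k >= 1) fourier_basis(theta, k) else NULL
  X <- cbind(`(Intercept)` = 1, fb, cv$matrix)
  y <- records$ltl_z
  ok <- is.finite(y) & !is.na(records$conception_date)
  if (!is.null(cv$matrix)) ok <- ok & stats::complete.cases(cv$matrix)
  if (!any(ok)) stop("no complete cases for the requested model")
  list(X = X[ok, , drop = FALSE], y = y[ok], n = sum(ok),
       n_dropped = sum(!ok), factor_cols = cv$factor_cols,
       rows = which(ok))
}

#' Fit a Gaussian linear model by least squares
#'
#' QR-based ordinary least squares with the maximum-likelihood error
#' variance `sigma2_mle = RSS/n` and the Gaussian log-likelihood
#' `-(n/2) * (log(2*pi*sigma2_mle) + 1)` used by the likelihood ratio
#' tests. The coefficient covariance uses the unbiased variance
#' `RSS/(n - p)`.
#'
#' @param y response vector.
#' @param X design matrix (including intercept).
#' @return object of class `model_fit`: `coefficients`, `covariance`,
#'   `sigma2_mle`, `loglik`, `n`, `p`, `rss`, `fitted`, `degenerate`
#'   (TRUE when RSS is numerically zero, making the likelihood
#'   unbounded), plus the `X`/`y` used (kept for summaries and
#'   bootstrap resampling).
#' @export
fit_gaussian_lm <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n)
  if (n <= p) stop("need more observations than parameters (n <= p)")
  fit <- stats::lm.fit(X, y)
  if (fit$rank < p) {
    dropped <- colnames(X)[fit$qr$pivot[(fit$rank + 1L):p]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  rss <- sum(fit$residuals^2)
  degenerate <- rss < 1e-12 * max(1, sum(y^2))
  sigma2 <- rss / n
  loglik <- if (degenerate) Inf else -n / 2 * (log(2 * pi * sigma2) + 1)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  structure(list(coefficients = fit$coefficients,
                 covariance = rss / (n - p) * xtx_inv,
                 sigma2_mle = sigma2, loglik = loglik, n = n, p = p,
                 rss = rss, fitted = y - fit$residuals,
                 degenerate = degenerate, X = X, y = y),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Gaussian linear model: n=%d, p=%d, logLik=%.3f, sigma=%.4f\n",
              x$n, x$p, x$loglik, sqrt(x$sigma2_mle)))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood ratio test for nested Gaussian linear models
#'
#' `chi2 = 2 * (logLik_full - logLik_reduced)` referred to a chi-squared
#' distribution with `df = p_full - p_reduced`. Both fits must use the
#' same observations, which complete-case alignment before fitting
#' guarantees; a mismatch in `n` is an error.
#'
#' @param full,reduced `model_fit` objects, reduced nested in full.
#' @return object of class `lrt_result`: `chi2`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "model_fit"), inherits(reduced, "model_fit"))
  if (full$n != reduced$n) {
    stop("LRT requires the same observations in both models (n ",
         full$n, " vs ", reduced$n, "); align complete cases before fitting")
  }
  df <- full$p - reduced$p
  if (df < 1L) stop("full model must have more parameters than reduced")
  chi2 <- max(0, 2 * (full$loglik - reduced$loglik))
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT chi2 = %.3f (%d df), p = %.4g\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Test seasonality of conception with one model comparison
#'
#' Fits the full model (intercept + `k` Fourier pairs + covariates) and
#' the baseline without the Fourier terms on the identical complete
#' cases, and compares them with a `2k`-df likelihood ratio test.
#'
#' @inheritParams build_design
#' @return list `full`, `reduced` (`model_fit`), `lrt` (`lrt_result`),
#'   `n`, `n_dropped`, `k`, `covariates`, `factor_cols`.
#' @export
seasonal_lrt <- function(records, k = 1, covariates = character(),
                         convention = "calendar") {
  d <- build_design(records, k = k, covariates = covariates,
                    convention = convention)
  fourier_cols <- colnames(fourier_basis(0, k))
  keep <- !colnames(d$X) %in% fourier_cols
  full <- fit_gaussian_lm(d$y, d$X)
  reduced <- fit_gaussian_lm(d$y, d$X[, keep, drop = FALSE])
  list(full = full, reduced = reduced,
       lrt = likelihood_ratio_test(full, reduced),
       n = d$n, n_dropped = d$n_dropped, k = k, covariates = covariates,
       factor_cols = d$factor_cols)
}

#' Choose the number of Fourier pairs by sequential likelihood ratio tests
#'
#' Starting from one pair, tests whether adding a further sine/cosine
#' pair improves fit (2-df LRT at level `alpha`); stops at the first
#' non-significant addition. Never returns fewer than one pair — the
#' significance of seasonality itself is assessed separately against the
#' covariate-only baseline.
#'
#' @inheritParams build_design
#' @param k_max largest number of pairs entertained.
#' @param alpha significance level for each addition.
#' @return list `k` (selected pairs) and `trail` (data frame of the
#'   sequential comparisons: k vs k+1, chi2, df, p).
#' @export
select_harmonics <- function(records, covariates = character(), k_max = 3,
                             alpha = 0.05, convention = "calendar") {
  stopifnot(k_max >= 1)
  trail <- list(); k <- 1L
  while (k < k_max) {
    d <- build_design(records, k = k + 1L, covariates = covariates,
                      convention = convention)
    extra <- colnames(fourier_basis(0, k + 1L))[2L * k + (1:2)]
    full <- fit_gaussian_lm(d$y, d$X)
    reduced <- fit_gaussian_lm(d$y, d$X[, !colnames(d$X) %in% extra,
                                        drop = FALSE])
    lrt <- likelihood_ratio_test(full, reduced)
    trail[[length(trail) + 1L]] <- data.frame(
      k_reduced = k, k_full = k + 1L, chi2 = lrt$chi2, df = lrt$df,
      p_value = lrt$p_value)
    if (lrt$p_value >= alpha) break
    k <- k + 1L
  }
  list(k = k, trail = if (length(trail)) do.call(rbind, trail) else NULL)
}

#' Amplitude and peak date of a fitted one-harmonic curve, closed form
#'
#' For `a*sin(theta) + b*cos(theta)` the peak-to-trough amplitude is
#' `2*sqrt(a^2 + b^2)` and the peak sits at `theta = atan2(a, b)`. Used
#' as a cross-check on the daily-grid summary.
#'
#' @param a,b sine and cosine coefficients of the first harmonic.
#' @param days_in_year grid year length used to convert angle to a day.
#' @return list `amplitude`, `peak_theta`, `peak_day`.
#' @export
harmonic_closed_form <- function(a, b, days_in_year = 366) {
  phi <- atan2(a, b) %% (2 * pi)
  list(amplitude = 2 * sqrt(a^2 + b^2), peak_theta = phi,
       peak_day = phi / (2 * pi) * days_in_year + 1)
}

#' Summarize the fitted seasonal curve: amplitude, peak and nadir
#'
#' Evaluates the fitted mean on a daily grid of 366 day-of-year points
#' with covariates held at reference values (column means for continuous
#' covariates, the reference level for categorical indicators), and
#' reports the amplitude as the curve maximum minus minimum together
#' with the peak and nadir days and a pointwise normal 95% confidence
#' band from the coefficient covariance.
#'
#' @param fit `model_fit` from [seasonal_lrt()]'s `full` element (or
#'   [fit_gaussian_lm()] on a design with named Fourier columns).
#' @param k number of Fourier pairs in the fit.
#' @param factor_cols names of indicator columns to hold at 0 (reference
#'   level) instead of their mean.
#' @param reference_covariates optional named vector overriding the
#'   reference value of specific columns.
#' @return object of class `seasonal_summary`: `amplitude`, `peak_day`,
#'   `nadir_day`, `day` (1..366), `curve`, `ci_lower`, `ci_upper`.
#' @export
seasonal_summary <- function(fit, k = 1, factor_cols = character(),
                             reference_covariates = NULL) {
  stopifnot(inherits(fit, "model_fit"))
  fourier_cols <- colnames(fourier_basis(0, k))
  if (!all(fourier_cols %in% names(fit$coefficients))) {
    stop("fit does not contain ", 2 * k, " named Fourier coefficients")
  }
  days <- 1:366
  theta <- 2 * pi * (days - 1) / 366
  ref <- colMeans(fit$X)
  ref[factor_cols[factor_cols %in% names(ref)]] <- 0
  if (!is.null(reference_covariates)) {
    ref[names(reference_covariates)] <- reference_covariates
  }
  Xg <- matrix(ref, nrow = length(days), ncol = length(ref), byrow = TRUE,
               dimnames = list(NULL, names(ref)))
  Xg[, fourier_cols] <- fourier_basis(theta, k)
  curve <- drop(Xg %*% fit$coefficients)
  se <- sqrt(rowSums((Xg %*% fit$covariance) * Xg))
  zc <- stats::qnorm(0.975)
  structure(list(amplitude = max(curve) - min(curve),
                 peak_day = days[which.max(curve)],
                 nadir_day = days[which.min(curve)],
                 day = days, curve = curve,
                 ci_lower = curve - zc * se, ci_upper = curve + zc * se),
            class = "seasonal_summary")
}

#' @export
print.seasonal_summary <- function(x, ...) {
  fmt_day <- function(d) format(as.Date(d - 1, origin = "2000-01-01"), "%d %b")
  cat(sprintf(
    "Seasonal curve: amplitude %.3f z-scores (max - min)\n  peak day %d (~%s), nadir day %d (~%s)\n",
    x$amplitude, x$peak_day, fmt_day(x$peak_day), x$nadir_day,
    fmt_day(x$nadir_day)))
  invisible(x)
}

#' Case-resampling bootstrap intervals for amplitude and peak date
#'
#' Resamples children with replacement, refits the Fourier model, and
#' recomputes the daily-grid amplitude and peak day for each replicate;
#' percentile intervals are returned. Rank-deficient replicates (which
#' can only arise with near-constant covariates) are redrawn and
#' counted. The peak-day interval is formed on angles via the circular
#' mean direction to avoid wrap-around artefacts.
#'
#' @inheritParams build_design
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed; the routine uses its own RNG stream and
#'   restores the caller's.
#' @param conf confidence level.
#' @return list `amplitude` (estimate, lower, upper), `peak_day`
#'   (estimate, lower, upper, on 1..366), `B`, `n_redrawn`,
#'   `replicates` (data frame of bootstrap amplitudes and peak days).
#' @export
bootstrap_amplitude_ci <- function(records, k = 1, covariates = character(),
                                   B = 1000, seed = 1, conf = 0.95,
                                   convention = "calendar") {
  stopifnot(B >= 100)
  d <- build_design(records, k = k, covariates = covariates,
                    convention = convention)
  fourier_cols <- colnames(fourier_basis(0, k))
  fi <- match(fourier_cols, colnames(d$X))
  days <- 1:366
  Fg <- fourier_basis(2 * pi * (days - 1) / 366, k)
  amp_peak <- function(beta_f) {
    curve <- drop(Fg %*% beta_f)
    c(max(curve) - min(curve), days[which.max(curve)])
  }
  fit0 <- fit_gaussian_lm(d$y, d$X)
  est <- amp_peak(fit0$coefficients[fi])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  amps <- numeric(B); peaks <- numeric(B)
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(d$n, d$n, replace = TRUE)
      fb <- stats::lm.fit(d$X[idx, , drop = FALSE], d$y[idx])
      if (fb$rank == ncol(d$X)) break
      n_redrawn <- n_redrawn + 1L
    }
    ap <- amp_peak(fb$coefficients[fi])
    amps[b] <- ap[1]; peaks[b] <- ap[2]
  }
  al <- (1 - conf) / 2
  amp_ci <- unname(stats::quantile(amps, c(al, 1 - al)))
  # circular percentile interval: recentre peak angles on the estimate
  ang <- 2 * pi * (peaks - 1) / 366
  ang0 <- 2 * pi * (est[2] - 1) / 366
  dev <- ((ang - ang0 + pi) %% (2 * pi)) - pi
  dev_ci <- unname(stats::quantile(dev, c(al, 1 - al)))
  peak_ci <- ((ang0 + dev_ci) %% (2 * pi)) / (2 * pi) * 366 + 1
  list(amplitude = c(estimate = est[1], lower = amp_ci[1], upper = amp_ci[2]),
       peak_day = c(estimate = est[2], lower = peak_ci[1], upper = peak_ci[2]),
       B = B, n_redrawn = n_redrawn,
       replicates = data.frame(amplitude = amps, peak_day = peaks))
}

#' Per-predictor effect models adjusted for age, sex and seasonality
#'
#' For each requested predictor (e.g. maternal BMI, birthweight,
#' supplementation arm, maternal folate) fits
#' `ltl_z ~ predictor + age + sex`, additionally including one Fourier
#' pair when the predictor is known to vary seasonally, and reports the
#' predictor's coefficient(s), standard error and t-test p-value.
#'
#' @param records cohort data frame (needs `ltl_z`, `conception_date`,
#'   `age`, `sex`, and the predictors).
#' @param predictors character vector of predictor column names.
#' @param seasonal_predictors predictors that get the extra Fourier-pair
#'   adjustment.
#' @param adjust_for baseline adjustment covariates.
#' @return data frame: `predictor`, `term`, `estimate`, `se`, `p_value`,
#'   `n`, `seasonal_adjusted`.
#' @export
covariate_effect_models <- function(records, predictors,
                                    seasonal_predictors = c("maternal_bmi",
                                                            "log_maternal_bmi",
                                                            "birthweight",
                                                            "maternal_folate",
                                                            "log_maternal_folate"),
                                    adjust_for = c("age", "sex"),
                                    convention = "calendar") {
  out <- list()
  for (pr in predictors) {
    if (!pr %in% names(records)) stop("unknown predictor: ", pr)
    v <- records[[pr]]
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop("predictor is constant: ", pr)
    }
    seasonal <- pr %in% seasonal_predictors
    k <- if (seasonal) 1 else 0
    d <- build_design(records, k = k, covariates = c(pr, adjust_for),
                      convention = convention)
    fit <- fit_gaussian_lm(d$y, d$X)
    terms <- if (is.numeric(v)) pr else grep(paste0("^", pr), names(fit$coefficients), value = TRUE)
    for (tm in terms) {
      est <- fit$coefficients[[tm]]
      se <- sqrt(fit$covariance[tm, tm])
      tval <- est / se
      out[[length(out) + 1L]] <- data.frame(
        predictor = pr, term = tm, estimate = est, se = se,
        p_value = 2 * stats::pt(abs(tval), fit$n - fit$p, lower.tail = FALSE),
        n = fit$n, seasonal_adjusted = seasonal, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
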