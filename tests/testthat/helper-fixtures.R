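# Shared fixture builders for the test suite. All randomness is drawn
# through withr-free local seeds (set.seed inside, callers pass seeds).

# Wells for a standard dilution series lying on cq = intercept + slope*log10(d)
make_standard_wells <- function(dilutions, slope, intercept, target = "tel",
                                plate_id = "P1", noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cq <- intercept + slope * log10(dilutions) +
    if (noise_sd > 0) rnorm(length(dilutions), 0, noise_sd) else 0
  data.frame(plate_id = plate_id, well = sprintf("W%02d", seq_along(dilutions)),
             sample_id = sprintf("STD_%g", dilutions), target = target,
             cq = cq, replicate_idx = 1L, role = "standard",
             dilution = dilutions, stringsAsFactors = FALSE)
}

# Sample wells whose per-replicate T/S ratios equal `ratios` exactly,
# given identical tel/scg curves with the supplied intercept/slope.
make_sample_wells <- function(ratios, slope = -1 / log10(2), intercept = 20,
                              sample_id = "S1", plate_id = "P1") {
  do.call(rbind, lapply(seq_along(ratios), function(r) {
    data.frame(plate_id = plate_id, well = sprintf("%s_W%d", sample_id, r),
               sample_id = sample_id, target = c("tel", "scg"),
               cq = c(intercept + slope * log10(ratios[r]), intercept),
               replicate_idx = r, role = "sample", dilution = NA_real_,
               stringsAsFactors = FALSE)
  }))
}

make_ts_records <- function(cvs, ts = 1, plate_id = "P1") {
  data.frame(sample_id = sprintf("S%02d", seq_along(cvs)),
             plate_id = plate_id, ts_ratio = ts, replicate_cv = cvs,
             n_replicates = 2L, qc_pass = NA, exclusion_reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Minimal cohort records for seasonal model fitting
make_seasonal_records <- function(n, amplitude = 0, peak_day = 244,
                                  sd = 1, seed = 1, year0 = 2006,
                                  covariates = FALSE) {
  set.seed(seed)
  conception <- as.Date(paste0(year0, "-01-01")) +
    sample.int(730, n, replace = TRUE) - 1L
  theta <- conception_angle(conception)
  theta_peak <- 2 * pi * (peak_day - 1) / 365
  df <- data.frame(child_id = sprintf("C%03d", seq_len(n)),
                   conception_date = conception,
                   ltl_z = amplitude / 2 * cos(theta - theta_peak) +
                     rnorm(n, 0, sd),
                   stringsAsFactors = FALSE)
  if (covariates) {
    df$age <- runif(n, 8.5, 9.5)
    df$sex <- sample(c("male", "female"), n, replace = TRUE)
  }
  df
}

# Independent OLS oracle via the explicit normal equations
ols_oracle <- function(X, y) unname(drop(solve(t(X) %*% X) %*% t(X) %*% y))

# Independent one-way ANOVA oracle from group sums of squares
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values); k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
}

rdirichlet_helper <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Brute-force simplex grid oracle for 3-type deconvolution
grid_oracle_3 <- function(R, p, step = 0.001) {
  stopifnot(ncol(R) == 3)
  m <- round(1 / step)
  ij <- expand.grid(i = 0:m, j = 0:m)
  ij <- ij[ij$i + ij$j <= m, ]
  W <- rbind(ij$i, ij$j, m - ij$i - ij$j) / m
  obj <- colSums((as.vector(p) - R %*% W)^2)
  best <- which.min(obj)
  list(w = W[, best], objective = obj[best])
}
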