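#' Per-plate z-score normalization of T/S ratios
#'
#' Converts raw T/S ratios to z-scores within each qPCR plate,
#' `z = (ts - plate mean) / plate sd` (sample sd), removing plate batch
#' effects in both location and scale. Plates with fewer than 3 usable
#' samples or zero within-plate sd cannot be standardized; their samples
#' are dropped and reported.
#'
#' @param records data frame with columns `sample_id`, `plate_id`,
#'   `ts_ratio` (typically the `kept` element of [apply_qc()], restricted
#'   to `role == "sample"`).
#' @return data frame `sample_id`, `plate_id`, `ltl_z`; attribute
#'   `"excluded_plates"` is a data frame of flagged plates and reasons.
#' @export
per_plate_zscore <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "plate_id", "ts_ratio") %in% names(records)))
  out <- list(); flagged <- list()
  for (pid in unique(records$plate_id)) {
    r <- records[records$plate_id == pid & is.finite(records$ts_ratio), ]
    s <- stats::sd(r$ts_ratio)
    if (nrow(r) < 3L || !is.finite(s) || s == 0) {
      flagged[[length(flagged) + 1L]] <- data.frame(
        plate_id = pid, n = nrow(r),
        reason = if (nrow(r) < 3L) "fewer than 3 samples" else "zero sd",
        stringsAsFactors = FALSE)
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      sample_id = r$sample_id, plate_id = pid,
      ltl_z = (r$ts_ratio - mean(r$ts_ratio)) / s,
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), plate_id = character(),
               ltl_z = numeric())
  rownames(res) <- NULL
  attr(res, "excluded_plates") <-
    if (length(flagged)) do.call(rbind, flagged) else NULL
  res
}

#' One-way ANOVA for a plate batch effect
#'
#' Tests whether mean raw T/S differs between plates, the diagnostic that
#' motivates per-plate z-scoring.
#'
#' @param records data frame with `plate_id` and `ts_ratio`.
#' @return list `f` (F statistic), `p`, `df` (numerator, denominator).
#' @export
plate_batch_anova <- function(records) {
  stopifnot(is.data.frame(records))
  r <- records[is.finite(records$ts_ratio), ]
  plate <- factor(r$plate_id)
  if (nlevels(plate) < 2L) stop("plate batch ANOVA needs at least 2 plates")
  if (any(table(plate) < 2L)) stop("plate batch ANOVA needs >=2 samples per plate")
  tab <- stats::anova(stats::lm(ts_ratio ~ plate, data = r))
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df = c(tab$Df[1], tab$Df[2]))
}

box_cox_eval <- function(x, lambda) {
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox power transformation with profile-likelihood lambda
#'
#' Applies `y = ((x + shift)^lambda - 1)/lambda` (the log for
#' `lambda = 0`). Because z-scores contain negative values, which the
#' power family cannot accept, a shift is chosen so that the minimum
#' maps to +0.01 whenever any value is non-positive; the shift is
#' returned for reproducibility. When `lambda` is not supplied it is
#' chosen by maximizing the Gaussian profile log-likelihood
#' `-(n/2) log(sigma2_hat(lambda)) + (lambda - 1) * sum(log(x + shift))`
#' over the fixed grid -2..2 in steps of 0.001 (deterministic).
#'
#' @param x numeric vector.
#' @param lambda optional fixed exponent; estimated when `NULL`.
#' @param shift optional fixed shift; chosen automatically when `NULL`.
#' @return list `values` (transformed vector), `lambda`, `shift`,
#'   `profile` (data frame of the grid and log-likelihood when lambda
#'   was estimated).
#' @export
boxcox_transform <- function(x, lambda = NULL, shift = NULL) {
  if (any(!is.finite(x))) stop("boxcox: non-finite input values")
  if (is.null(shift)) shift <- if (min(x) <= 0) 0.01 - min(x) else 0
  xs <- x + shift
  if (any(xs <= 0)) stop("boxcox: values not positive after shift")
  profile <- NULL
  if (is.null(lambda)) {
    grid <- seq(-2, 2, by = 1e-3)
    n <- length(xs)
    slx <- sum(log(xs))
    ll <- vapply(grid, function(l) {
      y <- box_cox_eval(xs, l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
    }, numeric(1))
    lambda <- grid[which.max(ll)]
    profile <- data.frame(lambda = grid, loglik = ll)
  }
  list(values = box_cox_eval(xs, lambda), lambda = lambda, shift = shift,
       profile = profile)
}

#' Natural-log transform of skewed predictor columns
#'
#' Replaces each named column by its natural logarithm and renames it
#' `log_<name>`, the standard treatment for right-skewed predictors such
#' as maternal BMI or folate concentration.
#'
#' @param table data frame.
#' @param columns character vector of column names; each must be
#'   strictly positive wherever non-missing.
#' @return the data frame with transformed, renamed columns.
#' @export
log_transform_predictors <- function(table, columns) {
  stopifnot(is.data.frame(table))
  for (cl in columns) {
    if (!cl %in% names(table)) stop("unknown predictor column: ", cl)
    v <- table[[cl]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop(sprintf("log transform of '%s': non-positive value at row %d",
                   cl, bad[1]))
    }
    table[[cl]] <- log(v)
    names(table)[names(table) == cl] <- paste0("log_", cl)
  }
  table
}
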