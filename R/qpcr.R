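#' Fit a qPCR standard curve for one plate and target
#'
#' Ordinary least-squares regression of quantification cycle (Cq) on
#' log10 relative concentration over a dilution series of the reference
#' DNA, as produced for each plate and each amplicon (telomere or
#' single-copy gene). The amplification efficiency is derived from the
#' slope as `10^(-1/slope) - 1`; a perfect doubling per cycle gives a
#' slope of -1/log10(2) = -3.3219 and efficiency 1.
#'
#' @param wells data frame of standard wells for a single plate and
#'   target, with columns `cq` and `dilution` (relative concentration,
#'   > 0). Additional columns are ignored.
#' @param plate_id,target identifiers recorded on the returned curve;
#'   defaults are taken from the wells when present.
#' @return an object of class `standard_curve`: a list with `plate_id`,
#'   `target`, `slope` (cycles per log10 unit), `intercept` (cycles at
#'   relative concentration 1), `efficiency`, `r_squared` and `n_points`.
#' @examples
#' w <- data.frame(dilution = c(1, 0.5, 0.25),
#'                 cq = c(10, 13.3219, 16.6439))
#' fit_standard_curve(w, plate_id = "P1", target = "tel")
#' @export
fit_standard_curve <- function(wells, plate_id = NULL, target = NULL) {
  stopifnot(is.data.frame(wells), all(c("cq", "dilution") %in% names(wells)))
  cq <- wells$cq
  dil <- wells$dilution
  if (anyNA(cq) || any(!is.finite(cq))) {
    stop("standard curve: non-finite Cq among standards")
  }
  if (any(!is.finite(dil)) || any(dil <= 0)) {
    stop("standard curve: dilutions must be finite and positive")
  }
  if (length(unique(dil)) < 3L) {
    stop("degenerate standard curve: fewer than 3 distinct dilution levels")
  }
  x <- log10(dil)
  if (stats::var(x) == 0) {
    stop("singular standard-curve fit: zero variance in log10(dilution)")
  }
  fit <- stats::lm.fit(cbind(1, x), cq)
  coef <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((cq - mean(cq))^2)
  structure(list(
    plate_id  = if (is.null(plate_id)) wells$plate_id[1] else plate_id,
    target    = if (is.null(target)) wells$target[1] else target,
    slope     = unname(coef[2]),
    intercept = unname(coef[1]),
    efficiency = 10^(-1 / unname(coef[2])) - 1,
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n_points  = length(cq)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve [plate %s, target %s]\n  slope %.4f cycles/log10, intercept %.3f, efficiency %.1f%%, R^2 %.5f (n=%d)\n",
    x$plate_id, x$target, x$slope, x$intercept, 100 * x$efficiency,
    x$r_squared, x$n_points))
  invisible(x)
}

#' Interpolate a relative quantity from a Cq value
#'
#' Inverts the standard curve: `quantity = 10^((cq - intercept)/slope)`.
#' A standard at relative concentration 1 therefore maps back to 1, and
#' each `|slope|` cycles correspond to a 10-fold change in quantity.
#'
#' @param cq numeric vector of quantification cycles.
#' @param curve a `standard_curve`.
#' @return numeric vector of relative quantities.
#' @export
quantify <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope >= 0) {
    stop("invalid standard curve: slope must be negative")
  }
  10^((cq - curve$intercept) / curve$slope)
}

#' Compute one sample's T/S ratio from its wells
#'
#' For each replicate with both the telomere (T) and single-copy gene (S)
#' targets measured, the relative T and S quantities are read off the two
#' plate standard curves and their ratio formed; the sample T/S ratio is
#' the mean over replicate ratios and the duplicate coefficient of
#' variation is the sample standard deviation of replicate ratios divided
#' by their mean. Replicates missing either target are dropped. The
#' `ratio_of_means` dialect instead divides the mean T quantity by the
#' mean S quantity (CV is then computed on per-replicate ratios still).
#'
#' @param sample_wells data frame of this sample's wells (one row per
#'   well-target reading) with columns `sample_id`, `plate_id`, `target`
#'   (`"tel"`/`"scg"`), `cq`, `replicate_idx`.
#' @param curve_t,curve_s `standard_curve` objects for the telomere and
#'   single-copy targets of this plate.
#' @param method `"per_replicate"` (default) or `"ratio_of_means"`.
#' @return one-row data frame: `sample_id`, `plate_id`, `ts_ratio`,
#'   `replicate_cv` (`NA` when fewer than 2 complete replicates),
#'   `n_replicates`, `qc_pass` (`NA`, set by [apply_qc()]),
#'   `exclusion_reason`. A sample with no complete replicate is returned
#'   with `ts_ratio = NA` and reason `"amplification failure"`.
#' @export
compute_ts_ratio <- function(sample_wells, curve_t, curve_s,
                             method = c("per_replicate", "ratio_of_means")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(sample_wells))
  sid <- sample_wells$sample_id[1]
  pid <- sample_wells$plate_id[1]
  tel <- sample_wells[sample_wells$target == "tel" & is.finite(sample_wells$cq), ]
  scg <- sample_wells[sample_wells$target == "scg" & is.finite(sample_wells$cq), ]
  reps <- intersect(tel$replicate_idx, scg$replicate_idx)
  rec <- data.frame(sample_id = sid, plate_id = pid, ts_ratio = NA_real_,
                    replicate_cv = NA_real_, n_replicates = length(reps),
                    qc_pass = NA, exclusion_reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(reps) == 0L) {
    rec$exclusion_reason <- "amplification failure"
    rec$qc_pass <- FALSE
    return(rec)
  }
  qt <- quantify(tel$cq[match(reps, tel$replicate_idx)], curve_t)
  qs <- quantify(scg$cq[match(reps, scg$replicate_idx)], curve_s)
  ratios <- qt / qs
  rec$ts_ratio <- if (method == "per_replicate") mean(ratios) else mean(qt) / mean(qs)
  if (length(ratios) >= 2L) {
    rec$replicate_cv <- stats::sd(ratios) / mean(ratios)
  }
  rec
}

#' Process a full plate table into per-sample T/S records
#'
#' Fits the two standard curves of each plate from its `role = "standard"`
#' wells and computes a T/S record for every sample, reference and control
#' on that plate.
#'
#' @param wells data frame in the raw plate dialect: columns `plate_id`,
#'   `well`, `sample_id`, `target` (`"tel"`/`"scg"`), `cq`,
#'   `replicate_idx`, `role` (`sample`/`standard`/`reference`/`control`),
#'   `dilution` (standards only).
#' @param method passed to [compute_ts_ratio()].
#' @return data frame of T/S records with an extra `role` column; the
#'   fitted curves are attached as attribute `"curves"` (a named list
#'   `plate:target -> standard_curve`).
#' @export
plate_ts_ratios <- function(wells, method = c("per_replicate", "ratio_of_means")) {
  method <- match.arg(method)
  needed <- c("plate_id", "well", "sample_id", "target", "cq", "replicate_idx",
              "role", "dilution")
  stopifnot(is.data.frame(wells), all(needed %in% names(wells)))
  out <- list(); curves <- list()
  for (pid in unique(wells$plate_id)) {
    pw <- wells[wells$plate_id == pid, ]
    std <- pw[pw$role == "standard", ]
    curve_t <- fit_standard_curve(std[std$target == "tel", ], pid, "tel")
    curve_s <- fit_standard_curve(std[std$target == "scg", ], pid, "scg")
    curves[[paste(pid, "tel", sep = ":")]] <- curve_t
    curves[[paste(pid, "scg", sep = ":")]] <- curve_s
    sm <- pw[pw$role %in% c("sample", "reference", "control"), ]
    for (sid in unique(sm$sample_id)) {
      sw <- sm[sm$sample_id == sid, ]
      rec <- compute_ts_ratio(sw, curve_t, curve_s, method = method)
      rec$role <- sw$role[1]
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "curves") <- curves
  res
}

#' Partition T/S records by duplicate-CV quality control
#'
#' Excludes samples that failed to amplify, samples whose duplicate
#' coefficient of variation exceeds the threshold (strictly; a CV equal
#' to the threshold is kept), and samples whose CV is undefined because
#' only a single complete replicate was measured.
#'
#' @param records data frame of T/S records from [plate_ts_ratios()].
#' @param cv_threshold exclusion threshold on the duplicate CV as a
#'   fraction; default 0.15 (15%).
#' @return list with elements `kept` and `excluded` (both data frames
#'   with `qc_pass`/`exclusion_reason` filled in) and `counts`.
#' @export
apply_qc <- function(records, cv_threshold = 0.15) {
  stopifnot(is.data.frame(records), cv_threshold >= 0)
  reason <- records$exclusion_reason
  failed <- !is.na(reason) & reason == "amplification failure"
  no_cv <- !failed & is.na(records$replicate_cv)
  high <- !failed & !no_cv & records$replicate_cv > cv_threshold
  reason[no_cv] <- "replicate CV undefined (single replicate)"
  reason[high] <- "duplicate CV > threshold"
  records$exclusion_reason <- reason
  records$qc_pass <- !(failed | no_cv | high)
  list(kept = records[records$qc_pass, , drop = FALSE],
       excluded = records[!records$qc_pass, , drop = FALSE],
       counts = c(kept = sum(records$qc_pass),
                  excluded_failed = sum(failed),
                  excluded_no_cv = sum(no_cv),
                  excluded_high_cv = sum(high)))
}

#' Intra- and inter-assay coefficients of variation
#'
#' The intra-assay CV is the mean duplicate CV over QC-passed records.
#' The inter-assay CV is computed from the reference and control samples
#' run on every plate: for each such sample measured on at least two
#' plates, the CV (sd/mean) of its per-plate T/S values; the report gives
#' the mean over those samples, or `NA` when no sample is common to
#' two or more plates.
#'
#' @param records T/S record data frame (with `role`, post-QC columns).
#' @param reference_ids,control_ids sample ids of the plate-common
#'   reference and control samples; by default taken from `role`.
#' @return list of class `assay_cv_report`: `intra_assay_cv`,
#'   `inter_assay_cv` (fractions), `n_samples`, `n_plates`.
#' @export
assay_cvs <- function(records, reference_ids = NULL, control_ids = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(reference_ids) && "role" %in% names(records)) {
    reference_ids <- unique(records$sample_id[records$role == "reference"])
  }
  if (is.null(control_ids) && "role" %in% names(records)) {
    control_ids <- unique(records$sample_id[records$role == "control"])
  }
  kept <- records[is.na(records$qc_pass) | records$qc_pass, , drop = FALSE]
  intra <- mean(kept$replicate_cv, na.rm = TRUE)
  common <- unique(c(reference_ids, control_ids))
  per_sample <- vapply(common, function(sid) {
    v <- kept$ts_ratio[kept$sample_id == sid & is.finite(kept$ts_ratio)]
    if (length(v) >= 2L) stats::sd(v) / mean(v) else NA_real_
  }, numeric(1))
  per_sample <- per_sample[is.finite(per_sample)]
  inter <- if (length(per_sample)) mean(per_sample) else NA_real_
  structure(list(intra_assay_cv = intra, inter_assay_cv = inter,
                 n_samples = length(unique(kept$sample_id)),
                 n_plates = length(unique(kept$plate_id))),
            class = "assay_cv_report")
}

#' @export
print.assay_cv_report <- function(x, ...) {
  cat(sprintf(
    "Assay CVs over %d samples on %d plates: intra %.1f%%, inter %s\n",
    x$n_samples, x$n_plates, 100 * x$intra_assay_cv,
    if (is.na(x$inter_assay_cv)) "undefined"
    else sprintf("%.1f%%", 100 * x$inter_assay_cv)))
  invisible(x)
}

#' Read a raw qPCR plate table from CSV
#'
#' Expects the header `plate_id,well,sample_id,target,cq,replicate_idx,
#' role,dilution`; `target` is `"tel"` or `"scg"` and `dilution` is empty
#' for non-standard wells.
#'
#' @param path CSV file path.
#' @return data frame of wells.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("plate_id", "well", "sample_id", "target", "cq",
              "replicate_idx", "role", "dilution")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("plate CSV missing columns: ", paste(miss, collapse = ", "))
  bad <- !df$target %in% c("tel", "scg")
  if (any(bad)) stop("plate CSV: unknown target values: ",
                     paste(unique(df$target[bad]), collapse = ", "))
  df
}
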