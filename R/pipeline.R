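#' Read a phenotype table from CSV
#'
#' Dates must be ISO-8601 (`YYYY-MM-DD`). Requires `child_id`,
#' `conception_date` and `collection_date`; all other columns are
#' carried through.
#'
#' @param path CSV file path.
#' @return data frame with parsed `Date` columns.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("child_id", "conception_date", "collection_date")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("phenotype CSV missing columns: ",
                         paste(miss, collapse = ", "))
  df$conception_date <- as.Date(df$conception_date)
  df$collection_date <- as.Date(df$collection_date)
  if (any(df$conception_date >= df$collection_date, na.rm = TRUE)) {
    stop("phenotype CSV: conception_date must precede collection_date")
  }
  df
}

#' Assemble a pipeline run configuration
#'
#' Either supply a [synthetic_config()] in `simulate`, or paths to a raw
#' plate CSV and a phenotype CSV.
#'
#' @param simulate optional [synthetic_config()]; when given, plates and
#'   phenotypes are generated rather than read.
#' @param plates_csv,phenotype_csv input paths (ignored when simulating).
#' @param out_dir output directory (created if needed); `NULL` disables
#'   file output.
#' @param models named list of model specifications, each a character
#'   vector of covariate names; `"@cells"` expands to the cell-fraction
#'   columns (first fraction dropped). Default: the five-model roster —
#'   crude; age + sex; age + sex + cell composition; age + sex +
#'   log maternal BMI; age + sex + birthweight — plus a
#'   supplementation-adjusted model when an arm column is present.
#' @param k Fourier pairs for the seasonal terms.
#' @param cv_threshold duplicate-CV exclusion threshold.
#' @param ts_method T/S dialect, see [compute_ts_ratio()].
#' @param boxcox apply a Box-Cox transform to the plate z-scores before
#'   modelling (as needed when the z-scores are visibly skewed).
#' @param bootstrap_B bootstrap replicates for the crude-model amplitude
#'   interval (0 skips the bootstrap).
#' @param seed integer seed for all stochastic steps.
#' @param convention date-angle convention, see [conception_angle()].
#' @param make_plots write fitted-curve figures (PNG) per model.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(simulate = NULL, plates_csv = NULL,
                            phenotype_csv = NULL, out_dir = NULL,
                            models = NULL, k = 1, cv_threshold = 0.15,
                            ts_method = "per_replicate", boxcox = FALSE,
                            bootstrap_B = 0, seed = 1,
                            convention = "calendar", make_plots = TRUE) {
  if (is.null(simulate)) {
    if (is.null(plates_csv) || is.null(phenotype_csv)) {
      stop("either 'simulate' or both 'plates_csv' and 'phenotype_csv' required")
    }
    for (p in c(plates_csv, phenotype_csv)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
  }
  structure(as.list(environment()), class = "run_config")
}

default_model_roster <- function(phenotype) {
  cells <- grep("^cf_", names(phenotype), value = TRUE)
  roster <- list(
    model1_crude = character(),
    model2_age_sex = c("age", "sex"),
    model3_cells = c("age", "sex", "@cells"),
    model4_maternal_bmi = c("age", "sex", "log_maternal_bmi"),
    model5_birthweight = c("age", "sex", "birthweight"))
  if (!length(cells)) roster$model3_cells <- NULL
  if (!"log_maternal_bmi" %in% names(phenotype)) roster$model4_maternal_bmi <- NULL
  if (!"birthweight" %in% names(phenotype)) roster$model5_birthweight <- NULL
  if ("maternal_arm" %in% names(phenotype) &&
      length(unique(stats::na.omit(phenotype$maternal_arm))) > 1L) {
    roster$model6_supplementation <- c("age", "sex", "maternal_arm")
  }
  roster
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full plates-to-report analysis pipeline
#'
#' Orchestrates: raw plates -> standard curves and T/S ratios ->
#' duplicate-CV quality control -> plate batch ANOVA -> per-plate
#' z-scores (optional Box-Cox) -> Fourier seasonal regression models
#' compared by likelihood ratio tests -> seasonal curve summaries and
#' per-predictor effect models, with fitted-curve figures and a QC
#' report. Every random step derives from `config$seed`, so a rerun with
#' the same configuration reproduces the report exactly.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list report bundle: `model_table` (data frame:
#'   model, N, chi2, df, p, amplitude, peak/nadir days), `summaries`
#'   (per-model `seasonal_summary`), `fits`, `qc` (counts and assay
#'   CVs), `batch_anova`, `normalized` (per-sample z-scores),
#'   `phenotype` (analysis table), `covariate_effects`, `bootstrap`,
#'   `truth` (when simulating), `files` (paths written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  files <- character()
  truth <- NULL

  if (!is.null(config$simulate)) {
    sim <- stage("simulate", {
      cg <- generate_cohort(config$simulate)
      pl <- generate_plates(cg$cohort, cg$truth, config$simulate)
      list(cohort = cg$cohort, wells = pl$wells, truth = pl$truth)
    })
    phenotype <- sim$cohort
    wells <- sim$wells
    truth <- sim$truth
  } else {
    phenotype <- stage("read_phenotype", read_phenotype_csv(config$phenotype_csv))
    wells <- stage("read_plates", read_plate_csv(config$plates_csv))
  }

  records <- stage("qpcr", plate_ts_ratios(wells, method = config$ts_method))
  qc <- stage("qc", apply_qc(records, cv_threshold = config$cv_threshold))
  cvs <- stage("assay_cvs", assay_cvs(qc$kept))
  kept_samples <- qc$kept[qc$kept$role == "sample", , drop = FALSE]
  batch <- stage("batch_anova", plate_batch_anova(kept_samples))
  normalized <- stage("zscore", per_plate_zscore(kept_samples))
  boxcox_info <- NULL
  if (isTRUE(config$boxcox)) {
    bc <- stage("boxcox", boxcox_transform(normalized$ltl_z))
    normalized$ltl_z <- bc$values
    boxcox_info <- list(lambda = bc$lambda, shift = bc$shift)
  }

  analysis <- stage("merge", {
    m <- merge(phenotype, normalized[, c("sample_id", "plate_id", "ltl_z")],
               by.x = "child_id", by.y = "sample_id",
               suffixes = c("_premeasure", ""))
    if ("maternal_bmi" %in% names(m)) {
      m <- log_transform_predictors(m, "maternal_bmi")
    }
    if ("maternal_folate" %in% names(m)) {
      m <- log_transform_predictors(m, "maternal_folate")
    }
    m
  })

  roster <- config$models
  if (is.null(roster)) roster <- default_model_roster(analysis)
  cells <- grep("^cf_", names(analysis), value = TRUE)
  if (length(cells) > 1L) cells <- cells[-1L]   # drop one fraction: simplex collinearity
  model_rows <- list(); summaries <- list(); fits <- list()
  for (nm in names(roster)) {
    covs <- roster[[nm]]
    covs <- unlist(lapply(covs, function(cv) if (cv == "@cells") cells else cv))
    res <- stage(paste0("model_", nm),
                 seasonal_lrt(analysis, k = config$k, covariates = covs,
                              convention = config$convention))
    sm <- seasonal_summary(res$full, k = config$k,
                           factor_cols = res$factor_cols)
    model_rows[[nm]] <- data.frame(
      model = nm, n = res$n, chi2 = res$lrt$chi2, df = res$lrt$df,
      p_value = res$lrt$p_value, amplitude = sm$amplitude,
      peak_day = sm$peak_day, nadir_day = sm$nadir_day,
      stringsAsFactors = FALSE)
    summaries[[nm]] <- sm
    fits[[nm]] <- res
  }
  model_table <- do.call(rbind, model_rows)
  rownames(model_table) <- NULL

  boot <- NULL
  if (config$bootstrap_B > 0) {
    boot <- stage("bootstrap",
                  bootstrap_amplitude_ci(analysis, k = config$k,
                                         covariates = character(),
                                         B = config$bootstrap_B,
                                         seed = config$seed,
                                         convention = config$convention))
  }

  predictors <- intersect(c("log_maternal_bmi", "birthweight",
                            "log_maternal_folate", "maternal_arm",
                            "infant_arm"), names(analysis))
  predictors <- predictors[vapply(predictors, function(p)
    length(unique(stats::na.omit(analysis[[p]]))) > 1L, logical(1))]
  effects <- if (length(predictors)) {
    stage("covariate_effects",
          covariate_effect_models(analysis, predictors,
                                  convention = config$convention))
  } else NULL

  qc_report <- list(
    n_records = nrow(records), counts = as.list(qc$counts),
    intra_assay_cv = cvs$intra_assay_cv,
    inter_assay_cv = cvs$inter_assay_cv,
    batch_anova = list(f = batch$f, p = batch$p),
    excluded_plates = attr(normalized, "excluded_plates"),
    boxcox = boxcox_info,
    n_analysis = nrow(analysis))

  if (!is.null(out_dir)) {
    wr <- function(obj, fname, writer) {
      path <- file.path(out_dir, fname)
      writer(obj, path)
      files[[length(files) + 1L]] <<- path
    }
    wr(model_table, "model_table.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(qc$excluded, "qc_excluded.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(normalized, "normalized_ltl.csv",
       function(o, p) utils::write.csv(o, p, row.names = FALSE))
    wr(qc_report, "qc_report.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = 10, pretty = TRUE))
    if (!is.null(effects)) {
      wr(effects, "covariate_effects.csv",
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
    }
    sm_json <- lapply(summaries, function(s)
      list(amplitude = s$amplitude, peak_day = s$peak_day,
           nadir_day = s$nadir_day))
    wr(sm_json, "seasonal_summaries.json",
       function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = 10, pretty = TRUE))
    if (isTRUE(config$make_plots)) {
      for (nm in names(summaries)) {
        pl <- plot_seasonal_fit(summaries[[nm]], analysis,
                                title = nm)
        path <- file.path(out_dir, paste0("fit_", nm, ".png"))
        ggplot2::ggsave(path, pl, width = 7, height = 4.5, dpi = 120)
        files[[length(files) + 1L]] <- path
      }
    }
  }

  invisible(list(model_table = model_table, summaries = summaries,
                 fits = fits, qc = qc_report, batch_anova = batch,
                 normalized = normalized, phenotype = analysis,
                 covariate_effects = effects, bootstrap = boot,
                 truth = truth, files = unlist(files)))
}

#' Plot a fitted seasonal curve with its confidence band
#'
#' Fitted mean LTL z-score (with pointwise 95% band) against conception
#' day of year, with the individual observations overlaid.
#'
#' @param summary a [seasonal_summary()].
#' @param records optional analysis data frame (`conception_date`,
#'   `ltl_z`) for the observation layer.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_seasonal_fit <- function(summary, records = NULL, title = NULL) {
  stopifnot(inherits(summary, "seasonal_summary"))
  df <- data.frame(day = summary$day, fit = summary$curve,
                   lo = summary$ci_lower, hi = summary$ci_upper)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day))
  if (!is.null(records)) {
    pts <- data.frame(
      day = as.POSIXlt(as.Date(records$conception_date))$yday + 1,
      ltl_z = records$ltl_z)
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(y = .data$ltl_z),
                                 alpha = 0.3, size = 0.8)
  }
  month_starts <- cumsum(c(1, 31, 29, 31, 30, 31, 30, 31, 31, 30, 31, 30))
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), linewidth = 0.9) +
    ggplot2::scale_x_continuous(breaks = month_starts,
                                labels = c("J", "F", "M", "A", "M", "J",
                                           "J", "A", "S", "O", "N", "D")) +
    ggplot2::labs(x = "Month of conception", y = "LTL (T/S z-score)",
                  title = title) +
    ggplot2::theme_minimal()
}
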