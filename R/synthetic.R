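#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a mid-childhood West-African cohort measured with
#' duplicate MMqPCR: 218 children, a season-of-conception effect of 0.6
#' z-scores peak-to-trough peaking on day 244 (1 September, end of the
#' rainy season), unit residual sd on the z-score scale, duplicate CV
#' 5%, plates of 32 samples with additive/multiplicative batch effects,
#' 55% boys, birthweight 3069 +/- 417 g, maternal BMI median 20.8.
#'
#' Two collection designs are available: `"window_locked"` collects all
#' samples in a fixed February-May window (conception and collection
#' dates essentially uncorrelated), while `"age_locked"` collects each
#' child at a fixed age of 2 years after birth, so collection date
#' tracks conception date almost perfectly — the structural confounding
#' contrast between the two cohort designs this generator emulates.
#'
#' @param n number of children.
#' @param design `"window_locked"` or `"age_locked"`.
#' @param true_amplitude seasonal effect size, curve maximum minus
#'   minimum, in z-score units.
#' @param peak_day day of year at which the seasonal effect peaks.
#' @param residual_sd residual sd of the outcome (z-score units).
#' @param covariate_effects named vector of outcome effects per covariate
#'   (continuous covariates enter per SD; `sex_male` is the male-female
#'   contrast). Default: all zero.
#' @param covariate_seasonality logical; give birthweight and maternal
#'   BMI a mild seasonal component (harvest-cycle-like) when TRUE.
#' @param ts_mean,ts_sd location/scale mapping z-scores to true T/S
#'   ratios (`ts = ts_mean + ts_sd * z`, floored at 0.05).
#' @param plate_size samples per plate.
#' @param plate_shift_sd,plate_scale_sd sd of the per-plate additive
#'   shift and of log multiplicative scale applied to true T/S.
#' @param duplicate_cv target coefficient of variation between duplicate
#'   wells (fraction).
#' @param high_cv_fraction fraction of samples given inflated duplicate
#'   noise (CV 0.25) so they fail the 15% QC rule.
#' @param fail_rate fraction of samples whose wells fail to amplify
#'   (missing Cq in all replicates).
#' @param missing_rates named vector of MCAR missingness rates for
#'   phenotype columns.
#' @param n_cell_types,n_markers cell-mixture dimensions.
#' @param seed integer seed; every generator draws from it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 218,
                             design = c("window_locked", "age_locked"),
                             true_amplitude = 0.6,
                             peak_day = 244,
                             residual_sd = 1,
                             covariate_effects = c(),
                             covariate_seasonality = TRUE,
                             ts_mean = 1.1, ts_sd = 0.28,
                             plate_size = 32,
                             plate_shift_sd = 0.15,
                             plate_scale_sd = 0.05,
                             duplicate_cv = 0.05,
                             high_cv_fraction = 0.05,
                             fail_rate = 0.02,
                             missing_rates = c(birthweight = 0.08,
                                               maternal_bmi = 0,
                                               cell_fractions = 0.02),
                             n_cell_types = 6, n_markers = 50,
                             seed = 1) {
  design <- match.arg(design)
  stopifnot(n > 0, true_amplitude >= 0, residual_sd > 0, plate_size >= 3,
            duplicate_cv >= 0, peak_day >= 1, peak_day <= 366)
  structure(as.list(environment()), class = "synthetic_config")
}

cell_type_names <- function(k) {
  base <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Gran")
  if (k <= length(base)) base[seq_len(k)] else c(base, paste0("type", seq_len(k - length(base))))
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cohort with known seasonal ground truth
#'
#' Conception dates are uniform over a multi-year window; the seasonal
#' effect is `s(theta) = (A/2) * cos(theta - theta_peak)` so the curve's
#' maximum minus minimum equals the configured amplitude; the outcome is
#' `ltl_z = s + sum(beta * covariate) + N(0, sd^2)`. In the
#' `age_locked` design collection is conception + 280 days gestation +
#' 2 years; in the `window_locked` design collection dates are drawn
#' within February-May 2016. Covariates (sex, birthweight, maternal BMI,
#' maternal folate, supplementation arms, true cell fractions) follow
#' the configured marginals, and missingness is applied completely at
#' random after the outcome is formed.
#'
#' @param config a [synthetic_config()].
#' @return list `cohort` (data frame of one row per child; its `ltl_z`
#'   column is the outcome before any measurement/plate noise, and is
#'   overwritten by the measured per-plate z-scores when the qPCR stages
#'   are run) and `truth`
#'   (class `synthetic_truth`: seasonal effect per child, true T/S,
#'   pre-missingness covariates, config echo).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  n <- config$n
  gestation <- 280
  if (config$design == "window_locked") {
    conc0 <- as.Date("2006-01-01")
    conception <- conc0 + sample.int(730, n, replace = TRUE) - 1L
    coll0 <- as.Date("2016-02-01")
    collection <- coll0 + sample.int(120, n, replace = TRUE) - 1L
  } else {
    conc0 <- as.Date("2010-01-01")
    conception <- conc0 + sample.int(1461, n, replace = TRUE) - 1L
    collection <- conception + gestation + 730
  }
  age <- as.numeric(collection - conception - gestation) / 365.25
  sex <- ifelse(stats::runif(n) < 0.55, "male", "female")
  doy_frac <- conception_angle(conception) / (2 * pi)
  season_bw <- if (config$covariate_seasonality)
    50 * cos(2 * pi * (doy_frac - 330 / 365)) else 0
  birthweight <- stats::rnorm(n, 3069, 417) + season_bw
  season_bmi <- if (config$covariate_seasonality)
    0.02 * cos(2 * pi * (doy_frac - 30 / 365)) else 0
  maternal_bmi <- exp(stats::rnorm(n, log(20.8), 0.127) + season_bmi)
  maternal_folate <- exp(stats::rnorm(n, log(13.0), 0.52))
  maternal_arm <- if (config$design == "window_locked") {
    ifelse(stats::runif(n) < 0.47, "UNIMMAP", "Placebo")
  } else {
    sample(c("FeFol", "MMN", "PE", "PE+MMN"), n, replace = TRUE)
  }
  infant_arm <- if (config$design == "age_locked") {
    ifelse(stats::runif(n) < 0.5, "LNS", "LNS+MMN")
  } else NA_character_
  cf <- rdirichlet1(n, c(4, 2, 1, 1, 1, 6)[seq_len(config$n_cell_types)] *
                      rep(1, config$n_cell_types))
  colnames(cf) <- paste0("cf_", cell_type_names(config$n_cell_types))

  theta <- conception_angle(conception)
  theta_peak <- 2 * pi * (config$peak_day - 1) / 365
  seasonal <- config$true_amplitude / 2 * cos(theta - theta_peak)
  beta <- config$covariate_effects
  lin <- numeric(n)
  if (length(beta)) {
    std <- list(age = age, sex_male = as.numeric(sex == "male"),
                birthweight = (birthweight - 3069) / 417,
                maternal_bmi = (log(maternal_bmi) - log(20.8)) / 0.127,
                maternal_folate = (log(maternal_folate) - log(13)) / 0.52)
    for (nm in names(beta)) {
      if (!nm %in% names(std)) stop("unknown covariate effect: ", nm)
      lin <- lin + beta[[nm]] * std[[nm]]
    }
  }
  ltl_z_true <- seasonal + lin + stats::rnorm(n, 0, config$residual_sd)
  ts_true <- pmax(config$ts_mean + config$ts_sd * ltl_z_true, 0.05)

  cohort <- data.frame(child_id = sprintf("C%04d", seq_len(n)),
                       conception_date = conception,
                       collection_date = collection,
                       age = age, sex = sex,
                       maternal_bmi = maternal_bmi,
                       birthweight = birthweight,
                       maternal_folate = maternal_folate,
                       maternal_arm = maternal_arm,
                       infant_arm = infant_arm,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(cf))
  truth_cov <- cohort
  mr <- config$missing_rates
  for (nm in names(mr)) {
    if (mr[[nm]] <= 0) next
    drop <- stats::runif(n) < mr[[nm]]
    if (nm == "cell_fractions") {
      cohort[drop, colnames(cf)] <- NA_real_
    } else if (nm %in% names(cohort)) {
      cohort[drop, nm] <- NA
    }
  }
  cohort$ltl_z <- ltl_z_true
  truth <- structure(list(config = config, seasonal_effect = seasonal,
                          linear_effect = lin, ts_true = ts_true,
                          ltl_z_true = ltl_z_true,
                          covariates_pre_missing = truth_cov),
                     class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

#' Generate raw qPCR plate tables for a synthetic cohort
#'
#' Maps each child's true T/S ratio to duplicate telomere and single-copy
#' Cq readings through configurable true standard curves, after applying
#' a per-plate additive shift and multiplicative scale (the batch effect
#' that per-plate z-scoring removes). Replicate noise is lognormal on the
#' T quantity with log-sd `sqrt(log(1 + cv^2))`, so the expected
#' duplicate CV of replicate T/S ratios equals the configured value. Each
#' plate carries a five-point two-fold dilution series of the reference
#' (relative concentrations 1 to 1/16) for both targets, a duplicated
#' reference sample (T/S 1) and three duplicated control samples
#' (T/S 1.90, 1.54, 1.09 — young, adult and elderly donors).
#'
#' @param cohort cohort data frame from [generate_cohort()].
#' @param truth matching `synthetic_truth`.
#' @param config the same [synthetic_config()].
#' @return list `wells` (raw plate data frame in the CSV dialect of
#'   [read_plate_csv()]), `plate_assignment` (child id -> plate), and
#'   `truth` updated with plate effects.
#' @export
generate_plates <- function(cohort, truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 1L)
  n <- nrow(cohort)
  n_plates <- ceiling(n / config$plate_size)
  plate_of <- rep(seq_len(n_plates), each = config$plate_size)[seq_len(n)]
  plate_ids <- sprintf("P%02d", plate_of)
  shift <- stats::rnorm(n_plates, 0, config$plate_shift_sd)
  scale <- exp(stats::rnorm(n_plates, 0, config$plate_scale_sd))
  # true instrument curves: near-perfect efficiency, T amplifies earlier
  slope <- -1 / log10(2)
  int_t <- 18; int_s <- 26
  sdlog <- sqrt(log(1 + config$duplicate_cv^2))
  # high-CV injection: duplicates at ratio*exp(+-delta) give a duplicate CV
  # of exactly sqrt(2)*tanh(delta) whatever the RNG draws
  delta_high <- atanh(0.25 / sqrt(2))
  high_cv <- stats::runif(n) < config$high_cv_fraction
  failed <- stats::runif(n) < config$fail_rate

  rows <- vector("list", n_plates)
  common_ts <- c(REF = 1.0, CTRL_young = 1.90, CTRL_adult = 1.54,
                 CTRL_old = 1.09)
  common_role <- c("reference", "control", "control", "control")
  dils <- 2^-(0:4)
  for (p in seq_len(n_plates)) {
    pid <- sprintf("P%02d", p)
    wells <- list(); wi <- 0L
    add <- function(sample_id, role, ts = NA, dilution = NA, reps = 2L,
                    high = FALSE, fail = FALSE) {
      logmult <- if (high) {
        sample(c(-1, 1), 1) * delta_high * c(1, -1)[seq_len(reps)]
      } else {
        stats::rnorm(reps, 0, sdlog)
      }
      for (r in seq_len(reps)) {
        wi <<- wi + 1L
        wname <- sprintf("W%03d", wi)
        if (fail) { cq_t <- NA_real_; cq_s <- NA_real_ }
        else if (role == "standard") {
          cq_t <- int_t + slope * log10(dilution)
          cq_s <- int_s + slope * log10(dilution)
        } else {
          ratio <- ts * exp(logmult[r])
          qty_s <- 1
          cq_t <- int_t + slope * log10(ratio * qty_s)
          cq_s <- int_s + slope * log10(qty_s)
        }
        wells[[length(wells) + 1L]] <<- data.frame(
          plate_id = pid, well = wname, sample_id = sample_id,
          target = c("tel", "scg"), cq = c(cq_t, cq_s),
          replicate_idx = r, role = role, dilution = dilution,
          stringsAsFactors = FALSE)
      }
    }
    for (d in dils) add(sprintf("STD_%g", d), "standard", dilution = d, reps = 1L)
    for (j in seq_along(common_ts)) {
      ts_c <- pmax(shift[p] + scale[p] * common_ts[j], 0.05)
      add(names(common_ts)[j], common_role[j], ts = ts_c)
    }
    idx <- which(plate_of == p)
    for (i in idx) {
      ts_p <- pmax(shift[p] + scale[p] * truth$ts_true[i], 0.05)
      add(cohort$child_id[i], "sample", ts = ts_p,
          high = high_cv[i], fail = failed[i])
    }
    rows[[p]] <- do.call(rbind, wells)
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL
  truth$plate_assignment <- data.frame(child_id = cohort$child_id,
                                       plate_id = plate_ids,
                                       stringsAsFactors = FALSE)
  truth$plate_shift <- shift
  truth$plate_scale <- scale
  truth$high_cv <- high_cv
  truth$failed <- failed
  list(wells = wells, plate_assignment = truth$plate_assignment,
       truth = truth)
}

#' Generate a synthetic reference matrix and mixed profiles
#'
#' Draws a markers-by-cell-types reference with well-separated columns,
#' Dirichlet(1,...,1) true mixing fractions, and observed profiles
#' `reference %*% w + N(0, noise_sd)` clipped to [0, 1].
#'
#' @param config a [synthetic_config()] (uses `n`, `n_cell_types`,
#'   `n_markers`, `seed`).
#' @param n_samples number of mixture profiles (default `config$n`).
#' @param noise_sd sd of the additive marker noise.
#' @return list `reference` ([reference_matrix()]), `profiles`
#'   (markers x samples), `true_fractions` (samples x cell types).
#' @export
generate_reference_mixtures <- function(config, n_samples = config$n,
                                        noise_sd = 0.01) {
  stopifnot(inherits(config, "synthetic_config"),
            config$n_markers >= config$n_cell_types)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed + 2L)
  k <- config$n_cell_types; m <- config$n_markers
  ref <- matrix(stats::rbeta(m * k, 0.5, 0.5), m, k,
                dimnames = list(paste0("cg", seq_len(m)), cell_type_names(k)))
  ref <- reference_matrix(ref)
  w <- rdirichlet1(n_samples, rep(1, k))
  colnames(w) <- cell_type_names(k)
  profiles <- unclass(ref) %*% t(w) +
    matrix(stats::rnorm(m * n_samples, 0, noise_sd), m, n_samples)
  profiles <- pmin(pmax(profiles, 0), 1)
  colnames(profiles) <- paste0("S", seq_len(n_samples))
  list(reference = ref, profiles = profiles, true_fractions = w)
}
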