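#' Simulation configuration for a synthetic hypertension cohort
#'
#' Builds the parameter manifest for [simulate_cohort()]. Defaults describe a
#' community cohort of 1,301 adults followed ten years for incident
#' hypertension: Hardy-Weinberg GNB3 genotypes with T-allele frequency 0.532
#' (so P(TT) is about 0.28), a two-class dietary sodium exposure with 11.2%
#' high intake, and odds-scale effects for the four genotype-by-sodium
#' categories. The joint odds ratio is an independent knob, so additive and
#' multiplicative interaction are both configurable.
#'
#' @param n_cohort Cohort size at entry.
#' @param t_allele_freq Frequency q of the T allele; genotypes are drawn
#'   with Hardy-Weinberg probabilities (q^2, 2q(1-q), (1-q)^2) for TT/CT/CC.
#' @param p_high_sodium Probability of the high-sodium exposure class.
#' @param p_male Probability of male gender.
#' @param baseline_odds Odds of incident hypertension in the doubly unexposed,
#'   covariate-reference stratum.
#' @param or_tt True odds ratio for TT genotype with low sodium (OR10).
#' @param or_high_sodium True odds ratio for high sodium with CC/CT (OR01).
#' @param or_joint True odds ratio for TT genotype with high sodium (OR11).
#' @param covariate_prevalences Named vector of Bernoulli prevalences for the
#'   binary covariates.
#' @param covariate_ors Named vector of true odds ratios for the same
#'   covariates; names must match `covariate_prevalences`.
#' @param age_distribution Named probability weights over the four age bands
#'   `le40`, `41-45`, `46-50`, `ge51`.
#' @param age_ors Odds ratios for the age bands (reference `le40` must be 1).
#' @param p_baseline_hypertensive Probability a subject is hypertensive at
#'   entry (such subjects are excluded from analysis sets downstream).
#' @param p_loss_followup Probability a subject is lost to follow-up.
#' @param matching_ratio Controls per case for gender frequency matching.
#' @param sodium_thresholds Length-2 vector `c(low_max, high_min)` in mg/day:
#'   intake <= low_max is low, > high_min is high, otherwise intermediate.
#' @param sodium_levels mg/day values assigned to the two exposure classes
#'   (the generator uses a two-point sodium distribution, so every simulated
#'   subject falls in the low or high class).
#' @param seed Integer seed; all draws in [simulate_cohort()] are reproducible
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cohort = 1301L,
                       t_allele_freq = 0.532,
                       p_high_sodium = 0.112,
                       p_male = 0.5,
                       baseline_odds = 0.028,
                       or_tt = 1.08,
                       or_high_sodium = 2.03,
                       or_joint = 2.88,
                       covariate_prevalences = c(
                         smoker = 0.104, alcohol = 0.107,
                         bmi_abnormal = 0.396, tg_high = 0.245,
                         hdl_low = 0.227, ldl_high = 0.110,
                         diabetes = 0.019, thyroid = 0.009),
                       covariate_ors = c(
                         smoker = 1.78, alcohol = 1.78,
                         bmi_abnormal = 2.51, tg_high = 6.63,
                         hdl_low = 2.60, ldl_high = 1.62,
                         diabetes = 2.86, thyroid = 1.51),
                       age_distribution = c(
                         "le40" = 0.087, "41-45" = 0.268,
                         "46-50" = 0.403, "ge51" = 0.242),
                       age_ors = c(
                         "le40" = 1, "41-45" = 1.31,
                         "46-50" = 2.08, "ge51" = 2.36),
                       p_baseline_hypertensive = 0,
                       p_loss_followup = 0,
                       matching_ratio = 3L,
                       sodium_thresholds = c(low_max = 2400, high_min = 4800),
                       sodium_levels = c(low = 1800, high = 6000),
                       seed = 1L) {
  cfg <- list(
    n_cohort = as.integer(n_cohort), t_allele_freq = t_allele_freq,
    p_high_sodium = p_high_sodium, p_male = p_male,
    baseline_odds = baseline_odds, or_tt = or_tt,
    or_high_sodium = or_high_sodium, or_joint = or_joint,
    covariate_prevalences = covariate_prevalences,
    covariate_ors = covariate_ors,
    age_distribution = age_distribution, age_ors = age_ors,
    p_baseline_hypertensive = p_baseline_hypertensive,
    p_loss_followup = p_loss_followup,
    matching_ratio = as.integer(matching_ratio),
    sodium_thresholds = c(low_max = unname(sodium_thresholds[1]),
                          high_min = unname(sodium_thresholds[2])),
    sodium_levels = c(low = unname(sodium_levels["low"]),
                      high = unname(sodium_levels["high"])),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_cohort >= 1L)
  probs <- c(cfg$t_allele_freq, cfg$p_high_sodium, cfg$p_male)
  if (any(probs <= 0) || any(probs >= 1))
    stop("t_allele_freq, p_high_sodium and p_male must lie in (0, 1)")
  ors <- c(cfg$baseline_odds, cfg$or_tt, cfg$or_high_sodium, cfg$or_joint,
           cfg$covariate_ors, cfg$age_ors)
  if (any(!is.finite(log(ors))))
    stop("baseline_odds and all odds ratios must be strictly positive ",
         "and finite (non-finite logit)")
  if (!identical(sort(names(cfg$covariate_prevalences)),
                 sort(names(cfg$covariate_ors))))
    stop("covariate_prevalences and covariate_ors must share names")
  if (any(cfg$covariate_prevalences < 0) || any(cfg$covariate_prevalences > 1))
    stop("covariate prevalences must lie in [0, 1]")
  if (abs(sum(cfg$age_distribution) - 1) > 1e-8)
    stop("age_distribution weights must sum to 1")
  if (cfg$age_ors[["le40"]] != 1)
    stop("the reference age band le40 must have odds ratio 1")
  thr <- cfg$sodium_thresholds
  if (thr[["low_max"]] > thr[["high_min"]])
    stop("sodium low_max threshold must not exceed high_min")
  q <- cfg$t_allele_freq
  hwe <- c(q^2, 2 * q * (1 - q), (1 - q)^2)
  stopifnot(abs(sum(hwe) - 1) < 1e-12)
  invisible(cfg)
}

# Age bands used throughout; band edges follow the descriptive table coding
# (three dummies against a <=40 reference).
age_band_levels <- function() c("le40", "41-45", "46-50", "ge51")

age_band_range <- function(band) {
  switch(band,
         "le40" = c(25L, 40L), "41-45" = c(41L, 45L),
         "46-50" = c(46L, 50L), "ge51" = c(51L, 60L))
}

#' Simulate a baseline cohort with known effect structure
#'
#' Draws `n_cohort` subjects under the configuration and simulates ten-year
#' incident hypertension directly on the odds scale: the four
#' genotype-by-sodium categories get log odds `log(baseline_odds)` plus
#' `log(or_tt)`, `log(or_high_sodium)` or `log(or_joint)` for the
#' TT-low, CC/CT-high and TT-high cells respectively, plus the sum of
#' `log(covariate_or)` over the subject's positive covariates and age band.
#' Generating the dichotomous outcome this way makes the true odds ratios
#' exact, which is what a case-control analysis consumes.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional override of `config$seed`.
#'
#' @return A data frame with one row per subject: `subject_id`, `gender`,
#'   `age_band`, `age_years`, `genotype`, `sodium_mg`, `sodium_class`, one
#'   0/1 column per covariate, `baseline_hypertensive`, `lost_followup` and
#'   `case` (incident hypertension, 0/1).
#' @export
simulate_cohort <- function(config, seed = NULL) {
  validate_sim_config(config)
  set.seed(if (is.null(seed)) config$seed else as.integer(seed))
  n <- config$n_cohort
  q <- config$t_allele_freq

  gender <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  genotype <- sample(c("TT", "CT", "CC"), n, replace = TRUE,
                     prob = c(q^2, 2 * q * (1 - q), (1 - q)^2))
  age_band <- sample(age_band_levels(), n, replace = TRUE,
                     prob = config$age_distribution[age_band_levels()])
  age_years <- vapply(age_band, function(b) {
    r <- age_band_range(b)
    sample(seq.int(r[1], r[2]), 1L)
  }, integer(1))

  high <- stats::runif(n) < config$p_high_sodium
  sodium_mg <- ifelse(high, config$sodium_levels[["high"]],
                      config$sodium_levels[["low"]])
  sodium_class <- classify_sodium(sodium_mg, config$sodium_thresholds)

  covs <- vapply(names(config$covariate_prevalences), function(nm) {
    as.integer(stats::runif(n) < config$covariate_prevalences[[nm]])
  }, integer(n))
  covs <- as.data.frame(covs)

  tt <- genotype == "TT"
  logit <- log(config$baseline_odds) +
    log(config$or_tt) * (tt & !high) +
    log(config$or_high_sodium) * (!tt & high) +
    log(config$or_joint) * (tt & high) +
    as.matrix(covs) %*% log(config$covariate_ors[names(covs)]) +
    log(config$age_ors)[match(age_band, names(config$age_ors))]
  logit <- drop(logit)
  if (any(!is.finite(logit))) stop("non-finite logit; rejecting config")

  case <- as.integer(stats::runif(n) < stats::plogis(logit))
  baseline_hypertensive <- stats::runif(n) < config$p_baseline_hypertensive
  lost_followup <- stats::runif(n) < config$p_loss_followup

  cbind(
    data.frame(
      subject_id = sprintf("S%05d", seq_len(n)),
      gender = gender, age_band = age_band, age_years = age_years,
      genotype = genotype, sodium_mg = sodium_mg,
      sodium_class = sodium_class, stringsAsFactors = FALSE),
    covs,
    data.frame(baseline_hypertensive = as.integer(baseline_hypertensive),
               lost_followup = as.integer(lost_followup),
               case = case))
}

#' Classify incident hypertension from the follow-up examination
#'
#' A subject is classified hypertensive when physician-diagnosed, on any
#' antihypertensive medication, or with resting systolic pressure >= 140 mmHg
#' or diastolic pressure >= 90 mmHg.
#'
#' @param sbp,dbp Resting systolic/diastolic blood pressure in mmHg.
#' @param physician_diagnosed,on_medication Logicals.
#' @return Logical vector.
#' @export
classify_outcome <- function(sbp, dbp, physician_diagnosed = FALSE,
                             on_medication = FALSE) {
  if (any(sbp < 0, na.rm = TRUE) || any(dbp < 0, na.rm = TRUE))
    stop("blood pressures must be non-negative")
  physician_diagnosed | on_medication | sbp >= 140 | dbp >= 90
}

#' Classify daily sodium intake into low / intermediate / high
#'
#' Intake at or below `low_max` is low; strictly above `high_min` is high;
#' anything between is intermediate (the analysis pipeline excludes the
#' intermediate class with a logged count, mirroring a design that
#' dichotomizes the exposure).
#'
#' @param sodium_mg Intake in mg/day, non-negative.
#' @param thresholds `c(low_max, high_min)` in mg/day, default `(2400, 4800)`.
#' @return Character vector in `{"low", "intermediate", "high"}`.
#' @export
classify_sodium <- function(sodium_mg, thresholds = c(2400, 4800)) {
  low_max <- thresholds[[1]]
  high_min <- thresholds[[2]]
  if (low_max > high_min) stop("low_max must not exceed high_min")
  if (any(sodium_mg < 0, na.rm = TRUE))
    stop("sodium_mg must be non-negative")
  out <- ifelse(sodium_mg <= low_max, "low",
                ifelse(sodium_mg > high_min, "high", "intermediate"))
  out[is.na(sodium_mg)] <- NA_character_
  out
}

#' Assemble a nested case-control sample by frequency matching
#'
#' All incident cases are kept; controls are sampled without replacement from
#' the eligible non-cases so that within each matching stratum the number of
#' controls is `ratio` times the number of cases (or all available controls
#' if the stratum is short, which sets the `partial` flag and warns).
#'
#' @param cohort Cohort data frame from [simulate_cohort()]; must already
#'   exclude baseline hypertensives (rows with `baseline_hypertensive == 1`
#'   are an error).
#' @param ratio Controls per case.
#' @param match_on Column defining the matching strata (default `"gender"`).
#' @param seed Integer seed for the control sampling.
#' @param controls_from `"followup_normotensive"` (default) samples controls
#'   among subjects who did not develop hypertension; `"baseline_roster"`
#'   samples among all non-case rows including those lost to follow-up.
#'
#' @return A list with `cases`, `controls` (data frames), `partial`
#'   (logical), and `by_stratum` (per-stratum accounting).
#' @export
frequency_match <- function(cohort, ratio = 3L, match_on = "gender",
                            seed = 1L,
                            controls_from = c("followup_normotensive",
                                              "baseline_roster")) {
  controls_from <- match.arg(controls_from)
  stopifnot(ratio >= 1L, match_on %in% names(cohort))
  if (any(cohort$baseline_hypertensive == 1))
    stop("cohort must exclude baseline hypertensives before matching")
  set.seed(as.integer(seed))

  followed <- cohort[cohort$lost_followup == 0, , drop = FALSE]
  cases <- followed[followed$case == 1, , drop = FALSE]
  if (nrow(cases) == 0L) stop("no incident cases to match")
  pool <- if (controls_from == "followup_normotensive") {
    followed[followed$case == 0, , drop = FALSE]
  } else {
    cohort[cohort$case == 0, , drop = FALSE]
  }

  strata <- unique(cases[[match_on]])
  picked <- list()
  acct <- data.frame(stratum = strata, n_cases = NA_integer_,
                     n_controls = NA_integer_, wanted = NA_integer_,
                     stringsAsFactors = FALSE)
  partial <- FALSE
  for (i in seq_along(strata)) {
    s <- strata[i]
    n_cases_s <- sum(cases[[match_on]] == s)
    avail <- pool[pool[[match_on]] == s, , drop = FALSE]
    wanted <- ratio * n_cases_s
    if (nrow(avail) == 0L && n_cases_s > 0L) {
      warning("stratum '", s, "' has cases but no eligible controls")
      partial <- TRUE
      take <- avail
    } else if (nrow(avail) < wanted) {
      warning("stratum '", s, "' has only ", nrow(avail),
              " eligible controls for ", wanted, " requested")
      partial <- TRUE
      take <- avail
    } else {
      take <- avail[sample.int(nrow(avail), wanted), , drop = FALSE]
    }
    picked[[i]] <- take
    acct$n_cases[i] <- n_cases_s
    acct$n_controls[i] <- nrow(take)
    acct$wanted[i] <- wanted
  }
  controls <- do.call(rbind, picked)
  rownames(controls) <- NULL
  rownames(cases) <- NULL
  list(cases = cases, controls = controls, partial = partial,
       by_stratum = acct)
}
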