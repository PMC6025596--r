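#' Relative excess risk due to interaction (RERI)
#'
#' Departure of the jointly exposed odds ratio from additivity of the two
#' single-exposure excesses, with odds ratios substituted for risk ratios:
#' `RERI = OR11 - OR10 - OR01 + 1`. Zero under exact additivity.
#'
#' @param or11 Odds ratio for the doubly exposed category.
#' @param or10,or01 Odds ratios for the two singly exposed categories.
#' @return Numeric RERI.
#' @export
reri <- function(or11, or10, or01) {
  check_positive_ors(or11, or10, or01)
  or11 - or10 - or01 + 1
}

#' Attributable proportion due to interaction (AP)
#'
#' Share of the doubly exposed group's relative odds attributable to
#' interaction: `AP = RERI / OR11`. This is the variant dividing by `OR11`,
#' not by `OR11 - 1`.
#'
#' @inheritParams reri
#' @return Numeric AP.
#' @export
attributable_proportion <- function(or11, or10, or01) {
  reri(or11, or10, or01) / or11
}

#' Rothman synergy index (S)
#'
#' `S = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1))`; values above 1 indicate a
#' super-additive (synergistic) joint effect. The index is undefined when
#' the denominator is non-positive, and sign-incoherent when `OR11 <= 1`;
#' both return `NA` with attribute `estimable = FALSE` rather than a signed
#' value.
#'
#' @inheritParams reri
#' @return Numeric S, or `NA` (attribute `estimable = FALSE`) when not
#'   estimable.
#' @export
synergy_index <- function(or11, or10, or01) {
  check_positive_ors(or11, or10, or01)
  denom <- (or10 - 1) + (or01 - 1)
  if (denom <= 0 || or11 <= 1)
    return(structure(NA_real_, estimable = FALSE))
  structure((or11 - 1) / denom, estimable = TRUE)
}

check_positive_ors <- function(or11, or10, or01) {
  if (any(c(or11, or10, or01) <= 0) || any(!is.finite(c(or11, or10, or01))))
    stop("odds ratios must be strictly positive and finite")
  invisible(TRUE)
}

#' Additive-interaction estimates from a fitted joint-exposure model
#'
#' Reads the three joint-exposure dummy coefficients off a logistic fit
#' (`or10 = exp(beta_g)`, `or01 = exp(beta_e)`, `or11 = exp(beta_ge)`; the
#' reference category has OR 1 by construction) and fills RERI, AP and the
#' synergy index with delta-method confidence intervals from the fit's
#' variance-covariance matrix.
#'
#' @param fit A converged `logistic_fit` containing the three dummies.
#' @param terms Coefficient names of the (g, e, ge) dummies.
#' @param level Confidence level.
#' @return An `interaction_estimates` object: `or10`, `or01`, `or11`
#'   ([adjusted_or()] results), `reri`, `ap`, `s`, intervals `ci_reri`,
#'   `ci_ap`, `ci_s`, `level`, `method`.
#' @export
interaction_from_fit <- function(fit, terms = c(g = "g", e = "e", ge = "ge"),
                                 level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge")
  missing <- setdiff(unname(terms), names(fit$coefficients))
  if (length(missing))
    stop("terms absent from fit: ", paste(missing, collapse = ", "))
  or10 <- exp(fit$coefficients[[terms[["g"]]]])
  or01 <- exp(fit$coefficients[[terms[["e"]]]])
  or11 <- exp(fit$coefficients[[terms[["ge"]]]])
  s <- synergy_index(or11, or10, or01)
  est <- list(
    or10 = adjusted_or(fit, terms[["g"]], level),
    or01 = adjusted_or(fit, terms[["e"]], level),
    or11 = adjusted_or(fit, terms[["ge"]], level),
    reri = reri(or11, or10, or01),
    ap = attributable_proportion(or11, or10, or01),
    s = s,
    ci_reri = delta_ci(fit, terms, "reri", level),
    ci_ap = delta_ci(fit, terms, "ap", level),
    ci_s = if (isTRUE(attr(s, "estimable")))
      delta_ci(fit, terms, "ln_s", level) else
        structure(c(NA_real_, NA_real_), estimable = FALSE),
    level = level, method = "delta")
  structure(est, class = "interaction_estimates")
}

#' @export
print.interaction_estimates <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3f (%.0f%% CI %.3f-%.3f)", v,
                                 100 * x$level, ci[1], ci[2])
  cat("Additive interaction on the odds-ratio scale (", x$method,
      " intervals)\n", sep = "")
  cat("  OR10 (gene only):    ", sprintf("%.3f", x$or10$or_point), "\n")
  cat("  OR01 (exposure only):", sprintf("%.3f", x$or01$or_point), "\n")
  cat("  OR11 (joint):        ", sprintf("%.3f", x$or11$or_point), "\n")
  cat("  RERI:", fmt(x$reri, x$ci_reri), "\n")
  cat("  AP:  ", fmt(x$ap, x$ci_ap), "\n")
  if (isTRUE(attr(x$s, "estimable"))) {
    cat("  S:   ", fmt(as.numeric(x$s), x$ci_s), "\n")
  } else {
    cat("  S:    not estimable (non-positive excess-odds denominator)\n")
  }
  invisible(x)
}

#' Delta-method confidence interval for an interaction statistic
#'
#' First-order variance propagation through the statistic's gradient with
#' respect to the three dummy coefficients, using the corresponding 3x3
#' block of the fit's variance-covariance matrix. RERI and AP intervals are
#' on the natural (symmetric) scale; the synergy-index interval is built on
#' `ln S` and exponentiated, which guarantees a positive, right-skewed
#' interval.
#'
#' @inheritParams interaction_from_fit
#' @param statistic One of `"reri"`, `"ap"`, `"ln_s"`.
#' @return Length-2 interval. For `"ln_s"` the returned endpoints are on the
#'   S scale. Attribute `estimable = FALSE` (with `NA` endpoints) when the
#'   synergy index is undefined at the point estimate.
#' @export
delta_ci <- function(fit, terms = c(g = "g", e = "e", ge = "ge"),
                     statistic = c("reri", "ap", "ln_s"), level = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("fit did not converge")
  nm <- c(terms[["g"]], terms[["e"]], terms[["ge"]])
  b <- fit$coefficients[nm]
  V <- fit$vcov[nm, nm]
  p1 <- exp(b[[1]]); p2 <- exp(b[[2]]); p3 <- exp(b[[3]])  # OR10, OR01, OR11
  z <- stats::qnorm(1 - (1 - level) / 2)

  if (statistic == "reri") {
    point <- p3 - p1 - p2 + 1
    grad <- c(-p1, -p2, p3)
  } else if (statistic == "ap") {
    point <- (p3 - p1 - p2 + 1) / p3
    grad <- c(-p1 / p3, -p2 / p3, (p1 + p2 - 1) / p3)
  } else {
    denom <- (p1 - 1) + (p2 - 1)
    if (denom <= 0 || p3 <= 1)
      return(structure(c(NA_real_, NA_real_), estimable = FALSE))
    point <- log(p3 - 1) - log(denom)
    grad <- c(-p1 / denom, -p2 / denom, p3 / (p3 - 1))
  }
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- c(point - z * se, point + z * se)
  if (statistic == "ln_s") ci <- exp(ci)
  structure(unname(ci), estimable = TRUE, se = se)
}

#' Bootstrap confidence interval for an interaction statistic
#'
#' Case-control-stratified resampling with replacement: cases are resampled
#' among cases and controls among controls, the joint-exposure logistic
#' model is refitted per replicate and the statistic recomputed; the
#' interval is the percentile interval across replicates. Replicates where
#' the statistic is not estimable (or the fit fails) are counted; when more
#' than 20% fail the interval is flagged unreliable.
#'
#' @param records Data frame with `case` and either precomputed `g`, `e`,
#'   `ge` dummies or `genotype` / `sodium_class` columns.
#' @param statistic One of `"reri"`, `"ap"`, `"s"`.
#' @param terms Dummy term names (added via [add_joint_dummies()] when
#'   absent).
#' @param covariates Extra adjustment terms to include in each refit.
#' @param n_boot Number of replicates (at least 200).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return Length-2 percentile interval with attributes `n_failed`,
#'   `unreliable`, `replicates`.
#' @export
bootstrap_ci <- function(records, statistic = c("reri", "ap", "s"),
                         terms = c(g = "g", e = "e", ge = "ge"),
                         covariates = character(0),
                         n_boot = 1000L, seed = 1L, level = 0.95) {
  statistic <- match.arg(statistic)
  if (n_boot < 200L) stop("n_boot must be at least 200")
  if (!all(unname(terms) %in% names(records)))
    records <- add_joint_dummies(records)
  set.seed(as.integer(seed))
  case_idx <- which(records$case == 1)
  ctrl_idx <- which(records$case == 0)
  stopifnot(length(case_idx) > 0, length(ctrl_idx) > 0)

  stat_fun <- function(or11, or10, or01) {
    switch(statistic,
           reri = reri(or11, or10, or01),
           ap = attributable_proportion(or11, or10, or01),
           s = as.numeric(synergy_index(or11, or10, or01)))
  }
  reps <- vapply(seq_len(n_boot), function(i) {
    idx <- c(sample(case_idx, length(case_idx), replace = TRUE),
             sample(ctrl_idx, length(ctrl_idx), replace = TRUE))
    boot <- records[idx, , drop = FALSE]
    tryCatch({
      fit <- fit_logistic_model(boot, "case",
                                c(unname(terms), covariates))
      or10 <- exp(fit$coefficients[[terms[["g"]]]])
      or01 <- exp(fit$coefficients[[terms[["e"]]]])
      or11 <- exp(fit$coefficients[[terms[["ge"]]]])
      stat_fun(or11, or10, or01)
    }, error = function(e) NA_real_)
  }, numeric(1))

  n_failed <- sum(is.na(reps))
  unreliable <- n_failed > 0.2 * n_boot
  if (unreliable)
    warning(sprintf("%d of %d bootstrap replicates not estimable; %s",
                    n_failed, n_boot, "interval flagged unreliable"))
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE,
                               type = 6))
  structure(ci, n_failed = n_failed, unreliable = unreliable,
            replicates = reps)
}
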