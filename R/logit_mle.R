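#' Add joint-exposure dummy columns to subject records
#'
#' Adds the three dummies used in the four-category interaction coding:
#' `g` = TT genotype with low sodium, `e` = CC/CT with high sodium,
#' `ge` = TT with high sodium; the doubly unexposed (CC/CT, low sodium) is
#' the reference with all three dummies zero. Rows with intermediate sodium
#' get `NA` dummies and are dropped at design-matrix time.
#'
#' @param records Data frame with `genotype` and `sodium_class` columns.
#' @return `records` with `g`, `e`, `ge` columns appended.
#' @export
add_joint_dummies <- function(records) {
  tt <- records$genotype == "TT"
  high <- ifelse(records$sodium_class %in% c("low", "high"),
                 records$sodium_class == "high", NA)
  records$g <- as.integer(tt & !high)
  records$e <- as.integer(!tt & high)
  records$ge <- as.integer(tt & high)
  records
}

#' Build a logistic-regression design matrix from subject records
#'
#' Numeric and 0/1 columns enter as single columns; character or factor
#' columns are expanded into dummy indicators against a reference level
#' (the first level unless given in `reference`). Rows with any missing
#' value in the outcome or terms are dropped and counted.
#'
#' @param records Data frame.
#' @param outcome Name of the binary outcome column.
#' @param terms Character vector of term (column) names, in model order.
#' @param reference Named list mapping a term to its reference level.
#' @return List with `X` (matrix including intercept), `y`, `n_dropped`,
#'   and `term_names`.
#' @export
build_design <- function(records, outcome, terms, reference = list()) {
  stopifnot(outcome %in% names(records))
  missing_terms <- setdiff(terms, names(records))
  if (length(missing_terms))
    stop("unknown terms: ", paste(missing_terms, collapse = ", "))
  if (anyDuplicated(terms)) stop("duplicated terms in design")

  used <- records[, c(outcome, terms), drop = FALSE]
  complete <- stats::complete.cases(used)
  n_dropped <- sum(!complete)
  used <- used[complete, , drop = FALSE]
  if (nrow(used) == 0L) stop("no complete rows for the design")

  y <- as.numeric(used[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")

  cols <- list("(Intercept)" = rep(1, nrow(used)))
  for (tm in terms) {
    v <- used[[tm]]
    if (is.numeric(v) || is.logical(v)) {
      cols[[tm]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      levs <- unique(v)
      ref <- if (!is.null(reference[[tm]])) reference[[tm]] else sort(levs)[1]
      if (!ref %in% levs)
        stop("reference level '", ref, "' absent from term ", tm)
      for (lv in setdiff(sort(levs), ref)) {
        cols[[paste0(tm, lv)]] <- as.numeric(v == lv)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop("aliased (constant) term after encoding: ",
         paste(names(const)[const], collapse = ", "))
  list(X = X, y = y, n_dropped = n_dropped, term_names = colnames(X)[-1])
}

bernoulli_loglik <- function(y, eta) {
  # log(1 + exp(eta)) ~ eta for large eta; keeps the likelihood finite
  lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  sum(y * eta - lse)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson on the Bernoulli log-likelihood with the canonical logit
#' link (observed information equals expected information). Step-halving
#' keeps the log-likelihood non-decreasing at every iteration. Convergence
#' is declared when the score max-norm falls below `tol`. Coefficients
#' drifting beyond `beta_guard` in absolute value raise a separation error
#' rather than returning silently diverging output; Firth's bias-reduced
#' score is available for separated or sparse data.
#'
#' @param X Design matrix including the intercept column (see
#'   [build_design()]).
#' @param y Binary outcome vector.
#' @param tol Convergence tolerance on `max |score|`, default `1e-8`.
#' @param max_iter Maximum Newton iterations, default 50.
#' @param firth Use Firth's penalized score (default `FALSE`).
#' @param beta_guard Separation guard on `max |beta|`, default 15.
#' @return Object of class `logistic_fit`: `coefficients` (named, intercept
#'   first), `vcov` (inverse observed information), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n_obs`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, max_iter = 50L, firth = FALSE,
                         beta_guard = 15) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  beta <- rep(0, ncol(X))
  ll_trace <- numeric(0)
  ll <- bernoulli_loglik(y, drop(X %*% beta))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X, X * w)
    score <- drop(crossprod(X, y - mu))
    if (firth) {
      # Firth adjustment: score_j + 0.5 * tr(I^-1 dI/dbeta_j)
      h <- rowSums((X %*% solve(info)) * X) * w
      score <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    }
    if (max(abs(score)) < tol) {
      converged <- TRUE
      ll_trace <- c(ll_trace, ll)
      break
    }
    step <- solve(info, score)
    # step-halving guarantees a monotone log-likelihood path
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- bernoulli_loglik(y, drop(X %*% cand))
      if (firth) ll_new <- ll_new + 0.5 * determinant(
        crossprod(X, X * pmax(stats::plogis(drop(X %*% cand)) *
                                (1 - stats::plogis(drop(X %*% cand))),
                              1e-12)))$modulus
      if (ll_new >= ll - 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta + lambda * step
    ll <- bernoulli_loglik(y, drop(X %*% beta))
    ll_trace <- c(ll_trace, ll)
    if (!firth && max(abs(beta)) > beta_guard)
      stop(errorCondition(paste0(
        "coefficients diverging (max |beta| > ", beta_guard,
        "): likely complete or quasi-complete separation"),
        class = "separation_error"))
    if (iter >= max_iter) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * pmax(mu * (1 - mu), 1e-12))
  vc <- solve(info)
  dimnames(vc) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov = vc,
                 loglik = bernoulli_loglik(y, eta),
                 loglik_trace = ll_trace, n_iter = iter,
                 converged = converged, n_obs = length(y),
                 firth = firth),
            class = "logistic_fit")
}

#' Fit a logistic model from records and a term list
#'
#' Convenience wrapper combining [build_design()] and [fit_logistic()].
#'
#' @inheritParams build_design
#' @param ... Passed to [fit_logistic()].
#' @return A `logistic_fit` with the design's `n_dropped` attached.
#' @export
fit_logistic_model <- function(records, outcome, terms, reference = list(),
                               ...) {
  d <- build_design(records, outcome, terms, reference)
  fit <- fit_logistic(d$X, d$y, ...)
  fit$n_dropped <- d$n_dropped
  fit
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (IRLS):", x$n_obs, "observations,",
      x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    or = exp(x$coefficients))
  print(round(tab, 4))
  invisible(x)
}

#' Adjusted odds ratio for one model term
#'
#' `exp(beta)` with a Wald interval `exp(beta +/- z * SE)` and the Wald
#' p-value for that coefficient.
#'
#' @param fit A `logistic_fit`.
#' @param term Coefficient name.
#' @param level Confidence level.
#' @return An `or_estimate`.
#' @export
adjusted_or <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!term %in% names(fit$coefficients))
    stop("unknown term: ", term)
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- stats::qnorm(1 - (1 - level) / 2)
  or_estimate(exp(b), exp(b - z * se), exp(b + z * se), level,
              2 * stats::pnorm(-abs(b / se)))
}
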