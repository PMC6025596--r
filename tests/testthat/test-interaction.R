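test_that("RERI, AP and S evaluate the defining formulas exactly", {
  # values computed from the published adjusted odds ratios
  expect_equal(reri(3.23, 1.08, 1.51), 1.64)
  expect_equal(round(attributable_proportion(3.23, 1.08, 1.51), 2), 0.51)
  expect_equal(as.numeric(synergy_index(3.23, 1.08, 1.51)), 2.23 / 0.59)
  # hand arithmetic
  expect_equal(attributable_proportion(4, 2, 2), 1 / 4)
  expect_equal(as.numeric(synergy_index(5, 2, 3)), 4 / 3)
  # exact additivity: RERI 0, AP 0, S 1
  expect_equal(reri(2.0, 1.5, 1.5), 0)
  expect_equal(attributable_proportion(2.0, 1.5, 1.5), 0)
  expect_equal(as.numeric(synergy_index(2.0, 1.5, 1.5)), 1)
  expect_error(reri(-1, 1, 1), "positive")
  expect_error(attributable_proportion(1, 0, 1), "positive")
})

test_that("multiplicative-null joint effects still show positive RERI", {
  set.seed(8)
  for (i in 1:20) {
    or10 <- 1 + rexp(1)
    or01 <- 1 + rexp(1)
    expect_equal(reri(or10 * or01, or10, or01), (or10 - 1) * (or01 - 1))
    expect_gt(reri(or10 * or01, or10, or01), 0)
  }
})

test_that("interaction identities hold exactly on random estimates", {
  set.seed(14)
  for (i in 1:50) {
    ors <- exp(rnorm(3, 0.3, 0.6))
    or11 <- ors[1]; or10 <- ors[2]; or01 <- ors[3]
    r <- reri(or11, or10, or01)
    ap <- attributable_proportion(or11, or10, or01)
    s <- synergy_index(or11, or10, or01)
    expect_equal(ap * or11, r)
    denom <- (or10 - 1) + (or01 - 1)
    if (isTRUE(attr(s, "estimable"))) {
      expect_equal(as.numeric(s) * denom, or11 - 1)
      # S > 1 iff RERI > 0 when the excess-odds denominator is positive
      expect_equal(as.numeric(s) > 1, r > 0)
    } else {
      expect_true(denom <= 0 || or11 <= 1)
    }
  }
})

test_that("the synergy index is flagged not estimable off its domain", {
  s1 <- synergy_index(2.5, 0.8, 1.1)   # denominator <= 0
  expect_true(is.na(s1))
  expect_false(attr(s1, "estimable"))
  s2 <- synergy_index(0.9, 1.5, 1.4)   # protective joint effect
  expect_false(attr(s2, "estimable"))
})

test_that("estimates read off a saturated joint fit equal the crude ORs and
           compose with the scalar formulas", {
  recs <- add_joint_dummies(counts_to_records(joint_counts))
  fit <- fit_logistic_model(recs, "case", c("g", "e", "ge"))
  inter <- interaction_from_fit(fit)
  crude <- joint_crude_ors(joint_counts)
  expect_equal(inter$or10$or_point, crude$or10$or_point, tolerance = 1e-9)
  expect_equal(inter$or01$or_point, crude$or01$or_point, tolerance = 1e-9)
  expect_equal(inter$or11$or_point, crude$or11$or_point, tolerance = 1e-9)
  # compositional identity with the scalar operations, machine precision
  expect_identical(inter$reri, reri(inter$or11$or_point,
                                    inter$or10$or_point,
                                    inter$or01$or_point))
  expect_identical(inter$ap,
                   attributable_proportion(inter$or11$or_point,
                                           inter$or10$or_point,
                                           inter$or01$or_point))
  expect_identical(as.numeric(inter$s),
                   as.numeric(synergy_index(inter$or11$or_point,
                                            inter$or10$or_point,
                                            inter$or01$or_point)))
  # the exponentiated ln-S interval is positive and contains the point
  expect_gt(inter$ci_s[1], 0)
  expect_lte(inter$ci_s[1], as.numeric(inter$s))
  expect_gte(inter$ci_s[2], as.numeric(inter$s))
  expect_error(interaction_from_fit(fit, terms = c(g = "g", e = "e",
                                                   ge = "absent")),
               "absent")
})

test_that("delta variance of RERI reduces to the three-term formula under a
           diagonal covariance", {
  b <- c("(Intercept)" = -1, g = 0.2, e = 0.5, ge = 1.1)
  V <- diag(c(0.01, 0.04, 0.03, 0.09))
  dimnames(V) <- list(names(b), names(b))
  fake <- structure(list(coefficients = b, vcov = V, converged = TRUE),
                    class = "logistic_fit")
  ci <- delta_ci(fake, statistic = "reri")
  # symbolic expansion: e^{2 b_ge} V_ge + e^{2 b_g} V_g + e^{2 b_e} V_e
  var_expect <- exp(2 * 1.1) * 0.09 + exp(2 * 0.2) * 0.04 +
    exp(2 * 0.5) * 0.03
  expect_equal(attr(ci, "se")^2, var_expect, tolerance = 1e-12)
  # interval is symmetric about the point on the natural scale
  point <- exp(1.1) - exp(0.2) - exp(0.5) + 1
  expect_equal(mean(ci), point)
  # ln-S interval undefined when the point is off-domain
  b2 <- b; b2[c("g", "e")] <- c(-0.4, -0.3)
  fake2 <- structure(list(coefficients = b2, vcov = V, converged = TRUE),
                     class = "logistic_fit")
  ci2 <- delta_ci(fake2, statistic = "ln_s")
  expect_false(attr(ci2, "estimable"))
  expect_true(all(is.na(ci2)))
})

test_that("bootstrap intervals are seed-stable and centred like the delta
           interval", {
  coh <- add_joint_dummies(simulate_cohort(exposure_only_config(
    3000, ors = c(1.2, 2.0, 3.1), seed = 19)))
  b1 <- bootstrap_ci(coh, "ap", n_boot = 300, seed = 7)
  b2 <- bootstrap_ci(coh, "ap", n_boot = 300, seed = 7)
  expect_identical(as.numeric(b1), as.numeric(b2))
  expect_lt(b1[1], b1[2])
  fit <- fit_logistic_model(coh, "case", c("g", "e", "ge"))
  ap_hat <- interaction_from_fit(fit)$ap
  expect_gt(ap_hat, b1[1])
  expect_lt(ap_hat, b1[2])
  expect_error(bootstrap_ci(coh, "ap", n_boot = 100), "at least 200")
})
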