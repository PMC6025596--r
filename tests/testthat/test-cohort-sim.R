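test_that("hypertension outcome classifier applies the diagnostic criteria", {
  expect_false(classify_outcome(139, 89, FALSE, FALSE))
  expect_true(classify_outcome(140, 80, FALSE, FALSE))
  expect_true(classify_outcome(120, 70, FALSE, TRUE))
  expect_true(classify_outcome(100, 90, FALSE, FALSE))
  expect_true(classify_outcome(100, 70, TRUE, FALSE))
  expect_equal(classify_outcome(c(139, 140), c(89, 89)), c(FALSE, TRUE))
  expect_error(classify_outcome(-1, 80), "non-negative")
})

test_that("sodium classifier respects both thresholds and the middle band", {
  thr <- c(2400, 4800)
  expect_identical(classify_sodium(2400, thr), "low")
  expect_identical(classify_sodium(4801, thr), "high")
  expect_identical(classify_sodium(3600, thr), "intermediate")
  expect_identical(classify_sodium(4800, thr), "intermediate")
  expect_identical(classify_sodium(c(0, 2500, 9000), thr),
                   c("low", "intermediate", "high"))
  # thresholds are configurable (e.g. the 2500/5000 variant)
  expect_identical(classify_sodium(2500, c(2500, 5000)), "low")
  expect_error(classify_sodium(-5, thr), "non-negative")
  expect_error(classify_sodium(3000, c(5000, 2400)), "low_max")
})

test_that("simulated genotypes follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n_cohort = 1e5, t_allele_freq = 0.532, seed = 1)
  coh <- simulate_cohort(cfg)
  q <- 0.532
  counts <- table(factor(coh$genotype, c("TT", "CT", "CC")))
  gof <- chisq.test(counts, p = c(q^2, 2 * q * (1 - q), (1 - q)^2))
  expect_gt(gof$p.value, 0.001)
  # TT fraction near the control-population value within binomial error
  p_tt <- q^2
  expect_lt(abs(mean(coh$genotype == "TT") - p_tt),
            4 * sqrt(p_tt * (1 - p_tt) / 1e5))
})

test_that("generator reproduces its configured marginals and risks", {
  cfg <- sim_config(n_cohort = 5e4, seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 5e4)
  expect_lt(abs(mean(coh$sodium_class == "high") - 0.112), 0.006)
  expect_lt(abs(mean(coh$gender == "male") - 0.5), 0.01)
  # overall ten-year incidence in the targeted band
  expect_gt(mean(coh$case), 0.18)
  expect_lt(mean(coh$case), 0.27)
  # reproducible from the seed
  expect_identical(coh, simulate_cohort(cfg))
  expect_error(simulate_cohort(sim_config(n_cohort = 0)), "n_cohort")
  expect_error(sim_config(or_tt = 0), "positive")
})

test_that("null-effect cohorts have the baseline risk in every exposure cell", {
  coh <- simulate_cohort(null_config(2e5, seed = 4, baseline_odds = 0.25))
  p0 <- 0.25 / 1.25
  tt <- coh$genotype == "TT"
  high <- coh$sodium_class == "high"
  cells <- list(ref = !tt & !high, g = tt & !high, e = !tt & high,
                ge = tt & high)
  for (cell in cells) {
    n <- sum(cell)
    expect_lt(abs(mean(coh$case[cell]) - p0), 4 * sqrt(p0 * (1 - p0) / n))
  }
})

test_that("frequency matching returns ratio-matched, seed-stable controls", {
  coh <- simulate_cohort(sim_config(n_cohort = 4000, seed = 5))
  m <- frequency_match(coh, ratio = 3, seed = 9)
  expect_equal(nrow(m$controls), 3 * nrow(m$cases))
  # case set is exactly the incident cases, untouched
  expect_setequal(m$cases$subject_id, coh$subject_id[coh$case == 1])
  # no control reused, no case doubles as control
  expect_false(anyDuplicated(m$controls$subject_id) > 0)
  expect_length(intersect(m$controls$subject_id, m$cases$subject_id), 0)
  expect_true(all(m$controls$case == 0))
  # gender split of controls mirrors the cases exactly per stratum
  for (g in unique(m$cases$gender)) {
    expect_equal(sum(m$controls$gender == g), 3 * sum(m$cases$gender == g))
  }
  expect_false(m$partial)
  # seed reproducibility
  m2 <- frequency_match(coh, ratio = 3, seed = 9)
  expect_identical(m$controls$subject_id, m2$controls$subject_id)
  # a 233-case sample at 1:3 gives 699 controls
  set.seed(42)
  toy <- data.frame(
    subject_id = as.character(1:3000), gender = rep(c("male", "female"), 1500),
    case = 0L, baseline_hypertensive = 0L, lost_followup = 0L)
  toy$case[sample.int(3000, 233)] <- 1L
  m3 <- frequency_match(toy, ratio = 3, seed = 1)
  expect_equal(nrow(m3$cases), 233)
  expect_equal(nrow(m3$controls), 699)
})

test_that("short control strata are flagged as partial with a warning", {
  toy <- data.frame(
    subject_id = as.character(1:20),
    gender = c(rep("male", 15), rep("female", 5)),
    case = c(rep(1L, 10), rep(0L, 5), rep(1L, 3), rep(0L, 2)),
    baseline_hypertensive = 0L, lost_followup = 0L)
  expect_warning(m <- frequency_match(toy, ratio = 3, seed = 1),
                 "eligible controls")
  expect_true(m$partial)
  expect_equal(nrow(m$cases), 13)
  # all available controls taken where the stratum is short
  expect_equal(nrow(m$controls), 7)
  expect_error(
    frequency_match(
      data.frame(subject_id = "a", gender = "male", case = 1L,
                 baseline_hypertensive = 1L, lost_followup = 0L)),
    "baseline hypertensives")
})

test_that("matched-sample crude OR is consistent for the cohort OR", {
  # the case-control design should not bias the joint odds ratio:
  # over replicates the mean log-OR difference (matched minus cohort) is ~0
  diffs <- vapply(1:200, function(i) {
    coh <- simulate_cohort(exposure_only_config(2500, seed = 1000 + i))
    full <- joint_crude_ors(tabulate_joint(coh))
    # short strata are fine here: all available controls are used
    m <- suppressWarnings(frequency_match(coh, ratio = 3, seed = 1000 + i))
    samp <- joint_crude_ors(tabulate_joint(rbind(m$cases, m$controls)))
    log(samp$or11$or_point) - log(full$or11$or_point)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)))
})
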