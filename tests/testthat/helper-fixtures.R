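# Published study counts used across tests (case-control layout:
# a exposed cases, b exposed controls, c unexposed cases, d unexposed
# controls).
genotype_counts <- c(a = 73, b = 198, c = 160, d = 501)
sodium_counts <- c(a = 51, b = 78, c = 182, d = 621)
joint_counts <- joint_table(cases = c(ref = 128, e = 32, g = 54, ge = 19),
                            controls = c(ref = 446, e = 55, g = 175,
                                         ge = 23))
# adjusted odds ratios as printed in the joint-effects table
printed_aors <- c(or11 = 3.23, or10 = 1.08, or01 = 1.51)

published_counts <- function() {
  utils::read.csv(system.file("extdata", "published_counts.csv",
                              package = "saltsynergy"),
                  stringsAsFactors = FALSE)
}

# small random subject set for brute-force tally oracles
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("X%03d", seq_len(n)),
    gender = sample(c("male", "female"), n, TRUE),
    genotype = sample(c("CC", "CT", "TT"), n, TRUE),
    sodium_class = sample(c("low", "high"), n, TRUE),
    case = rbinom(n, 1, 0.4),
    smoker = rbinom(n, 1, 0.3),
    stringsAsFactors = FALSE)
}

# a null-effect simulation config: every odds ratio 1
null_config <- function(n, seed = 1L, baseline_odds = 0.25) {
  sim_config(
    n_cohort = n, baseline_odds = baseline_odds,
    or_tt = 1, or_high_sodium = 1, or_joint = 1,
    covariate_ors = c(smoker = 1, alcohol = 1, bmi_abnormal = 1,
                      tg_high = 1, hdl_low = 1, ldl_high = 1,
                      diabetes = 1, thyroid = 1),
    age_ors = c("le40" = 1, "41-45" = 1, "46-50" = 1, "ge51" = 1),
    seed = seed)
}

# exposure effects only (covariates null) so the saturated joint model is
# correctly specified and the generating odds ratios are the exact truth
exposure_only_config <- function(n, ors = c(1.08, 2.03, 2.88),
                                 baseline_odds = 0.28, seed = 1L) {
  sim_config(
    n_cohort = n, baseline_odds = baseline_odds,
    or_tt = ors[1], or_high_sodium = ors[2], or_joint = ors[3],
    covariate_ors = c(smoker = 1, alcohol = 1, bmi_abnormal = 1,
                      tg_high = 1, hdl_low = 1, ldl_high = 1,
                      diabetes = 1, thyroid = 1),
    age_ors = c("le40" = 1, "41-45" = 1, "46-50" = 1, "ge51" = 1),
    seed = seed)
}
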