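test_that("crude odds ratios and Woolf intervals reproduce published rows", {
  pc <- published_counts()
  for (i in seq_len(nrow(pc))) {
    est <- crude_odds_ratio(two_by_two(pc$a[i], pc$b[i], pc$c[i], pc$d[i]))
    # printed values occasionally differ by one unit in the last digit
    # from the cross-product of their own counts; allow exactly that
    expect_equal(round(est$or_point, 2), pc$printed_or[i],
                 info = pc$label[i], tolerance = 0.011)
    expect_equal(round(est$ci_low, 2), pc$printed_ci_low[i],
                 info = pc$label[i], tolerance = 0.011)
    expect_equal(round(est$ci_high, 2), pc$printed_ci_high[i],
                 info = pc$label[i], tolerance = 0.011)
  }
})

test_that("the Wald p-value matches the published smoking p to 2 figures", {
  est <- crude_odds_ratio(two_by_two(40, 73, 193, 626))
  expect_equal(signif(est$p_value, 2), 0.0070)
})

test_that("tabulation agrees with a per-record brute-force tally", {
  recs <- random_records(50, seed = 7)
  tab <- tabulate_2x2(recs, recs$sodium_class == "high")
  # independent loop oracle
  a <- b <- c <- d <- 0
  for (i in seq_len(nrow(recs))) {
    exp_i <- recs$sodium_class[i] == "high"
    if (exp_i && recs$case[i] == 1) a <- a + 1
    else if (exp_i) b <- b + 1
    else if (recs$case[i] == 1) c <- c + 1
    else d <- d + 1
  }
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(a, b, c, d))
  # counts partition the records exactly
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(recs))
  # missing exposure rows are excluded and counted
  expos <- recs$sodium_class == "high"
  expos[c(3, 9)] <- NA
  tab2 <- tabulate_2x2(recs, expos)
  expect_equal(attr(tab2, "n_excluded"), 2L)
  expect_equal(tab2$a + tab2$b + tab2$c + tab2$d, nrow(recs) - 2L)
  # degenerate: everyone unexposed
  tab3 <- tabulate_2x2(recs, rep(FALSE, nrow(recs)))
  expect_equal(c(tab3$a, tab3$b), c(0, 0))
  expect_error(tabulate_2x2(recs[0, ], logical(0)), "no records")
})

test_that("joint tabulation matches brute-force cross-classification", {
  recs <- random_records(40, seed = 11)
  jt <- tabulate_joint(recs)
  for (lv in c("ref", "e", "g", "ge")) {
    tt <- recs$genotype == "TT"
    high <- recs$sodium_class == "high"
    pick <- switch(lv, ref = !tt & !high, e = !tt & high,
                   g = tt & !high, ge = tt & high)
    expect_equal(jt[lv, "case"], sum(pick & recs$case == 1))
    expect_equal(jt[lv, "control"], sum(pick & recs$case == 0))
  }
  expect_equal(sum(jt), nrow(recs))
  # intermediate sodium is excluded with a count
  recs$sodium_class[1:4] <- "intermediate"
  jt2 <- tabulate_joint(recs)
  expect_equal(attr(jt2, "n_excluded"), 4L)
  # single-category input leaves the other cells zero
  one <- data.frame(genotype = "TT", sodium_class = "high", case = 1)
  jt3 <- tabulate_joint(one)
  expect_equal(jt3["ge", "case"], 1L)
  expect_equal(sum(jt3), 1L)
})

test_that("joint crude ORs equal three independent 2x2 computations", {
  jt <- joint_table(cases = c(30, 12, 21, 9), controls = c(90, 25, 60, 8))
  ors <- joint_crude_ors(jt)
  expect_equal(ors$or01$or_point,
               crude_odds_ratio(two_by_two(12, 25, 30, 90))$or_point)
  expect_equal(ors$or10$or_point,
               crude_odds_ratio(two_by_two(21, 60, 30, 90))$or_point)
  expect_equal(ors$or11$or_point,
               crude_odds_ratio(two_by_two(9, 8, 30, 90))$or_point)
  # identical case:control ratio in every category gives OR 1 throughout
  flat <- joint_table(cases = c(10, 20, 30, 40),
                      controls = c(20, 40, 60, 80))
  expect_equal(vapply(joint_crude_ors(flat),
                      function(e) e$or_point, numeric(1)),
               c(or10 = 1, or01 = 1, or11 = 1))
})

test_that("odds-ratio symmetries and interval properties hold", {
  set.seed(21)
  for (i in 1:25) {
    cells <- rpois(4, 30) + 1
    est <- crude_odds_ratio(two_by_two(cells[1], cells[2],
                                       cells[3], cells[4]))
    # simultaneous relabel of exposure and outcome leaves the OR unchanged
    swapped <- crude_odds_ratio(two_by_two(cells[4], cells[3],
                                           cells[2], cells[1]))
    expect_equal(est$or_point, swapped$or_point)
    # control-sampling-fraction invariance (exact on real-valued counts)
    scaled <- crude_odds_ratio(two_by_two(cells[1], cells[2] * 2.5,
                                          cells[3], cells[4] * 2.5))
    expect_equal(est$or_point, scaled$or_point)
    # interval contains the point and is log-symmetric
    expect_lte(est$ci_low, est$or_point)
    expect_gte(est$ci_high, est$or_point)
    expect_equal(log(est$ci_high) - log(est$or_point),
                 log(est$or_point) - log(est$ci_low))
  }
  # CI width shrinks (never grows) as any single cell count rises
  w <- function(a) {
    e <- crude_odds_ratio(two_by_two(a, 20, 15, 40))
    log(e$ci_high) - log(e$ci_low)
  }
  widths <- vapply(c(5, 10, 20, 80), w, numeric(1))
  expect_true(all(diff(widths) <= 0))
})

test_that("zero cells are corrected and doubly-empty margins not estimable", {
  est <- crude_odds_ratio(two_by_two(0, 10, 12, 30))
  expect_true(est$corrected)
  expect_true(est$estimable)
  expect_equal(est$or_point, (0.5 * 30.5) / (10.5 * 12.5))
  clean <- crude_odds_ratio(two_by_two(5, 10, 12, 30))
  expect_false(clean$corrected)
  empty_row <- crude_odds_ratio(two_by_two(0, 0, 12, 30))
  expect_false(empty_row$estimable)
  expect_true(is.na(empty_row$or_point))
  empty_col <- crude_odds_ratio(two_by_two(0, 10, 0, 30))
  expect_false(empty_col$estimable)
})

test_that("the Pearson chi-square alternative agrees with stats::chisq.test", {
  est <- crude_odds_ratio(two_by_two(40, 73, 193, 626), p_method = "chisq")
  ref <- chisq.test(matrix(c(40, 73, 193, 626), 2, byrow = TRUE),
                    correct = FALSE)
  expect_equal(est$p_value, ref$p.value)
})
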