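#' Construct a 2x2 exposure-by-outcome table
#'
#' Cell layout follows the usual case-control convention:
#' `a` exposed cases, `b` exposed controls, `c` unexposed cases,
#' `d` unexposed controls.
#'
#' @param a,b,c,d Non-negative counts.
#' @param exposure_label,outcome_label Optional labels for reporting.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d, exposure_label = "exposed",
                       outcome_label = "case") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("cell counts must be non-negative and finite")
  structure(list(a = a, b = b, c = c, d = d,
                 exposure_label = exposure_label,
                 outcome_label = outcome_label),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c(x$exposure_label,
                                paste0("not ", x$exposure_label)),
                              c(x$outcome_label, "control")))
  print(m)
  invisible(x)
}

#' Tabulate subject records into a 2x2 table
#'
#' @param records Data frame with a 0/1 (or logical) `case` column.
#' @param exposure Either a logical vector aligned with `records`, or the
#'   name of a 0/1 / logical column in `records`. `NA` exposures are
#'   excluded; their count is attached as attribute `n_excluded`.
#' @param case_col Name of the case-status column.
#' @param exposure_label,outcome_label Labels passed through.
#' @return A `two_by_two` with attribute `n_excluded`.
#' @export
tabulate_2x2 <- function(records, exposure, case_col = "case",
                         exposure_label = "exposed",
                         outcome_label = "case") {
  if (nrow(records) == 0L) stop("no records to tabulate")
  if (is.character(exposure) && length(exposure) == 1L) {
    exposure_label <- exposure
    exposure <- as.logical(records[[exposure]])
  }
  stopifnot(length(exposure) == nrow(records))
  case <- as.logical(records[[case_col]])
  if (any(is.na(case))) stop("case status must be non-missing")
  keep <- !is.na(exposure)
  n_excluded <- sum(!keep)
  exposure <- exposure[keep]
  case <- case[keep]
  tab <- two_by_two(a = sum(exposure & case), b = sum(exposure & !case),
                    c = sum(!exposure & case), d = sum(!exposure & !case),
                    exposure_label = exposure_label,
                    outcome_label = outcome_label)
  attr(tab, "n_excluded") <- n_excluded
  tab
}

#' Crude odds ratio with Woolf confidence interval
#'
#' Point estimate is the cross-product `ad/bc`; the confidence interval is
#' Woolf's, `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`; the p-value
#' is the Wald test of `log(OR) = 0` (a Pearson chi-square alternative is
#' available). Tables containing a zero cell receive the Haldane-Anscombe
#' correction (+0.5 to every cell), flagged in the result; a table with two
#' zero cells in the same row or column is not estimable.
#'
#' @param table A `two_by_two`.
#' @param level Confidence level, default 0.95.
#' @param p_method `"wald"` (default) or `"chisq"`.
#' @return An `or_estimate`: list with `or_point`, `ci_low`, `ci_high`,
#'   `level`, `p_value`, `corrected`, `estimable`.
#' @export
crude_odds_ratio <- function(table, level = 0.95,
                             p_method = c("wald", "chisq")) {
  p_method <- match.arg(p_method)
  stopifnot(inherits(table, "two_by_two"), level > 0, level < 1)
  cells <- c(table$a, table$b, table$c, table$d)
  # not estimable when both cells of a margin are empty
  if ((table$a == 0 && table$b == 0) || (table$c == 0 && table$d == 0) ||
      (table$a == 0 && table$c == 0) || (table$b == 0 && table$d == 0)) {
    return(or_estimate(NA_real_, NA_real_, NA_real_, level, NA_real_,
                       corrected = FALSE, estimable = FALSE))
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (p_method == "wald") {
    2 * stats::pnorm(-abs(log_or / se))
  } else {
    n <- a + b + c + d
    e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
    o <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  }
  or_estimate(exp(log_or), exp(log_or - z * se), exp(log_or + z * se),
              level, p, corrected = corrected, estimable = TRUE)
}

or_estimate <- function(or_point, ci_low, ci_high, level, p_value,
                        corrected = FALSE, estimable = TRUE) {
  structure(list(or_point = or_point, ci_low = ci_low, ci_high = ci_high,
                 level = level, p_value = p_value, corrected = corrected,
                 estimable = estimable),
            class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, digits = 2, ...) {
  if (!x$estimable) {
    cat("OR not estimable\n")
    return(invisible(x))
  }
  cat(sprintf("OR %.*f (%.0f%% CI %.*f-%.*f), p = %.4g%s\n",
              digits, x$or_point, 100 * x$level, digits, x$ci_low,
              digits, x$ci_high, x$p_value,
              if (x$corrected) " [0.5 added to zero-cell table]" else ""))
  invisible(x)
}

joint_category_levels <- function() c("ref", "e", "g", "ge")

#' Tabulate the four genotype-by-sodium exposure categories
#'
#' Cross-classifies subjects into the four joint-exposure categories used in
#' additive-interaction analysis: `ref` (CC/CT genotype, low sodium), `e`
#' (CC/CT, high sodium), `g` (TT, low sodium), `ge` (TT, high sodium) —
#' the row order of the joint-effects table. Subjects with intermediate
#' sodium intake are excluded with a logged count.
#'
#' @param records Data frame with `genotype` (CC/CT/TT), `sodium_class`
#'   (low/high/intermediate) and `case` columns.
#' @param genotype_col,sodium_col,case_col Column names.
#' @return A `joint_table`: 4x2 count matrix (rows ref/e/g/ge, columns
#'   case/control) with attribute `n_excluded`.
#' @export
tabulate_joint <- function(records, genotype_col = "genotype",
                           sodium_col = "sodium_class", case_col = "case") {
  if (nrow(records) == 0L) stop("no records to tabulate")
  geno <- records[[genotype_col]]
  sod <- records[[sodium_col]]
  case <- as.logical(records[[case_col]])
  keep <- !is.na(geno) & !is.na(sod) & sod %in% c("low", "high")
  n_excluded <- sum(!keep)
  geno <- geno[keep]; sod <- sod[keep]; case <- case[keep]
  tt <- geno == "TT"
  high <- sod == "high"
  cat4 <- ifelse(!tt & !high, "ref",
                 ifelse(!tt & high, "e", ifelse(tt & !high, "g", "ge")))
  counts <- matrix(0L, 4, 2,
                   dimnames = list(joint_category_levels(),
                                   c("case", "control")))
  for (lv in joint_category_levels()) {
    counts[lv, "case"] <- sum(cat4 == lv & case)
    counts[lv, "control"] <- sum(cat4 == lv & !case)
  }
  structure(counts, class = c("joint_table", "matrix"),
            n_excluded = n_excluded)
}

#' Build a joint table directly from eight counts
#'
#' @param cases,controls Length-4 named or ordered vectors of counts for the
#'   categories `ref`, `e`, `g`, `ge`.
#' @return A `joint_table`.
#' @export
joint_table <- function(cases, controls) {
  stopifnot(length(cases) == 4L, length(controls) == 4L,
            all(cases >= 0), all(controls >= 0))
  counts <- cbind(case = as.integer(cases), control = as.integer(controls))
  rownames(counts) <- joint_category_levels()
  structure(counts, class = c("joint_table", "matrix"), n_excluded = 0L)
}

#' Crude odds ratios for the joint-exposure categories
#'
#' Each non-reference category is compared with the reference cell in its own
#' 2x2 table via [crude_odds_ratio()].
#'
#' @param table A `joint_table`.
#' @param level Confidence level.
#' @return A list with `or10` (TT, low sodium), `or01` (CC/CT, high sodium)
#'   and `or11` (TT, high sodium), each an `or_estimate`.
#' @export
joint_crude_ors <- function(table, level = 0.95) {
  stopifnot(inherits(table, "joint_table"))
  if (table["ref", "case"] == 0 || table["ref", "control"] == 0)
    stop("reference cell counts must be positive")
  one <- function(cat) {
    crude_odds_ratio(two_by_two(
      a = table[cat, "case"], b = table[cat, "control"],
      c = table["ref", "case"], d = table["ref", "control"],
      exposure_label = cat), level = level)
  }
  list(or10 = one("g"), or01 = one("e"), or11 = one("ge"))
}

#' Render a labelled odds-ratio table as aligned plain text
#'
#' @param rows Data frame with columns `label`, `cases`, `controls`,
#'   `or`, `ci_low`, `ci_high`, `p` (OR columns may be NA for reference
#'   rows).
#' @param title Heading line.
#' @return Character vector of lines.
#' @export
format_or_table <- function(rows, title = "") {
  n_case <- sum(rows$cases); n_ctrl <- sum(rows$controls)
  fmt_n <- function(n, tot) sprintf("%d (%.1f%%)", n, 100 * n / tot)
  body <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    or_txt <- if (is.na(r$or)) "1.00 (ref)" else
      sprintf("%.2f (%.2f-%.2f)", r$or, r$ci_low, r$ci_high)
    p_txt <- if (is.na(r$p)) "" else sprintf("%.4f", r$p)
    sprintf("%-28s %14s %14s %20s %8s", r$label,
            fmt_n(r$cases, n_case), fmt_n(r$controls, n_ctrl), or_txt, p_txt)
  }, character(1))
  header <- sprintf("%-28s %14s %14s %20s %8s", "", "cases n (%)",
                    "controls n (%)", "OR (95% CI)", "p")
  c(title, header, body)
}
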