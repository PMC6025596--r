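#' Read or write subject-level data as CSV
#'
#' The on-disk schema has one row per participant with a header row:
#' `subject_id`, `gender`, `age_years` (and optionally `age_band`),
#' `genotype` (CC/CT/TT strings), `sodium_mg`, `case`, plus one 0/1 column
#' per covariate.
#'
#' @param path File path.
#' @param drop_bad Drop rows failing validation instead of erroring.
#' @return Data frame of subjects.
#' @export
read_subjects <- function(path, drop_bad = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rep <- validate_input(df)
  if (length(rep$warnings)) for (w in rep$warnings) warning(w, call. = FALSE)
  df <- rep$records
  if (nrow(rep$bad_rows)) {
    msg <- paste0("invalid rows (line numbers include header): ",
                  paste(utils::head(rep$bad_rows$line, 10), collapse = ", "),
                  " -- ", paste(utils::head(rep$bad_rows$problem, 3),
                                collapse = "; "))
    if (!drop_bad) stop(msg, "\nPass drop_bad = TRUE to drop them.")
    warning(msg, call. = FALSE)
    df <- df[-rep$bad_rows$row, , drop = FALSE]
  }
  df
}

#' @rdname read_subjects
#' @param records Data frame of subjects.
#' @export
write_subjects <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a subject-level data frame
#'
#' Checks required columns, genotype levels (the synonym `TC` is normalized
#' to `CT` with a warning), a binary case column, and non-negative sodium.
#' Returns the (possibly normalized) records plus a per-row problem report
#' with 1-based file line numbers (header is line 1).
#'
#' @param records Data frame to validate.
#' @return List with `records`, `bad_rows` (columns `row`, `line`,
#'   `problem`), `warnings`, `n_missing` (per-column missing counts).
#' @export
validate_input <- function(records) {
  required <- c("gender", "genotype", "case")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!("sodium_mg" %in% names(records)) &&
      !("sodium_class" %in% names(records)))
    stop("need a sodium_mg or sodium_class column")

  warnings <- character(0)
  n_tc <- sum(records$genotype == "TC", na.rm = TRUE)
  if (n_tc > 0) {
    records$genotype[records$genotype == "TC"] <- "CT"
    warnings <- c(warnings, sprintf(
      "normalized %d 'TC' genotype string(s) to 'CT'", n_tc))
  }

  bad <- data.frame(row = integer(0), line = integer(0),
                    problem = character(0), stringsAsFactors = FALSE)
  flag <- function(rows, problem) {
    rows <- which(rows)
    if (length(rows))
      rbind(bad, data.frame(row = rows, line = rows + 1L, problem = problem,
                            stringsAsFactors = FALSE))
    else bad
  }
  bad <- flag(!(records$genotype %in% c("CC", "CT", "TT")) &
                !is.na(records$genotype), "unknown genotype level")
  bad <- flag(!(records$case %in% c(0, 1)) & !is.na(records$case),
              "non-binary case value")
  if ("sodium_mg" %in% names(records))
    bad <- flag(records$sodium_mg < 0 & !is.na(records$sodium_mg),
                "negative sodium_mg")
  n_missing <- vapply(records, function(col) sum(is.na(col)), integer(1))
  list(records = records, bad_rows = bad, warnings = warnings,
       n_missing = n_missing)
}

#' Assemble a run configuration for the analysis pipeline
#'
#' @param mode `"simulate"` (generate a cohort with [simulate_cohort()]) or
#'   `"load"` (read subjects from `input_path`).
#' @param simulation A [sim_config()] (simulate mode).
#' @param input_path CSV path (load mode).
#' @param sodium_thresholds `c(low_max, high_min)` mg/day.
#' @param matching_ratio Controls per case; `NA` skips matching and analyses
#'   the full input (use this for pre-assembled case-control files).
#' @param covariate_set Covariate columns adjusted for in the logistic
#'   models.
#' @param adjust_age Include age-band dummies in adjusted models.
#' @param ci_level Confidence level in (0, 1).
#' @param ci_method `"delta"`, `"bootstrap"` or `"both"`.
#' @param n_boot Bootstrap replicates if bootstrapping.
#' @param seed Integer seed for every random element of the run.
#' @param output_dir Directory for reports; `NULL` skips writing files.
#' @param drop_bad Passed to [read_subjects()] in load mode.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       simulation = sim_config(),
                       input_path = NULL,
                       sodium_thresholds = c(low_max = 2400, high_min = 4800),
                       matching_ratio = 3L,
                       covariate_set = c("smoker", "alcohol", "bmi_abnormal",
                                         "tg_high", "hdl_low", "ldl_high",
                                         "diabetes"),
                       adjust_age = TRUE,
                       ci_level = 0.95,
                       ci_method = c("delta", "bootstrap", "both"),
                       n_boot = 1000L, seed = 1L, output_dir = NULL,
                       drop_bad = FALSE) {
  mode <- match.arg(mode)
  ci_method <- match.arg(ci_method)
  if (mode == "load" && is.null(input_path))
    stop("load mode requires input_path")
  if (mode == "simulate" && !is.null(input_path))
    stop("provide exactly one of a simulation config or an input path")
  stopifnot(ci_level > 0, ci_level < 1)
  structure(list(mode = mode, simulation = simulation,
                 input_path = input_path,
                 sodium_thresholds = sodium_thresholds,
                 matching_ratio = matching_ratio,
                 covariate_set = covariate_set, adjust_age = adjust_age,
                 ci_level = ci_level, ci_method = ci_method,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 output_dir = output_dir, drop_bad = drop_bad),
            class = "run_config")
}

or_row <- function(label, a, b, est = NULL) {
  data.frame(label = label, cases = a, controls = b,
             or = if (is.null(est)) NA_real_ else est$or_point,
             ci_low = if (is.null(est)) NA_real_ else est$ci_low,
             ci_high = if (is.null(est)) NA_real_ else est$ci_high,
             p = if (is.null(est)) NA_real_ else est$p_value,
             stringsAsFactors = FALSE)
}

binary_or_rows <- function(records, column, level) {
  tab <- tabulate_2x2(records, column)
  est <- crude_odds_ratio(tab, level = level)
  rbind(or_row(paste0(column, ": no"), tab$c, tab$d),
        or_row(paste0(column, ": yes"), tab$a, tab$b, est))
}

#' Run the full gene-sodium additive-interaction analysis
#'
#' End-to-end driver: simulate (or load) subjects, exclude baseline
#' hypertensives and subjects lost to follow-up, classify sodium exposure
#' (excluding the intermediate class with a logged count), assemble the
#' case-control sample by gender frequency matching, then produce the four
#' standard reports: a descriptive covariate table with crude odds ratios,
#' genotype-only and sodium-only tables with crude and adjusted odds
#' ratios, and the four-category joint-exposure table with crude and
#' adjusted odds ratios plus RERI, attributable proportion and the Rothman
#' synergy index with confidence intervals. Every exclusion is counted so
#' the analysed n is auditable. Reports are self-audited: the crude odds
#' ratios are recomputed from the reported counts and must agree.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list bundle: `records` (analysis set), `exclusions`,
#'   `covariate_table`, `genotype_table`, `sodium_table`, `joint_table`,
#'   `joint_crude`, `adjusted` (per-table adjusted ORs), `interaction`,
#'   `bootstrap` (when requested), `provenance`. When `output_dir` is set,
#'   writes `report.json`, `report.txt` and per-table CSVs there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  level <- config$ci_level
  exclusions <- list()

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$simulation, seed = config$seed)
  } else {
    cohort <- read_subjects(config$input_path, drop_bad = config$drop_bad)
    if (!("baseline_hypertensive" %in% names(cohort)))
      cohort$baseline_hypertensive <- 0L
    if (!("lost_followup" %in% names(cohort)))
      cohort$lost_followup <- 0L
  }
  exclusions$n_input <- nrow(cohort)

  keep <- cohort$baseline_hypertensive == 0
  exclusions$baseline_hypertensive <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  keep <- cohort$lost_followup == 0
  exclusions$lost_followup <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]

  if (!("sodium_class" %in% names(cohort)))
    cohort$sodium_class <- classify_sodium(cohort$sodium_mg,
                                           config$sodium_thresholds)
  keep <- cohort$sodium_class %in% c("low", "high")
  exclusions$intermediate_sodium <- sum(!keep)
  cohort <- cohort[keep, , drop = FALSE]
  if (!any(cohort$case == 1)) stop("empty case set after exclusions")

  if (is.na(config$matching_ratio)) {
    records <- cohort
    matching <- NULL
  } else {
    matching <- frequency_match(cohort, ratio = config$matching_ratio,
                                match_on = "gender", seed = config$seed)
    records <- rbind(matching$cases, matching$controls)
  }
  exclusions$n_analysed <- nrow(records)

  covariates <- intersect(config$covariate_set, names(records))
  adj_terms <- covariates
  if (config$adjust_age && "age_band" %in% names(records))
    adj_terms <- c(adj_terms, "age_band")

  covariate_table <- if (length(covariates)) {
    do.call(rbind, lapply(covariates, binary_or_rows,
                          records = records, level = level))
  } else {
    data.frame(label = character(0), cases = integer(0),
               controls = integer(0), or = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), p = numeric(0))
  }

  # genotype table: TT vs CC + CT
  tt <- records$genotype == "TT"
  gtab <- tabulate_2x2(records, tt, exposure_label = "TT")
  gcrude <- crude_odds_ratio(gtab, level = level)
  gfit <- fit_logistic_model(cbind(records, tt = as.integer(tt)),
                             "case", c("tt", adj_terms),
                             reference = list(age_band = "le40"))
  genotype_table <- rbind(or_row("CC + CT", gtab$c, gtab$d),
                          or_row("TT", gtab$a, gtab$b, gcrude))
  g_adj <- adjusted_or(gfit, "tt", level)

  # sodium table: high vs low
  high <- records$sodium_class == "high"
  stab <- tabulate_2x2(records, high, exposure_label = "high sodium")
  scrude <- crude_odds_ratio(stab, level = level)
  sfit <- fit_logistic_model(cbind(records, high = as.integer(high)),
                             "case", c("high", adj_terms),
                             reference = list(age_band = "le40"))
  sodium_table <- rbind(or_row("low sodium", stab$c, stab$d),
                        or_row("high sodium", stab$a, stab$b, scrude))
  s_adj <- adjusted_or(sfit, "high", level)

  # joint four-category analysis
  jt <- tabulate_joint(records)
  jcrude <- joint_crude_ors(jt, level = level)
  records_j <- add_joint_dummies(records)
  jfit <- fit_logistic_model(records_j, "case", c("g", "e", "ge", adj_terms),
                             reference = list(age_band = "le40"))
  interaction <- interaction_from_fit(jfit, level = level)

  boot <- NULL
  if (config$ci_method %in% c("bootstrap", "both")) {
    boot <- list(
      reri = bootstrap_ci(records_j, "reri", covariates = adj_terms,
                          n_boot = config$n_boot, seed = config$seed,
                          level = level),
      ap = bootstrap_ci(records_j, "ap", covariates = adj_terms,
                        n_boot = config$n_boot, seed = config$seed,
                        level = level),
      s = bootstrap_ci(records_j, "s", covariates = adj_terms,
                       n_boot = config$n_boot, seed = config$seed,
                       level = level))
  }

  # self-consistency audit: crude ORs must equal the contingency module
  # applied to the report's own counts
  audit_or <- function(rows, est) {
    tab <- two_by_two(rows$cases[2], rows$controls[2],
                      rows$cases[1], rows$controls[1])
    stopifnot(isTRUE(all.equal(crude_odds_ratio(tab)$or_point,
                               est$or_point)))
  }
  audit_or(genotype_table, gcrude)
  audit_or(sodium_table, scrude)

  bundle <- list(
    records = records, exclusions = exclusions,
    matching = if (is.null(matching)) NULL else matching$by_stratum,
    covariate_table = covariate_table,
    genotype_table = genotype_table,
    genotype_adjusted = g_adj,
    sodium_table = sodium_table,
    sodium_adjusted = s_adj,
    joint_table = jt, joint_crude = jcrude,
    joint_fit = jfit, interaction = interaction, bootstrap = boot,
    provenance = list(
      seed = config$seed, mode = config$mode,
      ci_level = level, ci_method = config$ci_method,
      matching_ratio = config$matching_ratio,
      sodium_thresholds = as.list(config$sodium_thresholds),
      covariate_set = covariates,
      simulation = if (config$mode == "simulate")
        unclass(config$simulation) else NULL,
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("saltsynergy"))))

  if (!is.null(config$output_dir)) write_reports(bundle, config$output_dir)
  invisible(bundle)
}

or_est_json <- function(est) {
  if (is.null(est)) return(NULL)
  list(or = est$or_point, ci_low = est$ci_low, ci_high = est$ci_high,
       level = est$level, p_value = est$p_value, corrected = est$corrected,
       estimable = est$estimable)
}

#' Write the pipeline report bundle to disk
#'
#' Produces `report.json` (machine-readable results and provenance),
#' `report.txt` (aligned plain-text tables) and one CSV per table. Output
#' is deterministic: the same configuration and seed give byte-identical
#' files.
#'
#' @param bundle Result of [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  for (nm in c("covariate_table", "genotype_table", "sodium_table")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  jt_df <- data.frame(category = rownames(bundle$joint_table),
                      cases = bundle$joint_table[, "case"],
                      controls = bundle$joint_table[, "control"],
                      row.names = NULL)
  p <- file.path(dir, "joint_table.csv")
  utils::write.csv(jt_df, p, row.names = FALSE)
  paths <- c(paths, p)

  inter <- bundle$interaction
  txt <- c(
    "Gene-sodium additive interaction analysis",
    "",
    sprintf("Input records: %d; analysed: %d", bundle$exclusions$n_input,
            bundle$exclusions$n_analysed),
    sprintf(paste0("Excluded: %d baseline hypertensive, %d lost to ",
                   "follow-up, %d intermediate sodium"),
            bundle$exclusions$baseline_hypertensive,
            bundle$exclusions$lost_followup,
            bundle$exclusions$intermediate_sodium),
    "",
    format_or_table(bundle$covariate_table, "Covariates by case status"),
    "",
    format_or_table(bundle$genotype_table, "GNB3 genotype (TT vs CC+CT)"),
    sprintf("  adjusted OR %.2f (%.2f-%.2f)",
            bundle$genotype_adjusted$or_point,
            bundle$genotype_adjusted$ci_low, bundle$genotype_adjusted$ci_high),
    "",
    format_or_table(bundle$sodium_table, "Dietary sodium (high vs low)"),
    sprintf("  adjusted OR %.2f (%.2f-%.2f)", bundle$sodium_adjusted$or_point,
            bundle$sodium_adjusted$ci_low, bundle$sodium_adjusted$ci_high),
    "",
    "Joint genotype-by-sodium categories (crude / adjusted):",
    sprintf("  %-22s cases %4d  controls %4d", rownames(bundle$joint_table),
            bundle$joint_table[, "case"], bundle$joint_table[, "control"]),
    sprintf("  OR10 crude %.2f adjusted %.2f", bundle$joint_crude$or10$or_point,
            inter$or10$or_point),
    sprintf("  OR01 crude %.2f adjusted %.2f", bundle$joint_crude$or01$or_point,
            inter$or01$or_point),
    sprintf("  OR11 crude %.2f adjusted %.2f", bundle$joint_crude$or11$or_point,
            inter$or11$or_point),
    "",
    sprintf("  RERI %.3f (%.3f-%.3f)", inter$reri, inter$ci_reri[1],
            inter$ci_reri[2]),
    sprintf("  AP   %.3f (%.3f-%.3f)", inter$ap, inter$ci_ap[1],
            inter$ci_ap[2]),
    if (isTRUE(attr(inter$s, "estimable")))
      sprintf("  S    %.3f (%.3f-%.3f)", as.numeric(inter$s),
              inter$ci_s[1], inter$ci_s[2])
    else "  S    not estimable")
  p <- file.path(dir, "report.txt")
  writeLines(txt, p)
  paths <- c(paths, p)

  json <- list(
    exclusions = bundle$exclusions,
    matching = bundle$matching,
    covariate_table = bundle$covariate_table,
    genotype = list(table = bundle$genotype_table,
                    adjusted = or_est_json(bundle$genotype_adjusted)),
    sodium = list(table = bundle$sodium_table,
                  adjusted = or_est_json(bundle$sodium_adjusted)),
    joint = list(
      counts = jt_df,
      crude = lapply(bundle$joint_crude, or_est_json),
      adjusted = list(or10 = or_est_json(inter$or10),
                      or01 = or_est_json(inter$or01),
                      or11 = or_est_json(inter$or11)),
      reri = list(point = inter$reri, ci = as.numeric(inter$ci_reri)),
      ap = list(point = inter$ap, ci = as.numeric(inter$ci_ap)),
      synergy_index = list(
        point = as.numeric(inter$s),
        estimable = isTRUE(attr(inter$s, "estimable")),
        ci = as.numeric(inter$ci_s))),
    bootstrap = if (is.null(bundle$bootstrap)) NULL else
      lapply(bundle$bootstrap, function(b)
        list(ci = as.numeric(b), n_failed = attr(b, "n_failed"))),
    provenance = bundle$provenance)
  p <- file.path(dir, "report.json")
  jsonlite::write_json(json, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' Expand a joint-exposure count table into subject records
#'
#' Utility for building subject-level fixtures whose cross-classification
#' equals a given four-category table (useful for reanalysing published
#' counts at the subject level).
#'
#' @param table A `joint_table` (or 4x2 matrix with rows ref/e/g/ge).
#' @param gender Gender assigned to all records (matching is skipped for
#'   such reconstructed data).
#' @return Data frame with `genotype`, `sodium_class`, `sodium_mg`, `case`.
#' @export
counts_to_records <- function(table, gender = "male") {
  lv <- joint_category_levels()
  geno <- c(ref = "CC", e = "CC", g = "TT", ge = "TT")
  sod <- c(ref = "low", e = "high", g = "low", ge = "high")
  rows <- do.call(rbind, lapply(lv, function(cat) {
    do.call(rbind, lapply(c(1, 0), function(cs) {
      n <- table[cat, if (cs == 1) "case" else "control"]
      if (n == 0) return(NULL)
      data.frame(genotype = rep(geno[[cat]], n),
                 sodium_class = sod[[cat]],
                 sodium_mg = if (sod[[cat]] == "low") 1800 else 6000,
                 case = cs, stringsAsFactors = FALSE)
    }))
  }))
  rows$gender <- gender
  rows$subject_id <- sprintf("R%05d", seq_len(nrow(rows)))
  rows$baseline_hypertensive <- 0L
  rows$lost_followup <- 0L
  rownames(rows) <- NULL
  rows
}
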