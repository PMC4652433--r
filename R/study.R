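#' Study dataset schema and I/O
#'
#' A usability-study dataset holds one row per participant with columns
#' `id`, `group` (`"diagram"` or `"questionnaire"`), `gender`
#' (`"male"`/`"female"`), `age_band` (one of [age_bands()]), `web_use` (one
#' of [web_use_levels()]), `task_time` (seconds) and the 17 Likert items
#' `i01`..`i17` (1..7, missing allowed). The CSV serialisation writes
#' missing items as empty cells.
#'
#' @name study_io
NULL

#' @describeIn study_io The seven age bands, youngest first.
#' @export
age_bands <- function() {
  c("under_18", "18_24", "25_34", "35_44", "45_54", "55_64", "over_64")
}

#' @describeIn study_io Internet-use frequency levels.
#' @export
web_use_levels <- function() {
  c("less_than_monthly", "once_a_month", "several_times_a_month",
    "at_least_weekly")
}

.study_cols <- function() {
  c("id", "group", "gender", "age_band", "web_use", "task_time",
    sprintf("i%02d", 1:17))
}

#' Validate a study dataset
#'
#' @param data a data.frame in the study schema.
#' @return the data, invisibly; errors describe the first problem found.
#' @export
validate_study <- function(data) {
  missing <- setdiff(.study_cols(), names(data))
  if (length(missing))
    stop("study data missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(data$group) || !all(data$group %in% c("diagram", "questionnaire")))
    stop("group must be 'diagram' or 'questionnaire', never missing",
         call. = FALSE)
  if (!all(data$age_band %in% age_bands()))
    stop("unknown age_band value", call. = FALSE)
  items <- as.matrix(data[, sprintf("i%02d", 1:17)])
  bad <- !is.na(items) & (items < 1 | items > 7)
  if (any(bad)) stop("item responses must lie in 1..7 or be missing",
                     call. = FALSE)
  invisible(data)
}

#' @describeIn study_io Read a study CSV.
#' @param path file path.
#' @export
read_study <- function(path) {
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study(data)
  data
}

#' @describeIn study_io Write a study CSV (missing items as empty cells).
#' @param data a validated study data.frame.
#' @export
write_study <- function(data, path) {
  validate_study(data)
  utils::write.csv(data[, .study_cols()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Analyse a usability-study dataset
#'
#' Runs the full two-arm analysis:
#'
#' * **Efficiency** — per-group mean and SD of task time, per-group
#'   Shapiro-Wilk normality check, a pooled two-sided t-test, and a
#'   tie-corrected Mann-Whitney test. When any group's normality check
#'   rejects at `alpha` and group sizes are below 50, the nonparametric
#'   test is the selected result; otherwise the t-test is.
#' * **Satisfaction** — negatively worded items recoded, Little's MCAR test
#'   when items are missing, deterministic EM single imputation, totals
#'   summed per participant, Cronbach's alpha on the completed items,
#'   per-group mean/SD of the totals, and the same normality-gated group
#'   comparison.
#'
#' @param data a validated study data.frame (see [study_io]).
#' @param instrument a [csuq_instrument()].
#' @param alpha significance level for the normality gate (default 0.05).
#' @param mcar_alpha level at which a rejected MCAR test is flagged.
#' @param var_equal pooled-variance t-test (default TRUE).
#' @return an object of class `study_analysis`: lists `efficiency` and
#'   `satisfaction`, each with `group_stats`, `normality`, `t_test`,
#'   `mann_whitney`, `selected`; `satisfaction` additionally carries
#'   `n_missing_participants`, `mcar`, `alpha_reliability` and `notes`.
#' @export
analyze_study <- function(data, instrument = csuq_instrument(), alpha = 0.05,
                          mcar_alpha = 0.05, var_equal = TRUE) {
  validate_study(data)
  g1 <- data$group == "diagram"
  g2 <- data$group == "questionnaire"
  labels <- c("diagram", "questionnaire")

  compare <- function(x, y) {
    norm <- list(diagram = normality_check(x), questionnaire = normality_check(y))
    tt <- t_test_ind(x, y, var_equal = var_equal, labels = labels)
    mw <- mann_whitney(x, y, labels = labels)
    gate <- (norm$diagram$p_value < alpha || norm$questionnaire$p_value < alpha) &&
      (length(x) < 50L && length(y) < 50L)
    list(group_stats = .group_stats(x, y, labels), normality = norm,
         t_test = tt, mann_whitney = mw,
         selected = if (gate) "mann_whitney" else "t_test")
  }

  efficiency <- compare(data$task_time[g1], data$task_time[g2])

  items <- .item_matrix(data[, instrument$item], instrument)
  recoded <- recode_items(items, instrument)
  n_missing <- sum(apply(recoded, 1L, anyNA))
  notes <- character(0)
  if (n_missing > 0L) {
    mcar <- little_mcar(recoded)
    if (mcar$applicable && !is.na(mcar$p_value) && mcar$p_value < mcar_alpha) {
      notes <- c(notes, sprintf(
        "Little's MCAR test rejected randomness of the missingness (p = %.3g); single imputation may be biased",
        mcar$p_value))
    }
    completed <- impute_single(recoded)
  } else {
    mcar <- little_mcar(recoded)  # applicable = FALSE on complete data
    completed <- recoded
  }
  totals <- total_score(completed)
  satisfaction <- compare(totals[g1], totals[g2])
  satisfaction$n_missing_participants <- n_missing
  satisfaction$mcar <- mcar
  satisfaction$alpha_reliability <- cronbach_alpha(completed)
  satisfaction$notes <- notes

  structure(list(efficiency = efficiency, satisfaction = satisfaction,
                 n = c(diagram = sum(g1), questionnaire = sum(g2)),
                 alpha = alpha),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("<study_analysis>", sum(x$n), "participants (",
      paste(sprintf("%s = %d", names(x$n), x$n), collapse = ", "), ")\n")
  section <- function(name, s) {
    cat("\n--", name, "--\n")
    print(s$group_stats, row.names = FALSE)
    cat(sprintf("normality (Shapiro-Wilk): diagram p = %.3g, questionnaire p = %.3g\n",
                s$normality$diagram$p_value, s$normality$questionnaire$p_value))
    cat(sprintf("t-test: t = %.3f, df = %.1f, p = %.3g\n",
                s$t_test$statistic, s$t_test$df, s$t_test$p_value))
    cat(sprintf("Mann-Whitney: U = %.1f, p = %.3g\n",
                s$mann_whitney$statistic, s$mann_whitney$p_value))
    cat("selected test:", s$selected, "\n")
  }
  section("Efficiency (task time, s)", x$efficiency)
  section("Satisfaction (total score)", x$satisfaction)
  s <- x$satisfaction
  cat(sprintf("participants with missing items: %d\n", s$n_missing_participants))
  if (s$mcar$applicable) {
    cat(sprintf("Little's MCAR: d2 = %.2f, df = %d, p = %.3g\n",
                s$mcar$d2, s$mcar$df, s$mcar$p_value))
  } else cat("Little's MCAR: not applicable (no missing data)\n")
  cat(sprintf("Cronbach's alpha: %.3f\n", s$alpha_reliability))
  for (note in s$notes) cat("note:", note, "\n")
  invisible(x)
}
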