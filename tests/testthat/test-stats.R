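test_that("recoding reverses flagged items and is an involution", {
  spec <- csuq_instrument(reverse = c(TRUE, FALSE, rep(TRUE, 15L)))
  x <- matrix(c(1, 3, rep(4, 15L)), nrow = 1L,
              dimnames = list(NULL, spec$item))
  r <- recode_items(x, spec)
  expect_identical(r[1, "i01"], c(i01 = 7))   # 8 - 1
  expect_identical(r[1, "i02"], c(i02 = 3))   # positive item unchanged
  expect_identical(recode_items(r, spec), x)  # involution

  x[1, "i05"] <- NA
  expect_true(is.na(recode_items(x, spec)[1, "i05"]))
  x[1, "i05"] <- 9
  expect_error(recode_items(x, spec), "item i05.*outside the 1..7 scale")
})

test_that("total scores span 17..119 and propagate missingness", {
  expect_identical(total_score(rep(1, 17)), 17)
  expect_identical(total_score(rep(7, 17)), 119)
  m <- matrix(4, 2, 17, dimnames = list(NULL, csuq_instrument()$item))
  m[2, 3] <- NA
  expect_identical(total_score(m), c(68, NA))
})

test_that("cronbach alpha matches closed forms and flags degenerate input", {
  x <- c(1, 2, 3, 4, 6)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)            # 2*(1 - 2v/4v)
  y <- c(1, 1, -1, -1); z <- c(1, -1, 1, -1)              # orthogonal
  expect_equal(cronbach_alpha(cbind(y, z)), 0)            # 2*(1 - 2v/2v)
  expect_error(cronbach_alpha(matrix(3, 4, 3)), "zero variance")
  expect_error(cronbach_alpha(cbind(x)), ">= 2 items")
})

test_that("alpha is invariant under consistently recoded polarity", {
  set.seed(42)
  f <- rnorm(60)
  lat <- 4 + 0.8 * matrix(f, 60, 17) + matrix(rnorm(60 * 17), 60)
  items <- pmin(pmax(round(lat), 1), 7)
  colnames(items) <- csuq_instrument()$item
  all_pos <- csuq_instrument(reverse = rep(FALSE, 17L))
  flipped_spec <- csuq_instrument(reverse = c(rep(TRUE, 5L), rep(FALSE, 12L)))
  flipped_items <- items
  flipped_items[, 1:5] <- 8 - flipped_items[, 1:5]
  expect_equal(cronbach_alpha(recode_items(items, all_pos)),
               cronbach_alpha(recode_items(flipped_items, flipped_spec)))
})

test_that("the MCAR statistic is zero on complete data", {
  x <- matrix(rnorm(40), 10, 4)
  r <- little_mcar(x)
  expect_false(r$applicable)
  expect_identical(r$d2, 0)
  expect_identical(r$df, 0L)
  expect_identical(r$n_patterns, 1L)
})

test_that("the MCAR quadratic form matches a row-by-row EM oracle", {
  # six-row, two-variable toy with one incomplete pattern
  x <- matrix(c(1.0, 2.1,
                2.0, 2.9,
                3.0, 4.2,
                4.0, 5.1,
                5.0, NA,
                6.0, NA), ncol = 2L, byrow = TRUE)
  r <- little_mcar(x)
  expect_equal(r$d2, oracle_little_d2(x), tolerance = 1e-6)
  expect_identical(r$n_patterns, 2L)
  # df = (2 observed in complete pattern rows... ) sum p_j - p = (2 + 1) - 2
  expect_identical(r$df, 1L)
  expect_true(r$p_value >= 0 && r$p_value <= 1)

  # and on a larger mixed-pattern matrix
  set.seed(9)
  y <- matrix(rnorm(120), 30, 4)
  y[sample(length(y), 14)] <- NA
  y <- y[rowSums(!is.na(y)) > 0, ]
  expect_equal(little_mcar(y)$d2, oracle_little_d2(y), tolerance = 1e-5)
})

test_that("the MCAR test holds its nominal size under random missingness", {
  set.seed(1234)
  reps <- 200L
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    n <- 80L; p <- 3L
    S <- diag(p) * 0.6 + 0.4
    x <- matrix(rnorm(n * p), n, p) %*% chol(S)
    x[matrix(runif(n * p) < 0.1, n, p)] <- NA
    x <- x[rowSums(!is.na(x)) > 0, , drop = FALSE]
    r <- little_mcar(x)
    rej[i] <- r$applicable && r$p_value < 0.05
  }
  rate <- mean(rej)
  band <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, 0.05 - band)
  expect_lte(rate, 0.05 + band)
})

test_that("single imputation fills conditional means and never touches observed cells", {
  x <- matrix(rnorm(30), 15, 2)
  expect_identical(impute_single(x), x)  # complete -> unchanged

  set.seed(5)
  z <- matrix(rnorm(40), 20, 2) %*% chol(matrix(c(1, 0.7, 0.7, 1), 2))
  z_miss <- z
  z_miss[3, 2] <- NA
  done <- impute_single(z_miss)
  fit <- oracle_em(z_miss)
  by_hand <- fit$mu[2] + fit$sigma[1, 2] / fit$sigma[1, 1] *
    (z_miss[3, 1] - fit$mu[1])
  expect_equal(done[3, 2], by_hand, tolerance = 1e-6)
  expect_identical(done[-3, ], z_miss[-3, ])
  expect_identical(done[3, 1], z_miss[3, 1])
})

test_that("the pooled t-test matches the closed form on a small toy", {
  x <- c(3, 4, 5, 6); y <- c(5, 6, 7, 9)
  r <- t_test_ind(x, y)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 6))

  same <- t_test_ind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(t_test_ind(c(1), c(2, 3)), "at least 2")
  expect_error(t_test_ind(c(2, 2), c(3, 3)), "zero within-group variance")

  welch <- t_test_ind(x, c(y, 20), var_equal = FALSE)
  expect_match(welch$method, "Welch")
})

test_that("mann_whitney reproduces exact enumeration, with and without ties", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)

  set.seed(77)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(1:5, n1, replace = TRUE)  # heavy ties
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact_p(x, y),
                 info = sprintf("rep %d", i))
  }
})

test_that("the large-sample approximation agrees with wilcox.test", {
  set.seed(88)
  x <- rnorm(20); y <- rnorm(25, 0.4)   # continuous: no ties
  r <- mann_whitney(x, y)
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(r$statistic, unname(w$statistic))
  expect_equal(r$p_value, w$p.value, tolerance = 1e-10)
  expect_match(r$method, "normal approximation")
})

test_that("normality_check wraps Shapiro-Wilk", {
  set.seed(3)
  norm_p <- normality_check(rnorm(40))$p_value
  skew_p <- normality_check(rexp(40))$p_value
  expect_gt(norm_p, 0.05)
  expect_lt(skew_p, 0.01)
  expect_error(normality_check(c(1, 2)), "n >= 3")
})

test_that("analyze_study populates every stage on the default fixture", {
  d <- simulate_study(seed = 2024)
  a <- analyze_study(d)
  for (section in list(a$efficiency, a$satisfaction)) {
    expect_identical(section$group_stats$group, c("diagram", "questionnaire"))
    expect_true(all(is.finite(section$group_stats$mean)))
    expect_true(all(is.finite(section$group_stats$sd)))
    expect_true(is.finite(section$t_test$p_value))
    expect_true(is.finite(section$mann_whitney$p_value))
    expect_true(section$selected %in% c("t_test", "mann_whitney"))
  }
  expect_identical(a$satisfaction$n_missing_participants, 21L)
  expect_true(a$satisfaction$mcar$applicable)
  expect_true(is.finite(a$satisfaction$alpha_reliability))
  expect_gt(a$satisfaction$alpha_reliability, 0.7)
})

test_that("a complete dataset skips the MCAR/imputation machinery", {
  cfg <- study_sim_config(n_missing_participants = 0L)
  d <- simulate_study(cfg, seed = 5)
  a <- analyze_study(d)
  expect_false(a$satisfaction$mcar$applicable)
  expect_identical(a$satisfaction$n_missing_participants, 0L)
})

test_that("the normality gate selects the nonparametric test exactly on rejection", {
  set.seed(10)
  d <- simulate_study(seed = 10)
  # force a heavily skewed task-time distribution in one arm
  d$task_time[d$group == "questionnaire"] <-
    round(rexp(45, 1 / 20)^1.5 + 60, 2)
  a <- analyze_study(d)
  rejected <- a$efficiency$normality$diagram$p_value < 0.05 ||
    a$efficiency$normality$questionnaire$p_value < 0.05
  expect_true(rejected)
  expect_identical(a$efficiency$selected, "mann_whitney")

  d2 <- simulate_study(seed = 61)
  a2 <- analyze_study(d2)
  rej2 <- a2$efficiency$normality$diagram$p_value < 0.05 ||
    a2$efficiency$normality$questionnaire$p_value < 0.05
  expect_identical(a2$efficiency$selected,
                   if (rej2) "mann_whitney" else "t_test")
})

test_that("study CSV round-trips through read/write with missing cells", {
  d <- simulate_study(seed = 33)
  path <- withr::local_tempfile(fileext = ".csv")
  write_study(d, path)
  back <- read_study(path)
  expect_equal(back, d, ignore_attr = TRUE)
  expect_error(validate_study(d[, -2]), "missing columns: group")
  bad <- d; bad$i01[1] <- 9
  expect_error(validate_study(bad), "1..7")
})
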