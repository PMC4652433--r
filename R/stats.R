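#' The satisfaction instrument
#'
#' Seventeen items adapted from the IBM Computer System Usability
#' Questionnaire, each answered on a 7-point Likert scale anchored at
#' 1 = strongly agree and 7 = strongly disagree. With positively worded
#' statements under that anchoring, raw agreement scores low, so by default
#' every item is flagged for recoding (`x -> 8 - x`); after recoding, higher
#' totals mean higher satisfaction and the total ranges 17..119.
#'
#' @param reverse logical vector of length 17: which items are recoded.
#' @return a data.frame with columns `item` (`i01`..`i17`) and `reverse`.
#' @export
csuq_instrument <- function(reverse = rep(TRUE, 17L)) {
  stopifnot(length(reverse) == 17L, is.logical(reverse))
  data.frame(item = sprintf("i%02d", 1:17), reverse = reverse,
             stringsAsFactors = FALSE)
}

.item_matrix <- function(x, instrument) {
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L,
                                                 dimnames = list(NULL, instrument$item))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- instrument$item[seq_len(ncol(x))]
  missing_cols <- setdiff(instrument$item, colnames(x))
  if (length(missing_cols))
    stop("missing item columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  x[, instrument$item, drop = FALSE]
}

#' Recode negatively worded items
#'
#' Items flagged in the instrument are mapped `x -> 8 - x` on the 7-point
#' scale; other items and missing responses are unchanged. Applying the
#' recoding twice is the identity.
#'
#' @param x matrix/data.frame of responses (columns named as in the
#'   instrument) or a single 17-vector; values in 1..7 or `NA`.
#' @param instrument a [csuq_instrument()].
#' @return recoded matrix with the instrument's column order.
#' @export
recode_items <- function(x, instrument = csuq_instrument()) {
  m <- .item_matrix(x, instrument)
  bad <- which(!is.na(m) & (m < 1 | m > 7 | m != round(m)), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, ]
    stop(sprintf("item %s: response %s outside the 1..7 scale",
                 colnames(m)[i[2L]], m[i[1L], i[2L]]), call. = FALSE)
  }
  rev_cols <- instrument$item[instrument$reverse]
  m[, rev_cols] <- 8 - m[, rev_cols]
  m
}

#' Total satisfaction score
#'
#' Sums the 17 recoded items per respondent. Before imputation a respondent
#' with any missing item has a missing total; on complete recoded data the
#' total lies in 17..119.
#'
#' @param x recoded item matrix (or a single 17-vector).
#' @return numeric vector of totals (`NA` where any item is missing).
#' @export
total_score <- function(x) {
  if (is.vector(x) && is.numeric(x)) return(sum(x))
  rowSums(as.matrix(x))
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`, with sample
#' variances (n-1 denominator), on a complete item matrix.
#'
#' @param x complete numeric matrix, respondents in rows, >= 2 items and
#'   >= 2 respondents.
#' @return the reliability coefficient.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("cronbach_alpha needs a complete matrix", call. = FALSE)
  k <- ncol(x)
  if (k < 2L || nrow(x) < 2L)
    stop("need >= 2 items and >= 2 respondents", call. = FALSE)
  vt <- stats::var(rowSums(x))
  if (vt <= 0)
    stop("undefined reliability: total score has zero variance", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(x, 2L, stats::var)) / vt)
}

# ---- EM estimation of mean/covariance under ignorable missingness ----

.pattern_split <- function(x) {
  miss <- is.na(x)
  key <- apply(miss, 1L, function(r) paste(as.integer(r), collapse = ""))
  split(seq_len(nrow(x)), key)
}

# ML EM for a multivariate normal with missing cells; returns mu, sigma
em_mvnorm <- function(x, max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (p < 2L) stop("need >= 2 variables", call. = FALSE)
  n_obs_var <- colSums(!is.na(x))
  if (any(n_obs_var < 2L))
    stop("every variable must be observed at least twice", call. = FALSE)
  if (any(rowSums(!is.na(x)) == 0L))
    stop("rows with no observed values are not estimable", call. = FALSE)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, p)
  patterns <- .pattern_split(x)
  for (iter in seq_len(max_iter)) {
    s1 <- numeric(p)
    s2 <- matrix(0, p, p)
    for (rows in patterns) {
      o <- which(!is.na(x[rows[1L], ]))
      m <- setdiff(seq_len(p), o)
      xo <- x[rows, o, drop = FALSE]
      if (length(m) == 0L) {
        s1 <- s1 + colSums(xo)
        s2 <- s2 + crossprod(xo)
        next
      }
      B <- sigma[m, o, drop = FALSE] %*% solve(sigma[o, o, drop = FALSE])
      xm_hat <- matrix(mu[m], nrow = length(rows), ncol = length(m),
                       byrow = TRUE) +
        sweep(xo, 2L, mu[o]) %*% t(B)
      C <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
      xi <- matrix(0, nrow = length(rows), ncol = p)
      xi[, o] <- xo
      xi[, m] <- xm_hat
      s1 <- s1 + colSums(xi)
      s2 <- s2 + crossprod(xi)
      s2[m, m] <- s2[m, m] + length(rows) * C
    }
    mu_new <- s1 / n
    sigma_new <- s2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    delta <- max(max(abs(mu_new - mu)), max(abs(sigma_new - sigma)))
    mu <- mu_new
    sigma <- sigma_new
    if (delta < tol) break
  }
  list(mu = mu, sigma = sigma, iterations = iter, converged = delta < tol)
}

#' Little's test of missing completely at random
#'
#' Estimates the grand mean and covariance by maximum-likelihood EM, then
#' sums over missingness patterns `j` the quadratic forms
#' `n_j * (ybar_obs_j - mu_j)' Sigma_j^{-1} (ybar_obs_j - mu_j)`; under MCAR
#' the statistic is asymptotically chi-square with
#' `sum(variables observed per pattern) - total variables` degrees of
#' freedom. On a complete matrix no test applies (`applicable = FALSE`,
#' statistic 0, df 0).
#'
#' @param x numeric matrix/data.frame with possibly missing cells; >= 2
#'   variables, each observed at least twice.
#' @param max_iter,tol EM control.
#' @return an object of class `mcar_test`: `d2`, `df`, `p_value`,
#'   `n_patterns`, `applicable`, plus the EM `mu`/`sigma`.
#' @export
little_mcar <- function(x, max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(x)
  p <- ncol(x)
  patterns <- .pattern_split(x)
  if (!anyNA(x)) {
    return(structure(list(d2 = 0, df = 0L, p_value = NA_real_,
                          n_patterns = 1L, applicable = FALSE,
                          mu = colMeans(x), sigma = stats::cov(x)),
                     class = "mcar_test"))
  }
  fit <- em_mvnorm(x, max_iter = max_iter, tol = tol)
  d2 <- 0
  df <- 0L
  for (key in names(patterns)) {
    rows <- patterns[[key]]
    o <- which(!is.na(x[rows[1L], ]))
    ybar <- colMeans(x[rows, o, drop = FALSE])
    diff <- ybar - fit$mu[o]
    so <- fit$sigma[o, o, drop = FALSE]
    q <- tryCatch(
      drop(crossprod(diff, solve(so, diff))),
      error = function(e) stop(sprintf(
        "singular covariance for missingness pattern '%s'", key),
        call. = FALSE))
    d2 <- d2 + length(rows) * q
    df <- df + length(o)
  }
  df <- df - p
  applicable <- df > 0L
  structure(list(d2 = d2, df = df,
                 p_value = if (applicable)
                   stats::pchisq(d2, df, lower.tail = FALSE) else NA_real_,
                 n_patterns = length(patterns), applicable = applicable,
                 mu = fit$mu, sigma = fit$sigma),
            class = "mcar_test")
}

#' @export
print.mcar_test <- function(x, ...) {
  if (!x$applicable) {
    cat("<mcar_test> not applicable (",
        if (x$n_patterns == 1L) "data complete" else "insufficient patterns",
        ")\n", sep = "")
  } else {
    cat(sprintf("<mcar_test> d2 = %.3f, df = %d, p = %.3f (%d patterns)\n",
                x$d2, x$df, x$p_value, x$n_patterns))
  }
  invisible(x)
}

#' Deterministic single imputation
#'
#' Produces one completed dataset by replacing each missing cell with its
#' conditional mean given the row's observed values, under the EM-estimated
#' multivariate-normal mean and covariance (regression imputation).
#' Observed cells are returned bit-identical; a complete matrix is returned
#' unchanged. Intended after [little_mcar()] has not rejected randomness of
#' the missingness.
#'
#' @inheritParams little_mcar
#' @return completed numeric matrix of the same shape.
#' @export
impute_single <- function(x, max_iter = 500L, tol = 1e-6) {
  x <- as.matrix(x)
  if (!anyNA(x)) return(x)
  fit <- em_mvnorm(x, max_iter = max_iter, tol = tol)
  out <- x
  for (rows in .pattern_split(x)) {
    o <- which(!is.na(x[rows[1L], ]))
    m <- setdiff(seq_len(ncol(x)), o)
    if (length(m) == 0L) next
    B <- fit$sigma[m, o, drop = FALSE] %*% solve(fit$sigma[o, o, drop = FALSE])
    xo <- x[rows, o, drop = FALSE]
    out[rows, m] <- matrix(fit$mu[m], nrow = length(rows), ncol = length(m),
                           byrow = TRUE) + sweep(xo, 2L, fit$mu[o]) %*% t(B)
  }
  out
}

# ---- two-group comparisons ----

.group_stats <- function(x, y, labels) {
  data.frame(group = labels, n = c(length(x), length(y)),
             mean = c(mean(x), mean(y)), sd = c(stats::sd(x), stats::sd(y)),
             stringsAsFactors = FALSE)
}

#' Independent-groups t-test
#'
#' Two-sided t-test for two independent samples, pooled-variance by default
#' (Welch by flag), via [stats::t.test()].
#'
#' @param x,y the two samples.
#' @param var_equal pooled variance (default TRUE).
#' @param labels group labels for the summaries.
#' @return an object of class `famrisk_test` with `method`, `statistic`,
#'   `df`, `p_value` and per-group `group_stats` (M, SD).
#' @export
t_test_ind <- function(x, y, var_equal = TRUE,
                       labels = c("group1", "group2")) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 observations", call. = FALSE)
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0)
    stop("degenerate input: zero within-group variance", call. = FALSE)
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(list(method = if (var_equal) "pooled t-test" else "Welch t-test",
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, group_stats = .group_stats(x, y, labels)),
            class = "famrisk_test")
}

#' Shapiro-Wilk normality check
#'
#' @param x sample (3 <= n <= 5000).
#' @return a `famrisk_test` with the W statistic and p-value.
#' @export
normality_check <- function(x) {
  if (length(x) < 3L) stop("normality check needs n >= 3", call. = FALSE)
  sw <- stats::shapiro.test(x)
  structure(list(method = "Shapiro-Wilk", statistic = unname(sw$statistic),
                 df = NA_real_, p_value = sw$p.value,
                 group_stats = data.frame(group = "sample", n = length(x),
                                          mean = mean(x), sd = stats::sd(x),
                                          stringsAsFactors = FALSE)),
            class = "famrisk_test")
}

# U statistic from midranks (ties allowed)
.u_stat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both groups have at most `exact_max`
#' observations the null distribution of U is enumerated exactly over all
#' assignments of the observed (possibly tied) values to groups; otherwise a
#' tie-corrected normal approximation (no continuity correction) is used.
#'
#' @param x,y the two samples.
#' @param exact_max exact enumeration when both `n <= exact_max` (default 8).
#' @param labels group labels.
#' @return a `famrisk_test` with the U statistic (first group) and p-value.
#' @export
mann_whitney <- function(x, y, exact_max = 8L, labels = c("group1", "group2")) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  u_obs <- .u_stat(x, y)
  if (n1 <= exact_max && n2 <= exact_max) {
    r <- rank(c(x, y))
    base <- n1 * (n1 + 1) / 2
    combos <- utils::combn(N, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - base
    eps <- 1e-8
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    method <- "Mann-Whitney (exact)"
  } else {
    r <- rank(c(x, y))
    ties <- table(r)
    mu_u <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma_u <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
    if (sigma_u == 0)
      stop("degenerate input: all values tied", call. = FALSE)
    z <- (u_obs - mu_u) / sigma_u
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Mann-Whitney (normal approximation, tie-corrected)"
  }
  structure(list(method = method, statistic = u_obs, df = NA_real_,
                 p_value = p, group_stats = .group_stats(x, y, labels)),
            class = "famrisk_test")
}

#' @export
print.famrisk_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g%s, p = %.4g\n", x$method, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.4g", x$df),
              x$p_value))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}
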