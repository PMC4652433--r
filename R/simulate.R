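# restore the caller's RNG state after seeded simulation
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

#' Pedigree simulation configuration
#'
#' Controls the random-pedigree generator: a per-role probability that the
#' relative is affected by colorectal cancer, a truncated-normal
#' age-at-diagnosis distribution, flag probabilities (conditional on being
#' affected), and a distribution for the number of members present in each
#' pooled group role.
#'
#' @param affection_prob single probability applied to every role, or a
#'   named vector over [relative_roles()] (missing names default to the
#'   unnamed default of 0.1).
#' @param age_mean,age_sd age-at-diagnosis distribution (years), truncated
#'   to `age_range`.
#' @param age_range truncation bounds, default 25..95 years.
#' @param p_polyps,p_other,p_mcrc flag probabilities for affected relatives.
#' @param group_size_probs probabilities for 0..`group_cap` members present
#'   per pooled group.
#' @param group_cap maximum members per pooled group (default 7).
#' @return a list of class `pedigree_sim_config`.
#' @export
pedigree_sim_config <- function(affection_prob = 0.1, age_mean = 65,
                                age_sd = 12, age_range = c(25L, 95L),
                                p_polyps = 0.05, p_other = 0.08,
                                p_mcrc = 0.03,
                                group_size_probs = c(0.55, 0.20, 0.12, 0.06,
                                                     0.04, 0.02, 0.007, 0.003),
                                group_cap = 7L) {
  roles <- relative_roles()
  if (is.null(names(affection_prob))) {
    p <- stats::setNames(rep(affection_prob[1L], length(roles)), roles)
  } else {
    bad <- setdiff(names(affection_prob), roles)
    if (length(bad)) stop("config error: unknown role in affection_prob: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    p <- stats::setNames(rep(0.1, length(roles)), roles)
    p[names(affection_prob)] <- affection_prob
  }
  if (any(p < 0 | p > 1)) stop("config error: probabilities must be in [0,1]",
                               call. = FALSE)
  for (f in c("p_polyps", "p_other", "p_mcrc")) {
    v <- get(f)
    if (v < 0 || v > 1) stop("config error: ", f, " must be in [0,1]",
                             call. = FALSE)
  }
  if (length(group_size_probs) != group_cap + 1L || any(group_size_probs < 0))
    stop("config error: group_size_probs must give probabilities for 0..cap",
         call. = FALSE)
  structure(list(affection_prob = p, age_mean = age_mean, age_sd = age_sd,
                 age_range = as.integer(age_range), p_polyps = p_polyps,
                 p_other = p_other, p_mcrc = p_mcrc,
                 group_size_probs = group_size_probs / sum(group_size_probs),
                 group_cap = as.integer(group_cap)),
            class = "pedigree_sim_config")
}

.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(pmax(as.integer(round(stats::qnorm(u, mean, sd))), lo), hi)
}

#' Simulate a random pedigree
#'
#' Draws presence and cancer history for each of the twelve roles under the
#' configuration. The same seed always yields the identical pedigree.
#'
#' @param config a [pedigree_sim_config()].
#' @param seed integer seed (the caller's RNG state is restored afterwards);
#'   `NULL` uses the current RNG stream.
#' @return a validated [pedigree()].
#' @export
simulate_pedigree <- function(config = pedigree_sim_config(), seed = NULL) {
  stopifnot(inherits(config, "pedigree_sim_config"))
  .with_seed(seed, {
    rows <- list()
    counter <- integer(0)
    add_member <- function(role) {
      if (stats::runif(1) >= config$affection_prob[[role]]) return(invisible())
      idx <- if (.is_unique_role(role)) 0L else {
        i <- counter[role]; if (is.na(i) || length(i) == 0L) i <- 0L
        counter[role] <<- i + 1L
        i
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        role = role, member_index = idx, affected = TRUE,
        age_dx = .rtruncnorm_int(1L, config$age_mean, config$age_sd,
                                 config$age_range[1L], config$age_range[2L]),
        multiple_polyps = stats::runif(1) < config$p_polyps,
        other_cancers = stats::runif(1) < config$p_other,
        multiple_crc = stats::runif(1) < config$p_mcrc,
        stringsAsFactors = FALSE)
    }
    for (role in c("mother", "father", "maternal_grandmother",
                   "maternal_grandfather", "paternal_grandmother",
                   "paternal_grandfather")) add_member(role)
    groups <- list(
      c("maternal_aunt_uncle", "maternal_aunt_uncle_child"),
      c("paternal_aunt_uncle", "paternal_aunt_uncle_child"),
      "sibling", "child")
    for (g in groups) {
      k <- sample(0:config$group_cap, 1L, prob = config$group_size_probs)
      for (i in seq_len(k)) {
        role <- if (length(g) == 2L) sample(g, 1L) else g
        add_member(role)
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else .empty_relatives()
    .sort_pedigree(new_pedigree(df))
  })
}

# exact largest-remainder scaling of reference counts to a new total
.scale_counts <- function(counts, n) {
  if (sum(counts) == n) return(as.integer(counts))
  q <- counts / sum(counts) * n
  base <- floor(q)
  rem <- n - sum(base)
  extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
  base[extra] <- base[extra] + 1L
  as.integer(base)
}

#' Usability-study simulation configuration
#'
#' Defaults reproduce the study conditions: 90 participants assigned by a
#' 2x45 label pool, age-band counts (8, 9, 9, 29, 21, 9, 5), 41 male
#' participants, internet-use counts (11, 2, 7, 70) from least to most
#' frequent, gaussian task times per group (means 89.2 and 80.89 s, SDs 7.05
#' and 5.19), satisfaction totals per group (means 101.12 and 108.79, SDs
#' 11.9 and 9.08 on the recoded 17..119 scale) generated through a
#' one-factor item model discretized to 1..7, and item-level missingness
#' affecting exactly 21 participants (1-3 unanswered items each). When
#' `n_total` differs from 90 and a count is not supplied, the reference
#' counts are rescaled exactly by largest remainder.
#'
#' @param n_total number of participants.
#' @param group_sizes named sizes for the `diagram` and `questionnaire` arms.
#' @param age_band_counts counts over [age_bands()].
#' @param male_count number of male participants.
#' @param web_use_counts counts over [web_use_levels()].
#' @param task_time per-group `c(mean, sd)` of task time in seconds.
#' @param satisfaction per-group `c(mean, sd)` of the recoded total score.
#' @param n_missing_participants participants with at least one missing item.
#' @param missing_per_participant candidate numbers of missing items each.
#' @param loading one-factor loading of the latent satisfaction items.
#' @param skew optional skew of the participant factor (0 = gaussian).
#' @return a list of class `study_sim_config`.
#' @export
study_sim_config <- function(n_total = 90L, group_sizes = NULL,
                             age_band_counts = NULL, male_count = NULL,
                             web_use_counts = NULL,
                             task_time = list(diagram = c(mean = 89.2, sd = 7.05),
                                              questionnaire = c(mean = 80.89, sd = 5.19)),
                             satisfaction = list(diagram = c(mean = 101.12, sd = 11.9),
                                                 questionnaire = c(mean = 108.79, sd = 9.08)),
                             n_missing_participants = 21L,
                             missing_per_participant = 1:3,
                             loading = 0.55, skew = 0) {
  n_total <- as.integer(n_total)
  if (is.null(group_sizes)) {
    group_sizes <- stats::setNames(.scale_counts(c(45, 45), n_total),
                                   c("diagram", "questionnaire"))
  }
  if (is.null(age_band_counts))
    age_band_counts <- .scale_counts(c(8, 9, 9, 29, 21, 9, 5), n_total)
  if (is.null(male_count)) male_count <- .scale_counts(c(41, 49), n_total)[1L]
  if (is.null(web_use_counts))
    web_use_counts <- .scale_counts(c(11, 2, 7, 70), n_total)
  if (sum(group_sizes) != n_total)
    stop("config error: group sizes must sum to n_total", call. = FALSE)
  if (sum(age_band_counts) != n_total)
    stop("config error: age-band counts must sum to n_total", call. = FALSE)
  if (sum(web_use_counts) != n_total)
    stop("config error: web-use counts must sum to n_total", call. = FALSE)
  if (male_count > n_total)
    stop("config error: male_count exceeds n_total", call. = FALSE)
  if (n_missing_participants > n_total)
    stop("config error: n_missing_participants exceeds n_total", call. = FALSE)
  structure(list(n_total = n_total, group_sizes = group_sizes,
                 age_band_counts = as.integer(age_band_counts),
                 male_count = as.integer(male_count),
                 web_use_counts = as.integer(web_use_counts),
                 task_time = task_time, satisfaction = satisfaction,
                 n_missing_participants = as.integer(n_missing_participants),
                 missing_per_participant = as.integer(missing_per_participant),
                 loading = loading, skew = skew),
            class = "study_sim_config")
}

# expectation of round-and-clamp discretization of N(m, s) onto 1..7
.disc_mean <- function(m, s) {
  cuts <- stats::pnorm(c(-Inf, seq(1.5, 6.5, by = 1), Inf), m, s)
  sum((1:7) * diff(cuts))
}

# latent item mean whose discretized expectation equals the target
.calibrate_item_mean <- function(target, s) {
  if (target <= 1 || target >= 7)
    stop("config error: per-item satisfaction mean must lie inside (1, 7)",
         call. = FALSE)
  stats::uniroot(function(m) .disc_mean(m, s) - target,
                 interval = c(-6, 14), tol = 1e-8)$root
}

#' Simulate a usability-study dataset
#'
#' Demographic marginals (group sizes, age bands, gender, internet use)
#' match the configuration exactly, not in expectation: the generator
#' permutes label pools, mirroring the 2x45 prepared-label randomisation of
#' the study design. Task times are gaussian per group. Satisfaction items
#' are drawn from a one-factor latent model per participant, discretized to
#' the 1..7 scale by rounding with clamping; the latent means are calibrated
#' so the expected recoded total equals the configured group mean, and the
#' residual variance is solved from the configured total SD. Raw stored
#' responses are the inverse-recoded values (the instrument's reversed
#' anchoring), so the analysis pipeline's recoding recovers the satisfaction
#' scale. Exactly `n_missing_participants` rows then lose 1-3 random items.
#'
#' @param config a [study_sim_config()].
#' @param instrument a [csuq_instrument()] (controls which stored items are
#'   reverse-anchored).
#' @param seed integer seed; the caller's RNG state is restored.
#' @return a study data.frame (see [study_io]).
#' @export
simulate_study <- function(config = study_sim_config(),
                           instrument = csuq_instrument(), seed = NULL) {
  stopifnot(inherits(config, "study_sim_config"))
  .with_seed(seed, {
    n <- config$n_total
    group <- sample(rep(names(config$group_sizes), config$group_sizes))
    gender <- sample(rep(c("male", "female"),
                         c(config$male_count, n - config$male_count)))
    band <- sample(rep(age_bands(), config$age_band_counts))
    web <- sample(rep(web_use_levels(), config$web_use_counts))
    task_time <- numeric(n)
    items <- matrix(NA_real_, n, 17L,
                    dimnames = list(NULL, instrument$item))
    lambda <- config$loading
    for (g in names(config$group_sizes)) {
      rows <- which(group == g)
      tt <- config$task_time[[g]]
      task_time[rows] <- stats::rnorm(length(rows), tt[["mean"]], tt[["sd"]])
      st <- config$satisfaction[[g]]
      resid_var <- max((st[["sd"]]^2 - (17 * lambda)^2) / 17, 0.15)
      s_marg <- sqrt(lambda^2 + resid_var)
      m_lat <- .calibrate_item_mean(st[["mean"]] / 17, s_marg)
      f <- stats::rnorm(length(rows))
      if (config$skew != 0) {
        f <- (exp(config$skew * f) - 1) / config$skew
        f <- (f - mean_lognorm_shift(config$skew)) / sd_lognorm_shift(config$skew)
      }
      latent <- m_lat + lambda * f +
        matrix(stats::rnorm(length(rows) * 17L, sd = sqrt(resid_var)),
               nrow = length(rows))
      items[rows, ] <- pmin(pmax(round(latent), 1), 7)
    }
    # store raw responses: invert the instrument's recoding
    raw <- items
    raw[, instrument$item[instrument$reverse]] <-
      8 - raw[, instrument$item[instrument$reverse]]
    if (config$n_missing_participants > 0L) {
      who <- sample(n, config$n_missing_participants)
      for (i in who) {
        k <- if (length(config$missing_per_participant) == 1L)
          config$missing_per_participant else
          sample(config$missing_per_participant, 1L)
        raw[i, sample(17L, k)] <- NA_real_
      }
    }
    data <- data.frame(id = sprintf("P%03d", seq_len(n)), group = group,
                       gender = gender, age_band = band, web_use = web,
                       task_time = round(task_time, 2),
                       stringsAsFactors = FALSE)
    data <- cbind(data, as.data.frame(raw))
    validate_study(data)
    data
  })
}

# moments of the centred lognormal transform used by the skew option
mean_lognorm_shift <- function(a) (exp(a^2 / 2) - 1) / a
sd_lognorm_shift <- function(a) sqrt((exp(a^2) - 1) * exp(a^2)) / abs(a)
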