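# Independent oracles, deliberately sharing no code with the package
# internals they check.

# ---- naive rule-by-rule risk evaluator -------------------------------------

oracle_side <- function(role) {
  if (role %in% c("mother", "maternal_grandmother", "maternal_grandfather",
                  "maternal_aunt_uncle", "maternal_aunt_uncle_child"))
    return("mother_side")
  if (role %in% c("father", "paternal_grandmother", "paternal_grandfather",
                  "paternal_aunt_uncle", "paternal_aunt_uncle_child"))
    return("father_side")
  "your_side"
}

oracle_degree <- function(role) {
  if (role %in% c("mother", "father", "sibling", "child")) "FDR" else "SDR"
}

oracle_generation <- function(role) {
  if (grepl("grand", role)) return(2L)
  if (role %in% c("mother", "father", "maternal_aunt_uncle",
                  "paternal_aunt_uncle")) return(1L)
  if (role == "child") return(-1L)
  0L
}

# plain-loop re-check of every rule predicate against the relative list
oracle_assess <- function(ped, rules = rule_table()) {
  df <- ped$relatives
  n <- nrow(df)
  fired <- character(0)

  n_fdr <- 0L
  fdr_age <- NA_integer_
  for (i in seq_len(n)) {
    if (df$affected[i] && oracle_degree(df$role[i]) == "FDR") {
      n_fdr <- n_fdr + 1L
      fdr_age <- df$age_dx[i]
    }
  }
  # R2a
  for (i in seq_len(n)) {
    if (df$affected[i] && oracle_degree(df$role[i]) == "FDR" &&
        !is.na(df$age_dx[i]) && df$age_dx[i] < rules$age_cutoff_primary) {
      fired <- c(fired, "R2a"); break
    }
  }
  if (n_fdr >= 2L) fired <- c(fired, "R2b")
  for (s in c("mother_side", "father_side")) {
    members <- integer(0)
    for (i in seq_len(n)) {
      if (df$affected[i] &&
          oracle_side(df$role[i]) %in% c(s, "your_side"))
        members <- c(members, i)
    }
    if (length(members) == 0L) next
    gens <- unique(vapply(df$role[members], oracle_generation, integer(1)))
    any_early <- any(!is.na(df$age_dx[members]) &
                       df$age_dx[members] < rules$age_cutoff_high)
    if (length(members) >= rules$amsterdam_min_relatives &&
        length(gens) >= rules$amsterdam_min_generations && any_early)
      fired <- c(fired, "R3a")
    if (length(members) >= rules$high_risk_cluster_min &&
        (any_early || any(df$multiple_crc[members]) ||
           any(df$other_cancers[members])))
      fired <- c(fired, "R3b")
  }
  if (any(df$multiple_polyps)) fired <- c(fired, "R3c")
  fired <- intersect(fired, rules$enabled)
  rank_of <- c(R1 = 1L, R2a = 2L, R2b = 2L, R3a = 3L, R3b = 3L, R3c = 3L)
  top <- if (length(fired)) max(rank_of[unique(fired)]) else 0L
  if ("R1" %in% rules$enabled && top < 2L && n_fdr == 1L &&
      !is.na(fdr_age) && fdr_age >= rules$age_cutoff_primary) {
    fired <- c(fired, "R1")
    top <- max(top, 1L)
  }
  c("average", "slightly_increased", "moderately_increased",
    "potentially_high")[top + 1L]
}

# ---- Mann-Whitney exact enumeration via pairwise counting ------------------

oracle_mw_exact_p <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) u <- u + (ai > bj) + 0.5 * (ai == bj)
    u
  }
  v <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(v), n1)
  u_all <- apply(idx, 2L, function(k) u_of(v[k], v[-k]))
  u_obs <- u_of(x, y)
  eps <- 1e-8
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# ---- row-by-row EM for the multivariate normal -----------------------------

oracle_em <- function(x, iters = 5000L, tol = 1e-10) {
  p <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  sig <- diag(apply(x, 2L, var, na.rm = TRUE), p)
  for (it in seq_len(iters)) {
    xs <- matrix(0, nrow(x), p)
    cc_sum <- matrix(0, p, p)
    for (i in seq_len(nrow(x))) {
      o <- which(!is.na(x[i, ]))
      m <- which(is.na(x[i, ]))
      xi <- x[i, ]
      if (length(m)) {
        so_inv <- solve(sig[o, o, drop = FALSE])
        xi[m] <- mu[m] + sig[m, o, drop = FALSE] %*% so_inv %*% (x[i, o] - mu[o])
        cc_sum[m, m] <- cc_sum[m, m] + sig[m, m, drop = FALSE] -
          sig[m, o, drop = FALSE] %*% so_inv %*% sig[o, m, drop = FALSE]
      }
      xs[i, ] <- xi
    }
    mu_new <- colMeans(xs)
    sig_new <- (crossprod(xs) + cc_sum) / nrow(x) - tcrossprod(mu_new)
    done <- max(abs(mu_new - mu), abs(sig_new - sig)) < tol
    mu <- mu_new
    sig <- sig_new
    if (done) break
  }
  list(mu = mu, sigma = sig)
}

oracle_little_d2 <- function(x) {
  fit <- oracle_em(x)
  keys <- apply(is.na(x), 1L, paste, collapse = "")
  d2 <- 0
  for (k in unique(keys)) {
    rows <- which(keys == k)
    o <- which(!is.na(x[rows[1L], ]))
    ybar <- colMeans(x[rows, o, drop = FALSE])
    diff <- ybar - fit$mu[o]
    d2 <- d2 + length(rows) *
      drop(t(diff) %*% solve(fit$sigma[o, o, drop = FALSE]) %*% diff)
  }
  d2
}

# ---- misc ------------------------------------------------------------------

# richer random pedigrees than the generator defaults, for property tests
random_pedigree <- function(seed) {
  cfg <- pedigree_sim_config(
    affection_prob = 0.35, p_polyps = 0.08, p_other = 0.12, p_mcrc = 0.05,
    group_size_probs = c(0.35, 0.25, 0.18, 0.1, 0.06, 0.03, 0.02, 0.01))
  simulate_pedigree(cfg, seed = seed)
}

expect_same_pedigree <- function(a, b) {
  expect_equal(a$relatives, b$relatives, ignore_attr = TRUE)
}
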