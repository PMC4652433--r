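#' Risk categories
#'
#' The guideline stratifies lifetime colorectal-cancer risk into four ordered
#' categories. Ranks run 0 (average) to 3 (potentially high).
#'
#' @return named integer vector of ranks, names in rank order.
#' @export
#' @examples
#' risk_categories()
risk_categories <- function() {
  c(average = 0L, slightly_increased = 1L, moderately_increased = 2L,
    potentially_high = 3L)
}

.category_labels <- c(
  average = "average lifetime risk",
  slightly_increased = "slightly increased risk",
  moderately_increased = "moderately increased risk",
  potentially_high = "potentially high risk"
)

.rule_ids <- c("R1", "R2a", "R2b", "R3a", "R3b", "R3c")
.rule_rank <- c(R1 = 1L, R2a = 2L, R2b = 2L, R3a = 3L, R3b = 3L, R3c = 3L)

.default_recommendations <- function() {
  list(
    average = paste(
      "Your family history places you at average lifetime risk of colorectal",
      "cancer. No surveillance within the programme is recommended; see your",
      "general practitioner if you develop symptoms or your family history",
      "changes."),
    slightly_increased = paste(
      "Your family history places you at slightly increased lifetime risk.",
      "Discuss with your general practitioner whether a screening colonoscopy",
      "from age 50 is appropriate for you."),
    moderately_increased = paste(
      "Your family history places you at moderately increased lifetime risk.",
      "Surveillance colonoscopy is usually offered five-yearly from age 50,",
      "or ten years before the earliest cancer in your family; please discuss",
      "this with your general practitioner."),
    potentially_high = paste(
      "Your family history suggests a potentially high lifetime risk.",
      "A referral to a genetic service for assessment (including possible",
      "Lynch-syndrome or polyposis testing) and an individual surveillance",
      "plan is recommended; please see your general practitioner promptly.")
  )
}

.config_error <- function(field, msg) {
  stop(sprintf("rule-table config error in '%s': %s", field, msg), call. = FALSE)
}

#' Rule-table configuration for the risk engine
#'
#' Parameters of the guideline-style category rules. The printed guideline
#' rules are reconstructions of the standard familial-CRC criteria family
#' (one older-onset FDR = slight; early-onset or two FDR = moderate;
#' same-side clusters, polyposis or Lynch-spectrum signals = potentially
#' high); every threshold and every recommendation text is overridable here,
#' and individual rules can be disabled.
#'
#' @param age_cutoff_primary years; "diagnosed before age 55" boundary,
#'   compared strictly (`<`).
#' @param age_cutoff_high years; early-onset boundary for the high-risk
#'   cluster rules (strict `<`); must be below `age_cutoff_primary`.
#' @param amsterdam_min_relatives minimum same-side affected FDR/SDR for the
#'   Amsterdam-style cluster rule.
#' @param amsterdam_min_generations minimum distinct generations the cluster
#'   must span.
#' @param high_risk_cluster_min minimum same-side affected relatives for the
#'   two-relative high-risk cluster rule.
#' @param enabled character vector of enabled rule identifiers (subset of
#'   R1, R2a, R2b, R3a, R3b, R3c).
#' @param recommendations named list of plain-language recommendation texts,
#'   one per category. The potentially-high text must mention a genetic
#'   referral and the average text must mention surveillance (stating none is
#'   offered within the programme).
#' @return an object of class `rule_table`.
#' @seealso [assess_risk()], [load_rule_table()]
#' @export
rule_table <- function(age_cutoff_primary = 55L, age_cutoff_high = 50L,
                       amsterdam_min_relatives = 3L,
                       amsterdam_min_generations = 2L,
                       high_risk_cluster_min = 2L,
                       enabled = .rule_ids,
                       recommendations = .default_recommendations()) {
  rt <- structure(
    list(age_cutoff_primary = as.integer(age_cutoff_primary),
         age_cutoff_high = as.integer(age_cutoff_high),
         amsterdam_min_relatives = as.integer(amsterdam_min_relatives),
         amsterdam_min_generations = as.integer(amsterdam_min_generations),
         high_risk_cluster_min = as.integer(high_risk_cluster_min),
         enabled = enabled, recommendations = recommendations),
    class = "rule_table")
  .validate_rule_table(rt)
  rt
}

.validate_rule_table <- function(rt) {
  if (is.na(rt$age_cutoff_high) || is.na(rt$age_cutoff_primary))
    .config_error("age_cutoff", "cutoffs must be integers")
  if (rt$age_cutoff_high >= rt$age_cutoff_primary)
    .config_error("age_cutoff_high",
                  sprintf("must be < age_cutoff_primary (%d >= %d)",
                          rt$age_cutoff_high, rt$age_cutoff_primary))
  for (f in c("amsterdam_min_relatives", "amsterdam_min_generations",
              "high_risk_cluster_min")) {
    if (is.na(rt[[f]]) || rt[[f]] < 1L) .config_error(f, "must be >= 1")
  }
  bad <- setdiff(rt$enabled, .rule_ids)
  if (length(bad)) .config_error("enabled",
    paste("unknown rule id:", paste(bad, collapse = ", ")))
  cats <- names(risk_categories())
  for (cat in cats) {
    txt <- rt$recommendations[[cat]]
    if (is.null(txt) || !nzchar(txt))
      .config_error("recommendations", paste("missing text for", cat))
  }
  if (!grepl("referral|genetic", rt$recommendations$potentially_high,
             ignore.case = TRUE))
    .config_error("recommendations",
                  "potentially_high text must mention a genetic-service referral")
  if (!grepl("surveillance", rt$recommendations$average, ignore.case = TRUE))
    .config_error("recommendations",
                  "average text must mention surveillance within the programme")
  invisible(rt)
}

#' Load a rule table from a configuration file
#'
#' Reads a YAML or JSON file (by extension) containing any subset of the
#' [rule_table()] fields; unspecified fields take their defaults, and the
#' rule-table invariants are enforced after merging.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return a validated `rule_table`.
#' @export
load_rule_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("age_cutoff_primary", "age_cutoff_high", "amsterdam_min_relatives",
             "amsterdam_min_generations", "high_risk_cluster_min", "enabled",
             "recommendations")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) .config_error(bad[1L], "unknown field")
  defaults <- list(age_cutoff_primary = 55L, age_cutoff_high = 50L,
                   amsterdam_min_relatives = 3L, amsterdam_min_generations = 2L,
                   high_risk_cluster_min = 2L, enabled = .rule_ids,
                   recommendations = .default_recommendations())
  if (!is.null(cfg$recommendations)) {
    defaults$recommendations[names(cfg$recommendations)] <- cfg$recommendations
    cfg$recommendations <- NULL
  }
  defaults[names(cfg)] <- cfg
  do.call(rule_table, defaults)
}

#' Recommendation text for a risk category
#'
#' @param category one of `names(risk_categories())`.
#' @param rules a [rule_table()].
#' @return the configured plain-language recommendation.
#' @export
recommendation_for <- function(category, rules = rule_table()) {
  if (length(category) != 1L || !category %in% names(risk_categories()))
    .config_error("category", sprintf("unknown risk category '%s'",
                                      paste(category, collapse = ",")))
  txt <- rules$recommendations[[category]]
  if (is.null(txt) || !nzchar(txt))
    .config_error("recommendations", paste("missing text for", category))
  txt
}

.rel_label <- function(role, member_index) {
  ifelse(.is_unique_role(role), role, paste0(role, "#", member_index))
}

#' Assess lifetime colorectal-cancer risk from a pedigree
#'
#' The lifetime-risk calculation: evaluates the enabled guideline rules
#' against the pedigree's affected first- and second-degree relatives, their
#' ages at diagnosis, polyposis and Lynch-spectrum signals, and returns the
#' highest-ranking category with a trace of the triggered rules.
#'
#' Default rules (identifiers fixed; parameters from the [rule_table()]):
#' * `R1` (slightly increased) — exactly one affected FDR, diagnosed at or
#'   after the primary cutoff, and no higher rule fires.
#' * `R2a` (moderately increased) — any affected FDR diagnosed before the
#'   primary cutoff.
#' * `R2b` (moderately increased) — two or more affected FDR.
#' * `R3a` (potentially high) — an Amsterdam-style cluster: on one family
#'   side, at least `amsterdam_min_relatives` affected FDR/SDR spanning at
#'   least `amsterdam_min_generations` generations with at least one
#'   diagnosis before the high-risk cutoff.
#' * `R3b` (potentially high) — on one side, at least
#'   `high_risk_cluster_min` affected FDR/SDR and (early-onset diagnosis,
#'   multiple primary CRC, or other Lynch-spectrum cancer) in the cluster.
#' * `R3c` (potentially high) — any relative with multiple polyps.
#'
#' The proband's siblings and children ("your side") are blood relatives of
#' both lineages, so they count toward both parental sides for the same-side
#' cluster rules. A relative with an unknown age at diagnosis satisfies no
#' age comparison but still counts toward relative-count conditions.
#'
#' @param ped a [pedigree()] that passes [validate_pedigree()].
#' @param rules a [rule_table()].
#' @param check validate the pedigree first (default TRUE; the assessment
#'   refuses invalid pedigrees).
#' @return an object of class `risk_assessment`: list with `category`,
#'   `rank`, `triggered_rules` (named by rule id, each the matching relative
#'   labels, sorted by rule id), `side_counts` (affected per family side),
#'   `recommendation`.
#' @export
#' @examples
#' assess_risk(pedigree(relative("mother", affected = TRUE, age_dx = 60)))
assess_risk <- function(ped, rules = rule_table(), check = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  .validate_rule_table(rules)
  if (check) {
    rep <- validate_pedigree(ped)
    if (!isTRUE(attr(rep, "pass"))) {
      stop("invalid pedigree: ", paste(rep$message, collapse = "; "),
           call. = FALSE)
    }
  }
  df <- ped$relatives
  side <- side_of(df$role)
  degree <- degree_of(df$role)
  gen <- generation_of(df$role)
  lab <- .rel_label(df$role, df$member_index)
  aff <- df$affected
  age <- df$age_dx

  side_counts <- vapply(family_sides(), function(s) sum(aff & side == s),
                        integer(1))

  fdr_aff <- aff & degree == "FDR"
  triggered <- list()

  # R2a: >=1 affected FDR diagnosed before the primary cutoff
  hit <- fdr_aff & !is.na(age) & age < rules$age_cutoff_primary
  if ("R2a" %in% rules$enabled && any(hit)) triggered$R2a <- lab[hit]
  # R2b: >=2 affected FDR, any ages, any sides
  if ("R2b" %in% rules$enabled && sum(fdr_aff) >= 2L) triggered$R2b <- lab[fdr_aff]

  # same-side clusters; your_side members count toward both parental sides
  for (s in c("mother_side", "father_side")) {
    in_side <- aff & (side == s | side == "your_side")
    n_side <- sum(in_side)
    early <- in_side & !is.na(age) & age < rules$age_cutoff_high
    if ("R3a" %in% rules$enabled &&
        n_side >= rules$amsterdam_min_relatives &&
        length(unique(gen[in_side])) >= rules$amsterdam_min_generations &&
        any(early)) {
      triggered$R3a <- sort(unique(c(triggered$R3a, lab[in_side])))
    }
    if ("R3b" %in% rules$enabled &&
        n_side >= rules$high_risk_cluster_min &&
        (any(early) || any(in_side & df$multiple_crc) ||
         any(in_side & df$other_cancers))) {
      triggered$R3b <- sort(unique(c(triggered$R3b, lab[in_side])))
    }
  }
  # R3c: polyposis signal on any relative, affected or not
  if ("R3c" %in% rules$enabled && any(df$multiple_polyps)) {
    triggered$R3c <- lab[df$multiple_polyps]
  }

  max_rank_so_far <- if (length(triggered))
    max(.rule_rank[names(triggered)]) else 0L
  # R1 is guarded: exactly one affected FDR at/after the primary cutoff, and
  # no higher-ranking rule fires
  if ("R1" %in% rules$enabled && max_rank_so_far < 2L && sum(fdr_aff) == 1L) {
    a <- age[fdr_aff]
    if (!is.na(a) && a >= rules$age_cutoff_primary) triggered$R1 <- lab[fdr_aff]
  }

  triggered <- triggered[order(match(names(triggered), .rule_ids))]
  rank <- if (length(triggered)) max(.rule_rank[names(triggered)]) else 0L
  category <- names(risk_categories())[match(rank, risk_categories())]

  structure(
    list(category = category, rank = as.integer(rank),
         triggered_rules = triggered, side_counts = side_counts,
         recommendation = recommendation_for(category, rules)),
    class = "risk_assessment")
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %s (rank %d)\n",
              .category_labels[[x$category]], x$rank))
  cat("affected per side:",
      paste(sprintf("%s=%d", names(x$side_counts), x$side_counts),
            collapse = ", "), "\n")
  if (length(x$triggered_rules)) {
    for (id in names(x$triggered_rules)) {
      cat(sprintf("  %s: %s\n", id,
                  paste(x$triggered_rules[[id]], collapse = ", ")))
    }
  } else cat("  no rules triggered\n")
  cat("recommendation:", x$recommendation, "\n")
  invisible(x)
}
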