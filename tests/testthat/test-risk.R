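test_that("single-relative histories map to the documented categories", {
  expect_identical(assess_risk(pedigree())$category, "average")
  expect_length(assess_risk(pedigree())$triggered_rules, 0L)

  a <- assess_risk(pedigree(relative("mother", affected = TRUE, age_dx = 60)))
  expect_identical(a$category, "slightly_increased")
  expect_identical(names(a$triggered_rules), "R1")

  a <- assess_risk(pedigree(relative("father", affected = TRUE, age_dx = 50)))
  expect_identical(a$category, "moderately_increased")
  expect_identical(names(a$triggered_rules), "R2a")

  a <- assess_risk(pedigree(
    relative("mother", affected = TRUE, age_dx = 52),
    relative("maternal_grandmother", affected = TRUE, age_dx = 49),
    relative("maternal_aunt_uncle", affected = TRUE, age_dx = 47)))
  expect_identical(a$category, "potentially_high")
  expect_true("R3a" %in% names(a$triggered_rules))

  a <- assess_risk(pedigree(
    relative("sibling", affected = TRUE, multiple_polyps = TRUE)))
  expect_identical(a$category, "potentially_high")
  expect_true("R3c" %in% names(a$triggered_rules))
})

test_that("age cutoffs are strict and unknown ages satisfy no age rule", {
  at_cutoff <- assess_risk(pedigree(relative("mother", affected = TRUE,
                                             age_dx = 55)))
  expect_identical(at_cutoff$category, "slightly_increased")  # 55 is not < 55
  unknown <- assess_risk(pedigree(relative("mother", affected = TRUE)))
  expect_identical(unknown$category, "average")
  # but unknown-age relatives still count toward count rules
  two <- assess_risk(pedigree(relative("mother", affected = TRUE),
                              relative("father", affected = TRUE)))
  expect_identical(two$category, "moderately_increased")
})

test_that("your-side relatives join both parental clusters", {
  a <- assess_risk(pedigree(
    relative("maternal_grandmother", affected = TRUE, age_dx = 72),
    relative("sibling", affected = TRUE, age_dx = 44)))
  expect_true("R3b" %in% names(a$triggered_rules))
  expect_identical(a$category, "potentially_high")
})

test_that("assessment matches the brute-force rule oracle on random pedigrees", {
  for (seed in 1:400) {
    ped <- random_pedigree(seed)
    expect_identical(assess_risk(ped)$category, oracle_assess(ped),
                     info = paste("seed", seed))
  }
})

test_that("adding an affected relative never lowers the category rank", {
  ranks <- risk_categories()
  group_roles <- c("maternal_aunt_uncle", "maternal_aunt_uncle_child",
                   "paternal_aunt_uncle", "paternal_aunt_uncle_child",
                   "sibling", "child")
  checked <- 0L
  for (seed in 1:120) {
    ped <- random_pedigree(seed)
    before <- ranks[[assess_risk(ped)$category]]
    set.seed(seed + 7000)
    role <- sample(group_roles, 1L)
    df <- ped$relatives
    idx <- if (role %in% df$role)
      max(df$member_index[df$role == role]) + 1L else 0L
    augmented <- pedigree(c(
      lapply(seq_len(nrow(df)), function(i)
        relative(df$role[i], df$member_index[i], df$affected[i], df$age_dx[i],
                 df$multiple_polyps[i], df$other_cancers[i],
                 df$multiple_crc[i])),
      list(relative(role, idx, affected = TRUE,
                    age_dx = sample(c(NA, 45L, 60L), 1L)))))
    if (!pedigree_valid(augmented)) next  # group cap reached
    after <- ranks[[assess_risk(augmented)$category]]
    expect_gte(after, before)
    checked <- checked + 1L
  }
  expect_gt(checked, 80L)
})

test_that("assessment is deterministic with rule trace sorted by rule id", {
  ped <- pedigree(
    relative("mother", affected = TRUE, age_dx = 45),
    relative("father", affected = TRUE, age_dx = 48,
             multiple_polyps = TRUE, other_cancers = TRUE),
    relative("sibling", affected = TRUE, age_dx = 40))
  a1 <- assess_risk(ped)
  a2 <- assess_risk(ped)
  expect_identical(a1, a2)
  ids <- names(a1$triggered_rules)
  expect_identical(ids, sort(ids))
  expect_identical(a1$rank, max(c(R1 = 1L, R2a = 2L, R2b = 2L, R3a = 3L,
                                  R3b = 3L, R3c = 3L)[ids]))
})

test_that("invalid pedigrees and malformed rule tables are refused", {
  bad <- pedigree(relative("mother", affected = TRUE, age_dx = 60),
                  relative("mother"))
  expect_error(assess_risk(bad), "invalid pedigree")
  expect_error(rule_table(age_cutoff_high = 60, age_cutoff_primary = 55),
               "age_cutoff_high")
  expect_error(rule_table(amsterdam_min_relatives = 0), ">= 1")
  expect_error(rule_table(enabled = c("R1", "R9")), "unknown rule id")
})

test_that("recommendation texts honour the configured contracts", {
  rules <- rule_table()
  for (cat in names(risk_categories())) {
    expect_true(nzchar(recommendation_for(cat, rules)))
  }
  expect_match(recommendation_for("potentially_high", rules), "referral",
               ignore.case = TRUE)
  expect_match(recommendation_for("average", rules), "surveillance",
               ignore.case = TRUE)
  expect_error(recommendation_for("extreme", rules), "unknown risk category")
  expect_error(rule_table(recommendations = list(average = "see your GP")),
               "missing text")
})

test_that("rule tables load from config files with defaults applied", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  rt <- load_rule_table(empty)
  expect_identical(rt$age_cutoff_primary, 55L)
  expect_identical(rt$age_cutoff_high, 50L)
  expect_identical(rt$amsterdam_min_relatives, 3L)
  expect_identical(rt$amsterdam_min_generations, 2L)
  expect_identical(rt$high_risk_cluster_min, 2L)

  override <- withr::local_tempfile(fileext = ".yaml")
  writeLines("age_cutoff_primary: 60", override)
  rt2 <- load_rule_table(override)
  expect_identical(rt2$age_cutoff_primary, 60L)
  expect_identical(rt2$age_cutoff_high, 50L)

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"age_cutoff_high": 60, "age_cutoff_primary": 55}', bad)
  expect_error(load_rule_table(bad), "age_cutoff_high")

  shipped <- system.file("extdata", "example_rules.yaml", package = "famrisk")
  expect_identical(load_rule_table(shipped)$age_cutoff_primary, 55L)
})

test_that("a relative's category can be changed by the rule configuration", {
  ped <- pedigree(relative("mother", affected = TRUE, age_dx = 57))
  expect_identical(assess_risk(ped)$category, "slightly_increased")
  relaxed <- rule_table(age_cutoff_primary = 60L)
  expect_identical(assess_risk(ped, relaxed)$category, "moderately_increased")
  no_r1 <- rule_table(enabled = setdiff(c("R1", "R2a", "R2b", "R3a", "R3b",
                                          "R3c"), "R1"))
  expect_identical(assess_risk(ped, no_r1)$category, "average")
})
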