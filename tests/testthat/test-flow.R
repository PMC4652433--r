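# scripted traversals used across the tests
all_negative <- function() c(rep(list(list(affected = FALSE)), 6L),
                             rep(list(list(count = 0L)), 4L),
                             list(list(confirm = TRUE)))

maximal <- function() {
  a <- list()
  for (i in 1:6) {
    a <- c(a, list(list(affected = TRUE), list(age_dx = 60L)))
  }
  for (g in 1:4) {
    a <- c(a, list(list(count = 7L)))
    for (j in 1:7) a <- c(a, list(list(age_dx = 50L, relation = "aunt_uncle")))
  }
  c(a, list(list(confirm = TRUE)))
}

test_that("the base sequence starts at the mother and ends at confirm", {
  st <- start_flow()
  expect_identical(current_page(st)$role, "mother")
  expect_identical(st$pages_presented, 1L)
  visited <- character(0)
  for (p in all_negative()) {
    visited <- c(visited, current_page(st)$page_id)
    st <- flow_answer(st, p)
  }
  expect_length(visited, 11L)
  expect_identical(visited[length(visited)], "confirm")
  expect_true(st$finished)
})

test_that("traversal page counts hit the documented bounds", {
  st <- play_flow(all_negative())
  expect_true(st$finished)
  expect_identical(st$pages_presented, 11L)
  expect_identical(nrow(flow_to_pedigree(st)$relatives), 0L)

  st_max <- play_flow(maximal())
  expect_identical(st_max$pages_presented, 45L)

  # only the mother affirmative: 11 base pages + 1 detail
  mother_only <- c(list(list(affected = TRUE), list(age_dx = 60L)),
                   rep(list(list(affected = FALSE)), 5L),
                   rep(list(list(count = 0L)), 4L),
                   list(list(confirm = TRUE)))
  st_m <- play_flow(mother_only)
  expect_identical(st_m$pages_presented, 12L)
  ped <- flow_to_pedigree(st_m)
  expect_identical(ped$relatives$role, "mother")
  expect_identical(ped$relatives$age_dx, 60L)
})

test_that("page counts stay within 11..45 for random answer streams", {
  for (seed in 1:60) {
    ped <- random_pedigree(seed)
    st <- play_flow(famrisk:::pedigree_to_answers(ped))
    expect_true(st$finished)
    expect_gte(st$pages_presented, 11L)
    expect_lte(st$pages_presented, 45L)
    # every affirmative answer reaches the pedigree: no answer loss
    expect_identical(nrow(flow_to_pedigree(st)$relatives),
                     nrow(ped$relatives))
  }
})

test_that("group counts spawn one detail page per member with side roles", {
  answers <- c(rep(list(list(affected = FALSE)), 6L),
               list(list(count = 2L),
                    list(age_dx = 47L, relation = "aunt_uncle"),
                    list(age_dx = 62L, relation = "child")),
               rep(list(list(count = 0L)), 3L),
               list(list(confirm = TRUE)))
  st <- play_flow(answers)
  expect_identical(st$pages_presented, 13L)
  ped <- flow_to_pedigree(st)
  expect_setequal(ped$relatives$role,
                  c("maternal_aunt_uncle", "maternal_aunt_uncle_child"))
  expect_setequal(ped$relatives$age_dx, c(47L, 62L))
  expect_true(all(side_of(ped$relatives$role) == "mother_side"))
})

test_that("invalid payloads raise errors and leave the state unchanged", {
  st <- start_flow()
  expect_error(flow_answer(st, list(count = 1L)), "yes/no")
  expect_identical(st$pages_presented, 1L)
  st <- flow_answer(st, list(affected = FALSE))  # now at 'father'
  for (i in 1:5) st <- flow_answer(st, list(affected = FALSE))
  expect_error(flow_answer(st, list(count = 8L)), "outside 0..7")
  expect_error(flow_answer(st, list(count = NA)), "integer")
  st <- flow_answer(st, list(count = 1L))
  expect_error(flow_answer(st, list(age_dx = 60L)), "relation")
  expect_error(flow_answer(st, list(age_dx = 200L, relation = "child")),
               "outside")
  st_done <- play_flow(all_negative())
  expect_error(flow_answer(st_done, list(confirm = TRUE)), "finished")
  st_unfinished <- start_flow()
  expect_error(flow_to_pedigree(st_unfinished), "incomplete flow")
})

test_that("restart clears the answers and keeps counting pages", {
  answers <- c(list(list(affected = TRUE), list(age_dx = 60L)),
               rep(list(list(affected = FALSE)), 5L),
               rep(list(list(count = 0L)), 4L))
  st <- play_flow(answers)          # at confirm, page 12
  expect_identical(st$pages_presented, 12L)
  st <- flow_answer(st, list(restart = TRUE))
  expect_identical(current_page(st)$role, "mother")
  expect_identical(st$pages_presented, 13L)
  for (p in all_negative()) st <- flow_answer(st, p)
  expect_true(st$finished)
  expect_identical(st$pages_presented, 23L)
  expect_identical(nrow(flow_to_pedigree(st)$relatives), 0L)
})

test_that("diagram intake equals the questionnaire flow, pedigree for pedigree", {
  for (seed in 1:40) {
    ped <- random_pedigree(seed)
    form <- famrisk:::pedigree_to_diagram_form(ped)
    from_form <- diagram_intake(form)
    st <- play_flow(famrisk:::pedigree_to_answers(ped))
    from_flow <- flow_to_pedigree(st)
    expect_same_pedigree(from_form, from_flow)
    expect_identical(render_summary(from_form)$text,
                     render_summary(from_flow)$text)
  }
})

test_that("diagram forms validate coverage, caps and reset semantics", {
  expect_identical(nrow(diagram_intake(diagram_form())$relatives), 0L)

  f <- diagram_form()
  f$father <- list(age_dx = 50L)
  ped <- diagram_intake(f)
  expect_identical(ped$relatives$role, "father")
  expect_identical(assess_risk(ped)$category, "moderately_increased")

  partial <- unclass(diagram_form())
  partial$siblings <- NULL
  partial$children <- NULL
  expect_error(diagram_intake(partial), "missing blocks: siblings, children")

  over <- diagram_form()
  over$siblings <- rep(list(list(age_dx = 50L)), 8L)
  expect_error(diagram_intake(over), "cap is 7")

  bad_rel <- diagram_form()
  bad_rel$mother_side_others <- list(list(age_dx = 50L))
  expect_error(diagram_intake(bad_rel), "relation")

  filled <- diagram_form()
  filled$mother <- list(age_dx = 60L)
  expect_error(reset_diagram_form(filled), "confirm")
  cleared <- reset_diagram_form(filled, confirm = TRUE)
  expect_identical(nrow(diagram_intake(cleared)$relatives), 0L)
})

test_that("the summary report is deterministic and reflects the assessment", {
  empty <- render_summary(pedigree())
  expect_match(empty$text, "average lifetime risk")
  expect_match(empty$text, "no affected relatives entered")
  expect_match(empty$text, "general practitioner")

  ped <- pedigree(relative("mother", affected = TRUE, age_dx = 60))
  rep1 <- render_summary(ped)
  expect_match(rep1$text, "- mother: bowel cancer diagnosed at age 60")
  expect_match(rep1$text, "slightly increased risk")
  expect_identical(rep1$text, render_summary(ped)$text)
})
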