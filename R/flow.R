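#' Sequential questionnaire flow
#'
#' The questionnaire intake presents one question per page under a large
#' family-side heading. The base traversal is fixed: six yes/no screening
#' pages for the named relatives (mother, father, four grandparents), four
#' count pages for the group roles (mother-side aunts/uncles and their
#' children pooled, father-side likewise, your siblings, your children), and
#' a terminal confirm page — eleven pages when every answer is negative.
#' Each affirmative screening answer and each counted group member enqueues
#' one detail page (age at diagnosis, multiple polyps, other Lynch-spectrum
#' cancers, multiple primary CRCs; group detail pages also ask whether the
#' member is an aunt/uncle or one of their children). With every group at
#' the cap of 7 the traversal reaches 11 + 6 + 4*7 = 45 pages. Shared
#' introduction pages are not counted: `pages_presented` counts pages to
#' fill in.
#'
#' @param rules a [rule_table()] used later by [render_summary()].
#' @param group_cap maximum members per group-count answer (default 7).
#' @return `start_flow()`: an object of class `flow_state`, positioned at
#'   the first page with `pages_presented = 1`.
#' @seealso [flow_answer()], [flow_to_pedigree()], [diagram_intake()]
#' @name questionnaire_flow
NULL

.page <- function(page_id, heading, kind, role = NA_character_,
                  group = NA_character_) {
  list(page_id = page_id, heading = heading, kind = kind, role = role,
       group = group)
}

# the four group-count pages; side groups pool aunts/uncles with their children
.group_pages <- data.frame(
  group = c("mother_side_others", "father_side_others", "siblings", "children"),
  heading = c("Mother's side of the family", "Father's side of the family",
              "Your side of the family", "Your side of the family"),
  prompt = c("How many of your mother's siblings or their children have had bowel cancer?",
             "How many of your father's siblings or their children have had bowel cancer?",
             "How many of your siblings have had bowel cancer?",
             "How many of your children have had bowel cancer?"),
  stringsAsFactors = FALSE
)
# fixed role for the non-side groups; side groups resolve the role on the
# detail page (aunt/uncle vs their child)
.group_fixed_role <- c(mother_side_others = NA, father_side_others = NA,
                       siblings = "sibling", children = "child")
.group_side_roles <- list(
  mother_side_others = c("maternal_aunt_uncle", "maternal_aunt_uncle_child"),
  father_side_others = c("paternal_aunt_uncle", "paternal_aunt_uncle_child")
)

.base_pages <- function() {
  named <- list(
    c("mother", "Mother's side of the family"),
    c("father", "Father's side of the family"),
    c("maternal_grandmother", "Mother's side of the family"),
    c("maternal_grandfather", "Mother's side of the family"),
    c("paternal_grandmother", "Father's side of the family"),
    c("paternal_grandfather", "Father's side of the family")
  )
  pages <- lapply(named, function(x) {
    .page(paste0("screen_", x[1]), x[2], "screen_named", role = x[1])
  })
  for (i in seq_len(nrow(.group_pages))) {
    pages[[length(pages) + 1L]] <- .page(
      paste0("count_", .group_pages$group[i]), .group_pages$heading[i],
      "group_count", group = .group_pages$group[i])
  }
  pages[[length(pages) + 1L]] <- .page("confirm", "Review your entries",
                                       "confirm")
  pages
}

#' @rdname questionnaire_flow
#' @export
start_flow <- function(rules = rule_table(), group_cap = 7L) {
  .validate_rule_table(rules)
  pages <- .base_pages()
  structure(
    list(current = pages[[1L]], queue = pages[-1L], answers = list(),
         relatives = .empty_relatives(), role_counter = integer(0),
         pages_presented = 1L, finished = FALSE, group_cap = as.integer(group_cap),
         rules = rules),
    class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> page %d%s\n", x$pages_presented,
              if (x$finished) " (finished)" else ""))
  if (!x$finished) {
    cat("heading:", x$current$heading, "\n")
    cat("page id:", x$current$page_id, "(", x$current$kind, ")\n")
  }
  invisible(x)
}

#' Current page of a questionnaire flow
#'
#' @param state a `flow_state`.
#' @return the current page spec (`page_id`, `heading`, `kind`, target).
#' @export
current_page <- function(state) {
  stopifnot(inherits(state, "flow_state"))
  state$current
}

.flow_error <- function(msg) stop("flow validation error: ", msg, call. = FALSE)

.next_index <- function(state, role) {
  idx <- state$role_counter[role]
  if (is.na(idx) || is.null(idx) || length(idx) == 0L) idx <- 0L
  idx
}

.detail_payload_row <- function(role, member_index, payload) {
  age <- payload$age_dx
  age <- if (is.null(age) || is.na(age)) NA_integer_ else as.integer(age)
  data.frame(
    role = role, member_index = as.integer(member_index), affected = TRUE,
    age_dx = age,
    multiple_polyps = isTRUE(payload$multiple_polyps),
    other_cancers = isTRUE(payload$other_cancers),
    multiple_crc = isTRUE(payload$multiple_crc),
    stringsAsFactors = FALSE
  )
}

#' Answer the current page of the questionnaire flow
#'
#' Validates the payload against the current page's fields and advances the
#' flow; an invalid payload raises an error and leaves the state unchanged.
#' Affirmative screening answers and group counts enqueue detail pages
#' immediately after the current page. On the confirm page,
#' `list(confirm = TRUE)` finishes the flow and `list(restart = TRUE)`
#' clears all answers and re-presents the first page (re-presented pages are
#' counted again).
#'
#' @param state a `flow_state` from [start_flow()].
#' @param payload named list matching the current page kind:
#'   `list(affected =)` for screening pages, `list(count =)` for group-count
#'   pages (0 to the cap), detail fields
#'   (`age_dx`, `multiple_polyps`, `other_cancers`, `multiple_crc`, and
#'   `relation` — `"aunt_uncle"` or `"child"` — on side-group detail pages),
#'   and `confirm`/`restart` on the confirm page.
#' @return the advanced `flow_state`.
#' @export
flow_answer <- function(state, payload) {
  stopifnot(inherits(state, "flow_state"))
  if (state$finished) .flow_error("flow already finished")
  if (!is.list(payload)) .flow_error("payload must be a named list")
  pg <- state$current
  queue <- state$queue
  switch(pg$kind,
    screen_named = {
      if (!is.logical(payload$affected) || length(payload$affected) != 1L ||
          is.na(payload$affected))
        .flow_error(sprintf("page '%s' needs a yes/no 'affected' answer",
                            pg$page_id))
      if (payload$affected) {
        queue <- c(list(.page(paste0("detail_", pg$role), pg$heading, "detail",
                               role = pg$role)), queue)
      }
    },
    group_count = {
      k <- payload$count
      if (is.null(k) || length(k) != 1L || is.na(k) || k != as.integer(k))
        .flow_error(sprintf("page '%s' needs an integer 'count'", pg$page_id))
      k <- as.integer(k)
      if (k < 0L || k > state$group_cap)
        .flow_error(sprintf("count %d outside 0..%d on page '%s'",
                            k, state$group_cap, pg$page_id))
      if (k > 0L) {
        fixed <- .group_fixed_role[[pg$group]]
        details <- lapply(seq_len(k), function(i) {
          .page(sprintf("detail_%s_%d", pg$group, i), pg$heading, "detail",
                role = if (is.na(fixed)) NA_character_ else fixed,
                group = pg$group)
        })
        queue <- c(details, queue)
      }
    },
    detail = {
      role <- pg$role
      if (is.na(role)) {
        rel <- payload$relation
        allowed <- c("aunt_uncle", "child")
        if (is.null(rel) || !rel %in% allowed)
          .flow_error(sprintf(
            "page '%s' needs 'relation' (aunt_uncle or child)", pg$page_id))
        role <- if (pg$group == "mother_side_others") {
          if (rel == "aunt_uncle") "maternal_aunt_uncle" else "maternal_aunt_uncle_child"
        } else {
          if (rel == "aunt_uncle") "paternal_aunt_uncle" else "paternal_aunt_uncle_child"
        }
      }
      if (!is.null(payload$age_dx) && !is.na(payload$age_dx) &&
          (payload$age_dx <= 0 || payload$age_dx > 120))
        .flow_error(sprintf("age at diagnosis %s outside (0, 120]",
                            payload$age_dx))
      idx <- if (.is_unique_role(role)) 0L else .next_index(state, role)
      state$relatives <- rbind(state$relatives,
                               .detail_payload_row(role, idx, payload))
      if (!.is_unique_role(role)) state$role_counter[role] <- idx + 1L
    },
    confirm = {
      if (isTRUE(payload$restart)) {
        pages <- .base_pages()
        state$current <- pages[[1L]]
        state$queue <- pages[-1L]
        state$answers <- list()
        state$relatives <- .empty_relatives()
        state$role_counter <- integer(0)
        state$pages_presented <- state$pages_presented + 1L
        state$answers <- list()
        return(state)
      }
      if (!isTRUE(payload$confirm))
        .flow_error("confirm page needs confirm = TRUE (or restart = TRUE)")
      state$finished <- TRUE
    },
    .flow_error(sprintf("unknown page kind '%s'", pg$kind))
  )
  state$queue <- queue
  state$answers[[length(state$answers) + 1L]] <-
    list(page_id = pg$page_id, payload = payload)
  if (!state$finished) {
    state$current <- state$queue[[1L]]
    state$queue <- state$queue[-1L]
    state$pages_presented <- state$pages_presented + 1L
  }
  state
}

#' Play a scripted traversal
#'
#' Applies a list of payloads in order, starting from [start_flow()].
#'
#' @param answers list of payloads, one per presented page.
#' @inheritParams start_flow
#' @return the final `flow_state`.
#' @export
play_flow <- function(answers, rules = rule_table(), group_cap = 7L) {
  state <- start_flow(rules, group_cap)
  for (p in answers) state <- flow_answer(state, p)
  state
}

#' Extract the pedigree entered through a finished flow
#'
#' @param state a finished `flow_state`.
#' @return a validated [pedigree()] containing exactly the relatives whose
#'   screening/count answers were affirmative, with detail fields copied.
#' @export
flow_to_pedigree <- function(state) {
  stopifnot(inherits(state, "flow_state"))
  if (!state$finished)
    stop("incomplete flow: the confirm page has not been submitted",
         call. = FALSE)
  .sort_pedigree(new_pedigree(state$relatives))
}

# canonical ordering: role-table order, then member_index
.sort_pedigree <- function(ped) {
  df <- ped$relatives
  if (nrow(df) > 1L) {
    df <- df[order(match(df$role, .role_table$role), df$member_index), ,
             drop = FALSE]
  }
  new_pedigree(df, ped$proband_note)
}

# scripted answers reproducing a pedigree of affected relatives (indices are
# reassigned sequentially per role, i.e. the result is the canonical form)
pedigree_to_answers <- function(ped) {
  df <- .sort_pedigree(ped)$relatives
  if (nrow(df) && !all(df$affected))
    stop("flow intake covers affected relatives only", call. = FALSE)
  detail_of <- function(i, relation = NULL) {
    p <- list(age_dx = df$age_dx[i], multiple_polyps = df$multiple_polyps[i],
              other_cancers = df$other_cancers[i],
              multiple_crc = df$multiple_crc[i])
    if (!is.null(relation)) p$relation <- relation
    p
  }
  answers <- list()
  for (role in c("mother", "father", "maternal_grandmother",
                 "maternal_grandfather", "paternal_grandmother",
                 "paternal_grandfather")) {
    i <- which(df$role == role)
    answers[[length(answers) + 1L]] <- list(affected = length(i) > 0L)
    if (length(i)) answers[[length(answers) + 1L]] <- detail_of(i)
  }
  for (g in .group_pages$group) {
    roles <- if (is.na(.group_fixed_role[[g]])) .group_side_roles[[g]]
             else .group_fixed_role[[g]]
    idx <- which(df$role %in% roles)
    answers[[length(answers) + 1L]] <- list(count = length(idx))
    for (i in idx) {
      relation <- if (is.na(.group_fixed_role[[g]])) {
        if (grepl("child$", df$role[i])) "child" else "aunt_uncle"
      } else NULL
      answers[[length(answers) + 1L]] <- detail_of(i, relation)
    }
  }
  answers[[length(answers) + 1L]] <- list(confirm = TRUE)
  answers
}
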