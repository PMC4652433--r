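#' Single-form diagram intake
#'
#' The diagram intake mirrors a paper family-history tree: every relative
#' slot is visible on one form and submitted in a single step, yielding
#' exactly the same pedigree (and byte-identical summary) as an equivalent
#' questionnaire traversal.
#'
#' A form is a named list covering all twelve role slots: one entry per
#' unique role (`mother`, `father`, the four grandparents — `NULL` when the
#' relative has not had bowel cancer, otherwise a detail list with `age_dx`
#' and the history flags) and four repeatable group blocks
#' (`mother_side_others`, `father_side_others`, `siblings`, `children`) each
#' holding a list of detail entries; entries in the side blocks carry a
#' `relation` of `"aunt_uncle"` or `"child"`.
#'
#' @return `diagram_form()`: an empty form (all slots present, nothing
#'   entered).
#' @seealso [diagram_intake()], [questionnaire_flow]
#' @export
#' @examples
#' f <- diagram_form()
#' f$mother <- list(age_dx = 60)
#' diagram_intake(f)
diagram_form <- function() {
  structure(
    list(mother = NULL, father = NULL,
         maternal_grandmother = NULL, maternal_grandfather = NULL,
         paternal_grandmother = NULL, paternal_grandfather = NULL,
         mother_side_others = list(), father_side_others = list(),
         siblings = list(), children = list()),
    class = "diagram_form")
}

#' Reset a diagram form
#'
#' Clears every entry, as the form's reset button does; a confirmation is
#' required before anything is discarded.
#'
#' @param form a `diagram_form`.
#' @param confirm must be `TRUE` to discard the entries.
#' @return an empty `diagram_form`.
#' @export
reset_diagram_form <- function(form, confirm = FALSE) {
  stopifnot(inherits(form, "diagram_form"))
  if (!isTRUE(confirm))
    stop("reset discards all entries; call with confirm = TRUE", call. = FALSE)
  diagram_form()
}

#' Build a pedigree from a completed diagram form
#'
#' @param form a `diagram_form` with all twelve role slots present; a form
#'   missing blocks raises a validation error naming them.
#' @param group_cap maximum entries per group block (default 7, pooled per
#'   block as in the questionnaire flow).
#' @return a validated [pedigree()], identical to
#'   [flow_to_pedigree()] of the equivalent questionnaire traversal.
#' @export
diagram_intake <- function(form, group_cap = 7L) {
  required <- names(diagram_form())
  if (!is.list(form)) stop("form must be a diagram_form list", call. = FALSE)
  missing <- setdiff(required, names(form))
  if (length(missing))
    stop("incomplete diagram form; missing blocks: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rows <- list()
  counter <- integer(0)
  push <- function(role, entry) {
    idx <- if (.is_unique_role(role)) 0L else {
      i <- counter[role]; if (is.na(i) || length(i) == 0L) i <- 0L
      counter[role] <<- i + 1L
      i
    }
    rows[[length(rows) + 1L]] <<- .detail_payload_row(role, idx, entry)
  }
  for (role in c("mother", "father", "maternal_grandmother",
                 "maternal_grandfather", "paternal_grandmother",
                 "paternal_grandfather")) {
    entry <- form[[role]]
    if (!is.null(entry)) {
      if (!is.list(entry))
        stop(sprintf("entry for '%s' must be a detail list", role),
             call. = FALSE)
      push(role, entry)
    }
  }
  for (g in c("mother_side_others", "father_side_others", "siblings",
              "children")) {
    block <- form[[g]]
    if (!is.list(block))
      stop(sprintf("block '%s' must be a list of entries", g), call. = FALSE)
    if (length(block) > group_cap)
      stop(sprintf("block '%s' has %d entries, cap is %d", g, length(block),
                   group_cap), call. = FALSE)
    for (entry in block) {
      role <- if (g == "siblings") "sibling"
        else if (g == "children") "child"
        else {
          rel <- entry$relation
          if (is.null(rel) || !rel %in% c("aunt_uncle", "child"))
            stop(sprintf(
              "entries in block '%s' need relation 'aunt_uncle' or 'child'", g),
              call. = FALSE)
          side <- if (g == "mother_side_others") "maternal" else "paternal"
          paste0(side, "_aunt_uncle", if (rel == "child") "_child" else "")
        }
      push(role, entry)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else .empty_relatives()
  ped <- .sort_pedigree(new_pedigree(df))
  rep <- validate_pedigree(ped, group_cap = group_cap)
  if (!isTRUE(attr(rep, "pass")))
    stop("diagram form produced an invalid pedigree: ",
         paste(rep$message, collapse = "; "), call. = FALSE)
  ped
}

# inverse of diagram_intake for a pedigree of affected relatives
pedigree_to_diagram_form <- function(ped) {
  df <- .sort_pedigree(ped)$relatives
  if (nrow(df) && !all(df$affected))
    stop("diagram intake covers affected relatives only", call. = FALSE)
  form <- diagram_form()
  for (i in seq_len(nrow(df))) {
    role <- df$role[i]
    entry <- list(age_dx = df$age_dx[i],
                  multiple_polyps = df$multiple_polyps[i],
                  other_cancers = df$other_cancers[i],
                  multiple_crc = df$multiple_crc[i])
    if (.is_unique_role(role)) {
      form[[role]] <- entry
    } else if (role == "sibling") {
      form$siblings <- c(form$siblings, list(entry))
    } else if (role == "child") {
      form$children <- c(form$children, list(entry))
    } else {
      entry$relation <- if (grepl("child$", role)) "child" else "aunt_uncle"
      block <- if (grepl("^maternal", role)) "mother_side_others"
               else "father_side_others"
      form[[block]] <- c(form[[block]], list(entry))
    }
  }
  form
}

#' Render the summary report
#'
#' The deterministic end-of-assessment report: one line per entered
#' relative, the calculated risk category, the configured recommendation and
#' a general-practitioner advice line. Equal pedigrees render byte-identical
#' reports regardless of the intake mode that produced them.
#'
#' @param ped a validated [pedigree()].
#' @param rules a [rule_table()].
#' @return an object of class `summary_report` with `lines` (character),
#'   `text` (single string) and the underlying `assessment`.
#' @export
render_summary <- function(ped, rules = rule_table()) {
  ped <- .sort_pedigree(ped)
  assessment <- assess_risk(ped, rules)
  df <- ped$relatives
  entry_lines <- if (nrow(df) == 0L) {
    "- no affected relatives entered"
  } else {
    vapply(seq_len(nrow(df)), function(i) {
      parts <- character(0)
      if (df$affected[i]) {
        parts <- c(parts, if (is.na(df$age_dx[i])) "bowel cancer, age unknown"
                   else sprintf("bowel cancer diagnosed at age %d", df$age_dx[i]))
      }
      if (df$multiple_polyps[i]) parts <- c(parts, "multiple polyps")
      if (df$other_cancers[i]) parts <- c(parts, "other related cancers")
      if (df$multiple_crc[i]) parts <- c(parts, "multiple primary bowel cancers")
      sprintf("- %s: %s", .rel_label(df$role[i], df$member_index[i]),
              paste(parts, collapse = "; "))
    }, character(1))
  }
  lines <- c(
    "Family history summary",
    "======================",
    entry_lines,
    "",
    sprintf("Risk category: %s", .category_labels[[assessment$category]]),
    sprintf("Recommendation: %s", assessment$recommendation),
    "Please discuss this result with your general practitioner."
  )
  structure(list(lines = lines, text = paste(lines, collapse = "\n"),
                 assessment = assessment),
            class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' @export
format.summary_report <- function(x, ...) x$text
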