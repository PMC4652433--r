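#' Construct a relative record
#'
#' A relative couples a role with a cancer history: whether the relative was
#' affected by colorectal cancer, the age at diagnosis (years) when known, and
#' three boolean signals the guideline uses — multiple colorectal polyps
#' (polyposis signal), other Lynch-spectrum cancers, and multiple primary
#' CRCs. The family side and degree class are derived from the role, never
#' stored independently, so they cannot disagree with it.
#'
#' The polyp / other-cancer / multiple-CRC flags may be set on an unaffected
#' relative (a personal-history-only entry, e.g. a polyposis carrier without
#' CRC); an age at diagnosis, however, requires `affected = TRUE`.
#'
#' @param role one of [relative_roles()].
#' @param member_index non-negative integer distinguishing members of a group
#'   role (aunts/uncles, their children, siblings, children); must be 0 for
#'   the six unique roles.
#' @param affected was the relative diagnosed with colorectal cancer?
#' @param age_dx integer age at diagnosis in years, or `NA` if unknown.
#' @param multiple_polyps,other_cancers,multiple_crc history flags.
#' @return an object of class `relative` (a one-row record).
#' @export
#' @examples
#' relative("mother", affected = TRUE, age_dx = 60)
relative <- function(role, member_index = 0L, affected = FALSE, age_dx = NA,
                     multiple_polyps = FALSE, other_cancers = FALSE,
                     multiple_crc = FALSE) {
  .match_role(role)
  structure(
    list(
      role = role,
      member_index = as.integer(member_index),
      affected = isTRUE(affected),
      age_dx = if (is.na(age_dx)) NA_integer_ else as.integer(age_dx),
      multiple_polyps = isTRUE(multiple_polyps),
      other_cancers = isTRUE(other_cancers),
      multiple_crc = isTRUE(multiple_crc)
    ),
    class = "relative"
  )
}

# empty relatives table (internal canonical representation)
.empty_relatives <- function() {
  data.frame(
    role = character(0), member_index = integer(0), affected = logical(0),
    age_dx = integer(0), multiple_polyps = logical(0),
    other_cancers = logical(0), multiple_crc = logical(0),
    stringsAsFactors = FALSE
  )
}

# fast internal constructor: df must already have the canonical columns
new_pedigree <- function(relatives, proband_note = "") {
  rownames(relatives) <- NULL
  structure(list(relatives = relatives, proband_note = proband_note),
            class = "pedigree")
}

#' Construct a pedigree
#'
#' A pedigree is the unit of risk assessment: a collection of blood relatives
#' of the proband (see [roles]) with their colorectal-cancer histories, plus a
#' free-text note about the proband (which the risk engine does not score).
#'
#' @param ... [relative()] records (or a single list of them).
#' @param proband_note free text about the proband; excluded from scoring.
#' @return an object of class `pedigree`.
#' @seealso [validate_pedigree()], [assess_risk()], [read_pedigree()]
#' @export
#' @examples
#' ped <- pedigree(
#'   relative("mother", affected = TRUE, age_dx = 60),
#'   relative("maternal_grandfather", affected = TRUE, age_dx = 70)
#' )
#' count_affected(ped, side = "mother_side")
pedigree <- function(..., proband_note = "") {
  rels <- list(...)
  if (length(rels) == 1L && !inherits(rels[[1L]], "relative") &&
      is.list(rels[[1L]])) {
    rels <- rels[[1L]]
  }
  if (length(rels) == 0L) return(new_pedigree(.empty_relatives(), proband_note))
  ok <- vapply(rels, inherits, logical(1), what = "relative")
  if (!all(ok)) stop("all entries must be created with relative()", call. = FALSE)
  df <- do.call(rbind, lapply(rels, function(r) {
    data.frame(
      role = r$role, member_index = r$member_index, affected = r$affected,
      age_dx = r$age_dx, multiple_polyps = r$multiple_polyps,
      other_cancers = r$other_cancers, multiple_crc = r$multiple_crc,
      stringsAsFactors = FALSE
    )
  }))
  new_pedigree(df, proband_note)
}

#' @export
print.pedigree <- function(x, ...) {
  n <- nrow(x$relatives)
  cat(sprintf("<pedigree> %d relative%s, %d affected\n",
              n, if (n == 1L) "" else "s", sum(x$relatives$affected)))
  if (n > 0L) {
    df <- x$relatives
    df$side <- side_of(df$role)
    df$degree <- degree_of(df$role)
    print(df, row.names = FALSE)
  }
  if (nzchar(x$proband_note)) cat("proband note:", x$proband_note, "\n")
  invisible(x)
}

#' Validate a pedigree
#'
#' Checks structural invariants and returns the violations as data, never as
#' an error condition: at most one relative per unique role; unique
#' (role, member_index) pairs; member_index 0 for unique roles; an age at
#' diagnosis only on affected relatives and within (0, 120]; pooled group
#' sizes within the cap (each parental side pools aunts/uncles with their
#' children; siblings and children are capped separately).
#'
#' @param ped a [pedigree()].
#' @param group_cap maximum members per pooled group role (default 7).
#' @return a data.frame of violations (columns `rule`, `message`) with
#'   attribute `pass`; zero rows means the pedigree is valid. The input is
#'   never modified.
#' @export
#' @examples
#' validate_pedigree(pedigree())  # passes
validate_pedigree <- function(ped, group_cap = 7L) {
  stopifnot(inherits(ped, "pedigree"))
  df <- ped$relatives
  v <- list()
  add <- function(rule, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, message = message,
                                       stringsAsFactors = FALSE)
  }
  if (nrow(df) > 0L) {
    uniq <- df$role[.is_unique_role(df$role)]
    dup <- unique(uniq[duplicated(uniq)])
    for (r in dup) add("duplicate_unique_role",
                       sprintf("duplicate unique role '%s'", r))
    key <- paste(df$role, df$member_index)
    dupk <- unique(key[duplicated(key)])
    for (k in dupk) add("duplicate_member",
                        sprintf("duplicate (role, member_index) pair '%s'", k))
    bad_idx <- .is_unique_role(df$role) & df$member_index != 0L
    for (i in which(bad_idx)) add("unique_role_index",
      sprintf("unique role '%s' must have member_index 0", df$role[i]))
    neg <- df$member_index < 0L
    for (i in which(neg)) add("negative_index",
      sprintf("negative member_index for role '%s'", df$role[i]))
    age_no_aff <- !is.na(df$age_dx) & !df$affected
    for (i in which(age_no_aff)) add("age_without_affected",
      sprintf("%s has age_at_diagnosis %d but affected is FALSE",
              df$role[i], df$age_dx[i]))
    age_bad <- !is.na(df$age_dx) & (df$age_dx <= 0L | df$age_dx > 120L)
    for (i in which(age_bad)) add("age_out_of_range",
      sprintf("%s age_at_diagnosis %d outside (0, 120]", df$role[i], df$age_dx[i]))
    gk <- .group_key_of(df$role)
    tab <- table(gk[!is.na(gk)])
    for (g in names(tab)[tab > group_cap]) add("group_cap_exceeded",
      sprintf("group '%s' has %d members, cap is %d", g, tab[[g]], group_cap))
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(rule = character(0), message = character(0),
               stringsAsFactors = FALSE)
  attr(out, "pass") <- nrow(out) == 0L
  out
}

#' Is a pedigree valid?
#'
#' @inheritParams validate_pedigree
#' @return `TRUE` iff [validate_pedigree()] reports no violations.
#' @export
pedigree_valid <- function(ped, group_cap = 7L) {
  isTRUE(attr(validate_pedigree(ped, group_cap), "pass"))
}

#' Count affected relatives
#'
#' Counts relatives with `affected = TRUE`, optionally restricted by family
#' side, degree class, age at diagnosis and history flags. Filters compose
#' conjunctively; relatives with an unknown age never satisfy an age filter.
#'
#' @param ped a validated [pedigree()].
#' @param side `"all"` or one of [family_sides()].
#' @param degree `"all"`, `"FDR"` or `"SDR"`.
#' @param age_below count only relatives diagnosed strictly before this age.
#' @param age_at_least count only relatives diagnosed at or after this age.
#' @param flag optionally one of `"multiple_polyps"`, `"other_cancers"`,
#'   `"multiple_crc"`: count only relatives with that flag set.
#' @return integer count.
#' @export
count_affected <- function(ped, side = "all", degree = "all",
                           age_below = NULL, age_at_least = NULL, flag = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  df <- ped$relatives
  if (nrow(df) == 0L) return(0L)
  keep <- df$affected
  if (!identical(side, "all")) {
    side <- match.arg(side, family_sides())
    keep <- keep & side_of(df$role) == side
  }
  if (!identical(degree, "all")) {
    degree <- match.arg(degree, c("FDR", "SDR"))
    keep <- keep & degree_of(df$role) == degree
  }
  if (!is.null(age_below)) keep <- keep & !is.na(df$age_dx) & df$age_dx < age_below
  if (!is.null(age_at_least)) keep <- keep & !is.na(df$age_dx) & df$age_dx >= age_at_least
  if (!is.null(flag)) {
    flag <- match.arg(flag, c("multiple_polyps", "other_cancers", "multiple_crc"))
    keep <- keep & df[[flag]]
  }
  sum(keep)
}
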