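#' Relative roles, family sides and degree classes
#'
#' The assessment recognises twelve blood-relative roles around the proband.
#' Six are unique per pedigree (mother, father, the four grandparents); the
#' other six are group roles that may hold several members, distinguished by
#' `member_index`. Every role belongs to exactly one of three family sides
#' (mother's side, father's side, "your side" = the proband's siblings and
#' children) and to exactly one degree class: first-degree relatives (FDR:
#' mother, father, siblings, children) or second-degree relatives (SDR: all
#' others, including aunts/uncles and their children — the guideline pools
#' the latter, sometimes loosely called nieces and nephews, with the SDRs of
#' the corresponding parental side).
#'
#' @name roles
NULL

# Role metadata. generation is the offset from the proband's generation:
# grandparents 2, parents and aunts/uncles 1, proband generation 0, children -1.
.role_table <- data.frame(
  role = c(
    "mother", "father",
    "maternal_grandmother", "maternal_grandfather",
    "paternal_grandmother", "paternal_grandfather",
    "maternal_aunt_uncle", "maternal_aunt_uncle_child",
    "paternal_aunt_uncle", "paternal_aunt_uncle_child",
    "sibling", "child"
  ),
  side = c(
    "mother_side", "father_side",
    "mother_side", "mother_side",
    "father_side", "father_side",
    "mother_side", "mother_side",
    "father_side", "father_side",
    "your_side", "your_side"
  ),
  degree = c(
    "FDR", "FDR",
    "SDR", "SDR", "SDR", "SDR",
    "SDR", "SDR", "SDR", "SDR",
    "FDR", "FDR"
  ),
  generation = c(1L, 1L, 2L, 2L, 2L, 2L, 1L, 0L, 1L, 0L, 0L, -1L),
  unique_role = c(rep(TRUE, 6L), rep(FALSE, 6L)),
  # group roles are capped per pooled group: each parental side pools the
  # aunt/uncle role with their children; siblings and children stand alone
  group_key = c(
    NA, NA, NA, NA, NA, NA,
    "maternal_group", "maternal_group",
    "paternal_group", "paternal_group",
    "sibling", "child"
  ),
  stringsAsFactors = FALSE
)

.match_role <- function(role) {
  i <- match(role, .role_table$role)
  if (anyNA(i)) {
    bad <- unique(role[is.na(i)])
    stop("invalid relative role: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  i
}

#' @describeIn roles The twelve recognised relative roles, in canonical order.
#' @return `relative_roles()`: character vector of length 12.
#' @export
#' @examples
#' relative_roles()
#' side_of("maternal_grandmother")
#' degree_of(c("mother", "maternal_aunt_uncle"))
relative_roles <- function() .role_table$role

#' @describeIn roles The three family sides.
#' @export
family_sides <- function() c("mother_side", "father_side", "your_side")

#' @describeIn roles Map a role to its family side (vectorised; errors on an
#'   unknown role).
#' @param role character vector of roles (see `relative_roles()`).
#' @export
side_of <- function(role) .role_table$side[.match_role(role)]

#' @describeIn roles Map a role to its degree class, `"FDR"` or `"SDR"`.
#' @export
degree_of <- function(role) .role_table$degree[.match_role(role)]

#' @describeIn roles Generation offset from the proband: grandparents 2,
#'   parents and aunts/uncles 1, the proband's own generation (siblings and
#'   aunt/uncle children) 0, children -1. Used by the generation-spanning
#'   cluster rule of the risk engine.
#' @export
generation_of <- function(role) .role_table$generation[.match_role(role)]

.is_unique_role <- function(role) .role_table$unique_role[.match_role(role)]
.group_key_of <- function(role) .role_table$group_key[.match_role(role)]
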