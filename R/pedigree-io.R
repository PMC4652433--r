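#' Read and write pedigrees
#'
#' Two plain-text serialisations are supported:
#'
#' * `"json"` — a versioned schema (shipped at
#'   `system.file("extdata", "pedigree-schema.json", package = "famrisk")`)
#'   with a `relatives` array of role/history records and a `proband_note`.
#' * `"tabular"` — a PED-inspired tab-separated dialect with header row
#'   `role member_index affected age_dx multiple_polyps other_cancers
#'   multiple_crc`; booleans written as 0/1, unknown age as `.`, 0-based
#'   member_index, UTF-8, LF line endings. The layout is superficially
#'   PED-like only; no PLINK semantics are implied.
#'
#' `write_pedigree(read_pedigree(x))` reproduces `x` byte-for-byte for any
#' valid tabular file written by this package, and `read_pedigree` of a
#' written JSON file reproduces the pedigree object.
#'
#' @param path file path (or, for `read_pedigree`, a character vector of
#'   lines via `text =`).
#' @param format `"json"` or `"tabular"`; `read_pedigree` guesses from the
#'   file extension when missing (`.json` vs anything else).
#' @param ped a [pedigree()].
#' @param text optional character vector of lines to parse instead of `path`.
#' @return `read_pedigree`: a `pedigree`. `write_pedigree`: the serialised
#'   form, invisibly (a JSON string or a character vector of lines); written
#'   to `path` when `path` is given.
#' @name pedigree_io
NULL

.tab_header <- c("role", "member_index", "affected", "age_dx",
                 "multiple_polyps", "other_cancers", "multiple_crc")

.parse_error <- function(line, col, msg) {
  stop(sprintf("pedigree parse error at line %d, column %d: %s", line, col, msg),
       call. = FALSE)
}

.parse_tabular <- function(lines) {
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) .parse_error(1L, 1L, "empty input")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr, .tab_header)) {
    .parse_error(1L, 1L, paste0("expected header '",
                                paste(.tab_header, collapse = "\\t"), "'"))
  }
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    ln <- i + 1L
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 7L) .parse_error(ln, length(f) + 1L,
                                      sprintf("expected 7 fields, got %d", length(f)))
    if (!f[1L] %in% .role_table$role) .parse_error(ln, 1L,
      sprintf("invalid relative role '%s'", f[1L]))
    idx <- suppressWarnings(as.integer(f[2L]))
    if (is.na(idx)) .parse_error(ln, 2L, sprintf("bad member_index '%s'", f[2L]))
    bools <- f[c(3L, 5L, 6L, 7L)]
    badb <- which(!bools %in% c("0", "1"))
    if (length(badb)) .parse_error(ln, c(3L, 5L, 6L, 7L)[badb[1L]],
      sprintf("boolean field must be 0 or 1, got '%s'", bools[badb[1L]]))
    if (f[4L] == ".") {
      age <- NA_integer_
    } else {
      age <- suppressWarnings(as.integer(f[4L]))
      if (is.na(age)) .parse_error(ln, 4L, sprintf("bad age_dx '%s'", f[4L]))
    }
    rows[[i]] <- data.frame(
      role = f[1L], member_index = idx, affected = f[3L] == "1", age_dx = age,
      multiple_polyps = f[5L] == "1", other_cancers = f[6L] == "1",
      multiple_crc = f[7L] == "1", stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows)) do.call(rbind, rows) else .empty_relatives()
  new_pedigree(df)
}

.format_tabular <- function(ped) {
  df <- ped$relatives
  b <- function(x) as.character(as.integer(x))
  body <- if (nrow(df)) {
    paste(df$role, df$member_index, b(df$affected),
          ifelse(is.na(df$age_dx), ".", as.character(df$age_dx)),
          b(df$multiple_polyps), b(df$other_cancers), b(df$multiple_crc),
          sep = "\t")
  } else character(0)
  c(paste(.tab_header, collapse = "\t"), body)
}

.pedigree_to_list <- function(ped) {
  df <- ped$relatives
  list(
    schema_version = "1.0",
    proband_note = ped$proband_note,
    relatives = lapply(seq_len(nrow(df)), function(i) {
      list(
        role = df$role[i], member_index = df$member_index[i],
        affected = df$affected[i],
        age_dx = if (is.na(df$age_dx[i])) NULL else df$age_dx[i],
        multiple_polyps = df$multiple_polyps[i],
        other_cancers = df$other_cancers[i],
        multiple_crc = df$multiple_crc[i]
      )
    })
  )
}

.pedigree_from_list <- function(x) {
  rels <- x$relatives
  if (is.null(rels) || length(rels) == 0L) {
    return(new_pedigree(.empty_relatives(),
                        proband_note = x$proband_note %||% ""))
  }
  rows <- lapply(seq_along(rels), function(i) {
    r <- rels[[i]]
    if (is.null(r$role) || !r$role %in% .role_table$role) {
      stop(sprintf("invalid relative role in JSON relatives[%d]: '%s'",
                   i, r$role %||% "<missing>"), call. = FALSE)
    }
    data.frame(
      role = r$role,
      member_index = as.integer(r$member_index %||% 0L),
      affected = isTRUE(r$affected),
      age_dx = if (is.null(r$age_dx) || is.na(r$age_dx)) NA_integer_
               else as.integer(r$age_dx),
      multiple_polyps = isTRUE(r$multiple_polyps),
      other_cancers = isTRUE(r$other_cancers),
      multiple_crc = isTRUE(r$multiple_crc),
      stringsAsFactors = FALSE
    )
  })
  new_pedigree(do.call(rbind, rows), proband_note = x$proband_note %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname pedigree_io
#' @export
read_pedigree <- function(path = NULL, format = NULL, text = NULL) {
  if (is.null(format)) {
    format <- if (!is.null(path) &&
                  tolower(tools::file_ext(path)) == "json") "json" else "tabular"
  }
  format <- match.arg(format, c("json", "tabular"))
  if (format == "json") {
    src <- if (!is.null(text)) paste(text, collapse = "\n") else path
    x <- jsonlite::fromJSON(src, simplifyVector = FALSE)
    .pedigree_from_list(x)
  } else {
    lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
    .parse_tabular(lines)
  }
}

#' @rdname pedigree_io
#' @export
write_pedigree <- function(ped, path = NULL, format = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(format)) {
    format <- if (!is.null(path) &&
                  tolower(tools::file_ext(path)) == "json") "json" else "tabular"
  }
  format <- match.arg(format, c("json", "tabular"))
  out <- if (format == "json") {
    jsonlite::toJSON(.pedigree_to_list(ped), auto_unbox = TRUE, pretty = TRUE,
                     null = "null")
  } else {
    .format_tabular(ped)
  }
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(as.character(out), con, sep = "\n", useBytes = TRUE)
  }
  invisible(out)
}
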