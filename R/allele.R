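#' Parse an HLA allele name
#'
#' Parses a colon-delimited HLA allele designation of the form
#' \code{LOCUS*F1(:F2(:F3(:F4)))(suffix)}, e.g. \code{"DRB1*14:54"} or
#' \code{"A*24:02:01:02L"}.  Fields are kept as written (leading zeros
#' preserved) but compared numerically.  Serology-era names and G/P group
#' designations are not accepted.
#'
#' @param text character scalar, the allele designation.
#' @return An object of class \code{hla_allele}: a list with components
#'   \code{locus}, \code{fields} (character vector as written),
#'   \code{values} (integer field values), \code{suffix} (one of
#'   N, L, S, C, A, Q, or \code{NA}), and \code{raw} (the input text).
#' @examples
#' a <- parse_allele_name("A*24:02:01:02L")
#' a$locus
#' allele_resolution(a)
#' @export
parse_allele_name <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("allele name must be a single character string", call. = FALSE)
  m <- regexec("^([A-Z][A-Za-z0-9]*)\\*(\\d+(?::\\d+){0,3})([NLSCAQ]?)$",
               text)
  g <- regmatches(text, m)[[1]]
  if (length(g) == 0L) {
    # locate the first offending character for the error message
    ok <- regexpr("^[A-Z][A-Za-z0-9]*\\*?(\\d+:?)*[NLSCAQ]?", text)
    pos <- attr(ok, "match.length") + 1L
    stop(sprintf("malformed allele name '%s' (unexpected token at position %d)",
                 text, pos), call. = FALSE)
  }
  fields <- strsplit(g[3], ":", fixed = TRUE)[[1]]
  structure(list(locus = g[2],
                 fields = fields,
                 values = as.integer(fields),
                 suffix = if (nzchar(g[4])) g[4] else NA_character_,
                 raw = text),
            class = "hla_allele")
}

#' Serialize an allele name
#'
#' Reconstructs the text form of a parsed allele; round-trips the original
#' text exactly.
#'
#' @param a an \code{hla_allele}.
#' @return character scalar.
#' @export
format_allele <- function(a) {
  stopifnot(inherits(a, "hla_allele"))
  paste0(a$locus, "*", paste(a$fields, collapse = ":"),
         if (!is.na(a$suffix)) a$suffix else "")
}

#' @export
format.hla_allele <- function(x, ...) format_allele(x)

#' @export
print.hla_allele <- function(x, ...) {
  cat(format_allele(x), "\n")
  invisible(x)
}

#' Resolution level of an allele name
#'
#' The number of colon-separated fields: 1 = allele group (formerly
#' "2-digit"), 2 = protein (formerly "4-digit"), 3-4 = synonymous /
#' non-coding variation.
#'
#' @param a an \code{hla_allele} or allele string.
#' @return integer in 1..4.
#' @export
allele_resolution <- function(a) {
  a <- as_allele(a)
  length(a$fields)
}

as_allele <- function(a) {
  if (inherits(a, "hla_allele")) a else parse_allele_name(a)
}

#' Reduce an allele name to a lower resolution
#'
#' Truncates the field list to \code{level} fields (identity when the name is
#' already at or below that resolution).  The expression suffix cannot be
#' carried by a truncated name: dropping it is reported via a warning, and a
#' null-expression (N) allele merged into an expressed allele group gets a
#' dedicated warning because the merge changes what the name asserts about
#' expression.
#'
#' @param a allele (\code{hla_allele} or string).
#' @param level target number of fields, >= 1.
#' @return an \code{hla_allele} at resolution \code{min(level, resolution(a))}.
#' @examples
#' format_allele(reduce_resolution("DQB1*02:02", 2))
#' @export
reduce_resolution <- function(a, level) {
  a <- as_allele(a)
  level <- as.integer(level)
  if (is.na(level) || level < 1L)
    stop("level must be an integer >= 1", call. = FALSE)
  if (level >= length(a$fields)) return(a)
  fields <- a$fields[seq_len(level)]
  if (!is.na(a$suffix)) {
    if (a$suffix == "N") {
      warning(sprintf(
        "null allele %s merged into expressed allele group %s*%s",
        a$raw, a$locus, paste(fields, collapse = ":")), call. = FALSE)
    } else {
      warning(sprintf("expression suffix '%s' of %s lost by truncation",
                      a$suffix, a$raw), call. = FALSE)
    }
  }
  out <- paste0(a$locus, "*", paste(fields, collapse = ":"))
  parse_allele_name(out)
}

# canonical sort key: locus, then numeric fields padded, then suffix; used for
# unordered-pair canonicalization and deterministic output ordering
allele_sort_key <- function(text) {
  vapply(text, function(t) {
    a <- as_allele(t)
    vals <- sprintf("%05d", a$values)
    paste(a$locus, paste(vals, collapse = ":"),
          if (is.na(a$suffix)) "" else a$suffix, sep = "|")
  }, character(1), USE.NAMES = FALSE)
}

# numeric-field equality (02 == 2) without losing the written form
allele_equal <- function(x, y) {
  a <- as_allele(x); b <- as_allele(y)
  identical(a$locus, b$locus) &&
    identical(a$values, b$values) &&
    identical(is.na(a$suffix), is.na(b$suffix)) &&
    (is.na(a$suffix) || a$suffix == b$suffix)
}
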