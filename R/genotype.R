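#' Ambiguous genotypes
#'
#' A typing result consistent with more than one allele pair is stored as the
#' full list of candidate pairs required to explain it.  Candidates are
#' unordered pairs in canonical order (sorted by locus, then numeric field
#' sequence, then expression suffix), so \{a,b\} and \{b,a\} are the same
#' candidate; homozygotes are written with the allele duplicated
#' (\code{"A*01:01+A*01:01"}), never as a single allele.
#'
#' @param id individual identifier.
#' @param loci character vector of locus symbols covered by each candidate.
#' @param candidates list of candidates; each candidate is a list with one
#'   unordered pair (character vector of length 2) per locus, in \code{loci}
#'   order.
#' @param source how the ambiguity arose: one of \code{"pair_list"},
#'   \code{"code_expansion"}, \code{"kit_interpretation"},
#'   \code{"unambiguous"}.
#' @return an object of class \code{hla_genotype}.
#' @export
hla_genotype <- function(id, loci, candidates,
                         source = c("pair_list", "code_expansion",
                                    "kit_interpretation", "unambiguous")) {
  source <- match.arg(source)
  if (length(candidates) == 0L)
    stop("candidate set must be non-empty", call. = FALSE)
  candidates <- lapply(candidates, function(cand) {
    if (!is.list(cand)) cand <- list(cand)
    if (length(cand) != length(loci))
      stop("candidate does not cover the locus set", call. = FALSE)
    lapply(cand, canonical_pair)
  })
  candidates <- unique(candidates)
  if (length(candidates) == 1L && source == "pair_list")
    source <- "unambiguous"
  structure(list(id = id, loci = loci, candidates = candidates,
                 source = source),
            class = "hla_genotype")
}

# canonical unordered pair: checks both alleles parse and share the locus
canonical_pair <- function(pair) {
  if (length(pair) != 2L)
    stop("a genotype needs exactly two alleles (write homozygotes as a+a)",
         call. = FALSE)
  a <- as_allele(pair[1]); b <- as_allele(pair[2])
  if (a$locus != b$locus)
    stop(sprintf("mixed loci inside one pair: %s + %s", pair[1], pair[2]),
         call. = FALSE)
  unname(pair[order(allele_sort_key(pair))])
}

#' @export
print.hla_genotype <- function(x, ...) {
  cat(x$id, ": ", serialize_genotype(x), "  [", x$source, "]\n", sep = "")
  invisible(x)
}

n_candidates <- function(g) length(g$candidates)

#' Parse a genotype-list string
#'
#' The genotype-list (GL) dialect: \code{'/'} separates allele-level
#' ambiguity, \code{'+'} the two alleles of a genotype, \code{'|'}
#' alternative whole-genotype explanations, \code{'^'} loci.  The candidate
#' set is the cross-product expansion of the \code{'/'} lists within each
#' \code{'+'} pair, unioned over \code{'|'} alternatives, de-duplicated.
#' Note \code{"a1+b1|a2+b2"} yields exactly those two pairs, not the
#' four-pair cross-product: the \code{'|'} form states the pair list
#' explicitly.
#'
#' @param text the GL string.
#' @param id individual identifier to attach.
#' @param source source tag, see \code{\link{hla_genotype}}.
#' @return an \code{hla_genotype}.
#' @examples
#' g <- parse_genotype_string("A*01:01/A*01:02+A*02:01")
#' length(g$candidates)
#' @export
parse_genotype_string <- function(text, id = "ind", source = "pair_list") {
  stopifnot(is.character(text), length(text) == 1L)
  split_checked <- function(x, delim, what) {
    parts <- strsplit(x, delim, fixed = TRUE)[[1]]
    if (length(parts) == 0L || any(!nzchar(trimws(parts))) ||
        endsWith(x, delim) || startsWith(x, delim))
      stop("empty ", what, " in: ", x, call. = FALSE)
    parts
  }
  locus_blocks <- split_checked(text, "^", "locus block")
  per_locus <- lapply(locus_blocks, function(block) {
    alts <- split_checked(block, "|", "genotype alternative")
    pairs <- unlist(lapply(alts, function(alt) {
      sides <- strsplit(alt, "+", fixed = TRUE)[[1]]
      sides <- trimws(sides)
      if (length(sides) != 2L || any(!nzchar(sides)))
        stop("a genotype must have exactly two '+'-separated sides: ", alt,
             call. = FALSE)
      lists <- lapply(sides, function(side)
        trimws(split_checked(side, "/", "allele in ambiguity list")))
      # cross product of the two '/' lists
      apply(expand.grid(lists[[1]], lists[[2]],
                        stringsAsFactors = FALSE), 1L,
            function(p) canonical_pair(p), simplify = FALSE)
    }), recursive = FALSE)
    unique(pairs)
  })
  loci <- vapply(per_locus, function(p) as_allele(p[[1]][1])$locus,
                 character(1))
  if (anyDuplicated(loci))
    stop("duplicate locus across '^' blocks", call. = FALSE)
  # candidates: cross product over loci of the per-locus pair lists
  cand_idx <- expand.grid(lapply(per_locus, seq_along))
  candidates <- apply(cand_idx, 1L, function(row)
    lapply(seq_along(per_locus), function(l) per_locus[[l]][[row[l]]]),
    simplify = FALSE)
  hla_genotype(id, loci, candidates, source = source)
}

#' Serialize an ambiguous genotype
#'
#' \code{"pair_list"} style writes the recommended explicit list of
#' \code{'|'}-separated allele pairs.  \code{"factored"} style writes the
#' compact \code{'/'}+\code{'+'} factoring only when it is lossless (its
#' expansion equals the candidate set exactly); otherwise it falls back to
#' the pair list, because factoring would introduce spurious pairs.
#'
#' @param g an \code{hla_genotype}.
#' @param style \code{"pair_list"} (default) or \code{"factored"}.
#' @return the GL string.
#' @export
serialize_genotype <- function(g, style = c("pair_list", "factored")) {
  style <- match.arg(style)
  stopifnot(inherits(g, "hla_genotype"))
  per_locus_text <- vapply(seq_along(g$loci), function(l) {
    pairs <- unique(lapply(g$candidates, `[[`, l))
    if (style == "factored") {
      left <- sort(unique(vapply(pairs, `[`, character(1), 1L)))
      right <- sort(unique(vapply(pairs, `[`, character(1), 2L)))
      expansion <- unique(apply(
        expand.grid(left, right, stringsAsFactors = FALSE), 1L,
        canonical_pair, simplify = FALSE))
      if (setequal_pairs(expansion, pairs))
        return(paste(paste(left, collapse = "/"),
                     paste(right, collapse = "/"), sep = "+"))
    }
    paste(vapply(pairs, paste, character(1), collapse = "+"),
          collapse = "|")
  }, character(1))
  paste(per_locus_text, collapse = "^")
}

setequal_pairs <- function(x, y) {
  kx <- sort(vapply(x, paste, character(1), collapse = "+"))
  ky <- sort(vapply(y, paste, character(1), collapse = "+"))
  identical(kx, ky)
}

#' Read an NMDP-style multiple-allele-code table
#'
#' Two tab-separated columns: code, comma-separated second-field values the
#' code abbreviates.  \code{'#'} lines are comments.
#'
#' @param path file path.
#' @return named list code -> character vector of field values.
#' @export
read_mac_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("MAC table must have two tab-separated columns", call. = FALSE)
  codes <- vapply(parts, `[`, character(1), 1L)
  vals <- lapply(parts, function(p)
    trimws(strsplit(p[2], ",", fixed = TRUE)[[1]]))
  if (any(lengths(vals) == 0L))
    stop("MAC code with empty expansion", call. = FALSE)
  stats::setNames(vals, codes)
}

#' Expand NMDP-style abbreviation codes in a typing
#'
#' A typing such as \code{"A*01:XX+A*02:01"} with \code{XX -> \{01,02\}} is
#' expanded by replacing each coded allele by its allele list and taking the
#' full cross-product of the two sides.  This is exactly the artificial
#' inflation of the pair list that makes abbreviation codes undesirable for
#' population data; it is reproduced faithfully so it can be measured with
#' \code{\link{count_spurious_pairs}}.
#'
#' @param text a single-locus typing \code{"side1+side2"}, where each side is
#'   an allele name whose last field may be a code from \code{table}.
#' @param table a MAC table (named list code -> field values).
#' @param id individual identifier.
#' @return an \code{hla_genotype} with \code{source = "code_expansion"}.
#' @export
expand_mac <- function(text, table, id = "ind") {
  sides <- trimws(strsplit(text, "+", fixed = TRUE)[[1]])
  if (length(sides) != 2L)
    stop("typing must have exactly two '+'-separated sides", call. = FALSE)
  expand_side <- function(side) {
    m <- regexec("^([A-Z][A-Za-z0-9]*)\\*((?:\\d+:)*)([A-Z]{2,})$", side)
    g <- regmatches(side, m)[[1]]
    if (length(g) == 0L) {  # no code: a plain allele name
      parse_allele_name(side)
      return(side)
    }
    code <- g[4]
    if (is.null(table[[code]]))
      stop(sprintf("unknown abbreviation code '%s' in '%s'", code, side),
           call. = FALSE)
    paste0(g[2], "*", g[3], table[[code]])
  }
  lists <- lapply(sides, expand_side)
  pairs <- unique(apply(expand.grid(lists[[1]], lists[[2]],
                                    stringsAsFactors = FALSE), 1L,
                        canonical_pair, simplify = FALSE))
  loci <- as_allele(pairs[[1]][1])$locus
  hla_genotype(id, loci, lapply(pairs, list), source = "code_expansion")
}

#' Spurious pairs introduced by code expansion
#'
#' The number of candidate pairs the code expansion adds beyond the true
#' reported pair list: \code{|expanded| - |reported|}.  The reported set must
#' be contained in the expansion.
#'
#' @param reported the genotype as the laboratory's true pair list.
#' @param expanded the genotype obtained by expanding abbreviation codes.
#' @return non-negative integer.
#' @export
count_spurious_pairs <- function(reported, expanded) {
  stopifnot(inherits(reported, "hla_genotype"),
            inherits(expanded, "hla_genotype"))
  rk <- candidate_keys(reported)
  ek <- candidate_keys(expanded)
  if (!all(rk %in% ek))
    stop("reported pair list is not contained in the code expansion",
         call. = FALSE)
  length(ek) - length(rk)
}

candidate_keys <- function(g) {
  vapply(g$candidates, function(cand)
    paste(vapply(cand, paste, character(1), collapse = "+"),
          collapse = "^"), character(1))
}
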