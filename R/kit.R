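#' Typing-kit descriptions
#'
#' A kit description defines what a typing technology can distinguish: a
#' probe panel where each probe reacts with a known set of alleles, plus the
#' allele universe the kit can in principle report.  Reverse SSO typing
#' reports, for each individual, which probes reacted; interpreting that
#' pattern against the kit yields an ambiguous genotype in most cases.
#'
#' @param kit_id kit identifier.
#' @param locus locus symbol.
#' @param probes named list: probe id -> character vector of reactive
#'   alleles.
#' @param allele_universe alleles the kit can report; defaults to the union
#'   of the probes' reactive sets.
#' @return an object of class \code{hla_kit}.
#' @export
hla_kit <- function(kit_id, locus, probes, allele_universe = NULL) {
  stopifnot(is.list(probes), length(probes) >= 1L, !is.null(names(probes)))
  if (anyDuplicated(names(probes)))
    stop("probe ids must be unique", call. = FALSE)
  if (is.null(allele_universe))
    allele_universe <- sort(unique(unlist(probes)))
  extra <- setdiff(unlist(probes), allele_universe)
  if (length(extra))
    stop("reactive alleles outside the allele universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  structure(list(kit_id = kit_id, locus = locus, probes = probes,
                 allele_universe = allele_universe),
            class = "hla_kit")
}

#' @export
print.hla_kit <- function(x, ...) {
  cat(sprintf("Typing kit %s (locus %s): %d probes over %d alleles\n",
              x$kit_id, x$locus, length(x$probes),
              length(x$allele_universe)))
  invisible(x)
}

#' Read / write a kit description file
#'
#' TSV with columns \code{probe_id<TAB>comma-separated allele names}; a
#' \code{'#'} comment header carries \code{kit_id} and \code{locus} as
#' \code{# key: value} lines.
#'
#' @param path file path.
#' @param kit an \code{hla_kit} (for writing).
#' @return \code{read_kit}: an \code{hla_kit}.
#' @export
read_kit <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0("^#\\s*", key, ":\\s*(.*)$"), hdr))
    hit <- Filter(length, m)
    if (!length(hit)) stop("kit file missing '# ", key, ":' header",
                           call. = FALSE)
    trimws(hit[[1]][2])
  }
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("kit file rows must be probe_id<TAB>alleles", call. = FALSE)
  probes <- stats::setNames(
    lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]])),
    vapply(parts, `[`, character(1), 1L))
  hla_kit(get_field("kit_id"), get_field("locus"), probes)
}

#' @rdname read_kit
#' @export
write_kit <- function(kit, path) {
  writeLines(c(paste0("# kit_id: ", kit$kit_id),
               paste0("# locus: ", kit$locus),
               vapply(names(kit$probes), function(p)
                 paste0(p, "\t", paste(kit$probes[[p]], collapse = ",")),
                 character(1))), path)
  invisible(path)
}

#' Forward model: probe pattern of a genotype
#'
#' A probe is positive iff it reacts with at least one of the two alleles
#' (dominant-positive union rule, no probe noise).
#'
#' @param pair unordered allele pair (character vector of length 2).
#' @param kit an \code{hla_kit}; both alleles must be in its universe.
#' @return named logical vector over the kit's probes.
#' @export
predict_pattern <- function(pair, kit) {
  pair <- canonical_pair(pair)
  out <- setdiff(pair, kit$allele_universe)
  if (length(out))
    stop("allele(s) outside kit universe: ", paste(out, collapse = ", "),
         call. = FALSE)
  vapply(kit$probes, function(reactive) any(pair %in% reactive), logical(1))
}

# pattern of every unordered pair over the kit universe, memoized per kit
# via an environment keyed on kit_id + universe hash
kit_pattern_table <- local({
  cache <- new.env(parent = emptyenv())
  function(kit) {
    key <- paste(kit$kit_id, length(kit$allele_universe),
                 paste(names(kit$probes), collapse = ","),
                 digest_chr(unlist(kit$probes)), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    u <- kit$allele_universe
    k <- length(u)
    # allele x probe incidence, then pair pattern = OR of the two rows
    inc <- vapply(kit$probes, function(r) u %in% r,
                  logical(k))  # k x n_probes
    if (k == 1L) inc <- matrix(inc, nrow = 1L,
                               dimnames = list(NULL, names(kit$probes)))
    pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
    pat <- inc[pairs[, 1L], , drop = FALSE] | inc[pairs[, 2L], , drop = FALSE]
    res <- list(universe = u, i = pairs[, 1L], j = pairs[, 2L],
                patterns = pat)
    cache[[key]] <- res
    res
  }
})

digest_chr <- function(x) paste(nchar(paste(x, collapse = "")),
                                sum(utf8ToInt(paste(x, collapse = ""))))

#' Interpret a probe-reactivity pattern
#'
#' Returns the ambiguous genotype implied by a reactivity pattern: all
#' unordered allele pairs over the kit universe (homozygotes included) whose
#' predicted pattern equals the observed one.  When no pair explains the
#' pattern, the error carries the nearest achievable patterns (minimum
#' Hamming distance) as a diagnostic.
#'
#' @param pattern named logical (or 0/1) vector over the kit's probe ids.
#' @param kit an \code{hla_kit}.
#' @param id individual id for the resulting genotype.
#' @return an \code{hla_genotype} with \code{source = "kit_interpretation"}.
#' @export
interpret_pattern <- function(pattern, kit, id = "ind") {
  if (is.numeric(pattern)) pattern <- pattern > 0
  if (!setequal(names(pattern), names(kit$probes)))
    stop("pattern must cover exactly the kit's probe ids", call. = FALSE)
  pattern <- pattern[names(kit$probes)]
  tab <- kit_pattern_table(kit)
  hits <- which(colSums(t(tab$patterns) != pattern) == 0L)
  if (!length(hits)) {
    d <- rowSums(tab$patterns != matrix(pattern, nrow(tab$patterns),
                                        length(pattern), byrow = TRUE))
    near <- unique(apply(tab$patterns[d == min(d), , drop = FALSE], 1L,
                         function(p) paste0(names(kit$probes)[p],
                                            collapse = ",")))
    stop(sprintf(paste0("uninterpretable pattern: no allele pair produces ",
                        "it; nearest achievable patterns (Hamming %d): %s"),
                 min(d), paste(near, collapse = " | ")), call. = FALSE)
  }
  cands <- lapply(hits, function(h)
    list(canonical_pair(c(tab$universe[tab$i[h]], tab$universe[tab$j[h]]))))
  hla_genotype(id, kit$locus, cands, source = "kit_interpretation")
}

#' Read a reactivity file
#'
#' CSV, one row per individual: column \code{id} plus one 0/1 column per
#' probe id.
#'
#' @param path file path.
#' @param kit the kit whose probes the columns must cover.
#' @return named list of logical pattern vectors, one per individual.
#' @export
read_reactivity <- function(path, kit) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df))
    stop("reactivity file needs an 'id' column", call. = FALSE)
  probes <- setdiff(names(df), "id")
  if (!setequal(probes, names(kit$probes)))
    stop("reactivity columns must match the kit's probe ids", call. = FALSE)
  stats::setNames(lapply(seq_len(nrow(df)), function(r)
    stats::setNames(as.logical(as.numeric(df[r, probes])), probes)),
    df$id)
}
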