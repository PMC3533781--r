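#' Population sample with questionnaire metadata
#'
#' A population sample bundles the ambiguous genotypes of its individuals
#' with the population-data questionnaire metadata that reporting guidelines
#' require (study type, population name, geographic coordinates, language,
#' relatives policy, typing technique, ethics statement).
#'
#' @param genotypes list of \code{\link{hla_genotype}} objects sharing a
#'   locus set, with unique individual ids.
#' @param metadata an \code{hla_metadata} (see
#'   \code{\link{questionnaire_metadata}}); optional.
#' @return an object of class \code{hla_sample}.
#' @export
hla_sample <- function(genotypes, metadata = questionnaire_metadata()) {
  stopifnot(is.list(genotypes), length(genotypes) > 0L)
  loci <- genotypes[[1]]$loci
  for (g in genotypes)
    if (!identical(g$loci, loci))
      stop("all genotypes must share the locus set", call. = FALSE)
  ids <- vapply(genotypes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(genotypes = genotypes, loci = loci, metadata = metadata),
            class = "hla_sample")
}

#' @export
print.hla_sample <- function(x, ...) {
  amb <- mean(vapply(x$genotypes, n_candidates, integer(1)) > 1L)
  cat(sprintf("HLA population sample: %d individuals, locus %s, %.0f%% ambiguous\n",
              length(x$genotypes), paste(x$loci, collapse = "^"), 100 * amb))
  if (nzchar(x$metadata$population_name))
    cat("  population:", x$metadata$population_name, "\n")
  invisible(x)
}

#' Population-data questionnaire metadata
#'
#' Fields follow the population data questionnaire used for standardized HLA
#' population reporting: type of study, population name and alternatives,
#' geographic coordinates, language and linguistic family, whether
#' first-degree relatives were excluded, an ethics statement, and the typing
#' technique.
#'
#' @param study_type one of \code{"anthropology_field"}, \code{"registry"},
#'   \code{"patients"}.
#' @param population_name,alternative_names population naming.
#' @param latitude,longitude decimal degrees.
#' @param language,linguistic_family language spoken by the population.
#' @param first_degree_relatives_excluded logical.
#' @param ethics_statement free text.
#' @param typing_technique free text (e.g. "SSO", "SBT").
#' @param n_individuals declared sample size; checked against the genotypes
#'   by \code{\link{validate_sample}}.
#' @return an object of class \code{hla_metadata}.
#' @export
questionnaire_metadata <- function(study_type = c("anthropology_field",
                                                  "registry", "patients"),
                                   population_name = "",
                                   alternative_names = character(),
                                   latitude = NA_real_, longitude = NA_real_,
                                   language = "", linguistic_family = "",
                                   first_degree_relatives_excluded = NA,
                                   ethics_statement = "",
                                   typing_technique = "",
                                   n_individuals = NA_integer_) {
  study_type <- match.arg(study_type)
  if (!is.na(latitude) && abs(latitude) > 90)
    stop("latitude out of [-90, 90]", call. = FALSE)
  if (!is.na(longitude) && abs(longitude) > 180)
    stop("longitude out of [-180, 180]", call. = FALSE)
  structure(list(study_type = study_type,
                 population_name = population_name,
                 alternative_names = alternative_names,
                 latitude = latitude, longitude = longitude,
                 language = language, linguistic_family = linguistic_family,
                 first_degree_relatives_excluded =
                   first_degree_relatives_excluded,
                 ethics_statement = ethics_statement,
                 typing_technique = typing_technique,
                 n_individuals = as.integer(n_individuals)),
            class = "hla_metadata")
}

#' Validate a population sample
#'
#' Checks the formal requirements on genotype data before analysis: every
#' candidate set non-empty and consistent with the locus set, ids unique,
#' allele names parsable, no unexpanded abbreviation codes when the strict
#' pair-list policy applies, and metadata consistency (declared sample size,
#' coordinate ranges, relatives policy stated).
#'
#' @param s an \code{hla_sample}.
#' @param strict_pair_list flag typings whose source is
#'   \code{"code_expansion"} as violations (abbreviation codes should be
#'   avoided in favour of explicit pair lists).
#' @param strict error (instead of reporting) when violations are found.
#' @return an object of class \code{hla_validation}: list with
#'   \code{violations} (character vector) and \code{ok} (logical).
#' @export
validate_sample <- function(s, strict_pair_list = FALSE, strict = FALSE) {
  v <- character()
  if (!inherits(s, "hla_sample")) stop("not an hla_sample", call. = FALSE)
  ids <- vapply(s$genotypes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    v <- c(v, paste0("duplicate individual id: ",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (g in s$genotypes) {
    if (length(g$candidates) == 0L)
      v <- c(v, paste0(g$id, ": empty candidate set"))
    if (!identical(g$loci, s$loci))
      v <- c(v, paste0(g$id, ": locus set mismatch"))
    if (strict_pair_list && g$source == "code_expansion")
      v <- c(v, paste0(g$id, ": NMDP code present (pair list required)"))
    for (cand in g$candidates) for (pair in cand) for (al in pair) {
      ok <- tryCatch({ parse_allele_name(al); TRUE },
                     error = function(e) FALSE)
      if (!ok) v <- c(v, paste0(g$id, ": unparsable allele '", al, "'"))
    }
  }
  md <- s$metadata
  if (!is.na(md$n_individuals) &&
      md$n_individuals != length(s$genotypes))
    v <- c(v, sprintf("metadata declares %d individuals but sample has %d",
                      md$n_individuals, length(s$genotypes)))
  if (is.na(md$first_degree_relatives_excluded))
    v <- c(v, "metadata does not state whether first-degree relatives were excluded")
  out <- structure(list(violations = v, ok = length(v) == 0L),
                   class = "hla_validation")
  if (strict && !out$ok)
    stop("sample validation failed:\n  ",
         paste(v, collapse = "\n  "), call. = FALSE)
  out
}

#' @export
print.hla_validation <- function(x, ...) {
  if (x$ok) cat("Sample valid: no violations.\n")
  else cat("Violations:\n", paste0("  - ", x$violations, collapse = "\n"),
           "\n", sep = "")
  invisible(x)
}

#' Read and write samples in the tabular and GL-string dialects
#'
#' Tabular dialect: CSV/TSV with header \code{id,locus,genotype}, one row per
#' individual per locus, genotype in GL syntax without \code{'^'}.  GL-string
#' dialect: one line per individual, \code{id<TAB>glstring} with \code{'^'}
#' between loci.  Candidate sets are preserved exactly across a round-trip.
#'
#' @param path file path.
#' @param sep field separator for the tabular dialect (\code{","} or
#'   \code{"\t"}; inferred from the file for reading).
#' @param metadata metadata to attach on read.
#' @param s sample to write.
#' @param style serialization style, see \code{\link{serialize_genotype}}.
#' @return readers return an \code{hla_sample}; writers return the number of
#'   individuals written, invisibly.
#' @export
read_sample_tabular <- function(path, metadata = questionnaire_metadata()) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  need <- c("id", "locus", "genotype")
  if (!all(need %in% names(df)))
    stop("tabular dialect needs columns id, locus, genotype", call. = FALSE)
  rows_by_id <- split(seq_len(nrow(df)), factor(df$id, levels = unique(df$id)))
  genotypes <- lapply(names(rows_by_id), function(id) {
    rows <- rows_by_id[[id]]
    per_locus <- lapply(rows, function(r) {
      g <- tryCatch(parse_genotype_string(df$genotype[r], id = id),
                    error = function(e)
                      stop(sprintf("row %d: %s", r, conditionMessage(e)),
                           call. = FALSE))
      if (!identical(g$loci, df$locus[r]))
        stop(sprintf("row %d: genotype locus %s does not match column '%s'",
                     r, g$loci, df$locus[r]), call. = FALSE)
      g
    })
    merge_locus_genotypes(per_locus, id)
  })
  hla_sample(genotypes, metadata)
}

# combine per-locus single-locus genotypes of one individual into one
# multi-locus genotype (cross-product of candidates, unphased)
merge_locus_genotypes <- function(gs, id) {
  if (length(gs) == 1L) return(gs[[1]])
  loci <- vapply(gs, `[[`, character(1), "loci")
  idx <- expand.grid(lapply(gs, function(g) seq_along(g$candidates)))
  candidates <- apply(idx, 1L, function(row)
    unlist(lapply(seq_along(gs), function(l)
      gs[[l]]$candidates[[row[l]]]), recursive = FALSE),
    simplify = FALSE)
  src <- if (all(vapply(gs, `[[`, character(1), "source") == "unambiguous"))
    "unambiguous" else "pair_list"
  hla_genotype(id, loci, candidates, source = src)
}

#' @rdname read_sample_tabular
#' @export
write_sample_tabular <- function(s, path, sep = ",",
                                 style = "pair_list") {
  rows <- unlist(lapply(s$genotypes, function(g)
    vapply(seq_along(g$loci), function(l) {
      sub <- hla_genotype(g$id, g$loci[l],
                          lapply(unique(lapply(g$candidates, `[[`, l)), list),
                          source = g$source)
      paste(g$id, g$loci[l], serialize_genotype(sub, style), sep = sep)
    }, character(1))))
  writeLines(c(paste("id", "locus", "genotype", sep = sep), rows), path)
  invisible(length(s$genotypes))
}

#' @rdname read_sample_tabular
#' @export
read_sample_glstring <- function(path, metadata = questionnaire_metadata()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  genotypes <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("row %d: expected id<TAB>glstring", i), call. = FALSE)
    tryCatch(parse_genotype_string(parts[2], id = parts[1]),
             error = function(e)
               stop(sprintf("row %d: %s", i, conditionMessage(e)),
                    call. = FALSE))
  })
  hla_sample(genotypes, metadata)
}

#' @rdname read_sample_tabular
#' @export
write_sample_glstring <- function(s, path, style = "pair_list") {
  writeLines(vapply(s$genotypes, function(g)
    paste(g$id, serialize_genotype(g, style), sep = "\t"),
    character(1)), path)
  invisible(length(s$genotypes))
}

#' Convert a sample file between dialects
#'
#' Loss-free conversion between the tabular (\code{id,locus,genotype}
#' CSV/TSV) and GL-string (\code{id<TAB>glstring}) dialects: candidate sets
#' are identical after a round-trip.
#'
#' @param path_in,path_out input and output paths.
#' @param dialect_in,dialect_out \code{"tabular"} or \code{"glstring"}.
#' @return number of individuals written, invisibly.
#' @export
convert_format <- function(path_in, dialect_in, path_out, dialect_out) {
  dialect_in <- match.arg(dialect_in, c("tabular", "glstring"))
  dialect_out <- match.arg(dialect_out, c("tabular", "glstring"))
  s <- switch(dialect_in,
              tabular = read_sample_tabular(path_in),
              glstring = read_sample_glstring(path_in))
  n <- switch(dialect_out,
              tabular = write_sample_tabular(s, path_out),
              glstring = write_sample_glstring(s, path_out))
  invisible(n)
}
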