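#' Allele recoding maps (transliteration)
#'
#' An allele mapping is a named character vector: names are source allele
#' texts, values are target allele texts.  Applied to a sample it must be
#' total (every allele occurring in the data has an image) and idempotent
#' after one application (every image maps to itself).
#'
#' @param entries named character vector, source -> target.
#' @param description free-text provenance of the recoding.
#' @return an object of class \code{hla_mapping}.
#' @export
allele_mapping <- function(entries, description = "") {
  stopifnot(is.character(entries), !is.null(names(entries)))
  if (anyDuplicated(names(entries)))
    stop("duplicate source alleles in mapping", call. = FALSE)
  # close the map: images not listed as sources map to themselves
  missing_img <- setdiff(unique(unname(entries)), names(entries))
  if (length(missing_img))
    entries <- c(entries, stats::setNames(missing_img, missing_img))
  bad <- names(entries)[entries[entries] != entries]
  if (length(bad))
    stop("mapping not idempotent for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(entries = entries, description = description),
            class = "hla_mapping")
}

#' @export
print.hla_mapping <- function(x, ...) {
  cat("Allele mapping (", length(x$entries), " entries)",
      if (nzchar(x$description)) paste0(": ", x$description), "\n", sep = "")
  invisible(x)
}

#' Read / write an allele mapping as two-column TSV
#'
#' Format: two tab-separated columns (source, target); lines starting with
#' \code{#} are comments.
#'
#' @param path file path.
#' @param m an \code{hla_mapping} (for writing).
#' @return \code{read_mapping}: an \code{hla_mapping};
#'   \code{write_mapping}: the path, invisibly.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("mapping file must have exactly two tab-separated columns",
         call. = FALSE)
  src <- vapply(parts, `[`, character(1), 1L)
  tgt <- vapply(parts, `[`, character(1), 2L)
  allele_mapping(stats::setNames(tgt, src), description = path)
}

#' @rdname read_mapping
#' @export
write_mapping <- function(m, path) {
  stopifnot(inherits(m, "hla_mapping"))
  writeLines(c(paste0("# ", m$description),
               paste(names(m$entries), m$entries, sep = "\t")), path)
  invisible(path)
}

#' First-field recoding map for a set of alleles
#'
#' Convenience constructor for the common "recode protein-level alleles into
#' allele-group-level" transliteration: every allele maps to its name
#' truncated to \code{level} fields.
#'
#' @param alleles character vector of allele names.
#' @param level target resolution (default 1).
#' @return an \code{hla_mapping}.
#' @export
resolution_mapping <- function(alleles, level = 1L) {
  alleles <- unique(alleles)
  tgt <- vapply(alleles, function(t)
    format_allele(suppressWarnings(reduce_resolution(t, level))),
    character(1))
  allele_mapping(stats::setNames(tgt, alleles),
                 description = sprintf("truncation to %d field(s)", level))
}

apply_mapping <- function(m, alleles) {
  img <- m$entries[alleles]
  if (anyNA(img)) {
    miss <- unique(alleles[is.na(img)])
    stop("alleles without mapping entry: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unname(img)
}

#' Recode every allele of a sample through a mapping
#'
#' Substitutes each allele occurrence (including inside ambiguity sets) by
#' its image under \code{m}; candidate pairs made identical by merging are
#' de-duplicated.  The number of individuals is unchanged and no candidate
#' set can become empty.
#'
#' @param s an \code{hla_sample}.
#' @param m an \code{hla_mapping}, total on the alleles of \code{s}.
#' @return the recoded \code{hla_sample}.
#' @export
transliterate_sample <- function(s, m) {
  stopifnot(inherits(s, "hla_sample"), inherits(m, "hla_mapping"))
  s$genotypes <- lapply(s$genotypes, function(g) {
    g$candidates <- unique(lapply(g$candidates, function(cand)
      lapply(cand, function(pair) canonical_pair(apply_mapping(m, pair)))))
    g
  })
  s
}

#' Common allele pool across heterogeneous samples
#'
#' Distinct samples typed with distinct techniques do not distinguish the
#' same alleles.  This computes the finest partition of the union of observed
#' alleles such that no sample's reporting separates two alleles that it
#' cannot actually tell apart: any two alleles that co-occur in one reported
#' name's group (one allele name being a truncation-prefix of another) or
#' inside one ambiguity set are merged, transitively (union-find).  Each pool
#' class is named by the longest common field prefix of its members.
#'
#' @param samples list of two or more \code{hla_sample} objects at the same
#'   locus.
#' @return an \code{hla_mapping} sending every observed allele to its pool
#'   class name.
#' @export
build_common_pool <- function(samples) {
  if (length(samples) < 2L) stop(">= 2 samples required", call. = FALSE)
  loci <- unique(unlist(lapply(samples, `[[`, "loci")))
  if (length(loci) != 1L)
    stop("samples typed at different loci: ", paste(loci, collapse = ", "),
         call. = FALSE)
  alleles <- sort(unique(unlist(lapply(samples, sample_alleles))))
  idx <- seq_along(alleles)
  parent <- idx
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  parsed <- lapply(alleles, as_allele)
  # merge name-prefix groups: a reported low-resolution name covers every
  # higher-resolution allele sharing its field prefix
  for (i in idx) for (j in idx) if (i < j) {
    ai <- parsed[[i]]; aj <- parsed[[j]]
    ni <- length(ai$values); nj <- length(aj$values)
    npre <- min(ni, nj)
    if (identical(ai$values[seq_len(npre)], aj$values[seq_len(npre)]) &&
        ni != nj)
      union2(i, j)
  }
  # merge within-sample indistinguishability: when a typing leaves several
  # candidate pairs, the alleles that vary across the alternatives (union
  # minus the alleles common to every candidate) were not separated by it
  for (s in samples) for (g in s$genotypes) {
    if (length(g$candidates) < 2L) next
    per_cand <- lapply(g$candidates, function(cand) unique(unlist(cand)))
    common <- Reduce(intersect, per_cand)
    varying <- setdiff(unique(unlist(per_cand)), common)
    pos <- match(varying, alleles)
    if (length(pos) > 1L)
      for (p in pos[-1L]) union2(pos[1L], p)
  }
  roots <- vapply(idx, find, integer(1))
  entries <- character(length(alleles))
  for (r in unique(roots)) {
    members <- parsed[roots == r]
    vals <- lapply(members, `[[`, "values")
    npre <- min(lengths(vals))
    pre <- vals[[1]][seq_len(npre)]
    for (v in vals) {
      while (npre > 0L && !identical(v[seq_len(npre)], pre[seq_len(npre)]))
        npre <- npre - 1L
    }
    if (npre == 0L)
      stop("pool class with no common field prefix; alleles: ",
           paste(vapply(members, format_allele, character(1)),
                 collapse = ", "), call. = FALSE)
    # keep the written form of the shortest member for the prefix
    shortest <- members[[which.min(lengths(vals))]]
    name <- paste0(shortest$locus, "*",
                   paste(shortest$fields[seq_len(npre)], collapse = ":"))
    entries[roots == r] <- name
  }
  allele_mapping(stats::setNames(entries, alleles),
                 description = "common allele pool")
}

sample_alleles <- function(s) {
  unique(unlist(lapply(s$genotypes, function(g)
    unlist(g$candidates, use.names = FALSE))))
}

#' Alleles distinguished only outside the peptide-binding region
#'
#' A number of alleles differ from a frequent allele only outside the exons
#' encoding the peptide-binding site and were historically not separated by
#' typing, although some occur at significant frequencies.  The package
#' ships a warning list of such alleles with the populations where each is
#' known to matter; this screens a set of allele names against it.
#'
#' @param alleles character vector of allele names.
#' @param warning_list data frame with columns \code{allele},
#'   \code{populations}; defaults to the packaged list.
#' @return data frame of the input alleles found in the list, with their
#'   population annotations (zero rows when none match).
#' @export
flag_non_pbr_distinctions <- function(alleles,
                                      warning_list = non_pbr_alleles()) {
  hit <- match(vapply(alleles, function(t) allele_sort_key(t), character(1)),
               allele_sort_key(warning_list$allele))
  out <- warning_list[hit[!is.na(hit)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname flag_non_pbr_distinctions
#' @export
non_pbr_alleles <- function() {
  path <- system.file("extdata", "non_pbr_alleles.tsv", package = "hlapop",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
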