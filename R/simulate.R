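#' Generate a synthetic population sample
#'
#' Draws \code{N} independent individuals at one locus with genotype
#' probabilities \eqn{P(aa) = p_a^2 + f p_a(1-p_a)} and
#' \eqn{P(ab) = 2 p_a p_b (1-f)}: Hardy-Weinberg proportions when the
#' inbreeding coefficient \eqn{f = 0}, excess homozygosity for \eqn{f > 0}
#' (at \eqn{f = 1} no heterozygotes occur).  Individuals are independent,
#' matching the sampling assumption that first-degree relatives are
#' excluded.  Frequencies come either from an explicit vector or from a
#' symmetric Dirichlet draw.  Deterministic given \code{seed}.
#'
#' The attached questionnaire metadata is clearly fictional (population
#' "Simulandia", mid-ocean coordinates): fixtures must not imitate real
#' populations.
#'
#' @param k_alleles number of alleles (ignored when \code{frequencies}
#'   given).
#' @param frequencies named or unnamed vector of allele frequencies summing
#'   to 1; default a symmetric Dirichlet(\code{concentration}) draw over
#'   \code{k_alleles} alleles named \code{LOCUS*01 ... LOCUS*k}.
#' @param N number of individuals.
#' @param inbreeding_f inbreeding coefficient in [0, 1].
#' @param locus locus symbol for generated allele names.
#' @param concentration symmetric Dirichlet concentration for random
#'   frequencies.
#' @param seed RNG seed.
#' @return an \code{hla_sample} of unambiguous genotypes, with the true
#'   frequencies in attribute \code{"truth"}.
#' @export
generate_genotypes <- function(k_alleles = 5L, frequencies = NULL, N = 100L,
                               inbreeding_f = 0, locus = "A",
                               concentration = 1, seed = 1L) {
  if (N < 1L) stop("N must be >= 1", call. = FALSE)
  if (inbreeding_f < 0 || inbreeding_f > 1)
    stop("inbreeding_f must be in [0, 1]", call. = FALSE)
  draws <- with_seed(seed, {
    if (is.null(frequencies)) {
      g <- stats::rgamma(k_alleles, concentration)
      frequencies <- g / sum(g)
    }
    if (abs(sum(frequencies) - 1) > 1e-8)
      stop("frequencies must sum to 1", call. = FALSE)
    if (any(frequencies < 0)) stop("negative frequency", call. = FALSE)
    k <- length(frequencies)
    if (is.null(names(frequencies)))
      names(frequencies) <- sprintf("%s*%02d", locus, seq_len(k))
    a1 <- sample.int(k, N, replace = TRUE, prob = frequencies)
    ibd <- stats::runif(N) < inbreeding_f
    a2 <- ifelse(ibd, a1,
                 sample.int(k, N, replace = TRUE, prob = frequencies))
    list(a1 = a1, a2 = a2, frequencies = frequencies)
  })
  alleles <- names(draws$frequencies)
  locus_sym <- as_allele(alleles[1])$locus
  genotypes <- lapply(seq_len(N), function(i)
    hla_genotype(sprintf("ind%04d", i), locus_sym,
                 list(list(c(alleles[draws$a1[i]], alleles[draws$a2[i]]))),
                 source = "unambiguous"))
  md <- questionnaire_metadata(
    study_type = "anthropology_field",
    population_name = "Simulandia (synthetic)",
    latitude = 0, longitude = -160,
    language = "none (synthetic data)",
    linguistic_family = "none",
    first_degree_relatives_excluded = TRUE,
    ethics_statement = "synthetic data; no human subjects",
    typing_technique = "simulation",
    n_individuals = N)
  s <- hla_sample(genotypes, md)
  attr(s, "truth") <- list(frequencies = draws$frequencies,
                           inbreeding_f = inbreeding_f, seed = seed)
  s
}

#' Generate a random typing kit
#'
#' Builds a probe panel over the given alleles: each allele reacts with each
#' probe with probability 0.5.  The panel is re-drawn until every allele has
#' a distinct probe signature, or \code{max_attempts} is reached, in which
#' case the kit is returned with unresolvable allele groups (useful for
#' ambiguity stress tests) and an attribute \code{"resolved" = FALSE}.
#'
#' @param alleles character vector of allele names (the kit universe).
#' @param n_probes number of probes (>= 1).
#' @param seed RNG seed.
#' @param kit_id kit identifier.
#' @param max_attempts redraw cap.
#' @return an \code{hla_kit}.
#' @export
generate_kit <- function(alleles, n_probes, seed = 1L,
                         kit_id = "SIMKIT", max_attempts = 100L) {
  if (n_probes < 1L) stop("n_probes must be >= 1", call. = FALSE)
  locus <- as_allele(alleles[1])$locus
  with_seed(seed, {
    resolved <- FALSE
    for (attempt in seq_len(max_attempts)) {
      inc <- matrix(stats::runif(length(alleles) * n_probes) < 0.5,
                    nrow = length(alleles))
      sig <- apply(inc, 1L, paste, collapse = "")
      if (!anyDuplicated(sig)) { resolved <- TRUE; break }
    }
    probes <- stats::setNames(
      lapply(seq_len(n_probes), function(p) alleles[inc[, p]]),
      sprintf("P%02d", seq_len(n_probes)))
    kit <- hla_kit(kit_id, locus, probes, allele_universe = alleles)
    attr(kit, "resolved") <- resolved
    kit
  })
}

#' Mask a sample through a typing kit
#'
#' Replaces every genotype by the ambiguous genotype its probe-reactivity
#' pattern implies under the kit (forward prediction then interpretation) —
#' the mechanism by which reverse SSO typing creates ambiguity.  The true
#' genotype is always among the candidates.
#'
#' @param s a single-locus \code{hla_sample} of unambiguous genotypes whose
#'   alleles are all in the kit universe.
#' @param kit an \code{hla_kit}.
#' @return the masked \code{hla_sample} (truth attribute preserved).
#' @export
mask_with_kit <- function(s, kit) {
  stopifnot(inherits(s, "hla_sample"), inherits(kit, "hla_kit"))
  if (length(s$loci) != 1L)
    stop("kit masking is single-locus", call. = FALSE)
  genotypes <- lapply(s$genotypes, function(g) {
    pair <- g$candidates[[1]][[1]]
    interpret_pattern(predict_pattern(pair, kit), kit, id = g$id)
  })
  out <- hla_sample(genotypes, s$metadata)
  attr(out, "truth") <- attr(s, "truth")
  out
}

#' Kit-free random-merge ambiguity
#'
#' A cheap alternative ambiguity mechanism for stress-testing the EM: with
#' probability \code{rate}, an individual's candidate set is augmented with
#' one extra random allele pair (sharing the first allele), mimicking an
#' unresolved typing.
#'
#' @param s a single-locus unambiguous \code{hla_sample}.
#' @param rate probability an individual receives an extra candidate.
#' @param seed RNG seed.
#' @return the \code{hla_sample} with inflated candidate sets.
#' @export
random_merge_ambiguity <- function(s, rate = 0.3, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  alleles <- sort(sample_alleles(s))
  with_seed(seed, {
    genotypes <- lapply(s$genotypes, function(g) {
      if (stats::runif(1) >= rate) return(g)
      pair <- g$candidates[[1]][[1]]
      extra <- canonical_pair(c(pair[1], sample(alleles, 1L)))
      hla_genotype(g$id, g$loci,
                   unique(c(g$candidates, list(list(extra)))),
                   source = "pair_list")
    })
    out <- hla_sample(genotypes, s$metadata)
    attr(out, "truth") <- attr(s, "truth")
    out
  })
}

#' Generate a two-locus sample from haplotype frequencies
#'
#' Draws \code{N} individuals as two independent haplotypes from the given
#' haplotype frequency table (random union of gametes), then discards
#' phase.  Used to exercise haplotype EM and linkage-disequilibrium
#' estimation against known truth.
#'
#' @param hap_freq named numeric vector, names \code{"alleleA~alleleB"},
#'   summing to 1.
#' @param N individuals.
#' @param seed RNG seed.
#' @return an unphased two-locus \code{hla_sample}; truth attribute carries
#'   the haplotype frequencies.
#' @export
generate_two_locus <- function(hap_freq, N = 100L, seed = 1L) {
  stopifnot(abs(sum(hap_freq) - 1) < 1e-8)
  haps <- strsplit(names(hap_freq), "~", fixed = TRUE)
  loci <- vapply(haps[[1]], function(a) as_allele(a)$locus, character(1))
  draws <- with_seed(seed, {
    h1 <- sample.int(length(hap_freq), N, replace = TRUE, prob = hap_freq)
    h2 <- sample.int(length(hap_freq), N, replace = TRUE, prob = hap_freq)
    list(h1 = h1, h2 = h2)
  })
  genotypes <- lapply(seq_len(N), function(i) {
    ha <- haps[[draws$h1[i]]]; hb <- haps[[draws$h2[i]]]
    cand <- lapply(seq_along(loci), function(l)
      canonical_pair(c(ha[l], hb[l])))
    hla_genotype(sprintf("ind%04d", i), unname(loci), list(cand),
                 source = "unambiguous")
  })
  s <- hla_sample(genotypes)
  attr(s, "truth") <- list(hap_freq = hap_freq, seed = seed)
  s
}

#' Write a simulated dataset to disk
#'
#' Writes the tabular dialect, the kit file (when given) and a truth JSON
#' (true frequencies, inbreeding f, seed) so a simulation is fully
#' reproducible from its artifacts.
#'
#' @param s a generated \code{hla_sample} (with truth attribute).
#' @param dir output directory (created if needed).
#' @param kit optional \code{hla_kit} used for masking.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(s, dir, kit = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sample = file.path(dir, "sample.csv"),
             truth = file.path(dir, "truth.json"))
  write_sample_tabular(s, paths[["sample"]])
  truth <- attr(s, "truth")
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(kit)) {
    paths[["kit"]] <- file.path(dir, "kit.tsv")
    write_kit(kit, paths[["kit"]])
  }
  invisible(paths)
}
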