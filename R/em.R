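#' Maximum-likelihood allele frequencies from ambiguous genotypes
#'
#' Fits allele frequencies at one locus by expectation-maximization over the
#' ambiguity sets, maximizing the Hardy-Weinberg mixture likelihood
#' \deqn{L(p) = \prod_i \sum_{(a,b) \in C_i} g_{ab}(p), \quad
#'       g_{aa} = p_a^2,\; g_{ab} = 2 p_a p_b \;(a \ne b),}
#' where \eqn{C_i} is individual \eqn{i}'s candidate pair set.  The E-step
#' gives each candidate pair its posterior weight
#' \eqn{g_{ab}(p)/\sum_{C_i} g(p)}; the M-step sets each frequency to the
#' expected allele count over \eqn{2N} gene copies.  On fully unambiguous
#' data this is the direct counting estimator.
#'
#' Multiple starts are run (the first uniform, the rest Dirichlet(1) draws
#' from \code{seed}) and the best retained; the number of distinct local
#' optima found is reported, two optima counting as one solution when their
#' log-likelihoods differ by at most 0.01 and their frequency vectors by at
#' most 1e-4 in the sup norm.  Reporting starting points, distinct solutions
#' and convergence criteria alongside the estimates is part of the
#' recommended practice for EM frequency estimation.
#'
#' @param s an \code{hla_sample} at a single locus.
#' @param n_starts number of EM initializations (>= 1).
#' @param tol_loglik convergence threshold on the log-likelihood change.
#' @param tol_freq convergence threshold on the sup-norm frequency change.
#' @param max_iter maximum EM iterations per start.
#' @param seed integer seed for the random starts.
#' @return An object of class \code{hla_freq}: frequencies (named, summing
#'   to 1), \code{n_individuals}, \code{n_gene_copies}, \code{log_likelihood},
#'   \code{em_diagnostics} (n_starting_points, n_distinct_solutions,
#'   convergence_criterion, iterations, seed), and per-allele \code{flags}.
#' @examples
#' s <- generate_genotypes(k_alleles = 4, N = 100, seed = 1)
#' fit <- hla_em(s)
#' coef(fit)
#' @seealso \code{\link{hla_haplo_em}} for multi-locus haplotypes,
#'   \code{\link{hwe_test}}, \code{\link{ewens_watterson_test}}.
#' @export
hla_em <- function(s, n_starts = 5L, tol_loglik = 1e-8, tol_freq = 1e-9,
                   max_iter = 5000L, seed = 1L) {
  stopifnot(inherits(s, "hla_sample"))
  if (length(s$loci) != 1L)
    stop("hla_em is single-locus; use hla_haplo_em for multiple loci",
         call. = FALSE)
  if (length(s$genotypes) == 0L) stop("empty sample", call. = FALSE)
  agg <- aggregate_candidates(s)
  k <- length(agg$alleles)
  N <- length(s$genotypes)

  if (k == 1L) {
    fit <- list(p = 1, loglik = 0, iters = 0L, criterion = "monomorphic")
    sols <- list(fit)
  } else {
    starts <- with_seed(seed, {
      c(list(rep(1 / k, k)),
        lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
          g <- stats::rgamma(k, 1); g / sum(g)
        }))
    })
    sols <- lapply(starts, function(p0)
      em_run(p0, agg, tol_loglik, tol_freq, max_iter))
    fit <- sols[[which.max(vapply(sols, `[[`, numeric(1), "loglik"))]]
  }
  n_distinct <- count_distinct_solutions(sols)
  p <- stats::setNames(fit$p, agg$alleles)
  est <- structure(list(
    loci = s$loci,
    frequencies = p,
    n_individuals = N,
    n_gene_copies = 2L * N,
    log_likelihood = fit$loglik,
    em_diagnostics = list(
      n_starting_points = length(sols),
      n_distinct_solutions = n_distinct,
      convergence_criterion = sprintf(
        "|delta logL| < %g or sup-norm freq change < %g (met: %s)",
        tol_loglik, tol_freq, fit$criterion),
      iterations = fit$iters,
      seed = seed),
    ambiguity_fraction =
      mean(vapply(s$genotypes, n_candidates, integer(1)) > 1L),
    flags = NULL,
    call = match.call()),
    class = "hla_freq")
  est$flags <- cwd_flags(est)
  est
}

# single-locus sample -> aggregated candidate structure: unique candidate
# sets with multiplicities, pairs as allele-index rows
aggregate_candidates <- function(s) {
  alleles <- sort(unique(unlist(lapply(s$genotypes, function(g)
    unlist(g$candidates)))))
  keys <- vapply(s$genotypes, candidate_keys_joined, character(1))
  counts <- table(factor(keys, levels = unique(keys)))
  reps <- s$genotypes[match(names(counts), keys)]
  i1 <- integer(); i2 <- integer(); grp <- integer()
  for (g in seq_along(reps)) {
    for (cand in reps[[g]]$candidates) {
      pair <- cand[[1]]
      i1 <- c(i1, match(pair[1], alleles))
      i2 <- c(i2, match(pair[2], alleles))
      grp <- c(grp, g)
    }
  }
  list(alleles = alleles, i1 = i1, i2 = i2, grp = grp,
       count = as.numeric(counts), N = length(s$genotypes))
}

candidate_keys_joined <- function(g) paste(candidate_keys(g), collapse = "|")

em_run <- function(p, agg, tol_loglik, tol_freq, max_iter) {
  ll_old <- -Inf
  het <- ifelse(agg$i1 == agg$i2, 1, 2)
  twoN <- 2 * agg$N
  ngrp <- length(agg$count)
  for (it in seq_len(max_iter)) {
    g_row <- het * p[agg$i1] * p[agg$i2]
    s_grp <- rowsum_vec(g_row, agg$grp, ngrp)
    ll <- sum(agg$count * log(s_grp))
    w_row <- agg$count[agg$grp] * g_row / s_grp[agg$grp]
    cnt <- rowsum_vec(w_row, agg$i1, length(p)) +
           rowsum_vec(w_row, agg$i2, length(p))
    p_new <- cnt / twoN
    d_ll <- ll - ll_old
    d_p <- max(abs(p_new - p))
    p <- p_new
    if (it > 1L && abs(d_ll) < tol_loglik)
      return(list(p = p, loglik = ll, iters = it, criterion = "loglik"))
    if (d_p < tol_freq)
      return(list(p = p, loglik = ll, iters = it, criterion = "frequency"))
    ll_old <- ll
  }
  stop(structure(class = c("hla_em_nonconvergence", "error", "condition"),
                 list(message = sprintf(
                        "EM did not converge in %d iterations (last logL %.6f, delta %.3g)",
                        max_iter, ll, d_ll),
                      call = NULL, loglik = ll)))
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  acc <- rowsum(x, idx)
  out[as.integer(rownames(acc))] <- acc[, 1L]
  out
}

count_distinct_solutions <- function(sols, tol_ll = 0.01, tol_p = 1e-4) {
  reps <- list()
  for (s in sols) {
    dup <- any(vapply(reps, function(r)
      abs(r$loglik - s$loglik) <= tol_ll && max(abs(r$p - s$p)) <= tol_p,
      logical(1)))
    if (!dup) reps[[length(reps) + 1L]] <- s
  }
  length(reps)
}

#' @export
print.hla_freq <- function(x, digits = 4, ...) {
  cat(sprintf("ML %s frequencies, locus %s (N = %d individuals, 2N = %d)\n",
              if (!is.null(x$haplotypes)) "haplotype" else "allele",
              paste(x$loci, collapse = "^"), x$n_individuals,
              x$n_gene_copies))
  p <- sort(x$frequencies, decreasing = TRUE)
  print(round(p, digits))
  cat(sprintf("log-likelihood %.4f; %d start(s), %d distinct solution(s), %d iteration(s)\n",
              x$log_likelihood, x$em_diagnostics$n_starting_points,
              x$em_diagnostics$n_distinct_solutions,
              x$em_diagnostics$iterations))
  invisible(x)
}

#' @export
coef.hla_freq <- function(object, ...) object$frequencies

#' @export
logLik.hla_freq <- function(object, ...) {
  structure(object$log_likelihood,
            df = length(object$frequencies) - 1L,
            nobs = object$n_individuals, class = "logLik")
}

#' @export
summary.hla_freq <- function(object, threshold_model = "I_normal_two_tail",
                             ...) {
  flagged <- flag_nonsignificant(object, model = threshold_model)
  se <- sqrt(object$frequencies * (1 - object$frequencies) /
             object$n_gene_copies)
  tab <- data.frame(allele = names(object$frequencies),
                    frequency = unname(object$frequencies),
                    se = unname(se),
                    nonsignificant = flagged$flags$nonsignificant,
                    common = flagged$flags$common,
                    well_documented = flagged$flags$well_documented,
                    row.names = NULL)
  tab <- tab[order(-tab$frequency), ]
  rownames(tab) <- NULL
  structure(list(table = tab, est = flagged,
                 threshold = attr(flagged, "threshold_percent"),
                 threshold_model = threshold_model),
            class = "summary.hla_freq")
}

#' @export
print.summary.hla_freq <- function(x, digits = 4, ...) {
  print(x$est)
  cat(sprintf("\nSignificance threshold (model %s, N = %d): %.2f%%\n",
              x$threshold_model, x$est$n_individuals, x$threshold))
  df <- x$table
  df$frequency <- round(df$frequency, digits)
  df$se <- round(df$se, digits)
  print(df)
  if (any(df$nonsignificant))
    cat("Note: frequencies below the threshold are not significantly\n",
        "different from zero; avoid discussion of the number of alleles\n",
        "present or the presence/absence of given alleles.\n", sep = "")
  invisible(x)
}

#' @export
plot.hla_freq <- function(x, ...) barchart_freq(x, ...)

#' @export
simulate.hla_freq <- function(object, nsim = 1, seed = NULL, ...) {
  if (length(object$loci) != 1L)
    stop("simulate is implemented for single-locus fits", call. = FALSE)
  if (is.null(seed)) seed <- 1L
  lapply(seq_len(nsim), function(i)
    generate_genotypes(frequencies = object$frequencies,
                       N = object$n_individuals, seed = seed + i - 1L))
}

#' Common / well-documented allele classification
#'
#' An allele is classified \emph{common} when its frequency exceeds 0.0001
#' and \emph{well-documented} when it has been observed at least three
#' times.  Both inequalities follow the published rule exactly: the
#' frequency bound is strict, the count bound is not.
#'
#' @param freq allele frequency in [0, 1].
#' @param observed_count number of times the allele was observed.
#' @return character vector, a subset of
#'   \code{c("common", "well_documented")} (possibly empty).
#' @examples
#' classify_cwd(0.0002, 1)   # common
#' classify_cwd(0.00005, 3)  # well_documented
#' classify_cwd(0.0001, 2)   # neither (boundary is strict)
#' @export
classify_cwd <- function(freq, observed_count) {
  stopifnot(freq >= 0, freq <= 1, observed_count >= 0)
  out <- character()
  if (freq > 0.0001) out <- c(out, "common")
  if (observed_count >= 3) out <- c(out, "well_documented")
  out
}

cwd_flags <- function(est) {
  copies <- est$frequencies * est$n_gene_copies
  lab <- lapply(seq_along(est$frequencies), function(i)
    classify_cwd(est$frequencies[i], copies[i]))
  data.frame(allele = names(est$frequencies),
             common = vapply(lab, function(l) "common" %in% l, logical(1)),
             well_documented = vapply(lab, function(l)
               "well_documented" %in% l, logical(1)),
             nonsignificant = NA,
             row.names = NULL)
}

#' Flag frequencies not significantly different from zero
#'
#' Marks every allele whose estimated frequency is below the zero-containment
#' threshold for the sample size (see \code{\link{frequency_threshold}}).
#' Such estimates should not support statements about the number of alleles
#' present or the presence/absence of given alleles in the population.
#'
#' @param est an \code{hla_freq}.
#' @param model threshold sampling model, see
#'   \code{\link{frequency_threshold}}.
#' @return \code{est} with its \code{flags$nonsignificant} column filled;
#'   the threshold used (percent) is attached as attribute
#'   \code{"threshold_percent"}.
#' @export
flag_nonsignificant <- function(est, model = "I_normal_two_tail") {
  thr <- frequency_threshold(est$n_individuals, model = model)
  p_thr <- attr(thr, "unrounded") / 100
  est$flags$nonsignificant <- unname(est$frequencies < p_thr)
  attr(est, "threshold_percent") <- as.numeric(thr)
  attr(est, "threshold_model") <- model
  est
}
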