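#' Observed homozygosity
#'
#' \eqn{F = \sum_a \hat p_a^2}, the probability that two random gene copies
#' carry the same allele.  All estimated alleles are included by default;
#' optionally the sum is restricted to alleles whose frequency is
#' significant for the sample size (allele counts are sample-size
#' sensitive, so both behaviours are surfaced).
#'
#' @param est an \code{hla_freq}.
#' @param significant_only restrict to alleles at or above the
#'   zero-containment threshold (renormalizing is \emph{not} applied; the
#'   raw sum over the retained alleles is returned).
#' @param threshold_model model for the threshold, see
#'   \code{\link{frequency_threshold}}.
#' @return numeric scalar in (0, 1].
#' @export
observed_homozygosity <- function(est, significant_only = FALSE,
                                  threshold_model = "I_normal_two_tail") {
  stopifnot(inherits(est, "hla_freq"))
  p <- est$frequencies
  if (significant_only) {
    flagged <- flag_nonsignificant(est, model = threshold_model)
    p <- p[!flagged$flags$nonsignificant]
  }
  sum(p^2)
}

#' Solve for the scaled mutation rate from the allele count
#'
#' Finds \eqn{\hat\theta} such that the expected number of distinct alleles
#' in a neutral sample of \eqn{n} gene copies,
#' \eqn{E[K \mid \theta, n] = \sum_{i=0}^{n-1} \theta/(\theta+i)}, equals
#' the observed count \eqn{k} (monotone root-finding).
#'
#' @param n gene copies (2N).
#' @param k observed number of distinct alleles, \eqn{2 \le k \le n}
#'   (boundary cases \code{k = 1} and \code{k = n} return the degenerate
#'   limits 0 and Inf).
#' @return numeric scalar.
#' @export
solve_theta <- function(n, k) {
  if (k > n) stop("k cannot exceed n", call. = FALSE)
  if (k <= 1) return(0)
  if (k == n) return(Inf)
  ek <- function(theta) sum(theta / (theta + 0:(n - 1))) - k
  stats::uniroot(ek, lower = 1e-10, upper = 1e10, tol = 1e-12)$root
}

# one neutral sample of n gene copies by the sequential urn construction of
# the Ewens sampling formula: copy i joins an existing allele class with
# probability proportional to its count, founds a new one w.p. theta/(theta+i)
ewens_urn_draw <- function(n, theta) {
  counts <- integer(0)
  for (i in 0:(n - 1)) {
    if (is.infinite(theta) || stats::runif(1) < theta / (theta + i)) {
      counts <- c(counts, 1L)
    } else {
      j <- sample.int(length(counts), 1L, prob = counts)
      counts[j] <- counts[j] + 1L
    }
  }
  counts
}

#' Ewens-Watterson selective-neutrality test
#'
#' Compares the observed homozygosity \eqn{F = \sum \hat p^2} with its
#' sampling distribution under selective neutrality, conditional on the
#' sample size \eqn{n = 2N} and the number of distinct alleles \eqn{k}.
#' \eqn{\hat\theta} is solved from \eqn{E[K] = k}
#' (\code{\link{solve_theta}}); null allele configurations are drawn by the
#' sequential urn construction of the Ewens sampling formula and accepted
#' when they show exactly \eqn{k} alleles (rejection conditioning).  Tail
#' probabilities use the mid-p convention: ties at \eqn{F_{obs}} count half
#' in each tail, so \code{p_low + p_high = 1}.  Low \eqn{F} (balancing
#' selection) is the \code{p_low} tail, high \eqn{F} (directional
#' selection) the \code{p_high} tail.
#'
#' F_obs is computed from the point EM frequency estimates; ambiguity
#' uncertainty is not propagated into the null (noted in the output).
#'
#' @param est an \code{hla_freq} (single locus).
#' @param replicates accepted null replicates to collect (default 10000,
#'   at least 1000 recommended).
#' @param seed RNG seed for the resampling.
#' @param significant_only base \eqn{k} and \eqn{F_{obs}} on significant
#'   alleles only (see \code{\link{observed_homozygosity}}).
#' @param min_acceptance abort when the rejection-sampling acceptance rate
#'   falls below this (default 0.001), advising exact enumeration
#'   (\code{\link{exact_ewens_null}}) for small \eqn{n}.
#' @return An object of class \code{hla_neutrality}: \code{F_obs},
#'   \code{F_null_mean}, \code{F_null_sd}, \code{p_low}, \code{p_high},
#'   \code{k}, \code{n}, \code{theta_hat}, \code{replicates}, \code{seed},
#'   and the accepted null draws \code{F_null}.
#' @export
ewens_watterson_test <- function(est, replicates = 10000L, seed = 1L,
                                 significant_only = FALSE,
                                 min_acceptance = 0.001) {
  stopifnot(inherits(est, "hla_freq"))
  p <- est$frequencies
  if (significant_only) {
    flagged <- flag_nonsignificant(est)
    p <- p[!flagged$flags$nonsignificant]
  }
  k <- length(p)
  n <- est$n_gene_copies
  if (k > n) stop("k cannot exceed n = 2N", call. = FALSE)
  if (k < 2) stop("neutrality test needs at least 2 alleles", call. = FALSE)
  F_obs <- sum(p^2)
  theta <- solve_theta(n, k)
  F_null <- numeric(replicates)
  got <- 0L; tried <- 0L
  with_seed(seed, {
    while (got < replicates) {
      batch <- max(1000L, replicates - got)
      for (b in seq_len(batch)) {
        tried <- tried + 1L
        cnt <- ewens_urn_draw(n, theta)
        if (length(cnt) == k) {
          got <- got + 1L
          F_null[got] <- sum((cnt / n)^2)
          if (got == replicates) break
        }
      }
      if (tried >= 2000L && got / tried < min_acceptance)
        stop(sprintf(paste0("rejection acceptance rate %.4f%% below %.2f%%; ",
                            "use exact_ewens_null for small n"),
                     100 * got / tried, 100 * min_acceptance), call. = FALSE)
    }
  })
  eps <- 1e-12
  p_low <- (sum(F_null < F_obs - eps) + 0.5 * sum(abs(F_null - F_obs) <= eps)) /
    replicates
  structure(list(F_obs = F_obs,
                 F_null_mean = mean(F_null),
                 F_null_sd = stats::sd(F_null),
                 p_low = p_low, p_high = 1 - p_low,
                 k = k, n = n, theta_hat = theta,
                 replicates = replicates, seed = seed,
                 acceptance_rate = got / tried,
                 F_null = F_null,
                 note = paste("F_obs from point EM frequencies;",
                              "ambiguity uncertainty not propagated")),
            class = "hla_neutrality")
}

#' @export
print.hla_neutrality <- function(x, ...) {
  cat("Ewens-Watterson neutrality test (resampling null)\n")
  cat(sprintf("  k = %d alleles, n = %d gene copies, theta_hat = %.4g\n",
              x$k, x$n, x$theta_hat))
  cat(sprintf("  F_obs = %.4f; null mean %.4f (sd %.4f), %d replicates\n",
              x$F_obs, x$F_null_mean, x$F_null_sd, x$replicates))
  cat(sprintf("  p_low = %.4f (balancing), p_high = %.4f (directional)\n",
              x$p_low, x$p_high))
  cat("  expected and observed homozygosity should both be reported.\n")
  invisible(x)
}

#' Exact null distribution of homozygosity under neutrality
#'
#' Enumerates every partition of \eqn{n} gene copies into \eqn{k} allele
#' classes and weights it by the Ewens sampling formula conditional on
#' \eqn{K = k}: a configuration with \eqn{a_j} classes of size \eqn{j} has
#' probability proportional to \eqn{\prod_j (1/j)^{a_j} / a_j!}
#' (\eqn{\theta} cancels under the conditioning).  Returns the exact
#' distribution of \eqn{F = \sum (n_i/n)^2}.  Intended as the small-sample
#' oracle for the resampling test; \eqn{n \le 30}.
#'
#' @param n gene copies (<= 30).
#' @param k number of allele classes.
#' @return list with \code{support} (data frame \code{F}, \code{prob},
#'   aggregated over partitions with equal F), \code{mean}, \code{sd}, and
#'   the raw \code{partitions}.
#' @examples
#' exact_ewens_null(4, 2)$support   # F 0.625 w.p. 8/11, F 0.5 w.p. 3/11
#' @export
exact_ewens_null <- function(n, k) {
  if (n > 30) stop("n too large to enumerate; use the resampling test",
                   call. = FALSE)
  if (k > n || k < 1) stop("need 1 <= k <= n", call. = FALSE)
  parts <- integer_partitions(n, k)
  w <- vapply(parts, function(lambda) {
    tab <- table(lambda)
    sizes <- as.integer(names(tab)); mult <- as.integer(tab)
    prod((1 / sizes)^mult / factorial(mult))
  }, numeric(1))
  prob <- w / sum(w)
  F <- vapply(parts, function(lambda) sum((lambda / n)^2), numeric(1))
  agg <- rowsum(prob, F)
  support <- data.frame(F = as.numeric(rownames(agg)), prob = agg[, 1L])
  support <- support[order(-support$F), ]
  rownames(support) <- NULL
  m <- sum(F * prob)
  list(support = support, mean = m,
       sd = sqrt(max(0, sum(F^2 * prob) - m^2)),
       partitions = parts)
}

# all partitions of n into exactly k parts, non-increasing order
integer_partitions <- function(n, k, max_part = n) {
  if (k == 0L) return(if (n == 0L) list(integer(0)) else list())
  if (n < k) return(list())
  out <- list()
  for (first in seq(min(max_part, n - k + 1L), 1L)) {
    rest <- integer_partitions(n - first, k - 1L, min(first, n - first))
    for (r in rest) out[[length(out) + 1L]] <- c(first, r)
  }
  out
}
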