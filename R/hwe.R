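#' Hardy-Weinberg test tolerant of typing ambiguity
#'
#' Tests Hardy-Weinberg equilibrium by a nested likelihood ratio in which
#' both the null and the alternative likelihood are computed by summing over
#' each individual's candidate genotype set, so ambiguous typings contribute
#' exactly the information they carry.  Classical chi-square/G/exact tests
#' on the genotype contingency table are only valid in the absence of
#' ambiguity; when the sample is unambiguous and \code{fallback = TRUE} the
#' classical chi-square is also run for comparison.
#'
#' Two nested alternatives are available:
#' \describe{
#'   \item{inbreeding}{one-parameter departure with inbreeding coefficient
#'     \eqn{f}: \eqn{P(aa) = p_a^2 + f p_a(1-p_a)},
#'     \eqn{P(ab) = 2 p_a p_b (1-f)}; \eqn{f} is profiled within the range
#'     keeping all genotype probabilities non-negative; df = 1.}
#'   \item{saturated}{free genotype-frequency model over the observed
#'     genotype categories; df = k(k+1)/2 - k.  On unambiguous data the LR
#'     statistic equals the classical G statistic.}
#' }
#'
#' @param s an \code{hla_sample} at a single locus.
#' @param alternative \code{"inbreeding"} (default) or \code{"saturated"}.
#' @param fallback also run the classical chi-square when the sample has no
#'   ambiguity.
#' @param n_starts,seed multi-start control for the null EM fit.
#' @return An object of class \code{hla_hwe}: \code{method},
#'   \code{statistic}, \code{df}, \code{p_value}, \code{f_hat} (inbreeding
#'   alternative), \code{ambiguity_fraction}, log-likelihoods, and
#'   optionally \code{chi_square} (the fallback result).
#' @examples
#' s <- generate_genotypes(k_alleles = 3, N = 100, seed = 7)
#' hwe_test(s)
#' @export
hwe_test <- function(s, alternative = c("inbreeding", "saturated"),
                     fallback = FALSE, n_starts = 3L, seed = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(s, "hla_sample"))
  if (length(s$loci) != 1L) stop("hwe_test is single-locus", call. = FALSE)
  agg <- aggregate_candidates(s)
  k <- length(agg$alleles)
  amb <- mean(vapply(s$genotypes, n_candidates, integer(1)) > 1L)
  if (k == 1L) {
    warning("monomorphic sample: nested models coincide", call. = FALSE)
    return(structure(list(method = paste0("nested_LR_", alternative),
                          statistic = 0, df = 0L, p_value = 1,
                          f_hat = NA_real_, ambiguity_fraction = amb,
                          loglik_null = 0, loglik_alt = 0,
                          n_alleles = 1L, chi_square = NULL),
                     class = "hla_hwe"))
  }
  null_fit <- hla_em(s, n_starts = n_starts, seed = seed)
  ll0 <- null_fit$log_likelihood
  p0 <- unname(null_fit$frequencies[agg$alleles])

  if (alternative == "inbreeding") {
    opt <- fit_inbreeding(agg, p0, ll0)
    ll1 <- opt$loglik; f_hat <- opt$f; df <- 1L
  } else {
    sat <- fit_saturated(agg)
    ll1 <- sat$loglik; f_hat <- NA_real_
    df <- as.integer(k * (k + 1) / 2 - k)
  }
  stat <- 2 * (ll1 - ll0)
  if (stat < -1e-6)
    stop("alternative likelihood below null beyond numeric tolerance",
         call. = FALSE)
  stat <- max(stat, 0)
  res <- structure(list(method = paste0("nested_LR_", alternative),
                        statistic = stat, df = df,
                        p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                        f_hat = f_hat, ambiguity_fraction = amb,
                        loglik_null = ll0, loglik_alt = ll1,
                        n_alleles = k, chi_square = NULL),
                   class = "hla_hwe")
  if (fallback && amb == 0) res$chi_square <- classical_chisq(agg, p0)
  res
}

# ambiguity-mixture log-likelihood under the inbreeding model
loglik_inbreeding <- function(p, f, agg) {
  hom <- agg$i1 == agg$i2
  g_row <- ifelse(hom,
                  p[agg$i1]^2 + f * p[agg$i1] * (1 - p[agg$i1]),
                  2 * p[agg$i1] * p[agg$i2] * (1 - f))
  s_grp <- rowsum_vec(g_row, agg$grp, length(agg$count))
  if (any(s_grp <= 0)) return(-Inf)
  sum(agg$count * log(s_grp))
}

# maximize over (p, f) by profiling f: for each f the frequencies are
# re-optimized (softmax parametrization, warm-started along the profile),
# then the profile is refined around its grid maximum.  f = 0 is always a
# profile point, so the LR cannot go negative beyond numeric noise.
fit_inbreeding <- function(agg, p0, ll0, f_grid = (-19:19) * 0.05) {
  k <- length(p0)
  p0 <- pmax(p0, 1e-10); p0 <- p0 / sum(p0)
  to_p <- function(par) {
    m <- max(par, 0)
    w <- c(exp(par - m), exp(-m))
    w / sum(w)
  }
  inner <- function(f, start) {
    obj <- function(par) {
      ll <- loglik_inbreeding(to_p(par), f, agg)
      if (!is.finite(ll)) 1e10 else -ll
    }
    opt <- stats::nlminb(start, obj,
                         control = list(iter.max = 500, eval.max = 1000))
    list(ll = -opt$objective, par = opt$par)
  }
  start0 <- log(p0[-k] / p0[k])
  # exact 0 must be a single grid point: a floating-point near-duplicate
  # would truncate the refinement bracket around a near-null maximum
  f_grid <- sort(unique(round(c(0, f_grid), 10)))
  prof <- vector("list", length(f_grid))
  # sweep outward from f = 0 so warm starts stay close
  i0 <- which(f_grid == 0)
  order_idx <- c(i0, (i0 + 1):length(f_grid), (i0 - 1):1)
  order_idx <- order_idx[order_idx >= 1 & order_idx <= length(f_grid)]
  last_up <- start0; last_dn <- start0
  for (i in unique(order_idx)) {
    st <- if (i >= i0) last_up else last_dn
    prof[[i]] <- inner(f_grid[i], st)
    if (i >= i0) last_up <- prof[[i]]$par else last_dn <- prof[[i]]$par
  }
  lls <- vapply(prof, `[[`, numeric(1), "ll")
  best <- which.max(lls)
  # golden-section refinement between the neighbours of the grid maximum
  lo <- f_grid[max(1L, best - 1L)]; hi <- f_grid[min(length(f_grid), best + 1L)]
  warm <- prof[[best]]$par
  ref <- stats::optimize(function(f) inner(f, warm)$ll,
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  if (ref$objective >= lls[best]) {
    f_hat <- ref$maximum; ll1 <- ref$objective
  } else {
    f_hat <- f_grid[best]; ll1 <- lls[best]
  }
  fin <- inner(f_hat, warm)
  list(loglik = max(ll1, fin$ll, ll0), f = f_hat, p = to_p(fin$par))
}

# saturated genotype-category mixture: EM over the distinct candidate pairs
fit_saturated <- function(agg, tol = 1e-10, max_iter = 10000L) {
  cat_key <- paste(agg$i1, agg$i2)
  cats <- unique(cat_key)
  ci <- match(cat_key, cats)
  q <- rep(1 / length(cats), length(cats))
  N <- sum(agg$count)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    g_row <- q[ci]
    s_grp <- rowsum_vec(g_row, agg$grp, length(agg$count))
    ll <- sum(agg$count * log(s_grp))
    w_row <- agg$count[agg$grp] * g_row / s_grp[agg$grp]
    q <- rowsum_vec(w_row, ci, length(cats)) / N
    if (abs(ll - ll_old) < tol)
      return(list(loglik = ll, q = stats::setNames(q, cats)))
    ll_old <- ll
  }
  list(loglik = ll, q = stats::setNames(q, cats))
}

# classical Pearson chi-square on the genotype table (unambiguous data only)
classical_chisq <- function(agg, p) {
  k <- length(p)
  N <- sum(agg$count)
  obs <- matrix(0, k, k)
  for (r in seq_along(agg$i1)) {
    i <- agg$i1[r]; j <- agg$i2[r]
    obs[i, j] <- obs[i, j] + agg$count[r]
  }
  stat <- 0
  for (i in seq_len(k)) for (j in i:k) {
    e <- if (i == j) N * p[i]^2 else N * 2 * p[i] * p[j]
    stat <- stat + (obs[i, j] - e)^2 / e
  }
  df <- as.integer(k * (k + 1) / 2 - k)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' @export
print.hla_hwe <- function(x, ...) {
  cat("Hardy-Weinberg test (", x$method, ")\n", sep = "")
  cat(sprintf("  LR statistic = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.na(x$f_hat))
    cat(sprintf("  inbreeding coefficient f = %.4f\n", x$f_hat))
  cat(sprintf("  ambiguity: %.1f%% of individuals have >1 candidate\n",
              100 * x$ambiguity_fraction))
  if (!is.null(x$chi_square))
    cat(sprintf("  classical chi-square (no ambiguity): X2 = %.4f, df = %d, p = %.4g\n",
                x$chi_square$statistic, x$chi_square$df,
                x$chi_square$p_value))
  cat("  HWE assessment is mandatory before any use of allele frequencies;\n",
      "  contingency-table tests are only valid without ambiguities.\n",
      sep = "")
  invisible(x)
}
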