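# sample built from GL strings, ids auto-assigned
gl_sample <- function(..., metadata = questionnaire_metadata()) {
  strs <- c(...)
  hla_sample(lapply(seq_along(strs), function(i)
    parse_genotype_string(strs[i], id = sprintf("i%02d", i))),
    metadata = metadata)
}

uniform_freqs <- function(k, locus = "A") {
  stats::setNames(rep(1 / k, k), sprintf("%s*%02d", locus, seq_len(k)))
}

# independent maximizer of the single-locus ambiguity-mixture likelihood,
# used as the oracle against the EM path: direct optim over the simplex
oracle_allele_ml <- function(s, n_starts = 20, seed = 99) {
  agg <- hlapop:::aggregate_candidates(s)
  k <- length(agg$alleles)
  het <- ifelse(agg$i1 == agg$i2, 1, 2)
  ll <- function(p) {
    g <- het * p[agg$i1] * p[agg$i2]
    sg <- rowsum(g, agg$grp)[, 1]
    sum(agg$count * log(sg))
  }
  to_p <- function(par) {
    m <- max(par, 0); w <- c(exp(par - m), exp(-m)); w / sum(w)
  }
  best <- -Inf; best_p <- rep(1 / k, k)
  set.seed(seed)
  for (r in seq_len(n_starts)) {
    st <- rnorm(k - 1, 0, 1)
    o <- try(optim(st, function(par) -ll(to_p(par)), method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-14)),
             silent = TRUE)
    if (!inherits(o, "try-error") && -o$value > best) {
      best <- -o$value; best_p <- to_p(o$par)
    }
  }
  list(loglik = best, p = stats::setNames(best_p, agg$alleles))
}
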