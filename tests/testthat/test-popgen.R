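test_that("monomorphic samples give a degenerate HWE result", {
  s <- gl_sample("A*01+A*01", "A*01+A*01")
  expect_warning(h <- hwe_test(s), "monomorphic")
  expect_identical(h$statistic, 0)
  expect_identical(h$p_value, 1)
})

test_that("inbreeding LR matches a brute-force profile-likelihood oracle", {
  # unambiguous 2-allele sample, genotype counts (AA, AB, BB) = (30, 40, 30)
  strs <- c(rep("A*01+A*01", 30), rep("A*01+A*02", 40),
            rep("A*02+A*02", 30))
  s <- hla_sample(lapply(seq_along(strs), function(i)
    parse_genotype_string(strs[i], id = paste0("i", i))))
  h <- hwe_test(s, alternative = "inbreeding", fallback = TRUE)

  # oracle: dense 2-parameter grid over (p, f), refined once
  llfun <- function(p, f) {
    paa <- p^2 + f * p * (1 - p)
    pab <- 2 * p * (1 - p) * (1 - f)
    pbb <- (1 - p)^2 + f * (1 - p) * p
    if (min(paa, pab, pbb) <= 0) return(-Inf)
    30 * log(paa) + 40 * log(pab) + 30 * log(pbb)
  }
  ll0_grid <- max(vapply(seq(0.01, 0.99, 1e-4), function(p) llfun(p, 0),
                         numeric(1)))
  grid <- expand.grid(p = seq(0.01, 0.99, 5e-4),
                      f = seq(-0.99, 0.99, 5e-4))
  ll1_grid <- max(mapply(llfun, grid$p, grid$f))
  lr_oracle <- 2 * (ll1_grid - ll0_grid)
  expect_equal(h$statistic, lr_oracle, tolerance = 1e-3)
  expect_identical(h$df, 1L)
  # counts (30,40,30) at p = 0.5 show a heterozygote deficit: f_hat > 0
  expect_gt(h$f_hat, 0)
  expect_false(is.null(h$chi_square))
})

test_that("saturated LR equals the classical G statistic without ambiguity", {
  s <- generate_genotypes(k_alleles = 4, N = 120, seed = 17)
  h <- hwe_test(s, alternative = "saturated")
  # direct G computation from the genotype table
  keys <- vapply(s$genotypes, function(g)
    paste(g$candidates[[1]][[1]], collapse = "+"), character(1))
  obs <- table(keys)
  N <- length(keys)
  counts <- table(unlist(lapply(s$genotypes, function(g)
    g$candidates[[1]][[1]])))
  p <- counts / sum(counts)
  G <- 0
  for (cell in names(obs)) {
    al <- strsplit(cell, "+", fixed = TRUE)[[1]]
    e <- if (al[1] == al[2]) N * p[[al[1]]]^2
         else N * 2 * p[[al[1]]] * p[[al[2]]]
    G <- G + 2 * obs[[cell]] * log(obs[[cell]] / e)
  }
  expect_equal(h$statistic, G, tolerance = 1e-9)
  k <- length(p)
  expect_identical(h$df, as.integer(k * (k + 1) / 2 - k))
})

test_that("LR statistic is invariant under allele relabeling", {
  s <- generate_genotypes(k_alleles = 4, N = 100, inbreeding_f = 0.2,
                          seed = 23)
  relabel <- function(g) {
    g$candidates <- lapply(g$candidates, function(cand)
      lapply(cand, function(pair)
        hlapop:::canonical_pair(gsub("A\\*0", "A*2", pair))))
    g
  }
  s2 <- hla_sample(lapply(s$genotypes, relabel), s$metadata)
  h1 <- hwe_test(s, seed = 1)
  h2 <- hwe_test(s2, seed = 1)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-4)
})

test_that("ambiguous data are handled through the mixture likelihood", {
  s <- random_merge_ambiguity(
    generate_genotypes(k_alleles = 4, N = 150, seed = 29), 0.5, seed = 2)
  h <- hwe_test(s, seed = 1)
  expect_gt(h$ambiguity_fraction, 0.2)
  expect_gte(h$statistic, 0)
  expect_true(h$p_value >= 0 && h$p_value <= 1)
  expect_true(h$f_hat >= -1 && h$f_hat <= 1)
})

test_that("observed homozygosity is the sum of squared frequencies", {
  mk_est <- function(p, N = 100L) {
    structure(list(loci = "A",
                   frequencies = stats::setNames(p, sprintf("A*%02d",
                                                            seq_along(p))),
                   n_individuals = N, n_gene_copies = 2L * N,
                   log_likelihood = -1, em_diagnostics = list(),
                   flags = NULL),
              class = "hla_freq")
  }
  expect_equal(observed_homozygosity(mk_est(rep(0.25, 4))), 0.25)
  expect_equal(observed_homozygosity(mk_est(1)), 1)
  expect_equal(observed_homozygosity(mk_est(c(0.5, 0.3, 0.2))), 0.38)
  # restriction to significant alleles drops sub-threshold terms
  e <- mk_est(c(0.69, 0.3, 0.01), N = 100L)  # threshold 1.96%
  expect_equal(observed_homozygosity(e, significant_only = TRUE),
               0.69^2 + 0.3^2)
})

test_that("theta is solved from the expected allele count", {
  for (n in c(10, 100)) for (k in c(2, 5)) {
    th <- solve_theta(n, k)
    expect_equal(sum(th / (th + 0:(n - 1))), k, tolerance = 1e-8)
  }
  expect_identical(solve_theta(10, 1), 0)
  expect_identical(solve_theta(10, 10), Inf)
  expect_error(solve_theta(4, 5), "cannot exceed")
})

test_that("exact Ewens null enumerates partitions with ESF weights", {
  ex <- exact_ewens_null(4, 2)
  expect_equal(ex$support$F, c(0.625, 0.5))
  expect_equal(ex$support$prob, c(8 / 11, 3 / 11), tolerance = 1e-12)
  expect_equal(ex$mean, 6.5 / 11, tolerance = 1e-12)

  # k = 1: single partition, F = 1; k = n: all singletons, F = 1/n
  expect_equal(exact_ewens_null(7, 1)$support$F, 1)
  expect_equal(exact_ewens_null(7, 7)$support$F, 1 / 7)
  expect_error(exact_ewens_null(40, 3), "too large")
})

test_that("resampling EW test matches the exact null at small n", {
  mk_est <- function(p, N) {
    structure(list(loci = "A",
                   frequencies = stats::setNames(p, sprintf("A*%02d",
                                                            seq_along(p))),
                   n_individuals = N, n_gene_copies = 2L * N,
                   log_likelihood = -1, em_diagnostics = list(),
                   flags = NULL),
              class = "hla_freq")
  }
  for (cs in list(c(n = 8, k = 3), c(n = 12, k = 5), c(n = 10, k = 2))) {
    n <- cs[["n"]]; k <- cs[["k"]]
    est <- mk_est(rep(1 / k, k), N = n / 2)
    r <- ewens_watterson_test(est, replicates = 4000, seed = 11)
    ex <- exact_ewens_null(n, k)
    expect_setequal(round(unique(r$F_null), 10), round(ex$support$F, 10))
    mc_se <- ex$sd / sqrt(r$replicates)
    expect_lt(abs(r$F_null_mean - ex$mean), 3 * mc_se + 1e-12)
  }
})

test_that("EW tail probabilities use the mid-p convention", {
  s <- generate_genotypes(k_alleles = 5, N = 40, seed = 3)
  est <- hla_em(s, seed = 1)
  r <- ewens_watterson_test(est, replicates = 3000, seed = 7)
  expect_equal(r$p_low + r$p_high, 1, tolerance = 1e-12)
  expect_true(r$F_obs >= 1 / r$k && r$F_obs <= 1)
  expect_gte(r$replicates, 1000L)

  # k = n: all-singleton configuration, minimal F
  est2 <- structure(list(loci = "A",
                         frequencies = stats::setNames(rep(0.125, 8),
                                                       sprintf("A*%02d", 1:8)),
                         n_individuals = 4L, n_gene_copies = 8L,
                         log_likelihood = -1, em_diagnostics = list(),
                         flags = NULL), class = "hla_freq")
  r2 <- ewens_watterson_test(est2, replicates = 500, seed = 5)
  expect_equal(r2$F_obs, 1 / 8, tolerance = 1e-12)
  expect_lte(r2$p_low, 0.5)
  expect_error(ewens_watterson_test(
    structure(list(loci = "A",
                   frequencies = stats::setNames(rep(1 / 9, 9),
                                                 sprintf("A*%02d", 1:9)),
                   n_individuals = 4L, n_gene_copies = 8L,
                   log_likelihood = -1, em_diagnostics = list(),
                   flags = NULL), class = "hla_freq")), "cannot exceed")
})

test_that("HWE p-values are roughly uniform under the null", {
  # empirical CDF of simulated null p-values within the Kolmogorov 99% band
  p <- uniform_freqs(3)
  nrep <- 500
  pv <- vapply(seq_len(nrep), function(i) {
    s <- generate_genotypes(frequencies = p, N = 100, seed = 40000 + i)
    hwe_test(s, n_starts = 1, seed = 1)$p_value
  }, numeric(1))
  d <- max(abs(sort(pv) - (seq_len(nrep) / nrep)))
  expect_lt(d, 1.63 / sqrt(nrep))
})
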