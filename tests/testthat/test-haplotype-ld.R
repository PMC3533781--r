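test_that("haplotype EM is exact when phase is trivial", {
  # all double homozygotes: haplotypes read off directly
  s <- gl_sample("A*01+A*01^B*07+B*07",
                 "A*01+A*01^B*07+B*07",
                 "A*02+A*02^B*08+B*08")
  fit <- hla_haplo_em(s, n_starts = 2, seed = 1)
  expect_equal(unname(coef(fit)["A*01~B*07"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["A*02~B*08"]), 1 / 3, tolerance = 1e-9)
})

test_that("double-heterozygote phase is weighted by the EM, matching a direct maximizer", {
  # 3 individuals, one classic A/B + C/D double heterozygote
  s <- gl_sample("A*01+A*01^B*07+B*07",
                 "A*01+A*02^B*07+B*08",
                 "A*02+A*02^B*08+B*08")
  fit <- hla_haplo_em(s, n_starts = 5, seed = 1, prune_threshold = 0)
  # oracle: direct likelihood maximization over the 4-haplotype simplex
  haps <- c("A*01~B*07", "A*01~B*08", "A*02~B*07", "A*02~B*08")
  ll <- function(h) {
    names(h) <- haps
    log(h["A*01~B*07"]^2) + log(h["A*02~B*08"]^2) +
      log(2 * h["A*01~B*07"] * h["A*02~B*08"] +
          2 * h["A*01~B*08"] * h["A*02~B*07"])
  }
  to_h <- function(par) {
    m <- max(par, 0); w <- c(exp(par - m), exp(-m)); w / sum(w)
  }
  best <- -Inf
  set.seed(31)
  for (r in 1:30) {
    o <- optim(rnorm(3), function(par) -ll(to_h(par)), method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- max(best, -o$value)
  }
  expect_equal(fit$log_likelihood, best, tolerance = 1e-6)
  cross <- unname(coef(fit)["A*01~B*08"])
  if (is.na(cross)) cross <- 0
  expect_gt(unname(coef(fit)["A*01~B*07"]), cross)
})

test_that("haplotype EM with one locus reduces exactly to allele EM", {
  s <- random_merge_ambiguity(
    generate_genotypes(k_alleles = 5, N = 80, seed = 13), 0.3, seed = 4)
  a <- hla_em(s, n_starts = 3, seed = 1)
  h <- hla_haplo_em(s, n_starts = 3, seed = 1, prune_threshold = 0)
  expect_equal(coef(h)[names(coef(a))], coef(a), tolerance = 1e-9)
  expect_equal(h$log_likelihood, a$log_likelihood, tolerance = 1e-9)
})

test_that("LD is near zero for independent loci and exact for complete association", {
  # complete association 2x2 with h11 = p1 = q1 = 0.5
  hf <- c("A*01~B*07" = 0.5, "A*02~B*08" = 0.5)
  s <- generate_two_locus(hf, N = 200, seed = 3)
  ld <- linkage_disequilibrium(hla_haplo_em(s, n_starts = 3, seed = 1))
  expect_equal(ld$W_n, 1, tolerance = 1e-6)
  expect_true(all(abs(abs(ld$table$D_prime) - 1) < 1e-6))

  # independent loci: estimated D within 3 Monte-Carlo SE of 0
  hf2 <- as.vector(outer(c(0.6, 0.4), c(0.7, 0.3)))
  names(hf2) <- as.vector(outer(c("A*01", "A*02"), c("B*07", "B*08"),
                                function(a, b) paste0(a, "~", b)))
  N <- 800
  s2 <- generate_two_locus(hf2, N = N, seed = 4)
  ld2 <- linkage_disequilibrium(hla_haplo_em(s2, n_starts = 3, seed = 1))
  # SE of D-hat is of order sqrt(p q (1-p)(1-q) / 2N)
  se <- sqrt(0.6 * 0.4 * 0.7 * 0.3 / (2 * N))
  expect_true(all(abs(ld2$table$D) <= 3 * se))
})

test_that("W_n equals its direct formula and is relabeling-invariant", {
  mk_est <- function(h) {
    structure(list(loci = c("A", "B"), frequencies = h, haplotypes = TRUE,
                   n_individuals = 100L, n_gene_copies = 200L,
                   log_likelihood = -1, em_diagnostics = list(),
                   flags = NULL),
              class = "hla_freq")
  }
  set.seed(9)
  h <- runif(6); h <- h / sum(h)
  names(h) <- as.vector(outer(c("A*01", "A*02"),
                              c("B*07", "B*08", "B*09"),
                              function(a, b) paste0(a, "~", b)))
  ld <- linkage_disequilibrium(mk_est(h))
  # independent re-computation from the 2x3 table
  tab <- matrix(h[order(names(h))], nrow = 2, byrow = FALSE)
  tab <- matrix(0, 2, 3)
  a1 <- sub("~.*", "", names(h)); a2 <- sub(".*~", "", names(h))
  r <- match(a1, sort(unique(a1))); cc <- match(a2, sort(unique(a2)))
  for (i in seq_along(h)) tab[r[i], cc[i]] <- h[i]
  p <- rowSums(tab); q <- colSums(tab)
  D <- tab - outer(p, q)
  wn_direct <- sqrt(sum(D^2 / outer(p, q)) / (min(dim(tab)) - 1))
  expect_equal(ld$W_n, wn_direct, tolerance = 1e-12)

  # relabel alleles at both loci: W_n unchanged
  relab <- h
  names(relab) <- gsub("A\\*01", "A*91", names(relab))
  names(relab) <- gsub("B\\*07", "B*95", names(relab))
  expect_equal(linkage_disequilibrium(mk_est(relab))$W_n, ld$W_n,
               tolerance = 1e-12)

  # degenerate locus: error
  mono <- c("A*01~B*07" = 0.6, "A*01~B*08" = 0.4)
  expect_error(linkage_disequilibrium(mk_est(mono)), "monomorphic")
})
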