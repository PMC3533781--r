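#' Maximum-likelihood haplotype frequencies from unphased ambiguous data
#'
#' EM estimation of multi-locus haplotype frequencies.  Each individual's
#' candidate multi-locus genotypes (unphased, possibly ambiguous) are
#' expanded to their compatible phased haplotype pairs; the E-step weights a
#' diplotype \eqn{(j,k)} by \eqn{h_j h_k} (doubled when \eqn{j \ne k}) and
#' the M-step re-estimates each haplotype's frequency as its expected count
#' over \eqn{2N}.  Haplotypes whose frequency falls below
#' \code{prune_threshold} are dropped between iterations (unless that would
#' leave an individual unexplained) and the remaining frequencies
#' renormalized; this bounds the state space that heterozygosity at many
#' loci would otherwise blow up.  With a single locus the procedure reduces
#' exactly to \code{\link{hla_em}}.
#'
#' @param s an \code{hla_sample} (any number of loci).
#' @param n_starts,tol_loglik,tol_freq,max_iter,seed as in
#'   \code{\link{hla_em}}.
#' @param prune_threshold haplotype-frequency pruning threshold; default
#'   \code{1/(10 * 2N)}.
#' @param expansion_cap maximum number of phased diplotypes per individual
#'   (default 1e6); exceeding it is an error suggesting resolution reduction
#'   via \code{\link{transliterate_sample}}.
#' @return an \code{hla_freq} whose names are haplotypes written
#'   \code{"allele1~allele2~..."} in locus order.
#' @export
hla_haplo_em <- function(s, n_starts = 5L, tol_loglik = 1e-8,
                         tol_freq = 1e-9, max_iter = 5000L, seed = 1L,
                         prune_threshold = NULL, expansion_cap = 1e6) {
  stopifnot(inherits(s, "hla_sample"))
  N <- length(s$genotypes)
  if (N == 0L) stop("empty sample", call. = FALSE)
  if (is.null(prune_threshold)) prune_threshold <- 1 / (10 * 2 * N)

  # expand each unique candidate set to phased diplotypes
  keys <- vapply(s$genotypes, candidate_keys_joined, character(1))
  counts <- table(factor(keys, levels = unique(keys)))
  reps <- s$genotypes[match(names(counts), keys)]
  hap_env <- new.env(parent = emptyenv())
  hap_names <- character()
  hap_id <- function(h) {
    key <- paste(h, collapse = "~")
    id <- hap_env[[key]]
    if (is.null(id)) {
      id <- length(hap_names) + 1L
      hap_names[[id]] <<- key
      hap_env[[key]] <- id
    }
    id
  }
  j1 <- integer(); j2 <- integer(); grp <- integer()
  for (g in seq_along(reps)) {
    dips <- list()
    for (cand in reps[[g]]$candidates) {
      d <- expand_diplotypes(cand, expansion_cap)
      dips <- c(dips, d)
      if (length(dips) > expansion_cap)
        stop(sprintf(paste0("diplotype expansion for individual '%s' ",
                            "exceeds %g; reduce typing resolution first ",
                            "(transliterate_sample)"),
                     reps[[g]]$id, expansion_cap), call. = FALSE)
    }
    dips <- unique(dips)
    for (d in dips) {
      j1 <- c(j1, hap_id(d[[1]])); j2 <- c(j2, hap_id(d[[2]]))
      grp <- c(grp, g)
    }
  }
  H <- length(hap_names)
  agg <- list(i1 = j1, i2 = j2, grp = grp, count = as.numeric(counts), N = N)

  starts <- with_seed(seed, {
    c(list(rep(1 / H, H)),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
        g <- stats::rgamma(H, 1); g / sum(g)
      }))
  })
  sols <- lapply(starts, function(p0)
    haplo_em_run(p0, agg, tol_loglik, tol_freq, max_iter, prune_threshold))
  fit <- sols[[which.max(vapply(sols, `[[`, numeric(1), "loglik"))]]
  keep <- fit$p > 0
  p <- stats::setNames(fit$p[keep], hap_names[keep])
  p <- p[order(-p, names(p))]
  est <- structure(list(
    loci = s$loci,
    frequencies = p / sum(p),
    haplotypes = TRUE,
    n_individuals = N,
    n_gene_copies = 2L * N,
    log_likelihood = fit$loglik,
    em_diagnostics = list(
      n_starting_points = length(sols),
      n_distinct_solutions = count_distinct_solutions_named(sols, hap_names),
      convergence_criterion = sprintf(
        "|delta logL| < %g or sup-norm freq change < %g (met: %s); prune < %g",
        tol_loglik, tol_freq, fit$criterion, prune_threshold),
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

# all phased haplotype pairs compatible with one unphased multi-locus
# candidate (list of per-locus unordered pairs); 2^(h-1) pairs for h
# heterozygous loci, with the first heterozygous locus's orientation fixed
expand_diplotypes <- function(cand, cap = 1e6) {
  L <- length(cand)
  het <- vapply(cand, function(p) p[1] != p[2], logical(1))
  nh <- sum(het)
  n_dip <- max(1L, 2^(max(0L, nh - 1L)))
  if (n_dip > cap)
    stop(sprintf("diplotype expansion of one candidate exceeds %g", cap),
         call. = FALSE)
  first_het <- which(het)[1]
  flips <- if (nh <= 1L) matrix(FALSE, nrow = n_dip, ncol = max(1L, nh))
           else as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), nh - 1L)))
  lapply(seq_len(n_dip), function(r) {
    h1 <- character(L); h2 <- character(L)
    fi <- 0L
    for (l in seq_len(L)) {
      if (!het[l]) { h1[l] <- cand[[l]][1]; h2[l] <- cand[[l]][2] }
      else if (l == first_het) { h1[l] <- cand[[l]][1]; h2[l] <- cand[[l]][2] }
      else {
        fi <- fi + 1L
        if (nh > 1L && flips[r, fi]) { h1[l] <- cand[[l]][2]; h2[l] <- cand[[l]][1] }
        else { h1[l] <- cand[[l]][1]; h2[l] <- cand[[l]][2] }
      }
    }
    # canonical diplotype order so duplicates collapse
    k1 <- paste(h1, collapse = "~"); k2 <- paste(h2, collapse = "~")
    if (k1 <= k2) list(h1, h2) else list(h2, h1)
  })
}

haplo_em_run <- function(p, agg, tol_loglik, tol_freq, max_iter,
                         prune_threshold) {
  ll_old <- -Inf
  het <- ifelse(agg$i1 == agg$i2, 1, 2)
  twoN <- 2 * agg$N
  ngrp <- length(agg$count)
  active_rows <- rep(TRUE, length(agg$i1))
  for (it in seq_len(max_iter)) {
    i1 <- agg$i1[active_rows]; i2 <- agg$i2[active_rows]
    g_row <- het[active_rows] * p[i1] * p[i2]
    s_grp <- rowsum_vec(g_row, agg$grp[active_rows], ngrp)
    ll <- sum(agg$count * log(s_grp))
    w_row <- agg$count[agg$grp[active_rows]] * g_row / s_grp[agg$grp[active_rows]]
    cnt <- rowsum_vec(w_row, i1, length(p)) + rowsum_vec(w_row, i2, length(p))
    p_new <- cnt / twoN
    # prune rare haplotypes unless that would leave a group with no rows
    low <- which(p_new > 0 & p_new < prune_threshold)
    if (length(low)) {
      drop_rows <- active_rows & (agg$i1 %in% low | agg$i2 %in% low)
      remaining <- tabulate(agg$grp[active_rows & !drop_rows], ngrp)
      if (all(remaining > 0L)) {
        p_new[low] <- 0
        p_new <- p_new / sum(p_new)
        active_rows <- active_rows & !drop_rows
      }
    }
    d_ll <- ll - ll_old
    d_p <- max(abs(p_new - p))
    p <- p_new
    if (it > 1L && abs(d_ll) < tol_loglik)
      return(list(p = p, loglik = ll, iters = it, criterion = "loglik"))
    if (d_p < tol_freq)
      return(list(p = p, loglik = ll, iters = it, criterion = "frequency"))
    ll_old <- ll
  }
  stop(sprintf("haplotype EM did not converge in %d iterations", max_iter),
       call. = FALSE)
}

count_distinct_solutions_named <- function(sols, hap_names,
                                           tol_ll = 0.01, tol_p = 1e-4) {
  count_distinct_solutions(sols, tol_ll, tol_p)
}

#' Pairwise linkage disequilibrium from haplotype frequencies
#'
#' For a two-locus haplotype frequency estimate, computes the raw
#' disequilibrium \eqn{D_{jk} = h_{jk} - p_j q_k} for every allele pair, the
#' normalized \eqn{D'_{jk} = D_{jk}/D_{max}} with the conventional bounds,
#' and the overall normalized measure
#' \deqn{W_n = \sqrt{\frac{\sum_{jk} D_{jk}^2/(p_j q_k)}{\min(k_1,k_2)-1}}}
#' (the multi-allelic extension of the correlation coefficient,
#' \eqn{W_n \in [0,1]}).
#'
#' @param est an \code{hla_freq} from \code{\link{hla_haplo_em}} over
#'   exactly 2 loci.
#' @return an object of class \code{hla_ld}: per-haplotype table with
#'   \code{D} and \code{D_prime}, and the scalar \code{W_n}.
#' @export
linkage_disequilibrium <- function(est) {
  stopifnot(inherits(est, "hla_freq"))
  if (length(est$loci) != 2L)
    stop("linkage_disequilibrium needs a 2-locus haplotype estimate",
         call. = FALSE)
  parts <- strsplit(names(est$frequencies), "~", fixed = TRUE)
  a1 <- vapply(parts, `[`, character(1), 1L)
  a2 <- vapply(parts, `[`, character(1), 2L)
  al1 <- sort(unique(a1)); al2 <- sort(unique(a2))
  if (length(al1) < 2L || length(al2) < 2L)
    stop("W_n undefined: a locus is monomorphic in the haplotype table",
         call. = FALSE)
  h <- matrix(0, length(al1), length(al2), dimnames = list(al1, al2))
  h[cbind(match(a1, al1), match(a2, al2))] <- est$frequencies
  p <- rowSums(h); q <- colSums(h)
  D <- h - outer(p, q)
  Dmax <- ifelse(D >= 0,
                 pmin(outer(p, 1 - q), outer(1 - p, q)),
                 pmin(outer(p, q), outer(1 - p, 1 - q)))
  Dp <- ifelse(Dmax > 0, D / Dmax, 0)
  Wn <- sqrt(sum(D^2 / outer(p, q)) / (min(length(al1), length(al2)) - 1))
  tab <- data.frame(
    allele1 = rep(al1, times = length(al2)),
    allele2 = rep(al2, each = length(al1)),
    haplotype_freq = as.vector(h),
    D = as.vector(D),
    D_prime = as.vector(Dp))
  structure(list(loci = est$loci, table = tab, W_n = Wn),
            class = "hla_ld")
}

#' @export
print.hla_ld <- function(x, digits = 4, ...) {
  cat(sprintf("Linkage disequilibrium %s x %s: W_n = %.4f\n",
              x$loci[1], x$loci[2], x$W_n))
  df <- x$table
  df$haplotype_freq <- round(df$haplotype_freq, digits)
  df$D <- round(df$D, digits)
  df$D_prime <- round(df$D_prime, digits)
  print(df)
  invisible(x)
}
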