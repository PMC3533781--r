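#' Allele-frequency significance threshold for a sample size
#'
#' The smallest allele frequency that is significantly different from zero
#' in a sample of \code{N} individuals (2N gene copies), i.e. the threshold
#' below which the 95\% confidence interval contains 0.  Frequency estimates
#' below it are "nonsignificant": the allele may well be absent from the
#' population, or an absent allele may well have such a frequency.
#'
#' Three sampling models are supported:
#' \describe{
#'   \item{I (two-tail normal)}{solves \eqn{p = z\sqrt{p(1-p)/2N}} with
#'     \eqn{z = 2} ("two standard deviations"), closed form
#'     \eqn{p^* = z^2/(2N + z^2)}.}
#'   \item{II (one-tail normal)}{same form with the one-tail quantile
#'     \eqn{z_1} (default 1.645).  Flagged approximate: published tables of
#'     this column are not reproduced by this analogue and no formula is
#'     documented for them.}
#'   \item{III (exact binomial)}{solves \eqn{(1-p)^{2N} = \alpha}, i.e.
#'     \eqn{p^* = 1 - \alpha^{1/2N}}: the frequency at which a sample of 2N
#'     copies misses the allele entirely with probability \eqn{\alpha}.}
#' }
#'
#' @param N number of individuals.
#' @param model \code{"I_normal_two_tail"}, \code{"II_normal_one_tail"} or
#'   \code{"III_exact_binomial"} (prefix matching allowed via "I", "II",
#'   "III").
#' @param alpha significance level (default 0.05; models I/II use quantiles
#'   \code{z}/\code{z_one_tail} directly).
#' @param z normal quantile for model I (default 2).
#' @param z_one_tail normal quantile for model II (default 1.645).
#' @return threshold in percent, rounded half away from zero to 2 decimals;
#'   the unrounded percent is attached as attribute \code{"unrounded"}.
#' @examples
#' frequency_threshold(50)          # 3.85
#' frequency_threshold(500, "III")  # 0.30
#' @export
frequency_threshold <- function(N, model = c("I_normal_two_tail",
                                             "II_normal_one_tail",
                                             "III_exact_binomial"),
                                alpha = 0.05, z = 2, z_one_tail = 1.645) {
  if (length(model) == 1L && model %in% c("I", "II", "III"))
    model <- c(I = "I_normal_two_tail", II = "II_normal_one_tail",
               III = "III_exact_binomial")[[model]]
  model <- match.arg(model)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be an integer >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  p <- switch(model,
              I_normal_two_tail = z^2 / (2 * N + z^2),
              II_normal_one_tail = z_one_tail^2 / (2 * N + z_one_tail^2),
              III_exact_binomial = 1 - alpha^(1 / (2 * N)))
  pct <- 100 * p
  structure(round_half_away(pct, 2L), unrounded = pct, model = model)
}

#' Threshold table across sample sizes
#'
#' Reproduces the significance-threshold table for a set of sample sizes:
#' one row per N, one column per sampling model, in percent to 2 decimals.
#' Thresholds decrease monotonically with N.
#'
#' @param Ns integer vector of sample sizes (default the published grid
#'   30, 50, 100, 150, 200, 500).
#' @return data frame with columns \code{N}, \code{model_I}, \code{model_II},
#'   \code{model_III}.
#' @export
threshold_table <- function(Ns = c(30L, 50L, 100L, 150L, 200L, 500L)) {
  data.frame(
    N = Ns,
    model_I = vapply(Ns, function(n)
      as.numeric(frequency_threshold(n, "I_normal_two_tail")), numeric(1)),
    model_II = vapply(Ns, function(n)
      as.numeric(frequency_threshold(n, "II_normal_one_tail")), numeric(1)),
    model_III = vapply(Ns, function(n)
      as.numeric(frequency_threshold(n, "III_exact_binomial")), numeric(1)))
}

#' Printed reference threshold table
#'
#' The packaged copy of the published threshold table (percent), used to
#' mark cells where the computed table deviates from the printed one (a few
#' printed cells differ from the formulas by up to 0.02, and the one-tail
#' normal column follows no documented formula).
#'
#' @return data frame with the same shape as \code{\link{threshold_table}}.
#' @export
printed_threshold_table <- function() {
  path <- system.file("extdata", "printed_threshold_table.tsv",
                      package = "hlapop", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#")
}

#' Minimum sample-size advisory
#'
#' Population-reporting guidelines set a minimal threshold of 100 individuals
#' per sample; this returns a warning message for smaller samples and notes
#' that larger samples detect more alleles.
#'
#' @param N number of individuals.
#' @return character scalar advisory (empty when no warning applies), with
#'   attribute \code{"warning"} (logical).
#' @export
minimum_sample_check <- function(N) {
  if (N < 100) {
    msg <- sprintf(paste0(
      "sample of %d individuals is below the recommended minimal threshold ",
      "of 100; keep sample sizes as close as possible to this threshold. ",
      "Larger samples detect more alleles and estimate low frequencies ",
      "more reliably."), N)
    structure(msg, warning = TRUE)
  } else {
    structure("", warning = FALSE)
  }
}
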