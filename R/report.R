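#' Run the standard analysis pipeline
#'
#' Executes the recommended analysis chain on one sample: validate ->
#' (optional) expand/interpret -> (optional) transliterate -> EM frequency
#' estimation -> Hardy-Weinberg assessment -> Ewens-Watterson neutrality ->
#' sample-size threshold context -> report.  Every stage is recorded with
#' its parameters; skipping the mandatory HWE assessment while reporting
#' allele frequencies marks the report incomplete.
#'
#' @param config a named list or path to a YAML file with keys:
#'   \code{input} (sample file path) and \code{dialect}
#'   (\code{"tabular"}/\code{"glstring"}), or \code{sample} (an
#'   \code{hla_sample} directly); optional \code{transliterate_level},
#'   \code{mapping} (TSV path), \code{strict} (fail on validation
#'   violations), \code{run_hwe}/\code{run_neutrality} (default TRUE),
#'   \code{hwe_alternative}, \code{threshold_model}, \code{n_starts},
#'   \code{replicates}, \code{seed}.
#' @return an object of class \code{hla_report}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(
    dialect = "tabular", transliterate_level = NULL, mapping = NULL,
    strict = FALSE, strict_pair_list = FALSE,
    run_hwe = TRUE, run_neutrality = TRUE,
    hwe_alternative = "inbreeding",
    threshold_model = "I_normal_two_tail",
    n_starts = 5L, replicates = 10000L, seed = 1L), config)
  log <- list()
  stage <- function(name, params) log[[length(log) + 1L]] <<-
    c(list(stage = name), params)

  s <- if (!is.null(cfg$sample)) cfg$sample
  else switch(cfg$dialect,
              tabular = read_sample_tabular(cfg$input),
              glstring = read_sample_glstring(cfg$input),
              stop("unknown dialect: ", cfg$dialect, call. = FALSE))
  stage("load", list(n = length(s$genotypes),
                     locus = paste(s$loci, collapse = "^")))

  val <- validate_sample(s, strict_pair_list = cfg$strict_pair_list,
                         strict = cfg$strict)
  stage("validate", list(violations = length(val$violations)))

  if (!is.null(cfg$mapping)) {
    s <- transliterate_sample(s, read_mapping(cfg$mapping))
    stage("transliterate", list(mapping = cfg$mapping))
  } else if (!is.null(cfg$transliterate_level)) {
    m <- resolution_mapping(sample_alleles(s), cfg$transliterate_level)
    s <- suppressWarnings(transliterate_sample(s, m))
    stage("transliterate", list(level = cfg$transliterate_level))
  }

  est <- hla_em(s, n_starts = cfg$n_starts, seed = cfg$seed)
  est <- flag_nonsignificant(est, model = cfg$threshold_model)
  stage("frequencies", est$em_diagnostics)

  hwe <- NULL
  if (isTRUE(cfg$run_hwe)) {
    hwe <- hwe_test(s, alternative = cfg$hwe_alternative, seed = cfg$seed)
    stage("hwe", list(method = hwe$method, p = hwe$p_value))
  }
  neut <- NULL
  if (isTRUE(cfg$run_neutrality) && length(est$frequencies) >= 2L) {
    neut <- ewens_watterson_test(est, replicates = cfg$replicates,
                                 seed = cfg$seed)
    stage("neutrality", list(replicates = cfg$replicates,
                             p_low = neut$p_low))
  }
  thr <- frequency_threshold(est$n_individuals, model = cfg$threshold_model)
  advisory <- minimum_sample_check(est$n_individuals)
  stage("thresholds", list(model = cfg$threshold_model,
                           percent = as.numeric(thr)))

  violations <- val$violations
  if (is.null(hwe))
    violations <- c(violations,
                    "incomplete: HWE assessment is mandatory whenever allele frequencies are reported")
  structure(list(
    metadata = s$metadata,
    validation = val,
    frequencies = est,
    hwe = hwe,
    neutrality = neut,
    threshold = list(N = est$n_individuals, model = cfg$threshold_model,
                     percent = as.numeric(thr)),
    sample_size_advisory = as.character(advisory),
    report_violations = violations,
    complete = !is.null(hwe) && val$ok,
    provenance = list(package = "hlapop",
                      version = as.character(utils::packageVersion("hlapop")),
                      seed = cfg$seed,
                      config = cfg[setdiff(names(cfg), "sample")],
                      log = log)),
    class = "hla_report")
}

#' @export
print.hla_report <- function(x, ...) {
  cat("=== HLA population analysis report ===\n")
  if (nzchar(x$metadata$population_name))
    cat("Population:", x$metadata$population_name, "\n")
  cat("Ethics:", if (nzchar(x$metadata$ethics_statement))
    x$metadata$ethics_statement else "(none provided)", "\n\n")
  print(x$frequencies)
  cat(sprintf("\nThreshold (model %s, N = %d): %.2f%%\n",
              x$threshold$model, x$threshold$N, x$threshold$percent))
  if (nzchar(x$sample_size_advisory))
    cat("Advisory:", x$sample_size_advisory, "\n")
  if (!is.null(x$hwe)) { cat("\n"); print(x$hwe) }
  if (!is.null(x$neutrality)) { cat("\n"); print(x$neutrality) }
  if (length(x$report_violations)) {
    cat("\nReport violations:\n")
    cat(paste0("  - ", x$report_violations, collapse = "\n"), "\n")
  }
  cat(sprintf("\n[%s %s, seed %s, %s]\n", x$provenance$package,
              x$provenance$version, x$provenance$seed,
              if (x$complete) "complete" else "INCOMPLETE"))
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Every number in the JSON traces to a module output; nothing is
#' recomputed in the presentation layer.
#'
#' @param report an \code{hla_report}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_report_json <- function(report, path) {
  est <- report$frequencies
  out <- list(
    metadata = unclass(report$metadata),
    validation = report$validation$violations,
    frequencies = list(
      loci = est$loci,
      n_individuals = est$n_individuals,
      n_gene_copies = est$n_gene_copies,
      estimates = as.list(est$frequencies),
      flags = est$flags,
      log_likelihood = est$log_likelihood,
      em_diagnostics = est$em_diagnostics),
    hwe = if (!is.null(report$hwe))
      report$hwe[c("method", "statistic", "df", "p_value", "f_hat",
                   "ambiguity_fraction")],
    neutrality = if (!is.null(report$neutrality))
      report$neutrality[c("F_obs", "F_null_mean", "F_null_sd", "p_low",
                          "p_high", "k", "n", "theta_hat", "replicates",
                          "seed")],
    threshold = report$threshold,
    sample_size_advisory = report$sample_size_advisory,
    report_violations = report$report_violations,
    complete = report$complete,
    provenance = report$provenance[c("package", "version", "seed")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

# draw the frequency bar chart on the current device
barchart_freq <- function(est, main = NULL, ...) {
  p <- sort(est$frequencies, decreasing = TRUE)
  se <- sqrt(p * (1 - p) / est$n_gene_copies)
  nonsig <- if (!is.null(est$flags) &&
                !all(is.na(est$flags$nonsignificant))) {
    est$flags$nonsignificant[match(names(p), est$flags$allele)]
  } else rep(FALSE, length(p))
  dens <- ifelse(nonsig, 20, NA)  # hatched bars mark nonsignificant alleles
  mid <- graphics::barplot(p, names.arg = names(p), las = 2,
                           col = ifelse(nonsig, "grey70", "steelblue"),
                           density = dens,
                           ylab = "estimated frequency",
                           ylim = c(0, min(1, max(p + 2 * se) * 1.15)),
                           main = main %||%
                             sprintf("Locus %s (N = %d)",
                                     paste(est$loci, collapse = "^"),
                                     est$n_individuals), ...)
  graphics::arrows(mid, pmax(0, p - 2 * se), mid, p + 2 * se,
                   angle = 90, code = 3, length = 0.04)
  invisible(mid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the frequency bar chart to a file
#'
#' Bar charts (never pie charts) are the recommended graphic for frequency
#' reporting.  Bars are sorted by descending frequency with whiskers at
#' plus/minus two standard errors; nonsignificant alleles are hatched.
#' SVG output contains no timestamp, so it is byte-stable for fixed input.
#'
#' @param est an \code{hla_freq} (run \code{\link{flag_nonsignificant}}
#'   first to mark nonsignificant alleles).
#' @param path output file.
#' @param format \code{"svg"} or \code{"png"}.
#' @param width,height device size in inches (svg) / pixels (png).
#' @return the path, invisibly.
#' @export
render_barchart <- function(est, path, format = c("svg", "png"),
                            width = 7, height = 5) {
  format <- match.arg(format)
  if (format == "svg") grDevices::svg(path, width = width, height = height)
  else grDevices::png(path, width = width * 100, height = height * 100)
  on.exit(grDevices::dev.off())
  barchart_freq(est)
  invisible(path)
}
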