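#' Per-sample analytical specificity (false-positive rate)
#'
#' A sample passes specificity when at most 20 percent of its truly
#' negative cells are called positive. A slide flagged for diffuse
#' alkaline-phosphatase background is recorded as a specificity failure
#' regardless of its rate: that artifact is exactly the failure mode the
#' criterion exists to catch.
#'
#' @param truth_positive Logical vector: true per-cell positivity
#'   (pathologist labels in a clinical run; renderer ground truth here).
#' @param pred_positive Logical vector, aligned by cell: called positive.
#' @param artifact_flagged Whether the slide carries the AP artifact flag.
#' @param max_fp_rate Pass threshold on the FP rate (default 0.20).
#' @return List with `fp_rate`, `n_negative`, `pass`, and `reason`.
#' @export
evaluate_specificity <- function(truth_positive, pred_positive,
                                 artifact_flagged = FALSE,
                                 max_fp_rate = 0.20) {
  check_aligned(truth_positive, pred_positive)
  n_neg <- sum(!truth_positive)
  if (n_neg == 0L)
    stop("FP rate undefined: no truly negative cells", call. = FALSE)
  fp <- sum(!truth_positive & pred_positive) / n_neg
  pass <- fp <= max_fp_rate && !artifact_flagged
  reason <- if (artifact_flagged)
    "artifact-flagged: diffuse AP background"
  else if (fp > max_fp_rate)
    sprintf("FP rate %.3f > %.2f", fp, max_fp_rate)
  else ""
  list(fp_rate = fp, n_negative = n_neg, pass = pass, reason = reason)
}

#' Per-sample analytical sensitivity (false-negative rate)
#'
#' Mirror of [evaluate_specificity()]: a sample passes when at most 20
#' percent of its truly positive cells are called negative.
#'
#' @inheritParams evaluate_specificity
#' @param max_fn_rate Pass threshold on the FN rate (default 0.20).
#' @return List with `fn_rate`, `n_positive`, `pass`, and `reason`.
#' @export
evaluate_sensitivity <- function(truth_positive, pred_positive,
                                 max_fn_rate = 0.20) {
  check_aligned(truth_positive, pred_positive)
  n_pos <- sum(truth_positive)
  if (n_pos == 0L)
    stop("FN rate undefined: no truly positive cells", call. = FALSE)
  fn <- sum(truth_positive & !pred_positive) / n_pos
  list(fn_rate = fn, n_positive = n_pos, pass = fn <= max_fn_rate,
       reason = if (fn <= max_fn_rate) "" else
         sprintf("FN rate %.3f > %.2f", fn, max_fn_rate))
}

check_aligned <- function(truth, pred) {
  if (!is.logical(truth) || !is.logical(pred) ||
      length(truth) != length(pred) || anyNA(truth) || anyNA(pred))
    stop("truth and prediction must be aligned logical vectors",
         call. = FALSE)
}

#' Accuracy: correlation against an orthogonal measurement
#'
#' Accuracy passes with a positive correlation at p <= 0.05 between the
#' H-scores and the orthogonal values (qPCR for the staining assay,
#' manual H-scores for the digital algorithm). The Spearman p-value is
#' exact (full permutation distribution) for n < 10 without ties and uses
#' the t approximation otherwise.
#'
#' @param h_scores Numeric vector of per-sample H-scores.
#' @param orthogonal Paired orthogonal values, same order.
#' @param method `"spearman"` or `"pearson"`.
#' @param alpha Significance level (default 0.05).
#' @return List with `coefficient`, `p_value`, `n`, `method`, `pass`.
#' @export
evaluate_accuracy <- function(h_scores, orthogonal,
                              method = c("spearman", "pearson"),
                              alpha = 0.05) {
  method <- match.arg(method)
  if (length(h_scores) != length(orthogonal) || anyNA(h_scores) ||
      anyNA(orthogonal))
    stop("paired vectors without missing values required", call. = FALSE)
  n <- length(h_scores)
  if (n < 3)
    stop("at least 3 paired samples required", call. = FALSE)
  if (stats::sd(h_scores) == 0 || stats::sd(orthogonal) == 0)
    stop("correlation undefined on a constant vector", call. = FALSE)
  ct <- if (method == "spearman") {
    ties <- anyDuplicated(h_scores) > 0 || anyDuplicated(orthogonal) > 0
    suppressWarnings(stats::cor.test(h_scores, orthogonal,
                                     method = "spearman",
                                     exact = n < 10 && !ties))
  } else {
    stats::cor.test(h_scores, orthogonal, method = "pearson")
  }
  coef <- unname(ct$estimate)
  p <- ct$p.value
  list(coefficient = coef, p_value = p, n = n, method = method,
       pass = coef > 0 && p <= alpha)
}

#' Precision over three staining-day replicates
#'
#' Each sample is stained on three different days. A sample passes when
#' all three replicate H-scores fall in the same expression bin
#' (negative H = 0, low 0 < H < 35, high H >= 35), or, with discordant
#' bins, when the replicates still span at most 20 H-score points
#' (max - min <= 20; for three values this equals the pairwise +/- 20
#' reading). The cohort passes when at least `min_pass_frac` of samples
#' pass.
#'
#' @param replicates Data frame with columns `sample_id` and `h_score`
#'   (long form, exactly 3 rows per sample), or a list of numeric
#'   length-3 vectors named by sample.
#' @param min_pass_frac Cohort pass threshold (default 0.80).
#' @param max_range Tolerated replicate H-score range under discordant
#'   binning (default 20).
#' @return List with `per_sample` (data frame: `sample_id`, bins,
#'   `h_range`, `pass`, `reason`), `n`, `n_pass`, `pass_frac`, `pass`.
#' @examples
#' evaluate_precision(list(a = c(0, 0, 0), b = c(32, 54, 75)))
#' @export
evaluate_precision <- function(replicates, min_pass_frac = 0.80,
                               max_range = 20) {
  if (is.data.frame(replicates)) {
    if (!all(c("sample_id", "h_score") %in% names(replicates)))
      stop("data frame input needs columns sample_id, h_score",
           call. = FALSE)
    replicates <- split(replicates$h_score, replicates$sample_id)
  }
  if (length(replicates) == 0L)
    stop("no precision samples supplied", call. = FALSE)
  if (is.null(names(replicates)))
    names(replicates) <- sprintf("sample%02d", seq_along(replicates))
  rows <- lapply(names(replicates), function(id) {
    h <- replicates[[id]]
    if (length(h) != 3L)
      stop(sprintf("sample '%s' has %d replicates; exactly 3 required",
                   id, length(h)), call. = FALSE)
    if (anyNA(h) || any(h < 0 | h > 300))
      stop(sprintf("sample '%s': H-scores must lie in [0, 300]", id),
           call. = FALSE)
    bins <- assign_expression_bin(h)
    rng <- max(h) - min(h)
    concordant <- length(unique(bins)) == 1L
    pass <- concordant || rng <= max_range
    data.frame(sample_id = id,
               bins = paste(bins, collapse = "/"),
               h_range = rng, concordant_bins = concordant, pass = pass,
               reason = if (pass) "" else
                 sprintf("discordant bins (%s) with H range %.1f > %g",
                         paste(sort(unique(bins)), collapse = " vs "),
                         rng, max_range),
               stringsAsFactors = FALSE)
  })
  per_sample <- do.call(rbind, rows)
  n <- nrow(per_sample); n_pass <- sum(per_sample$pass)
  list(per_sample = per_sample, n = n, n_pass = n_pass,
       pass_frac = n_pass / n, pass = n_pass / n >= min_pass_frac)
}

#' Roll per-sample results up into a validation report
#'
#' Applies the cohort acceptance thresholds: the staining-assay profile
#' requires 90 percent of samples to pass specificity and sensitivity,
#' the digital-algorithm profile 85 percent; both require a passing
#' accuracy correlation and at least 80 percent precision passes.
#'
#' @param specificity Logical vector (or data frame with `sample_id`,
#'   `pass`) of per-sample specificity verdicts.
#' @param sensitivity Same, for sensitivity.
#' @param accuracy Result of [evaluate_accuracy()], or `NULL`.
#' @param precision Result of [evaluate_precision()], or `NULL`.
#' @param profile `"algorithm"` (85 percent) or `"assay"` (90 percent).
#' @param excluded Optional data frame (`sample_id`, `reason`) listing
#'   samples excluded before evaluation (e.g. specificity failures
#'   removed ahead of the accuracy correlation); fractions count
#'   evaluated samples only.
#' @return An object of class `"validation_report"`: a `parameters` data
#'   frame mirroring the published validation tables (parameter, n,
#'   fraction or statistic, verdict), the per-parameter details, the
#'   profile and thresholds, and the exclusion list.
#' @export
cohort_rollup <- function(specificity = NULL, sensitivity = NULL,
                          accuracy = NULL, precision = NULL,
                          profile = c("algorithm", "assay"),
                          excluded = NULL) {
  profile <- match.arg(profile)
  spec_sens_frac <- if (profile == "assay") 0.90 else 0.85
  as_pass <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.data.frame(x)) as.logical(x$pass) else as.logical(x)
  }
  sp <- as_pass(specificity); se <- as_pass(sensitivity)
  if (is.null(sp) && is.null(se) && is.null(accuracy) && is.null(precision))
    stop("empty cohort: no per-sample results supplied", call. = FALSE)
  rows <- list()
  frac_row <- function(param, pass_vec, threshold) {
    n <- length(pass_vec); k <- sum(pass_vec)
    data.frame(parameter = param, n = n,
               result = sprintf("%.0f%% (%d/%d)", 100 * k / n, k, n),
               fraction = k / n, threshold = threshold,
               pass = (k / n) >= threshold, stringsAsFactors = FALSE)
  }
  if (!is.null(sp))
    rows$specificity <- frac_row("Analytical specificity", sp,
                                 spec_sens_frac)
  if (!is.null(se))
    rows$sensitivity <- frac_row("Analytical sensitivity", se,
                                 spec_sens_frac)
  if (!is.null(accuracy))
    rows$accuracy <- data.frame(
      parameter = "Accuracy", n = accuracy$n,
      result = sprintf("%s = %.3f, p = %.4g",
                       if (accuracy$method == "spearman") "rho" else "r",
                       accuracy$coefficient, accuracy$p_value),
      fraction = NA_real_, threshold = NA_real_,
      pass = accuracy$pass, stringsAsFactors = FALSE)
  if (!is.null(precision))
    rows$precision <- data.frame(
      parameter = "Precision", n = precision$n,
      result = sprintf("%.0f%% (%d/%d)", 100 * precision$pass_frac,
                       precision$n_pass, precision$n),
      fraction = precision$pass_frac, threshold = 0.80,
      pass = precision$pass, stringsAsFactors = FALSE)
  params <- do.call(rbind, unname(rows))
  structure(list(parameters = params, profile = profile,
                 spec_sens_threshold = spec_sens_frac,
                 precision_threshold = 0.80,
                 accuracy = accuracy, precision = precision,
                 excluded = excluded,
                 overall_pass = all(params$pass)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (%s profile: spec/sens >= %.0f%%)\n",
              x$profile, 100 * x$spec_sens_threshold))
  p <- x$parameters
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-24s n=%-3d %-22s %s\n", p$parameter[i], p$n[i],
                p$result[i], if (p$pass[i]) "Pass" else "FAIL"))
  if (!is.null(x$excluded) && nrow(x$excluded) > 0) {
    cat("  excluded samples:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("    %s: %s\n", x$excluded$sample_id[i],
                  x$excluded$reason[i]))
  }
  cat("  overall:", if (x$overall_pass) "Pass" else "FAIL", "\n")
  invisible(x)
}
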