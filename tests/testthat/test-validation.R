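# CLIA-style validation harness: specificity, sensitivity, accuracy,
# precision, cohort roll-up.

test_that("specificity is the FP rate over truly negative cells", {
  truth <- rep(c(TRUE, FALSE), c(50, 100))
  perfect <- evaluate_specificity(truth, truth)
  expect_equal(perfect$fp_rate, 0)
  expect_true(perfect$pass)
  pred <- truth; pred[51:75] <- TRUE       # 25 of 100 negatives positive
  r <- evaluate_specificity(truth, pred)
  expect_equal(r$fp_rate, 0.25)
  expect_false(r$pass)
  # exactly at the 20% boundary still passes
  pred2 <- truth; pred2[51:70] <- TRUE
  expect_true(evaluate_specificity(truth, pred2)$pass)
  expect_error(evaluate_specificity(rep(TRUE, 5), rep(TRUE, 5)),
               "no truly negative")
})

test_that("an artifact-flagged slide fails specificity regardless of rate", {
  truth <- rep(c(TRUE, FALSE), c(50, 100))
  r <- evaluate_specificity(truth, truth, artifact_flagged = TRUE)
  expect_equal(r$fp_rate, 0)
  expect_false(r$pass)
  expect_match(r$reason, "artifact")
})

test_that("sensitivity mirrors specificity with the FN rate", {
  truth <- rep(c(TRUE, FALSE), c(100, 50))
  expect_equal(evaluate_sensitivity(truth, truth)$fn_rate, 0)
  pred <- truth; pred[1:30] <- FALSE       # 30 of 100 positives missed
  r <- evaluate_sensitivity(truth, pred)
  expect_equal(r$fn_rate, 0.30)
  expect_false(r$pass)
  expect_error(evaluate_sensitivity(rep(FALSE, 5), rep(FALSE, 5)),
               "no truly positive")
  # rates are bounded and complementary counts add up by construction
  expect_gte(r$fn_rate, 0); expect_lte(r$fn_rate, 1)
})

test_that("accuracy requires a positive significant correlation", {
  x <- 1:20
  r <- evaluate_accuracy(2 * x, x, method = "spearman")
  expect_equal(r$coefficient, 1)
  expect_true(r$pass)
  r2 <- evaluate_accuracy(-1 * x + 0.5 * rnorm(20), x, method = "pearson")
  expect_false(r2$pass)                    # negative coefficient
  expect_error(evaluate_accuracy(rep(1, 10), 1:10), "constant")
  expect_error(evaluate_accuracy(1:2, 1:2), "at least 3")
})

test_that("accuracy power at r = 0.7, n = 20 clears 90% over 500 seeds", {
  passes <- vapply(1:500, function(s) {
    set.seed(s)
    x <- rnorm(20)
    y <- 0.7 * x + sqrt(1 - 0.49) * rnorm(20)
    evaluate_accuracy(x, y, method = "pearson")$pass
  }, logical(1))
  expect_gte(mean(passes), 0.90)
})

test_that("the Spearman evaluator matches an exhaustive permutation oracle", {
  set.seed(41)
  for (n in 3:8) {
    for (rep in 1:3) {
      x <- sample(seq_len(50), n)            # distinct values, no ties
      y <- sample(seq_len(50), n)
      got <- evaluate_accuracy(x, y, method = "spearman", alpha = 0.05)
      want <- spearman_oracle(x, y)
      expect_equal(got$coefficient, want$rho, tolerance = 1e-12)
      expect_equal(got$p_value, want$p, tolerance = 1e-8)
    }
  }
})

test_that("precision applies the binned-concordance-or-20-point rule", {
  r <- evaluate_precision(list(s1 = c(0, 0, 0),        # same bin
                               s2 = c(32, 54, 75),     # low/high, range 43
                               s3 = c(30, 40, 45)))    # discordant, range 15
  expect_equal(r$per_sample$pass, c(TRUE, FALSE, TRUE))
  expect_match(r$per_sample$reason[2], "discordant")
  expect_equal(r$pass_frac, 2 / 3)
  expect_error(evaluate_precision(list(s = c(1, 2))), "exactly 3")
  expect_error(evaluate_precision(list(s = c(1, 2, 400))), "0, 300")
})

test_that("precision verdicts are invariant to replicate order", {
  h <- c(32, 54, 75)
  base <- evaluate_precision(list(s = h))$per_sample$pass
  for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(evaluate_precision(list(s = h[p]))$per_sample$pass, base)
})

test_that("long-form precision input is accepted", {
  df <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                   h_score = c(0, 0, 2, 100, 150, 90))
  r <- evaluate_precision(df)
  expect_equal(nrow(r$per_sample), 2)
  expect_true(all(r$per_sample$pass))      # ranges 2 and 60-but-same-bin
})

test_that("cohort roll-up reproduces the published table arithmetic", {
  # digital-algorithm profile: 36/40 specificity = 90% >= 85% -> pass
  rep1 <- cohort_rollup(
    specificity = rep(c(TRUE, FALSE), c(36, 4)),
    sensitivity = rep(TRUE, 40),
    precision = evaluate_precision(
      c(lapply(1:11, function(i) c(40, 45, 50)), list(c(32, 54, 75)))),
    profile = "algorithm")
  p <- rep1$parameters
  expect_equal(p$result[p$parameter == "Analytical specificity"],
               "90% (36/40)")
  expect_true(p$pass[p$parameter == "Analytical specificity"])
  expect_equal(p$result[p$parameter == "Precision"], "92% (11/12)")
  expect_true(p$pass[p$parameter == "Precision"])
  expect_true(rep1$overall_pass)
  # assay profile needs 90%: 35/40 = 87.5% fails
  rep2 <- cohort_rollup(specificity = rep(c(TRUE, FALSE), c(35, 5)),
                        profile = "assay")
  expect_false(rep2$parameters$pass[1])
  # 7/10 precision under the 80% bar fails
  rep3 <- cohort_rollup(precision = evaluate_precision(
    c(lapply(1:7, function(i) c(10, 12, 14)),
      lapply(8:10, function(i) c(0, 40, 80)))))
  expect_false(rep3$parameters$pass[1])
  expect_error(cohort_rollup(), "empty cohort")
})

test_that("a rendered precision study passes, and a drifting sample fails", {
  # 12 samples x 3 replicate slides; replicate-level jitter only comes
  # from re-drawing counts and layout under new seeds
  specs <- c(rep(list(c(1, 0, 0, 0)), 4),
             rep(list(c(0.1, 0.2, 0.3, 0.4)), 4),
             rep(list(c(0, 0, 0.3, 0.7)), 4))
  h_of <- function(fracs, seed) {
    out <- mini_slide(fracs, n_cells = 25, seed = seed,
                      width = 384, height = 384)
    score_slide(out$image)$h_score
  }
  reps <- lapply(seq_along(specs), function(i)
    vapply(1:3, function(j) h_of(specs[[i]], seed = 100 * i + j),
           numeric(1)))
  names(reps) <- sprintf("s%02d", seq_along(specs))
  r <- evaluate_precision(reps)
  expect_true(r$pass)
  expect_true(all(r$per_sample$pass))
  # inject one sample whose replicates drift across bins by > 20 points
  reps$s05 <- c(h_of(c(1, 0, 0, 0), 901), h_of(c(0.2, 0.3, 0.3, 0.2), 902),
                h_of(c(0, 0, 0.2, 0.8), 903))
  r2 <- evaluate_precision(reps)
  expect_false(r2$per_sample$pass[r2$per_sample$sample_id == "s05"])
  expect_equal(sum(!r2$per_sample$pass), 1)
  expect_true(r2$pass)                     # 11/12 still >= 80%
})
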