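# Punctum detection, declumping, cell assignment, artifact flagging.

test_that("a blank channel has no dots and requires a threshold", {
  ds <- detect_dots(matrix(0, 64, 64), threshold = 0.15)
  expect_equal(nrow(ds$dots), 0)
  expect_error(detect_dots(matrix(0, 4, 4), threshold = NULL), "threshold")
})

test_that("declumping quantizes blob area by the reference dot area", {
  ch <- matrix(0, 64, 64)
  ref_px <- (pi * 0.5^2) / 0.25^2           # 12.57 px at 0.25 um/px
  ch[20:24, 10:17] <- 0.9                   # 40 px ~ 3 reference dots
  ds <- detect_dots(ch, threshold = 0.5)
  expect_equal(nrow(ds$dots), 1)
  expect_equal(ds$dots$mol_equiv, 3L)
  expect_equal(ds$dots$mol_equiv, as.integer(round(40 / ref_px)))
  # a single tiny blob still counts at least one molecule
  ch2 <- matrix(0, 32, 32); ch2[10:11, 10:12] <- 0.9
  expect_equal(detect_dots(ch2, threshold = 0.5,
                           min_area_um2 = 0.1)$dots$mol_equiv, 1L)
})

test_that("isolated rendered dots are detected with F1 >= 0.95", {
  gt <- generate_count_table(bin_fraction_spec(0, 1, 0, 0), 100, seed = 21)
  cfg <- render_config(width = 768, height = 768, min_spacing_um = 12,
                       seed = 21)
  out <- render_slide(gt, cfg)
  ch <- separate_stains(out$image)
  thr <- estimate_dot_threshold(ch$red)
  ds <- detect_dots(ch$red, thr)
  truth <- as.matrix(out$truth$dots[, c("row", "col")])
  det <- as.matrix(ds$dots[, c("row", "col")])
  matched <- match_points(det, truth, radius = 4)
  prec <- matched / nrow(det)
  rec <- matched / nrow(truth)
  f1 <- 2 * prec * rec / (prec + rec)
  expect_gte(f1, 0.95)
})

test_that("dots go to the nearest cell within range, ties to the lower id", {
  cs <- make_cellset(row = c(50, 50), col = c(20, 220))  # 50 um apart
  # at a centroid; equidistant between both; far from everything
  ds <- make_dotset(row = c(50, 50, 10), col = c(20, 120, 600))
  res <- assign_dots_to_cells(ds, cs, max_radius_um = 6.5)
  expect_equal(res$dots$dots$cell_id, c(1L, NA_integer_, NA_integer_))
  # equidistant within range: lower cell id wins
  res2 <- assign_dots_to_cells(ds, cs, max_radius_um = 26)
  expect_equal(res2$dots$dots$cell_id[2], 1L)
  expect_equal(res2$cells$cells$dot_count, c(2L, 0L))
})

test_that("molecule equivalents are conserved through assignment", {
  out <- mini_slide(fracs = c(0.2, 0.3, 0.3, 0.2), n_cells = 25, seed = 22,
                    width = 512, height = 512)
  ch <- separate_stains(out$image)
  thr <- estimate_dot_threshold(ch$red)
  ds <- detect_dots(ch$red, thr)
  cs <- detect_nuclei(ch$hematoxylin)
  res <- assign_dots_to_cells(ds, cs)
  total <- sum(res$dots$dots$mol_equiv)
  assigned <- sum(res$cells$cells$dot_count)
  unassigned <- sum(res$dots$dots$mol_equiv[is.na(res$dots$dots$cell_id)])
  expect_equal(assigned + unassigned, total)
})

test_that("raising the threshold never increases the dot count", {
  out <- mini_slide(n_cells = 20, seed = 23)
  ch <- separate_stains(out$image)
  counts <- sapply(seq(0.1, 1.2, by = 0.1), function(t)
    nrow(detect_dots(ch$red, threshold = t)$dots))
  expect_true(all(diff(counts) <= 0))
})

test_that("pipeline counts equal brute-force truth assignment on isolated slides", {
  gt <- generate_count_table(bin_fraction_spec(0, 1, 0, 0), 40, seed = 24)
  gt$cells$true_dots <- rep(1L, 40)
  # dots are placed well inside the 6.5 um assignment radius so that
  # sub-pixel centroid jitter cannot flip a rim dot in or out of range
  cfg <- render_config(width = 704, height = 704, min_spacing_um = 16,
                       assignment_margin_um = 0.5, seed = 24)
  out <- render_slide(gt, cfg)
  ch <- separate_stains(out$image)
  cs <- detect_nuclei(ch$hematoxylin)
  ds <- detect_dots(ch$red, estimate_dot_threshold(ch$red))
  res <- assign_dots_to_cells(ds, cs)
  # brute force: assign every true dot center to the nearest detected
  # cell centroid (same radius rule), O(n^2) loop
  max_px <- 6.5 / cs$mpp
  brute <- rep(0L, nrow(cs$cells))
  for (i in seq_len(nrow(out$truth$dots))) {
    d <- sqrt((cs$cells$row - out$truth$dots$row[i])^2 +
                (cs$cells$col - out$truth$dots$col[i])^2)
    j <- which.min(d)
    if (d[j] <= max_px) brute[j] <- brute[j] + 1L
  }
  expect_identical(res$cells$cells$dot_count, brute)
})

test_that("clean slides are never artifact-flagged", {
  out <- mini_slide(n_cells = 20, seed = 25)
  ch <- separate_stains(out$image)
  ds <- detect_dots(ch$red, estimate_dot_threshold(ch$red))
  flag <- flag_ap_artifact(ch$red, ds)
  expect_false(flag$flagged)
  expect_lt(flag$diffuse_frac, 0.01)
  expect_equal(flag$rationale, "")
})

test_that("the renderer's AP-background mode triggers the flag", {
  out <- mini_slide(n_cells = 20, seed = 26, ap_background_level = 0.3)
  ch <- separate_stains(out$image)
  ds <- detect_dots(ch$red, estimate_dot_threshold(ch$red))
  flag <- flag_ap_artifact(ch$red, ds)
  expect_true(flag$flagged)
  expect_match(flag$rationale, "diffuse|non-punctate")
})

test_that("a single large non-circular blotch is flagged by name", {
  ch <- matrix(0, 256, 256)
  for (p in seq(0, 60, by = 4))                   # a few real dots
    ch <- cishscore:::add_disk(ch, 30 + p, 40 + 2 * p, 2, 0.9)
  ch[150:190, 60:200] <- 0.6                      # 41 x 141 px blotch
  ds <- detect_dots(ch, threshold = 0.4)
  flag <- flag_ap_artifact(ch, ds)
  expect_true(flag$flagged)
  expect_match(flag$rationale, "non-punctate red fraction")
})
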