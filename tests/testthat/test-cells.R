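# Nucleus detection, per-cell features, tumor/stroma classification.

test_that("a blank channel yields zero cells, not an error", {
  cs <- detect_nuclei(matrix(0, 64, 64))
  expect_equal(nrow(cs$cells), 0)
  expect_error(detect_nuclei(matrix(c(NA, 1), 2, 2)), "non-finite")
})

test_that("non-overlapping rendered nuclei are each detected exactly once", {
  out <- mini_slide(fracs = c(1, 0, 0, 0), n_cells = 30, seed = 4,
                    width = 512, height = 512)
  ch <- separate_stains(out$image)
  cs <- detect_nuclei(ch$hematoxylin)
  expect_equal(nrow(cs$cells), 30)
  r_px <- out$cfg$nucleus_radius_um / out$cfg$mpp
  matched <- match_points(as.matrix(cs$cells[, c("row", "col")]),
                          as.matrix(out$truth$cells[, c("row", "col")]),
                          radius = r_px)
  recall <- matched / nrow(out$truth$cells)
  precision <- matched / nrow(cs$cells)
  expect_gte(recall, 0.98)
  expect_gte(precision, 0.98)
})

test_that("watershed splits two overlapping nuclei", {
  R <- 14
  od <- matrix(0, 128, 128)
  od <- cishscore:::add_disk(od, 60, 54, R, 0.7)
  od <- cishscore:::add_disk(od, 60, 54 + 1.4 * R, R, 0.7)  # ~30% overlap
  cs <- detect_nuclei(od, threshold = 0.3)
  expect_equal(nrow(cs$cells), 2)
})

test_that("local density has the right closed form for an isolated cell", {
  gt <- generate_count_table(bin_fraction_spec(1, 0, 0, 0), 1, seed = 1)
  cfg <- render_config(width = 256, height = 256, seed = 1)
  out <- render_slide(gt, cfg)
  ch <- separate_stains(out$image)
  cs <- extract_features(detect_nuclei(ch$hematoxylin), ch,
                         neighborhood_radius_um = 25)
  expect_equal(nrow(cs$cells), 1)
  expect_equal(cs$cells$local_density, 1 / (pi * 25^2))
  expect_error(extract_features(cs, ch, neighborhood_radius_um = 0),
               "neighborhood_radius_um")
})

test_that("identical twin images give identical feature tables", {
  f <- function() {
    out <- mini_slide(n_cells = 12, seed = 13)
    ch <- separate_stains(out$image)
    extract_features(detect_nuclei(ch$hematoxylin), ch)$cells
  }
  expect_identical(f(), f())
})

test_that("tumor and stroma features differ in the constructed directions", {
  cfg <- render_config(width = 640, height = 640, layout = "split",
                       n_stroma_cells = 15, seed = 6)
  gt <- generate_count_table(bin_fraction_spec(0.5, 0.5, 0, 0), 45,
                             seed = 6)
  out <- render_slide(gt, cfg)
  ch <- separate_stains(out$image)
  cs <- extract_features(detect_nuclei(ch$hematoxylin), ch)
  truth <- out$truth$cells
  d2 <- outer(cs$cells$row, truth$row, "-")^2 +
    outer(cs$cells$col, truth$col, "-")^2
  lab <- truth$compartment[apply(d2, 1, which.min)]
  # tumor nuclei are rendered larger and packed denser than stroma
  expect_gt(mean(cs$cells$area_um2[lab == "tumor"]),
            mean(cs$cells$area_um2[lab == "stroma"]))
  expect_gt(mean(cs$cells$local_density[lab == "tumor"]),
            mean(cs$cells$local_density[lab == "stroma"]))
})

# Synthetic, linearly separable feature table with cells laid out in two
# horizontal bands; seeds are rectangles inside each band.
separable_cellset <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  row <- c(runif(n_per_class, 10, 190), runif(n_per_class, 210, 390))
  col <- runif(n, 10, 390)
  cs <- make_cellset(row, col)
  cls <- rep(c("tumor", "stroma"), each = n_per_class)
  cs$cells$area_um2 <- rnorm(n, ifelse(cls == "tumor", 40, 15), 2)
  cs$cells$eccentricity <- runif(n, 0.2, 0.6)
  cs$cells$solidity <- rep(1, n)
  cs$cells$mean_hema_od <- rnorm(n, 0.7, 0.05)
  cs$cells$mean_red_od <- abs(rnorm(n, 0.02, 0.01))
  cs$cells$local_density <- rnorm(n, ifelse(cls == "tumor", 8e-3, 3e-3),
                                  5e-4)
  list(cellset = cs, truth = cls)
}

test_that("the compartment classifier learns separable features", {
  sc <- separable_cellset(100, seed = 2)
  seeds <- structure(list(rect_region(0, 0, 400, 200, "tumor"),
                          rect_region(0, 200, 400, 400, "stroma")),
                     class = "annotation_set")
  for (mdl in c("lda", "rf")) {
    model <- train_compartment_classifier(sc$cellset, seeds, model = mdl,
                                          seed = 3)
    expect_gte(model$cv_accuracy, 0.95)
    out <- classify_compartments(model, sc$cellset)
    expect_gte(mean(out$cells$compartment == sc$truth), 0.95)
    # determinism: same seed, same predictions
    model2 <- train_compartment_classifier(sc$cellset, seeds, model = mdl,
                                           seed = 3)
    out2 <- classify_compartments(model2, sc$cellset)
    expect_identical(out$cells$compartment, out2$cells$compartment)
    # idempotence: relabeling with the same model changes nothing
    out3 <- classify_compartments(model, out)
    expect_identical(out3$cells$compartment, out$cells$compartment)
  }
})

test_that("training refuses a missing class or too few seeds", {
  sc <- separable_cellset(50, seed = 4)
  tumor_only <- structure(list(rect_region(0, 0, 400, 200, "tumor")),
                          class = "annotation_set")
  expect_error(train_compartment_classifier(sc$cellset, tumor_only),
               "stroma")
  tiny <- structure(list(rect_region(0, 0, 400, 200, "tumor"),
                         rect_region(0, 200, 400, 245, "stroma")),
                    class = "annotation_set")
  expect_error(train_compartment_classifier(sc$cellset, tiny,
                                            min_seeds = 30),
               "minimum")
})

test_that("rendered 70/30 layouts recover compartment fractions within 5 points", {
  cfg <- render_config(width = 704, height = 704, layout = "split",
                       tumor_width_frac = 0.5, n_stroma_cells = 27,
                       seed = 15)
  gt <- generate_count_table(bin_fraction_spec(0.4, 0.4, 0.2, 0), 63,
                             seed = 15)
  out <- render_slide(gt, cfg)
  ch <- separate_stains(out$image)
  cs <- extract_features(detect_nuclei(ch$hematoxylin), ch)
  seeds <- synthetic_seed_regions(out$truth, n_per_class = 20, seed = 16)
  model <- train_compartment_classifier(cs, seeds, seed = 16)
  cs <- classify_compartments(model, cs)
  frac_true <- mean(out$truth$cells$compartment == "tumor")
  frac_pred <- mean(cs$cells$compartment == "tumor")
  expect_lt(abs(frac_pred - frac_true), 0.05)
})
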