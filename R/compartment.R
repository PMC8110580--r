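#' Train a tumor/stroma compartment classifier from analyst seed regions
#'
#' Mirrors the analyst-seeded workflow used in digital pathology: an
#' analyst circles small areas of tumor and small areas of stroma; cells
#' whose centroids fall inside those regions become labeled training
#' examples, and a shallow supervised model learns to separate the
#' compartments from the per-cell feature profiles.
#'
#' @param cellset A `"cell_set"` with features (see [extract_features()]).
#' @param seed_regions An annotation set (see [read_annotations()])
#'   containing polygons with class `"tumor"` and `"stroma"`.
#' @param model `"lda"` (linear discriminant, default) or `"rf"` (random
#'   forest).
#' @param min_seeds Minimum labeled cells required per class (default 10);
#'   the model refuses to train (and later predict) below it.
#' @param cv_folds Stratified cross-validation folds for the recorded
#'   held-out accuracy estimate.
#' @param seed RNG seed (fold shuffling, forest bootstraps); the same seed
#'   gives identical models and predictions.
#' @return An object of class `"compartment_model"`: fitted model,
#'   feature normalization parameters, and a training summary with
#'   per-class seed counts and cross-validated accuracy.
#' @export
train_compartment_classifier <- function(cellset, seed_regions,
                                         model = c("lda", "rf"),
                                         min_seeds = 10, cv_folds = 5,
                                         seed = 1) {
  model <- match.arg(model)
  cells <- cellset$cells
  if (!all(feature_names() %in% names(cells)))
    stop("cells lack feature columns; run extract_features first",
         call. = FALSE)
  lab <- rep(NA_character_, nrow(cells))
  for (cls in c("tumor", "stroma")) {
    inside <- points_in_regions(cells$row, cells$col, seed_regions, cls)
    lab[inside] <- cls
  }
  for (cls in c("tumor", "stroma")) {
    k <- sum(lab == cls, na.rm = TRUE)
    if (k == 0L)
      stop(sprintf("no seed cells for class '%s'; both classes required",
                   cls), call. = FALSE)
    if (k < min_seeds)
      stop(sprintf("only %d seed cells for class '%s' (minimum %d)",
                   k, cls, min_seeds), call. = FALSE)
  }
  sel <- !is.na(lab)
  x <- as.matrix(cells[sel, feature_names()])
  y <- factor(lab[sel], levels = c("stroma", "tumor"))
  # near-constant features carry no signal and break discriminant fits
  informative <- apply(x, 2, stats::sd) > 1e-9
  if (!any(informative))
    stop("all features are constant over the seed cells", call. = FALSE)
  x <- x[, informative, drop = FALSE]
  feats <- feature_names()[informative]
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- scale(x, ctr, scl)

  fit_fun <- function(xtr, ytr) {
    if (model == "lda") MASS::lda(xtr, grouping = ytr)
    else randomForest::randomForest(xtr, ytr, ntree = 200)
  }
  pred_fun <- function(fit, xte) {
    if (model == "lda") {
      p <- stats::predict(fit, xte)
      list(class = p$class, conf = apply(p$posterior, 1, max))
    } else {
      pr <- stats::predict(fit, xte, type = "prob")
      cl <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                   levels = levels(y))
      list(class = cl, conf = apply(pr, 1, max))
    }
  }

  cv_acc <- with_seed(seed, {
    folds <- integer(length(y))
    for (cls in levels(y)) {
      i <- which(y == cls)
      folds[i] <- sample(rep_len(seq_len(cv_folds), length(i)))
    }
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      te <- folds == f
      if (!any(te) || length(unique(y[!te])) < 2L) next
      fit <- fit_fun(xs[!te, , drop = FALSE], y[!te])
      hits <- hits + sum(pred_fun(fit, xs[te, , drop = FALSE])$class ==
                           y[te])
    }
    hits / length(y)
  })
  fit <- with_seed(seed, fit_fun(xs, y))
  structure(list(fit = fit, model = model, center = ctr, scale = scl,
                 features = feats, min_seeds = min_seeds,
                 n_seeds = table(y), cv_accuracy = cv_acc, seed = seed),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(paste0("Compartment classifier (%s): %d tumor / %d stroma ",
                     "seeds, CV accuracy %.3f\n"),
              x$model, x$n_seeds[["tumor"]], x$n_seeds[["stroma"]],
              x$cv_accuracy))
  invisible(x)
}

#' Label every cell as tumor or stroma
#'
#' @param model A trained `"compartment_model"`.
#' @param cellset A `"cell_set"` with the same feature columns the model
#'   was trained on.
#' @return The cell set with `compartment` filled (`"tumor"`/`"stroma"`)
#'   and a `compartment_confidence` column (posterior of the assigned
#'   class). Relabeling with the same model is idempotent.
#' @export
classify_compartments <- function(model, cellset) {
  if (!inherits(model, "compartment_model"))
    stop("'model' must be a compartment_model", call. = FALSE)
  cells <- cellset$cells
  if (!all(model$features %in% names(cells)))
    stop("cells lack the model's feature columns: ",
         paste(setdiff(model$features, names(cells)), collapse = ", "),
         call. = FALSE)
  if (nrow(cells) == 0L) {
    cells$compartment_confidence <- numeric(0)
    cellset$cells <- cells
    return(cellset)
  }
  xs <- scale(as.matrix(cells[, model$features]), model$center,
              model$scale)
  pred <- if (model$model == "lda") {
    p <- stats::predict(model$fit, xs)
    list(class = p$class, conf = apply(p$posterior, 1, max))
  } else {
    pr <- stats::predict(model$fit, xs, type = "prob")
    cl <- factor(colnames(pr)[max.col(pr, ties.method = "first")],
                 levels = colnames(pr))
    list(class = cl, conf = apply(pr, 1, max))
  }
  cells$compartment <- as.character(pred$class)
  cells$compartment_confidence <- pred$conf
  cellset$cells <- cells
  cellset
}
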