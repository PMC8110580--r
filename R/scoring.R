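#' Classify a per-cell dot count into an expression bin
#'
#' The four standard CISH scoring bins: negative (0 dots/cell), low (1-3),
#' medium (4-9) and high (10+ dots/cell).
#'
#' @param dot_count Vector of non-negative integer dot counts.
#' @return Character vector of bins, same length as the input.
#' @examples
#' classify_cell_bin(c(0, 1, 3, 4, 9, 10))
#' @export
classify_cell_bin <- function(dot_count) {
  if (!is.numeric(dot_count) || anyNA(dot_count) ||
      any(dot_count < 0) || any(dot_count != round(dot_count)))
    stop("'dot_count' must be non-negative integers", call. = FALSE)
  ifelse(dot_count == 0, "negative",
         ifelse(dot_count <= 3, "low",
                ifelse(dot_count <= 9, "medium", "high")))
}

#' Compute bin percentages and the H-score
#'
#' H-score = 3 x (percent high) + 2 x (percent medium) + 1 x (percent
#' low), with percentages taken over all evaluable tumor cells --
#' negatives included in the denominator. The theoretical maximum is 300
#' (every cell in the high bin). Keeping negatives in the denominator is
#' what exhaustive digital counting guarantees and manual scoring of
#' large tissues tends to get wrong (the "denominator effect").
#'
#' @param bins Either a character/factor vector of per-cell bins (from
#'   [classify_cell_bin()]), a vector of per-cell dot counts (integers,
#'   auto-binned), or a named count vector/table with names `negative`,
#'   `low`, `medium`, `high`.
#' @return A list with `n_evaluable`, `percent` (named, sums to 100) and
#'   `h_score`. Zero evaluable cells is an error (an undefined score is
#'   not the same thing as H = 0).
#' @examples
#' compute_h_score(c(high = 50))$h_score            # 300
#' compute_h_score(c(negative = 100, low = 100))    # H = 50
#' @export
compute_h_score <- function(bins) {
  counts <- bin_counts(bins)
  n <- sum(counts)
  if (n < 1)
    stop("H-score undefined: zero evaluable tumor cells", call. = FALSE)
  pct <- 100 * counts / n
  h <- 3 * pct[["high"]] + 2 * pct[["medium"]] + 1 * pct[["low"]]
  list(n_evaluable = n, percent = pct, h_score = h)
}

# Normalize the accepted input forms to a named bin-count vector.
bin_counts <- function(bins) {
  out <- stats::setNames(numeric(4), BIN_LEVELS)
  if (!is.null(names(bins)) || is.table(bins)) {
    b <- if (is.table(bins)) as.vector(bins) else as.numeric(bins)
    nm <- if (is.table(bins)) names(bins) else names(bins)
    if (!all(nm %in% BIN_LEVELS))
      stop("unknown bin names: ",
           paste(setdiff(nm, BIN_LEVELS), collapse = ", "), call. = FALSE)
    out[nm] <- b
    return(out)
  }
  if (is.numeric(bins)) bins <- classify_cell_bin(bins)
  bins <- as.character(bins)
  if (!all(bins %in% BIN_LEVELS))
    stop("unknown bins: ",
         paste(setdiff(unique(bins), BIN_LEVELS), collapse = ", "),
         call. = FALSE)
  tb <- table(factor(bins, levels = BIN_LEVELS))
  out[] <- as.vector(tb)
  out
}

#' Gate a slide on control-probe quality criteria
#'
#' A slide is reportable only with sufficiently intact RNA (PPIB-like
#' positive control of at least 4 dots/cell), minimal background
#' (dapB-like negative control under `dapb_limit` dots/cell) and at least
#' 100 evaluable tumor cells. Degraded samples that still clear the PPIB
#' bar remain acceptable: the score counts dots, not stain intensity.
#'
#' @param ppib_mean_dots Mean PPIB control dots per cell in the ROA.
#' @param dapb_mean_dots Mean dapB control dots per cell.
#' @param n_evaluable Number of evaluable tumor cells.
#' @param dapb_limit Background limit (default 1 dot/cell, the strict end
#'   of the conventional "< 1-3 dots/cell" range; configurable up to 3).
#' @param ppib_min,min_cells The other two gate thresholds.
#' @return An object of class `"qc_result"`: the inputs, `pass`, and a
#'   `reasons` character vector with one entry per failed criterion.
#' @examples
#' qc_gate(5.2, 0.1, 150)  # pass
#' qc_gate(3.9, 0.1, 150)  # fail: insufficient PPIB signal
#' @export
qc_gate <- function(ppib_mean_dots, dapb_mean_dots, n_evaluable,
                    dapb_limit = 1, ppib_min = 4, min_cells = 100) {
  for (nm in c("ppib_mean_dots", "dapb_mean_dots", "n_evaluable"))
    check_nonneg(get(nm), nm)
  reasons <- character(0)
  if (ppib_mean_dots < ppib_min)
    reasons <- c(reasons,
                 sprintf("insufficient RNA integrity: PPIB %.2f < %g dots/cell",
                         ppib_mean_dots, ppib_min))
  if (dapb_mean_dots >= dapb_limit)
    reasons <- c(reasons,
                 sprintf("excess background: dapB %.2f >= %g dots/cell",
                         dapb_mean_dots, dapb_limit))
  if (n_evaluable < min_cells)
    reasons <- c(reasons,
                 sprintf("too few evaluable tumor cells: %d < %d",
                         as.integer(n_evaluable), as.integer(min_cells)))
  structure(list(ppib_mean_dots = ppib_mean_dots,
                 dapb_mean_dots = dapb_mean_dots,
                 n_evaluable = as.integer(n_evaluable),
                 dapb_limit = dapb_limit, ppib_min = ppib_min,
                 min_cells = min_cells,
                 pass = length(reasons) == 0L, reasons = reasons),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("QC: %s (PPIB %.2f, dapB %.2f, %d evaluable cells)\n",
              if (x$pass) "pass" else "FAIL",
              x$ppib_mean_dots, x$dapb_mean_dots, x$n_evaluable))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}

#' Assign an H-score to an expression bin
#'
#' Bins: negative (H = 0), low (0 < H < 35), high (H >= 35). The
#' conventional printed bin labels leave 34 <= H < 35 unstated ("< 34"
#' vs ">= 35"); here the clinically anchored cutoff of 35 is the single
#' boundary, so the low bin is the open interval (0, 35).
#'
#' @param h_score Numeric H-score(s) in \[0, 300\].
#' @return Character vector in `{"negative", "low", "high"}`.
#' @examples
#' assign_expression_bin(c(0, 20, 34.5, 35))
#' @export
assign_expression_bin <- function(h_score) {
  if (!is.numeric(h_score) || anyNA(h_score) ||
      any(h_score < 0 | h_score > 300))
    stop("'h_score' must lie in [0, 300]", call. = FALSE)
  ifelse(h_score == 0, "negative", ifelse(h_score < 35, "low", "high"))
}

#' Score one slide end to end
#'
#' Runs the full pipeline on a target image with optional control-probe
#' images: stain separation, dot-intensity threshold estimation (from the
#' dapB background when available), nucleus detection, feature
#' extraction, tumor/stroma classification from analyst seed regions, dot
#' detection and per-cell assignment, the AP-background artifact flag,
#' the control-probe QC gate, and finally bins and H-score over evaluable
#' tumor cells inside the region of analysis.
#'
#' @param target RGB image array (or file path) of the target-probe slide.
#' @param ppib,dapb Optional control-probe images sharing the target's
#'   geometry. Without them the QC gate cannot run and the score is
#'   marked unreviewed rather than QC-passed.
#' @param roa Optional annotation set (or GeoJSON path) whose `"roa"`
#'   regions define the region of analysis; cells are included iff their
#'   centroid falls inside (centroid rule). `NULL` scores the whole image.
#' @param seeds Optional annotation set with `"tumor"`/`"stroma"` seed
#'   regions. Without seeds every cell is treated as tumor
#'   (single-compartment mode).
#' @param config Named list of overrides: `mpp`, `stain_matrix`,
#'   `threshold_method`, `fixed_threshold`, nucleus parameters
#'   (`min_nucleus_area_um2`, `max_nucleus_area_um2`,
#'   `watershed_tolerance`), dot parameters (`min_dot_area_um2`,
#'   `max_dot_area_um2`, `min_circularity`, `reference_dot_area_um2`,
#'   `max_assign_radius_um`), artifact limits (`max_diffuse_frac`,
#'   `max_nonpunctate_frac`), QC (`dapb_limit`, `ppib_min`, `min_cells`),
#'   classifier (`model`, `min_seeds`, `seed`), and `roa_id`.
#' @return An object of class `"slide_score"` carrying the evaluable-cell
#'   count, bin percentages, H-score (NA when QC fails), expression bin,
#'   QC result, artifact flag, `requires_review`, the threshold used, and
#'   the per-cell / per-dot tables for audit.
#' @export
score_slide <- function(target, ppib = NULL, dapb = NULL, roa = NULL,
                        seeds = NULL, config = list()) {
  cfg <- utils::modifyList(list(
    mpp = 0.25, stain_matrix = default_stain_matrix(),
    threshold_method = "auto", fixed_threshold = NULL,
    min_nucleus_area_um2 = 6, max_nucleus_area_um2 = 200,
    watershed_tolerance = 1,
    min_dot_area_um2 = 0.15, max_dot_area_um2 = 40, min_circularity = 0.2,
    reference_dot_area_um2 = pi * 0.5^2, max_assign_radius_um = 6.5,
    max_diffuse_frac = 0.05, max_nonpunctate_frac = 0.30,
    dapb_limit = 1, ppib_min = 4, min_cells = 100,
    model = "lda", min_seeds = 10, seed = 1, roa_id = "roa-1"
  ), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if (is.character(target)) target <- read_slide_image(target)
  if (is.character(ppib)) ppib <- read_slide_image(ppib)
  if (is.character(dapb)) dapb <- read_slide_image(dapb)
  if (is.character(roa)) roa <- read_annotations(roa)
  if (is.character(seeds)) seeds <- read_annotations(seeds)
  for (ctrl in list(ppib, dapb))
    if (!is.null(ctrl) && !all(dim(ctrl) == dim(target)))
      stop("control images must share the target image's geometry",
           call. = FALSE)

  ch <- stage("stains", separate_stains(target, cfg$stain_matrix))

  bg <- NULL
  if (!is.null(dapb))
    bg <- stage("stains", separate_stains(dapb, cfg$stain_matrix))$red
  thr <- stage("stains", {
    if (!is.null(cfg$fixed_threshold))
      estimate_dot_threshold(ch$red, method = "fixed",
                             value = cfg$fixed_threshold)
    else estimate_dot_threshold(ch$red, background = bg,
                                method = cfg$threshold_method)
  })

  cs <- stage("cells", {
    cs <- detect_nuclei(ch$hematoxylin, mpp = cfg$mpp,
                        min_area_um2 = cfg$min_nucleus_area_um2,
                        max_area_um2 = cfg$max_nucleus_area_um2,
                        watershed_tolerance = cfg$watershed_tolerance)
    extract_features(cs, ch)
  })
  model <- NULL
  if (!is.null(seeds)) {
    cs <- stage("cells", {
      model <- train_compartment_classifier(cs, seeds, model = cfg$model,
                                            min_seeds = cfg$min_seeds,
                                            seed = cfg$seed)
      classify_compartments(model, cs)
    })
  } else {
    cs$cells$compartment <- rep("tumor", nrow(cs$cells))
  }

  res <- stage("dots", {
    ds <- detect_dots(ch$red, thr, mpp = cfg$mpp,
                      min_area_um2 = cfg$min_dot_area_um2,
                      max_area_um2 = cfg$max_dot_area_um2,
                      min_circularity = cfg$min_circularity,
                      reference_dot_area_um2 = cfg$reference_dot_area_um2)
    assign_dots_to_cells(ds, cs, max_radius_um = cfg$max_assign_radius_um)
  })
  ds <- res$dots; cs <- res$cells
  artifact <- stage("dots",
                    flag_ap_artifact(ch$red, ds,
                                     max_diffuse_frac = cfg$max_diffuse_frac,
                                     max_nonpunctate_frac = cfg$max_nonpunctate_frac))

  cells <- cs$cells
  in_roa <- if (is.null(roa)) rep(TRUE, nrow(cells))
            else points_in_regions(cells$row, cells$col, roa, "roa")
  cells$evaluable <- in_roa & cells$compartment == "tumor"
  cs$cells <- cells
  n_eval <- sum(cells$evaluable)

  control_mean <- function(img) {
    cch <- separate_stains(img, cfg$stain_matrix)
    ccs <- detect_nuclei(cch$hematoxylin, mpp = cfg$mpp,
                         min_area_um2 = cfg$min_nucleus_area_um2,
                         max_area_um2 = cfg$max_nucleus_area_um2,
                         watershed_tolerance = cfg$watershed_tolerance)
    cth <- estimate_dot_threshold(cch$red, background = bg,
                                  method = if (is.null(bg)) "otsu" else
                                    "percentile")
    cds <- detect_dots(cch$red, cth, mpp = cfg$mpp,
                       min_area_um2 = cfg$min_dot_area_um2,
                       max_area_um2 = cfg$max_dot_area_um2,
                       min_circularity = cfg$min_circularity,
                       reference_dot_area_um2 = cfg$reference_dot_area_um2)
    asn <- assign_dots_to_cells(cds, ccs,
                                max_radius_um = cfg$max_assign_radius_um)
    ccells <- asn$cells$cells
    keep <- if (is.null(roa)) rep(TRUE, nrow(ccells))
            else points_in_regions(ccells$row, ccells$col, roa, "roa")
    if (!any(keep)) 0 else mean(ccells$dot_count[keep])
  }
  qc <- NULL
  if (!is.null(ppib) && !is.null(dapb)) {
    qc <- stage("qc", {
      # dapB mean uses an otsu threshold on its own channel: the dapB
      # slide defines background, so it cannot gate itself
      dapb_mean <- {
        dch_red <- bg
        dth <- tryCatch(estimate_dot_threshold(dch_red, method = "otsu"),
                        error = function(e) NULL)
        if (is.null(dth) || dth$value < 0.1) 0 else {
          dds <- detect_dots(dch_red, dth, mpp = cfg$mpp,
                             min_area_um2 = cfg$min_dot_area_um2,
                             max_area_um2 = cfg$max_dot_area_um2,
                             min_circularity = cfg$min_circularity,
                             reference_dot_area_um2 = cfg$reference_dot_area_um2)
          ccs <- detect_nuclei(separate_stains(dapb,
                                               cfg$stain_matrix)$hematoxylin,
                               mpp = cfg$mpp,
                               min_area_um2 = cfg$min_nucleus_area_um2,
                               max_area_um2 = cfg$max_nucleus_area_um2)
          if (nrow(ccs$cells) == 0) 0 else
            sum(dds$dots$mol_equiv) / nrow(ccs$cells)
        }
      }
      qc_gate(control_mean(ppib), dapb_mean, n_eval,
              dapb_limit = cfg$dapb_limit, ppib_min = cfg$ppib_min,
              min_cells = cfg$min_cells)
    })
  }

  score <- stage("scoring", {
    if (n_eval >= 1) compute_h_score(cells$dot_count[cells$evaluable])
    else list(n_evaluable = 0L,
              percent = stats::setNames(rep(NA_real_, 4), BIN_LEVELS),
              h_score = NA_real_)
  })
  qc_pass <- if (is.null(qc)) NA else qc$pass
  reportable <- isTRUE(qc_pass) || is.na(qc_pass)
  h <- if (reportable) score$h_score else NA_real_
  structure(list(
    roa_id = cfg$roa_id,
    n_evaluable_tumor_cells = score$n_evaluable,
    percent = if (reportable) score$percent else
      stats::setNames(rep(NA_real_, 4), BIN_LEVELS),
    h_score = h,
    expression_bin = if (!is.na(h)) assign_expression_bin(h) else
      NA_character_,
    qc = qc,
    artifact = artifact,
    requires_review = artifact$flagged || isFALSE(qc_pass),
    threshold = thr,
    compartment_model = model,
    cells = cs$cells,
    dots = ds$dots,
    config = cfg
  ), class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  cat("Slide score (", x$roa_id, ")\n", sep = "")
  cat("  evaluable tumor cells:", x$n_evaluable_tumor_cells, "\n")
  if (!is.na(x$h_score)) {
    cat(sprintf("  bins: neg %.1f%% / low %.1f%% / med %.1f%% / high %.1f%%\n",
                x$percent[["negative"]], x$percent[["low"]],
                x$percent[["medium"]], x$percent[["high"]]))
    cat(sprintf("  H-score: %.1f (%s expression)\n", x$h_score,
                x$expression_bin))
  } else {
    cat("  H-score: not reported\n")
  }
  if (!is.null(x$qc)) print(x$qc)
  if (x$artifact$flagged)
    cat("  ARTIFACT:", x$artifact$rationale, "\n")
  if (x$requires_review) cat("  >> requires manual review\n")
  invisible(x)
}
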