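#' Detect chromogenic puncta in the red-stain channel
#'
#' Connected components of the red OD channel at or above the intensity
#' threshold are candidate dots. Components must fall within the
#' configured shape bounds (area range, minimum circularity); accepted
#' blobs larger than one reference dot are declumped by area
#' quantization: the molecule-equivalent count is the blob area divided by
#' the reference single-dot area, rounded, with a floor of 1.
#'
#' @param red_channel Red-chromogen OD matrix.
#' @param threshold An `"intensity_threshold"` (or bare numeric OD value).
#' @param mpp Microns per pixel.
#' @param min_area_um2,max_area_um2 Accepted blob area range.
#' @param min_circularity Minimum circularity, `4 * pi * area /
#'   perimeter^2` clipped to \[0, 1\]. The default (0.2) is permissive
#'   because merged clusters of genuine puncta are elongated; irregular
#'   background blotches are caught primarily by the area bound.
#' @param reference_dot_area_um2 Area of a single punctum used for
#'   declumping; defaults to a disk of 0.5 um radius, matching the
#'   renderer's default dot size.
#' @return An object of class `"dot_set"`: `dots` data frame (`dot_id`,
#'   `row`, `col`, `area_um2`, `peak_od`, `circularity`, `mol_equiv`,
#'   `cell_id` NA until assignment), plus the label matrix, accepted
#'   label ids, threshold, and bookkeeping fields.
#' @export
detect_dots <- function(red_channel, threshold, mpp = 0.25,
                        min_area_um2 = 0.15, max_area_um2 = 40,
                        min_circularity = 0.2,
                        reference_dot_area_um2 = pi * 0.5^2) {
  thr <- threshold_value(threshold)
  check_positive(min_area_um2, "min_area_um2")
  check_positive(max_area_um2, "max_area_um2")
  mask <- red_channel >= thr
  empty <- data.frame(dot_id = integer(0), row = numeric(0),
                      col = numeric(0), area_um2 = numeric(0),
                      peak_od = numeric(0), circularity = numeric(0),
                      mol_equiv = integer(0), cell_id = integer(0))
  mk <- function(dots, labels, accepted) {
    structure(list(dots = dots, labels = labels, accepted = accepted,
                   threshold = thr, mpp = mpp,
                   reference_dot_area_um2 = reference_dot_area_um2,
                   min_area_um2 = min_area_um2,
                   max_area_um2 = max_area_um2,
                   min_circularity = min_circularity),
              class = "dot_set")
  }
  if (!any(mask))
    return(mk(empty, matrix(0L, nrow(red_channel), ncol(red_channel)),
              integer(0)))
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  storage.mode(labels) <- "integer"
  shp <- EBImage::computeFeatures.shape(labels)
  cent <- label_centroids(labels)
  area_px <- shp[, "s.area"]
  perim <- pmax(shp[, "s.perimeter"], 1e-6)
  circ <- pmin(1, 4 * pi * area_px / perim^2)
  circ[area_px <= 4] <- 1  # perimeter estimates are meaningless this small
  area_um2 <- area_px * mpp^2
  peak <- as.vector(tapply(red_channel[labels > 0L], labels[labels > 0L],
                           max))
  ok <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2 &
    circ >= min_circularity
  accepted <- cent$label[ok]
  ref_px <- reference_dot_area_um2 / mpp^2
  dots <- data.frame(dot_id = seq_len(sum(ok)),
                     row = cent$row[ok], col = cent$col[ok],
                     area_um2 = area_um2[ok], peak_od = peak[ok],
                     circularity = circ[ok],
                     mol_equiv = pmax(1L,
                                      as.integer(round(area_px[ok] / ref_px))),
                     cell_id = rep(NA_integer_, sum(ok)))
  mk(dots, labels, accepted)
}

#' @export
print.dot_set <- function(x, ...) {
  cat("Dot set:", nrow(x$dots), "puncta,",
      sum(x$dots$mol_equiv), "molecule equivalents",
      sprintf("(threshold OD >= %.3f)\n", x$threshold))
  invisible(x)
}

#' Assign detected dots to their owning cells
#'
#' Each dot goes to the nearest cell centroid within `max_radius_um`;
#' farther dots stay unassigned. Exact distance ties break toward the
#' lower cell id. Cell `dot_count` becomes the sum of molecule-equivalent
#' counts of its dots, so the total molecule-equivalents are conserved
#' between cells and the unassigned pool.
#'
#' @param dotset A `"dot_set"` from [detect_dots()].
#' @param cellset A `"cell_set"` from [detect_nuclei()].
#' @param max_radius_um Maximum centroid distance for assignment; the
#'   default (6.5 um) matches a typical nucleus radius plus a 3 um
#'   cytoplasmic margin.
#' @return A list with the updated `dots` (`cell_id` filled) and `cells`
#'   (`dot_count` filled) objects.
#' @export
assign_dots_to_cells <- function(dotset, cellset, max_radius_um = 6.5) {
  check_positive(max_radius_um, "max_radius_um")
  dots <- dotset$dots
  cells <- cellset$cells
  cells$dot_count <- rep(0L, nrow(cells))
  if (nrow(dots) > 0L && nrow(cells) > 0L) {
    d2 <- cross_dist2(cbind(dots$row, dots$col),
                      cbind(cells$row, cells$col))
    nearest <- max.col(-d2, ties.method = "first")  # lowest id on ties
    best <- d2[cbind(seq_len(nrow(dots)), nearest)]
    max_px2 <- (max_radius_um / cellset$mpp)^2
    dots$cell_id <- ifelse(best <= max_px2, cells$cell_id[nearest],
                           NA_integer_)
    agg <- tapply(dots$mol_equiv, dots$cell_id, sum)
    hit <- match(as.integer(names(agg)), cells$cell_id)
    cells$dot_count[hit] <- as.integer(agg)
  } else if (nrow(dots) > 0L) {
    dots$cell_id <- NA_integer_
  }
  dotset$dots <- dots
  cellset$cells <- cells
  list(dots = dotset, cells = cellset)
}

#' Flag diffuse endogenous-alkaline-phosphatase background
#'
#' Endogenous alkaline phosphatase converts the red substrate into a
#' diffuse, non-punctate wash that mimics signal and breaks specificity.
#' Two metrics operationalize the "visibly distinct from true signal"
#' judgment: the fraction of tissue pixels above the intensity threshold
#' that lie outside any accepted dot (diffuse-positive area fraction),
#' and the fraction of above-threshold pixels belonging to
#' shape-rejected blobs (non-punctate red fraction). Exceeding either
#' limit raises the flag; a flagged slide's score requires manual review.
#'
#' @param red_channel Red-chromogen OD matrix the dots were detected on.
#' @param dotset The `"dot_set"` from [detect_dots()].
#' @param max_diffuse_frac Limit on the diffuse-positive area fraction.
#' @param max_nonpunctate_frac Limit on the non-punctate red fraction.
#' @return An object of class `"artifact_flag"`: `flagged`,
#'   `diffuse_frac`, `nonpunctate_frac`, limits, and a `rationale` string
#'   naming each exceeded metric (empty when clean).
#' @export
flag_ap_artifact <- function(red_channel, dotset, max_diffuse_frac = 0.05,
                             max_nonpunctate_frac = 0.30) {
  if (!inherits(dotset, "dot_set"))
    stop("'dotset' must come from detect_dots", call. = FALSE)
  above <- red_channel >= dotset$threshold
  n_above <- sum(above)
  in_accepted <- dotset$labels > 0L &
    matrix(dotset$labels %in% dotset$accepted, nrow(dotset$labels))
  diffuse <- sum(above & !in_accepted) / length(red_channel)
  nonp <- if (n_above == 0L) 0 else sum(above & !in_accepted) / n_above
  reasons <- character(0)
  if (diffuse > max_diffuse_frac)
    reasons <- c(reasons,
                 sprintf("diffuse-positive area fraction %.3f > limit %.3f",
                         diffuse, max_diffuse_frac))
  if (nonp > max_nonpunctate_frac)
    reasons <- c(reasons,
                 sprintf("non-punctate red fraction %.3f > limit %.3f",
                         nonp, max_nonpunctate_frac))
  structure(list(flagged = length(reasons) > 0L,
                 diffuse_frac = diffuse, nonpunctate_frac = nonp,
                 max_diffuse_frac = max_diffuse_frac,
                 max_nonpunctate_frac = max_nonpunctate_frac,
                 rationale = paste(reasons, collapse = "; ")),
            class = "artifact_flag")
}

#' @export
print.artifact_flag <- function(x, ...) {
  cat("AP-background artifact flag:",
      if (x$flagged) "FLAGGED" else "clean",
      sprintf("(diffuse %.4f, non-punctate %.4f)\n",
              x$diffuse_frac, x$nonpunctate_frac))
  if (x$flagged) cat("  ", x$rationale, "\n")
  invisible(x)
}
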