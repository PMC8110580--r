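#' Detect nuclei in a hematoxylin optical-density channel
#'
#' Thresholds the counterstain channel, fills holes, and splits touching
#' nuclei by marker-based watershed on the distance transform. Objects
#' outside the plausible nucleus area range are discarded.
#'
#' @param hema_channel Hematoxylin OD matrix from [separate_stains()].
#' @param mpp Microns per pixel.
#' @param min_area_um2,max_area_um2 Accepted nucleus area range.
#' @param threshold `"otsu"` or a numeric OD cutoff.
#' @param watershed_tolerance Minimum object-height difference (in
#'   distance-map units, px) for watershed to keep two objects separate.
#' @return An object of class `"cell_set"`: list with `cells` (data frame:
#'   `cell_id`, `row`, `col` 0-based centroid, `area_um2`, `compartment`
#'   initialized `"unassigned"`, `dot_count` NA until dots are assigned,
#'   `evaluable` NA until scoring), the integer `labels` matrix, and
#'   `mpp`. A blank channel yields zero cells, not an error.
#' @export
detect_nuclei <- function(hema_channel, mpp = 0.25, min_area_um2 = 6,
                          max_area_um2 = 200, threshold = "otsu",
                          watershed_tolerance = 1) {
  if (!is.matrix(hema_channel))
    stop("'hema_channel' must be a matrix (use separate_stains)",
         call. = FALSE)
  if (!all(is.finite(hema_channel)))
    stop("'hema_channel' contains non-finite values", call. = FALSE)
  check_positive(mpp, "mpp")
  check_positive(min_area_um2, "min_area_um2")
  check_positive(max_area_um2, "max_area_um2")

  empty <- function() {
    cells <- data.frame(cell_id = integer(0), row = numeric(0),
                        col = numeric(0), area_um2 = numeric(0),
                        compartment = character(0), dot_count = integer(0),
                        evaluable = logical(0), stringsAsFactors = FALSE)
    structure(list(cells = cells,
                   labels = matrix(0L, nrow(hema_channel),
                                   ncol(hema_channel)),
                   mpp = mpp),
              class = "cell_set")
  }
  if (identical(threshold, "otsu")) {
    if (diff(range(hema_channel)) < 1e-6) return(empty())
    thr <- EBImage::otsu(EBImage::Image(hema_channel),
                         range = c(0, max(hema_channel)), levels = 256L)
  } else thr <- threshold
  mask <- hema_channel > thr
  if (!any(mask)) return(empty())
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dmap <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dmap,
                                                  tolerance = watershed_tolerance))
  storage.mode(labels) <- "integer"

  cent <- label_centroids(labels)
  area_um2 <- cent$area_px * mpp^2
  keep <- area_um2 >= min_area_um2 & area_um2 <= max_area_um2
  cent <- cent[keep, , drop = FALSE]
  area_um2 <- area_um2[keep]
  # relabel sequentially, dropping rejected objects
  map <- integer(max(labels, 1L))
  map[cent$label] <- seq_len(nrow(cent))
  labels[labels > 0L] <- map[labels[labels > 0L]]

  cells <- data.frame(cell_id = seq_len(nrow(cent)),
                      row = cent$row, col = cent$col,
                      area_um2 = area_um2,
                      compartment = rep("unassigned", nrow(cent)),
                      dot_count = rep(NA_integer_, nrow(cent)),
                      evaluable = rep(NA, nrow(cent)),
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, labels = labels, mpp = mpp),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat("Cell set:", nrow(x$cells), "cells")
  if (nrow(x$cells) > 0 && any(x$cells$compartment != "unassigned")) {
    tb <- table(x$cells$compartment)
    cat(" (", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

# Shoelace polygon area.
poly_area <- function(x, y) {
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Extract per-cell morphology, staining and spatial features
#'
#' Fills each cell's feature vector: nucleus area, eccentricity (from
#' second central moments), solidity (area over convex-hull area), mean
#' hematoxylin and red OD over the nucleus mask, and local cell density
#' (cells whose centroids fall within `neighborhood_radius_um`, including
#' the cell itself, divided by the disk area).
#'
#' @param cellset A `"cell_set"` from [detect_nuclei()].
#' @param channels `"stain_channels"` aligned to the same image.
#' @param neighborhood_radius_um Radius of the density neighborhood
#'   (microns, > 0).
#' @return The cell set with feature columns added to `$cells`.
#' @export
extract_features <- function(cellset, channels,
                             neighborhood_radius_um = 25) {
  if (!inherits(cellset, "cell_set"))
    stop("'cellset' must come from detect_nuclei", call. = FALSE)
  check_positive(neighborhood_radius_um, "neighborhood_radius_um")
  cells <- cellset$cells
  n <- nrow(cells)
  if (n == 0L) {
    for (nm in feature_names()) cells[[nm]] <- numeric(0)
    cellset$cells <- cells
    return(cellset)
  }
  if (!inherits(channels, "stain_channels") ||
      !all(dim(channels$hematoxylin) == dim(cellset$labels)))
    stop("'channels' must be stain_channels aligned to the cell labels",
         call. = FALSE)
  L <- cellset$labels
  idx <- which(L > 0L)
  lab <- L[idx]
  nr <- nrow(L)
  r0 <- (idx - 1L) %% nr
  c0 <- (idx - 1L) %/% nr
  area_px <- as.vector(table(lab))

  mean_by <- function(v) as.vector(rowsum(v, lab)) / area_px
  mu_r <- mean_by(r0); mu_c <- mean_by(c0)
  dr <- r0 - mu_r[lab]; dc <- c0 - mu_c[lab]
  m20 <- mean_by(dr^2); m02 <- mean_by(dc^2); m11 <- mean_by(dr * dc)
  tr2 <- (m20 + m02) / 2
  disc <- sqrt(pmax(0, ((m20 - m02) / 2)^2 + m11^2))
  l1 <- tr2 + disc; l2 <- pmax(tr2 - disc, 0)
  ecc <- sqrt(pmax(0, 1 - l2 / pmax(l1, 1e-12)))

  solidity <- vapply(seq_len(n), function(k) {
    pr <- r0[lab == k]; pc <- c0[lab == k]
    if (length(pr) < 3L) return(1)
    # convex hull over pixel centers, padded half a pixel via area + P/2 + 1
    hull <- grDevices::chull(pc, pr)
    ha <- poly_area(pc[hull], pr[hull])
    a <- length(pr)
    # pixel-count area vs vertex-polygon hull area: pad hull by boundary
    min(1, a / max(ha + length(hull) / 2 + 1, 1))
  }, numeric(1))

  mpp <- cellset$mpp
  r_nb <- neighborhood_radius_um / mpp
  d2 <- cross_dist2(cbind(cells$row, cells$col), cbind(cells$row, cells$col))
  n_in <- rowSums(d2 <= r_nb^2)
  density <- n_in / (pi * neighborhood_radius_um^2)  # cells per um^2

  cells$eccentricity <- ecc
  cells$solidity <- solidity
  cells$mean_hema_od <- mean_by(channels$hematoxylin[idx])
  cells$mean_red_od <- mean_by(channels$red[idx])
  cells$local_density <- density
  if (any(!is.finite(as.matrix(cells[, feature_names()]))))
    stop("non-finite feature values computed", call. = FALSE)
  cellset$cells <- cells
  cellset
}

feature_names <- function() {
  c("area_um2", "eccentricity", "solidity", "mean_hema_od",
    "mean_red_od", "local_density")
}
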