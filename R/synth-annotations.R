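#' Synthetic analyst annotations for a rendered slide
#'
#' Emulates the analyst's seed annotations: picks `n_per_class` rendered
#' cells of each compartment and circles each with a small square region,
#' labeled with its true compartment. Only call this on split-layout
#' truths that contain both compartments.
#'
#' @param truth Ground truth with layout from [render_slide()].
#' @param n_per_class Seed cells per class (default 25).
#' @param half_side Half side length of each seed square, px.
#' @param seed RNG seed for the cell draw.
#' @return An `"annotation_set"` of seed regions.
#' @export
synthetic_seed_regions <- function(truth, n_per_class = 25, half_side = 2,
                                   seed = 1) {
  cells <- truth$cells
  regs <- with_seed(seed, {
    out <- list()
    for (cls in c("tumor", "stroma")) {
      i <- which(cells$compartment == cls)
      if (length(i) < n_per_class)
        stop(sprintf("only %d '%s' cells available for %d seeds",
                     length(i), cls, n_per_class), call. = FALSE)
      for (j in sample(i, n_per_class))
        out[[length(out) + 1L]] <-
          rect_region(cells$col[j] - half_side, cells$row[j] - half_side,
                      cells$col[j] + half_side, cells$row[j] + half_side,
                      class = cls)
    }
    out
  })
  structure(regs, class = "annotation_set")
}

#' Region of analysis covering a rendered slide's tumor compartment
#'
#' @param cfg The slide's [render_config()].
#' @return An `"annotation_set"` with one `"roa"` polygon: the whole
#'   canvas for the single-compartment layout, the tumor half for the
#'   split layout.
#' @export
synthetic_roa <- function(cfg) {
  regs <- compartment_regions(cfg)
  tum <- regs[[1]]
  structure(list(list(class = "roa", coords = tum$coords)),
            class = "annotation_set")
}
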