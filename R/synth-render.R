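#' Rendering configuration for synthetic brightfield CISH slides
#'
#' Describes the geometry, optics and layout of a rendered slide. Stains are
#' composed in optical-density (OD) space under Beer-Lambert with fixed
#' absorbance vectors (hematoxylin counterstain for nuclei, a red chromogen
#' for ISH puncta), then converted to 8-bit sRGB, so the composition is
#' analytically invertible by [separate_stains()].
#'
#' @param width,height Canvas size in pixels.
#' @param mpp Microns per pixel (40x-scan scale convention, default 0.25).
#' @param nucleus_radius_um Mean nucleus radius (microns).
#' @param nucleus_radius_sd_um SD of nucleus radius; radii are clipped to
#'   \[0.6, 1.6\] times the mean.
#' @param min_spacing_um Minimum spacing between nucleus centers (microns).
#' @param dot_radius_um Radius of a single rendered punctum.
#' @param dot_peak_od Chromogen OD of a single punctum before degradation.
#' @param hema_od Hematoxylin OD inside nuclei (per-nucleus jitter of
#'   +/- 15 percent is applied).
#' @param degradation Factor in (0, 1\] attenuating dot OD, mimicking
#'   partial RNA degradation (fewer probes hybridized, fainter signal).
#' @param ap_background_level OD of a diffuse non-punctate red wash
#'   emulating endogenous alkaline-phosphatase activity; 0 disables it.
#'   When positive, irregular red blotches are also drawn and recorded in
#'   the ground truth as artifact pixels, never as dots.
#' @param n_ap_blotches Number of irregular blotches in artifact mode.
#' @param background_rgb Background (no-tissue) color, a pale eosinophilic
#'   off-white.
#' @param layout `"tumor"` (whole canvas is tumor) or `"split"` (left
#'   `tumor_width_frac` of the canvas is tumor, the rest stroma).
#' @param tumor_width_frac Tumor fraction of the canvas width in `"split"`
#'   layout.
#' @param n_stroma_cells Number of stromal cells rendered in `"split"`
#'   layout (smaller nuclei, sparser, dot counts Poisson with mean
#'   `stroma_dot_rate`).
#' @param stroma_radius_factor Stromal nucleus radius relative to tumor.
#' @param stroma_spacing_factor Stromal center spacing relative to
#'   `min_spacing_um`; stroma is rendered sparser as well as
#'   smaller-celled, so compartments differ in both morphology and local
#'   density.
#' @param stroma_dot_rate Mean dots per stromal cell (default 0).
#' @param assignment_margin_um Dots are placed inside a disk of radius
#'   (nucleus radius + this margin) around the owning nucleus center,
#'   mirroring cytoplasmic signal.
#' @param stain_matrix 3x3 absorbance matrix (rows: hematoxylin, red
#'   chromogen, residual) used for composition; see
#'   [default_stain_matrix()].
#' @param seed RNG seed; the seed fully determines the rendered image
#'   (re-rendering is bit-identical).
#' @return An object of class `"render_config"`.
#' @export
render_config <- function(width = 1024, height = 1024, mpp = 0.25,
                          nucleus_radius_um = 3.5,
                          nucleus_radius_sd_um = 0.4,
                          min_spacing_um = 10,
                          dot_radius_um = 0.5, dot_peak_od = 0.9,
                          hema_od = 0.7, degradation = 1,
                          ap_background_level = 0, n_ap_blotches = 3,
                          background_rgb = c(245, 240, 242),
                          layout = c("tumor", "split"),
                          tumor_width_frac = 0.6, n_stroma_cells = 0,
                          stroma_radius_factor = 0.6,
                          stroma_spacing_factor = 1.5, stroma_dot_rate = 0,
                          assignment_margin_um = 3,
                          stain_matrix = default_stain_matrix(),
                          seed = 1) {
  layout <- match.arg(layout)
  for (nm in c("width", "height", "mpp", "nucleus_radius_um",
               "min_spacing_um", "dot_radius_um", "dot_peak_od", "hema_od",
               "tumor_width_frac", "assignment_margin_um"))
    check_positive(get(nm), nm)
  for (nm in c("nucleus_radius_sd_um", "ap_background_level",
               "stroma_dot_rate"))
    check_nonneg(get(nm), nm)
  if (degradation <= 0 || degradation > 1)
    stop("'degradation' must be in (0, 1]", call. = FALSE)
  max_r_px <- 1.6 * nucleus_radius_um / mpp
  if (2 * max_r_px >= min(width, height))
    stop("nuclei do not fit inside the canvas at this scale", call. = FALSE)
  structure(list(width = as.integer(width), height = as.integer(height),
                 mpp = mpp, nucleus_radius_um = nucleus_radius_um,
                 nucleus_radius_sd_um = nucleus_radius_sd_um,
                 min_spacing_um = min_spacing_um,
                 dot_radius_um = dot_radius_um, dot_peak_od = dot_peak_od,
                 hema_od = hema_od, degradation = degradation,
                 ap_background_level = ap_background_level,
                 n_ap_blotches = as.integer(n_ap_blotches),
                 background_rgb = background_rgb, layout = layout,
                 tumor_width_frac = tumor_width_frac,
                 n_stroma_cells = as.integer(n_stroma_cells),
                 stroma_radius_factor = stroma_radius_factor,
                 stroma_spacing_factor = stroma_spacing_factor,
                 stroma_dot_rate = stroma_dot_rate,
                 assignment_margin_um = assignment_margin_um,
                 stain_matrix = stain_matrix, seed = seed),
            class = "render_config")
}

#' Compartment layout polygons of a render configuration
#'
#' @param cfg A [render_config()].
#' @return An annotation set with a `"tumor"` region and, for the split
#'   layout, a `"stroma"` region. Pixel coordinates, half-open on the
#'   right/bottom edges by construction.
#' @export
compartment_regions <- function(cfg) {
  w <- cfg$width; h <- cfg$height
  if (cfg$layout == "tumor") {
    regs <- list(rect_region(0, 0, w - 1, h - 1, "tumor"))
  } else {
    xs <- cfg$tumor_width_frac * w
    regs <- list(rect_region(0, 0, xs - 1e-6, h - 1, "tumor"),
                 rect_region(xs, 0, w - 1, h - 1, "stroma"))
  }
  structure(regs, class = "annotation_set")
}

# Dart-throwing placement of centers with a minimum pairwise spacing.
# xr / yr are 0-based coordinate ranges (cols / rows). Existing centers
# (two-column row, col matrix) also constrain spacing.
place_centers <- function(n, xr, yr, min_spacing_px, existing = NULL,
                          budget_per_center = 400) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  pts <- if (is.null(existing)) matrix(numeric(0), ncol = 2) else existing
  out <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  budget <- budget_per_center * n
  sp2 <- min_spacing_px^2
  while (placed < n && attempts < budget) {
    attempts <- attempts + 1L
    r <- runif(1, yr[1], yr[2])
    c <- runif(1, xr[1], xr[2])
    ok <- TRUE
    if (nrow(pts) > 0) {
      d2 <- (pts[, 1] - r)^2 + (pts[, 2] - c)^2
      ok <- all(d2 >= sp2)
    }
    if (ok) {
      placed <- placed + 1L
      out[placed, ] <- c(r, c)
      pts <- rbind(pts, c(r, c))
    }
  }
  if (placed < n)
    stop(sprintf(paste0("nucleus placement infeasible: could not satisfy ",
                        "min center spacing of %.1f px for %d nuclei ",
                        "after %d attempts"),
                 min_spacing_px, n, attempts), call. = FALSE)
  out
}

# Add `value` to `mat` inside a disk (0-based center r0, c0; radius px).
# Pixel centers sit at integer coordinates; a pixel is inside if its
# center is within `radius`.
add_disk <- function(mat, r0, c0, radius, value) {
  nr <- nrow(mat); nc <- ncol(mat)
  rr <- max(0, ceiling(r0 - radius)):min(nr - 1, floor(r0 + radius))
  cc <- max(0, ceiling(c0 - radius)):min(nc - 1, floor(c0 + radius))
  if (length(rr) == 0L || length(cc) == 0L) return(mat)
  sel <- outer((rr - r0)^2, (cc - c0)^2, "+") <= radius^2
  sub <- mat[rr + 1, cc + 1, drop = FALSE]
  sub[sel] <- sub[sel] + value
  mat[rr + 1, cc + 1] <- sub
  mat
}

# Compose hematoxylin / red OD fields into an 8-bit sRGB image.
compose_rgb <- function(od_h, od_r, cfg) {
  hv <- cfg$stain_matrix[1, ]
  rv <- cfg$stain_matrix[2, ]
  bg_od <- -log10(pmax(cfg$background_rgb, 1) / 255)
  img <- array(0L, dim = c(nrow(od_h), ncol(od_h), 3L))
  for (ch in 1:3) {
    od <- bg_od[ch] + od_h * hv[ch] + od_r * rv[ch]
    img[, , ch] <- as.integer(pmax(0, pmin(255, round(255 * 10^(-od)))))
  }
  img
}

# Draw per-cell dot centers and rasterize them into an OD field.
rasterize_dots <- function(od_r, cells, counts, cfg) {
  dot_r_px <- cfg$dot_radius_um / cfg$mpp
  od <- cfg$dot_peak_od * cfg$degradation
  nr <- nrow(od_r); nc <- ncol(od_r)
  rows <- cols <- owner <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    k <- counts[i]
    if (k == 0L) next
    R <- cells$radius_px[i] + cfg$assignment_margin_um / cfg$mpp
    rad <- R * sqrt(runif(k))
    th <- runif(k, 0, 2 * pi)
    dr <- pmin(nr - 1, pmax(0, cells$row[i] + rad * sin(th)))
    dc <- pmin(nc - 1, pmax(0, cells$col[i] + rad * cos(th)))
    rows <- c(rows, dr); cols <- c(cols, dc)
    owner <- c(owner, rep(cells$cell_id[i], k))
  }
  for (j in seq_along(rows))
    od_r <- add_disk(od_r, rows[j], cols[j], dot_r_px, od)
  list(od_r = od_r,
       dots = data.frame(dot_id = seq_along(rows), cell_id = owner,
                         row = rows, col = cols))
}

#' Render a synthetic brightfield CISH slide
#'
#' Places hematoxylin-stained nuclei on a pale background, draws each
#' cell's red puncta inside its assignment disk, optionally adds the
#' diffuse endogenous-alkaline-phosphatase background mode, and returns
#' the 8-bit RGB image together with pixel-exact ground truth.
#'
#' @param gt A counts-only `"ground_truth"` from [generate_count_table()],
#'   or `NULL` for an empty slide.
#' @param cfg A [render_config()]. Its `seed` drives all placement
#'   randomness; identical `(gt, cfg)` re-render bit-identically.
#' @return A list with `image` (integer array height x width x 3, values
#'   0-255) and `truth` (the input ground truth augmented with per-cell
#'   geometry, stromal cells if configured, the dot-center table, artifact
#'   bookkeeping and a config echo).
#' @export
render_slide <- function(gt, cfg) {
  if (!inherits(cfg, "render_config"))
    stop("'cfg' must be a render_config", call. = FALSE)
  n_tumor <- if (is.null(gt)) 0L else nrow(gt$cells)
  with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width; mpp <- cfg$mpp
    sp_px <- cfg$min_spacing_um / mpp
    mean_r_px <- cfg$nucleus_radius_um / mpp
    sd_r_px <- cfg$nucleus_radius_sd_um / mpp
    margin <- 1.6 * mean_r_px

    draw_radii <- function(n, scale = 1) {
      r <- rnorm(n, mean_r_px, sd_r_px)
      pmin(1.6 * mean_r_px, pmax(0.6 * mean_r_px, r)) * scale
    }

    split_x <- if (cfg$layout == "split") cfg$tumor_width_frac * w else w
    # tumor centers
    t_centers <- place_centers(n_tumor,
                               xr = c(margin, split_x - 1 - margin),
                               yr = c(margin, h - 1 - margin),
                               min_spacing_px = sp_px)
    cells <- data.frame(cell_id = integer(0), row = numeric(0),
                        col = numeric(0), radius_px = numeric(0),
                        compartment = character(0),
                        true_dots = integer(0), stringsAsFactors = FALSE)
    counts <- integer(0)
    if (n_tumor > 0) {
      cells <- data.frame(cell_id = gt$cells$cell_id,
                          row = t_centers[, 1], col = t_centers[, 2],
                          radius_px = draw_radii(n_tumor),
                          compartment = "tumor",
                          true_dots = gt$cells$true_dots,
                          stringsAsFactors = FALSE)
      counts <- gt$cells$true_dots
    }
    if (cfg$layout == "split" && cfg$n_stroma_cells > 0) {
      s_centers <- place_centers(cfg$n_stroma_cells,
                                 xr = c(split_x + margin, w - 1 - margin),
                                 yr = c(margin, h - 1 - margin),
                                 min_spacing_px = sp_px *
                                   cfg$stroma_spacing_factor,
                                 existing = as.matrix(cells[, c("row", "col")]))
      s_counts <- stats::rpois(cfg$n_stroma_cells, cfg$stroma_dot_rate)
      s <- data.frame(cell_id = n_tumor + seq_len(cfg$n_stroma_cells),
                      row = s_centers[, 1], col = s_centers[, 2],
                      radius_px = draw_radii(cfg$n_stroma_cells,
                                             cfg$stroma_radius_factor),
                      compartment = "stroma",
                      true_dots = as.integer(s_counts),
                      stringsAsFactors = FALSE)
      cells <- rbind(cells, s)
      counts <- c(counts, s$true_dots)
    }

    # hematoxylin field
    od_h <- matrix(0, h, w)
    if (nrow(cells) > 0) {
      jit <- runif(nrow(cells), 0.85, 1.15)
      for (i in seq_len(nrow(cells)))
        od_h <- add_disk(od_h, cells$row[i], cells$col[i],
                         cells$radius_px[i], cfg$hema_od * jit[i])
    }

    # red chromogen field: puncta, then optional AP background
    od_r <- matrix(0, h, w)
    rd <- rasterize_dots(od_r, cells, counts, cfg)
    od_r <- rd$od_r
    n_artifact_px <- 0L
    if (cfg$ap_background_level > 0) {
      od_r <- od_r + cfg$ap_background_level
      amask <- matrix(FALSE, h, w)
      for (b in seq_len(cfg$n_ap_blotches)) {
        br <- runif(1, margin, h - 1 - margin)
        bc <- runif(1, margin, w - 1 - margin)
        for (k in seq_len(5L)) {
          rr <- br + rnorm(1, 0, 12); cc <- bc + rnorm(1, 0, 12)
          rad <- runif(1, 8, 20)
          tmp <- matrix(0, h, w)
          tmp <- add_disk(tmp, rr, cc, rad, 1)
          amask <- amask | (tmp > 0)
        }
      }
      od_r[amask] <- od_r[amask] + 0.5
      n_artifact_px <- sum(amask)
    }

    img <- compose_rgb(od_h, od_r, cfg)

    truth <- structure(list(
      cells = cells,
      dots = rd$dots,
      bin_fractions = if (is.null(gt)) NULL else gt$bin_fractions,
      h_score = if (is.null(gt)) NA_real_ else gt$h_score,
      n_cells = nrow(cells),
      artifact = list(present = cfg$ap_background_level > 0,
                      ap_level = cfg$ap_background_level,
                      n_artifact_px = n_artifact_px),
      seed = cfg$seed,
      config = cfg
    ), class = "ground_truth")
    list(image = img, truth = truth)
  })
}

#' Render a control-probe slide over an existing nucleus layout
#'
#' Control probes gate slide quality: a PPIB-like positive control checks
#' RNA integrity (>= 4 dots/cell required) and a dapB-like negative
#' control measures assay background. The control slide reuses the target
#' slide's nucleus layout; per-cell control counts are Poisson with the
#' stated mean.
#'
#' @param truth Ground truth with layout from [render_slide()].
#' @param control_kind `"ppib"` or `"dapb"` (labels the ground truth only).
#' @param mean_dots_per_cell Poisson mean of per-cell control counts
#'   (>= 0); defaults to 5 for PPIB-like and 0.2 for dapB-like controls.
#' @param seed RNG seed for the control draw.
#' @return A list with `image` and `truth` as for [render_slide()].
#' @export
render_control_pair <- function(truth, control_kind = c("ppib", "dapb"),
                                mean_dots_per_cell = NULL, seed = 1) {
  control_kind <- match.arg(control_kind)
  if (is.null(truth$cells$row))
    stop("'truth' must carry a rendered layout (use render_slide first)",
         call. = FALSE)
  if (is.null(mean_dots_per_cell))
    mean_dots_per_cell <- if (control_kind == "ppib") 5 else 0.2
  check_nonneg(mean_dots_per_cell, "mean_dots_per_cell")
  cfg <- truth$config
  cfg$ap_background_level <- 0
  with_seed(seed, {
    cells <- truth$cells
    counts <- stats::rpois(nrow(cells), mean_dots_per_cell)
    cells$true_dots <- as.integer(counts)
    h <- cfg$height; w <- cfg$width
    od_h <- matrix(0, h, w)
    jit <- runif(nrow(cells), 0.85, 1.15)
    for (i in seq_len(nrow(cells)))
      od_h <- add_disk(od_h, cells$row[i], cells$col[i],
                       cells$radius_px[i], cfg$hema_od * jit[i])
    rd <- rasterize_dots(matrix(0, h, w), cells, counts, cfg)
    img <- compose_rgb(od_h, rd$od_r, cfg)
    tr <- structure(list(cells = cells, dots = rd$dots,
                         control_kind = control_kind,
                         mean_dots_per_cell = mean_dots_per_cell,
                         n_cells = nrow(cells),
                         artifact = list(present = FALSE, ap_level = 0,
                                         n_artifact_px = 0L),
                         seed = seed, config = cfg),
                    class = "ground_truth")
    list(image = img, truth = tr)
  })
}
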