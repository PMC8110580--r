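#' Read and write 8-bit RGB slide images
#'
#' Images are plain 8-bit RGB TIFF or PNG, chosen by file extension.
#' In memory an image is an integer array `height x width x 3` with
#' values 0-255, rows indexing image rows (0-based coordinates in all
#' tables).
#'
#' @param image Integer/numeric array `height x width x 3`, values 0-255.
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @return `write_slide_image` returns `path` invisibly;
#'   `read_slide_image` returns the image array.
#' @export
write_slide_image <- function(image, path) {
  x <- image / 255
  x[x < 0] <- 0
  x[x > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(x, path, bits.per.sample = 8L)
  else if (ext == "png")
    png::writePNG(x, path)
  else stop("unsupported image extension: ", ext, call. = FALSE)
  invisible(path)
}

#' @rdname write_slide_image
#' @export
read_slide_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image extension: ", ext, call. = FALSE)
  if (length(dim(x)) == 3L && dim(x)[3] > 3L) x <- x[, , 1:3]
  storage.mode(x) <- "double"
  x <- round(x * 255)
  storage.mode(x) <- "integer"
  x
}

#' Export synthetic ground truth to CSV plus a JSON sidecar
#'
#' The per-cell table (id, 0-based center, compartment, true dot count)
#' goes to CSV; the analytic summary (true H-score, bin fractions, seed,
#' config echo) goes to a JSON sidecar next to it.
#'
#' @param truth A `"ground_truth"` (with or without layout).
#' @param csv_path Output CSV path.
#' @param json_path Sidecar path; default replaces the CSV extension.
#' @return Invisibly, `c(csv_path, json_path)`.
#' @export
write_ground_truth <- function(truth, csv_path,
                               json_path = sub("\\.csv$", ".json",
                                               csv_path)) {
  cells <- truth$cells
  keep <- intersect(c("cell_id", "row", "col", "compartment", "true_dots"),
                    names(cells))
  utils::write.csv(cells[, keep], csv_path, row.names = FALSE)
  cfg <- truth$config
  if (!is.null(cfg)) {
    cfg <- unclass(cfg)
    cfg$stain_matrix <- as.vector(t(cfg$stain_matrix))
  }
  jsonlite::write_json(
    list(h_score = truth$h_score,
         bin_fractions = as.list(truth$bin_fractions),
         n_cells = truth$n_cells,
         n_dot_centers = if (is.null(truth$dots)) sum(cells$true_dots)
                         else nrow(truth$dots),
         artifact = truth$artifact,
         seed = truth$seed,
         config = cfg),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv_path, json_path))
}

#' Write a per-slide score report as JSON
#'
#' Persists the audit trail of one scored ROA: config echo, intensity
#' threshold, QC result, bin percentages, H-score, expression bin and
#' flags.
#'
#' @param score A `"slide_score"` from [score_slide()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_score_report <- function(score, path) {
  cfg <- unclass(score$config)
  cfg$stain_matrix <- as.vector(t(cfg$stain_matrix))
  out <- list(
    roa_id = score$roa_id,
    n_evaluable_tumor_cells = score$n_evaluable_tumor_cells,
    percent = as.list(score$percent),
    h_score = score$h_score,
    expression_bin = score$expression_bin,
    qc = if (is.null(score$qc)) NULL else unclass(score$qc),
    artifact = unclass(score$artifact),
    requires_review = score$requires_review,
    threshold = list(value = score$threshold$value,
                     method = score$threshold$method,
                     background_summary =
                       as.list(score$threshold$background_summary)),
    config = cfg
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Export the per-cell and per-dot tables of a scored slide
#'
#' @param score A `"slide_score"`.
#' @param cells_path,dots_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_score_tables <- function(score, cells_path = NULL, dots_path = NULL) {
  if (!is.null(cells_path))
    utils::write.csv(score$cells, cells_path, row.names = FALSE)
  if (!is.null(dots_path))
    utils::write.csv(score$dots, dots_path, row.names = FALSE)
  invisible(c(cells_path, dots_path))
}
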