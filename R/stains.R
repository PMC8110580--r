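#' Default stain absorbance matrix
#'
#' Rows are unit absorbance (optical-density) vectors in RGB for the
#' hematoxylin counterstain, the red alkaline-phosphatase chromogen, and a
#' residual direction orthogonal to both. The red vector matches the
#' synthetic renderer's default so stain separation is analytically
#' invertible on rendered slides; real Fast Red spectra vary by lot, so the
#' matrix is configurable per assay.
#'
#' @return A 3x3 numeric matrix with unit-norm rows, rownames
#'   `c("hematoxylin", "red", "residual")`.
#' @export
default_stain_matrix <- function() {
  hema <- c(0.650, 0.704, 0.286)
  red <- c(0.150, 0.800, 0.580)
  m <- normalize_stain_matrix(rbind(hema, red, pracma::cross(hema, red)))
  rownames(m) <- c("hematoxylin", "red", "residual")
  colnames(m) <- c("R", "G", "B")
  m
}

normalize_stain_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || !all(is.finite(m)))
    stop("stain matrix must be a finite 3x3 matrix", call. = FALSE)
  m <- m / sqrt(rowSums(m^2))
  if (abs(det(m)) < 1e-3)
    stop("stain matrix is singular or has collinear rows; ",
         "stains cannot be separated", call. = FALSE)
  m
}

# OD transform of an 8-bit image or channel: -log10((pixel + eps) / 255),
# eps = 1/255 to avoid log(0).
rgb_to_od <- function(x) -log10((x + 1 / 255) / 255)

#' Separate an RGB brightfield image into per-stain optical densities
#'
#' Converts each 8-bit channel to optical density, OD = -log10((pixel +
#' 1/255) / 255), and projects the per-pixel OD vector onto the stain
#' basis (rows of the absorbance matrix). Under Beer-Lambert the stain
#' amount is linear in OD, so on noiseless synthetic slides the recovered
#' channels reproduce the rendered fields up to 8-bit quantization.
#'
#' @param image Integer/numeric array height x width x 3, values 0-255.
#' @param matrix 3x3 absorbance matrix, rows hematoxylin / red / residual;
#'   rows are re-normalized to unit length. Collinear rows are an error.
#' @param clip Clip negative stain amounts to 0 (default TRUE). With
#'   `clip = FALSE` the decomposition is exactly invertible.
#' @return An object of class `"stain_channels"`: list with matrices
#'   `hematoxylin`, `red`, `residual` (same height x width as the image)
#'   and the `matrix` used.
#' @export
separate_stains <- function(image, matrix = default_stain_matrix(),
                            clip = TRUE) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("'image' must be a height x width x 3 RGB array", call. = FALSE)
  if (!all(is.finite(image)))
    stop("'image' contains non-finite values", call. = FALSE)
  m <- normalize_stain_matrix(matrix)
  d <- dim(image)
  od <- rgb_to_od(pmax(0, pmin(255, image)))
  odm <- base::matrix(od, nrow = d[1] * d[2], ncol = 3)
  conc <- odm %*% solve(m)  # OD = conc %*% m
  if (clip) conc[conc < 0] <- 0
  shape <- function(j) base::matrix(conc[, j], d[1], d[2])
  structure(list(hematoxylin = shape(1), red = shape(2),
                 residual = shape(3), matrix = m, clip = clip),
            class = "stain_channels")
}

# Recompose stain channels into an RGB-space OD array (inverse of
# separate_stains with clip = FALSE).
compose_od <- function(channels) {
  m <- channels$matrix
  d <- c(dim(channels$hematoxylin), 3L)
  conc <- cbind(as.vector(channels$hematoxylin),
                as.vector(channels$red),
                as.vector(channels$residual))
  array(conc %*% m, dim = d)
}

#' Estimate the above-background dot intensity threshold
#'
#' Every accepted punctum must exceed a chromogen OD threshold established
#' above background. When a negative-control (dapB-like) red channel is
#' available it defines the background distribution and the threshold is a
#' high quantile of it plus a safety margin; otherwise Otsu's method on
#' the target channel separates signal from background.
#'
#' @param red_channel Red-chromogen OD matrix of the slide being scored.
#' @param background Optional OD matrix sampled from a background
#'   reference (typically the dapB control slide's red channel).
#' @param method `"auto"` (percentile if `background` given, else otsu),
#'   `"otsu"`, `"percentile"`, or `"fixed"`.
#' @param value Threshold for `method = "fixed"`.
#' @param probs Quantile for the percentile method (default 0.995).
#' @param min_threshold Absolute OD floor applied to the otsu and
#'   percentile estimates (default 0.1). On a slide with little or no
#'   signal both estimators otherwise land inside the background noise;
#'   the floor keeps the threshold above any plausible background while
#'   staying far below true chromogen OD. The fixed method is exempt.
#' @return An object of class `"intensity_threshold"`: list with `value`,
#'   `method` and `background_summary` (median, mean, q99, q995 of the
#'   background sample used, where applicable).
#' @export
estimate_dot_threshold <- function(red_channel, background = NULL,
                                   method = c("auto", "otsu", "percentile",
                                              "fixed"),
                                   value = NULL, probs = 0.995,
                                   min_threshold = 0.1) {
  method <- match.arg(method)
  if (length(red_channel) == 0L)
    stop("'red_channel' is empty", call. = FALSE)
  if (method == "auto")
    method <- if (is.null(background)) "otsu" else "percentile"
  bg <- background %||% red_channel
  summ <- c(median = stats::median(bg), mean = mean(bg),
            q99 = unname(stats::quantile(bg, 0.99)),
            q995 = unname(stats::quantile(bg, 0.995)))
  thr <- switch(method,
    fixed = {
      check_positive(value, "value")
      value
    },
    percentile = {
      if (probs <= 0 || probs >= 1)
        stop("'probs' must be in (0, 1)", call. = FALSE)
      q <- unname(stats::quantile(bg, probs))
      q + max(0.02, 0.1 * q)  # margin keeps it strictly above background
    },
    otsu = {
      if (diff(range(red_channel)) < 1e-8)
        stop("otsu thresholding is degenerate on a constant channel; ",
             "use method = 'fixed'", call. = FALSE)
      EBImage::otsu(EBImage::Image(red_channel),
                    range = range(red_channel), levels = 256L)
    })
  if (method != "fixed") thr <- max(thr, min_threshold)
  structure(list(value = thr, method = method, background_summary = summ),
            class = "intensity_threshold")
}

#' @export
print.intensity_threshold <- function(x, ...) {
  cat(sprintf("Dot intensity threshold: OD >= %.4f (method: %s)\n",
              x$value, x$method))
  invisible(x)
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "intensity_threshold")) threshold$value
  else if (is.numeric(threshold) && length(threshold) == 1L) threshold
  else stop("dot detection requires an intensity threshold; ",
            "run estimate_dot_threshold first", call. = FALSE)
}
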