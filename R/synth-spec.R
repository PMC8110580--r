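#' Bin-fraction specification for a synthetic cell population
#'
#' Per-cell dot counts in chromogenic ISH scoring fall into four bins:
#' negative (0 dots), low (1-3), medium (4-9) and high (10+). A
#' `bin_fraction_spec` fixes the fraction of cells in each bin; within a
#' bin, counts are sampled uniformly over the bin's support, with the open
#' high bin capped at `dot_cap`.
#'
#' @param negative,low,medium,high Fractions of cells per bin; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @param dot_cap Upper bound for counts sampled in the high bin
#'   (default 25). Must be >= 10.
#' @return An object of class `"bin_fraction_spec"`.
#' @examples
#' bin_fraction_spec(0.25, 0.25, 0.25, 0.25)
#' @export
bin_fraction_spec <- function(negative, low, medium, high, dot_cap = 25) {
  fr <- c(negative = negative, low = low, medium = medium, high = high)
  if (!is.numeric(fr) || length(fr) != 4L || anyNA(fr) || any(fr < 0))
    stop("bin fractions must be four non-negative numbers", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9)
    stop(sprintf("bin fractions must sum to 1 (got %.12g)", sum(fr)),
         call. = FALSE)
  if (!is.numeric(dot_cap) || length(dot_cap) != 1L || dot_cap < 10)
    stop("'dot_cap' must be a single number >= 10", call. = FALSE)
  structure(list(fractions = fr, dot_cap = as.integer(dot_cap)),
            class = "bin_fraction_spec")
}

# Per-bin count supports: {0}, {1..3}, {4..9}, {10..dot_cap}.
bin_support <- function(bin, dot_cap) {
  switch(bin,
         negative = 0L,
         low = 1:3,
         medium = 4:9,
         high = 10:dot_cap,
         stop("unknown bin: ", bin, call. = FALSE))
}

BIN_LEVELS <- c("negative", "low", "medium", "high")

#' Draw a per-cell ground-truth count table
#'
#' Samples `n_cells` dot counts according to a [bin_fraction_spec()]: each
#' cell is assigned a bin by the spec's fractions, then a count uniformly
#' from that bin's support. The true H-score is computed analytically from
#' the realized counts.
#'
#' @param spec A [bin_fraction_spec()].
#' @param n_cells Number of cells (>= 1).
#' @param seed RNG seed; the same seed reproduces the table exactly.
#' @return An object of class `"ground_truth"`: list with `cells` (data
#'   frame: `cell_id`, `true_dots`, `bin`, `compartment`), `bin_fractions`
#'   (realized), `h_score` (true H-score of the realized population),
#'   `n_cells` and `seed`.
#' @examples
#' gt <- generate_count_table(bin_fraction_spec(0, 0, 0, 1), 50, seed = 1)
#' gt$h_score  # 300: every cell is in the high bin
#' @export
generate_count_table <- function(spec, n_cells, seed = 1) {
  if (!inherits(spec, "bin_fraction_spec"))
    stop("'spec' must be a bin_fraction_spec", call. = FALSE)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1 ||
      n_cells != round(n_cells))
    stop("'n_cells' must be a positive integer", call. = FALSE)
  n_cells <- as.integer(n_cells)
  counts <- with_seed(seed, {
    bins <- sample(BIN_LEVELS, n_cells, replace = TRUE,
                   prob = spec$fractions)
    vapply(bins, function(b) {
      s <- bin_support(b, spec$dot_cap)
      if (length(s) == 1L) s else sample(s, 1L)
    }, integer(1), USE.NAMES = FALSE)
  })
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    true_dots = counts,
    bin = factor(classify_cell_bin(counts), levels = BIN_LEVELS),
    compartment = "tumor",
    stringsAsFactors = FALSE
  )
  fr <- as.vector(table(cells$bin)) / n_cells
  names(fr) <- BIN_LEVELS
  structure(list(cells = cells,
                 bin_fractions = fr,
                 h_score = compute_h_score(cells$bin)$h_score,
                 n_cells = n_cells,
                 seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", x$n_cells, "cells")
  if (!is.null(x$dots)) cat(",", nrow(x$dots), "dot centers")
  cat("\n  true H-score:", format(x$h_score, digits = 4),
      "\n  bin fractions:",
      paste(sprintf("%s=%.3f", names(x$bin_fractions), x$bin_fractions),
            collapse = " "), "\n")
  invisible(x)
}
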