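# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

um_to_px <- function(um, mpp) um / mpp

px_to_um <- function(px, mpp) px * mpp

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(x)
}

# Centroids / per-label summaries for a label matrix, 0-based (row, col).
label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(), row = numeric(), col = numeric(),
                      area_px = integer()))
  lab <- labels[idx]
  nr <- nrow(labels)
  r0 <- (idx - 1L) %% nr          # 0-based row
  c0 <- (idx - 1L) %/% nr         # 0-based col
  area <- as.vector(table(lab))
  u <- sort(unique(lab))
  data.frame(
    label = u,
    row = as.vector(tapply(r0, lab, mean)),
    col = as.vector(tapply(c0, lab, mean)),
    area_px = area
  )
}

# Pairwise squared distances between two (row, col) point sets.
cross_dist2 <- function(a, b) {
  outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
}

`%||%` <- function(x, y) if (is.null(x)) y else x
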