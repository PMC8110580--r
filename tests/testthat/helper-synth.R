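# Shared fixtures: all synthetic, generated in code at test time.

# Render a small slide; returns image, truth, cfg, gt.
mini_slide <- function(fracs = c(0.25, 0.25, 0.25, 0.25), n_cells = 30,
                       seed = 1, width = 384, height = 384, ...) {
  spec <- bin_fraction_spec(fracs[1], fracs[2], fracs[3], fracs[4])
  gt <- generate_count_table(spec, n_cells, seed = seed)
  cfg <- render_config(width = width, height = height, seed = seed, ...)
  out <- render_slide(gt, cfg)
  out$cfg <- cfg
  out$gt <- gt
  out
}

# Greedy one-to-one matching of two (row, col) point sets within a radius;
# returns the number of matched pairs.
match_points <- function(a, b, radius) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  r2 <- radius^2
  matched <- 0L
  repeat {
    m <- which.min(d2)
    if (d2[m] > r2) break
    i <- (m - 1) %% nrow(d2) + 1
    j <- (m - 1) %/% nrow(d2) + 1
    matched <- matched + 1L
    d2[i, ] <- Inf
    d2[, j] <- Inf
    if (all(is.infinite(d2))) break
  }
  matched
}

# Hand-built cell_set from a centroid table (for assignment-rule tests
# that need exact geometry rather than a rendered slide).
make_cellset <- function(row, col, mpp = 0.25) {
  n <- length(row)
  cells <- data.frame(cell_id = seq_len(n), row = row, col = col,
                      area_um2 = rep(40, n),
                      compartment = rep("unassigned", n),
                      dot_count = rep(NA_integer_, n),
                      evaluable = rep(NA, n), stringsAsFactors = FALSE)
  structure(list(cells = cells, labels = matrix(0L, 1, 1), mpp = mpp),
            class = "cell_set")
}

# Hand-built dot_set likewise.
make_dotset <- function(row, col, mol_equiv = rep(1L, length(row)),
                        mpp = 0.25) {
  n <- length(row)
  dots <- data.frame(dot_id = seq_len(n), row = row, col = col,
                     area_um2 = rep(0.8, n), peak_od = rep(0.9, n),
                     circularity = rep(1, n),
                     mol_equiv = as.integer(mol_equiv),
                     cell_id = rep(NA_integer_, n))
  structure(list(dots = dots, labels = matrix(0L, 1, 1),
                 accepted = integer(0), threshold = 0.15, mpp = mpp,
                 reference_dot_area_um2 = pi * 0.25,
                 min_area_um2 = 0.15, max_area_um2 = 40,
                 min_circularity = 0.2),
            class = "dot_set")
}

# All permutations of 1..n (n small), one per row.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Independent exhaustive-permutation Spearman oracle: rho from rank
# correlation, two-sided p from the full permutation distribution
# (2 * min tail, capped at 1) -- usable for n <= 8.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  P <- all_perms(length(y))
  rhos <- apply(P, 1, function(p) stats::cor(rx, ry[p]))
  eps <- 1e-12
  p <- 2 * min(mean(rhos <= rho + eps), mean(rhos >= rho - eps))
  list(rho = rho, p = min(1, p))
}
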