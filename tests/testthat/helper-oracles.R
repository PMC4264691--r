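# Shared fixtures and independent oracles for the test suite.

# small layout whose anchor lattice is 3 x 3: 3 x 3 subgrids of 3 x 4 spots,
# one positive-control set per subgrid, 3 dilutions
toy_layout <- function() {
  build_layout(n_subgrid_rows = 3, n_subgrid_cols = 3,
               subgrid_height = 3, subgrid_width = 4,
               n_dilutions = 3, dilution_factor = 0.5,
               n_samples_per_subgrid = 2, n_pc_sets_per_subgrid = 1)
}

# naive four-corner bilinear evaluation: scans for the enclosing cell and
# applies the closed-form blend, one query at a time
naive_bilinear <- function(rows, cols, values, r, c) {
  vapply(seq_along(r), function(k) {
    if (r[k] < rows[1] || r[k] > rows[length(rows)] ||
        c[k] < cols[1] || c[k] > cols[length(cols)]) {
      return(NA_real_)
    }
    i <- max(which(rows <= r[k]))
    if (i == length(rows)) i <- i - 1L
    j <- max(which(cols <= c[k]))
    if (j == length(cols)) j <- j - 1L
    t <- (r[k] - rows[i]) / (rows[i + 1] - rows[i])
    u <- (c[k] - cols[j]) / (cols[j + 1] - cols[j])
    (1 - t) * (1 - u) * values[i, j] + (1 - t) * u * values[i, j + 1] +
      t * (1 - u) * values[i + 1, j] + t * u * values[i + 1, j + 1]
  }, numeric(1))
}

# exhaustive nearest-covered-grid-point search with lexicographic tie-break
brute_nearest <- function(rows, cols, values, r, c) {
  cand <- expand.grid(row = seq(ceiling(rows[1]), floor(rows[length(rows)])),
                      col = seq(ceiling(cols[1]), floor(cols[length(cols)])))
  cand <- cand[order(cand$row, cand$col), ]
  vapply(seq_along(r), function(k) {
    d2 <- (cand$row - r[k])^2 + (cand$col - c[k])^2
    best <- cand[which.min(d2), ]   # which.min takes the first = lexic. min
    naive_bilinear(rows, cols, values, best$row, best$col)
  }, numeric(1))
}

# definitional statistics, written out from first principles
oracle_cv <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  100 * sqrt(sum((x - m)^2) / (n - 1)) / m
}
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}
oracle_zprime <- function(p, q) {
  sdp <- sqrt(sum((p - mean(p))^2) / (length(p) - 1))
  sdq <- sqrt(sum((q - mean(q))^2) / (length(q) - 1))
  1 - 3 * (sdp + sdq) / abs(mean(p) - mean(q))
}
oracle_welch <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  (mean(a) - mean(b)) / sqrt(va / length(a) + vb / length(b))
}

# slide whose positive controls all share one noise-free series; other
# spots get arbitrary deterministic intensities
uniform_control_slide <- function(layout = build_default_layout(),
                                  control_level = 1000) {
  rm <- layout$role_map
  intensity <- numeric(nrow(rm))
  pc <- rm$role == "POSITIVE_CONTROL"
  intensity[pc] <- control_level * layout$dilution_factor^(rm$dilution[pc] - 1)
  s <- rm$role == "SAMPLE"
  intensity[s] <- 500 + 7 * (seq_len(sum(s)) %% 101)
  intensity[rm$role == "NEGATIVE_CONTROL"] <- 20
  new_slide(layout, intensity)
}

# mean held-out control-dilution %CV before and after normalization for one
# simulated slide
heldout_cv_pair <- function(sim) {
  norm <- normalize_slide(sim$slide)
  anch <- norm$surface$anchors
  before <- control_dilution_cv(sim$slide, exclude_anchors = anch)
  after <- control_dilution_cv(sim$slide, values = norm$corrected,
                               exclude_anchors = anch)
  c(before = mean(before$cv), after = mean(after$cv))
}
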