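# A single-subgrid layout with two 5-dilution control sets, convenient for
# spelling out anchor-selection cases spot by spot.
mini_layout <- function() {
  build_layout(1, 1, 3, 11, n_dilutions = 5, n_samples_per_subgrid = 2,
               n_pc_sets_per_subgrid = 2)
}

mini_slide <- function(pc1, pc2, invalid_at = integer()) {
  lay <- mini_layout()
  rm <- lay$role_map
  intensity <- rep(100, nrow(rm))
  intensity[rm$set_id %in% "PC001"] <- pc1[rm$dilution[rm$set_id %in% "PC001"]]
  intensity[rm$set_id %in% "PC002"] <- pc2[rm$dilution[rm$set_id %in% "PC002"]]
  valid <- rep(TRUE, nrow(rm))
  valid[invalid_at] <- FALSE
  new_slide(lay, intensity, valid)
}

test_that("median anchor policy picks the median-intensity spot of each set", {
  sl <- mini_slide(pc1 = c(100, 50, 25, 12.5, 6.25),
                   pc2 = c(40, 10, 30, 20, 50))
  a <- select_anchors(sl)
  a <- a[order(a$set_id), ]
  expect_equal(a$pci, c(25, 30))
  # anchor sits at the spot attaining the median value
  sp <- sl$spots
  expect_equal(a$col[1], sp$col[which(sp$set_id %in% "PC001" &
                                        sp$intensity == 25)])
  expect_equal(a$col[2], sp$col[which(sp$set_id %in% "PC002" &
                                        sp$intensity == 30)])

  # even count after invalid-spot removal: the lower-median spot
  sp50 <- which(sp$set_id %in% "PC002" & sp$intensity == 50)
  sl2 <- mini_slide(pc1 = c(100, 50, 25, 12.5, 6.25),
                    pc2 = c(40, 10, 30, 20, 50), invalid_at = sp50)
  a2 <- select_anchors(sl2)
  expect_equal(a2$pci[a2$set_id == "PC002"], 20)
})

test_that("fixed-dilution anchor policy and degenerate sets behave as declared", {
  sl <- mini_slide(pc1 = c(100, 50, 25, 12.5, 6.25),
                   pc2 = c(40, 10, 30, 20, 50))
  a <- select_anchors(sl, policy = "fixed", fixed_dilution = 2)
  a <- a[order(a$set_id), ]
  expect_equal(a$pci, c(50, 10))

  # a set with no valid positive-intensity spot is an error naming the set
  bad <- which(sl$spots$set_id %in% "PC001")
  sl_bad <- mini_slide(pc1 = c(100, 50, 25, 12.5, 6.25),
                       pc2 = c(40, 10, 30, 20, 50), invalid_at = bad)
  expect_error(select_anchors(sl_bad), "PC001")

  # constant control field: every anchor carries the constant
  sl_c <- mini_slide(pc1 = rep(7, 5), pc2 = rep(7, 5))
  expect_equal(select_anchors(sl_c)$pci, c(7, 7))
})

test_that("reference intensity is the mean anchor PCI", {
  mk <- function(pci) {
    structure(data.frame(set_id = paste0("PC", seq_along(pci)),
                         row = 1, col = seq_along(pci),
                         subgrid_row = 1, subgrid_col = 1, pci = pci),
              class = c("rppa_anchors", "data.frame"))
  }
  expect_equal(compute_reference(mk(c(10, 20, 30))), 20)
  expect_equal(compute_reference(mk(7)), 7)
  set.seed(101)
  pci <- rlnorm(96, log(5000), 0.3)
  expect_equal(compute_reference(mk(pci)), sum(pci) / 96, tolerance = 1e-12)
  expect_error(compute_reference(data.frame(pci = numeric(0))), "no anchors")
})

lat <- function(rows, cols, values) {
  structure(list(rows = rows, cols = cols,
                 values = matrix(values, length(rows), length(cols),
                                 byrow = TRUE)),
            class = "rppa_lattice")
}

test_that("bilinear interpolation is exact at knots, constant-preserving and bounded", {
  L <- lat(c(1, 5, 9), c(1, 4, 7), rep(3.5, 9))
  expect_equal(bilinear_interpolate(L, c(2.2, 5, 8.9), c(1.7, 4, 6.1)),
               rep(3.5, 3))

  U <- lat(c(0, 1), c(0, 1), c(1, 2, 3, 4))
  expect_equal(bilinear_interpolate(U, 0.5, 0.5), 2.5)
  # knot property at all four corners
  expect_equal(bilinear_interpolate(U, c(0, 0, 1, 1), c(0, 1, 0, 1)),
               c(1, 2, 3, 4))
  expect_error(bilinear_interpolate(U, 1.5, 0.5), "exterior")

  set.seed(202)
  R <- sort(runif(5, 0, 50))
  C <- sort(runif(4, 0, 30))
  V <- matrix(rlnorm(20, 0, 0.5), 5, 4)
  Lr <- structure(list(rows = R, cols = C, values = V),
                  class = "rppa_lattice")
  qr <- runif(200, R[1], R[5])
  qc <- runif(200, C[1], C[4])
  got <- bilinear_interpolate(Lr, qr, qc)
  expect_equal(got, naive_bilinear(R, C, V, qr, qc), tolerance = 1e-12)
  # boundedness by the enclosing cell corners
  for (k in 1:200) {
    i <- findInterval(qr[k], R, all.inside = TRUE)
    j <- findInterval(qc[k], C, all.inside = TRUE)
    corners <- V[i:(i + 1), j:(j + 1)]
    expect_gte(got[k], min(corners) - 1e-12)
    expect_lte(got[k], max(corners) + 1e-12)
  }
  # cross-check against an established implementation
  expect_equal(got,
               pracma::interp2(x = C, y = R, Z = V, xp = qc, yp = qr,
                               method = "linear"),
               tolerance = 1e-10)
})

test_that("nearest-covered-point extrapolation matches exhaustive search", {
  L <- lat(c(10, 20), c(5, 15), c(1, 2, 3, 4))
  # one row above the top anchor row: the point directly below it
  expect_equal(extrapolate_nearest(L, 9, 11),
               bilinear_interpolate(L, 10, 11))
  # covered positions are untouched
  expect_equal(extrapolate_nearest(L, 14, 9), bilinear_interpolate(L, 14, 9))

  set.seed(303)
  R <- c(11, 22, 33, 44)
  C <- c(3, 8, 14, 19, 25)
  V <- matrix(rlnorm(20, log(100), 0.4), 4, 5)
  Lr <- structure(list(rows = R, cols = C, values = V),
                  class = "rppa_lattice")
  # 50 integer queries outside the covered rectangle
  q <- matrix(nrow = 0, ncol = 2)
  while (nrow(q) < 50) {
    cand <- cbind(sample(1:60, 50, TRUE), sample(1:40, 50, TRUE))
    out <- cand[, 1] < 11 | cand[, 1] > 44 | cand[, 2] < 3 | cand[, 2] > 25
    q <- rbind(q, cand[out, , drop = FALSE])
  }
  q <- q[1:50, ]
  expect_equal(extrapolate_nearest(Lr, q[, 1], q[, 2]),
               brute_nearest(R, C, V, q[, 1], q[, 2]), tolerance = 1e-12)
})

test_that("uniform positive controls give the identity correction", {
  sl <- uniform_control_slide()
  norm <- normalize_slide(sl)
  expect_equal(norm$surface$cf, rep(1, 5808), tolerance = 1e-12)
  expect_equal(norm$corrected, sl$spots$intensity, tolerance = 1e-12)
  # spline route too (12 x 8 lattice supports a cubic)
  norm_s <- normalize_slide(sl, method = "spline")
  expect_equal(norm_s$surface$cf, rep(1, 5808), tolerance = 1e-10)
})

test_that("correction factors are scale invariant and corrected values equivariant", {
  cfg <- simulation_config(seed = 5, bias = bias_field("radial_gaussian", 0.25))
  sim <- simulate_slide(cfg)
  n1 <- normalize_slide(sim$slide)
  sl2 <- new_slide(sim$slide$layout, sim$slide$spots$intensity * 3.7)
  n2 <- normalize_slide(sl2)
  expect_equal(n2$surface$cf, n1$surface$cf, tolerance = 1e-12)
  expect_equal(n2$corrected, 3.7 * n1$corrected, tolerance = 1e-12)
})

test_that("pseudo-PCI honours the knot property at every anchor", {
  cfg <- simulation_config(seed = 9, noise_sigma_log = 0.05,
                           bias = bias_field("low_freq_sinusoid", 0.3))
  sim <- simulate_slide(cfg)
  for (method in c("bilinear", "spline")) {
    sf <- build_surface(sim$slide, method = method)
    sp <- sim$slide$spots
    at <- match(paste(sf$anchors$row, sf$anchors$col),
                paste(sp$row, sp$col))
    expect_equal(sf$pseudo_pci[at], sf$anchors$pci, tolerance = 1e-9)
  }
})

test_that("bilinear surface equals naive four-corner evaluation on a 3x3 anchor lattice", {
  lay <- toy_layout()
  set.seed(17)
  rm <- lay$role_map
  intensity <- rlnorm(nrow(rm), log(300), 0.3)
  sl <- new_slide(lay, intensity)
  sf <- build_surface(sl)
  L <- sf$lattice
  expect_equal(dim(L$values), c(3L, 3L))
  expected <- naive_bilinear(L$rows, L$cols, L$values, rm$row, rm$col)
  ext <- is.na(expected)
  expected[ext] <- brute_nearest(L$rows, L$cols, L$values,
                                 rm$row[ext], rm$col[ext])
  expect_equal(sf$pseudo_pci, expected, tolerance = 1e-12)
})

test_that("spline surface reproduces bicubic polynomial control fields", {
  lay <- build_default_layout()
  rm <- lay$role_map
  p_fun <- function(r, c) {
    200 + 1.5 * r + 2 * c + 0.02 * r * c + 1e-4 * r^3 + 2e-4 * c^3 +
      5e-3 * r^2 - 3e-3 * c^2
  }
  sl <- new_slide(lay, p_fun(rm$row, rm$col))
  # fixed-dilution anchors sit at identical within-subgrid positions, so
  # lattice nodes coincide with anchor spots exactly
  sf <- build_surface(sl, method = "spline", anchor_policy = "fixed",
                      fixed_dilution = 3)
  inner <- rm$row >= min(sf$lattice$rows) & rm$row <= max(sf$lattice$rows) &
    rm$col >= min(sf$lattice$cols) & rm$col <= max(sf$lattice$cols)
  truth <- p_fun(rm$row, rm$col)
  expect_lt(max(abs(sf$pseudo_pci[inner] - truth[inner]) / truth[inner]),
            1e-8)
})

test_that("spline requests fall back to bilinear on lattices too small for a cubic", {
  lay <- toy_layout()
  set.seed(23)
  sl <- new_slide(lay, rlnorm(nrow(lay$role_map), log(300), 0.2))
  expect_warning(sf <- build_surface(sl, method = "spline"),
                 "falling back to bilinear")
  expect_equal(sf$method, "bilinear")
})

test_that("correction factors are clamped into bounds and events counted", {
  sl <- mini_slide(pc1 = c(100, 50, 25, 12.5, 6.25) * 1e-4,
                   pc2 = c(100, 50, 25, 12.5, 6.25) * 1e4)
  expect_message(sf <- build_surface(sl), "clamped")
  expect_gte(min(sf$cf), 0.1)
  expect_lte(max(sf$cf), 10)
  expect_gt(sf$n_clamped, 0)
})

test_that("apply_correction divides intensities by CF and preserves flags", {
  sl <- uniform_control_slide()
  sf <- build_surface(sl)
  sf$cf <- rep(2, length(sf$cf))
  norm <- apply_correction(sl, sf)
  expect_equal(norm$corrected, sl$spots$intensity / 2)
  expect_identical(norm$slide$spots$intensity, sl$spots$intensity)

  sf_short <- sf
  sf_short$cf <- sf$cf[-1]
  expect_error(apply_correction(sl, sf_short), "does not cover")
})

test_that("corrected anchor spots land exactly on the reference intensity", {
  cfg <- simulation_config(seed = 31, noise_sigma_log = 0,
                           bias = bias_field("low_freq_sinusoid", 0.3,
                                             phase_row = 0.4, phase_col = 1.1))
  sim <- simulate_slide(cfg)
  norm <- normalize_slide(sim$slide)
  sp <- sim$slide$spots
  at <- match(paste(norm$surface$anchors$row, norm$surface$anchors$col),
              paste(sp$row, sp$col))
  expect_equal(norm$corrected[at], rep(norm$surface$reference, length(at)),
               tolerance = 1e-9)
})

test_that("cellwise-bilinear bias with zero noise is removed exactly", {
  cfg <- simulation_config(seed = 42, noise_sigma_log = 0,
                           bias = bias_field("cellwise_bilinear", 0.3))
  sim <- simulate_slide(cfg)
  norm <- normalize_slide(sim$slide)
  relerr <- abs(norm$corrected - sim$truth$true_intensity) /
    sim$truth$true_intensity
  expect_lt(max(relerr), 1e-9)
})
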