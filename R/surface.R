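# Correction-surface construction: interpolation, extrapolation, CF assembly.

#' Bilinear interpolation on an anchor lattice
#'
#' Evaluates the pseudo-positive-control intensity at query positions lying
#' inside the lattice rectangle: linear in row at fixed column and linear in
#' column at fixed row, exact at the four surrounding anchors, and bounded
#' by their minimum and maximum.
#'
#' @param lattice An `rppa_lattice` from [anchor_lattice()].
#' @param row,col Numeric vectors of query positions (absolute spot indices,
#'   recycled to common length).
#' @return Numeric vector of interpolated values. Queries outside the
#'   lattice rectangle are an error; use [extrapolate_nearest()] for those.
#' @export
bilinear_interpolate <- function(lattice, row, col) {
  n <- max(length(row), length(col))
  row <- rep_len(as.numeric(row), n)
  col <- rep_len(as.numeric(col), n)
  out <- .eval_bilinear(lattice, row, col)
  if (anyNA(out)) {
    stop("query outside the anchor lattice (exterior); ",
         "use extrapolate_nearest()")
  }
  out
}

# vectorized core: returns NA for exterior queries
.eval_bilinear <- function(lattice, row, col) {
  R <- lattice$rows
  C <- lattice$cols
  V <- lattice$values
  inside <- row >= R[1] & row <= R[length(R)] &
    col >= C[1] & col <= C[length(C)]
  out <- rep(NA_real_, length(row))
  if (!any(inside)) return(out)
  r <- row[inside]
  c_ <- col[inside]
  i <- pmin(pmax(findInterval(r, R), 1L), length(R) - 1L)
  j <- pmin(pmax(findInterval(c_, C), 1L), length(C) - 1L)
  if (length(R) == 1L) i <- integer(length(r)) * 0L + 1L
  if (length(C) == 1L) j <- integer(length(c_)) * 0L + 1L
  t <- if (length(R) > 1L) (r - R[i]) / (R[i + 1L] - R[i]) else rep(0, length(r))
  u <- if (length(C) > 1L) (c_ - C[j]) / (C[j + 1L] - C[j]) else rep(0, length(c_))
  i2 <- if (length(R) > 1L) i + 1L else i
  j2 <- if (length(C) > 1L) j + 1L else j
  v11 <- V[cbind(i, j)]
  v12 <- V[cbind(i, j2)]
  v21 <- V[cbind(i2, j)]
  v22 <- V[cbind(i2, j2)]
  out[inside] <- (1 - t) * (1 - u) * v11 + (1 - t) * u * v12 +
    t * (1 - u) * v21 + t * u * v22
  out
}

#' Nearest-covered-point extrapolation outside the anchor lattice
#'
#' Slide regions beyond the outermost positive controls (in the default
#' design, the sample rows above the first control row and the columns
#' flanking the outer control sets) have no surrounding anchors. Such spots
#' take the pseudo-PCI of the nearest grid position covered by the lattice
#' rectangle, under Euclidean distance in spot-index space, with ties broken
#' toward smaller (row, col). For a rectangle this is per-axis clamping to
#' the nearest covered integer position, where the interpolant is then
#' evaluated.
#'
#' @inheritParams bilinear_interpolate
#' @param interpolant Function `(lattice, row, col) -> values` used at the
#'   clamped position; defaults to bilinear evaluation.
#' @return Numeric vector of extrapolated values.
#' @export
extrapolate_nearest <- function(lattice, row, col,
                                interpolant = bilinear_interpolate) {
  n <- max(length(row), length(col))
  row <- rep_len(as.numeric(row), n)
  col <- rep_len(as.numeric(col), n)
  # nearest integer grid position inside the covered rectangle; for integer
  # queries per-axis clamping is the unique Euclidean minimizer, and the
  # ceiling/floor choice lands on the lexicographically smaller tie
  rlo <- ceiling(lattice$rows[1])
  rhi <- floor(lattice$rows[length(lattice$rows)])
  clo <- ceiling(lattice$cols[1])
  chi <- floor(lattice$cols[length(lattice$cols)])
  rq <- pmin(pmax(row, rlo), rhi)
  cq <- pmin(pmax(col, clo), chi)
  interpolant(lattice, rq, cq)
}

# tensor-product cubic spline evaluation on the lattice (FMM end conditions,
# exact on cubic polynomial surfaces); rows first, then columns
.eval_spline <- function(lattice, row, col) {
  R <- lattice$rows
  C <- lattice$cols
  V <- lattice$values
  if (length(R) < 4L || length(C) < 4L) {
    stop("spline evaluation needs >= 4 lattice rows and columns")
  }
  ur <- sort(unique(row))
  uc <- sort(unique(col))
  # spline along rows at each lattice column, evaluated at the query rows
  byrow <- vapply(seq_along(C), function(j) {
    stats::splinefun(R, V[, j], method = "fmm")(ur)
  }, numeric(length(ur)))
  byrow <- matrix(byrow, nrow = length(ur))
  # then along columns at each query row
  full <- t(vapply(seq_along(ur), function(i) {
    stats::splinefun(C, byrow[i, ], method = "fmm")(uc)
  }, numeric(length(uc))))
  full <- matrix(full, nrow = length(ur))
  full[cbind(match(row, ur), match(col, uc))]
}

#' Build the correction-factor surface for a slide
#'
#' The full pipeline from raw slide to per-spot correction factors:
#' anchors are selected from the positive-control sets
#' ([select_anchors()]), assembled into a regular lattice
#' ([anchor_lattice()]), and the pseudo-positive-control intensity is
#' interpolated at every spot (bilinear by default, tensor cubic spline as
#' an alternative; exterior spots take the nearest covered value). Dividing
#' by the reference intensity — the mean anchor PCI — turns the surface into
#' correction factors: CF > 1 marks regions biased high, CF < 1 regions
#' biased low. CFs are finally clamped into `clamp_bounds` so that dead
#' regions of a slide cannot blow up corrected intensities; clamp events are
#' reported via [message()].
#'
#' @param slide An `rppa_slide`.
#' @param method `"bilinear"` (default) or `"spline"`. A spline request on a
#'   lattice with fewer than 4 rows or columns falls back to bilinear with a
#'   warning.
#' @param anchor_policy,fixed_dilution Passed to [select_anchors()].
#' @param clamp_bounds Length-2 positive numeric, the (low, high) CF clamp.
#' @return An object of class `rppa_surface`: list with per-spot `cf` and
#'   `pseudo_pci` (layout order), `reference`, `method`, `clamp_bounds`,
#'   `n_clamped`, `anchors` and `lattice`.
#' @export
build_surface <- function(slide, method = c("bilinear", "spline"),
                          anchor_policy = "median", fixed_dilution = NULL,
                          clamp_bounds = c(0.1, 10)) {
  method <- match.arg(method)
  stopifnot(length(clamp_bounds) == 2, clamp_bounds[1] > 0,
            clamp_bounds[2] > clamp_bounds[1])
  anchors <- select_anchors(slide, policy = anchor_policy,
                            fixed_dilution = fixed_dilution)
  lattice <- anchor_lattice(anchors)
  reference <- compute_reference(anchors)

  if (method == "spline" &&
      (length(lattice$rows) < 4L || length(lattice$cols) < 4L)) {
    warning("anchor lattice too small for a cubic spline (needs >= 4 rows ",
            "and columns); falling back to bilinear")
    method <- "bilinear"
  }
  evalfun <- if (method == "spline") {
    function(lat, r, c) .eval_spline(lat, r, c)
  } else {
    function(lat, r, c) .eval_bilinear(lat, r, c)
  }

  sp <- slide$spots
  pseudo <- evalfun(lattice, sp$row, sp$col)
  ext <- is.na(pseudo)
  if (method == "spline") {
    # spline extends smoothly outside the rectangle; exterior spots still
    # use the nearest covered value, mirroring the bilinear edge rule
    ext <- sp$row < lattice$rows[1] |
      sp$row > lattice$rows[length(lattice$rows)] |
      sp$col < lattice$cols[1] |
      sp$col > lattice$cols[length(lattice$cols)]
  }
  if (any(ext)) {
    pseudo[ext] <- extrapolate_nearest(
      lattice, sp$row[ext], sp$col[ext],
      interpolant = function(lat, r, c) evalfun(lat, r, c))
  }

  cf_raw <- pseudo / reference
  cf <- pmin(pmax(cf_raw, clamp_bounds[1]), clamp_bounds[2])
  n_clamped <- sum(cf != cf_raw | !is.finite(cf_raw))
  if (n_clamped > 0) {
    message(n_clamped, " correction factor(s) clamped into [",
            clamp_bounds[1], ", ", clamp_bounds[2], "]")
  }
  if (any(!is.finite(cf)) || any(cf <= 0)) {
    stop("non-finite or non-positive correction factors")
  }

  structure(list(cf = cf, pseudo_pci = pseudo, reference = reference,
                 method = method, clamp_bounds = clamp_bounds,
                 n_clamped = n_clamped, anchors = anchors,
                 lattice = lattice),
            class = "rppa_surface")
}

#' @export
print.rppa_surface <- function(x, ...) {
  cat(sprintf(
    "RPPA correction surface (%s): %d anchors on a %d x %d lattice\n",
    x$method, nrow(x$anchors), length(x$lattice$rows),
    length(x$lattice$cols)))
  cat(sprintf("  reference <PCI> = %.6g; CF range [%.4g, %.4g]; %d clamped\n",
              x$reference, min(x$cf), max(x$cf), x$n_clamped))
  invisible(x)
}

#' Apply a correction surface to a slide
#'
#' Divides every measured intensity by its correction factor:
#' `corrected = intensity / CF`. Invalid spots are corrected too but keep
#' their flag; raw intensities are preserved on the slide.
#'
#' @param slide An `rppa_slide`.
#' @param surface An `rppa_surface` covering the same layout.
#' @return An object of class `rppa_normalized`: list of `slide`,
#'   `corrected` (per-spot, layout order) and `surface`.
#' @export
apply_correction <- function(slide, surface) {
  if (length(surface$cf) != nrow(slide$spots)) {
    stop("surface does not cover the slide (",
         length(surface$cf), " vs ", nrow(slide$spots), " spots)")
  }
  structure(list(slide = slide,
                 corrected = slide$spots$intensity / surface$cf,
                 surface = surface),
            class = "rppa_normalized")
}

#' @export
print.rppa_normalized <- function(x, ...) {
  cat("Spatially normalized slide\n")
  print(x$surface)
  print(x$slide)
  invisible(x)
}

#' One-call spatial normalization
#'
#' Convenience wrapper: [build_surface()] then [apply_correction()].
#'
#' @inheritParams build_surface
#' @return An `rppa_normalized`.
#' @export
normalize_slide <- function(slide, method = "bilinear",
                            anchor_policy = "median", fixed_dilution = NULL,
                            clamp_bounds = c(0.1, 10)) {
  surface <- build_surface(slide, method = method,
                           anchor_policy = anchor_policy,
                           fixed_dilution = fixed_dilution,
                           clamp_bounds = clamp_bounds)
  apply_correction(slide, surface)
}
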