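# Anchor selection and lattice assembly for the correction surface.

#' Select interpolation anchors from positive-control sets
#'
#' Every positive-control dilution set on the slide contributes one anchor:
#' an intensity (the PCI) pinned to an absolute spot position. Under the
#' default `"median"` policy the anchor is the set's median-intensity valid
#' spot — the dilution most likely to sit in the assay's linear range — and
#' the anchor position is that spot's own position. With an even number of
#' valid spots the lower-median spot is used, so the anchor is always a real
#' printed spot. The `"fixed"` policy instead takes dilution step
#' `fixed_dilution` of every set.
#'
#' @param slide An `rppa_slide`.
#' @param policy `"median"` or `"fixed"`.
#' @param fixed_dilution Dilution step used when `policy = "fixed"`.
#' @return Data frame of class `rppa_anchors`: one row per positive-control
#'   set with `set_id`, absolute `row`/`col`, and `pci`.
#' @export
select_anchors <- function(slide, policy = c("median", "fixed"),
                           fixed_dilution = NULL) {
  policy <- match.arg(policy)
  sp <- slide$spots
  pc <- sp[sp$role == "POSITIVE_CONTROL" & sp$valid & sp$intensity > 0, ,
           drop = FALSE]
  all_sets <- unique(sp$set_id[sp$role == "POSITIVE_CONTROL"])
  empty <- setdiff(all_sets, unique(pc$set_id))
  if (length(empty)) {
    stop("positive-control set(s) with no valid positive-intensity spot: ",
         paste(empty, collapse = ", "))
  }
  if (policy == "fixed") {
    if (is.null(fixed_dilution)) {
      fixed_dilution <- (slide$layout$n_dilutions + 1L) %/% 2L
    }
    pick <- pc[pc$dilution == fixed_dilution, , drop = FALSE]
    empty <- setdiff(all_sets, unique(pick$set_id))
    if (length(empty)) {
      stop("set(s) missing a valid spot at dilution ", fixed_dilution, ": ",
           paste(empty, collapse = ", "))
    }
  } else {
    # lower-median spot per set, ties resolved toward smaller (row, col)
    ord <- order(pc$set_id, pc$intensity, pc$row, pc$col)
    pc <- pc[ord, , drop = FALSE]
    idx <- unlist(lapply(split(seq_len(nrow(pc)), pc$set_id), function(i) {
      i[floor((length(i) + 1L) / 2L)]
    }), use.names = FALSE)
    pick <- pc[idx, , drop = FALSE]
  }
  anchors <- data.frame(set_id = pick$set_id, row = pick$row, col = pick$col,
                        subgrid_row = pick$subgrid_row,
                        subgrid_col = pick$subgrid_col,
                        pci = pick$intensity, stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$row, anchors$col), , drop = FALSE]
  rownames(anchors) <- NULL
  class(anchors) <- c("rppa_anchors", "data.frame")
  anchors
}

#' Reference positive-control intensity
#'
#' The reference against which correction factors are formed: the arithmetic
#' mean of the anchor PCIs, so that the average correction over the anchor
#' lattice is 1 and corrected intensities stay on the scale of the raw data.
#'
#' @param anchors Output of [select_anchors()].
#' @return The mean anchor intensity (positive scalar).
#' @export
compute_reference <- function(anchors) {
  if (NROW(anchors) == 0) stop("no anchors")
  mean(anchors$pci)
}

#' Arrange anchors on a regular rectangular lattice
#'
#' Bilinear interpolation needs four axis-aligned corners around every query
#' point, so the anchors (one per positive-control set) are organized into a
#' rectangular lattice: lattice rows are subgrid rows, lattice columns are
#' the control sets ordered left-to-right within each subgrid row. The
#' coordinate of each lattice line is the mean absolute position of its
#' anchors, which absorbs the within-set jitter of median-spot positions
#' without breaking rectangularity.
#'
#' @param anchors Output of [select_anchors()].
#' @return List of class `rppa_lattice` with increasing coordinate vectors
#'   `rows`, `cols` and value matrix `values` (`length(rows)` x
#'   `length(cols)`).
#' @export
anchor_lattice <- function(anchors) {
  a <- anchors[order(anchors$subgrid_row, anchors$col), , drop = FALSE]
  nr <- length(unique(a$subgrid_row))
  cnt <- table(a$subgrid_row)
  if (length(unique(as.integer(cnt))) != 1L) {
    stop("anchor lattice is ragged: subgrid rows hold differing set counts")
  }
  nc <- as.integer(cnt[1])
  rows <- rowMeans(matrix(a$row, nrow = nr, ncol = nc, byrow = TRUE))
  cols <- colMeans(matrix(a$col, nrow = nr, ncol = nc, byrow = TRUE))
  values <- matrix(a$pci, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.unsorted(rows, strictly = TRUE) ||
      is.unsorted(cols, strictly = TRUE)) {
    stop("anchor lattice coordinates are not strictly increasing")
  }
  structure(list(rows = rows, cols = cols, values = values),
            class = "rppa_lattice")
}
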