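#' Construct an RPPA slide layout
#'
#' A layout describes the geometry of a printed slide — a grid of subgrids,
#' each printed by one pin — and assigns a role to every spot: serially
#' diluted experimental samples, serially diluted positive-control lysate
#' (the anchors for spatial normalization), and protein-free buffer spots
#' (negative controls).
#'
#' Within each subgrid the control spots occupy the last spot row: each
#' positive-control set is a contiguous run of `n_dilutions` spots (left to
#' right, undiluted first), followed by buffer spots filling the remainder of
#' the row. Sample dilution series fill the preceding rows row-major, one
#' series after another; any spots left over after all sample series are
#' placed become additional buffer spots.
#'
#' @param n_subgrid_rows,n_subgrid_cols Number of subgrids down / across the
#'   slide.
#' @param subgrid_height,subgrid_width Spots per subgrid down / across.
#' @param n_dilutions Number of steps in every dilution series (step 1 is
#'   undiluted).
#' @param dilution_factor Concentration ratio between consecutive steps,
#'   in (0, 1); 0.5 is a serial half-dilution.
#' @param n_samples_per_subgrid Number of distinct sample series printed in
#'   each subgrid.
#' @param n_pc_sets_per_subgrid Number of positive-control dilution sets
#'   printed in each subgrid.
#' @return An object of class `rppa_layout`: a list with the geometry fields
#'   above plus `role_map`, a data frame with one row per spot giving subgrid
#'   and within-subgrid indices, absolute `row`/`col`, `role` (one of
#'   `"SAMPLE"`, `"POSITIVE_CONTROL"`, `"NEGATIVE_CONTROL"`), `sample_id`,
#'   `dilution` (NA for buffer spots) and `set_id` (positive-control set
#'   identifier, NA otherwise).
#' @seealso [build_default_layout()] for the 132x44 default design.
#' @export
build_layout <- function(n_subgrid_rows, n_subgrid_cols,
                         subgrid_height, subgrid_width,
                         n_dilutions = 5L, dilution_factor = 0.5,
                         n_samples_per_subgrid,
                         n_pc_sets_per_subgrid = 2L) {
  n_subgrid_rows <- as.integer(n_subgrid_rows)
  n_subgrid_cols <- as.integer(n_subgrid_cols)
  subgrid_height <- as.integer(subgrid_height)
  subgrid_width <- as.integer(subgrid_width)
  n_dilutions <- as.integer(n_dilutions)
  n_samples_per_subgrid <- as.integer(n_samples_per_subgrid)
  n_pc_sets_per_subgrid <- as.integer(n_pc_sets_per_subgrid)
  stopifnot(n_subgrid_rows >= 1, n_subgrid_cols >= 1,
            subgrid_height >= 2, subgrid_width >= 1,
            n_dilutions >= 1, dilution_factor > 0, dilution_factor < 1,
            n_pc_sets_per_subgrid >= 1)
  if (n_pc_sets_per_subgrid * n_dilutions > subgrid_width) {
    stop("control row too narrow: ", n_pc_sets_per_subgrid, " sets of ",
         n_dilutions, " dilutions do not fit in ", subgrid_width, " columns")
  }
  if (n_samples_per_subgrid * n_dilutions > (subgrid_height - 1L) * subgrid_width) {
    stop("sample series do not fit in the subgrid above the control row")
  }

  n_subgrids <- n_subgrid_rows * n_subgrid_cols
  per <- subgrid_height * subgrid_width

  # within-subgrid template, row-major spot index 1..per
  spot_row <- rep(seq_len(subgrid_height), each = subgrid_width)
  spot_col <- rep(seq_len(subgrid_width), times = subgrid_height)
  role <- rep("NEGATIVE_CONTROL", per)
  dil <- rep(NA_integer_, per)
  sample_slot <- rep(NA_integer_, per)   # within-subgrid sample index
  set_slot <- rep(NA_integer_, per)      # within-subgrid PC-set index

  idx_samples <- seq_len(n_samples_per_subgrid * n_dilutions)
  role[idx_samples] <- "SAMPLE"
  sample_slot[idx_samples] <- (idx_samples - 1L) %/% n_dilutions + 1L
  dil[idx_samples] <- (idx_samples - 1L) %% n_dilutions + 1L

  ctrl_row_start <- (subgrid_height - 1L) * subgrid_width
  idx_pc <- ctrl_row_start + seq_len(n_pc_sets_per_subgrid * n_dilutions)
  role[idx_pc] <- "POSITIVE_CONTROL"
  set_slot[idx_pc] <- (seq_along(idx_pc) - 1L) %/% n_dilutions + 1L
  dil[idx_pc] <- (seq_along(idx_pc) - 1L) %% n_dilutions + 1L

  sg <- expand.grid(subgrid_col = seq_len(n_subgrid_cols),
                    subgrid_row = seq_len(n_subgrid_rows))
  # subgrid linear index, row-major across the slide
  sg_idx <- (sg$subgrid_row - 1L) * n_subgrid_cols + sg$subgrid_col

  role_map <- data.frame(
    subgrid_row = rep(sg$subgrid_row, each = per),
    subgrid_col = rep(sg$subgrid_col, each = per),
    spot_row = rep(spot_row, n_subgrids),
    spot_col = rep(spot_col, n_subgrids),
    role = rep(role, n_subgrids),
    dilution = rep(dil, n_subgrids),
    stringsAsFactors = FALSE
  )
  role_map$row <- (role_map$subgrid_row - 1L) * subgrid_height + role_map$spot_row
  role_map$col <- (role_map$subgrid_col - 1L) * subgrid_width + role_map$spot_col

  sg_rep <- rep(sg_idx, each = per)
  samp <- rep(sample_slot, n_subgrids)
  sets <- rep(set_slot, n_subgrids)
  sample_global <- (sg_rep - 1L) * n_samples_per_subgrid + samp
  set_global <- (sg_rep - 1L) * n_pc_sets_per_subgrid + sets

  wid_s <- max(4L, nchar(as.character(n_subgrids * n_samples_per_subgrid)))
  role_map$sample_id <- ifelse(
    role_map$role == "SAMPLE",
    sprintf("S%0*d", wid_s, sample_global),
    ifelse(role_map$role == "POSITIVE_CONTROL",
           sprintf("PC%03d", set_global), "BUF"))
  role_map$set_id <- ifelse(role_map$role == "POSITIVE_CONTROL",
                            sprintf("PC%03d", set_global), NA_character_)

  structure(list(
    n_subgrid_rows = n_subgrid_rows, n_subgrid_cols = n_subgrid_cols,
    subgrid_height = subgrid_height, subgrid_width = subgrid_width,
    n_dilutions = n_dilutions, dilution_factor = dilution_factor,
    n_samples_per_subgrid = n_samples_per_subgrid,
    n_pc_sets_per_subgrid = n_pc_sets_per_subgrid,
    role_map = role_map
  ), class = "rppa_layout")
}

#' The default 132x44 RPPA slide layout
#'
#' The standard design: 48 subgrids (12 down, 4 across) of 11x11 spots, 5808
#' spots in all. Each subgrid carries 22 samples and 2 positive-control sets,
#' every series in five serial half-dilutions, plus one buffer spot — so a
#' slide holds 1056 samples, 96 positive-control sets (480 spots) and 48
#' negative-control spots. The positive-control sets recur at the same
#' within-subgrid position in every subgrid, giving a regular 12x8 anchor
#' lattice for interpolation.
#'
#' @return An `rppa_layout`; see [build_layout()].
#' @examples
#' lay <- build_default_layout()
#' table(lay$role_map$role)
#' @export
build_default_layout <- function() {
  build_layout(n_subgrid_rows = 12L, n_subgrid_cols = 4L,
               subgrid_height = 11L, subgrid_width = 11L,
               n_dilutions = 5L, dilution_factor = 0.5,
               n_samples_per_subgrid = 22L, n_pc_sets_per_subgrid = 2L)
}

#' Absolute slide position of a grid coordinate
#'
#' Maps (subgrid row, subgrid col, spot row, spot col) — the MicroVigene
#' Main Row / Main Col / Sub Row / Sub Col vocabulary, all 1-based — to the
#' absolute (row, col) spot index on the full slide. The map is a bijection
#' onto `1..n_subgrid_rows*subgrid_height` x `1..n_subgrid_cols*subgrid_width`.
#'
#' @param subgrid_row,subgrid_col,spot_row,spot_col Integer vectors
#'   (recycled to common length).
#' @param layout An `rppa_layout`.
#' @return A data frame with columns `row` and `col`.
#' @export
absolute_position <- function(subgrid_row, subgrid_col, spot_row, spot_col,
                              layout) {
  n <- max(length(subgrid_row), length(subgrid_col),
           length(spot_row), length(spot_col))
  subgrid_row <- rep_len(as.integer(subgrid_row), n)
  subgrid_col <- rep_len(as.integer(subgrid_col), n)
  spot_row <- rep_len(as.integer(spot_row), n)
  spot_col <- rep_len(as.integer(spot_col), n)
  bad <- subgrid_row < 1L | subgrid_row > layout$n_subgrid_rows |
    subgrid_col < 1L | subgrid_col > layout$n_subgrid_cols |
    spot_row < 1L | spot_row > layout$subgrid_height |
    spot_col < 1L | spot_col > layout$subgrid_width
  if (any(bad)) {
    stop("coordinate outside layout bounds at index ", which(bad)[1])
  }
  data.frame(row = (subgrid_row - 1L) * layout$subgrid_height + spot_row,
             col = (subgrid_col - 1L) * layout$subgrid_width + spot_col)
}

#' @export
print.rppa_layout <- function(x, ...) {
  rm <- x$role_map
  cat(sprintf("RPPA slide layout: %d x %d spots (%d subgrids of %d x %d)\n",
              x$n_subgrid_rows * x$subgrid_height,
              x$n_subgrid_cols * x$subgrid_width,
              x$n_subgrid_rows * x$n_subgrid_cols,
              x$subgrid_height, x$subgrid_width))
  cat(sprintf("  %d sample series, %d positive-control sets, %d buffer spots\n",
              length(unique(rm$sample_id[rm$role == "SAMPLE"])),
              length(unique(rm$set_id[rm$role == "POSITIVE_CONTROL"])),
              sum(rm$role == "NEGATIVE_CONTROL")))
  cat(sprintf("  %d dilutions per series, factor %g\n",
              x$n_dilutions, x$dilution_factor))
  invisible(x)
}

#' Read / write a layout declaration file
#'
#' Layouts are serialized as YAML key-value files holding the geometric
#' parameters accepted by [build_layout()]; the role map is reconstructed on
#' read, so the file stays small and editable.
#'
#' @param path File path.
#' @param layout An `rppa_layout` (for writing).
#' @return `read_layout_file` returns an `rppa_layout`;
#'   `write_layout_file` returns `path` invisibly.
#' @export
read_layout_file <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("n_subgrid_rows", "n_subgrid_cols", "subgrid_height",
            "subgrid_width", "n_samples_per_subgrid")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("layout file missing fields: ",
                         paste(miss, collapse = ", "))
  build_layout(n_subgrid_rows = y$n_subgrid_rows,
               n_subgrid_cols = y$n_subgrid_cols,
               subgrid_height = y$subgrid_height,
               subgrid_width = y$subgrid_width,
               n_dilutions = y$n_dilutions %||% 5L,
               dilution_factor = y$dilution_factor %||% 0.5,
               n_samples_per_subgrid = y$n_samples_per_subgrid,
               n_pc_sets_per_subgrid = y$n_pc_sets_per_subgrid %||% 2L)
}

#' @rdname read_layout_file
#' @export
write_layout_file <- function(layout, path) {
  yaml::write_yaml(layout[c("n_subgrid_rows", "n_subgrid_cols",
                            "subgrid_height", "subgrid_width",
                            "n_dilutions", "dilution_factor",
                            "n_samples_per_subgrid",
                            "n_pc_sets_per_subgrid")], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
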