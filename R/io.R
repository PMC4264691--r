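# Slide container and MicroVigene-style table I/O.

#' Assemble a slide from a layout and per-spot intensities
#'
#' @param layout An `rppa_layout`.
#' @param intensity Numeric vector of measured signal intensities, one per
#'   spot, in the order of `layout$role_map`.
#' @param valid Logical vector flagging usable spots. Invalid spots are
#'   excluded from anchor selection and QC statistics but still receive a
#'   correction factor.
#' @param antibody,slide_id Free-text metadata carried through output tables.
#' @return An object of class `rppa_slide`: list of `layout`, `spots` (the
#'   role map plus `intensity` and `valid` columns) and `metadata`.
#' @export
new_slide <- function(layout, intensity, valid = NULL,
                      antibody = "", slide_id = "") {
  stopifnot(inherits(layout, "rppa_layout"))
  n <- nrow(layout$role_map)
  if (length(intensity) != n) {
    stop("intensity must have one value per layout spot (", n, ")")
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (any(intensity[valid] < 0)) stop("negative intensity on a valid spot")
  spots <- layout$role_map
  spots$intensity <- as.numeric(intensity)
  spots$valid <- as.logical(valid)
  structure(list(layout = layout, spots = spots,
                 metadata = list(antibody = antibody, slide_id = slide_id)),
            class = "rppa_slide")
}

#' @export
print.rppa_slide <- function(x, ...) {
  cat(sprintf("RPPA slide%s%s: %d spots (%d invalid)\n",
              if (nzchar(x$metadata$slide_id))
                paste0(" ", x$metadata$slide_id) else "",
              if (nzchar(x$metadata$antibody))
                paste0(" [", x$metadata$antibody, "]") else "",
              nrow(x$spots), sum(!x$spots$valid)))
  print(x$layout)
  invisible(x)
}

# canonical column names of the tab-delimited spot table
.qcols <- c(subgrid_row = "Main Row", subgrid_col = "Main Col",
            spot_row = "Sub Row", spot_col = "Sub Col",
            sample_id = "Sample", dilution = "Dilution",
            intensity = "Signal")

#' Read a spot quantification table into a slide
#'
#' Ingests MicroVigene-style tab-delimited output: one record per spot with
#' grid indices (`Main Row`, `Main Col`, `Sub Row`, `Sub Col`), `Sample`,
#' `Dilution` and `Signal` columns. Lines starting with `#` are treated as
#' comments (provenance headers written by [write_slide()]). Records are
#' matched to the layout by grid coordinate; spots of the layout missing
#' from the table become invalid spots with intensity 0 (with a warning),
#' duplicated or out-of-bounds coordinates and non-numeric signals are
#' errors.
#'
#' @param path Path to (or connection for) the tab-delimited table.
#' @param layout The `rppa_layout` the table must conform to.
#' @param columns Named character vector remapping the expected column
#'   names; names are the internal keys of `.qcols`.
#' @param antibody,slide_id Metadata; default taken from the file's
#'   provenance header when present.
#' @return An `rppa_slide`. If the table has a `Corrected` column it is
#'   attached as attribute `"corrected"`.
#' @export
read_quantification <- function(path, layout, columns = NULL,
                                antibody = NULL, slide_id = NULL) {
  cols <- .qcols
  if (!is.null(columns)) cols[names(columns)] <- columns
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- cols[c("subgrid_row", "subgrid_col", "spot_row", "spot_col",
                 "intensity")]
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("quantification table missing columns: ",
         paste(miss, collapse = ", "))
  }
  sig <- tab[[cols["intensity"]]]
  if (!is.numeric(sig)) {
    bad <- which(is.na(suppressWarnings(as.numeric(sig))))[1]
    stop("non-numeric intensity at table row ", bad)
  }

  pos <- absolute_position(tab[[cols["subgrid_row"]]],
                           tab[[cols["subgrid_col"]]],
                           tab[[cols["spot_row"]]],
                           tab[[cols["spot_col"]]], layout)
  ncol_slide <- layout$n_subgrid_cols * layout$subgrid_width
  key <- (pos$row - 1L) * ncol_slide + pos$col
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate coordinate at table row ", d, " (absolute position ",
         pos$row[d], ",", pos$col[d], ")")
  }

  rm <- layout$role_map
  lkey <- (rm$row - 1L) * ncol_slide + rm$col
  m <- match(lkey, key)
  if (anyNA(m)) {
    warning(sum(is.na(m)), " layout spot(s) missing from table; ",
            "marked invalid with intensity 0")
  }
  intensity <- ifelse(is.na(m), 0, sig[m])
  valid <- !is.na(m)
  if ("Valid" %in% names(tab)) {
    flg <- as.logical(tab[["Valid"]][m])
    valid <- valid & !is.na(flg) & flg
  }

  sl <- new_slide(layout, intensity, valid,
                  antibody = antibody %||% "", slide_id = slide_id %||% "")
  if ("Corrected" %in% names(tab)) {
    corr <- rep(NA_real_, nrow(rm))
    corr[valid] <- tab[["Corrected"]][m[valid]]
    attr(sl, "corrected") <- corr
  }
  sl
}

#' Write a slide (optionally with corrected intensities) as a spot table
#'
#' Emits the tab-delimited schema read by [read_quantification()], preceded
#' by `#`-prefixed provenance comment lines. When `corrected` (or a
#' normalized slide's values) is supplied, `Corrected` and `CF` columns are
#' appended to the raw `Signal`.
#'
#' @param slide An `rppa_slide`.
#' @param path Output file path or connection.
#' @param corrected Optional numeric vector of corrected intensities, one
#'   per spot in layout order.
#' @param cf Optional per-spot correction factors, written alongside.
#' @param extra_header Character vector of extra provenance lines (written
#'   as `# ...`).
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path, corrected = NULL, cf = NULL,
                        extra_header = character()) {
  sp <- slide$spots
  if (!is.null(corrected) && length(corrected) != nrow(sp)) {
    stop("corrected must cover every spot")
  }
  out <- data.frame(sp$subgrid_row, sp$subgrid_col, sp$spot_row, sp$spot_col,
                    sp$sample_id, ifelse(is.na(sp$dilution), "", sp$dilution),
                    format(sp$intensity, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    as.integer(sp$valid),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(.qcols[c("subgrid_row", "subgrid_col", "spot_row",
                           "spot_col", "sample_id", "dilution", "intensity")],
                  "Valid")
  if (!is.null(corrected)) {
    out$Corrected <- format(corrected, digits = 15, trim = TRUE,
                            scientific = FALSE)
  }
  if (!is.null(cf)) {
    out$CF <- format(cf, digits = 15, trim = TRUE, scientific = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# rppanorm %s",
                   as.character(utils::packageVersion("rppanorm"))),
           sprintf("# slide_id=%s antibody=%s",
                   slide$metadata$slide_id, slide$metadata$antibody))
  if (length(extra_header)) hdr <- c(hdr, sprintf("# %s", extra_header))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a replicate grouping map
#'
#' A grouping map links `sample_id`s to replicate groups for QC: tab-
#' delimited with columns `Sample`, `Group` and `Kind` (one of
#' `TECHNICAL_INTRA`, `TECHNICAL_INTER`, `BIOLOGICAL`).
#'
#' @param path File path.
#' @param grouping Data frame with columns `sample_id`, `group`, `kind`.
#' @return `read_grouping` returns that data frame.
#' @export
read_grouping <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  miss <- setdiff(c("Sample", "Group", "Kind"), names(tab))
  if (length(miss)) stop("grouping file missing columns: ",
                         paste(miss, collapse = ", "))
  data.frame(sample_id = tab$Sample, group = tab$Group, kind = tab$Kind,
             stringsAsFactors = FALSE)
}

#' @rdname read_grouping
#' @export
write_grouping <- function(grouping, path) {
  out <- data.frame(Sample = grouping$sample_id, Group = grouping$group,
                    Kind = grouping$kind)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
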