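# Replicate-agreement and assay-quality statistics.

#' Percent coefficient of variation
#'
#' `100 * sd / mean` of a set of replicate measurements, with the sample
#' (n-1) standard deviation. The primary within-slide noise metric: slides
#' are conventionally accepted when the average %CV of biological replicates
#' is at or below 15%.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return The %CV (percentage points).
#' @export
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values for %CV")
  m <- mean(values)
  if (m == 0) stop("%CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Pearson correlation between paired replicate measurements
#'
#' Product-moment correlation between corresponding spot intensities (or
#' concentrations) of two slides, used for inter-slide agreement.
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(a, b, method = "pearson")
}

#' Z'-factor of positive/negative control separation
#'
#' Screening-assay quality statistic `1 - 3*(sd_p + sd_n)/|mean_p - mean_n|`
#' (Zhang, Chung and Oldenburg 1999). 1 is the noise-free limit; values
#' above 0.5 indicate an excellent assay window.
#'
#' @param positive,negative Numeric vectors, >= 2 values each, with
#'   distinct means.
#' @return The Z'-factor (<= 1).
#' @export
z_prime <- function(positive, negative) {
  if (length(positive) < 2 || length(negative) < 2) {
    stop("need at least 2 values per group")
  }
  mp <- mean(positive)
  mn <- mean(negative)
  if (mp == mn) stop("Z' undefined for equal group means")
  1 - 3 * (stats::sd(positive) + stats::sd(negative)) / abs(mp - mn)
}

#' Welch's t statistic for a two-group mean difference
#'
#' `(mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with sample variances;
#' reported as a descriptive statistic of control separation, not as a
#' hypothesis test.
#'
#' @param a,b Numeric vectors, >= 2 values each.
#' @return The t statistic.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  (mean(a) - mean(b)) /
    sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
}

# resolve replicate groups to per-spot value vectors; groups are
# (group label x dilution step) cells so that replicates are always
# compared at matching dilution
.resolve_groups <- function(slide, grouping, values = NULL) {
  sp <- slide$spots
  if (is.null(values)) values <- sp$intensity
  keep <- sp$valid & sp$sample_id %in% grouping$sample_id
  grp <- grouping$group[match(sp$sample_id[keep], grouping$sample_id)]
  dil <- sp$dilution[keep]
  lab <- ifelse(is.na(dil), grp, paste0(grp, "@d", dil))
  split(values[keep], lab)
}

#' Within-slide replicate %CV report
#'
#' Resolves a replicate grouping map against a slide, computes the %CV of
#' every replicate group (group label crossed with dilution step, so
#' replicates are compared at matching dilution), and summarizes the slide
#' by the unweighted mean of group %CVs against an acceptance cutoff.
#'
#' @param slide An `rppa_slide`.
#' @param grouping Data frame with columns `sample_id`, `group`, `kind`
#'   (see [read_grouping()]).
#' @param values Optional per-spot values to use instead of raw intensities
#'   (e.g. the `corrected` vector of a normalized slide, or relative
#'   concentrations).
#' @param cv_cutoff Slide acceptance cutoff on the mean %CV (default 15).
#' @return Object of class `rppa_qc`: list with `per_group` (data frame of
#'   group, n, cv), `mean_cv`, `cv_cutoff`, `pass`, and `unresolved` (groups
#'   with fewer than 2 valid spots, excluded from the mean).
#' @export
slide_cv <- function(slide, grouping, values = NULL, cv_cutoff = 15) {
  groups <- .resolve_groups(slide, grouping, values)
  n <- vapply(groups, length, integer(1))
  ok <- n >= 2
  absent <- setdiff(unique(grouping$group),
                    unique(sub("@d[0-9]+$", "", names(groups))))
  if (any(!ok) || length(absent)) {
    warning(sum(!ok) + length(absent),
            " replicate group(s) with fewer than 2 valid spots ",
            "excluded from the slide mean")
  }
  cvs <- vapply(groups[ok], cv_percent, numeric(1))
  per_group <- data.frame(group = names(groups)[ok], n = n[ok], cv = cvs,
                          row.names = NULL, stringsAsFactors = FALSE)
  mean_cv <- mean(cvs)
  structure(list(per_group = per_group, mean_cv = mean_cv,
                 cv_cutoff = cv_cutoff, pass = mean_cv <= cv_cutoff,
                 unresolved = c(names(groups)[!ok], absent)),
            class = "rppa_qc")
}

#' @export
print.rppa_qc <- function(x, ...) {
  cat(sprintf("Slide QC: mean replicate %%CV = %.2f%% over %d groups -> %s",
              x$mean_cv, nrow(x$per_group),
              if (x$pass) "PASS" else "FAIL"),
      sprintf("(cutoff %.4g%%)\n", x$cv_cutoff))
  if (length(x$unresolved)) {
    cat("  unresolved groups:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}

#' %CV of held-out positive-control dilutions
#'
#' All positive-control spots of one dilution are technical replicates of
#' each other. The normalizer consumes one spot per set (the anchor); the
#' remaining control spots are untouched by the fit and their per-dilution
#' %CV before vs after correction is an honest measure of bias removal.
#'
#' @param slide An `rppa_slide`.
#' @param values Optional per-spot values (e.g. corrected intensities);
#'   defaults to raw.
#' @param exclude_anchors Optional `rppa_anchors`; those spots are held out.
#' @return Data frame with `dilution`, `n` and `cv` per control dilution.
#' @export
control_dilution_cv <- function(slide, values = NULL, exclude_anchors = NULL) {
  sp <- slide$spots
  if (is.null(values)) values <- sp$intensity
  keep <- sp$role == "POSITIVE_CONTROL" & sp$valid
  if (!is.null(exclude_anchors)) {
    akey <- paste(exclude_anchors$row, exclude_anchors$col)
    keep <- keep & !(paste(sp$row, sp$col) %in% akey)
  }
  dil <- sp$dilution[keep]
  v <- split(values[keep], dil)
  v <- v[vapply(v, length, integer(1)) >= 2]
  data.frame(dilution = as.integer(names(v)),
             n = vapply(v, length, integer(1)),
             cv = vapply(v, cv_percent, numeric(1)),
             row.names = NULL)
}

#' Before/after normalization QC comparison
#'
#' Tabulates replicate %CV per group before and after correction, the slide
#' means, control-separation statistics (Z' and Welch t on the undiluted
#' positive-control spots vs buffer spots — pooling control dilutions would
#' fold the dilution-series spread into the positive group's dispersion),
#' and — when a duplicate slide pair is supplied — the inter-slide Pearson
#' correlation on matched spot positions.
#'
#' @param raw An `rppa_slide`.
#' @param normalized The matching `rppa_normalized`.
#' @param grouping Replicate grouping map (see [slide_cv()]).
#' @param duplicate Optional list `(raw, normalized)` for a duplicate slide
#'   printed with the same samples in equivalent locations.
#' @param cv_cutoff Passed to [slide_cv()].
#' @return Object of class `rppa_qc_comparison`: list with `per_group`
#'   (group, cv_before, cv_after, delta), `mean_cv_before`, `mean_cv_after`,
#'   `z_prime_before/after`, `welch_t_before/after`, and when a duplicate is
#'   given `rho_before/after`.
#' @export
compare_before_after <- function(raw, normalized, grouping,
                                 duplicate = NULL, cv_cutoff = 15) {
  if (!identical(dim(raw$spots), dim(normalized$slide$spots)) ||
      !identical(raw$layout$role_map$row, normalized$slide$layout$role_map$row)) {
    stop("raw and normalized slides have mismatched layouts")
  }
  before <- slide_cv(raw, grouping, cv_cutoff = cv_cutoff)
  after <- slide_cv(raw, grouping, values = normalized$corrected,
                    cv_cutoff = cv_cutoff)
  per_group <- merge(before$per_group[c("group", "cv")],
                     after$per_group[c("group", "cv")],
                     by = "group", suffixes = c("_before", "_after"))
  per_group$delta <- per_group$cv_after - per_group$cv_before

  sp <- raw$spots
  pos <- sp$role == "POSITIVE_CONTROL" & sp$valid & sp$dilution == 1
  pos[is.na(pos)] <- FALSE
  neg <- sp$role == "NEGATIVE_CONTROL" & sp$valid
  res <- list(per_group = per_group,
              mean_cv_before = before$mean_cv,
              mean_cv_after = after$mean_cv,
              pass_before = before$pass, pass_after = after$pass,
              z_prime_before = z_prime(sp$intensity[pos], sp$intensity[neg]),
              z_prime_after = z_prime(normalized$corrected[pos],
                                      normalized$corrected[neg]),
              welch_t_before = welch_t(sp$intensity[pos], sp$intensity[neg]),
              welch_t_after = welch_t(normalized$corrected[pos],
                                      normalized$corrected[neg]))

  if (!is.null(duplicate)) {
    sp2 <- duplicate$raw$spots
    if (nrow(sp2) != nrow(sp)) stop("duplicate slide layout mismatch")
    m <- sp$valid & sp2$valid
    res$rho_before <- pearson(sp$intensity[m], sp2$intensity[m])
    res$rho_after <- pearson(normalized$corrected[m],
                             duplicate$normalized$corrected[m])
  }
  class(res) <- "rppa_qc_comparison"
  res
}

#' @export
print.rppa_qc_comparison <- function(x, ...) {
  cat(sprintf("Mean replicate %%CV: %.2f%% -> %.2f%%\n",
              x$mean_cv_before, x$mean_cv_after))
  cat(sprintf("Z'-factor: %.3f -> %.3f | Welch t: %.2f -> %.2f\n",
              x$z_prime_before, x$z_prime_after,
              x$welch_t_before, x$welch_t_after))
  if (!is.null(x$rho_before)) {
    cat(sprintf("Duplicate-slide rho: %.4f -> %.4f\n",
                x$rho_before, x$rho_after))
  }
  invisible(x)
}

#' Pooled vs per-dilution correlation between duplicate slides
#'
#' A dilution series spans a wide intensity range by design; a correlation
#' pooled across all dilutions of all samples is therefore inflated by the
#' spread between dilution steps and can overstate reproducibility. This
#' helper computes both the pooled correlation over matched sample spots of
#' a duplicate pair and the correlation within each dilution step, making
#' the range-inflation artefact visible.
#'
#' @param slide_a,slide_b Duplicate `rppa_slide`s (same layout).
#' @param values_a,values_b Optional per-spot values (default raw
#'   intensities).
#' @return List with `pooled` (single rho) and `per_dilution` (data frame of
#'   dilution, n, rho).
#' @export
dilution_series_correlation <- function(slide_a, slide_b,
                                        values_a = NULL, values_b = NULL) {
  spa <- slide_a$spots
  spb <- slide_b$spots
  if (nrow(spa) != nrow(spb)) stop("slides have mismatched layouts")
  if (is.null(values_a)) values_a <- spa$intensity
  if (is.null(values_b)) values_b <- spb$intensity
  m <- spa$role == "SAMPLE" & spa$valid & spb$valid
  pooled <- pearson(values_a[m], values_b[m])
  per <- lapply(split(which(m), spa$dilution[m]), function(i) {
    data.frame(n = length(i), rho = pearson(values_a[i], values_b[i]))
  })
  per_dilution <- do.call(rbind, per)
  per_dilution <- data.frame(dilution = as.integer(names(per)),
                             per_dilution, row.names = NULL)
  list(pooled = pooled, per_dilution = per_dilution)
}
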