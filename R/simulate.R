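# Synthetic slides with known truth: true intensities, a multiplicative
# spatial bias field, and lognormal measurement noise.

#' Declare a spatial bias field
#'
#' A bias field is the simulator's model of spatial variation: a positive
#' multiplicative surface over the slide, normalized to unit mean so that
#' the mean positive-control intensity remains an unbiased reference.
#' Available kinds:
#'
#' * `"constant"` — no spatial bias (field identically 1).
#' * `"linear_gradient"` — intensity ramp along a direction `theta`
#'   (radians from the row axis), spanning `1 - amplitude` to
#'   `1 + amplitude` before unit-mean rescaling.
#' * `"radial_gaussian"` — a Gaussian bump of relative height `amplitude`
#'   centred at `centre` (fractional slide coordinates) with width `sigma`
#'   (fraction of the slide diagonal axes).
#' * `"low_freq_sinusoid"` — a smooth low-frequency wave
#'   `1 + amplitude * sin(2*pi*freq*x + phase_row) * cos(2*pi*freq*y +
#'   phase_col)`; phases left `NULL` are drawn at simulation time, giving
#'   independent bias realisations across slides.
#' * `"cellwise_bilinear"` — node values on the slide's nominal anchor
#'   lattice (the middle-dilution positive-control positions), drawn
#'   uniformly in `1 +/- amplitude` at simulation time unless supplied via
#'   `nodes`, and interpolated bilinearly between nodes (nearest covered
#'   value outside). This field lies exactly in the span of the bilinear
#'   normalizer, so correction recovers the truth to machine precision;
#'   its node values (not the whole slide) are rescaled to unit mean.
#'
#' @param kind Field kind, as above.
#' @param amplitude Fractional amplitude (0.3 = +/-30%).
#' @param theta,centre,sigma,freq,phase_row,phase_col,nodes Kind-specific
#'   parameters, see above.
#' @return Object of class `rppa_bias_field`.
#' @export
bias_field <- function(kind = c("constant", "linear_gradient",
                                "radial_gaussian", "low_freq_sinusoid",
                                "cellwise_bilinear"),
                       amplitude = 0.3, theta = pi / 6,
                       centre = c(0.5, 0.5), sigma = 0.25, freq = 1,
                       phase_row = NULL, phase_col = NULL, nodes = NULL) {
  kind <- match.arg(kind)
  stopifnot(amplitude >= 0, amplitude < 1)
  structure(list(kind = kind, amplitude = amplitude, theta = theta,
                 centre = centre, sigma = sigma, freq = freq,
                 phase_row = phase_row, phase_col = phase_col,
                 nodes = nodes),
            class = "rppa_bias_field")
}

# nominal anchor lattice of a layout: positions of the middle-dilution
# positive-control spots, arranged as anchor_lattice() would arrange them
nominal_lattice <- function(layout) {
  rm <- layout$role_map
  mid <- (layout$n_dilutions + 1L) %/% 2L
  pc <- rm[rm$role == "POSITIVE_CONTROL" & rm$dilution == mid, , drop = FALSE]
  pc <- pc[order(pc$subgrid_row, pc$col), , drop = FALSE]
  nr <- length(unique(pc$subgrid_row))
  nc <- nrow(pc) / nr
  list(rows = rowMeans(matrix(pc$row, nr, nc, byrow = TRUE)),
       cols = colMeans(matrix(pc$col, nr, nc, byrow = TRUE)),
       nr = nr, nc = nc)
}

# materialize a bias field over a layout; consumes RNG for unset random
# parameters. Returns list(field, spot_bias): the resolved field (with any
# drawn parameters fixed) and the per-spot bias in role_map order.
resolve_bias <- function(field, layout) {
  rm <- layout$role_map
  nrow_s <- layout$n_subgrid_rows * layout$subgrid_height
  ncol_s <- layout$n_subgrid_cols * layout$subgrid_width
  x <- (rm$row - 1) / max(nrow_s - 1, 1)
  y <- (rm$col - 1) / max(ncol_s - 1, 1)

  if (field$kind == "cellwise_bilinear") {
    lat <- nominal_lattice(layout)
    nodes <- field$nodes
    if (is.null(nodes)) {
      nodes <- matrix(1 + field$amplitude * (2 * stats::runif(lat$nr * lat$nc) - 1),
                      lat$nr, lat$nc)
    }
    nodes <- nodes / mean(nodes)   # unit mean over the anchor nodes
    field$nodes <- nodes
    lattice <- structure(list(rows = lat$rows, cols = lat$cols,
                              values = nodes), class = "rppa_lattice")
    b <- .eval_bilinear(lattice, rm$row, rm$col)
    ext <- is.na(b)
    if (any(ext)) {
      b[ext] <- extrapolate_nearest(lattice, rm$row[ext], rm$col[ext])
    }
    return(list(field = field, spot_bias = b))
  }

  b0 <- switch(field$kind,
    constant = rep(1, nrow(rm)),
    linear_gradient = {
      u <- cos(field$theta) * x + sin(field$theta) * y
      s <- if (diff(range(u)) > 0) (u - min(u)) / diff(range(u)) else rep(0.5, length(u))
      1 + field$amplitude * (2 * s - 1)
    },
    radial_gaussian = {
      d2 <- (x - field$centre[1])^2 + (y - field$centre[2])^2
      1 + field$amplitude * exp(-d2 / (2 * field$sigma^2))
    },
    low_freq_sinusoid = {
      if (is.null(field$phase_row)) field$phase_row <- stats::runif(1, 0, 2 * pi)
      if (is.null(field$phase_col)) field$phase_col <- stats::runif(1, 0, 2 * pi)
      1 + field$amplitude *
        sin(2 * pi * field$freq * x + field$phase_row) *
        cos(2 * pi * field$freq * y + field$phase_col)
    }
  )
  b <- b0 / mean(b0)   # unit mean over the slide
  list(field = field, spot_bias = b)
}

#' Simulation configuration
#'
#' Bundles everything a simulated slide depends on. Defaults model a
#' well-behaved slide in the default layout: positive-control lysate at a
#' top-dilution signal of 10000 units, sample top intensities lognormal
#' around ~8000 with sdlog 0.5 (a realistic two-order-of-magnitude sample
#' spread), buffer background at 200 units, and 5% multiplicative
#' measurement noise.
#'
#' @param layout An `rppa_layout`.
#' @param seed Integer seed; identical config + seed gives identical slides.
#' @param control_level Top-dilution positive-control intensity.
#' @param sample_meanlog,sample_sdlog Lognormal parameters for sample
#'   top-dilution intensities.
#' @param noise_sigma_log SD of multiplicative lognormal measurement noise.
#' @param background_level Buffer-spot intensity before bias and noise.
#' @param bias An [bias_field()] declaration.
#' @return Object of class `rppa_sim_config`.
#' @export
simulation_config <- function(layout = build_default_layout(), seed = 1L,
                              control_level = 10000,
                              sample_meanlog = log(8000),
                              sample_sdlog = 0.5,
                              noise_sigma_log = 0.05,
                              background_level = 200,
                              bias = bias_field("low_freq_sinusoid")) {
  stopifnot(control_level > 0, background_level >= 0, noise_sigma_log >= 0,
            inherits(layout, "rppa_layout"),
            inherits(bias, "rppa_bias_field"))
  structure(list(layout = layout, seed = as.integer(seed),
                 control_level = control_level,
                 sample_meanlog = sample_meanlog,
                 sample_sdlog = sample_sdlog,
                 noise_sigma_log = noise_sigma_log,
                 background_level = background_level, bias = bias),
            class = "rppa_sim_config")
}

# truth assembly shared by the simulators: per-spot true intensity given
# top-dilution levels per sample series
.true_intensities <- function(layout, sample_tops, control_level,
                              background_level) {
  rm <- layout$role_map
  f <- layout$dilution_factor
  truth <- numeric(nrow(rm))
  is_pc <- rm$role == "POSITIVE_CONTROL"
  is_s <- rm$role == "SAMPLE"
  truth[is_pc] <- control_level * f^(rm$dilution[is_pc] - 1)
  truth[is_s] <- sample_tops[rm$sample_id[is_s]] * f^(rm$dilution[is_s] - 1)
  truth[rm$role == "NEGATIVE_CONTROL"] <- background_level
  truth
}

# measurement step: truth x bias x lognormal noise; consumes RNG
.measure <- function(config, truth) {
  res <- resolve_bias(config$bias, config$layout)
  n <- length(truth)
  noise <- if (config$noise_sigma_log > 0) {
    exp(stats::rnorm(n, 0, config$noise_sigma_log))
  } else rep(1, n)
  list(intensity = truth * res$spot_bias * noise, bias = res$spot_bias,
       noise = noise, field = res$field)
}

#' Simulate one slide with known truth
#'
#' Positive-control sets share a single true dilution series
#' (`control_level * dilution_factor^(step-1)`); each sample series draws an
#' independent lognormal top level and dilutes identically; buffer spots sit
#' at `background_level`. Every spot is then measured as
#' `truth * bias(position) * exp(N(0, noise_sigma_log))`.
#'
#' @param config An [simulation_config()].
#' @return List with `slide` (an `rppa_slide`) and `truth` (a record holding
#'   per-spot `true_intensity`, `bias`, `noise`, and the resolved `field`
#'   and `config`).
#' @export
simulate_slide <- function(config) {
  stopifnot(inherits(config, "rppa_sim_config"))
  set.seed(config$seed)
  rm <- config$layout$role_map
  ids <- unique(rm$sample_id[rm$role == "SAMPLE"])
  tops <- stats::setNames(
    stats::rlnorm(length(ids), config$sample_meanlog, config$sample_sdlog),
    ids)
  truth <- .true_intensities(config$layout, tops, config$control_level,
                             config$background_level)
  meas <- .measure(config, truth)
  slide <- new_slide(config$layout, meas$intensity,
                     slide_id = sprintf("sim%d", config$seed),
                     antibody = "simulated")
  list(slide = slide,
       truth = list(true_intensity = truth, bias = meas$bias,
                    noise = meas$noise, field = meas$field, config = config))
}

#' Simulate a biological-replicate study on one slide
#'
#' Sample series are grouped into experimental conditions of
#' `n_bio_replicates` each (mirroring a drug-perturbation design measured in
#' triplicate); replicates of a condition share a lognormal condition mean
#' and scatter around it with coefficient of variation `replicate_cv`.
#' Replicate sets are printed in successive blocks — replicate 1 of every
#' condition first, then replicate 2, and so on — so the replicates of a
#' condition sit in distant regions of the slide and spatial bias acts
#' between, not within, replicate positions, as in real replicate designs.
#'
#' @param config An [simulation_config()].
#' @param n_bio_replicates Replicates per condition (default 3).
#' @param replicate_cv Biological dispersion as a fraction (0.1 = 10% CV).
#' @return As [simulate_slide()], plus `grouping`: a replicate map
#'   (`sample_id`, `group`, `kind = "BIOLOGICAL"`) in the format
#'   [slide_cv()] consumes.
#' @export
simulate_replicate_study <- function(config, n_bio_replicates = 3L,
                                     replicate_cv = 0.1) {
  stopifnot(inherits(config, "rppa_sim_config"), n_bio_replicates >= 2,
            replicate_cv >= 0)
  set.seed(config$seed)
  rm <- config$layout$role_map
  ids <- unique(rm$sample_id[rm$role == "SAMPLE"])
  n_cond <- length(ids) %/% n_bio_replicates
  if (n_cond < 1) stop("not enough sample slots for the replicate structure")
  used <- ids[seq_len(n_cond * n_bio_replicates)]
  cond <- rep(sprintf("C%03d", seq_len(n_cond)), times = n_bio_replicates)
  cond_mean <- stats::setNames(
    stats::rlnorm(n_cond, config$sample_meanlog, config$sample_sdlog),
    sprintf("C%03d", seq_len(n_cond)))
  sdlog_rep <- sqrt(log(1 + replicate_cv^2))
  tops <- cond_mean[cond] * exp(stats::rnorm(length(used), 0, sdlog_rep))
  names(tops) <- used
  # unused sample slots (when slots are not a multiple of the replicate
  # count) keep independent draws and stay out of the grouping
  rest <- setdiff(ids, used)
  if (length(rest)) {
    tops <- c(tops, stats::setNames(
      stats::rlnorm(length(rest), config$sample_meanlog, config$sample_sdlog),
      rest))
  }
  truth <- .true_intensities(config$layout, tops, config$control_level,
                             config$background_level)
  meas <- .measure(config, truth)
  slide <- new_slide(config$layout, meas$intensity,
                     slide_id = sprintf("sim%d", config$seed),
                     antibody = "simulated")
  list(slide = slide,
       truth = list(true_intensity = truth, bias = meas$bias,
                    noise = meas$noise, field = meas$field, config = config),
       grouping = data.frame(sample_id = used, group = cond,
                             kind = "BIOLOGICAL", stringsAsFactors = FALSE))
}

#' Simulate a duplicate slide pair
#'
#' Two slides printed with the same samples in equivalent locations: a
#' single shared truth, but an independent bias-field realisation and
#' independent noise on each slide.
#'
#' @param config An [simulation_config()]; its `bias` declaration is
#'   resolved independently per slide (random parameters redrawn).
#' @param bias_b Optional distinct [bias_field()] for the second slide.
#' @return List with elements `a` and `b`, each as [simulate_slide()].
#' @export
simulate_duplicate_pair <- function(config, bias_b = NULL) {
  stopifnot(inherits(config, "rppa_sim_config"))
  set.seed(config$seed)
  rm <- config$layout$role_map
  ids <- unique(rm$sample_id[rm$role == "SAMPLE"])
  tops <- stats::setNames(
    stats::rlnorm(length(ids), config$sample_meanlog, config$sample_sdlog),
    ids)
  truth <- .true_intensities(config$layout, tops, config$control_level,
                             config$background_level)
  one <- function(cfg) {
    meas <- .measure(cfg, truth)
    list(slide = new_slide(cfg$layout, meas$intensity,
                           slide_id = sprintf("sim%d", cfg$seed),
                           antibody = "simulated"),
         truth = list(true_intensity = truth, bias = meas$bias,
                      noise = meas$noise, field = meas$field, config = cfg))
  }
  a <- one(config)
  cfg_b <- config
  if (!is.null(bias_b)) cfg_b$bias <- bias_b
  b <- one(cfg_b)
  list(a = a, b = b)
}
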