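#' Configuration for the synthetic-cytometry generators
#'
#' Describes the population structure emulated by the fluorescence
#' generators: true relative expression levels, the split of lognormal
#' cell-to-cell variability into a shared extrinsic and an independent
#' intrinsic component, additive Gaussian autofluorescence, and the
#' fraction of log-variance shared between the two channels of a
#' two-color measurement.
#'
#' @param true_relative_levels Relative expression fractions (one
#'   population per level).
#' @param extrinsic_cv,intrinsic_cv Dimensionless CVs (>= 0).  The split
#'   between the two is a free calibration; the defaults compose to a
#'   total population CV of 0.30 (`(1+cv_e^2)(1+cv_i^2) - 1 = 0.3^2`),
#'   the constitutive-gene noise plateau.
#' @param autofluorescence_mean,autofluorescence_sd Blank signal (a.u.).
#' @param two_color_shared_fraction Fraction of log-variance shared
#'   between channels, in `[0, 1]`.
#' @param n_cells Cells per population (>= 1).
#' @param seed Master seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(true_relative_levels = 1,
                             extrinsic_cv = 0.25, intrinsic_cv = 0.161,
                             autofluorescence_mean = 0,
                             autofluorescence_sd = 0,
                             two_color_shared_fraction = 0.5,
                             n_cells = 10000, seed = 1L) {
  ko_check(is.numeric(true_relative_levels) &&
             all(true_relative_levels >= 0),
           "true_relative_levels must be >= 0")
  for (nm in c("extrinsic_cv", "intrinsic_cv", "autofluorescence_sd")) {
    v <- get(nm)
    ko_check(is_number(v) && v >= 0, paste(nm, "must be >= 0"))
  }
  ko_check(is_number(autofluorescence_mean), "autofluorescence_mean invalid")
  ko_check(is_number(two_color_shared_fraction) &&
             two_color_shared_fraction >= 0 &&
             two_color_shared_fraction <= 1,
           "two_color_shared_fraction must lie in [0, 1]")
  ko_check(is_number(n_cells) && n_cells >= 1, "n_cells must be >= 1")
  structure(list(true_relative_levels = true_relative_levels,
                 extrinsic_cv = extrinsic_cv, intrinsic_cv = intrinsic_cv,
                 autofluorescence_mean = autofluorescence_mean,
                 autofluorescence_sd = autofluorescence_sd,
                 two_color_shared_fraction = two_color_shared_fraction,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "generator_config")
}

# one population of per-cell values at a given level; assumes the RNG
# state is already set by the caller
gen_values <- function(config, level) {
  n <- config$n_cells
  v <- level * rlnorm_cv(n, config$extrinsic_cv) *
    rlnorm_cv(n, config$intrinsic_cv) +
    rnorm(n, config$autofluorescence_mean, config$autofluorescence_sd)
  pmax(v, 0)
}

#' Generate synthetic single-cell fluorescence populations
#'
#' One population per entry of `true_relative_levels`: per-cell value =
#' `level * lognormal(extrinsic) * lognormal(intrinsic) + Gaussian
#' autofluorescence`, truncated at zero.  A pure-autofluorescence blank
#' population (`level = 0`) is appended with `sample_id = "blank"`.
#' Sample `k` uses the counter-derived subseed `k`, so adding populations
#' does not perturb earlier ones.
#'
#' @param config A [generator_config()].
#' @param replicate Replicate index stamped on the samples.
#' @param channel Channel stamped on the samples.
#' @return Named list of [population_sample()] objects (`level_<value>`
#'   entries plus `blank`).
#' @export
gen_population <- function(config, replicate = 1L, channel = "GFP") {
  ko_check(inherits(config, "generator_config"),
           "config must be a generator_config")
  levels <- c(config$true_relative_levels, 0)
  ids <- c(paste0("level_", config$true_relative_levels), "blank")
  out <- vector("list", length(levels))
  for (k in seq_along(levels)) {
    set.seed(derive_seed(config$seed, k))
    out[[k]] <- population_sample(ids[k], gen_values(config, levels[k]),
                                  replicate = replicate, channel = channel)
  }
  names(out) <- ids
  out
}

#' Generate paired two-color populations
#'
#' Both channels of each cell share one extrinsic lognormal factor whose
#' log-variance is `two_color_shared_fraction` of the total per-channel
#' log-variance; the remainder is independent per channel.  The
#' cross-channel Pearson correlation of the noise factors has the
#' lognormal closed form `(exp(f v) - 1) / (exp(v) - 1)` with `v` the
#' total log-variance and `f` the shared fraction.
#'
#' @param config A [generator_config()].
#' @param level_gfp,level_rfp Relative expression levels of the two
#'   reporters.
#' @param replicate Replicate index.
#' @return List with [population_sample()] elements `gfp` and `rfp`
#'   (cells aligned by index).
#' @export
gen_two_color <- function(config, level_gfp, level_rfp, replicate = 1L) {
  ko_check(inherits(config, "generator_config"),
           "config must be a generator_config")
  ko_check(is_number(level_gfp) && level_gfp >= 0 &&
             is_number(level_rfp) && level_rfp >= 0,
           "levels must be >= 0")
  n <- config$n_cells
  v_tot <- log(1 + config$extrinsic_cv^2) + log(1 + config$intrinsic_cv^2)
  f <- config$two_color_shared_fraction
  v_sh <- f * v_tot
  v_in <- (1 - f) * v_tot
  set.seed(derive_seed(config$seed, 101L))
  shared <- rlnorm(n, -v_sh / 2, sqrt(v_sh))
  own_g <- rlnorm(n, -v_in / 2, sqrt(v_in))
  own_r <- rlnorm(n, -v_in / 2, sqrt(v_in))
  af <- function() rnorm(n, config$autofluorescence_mean,
                         config$autofluorescence_sd)
  gfp <- pmax(level_gfp * shared * own_g + af(), 0)
  rfp <- pmax(level_rfp * shared * own_r + af(), 0)
  list(gfp = population_sample("two_color", gfp, replicate, "GFP"),
       rfp = population_sample("two_color", rfp, replicate, "RFP"))
}

#' Generate an aTc titration series
#'
#' Chains the inducer dose--response ([atc_induction()]), decoy dilution
#' of active complexes ([active_dcas9_fraction()]) and the stochastic
#' population simulator: at each aTc value the mean active-dCas9 level
#' rescales the rebinding rate of `base_config`.  With more decoys the
#' expression transition shifts to higher aTc.
#'
#' @param atc_values Inducer concentrations (ng/ml).
#' @param base_config A [sim_config()]; its `rebinding_rate` is the value
#'   at active-dCas9 level 1.
#' @param n_decoys Number of decoy spacers in the array.
#' @param induction Named list of [atc_induction()] parameters
#'   (`vmax`, `km`, `hill`, `basal`).
#' @return data.frame per aTc point: `atc`, `active_level`,
#'   `mean_expression`, `noise_cv`, `mean_occupancy`.
#' @export
gen_titration <- function(atc_values, base_config, n_decoys = 0,
                          induction = list(vmax = 1, km = 10, hill = 2,
                                           basal = 0.002)) {
  ko_check(inherits(base_config, "sim_config"),
           "base_config must be a sim_config")
  ko_check(is.numeric(atc_values) && all(atc_values >= 0),
           "atc_values must be >= 0")
  lev <- do.call(atc_induction, c(list(atc = atc_values), induction)) *
    active_dcas9_fraction(n_decoys)
  out <- vector("list", length(atc_values))
  for (i in seq_along(atc_values)) {
    cfg <- base_config
    cfg$kinetics$rebinding_rate <- base_config$kinetics$rebinding_rate *
      lev[i]
    cfg$seed <- derive_seed(base_config$seed, i)
    s <- simulate_population(cfg)$summary
    out[[i]] <- data.frame(atc = atc_values[i], active_level = lev[i],
                           mean_expression = s$mean_expression,
                           noise_cv = s$noise_cv,
                           mean_occupancy = s$mean_occupancy)
  }
  do.call(rbind, out)
}

#' aTc concentration at half-repression
#'
#' Log-linear interpolation of the expression midpoint of a titration
#' table: the aTc value at which `mean_expression` crosses halfway
#' between its maximum and minimum over the series.
#'
#' @param titration Output of [gen_titration()].
#' @return Midpoint aTc concentration.
#' @export
titration_midpoint <- function(titration) {
  ko_check(is.data.frame(titration) && nrow(titration) >= 3,
           "titration needs >= 3 points")
  ord <- order(titration$atc)
  x <- titration$atc[ord]
  y <- titration$mean_expression[ord]
  half <- (max(y) + min(y)) / 2
  below <- which(y <= half)
  ko_check(length(below) >= 1 && min(below) > 1,
           "series does not cross its midpoint")
  i <- min(below)
  # interpolate in log-aTc where possible
  x1 <- x[i - 1]; x2 <- x[i]; y1 <- y[i - 1]; y2 <- y[i]
  if (x1 > 0) {
    exp(log(x1) + (half - y1) * (log(x2) - log(x1)) / (y2 - y1))
  } else {
    x1 + (half - y1) * (x2 - x1) / (y2 - y1)
  }
}

#' Generate a synthetic feedback dataset
#'
#' Observations are the model steady state at each passage probability,
#' multiplied by lognormal measurement noise, for each replicate.
#'
#' @param params A [feedback_params()] (the ground truth).
#' @param r_values Passage probabilities in `(0, 1]`.
#' @param noise_cv Lognormal measurement CV (>= 0).
#' @param n_replicates Replicates per `r` (>= 1).
#' @param seed Seed.
#' @return A [feedback_dataset()] with attribute `truth = params`.
#' @export
gen_feedback_dataset <- function(params, r_values, noise_cv = 0.05,
                                 n_replicates = 3, seed = 1L) {
  ko_check(inherits(params, "feedback_params"),
           "params must be feedback_params")
  ko_check(is.numeric(r_values) && all(r_values > 0 & r_values <= 1),
           "r_values must lie in (0, 1]")
  ko_check(is_number(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  g_true <- steady_state(r_values, params)
  rows <- list()
  for (rep in seq_len(n_replicates)) {
    set.seed(derive_seed(seed, rep))
    g <- pmin(g_true * rlnorm_cv(length(r_values), noise_cv), 1)
    rows[[rep]] <- data.frame(r = r_values, g_obs = g, replicate = rep)
  }
  d <- do.call(rbind, rows)
  out <- feedback_dataset(d$r, d$g_obs, replicate = d$replicate,
                          condition = params$dapg_label)
  attr(out, "truth") <- params
  out
}

#' Generate a capsule (spherocylinder) cell contour
#'
#' Samples `n_vertices` points at equal arc length along the outline of a
#' spherocylinder of given total length and cap radius, optionally jitters
#' them with Gaussian noise (applied in the body frame, so a rotated
#' contour with the same seed is the same noisy polygon rigidly rotated),
#' then rotates and translates the polygon.
#'
#' @param radius Cap radius (micrometres).
#' @param length Total pole-to-pole length (>= `2 * radius`).
#' @param orientation Rotation of the long axis (degrees).
#' @param center Centre `c(x, y)`.
#' @param vertex_noise_sd Gaussian jitter sd per coordinate.
#' @param n_vertices Number of contour vertices (>= 20).
#' @param seed Seed for the jitter.
#' @param cell_id Label.
#' @return A [cell_contour()].
#' @export
gen_capsule_contour <- function(radius, length, orientation = 0,
                                center = c(0, 0), vertex_noise_sd = 0,
                                n_vertices = 100, seed = 1L,
                                cell_id = "cell") {
  ko_check(is_number(radius) && radius > 0, "radius must be > 0")
  ko_check(is_number(length) && length >= 2 * radius,
           "length must be >= 2 * radius")
  ko_check(is_number(n_vertices) && n_vertices >= 20,
           "n_vertices must be >= 20")
  ko_check(is_number(vertex_noise_sd) && vertex_noise_sd >= 0,
           "vertex_noise_sd must be >= 0")
  half <- length / 2 - radius           # half-length of the straight part
  straight <- 2 * half
  cap <- pi * radius
  per <- 2 * straight + 2 * cap
  s <- (seq_len(n_vertices) - 1) / n_vertices * per
  xy <- t(vapply(s, function(si) {
    if (si < straight) {                      # top side, +x direction
      c(-half + si, radius)
    } else if (si < straight + cap) {         # right cap
      th <- (si - straight) / radius          # 0..pi from top to bottom
      c(half + radius * sin(th), radius * cos(th))
    } else if (si < 2 * straight + cap) {     # bottom side, -x direction
      c(half - (si - straight - cap), -radius)
    } else {                                  # left cap
      th <- (si - 2 * straight - cap) / radius
      c(-half - radius * sin(th), -radius * cos(th))
    }
  }, numeric(2)))
  if (vertex_noise_sd > 0) {
    set.seed(as.integer(seed))
    xy <- xy + matrix(rnorm(2 * n_vertices, 0, vertex_noise_sd),
                      ncol = 2)
  }
  th <- orientation * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- xy %*% t(rot)
  xy[, 1] <- xy[, 1] + center[1]
  xy[, 2] <- xy[, 2] + center[2]
  cell_contour(cell_id, xy)
}
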