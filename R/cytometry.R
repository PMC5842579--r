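#' Single-cell fluorescence sample
#'
#' One cytometry population: per-cell fluorescence values for a given
#' sample, replicate and channel.
#'
#' @param sample_id Sample label.
#' @param values Numeric vector of per-cell fluorescence (a.u.), finite.
#' @param replicate Replicate index.
#' @param channel `"GFP"` or `"RFP"`.
#' @return An object of class `population_sample`.
#' @export
population_sample <- function(sample_id, values, replicate = 1L,
                              channel = c("GFP", "RFP")) {
  channel <- match.arg(channel)
  ko_check(is.character(sample_id) && length(sample_id) == 1L,
           "sample_id must be a single string")
  ko_check(is.numeric(values) && length(values) >= 2 &&
             all(is.finite(values)),
           "values must be >= 2 finite numbers")
  structure(list(sample_id = sample_id, replicate = as.integer(replicate),
                 channel = channel, values = as.numeric(values)),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf("%s (%s, rep %d): %d cells, mean %.4g, cv %.3g\n",
              x$sample_id, x$channel, x$replicate, length(x$values),
              mean(x$values), sd(x$values) / mean(x$values)))
  invisible(x)
}

#' Discard outliers beyond three standard deviations
#'
#' Single-pass rule: the population mean and sd are computed once on the
#' full sample and every value farther than `k` sd from the mean is
#' discarded.  The rule is not iterated.
#'
#' @param sample A [population_sample()] (>= 3 values).
#' @param k Cut-off in standard deviations (default 3).
#' @return The trimmed [population_sample()], with attribute `n_removed`.
#' @export
trim_outliers <- function(sample, k = 3) {
  ko_check(inherits(sample, "population_sample"),
           "sample must be a population_sample")
  ko_check(length(sample$values) >= 3, "need at least 3 values to trim")
  mu <- mean(sample$values)
  s <- sd(sample$values)
  keep <- abs(sample$values - mu) <= k * s
  out <- sample
  out$values <- sample$values[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Blank-corrected expression noise
#'
#' Noise is `sigma / mu` with `mu = mean(sample) - mean(blank)` and the
#' sample sd corrected for autofluorescence.  The default correction is in
#' quadrature, `sigma = sqrt(sd_sample^2 - sd_blank^2)`, treating
#' autofluorescence as an independent additive noise source;
#' `method = "linear"` subtracts the sds directly for exact replication of
#' a linear-subtraction convention.
#'
#' @param sample,blank [population_sample()] objects; `blank` is a
#'   no-reporter (autofluorescence) population.
#' @param method `"quadrature"` (default) or `"linear"`.
#' @return A list of class `noise_summary`: `mu`, `sigma`, `sigma_sample`,
#'   `sigma_blank`, `noise`, `method`.
#' @export
noise_cv <- function(sample, blank, method = c("quadrature", "linear")) {
  method <- match.arg(method)
  ko_check(inherits(sample, "population_sample") &&
             inherits(blank, "population_sample"),
           "sample and blank must be population_sample objects")
  mu <- mean(sample$values) - mean(blank$values)
  s_s <- sd(sample$values)
  s_b <- sd(blank$values)
  if (s_b > s_s) {
    ko_stop("blank sd exceeds sample sd: corrected variance is negative",
            "kickout_negative_variance")
  }
  if (mu <= 0) {
    ko_stop("sample mean does not exceed the blank mean",
            "kickout_below_background")
  }
  sig <- if (method == "quadrature") sqrt(s_s^2 - s_b^2) else s_s - s_b
  structure(list(mu = mu, sigma = sig, sigma_sample = s_s, sigma_blank = s_b,
                 noise = sig / mu, method = method),
            class = "noise_summary")
}

#' Relative expression table across samples
#'
#' Blank-corrects every sample mean and normalizes to the non-targeting
#' control: `(mean - mean_blank) / (mean_control - mean_blank)`.  The
#' control row is 1 by construction, and the table is invariant to a
#' common multiplicative gain.
#'
#' @param samples List of [population_sample()] objects.
#' @param control_id `sample_id` of the non-targeting control.
#' @param blank_id `sample_id` of the no-reporter blank.
#' @return data.frame with `sample_id`, `replicate`, `n_cells`, `mean`,
#'   `relative_mean` (blank and control included).
#' @export
relative_expression_table <- function(samples, control_id, blank_id) {
  ko_check(is.list(samples) && length(samples) >= 1 &&
             all(vapply(samples, inherits, logical(1), "population_sample")),
           "samples must be a list of population_sample objects")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  ko_check(control_id %in% ids, "control sample not present")
  ko_check(blank_id %in% ids, "blank sample not present")
  means <- vapply(samples, function(s) mean(s$values), numeric(1))
  blank_mean <- mean(means[ids == blank_id])
  control_mean <- mean(means[ids == control_id])
  if (control_mean <= blank_mean) {
    ko_stop("control signal at or below the blank",
            "kickout_normalization_error")
  }
  data.frame(
    sample_id = ids,
    replicate = vapply(samples, `[[`, integer(1), "replicate"),
    n_cells = vapply(samples, function(s) length(s$values), integer(1)),
    mean = means,
    relative_mean = (means - blank_mean) / (control_mean - blank_mean))
}

#' t-test on log mean expression with Bonferroni correction
#'
#' Two-sided Student's t-test on the natural logarithms of per-replicate
#' mean expression, with the significance threshold Bonferroni-corrected
#' as `0.05 / n_comparisons`.  Replicate means, never pooled cells, are
#' the statistical unit.
#'
#' @param group_a,group_b Numeric vectors of per-replicate means (>= 2
#'   each, all > 0).
#' @param n_comparisons Number of simultaneous comparisons (>= 1).
#' @return List: `p_value`, `threshold`, `significant`.
#' @export
log_t_test <- function(group_a, group_b, n_comparisons = 1) {
  ko_check(is.numeric(group_a) && is.numeric(group_b) &&
             length(group_a) >= 2 && length(group_b) >= 2,
           "need >= 2 replicate means per group")
  if (any(c(group_a, group_b) <= 0)) {
    ko_stop("log t-test requires strictly positive means",
            "kickout_domain_error")
  }
  ko_check(is_number(n_comparisons) && n_comparisons >= 1,
           "n_comparisons must be >= 1")
  la <- log(group_a)
  lb <- log(group_b)
  p <- if (sd(la) == 0 && sd(lb) == 0) {
    # degenerate replicate sets: identical groups are maximally
    # non-significant, distinct constants maximally significant
    if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0
  } else {
    t.test(la, lb, var.equal = TRUE)$p.value
  }
  thr <- 0.05 / n_comparisons
  list(p_value = p, threshold = thr, significant = p < thr)
}

#' Doubling time from an exponential growth curve
#'
#' Fits `ln(OD)` linearly against time over an optional window
#' (exponential phase) and returns `ln 2 / slope`.
#'
#' @param times Time points (minutes).
#' @param od Optical densities (> 0).
#' @param window Optional `c(t_min, t_max)` restricting the fit.
#' @return Doubling time in minutes, with attribute `slope`.
#' @export
doubling_time <- function(times, od, window = NULL) {
  ko_check(is.numeric(times) && is.numeric(od) &&
             length(times) == length(od), "times and od must match")
  ko_check(all(od > 0), "od must be > 0")
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; od <- od[keep]
  }
  ko_check(length(times) >= 3, "need at least 3 points in the window")
  fit <- lm(log(od) ~ times)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    ko_stop("no exponential growth in the selected window",
            "kickout_no_growth")
  }
  structure(log(2) / slope, slope = slope)
}
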