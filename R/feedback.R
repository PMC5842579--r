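#' Parameters of the auto-repressor feedback model
#'
#' Steady-state description of a transcription factor (PhlF) repressing its
#' own operon.  `K` is the binding constant in units of the normalized
#' expression (expression is normalized to the maximum without repressor),
#' `n` the Hill coefficient, `beta` the maximal normalized expression.
#'
#' @param K Binding constant (> 0).
#' @param n Hill coefficient (> 0).
#' @param beta Maximal normalized expression (> 0, default 1).
#' @param dapg_label Optional condition tag (inducer concentration).
#' @return An object of class `feedback_params`.
#' @export
feedback_params <- function(K, n, beta = 1, dapg_label = NA_character_) {
  ko_check(is_number(K) && K > 0, "K must be > 0")
  ko_check(is_number(n) && n > 0, "n must be > 0")
  ko_check(is_number(beta) && beta > 0, "beta must be > 0")
  structure(list(K = K, n = n, beta = beta,
                 dapg_label = as.character(dapg_label)),
            class = "feedback_params")
}

#' Feedback dataset
#'
#' Observations of normalized expression `g_obs` of the auto-repressed
#' operon at several CRISPRi-set passage probabilities `r`, optionally
#' replicated.  At least three distinct design points are required to
#' constrain the two-parameter model.
#'
#' @param r Passage probabilities, each in `(0, 1]`.
#' @param g_obs Normalized expression values, each in `(0, 1]`.
#' @param g_sd Optional standard deviations (>= 0); used as weights.
#' @param replicate Optional replicate index.
#' @param condition Condition tag.
#' @return An object of class `feedback_dataset` (a data.frame).
#' @export
feedback_dataset <- function(r, g_obs, g_sd = NULL, replicate = NULL,
                             condition = NA_character_) {
  ko_check(is.numeric(r) && all(r > 0 & r <= 1), "each r must lie in (0, 1]")
  ko_check(is.numeric(g_obs) && all(g_obs > 0 & g_obs <= 1),
           "each g_obs must lie in (0, 1]")
  ko_check(length(r) == length(g_obs), "r and g_obs lengths differ")
  ko_check(length(r) >= 3, "at least 3 points are needed for a 2-parameter fit")
  if (!is.null(g_sd)) {
    ko_check(is.numeric(g_sd) && all(g_sd >= 0) && length(g_sd) == length(r),
             "g_sd must be >= 0 and match r in length")
  }
  d <- data.frame(
    r = r, g_obs = g_obs,
    g_sd = if (is.null(g_sd)) NA_real_ else g_sd,
    replicate = if (is.null(replicate)) 1L else as.integer(replicate))
  attr(d, "condition") <- as.character(condition)
  class(d) <- c("feedback_dataset", "data.frame")
  d
}

#' Steady state of the auto-repressor under CRISPRi
#'
#' CRISPRi scales the initiation rate by the passage probability `r`; the
#' repressor concentration is proportional to the reporter (same operon at
#' steady state), giving the normalized fixed point
#' \deqn{g = \frac{r\,\beta}{1 + (g/K)^n}.}
#' The right-hand side is strictly decreasing in `g`, so the positive root
#' is unique; it is found by bracketed root-finding on `[0, r*beta]` with
#' tolerance `1e-10`.
#'
#' @param r Passage probability (or vector of them), each in `(0, 1]`.
#' @param params A [feedback_params()].
#' @return The steady-state normalized expression `g*` (vectorized over
#'   `r`), with `g* <= r * beta` always.
#' @examples
#' steady_state(1, feedback_params(K = 1, n = 2))  # golden-ratio-like root
#' @export
steady_state <- function(r, params) {
  ko_check(inherits(params, "feedback_params"),
           "params must be feedback_params")
  ko_check(is.numeric(r) && all(r > 0 & r <= 1), "each r must lie in (0, 1]")
  vapply(r, function(ri) {
    top <- ri * params$beta
    f <- function(g) g * (1 + (g / params$K)^params$n) - top
    # f(0) = -top < 0, f(top) >= 0: bracket is guaranteed
    uniroot(f, lower = 0, upper = top, tol = 1e-10)$root
  }, numeric(1))
}

# weighted residual sum of squares on log expression
feedback_rss <- function(data, K, n, beta = 1) {
  g_hat <- steady_state(data$r, feedback_params(K = K, n = n, beta = beta))
  w <- ifelse(is.finite(data$g_sd) & data$g_sd > 0,
              1 / (data$g_sd / data$g_obs)^2, 1)
  sum(w * (log(data$g_obs) - log(g_hat))^2)
}

#' Fit the feedback model to data
#'
#' Weighted least squares on log-expression residuals, minimizing over
#' `(K, n)` jointly or over `K` with the Hill coefficient fixed.  The fit
#' is deterministic: a fixed log-spaced grid of `K` starting values
#' (crossed with `n` in `{0.5, 1, 2, 4}` for the joint fit) seeds
#' quasi-Newton polishing, and the best polished optimum is returned.
#'
#' @param data A [feedback_dataset()].
#' @param n_fixed Optional fixed Hill coefficient; if `NULL`, `n` is
#'   estimated.
#' @param beta Maximal normalized expression (held fixed, default 1).
#' @return A list of class `feedback_fit`: `params`
#'   (a [feedback_params()]), `rss`, `residuals` (per point, log scale),
#'   and `n_fixed`.
#' @export
fit_feedback <- function(data, n_fixed = NULL, beta = 1) {
  ko_check(inherits(data, "feedback_dataset"),
           "data must be a feedback_dataset")
  k_grid <- 10^seq(-3, 3, length.out = 13)
  best <- NULL
  if (is.null(n_fixed)) {
    starts <- expand.grid(logK = log(k_grid), logn = log(c(0.5, 1, 2, 4)))
    obj <- function(par) {
      feedback_rss(data, K = exp(par[1]), n = exp(par[2]), beta = beta)
    }
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
              lower = c(log(1e-6), log(0.1)),
              upper = c(log(1e6), log(10))),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      ko_stop("feedback fit failed to converge from every start",
              "kickout_fit_failure")
    }
    K_hat <- exp(best$par[1]); n_hat <- exp(best$par[2])
  } else {
    ko_check(is_number(n_fixed) && n_fixed > 0, "n_fixed must be > 0")
    obj <- function(logK) {
      feedback_rss(data, K = exp(logK), n = n_fixed, beta = beta)
    }
    vals <- vapply(log(k_grid), obj, numeric(1))
    i0 <- which.min(vals)
    lo <- log(k_grid[max(1, i0 - 1)]); hi <- log(k_grid[min(13, i0 + 1)])
    opt <- optimize(obj, interval = c(lo, hi), tol = 1e-10)
    # guard against a boundary minimum of the grid
    if (i0 %in% c(1L, 13L) && vals[i0] < opt$objective) {
      opt <- list(minimum = log(k_grid[i0]), objective = vals[i0])
    }
    K_hat <- exp(opt$minimum); n_hat <- n_fixed
    best <- list(value = opt$objective)
  }
  g_hat <- steady_state(data$r, feedback_params(K = K_hat, n = n_hat,
                                                beta = beta))
  structure(list(
    params = feedback_params(K = K_hat, n = n_hat, beta = beta,
                             dapg_label = attr(data, "condition")),
    rss = best$value,
    residuals = log(data$g_obs) - log(g_hat),
    n_fixed = n_fixed
  ), class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("feedback fit: K = %.4g, n = %.3g (rss = %.4g%s)\n",
              x$params$K, x$params$n, x$rss,
              if (is.null(x$n_fixed)) "" else ", n fixed"))
  invisible(x)
}

#' Compare candidate Hill coefficients
#'
#' Fits the feedback model with each candidate Hill coefficient held fixed
#' and ranks the candidates by residual sum of squares (ties broken toward
#' the smaller, more parsimonious `n`).
#'
#' @param data A [feedback_dataset()].
#' @param candidates Numeric vector of Hill coefficients (>= 1 value).
#' @param beta Maximal normalized expression.
#' @return A data.frame ranked by fit quality with columns `n`, `K`,
#'   `rss`, `rank`.
#' @export
compare_hill <- function(data, candidates, beta = 1) {
  ko_check(is.numeric(candidates) && length(candidates) >= 1 &&
             all(candidates > 0), "candidates must be positive numbers")
  fits <- lapply(candidates, function(nn) fit_feedback(data, n_fixed = nn,
                                                       beta = beta))
  out <- data.frame(
    n = candidates,
    K = vapply(fits, function(f) f$params$K, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)))
  out <- out[order(out$rss, out$n), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
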