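#' Steady-state relative expression under the kick-out model
#'
#' The expression level of a dCas9-targeted gene relative to its unrepressed
#' level is
#' \deqn{\gamma^* = \frac{r + \lambda r + \alpha}{1 + \lambda r + \alpha},}
#' where `r` is the passage probability, `lambda*r` the dimensionless
#' kick-out rate and `alpha` the dimensionless spontaneous-unbinding rate.
#' In the saturated limit (`lambda -> 0`, `alpha -> 0`) this reduces to
#' `gamma* = r`; for `lambda*r + alpha -> Inf` occupancy is lost and
#' `gamma* -> 1`.
#'
#' @param point A [dimensionless_point()].
#' @return Relative expression `gamma*`, a number in `[r, 1]`.
#' @examples
#' relative_expression(dimensionless_point(lambda_r = 0.4324, r = 0.026))
#' @export
relative_expression <- function(point) {
  ko_check(inherits(point, "dimensionless_point"),
           "point must be a dimensionless_point")
  gamma_star_num(point$lambda_r, point$alpha, point$r)
}

# numeric core shared with the Monte-Carlo propagation
gamma_star_num <- function(lambda_r, alpha, r) {
  (r + lambda_r + alpha) / (1 + lambda_r + alpha)
}

#' Equilibrium occupancy of the target site
#'
#' `P(bound) = rebinding / (rebinding + kout)` where `rebinding` is
#' `kon * [dCas9]` and `kout` the total rate at which dCas9 leaves the
#' target (see [kout_rate()]).
#'
#' @param params A [kinetic_params()] (only `rebinding_rate` is used).
#' @param kout Total leaving rate (per minute, >= 0).
#' @return Occupancy probability in `[0, 1]`.
#' @export
occupancy <- function(params, kout) {
  ko_check(inherits(params, "kinetic_params"), "params must be kinetic_params")
  ko_check(is_number(kout) && kout >= 0, "kout must be a rate >= 0")
  if (params$rebinding_rate == 0 && kout == 0) {
    ko_stop("occupancy undefined: rebinding_rate and kout are both zero",
            "kickout_undefined_occupancy")
  }
  params$rebinding_rate / (params$rebinding_rate + kout)
}

#' Total rate at which dCas9 leaves its target
#'
#' dCas9 leaves the target either spontaneously (rate `koff`) or by being
#' kicked out during a successful RNAP passage, which occurs at rate
#' `delta * r * gamma0`:
#' \deqn{k_{out} = \delta\, (1 - P(stop))\, \gamma_0 + k_{off}.}
#'
#' @param params A [kinetic_params()].
#' @param guide A [guide_spec()] supplying the passage probability `r`.
#' @return Leaving rate in per minute.
#' @export
kout_rate <- function(params, guide) {
  ko_check(inherits(params, "kinetic_params"), "params must be kinetic_params")
  ko_check(inherits(guide, "guide_spec"), "guide must be a guide_spec")
  params$delta * guide$r * params$gamma0 + params$koff
}

#' Infer the normalized kick-out rate from measured repression
#'
#' Inverts the steady-state relation for the product `lambda*r`:
#' \deqn{\lambda r = \frac{(1+\alpha)\gamma^*_{obs} - r - \alpha}
#'                        {1 - \gamma^*_{obs}}.}
#' The product is the primary inferred quantity; `lambda` itself is only
#' formed (as `lambda_r / r`) where unbinding bounds require it, to avoid
#' spurious precision when `r` is small.
#'
#' @param gamma_star_obs Measured relative expression, in `[r, 1)`.
#' @param guide A [guide_spec()].
#' @param alpha Dimensionless spontaneous-unbinding rate (>= 0).
#' @return The inferred `lambda*r` (dimensionless, >= 0).
#' @examples
#' g <- guide_spec("G20", r = 0.026)
#' infer_lambda_r(0.32, g)  # ~0.43
#' @export
infer_lambda_r <- function(gamma_star_obs, guide, alpha = 0) {
  ko_check(inherits(guide, "guide_spec"), "guide must be a guide_spec")
  ko_check(is_number(gamma_star_obs), "gamma_star_obs must be a number")
  ko_check(is_number(alpha) && alpha >= 0, "alpha must be >= 0")
  if (gamma_star_obs >= 1) {
    ko_stop("gamma_star_obs >= 1: kick-out rate diverges",
            "kickout_divergent_inference")
  }
  lr <- infer_lambda_r_num(gamma_star_obs, guide$r, alpha)
  if (lr < 0) {
    ko_stop(paste0("gamma_star_obs = ", gamma_star_obs,
                   " lies below the saturated floor r + alpha terms; ",
                   "inputs are inconsistent"),
            "kickout_inconsistent_inputs")
  }
  lr
}

infer_lambda_r_num <- function(gamma_star_obs, r, alpha) {
  ((1 + alpha) * gamma_star_obs - r - alpha) / (1 - gamma_star_obs)
}

#' Predict relative expression of a second promoter
#'
#' Infers `lambda*r` for the reference promoter from its measured relative
#' expression, scales `lambda` by the promoter-strength ratio (`lambda` is
#' proportional to `gamma0`, so `lambda_target = fold * lambda_ref`), and
#' evaluates the steady state for the target promoter.  The prediction is
#' strictly increasing in `strength_fold` and strictly decreasing in
#' `alpha`.
#'
#' @param pair A [promoter_pair()].
#' @param guide A [guide_spec()].
#' @param alpha Dimensionless spontaneous-unbinding rate (>= 0).
#' @return Predicted relative expression of the target promoter.
#' @examples
#' pp <- promoter_pair("P127", "PPhlF", strength_fold = 2.6,
#'                     gamma_star_ref = 0.32)
#' predict_promoter(pp, guide_spec("G20", r = 0.026))  # ~0.54
#' @export
predict_promoter <- function(pair, guide, alpha = 0) {
  ko_check(inherits(pair, "promoter_pair"), "pair must be a promoter_pair")
  ko_check(inherits(guide, "guide_spec"), "guide must be a guide_spec")
  lr_ref <- infer_lambda_r(pair$gamma_star_ref, guide, alpha)
  gamma_star_num(pair$strength_fold * lr_ref, alpha, guide$r)
}

# numeric core (used by the MC propagation): all-scalar arguments
predict_promoter_num <- function(gamma_star_ref, strength_fold, r, alpha = 0) {
  if (gamma_star_ref >= 1 || gamma_star_ref < r || strength_fold <= 0 ||
      r < 0 || r > 1) {
    ko_stop("invalid draw for promoter prediction", "kickout_domain_error")
  }
  lr <- infer_lambda_r_num(gamma_star_ref, r, alpha)
  if (lr < 0) ko_stop("negative lambda*r draw", "kickout_domain_error")
  gamma_star_num(strength_fold * lr, alpha, r)
}

#' Spontaneous-unbinding threshold compatible with an expression bound
#'
#' Finds the value of `alpha` at which the cross-promoter prediction drops
#' to a given bound.  Because [predict_promoter()] is strictly decreasing
#' in `alpha`, the root is unique; it is located by bisection
#' ([stats::uniroot()]) on `[0, 10]` with tolerance `1e-8`.
#'
#' @param pair A [promoter_pair()].
#' @param guide A [guide_spec()].
#' @param gamma_star_bound Expression level defining the crossing.
#' @param interval Search interval for `alpha`.
#' @return The crossing value `alpha*`.
#' @export
alpha_crossing <- function(pair, guide, gamma_star_bound,
                           interval = c(0, 10)) {
  ko_check(is_number(gamma_star_bound), "gamma_star_bound must be a number")
  f <- function(a) predict_promoter(pair, guide, alpha = a) - gamma_star_bound
  # the inference is only defined while the inferred lambda*r stays >= 0,
  # i.e. for alpha below (gamma*_ref - r) / (1 - gamma*_ref); as alpha
  # approaches that supremum the prediction tends to gamma*_ref itself
  a_sup <- (pair$gamma_star_ref - guide$r) / (1 - pair$gamma_star_ref)
  hi <- min(interval[2], a_sup * (1 - 1e-12))
  f0 <- f(interval[1])
  if (f0 < 0) {
    ko_stop("prediction at alpha = 0 already below the bound",
            "kickout_no_crossing")
  }
  if (f0 == 0) return(interval[1])
  if (f(hi) > 0) {
    ko_stop("no crossing inside the feasible alpha range",
            "kickout_no_crossing")
  }
  uniroot(f, interval = c(interval[1], hi), tol = 1e-8)$root
}

#' Upper bound on the spontaneous unbinding rate
#'
#' From `alpha <= alpha_max` and `lambda = delta * gamma0 / (kon [dCas9])`,
#' the spontaneous unbinding rate obeys
#' `koff <= alpha_max * kon [dCas9] = alpha_max * delta * gamma0 / lambda`.
#'
#' @param alpha_max Largest `alpha` consistent with the data (>= 0).
#' @param lambda_ Dimensionless kick-out ratio (> 0); typically
#'   `lambda_r / r`.
#' @param gamma0 Transcription-initiation rate (per minute).
#' @param delta Ejection frequency in `[0, 1]`.
#' @return Rate bound in per minute (`gamma0 = 1` yields the dimensionless
#'   coefficient multiplying `delta * gamma0`).
#' @examples
#' lam <- infer_lambda_r(0.32, guide_spec("G20", r = 0.026)) / 0.026
#' koff_upper_bound(0.14, lam, gamma0 = 1)  # ~8e-3 (coefficient of gamma0)
#' @export
koff_upper_bound <- function(alpha_max, lambda_, gamma0, delta = 1) {
  ko_check(is_number(alpha_max) && alpha_max >= 0, "alpha_max must be >= 0")
  ko_check(is_number(gamma0) && gamma0 >= 0, "gamma0 must be >= 0")
  ko_check(is_number(delta) && delta >= 0 && delta <= 1,
           "delta must lie in [0, 1]")
  if (!is_number(lambda_) || lambda_ <= 0) {
    ko_stop("lambda_ must be > 0 to bound koff", "kickout_division_error")
  }
  alpha_max * delta * gamma0 / lambda_
}

#' Lower bound on the lifetime of the dCas9--DNA complex
#'
#' With `n` target copies per cell, the per-complex lifetime obeys
#' `n / koff >= n / koff_bound`.  A zero rate bound yields `Inf`.
#'
#' @param copy_number Average target copies per cell (> 0).
#' @param koff_bound Upper bound on `koff` (per minute, >= 0).
#' @return Minimum complex lifetime in minutes (possibly `Inf`).
#' @export
lifetime_bound <- function(copy_number, koff_bound) {
  ko_check(is_number(copy_number) && copy_number > 0,
           "copy_number must be > 0")
  ko_check(is_number(koff_bound) && koff_bound >= 0,
           "koff_bound must be >= 0")
  if (koff_bound == 0) return(Inf)
  copy_number / koff_bound
}

#' Average gene copy number per cell
#'
#' Cooper--Helmstetter gene dosage for exponentially growing bacteria with
#' overlapping replication rounds:
#' \deqn{n(\Phi) = 2^{(t_C (1 - \Phi) + t_D)/t_d}.}
#' A locus at the origin (`phi = 0`) has the highest dosage, the terminus
#' (`phi = 1`) the lowest.
#'
#' @param params A [copy_number_params()].
#' @return Average copies per cell (dimensionless, >= 1).
#' @export
gene_copy_number <- function(params) {
  ko_check(inherits(params, "copy_number_params"),
           "params must be copy_number_params")
  2^((params$tC * (1 - params$phi) + params$tD) / params$td)
}
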