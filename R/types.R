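#' Guide RNA specification
#'
#' A guide RNA is characterized by the number of PAM-proximal bases matching
#' the target and by its passage probability `r = 1 - P(stop)`: the
#' probability that an elongating RNA polymerase transcribes through the
#' dCas9 roadblock upon collision.  `r` is measured independently in
#' saturating conditions (where relative expression equals `r`).
#'
#' @param spacer_id Character label for the spacer.
#' @param r Passage probability, in `[0, 1]`.
#' @param r_sd Standard deviation of `r` (>= 0).
#' @param complementarity_bp Integer count of matching PAM-proximal bases
#'   (0--20).
#' @return An object of class `guide_spec`.
#' @examples
#' g20 <- guide_spec("G20", r = 0.026, r_sd = 0.003, complementarity_bp = 20)
#' @export
guide_spec <- function(spacer_id, r, r_sd = 0, complementarity_bp = NA_integer_) {
  ko_check(is.character(spacer_id) && length(spacer_id) == 1L,
           "spacer_id must be a single string")
  ko_check(is_number(r) && r >= 0 && r <= 1, "r must lie in [0, 1]")
  ko_check(is_number(r_sd) && r_sd >= 0, "r_sd must be >= 0")
  if (!is.na(complementarity_bp)) {
    ko_check(is_number(complementarity_bp) &&
               complementarity_bp >= 0 && complementarity_bp <= 20,
             "complementarity_bp must lie in 0..20")
  }
  structure(list(spacer_id = spacer_id, r = r, r_sd = r_sd,
                 complementarity_bp = as.integer(complementarity_bp)),
            class = "guide_spec")
}

#' Kinetic parameters of the dCas9 target cycle
#'
#' Rates are per minute.  `rebinding_rate` is the product `kon * [dCas9]`
#' (binding is pseudo-first-order in free target sites); `koff` is the
#' spontaneous, transcription-independent unbinding rate; `delta` is the
#' ejection frequency: the probability that a successful RNAP passage
#' displaces dCas9 from the target.
#'
#' @param gamma0 Transcription-initiation rate (per minute).
#' @param rebinding_rate `kon * [dCas9]` (per minute).
#' @param koff Spontaneous unbinding rate (per minute).
#' @param delta Ejection frequency in `[0, 1]`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(gamma0 = 20, rebinding_rate = 1, koff = 0,
                           delta = 1) {
  for (nm in c("gamma0", "rebinding_rate", "koff")) {
    v <- get(nm)
    ko_check(is_number(v) && v >= 0, paste(nm, "must be a rate >= 0"))
  }
  ko_check(is_number(delta) && delta >= 0 && delta <= 1,
           "delta must lie in [0, 1]")
  structure(list(gamma0 = gamma0, rebinding_rate = rebinding_rate,
                 koff = koff, delta = delta),
            class = "kinetic_params")
}

#' Dimensionless model state
#'
#' The steady-state relative expression depends on the kinetics only through
#' `lambda = delta * gamma0 / (kon * [dCas9])` (induced displacements over
#' rebinding), `alpha = koff / (kon * [dCas9])` (spontaneous unbinding over
#' rebinding) and the passage probability `r`.  Because `lambda` and `r`
#' only ever enter the steady state as the product `lambda * r`, the product
#' may be supplied directly via `lambda_r`.
#'
#' @param lambda_ Dimensionless kick-out ratio (>= 0); alternative to
#'   `lambda_r`.
#' @param alpha Dimensionless spontaneous-unbinding ratio (>= 0).
#' @param r Passage probability in `[0, 1]`.
#' @param lambda_r The product `lambda * r`; if supplied, `lambda_` is
#'   ignored.
#' @return An object of class `dimensionless_point` carrying `lambda_r`,
#'   `alpha` and `r`.
#' @export
dimensionless_point <- function(lambda_ = NULL, alpha = 0, r = 1,
                                lambda_r = NULL) {
  ko_check(is_number(alpha) && alpha >= 0, "alpha must be >= 0")
  ko_check(is_number(r) && r >= 0 && r <= 1, "r must lie in [0, 1]")
  if (is.null(lambda_r)) {
    ko_check(is_number(lambda_) && lambda_ >= 0,
             "lambda_ must be >= 0 when lambda_r is not given")
    lambda_r <- lambda_ * r
  } else {
    ko_check(is_number(lambda_r) && lambda_r >= 0, "lambda_r must be >= 0")
  }
  structure(list(lambda_r = lambda_r, alpha = alpha, r = r),
            class = "dimensionless_point")
}

#' Promoter pair for cross-promoter prediction
#'
#' Bundles a reference promoter with a measured relative expression under
#' repression (`gamma_star_ref`) and a target promoter whose strength is
#' `strength_fold` times the reference.  In non-saturating conditions the
#' kick-out model predicts the target's relative expression from these
#' inputs alone.
#'
#' @param ref_name,target_name Promoter labels.
#' @param strength_fold Ratio of target to reference promoter strength (> 0).
#' @param strength_fold_sd Standard deviation of the ratio (>= 0).
#' @param gamma_star_ref Measured relative expression of the repressed
#'   reference, in `(0, 1]`.
#' @param gamma_star_ref_sd Standard deviation of `gamma_star_ref` (>= 0).
#' @return An object of class `promoter_pair`.
#' @export
promoter_pair <- function(ref_name, target_name, strength_fold,
                          gamma_star_ref, strength_fold_sd = 0,
                          gamma_star_ref_sd = 0) {
  ko_check(is_number(strength_fold) && strength_fold > 0,
           "strength_fold must be > 0")
  ko_check(is_number(gamma_star_ref) && gamma_star_ref > 0 &&
             gamma_star_ref <= 1,
           "gamma_star_ref must lie in (0, 1]")
  ko_check(is_number(strength_fold_sd) && strength_fold_sd >= 0,
           "strength_fold_sd must be >= 0")
  ko_check(is_number(gamma_star_ref_sd) && gamma_star_ref_sd >= 0,
           "gamma_star_ref_sd must be >= 0")
  structure(list(ref_name = ref_name, target_name = target_name,
                 strength_fold = strength_fold,
                 strength_fold_sd = strength_fold_sd,
                 gamma_star_ref = gamma_star_ref,
                 gamma_star_ref_sd = gamma_star_ref_sd),
            class = "promoter_pair")
}

#' Chromosome replication parameters for gene dosage
#'
#' Parameters of the Cooper--Helmstetter description of overlapping
#' replication rounds: the C period (`tC`, replication of the chromosome),
#' the D period (`tD`, between termination and division), the doubling time
#' `td`, and the relative position `phi` of the locus between origin (0)
#' and terminus (1).
#'
#' @param tC,tD,td Periods in minutes (> 0; `tC`/`tD` may be 0).
#' @param phi Relative origin--terminus distance in `[0, 1]`.
#' @return An object of class `copy_number_params`.
#' @export
copy_number_params <- function(tC = 60, tD = 20, td = 30, phi = 0.66) {
  ko_check(is_number(tC) && tC >= 0, "tC must be >= 0")
  ko_check(is_number(tD) && tD >= 0, "tD must be >= 0")
  ko_check(is_number(td) && td > 0, "td must be > 0")
  ko_check(is_number(phi) && phi >= 0 && phi <= 1, "phi must lie in [0, 1]")
  structure(list(tC = tC, tD = tD, td = td, phi = phi),
            class = "copy_number_params")
}

#' Value with standard deviation
#'
#' Plain container for a mean and a standard deviation, used by the
#' Monte-Carlo uncertainty propagation.
#'
#' @param mean Numeric value.
#' @param sd Standard deviation (>= 0).
#' @return An object of class `uncertain_value`.
#' @export
uncertain_value <- function(mean, sd = 0) {
  ko_check(is_number(mean), "mean must be a finite number")
  ko_check(is_number(sd) && sd >= 0, "sd must be >= 0")
  structure(list(mean = mean, sd = sd), class = "uncertain_value")
}

#' @export
print.uncertain_value <- function(x, ...) {
  cat(sprintf("%g +/- %g\n", x$mean, x$sd))
  invisible(x)
}

#' @export
print.dimensionless_point <- function(x, ...) {
  cat(sprintf("dimensionless point: lambda*r = %g, alpha = %g, r = %g\n",
              x$lambda_r, x$alpha, x$r))
  invisible(x)
}
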