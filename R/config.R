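#' Read a model configuration file
#'
#' Configurations are JSON with optional blocks `guides` (array of
#' `spacer_id`, `complementarity_bp`, `r`, `r_sd`), `promoters`
#' (`ref_name`, `target_name`, `strength_fold`, `strength_fold_sd`,
#' `gamma_star_ref`, `gamma_star_ref_sd`), `kinetics` (`gamma0`,
#' `rebinding_rate`, `koff`, `delta`), `copy_number` (`tC`, `tD`, `td`,
#' `phi`), `mc` (`n_draws`, `seed`) and `simulation` (fields of
#' [sim_config()] except `kinetics`/`guide`).  All rates are per minute
#' and expression values are dimensionless fractions of the unrepressed
#' level; validation is delegated to the type constructors.
#'
#' @param path Path to a JSON file.
#' @return List with any of: `guides` (named list of [guide_spec()]),
#'   `pair` (a [promoter_pair()]), `kinetics`, `copy_number`, `mc`,
#'   `simulation` (raw list), `alpha`.
#' @export
read_kickout_config <- function(path) {
  ko_check(file.exists(path), paste("config not found:", path))
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  out <- list()
  if (!is.null(raw$guides)) {
    out$guides <- lapply(raw$guides, function(g) {
      guide_spec(g$spacer_id, r = g$r,
                 r_sd = if (is.null(g$r_sd)) 0 else g$r_sd,
                 complementarity_bp =
                   if (is.null(g$complementarity_bp)) NA_integer_
                   else g$complementarity_bp)
    })
    names(out$guides) <- vapply(out$guides, `[[`, character(1), "spacer_id")
  }
  if (!is.null(raw$promoters)) {
    p <- raw$promoters
    out$pair <- promoter_pair(
      p$ref_name, p$target_name, strength_fold = p$strength_fold,
      gamma_star_ref = p$gamma_star_ref,
      strength_fold_sd = if (is.null(p$strength_fold_sd)) 0
                         else p$strength_fold_sd,
      gamma_star_ref_sd = if (is.null(p$gamma_star_ref_sd)) 0
                          else p$gamma_star_ref_sd)
  }
  if (!is.null(raw$kinetics)) out$kinetics <- do.call(kinetic_params,
                                                      raw$kinetics)
  if (!is.null(raw$copy_number)) out$copy_number <- do.call(
    copy_number_params, raw$copy_number)
  out$mc <- raw$mc
  out$simulation <- raw$simulation
  out$alpha <- if (is.null(raw$alpha)) 0 else raw$alpha
  out
}
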