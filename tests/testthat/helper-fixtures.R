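# shared fixtures and independent oracles

guide20 <- function() guide_spec("G20", r = 0.026, r_sd = 0.003,
                                 complementarity_bp = 20)
guide14 <- function() guide_spec("G14", r = 0.056, r_sd = 0.001,
                                 complementarity_bp = 14)

pair127 <- function() promoter_pair("P127", "PPhlF", strength_fold = 2.6,
                                    gamma_star_ref = 0.32,
                                    strength_fold_sd = 0.2,
                                    gamma_star_ref_sd = 0.04)

# independent closed-form chain for the cross-promoter prediction, written
# out directly from the steady-state algebra (no package calls)
oracle_predict <- function(g_ref, fold, r, alpha = 0) {
  lr <- ((1 + alpha) * g_ref - r - alpha) / (1 - g_ref)
  x <- fold * lr
  (r + x + alpha) / (1 + x + alpha)
}

# bisection oracle for the alpha at which the predicted expression hits a
# bound; relies only on oracle_predict being decreasing in alpha
oracle_alpha_crossing <- function(g_ref, fold, r, bound,
                                  lo = 0, hi = NULL, iter = 60) {
  if (is.null(hi)) hi <- (g_ref - r) / (1 - g_ref) * (1 - 1e-9)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (oracle_predict(g_ref, fold, r, mid) > bound) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# brute-force fixed point of the feedback steady state by damped iteration
oracle_steady_state <- function(r, K, n, beta = 1, iter = 400) {
  g <- r * beta / 2
  for (i in seq_len(iter)) g <- 0.5 * g + 0.5 * r * beta / (1 + (g / K)^n)
  g
}

# small simulated population with fixed per-cell factors
fixed_population <- function(r, rebinding, n_cells, seed,
                             gamma0 = 20, koff = 0, delta = 1) {
  sim_config(kinetics = kinetic_params(gamma0 = gamma0,
                                       rebinding_rate = rebinding,
                                       koff = koff, delta = delta),
             guide = guide_spec("G", r = r),
             extrinsic_cv = 0, dcas9_cv = 0,
             n_cells = n_cells, seed = seed)
}
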