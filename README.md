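# kickout

Mechanistic modelling of CRISPR interference (CRISPRi) in bacteria under
the **kick-out mechanism**: when catalytically dead Cas9 (dCas9) sits
inside an open reading frame as a transcriptional roadblock, an elongating
RNA polymerase passes it with probability `r = 1 − P(stop)` set by
guide-RNA/target complementarity, and each successful passage can eject
dCas9 from the DNA. The package is aimed at quantitative/synthetic
biologists who tune gene expression with mismatched guide RNAs and want to
reason about repression strength, its promoter-strength dependence, and
its single-cell noise.

## The model

The steady-state expression of a targeted gene relative to its unrepressed
level is

    gamma* = 1 − P(stop) · P(bound),      P(bound) = kon[dCas9] / (kon[dCas9] + kout)
    kout   = delta · r · gamma0 + koff

with `gamma0` the transcription-initiation rate, `delta` the ejection
frequency and `koff` the spontaneous unbinding rate. In dimensionless form
(`lambda = delta·gamma0 / kon[dCas9]`, `alpha = koff / kon[dCas9]`):

    gamma* = (r + lambda·r + alpha) / (1 + lambda·r + alpha)

At saturating dCas9 (`lambda, alpha → 0`) repression depends only on the
guide (`gamma* = r`), which is why complementarity-tuned knockdown is
robust to dCas9 copy-number fluctuations and promoter strength, while
concentration-tuned knockdown is noisy and promoter-strength dependent.

The package provides, as tested modules:

* **Analytic core** — `relative_expression()`, `infer_lambda_r()`,
  `predict_promoter()`, `alpha_crossing()`, `koff_upper_bound()`,
  `lifetime_bound()`, `gene_copy_number()`, Monte-Carlo
  `propagate_uncertainty()`.
* **Stochastic simulator** — exact Gillespie simulation of the
  (occupancy, mRNA, protein) system per cell with shared extrinsic noise
  and per-cell dCas9 variability: `sim_config()`, `run_cell()`,
  `simulate_population()`, plus `active_dcas9_fraction()` (decoy arrays)
  and `atc_induction()`.
* **Auto-repressor feedback** — fixed point `steady_state()`,
  `fit_feedback()` and `compare_hill()` for inferring the repressor
  binding constant `K` and Hill coefficient `n` per inducer condition.
* **Cytometry statistics** — `trim_outliers()`, blank-corrected
  `noise_cv()`, `relative_expression_table()`, `log_t_test()`,
  `doubling_time()`.
* **Morphometrics** — `principal_axis()` (total regression),
  `cell_width()` (pole-excluded mean contour distance), `cell_length()`.
* **Synthetic data** — generators emulating flow/imaging-cytometry
  single-cell distributions (`gen_population()`, `gen_two_color()`,
  `gen_titration()`, `gen_feedback_dataset()`, `gen_capsule_contour()`),
  so every analysis stage is testable without instrument data.

## Worked example

```r
library(kickout)

guide <- guide_spec("G20", r = 0.026, r_sd = 0.003, complementarity_bp = 20)
pair  <- promoter_pair("P127", "PPhlF", strength_fold = 2.6,
                       gamma_star_ref = 0.32,
                       strength_fold_sd = 0.2, gamma_star_ref_sd = 0.04)

(lr <- infer_lambda_r(pair$gamma_star_ref, guide))   # normalized kick-out rate
#> 0.4324
predict_promoter(pair, guide)                        # stronger promoter, predicted
#> 0.5415
propagate_uncertainty(
  list(gamma_star_ref = uncertain_value(0.32, 0.04),
       strength_fold  = uncertain_value(2.6, 0.2),
       r              = uncertain_value(0.026, 0.003)),
  "predict_promoter", n_draws = 1e5, seed = 1)
#> 0.538486 +/- 0.0512587
koff_upper_bound(0.14, lr / guide$r, gamma0 = 20)    # unbinding-rate bound
#> 0.168
lifetime_bound(gene_copy_number(copy_number_params()), 0.168)
#> 15.1                                               # minutes, lower bound

cfg <- sim_config(guide = guide, n_cells = 2000, seed = 1)
simulate_population(cfg)$summary
#> population of 2000 cells: mean expression 0.02632 (se 0.0002), noise 0.348, occupancy 1
```

Reading: a reference promoter repressed to 32% with a full-complementarity
guide (`r = 0.026`) implies a dimensionless kick-out rate `lambda·r ≈ 0.43`;
a 2.6-fold stronger promoter is then predicted to be repressed only to
`0.54 ± 0.05` of its own unrepressed level — repression weakens with
promoter strength when dCas9 does not saturate the target. The bound on
spontaneous unbinding (`≤ 0.17/min` at `gamma0 = 20/min`) translates into a
complex lifetime of at least ~15 min for ~2.5 gene copies per cell (12 min
when 2 copies are assumed). At saturation the simulated population mean
settles at the passage probability (2.6%, the ~3% residual-expression
plateau) with population noise ~0.3, independent of repression strength.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "kickout", package = "kickout"))')
CFG=$(Rscript -e 'cat(system.file("extdata", "demo_config.json", package = "kickout"))')
"$CLI" predict  --config "$CFG" --out prediction.json
"$CLI" bounds   --config "$CFG" --out bounds.json
"$CLI" simulate --config "$CFG" --out cells.csv --summary summary.json
"$CLI" gen feedback --out fb.csv --K 0.3 --hill 2 --seed 3
"$CLI" fit-feedback --data fb.csv --out fb_fit.json --hill 1,2
```

## Vignette

`vignettes/kickout-methods.Rmd` documents the model assumptions, the
simulator's noise calibration, the reconstructed feedback model, numerical
choices (root brackets, tolerances, degenerate inputs) and known
limitations.
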