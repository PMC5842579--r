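#include <Rcpp.h>
using namespace Rcpp;

// Exact (Gillespie) simulation of one cell carrying a dCas9-targeted gene.
//
// State: promoter occupancy (dCas9 bound / free), mRNA count m, protein
// count p.  Reactions (rates per minute):
//   binding      free -> bound        at bind_rate (= kon * [dCas9] level)
//   unbinding    bound -> free        at koff
//   initiation   attempt              at gamma0 * scale
//                if free: m += 1
//                if bound: with prob r, m += 1 and with prob delta the
//                polymerase kicks dCas9 out (bound -> free)
//   mRNA decay   m -> m - 1           at m * mrna_decay
//   translation  p -> p + 1           at m * k_tl * scale
//   dilution     p -> p - 1           at p * k_dil
//
// `scale` is the per-cell extrinsic factor applied to transcription and
// translation.  Statistics (time-averaged protein and occupancy,
// transcripts made) are collected on [burn_in, t_end].  Uses R's RNG so
// that seeding from R makes runs fully reproducible.
// [[Rcpp::export]]
NumericVector ssa_cell_cpp(double bind_rate, double koff, double gamma0,
                           double r, double delta, double mrna_decay,
                           double k_tl, double k_dil, double scale,
                           double t_end, double burn_in,
                           int bound0, double m0, double p0) {
  RNGScope rngScope;
  double t = 0.0;
  int bound = bound0;
  double m = m0, p = p0;
  double int_p = 0.0, int_bound = 0.0;
  double transcripts = 0.0;
  const double window = t_end - burn_in;

  while (t < t_end) {
    const double a_bind = bound ? 0.0 : bind_rate;
    const double a_unbind = bound ? koff : 0.0;
    const double a_init = gamma0 * scale;
    const double a_mdec = m * mrna_decay;
    const double a_tl = m * k_tl * scale;
    const double a_pdil = p * k_dil;
    const double a_tot = a_bind + a_unbind + a_init + a_mdec + a_tl + a_pdil;
    if (a_tot <= 0.0) {
      // frozen state: integrate it to the end of the recording window
      double lo = t > burn_in ? t : burn_in;
      if (t_end > lo) {
        int_p += p * (t_end - lo);
        int_bound += bound * (t_end - lo);
      }
      t = t_end;
      break;
    }
    const double dt = R::exp_rand() / a_tot;
    double t_new = t + dt;
    if (t_new > t_end) t_new = t_end;
    // accumulate the held state over the part of [t, t_new] after burn_in
    double lo = t > burn_in ? t : burn_in;
    if (t_new > lo) {
      int_p += p * (t_new - lo);
      int_bound += bound * (t_new - lo);
    }
    if (t + dt > t_end) { t = t_end; break; }
    t = t_new;

    double u = unif_rand() * a_tot;
    if ((u -= a_bind) < 0.0) {
      bound = 1;
    } else if ((u -= a_unbind) < 0.0) {
      bound = 0;
    } else if ((u -= a_init) < 0.0) {
      if (!bound) {
        m += 1.0;
        if (t > burn_in) transcripts += 1.0;
      } else if (unif_rand() < r) {
        m += 1.0;
        if (t > burn_in) transcripts += 1.0;
        if (delta > 0.0 && unif_rand() < delta) bound = 0;
      }
    } else if ((u -= a_mdec) < 0.0) {
      m -= 1.0;
    } else if ((u -= a_tl) < 0.0) {
      p += 1.0;
    } else {
      p -= 1.0;
    }
  }

  NumericVector out(4);
  out[0] = window > 0 ? int_p / window : p;        // time-averaged protein
  out[1] = window > 0 ? int_bound / window : (double)bound; // occupancy
  out[2] = transcripts;                            // transcripts in window
  out[3] = p;                                      // final protein count
  return out;
}
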