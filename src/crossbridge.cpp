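#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step tau-leap update of a two-state cross-bridge ensemble.
// Bridges attach at constant rate f_att with strain drawn uniformly on
// [-d_stroke/2, d_stroke/2]; attached strains are advected by the imposed
// length change; detachment rate is g0 * exp(|x|/delta) (signed_exp = 0)
// or g0 * exp(x/delta) (signed_exp = 1), delta <= 0 meaning
// strain-independent.  Uses R's RNG so results are reproducible under
// set.seed().  strain_fine holds the imposed strain at every fine step
// (including t = 0); every `substeps`-th state is recorded.
// [[Rcpp::export]]
List cb_simulate(int n_bridges, double f_att, double g0, double delta,
                 int signed_exp, double kappa, double d_stroke,
                 double sarcomere_area, double hs_length,
                 NumericVector strain_fine, int substeps, double dt_fine,
                 double duty_init) {
  int n_fine = strain_fine.size();
  int n_samp = (n_fine - 1) / substeps + 1;
  NumericVector stress(n_samp), frac(n_samp);
  std::vector<char> attached(n_bridges);
  std::vector<double> x(n_bridges);
  double half = d_stroke / 2.0;

  for (int i = 0; i < n_bridges; ++i) {
    attached[i] = (unif_rand() < duty_init) ? 1 : 0;
    x[i] = attached[i] ? (unif_rand() * d_stroke - half) : 0.0;
  }
  double p_att = 1.0 - std::exp(-f_att * dt_fine);
  bool strain_dep = delta > 0.0;

  int rec = 0;
  // record initial state
  {
    double s = 0.0; int na = 0;
    for (int i = 0; i < n_bridges; ++i)
      if (attached[i]) { s += x[i] + d_stroke; ++na; }
    stress[rec] = s * kappa / sarcomere_area * 1000.0;
    frac[rec] = (double)na / n_bridges;
    ++rec;
  }
  double strain_prev = strain_fine[0];
  for (int step = 1; step < n_fine; ++step) {
    double dx = (strain_fine[step] - strain_prev) * hs_length;
    strain_prev = strain_fine[step];
    for (int i = 0; i < n_bridges; ++i) {
      if (attached[i]) {
        double xi = x[i] + dx;
        double g = g0;
        if (strain_dep)
          g = g0 * std::exp((signed_exp ? xi : std::fabs(xi)) / delta);
        double p_det = 1.0 - std::exp(-g * dt_fine);
        if (unif_rand() < p_det) {
          attached[i] = 0;
          x[i] = 0.0;
        } else {
          x[i] = xi;
        }
      } else {
        if (unif_rand() < p_att) {
          attached[i] = 1;
          x[i] = unif_rand() * d_stroke - half;
        }
      }
    }
    if (step % substeps == 0) {
      double s = 0.0; int na = 0;
      for (int i = 0; i < n_bridges; ++i)
        if (attached[i]) { s += x[i] + d_stroke; ++na; }
      stress[rec] = s * kappa / sarcomere_area * 1000.0;
      frac[rec] = (double)na / n_bridges;
      ++rec;
    }
  }
  return List::create(_["stress"] = stress, _["frac"] = frac);
}
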