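#include <Rcpp.h>
using namespace Rcpp;

// Explicit 5-point diffusion with no-flux (reflecting) boundaries, applied
// in place. lambda_total = D * dt / dx^2 for the whole macro step; it is
// split into nsub sub-steps so that each sub-step satisfies lambda <= 0.25
// (chosen by the R wrapper). The symmetric difference form conserves total
// mass exactly up to floating point.
// [[Rcpp::export]]
void cpp_diffuse_inplace(NumericMatrix f, double lambda_total, int nsub) {
  if (lambda_total <= 0.0 || nsub <= 0) return;
  int nr = f.nrow(), nc = f.ncol();
  if ((R_xlen_t)nr * nc <= 1) return;
  double lam = lambda_total / nsub;
  NumericMatrix tmp(nr, nc);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        double c = f(i, j), acc = 0.0;
        if (i > 0)      acc += f(i - 1, j) - c;
        if (i < nr - 1) acc += f(i + 1, j) - c;
        if (j > 0)      acc += f(i, j - 1) - c;
        if (j < nc - 1) acc += f(i, j + 1) - c;
        tmp(i, j) = c + lam * acc;
      }
    }
    std::copy(tmp.begin(), tmp.end(), f.begin());
  }
}

// Diffuse each of the nk layers of an nr x nc x nk biomass array in place.
// [[Rcpp::export]]
void cpp_diffuse_layers(NumericVector bio, int nr, int nc, int nk,
                        double lambda_total, int nsub) {
  if (lambda_total <= 0.0 || nsub <= 0) return;
  R_xlen_t nbox = (R_xlen_t)nr * nc;
  for (int k = 0; k < nk; ++k) {
    NumericMatrix layer(nr, nc);
    std::copy(bio.begin() + k * nbox, bio.begin() + (k + 1) * nbox,
              layer.begin());
    cpp_diffuse_inplace(layer, lambda_total, nsub);
    std::copy(layer.begin(), layer.end(), bio.begin() + k * nbox);
  }
}

// One explicit-Euler growth step over every lattice box, modifying carbon,
// toxin and the per-colony biomass layers in place.
//
// bio is an nx*ny*ncolony array (column-major). Per colony k:
//   mu_max_k   = v_max_k * yield_k / (1 + cost_k)
//   signal     = bounded-linear cut of mu_max for susceptible colonies
//   phi_k      = mu_k (1 + cost_k) / yield_k      (carbon uptake flux)
//   demand_k   = phi_k * B_k * dt
// If the summed carbon demand in a box exceeds the carbon present, every
// colony's uptake (hence growth) is scaled by the same factor, so allocation
// is proportional and order-independent. Toxin is produced at
// tau_k (1 + cost_k) per unit biomass flux and never consumed.
// [[Rcpp::export]]
void cpp_growth_inplace(NumericMatrix carbon, NumericMatrix toxin,
                        NumericVector bio,
                        NumericVector v_max, NumericVector cost,
                        NumericVector yield, NumericVector tau,
                        NumericVector delta, LogicalVector susceptible,
                        double K, double vol_box, bool conc_signal,
                        double dt) {
  R_xlen_t nbox = (R_xlen_t)carbon.nrow() * carbon.ncol();
  int nk = v_max.size();
  std::vector<double> mu(nk), phi(nk);
  for (R_xlen_t b = 0; b < nbox; ++b) {
    double cb = carbon[b];
    double conc = conc_signal ? toxin[b] / vol_box : toxin[b];
    double demand = 0.0;
    for (int k = 0; k < nk; ++k) {
      mu[k] = 0.0; phi[k] = 0.0;
      double B = bio[b + (R_xlen_t)k * nbox];
      if (B <= 0.0 || cb <= 0.0) continue;
      double m = v_max[k] * yield[k] / (1.0 + cost[k]);
      if (susceptible[k]) {
        double fac = 1.0 - conc / K;
        if (fac < 0.0) fac = 0.0;
        m *= fac;
      }
      if (m <= 0.0) continue;
      mu[k] = m;
      phi[k] = m * (1.0 + cost[k]) / yield[k];
      demand += phi[k] * B * dt;
    }
    double scale = (demand > cb && demand > 0.0) ? cb / demand : 1.0;
    double used = 0.0, made = 0.0;
    for (int k = 0; k < nk; ++k) {
      R_xlen_t idx = b + (R_xlen_t)k * nbox;
      double B = bio[idx];
      if (B <= 0.0) continue;
      double mu_real = mu[k] * scale;
      double newB = B + (mu_real - delta[k]) * B * dt;
      if (newB < 0.0) newB = 0.0;
      bio[idx] = newB;
      used += phi[k] * scale * B * dt;
      made += tau[k] * (1.0 + cost[k]) * mu_real * B * dt;
    }
    double rem = cb - used;
    carbon[b] = (rem > 0.0) ? rem : 0.0;
    toxin[b] += made;
  }
}
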