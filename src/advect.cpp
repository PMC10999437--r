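#include <Rcpp.h>
using namespace Rcpp;

// Conservative upwind transport of stage densities along physiological
// age, with flux hand-off between consecutive stages.
//
// Each of the 6 developing stages carries a phase accumulator; a substep
// adds v_i * dt / dx to it and, whenever the accumulator reaches 1, the
// stage's cell masses are shifted by exactly one cell (an upwind step at
// Courant number 1, hence free of numerical diffusion). The mass leaving
// the last cell of stage i is injected into the first cell of stage i+1
// within the same substep; outflow from stage 6 (N5) accumulates as adult
// emergences. Total mass is conserved to machine precision.
//
// mass:      J x 6 matrix of cell masses (individuals), modified copy.
// phase:     length-6 phase accumulators in [0, 1).
// adult:     adult accumulator.
// cum_in:    length-6 running totals of entries into stages 2..7.
// courant:   n_steps x 6 matrix of v_i(t) * dt / dx per substep.
// record_at: 1-based substep indices (ascending) at which to snapshot
//            cum_in.
// diff_cells: D * dt / dx^2 if a constant diffusivity is enabled (0 = off);
//            applied with no-flux boundaries.
// [[Rcpp::export]]
List advect_run(NumericMatrix mass, NumericVector phase, double adult,
                NumericVector cum_in, NumericMatrix courant,
                IntegerVector record_at, double diff_cells) {
  const int J = mass.nrow();
  const int S = mass.ncol();
  const int n_steps = courant.nrow();
  const int n_rec = record_at.size();
  NumericMatrix m = clone(mass);
  NumericVector ph = clone(phase);
  NumericVector ci = clone(cum_in);
  NumericMatrix rec(n_rec, S);
  std::vector<double> buf(J);
  int r = 0;

  for (int s = 0; s < n_steps; ++s) {
    double inflow = 0.0;
    for (int i = 0; i < S; ++i) {
      ph[i] += courant(s, i);
      double out = 0.0;
      while (ph[i] >= 1.0) {
        out += m(J - 1, i);
        for (int j = J - 1; j > 0; --j) m(j, i) = m(j - 1, i);
        m(0, i) = 0.0;
        ph[i] -= 1.0;
      }
      m(0, i) += inflow;         // arrivals from the previous stage, age 0
      inflow = out;
      ci[i] += out;              // entries into stage i+2 (1-based: i+1 -> i+2)
      if (diff_cells > 0.0) {
        for (int j = 0; j < J; ++j) {
          double lo = (j > 0) ? m(j - 1, i) : m(j, i);
          double hi = (j < J - 1) ? m(j + 1, i) : m(j, i);
          buf[j] = m(j, i) + diff_cells * (lo - 2.0 * m(j, i) + hi);
        }
        for (int j = 0; j < J; ++j) m(j, i) = buf[j];
      }
    }
    adult += inflow;
    while (r < n_rec && record_at[r] == s + 1) {
      for (int i = 0; i < S; ++i) rec(r, i) = ci[i];
      ++r;
    }
  }
  return List::create(_["mass"] = m, _["phase"] = ph, _["adult"] = adult,
                      _["cum_in"] = ci, _["rec"] = rec);
}
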