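// Operator-split stepping kernel for the coupled
// advection-diffusion-reaction fields.
//
// Grid: nx * ny cell-centred cells, cell index = i + nx*j (0-based,
// x-fastest). Face velocities on the MAC grid: u is (nx+1) x ny,
// v is nx x (ny+1). Units: nM, s, um.
//
// Per step: (1) first-order upwind advection for convecting species,
// (2) explicit 5-point diffusion (gel does not hinder diffusion),
// (3) per-cell chemistry with an adaptive embedded Heun/Euler pair,
// (4) fibrin gel-mask latching.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SchemePtrs {
  int ns, nr;
  const int *rtype, *eidx, *sidx;
  const double *kf, *kr, *km;
  const int *fptr, *fidx, *fpow, *bptr, *bidx, *bpow, *nptr, *nidx;
  const double *ncoef;
};

inline void calc_rates(const double* c, double* dcdt, const SchemePtrs& S) {
  for (int s = 0; s < S.ns; ++s) dcdt[s] = 0.0;
  for (int r = 0; r < S.nr; ++r) {
    double rate;
    if (S.rtype[r] == 1) {           // Michaelis-Menten
      double cs = c[S.sidx[r]];
      rate = S.kf[r] * c[S.eidx[r]] * cs / (S.km[r] + cs);
    } else {                          // mass action / reversible binding
      double fwd = S.kf[r];
      for (int k = S.fptr[r]; k < S.fptr[r + 1]; ++k) {
        double cc = c[S.fidx[k]];
        for (int p = 0; p < S.fpow[k]; ++p) fwd *= cc;
      }
      double rev = 0.0;
      if (S.kr[r] > 0.0) {
        rev = S.kr[r];
        for (int k = S.bptr[r]; k < S.bptr[r + 1]; ++k) {
          double cc = c[S.bidx[k]];
          for (int p = 0; p < S.bpow[k]; ++p) rev *= cc;
        }
      }
      rate = fwd - rev;
    }
    for (int k = S.nptr[r]; k < S.nptr[r + 1]; ++k)
      dcdt[S.nidx[k]] += S.ncoef[k] * rate;
  }
}

// Adaptive chemistry sub-integration over one transport step.
// Embedded Heun(2)/Euler(1) pair; per-substep relative error kept
// below tol. Negative excursions are clipped to zero and logged.
inline void react_cell(double* c, double dt, double tol,
                       const SchemePtrs& S, double* clip,
                       std::vector<double>& r1, std::vector<double>& r2,
                       std::vector<double>& ce, std::vector<double>& ch) {
  const int ns = S.ns;
  double t = 0.0, h = dt;
  int guard = 0;
  while (t < dt * (1.0 - 1e-12) && ++guard < 100000) {
    if (t + h > dt) h = dt - t;
    calc_rates(c, r1.data(), S);
    for (int s = 0; s < ns; ++s) {
      ce[s] = c[s] + h * r1[s];
      if (ce[s] < 0.0) ce[s] = 0.0;
    }
    calc_rates(ce.data(), r2.data(), S);
    double err = 0.0;
    for (int s = 0; s < ns; ++s) {
      ch[s] = c[s] + 0.5 * h * (r1[s] + r2[s]);
      double sc = std::max(std::max(std::fabs(ch[s]), std::fabs(c[s])), 1.0);
      double e = std::fabs(ch[s] - ce[s]) / sc;
      if (e > err) err = e;
    }
    if (err > tol && h > dt * 1e-8) {
      h *= std::max(0.2, 0.9 * std::sqrt(tol / err));
      continue;
    }
    for (int s = 0; s < ns; ++s) {
      double v = ch[s];
      if (v < 0.0) { clip[s] += -v; v = 0.0; }
      c[s] = v;
    }
    t += h;
    double fac = (err > 0.0) ? 0.9 * std::sqrt(tol / err) : 2.0;
    h *= std::min(2.0, std::max(0.5, fac));
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_advance(NumericMatrix conc,        // (nx*ny) x ns, modified in place
                 NumericMatrix uface,       // (nx+1) x ny
                 NumericMatrix vface,       // nx x (ny+1)
                 IntegerVector gel,         // nx*ny latched mask, in place
                 int nx, int ny, double dx,
                 NumericVector D, LogicalVector convects,
                 NumericVector inlet,       // ns Dirichlet inlet values
                 bool closed,
                 List rxn, int fn_idx,      // fn_idx 0-based, -1 = none
                 double gel_threshold,
                 double dt, int nsteps, double rxn_tol,
                 NumericVector clip_mass) { // ns, accumulated, in place
  const int nc = nx * ny, ns = conc.ncol();
  IntegerVector rtype = rxn["rtype"], eidx = rxn["eidx"], sidx = rxn["sidx"],
    fptr = rxn["fptr"], fidx = rxn["fidx"], fpow = rxn["fpow"],
    bptr = rxn["bptr"], bidx = rxn["bidx"], bpow = rxn["bpow"],
    nptr = rxn["nptr"], nidx = rxn["nidx"];
  NumericVector kf = rxn["kf"], kr = rxn["kr"], km = rxn["km"],
    ncoef = rxn["ncoef"];
  SchemePtrs S;
  S.ns = ns; S.nr = rtype.size();
  S.rtype = rtype.begin(); S.eidx = eidx.begin(); S.sidx = sidx.begin();
  S.kf = kf.begin(); S.kr = kr.begin(); S.km = km.begin();
  S.fptr = fptr.begin(); S.fidx = fidx.begin(); S.fpow = fpow.begin();
  S.bptr = bptr.begin(); S.bidx = bidx.begin(); S.bpow = bpow.begin();
  S.nptr = nptr.begin(); S.nidx = nidx.begin(); S.ncoef = ncoef.begin();

  std::vector<double> tmp(nc), cl(ns), r1(ns), r2(ns), ce(ns), ch(ns);
  double* C = conc.begin();
  double* U = uface.begin();
  double* V = vface.begin();
  int* G = gel.begin();
  bool mask_changed = false;
  int n_new_gel = 0;
  bool blowup = false;
  int bad_cell = -1, bad_sp = -1;

  for (int step = 0; step < nsteps && !blowup; ++step) {
    // ---- transport ----
    for (int sp = 0; sp < ns; ++sp) {
      const double Dsp = D[sp];
      const bool cv = convects[sp] && !closed;
      const bool dif = Dsp > 0.0;
      if (!cv && !dif) continue;
      double* c = C + (size_t)sp * nc;
      const double cin = inlet[sp];
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          const int idx = i + nx * j;
          double net = 0.0;
          if (cv) {
            const double uW = U[i + (nx + 1) * j];
            const double uE = U[i + 1 + (nx + 1) * j];
            const double cW = uW > 0.0 ? (i > 0 ? c[idx - 1] : cin)
                                       : c[idx];
            const double cE = uE > 0.0 ? c[idx]
                                       : (i < nx - 1 ? c[idx + 1] : c[idx]);
            net += uW * cW - uE * cE;
            const double vS = V[i + nx * j];
            const double vN = V[i + nx * (j + 1)];
            const double cS = vS > 0.0 ? (j > 0 ? c[idx - nx] : 0.0)
                                       : c[idx];
            const double cN = vN > 0.0 ? c[idx]
                                       : (j < ny - 1 ? c[idx + nx] : c[idx]);
            net += vS * cS - vN * cN;
          }
          if (dif) {
            if (i > 0)       net += Dsp * (c[idx - 1] - c[idx]) / dx;
            else if (!closed) net += 2.0 * Dsp * (cin - c[idx]) / dx;
            if (i < nx - 1)  net += Dsp * (c[idx + 1] - c[idx]) / dx;
            if (j > 0)       net += Dsp * (c[idx - nx] - c[idx]) / dx;
            if (j < ny - 1)  net += Dsp * (c[idx + nx] - c[idx]) / dx;
          }
          tmp[idx] = c[idx] + dt / dx * net;
        }
      }
      for (int idx = 0; idx < nc; ++idx) {
        double v = tmp[idx];
        if (v < 0.0) { clip_mass[sp] += -v; v = 0.0; }
        c[idx] = v;
      }
    }
    // ---- chemistry ----
    if (S.nr > 0) {
      for (int idx = 0; idx < nc; ++idx) {
        for (int s = 0; s < ns; ++s) cl[s] = C[(size_t)s * nc + idx];
        react_cell(cl.data(), dt, rxn_tol, S, &clip_mass[0], r1, r2, ce, ch);
        for (int s = 0; s < ns; ++s) {
          double v = cl[s];
          if (!std::isfinite(v)) {
            blowup = true; bad_cell = idx; bad_sp = s; v = 0.0;
          }
          C[(size_t)s * nc + idx] = v;
        }
        if (blowup) break;
      }
    }
    // ---- gel latch ----
    if (fn_idx >= 0) {
      const double* fn = C + (size_t)fn_idx * nc;
      for (int idx = 0; idx < nc; ++idx) {
        if (!G[idx] && fn[idx] >= gel_threshold) {
          G[idx] = 1; mask_changed = true; ++n_new_gel;
        }
      }
    }
  }
  return List::create(_["mask_changed"] = mask_changed,
                      _["n_new_gel"] = n_new_gel,
                      _["blowup"] = blowup,
                      _["bad_cell"] = bad_cell + 1,
                      _["bad_species"] = bad_sp + 1);
}
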