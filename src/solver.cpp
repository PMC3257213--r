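#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steady-state solver for networks of covalent modification cycles sharing
// kinases, with a competitive inhibitor sequestering the active species of
// one cycle.
//
// Unknowns are the normalized free concentrations y_i (inactive) and y_i*
// (active).  Complexes are eliminated exactly through their own steady-state
// conditions, so the algebraic system solved here is the exact steady state
// of the mass-action network, not a quasi-steady-state approximation.
//
// Topology: cycle 1 is activated by a dedicated kinase; every other cycle
// hangs off cycle 1 in simple chains (a chain of length one is a single
// cycle activated by y_1*).  The solver exploits this structure:
//
//   * a chain is solved by a shooting sweep: guess y* at the bottom cycle,
//     propagate conservation/rate balance upward to obtain the activator
//     concentration the chain demands at its top, and bisect the guess until
//     that demand matches the supplied y_1* (or y_2* for nested chains);
//   * the root cycle is solved by bisecting y_1* on its own conservation
//     residual, with all chains re-solved at each trial value.
//
// Every scalar solve is a bracketed bisection on [0, 1], so the method has
// no divergence failure modes; accuracy saturates machine precision.

struct Net {
  int n;                  // number of cycles
  int inhib;              // 0-based index of the inhibited cycle
  std::vector<std::vector<int> > chains; // 0-based cycle indices, top..bottom
};

struct Pars {
  const double *E, *Ep, *K, *Kp, *P;
  double KB, I;
};

static const int BISECT_ITERS = 90;

// Sweep a chain upward from a trial bottom activity x.  Fills y/ys (chain
// local, top..bottom) and returns the activator concentration required at
// the chain top; returns -1 when x is infeasible (a free pool went
// non-positive or an implied activity exceeded 1).
static double chain_sweep(const std::vector<int> &chain, double x,
                          const Pars &p, const Net &net,
                          std::vector<double> &y, std::vector<double> &ys) {
  const int k = (int)chain.size();
  ys[k - 1] = x;
  double act = 0.0;
  for (int j = k - 1; j >= 0; --j) {
    const int c = chain[j];
    const double Rp = ys[j] / (ys[j] + p.Kp[c]);
    const double q = Rp * p.K[c] / p.P[c];        // = y_c * (activator)
    const double ih = (c == net.inhib) ? p.I * ys[j] / (ys[j] + p.KB) : 0.0;
    const double child = (j < k - 1) ? y[j + 1] / p.K[chain[j + 1]] : 0.0;
    const double yy = 1.0 - p.E[c] * q / p.K[c] - ys[j] * (1.0 + child)
                      - p.Ep[c] * Rp - ih;
    if (yy <= 0.0) return -1.0;
    y[j] = yy;
    act = q / yy;
    if (j > 0) {
      if (act >= 1.0) return -1.0;
      ys[j - 1] = act;
    }
  }
  return act;
}

// Solve one chain given the activator concentration a at its top.
static void chain_solve(const std::vector<int> &chain, double a,
                        const Pars &p, const Net &net,
                        std::vector<double> &y, std::vector<double> &ys) {
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < BISECT_ITERS; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double act = chain_sweep(chain, mid, p, net, y, ys);
    if (act < 0.0 || act > a) hi = mid; else lo = mid;
  }
  chain_sweep(chain, lo, p, net, y, ys);
}

// Conservation residual of the root cycle at trial activity s = y_1*;
// solves all chains as a side effect.  Returns +Inf when s is infeasible
// (the kinase rate balance cannot be satisfied by any finite y_1).
static double root_residual(double s, const Pars &p, const Net &net,
                            std::vector<double> &y, std::vector<double> &ys) {
  const double Rp = s / (s + p.Kp[0]);
  if (Rp >= p.P[0]) return R_PosInf;
  const double y1 = p.K[0] * Rp / (p.P[0] - Rp);
  double load = 0.0;
  std::vector<double> cy, cys;
  for (size_t ci = 0; ci < net.chains.size(); ++ci) {
    const std::vector<int> &chain = net.chains[ci];
    cy.assign(chain.size(), 0.0);
    cys.assign(chain.size(), 0.0);
    chain_solve(chain, s, p, net, cy, cys);
    for (size_t j = 0; j < chain.size(); ++j) {
      y[chain[j]] = cy[j];
      ys[chain[j]] = cys[j];
    }
    load += cy[0] / p.K[chain[0]];
  }
  y[0] = y1;
  ys[0] = s;
  // bound cycle-1 kinase term E1*y1/(y1+K1) equals E1*Rp/P1 by rate balance
  return -1.0 + y1 + s * (1.0 + load) + (p.E[0] / p.P[0] + p.Ep[0]) * Rp;
}

// Full dimensionless residual system (2n equations) at a candidate state.
static double max_abs_residual(const std::vector<double> &y,
                               const std::vector<double> &ys,
                               const Pars &p, const Net &net,
                               std::vector<int> &kin) {
  const int n = net.n;
  double worst = 0.0;
  std::vector<double> load(n, 0.0);
  for (int i = 1; i < n; ++i) load[kin[i]] += y[i] / p.K[i];
  for (int i = 0; i < n; ++i) {
    const double Rp = ys[i] / (ys[i] + p.Kp[i]);
    double rate, bound;
    if (i == 0) {
      rate = p.P[i] * y[i] / (y[i] + p.K[i]) - Rp;
      bound = p.E[i] * y[i] / (y[i] + p.K[i]);
    } else {
      const double a = ys[kin[i]];
      rate = p.P[i] * y[i] * a / p.K[i] - Rp;
      bound = p.E[i] * y[i] * a / p.K[i];
    }
    const double ih = (i == net.inhib) ? p.I * ys[i] / (ys[i] + p.KB) : 0.0;
    const double pool = -1.0 + y[i] + bound + ys[i] * (1.0 + load[i])
                        + p.Ep[i] * Rp + ih;
    worst = std::max(worst, std::fabs(rate));
    worst = std::max(worst, std::fabs(pool));
  }
  return worst;
}

static Net make_net(List chains, int inhibited, int n) {
  Net net;
  net.n = n;
  net.inhib = inhibited - 1;
  for (int ci = 0; ci < chains.size(); ++ci) {
    IntegerVector ch = chains[ci];
    std::vector<int> v(ch.size());
    for (int j = 0; j < ch.size(); ++j) v[j] = ch[j] - 1;
    net.chains.push_back(v);
  }
  return net;
}

static std::vector<int> kin_map(const Net &net) {
  std::vector<int> kin(net.n, 0);
  for (size_t ci = 0; ci < net.chains.size(); ++ci) {
    const std::vector<int> &chain = net.chains[ci];
    kin[chain[0]] = 0;
    for (size_t j = 1; j < chain.size(); ++j) kin[chain[j]] = chain[j - 1];
  }
  return kin;
}

static void solve_one(const Pars &p, const Net &net,
                      std::vector<double> &y, std::vector<double> &ys,
                      double &resid) {
  double lo = 0.0, hi = 1.0;
  for (int it = 0; it < BISECT_ITERS; ++it) {
    const double mid = 0.5 * (lo + hi);
    const double F = root_residual(mid, p, net, y, ys);
    if (!R_finite(F) || F > 0.0) hi = mid; else lo = mid;
  }
  root_residual(lo, p, net, y, ys);
  std::vector<int> kin = kin_map(net);
  resid = max_abs_residual(y, ys, p, net, kin);
}

// [[Rcpp::export]]
List ss_solve_cpp(NumericVector E, NumericVector Ep, NumericVector K,
                  NumericVector Kp, NumericVector P, double KB, double I,
                  List chains, int inhibited) {
  const int n = E.size();
  Net net = make_net(chains, inhibited, n);
  Pars p;
  p.E = E.begin(); p.Ep = Ep.begin(); p.K = K.begin();
  p.Kp = Kp.begin(); p.P = P.begin(); p.KB = KB; p.I = I;
  std::vector<double> y(n), ys(n);
  double resid;
  solve_one(p, net, y, ys, resid);
  return List::create(_["y"] = NumericVector(y.begin(), y.end()),
                      _["ystar"] = NumericVector(ys.begin(), ys.end()),
                      _["residual"] = resid);
}

// Batch two-dose response: params has one row per parameter set with columns
// E1..En, Ep1..Epn, K1..Kn, Kp1..Kpn, P1..Pn, KB.  Returns per set the
// signed steady-state deltas y(I_high) - y(I_low) for every cycle plus the
// worst residual across the two solves.
// [[Rcpp::export]]
List batch_response_cpp(NumericMatrix params, List chains, int inhibited,
                        int n, double I_low, double I_high) {
  const int nsets = params.nrow();
  Net net = make_net(chains, inhibited, n);
  NumericMatrix dy(nsets, n), dys(nsets, n);
  NumericMatrix ylo(nsets, n), yslo(nsets, n), yhi(nsets, n), yshi(nsets, n);
  NumericVector resid(nsets);
  std::vector<double> E(n), Ep(n), K(n), Kp(n), P(n), y(n), ys(n), y2(n), ys2(n);
  for (int r = 0; r < nsets; ++r) {
    for (int i = 0; i < n; ++i) {
      E[i] = params(r, i);
      Ep[i] = params(r, n + i);
      K[i] = params(r, 2 * n + i);
      Kp[i] = params(r, 3 * n + i);
      P[i] = params(r, 4 * n + i);
    }
    Pars p;
    p.E = &E[0]; p.Ep = &Ep[0]; p.K = &K[0]; p.Kp = &Kp[0]; p.P = &P[0];
    p.KB = params(r, 5 * n);
    double r1, r2;
    p.I = I_low;
    solve_one(p, net, y, ys, r1);
    p.I = I_high;
    solve_one(p, net, y2, ys2, r2);
    for (int i = 0; i < n; ++i) {
      ylo(r, i) = y[i]; yslo(r, i) = ys[i];
      yhi(r, i) = y2[i]; yshi(r, i) = ys2[i];
      dy(r, i) = y2[i] - y[i];
      dys(r, i) = ys2[i] - ys[i];
    }
    resid[r] = std::max(r1, r2);
  }
  return List::create(_["dy"] = dy, _["dystar"] = dys,
                      _["y_low"] = ylo, _["ystar_low"] = yslo,
                      _["y_high"] = yhi, _["ystar_high"] = yshi,
                      _["residual"] = resid);
}
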