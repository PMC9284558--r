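// Deterministic and stochastic simulation backends for mass-action CRNs.
//
// The ODE backend is a Kaps-Rentrop Rosenbrock 4(3) method (Shampine
// parameter set) with an analytic Jacobian assembled from the stoichiometry.
// Strand-displacement networks mix rate constants over many orders of
// magnitude (toehold dissociation ~1e1 /s against trimolecular terms at
// nanomolar concentrations), so an L-stable implicit method is required; an
// explicit solver at these tolerances is not usable.
//
// State is in nM, time in s; rate constants must already be converted to
// nM-based units by the caller. Reaction systems are autonomous, so the
// df/dt terms of the general Rosenbrock formulation vanish.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// Shampine's parameters for the Kaps-Rentrop GRK4T family.
const double GAM = 0.5;
const double A21 = 2.0;
const double A31 = 48.0 / 25.0, A32 = 6.0 / 25.0;
const double C21 = -8.0;
const double C31 = 372.0 / 25.0, C32 = 12.0 / 5.0;
const double C41 = -112.0 / 125.0, C42 = -54.0 / 125.0, C43 = -2.0 / 5.0;
const double B1 = 19.0 / 9.0, B2 = 0.5, B3 = 25.0 / 108.0, B4 = 125.0 / 108.0;
const double E1 = 17.0 / 54.0, E2 = 7.0 / 36.0, E3 = 0.0, E4 = 125.0 / 108.0;

struct MassAction {
  arma::imat re;   // species x reactions reactant stoichiometry
  arma::mat nets;  // species x reactions net stoichiometry
  arma::vec k;     // rate constants, nM/s units
  int ns, nr;

  MassAction(const arma::imat& re_, const arma::mat& net_, const arma::vec& k_)
      : re(re_), nets(net_), k(k_), ns(re_.n_rows), nr(re_.n_cols) {}

  // propensities v_j = k_j * prod_i y_i^{m_ij}
  void propensities(const arma::vec& y, arma::vec& v) const {
    for (int j = 0; j < nr; ++j) {
      double p = k[j];
      for (int i = 0; i < ns; ++i) {
        int m = re(i, j);
        if (m == 1) p *= y[i];
        else if (m == 2) p *= y[i] * y[i];
        else if (m == 3) p *= y[i] * y[i] * y[i];
      }
      v[j] = p;
    }
  }

  void rhs(const arma::vec& y, arma::vec& f) const {
    arma::vec v(nr);
    propensities(y, v);
    f = nets * v;
  }

  // J = N * dv/dy with dv_j/dy_i = k_j m_ij y_i^{m_ij-1} prod_{l != i} y_l^{m_lj}
  void jacobian(const arma::vec& y, arma::mat& J) const {
    J.zeros(ns, ns);
    for (int j = 0; j < nr; ++j) {
      for (int i = 0; i < ns; ++i) {
        int m = re(i, j);
        if (m == 0) continue;
        double d = k[j] * m;
        if (m == 2) d *= y[i];
        else if (m == 3) d *= y[i] * y[i];
        for (int l = 0; l < ns; ++l) {
          if (l == i) continue;
          int ml = re(l, j);
          if (ml == 1) d *= y[l];
          else if (ml == 2) d *= y[l] * y[l];
          else if (ml == 3) d *= y[l] * y[l] * y[l];
        }
        for (int s = 0; s < ns; ++s) {
          double n = nets(s, j);
          if (n != 0.0) J(s, i) += n * d;
        }
      }
    }
  }
};

}  // namespace

// Integrate one event-free segment from t0 to t1, writing the state at each
// requested sample time (sorted, all in (t0, t1]). Returns the matrix of
// sampled states and the final state.
// [[Rcpp::export(name = ".ros_segment")]]
List ros_segment(const arma::imat& reactant_stoich,
                 const arma::mat& net_stoich,
                 const arma::vec& rates,
                 const arma::vec& y0,
                 double t0, double t1,
                 const arma::vec& sample_times,
                 double rtol, double atol,
                 double hmax) {
  MassAction sys(reactant_stoich, net_stoich, rates);
  const int ns = sys.ns;
  const int nsamp = sample_times.n_elem;
  arma::mat out(nsamp, ns);

  arma::vec y = y0, f0(ns), f1(ns), f2(ns), g1(ns), g2(ns), g3(ns), g4(ns);
  arma::vec ytmp(ns), ynew(ns), errv(ns), rhs2(ns);
  arma::mat J(ns, ns), W(ns, ns);

  double t = t0;
  double h = std::min(hmax, std::max((t1 - t0) * 1e-4, 1e-6));
  const double hmin = std::max(1e-14, (t1 - t0) * 1e-14);
  long nstep = 0;
  const long max_steps = 200000000L;

  int isamp = 0;
  while (isamp < nsamp) {
    double target = sample_times[isamp];
    while (t < target) {
      if (++nstep > max_steps)
        stop("ODE integration exceeded the step budget in segment [%g, %g] at t = %g",
             t0, t1, t);
      bool clipped = (t + h > target);
      double hs = clipped ? (target - t) : h;
      if (hs < hmin) { t = target; break; }

      sys.rhs(y, f0);
      sys.jacobian(y, J);
      W = -J;
      W.diag() += 1.0 / (GAM * hs);

      bool ok = true;

      if (!arma::solve(g1, W, f0, arma::solve_opts::fast)) ok = false;
      if (ok) {
        ytmp = y + A21 * g1;
        sys.rhs(ytmp, f1);
        rhs2 = f1 + (C21 / hs) * g1;
        if (!arma::solve(g2, W, rhs2, arma::solve_opts::fast)) ok = false;
      }
      if (ok) {
        ytmp = y + A31 * g1 + A32 * g2;
        sys.rhs(ytmp, f2);
        rhs2 = f2 + (C31 * g1 + C32 * g2) / hs;
        if (!arma::solve(g3, W, rhs2, arma::solve_opts::fast)) ok = false;
      }
      if (ok) {
        rhs2 = f2 + (C41 * g1 + C42 * g2 + C43 * g3) / hs;
        if (!arma::solve(g4, W, rhs2, arma::solve_opts::fast)) ok = false;
      }

      double err = 0.0;
      if (ok) {
        ynew = y + B1 * g1 + B2 * g2 + B3 * g3 + B4 * g4;
        errv = E1 * g1 + E2 * g2 + E3 * g3 + E4 * g4;
        for (int i = 0; i < ns; ++i) {
          double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
          double e = std::fabs(errv[i]) / sc;
          if (e > err) err = e;
        }
        if (!ynew.is_finite()) ok = false;
      }

      if (ok && err <= 1.0) {
        t += hs;
        y = ynew;
        double fac = (err > 1e-10) ? 0.9 * std::pow(err, -0.25) : 5.0;
        if (fac > 5.0) fac = 5.0;
        double hnew = std::min(hs * fac, hmax);
        // keep the larger proposal when the step was clipped to a sample time
        if (!clipped || hnew > h) h = hnew;
      } else {
        double fac = ok ? std::max(0.1, 0.9 * std::pow(err, -1.0 / 3.0)) : 0.1;
        h = hs * fac;
        if (h < hmin)
          stop("ODE integration failed in segment [%g, %g]: step size underflow at t = %g",
               t0, t1, t);
      }
    }
    out.row(isamp) = y.t();
    ++isamp;
  }

  return List::create(_["states"] = out, _["y_end"] = y);
}

// Gillespie direct-method SSA over one event-free segment. Copy numbers are
// integers stored as doubles; `omega` is copies per nM so that stochastic
// propensities a_j = k_j / omega^(order-1) * prod falling_factorial(n_i, m_ij)
// match the deterministic rates at large copy number. Uses R's RNG, so runs
// are reproducible under set.seed().
// [[Rcpp::export(name = ".ssa_segment")]]
List ssa_segment(const arma::imat& reactant_stoich,
                 const arma::mat& net_stoich,
                 const arma::vec& rates,
                 const arma::vec& x0,
                 double omega,
                 double t0, double t1,
                 const arma::vec& sample_times) {
  const int ns = reactant_stoich.n_rows;
  const int nr = reactant_stoich.n_cols;
  const int nsamp = sample_times.n_elem;
  arma::mat out(nsamp, ns);
  arma::vec x = x0, a(nr);

  // stochastic rate constants
  arma::vec c(nr);
  for (int j = 0; j < nr; ++j) {
    int order = 0;
    for (int i = 0; i < ns; ++i) order += reactant_stoich(i, j);
    c[j] = rates[j] / std::pow(omega, order - 1);
  }

  RNGScope scope;
  double t = t0;
  int isamp = 0;
  long nevent = 0;
  const long max_events = 500000000L;

  while (isamp < nsamp) {
    // propensities
    double atot = 0.0;
    for (int j = 0; j < nr; ++j) {
      double p = c[j];
      for (int i = 0; i < ns; ++i) {
        int m = reactant_stoich(i, j);
        for (int q = 0; q < m; ++q) p *= std::max(0.0, x[i] - q);
      }
      a[j] = p;
      atot += p;
    }

    double tnext;
    if (atot <= 0.0) {
      tnext = R_PosInf;  // quiescent: pad remaining samples with constant state
    } else {
      if (++nevent > max_events)
        stop("SSA exceeded the event budget at t = %g", t);
      tnext = t + ::Rf_rexp(1.0 / atot);
    }

    while (isamp < nsamp && sample_times[isamp] <= tnext) {
      out.row(isamp) = x.t();
      ++isamp;
    }
    if (isamp >= nsamp) break;
    if (!R_FINITE(tnext)) break;

    // choose channel
    double u = ::unif_rand() * atot;
    double acc = 0.0;
    int jsel = nr - 1;
    for (int j = 0; j < nr; ++j) {
      acc += a[j];
      if (u <= acc) { jsel = j; break; }
    }
    for (int i = 0; i < ns; ++i) x[i] += net_stoich(i, jsel);
    t = tnext;
  }
  // pad any remaining samples (quiescent exit)
  while (isamp < nsamp) {
    out.row(isamp) = x.t();
    ++isamp;
  }
  return List::create(_["states"] = out, _["x_end"] = x);
}
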