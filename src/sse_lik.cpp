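// Backward-time integration of the state-dependent speciation-extinction
// equations along every branch of a tree, in postorder.
//
// For composite state i with speciation lambda_i, extinction mu_i and
// anagenetic rates q_ij (off-diagonal), moving from the present toward the
// root:
//   dE_i/dt = mu_i - (lambda_i + mu_i + sum_j q_ij) E_i
//             + lambda_i E_i^2 + sum_j q_ij E_j
//   dD_i/dt = -(lambda_i + mu_i + sum_j q_ij) D_i
//             + 2 lambda_i E_i D_i + sum_j q_ij D_j
// with tip conditions D_i = rho_i [state match] and E_i = 1 - rho_i.
// D is renormalized at each node (log factors accumulated) so deep trees
// do not underflow.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SseParams {
  int ns;
  std::vector<double> lambda, mu, totr; // totr = lambda+mu+rowsum(q)
  std::vector<double> q;                // ns*ns row-major, diag 0
};

inline void deriv(const SseParams &p, const double *y, double *dy) {
  const int ns = p.ns;
  const double *E = y, *D = y + ns;
  double *dE = dy, *dD = dy + ns;
  for (int i = 0; i < ns; ++i) {
    double qe = 0.0, qd = 0.0;
    const double *qi = &p.q[(size_t)i * ns];
    for (int j = 0; j < ns; ++j) {
      qe += qi[j] * E[j];
      qd += qi[j] * D[j];
    }
    dE[i] = p.mu[i] - p.totr[i] * E[i] + p.lambda[i] * E[i] * E[i] + qe;
    dD[i] = -p.totr[i] * D[i] + 2.0 * p.lambda[i] * E[i] * D[i] + qd;
  }
}

// Cash-Karp embedded Runge-Kutta 4(5) step
const double b21 = 1.0 / 5.0;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
             b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
             b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
             b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
             c6 = 512.0 / 1771.0;
const double d1 = c1 - 2825.0 / 27648.0, d3 = c3 - 18575.0 / 48384.0,
             d4 = c4 - 13525.0 / 55296.0, d5 = -277.0 / 14336.0,
             d6 = c6 - 0.25;

// integrate y over [0, tlen]; returns false on failure
bool integrate_branch(const SseParams &p, std::vector<double> &y, double tlen,
                      double atol, double rtol) {
  const int n = 2 * p.ns;
  if (tlen <= 0.0) return true;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), ytmp(n),
      yerr(n), ynew(n);
  double t = 0.0;
  double h = tlen;
  // initial step bounded by the fastest rate
  double rmax = 1e-8;
  for (int i = 0; i < p.ns; ++i) rmax = std::max(rmax, p.totr[i]);
  h = std::min(h, 0.1 / rmax);
  long steps = 0;
  while (t < tlen) {
    if (++steps > 2000000L) return false;
    if (t + h > tlen) h = tlen - t;
    deriv(p, y.data(), k1.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    deriv(p, ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    deriv(p, ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    deriv(p, ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                            b54 * k4[i]);
    deriv(p, ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    deriv(p, ytmp.data(), k6.data());
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] +
                     d6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      errmax = std::max(errmax, std::fabs(yerr[i]) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      y = ynew;
      // clamp tiny negatives introduced by the integrator
      for (int i = 0; i < p.ns; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
        if (y[p.ns + i] < 0.0 && y[p.ns + i] > -atol) y[p.ns + i] = 0.0;
      }
      double fac = 0.9 * std::pow(std::max(errmax, 1e-12), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (h < 1e-14 * tlen) return false;
  }
  return true;
}

}  // namespace

// [[Rcpp::export]]
List sse_postorder_cpp(IntegerMatrix edge, NumericVector edge_len,
                       IntegerVector postorder, int n_tip, int n_node,
                       NumericMatrix tipD, NumericVector tipE,
                       NumericVector lambda, NumericVector mu,
                       NumericMatrix Qr, int force_node,
                       NumericVector force_mask, double atol, double rtol) {
  const int ns = lambda.size();
  SseParams p;
  p.ns = ns;
  p.lambda.assign(lambda.begin(), lambda.end());
  p.mu.assign(mu.begin(), mu.end());
  p.q.assign((size_t)ns * ns, 0.0);
  p.totr.assign(ns, 0.0);
  for (int i = 0; i < ns; ++i) {
    double rs = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (i != j) {
        p.q[(size_t)i * ns + j] = Qr(i, j);
        rs += Qr(i, j);
      }
    }
    p.totr[i] = p.lambda[i] + p.mu[i] + rs;
  }

  std::vector<std::vector<double> > nodeE(n_node), nodeD(n_node);
  std::vector<int> nseen(n_node, 0);
  double logscale = 0.0;
  bool ok = true;

  // tip initialization (with optional forcing mask on a tip)
  for (int tip = 0; tip < n_tip; ++tip) {
    nodeE[tip].assign(ns, 0.0);
    nodeD[tip].assign(ns, 0.0);
    for (int i = 0; i < ns; ++i) {
      nodeE[tip][i] = tipE[i];
      double d = tipD(tip, i);
      if (force_node == tip + 1) d *= force_mask[i];
      nodeD[tip][i] = d;
    }
  }

  const int nedge = edge.nrow();
  std::vector<int> nchild(n_node, 0);
  for (int k = 0; k < nedge; ++k) nchild[edge(k, 0) - 1] += 1;

  for (int idx = 0; idx < postorder.size() && ok; ++idx) {
    int k = postorder[idx] - 1;
    int par = edge(k, 0) - 1;
    int ch = edge(k, 1) - 1;
    std::vector<double> y(2 * ns);
    for (int i = 0; i < ns; ++i) {
      y[i] = nodeE[ch][i];
      y[ns + i] = nodeD[ch][i];
    }
    if (!integrate_branch(p, y, edge_len[k], atol, rtol)) {
      ok = false;
      break;
    }
    if (nseen[par] == 0) {
      nodeE[par].assign(ns, 0.0);
      nodeD[par].assign(ns, 0.0);
      for (int i = 0; i < ns; ++i) {
        nodeE[par][i] = y[i];
        nodeD[par][i] = y[ns + i];
      }
    } else {
      for (int i = 0; i < ns; ++i) {
        // combine: one lambda factor per extra child (polytomy-safe)
        nodeD[par][i] *= p.lambda[i] * y[ns + i];
      }
    }
    nseen[par] += 1;
    if (nseen[par] == nchild[par]) {
      // node complete: apply forcing, then rescale so deep trees cannot
      // underflow (the D system is linear in D so the factor is exact)
      if (force_node == par + 1) {
        for (int i = 0; i < ns; ++i) nodeD[par][i] *= force_mask[i];
      }
      double s = 0.0;
      for (int i = 0; i < ns; ++i) s += nodeD[par][i];
      if (s <= 0.0 || !std::isfinite(s)) {
        ok = false;
        logscale = R_NegInf;
        break;
      }
      for (int i = 0; i < ns; ++i) nodeD[par][i] /= s;
      logscale += std::log(s);
    }
  }

  int root = n_tip;  // 0-based root index (ape convention n_tip + 1)
  NumericVector rootD(ns), rootE(ns);
  if (ok) {
    for (int i = 0; i < ns; ++i) {
      rootD[i] = nodeD[root][i];
      rootE[i] = nodeE[root][i];
    }
  }
  return List::create(_["ok"] = ok, _["rootD"] = rootD, _["rootE"] = rootE,
                      _["logscale"] = logscale);
}
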