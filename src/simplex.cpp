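// Bounded-variable two-phase revised simplex with an explicit basis inverse.
//
// Solves   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
//
// Written because the target environment ships no R linear-programming
// package.  The design is tuned for dynamic FBA: the constraint matrix is
// fixed for a given metabolic model while bounds and objective change every
// time step, so a workspace holds A once and caches optimal bases keyed by
// (genotype, stage) for warm starts.  Problem sizes are small (m ~ 80 rows,
// n ~ 200 columns), so a dense inverse with periodic refactorisation is both
// simple and fast.

#include <RcppArmadillo.h>
#include <map>
#include <vector>
#include <limits>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double FEAS_TOL = 1e-9;   // bound violation considered feasible
static const double WARM_TOL = 1e-7;   // warm-start basis accepted if this close
static const double DUAL_TOL = 1e-9;   // reduced-cost optimality tolerance
static const double PIV_TOL  = 1e-9;   // minimum pivot magnitude
static const double PH1_TOL  = 1e-7;   // residual infeasibility declared infeasible
static const int    REFACTOR = 60;     // iterations between refactorisations
static const int    MAX_ITER = 50000;

struct SavedBasis {
  std::vector<int> basis;   // column index per row (may include artificials)
  std::vector<int> vstat;   // 0 = nonbasic at lb, 1 = nonbasic at ub, 2 = basic
  std::vector<double> asign;
};

struct Workspace {
  arma::mat A;   // m x n structural columns
  arma::vec b;
  int m, n;
  std::map<int, SavedBasis> saved;
};

struct Solver {
  const arma::mat& A;
  const arma::vec& b;
  int m, n, N;                 // N = n + m (artificial columns appended)
  arma::vec lbx, ubx;          // length N
  std::vector<double> asign;   // artificial column i is asign[i] * e_i
  std::vector<int> basis;      // length m
  std::vector<int> vstat;      // length N
  arma::mat Binv;
  arma::vec xB;
  int status;                  // 0 optimal, 1 infeasible, 2 unbounded, 3 failure

  Solver(const arma::mat& A_, const arma::vec& b_, const arma::vec& lb,
         const arma::vec& ub)
    : A(A_), b(b_), m(A_.n_rows), n(A_.n_cols), N(n + m), status(3) {
    lbx.set_size(N); ubx.set_size(N);
    lbx.subvec(0, n - 1) = lb;
    ubx.subvec(0, n - 1) = ub;
    for (int i = 0; i < m; ++i) {       // artificials: phase-1 bounds
      lbx(n + i) = 0.0;
      ubx(n + i) = std::numeric_limits<double>::infinity();
    }
    asign.assign(m, 1.0);
    vstat.assign(N, 0);
    basis.assign(m, -1);
    Binv.set_size(m, m);
    xB.set_size(m);
  }

  arma::vec acol(int j) const {
    if (j < n) return A.col(j);
    arma::vec e(m, arma::fill::zeros);
    e(j - n) = asign[j - n];
    return e;
  }

  double xval(int j) const {            // value of a nonbasic column
    return vstat[j] == 1 ? ubx(j) : lbx(j);
  }

  bool refactor() {
    arma::mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = acol(basis[i]);
    arma::mat inv;
    if (!arma::inv(inv, B)) return false;
    Binv = inv;
    return true;
  }

  void compute_xB() {
    arma::vec r = b;
    for (int j = 0; j < N; ++j) {
      if (vstat[j] == 2) continue;
      double v = xval(j);
      if (v != 0.0) r -= acol(j) * v;
    }
    xB = Binv * r;
  }

  double max_infeas() const {
    double w = 0.0;
    for (int i = 0; i < m; ++i) {
      int j = basis[i];
      w = std::max(w, lbx(j) - xB(i));
      w = std::max(w, xB(i) - ubx(j));
    }
    return w;
  }

  // one simplex phase on cost vector cc (length N), minimisation
  // returns final objective, sets status to 0 (optimal), 2 (unbounded) or 3
  double iterate(const arma::vec& cc, int& iter_budget) {
    int stall = 0;
    bool bland = false;
    double zprev = std::numeric_limits<double>::infinity();
    int it = 0;
    while (true) {
      if (iter_budget-- <= 0) { status = 3; break; }
      if (it % REFACTOR == 0) {
        if (!refactor()) { status = 3; break; }
        compute_xB();
      }
      ++it;
      // duals and pricing
      arma::vec cB(m);
      for (int i = 0; i < m; ++i) cB(i) = cc(basis[i]);
      arma::vec y = Binv.t() * cB;
      int q = -1; double best = DUAL_TOL; int dir = 0;
      for (int j = 0; j < N; ++j) {
        if (vstat[j] == 2) continue;
        if (ubx(j) - lbx(j) < 1e-12) continue;           // fixed column
        double dj;
        if (j < n) dj = cc(j) - arma::dot(y, A.col(j));
        else       dj = cc(j) - y(j - n) * asign[j - n];
        double viol = (vstat[j] == 0) ? -dj : dj;
        if (viol > (bland ? DUAL_TOL : best)) {
          q = j; dir = (vstat[j] == 0) ? 1 : -1;
          if (bland) break;
          best = viol;
        }
      }
      if (q < 0) { status = 0; break; }      // optimal
      arma::vec w = Binv * acol(q);
      // ratio test
      double tmax = ubx(q) - lbx(q);
      int leave = -1; double leave_piv = 0.0; int leave_dir = 0;
      for (int i = 0; i < m; ++i) {
        double g = dir * w(i);
        double lim;
        int ldir;
        if (g > PIV_TOL) { lim = (xB(i) - lbx(basis[i])) / g; ldir = 0; }
        else if (g < -PIV_TOL) { lim = (xB(i) - ubx(basis[i])) / g; ldir = 1; }
        else continue;
        if (lim < 0) lim = 0;
        if (lim < tmax - 1e-12 ||
            (lim < tmax + 1e-12 && std::fabs(g) > std::fabs(leave_piv))) {
          tmax = lim; leave = i; leave_piv = w(i); leave_dir = ldir;
        }
      }
      if (!std::isfinite(tmax)) { status = 2; break; }   // unbounded
      // apply step
      if (tmax > 0) xB -= (dir * tmax) * w;
      if (leave < 0) {
        vstat[q] = vstat[q] == 0 ? 1 : 0;                // bound flip
      } else {
        int lv = basis[leave];
        double xq = xval(q) + dir * tmax;
        basis[leave] = q;
        vstat[q] = 2;
        vstat[lv] = leave_dir;
        xB(leave) = xq;
        // product-form update of the inverse
        double piv = w(leave);
        if (std::fabs(piv) < PIV_TOL) {
          if (!refactor()) { status = 3; break; }
          compute_xB();
        } else {
          arma::rowvec pr = Binv.row(leave) / piv;
          for (int i = 0; i < m; ++i) {
            if (i == leave) continue;
            double f = w(i);
            if (f != 0.0) Binv.row(i) -= f * pr;
          }
          Binv.row(leave) = pr;
        }
      }
      // stall detection -> Bland's rule (anti-cycling)
      arma::vec cBn(m);
      for (int i = 0; i < m; ++i) cBn(i) = cc(basis[i]);
      double z = arma::dot(cBn, xB);
      for (int j = 0; j < N; ++j)
        if (vstat[j] != 2 && cc(j) != 0.0) z += cc(j) * xval(j);
      if (z < zprev - 1e-12) { stall = 0; bland = false; }
      else if (++stall > 50) bland = true;
      zprev = z;
    }
    arma::vec cB(m);
    for (int i = 0; i < m; ++i) cB(i) = cc(basis[i]);
    double z = arma::dot(cB, xB);
    for (int j = 0; j < N; ++j)
      if (vstat[j] != 2 && cc(j) != 0.0) z += cc(j) * xval(j);
    return z;
  }

  void cold_start() {
    // all structural columns nonbasic at the finite bound nearest zero
    for (int j = 0; j < n; ++j)
      vstat[j] = (std::fabs(lbx(j)) <= std::fabs(ubx(j))) ? 0 : 1;
    arma::vec r = b;
    for (int j = 0; j < n; ++j) {
      double v = xval(j);
      if (v != 0.0) r -= A.col(j) * v;
    }
    for (int i = 0; i < m; ++i) {
      asign[i] = (r(i) >= 0) ? 1.0 : -1.0;
      basis[i] = n + i;
      vstat[n + i] = 2;
      lbx(n + i) = 0.0;
      ubx(n + i) = std::numeric_limits<double>::infinity();
      xB(i) = std::fabs(r(i));
      Binv.zeros();
    }
    for (int i = 0; i < m; ++i) Binv(i, i) = asign[i];
  }

  void drive_out_artificials() {
    for (int r = 0; r < m; ++r) {
      if (basis[r] < n) continue;
      arma::rowvec br = Binv.row(r);
      int enter = -1; double bestp = PIV_TOL * 10;
      for (int j = 0; j < n; ++j) {
        if (vstat[j] == 2) continue;
        double p = arma::dot(br, A.col(j));
        if (std::fabs(p) > bestp) { bestp = std::fabs(p); enter = j; }
      }
      if (enter < 0) continue;           // redundant row; artificial pinned at 0
      int lv = basis[r];
      double piv = arma::dot(br, A.col(enter));
      arma::vec w = Binv * A.col(enter);
      basis[r] = enter;
      double old = xval(enter);
      vstat[enter] = 2;
      vstat[lv] = 0;
      arma::rowvec pr = Binv.row(r) / piv;
      for (int i = 0; i < m; ++i) {
        if (i == r) continue;
        double f = w(i);
        if (f != 0.0) Binv.row(i) -= f * pr;
      }
      Binv.row(r) = pr;
      xB(r) = old;                       // degenerate pivot: value unchanged (0-level)
      compute_xB();
    }
  }

  // full solve; cc2 is the phase-2 cost (length n, minimisation form)
  double solve(const arma::vec& c2min, bool warm, const SavedBasis* sb) {
    int budget = MAX_ITER;
    bool have_feasible = false;
    if (warm && sb && (int)sb->basis.size() == m) {
      basis = sb->basis;
      vstat = sb->vstat;
      asign = sb->asign;
      // artificials that are in the saved basis stay pinned at zero
      for (int i = 0; i < m; ++i) { lbx(n + i) = 0.0; ubx(n + i) = 0.0; }
      for (int j = 0; j < N; ++j)
        if (vstat[j] == 2) { bool inb = false;
          for (int i = 0; i < m; ++i) if (basis[i] == j) { inb = true; break; }
          if (!inb) vstat[j] = 0; }
      if (refactor()) {
        compute_xB();
        if (max_infeas() < WARM_TOL) have_feasible = true;
      }
    }
    if (!have_feasible) {
      cold_start();
      arma::vec c1(N, arma::fill::zeros);
      for (int i = 0; i < m; ++i) c1(n + i) = 1.0;
      double z1 = iterate(c1, budget);
      if (status != 0) return NA_REAL;
      if (z1 > PH1_TOL) { status = 1; return NA_REAL; }
      drive_out_artificials();
      for (int i = 0; i < m; ++i) ubx(n + i) = 0.0;
    }
    arma::vec cc(N, arma::fill::zeros);
    cc.subvec(0, n - 1) = c2min;
    double z = iterate(cc, budget);
    if (status == 0 && max_infeas() > 1e-6) {
      if (refactor()) { compute_xB(); }
      if (max_infeas() > 1e-6) status = 3;
    }
    return z;
  }

  arma::vec solution() const {
    arma::vec x(n);
    for (int j = 0; j < n; ++j) x(j) = xval(j);
    for (int i = 0; i < m; ++i)
      if (basis[i] < n) x(basis[i]) = xB(i);
    return x;
  }
};

//' @noRd
// [[Rcpp::export]]
SEXP lp_workspace_new(const arma::mat& A, const arma::vec& b) {
  Workspace* ws = new Workspace();
  ws->A = A; ws->b = b;
  ws->m = A.n_rows; ws->n = A.n_cols;
  XPtr<Workspace> p(ws, true);
  return p;
}

//' @noRd
// [[Rcpp::export]]
List lp_workspace_solve(SEXP wsp, const arma::vec& c, const arma::vec& lb,
                        const arma::vec& ub, bool maximize, int warm_key) {
  XPtr<Workspace> ws(wsp);
  arma::vec cmin = maximize ? arma::vec(-c) : c;
  Solver s(ws->A, ws->b, lb, ub);
  const SavedBasis* sb = nullptr;
  bool warm = false;
  if (warm_key >= 0) {
    auto it = ws->saved.find(warm_key);
    if (it != ws->saved.end()) { sb = &it->second; warm = true; }
  }
  double z = s.solve(cmin, warm, sb);
  Solver* sp = &s;
  Solver s2(ws->A, ws->b, lb, ub);
  if (s.status == 3 && warm) {          // warm start failed; retry cold
    z = s2.solve(cmin, false, nullptr);
    sp = &s2;
  }
  List out;
  out["status"] = sp->status;
  if (sp->status == 0) {
    out["obj"] = maximize ? -z : z;
    arma::vec x = sp->solution();
    out["x"] = NumericVector(x.begin(), x.end());
    if (warm_key >= 0) {
      SavedBasis sv; sv.basis = sp->basis; sv.vstat = sp->vstat;
      sv.asign = sp->asign;
      ws->saved[warm_key] = sv;
    }
  } else {
    out["obj"] = NA_REAL;
    out["x"] = NumericVector(ws->n, NA_REAL);
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
void lp_workspace_forget(SEXP wsp, IntegerVector keys) {
  XPtr<Workspace> ws(wsp);
  for (int k : keys) ws->saved.erase(k);
}

//' @noRd
// [[Rcpp::export]]
List lp_solve_dense(const arma::mat& A, const arma::vec& b, const arma::vec& c,
                    const arma::vec& lb, const arma::vec& ub, bool maximize) {
  Workspace ws; ws.A = A; ws.b = b; ws.m = A.n_rows; ws.n = A.n_cols;
  arma::vec cmin = maximize ? arma::vec(-c) : c;
  Solver s(ws.A, ws.b, lb, ub);
  double z = s.solve(cmin, false, nullptr);
  List out;
  out["status"] = s.status;
  if (s.status == 0) {
    out["obj"] = maximize ? -z : z;
    arma::vec x = s.solution();
    out["x"] = NumericVector(x.begin(), x.end());
  } else {
    out["obj"] = NA_REAL;
    out["x"] = NumericVector(ws.n, NA_REAL);
  }
  return out;
}
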