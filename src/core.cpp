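// Compiled core of the vertex-model simulator: potential energy of the
// polygonal tube surface, its analytic gradient, the fixed-step RK4
// integrator, short-edge scanning for T1 reconnection, and random
// sequential adsorption of disc centres for the initial tessellation.
//
// Mesh layout passed from R (all indices 0-based here):
//   X            vertex coordinates, vertex i at X[3i..3i+2]
//   fptr/fvert   CSR face loops; lateral cells first, then the two caps
//   e1/e2/emult  unique edges of the lateral cells; emult is the summed
//                per-cell edge weight (2 for an interior edge with w=1
//                on both sides, 1 for a cap-ring edge, +w-1 per cell
//                declaring the edge "special")
//   topv/botv    ordered cap-ring vertex ids (z held fixed on these)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Params {
  double sigmaL, kS, kV, kB, S0, V0, R2top, R2bot;
  bool fix_ring_z;
};

struct Topo {
  int nv, nf, nlat, maxm;
  std::vector<int> fptr, fvert;
  std::vector<int> e1, e2;
  std::vector<double> emult;
  std::vector<int> topv, botv;
  std::vector<char> capmask;  // per-vertex: on a cap ring
};

inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

Params read_params(const List& par) {
  Params P;
  P.sigmaL = as<double>(par["sigma_L"]);
  P.kS = as<double>(par["kappa_S"]);
  P.kV = as<double>(par["kappa_V"]);
  P.kB = as<double>(par["kappa_B"]);
  P.S0 = as<double>(par["S_o"]);
  P.V0 = as<double>(par["V_o"]);
  double rt = as<double>(par["R_top"]), rb = as<double>(par["R_bottom"]);
  P.R2top = rt * rt;
  P.R2bot = rb * rb;
  P.fix_ring_z = true;
  if (par.containsElementNamed("fix_ring_z"))
    P.fix_ring_z = as<bool>(par["fix_ring_z"]);
  return P;
}

Topo build_topo(int nv, const IntegerVector& fptr, const IntegerVector& fvert,
                int nlat, const IntegerVector& e1, const IntegerVector& e2,
                const NumericVector& emult, const IntegerVector& topv,
                const IntegerVector& botv) {
  Topo T;
  T.nv = nv;
  T.nf = fptr.size() - 1;
  T.nlat = nlat;
  T.fptr.assign(fptr.begin(), fptr.end());
  T.fvert.assign(fvert.begin(), fvert.end());
  T.e1.assign(e1.begin(), e1.end());
  T.e2.assign(e2.begin(), e2.end());
  T.emult.assign(emult.begin(), emult.end());
  T.topv.assign(topv.begin(), topv.end());
  T.botv.assign(botv.begin(), botv.end());
  T.capmask.assign(nv, 0);
  for (int v : T.topv) T.capmask[v] = 1;
  for (int v : T.botv) T.capmask[v] = 1;
  T.maxm = 0;
  for (int f = 0; f < T.nf; ++f)
    T.maxm = std::max(T.maxm, T.fptr[f + 1] - T.fptr[f]);
  return T;
}

void ring_term(const std::vector<double>& X, const std::vector<int>& ids,
               double R2, double kB, double& UB, double* G) {
  const int m = (int)ids.size();
  if (m == 0) return;
  double p[3] = {0, 0, 0};
  for (int id : ids) {
    p[0] += X[3 * id];
    p[1] += X[3 * id + 1];
    p[2] += X[3 * id + 2];
  }
  p[0] /= m; p[1] /= m; p[2] /= m;
  std::vector<double> dj(m);
  double sum_dv[3] = {0, 0, 0};
  for (int j = 0; j < m; ++j) {
    const int id = ids[j];
    double r[3] = {X[3 * id] - p[0], X[3 * id + 1] - p[1], X[3 * id + 2] - p[2]};
    dj[j] = r[0] * r[0] + r[1] * r[1] + r[2] * r[2] - R2;
    UB += kB * dj[j] * dj[j];
    if (G)
      for (int k = 0; k < 3; ++k) sum_dv[k] += dj[j] * r[k];
  }
  if (G) {
    for (int j = 0; j < m; ++j) {
      const int id = ids[j];
      for (int k = 0; k < 3; ++k) {
        double r = X[3 * id + k] - p[k];
        G[3 * id + k] += kB * 4.0 * (dj[j] * r - sum_dv[k] / m);
      }
    }
  }
}

// Energy terms (UL, UES, UEV, UB) and optionally the gradient of their sum.
void eval_U(const std::vector<double>& X, const Topo& T, const Params& P,
            double* Uout, std::vector<double>* Gp,
            std::vector<double>& dS_scratch) {
  const int nv = T.nv;
  double UL = 0, UES = 0, UEV = 0, UB = 0;
  double* G = nullptr;
  if (Gp) {
    Gp->assign(3 * nv, 0.0);
    G = Gp->data();
  }

  // edge energy
  const int ne = (int)T.e1.size();
  for (int e = 0; e < ne; ++e) {
    const int i = T.e1[e], j = T.e2[e];
    double d[3] = {X[3 * i] - X[3 * j], X[3 * i + 1] - X[3 * j + 1],
                   X[3 * i + 2] - X[3 * j + 2]};
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    UL += P.sigmaL * T.emult[e] * L;
    if (G && L > 1e-14) {
      double c = P.sigmaL * T.emult[e] / L;
      for (int k = 0; k < 3; ++k) {
        G[3 * i + k] += c * d[k];
        G[3 * j + k] -= c * d[k];
      }
    }
  }

  // areas (lateral faces, centroid fan) and enclosed volume (all faces)
  double Vol = 0.0;
  if ((int)dS_scratch.size() < 3 * T.maxm) dS_scratch.assign(3 * T.maxm, 0.0);
  for (int f = 0; f < T.nf; ++f) {
    const int s = T.fptr[f], m = T.fptr[f + 1] - s;
    double c[3] = {0, 0, 0};
    for (int k = 0; k < m; ++k) {
      const int v = T.fvert[s + k];
      c[0] += X[3 * v]; c[1] += X[3 * v + 1]; c[2] += X[3 * v + 2];
    }
    c[0] /= m; c[1] /= m; c[2] /= m;

    // volume contribution: tetrahedra (origin, centroid, v_k, v_k+1)
    for (int k = 0; k < m; ++k) {
      const double* a = &X[3 * T.fvert[s + k]];
      const double* b = &X[3 * T.fvert[s + (k + 1) % m]];
      double cr[3];
      cross3(a, b, cr);
      Vol += (c[0] * cr[0] + c[1] * cr[1] + c[2] * cr[2]) / 6.0;
    }

    if (f >= T.nlat) continue;  // caps carry no area elasticity

    double S = 0.0, dSc[3] = {0, 0, 0};
    double* dS = dS_scratch.data();
    if (G) std::fill(dS, dS + 3 * m, 0.0);
    for (int k = 0; k < m; ++k) {
      const int k1 = (k + 1) % m;
      const double* a = &X[3 * T.fvert[s + k]];
      const double* b = &X[3 * T.fvert[s + k1]];
      double u[3] = {a[0] - c[0], a[1] - c[1], a[2] - c[2]};
      double w[3] = {b[0] - c[0], b[1] - c[1], b[2] - c[2]};
      double n[3];
      cross3(u, w, n);
      double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
      S += 0.5 * nn;
      if (G && nn > 1e-14) {
        double nh[3] = {n[0] / nn, n[1] / nn, n[2] / nn};
        double t1[3], t2[3];
        cross3(w, nh, t1);   // dA/dv_k   = 0.5 * (w x nhat)
        cross3(nh, u, t2);   // dA/dv_k+1 = 0.5 * (nhat x u)
        for (int q = 0; q < 3; ++q) {
          dS[3 * k + q] += 0.5 * t1[q];
          dS[3 * k1 + q] += 0.5 * t2[q];
          dSc[q] -= 0.5 * (t1[q] + t2[q]);
        }
      }
    }
    UES += P.kS * (S - P.S0) * (S - P.S0);
    if (G) {
      const double coef = 2.0 * P.kS * (S - P.S0);
      for (int k = 0; k < m; ++k) {
        const int v = T.fvert[s + k];
        for (int q = 0; q < 3; ++q)
          G[3 * v + q] += coef * (dS[3 * k + q] + dSc[q] / m);
      }
    }
  }
  UEV = P.kV * (Vol - P.V0) * (Vol - P.V0);

  // gradient of the volume term needs the final Vol: second face pass
  if (G) {
    const double cv = 2.0 * P.kV * (Vol - P.V0) / 6.0;
    for (int f = 0; f < T.nf; ++f) {
      const int s = T.fptr[f], m = T.fptr[f + 1] - s;
      double c[3] = {0, 0, 0};
      for (int k = 0; k < m; ++k) {
        const int v = T.fvert[s + k];
        c[0] += X[3 * v]; c[1] += X[3 * v + 1]; c[2] += X[3 * v + 2];
      }
      c[0] /= m; c[1] /= m; c[2] /= m;
      double dVc[3] = {0, 0, 0};
      for (int k = 0; k < m; ++k) {
        const int va = T.fvert[s + k], vb = T.fvert[s + (k + 1) % m];
        const double* a = &X[3 * va];
        const double* b = &X[3 * vb];
        double cr[3];
        cross3(a, b, cr);
        for (int q = 0; q < 3; ++q) dVc[q] += cr[q];
        cross3(b, c, cr);  // dV/dv_k = (v_k+1 x c)/6
        for (int q = 0; q < 3; ++q) G[3 * va + q] += cv * cr[q];
        cross3(c, a, cr);  // dV/dv_k+1 = (c x v_k)/6
        for (int q = 0; q < 3; ++q) G[3 * vb + q] += cv * cr[q];
      }
      for (int k = 0; k < m; ++k) {
        const int v = T.fvert[s + k];
        for (int q = 0; q < 3; ++q) G[3 * v + q] += cv * dVc[q] / m;
      }
    }
  }

  // cap-ring restriction about instantaneous ring centroids
  ring_term(X, T.topv, P.R2top, P.kB, UB, G);
  ring_term(X, T.botv, P.R2bot, P.kB, UB, G);

  Uout[0] = UL; Uout[1] = UES; Uout[2] = UEV; Uout[3] = UB;
  Uout[4] = UL + UES + UEV + UB;
}

// F = -grad U, with constrained components zeroed: cap-ring z always
// (end rings live in their initial planes), cap-ring x/y when fix_xy.
void forces(const std::vector<double>& X, const Topo& T, const Params& P,
            bool fix_xy, std::vector<double>& F, std::vector<double>& scratch) {
  double U[5];
  eval_U(X, T, P, U, &F, scratch);
  for (double& g : F) g = -g;
  for (int v = 0; v < T.nv; ++v) {
    if (T.capmask[v]) {
      if (P.fix_ring_z) F[3 * v + 2] = 0.0;
      if (fix_xy) { F[3 * v] = 0.0; F[3 * v + 1] = 0.0; }
    }
  }
}

struct RK4Work {
  std::vector<double> k1, k2, k3, k4, xt, scratch;
};

void rk4_step(std::vector<double>& X, double h, const Topo& T, const Params& P,
              bool fix_xy, RK4Work& W) {
  const size_t n = X.size();
  W.xt.resize(n);
  forces(X, T, P, fix_xy, W.k1, W.scratch);
  for (size_t i = 0; i < n; ++i) W.xt[i] = X[i] + 0.5 * h * W.k1[i];
  forces(W.xt, T, P, fix_xy, W.k2, W.scratch);
  for (size_t i = 0; i < n; ++i) W.xt[i] = X[i] + 0.5 * h * W.k2[i];
  forces(W.xt, T, P, fix_xy, W.k3, W.scratch);
  for (size_t i = 0; i < n; ++i) W.xt[i] = X[i] + h * W.k3[i];
  forces(W.xt, T, P, fix_xy, W.k4, W.scratch);
  for (size_t i = 0; i < n; ++i)
    X[i] += h / 6.0 * (W.k1[i] + 2.0 * W.k2[i] + 2.0 * W.k3[i] + W.k4[i]);
}

std::vector<double> flatten(const NumericMatrix& V) {
  const int nv = V.nrow();
  std::vector<double> X(3 * nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) X[3 * i + k] = V(i, k);
  return X;
}

NumericMatrix unflatten(const std::vector<double>& X) {
  const int nv = (int)X.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = X[3 * i + k];
  return V;
}

}  // namespace

// [[Rcpp::export]]
List cpp_energy(NumericMatrix V, IntegerVector fptr, IntegerVector fvert,
                int nlat, IntegerVector e1, IntegerVector e2,
                NumericVector emult, IntegerVector topv, IntegerVector botv,
                List par) {
  Topo T = build_topo(V.nrow(), fptr, fvert, nlat, e1, e2, emult, topv, botv);
  Params P = read_params(par);
  std::vector<double> X = flatten(V), scratch;
  double U[5];
  eval_U(X, T, P, U, nullptr, scratch);
  return List::create(_["U_L"] = U[0], _["U_ES"] = U[1], _["U_EV"] = U[2],
                      _["U_B"] = U[3], _["U"] = U[4]);
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix V, IntegerVector fptr,
                         IntegerVector fvert, int nlat, IntegerVector e1,
                         IntegerVector e2, NumericVector emult,
                         IntegerVector topv, IntegerVector botv, List par,
                         bool fix_xy) {
  Topo T = build_topo(V.nrow(), fptr, fvert, nlat, e1, e2, emult, topv, botv);
  Params P = read_params(par);
  std::vector<double> X = flatten(V), F, scratch;
  forces(X, T, P, fix_xy, F, scratch);
  return unflatten(F);
}

// [[Rcpp::export]]
NumericVector cpp_face_areas(NumericMatrix V, IntegerVector fptr,
                             IntegerVector fvert) {
  const int nf = fptr.size() - 1;
  NumericVector out(nf);
  std::vector<double> X = flatten(V);
  for (int f = 0; f < nf; ++f) {
    const int s = fptr[f], m = fptr[f + 1] - s;
    double c[3] = {0, 0, 0};
    for (int k = 0; k < m; ++k) {
      const int v = fvert[s + k];
      c[0] += X[3 * v]; c[1] += X[3 * v + 1]; c[2] += X[3 * v + 2];
    }
    c[0] /= m; c[1] /= m; c[2] /= m;
    double S = 0;
    for (int k = 0; k < m; ++k) {
      const double* a = &X[3 * fvert[s + k]];
      const double* b = &X[3 * fvert[s + (k + 1) % m]];
      double u[3] = {a[0] - c[0], a[1] - c[1], a[2] - c[2]};
      double w[3] = {b[0] - c[0], b[1] - c[1], b[2] - c[2]};
      double n[3];
      cross3(u, w, n);
      S += 0.5 * std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
    }
    out[f] = S;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_enclosed_volume(NumericMatrix V, IntegerVector fptr,
                           IntegerVector fvert) {
  const int nf = fptr.size() - 1;
  std::vector<double> X = flatten(V);
  double Vol = 0;
  for (int f = 0; f < nf; ++f) {
    const int s = fptr[f], m = fptr[f + 1] - s;
    double c[3] = {0, 0, 0};
    for (int k = 0; k < m; ++k) {
      const int v = fvert[s + k];
      c[0] += X[3 * v]; c[1] += X[3 * v + 1]; c[2] += X[3 * v + 2];
    }
    c[0] /= m; c[1] /= m; c[2] /= m;
    for (int k = 0; k < m; ++k) {
      const double* a = &X[3 * fvert[s + k]];
      const double* b = &X[3 * fvert[s + (k + 1) % m]];
      double cr[3];
      cross3(a, b, cr);
      Vol += (c[0] * cr[0] + c[1] * cr[1] + c[2] * cr[2]) / 6.0;
    }
  }
  return Vol;
}

// Integrate nsteps of RK4 (or fewer: returns early with status 1 when a
// reconnectable edge falls below delta, checked before every step, so a
// caller performing the T1 swap can resume). Only "armed" edges trigger;
// a disarmed edge re-arms once its length reaches arm_length (anti-livelock
// rule: the caller disarms the edge created by a T1, and a refused swap,
// so a pair cannot toggle without first growing well past delta). States
// and energy terms are recorded whenever the global step count (step0 +
// steps done) is a multiple of save_every.
// status: 0 done, 1 short edge, 2 non-finite.
// [[Rcpp::export]]
List cpp_run(NumericMatrix V, IntegerVector fptr, IntegerVector fvert,
             int nlat, IntegerVector e1, IntegerVector e2, NumericVector emult,
             IntegerVector topv, IntegerVector botv, List par, double h,
             int nsteps, int step0, int save_every, double delta,
             bool reconnect, LogicalVector reco_ok, LogicalVector armed_in,
             double arm_length, bool fix_xy) {
  Topo T = build_topo(V.nrow(), fptr, fvert, nlat, e1, e2, emult, topv, botv);
  Params P = read_params(par);
  std::vector<double> X = flatten(V), scratch;
  RK4Work W;
  const int ne = (int)T.e1.size();
  std::vector<char> armed(armed_in.begin(), armed_in.end());

  auto edge_len = [&](int e) {
    const int i = T.e1[e], j = T.e2[e];
    double d0 = X[3 * i] - X[3 * j], d1 = X[3 * i + 1] - X[3 * j + 1],
           d2 = X[3 * i + 2] - X[3 * j + 2];
    return std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
  };

  auto scan_short = [&]() -> int {
    int best = -1;
    double bestL = delta;
    for (int e = 0; e < ne; ++e) {
      if (!reco_ok[e]) continue;
      double L = edge_len(e);
      if (!armed[e]) {
        if (L >= arm_length) armed[e] = 1;
        continue;
      }
      if (L < bestL) { bestL = L; best = e; }
    }
    return best;
  };

  std::vector<int> save_steps;
  std::vector<double> save_U, snaps;
  double shortL = NA_REAL;
  int done = 0, status = 0, short_e = -1;

  while (true) {
    if (reconnect) {
      short_e = scan_short();
      if (short_e >= 0) {
        shortL = edge_len(short_e);
        status = 1;
        break;
      }
    }
    if (done >= nsteps) { status = 0; break; }
    rk4_step(X, h, T, P, fix_xy, W);
    ++done;
    double s = 0;
    for (double x : X) s += x;
    if (!std::isfinite(s)) { status = 2; break; }
    if ((step0 + done) % save_every == 0) {
      double U[5];
      eval_U(X, T, P, U, nullptr, scratch);
      save_steps.push_back(step0 + done);
      for (int q = 0; q < 5; ++q) save_U.push_back(U[q]);
      snaps.insert(snaps.end(), X.begin(), X.end());
      Rcpp::checkUserInterrupt();
    }
  }

  const int nsave = (int)save_steps.size();
  NumericMatrix Umat(nsave, 5);
  for (int r = 0; r < nsave; ++r)
    for (int q = 0; q < 5; ++q) Umat(r, q) = save_U[5 * r + q];
  NumericVector states(snaps.begin(), snaps.end());
  if (nsave > 0) states.attr("dim") = IntegerVector::create(3, V.nrow(), nsave);

  LogicalVector armed_out(ne);
  for (int e = 0; e < ne; ++e) armed_out[e] = armed[e] != 0;

  return List::create(
      _["V"] = unflatten(X), _["steps_done"] = done, _["status"] = status,
      _["short_edge"] = short_e + 1, _["short_length"] = shortL,
      _["save_steps"] = wrap(save_steps), _["save_U"] = Umat,
      _["states"] = states, _["armed"] = armed_out);
}

// Random sequential adsorption of n hard discs (centre spacing >= dmin) in
// [0,W) x [0,H], periodic in x only. Uses R's RNG. Errors out if the
// attempt budget is exhausted before n discs are placed.
// [[Rcpp::export]]
NumericMatrix cpp_rsa_pack(int n, double W, double H, double dmin,
                           int max_attempts) {
  const int ngx = std::max(1, (int)std::floor(W / dmin));
  const int ngy = std::max(1, (int)std::floor(H / dmin));
  const double gx = W / ngx, gy = H / ngy;
  std::vector<std::vector<int>> grid(ngx * ngy);
  std::vector<double> xs, ys;
  xs.reserve(n); ys.reserve(n);
  const double d2 = dmin * dmin;
  int placed = 0;
  for (int att = 0; att < max_attempts && placed < n; ++att) {
    const double x = R::runif(0.0, W), y = R::runif(0.0, H);
    const int cx = std::min((int)(x / gx), ngx - 1);
    const int cy = std::min((int)(y / gy), ngy - 1);
    bool ok = true;
    for (int dx = -1; dx <= 1 && ok; ++dx) {
      for (int dy = -1; dy <= 1 && ok; ++dy) {
        const int ccy = cy + dy;
        if (ccy < 0 || ccy >= ngy) continue;
        const int ccx = ((cx + dx) % ngx + ngx) % ngx;
        for (int id : grid[ccx + ngx * ccy]) {
          double ddx = std::fabs(xs[id] - x);
          ddx = std::min(ddx, W - ddx);
          const double ddy = ys[id] - y;
          if (ddx * ddx + ddy * ddy < d2) { ok = false; break; }
        }
      }
    }
    if (ok) {
      xs.push_back(x);
      ys.push_back(y);
      grid[cx + ngx * cy].push_back(placed);
      ++placed;
    }
  }
  if (placed < n)
    stop("disc packing failed: placed %d of %d discs within %d attempts",
         placed, n, max_attempts);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = xs[i]; out(i, 1) = ys[i]; }
  return out;
}
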