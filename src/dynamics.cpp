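// Recursive Newton-Euler inverse dynamics and forward kinematics on the
// expanded single-axis node tree. Nodes are topologically ordered (parent
// index < own index, 0 = ground). Frames: ground-fixed world frame; gravity
// is applied through a fictitious base acceleration a0 = -g.

#include <Rcpp.h>
using namespace Rcpp;

static inline void cross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// y = R * x, R column-major 3x3
static inline void matvec(const double* R, const double* x, double* y) {
  y[0] = R[0] * x[0] + R[3] * x[1] + R[6] * x[2];
  y[1] = R[1] * x[0] + R[4] * x[1] + R[7] * x[2];
  y[2] = R[2] * x[0] + R[5] * x[1] + R[8] * x[2];
}

// C = A * B (3x3, column-major)
static inline void matmat(const double* A, const double* B, double* C) {
  for (int j = 0; j < 3; ++j) {
    matvec(A, B + 3 * j, C + 3 * j);
  }
}

// Rodrigues rotation about unit axis u by angle th, column-major output
static void axis_rot(const double* u, double th, double* R) {
  double c = std::cos(th), s = std::sin(th), v = 1.0 - c;
  double x = u[0], y = u[1], z = u[2];
  R[0] = x * x * v + c;     R[3] = x * y * v - z * s; R[6] = x * z * v + y * s;
  R[1] = x * y * v + z * s; R[4] = y * y * v + c;     R[7] = y * z * v - x * s;
  R[2] = x * z * v - y * s; R[5] = y * z * v + x * s; R[8] = z * z * v + c;
}

// [[Rcpp::export]]
List rnea_cpp(IntegerVector parent, IntegerVector is_rot,
              NumericMatrix Rpre, NumericMatrix tpre, NumericMatrix axis,
              NumericVector mass, NumericMatrix com, NumericMatrix inertia,
              NumericVector q, NumericVector qd, NumericVector qdd,
              NumericVector a0,
              IntegerVector ext_node, NumericMatrix ext_lp,
              NumericMatrix ext_f, NumericMatrix ext_t,
              bool want_kinematics) {
  const int n = parent.size();
  NumericMatrix Rw(9, n), pw(3, n), zw(3, n), ww(3, n), aw(3, n),
      vw(3, n), lw(3, n), fj(3, n), nj(3, n), ac(3, n);
  NumericVector tau(n);

  // ---- forward pass ----
  for (int i = 0; i < n; ++i) {
    int pa = parent[i] - 1;  // -1 = ground
    double Rpar_id[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    const double* Rpar = pa >= 0 ? &Rw(0, pa) : Rpar_id;
    double zero3[3] = {0, 0, 0};
    const double* ppar = pa >= 0 ? &pw(0, pa) : zero3;
    const double* wpar = pa >= 0 ? &ww(0, pa) : zero3;
    const double* apar = pa >= 0 ? &aw(0, pa) : zero3;
    const double* vpar = pa >= 0 ? &vw(0, pa) : zero3;
    const double* lpar = pa >= 0 ? &lw(0, pa) : &a0[0];

    double Ra[9], pA[3], z[3], tmp[3];
    matmat(Rpar, &Rpre(0, i), Ra);
    matvec(Rpar, &tpre(0, i), tmp);
    for (int k = 0; k < 3; ++k) pA[k] = ppar[k] + tmp[k];
    matvec(Ra, &axis(0, i), z);
    for (int k = 0; k < 3; ++k) zw(k, i) = z[k];

    double d[3], wxd[3], wxwxd[3], axd[3];
    if (is_rot[i]) {
      double Rj[9];
      axis_rot(&axis(0, i), q[i], Rj);
      matmat(Ra, Rj, &Rw(0, i));
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k];
      for (int k = 0; k < 3; ++k) d[k] = pA[k] - ppar[k];
      double wxz[3];
      cross(wpar, z, wxz);
      for (int k = 0; k < 3; ++k) {
        ww(k, i) = wpar[k] + z[k] * qd[i];
        aw(k, i) = apar[k] + z[k] * qdd[i] + wxz[k] * qd[i];
      }
      cross(wpar, d, wxd);
      cross(apar, d, axd);
      cross(wpar, wxd, wxwxd);
      for (int k = 0; k < 3; ++k) {
        vw(k, i) = vpar[k] + wxd[k];
        lw(k, i) = lpar[k] + axd[k] + wxwxd[k];
      }
    } else {
      for (int k = 0; k < 9; ++k) Rw(k, i) = Ra[k];
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k] + z[k] * q[i];
      for (int k = 0; k < 3; ++k) d[k] = pw(k, i) - ppar[k];
      for (int k = 0; k < 3; ++k) { ww(k, i) = wpar[k]; aw(k, i) = apar[k]; }
      cross(wpar, d, wxd);
      cross(apar, d, axd);
      cross(wpar, wxd, wxwxd);
      double wxz[3];
      cross(wpar, z, wxz);
      for (int k = 0; k < 3; ++k) {
        vw(k, i) = vpar[k] + wxd[k] + z[k] * qd[i];
        lw(k, i) = lpar[k] + axd[k] + wxwxd[k] + 2.0 * wxz[k] * qd[i] +
                   z[k] * qdd[i];
      }
    }
  }

  // ---- accumulate external wrenches per node ----
  std::vector<double> fext(3 * n, 0.0), next(3 * n, 0.0);
  for (int e = 0; e < ext_node.size(); ++e) {
    int nd = ext_node[e] - 1;
    if (nd < 0) continue;
    double papp[3], tmp[3];
    matvec(&Rw(0, nd), &ext_lp(0, e), tmp);
    for (int k = 0; k < 3; ++k) papp[k] = pw(k, nd) + tmp[k];
    double r[3], rxf[3];
    for (int k = 0; k < 3; ++k) r[k] = papp[k] - pw(k, nd);
    cross(r, &ext_f(0, e), rxf);
    for (int k = 0; k < 3; ++k) {
      fext[3 * nd + k] += ext_f(k, e);
      next[3 * nd + k] += rxf[k] + ext_t(k, e);
    }
  }

  // ---- backward pass (topological order guarantees parent < child) ----
  std::vector<double> facc(3 * n, 0.0), nacc(3 * n, 0.0);
  for (int i = n - 1; i >= 0; --i) {
    double r[3], Iw[9], RIt[9], tmp9[9];
    matvec(&Rw(0, i), &com(0, i), r);
    // Iw = R I R^T
    matmat(&Rw(0, i), &inertia(0, i), tmp9);
    // RIt = tmp9 * R^T  -> compute column by column of R^T
    for (int cj = 0; cj < 3; ++cj) {
      double col[3] = {(&Rw(0, i))[cj], (&Rw(0, i))[cj + 3],
                       (&Rw(0, i))[cj + 6]};
      matvec(tmp9, col, RIt + 3 * cj);
    }
    for (int k = 0; k < 9; ++k) Iw[k] = RIt[k];

    double axr[3], wxr[3], wxwxr[3];
    cross(&aw(0, i), r, axr);
    cross(&ww(0, i), r, wxr);
    cross(&ww(0, i), wxr, wxwxr);
    double acom[3];
    for (int k = 0; k < 3; ++k) acom[k] = lw(k, i) + axr[k] + wxwxr[k];
    for (int k = 0; k < 3; ++k) ac(k, i) = acom[k];

    double Fi[3];
    for (int k = 0; k < 3; ++k) Fi[k] = mass[i] * acom[k];
    double Iww[3], Iwa[3], wxIww[3];
    matvec(Iw, &ww(0, i), Iww);
    matvec(Iw, &aw(0, i), Iwa);
    cross(&ww(0, i), Iww, wxIww);
    double Ni[3];
    for (int k = 0; k < 3; ++k) Ni[k] = Iwa[k] + wxIww[k];

    double rxF[3];
    cross(r, Fi, rxF);
    double f[3], nn[3];
    for (int k = 0; k < 3; ++k) {
      f[k] = Fi[k] + facc[3 * i + k] - fext[3 * i + k];
      nn[k] = Ni[k] + rxF[k] + nacc[3 * i + k] - next[3 * i + k];
    }
    for (int k = 0; k < 3; ++k) { fj(k, i) = f[k]; nj(k, i) = nn[k]; }
    tau[i] = is_rot[i]
                 ? zw(0, i) * nn[0] + zw(1, i) * nn[1] + zw(2, i) * nn[2]
                 : zw(0, i) * f[0] + zw(1, i) * f[1] + zw(2, i) * f[2];

    int pa = parent[i] - 1;
    if (pa >= 0) {
      double d[3], dxf[3];
      for (int k = 0; k < 3; ++k) d[k] = pw(k, i) - pw(k, pa);
      cross(d, f, dxf);
      for (int k = 0; k < 3; ++k) {
        facc[3 * pa + k] += f[k];
        nacc[3 * pa + k] += nn[k] + dxf[k];
      }
    }
  }

  if (want_kinematics) {
    return List::create(_["tau"] = tau, _["fjoint"] = fj, _["njoint"] = nj,
                        _["acom"] = ac, _["node_p"] = pw, _["node_R"] = Rw,
                        _["node_z"] = zw, _["node_w"] = ww,
                        _["node_v"] = vw, _["node_alpha"] = aw,
                        _["node_a"] = lw);
  }
  return List::create(_["tau"] = tau, _["fjoint"] = fj, _["njoint"] = nj,
                      _["acom"] = ac);
}

// Forward kinematics only: node rotations (9 x n), origins and world axes.
// [[Rcpp::export]]
List fk_cpp(IntegerVector parent, IntegerVector is_rot, NumericMatrix Rpre,
            NumericMatrix tpre, NumericMatrix axis, NumericVector q) {
  const int n = parent.size();
  NumericMatrix Rw(9, n), pw(3, n), zw(3, n);
  for (int i = 0; i < n; ++i) {
    int pa = parent[i] - 1;
    double Rpar_id[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    const double* Rpar = pa >= 0 ? &Rw(0, pa) : Rpar_id;
    double zero3[3] = {0, 0, 0};
    const double* ppar = pa >= 0 ? &pw(0, pa) : zero3;
    double Ra[9], pA[3], z[3], tmp[3];
    matmat(Rpar, &Rpre(0, i), Ra);
    matvec(Rpar, &tpre(0, i), tmp);
    for (int k = 0; k < 3; ++k) pA[k] = ppar[k] + tmp[k];
    matvec(Ra, &axis(0, i), z);
    for (int k = 0; k < 3; ++k) zw(k, i) = z[k];
    if (is_rot[i]) {
      double Rj[9];
      axis_rot(&axis(0, i), q[i], Rj);
      matmat(Ra, Rj, &Rw(0, i));
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k];
    } else {
      for (int k = 0; k < 9; ++k) Rw(k, i) = Ra[k];
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k] + z[k] * q[i];
    }
  }
  return List::create(_["node_R"] = Rw, _["node_p"] = pw, _["node_z"] = zw);
}

// Musculotendon lengths, rigid-tendon Hill tensions (zero fiber velocity)
// and the generalized forces of all muscle path forces, in one pass.
// Points are given as (node anchor, local-in-node-frame position); hill =
// (fl_width, fp_kpe, fp_e0, l_opt..) constants vector.
// [[Rcpp::export]]
List muscle_q_cpp(IntegerVector parent, IntegerVector is_rot,
                  NumericMatrix Rpre, NumericMatrix tpre, NumericMatrix axis,
                  NumericVector q,
                  IntegerVector pt_node, NumericMatrix pt_local,
                  IntegerVector mu_ptr,  // 1-based start index per muscle, length nmu+1
                  NumericVector f_max, NumericVector l_opt,
                  NumericVector l_slack, NumericVector penn,
                  NumericVector act, NumericVector hill) {
  const int n = parent.size();
  const int nmu = f_max.size();
  // forward kinematics
  NumericMatrix Rw(9, n), pw(3, n), zw(3, n);
  for (int i = 0; i < n; ++i) {
    int pa = parent[i] - 1;
    double Rpar_id[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
    const double* Rpar = pa >= 0 ? &Rw(0, pa) : Rpar_id;
    double zero3[3] = {0, 0, 0};
    const double* ppar = pa >= 0 ? &pw(0, pa) : zero3;
    double Ra[9], pA[3], z[3], tmp[3];
    matmat(Rpar, &Rpre(0, i), Ra);
    matvec(Rpar, &tpre(0, i), tmp);
    for (int k = 0; k < 3; ++k) pA[k] = ppar[k] + tmp[k];
    matvec(Ra, &axis(0, i), z);
    for (int k = 0; k < 3; ++k) zw(k, i) = z[k];
    if (is_rot[i]) {
      double Rj[9];
      axis_rot(&axis(0, i), q[i], Rj);
      matmat(Ra, Rj, &Rw(0, i));
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k];
    } else {
      for (int k = 0; k < 9; ++k) Rw(k, i) = Ra[k];
      for (int k = 0; k < 3; ++k) pw(k, i) = pA[k] + z[k] * q[i];
    }
  }
  // world positions of path points
  const int npts = pt_node.size();
  std::vector<double> P(3 * npts);
  for (int p = 0; p < npts; ++p) {
    int nd = pt_node[p] - 1;
    if (nd < 0) {
      for (int k = 0; k < 3; ++k) P[3 * p + k] = pt_local(k, p);
    } else {
      double tmp[3];
      matvec(&Rw(0, nd), &pt_local(0, p), tmp);
      for (int k = 0; k < 3; ++k) P[3 * p + k] = pw(k, nd) + tmp[k];
    }
  }
  const double fl_width = hill[0], fp_kpe = hill[1], fp_e0 = hill[2];
  NumericVector Q(n), tension(nmu), lmt(nmu);
  for (int m = 0; m < nmu; ++m) {
    int p0 = mu_ptr[m] - 1, p1 = mu_ptr[m + 1] - 1;  // [p0, p1)
    double L = 0.0;
    for (int p = p0; p + 1 < p1; ++p) {
      double d0 = P[3 * (p + 1)] - P[3 * p];
      double d1 = P[3 * (p + 1) + 1] - P[3 * p + 1];
      double d2 = P[3 * (p + 1) + 2] - P[3 * p + 2];
      L += std::sqrt(d0 * d0 + d1 * d1 + d2 * d2);
    }
    lmt[m] = L;
    // rigid tendon, constant-thickness pennation, zero fiber velocity
    double l_along = L - l_slack[m];
    if (l_along < 1e-6) l_along = 1e-6;
    double h = l_opt[m] * std::sin(penn[m]);
    double lf = std::sqrt(l_along * l_along + h * h);
    double cos_a = l_along / lf;
    if (cos_a < 1e-9) cos_a = 1e-9;
    double ln = lf / l_opt[m];
    double fl = std::exp(-((ln - 1) / fl_width) * ((ln - 1) / fl_width));
    double fp = ln <= 1 ? 0.0
                        : (std::exp(fp_kpe * (ln - 1) / fp_e0) - 1.0) /
                              (std::exp(fp_kpe) - 1.0);
    double f = f_max[m] * (act[m] * fl + fp) * cos_a;
    tension[m] = f;
    if (f == 0.0) continue;
    for (int p = p0; p + 1 < p1; ++p) {
      double u[3] = {P[3 * (p + 1)] - P[3 * p],
                     P[3 * (p + 1) + 1] - P[3 * p + 1],
                     P[3 * (p + 1) + 2] - P[3 * p + 2]};
      double len = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (len < 1e-12) continue;
      for (int k = 0; k < 3; ++k) u[k] = f * u[k] / len;
      // +u at point p (its node chain), -u at point p+1
      for (int which = 0; which < 2; ++which) {
        int pp = which == 0 ? p : p + 1;
        double F[3] = {u[0], u[1], u[2]};
        if (which == 1) { F[0] = -F[0]; F[1] = -F[1]; F[2] = -F[2]; }
        int nd = pt_node[pp] - 1;
        const double* papp = &P[3 * pp];
        while (nd >= 0) {
          if (is_rot[nd]) {
            double r[3] = {papp[0] - pw(0, nd), papp[1] - pw(1, nd),
                           papp[2] - pw(2, nd)};
            double rxF[3];
            cross(r, F, rxF);
            Q[nd] += zw(0, nd) * rxF[0] + zw(1, nd) * rxF[1] +
                     zw(2, nd) * rxF[2];
          } else {
            Q[nd] += zw(0, nd) * F[0] + zw(1, nd) * F[1] + zw(2, nd) * F[2];
          }
          nd = parent[nd] - 1;
        }
      }
    }
  }
  return List::create(_["Q"] = Q, _["tension"] = tension, _["l_mt"] = lmt);
}
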