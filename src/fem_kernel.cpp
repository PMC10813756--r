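#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Constant-strain T4 kernel.
//
// Voigt convention throughout: strain = (e11, e22, e33, g12, g13, g23) with
// engineering shears g_ij = 2 e_ij; stress = (s11, s22, s33, s12, s13, s23).
// Plastic strain is stored in the same engineering convention so that
// sigma = D_e (eps - eps_p) holds componentwise.

// [[Rcpp::export]]
List tet_precompute_cpp(NumericMatrix nodes, IntegerMatrix tets) {
  const int m = tets.nrow();
  NumericMatrix grad(m, 12);   // gx1,gy1,gz1, gx2,... per element
  NumericVector vol(m);

  for (int e = 0; e < m; ++e) {
    int a = tets(e, 0) - 1, b = tets(e, 1) - 1,
        c = tets(e, 2) - 1, d = tets(e, 3) - 1;
    double J[3][3];
    for (int k = 0; k < 3; ++k) {
      J[k][0] = nodes(b, k) - nodes(a, k);
      J[k][1] = nodes(c, k) - nodes(a, k);
      J[k][2] = nodes(d, k) - nodes(a, k);
    }
    double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1])
               - J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0])
               + J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
    if (det <= 0.0)
      stop("element %d has non-positive volume", e + 1);
    vol[e] = det / 6.0;
    double inv[3][3];
    inv[0][0] =  (J[1][1] * J[2][2] - J[1][2] * J[2][1]) / det;
    inv[0][1] = -(J[0][1] * J[2][2] - J[0][2] * J[2][1]) / det;
    inv[0][2] =  (J[0][1] * J[1][2] - J[0][2] * J[1][1]) / det;
    inv[1][0] = -(J[1][0] * J[2][2] - J[1][2] * J[2][0]) / det;
    inv[1][1] =  (J[0][0] * J[2][2] - J[0][2] * J[2][0]) / det;
    inv[1][2] = -(J[0][0] * J[1][2] - J[0][2] * J[1][0]) / det;
    inv[2][0] =  (J[1][0] * J[2][1] - J[1][1] * J[2][0]) / det;
    inv[2][1] = -(J[0][0] * J[2][1] - J[0][1] * J[2][0]) / det;
    inv[2][2] =  (J[0][0] * J[1][1] - J[0][1] * J[1][0]) / det;
    // grad N_{a+1} = row a of inv(J) for local nodes 2..4; node 1 closes sum
    for (int k = 0; k < 3; ++k) {
      grad(e, 3 + k)  = inv[0][k];
      grad(e, 6 + k)  = inv[1][k];
      grad(e, 9 + k)  = inv[2][k];
      grad(e, k) = -(inv[0][k] + inv[1][k] + inv[2][k]);
    }
  }
  return List::create(_["grad"] = grad, _["vol"] = vol);
}

static inline void build_B(const double *g, double B[6][12]) {
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 12; ++j) B[i][j] = 0.0;
  for (int a = 0; a < 4; ++a) {
    double gx = g[3 * a], gy = g[3 * a + 1], gz = g[3 * a + 2];
    int cx = 3 * a, cy = 3 * a + 1, cz = 3 * a + 2;
    B[0][cx] = gx;
    B[1][cy] = gy;
    B[2][cz] = gz;
    B[3][cx] = gy; B[3][cy] = gx;
    B[4][cx] = gz; B[4][cz] = gx;
    B[5][cy] = gz; B[5][cz] = gy;
  }
}

// One elastic-predictor / radial-return sweep over all elements.
// Returns internal force, per-element updated state, and (optionally) the
// element tangent stiffness entries in a fixed triplet order:
// element-major, 12x12 column-major.
// [[Rcpp::export]]
List fem_state_update_cpp(NumericMatrix grad, NumericVector vol,
                          IntegerMatrix tets, NumericVector u,
                          NumericVector E, NumericVector nu,
                          NumericVector sigy, NumericMatrix epsp,
                          bool want_tangent) {
  const int m = tets.nrow();
  const int ndof = u.size();
  NumericVector fint(ndof);
  NumericMatrix epsp_new(m, 6), stress(m, 6);
  NumericVector dpeeq(m), vm(m);
  NumericVector Kvals(want_tangent ? 144 * m : 0);

  double B[6][12], D[6][6], DB[6][12];

  for (int e = 0; e < m; ++e) {
    const double g[12] = {
      grad(e, 0), grad(e, 1), grad(e, 2),  grad(e, 3), grad(e, 4), grad(e, 5),
      grad(e, 6), grad(e, 7), grad(e, 8),  grad(e, 9), grad(e, 10), grad(e, 11)};
    int dof[12];
    for (int a = 0; a < 4; ++a) {
      int n0 = 3 * (tets(e, a) - 1);
      dof[3 * a] = n0; dof[3 * a + 1] = n0 + 1; dof[3 * a + 2] = n0 + 2;
    }
    double ue[12];
    for (int j = 0; j < 12; ++j) ue[j] = u[dof[j]];

    // total strain (engineering Voigt)
    double eps[6] = {0, 0, 0, 0, 0, 0};
    for (int a = 0; a < 4; ++a) {
      double gx = g[3 * a], gy = g[3 * a + 1], gz = g[3 * a + 2];
      double ux = ue[3 * a], uy = ue[3 * a + 1], uz = ue[3 * a + 2];
      eps[0] += gx * ux;
      eps[1] += gy * uy;
      eps[2] += gz * uz;
      eps[3] += gy * ux + gx * uy;
      eps[4] += gz * ux + gx * uz;
      eps[5] += gz * uy + gy * uz;
    }

    double Ee = E[e], nue = nu[e], sy = sigy[e];
    double mu = Ee / (2.0 * (1.0 + nue));
    double lam = Ee * nue / ((1.0 + nue) * (1.0 - 2.0 * nue));
    double kap = lam + 2.0 * mu / 3.0;

    // elastic trial stress
    double ee[6];
    for (int i = 0; i < 6; ++i) ee[i] = eps[i] - epsp(e, i);
    double tr = ee[0] + ee[1] + ee[2];
    double s[6];
    s[0] = lam * tr + 2.0 * mu * ee[0];
    s[1] = lam * tr + 2.0 * mu * ee[1];
    s[2] = lam * tr + 2.0 * mu * ee[2];
    s[3] = mu * ee[3];
    s[4] = mu * ee[4];
    s[5] = mu * ee[5];

    double p = (s[0] + s[1] + s[2]) / 3.0;
    double dv[6] = {s[0] - p, s[1] - p, s[2] - p, s[3], s[4], s[5]};
    double q = std::sqrt(1.5 * (dv[0] * dv[0] + dv[1] * dv[1] + dv[2] * dv[2])
                         + 3.0 * (dv[3] * dv[3] + dv[4] * dv[4] + dv[5] * dv[5]));

    bool plastic = q > sy;
    double beta = 1.0, dg = 0.0;
    if (plastic) {
      beta = sy / q;
      dg = (q - sy) / (3.0 * mu);
      // scaled return: deviator shrinks onto the yield surface
      for (int i = 0; i < 3; ++i) s[i] = p + beta * dv[i];
      for (int i = 3; i < 6; ++i) s[i] = beta * dv[i];
      // plastic flow: d eps_p = dg * n, n = (3/2) dev/q (tensor components)
      double f = dg * 1.5 / q;
      epsp_new(e, 0) = epsp(e, 0) + f * dv[0];
      epsp_new(e, 1) = epsp(e, 1) + f * dv[1];
      epsp_new(e, 2) = epsp(e, 2) + f * dv[2];
      epsp_new(e, 3) = epsp(e, 3) + 2.0 * f * dv[3];
      epsp_new(e, 4) = epsp(e, 4) + 2.0 * f * dv[4];
      epsp_new(e, 5) = epsp(e, 5) + 2.0 * f * dv[5];
    } else {
      for (int i = 0; i < 6; ++i) epsp_new(e, i) = epsp(e, i);
    }
    dpeeq[e] = dg;
    for (int i = 0; i < 6; ++i) stress(e, i) = s[i];
    vm[e] = plastic ? sy : q;

    double V = vol[e];
    for (int a = 0; a < 4; ++a) {
      double gx = g[3 * a], gy = g[3 * a + 1], gz = g[3 * a + 2];
      fint[dof[3 * a]]     += V * (gx * s[0] + gy * s[3] + gz * s[4]);
      fint[dof[3 * a + 1]] += V * (gy * s[1] + gx * s[3] + gz * s[5]);
      fint[dof[3 * a + 2]] += V * (gz * s[2] + gx * s[4] + gy * s[5]);
    }

    if (want_tangent) {
      // consistent tangent; for perfect plasticity
      // D = kap J + 2 mu beta (I_dev) - 2 mu beta nhat nhat^T
      // with nhat = dev_trial / ||dev_trial|| (tensor norm)
      double tmu = plastic ? mu * beta : mu;
      for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 6; ++j) D[i][j] = 0.0;
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          D[i][j] = kap - 2.0 * tmu / 3.0;
      for (int i = 0; i < 3; ++i) D[i][i] += 2.0 * tmu;
      for (int i = 3; i < 6; ++i) D[i][i] = tmu;
      if (plastic) {
        double nrm = std::sqrt(2.0 / 3.0) * q;  // ||dev_trial||
        double nh[6];
        for (int i = 0; i < 6; ++i) nh[i] = dv[i] / nrm;
        for (int i = 0; i < 6; ++i)
          for (int j = 0; j < 6; ++j)
            D[i][j] -= 2.0 * mu * beta * nh[i] * nh[j];
      }
      build_B(g, B);
      for (int i = 0; i < 6; ++i)
        for (int j = 0; j < 12; ++j) {
          double acc = 0.0;
          for (int k = 0; k < 6; ++k) acc += D[i][k] * B[k][j];
          DB[i][j] = acc;
        }
      double *Ke = &Kvals[144 * e];
      for (int j = 0; j < 12; ++j)        // column-major 12x12
        for (int i = 0; i < 12; ++i) {
          double acc = 0.0;
          for (int k = 0; k < 6; ++k) acc += B[k][i] * DB[k][j];
          Ke[12 * j + i] = V * acc;
        }
    }
  }

  List out = List::create(_["fint"] = fint, _["epsp"] = epsp_new,
                          _["dpeeq"] = dpeeq, _["stress"] = stress,
                          _["vm"] = vm);
  if (want_tangent) out["Kvals"] = Kvals;
  return out;
}

// Scatter triplet values into pre-matched CSC slots (1-based map).
// [[Rcpp::export]]
NumericVector accumulate_slots_cpp(IntegerVector map, NumericVector vals,
                                   int nnz) {
  NumericVector x(nnz);
  const int n = map.size();
  for (int k = 0; k < n; ++k) x[map[k] - 1] += vals[k];
  return x;
}
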