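#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear 8-node hexahedron, compressible Neo-Hookean strain energy
//   W(F) = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2
// integrated with 2x2x2 Gauss quadrature.  Element node ordering follows
// the VTK hexahedron convention; element DOFs are node-major (x,y,z).

static const double XI[8][3] = {
  {-1,-1,-1},{ 1,-1,-1},{ 1, 1,-1},{-1, 1,-1},
  {-1,-1, 1},{ 1,-1, 1},{ 1, 1, 1},{-1, 1, 1}
};

static bool inv3(const double A[3][3], double Ainv[3][3], double &det) {
  det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
      - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
      + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  if (det == 0.0) return false;
  double id = 1.0/det;
  Ainv[0][0] =  (A[1][1]*A[2][2]-A[1][2]*A[2][1])*id;
  Ainv[0][1] = -(A[0][1]*A[2][2]-A[0][2]*A[2][1])*id;
  Ainv[0][2] =  (A[0][1]*A[1][2]-A[0][2]*A[1][1])*id;
  Ainv[1][0] = -(A[1][0]*A[2][2]-A[1][2]*A[2][0])*id;
  Ainv[1][1] =  (A[0][0]*A[2][2]-A[0][2]*A[2][0])*id;
  Ainv[1][2] = -(A[0][0]*A[1][2]-A[0][2]*A[1][0])*id;
  Ainv[2][0] =  (A[1][0]*A[2][1]-A[1][1]*A[2][0])*id;
  Ainv[2][1] = -(A[0][0]*A[2][1]-A[0][1]*A[2][0])*id;
  Ainv[2][2] =  (A[0][0]*A[1][1]-A[0][1]*A[1][0])*id;
  return true;
}

// One element at one state.  X, u are 8x3 (rows = local nodes).
// Returns energy; fills force (24) and K (24x24) when the pointers are
// non-null.  Sets *inverted when det F <= 0 at any quadrature point.
static double hex_efk(const double X[8][3], const double u[8][3],
                      double mu, double lambda,
                      double *force, double *K, bool *inverted) {
  const double g = 1.0 / std::sqrt(3.0);
  double energy = 0.0;
  *inverted = false;
  for (int gp = 0; gp < 8; ++gp) {
    const double xi = g*XI[gp][0], eta = g*XI[gp][1], zeta = g*XI[gp][2];
    double dNdxi[8][3];
    for (int a = 0; a < 8; ++a) {
      dNdxi[a][0] = 0.125*XI[a][0]*(1+eta*XI[a][1])*(1+zeta*XI[a][2]);
      dNdxi[a][1] = 0.125*XI[a][1]*(1+xi *XI[a][0])*(1+zeta*XI[a][2]);
      dNdxi[a][2] = 0.125*XI[a][2]*(1+xi *XI[a][0])*(1+eta *XI[a][1]);
    }
    // reference Jacobian J0 = dX/dxi
    double J0[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          J0[i][j] += X[a][i] * dNdxi[a][j];
    double J0inv[3][3], detJ0;
    if (!inv3(J0, J0inv, detJ0) || detJ0 <= 0) { *inverted = true; return NA_REAL; }
    // material shape gradients gA = dN/dX
    double gA[8][3];
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j)
        gA[a][j] = dNdxi[a][0]*J0inv[0][j] + dNdxi[a][1]*J0inv[1][j] + dNdxi[a][2]*J0inv[2][j];
    // deformation gradient F = I + sum_a u_a (x) gA_a
    double Fm[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          Fm[i][j] += u[a][i] * gA[a][j];
    double Finv[3][3], detF;
    if (!inv3(Fm, Finv, detF) || detF <= 0) { *inverted = true; return NA_REAL; }
    const double lnJ = std::log(detF);
    double I1 = 0;
    for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) I1 += Fm[i][j]*Fm[i][j];
    const double w = detJ0;  // unit Gauss weights
    energy += w * (0.5*mu*(I1 - 3.0) - mu*lnJ + 0.5*lambda*lnJ*lnJ);
    if (force || K) {
      // G = F^{-T};  P = mu (F - G) + lambda lnJ G
      double G[3][3];
      for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) G[i][j] = Finv[j][i];
      double P[3][3];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          P[i][j] = mu*(Fm[i][j] - G[i][j]) + lambda*lnJ*G[i][j];
      double ga[8][3];  // ga_a = G * gA_a (spatial gradients)
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          ga[a][i] = G[i][0]*gA[a][0] + G[i][1]*gA[a][1] + G[i][2]*gA[a][2];
      if (force) {
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            force[3*a+i] += w * (P[i][0]*gA[a][0] + P[i][1]*gA[a][1] + P[i][2]*gA[a][2]);
      }
      if (K) {
        const double c2 = mu - lambda*lnJ;
        for (int a = 0; a < 8; ++a)
          for (int b = 0; b < 8; ++b) {
            const double gg = gA[a][0]*gA[b][0] + gA[a][1]*gA[b][1] + gA[a][2]*gA[b][2];
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j) {
                double kij = lambda*ga[a][i]*ga[b][j] + c2*ga[b][i]*ga[a][j];
                if (i == j) kij += mu*gg;
                K[(3*a+i) + 24*(3*b+j)] += w * kij;
              }
          }
      }
    }
  }
  return energy;
}

// Single-element energy/force/stiffness (test and inspection entry point).
// X, u: 8x3 matrices of rest positions and displacements.
// [[Rcpp::export]]
List cpp_hex_efk(NumericMatrix X, NumericMatrix u, double mu, double lambda) {
  double Xl[8][3], ul[8][3];
  for (int a = 0; a < 8; ++a)
    for (int k = 0; k < 3; ++k) { Xl[a][k] = X(a,k); ul[a][k] = u(a,k); }
  NumericVector force(24);
  NumericMatrix K(24, 24);
  bool inverted = false;
  double e = hex_efk(Xl, ul, mu, lambda, REAL(force), REAL(K), &inverted);
  return List::create(_["energy"] = e, _["force"] = force, _["K"] = K,
                      _["inverted"] = inverted);
}

// Global assembly over all elements.  nodes: Nx3 rest positions, hexes:
// Mx8 1-based node indices, u: length-3N displacement vector (node-major).
// want = 0: energy only; 1: + gradient; 2: + stiffness triplets.
// [[Rcpp::export]]
List cpp_assemble(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u,
                  double mu, double lambda, int want) {
  const int ne = hexes.nrow(), nn = nodes.nrow();
  double energy = 0.0;
  bool any_inverted = false;
  NumericVector grad(want >= 1 ? 3*nn : 0);
  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (want >= 2) { ti.reserve(ne*576); tj.reserve(ne*576); tv.reserve(ne*576); }
  double Kbuf[576], fbuf[24];
  for (int e = 0; e < ne; ++e) {
    double X[8][3], ul[8][3];
    int idx[8];
    for (int a = 0; a < 8; ++a) {
      idx[a] = hexes(e,a) - 1;
      for (int k = 0; k < 3; ++k) {
        X[a][k] = nodes(idx[a], k);
        ul[a][k] = u[3*idx[a] + k];
      }
    }
    bool inverted = false;
    if (want >= 2) std::fill(Kbuf, Kbuf+576, 0.0);
    if (want >= 1) std::fill(fbuf, fbuf+24, 0.0);
    double ee = hex_efk(X, ul, mu, lambda,
                        want >= 1 ? fbuf : (double*)0,
                        want >= 2 ? Kbuf : (double*)0, &inverted);
    if (inverted) { any_inverted = true; break; }
    energy += ee;
    if (want >= 1)
      for (int a = 0; a < 8; ++a)
        for (int k = 0; k < 3; ++k)
          grad[3*idx[a] + k] += fbuf[3*a + k];
    if (want >= 2)
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              double v = Kbuf[(3*a+i) + 24*(3*b+j)];
              if (v != 0.0) {
                ti.push_back(3*idx[a] + i + 1);
                tj.push_back(3*idx[b] + j + 1);
                tv.push_back(v);
              }
            }
  }
  if (any_inverted)
    return List::create(_["inverted"] = true);
  List out = List::create(_["inverted"] = false, _["energy"] = energy);
  if (want >= 1) out["grad"] = grad;
  if (want >= 2) {
    out["ki"] = wrap(ti);
    out["kj"] = wrap(tj);
    out["kv"] = wrap(tv);
  }
  return out;
}

// Assembly with a fixed element-slot ordering: returns all ne*576 stiffness
// entries (zeros included) so the sparse pattern can be precomputed once on
// the R side and values scattered into the cached CSC structure.
// [[Rcpp::export]]
List cpp_assemble_slots(NumericMatrix nodes, IntegerMatrix hexes, NumericVector u,
                        double mu, double lambda) {
  const int ne = hexes.nrow(), nn = nodes.nrow();
  double energy = 0.0;
  NumericVector grad(3*nn);
  NumericVector kv((size_t)ne * 576);
  double Kbuf[576], fbuf[24];
  double *pkv = REAL(kv);
  const double *pn = REAL(nodes);
  const int *ph = INTEGER(hexes);
  const double *pu = REAL(u);
  for (int e = 0; e < ne; ++e) {
    double X[8][3], ul[8][3];
    int idx[8];
    for (int a = 0; a < 8; ++a) {
      idx[a] = ph[e + (size_t)ne*a] - 1;
      for (int k = 0; k < 3; ++k) {
        X[a][k] = pn[idx[a] + (size_t)nn*k];
        ul[a][k] = pu[3*idx[a] + k];
      }
    }
    bool inverted = false;
    std::fill(Kbuf, Kbuf+576, 0.0);
    std::fill(fbuf, fbuf+24, 0.0);
    double ee = hex_efk(X, ul, mu, lambda, fbuf, Kbuf, &inverted);
    if (inverted) return List::create(_["inverted"] = true);
    energy += ee;
    for (int a = 0; a < 8; ++a)
      for (int k = 0; k < 3; ++k)
        grad[3*idx[a] + k] += fbuf[3*a + k];
    double *slot = pkv + (size_t)e * 576;
    for (int a = 0; a < 8; ++a)
      for (int b = 0; b < 8; ++b)
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            slot[((a*8 + b)*3 + i)*3 + j] = Kbuf[(3*a+i) + 24*(3*b+j)];
  }
  return List::create(_["inverted"] = false, _["energy"] = energy,
                      _["grad"] = grad, _["kv"] = kv);
}

// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector values, IntegerVector map, int n) {
  NumericVector out(n);
  double *po = REAL(out);
  const double *pv = REAL(values);
  const int *pm = INTEGER(map);
  for (R_xlen_t t = 0; t < values.size(); ++t) po[pm[t] - 1] += pv[t];
  return out;
}
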