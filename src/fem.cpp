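// Geometrically nonlinear FEM kernels: total-Lagrangian 4-node tetrahedra
// with a compressible Neo-Hookean law
//   W = mu/2 (I1 - 3) - mu ln J + lambda/2 (ln J)^2
// and follower (deformed-normal) pressure loads on boundary triangles.
// Units: coordinates in micrometres, moduli/stresses in Pa; nodal forces
// then come out in Pa*um^2 (piconewtons), consistent throughout.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double det3(const double A[3][3]) {
  return A[0][0] * (A[1][1] * A[2][2] - A[1][2] * A[2][1])
       - A[0][1] * (A[1][0] * A[2][2] - A[1][2] * A[2][0])
       + A[0][2] * (A[1][0] * A[2][1] - A[1][1] * A[2][0]);
}

static inline void inv3(const double A[3][3], double d, double Ai[3][3]) {
  double id = 1.0 / d;
  Ai[0][0] =  (A[1][1] * A[2][2] - A[1][2] * A[2][1]) * id;
  Ai[0][1] = -(A[0][1] * A[2][2] - A[0][2] * A[2][1]) * id;
  Ai[0][2] =  (A[0][1] * A[1][2] - A[0][2] * A[1][1]) * id;
  Ai[1][0] = -(A[1][0] * A[2][2] - A[1][2] * A[2][0]) * id;
  Ai[1][1] =  (A[0][0] * A[2][2] - A[0][2] * A[2][0]) * id;
  Ai[1][2] = -(A[0][0] * A[1][2] - A[0][2] * A[1][0]) * id;
  Ai[2][0] =  (A[1][0] * A[2][1] - A[1][1] * A[2][0]) * id;
  Ai[2][1] = -(A[0][0] * A[2][1] - A[0][1] * A[2][0]) * id;
  Ai[2][2] =  (A[0][0] * A[1][1] - A[0][1] * A[1][0]) * id;
}

// Assemble internal forces, consistent tangent (triplets), and per-element
// Cauchy stress for the current displacement state u (length 3N, xyz blocked
// per node). tets are 0-based. Returns ok = FALSE with the offending element
// if an element has J <= 0 (caller halves the load step).
// [[Rcpp::export]]
List cpp_tet4_assemble(const NumericMatrix& X0, const IntegerMatrix& tets,
                       const NumericVector& u, double mu, double lambda,
                       bool want_tangent) {
  const int N = X0.nrow(), M = tets.nrow();
  NumericVector fint(3 * N);
  NumericMatrix sigma(M, 6);    // xx yy zz xy xz yz
  NumericVector Jout(M), vcur(M), vref(M);

  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (want_tangent) {
    Ki = IntegerVector(144 * M);
    Kj = IntegerVector(144 * M);
    Kx = NumericVector(144 * M);
  }

  for (int e = 0; e < M; ++e) {
    int n[4] = { tets(e, 0), tets(e, 1), tets(e, 2), tets(e, 3) };
    double D[3][3];
    for (int c = 0; c < 3; ++c)
      for (int i = 0; i < 3; ++i)
        D[i][c] = X0(n[c + 1], i) - X0(n[0], i);
    double dD = det3(D);
    if (dD <= 0.0)
      return List::create(_["ok"] = false, _["bad"] = e + 1,
                          _["why"] = "reference element inverted");
    double V0 = dD / 6.0;
    double Di[3][3];
    inv3(D, dD, Di);
    // shape gradients G[a][j], a = 0..3
    double G[4][3];
    for (int a = 1; a <= 3; ++a)
      for (int j = 0; j < 3; ++j) G[a][j] = Di[a - 1][j];
    for (int j = 0; j < 3; ++j)
      G[0][j] = -(G[1][j] + G[2][j] + G[3][j]);

    double F[3][3] = { {1, 0, 0}, {0, 1, 0}, {0, 0, 1} };
    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          F[i][j] += u[3 * n[a] + i] * G[a][j];
    double J = det3(F);
    if (J <= 0.0)
      return List::create(_["ok"] = false, _["bad"] = e + 1,
                          _["why"] = "element inverted (J <= 0)");
    double Fi[3][3];
    inv3(F, J, Fi);
    double lnJ = std::log(J);

    // first Piola-Kirchhoff: P = mu F + (lambda lnJ - mu) F^{-T}
    double P[3][3];
    for (int i = 0; i < 3; ++i)
      for (int Jj = 0; Jj < 3; ++Jj)
        P[i][Jj] = mu * F[i][Jj] + (lambda * lnJ - mu) * Fi[Jj][i];

    for (int a = 0; a < 4; ++a)
      for (int i = 0; i < 3; ++i) {
        double s = 0;
        for (int Jj = 0; Jj < 3; ++Jj) s += P[i][Jj] * G[a][Jj];
        fint[3 * n[a] + i] += V0 * s;
      }

    // Cauchy sigma = (mu (B - I) + lambda lnJ I)/J
    double B[3][3];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int k = 0; k < 3; ++k) s += F[i][k] * F[j][k];
        B[i][j] = s;
      }
    double iJ = 1.0 / J;
    sigma(e, 0) = (mu * (B[0][0] - 1) + lambda * lnJ) * iJ;
    sigma(e, 1) = (mu * (B[1][1] - 1) + lambda * lnJ) * iJ;
    sigma(e, 2) = (mu * (B[2][2] - 1) + lambda * lnJ) * iJ;
    sigma(e, 3) = mu * B[0][1] * iJ;
    sigma(e, 4) = mu * B[0][2] * iJ;
    sigma(e, 5) = mu * B[1][2] * iJ;
    Jout[e] = J;
    vref[e] = V0;
    vcur[e] = J * V0;

    if (want_tangent) {
      // FtG[a][i] = (F^{-T} G_a)_i
      double FtG[4][3];
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0;
          for (int Jj = 0; Jj < 3; ++Jj) s += Fi[Jj][i] * G[a][Jj];
          FtG[a][i] = s;
        }
      double c1 = mu, c2 = lambda, c3 = mu - lambda * lnJ;
      int base = 144 * e, q = 0;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double gab = G[a][0] * G[b][0] + G[a][1] * G[b][1] + G[a][2] * G[b][2];
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              double k = c2 * FtG[a][i] * FtG[b][j]
                       + c3 * FtG[b][i] * FtG[a][j];
              if (i == j) k += c1 * gab;
              Ki[base + q] = 3 * n[a] + i + 1;   // 1-based for R
              Kj[base + q] = 3 * n[b] + j + 1;
              Kx[base + q] = V0 * k;
              ++q;
            }
        }
    }
  }
  List out = List::create(_["ok"] = true, _["fint"] = fint, _["sigma"] = sigma,
                          _["J"] = Jout, _["vcur"] = vcur, _["vref"] = vref);
  if (want_tangent) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx;
  }
  return out;
}

// Follower pressure on boundary triangles (outward winding): consistent
// nodal forces -p * (e1 x e2)/6 on each face node in the *current*
// configuration, plus the load-stiffness triplets d f_ext / d u.
// pmag is the per-face pressure magnitude (positive = compressive).
// [[Rcpp::export]]
List cpp_follower_pressure(const NumericMatrix& X0, const IntegerMatrix& faces,
                           const NumericVector& pmag, const NumericVector& u,
                           bool want_tangent) {
  const int N = X0.nrow(), F = faces.nrow();
  NumericVector fext(3 * N);
  IntegerVector Ki, Kj;
  NumericVector Kx;
  if (want_tangent) {
    Ki = IntegerVector(81 * F);
    Kj = IntegerVector(81 * F);
    Kx = NumericVector(81 * F);
  }
  for (int f = 0; f < F; ++f) {
    int n[3] = { faces(f, 0), faces(f, 1), faces(f, 2) };
    double x[3][3];
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        x[a][i] = X0(n[a], i) + u[3 * n[a] + i];
    double e1[3], e2[3];
    for (int i = 0; i < 3; ++i) {
      e1[i] = x[1][i] - x[0][i];
      e2[i] = x[2][i] - x[0][i];
    }
    double c[3] = { e1[1] * e2[2] - e1[2] * e2[1],
                    e1[2] * e2[0] - e1[0] * e2[2],
                    e1[0] * e2[1] - e1[1] * e2[0] };
    double p6 = pmag[f] / 6.0;
    for (int a = 0; a < 3; ++a)
      for (int i = 0; i < 3; ++i)
        fext[3 * n[a] + i] -= p6 * c[i];

    if (want_tangent) {
      // skew matrices of e1, e2
      auto skew = [](const double v[3], double S[3][3]) {
        S[0][0] = 0;      S[0][1] = -v[2]; S[0][2] =  v[1];
        S[1][0] =  v[2];  S[1][1] = 0;     S[1][2] = -v[0];
        S[2][0] = -v[1];  S[2][1] =  v[0]; S[2][2] = 0;
      };
      double S1[3][3], S2[3][3], dc[3][3][3]; // dc[b][i][j] = d c_i / d x_b,j
      skew(e1, S1);
      skew(e2, S2);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          dc[0][i][j] = S2[i][j] - S1[i][j];
          dc[1][i][j] = -S2[i][j];
          dc[2][i][j] = S1[i][j];
        }
      int base = 81 * f, q = 0;
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b)
          for (int i = 0; i < 3; ++i)
            for (int j = 0; j < 3; ++j) {
              Ki[base + q] = 3 * n[a] + i + 1;
              Kj[base + q] = 3 * n[b] + j + 1;
              Kx[base + q] = -p6 * dc[b][i][j];   // d f_ext / d u
              ++q;
            }
    }
  }
  List out = List::create(_["fext"] = fext);
  if (want_tangent) {
    out["Ki"] = Ki; out["Kj"] = Kj; out["Kx"] = Kx;
  }
  return out;
}
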