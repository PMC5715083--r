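#include <Rcpp.h>
using namespace Rcpp;

// Khachiyan-style iterative reweighting with away steps for the
// minimum-area enclosing ellipse of planar points.
// Returns center (2), scatter S (2x2) with ellipse {x: (x-c)' (2S)^{-1} (x-c) <= 1},
// iterations, achieved eps.
// [[Rcpp::export]]
List mvee_khachiyan(NumericMatrix P, double tol, int maxit) {
  const int n = P.nrow();
  const double d = 2.0;
  std::vector<double> u(n, 1.0 / n), M(n);
  const double thr = tol * d / (d + 1.0);
  int it = 0;
  double ep = 0.0, em = 0.0;
  for (it = 1; it <= maxit; ++it) {
    // X = sum u_i q_i q_i', q = (x, y, 1); symmetric 3x3
    double a11=0,a12=0,a13=0,a22=0,a23=0,a33=0;
    for (int i = 0; i < n; ++i) {
      double w = u[i], x = P(i,0), y = P(i,1);
      a11 += w*x*x; a12 += w*x*y; a13 += w*x;
      a22 += w*y*y; a23 += w*y;  a33 += w;
    }
    // inverse of symmetric 3x3 via cofactors
    double c11 = a22*a33 - a23*a23;
    double c12 = a13*a23 - a12*a33;
    double c13 = a12*a23 - a13*a22;
    double c22 = a11*a33 - a13*a13;
    double c23 = a12*a13 - a11*a23;
    double c33 = a11*a22 - a12*a12;
    double det = a11*c11 + a12*c12 + a13*c13;
    if (det == 0.0 || !std::isfinite(det)) return List::create(_["ok"]=false);
    double i11=c11/det, i12=c12/det, i13=c13/det, i22=c22/det, i23=c23/det, i33=c33/det;
    int jp = 0, jm = -1;
    double Mmax = -1.0, Mmin = R_PosInf;
    for (int i = 0; i < n; ++i) {
      double x = P(i,0), y = P(i,1);
      double m = x*(i11*x + i12*y + i13) + y*(i12*x + i22*y + i23) + (i13*x + i23*y + i33);
      M[i] = m;
      if (m > Mmax) { Mmax = m; jp = i; }
      if (u[i] > 1e-10 && m < Mmin) { Mmin = m; jm = i; }
    }
    ep = Mmax / (d + 1.0) - 1.0;
    em = (jm >= 0) ? 1.0 - Mmin / (d + 1.0) : 0.0;
    if (ep <= thr && em <= thr) break;
    if (ep >= em) {
      double step = (Mmax - d - 1.0) / ((d + 1.0) * (Mmax - 1.0));
      for (int i = 0; i < n; ++i) u[i] *= (1.0 - step);
      u[jp] += step;
    } else {
      double step = (d + 1.0 - Mmin) / ((d + 1.0) * (Mmin - 1.0));
      double cap = u[jm] / (1.0 - u[jm]);
      if (step > cap) step = cap;
      for (int i = 0; i < n; ++i) u[i] *= (1.0 + step);
      u[jm] -= step;
      if (u[jm] < 0) u[jm] = 0;
    }
  }
  double cx=0, cy=0;
  for (int i = 0; i < n; ++i) { cx += u[i]*P(i,0); cy += u[i]*P(i,1); }
  double s11=0, s12=0, s22=0;
  for (int i = 0; i < n; ++i) {
    double dx = P(i,0)-cx, dy = P(i,1)-cy;
    s11 += u[i]*dx*dx; s12 += u[i]*dx*dy; s22 += u[i]*dy*dy;
  }
  NumericMatrix S(2,2);
  S(0,0)=s11; S(0,1)=s12; S(1,0)=s12; S(1,1)=s22;
  return List::create(_["ok"]=true, _["center"]=NumericVector::create(cx, cy),
                      _["S"]=S, _["iter"]=it, _["eps"]=std::max(ep, em));
}
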