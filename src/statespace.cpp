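#include <Rcpp.h>
using namespace Rcpp;

// Stride-by-stride forward recursions for the three candidate learning
// models. `pert` is the perturbation signal (1 while the belts are split,
// 0 once they are tied again) and `fb` flags strides on which the visual
// feedback is shown. States start at 0; the explicit state is memoryless:
// it is recomputed each stride from the previous error and zeroed the
// moment feedback goes off.

// [[Rcpp::export]]
NumericMatrix cpp_simulate_vc(NumericVector pert, LogicalVector fb,
                              double Afast, double Bfast,
                              double Aslow, double Bslow,
                              double Bexplicit) {
  int n = pert.size();
  NumericMatrix out(n, 6); // xfast, xslow, xexplicit, ximplicit, x, error
  double xf = 0.0, xs = 0.0, xe = 0.0;
  for (int s = 0; s < n; ++s) {
    double xi = xf + xs;
    double err = pert[s] - xi;
    out(s, 0) = xf;
    out(s, 1) = xs;
    out(s, 2) = xe;
    out(s, 3) = xi;
    out(s, 4) = xe + xi;
    out(s, 5) = err;
    double xf1 = Afast * xf + Bfast * err;
    double xs1 = Aslow * xs + Bslow * err;
    // gate on feedback at the stride where the output is expressed (s+1)
    double xe1 = (s + 1 < n && fb[s + 1]) ? Bexplicit * err : 0.0;
    xf = xf1; xs = xs1; xe = xe1;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_simulate_single(NumericVector pert, double A, double B) {
  int n = pert.size();
  NumericMatrix out(n, 2); // x, error
  double x = 0.0;
  for (int s = 0; s < n; ++s) {
    double err = pert[s] - x;
    out(s, 0) = x;
    out(s, 1) = err;
    x = A * x + B * err;
  }
  return out;
}

// Sum of squared errors between model output and observed AI on the
// retained strides (1-based indices into the raw stride grid). Keeping
// this in C++ makes the multi-restart fits and the recovery analysis fast.

// [[Rcpp::export]]
double cpp_sse_vc(NumericVector pert, LogicalVector fb,
                  double Afast, double Bfast, double Aslow, double Bslow,
                  double Bexplicit, IntegerVector idx, NumericVector obs) {
  int n = pert.size();
  double xf = 0.0, xs = 0.0, xe = 0.0, sse = 0.0;
  int j = 0, m = idx.size();
  for (int s = 0; s < n && j < m; ++s) {
    double xi = xf + xs;
    double err = pert[s] - xi;
    if (idx[j] == s + 1) {
      double r = obs[j] - (xe + xi);
      sse += r * r;
      ++j;
    }
    double xf1 = Afast * xf + Bfast * err;
    double xs1 = Aslow * xs + Bslow * err;
    double xe1 = (s + 1 < n && fb[s + 1]) ? Bexplicit * err : 0.0;
    xf = xf1; xs = xs1; xe = xe1;
  }
  return sse;
}

// [[Rcpp::export]]
double cpp_sse_single(NumericVector pert, double A, double B,
                      IntegerVector idx, NumericVector obs) {
  int n = pert.size();
  double x = 0.0, sse = 0.0;
  int j = 0, m = idx.size();
  for (int s = 0; s < n && j < m; ++s) {
    if (idx[j] == s + 1) {
      double r = obs[j] - x;
      sse += r * r;
      ++j;
    }
    x = A * x + B * (pert[s] - x);
  }
  return sse;
}
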