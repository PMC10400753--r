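// Exhaustive continuous piecewise-linear fit of a time-volume curve.
//
// Model: v(t) = a + s1*t + c1*(t-t1)_+ + c2*(t-t2)_+ + c3*(t-t3)_+ with knots
// t1 < t2 < t3 chosen among the sample times (restricted to a candidate index
// set). For each knot triple the 5-parameter least-squares problem is solved
// from suffix sums of {1, t, t^2, v, v*t}, so one candidate costs a 5x5 solve.
// Segment slopes are s1, s1+c1, s1+c1+c2, s1+c1+c2+c3 and must satisfy the
// cardiac-phase sign pattern: ejection < 0, filling > 0, and the two
// isovolumetric slopes below `isovol_ratio` times the smaller of the
// ejection/filling magnitudes (isovolumetric phases carry essentially no
// volume change, and an unconstrained plateau tilt biases the fitted
// EDV/ESV under noise). The feasible triple
// with minimal SSE wins; ties go to the earlier breakpoints because a new
// optimum must improve strictly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List plr_search_cpp(const arma::vec& t, const arma::vec& v,
                    const arma::ivec& candidates, int min_gap,
                    double isovol_ratio) {
  const int n = t.n_elem;
  // suffix sums over samples j..n-1
  arma::vec S0(n + 1, arma::fill::zeros), S1(n + 1, arma::fill::zeros),
      S2(n + 1, arma::fill::zeros), Sv(n + 1, arma::fill::zeros),
      Svt(n + 1, arma::fill::zeros);
  for (int j = n - 1; j >= 0; --j) {
    S0(j) = S0(j + 1) + 1.0;
    S1(j) = S1(j + 1) + t(j);
    S2(j) = S2(j + 1) + t(j) * t(j);
    Sv(j) = Sv(j + 1) + v(j);
    Svt(j) = Svt(j + 1) + v(j) * t(j);
  }
  const double yty = arma::dot(v, v);
  const double sum1 = S0(0), sumt = S1(0), sumt2 = S2(0);
  const double sumv = Sv(0), sumvt = Svt(0);

  // hinge-column cross products: column for knot k is (t - t(k))_+ which is
  // nonzero for samples j > k (sample times strictly increasing).
  // <h_a, h_b> with a<=b = sum_{j>b} (t_j - t_a)(t_j - t_b)
  //                       = S2 - (ta+tb) S1 + ta tb S0, suffixes from b+1.
  auto hdot = [&](int a, int b) {
    int s = std::max(a, b) + 1;
    double ta = t(a), tb = t(b);
    return S2(s) - (ta + tb) * S1(s) + ta * tb * S0(s);
  };
  auto hone = [&](int k) { // <h_k, 1>
    return S1(k + 1) - t(k) * S0(k + 1);
  };
  auto ht = [&](int k) { // <h_k, t>
    return S2(k + 1) - t(k) * S1(k + 1);
  };
  auto hv = [&](int k) { // <h_k, v>
    return Svt(k + 1) - t(k) * Sv(k + 1);
  };

  const int nc = candidates.n_elem;
  double best_sse = R_PosInf;
  int bi = -1, bj = -1, bk = -1;
  arma::vec best_beta(5, arma::fill::zeros);
  arma::mat A(5, 5);
  arma::vec b(5), beta(5);

  for (int ii = 0; ii < nc; ++ii) {
    int k1 = candidates(ii);
    if (k1 < min_gap) continue;
    for (int jj = ii + 1; jj < nc; ++jj) {
      int k2 = candidates(jj);
      if (k2 - k1 < min_gap) continue;
      for (int kk = jj + 1; kk < nc; ++kk) {
        int k3 = candidates(kk);
        if (k3 - k2 < min_gap || (n - 1) - k3 < min_gap - 1) continue;

        A(0, 0) = sum1;      A(0, 1) = sumt;
        A(0, 2) = hone(k1);  A(0, 3) = hone(k2); A(0, 4) = hone(k3);
        A(1, 1) = sumt2;
        A(1, 2) = ht(k1);    A(1, 3) = ht(k2);   A(1, 4) = ht(k3);
        A(2, 2) = hdot(k1, k1); A(2, 3) = hdot(k1, k2); A(2, 4) = hdot(k1, k3);
        A(3, 3) = hdot(k2, k2); A(3, 4) = hdot(k2, k3);
        A(4, 4) = hdot(k3, k3);
        for (int r = 1; r < 5; ++r)
          for (int c = 0; c < r; ++c) A(r, c) = A(c, r);
        b(0) = sumv; b(1) = sumvt;
        b(2) = hv(k1); b(3) = hv(k2); b(4) = hv(k3);

        bool ok = arma::solve(beta, A, b,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
        if (!ok) continue;

        double s1 = beta(1);
        double s2 = s1 + beta(2);
        double s3 = s2 + beta(3);
        double s4 = s3 + beta(4);
        if (!(s2 < 0.0 && s4 > 0.0)) continue;
        double cap = isovol_ratio * std::min(-s2, s4);
        if (std::abs(s1) >= cap || std::abs(s3) >= cap) continue;

        double sse = yty - arma::dot(beta, 2.0 * b - A * beta);
        if (sse < 0 && sse > -1e-8 * yty) sse = 0.0;
        if (sse < best_sse - 1e-12 * (1.0 + yty)) {
          best_sse = sse;
          bi = k1; bj = k2; bk = k3;
          best_beta = beta;
        }
      }
    }
  }

  return List::create(_["feasible"] = bi >= 0,
                      _["knots"] = IntegerVector::create(bi, bj, bk),
                      _["beta"] = best_beta, _["sse"] = best_sse);
}

// Flat-plateau variant: IVC and IVR are exactly isovolumetric (slope 0).
// Model: V = a1 on [t0,t1]; linear a1->a2 on [t1,t2]; a2 on [t2,t3];
// a2 + s4 (t - t3) after t3. Linear in (a1, d = a2 - a1, s4); constraints
// d < 0, s4 > 0.
// [[Rcpp::export]]
List plr_search_flat_cpp(const arma::vec& t, const arma::vec& v,
                         const arma::ivec& candidates, int min_gap) {
  const int n = t.n_elem;
  const int nc = candidates.n_elem;
  double best_sse = R_PosInf;
  int bi = -1, bj = -1, bk = -1;
  arma::vec best_beta(3, arma::fill::zeros);
  arma::mat A(3, 3);
  arma::vec b(3), beta(3), x2(n), x3(n);
  const double yty = arma::dot(v, v);

  for (int ii = 0; ii < nc; ++ii) {
    int k1 = candidates(ii);
    if (k1 < min_gap) continue;
    for (int jj = ii + 1; jj < nc; ++jj) {
      int k2 = candidates(jj);
      if (k2 - k1 < min_gap) continue;
      for (int kk = jj + 1; kk < nc; ++kk) {
        int k3 = candidates(kk);
        if (k3 - k2 < min_gap || (n - 1) - k3 < min_gap - 1) continue;
        double t1 = t(k1), t2 = t(k2), t3 = t(k3);
        double inv = 1.0 / (t2 - t1);
        for (int s = 0; s < n; ++s) {
          double u = (t(s) - t1) * inv;
          x2(s) = u < 0 ? 0.0 : (u > 1 ? 1.0 : u);
          x3(s) = t(s) > t3 ? t(s) - t3 : 0.0;
        }
        A(0, 0) = n;
        A(0, 1) = arma::accu(x2);
        A(0, 2) = arma::accu(x3);
        A(1, 1) = arma::dot(x2, x2);
        A(1, 2) = arma::dot(x2, x3);
        A(2, 2) = arma::dot(x3, x3);
        A(1, 0) = A(0, 1); A(2, 0) = A(0, 2); A(2, 1) = A(1, 2);
        b(0) = arma::accu(v);
        b(1) = arma::dot(x2, v);
        b(2) = arma::dot(x3, v);
        bool ok = arma::solve(beta, A, b,
                              arma::solve_opts::likely_sympd +
                              arma::solve_opts::no_approx);
        if (!ok) continue;
        if (!(beta(1) < 0.0 && beta(2) > 0.0)) continue;
        double sse = yty - arma::dot(beta, 2.0 * b - A * beta);
        if (sse < 0 && sse > -1e-8 * yty) sse = 0.0;
        if (sse < best_sse - 1e-12 * (1.0 + yty)) {
          best_sse = sse;
          bi = k1; bj = k2; bk = k3;
          best_beta = beta;
        }
      }
    }
  }
  return List::create(_["feasible"] = bi >= 0,
                      _["knots"] = IntegerVector::create(bi, bj, bk),
                      _["beta"] = best_beta, _["sse"] = best_sse);
}
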