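// Kabsch superposition and the TM-score maximization heuristic.
//
// TM-score of a model against a reference of length L:
//   TMS = max over superpositions of (1/L) sum_i 1 / (1 + (d_i/d0)^2)
// with d0 = 1.24 (L-15)^(1/3) - 1.8 clamped at >= 0.5 A.  The maximum is
// searched with the canonical deterministic heuristic: superpose on
// contiguous seed fragments of several lengths, then iteratively re-superpose
// on the residues closer than a cutoff until the included set is stable,
// keeping the best score seen.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// optimal proper rotation R and translation t with P*R + t ~= Q (rows = points)
static void kabsch_core(const arma::mat& P, const arma::mat& Q,
                        arma::mat33& R, arma::rowvec& t, double& rmsd) {
  arma::rowvec cp = arma::mean(P, 0), cq = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - cp, Qc = Q.each_row() - cq;
  arma::mat H = Pc.t() * Qc;           // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat33 D = arma::eye(3, 3);
  D(2, 2) = d;
  R = U * D * V.t();
  t = cq - cp * R;
  arma::mat E = Pc * R - Qc;
  rmsd = std::sqrt(arma::accu(E % E) / P.n_rows);
}

// [[Rcpp::export]]
List kabsch_cpp(const arma::mat& P, const arma::mat& Q) {
  if (P.n_rows < 3 || P.n_rows != Q.n_rows || P.n_cols != 3 || Q.n_cols != 3)
    stop("kabsch needs two equal n x 3 matrices with n >= 3");
  arma::mat33 R;
  arma::rowvec t;
  double rmsd;
  kabsch_core(P, Q, R, t, rmsd);
  arma::mat Rout = R;   // fixed-size mat33 would wrap as a bare vector
  return List::create(_["rotation"] = Rout, _["translation"] = t,
                      _["rmsd"] = rmsd);
}

static double score_all(const arma::mat& P, const arma::mat& Q,
                        const arma::uvec& idx, double d0, arma::vec& dist) {
  arma::mat33 R;
  arma::rowvec t;
  double rmsd;
  kabsch_core(P.rows(idx), Q.rows(idx), R, t, rmsd);
  arma::mat Pa = P * R;
  Pa.each_row() += t;
  arma::mat E = Pa - Q;
  dist = arma::sqrt(arma::sum(E % E, 1));
  double s = 0.0;
  for (arma::uword i = 0; i < dist.n_elem; ++i)
    s += 1.0 / (1.0 + (dist(i) / d0) * (dist(i) / d0));
  return s / P.n_rows;
}

// [[Rcpp::export]]
double tm_score_cpp(const arma::mat& P, const arma::mat& Q, double d0,
                    int stride, int max_iter) {
  const int L = P.n_rows;
  if (L < 3 || Q.n_rows != (arma::uword)L) stop("equal-length coordinate sets required");
  std::vector<int> lens;
  for (int l : {L, L / 2, L / 4, 4})
    if (l >= 4 && std::find(lens.begin(), lens.end(), l) == lens.end())
      lens.push_back(l);
  if (stride < 1) stride = 1;
  double best = 0.0;
  arma::vec dist;
  for (int lf : lens) {
    for (int start = 0; start + lf <= L; start += stride) {
      arma::uvec idx = arma::regspace<arma::uvec>(start, start + lf - 1);
      for (int it = 0; it < max_iter; ++it) {
        double sc = score_all(P, Q, idx, d0, dist);
        if (sc > best) best = sc;
        // include residues within the cutoff; relax cutoff if too few
        double cut = d0;
        arma::uvec nidx = arma::find(dist < cut);
        while (nidx.n_elem < 3) {
          cut += 0.5;
          nidx = arma::find(dist < cut);
        }
        if (nidx.n_elem == idx.n_elem &&
            arma::all(nidx == idx)) break;
        idx = nidx;
      }
    }
  }
  return best;
}
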