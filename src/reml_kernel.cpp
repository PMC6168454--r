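#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Accumulate the building blocks of the restricted log-likelihood for a
// multi-trait individual-random-intercept model, individual by individual.
//
// For individual i the marginal covariance of its stacked observations is
//   V_i[r,s] = Sigma_ind[g](t_r, t_s) + 1(occ_r == occ_s) * Sigma_res[g](t_r, t_s)
// where t_r is the trait of row r, occ_r its measurement occasion and g the
// individual's group (population). Rows are pre-sorted by individual;
// ind_start/ind_len give each individual's row block (0-based).
// Returns sum log|V_i|, X'V^-1X, X'V^-1y and y'V^-1y, or ok = FALSE when
// some V_i is not positive definite.
// [[Rcpp::export]]
List reml_kernel(const arma::mat& X, const arma::vec& y,
                 const arma::ivec& trait, const arma::ivec& occ,
                 const arma::ivec& ind_start, const arma::ivec& ind_len,
                 const arma::ivec& grp_of_ind,
                 const List& Sigma_ind, const List& Sigma_res) {
  const int p = X.n_cols;
  const int nind = ind_start.n_elem;
  const int G = Sigma_ind.size();

  std::vector<arma::mat> Gm(G), Rm(G);
  for (int g = 0; g < G; ++g) {
    Gm[g] = as<arma::mat>(Sigma_ind[g]);
    Rm[g] = as<arma::mat>(Sigma_res[g]);
  }

  arma::mat XtVX(p, p, arma::fill::zeros);
  arma::vec XtVy(p, arma::fill::zeros);
  double ytVy = 0.0, logdetV = 0.0;

  for (int i = 0; i < nind; ++i) {
    const int a = ind_start[i];
    const int m = ind_len[i];
    const int g = grp_of_ind[i];
    const arma::mat& Gg = Gm[g];
    const arma::mat& Rg = Rm[g];

    arma::mat V(m, m);
    for (int r = 0; r < m; ++r) {
      const int tr_r = trait[a + r], oc_r = occ[a + r];
      for (int s = 0; s <= r; ++s) {
        double v = Gg(tr_r, trait[a + s]);
        if (oc_r == occ[a + s]) v += Rg(tr_r, trait[a + s]);
        V(r, s) = v;
        V(s, r) = v;
      }
    }

    try {
      arma::mat L;
      if (!arma::chol(L, V, "lower"))
        return List::create(_["ok"] = false);
      if (L.diag().min() < 1e-10)
        return List::create(_["ok"] = false);

      logdetV += 2.0 * arma::accu(arma::log(L.diag()));
      arma::mat Xw = arma::solve(arma::trimatl(L), X.rows(a, a + m - 1));
      arma::vec yw = arma::solve(arma::trimatl(L), y.subvec(a, a + m - 1));
      XtVX += Xw.t() * Xw;
      XtVy += Xw.t() * yw;
      ytVy += arma::dot(yw, yw);
    } catch (...) {
      return List::create(_["ok"] = false);
    }
  }

  return List::create(_["ok"] = true, _["logdetV"] = logdetV,
                      _["XtVX"] = XtVX, _["XtVy"] = XtVy, _["ytVy"] = ytVy);
}
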