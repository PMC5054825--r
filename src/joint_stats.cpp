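// Joint recomputation of the five network-difference statistics
// (WNES, NES, NS, ES, RT) over a stream of group-label permutations.
//
// Each row of `splits` is one arrangement: the 0-based indices of the rows
// of the pooled data matrix assigned to group D (the remaining rows form
// group C).  For every arrangement the full pipeline is re-run: group node
// means/variances, per-child OLS with intercept in each group's own network
// orientation, squared standardized differences, weighted combination, and
// the aligned-rank distance from the precomputed rank matrix (pooled
// alignment and within-subject ranking are label-invariant, so the rank
// matrix is computed once in R).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Regression {
  arma::uword child;
  arma::uvec parents;
};

std::vector<Regression> unpack_regs(const List& regs) {
  std::vector<Regression> out;
  out.reserve(regs.size());
  for (R_xlen_t i = 0; i < regs.size(); ++i) {
    IntegerVector r = regs[i];  // child, parents... (0-based)
    Regression reg;
    reg.child = static_cast<arma::uword>(r[0]);
    reg.parents.set_size(r.size() - 1);
    for (int j = 1; j < r.size(); ++j)
      reg.parents[j - 1] = static_cast<arma::uword>(r[j]);
    out.push_back(reg);
  }
  return out;
}

// OLS of child on parents + intercept over the rows in idx; writes the
// coefficient and its sampling variance for each parent.
void run_ols(const arma::mat& X, const arma::uvec& idx,
             const Regression& reg, arma::vec& beta_out,
             arma::vec& varb_out) {
  const arma::uword n = idx.n_elem, p = reg.parents.n_elem;
  arma::mat Z(n, p + 1);
  Z.col(0).ones();
  for (arma::uword j = 0; j < p; ++j)
    Z.col(j + 1) = X.submat(idx, arma::uvec{reg.parents[j]});
  arma::vec y = X.submat(idx, arma::uvec{reg.child});
  arma::mat XtX = Z.t() * Z;
  arma::mat XtXinv;
  if (!arma::inv_sympd(XtXinv, XtX)) {
    if (!arma::inv(XtXinv, XtX))
      stop("collinear parent design in permutation OLS");
  }
  arma::vec coef = XtXinv * (Z.t() * y);
  arma::vec resid = y - Z * coef;
  double df = static_cast<double>(n) - static_cast<double>(p) - 1.0;
  double sigma2 = arma::dot(resid, resid) / df;
  for (arma::uword j = 0; j < p; ++j) {
    beta_out[j] = coef[j + 1];
    varb_out[j] = sigma2 * XtXinv(j + 1, j + 1);
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_joint_stats")]]
NumericMatrix cpp_joint_stats(const arma::mat& X,
                              const IntegerMatrix& splits,
                              const List& regs_D, const List& regs_C,
                              const IntegerMatrix& edge_map,
                              const LogicalVector& node_in_D,
                              const LogicalVector& node_in_C,
                              const NumericVector& weights,
                              const arma::mat& ranks,
                              bool do_nes, bool do_rt) {
  const arma::uword n = X.n_rows, K = X.n_cols;
  const arma::uword n1 = splits.ncol();
  const arma::uword n2 = n - n1;
  const R_xlen_t B = splits.nrow();
  if (n2 < 1) stop("empty second group");

  std::vector<Regression> rd = unpack_regs(regs_D);
  std::vector<Regression> rc = unpack_regs(regs_C);
  const int M = edge_map.nrow();

  // per-regression coefficient buffers
  std::vector<arma::vec> bD(rd.size()), vD(rd.size());
  std::vector<arma::vec> bC(rc.size()), vC(rc.size());
  for (size_t i = 0; i < rd.size(); ++i) {
    bD[i].set_size(rd[i].parents.n_elem);
    vD[i].set_size(rd[i].parents.n_elem);
  }
  for (size_t i = 0; i < rc.size(); ++i) {
    bC[i].set_size(rc[i].parents.n_elem);
    vC[i].set_size(rc[i].parents.n_elem);
  }

  NumericMatrix out(B, 5);
  colnames(out) = CharacterVector::create("WNES", "NES", "NS", "ES", "RT");

  arma::uvec idxD(n1), idxC(n2);
  std::vector<bool> inD(n);

  for (R_xlen_t b = 0; b < B; ++b) {
    std::fill(inD.begin(), inD.end(), false);
    for (arma::uword i = 0; i < n1; ++i) {
      int r = splits(b, i);
      idxD[i] = static_cast<arma::uword>(r);
      inD[r] = true;
    }
    arma::uword k2 = 0;
    for (arma::uword r = 0; r < n; ++r)
      if (!inD[r]) idxC[k2++] = r;

    double NS = 0.0, wNS = 0.0, ES = 0.0;
    bool degenerate = false;

    if (do_nes) {
      // node terms
      for (arma::uword k = 0; k < K; ++k) {
        double mD = 0.0, vDk = 0.0, mC = 0.0, vCk = 0.0;
        if (node_in_D[k]) {
          const arma::vec col = X.col(k);
          double s = 0.0, ss = 0.0;
          for (arma::uword i = 0; i < n1; ++i) s += col[idxD[i]];
          mD = s / n1;
          for (arma::uword i = 0; i < n1; ++i) {
            double d = col[idxD[i]] - mD;
            ss += d * d;
          }
          vDk = ss / (n1 - 1.0);
        }
        if (node_in_C[k]) {
          const arma::vec col = X.col(k);
          double s = 0.0, ss = 0.0;
          for (arma::uword i = 0; i < n2; ++i) s += col[idxC[i]];
          mC = s / n2;
          for (arma::uword i = 0; i < n2; ++i) {
            double d = col[idxC[i]] - mC;
            ss += d * d;
          }
          vCk = ss / (n2 - 1.0);
        }
        double num = (mD - mC) * (mD - mC);
        double den = vDk / n1 + vCk / n2;
        double U;
        if (den > 0.0) U = num / den;
        else if (num == 0.0) U = 0.0;
        else { degenerate = true; break; }
        NS += U;
        wNS += weights[k] * U;
      }

      // per-group regressions
      if (!degenerate) {
        for (size_t i = 0; i < rd.size(); ++i)
          run_ols(X, idxD, rd[i], bD[i], vD[i]);
        for (size_t i = 0; i < rc.size(); ++i)
          run_ols(X, idxC, rc[i], bC[i], vC[i]);

        for (int m = 0; m < M; ++m) {
          double betaD = 0.0, varD = 0.0, betaC = 0.0, varC = 0.0;
          int rD = edge_map(m, 0), pD = edge_map(m, 1);
          int rC = edge_map(m, 2), pC = edge_map(m, 3);
          if (rD >= 0) { betaD = bD[rD][pD]; varD = vD[rD][pD]; }
          if (rC >= 0) { betaC = bC[rC][pC]; varC = vC[rC][pC]; }
          double num = (betaD - betaC) * (betaD - betaC);
          double den = varD + varC;
          double V;
          if (den > 0.0) V = num / den;
          else if (num == 0.0) V = 0.0;
          else { degenerate = true; break; }
          ES += V;
        }
      }
    }

    if (degenerate) {
      out(b, 0) = out(b, 1) = out(b, 2) = out(b, 3) = NA_REAL;
    } else if (do_nes) {
      out(b, 0) = wNS + ES;
      out(b, 1) = NS + ES;
      out(b, 2) = NS;
      out(b, 3) = ES;
    } else {
      out(b, 0) = out(b, 1) = out(b, 2) = out(b, 3) = NA_REAL;
    }

    if (do_rt) {
      double rt = 0.0;
      for (arma::uword k = 0; k < ranks.n_cols; ++k) {
        const arma::vec col = ranks.col(k);
        double sD = 0.0, sC = 0.0;
        for (arma::uword i = 0; i < n1; ++i) sD += col[idxD[i]];
        for (arma::uword i = 0; i < n2; ++i) sC += col[idxC[i]];
        double d = sD / n1 - sC / n2;
        rt += d * d;
      }
      out(b, 4) = (static_cast<double>(n1) * n2 / (n1 + n2)) * rt;
    } else {
      out(b, 4) = NA_REAL;
    }

    if (b % 64 == 0) checkUserInterrupt();
  }
  return out;
}
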