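#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Pedigree arguments use 1-based member indices in topological order
// (parents always precede offspring); 0 marks a founder.

// [[Rcpp::export]]
NumericMatrix cpp_kinship_mc(IntegerVector father, IntegerVector mother,
                             int n_drops) {
  const int n = father.size();
  std::vector<int> a1(n), a2(n);
  NumericMatrix acc(n, n);

  for (int d = 0; d < n_drops; ++d) {
    for (int i = 0; i < n; ++i) {
      if (father[i] == 0) {          // founder: two unique allele labels
        a1[i] = 2 * i + 1;
        a2[i] = 2 * i + 2;
      } else {
        int f = father[i] - 1, m = mother[i] - 1;
        a1[i] = (unif_rand() < 0.5) ? a1[f] : a2[f];
        a2[i] = (unif_rand() < 0.5) ? a1[m] : a2[m];
      }
    }
    for (int i = 0; i < n; ++i) {
      acc(i, i) += 0.5 * (1.0 + (a1[i] == a2[i]));
      for (int j = i + 1; j < n; ++j) {
        int m = (a1[i] == a1[j]) + (a1[i] == a2[j]) +
                (a2[i] == a1[j]) + (a2[i] == a2[j]);
        acc(i, j) += 0.25 * m;
      }
    }
  }
  NumericMatrix phi(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = acc(i, j) / n_drops;
      phi(i, j) = v;
      phi(j, i) = v;
    }
  return phi;
}

// Drop founder haplotype labels down the pedigree along one chromosome.
// Recombination follows the Haldane model: the number of crossovers per
// meiosis is Poisson(length_cM / 100) and crossover positions are uniform.
// Returns an n x (2 * npos) integer matrix: columns 1..npos hold the
// paternally inherited label at each grid position, columns npos+1..2*npos
// the maternally inherited label.

// [[Rcpp::export]]
IntegerMatrix cpp_drop_chromosome(IntegerVector father, IntegerVector mother,
                                  NumericVector pos_cm) {
  const int n = father.size();
  const int npos = pos_cm.size();
  const double len = pos_cm[npos - 1] - pos_cm[0];
  IntegerMatrix H(n, 2 * npos);

  std::vector<double> xo;
  for (int i = 0; i < n; ++i) {
    if (father[i] == 0) {
      for (int p = 0; p < npos; ++p) {
        H(i, p) = 2 * i + 1;
        H(i, npos + p) = 2 * i + 2;
      }
      continue;
    }
    for (int side = 0; side < 2; ++side) {   // 0: gamete from father
      int par = (side == 0 ? father[i] : mother[i]) - 1;
      int nxo = (int) R::rpois(len / 100.0);
      xo.resize(nxo);
      for (int k = 0; k < nxo; ++k) xo[k] = pos_cm[0] + unif_rand() * len;
      std::sort(xo.begin(), xo.end());
      int strand = (unif_rand() < 0.5) ? 0 : 1;  // start on hap 0 or 1
      int k = 0;
      for (int p = 0; p < npos; ++p) {
        while (k < nxo && xo[k] <= pos_cm[p]) { strand ^= 1; ++k; }
        int lab = (strand == 0) ? H(par, p) : H(par, npos + p);
        H(i, side * npos + p) = lab;
      }
    }
  }
  return H;
}

// Pairwise IBD-sharing proportion pihat from two label vectors (the two
// haplotypes each individual carries at one locus): half the number of
// label-identical pairs among the four cross-individual allele pairs.
// Diagonal is 1 for non-inbred individuals, 2 when autozygous.

// [[Rcpp::export]]
NumericMatrix cpp_pihat(IntegerVector h1, IntegerVector h2) {
  const int n = h1.size();
  NumericMatrix pi(n, n);
  for (int i = 0; i < n; ++i) {
    pi(i, i) = 0.5 * (2 + 2 * (h1[i] == h2[i]));
    for (int j = i + 1; j < n; ++j) {
      int m = (h1[i] == h1[j]) + (h1[i] == h2[j]) +
              (h2[i] == h1[j]) + (h2[i] == h2[j]);
      pi(i, j) = pi(j, i) = 0.5 * m;
    }
  }
  return pi;
}

// Profiled negative log-likelihood of the three-component locus model at
// variance shares (hq, ha): V = hq*Pi + ha*G + (1-hq-ha)*I, beta by GLS and
// the total variance by rss/n, both in closed form. Implemented here to
// avoid repeated large R-level allocations inside the optimiser loop.
// [[Rcpp::export]]
double cpp_qtl_nll(double hq, double ha, NumericMatrix Pi, NumericMatrix G,
                   NumericVector y, NumericMatrix X) {
  const int n = y.size(), p = X.ncol();
  arma::mat Pm(Pi.begin(), n, n, false, true);
  arma::mat Gm(G.begin(), n, n, false, true);
  arma::mat Xm(X.begin(), n, p, false, true);
  arma::vec yv(y.begin(), n, false, true);
  double he = 1.0 - hq - ha;
  arma::mat V = hq * Pm + ha * Gm;
  V.diag() += he;
  arma::mat R;
  if (!arma::chol(R, V)) return 1e300;
  arma::mat Xs = arma::solve(arma::trimatl(R.t()), Xm);
  arma::vec ys = arma::solve(arma::trimatl(R.t()), yv);
  arma::vec beta = arma::solve(Xs.t() * Xs, Xs.t() * ys);
  arma::vec r = ys - Xs * beta;
  double rss = arma::dot(r, r);
  if (rss <= 0) return 1e300;
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  return 0.5 * (n * std::log(2.0 * M_PI) + n + n * std::log(rss / n) + logdet);
}

// Value and analytic gradient of the profiled negative log-likelihood with
// respect to the variance shares (hq, ha). Writing V = I + hq(Pi-I) +
// ha(G-I), d logdet/d theta = tr(V^-1 A) and, by the envelope theorem at
// the GLS optimum, d rss/d theta = -z' A z with z = V^-1 r.
// Returns (nll, d nll/d hq, d nll/d ha).
// [[Rcpp::export]]
NumericVector cpp_qtl_nll_grad(double hq, double ha, NumericMatrix Pi,
                               NumericMatrix G, NumericVector y,
                               NumericMatrix X) {
  const int n = y.size(), p = X.ncol();
  arma::mat Pm(Pi.begin(), n, n, false, true);
  arma::mat Gm(G.begin(), n, n, false, true);
  arma::mat Xm(X.begin(), n, p, false, true);
  arma::vec yv(y.begin(), n, false, true);
  double he = 1.0 - hq - ha;
  arma::mat V = hq * Pm + ha * Gm;
  V.diag() += he;
  arma::mat R;
  if (!arma::chol(R, V))
    return NumericVector::create(1e300, 0.0, 0.0);
  arma::mat Xs = arma::solve(arma::trimatl(R.t()), Xm);
  arma::vec ys = arma::solve(arma::trimatl(R.t()), yv);
  arma::vec beta = arma::solve(Xs.t() * Xs, Xs.t() * ys);
  arma::vec rs = ys - Xs * beta;
  double rss = arma::dot(rs, rs);
  if (rss <= 0) return NumericVector::create(1e300, 0.0, 0.0);
  double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  double nll = 0.5 * (n * std::log(2.0 * M_PI) + n +
                      n * std::log(rss / n) + logdet);
  // z = V^-1 r (one more backsolve), V^-1 via the Cholesky factor
  arma::vec z = arma::solve(arma::trimatu(R), rs);
  arma::mat Vinv;
  if (!arma::inv_sympd(Vinv, V))
    return NumericVector::create(nll, NA_REAL, NA_REAL);
  double trVi = arma::trace(Vinv);
  double trViPi = arma::accu(Vinv % Pm);
  double trViG = arma::accu(Vinv % Gm);
  arma::vec Pz = Pm * z, Gz = Gm * z;
  double zz = arma::dot(z, z);
  double zPz = arma::dot(z, Pz), zGz = arma::dot(z, Gz);
  double gq = 0.5 * ((trViPi - trVi) - (double) n * (zPz - zz) / rss);
  double ga = 0.5 * ((trViG - trVi) - (double) n * (zGz - zz) / rss);
  return NumericVector::create(nll, gq, ga);
}
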