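// Coordinate-dependent graph featurisation (dynamic edges, pooled angular
// harmonics, radial basis rows), mirroring the R implementation in
// R/denoiser.R / R/graph.R; the two paths are cross-checked in the tests.

#include <RcppArmadillo.h>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Legendre polynomials P_0..P_{L-1} at x.
void legendre_vals(double x, int L, double* out) {
  out[0] = 1.0;
  if (L > 1) out[1] = x;
  for (int l = 2; l < L; ++l)
    out[l] = ((2 * l - 1) * x * out[l - 1] - (l - 1) * out[l - 2]) / l;
}

rowvec radial_row(double d, double cutoff, int nr) {
  rowvec out(nr, fill::zeros);
  if (d >= cutoff) return out;
  double env = 0.5 * (std::cos(datum::pi * d / cutoff) + 1.0);
  double pref = env * std::sqrt(2.0 / cutoff) / d;
  for (int k = 0; k < nr; ++k)
    out[k] = pref * std::sin((k + 1) * datum::pi * d / cutoff);
  return out;
}

struct Cand { double d; unsigned int i, j; bool local; };

}  // namespace

// [[Rcpp::export]]
Rcpp::List graph_inputs_cpp(const arma::mat& coords,
                            const arma::uvec& st_i, const arma::uvec& st_j,
                            double local_cutoff, double global_cutoff,
                            int k_max, int n_radial, int n_harm) {
  const unsigned int n = coords.n_rows;
  // candidate dynamic edges: all non-static pairs within the global cutoff
  std::vector<bool> blocked(n * n, false);
  for (uword e = 0; e < st_i.n_elem; ++e) {
    blocked[st_i[e] * n + st_j[e]] = true;
    blocked[st_j[e] * n + st_i[e]] = true;
  }
  std::vector<Cand> cands;
  for (unsigned int i = 0; i + 1 < n; ++i)
    for (unsigned int j = i + 1; j < n; ++j) {
      if (blocked[i * n + j]) continue;
      double d = norm(coords.row(i) - coords.row(j));
      if (d <= 0 || d > global_cutoff) continue;
      cands.push_back({d, i, j, d <= local_cutoff});
    }
  std::stable_sort(cands.begin(), cands.end(),
                   [](const Cand& a, const Cand& b) {
                     if (a.d != b.d) return a.d < b.d;
                     if (a.i != b.i) return a.i < b.i;
                     return a.j < b.j;
                   });
  std::vector<int> deg_l(n, 0), deg_g(n, 0);
  std::vector<Cand> loc, glob;
  for (const Cand& c : cands) {
    if (c.local) {
      if (deg_l[c.i] < k_max && deg_l[c.j] < k_max) {
        ++deg_l[c.i]; ++deg_l[c.j]; loc.push_back(c);
      }
    } else {
      if (deg_g[c.i] < k_max && deg_g[c.j] < k_max) {
        ++deg_g[c.i]; ++deg_g[c.j]; glob.push_back(c);
      }
    }
  }
  auto by_ij = [](const Cand& a, const Cand& b) {
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  };
  std::sort(loc.begin(), loc.end(), by_ij);
  std::sort(glob.begin(), glob.end(), by_ij);

  // directed close edges: static (long-range basis cutoff) then dynamic
  // local (local basis cutoff); each undirected edge in both directions
  const unsigned int ns = st_i.n_elem, nl = loc.size(), ng = glob.size();
  const unsigned int ml = 2 * (ns + nl), mg = 2 * ng;
  uvec csrc(ml), cdst(ml); vec ccut(ml);
  for (unsigned int e = 0; e < ns; ++e) {
    csrc[e] = st_i[e]; cdst[e] = st_j[e]; ccut[e] = global_cutoff;
    csrc[ns + nl + e] = st_j[e]; cdst[ns + nl + e] = st_i[e];
    ccut[ns + nl + e] = global_cutoff;
  }
  for (unsigned int e = 0; e < nl; ++e) {
    csrc[ns + e] = loc[e].i; cdst[ns + e] = loc[e].j;
    ccut[ns + e] = local_cutoff;
    csrc[2 * ns + nl + e] = loc[e].j; cdst[2 * ns + nl + e] = loc[e].i;
    ccut[2 * ns + nl + e] = local_cutoff;
  }
  uvec gsrc(mg), gdst(mg);
  for (unsigned int e = 0; e < ng; ++e) {
    gsrc[e] = glob[e].i; gdst[e] = glob[e].j;
    gsrc[ng + e] = glob[e].j; gdst[ng + e] = glob[e].i;
  }

  // close-edge features: radial basis + mean-Legendre x radial products
  mat cfeat(ml, n_radial + n_harm * n_radial, fill::zeros);
  mat vecs(ml, 3);
  vec dd(ml);
  for (unsigned int e = 0; e < ml; ++e) {
    rowvec v = coords.row(cdst[e]) - coords.row(csrc[e]);
    vecs.row(e) = v;
    dd[e] = std::max(norm(v), 1e-8);
  }
  mat rbf(ml, n_radial);
  for (unsigned int e = 0; e < ml; ++e)
    rbf.row(e) = radial_row(dd[e], ccut[e], n_radial);
  // group edges by source node for the one-hop angle pooling
  std::vector<std::vector<unsigned int>> by_src(n);
  for (unsigned int e = 0; e < ml; ++e) by_src[csrc[e]].push_back(e);
  mat plbar(ml, n_harm, fill::zeros);
  std::vector<double> pl(n_harm);
  for (unsigned int j = 0; j < n; ++j) {
    const auto& es = by_src[j];
    const unsigned int k = es.size();
    if (k < 2) continue;
    mat U(k, 3);
    for (unsigned int r = 0; r < k; ++r)
      U.row(r) = vecs.row(es[r]) / dd[es[r]];
    mat Cc = U * U.t();
    for (unsigned int r = 0; r < k; ++r) {
      rowvec acc(n_harm, fill::zeros);
      for (unsigned int c = 0; c < k; ++c) {
        if (c == r) continue;
        double x = std::min(1.0, std::max(-1.0, Cc(r, c)));
        legendre_vals(x, n_harm, pl.data());
        for (int l = 0; l < n_harm; ++l) acc[l] += pl[l];
      }
      plbar.row(es[r]) = acc / (double)(k - 1);
    }
  }
  for (unsigned int e = 0; e < ml; ++e) {
    for (int k = 0; k < n_radial; ++k) {
      cfeat(e, k) = rbf(e, k);
      for (int l = 0; l < n_harm; ++l)
        cfeat(e, n_radial + k * n_harm + l) = plbar(e, l) * rbf(e, k);
    }
  }
  mat gfeat(mg, n_radial);
  for (unsigned int e = 0; e < mg; ++e) {
    double d = norm(coords.row(gdst[e]) - coords.row(gsrc[e]));
    gfeat.row(e) = radial_row(d, global_cutoff, n_radial);
  }
  return Rcpp::List::create(
    Rcpp::Named("csrc") = csrc + 1, Rcpp::Named("cdst") = cdst + 1,
    Rcpp::Named("cfeat") = cfeat,
    Rcpp::Named("gsrc") = gsrc + 1, Rcpp::Named("gdst") = gdst + 1,
    Rcpp::Named("gfeat") = gfeat);
}
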