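#include <Rcpp.h>
using namespace Rcpp;

// Phylogeny-aware overlap similarity between two relative-abundance profiles.
//
// Profiles are indexed by tree tip number (1..ntip). The tree arrives as its
// postorder edge list (children always precede their parent's closing edge),
// with edge lengths already clamped to [0, 1]. At each tip the shared mass
// min(a_i, b_i) is matched; the per-sample leftovers travel up the tree,
// attenuated by (1 - branch length) on every edge, and are matched against
// the opposite sample's leftovers at each internal node. Residual mass
// reaching past the root is discarded.
static double ms_pair(const double *a, const double *b,
                      const int *parent, const int *child,
                      const double *elen, int nedge, int ntot, int ntip,
                      std::vector<double> &ra, std::vector<double> &rb) {
  std::fill(ra.begin(), ra.begin() + ntot, 0.0);
  std::fill(rb.begin(), rb.begin() + ntot, 0.0);
  double S = 0.0;
  for (int e = 0; e < nedge; ++e) {
    const int c = child[e] - 1;
    const int p = parent[e] - 1;
    double xa, xb;
    if (c < ntip) {
      xa = a[c];
      xb = b[c];
    } else {
      xa = ra[c];
      xb = rb[c];
    }
    const double m = xa < xb ? xa : xb;
    S += m;
    const double f = 1.0 - elen[e];
    ra[p] += (xa - m) * f;
    rb[p] += (xb - m) * f;
  }
  const int root = parent[nedge - 1] - 1;
  const double m = ra[root] < rb[root] ? ra[root] : rb[root];
  return S + m;
}

// Q and R hold one profile per column (ntip rows); returns ncol(Q) x ncol(R).
// [[Rcpp::export]]
NumericMatrix ms_similarity_batch(NumericMatrix Q, NumericMatrix R,
                                  IntegerVector parent, IntegerVector child,
                                  NumericVector elen, int ntip, int nnode) {
  const int nq = Q.ncol(), nr = R.ncol(), ntot = ntip + nnode;
  const int nedge = parent.size();
  if (Q.nrow() != ntip || R.nrow() != ntip)
    stop("profile matrices must have one row per tree tip");
  std::vector<double> ra(ntot), rb(ntot);
  NumericMatrix out(nq, nr);
  for (int i = 0; i < nq; ++i) {
    const double *qi = &Q(0, i);
    for (int j = 0; j < nr; ++j) {
      double s = ms_pair(qi, &R(0, j), parent.begin(), child.begin(),
                         elen.begin(), nedge, ntot, ntip, ra, rb);
      out(i, j) = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
    }
  }
  return out;
}

// Symmetric pairwise variant over the columns of P, diagonal forced to 1.
// [[Rcpp::export]]
NumericMatrix ms_similarity_pairwise(NumericMatrix P, IntegerVector parent,
                                     IntegerVector child, NumericVector elen,
                                     int ntip, int nnode) {
  const int n = P.ncol(), ntot = ntip + nnode;
  const int nedge = parent.size();
  if (P.nrow() != ntip)
    stop("profile matrix must have one row per tree tip");
  std::vector<double> ra(ntot), rb(ntot);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double s = ms_pair(&P(0, i), &P(0, j), parent.begin(), child.begin(),
                         elen.begin(), nedge, ntot, ntip, ra, rb);
      s = s < 0.0 ? 0.0 : (s > 1.0 ? 1.0 : s);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}
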