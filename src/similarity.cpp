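// All-pairs motif similarity.
//
// Mirrors motif_similarity() in R/motif.R exactly: one direction scores the
// profile matrix of x against the observed column proportions of y over all
// ungapped offsets, keeping the offsets with the maximum number of aligned
// columns (per-column score > tau * column maximum) and, among those, the
// largest aggregate score normalised by the sum of column maxima of P_x.
// The pair score is the symmetrised mean, maximised over the forward and
// reverse-complement orientation of y, clipped to [0, 1].

#include <Rcpp.h>
using namespace Rcpp;

// Access column i (0-based) of a 4 x L block starting at column `off` of a
// concatenated 4-row matrix, optionally reverse-complemented (reverse
// columns, complement rows A<->T, C<->G i.e. b -> 3-b).
static inline double getm(const double *m, int off, int L, int b, int i,
                          bool rc) {
  if (rc) return m[(off + (L - 1 - i)) * 4 + (3 - b)];
  return m[(off + i) * 4 + b];
}

// Best ungapped alignment score of profile x against frequencies of y.
static double s_dir(const double *P, int offx, int Lx, bool rcx,
                    const double *F, int offy, int Ly, bool rcy,
                    const double *cmax, double denom, double tau) {
  if (denom <= 0.0) return 0.0;
  int best_n = 0;
  double best_s = 0.0;
  auto visit = [&](int o) {
    int i0 = std::max(0, -o);
    int i1 = std::min(Lx - 1, Ly - 1 - o);
    int ncols = 0;
    double ssum = 0.0;
    for (int i = i0; i <= i1; ++i) {
      double c = 0.0;
      for (int b = 0; b < 4; ++b)
        c += getm(P, offx, Lx, b, i, rcx) * getm(F, offy, Ly, b, i + o, rcy);
      // column maximum of P_x, reversed when x is reverse-complemented
      double cm = rcx ? cmax[offx + Lx - 1 - i] : cmax[offx + i];
      if (c > tau * cm) {
        ++ncols;
        ssum += c;
      }
    }
    if (ncols > 0) {
      double sc = ssum / denom;
      if (ncols > best_n || (ncols == best_n && sc > best_s)) {
        best_n = ncols;
        best_s = sc;
      }
    }
  };
  // visit offsets in order of decreasing overlap (plateau first, then
  // outward): once the overlap drops below the best aligned-column
  // count, no remaining offset can win or tie
  const int pl = std::min(0, Ly - Lx);
  const int ph = std::max(0, Ly - Lx);
  for (int o = pl; o <= ph; ++o) visit(o);
  for (int d = 1;; ++d) {
    int ov = std::min(Lx, Ly) - d;
    if (ov < 1 || ov < best_n) break;
    visit(pl - d);
    visit(ph + d);
  }
  return best_n == 0 ? 0.0 : best_s;
}

// [[Rcpp::export]]
NumericMatrix sim_matrix_cpp(NumericMatrix P, NumericMatrix Fh,
                             IntegerVector widths, IntegerVector offsets,
                             double tau) {
  const int n = widths.size();
  const double *pP = P.begin();
  const double *pF = Fh.begin();
  const int ncol = P.ncol();

  // per-column maxima of P and per-motif denominators
  std::vector<double> cmax(ncol);
  for (int j = 0; j < ncol; ++j) {
    double m = pP[j * 4];
    for (int b = 1; b < 4; ++b) m = std::max(m, pP[j * 4 + b]);
    cmax[j] = m;
  }
  std::vector<double> denom(n);
  for (int k = 0; k < n; ++k) {
    double d = 0.0;
    for (int j = 0; j < widths[k]; ++j) d += cmax[offsets[k] + j];
    denom[k] = d;
  }

  NumericMatrix S(n, n);
  for (int a = 0; a < n; ++a) {
    S(a, a) = 1.0;
    for (int b = a + 1; b < n; ++b) {
      const int oa = offsets[a], ob = offsets[b];
      const int La = widths[a], Lb = widths[b];
      double fwd = 0.5 * (s_dir(pP, oa, La, false, pF, ob, Lb, false,
                                cmax.data(), denom[a], tau) +
                          s_dir(pP, ob, Lb, false, pF, oa, La, false,
                                cmax.data(), denom[b], tau));
      double rc = 0.5 * (s_dir(pP, oa, La, false, pF, ob, Lb, true,
                               cmax.data(), denom[a], tau) +
                         s_dir(pP, ob, Lb, true, pF, oa, La, false,
                               cmax.data(), denom[b], tau));
      double s = std::max(fwd, rc);
      s = std::min(std::max(s, 0.0), 1.0);
      S(a, b) = s;
      S(b, a) = s;
    }
  }
  return S;
}
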