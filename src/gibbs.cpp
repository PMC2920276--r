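// Gibbs site sampler for de novo motif discovery.
//
// One site per sequence (OOPS), both strands, random restarts; the best
// configuration by joint log-odds is polished by deterministic argmax
// passes.  Subsequent motifs are obtained by masking the sites of earlier
// ones and re-running.  Randomness comes from R's RNG so callers control
// reproducibility with set.seed().

#include <Rcpp.h>
using namespace Rcpp;

struct Win {
  int strand;  // 0 = forward, 1 = reverse complement
  int pos;     // window start on the given strand's coordinates
};

// Letter (0..3) at column j of a window.
static inline int letter(const std::vector<int> &x, int L, const Win &w,
                         int jcol, int width) {
  if (w.strand == 0) return x[w.pos + jcol];
  return 3 - x[L - 1 - w.pos - jcol];
}

// Leftmost forward-strand position covered by a window.
static inline int fwd_start(int L, const Win &w, int width) {
  return w.strand == 0 ? w.pos : L - w.pos - width;
}

static inline bool win_ok(const std::vector<int> &x,
                          const std::vector<bool> &mask, int width,
                          const Win &w) {
  const int L = (int)x.size();
  if (w.pos < 0 || w.pos + width > L) return false;
  int f0 = fwd_start(L, w, width);
  for (int j = f0; j < f0 + width; ++j)
    if (mask[j] || x[j] < 0) return false;
  return true;
}

static std::vector<Win> valid_windows(const std::vector<int> &x,
                                      const std::vector<bool> &mask,
                                      int width) {
  const int L = (int)x.size();
  std::vector<Win> out;
  for (int s = 0; s < 2; ++s)
    for (int p = 0; p + width <= L; ++p) {
      Win w{s, p};
      int f0 = fwd_start(L, w, width);
      bool ok = true;
      for (int j = f0; j < f0 + width; ++j)
        if (mask[j] || x[j] < 0) { ok = false; break; }
      if (ok) out.push_back(w);
    }
  return out;
}

// Joint log-odds score of a configuration (PWM built from all sites).
static double joint_score(const std::vector<std::vector<int> > &seqs,
                          const std::vector<int> &active,
                          const std::vector<Win> &cfg, int width,
                          const std::vector<double> &bg, double delta) {
  const int n = (int)active.size();
  std::vector<double> cnt(4 * width, 0.0);
  for (int a = 0; a < n; ++a) {
    const std::vector<int> &x = seqs[active[a]];
    for (int j = 0; j < width; ++j)
      cnt[j * 4 + letter(x, (int)x.size(), cfg[a], j, width)] += 1.0;
  }
  double sc = 0.0;
  for (int a = 0; a < n; ++a) {
    const std::vector<int> &x = seqs[active[a]];
    for (int j = 0; j < width; ++j) {
      int b = letter(x, (int)x.size(), cfg[a], j, width);
      double p = (cnt[j * 4 + b] + delta * bg[b]) / (n + delta);
      sc += std::log(p / bg[b]);
    }
  }
  return sc;
}

// Information content (bits) of the PWM implied by a configuration.
static double config_ic(const std::vector<std::vector<int> > &seqs,
                        const std::vector<int> &active,
                        const std::vector<Win> &cfg, int width,
                        const std::vector<double> &bg, double delta) {
  const int n = (int)active.size();
  double ic = 0.0;
  std::vector<double> cnt(4 * width, 0.0);
  for (int a = 0; a < n; ++a) {
    const std::vector<int> &x = seqs[active[a]];
    for (int j = 0; j < width; ++j)
      cnt[j * 4 + letter(x, (int)x.size(), cfg[a], j, width)] += 1.0;
  }
  for (int j = 0; j < width; ++j)
    for (int b = 0; b < 4; ++b) {
      double p = (cnt[j * 4 + b] + delta * bg[b]) / (n + delta);
      ic += p * std::log2(p / bg[b]);
    }
  return ic;
}

// [[Rcpp::export]]
List gibbs_sampler_cpp(List seqs_, int width, int n_results, int n_restarts,
                       int n_iter, NumericVector bg_, double delta) {
  const int n = seqs_.size();
  std::vector<std::vector<int> > seqs(n);
  std::vector<std::vector<bool> > mask(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = seqs_[i];
    seqs[i].assign(v.begin(), v.end());
    mask[i].assign(v.size(), false);
  }
  std::vector<double> bg(bg_.begin(), bg_.end());

  List results;
  for (int k = 0; k < n_results; ++k) {
    // enumerate usable windows per sequence
    std::vector<std::vector<Win> > wins(n);
    std::vector<int> active;
    for (int i = 0; i < n; ++i) {
      wins[i] = valid_windows(seqs[i], mask[i], width);
      if (!wins[i].empty()) active.push_back(i);
    }
    const int na = (int)active.size();
    if (na < 2) break;

    std::vector<Win> best_cfg(na);
    double best_sc = R_NegInf;
    std::vector<double> cnt(4 * width), lw;

    for (int r = 0; r < n_restarts; ++r) {
      // random initial configuration
      std::vector<Win> cfg(na);
      for (int a = 0; a < na; ++a) {
        const std::vector<Win> &wv = wins[active[a]];
        cfg[a] = wv[(int)(unif_rand() * wv.size()) % wv.size()];
      }
      // sampling iterations
      for (int it = 0; it < n_iter; ++it) {
        for (int z = 0; z < na; ++z) {
          std::fill(cnt.begin(), cnt.end(), 0.0);
          for (int a = 0; a < na; ++a) {
            if (a == z) continue;
            const std::vector<int> &x = seqs[active[a]];
            for (int j = 0; j < width; ++j)
              cnt[j * 4 + letter(x, (int)x.size(), cfg[a], j, width)] += 1.0;
          }
          const std::vector<int> &x = seqs[active[z]];
          const std::vector<Win> &wv = wins[active[z]];
          lw.resize(wv.size());
          double mx = R_NegInf;
          for (size_t wI = 0; wI < wv.size(); ++wI) {
            double sc = 0.0;
            for (int j = 0; j < width; ++j) {
              int b = letter(x, (int)x.size(), wv[wI], j, width);
              double p = (cnt[j * 4 + b] + delta * bg[b]) / (na - 1 + delta);
              sc += std::log(p / bg[b]);
            }
            lw[wI] = sc;
            if (sc > mx) mx = sc;
          }
          double tot = 0.0;
          for (size_t wI = 0; wI < wv.size(); ++wI) {
            lw[wI] = std::exp(lw[wI] - mx);
            tot += lw[wI];
          }
          double u = unif_rand() * tot, acc = 0.0;
          size_t pick = wv.size() - 1;
          for (size_t wI = 0; wI < wv.size(); ++wI) {
            acc += lw[wI];
            if (u <= acc) { pick = wI; break; }
          }
          cfg[z] = wv[pick];
        }
      }
      // deterministic polish: argmax passes plus whole-configuration
      // phase-shift moves (the classic escape from shifted local
      // optima), iterated until stable
      for (int pass = 0; pass < 20; ++pass) {
        bool changed = false;
        // phase shift: move every site by d in its own strand frame
        {
          double cur = joint_score(seqs, active, cfg, width, bg, delta);
          for (int d = -3; d <= 3; ++d) {
            if (d == 0) continue;
            std::vector<Win> shifted(cfg);
            bool ok = true;
            for (int a = 0; a < na; ++a) {
              shifted[a].pos += d;
              if (!win_ok(seqs[active[a]], mask[active[a]], width,
                          shifted[a])) {
                ok = false;
                break;
              }
            }
            if (!ok) continue;
            double sc = joint_score(seqs, active, shifted, width, bg,
                                    delta);
            if (sc > cur + 1e-12) {
              cfg = shifted;
              cur = sc;
              changed = true;
            }
          }
        }
        for (int z = 0; z < na; ++z) {
          std::fill(cnt.begin(), cnt.end(), 0.0);
          for (int a = 0; a < na; ++a) {
            if (a == z) continue;
            const std::vector<int> &x = seqs[active[a]];
            for (int j = 0; j < width; ++j)
              cnt[j * 4 + letter(x, (int)x.size(), cfg[a], j, width)] += 1.0;
          }
          const std::vector<int> &x = seqs[active[z]];
          const std::vector<Win> &wv = wins[active[z]];
          double bsc = R_NegInf;
          size_t bI = 0;
          for (size_t wI = 0; wI < wv.size(); ++wI) {
            double sc = 0.0;
            for (int j = 0; j < width; ++j) {
              int b = letter(x, (int)x.size(), wv[wI], j, width);
              double p = (cnt[j * 4 + b] + delta * bg[b]) / (na - 1 + delta);
              sc += std::log(p / bg[b]);
            }
            if (sc > bsc) { bsc = sc; bI = wI; }
          }
          if (cfg[z].strand != wv[bI].strand || cfg[z].pos != wv[bI].pos) {
            cfg[z] = wv[bI];
            changed = true;
          }
        }
        if (!changed) break;
      }
      double sc = joint_score(seqs, active, cfg, width, bg, delta);
      if (sc > best_sc) {
        best_sc = sc;
        best_cfg = cfg;
      }
    }

    // record result and mask its sites
    IntegerVector seq_index(na), offset(na);
    LogicalVector revcomp(na);
    for (int a = 0; a < na; ++a) {
      const int i = active[a];
      const int L = (int)seqs[i].size();
      seq_index[a] = i + 1;
      offset[a] = fwd_start(L, best_cfg[a], width);
      revcomp[a] = best_cfg[a].strand == 1;
      for (int j = offset[a]; j < offset[a] + width; ++j) mask[i][j] = true;
    }
    double ic = config_ic(seqs, active, best_cfg, width, bg, delta);
    results.push_back(List::create(
        Named("seq_index") = seq_index, Named("offset") = offset,
        Named("revcomp") = revcomp, Named("score") = ic));
  }
  return results;
}
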