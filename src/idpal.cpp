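#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Batch sequence featurization. Sequences are integer vectors of residue
// codes 1..20 (alphabetical one-letter ordering). Returns an n x 30 matrix:
// columns 1-20 composition fractions, columns 21-30 raw descriptors in the
// order N, lambda_bar, SHD, q+, q-, |q|, SCD, B2_MF, S, Mbar.
// SHD = (1/N) sum_{m>n} (lam_m + lam_n) * (m-n)^(-shd_beta)
// SCD = (1/N) sum_{m>n} q_m q_n * (m-n)^(scd_exp)
// B2_MF = N^2 * sum_ab f_a f_b b2pair[a,b]
// [[Rcpp::export]]
NumericMatrix cpp_seq_features(List seqs, NumericVector lambda,
                               NumericVector charge, NumericVector mass,
                               NumericMatrix b2pair, double shd_beta,
                               double scd_exp) {
  int n = seqs.size();
  NumericMatrix out(n, 30);
  // distance-kernel lookup tables (sequence separations are small integers)
  int max_n = 1;
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    if (sq.size() > max_n) max_n = sq.size();
  }
  std::vector<double> shd_k(max_n + 1, 0.0), scd_k(max_n + 1, 0.0);
  for (int d = 1; d <= max_n; ++d) {
    shd_k[d] = std::pow((double)d, -shd_beta);
    scd_k[d] = std::pow((double)d, scd_exp);
  }
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    int N = sq.size();
    std::vector<double> f(20, 0.0);
    double lam_bar = 0.0, qplus = 0.0, qminus = 0.0, net = 0.0, mbar = 0.0;
    for (int i = 0; i < N; ++i) {
      int a = sq[i] - 1;
      f[a] += 1.0;
      lam_bar += lambda[a];
      double q = charge[a];
      net += q;
      if (q > 0) qplus += 1.0;
      if (q < 0) qminus += 1.0;
      mbar += mass[a];
    }
    for (int a = 0; a < 20; ++a) f[a] /= N;
    lam_bar /= N; qplus /= N; qminus /= N; mbar /= N;
    double shd = 0.0, scd = 0.0;
    for (int m = 1; m < N; ++m) {
      int am = sq[m] - 1;
      double lm = lambda[am], qm = charge[am];
      for (int nn = 0; nn < m; ++nn) {
        int an = sq[nn] - 1;
        int d = m - nn;
        shd += (lm + lambda[an]) * shd_k[d];
        if (qm != 0.0 && charge[an] != 0.0)
          scd += qm * charge[an] * scd_k[d];
      }
    }
    shd /= N; scd /= N;
    double b2mf = 0.0;
    for (int a = 0; a < 20; ++a) {
      if (f[a] == 0.0) continue;
      for (int b = 0; b < 20; ++b) {
        if (f[b] == 0.0) continue;
        b2mf += f[a] * f[b] * b2pair(a, b);
      }
    }
    b2mf *= (double)N * (double)N;
    double S = 0.0;
    for (int a = 0; a < 20; ++a) if (f[a] > 0) S -= f[a] * std::log(f[a]);
    for (int a = 0; a < 20; ++a) out(s, a) = f[a];
    out(s, 20) = N;
    out(s, 21) = lam_bar;
    out(s, 22) = shd;
    out(s, 23) = qplus;
    out(s, 24) = qminus;
    out(s, 25) = std::fabs(net / N);
    out(s, 26) = scd;
    out(s, 27) = b2mf;
    out(s, 28) = S;
    out(s, 29) = mbar;
  }
  return out;
}

// Evaluate a flattened randomForest classification forest on a feature
// matrix. Tree arrays are concatenated with 0-based node offsets; leftd/
// rightd are 1-based node indices within a tree (0 = none), splitvar is a
// 1-based feature index (0 at leaves), pred holds the 1-based class index at
// leaves. Returns the fraction of trees voting for class 2.
// [[Rcpp::export]]
NumericVector cpp_forest_score(NumericMatrix X, IntegerVector offset,
                               IntegerVector leftd, IntegerVector rightd,
                               IntegerVector splitvar, NumericVector splitval,
                               IntegerVector pred) {
  int n = X.nrow();
  int ntree = offset.size();
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    int votes2 = 0;
    for (int t = 0; t < ntree; ++t) {
      int base = offset[t];
      int node = 0;
      while (splitvar[base + node] != 0) {
        double x = X(i, splitvar[base + node] - 1);
        node = (x <= splitval[base + node])
          ? leftd[base + node] - 1 : rightd[base + node] - 1;
      }
      if (pred[base + node] == 2) ++votes2;
    }
    score[i] = (double)votes2 / ntree;
  }
  return score;
}

static inline double phi_pdf(double z) { return R::dnorm(z, 0.0, 1.0, 0); }
static inline double Phi_cdf(double z) { return R::pnorm(z, 0.0, 1.0, 1, 0); }

// E[(Y - c)_+] for Y ~ N(mu, sd)
static inline double e_excess(double mu, double sd, double c) {
  if (sd <= 0) return std::max(mu - c, 0.0);
  double z = (mu - c) / sd;
  return (mu - c) * Phi_cdf(z) + sd * phi_pdf(z);
}

// E[(min(Y, hi) - lo)_+] for Y ~ N(mu, sd), lo < hi (hi may be +Inf)
static inline double e_clipped(double mu, double sd, double lo, double hi) {
  if (!R_finite(hi)) return e_excess(mu, sd, lo);
  if (sd <= 0) return std::max(std::min(mu, hi) - lo, 0.0);
  double zl = (lo - mu) / sd, zh = (hi - mu) / sd;
  // E[(Y-lo) 1{lo<Y<=hi}] + (hi-lo) P(Y>hi)
  double part = (mu - lo) * (Phi_cdf(zh) - Phi_cdf(zl))
    + sd * (phi_pdf(zl) - phi_pdf(zh));
  return part + (hi - lo) * (1.0 - Phi_cdf(zh));
}

// Exact two-objective EHVI (both objectives maximized, independent Gaussian
// predictions) over a nondominated front. front_a must be sorted ascending,
// front_b is the matching second objective (strictly descending for a
// nondominated set). (r1, r2) is the hypervolume reference point.
// Strip decomposition: with a_0 = r1, a_{n+1} = +Inf and staircase height
// H_i = b_i (H_{n+1} = r2), the improvement factorizes per strip into
// E[(min(Y1,a_i) - a_{i-1})_+] * E[(Y2 - H_i)_+].
// [[Rcpp::export]]
NumericVector cpp_ehvi_batch(NumericVector mu1, NumericVector sd1,
                             NumericVector mu2, NumericVector sd2,
                             NumericVector front_a, NumericVector front_b,
                             double r1, double r2) {
  int n = front_a.size();
  int m = mu1.size();
  NumericVector out(m);
  for (int c = 0; c < m; ++c) {
    double total = 0.0;
    for (int i = 0; i <= n; ++i) {
      double lo = (i == 0) ? r1 : front_a[i - 1];
      double hi = (i == n) ? R_PosInf : front_a[i];
      double H = (i == n) ? r2 : front_b[i];
      if (hi <= lo) continue;
      double e1 = e_clipped(mu1[c], sd1[c], lo, hi);
      if (e1 <= 0) continue;
      total += e1 * e_excess(mu2[c], sd2[c], H);
    }
    out[c] = total;
  }
  return out;
}

// ---- GA move engine ---------------------------------------------------------
// Batched proposal step: applies crossover, mutation, deletion and growth (in
// that order, each with its own probability) to every current sequence.
// Sequences are integer code vectors (1..20). Uses R's RNG so results are
// reproducible under set.seed().

static std::vector<int> cross_move(const std::vector<int>& a,
                                   const std::vector<int>& b,
                                   int len_min, int len_max) {
  int na = a.size(), nb = b.size();
  if (na < 2 || nb < 2) return a;
  int nm = std::min(na, nb);
  for (int t = 0; t < 10; ++t) {
    // shared cut position: prefix of a joined to the suffix of b beyond it
    int cut = 1 + (int)(unif_rand() * (nm - 1)); if (cut > nm - 1) cut = nm - 1;
    if (nb >= len_min && nb <= len_max) {
      std::vector<int> child(a.begin(), a.begin() + cut);
      child.insert(child.end(), b.begin() + cut, b.end());
      return child;
    }
  }
  return a;
}

// [[Rcpp::export]]
List cpp_ga_batch_propose(List current, List parents, double p_cross,
                          double p_mut, double p_del, double p_grow,
                          int len_min, int len_max) {
  int nt = current.size();
  int np = parents.size();
  List out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector cur = current[t];
    std::vector<int> ch(cur.begin(), cur.end());
    if (unif_rand() < p_cross) {
      int pi = (int)(unif_rand() * np); if (pi >= np) pi = np - 1;
      IntegerVector par = parents[pi];
      std::vector<int> pv(par.begin(), par.end());
      ch = cross_move(ch, pv, len_min, len_max);
    }
    if (unif_rand() < p_mut) {
      int n = ch.size();
      int i = (int)(unif_rand() * n); if (i >= n) i = n - 1;
      int r = 1 + (int)(unif_rand() * 20); if (r > 20) r = 20;
      ch[i] = r;
    }
    if (unif_rand() < p_del) {
      int n = ch.size();
      int max_del = n - len_min;
      if (max_del >= 1) {
        int len = 1 + (int)(unif_rand() * max_del); if (len > max_del) len = max_del;
        int start = (int)(unif_rand() * (n - len + 1));
        if (start > n - len) start = n - len;
        ch.erase(ch.begin() + start, ch.begin() + start + len);
      }
    }
    if (unif_rand() < p_grow) {
      int n = ch.size();
      int max_grow = std::min(len_max - n, n);
      if (max_grow >= 1) {
        int len = 1 + (int)(unif_rand() * max_grow); if (len > max_grow) len = max_grow;
        int start = (int)(unif_rand() * (n - len + 1));
        if (start > n - len) start = n - len;
        std::vector<int> seg(ch.begin() + start, ch.begin() + start + len);
        ch.insert(ch.begin() + start + len, seg.begin(), seg.end());
      }
    }
    out[t] = IntegerVector(ch.begin(), ch.end());
  }
  return out;
}
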