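#include <Rcpp.h>
using namespace Rcpp;

// Change-point statistics for one segment of a per-cell track.
//
// Both detectors scan two-boundary candidate segments (i, j): the inner
// bins i..j (1-based, inclusive) against their complement, as circular
// binary segmentation does. A candidate with i == 1 or j == n degenerates
// to a single split. Permutation nulls re-run the same scan on shuffled
// values; shuffling uses R's RNG, so set.seed() governs reproducibility.
//
// Admissible candidates: inner length >= minlen, complement length >=
// minlen, and each outer flank either empty or >= minlen (so recursion
// never creates segments shorter than minlen).

static const double VAR_FLOOR = 1e-24;

struct BestPair { int i, j; double stat; };

// max over (i, j) of |t| between inner segment and complement, pooled
// within-group variance; O(n^2) via prefix sums
static BestPair scan_t(const std::vector<double>& x, int minlen) {
  int n = x.size();
  BestPair best = {-1, -1, 0.0};
  if (n < 2 * minlen) return best;
  std::vector<double> cs(n + 1, 0.0), css(n + 1, 0.0);
  for (int k = 0; k < n; ++k) {
    cs[k + 1] = cs[k] + x[k];
    css[k + 1] = css[k] + x[k] * x[k];
  }
  double tot = cs[n], tot2 = css[n];
  for (int i = 1; i <= n; ++i) {
    int left = i - 1;
    if (left != 0 && left < minlen) continue;
    for (int j = i + minlen - 1; j <= n; ++j) {
      int right = n - j;
      if (right != 0 && right < minlen) continue;
      int m = j - i + 1, mm = n - m;
      if (mm < minlen) continue;
      double sin_ = cs[j] - cs[i - 1];
      double sin2 = css[j] - css[i - 1];
      double mu1 = sin_ / m, mu2 = (tot - sin_) / mm;
      double ssw = (sin2 - sin_ * sin_ / m) +
                   ((tot2 - sin2) - (tot - sin_) * (tot - sin_) / mm);
      double varp = (n > 2) ? ssw / (n - 2) : ssw;
      if (varp < VAR_FLOOR) varp = VAR_FLOOR;
      double stat = std::fabs(mu1 - mu2) /
                    std::sqrt(varp * (1.0 / m + 1.0 / mm));
      if (stat > best.stat) { best.stat = stat; best.i = i; best.j = j; }
    }
  }
  return best;
}

// max over (i, j) of the energy statistic
//   Q = m*mm/(m+mm) * (2 E|X-Y| - E|X-X'| - E|Y-Y'|)
// between inner segment X and complement Y; O(n^2) per scan after an
// O(n^2) build of the pairwise-distance prefix structure.
// ord maps scan position -> index into x (identity, or a permutation).
static BestPair scan_energy(const std::vector<double>& x,
                            const std::vector<int>& ord, int minlen,
                            std::vector<double>& P,
                            std::vector<double>& rowtot) {
  int n = x.size();
  BestPair best = {-1, -1, 0.0};
  if (n < 2 * minlen) return best;
  // P is an (n+1)x(n+1) 2D prefix over D[ord[k]][ord[l]] = |x_ordk - x_ordl|
  int w = n + 1;
  std::fill(P.begin(), P.end(), 0.0);
  for (int k = 1; k <= n; ++k) {
    double xk = x[ord[k - 1]];
    double rowsum = 0.0;
    for (int l = 1; l <= n; ++l) {
      double d = std::fabs(xk - x[ord[l - 1]]);
      rowsum += d;
      P[k * w + l] = P[(k - 1) * w + l] + P[k * w + l - 1] -
                     P[(k - 1) * w + l - 1] + d;
    }
    rowtot[k] = rowtot[k - 1] + rowsum;
  }
  double totD = P[n * w + n];
  for (int i = 1; i <= n; ++i) {
    int left = i - 1;
    if (left != 0 && left < minlen) continue;
    for (int j = i + minlen - 1; j <= n; ++j) {
      int right = n - j;
      if (right != 0 && right < minlen) continue;
      int m = j - i + 1, mm = n - m;
      if (mm < minlen) continue;
      double within = P[j * w + j] - P[(i - 1) * w + j] - P[j * w + i - 1] +
                      P[(i - 1) * w + i - 1];
      double rows = rowtot[j] - rowtot[i - 1];
      double cross = rows - within;
      double yy = totD - within - 2.0 * cross;
      double dm = (double)m, dmm = (double)mm;
      double stat = (dm * dmm / (dm + dmm)) *
        (2.0 * cross / (dm * dmm) - within / (dm * dm) - yy / (dmm * dmm));
      if (stat > best.stat) { best.stat = stat; best.i = i; best.j = j; }
    }
  }
  return best;
}

static void shuffle_in_place(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// [[Rcpp::export]]
List cpp_best_segment(NumericVector x, int minlen, std::string method) {
  std::vector<double> v(x.begin(), x.end());
  int n = v.size();
  BestPair best;
  if (method == "t") {
    best = scan_t(v, minlen);
  } else {
    std::vector<int> ord(n);
    for (int k = 0; k < n; ++k) ord[k] = k;
    std::vector<double> P((n + 1) * (n + 1), 0.0), rowtot(n + 1, 0.0);
    best = scan_energy(v, ord, minlen, P, rowtot);
  }
  return List::create(_["i"] = best.i, _["j"] = best.j,
                      _["stat"] = best.stat);
}

// Permutation p-value of the observed max segment statistic, with
// sequential early stopping: once the number of null maxima >= obs makes
// p >= alpha certain for the full run, the scan is abandoned and the
// current conservative estimate is returned (only the p < alpha decision
// matters to the caller). p = (1 + #exceedances) / (1 + #permutations).
// [[Rcpp::export]]
double cpp_perm_pvalue(NumericVector x, int minlen, int nperm,
                       std::string method, double obs, double alpha) {
  int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  std::vector<int> ord(n);
  for (int k = 0; k < n; ++k) ord[k] = k;
  RNGScope scope;
  std::vector<double> P, rowtot;
  if (method != "t") {
    P.assign((size_t)(n + 1) * (n + 1), 0.0);
    rowtot.assign(n + 1, 0.0);
  }
  int exceed = 0;
  // smallest exceedance count that already forces p >= alpha
  int stop_at = (int)std::ceil(alpha * (1 + nperm) - 1.0);
  if (stop_at < 1) stop_at = 1;
  std::vector<double> xp(n);
  for (int p = 0; p < nperm; ++p) {
    shuffle_in_place(ord);
    double stat;
    if (method == "t") {
      for (int k = 0; k < n; ++k) xp[k] = v[ord[k]];
      stat = scan_t(xp, minlen).stat;
    } else {
      stat = scan_energy(v, ord, minlen, P, rowtot).stat;
    }
    if (stat >= obs) {
      ++exceed;
      if (exceed >= stop_at)
        return (double)(1 + exceed) / (double)(2 + p);
    }
  }
  return (double)(1 + exceed) / (double)(1 + nperm);
}
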