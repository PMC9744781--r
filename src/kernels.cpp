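// Hot loops of the EEG simulator and artifact-rejection scan.
//
// Randomness: the noise kernel uses an internal xoshiro256++ generator
// seeded from R's RNG at entry, so set.seed() fully determines the output
// while draws stay cheap enough for ~50M normals per simulated subject.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---- xoshiro256++ (public-domain algorithm) + polar Box-Muller ----------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(void) {
    // seed from R's RNG stream (reproducible under set.seed)
    for (int i = 0; i < 4; i++) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (uint64_t)0x9E3779B97F4A7C15ULL;
    }
    // avoid the all-zero state
    if ((s[0] | s[1] | s[2] | s[3]) == 0) s[0] = 1;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { // in (-1, 1)
    return ((int64_t)next() >> 10) * (1.0 / 9007199254740992.0);
  }
  double spare;
  bool has_spare = false;
  inline double rnorm() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u, v, q;
    do {
      u = runif();
      v = runif();
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// Shaped background-noise synthesis (see synthesize_noise() for the model).
// Per channel: broadband = white_w * x + pink_w * cascade(x) with x one
// standard-normal stream and the cascade n_sec first-order pole/zero
// sections (b0, b1, a1) approximating an f^(-alpha/2) magnitude; plus an
// envelope-modulated `alpha_hz` narrowband component with quadrature
// envelopes drawn at env_hz and linearly interpolated. Broadband is scaled
// (empirically, per channel) to sd_bb and the narrowband part to RMS
// alpha_rms. Returns an (n_ch x n) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_shaped_noise(int n, int n_ch,
                               NumericVector b0, NumericVector b1,
                               NumericVector a1,
                               double white_w, double pink_w,
                               double sd_bb,
                               double alpha_rms, double alpha_hz,
                               double env_hz, double fs) {
  NumericMatrix out(n_ch, n);
  if (sd_bb <= 0.0 && alpha_rms <= 0.0) return out;
  const int n_sec = b0.size();
  std::vector<double> x(n), y(n), al;
  std::vector<double> ct, st;
  if (alpha_rms > 0.0) {
    al.resize(n);
    ct.resize(n);
    st.resize(n);
    double w0 = 2.0 * M_PI * alpha_hz / fs;
    for (int t = 0; t < n; t++) {
      ct[t] = std::cos(w0 * t);
      st[t] = std::sin(w0 * t);
    }
  }
  const int n_env = (int)std::ceil(n * env_hz / fs) + 2;
  const double env_step = fs / env_hz;
  std::vector<double> ea(n_env), eb(n_env);
  std::vector<double> sx1(n_sec), sy1(n_sec), cb0(n_sec), cb1(n_sec),
      ca1(n_sec);
  for (int s = 0; s < n_sec; s++) {
    cb0[s] = b0[s];
    cb1[s] = b1[s];
    ca1[s] = a1[s];
  }
  GetRNGstate();
  Xoshiro rng;
  PutRNGstate();
  // generate channel-contiguous into tmp, blocked-transpose at the end
  std::vector<double> tmp((size_t)n * n_ch);
  for (int ch = 0; ch < n_ch; ch++) {
    // white stream, fused pink cascade, accumulate broadband moments
    std::fill(sx1.begin(), sx1.end(), 0.0);
    std::fill(sy1.begin(), sy1.end(), 0.0);
    double m = 0.0, m2 = 0.0;
    for (int t = 0; t < n; t++) {
      double w = rng.rnorm();
      x[t] = w;
      double v = w;
      for (int s = 0; s < n_sec; s++) {
        double o = cb0[s] * v + cb1[s] * sx1[s] - ca1[s] * sy1[s];
        sx1[s] = v;
        sy1[s] = o;
        v = o;
      }
      double bb = white_w * w + pink_w * v;
      y[t] = bb;
      m += bb;
      m2 += bb * bb;
    }
    m /= n;
    double sd = std::sqrt(std::max(0.0, m2 / n - m * m));
    double g = (sd > 0.0 && sd_bb > 0.0) ? sd_bb / sd : 0.0;
    double ga = 0.0;
    if (alpha_rms > 0.0) {
      for (int k = 0; k < n_env; k++) {
        ea[k] = rng.rnorm();
        eb[k] = rng.rnorm();
      }
      double s2 = 0.0;
      for (int t = 0; t < n; t++) {
        double pos = t / env_step;
        int k = (int)pos;
        double f = pos - k;
        double A = ea[k] * (1.0 - f) + ea[k + 1] * f;
        double B = eb[k] * (1.0 - f) + eb[k + 1] * f;
        double a = A * ct[t] + B * st[t];
        al[t] = a;
        s2 += a * a;
      }
      double rms = std::sqrt(s2 / n);
      ga = rms > 0.0 ? alpha_rms / rms : 0.0;
    }
    double *dst = tmp.data() + (size_t)ch * n;
    if (alpha_rms > 0.0) {
      for (int t = 0; t < n; t++) dst[t] = (y[t] - m) * g + ga * al[t];
    } else {
      for (int t = 0; t < n; t++) dst[t] = (y[t] - m) * g;
    }
  }
  // cache-blocked transpose: tmp (n x n_ch, channel-contiguous) -> out
  double *po = out.begin();
  const int B = 64;
  for (int c0 = 0; c0 < n_ch; c0 += B) {
    int c1 = std::min(n_ch, c0 + B);
    for (int t0 = 0; t0 < n; t0 += B) {
      int t1 = std::min(n, t0 + B);
      for (int c = c0; c < c1; c++) {
        const double *src = tmp.data() + (size_t)c * n;
        for (int t = t0; t < t1; t++) po[(size_t)t * n_ch + c] = src[t];
      }
    }
  }
  return out;
}

// Gather stimulus-locked epochs: returns (n_ch x n_t x n_ep) tensor, with
// epoch e spanning columns start_cols[e] .. start_cols[e] + n_t - 1
// (0-based) of `data`.
// [[Rcpp::export]]
NumericVector cpp_extract_epochs(NumericMatrix data, IntegerVector start_cols,
                                 int n_t) {
  int n_ch = data.nrow();
  int n_ep = start_cols.size();
  NumericVector out(Dimension(n_ch, n_t, n_ep));
  size_t len = (size_t)n_ch * n_t;
  const double *pd = data.begin();
  double *po = out.begin();
  for (int e = 0; e < n_ep; e++) {
    std::copy(pd + (size_t)start_cols[e] * n_ch,
              pd + (size_t)start_cols[e] * n_ch + len, po + e * len);
  }
  return out;
}

// Per-epoch peak-to-peak scan over a (n_ch x n_time x n_epoch) tensor.
// Returns a 2 x n_epoch matrix: row 1 = max over channels of within-epoch
// (max - min), row 2 = 1-based index of the worst channel.
// [[Rcpp::export]]
NumericMatrix cpp_peak_to_peak(NumericVector tensor, IntegerVector dims) {
  int n_ch = dims[0], n_t = dims[1], n_ep = dims[2];
  NumericMatrix out(2, n_ep);
  const double *p = tensor.begin();
  std::vector<double> mn(n_ch), mx(n_ch);
  for (int e = 0; e < n_ep; e++) {
    const double *ep = p + (size_t)e * n_ch * n_t;
    for (int c = 0; c < n_ch; c++) {
      mn[c] = ep[c];
      mx[c] = ep[c];
    }
    for (int t = 1; t < n_t; t++) {
      const double *col = ep + (size_t)t * n_ch;
      for (int c = 0; c < n_ch; c++) {
        double v = col[c];
        if (v < mn[c]) mn[c] = v;
        else if (v > mx[c]) mx[c] = v;
      }
    }
    double best = -1.0;
    int worst = 0;
    for (int c = 0; c < n_ch; c++) {
      double pp = mx[c] - mn[c];
      if (pp > best) {
        best = pp;
        worst = c;
      }
    }
    out(0, e) = best;
    out(1, e) = worst + 1;
  }
  return out;
}

// In-place addition of a pattern at each given onset column (0-based).
// `rows` (0-based) selects the data rows the pattern rows map onto, so
// near-zero channels can be skipped. `data` is modified in place.
// [[Rcpp::export]]
void cpp_add_pattern(NumericMatrix data, IntegerVector start_cols,
                     NumericMatrix pattern, IntegerVector rows) {
  int n_ch = data.nrow(), n = data.ncol();
  int pt = pattern.ncol(), pr = pattern.nrow();
  if (rows.size() != pr) stop("rows/pattern mismatch");
  double *pd = data.begin();
  const double *pp = pattern.begin();
  bool dense = (pr == n_ch);
  if (dense) {
    for (int c = 0; c < pr; c++) {
      if (rows[c] != c) { dense = false; break; }
    }
  }
  for (int k = 0; k < start_cols.size(); k++) {
    int s = start_cols[k];
    int t0 = s < 0 ? -s : 0;
    int t1 = std::min(pt, n - s);
    if (dense) { // contiguous, vectorizable
      for (int t = t0; t < t1; t++) {
        double *dc = pd + (size_t)(s + t) * n_ch;
        const double *pc = pp + (size_t)t * pr;
        for (int c = 0; c < pr; c++) dc[c] += pc[c];
      }
    } else {
      for (int t = t0; t < t1; t++) {
        double *dc = pd + (size_t)(s + t) * n_ch;
        const double *pc = pp + (size_t)t * pr;
        for (int c = 0; c < pr; c++) dc[rows[c]] += pc[c];
      }
    }
  }
}

// In-place baseline correction: subtract, per epoch and channel, the mean
// over the first n_pre samples.
// [[Rcpp::export]]
void cpp_baseline_correct(NumericVector tensor, IntegerVector dims,
                          int n_pre) {
  int n_ch = dims[0], n_t = dims[1], n_ep = dims[2];
  double *p = tensor.begin();
  std::vector<double> bl(n_ch);
  for (int e = 0; e < n_ep; e++) {
    double *ep = p + (size_t)e * n_ch * n_t;
    std::fill(bl.begin(), bl.end(), 0.0);
    for (int t = 0; t < n_pre; t++) {
      const double *col = ep + (size_t)t * n_ch;
      for (int c = 0; c < n_ch; c++) bl[c] += col[c];
    }
    for (int c = 0; c < n_ch; c++) bl[c] /= n_pre;
    for (int t = 0; t < n_t; t++) {
      double *col = ep + (size_t)t * n_ch;
      for (int c = 0; c < n_ch; c++) col[c] -= bl[c];
    }
  }
}

// Mean over kept epochs per group: returns (n_ch * n_t) x n_groups matrix.
// `group` is 1-based per epoch (0 = skip), `kept` a logical mask.
// [[Rcpp::export]]
NumericMatrix cpp_group_means(NumericVector tensor, IntegerVector dims,
                              IntegerVector group, LogicalVector kept,
                              int n_groups) {
  int n_ch = dims[0], n_t = dims[1], n_ep = dims[2];
  size_t len = (size_t)n_ch * n_t;
  NumericMatrix out((int)len, n_groups);
  std::vector<int> counts(n_groups, 0);
  const double *p = tensor.begin();
  double *po = out.begin();
  for (int e = 0; e < n_ep; e++) {
    if (!kept[e] || group[e] < 1) continue;
    int g = group[e] - 1;
    counts[g]++;
    const double *ep = p + (size_t)e * len;
    double *og = po + (size_t)g * len;
    for (size_t i = 0; i < len; i++) og[i] += ep[i];
  }
  for (int g = 0; g < n_groups; g++) {
    if (counts[g] == 0) continue;
    double inv = 1.0 / counts[g];
    double *og = po + (size_t)g * len;
    for (size_t i = 0; i < len; i++) og[i] *= inv;
  }
  out.attr("counts") = IntegerVector(counts.begin(), counts.end());
  return out;
}
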