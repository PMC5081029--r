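// Kinetic Monte Carlo engine for the coupled regulatory-unit filament.
//
// The normative scheme is synchronous discrete time: in each step of size
// dt every live RU independently changes state with probability rate*dt per
// allowed move, using neighbor states from the pre-step configuration.  The
// per-step survival of an RU whose hazards are constant is geometric, so
// instead of visiting every step the engine samples, for each RU, the step
// index of its next transition and advances event to event.  Timers are
// discarded and redrawn whenever an RU's hazard changes (a neighbor moved,
// the calcium concentration changed, or a protocol reset fired), which the
// memorylessness of the geometric law makes exactly equivalent to the
// naive per-step sweep.  Simultaneous transitions (equal step index) are
// resolved with pre-step neighbor states, as in the synchronous sweep.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int64_t FAR_FUTURE = INT64_C(4611686018427387904); // 2^62

static inline uint64_t splitmix64(uint64_t& x) {
  x += UINT64_C(0x9E3779B97F4A7C15);
  uint64_t z = x;
  z = (z ^ (z >> 30)) * UINT64_C(0xBF58476D1CE4E5B9);
  z = (z ^ (z >> 27)) * UINT64_C(0x94D049BB133111EB);
  return z ^ (z >> 31);
}

// xoshiro256++ (Blackman & Vigna); platform-independent stream per run
struct RunRng {
  uint64_t s[4];
  explicit RunRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on (0,1), never exactly 0 or 1
  double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) *
           (1.0 / 9007199254740992.0);
  }
};

// steps until next transition when per-step probability is p
static inline int64_t geom_steps(double p, RunRng& rng) {
  if (p <= 0.0) return FAR_FUTURE;
  double u = rng.unif();
  double k = std::floor(std::log(u) / std::log1p(-p)) + 1.0;
  if (!(k >= 1.0)) k = 1.0;
  if (k > 4.0e18) return FAR_FUTURE;
  return static_cast<int64_t>(k);
}

// tropomyosin level (0=B,1=C,2=M) of a six-state index (B0,B1,C0,C1,M0,M1)
static inline int tm_of(int s) { return s >> 1; }

// [[Rcpp::export]]
List engine_run(int n_live,
                NumericVector horiz,      // 9*6*6, ctx-major, ca-independent
                NumericVector ca_on,      // 6*6 coefficient on [Ca]
                double dt,
                int record_every,
                NumericVector ca_per_bin, // [Ca] during each record interval
                int n_runs,
                double seed,
                int reset_rec,            // record index of M->C reset, or -1
                int avg_start) {          // first record index of avg window
  if (n_live < 1) stop("n_live must be >= 1");
  if (n_runs < 1) stop("n_runs must be >= 1");
  if (dt <= 0) stop("dt must be > 0");
  if (record_every < 1) stop("record_every must be >= 1");
  const int n_bins = ca_per_bin.size();
  if (n_bins < 1) stop("need at least one record interval");
  const int n_rec = n_bins + 1;

  // per (ctx, state) constant part and calcium coefficient of the exit rate
  double tot_const[9][6], tot_ca[6];
  for (int c = 0; c < 9; ++c)
    for (int s = 0; s < 6; ++s) {
      double t = 0.0;
      for (int to = 0; to < 6; ++to) t += horiz[c * 36 + s * 6 + to];
      tot_const[c][s] = t;
    }
  for (int s = 0; s < 6; ++s) {
    double t = 0.0;
    for (int to = 0; to < 6; ++to) t += ca_on[s * 6 + to];
    tot_ca[s] = t;
  }

  std::vector<double> sumF(n_rec, 0.0), sumF2(n_rec, 0.0);
  std::vector<double> sumOcc(static_cast<size_t>(n_rec) * 6, 0.0);
  NumericVector run_means(n_runs);

  std::vector<int> state(n_live + 2);
  std::vector<int64_t> fire(n_live + 2);
  std::vector<int> fired;   fired.reserve(n_live);
  std::vector<int> newstate(n_live + 2);
  double ptot[9][6];

  uint64_t seed0 = static_cast<uint64_t>(seed);

  for (int run = 0; run < n_runs; ++run) {
    uint64_t sx = seed0 + UINT64_C(0x51ED2700) * (run + 1);
    RunRng rng(splitmix64(sx));

    // all live RUs start blocked and calcium-free; boundaries fixed at B0
    for (int i = 0; i < n_live + 2; ++i) state[i] = 0;
    double ca = -1.0;

    // context of live RU i (1-based position in the padded chain)
    auto ctx_of = [&](int i) {
      return tm_of(state[i - 1]) * 3 + tm_of(state[i + 1]);
    };
    auto resample = [&](int i, int64_t now) {
      double p = ptot[ctx_of(i)][state[i]];  // already a per-step probability
      fire[i] = (p <= 0.0) ? FAR_FUTURE : now + geom_steps(p, rng);
    };

    // record index 0 = initial condition
    auto record = [&](int rec) {
      int m = 0;
      for (int i = 1; i <= n_live; ++i) {
        sumOcc[static_cast<size_t>(rec) * 6 + state[i]] += 1.0;
        if (tm_of(state[i]) == 2) ++m;
      }
      double f = static_cast<double>(m) / n_live;
      sumF[rec] += f;
      sumF2[rec] += f * f;
      return f;
    };
    double f0 = record(0);
    double wsum = 0.0;
    int wn = 0;
    if (avg_start <= 0) { wsum += f0; ++wn; }

    int64_t now = 0;
    for (int bin = 0; bin < n_bins; ++bin) {
      double ca_bin = ca_per_bin[bin];
      if (bin == 0 || ca_bin != ca) {
        ca = ca_bin;
        for (int c = 0; c < 9; ++c)
          for (int s = 0; s < 6; ++s) {
            double p = (tot_const[c][s] + ca * tot_ca[s]) * dt;
            if (p > 1.0 + 1e-12)
              stop("time-step violation: cumulative transition probability "
                   "%f > 1; decrease dt", p);
            ptot[c][s] = p;
          }
        for (int i = 1; i <= n_live; ++i) resample(i, now);
      }
      int64_t end_step = static_cast<int64_t>(bin + 1) * record_every;

      for (;;) {
        int64_t mstep = FAR_FUTURE;
        for (int i = 1; i <= n_live; ++i)
          if (fire[i] < mstep) mstep = fire[i];
        if (mstep > end_step) break;

        fired.clear();
        for (int i = 1; i <= n_live; ++i)
          if (fire[i] == mstep) fired.push_back(i);

        // choose destinations with pre-step neighbor states
        for (size_t k = 0; k < fired.size(); ++k) {
          int i = fired[k];
          int c = ctx_of(i);
          int s = state[i];
          double r[6], tot = 0.0;
          for (int to = 0; to < 6; ++to) {
            r[to] = horiz[c * 36 + s * 6 + to] + ca * ca_on[s * 6 + to];
            tot += r[to];
          }
          int to = s;
          if (tot > 0.0) {
            double target = rng.unif() * tot, acc = 0.0;
            for (int j = 0; j < 6; ++j) {
              if (r[j] <= 0.0) continue;
              acc += r[j];
              to = j;
              if (target <= acc) break;
            }
          }
          newstate[i] = to;
        }
        for (size_t k = 0; k < fired.size(); ++k)
          state[fired[k]] = newstate[fired[k]];
        // redraw timers for fired RUs and their live neighbors
        for (size_t k = 0; k < fired.size(); ++k) {
          int i = fired[k];
          for (int j = i - 1; j <= i + 1; ++j)
            if (j >= 1 && j <= n_live) fire[j] = -1; // mark
        }
        for (int i = 1; i <= n_live; ++i)
          if (fire[i] == -1) resample(i, mstep);
      }

      now = end_step;
      // protocol reset: all open RUs dropped back to closed (M0->C0, M1->C1)
      if (reset_rec >= 0 && bin + 1 == reset_rec) {
        for (int i = 1; i <= n_live; ++i)
          if (tm_of(state[i]) == 2) state[i] -= 2;
        for (int i = 1; i <= n_live; ++i) resample(i, now);
      }
      double f = record(bin + 1);
      if (bin + 1 >= avg_start) { wsum += f; ++wn; }
    }
    run_means[run] = (wn > 0) ? wsum / wn : NA_REAL;
  }

  NumericVector meanF(n_rec), semF(n_rec);
  NumericMatrix occ(n_rec, 6);
  for (int k = 0; k < n_rec; ++k) {
    double m = sumF[k] / n_runs;
    meanF[k] = m;
    if (n_runs > 1) {
      double var = (sumF2[k] - n_runs * m * m) / (n_runs - 1);
      if (var < 0) var = 0;
      semF[k] = std::sqrt(var / n_runs);
    } else {
      semF[k] = NA_REAL;
    }
    for (int s = 0; s < 6; ++s)
      occ(k, s) = sumOcc[static_cast<size_t>(k) * 6 + s] / (n_runs *
                  static_cast<double>(n_live));
  }
  return List::create(_["force"] = meanF, _["force_sem"] = semF,
                      _["occupancy"] = occ, _["run_means"] = run_means);
}
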