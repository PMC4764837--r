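// Batch trial integrator for the multi-module attractor network.
//
// Dynamics per module k and option population i in {A, B}:
//   ds/dt = -s/tau + gamma * (1 - s) * r,   r = phi(I_rec + I0 + I_ext + eta)
// with recurrent current under uniform inter-module coupling IC
//   I_rec(k,i) = sum_j w_ij * [(1 - IC) s_j^k + IC * mean_l s_j^l],
// eta an Ornstein-Uhlenbeck background current (exact discretization), and
// phi the effective f-I curve phi(I) = (aI - b) / (1 - exp(-d(aI - b))).
//
// Votes latch at the first lambda crossing; the trial stops at a strict
// majority (free-response) or at stimulus offset (forced choice).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: the integrator draws ~10^6 normals
// per trial, which R's RNG API is too slow for. Seeds come from R's RNG so
// set.seed() still governs reproducibility.
struct Xoshiro {
  uint64_t s[4];
  double spare;
  bool has_spare;

  explicit Xoshiro(uint64_t seed) : has_spare(false) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return (static_cast<double>(next() >> 11) + 0.5) * 1.1102230246251565e-16;
  }
  inline double norm() {  // Box-Muller
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 6.283185307179586 * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

// f-I transfer with a series branch through the removable singularity at
// a*I = b, where the limit is 1/d.
inline double phi(double I, double a, double b, double d) {
  const double x = a * I - b;
  const double u = d * x;
  if (std::fabs(u) < 1e-4) {
    return (1.0 + 0.5 * u + u * u / 12.0) / d;
  }
  if (u < -700.0) return 0.0;  // denominator overflows; rate underflows to 0
  return x / (1.0 - std::exp(-u));
}

}  // namespace

// [[Rcpp::export(name = ".sim_trials_cpp")]]
List sim_trials_cpp(List par, List stim_currents, double frame_s, double onset,
                    double max_t, std::string stop_rule, NumericVector seeds,
                    int record_stride) {
  const int N = as<int>(par["n_modules"]);
  const double ic = as<double>(par["ic"]);
  const double tau = as<double>(par["tau_nmda"]);
  const double gamma = as<double>(par["gamma"]);
  const double w_same = as<double>(par["w_same"]);
  const double w_diff = as<double>(par["w_diff"]);
  const double fa = as<double>(par["fi_a"]);
  const double fb = as<double>(par["fi_b"]);
  const double fd = as<double>(par["fi_d"]);
  const double i0 = as<double>(par["i0"]);
  const double ou_tau = as<double>(par["ou_tau"]);
  const double ou_var = as<double>(par["ou_var"]);
  const double lambda = as<double>(par["lambda_thr"]);
  const double dt = as<double>(par["dt"]);

  const int n_trials = stim_currents.size();
  const bool forced = (stop_rule == "offset");
  const int max_steps = static_cast<int>(std::ceil(max_t / dt - 1e-9));

  const double ou_decay = std::exp(-dt / ou_tau);
  const double ou_sd = std::sqrt(ou_var * (1.0 - ou_decay * ou_decay));

  IntegerVector choice(n_trials);  // 1 = A, 2 = B, 0 = undecided
  NumericVector rt(n_trials, NA_REAL);
  LogicalVector early(n_trials);
  IntegerMatrix vote_opt(n_trials, N);
  NumericMatrix vote_time(n_trials, N);
  NumericMatrix rates_A(n_trials, N), rates_B(n_trials, N);
  std::fill(vote_time.begin(), vote_time.end(), NA_REAL);

  // optional dense recording (single-trial traces)
  const bool record = record_stride > 0;
  std::vector<double> rec_t, rec_r, rec_s;
  if (record && n_trials != 1)
    stop("trace recording is only supported for a single trial");

  std::vector<double> s(2 * N), eta(2 * N), r(2 * N);

  for (int tr = 0; tr < n_trials; ++tr) {
    NumericMatrix I_stim = as<NumericMatrix>(stim_currents[tr]);
    const int n_frames = I_stim.nrow();
    Xoshiro rng(static_cast<uint64_t>(seeds[tr]));

    std::fill(s.begin(), s.end(), 0.0);
    std::fill(eta.begin(), eta.end(), 0.0);
    std::vector<int> vopt(N, 0);
    std::vector<double> vtime(N, NA_REAL);
    int votes_A = 0, votes_B = 0;
    int done_choice = 0;
    double done_t = NA_REAL;
    bool stopped = false;

    for (int step = 0; step < max_steps && !stopped; ++step) {
      const double t_now = step * dt;
      const double t_next = t_now + dt;

      // stimulus current, piecewise constant on the frame grid
      double Iext_A = 0.0, Iext_B = 0.0;
      if (t_now >= onset) {
        int f = static_cast<int>((t_now - onset) / frame_s + 1e-9);
        if (f < n_frames) {
          Iext_A = I_stim(f, 0);
          Iext_B = I_stim(f, 1);
        }
      }

      double sbar_A = 0.0, sbar_B = 0.0;
      if (ic > 0.0) {
        for (int k = 0; k < N; ++k) {
          sbar_A += s[2 * k];
          sbar_B += s[2 * k + 1];
        }
        sbar_A /= N;
        sbar_B /= N;
      }

      for (int k = 0; k < N; ++k) {
        double &eA = eta[2 * k], &eB = eta[2 * k + 1];
        eA = eA * ou_decay + ou_sd * rng.norm();
        eB = eB * ou_decay + ou_sd * rng.norm();

        const double sA = s[2 * k], sB = s[2 * k + 1];
        const double mix_A = (1.0 - ic) * sA + ic * sbar_A;
        const double mix_B = (1.0 - ic) * sB + ic * sbar_B;
        const double I_A = w_same * mix_A + w_diff * mix_B + i0 + Iext_A + eA;
        const double I_B = w_same * mix_B + w_diff * mix_A + i0 + Iext_B + eB;
        const double rA = phi(I_A, fa, fb, fd);
        const double rB = phi(I_B, fa, fb, fd);
        if (!std::isfinite(rA) || !std::isfinite(rB))
          stop("non-finite firing rate in module %d at t = %f s", k + 1, t_next);
        r[2 * k] = rA;
        r[2 * k + 1] = rB;

        if (vopt[k] == 0 && (rA >= lambda || rB >= lambda)) {
          // ties within one step go to the higher rate, then to option A
          int v = (rA >= rB) ? 1 : 2;
          if (rA < lambda) v = 2;
          if (rB < lambda) v = 1;
          vopt[k] = v;
          vtime[k] = t_next;
          if (v == 1) ++votes_A; else ++votes_B;
        }

        double ds_A = dt * (-sA / tau + gamma * (1.0 - sA) * rA);
        double ds_B = dt * (-sB / tau + gamma * (1.0 - sB) * rB);
        double nsA = sA + ds_A, nsB = sB + ds_B;
        s[2 * k] = nsA < 0.0 ? 0.0 : (nsA > 1.0 ? 1.0 : nsA);
        s[2 * k + 1] = nsB < 0.0 ? 0.0 : (nsB > 1.0 ? 1.0 : nsB);
      }

      if (record && (step % record_stride == 0 || step == max_steps - 1)) {
        rec_t.push_back(t_next);
        for (int k = 0; k < N; ++k) {
          rec_r.push_back(r[2 * k]);
          rec_r.push_back(r[2 * k + 1]);
          rec_s.push_back(s[2 * k]);
          rec_s.push_back(s[2 * k + 1]);
        }
      }

      if (!forced && done_choice == 0) {
        if (2 * votes_A > N) {
          done_choice = 1;
        } else if (2 * votes_B > N) {
          done_choice = 2;
        }
        if (done_choice != 0) {
          done_t = t_next;
          stopped = true;
        }
      }
    }

    if (forced) {
      // decision forced at integration end: majority of latched votes,
      // ties broken by the higher mean rate across modules
      done_t = max_steps * dt;
      if (votes_A != votes_B) {
        done_choice = votes_A > votes_B ? 1 : 2;
      } else {
        double mA = 0.0, mB = 0.0;
        for (int k = 0; k < N; ++k) {
          mA += r[2 * k];
          mB += r[2 * k + 1];
        }
        done_choice = (mA >= mB) ? 1 : 2;
      }
    }

    choice[tr] = done_choice;
    rt[tr] = done_choice != 0 ? done_t : NA_REAL;
    early[tr] = (done_choice != 0) && (done_t < onset);
    for (int k = 0; k < N; ++k) {
      vote_opt(tr, k) = vopt[k];
      vote_time(tr, k) = vtime[k];
      rates_A(tr, k) = r[2 * k];
      rates_B(tr, k) = r[2 * k + 1];
    }
  }

  List out = List::create(
      _["choice"] = choice, _["rt"] = rt, _["early"] = early,
      _["vote_opt"] = vote_opt, _["vote_time"] = vote_time,
      _["rates_a"] = rates_A, _["rates_b"] = rates_B);

  if (record) {
    const int n_rec = rec_t.size();
    NumericVector times(rec_t.begin(), rec_t.end());
    NumericVector rates(rec_r.begin(), rec_r.end());
    NumericVector gating(rec_s.begin(), rec_s.end());
    // layout: (option fastest, then module, then time)
    rates.attr("dim") = IntegerVector::create(2, N, n_rec);
    gating.attr("dim") = IntegerVector::create(2, N, n_rec);
    out["trace_times"] = times;
    out["trace_rates"] = rates;
    out["trace_s"] = gating;
  }
  return out;
}
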