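// Core replicate engine for the roving-payoff model.
//
// A foray is one departure of the focal male from his territory.  Within a
// foray every EPC-seeking male (the focal male plus rival rovers and
// wanderers) performs a copulation search of `attempts` sequential uniform
// tile draws.  A draw that lands inside an available unguarded territory is
// a copulation; a rival landing on the focal male's own female cuckolds him
// (at most once per foray).  Two within-search depletion dialects are
// supported:
//   per_attempt_minus1   : every attempt excludes one visited tile, so the
//                          attempt probabilities are TU/(T-1), (TU-1)/(T-2),
//                          (TU-2)/(T-3); territories are never removed.
//   per_territory_minus40: a successful visit removes the whole territory
//                          (territory_tiles tiles) from the field, making
//                          that female unavailable for the rest of the foray.
// With shared_depletion the seekers of one foray deplete a common pool in
// uniformly random order; otherwise each seeker searches the fresh field.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

namespace {

// xoshiro256++ seeded through splitmix64: fast, portable, reproducible
// independently of R's global RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) { return static_cast<int>(unif() * n); }
};

enum Depletion { MINUS1 = 0, MINUS40 = 1 };

// Per-foray mutable field state (counts only; territories are exchangeable
// apart from ownership, so partner territories are tracked by id).
struct ForayState {
  std::vector<int> avail;        // ids of available rival-partner territories
  std::vector<char> avail_flag;  // indexed by partner id
  int n_unpaired;                // available unpaired-female territories
  bool fem_avail;                // focal female targetable by rivals
  long T_now;                    // current total tiles (minus40 shrinks it)
  int sh_u, sh_t;                // accumulated tile exclusions (minus1+shared)
};

struct Undo {
  enum Kind { PARTNER, UNPAIRED, FEM } kind;
  int victim, idx;
};

struct SearchResult {
  int e;        // copulations gained by this seeker
  bool hit_fem; // landed on the focal male's female (rivals only)
};

// One seeker's copulation search. own = partner id of a rival rover (his own
// female is not a target), -1 for the focal male and for wanderers.
// is_rival: the focal female is in the target pool.
SearchResult run_search(ForayState& st, Xoshiro& rng, int attempts,
                        int terr, int own, bool is_rival, int depletion,
                        std::vector<Undo>* undo_log) {
  SearchResult res{0, false};
  // minus1 keeps the eligible-territory count fixed for the whole search
  const int elig0 = static_cast<int>(st.avail.size())
    - ((own >= 0 && st.avail_flag[own]) ? 1 : 0)
    + st.n_unpaired + ((is_rival && st.fem_avail) ? 1 : 0);

  for (int k = 1; k <= attempts; ++k) {
    int elig, ep;
    double p;
    if (depletion == MINUS1) {
      elig = elig0;
      ep = static_cast<int>(st.avail.size())
        - ((own >= 0 && st.avail_flag[own]) ? 1 : 0);
      double num = static_cast<double>(terr) * elig0 - (k - 1) - st.sh_u;
      double den = static_cast<double>(st.T_now) - k - st.sh_t;
      p = (num <= 0.0 || den <= 0.0) ? 0.0 : num / den;
    } else {
      ep = static_cast<int>(st.avail.size())
        - ((own >= 0 && st.avail_flag[own]) ? 1 : 0);
      elig = ep + st.n_unpaired + ((is_rival && st.fem_avail) ? 1 : 0);
      double den = static_cast<double>(st.T_now) - 1.0;
      p = (elig <= 0 || den <= 0.0)
        ? 0.0 : static_cast<double>(terr) * elig / den;
    }
    if (p > 1.0) p = 1.0;
    if (p <= 0.0 || rng.unif() >= p) continue;

    // success: the visited territory is uniform among eligible ones
    res.e += 1;
    int j = rng.below(elig);
    if (j < ep) {
      if (depletion == MINUS40) {
        int idx;
        do { idx = rng.below(static_cast<int>(st.avail.size())); }
        while (own >= 0 && st.avail[idx] == own);
        int victim = st.avail[idx];
        st.avail[idx] = st.avail.back();
        st.avail.pop_back();
        st.avail_flag[victim] = 0;
        st.T_now -= terr;
        if (undo_log) undo_log->push_back({Undo::PARTNER, victim, idx});
      }
    } else if (j < ep + st.n_unpaired) {
      if (depletion == MINUS40) {
        st.n_unpaired -= 1;
        st.T_now -= terr;
        if (undo_log) undo_log->push_back({Undo::UNPAIRED, 0, 0});
      }
    } else {
      // focal female: a cuckolding visit, she is visited by one male at most
      res.hit_fem = true;
      if (depletion == MINUS40) {
        st.fem_avail = false;
        st.T_now -= terr;
        if (undo_log) undo_log->push_back({Undo::FEM, 0, 0});
      } else {
        st.fem_avail = false;  // at most one visit per foray in both dialects
        if (undo_log) undo_log->push_back({Undo::FEM, 0, 0});
      }
    }
  }
  return res;
}

void apply_undo(ForayState& st, std::vector<Undo>& log, int terr,
                int depletion) {
  for (int i = static_cast<int>(log.size()) - 1; i >= 0; --i) {
    const Undo& u = log[i];
    switch (u.kind) {
    case Undo::PARTNER:
      if (u.idx == static_cast<int>(st.avail.size())) {
        st.avail.push_back(u.victim);
      } else {
        st.avail.push_back(st.avail[u.idx]);
        st.avail[u.idx] = u.victim;
      }
      st.avail_flag[u.victim] = 1;
      st.T_now += terr;
      break;
    case Undo::UNPAIRED:
      st.n_unpaired += 1;
      st.T_now += terr;
      break;
    case Undo::FEM:
      st.fem_avail = true;
      if (depletion == MINUS40) st.T_now += terr;
      break;
    }
  }
  log.clear();
}

// Exact per-foray probability that one rival with `elig` eligible
// territories (the focal female among them) never visits the focal female
// during a fresh-field search. Used by the closed-form rival mode.
double p_no_fem_hit(int attempts, int terr, long T, int elig, int depletion,
                    int k = 1) {
  if (k > attempts || elig <= 0) return 1.0;
  if (depletion == MINUS1) {
    double out = 1.0;
    for (int a = k; a <= attempts; ++a) {
      double num = static_cast<double>(terr) * elig - (a - 1);
      double den = static_cast<double>(T) - a;
      double p = (num <= 0.0 || den <= 0.0) ? 0.0 : num / den;
      if (p > 1.0) p = 1.0;
      out *= (1.0 - p / elig);
    }
    return out;
  }
  double den = static_cast<double>(T) - 1.0;
  double p = (den <= 0.0) ? 0.0 : static_cast<double>(terr) * elig / den;
  if (p > 1.0) p = 1.0;
  double p_fem = p / elig;
  double p_other = p - p_fem;
  return (1.0 - p) * p_no_fem_hit(attempts, terr, T, elig, depletion, k + 1)
    + p_other * p_no_fem_hit(attempts, terr, T - terr, elig - 1, depletion,
                             k + 1);
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::IntegerMatrix cpp_simulate(int n_reps, int forays, int attempts,
                                 double total_tiles, int territory_tiles,
                                 int n_partner_terrs, int n_unpaired_fem,
                                 int n_wanderers, bool focal_roving,
                                 bool focal_searches, int depletion,
                                 bool shared, bool rival_closed_form,
                                 double seed) {
  if (n_reps < 0) Rcpp::stop("n_reps must be non-negative");
  if (total_tiles < 2) Rcpp::stop("total_tiles must be at least 2");
  if (shared && rival_closed_form)
    Rcpp::stop("closed-form rival mode requires independent (non-shared) searches");

  Xoshiro rng(static_cast<uint64_t>(seed));
  Rcpp::IntegerMatrix out(n_reps, 2);
  colnames(out) = Rcpp::CharacterVector::create("E", "C");

  const int n_rivals = n_partner_terrs + n_wanderers;
  // seekers: -1 focal, 0..n_partner_terrs-1 rival rovers, -2 wanderers
  std::vector<int> seekers;
  if (focal_searches) seekers.push_back(-1);
  for (int i = 0; i < n_partner_terrs; ++i) seekers.push_back(i);
  for (int i = 0; i < n_wanderers; ++i) seekers.push_back(-2);

  // closed-form per-foray cuckolding probability (fresh field each foray)
  double c_prob = 0.0;
  if (rival_closed_form && focal_roving && n_rivals > 0) {
    double p_no = 1.0;
    if (n_partner_terrs > 0) {
      int elig_r = (n_partner_terrs - 1) + n_unpaired_fem + 1;
      p_no *= std::pow(p_no_fem_hit(attempts, territory_tiles,
                                    static_cast<long>(total_tiles), elig_r,
                                    depletion),
                       static_cast<double>(n_partner_terrs));
    }
    if (n_wanderers > 0) {
      int elig_w = n_partner_terrs + n_unpaired_fem + 1;
      p_no *= std::pow(p_no_fem_hit(attempts, territory_tiles,
                                    static_cast<long>(total_tiles), elig_w,
                                    depletion),
                       static_cast<double>(n_wanderers));
    }
    c_prob = 1.0 - p_no;
  }

  ForayState st;
  std::vector<Undo> undo;
  std::vector<int> order(seekers.size());

  for (int rep = 0; rep < n_reps; ++rep) {
    int E = 0, C = 0;
    for (int f = 0; f < forays; ++f) {
      // fresh field view: all within-foray depletion is discarded
      st.avail.resize(n_partner_terrs);
      for (int i = 0; i < n_partner_terrs; ++i) st.avail[i] = i;
      st.avail_flag.assign(n_partner_terrs, 1);
      st.n_unpaired = n_unpaired_fem;
      st.fem_avail = focal_roving;
      st.T_now = static_cast<long>(total_tiles);
      st.sh_u = 0;
      st.sh_t = 0;

      int c_foray = 0;
      if (rival_closed_form) {
        if (focal_searches) {
          SearchResult r = run_search(st, rng, attempts, territory_tiles, -1,
                                      false, depletion, NULL);
          E += r.e;
        }
        if (c_prob > 0.0 && rng.unif() < c_prob) c_foray = 1;
      } else {
        const int ns = static_cast<int>(seekers.size());
        for (int i = 0; i < ns; ++i) order[i] = seekers[i];
        if (shared) {
          // uniformly random seeker order: simultaneity surrogate
          for (int i = ns - 1; i > 0; --i) {
            int j = rng.below(i + 1);
            std::swap(order[i], order[j]);
          }
        }
        for (int i = 0; i < ns; ++i) {
          int who = order[i];
          bool is_focal = (who == -1);
          int own = (who >= 0) ? who : -1;
          SearchResult r = run_search(st, rng, attempts, territory_tiles, own,
                                      !is_focal, depletion,
                                      shared ? NULL : &undo);
          if (is_focal) E += r.e;
          else if (r.hit_fem) c_foray = 1;
          if (!shared) apply_undo(st, undo, territory_tiles, depletion);
          if (shared && depletion == MINUS1) {
            st.sh_u += attempts;  // visited tiles stay excluded this foray
            st.sh_t += attempts;
          }
        }
      }
      C += c_foray;
    }
    out(rep, 0) = E;
    out(rep, 1) = C;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_cuckold_prob")]]
double cpp_cuckold_prob(int attempts, double total_tiles, int territory_tiles,
                        int n_partner_terrs, int n_unpaired_fem,
                        int n_wanderers, int depletion) {
  double p_no = 1.0;
  if (n_partner_terrs > 0) {
    int elig_r = (n_partner_terrs - 1) + n_unpaired_fem + 1;
    p_no *= std::pow(p_no_fem_hit(attempts, territory_tiles,
                                  static_cast<long>(total_tiles), elig_r,
                                  depletion),
                     static_cast<double>(n_partner_terrs));
  }
  if (n_wanderers > 0) {
    int elig_w = n_partner_terrs + n_unpaired_fem + 1;
    p_no *= std::pow(p_no_fem_hit(attempts, territory_tiles,
                                  static_cast<long>(total_tiles), elig_w,
                                  depletion),
                     static_cast<double>(n_wanderers));
  }
  return 1.0 - p_no;
}
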