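// Asynchronous probabilistic Boolean network engine.
//
// Rules arrive as concatenated reverse-Polish integer code:
//   token >= 0 : node index (0-based)
//   -1 NOT, -2 AND, -3 OR, -4 constant FALSE, -5 constant TRUE
//
// Randomness is a SplitMix64 counter stream: repetition r of a run seeded
// with s draws from the stream seeded by s*GOLDEN + r, so simulations are
// bit-reproducible across platforms and extending n_reps never reshuffles
// earlier repetitions.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const uint64_t GOLDEN = 0x9E3779B97F4A7C15ULL;

static inline uint64_t splitmix64(uint64_t &x) {
  x += GOLDEN;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t &s) {
  return (splitmix64(s) >> 11) * (1.0 / 9007199254740992.0);
}

static bool eval_rpn(const int *code, int len,
                     const std::vector<uint8_t> &state,
                     std::vector<uint8_t> &stack) {
  size_t sp = 0;
  for (int k = 0; k < len; ++k) {
    int tok = code[k];
    if (tok >= 0) {
      stack[sp++] = state[tok];
    } else if (tok == -1) {
      stack[sp - 1] = !stack[sp - 1];
    } else if (tok == -2) {
      stack[sp - 2] = stack[sp - 2] && stack[sp - 1];
      --sp;
    } else if (tok == -3) {
      stack[sp - 2] = stack[sp - 2] || stack[sp - 1];
      --sp;
    } else if (tok == -4) {
      stack[sp++] = 0;
    } else {
      stack[sp++] = 1;
    }
  }
  return stack[0] != 0;
}

// Monte-Carlo ensemble of asynchronous random walks.
//
// code/offset/len: per-node RPN programs (offset 0-based into code).
// init_p: per-node ON-probability at step 0.
// forced: per-node -1 (free) or 0/1 (pinned).
// Returns (n_steps+1) x n matrix of ON-frequencies across repetitions.
// [[Rcpp::export]]
NumericMatrix pbn_simulate_cpp(IntegerVector code, IntegerVector offset,
                               IntegerVector len, NumericVector init_p,
                               IntegerVector forced, int n_steps, int n_reps,
                               double seed) {
  const int n = init_p.size();
  NumericMatrix counts(n_steps + 1, n);
  std::vector<uint8_t> state(n), stack(code.size() + 1);
  std::vector<int> flippable(n);
  const int *codep = INTEGER(code);
  const uint64_t base = (uint64_t)(int64_t)seed * GOLDEN;

  for (int rep = 0; rep < n_reps; ++rep) {
    uint64_t rng = base + (uint64_t)rep;
    splitmix64(rng);  // warm up: decorrelate nearby counters
    for (int i = 0; i < n; ++i) {
      state[i] = unif01(rng) < init_p[i] ? 1 : 0;
      if (forced[i] >= 0) state[i] = (uint8_t)forced[i];
    }
    for (int i = 0; i < n; ++i) counts(0, i) += state[i];
    for (int t = 1; t <= n_steps; ++t) {
      int k = 0;
      for (int i = 0; i < n; ++i) {
        if (forced[i] >= 0) continue;
        bool target = eval_rpn(codep + offset[i], len[i], state, stack);
        if (target != (state[i] != 0)) flippable[k++] = i;
      }
      if (k > 0) {
        int pick = (int)(unif01(rng) * k);
        if (pick >= k) pick = k - 1;
        state[flippable[pick]] ^= 1;
      }
      for (int i = 0; i < n; ++i) counts(t, i) += state[i];
    }
  }
  for (int t = 0; t <= n_steps; ++t)
    for (int i = 0; i < n; ++i) counts(t, i) /= n_reps;
  return counts;
}

// Enumerate the asynchronous transition structure over the free-node state
// space. States are indexed by the bits of the free nodes (free node j is
// bit j). Returns, for each state, the free-node indices whose rule output
// disagrees with the current value (the flippable set U).
// [[Rcpp::export]]
List pbn_transitions_cpp(IntegerVector code, IntegerVector offset,
                         IntegerVector len, IntegerVector forced,
                         IntegerVector free_idx) {
  const int n = forced.size();
  const int m = free_idx.size();
  if (m > 25) stop("state space too large");
  const size_t S = (size_t)1 << m;
  std::vector<uint8_t> state(n), stack(code.size() + 1);
  const int *codep = INTEGER(code);
  List out(S);
  for (size_t s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) state[i] = forced[i] >= 0 ? forced[i] : 0;
    for (int j = 0; j < m; ++j)
      if (s & ((size_t)1 << j)) state[free_idx[j]] = 1;
    std::vector<int> flips;
    for (int j = 0; j < m; ++j) {
      int i = free_idx[j];
      bool target = eval_rpn(codep + offset[i], len[i], state, stack);
      if (target != (state[i] != 0)) flips.push_back(j);
    }
    out[s] = wrap(flips);
  }
  return out;
}
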