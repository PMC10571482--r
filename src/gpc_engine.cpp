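#include <Rcpp.h>
using namespace Rcpp;

// The engine works from per-outcome score matrices S_k (n x n, values in
// {-1, 0, 1}) where S_k(i, j) is the single-outcome score of subject i
// taken as treated against subject j taken as control.  The matrices are
// antisymmetric by construction (built in R from the rate table and the
// outcome specs), so any relabelling of arms is a row/column selection —
// this is what makes the permutation loop cheap.

namespace {

struct GpcTally {
  double delta, wins, losses, neutral;
  std::vector<double> deciding; // K + 1 slots; last = fully neutral pairs
};

inline GpcTally eval_split(const std::vector<IntegerMatrix> &S,
                           const std::vector<int> &tidx,
                           const std::vector<int> &cidx,
                           bool prioritized,
                           const NumericVector &weights) {
  const int K = S.size();
  const int nt = tidx.size(), nc = cidx.size();
  GpcTally out{0.0, 0.0, 0.0, 0.0, std::vector<double>(K + 1, 0.0)};
  double sum = 0.0;
  for (int a = 0; a < nt; ++a) {
    const int i = tidx[a];
    for (int b = 0; b < nc; ++b) {
      const int j = cidx[b];
      if (prioritized) {
        int s = 0, k = 0;
        for (; k < K; ++k) {
          s = S[k](i, j);
          if (s != 0) break;
        }
        sum += s;
        if (s > 0) out.wins += 1.0;
        else if (s < 0) out.losses += 1.0;
        else out.neutral += 1.0;
        out.deciding[s == 0 ? K : k] += 1.0;
      } else {
        double s = 0.0;
        for (int k = 0; k < K; ++k) s += weights[k] * S[k](i, j);
        sum += s;
        if (s > 0) out.wins += s;
        else if (s < 0) out.losses += -s;
        else out.neutral += 0.0;
      }
    }
  }
  const double np = static_cast<double>(nt) * nc;
  out.delta = np > 0 ? sum / np : 0.0;
  if (!prioritized) out.neutral = np - out.wins - out.losses;
  return out;
}

std::vector<IntegerMatrix> as_mats(List S) {
  std::vector<IntegerMatrix> mats;
  mats.reserve(S.size());
  for (int k = 0; k < S.size(); ++k) mats.push_back(as<IntegerMatrix>(S[k]));
  return mats;
}

} // namespace

// Evaluate one arm split.  S: list of K n x n integer score matrices,
// ordered by priority (prioritized mode) or matching `weights`
// (non-prioritized).  tidx/cidx: 1-based subject indices per arm.
// [[Rcpp::export]]
List cpp_gpc_eval(List S, IntegerVector tidx, IntegerVector cidx,
                  bool prioritized, NumericVector weights) {
  std::vector<IntegerMatrix> mats = as_mats(S);
  std::vector<int> t(tidx.begin(), tidx.end()), c(cidx.begin(), cidx.end());
  for (int &v : t) --v;
  for (int &v : c) --v;
  GpcTally r = eval_split(mats, t, c, prioritized, weights);
  return List::create(_["delta"] = r.delta, _["wins"] = r.wins,
                      _["losses"] = r.losses, _["neutral"] = r.neutral,
                      _["deciding"] = NumericVector(r.deciding.begin(),
                                                    r.deciding.end()));
}

// Net-benefit statistics over pre-drawn label permutations.  Each row of
// `perms` is a permutation of 1..n; its first n_t entries are taken as the
// treated arm.  Returns the vector of permuted deltas.
// [[Rcpp::export]]
NumericVector cpp_perm_deltas(List S, IntegerMatrix perms, int n_t,
                              bool prioritized, NumericVector weights) {
  std::vector<IntegerMatrix> mats = as_mats(S);
  const int B = perms.nrow(), n = perms.ncol();
  NumericVector deltas(B);
  std::vector<int> t(n_t), c(n - n_t);
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < n_t; ++j) t[j] = perms(b, j) - 1;
    for (int j = n_t; j < n; ++j) c[j - n_t] = perms(b, j) - 1;
    deltas[b] = eval_split(mats, t, c, prioritized, weights).delta;
  }
  return deltas;
}
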