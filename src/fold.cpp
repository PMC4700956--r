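#include <Rcpp.h>
#include <vector>
#include <string>
#include <set>
using namespace Rcpp;

// Maximum base-pairing (Nussinov) folding engine with G.U wobble and a
// minimum hairpin loop of 3 unpaired nucleotides.  Serves as the built-in
// folding backend: the objective is the pair count (energy = -pairs).

static inline bool can_pair(char a, char b) {
  switch (a) {
    case 'A': return b == 'T' || b == 'U';
    case 'C': return b == 'G';
    case 'G': return b == 'C' || b == 'T' || b == 'U';
    case 'T':
    case 'U': return b == 'A' || b == 'G';
    default:  return false;
  }
}

static const int MIN_LOOP = 3;

// deterministic pseudo-random tie-break hash (variant 0 = canonical)
static inline unsigned int mixhash(unsigned int k, unsigned int i, unsigned int j) {
  unsigned int h = k * 2654435761u ^ (i * 40503u) ^ (j * 9973u);
  h ^= h >> 13; h *= 0x5bd1e995u; h ^= h >> 15;
  return h;
}

struct Fold {
  int n;
  const std::string& s;
  std::vector<int> M; // n*n DP matrix, row-major
  Fold(const std::string& seq) : n((int)seq.size()), s(seq), M((size_t)seq.size() * seq.size(), 0) {}
  inline int& at(int i, int j) { return M[(size_t)i * n + j]; }

  void fill() {
    for (int span = MIN_LOOP + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        int best = at(i + 1, j);                  // i unpaired
        int v = at(i, j - 1);                      // j unpaired
        if (v > best) best = v;
        if (can_pair(s[i], s[j])) {
          v = (i + 1 <= j - 1 ? at(i + 1, j - 1) : 0) + 1;
          if (v > best) best = v;
        }
        for (int k = i + 1; k < j; ++k) {          // bifurcation
          v = at(i, k) + at(k + 1, j);
          if (v > best) best = v;
        }
        at(i, j) = best;
      }
    }
  }

  // traceback with tie-breaking controlled by variant; variant 0 prefers
  // closing pairs (long helices), others permute among co-optimal moves.
  std::string traceback(unsigned int variant) {
    std::string db(n, '.');
    std::vector<std::pair<int,int>> stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (j - i <= MIN_LOOP) continue;
      int score = at(i, j);
      if (score == 0) continue;
      // candidate moves: 0 = pair(i,j), 1 = i unpaired, 2 = j unpaired,
      // 3.. = bifurcations
      bool pair_ok = can_pair(s[i], s[j]) &&
        ((i + 1 <= j - 1 ? at(i + 1, j - 1) : 0) + 1 == score);
      bool iun_ok = at(i + 1, j) == score;
      bool jun_ok = at(i, j - 1) == score;
      int choice = -1;
      if (variant == 0) {
        if (pair_ok) choice = 0; else if (iun_ok) choice = 1; else if (jun_ok) choice = 2;
      } else {
        std::vector<int> opts;
        if (pair_ok) opts.push_back(0);
        if (iun_ok) opts.push_back(1);
        if (jun_ok) opts.push_back(2);
        if (!opts.empty())
          choice = opts[mixhash(variant, i, j) % opts.size()];
      }
      if (choice == 0) {
        db[i] = '('; db[j] = ')';
        stack.push_back(std::make_pair(i + 1, j - 1));
        continue;
      } else if (choice == 1) {
        stack.push_back(std::make_pair(i + 1, j));
        continue;
      } else if (choice == 2) {
        stack.push_back(std::make_pair(i, j - 1));
        continue;
      }
      // bifurcation
      bool done = false;
      for (int k = i + 1; k < j && !done; ++k) {
        if (at(i, k) + at(k + 1, j) == score) {
          stack.push_back(std::make_pair(i, k));
          stack.push_back(std::make_pair(k + 1, j));
          done = true;
        }
      }
      if (!done) stop("traceback failure");
    }
    return db;
  }
};

//' @noRd
// [[Rcpp::export(name = ".fold_engine_cpp")]]
List fold_engine_cpp(std::string seq, int n_suboptimal) {
  int n = (int)seq.size();
  if (n < 2) stop("sequence too short to fold");
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'U')
      stop("sequence contains non-ACGTU letter");
  }
  Fold f(seq);
  f.fill();
  int best = f.at(0, n - 1);
  std::vector<std::string> structs;
  std::set<std::string> seen;
  std::string mfe = f.traceback(0);
  structs.push_back(mfe);
  seen.insert(mfe);
  // sample alternative co-optimal tracebacks as "suboptimal" structures
  unsigned int variant = 1;
  while ((int)structs.size() < 1 + n_suboptimal && variant < (unsigned int)(20 * (n_suboptimal + 1))) {
    std::string alt = f.traceback(variant++);
    if (seen.insert(alt).second) structs.push_back(alt);
  }
  CharacterVector sv(structs.size());
  IntegerVector sc(structs.size());
  for (size_t k = 0; k < structs.size(); ++k) {
    sv[k] = structs[k];
    sc[k] = best;
  }
  return List::create(_["structure"] = sv, _["pairs"] = sc);
}
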