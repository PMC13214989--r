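#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// End-gap-free global alignment ("overlap" alignment) of two nucleotide
// sequences with fixed scoring: match +1, mismatch -1, gap -2 per gapped
// position.  Identity is matches / aligned columns, where aligned columns
// exclude terminal-gap runs but include internal gap columns (which count
// as mismatching columns).  'N' (or any non-ACGT letter) matches nothing.
//
// Among co-optimal (max-score) alignments the one with the most matches,
// then the fewest columns, defines the reported identity.  Score, matches
// and columns are all invariant under swapping the sequences, so the
// result is exactly symmetric.  Implemented as a rolling-row DP over the
// (score, matches, columns) triple; no traceback needed.

static inline int encode_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // N / anything else: never matches
  }
}

static const int GAP = 2;   // penalty magnitude per gapped column

struct AlnResult {
  int matches;
  int columns;
  int score;
};

struct Cell { int s, m, c; };

// lexicographic preference: higher score, then more matches, then fewer
// columns
static inline bool better(int s, int m, int c, const Cell &ref) {
  if (s != ref.s) return s > ref.s;
  if (m != ref.m) return m > ref.m;
  return c < ref.c;
}

static AlnResult nw_endsfree(const std::string &a, const std::string &b) {
  const int m = (int)a.size(), n = (int)b.size();
  std::vector<int> ea(m), eb(n);
  for (int i = 0; i < m; ++i) ea[i] = encode_base(a[i]);
  for (int j = 0; j < n; ++j) eb[j] = encode_base(b[j]);

  std::vector<int> prevS(n + 1, 0), curS(n + 1, 0);
  std::vector<int> prevM(n + 1, 0), curM(n + 1, 0);
  std::vector<int> prevC(n + 1, 0), curC(n + 1, 0);

  Cell best = {0, 0, 0};   // empty alignment at (0, n) / (m, 0) borders

  const int *ebp = eb.data();
  for (int i = 1; i <= m; ++i) {
    const int ai = ea[i - 1];
    curS[0] = 0; curM[0] = 0; curC[0] = 0;   // free leading gaps
    for (int j = 1; j <= n; ++j) {
      const int sub = (ai == ebp[j - 1] && ai < 4) ? 1 : -1;
      // diagonal
      int s = prevS[j - 1] + sub;
      int mm = prevM[j - 1] + (sub == 1);
      int c = prevC[j - 1] + 1;
      // up: gap in b (consume a[i-1])
      int s2 = prevS[j] - GAP;
      if (s2 > s || (s2 == s && (prevM[j] > mm ||
                                 (prevM[j] == mm && prevC[j] + 1 < c)))) {
        s = s2; mm = prevM[j]; c = prevC[j] + 1;
      }
      // left: gap in a (consume b[j-1])
      int s3 = curS[j - 1] - GAP;
      if (s3 > s || (s3 == s && (curM[j - 1] > mm ||
                                 (curM[j - 1] == mm && curC[j - 1] + 1 < c)))) {
        s = s3; mm = curM[j - 1]; c = curC[j - 1] + 1;
      }
      curS[j] = s; curM[j] = mm; curC[j] = c;
    }
    // border cell (i, n): free trailing gaps in b
    if (better(curS[n], curM[n], curC[n], best)) {
      best.s = curS[n]; best.m = curM[n]; best.c = curC[n];
    }
    std::swap(prevS, curS); std::swap(prevM, curM); std::swap(prevC, curC);
  }
  // last row (m, j): free trailing gaps in a
  for (int j = 0; j <= n; ++j) {
    if (better(prevS[j], prevM[j], prevC[j], best)) {
      best.s = prevS[j]; best.m = prevM[j]; best.c = prevC[j];
    }
  }
  AlnResult r; r.matches = best.m; r.columns = best.c; r.score = best.s;
  return r;
}

// [[Rcpp::export(name = ".align_endsfree_cpp")]]
List align_endsfree_cpp(std::string a, std::string b) {
  AlnResult r = nw_endsfree(a, b);
  double id = r.columns > 0 ? 100.0 * r.matches / r.columns : 0.0;
  return List::create(_["matches"] = r.matches,
                      _["aligned_columns"] = r.columns,
                      _["identity_pct"] = id,
                      _["score"] = r.score);
}

// Identity matrix: queries x refs (percent identity, same contract as above).
// [[Rcpp::export(name = ".identity_matrix_cpp")]]
NumericMatrix identity_matrix_cpp(CharacterVector queries, CharacterVector refs) {
  const int nq = queries.size(), nr = refs.size();
  NumericMatrix out(nq, nr);
  std::vector<std::string> rs(nr);
  for (int j = 0; j < nr; ++j) rs[j] = as<std::string>(refs[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nr; ++j) {
      AlnResult r = nw_endsfree(q, rs[j]);
      out(i, j) = r.columns > 0 ? 100.0 * r.matches / r.columns : 0.0;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
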