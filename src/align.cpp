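// Global (end-to-end) pairwise alignment with affine gap penalties
// (Gotoh three-state DP). A gap run of length L scores
// gap_open + L * gap_extend. 'N' scores 0 against anything so that
// ambiguous read bases are alignment-neutral.
//
// Tie-breaking is deterministic: at equal score the traceback prefers the
// aligned (diagonal) state over gap states, which minimizes the number of
// gap runs; remaining placement freedom inside repeats is resolved by
// left-normalization in R.

#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static const double NEG = -1e18;

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return 0.0;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".affine_align")]]
List affine_align(std::string ref, CharacterVector reads,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int) ref.size();
  List out(reads.size());

  for (int r = 0; r < reads.size(); ++r) {
    std::string q = as<std::string>(reads[r]);
    const int m = (int) q.size();

    // score matrices, (n+1) x (m+1), row-major
    std::vector<double> M((n + 1) * (m + 1), NEG);
    std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in read (deletion)
    std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in ref (insertion)
    // traceback: which predecessor state fed each cell (0=M,1=X,2=Y)
    std::vector<unsigned char> tM((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tX((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tY((n + 1) * (m + 1), 0);
    const int W = m + 1;

    M[0] = 0.0;
    for (int i = 1; i <= n; ++i) {
      X[i * W] = gap_open + i * gap_extend;
      tX[i * W] = 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[j] = gap_open + j * gap_extend;
      tY[j] = 2;
    }

    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        const int c = i * W + j, d = (i - 1) * W + (j - 1);
        const int u = (i - 1) * W + j, l = i * W + (j - 1);
        // M: diagonal; prefer M predecessor on ties (fewer gap runs)
        double best = M[d]; unsigned char bs = 0;
        if (X[d] > best) { best = X[d]; bs = 1; }
        if (Y[d] > best) { best = Y[d]; bs = 2; }
        M[c] = best + subscore(ref[i - 1], q[j - 1], match, mismatch);
        tM[c] = bs;
        // X: gap in read; prefer extending an open gap on ties
        double ext = X[u] + gap_extend;
        double opn = M[u] + gap_open + gap_extend;
        if (ext >= opn) { X[c] = ext; tX[c] = 1; }
        else            { X[c] = opn; tX[c] = 0; }
        // Y: gap in ref
        ext = Y[l] + gap_extend;
        opn = M[l] + gap_open + gap_extend;
        if (ext >= opn) { Y[c] = ext; tY[c] = 2; }
        else            { Y[c] = opn; tY[c] = 0; }
      }
    }

    const int end = n * W + m;
    double score = M[end]; unsigned char state = 0;
    if (X[end] > score) { score = X[end]; state = 1; }
    if (Y[end] > score) { score = Y[end]; state = 2; }

    std::string ra, qa;  // built backwards
    ra.reserve(n + m); qa.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
      const int c = i * W + j;
      if (state == 0) {
        ra.push_back(ref[i - 1]); qa.push_back(q[j - 1]);
        state = tM[c]; --i; --j;
      } else if (state == 1) {
        ra.push_back(ref[i - 1]); qa.push_back('-');
        state = tX[c]; --i;
      } else {
        ra.push_back('-'); qa.push_back(q[j - 1]);
        state = tY[c]; --j;
      }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(qa.begin(), qa.end());
    out[r] = List::create(_["ref_row"] = ra, _["read_row"] = qa,
                          _["score"] = score);
  }
  return out;
}
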