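#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), deterministic
// traceback. Residues arrive as 1-based indices into the substitution
// matrix alphabet. A gap of length k costs gap_open + k * gap_ext.
//
// Tie rules, all deterministic: the reported alignment ends at the
// highest-scoring cell, smallest (i, j) in row-major order among ties;
// within state H the predecessor preference is diagonal > up (query residue
// against a subject gap) > left; a gap that can be explained either as an
// extension or a fresh opening is closed as early as possible (H preferred).
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                  int gap_open, int gap_ext) {
  const int m = q.size(), n = s.size();
  const int NEG = -1000000000;
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG); // left moves: gap in query
  std::vector<int> F((m + 1) * (n + 1), NEG); // up moves: gap in subject
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] - gap_open - gap_ext,
                       E[at(i, j - 1)] - gap_ext);
      int f = std::max(H[at(i - 1, j)] - gap_open - gap_ext,
                       F[at(i - 1, j)] - gap_ext);
      int d = H[at(i - 1, j - 1)] + sub(q[i - 1] - 1, s[j - 1] - 1);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // Traceback from (bi, bj) starting in state H until a zero H cell.
  std::vector<int> qa, sa; // aligned 1-based positions, 0 = gap
  int i = bi, j = bj;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      const int h = H[at(i, j)];
      if (h == 0) break;
      const int d = H[at(i - 1, j - 1)] + sub(q[i - 1] - 1, s[j - 1] - 1);
      if (h == d) {
        qa.push_back(i); sa.push_back(j); --i; --j;
      } else if (h == F[at(i, j)]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') {
      qa.push_back(i); sa.push_back(0);
      const bool from_h = F[at(i, j)] == H[at(i - 1, j)] - gap_open - gap_ext;
      --i;
      state = from_h ? 'H' : 'F';
    } else { // 'E'
      qa.push_back(0); sa.push_back(j);
      const bool from_h = E[at(i, j)] == H[at(i, j - 1)] - gap_open - gap_ext;
      --j;
      state = from_h ? 'H' : 'E';
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());

  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  for (size_t k = 0; k < qa.size(); ++k) {
    if (qa[k] > 0) { if (q_start == 0) q_start = qa[k]; q_end = qa[k]; }
    if (sa[k] > 0) { if (s_start == 0) s_start = sa[k]; s_end = sa[k]; }
  }

  return List::create(_["score"] = best,
                      _["q_pos"] = IntegerVector(qa.begin(), qa.end()),
                      _["s_pos"] = IntegerVector(sa.begin(), sa.end()),
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["s_start"] = s_start, _["s_end"] = s_end);
}
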