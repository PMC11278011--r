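#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh). A gap of length k costs open + k * ext,
// matching the BLAST convention for "gap open 11 / extend 1".
//
// Traceback states for H: 0 = stop (score 0), 1 = diagonal, 2 = gap in A
// (consume B only), 3 = gap in B (consume A only).

struct AlnResult {
  int score;
  int ali_len;
  int matches;
  int q_start, q_end;   // 1-based, inclusive, on A
  int s_start, s_end;   // 1-based, inclusive, on B
};

static AlnResult sw_align_one(const std::vector<int>& a, const std::vector<int>& b,
                              const int* sub, int nlet, int open, int ext,
                              std::vector<int>& H, std::vector<int>& E,
                              std::vector<int>& F, std::vector<unsigned char>& tbH,
                              std::vector<unsigned char>& tbE,
                              std::vector<unsigned char>& tbF) {
  const int n = (int)a.size(), m = (int)b.size();
  const int W = m + 1;
  const int NEG = -1000000000;
  H.assign((size_t)(n + 1) * W, 0);
  E.assign((size_t)(n + 1) * W, NEG);
  F.assign((size_t)(n + 1) * W, NEG);
  tbH.assign((size_t)(n + 1) * W, 0);
  tbE.assign((size_t)(n + 1) * W, 0);  // 0: opened from H, 1: extended
  tbF.assign((size_t)(n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  const int gapopen1 = open + ext;  // cost of a length-1 gap

  for (int i = 1; i <= n; ++i) {
    const int* srow = sub + (size_t)a[i - 1] * nlet;
    size_t off = (size_t)i * W, offp = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      // E: gap in A (horizontal, consumes b[j-1])
      int e_open = H[off + j - 1] - gapopen1;
      int e_ext = E[off + j - 1] - ext;
      if (e_open >= e_ext) { E[off + j] = e_open; tbE[off + j] = 0; }
      else                 { E[off + j] = e_ext;  tbE[off + j] = 1; }
      // F: gap in B (vertical, consumes a[i-1])
      int f_open = H[offp + j] - gapopen1;
      int f_ext = F[offp + j] - ext;
      if (f_open >= f_ext) { F[off + j] = f_open; tbF[off + j] = 0; }
      else                 { F[off + j] = f_ext;  tbF[off + j] = 1; }
      // H
      int diag = H[offp + j - 1] + srow[b[j - 1]];
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[off + j] > h) { h = E[off + j]; t = 2; }
      if (F[off + j] > h) { h = F[off + j]; t = 3; }
      H[off + j] = h; tbH[off + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  AlnResult r; r.score = best; r.ali_len = 0; r.matches = 0;
  r.q_start = r.q_end = r.s_start = r.s_end = 0;
  if (best <= 0) return r;

  // traceback from (bi, bj) until a stop state
  int i = bi, j = bj;
  r.q_end = bi; r.s_end = bj;
  while (i > 0 && j > 0) {
    size_t off = (size_t)i * W;
    unsigned char t = tbH[off + j];
    if (t == 0) break;
    if (t == 1) {
      r.ali_len++;
      if (a[i - 1] == b[j - 1]) r.matches++;
      --i; --j;
    } else if (t == 2) {
      // walk the whole horizontal gap run
      while (true) {
        r.ali_len++;
        unsigned char te = tbE[(size_t)i * W + j];
        --j;
        if (te == 0) break;
      }
    } else {
      while (true) {
        r.ali_len++;
        unsigned char tf = tbF[(size_t)i * W + j];
        --i;
        if (tf == 0) break;
      }
    }
  }
  r.q_start = i + 1; r.s_start = j + 1;
  return r;
}

static std::vector<int> encode_seq(const char* s, const int* code) {
  size_t n = std::strlen(s);
  std::vector<int> out(n);
  for (size_t k = 0; k < n; ++k) {
    int c = code[(unsigned char)s[k]];
    if (c < 0) stop("non-amino-acid character '%c' in sequence", s[k]);
    out[k] = c;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame sw_align_pairs_cpp(CharacterVector seqs, IntegerVector qi, IntegerVector si,
                             IntegerMatrix submat, int gap_open, int gap_ext) {
  const int nlet = submat.nrow();
  if (submat.ncol() != nlet) stop("substitution matrix must be square");
  CharacterVector letters = rownames(submat);
  int code[256];
  for (int k = 0; k < 256; ++k) code[k] = -1;
  for (int k = 0; k < nlet; ++k) {
    std::string l = as<std::string>(letters[k]);
    if (l.size() != 1) stop("matrix row names must be single letters");
    code[(unsigned char)l[0]] = k;
  }
  std::vector<int> sub((size_t)nlet * nlet);
  for (int i = 0; i < nlet; ++i)
    for (int j = 0; j < nlet; ++j) sub[(size_t)i * nlet + j] = submat(i, j);

  const int ns = seqs.size();
  std::vector<std::vector<int>> enc(ns);
  for (int k = 0; k < ns; ++k) enc[k] = encode_seq(CHAR(STRING_ELT(seqs, k)), code);

  const int np = qi.size();
  if (si.size() != np) stop("qi and si must have equal length");
  IntegerVector score(np), ali_len(np), matches(np),
      q_start(np), q_end(np), s_start(np), s_end(np);

  std::vector<int> H, E, F;
  std::vector<unsigned char> tbH, tbE, tbF;
  for (int p = 0; p < np; ++p) {
    int a = qi[p] - 1, b = si[p] - 1;
    if (a < 0 || a >= ns || b < 0 || b >= ns) stop("pair index out of range");
    AlnResult r = sw_align_one(enc[a], enc[b], sub.data(), nlet, gap_open, gap_ext,
                               H, E, F, tbH, tbE, tbF);
    score[p] = r.score; ali_len[p] = r.ali_len; matches[p] = r.matches;
    q_start[p] = r.q_start; q_end[p] = r.q_end;
    s_start[p] = r.s_start; s_end[p] = r.s_end;
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["score"] = score, _["ali_len"] = ali_len,
                           _["matches"] = matches, _["q_start"] = q_start,
                           _["q_end"] = q_end, _["s_start"] = s_start,
                           _["s_end"] = s_end);
}
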