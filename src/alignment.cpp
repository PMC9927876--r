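#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Substitution matrix wrapper. Characters absent from the matrix alphabet
// are remapped to 'X' when present; pairs involving an unmappable residue
// score 0.
struct ScoreTable {
  int lut[256];
  std::vector<int> mat;
  int n;
  int xi;
};

static ScoreTable build_table(const IntegerMatrix& m) {
  ScoreTable t;
  List dn = m.attr("dimnames");
  if (dn.size() < 1 || Rf_isNull(dn[0]))
    stop("substitution matrix must have row names");
  CharacterVector rn = dn[0];
  t.n = m.nrow();
  for (int i = 0; i < 256; i++) t.lut[i] = -1;
  t.xi = -1;
  for (int i = 0; i < t.n; i++) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() != 1) stop("matrix row names must be single characters");
    t.lut[(unsigned char)s[0]] = i;
    if (s[0] == 'X') t.xi = i;
  }
  t.mat.resize((size_t)t.n * t.n);
  for (int i = 0; i < t.n; i++)
    for (int j = 0; j < t.n; j++)
      t.mat[(size_t)i * t.n + j] = m(i, j);
  return t;
}

static inline int enc1(const ScoreTable& t, char c) {
  int v = t.lut[(unsigned char)c];
  if (v < 0) v = t.xi;
  return v;
}

static inline int sc(const ScoreTable& t, int a, int b) {
  if (a < 0 || b < 0) return 0;
  return t.mat[(size_t)a * t.n + b];
}

static void encode(const std::string& s, const ScoreTable& t, std::vector<int>& out) {
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); i++) out[i] = enc1(t, s[i]);
}

static const int NEG = -1000000000;

// Affine-gap local alignment, score only.  A gap of total length k costs
// gap_open + k * gap_extend (first gapped position pays open + extend).
static int sw_score_core(const std::vector<int>& a, const std::vector<int>& b,
                         const ScoreTable& t, int go, int ge) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) return 0;
  std::vector<int> H(lb + 1, 0), F(lb + 1, NEG);
  int best = 0;
  for (int i = 1; i <= la; i++) {
    int diag = 0;   // H[i-1][j-1]
    int E = NEG;    // horizontal gap state, carried along the row
    int ai = a[i - 1];
    for (int j = 1; j <= lb; j++) {
      int hup = H[j];                                  // H[i-1][j]
      E = std::max(E - ge, H[j - 1] - go - ge);        // from (i, j-1), row i
      F[j] = std::max(F[j] - ge, hup - go - ge);       // from (i-1, j)
      int h = diag + sc(t, ai, b[j - 1]);
      if (E > h) h = E;
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      diag = hup;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
int c_sw_score(std::string a, std::string b, IntegerMatrix mat,
               int gap_open, int gap_extend) {
  ScoreTable t = build_table(mat);
  std::vector<int> ea, eb;
  encode(a, t, ea);
  encode(b, t, eb);
  return sw_score_core(ea, eb, t, gap_open, gap_extend);
}

// [[Rcpp::export]]
IntegerVector c_sw_score_batch(std::string q, CharacterVector targets,
                               IntegerMatrix mat, int gap_open, int gap_extend) {
  ScoreTable t = build_table(mat);
  std::vector<int> eq;
  encode(q, t, eq);
  int n = targets.size();
  IntegerVector out(n);
  std::vector<int> et;
  for (int i = 0; i < n; i++) {
    std::string ts = as<std::string>(targets[i]);
    encode(ts, t, et);
    out[i] = sw_score_core(eq, et, t, gap_open, gap_extend);
  }
  return out;
}

// Full affine-gap local alignment with traceback.
// States: 0 = stop, 1 = diagonal (H), 2 = gap along a / consume b (E),
// 3 = gap along b / consume a (F).
// [[Rcpp::export]]
List c_sw_align(std::string a, std::string b, IntegerMatrix mat,
                int gap_open, int gap_extend) {
  ScoreTable t = build_table(mat);
  std::vector<int> ea, eb;
  encode(a, t, ea);
  encode(b, t, eb);
  const int la = (int)ea.size(), lb = (int)eb.size();
  const int go = gap_open, ge = gap_extend;
  if ((double)(la + 1) * (double)(lb + 1) > 6.4e7)
    stop("sequences too long for traceback alignment");

  size_t W = (size_t)lb + 1;
  std::vector<int> H((size_t)(la + 1) * W, 0), E((size_t)(la + 1) * W, NEG),
      F((size_t)(la + 1) * W, NEG);
  // trace: for H cells 0..3 as above; for E/F whether the gap was opened (1) or
  // extended (0)
  std::vector<unsigned char> TH((size_t)(la + 1) * W, 0),
      TE((size_t)(la + 1) * W, 0), TF((size_t)(la + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; i++) {
    for (int j = 1; j <= lb; j++) {
      size_t c = (size_t)i * W + j, up = c - W, left = c - 1, dg = c - W - 1;
      int eo = H[left] - go - ge, ee = E[left] - ge;
      if (eo >= ee) { E[c] = eo; TE[c] = 1; } else { E[c] = ee; TE[c] = 0; }
      int fo = H[up] - go - ge, fe = F[up] - ge;
      if (fo >= fe) { F[c] = fo; TF[c] = 1; } else { F[c] = fe; TF[c] = 0; }
      int hd = H[dg] + sc(t, ea[i - 1], eb[j - 1]);
      int h = 0; unsigned char th = 0;
      if (hd > h) { h = hd; th = 1; }
      if (E[c] > h) { h = E[c]; th = 2; }
      if (F[c] > h) { h = F[c]; th = 3; }
      H[c] = h; TH[c] = th;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, ta;
  int i = bi, j = bj;
  int n_id = 0, n_mm = 0, n_gap = 0, n_gapopen = 0;
  int state = 1; // start in H
  if (best > 0) {
    while (i > 0 && j > 0) {
      size_t c = (size_t)i * W + j;
      if (state == 1) {
        unsigned char th = TH[c];
        if (th == 0) break;
        if (th == 1) {
          qa.push_back(a[i - 1]);
          ta.push_back(b[j - 1]);
          if (a[i - 1] == b[j - 1]) n_id++; else n_mm++;
          i--; j--;
        } else {
          state = (th == 2) ? 2 : 3;
        }
      } else if (state == 2) { // gap along a: consume b
        qa.push_back('-');
        ta.push_back(b[j - 1]);
        n_gap++;
        if (TE[c] == 1) { n_gapopen++; state = 1; }
        j--;
      } else { // state 3: gap along b: consume a
        qa.push_back(a[i - 1]);
        ta.push_back('-');
        n_gap++;
        if (TF[c] == 1) { n_gapopen++; state = 1; }
        i--;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  int aln_len = (int)qa.size();
  double pid = aln_len > 0 ? 100.0 * n_id / aln_len : 0.0;
  return List::create(
      _["score"] = best, _["q_aln"] = qa, _["t_aln"] = ta,
      _["q_start"] = best > 0 ? i : 0, _["q_end"] = best > 0 ? bi : 0,
      _["t_start"] = best > 0 ? j : 0, _["t_end"] = best > 0 ? bj : 0,
      _["n_id"] = n_id, _["n_mismatch"] = n_mm, _["n_gap"] = n_gap,
      _["n_gapopen"] = n_gapopen, _["aln_len"] = aln_len,
      _["pct_identity"] = pid);
}

// Best ungapped window score of a position-specific scoring matrix against
// each protein.  pssm is L x A with column names = residue alphabet; residues
// outside the alphabet contribute 0.
// [[Rcpp::export]]
NumericVector c_pssm_best_batch(CharacterVector prots, NumericMatrix pssm) {
  List dn = pssm.attr("dimnames");
  if (dn.size() < 2 || Rf_isNull(dn[1]))
    stop("pssm must have residue column names");
  CharacterVector cn = dn[1];
  int L = pssm.nrow(), A = pssm.ncol();
  int lut[256];
  for (int i = 0; i < 256; i++) lut[i] = -1;
  for (int i = 0; i < A; i++) {
    std::string s = as<std::string>(cn[i]);
    lut[(unsigned char)s[0]] = i;
  }
  int n = prots.size();
  NumericVector out(n);
  for (int p = 0; p < n; p++) {
    std::string s = as<std::string>(prots[p]);
    int ls = (int)s.size();
    if (ls < L) { out[p] = NA_REAL; continue; }
    double best = R_NegInf;
    for (int off = 0; off + L <= ls; off++) {
      double tot = 0.0;
      for (int i = 0; i < L; i++) {
        int ri = lut[(unsigned char)s[off + i]];
        if (ri >= 0) tot += pssm(i, ri);
      }
      if (tot > best) best = tot;
    }
    out[p] = best;
  }
  return out;
}

// Offset of the best window (0-based), companion to c_pssm_best_batch.
// [[Rcpp::export]]
int c_pssm_best_offset(std::string s, NumericMatrix pssm) {
  List dn = pssm.attr("dimnames");
  CharacterVector cn = dn[1];
  int L = pssm.nrow(), A = pssm.ncol();
  int lut[256];
  for (int i = 0; i < 256; i++) lut[i] = -1;
  for (int i = 0; i < A; i++) {
    std::string cs = as<std::string>(cn[i]);
    lut[(unsigned char)cs[0]] = i;
  }
  int ls = (int)s.size();
  if (ls < L) return -1;
  double best = R_NegInf;
  int besto = 0;
  for (int off = 0; off + L <= ls; off++) {
    double tot = 0.0;
    for (int i = 0; i < L; i++) {
      int ri = lut[(unsigned char)s[off + i]];
      if (ri >= 0) tot += pssm(i, ri);
    }
    if (tot > best) { best = tot; besto = off; }
  }
  return besto;
}
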