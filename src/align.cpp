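#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap glocal alignment: the read is aligned end to end, the reference
// contributes a free prefix and suffix (rendered as a start offset, never as
// CIGAR ops). The first base of a gap costs gap_open + gap_extend, each
// further base gap_extend. Three-state DP (M = diagonal, I = read-only gap,
// D = reference-only gap) with deterministic tie-breaking M > I > D and,
// among equal-scoring end columns, the leftmost.

static const int NEG_INF = INT_MIN / 4;

struct Scheme {
  int match, mismatch, gopen, gext;
};

static inline int subst(char a, char b, const Scheme& s) {
  return (a == b) ? s.match : -s.mismatch;
}

// Score-only pass with two rolling rows; used to rank candidate references
// before a single full traceback on the winner. NEG_INF is far enough from
// INT_MIN that subtracting penalties never wraps, so the hot loop is
// branch-free.
// [[Rcpp::export]]
int cpp_align_score(std::string read, std::string ref, int match, int mismatch,
                    int gap_open, int gap_extend) {
  int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int goe = gap_open + gap_extend, ge = gap_extend;
  std::vector<int> Mp(m + 1), Ip(m + 1), Dp(m + 1), Mc(m + 1), Ic(m + 1), Dc(m + 1);
  for (int j = 0; j <= m; ++j) { Mp[j] = 0; Ip[j] = NEG_INF; Dp[j] = NEG_INF; }
  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    int *MP = Mp.data(), *IP = Ip.data(), *DP = Dp.data();
    int *MC = Mc.data(), *IC = Ic.data(), *DC = Dc.data();
    MC[0] = NEG_INF;
    DC[0] = NEG_INF;
    IC[0] = std::max(std::max(MP[0], DP[0]) - goe, IP[0] - ge);
    for (int j = 1; j <= m; ++j) {
      int diag = std::max(MP[j - 1], std::max(IP[j - 1], DP[j - 1]));
      MC[j] = diag + ((rc == ref[j - 1]) ? match : -mismatch);
      IC[j] = std::max(std::max(MP[j], DP[j]) - goe, IP[j] - ge);
      DC[j] = std::max(std::max(MC[j - 1], IC[j - 1]) - goe, DC[j - 1] - ge);
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  int best = NEG_INF;
  for (int j = 0; j <= m; ++j) {
    int v = std::max(Mp[j], Ip[j]);  // trailing deletions are free ref suffix
    if (v > best) best = v;
  }
  return best;
}

// Score a read against many references (both orientations handled by the
// caller passing oriented reads): returns the score vector without R-level
// loop overhead.
// [[Rcpp::export]]
IntegerVector cpp_align_score_multi(std::string read, std::string read_rc,
                                    std::vector<std::string> refs, int match,
                                    int mismatch, int gap_open, int gap_extend) {
  IntegerVector out(2 * refs.size());
  for (size_t k = 0; k < refs.size(); ++k) {
    out[2 * k] = cpp_align_score(read, refs[k], match, mismatch, gap_open,
                                 gap_extend);
    out[2 * k + 1] = cpp_align_score(read_rc, refs[k], match, mismatch,
                                     gap_open, gap_extend);
  }
  return out;
}

// Banded variant: cells restricted to diagonals d = j - i in
// [-band, (m - n) + band]. Equals the full DP whenever the optimal path's
// indel imbalance stays inside the corridor.
// [[Rcpp::export]]
int cpp_align_score_banded(std::string read, std::string ref, int match,
                           int mismatch, int gap_open, int gap_extend, int band) {
  Scheme sc{match, mismatch, gap_open, gap_extend};
  int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  int lo_d = -band, hi_d = (m - n) + band;
  std::vector<int> Mp(m + 1, NEG_INF), Ip(m + 1, NEG_INF), Dp(m + 1, NEG_INF),
      Mc(m + 1), Ic(m + 1), Dc(m + 1);
  for (int j = 0; j <= m; ++j) Mp[j] = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i + lo_d), jhi = std::min(m, i + hi_d);
    for (int j = 0; j <= m; ++j) { Mc[j] = NEG_INF; Ic[j] = NEG_INF; Dc[j] = NEG_INF; }
    for (int j = jlo; j <= jhi; ++j) {
      if (j >= 1) {
        int diag = std::max(Mp[j - 1], std::max(Ip[j - 1], Dp[j - 1]));
        if (diag != NEG_INF) Mc[j] = diag + subst(read[i - 1], ref[j - 1], sc);
      }
      int io = std::max(Mp[j], Dp[j]);
      int iv = std::max(io == NEG_INF ? NEG_INF : io - sc.gopen - sc.gext,
                        Ip[j] == NEG_INF ? NEG_INF : Ip[j] - sc.gext);
      Ic[j] = iv;
      if (j >= 1) {
        int dop = std::max(Mc[j - 1], Ic[j - 1]);
        int dv = std::max(dop == NEG_INF ? NEG_INF : dop - sc.gopen - sc.gext,
                          Dc[j - 1] == NEG_INF ? NEG_INF : Dc[j - 1] - sc.gext);
        Dc[j] = dv;
      }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  int best = NEG_INF;
  for (int j = 0; j <= m; ++j) {
    int v = std::max(Mp[j], Ip[j]);
    if (v > best) best = v;
  }
  return best;
}

// Full DP with traceback. States: 0 = M, 1 = I, 2 = D; 3 marks the free start
// (row 0). Tie-breaks: predecessor preference M > I > D; among equal-scoring
// alignment ends the smallest reference column (leftmost placement).
// [[Rcpp::export]]
List cpp_align_glocal(std::string read, std::string ref, int match, int mismatch,
                      int gap_open, int gap_extend) {
  int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int goe = gap_open + gap_extend, ge = gap_extend;
  size_t W = (size_t)m + 1;
  // rolling score rows; one packed traceback byte per cell
  // (bits 0-1: M predecessor, 2-3: I predecessor, 4-5: D predecessor)
  std::vector<int> Mp(W, 0), Ip(W, NEG_INF), Dp(W, NEG_INF), Mc(W), Ic(W), Dc(W);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0x3F);

  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    size_t r = (size_t)i * W;
    int *MP = Mp.data(), *IP = Ip.data(), *DP = Dp.data();
    int *MC = Mc.data(), *IC = Ic.data(), *DC = Dc.data();
    unsigned char *TB = tb.data() + r;
    MC[0] = NEG_INF;
    DC[0] = NEG_INF;
    {
      int best = MP[0] - goe; unsigned char sti = 0;
      if (IP[0] - ge > best) { best = IP[0] - ge; sti = 1; }
      if (DP[0] - goe > best) { best = DP[0] - goe; sti = 2; }
      IC[0] = best;
      if (i == 1 && sti == 0) sti = 3;
      TB[0] = (unsigned char)(3 | (sti << 2) | (3 << 4));
    }
    for (int j = 1; j <= m; ++j) {
      // prefer M, then I, then D on ties
      int best = MP[j - 1]; unsigned char stm = 0;
      if (IP[j - 1] > best) { best = IP[j - 1]; stm = 1; }
      if (DP[j - 1] > best) { best = DP[j - 1]; stm = 2; }
      MC[j] = best + ((rc == ref[j - 1]) ? match : -mismatch);
      if (i == 1) stm = 3;

      best = MP[j] - goe; unsigned char sti = 0;
      if (IP[j] - ge > best) { best = IP[j] - ge; sti = 1; }
      if (DP[j] - goe > best) { best = DP[j] - goe; sti = 2; }
      IC[j] = best;
      if (i == 1 && sti == 0) sti = 3;

      best = MC[j - 1] - goe; unsigned char std_ = 0;
      if (IC[j - 1] - goe > best) { best = IC[j - 1] - goe; std_ = 1; }
      if (DC[j - 1] - ge > best) { best = DC[j - 1] - ge; std_ = 2; }
      DC[j] = best;
      TB[j] = (unsigned char)(stm | (sti << 2) | (std_ << 4));
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  // pick alignment end: max over columns of M/I at the last row,
  // preferring M over I, then the smallest column
  int best = NEG_INF, bj = 0; unsigned char bstate = 0;
  for (int j = 0; j <= m; ++j) {
    if (Mp[j] > best) { best = Mp[j]; bj = j; bstate = 0; }
    if (Ip[j] > best) { best = Ip[j]; bj = j; bstate = 1; }
  }

  // traceback
  std::string ops;
  int i = n, j = bj, nm = 0;
  unsigned char st = bstate;
  while (i > 0) {
    size_t r = (size_t)i * W;
    unsigned char cell = tb[r + j];
    if (st == 0) {
      ops.push_back('M');
      if (read[i - 1] != ref[j - 1]) ++nm;
      unsigned char prev = cell & 3;
      --i; --j;
      st = (prev == 3) ? 0 : prev;
      if (prev == 3) break;
    } else if (st == 1) {
      ops.push_back('I');
      ++nm;
      unsigned char prev = (cell >> 2) & 3;
      --i;
      if (prev == 3) break;
      st = prev;
    } else {
      ops.push_back('D');
      ++nm;
      unsigned char prev = (cell >> 4) & 3;
      --j;
      st = prev;
    }
  }
  int start0 = j;  // 0-based ref offset of alignment start

  // collapse run-length CIGAR (ops currently reversed)
  std::string cigar;
  int len = (int)ops.size();
  int k = len - 1;
  while (k >= 0) {
    char op = ops[k];
    int run = 0;
    while (k >= 0 && ops[k] == op) { ++run; --k; }
    cigar += std::to_string(run);
    cigar.push_back(op);
  }

  return List::create(_["score"] = best, _["start"] = start0 + 1,
                      _["cigar"] = cigar, _["nm"] = nm);
}
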