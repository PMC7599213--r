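// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps, maximizing
// alignment score and, among score-optimal alignments, the number of matched
// columns. The lexicographic objective makes the matched-column count (and
// hence sequence identity) a well-defined function of the two inputs, not of
// traceback tie-breaking.
//
// Scoring: case-insensitive; any position involving N scores `n_score` and
// never counts as a match. A gap run of length L costs gap_open + L *
// gap_extend (gap_open charged once at the opening).

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <cctype>

using namespace Rcpp;

// encode (score, matches) lexicographically; scores are integral in the
// schemes used here, |score| < 1e12 and matches < 1e6
static const int64_t MMUL = 1000000LL;
static const int64_t NEG = INT64_MIN / 4;

static inline int64_t enc(int64_t score, int64_t matches) {
  return score * MMUL + matches;
}

// [[Rcpp::export(name = ".gotoh_align_cpp", rng = false)]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch, double n_score,
                     double gap_open, double gap_extend,
                     bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const int64_t MA = (int64_t)match, MI = (int64_t)mismatch,
                NS = (int64_t)n_score, GO = (int64_t)gap_open,
                GE = (int64_t)gap_extend;

  std::vector<char> ua(n), ub(m);
  for (int i = 0; i < n; ++i) ua[i] = (char)std::toupper((unsigned char)a[i]);
  for (int j = 0; j < m; ++j) ub[j] = (char)std::toupper((unsigned char)b[j]);
  auto sub = [&](int i, int j, int64_t &sc, int64_t &mt) {
    char x = ua[i], y = ub[j];
    if (x == 'N' || y == 'N') { sc = NS; mt = 0; }
    else if (x == y) { sc = MA; mt = 1; }
    else { sc = MI; mt = 0; }
  };

  // rolling rows of encoded values for states M (diag), X (gap in b,
  // consumes a), Y (gap in a, consumes b)
  std::vector<int64_t> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  std::vector<int64_t> Mc(m + 1), Xc(m + 1), Yc(m + 1);

  // traceback: predecessor state per cell per state (0=M,1=X,2=Y,3=none)
  std::vector<uint8_t> tbM, tbX, tbY;
  if (traceback) {
    double cells = (double)(n + 1) * (double)(m + 1);
    if (cells > 3.0e8)
      stop("alignment problem too large for traceback (%d x %d)", n, m);
    tbM.assign((size_t)(n + 1) * (m + 1), 3);
    tbX.assign((size_t)(n + 1) * (m + 1), 3);
    tbY.assign((size_t)(n + 1) * (m + 1), 3);
  }
  auto at = [&](int i, int j) { return (size_t)i * (m + 1) + j; };

  Mp[0] = enc(0, 0); Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = enc(GO + GE * j, 0);
    if (traceback) tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = enc(GO + GE * i, 0);
    if (traceback) tbX[at(i, 0)] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      int64_t sc, mt;
      sub(i - 1, j - 1, sc, mt);
      int64_t d = enc(sc, mt);
      // M: diagonal from best of the three at (i-1, j-1)
      {
        int64_t vm = Mp[j - 1], vx = Xp[j - 1], vy = Yp[j - 1];
        int64_t best = vm; uint8_t who = 0;
        if (vx > best) { best = vx; who = 1; }
        if (vy > best) { best = vy; who = 2; }
        Mc[j] = (best <= NEG) ? NEG : best + d;
        if (traceback) tbM[at(i, j)] = who;
      }
      // X: gap in b (consume a[i-1]) from (i-1, j)
      {
        int64_t open = (Mp[j] <= NEG) ? NEG : Mp[j] + enc(GO + GE, 0);
        int64_t extd = (Xp[j] <= NEG) ? NEG : Xp[j] + enc(GE, 0);
        int64_t openy = (Yp[j] <= NEG) ? NEG : Yp[j] + enc(GO + GE, 0);
        int64_t best = open; uint8_t who = 0;
        if (extd > best) { best = extd; who = 1; }
        if (openy > best) { best = openy; who = 2; }
        Xc[j] = best;
        if (traceback) tbX[at(i, j)] = who;
      }
      // Y: gap in a (consume b[j-1]) from (i, j-1)
      {
        int64_t open = (Mc[j - 1] <= NEG) ? NEG : Mc[j - 1] + enc(GO + GE, 0);
        int64_t openx = (Xc[j - 1] <= NEG) ? NEG : Xc[j - 1] + enc(GO + GE, 0);
        int64_t extd = (Yc[j - 1] <= NEG) ? NEG : Yc[j - 1] + enc(GE, 0);
        int64_t best = open; uint8_t who = 0;
        if (openx > best) { best = openx; who = 1; }
        if (extd > best) { best = extd; who = 2; }
        Yc[j] = best;
        if (traceback) tbY[at(i, j)] = who;
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  int64_t vm = Mp[m], vx = Xp[m], vy = Yp[m];
  int state = 0; int64_t best = vm;
  if (vx > best) { best = vx; state = 1; }
  if (vy > best) { best = vy; state = 2; }
  int64_t matches = ((best % MMUL) + MMUL) % MMUL;
  double score = (double)((best - matches) / MMUL);

  if (!traceback) {
    return List::create(_["score"] = score, _["matches"] = (double)matches);
  }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m, st = state;
  while (i > 0 || j > 0) {
    if (st == 0) {          // M consumed a[i-1], b[j-1]
      uint8_t prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == 1) {   // X consumed a[i-1]
      uint8_t prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; st = prev;
    } else {                // Y consumed b[j-1]
      uint8_t prev = tbY[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["matches"] = (double)matches,
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}
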