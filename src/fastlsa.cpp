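// Blocked affine-gap dynamic programming with boundary caching.
//
// The matrix is partitioned into k x k blocks.  The forward pass fills
// blocks in any order that respects the wave-front dependency (block
// (bi,bj) after (bi-1,bj) and (bi,bj-1)) and retains only the H/E/F
// values on the k+1 horizontal and k+1 vertical block-boundary grid
// lines.  The traceback walks from the end cell back to the origin,
// recomputing one block interior at a time from its cached top row and
// left column.  All arithmetic is exact 32-bit integer (scores are
// scaled by 100 at the R level), so results are bit-identical for every
// legal k and every legal block execution order.

#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;  // "minus infinity" sentinel
static const int SAT = INT_MAX / 4;  // saturation guard

static inline int clampneg(int x) { return x < NEG ? NEG : x; }

// ---------------------------------------------------------------------------
// Scorers: sequence mode (substitution matrix, scalar gap penalties) and
// profile mode (column dot products, position-specific gap penalties).
// Gap penalties are positive costs; goA/geA apply when a row (an 'a'
// position) is consumed against a gap, goB/geB when a column is.
// ---------------------------------------------------------------------------

struct Scorer {
  int La, Lb;
  virtual ~Scorer() {}
  virtual int score(int i, int j) = 0;  // 1-based DP indices
  virtual int goA(int i) const = 0;
  virtual int geA(int i) const = 0;
  virtual int goB(int j) const = 0;
  virtual int geB(int j) const = 0;
  // called before a block (rows (r0,r1], cols (c0,c1]) is computed
  virtual void prepare(int r0, int r1, int c0, int c1) {}
};

struct SeqScorer : Scorer {
  IntegerVector a, b;   // 0-based residue category codes
  IntegerMatrix sub;    // scaled integer substitution matrix
  int go, ge;

  SeqScorer(List in) {
    a = in["a"]; b = in["b"]; sub = as<IntegerMatrix>(in["sub"]);
    go = as<int>(in["gap_open"]); ge = as<int>(in["gap_ext"]);
    La = a.size(); Lb = b.size();
  }
  int score(int i, int j) override { return sub(a[i - 1], b[j - 1]); }
  int goA(int) const override { return go; }
  int geA(int) const override { return ge; }
  int goB(int) const override { return go; }
  int geB(int) const override { return ge; }
};

struct ProfScorer : Scorer {
  // 33 x m score/frequency matrices per profile, user (double) scale
  NumericMatrix sA, fA, sB, fB;
  IntegerVector goAv, geAv, goBv, geBv;  // scaled integer penalties
  bool fragment;
  // fragment-policy buffers: local copies of the block's profile columns
  std::vector<double> lsA, lfA, lsB, lfB;
  int fr0, fc0;
  bool loaded;

  ProfScorer(List in) {
    sA = as<NumericMatrix>(in["score_a"]); fA = as<NumericMatrix>(in["freq_a"]);
    sB = as<NumericMatrix>(in["score_b"]); fB = as<NumericMatrix>(in["freq_b"]);
    goAv = in["go_a"]; geAv = in["ge_a"]; goBv = in["go_b"]; geBv = in["ge_b"];
    fragment = as<bool>(in["fragment"]);
    La = sA.ncol(); Lb = sB.ncol();
    loaded = false; fr0 = fc0 = 0;
  }

  void prepare(int r0, int r1, int c0, int c1) override {
    if (!fragment) return;
    // copy only the profile fragments this block touches (cols r0+1..r1 of
    // profile A, c0+1..c1 of profile B) into worker-local storage
    int na = r1 - r0, nb = c1 - c0;
    lsA.assign((size_t)33 * na, 0.0); lfA.assign((size_t)33 * na, 0.0);
    lsB.assign((size_t)33 * nb, 0.0); lfB.assign((size_t)33 * nb, 0.0);
    for (int t = 0; t < na; ++t)
      for (int r = 0; r < 33; ++r) {
        lsA[(size_t)33 * t + r] = sA(r, r0 + t);
        lfA[(size_t)33 * t + r] = fA(r, r0 + t);
      }
    for (int t = 0; t < nb; ++t)
      for (int r = 0; r < 33; ++r) {
        lsB[(size_t)33 * t + r] = sB(r, c0 + t);
        lfB[(size_t)33 * t + r] = fB(r, c0 + t);
      }
    fr0 = r0; fc0 = c0; loaded = true;
  }

  int score(int i, int j) override {
    const double *x1, *y1, *x2, *y2;
    if (fragment && loaded) {
      x1 = &lsA[(size_t)33 * (i - 1 - fr0)];
      y1 = &lfA[(size_t)33 * (i - 1 - fr0)];
      x2 = &lsB[(size_t)33 * (j - 1 - fc0)];
      y2 = &lfB[(size_t)33 * (j - 1 - fc0)];
    } else {
      x1 = &sA(0, i - 1); y1 = &fA(0, i - 1);
      x2 = &sB(0, j - 1); y2 = &fB(0, j - 1);
    }
    double s = 0.0;
    for (int r = 0; r < 33; ++r) s += x1[r] * y2[r] + x2[r] * y1[r];
    return (int)std::llround(50.0 * s);  // 100 * 0.5 * symmetrized product
  }
  int goA(int i) const override { return goAv[i - 1]; }
  int geA(int i) const override { return geAv[i - 1]; }
  int goB(int j) const override { return goBv[j - 1]; }
  int geB(int j) const override { return geBv[j - 1]; }
};

static Scorer *make_scorer(List input) {
  std::string mode = as<std::string>(input["mode"]);
  if (mode == "seq") return new SeqScorer(input);
  if (mode == "profile") return new ProfScorer(input);
  stop("unknown scorer mode '%s'", mode.c_str());
  return NULL;
}

// ---------------------------------------------------------------------------
// Boundary initialization.  Cache layout:
//   rowsX(g, j) = X(row_cuts[g], j)  for j = 0..Lb   (g = 0..k)
//   colsX(g, i) = X(i, col_cuts[g])  for i = 0..La
// ---------------------------------------------------------------------------

struct Caches {
  IntegerMatrix rH, rE, rF, cH, cE, cF;
};

static void init_boundaries(Scorer *sc, const IntegerVector &rc,
                            const IntegerVector &cc, bool local, Caches &ca) {
  int La = sc->La, Lb = sc->Lb, k = rc.size() - 1;
  ca.rH(0, 0) = 0; ca.rE(0, 0) = NEG; ca.rF(0, 0) = NEG;
  if (local) {
    for (int j = 1; j <= Lb; ++j) {
      ca.rH(0, j) = 0; ca.rE(0, j) = NEG; ca.rF(0, j) = NEG;
    }
    for (int i = 0; i <= La; ++i) {
      ca.cH(0, i) = 0; ca.cE(0, i) = NEG; ca.cF(0, i) = NEG;
    }
  } else {
    int ph = 0, pe = NEG;
    for (int j = 1; j <= Lb; ++j) {
      int e = std::max(clampneg(ph - sc->goB(j) - sc->geB(j)),
                       clampneg(pe - sc->geB(j)));
      e = clampneg(e);
      ca.rH(0, j) = e; ca.rE(0, j) = e; ca.rF(0, j) = NEG;
      ph = e; pe = e;
    }
    ca.cH(0, 0) = 0; ca.cE(0, 0) = NEG; ca.cF(0, 0) = NEG;
    int qh = 0, qf = NEG;
    for (int i = 1; i <= La; ++i) {
      int f = std::max(clampneg(qh - sc->goA(i) - sc->geA(i)),
                       clampneg(qf - sc->geA(i)));
      f = clampneg(f);
      ca.cH(0, i) = f; ca.cF(0, i) = f; ca.cE(0, i) = NEG;
      qh = f; qf = f;
    }
  }
  // corner values of the other grid lines, taken from row 0 / col 0
  for (int g = 0; g <= k; ++g) {
    int j = cc[g];
    ca.cH(g, 0) = ca.rH(0, j); ca.cE(g, 0) = ca.rE(0, j); ca.cF(g, 0) = ca.rF(0, j);
    int i = rc[g];
    ca.rH(g, 0) = ca.cH(0, i); ca.rE(g, 0) = ca.cE(0, i); ca.rF(g, 0) = ca.cF(0, i);
  }
}

// ---------------------------------------------------------------------------
// Forward fill of one block (rolling row), writing its bottom row and right
// column into the caches, and tracking the best local cell.
// ---------------------------------------------------------------------------

struct Best {
  int score, i, j;
};

static void fill_block(Scorer *sc, const IntegerVector &rc,
                       const IntegerVector &cc, bool local, Caches &ca,
                       int bi, int bj, Best &best) {
  int r0 = rc[bi], r1 = rc[bi + 1], c0 = cc[bj], c1 = cc[bj + 1];
  sc->prepare(r0, r1, c0, c1);
  int w = c1 - c0;
  std::vector<int> ph(w + 1), pe(w + 1), pf(w + 1);
  std::vector<int> hh(w + 1), ee(w + 1), ff(w + 1);
  for (int t = 0; t <= w; ++t) {
    ph[t] = ca.rH(bi, c0 + t); pe[t] = ca.rE(bi, c0 + t); pf[t] = ca.rF(bi, c0 + t);
  }
  for (int r = r0 + 1; r <= r1; ++r) {
    hh[0] = ca.cH(bj, r); ee[0] = ca.cE(bj, r); ff[0] = ca.cF(bj, r);
    int gA_o = sc->goA(r), gA_e = sc->geA(r);
    for (int c = c0 + 1; c <= c1; ++c) {
      int t = c - c0;
      int e = std::max(clampneg(hh[t - 1] - sc->goB(c) - sc->geB(c)),
                       clampneg(ee[t - 1] - sc->geB(c)));
      int f = std::max(clampneg(ph[t] - gA_o - gA_e),
                       clampneg(pf[t] - gA_e));
      e = clampneg(e); f = clampneg(f);
      int h = clampneg(ph[t - 1]) ;
      h = (h <= NEG) ? NEG : h + sc->score(r, c);
      if (f > h) h = f;
      if (e > h) h = e;
      if (local && h < 0) h = 0;
      if (h > SAT) stop("DP cell value overflow (saturation) at (%d,%d)", r, c);
      hh[t] = h; ee[t] = e; ff[t] = f;
      if (local && h > 0) {
        if (h > best.score ||
            (h == best.score && (r < best.i || (r == best.i && c < best.j)))) {
          best.score = h; best.i = r; best.j = c;
        }
      }
    }
    if (r == r1)
      for (int t = 0; t <= w; ++t) {
        ca.rH(bi + 1, c0 + t) = hh[t];
        ca.rE(bi + 1, c0 + t) = ee[t];
        ca.rF(bi + 1, c0 + t) = ff[t];
      }
    ca.cH(bj + 1, r) = hh[w]; ca.cE(bj + 1, r) = ee[w]; ca.cF(bj + 1, r) = ff[w];
    ph.swap(hh); pe.swap(ee); pf.swap(ff);
  }
}

// [[Rcpp::export(name = ".fl_forward_cpp")]]
List fl_forward_cpp(List input, IntegerVector row_cuts, IntegerVector col_cuts,
                    bool local, IntegerMatrix order) {
  Scorer *sc = make_scorer(input);
  int La = sc->La, Lb = sc->Lb, k = row_cuts.size() - 1;
  if (col_cuts.size() != k + 1) { delete sc; stop("row/col cut length mismatch"); }
  Caches ca;
  ca.rH = IntegerMatrix(k + 1, Lb + 1); ca.rE = IntegerMatrix(k + 1, Lb + 1);
  ca.rF = IntegerMatrix(k + 1, Lb + 1);
  ca.cH = IntegerMatrix(k + 1, La + 1); ca.cE = IntegerMatrix(k + 1, La + 1);
  ca.cF = IntegerMatrix(k + 1, La + 1);
  init_boundaries(sc, row_cuts, col_cuts, local, ca);

  if (order.nrow() != k * k || order.ncol() != 2) {
    delete sc; stop("block order must be a (k*k) x 2 matrix");
  }
  std::vector<char> done((size_t)k * k, 0);
  Best best; best.score = 0; best.i = 0; best.j = 0;
  for (int t = 0; t < order.nrow(); ++t) {
    int bi = order(t, 0), bj = order(t, 1);
    if (bi < 0 || bi >= k || bj < 0 || bj >= k) { delete sc; stop("block index out of range"); }
    size_t id = (size_t)bi * k + bj;
    if (done[id]) { delete sc; stop("block (%d,%d) scheduled twice", bi, bj); }
    if (bi > 0 && !done[(size_t)(bi - 1) * k + bj]) {
      delete sc; stop("wave-front dependency violated at block (%d,%d)", bi, bj);
    }
    if (bj > 0 && !done[(size_t)bi * k + bj - 1]) {
      delete sc; stop("wave-front dependency violated at block (%d,%d)", bi, bj);
    }
    fill_block(sc, row_cuts, col_cuts, local, ca, bi, bj, best);
    done[id] = 1;
  }
  for (size_t id = 0; id < done.size(); ++id)
    if (!done[id]) { delete sc; stop("incomplete block schedule"); }

  int bscore, bi_, bj_;
  if (local) {
    bscore = best.score; bi_ = best.i; bj_ = best.j;
  } else {
    bscore = ca.rH(k, Lb); bi_ = La; bj_ = Lb;
  }
  delete sc;
  return List::create(_["rows_h"] = ca.rH, _["rows_e"] = ca.rE, _["rows_f"] = ca.rF,
                      _["cols_h"] = ca.cH, _["cols_e"] = ca.cE, _["cols_f"] = ca.cF,
                      _["best"] = bscore, _["best_i"] = bi_, _["best_j"] = bj_);
}

// ---------------------------------------------------------------------------
// Traceback: recompute block interiors on demand from cached boundaries.
// Tie-breaks: diagonal > vertical (gap in b) > horizontal (gap in a);
// within a gap state, closing the gap (H origin) is preferred.
// ---------------------------------------------------------------------------

struct BlockView {
  int bi, bj, r0, r1, c0, c1;
  std::vector<int> H, E, F;  // (r1-r0+1) x (c1-c0+1), row-major
  bool valid;
  BlockView() : bi(-1), bj(-1), valid(false) {}
  inline size_t idx(int i, int j) const {
    return (size_t)(i - r0) * (c1 - c0 + 1) + (j - c0);
  }
};

struct Tracer {
  Scorer *sc;
  IntegerVector rc, cc;
  Caches ca;
  bool local;
  BlockView bv;
  int k;

  int find_cut(const IntegerVector &cuts, int x) const {
    // largest g with cuts[g] < x  (x >= 1)
    int g = 0;
    while (g + 1 < cuts.size() && cuts[g + 1] < x) ++g;
    return g;
  }

  void load(int bi, int bj) {
    if (bv.valid && bv.bi == bi && bv.bj == bj) return;
    int r0 = rc[bi], r1 = rc[bi + 1], c0 = cc[bj], c1 = cc[bj + 1];
    sc->prepare(r0, r1, c0, c1);
    bv.bi = bi; bv.bj = bj; bv.r0 = r0; bv.r1 = r1; bv.c0 = c0; bv.c1 = c1;
    size_t n = (size_t)(r1 - r0 + 1) * (c1 - c0 + 1);
    bv.H.assign(n, NEG); bv.E.assign(n, NEG); bv.F.assign(n, NEG);
    for (int j = c0; j <= c1; ++j) {
      bv.H[bv.idx(r0, j)] = ca.rH(bi, j);
      bv.E[bv.idx(r0, j)] = ca.rE(bi, j);
      bv.F[bv.idx(r0, j)] = ca.rF(bi, j);
    }
    for (int i = r0; i <= r1; ++i) {
      bv.H[bv.idx(i, c0)] = ca.cH(bj, i);
      bv.E[bv.idx(i, c0)] = ca.cE(bj, i);
      bv.F[bv.idx(i, c0)] = ca.cF(bj, i);
    }
    for (int i = r0 + 1; i <= r1; ++i) {
      int gA_o = sc->goA(i), gA_e = sc->geA(i);
      for (int j = c0 + 1; j <= c1; ++j) {
        int e = std::max(clampneg(bv.H[bv.idx(i, j - 1)] - sc->goB(j) - sc->geB(j)),
                         clampneg(bv.E[bv.idx(i, j - 1)] - sc->geB(j)));
        int f = std::max(clampneg(bv.H[bv.idx(i - 1, j)] - gA_o - gA_e),
                         clampneg(bv.F[bv.idx(i - 1, j)] - gA_e));
        e = clampneg(e); f = clampneg(f);
        int ph = bv.H[bv.idx(i - 1, j - 1)];
        int h = (ph <= NEG) ? NEG : ph + sc->score(i, j);
        if (f > h) h = f;
        if (e > h) h = e;
        if (local && h < 0) h = 0;
        bv.H[bv.idx(i, j)] = h; bv.E[bv.idx(i, j)] = e; bv.F[bv.idx(i, j)] = f;
      }
    }
    bv.valid = true;
  }

  void at(int i, int j, int &h, int &e, int &f) {
    if (i == 0) { h = ca.rH(0, j); e = ca.rE(0, j); f = ca.rF(0, j); return; }
    if (j == 0) { h = ca.cH(0, i); e = ca.cE(0, i); f = ca.cF(0, i); return; }
    load(find_cut(rc, i), find_cut(cc, j));
    h = bv.H[bv.idx(i, j)]; e = bv.E[bv.idx(i, j)]; f = bv.F[bv.idx(i, j)];
  }
  int H(int i, int j) { int h, e, f; at(i, j, h, e, f); return h; }
  int E(int i, int j) { int h, e, f; at(i, j, h, e, f); return e; }
  int F(int i, int j) { int h, e, f; at(i, j, h, e, f); return f; }
  int scoreAt(int i, int j) {
    // ensure fragment scorers have the containing block prepared
    load(find_cut(rc, i), find_cut(cc, j));
    return sc->score(i, j);
  }
};

// [[Rcpp::export(name = ".fl_traceback_cpp")]]
List fl_traceback_cpp(List input, IntegerVector row_cuts, IntegerVector col_cuts,
                      List cache, bool local, int start_i, int start_j) {
  Scorer *sc = make_scorer(input);
  Tracer tr;
  tr.sc = sc; tr.rc = row_cuts; tr.cc = col_cuts; tr.local = local;
  tr.k = row_cuts.size() - 1;
  tr.ca.rH = as<IntegerMatrix>(cache["rows_h"]);
  tr.ca.rE = as<IntegerMatrix>(cache["rows_e"]);
  tr.ca.rF = as<IntegerMatrix>(cache["rows_f"]);
  tr.ca.cH = as<IntegerMatrix>(cache["cols_h"]);
  tr.ca.cE = as<IntegerMatrix>(cache["cols_e"]);
  tr.ca.cF = as<IntegerMatrix>(cache["cols_f"]);
  if (tr.ca.rH.ncol() != sc->Lb + 1 || tr.ca.cH.ncol() != sc->La + 1 ||
      tr.ca.rH.nrow() != tr.k + 1) {
    delete sc; stop("grid cache does not match the supplied inputs");
  }

  std::vector<int> pa, pb;  // 1-based consumed positions; 0 = gap
  int i = start_i, j = start_j;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  for (;;) {
    if (state == 0) {
      if (local && tr.H(i, j) == 0) break;
      if (i == 0 && j == 0) break;
      if (i > 0 && j > 0) {
        int h = tr.H(i, j);
        int dg = tr.H(i - 1, j - 1);
        if (dg > NEG && h == dg + tr.scoreAt(i, j)) {
          pa.push_back(i); pb.push_back(j); --i; --j;
        } else if (h == tr.F(i, j)) {
          state = 2;
        } else if (h == tr.E(i, j)) {
          state = 1;
        } else {
          delete sc; stop("traceback inconsistency at (%d,%d)", i, j);
        }
      } else if (i > 0) {
        state = 2;  // column 0: H == F in global mode
      } else {
        state = 1;  // row 0
      }
    } else if (state == 2) {  // gap in b, consume a[i]
      int f = tr.F(i, j);
      int hup = tr.H(i - 1, j);
      pa.push_back(i); pb.push_back(0);
      bool close = (hup > NEG && f == hup - sc->goA(i) - sc->geA(i));
      --i;
      if (close) state = 0;
    } else {  // gap in a, consume b[j]
      int e = tr.E(i, j);
      int hl = tr.H(i, j - 1);
      pa.push_back(0); pb.push_back(j);
      bool close = (hl > NEG && e == hl - sc->goB(j) - sc->geB(j));
      --j;
      if (close) state = 0;
    }
  }
  delete sc;
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["pos_a"] = wrap(pa), _["pos_b"] = wrap(pb),
                      _["origin_i"] = i, _["origin_j"] = j);
}
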