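// CYK-style dynamic programming for the simplified covariance model.
//
// For every guide-tree node v and subject window x[i..j) the decks hold:
//   MOPT(v,i,j)  best score with v's own action = match/pair emission
//   DOPT(v,i,j)  child part of v's delete option (= ENT_D(child,i,j))
//   INS(v,i,j)   best score entered after >=1 left inserts (extend chain)
//   INSR(v,i,j)  (MATP children) best score followed by >=1 right inserts
// with ENT_p(v,i,j) = max(core_p, insert_open + INS(v,i+1,j)) and
// core_p = max(MOPT, dcost(v,p) + DOPT) for match nodes.  Delete runs are
// affine along the node chain (context p in {N,D}); the chain resets across
// inserts and across the right branch of a bifurcation.  Global mode aligns
// the whole model to the whole input with root-level flank inserts charged;
// local mode leaves subject flanks free (score 0 per flanking residue).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double NEG = -1e18;
const double EPS = 1e-6;

struct CM {
  int n, top, L;
  std::vector<int> type, child, left, right, col5, col3;
  std::vector<std::vector<double>> emit;   // 5 (MATL) or 25 (MATP col-major)
  double io, ie, dopen, dext;
  const int* x;                            // subject codes 0..3, 4 = other

  std::vector<size_t> off;                 // triangular offsets
  std::vector<std::vector<double>> MOPT, DOPT, INS, INSR;
  std::vector<char> need_insr;

  inline size_t idx(int i, int j) const { return off[i] + (j - i); }

  double el(int v, int b) const { return emit[v][b]; }
  double ep(int v, int b5, int b3) const { return emit[v][b5 + 5 * b3]; }

  double dcost(int v, int p) const {
    if (type[v] == 0) return p ? dext : dopen;
    return p ? 2 * dext : dopen + dext;   // MATP deletes both columns
  }

  double core(int v, int i, int j, int p) const {
    int t = type[v];
    size_t c = idx(i, j);
    if (t == 3) return MOPT[v][c];                      // END
    if (t == 2) return p ? DOPT[v][c] : MOPT[v][c];     // BIF
    double m = MOPT[v][c];
    double d = DOPT[v][c];
    double dd = d > NEG / 2 ? dcost(v, p) + d : NEG;
    return m > dd ? m : dd;
  }

  double ent(int v, int i, int j, int p) const {
    double best = core(v, i, j, p);
    if (i < j) {
      double alt = INS[v][idx(i + 1, j)];
      if (alt > NEG / 2 && io + alt > best) best = io + alt;
    }
    return best;
  }

  double entr(int v, int i, int j) const {   // right-trailing inserts
    double best = ent(v, i, j, 0);
    if (i < j) {
      double alt = INSR[v][idx(i, j - 1)];
      if (alt > NEG / 2 && io + alt > best) best = io + alt;
    }
    return best;
  }

  void fill() {
    size_t ncell = off[L] + 1;
    MOPT.assign(n, std::vector<double>());
    DOPT.assign(n, std::vector<double>());
    INS.assign(n, std::vector<double>());
    INSR.assign(n, std::vector<double>());
    need_insr.assign(n, 0);
    for (int v = 0; v < n; ++v)
      if (type[v] == 1) need_insr[child[v]] = 1;
    for (int v = 0; v < n; ++v) {
      MOPT[v].assign(ncell, NEG);
      DOPT[v].assign(ncell, NEG);
      INS[v].assign(ncell, NEG);
      if (need_insr[v]) INSR[v].assign(ncell, NEG);
    }
    for (int d = 0; d <= L; ++d) {
      for (int v = 0; v < n; ++v) {     // postorder: children first
        int t = type[v];
        for (int i = 0; i + d <= L; ++i) {
          int j = i + d;
          size_t c = idx(i, j);
          if (t == 3) {                               // END
            MOPT[v][c] = (i == j) ? 0.0 : NEG;
            DOPT[v][c] = MOPT[v][c];
          } else if (t == 0) {                        // MATL
            if (i < j) {
              double sub = ent(child[v], i + 1, j, 0);
              if (sub > NEG / 2) MOPT[v][c] = el(v, x[i]) + sub;
            }
            DOPT[v][c] = ent(child[v], i, j, 1);
          } else if (t == 1) {                        // MATP
            if (d >= 2) {
              double sub = entr(child[v], i + 1, j - 1);
              if (sub > NEG / 2)
                MOPT[v][c] = ep(v, x[i], x[j - 1]) + sub;
            }
            DOPT[v][c] = ent(child[v], i, j, 1);
          } else {                                    // BIF
            double bn = NEG, bd = NEG;
            for (int k = i; k <= j; ++k) {
              double rr = ent(right[v], k, j, 0);
              if (rr < NEG / 2) continue;
              double ln = ent(left[v], i, k, 0);
              double ld = ent(left[v], i, k, 1);
              if (ln > NEG / 2 && ln + rr > bn) bn = ln + rr;
              if (ld > NEG / 2 && ld + rr > bd) bd = ld + rr;
            }
            MOPT[v][c] = bn;
            DOPT[v][c] = bd;
          }
          double cn = core(v, i, j, 0);
          if (i < j) {
            double alt = INS[v][idx(i + 1, j)];
            if (alt > NEG / 2 && ie + alt > cn) cn = ie + alt;
          }
          INS[v][c] = cn;
          if (need_insr[v]) {
            double rr = ent(v, i, j, 0);
            if (i < j) {
              double alt = INSR[v][idx(i, j - 1)];
              if (alt > NEG / 2 && ie + alt > rr) rr = ie + alt;
            }
            INSR[v][c] = rr;
          }
        }
      }
    }
  }

  // ---- traceback ----------------------------------------------------
  std::vector<int> colpos;

  static bool approx(double a, double b) { return std::fabs(a - b) < EPS; }

  void tb_ent(int v, int i, int j, int p) {
    double val = ent(v, i, j, p);
    if (approx(val, core(v, i, j, p))) { tb_core(v, i, j, p); return; }
    tb_ins(v, i + 1, j);                  // residue i inserted
  }

  void tb_ins(int v, int i, int j) {
    double val = INS[v][idx(i, j)];
    if (approx(val, core(v, i, j, 0))) { tb_core(v, i, j, 0); return; }
    tb_ins(v, i + 1, j);
  }

  void tb_insr(int v, int i, int j) {
    double val = INSR[v][idx(i, j)];
    if (approx(val, ent(v, i, j, 0))) { tb_ent(v, i, j, 0); return; }
    tb_insr(v, i, j - 1);
  }

  void tb_core(int v, int i, int j, int p) {
    int t = type[v];
    size_t c = idx(i, j);
    double val = core(v, i, j, p);
    if (t == 3) return;
    if (t == 2) {                                     // BIF
      for (int k = i; k <= j; ++k) {
        double lv = ent(left[v], i, k, p);
        double rv = ent(right[v], k, j, 0);
        if (lv > NEG / 2 && rv > NEG / 2 && approx(val, lv + rv)) {
          tb_ent(left[v], i, k, p);
          tb_ent(right[v], k, j, 0);
          return;
        }
      }
      stop("traceback failure at BIF node");
    }
    if (approx(val, MOPT[v][c])) {
      if (t == 0) {                                   // MATL match
        colpos[col5[v] - 1] = i;
        tb_ent(child[v], i + 1, j, 0);
      } else {                                        // MATP pair
        colpos[col5[v] - 1] = i;
        colpos[col3[v] - 1] = j - 1;
        double sub = entr(child[v], i + 1, j - 1);
        if (approx(sub, ent(child[v], i + 1, j - 1, 0)))
          tb_ent(child[v], i + 1, j - 1, 0);
        else
          tb_insr(child[v], i + 1, j - 2);
      }
      return;
    }
    // delete
    tb_ent(child[v], i, j, 1);
  }
};

CM make_cm(List nodes, List pen, IntegerVector subj, int top) {
  CM cm;
  cm.type = as<std::vector<int>>(nodes["type"]);
  cm.child = as<std::vector<int>>(nodes["child"]);
  cm.left = as<std::vector<int>>(nodes["left"]);
  cm.right = as<std::vector<int>>(nodes["right"]);
  cm.col5 = as<std::vector<int>>(nodes["col5"]);
  cm.col3 = as<std::vector<int>>(nodes["col3"]);
  List em = nodes["emit"];
  for (R_xlen_t k = 0; k < em.size(); ++k)
    cm.emit.push_back(as<std::vector<double>>(em[k]));
  cm.n = cm.type.size();
  cm.top = top;
  cm.io = as<double>(pen["insert_open"]);
  cm.ie = as<double>(pen["insert_extend"]);
  cm.dopen = as<double>(pen["delete_open"]);
  cm.dext = as<double>(pen["delete_extend"]);
  cm.L = subj.size();
  cm.x = subj.begin();
  cm.off.resize(cm.L + 1);
  size_t o = 0;
  for (int i = 0; i <= cm.L; ++i) {
    cm.off[i] = o;
    o += (size_t)(cm.L - i + 1);
  }
  return cm;
}

} // namespace

// [[Rcpp::export]]
List cpp_cm_score(List nodes, int top, List penalties, IntegerVector subj,
                  int ncol, bool global) {
  CM cm = make_cm(nodes, penalties, subj, top);
  cm.fill();
  int L = cm.L;
  cm.colpos.assign(ncol, -1);
  double score;
  int si, sj;
  if (global) {
    double ins0 = 0;  // flank insert cost, computed incrementally
    double best = NEG;
    int ba = 0, bb = L;
    for (int a = 0; a <= L; ++a) {
      double costa = a == 0 ? 0.0 : cm.io + (a - 1) * cm.ie;
      for (int b = a; b <= L; ++b) {
        double costb = (L - b) == 0 ? 0.0 : cm.io + (L - b - 1) * cm.ie;
        double e = cm.ent(cm.top, a, b, 0);
        if (e > NEG / 2 && costa + e + costb > best) {
          best = costa + e + costb;
          ba = a; bb = b;
        }
      }
    }
    (void)ins0;
    score = best;
    cm.tb_ent(cm.top, ba, bb, 0);
    si = 0; sj = L;
  } else {
    double best = NEG;
    int bi = 0, bj = 0;
    for (int i = 0; i <= L; ++i)
      for (int j = i; j <= L; ++j) {
        double e = cm.ent(cm.top, i, j, 0);
        if (e > best + EPS) { best = e; bi = i; bj = j; }
      }
    score = best;
    cm.tb_ent(cm.top, bi, bj, 0);
    si = bi; sj = bj;
  }
  return List::create(_["score"] = score, _["start"] = si, _["end"] = sj,
                      _["colpos"] = IntegerVector(cm.colpos.begin(),
                                                  cm.colpos.end()));
}
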