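// Depth-first descriptor matcher.
//
// A descriptor is an ordered topology of single-strand (SS) elements and
// helix strands.  Matching anchored at a position walks the topology
// left-to-right: SS elements consume residues token by token (run tokens
// branch over lengths, shortest first); a helix opening strand consumes and
// records its span; the closing strand checks reversed-position pairing
// against the recorded span within its mispair budget.  The first success in
// this enumeration order wins per anchor.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Tok { int type; int sym; int rmin; int rmax; }; // type 0 fixed, 1 run

struct Elem {
  int type;                // 0 ss, 1 helix open, 2 helix close
  int budget;
  std::vector<Tok> toks;   // ss
  std::vector<int> mask;   // helix strand symbol masks (5'->3')
  int open_idx;            // close: topology slot of the opening strand
  bool pair[4][4];         // close: allowed (b5, b3) pairs over A,C,G,T
};

inline int baseidx(int mask) {
  switch (mask) { case 1: return 0; case 2: return 1;
                  case 4: return 2; case 8: return 3; }
  return -1;
}

std::vector<Elem> decode_model(const List& elems) {
  std::vector<Elem> E;
  for (R_xlen_t i = 0; i < elems.size(); ++i) {
    List el = elems[i];
    Elem e;
    e.type = as<int>(el["type"]);
    e.budget = as<int>(el["budget"]);
    e.open_idx = -1;
    std::memset(e.pair, 0, sizeof(e.pair));
    if (e.type == 0) {
      IntegerVector tt = el["tok_type"], sym = el["sym"],
                    rmin = el["rmin"], rmax = el["rmax"];
      for (int k = 0; k < tt.size(); ++k)
        e.toks.push_back(Tok{tt[k], sym[k], rmin[k], rmax[k]});
    } else {
      IntegerVector m = el["mask"];
      e.mask.assign(m.begin(), m.end());
      if (e.type == 2) {
        e.open_idx = as<int>(el["open_idx"]);
        IntegerVector pm = el["pairmat"]; // 16 ints, column-major 4x4
        for (int a = 0; a < 4; ++a)
          for (int b = 0; b < 4; ++b)
            e.pair[a][b] = pm[a + 4 * b] != 0;
      }
    }
    E.push_back(e);
  }
  return E;
}

struct Matcher {
  const int* S;
  int L;
  const std::vector<Elem>& E;
  std::vector<int> es, ee, open_start;
  int total_mm, total_mp, end_pos;

  Matcher(const int* s, int l, const std::vector<Elem>& e)
    : S(s), L(l), E(e), es(e.size()), ee(e.size()), open_start(e.size()) {}

  bool run(int anchor) {
    total_mm = total_mp = 0;
    return elem(0, anchor);
  }

  bool elem(size_t e, int pos) {
    if (e == E.size()) { end_pos = pos; return true; }
    es[e] = pos;
    const Elem& el = E[e];
    if (el.type == 0) return ss_tok(e, 0, pos, 0);
    int len = (int)el.mask.size();
    if (pos + len > L) return false;
    if (el.type == 1) {
      for (int k = 0; k < len; ++k)
        if ((S[pos + k] & el.mask[k]) == 0) return false;
      open_start[e] = pos;
      ee[e] = pos + len;
      return elem(e + 1, pos + len);
    }
    // closing strand: a position is a mispair when its symbol or its
    // pairing against the recorded opening span fails (counted once)
    int os = open_start[el.open_idx];
    int mp = 0;
    for (int m = 0; m < len; ++m) {
      int b3 = S[pos + m];
      bool symok = (b3 & el.mask[m]) != 0;
      int b5 = S[os + (len - 1 - m)];
      int i5 = baseidx(b5), i3 = baseidx(b3);
      bool pairok = i5 >= 0 && i3 >= 0 && el.pair[i5][i3];
      if (!(symok && pairok) && ++mp > el.budget) return false;
    }
    ee[e] = pos + len;
    int save = total_mp;
    total_mp += mp;
    if (elem(e + 1, pos + len)) return true;
    total_mp = save;
    return false;
  }

  bool ss_tok(size_t e, size_t t, int pos, int mm) {
    const Elem& el = E[e];
    if (t == el.toks.size()) {
      ee[e] = pos;
      int save = total_mm;
      total_mm += mm;
      if (elem(e + 1, pos)) return true;
      total_mm = save;
      return false;
    }
    const Tok& tk = el.toks[t];
    if (tk.type == 0) {
      if (pos >= L) return false;
      int m2 = mm + (((S[pos] & tk.sym) == 0) ? 1 : 0);
      if (m2 > el.budget) return false;
      return ss_tok(e, t + 1, pos + 1, m2);
    }
    for (int len = tk.rmin; len <= tk.rmax; ++len) {
      if (pos + len > L) break;
      if (ss_tok(e, t + 1, pos + len, mm)) return true;
    }
    return false;
  }

  List hit(int anchor) {
    IntegerMatrix spans((int)E.size(), 2);
    for (size_t k = 0; k < E.size(); ++k) {
      spans(k, 0) = es[k];
      spans(k, 1) = ee[k];
    }
    return List::create(_["start"] = anchor, _["end"] = end_pos,
                        _["spans"] = spans,
                        _["mismatches"] = total_mm,
                        _["mispairs"] = total_mp);
  }
};

} // namespace

// [[Rcpp::export]]
SEXP cpp_dm_match_at(IntegerVector subject, List elems, int pos) {
  std::vector<Elem> E = decode_model(elems);
  Matcher m(subject.begin(), subject.size(), E);
  if (pos < 0 || pos > subject.size()) stop("anchor out of range");
  if (!m.run(pos)) return R_NilValue;
  return m.hit(pos);
}

// [[Rcpp::export]]
List cpp_dm_scan(IntegerVector subject, List elems, int min_span) {
  std::vector<Elem> E = decode_model(elems);
  Matcher m(subject.begin(), subject.size(), E);
  List out;
  int L = subject.size();
  for (int a = 0; a + min_span <= L; ++a)
    if (m.run(a)) out.push_back(m.hit(a));
  return out;
}
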