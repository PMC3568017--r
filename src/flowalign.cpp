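// Frame-shift-capable Smith-Waterman-Gotoh kernel.
//
// Nucleotide codes: T=0, A=1, C=2, G=3, N=4.  Amino acids are indices into
// the package residue alphabet (X = 22, stop = 23).  The query profile
// stores, per width w in {1,2,3,4,5} and per window end position, the best
// composite score max_k( m3(aa, T_k) - P_k ) over all frame-shift
// candidates of that window; traceback re-enumerates candidates on demand,
// in the same deterministic preference order, to recover the winner.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -1e30;

struct Par {
  double S, D, h, k, G0, Ge, stop_score;
  bool V, neutral;
};

struct ReadCtx {
  std::vector<int> seq;        // per-base nucleotide codes
  std::vector<double> run_p;   // per-base run flowpeak
  std::vector<int> run_n;      // per-base run length
  std::vector<int> run_id;
  // insertion context, indexed [nt][gap] with gap in 0..L
  std::vector<int> ikind, in_;
  std::vector<double> ip;
  std::vector<int> iallow;
  int L;
  int codon_aa[125];           // codes c1*25 + c2*5 + c3 -> residue index

  int kat(int a, int g) const { return ikind[g * 4 + a]; }
  double pat(int a, int g) const { return ip[g * 4 + a]; }
  int nat(int a, int g) const { return in_[g * 4 + a]; }
  bool allowed(int a, int g) const { return iallow[g * 4 + a] != 0; }
  int aa_of(int c1, int c2, int c3) const {
    return codon_aa[c1 * 25 + c2 * 5 + c3];
  }
};

struct Cand {
  int trip[3];
  int event;              // 1 del1, 2 del2g, 3 del2s, 4 ins1, 5 ins2g, 6 ins2s
  int pos1, pos2;         // deleted read positions, -1 if none
  int gap1, gap2;         // insertion gaps, -1 if none
  int nt1, nt2;           // inserted nucleotide codes, -1 if none
  double penalty;
};

static inline double dev(double p, int n, int m) {
  double d = (m < n) ? p - (m + 0.5) : (m > n ? (m - 0.5) - p : 0.0);
  return d > 0 ? d : 0;
}

static inline double pfac(double p, int n, int m, double k) {
  double f = 1.0 - dev(p, n, m) / (k * (n > 1 ? n : 1));
  if (f < 0) f = 0;
  if (f > 1) f = 1;
  return f;
}

static inline double fpen(double P0, double h, double f) {
  return P0 - P0 * (1.0 - h) * f;
}

static inline double del_factor(const ReadCtx& r, const Par& par, int t,
                                int off) {
  if (par.neutral) return 0.0;
  return pfac(r.run_p[t], r.run_n[t], r.run_n[t] - off, par.k);
}

static inline double ins_factor(const ReadCtx& r, const Par& par, int g,
                                int a, int count) {
  if (par.neutral) return 0.0;
  int kind = r.kat(a, g);
  if (kind == 1) {
    int n = r.nat(a, g);
    return pfac(r.pat(a, g), n, n + count, par.k);
  }
  if (kind == 2) return pfac(r.pat(a, g), 0, count, par.k);
  return 0.0;
}

// Alphabetical insertion order over codes: A=1, C=2, G=3, T=0.
static const int ALPHA[4] = {1, 2, 3, 0};

// Enumerate candidates for the window of `w` bases ending at 0-based `at`,
// in tie-break preference order (grouped before split, leftmost first,
// alphabetical inserted nucleotide).
static void enumerate(const ReadCtx& r, const Par& par, int at, int w,
                      std::vector<Cand>& out) {
  out.clear();
  bool validate = par.V && !par.neutral;
  if (w == 4 || w == 5) {
    int s = at - w + 1;
    if (w == 4) {
      for (int t = s; t <= s + 3; ++t) {
        Cand c{};
        int k = 0;
        for (int u = s; u <= at; ++u) if (u != t) c.trip[k++] = r.seq[u];
        c.event = 1; c.pos1 = t; c.pos2 = -1;
        c.gap1 = c.gap2 = c.nt1 = c.nt2 = -1;
        c.penalty = fpen(par.S, par.h, del_factor(r, par, t, 1));
        out.push_back(c);
      }
    } else {
      for (int t = s; t <= s + 3; ++t) {       // grouped adjacent pairs
        Cand c{};
        int k = 0;
        for (int u = s; u <= at; ++u)
          if (u != t && u != t + 1) c.trip[k++] = r.seq[u];
        double f = (r.run_id[t] == r.run_id[t + 1])
                     ? del_factor(r, par, t, 2) : 0.0;
        c.event = 2; c.pos1 = t; c.pos2 = t + 1;
        c.gap1 = c.gap2 = c.nt1 = c.nt2 = -1;
        c.penalty = fpen(par.D, par.h, f);
        out.push_back(c);
      }
      for (int t1 = s; t1 <= s + 2; ++t1) {    // split pairs
        for (int t2 = t1 + 2; t2 <= s + 4; ++t2) {
          Cand c{};
          int k = 0;
          for (int u = s; u <= at; ++u)
            if (u != t1 && u != t2) c.trip[k++] = r.seq[u];
          c.event = 3; c.pos1 = t1; c.pos2 = t2;
          c.gap1 = c.gap2 = c.nt1 = c.nt2 = -1;
          c.penalty = fpen(par.S, par.h, del_factor(r, par, t1, 1)) +
                      fpen(par.S, par.h, del_factor(r, par, t2, 1));
          out.push_back(c);
        }
      }
    }
    return;
  }
  if (w == 2) {                                // single insertion
    int s = at - 1;
    for (int g = s; g <= s + 2; ++g) {
      for (int ai = 0; ai < 4; ++ai) {
        int a = ALPHA[ai];
        if (validate && !r.allowed(a, g)) continue;
        Cand c{};
        if (g == s)      { c.trip[0] = a; c.trip[1] = r.seq[s]; c.trip[2] = r.seq[at]; }
        else if (g == s + 1) { c.trip[0] = r.seq[s]; c.trip[1] = a; c.trip[2] = r.seq[at]; }
        else             { c.trip[0] = r.seq[s]; c.trip[1] = r.seq[at]; c.trip[2] = a; }
        c.event = 4; c.pos1 = c.pos2 = -1;
        c.gap1 = g; c.gap2 = -1; c.nt1 = a; c.nt2 = -1;
        c.penalty = fpen(par.S, par.h, ins_factor(r, par, g, a, 1));
        out.push_back(c);
      }
    }
    return;
  }
  // w == 1: double insertion around base `at`
  int s = at;
  for (int g = s; g <= s + 1; ++g) {           // grouped
    for (int i1 = 0; i1 < 4; ++i1) for (int i2 = 0; i2 < 4; ++i2) {
      int a1 = ALPHA[i1], a2 = ALPHA[i2];
      if (validate && (!r.allowed(a1, g) || !r.allowed(a2, g))) continue;
      Cand c{};
      if (g == s) { c.trip[0] = a1; c.trip[1] = a2; c.trip[2] = r.seq[s]; }
      else        { c.trip[0] = r.seq[s]; c.trip[1] = a1; c.trip[2] = a2; }
      double f = (a1 == a2) ? ins_factor(r, par, g, a1, 2) : 0.0;
      c.event = 5; c.pos1 = c.pos2 = -1;
      c.gap1 = g; c.gap2 = g; c.nt1 = a1; c.nt2 = a2;
      c.penalty = fpen(par.D, par.h, f);
      out.push_back(c);
    }
  }
  for (int i1 = 0; i1 < 4; ++i1) for (int i2 = 0; i2 < 4; ++i2) {  // split
    int a1 = ALPHA[i1], a2 = ALPHA[i2];
    if (validate && (!r.allowed(a1, s) || !r.allowed(a2, s + 1))) continue;
    Cand c{};
    c.trip[0] = a1; c.trip[1] = r.seq[s]; c.trip[2] = a2;
    c.event = 6; c.pos1 = c.pos2 = -1;
    c.gap1 = s; c.gap2 = s + 1; c.nt1 = a1; c.nt2 = a2;
    c.penalty = fpen(par.S, par.h, ins_factor(r, par, s, a1, 1)) +
                fpen(par.S, par.h, ins_factor(r, par, s + 1, a2, 1));
    out.push_back(c);
  }
}

// m3 of residue `aa` against the (possibly N-containing) triplet.
static inline double m3c(const ReadCtx& r, const Par& par,
                         const NumericMatrix& mat, int aa,
                         int c1, int c2, int c3) {
  int res = r.aa_of(c1, c2, c3);
  if (res == 23) return par.stop_score;  // stop sentinel
  return mat(aa, res);
}

// Best candidate for (aa, window ending at `at`, width w); returns score,
// sets *win to the index of the winner (first at ties).
static double best_candidate(const ReadCtx& r, const Par& par,
                             const NumericMatrix& mat, int aa, int at, int w,
                             std::vector<Cand>& scratch, int* win) {
  enumerate(r, par, at, w, scratch);
  double best = NEG_INF;
  int bi = -1;
  for (size_t i = 0; i < scratch.size(); ++i) {
    const Cand& c = scratch[i];
    double v = m3c(r, par, mat, aa, c.trip[0], c.trip[1], c.trip[2]) -
               c.penalty;
    if (v > best) { best = v; bi = (int)i; }
  }
  if (win) *win = bi;
  return best;
}

static ReadCtx make_ctx(const List& rc) {
  ReadCtx r;
  IntegerVector seq = rc["seq"];
  NumericVector rp = rc["run_p"];
  IntegerVector rn = rc["run_n"], rid = rc["run_id"];
  IntegerMatrix ik = rc["ins_kind"], in2 = rc["ins_n"], ia = rc["ins_allowed"];
  NumericMatrix ipm = rc["ins_p"];
  IntegerVector cod = rc["codon_aa"];
  r.L = seq.size();
  r.seq.assign(seq.begin(), seq.end());
  r.run_p.assign(rp.begin(), rp.end());
  r.run_n.assign(rn.begin(), rn.end());
  r.run_id.assign(rid.begin(), rid.end());
  r.ikind.assign(ik.begin(), ik.end());
  r.ip.assign(ipm.begin(), ipm.end());
  r.in_.assign(in2.begin(), in2.end());
  r.iallow.assign(ia.begin(), ia.end());
  for (int i = 0; i < 125; ++i) r.codon_aa[i] = cod[i];
  return r;
}

static Par make_par(const List& pl) {
  Par p;
  p.S = pl["S"]; p.D = pl["D"]; p.h = pl["h"]; p.k = pl["k"];
  p.G0 = pl["G0"]; p.Ge = pl["Ge"];
  p.V = as<bool>(pl["V"]);
  p.neutral = as<bool>(pl["neutral"]);
  p.stop_score = pl["stop_score"];
  return p;
}

// [[Rcpp::export]]
List cpp_build_profile(List read_ctx, List par_list, NumericMatrix mat) {
  ReadCtx r = make_ctx(read_ctx);
  Par par = make_par(par_list);
  const int nAA = mat.nrow();
  const int widths[5] = {1, 2, 3, 4, 5};
  List out(5);
  std::vector<Cand> scratch;
  for (int wi = 0; wi < 5; ++wi) {
    int w = widths[wi];
    NumericMatrix m(nAA, r.L);
    for (int at = 0; at < r.L; ++at) {
      if (at - w + 1 < 0) {
        for (int aa = 0; aa < nAA; ++aa) m(aa, at) = NEG_INF;
        continue;
      }
      if (w == 3) {
        for (int aa = 0; aa < nAA; ++aa)
          m(aa, at) = m3c(r, par, mat, aa, r.seq[at - 2], r.seq[at - 1],
                          r.seq[at]);
      } else {
        enumerate(r, par, at, w, scratch);
        for (int aa = 0; aa < nAA; ++aa) {
          double best = NEG_INF;
          for (size_t ci = 0; ci < scratch.size(); ++ci) {
            const Cand& c = scratch[ci];
            double v = m3c(r, par, mat, aa, c.trip[0], c.trip[1],
                           c.trip[2]) - c.penalty;
            if (v > best) best = v;
          }
          m(aa, at) = best;
        }
      }
    }
    out[wi] = m;
  }
  out.attr("names") = CharacterVector::create("m1", "m2", "m3", "m4", "m5");
  return out;
}

// [[Rcpp::export]]
List cpp_align(List profile, List read_ctx, List par_list, NumericMatrix mat,
               IntegerVector protein) {
  ReadCtx r = make_ctx(read_ctx);
  Par par = make_par(par_list);
  const int Lp = protein.size(), Lq = r.L;
  NumericMatrix pm[5] = {as<NumericMatrix>(profile[0]),
                         as<NumericMatrix>(profile[1]),
                         as<NumericMatrix>(profile[2]),
                         as<NumericMatrix>(profile[3]),
                         as<NumericMatrix>(profile[4])};
  const size_t ncell = (size_t)(Lp + 1) * (Lq + 1);
  std::vector<double> S(ncell, 0.0), E(ncell, NEG_INF), H(ncell, NEG_INF);
  std::vector<signed char> ptrS(ncell, 0), openE(ncell, 0), openH(ncell, 0);
  const int W = Lq + 1;
#define IX(i, j) ((size_t)(i) * W + (j))
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= Lp; ++i) {
    int aa = protein[i - 1];
    for (int j = 0; j <= Lq; ++j) {
      // E: protein-consuming gap
      double eo = S[IX(i - 1, j)] - par.G0;
      double ee = (i >= 2) ? E[IX(i - 1, j)] - par.Ge : NEG_INF;
      if (eo >= ee) { E[IX(i, j)] = eo; openE[IX(i, j)] = 1; }
      else          { E[IX(i, j)] = ee; openE[IX(i, j)] = 0; }
      // H: codon-consuming gap
      if (j >= 3) {
        double ho = S[IX(i, j - 3)] - par.G0;
        double he = H[IX(i, j - 3)] - par.Ge;
        if (ho >= he) { H[IX(i, j)] = ho; openH[IX(i, j)] = 1; }
        else          { H[IX(i, j)] = he; openH[IX(i, j)] = 0; }
      }
      double v = NEG_INF;
      signed char pt = 0;
      for (int w = 1; w <= 5; ++w) {
        if (j - w < 0) continue;
        double mw = pm[w - 1](aa, j - 1);
        if (mw <= NEG_INF / 2) continue;
        double cand = S[IX(i - 1, j - w)] + mw;
        if (cand > v) { v = cand; pt = (signed char)w; }
      }
      if (E[IX(i, j)] > v) { v = E[IX(i, j)]; pt = 6; }
      if (H[IX(i, j)] > v) { v = H[IX(i, j)]; pt = 7; }
      if (v < 0) { v = 0.0; pt = 0; }
      S[IX(i, j)] = v;
      ptrS[IX(i, j)] = pt;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  // Traceback
  std::vector<Cand> scratch;
  std::vector<std::array<double, 16>> steps;  // reversed order
  int i = bi, j = bj;
  if (best > 0) {
    while (i > 0 && S[IX(i, j)] > 0 && ptrS[IX(i, j)] != 0) {
      signed char pt = ptrS[IX(i, j)];
      if (pt >= 1 && pt <= 5) {
        int w = pt;
        std::array<double, 16> st{};
        st[0] = 0; st[1] = w; st[2] = i; st[3] = j;
        if (w == 3) {
          st[4] = -1; st[5] = r.seq[j - 3]; st[6] = r.seq[j - 2];
          st[7] = r.seq[j - 1];
          for (int q = 8; q < 15; ++q) st[q] = -1;
          st[15] = 0.0;
        } else {
          int win = -1;
          best_candidate(r, par, mat, protein[i - 1], j - 1, w, scratch,
                         &win);
          const Cand& c = scratch[win];
          st[4] = c.event;
          st[5] = c.trip[0]; st[6] = c.trip[1]; st[7] = c.trip[2];
          st[8] = c.pos1; st[9] = c.pos2;
          st[10] = c.gap1; st[11] = c.gap2;
          st[12] = c.nt1; st[13] = c.nt2;
          st[14] = -1;
          st[15] = c.penalty;
        }
        steps.push_back(st);
        i -= 1; j -= w;
      } else if (pt == 6) {
        while (true) {
          std::array<double, 16> st{};
          st[0] = 1; st[1] = 0; st[2] = i; st[3] = j;
          for (int q = 4; q < 15; ++q) st[q] = -1;
          bool op = openE[IX(i, j)] != 0;
          st[14] = op ? 1 : 0;
          steps.push_back(st);
          i -= 1;
          if (op) break;
        }
      } else {  // pt == 7
        while (true) {
          std::array<double, 16> st{};
          st[0] = 2; st[1] = 0; st[2] = i; st[3] = j;
          st[4] = -1;
          st[5] = r.seq[j - 3]; st[6] = r.seq[j - 2]; st[7] = r.seq[j - 1];
          for (int q = 8; q < 14; ++q) st[q] = -1;
          bool op = openH[IX(i, j)] != 0;
          st[14] = op ? 1 : 0;
          steps.push_back(st);
          j -= 3;
          if (op) break;
        }
      }
    }
  }
  int ns = (int)steps.size();
  NumericMatrix sm(ns, 16);
  for (int s = 0; s < ns; ++s)
    for (int q = 0; q < 16; ++q) sm(s, q) = steps[ns - 1 - s][q];
  colnames(sm) = CharacterVector::create(
      "kind", "w", "i", "j", "event", "t1", "t2", "t3", "pos1", "pos2",
      "gap1", "gap2", "nt1", "nt2", "spare", "penalty");
  return List::create(_["score"] = best, _["i_end"] = bi, _["j_end"] = bj,
                      _["i_start"] = i, _["j_start"] = j, _["steps"] = sm);
#undef IX
}

// [[Rcpp::export]]
List cpp_best_candidate(List read_ctx, List par_list, NumericMatrix mat,
                        int aa, int at, int w) {
  ReadCtx r = make_ctx(read_ctx);
  Par par = make_par(par_list);
  std::vector<Cand> scratch;
  int win = -1;
  double sc = best_candidate(r, par, mat, aa, at, w, scratch, &win);
  if (win < 0) return List::create(_["score"] = NEG_INF);
  const Cand& c = scratch[win];
  return List::create(
      _["score"] = sc, _["event"] = c.event,
      _["triplet"] = IntegerVector::create(c.trip[0], c.trip[1], c.trip[2]),
      _["pos"] = IntegerVector::create(c.pos1, c.pos2),
      _["gap"] = IntegerVector::create(c.gap1, c.gap2),
      _["nt"] = IntegerVector::create(c.nt1, c.nt2),
      _["penalty"] = c.penalty);
}
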