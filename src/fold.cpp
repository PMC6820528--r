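#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Self-contained pseudoknot-free secondary-structure model:
//   score = pair_score per canonical pair {AU,UA,GC,CG,GU,UG}
//         + stack_score per stacked pair (i,j) with (i+1,j-1) also paired,
//   hairpin loops >= min_loop unpaired nucleotides.
// MFE by dynamic programming over
//   W(i,j) = best score on [i,j]
//   V(i,j) = best score on [i,j] given (i,j) paired
// and equilibrium pairing probabilities by an unambiguous inside-outside
// recursion over the same ensemble at inverse temperature beta, with
// per-nucleotide rescaling so long sequences neither overflow nor underflow.

static const double INF = std::numeric_limits<double>::infinity();

static inline int encode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline bool can_pair(int a, int b) {
  if (a < 0 || b < 0) return false;
  int x = a * 4 + b;
  // AU, UA, GC, CG, GU, UG
  return x == 3 || x == 12 || x == 6 || x == 9 || x == 11 || x == 14;
}

struct FoldParams {
  double ep;      // score per pair (negative = favourable)
  double es;      // extra score per stacked pair
  int ml;         // minimum hairpin loop length
  double beta;    // dimensionless inverse temperature
};

class Idx {
public:
  int n;
  explicit Idx(int n_) : n(n_) {}
  inline size_t operator()(int i, int j) const { return (size_t)i * n + j; }
};

static std::vector<int> encode_seq(const std::string &s) {
  std::vector<int> e(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    e[i] = encode(s[i]);
    if (e[i] < 0) stop("invalid nucleotide in sequence");
  }
  return e;
}

// ---------------- MFE ----------------

static void fill_mfe(const std::vector<int> &s, const FoldParams &p,
                     std::vector<double> &W, std::vector<double> &V) {
  int n = (int)s.size();
  Idx ix(n);
  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (span < p.ml + 1) { W[ix(i, j)] = 0.0; V[ix(i, j)] = INF; continue; }
      // V(i,j)
      double v = INF;
      if (can_pair(s[i], s[j])) {
        // interior [i+1, j-1]: either (i+1,j-1) paired (stack) or not (Wnp)
        double inner = INF;
        int a = i + 1, b = j - 1;
        if (b - a >= p.ml + 1 && can_pair(s[a], s[b]) && V[ix(a, b)] < INF)
          inner = std::min(inner, V[ix(a, b)] + p.es);
        // Wnp(a,b): best on [a,b] with (a,b) not mutually paired
        double wnp;
        if (b - a < p.ml + 1) {
          wnp = 0.0;
        } else {
          wnp = W[ix(a, b - 1)];
          for (int k = a + 1; k <= b - p.ml - 1; ++k) {
            if (can_pair(s[k], s[b]) && V[ix(k, b)] < INF) {
              double cand = W[ix(a, k - 1)] + V[ix(k, b)];
              if (cand < wnp) wnp = cand;
            }
          }
        }
        inner = std::min(inner, wnp);
        v = p.ep + inner;
      }
      V[ix(i, j)] = v;
      // W(i,j): j unpaired, or j paired with k
      double w = W[ix(i, j - 1)];
      for (int k = i; k <= j - p.ml - 1; ++k) {
        if (can_pair(s[k], s[j]) && V[ix(k, j)] < INF) {
          double left = (k > i) ? W[ix(i, k - 1)] : 0.0;
          double cand = left + V[ix(k, j)];
          if (cand < w) w = cand;
        }
      }
      W[ix(i, j)] = w;
    }
  }
}

static const double EPSC = 1e-9;

static void trace_W(int i, int j, const std::vector<int> &s, const FoldParams &p,
                    const std::vector<double> &W, const std::vector<double> &V,
                    std::string &db);

static void trace_V(int i, int j, const std::vector<int> &s, const FoldParams &p,
                    const std::vector<double> &W, const std::vector<double> &V,
                    std::string &db) {
  Idx ix((int)s.size());
  db[i] = '('; db[j] = ')';
  int a = i + 1, b = j - 1;
  if (b - a < p.ml + 1) return;
  double target = V[ix(i, j)] - p.ep;
  // prefer the stacked continuation when it attains the optimum
  if (can_pair(s[a], s[b]) && V[ix(a, b)] < INF &&
      std::fabs(V[ix(a, b)] + p.es - target) < EPSC) {
    trace_V(a, b, s, p, W, V, db);
    return;
  }
  // otherwise trace Wnp(a,b)
  if (std::fabs(W[ix(a, b - 1)] - target) < EPSC) {
    trace_W(a, b - 1, s, p, W, V, db);
    return;
  }
  for (int k = a + 1; k <= b - p.ml - 1; ++k) {
    if (can_pair(s[k], s[b]) && V[ix(k, b)] < INF &&
        std::fabs(W[ix(a, k - 1)] + V[ix(k, b)] - target) < EPSC) {
      trace_W(a, k - 1, s, p, W, V, db);
      trace_V(k, b, s, p, W, V, db);
      return;
    }
  }
  stop("internal traceback failure (V)");
}

static void trace_W(int i, int j, const std::vector<int> &s, const FoldParams &p,
                    const std::vector<double> &W, const std::vector<double> &V,
                    std::string &db) {
  Idx ix((int)s.size());
  while (j - i >= p.ml + 1) {
    if (std::fabs(W[ix(i, j)] - W[ix(i, j - 1)]) < EPSC) { --j; continue; }
    bool found = false;
    for (int k = i; k <= j - p.ml - 1; ++k) {
      if (!can_pair(s[k], s[j]) || !(V[ix(k, j)] < INF)) continue;
      double left = (k > i) ? W[ix(i, k - 1)] : 0.0;
      if (std::fabs(left + V[ix(k, j)] - W[ix(i, j)]) < EPSC) {
        trace_V(k, j, s, p, W, V, db);
        if (k > i) { j = k - 1; } else { return; }
        found = true;
        break;
      }
    }
    if (!found) stop("internal traceback failure (W)");
  }
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, double pair_score, double stack_score,
                  int min_loop) {
  std::vector<int> s = encode_seq(seq);
  int n = (int)s.size();
  FoldParams p{pair_score, stack_score, min_loop, 1.0};
  if (n == 0) return List::create(_["energy"] = 0.0, _["dotbracket"] = "");
  if (n > 20000) stop("sequence too long for the built-in folder");
  Idx ix(n);
  std::vector<double> W((size_t)n * n, 0.0), V((size_t)n * n, INF);
  fill_mfe(s, p, W, V);
  std::string db(n, '.');
  trace_W(0, n - 1, s, p, W, V, db);
  return List::create(_["energy"] = W[ix(0, n - 1)], _["dotbracket"] = db);
}

// ---------------- partition function / pairing probabilities ----------------
//
// Scaled Boltzmann weights: every nucleotide carries a factor f = exp(-a);
// qp = exp(-beta*ep), qs = exp(-beta*es). Unambiguous decomposition:
//   Z(i,j)  = Z(i,j-1)*f + sum_k Z(i,k-1)*Zb(k,j)
//   Zb(i,j) = qp*f^2 * ( Zb(i+1,j-1)*qs + Znp(i+1,j-1) ),
//   Znp     = Z - Zb (Z minus the (i,j)-mutually-paired structures).
// Outside weight O(i,j) of a pair, processed by decreasing span:
//   O(i,j) = Z(0,i-1)*Z(j+1,n-1)
//          + sum_{k<i,l>j} O(k,l)*qp(k,l)*f^2 *
//              ( (k,l)==(i-1,j+1) ? qs : Z(k+1,i-1)*Z(j+1,l-1) )
// organised through M(k,j) = sum_{l>j} O(k,l)*qp*f^2*Z(j+1,l-1) so the whole
// pass stays O(n^3). P(i,j) = Zb(i,j)*O(i,j)/Z(0,n-1).

struct InsideResult {
  std::vector<double> Z, Zb;
  double Ztot;
  bool overflow;
};

static void run_inside(const std::vector<int> &s, const FoldParams &p,
                       double f, InsideResult &res) {
  int n = (int)s.size();
  Idx ix(n);
  double qp = std::exp(-p.beta * p.ep), qs = std::exp(-p.beta * p.es);
  res.Z.assign((size_t)n * n, 0.0);
  res.Zb.assign((size_t)n * n, 0.0);
  res.overflow = false;
  std::vector<double> &Z = res.Z, &Zb = res.Zb;
  for (int span = 0; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (span < p.ml + 1) {
        // only the open chain
        Z[ix(i, j)] = std::pow(f, span + 1);
        continue;
      }
      int a = i + 1, b = j - 1;
      double zin;   // interior Z on [a,b]
      double zbin;  // interior Zb(a,b)
      if (b - a < p.ml + 1) { zin = std::pow(f, b - a + 1); zbin = 0.0; }
      else { zin = Z[ix(a, b)]; zbin = Zb[ix(a, b)]; }
      if (can_pair(s[i], s[j])) {
        double znp = zin - zbin;
        Zb[ix(i, j)] = qp * f * f * (zbin * qs + znp);
      }
      double z = Z[ix(i, j - 1)] * f;
      for (int k = i; k <= j - p.ml - 1; ++k) {
        if (Zb[ix(k, j)] > 0.0) {
          double left = (k > i) ? Z[ix(i, k - 1)] : 1.0;
          z += left * Zb[ix(k, j)];
        }
      }
      Z[ix(i, j)] = z;
      if (z > 1e280 || !std::isfinite(z)) { res.overflow = true; return; }
    }
  }
  res.Ztot = Z[ix(0, n - 1)];
}

// [[Rcpp::export(name = ".pair_prob_cpp")]]
NumericVector pair_prob_cpp(std::string seq, double pair_score,
                            double stack_score, int min_loop, double beta) {
  std::vector<int> s = encode_seq(seq);
  int n = (int)s.size();
  NumericVector pv(n);
  if (n == 0) return pv;
  if (n > 4000) stop("sequence too long for the built-in partition function");
  FoldParams p{pair_score, stack_score, min_loop, beta};
  Idx ix(n);

  bool any_pair = false;
  for (int i = 0; i < n && !any_pair; ++i)
    for (int j = i + p.ml + 1; j < n; ++j)
      if (can_pair(s[i], s[j])) { any_pair = true; break; }
  if (!any_pair) return pv;  // open chain only: all probabilities zero

  // MFE for the initial scale estimate
  std::vector<double> W((size_t)n * n, 0.0), V((size_t)n * n, INF);
  fill_mfe(s, p, W, V);
  double e0 = W[ix(0, n - 1)];

  double a = p.beta * std::fabs(e0) / n + 0.3;
  InsideResult ins;
  bool ok = false;
  for (int iter = 0; iter < 24 && !ok; ++iter) {
    run_inside(s, p, std::exp(-a), ins);
    if (ins.overflow) { a += 1.0; continue; }
    if (!(ins.Ztot > 0.0)) { a -= 1.0; continue; }
    double lz = std::log(ins.Ztot);
    if (std::fabs(lz) > 180.0) { a += lz / n; continue; }
    ok = true;
  }
  if (!ok) stop("partition function scaling failed to converge");
  double f = std::exp(-a);
  double qs = std::exp(-p.beta * p.es);
  std::vector<double> &Z = ins.Z, &Zb = ins.Zb;
  double Ztot = ins.Ztot;

  // helper: Z over [i,j] with empty regions = 1
  auto Zr = [&](int i, int j) -> double {
    if (i > j) return 1.0;
    return Z[ix(i, j)];
  };

  std::vector<double> O((size_t)n * n, 0.0), M((size_t)n * n, 0.0);
  double f2 = f * f;
  double qpf2 = std::exp(-p.beta * p.ep) * f2;

  for (int span = n - 1; span >= p.ml + 1; --span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      if (Zb[ix(i, j)] <= 0.0) continue;
      // exterior with (i,j) unenclosed
      double o = Zr(0, i - 1) * Zr(j + 1, n - 1);
      // enclosed by some (k,l), via M
      for (int k = 0; k < i; ++k) {
        if (M[ix(k, j)] > 0.0) o += M[ix(k, j)] * Zr(k + 1, i - 1);
      }
      // stacking correction for the immediately enclosing pair
      if (i >= 1 && j + 1 < n && Zb[ix(i - 1, j + 1)] > 0.0 && O[ix(i - 1, j + 1)] > 0.0) {
        o += O[ix(i - 1, j + 1)] * qpf2 * (qs - 1.0);
      }
      O[ix(i, j)] = o;
    }
    // push this span's outside weights into M for smaller spans
    for (int k = 0; k + span < n; ++k) {
      int l = k + span;
      if (Zb[ix(k, l)] <= 0.0 || O[ix(k, l)] <= 0.0) continue;
      double base = O[ix(k, l)] * qpf2;
      for (int j = k + 1; j < l; ++j) {
        M[ix(k, j)] += base * Zr(j + 1, l - 1);
      }
    }
  }

  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = i + p.ml + 1; j < n; ++j)
      if (Zb[ix(i, j)] > 0.0) acc += Zb[ix(i, j)] * O[ix(i, j)] / Ztot;
    for (int k = 0; k + p.ml + 1 <= i; ++k)
      if (Zb[ix(k, i)] > 0.0) acc += Zb[ix(k, i)] * O[ix(k, i)] / Ztot;
    pv[i] = std::min(std::max(acc, 0.0), 1.0);
  }
  return pv;
}
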