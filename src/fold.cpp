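// Thermodynamic folding core: minimum-free-energy dynamic programming with
// deterministic traceback, and an inside-outside partition function giving
// base-pair probabilities. Both recursions score structures with exactly
// the same loop-decomposition model as the R-level structure_energy()
// oracle: stacks, length-dependent hairpin/bulge/internal penalties with
// logarithmic extrapolation beyond 30 nt, and an affine multibranch term
// a + b*(branches incl. closing) + c*unpaired. No dangles, no coaxial
// stacking, no pseudoknots.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

struct Model {
  double stack[6][6];
  double hp[31], bu[31], il[31]; // 1-based loop length tables
  double coef;                   // log-extrapolation slope
  double a, b, c;                // multiloop affine terms
  int minhp, maxspan;
  double rt;
};

// base codes: A=0, C=1, G=2, U=3; pair types AU,UA,CG,GC,GU,UG -> 0..5
static inline int ptype(int x, int y) {
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

static inline double loopE(const double *tab, int len, double coef) {
  return (len <= 30) ? tab[len] : tab[30] + coef * std::log(len / 30.0);
}

// energy of the loop between outer pair (with type ptO) and inner pair
// (type ptI) with l1/l2 unpaired nucleotides on the 5'/3' sides
static inline double interiorE(const Model &m, int ptO, int ptI,
                               int l1, int l2) {
  if (l1 == 0 && l2 == 0) return m.stack[ptO][ptI];
  if (l1 + l2 > m.maxspan) return INF;
  if (l1 == 0 || l2 == 0) return loopE(m.bu, l1 + l2, m.coef);
  return loopE(m.il, l1 + l2, m.coef);
}

static Model build_model(NumericMatrix stack, NumericVector hp,
                         NumericVector bu, NumericVector il, double coef,
                         NumericVector ml, int minhp, int maxspan,
                         double rt) {
  Model m;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) m.stack[i][j] = stack(i, j);
  for (int l = 1; l <= 30; ++l) {
    m.hp[l] = hp[l - 1];
    m.bu[l] = bu[l - 1];
    m.il[l] = il[l - 1];
  }
  m.coef = coef;
  m.a = ml[0];
  m.b = ml[1];
  m.c = ml[2];
  m.minhp = minhp;
  m.maxspan = maxspan;
  m.rt = rt;
  return m;
}

// [[Rcpp::export]]
List c_mfe_fold(IntegerVector seq, NumericMatrix stack, NumericVector hp,
                NumericVector bu, NumericVector il, double coef,
                NumericVector ml, int minhp, int maxspan) {
  const int n = seq.size();
  if (n > 10000) stop("sequence longer than the 10000-nt folding limit");
  Model m = build_model(stack, hp, bu, il, coef, ml, minhp, maxspan, 0.0);
  std::vector<int> s(seq.begin(), seq.end());

  if (n == 0) return List::create(_["structure"] = "", _["energy"] = 0.0);

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF),
      WM1((size_t)n * n, INF);
  std::vector<double> W(n + 1, 0.0);

  for (int j = 0; j < n; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      const int pt0 = ptype(s[i], s[j]);
      double best = INF;
      if (pt0 >= 0 && j - i - 1 >= m.minhp) {
        best = loopE(m.hp, j - i - 1, m.coef);
        for (int l1 = 0; l1 <= m.maxspan; ++l1) {
          const int k = i + 1 + l1;
          if (k >= j) break;
          for (int l2 = 0; l2 <= m.maxspan - l1; ++l2) {
            const int l = j - 1 - l2;
            if (l - k - 1 < m.minhp) break;
            const double vkl = V[(size_t)k * n + l];
            if (vkl < INF / 2) {
              const double e =
                  interiorE(m, pt0, ptype(s[k], s[l]), l1, l2) + vkl;
              if (e < best) best = e;
            }
          }
        }
        for (int k = i + 2; k <= j - 2; ++k) {
          const double wma = WM[(size_t)(i + 1) * n + (k - 1)];
          const double wm1 = WM1[(size_t)k * n + (j - 1)];
          if (wma < INF / 2 && wm1 < INF / 2) {
            const double e = m.a + m.b + wma + wm1;
            if (e < best) best = e;
          }
        }
      }
      V[(size_t)i * n + j] = best;

      // WM1(i,j): one branch starting at i, trailing unpaired to j
      double w1 = INF;
      const double prev = WM1[(size_t)i * n + (j - 1)];
      if (j - 1 > i && prev < INF / 2) w1 = prev + m.c;
      if (best < INF / 2 && best + m.b < w1) w1 = best + m.b;
      WM1[(size_t)i * n + j] = w1;
    }
    // WM(i,j): >=1 branch on i..j, decomposed by the start of the last one
    for (int i = j - 1; i >= 0; --i) {
      double best = INF;
      for (int k = i; k <= j; ++k) {
        const double w1 = WM1[(size_t)k * n + j];
        if (w1 >= INF / 2) continue;
        const double pre = m.c * (k - i) + w1;
        if (pre < best) best = pre;
        if (k > i) {
          const double wmp = WM[(size_t)i * n + (k - 1)];
          if (wmp < INF / 2 && wmp + w1 < best) best = wmp + w1;
        }
      }
      WM[(size_t)i * n + j] = best;
    }
  }

  for (int j = 0; j < n; ++j) {
    W[j + 1] = W[j];
    for (int i = 0; i <= j; ++i) {
      const double v = V[(size_t)i * n + j];
      if (v < INF / 2 && W[i] + v < W[j + 1]) W[j + 1] = W[i] + v;
    }
  }

  // deterministic traceback; candidates scanned 5' to 3'
  std::vector<int> pair(n, -1);
  struct Frame {
    int type; // 0 = pair closed at (i,j), 1 = WM, 2 = WM1
    int i, j;
  };
  std::vector<Frame> stk;
  {
    int j = n - 1;
    while (j >= 0) {
      if (std::fabs(W[j + 1] - W[j]) < EPS &&
          W[j + 1] >= W[j] - EPS) {
        // leaving j unpaired is optimal only if W[j+1] == W[j]
        bool paired = false;
        if (W[j + 1] < W[j] - EPS) paired = true;
        if (!paired) {
          --j;
          continue;
        }
      }
      int found = -1;
      for (int i = 0; i <= j; ++i) {
        const double v = V[(size_t)i * n + j];
        if (v < INF / 2 && std::fabs(W[i] + v - W[j + 1]) < EPS) {
          found = i;
          break;
        }
      }
      if (found < 0) { --j; continue; } // numerical safety net
      stk.push_back({0, found, j});
      j = found - 1;
    }
  }
  while (!stk.empty()) {
    Frame f = stk.back();
    stk.pop_back();
    const int i = f.i, j = f.j;
    if (f.type == 0) {
      pair[i] = j;
      pair[j] = i;
      const int pt0 = ptype(s[i], s[j]);
      const double v = V[(size_t)i * n + j];
      if (std::fabs(v - loopE(m.hp, j - i - 1, m.coef)) < EPS) continue;
      bool done = false;
      for (int l1 = 0; l1 <= m.maxspan && !done; ++l1) {
        const int k = i + 1 + l1;
        if (k >= j) break;
        for (int l2 = 0; l2 <= m.maxspan - l1; ++l2) {
          const int l = j - 1 - l2;
          if (l - k - 1 < m.minhp) break;
          const double vkl = V[(size_t)k * n + l];
          if (vkl < INF / 2 &&
              std::fabs(interiorE(m, pt0, ptype(s[k], s[l]), l1, l2) + vkl -
                        v) < EPS) {
            stk.push_back({0, k, l});
            done = true;
            break;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 2; ++k) {
        const double wma = WM[(size_t)(i + 1) * n + (k - 1)];
        const double wm1 = WM1[(size_t)k * n + (j - 1)];
        if (wma < INF / 2 && wm1 < INF / 2 &&
            std::fabs(m.a + m.b + wma + wm1 - v) < EPS) {
          stk.push_back({1, i + 1, k - 1});
          stk.push_back({2, k, j - 1});
          break;
        }
      }
    } else if (f.type == 2) {
      int jj = j;
      while (jj - 1 > i &&
             WM1[(size_t)i * n + (jj - 1)] < INF / 2 &&
             std::fabs(WM1[(size_t)i * n + jj] -
                       (WM1[(size_t)i * n + (jj - 1)] + m.c)) < EPS)
        --jj;
      stk.push_back({0, i, jj});
    } else { // WM
      const double wm = WM[(size_t)i * n + j];
      for (int k = i; k <= j; ++k) {
        const double w1 = WM1[(size_t)k * n + j];
        if (w1 >= INF / 2) continue;
        if (std::fabs(m.c * (k - i) + w1 - wm) < EPS) {
          stk.push_back({2, k, j});
          break;
        }
        if (k > i) {
          const double wmp = WM[(size_t)i * n + (k - 1)];
          if (wmp < INF / 2 && std::fabs(wmp + w1 - wm) < EPS) {
            stk.push_back({1, i, k - 1});
            stk.push_back({2, k, j});
            break;
          }
        }
      }
    }
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i)
    if (pair[i] > i) {
      db[i] = '(';
      db[pair[i]] = ')';
    }
  return List::create(_["structure"] = db, _["energy"] = W[n]);
}

// [[Rcpp::export]]
List c_partition(IntegerVector seq, NumericMatrix stack, NumericVector hp,
                 NumericVector bu, NumericVector il, double coef,
                 NumericVector ml, int minhp, int maxspan, double rt) {
  const int n = seq.size();
  if (n > 5000) stop("sequence longer than the 5000-nt partition limit");
  Model m = build_model(stack, hp, bu, il, coef, ml, minhp, maxspan, rt);
  std::vector<int> s(seq.begin(), seq.end());
  NumericMatrix P(n, n);
  if (n == 0) return List::create(_["prob"] = P, _["log_partition"] = 0.0);

  auto bw = [&](double e) { return std::exp(-e / m.rt); }; // Boltzmann
  const double ea = bw(m.a), eb = bw(m.b), ec = bw(m.c);

  std::vector<double> Qb((size_t)n * n, 0.0), Qm((size_t)n * n, 0.0),
      Qm1((size_t)n * n, 0.0);
  std::vector<double> ecp(n + 2, 1.0);
  for (int d = 1; d <= n + 1; ++d) ecp[d] = ecp[d - 1] * ec;

  for (int j = 0; j < n; ++j) {
    for (int i = j - 1; i >= 0; --i) {
      const int pt0 = ptype(s[i], s[j]);
      if (pt0 >= 0 && j - i - 1 >= m.minhp) {
        double q = bw(loopE(m.hp, j - i - 1, m.coef));
        for (int l1 = 0; l1 <= m.maxspan; ++l1) {
          const int k = i + 1 + l1;
          if (k >= j) break;
          for (int l2 = 0; l2 <= m.maxspan - l1; ++l2) {
            const int l = j - 1 - l2;
            if (l - k - 1 < m.minhp) break;
            const double qkl = Qb[(size_t)k * n + l];
            if (qkl > 0)
              q += bw(interiorE(m, pt0, ptype(s[k], s[l]), l1, l2)) * qkl;
          }
        }
        double qm = 0.0;
        for (int k = i + 2; k <= j - 2; ++k)
          qm += Qm[(size_t)(i + 1) * n + (k - 1)] *
                Qm1[(size_t)k * n + (j - 1)];
        Qb[(size_t)i * n + j] = q + ea * eb * qm;
      }
      Qm1[(size_t)i * n + j] =
          Qm1[(size_t)i * n + (j - 1)] * ec + Qb[(size_t)i * n + j] * eb;
    }
    for (int i = j - 1; i >= 0; --i) {
      double q = 0.0;
      for (int k = i; k <= j; ++k) {
        const double w1 = Qm1[(size_t)k * n + j];
        if (w1 <= 0) continue;
        q += ecp[k - i] * w1;
        if (k > i) q += Qm[(size_t)i * n + (k - 1)] * w1;
      }
      Qm[(size_t)i * n + j] = q;
    }
  }

  std::vector<double> Q(n + 1, 1.0), Qr(n + 2, 1.0);
  for (int j = 0; j < n; ++j) {
    Q[j + 1] = Q[j];
    for (int i = 0; i <= j; ++i) Q[j + 1] += Q[i] * Qb[(size_t)i * n + j];
  }
  for (int k = n - 1; k >= 0; --k) {
    Qr[k] = Qr[k + 1];
    for (int l = k + 1; l < n; ++l)
      Qr[k] += Qb[(size_t)k * n + l] * Qr[l + 1];
  }
  const double Z = Q[n];

  // outside pass: distribute enclosing-context weight to inner pairs
  std::vector<double> Qh((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (Qb[(size_t)i * n + j] > 0)
        Qh[(size_t)i * n + j] = Q[i] * Qr[j + 1];

  for (int d = n - 1; d >= m.minhp + 1; --d) {
    for (int i = 0; i + d < n; ++i) {
      const int j = i + d;
      const double qh = Qh[(size_t)i * n + j];
      if (Qb[(size_t)i * n + j] <= 0 || qh <= 0) continue;
      const int pt0 = ptype(s[i], s[j]);
      for (int l1 = 0; l1 <= m.maxspan; ++l1) {
        const int k = i + 1 + l1;
        if (k >= j) break;
        for (int l2 = 0; l2 <= m.maxspan - l1; ++l2) {
          const int l = j - 1 - l2;
          if (l - k - 1 < m.minhp) break;
          if (Qb[(size_t)k * n + l] > 0)
            Qh[(size_t)k * n + l] +=
                bw(interiorE(m, pt0, ptype(s[k], s[l]), l1, l2)) * qh;
        }
      }
      // (i,j) closes a multiloop containing the inner branch (ii,jj) plus
      // at least one more branch, either left of it or right of it
      const double base = qh * ea * eb * eb;
      for (int ii = i + 1; ii < j; ++ii) {
        const double leftQm =
            (ii - 1 >= i + 1) ? Qm[(size_t)(i + 1) * n + (ii - 1)] : 0.0;
        const double leftU = ecp[ii - i - 1];
        for (int jj = ii + m.minhp + 1; jj < j; ++jj) {
          if (Qb[(size_t)ii * n + jj] <= 0) continue;
          const double rightQm =
              (jj + 1 <= j - 2) ? Qm[(size_t)(jj + 1) * n + (j - 1)] : 0.0;
          const double rightAny = ecp[j - 1 - jj] + rightQm;
          const double w = base * (leftQm * rightAny + leftU * rightQm);
          if (w > 0) Qh[(size_t)ii * n + jj] += w;
        }
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double p = Qb[(size_t)i * n + j] * Qh[(size_t)i * n + j] / Z;
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i, j) = p;
    }
  return List::create(_["prob"] = P, _["log_partition"] = std::log(Z));
}
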