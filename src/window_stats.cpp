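#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Fast path for compute_profile(): the 12 per-subwindow statistics computed
// in one pass over a genotype matrix. Semantics match the R reference
// functions exactly (per-site called-chromosome counts, pairwise-complete
// genotype distances and r^2, diplotype spectrum over complete individuals,
// omega with zero-between-sum splits skipped).

namespace {

double harmonic_n(int k) {
  double a = 0;
  for (int i = 1; i <= k; ++i) a += 1.0 / i;
  return a;
}

struct WinStats {
  double pi, thetaW, tajD, varG, skewG, kurtG, nDip, J1, J12, J2J1, ZnS, omega;
};

// column-major access into the n x m genotype matrix (NA = INT_MIN)
inline int gv(const IntegerMatrix &G, int i, int j) { return G(i, j); }

WinStats window_stats_one(const IntegerMatrix &G, const std::vector<int> &cols) {
  WinStats w = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  int n = G.nrow();
  int m = (int)cols.size();

  // per-site counts
  std::vector<int> alt(m), called(m);
  for (int jj = 0; jj < m; ++jj) {
    int j = cols[jj], a = 0, c = 0;
    for (int i = 0; i < n; ++i) {
      int g = gv(G, i, j);
      if (g != NA_INTEGER) { a += g; c += 2; }
    }
    alt[jj] = a;
    called[jj] = c;
  }

  // SFS statistics
  double s_poly = 0, nc_sum = 0;
  for (int jj = 0; jj < m; ++jj) {
    if (called[jj] < 2) continue;
    double a = alt[jj], nc = called[jj];
    w.pi += 2.0 * a * (nc - a) / (nc * (nc - 1.0));
    if (alt[jj] > 0 && alt[jj] < called[jj]) {
      w.thetaW += 1.0 / harmonic_n(called[jj] - 1);
      s_poly += 1;
      nc_sum += nc;
    }
  }
  if (s_poly > 0) {
    int nb = (int)::Rf_fround(nc_sum / s_poly, 0);  // R's round(): half to even
    if (nb >= 4) {
      double a1 = harmonic_n(nb - 1), a2 = 0;
      for (int i = 1; i <= nb - 1; ++i) a2 += 1.0 / ((double)i * i);
      double b1 = (nb + 1.0) / (3.0 * (nb - 1.0));
      double b2 = 2.0 * (nb * (double)nb + nb + 3.0) / (9.0 * nb * (nb - 1.0));
      double c1 = b1 - 1.0 / a1;
      double c2 = b2 - (nb + 2.0) / (a1 * nb) + a2 / (a1 * a1);
      double v = (c1 / a1) * s_poly + (c2 / (a1 * a1 + a2)) * s_poly * (s_poly - 1);
      if (v > 0) w.tajD = (w.pi - w.thetaW) / std::sqrt(v);
    }
  }

  // genotype-distance moments (pairwise-complete)
  if (n >= 2 && m >= 1) {
    std::vector<double> d;
    d.reserve((size_t)n * (n - 1) / 2);
    for (int k = 0; k < n - 1; ++k) {
      for (int l = k + 1; l < n; ++l) {
        int dd = 0;
        for (int jj = 0; jj < m; ++jj) {
          int a = gv(G, k, cols[jj]), b = gv(G, l, cols[jj]);
          if (a != NA_INTEGER && b != NA_INTEGER && a != b) ++dd;
        }
        d.push_back(dd);
      }
    }
    double mean = 0;
    for (double x : d) mean += x;
    mean /= d.size();
    double m2 = 0, m3 = 0, m4 = 0;
    for (double x : d) {
      double c = x - mean;
      m2 += c * c;
      m3 += c * c * c;
      m4 += c * c * c * c;
    }
    m2 /= d.size(); m3 /= d.size(); m4 /= d.size();
    if (m2 > 0) {
      w.varG = m2;
      w.skewG = m3 / std::pow(m2, 1.5);
      w.kurtG = m4 / (m2 * m2);
    }
  }

  // diplotype spectrum over individuals complete in the window
  {
    std::map<std::vector<int>, int> tab;
    int nc = 0;
    std::vector<int> key(m);
    for (int i = 0; i < n; ++i) {
      bool ok = true;
      for (int jj = 0; jj < m; ++jj) {
        int g = gv(G, i, cols[jj]);
        if (g == NA_INTEGER) { ok = false; break; }
        key[jj] = g;
      }
      if (!ok) continue;
      ++tab[key];
      ++nc;
    }
    if (nc > 0) {
      std::vector<double> p;
      for (auto &kv : tab) p.push_back((double)kv.second / nc);
      std::sort(p.begin(), p.end(), std::greater<double>());
      double j1 = 0;
      for (double x : p) j1 += x * x;
      double j12 = j1;
      if (p.size() >= 2) j12 = (p[0] + p[1]) * (p[0] + p[1]) + (j1 - p[0] * p[0] - p[1] * p[1]);
      w.nDip = (double)p.size();
      w.J1 = j1;
      w.J12 = j12;
      w.J2J1 = (j1 - p[0] * p[0]) / j1;
    }
  }

  // genotypic LD: ZnS and omega over polymorphic columns in position order
  std::vector<int> poly;
  for (int jj = 0; jj < m; ++jj)
    if (called[jj] >= 2 && alt[jj] > 0 && alt[jj] < called[jj]) poly.push_back(cols[jj]);
  int S = (int)poly.size();
  if (S >= 2) {
    std::vector<double> r2((size_t)S * S, NA_REAL);
    for (int a = 0; a < S - 1; ++a) {
      for (int b = a + 1; b < S; ++b) {
        double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
        int cnt = 0;
        for (int i = 0; i < n; ++i) {
          int x = gv(G, i, poly[a]), y = gv(G, i, poly[b]);
          if (x == NA_INTEGER || y == NA_INTEGER) continue;
          sx += x; sy += y; sxx += (double)x * x; syy += (double)y * y;
          sxy += (double)x * y;
          ++cnt;
        }
        if (cnt < 2) continue;
        double vx = sxx - sx * sx / cnt, vy = syy - sy * sy / cnt;
        if (vx <= 0 || vy <= 0) continue;
        double cv = sxy - sx * sy / cnt;
        r2[a * S + b] = (cv * cv) / (vx * vy);
      }
    }
    double zsum = 0;
    int zn = 0;
    for (int a = 0; a < S - 1; ++a)
      for (int b = a + 1; b < S; ++b)
        if (!ISNA(r2[a * S + b])) { zsum += r2[a * S + b]; ++zn; }
    if (zn > 0) w.ZnS = zsum / zn;
    if (S >= 6) {
      double best = 0;
      for (int l = 3; l <= S - 3; ++l) {
        double ws = 0, bs = 0;
        int wn = 0, bn = 0;
        for (int a = 0; a < S - 1; ++a) {
          for (int b = a + 1; b < S; ++b) {
            double v = r2[a * S + b];
            if (ISNA(v)) continue;
            if (b < l || a >= l) { ws += v; ++wn; }  // both left (idx<l) or both right
            else { bs += v; ++bn; }
          }
        }
        if (bn == 0 || bs == 0 || wn == 0) continue;
        double om = (ws / wn) / (bs / bn);
        if (std::isfinite(om) && om > best) best = om;
      }
      w.omega = best;
    }
  }
  return w;
}

}  // namespace

// [[Rcpp::export(name = ".stats_profile_cpp")]]
NumericMatrix stats_profile_cpp(IntegerMatrix G, NumericVector positions,
                                NumericVector breaks) {
  int w = breaks.size() - 1;
  NumericMatrix out(12, w);
  for (int win = 0; win < w; ++win) {
    std::vector<int> cols;
    for (int j = 0; j < positions.size(); ++j)
      if (positions[j] >= breaks[win] && positions[j] < breaks[win + 1])
        cols.push_back(j);
    WinStats s = window_stats_one(G, cols);
    out(0, win) = s.pi; out(1, win) = s.thetaW; out(2, win) = s.tajD;
    out(3, win) = s.varG; out(4, win) = s.skewG; out(5, win) = s.kurtG;
    out(6, win) = s.nDip; out(7, win) = s.J1; out(8, win) = s.J12;
    out(9, win) = s.J2J1; out(10, win) = s.ZnS; out(11, win) = s.omega;
  }
  return out;
}
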