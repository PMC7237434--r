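// Incremental Bowyer-Watson 3D Delaunay tetrahedralization with exact
// integer predicates.
//
// Input points are rescaled to a 2^18 lattice, perturbed by +/-1 lattice
// unit of deterministic jitter, and snapped to integers; orient3d and
// insphere are then evaluated exactly in 128-bit integer arithmetic, which
// makes the incremental algorithm robust on degenerate inputs (regular
// grids, cospherical clouds). The returned tetrahedra index the original,
// unperturbed points; callers compute volumes and circumradii from those.
// Exactly degenerate ties that survive the jitter trigger a retry with a
// fresh jitter seed.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>
#include <unordered_set>

using Rcpp::NumericMatrix;
using Rcpp::IntegerMatrix;

namespace {

typedef __int128 int128;

struct Tet {
  int v[4];       // vertex ids
  int nb[4];      // neighbour tet index opposite v[i], -1 on hull
  bool alive;
};

// deterministic 64-bit LCG
static inline double lcg_unif(uint64_t &s) {
  s = s * 6364136223846793005ULL + 1442695040888963407ULL;
  return ((s >> 11) & ((1ULL << 53) - 1)) / static_cast<double>(1ULL << 53);
}

static inline int sgn128(int128 x) { return (x > 0) - (x < 0); }

// exact orientation: > 0 / < 0 / == 0
static inline int orient3d(const int64_t *a, const int64_t *b,
                           const int64_t *c, const int64_t *d) {
  int128 ad[3], bd[3], cd[3];
  for (int k = 0; k < 3; ++k) {
    ad[k] = (int128)a[k] - d[k];
    bd[k] = (int128)b[k] - d[k];
    cd[k] = (int128)c[k] - d[k];
  }
  int128 det = ad[0] * (bd[1] * cd[2] - bd[2] * cd[1])
             - ad[1] * (bd[0] * cd[2] - bd[2] * cd[0])
             + ad[2] * (bd[0] * cd[1] - bd[1] * cd[0]);
  return sgn128(det);
}

// exact insphere determinant sign; for tets kept with orient3d(a,b,c,d) > 0
// in this code's convention, e is inside the circumsphere when the sign is
// negative
static inline int insphere(const int64_t *a, const int64_t *b,
                           const int64_t *c, const int64_t *d,
                           const int64_t *e) {
  int128 q[4][4];
  const int64_t *p[4] = {a, b, c, d};
  for (int i = 0; i < 4; ++i) {
    int128 dx = (int128)p[i][0] - e[0];
    int128 dy = (int128)p[i][1] - e[1];
    int128 dz = (int128)p[i][2] - e[2];
    q[i][0] = dx; q[i][1] = dy; q[i][2] = dz;
    q[i][3] = dx * dx + dy * dy + dz * dz;
  }
  // coordinates bounded by 2^23 lattice units, so every product below stays
  // within 128 bits
  auto det3 = [&](int r0, int r1, int r2) {
    return q[r0][0] * (q[r1][1] * q[r2][2] - q[r1][2] * q[r2][1])
         - q[r0][1] * (q[r1][0] * q[r2][2] - q[r1][2] * q[r2][0])
         + q[r0][2] * (q[r1][0] * q[r2][1] - q[r1][1] * q[r2][0]);
  };
  int128 det = q[0][3] * det3(1, 2, 3) - q[1][3] * det3(0, 2, 3)
             + q[2][3] * det3(0, 1, 3) - q[3][3] * det3(0, 1, 2);
  return sgn128(det);
}

class Delaunay3 {
public:
  std::vector<std::array<int64_t, 3>> pts;  // lattice points (+ 4 super verts)
  std::vector<Tet> tets;
  int n;
  bool tie;                                 // an exact degeneracy was hit

  static const int64_t LATTICE = 1 << 18;

  Delaunay3(const NumericMatrix &P, uint64_t seed) : n(P.nrow()), tie(false) {
    double lo[3], hi[3];
    for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], P(i, k));
        hi[k] = std::max(hi[k], P(i, k));
      }
    double span = 1e-300;
    for (int k = 0; k < 3; ++k) span = std::max(span, hi[k] - lo[k]);
    uint64_t st = seed ? seed : 0x9E3779B97F4A7C15ULL;
    pts.resize(n + 4);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) {
        double u = (P(i, k) - lo[k]) / span;      // in [0, 1]
        double j = 2.0 * (lcg_unif(st) - 0.5);    // +/- 1 lattice unit
        pts[i][k] = (int64_t)std::llround(u * LATTICE + j);
      }
    const int64_t big = LATTICE << 4;             // well within 2^23
    pts[n]     = {{ LATTICE / 2,  LATTICE / 2,  2 * big}};
    pts[n + 1] = {{ LATTICE / 2,  2 * big, -big}};
    pts[n + 2] = {{ 2 * big, -big, -big}};
    pts[n + 3] = {{-2 * big, -big, -big}};
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    if (orient3d(pt(t0.v[0]), pt(t0.v[1]), pt(t0.v[2]), pt(t0.v[3])) < 0)
      std::swap(t0.v[2], t0.v[3]);
    t0.nb[0] = t0.nb[1] = t0.nb[2] = t0.nb[3] = -1;
    t0.alive = true;
    tets.push_back(t0);
  }

  const int64_t *pt(int i) const { return pts[i].data(); }

  bool in_sphere(const Tet &t, int p) {
    int s = insphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), pt(p));
    if (s == 0) tie = true;
    return s < 0;
  }

  // stochastic visibility walk; falls back to a linear conflict scan
  int locate(int p, int start, uint64_t &rng) {
    int cur = start;
    const int64_t *pp = pt(p);
    for (int guard = 0; guard < 50000; ++guard) {
      const Tet &t = tets[cur];
      int cand[4]; int ncand = 0;
      for (int f = 0; f < 4; ++f) {
        int a = t.v[(f + 1) & 3], b = t.v[(f + 2) & 3], c = t.v[(f + 3) & 3];
        int o_apex = orient3d(pt(a), pt(b), pt(c), pt(t.v[f]));
        int o_p = orient3d(pt(a), pt(b), pt(c), pp);
        if (o_apex == 0 || o_p == 0) continue;
        if (o_apex != o_p && t.nb[f] >= 0) cand[ncand++] = t.nb[f];
      }
      if (ncand == 0) return cur;
      cur = (ncand == 1) ? cand[0]
                         : cand[(int)(lcg_unif(rng) * ncand) % ncand];
    }
    for (int ti = (int)tets.size() - 1; ti >= 0; --ti)
      if (tets[ti].alive && in_sphere(tets[ti], p)) return ti;
    Rcpp::stop("point location failed");
    return cur;
  }

  void insert(int p, int &last, uint64_t &rng) {
    int t0 = locate(p, last, rng);
    std::vector<int> cavity;
    std::vector<char> mark(tets.size(), 0);
    std::vector<int> stack{t0};
    mark[t0] = 1;
    while (!stack.empty()) {
      int ti = stack.back(); stack.pop_back();
      if (!tets[ti].alive || !in_sphere(tets[ti], p)) { mark[ti] = 2; continue; }
      cavity.push_back(ti);
      mark[ti] = 3;
      for (int f = 0; f < 4; ++f) {
        int nb = tets[ti].nb[f];
        if (nb >= 0 && !mark[nb]) { mark[nb] = 1; stack.push_back(nb); }
      }
    }
    if (cavity.empty()) { tie = true; return; }   // degenerate placement
    struct BFace { int a, b, c, outside; };
    std::vector<BFace> bnd;
    for (int ti : cavity) {
      const Tet &t = tets[ti];
      for (int f = 0; f < 4; ++f) {
        int nb = t.nb[f];
        if (nb >= 0 && mark[nb] == 3) continue;
        int a = t.v[(f + 1) & 3], b = t.v[(f + 2) & 3], c = t.v[(f + 3) & 3];
        int o = orient3d(pt(a), pt(b), pt(c), pt(p));
        if (o == 0) tie = true;
        if (o < 0) std::swap(b, c);
        bnd.push_back({a, b, c, nb});
      }
    }
    for (int ti : cavity) tets[ti].alive = false;
    std::vector<int> fresh(bnd.size());
    for (size_t i = 0; i < bnd.size(); ++i) {
      Tet nt;
      nt.v[0] = bnd[i].a; nt.v[1] = bnd[i].b; nt.v[2] = bnd[i].c; nt.v[3] = p;
      nt.nb[0] = nt.nb[1] = nt.nb[2] = -1;
      nt.nb[3] = bnd[i].outside;
      nt.alive = true;
      fresh[i] = (int)tets.size();
      tets.push_back(nt);
      if (bnd[i].outside >= 0) {
        Tet &ot = tets[bnd[i].outside];
        for (int f = 0; f < 4; ++f) {
          int a = ot.v[(f + 1) & 3], b = ot.v[(f + 2) & 3], c = ot.v[(f + 3) & 3];
          int s = (a == bnd[i].a) + (a == bnd[i].b) + (a == bnd[i].c)
                + (b == bnd[i].a) + (b == bnd[i].b) + (b == bnd[i].c)
                + (c == bnd[i].a) + (c == bnd[i].b) + (c == bnd[i].c);
          if (s == 3) { ot.nb[f] = fresh[i]; break; }
        }
      }
    }
    // link fresh tets across the faces that contain p
    struct EdgeRec { int a, b, tet, slot; };
    std::vector<EdgeRec> recs;
    recs.reserve(3 * fresh.size());
    for (size_t i = 0; i < fresh.size(); ++i) {
      int vv[3] = {bnd[i].a, bnd[i].b, bnd[i].c};
      for (int k = 0; k < 3; ++k) {
        int a = vv[(k + 1) % 3], b = vv[(k + 2) % 3];
        recs.push_back({std::min(a, b), std::max(a, b), fresh[i], k});
      }
    }
    for (size_t i = 0; i < recs.size(); ++i)
      for (size_t j = i + 1; j < recs.size(); ++j)
        if (recs[i].a == recs[j].a && recs[i].b == recs[j].b) {
          tets[recs[i].tet].nb[recs[i].slot] = recs[j].tet;
          tets[recs[j].tet].nb[recs[j].slot] = recs[i].tet;
        }
    last = fresh[0];
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix P, int seed = 1) {
  int n = P.nrow();
  if (n < 4) Rcpp::stop("need at least 4 points");
  for (int attempt = 0; attempt < 8; ++attempt) {
    uint64_t jseed = (uint64_t)seed + 0x100000001ULL * attempt + 1ULL;
    Delaunay3 D(P, jseed);
    // drop exact lattice duplicates (their Delaunay contribution is void)
    std::unordered_set<uint64_t> seen;
    std::vector<int> order;
    order.reserve(n);
    for (int i = 0; i < n; ++i) {
      uint64_t h = 1469598103934665603ULL;
      for (int k = 0; k < 3; ++k) {
        h ^= (uint64_t)(D.pts[i][k] + (1 << 24));
        h *= 1099511628211ULL;
      }
      if (seen.insert(h).second) order.push_back(i);
    }
    uint64_t st = jseed * 0x9E3779B97F4A7C15ULL + 12345ULL;
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = (int)(lcg_unif(st) * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    int last = 0;
    for (int i : order) D.insert(i, last, st);
    if (D.tie && attempt < 7) continue;         // degeneracy: retry new jitter
    std::vector<std::array<int, 4>> out;
    for (const Tet &t : D.tets) {
      if (!t.alive) continue;
      bool super = false;
      for (int k = 0; k < 4; ++k) if (t.v[k] >= n) { super = true; break; }
      if (!super)
        out.push_back({{t.v[0], t.v[1], t.v[2], t.v[3]}});
    }
    IntegerMatrix M(out.size(), 4);
    for (size_t i = 0; i < out.size(); ++i)
      for (int k = 0; k < 4; ++k) M(i, k) = out[i][k] + 1;
    return M;
  }
  Rcpp::stop("unreachable");
}
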