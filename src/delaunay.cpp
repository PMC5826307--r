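#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Gift-wrapping (face-pivoting) Delaunay tetrahedralization.
//
// The triangulation is computed on a normalized, deterministically jittered
// copy of the coordinates (the jitter breaks cospherical/coplanar
// degeneracies, e.g. the corners of a cube); only the combinatorial
// structure (vertex indices, consistently oriented in the jittered frame)
// is returned.  Volumes and circumradii are then evaluated in R from the
// ORIGINAL coordinates: summing signed volumes of consistently oriented
// tetrahedra gives the exact hull volume even for degenerate inputs,
// because any valid triangulation of the vertex set partitions the hull.
//
// Starting from one Delaunay facet, each face is pivoted to the point
// whose circumsphere is empty on the search side; the pivot tournament
// uses the classic orientation/insphere determinants in long double, which
// comfortably dominates the 1e-6 jitter scale.  Unlike Bowyer-Watson this
// needs no enclosing super-simplex, whose finite geometry corrupts
// boundary cavities.

namespace {

long double det3(long double a1, long double a2, long double a3,
                 long double b1, long double b2, long double b3,
                 long double c1, long double c2, long double c3) {
  return a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) +
         a3 * (b1 * c2 - b2 * c1);
}

struct Pts {
  std::vector<double> X, Y, Z;
};

long double orient3d(const Pts& P, int a, int b, int c, int d) {
  return det3(
      (long double)P.X[a] - P.X[d], (long double)P.Y[a] - P.Y[d],
      (long double)P.Z[a] - P.Z[d],
      (long double)P.X[b] - P.X[d], (long double)P.Y[b] - P.Y[d],
      (long double)P.Z[b] - P.Z[d],
      (long double)P.X[c] - P.X[d], (long double)P.Y[c] - P.Y[d],
      (long double)P.Z[c] - P.Z[d]);
}

// raw insphere determinant; multiplied by sign(orient3d(a,b,c,d)) it is
// positive exactly when e lies inside the circumsphere of (a,b,c,d)
long double insphere_raw(const Pts& P, int a, int b, int c, int d, int e) {
  const long double aex = (long double)P.X[a] - P.X[e],
                    aey = (long double)P.Y[a] - P.Y[e],
                    aez = (long double)P.Z[a] - P.Z[e];
  const long double bex = (long double)P.X[b] - P.X[e],
                    bey = (long double)P.Y[b] - P.Y[e],
                    bez = (long double)P.Z[b] - P.Z[e];
  const long double cex = (long double)P.X[c] - P.X[e],
                    cey = (long double)P.Y[c] - P.Y[e],
                    cez = (long double)P.Z[c] - P.Z[e];
  const long double dex = (long double)P.X[d] - P.X[e],
                    dey = (long double)P.Y[d] - P.Y[e],
                    dez = (long double)P.Z[d] - P.Z[e];
  const long double ae2 = aex * aex + aey * aey + aez * aez;
  const long double be2 = bex * bex + bey * bey + bez * bez;
  const long double ce2 = cex * cex + cey * cey + cez * cez;
  const long double de2 = dex * dex + dey * dey + dez * dez;
  return -ae2 * det3(bex, bey, bez, cex, cey, cez, dex, dey, dez)
         + be2 * det3(aex, aey, aez, cex, cey, cez, dex, dey, dez)
         - ce2 * det3(aex, aey, aez, bex, bey, bez, dex, dey, dez)
         + de2 * det3(aex, aey, aez, bex, bey, bez, cex, cey, cez);
}

bool inside_sphere(const Pts& P, int a, int b, int c, int d, int e) {
  const long double o = orient3d(P, a, b, c, d);
  if (o == 0.0L) return true;  // flat: treat as all-swallowing
  const long double s = insphere_raw(P, a, b, c, d, e);
  return (o > 0) ? (s > 0) : (s < 0);
}

// deterministic pseudo-random in [-0.5, 0.5) from an integer key (SplitMix64)
double hash_unit(std::uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  x = x ^ (x >> 31);
  return static_cast<double>(x >> 11) / 9007199254740992.0 - 0.5;
}

struct QFace {
  int a, b, c;  // face vertices
  int from;     // opposite vertex of the tet that generated this face
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return IntegerMatrix(0, 4);

  // normalize into ~[0,1]^3 and jitter
  double mn[3], mx[3];
  for (int j = 0; j < 3; ++j) {
    mn[j] = R_PosInf;
    mx[j] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (pts(i, j) < mn[j]) mn[j] = pts(i, j);
      if (pts(i, j) > mx[j]) mx[j] = pts(i, j);
    }
  }
  double span = 0.0;
  for (int j = 0; j < 3; ++j) span = std::max(span, mx[j] - mn[j]);
  if (span <= 0) span = 1.0;

  Pts P;
  P.X.resize(n); P.Y.resize(n); P.Z.resize(n);
  for (int i = 0; i < n; ++i) {
    P.X[i] = (pts(i, 0) - mn[0]) / span + 1e-6 * hash_unit(3ULL * i + 0);
    P.Y[i] = (pts(i, 1) - mn[1]) / span + 1e-6 * hash_unit(3ULL * i + 1);
    P.Z[i] = (pts(i, 2) - mn[2]) / span + 1e-6 * hash_unit(3ULL * i + 2);
  }

  // --- initial Delaunay facet ------------------------------------------
  // p0: lexicographic minimum; p1: nearest neighbour of p0; p2: minimizer
  // of the circumradius of triangle (p0, p1, p2)
  int p0 = 0;
  for (int i = 1; i < n; ++i) {
    if (P.Z[i] < P.Z[p0] ||
        (P.Z[i] == P.Z[p0] &&
         (P.Y[i] < P.Y[p0] || (P.Y[i] == P.Y[p0] && P.X[i] < P.X[p0]))))
      p0 = i;
  }
  int p1 = -1;
  long double best = 0;
  for (int i = 0; i < n; ++i) {
    if (i == p0) continue;
    const long double dx = (long double)P.X[i] - P.X[p0],
                      dy = (long double)P.Y[i] - P.Y[p0],
                      dz = (long double)P.Z[i] - P.Z[p0];
    const long double d2 = dx * dx + dy * dy + dz * dz;
    if (p1 < 0 || d2 < best) { p1 = i; best = d2; }
  }
  int p2 = -1;
  best = 0;
  for (int i = 0; i < n; ++i) {
    if (i == p0 || i == p1) continue;
    // squared circumradius of the triangle via R = abc / (4K)
    const long double ax = (long double)P.X[p1] - P.X[p0],
                      ay = (long double)P.Y[p1] - P.Y[p0],
                      az = (long double)P.Z[p1] - P.Z[p0];
    const long double bx = (long double)P.X[i] - P.X[p0],
                      by = (long double)P.Y[i] - P.Y[p0],
                      bz = (long double)P.Z[i] - P.Z[p0];
    const long double cx = (long double)P.X[i] - P.X[p1],
                      cy = (long double)P.Y[i] - P.Y[p1],
                      cz = (long double)P.Z[i] - P.Z[p1];
    const long double a2 = ax * ax + ay * ay + az * az;
    const long double b2 = bx * bx + by * by + bz * bz;
    const long double c2 = cx * cx + cy * cy + cz * cz;
    const long double nx = ay * bz - az * by, ny = az * bx - ax * bz,
                      nz = ax * by - ay * bx;
    const long double four_k2 = nx * nx + ny * ny + nz * nz;
    if (four_k2 <= 0) continue;
    const long double r2 = a2 * b2 * c2 / (4 * four_k2);
    if (p2 < 0 || r2 < best) { p2 = i; best = r2; }
  }
  if (p2 < 0) return IntegerMatrix(0, 4);  // all points collinear

  typedef std::array<int, 3> Face;
  std::map<Face, int> faceCount;
  std::vector<std::array<int, 4> > tets;
  tets.reserve(8 * n);
  std::vector<QFace> stack;
  stack.reserve(16 * n);

  Face f0 = {p0, p1, p2};
  std::sort(f0.begin(), f0.end());
  stack.push_back(QFace{f0[0], f0[1], f0[2], -1});

  const long int max_tets = 40L * n + 64;
  while (!stack.empty()) {
    const QFace qf = stack.back();
    stack.pop_back();
    Face key = {qf.a, qf.b, qf.c};
    std::sort(key.begin(), key.end());
    if (faceCount[key] >= 2) continue;  // both adjacent tets known

    // pivot: among candidates on the search side, keep the one whose
    // circumsphere (with the face) excludes all later challengers
    int bestd = -1;
    for (int d = 0; d < n; ++d) {
      if (d == qf.a || d == qf.b || d == qf.c || d == qf.from) continue;
      if (qf.from >= 0) {
        // restrict to the side of the face plane opposite `from`
        const long double sd = orient3d(P, qf.a, qf.b, qf.c, d);
        const long double sf = orient3d(P, qf.a, qf.b, qf.c, qf.from);
        if (sd == 0.0L || (sd > 0) == (sf > 0)) continue;
      }
      if (bestd < 0 || inside_sphere(P, qf.a, qf.b, qf.c, bestd, d)) bestd = d;
    }
    if (bestd < 0) continue;  // hull face (or nothing on the requested side)
    if (qf.from < 0) {
      // the very first face must also be wrapped from its other side
      stack.push_back(QFace{qf.a, qf.b, qf.c, bestd});
    }
    if ((long int)tets.size() >= max_tets) {
      stop("Delaunay face pivoting failed to terminate (degenerate input?)");
    }
    tets.push_back(std::array<int, 4>{qf.a, qf.b, qf.c, bestd});
    const int vv[4] = {qf.a, qf.b, qf.c, bestd};
    static const int ff[4][3] = {{0, 1, 2}, {0, 1, 3}, {0, 2, 3}, {1, 2, 3}};
    for (int k = 0; k < 4; ++k) {
      Face fc = {vv[ff[k][0]], vv[ff[k][1]], vv[ff[k][2]]};
      std::sort(fc.begin(), fc.end());
      faceCount[fc]++;
      if (k > 0 && faceCount[fc] < 2) {
        const int opp = vv[3 - k];  // vertex of this tet not on face k
        stack.push_back(QFace{fc[0], fc[1], fc[2], opp});
      }
    }
  }

  IntegerMatrix out(tets.size(), 4);
  for (size_t t = 0; t < tets.size(); ++t) {
    // emit so that the R-side signed volume det[v2-v1; v3-v1; v4-v1] is
    // positive in the jittered frame (that determinant equals -orient3d)
    int a = tets[t][2], b = tets[t][3];
    if (orient3d(P, tets[t][0], tets[t][1], tets[t][2], tets[t][3]) > 0)
      std::swap(a, b);
    out(t, 0) = tets[t][0] + 1;  // 1-based
    out(t, 1) = tets[t][1] + 1;
    out(t, 2) = a + 1;
    out(t, 3) = b + 1;
  }
  return out;
}
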