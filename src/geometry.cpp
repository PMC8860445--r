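// Geometric kernels: incremental 3D convex hull, half-space clipping of
// convex polyhedra (bounded Voronoi cells), and overdamped mechanical
// relaxation. All tolerances are absolute in the caller's length units and
// scaled by the bounding-box diagonal where noted.

#include <Rcpp.h>
#include <array>
#include <vector>
#include <map>
#include <cmath>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

typedef std::array<double, 3> Vec3;

static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a[0] - b[0], a[1] - b[1], a[2] - b[2]};
}
static inline Vec3 add(const Vec3 &a, const Vec3 &b) {
  return {a[0] + b[0], a[1] + b[1], a[2] + b[2]};
}
static inline Vec3 scale(const Vec3 &a, double s) {
  return {a[0] * s, a[1] * s, a[2] * s};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a[1] * b[2] - a[2] * b[1],
          a[2] * b[0] - a[0] * b[2],
          a[0] * b[1] - a[1] * b[0]};
}
static inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

// ---------------------------------------------------------------------------
// Incremental convex hull
// ---------------------------------------------------------------------------

struct HullFace {
  int a, b, c;     // vertex indices
  Vec3 n;          // outward unit normal
  double d;        // plane offset: n . x = d
  bool alive;
};

static void face_plane(const std::vector<Vec3> &pts, HullFace &f,
                       const Vec3 &inside) {
  Vec3 u = sub(pts[f.b], pts[f.a]);
  Vec3 v = sub(pts[f.c], pts[f.a]);
  Vec3 n = cross(u, v);
  double ln = norm3(n);
  if (ln > 0) n = scale(n, 1.0 / ln);
  double d = dot(n, pts[f.a]);
  if (dot(n, inside) > d) {  // flip so interior point is below the plane
    n = scale(n, -1.0);
    d = -d;
    std::swap(f.b, f.c);
  }
  f.n = n;
  f.d = d;
}

// Returns an m x 3 (1-based) matrix of hull triangle vertex indices.
// [[Rcpp::export]]
IntegerMatrix cpp_convex_hull(NumericMatrix points) {
  int n = points.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");
  std::vector<Vec3> pts(n);
  for (int i = 0; i < n; ++i) pts[i] = {points(i, 0), points(i, 1), points(i, 2)};

  // bounding-box scale for tolerances
  Vec3 lo = pts[0], hi = pts[0];
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], pts[i][k]);
      hi[k] = std::max(hi[k], pts[i][k]);
    }
  double diag = norm3(sub(hi, lo));
  if (diag <= 0) stop("degenerate point set (all points coincide)");
  double eps = 1e-10 * diag;

  // initial simplex: two extreme points, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  for (int i = 0; i < n; ++i) {
    if (pts[i][0] < pts[i0][0]) i0 = i;
    if (pts[i][0] > pts[i1][0]) i1 = i;
  }
  if (i0 == i1) { i1 = (i0 == 0) ? 1 : 0; }
  int i2 = -1;
  double best = eps;
  Vec3 dir = sub(pts[i1], pts[i0]);
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double h = norm3(cross(dir, sub(pts[i], pts[i0])));
    if (h > best) { best = h; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set (collinear)");
  int i3 = -1;
  best = eps;
  Vec3 nrm = cross(sub(pts[i1], pts[i0]), sub(pts[i2], pts[i0]));
  double ln = norm3(nrm);
  nrm = scale(nrm, 1.0 / ln);
  double d0 = dot(nrm, pts[i0]);
  for (int i = 0; i < n; ++i) {
    double h = std::fabs(dot(nrm, pts[i]) - d0);
    if (h > best) { best = h; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set (coplanar)");

  Vec3 inside = scale(add(add(pts[i0], pts[i1]), add(pts[i2], pts[i3])), 0.25);
  std::vector<HullFace> faces;
  int init[4][3] = {{i0, i1, i2}, {i0, i1, i3}, {i0, i2, i3}, {i1, i2, i3}};
  for (auto &t : init) {
    HullFace f{t[0], t[1], t[2], {0, 0, 0}, 0.0, true};
    face_plane(pts, f, inside);
    faces.push_back(f);
  }

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // faces visible from p
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      if (dot(faces[f].n, pts[p]) - faces[f].d > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;  // interior point
    // horizon edges: edges of visible faces not shared with another visible face
    std::map<std::pair<int, int>, std::pair<int, int>> edges;  // sorted -> oriented
    for (int fi : vis) {
      const HullFace &f = faces[fi];
      int vv[3] = {f.a, f.b, f.c};
      for (int e = 0; e < 3; ++e) {
        int u = vv[e], w = vv[(e + 1) % 3];
        auto key = std::make_pair(std::min(u, w), std::max(u, w));
        auto it = edges.find(key);
        if (it == edges.end()) edges[key] = std::make_pair(u, w);
        else edges.erase(it);  // shared between two visible faces
      }
    }
    for (int fi : vis) faces[fi].alive = false;
    for (auto &kv : edges) {
      HullFace f{kv.second.first, kv.second.second, p, {0, 0, 0}, 0.0, true};
      face_plane(pts, f, inside);
      faces.push_back(f);
    }
  }

  int m = 0;
  for (auto &f : faces) if (f.alive) ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (auto &f : faces) {
    if (!f.alive) continue;
    out(r, 0) = f.a + 1;
    out(r, 1) = f.b + 1;
    out(r, 2) = f.c + 1;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convex polyhedron in face-ring representation, clipped by half-spaces
// ---------------------------------------------------------------------------

struct Poly {
  std::vector<Vec3> v;
  std::vector<std::vector<int>> faces;  // vertex index rings
  std::vector<int> face_id;             // clipping-plane id per face (-1 = box/hull)
};

static Poly make_cube(const Vec3 &c, double h) {
  Poly p;
  for (int i = 0; i < 8; ++i)
    p.v.push_back({c[0] + ((i & 1) ? h : -h),
                   c[1] + ((i & 2) ? h : -h),
                   c[2] + ((i & 4) ? h : -h)});
  int f[6][4] = {{0, 2, 3, 1}, {4, 5, 7, 6}, {0, 1, 5, 4},
                 {2, 6, 7, 3}, {0, 4, 6, 2}, {1, 3, 7, 5}};
  for (auto &q : f) {
    p.faces.push_back({q[0], q[1], q[2], q[3]});
    p.face_id.push_back(-1);
  }
  return p;
}

// Clip poly by half-space n.x <= d. Returns false if the result is empty.
static bool clip_poly(Poly &p, const Vec3 &n, double d, int plane_id, double eps) {
  int nv = (int)p.v.size();
  std::vector<double> sd(nv);
  bool any_out = false, any_in = false;
  for (int i = 0; i < nv; ++i) {
    sd[i] = dot(n, p.v[i]) - d;
    if (sd[i] > eps) any_out = true;
    if (sd[i] < -eps) any_in = true;
  }
  if (!any_out) return true;            // untouched
  if (!any_in) { p.v.clear(); p.faces.clear(); p.face_id.clear(); return false; }

  std::map<std::pair<int, int>, int> cut;  // edge -> new vertex index
  std::vector<Vec3> nverts = p.v;
  std::vector<std::vector<int>> nfaces;
  std::vector<int> nids;
  std::vector<int> capverts;

  auto cut_vertex = [&](int a, int b) -> int {
    auto key = std::make_pair(std::min(a, b), std::max(a, b));
    auto it = cut.find(key);
    if (it != cut.end()) return it->second;
    double t = sd[a] / (sd[a] - sd[b]);
    Vec3 x = add(p.v[a], scale(sub(p.v[b], p.v[a]), t));
    nverts.push_back(x);
    int idx = (int)nverts.size() - 1;
    cut[key] = idx;
    return idx;
  };

  for (size_t f = 0; f < p.faces.size(); ++f) {
    const std::vector<int> &ring = p.faces[f];
    std::vector<int> nring;
    int m = (int)ring.size();
    for (int e = 0; e < m; ++e) {
      int a = ring[e], b = ring[(e + 1) % m];
      bool ain = sd[a] <= eps, bin = sd[b] <= eps;
      if (ain) nring.push_back(a);
      if (ain != bin && std::fabs(sd[a] - sd[b]) > 0) {
        int c = cut_vertex(a, b);
        nring.push_back(c);
        capverts.push_back(c);
      }
    }
    // drop duplicate consecutive indices
    std::vector<int> cleaned;
    for (int idx : nring)
      if (cleaned.empty() || cleaned.back() != idx) cleaned.push_back(idx);
    while (cleaned.size() > 1 && cleaned.front() == cleaned.back()) cleaned.pop_back();
    if (cleaned.size() >= 3) {
      nfaces.push_back(cleaned);
      nids.push_back(p.face_id[f]);
    }
  }

  // cap face: unique new vertices ordered by angle about the plane normal
  std::sort(capverts.begin(), capverts.end());
  capverts.erase(std::unique(capverts.begin(), capverts.end()), capverts.end());
  if (capverts.size() >= 3) {
    Vec3 cen{0, 0, 0};
    for (int idx : capverts) cen = add(cen, nverts[idx]);
    cen = scale(cen, 1.0 / capverts.size());
    // orthonormal basis in the plane
    Vec3 u = std::fabs(n[0]) < 0.9 ? Vec3{1, 0, 0} : Vec3{0, 1, 0};
    Vec3 e1 = cross(n, u); e1 = scale(e1, 1.0 / norm3(e1));
    Vec3 e2 = cross(n, e1);
    std::vector<std::pair<double, int>> ang;
    for (int idx : capverts) {
      Vec3 r = sub(nverts[idx], cen);
      ang.push_back({std::atan2(dot(r, e2), dot(r, e1)), idx});
    }
    std::sort(ang.begin(), ang.end());
    std::vector<int> ring;
    for (auto &pr : ang) ring.push_back(pr.second);
    nfaces.push_back(ring);
    nids.push_back(plane_id);
  }

  // compact unused vertices
  std::vector<int> remap(nverts.size(), -1);
  Poly q;
  for (auto &ring : nfaces)
    for (int idx : ring)
      if (remap[idx] < 0) { remap[idx] = (int)q.v.size(); q.v.push_back(nverts[idx]); }
  for (size_t f = 0; f < nfaces.size(); ++f) {
    std::vector<int> ring;
    for (int idx : nfaces[f]) ring.push_back(remap[idx]);
    q.faces.push_back(ring);
  }
  q.face_id = nids;
  p = q;
  return !p.v.empty();
}

static double poly_volume(const Poly &p) {
  if (p.v.empty()) return 0.0;
  Vec3 cen{0, 0, 0};
  for (auto &x : p.v) cen = add(cen, x);
  cen = scale(cen, 1.0 / p.v.size());
  double vol = 0.0;
  for (auto &ring : p.faces) {
    for (size_t t = 1; t + 1 < ring.size(); ++t) {
      Vec3 a = sub(p.v[ring[0]], cen);
      Vec3 b = sub(p.v[ring[t]], cen);
      Vec3 c = sub(p.v[ring[t + 1]], cen);
      vol += std::fabs(dot(a, cross(b, c))) / 6.0;
    }
  }
  return vol;
}

static double ring_area(const Poly &p, const std::vector<int> &ring) {
  Vec3 acc{0, 0, 0};
  const Vec3 &o = p.v[ring[0]];
  for (size_t t = 1; t + 1 < ring.size(); ++t) {
    Vec3 b = sub(p.v[ring[t]], o);
    Vec3 c = sub(p.v[ring[t + 1]], o);
    acc = add(acc, cross(b, c));
  }
  return 0.5 * norm3(acc);
}

// Voronoi cells of `centers` clipped to the intersection of half-spaces
// `planes` (rows n1,n2,n3,d with n.x <= d). `bound` is a radius guaranteed to
// contain the clipped region (seeds the initial bounding cube).
// [[Rcpp::export]]
List cpp_voronoi_cells(NumericMatrix centers, NumericMatrix planes,
                       double bound, bool keep_geometry = false) {
  int n = centers.nrow();
  std::vector<Vec3> cs(n);
  for (int i = 0; i < n; ++i) cs[i] = {centers(i, 0), centers(i, 1), centers(i, 2)};
  double eps = 1e-10 * std::max(1.0, bound);

  NumericVector volumes(n);
  List neighbors(n), geometry(keep_geometry ? n : 0);

  // neighbor order by distance, shared workspace
  std::vector<int> order(n);

  for (int i = 0; i < n; ++i) {
    Poly p = make_cube({0, 0, 0}, bound * 1.5);
    for (int h = 0; h < planes.nrow(); ++h) {
      Vec3 nn{planes(h, 0), planes(h, 1), planes(h, 2)};
      if (!clip_poly(p, nn, planes(h, 3), -1, eps)) break;
    }
    if (!p.v.empty()) {
      std::iota(order.begin(), order.end(), 0);
      std::sort(order.begin(), order.end(), [&](int a, int b) {
        return dot(sub(cs[a], cs[i]), sub(cs[a], cs[i])) <
               dot(sub(cs[b], cs[i]), sub(cs[b], cs[i]));
      });
      for (int oj : order) {
        if (oj == i) continue;
        Vec3 dvec = sub(cs[oj], cs[i]);
        double dist = norm3(dvec);
        if (dist < 1e-12) stop("duplicate cell centers");
        // prune: bisector cannot cut if farther than current max vertex distance
        double maxd = 0.0;
        for (auto &x : p.v) maxd = std::max(maxd, norm3(sub(x, cs[i])));
        if (dist / 2.0 > maxd) break;
        Vec3 nn = scale(dvec, 1.0 / dist);
        Vec3 mid = scale(add(cs[i], cs[oj]), 0.5);
        if (!clip_poly(p, nn, dot(nn, mid), oj, eps)) break;
      }
    }
    volumes[i] = poly_volume(p);
    std::vector<int> nb;
    double amin = 1e-9 * bound * bound;
    for (size_t f = 0; f < p.faces.size(); ++f)
      if (p.face_id[f] >= 0 && ring_area(p, p.faces[f]) > amin)
        nb.push_back(p.face_id[f] + 1);
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    neighbors[i] = IntegerVector(nb.begin(), nb.end());
    if (keep_geometry) {
      NumericMatrix vm(p.v.size(), 3);
      for (size_t k = 0; k < p.v.size(); ++k)
        for (int c = 0; c < 3; ++c) vm(k, c) = p.v[k][c];
      List rings(p.faces.size());
      for (size_t f = 0; f < p.faces.size(); ++f) {
        IntegerVector r(p.faces[f].size());
        for (size_t t = 0; t < p.faces[f].size(); ++t) r[t] = p.faces[f][t] + 1;
        rings[f] = r;
      }
      geometry[i] = List::create(_["vertices"] = vm, _["faces"] = rings);
    }
  }
  List out = List::create(_["volumes"] = volumes, _["neighbors"] = neighbors);
  if (keep_geometry) out["geometry"] = geometry;
  return out;
}

// ---------------------------------------------------------------------------
// Overdamped relaxation (explicit Euler, mobility 1)
// ---------------------------------------------------------------------------

static double lens_volume(double r1, double r2, double d) {
  // intersection volume of spheres with radii r1, r2 at center distance d
  if (d >= r1 + r2) return 0.0;
  double rmin = std::min(r1, r2);
  if (d <= std::fabs(r1 - r2)) return 4.0 * M_PI / 3.0 * rmin * rmin * rmin;
  double num = (r1 + r2 - d) * (r1 + r2 - d) *
               (d * d + 2.0 * d * r2 - 3.0 * r2 * r2 + 2.0 * d * r1 +
                6.0 * r1 * r2 - 3.0 * r1 * r1);
  return M_PI * num / (12.0 * d);
}

// [[Rcpp::export]]
double cpp_lens_volume(double r1, double r2, double d) {
  return lens_volume(r1, r2, d);
}

// Relax positions under selected force laws until the largest per-cell
// displacement in a step drops below `tol` or `max_iters` is reached.
// bonds: B x 2 (1-based mother, daughter); bond_offsets: B x 6
// (daughter birth-scar offset xyz, mother bud-scar offset xyz), fixed in the
// world frame (cells translate without rotating).
// [[Rcpp::export]]
List cpp_relax(NumericMatrix pos, NumericVector radii,
               bool use_steric, double ks,
               bool use_adhesive, double ka, double awell,
               bool use_membrane, double membrane_radius, double km,
               IntegerMatrix bonds, NumericMatrix bond_offsets,
               double kb, double L0,
               double dt, double tol, int max_iters) {
  int n = pos.nrow();
  std::vector<Vec3> x(n), F(n), Fprev(n, {0, 0, 0});
  for (int i = 0; i < n; ++i) x[i] = {pos(i, 0), pos(i, 1), pos(i, 2)};
  std::vector<double> R(radii.begin(), radii.end());
  int nb = bonds.nrow();
  // Reformable adhesive bonds: a pair bonds on contact (d <= Ri+Rj) and
  // unbonds when stretched past 2(Ri+Rj); only bonded pairs feel the
  // adhesive force. Initialize from pairs currently in contact.
  std::vector<char> sticky;
  if (use_adhesive) {
    sticky.assign((size_t)n * n, 0);
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = norm3(sub(x[j], x[i]));
        if (d <= (R[i] + R[j]) * (1.0 + 1e-9))
          sticky[(size_t)i * n + j] = 1;
      }
  }
  bool converged = false;
  // Adaptive step: the printed adhesion law is discontinuous at contact, so
  // a fixed explicit-Euler step limit-cycles across the crossover. When the
  // force field reverses against the previous step (overshoot), the step is
  // halved (FIRE-style backoff) and recovered slowly during aligned descent.
  double dtc = dt;
  int aligned = 0;
  int it = 0;
  for (it = 0; it < max_iters; ++it) {
    for (int i = 0; i < n; ++i) F[i] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        Vec3 rij = sub(x[j], x[i]);
        double d = norm3(rij);
        if (d < 1e-12) continue;  // coincident; no defined direction
        double sumR = R[i] + R[j];
        Vec3 rhat = scale(rij, 1.0 / d);
        if (use_steric && d <= sumR) {
          double g = ks * (d - sumR);  // negative: pushes i away from j
          F[i] = add(F[i], scale(rhat, g));
          F[j] = add(F[j], scale(rhat, -g));
        }
        if (use_adhesive) {
          char &bnd = sticky[(size_t)i * n + j];
          if (d <= sumR) bnd = 1;            // contact (re)forms the bond
          else if (d > 2.0 * sumR) bnd = 0;  // over-stretched bond breaks
          if (bnd && d >= sumR && d <= 2.0 * sumR) {
            double g = ka * (d - awell * sumR);  // positive pulls i toward j
            F[i] = add(F[i], scale(rhat, g));
            F[j] = add(F[j], scale(rhat, -g));
          }
        }
      }
      if (use_membrane) {
        double d = norm3(x[i]);
        double vc = 4.0 * M_PI / 3.0 * R[i] * R[i] * R[i];
        double vi = lens_volume(R[i], membrane_radius, d);
        double mag = km * (vc - vi);
        if (mag > 0 && d > 1e-12)
          F[i] = add(F[i], scale(x[i], -mag / d));  // toward membrane center
      }
    }
    for (int b = 0; b < nb; ++b) {
      int mo = bonds(b, 0) - 1, da = bonds(b, 1) - 1;
      Vec3 obi{bond_offsets(b, 0), bond_offsets(b, 1), bond_offsets(b, 2)};
      Vec3 obu{bond_offsets(b, 3), bond_offsets(b, 4), bond_offsets(b, 5)};
      Vec3 r = sub(add(x[da], obi), add(x[mo], obu));
      double d = norm3(r);
      if (d < 1e-12) continue;
      Vec3 rhat = scale(r, 1.0 / d);
      double g = kb * (d - L0);  // restoring along the scar-to-scar vector
      F[da] = add(F[da], scale(rhat, -g));
      F[mo] = add(F[mo], scale(rhat, g));
    }
    double p = 0.0;
    for (int i = 0; i < n; ++i) p += dot(F[i], Fprev[i]);
    if (it > 0 && p < 0) {
      dtc = std::max(dtc * 0.5, dt * 1e-5);
      aligned = 0;
    } else if (++aligned > 20) {
      dtc = std::min(dtc * 1.1, 10.0 * dt);  // FIRE-style growth cap
    }
    Fprev = F;
    double maxdisp = 0.0;
    for (int i = 0; i < n; ++i) {
      Vec3 dx = scale(F[i], dtc);
      maxdisp = std::max(maxdisp, norm3(dx));
      x[i] = add(x[i], dx);
    }
    if (maxdisp < tol) { converged = true; ++it; break; }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = x[i][c];
  return List::create(_["positions"] = out, _["converged"] = converged,
                      _["iterations"] = it);
}
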