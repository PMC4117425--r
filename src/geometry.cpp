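// Spatial kernels for the site-point grid, enclosure ray casting, clustering
// and probe-pose scoring. All neighbour searches go through a uniform cell
// list so fields stay near-linear in grid size.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

namespace {

struct CellList {
  double cell;
  double ox, oy, oz;
  int nx, ny, nz;
  std::vector<std::vector<int>> cells;
  const NumericMatrix& pts;

  CellList(const NumericMatrix& p, double cell_size) : cell(cell_size), pts(p) {
    double inf = std::numeric_limits<double>::infinity();
    double xlo = inf, ylo = inf, zlo = inf, xhi = -inf, yhi = -inf, zhi = -inf;
    for (int i = 0; i < p.nrow(); ++i) {
      xlo = std::min(xlo, p(i,0)); xhi = std::max(xhi, p(i,0));
      ylo = std::min(ylo, p(i,1)); yhi = std::max(yhi, p(i,1));
      zlo = std::min(zlo, p(i,2)); zhi = std::max(zhi, p(i,2));
    }
    if (p.nrow() == 0) { xlo = ylo = zlo = 0; xhi = yhi = zhi = 0; }
    ox = xlo - 1e-9; oy = ylo - 1e-9; oz = zlo - 1e-9;
    nx = std::max(1, (int)std::floor((xhi - ox) / cell) + 1);
    ny = std::max(1, (int)std::floor((yhi - oy) / cell) + 1);
    nz = std::max(1, (int)std::floor((zhi - oz) / cell) + 1);
    cells.resize((size_t)nx * ny * nz);
    for (int i = 0; i < p.nrow(); ++i) cells[index_of(p(i,0), p(i,1), p(i,2))].push_back(i);
  }
  size_t index_of(double x, double y, double z) const {
    int ix = clampi((int)std::floor((x - ox) / cell), nx);
    int iy = clampi((int)std::floor((y - oy) / cell), ny);
    int iz = clampi((int)std::floor((z - oz) / cell), nz);
    return ((size_t)ix * ny + iy) * nz + iz;
  }
  static int clampi(int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); }

  // visit indices of stored points within `radius` of (x,y,z); returns them
  void gather(double x, double y, double z, double radius, std::vector<int>& out) const {
    out.clear();
    int reach = (int)std::ceil(radius / cell);
    int ix = (int)std::floor((x - ox) / cell);
    int iy = (int)std::floor((y - oy) / cell);
    int iz = (int)std::floor((z - oz) / cell);
    double r2 = radius * radius;
    for (int dx = -reach; dx <= reach; ++dx) {
      int jx = ix + dx; if (jx < 0 || jx >= nx) continue;
      for (int dy = -reach; dy <= reach; ++dy) {
        int jy = iy + dy; if (jy < 0 || jy >= ny) continue;
        for (int dz = -reach; dz <= reach; ++dz) {
          int jz = iz + dz; if (jz < 0 || jz >= nz) continue;
          const std::vector<int>& c = cells[((size_t)jx * ny + jy) * nz + jz];
          for (int k : c) {
            double ddx = pts(k,0) - x, ddy = pts(k,1) - y, ddz = pts(k,2) - z;
            if (ddx*ddx + ddy*ddy + ddz*ddz <= r2) out.push_back(k);
          }
        }
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
LogicalVector cpp_points_inside(NumericMatrix points, NumericMatrix atoms,
                                NumericVector radii) {
  double rmax = 0;
  for (double r : radii) rmax = std::max(rmax, r);
  CellList cl(atoms, std::max(2.0, rmax));
  LogicalVector out(points.nrow());
  std::vector<int> near;
  for (int i = 0; i < points.nrow(); ++i) {
    cl.gather(points(i,0), points(i,1), points(i,2), rmax, near);
    bool inside = false;
    for (int j : near) {
      double dx = atoms(j,0) - points(i,0), dy = atoms(j,1) - points(i,1),
             dz = atoms(j,2) - points(i,2);
      if (dx*dx + dy*dy + dz*dz <= radii[j] * radii[j]) { inside = true; break; }
    }
    out[i] = inside;
  }
  return out;
}

// Lennard-Jones 6-12 probe field: sum over atoms within cutoff of
// eps_pair * ((rmin/r)^12 - 2 (rmin/r)^6), pair parameters precombined in R.
// [[Rcpp::export]]
NumericVector cpp_vdw_field(NumericMatrix points, NumericMatrix atoms,
                            NumericVector eps_pair, NumericVector rmin_pair,
                            double cutoff) {
  CellList cl(atoms, std::max(2.0, cutoff / 2.0));
  NumericVector out(points.nrow());
  std::vector<int> near;
  for (int i = 0; i < points.nrow(); ++i) {
    cl.gather(points(i,0), points(i,1), points(i,2), cutoff, near);
    double e = 0;
    for (int j : near) {
      double dx = atoms(j,0) - points(i,0), dy = atoms(j,1) - points(i,1),
             dz = atoms(j,2) - points(i,2);
      double r2 = dx*dx + dy*dy + dz*dz;
      if (r2 < 1e-12) r2 = 1e-12;
      double s2 = rmin_pair[j] * rmin_pair[j] / r2;
      double s6 = s2 * s2 * s2;
      e += eps_pair[j] * (s6 * s6 - 2.0 * s6);
    }
    out[i] = e;
  }
  return out;
}

// Enclosure: fraction of directions whose ray first enters the receptor vdW
// envelope within maxdist of the origin point. Closed-form ray-sphere entry.
// [[Rcpp::export]]
NumericVector cpp_enclosure(NumericMatrix points, NumericMatrix dirs,
                            NumericMatrix atoms, NumericVector radii,
                            double maxdist) {
  double rmax = 0;
  for (double r : radii) rmax = std::max(rmax, r);
  CellList cl(atoms, 4.0);
  NumericVector out(points.nrow());
  int nd = dirs.nrow();
  std::vector<int> near;
  std::vector<double> hx, hy, hz, ca, dist, r2v;   // per-point atom geometry
  for (int i = 0; i < points.nrow(); ++i) {
    cl.gather(points(i,0), points(i,1), points(i,2), maxdist + rmax, near);
    if (near.empty()) { out[i] = 0.0; continue; }
    size_t na = near.size();
    hx.assign(na, 0); hy.assign(na, 0); hz.assign(na, 0);
    ca.assign(na, 0); dist.assign(na, 0); r2v.assign(na, 0);
    // sort candidates nearest-first so interior rays terminate early
    std::sort(near.begin(), near.end(), [&](int a, int b) {
      double da = 0, db = 0;
      for (int k = 0; k < 3; ++k) {
        double va = atoms(a,k) - points(i,k), vb = atoms(b,k) - points(i,k);
        da += va*va; db += vb*vb;
      }
      return da < db;
    });
    bool inside_any = false;
    for (size_t j = 0; j < na; ++j) {
      int aj = near[j];
      double ax = atoms(aj,0) - points(i,0), ay = atoms(aj,1) - points(i,1),
             az = atoms(aj,2) - points(i,2);
      double a2 = ax*ax + ay*ay + az*az;
      double r2 = radii[aj] * radii[aj];
      if (a2 <= r2) { inside_any = true; break; }
      double an = std::sqrt(a2);
      hx[j] = ax / an; hy[j] = ay / an; hz[j] = az / an;
      dist[j] = an; r2v[j] = r2;
      ca[j] = std::sqrt(1.0 - r2 / a2);            // cos of tangent half-angle
    }
    if (inside_any) { out[i] = 1.0; continue; }
    int hits = 0;
    for (int d = 0; d < nd; ++d) {
      double ux = dirs(d,0), uy = dirs(d,1), uz = dirs(d,2);
      bool hit = false;
      for (size_t j = 0; j < na; ++j) {
        double dp = hx[j]*ux + hy[j]*uy + hz[j]*uz;
        if (dp < ca[j]) continue;                  // outside tangent cone
        double b = dp * dist[j];
        double disc = r2v[j] - (dist[j]*dist[j] - b*b);
        if (disc < 0) continue;
        double t = b - std::sqrt(disc);            // first entry
        if (t >= 0 && t <= maxdist) { hit = true; break; }
      }
      if (hit) ++hits;
    }
    out[i] = (double)hits / nd;
  }
  return out;
}

// Distance-weighted kernel sum: sum_j w_j * (1 - r/cutoff)^2 for r < cutoff.
// [[Rcpp::export]]
NumericVector cpp_kernel_sum(NumericMatrix points, NumericMatrix atoms,
                             NumericVector weights, double cutoff) {
  CellList cl(atoms, std::max(2.0, cutoff / 2.0));
  NumericVector out(points.nrow());
  std::vector<int> near;
  for (int i = 0; i < points.nrow(); ++i) {
    cl.gather(points(i,0), points(i,1), points(i,2), cutoff, near);
    double s = 0;
    for (int j : near) {
      double dx = atoms(j,0) - points(i,0), dy = atoms(j,1) - points(i,1),
             dz = atoms(j,2) - points(i,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double f = 1.0 - r / cutoff;
      s += weights[j] * f * f;
    }
    out[i] = s;
  }
  return out;
}

// Number of OTHER points within `radius` of each point.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count(NumericMatrix points, double radius) {
  CellList cl(points, std::max(1.0, radius));
  IntegerVector out(points.nrow());
  std::vector<int> near;
  for (int i = 0; i < points.nrow(); ++i) {
    cl.gather(points(i,0), points(i,1), points(i,2), radius, near);
    int n = 0;
    for (int j : near) if (j != i) ++n;
    out[i] = n;
  }
  return out;
}

// Connected components of the graph joining points strictly closer than
// dthresh (single-linkage clusters cut at dthresh). 1-based labels.
// [[Rcpp::export]]
IntegerVector cpp_cluster_threshold(NumericMatrix points, double dthresh) {
  int n = points.nrow();
  CellList cl(points, std::max(1.0, dthresh));
  IntegerVector label(n, 0);
  std::vector<int> near;
  int next = 0;
  double d2 = dthresh * dthresh;
  for (int s = 0; s < n; ++s) {
    if (label[s]) continue;
    ++next;
    std::queue<int> q;
    q.push(s); label[s] = next;
    while (!q.empty()) {
      int i = q.front(); q.pop();
      cl.gather(points(i,0), points(i,1), points(i,2), dthresh, near);
      for (int j : near) {
        if (label[j]) continue;
        double dx = points(j,0) - points(i,0), dy = points(j,1) - points(i,1),
               dz = points(j,2) - points(i,2);
        if (dx*dx + dy*dy + dz*dz < d2) { label[j] = next; q.push(j); }
      }
    }
  }
  return label;
}

// Probe-receptor contact scoring used by docking and repacking.
// Returns (lj_sum, n_clash, n_phobic_contact) where a clash is a vdW overlap
// deeper than clash_tol and a phobic contact pairs two apolar atoms within
// touch + 0.8 A. The repulsive branch is capped at lj_cap per pair: a soft
// core, so induced-fit stages can admit poses that repacking later relieves.
// [[Rcpp::export]]
NumericVector cpp_contact_score(NumericMatrix a_xyz, NumericVector a_rad,
                                NumericVector a_eps, LogicalVector a_apolar,
                                NumericMatrix b_xyz, NumericVector b_rad,
                                NumericVector b_eps, LogicalVector b_apolar,
                                double cutoff, double clash_tol,
                                double lj_cap = 50.0) {
  CellList cl(b_xyz, std::max(2.0, cutoff / 2.0));
  double lj = 0; int nclash = 0, nphob = 0;
  std::vector<int> near;
  for (int i = 0; i < a_xyz.nrow(); ++i) {
    cl.gather(a_xyz(i,0), a_xyz(i,1), a_xyz(i,2), cutoff, near);
    for (int j : near) {
      double dx = b_xyz(j,0) - a_xyz(i,0), dy = b_xyz(j,1) - a_xyz(i,1),
             dz = b_xyz(j,2) - a_xyz(i,2);
      double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      double touch = a_rad[i] + b_rad[j];
      if (r < touch - clash_tol) ++nclash;
      if (a_apolar[i] && b_apolar[j] && r < touch + 0.8) ++nphob;
      double rmin = touch;                     // vdW contact distance as LJ minimum
      if (r < 1e-6) r = 1e-6;
      double s2 = rmin * rmin / (r * r);
      double s6 = s2 * s2 * s2;
      double e = std::sqrt(a_eps[i] * b_eps[j]) * (s6 * s6 - 2.0 * s6);
      lj += (e < lj_cap) ? e : lj_cap;
    }
  }
  return NumericVector::create(lj, (double)nclash, (double)nphob);
}
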