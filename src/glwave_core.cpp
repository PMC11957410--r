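#include <RcppArmadillo.h>
#include <queue>
#include <utility>
#include <complex>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Plane-wave superposition S(r) = sqrt(2/n) * sum_n exp(i (k_n . r + phi_n))
// evaluated at voxel centers (i + 1/2) * spacing. exp(i k.r) factorizes
// along the axes, so each z slice is one rank-n_waves complex matrix
// product S_z = Ex * (Ey .* b_z)^T, dispatched to BLAS zgemm.
// [[Rcpp::export]]
ComplexVector cpp_plane_field(NumericVector kx, NumericVector ky,
                              NumericVector kz, NumericVector phi,
                              int n, double spacing) {
  const int nw = kx.size();
  const R_xlen_t ntot = (R_xlen_t)n * n * n;
  const double amp = std::sqrt(2.0 / (double)nw);
  const std::complex<double> I(0.0, 1.0);

  arma::cx_mat Ex(n, nw), Ey(n, nw), Ez(n, nw);
  for (int w = 0; w < nw; ++w) {
    const std::complex<double> ph = std::exp(I * phi[w]);
    for (int i = 0; i < n; ++i) {
      const double c = (i + 0.5) * spacing;
      Ex(i, w) = std::exp(I * (kx[w] * c));
      Ey(i, w) = std::exp(I * (ky[w] * c));
      Ez(i, w) = std::exp(I * (kz[w] * c)) * ph;  // fold in the phase shift
    }
  }

  ComplexVector out(ntot);
  arma::cx_mat Cyz(n, nw), Sz(n, n);
  for (int iz = 0; iz < n; ++iz) {
    Cyz = Ey.each_row() % Ez.row(iz);
    Sz = Ex * Cyz.st();                 // (ix, iy) slice, x fastest
    const std::complex<double> *p = Sz.memptr();
    Rcomplex *q = &out[(R_xlen_t)n * n * iz];
    for (R_xlen_t j = 0; j < (R_xlen_t)n * n; ++j) {
      q[j].r = amp * p[j].real();
      q[j].i = amp * p[j].imag();
    }
  }
  return out;
}

// Spherical (radial phase) wave superposition
//   S(r) = sqrt(2/n) * sum_n A_n(r) exp(i (k_n |r - c_n| + phi_n))
// with A_n = 1 (default) or 1/max(|r - c_n|, spacing) when inv_r is true.
// [[Rcpp::export]]
ComplexVector cpp_spherical_field(NumericVector k, NumericVector cx,
                                  NumericVector cy, NumericVector cz,
                                  NumericVector phi, int n, double spacing,
                                  bool inv_r) {
  const int nw = k.size();
  const R_xlen_t ntot = (R_xlen_t)n * n * n;
  std::vector<std::complex<double> > S(ntot, std::complex<double>(0.0, 0.0));
  const double amp = std::sqrt(2.0 / (double)nw);

  for (int w = 0; w < nw; ++w) {
    R_xlen_t idx = 0;
    for (int iz = 0; iz < n; ++iz) {
      const double dz = (iz + 0.5) * spacing - cz[w];
      for (int iy = 0; iy < n; ++iy) {
        const double dy = (iy + 0.5) * spacing - cy[w];
        const double dyz = dy * dy + dz * dz;
        for (int ix = 0; ix < n; ++ix, ++idx) {
          const double dx = (ix + 0.5) * spacing - cx[w];
          const double r = std::sqrt(dx * dx + dyz);
          double a = 1.0;
          if (inv_r) a = 1.0 / std::max(r, spacing);
          S[idx] += std::polar(a, k[w] * r + phi[w]);
        }
      }
    }
  }

  ComplexVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) {
    out[i].r = amp * S[i].real();
    out[i].i = amp * S[i].imag();
  }
  return out;
}

// Thin the winding labels to line-center voxels. For each scan
// orientation, every 2-D slice's 8-connected clusters of nonzero-winding
// pixels are collapsed to the labeled pixel nearest the cluster centroid
// (a singular line pierces a slice in one point, but the 8-neighbor loop
// flags every pixel whose loop encloses the zero, giving ~2-pixel-wide
// clusters). The union of the three thinned orientations approximates
// the singular set at one voxel width.
// cyz/czx/cxy are the cumulative-phase arrays of the three orientations.
// [[Rcpp::export]]
LogicalVector cpp_thin_mask(NumericVector cyz, NumericVector czx,
                            NumericVector cxy, int n) {
  const R_xlen_t ntot = (R_xlen_t)n * n * n;
  LogicalVector out(ntot, false);
  const double twopi = 2.0 * M_PI;
  std::vector<char> lab((size_t)n * n), seen((size_t)n * n);
  std::vector<int> stack, cluster;

  for (int axis = 0; axis < 3; ++axis) {
    const NumericVector &cs = (axis == 0) ? cyz : (axis == 1) ? czx : cxy;
    for (int s = 0; s < n; ++s) {
      // in-slice coordinates (u, v); voxel index per cpp_winding layout
      auto lin = [&](int u, int v) -> R_xlen_t {
        int jx, jy, jz;
        if (axis == 0) { jx = s; jy = u; jz = v; }
        else if (axis == 1) { jx = v; jy = s; jz = u; }
        else { jx = u; jy = v; jz = s; }
        return (R_xlen_t)jx + (R_xlen_t)n * (jy + (R_xlen_t)n * jz);
      };
      bool any = false;
      for (int v = 0; v < n; ++v)
        for (int u = 0; u < n; ++u) {
          const double c = cs[lin(u, v)];
          const bool l = std::abs(c / twopi - std::round(c / twopi)) < 1e-6
                         && std::round(c / twopi) != 0.0;
          lab[(size_t)u + (size_t)n * v] = l ? 1 : 0;
          seen[(size_t)u + (size_t)n * v] = 0;
          if (l) any = true;
        }
      if (!any) continue;
      for (int v0 = 0; v0 < n; ++v0)
        for (int u0 = 0; u0 < n; ++u0) {
          const size_t p0 = (size_t)u0 + (size_t)n * v0;
          if (!lab[p0] || seen[p0]) continue;
          // BFS this 8-connected cluster
          stack.clear(); cluster.clear();
          stack.push_back((int)p0); seen[p0] = 1;
          while (!stack.empty()) {
            const int p = stack.back(); stack.pop_back();
            cluster.push_back(p);
            const int u = p % n, v = p / n;
            for (int dv = -1; dv <= 1; ++dv)
              for (int du = -1; du <= 1; ++du) {
                const int uu = u + du, vv = v + dv;
                if (uu < 0 || uu >= n || vv < 0 || vv >= n) continue;
                const size_t q = (size_t)uu + (size_t)n * vv;
                if (lab[q] && !seen[q]) { seen[q] = 1; stack.push_back((int)q); }
              }
          }
          double mu = 0, mv = 0;
          for (size_t j = 0; j < cluster.size(); ++j) {
            mu += cluster[j] % n; mv += cluster[j] / n;
          }
          mu /= cluster.size(); mv /= cluster.size();
          int bestp = cluster[0];
          double bestd = 1e30;
          for (size_t j = 0; j < cluster.size(); ++j) {
            const double du = cluster[j] % n - mu, dv = cluster[j] / n - mv;
            const double dd = du * du + dv * dv;
            if (dd < bestd - 1e-12) { bestd = dd; bestp = cluster[j]; }
          }
          out[lin(bestp % n, bestp / n)] = true;
        }
    }
  }
  return out;
}

// Greedy deterministic path extraction over the 26-neighbor graph of a
// voxel mask. Paths start at the unvisited voxel with the fewest
// unvisited neighbors (ties by voxel order), then walk to unvisited
// neighbors, preferring the continuation closest to the current heading;
// a path ends when no unvisited neighbor remains. Paths shorter than
// min_length voxels are dropped. Returns a list of 1-based linear-index
// vectors into the grid.
// [[Rcpp::export]]
List cpp_trace_paths(IntegerVector idx, int n, int min_length) {
  const int nv = idx.size();
  std::vector<int> lookup((size_t)n * n * n, -1);
  std::vector<int> cx(nv), cy(nv), cz(nv);
  for (int i = 0; i < nv; ++i) {
    const R_xlen_t lin = (R_xlen_t)idx[i] - 1;
    lookup[lin] = i;
    cx[i] = (int)(lin % n);
    cy[i] = (int)((lin / n) % n);
    cz[i] = (int)(lin / ((R_xlen_t)n * n));
  }
  // offsets in fixed order: dx fastest, matching the documented order
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  auto neighbors = [&](int i, std::vector<int> &out) {
    out.clear();
    for (size_t j = 0; j < ox.size(); ++j) {
      const int qx = cx[i] + ox[j], qy = cy[i] + oy[j], qz = cz[i] + oz[j];
      if (qx < 0 || qx >= n || qy < 0 || qy >= n || qz < 0 || qz >= n)
        continue;
      const int hit = lookup[(size_t)qx + (size_t)n * (qy + (size_t)n * qz)];
      if (hit >= 0) out.push_back(hit);
    }
  };

  std::vector<int> udeg(nv, 0);
  std::vector<char> visited(nv, 0);
  std::vector<int> nb;
  for (int i = 0; i < nv; ++i) { neighbors(i, nb); udeg[i] = (int)nb.size(); }

  // min-heap on (udeg, node) with lazy invalidation
  typedef std::pair<int, int> Key;
  std::priority_queue<Key, std::vector<Key>, std::greater<Key> > heap;
  for (int i = 0; i < nv; ++i) heap.push(Key(udeg[i], i));

  List out;
  std::vector<int> path;
  std::vector<int> cand;
  while (!heap.empty()) {
    Key top = heap.top(); heap.pop();
    const int start = top.second;
    if (visited[start] || top.first != udeg[start]) continue;
    path.clear();
    path.push_back(start);
    visited[start] = 1;
    neighbors(start, nb);
    for (size_t j = 0; j < nb.size(); ++j) {
      if (!visited[nb[j]]) { --udeg[nb[j]]; heap.push(Key(udeg[nb[j]], nb[j])); }
    }
    double hx = 0, hy = 0, hz = 0;
    bool has_heading = false;
    for (;;) {
      const int cur = path.back();
      neighbors(cur, nb);
      cand.clear();
      for (size_t j = 0; j < nb.size(); ++j)
        if (!visited[nb[j]]) cand.push_back(nb[j]);
      if (cand.empty()) break;
      int nxt = cand[0];
      if (cand.size() > 1 && has_heading) {
        double best = -2.0;
        for (size_t j = 0; j < cand.size(); ++j) {
          const double vx = cx[cand[j]] - cx[cur];
          const double vy = cy[cand[j]] - cy[cur];
          const double vz = cz[cand[j]] - cz[cur];
          const double nv_ = std::sqrt(vx * vx + vy * vy + vz * vz);
          const double sc = (vx * hx + vy * hy + vz * hz) / nv_;
          if (sc > best + 1e-12) { best = sc; nxt = cand[j]; }
        }
      }
      const double vx = cx[nxt] - cx[cur], vy = cy[nxt] - cy[cur],
                   vz = cz[nxt] - cz[cur];
      const double nv_ = std::sqrt(vx * vx + vy * vy + vz * vz);
      hx = vx / nv_; hy = vy / nv_; hz = vz / nv_;
      has_heading = true;
      visited[nxt] = 1;
      neighbors(nxt, nb);
      for (size_t j = 0; j < nb.size(); ++j)
        if (!visited[nb[j]]) { --udeg[nb[j]]; heap.push(Key(udeg[nb[j]], nb[j])); }
      path.push_back(nxt);
    }
    if ((int)path.size() >= min_length) {
      IntegerVector pv(path.size());
      for (size_t j = 0; j < path.size(); ++j) pv[j] = idx[path[j]];
      out.push_back(pv);
    }
  }
  return out;
}

static inline double wrap_pi(double d) {
  // map to (-pi, pi], boundary assigned to +pi
  const double twopi = 2.0 * M_PI;
  d -= twopi * std::ceil((d - M_PI) / twopi);
  return d;
}

// Cumulative phase difference around the counterclockwise 8-neighbor loop of
// every pixel, in 2-D slices taken over the three axis orientations of a
// cubic phase grid. Loop offsets start at (-1,-1). axis = 0: loops in the
// (y,z) plane; 1: (z,x); 2: (x,y). With periodic = true the loop wraps
// across slice boundaries; otherwise edge pixels get c = 0 (unlabeled).
// [[Rcpp::export]]
NumericVector cpp_winding(NumericVector psi, int n, int axis, bool periodic) {
  // counterclockwise ring around the center, starting at (-1,-1)
  static const int du[8] = {-1, 0, 1, 1, 1, 0, -1, -1};
  static const int dv[8] = {-1, -1, -1, 0, 1, 1, 1, 0};
  const R_xlen_t ntot = (R_xlen_t)n * n * n;
  NumericVector cout(ntot, 0.0);

  // linear index of (ix, iy, iz) in an R array: ix + n*(iy + n*iz)
  for (int iz = 0; iz < n; ++iz) {
    for (int iy = 0; iy < n; ++iy) {
      for (int ix = 0; ix < n; ++ix) {
        // (u, v) are the in-slice coordinates for this axis
        int u, v;
        if (axis == 0) { u = iy; v = iz; }
        else if (axis == 1) { u = iz; v = ix; }
        else { u = ix; v = iy; }
        if (!periodic && (u == 0 || u == n - 1 || v == 0 || v == n - 1))
          continue;
        double csum = 0.0, prev = 0.0;
        for (int s = 0; s <= 8; ++s) {
          const int ss = s % 8;
          int uu = u + du[ss], vv = v + dv[ss];
          if (periodic) {
            uu = (uu + n) % n;
            vv = (vv + n) % n;
          }
          int jx, jy, jz;
          if (axis == 0) { jx = ix; jy = uu; jz = vv; }
          else if (axis == 1) { jx = vv; jy = iy; jz = uu; }
          else { jx = uu; jy = vv; jz = iz; }
          const double p = psi[(R_xlen_t)jx + (R_xlen_t)n * (jy + (R_xlen_t)n * jz)];
          if (s > 0) csum += wrap_pi(p - prev);
          prev = p;
        }
        cout[(R_xlen_t)ix + (R_xlen_t)n * (iy + (R_xlen_t)n * iz)] = csum;
      }
    }
  }
  return cout;
}
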