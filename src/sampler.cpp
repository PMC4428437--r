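// Metropolis Monte Carlo (and overdamped Brownian-dynamics cross-check) for
// the wall-tethered, chaperone-bound coarse-grained complex.
//
// Geometry conventions (0-based here; 1-based at the R surface):
//   substrate beads 0..n-1; bead n-1 tethered at the origin on the wall z=0;
//   beads 0..6 are the clamped heptapeptide, rigid with the SBD unit;
//   the wall (z >= 0) constrains substrate beads only, chaperone beads are
//   transparent to it and a chaperone/linker bead with z < 0 flags overlap.
// Rigid units are stored as a local-frame bead table plus a pose (R, t), so
// intra-unit distances are exact regardless of how many moves compose.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static const double RC_FACT2 = std::pow(2.0, 1.0 / 3.0); // (2^(1/6))^2

struct Pose {
  double R[9]; // row-major
  double t[3];
  Pose() {
    for (int i = 0; i < 9; ++i) R[i] = 0.0;
    R[0] = R[4] = R[8] = 1.0;
    t[0] = t[1] = t[2] = 0.0;
  }
  inline void apply(const double* p, double* out) const {
    out[0] = R[0] * p[0] + R[1] * p[1] + R[2] * p[2] + t[0];
    out[1] = R[3] * p[0] + R[4] * p[1] + R[5] * p[2] + t[1];
    out[2] = R[6] * p[0] + R[7] * p[1] + R[8] * p[2] + t[2];
  }
  inline void apply_inv(const double* p, double* out) const {
    double q0 = p[0] - t[0], q1 = p[1] - t[1], q2 = p[2] - t[2];
    out[0] = R[0] * q0 + R[3] * q1 + R[6] * q2;
    out[1] = R[1] * q0 + R[4] * q1 + R[7] * q2;
    out[2] = R[2] * q0 + R[5] * q1 + R[8] * q2;
  }
  void orthonormalize() {
    // Gram-Schmidt on rows
    double* a = R; double* b = R + 3; double* c = R + 6;
    double na = std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]);
    for (int i = 0; i < 3; ++i) a[i] /= na;
    double ab = a[0]*b[0] + a[1]*b[1] + a[2]*b[2];
    for (int i = 0; i < 3; ++i) b[i] -= ab * a[i];
    double nb = std::sqrt(b[0]*b[0] + b[1]*b[1] + b[2]*b[2]);
    for (int i = 0; i < 3; ++i) b[i] /= nb;
    c[0] = a[1]*b[2] - a[2]*b[1];
    c[1] = a[2]*b[0] - a[0]*b[2];
    c[2] = a[0]*b[1] - a[1]*b[0];
  }
};

// rotation matrix about unit axis u by angle ang (row-major)
static void axis_rot(const double* u, double ang, double* M) {
  double c = std::cos(ang), s = std::sin(ang), oc = 1.0 - c;
  M[0] = c + u[0]*u[0]*oc;       M[1] = u[0]*u[1]*oc - u[2]*s; M[2] = u[0]*u[2]*oc + u[1]*s;
  M[3] = u[1]*u[0]*oc + u[2]*s;  M[4] = c + u[1]*u[1]*oc;      M[5] = u[1]*u[2]*oc - u[0]*s;
  M[6] = u[2]*u[0]*oc - u[1]*s;  M[7] = u[2]*u[1]*oc + u[0]*s; M[8] = c + u[2]*u[2]*oc;
}

// out = M %*% pose (rotate pose about world point `ctr` by matrix M)
static Pose compose_about(const Pose& p, const double* M, const double* ctr,
                          const double* shift) {
  Pose q;
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += M[r*3+k] * p.R[k*3+c];
      q.R[r*3+c] = s;
    }
  for (int r = 0; r < 3; ++r) {
    double s = 0;
    for (int k = 0; k < 3; ++k) s += M[r*3+k] * (p.t[k] - ctr[k]);
    q.t[r] = s + ctr[r] + shift[r];
  }
  return q;
}

struct CellList {
  double cell, ox, oy, oz;
  int nx, ny, nz;
  std::vector<int> head;   // per cell, index of first bead (-1 none)
  std::vector<int> nxt;    // per bead
  const std::vector<double>* loc; // local coords (3 per bead)

  void build(const std::vector<double>& local, double cutoff) {
    loc = &local;
    int n = (int)local.size() / 3;
    cell = cutoff;
    double lo[3] = {1e30, 1e30, 1e30}, hi[3] = {-1e30, -1e30, -1e30};
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        lo[d] = std::min(lo[d], local[3*i+d]);
        hi[d] = std::max(hi[d], local[3*i+d]);
      }
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    nx = std::max(1, (int)((hi[0] - lo[0]) / cell) + 1);
    ny = std::max(1, (int)((hi[1] - lo[1]) / cell) + 1);
    nz = std::max(1, (int)((hi[2] - lo[2]) / cell) + 1);
    head.assign((size_t)nx * ny * nz, -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)((local[3*i] - ox) / cell);
      int cy = (int)((local[3*i+1] - oy) / cell);
      int cz = (int)((local[3*i+2] - oz) / cell);
      size_t c = ((size_t)cx * ny + cy) * nz + cz;
      nxt[i] = head[c];
      head[c] = (int)i;
    }
  }

  // sum of WCA energy between local-frame point p and the beads; `skip`
  // excludes one bead index (bonded anchor partner)
  inline double energy(const double* p, double sig2, double eps, double rc2,
                       int skip = -1) const {
    int cx = (int)std::floor((p[0] - ox) / cell);
    int cy = (int)std::floor((p[1] - oy) / cell);
    int cz = (int)std::floor((p[2] - oz) / cell);
    double e = 0.0;
    for (int dx = -1; dx <= 1; ++dx) {
      int x = cx + dx; if (x < 0 || x >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy + dy; if (y < 0 || y >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = cz + dz; if (z < 0 || z >= nz) continue;
          for (int i = head[((size_t)x * ny + y) * nz + z]; i >= 0;
               i = nxt[i]) {
            if (i == skip) continue;
            double ddx = (*loc)[3*i] - p[0];
            double ddy = (*loc)[3*i+1] - p[1];
            double ddz = (*loc)[3*i+2] - p[2];
            double r2 = ddx*ddx + ddy*ddy + ddz*ddz;
            if (r2 < rc2) {
              double sr6 = sig2 / r2; sr6 = sr6 * sr6 * sr6;
              e += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
            }
          }
        }
      }
    }
    return e;
  }

  // WCA force of the beads on local-frame point p (d e / d p), plus the
  // reaction accumulated as force/torque on the unit (local frame quantities)
  inline double force(const double* p, double sig2, double eps, double rc2,
                      double* f_p, double* f_unit, double* tq_unit,
                      const double* c_unit, int skip = -1) const {
    int cx = (int)std::floor((p[0] - ox) / cell);
    int cy = (int)std::floor((p[1] - oy) / cell);
    int cz = (int)std::floor((p[2] - oz) / cell);
    double e = 0.0;
    for (int dx = -1; dx <= 1; ++dx) {
      int x = cx + dx; if (x < 0 || x >= nx) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        int y = cy + dy; if (y < 0 || y >= ny) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          int z = cz + dz; if (z < 0 || z >= nz) continue;
          for (int i = head[((size_t)x * ny + y) * nz + z]; i >= 0;
               i = nxt[i]) {
            if (i == skip) continue;
            double rx = p[0] - (*loc)[3*i];
            double ry = p[1] - (*loc)[3*i+1];
            double rz = p[2] - (*loc)[3*i+2];
            double r2 = rx*rx + ry*ry + rz*rz;
            if (r2 < rc2) {
              double sr6 = sig2 / r2; sr6 = sr6 * sr6 * sr6;
              e += 4.0 * eps * (sr6 * sr6 - sr6) + eps;
              double fmag = 24.0 * eps * (2.0 * sr6 * sr6 - sr6) / r2;
              double fx = fmag * rx, fy = fmag * ry, fz = fmag * rz;
              f_p[0] += fx; f_p[1] += fy; f_p[2] += fz;
              if (f_unit) {
                f_unit[0] -= fx; f_unit[1] -= fy; f_unit[2] -= fz;
                double ax = (*loc)[3*i] - c_unit[0];
                double ay = (*loc)[3*i+1] - c_unit[1];
                double az = (*loc)[3*i+2] - c_unit[2];
                tq_unit[0] += ay * (-fz) - az * (-fy);
                tq_unit[1] += az * (-fx) - ax * (-fz);
                tq_unit[2] += ax * (-fy) - ay * (-fx);
              }
            }
          }
        }
      }
    }
    return e;
  }
};

struct Complex {
  int n, nl;
  std::vector<double> sub;                       // world, 3n
  std::vector<double> sbd_local, nbd_local, clamp_local, lnk;
  Pose sbd, nbd;
  int nbd_anchor, sbd_anchor;                    // bead indices, 0-based
  CellList cl_sbd, cl_nbd;
  double sig2, eps, rc2, rc, kbond, r0, kbend, ktor;
  double c_sbd[3], c_nbd[3], r_sbd, r_nbd;       // local bounding spheres
  long pose_updates;

  inline double wca(double r2) const {
    if (r2 >= rc2) return 0.0;
    double sr6 = sig2 / r2; sr6 = sr6 * sr6 * sr6;
    return 4.0 * eps * (sr6 * sr6 - sr6) + eps;
  }
  inline double bond(const double* p, const double* q) const {
    double dx = p[0]-q[0], dy = p[1]-q[1], dz = p[2]-q[2];
    double d = std::sqrt(dx*dx + dy*dy + dz*dz) - r0;
    return 0.5 * kbond * d * d;
  }
  inline double e_bead_domain(const double* p, const Pose& pose,
                              const CellList& cl, const double* c_loc,
                              double rb, int skip = -1) const {
    // bounding-sphere precheck: most beads are far from a given domain
    double cw[3];
    pose.apply(c_loc, cw);
    double dx = p[0]-cw[0], dy = p[1]-cw[1], dz = p[2]-cw[2];
    double lim = rb + rc;
    if (dx*dx + dy*dy + dz*dz > lim*lim) return 0.0;
    double q[3];
    pose.apply_inv(p, q);
    return cl.energy(q, sig2, eps, rc2, skip);
  }
  inline double e_bead_sbd(const double* p, const Pose& pose,
                           int skip = -1) const {
    return e_bead_domain(p, pose, cl_sbd, c_sbd, r_sbd, skip);
  }
  inline double e_bead_nbd(const double* p, const Pose& pose,
                           int skip = -1) const {
    return e_bead_domain(p, pose, cl_nbd, c_nbd, r_nbd, skip);
  }
  // SBD beads vs NBD beads for given poses (sphere prechecks at both levels)
  double e_dom_dom(const Pose& sbdPose, const Pose& nbdPose) const {
    double ca[3], cb[3];
    sbdPose.apply(c_sbd, ca);
    nbdPose.apply(c_nbd, cb);
    double dx = ca[0]-cb[0], dy = ca[1]-cb[1], dz = ca[2]-cb[2];
    double lim = r_sbd + r_nbd + rc;
    if (dx*dx + dy*dy + dz*dz > lim*lim) return 0.0;
    double e = 0.0, w[3];
    int m = (int)sbd_local.size() / 3;
    double lim2 = (r_nbd + rc) * (r_nbd + rc);
    for (int i = 0; i < m; ++i) {
      sbdPose.apply(&sbd_local[3*i], w);
      double ex = w[0]-cb[0], ey = w[1]-cb[1], ez = w[2]-cb[2];
      if (ex*ex + ey*ey + ez*ez > lim2) continue;
      double q[3];
      nbdPose.apply_inv(w, q);
      e += cl_nbd.energy(q, sig2, eps, rc2);
    }
    return e;
  }
  // bead k of the substrate (world position p) vs other substrate beads:
  // skip bonded neighbours and pairs internal to the clamp
  inline double e_bead_sub(int k, const double* p) const {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      int dj = j > k ? j - k : k - j;
      if (dj < 2) continue;
      if (j < 7 && k < 7) continue;
      double dx = p[0]-sub[3*j], dy = p[1]-sub[3*j+1], dz = p[2]-sub[3*j+2];
      e += wca(dx*dx + dy*dy + dz*dz);
    }
    return e;
  }
  inline double e_bead_lnk(const double* p, int skip = -1) const {
    double e = 0.0;
    for (int j = 0; j < nl; ++j) {
      if (j == skip) continue;
      double dx = p[0]-lnk[3*j], dy = p[1]-lnk[3*j+1], dz = p[2]-lnk[3*j+2];
      e += wca(dx*dx + dy*dy + dz*dz);
    }
    return e;
  }
  inline void sbd_anchor_world(const Pose& pose, double* out) const {
    pose.apply(&sbd_local[3*sbd_anchor], out);
  }
  inline void nbd_anchor_world(const Pose& pose, double* out) const {
    pose.apply(&nbd_local[3*nbd_anchor], out);
  }

  // bending + torsion over the substrate chain (full; O(n), used as a
  // before/after delta whenever the local potentials are enabled)
  double sub_bt_energy(const std::vector<double>& s) const {
    if (kbend <= 0.0 && ktor <= 0.0) return 0.0;
    double e = 0.0;
    if (kbend > 0.0) {
      for (int i = 1; i < n - 1; ++i) {
        double ux = s[3*(i-1)] - s[3*i], uy = s[3*(i-1)+1] - s[3*i+1],
               uz = s[3*(i-1)+2] - s[3*i+2];
        double vx = s[3*(i+1)] - s[3*i], vy = s[3*(i+1)+1] - s[3*i+1],
               vz = s[3*(i+1)+2] - s[3*i+2];
        double ct = (ux*vx + uy*vy + uz*vz) /
          std::sqrt((ux*ux+uy*uy+uz*uz) * (vx*vx+vy*vy+vz*vz));
        e += kbend * (1.0 + ct);
      }
    }
    if (ktor > 0.0) {
      for (int i = 0; i < n - 3; ++i) {
        const double* p1 = &s[3*i]; const double* p2 = &s[3*(i+1)];
        const double* p3 = &s[3*(i+2)]; const double* p4 = &s[3*(i+3)];
        double b1[3] = {p2[0]-p1[0], p2[1]-p1[1], p2[2]-p1[2]};
        double b2[3] = {p3[0]-p2[0], p3[1]-p2[1], p3[2]-p2[2]};
        double b3[3] = {p4[0]-p3[0], p4[1]-p3[1], p4[2]-p3[2]};
        double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                        b1[0]*b2[1]-b1[1]*b2[0]};
        double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                        b2[0]*b3[1]-b2[1]*b3[0]};
        double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
        double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                        n1[0]*b2[1]-n1[1]*b2[0]};
        double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
        double y = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
        e += ktor * (1.0 + std::cos(std::atan2(y, x)));
      }
    }
    return e;
  }

  // full potential energy, matching the plain-R reference implementation
  double full_energy() const {
    double e = 0.0;
    // substrate bonds (all consecutive, clamp-internal included as constants)
    for (int i = 0; i + 1 < n; ++i) e += bond(&sub[3*i], &sub[3*(i+1)]);
    e += sub_bt_energy(sub);
    // substrate-substrate non-bonded
    for (int i = 0; i + 2 < n; ++i)
      for (int j = i + 2; j < n; ++j) {
        if (i < 7 && j < 7) continue;
        double dx = sub[3*i]-sub[3*j], dy = sub[3*i+1]-sub[3*j+1],
               dz = sub[3*i+2]-sub[3*j+2];
        e += wca(dx*dx + dy*dy + dz*dz);
      }
    // substrate vs chaperone
    for (int i = 0; i < n; ++i) {
      e += e_bead_nbd(&sub[3*i], nbd);
      if (i >= 7) e += e_bead_sbd(&sub[3*i], sbd);
      e += e_bead_lnk(&sub[3*i]);
    }
    // NBD vs SBD (iterate SBD beads, usually the smaller unit)
    e += e_dom_dom(sbd, nbd);
    // linker: bonds, anchors, internal non-bonded, vs domains
    for (int i = 0; i + 1 < nl; ++i) e += bond(&lnk[3*i], &lnk[3*(i+1)]);
    double aw[3];
    nbd_anchor_world(nbd, aw);
    e += bond(&lnk[0], aw);
    sbd_anchor_world(sbd, aw);
    e += bond(&lnk[3*(nl-1)], aw);
    for (int i = 0; i + 2 < nl; ++i)
      for (int j = i + 2; j < nl; ++j) {
        double dx = lnk[3*i]-lnk[3*j], dy = lnk[3*i+1]-lnk[3*j+1],
               dz = lnk[3*i+2]-lnk[3*j+2];
        e += wca(dx*dx + dy*dy + dz*dz);
      }
    for (int i = 0; i < nl; ++i) {
      e += e_bead_nbd(&lnk[3*i], nbd, i == 0 ? nbd_anchor : -1);
      e += e_bead_sbd(&lnk[3*i], sbd, i == nl - 1 ? sbd_anchor : -1);
    }
    return e;
  }

  // 1 if no chaperone/linker bead centre is below the wall (z < 0)
  int nonoverlap_indicator() const {
    for (int i = 0; i < nl; ++i) if (lnk[3*i+2] < 0.0) return 0;
    int m = (int)sbd_local.size() / 3;
    for (int i = 0; i < m; ++i) {
      double z = sbd.R[6]*sbd_local[3*i] + sbd.R[7]*sbd_local[3*i+1] +
                 sbd.R[8]*sbd_local[3*i+2] + sbd.t[2];
      if (z < 0.0) return 0;
    }
    m = (int)nbd_local.size() / 3;
    for (int i = 0; i < m; ++i) {
      double z = nbd.R[6]*nbd_local[3*i] + nbd.R[7]*nbd_local[3*i+1] +
                 nbd.R[8]*nbd_local[3*i+2] + nbd.t[2];
      if (z < 0.0) return 0;
    }
    return 1;
  }
};

static Complex make_complex(const NumericMatrix& sub, const NumericMatrix& nbd,
                            const NumericMatrix& sbd, const NumericMatrix& lnk,
                            int nbd_anchor, int sbd_anchor, const List& ff) {
  Complex cx;
  cx.n = sub.nrow();
  cx.nl = lnk.nrow();
  double sigma = as<double>(ff["sigma"]);
  cx.sig2 = sigma * sigma;
  cx.rc2 = RC_FACT2 * cx.sig2;
  cx.eps = as<double>(ff["epsilon"]);
  cx.kbond = as<double>(ff["bond_stiffness"]);
  cx.r0 = as<double>(ff["bond_length"]);
  cx.kbend = as<double>(ff["bending_k"]);
  cx.ktor = as<double>(ff["torsion_k"]);
  cx.pose_updates = 0;
  cx.sub.resize(3 * cx.n);
  for (int i = 0; i < cx.n; ++i)
    for (int d = 0; d < 3; ++d) cx.sub[3*i+d] = sub(i, d);
  auto fill = [](const NumericMatrix& m, std::vector<double>& v) {
    v.resize(3 * m.nrow());
    for (int i = 0; i < m.nrow(); ++i)
      for (int d = 0; d < 3; ++d) v[3*i+d] = m(i, d);
  };
  fill(nbd, cx.nbd_local);
  fill(sbd, cx.sbd_local);
  fill(lnk, cx.lnk);
  // clamp = current substrate beads 0..6 in the SBD frame (pose = identity)
  cx.clamp_local.resize(21);
  for (int i = 0; i < 7 && i < cx.n; ++i)
    for (int d = 0; d < 3; ++d) cx.clamp_local[3*i+d] = cx.sub[3*i+d];
  cx.nbd_anchor = nbd_anchor;
  cx.sbd_anchor = sbd_anchor;
  cx.rc = std::sqrt(cx.rc2);
  auto bound = [](const std::vector<double>& v, double* c, double& r) {
    int m = (int)v.size() / 3;
    c[0] = c[1] = c[2] = 0.0;
    for (int i = 0; i < m; ++i)
      for (int d = 0; d < 3; ++d) c[d] += v[3*i+d] / m;
    r = 0.0;
    for (int i = 0; i < m; ++i) {
      double r2 = 0.0;
      for (int d = 0; d < 3; ++d) {
        double x = v[3*i+d] - c[d];
        r2 += x * x;
      }
      r = std::max(r, r2);
    }
    r = std::sqrt(r);
  };
  bound(cx.sbd_local, cx.c_sbd, cx.r_sbd);
  bound(cx.nbd_local, cx.c_nbd, cx.r_nbd);
  // cell lists are built by the caller once the object has its final address
  return cx;
}

static void build_cells(Complex& cx) {
  double cutoff = std::sqrt(cx.rc2);
  cx.cl_nbd.build(cx.nbd_local, cutoff);
  cx.cl_sbd.build(cx.sbd_local, cutoff);
}

// [[Rcpp::export(name = ".complex_energy_cpp")]]
double complex_energy_cpp(NumericMatrix sub, NumericMatrix nbd,
                          NumericMatrix sbd, NumericMatrix lnk,
                          int nbd_anchor, int sbd_anchor, List ff) {
  Complex cx = make_complex(sub, nbd, sbd, lnk, nbd_anchor - 1,
                            sbd_anchor - 1, ff);
  build_cells(cx);
  return cx.full_energy();
}

// ---------------------------------------------------------------------------
// Metropolis sampler

struct MoveStats { long att[6] = {0,0,0,0,0,0}; long acc[6] = {0,0,0,0,0,0}; };

// energy of the SBD unit + clamped beads against everything that is not rigid
// with them, for a candidate pose (clamp positions supplied in `clampw`)
static double e_sbd_unit(const Complex& cx, const Pose& pose,
                         const double* clampw) {
  double e = 0.0;
  int nclamp = std::min(7, cx.n);
  // clamp beads vs free substrate beads (skip bonded 6-7 pair), NBD, linker
  for (int k = 0; k < nclamp; ++k) {
    const double* p = clampw + 3*k;
    for (int j = 7; j < cx.n; ++j) {
      if (j - k < 2) continue;
      double dx = p[0]-cx.sub[3*j], dy = p[1]-cx.sub[3*j+1],
             dz = p[2]-cx.sub[3*j+2];
      e += cx.wca(dx*dx + dy*dy + dz*dz);
    }
    e += cx.e_bead_nbd(p, cx.nbd);
    e += cx.e_bead_lnk(p);
  }
  // bond clamp bead 6 -- substrate bead 7
  if (cx.n > 7) e += cx.bond(clampw + 18, &cx.sub[21]);
  // SBD beads vs free substrate beads
  for (int j = 7; j < cx.n; ++j)
    e += cx.e_bead_sbd(&cx.sub[3*j], pose);
  // SBD vs NBD
  e += cx.e_dom_dom(pose, cx.nbd);
  // SBD vs linker (+ anchor bond)
  for (int i = 0; i < cx.nl; ++i)
    e += cx.e_bead_sbd(&cx.lnk[3*i], pose,
                       i == cx.nl - 1 ? cx.sbd_anchor : -1);
  double aw[3];
  cx.sbd_anchor_world(pose, aw);
  e += cx.bond(&cx.lnk[3*(cx.nl-1)], aw);
  return e;
}

static double e_nbd_unit(const Complex& cx, const Pose& pose) {
  double e = 0.0;
  for (int i = 0; i < cx.n; ++i)
    e += cx.e_bead_nbd(&cx.sub[3*i], pose);
  e += cx.e_dom_dom(cx.sbd, pose);
  for (int i = 0; i < cx.nl; ++i)
    e += cx.e_bead_nbd(&cx.lnk[3*i], pose, i == 0 ? cx.nbd_anchor : -1);
  double aw[3];
  cx.nbd_anchor_world(pose, aw);
  e += cx.bond(&cx.lnk[0], aw);
  return e;
}

// [[Rcpp::export(name = ".sample_complex_cpp")]]
List sample_complex_cpp(NumericMatrix sub, NumericMatrix nbd,
                        NumericMatrix sbd, NumericMatrix lnk,
                        int nbd_anchor, int sbd_anchor, List ff,
                        int n_sweeps, int moves_per_sweep, int equil,
                        int thin, NumericVector weights, double disp_sigma,
                        double crank_max, double pivot_max, double rb_rot_max,
                        double rb_trans_sigma, double seed) {
  Complex cx = make_complex(sub, nbd, sbd, lnk, nbd_anchor - 1,
                            sbd_anchor - 1, ff);
  build_cells(cx);
  Rng rng((uint64_t)seed);
  const int n = cx.n, nl = cx.nl;
  const bool bt = (cx.kbend > 0.0 || cx.ktor > 0.0);
  double wsum = 0.0;
  double wcum[6];
  for (int i = 0; i < 6; ++i) { wsum += weights[i]; wcum[i] = wsum; }
  if (wsum <= 0) stop("all move weights are zero");
  MoveStats ms;
  std::vector<int> indicators;
  indicators.reserve((n_sweeps - equil) / thin + 1);
  std::vector<double> cv_nbdz, cv_sbdz, cv_minz;

  std::vector<double> tmp(3 * std::max(n, nl));

  auto metro = [&](double dE) {
    return dE <= 0.0 || rng.unif() < std::exp(-dE);
  };

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int mv = 0; mv < moves_per_sweep; ++mv) {
      double u = rng.unif() * wsum;
      int kind = 0;
      while (kind < 5 && u > wcum[kind]) ++kind;
      switch (kind) {
      case 0: { // single-bead displacement, free beads 7..n-2
        if (n < 9) break;
        ms.att[0]++;
        int k = 7 + rng.below(n - 8);
        double p[3] = {cx.sub[3*k] + disp_sigma * rng.gauss(),
                       cx.sub[3*k+1] + disp_sigma * rng.gauss(),
                       cx.sub[3*k+2] + disp_sigma * rng.gauss()};
        if (p[2] < 0.0) break; // hard wall
        double e0 = cx.bond(&cx.sub[3*(k-1)], &cx.sub[3*k]) +
                    cx.bond(&cx.sub[3*k], &cx.sub[3*(k+1)]) +
                    cx.e_bead_sub(k, &cx.sub[3*k]) +
                    cx.e_bead_sbd(&cx.sub[3*k], cx.sbd) +
                    cx.e_bead_nbd(&cx.sub[3*k], cx.nbd) +
                    cx.e_bead_lnk(&cx.sub[3*k]);
        double ebt0 = bt ? cx.sub_bt_energy(cx.sub) : 0.0;
        double old[3] = {cx.sub[3*k], cx.sub[3*k+1], cx.sub[3*k+2]};
        cx.sub[3*k] = p[0]; cx.sub[3*k+1] = p[1]; cx.sub[3*k+2] = p[2];
        double e1 = cx.bond(&cx.sub[3*(k-1)], &cx.sub[3*k]) +
                    cx.bond(&cx.sub[3*k], &cx.sub[3*(k+1)]) +
                    cx.e_bead_sub(k, &cx.sub[3*k]) +
                    cx.e_bead_sbd(&cx.sub[3*k], cx.sbd) +
                    cx.e_bead_nbd(&cx.sub[3*k], cx.nbd) +
                    cx.e_bead_lnk(&cx.sub[3*k]);
        double ebt1 = bt ? cx.sub_bt_energy(cx.sub) : 0.0;
        if (metro(e1 + ebt1 - e0 - ebt0)) { ms.acc[0]++; }
        else { cx.sub[3*k] = old[0]; cx.sub[3*k+1] = old[1];
               cx.sub[3*k+2] = old[2]; }
        break;
      }
      case 1: { // crankshaft of a free bead about its neighbours' axis
        if (n < 9) break;
        ms.att[1]++;
        int k = 7 + rng.below(n - 8);
        double ax[3] = {cx.sub[3*(k+1)] - cx.sub[3*(k-1)],
                        cx.sub[3*(k+1)+1] - cx.sub[3*(k-1)+1],
                        cx.sub[3*(k+1)+2] - cx.sub[3*(k-1)+2]};
        double na = std::sqrt(ax[0]*ax[0] + ax[1]*ax[1] + ax[2]*ax[2]);
        if (na < 1e-9) break;
        for (int d = 0; d < 3; ++d) ax[d] /= na;
        double M[9];
        axis_rot(ax, (2.0 * rng.unif() - 1.0) * crank_max, M);
        double q0 = cx.sub[3*k]   - cx.sub[3*(k-1)];
        double q1 = cx.sub[3*k+1] - cx.sub[3*(k-1)+1];
        double q2 = cx.sub[3*k+2] - cx.sub[3*(k-1)+2];
        double p[3] = {M[0]*q0 + M[1]*q1 + M[2]*q2 + cx.sub[3*(k-1)],
                       M[3]*q0 + M[4]*q1 + M[5]*q2 + cx.sub[3*(k-1)+1],
                       M[6]*q0 + M[7]*q1 + M[8]*q2 + cx.sub[3*(k-1)+2]};
        if (p[2] < 0.0) break;
        double e0 = cx.e_bead_sub(k, &cx.sub[3*k]) +
                    cx.e_bead_sbd(&cx.sub[3*k], cx.sbd) +
                    cx.e_bead_nbd(&cx.sub[3*k], cx.nbd) +
                    cx.e_bead_lnk(&cx.sub[3*k]);
        double ebt0 = bt ? cx.sub_bt_energy(cx.sub) : 0.0;
        double old[3] = {cx.sub[3*k], cx.sub[3*k+1], cx.sub[3*k+2]};
        cx.sub[3*k] = p[0]; cx.sub[3*k+1] = p[1]; cx.sub[3*k+2] = p[2];
        double e1 = cx.e_bead_sub(k, &cx.sub[3*k]) +
                    cx.e_bead_sbd(&cx.sub[3*k], cx.sbd) +
                    cx.e_bead_nbd(&cx.sub[3*k], cx.nbd) +
                    cx.e_bead_lnk(&cx.sub[3*k]);
        double ebt1 = bt ? cx.sub_bt_energy(cx.sub) : 0.0;
        if (metro(e1 + ebt1 - e0 - ebt0)) { ms.acc[1]++; }
        else { cx.sub[3*k] = old[0]; cx.sub[3*k+1] = old[1];
               cx.sub[3*k+2] = old[2]; }
        break;
      }
      case 2: { // pivot: rotate head (beads 0..j-1 + whole chaperone) about j
        ms.att[2]++;
        int j = 7 + rng.below(n - 7); // 7..n-1
        double axu[3];
        rng.unit_vec(axu);
        double M[9];
        axis_rot(axu, (2.0 * rng.unif() - 1.0) * pivot_max, M);
        const double* ctr = &cx.sub[3*j];
        // candidate head coordinates
        bool legal = true;
        for (int i = 0; i < j; ++i) {
          double q0 = cx.sub[3*i] - ctr[0], q1 = cx.sub[3*i+1] - ctr[1],
                 q2 = cx.sub[3*i+2] - ctr[2];
          tmp[3*i]   = M[0]*q0 + M[1]*q1 + M[2]*q2 + ctr[0];
          tmp[3*i+1] = M[3]*q0 + M[4]*q1 + M[5]*q2 + ctr[1];
          tmp[3*i+2] = M[6]*q0 + M[7]*q1 + M[8]*q2 + ctr[2];
          if (tmp[3*i+2] < 0.0) { legal = false; break; }
        }
        if (!legal) break;
        double zero[3] = {0, 0, 0};
        Pose sbdC = compose_about(cx.sbd, M, ctr, zero);
        Pose nbdC = compose_about(cx.nbd, M, ctr, zero);
        std::vector<double> lnkC(3 * nl);
        for (int i = 0; i < nl; ++i) {
          double q0 = cx.lnk[3*i] - ctr[0], q1 = cx.lnk[3*i+1] - ctr[1],
                 q2 = cx.lnk[3*i+2] - ctr[2];
          lnkC[3*i]   = M[0]*q0 + M[1]*q1 + M[2]*q2 + ctr[0];
          lnkC[3*i+1] = M[3]*q0 + M[4]*q1 + M[5]*q2 + ctr[1];
          lnkC[3*i+2] = M[6]*q0 + M[7]*q1 + M[8]*q2 + ctr[2];
        }
        // dE: moved set vs unmoved substrate beads j..n-1
        double e0 = 0.0, e1 = 0.0;
        for (int i = j; i < n; ++i) {
          const double* p = &cx.sub[3*i];
          e0 += cx.e_bead_sbd(p, cx.sbd) + cx.e_bead_nbd(p, cx.nbd);
          e1 += cx.e_bead_sbd(p, sbdC) + cx.e_bead_nbd(p, nbdC);
          for (int m2 = 0; m2 < j; ++m2) {
            if (i - m2 < 2) continue;
            double dx = p[0]-cx.sub[3*m2], dy = p[1]-cx.sub[3*m2+1],
                   dz = p[2]-cx.sub[3*m2+2];
            e0 += cx.wca(dx*dx + dy*dy + dz*dz);
            dx = p[0]-tmp[3*m2]; dy = p[1]-tmp[3*m2+1]; dz = p[2]-tmp[3*m2+2];
            e1 += cx.wca(dx*dx + dy*dy + dz*dz);
          }
          for (int m2 = 0; m2 < nl; ++m2) {
            double dx = p[0]-cx.lnk[3*m2], dy = p[1]-cx.lnk[3*m2+1],
                   dz = p[2]-cx.lnk[3*m2+2];
            e0 += cx.wca(dx*dx + dy*dy + dz*dz);
            dx = p[0]-lnkC[3*m2]; dy = p[1]-lnkC[3*m2+1];
            dz = p[2]-lnkC[3*m2+2];
            e1 += cx.wca(dx*dx + dy*dy + dz*dz);
          }
        }
        double ebt0 = 0.0, ebt1 = 0.0;
        if (bt) {
          ebt0 = cx.sub_bt_energy(cx.sub);
          std::vector<double> subC(cx.sub);
          for (int i = 0; i < j; ++i)
            for (int d = 0; d < 3; ++d) subC[3*i+d] = tmp[3*i+d];
          ebt1 = cx.sub_bt_energy(subC);
        }
        if (metro(e1 + ebt1 - e0 - ebt0)) {
          ms.acc[2]++;
          for (int i = 0; i < j; ++i)
            for (int d = 0; d < 3; ++d) cx.sub[3*i+d] = tmp[3*i+d];
          cx.sbd = sbdC;
          cx.nbd = nbdC;
          cx.lnk = lnkC;
          if (++cx.pose_updates % 512 == 0) {
            cx.sbd.orthonormalize();
            cx.nbd.orthonormalize();
          }
        }
        break;
      }
      case 3: { // chaperone-assembly rotation about the pore-side clamp
                // end (+ small translation): SBD, clamped heptapeptide, NBD
                // and linker move as one piece, so no internal bond changes
        ms.att[3]++;
        int nclamp = std::min(7, n);
        double ctr[3] = {cx.sub[3*(nclamp-1)], cx.sub[3*(nclamp-1)+1],
                         cx.sub[3*(nclamp-1)+2]};
        double axu[3];
        rng.unit_vec(axu);
        double M[9];
        axis_rot(axu, (2.0 * rng.unif() - 1.0) * rb_rot_max, M);
        double shift[3] = {rb_trans_sigma * rng.gauss(),
                           rb_trans_sigma * rng.gauss(),
                           rb_trans_sigma * rng.gauss()};
        Pose sbdC = compose_about(cx.sbd, M, ctr, shift);
        Pose nbdC = compose_about(cx.nbd, M, ctr, shift);
        double clampC[21];
        bool legal = true;
        for (int k = 0; k < nclamp; ++k) {
          sbdC.apply(&cx.clamp_local[3*k], clampC + 3*k);
          if (clampC[3*k+2] < 0.0) { legal = false; break; }
        }
        if (!legal) break;
        std::vector<double> lnkC(3 * nl);
        for (int i = 0; i < nl; ++i) {
          double q0 = cx.lnk[3*i] - ctr[0], q1 = cx.lnk[3*i+1] - ctr[1],
                 q2 = cx.lnk[3*i+2] - ctr[2];
          lnkC[3*i]   = M[0]*q0 + M[1]*q1 + M[2]*q2 + ctr[0] + shift[0];
          lnkC[3*i+1] = M[3]*q0 + M[4]*q1 + M[5]*q2 + ctr[1] + shift[1];
          lnkC[3*i+2] = M[6]*q0 + M[7]*q1 + M[8]*q2 + ctr[2] + shift[2];
        }
        // dE: moved assembly vs unmoved substrate beads 7..n-1, plus the
        // clamp-to-chain bond when the assembly is translated
        double e0 = 0.0, e1 = 0.0;
        if (n > 7) {
          e0 += cx.bond(&cx.sub[3*(nclamp-1)], &cx.sub[3*nclamp]);
          e1 += cx.bond(clampC + 3*(nclamp-1), &cx.sub[3*nclamp]);
        }
        for (int i = 7; i < n; ++i) {
          const double* p = &cx.sub[3*i];
          e0 += cx.e_bead_sbd(p, cx.sbd) + cx.e_bead_nbd(p, cx.nbd);
          e1 += cx.e_bead_sbd(p, sbdC) + cx.e_bead_nbd(p, nbdC);
          for (int k = 0; k < nclamp; ++k) {
            if (i - k < 2) continue;
            double dx = p[0]-cx.sub[3*k], dy = p[1]-cx.sub[3*k+1],
                   dz = p[2]-cx.sub[3*k+2];
            e0 += cx.wca(dx*dx + dy*dy + dz*dz);
            dx = p[0]-clampC[3*k]; dy = p[1]-clampC[3*k+1];
            dz = p[2]-clampC[3*k+2];
            e1 += cx.wca(dx*dx + dy*dy + dz*dz);
          }
          for (int m2 = 0; m2 < nl; ++m2) {
            double dx = p[0]-cx.lnk[3*m2], dy = p[1]-cx.lnk[3*m2+1],
                   dz = p[2]-cx.lnk[3*m2+2];
            e0 += cx.wca(dx*dx + dy*dy + dz*dz);
            dx = p[0]-lnkC[3*m2]; dy = p[1]-lnkC[3*m2+1];
            dz = p[2]-lnkC[3*m2+2];
            e1 += cx.wca(dx*dx + dy*dy + dz*dz);
          }
        }
        double ebt0 = 0.0, ebt1 = 0.0;
        if (bt) {
          ebt0 = cx.sub_bt_energy(cx.sub);
          std::vector<double> subC(cx.sub);
          for (int k = 0; k < nclamp; ++k)
            for (int d = 0; d < 3; ++d) subC[3*k+d] = clampC[3*k+d];
          ebt1 = cx.sub_bt_energy(subC);
        }
        if (metro(e1 + ebt1 - e0 - ebt0)) {
          ms.acc[3]++;
          cx.sbd = sbdC;
          cx.nbd = nbdC;
          cx.lnk = lnkC;
          for (int k = 0; k < nclamp; ++k)
            for (int d = 0; d < 3; ++d) cx.sub[3*k+d] = clampC[3*k+d];
          if (++cx.pose_updates % 512 == 0) {
            cx.sbd.orthonormalize();
            cx.nbd.orthonormalize();
          }
        }
        break;
      }
      case 4: { // NBD rigid move about its linker anchor bead, which
                // preserves the linker-NBD anchor bond under pure rotation
        ms.att[4]++;
        double ctr[3];
        cx.nbd_anchor_world(cx.nbd, ctr);
        double axu[3];
        rng.unit_vec(axu);
        double M[9];
        axis_rot(axu, (2.0 * rng.unif() - 1.0) * rb_rot_max, M);
        double shift[3] = {rb_trans_sigma * rng.gauss(),
                           rb_trans_sigma * rng.gauss(),
                           rb_trans_sigma * rng.gauss()};
        Pose nbdC = compose_about(cx.nbd, M, ctr, shift);
        double e0 = e_nbd_unit(cx, cx.nbd);
        double e1 = e_nbd_unit(cx, nbdC);
        if (metro(e1 - e0)) {
          ms.acc[4]++;
          cx.nbd = nbdC;
          if (++cx.pose_updates % 512 == 0) cx.nbd.orthonormalize();
        }
        break;
      }
      case 5: { // linker bead displacement
        ms.att[5]++;
        int i = rng.below(nl);
        double p[3] = {cx.lnk[3*i] + disp_sigma * rng.gauss(),
                       cx.lnk[3*i+1] + disp_sigma * rng.gauss(),
                       cx.lnk[3*i+2] + disp_sigma * rng.gauss()};
        double aw[3];
        auto e_here = [&](const double* q) {
          double e = 0.0;
          if (i > 0) e += cx.bond(&cx.lnk[3*(i-1)], q);
          else { cx.nbd_anchor_world(cx.nbd, aw); e += cx.bond(q, aw); }
          if (i < nl - 1) e += cx.bond(q, &cx.lnk[3*(i+1)]);
          else { cx.sbd_anchor_world(cx.sbd, aw); e += cx.bond(q, aw); }
          for (int j = 0; j < nl; ++j) {
            if (std::abs(j - i) < 2) continue;
            double dx = q[0]-cx.lnk[3*j], dy = q[1]-cx.lnk[3*j+1],
                   dz = q[2]-cx.lnk[3*j+2];
            e += cx.wca(dx*dx + dy*dy + dz*dz);
          }
          for (int j = 0; j < n; ++j) {
            double dx = q[0]-cx.sub[3*j], dy = q[1]-cx.sub[3*j+1],
                   dz = q[2]-cx.sub[3*j+2];
            e += cx.wca(dx*dx + dy*dy + dz*dz);
          }
          e += cx.e_bead_nbd(q, cx.nbd, i == 0 ? cx.nbd_anchor : -1);
          e += cx.e_bead_sbd(q, cx.sbd, i == nl - 1 ? cx.sbd_anchor : -1);
          return e;
        };
        double e0 = e_here(&cx.lnk[3*i]);
        double e1 = e_here(p);
        if (metro(e1 - e0)) {
          ms.acc[5]++;
          for (int d = 0; d < 3; ++d) cx.lnk[3*i+d] = p[d];
        }
        break;
      }
      }
    }
    if (sweep == equil - 1) {
      long acc = 0;
      for (int i = 0; i < 6; ++i) acc += ms.acc[i];
      if (acc == 0)
        stop("no move accepted during equilibration; reduce move sizes");
    }
    if (sweep >= equil && (sweep - equil) % thin == 0) {
      indicators.push_back(cx.nonoverlap_indicator());
      double cw[3];
      cx.nbd.apply(cx.c_nbd, cw);
      cv_nbdz.push_back(cw[2]);
      cx.sbd.apply(cx.c_sbd, cw);
      cv_sbdz.push_back(cw[2]);
      double mz = 1e30;
      for (int i = 0; i < nl; ++i) mz = std::min(mz, cx.lnk[3*i+2]);
      int msb2 = (int)cx.sbd_local.size() / 3;
      for (int i = 0; i < msb2; ++i) {
        double z = cx.sbd.R[6]*cx.sbd_local[3*i] + cx.sbd.R[7]*cx.sbd_local[3*i+1] +
                   cx.sbd.R[8]*cx.sbd_local[3*i+2] + cx.sbd.t[2];
        mz = std::min(mz, z);
      }
      int mnb2 = (int)cx.nbd_local.size() / 3;
      for (int i = 0; i < mnb2; ++i) {
        double z = cx.nbd.R[6]*cx.nbd_local[3*i] + cx.nbd.R[7]*cx.nbd_local[3*i+1] +
                   cx.nbd.R[8]*cx.nbd_local[3*i+2] + cx.nbd.t[2];
        mz = std::min(mz, z);
      }
      cv_minz.push_back(mz);
    }
    if (sweep % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // final world coordinates
  int msb = (int)cx.sbd_local.size() / 3, mnb = (int)cx.nbd_local.size() / 3;
  NumericMatrix subF(n, 3), sbdF(msb, 3), nbdF(mnb, 3), lnkF(nl, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) subF(i, d) = cx.sub[3*i+d];
  double w[3];
  for (int i = 0; i < msb; ++i) {
    cx.sbd.apply(&cx.sbd_local[3*i], w);
    for (int d = 0; d < 3; ++d) sbdF(i, d) = w[d];
  }
  for (int i = 0; i < mnb; ++i) {
    cx.nbd.apply(&cx.nbd_local[3*i], w);
    for (int d = 0; d < 3; ++d) nbdF(i, d) = w[d];
  }
  for (int i = 0; i < nl; ++i)
    for (int d = 0; d < 3; ++d) lnkF(i, d) = cx.lnk[3*i+d];

  NumericVector att(6), acc(6);
  for (int i = 0; i < 6; ++i) { att[i] = (double)ms.att[i];
                                acc[i] = (double)ms.acc[i]; }
  return List::create(_["indicators"] = wrap(indicators),
                      _["attempted"] = att, _["accepted"] = acc,
                      _["sub"] = subF, _["sbd"] = sbdF, _["nbd"] = nbdF,
                      _["linker"] = lnkF,
                      _["nbd_z"] = wrap(cv_nbdz), _["sbd_z"] = wrap(cv_sbdz),
                      _["min_z"] = wrap(cv_minz),
                      _["final_energy"] = cx.full_energy());
}

// ---------------------------------------------------------------------------
// Overdamped Brownian dynamics (cross-check mode). Gradient forces only, so
// the local bending/torsion potentials must be zero. Rigid units get net
// force/torque updates with free-draining mobilities derived from the
// Langevin damping time and the average residue mass.

// [[Rcpp::export(name = ".langevin_complex_cpp")]]
List langevin_complex_cpp(NumericMatrix sub, NumericMatrix nbd,
                          NumericMatrix sbd, NumericMatrix lnk,
                          int nbd_anchor, int sbd_anchor, List ff,
                          double n_steps, double timestep_fs,
                          double damping_fs, int record_every, double seed) {
  Complex cx = make_complex(sub, nbd, sbd, lnk, nbd_anchor - 1,
                            sbd_anchor - 1, ff);
  build_cells(cx);
  if (cx.kbend > 0.0 || cx.ktor > 0.0)
    stop("Langevin mode requires zeroed bending/torsion potentials");
  Rng rng((uint64_t)seed);
  const int n = cx.n, nl = cx.nl;
  // bead diffusion coefficient in A^2/fs: D = kBT * damping / m_residue
  const double kBT_J = 1.380649e-23 * as<double>(ff["temperature"]);
  const double m_res = 110.0 * 1.66053906660e-27; // kg, average residue
  const double D_bead = kBT_J * (damping_fs * 1e-15) / m_res * 1e20 / 1e15;
  const double dt = timestep_fs;
  const double sq = std::sqrt(2.0 * D_bead * dt);

  const int msb = (int)cx.sbd_local.size() / 3;
  const int mnb = (int)cx.nbd_local.size() / 3;
  // unit mobilities (free-draining): translation ~ 1/N, rotation ~ 1/sum r^2
  double c_sbd[3] = {0, 0, 0}, c_nbd[3] = {0, 0, 0};
  for (int i = 0; i < msb; ++i)
    for (int d = 0; d < 3; ++d) c_sbd[d] += cx.sbd_local[3*i+d] / msb;
  for (int i = 0; i < mnb; ++i)
    for (int d = 0; d < 3; ++d) c_nbd[d] += cx.nbd_local[3*i+d] / mnb;
  double I_sbd = 0.0, I_nbd = 0.0;
  for (int i = 0; i < msb; ++i) {
    double r2 = 0;
    for (int d = 0; d < 3; ++d) {
      double x = cx.sbd_local[3*i+d] - c_sbd[d];
      r2 += x * x;
    }
    I_sbd += r2;
  }
  int nclamp = std::min(7, n);
  for (int k = 0; k < nclamp; ++k) {
    double r2 = 0;
    for (int d = 0; d < 3; ++d) {
      double x = cx.clamp_local[3*k+d] - c_sbd[d];
      r2 += x * x;
    }
    I_sbd += r2;
  }
  for (int i = 0; i < mnb; ++i) {
    double r2 = 0;
    for (int d = 0; d < 3; ++d) {
      double x = cx.nbd_local[3*i+d] - c_nbd[d];
      r2 += x * x;
    }
    I_nbd += r2;
  }
  const double Dt_sbd = D_bead / (msb + nclamp), Dt_nbd = D_bead / mnb;
  const double Dr_sbd = D_bead / I_sbd, Dr_nbd = D_bead / I_nbd;

  std::vector<double> f_sub(3 * n), f_lnk(3 * nl);
  std::vector<int> indicators;

  auto add_pair = [&](const double* p, const double* q, double* fp,
                      double* fq) {
    double rx = p[0]-q[0], ry = p[1]-q[1], rz = p[2]-q[2];
    double r2 = rx*rx + ry*ry + rz*rz;
    if (r2 >= cx.rc2) return;
    double sr6 = cx.sig2 / r2; sr6 = sr6 * sr6 * sr6;
    double fmag = 24.0 * cx.eps * (2.0 * sr6 * sr6 - sr6) / r2;
    if (fp) { fp[0] += fmag*rx; fp[1] += fmag*ry; fp[2] += fmag*rz; }
    if (fq) { fq[0] -= fmag*rx; fq[1] -= fmag*ry; fq[2] -= fmag*rz; }
  };
  auto add_bond = [&](const double* p, const double* q, double* fp,
                      double* fq) {
    double rx = p[0]-q[0], ry = p[1]-q[1], rz = p[2]-q[2];
    double r = std::sqrt(rx*rx + ry*ry + rz*rz);
    if (r < 1e-12) return;
    double fmag = -cx.kbond * (r - cx.r0) / r;
    if (fp) { fp[0] += fmag*rx; fp[1] += fmag*ry; fp[2] += fmag*rz; }
    if (fq) { fq[0] -= fmag*rx; fq[1] -= fmag*ry; fq[2] -= fmag*rz; }
  };

  double f_su[3], tq_su[3], f_nu[3], tq_nu[3]; // unit forces/torques (world)
  std::vector<double> sbd_w(3 * msb), nbd_w(3 * mnb);
  double cs_w[3], cn_w[3];

  long total = (long)n_steps;
  for (long step = 0; step < total; ++step) {
    std::fill(f_sub.begin(), f_sub.end(), 0.0);
    std::fill(f_lnk.begin(), f_lnk.end(), 0.0);
    for (int d = 0; d < 3; ++d) {
      f_su[d] = tq_su[d] = f_nu[d] = tq_nu[d] = 0.0;
    }
    for (int i = 0; i < msb; ++i) cx.sbd.apply(&cx.sbd_local[3*i], &sbd_w[3*i]);
    for (int i = 0; i < mnb; ++i) cx.nbd.apply(&cx.nbd_local[3*i], &nbd_w[3*i]);
    cx.sbd.apply(c_sbd, cs_w);
    cx.nbd.apply(c_nbd, cn_w);

    auto unit_acc = [&](double* fu, double* tq, const double* c,
                        const double* at, const double* f) {
      fu[0] += f[0]; fu[1] += f[1]; fu[2] += f[2];
      double ax = at[0]-c[0], ay = at[1]-c[1], az = at[2]-c[2];
      tq[0] += ay*f[2] - az*f[1];
      tq[1] += az*f[0] - ax*f[2];
      tq[2] += ax*f[1] - ay*f[0];
    };

    // substrate bonds (skip clamp-internal; bond 6-7 pulls the SBD unit)
    for (int i = 0; i + 1 < n; ++i) {
      if (i + 1 < 7) continue;
      double fa[3] = {0,0,0}, fb[3] = {0,0,0};
      add_bond(&cx.sub[3*i], &cx.sub[3*(i+1)], fa, fb);
      if (i < 7) unit_acc(f_su, tq_su, cs_w, &cx.sub[3*i], fa);
      else for (int d = 0; d < 3; ++d) f_sub[3*i+d] += fa[d];
      for (int d = 0; d < 3; ++d) f_sub[3*(i+1)+d] += fb[d];
    }
    // substrate-substrate WCA
    for (int i = 0; i + 2 < n; ++i)
      for (int j = i + 2; j < n; ++j) {
        if (i < 7 && j < 7) continue;
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&cx.sub[3*i], &cx.sub[3*j], fa, fb);
        if (i < 7) unit_acc(f_su, tq_su, cs_w, &cx.sub[3*i], fa);
        else for (int d = 0; d < 3; ++d) f_sub[3*i+d] += fa[d];
        for (int d = 0; d < 3; ++d) f_sub[3*j+d] += fb[d];
      }
    // substrate & linker & domain-domain WCA via direct loops over world
    for (int i = 0; i < n; ++i) {
      double* fi = (i < 7) ? nullptr : &f_sub[3*i];
      for (int b = 0; b < mnb; ++b) {
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&cx.sub[3*i], &nbd_w[3*b], fa, fb);
        if (i < 7) unit_acc(f_su, tq_su, cs_w, &cx.sub[3*i], fa);
        else for (int d = 0; d < 3; ++d) fi[d] += fa[d];
        unit_acc(f_nu, tq_nu, cn_w, &nbd_w[3*b], fb);
      }
      if (i >= 7)
        for (int b = 0; b < msb; ++b) {
          double fa[3] = {0,0,0}, fb[3] = {0,0,0};
          add_pair(&cx.sub[3*i], &sbd_w[3*b], fa, fb);
          for (int d = 0; d < 3; ++d) fi[d] += fa[d];
          unit_acc(f_su, tq_su, cs_w, &sbd_w[3*b], fb);
        }
      for (int b = 0; b < nl; ++b) {
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&cx.sub[3*i], &cx.lnk[3*b], fa, fb);
        if (i < 7) unit_acc(f_su, tq_su, cs_w, &cx.sub[3*i], fa);
        else for (int d = 0; d < 3; ++d) fi[d] += fa[d];
        for (int d = 0; d < 3; ++d) f_lnk[3*b+d] += fb[d];
      }
    }
    for (int a = 0; a < msb; ++a)
      for (int b = 0; b < mnb; ++b) {
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&sbd_w[3*a], &nbd_w[3*b], fa, fb);
        unit_acc(f_su, tq_su, cs_w, &sbd_w[3*a], fa);
        unit_acc(f_nu, tq_nu, cn_w, &nbd_w[3*b], fb);
      }
    // linker bonds + anchors + internal WCA + vs domains
    for (int i = 0; i + 1 < nl; ++i)
      add_bond(&cx.lnk[3*i], &cx.lnk[3*(i+1)], &f_lnk[3*i], &f_lnk[3*(i+1)]);
    {
      double fa[3] = {0,0,0}, fb[3] = {0,0,0};
      add_bond(&cx.lnk[0], &nbd_w[3*cx.nbd_anchor], fa, fb);
      for (int d = 0; d < 3; ++d) f_lnk[d] += fa[d];
      unit_acc(f_nu, tq_nu, cn_w, &nbd_w[3*cx.nbd_anchor], fb);
      double fc[3] = {0,0,0}, fd[3] = {0,0,0};
      add_bond(&cx.lnk[3*(nl-1)], &sbd_w[3*cx.sbd_anchor], fc, fd);
      for (int d = 0; d < 3; ++d) f_lnk[3*(nl-1)+d] += fc[d];
      unit_acc(f_su, tq_su, cs_w, &sbd_w[3*cx.sbd_anchor], fd);
    }
    for (int i = 0; i + 2 < nl; ++i)
      for (int j = i + 2; j < nl; ++j)
        add_pair(&cx.lnk[3*i], &cx.lnk[3*j], &f_lnk[3*i], &f_lnk[3*j]);
    for (int i = 0; i < nl; ++i) {
      for (int b = 0; b < mnb; ++b) {
        if (i == 0 && b == cx.nbd_anchor) continue;
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&cx.lnk[3*i], &nbd_w[3*b], fa, fb);
        for (int d = 0; d < 3; ++d) f_lnk[3*i+d] += fa[d];
        unit_acc(f_nu, tq_nu, cn_w, &nbd_w[3*b], fb);
      }
      for (int b = 0; b < msb; ++b) {
        if (i == nl - 1 && b == cx.sbd_anchor) continue;
        double fa[3] = {0,0,0}, fb[3] = {0,0,0};
        add_pair(&cx.lnk[3*i], &sbd_w[3*b], fa, fb);
        for (int d = 0; d < 3; ++d) f_lnk[3*i+d] += fa[d];
        unit_acc(f_su, tq_su, cs_w, &sbd_w[3*b], fb);
      }
    }

    // updates: free substrate beads (reflecting wall), linker, rigid units
    for (int i = 7; i + 1 < n; ++i) {
      for (int d = 0; d < 3; ++d) {
        cx.sub[3*i+d] += D_bead * dt * f_sub[3*i+d] + sq * rng.gauss();
      }
      if (cx.sub[3*i+2] < 0.0) cx.sub[3*i+2] = -cx.sub[3*i+2];
    }
    for (int i = 0; i < nl; ++i)
      for (int d = 0; d < 3; ++d)
        cx.lnk[3*i+d] += D_bead * dt * f_lnk[3*i+d] +
          sq * rng.gauss();
    // SBD unit (carries the clamp; reject the update if it would push a
    // clamped substrate bead through the wall)
    {
      double dw[3], dx[3];
      for (int d = 0; d < 3; ++d) {
        dw[d] = Dr_sbd * dt * tq_su[d] +
          std::sqrt(2.0 * Dr_sbd * dt) * rng.gauss();
        dx[d] = Dt_sbd * dt * f_su[d] +
          std::sqrt(2.0 * Dt_sbd * dt) * rng.gauss();
      }
      double ang = std::sqrt(dw[0]*dw[0] + dw[1]*dw[1] + dw[2]*dw[2]);
      double M[9] = {1,0,0, 0,1,0, 0,0,1};
      if (ang > 1e-14) {
        double u[3] = {dw[0]/ang, dw[1]/ang, dw[2]/ang};
        axis_rot(u, ang, M);
      }
      Pose sbdC = compose_about(cx.sbd, M, cs_w, dx);
      bool legal = true;
      double clampC[21];
      for (int k = 0; k < nclamp; ++k) {
        sbdC.apply(&cx.clamp_local[3*k], clampC + 3*k);
        if (clampC[3*k+2] < 0.0) { legal = false; break; }
      }
      if (legal) {
        cx.sbd = sbdC;
        for (int k = 0; k < nclamp; ++k)
          for (int d = 0; d < 3; ++d) cx.sub[3*k+d] = clampC[3*k+d];
      }
    }
    { // NBD unit
      double dw[3], dx[3];
      for (int d = 0; d < 3; ++d) {
        dw[d] = Dr_nbd * dt * tq_nu[d] +
          std::sqrt(2.0 * Dr_nbd * dt) * rng.gauss();
        dx[d] = Dt_nbd * dt * f_nu[d] +
          std::sqrt(2.0 * Dt_nbd * dt) * rng.gauss();
      }
      double ang = std::sqrt(dw[0]*dw[0] + dw[1]*dw[1] + dw[2]*dw[2]);
      double M[9] = {1,0,0, 0,1,0, 0,0,1};
      if (ang > 1e-14) {
        double u[3] = {dw[0]/ang, dw[1]/ang, dw[2]/ang};
        axis_rot(u, ang, M);
      }
      cx.nbd = compose_about(cx.nbd, M, cn_w, dx);
    }
    if (step % 256 == 0) {
      cx.sbd.orthonormalize();
      cx.nbd.orthonormalize();
    }
    if ((step + 1) % record_every == 0)
      indicators.push_back(cx.nonoverlap_indicator());
    if (step % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix subF(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) subF(i, d) = cx.sub[3*i+d];
  return List::create(_["indicators"] = wrap(indicators), _["sub"] = subF,
                      _["final_energy"] = cx.full_energy());
}
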