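// Molecular dynamics kernels: neighbor lists, pair/bond/wall forces,
// velocity-Verlet with Nose-Hoover or Langevin (BAOAB) thermostats.
// Geometry: periodic in x and y, implicit walls bound z in (0, H).
// All quantities in reduced LJ units (unit mass, unit length, kBT energy).
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
#include <algorithm>
#include <unordered_set>
using namespace Rcpp;

namespace {

struct MDSystem {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> type;        // 0-based type codes
  std::vector<char> mobile;
  std::vector<int> b1, b2;      // bonds, 0-based
  std::unordered_set<long long> bonded;  // Kremer-Grest: bonded pairs are
                                         // excluded from type-pair terms
  double Lx, Ly, H;
  bool pz = false;   // true: periodic in z too (bulk box, no walls)
  int ntype;
  std::vector<double> peps, prc2, pshift;   // ntype*ntype pair tables
  std::vector<double> wlo_eps, wlo_zc, whi_eps, whi_zc;
  std::vector<int> wlo_style, whi_style;  // 0 = 9-3, 1 = 12-6 LJ in z
  double kfene, rfene2, rfene;
  // bias spring on the z center of mass of a bead group
  double bias_k = 0.0, bias_l = 1.0;
  std::vector<int> bias_group;
  // neighbor list state
  double rlist2 = 0.0, rcmax = 0.0, skin = 0.3;
  std::vector<int> nbi, nbj;
  std::vector<double> xr, yr, zr;

  bool is_bonded(int i, int j) const {
    if (i > j) std::swap(i, j);
    return bonded.count((long long)i * n + j) > 0;
  }

  double pair_eps(int a, int b) const { return peps[a * ntype + b]; }
  double pair_rc2(int a, int b) const { return prc2[a * ntype + b]; }
  double pair_shift(int a, int b) const { return pshift[a * ntype + b]; }

  void wrap_dr(double& dx, double& dy, double& dz) const {
    dx -= Lx * std::nearbyint(dx / Lx);
    dy -= Ly * std::nearbyint(dy / Ly);
    if (pz) dz -= H * std::nearbyint(dz / H);
  }

  void build_neighbors() {
    const double rl = rcmax + skin;
    const double rl2 = rl * rl;
    rlist2 = rl2;
    nbi.clear();
    nbj.clear();
    int ncx = std::max(1, (int)std::floor(Lx / rl));
    int ncy = std::max(1, (int)std::floor(Ly / rl));
    int ncz = std::max(1, (int)std::floor(H / rl));
    if (ncx < 3 || ncy < 3 || (pz && ncz < 3)) {
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          if (is_bonded(i, j)) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
          wrap_dr(dx, dy, dz);
          if (dx * dx + dy * dy + dz * dz < rl2) { nbi.push_back(i); nbj.push_back(j); }
        }
      }
    } else {
      const int ncell = ncx * ncy * ncz;
      std::vector<int> head(ncell, -1), nxt(n, -1), cellof(n);
      for (int i = 0; i < n; ++i) {
        double xw = x[i] - Lx * std::floor(x[i] / Lx);
        double yw = y[i] - Ly * std::floor(y[i] / Ly);
        double zw = pz ? (z[i] - H * std::floor(z[i] / H)) : z[i];
        int cx = std::min(ncx - 1, std::max(0, (int)std::floor(xw / Lx * ncx)));
        int cy = std::min(ncy - 1, std::max(0, (int)std::floor(yw / Ly * ncy)));
        int cz = std::min(ncz - 1, std::max(0, (int)std::floor(zw / H * ncz)));
        int c = (cz * ncy + cy) * ncx + cx;
        cellof[i] = c;
        nxt[i] = head[c];
        head[c] = i;
      }
      for (int cz = 0; cz < ncz; ++cz) {
        for (int cy = 0; cy < ncy; ++cy) {
          for (int cx = 0; cx < ncx; ++cx) {
            const int c = (cz * ncy + cy) * ncx + cx;
            for (int oz = -1; oz <= 1; ++oz) {
              int czn = cz + oz;
              if (pz) czn = (czn + ncz) % ncz;
              else if (czn < 0 || czn >= ncz) continue;
              for (int oy = -1; oy <= 1; ++oy) {
                int cyn = (cy + oy + ncy) % ncy;
                for (int ox = -1; ox <= 1; ++ox) {
                  int cxn = (cx + ox + ncx) % ncx;
                  const int cn = (czn * ncy + cyn) * ncx + cxn;
                  if (cn < c) continue;
                  for (int i = head[c]; i >= 0; i = nxt[i]) {
                    for (int j = head[cn]; j >= 0; j = nxt[j]) {
                      if (cn == c && j <= i) continue;
                      if (is_bonded(i, j)) continue;
                      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
                      wrap_dr(dx, dy, dz);
                      if (dx * dx + dy * dy + dz * dz < rl2) {
                        nbi.push_back(i); nbj.push_back(j);
                      }
                    }
                  }
                }
              }
            }
          }
        }
      }
    }
    xr = x; yr = y; zr = z;
  }

  bool needs_rebuild() const {
    const double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      if (!mobile[i]) continue;
      double dx = x[i] - xr[i], dy = y[i] - yr[i], dz = z[i] - zr[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // Returns total potential energy; fills fx,fy,fz (forces on ALL beads,
  // including immobile ones, which the integrator will simply not move).
  double forces(double* epair_out = nullptr, double* ebond_out = nullptr,
                double* ewall_out = nullptr, double* ebias_out = nullptr,
                double* biasz_out = nullptr) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    double epair = 0.0, ebond = 0.0, ewall = 0.0, ebias = 0.0;

    const size_t np = nbi.size();
    for (size_t k = 0; k < np; ++k) {
      const int i = nbi[k], j = nbj[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      wrap_dr(dx, dy, dz);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const int ti = type[i], tj = type[j];
      const double rc2 = pair_rc2(ti, tj);
      if (r2 >= rc2) continue;
      if (r2 < 1e-12)
        stop("bead overlap: beads %d and %d at separation %g", i + 1, j + 1, std::sqrt(r2));
      const double eps = pair_eps(ti, tj);
      const double inv2 = 1.0 / r2;
      const double inv6 = inv2 * inv2 * inv2;
      const double inv12 = inv6 * inv6;
      epair += 4.0 * eps * (inv12 - inv6) - pair_shift(ti, tj);
      const double fscal = 24.0 * eps * (2.0 * inv12 - inv6) * inv2;
      fx[i] += fscal * dx; fx[j] -= fscal * dx;
      fy[i] += fscal * dy; fy[j] -= fscal * dy;
      fz[i] += fscal * dz; fz[j] -= fscal * dz;
    }

    // bonds: FENE plus the purely repulsive WCA core (Kremer-Grest);
    // the tabulated type-pair interaction does not act within a bond
    const double wca_rc2 = std::pow(2.0, 1.0 / 3.0);
    const size_t nb = b1.size();
    for (size_t k = 0; k < nb; ++k) {
      const int i = b1[k], j = b2[k];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      wrap_dr(dx, dy, dz);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rfene2)
        stop("FENE bond overstretched: beads %d-%d at length %g (RFENE = %g)",
             i + 1, j + 1, std::sqrt(r2), rfene);
      const double om = 1.0 - r2 / rfene2;
      ebond += -0.5 * kfene * rfene2 * std::log(om);
      double fscal = -kfene / om;
      if (r2 < wca_rc2) {
        const double inv2 = 1.0 / r2;
        const double inv6 = inv2 * inv2 * inv2;
        const double inv12 = inv6 * inv6;
        ebond += 4.0 * (inv12 - inv6) + 1.0;
        fscal += 24.0 * (2.0 * inv12 - inv6) * inv2;
      }
      fx[i] += fscal * dx; fx[j] -= fscal * dx;
      fy[i] += fscal * dy; fy[j] -= fscal * dy;
      fz[i] += fscal * dz; fz[j] -= fscal * dz;
    }

    // wall energy at distance zz from the plane; fw = -dW/dzz (along +zz)
    auto wall_ef = [](double zz, double eps, double zc, int style,
                      double& e, double& fw) {
      if (style == 0) {  // 9-3
        const double iz3 = 1.0 / (zz * zz * zz);
        const double iz9 = iz3 * iz3 * iz3;
        const double izc3 = 1.0 / (zc * zc * zc);
        const double izc9 = izc3 * izc3 * izc3;
        e = eps * ((2.0 / 15.0) * iz9 - iz3 - (2.0 / 15.0) * izc9 + izc3);
        fw = eps * ((6.0 / 5.0) * iz9 / zz - 3.0 * iz3 / zz);
      } else {           // 12-6 LJ in the wall-normal coordinate
        const double iz6 = 1.0 / std::pow(zz, 6.0);
        const double iz12 = iz6 * iz6;
        const double izc6 = 1.0 / std::pow(zc, 6.0);
        e = 4.0 * eps * (iz12 - iz6 - izc6 * izc6 + izc6);
        fw = 24.0 * eps * (2.0 * iz12 - iz6) / zz;
      }
    };
    for (int i = 0; pz ? false : (i < n); ++i) {
      const int t = type[i];
      const double elo = wlo_eps[t], ehi = whi_eps[t];
      if (elo > 0.0) {
        const double zz = z[i];
        if (zz <= 0.0) {
          if (mobile[i])
            stop("bead %d escaped below the lower wall (z = %g)", i + 1, zz);
        } else if (zz < wlo_zc[t]) {
          double e, fw;
          wall_ef(zz, elo, wlo_zc[t], wlo_style[t], e, fw);
          ewall += e;
          fz[i] += fw;
        }
      }
      if (ehi > 0.0) {
        const double zz = H - z[i];
        if (zz <= 0.0) {
          if (mobile[i])
            stop("bead %d escaped above the upper wall (z = %g)", i + 1, z[i]);
        } else if (zz < whi_zc[t]) {
          double e, fw;
          wall_ef(zz, ehi, whi_zc[t], whi_style[t], e, fw);
          ewall += e;
          fz[i] -= fw;
        }
      }
    }

    double zcom = NA_REAL;
    if (bias_k > 0.0 && !bias_group.empty()) {
      zcom = 0.0;
      for (int i : bias_group) zcom += z[i];
      zcom /= (double)bias_group.size();
      const double dzc = zcom - bias_l;
      ebias = 0.5 * bias_k * dzc * dzc;
      const double f = -bias_k * dzc / (double)bias_group.size();
      for (int i : bias_group) fz[i] += f;
    } else if (!bias_group.empty()) {
      zcom = 0.0;
      for (int i : bias_group) zcom += z[i];
      zcom /= (double)bias_group.size();
    }

    if (epair_out) *epair_out = epair;
    if (ebond_out) *ebond_out = ebond;
    if (ewall_out) *ewall_out = ewall;
    if (ebias_out) *ebias_out = ebias;
    if (biasz_out) *biasz_out = zcom;
    return epair + ebond + ewall + ebias;
  }

  double kinetic() const {
    double k = 0.0;
    for (int i = 0; i < n; ++i)
      if (mobile[i]) k += vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i];
    return 0.5 * k;  // unit masses
  }

  int n_mobile() const {
    int m = 0;
    for (int i = 0; i < n; ++i) if (mobile[i]) ++m;
    return m;
  }
};

MDSystem make_system(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                     LogicalVector mobile, IntegerMatrix bonds, NumericVector box,
                     NumericMatrix pair_eps, NumericMatrix pair_rc,
                     NumericMatrix wall_lo, NumericMatrix wall_hi,
                     double kfene, double rfene, double skin) {
  MDSystem s;
  s.n = pos.nrow();
  s.Lx = box[0]; s.Ly = box[1]; s.H = box[2];
  s.pz = box.size() > 3 && box[3] != 0;
  s.ntype = pair_eps.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  s.vx.resize(s.n); s.vy.resize(s.n); s.vz.resize(s.n);
  s.fx.resize(s.n); s.fy.resize(s.n); s.fz.resize(s.n);
  s.type.resize(s.n); s.mobile.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
    s.vx[i] = vel(i, 0); s.vy[i] = vel(i, 1); s.vz[i] = vel(i, 2);
    s.type[i] = type[i] - 1;
    if (s.type[i] < 0 || s.type[i] >= s.ntype) stop("bead %d has invalid type", i + 1);
    s.mobile[i] = (char)(mobile[i] ? 1 : 0);
  }
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    s.b1.push_back(i);
    s.b2.push_back(j);
    if (i > j) std::swap(i, j);
    s.bonded.insert((long long)i * s.n + j);
  }
  const int nt = s.ntype;
  s.peps.resize(nt * nt); s.prc2.resize(nt * nt); s.pshift.resize(nt * nt);
  for (int a = 0; a < nt; ++a) {
    for (int b = 0; b < nt; ++b) {
      const double eps = pair_eps(a, b), rc = pair_rc(a, b);
      s.peps[a * nt + b] = eps;
      s.prc2[a * nt + b] = rc * rc;
      const double i6 = 1.0 / std::pow(rc, 6.0);
      s.pshift[a * nt + b] = 4.0 * eps * (i6 * i6 - i6);
    }
  }
  s.wlo_eps.resize(nt); s.wlo_zc.resize(nt); s.whi_eps.resize(nt); s.whi_zc.resize(nt);
  s.wlo_style.resize(nt); s.whi_style.resize(nt);
  for (int a = 0; a < nt; ++a) {
    s.wlo_eps[a] = wall_lo(a, 0); s.wlo_zc[a] = wall_lo(a, 1);
    s.whi_eps[a] = wall_hi(a, 0); s.whi_zc[a] = wall_hi(a, 1);
    s.wlo_style[a] = (wall_lo.ncol() > 2) ? (int)wall_lo(a, 2) : 0;
    s.whi_style[a] = (wall_hi.ncol() > 2) ? (int)wall_hi(a, 2) : 0;
  }
  s.kfene = kfene; s.rfene = rfene; s.rfene2 = rfene * rfene;
  s.skin = skin;
  // largest cutoff among type pairs actually present
  std::vector<char> present(nt, 0);
  for (int i = 0; i < s.n; ++i) present[s.type[i]] = 1;
  double rcmax = 0.0;
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b)
      if (present[a] && present[b]) rcmax = std::max(rcmax, pair_rc(a, b));
  s.rcmax = rcmax;  // bonds are iterated over the bond list, not the neighbor list
  return s;
}

}  // namespace

// Single-point force and energy evaluation.
// [[Rcpp::export]]
List forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                LogicalVector mobile, IntegerMatrix bonds, NumericVector box,
                NumericMatrix pair_eps, NumericMatrix pair_rc,
                NumericMatrix wall_lo, NumericMatrix wall_hi,
                double kfene, double rfene,
                double bias_k, double bias_l, IntegerVector bias_group) {
  MDSystem s = make_system(pos, vel, type, mobile, bonds, box,
                           pair_eps, pair_rc, wall_lo, wall_hi, kfene, rfene, 0.3);
  s.bias_k = bias_k; s.bias_l = bias_l;
  for (int i = 0; i < bias_group.size(); ++i) s.bias_group.push_back(bias_group[i] - 1);
  s.build_neighbors();
  double ep, eb, ew, ebi, bz;
  const double etot = s.forces(&ep, &eb, &ew, &ebi, &bz);
  NumericMatrix f(s.n, 3);
  for (int i = 0; i < s.n; ++i) { f(i, 0) = s.fx[i]; f(i, 1) = s.fy[i]; f(i, 2) = s.fz[i]; }
  return List::create(_["forces"] = f, _["energy"] = etot, _["epair"] = ep,
                      _["ebond"] = eb, _["ewall"] = ew, _["ebias"] = ebi,
                      _["bias_z"] = bz);
}

// MD driver. thermostat: 0 = none (NVE), 1 = Nose-Hoover, 2 = Langevin (BAOAB).
// [[Rcpp::export]]
List md_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                LogicalVector mobile, IntegerMatrix bonds, NumericVector box,
                NumericMatrix pair_eps, NumericMatrix pair_rc,
                NumericMatrix wall_lo, NumericMatrix wall_hi,
                double kfene, double rfene,
                int nsteps, double dt, int thermostat, double Tset, double damp,
                double skin, int sample_every, IntegerVector record_idx,
                double bias_k, double bias_l, IntegerVector bias_group,
                int seed, double xi0, double vmax) {
  MDSystem s = make_system(pos, vel, type, mobile, bonds, box,
                           pair_eps, pair_rc, wall_lo, wall_hi, kfene, rfene, skin);
  s.bias_k = bias_k; s.bias_l = bias_l;
  for (int i = 0; i < bias_group.size(); ++i) s.bias_group.push_back(bias_group[i] - 1);

  const int nmob = s.n_mobile();
  const double g = 3.0 * nmob;                  // translational DOF of mobile beads
  const double Q = g * std::max(Tset, 1e-12) * damp * damp;  // Nose-Hoover mass
  double xi = xi0;

  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = std::exp(-dt / damp);       // Langevin OU decay over a full step
  const double c2 = std::sqrt(Tset * (1.0 - c1 * c1));

  const int nrec = record_idx.size();
  std::vector<int> rid(nrec);
  for (int i = 0; i < nrec; ++i) rid[i] = record_idx[i] - 1;
  const int nframes = nsteps / sample_every + 1;
  NumericVector frames(Dimension(nrec, 3, nframes));
  NumericMatrix thermo(nframes, 7);  // time, T, KE, PE, Etot, bias_z, xi
  colnames(thermo) = CharacterVector::create("time", "temp", "ke", "pe", "etot",
                                             "bias_z", "xi");
  NumericVector times(nframes);

  s.build_neighbors();
  double ep, eb, ew, ebi, bz;
  double pe = s.forces(&ep, &eb, &ew, &ebi, &bz);

  int iframe = 0;
  auto record = [&](int step) {
    for (int i = 0; i < nrec; ++i) {
      frames[iframe * 3 * nrec + 0 * nrec + i] = s.x[rid[i]];
      frames[iframe * 3 * nrec + 1 * nrec + i] = s.y[rid[i]];
      frames[iframe * 3 * nrec + 2 * nrec + i] = s.z[rid[i]];
    }
    const double ke = s.kinetic();
    times[iframe] = step * dt;
    thermo(iframe, 0) = step * dt;
    thermo(iframe, 1) = (nmob > 0) ? 2.0 * ke / g : 0.0;
    thermo(iframe, 2) = ke;
    thermo(iframe, 3) = pe;
    thermo(iframe, 4) = ke + pe;
    thermo(iframe, 5) = bz;
    thermo(iframe, 6) = xi;
    ++iframe;
  };
  record(0);

  const double half = 0.5 * dt;
  for (int step = 1; step <= nsteps; ++step) {
    if (thermostat == 1) {  // Nose-Hoover half update (quarter-scale-quarter)
      double K = s.kinetic();
      xi += 0.25 * dt * (2.0 * K - g * Tset) / Q;
      const double sc = std::exp(-half * xi);
      for (int i = 0; i < s.n; ++i)
        if (s.mobile[i]) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
      K *= sc * sc;
      xi += 0.25 * dt * (2.0 * K - g * Tset) / Q;
    }

    for (int i = 0; i < s.n; ++i) {
      if (!s.mobile[i]) continue;
      s.vx[i] += half * s.fx[i];
      s.vy[i] += half * s.fy[i];
      s.vz[i] += half * s.fz[i];
    }

    if (thermostat == 2) {
      // BAOAB: drift half, OU kick, drift half
      for (int i = 0; i < s.n; ++i) {
        if (!s.mobile[i]) continue;
        s.x[i] += half * s.vx[i]; s.y[i] += half * s.vy[i]; s.z[i] += half * s.vz[i];
      }
      for (int i = 0; i < s.n; ++i) {
        if (!s.mobile[i]) continue;
        s.vx[i] = c1 * s.vx[i] + c2 * gauss(rng);
        s.vy[i] = c1 * s.vy[i] + c2 * gauss(rng);
        s.vz[i] = c1 * s.vz[i] + c2 * gauss(rng);
      }
      for (int i = 0; i < s.n; ++i) {
        if (!s.mobile[i]) continue;
        s.x[i] += half * s.vx[i]; s.y[i] += half * s.vy[i]; s.z[i] += half * s.vz[i];
      }
    } else {
      for (int i = 0; i < s.n; ++i) {
        if (!s.mobile[i]) continue;
        s.x[i] += dt * s.vx[i]; s.y[i] += dt * s.vy[i]; s.z[i] += dt * s.vz[i];
      }
    }

    if (s.needs_rebuild()) s.build_neighbors();
    pe = s.forces(&ep, &eb, &ew, &ebi, &bz);

    for (int i = 0; i < s.n; ++i) {
      if (!s.mobile[i]) continue;
      s.vx[i] += half * s.fx[i];
      s.vy[i] += half * s.fy[i];
      s.vz[i] += half * s.fz[i];
    }

    if (thermostat == 1) {
      double K = s.kinetic();
      xi += 0.25 * dt * (2.0 * K - g * Tset) / Q;
      const double sc = std::exp(-half * xi);
      for (int i = 0; i < s.n; ++i)
        if (s.mobile[i]) { s.vx[i] *= sc; s.vy[i] *= sc; s.vz[i] *= sc; }
      K *= sc * sc;
      xi += 0.25 * dt * (2.0 * K - g * Tset) / Q;
    }

    for (int i = 0; i < s.n; ++i) {
      if (!s.mobile[i]) continue;
      if (std::fabs(s.vx[i]) > vmax || std::fabs(s.vy[i]) > vmax ||
          std::fabs(s.vz[i]) > vmax)
        stop("numerical blow-up at step %d: bead %d has |v| > %g", step, i + 1, vmax);
    }

    if (step % sample_every == 0) record(step);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix pos_out(s.n, 3), vel_out(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    pos_out(i, 0) = s.x[i]; pos_out(i, 1) = s.y[i]; pos_out(i, 2) = s.z[i];
    vel_out(i, 0) = s.vx[i]; vel_out(i, 1) = s.vy[i]; vel_out(i, 2) = s.vz[i];
  }
  return List::create(_["frames"] = frames, _["times"] = times, _["thermo"] = thermo,
                      _["pos"] = pos_out, _["vel"] = vel_out, _["xi"] = xi,
                      _["record_idx"] = record_idx);
}

// Water insertion on a jittered simple-cubic lattice (random sequential
// insertion jams well below liquid densities). Sites clashing with existing
// beads (distance < mindist, xy periodic) are discarded; n_add of the
// remaining sites are chosen at random. The lattice spacing shrinks toward
// mindist until enough free sites exist; if even the tightest admissible
// lattice cannot host n_add beads the target density is unreachable.
// [[Rcpp::export]]
NumericMatrix fill_water_cpp(NumericMatrix existing, NumericVector box, int n_add,
                             double zmin, double zmax, double mindist, int seed,
                             double max_tries_per_bead) {
  (void)max_tries_per_bead;
  const double Lx = box[0], Ly = box[1], H = box[2];
  const bool pz = box.size() > 3 && box[3] != 0;
  const double md2 = mindist * mindist;
  const double depth = zmax - zmin;
  if (depth <= 0) stop("fill_water: empty z range");
  const double vavail = Lx * Ly * depth;
  const int ne = existing.nrow();
  std::mt19937_64 rng((uint64_t)seed);

  // cell grid over existing beads for clash checks
  const double cell = std::max(mindist, 1e-3);
  const int ncx = std::max(1, (int)std::floor(Lx / cell));
  const int ncy = std::max(1, (int)std::floor(Ly / cell));
  const int ncz = std::max(1, (int)std::floor(H / cell));
  std::vector<std::vector<int>> grid(ncx * ncy * ncz);
  for (int i = 0; i < ne; ++i) {
    double xw = existing(i, 0) - Lx * std::floor(existing(i, 0) / Lx);
    double yw = existing(i, 1) - Ly * std::floor(existing(i, 1) / Ly);
    double zw = pz ? (existing(i, 2) - H * std::floor(existing(i, 2) / H))
                   : existing(i, 2);
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor(xw / Lx * ncx)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor(yw / Ly * ncy)));
    int cz = std::min(ncz - 1, std::max(0, (int)std::floor(zw / H * ncz)));
    grid[(cz * ncy + cy) * ncx + cx].push_back(i);
  }
  auto clash = [&](double px, double py, double zq) {
    double xw = px - Lx * std::floor(px / Lx);
    double yw = py - Ly * std::floor(py / Ly);
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor(xw / Lx * ncx)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor(yw / Ly * ncy)));
    int cz = std::min(ncz - 1, std::max(0, (int)std::floor(zq / H * ncz)));
    for (int oz = -1; oz <= 1; ++oz) {
      int czn = cz + oz;
      if (pz) czn = (czn + ncz) % ncz;
      else if (czn < 0 || czn >= ncz) continue;
      for (int oy = -1; oy <= 1; ++oy) {
        int cyn = (cy + oy + ncy) % ncy;
        for (int ox = -1; ox <= 1; ++ox) {
          int cxn = (cx + ox + ncx) % ncx;
          for (int idx : grid[(czn * ncy + cyn) * ncx + cxn]) {
            double dx = px - existing(idx, 0), dy = py - existing(idx, 1),
                   dz = zq - existing(idx, 2);
            dx -= Lx * std::nearbyint(dx / Lx);
            dy -= Ly * std::nearbyint(dy / Ly);
            if (pz) dz -= H * std::nearbyint(dz / H);
            if (dx * dx + dy * dy + dz * dz < md2) return true;
          }
        }
      }
    }
    return false;
  };

  NumericMatrix out(n_add, 3);
  if (n_add == 0) return out;
  double slack = 1.05;
  for (int attempt = 0; ; ++attempt) {
    double a = std::cbrt(vavail / (slack * (double)n_add));
    bool last = false;
    if (a < mindist) { a = mindist; last = true; }
    const int nx = std::max(1, (int)std::floor(Lx / a));
    const int ny = std::max(1, (int)std::floor(Ly / a));
    const int nz = std::max(1, (int)std::floor(depth / a));
    const double ax = Lx / nx, ay = Ly / ny, az = depth / nz;
    // flooring guarantees ax, ay, az >= a >= mindist
    const double amin = std::min({ax, ay, az});
    const double jit =
        std::max(0.0, std::min(0.2, 0.45 * (amin - mindist) / std::sqrt(3.0)));
    std::uniform_real_distribution<double> uj(-jit, jit);
    std::vector<double> sx, sy, sz;
    sx.reserve((size_t)nx * ny * nz);
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          double px = (ix + 0.5) * ax + uj(rng);
          double py = (iy + 0.5) * ay + uj(rng);
          double zq = zmin + (iz + 0.5) * az + uj(rng);
          zq = std::min(std::max(zq, zmin), zmax);
          if (ne > 0 && clash(px, py, zq)) continue;
          sx.push_back(px); sy.push_back(py); sz.push_back(zq);
        }
    if ((int)sx.size() >= n_add) {
      std::vector<int> idx(sx.size());
      for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
      std::shuffle(idx.begin(), idx.end(), rng);
      for (int k = 0; k < n_add; ++k) {
        out(k, 0) = sx[idx[k]]; out(k, 1) = sy[idx[k]]; out(k, 2) = sz[idx[k]];
      }
      return out;
    }
    if (last || attempt >= 8)
      stop("fill_water: target density too high for this box "
           "(%d free lattice sites for %d beads)", (int)sx.size(), n_add);
    slack *= 1.2;
  }
}

// Minimum pairwise distance under box periodicity (construction-time check).
// [[Rcpp::export]]
double min_pair_dist_cpp(NumericMatrix pos, NumericVector box) {
  const int n = pos.nrow();
  const double Lx = box[0], Ly = box[1];
  const bool pz = box.size() > 3 && box[3] != 0;
  double best = R_PosInf;
  // coarse cell grid keeps this O(n) for dense systems
  const double cell = 1.5;
  const double H = box[2];
  const int ncx = std::max(1, (int)std::floor(Lx / cell));
  const int ncy = std::max(1, (int)std::floor(Ly / cell));
  const int ncz = std::max(1, (int)std::floor((H > 0 ? H : 1.0) / cell));
  if (ncx < 3 || ncy < 3 || (pz && ncz < 3)) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
               dz = pos(i, 2) - pos(j, 2);
        dx -= Lx * std::nearbyint(dx / Lx);
        dy -= Ly * std::nearbyint(dy / Ly);
        if (pz) dz -= H * std::nearbyint(dz / H);
        best = std::min(best, dx * dx + dy * dy + dz * dz);
      }
    }
    return std::sqrt(best);
  }
  std::vector<std::vector<int>> grid(ncx * ncy * ncz);
  for (int i = 0; i < n; ++i) {
    double xw = pos(i, 0) - Lx * std::floor(pos(i, 0) / Lx);
    double yw = pos(i, 1) - Ly * std::floor(pos(i, 1) / Ly);
    double zw = pz ? (pos(i, 2) - H * std::floor(pos(i, 2) / H)) : pos(i, 2);
    int cx = std::min(ncx - 1, std::max(0, (int)std::floor(xw / Lx * ncx)));
    int cy = std::min(ncy - 1, std::max(0, (int)std::floor(yw / Ly * ncy)));
    int cz = std::min(ncz - 1, std::max(0, (int)std::floor(zw / H * ncz)));
    grid[(cz * ncy + cy) * ncx + cx].push_back(i);
  }
  for (int cz = 0; cz < ncz; ++cz)
    for (int cy = 0; cy < ncy; ++cy)
      for (int cx = 0; cx < ncx; ++cx) {
        const int c = (cz * ncy + cy) * ncx + cx;
        for (int oz = -1; oz <= 1; ++oz) {
          int czn = cz + oz;
          if (pz) czn = (czn + ncz) % ncz;
          else if (czn < 0 || czn >= ncz) continue;
          for (int oy = -1; oy <= 1; ++oy) {
            int cyn = (cy + oy + ncy) % ncy;
            for (int ox = -1; ox <= 1; ++ox) {
              int cxn = (cx + ox + ncx) % ncx;
              const int cn = (czn * ncy + cyn) * ncx + cxn;
              if (cn < c) continue;
              for (int i : grid[c])
                for (int j : grid[cn]) {
                  if (cn == c && j <= i) continue;
                  double dx = pos(i, 0) - pos(j, 0), dy = pos(i, 1) - pos(j, 1),
                         dz = pos(i, 2) - pos(j, 2);
                  dx -= Lx * std::nearbyint(dx / Lx);
                  dy -= Ly * std::nearbyint(dy / Ly);
                  if (pz) dz -= H * std::nearbyint(dz / H);
                  best = std::min(best, dx * dx + dy * dy + dz * dz);
                }
            }
          }
        }
      }
  return std::sqrt(best);
}
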