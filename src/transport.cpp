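// Monte Carlo keV-photon transport through a voxel phantom inside a simple
// room model (air + concrete wall shell + low-density table slab).
//
// - Free paths inside the phantom grid: Woodcock (delta) tracking with an
//   energy-dependent majorant over the materials present.
// - Homogeneous regions (room air, walls, table): analytic exponential
//   sampling with distance-to-boundary handling.
// - Interactions: photoelectric (local deposition), Compton (Klein-Nishina
//   via Kahn's rejection method, deposit E - E'), optional coherent
//   scatter. With coherent scatter disabled the coherent part of the
//   attenuation coefficient is excluded consistently.
// - Scoring: analog energy deposition in skin-mask voxels (kerma
//   approximation: transferred energy deposited locally) and a
//   track-length fluence estimator for air kerma on a coarse room lattice.
// - Uncertainty: batch statistics (relative standard error of the batch
//   mean per voxel).
// - RNG: self-contained xoshiro256++ seeded via splitmix64, so runs are
//   bit-reproducible for a given seed on any platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static const double KEV2J = 1.602176634e-16;

// ---------------------------------------------------------------- RNG
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; i++) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double u() { return (next() >> 11) * 0x1.0p-53; }
};

// ------------------------------------------------- material data + cache
struct MatData {
  int ne, nm;
  std::vector<double> logE, logMu, logMutr, fPe, fCo;
  double emin, emax;
  void init(NumericVector eg, NumericMatrix mu, NumericMatrix mutr,
            NumericMatrix fpe, NumericMatrix fco) {
    ne = eg.size(); nm = mu.ncol();
    logE.resize(ne); logMu.resize(ne * nm); logMutr.resize(ne * nm);
    fPe.resize(ne * nm); fCo.resize(ne * nm);
    for (int i = 0; i < ne; i++) logE[i] = std::log(eg[i]);
    for (int m = 0; m < nm; m++)
      for (int i = 0; i < ne; i++) {
        logMu[m * ne + i] = std::log(mu(i, m));
        logMutr[m * ne + i] = std::log(mutr(i, m));
        fPe[m * ne + i] = fpe(i, m);
        fCo[m * ne + i] = fco(i, m);
      }
    emin = eg[0]; emax = eg[ne - 1];
  }
  // index + fraction for log-energy interpolation (clamped)
  void locate(double ekev, int &i0, double &w) const {
    double le = std::log(std::min(std::max(ekev, emin), emax));
    int lo = 0, hi = ne - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2;
      if (logE[mid] <= le) lo = mid; else hi = mid; }
    i0 = lo;
    w = (le - logE[lo]) / (logE[lo + 1] - logE[lo]);
  }
  double muRho(int mat, int i0, double w) const {
    const double *t = &logMu[mat * ne];
    return std::exp(t[i0] * (1 - w) + t[i0 + 1] * w);
  }
  double mutrRho(int mat, int i0, double w) const {
    const double *t = &logMutr[mat * ne];
    return std::exp(t[i0] * (1 - w) + t[i0 + 1] * w);
  }
  double fpe(int mat, int i0, double w) const {
    const double *t = &fPe[mat * ne];
    return t[i0] * (1 - w) + t[i0 + 1] * w;
  }
  double fco(int mat, int i0, double w) const {
    const double *t = &fCo[mat * ne];
    return t[i0] * (1 - w) + t[i0 + 1] * w;
  }
};

// ------------------------------------------------------------- geometry
struct Box {
  double lo[3], hi[3];
  bool contains(const double *p) const {
    for (int a = 0; a < 3; a++) if (p[a] < lo[a] || p[a] >= hi[a]) return false;
    return true;
  }
  // slab intersection; returns false if the ray misses
  bool intersect(const double *p, const double *d, double &t0, double &t1) const {
    t0 = -1e300; t1 = 1e300;
    for (int a = 0; a < 3; a++) {
      if (std::fabs(d[a]) < 1e-15) {
        if (p[a] < lo[a] || p[a] >= hi[a]) return false;
      } else {
        double ta = (lo[a] - p[a]) / d[a], tb = (hi[a] - p[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    return t1 > t0;
  }
};

struct Engine {
  MatData mat;
  // phantom
  int pd[3]; double psp[3], por[3]; Box pbox;
  const int *matId; const double *dens; const int *skin;
  double maxRho[8]; bool matPresent[8];
  // room
  Box inner, outer, table;
  bool hasWalls, hasTable;
  int wallMat, tableMat;
  double wallDens, tableDens, airDens;
  // scoring lattices
  bool scoreSkin, scoreAir;
  Box abox; int ad[3]; double asp[3], aor[3];
  std::vector<double> skinBuf, airBuf;
  // physics flags
  bool rayleigh; double cutoff;
  // tallies
  double emitted, deposited, escaped;

  // per-energy cache
  double cE = -1;
  double cMuAir, cMuWall, cMuTable, cMuMaj, cMutrAir;
  int cI0; double cW;

  double effFrac(int m, int i0, double w) const {
    return rayleigh ? 1.0 : mat.fpe(m, i0, w) + mat.fco(m, i0, w);
  }
  void setEnergy(double E) {
    if (E == cE) return;
    cE = E;
    mat.locate(E, cI0, cW);
    cMuAir = mat.muRho(0, cI0, cW) * airDens * effFrac(0, cI0, cW);
    cMutrAir = mat.mutrRho(0, cI0, cW);
    cMuWall = hasWalls ?
      mat.muRho(wallMat, cI0, cW) * wallDens * effFrac(wallMat, cI0, cW) : 0;
    cMuTable = hasTable ?
      mat.muRho(tableMat, cI0, cW) * tableDens * effFrac(tableMat, cI0, cW) : 0;
    cMuMaj = 0;
    for (int m = 0; m < mat.nm; m++)
      if (matPresent[m]) {
        double v = mat.muRho(m, cI0, cW) * maxRho[m] * effFrac(m, cI0, cW);
        if (v > cMuMaj) cMuMaj = v;
      }
  }

  int voxelAt(const double *p) const {
    int idx[3];
    for (int a = 0; a < 3; a++) {
      idx[a] = (int)std::floor((p[a] - por[a]) / psp[a]);
      if (idx[a] < 0 || idx[a] >= pd[a]) return -1;
    }
    return idx[0] + pd[0] * (idx[1] + pd[1] * idx[2]);
  }

  // track-length scoring of a segment (air kerma lattice), lengths in cm
  void scoreSegment(const double *p, const double *d, double L, double E) {
    if (!scoreAir || L <= 0) return;
    double t0, t1;
    if (!abox.intersect(p, d, t0, t1)) return;
    t0 = std::max(t0, 0.0); t1 = std::min(t1, L);
    if (t1 <= t0) return;
    double factor = E * KEV2J * cMutrAir * 1000.0 /
      (asp[0] * asp[1] * asp[2]);
    // Amanatides-Woo traversal
    double q[3]; int idx[3], step[3]; double tMax[3], tDelta[3];
    double t = t0 + 1e-9;
    for (int a = 0; a < 3; a++) q[a] = p[a] + t * d[a];
    for (int a = 0; a < 3; a++) {
      idx[a] = (int)std::floor((q[a] - aor[a]) / asp[a]);
      if (idx[a] < 0) idx[a] = 0;
      if (idx[a] >= ad[a]) idx[a] = ad[a] - 1;
      if (d[a] > 1e-15) {
        step[a] = 1;
        tMax[a] = t + (aor[a] + (idx[a] + 1) * asp[a] - q[a]) / d[a];
        tDelta[a] = asp[a] / d[a];
      } else if (d[a] < -1e-15) {
        step[a] = -1;
        tMax[a] = t + (aor[a] + idx[a] * asp[a] - q[a]) / d[a];
        tDelta[a] = -asp[a] / d[a];
      } else { step[a] = 0; tMax[a] = 1e300; tDelta[a] = 1e300; }
    }
    while (t < t1) {
      int ax = 0;
      if (tMax[1] < tMax[ax]) ax = 1;
      if (tMax[2] < tMax[ax]) ax = 2;
      double tNext = std::min(tMax[ax], t1);
      airBuf[idx[0] + ad[0] * (idx[1] + ad[1] * idx[2])] +=
        factor * (tNext - t);
      t = tNext;
      if (tMax[ax] >= t1) break;
      idx[ax] += step[ax];
      if (idx[ax] < 0 || idx[ax] >= ad[ax]) break;
      tMax[ax] += tDelta[ax];
    }
  }

  void deposit(double E, const double *p) {
    (void)p;
    deposited += E;
  }

  // track-length collision-kerma estimator on the phantom grid:
  // dose += E * (mu_tr/rho)(cell) * L / V per unit mass, scored in
  // skin-mask voxels only (Gy per photon after batch normalization)
  void scoreSkinSegment(const double *p, const double *d, double L,
                        double E) {
    if (!scoreSkin || L <= 0) return;
    double t0, t1;
    if (!pbox.intersect(p, d, t0, t1)) return;
    t0 = std::max(t0, 0.0); t1 = std::min(t1, L);
    if (t1 <= t0) return;
    double base = E * KEV2J * 1000.0 / (psp[0] * psp[1] * psp[2]);
    double q[3]; int idx[3], step[3]; double tMax[3], tDelta[3];
    double t = t0 + 1e-9;
    for (int a = 0; a < 3; a++) q[a] = p[a] + t * d[a];
    for (int a = 0; a < 3; a++) {
      idx[a] = (int)std::floor((q[a] - por[a]) / psp[a]);
      if (idx[a] < 0) idx[a] = 0;
      if (idx[a] >= pd[a]) idx[a] = pd[a] - 1;
      if (d[a] > 1e-15) {
        step[a] = 1;
        tMax[a] = t + (por[a] + (idx[a] + 1) * psp[a] - q[a]) / d[a];
        tDelta[a] = psp[a] / d[a];
      } else if (d[a] < -1e-15) {
        step[a] = -1;
        tMax[a] = t + (por[a] + idx[a] * psp[a] - q[a]) / d[a];
        tDelta[a] = -psp[a] / d[a];
      } else { step[a] = 0; tMax[a] = 1e300; tDelta[a] = 1e300; }
    }
    while (t < t1) {
      int ax = 0;
      if (tMax[1] < tMax[ax]) ax = 1;
      if (tMax[2] < tMax[ax]) ax = 2;
      double tNext = std::min(tMax[ax], t1);
      R_xlen_t v = idx[0] + (R_xlen_t)pd[0] * (idx[1] + (R_xlen_t)pd[1] * idx[2]);
      if (skin[v]) {
        int m = matId[v] - 1;
        skinBuf[v] += base * mat.mutrRho(m, cI0, cW) * (tNext - t);
      }
      t = tNext;
      if (tMax[ax] >= t1) break;
      idx[ax] += step[ax];
      if (idx[ax] < 0 || idx[ax] >= pd[ax]) break;
      tMax[ax] += tDelta[ax];
    }
  }

  // Kahn's rejection method for the Klein-Nishina distribution
  void knSample(double E, Rng &rng, double &Eout, double &cost) {
    double a = E / 510.998950;
    for (;;) {
      double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
      double eta;
      if (r1 <= (1 + 2 * a) / (9 + 2 * a)) {
        eta = 1 + 2 * a * r2;
        if (r3 <= 4 * (eta - 1) / (eta * eta)) {
          cost = 1 - (eta - 1) / a; Eout = E / eta; return;
        }
      } else {
        eta = (1 + 2 * a) / (1 + 2 * a * r2);
        double c = 1 - (eta - 1) / a;
        if (r3 <= 0.5 * (c * c + 1 / eta)) { cost = c; Eout = E / eta; return; }
      }
    }
  }

  static void rotate(double *d, double cost, double phi) {
    double sint = std::sqrt(std::max(0.0, 1 - cost * cost));
    double cphi = std::cos(phi), sphi = std::sin(phi);
    double ux = d[0], uy = d[1], uz = d[2];
    if (std::fabs(uz) < 0.999999) {
      double den = std::sqrt(1 - uz * uz);
      d[0] = ux * cost + sint * (ux * uz * cphi - uy * sphi) / den;
      d[1] = uy * cost + sint * (uy * uz * cphi + ux * sphi) / den;
      d[2] = uz * cost - sint * den * cphi;
    } else {
      d[0] = sint * cphi; d[1] = sint * sphi;
      d[2] = (uz > 0 ? cost : -cost);
    }
    double n = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    d[0] /= n; d[1] /= n; d[2] /= n;
  }

  // returns: 0 absorbed/terminated, 1 scattered (E, dir updated)
  int collide(double &E, double *d, const double *p, Rng &rng) {
    double fpe = mat.fpe(cMatCache, cI0, cW), fco = mat.fco(cMatCache, cI0, cW);
    double tot = rayleigh ? 1.0 : fpe + fco;
    double r = rng.u() * tot;
    if (r < fpe) { deposit(E, p); return 0; }
    if (r < fpe + fco) {
      double Eo, cost;
      knSample(E, rng, Eo, cost);
      deposit(E - Eo, p);
      E = Eo;
      rotate(d, cost, 2 * M_PI * rng.u());
      if (E < cutoff) { deposit(E, p); return 0; }
      setEnergy(E);
      return 1;
    }
    // coherent: direction change only, Thomson-like (1 + cos^2)/2
    double cost;
    for (;;) {
      double c = 2 * rng.u() - 1;
      if (rng.u() <= 0.5 * (1 + c * c)) { cost = c; break; }
    }
    rotate(d, cost, 2 * M_PI * rng.u());
    return 1;
  }
  int cMatCache = 0; // material at the current (real) collision site

  // transport one photon; if firstDepth != nullptr, record distance to the
  // first real collision and stop there
  void transport(double E, double *p, double *d, Rng &rng,
                 double *firstDepth) {
    emitted += E;
    if (firstDepth) *firstDepth = R_PosInf;
    double path = 0;
    setEnergy(E);
    int guard = 0;
    while (++guard < 100000) {
      if (!outer.contains(p)) { escaped += E; return; }
      bool inPh = pbox.contains(p);
      if (inPh) {
        // Woodcock tracking inside the phantom bounding box
        double t0, t1;
        pbox.intersect(p, d, t0, t1);
        double texit = t1;
        double t = 0;
        bool exited = false;
        for (;;) {
          double s = (cMuMaj > 0) ? -std::log(1 - rng.u()) / cMuMaj : 1e300;
          double q0[3] = { p[0] + t * d[0], p[1] + t * d[1], p[2] + t * d[2] };
          if (t + s >= texit) {
            scoreSkinSegment(q0, d, texit - t, E);
            double adv = texit - t + 1e-6;
            for (int a = 0; a < 3; a++) p[a] += adv * d[a];
            exited = true; break;
          }
          scoreSkinSegment(q0, d, s, E);
          t += s;
          double q[3] = { p[0] + t * d[0], p[1] + t * d[1], p[2] + t * d[2] };
          int v = voxelAt(q);
          double muLoc;
          int m;
          if (v < 0) { m = 0; muLoc = cMuAir; }
          else {
            m = matId[v] - 1;
            muLoc = mat.muRho(m, cI0, cW) * dens[v] * effFrac(m, cI0, cW);
          }
          if (rng.u() * cMuMaj < muLoc) {
            // real collision
            for (int a = 0; a < 3; a++) p[a] = q[a];
            if (firstDepth) { *firstDepth = path + t; escaped += E; return; }
            cMatCache = m;
            double Eb = E;
            if (!collide(E, d, p, rng)) return;
            (void)Eb;
            path += t;
            break; // direction/energy changed: restart region logic
          }
        }
        if (exited) { path += texit; }
        continue;
      }
      // homogeneous region
      double mu, texit;
      bool inT = hasTable && table.contains(p);
      bool inAir = !inT && inner.contains(p);
      if (inT) {
        double t0, t1; table.intersect(p, d, t0, t1);
        mu = cMuTable; texit = t1;
      } else if (inAir) {
        double t0, t1; inner.intersect(p, d, t0, t1);
        texit = t1;
        if (pbox.intersect(p, d, t0, t1) && t1 > 0 && t0 > 1e-9)
          texit = std::min(texit, t0);
        if (hasTable && table.intersect(p, d, t0, t1) && t1 > 0 && t0 > 1e-9)
          texit = std::min(texit, t0);
        mu = cMuAir;
      } else {
        // wall shell (between inner and outer boxes)
        if (!hasWalls) { escaped += E; return; }
        double t0, t1; outer.intersect(p, d, t0, t1);
        texit = t1;
        if (inner.intersect(p, d, t0, t1) && t1 > 0 && t0 > 1e-9)
          texit = std::min(texit, t0);
        mu = cMuWall;
      }
      double s = (mu > 0) ? -std::log(1 - rng.u()) / mu : 1e300;
      if (s >= texit) {
        if (inAir) scoreSegment(p, d, texit, E);
        double adv = texit + 1e-6;
        for (int a = 0; a < 3; a++) p[a] += adv * d[a];
        path += texit;
        continue;
      }
      if (inAir) scoreSegment(p, d, s, E);
      for (int a = 0; a < 3; a++) p[a] += s * d[a];
      path += s;
      if (firstDepth) { *firstDepth = path; escaped += E; return; }
      int v = inPh ? -1 : voxelAt(p); (void)v;
      cMatCache = inT ? tableMat : (inAir ? 0 : wallMat);
      if (!collide(E, d, p, rng)) return;
    }
    // pathological loop guard: treat as escaped
    escaped += E;
  }
};

// [[Rcpp::export]]
List cpp_transport(IntegerVector phDims, NumericVector phSpacingCm,
                   NumericVector phOriginCm, IntegerVector matId,
                   NumericVector density, IntegerVector skinMask,
                   NumericVector egrid, NumericMatrix muRho,
                   NumericMatrix mutrRho, NumericMatrix fPe,
                   NumericMatrix fCo,
                   NumericVector specE, NumericVector specCdf,
                   NumericVector srcCm, NumericVector detCm,
                   NumericVector detU, NumericVector detV, double halfFovCm,
                   NumericVector roomMinCm, NumericVector roomMaxCm,
                   double wallThickCm, double wallDensity, int wallMat,
                   NumericVector tableMinCm, NumericVector tableMaxCm,
                   double tableDensity, int tableMat, double airDensity,
                   bool scoreSkin, bool scoreAir,
                   NumericVector airOriginCm, NumericVector airSpacingCm,
                   IntegerVector airDims,
                   double nPhotons, int nBatches, double seed,
                   bool rayleigh, double cutoffKeV, bool firstDepthMode) {
  Engine eng;
  eng.mat.init(egrid, muRho, mutrRho, fPe, fCo);
  for (int a = 0; a < 3; a++) {
    eng.pd[a] = phDims[a]; eng.psp[a] = phSpacingCm[a];
    eng.por[a] = phOriginCm[a];
    eng.pbox.lo[a] = phOriginCm[a];
    eng.pbox.hi[a] = phOriginCm[a] + phDims[a] * phSpacingCm[a];
    eng.inner.lo[a] = roomMinCm[a]; eng.inner.hi[a] = roomMaxCm[a];
    eng.outer.lo[a] = roomMinCm[a] - wallThickCm;
    eng.outer.hi[a] = roomMaxCm[a] + wallThickCm;
    eng.table.lo[a] = tableMinCm[a]; eng.table.hi[a] = tableMaxCm[a];
  }
  eng.hasWalls = wallThickCm > 0;
  eng.hasTable = true;
  for (int a = 0; a < 3; a++)
    if (tableMaxCm[a] <= tableMinCm[a]) eng.hasTable = false;
  eng.wallMat = wallMat - 1; eng.tableMat = tableMat - 1;
  eng.wallDens = wallDensity; eng.tableDens = tableDensity;
  eng.airDens = airDensity;
  eng.matId = INTEGER(matId); eng.dens = REAL(density);
  eng.skin = INTEGER(skinMask);
  eng.rayleigh = rayleigh; eng.cutoff = cutoffKeV;
  eng.scoreSkin = scoreSkin; eng.scoreAir = scoreAir;

  R_xlen_t nvox = (R_xlen_t)eng.pd[0] * eng.pd[1] * eng.pd[2];
  for (int m = 0; m < 8; m++) { eng.maxRho[m] = 0; eng.matPresent[m] = false; }
  for (R_xlen_t i = 0; i < nvox; i++) {
    int m = eng.matId[i] - 1;
    eng.matPresent[m] = true;
    if (eng.dens[i] > eng.maxRho[m]) eng.maxRho[m] = eng.dens[i];
  }
  if (eng.hasWalls) {
    eng.matPresent[eng.wallMat] = true;
    if (wallDensity > eng.maxRho[eng.wallMat])
      eng.maxRho[eng.wallMat] = wallDensity;
  }

  int nair = 1;
  if (scoreAir) {
    for (int a = 0; a < 3; a++) {
      eng.ad[a] = airDims[a]; eng.asp[a] = airSpacingCm[a];
      eng.aor[a] = airOriginCm[a];
      eng.abox.lo[a] = airOriginCm[a];
      eng.abox.hi[a] = airOriginCm[a] + airDims[a] * airSpacingCm[a];
    }
    nair = eng.ad[0] * eng.ad[1] * eng.ad[2];
  } else {
    for (int a = 0; a < 3; a++) { eng.ad[a] = 1; eng.asp[a] = 1; eng.aor[a] = 0; }
  }
  eng.skinBuf.assign(scoreSkin ? nvox : 1, 0.0);
  eng.airBuf.assign(scoreAir ? nair : 1, 0.0);
  eng.emitted = eng.deposited = eng.escaped = 0;

  std::vector<double> skinSum(scoreSkin ? nvox : 1, 0.0),
      skinSq(scoreSkin ? nvox : 1, 0.0),
      airSum(scoreAir ? nair : 1, 0.0), airSq(scoreAir ? nair : 1, 0.0);

  NumericVector firstDepth(firstDepthMode ? (R_xlen_t)nPhotons : 0);

  double nb = std::floor(nPhotons / nBatches);
  int nspec = specE.size();
  R_xlen_t photonIdx = 0;
  for (int b = 0; b < nBatches; b++) {
    uint64_t s0 = (uint64_t)seed;
    uint64_t sb = s0 * 0x9e3779b97f4a7c15ULL + 0x100001b3ULL * (b + 1);
    Rng rng(sb);
    std::fill(eng.skinBuf.begin(), eng.skinBuf.end(), 0.0);
    std::fill(eng.airBuf.begin(), eng.airBuf.end(), 0.0);
    for (R_xlen_t i = 0; i < (R_xlen_t)nb; i++) {
      // energy from the spectrum CDF
      double r = rng.u();
      int lo = 0, hi = nspec - 1;
      while (hi > lo) { int mid = (lo + hi) / 2;
        if (specCdf[mid] < r) lo = mid + 1; else hi = mid; }
      double E = specE[lo];
      double p[3] = { srcCm[0], srcCm[1], srcCm[2] };
      double d[3];
      if (halfFovCm < 0) {
        // isotropic point source
        double c = 2 * rng.u() - 1, ph = 2 * M_PI * rng.u();
        double s2 = std::sqrt(1 - c * c);
        d[0] = s2 * std::cos(ph); d[1] = s2 * std::sin(ph); d[2] = c;
      } else {
        // direction through a uniform point on the collimated detector square
        double tx = (2 * rng.u() - 1) * halfFovCm;
        double ty = (2 * rng.u() - 1) * halfFovCm;
        double nrm = 0;
        for (int a = 0; a < 3; a++) {
          d[a] = detCm[a] + tx * detU[a] + ty * detV[a] - srcCm[a];
          nrm += d[a] * d[a];
        }
        nrm = std::sqrt(nrm);
        for (int a = 0; a < 3; a++) d[a] /= nrm;
      }
      eng.transport(E, p, d, rng,
                    firstDepthMode ? &firstDepth[photonIdx] : (double *)0);
      photonIdx++;
      if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    if (scoreSkin)
      for (R_xlen_t v = 0; v < nvox; v++) {
        skinSum[v] += eng.skinBuf[v];
        skinSq[v] += eng.skinBuf[v] * eng.skinBuf[v];
      }
    if (scoreAir)
      for (int v = 0; v < nair; v++) {
        airSum[v] += eng.airBuf[v];
        airSq[v] += eng.airBuf[v] * eng.airBuf[v];
      }
  }

  double nRun = nb * nBatches;
  auto finish = [&](std::vector<double> &sum, std::vector<double> &sq,
                    R_xlen_t n, double perPhotonScale, NumericVector &mean,
                    NumericVector &relse) {
    for (R_xlen_t v = 0; v < n; v++) {
      double m = sum[v] / nBatches;             // per-batch total
      double var = (sq[v] / nBatches - m * m) * nBatches / (nBatches - 1.0);
      if (var < 0) var = 0;
      double se = std::sqrt(var / nBatches);
      mean[v] = m / nb * perPhotonScale;
      relse[v] = (m > 0) ? se / m : NA_REAL;
    }
  };

  List out;
  if (scoreSkin) {
    NumericVector mean(nvox), relse(nvox);
    finish(skinSum, skinSq, nvox, 1.0, mean, relse);
    out["skin_dose"] = mean; out["skin_relse"] = relse;
  }
  if (scoreAir) {
    NumericVector mean(nair), relse(nair);
    finish(airSum, airSq, nair, 1.0, mean, relse);
    out["air_kerma"] = mean; out["air_relse"] = relse;
  }
  out["emitted_keV"] = eng.emitted;
  out["deposited_keV"] = eng.deposited;
  out["escaped_keV"] = eng.escaped;
  out["n_photons_run"] = nRun;
  if (firstDepthMode) out["first_depth_cm"] = firstDepth;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kn_sample(double energyKeV, int n, double seed) {
  Rng rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 7);
  Engine eng;
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; i++) {
    double Eo, c;
    eng.knSample(energyKeV, rng, Eo, c);
    out(i, 0) = Eo; out(i, 1) = c;
  }
  return out;
}
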