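// Metropolis Monte Carlo engine for a bead-spring polyelectrolyte around a
// patchy dielectric sphere in Debye-Hueckel electrolyte.
//
// Energy model (units: Angstrom / kBT / e0):
//   bonds:     k (r - r0)^2 over consecutive beads
//   bead-bead: q^2 lB exp(-kappa r)/r over all pairs, hard core at 2b
//   particle:  q * Psi_sigma(r,theta)        direct multipole series
//              q^2/2 * sum_l R_l k_l(kr)^2   image-charge self term
//              q^2 * sum R_l k_l(kr_i)k_l(kr_j)P_l(cos gamma)  cross, once
//              per pair
// The coefficient vectors Cs (direct) and Rp (polarization, lB*kappa
// included) are precomputed in R.  Modified spherical Bessel k_l uses the
// exponential convention k_0(x) = exp(-x)/x via stable upward recursion.
//
// Moves: pivot / crankshaft (bond-length preserving rotations), single-bead
// displacement, whole-chain translation, whole-chain rotation about the
// centroid.  Incremental energies exploit which pair terms a move can
// change; a full recompute runs periodically to cancel roundoff drift.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct PCG32 {
  uint64_t state, inc;
  PCG32(uint64_t seed, uint64_t seq = 0xda3e39cb94b95bdbULL) {
    state = 0U; inc = (seq << 1u) | 1u;
    next(); state += seed; next();
  }
  uint32_t next() {
    uint64_t old = state;
    state = old * 6364136223846793005ULL + inc;
    uint32_t xorshifted = (uint32_t)(((old >> 18u) ^ old) >> 27u);
    uint32_t rot = (uint32_t)(old >> 59u);
    return (xorshifted >> rot) | (xorshifted << ((-rot) & 31));
  }
  double unif() { return (next() + 0.5) * (1.0 / 4294967296.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

enum MoveKind { PIVOT = 0, CRANK = 1, DISPLACE = 2, TRANSLATE = 3,
                ROTATE = 4, NKINDS = 5 };

struct Vec3 { double x, y, z; };

inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline double clamp1(double c) {
  return c > 1 ? 1 : (c < -1 ? -1 : c);
}
inline double norm(const Vec3& a) {
  return std::sqrt(a.x * a.x + a.y * a.y + a.z * a.z);
}

// Rodrigues rotation of p about unit axis u through origin by angle t
inline Vec3 rot_axis(const Vec3& p, const Vec3& u, double ct, double st) {
  double dot = u.x * p.x + u.y * p.y + u.z * p.z;
  Vec3 cr = {u.y * p.z - u.z * p.y, u.z * p.x - u.x * p.z,
             u.x * p.y - u.y * p.x};
  return {p.x * ct + cr.x * st + u.x * dot * (1 - ct),
          p.y * ct + cr.y * st + u.y * dot * (1 - ct),
          p.z * ct + cr.z * st + u.z * dot * (1 - ct)};
}

struct Engine {
  int N, L;                       // beads, lmax+1
  double a, b, box, kappa, lB, bond_k, r0, q;
  double hc2;                     // (2b)^2 hard core
  double rmin, rmax;              // radial limits a+b, box-b
  std::vector<double> Cs, Rp;     // series coefficients
  bool images;

  std::vector<Vec3> cur, trial;
  std::vector<double> rad, trad;            // |r_i|
  std::vector<double> kl, tkl;              // N*L tables of k_l(kappa r_i)
  std::vector<double> usig, tusig;          // q*Psi_sigma per bead
  std::vector<double> uself, tuself;        // q^2 * full self polar per bead
  std::vector<int> moved; std::vector<char> inM;

  double Ubond, Uyuk, Usig, Uself, Ucross;
  PCG32 rng;

  Engine(uint64_t seed) : rng(seed) {}

  void bessel_row(double r, double* out) const {
    double x = kappa * r;
    double e = std::exp(-x);
    out[0] = e / x;
    if (L > 1) out[1] = e * (1.0 / x + 1.0 / (x * x));
    for (int l = 1; l < L - 1; l++)
      out[l + 1] = out[l - 1] + (2.0 * l + 1.0) / x * out[l];
  }

  double psi_direct(const Vec3& p, double r, const double* klrow) const {
    double c = p.z / r;
    double pl0 = 1.0, pl1 = c;
    double s = Cs[0] * klrow[0];
    if (L > 1) s += Cs[1] * klrow[1] * c;
    for (int l = 1; l < L - 1; l++) {
      double pl2 = ((2.0 * l + 1.0) * c * pl1 - l * pl0) / (l + 1.0);
      s += Cs[l + 1] * klrow[l + 1] * pl2;
      pl0 = pl1; pl1 = pl2;
    }
    return s;
  }

  double self_polar(const double* klrow) const {
    double s = 0;
    for (int l = 0; l < L; l++) s += Rp[l] * klrow[l] * klrow[l];
    return s;
  }

  // cross polarization between beads with tables k1,k2 and cos(gamma)
  double cross_polar(const double* k1, const double* k2, double cg) const {
    double pl0 = 1.0, pl1 = cg;
    double s = Rp[0] * k1[0] * k2[0];
    if (L > 1) s += Rp[1] * k1[1] * k2[1] * cg;
    for (int l = 1; l < L - 1; l++) {
      double pl2 = ((2.0 * l + 1.0) * cg * pl1 - l * pl0) / (l + 1.0);
      s += Rp[l + 1] * k1[l + 1] * k2[l + 1] * pl2;
      pl0 = pl1; pl1 = pl2;
    }
    return s;
  }

  double yuk(double d) const { return q * q * lB * std::exp(-kappa * d) / d; }

  inline double dist(const Vec3& p1, const Vec3& p2) const {
    return norm(sub(p1, p2));
  }
  inline double dist2(const Vec3& p1, const Vec3& p2) const {
    Vec3 d = sub(p1, p2);
    return d.x * d.x + d.y * d.y + d.z * d.z;
  }

  void refresh_bead(int i) {
    rad[i] = norm(cur[i]);
    bessel_row(rad[i], &kl[i * L]);
    usig[i] = q * psi_direct(cur[i], rad[i], &kl[i * L]);
    uself[i] = images ? q * q * self_polar(&kl[i * L]) : 0.0;
  }

  void full_recompute() {
    Ubond = Uyuk = Usig = Uself = Ucross = 0;
    for (int i = 0; i < N; i++) {
      refresh_bead(i);
      Usig += usig[i]; Uself += uself[i];
    }
    for (int i = 0; i + 1 < N; i++) {
      double d = dist(cur[i], cur[i + 1]);
      Ubond += bond_k * (d - r0) * (d - r0);
    }
    for (int i = 0; i < N; i++)
      for (int j = i + 1; j < N; j++) {
        double d = dist(cur[i], cur[j]);
        Uyuk += yuk(d);
        if (images) {
          double cg = clamp1((cur[i].x * cur[j].x + cur[i].y * cur[j].y +
                              cur[i].z * cur[j].z) / (rad[i] * rad[j]));
          Ucross += q * q * cross_polar(&kl[i * L], &kl[j * L], cg);
        }
      }
  }

  double binding() const { return Usig + 0.5 * Uself + Ucross; }
  double total() const { return Ubond + Uyuk + binding(); }

  Vec3 rand_unit() {
    double u1, u2, s;
    do {
      u1 = 2 * rng.unif() - 1; u2 = 2 * rng.unif() - 1;
      s = u1 * u1 + u2 * u2;
    } while (s >= 1 || s == 0);
    double f = 2 * std::sqrt(1 - s);
    return {u1 * f, u2 * f, 1 - 2 * s};
  }

  // ---- proposals: fill `moved`, write trial coords into `trial` ---------
  // return value: true if pair distances inside the moved set are preserved
  // (rigid move) -- they always are for the implemented kinds.

  void propose_rigid_rotation(int lo, int hi, const Vec3& origin,
                              const Vec3& axis, double angle) {
    double ct = std::cos(angle), st = std::sin(angle);
    for (int i = lo; i <= hi; i++) {
      Vec3 rel = sub(cur[i], origin);
      Vec3 rr = rot_axis(rel, axis, ct, st);
      trial[i] = {origin.x + rr.x, origin.y + rr.y, origin.z + rr.z};
      moved.push_back(i);
    }
  }

  bool propose(int kind, double amp) {
    moved.clear();
    switch (kind) {
    case PIVOT: {
      if (N < 2) return false;
      int p = rng.below(N);
      bool left_ok = p > 0, right_ok = p < N - 1;
      bool go_left = left_ok && (!right_ok || rng.unif() < 0.5);
      double angle = amp * (2 * rng.unif() - 1);
      Vec3 axis = rand_unit();
      if (go_left) propose_rigid_rotation(0, p - 1, cur[p], axis, angle);
      else propose_rigid_rotation(p + 1, N - 1, cur[p], axis, angle);
      break;
    }
    case CRANK: {
      if (N < 3) return false;
      int i = rng.below(N - 2);
      int j = i + 2 + rng.below(N - i - 2);
      Vec3 ax = sub(cur[j], cur[i]);
      double n = norm(ax);
      if (n < 1e-12) return false;
      ax.x /= n; ax.y /= n; ax.z /= n;
      double angle = amp * (2 * rng.unif() - 1);
      propose_rigid_rotation(i + 1, j - 1, cur[i], ax, angle);
      break;
    }
    case DISPLACE: {
      int j = rng.below(N);
      trial[j] = {cur[j].x + amp * (2 * rng.unif() - 1),
                  cur[j].y + amp * (2 * rng.unif() - 1),
                  cur[j].z + amp * (2 * rng.unif() - 1)};
      moved.push_back(j);
      break;
    }
    case TRANSLATE: {
      Vec3 d = {amp * (2 * rng.unif() - 1), amp * (2 * rng.unif() - 1),
                amp * (2 * rng.unif() - 1)};
      for (int i = 0; i < N; i++) {
        trial[i] = {cur[i].x + d.x, cur[i].y + d.y, cur[i].z + d.z};
        moved.push_back(i);
      }
      break;
    }
    case ROTATE: {
      Vec3 com = {0, 0, 0};
      for (int i = 0; i < N; i++) {
        com.x += cur[i].x; com.y += cur[i].y; com.z += cur[i].z;
      }
      com.x /= N; com.y /= N; com.z /= N;
      Vec3 axis = rand_unit();
      double angle = amp * (2 * rng.unif() - 1);
      propose_rigid_rotation(0, N - 1, com, axis, angle);
      break;
    }
    default: return false;
    }
    return !moved.empty();
  }

  // ---- incremental energy ----------------------------------------------
  // returns false when a hard constraint rejects the move outright
  bool delta_energy(double& dU) {
    int M = (int)moved.size();
    bool whole = (M == N);
    // trial per-bead caches + radial constraints
    for (int t = 0; t < M; t++) {
      int i = moved[t];
      double r = norm(trial[i]);
      if (r < rmin || r > rmax) return false;
      trad[i] = r;
      bessel_row(r, &tkl[i * L]);
      tusig[i] = q * psi_direct(trial[i], r, &tkl[i * L]);
      tuself[i] = images ? q * q * self_polar(&tkl[i * L]) : 0.0;
    }
    double dSig = 0, dSelf = 0, dYuk = 0, dCross = 0, dBond = 0;
    for (int t = 0; t < M; t++) {
      int i = moved[t];
      dSig += tusig[i] - usig[i];
      dSelf += tuself[i] - uself[i];
      inM[i] = 1;
    }
    // bonds touching the moved set
    for (int t = 0; t < M; t++) {
      int i = moved[t];
      for (int s = -1; s <= 1; s += 2) {
        int j = i + s;
        if (j < 0 || j >= N) continue;
        if (inM[j] && j < i) continue;           // count each bond once
        if (inM[j] && j > i) {
          // both ends moved: rigid moves preserve it, but recompute anyway
          double dn = dist(trial[i], trial[j]);
          double dold = dist(cur[i], cur[j]);
          dBond += bond_k * ((dn - r0) * (dn - r0) -
                             (dold - r0) * (dold - r0));
        } else if (!inM[j]) {
          double dn = dist(trial[i], cur[j]);
          double dold = dist(cur[i], cur[j]);
          dBond += bond_k * ((dn - r0) * (dn - r0) -
                             (dold - r0) * (dold - r0));
        }
      }
    }
    // pair terms between moved and unmoved beads (rigid moves leave
    // intra-set distances unchanged; whole-chain moves leave all of them)
    if (!whole) {
      for (int t = 0; t < M; t++) {
        int i = moved[t];
        for (int j = 0; j < N; j++) {
          if (inM[j]) continue;
          double d2n = dist2(trial[i], cur[j]);
          if (d2n <= hc2) { clear_marks(); return false; }
          double dn = std::sqrt(d2n);
          double dold = dist(cur[i], cur[j]);
          dYuk += yuk(dn) - yuk(dold);
          if (images) {
            double cgn = (trial[i].x * cur[j].x + trial[i].y * cur[j].y +
                          trial[i].z * cur[j].z) / (trad[i] * rad[j]);
            double cgo = (cur[i].x * cur[j].x + cur[i].y * cur[j].y +
                          cur[i].z * cur[j].z) / (rad[i] * rad[j]);
            cgn = clamp1(cgn); cgo = clamp1(cgo);
            dCross += q * q *
              (cross_polar(&tkl[i * L], &kl[j * L], cgn) -
               cross_polar(&kl[i * L], &kl[j * L], cgo));
          }
        }
      }
    }
    // cross-polarization inside the moved set: radial distances change for
    // any rotation whose axis misses the particle center, so these pairs
    // must be recomputed even for rigid moves
    if (images && M >= 2) {
      for (int t = 0; t < M; t++)
        for (int u = t + 1; u < M; u++) {
          int i = moved[t], j = moved[u];
          double cgn = (trial[i].x * trial[j].x + trial[i].y * trial[j].y +
                        trial[i].z * trial[j].z) / (trad[i] * trad[j]);
          double cgo = (cur[i].x * cur[j].x + cur[i].y * cur[j].y +
                        cur[i].z * cur[j].z) / (rad[i] * rad[j]);
          cgn = clamp1(cgn); cgo = clamp1(cgo);
          dCross += q * q *
            (cross_polar(&tkl[i * L], &tkl[j * L], cgn) -
             cross_polar(&kl[i * L], &kl[j * L], cgo));
        }
    }
    clear_marks();
    dU = dBond + dYuk + dSig + 0.5 * dSelf + dCross;
    dBond_ = dBond; dYuk_ = dYuk; dSig_ = dSig; dSelf_ = dSelf;
    dCross_ = dCross;
    return true;
  }

  double dBond_, dYuk_, dSig_, dSelf_, dCross_;

  void clear_marks() {
    for (size_t t = 0; t < moved.size(); t++) inM[moved[t]] = 0;
  }

  void accept_move() {
    for (size_t t = 0; t < moved.size(); t++) {
      int i = moved[t];
      cur[i] = trial[i];
      rad[i] = trad[i];
      std::copy(&tkl[i * L], &tkl[i * L] + L, &kl[i * L]);
      usig[i] = tusig[i]; uself[i] = tuself[i];
    }
    Ubond += dBond_; Uyuk += dYuk_; Usig += dSig_; Uself += dSelf_;
    Ucross += dCross_;
  }

  double rg2() const {
    Vec3 c = {0, 0, 0};
    for (int i = 0; i < N; i++) {
      c.x += cur[i].x; c.y += cur[i].y; c.z += cur[i].z;
    }
    c.x /= N; c.y /= N; c.z /= N;
    double s = 0;
    for (int i = 0; i < N; i++) s += dist2(cur[i], c);
    return s / N;
  }

  double min_surface_dist() const {
    double m = R_PosInf;
    for (int i = 0; i < N; i++) m = std::min(m, rad[i] - a - b);
    return m;
  }
};

} // namespace

// [[Rcpp::export(name = ".run_mc_cpp")]]
List run_mc_cpp(NumericMatrix positions0,
                double a, double b, double box,
                double kappa, double lB, double bond_k, double r0,
                double valence,
                NumericVector Cs, NumericVector Rp, bool images,
                double equil_moves, int sample_interval, int n_samples,
                bool tune, int tune_window,
                NumericVector amplitudes, IntegerVector kinds,
                double adsorption_threshold, int snapshot_every,
                double seed) {
  int N = positions0.nrow();
  Engine e((uint64_t)seed);
  e.N = N; e.L = Cs.size();
  e.a = a; e.b = b; e.box = box; e.kappa = kappa; e.lB = lB;
  e.bond_k = bond_k; e.r0 = r0; e.q = valence;
  e.hc2 = 4 * b * b;
  e.rmin = a + b; e.rmax = box - b;
  e.Cs = as<std::vector<double>>(Cs);
  e.Rp = as<std::vector<double>>(Rp);
  if ((int)e.Rp.size() != e.L) e.Rp.assign(e.L, 0.0);
  e.images = images;
  e.cur.resize(N); e.trial.resize(N);
  e.rad.resize(N); e.trad.resize(N);
  e.kl.resize(N * e.L); e.tkl.resize(N * e.L);
  e.usig.resize(N); e.tusig.resize(N);
  e.uself.resize(N); e.tuself.resize(N);
  e.inM.assign(N, 0);
  for (int i = 0; i < N; i++)
    e.cur[i] = {positions0(i, 0), positions0(i, 1), positions0(i, 2)};
  e.full_recompute();

  std::vector<int> enabled;
  for (int i = 0; i < kinds.size(); i++) {
    int k = kinds[i];
    if (k == PIVOT && N < 2) continue;
    if (k == CRANK && N < 3) continue;
    if (k == ROTATE && N < 2) continue;
    enabled.push_back(k);
  }
  if (enabled.empty()) enabled.push_back(DISPLACE);

  std::vector<double> amp(NKINDS);
  for (int k = 0; k < NKINDS; k++) amp[k] = amplitudes[k];
  double amp_lo[NKINDS] = {1e-3, 1e-3, 0.05, box / 8.0, 1e-3};
  double amp_hi[NKINDS] = {M_PI, M_PI, 0.5 * box, 2.0 * box, M_PI};
  for (int k = 0; k < NKINDS; k++) {
    if (amp[k] < amp_lo[k]) amp[k] = amp_lo[k];
    if (amp[k] > amp_hi[k]) amp[k] = amp_hi[k];
  }

  std::vector<double> att(NKINDS, 0), acc(NKINDS, 0);
  std::vector<double> watt(NKINDS, 0), wacc(NKINDS, 0);

  NumericVector sEB(n_samples), sRg2(n_samples), sMin(n_samples);
  LogicalVector sAds(n_samples);
  NumericVector sMoves(n_samples);
  List snaps;

  double total_moves = equil_moves + (double)sample_interval * n_samples;
  double move = 0;
  long long since_refresh = 0;
  int isample = 0;
  double next_sample = equil_moves + sample_interval;

  while (move < total_moves) {
    move += 1;
    since_refresh++;
    bool equil = move <= equil_moves;
    int kind = enabled[e.rng.below((int)enabled.size())];
    att[kind]++; if (equil) watt[kind]++;
    if (e.propose(kind, amp[kind])) {
      double dU;
      if (e.delta_energy(dU)) {
        if (dU <= 0 || e.rng.unif() < std::exp(-dU)) {
          e.accept_move();
          acc[kind]++; if (equil) wacc[kind]++;
        }
      }
    }
    if (equil && tune && ((long long)move % tune_window == 0)) {
      for (int k = 0; k < NKINDS; k++) {
        if (watt[k] >= 10) {
          double rate = wacc[k] / watt[k];
          if (rate > 0.55) amp[k] *= 1.1;
          else if (rate < 0.45) amp[k] /= 1.1;
          if (amp[k] < amp_lo[k]) amp[k] = amp_lo[k];
          if (amp[k] > amp_hi[k]) amp[k] = amp_hi[k];
        }
        watt[k] = wacc[k] = 0;
      }
    }
    if (since_refresh >= 1048576) {   // cancel incremental roundoff drift
      e.full_recompute();
      since_refresh = 0;
    }
    if (!equil && move >= next_sample && isample < n_samples) {
      sEB[isample] = e.binding();
      sRg2[isample] = e.rg2();
      sMin[isample] = e.min_surface_dist();
      sAds[isample] = e.binding() < adsorption_threshold;
      sMoves[isample] = move;
      if (snapshot_every > 0 && (isample % snapshot_every) == 0) {
        NumericMatrix snap(N, 3);
        for (int i = 0; i < N; i++) {
          snap(i, 0) = e.cur[i].x; snap(i, 1) = e.cur[i].y;
          snap(i, 2) = e.cur[i].z;
        }
        snaps.push_back(snap);
      }
      isample++;
      next_sample += sample_interval;
    }
  }

  NumericVector inc = NumericVector::create(
    _["bond"] = e.Ubond, _["pe_pe"] = e.Uyuk, _["direct"] = e.Usig,
    _["polar_self"] = 0.5 * e.Uself, _["polar_cross"] = e.Ucross,
    _["binding"] = e.binding(), _["total"] = e.total());
  e.full_recompute();
  NumericVector scratch = NumericVector::create(
    _["bond"] = e.Ubond, _["pe_pe"] = e.Uyuk, _["direct"] = e.Usig,
    _["polar_self"] = 0.5 * e.Uself, _["polar_cross"] = e.Ucross,
    _["binding"] = e.binding(), _["total"] = e.total());

  NumericMatrix finalpos(N, 3);
  for (int i = 0; i < N; i++) {
    finalpos(i, 0) = e.cur[i].x; finalpos(i, 1) = e.cur[i].y;
    finalpos(i, 2) = e.cur[i].z;
  }
  CharacterVector kind_names = CharacterVector::create(
    "pivot", "crankshaft", "displace", "translate", "rotate");
  NumericVector attv(att.begin(), att.end()), accv(acc.begin(), acc.end()),
    ampv(amp.begin(), amp.end());
  attv.names() = kind_names; accv.names() = kind_names;
  ampv.names() = kind_names;

  return List::create(
    _["E_B"] = sEB, _["Rg2"] = sRg2, _["min_dist"] = sMin,
    _["adsorbed"] = sAds, _["n_moves"] = sMoves,
    _["final_positions"] = finalpos,
    _["attempts"] = attv, _["accepts"] = accv,
    _["final_amplitudes"] = ampv,
    _["energy_incremental"] = inc, _["energy_scratch"] = scratch,
    _["snapshots"] = snaps);
}
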