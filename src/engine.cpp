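// Compiled core: strain-dependent three-state crossbridge rates, fixed-step
// Monte Carlo engine (geometric jump sampling between events), quasi-static
// spring-network equilibrium of extensible filaments, and the meridional
// diffraction sum.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <limits>
#include <random>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Rates
// ---------------------------------------------------------------------------

struct RateP {
  double kbind, dGb, dGs, kadp0, d, delta, kappa, kBT;
  double cap23, cap32, cap31, dt, reach;
};

static RateP rateFromList(const List& rp) {
  RateP p;
  p.kbind = rp["kBind"]; p.dGb = rp["dGbind"]; p.dGs = rp["dGstroke"];
  p.kadp0 = rp["kAdp0"]; p.d = rp["strokeD"]; p.delta = rp["delta2"];
  p.kappa = rp["kappaXb"]; p.kBT = rp["kBT"];
  p.cap23 = rp["capK23"]; p.cap32 = rp["capK32"]; p.cap31 = rp["capK31"];
  p.dt = rp["dt"]; p.reach = rp["bindingReach"];
  return p;
}

static inline double G2(const RateP& p, double x) {
  return p.dGb + p.kappa * x * x / (2.0 * p.kBT);
}
static inline double G3(const RateP& p, double x) {
  double u = x + p.d;
  return p.dGb + p.dGs + p.kappa * u * u / (2.0 * p.kBT);
}
static inline double k12f(const RateP& p, double x) {
  return p.kbind * std::exp(-p.kappa * x * x / (2.0 * p.kBT));
}
// k12/k21 = exp(-(G2-G1)) => k21 = kbind * exp(dGbind), strain independent
static inline double k21f(const RateP& p, double /*x*/) {
  return p.kbind * std::exp(p.dGb);
}
// Sigmoidal stroke rate bounded by its cap; the reverse follows from
// detailed balance, and when it would exceed its own cap the pair is
// re-anchored at the reverse cap so kij/kji = exp(-dGij) holds everywhere.
static inline void k23f(const RateP& p, double x, double& k23, double& k32) {
  double dG = G3(p, x) - G2(p, x);
  if (dG >= 0) {
    double e = std::exp(-dG);
    k23 = p.cap23 * e / (1.0 + e);
    k32 = p.cap23 / (1.0 + e);
  } else {
    double e = std::exp(dG);
    k23 = p.cap23 / (1.0 + e);
    k32 = p.cap23 * e / (1.0 + e);
  }
  if (k32 > p.cap32) {
    k32 = p.cap32;
    k23 = p.cap32 * std::exp(-dG);
  }
}
// ADP release / detachment: strain-accelerated only for negative post-stroke
// extension (x + d <= 0), capped.
static inline double k31f(const RateP& p, double x) {
  double u = x + p.d;
  double k;
  if (u <= 0) {
    k = p.kadp0 *
        std::exp(-(p.kappa * p.delta * u + 0.5 * p.kappa * p.delta * p.delta) /
                 p.kBT);
  } else {
    k = p.kadp0;
  }
  return std::min(k, p.cap31);
}

// [[Rcpp::export]]
NumericMatrix cxx_rates(NumericVector x, List rp) {
  RateP p = rateFromList(rp);
  int n = x.size();
  NumericMatrix out(n, 6);
  colnames(out) =
      CharacterVector::create("k12", "k21", "k23", "k32", "k31", "k13");
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(x[i])) stop("NaN/Inf strain x rejected");
    double k23, k32;
    k23f(p, x[i], k23, k32);
    out(i, 0) = k12f(p, x[i]);
    out(i, 1) = k21f(p, x[i]);
    out(i, 2) = k23;
    out(i, 3) = k32;
    out(i, 4) = k31f(p, x[i]);
    out(i, 5) = 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Spring network equilibrium
// ---------------------------------------------------------------------------

struct Mech {
  int nm, nc, Tn, F;
  double s0, h;        // actin segment rest length, crown spacing
  double bare;         // anchor-to-first-crown rest length
  double anchor;       // fixed M-band anchor position
  double ka, km, kb0;  // segment stiffnesses Ka/s0, Km/h, Km/bare
  double kappa, kt;    // crossbridge and titin stiffness
  double tip0;         // relaxed thick tip position (titin rest)
};

// Attachment bookkeeping kept incrementally up to date between events so the
// per-event solve allocates nothing.
struct ThinAtt { int mono, crownG, head; double off; };
struct CrownAtt { int thin, mono, head; double off; };

struct AttView {
  std::vector<std::vector<ThinAtt>> thin;    // per thin filament
  std::vector<std::vector<CrownAtt>> crown;  // per crown node (f*nc + c)
  void init(int Tn, int nCrownNodes) {
    thin.assign(Tn, {});
    crown.assign(nCrownNodes, {});
  }
  void add(int t, int mono, int cg, int head, double off) {
    thin[t].push_back({mono, cg, head, off});
    crown[cg].push_back({t, mono, head, off});
  }
  void remove(int t, int cg, int head) {
    auto& tv = thin[t];
    for (size_t i = 0; i < tv.size(); ++i)
      if (tv[i].head == head) { tv[i] = tv.back(); tv.pop_back(); break; }
    auto& cv = crown[cg];
    for (size_t i = 0; i < cv.size(); ++i)
      if (cv[i].head == head) { cv[i] = cv.back(); cv.pop_back(); break; }
  }
  void setOffset(int t, int cg, int head, double off) {
    for (auto& a : thin[t]) if (a.head == head) { a.off = off; break; }
    for (auto& a : crown[cg]) if (a.head == head) { a.off = off; break; }
  }
};

struct Workspace {
  std::vector<double> diag, rhs, cp, f;
  void init(int n) { diag.resize(n); rhs.resize(n); cp.resize(n); f.resize(n); }
};

// exact tridiagonal (Thomas) solve of one thin chain given the current crown
// positions; returns the largest node displacement
static double solveThinChain(std::vector<double>& az,
                             const std::vector<double>& my, const Mech& M,
                             const AttView& v, Workspace& ws, int t) {
  int nm = M.nm, nc = M.nc;
  double ka = M.ka;
  double* diag = ws.diag.data();
  double* rhs = ws.rhs.data();
  double* cp = ws.cp.data();
  double* z = &az[(size_t)t * nm];
  int n = nm - 1;
  for (int j = 0; j < n; ++j) { diag[j] = 2.0 * ka; rhs[j] = 0.0; }
  diag[n - 1] = ka;
  rhs[0] += ka * z[0];
  rhs[n - 1] += ka * M.s0;
  for (const auto& a : v.thin[t]) {
    int j = a.mono - 1;  // unknown index
    double y = my[(size_t)(a.crownG / nc) * nc + (a.crownG % nc)];
    diag[j] += M.kappa;
    rhs[j] += M.kappa * (y + a.off);
  }
  cp[0] = -ka / diag[0];
  rhs[0] /= diag[0];
  for (int j = 1; j < n; ++j) {
    double m = diag[j] + ka * cp[j - 1];
    cp[j] = -ka / m;
    rhs[j] = (rhs[j] + ka * rhs[j - 1]) / m;
  }
  double delta = std::fabs(rhs[n - 1] - z[nm - 1]);
  z[nm - 1] = rhs[n - 1];
  for (int j = n - 2; j >= 0; --j) {
    rhs[j] = rhs[j] - cp[j] * rhs[j + 1];
    delta = std::max(delta, std::fabs(rhs[j] - z[j + 1]));
    z[j + 1] = rhs[j];
  }
  return delta;
}

static double solveThickChain(const std::vector<double>& az,
                              std::vector<double>& my, const Mech& M,
                              const AttView& v, Workspace& ws, int fi) {
  int nm = M.nm, nc = M.nc;
  double km = M.km;
  double* diag = ws.diag.data();
  double* rhs = ws.rhs.data();
  double* cp = ws.cp.data();
  double* y = &my[(size_t)fi * nc];
  for (int c = 0; c < nc; ++c) { diag[c] = 0.0; rhs[c] = 0.0; }
  diag[0] += M.kb0;
  rhs[0] += M.kb0 * (M.anchor - M.bare);
  for (int c = 1; c < nc; ++c) {  // segment c-1 -- c, rest length h
    diag[c - 1] += km; diag[c] += km;
    rhs[c - 1] += km * M.h;
    rhs[c] -= km * M.h;
  }
  diag[nc - 1] += M.kt;
  rhs[nc - 1] += M.kt * M.tip0;
  for (int c = 0; c < nc; ++c) {
    int cg = fi * nc + c;
    for (const auto& a : v.crown[cg]) {
      diag[c] += M.kappa;
      rhs[c] += M.kappa * (az[(size_t)a.thin * nm + a.mono] - a.off);
    }
  }
  cp[0] = -km / diag[0];
  rhs[0] /= diag[0];
  for (int c = 1; c < nc; ++c) {
    double m = diag[c] + km * cp[c - 1];
    cp[c] = (c == nc - 1) ? 0.0 : -km / m;
    rhs[c] = (rhs[c] + km * rhs[c - 1]) / m;
  }
  double delta = std::fabs(rhs[nc - 1] - y[nc - 1]);
  y[nc - 1] = rhs[nc - 1];
  for (int c = nc - 2; c >= 0; --c) {
    rhs[c] = rhs[c] - cp[c] * rhs[c + 1];
    delta = std::max(delta, std::fabs(rhs[c] - y[c]));
    y[c] = rhs[c];
  }
  return delta;
}

// max |net nodal force| over all free nodes, for verification of a full solve
static double residualForce(const std::vector<double>& az,
                            const std::vector<double>& my, const Mech& M,
                            const AttView& v, Workspace& ws) {
  int nm = M.nm, nc = M.nc;
  double r = 0;
  for (int t = 0; t < M.Tn; ++t) {
    const double* z = &az[(size_t)t * nm];
    double* f = ws.f.data();
    for (int j = 1; j < nm - 1; ++j)
      f[j] = M.ka * (z[j + 1] - 2.0 * z[j] + z[j - 1]);
    f[nm - 1] = -M.ka * (z[nm - 1] - z[nm - 2] - M.s0);
    for (const auto& a : v.thin[t]) {
      double y = my[(size_t)(a.crownG / nc) * nc + (a.crownG % nc)];
      f[a.mono] += M.kappa * (y - z[a.mono] + a.off);
    }
    for (int j = 1; j < nm; ++j) r = std::max(r, std::fabs(f[j]));
  }
  for (int fi = 0; fi < M.F; ++fi) {
    const double* y = &my[(size_t)fi * nc];
    double* f = ws.f.data();
    f[0] = M.kb0 * (M.anchor - y[0] - M.bare);
    if (nc > 1) f[0] -= M.km * (y[0] - y[1] - M.h);
    for (int c = 1; c < nc - 1; ++c)
      f[c] = M.km * (y[c - 1] - 2.0 * y[c] + y[c + 1]);
    if (nc > 1) f[nc - 1] = M.km * (y[nc - 2] - y[nc - 1] - M.h);
    f[nc - 1] -= M.kt * (y[nc - 1] - M.tip0);
    for (int c = 0; c < nc; ++c) {
      int cg = fi * nc + c;
      for (const auto& a : v.crown[cg])
        f[c] -= M.kappa * (y[c] - az[(size_t)a.thin * nm + a.mono] + a.off);
    }
    for (int c = 0; c < nc; ++c) r = std::max(r, std::fabs(f[c]));
  }
  return r;
}

// Worklist relaxation: filaments carry conservative bounds on their residual
// nodal force. A chain whose bound exceeds the threshold is re-solved
// exactly; its displacement delta adds kappa*delta (per possible bridge) to
// the bounds of its partner filaments. Terminates when every bound is below
// tol/2, which rigorously guarantees net nodal forces below tol (chain
// solves are exact up to Thomas roundoff). Between crossbridge events only
// the filaments touched by an event and their elastic neighbourhood are
// revisited, so the cost per event is local.
struct Relax {
  std::vector<double> resThin, resThick;
  std::vector<char> movedThin, movedThick;  // positions changed since the
                                            // last head-rescheduling pass
  std::vector<long long> seenThin, seenThick;  // per-partner dedup stamps
  long long bstamp = 0;
  static constexpr double MOVE_EPS = 1e-9;  // nm

  void init(int Tn, int F) {
    resThin.assign(Tn, std::numeric_limits<double>::infinity());
    resThick.assign(F, std::numeric_limits<double>::infinity());
    movedThin.assign(Tn, 1);
    movedThick.assign(F, 1);
    seenThin.assign(Tn, -1);
    seenThick.assign(F, -1);
  }
  void markThin(int t) { resThin[t] = std::numeric_limits<double>::infinity(); }
  void markThick(int f) {
    resThick[f] = std::numeric_limits<double>::infinity();
  }

  // returns iterations used, or -1 on failure
  int run(std::vector<double>& az, std::vector<double>& my, const Mech& M,
          const AttView& v, Workspace& ws, double tol, int maxit, int hpc) {
    double thr = 0.5 * tol;
    for (int it = 0; it < maxit; ++it) {
      bool any = false;
      for (int t = 0; t < M.Tn; ++t) {
        if (resThin[t] <= thr) continue;
        any = true;
        double d = solveThinChain(az, my, M, v, ws, t);
        resThin[t] = 0;
        if (d > MOVE_EPS) {
          movedThin[t] = 1;
          // each crown holds at most hpc bridges, so a partner thick's
          // worst node picks up at most hpc * kappa * d; add once per thick
          ++bstamp;
          for (const auto& a : v.thin[t]) {
            int f = a.crownG / M.nc;
            if (seenThick[f] == bstamp) continue;
            seenThick[f] = bstamp;
            resThick[f] += hpc * M.kappa * d;
          }
        }
      }
      for (int f = 0; f < M.F; ++f) {
        if (resThick[f] <= thr) continue;
        any = true;
        double d = solveThickChain(az, my, M, v, ws, f);
        resThick[f] = 0;
        if (d > MOVE_EPS) {
          movedThick[f] = 1;
          // a thin monomer node holds at most one bridge: kappa * d once
          // per partner thin filament
          ++bstamp;
          for (int c = 0; c < M.nc; ++c)
            for (const auto& a : v.crown[(size_t)f * M.nc + c]) {
              if (seenThin[a.thin] == bstamp) continue;
              seenThin[a.thin] = bstamp;
              resThin[a.thin] += M.kappa * d;
            }
        }
      }
      if (!any) return it + 1;
    }
    return -1;
  }
};

static Mech mechFromList(const List& lt) {
  Mech M;
  NumericMatrix az = lt["actinZ"], my = lt["myosinZ"];
  M.nm = az.nrow(); M.Tn = az.ncol(); M.nc = my.nrow(); M.F = my.ncol();
  M.s0 = lt["s0"]; M.h = lt["crownSpacing"]; M.bare = lt["bareLength"];
  M.anchor = lt["anchorZ"];
  double Ka = lt["Ka"], Km = lt["Km"];
  M.ka = Ka / M.s0; M.km = Km / M.h; M.kb0 = Km / M.bare;
  M.kappa = lt["kappaXb"]; M.kt = lt["titinStiffness"];
  M.tip0 = M.anchor - M.bare - (M.nc - 1) * M.h;
  return M;
}

// attachment columns (1-based in R): head, thin, monomer, state
static void attIntoView(const List& lt, double strokeD, const Mech& M,
                        AttView& v, std::vector<int>* headState = nullptr,
                        std::vector<int>* headMono = nullptr,
                        std::vector<int>* occ = nullptr) {
  DataFrame att = as<DataFrame>(lt["attachments"]);
  IntegerVector hd = att["head"], th = att["thin"], mo = att["monomer"],
                st = att["state"];
  int hpc = lt["headsPerCrown"];
  int perF = M.nc * hpc;
  for (int i = 0; i < hd.size(); ++i) {
    int h = hd[i] - 1;
    int c = (h % perF) / hpc;
    int f = h / perF;
    int t = th[i] - 1, m = mo[i] - 1;
    double off = (st[i] == 3) ? strokeD : 0.0;
    v.add(t, m, f * M.nc + c, h, off);
    if (headState) (*headState)[h] = st[i];
    if (headMono) (*headMono)[h] = m;
    if (occ) (*occ)[(size_t)t * M.nm + m] = h;
  }
}

// [[Rcpp::export]]
List cxx_solve_equilibrium(List lt, double strokeD, double tol, int maxit) {
  Mech M = mechFromList(lt);
  NumericMatrix azR = lt["actinZ"], myR = lt["myosinZ"];
  std::vector<double> az(azR.begin(), azR.end()), my(myR.begin(), myR.end());
  AttView v;
  v.init(M.Tn, M.F * M.nc);
  int hpc = lt["headsPerCrown"];
  attIntoView(lt, strokeD, M, v);
  Workspace ws;
  ws.init(std::max(M.nm, M.nc));
  Relax rx;
  rx.init(M.Tn, M.F);
  int it = rx.run(az, my, M, v, ws, tol, maxit, hpc);
  double resid = residualForce(az, my, M, v, ws);
  if (it < 0 || resid > tol)
    stop("equilibrium solve did not converge: residual " +
         std::to_string(resid) + " pN after " + std::to_string(maxit) +
         " sweeps");
  NumericMatrix azOut(M.nm, M.Tn), myOut(M.nc, M.F);
  std::copy(az.begin(), az.end(), azOut.begin());
  std::copy(my.begin(), my.end(), myOut.begin());
  return List::create(_["actinZ"] = azOut, _["myosinZ"] = myOut,
                      _["iterations"] = it, _["residual"] = resid);
}

// ---------------------------------------------------------------------------
// Monte Carlo engine
// ---------------------------------------------------------------------------

static const long long NEVER = std::numeric_limits<long long>::max() / 4;

struct Engine {
  Mech M;
  RateP P;
  int hpc, H;
  std::vector<double> az, my;
  std::vector<int> headThin;             // 0-based target thin filament
  std::vector<int> headState, headMono;  // state 1/2/3; bound monomer or -1
  std::vector<int> occ;                  // per (thin,monomer): head id or -1
  std::vector<long long> nextStep;
  std::vector<int> nextTrans;  // 0 bind, 1 k21, 2 k23, 3 k32, 4 k31
  std::vector<std::vector<int>> targetHeads;  // heads wired to each thin
  std::vector<long long> schedStamp;
  long long stamp = 0;
  AttView view;
  Workspace ws;
  Relax rx;
  std::mt19937_64 rng;
  bool rigid;
  double tol;
  int maxit;
  long long nSolves = 0;

  int crownOf(int h) const { return (h % (M.nc * hpc)) / hpc; }
  int thickOf(int h) const { return h / (M.nc * hpc); }
  int crownG(int h) const { return thickOf(h) * M.nc + crownOf(h); }
  double crownZ(int h) const {
    return my[(size_t)thickOf(h) * M.nc + crownOf(h)];
  }

  double unif() {  // (0,1], 53-bit, generator-explicit for reproducibility
    return ((rng() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  long long geomSteps(double p) {
    if (p <= 0) return NEVER;
    if (p >= 1) return 1;
    double g = std::floor(std::log(unif()) / std::log1p(-p));
    if (g > 1e17 || !std::isfinite(g)) return NEVER;
    return 1 + (long long)g;
  }

  void siteRange(int t, double y, int& jlo, int& jhi) {
    const double* z = &az[(size_t)t * M.nm];
    jlo = (int)(std::lower_bound(z, z + M.nm, y - P.reach) - z);
    jhi = (int)(std::upper_bound(z, z + M.nm, y + P.reach) - z) - 1;
  }

  double bindTotalRate(int h) {
    int t = headThin[h];
    double y = crownZ(h);
    int jlo, jhi;
    siteRange(t, y, jlo, jhi);
    double tot = 0;
    for (int j = jlo; j <= jhi; ++j) {
      if (occ[(size_t)t * M.nm + j] >= 0) continue;
      tot += k12f(P, y - az[(size_t)t * M.nm + j]);
    }
    return tot;
  }

  void schedule(int h, long long now) {
    int s = headState[h];
    long long g;
    if (s == 1) {
      g = geomSteps(-std::expm1(-bindTotalRate(h) * P.dt));
      nextTrans[h] = 0;
    } else {
      double x = crownZ(h) - az[(size_t)headThin[h] * M.nm + headMono[h]];
      double k23, k32, kA, kB;
      int cA, cB;
      k23f(P, x, k23, k32);
      if (s == 2) {
        kA = k21f(P, x); cA = 1;
        kB = k23; cB = 2;
      } else {
        kA = k32; cA = 3;
        kB = k31f(P, x); cB = 4;
      }
      long long gA = geomSteps(-std::expm1(-kA * P.dt));
      long long gB = geomSteps(-std::expm1(-kB * P.dt));
      if (gA <= gB) { g = gA; nextTrans[h] = cA; }
      else { g = gB; nextTrans[h] = cB; }
    }
    nextStep[h] = (g >= NEVER) ? NEVER : now + g;
  }

  // resample only heads whose rate inputs changed: heads wired to thin
  // filaments that moved (or whose occupancy changed) and heads of thick
  // filaments that moved
  void rescheduleAffected(long long now) {
    ++stamp;
    for (int t = 0; t < M.Tn; ++t) {
      if (!rx.movedThin[t]) continue;
      rx.movedThin[t] = 0;
      for (int h : targetHeads[t]) {
        if (schedStamp[h] == stamp) continue;
        schedStamp[h] = stamp;
        schedule(h, now);
      }
    }
    int perF = M.nc * hpc;
    for (int f = 0; f < M.F; ++f) {
      if (!rx.movedThick[f]) continue;
      rx.movedThick[f] = 0;
      for (int h = f * perF; h < (f + 1) * perF; ++h) {
        if (schedStamp[h] == stamp) continue;
        schedStamp[h] = stamp;
        schedule(h, now);
      }
    }
  }

  void markEvent(int h, int t) {
    rx.markThin(t);
    rx.markThick(thickOf(h));
    rx.movedThin[t] = 1;    // occupancy/rate change even without motion
    rx.movedThick[thickOf(h)] = 1;
  }

  bool applyBind(int h) {
    int t = headThin[h];
    double y = crownZ(h);
    int jlo, jhi;
    siteRange(t, y, jlo, jhi);
    double tot = 0;
    int cnt = 0;
    int idx[32];
    double w[32];
    for (int j = jlo; j <= jhi && cnt < 32; ++j) {
      if (occ[(size_t)t * M.nm + j] >= 0) continue;
      w[cnt] = k12f(P, y - az[(size_t)t * M.nm + j]);
      idx[cnt] = j;
      tot += w[cnt];
      ++cnt;
    }
    if (!cnt || tot <= 0) return false;
    double u = unif() * tot, acc = 0;
    int pick = idx[cnt - 1];
    for (int i = 0; i < cnt; ++i) {
      acc += w[i];
      if (u <= acc) { pick = idx[i]; break; }
    }
    headState[h] = 2;
    headMono[h] = pick;
    occ[(size_t)t * M.nm + pick] = h;
    view.add(t, pick, crownG(h), h, 0.0);
    markEvent(h, t);
    return true;
  }

  void detach(int h) {
    int t = headThin[h];
    view.remove(t, crownG(h), h);
    occ[(size_t)t * M.nm + headMono[h]] = -1;
    headState[h] = 1;
    headMono[h] = -1;
    markEvent(h, t);
  }

  void setState(int h, int s) {
    headState[h] = s;
    view.setOffset(headThin[h], crownG(h), h, s == 3 ? P.d : 0.0);
    markEvent(h, headThin[h]);
  }

  void solveMech(long long step) {
    int it = rx.run(az, my, M, view, ws, tol, maxit, hpc);
    if (it < 0)
      stop("equilibrium solve did not converge at step " +
           std::to_string((double)step));
    ++nSolves;
  }
};

// [[Rcpp::export]]
List cxx_run_sim(List lt, List rp, double duration, int seed, double recordDt,
                 double snapshotDt, double snapshotStart, bool rigid,
                 double tol, int maxit, bool logEvents) {
  Engine E;
  E.M = mechFromList(lt);
  E.P = rateFromList(rp);
  E.hpc = lt["headsPerCrown"];
  E.H = E.M.F * E.M.nc * E.hpc;
  NumericMatrix azR = lt["actinZ"], myR = lt["myosinZ"];
  E.az.assign(azR.begin(), azR.end());
  E.my.assign(myR.begin(), myR.end());
  IntegerVector ht = lt["headThin"];
  E.headThin.resize(E.H);
  E.targetHeads.assign(E.M.Tn, {});
  for (int h = 0; h < E.H; ++h) {
    E.headThin[h] = ht[h] - 1;
    E.targetHeads[E.headThin[h]].push_back(h);
  }
  E.headState.assign(E.H, 1);
  E.headMono.assign(E.H, -1);
  E.occ.assign((size_t)E.M.Tn * E.M.nm, -1);
  E.nextStep.assign(E.H, NEVER);
  E.nextTrans.assign(E.H, 0);
  E.schedStamp.assign(E.H, -1);
  E.view.init(E.M.Tn, E.M.F * E.M.nc);
  E.ws.init(std::max(E.M.nm, E.M.nc));
  E.rx.init(E.M.Tn, E.M.F);
  E.rng.seed((uint64_t)(uint32_t)seed + 0x9E3779B97F4A7C15ULL);
  E.rigid = rigid;
  E.tol = tol;
  E.maxit = maxit;

  attIntoView(lt, E.P.d, E.M, E.view, &E.headState, &E.headMono, &E.occ);
  bool anyInit = false;
  for (int h = 0; h < E.H; ++h) anyInit = anyInit || (E.headState[h] != 1);
  // a lattice with no attachments is already at its exact rest state; the
  // residual bounds stay flagged so the first event triggers a full solve
  if (anyInit && !rigid) E.solveMech(0);

  double dt = E.P.dt;
  long long nsteps = (long long)std::llround(duration / dt);
  long long recStride = std::max(1LL, (long long)std::llround(recordDt / dt));
  long long snapStride =
      snapshotDt > 0 ? std::max(1LL, (long long)std::llround(snapshotDt / dt))
                     : NEVER;
  long long snapFrom =
      snapshotDt > 0 ? (long long)std::llround(snapshotStart / dt) : NEVER;

  int nRec = (int)(nsteps / recStride) + 1;
  NumericVector times(nRec);
  NumericMatrix thinF(nRec, E.M.Tn), thickF(nRec, E.M.F);
  IntegerMatrix n2(nRec, E.M.F), n3(nRec, E.M.F);
  NumericVector xbSum(nRec), xbCount(nRec);
  std::vector<NumericMatrix> snaps;
  std::vector<double> snapTimes;
  std::vector<int> evStep, evHead, evFrom, evTo, evThin, evMono;
  long long nEvents = 0;

  auto record = [&](int r, long long step) {
    times[r] = step * dt;
    for (int t = 0; t < E.M.Tn; ++t)
      thinF(r, t) =
          E.M.ka * (E.az[(size_t)t * E.M.nm + 1] - E.az[(size_t)t * E.M.nm] -
                    E.M.s0);
    for (int f = 0; f < E.M.F; ++f)
      thickF(r, f) =
          E.M.kb0 * (E.M.anchor - E.my[(size_t)f * E.M.nc] - E.M.bare);
    double fs = 0;
    int cnt = 0;
    for (int h = 0; h < E.H; ++h) {
      if (E.headState[h] == 1) continue;
      int f = E.thickOf(h);
      if (E.headState[h] == 2) n2(r, f)++; else n3(r, f)++;
      double x = E.crownZ(h) -
                 E.az[(size_t)E.headThin[h] * E.M.nm + E.headMono[h]];
      fs += E.P.kappa * (x + (E.headState[h] == 3 ? E.P.d : 0.0));
      ++cnt;
    }
    xbSum[r] = fs;
    xbCount[r] = cnt;
  };
  auto snapshot = [&](long long step) {
    NumericMatrix s(E.M.nm, E.M.Tn);
    std::copy(E.az.begin(), E.az.end(), s.begin());
    snaps.push_back(s);
    snapTimes.push_back(step * dt);
  };

  E.rescheduleAffected(0);  // everything starts flagged as moved
  long long nextRec = 0;
  long long nextSnap = snapFrom;
  std::vector<int> firing;

  while (true) {
    long long sev = NEVER;
    for (int h = 0; h < E.H; ++h) sev = std::min(sev, E.nextStep[h]);
    long long upto = std::min(sev, nsteps + 1);
    while (nextRec < upto && nextRec <= nsteps) {
      record((int)(nextRec / recStride), nextRec);
      nextRec += recStride;
    }
    while (nextSnap < upto && nextSnap <= nsteps) {
      snapshot(nextSnap);
      nextSnap += snapStride;
    }
    if (sev > nsteps) break;

    firing.clear();
    for (int h = 0; h < E.H; ++h)
      if (E.nextStep[h] == sev) firing.push_back(h);
    bool changed = false;
    for (int h : firing) {
      int from = E.headState[h];
      int code = E.nextTrans[h];
      bool ok = false;
      int to = from;
      switch (code) {
        case 0:
          if (from == 1) { ok = E.applyBind(h); to = 2; }
          break;
        case 1:
          if (from == 2) { E.detach(h); ok = true; to = 1; }
          break;
        case 2:
          if (from == 2) { E.setState(h, 3); ok = true; to = 3; }
          break;
        case 3:
          if (from == 3) { E.setState(h, 2); ok = true; to = 2; }
          break;
        case 4:
          if (from == 3) { E.detach(h); ok = true; to = 1; }
          break;
      }
      if (!ok) E.schedule(h, sev);  // stale transition: resample only
      if (ok) {
        ++nEvents;
        changed = true;
        if (logEvents) {
          evStep.push_back((int)sev);
          evHead.push_back(h + 1);
          evFrom.push_back(from);
          evTo.push_back(to);
          evThin.push_back(E.headThin[h] + 1);
          evMono.push_back(E.headMono[h] >= 0 ? E.headMono[h] + 1 : NA_INTEGER);
        }
      }
    }
    if (changed && !E.rigid) E.solveMech(sev);
    E.rescheduleAffected(sev);
    if ((nEvents & 0xFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int nb = 0;
  for (int h = 0; h < E.H; ++h) nb += (E.headState[h] != 1);
  IntegerVector fh(nb), ft(nb), fm(nb), fs(nb);
  for (int h = 0, i = 0; h < E.H; ++h) {
    if (E.headState[h] == 1) continue;
    fh[i] = h + 1; ft[i] = E.headThin[h] + 1; fm[i] = E.headMono[h] + 1;
    fs[i] = E.headState[h];
    ++i;
  }
  NumericMatrix azOut(E.M.nm, E.M.Tn), myOut(E.M.nc, E.M.F);
  std::copy(E.az.begin(), E.az.end(), azOut.begin());
  std::copy(E.my.begin(), E.my.end(), myOut.begin());
  double finalResid =
      rigid ? 0.0 : residualForce(E.az, E.my, E.M, E.view, E.ws);

  return List::create(
      _["times"] = times, _["thinForce"] = thinF, _["thickForce"] = thickF,
      _["nState2"] = n2, _["nState3"] = n3, _["xbForceSum"] = xbSum,
      _["xbCount"] = xbCount, _["snapshots"] = wrap(snaps),
      _["snapshotTimes"] = wrap(snapTimes),
      _["events"] = List::create(_["step"] = wrap(evStep),
                                 _["head"] = wrap(evHead),
                                 _["from"] = wrap(evFrom),
                                 _["to"] = wrap(evTo),
                                 _["thin"] = wrap(evThin),
                                 _["monomer"] = wrap(evMono)),
      _["actinZ"] = azOut, _["myosinZ"] = myOut,
      _["attHead"] = fh, _["attThin"] = ft, _["attMonomer"] = fm,
      _["attState"] = fs, _["nEvents"] = (double)nEvents,
      _["nSolves"] = (double)E.nSolves, _["residual"] = finalResid);
}

// ---------------------------------------------------------------------------
// Meridional diffraction sum
// ---------------------------------------------------------------------------

// Incoherent sum over filaments of |sum_j f(Z) exp(2 pi i Z z_j)|^2.
// Uses a phase recurrence along uniform Z grids; falls back to direct
// evaluation on non-uniform grids.
// [[Rcpp::export]]
NumericVector cxx_meridional_intensity(List positions, NumericVector Z,
                                       NumericVector formFactor2) {
  int nZ = Z.size();
  NumericVector I(nZ);
  bool uniform = true;
  double dZ = nZ > 1 ? Z[1] - Z[0] : 0.0;
  for (int k = 2; k < nZ; ++k)
    if (std::fabs((Z[k] - Z[k - 1]) - dZ) > 1e-12 * std::fabs(dZ)) {
      uniform = false;
      break;
    }
  std::vector<double> accRe(nZ), accIm(nZ);
  const double twoPi = 2.0 * M_PI;
  for (int fi = 0; fi < positions.size(); ++fi) {
    NumericVector z = positions[fi];
    if (z.size() == 0) stop("empty position set for filament %d", fi + 1);
    std::fill(accRe.begin(), accRe.end(), 0.0);
    std::fill(accIm.begin(), accIm.end(), 0.0);
    if (uniform && nZ > 4) {
      for (int j = 0; j < z.size(); ++j) {
        double pr = std::cos(twoPi * Z[0] * z[j]),
               pi = std::sin(twoPi * Z[0] * z[j]);
        double sr = std::cos(twoPi * dZ * z[j]),
               si = std::sin(twoPi * dZ * z[j]);
        for (int k = 0; k < nZ; ++k) {
          accRe[k] += pr;
          accIm[k] += pi;
          double nr = pr * sr - pi * si;
          pi = pr * si + pi * sr;
          pr = nr;
        }
      }
    } else {
      for (int k = 0; k < nZ; ++k) {
        double re = 0, im = 0;
        for (int j = 0; j < z.size(); ++j) {
          re += std::cos(twoPi * Z[k] * z[j]);
          im += std::sin(twoPi * Z[k] * z[j]);
        }
        accRe[k] = re;
        accIm[k] = im;
      }
    }
    for (int k = 0; k < nZ; ++k)
      I[k] += accRe[k] * accRe[k] + accIm[k] * accIm[k];
  }
  if (formFactor2.size() == nZ)
    for (int k = 0; k < nZ; ++k) I[k] *= formFactor2[k];
  return I;
}
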