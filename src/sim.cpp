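// Compiled core of the individual-based simulator: cell-list neighbor
// search, synchronous schooling/diffusion movement sub-steps, and the
// daily demographic + fleet event loop.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <chrono>
using namespace Rcpp;

namespace {
struct SectionTimers {
  double pack = 0, scan = 0, demog = 0, fleet = 0;
  double nbr_sum = 0, nbr_n = 0, nbr_max = 0;
};
SectionTimers g_timers;
inline double now_s() {
  return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
}
}

namespace {

struct EnvFields {
  int nx, ny;
  const double *u, *v, *gx, *gy;  // nx x ny, column-major (ix + nx*iy)
  inline int sector_x(double x) const {
    int i = (int)std::floor(x);
    if (i < 0) i = 0; if (i >= nx) i = nx - 1;
    return i;
  }
  inline int sector_y(double y) const {
    int j = (int)std::floor(y);
    if (j < 0) j = 0; if (j >= ny) j = ny - 1;
    return j;
  }
  inline int sector(double x, double y) const {
    return sector_x(x) + nx * sector_y(y);
  }
};

struct MoveParams {
  bool social, use_sst, use_currents;
  double rr, ro, ra, alpha, beta, diff_coef, dt;
  double egg_speed_lo, egg_speed_hi;
  int egg_decay_days;
  double adult_speed_lo, adult_speed_hi;
  int juvenile_age, maturity_age;
};

struct Fish {
  std::vector<double> x, y, ux, uy, v, adult_v, natal_v;
  std::vector<int> age, repro_day;
  size_t size() const { return x.size(); }
  void reserve(size_t n) {
    x.reserve(n); y.reserve(n); ux.reserve(n); uy.reserve(n); v.reserve(n);
    adult_v.reserve(n); natal_v.reserve(n); age.reserve(n);
    repro_day.reserve(n);
  }
  void push(double xi, double yi, double uxi, double uyi, double vi,
            double avi, double nvi, int agei, int rdi) {
    x.push_back(xi); y.push_back(yi); ux.push_back(uxi); uy.push_back(uyi);
    v.push_back(vi); adult_v.push_back(avi); natal_v.push_back(nvi);
    age.push_back(agei); repro_day.push_back(rdi);
  }
  void compact(const std::vector<char>& dead) {
    size_t w = 0, n = size();
    for (size_t i = 0; i < n; ++i) {
      if (dead[i]) continue;
      if (w != i) {
        x[w] = x[i]; y[w] = y[i]; ux[w] = ux[i]; uy[w] = uy[i];
        v[w] = v[i]; adult_v[w] = adult_v[i]; natal_v[w] = natal_v[i];
        age[w] = age[i]; repro_day[w] = repro_day[i];
      }
      ++w;
    }
    x.resize(w); y.resize(w); ux.resize(w); uy.resize(w); v.resize(w);
    adult_v.resize(w); natal_v.resize(w); age.resize(w); repro_day.resize(w);
  }
};

// Mirror reflection into [0, L]; flips the matching heading component.
inline void reflect1(double& z, double& u, double L) {
  if (z < 0) { z = -z; u = -u; }
  if (z > L) { z = 2 * L - z; u = -u; }
  // a second pass catches displacements up to one domain width
  if (z < 0) { z = -z; u = -u; }
  if (z > L) { z = 2 * L - z; u = -u; }
}

// Cell list over social participants (cell side = attraction radius).
struct CellList {
  int cx, cy;
  double cell, inv;
  std::vector<int> head, nxt;
  std::vector<int> touched;
  void init(int nx, int ny, double ra) {
    // cell side >= interaction radius (3x3 block covers it); floor bounds
    // the table size for very small radii
    cell = std::max(ra, std::max(nx, ny) / 4096.0);
    inv = 1.0 / cell;
    cx = (int)std::ceil(nx / cell) + 1;
    cy = (int)std::ceil(ny / cell) + 1;
    head.assign((size_t)cx * cy, -1);
  }
  inline int cell_of(double x, double y) const {
    int i = (int)(x * inv), j = (int)(y * inv);
    if (i >= cx) i = cx - 1; if (j >= cy) j = cy - 1;
    if (i < 0) i = 0; if (j < 0) j = 0;
    return i + cx * j;
  }
  void build(const Fish& F, const std::vector<int>& members) {
    for (int c : touched) head[c] = -1;
    touched.clear();
    nxt.assign(F.size(), -1);
    for (int i : members) {
      int c = cell_of(F.x[i], F.y[i]);
      if (head[c] == -1) touched.push_back(c);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Reusable buffers for the synchronous update. The scan structure packs
// the social participants into cell-ordered contiguous arrays each
// sub-step (counting sort over occupied cells), so the 3x3-block neighbor
// scans walk linear memory.
struct Work {
  std::vector<double> nx_, ny_, nux, nuy, nv;
  std::vector<int> members;
  std::vector<long long> keys;
  // compact scan structure
  std::vector<double> sx, sy, sux, suy, sv;
  std::vector<int> sid;                  // original fish index
  std::vector<int> slot;                 // cell -> touched slot (-1 empty)
  std::vector<int> tcell, tstart, tcount;  // per touched cell
};

// Reorder all per-fish arrays by grid cell (counting locality sort); run
// once per day so the neighbor scans walk near-contiguous memory.
void sort_by_cell(Fish& F, const CellList& cl, Work& W) {
  const size_t n = F.size();
  if (n < 2) return;
  W.keys.resize(n);
  for (size_t i = 0; i < n; ++i)
    W.keys[i] = ((long long)cl.cell_of(F.x[i], F.y[i]) << 24) | (long long)i;
  std::sort(W.keys.begin(), W.keys.end());
  Fish G;
  G.reserve(n);
  for (size_t w = 0; w < n; ++w) {
    size_t i = (size_t)(W.keys[w] & 0xFFFFFF);
    G.push(F.x[i], F.y[i], F.ux[i], F.uy[i], F.v[i], F.adult_v[i],
           F.natal_v[i], F.age[i], F.repro_day[i]);
  }
  F = std::move(G);
}

// One synchronous movement sub-step for the whole population.
void substep(Fish& F, const EnvFields& env, const MoveParams& P,
             CellList& cl, Work& W) {
  const size_t n = F.size();
  if (n == 0) return;
  const double tol = 1e-12;
  W.nx_.resize(n); W.ny_.resize(n); W.nux.resize(n); W.nuy.resize(n);
  W.nv.resize(n);
  std::vector<double>& nx_ = W.nx_;
  std::vector<double>& ny_ = W.ny_;
  std::vector<double>& nux = W.nux;
  std::vector<double>& nuy = W.nuy;
  std::vector<double>& nv = W.nv;

  if (!P.social) {
    // diffusive scenario: Gaussian walk, MSD = 4 D t
    const double sd = std::sqrt(2.0 * P.diff_coef * P.dt);
    for (size_t i = 0; i < n; ++i) {
      double x = F.x[i] + norm_rand() * sd;
      double y = F.y[i] + norm_rand() * sd;
      double ux = F.ux[i], uy = F.uy[i];
      reflect1(x, ux, (double)env.nx);
      reflect1(y, uy, (double)env.ny);
      nx_[i] = x; ny_[i] = y; nux[i] = ux; nuy[i] = uy; nv[i] = F.v[i];
    }
  } else {
    double t0 = now_s();
    // pack social participants (juveniles and adults) into cell order
    std::vector<int>& members = W.members;
    members.clear();
    for (size_t i = 0; i < n; ++i)
      if (F.age[i] >= P.juvenile_age) members.push_back((int)i);
    const size_t ncell = (size_t)cl.cx * cl.cy;
    if (W.slot.size() != ncell) W.slot.assign(ncell, -1);
    else for (int c : W.tcell) W.slot[c] = -1;
    W.tcell.clear(); W.tcount.clear(); W.tstart.clear();
    for (int m : members) {
      int c = cl.cell_of(F.x[m], F.y[m]);
      int t = W.slot[c];
      if (t == -1) {
        t = (int)W.tcell.size();
        W.slot[c] = t;
        W.tcell.push_back(c);
        W.tcount.push_back(0);
      }
      ++W.tcount[t];
    }
    W.tstart.resize(W.tcell.size());
    int acc = 0;
    for (size_t t = 0; t < W.tcell.size(); ++t) {
      W.tstart[t] = acc;
      acc += W.tcount[t];
    }
    const size_t nm = members.size();
    W.sx.resize(nm); W.sy.resize(nm); W.sux.resize(nm); W.suy.resize(nm);
    W.sv.resize(nm); W.sid.resize(nm);
    {
      std::vector<int> pos = W.tstart;
      for (int m : members) {
        int t = W.slot[cl.cell_of(F.x[m], F.y[m])];
        int w = pos[t]++;
        W.sx[w] = F.x[m]; W.sy[w] = F.y[m];
        W.sux[w] = F.ux[m]; W.suy[w] = F.uy[m];
        W.sv[w] = F.v[m]; W.sid[w] = m;
      }
    }
    const double rr2 = P.rr * P.rr, ro2 = P.ro * P.ro, ra2 = P.ra * P.ra;
    const double* sx = W.sx.data();
    const double* sy = W.sy.data();
    const double* sux = W.sux.data();
    const double* suy = W.suy.data();
    const double* sv = W.sv.data();
    const int* sid = W.sid.data();
    double t1 = now_s();
    g_timers.pack += t1 - t0;

    for (size_t i = 0; i < n; ++i) {
      double x = F.x[i], y = F.y[i];
      double vi, dx, dy;       // new speed and travel direction
      double uxi = F.ux[i], uyi = F.uy[i];
      if (F.age[i] < P.juvenile_age) {
        // egg/larva: natal drift decaying to rest over the first week
        double fade = 1.0 - (double)F.age[i] / P.egg_decay_days;
        if (fade < 0) fade = 0;
        vi = F.natal_v[i] * fade;
        dx = uxi; dy = uyi;
      } else {
        // neighbor scan over the 3x3 cell block
        double rep_x = 0, rep_y = 0, ori_x = uxi, ori_y = uyi;
        double att_x = 0, att_y = 0, vsum = F.v[i];
        int nR = 0, nO = 1, nA = 0;  // self included in orientation set
        int ci = (int)(x * cl.inv), cj = (int)(y * cl.inv);
        if (ci >= cl.cx) ci = cl.cx - 1; if (cj >= cl.cy) cj = cl.cy - 1;
        for (int b = cj - 1; b <= cj + 1; ++b) {
          if (b < 0 || b >= cl.cy) continue;
          for (int a = ci - 1; a <= ci + 1; ++a) {
            if (a < 0 || a >= cl.cx) continue;
            int t = W.slot[a + cl.cx * b];
            if (t == -1) continue;
            int w0 = W.tstart[t], w1 = w0 + W.tcount[t];
            for (int w = w0; w < w1; ++w) {
              double ddx = sx[w] - x, ddy = sy[w] - y;
              double d2 = ddx * ddx + ddy * ddy;
              if (d2 > ra2 || (size_t)sid[w] == i) continue;
              if (d2 <= rr2) {
                double d = std::sqrt(d2);
                if (d > 0) { rep_x -= ddx / d; rep_y -= ddy / d; }
                else {
                  double th = unif_rand() * 2 * M_PI;
                  rep_x += std::cos(th); rep_y += std::sin(th);
                }
                ++nR;
              } else if (d2 <= ro2) {
                ori_x += sux[w]; ori_y += suy[w];
                vsum += sv[w];
                ++nO;
              } else {
                double d = std::sqrt(d2);
                att_x += ddx / d; att_y += ddy / d;
                ++nA;
              }
            }
          }
        }
        int nbr = nR + nO - 1 + nA;
        g_timers.nbr_sum += nbr; g_timers.nbr_n += 1;
        if (nbr > g_timers.nbr_max) g_timers.nbr_max = nbr;
        vi = vsum / nO;
        if (F.age[i] < P.maturity_age) {
          // juvenile speed cap: linear ramp from the natal egg speed at
          // the juvenile boundary to the personal adult cruise speed
          double frac = (double)(F.age[i] - P.juvenile_age) /
                        (P.maturity_age - P.juvenile_age);
          double cap = F.natal_v[i] + (F.adult_v[i] - F.natal_v[i]) * frac;
          if (vi > cap) vi = cap;
        }
        double inv = 1.0 / (nR + nO + nA);
        double dsx = (rep_x + ori_x + att_x) * inv;
        double dsy = (rep_y + ori_y + att_y) * inv;
        double nd = std::sqrt(dsx * dsx + dsy * dsy);
        double dhx, dhy;
        if (nd > tol) { dhx = dsx / nd; dhy = dsy / nd; }
        else { dhx = uxi; dhy = uyi; }
        double Dx = P.alpha * dhx, Dy = P.alpha * dhy;
        if (P.use_sst) {
          int s = env.sector(x, y);
          Dx += P.beta * env.gx[s];
          Dy += P.beta * env.gy[s];
        }
        double nD = std::sqrt(Dx * Dx + Dy * Dy);
        if (nD > tol) { dx = Dx / nD; dy = Dy / nD; }
        else { dx = uxi; dy = uyi; }
      }
      double xn = x + P.dt * vi * dx;
      double yn = y + P.dt * vi * dy;
      if (P.use_currents) {
        int s = env.sector(x, y);
        xn += P.dt * env.u[s];
        yn += P.dt * env.v[s];
      }
      double uxn = dx, uyn = dy;
      reflect1(xn, uxn, (double)env.nx);
      reflect1(yn, uyn, (double)env.ny);
      nx_[i] = xn; ny_[i] = yn; nux[i] = uxn; nuy[i] = uyn; nv[i] = vi;
    }
    g_timers.scan += now_s() - t1;
  }
  F.x.swap(nx_); F.y.swap(ny_); F.ux.swap(nux); F.uy.swap(nuy); F.v.swap(nv);
}

inline int clamp_doy(double d) {
  int r = (int)std::lround(d);
  if (r < 1) r = 1; if (r > 365) r = 365;
  return r;
}

}  // namespace

// [[Rcpp::export]]
List sim_run_cpp(NumericVector x0, NumericVector y0, NumericVector heading0,
                 NumericVector speed0, IntegerVector age0,
                 IntegerVector repro_day0, NumericVector adult_speed0,
                 NumericVector natal_speed0,
                 int nx, int ny, NumericMatrix u, NumericMatrix v,
                 NumericMatrix gx, NumericMatrix gy,
                 bool social, bool use_sst, bool use_currents,
                 double rr, double ro, double ra, double alpha, double beta,
                 double diff_coef, double dt, int n_substeps,
                 double adult_speed_lo, double adult_speed_hi,
                 double egg_speed_lo, double egg_speed_hi, int egg_decay_days,
                 double z_young, double z_old, int fecundity,
                 int juvenile_age, int maturity_age,
                 double spawn_mu, double spawn_sd, double K, double r_growth,
                 double n_boats, double c_aggr, double F_annual,
                 double q_scale, int total_years, int fishing_start,
                 int mpa_start, LogicalMatrix mpa_closed,
                 bool daily_record, bool verbose,
                 int start_year = 1, bool return_state = false) {
  g_timers = SectionTimers();
  const int n0 = x0.size();
  Fish F;
  F.reserve((size_t)n0 * 2);
  for (int i = 0; i < n0; ++i)
    F.push(x0[i], y0[i], std::cos(heading0[i]), std::sin(heading0[i]),
           speed0[i], adult_speed0[i], natal_speed0[i], age0[i],
           repro_day0[i]);

  EnvFields env{nx, ny, u.begin(), v.begin(), gx.begin(), gy.begin()};
  MoveParams P{social, use_sst, use_currents, rr, ro, ra, alpha, beta,
               diff_coef, dt, egg_speed_lo, egg_speed_hi, egg_decay_days,
               adult_speed_lo, adult_speed_hi, juvenile_age, maturity_age};
  CellList cl;
  cl.init(nx, ny, ra);
  Work W;

  const int n_sectors = nx * ny;
  std::vector<int> open_idx;
  for (int s = 0; s < n_sectors; ++s)
    if (!mpa_closed[s]) open_idx.push_back(s);

  IntegerVector adults_census(total_years), landings_y(total_years),
      juveniles_end(total_years), eggs_end(total_years),
      adults_end(total_years);
  NumericVector rec_target_y(total_years), realized_F(total_years);
  std::vector<int> daily_landings, daily_adults;
  if (daily_record) {
    daily_landings.reserve((size_t)total_years * 365);
    daily_adults.reserve((size_t)total_years * 365);
  }
  int extinction_year = 0;
  double max_boat_dev = 0;
  long closed_landings = 0;
  // abundance-weighted fishing hazard over all fished days: the
  // "average over space and time" fishing mortality per fish-day
  double haz_num = 0, haz_den = 0;

  std::vector<int> count(n_sectors);
  std::vector<double> p_capt(n_sectors), hazard(n_sectors);
  double rec_target = 0;
  const double F_daily = F_annual / 365.0;
  const int old_age = 5 * 365;

  for (int year = start_year; year <= total_years; ++year) {
    const bool fishing = (F_annual > 0) && (year > fishing_start);
    const bool mpa_on = year > mpa_start;
    long land_year = 0;
    double Fhaz_year = 0;

    for (int doy = 1; doy <= 365; ++doy) {
      size_t n = F.size();
      // annual census: logistic recruitment target from adult count
      if (doy == 1) {
        int N_t = 0;
        for (size_t i = 0; i < n; ++i)
          if (F.age[i] >= maturity_age) ++N_t;
        rec_target = r_growth * N_t * (1.0 - (double)N_t / K);
        if (rec_target < 0) rec_target = 0;
        adults_census[year - 1] = N_t;
        rec_target_y[year - 1] = rec_target;
      }
      double td0 = now_s();
      // (1) ageing
      for (size_t i = 0; i < n; ++i) ++F.age[i];
      // (2) natural mortality; eggs face the density-dependent hazard
      long neggs = 0;
      for (size_t i = 0; i < n; ++i)
        if (F.age[i] < juvenile_age) ++neggs;
      double s_prob = 1.0;
      if (neggs > 0) {
        s_prob = rec_target / (double)neggs;
        if (s_prob > 1) s_prob = 1;
        if (s_prob < 0) s_prob = 0;
      }
      std::vector<char> dead(n, 0);
      bool any_dead = false;
      for (size_t i = 0; i < n; ++i) {
        double p;
        if (F.age[i] < juvenile_age) p = 1.0 - s_prob;
        else if (F.age[i] < old_age) p = z_young;
        else p = z_old;
        if (unif_rand() < p) { dead[i] = 1; any_dead = true; }
      }
      if (any_dead) F.compact(dead);
      n = F.size();
      // (3) spawning
      for (size_t i = 0, n_par = n; i < n_par; ++i) {
        if (F.age[i] < maturity_age || F.repro_day[i] != doy) continue;
        double px = F.x[i], py = F.y[i];
        for (int e = 0; e < fecundity; ++e) {
          double th = unif_rand() * 2 * M_PI;
          double nv = egg_speed_lo + unif_rand() * (egg_speed_hi - egg_speed_lo);
          double av = adult_speed_lo +
                      unif_rand() * (adult_speed_hi - adult_speed_lo);
          int rd = clamp_doy(norm_rand() * spawn_sd + spawn_mu);
          F.push(px, py, std::cos(th), std::sin(th), nv, av, nv, 0, rd);
        }
        F.repro_day[i] = clamp_doy(norm_rand() * spawn_sd + spawn_mu);
      }
      n = F.size();
      g_timers.demog += now_s() - td0;
      // (4) movement sub-steps (daily locality sort keeps scans cache-friendly)
      if (social) sort_by_cell(F, cl, W);
      for (int s = 0; s < n_substeps; ++s) substep(F, env, P, cl, W);
      // (5) fleet reallocation and fishing mortality
      double tf0 = now_s();
      int n_adults = 0;
      if (fishing && n > 0) {
        std::fill(count.begin(), count.end(), 0);
        for (size_t i = 0; i < n; ++i)
          if (F.age[i] >= maturity_age) {
            ++count[env.sector(F.x[i], F.y[i])];
            ++n_adults;
          }
        int M = 0;
        if (mpa_on) {
          for (int s : open_idx)
            if (count[s] > M) M = count[s];
        } else {
          for (int s = 0; s < n_sectors; ++s)
            if (count[s] > M) M = count[s];
        }
        double rel_sum = 0;
        std::fill(hazard.begin(), hazard.end(), 0.0);
        for (int s = 0; s < n_sectors; ++s) {
          bool closed = mpa_on && mpa_closed[s];
          double rel = 0;
          if (!closed)
            rel = (M > 0) ? std::exp(-c_aggr * (1.0 - (double)count[s] / M))
                          : std::exp(-c_aggr);
          hazard[s] = rel;  // relative effort, scaled below
          rel_sum += rel;
        }
        double boat_sum = 0, Hsum = 0;
        for (int s = 0; s < n_sectors; ++s) {
          double boats = n_boats * hazard[s] / rel_sum;
          boat_sum += boats;
          double h = F_daily * boats * q_scale;
          hazard[s] = h;
          p_capt[s] = 1.0 - std::exp(-h);
          Hsum += (double)count[s] * h;
        }
        double dev = std::fabs(boat_sum - n_boats);
        if (dev > max_boat_dev) max_boat_dev = dev;
        if (n_adults > 0) Fhaz_year += Hsum / n_adults;
        haz_num += Hsum; haz_den += n_adults;
        std::vector<char> caught(n, 0);
        bool any = false;
        long land_day = 0;
        for (size_t i = 0; i < n; ++i) {
          if (F.age[i] < maturity_age) continue;
          int s = env.sector(F.x[i], F.y[i]);
          if (mpa_on && mpa_closed[s]) continue;
          if (unif_rand() < p_capt[s]) {
            caught[i] = 1; any = true; ++land_day;
            if (mpa_on && mpa_closed[s]) ++closed_landings;  // never reached
          }
        }
        if (any) F.compact(caught);
        land_year += land_day;
        if (daily_record) daily_landings.push_back((int)land_day);
      } else if (daily_record) {
        daily_landings.push_back(0);
      }
      g_timers.fleet += now_s() - tf0;
      if (daily_record) {
        int na = 0;
        for (size_t i = 0; i < F.size(); ++i)
          if (F.age[i] >= maturity_age) ++na;
        daily_adults.push_back(na);
      }
    }  // doy

    // year-end stage counts
    int ne = 0, nj = 0, na = 0;
    for (size_t i = 0; i < F.size(); ++i) {
      if (F.age[i] < juvenile_age) ++ne;
      else if (F.age[i] < maturity_age) ++nj;
      else ++na;
    }
    eggs_end[year - 1] = ne;
    juveniles_end[year - 1] = nj;
    adults_end[year - 1] = na;
    landings_y[year - 1] = (int)land_year;
    realized_F[year - 1] = Fhaz_year;
    if (F.size() == 0 && extinction_year == 0) extinction_year = year;
    if (verbose)
      Rprintf("year %d: density %d, landings %ld, adults %d\n",
              year, ne + nj + na, land_year, na);
    Rcpp::checkUserInterrupt();
  }

  List out = List::create(
      _["adults_census"] = adults_census, _["rec_target"] = rec_target_y,
      _["eggs_end"] = eggs_end, _["juveniles_end"] = juveniles_end,
      _["adults_end"] = adults_end, _["landings"] = landings_y,
      _["realized_F"] = realized_F,
      _["mean_F"] = haz_den > 0 ? 365.0 * haz_num / haz_den : 0.0,
      _["extinction_year"] = extinction_year,
      _["max_boat_dev"] = max_boat_dev,
      _["timers"] = NumericVector::create(g_timers.pack, g_timers.scan,
                                          g_timers.demog, g_timers.fleet,
                                          g_timers.nbr_sum / std::max(1.0, g_timers.nbr_n),
                                          g_timers.nbr_max),
      _["closed_landings"] = (double)closed_landings);
  if (daily_record) {
    out["daily_landings"] = wrap(daily_landings);
    out["daily_adults"] = wrap(daily_adults);
  }
  if (return_state) {
    const size_t nf = F.size();
    NumericVector hx(nf);
    for (size_t i = 0; i < nf; ++i) hx[i] = std::atan2(F.uy[i], F.ux[i]);
    out["state"] = List::create(
        _["x"] = wrap(F.x), _["y"] = wrap(F.y), _["heading"] = hx,
        _["speed"] = wrap(F.v), _["age"] = wrap(F.age),
        _["repro_day"] = wrap(F.repro_day),
        _["adult_speed"] = wrap(F.adult_v),
        _["natal_speed"] = wrap(F.natal_v));
  }
  return out;
}

// One synchronous movement sub-step over the whole population; same code
// path as the engine loop (used for cross-checks against the plain-R
// single-fish operations).
// [[Rcpp::export]]
List move_substep_cpp(NumericVector x, NumericVector y,
                      NumericVector heading, NumericVector speed,
                      IntegerVector age, NumericVector adult_speed,
                      NumericVector natal_speed,
                      int nx, int ny, NumericMatrix u, NumericMatrix v,
                      NumericMatrix gx, NumericMatrix gy,
                      bool social, bool use_sst, bool use_currents,
                      double rr, double ro, double ra,
                      double alpha, double beta,
                      double diff_coef, double dt,
                      int egg_decay_days = 7, int juvenile_age = 183,
                      int maturity_age = 365) {
  Fish F;
  const int n = x.size();
  F.reserve(n);
  for (int i = 0; i < n; ++i)
    F.push(x[i], y[i], std::cos(heading[i]), std::sin(heading[i]), speed[i],
           adult_speed[i], natal_speed[i], age[i], 250);
  EnvFields env{nx, ny, u.begin(), v.begin(), gx.begin(), gy.begin()};
  MoveParams P{social, use_sst, use_currents, rr, ro, ra, alpha, beta,
               diff_coef, dt, 0, 0.1, egg_decay_days, 0.42, 0.50,
               juvenile_age, maturity_age};
  CellList cl;
  cl.init(nx, ny, ra);
  Work W;
  substep(F, env, P, cl, W);
  NumericVector hx(n);
  for (int i = 0; i < n; ++i) hx[i] = std::atan2(F.uy[i], F.ux[i]);
  return List::create(_["x"] = wrap(F.x), _["y"] = wrap(F.y),
                      _["heading"] = hx, _["speed"] = wrap(F.v));
}

// Cell-list neighbor sets of fish k (1-based); eligibility mask marks the
// social participants. Returns 1-based sorted index vectors.
// [[Rcpp::export]]
List neighbor_sets_cpp(NumericVector x, NumericVector y,
                       LogicalVector eligible, int k,
                       double rr, double ro, double ra) {
  const int n = x.size();
  Fish F;
  F.reserve(n);
  for (int i = 0; i < n; ++i)
    F.push(x[i], y[i], 1, 0, 0, 0, 0, 365, 250);
  CellList cl;
  // domain bounds just large enough for the data
  double xmax = 1, ymax = 1;
  for (int i = 0; i < n; ++i) {
    if (x[i] > xmax) xmax = x[i];
    if (y[i] > ymax) ymax = y[i];
  }
  cl.init((int)std::ceil(xmax) + 1, (int)std::ceil(ymax) + 1, ra);
  std::vector<int> members;
  for (int i = 0; i < n; ++i) if (eligible[i]) members.push_back(i);
  cl.build(F, members);
  const int k0 = k - 1;
  const double rr2 = rr * rr, ro2 = ro * ro, ra2 = ra * ra;
  std::vector<int> NR, NO, NAt;
  NO.push_back(k);
  int ci = (int)(x[k0] * cl.inv), cj = (int)(y[k0] * cl.inv);
  if (ci >= cl.cx) ci = cl.cx - 1; if (cj >= cl.cy) cj = cl.cy - 1;
  for (int a = ci - 1; a <= ci + 1; ++a) {
    if (a < 0 || a >= cl.cx) continue;
    for (int b = cj - 1; b <= cj + 1; ++b) {
      if (b < 0 || b >= cl.cy) continue;
      for (int j = cl.head[a + cl.cx * b]; j != -1; j = cl.nxt[j]) {
        if (j == k0) continue;
        double dx = x[j] - x[k0], dy = y[j] - y[k0];
        double d2 = dx * dx + dy * dy;
        if (d2 > ra2) continue;
        if (d2 <= rr2) NR.push_back(j + 1);
        else if (d2 <= ro2) NO.push_back(j + 1);
        else NAt.push_back(j + 1);
      }
    }
  }
  std::sort(NR.begin(), NR.end());
  std::sort(NO.begin(), NO.end());
  std::sort(NAt.begin(), NAt.end());
  return List::create(_["NR"] = wrap(NR), _["NO"] = wrap(NO),
                      _["NA_"] = wrap(NAt));
}
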