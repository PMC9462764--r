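// Compiled hot loop of the multiscale desquamation model.
//
// Mirrors the pure-R reference step (step_multiscale) exactly, per mechanics
// step: per-cell chemistry (frozen below the corneum base), pair forces with
// CND-scaled adhesion, basal membrane, rotational forces on dividing pairs,
// removal force on surface cells, forward-Euler positions, divisions,
// detachment cull (or ceiling removal during filling), surface refresh and
// scheduled thickness refresh. All randomness comes from the R session RNG.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <deque>
using namespace Rcpp;

namespace {

struct Pars {
  double Lx, Ly, k_rep, gamma_, alpha_0, k_phi, eta, dt, R_0, cutoff;
  double division_offset, growth_time, dx, F_D, contact_gap, h, f_h;
  double fill_ceiling, s_0, e_T;
  double k_plus1, k_minus1, k_2, a3, b3, A3, B3;
  double ph_c0, ph_c1, ph_c2, ph_c3;
  double cycle_low, cycle_high;
  bool dual_mode, filling;
};

struct Pop {
  std::vector<int> id, type, partner; // type: 0 stem, 1 diff; partner: -1 none
  std::vector<double> x, y, z, radius, birth_time, t_c, i_t_level;
  std::vector<double> e, s, i_, cs, ci, p, entry_time; // entry NaN = unset
  std::vector<int> is_surface;
  size_t n() const { return id.size(); }
};

inline double clamp01(double v) { return v < 0 ? 0 : (v > 1 ? 1 : v); }

// z-bucket index: pair candidates are restricted to the same or adjacent
// bucket (bucket height = cutoff), since |dz| >= cutoff excludes a pair
template <typename F>
void for_candidate_pairs(const std::vector<double>& z, double cutoff, F&& f) {
  size_t n = z.size();
  if (n < 2) return;
  double zmax = 0.0;
  for (double v : z) zmax = std::max(zmax, v);
  int nb = (int)std::floor(zmax / cutoff) + 1;
  std::vector<std::vector<int> > bucket(nb);
  for (size_t m = 0; m < n; ++m)
    bucket[(int)std::floor(z[m] / cutoff)].push_back((int)m);
  for (int b = 0; b < nb; ++b) {
    const std::vector<int>& B = bucket[b];
    for (size_t a = 0; a + 1 < B.size(); ++a)
      for (size_t c = a + 1; c < B.size(); ++c)
        f(std::min(B[a], B[c]), std::max(B[a], B[c]));
    if (b + 1 < nb) {
      for (int i : B)
        for (int j : bucket[b + 1])
          f(std::min(i, j), std::max(i, j));
    }
  }
}

inline double min_img(double d, double L) { return d - L * std::round(d / L); }

inline double ph_at(double xi, const Pars& P) {
  xi = clamp01(xi);
  return P.ph_c0 + xi * (P.ph_c1 + xi * (P.ph_c2 + xi * P.ph_c3));
}

inline double adhesion_shape(double rs, double gam) {
  double c0 = 1.0 / (2.0 * gam);
  return (rs + c0) * std::exp(-gam * (rs + c0) * (rs + c0)) -
         c0 * std::exp(-gam * (rs * rs + c0 * c0));
}

// mass-action RHS of the dimensionless six-species system
inline void chem_rhs(const double* y, double* dy, const Pars& P,
                     double k3p, double k3m) {
  double e = y[0], s = y[1], i = y[2], cs = y[3], ci = y[4];
  double bind_s = P.k_plus1 * P.s_0 * e * s;
  double unbind_s = (P.k_minus1 + P.k_2) * cs;
  double bind_i = k3p * P.s_0 * e * i;
  double unbind_i = k3m * ci;
  double r = P.e_T / P.s_0;
  dy[0] = -bind_s + unbind_s - bind_i + unbind_i;
  dy[1] = -P.k_plus1 * P.e_T * e * s + P.k_minus1 * r * cs;
  dy[2] = -k3p * P.e_T * e * i + k3m * r * ci;
  dy[3] = bind_s - unbind_s;
  dy[4] = bind_i - unbind_i;
  dy[5] = P.k_2 * r * cs;
}

// fixed-substep RK4 with the substep count bounded by the fastest local
// relaxation rate (explicit stability), pH frozen over the step
inline void chem_step(double* y, double dt, const Pars& P,
                      double k3p, double k3m) {
  double lam = P.k_plus1 * P.s_0 * y[1] + P.k_minus1 + P.k_2 +
               k3p * P.s_0 * y[2] + k3m;
  int n_sub = (int)std::ceil(dt * lam / 2.0) + 1; // h * lambda <= 2
  double h = dt / n_sub;
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  for (int s = 0; s < n_sub; ++s) {
    chem_rhs(y, k1, P, k3p, k3m);
    for (int q = 0; q < 6; ++q) tmp[q] = y[q] + 0.5 * h * k1[q];
    chem_rhs(tmp, k2, P, k3p, k3m);
    for (int q = 0; q < 6; ++q) tmp[q] = y[q] + 0.5 * h * k2[q];
    chem_rhs(tmp, k3, P, k3p, k3m);
    for (int q = 0; q < 6; ++q) tmp[q] = y[q] + h * k3[q];
    chem_rhs(tmp, k4, P, k3p, k3m);
    for (int q = 0; q < 6; ++q)
      y[q] += h / 6.0 * (k1[q] + 2 * k2[q] + 2 * k3[q] + k4[q]);
  }
  for (int q = 0; q < 6; ++q) if (y[q] < 0 && y[q] > -1e-8) y[q] = 0;
}

void surface_refresh(Pop& C, const Pars& P) {
  int nx = (int)std::lround(P.Lx / P.dx);
  int ny = (int)std::lround(P.Ly / P.dx);
  std::vector<int> top(nx * ny, -1);
  for (size_t m = 0; m < C.n(); ++m) {
    double xw = C.x[m] - P.Lx * std::floor(C.x[m] / P.Lx);
    double yw = C.y[m] - P.Ly * std::floor(C.y[m] / P.Ly);
    int gx = std::min((int)std::floor(xw / P.dx), nx - 1);
    int gy = std::min((int)std::floor(yw / P.dx), ny - 1);
    int key = gx * ny + gy;
    if (top[key] < 0 || C.z[m] > C.z[top[key]]) top[key] = (int)m;
  }
  std::fill(C.is_surface.begin(), C.is_surface.end(), 0);
  for (int k : top) if (k >= 0) C.is_surface[k] = 1;
}

void keep_subset(Pop& C, const std::vector<char>& keep) {
  Pop out;
  for (size_t m = 0; m < C.n(); ++m) {
    if (!keep[m]) continue;
    out.id.push_back(C.id[m]); out.type.push_back(C.type[m]);
    out.partner.push_back(C.partner[m]);
    out.x.push_back(C.x[m]); out.y.push_back(C.y[m]); out.z.push_back(C.z[m]);
    out.radius.push_back(C.radius[m]);
    out.birth_time.push_back(C.birth_time[m]);
    out.t_c.push_back(C.t_c[m]); out.i_t_level.push_back(C.i_t_level[m]);
    out.e.push_back(C.e[m]); out.s.push_back(C.s[m]); out.i_.push_back(C.i_[m]);
    out.cs.push_back(C.cs[m]); out.ci.push_back(C.ci[m]); out.p.push_back(C.p[m]);
    out.entry_time.push_back(C.entry_time[m]);
    out.is_surface.push_back(C.is_surface[m]);
  }
  C = out;
}

} // namespace

// [[Rcpp::export]]
List run_steps_cpp(DataFrame cells, List params, int steps, double t0,
                   double tau0, int step0, int snapshot_every) {
  Pars P;
  P.Lx = params["Lx"]; P.Ly = params["Ly"];
  P.k_rep = params["k_rep"]; P.gamma_ = params["gamma"];
  P.alpha_0 = params["alpha_0"]; P.k_phi = params["k_phi"];
  P.eta = params["eta"]; P.dt = params["dt"]; P.R_0 = params["R_0"];
  P.cutoff = params["cutoff"];
  P.division_offset = params["division_offset"];
  P.growth_time = params["growth_time"];
  P.dx = params["dx"]; P.F_D = params["F_D"];
  P.contact_gap = params["contact_gap"]; P.h = params["h"];
  P.f_h = params["f_h"]; P.fill_ceiling = params["fill_ceiling"];
  P.s_0 = params["s_0"]; P.e_T = params["e_T"];
  P.k_plus1 = params["k_plus1"]; P.k_minus1 = params["k_minus1"];
  P.k_2 = params["k_2"]; P.a3 = params["a3"]; P.b3 = params["b3"];
  P.A3 = params["A3"]; P.B3 = params["B3"];
  P.ph_c0 = params["ph_c0"]; P.ph_c1 = params["ph_c1"];
  P.ph_c2 = params["ph_c2"]; P.ph_c3 = params["ph_c3"];
  P.cycle_low = params["cycle_low"]; P.cycle_high = params["cycle_high"];
  P.dual_mode = as<int>(params["dual_mode"]) != 0;
  P.filling = as<int>(params["filling"]) != 0;

  Pop C;
  {
    IntegerVector id = cells["id"];
    CharacterVector type = cells["type"];
    NumericVector x = cells["x"], y = cells["y"], z = cells["z"];
    NumericVector radius = cells["radius"], birth = cells["birth_time"];
    NumericVector tc = cells["t_c"], itl = cells["i_t_level"];
    NumericVector e = cells["e"], s = cells["s"], ii = cells["i"];
    NumericVector cs = cells["c_s"], ci = cells["c_i"], p = cells["p"];
    NumericVector entry = cells["entry_time"];
    LogicalVector surf = cells["is_surface"];
    IntegerVector partner = cells["partner"];
    size_t n = id.size();
    for (size_t m = 0; m < n; ++m) {
      C.id.push_back(id[m]);
      C.type.push_back(std::string(type[m]) == "stem" ? 0 : 1);
      C.x.push_back(x[m]); C.y.push_back(y[m]); C.z.push_back(z[m]);
      C.radius.push_back(radius[m]); C.birth_time.push_back(birth[m]);
      C.t_c.push_back(tc[m]); C.i_t_level.push_back(itl[m]);
      C.e.push_back(e[m]); C.s.push_back(s[m]); C.i_.push_back(ii[m]);
      C.cs.push_back(cs[m]); C.ci.push_back(ci[m]); C.p.push_back(p[m]);
      C.entry_time.push_back(entry[m]);
      C.is_surface.push_back(surf[m] == TRUE ? 1 : 0);
      C.partner.push_back(partner[m] == NA_INTEGER ? -1 : partner[m]);
    }
  }

  double t = t0, tau = tau0;
  int step = step0;
  int next_id = 0;
  for (size_t m = 0; m < C.n(); ++m) next_id = std::max(next_id, C.id[m]);
  next_id += 1;
  int divisions = 0;
  int steps_per_refresh = std::max(1, (int)std::lround(1.0 / (P.f_h * P.dt)));

  std::vector<double> th_t, th_tissue, th_tau;
  std::vector<int> rm_id, rm_clump;
  std::vector<double> rm_time, rm_age, rm_z, rm_s, rm_entry;
  int clump_offset = 0;
  List snapshots;

  RNGScope rng;

  for (int it = 0; it < steps; ++it) {
    size_t n = C.n();

    // ---- (1) chemistry (frozen below the corneum base) ----
    for (size_t m = 0; m < n; ++m) {
      if (C.z[m] < P.h) continue;
      if (!R_finite(C.entry_time[m])) C.entry_time[m] = t;
      if (P.e_T == 0.0) continue;  // enzyme-free: the system is exactly frozen
      double xi = tau > 0 ? clamp01((C.z[m] - P.h) / tau)
                          : (C.z[m] > P.h ? 1.0 : 0.0);
      double pH = ph_at(xi, P);
      double k3p = std::max(P.a3 * pH - P.b3, 0.0) * 1e7;
      double k3m = P.A3 * std::exp(-P.B3 * pH);
      double yv[6] = {C.e[m], C.s[m], C.i_[m], C.cs[m], C.ci[m], C.p[m]};
      chem_step(yv, P.dt, P, k3p, k3m);
      C.e[m] = yv[0]; C.s[m] = yv[1]; C.i_[m] = yv[2];
      C.cs[m] = yv[3]; C.ci[m] = yv[4]; C.p[m] = yv[5];
    }

    // ---- (2) forces ----
    std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
    // contact graph for the detachment cull, collected from the same scan
    // (pre-move positions; partner edges are added after divisions)
    std::vector<std::vector<int> > adj(n);
    for_candidate_pairs(C.z, P.cutoff, [&](int i, int j) {
      double dz = C.z[j] - C.z[i];
      if (std::fabs(dz) >= P.cutoff) return;
      double dx = min_img(C.x[j] - C.x[i], P.Lx);
      if (std::fabs(dx) >= P.cutoff) return;
      double dy = min_img(C.y[j] - C.y[i], P.Ly);
      if (std::fabs(dy) >= P.cutoff) return;
      double dist2 = dx * dx + dy * dy + dz * dz;
      if (dist2 >= P.cutoff * P.cutoff) return;
      double dist = std::sqrt(dist2);
      if (dist < 1e-12) { // coincident: random separation axis
        double ux = norm_rand(), uy = norm_rand(), uz = norm_rand();
        double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
        dx = ux / nn * 1e-9; dy = uy / nn * 1e-9; dz = uz / nn * 1e-9;
        dist = 1e-9;
      }
      double gap = dist - C.radius[i] - C.radius[j];
      if (gap < P.contact_gap) {
        adj[i].push_back(j);
        adj[j].push_back(i);
      }
      double fmag;
      if (gap < 0) {
        if (gap <= -1.0) stop("total overlap between cells %d and %d",
                              C.id[i], C.id[j]);
        fmag = P.k_rep * std::log(1.0 + gap);
      } else if (gap > 0) {
        double alpha = 0.5 * (C.s[i] + C.s[j]) * P.alpha_0;
        fmag = alpha * adhesion_shape(gap / P.R_0, P.gamma_);
      } else fmag = 0.0;
      double inv = fmag / dist;
      fx[i] += inv * dx; fy[i] += inv * dy; fz[i] += inv * dz;
      fx[j] -= inv * dx; fy[j] -= inv * dy; fz[j] -= inv * dz;
    });
    // basal membrane
    for (size_t m = 0; m < n; ++m) {
      double gap = C.z[m] - C.radius[m];
      if (gap < 0) {
        if (gap <= -1.0) stop("cell %d pushed through the basal membrane",
                              C.id[m]);
        fz[m] += -P.k_rep * std::log(1.0 + gap);
      } else if (C.type[m] == 0 && gap > 0) {
        fz[m] += -P.alpha_0 * adhesion_shape(gap / P.R_0, P.gamma_);
      }
    }
    // rotational force on dividing pairs
    {
      std::unordered_map<int, size_t> idx;
      bool have_pairs = false;
      for (size_t m = 0; m < n; ++m) if (C.partner[m] >= 0) have_pairs = true;
      if (have_pairs) {
        for (size_t m = 0; m < n; ++m) idx[C.id[m]] = m;
        for (size_t m = 0; m < n; ++m) {
          if (C.partner[m] < 0) continue;
          auto it2 = idx.find(C.partner[m]);
          if (it2 == idx.end()) { C.partner[m] = -1; continue; }
          size_t w = it2->second;
          bool lower = C.z[m] < C.z[w] ||
                       (C.z[m] == C.z[w] && C.id[m] < C.id[w]);
          // r = from lower to upper
          size_t lo = lower ? m : w, up = lower ? w : m;
          double rx = min_img(C.x[up] - C.x[lo], P.Lx);
          double ry = min_img(C.y[up] - C.y[lo], P.Ly);
          double rz = C.z[up] - C.z[lo];
          double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
          if (rn < 1e-12) continue;
          double cosphi = rz / rn;
          cosphi = std::max(-1.0, std::min(1.0, cosphi));
          double phi = std::acos(cosphi);
          double px = -cosphi * rx / rn;
          double py = -cosphi * ry / rn;
          double pz = 1.0 - cosphi * rz / rn;
          double pn = std::sqrt(px * px + py * py + pz * pz);
          if (pn < 1e-12) continue;
          double sgn = lower ? 1.0 : -1.0; // force on lower is -k_phi*phi*n_hat
          fx[m] += sgn * (-P.k_phi) * phi * px / pn;
          fy[m] += sgn * (-P.k_phi) * phi * py / pn;
          fz[m] += sgn * (-P.k_phi) * phi * pz / pn;
        }
      }
    }
    // removal force
    if (!P.filling && P.F_D > 0) {
      for (size_t m = 0; m < n; ++m)
        if (C.is_surface[m]) fz[m] += P.F_D;
    }

    // ---- (3) positions ----
    double mob = P.dt / P.eta;
    for (size_t m = 0; m < n; ++m) {
      double ddx = fx[m] * mob, ddy = fy[m] * mob, ddz = fz[m] * mob;
      if (ddx * ddx + ddy * ddy + ddz * ddz > 1.0)
        stop("mechanics instability: cell id %d displaced > 1 CD in one step",
             C.id[m]);
      C.x[m] += ddx; C.y[m] += ddy; C.z[m] = std::max(C.z[m] + ddz, 0.0);
      C.x[m] -= P.Lx * std::floor(C.x[m] / P.Lx);
      C.y[m] -= P.Ly * std::floor(C.y[m] / P.Ly);
    }

    // newborn growth and pair release
    for (size_t m = 0; m < n; ++m) {
      double age = t + P.dt - C.birth_time[m];
      C.radius[m] = (C.type[m] == 1 && age < P.growth_time)
                        ? P.R_0 * (0.5 + 0.5 * age / P.growth_time)
                        : P.R_0;
    }
    {
      std::unordered_map<int, size_t> idx;
      for (size_t m = 0; m < n; ++m) idx[C.id[m]] = m;
      for (size_t m = 0; m < n; ++m) {
        if (C.partner[m] < 0) continue;
        auto it2 = idx.find(C.partner[m]);
        if (it2 == idx.end()) { C.partner[m] = -1; continue; }
        size_t w = it2->second;
        double dx = min_img(C.x[w] - C.x[m], P.Lx);
        double dy = min_img(C.y[w] - C.y[m], P.Ly);
        double dz = C.z[w] - C.z[m];
        if (std::sqrt(dx * dx + dy * dy + dz * dz) >= 2.0 * P.R_0) {
          C.partner[w] = -1;
          C.partner[m] = -1;
        }
      }
    }

    // ---- (4) divisions ----
    for (size_t m = 0, n_now = C.n(); m < n_now; ++m) {
      if (C.type[m] != 0 || !R_finite(C.t_c[m])) continue;
      if (t + P.dt - C.birth_time[m] < C.t_c[m]) continue;
      // random upward-hemisphere direction
      double ux, uy, uz, nn;
      do {
        ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
        nn = std::sqrt(ux * ux + uy * uy + uz * uz);
      } while (nn < 1e-9);
      ux /= nn; uy /= nn; uz = std::fabs(uz / nn);
      double nx = C.x[m] + P.division_offset * ux;
      double ny = C.y[m] + P.division_offset * uy;
      double nz = std::max(C.z[m] + P.division_offset * uz, 1e-6);
      // quasi-equilibrium chemistry IC with the inherited inhibitor level
      double iT = std::min(C.i_t_level[m], P.e_T);
      double frac_i = P.e_T > 0 ? iT / P.e_T : 0.0;
      double e0 = P.e_T > 0
                      ? P.k_2 / (P.k_plus1 * P.s_0 + P.k_2) * (1.0 - frac_i)
                      : 0.0;
      C.id.push_back(next_id); C.type.push_back(1);
      C.partner.push_back(C.id[m]);
      C.x.push_back(nx - P.Lx * std::floor(nx / P.Lx));
      C.y.push_back(ny - P.Ly * std::floor(ny / P.Ly));
      C.z.push_back(nz);
      C.radius.push_back(P.R_0 / 2.0);
      C.birth_time.push_back(t + P.dt);
      C.t_c.push_back(NA_REAL);
      C.i_t_level.push_back(C.i_t_level[m]);
      C.e.push_back(e0); C.s.push_back(1.0); C.i_.push_back(0.0);
      C.cs.push_back(P.e_T > 0 ? 1.0 - e0 - frac_i : 0.0);
      C.ci.push_back(frac_i); C.p.push_back(0.0);
      C.entry_time.push_back(NA_REAL);
      C.is_surface.push_back(0);
      C.partner[m] = next_id;
      C.birth_time[m] = t + P.dt;
      if (!P.dual_mode)
        C.t_c[m] = unif_rand() * (P.cycle_high - P.cycle_low) + P.cycle_low;
      ++next_id;
      ++divisions;
    }

    t += P.dt;
    ++step;

    // ---- (5) removal ----
    if (P.filling) {
      bool any_gone = false;
      std::vector<char> keep(C.n(), 1);
      for (size_t m = 0; m < C.n(); ++m)
        if (C.z[m] > P.fill_ceiling) { keep[m] = 0; any_gone = true; }
      if (any_gone) keep_subset(C, keep);
    } else {
      adj.resize(C.n());
      // dividing pairs are in physical contact; the edge keeps newborn
      // daughters (absent from the pre-division scan) attached
      {
        std::unordered_map<int, size_t> idx;
        for (size_t m = 0; m < C.n(); ++m) idx[C.id[m]] = m;
        for (size_t m = 0; m < C.n(); ++m) {
          if (C.partner[m] < 0) continue;
          auto it2 = idx.find(C.partner[m]);
          if (it2 == idx.end()) continue;
          adj[m].push_back((int)it2->second);
        }
      }
      std::vector<char> main(C.n(), 0);
      std::deque<int> queue;
      for (size_t m = 0; m < C.n(); ++m)
        if (C.z[m] <= P.R_0 + P.contact_gap) { main[m] = 1; queue.push_back((int)m); }
      if (queue.empty()) stop("simulation integrity: no cells in the basal seed band");
      while (!queue.empty()) {
        int v = queue.front(); queue.pop_front();
        for (int w : adj[v]) if (!main[w]) { main[w] = 1; queue.push_back(w); }
      }
      bool any_gone = false;
      for (size_t m = 0; m < C.n(); ++m) if (!main[m]) any_gone = true;
      if (any_gone) {
        // clump labels: components of the detached set
        std::vector<int> lab(C.n(), -1);
        int comp = 0;
        for (size_t sdx = 0; sdx < C.n(); ++sdx) {
          if (main[sdx] || lab[sdx] >= 0) continue;
          ++comp;
          std::deque<int> q2; q2.push_back((int)sdx); lab[sdx] = comp;
          while (!q2.empty()) {
            int v = q2.front(); q2.pop_front();
            for (int w : adj[v])
              if (!main[w] && lab[w] < 0) { lab[w] = comp; q2.push_back(w); }
          }
        }
        std::vector<char> keep(C.n(), 1);
        for (size_t m = 0; m < C.n(); ++m) {
          if (main[m]) continue;
          keep[m] = 0;
          rm_id.push_back(C.id[m]);
          rm_time.push_back(t);
          rm_age.push_back(t - C.birth_time[m]);
          rm_z.push_back(C.z[m]);
          rm_s.push_back(C.s[m]);
          rm_entry.push_back(C.entry_time[m]);
          rm_clump.push_back(clump_offset + lab[m]);
        }
        clump_offset += comp;
        keep_subset(C, keep);
      }
    }

    // ---- (6) surface refresh ----
    surface_refresh(C, P);

    // ---- (7) scheduled thickness refresh ----
    if (step % steps_per_refresh == 0) {
      double sum = 0.0; int cnt = 0;
      for (size_t m = 0; m < C.n(); ++m)
        if (C.is_surface[m]) { sum += C.z[m]; ++cnt; }
      if (cnt == 0) stop("cannot compute thickness of an empty tissue");
      double tissue = sum / cnt;
      tau = std::max(tissue - P.h, 0.0);
      th_t.push_back(t); th_tissue.push_back(tissue); th_tau.push_back(tau);
    }

    if (snapshot_every > 0 && step % snapshot_every == 0) {
      size_t nn = C.n();
      IntegerVector sid(nn), stype(nn), ssurf(nn);
      NumericVector sz(nn), ss(nn), se(nn), sci(nn), sbirth(nn);
      for (size_t m = 0; m < nn; ++m) {
        sid[m] = C.id[m]; stype[m] = C.type[m]; ssurf[m] = C.is_surface[m];
        sz[m] = C.z[m]; ss[m] = C.s[m]; se[m] = C.e[m]; sci[m] = C.ci[m];
        sbirth[m] = C.birth_time[m];
      }
      snapshots.push_back(DataFrame::create(
          _["t_hr"] = t, _["id"] = sid, _["stem"] = stype == 0,
          _["z_cd"] = sz, _["s"] = ss, _["e"] = se, _["c_i"] = sci,
          _["birth_time"] = sbirth, _["is_surface"] = ssurf == 1));
    }

    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  size_t n = C.n();
  IntegerVector id(n), partner(n);
  CharacterVector type(n);
  NumericVector x(n), y(n), z(n), radius(n), birth(n), tc(n), itl(n);
  NumericVector e(n), s(n), ii(n), cs(n), ci(n), p(n), entry(n);
  LogicalVector surf(n);
  for (size_t m = 0; m < n; ++m) {
    id[m] = C.id[m];
    type[m] = C.type[m] == 0 ? "stem" : "diff";
    x[m] = C.x[m]; y[m] = C.y[m]; z[m] = C.z[m]; radius[m] = C.radius[m];
    birth[m] = C.birth_time[m]; tc[m] = C.t_c[m]; itl[m] = C.i_t_level[m];
    e[m] = C.e[m]; s[m] = C.s[m]; ii[m] = C.i_[m];
    cs[m] = C.cs[m]; ci[m] = C.ci[m]; p[m] = C.p[m];
    entry[m] = C.entry_time[m];
    surf[m] = C.is_surface[m] == 1;
    partner[m] = C.partner[m] < 0 ? NA_INTEGER : C.partner[m];
  }
  DataFrame out = DataFrame::create(
      _["id"] = id, _["type"] = type, _["x"] = x, _["y"] = y, _["z"] = z,
      _["radius"] = radius, _["birth_time"] = birth, _["t_c"] = tc,
      _["i_t_level"] = itl, _["e"] = e, _["s"] = s, _["i"] = ii,
      _["c_s"] = cs, _["c_i"] = ci, _["p"] = p, _["entry_time"] = entry,
      _["is_surface"] = surf, _["partner"] = partner,
      _["stringsAsFactors"] = false);

  return List::create(
      _["cells"] = out, _["t"] = t, _["tau"] = tau, _["step"] = step,
      _["divisions"] = divisions,
      _["thickness"] = DataFrame::create(_["t_hr"] = th_t,
                                         _["tissue_cd"] = th_tissue,
                                         _["tau_cd"] = th_tau),
      _["removals"] = DataFrame::create(
          _["id"] = rm_id, _["time_hr"] = rm_time, _["age_hr"] = rm_age,
          _["z_cd"] = rm_z, _["s"] = rm_s, _["entry_time_hr"] = rm_entry,
          _["clump"] = rm_clump),
      _["snapshots"] = snapshots);
}
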