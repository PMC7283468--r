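// Overdamped time integration of the coupled cell-substrate system:
// cortex elasticity, transient adhesive contact, focal-adhesion (FA) and
// stress-fiber (SF) populations, actin polarity field, protrusion/counter
// forces, friction solve, and event bookkeeping (ruptures, full retractions).
// The per-category force kernels live in kernels.cpp and are reused here so
// the unit-tested code paths are the ones the simulation runs.
#include <Rcpp.h>
#include <vector>
#include <deque>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// kernels.cpp
NumericMatrix cpp_spring_forces(const NumericMatrix&, const IntegerMatrix&,
                                const NumericVector&, double);
NumericMatrix cpp_area_forces(const NumericMatrix&, const IntegerMatrix&,
                              const NumericVector&, double, double, double);
NumericMatrix cpp_volume_force(const NumericMatrix&, const IntegerMatrix&,
                               double, double);
double cpp_volume(const NumericMatrix&, const IntegerMatrix&);
NumericMatrix cpp_bend_forces(const NumericMatrix&, const IntegerMatrix&,
                              const NumericVector&, double);
NumericMatrix cpp_fv_weights(const NumericMatrix&, const IntegerMatrix&,
                             const IntegerMatrix&);
NumericVector cpp_actin_step(const NumericVector&, const IntegerMatrix&,
                             const NumericMatrix&, const NumericVector&,
                             const LogicalVector&, double, double, double,
                             double, int);
double cpp_actin_stable_dt(const IntegerMatrix&, const NumericMatrix&,
                           const NumericVector&, double, double);
NumericMatrix cpp_tri_gradients(const NumericMatrix&, const IntegerMatrix&,
                                const IntegerMatrix&, const NumericVector&);
double cpp_md_force(double, double, double, double, double);
double cpp_fit_radius_points(const NumericMatrix&, double);
NumericMatrix cpp_solve_velocities(const NumericMatrix&, const IntegerMatrix&,
                                   const IntegerVector&, double, double, double,
                                   const NumericMatrix&, const NumericMatrix&,
                                   double, int);

static inline double pdist3(const NumericMatrix& pos, int i, int j) {
  double dx = pos(i,0)-pos(j,0), dy = pos(i,1)-pos(j,1), dz = pos(i,2)-pos(j,2);
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

// Adhesive Dugdale-zone contact of each cell triangle with the rigid plane
// z = 0: each triangle is replaced by its locally fitted sphere (vertices +
// the opposite vertices of its edge neighbors); the plane has infinite
// radius, so the effective radius is the cell-side one (capped at r_cap for
// flat patches). Forces act along the plane normal, a third per vertex; the
// reaction on the substrate is the negative of `tri_fz`.
// [[Rcpp::export]]
List cpp_contact_forces(const NumericMatrix& pos, const IntegerMatrix& tris,
                        const IntegerMatrix& tri_opp, double E_star, double w,
                        double h0, double d_c, double r_cap) {
  int nt = tris.nrow();
  NumericMatrix F(pos.nrow(), 3);
  NumericVector tri_fz(nt);
  for (int t = 0; t < nt; ++t) {
    int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
    double zc = (pos(ia,2) + pos(ib,2) + pos(ic,2)) / 3.0;
    double gap = zc - d_c;
    if (gap >= h0) continue;
    int ids[6] = {ia, ib, ic, tri_opp(t,0)-1, tri_opp(t,1)-1, tri_opp(t,2)-1};
    int npts = 0;
    NumericMatrix pts(6, 3);
    for (int k = 0; k < 6; ++k) {
      if (ids[k] < 0) continue;
      pts(npts,0) = pos(ids[k],0); pts(npts,1) = pos(ids[k],1);
      pts(npts,2) = pos(ids[k],2);
      ++npts;
    }
    NumericMatrix sub(npts, 3);
    for (int r = 0; r < npts; ++r)
      for (int c = 0; c < 3; ++c) sub(r,c) = pts(r,c);
    double R = cpp_fit_radius_points(sub, r_cap);
    if (!R_finite(R) || R > r_cap) R = r_cap;
    double fz = cpp_md_force(gap, R, E_star, w, h0);
    tri_fz[t] = fz;
    F(ia,2) += fz / 3.0; F(ib,2) += fz / 3.0; F(ic,2) += fz / 3.0;
  }
  return List::create(_["force"] = F, _["tri_fz"] = tri_fz);
}

struct SFib {
  int ni, nj;            // cortex node ids (0-based)
  double L0;             // length at formation
  int nstr;              // strengthening factor, 1..n_str_max
  bool has_i, has_j;     // endpoint FA still present
  double birth;
  double block_sum;      // moving-average accumulator for the current window
  int block_n;
  double prev_avg;
  bool prev_valid;
  bool alive;
  double detach_time;    // when the first endpoint FA was lost (NA if none)
};

// [[Rcpp::export]]
List cpp_simulate(List state, List mesh, List params, List grid,
                  bool fa_mat, bool sf_str, double k_ECM, double r_off0,
                  int n_steps, int save_every, bool enable_fas,
                  bool enable_prot, double spread_force, bool record_events) {
  // ---- unpack mesh ----
  NumericMatrix pos = clone(as<NumericMatrix>(state["pos"]));
  NumericMatrix vel = clone(as<NumericMatrix>(state["vel"]));
  NumericVector G = clone(as<NumericVector>(state["G"]));
  NumericVector refractory = clone(as<NumericVector>(state["refractory"]));
  IntegerVector fa_alive = clone(as<IntegerVector>(state["fa_alive"]));
  NumericVector fa_ax = clone(as<NumericVector>(state["fa_ax"]));
  NumericVector fa_ay = clone(as<NumericVector>(state["fa_ay"]));
  NumericVector fa_birth = clone(as<NumericVector>(state["fa_birth"]));
  IntegerVector fa_sf = clone(as<IntegerVector>(state["fa_sf"])); // 1-based, 0 = unbound
  NumericVector fa_L0 = clone(as<NumericVector>(state["fa_L0"])); // per-bond rest length
  double clock = as<double>(state["clock"]);
  int cum_rupt = as<int>(state["cum_rupt"]);
  int cum_dis = as<int>(state["cum_dis"]);
  int cum_form = as<int>(state["cum_form"]);
  int n_retract = as<int>(state["n_retract"]);
  double last_com = as<double>(state["last_com"]);
  std::deque<double> rupture_times;
  {
    NumericVector rt = state["rupture_times"];
    for (int i = 0; i < rt.size(); ++i) rupture_times.push_back(rt[i]);
  }
  std::vector<double> retract_times;
  {
    NumericVector rt = state["retract_times"];
    for (int i = 0; i < rt.size(); ++i) retract_times.push_back(rt[i]);
  }
  std::vector<SFib> sfs;
  {
    NumericMatrix sm = state["sf"];
    for (int i = 0; i < sm.nrow(); ++i) {
      SFib f;
      f.ni = (int)sm(i,0) - 1; f.nj = (int)sm(i,1) - 1;
      f.L0 = sm(i,2); f.nstr = (int)sm(i,3);
      f.has_i = sm(i,4) != 0; f.has_j = sm(i,5) != 0;
      f.birth = sm(i,6); f.block_sum = sm(i,7); f.block_n = (int)sm(i,8);
      f.prev_avg = sm(i,9); f.prev_valid = sm(i,10) != 0;
      f.alive = sm(i,11) != 0; f.detach_time = sm(i,12);
      sfs.push_back(f);
    }
  }

  IntegerMatrix tris = mesh["tris"];
  IntegerMatrix edges = mesh["edges"];
  NumericVector edge_rest = mesh["edge_rest"];
  IntegerMatrix hinges = mesh["hinges"];
  NumericVector theta_ref = mesh["theta_ref"];
  IntegerMatrix tri_adj = mesh["tri_adj"];
  IntegerMatrix tri_opp = mesh["tri_opp"];
  NumericVector tri_ref_area = mesh["tri_ref_area"];
  double ref_total_area = as<double>(mesh["ref_total_area"]);
  double ref_volume = as<double>(mesh["ref_volume"]);
  IntegerVector nt_ptr = mesh["node_tri_ptr"]; // CSR, 0-based offsets
  IntegerVector nt_idx = mesh["node_tri_idx"]; // 0-based triangle ids

  int nn = pos.nrow(), nt = tris.nrow();

  // ---- unpack parameters ----
  double dt = as<double>(params["dt"]);
  double k_cortex = as<double>(params["k_cortex"]);
  double Lambda_d = as<double>(params["Lambda_d"]);
  double k_area_loc = as<double>(params["k_area_loc"]);
  double k_area_glob = as<double>(params["k_area_glob"]);
  double k_vol = as<double>(params["k_vol"]);
  double k_bend = as<double>(params["k_bend"]);
  double k_gen = as<double>(params["k_gen"]);
  double k_deg = as<double>(params["k_deg"]);
  double D_actin = as<double>(params["D_actin"]);
  double theta_Lp = as<double>(params["theta_Lp"]);
  double theta_Lm = as<double>(params["theta_Lm"]);
  double k_prot = as<double>(params["k_prot"]);
  double eps_grad = as<double>(params["eps_grad"]);
  double k_FA = as<double>(params["k_FA"]);
  double L_FA0 = as<double>(params["L_FA0"]);
  double L_ECM0 = as<double>(params["L_ECM0"]);
  double r_on_FA = as<double>(params["r_on_FA"]);
  double zeta_FA = as<double>(params["zeta_FA"]);
  double lambda_ref = as<double>(params["lambda_ref"]);
  double F_am = as<double>(params["F_am"]);
  double F_rup = as<double>(params["F_rup"]);
  double L_thr = as<double>(params["L_thr"]);
  double mu = as<double>(params["mu"]);
  double dL50 = as<double>(params["dL50"]);
  int n_thr = (int)as<double>(params["n_thr"]);
  int n_str_max = (int)as<double>(params["n_str_max"]);
  double beta_front = as<double>(params["beta_front"]);
  double beta_rear = as<double>(params["beta_rear"]);
  double outside_factor = as<double>(params["outside_Lm_factor"]);
  double bind_distance = as<double>(params["bind_distance"]);
  double rupture_window = as<double>(params["rupture_window"]);
  double ma_window = as<double>(params["ma_window"]);
  double Gamma_subs = as<double>(params["Gamma_subs"]);
  double Gamma_liquid = as<double>(params["Gamma_liquid"]);
  double E_contact = as<double>(params["E_contact"]);
  double w_adh = as<double>(params["w_adh"]);
  double h0_adh = as<double>(params["h0_adh"]);
  double d_contact = as<double>(params["d_contact"]);
  double z_interface = as<double>(params["z_interface"]);
  double L_fib_min0 = as<double>(params["L_fib_min0"]);
  double r_sf = as<double>(params["r_sf"]);
  double R_c = as<double>(params["R_c"]);

  double gx0 = as<double>(grid["x0"]), gy0 = as<double>(grid["y0"]);
  double gl = as<double>(grid["l"]), gA = as<double>(grid["A_tri"]);
  int gnx = as<int>(grid["nx"]), gny = as<int>(grid["ny"]);

  double k_ser = 1.0 / (1.0 / k_FA + 1.0 / k_ECM);
  double L0_fa = L_FA0 + L_ECM0;
  double Gstar = k_gen / k_deg;
  int nblock = (int)std::lround(ma_window / dt);
  double p_on = 1.0 - std::exp(-r_on_FA * dt);
  double p_sf = 1.0 - std::exp(-r_sf * dt);
  double r_cap = 4.0 * R_c;
  double max_disp = 0.5e-6;
  double gmin = eps_grad * Gstar / R_c;

  int n_save = n_steps / save_every;
  NumericMatrix metrics(n_save, 13);
  int save_row = 0;

  std::vector<double> ev_t, ev_F;
  std::vector<int> ev_node, ev_type, ev_region;

  // scratch
  std::vector<int> region(nt);      // 0 body/top, 1 Lp, 2 frontLm, 3 rearLm
  std::vector<bool> ifn(nn), in_lm(nn);
  std::vector<double> fa_fx(nn), fa_fy(nn), fa_fz(nn), fa_fmag(nn);
  IntegerVector contact_flag(nn);
  double mean_fprot = 0;
  LogicalVector source(nt);

  for (int step = 1; step <= n_steps; ++step) {
    clock += dt;

    // ---- geometry-dependent labels ----
    for (int i = 0; i < nn; ++i) ifn[i] = pos(i,2) < z_interface;
    std::vector<bool> ift(nt);
    for (int t = 0; t < nt; ++t)
      ift[t] = ifn[tris(t,0)-1] && ifn[tris(t,1)-1] && ifn[tris(t,2)-1];
    double com = 0; int n_if = 0;
    for (int i = 0; i < nn; ++i) if (ifn[i]) { com += pos(i,0); ++n_if; }
    if (n_if > 0) { com /= n_if; last_com = com; } else com = last_com;

    // periphery ring of the interface = actin sources
    for (int t = 0; t < nt; ++t) {
      bool src = false;
      if (ift[t]) {
        for (int k = 0; k < 3; ++k) {
          int u = tri_adj(t,k) - 1;
          if (u >= 0 && !ift[u]) { src = true; break; }
        }
      }
      source[t] = src;
    }

    // ---- actin field ----
    NumericVector areasv(nt);
    {
      for (int t = 0; t < nt; ++t) {
        int ia = tris(t,0)-1, ib = tris(t,1)-1, ic = tris(t,2)-1;
        double e1x = pos(ib,0)-pos(ia,0), e1y = pos(ib,1)-pos(ia,1), e1z = pos(ib,2)-pos(ia,2);
        double e2x = pos(ic,0)-pos(ia,0), e2y = pos(ic,1)-pos(ia,1), e2z = pos(ic,2)-pos(ia,2);
        double cx = e1y*e2z - e1z*e2y, cy = e1z*e2x - e1x*e2z, cz = e1x*e2y - e1y*e2x;
        areasv[t] = 0.5 * std::sqrt(cx*cx + cy*cy + cz*cz);
      }
      NumericMatrix W = cpp_fv_weights(pos, tris, tri_adj);
      double sdt = cpp_actin_stable_dt(tri_adj, W, areasv, k_deg, D_actin);
      int nsub = (dt <= sdt) ? 1 : (int)std::ceil(dt / sdt);
      G = cpp_actin_step(G, tri_adj, W, areasv, source, k_gen, k_deg,
                         D_actin, dt, nsub);
    }

    // ---- region demarcation (thresholds relative to the peak level) ----
    double gmax = 0;
    for (int t = 0; t < nt; ++t) if (G[t] > gmax) gmax = G[t];
    double thLp = theta_Lp * gmax, thLm = theta_Lm * gmax;
    std::vector<double> tcx(nt);
    for (int t = 0; t < nt; ++t)
      tcx[t] = (pos(tris(t,0)-1,0) + pos(tris(t,1)-1,0) + pos(tris(t,2)-1,0)) / 3.0;
    for (int t = 0; t < nt; ++t) {
      region[t] = 0;
      if (!ift[t]) continue;
      bool front = tcx[t] >= com;
      if (G[t] >= thLp) {
        if (front) region[t] = 1;          // Lp fans out the leading front only
        else if (G[t] >= thLm) region[t] = 3;
      } else if (G[t] >= thLm) {
        region[t] = front ? 2 : 3;
      }
    }
    for (int i = 0; i < nn; ++i) {
      bool lm = false;
      for (int k = nt_ptr[i]; k < nt_ptr[i+1]; ++k) {
        int r = region[nt_idx[k]];
        if (r == 2 || r == 3) { lm = true; break; }
      }
      in_lm[i] = lm;
    }

    // ---- forces ----
    NumericMatrix F = cpp_spring_forces(pos, edges, edge_rest, k_cortex);
    {
      NumericMatrix Fa = cpp_area_forces(pos, tris, tri_ref_area, ref_total_area,
                                         k_area_loc, k_area_glob);
      NumericMatrix Fv = cpp_volume_force(pos, tris, ref_volume, k_vol);
      NumericMatrix Fb = cpp_bend_forces(pos, hinges, theta_ref, k_bend);
      for (int i = 0; i < nn; ++i)
        for (int c = 0; c < 3; ++c) F(i,c) += Fa(i,c) + Fv(i,c) + Fb(i,c);
    }
    {
      List ct = cpp_contact_forces(pos, tris, tri_opp, E_contact, w_adh,
                                   h0_adh, d_contact, r_cap);
      NumericMatrix Fc = ct["force"];
      for (int i = 0; i < nn; ++i) F(i,2) += Fc(i,2);
    }
    if (spread_force > 0)
      for (int i = 0; i < nn; ++i) F(i,2) -= spread_force;

    // protrusion on Lp triangles + global counter force
    double tot_px = 0, tot_py = 0;
    mean_fprot = 0;
    if (enable_prot) {
      NumericMatrix gr = cpp_tri_gradients(pos, tris, tri_adj, G);
      int n_lp = 0;
      for (int t = 0; t < nt; ++t) {
        if (region[t] != 1) continue;
        double gx = gr(t,0), gy = gr(t,1), gz = gr(t,2);
        double gn = std::sqrt(gx*gx + gy*gy + gz*gz);
        ++n_lp;
        if (gn < gmin) continue;
        double fx = k_prot * G[t] * gx / gn;
        double fy = k_prot * G[t] * gy / gn;
        // projected onto the substrate-tangent plane: z-component dropped
        tot_px += fx; tot_py += fy;
        mean_fprot += std::sqrt(fx*fx + fy*fy);
        for (int k = 0; k < 3; ++k) {
          int v = tris(t,k) - 1;
          F(v,0) += fx / 3.0; F(v,1) += fy / 3.0;
        }
      }
      if (n_lp > 0) mean_fprot /= n_lp;
      for (int i = 0; i < nn; ++i) {
        F(i,0) -= tot_px / nn; F(i,1) -= tot_py / nn;
      }
    }

    // FA two-spring forces (node pulled toward its anchor when stretched)
    for (int i = 0; i < nn; ++i) {
      fa_fx[i] = fa_fy[i] = fa_fz[i] = fa_fmag[i] = 0;
      if (!fa_alive[i]) continue;
      double dx = fa_ax[i] - pos(i,0), dy = fa_ay[i] - pos(i,1), dz = -pos(i,2);
      double L = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (L > fa_L0[i] && L > 0) {
        double fm = k_ser * (L - fa_L0[i]);
        fa_fx[i] = fm * dx / L; fa_fy[i] = fm * dy / L; fa_fz[i] = fm * dz / L;
        fa_fmag[i] = fm;
        F(i,0) += fa_fx[i]; F(i,1) += fa_fy[i]; F(i,2) += fa_fz[i];
      }
    }

    // SF contractile force pairs
    for (size_t s = 0; s < sfs.size(); ++s) {
      SFib& f = sfs[s];
      if (!f.alive) continue;
      double dx = pos(f.nj,0)-pos(f.ni,0), dy = pos(f.nj,1)-pos(f.ni,1),
             dz = pos(f.nj,2)-pos(f.ni,2);
      double L = std::sqrt(dx*dx + dy*dy + dz*dz);
      if (L <= 0) continue;
      double dL = L - f.L0;
      double phi = 1.0 / (1.0 + std::exp(-mu * (dL + dL50)));
      double fm = f.nstr * F_am * phi;
      F(f.ni,0) += fm * dx / L; F(f.ni,1) += fm * dy / L; F(f.ni,2) += fm * dz / L;
      F(f.nj,0) -= fm * dx / L; F(f.nj,1) -= fm * dy / L; F(f.nj,2) -= fm * dz / L;
    }

    // ---- friction solve and position update ----
    for (int i = 0; i < nn; ++i) contact_flag[i] = ifn[i] ? 1 : 0;
    vel = cpp_solve_velocities(pos, edges, contact_flag, Lambda_d, Gamma_subs,
                               Gamma_liquid, F, vel, 2e-8, 2000);
    double vmax = 0;
    for (int i = 0; i < nn; ++i) {
      double v2 = vel(i,0)*vel(i,0) + vel(i,1)*vel(i,1) + vel(i,2)*vel(i,2);
      if (v2 > vmax) vmax = v2;
    }
    if (std::sqrt(vmax) * dt > max_disp)
      stop("numerical instability: node displacement exceeded 0.5 um in one step (t = %g s)", clock);
    for (int i = 0; i < nn; ++i)
      for (int c = 0; c < 3; ++c) pos(i,c) += vel(i,c) * dt;

    // ---- refractory timers ----
    for (int i = 0; i < nn; ++i)
      if (refractory[i] > 0) refractory[i] = std::max(0.0, refractory[i] - dt);

    if (enable_fas) {
      // ---- SF moving-average sampling and stall/strengthen ----
      for (size_t s = 0; s < sfs.size(); ++s) {
        SFib& f = sfs[s];
        if (!f.alive) continue;
        f.block_sum += pdist3(pos, f.ni, f.nj);
        f.block_n += 1;
        if (f.block_n >= nblock) {
          double avg = f.block_sum / f.block_n;
          if (f.prev_valid && std::fabs(avg - f.prev_avg) < L_thr) {
            if (sf_str && f.nstr < n_str_max) f.nstr += 1; // stalled
          }
          f.prev_avg = avg; f.prev_valid = true;
          f.block_sum = 0; f.block_n = 0;
        }
      }

      // ---- FA rupture (|F| > F_rup, strict) then stochastic disassembly ----
      for (int i = 0; i < nn; ++i) {
        if (!fa_alive[i]) continue;
        bool front = pos(i,0) >= com;
        if (fa_fmag[i] > F_rup) {
          fa_alive[i] = 0;
          refractory[i] = lambda_ref;
          ++cum_rupt;
          rupture_times.push_back(clock);
          if (fa_sf[i] > 0) {
            SFib& f = sfs[fa_sf[i] - 1];
            if (f.ni == i) f.has_i = false; else f.has_j = false;
            if (!R_finite(f.detach_time)) f.detach_time = clock;
            fa_sf[i] = 0;
          }
          if (record_events) {
            ev_t.push_back(clock); ev_node.push_back(i+1); ev_type.push_back(3);
            ev_F.push_back(fa_fmag[i]); ev_region.push_back(front ? 1 : 2);
          }
          continue;
        }
        double beta = front ? beta_front : beta_rear;
        double r = beta * r_off0;
        if (fa_mat) r *= std::exp(-zeta_FA * fa_fmag[i]);
        if (!in_lm[i]) r *= outside_factor;
        double p = 1.0 - std::exp(-r * dt);
        if (unif_rand() < p) {
          fa_alive[i] = 0;
          ++cum_dis;
          if (fa_sf[i] > 0) {
            SFib& f = sfs[fa_sf[i] - 1];
            if (f.ni == i) f.has_i = false; else f.has_j = false;
            if (!R_finite(f.detach_time)) f.detach_time = clock;
            fa_sf[i] = 0;
          }
          if (record_events) {
            ev_t.push_back(clock); ev_node.push_back(i+1); ev_type.push_back(2);
            ev_F.push_back(fa_fmag[i]); ev_region.push_back(front ? 1 : 2);
          }
        }
      }

      // ---- full (collective) retraction ----
      while (!rupture_times.empty() &&
             rupture_times.front() <= clock - rupture_window)
        rupture_times.pop_front();
      if ((int)rupture_times.size() >= n_thr) {
        for (int i = 0; i < nn; ++i) {
          if (fa_alive[i]) {
            fa_alive[i] = 0;
            if (fa_sf[i] > 0) {
              SFib& f = sfs[fa_sf[i] - 1];
              if (f.ni == i) f.has_i = false; else f.has_j = false;
              fa_sf[i] = 0;
            }
          }
          if (in_lm[i]) refractory[i] = lambda_ref;
        }
        retract_times.push_back(clock);
        ++n_retract;
        rupture_times.clear();
      }

      // ---- FA formation on lamellar nodes ----
      for (int i = 0; i < nn; ++i) {
        if (fa_alive[i] || !in_lm[i] || refractory[i] > 0) continue;
        if (std::fabs(pos(i,2)) > bind_distance) continue;
        if (unif_rand() < p_on) {
          fa_alive[i] = 1;
          fa_ax[i] = pos(i,0); fa_ay[i] = pos(i,1);
          // the complex assembles unstretched: its rest length is the gap it
          // spans at formation (at least the two spring rest lengths)
          fa_L0[i] = std::max(L0_fa, std::fabs(pos(i,2)));
          fa_birth[i] = clock; fa_sf[i] = 0;
          ++cum_form;
          if (record_events) {
            ev_t.push_back(clock); ev_node.push_back(i+1); ev_type.push_back(1);
            ev_F.push_back(0.0); ev_region.push_back(pos(i,0) >= com ? 1 : 2);
          }
        }
      }

      // ---- SF formation between unbound FAs ----
      {
        std::vector<int> unbound;
        for (int i = 0; i < nn; ++i)
          if (fa_alive[i] && fa_sf[i] == 0) unbound.push_back(i);
        for (size_t u = 0; u < unbound.size(); ++u) {
          int i = unbound[u];
          if (fa_sf[i] != 0 || !fa_alive[i]) continue;
          if (unif_rand() >= p_sf) continue;
          std::vector<int> cand;
          for (size_t v = 0; v < unbound.size(); ++v) {
            int j = unbound[v];
            if (j != i && fa_alive[j] && fa_sf[j] == 0) cand.push_back(j);
          }
          if (cand.empty()) continue;
          int j = cand[(int)(unif_rand() * cand.size()) % cand.size()];
          double L = pdist3(pos, i, j);
          if (L < L_fib_min0) continue;   // minimum initial fiber length
          SFib f;
          f.ni = i; f.nj = j; f.L0 = L; f.nstr = 1;
          f.has_i = true; f.has_j = true; f.birth = clock;
          f.block_sum = 0; f.block_n = 0; f.prev_avg = 0; f.prev_valid = false;
          f.alive = true; f.detach_time = NA_REAL;
          sfs.push_back(f);
          fa_sf[i] = (int)sfs.size(); fa_sf[j] = (int)sfs.size();
        }
      }

      // ---- SF pruning: deleted when both endpoint FAs are gone ----
      for (size_t s = 0; s < sfs.size(); ++s) {
        SFib& f = sfs[s];
        if (f.alive && !f.has_i && !f.has_j) f.alive = false;
      }
    }

    // ---- metrics ----
    if (step % save_every == 0) {
      int nfa = 0;
      for (int i = 0; i < nn; ++i) if (fa_alive[i]) ++nfa;
      int nsf = 0; double snstr = 0;
      for (size_t s = 0; s < sfs.size(); ++s)
        if (sfs[s].alive) { ++nsf; snstr += sfs[s].nstr; }
      // traction: FA forces grouped by substrate triangle, sum of magnitudes
      double traction = 0;
      {
        std::unordered_map<long long, std::array<double,3> > acc;
        for (int i = 0; i < nn; ++i) {
          if (!fa_alive[i] || fa_fmag[i] <= 0) continue;
          double x = fa_ax[i], y = fa_ay[i];
          long long ii = (long long)std::floor((x - gx0) / gl);
          long long jj = (long long)std::floor((y - gy0) / gl);
          if (ii < 0 || ii >= gnx || jj < 0 || jj >= gny)
            stop("FA anchor outside the substrate grid: enlarge the grid");
          double u = (x - gx0) - ii * gl, v = (y - gy0) - jj * gl;
          long long id = 2 * (jj * gnx + ii) + (u + v > gl ? 1 : 0);
          std::array<double,3>& a = acc[id];
          a[0] += fa_fx[i]; a[1] += fa_fy[i]; a[2] += fa_fz[i];
        }
        for (std::unordered_map<long long, std::array<double,3> >::iterator
               it = acc.begin(); it != acc.end(); ++it) {
          std::array<double,3>& a = it->second;
          traction += std::sqrt(a[0]*a[0] + a[1]*a[1] + a[2]*a[2]) / gA;
        }
      }
      int n_if2 = 0;
      for (int i = 0; i < nn; ++i) if (ifn[i]) ++n_if2;
      metrics(save_row, 0) = clock;
      metrics(save_row, 1) = last_com;
      metrics(save_row, 2) = nfa;
      metrics(save_row, 3) = nsf;
      metrics(save_row, 4) = cum_rupt;
      metrics(save_row, 5) = cum_dis;
      metrics(save_row, 6) = n_retract;
      metrics(save_row, 7) = traction;
      metrics(save_row, 8) = nsf > 0 ? snstr / nsf : 0.0;
      metrics(save_row, 9) = cpp_volume(pos, tris);
      metrics(save_row, 10) = n_if2;
      metrics(save_row, 11) = mean_fprot;
      metrics(save_row, 12) = cum_form;
      ++save_row;
    }
  }

  // ---- pack state back ----
  NumericMatrix sfm(sfs.size(), 13);
  for (size_t s = 0; s < sfs.size(); ++s) {
    const SFib& f = sfs[s];
    sfm(s,0) = f.ni + 1; sfm(s,1) = f.nj + 1; sfm(s,2) = f.L0;
    sfm(s,3) = f.nstr; sfm(s,4) = f.has_i ? 1 : 0; sfm(s,5) = f.has_j ? 1 : 0;
    sfm(s,6) = f.birth; sfm(s,7) = f.block_sum; sfm(s,8) = f.block_n;
    sfm(s,9) = f.prev_avg; sfm(s,10) = f.prev_valid ? 1 : 0;
    sfm(s,11) = f.alive ? 1 : 0; sfm(s,12) = f.detach_time;
  }
  NumericVector rt(rupture_times.size());
  for (size_t i = 0; i < rupture_times.size(); ++i) rt[i] = rupture_times[i];
  NumericVector rtt(retract_times.size());
  for (size_t i = 0; i < retract_times.size(); ++i) rtt[i] = retract_times[i];
  NumericMatrix events(ev_t.size(), 5);
  for (size_t i = 0; i < ev_t.size(); ++i) {
    events(i,0) = ev_t[i]; events(i,1) = ev_node[i]; events(i,2) = ev_type[i];
    events(i,3) = ev_F[i]; events(i,4) = ev_region[i];
  }
  return List::create(
    _["pos"] = pos, _["vel"] = vel, _["G"] = G, _["refractory"] = refractory,
    _["fa_alive"] = fa_alive, _["fa_ax"] = fa_ax, _["fa_ay"] = fa_ay,
    _["fa_birth"] = fa_birth, _["fa_sf"] = fa_sf, _["fa_L0"] = fa_L0,
    _["sf"] = sfm,
    _["clock"] = clock, _["cum_rupt"] = cum_rupt, _["cum_dis"] = cum_dis,
    _["cum_form"] = cum_form, _["n_retract"] = n_retract,
    _["last_com"] = last_com, _["rupture_times"] = rt,
    _["retract_times"] = rtt, _["metrics"] = metrics, _["events"] = events);
}

// Idealized isolated two-spring experiment: a single node bound to the plane
// through the FA + ligand springs in series, pulled horizontally by one SF
// anchored at a fixed distant point, with stalling-driven strengthening.
// Returns the time trace of the force carried by the ligand spring and the
// stall times. The node is not part of any cortex; its drag is `gamma`.
// [[Rcpp::export]]
List cpp_two_spring(double k_ECM, double duration, List params, bool sf_str,
                    double gamma) {
  double dt = as<double>(params["dt"]);
  double k_FA = as<double>(params["k_FA"]);
  double L_FA0 = as<double>(params["L_FA0"]);
  double L_ECM0 = as<double>(params["L_ECM0"]);
  double F_am = as<double>(params["F_am"]);
  double L_thr = as<double>(params["L_thr"]);
  double mu = as<double>(params["mu"]);
  double dL50 = as<double>(params["dL50"]);
  int n_str_max = (int)as<double>(params["n_str_max"]);
  double ma_window = as<double>(params["ma_window"]);
  double L_fib = as<double>(params["L_fib_min0"]);

  double k_ser = 1.0 / (1.0 / k_FA + 1.0 / k_ECM);
  double L0 = L_FA0 + L_ECM0;
  int nblock = (int)std::lround(ma_window / dt);
  int n_steps = (int)std::lround(duration / dt);

  // geometry: anchor at x = 0; node starts at x = 0 (rest); SF far anchor at
  // x = L_fib0 so the fiber pulls the node in +x, stretching the FA springs.
  double x = 0.0;
  double L_fib0 = L_fib;
  int nstr = 1;
  double block_sum = 0; int block_n = 0;
  double prev_avg = 0; bool prev_valid = false;
  int n_save = n_steps;
  NumericVector tv(n_save), fv(n_save), nv(n_save);
  std::vector<double> stall_times;
  for (int step = 1; step <= n_steps; ++step) {
    double t = step * dt;
    double Lf = L_fib0 - x;             // current fiber length
    double dL = Lf - L_fib0;
    double phi = 1.0 / (1.0 + std::exp(-mu * (dL + dL50)));
    double f_sf = nstr * F_am * phi;    // pulls +x
    // the ligand+FA series spring is at rest (length L0) when the node sits
    // at x = 0 and stretches by x beyond that; no force under compression
    double f_fa = (x > 0) ? -k_ser * x : 0.0;
    (void)L0;
    double v = (f_sf + f_fa) / gamma;
    x += v * dt;
    // stall bookkeeping on the fiber length moving average
    block_sum += (L_fib0 - x); block_n += 1;
    if (block_n >= nblock) {
      double avg = block_sum / block_n;
      if (prev_valid && std::fabs(avg - prev_avg) < L_thr) {
        stall_times.push_back(t);
        if (sf_str && nstr < n_str_max) nstr += 1;
      }
      prev_avg = avg; prev_valid = true;
      block_sum = 0; block_n = 0;
    }
    tv[step-1] = t;
    fv[step-1] = k_ser * std::max(x, 0.0); // force carried by the ligand spring
    nv[step-1] = nstr;
  }
  NumericVector st(stall_times.size());
  for (size_t i = 0; i < stall_times.size(); ++i) st[i] = stall_times[i];
  return List::create(_["time"] = tv, _["F_ECM"] = fv, _["n_str"] = nv,
                      _["stall_times"] = st);
}
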