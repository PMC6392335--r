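// Core time-stepping engine: overdamped Euler dynamics of nucleus, MTOCs/SPBs
// and kinetochores driven by cytoplasmic microtubule cortical forces and a
// minimal nuclear spindle. All lengths um, forces pN, times s.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static const double PI2 = M_PI * M_PI;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(x * x + y * y + z * z); }
  Vec3 unit() const {
    double n = norm();
    return n > 1e-300 ? Vec3(x / n, y / n, z / n) : Vec3(1, 0, 0);
  }
};

static Vec3 rand_unit() {
  // isotropic direction via normal deviates (uses R's RNG stream)
  double a = norm_rand(), b = norm_rand(), c = norm_rand();
  Vec3 v(a, b, c);
  double n = v.norm();
  if (n < 1e-12) return Vec3(1, 0, 0);
  return v * (1.0 / n);
}

static Vec3 rand_outward_hemisphere(const Vec3& normal) {
  Vec3 v = rand_unit();
  if (v.dot(normal) < 0) v = v * (-1.0);
  return v;
}

// Two-sphere ("snowman") cell: mother at origin, bud along `axis`.
struct Geom {
  Vec3 axis;
  double rm, wcor, neck_frac, finalBI, Tgrow;
  // time-dependent state
  double rb, septin_a, septin_r, bud_c; // bud centre distance along axis
  void update(double t) {
    double frac = (Tgrow > 0) ? std::min(1.0, t / Tgrow) : 1.0;
    rb = rm * finalBI * frac;
    if (rb > 1e-9) {
      septin_r = neck_frac * rb;
      septin_a = std::sqrt(rm * rm - septin_r * septin_r);
      bud_c = septin_a + std::sqrt(rb * rb - septin_r * septin_r);
    } else {
      rb = 0.0; septin_r = 0.0; septin_a = rm; bud_c = rm;
    }
  }
  // Nearest point of the septin ring to p, and a tangential unit vector at p
  Vec3 ring_point(const Vec3& p) const {
    double s = p.dot(axis);
    Vec3 perp = p - axis * s;
    double rho = perp.norm();
    Vec3 erho = (rho > 1e-12) ? perp * (1.0 / rho) : [this]() {
      // arbitrary unit vector perpendicular to axis
      Vec3 ref = (std::fabs(axis.x) < 0.9) ? Vec3(1, 0, 0) : Vec3(0, 1, 0);
      Vec3 t(axis.y * ref.z - axis.z * ref.y,
             axis.z * ref.x - axis.x * ref.z,
             axis.x * ref.y - axis.y * ref.x);
      return t.unit();
    }();
    return axis * septin_a + erho * septin_r;
  }
  // Signed inside-distance to the union boundary, inward direction and region.
  // region: 0 mother interior, 1 mother cortex, 2 daughter interior,
  //         3 daughter cortex, -1 outside the cell.
  void classify(const Vec3& p, double& d_in, Vec3& n_in, int& region) const {
    double s = p.dot(axis);
    double lp = p.norm();
    bool in_mother = (lp <= rm);
    bool in_bud = false;
    Vec3 q;            // position relative to bud centre
    double lq = 0.0;
    if (rb > 1e-9) {
      q = p - axis * bud_c;
      lq = q.norm();
      in_bud = (lq <= rb);
    }
    bool inside = in_mother || in_bud;

    // distance to the mother boundary cap (surface with axial coord <= septin_a)
    double dm; Vec3 nm;
    bool have_m = true;
    if (lp < 1e-9) { dm = rm; nm = Vec3(0, 0, 1); }
    else {
      double s_proj = s * rm / lp; // axial coord of radial projection
      if (s_proj <= septin_a + 1e-12) {
        dm = rm - lp;              // signed: negative outside the sphere
        nm = p * (-1.0 / lp);      // inward radial normal
      } else {
        // nearest boundary point is on the septin ring edge
        Vec3 rp = ring_point(p);
        Vec3 d = p - rp;
        double dist = d.norm();
        dm = inside ? dist : -dist;
        nm = (dist > 1e-12) ? d * (1.0 / dist) : axis * (-1.0);
        if (!inside) nm = nm * (-1.0); // point back toward the ring
      }
    }
    // distance to the daughter boundary cap (axial coord >= septin_a)
    double db = 1e300; Vec3 nb; bool have_b = (rb > 1e-9);
    if (have_b) {
      if (lq < 1e-9) { db = rb; nb = axis * (-1.0); }
      else {
        double s_proj = bud_c + (s - bud_c) * rb / lq;
        if (s_proj >= septin_a - 1e-12) {
          db = rb - lq;
          nb = q * (-1.0 / lq);
        } else {
          Vec3 rp = ring_point(p);
          Vec3 d = p - rp;
          double dist = d.norm();
          db = inside ? dist : -dist;
          nb = (dist > 1e-12) ? d * (1.0 / dist) : axis;
          if (!inside) nb = nb * (-1.0);
        }
      }
    }
    if (inside) {
      // take the nearer boundary piece (only non-negative candidates are real
      // distances; a negative dm with p inside the bud means the mother sphere
      // does not bound p there)
      double dmm = (have_m && dm >= 0) ? dm : 1e300;
      double dbb = (have_b && db >= 0) ? db : 1e300;
      if (dmm <= dbb) { d_in = dmm; n_in = nm; }
      else { d_in = dbb; n_in = nb; }
      if (d_in > 1e200) { // inside one sphere but 'outside' the other's cap: fall back
        d_in = std::max(dm, db == 1e300 ? -1e300 : db);
        n_in = (dm >= db) ? nm : nb;
      }
      bool daughter = (rb > 1e-9) && (s >= septin_a);
      bool cortex = (d_in < wcor);
      region = daughter ? (cortex ? 3 : 2) : (cortex ? 1 : 0);
    } else {
      double dmm = have_m ? std::fabs(dm) : 1e300;
      double dbb = have_b ? std::fabs(db) : 1e300;
      if (dmm <= dbb) { d_in = -dmm; n_in = nm; }
      else { d_in = -dbb; n_in = nb; }
      region = -1;
    }
  }
  // project a point onto the outer boundary surface of its side
  Vec3 project_to_surface(const Vec3& p) const {
    double s = p.dot(axis);
    if (rb > 1e-9 && s >= septin_a) {
      Vec3 q = p - axis * bud_c;
      Vec3 out = axis * bud_c + q.unit() * rb;
      // keep on the daughter cap; if projection slid past the ring, clamp to ring
      if (out.dot(axis) < septin_a) out = ring_point(p);
      return out;
    }
    Vec3 out = p.unit() * rm;
    if (out.dot(axis) > septin_a) out = ring_point(p);
    return out;
  }
};

struct Par {
  double r_nuc, r_spb, r_kt;
  double k_cor, eta_cyt, eta_nu, eta_ne, eta_nuc;
  double vg, vs, fc, fr, fc_stall, f_stall;
  double f_dyn, lambda_dyn, lambda_ipmt, f_k5;
  double k_coh, k_c, k_fibril, c_rep, f_wall;
  double dt, h_kmt, lambda_bim1, kappa;
  double slide_angle, patch_cos;
  double B, mother_mult, patch_mult, rest_mult, daughter_onset_bi, daughter_trans;
  int punctate, bias_scales_dynein;
  double cutoff, mig_thresh;
  int n_cmt, n_ipmt, sample_every, stop_early, record_series;
};

struct Body {
  Vec3 dir;      // unit vector from nucleus centre (NE embedding)
  double r;
  int founders;
  bool alive;
};

struct Cmt {
  int body;
  Vec3 dir;
  double len;
  int state;     // 0 growing, 1 shrinking
  bool sliding, buckled;
  Vec3 tip;      // world tip, maintained when sliding
  double entry_len; // rod length when sliding began (cortex entry point)
};

struct Kt {
  Vec3 pos;
  int sister;    // index of sister KT
  int body;      // attached MTOC/SPB body
  double kmt_len;
  int kmt_state;
};

struct Ipmt { int spb; double len; int state; };

static void load_dependent(const Par& P, double fc0, double f_load,
                           double& vg_eff, double& fc_eff) {
  double e = std::exp(-f_load / P.f_stall);
  vg_eff = P.vg * e;
  fc_eff = P.fc_stall / (1.0 + (P.fc_stall / fc0 - 1.0) * e);
}

// [[Rcpp::export(name = ".sim_run_cell_cpp")]]
List sim_run_cell_cpp(List init, List par) {
  Par P;
  NumericVector pv = par["values"];
  CharacterVector pn = pv.names();
  std::map<std::string, double> M;
  for (int i = 0; i < pv.size(); ++i) M[std::string(pn[i])] = pv[i];
  Geom G;
  G.rm = M["r_mother"]; G.wcor = M["w_cor"]; G.neck_frac = M["neck_fraction"];
  G.finalBI = M["final_budding_index"]; G.Tgrow = M["bud_growth_s"];
  P.r_nuc = M["r_nuc"]; P.r_spb = M["r_spb"]; P.r_kt = M["r_kt"];
  P.k_cor = M["k_cor"]; P.eta_cyt = M["eta_cyt"]; P.eta_nu = M["eta_nu"];
  P.eta_ne = M["eta_ne"]; P.eta_nuc = M["eta_nucleus"];
  P.vg = M["v_g_s"]; P.vs = M["v_s_s"]; P.fc = M["f_c_s"]; P.fr = M["f_r_s"];
  P.fc_stall = M["f_c_stall"]; P.f_stall = M["f_stall"];
  P.f_dyn = M["f_dyn"]; P.lambda_dyn = M["lambda_dyn"];
  P.lambda_ipmt = M["lambda_ipmt"]; P.f_k5 = M["f_kinesin5"];
  P.k_coh = M["k_cohesion"]; P.k_c = M["k_c"]; P.k_fibril = M["k_fibril"];
  P.c_rep = M["c_kt_repulsion"]; P.f_wall = M["f_wall"];
  P.dt = M["dt"]; P.h_kmt = M["h_kmt_s"]; P.lambda_bim1 = M["lambda_bim1"];
  P.kappa = M["kappa_mt"]; P.slide_angle = M["sliding_angle_rad"];
  P.patch_cos = M["patch_cos"];
  P.B = M["bias_B"]; P.mother_mult = M["mother_dyn_mult"];
  P.patch_mult = M["lambda_dynein_patch"]; P.rest_mult = M["lambda_dynein_rest"];
  P.daughter_onset_bi = M["daughter_dynein_onset_bi"];
  P.daughter_trans = M["daughter_trans"];
  P.punctate = (int)M["punctate"];
  P.bias_scales_dynein = (int)M["bias_scales_dynein"];
  P.cutoff = M["cutoff_s"]; P.mig_thresh = M["migration_threshold"];
  P.n_cmt = (int)M["n_cmt_per_mtoc"]; P.n_ipmt = (int)M["n_ipmt_per_spb"];
  P.sample_every = std::max(1, (int)M["sample_every"]);
  P.stop_early = (int)M["stop_early"];
  P.record_series = (int)M["record_series"];

  NumericVector axis0 = init["axis"];
  G.axis = Vec3(axis0[0], axis0[1], axis0[2]);
  NumericVector xn0 = init["nucleus"];
  Vec3 x_nuc(xn0[0], xn0[1], xn0[2]);
  NumericMatrix md = init["mtoc_dirs"];
  NumericMatrix cd = init["cmt_dirs"];
  IntegerVector ca = init["cmt_anchor"]; // 1-based body index

  int n_founders = md.nrow();
  std::vector<Body> bodies(n_founders);
  for (int i = 0; i < n_founders; ++i) {
    bodies[i].dir = Vec3(md(i, 0), md(i, 1), md(i, 2)).unit();
    bodies[i].r = P.r_spb;
    bodies[i].founders = 1;
    bodies[i].alive = true;
  }
  std::vector<Cmt> cmts(cd.nrow());
  for (int i = 0; i < cd.nrow(); ++i) {
    cmts[i].body = ca[i] - 1;
    cmts[i].dir = Vec3(cd(i, 0), cd(i, 1), cd(i, 2)).unit();
    cmts[i].len = 0.0;
    cmts[i].state = 0;
    cmts[i].sliding = cmts[i].buckled = false;
    cmts[i].entry_len = 0.0;
  }
  // one kinetochore per founding MTOC, tethered just under the envelope;
  // sisters are consecutive pairs (0,1), (2,3), ...
  std::vector<Kt> kts(n_founders);
  double kt_depth = P.r_nuc - P.r_spb - P.r_kt;
  for (int i = 0; i < n_founders; ++i) {
    kts[i].pos = x_nuc + bodies[i].dir * kt_depth;
    kts[i].sister = (i % 2 == 0) ? i + 1 : i - 1;
    if (kts[i].sister >= n_founders) kts[i].sister = -1;
    kts[i].body = i;
    kts[i].kmt_len = P.r_spb + P.r_kt; // spans MTOC surface to KT surface
    kts[i].kmt_state = 0;
  }
  std::vector<Ipmt> ipmts;

  bool clustered = (n_founders == 1);
  bool duplicated = false;
  bool migrated = false;
  double t_cluster = NA_REAL, t_migrate = NA_REAL;
  int n_alive = n_founders;

  // logs
  std::vector<double> ev_t, ev_a, ev_b, ev_merged, ev_nrem;
  std::vector<double> tr_t, tr_neck, tr_nx, tr_ny, tr_nz, tr_nb, tr_ml, tr_rb, tr_sp;
  double max_fint = 0.0, max_ne_resid = 0.0, max_disp = 0.0;
  double cum_len = 0.0; long cum_len_n = 0;
  double disp_cap = 0.1 * P.r_spb; // numerical safeguard on per-step motion

  int n_steps = (int)std::ceil(P.cutoff / P.dt);
  double fc_cell = P.fc; // per-cell cMT catastrophe rate (s^-1)

  std::vector<Vec3> Fbody(bodies.size());
  std::vector<Vec3> Fkt(kts.size());

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * P.dt;
    G.update(t);
    Vec3 F_nuc;
    Vec3 F_int_sum; // action-reaction bookkeeping over internal forces
    for (size_t i = 0; i < bodies.size(); ++i) Fbody[i] = Vec3();
    for (size_t i = 0; i < kts.size(); ++i) Fkt[i] = Vec3();

    // world anchor positions of alive bodies
    std::vector<Vec3> A(bodies.size());
    for (size_t b = 0; b < bodies.size(); ++b)
      if (bodies[b].alive) A[b] = x_nuc + bodies[b].dir * P.r_nuc;

    int mother_spb = -1; // post-duplication, the SPB closer to the mother pole
    if (duplicated) {
      int alive_idx[2]; int k = 0;
      for (size_t b = 0; b < bodies.size(); ++b)
        if (bodies[b].alive && k < 2) alive_idx[k++] = (int)b;
      if (k == 2) {
        mother_spb = (A[alive_idx[0]].dot(G.axis) <= A[alive_idx[1]].dot(G.axis))
                     ? alive_idx[0] : alive_idx[1];
      }
    }

    // ---- cytoplasmic MTs ----
    double sum_len = 0.0;
    for (size_t m = 0; m < cmts.size(); ++m) {
      Cmt& mt = cmts[m];
      if (!bodies[mt.body].alive) continue; // reassigned on fusion; safety
      Vec3 anchor = A[mt.body];
      if (mt.sliding) {
        Vec3 d = mt.tip - anchor;
        mt.len = d.norm();
        if (mt.len < 1e-6) { mt.sliding = false; mt.len = 0; }
        else mt.dir = d * (1.0 / mt.len);
      }
      Vec3 tip = mt.sliding ? mt.tip : anchor + mt.dir * mt.len;
      double d_in; Vec3 n_in; int region;
      G.classify(tip, d_in, n_in, region);
      double l_cor = G.wcor - d_in;
      if (l_cor < 0) l_cor = 0;
      if (l_cor > G.wcor) l_cor = G.wcor;
      bool in_mother_cortex = (region == 1) || (region == -1 && tip.dot(G.axis) < G.septin_a);
      bool in_daughter_cortex = (region == 3) || (region == -1 && tip.dot(G.axis) >= G.septin_a);

      // cortical interaction with bias applies to all pre-duplication MTOC
      // cMTs; after SPB duplication only to cMTs from the mother-side SPB
      bool bias_active = !duplicated || (mt.body == mother_spb);

      double f_load = 0.0;
      if (l_cor > 0) {
        double lam_mult;
        if (in_daughter_cortex) {
          // daughter-cortex dynein puncta belong to the large-budded stage
          if (G.rb < P.daughter_onset_bi * G.rm) lam_mult = 0.0;
          else if (P.punctate) {
            Vec3 qb = (tip - G.axis * G.bud_c).unit();
            lam_mult = (qb.dot(G.axis) > P.patch_cos) ? P.patch_mult : P.rest_mult;
          } else lam_mult = 1.0;
          lam_mult *= P.daughter_trans;
        } else {
          lam_mult = P.mother_mult;
          if (P.bias_scales_dynein && bias_active) lam_mult *= P.B;
        }
        // dynein acts along the whole cortex-embedded segment of a cMT that
        // slid into the daughter cortex ("long sliding cMTs ... experience
        // strong effective dynein pull"); radial penetration bounds the
        // mother-cortex and non-sliding contacts
        double l_pull = l_cor;
        if (mt.sliding) {
          double seg = mt.len - mt.entry_len + G.wcor;
          if (seg > mt.len) seg = mt.len;
          if (seg > 3.0) seg = 3.0;
          if (seg > l_pull) l_pull = seg;
        }
        // with bias_scales_dynein the scale B attenuates the whole
        // mother-cortex interaction (structurally compromised cMTs
        // transmit little force)
        double trans = (P.bias_scales_dynein && bias_active &&
                        !in_daughter_cortex) ? P.B : 1.0;
        double f_pull = l_pull * P.lambda_dyn * lam_mult * P.f_dyn;
        Vec3 fp = mt.dir * f_pull;
        F_nuc += fp; Fbody[mt.body] += fp;
        if (mt.state == 0) {
          // elastic resistance while growing into the cortex, inward along
          // the MT axis
          double f_push = l_cor * P.k_cor * trans;
          Vec3 fq = mt.dir * (-f_push);
          F_nuc += fq; Fbody[mt.body] += fq;
          f_load += f_push;
        }
        // Bim1 bias: the tangential force acts at the plus end and biases
        // its movement toward the septin ring (rod pivots about the anchor
        // with rotational mobility 3 ln(2L/d) / (pi eta L^3)); it is not a
        // body force on the nucleus.
        if (in_mother_cortex && bias_active && P.lambda_bim1 > 0 &&
            mt.len > 0.05) {
          double f_b = P.B * l_cor * P.lambda_bim1 * P.f_dyn;
          Vec3 rp = G.ring_point(tip);
          Vec3 v = rp - tip;
          Vec3 n_out = n_in * (-1.0);
          Vec3 vt = v - n_out * v.dot(n_out);
          double vn = vt.norm();
          if (vn > 1e-9 && f_b > 0) {
            double L = std::max(mt.len, 0.2);
            double v_tip = 3.0 * f_b * std::log(2.0 * L / 0.025) /
                           (M_PI * P.eta_cyt * L);
            // engaged cortical dyneins grip the MT and resist tangential
            // plus-end movement
            v_tip /= std::max(1.0, P.mother_mult);
            if (v_tip > 1.0) v_tip = 1.0; // um/s safety cap
            Vec3 newtip = tip + vt * (v_tip * P.dt / vn);
            // the rod cannot rotate inward through the nucleus: herding is
            // deflected along the tangency horizon of the anchor
            Vec3 nd = (newtip - anchor).unit();
            double dm = nd.dot(bodies[mt.body].dir);
            if (dm < 0.05)
              nd = (nd + bodies[mt.body].dir * (0.05 - dm)).unit();
            if (mt.sliding) {
              mt.tip = G.project_to_surface(anchor + nd * std::max(mt.len, 0.1));
              Vec3 d = mt.tip - anchor;
              mt.len = d.norm();
              if (mt.len > 1e-9) mt.dir = d * (1.0 / mt.len);
            } else {
              mt.dir = nd;
              if (mt.buckled) {
                // reoriented toward tangency: convert to sliding when the
                // incidence angle falls below the threshold
                double sin_th = std::fabs(mt.dir.dot(n_out));
                if (std::asin(std::min(1.0, sin_th)) < P.slide_angle) {
                  mt.buckled = false;
                  mt.sliding = true;
                  mt.tip = G.project_to_surface(anchor + mt.dir * mt.len);
                  Vec3 d = mt.tip - anchor;
                  mt.len = d.norm();
                  mt.entry_len = mt.len;
                  if (mt.len > 1e-9) mt.dir = d * (1.0 / mt.len);
                }
              }
            }
          }
        }
      }
      if (mt.buckled && mt.len > 0.05) {
        // first-order Euler buckling ~ 1/l^2; short rods cannot buckle --
        // their critical force exceeds anything the cortex supplies, so the
        // transmitted force saturates at the stall scale
        double f_bk = PI2 * P.kappa / (mt.len * mt.len);
        if (f_bk > 2.0) f_bk = 2.0;
        if (P.bias_scales_dynein && bias_active && !in_daughter_cortex)
          f_bk *= P.B;
        Vec3 fb = mt.dir * (-f_bk);
        F_nuc += fb; Fbody[mt.body] += fb;
        f_load += f_bk;
      }

      // dynamic instability
      if (mt.state == 0) {
        double vg_eff, fc_eff;
        load_dependent(P, fc_cell, f_load, vg_eff, fc_eff);
        if (unif_rand() < 1.0 - std::exp(-fc_eff * P.dt)) {
          mt.state = 1;
          if (l_cor >= 0.99 * G.wcor || mt.buckled) { // catastrophe at the wall
            double fw_mag = P.f_wall;
            if (P.bias_scales_dynein && bias_active && !in_daughter_cortex)
              fw_mag *= P.B;
            Vec3 fw = mt.dir * (-fw_mag);
            F_nuc += fw; Fbody[mt.body] += fw;
          }
          mt.sliding = false; mt.buckled = false;
        } else if (mt.sliding) {
          Vec3 n_out = n_in * (-1.0);
          Vec3 tdir = mt.dir - n_out * mt.dir.dot(n_out);
          double tn = tdir.norm();
          if (tn > 1e-9) {
            mt.tip = G.project_to_surface(mt.tip + tdir * (vg_eff * P.dt / tn));
            Vec3 d = mt.tip - anchor;
            mt.len = d.norm();
            if (mt.len > 1e-9) mt.dir = d * (1.0 / mt.len);
          } else { mt.sliding = false; mt.buckled = true; }
        } else if (!mt.buckled) {
          double newlen = mt.len + vg_eff * P.dt;
          Vec3 newtip = anchor + mt.dir * newlen;
          double d2; Vec3 n2; int reg2;
          G.classify(newtip, d2, n2, reg2);
          if (d2 < 0) { // would exit the cell
            Vec3 n_out = n2 * (-1.0);
            double sin_th = std::fabs(mt.dir.dot(n_out));
            double theta = std::asin(std::min(1.0, sin_th));
            if (theta < P.slide_angle) {
              mt.sliding = true;
              mt.tip = G.project_to_surface(newtip);
              Vec3 d = mt.tip - anchor;
              mt.len = d.norm();
              mt.entry_len = mt.len;
              if (mt.len > 1e-9) mt.dir = d * (1.0 / mt.len);
            } else {
              mt.buckled = true; // pinned at the boundary; no further growth
            }
          } else {
            mt.len = newlen;
          }
        }
      } else {
        mt.len -= P.vs * P.dt;
        if (mt.len <= 0) { // full depolymerisation: renucleate
          mt.len = 0; mt.state = 0; mt.sliding = false; mt.buckled = false;
          mt.entry_len = 0.0;
          mt.dir = rand_outward_hemisphere(bodies[mt.body].dir);
        } else if (unif_rand() < 1.0 - std::exp(-P.fr * P.dt)) {
          mt.state = 0;
        }
      }
      if (mt.sliding) { // keep tip inside; anchor drift can strand it
        double d3; Vec3 n3; int r3;
        G.classify(mt.tip, d3, n3, r3);
        if (d3 < 0) mt.tip = G.project_to_surface(mt.tip);
      }
      sum_len += mt.len;
    }
    cum_len += sum_len / std::max((size_t)1, cmts.size());
    cum_len_n += 1;

    // ---- kinetochore MTs (MTOC/SPB -> KT) ----
    // before SPB duplication the kinetochore rides rigidly under its MTOC
    // ("a single kinetochore is associated with a single MTOC"); kMT
    // mechanics begin with spindle assembly
    for (size_t k = 0; k < kts.size() && duplicated; ++k) {
      Kt& kt = kts[k];
      if (!bodies[kt.body].alive) continue;
      Vec3 d = kt.pos - A[kt.body];
      double d_bk = d.norm();
      if (d_bk < 1e-9) continue;
      Vec3 dirk = d * (1.0 / d_bk);
      double d_c = d_bk - P.r_kt; // anchor to KT surface
      double l_pen = kt.kmt_len - d_c;
      double f_load = 0.0;
      if (l_pen > 0) {
        if (l_pen > 2 * P.r_kt) l_pen = 2 * P.r_kt;
        Vec3 fv = dirk * (l_pen * P.k_fibril);
        Fkt[k] += fv; F_int_sum += fv;
        Fbody[kt.body] -= fv; F_int_sum -= fv;
        f_load = l_pen * P.k_fibril;
      } else {
        // attachment spring: a tip short of the kinetochore leaves a gap
        // and the kMT-KT spring pulls them together (pulling state is
        // defined by l_gap > 0)
        double l_gap = d_c - kt.kmt_len;
        if (l_gap > 0) {
          Vec3 fv = dirk * (l_gap * P.k_c);
          Fkt[k] -= fv; F_int_sum -= fv;
          Fbody[kt.body] += fv; F_int_sum += fv;
        }
      }
      // instability with length-dependent catastrophe
      if (kt.kmt_state == 0) {
        double fc0 = std::max(1e-8, P.h_kmt * kt.kmt_len);
        double vg_eff, fc_eff;
        load_dependent(P, fc0, f_load, vg_eff, fc_eff);
        if (unif_rand() < 1.0 - std::exp(-fc_eff * P.dt)) kt.kmt_state = 1;
        else {
          kt.kmt_len += vg_eff * P.dt;
          double lmax = d_c + 2 * P.r_kt;
          if (kt.kmt_len > lmax) kt.kmt_len = lmax;
        }
      } else {
        kt.kmt_len -= P.vs * P.dt;
        if (kt.kmt_len <= 0) { kt.kmt_len = 0; kt.kmt_state = 0; }
        else if (unif_rand() < 1.0 - std::exp(-P.fr * P.dt)) kt.kmt_state = 0;
      }
    }

    // ---- kinetochore pair forces: cohesin + hard-core repulsion ----
    for (size_t i = 0; i < kts.size() && duplicated; ++i) {
      for (size_t j = i + 1; j < kts.size(); ++j) {
        Vec3 d = kts[j].pos - kts[i].pos;
        double dist = d.norm();
        if (dist < 1e-9) continue;
        Vec3 u = d * (1.0 / dist);
        if (duplicated && (int)j == kts[i].sister) {
          // cohesin engages with the metaphase spindle, after duplication
          Vec3 fv = u * (P.k_coh * dist);
          Fkt[i] += fv; F_int_sum += fv;
          Fkt[j] -= fv; F_int_sum -= fv;
        }
        double ov = 2 * P.r_kt - dist;
        if (ov > 0) {
          Vec3 fv = u * (P.c_rep * ov);
          Fkt[i] -= fv; F_int_sum -= fv;
          Fkt[j] += fv; F_int_sum += fv;
        }
      }
    }

    // ---- interpolar MTs (post-duplication kinesin-5 sliding) ----
    if (duplicated && mother_spb >= 0) {
      int other = -1;
      for (size_t b = 0; b < bodies.size(); ++b)
        if (bodies[b].alive && (int)b != mother_spb) other = (int)b;
      if (other >= 0) {
        Vec3 d12 = A[other] - A[mother_spb];
        double dd = d12.norm();
        Vec3 u = (dd > 1e-9) ? d12 * (1.0 / dd) : Vec3(1, 0, 0);
        double l_ov = 0.0;
        for (size_t i = 0; i < ipmts.size(); ++i) {
          if (ipmts[i].spb != 0) continue;
          double L0 = ipmts[i].len;
          for (size_t j = 0; j < ipmts.size(); ++j) {
            if (ipmts[j].spb != 1) continue;
            double L1 = ipmts[j].len;
            double ov = std::min(L0, dd) - std::max(0.0, dd - L1);
            if (ov > 0) l_ov += ov;
          }
        }
        Vec3 fv = u * (l_ov * P.lambda_ipmt * P.f_k5);
        Fbody[mother_spb] -= fv; F_int_sum -= fv;
        Fbody[other] += fv; F_int_sum += fv;
        // ipMT dynamics (length-regulated like kMTs, confined by the nucleus)
        for (size_t i = 0; i < ipmts.size(); ++i) {
          Ipmt& ip = ipmts[i];
          if (ip.state == 0) {
            double fc0 = std::max(1e-8, P.h_kmt * ip.len);
            if (unif_rand() < 1.0 - std::exp(-fc0 * P.dt)) ip.state = 1;
            else {
              ip.len += P.vg * P.dt;
              if (ip.len > 2 * P.r_nuc) ip.len = 2 * P.r_nuc;
            }
          } else {
            ip.len -= P.vs * P.dt;
            if (ip.len <= 0) { ip.len = 0; ip.state = 0; }
            else if (unif_rand() < 1.0 - std::exp(-P.fr * P.dt)) ip.state = 0;
          }
        }
      }
    }

    // ---- nucleus containment (soft harmonic shell) ----
    {
      double d_in; Vec3 n_in; int region;
      G.classify(x_nuc, d_in, n_in, region);
      if (d_in < P.r_nuc) F_nuc += n_in * (P.k_cor * (P.r_nuc - d_in));
    }

    // ---- integrate (overdamped Euler + constraint re-projection) ----
    double xi_nuc = 6 * M_PI * P.eta_nuc * P.r_nuc;
    double xi_kt = 6 * M_PI * P.eta_nu * P.r_kt;
    Vec3 dx_nuc = F_nuc * (P.dt / xi_nuc);
    double dn = dx_nuc.norm();
    if (dn > disp_cap) dx_nuc = dx_nuc * (disp_cap / dn);
    if (dn > max_disp) max_disp = dn;
    Vec3 x_nuc_new = x_nuc + dx_nuc;
    { // hard steric backstop: centre cannot sink deeper than w_cor into the shell
      double d_in; Vec3 n_in; int region;
      G.classify(x_nuc_new, d_in, n_in, region);
      double floor_d = P.r_nuc - G.wcor;
      if (d_in < floor_d) x_nuc_new += n_in * (floor_d - d_in);
      dx_nuc = x_nuc_new - x_nuc;
    }

    for (size_t b = 0; b < bodies.size(); ++b) {
      if (!bodies[b].alive) continue;
      double xi_b = 6 * M_PI * P.eta_ne * bodies[b].r;
      Vec3 dxb = Fbody[b] * (P.dt / xi_b);
      double nb2 = dxb.norm();
      if (nb2 > disp_cap) dxb = dxb * (disp_cap / nb2);
      if (nb2 > max_disp) max_disp = nb2;
      Vec3 Xw = A[b] + dxb;
      bodies[b].dir = (Xw - x_nuc_new).unit(); // re-project onto the NE sphere
      double resid = std::fabs((x_nuc_new + bodies[b].dir * P.r_nuc - x_nuc_new).norm() - P.r_nuc);
      if (resid > max_ne_resid) max_ne_resid = resid;
    }
    for (size_t k = 0; k < kts.size(); ++k) {
      if (!duplicated) { // rigid association: ride under the tether body
        int b = kts[k].body;
        kts[k].pos = x_nuc_new + bodies[b].dir *
                     (P.r_nuc - bodies[b].r - P.r_kt);
        continue;
      }
      Vec3 dxk = Fkt[k] * (P.dt / xi_kt);
      double nk = dxk.norm();
      if (nk > disp_cap) dxk = dxk * (disp_cap / nk);
      if (nk > max_disp) max_disp = nk;
      // advected with the nucleoplasm, then confined inside the nucleus
      Vec3 pos = kts[k].pos + dxk + dx_nuc;
      Vec3 rel = pos - x_nuc_new;
      double rr = rel.norm();
      double rmax = P.r_nuc - P.r_kt;
      if (rr > rmax) pos = x_nuc_new + rel * (rmax / rr);
      kts[k].pos = pos;
    }
    x_nuc = x_nuc_new;
    double fi = F_int_sum.norm();
    if (fi > max_fint) max_fint = fi;

    // ---- MTOC fusion (surface contact), pre-duplication only ----
    if (!duplicated && n_alive > 1) {
      bool merged_any = true;
      while (merged_any && n_alive > 1) {
        merged_any = false;
        for (size_t i = 0; i < bodies.size() && !merged_any; ++i) {
          if (!bodies[i].alive) continue;
          for (size_t j = i + 1; j < bodies.size() && !merged_any; ++j) {
            if (!bodies[j].alive) continue;
            Vec3 Ai = x_nuc + bodies[i].dir * P.r_nuc;
            Vec3 Aj = x_nuc + bodies[j].dir * P.r_nuc;
            double dist = (Ai - Aj).norm();
            if (dist <= bodies[i].r + bodies[j].r + 1e-3) {
              double wi = std::pow(bodies[i].r, 3), wj = std::pow(bodies[j].r, 3);
              Vec3 mid = (Ai * wi + Aj * wj) * (1.0 / (wi + wj));
              bodies[i].dir = (mid - x_nuc).unit();
              bodies[i].r = std::cbrt(wi + wj);
              bodies[i].founders += bodies[j].founders;
              bodies[j].alive = false;
              for (size_t m = 0; m < cmts.size(); ++m)
                if (cmts[m].body == (int)j) cmts[m].body = (int)i;
              for (size_t k = 0; k < kts.size(); ++k)
                if (kts[k].body == (int)j) kts[k].body = (int)i;
              n_alive -= 1;
              ev_t.push_back(t / 60.0);
              ev_a.push_back((double)i + 1);
              ev_b.push_back((double)j + 1);
              ev_merged.push_back((double)i + 1);
              ev_nrem.push_back((double)n_alive);
              merged_any = true;
            }
          }
        }
      }
      if (n_alive == 1 && !clustered) {
        clustered = true;
        t_cluster = t / 60.0;
        // ---- SPB duplication ----
        int i0 = -1;
        for (size_t b = 0; b < bodies.size(); ++b) if (bodies[b].alive) i0 = (int)b;
        double vol = std::pow(bodies[i0].r, 3);
        double r_half = std::cbrt(vol / 2.0);
        Vec3 n0 = bodies[i0].dir;
        Vec3 tdir = rand_unit();
        tdir = (tdir - n0 * tdir.dot(n0)).unit();
        Vec3 Ai = x_nuc + n0 * P.r_nuc;
        Body b1, b2;
        b1.dir = ((Ai + tdir * P.r_spb) - x_nuc).unit();
        b2.dir = ((Ai - tdir * P.r_spb) - x_nuc).unit();
        b1.r = b2.r = r_half;
        b1.founders = bodies[i0].founders / 2;
        b2.founders = bodies[i0].founders - b1.founders;
        b1.alive = b2.alive = true;
        bodies[i0].alive = false;
        bodies.push_back(b1);
        bodies.push_back(b2);
        Fbody.resize(bodies.size());
        int id1 = (int)bodies.size() - 2, id2 = (int)bodies.size() - 1;
        int flip = 0;
        for (size_t m = 0; m < cmts.size(); ++m)
          if (cmts[m].body == i0) cmts[m].body = (flip++ % 2 == 0) ? id1 : id2;
        // bi-orient sisters across the two SPBs; kMT spans the current gap
        for (size_t k = 0; k < kts.size(); ++k) {
          int target = (k % 2 == 0) ? id1 : id2;
          kts[k].body = target;
          Vec3 Ab = x_nuc + bodies[target].dir * P.r_nuc;
          kts[k].kmt_len = std::max(0.0, (kts[k].pos - Ab).norm() - P.r_kt);
          kts[k].kmt_state = 0;
        }
        for (int s = 0; s < 2; ++s)
          for (int i = 0; i < P.n_ipmt; ++i) {
            Ipmt ip; ip.spb = s; ip.len = 0.1; ip.state = 0;
            ipmts.push_back(ip);
          }
        duplicated = true;
      }
    }

    // ---- migration detection ----
    double neck_dist = x_nuc.dot(G.axis) - G.septin_a;
    if (!migrated && neck_dist >= P.mig_thresh) {
      migrated = true;
      t_migrate = t / 60.0;
    }

    // ---- sampling ----
    if (step % P.sample_every == 0 && P.record_series) {
      tr_t.push_back(t / 60.0);
      tr_neck.push_back(neck_dist);
      tr_nx.push_back(x_nuc.x); tr_ny.push_back(x_nuc.y); tr_nz.push_back(x_nuc.z);
      tr_nb.push_back((double)n_alive);
      tr_ml.push_back(sum_len / std::max((size_t)1, cmts.size()));
      tr_rb.push_back(G.rb);
      double spread = 0.0;
      for (size_t i = 0; i < bodies.size(); ++i) {
        if (!bodies[i].alive) continue;
        for (size_t j = i + 1; j < bodies.size(); ++j) {
          if (!bodies[j].alive) continue;
          double dd = ((bodies[i].dir - bodies[j].dir) * P.r_nuc).norm();
          if (dd > spread) spread = dd;
        }
      }
      tr_sp.push_back(spread);
    }
    if (P.stop_early && clustered && migrated) break;
  }

  double final_neck = x_nuc.dot(G.axis) - G.septin_a;
  List traj = List::create(
    _["time_min"] = tr_t, _["neck_dist_um"] = tr_neck,
    _["nucleus_x"] = tr_nx, _["nucleus_y"] = tr_ny, _["nucleus_z"] = tr_nz,
    _["n_bodies"] = tr_nb, _["mean_cmt_len_um"] = tr_ml, _["bud_radius_um"] = tr_rb,
    _["body_spread_um"] = tr_sp);
  List fusion = List::create(
    _["time_min"] = ev_t, _["body_a"] = ev_a, _["body_b"] = ev_b,
    _["merged_id"] = ev_merged, _["n_remaining"] = ev_nrem);
  return List::create(
    _["clustering_time_min"] = t_cluster,
    _["clustering_complete"] = clustered,
    _["migration_time_min"] = t_migrate,
    _["migrated"] = migrated,
    _["mean_cmt_length_um"] = (cum_len_n > 0 ? cum_len / cum_len_n : NA_REAL),
    _["final_neck_dist_um"] = final_neck,
    _["n_bodies_final"] = n_alive,
    _["frac_mtocs_fused"] = 1.0 - (double)(n_alive - 1) / std::max(1, n_founders - 1),
    _["max_internal_force_residual"] = max_fint,
    _["max_ne_residual"] = max_ne_resid,
    _["max_step_displacement"] = max_disp,
    _["trajectory"] = traj,
    _["fusion_log"] = fusion);
}

// Free-space dynamic instability: lengths sampled from one long trajectory of
// an unconfined MT that renucleates (growing, length 0) on full shrinkage.
// [[Rcpp::export(name = ".free_mt_lengths_cpp")]]
NumericVector free_mt_lengths_cpp(int n_samples, double sample_interval,
                                  double vg, double vs, double fc, double fr,
                                  double dt, double burnin) {
  NumericVector out(n_samples);
  double len = 0.0; int state = 0;
  int steps_per_sample = std::max(1, (int)std::round(sample_interval / dt));
  int burn_steps = (int)std::round(burnin / dt);
  double p_cat = 1.0 - std::exp(-fc * dt), p_res = 1.0 - std::exp(-fr * dt);
  long total = (long)n_samples * steps_per_sample + burn_steps;
  int isamp = 0, since = 0;
  for (long s = 0; s < total && isamp < n_samples; ++s) {
    if (state == 0) {
      if (unif_rand() < p_cat) state = 1; else len += vg * dt;
    } else {
      len -= vs * dt;
      if (len <= 0) { len = 0; state = 0; }
      else if (unif_rand() < p_res) state = 0;
    }
    if (s >= burn_steps) {
      if (++since == steps_per_sample) { out[isamp++] = len; since = 0; }
    }
  }
  return out;
}
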