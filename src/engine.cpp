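// Simulation engine: synchronous per-tick fish steering updates, diver
// movement, once-per-second saturating counts and 10-second behavioural
// state re-picks.  All stochastic draws come from R's RNG so that runs are
// reproducible from set.seed() and bit-identical to the R-level reference
// formulas.
//
// RNG draw order (the contract the R mirrors rely on):
//   * movement tick: one uniform per fish, ascending index (wander deviation,
//     drawn whether or not the wander weight is zero);
//   * state re-pick: two uniforms per fish, ascending index
//     (state pick, then hidden ~ Bernoulli(1 - detectability)).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double DT = 0.1;      // movement tick, seconds
static const double EPS = 1e-9;

struct FT {
  double size, id_dist, approach, percep, percep2, cos_half;
  bool cone_all;                   // perception angle == 360 degrees
  double amax, vsus, vburst, k;    // k: quadratic drag constant
  int ns;
  bool any_school;
  std::vector<double> freq_cum, detect, school_dist, patch_dist;
  std::vector<double> wa, wc, ws, ww, wr, wcr, wp, wd;
  std::vector<int> school;
};

struct Fish {
  int n;
  std::vector<double> x, y, vx, vy, hx, hy, px, py;
  std::vector<int> state;          // 1-based
  std::vector<int> hidden;
};

struct Diver {
  bool present;
  int protocol;                    // 0 transect, 1 point
  double x, y, heading;            // heading in radians
  double speed, rot;               // m/s and rad/s (clockwise)
  double half_width, y0, y1;       // transect strip limits
  double radius;                   // point-count radius
  double cos_view_half;
  int mem_rule;                    // 0: forget on leaving the sampling unit
                                   // 1: forget on leaving the view cone /
                                   //    going hidden (instantaneous FOV)
  std::vector<int> mem;
  int count;
  double dist;                     // distance travelled (transect)
};

static FT parse_ft(const List& ft) {
  FT f;
  f.size     = as<double>(ft["size"]);
  f.id_dist  = as<double>(ft["id_dist"]);
  f.approach = as<double>(ft["approach_dist"]);
  f.percep   = as<double>(ft["percep_dist"]);
  f.percep2  = f.percep * f.percep;
  double ang = as<double>(ft["percep_angle"]);      // degrees
  f.cone_all = ang >= 360.0 - 1e-9;
  f.cos_half = std::cos(ang * M_PI / 360.0);        // cos(half angle)
  f.amax     = as<double>(ft["max_accel"]);
  f.vsus     = as<double>(ft["max_sustained_speed"]);
  f.vburst   = as<double>(ft["burst_speed"]);
  f.k        = as<double>(ft["drag_k"]);
  NumericVector fr = ft["freq"], de = ft["detect"],
    sd = ft["school_dist_m"], pd = ft["patch_dist"],
    wa = ft["w_align"], wc = ft["w_centre"], ws = ft["w_spacing"],
    ww = ft["w_wander"], wr = ft["w_rest"], wcr = ft["w_cruise"],
    wp = ft["w_patch"], wd = ft["w_diver"];
  IntegerVector sc = ft["school"];
  f.ns = fr.size();
  double cum = 0.0;
  f.any_school = false;
  for (int s = 0; s < f.ns; ++s) {
    cum += fr[s];
    f.freq_cum.push_back(cum);
    f.detect.push_back(de[s]);
    f.school_dist.push_back(sd[s]);
    f.patch_dist.push_back(pd[s]);
    f.wa.push_back(wa[s]); f.wc.push_back(wc[s]); f.ws.push_back(ws[s]);
    f.ww.push_back(ww[s]); f.wr.push_back(wr[s]); f.wcr.push_back(wcr[s]);
    f.wp.push_back(wp[s]); f.wd.push_back(wd[s]);
    f.school.push_back(sc[s]);
    if (sc[s]) f.any_school = true;
  }
  f.freq_cum[f.ns - 1] = 1.0;      // guard against rounding
  return f;
}

static Fish parse_fish(const List& fl) {
  Fish f;
  NumericVector x = fl["x"], y = fl["y"], vx = fl["vx"], vy = fl["vy"],
    hx = fl["hx"], hy = fl["hy"], px = fl["px"], py = fl["py"];
  IntegerVector st = fl["state"], hid = fl["hidden"];
  f.n = x.size();
  f.x.assign(x.begin(), x.end());   f.y.assign(y.begin(), y.end());
  f.vx.assign(vx.begin(), vx.end()); f.vy.assign(vy.begin(), vy.end());
  f.hx.assign(hx.begin(), hx.end()); f.hy.assign(hy.begin(), hy.end());
  f.px.assign(px.begin(), px.end()); f.py.assign(py.begin(), py.end());
  f.state.assign(st.begin(), st.end());
  f.hidden.assign(hid.begin(), hid.end());
  return f;
}

static List fish_to_list(const Fish& f) {
  return List::create(
    _["x"] = wrap(f.x), _["y"] = wrap(f.y),
    _["vx"] = wrap(f.vx), _["vy"] = wrap(f.vy),
    _["hx"] = wrap(f.hx), _["hy"] = wrap(f.hy),
    _["px"] = wrap(f.px), _["py"] = wrap(f.py),
    _["state"] = wrap(f.state), _["hidden"] = wrap(f.hidden));
}

static Diver parse_diver(SEXP dsexp) {
  Diver d;
  if (Rf_isNull(dsexp)) { d.present = false; return d; }
  List dl(dsexp);
  d.present = true;
  d.protocol = as<int>(dl["protocol"]);
  d.x = as<double>(dl["x"]); d.y = as<double>(dl["y"]);
  d.heading = as<double>(dl["heading"]);
  d.speed = as<double>(dl["speed_mps"]);
  d.rot = as<double>(dl["rot_rad_ps"]);
  d.half_width = as<double>(dl["half_width"]);
  d.y0 = as<double>(dl["y0"]); d.y1 = as<double>(dl["y1"]);
  d.radius = as<double>(dl["radius"]);
  d.cos_view_half = as<double>(dl["cos_view_half"]);
  d.mem_rule = as<int>(dl["mem_rule"]);
  IntegerVector mem = dl["mem"];
  d.mem.assign(mem.begin(), mem.end());
  d.count = as<int>(dl["count"]);
  d.dist = as<double>(dl["dist"]);
  return d;
}

static SEXP diver_to_list(const Diver& d) {
  if (!d.present) return R_NilValue;
  return List::create(
    _["protocol"] = d.protocol, _["x"] = d.x, _["y"] = d.y,
    _["heading"] = d.heading, _["speed_mps"] = d.speed,
    _["rot_rad_ps"] = d.rot, _["half_width"] = d.half_width,
    _["y0"] = d.y0, _["y1"] = d.y1, _["radius"] = d.radius,
    _["cos_view_half"] = d.cos_view_half, _["mem_rule"] = d.mem_rule,
    _["mem"] = wrap(d.mem),
    _["count"] = d.count, _["dist"] = d.dist);
}

// minimum-image (shortest toroidal) separation for positions in [0, L)
static inline double mimg(double d, double L) {
  if (d > 0.5 * L) d -= L; else if (d < -0.5 * L) d += L;
  return d;
}

// spatial hash with 1 m cells for schoolmate search (toroidal)
struct Grid {
  int w, h;
  std::vector<int> head, nxt;
  void build(const Fish& f, double W, double H) {
    w = (int)std::ceil(W); h = (int)std::ceil(H);
    head.assign(w * h, -1);
    nxt.assign(f.n, -1);
    for (int i = 0; i < f.n; ++i) {
      int cx = (int)f.x[i]; if (cx >= w) cx = w - 1;
      int cy = (int)f.y[i]; if (cy >= h) cy = h - 1;
      int c = cy * w + cx;
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// one synchronous movement tick: all urges from the pre-step configuration,
// then every agent moves
static void move_tick(Fish& f, const FT& ft, Diver& d, double W, double H) {
  const int n = f.n;
  static std::vector<double> nvx, nvy, nx, ny, nhx, nhy;
  nvx.resize(n); nvy.resize(n); nx.resize(n); ny.resize(n);
  nhx.resize(n); nhy.resize(n);

  Grid grid;
  int rng_cells = 1;
  if (ft.any_school) {
    grid.build(f, W, H);
    rng_cells = std::max(1, (int)std::ceil(ft.percep));
  }

  for (int i = 0; i < n; ++i) {
    const double u = unif_rand();         // wander deviation draw (always)
    const int s = f.state[i] - 1;
    double ux = 0.0, uy = 0.0;
    bool burst = false;

    if (ft.school[s]) {
      // schoolmates within perception distance and cone (toroidal metric)
      double sax = 0, say = 0, scx = 0, scy = 0, ssx = 0, ssy = 0;
      int nn = 0;
      int cx = (int)f.x[i], cy = (int)f.y[i];
      for (int dy = -rng_cells; dy <= rng_cells; ++dy) {
        int gy = ((cy + dy) % grid.h + grid.h) % grid.h;
        for (int dx = -rng_cells; dx <= rng_cells; ++dx) {
          int gx = ((cx + dx) % grid.w + grid.w) % grid.w;
          for (int j = grid.head[gy * grid.w + gx]; j >= 0; j = grid.nxt[j]) {
            if (j == i) continue;
            double ddx = mimg(f.x[j] - f.x[i], W);
            double ddy = mimg(f.y[j] - f.y[i], H);
            double d2 = ddx * ddx + ddy * ddy;
            if (d2 > ft.percep2 || d2 < EPS * EPS) continue;
            double dist = std::sqrt(d2);
            if (!ft.cone_all) {
              double c = (ddx * f.hx[i] + ddy * f.hy[i]) / dist;
              if (c < ft.cos_half) continue;
            }
            ++nn;
            sax += f.hx[j]; say += f.hy[j];
            scx += ddx;     scy += ddy;
            if (dist < ft.school_dist[s]) {
              ssx -= ddx / dist; ssy -= ddy / dist;
            }
          }
        }
      }
      if (nn > 0) {
        double an = std::sqrt(sax * sax + say * say);
        if (an > EPS) { ux += ft.wa[s] * sax / an; uy += ft.wa[s] * say / an; }
        double cn = std::sqrt(scx * scx + scy * scy);
        if (cn > EPS) { ux += ft.wc[s] * scx / cn; uy += ft.wc[s] * scy / cn; }
        double sn = std::sqrt(ssx * ssx + ssy * ssy);
        if (sn > 1.0) { ssx /= sn; ssy /= sn; }   // clamp magnitude at 1
        ux += ft.ws[s] * ssx; uy += ft.ws[s] * ssy;
      }
    }

    if (ft.ww[s] != 0.0) {
      // wander: current heading rotated by U(-30, 30) degrees
      double dev = (-30.0 + 60.0 * u) * M_PI / 180.0;
      double cd = std::cos(dev), sd = std::sin(dev);
      ux += ft.ww[s] * (f.hx[i] * cd - f.hy[i] * sd);
      uy += ft.ww[s] * (f.hx[i] * sd + f.hy[i] * cd);
    }

    double spd = std::sqrt(f.vx[i] * f.vx[i] + f.vy[i] * f.vy[i]);
    if (ft.wr[s] != 0.0 && spd > EPS) {           // rest: oppose motion
      ux -= ft.wr[s] * f.vx[i] / spd;
      uy -= ft.wr[s] * f.vy[i] / spd;
    }
    if (ft.wcr[s] != 0.0) {                        // cruise: along heading
      ux += ft.wcr[s] * f.hx[i];
      uy += ft.wcr[s] * f.hy[i];
    }
    if (ft.wp[s] != 0.0) {                         // patch gathering
      double ddx = mimg(f.px[i] - f.x[i], W);
      double ddy = mimg(f.py[i] - f.y[i], H);
      double dist = std::sqrt(ddx * ddx + ddy * ddy);
      if (dist > ft.patch_dist[s] && dist > EPS) {
        ux += ft.wp[s] * ddx / dist;
        uy += ft.wp[s] * ddy / dist;
      }
    }
    if (d.present && ft.wd[s] != 0.0) {            // diver avoidance/attraction
      double ddx = mimg(f.x[i] - d.x, W);
      double ddy = mimg(f.y[i] - d.y, H);
      double dist = std::sqrt(ddx * ddx + ddy * ddy);
      if (dist < ft.id_dist) {
        burst = true;                              // flight/approach response
        double mag;
        if (dist <= ft.approach)
          mag = (ft.wd[s] > 0.0) ? 1.0 : 0.0;      // standoff for attraction
        else
          mag = (ft.id_dist - dist) / (ft.id_dist - ft.approach);
        if (mag > 0.0 && dist > EPS) {
          ux += ft.wd[s] * mag * ddx / dist;
          uy += ft.wd[s] * mag * ddy / dist;
        }
      }
    }

    // steering clipped at maximum acceleration
    double un = std::sqrt(ux * ux + uy * uy);
    if (un > ft.amax) { ux *= ft.amax / un; uy *= ft.amax / un; }

    // quadratic friction drag, then speed cap (burst only while reacting
    // to the diver)
    double decay = 1.0 - ft.k * spd * DT;
    if (decay < 0.0) decay = 0.0;
    double vx2 = f.vx[i] * decay + ux * DT;
    double vy2 = f.vy[i] * decay + uy * DT;
    double cap = burst ? ft.vburst : ft.vsus;
    double s2 = std::sqrt(vx2 * vx2 + vy2 * vy2);
    if (s2 > cap) { vx2 *= cap / s2; vy2 *= cap / s2; s2 = cap; }

    nvx[i] = vx2; nvy[i] = vy2;
    double xx = f.x[i] + vx2 * DT;
    double yy = f.y[i] + vy2 * DT;
    if (xx >= W) xx -= W; else if (xx < 0.0) xx += W;
    if (yy >= H) yy -= H; else if (yy < 0.0) yy += H;
    nx[i] = xx; ny[i] = yy;
    if (s2 > EPS) { nhx[i] = vx2 / s2; nhy[i] = vy2 / s2; }
    else          { nhx[i] = f.hx[i];  nhy[i] = f.hy[i]; }
  }

  for (int i = 0; i < n; ++i) {
    f.x[i] = nx[i]; f.y[i] = ny[i];
    f.vx[i] = nvx[i]; f.vy[i] = nvy[i];
    f.hx[i] = nhx[i]; f.hy[i] = nhy[i];
  }

  if (d.present) {
    if (d.protocol == 0) {                          // transect: forward
      d.y += d.speed * DT;
      d.dist += d.speed * DT;
    } else {                                        // point: rotate clockwise
      d.heading -= d.rot * DT;
    }
  }
}

// fish currently visible to the diver: not hidden, inside the sampling-unit
// limits, within visibility range and inside the view cone.  Plain (non-
// toroidal) geometry: the sampling unit never touches an edge.
static void visible_now(const Fish& f, const Diver& d, double vis,
                        std::vector<char>& vis_flag,
                        std::vector<char>& unit_flag,
                        std::vector<double>& dist) {
  double hx = std::cos(d.heading), hy = std::sin(d.heading);
  double vis2 = vis * vis;
  for (int i = 0; i < f.n; ++i) {
    vis_flag[i] = 0;
    unit_flag[i] = 0;
    double dx = f.x[i] - d.x, dy = f.y[i] - d.y;
    double d2 = dx * dx + dy * dy;
    if (d2 > vis2) continue;
    if (d.protocol == 0) {
      if (std::fabs(dx) > d.half_width) continue;
      if (f.y[i] < d.y0 || f.y[i] > d.y1) continue;
    } else {
      if (d2 > d.radius * d.radius) continue;
    }
    unit_flag[i] = 1;                    // inside sample limits and range
    if (f.hidden[i]) continue;
    double dd = std::sqrt(d2);
    if (dd > EPS) {
      double c = (dx * hx + dy * hy) / dd;
      if (c < d.cos_view_half) continue;
    }
    vis_flag[i] = 1;
    dist[i] = dd;
  }
}

// once-per-second count: prune the memory of counted fish, then add up to
// 3 closest un-remembered visible fish.  mem_rule 0 forgets a fish when it
// leaves the sampling unit (or visibility range); mem_rule 1 forgets it as
// soon as it drops out of the instantaneous field of view (cone or hidden
// included), making it recountable every time the view sweeps back.
static void count_second(const Fish& f, Diver& d, double vis) {
  std::vector<char> vflag(f.n), uflag(f.n);
  std::vector<double> dist(f.n);
  visible_now(f, d, vis, vflag, uflag, dist);
  std::vector<std::pair<double, int> > cand;
  double vis2 = vis * vis;
  for (int i = 0; i < f.n; ++i) {
    char keep;
    if (d.mem_rule == 1) keep = vflag[i];        // instantaneous FOV
    else if (d.mem_rule == 0) keep = uflag[i];   // sampling-unit limits
    else {                                       // visibility range only
      double dx = f.x[i] - d.x, dy = f.y[i] - d.y;
      keep = (dx * dx + dy * dy <= vis2) ? 1 : 0;
    }
    if (!keep) d.mem[i] = 0;
    if (vflag[i] && !d.mem[i])
      cand.push_back(std::make_pair(dist[i], i));
  }
  size_t take = cand.size() < 3 ? cand.size() : 3;
  std::partial_sort(cand.begin(), cand.begin() + take, cand.end());
  for (size_t k = 0; k < take; ++k) {
    d.mem[cand[k].second] = 1;
    d.count += 1;
  }
}

// every-10-seconds behavioural re-pick (with replacement) and hidden redraw
static void switch_states(Fish& f, const FT& ft) {
  for (int i = 0; i < f.n; ++i) {
    double u1 = unif_rand();
    int s = 0;
    while (s < ft.ns - 1 && u1 > ft.freq_cum[s]) ++s;
    f.state[i] = s + 1;
    double u2 = unif_rand();
    f.hidden[i] = (u2 > ft.detect[s]) ? 1 : 0;
  }
}

// [[Rcpp::export]]
List eng_move(List fish, List ftype, SEXP diver, List wcfg, int nticks) {
  Fish f = parse_fish(fish);
  FT ft = parse_ft(ftype);
  Diver d = parse_diver(diver);
  double W = as<double>(wcfg["width"]), H = as<double>(wcfg["height"]);
  for (int t = 0; t < nticks; ++t) move_tick(f, ft, d, W, H);
  return List::create(_["fish"] = fish_to_list(f),
                      _["diver"] = diver_to_list(d));
}

// [[Rcpp::export]]
List eng_count(List fish, List diver, List wcfg) {
  Fish f = parse_fish(fish);
  Diver d = parse_diver(diver);
  double vis = as<double>(wcfg["visibility"]);
  count_second(f, d, vis);
  return List(diver_to_list(d));
}

// [[Rcpp::export]]
List eng_switch(List fish, List ftype) {
  Fish f = parse_fish(fish);
  FT ft = parse_ft(ftype);
  switch_states(f, ft);
  return fish_to_list(f);
}

// [[Rcpp::export]]
List eng_visible(List fish, List diver, List wcfg) {
  Fish f = parse_fish(fish);
  Diver d = parse_diver(diver);
  double vis = as<double>(wcfg["visibility"]);
  std::vector<char> vflag(f.n), uflag(f.n);
  std::vector<double> dist(f.n);
  visible_now(f, d, vis, vflag, uflag, dist);
  std::vector<std::pair<double, int> > out;
  for (int i = 0; i < f.n; ++i)
    if (vflag[i]) out.push_back(std::make_pair(dist[i], i));
  std::sort(out.begin(), out.end());
  IntegerVector idx(out.size());
  NumericVector dd(out.size());
  for (size_t k = 0; k < out.size(); ++k) {
    idx[k] = out[k].second + 1;            // 1-based for R
    dd[k] = out[k].first;
  }
  return List::create(_["index"] = idx, _["distance"] = dd);
}

// full survey loop: nsec seconds of (10 movement ticks, then the per-second
// procedures).  Counting happens if a diver is present; state re-picks at
// model-clock values divisible by 10.
// [[Rcpp::export]]
List eng_run(List fish, List ftype, SEXP diver, List wcfg,
             int nsec, int clock0) {
  Fish f = parse_fish(fish);
  FT ft = parse_ft(ftype);
  Diver d = parse_diver(diver);
  double W = as<double>(wcfg["width"]), H = as<double>(wcfg["height"]);
  double vis = as<double>(wcfg["visibility"]);
  int clock = clock0;
  for (int s = 0; s < nsec; ++s) {
    for (int t = 0; t < 10; ++t) move_tick(f, ft, d, W, H);
    clock += 1;
    if (d.present) count_second(f, d, vis);
    if (clock % 10 == 0) switch_states(f, ft);
  }
  return List::create(_["fish"] = fish_to_list(f),
                      _["diver"] = diver_to_list(d),
                      _["clock"] = clock);
}
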