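// Exact stochastic simulation of the spatial consumer-resource /
// host-parasite metacommunity model on the unit torus, using the modified
// next-reaction method with one counter-based random stream per entity
// (individual, resource particle, production component).
//
// Why per-entity streams: replicate and removal (treatment/control)
// experiments share seeds. With entity-keyed streams, two paired runs
// perform identical draws for every entity whose local environment is
// unaffected by the manipulation, so treatment and control trajectories
// are exactly identical outside the causal cone of the removal. A single
// global stream would decouple the pair at the first event and bury small
// fitness effects in unrelated demographic noise. Offspring streams are
// keyed by (parent key, parent birth count), so lineages far from a
// perturbation stay coupled too.
//
// Event classes and their hazards:
//   production   : per landscape component, constant rate
//   expiry       : (1/tau_R) per unconsumed particle
//   movement     : m[sp] per live consumer (parasites ride their host)
//   death        : d[sp] (+ delta of the infecting parasite) per consumer,
//                  d_p[sp] per parasite; a host death kills its parasite
//   consumption  : contact * (#in-range usable consumers) per particle;
//                  each consumption triggers a birth with prob b[sp],
//                  offspring displaced by the wrapped Gaussian kernel
//   transmission : beta[sp] * (#in-range susceptible hosts) per parasite;
//                  creates a new parasite in the recipient host (logged as
//                  an infect event plus a birth parented by the infector)

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>
#include <cmath>
#include <utility>
using namespace Rcpp;

namespace {

// ---- counter-based RNG (splitmix64 core) -------------------------------
inline uint64_t mix64(uint64_t z) {
  z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
  z ^= z >> 27; z *= 0x94D049BB133111EBULL;
  z ^= z >> 31;
  return z;
}

struct Stream {
  uint64_t s;
  double unif() { // in (0,1)
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = mix64(s);
    return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expo() { return -std::log(unif()); }
  void norm2(double &a, double &b) { // Box-Muller pair
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u)), th = 6.283185307179586 * v;
    a = r * std::cos(th); b = r * std::sin(th);
  }
};

// derive a fresh key from a parent key and two tags
inline uint64_t derive(uint64_t base, uint64_t tag1, uint64_t tag2) {
  return mix64(base ^ mix64(tag1 * 0xA24BAED4963EE407ULL +
                            tag2 * 0x9FB21C651E98DF25ULL + 1ULL));
}

const double INF = std::numeric_limits<double>::infinity();

inline double wrap01(double x) { return x - std::floor(x); }

inline double tor_d2(double x1, double y1, double x2, double y2) {
  double dx = std::fabs(x1 - x2); if (dx > 0.5) dx = 1.0 - dx;
  double dy = std::fabs(y1 - y2); if (dy > 0.5) dy = 1.0 - dy;
  return dx * dx + dy * dy;
}

struct Ind {
  int id, sp, guild, host, para, parent;
  double x, y, born, died;
  bool alive;
  uint64_t key;   // identity key (fixed at creation; seeds offspring keys)
  Stream st;      // event stream
  uint32_t nkids; // births so far (tags offspring keys)
  double Wmove, Wdeath, Wtrans; // residual Exp(1) work per clock
};

struct Part {
  int id, type;
  double x, y, created;
  bool alive;
  int cnt; // number of live consumers that could consume it right now
  Stream st;
  double Wexp, Wcons;
};

struct Log {
  std::vector<double> time, x, y;
  std::vector<int> kind, actor, object, species, parent, rtype;
  void push(double t, int k, int a, int o, double px, double py,
            int sp, int par, int rt) {
    time.push_back(t); kind.push_back(k); actor.push_back(a);
    object.push_back(o); x.push_back(px); y.push_back(py);
    species.push_back(sp); parent.push_back(par); rtype.push_back(rt);
  }
};

} // namespace

// [[Rcpp::export]]
List engine_run_cpp(List state, List rates, NumericMatrix comps,
                    double horizon, double seed, bool log_moves,
                    bool record_interactions, double max_events) {
  // --- unpack rate model ------------------------------------------------
  IntegerMatrix usage = rates["usage"];          // S_c x T
  NumericVector m = rates["m"], sigma = rates["sigma"], d = rates["d"],
                rc = rates["r_c"], b = rates["b"];
  double contact = as<double>(rates["contact"]);
  double muR = 1.0 / as<double>(rates["tau_R"]);
  IntegerMatrix host_range = rates["host_range"]; // S_p x S_c (0 rows if none)
  NumericVector pd = rates["par_d"], pbeta = rates["par_beta"],
                prt = rates["par_rt"], pdelta = rates["par_delta"];
  const int Sc = usage.nrow();
  const int Sp = host_range.nrow();
  const uint64_t base = mix64((uint64_t)(int64_t)seed + 0x5851F42D4C957F2DULL);

  // --- landscape components --------------------------------------------
  // columns: type(1-based), rate, cx, cy, radius, uniform(0/1)
  const int ncomp = comps.nrow();
  std::vector<Stream> comp_st(ncomp);
  std::vector<double> comp_W(ncomp);
  std::vector<uint32_t> comp_n(ncomp, 0);
  std::vector<uint64_t> comp_key(ncomp);
  for (int k = 0; k < ncomp; ++k) {
    comp_key[k] = derive(base, 3, (uint64_t)k);
    comp_st[k].s = comp_key[k];
    comp_W[k] = comp_st[k].expo();
  }

  // --- unpack state ------------------------------------------------------
  double t = as<double>(state["time"]);
  const double t_end = t + horizon;
  IntegerVector s_id = state["id"], s_sp = state["species"],
                s_guild = state["guild"], s_host = state["host_id"];
  NumericVector s_x = state["x"], s_y = state["y"], s_born = state["born_at"];
  int next_id = as<int>(state["next_id"]);
  IntegerVector p_id = state["pid"], p_type = state["prtype"];
  NumericVector p_x = state["px"], p_y = state["py"], p_cr = state["pcreated"];
  int next_pid = as<int>(state["next_pid"]);

  std::vector<Ind> inds;
  inds.reserve(s_id.size() * 4 + 64);
  for (int i = 0; i < s_id.size(); ++i) {
    Ind a; a.id = s_id[i]; a.sp = s_sp[i] - 1; a.guild = s_guild[i];
    a.host = -1; a.para = -1; a.parent = NA_INTEGER;
    a.x = s_x[i]; a.y = s_y[i]; a.born = s_born[i]; a.died = NA_REAL;
    a.alive = true;
    a.key = derive(base, 1, (uint64_t)a.id);
    a.st.s = a.key; a.nkids = 0;
    a.Wmove = a.st.expo(); a.Wdeath = a.st.expo(); a.Wtrans = a.st.expo();
    inds.push_back(a);
  }
  // resolve host ids -> indices
  for (int i = 0; i < (int)inds.size(); ++i) {
    if (inds[i].guild == 1) {
      int hid = s_host[i];
      int hidx = -1;
      for (int j = 0; j < (int)inds.size(); ++j)
        if (inds[j].id == hid && inds[j].guild == 0) { hidx = j; break; }
      if (hidx < 0) stop("parasite %d references unknown host id %d",
                         inds[i].id, hid);
      if (inds[hidx].para >= 0) stop("host id %d carries two parasites", hid);
      inds[i].host = hidx;
      inds[hidx].para = i;
      inds[i].x = inds[hidx].x; inds[i].y = inds[hidx].y;
    }
  }
  std::vector<Ind> archive; // dead, compacted out

  std::vector<Part> parts;
  parts.reserve(p_id.size() * 2 + 1024);
  for (int k = 0; k < p_id.size(); ++k) {
    Part p; p.id = p_id[k]; p.type = p_type[k] - 1;
    p.x = p_x[k]; p.y = p_y[k]; p.created = p_cr[k];
    p.alive = true; p.cnt = 0;
    p.st.s = derive(base, 2, (uint64_t)p.id);
    p.Wexp = p.st.expo(); p.Wcons = p.st.expo();
    parts.push_back(p);
  }

  auto eligible = [&](const Ind &a, const Part &p) -> bool {
    if (!a.alive || a.guild != 0) return false;
    if (!usage(a.sp, p.type)) return false;
    double r = rc[a.sp];
    return tor_d2(a.x, a.y, p.x, p.y) < r * r;
  };
  for (auto &p : parts) {
    if (!p.alive) continue;
    int c = 0;
    for (auto &a : inds) if (eligible(a, p)) ++c;
    p.cnt = c;
  }

  Log lg;
  std::set<std::pair<int,int> > pairs;
  auto add_pair = [&](int i, int j) {
    if (i == j) return;
    pairs.insert(std::make_pair(std::min(i, j), std::max(i, j)));
  };

  // spawn a consumer offspring next to its parent
  auto spawn_child = [&](Ind &par, double tt) {
    Ind ch; ch.id = next_id++; ch.sp = par.sp; ch.guild = 0;
    ch.host = -1; ch.para = -1; ch.parent = par.id;
    ch.key = derive(par.key, 4, (uint64_t)(++par.nkids));
    ch.st.s = ch.key; ch.nkids = 0;
    double n1, n2;
    ch.st.norm2(n1, n2);
    ch.x = wrap01(par.x + sigma[ch.sp] * n1);
    ch.y = wrap01(par.y + sigma[ch.sp] * n2);
    ch.born = tt; ch.died = NA_REAL; ch.alive = true;
    ch.Wmove = ch.st.expo(); ch.Wdeath = ch.st.expo();
    ch.Wtrans = ch.st.expo();
    double r2 = rc[ch.sp] * rc[ch.sp];
    for (auto &q : parts)
      if (q.alive && usage(ch.sp, q.type) &&
          tor_d2(ch.x, ch.y, q.x, q.y) < r2) ++q.cnt;
    lg.push(tt, 1, ch.id, NA_INTEGER, ch.x, ch.y, ch.sp + 1, par.id,
            NA_INTEGER);
    inds.push_back(ch);
  };

  std::vector<double> tcnt;      // per-parasite transmission counts
  bool trans_dirty = true;       // positions / infection states changed
  bool haveTrans = false;
  bool extinct = false;
  double n_events = 0;
  int nInd_dead = 0, nPart_dead = 0;

  auto compact_parts = [&]() {
    std::vector<Part> keep; keep.reserve(parts.size());
    for (auto &p : parts) if (p.alive) keep.push_back(p);
    parts.swap(keep); nPart_dead = 0;
  };
  auto compact_inds = [&]() {
    std::vector<int> remap(inds.size(), -1);
    std::vector<Ind> keep; keep.reserve(inds.size());
    for (int i = 0; i < (int)inds.size(); ++i) {
      if (inds[i].alive) { remap[i] = (int)keep.size(); keep.push_back(inds[i]); }
      else archive.push_back(inds[i]);
    }
    for (auto &a : keep) {
      if (a.host >= 0) a.host = remap[a.host];
      if (a.para >= 0) a.para = remap[a.para];
    }
    inds.swap(keep); nInd_dead = 0;
  };

  // event codes: 0 production, 1 expiry, 2 consume, 3 move, 4 death,
  //              5 transmit
  while (t < t_end) {
    if (n_events >= max_events)
      stop("event budget exceeded (%.0f events); rates likely diverging",
           max_events);
    if (nPart_dead > 512 && nPart_dead * 2 > (int)parts.size()) compact_parts();
    if (nInd_dead > 256 && nInd_dead * 2 > (int)inds.size()) compact_inds();

    int nAliveInd = 0;
    for (auto &a : inds) if (a.alive) ++nAliveInd;
    if (nAliveInd == 0) { extinct = true; break; }

    // transmission counts (per live parasite); particles do not affect
    // them, so production/expiry events leave the cache clean
    if (Sp > 0 && trans_dirty) {
      haveTrans = false;
      tcnt.assign(inds.size(), 0.0);
      for (int i = 0; i < (int)inds.size(); ++i) {
        Ind &q = inds[i];
        if (!q.alive || q.guild != 1) continue;
        double r = prt[q.sp]; int c = 0;
        for (auto &h : inds) {
          if (!h.alive || h.guild != 0 || h.para >= 0) continue;
          if (!host_range(q.sp, h.sp)) continue;
          if (tor_d2(q.x, q.y, h.x, h.y) < r * r) ++c;
        }
        tcnt[i] = (double)c;
        if (c > 0) haveTrans = true;
      }
      trans_dirty = false;
    }

    // ---- next firing over all clocks ----
    double best = INF;
    int ev = -1, who = -1;
    for (int k = 0; k < ncomp; ++k) {
      double dt = comp_W[k] / comps(k, 1);
      if (dt < best) { best = dt; ev = 0; who = k; }
    }
    for (int k = 0; k < (int)parts.size(); ++k) {
      Part &p = parts[k];
      if (!p.alive) continue;
      double dt = p.Wexp / muR;
      if (dt < best) { best = dt; ev = 1; who = k; }
      if (p.cnt > 0 && contact > 0) {
        dt = p.Wcons / (contact * p.cnt);
        if (dt < best) { best = dt; ev = 2; who = k; }
      }
    }
    for (int i = 0; i < (int)inds.size(); ++i) {
      Ind &a = inds[i];
      if (!a.alive) continue;
      if (a.guild == 0) {
        if (m[a.sp] > 0) {
          double dt = a.Wmove / m[a.sp];
          if (dt < best) { best = dt; ev = 3; who = i; }
        }
        double dr = d[a.sp] + (a.para >= 0 ? pdelta[inds[a.para].sp] : 0.0);
        if (dr > 0) {
          double dt = a.Wdeath / dr;
          if (dt < best) { best = dt; ev = 4; who = i; }
        }
      } else {
        if (pd[a.sp] > 0) {
          double dt = a.Wdeath / pd[a.sp];
          if (dt < best) { best = dt; ev = 4; who = i; }
        }
        if (haveTrans && tcnt[i] > 0 && pbeta[a.sp] > 0) {
          double dt = a.Wtrans / (pbeta[a.sp] * tcnt[i]);
          if (dt < best) { best = dt; ev = 5; who = i; }
        }
      }
    }

    if (!std::isfinite(best)) break; // frozen system: no clock can fire
    double step = best;
    if (t + step >= t_end) step = t_end - t;

    // advance all integrated hazards by `step`
    for (int k = 0; k < ncomp; ++k) comp_W[k] -= comps(k, 1) * step;
    for (auto &p : parts) {
      if (!p.alive) continue;
      p.Wexp -= muR * step;
      if (p.cnt > 0 && contact > 0) p.Wcons -= contact * p.cnt * step;
    }
    for (int i = 0; i < (int)inds.size(); ++i) {
      Ind &a = inds[i];
      if (!a.alive) continue;
      if (a.guild == 0) {
        if (m[a.sp] > 0) a.Wmove -= m[a.sp] * step;
        double dr = d[a.sp] + (a.para >= 0 ? pdelta[inds[a.para].sp] : 0.0);
        if (dr > 0) a.Wdeath -= dr * step;
      } else {
        if (pd[a.sp] > 0) a.Wdeath -= pd[a.sp] * step;
        if (haveTrans && tcnt[i] > 0 && pbeta[a.sp] > 0)
          a.Wtrans -= pbeta[a.sp] * tcnt[i] * step;
      }
    }
    t += step;
    if (t >= t_end) { t = t_end; break; }
    n_events += 1;

    // consumption, movement, death and transmission can change positions
    // or susceptibility; production and expiry cannot
    if (ev >= 2) trans_dirty = true;

    switch (ev) {
    case 0: { // ---- resource production ----
      Stream &cst = comp_st[who];
      Part p; p.id = next_pid++; p.type = (int)comps(who, 0) - 1;
      if (comps(who, 5) > 0.5) {
        p.x = cst.unif(); p.y = cst.unif();
      } else {
        double r = comps(who, 4) * std::sqrt(cst.unif());
        double th = 6.283185307179586 * cst.unif();
        p.x = wrap01(comps(who, 2) + r * std::cos(th));
        p.y = wrap01(comps(who, 3) + r * std::sin(th));
      }
      p.created = t; p.alive = true; p.cnt = 0;
      p.st.s = derive(comp_key[who], 5, (uint64_t)(++comp_n[who]));
      p.Wexp = p.st.expo(); p.Wcons = p.st.expo();
      for (auto &a : inds) if (eligible(a, p)) ++p.cnt;
      parts.push_back(p);
      comp_W[who] = comp_st[who].expo();
      break;
    }
    case 1: { // ---- particle expiry ----
      parts[who].alive = false; ++nPart_dead;
      break;
    }
    case 2: { // ---- consumption (+ possible birth) ----
      Part &p = parts[who];
      // consumer chosen uniformly among eligibles, in identity-key order
      // (stable across paired runs regardless of id numbering)
      std::vector<int> el;
      for (int i = 0; i < (int)inds.size(); ++i)
        if (eligible(inds[i], p)) el.push_back(i);
      if (el.empty()) { p.Wcons = p.st.expo(); break; }
      for (size_t a2 = 1; a2 < el.size(); ++a2) // insertion sort by key
        for (size_t b2 = a2; b2 > 0 &&
             inds[el[b2]].key < inds[el[b2 - 1]].key; --b2)
          std::swap(el[b2], el[b2 - 1]);
      int pick = (int)std::floor(p.st.unif() * el.size());
      if (pick >= (int)el.size()) pick = (int)el.size() - 1;
      Ind &a = inds[el[pick]];
      if (record_interactions)
        for (int j : el) if (inds[j].id != a.id) add_pair(a.id, inds[j].id);
      lg.push(t, 4, a.id, p.id, p.x, p.y, a.sp + 1, NA_INTEGER, p.type + 1);
      p.alive = false; ++nPart_dead;
      if (a.st.unif() < b[a.sp]) spawn_child(a, t);
      break;
    }
    case 3: { // ---- movement ----
      Ind &a = inds[who];
      double ox = a.x, oy = a.y, n1, n2;
      a.st.norm2(n1, n2);
      a.x = wrap01(a.x + sigma[a.sp] * n1);
      a.y = wrap01(a.y + sigma[a.sp] * n2);
      if (a.para >= 0) { inds[a.para].x = a.x; inds[a.para].y = a.y; }
      double r2 = rc[a.sp] * rc[a.sp];
      for (auto &p : parts) {
        if (!p.alive || !usage(a.sp, p.type)) continue;
        bool was = tor_d2(ox, oy, p.x, p.y) < r2;
        bool now = tor_d2(a.x, a.y, p.x, p.y) < r2;
        if (was != now) p.cnt += now ? 1 : -1;
      }
      if (log_moves)
        lg.push(t, 3, a.id, NA_INTEGER, a.x, a.y,
                a.sp + 1, NA_INTEGER, NA_INTEGER);
      a.Wmove = a.st.expo();
      break;
    }
    case 4: { // ---- death ----
      Ind &a = inds[who];
      a.alive = false; a.died = t; ++nInd_dead;
      if (a.guild == 0) {
        double r2 = rc[a.sp] * rc[a.sp];
        for (auto &p : parts)
          if (p.alive && usage(a.sp, p.type) &&
              tor_d2(a.x, a.y, p.x, p.y) < r2) --p.cnt;
        lg.push(t, 2, a.id, NA_INTEGER, a.x, a.y,
                a.sp + 1, NA_INTEGER, NA_INTEGER);
        if (a.para >= 0) { // host death kills its parasite
          Ind &q = inds[a.para];
          q.alive = false; q.died = t; ++nInd_dead;
          lg.push(t, 2, q.id, NA_INTEGER, q.x, q.y,
                  Sc + q.sp + 1, NA_INTEGER, NA_INTEGER);
          a.para = -1;
        }
      } else {
        if (a.host >= 0) inds[a.host].para = -1;
        lg.push(t, 2, a.id, NA_INTEGER, a.x, a.y,
                Sc + a.sp + 1, NA_INTEGER, NA_INTEGER);
      }
      break;
    }
    case 5: { // ---- parasite transmission ----
      Ind &q = inds[who];
      double r2 = prt[q.sp] * prt[q.sp];
      std::vector<int> cand;
      for (int i = 0; i < (int)inds.size(); ++i) {
        Ind &h = inds[i];
        if (!h.alive || h.guild != 0 || h.para >= 0) continue;
        if (!host_range(q.sp, h.sp)) continue;
        if (tor_d2(q.x, q.y, h.x, h.y) < r2) cand.push_back(i);
      }
      if (cand.empty()) { q.Wtrans = q.st.expo(); break; }
      for (size_t a2 = 1; a2 < cand.size(); ++a2)
        for (size_t b2 = a2; b2 > 0 &&
             inds[cand[b2]].key < inds[cand[b2 - 1]].key; --b2)
          std::swap(cand[b2], cand[b2 - 1]);
      int pick = (int)std::floor(q.st.unif() * cand.size());
      if (pick >= (int)cand.size()) pick = (int)cand.size() - 1;
      int hi = cand[pick];
      Ind &h = inds[hi];
      Ind np; np.id = next_id++; np.sp = q.sp; np.guild = 1;
      np.host = hi; np.para = -1; np.parent = q.id;
      np.key = derive(q.key, 4, (uint64_t)(++q.nkids));
      np.st.s = np.key; np.nkids = 0;
      np.x = h.x; np.y = h.y; np.born = t; np.died = NA_REAL;
      np.alive = true;
      np.Wmove = np.st.expo(); np.Wdeath = np.st.expo();
      np.Wtrans = np.st.expo();
      lg.push(t, 5, q.id, h.id, h.x, h.y,
              Sc + q.sp + 1, NA_INTEGER, NA_INTEGER);
      lg.push(t, 1, np.id, NA_INTEGER, np.x, np.y,
              Sc + np.sp + 1, q.id, NA_INTEGER);
      if (record_interactions) {
        add_pair(q.id, h.id);
        for (auto &o : inds) {
          if (!o.alive || o.guild != 1 || o.id == q.id) continue;
          if (!host_range(o.sp, h.sp)) continue;
          double ro = prt[o.sp];
          if (tor_d2(o.x, o.y, h.x, h.y) < ro * ro) add_pair(q.id, o.id);
        }
      }
      inds.push_back(np);
      inds[hi].para = (int)inds.size() - 1;
      q.Wtrans = inds[who].st.expo(); // q may be dangling after push_back
      break;
    }
    }
  }

  // ---- assemble outputs -------------------------------------------------
  compact_inds(); // moves all dead to archive; `inds` = alive
  int nOut = (int)inds.size() + (int)archive.size();
  IntegerVector o_id(nOut), o_sp(nOut), o_guild(nOut), o_host(nOut),
                o_parent(nOut);
  NumericVector o_x(nOut), o_y(nOut), o_born(nOut), o_died(nOut);
  int w = 0;
  auto emit = [&](const Ind &a) {
    o_id[w] = a.id;
    o_sp[w] = a.sp + 1;
    o_guild[w] = a.guild;
    o_host[w] = (a.guild == 1 && a.alive && a.host >= 0)
                  ? inds[a.host].id : NA_INTEGER;
    o_parent[w] = a.parent;
    o_x[w] = a.x; o_y[w] = a.y; o_born[w] = a.born; o_died[w] = a.died;
    ++w;
  };
  for (auto &a : inds) emit(a);
  for (auto &a : archive) emit(a);

  int nP = 0;
  for (auto &p : parts) if (p.alive) ++nP;
  IntegerVector q_id(nP), q_type(nP);
  NumericVector q_x(nP), q_y(nP), q_cr(nP);
  w = 0;
  for (auto &p : parts) {
    if (!p.alive) continue;
    q_id[w] = p.id; q_type[w] = p.type + 1;
    q_x[w] = p.x; q_y[w] = p.y; q_cr[w] = p.created; ++w;
  }

  int nPairs = (int)pairs.size();
  IntegerMatrix pm(nPairs, 2);
  w = 0;
  for (auto &pr : pairs) { pm(w, 0) = pr.first; pm(w, 1) = pr.second; ++w; }

  return List::create(
    _["time"] = t,
    _["log"] = List::create(
      _["time"] = wrap(lg.time), _["kind"] = wrap(lg.kind),
      _["actor"] = wrap(lg.actor), _["object"] = wrap(lg.object),
      _["x"] = wrap(lg.x), _["y"] = wrap(lg.y),
      _["species"] = wrap(lg.species), _["parent"] = wrap(lg.parent),
      _["rtype"] = wrap(lg.rtype)),
    _["individuals"] = List::create(
      _["id"] = o_id, _["species"] = o_sp, _["guild"] = o_guild,
      _["x"] = o_x, _["y"] = o_y, _["host_id"] = o_host,
      _["parent_id"] = o_parent, _["born_at"] = o_born,
      _["died_at"] = o_died),
    _["particles"] = List::create(
      _["pid"] = q_id, _["prtype"] = q_type, _["px"] = q_x, _["py"] = q_y,
      _["pcreated"] = q_cr),
    _["pairs"] = pm,
    _["next_id"] = next_id,
    _["next_pid"] = next_pid,
    _["extinct"] = extinct,
    _["n_events"] = n_events);
}
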