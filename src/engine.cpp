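#include "model.h"

using namespace Rcpp;

// Moore neighborhood, fixed draw order
static const int NBX[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
static const int NBY[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };

static inline double sq(double v) { return v * v; }

// Energy change of overwriting site (x, y) with label xval: the two affected
// cells' area-constraint terms plus the contact-energy bonds around the site
// (8-neighborhood, matching the copy neighborhood).
static double delta_H(const Model& m, int x, int y, int xval) {
  const Params& P = m.P;
  int old = m.sig(x, y);
  double dH = 0.0;
  if (old > 0) {
    double a = m.cells[old - 1].area;
    dH += P.lamV * (sq(a - 1 - P.VT) - sq(a - P.VT));
  }
  if (xval > 0) {
    double a = m.cells[xval - 1].area;
    dH += P.lamV * (sq(a + 1 - P.VT) - sq(a - P.VT));
  }
  for (int k = 0; k < 8; ++k) {
    int nx = x + NBX[k], ny = y + NBY[k];
    if (nx < 0 || nx >= m.W || ny < 0 || ny >= m.H) continue;
    int s = m.sig(nx, ny);
    dH += m.Jval(xval, s) - m.Jval(old, s);
  }
  return dH;
}

// Work bias W of the attempt: extension-only chemotaxis (only when a cell
// extends into a medium site; never at contact sites or during retraction),
// persistent-adhesion springs, and polarized motility. The spring and
// polarity terms are forces dotted with the attempt-induced centroid
// displacement of each affected cell.
static double work_bias(const Model& m, int tx, int ty, int sx, int sy,
                        int xval, bool retract) {
  const Params& P = m.P;
  int old = m.sig(tx, ty);
  double w = 0.0;
  if (!retract && old == 0 && xval > 0 && m.cells[xval - 1].type == 1) {
    size_t ft = m.fidx(tx, ty), fs = m.fidx(sx, sy);
    w += P.lam_A * (m.cA[ft] - m.cA[fs])
       + P.lam_S * (m.cS[ft] - m.cS[fs])
       + P.lam_I * (m.cI[ft] - m.cI[fs]);
  }
  int ids[2] = { old, xval };
  for (int q = 0; q < 2; ++q) {
    int id = ids[q];
    if (id == 0) continue;
    const Cell& c = m.cells[id - 1];
    // Attempt-induced cell displacement, at site scale: the centroid
    // displacement scaled by the post-copy area, i.e. the lever arm from the
    // centroid to the modified site. Site-scale displacement is required for
    // the printed motility/adhesion weights to act on the same scale as the
    // contact energies; the bare centroid displacement (~ lever/V) would
    // render them inert.
    double drx, dry;
    if (q == 0) {                       // cell losing the target site
      if (c.area <= 1) continue;
      drx = c.cx() - tx;
      dry = c.cy() - ty;
    } else {                            // cell gaining the target site
      drx = tx - c.cx();
      dry = ty - c.cy();
    }
    double dlen = std::sqrt(drx * drx + dry * dry);
    if (dlen < 1e-12) continue;
    drx /= dlen; dry /= dlen;
    const std::vector<int>& la = m.linkadj[id];
    for (size_t u = 0; u < la.size(); ++u) {
      const Cell& o = m.cells[la[u] - 1];
      double vx = o.cx() - c.cx(), vy = o.cy() - c.cy();
      double len = std::sqrt(vx * vx + vy * vy);
      if (len < 1e-12) continue;
      w += P.lamM[c.type][o.type] * (len - P.d0) * (vx * drx + vy * dry) / len;
    }
    double pl = std::sqrt(c.px * c.px + c.py * c.py);
    if (pl > 1e-12)
      w += P.lamP[c.type] * (drx * c.px + dry * c.py) / pl;
  }
  return w;
}

static void apply_copy(Model& m, int x, int y, int xval) {
  int old = m.sig(x, y);
  if (old > 0) {
    Cell& c = m.cells[old - 1];
    c.area -= 1; c.sx -= x; c.sy -= y;
  }
  if (xval > 0) {
    Cell& c = m.cells[xval - 1];
    c.area += 1; c.sx += x; c.sy += y;
  }
  m.sig(x, y) = xval;
}

struct Counters {
  int accepted, invalid, links_formed, links_broken;
  int cil_entries, cil_exits, emt_insertions;
  Counters() : accepted(0), invalid(0), links_formed(0), links_broken(0),
               cil_entries(0), cil_exits(0), emt_insertions(0) {}
};

// One elementary copy attempt. RNG draws, in order: target site; retraction
// flag; neighbor direction (unless retraction); acceptance (only if W - dH
// < 0). No-op attempts (identical label, out-of-lattice neighbor) and
// attempts that would annihilate a cell's last site consume no acceptance
// draw.
static void do_attempt(Model& m, Counters& cnt) {
  const Params& P = m.P;
  int N = m.W * m.H;
  int idx = (int)(unif_rand() * N);
  if (idx >= N) idx = N - 1;
  int x = idx / m.H, y = idx % m.H;
  int xval, sx = -1, sy = -1;
  bool retract = unif_rand() < P.p_retract;
  if (retract) {
    xval = 0;
  } else {
    int k = (int)(unif_rand() * 8);
    if (k > 7) k = 7;
    sx = x + NBX[k]; sy = y + NBY[k];
    if (sx < 0 || sx >= m.W || sy < 0 || sy >= m.H) { cnt.invalid++; return; }
    xval = m.sig(sx, sy);
  }
  int old = m.sig(x, y);
  if (xval == old) { cnt.invalid++; return; }
  if (old > 0 && m.cells[old - 1].area <= 1) { cnt.invalid++; return; }

  double arg = work_bias(m, x, y, sx, sy, xval, retract) - delta_H(m, x, y, xval);
  bool acc = (arg >= 0.0) || (unif_rand() < std::exp(arg));
  if (acc) {
    apply_copy(m, x, y, xval);
    cnt.accepted++;
  }
}

// Persistent-link bookkeeping: links to pairs that lost lattice contact are
// removed deterministically; surviving links break with probability
// max(0, min(1, (|r_ij| - d0)/divisor)); unlinked contacting pairs form a
// link with probability p_link. Pairs are visited in sorted id order.
static void update_links(Model& m, const ContactInfo& ci, Counters& cnt) {
  const Params& P = m.P;
  std::vector<std::pair<int, int> > rm, add;
  for (PairSet::const_iterator it = m.links.begin(); it != m.links.end(); ++it) {
    if (!ci.pairs.count(*it)) { rm.push_back(*it); continue; }
    const Cell& a = m.cells[it->first - 1];
    const Cell& b = m.cells[it->second - 1];
    double len = std::sqrt(sq(a.cx() - b.cx()) + sq(a.cy() - b.cy()));
    double pb = (len - P.d0) / P.break_div;
    if (pb > 0.0) {
      if (pb > 1.0) pb = 1.0;
      if (unif_rand() < pb) rm.push_back(*it);
    }
  }
  for (PairSet::const_iterator it = ci.pairs.begin(); it != ci.pairs.end(); ++it)
    if (!m.links.count(*it) && unif_rand() < P.p_link)
      add.push_back(*it);
  for (size_t i = 0; i < rm.size(); ++i) m.links.erase(rm[i]);
  for (size_t i = 0; i < add.size(); ++i) m.links.insert(add[i]);
  cnt.links_broken += rm.size();
  cnt.links_formed += add.size();
  m.rebuild_linkadj();
}

// CIL switching: every NEW contact between an NC and any cell (NC-NC or
// NC-placode; placode-placode pairs never trigger) gives each participant an
// independent chance to enter the CIL state with its type's probability.
// Cells leave the CIL state when no triggering contact remains.
static void update_cil(Model& m, const ContactInfo& ci, Counters& cnt) {
  const Params& P = m.P;
  for (PairSet::const_iterator it = ci.pairs.begin(); it != ci.pairs.end(); ++it) {
    Cell& a = m.cells[it->first - 1];
    Cell& b = m.cells[it->second - 1];
    if (a.type == 2 && b.type == 2) continue;
    if (m.prev_contacts.count(*it)) continue;   // only new contact events
    if (!a.cil && unif_rand() < P.pCIL[a.type]) { a.cil = true; cnt.cil_entries++; }
    if (!b.cil && unif_rand() < P.pCIL[b.type]) { b.cil = true; cnt.cil_entries++; }
  }
  for (size_t i = 0; i < m.cells.size(); ++i) {
    Cell& c = m.cells[i];
    if (!c.cil) continue;
    bool eligible = false;
    const std::vector<int>& pt = ci.partners[i + 1];
    for (size_t u = 0; u < pt.size(); ++u)
      if (c.type == 1 || m.cells[pt[u] - 1].type == 1) { eligible = true; break; }
    if (!eligible) { c.cil = false; cnt.cil_exits++; }
  }
}

// Polarity persistence: p <- (1 - deltaP) p + dr, with deltaP chosen by cell
// type and contact status; cells in CIL state are additionally repolarized
// away from the normalized sum of vectors to all contacting neighbors.
static void update_polarity(Model& m, const ContactInfo& ci,
                            const std::vector<double>& drx,
                            const std::vector<double>& dry) {
  const Params& P = m.P;
  for (size_t i = 0; i < drx.size(); ++i) {
    Cell& c = m.cells[i];
    bool contact = ci.any_contact[i + 1] != 0;
    double dP = contact ? P.dP_contact[c.type] : P.dP_free[c.type];
    c.px = (1.0 - dP) * c.px + drx[i];
    c.py = (1.0 - dP) * c.py + dry[i];
    if (c.cil) {
      // repolarize away from the contacts this cell has a CIL interaction
      // with: any contacting cell for NC, contacting NC only for placodes
      // (placode-placode contacts carry no CIL)
      double vx = 0.0, vy = 0.0;
      const std::vector<int>& pt = ci.partners[i + 1];
      for (size_t u = 0; u < pt.size(); ++u) {
        const Cell& o = m.cells[pt[u] - 1];
        if (c.type == 2 && o.type != 1) continue;
        vx += o.cx() - c.cx(); vy += o.cy() - c.cy();
      }
      double len = std::sqrt(vx * vx + vy * vy);
      if (len > 1e-12) {
        c.px -= P.lam_CIL * vx / len;
        c.py -= P.lam_CIL * vy / len;
      }
    }
  }
}

// Dorsal EMT: scan the top strip left to right for fully cell-free 5 x 3
// windows anchored at the dorsal edge; each found window seeds one new NC
// cell (fresh id, zero polarity, no links) and the scan resumes past it.
static void emt_insert(Model& m, Counters& cnt) {
  const Params& P = m.P;
  if (!P.emt_enabled || m.W < P.emt_w || m.H < P.emt_h) return;
  int x = 0;
  while (x + P.emt_w <= m.W) {
    bool free = true;
    for (int i = 0; free && i < P.emt_w; ++i)
      for (int j = 0; j < P.emt_h; ++j)
        if (m.sig(x + i, j) != 0) { free = false; break; }
    if (!free) { x += 1; continue; }
    Cell c;
    c.type = 1; c.area = P.emt_w * P.emt_h;
    c.sx = 0.0; c.sy = 0.0; c.px = 0.0; c.py = 0.0; c.cil = false;
    int id = (int)m.cells.size() + 1;
    for (int i = 0; i < P.emt_w; ++i)
      for (int j = 0; j < P.emt_h; ++j) {
        m.sig(x + i, j) = id;
        c.sx += x + i; c.sy += j;
      }
    m.cells.push_back(c);
    m.linkadj.resize(m.cells.size() + 1);
    cnt.emt_insertions++;
    x += P.emt_w;
  }
}

// Fixed update order within one MCS: N copy attempts, then links, CIL state,
// polarity, fields, EMT insertion, clock.
static void run_one_mcs(Model& m, Counters& cnt,
                        double& speed_nc, double& speed_pl) {
  int N = m.W * m.H;
  size_t nc0 = m.cells.size();
  std::vector<double> sx0(nc0), sy0(nc0);
  for (size_t i = 0; i < nc0; ++i) {
    sx0[i] = m.cells[i].cx(); sy0[i] = m.cells[i].cy();
  }
  for (int a = 0; a < N; ++a) do_attempt(m, cnt);

  ContactInfo ci;
  compute_contacts(m, ci);
  update_links(m, ci, cnt);
  update_cil(m, ci, cnt);

  std::vector<double> drx(nc0), dry(nc0);
  double sp1 = 0.0, sp2 = 0.0; int n1 = 0, n2 = 0;
  for (size_t i = 0; i < nc0; ++i) {
    drx[i] = m.cells[i].cx() - sx0[i];
    dry[i] = m.cells[i].cy() - sy0[i];
    double mag = std::sqrt(drx[i] * drx[i] + dry[i] * dry[i]);
    if (m.cells[i].type == 1) { sp1 += mag; n1++; } else { sp2 += mag; n2++; }
  }
  speed_nc = n1 ? sp1 / n1 : NA_REAL;
  speed_pl = n2 ? sp2 / n2 : NA_REAL;
  update_polarity(m, ci, drx, dry);
  step_fields_once(m);
  emt_insert(m, cnt);
  m.prev_contacts.swap(ci.pairs);
  m.mcs += 1;
}

// [[Rcpp::export]]
List cpp_run(List state, List params, int n_mcs) {
  Model m = parse_state(state, params);
  NumericMatrix met(n_mcs, 15);
  colnames(met) = CharacterVector::create(
    "mcs", "accepted", "invalid", "speed_nc", "speed_pl",
    "mean_cA", "mean_cS", "mean_cI",
    "links_formed", "links_broken", "cil_entries", "cil_exits",
    "emt_insertions", "n_cells", "n_links");
  size_t ncore = (size_t)m.W * m.H;
  for (int s = 0; s < n_mcs; ++s) {
    Counters cnt;
    double sp_nc, sp_pl;
    run_one_mcs(m, cnt, sp_nc, sp_pl);
    double mA = 0.0, mS = 0.0, mI = 0.0;
    for (int x = 0; x < m.W; ++x)
      for (int y = 0; y < m.H; ++y) {
        size_t f = m.fidx(x, y);
        mA += m.cA[f]; mS += m.cS[f]; mI += m.cI[f];
      }
    met(s, 0) = m.mcs; met(s, 1) = cnt.accepted; met(s, 2) = cnt.invalid;
    met(s, 3) = sp_nc; met(s, 4) = sp_pl;
    met(s, 5) = mA / ncore; met(s, 6) = mS / ncore; met(s, 7) = mI / ncore;
    met(s, 8) = cnt.links_formed; met(s, 9) = cnt.links_broken;
    met(s, 10) = cnt.cil_entries; met(s, 11) = cnt.cil_exits;
    met(s, 12) = cnt.emt_insertions;
    met(s, 13) = m.cells.size(); met(s, 14) = m.links.size();
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["state"] = state_to_r(m), _["metrics"] = met);
}

// --- fine-grained operations exposed for direct use and testing ---

// Evaluate (and optionally repeat the acceptance draw of) a fully specified
// copy attempt without modifying the state. Coordinates are 1-based; sx = 0
// denotes a retraction attempt.
// [[Rcpp::export]]
List cpp_eval_attempt(List state, List params, int tx, int ty, int sx, int sy,
                      int nrep) {
  Model m = parse_state(state, params);
  int x = tx - 1, y = ty - 1;
  if (x < 0 || x >= m.W || y < 0 || y >= m.H) stop("target site outside lattice");
  bool retract = (sx == 0);
  int xval = 0, sx0 = -1, sy0 = -1;
  if (!retract) {
    sx0 = sx - 1; sy0 = sy - 1;
    if (sx0 < 0 || sx0 >= m.W || sy0 < 0 || sy0 >= m.H)
      stop("source site outside lattice");
    if (std::abs(sx0 - x) > 1 || std::abs(sy0 - y) > 1 || (sx0 == x && sy0 == y))
      stop("source site is not a lattice neighbor of the target");
    xval = m.sig(sx0, sy0);
  }
  int old = m.sig(x, y);
  double dH, w, p;
  if (xval == old) {
    dH = 0.0; w = 0.0; p = 1.0;
  } else if (old > 0 && m.cells[old - 1].area <= 1) {
    dH = NA_REAL; w = NA_REAL; p = 0.0;    // last-site attempts auto-rejected
  } else {
    dH = delta_H(m, x, y, xval);
    w = work_bias(m, x, y, sx0, sy0, xval, retract);
    double arg = w - dH;
    p = arg >= 0.0 ? 1.0 : std::exp(arg);
  }
  int acc = 0;
  for (int r = 0; r < nrep; ++r)
    if (p >= 1.0 || unif_rand() < p) acc++;
  return List::create(_["dH"] = dH, _["W"] = w, _["p"] = p,
                      _["accepted"] = acc, _["xval"] = xval);
}

// One random elementary copy attempt, exactly as inside the MCS loop,
// applied to the state when accepted.
// [[Rcpp::export]]
List cpp_attempt_copy(List state, List params) {
  Model m = parse_state(state, params);
  Counters cnt;
  int before = m.mcs;   // unchanged; attempts do not advance the clock
  do_attempt(m, cnt);
  (void)before;
  return List::create(_["state"] = state_to_r(m),
                      _["accepted"] = cnt.accepted,
                      _["invalid"] = cnt.invalid);
}

// [[Rcpp::export]]
List cpp_update_links(List state, List params) {
  Model m = parse_state(state, params);
  ContactInfo ci; compute_contacts(m, ci);
  Counters cnt;
  update_links(m, ci, cnt);
  return List::create(_["state"] = state_to_r(m),
                      _["formed"] = cnt.links_formed,
                      _["broken"] = cnt.links_broken);
}

// [[Rcpp::export]]
List cpp_update_cil(List state, List params) {
  Model m = parse_state(state, params);
  ContactInfo ci; compute_contacts(m, ci);
  Counters cnt;
  update_cil(m, ci, cnt);
  m.prev_contacts.swap(ci.pairs);
  return List::create(_["state"] = state_to_r(m),
                      _["entries"] = cnt.cil_entries,
                      _["exits"] = cnt.cil_exits);
}

// [[Rcpp::export]]
List cpp_update_polarity(List state, List params, NumericMatrix displacement) {
  Model m = parse_state(state, params);
  if ((size_t)displacement.nrow() != m.cells.size() || displacement.ncol() != 2)
    stop("displacement must be an n_cells x 2 matrix");
  ContactInfo ci; compute_contacts(m, ci);
  std::vector<double> drx(m.cells.size()), dry(m.cells.size());
  for (size_t i = 0; i < m.cells.size(); ++i) {
    drx[i] = displacement(i, 0); dry[i] = displacement(i, 1);
  }
  update_polarity(m, ci, drx, dry);
  return state_to_r(m);
}

// [[Rcpp::export]]
List cpp_emt_insert(List state, List params) {
  Model m = parse_state(state, params);
  Counters cnt;
  emt_insert(m, cnt);
  return List::create(_["state"] = state_to_r(m),
                      _["insertions"] = cnt.emt_insertions);
}

// [[Rcpp::export]]
IntegerMatrix cpp_contacts(List state, List params) {
  Model m = parse_state(state, params);
  ContactInfo ci; compute_contacts(m, ci);
  IntegerMatrix out(ci.pairs.size(), 2);
  int r = 0;
  for (PairSet::const_iterator it = ci.pairs.begin(); it != ci.pairs.end(); ++it, ++r) {
    out(r, 0) = it->first; out(r, 1) = it->second;
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}
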