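#include "model.h"

using namespace Rcpp;

static double num(const List& l, const char* nm) {
  return as<double>(l[nm]);
}

Params parse_params(const List& pl) {
  Params P;
  P.S_A = num(pl, "S_A"); P.S_S = num(pl, "S_S"); P.S_I = num(pl, "S_I");
  P.D_A = num(pl, "D_A"); P.D_S = num(pl, "D_S"); P.D_I = num(pl, "D_I");
  P.dA = num(pl, "delta_A"); P.dS = num(pl, "delta_S"); P.dI = num(pl, "delta_I");
  P.lam_A = num(pl, "lambda_A"); P.lam_S = num(pl, "lambda_S_eff");
  P.lam_I = num(pl, "lambda_I");
  P.lamP[0] = 0.0; P.lamP[1] = num(pl, "lambda_P_NC"); P.lamP[2] = num(pl, "lambda_P_PL");
  P.dP_free[0] = 0.0; P.dP_contact[0] = 0.0;
  P.dP_free[1] = num(pl, "deltaP_NC_free"); P.dP_contact[1] = num(pl, "deltaP_NC_contact");
  P.dP_free[2] = num(pl, "deltaP_PL_free"); P.dP_contact[2] = num(pl, "deltaP_PL_contact");
  P.lam_CIL = num(pl, "lambda_CIL");
  P.pCIL[0] = 0.0; P.pCIL[1] = num(pl, "p_CIL_NC"); P.pCIL[2] = num(pl, "p_CIL_PL");
  NumericMatrix lm = pl["lambda_M"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) P.lamM[i][j] = 0.0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j) P.lamM[i + 1][j + 1] = lm(i, j);
  P.lamV = num(pl, "lambda_V"); P.VT = num(pl, "V_T");
  P.d0 = 2.0 * std::sqrt(P.VT / M_PI);
  NumericMatrix J = pl["J"];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) P.J[i][j] = J(i, j);
  P.U_S = num(pl, "U_S");
  P.W = as<int>(pl["lattice_width"]); P.H = as<int>(pl["lattice_height"]);
  P.halo = as<int>(pl["halo"]);
  P.substeps = as<int>(pl["field_substeps_per_MCS"]);
  P.p_retract = num(pl, "p_medium_retraction");
  P.p_link = num(pl, "p_link_form");
  P.break_div = num(pl, "link_break_divisor");
  P.emt_enabled = as<bool>(pl["emt_enabled"]);
  P.emt_w = 5; P.emt_h = 3;
  return P;
}

Model parse_state(const List& st, const List& pl) {
  Model m;
  m.P = parse_params(pl);
  m.W = m.P.W; m.H = m.P.H;
  m.WE = m.W + 2 * m.P.halo; m.HE = m.H + 2 * m.P.halo;

  IntegerMatrix sig = st["sigma"];
  if (sig.nrow() != m.H || sig.ncol() != m.W)
    stop("sigma dimensions (%d x %d) do not match params lattice (%d x %d)",
         sig.nrow(), sig.ncol(), m.H, m.W);
  m.sigma.assign(sig.begin(), sig.end());

  List fl = st["fields"];
  NumericMatrix fA = fl["A"], fS = fl["S"], fI = fl["I"];
  if (fA.nrow() != m.HE || fA.ncol() != m.WE)
    stop("field dimensions do not match lattice + halo");
  m.cA.assign(fA.begin(), fA.end());
  m.cS.assign(fS.begin(), fS.end());
  m.cI.assign(fI.begin(), fI.end());
  m.buf.assign(m.cA.size(), 0.0);

  DataFrame cd = as<DataFrame>(st["cells"]);
  IntegerVector type = cd["type"], area = cd["area"];
  NumericVector cx = cd["cx"], cy = cd["cy"], px = cd["px"], py = cd["py"];
  LogicalVector cil = cd["cil"];
  int n = type.size();
  m.cells.resize(n);
  for (int i = 0; i < n; ++i) {
    Cell& c = m.cells[i];
    c.type = type[i]; c.area = area[i];
    // centroids are stored 1-based on the R side
    c.sx = (cx[i] - 1.0) * area[i]; c.sy = (cy[i] - 1.0) * area[i];
    c.px = px[i]; c.py = py[i]; c.cil = cil[i];
  }
  // recompute exact coordinate sums from the lattice (centroid round-trip
  // through averages would accumulate error)
  std::vector<double> sx(n, 0.0), sy(n, 0.0);
  std::vector<int> ar(n, 0);
  for (int x = 0; x < m.W; ++x)
    for (int y = 0; y < m.H; ++y) {
      int s = m.sig(x, y);
      if (s > 0) {
        if (s > n) stop("sigma contains label %d with no registry entry", s);
        sx[s - 1] += x; sy[s - 1] += y; ar[s - 1] += 1;
      }
    }
  for (int i = 0; i < n; ++i) {
    if (ar[i] != m.cells[i].area)
      stop("registry area of cell %d (%d) does not match lattice (%d)",
           i + 1, m.cells[i].area, ar[i]);
    m.cells[i].sx = sx[i]; m.cells[i].sy = sy[i];
  }

  IntegerMatrix lk = st["links"];
  for (int r = 0; r < lk.nrow(); ++r) {
    int a = lk(r, 0), b = lk(r, 1);
    if (a > b) std::swap(a, b);
    m.links.insert(std::make_pair(a, b));
  }
  m.rebuild_linkadj();

  IntegerMatrix ct = st["contacts"];
  for (int r = 0; r < ct.nrow(); ++r) {
    int a = ct(r, 0), b = ct(r, 1);
    if (a > b) std::swap(a, b);
    m.prev_contacts.insert(std::make_pair(a, b));
  }
  m.mcs = as<int>(st["mcs"]);
  return m;
}

static IntegerMatrix pairs_to_matrix(const PairSet& s) {
  IntegerMatrix out(s.size(), 2);
  int r = 0;
  for (PairSet::const_iterator it = s.begin(); it != s.end(); ++it, ++r) {
    out(r, 0) = it->first; out(r, 1) = it->second;
  }
  colnames(out) = CharacterVector::create("i", "j");
  return out;
}

List state_to_r(const Model& m) {
  IntegerMatrix sig(m.H, m.W);
  std::copy(m.sigma.begin(), m.sigma.end(), sig.begin());
  NumericMatrix fA(m.HE, m.WE), fS(m.HE, m.WE), fI(m.HE, m.WE);
  std::copy(m.cA.begin(), m.cA.end(), fA.begin());
  std::copy(m.cS.begin(), m.cS.end(), fS.begin());
  std::copy(m.cI.begin(), m.cI.end(), fI.begin());

  int n = m.cells.size();
  IntegerVector id(n), type(n), area(n);
  NumericVector cx(n), cy(n), px(n), py(n);
  LogicalVector cil(n);
  for (int i = 0; i < n; ++i) {
    const Cell& c = m.cells[i];
    id[i] = i + 1; type[i] = c.type; area[i] = c.area;
    cx[i] = c.cx() + 1.0; cy[i] = c.cy() + 1.0;
    px[i] = c.px; py[i] = c.py; cil[i] = c.cil;
  }
  DataFrame cd = DataFrame::create(
    _["id"] = id, _["type"] = type, _["area"] = area,
    _["cx"] = cx, _["cy"] = cy, _["px"] = px, _["py"] = py, _["cil"] = cil);

  List st = List::create(
    _["sigma"] = sig,
    _["cells"] = cd,
    _["fields"] = List::create(_["A"] = fA, _["S"] = fS, _["I"] = fI),
    _["links"] = pairs_to_matrix(m.links),
    _["contacts"] = pairs_to_matrix(m.prev_contacts),
    _["mcs"] = m.mcs);
  st.attr("class") = "nc_state";
  return st;
}

// Lattice contacts between distinct cells over the 8-neighborhood. Each
// unordered pair is recorded once; scanning only the E, SE, S, SW offsets
// of every site covers all neighbor pairs exactly once.
void compute_contacts(const Model& m, ContactInfo& ci) {
  static const int dx[4] = { 1, 1, 0, -1 };
  static const int dy[4] = { 0, 1, 1, 1 };
  ci.pairs.clear();
  ci.partners.assign(m.cells.size() + 1, std::vector<int>());
  ci.any_contact.assign(m.cells.size() + 1, 0);
  for (int x = 0; x < m.W; ++x)
    for (int y = 0; y < m.H; ++y) {
      int a = m.sig(x, y);
      if (a == 0) continue;
      for (int k = 0; k < 4; ++k) {
        int nx = x + dx[k], ny = y + dy[k];
        if (nx < 0 || nx >= m.W || ny < 0 || ny >= m.H) continue;
        int b = m.sig(nx, ny);
        if (b == 0 || b == a) continue;
        int lo = a < b ? a : b, hi = a < b ? b : a;
        if (ci.pairs.insert(std::make_pair(lo, hi)).second) {
          ci.partners[lo].push_back(hi);
          ci.partners[hi].push_back(lo);
          ci.any_contact[lo] = 1;
          ci.any_contact[hi] = 1;
        }
      }
    }
}
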