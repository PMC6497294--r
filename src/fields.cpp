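#include "model.h"

using namespace Rcpp;

// One explicit forward-Euler substep of dc/dt = D lap(c) - delta c on the
// halo-extended grid, 5-point Laplacian, zero-flux (reflecting) outer
// boundary. Returns false if a non-finite value appeared.
static bool sweep(std::vector<double>& f, std::vector<double>& buf,
                  int WE, int HE, double D, double del, double dt) {
  double acc = 0.0;
  const double Ddt = D * dt, keep = 1.0 - del * dt;
  for (int x = 0; x < WE; ++x) {
    const double* col = &f[(size_t)x * HE];
    const double* lft = (x > 0) ? col - HE : col;
    const double* rgt = (x < WE - 1) ? col + HE : col;
    double* out = &buf[(size_t)x * HE];
    // y = 0 and y = HE-1 handled with reflected vertical neighbors
    {
      double c = col[0];
      double dn = (HE > 1) ? col[1] : c;
      double nf = c * keep + Ddt * (lft[0] + rgt[0] + c + dn - 4.0 * c);
      out[0] = nf; acc += nf;
    }
    for (int y = 1; y < HE - 1; ++y) {
      double c = col[y];
      double nf = c * keep +
        Ddt * (lft[y] + rgt[y] + col[y - 1] + col[y + 1] - 4.0 * c);
      out[y] = nf; acc += nf;
    }
    if (HE > 1) {
      int y = HE - 1;
      double c = col[y];
      double nf = c * keep + Ddt * (lft[y] + rgt[y] + col[y - 1] + c - 4.0 * c);
      out[y] = nf; acc += nf;
    }
  }
  f.swap(buf);
  return std::isfinite(acc);
}

// Net per-site sources at the current cell configuration, as (index, rate)
// lists over the extended grid. NC sites secrete A and take up S (clamped at
// the available concentration when applied); placode sites secrete S and I.
struct Sources {
  std::vector<size_t> idx;
  std::vector<double> sA, sS, sI;
};

static void collect_sources(const Model& m, Sources& src) {
  src.idx.clear(); src.sA.clear(); src.sS.clear(); src.sI.clear();
  for (int x = 0; x < m.W; ++x)
    for (int y = 0; y < m.H; ++y) {
      int s = m.sig(x, y);
      if (s == 0) continue;
      int t = m.cells[s - 1].type;
      src.idx.push_back(m.fidx(x, y));
      if (t == 1) {                       // NC: secrete A, take up S
        src.sA.push_back(m.P.S_A); src.sS.push_back(-m.P.U_S); src.sI.push_back(0.0);
      } else {                            // placode: secrete S and I
        src.sA.push_back(0.0); src.sS.push_back(m.P.S_S); src.sI.push_back(m.P.S_I);
      }
    }
}

static void apply_sources(std::vector<double>& f, const std::vector<size_t>& idx,
                          const std::vector<double>& rate, double dt) {
  for (size_t k = 0; k < idx.size(); ++k) {
    double nf = f[idx[k]] + dt * rate[k];
    f[idx[k]] = (nf < 0.0) ? 0.0 : nf;    // uptake clamped at availability
  }
}

// Advance all three fields by one MCS of model time. Sources are evaluated
// from the current lattice and held fixed across the substeps of the MCS.
void step_fields_once(Model& m) {
  const int n = m.P.substeps;
  const double dt = 1.0 / n;
  Sources src;
  collect_sources(m, src);
  for (int k = 0; k < n; ++k) {
    if (!sweep(m.cA, m.buf, m.WE, m.HE, m.P.D_A, m.P.dA, dt))
      stop("numerical failure in field A at MCS %d substep %d", m.mcs + 1, k + 1);
    apply_sources(m.cA, src.idx, src.sA, dt);
    if (!sweep(m.cS, m.buf, m.WE, m.HE, m.P.D_S, m.P.dS, dt))
      stop("numerical failure in field S at MCS %d substep %d", m.mcs + 1, k + 1);
    apply_sources(m.cS, src.idx, src.sS, dt);
    if (!sweep(m.cI, m.buf, m.WE, m.HE, m.P.D_I, m.P.dI, dt))
      stop("numerical failure in field I at MCS %d substep %d", m.mcs + 1, k + 1);
    apply_sources(m.cI, src.idx, src.sI, dt);
  }
}

// [[Rcpp::export]]
List cpp_step_fields(List state, List params, int n_mcs) {
  Model m = parse_state(state, params);
  for (int i = 0; i < n_mcs; ++i) {
    step_fields_once(m);
    if ((i & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return state_to_r(m);
}

// [[Rcpp::export]]
NumericMatrix cpp_source_map(List state, List params, std::string substance) {
  Model m = parse_state(state, params);
  NumericMatrix out(m.H, m.W);
  int which = (substance == "A") ? 0 : (substance == "S") ? 1 : 2;
  for (int x = 0; x < m.W; ++x)
    for (int y = 0; y < m.H; ++y) {
      int s = m.sig(x, y);
      if (s == 0) continue;
      int t = m.cells[s - 1].type;
      double v = 0.0;
      if (which == 0) v = (t == 1) ? m.P.S_A : 0.0;
      else if (which == 1) v = (t == 1) ? -m.P.U_S : m.P.S_S;
      else v = (t == 2) ? m.P.S_I : 0.0;
      out(y, x) = v;
    }
  return out;
}
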