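#ifndef NCSTREAMS_MODEL_H
#define NCSTREAMS_MODEL_H

#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>

// Cell types: 0 = medium, 1 = NC, 2 = placode.
// Lattice layout mirrors the R matrix: sigma is lattice_height x lattice_width,
// column-major, so site (x, y) (0-based; x = AP axis / column, y = DV axis /
// row, y increasing ventrally) lives at index x*H + y.

struct Params {
  double S_A, S_S, S_I;
  double D_A, D_S, D_I;
  double dA, dS, dI;
  double lam_A, lam_S, lam_I;       // NC chemotaxis weights; placodes have none
  double lamP[3];                    // index by type, [0] unused
  double dP_free[3], dP_contact[3];
  double lam_CIL, pCIL[3];
  double lamM[3][3];                 // persistent adhesion by type pair
  double lamV, VT, d0;
  double J[3][3];                    // contact energies by type pair, J[0][0]=0
  double U_S;
  int W, H, halo;
  int substeps;
  double p_retract, p_link, break_div;
  bool emt_enabled;
  int emt_w, emt_h;                  // dorsal insertion patch, 5 x 3
};

struct Cell {
  int type;                          // 1 = NC, 2 = placode
  int area;
  double sx, sy;                     // sums of occupied-site coordinates
  double px, py;                     // polarity vector
  bool cil;
  double cx() const { return sx / area; }
  double cy() const { return sy / area; }
};

typedef std::set<std::pair<int, int> > PairSet;   // ordered: deterministic

struct Model {
  Params P;
  int W, H, WE, HE;                  // core and halo-extended dimensions
  std::vector<int> sigma;            // W*H
  std::vector<double> cA, cS, cI;    // WE*HE
  std::vector<double> buf;           // scratch for field sweeps
  std::vector<Cell> cells;           // index = id - 1
  PairSet links;
  std::vector<std::vector<int> > linkadj;   // per-cell linked partner ids
  PairSet prev_contacts;
  int mcs;

  int sig(int x, int y) const { return sigma[(size_t)x * H + y]; }
  int& sig(int x, int y) { return sigma[(size_t)x * H + y]; }
  size_t fidx(int x, int y) const {               // core coords into field grid
    return (size_t)(x + P.halo) * HE + (y + P.halo);
  }
  int type_of(int label) const { return label == 0 ? 0 : cells[label - 1].type; }
  double Jval(int a, int b) const {               // labels, not types
    if (a == b) return 0.0;
    return P.J[type_of(a)][type_of(b)];
  }
  void rebuild_linkadj() {
    linkadj.assign(cells.size() + 1, std::vector<int>());
    for (PairSet::const_iterator it = links.begin(); it != links.end(); ++it) {
      linkadj[it->first].push_back(it->second);
      linkadj[it->second].push_back(it->first);
    }
  }
};

Params parse_params(const Rcpp::List& pl);
Model parse_state(const Rcpp::List& st, const Rcpp::List& pl);
Rcpp::List state_to_r(const Model& m);

// engine internals shared across translation units
struct ContactInfo {
  PairSet pairs;
  std::vector<std::vector<int> > partners;  // per cell id (1-based index)
  std::vector<char> any_contact;            // per cell id
};
void compute_contacts(const Model& m, ContactInfo& ci);
void step_fields_once(Model& m);

#endif
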