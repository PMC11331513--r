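#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Minimum-image displacement component for an orthorhombic box.
// nearbyint (round-half-to-even under the default FP mode) matches R's
// round(), so the pure-R brute-force oracle computes bitwise-identical
// distances.
static inline double min_image(double d, double box) {
  return d - box * std::nearbyint(d / box);
}

static inline double dist2_mi(const double* a, const double* b,
                              const double* box) {
  double dx = min_image(a[0] - b[0], box[0]);
  double dy = min_image(a[1] - b[1], box[1]);
  double dz = min_image(a[2] - b[2], box[2]);
  double s = dx * dx;
  s += dy * dy;
  s += dz * dz;
  return s;
}

struct CellGrid {
  int nc[3];
  double cs[3];
  double box[3];
  std::vector<int> head;   // cell -> first atom (0-based), -1 if empty
  std::vector<int> nxt;    // atom -> next atom in same cell

  CellGrid(const NumericMatrix& xyz, const double* b, double cutoff) {
    int n = xyz.nrow();
    for (int k = 0; k < 3; ++k) {
      box[k] = b[k];
      nc[k] = std::max(1, (int)std::floor(b[k] / cutoff));
      cs[k] = b[k] / nc[k];
    }
    head.assign((size_t)nc[0] * nc[1] * nc[2], -1);
    nxt.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int c = cell_of(xyz(i, 0), xyz(i, 1), xyz(i, 2));
      nxt[i] = head[c];
      head[c] = i;
    }
  }

  inline int idx1(double x, double box, double cs, int nc) const {
    double w = x - box * std::floor(x / box);  // wrap into [0, box)
    int i = (int)std::floor(w / cs);
    if (i >= nc) i = nc - 1;
    if (i < 0) i = 0;
    return i;
  }

  inline int cell_of(double x, double y, double z) const {
    int ix = idx1(x, box[0], cs[0], nc[0]);
    int iy = idx1(y, box[1], cs[1], nc[1]);
    int iz = idx1(z, box[2], cs[2], nc[2]);
    return (iz * nc[1] + iy) * nc[0] + ix;
  }
};

// Per-solvent-molecule minimum distance to the solute under PBC.
//
// solute:  ns x 3 coordinates (Angstrom)
// solvent: m x 3 coordinates
// solv_mol: length-m molecule id per solvent atom, 1-based in 1..n_mol
// box: 3 orthorhombic side lengths
// cutoff: censoring distance; molecules with no solute atom within cutoff
//         get NA results.
//
// Ties in distance are broken to the lower solute atom index, then the
// lower solvent atom index.
// [[Rcpp::export]]
List cpp_min_distances(NumericMatrix solute, NumericMatrix solvent,
                       IntegerVector solv_mol, int n_mol,
                       NumericVector box, double cutoff) {
  const double b[3] = {box[0], box[1], box[2]};
  const int m = solvent.nrow();
  CellGrid grid(solute, b, cutoff);
  const double cut2 = cutoff * cutoff;

  NumericVector rmin(n_mol, NA_REAL);
  IntegerVector isol(n_mol, NA_INTEGER), jsolv(n_mol, NA_INTEGER);
  std::vector<double> best2(n_mol, R_PosInf);

  for (int j = 0; j < m; ++j) {
    const double p[3] = {solvent(j, 0), solvent(j, 1), solvent(j, 2)};
    int mol = solv_mol[j] - 1;
    int cx = grid.idx1(p[0], b[0], grid.cs[0], grid.nc[0]);
    int cy = grid.idx1(p[1], b[1], grid.cs[1], grid.nc[1]);
    int cz = grid.idx1(p[2], b[2], grid.cs[2], grid.nc[2]);
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = (cz + dz + grid.nc[2]) % grid.nc[2];
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = (cy + dy + grid.nc[1]) % grid.nc[1];
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = (cx + dx + grid.nc[0]) % grid.nc[0];
          int c = (iz * grid.nc[1] + iy) * grid.nc[0] + ix;
          for (int i = grid.head[c]; i != -1; i = grid.nxt[i]) {
            const double q[3] = {solute(i, 0), solute(i, 1), solute(i, 2)};
            double d2 = dist2_mi(p, q, b);
            if (d2 > cut2) continue;
            if (d2 < best2[mol] ||
                (d2 == best2[mol] &&
                 (i + 1 < isol[mol] ||
                  (i + 1 == isol[mol] && j + 1 < jsolv[mol])))) {
              best2[mol] = d2;
              isol[mol] = i + 1;
              jsolv[mol] = j + 1;
            }
          }
        }
      }
    }
  }
  for (int k = 0; k < n_mol; ++k)
    if (R_finite(best2[k])) rmin[k] = std::sqrt(best2[k]);
  return List::create(_["rmin"] = rmin, _["solute_atom"] = isol,
                      _["solvent_atom"] = jsolv);
}

// Molecular minimum distances between every pair of molecules from two
// disjoint atom groups, reported only for pairs closer than cutoff.
// Returns parallel vectors (mol_a, mol_b, dmin).
// [[Rcpp::export]]
List cpp_cross_min_distances(NumericMatrix a_xyz, IntegerVector a_mol,
                             NumericMatrix b_xyz, IntegerVector b_mol,
                             int n_b_mol, NumericVector box, double cutoff) {
  const double b[3] = {box[0], box[1], box[2]};
  CellGrid grid(b_xyz, b, cutoff);
  const double cut2 = cutoff * cutoff;
  const int na = a_xyz.nrow();

  std::unordered_map<long long, double> best;
  for (int i = 0; i < na; ++i) {
    const double p[3] = {a_xyz(i, 0), a_xyz(i, 1), a_xyz(i, 2)};
    long long amol = a_mol[i] - 1;
    int cx = grid.idx1(p[0], b[0], grid.cs[0], grid.nc[0]);
    int cy = grid.idx1(p[1], b[1], grid.cs[1], grid.nc[1]);
    int cz = grid.idx1(p[2], b[2], grid.cs[2], grid.nc[2]);
    for (int dz = -1; dz <= 1; ++dz) {
      int iz = (cz + dz + grid.nc[2]) % grid.nc[2];
      for (int dy = -1; dy <= 1; ++dy) {
        int iy = (cy + dy + grid.nc[1]) % grid.nc[1];
        for (int dx = -1; dx <= 1; ++dx) {
          int ix = (cx + dx + grid.nc[0]) % grid.nc[0];
          int c = (iz * grid.nc[1] + iy) * grid.nc[0] + ix;
          for (int jb = grid.head[c]; jb != -1; jb = grid.nxt[jb]) {
            const double q[3] = {b_xyz(jb, 0), b_xyz(jb, 1), b_xyz(jb, 2)};
            double d2 = dist2_mi(p, q, b);
            if (d2 > cut2) continue;
            long long key = amol * (long long)n_b_mol + (b_mol[jb] - 1);
            auto it = best.find(key);
            if (it == best.end() || d2 < it->second) best[key] = d2;
          }
        }
      }
    }
  }
  int n = best.size();
  IntegerVector ma(n), mb(n);
  NumericVector d(n);
  int k = 0;
  for (auto& kv : best) {
    ma[k] = (int)(kv.first / n_b_mol) + 1;
    mb[k] = (int)(kv.first % n_b_mol) + 1;
    d[k] = std::sqrt(kv.second);
    ++k;
  }
  return List::create(_["mol_a"] = ma, _["mol_b"] = mb, _["dmin"] = d);
}
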