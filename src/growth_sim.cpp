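// 3D lattice birth/death/migration simulation of barcoded tumor growth.
// One cell per site; daughters inherit the barcode; division is suppressed
// when a cell has no empty neighbor. Uses R's RNG so results are fully
// determined by set.seed() on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int OFF = 1 << 20;  // coordinate offset for key packing

static inline long long pack(int x, int y, int z) {
  return (long long)(x + OFF) |
         ((long long)(y + OFF) << 21) |
         ((long long)(z + OFF) << 42);
}

struct Lattice {
  std::vector<int> x, y, z, label;
  std::unordered_map<long long, int> occ;  // site key -> cell index

  int size() const { return (int)x.size(); }

  void add(int cx, int cy, int cz, int lab) {
    occ[pack(cx, cy, cz)] = size();
    x.push_back(cx); y.push_back(cy); z.push_back(cz);
    label.push_back(lab);
  }

  void remove(int i) {  // swap with last cell, pop
    int last = size() - 1;
    occ.erase(pack(x[i], y[i], z[i]));
    if (i != last) {
      x[i] = x[last]; y[i] = y[last]; z[i] = z[last]; label[i] = label[last];
      occ[pack(x[i], y[i], z[i])] = i;
    }
    x.pop_back(); y.pop_back(); z.pop_back(); label.pop_back();
  }

  void move(int i, int nx, int ny, int nz) {
    occ.erase(pack(x[i], y[i], z[i]));
    x[i] = nx; y[i] = ny; z[i] = nz;
    occ[pack(nx, ny, nz)] = i;
  }
};

// [[Rcpp::export(name = ".sim_growth_cpp")]]
List sim_growth_cpp(int n_init, double birth, double death, double migration,
                    int target, bool moore, double max_events) {
  std::vector<std::array<int, 3>> nb;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (!moore && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
        nb.push_back({dx, dy, dz});
      }
  const int nnb = (int)nb.size();

  // compact seeded cluster: n_init closest-to-origin sites, deterministic
  Lattice lat;
  {
    int R = (int)std::ceil(std::cbrt((double)n_init)) + 2;
    std::vector<std::array<int, 4>> sites;  // dist2, x, y, z
    for (int cx = -R; cx <= R; ++cx)
      for (int cy = -R; cy <= R; ++cy)
        for (int cz = -R; cz <= R; ++cz)
          sites.push_back({cx * cx + cy * cy + cz * cz, cx, cy, cz});
    std::sort(sites.begin(), sites.end());
    for (int i = 0; i < n_init; ++i)
      lat.add(sites[i][1], sites[i][2], sites[i][3], i + 1);
  }

  const double total_rate = birth + death + migration;
  double t = 0.0, events = 0.0;
  long long births = 0, deaths = 0, migrations = 0;
  int empties[26];

  while (lat.size() > 0 && lat.size() < target && events < max_events) {
    events += 1.0;
    int n = lat.size();
    t += -std::log(unif_rand()) / (n * total_rate);
    int i = (int)(unif_rand() * n);
    if (i >= n) i = n - 1;
    double u = unif_rand() * total_rate;
    if (u < birth) {
      int ne = 0;
      for (int k = 0; k < nnb; ++k) {
        long long key = pack(lat.x[i] + nb[k][0], lat.y[i] + nb[k][1],
                             lat.z[i] + nb[k][2]);
        if (lat.occ.find(key) == lat.occ.end()) empties[ne++] = k;
      }
      if (ne > 0) {  // else division suppressed by contact inhibition
        int k = empties[(int)(unif_rand() * ne)];
        lat.add(lat.x[i] + nb[k][0], lat.y[i] + nb[k][1],
                lat.z[i] + nb[k][2], lat.label[i]);
        ++births;
      }
    } else if (u < birth + death) {
      lat.remove(i);
      ++deaths;
    } else {
      int ne = 0;
      for (int k = 0; k < nnb; ++k) {
        long long key = pack(lat.x[i] + nb[k][0], lat.y[i] + nb[k][1],
                             lat.z[i] + nb[k][2]);
        if (lat.occ.find(key) == lat.occ.end()) empties[ne++] = k;
      }
      if (ne > 0) {
        int k = empties[(int)(unif_rand() * ne)];
        lat.move(i, lat.x[i] + nb[k][0], lat.y[i] + nb[k][1],
                 lat.z[i] + nb[k][2]);
        ++migrations;
      }
    }
    if (((long long)events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  int n = lat.size();
  IntegerMatrix coords(n, 3);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) {
    coords(i, 0) = lat.x[i];
    coords(i, 1) = lat.y[i];
    coords(i, 2) = lat.z[i];
    labels[i] = lat.label[i];
  }
  return List::create(
    _["coords"] = coords, _["labels"] = labels, _["time"] = t,
    _["births"] = (double)births, _["deaths"] = (double)deaths,
    _["migrations"] = (double)migrations,
    _["extinct"] = (n == 0), _["reached_target"] = (n >= target),
    _["events"] = events);
}
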