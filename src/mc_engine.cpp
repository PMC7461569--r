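// Coarse-grained FCC lattice Monte Carlo engine for pentablock surfactant
// chains in explicit solvent.  Sites are the even-parity nodes of an L^3
// simple-cubic grid (x+y+z even), coordination 12, bond length a*sqrt(2).
// Species: 1 = A (tail/spacer, solvophobic), 2 = B (head), empty = solvent.
// Reduced energy E* counts A-B and A-S nearest-neighbour contacts (all other
// pairs are athermal), so E* is a non-negative integer.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>
#include <functional>

using namespace Rcpp;

static const int OFF[12][3] = {
  { 1, 1, 0}, { 1,-1, 0}, {-1, 1, 0}, {-1,-1, 0},
  { 1, 0, 1}, { 1, 0,-1}, {-1, 0, 1}, {-1, 0,-1},
  { 0, 1, 1}, { 0, 1,-1}, { 0,-1, 1}, { 0,-1,-1}
};

// Deterministic, portable RNG (mt19937_64 with explicit scaling; we avoid
// std distributions because their streams are implementation-defined).
struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed + 0x9E3779B97F4A7C15ULL) {}
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(gen() % static_cast<uint64_t>(n)); }
};

static inline int wrap(int x, int L) { int r = x % L; return r < 0 ? r + L : r; }
static inline int sidx(int x, int y, int z, int L) {
  return wrap(x, L) + L * (wrap(y, L) + L * wrap(z, L));
}

// symmetric pair energy in units of eps: 1 for {A,B} and {A,S}, else 0
// occupant code o: 0 solvent, 1 A, 2 B
static inline int pairE(int a, int b) {
  return ((a == 1 && b != 1) || (b == 1 && a != 1)) ? 1 : 0;
}

struct Lattice {
  int L, n;                 // n monomers
  std::vector<int> occ;     // L^3, monomer index + 1, 0 = solvent
  std::vector<int> cx, cy, cz;   // unwrapped monomer coordinates
  const int* spe;           // species per monomer (1/2)

  Lattice(int L_, const IntegerMatrix& coords, const IntegerVector& species)
    : L(L_), n(coords.nrow()), occ(static_cast<size_t>(L_) * L_ * L_, 0),
      cx(n), cy(n), cz(n), spe(&species[0]) {
    for (int m = 0; m < n; ++m) {
      cx[m] = coords(m, 0); cy[m] = coords(m, 1); cz[m] = coords(m, 2);
      int id = sidx(cx[m], cy[m], cz[m], L);
      if ((wrap(cx[m],L) + wrap(cy[m],L) + wrap(cz[m],L)) % 2 != 0)
        stop("monomer %d sits on an odd-parity (non-FCC) site", m + 1);
      if (occ[id] != 0) stop("site collision at monomer %d", m + 1);
      occ[id] = m + 1;
    }
  }

  long totalEnergy() const {
    long e = 0;
    for (int m = 0; m < n; ++m) {
      if (spe[m] != 1) continue;          // count every A-X contact from the A side
      for (int k = 0; k < 12; ++k) {
        int o = occ[sidx(cx[m] + OFF[k][0], cy[m] + OFF[k][1], cz[m] + OFF[k][2], L)];
        if (o == 0 || spe[o - 1] == 2) ++e;   // A-S or A-B
      }
    }
    return e;
  }
};

// one Monte Carlo step: attempt to move every monomer once, in random order
// chainLen: monomers per chain (bonds link consecutive monomers of a chain)
// tstar <= 0 or +Inf means athermal (accept every geometrically valid move)
static void sweep(Lattice& lat, int chainLen, double tstar, Rng& rng,
                  long& E, long& nProp, long& nValid, long& nAcc,
                  std::vector<int>& order) {
  const int n = lat.n, L = lat.L;
  bool athermal = !(tstar > 0.0) || !std::isfinite(tstar);
  for (int i = 0; i < n; ++i) order[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(order[i], order[rng.below(i + 1)]);

  for (int i = 0; i < n; ++i) {
    int m = order[i];
    int k = rng.below(12);
    int nx = lat.cx[m] + OFF[k][0], ny = lat.cy[m] + OFF[k][1], nz = lat.cz[m] + OFF[k][2];
    int tid = sidx(nx, ny, nz, L);
    ++nProp;
    if (lat.occ[tid] != 0) continue;                   // target must be solvent
    // bond constraint: both bonded neighbours must stay at distance sqrt(2)
    int within = m % chainLen;
    bool ok = true;
    for (int d = -1; d <= 1; d += 2) {
      int w = within + d;
      if (w < 0 || w >= chainLen) continue;
      int b = m + d;
      int dx = lat.cx[b] - nx, dy = lat.cy[b] - ny, dz = lat.cz[b] - nz;
      if (dx*dx + dy*dy + dz*dz != 2) { ok = false; break; }
    }
    if (!ok) continue;
    ++nValid;

    int sid = sidx(lat.cx[m], lat.cy[m], lat.cz[m], L);
    int c = lat.spe[m];
    int dE = 0;
    for (int q = 0; q < 12; ++q) {
      int u = sidx(lat.cx[m] + OFF[q][0], lat.cy[m] + OFF[q][1], lat.cz[m] + OFF[q][2], L);
      if (u == tid) continue;                          // (s,t) pair unchanged
      int o = lat.occ[u];
      int os = (o == 0) ? 0 : lat.spe[o - 1];
      dE += pairE(0, os) - pairE(c, os);               // site s becomes solvent
    }
    for (int q = 0; q < 12; ++q) {
      int u = sidx(nx + OFF[q][0], ny + OFF[q][1], nz + OFF[q][2], L);
      if (u == sid) continue;
      int o = lat.occ[u];
      int os = (o == 0) ? 0 : lat.spe[o - 1];
      dE += pairE(c, os) - pairE(0, os);               // site t gains the monomer
    }

    bool accept = athermal || dE <= 0 || rng.unif() < std::exp(-dE / tstar);
    if (accept) {
      lat.occ[sid] = 0;
      lat.occ[tid] = m + 1;
      lat.cx[m] = nx; lat.cy[m] = ny; lat.cz[m] = nz;
      E += dE;
      ++nAcc;
    }
  }
}

static IntegerMatrix coordsOut(const Lattice& lat) {
  IntegerMatrix out(lat.n, 3);
  for (int m = 0; m < lat.n; ++m) {
    out(m, 0) = lat.cx[m]; out(m, 1) = lat.cy[m]; out(m, 2) = lat.cz[m];
  }
  return out;
}

// [[Rcpp::export]]
double cpp_total_energy(int L, IntegerMatrix coords, IntegerVector species) {
  Lattice lat(L, coords, species);
  return static_cast<double>(lat.totalEnergy());
}

// Run n_sweeps Monte Carlo steps at a single temperature.
// check_every > 0: recount the total energy every check_every sweeps and
// stop if the incremental bookkeeping has drifted (test mode).
// [[Rcpp::export]]
List cpp_run_mc(int L, IntegerMatrix coords, IntegerVector species, int chain_len,
                double tstar, int n_sweeps, double seed, int sample_stride,
                int check_every = 0) {
  Lattice lat(L, coords, species);
  Rng rng(static_cast<uint64_t>(seed));
  long E = lat.totalEnergy(), nProp = 0, nValid = 0, nAcc = 0;
  std::vector<int> order(lat.n);
  std::vector<double> es;
  if (sample_stride > 0) es.reserve(n_sweeps / sample_stride + 1);

  for (int s = 1; s <= n_sweeps; ++s) {
    sweep(lat, chain_len, tstar, rng, E, nProp, nValid, nAcc, order);
    if (sample_stride > 0 && s % sample_stride == 0) es.push_back(static_cast<double>(E));
    if (check_every > 0 && s % check_every == 0) {
      long full = lat.totalEnergy();
      if (full != E)
        stop("energy bookkeeping drift: incremental %ld vs recount %ld", E, full);
    }
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["coords"] = coordsOut(lat),
    _["energy"] = static_cast<double>(E),
    _["energy_recount"] = static_cast<double>(lat.totalEnergy()),
    _["energy_series"] = NumericVector(es.begin(), es.end()),
    _["n_proposed"] = static_cast<double>(nProp),
    _["n_valid"] = static_cast<double>(nValid),
    _["n_accepted"] = static_cast<double>(nAcc));
}

// Parallel tempering over a ladder of temperatures.  Replica sweeps are
// interleaved with configuration-swap attempts every swap_every sweeps,
// alternating even/odd adjacent pairs.  Swap acceptance:
// min(1, exp((1/Ti - 1/Tj) (Ei - Ej))).
// [[Rcpp::export]]
List cpp_run_pt(int L, List coords_list, IntegerVector species, int chain_len,
                NumericVector temps, int n_sweeps, int swap_every, double seed,
                int sample_stride) {
  int R = temps.size();
  if (static_cast<int>(coords_list.size()) != R) stop("one configuration per temperature required");
  std::vector<Lattice> reps;
  reps.reserve(R);
  for (int r = 0; r < R; ++r)
    reps.emplace_back(L, as<IntegerMatrix>(coords_list[r]), species);

  std::vector<Rng> rngs;
  for (int r = 0; r < R; ++r) rngs.emplace_back(static_cast<uint64_t>(seed) * 1315423911ULL + r);
  Rng swapRng(static_cast<uint64_t>(seed) + 0x51ED270F3ULL);

  std::vector<long> E(R), nProp(R, 0), nValid(R, 0), nAcc(R, 0);
  for (int r = 0; r < R; ++r) E[r] = reps[r].totalEnergy();
  std::vector<int> order(reps[0].n);
  // replica r currently holds configuration conf[r] (identity of walkers only
  // matters for diagnostics; configurations are swapped in place)
  std::vector<double> swapProp(std::max(R - 1, 0), 0), swapAcc(std::max(R - 1, 0), 0);
  int n_samp = (sample_stride > 0) ? n_sweeps / sample_stride : 0;
  NumericMatrix eseries(n_samp, R);
  int isamp = 0, parity = 0;

  for (int s = 1; s <= n_sweeps; ++s) {
    for (int r = 0; r < R; ++r)
      sweep(reps[r], chain_len, temps[r], rngs[r], E[r], nProp[r], nValid[r], nAcc[r], order);
    if (swap_every > 0 && s % swap_every == 0) {
      for (int i = parity; i < R - 1; i += 2) {
        ++swapProp[i];
        double arg = (1.0 / temps[i] - 1.0 / temps[i + 1]) *
                     (static_cast<double>(E[i]) - static_cast<double>(E[i + 1]));
        if (arg >= 0 || swapRng.unif() < std::exp(arg)) {
          std::swap(reps[i].occ, reps[i + 1].occ);
          std::swap(reps[i].cx, reps[i + 1].cx);
          std::swap(reps[i].cy, reps[i + 1].cy);
          std::swap(reps[i].cz, reps[i + 1].cz);
          std::swap(E[i], E[i + 1]);
          ++swapAcc[i];
        }
      }
      parity = 1 - parity;
    }
    if (sample_stride > 0 && s % sample_stride == 0 && isamp < n_samp) {
      for (int r = 0; r < R; ++r) eseries(isamp, r) = static_cast<double>(E[r]);
      ++isamp;
    }
    if (s % 512 == 0) Rcpp::checkUserInterrupt();
  }

  List outCoords(R);
  NumericVector eOut(R);
  for (int r = 0; r < R; ++r) { outCoords[r] = coordsOut(reps[r]); eOut[r] = E[r]; }
  return List::create(
    _["coords"] = outCoords, _["energy"] = eOut, _["energy_series"] = eseries,
    _["swap_proposed"] = NumericVector(swapProp.begin(), swapProp.end()),
    _["swap_accepted"] = NumericVector(swapAcc.begin(), swapAcc.end()));
}

// Grow self- and mutually-avoiding nearest-neighbour walks on the FCC lattice.
// [[Rcpp::export]]
List cpp_place_chains(int L, int n_chains, int chain_len, double seed,
                      int max_restarts = 200) {
  Rng rng(static_cast<uint64_t>(seed));
  size_t nsite = static_cast<size_t>(L) * L * L;
  std::vector<int> occ(nsite, 0);
  int n = n_chains * chain_len;
  IntegerMatrix coords(n, 3);

  for (int c = 0; c < n_chains; ++c) {
    bool placed = false;
    for (int attempt = 0; attempt < max_restarts && !placed; ++attempt) {
      // random vacant even-parity start
      int x, y, z, tries = 0;
      do {
        x = rng.below(L); y = rng.below(L); z = rng.below(L);
        if (++tries > 100000) stop("no vacant site found; lower the volume fraction");
      } while ((x + y + z) % 2 != 0 || occ[sidx(x, y, z, L)] != 0);
      std::vector<int> px(chain_len), py(chain_len), pz(chain_len);
      px[0] = x; py[0] = y; pz[0] = z;
      occ[sidx(x, y, z, L)] = c * chain_len + 1;
      int grown = 1;
      for (; grown < chain_len; ++grown) {
        int perm[12];
        for (int k = 0; k < 12; ++k) perm[k] = k;
        for (int k = 11; k > 0; --k) std::swap(perm[k], perm[rng.below(k + 1)]);
        bool found = false;
        for (int k = 0; k < 12 && !found; ++k) {
          int nx = px[grown-1] + OFF[perm[k]][0];
          int ny = py[grown-1] + OFF[perm[k]][1];
          int nz = pz[grown-1] + OFF[perm[k]][2];
          if (occ[sidx(nx, ny, nz, L)] == 0) {
            px[grown] = nx; py[grown] = ny; pz[grown] = nz;
            occ[sidx(nx, ny, nz, L)] = c * chain_len + grown + 1;
            found = true;
          }
        }
        if (!found) break;      // dead end
      }
      if (grown == chain_len) {
        for (int m = 0; m < chain_len; ++m) {
          coords(c * chain_len + m, 0) = px[m];
          coords(c * chain_len + m, 1) = py[m];
          coords(c * chain_len + m, 2) = pz[m];
        }
        placed = true;
      } else {
        for (int m = 0; m < grown; ++m) occ[sidx(px[m], py[m], pz[m], L)] = 0;
      }
    }
    if (!placed)
      stop("chain placement failed after %d restarts; lower the volume fraction or enlarge the box",
           max_restarts);
  }
  return List::create(_["coords"] = coords);
}

// Connected components of the chain contact graph: chains are linked when an
// A monomer of one sits on a nearest-neighbour site of an A monomer of the
// other.  Returns a 1-based cluster id per chain.
// [[Rcpp::export]]
IntegerVector cpp_find_clusters(int L, IntegerMatrix coords, IntegerVector species,
                                int chain_len) {
  Lattice lat(L, coords, species);
  int n_chains = lat.n / chain_len;
  std::vector<int> parent(n_chains);
  for (int i = 0; i < n_chains; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int m = 0; m < lat.n; ++m) {
    if (lat.spe[m] != 1) continue;
    for (int k = 0; k < 12; ++k) {
      int o = lat.occ[sidx(lat.cx[m] + OFF[k][0], lat.cy[m] + OFF[k][1], lat.cz[m] + OFF[k][2], L)];
      if (o == 0 || lat.spe[o - 1] != 1) continue;
      int ca = m / chain_len, cb = (o - 1) / chain_len;
      if (ca == cb) continue;
      int ra = find(ca), rb = find(cb);
      if (ra != rb) parent[ra] = rb;
    }
  }
  IntegerVector out(n_chains);
  std::vector<int> relabel(n_chains, 0);
  int next = 0;
  for (int i = 0; i < n_chains; ++i) {
    int r = find(i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  return out;
}

// Per-cluster geometry: BFS over the monomer contact graph of each cluster,
// assigning image-consistent (unwrapped) coordinates from an arbitrary root.
// When a BFS edge closes a loop whose coordinate mismatch is non-zero the
// cluster wraps the torus; the affected axes are flagged as percolating.
// Returns BFS coordinates per monomer and percolation flags per cluster.
// [[Rcpp::export]]
List cpp_cluster_geometry(int L, IntegerMatrix coords, IntegerVector species,
                          int chain_len, IntegerVector chain_cluster) {
  Lattice lat(L, coords, species);
  int n = lat.n;
  int n_clusters = 0;
  for (int i = 0; i < chain_cluster.size(); ++i)
    if (chain_cluster[i] > n_clusters) n_clusters = chain_cluster[i];

  IntegerMatrix bfs(n, 3);
  LogicalMatrix perc(n_clusters, 3);
  std::vector<char> visited(n, 0);
  std::vector<int> queue;

  for (int m0 = 0; m0 < n; ++m0) {
    if (visited[m0]) continue;
    int cl = chain_cluster[m0 / chain_len] - 1;
    queue.clear();
    queue.push_back(m0);
    visited[m0] = 1;
    bfs(m0, 0) = lat.cx[m0]; bfs(m0, 1) = lat.cy[m0]; bfs(m0, 2) = lat.cz[m0];
    for (size_t qi = 0; qi < queue.size(); ++qi) {
      int m = queue[qi];
      // neighbours in the contact graph: NN occupied sites of the same
      // cluster (covers bonds, which are NN by construction)
      for (int k = 0; k < 12; ++k) {
        int o = lat.occ[sidx(lat.cx[m] + OFF[k][0], lat.cy[m] + OFF[k][1], lat.cz[m] + OFF[k][2], L)];
        if (o == 0) continue;
        int mb = o - 1;
        if (chain_cluster[mb / chain_len] - 1 != cl) continue;
        // offset in true (stored) coordinates between the two monomers,
        // reduced to the wrapped displacement of this contact
        int ex = bfs(m, 0) + OFF[k][0], ey = bfs(m, 1) + OFF[k][1], ez = bfs(m, 2) + OFF[k][2];
        if (!visited[mb]) {
          visited[mb] = 1;
          bfs(mb, 0) = ex; bfs(mb, 1) = ey; bfs(mb, 2) = ez;
          queue.push_back(mb);
        } else {
          if (bfs(mb, 0) != ex) perc(cl, 0) = true;
          if (bfs(mb, 1) != ey) perc(cl, 1) = true;
          if (bfs(mb, 2) != ez) perc(cl, 2) = true;
        }
      }
    }
  }
  return List::create(_["bfs_coords"] = bfs, _["percolates"] = perc);
}
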