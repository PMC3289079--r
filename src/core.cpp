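// Engine for triangular-lattice HP folding: fitness evaluation on an
// occupancy grid, the ERS-GA / HHGA generation loop, both hill-climbing
// operators, and the exhaustive enumeration oracle.
//
// Direction encoding (shared with the R side, see R/lattice.R):
//   0=R (1,0), 1=RU (0,1), 2=LU (-1,1), 3=L (-1,0), 4=LD (0,-1), 5=RD (1,-1)
// The order is the counter-clockwise 60-degree ring, so rotation by k steps
// is (d + k) mod 6 and the opposite direction is (d + 3) mod 6.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

const int DX[6] = {1, 0, -1, -1, 0, 1};
const int DY[6] = {0, 1, 1, 0, -1, -1};

typedef std::mt19937 RNG;

inline int randInt(RNG &rng, int lo, int hi) { // inclusive bounds
  return std::uniform_int_distribution<int>(lo, hi)(rng);
}
inline double randU(RNG &rng) {
  return std::uniform_real_distribution<double>(0.0, 1.0)(rng);
}
// a direction drawn uniformly from the five symbols other than `cur`
inline int randOther(RNG &rng, int cur) {
  int d = randInt(rng, 0, 4);
  return d >= cur ? d + 1 : d;
}

// Fitness evaluator with a reusable version-stamped occupancy grid.
// fitness = -contacts + penalty * colliding_pairs; lower is better.
// Contacts are counted on the coordinates as decoded whether or not the
// walk is self-avoiding (gives the penalty landscape a gradient).
class Evaluator {
public:
  Evaluator(const std::vector<char> &isH, long long penalty)
      : isH_(isH), n_((int)isH.size()), W_(2 * n_ + 1), penalty_(penalty),
        ver_(W_ * W_, -1), occ_(W_ * W_, 0), head_(W_ * W_, -1),
        nxt_(n_, -1), xs_(n_), ys_(n_), stamp_(0) {}

  long long eval(const int *folds, int &contacts, int &collisions) {
    ++stamp_;
    int x = 0, y = 0;
    collisions = 0;
    for (int i = 0; i < n_; ++i) {
      if (i > 0) {
        x += DX[folds[i - 1]];
        y += DY[folds[i - 1]];
      }
      xs_[i] = x;
      ys_[i] = y;
      int key = (x + n_) * W_ + (y + n_);
      if (ver_[key] != stamp_) {
        ver_[key] = stamp_;
        occ_[key] = 0;
        head_[key] = -1;
      }
      collisions += occ_[key]; // pairs with every residue already on the site
      ++occ_[key];
      nxt_[i] = head_[key];
      head_[key] = i;
    }
    contacts = 0;
    for (int i = 0; i < n_; ++i) {
      if (!isH_[i]) continue;
      for (int d = 0; d < 6; ++d) {
        int key = (xs_[i] + DX[d] + n_) * W_ + (ys_[i] + DY[d] + n_);
        if (ver_[key] != stamp_) continue;
        for (int j = head_[key]; j >= 0; j = nxt_[j])
          if (j > i + 1 && isH_[j]) ++contacts; // each pair found once (j > i+1)
      }
    }
    return -(long long)contacts + penalty_ * (long long)collisions;
  }

  int n() const { return n_; }

private:
  std::vector<char> isH_;
  int n_, W_;
  long long penalty_;
  std::vector<int> ver_, occ_, head_, nxt_, xs_, ys_;
  int stamp_;
};

struct Ind {
  std::vector<int> g;
  long long fit;
  int contacts, collisions;
};

inline void evalInd(Ind &ind, Evaluator &ev) {
  ind.fit = ev.eval(ind.g.data(), ind.contacts, ind.collisions);
}

struct Cfg {
  int pop, gens;
  double cx, mut;
  long long penalty;
  bool ls;
  int ls1, ls2;
  int parentPool;    // 0 = bottom half, 1 = whole population, 2 = top half
  bool mutPerChrom;  // mutation rate interpreted per chromosome
  bool ls2ScanAll;   // LS2 scans every pivot instead of one random pivot
};

// Two-point crossover; cut points are two independent uniform draws in 0..m
// sorted, so p == q (cloning) is permitted.
void crossover(const std::vector<int> &a, const std::vector<int> &b,
               std::vector<int> &c1, std::vector<int> &c2, RNG &rng,
               int *pp = 0, int *qq = 0) {
  int m = (int)a.size();
  int p = randInt(rng, 0, m), q = randInt(rng, 0, m);
  if (p > q) std::swap(p, q);
  c1 = a;
  c2 = b;
  for (int i = p; i < q; ++i) {
    c1[i] = b[i];
    c2[i] = a[i];
  }
  if (pp) *pp = p;
  if (qq) *qq = q;
}

void mutate(std::vector<int> &g, double rate, bool perChrom, RNG &rng) {
  int m = (int)g.size();
  if (perChrom) {
    if (randU(rng) < rate) {
      int pos = randInt(rng, 0, m - 1);
      g[pos] = randOther(rng, g[pos]);
    }
  } else {
    for (int i = 0; i < m; ++i)
      if (randU(rng) < rate) g[i] = randOther(rng, g[i]);
  }
}

// Local search I: first-improvement hill climbing over single-direction
// changes; each pass visits every gene once in random order and proposes one
// random different symbol there.
void localSearch1(Ind &ind, Evaluator &ev, int passes, RNG &rng) {
  int m = (int)ind.g.size();
  if (m == 0) return;
  std::vector<int> order(m);
  std::iota(order.begin(), order.end(), 0);
  for (int pass = 0; pass < passes; ++pass) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int k = 0; k < m; ++k) {
      int pos = order[k];
      int old = ind.g[pos];
      ind.g[pos] = randOther(rng, old);
      int c, col;
      long long f = ev.eval(ind.g.data(), c, col);
      if (f < ind.fit) {
        ind.fit = f;
        ind.contacts = c;
        ind.collisions = col;
      } else {
        ind.g[pos] = old;
      }
    }
  }
}

// Rotate the suffix starting at gene `pivot` by each of the five non-trivial
// 60-degree multiples; keep the best rotation if it strictly improves.
bool bestSuffixRotation(Ind &ind, Evaluator &ev, int pivot) {
  int m = (int)ind.g.size();
  long long bestF = ind.fit;
  int bestK = 0, bc = 0, bcol = 0;
  std::vector<int> tmp = ind.g;
  for (int k = 1; k <= 5; ++k) {
    for (int i = pivot; i < m; ++i) tmp[i] = (ind.g[i] + k) % 6;
    int c, col;
    long long f = ev.eval(tmp.data(), c, col);
    if (f < bestF) {
      bestF = f;
      bestK = k;
      bc = c;
      bcol = col;
    }
  }
  if (bestK == 0) return false;
  for (int i = pivot; i < m; ++i) ind.g[i] = (ind.g[i] + bestK) % 6;
  ind.fit = bestF;
  ind.contacts = bc;
  ind.collisions = bcol;
  return true;
}

// Local search II: tail-segment rotation about a pivot residue.
void localSearch2(Ind &ind, Evaluator &ev, int trials, bool scanAll,
                  RNG &rng) {
  int m = (int)ind.g.size();
  if (m < 2) return; // no proper suffix to rotate
  if (scanAll) {
    for (int p = 1; p < m; ++p) bestSuffixRotation(ind, ev, p);
  } else {
    for (int t = 0; t < trials; ++t)
      bestSuffixRotation(ind, ev, randInt(rng, 1, m - 1));
  }
}

inline bool fitLess(const Ind &a, const Ind &b) { return a.fit < b.fit; }

// One ERS generation: the top half survives unchanged; the bottom half is
// replaced by offspring bred from the parent pool (crossover with probability
// cx, else cloning; then mutation; then, in HHGA mode, LS-I and LS-II).
// RNG draw order: pairing shuffle -> per pair crossover decision and cuts ->
// per offspring mutation -> LS-I -> LS-II.
void nextGeneration(std::vector<Ind> &pop, const Cfg &cfg, Evaluator &ev,
                    RNG &rng) {
  int P = (int)pop.size(), half = P / 2;
  std::vector<int> pool;
  if (cfg.parentPool == 1) {
    pool.resize(P);
    std::iota(pool.begin(), pool.end(), 0);
    std::shuffle(pool.begin(), pool.end(), rng);
    pool.resize(half);
  } else {
    pool.resize(half);
    std::iota(pool.begin(), pool.end(), cfg.parentPool == 2 ? 0 : half);
    std::shuffle(pool.begin(), pool.end(), rng);
  }
  std::vector<Ind> kids;
  kids.reserve(half + 1);
  auto refine = [&](Ind &ch) {
    mutate(ch.g, cfg.mut, cfg.mutPerChrom, rng);
    evalInd(ch, ev);
    if (cfg.ls) {
      localSearch1(ch, ev, cfg.ls1, rng);
      localSearch2(ch, ev, cfg.ls2, cfg.ls2ScanAll, rng);
    }
  };
  for (size_t i = 0; i + 1 < pool.size(); i += 2) {
    const Ind &a = pop[pool[i]], &b = pop[pool[i + 1]];
    Ind c1, c2;
    if (randU(rng) < cfg.cx) {
      crossover(a.g, b.g, c1.g, c2.g, rng);
    } else {
      c1.g = a.g;
      c2.g = b.g;
    }
    refine(c1);
    refine(c2);
    kids.push_back(std::move(c1));
    kids.push_back(std::move(c2));
  }
  if ((int)kids.size() < half) { // odd pool: clone the leftover parent
    Ind c;
    c.g = pop[pool.back()].g;
    refine(c);
    kids.push_back(std::move(c));
  }
  for (int i = 0; i < half; ++i) pop[half + i] = std::move(kids[i]);
  std::stable_sort(pop.begin(), pop.end(), fitLess);
}

std::vector<char> asHvec(const LogicalVector &isH) {
  std::vector<char> v(isH.size());
  for (int i = 0; i < isH.size(); ++i) v[i] = isH[i] ? 1 : 0;
  return v;
}

std::vector<int> asGenes(const IntegerVector &g) {
  std::vector<int> v(g.size());
  for (int i = 0; i < g.size(); ++i) {
    if (g[i] < 0 || g[i] > 5) stop("fold code out of range 0..5");
    v[i] = g[i];
  }
  return v;
}

Cfg makeCfg(int pop, int gens, double cx, double mut, double penalty,
            bool ls, int ls1, int ls2, int parentPool, bool mutPerChrom,
            bool ls2ScanAll) {
  Cfg c;
  c.pop = pop;
  c.gens = gens;
  c.cx = cx;
  c.mut = mut;
  c.penalty = (long long)penalty;
  c.ls = ls;
  c.ls1 = ls1;
  c.ls2 = ls2;
  c.parentPool = parentPool;
  c.mutPerChrom = mutPerChrom;
  c.ls2ScanAll = ls2ScanAll;
  return c;
}

} // namespace

// [[Rcpp::export(name = ".cpp_decode")]]
IntegerMatrix cpp_decode(IntegerVector folds) {
  std::vector<int> g = asGenes(folds);
  int n = (int)g.size() + 1;
  IntegerMatrix out(n, 2);
  int x = 0, y = 0;
  out(0, 0) = 0;
  out(0, 1) = 0;
  for (int i = 1; i < n; ++i) {
    x += DX[g[i - 1]];
    y += DY[g[i - 1]];
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_evaluate")]]
List cpp_evaluate(LogicalVector isH, IntegerVector folds, double penalty) {
  if (isH.size() != folds.size() + 1)
    stop("sequence/conformation length mismatch");
  std::vector<char> h = asHvec(isH);
  Evaluator ev(h, (long long)penalty);
  std::vector<int> g = asGenes(folds);
  int c, col;
  long long f = ev.eval(g.data(), c, col);
  return List::create(_["fitness"] = (double)f, _["contacts"] = c,
                      _["collisions"] = col);
}

// [[Rcpp::export(name = ".cpp_init_population")]]
IntegerMatrix cpp_init_population(int m, int popSize, int seed) {
  RNG rng((unsigned)seed);
  IntegerMatrix out(popSize, m);
  for (int i = 0; i < popSize; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = randInt(rng, 0, 5);
  return out;
}

// [[Rcpp::export(name = ".cpp_crossover")]]
List cpp_crossover(IntegerVector a, IntegerVector b, int seed) {
  if (a.size() != b.size()) stop("parents must have equal length");
  RNG rng((unsigned)seed);
  std::vector<int> va = asGenes(a), vb = asGenes(b), c1, c2;
  int p, q;
  crossover(va, vb, c1, c2, rng, &p, &q);
  return List::create(_["child1"] = wrap(c1), _["child2"] = wrap(c2),
                      _["p"] = p, _["q"] = q);
}

// [[Rcpp::export(name = ".cpp_mutate")]]
IntegerVector cpp_mutate(IntegerVector folds, double rate, bool perChrom,
                         int seed) {
  RNG rng((unsigned)seed);
  std::vector<int> g = asGenes(folds);
  mutate(g, rate, perChrom, rng);
  return wrap(g);
}

// [[Rcpp::export(name = ".cpp_local_search1")]]
List cpp_local_search1(LogicalVector isH, IntegerVector folds, int passes,
                       double penalty, int seed) {
  if (isH.size() != folds.size() + 1)
    stop("sequence/conformation length mismatch");
  RNG rng((unsigned)seed);
  std::vector<char> h = asHvec(isH);
  Evaluator ev(h, (long long)penalty);
  Ind ind;
  ind.g = asGenes(folds);
  evalInd(ind, ev);
  localSearch1(ind, ev, passes, rng);
  return List::create(_["folds"] = wrap(ind.g), _["fitness"] = (double)ind.fit,
                      _["contacts"] = ind.contacts,
                      _["collisions"] = ind.collisions);
}

// [[Rcpp::export(name = ".cpp_local_search2")]]
List cpp_local_search2(LogicalVector isH, IntegerVector folds, int trials,
                       bool scanAll, double penalty, int seed, int pivot) {
  if (isH.size() != folds.size() + 1)
    stop("sequence/conformation length mismatch");
  RNG rng((unsigned)seed);
  std::vector<char> h = asHvec(isH);
  Evaluator ev(h, (long long)penalty);
  Ind ind;
  ind.g = asGenes(folds);
  evalInd(ind, ev);
  int m = (int)ind.g.size();
  if (pivot >= 1 && pivot < m) {
    bestSuffixRotation(ind, ev, pivot);
  } else {
    localSearch2(ind, ev, trials, scanAll, rng);
  }
  return List::create(_["folds"] = wrap(ind.g), _["fitness"] = (double)ind.fit,
                      _["contacts"] = ind.contacts,
                      _["collisions"] = ind.collisions);
}

// [[Rcpp::export(name = ".cpp_next_generation")]]
List cpp_next_generation(LogicalVector isH, IntegerMatrix pop, int popSize,
                         double cx, double mut, double penalty, bool ls,
                         int ls1, int ls2, int parentPool, bool mutPerChrom,
                         bool ls2ScanAll, int seed) {
  int P = pop.nrow(), m = pop.ncol();
  if (isH.size() != m + 1) stop("sequence/conformation length mismatch");
  if (P % 2 != 0) stop("population size must be even");
  Cfg cfg = makeCfg(popSize, 1, cx, mut, penalty, ls, ls1, ls2, parentPool,
                    mutPerChrom, ls2ScanAll);
  RNG rng((unsigned)seed);
  std::vector<char> h = asHvec(isH);
  Evaluator ev(h, cfg.penalty);
  std::vector<Ind> v(P);
  for (int i = 0; i < P; ++i) {
    v[i].g.resize(m);
    for (int j = 0; j < m; ++j) v[i].g[j] = pop(i, j);
    evalInd(v[i], ev);
  }
  std::stable_sort(v.begin(), v.end(), fitLess);
  nextGeneration(v, cfg, ev, rng);
  IntegerMatrix out(P, m);
  NumericVector fit(P);
  for (int i = 0; i < P; ++i) {
    for (int j = 0; j < m; ++j) out(i, j) = v[i].g[j];
    fit[i] = (double)v[i].fit;
  }
  return List::create(_["pop"] = out, _["fitness"] = fit);
}

// [[Rcpp::export(name = ".cpp_run_ga")]]
List cpp_run_ga(LogicalVector isH, int popSize, int gens, double cx,
                double mut, double penalty, bool ls, int ls1, int ls2,
                int parentPool, bool mutPerChrom, bool ls2ScanAll,
                int seed) {
  int n = isH.size(), m = n - 1;
  if (n < 2) stop("sequence must have at least 2 residues");
  if (popSize < 2 || popSize % 2 != 0)
    stop("population size must be a positive even integer");
  Cfg cfg = makeCfg(popSize, gens, cx, mut, penalty, ls, ls1, ls2,
                    parentPool, mutPerChrom, ls2ScanAll);
  RNG rng((unsigned)seed);
  std::vector<char> h = asHvec(isH);
  Evaluator ev(h, cfg.penalty);

  std::vector<Ind> pop(popSize);
  for (int i = 0; i < popSize; ++i) {
    pop[i].g.resize(m);
    for (int j = 0; j < m; ++j) pop[i].g[j] = randInt(rng, 0, 5);
    evalInd(pop[i], ev);
  }
  std::stable_sort(pop.begin(), pop.end(), fitLess);

  bool haveBest = false;
  Ind best;
  auto track = [&]() {
    for (int i = 0; i < popSize; ++i) {
      if (pop[i].collisions == 0 && (!haveBest || pop[i].fit < best.fit)) {
        best = pop[i];
        haveBest = true;
      }
      if (pop[i].fit >= (haveBest ? best.fit : pop[i].fit + 1)) break;
      // pop is sorted: once fitness exceeds the incumbent nothing better follows
    }
  };
  track();

  NumericVector genBest(gens), genMean(gens);
  for (int g = 0; g < gens; ++g) {
    nextGeneration(pop, cfg, ev, rng);
    double s = 0;
    for (int i = 0; i < popSize; ++i) s += (double)pop[i].fit;
    genBest[g] = (double)pop[0].fit;
    genMean[g] = s / popSize;
    track();
  }

  List out = List::create(
      _["feasible"] = haveBest,
      _["bestFolds"] = haveBest ? wrap(best.g) : R_NilValue,
      _["bestEnergy"] = haveBest ? IntegerVector::create(-best.contacts)
                                 : IntegerVector::create(NA_INTEGER),
      _["bestFitness"] = haveBest ? NumericVector::create((double)best.fit)
                                  : NumericVector::create(NA_REAL),
      _["genBest"] = genBest, _["genMean"] = genMean,
      _["generations"] = gens);
  return out;
}

namespace {

// Exhaustive enumeration of self-avoiding walks with depth-first prefix
// pruning. With `symmetry`, the first step is fixed to R and the first
// off-axis step is restricted to the upper half plane {RU, LU}, quotienting
// out the rotation/reflection group. Leaf energies are computed by an O(n^2)
// pair scan kept deliberately independent of the Evaluator's grid counting.
class Enumerator {
public:
  Enumerator(const std::vector<char> &isH, bool symmetry)
      : isH_(isH), n_((int)isH.size()), W_(2 * n_ + 1), symmetry_(symmetry),
        grid_(W_ * W_, 0), xs_(n_), ys_(n_), folds_(std::max(n_ - 1, 0)),
        bestE_(1), count_(0) {}

  void run() {
    xs_[0] = 0;
    ys_[0] = 0;
    if (n_ == 1) {
      bestE_ = 0;
      count_ = 1;
      return;
    }
    grid_[key(0, 0)] = 1;
    rec(1, true);
    grid_[key(0, 0)] = 0;
  }

  int bestE() const { return bestE_; }
  double count() const { return count_; }
  const std::vector<int> &witness() const { return bestFolds_; }

private:
  inline int key(int x, int y) const { return (x + n_) * W_ + (y + n_); }

  void rec(int i, bool axialOnly) {
    if (i == n_) {
      int e = energy();
      if (e < bestE_) {
        bestE_ = e;
        count_ = 1;
        bestFolds_ = folds_;
      } else if (e == bestE_) {
        ++count_;
      }
      return;
    }
    for (int d = 0; d < 6; ++d) {
      if (symmetry_) {
        if (i == 1 && d != 0) continue;                  // first step = R
        if (axialOnly && (d == 4 || d == 5)) continue;   // first turn upward
      }
      int x = xs_[i - 1] + DX[d], y = ys_[i - 1] + DY[d];
      int k = key(x, y);
      if (grid_[k]) continue;
      grid_[k] = 1;
      xs_[i] = x;
      ys_[i] = y;
      folds_[i - 1] = d;
      rec(i + 1, axialOnly && (d == 0 || d == 3));
      grid_[k] = 0;
    }
  }

  int energy() const {
    int e = 0;
    for (int i = 0; i < n_; ++i) {
      if (!isH_[i]) continue;
      for (int j = i + 2; j < n_; ++j) {
        if (!isH_[j]) continue;
        int dx = xs_[j] - xs_[i], dy = ys_[j] - ys_[i];
        for (int d = 0; d < 6; ++d)
          if (dx == DX[d] && dy == DY[d]) {
            ++e;
            break;
          }
      }
    }
    return -e;
  }

  std::vector<char> isH_;
  int n_, W_;
  bool symmetry_;
  std::vector<int> grid_, xs_, ys_, folds_, bestFolds_;
  int bestE_;
  double count_;
};

} // namespace

// [[Rcpp::export(name = ".cpp_enumerate")]]
List cpp_enumerate(LogicalVector isH, bool symmetry) {
  std::vector<char> h = asHvec(isH);
  Enumerator en(h, symmetry);
  en.run();
  return List::create(_["minEnergy"] = en.bestE(),
                      _["optimalCount"] = en.count(),
                      _["witness"] = wrap(en.witness()));
}
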