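// Simulation kernels for the gland growth model.  Genotypes are integer
// vectors of segregating mutation ids; mutation ids are allocated
// sequentially starting at `start_id` and the number of new ids drawn is
// returned alongside the cells, so the R-level registry can attribute
// them to a growth phase.  All randomness uses R's RNG, so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

typedef std::vector<std::vector<int> > CellPool;

static CellPool pool_from_list(const List &cells) {
  CellPool out(cells.size());
  for (R_xlen_t i = 0; i < cells.size(); ++i) {
    IntegerVector g = cells[i];
    out[i].assign(g.begin(), g.end());
  }
  return out;
}

static List pool_to_list(const CellPool &pool) {
  List out(pool.size());
  for (size_t i = 0; i < pool.size(); ++i)
    out[i] = IntegerVector(pool[i].begin(), pool[i].end());
  return out;
}

static inline void add_mutations(std::vector<int> &cell, int &next_id,
                                 double rate) {
  if (rate <= 0.0) return;
  int nm = (int) R::rpois(rate);
  for (int j = 0; j < nm; ++j) cell.push_back(next_id++);
}

// Balanced binary expansion of a cell pool to `n_target` cells: every
// round all cells divide, except a final partial round in which only the
// first (left-to-right) cells needed to reach the target divide.  Each
// daughter receives an independent Poisson(rate) set of new mutations.
// [[Rcpp::export]]
List cpp_grow(List cells, int n_target, double rate, int start_id) {
  CellPool cur = pool_from_list(cells);
  int next_id = start_id;
  while ((int) cur.size() < n_target) {
    int n_div = std::min((int) cur.size(), n_target - (int) cur.size());
    CellPool nxt;
    nxt.reserve(cur.size() + n_div);
    for (int i = 0; i < n_div; ++i) {
      for (int d = 0; d < 2; ++d) {
        nxt.push_back(cur[i]);
        add_mutations(nxt.back(), next_id, rate);
      }
    }
    for (size_t i = n_div; i < cur.size(); ++i) nxt.push_back(cur[i]);
    cur.swap(nxt);
  }
  return List::create(_["cells"] = pool_to_list(cur),
                      _["n_new"] = next_id - start_id);
}

// Bottleneck regrowth of many glands at once: every gland starts from a
// single founder cell with an empty segregating set (founder mutations
// live in the gland's fixed set) and expands to n_csc cells.
// [[Rcpp::export]]
List cpp_joint_expand(int n_glands, int n_csc, double rate, int start_id) {
  int next_id = start_id;
  List out(n_glands);
  for (int g = 0; g < n_glands; ++g) {
    CellPool cur(1);
    while ((int) cur.size() < n_csc) {
      int n_div = std::min((int) cur.size(), n_csc - (int) cur.size());
      CellPool nxt;
      nxt.reserve(cur.size() + n_div);
      for (int i = 0; i < n_div; ++i) {
        for (int d = 0; d < 2; ++d) {
          nxt.push_back(cur[i]);
          add_mutations(nxt.back(), next_id, rate);
        }
      }
      for (size_t i = n_div; i < cur.size(); ++i) nxt.push_back(cur[i]);
      cur.swap(nxt);
    }
    out[g] = pool_to_list(cur);
  }
  return List::create(_["glands"] = out, _["n_new"] = next_id - start_id);
}

// Constant-size phase over t3 synchronous generations for a joint pool
// of cells labelled by gland (`gid`, 1-based).  Each CSC divides
// asymmetrically with probability r (one CSC daughter), into two CSCs
// with probability (1-r)/2, and into two non-CSCs (lineage loss)
// otherwise; every retained daughter gains Poisson(beta) new mutations.
// [[Rcpp::export]]
List cpp_constant_phase(List cells, IntegerVector gid, double r,
                        double beta, int t3, int start_id) {
  CellPool cur = pool_from_list(cells);
  std::vector<int> g(gid.begin(), gid.end());
  int next_id = start_id;
  double p2 = r + (1.0 - r) / 2.0;
  for (int t = 0; t < t3 && !cur.empty(); ++t) {
    CellPool nxt;
    std::vector<int> gn;
    nxt.reserve(cur.size() + 8);
    gn.reserve(cur.size() + 8);
    for (size_t i = 0; i < cur.size(); ++i) {
      double u = unif_rand();
      int n_off = u < r ? 1 : (u < p2 ? 2 : 0);
      for (int d = 0; d < n_off; ++d) {
        nxt.push_back(cur[i]);
        add_mutations(nxt.back(), next_id, beta);
        gn.push_back(g[i]);
      }
    }
    cur.swap(nxt);
    g.swap(gn);
  }
  return List::create(_["cells"] = pool_to_list(cur),
                      _["gid"] = IntegerVector(g.begin(), g.end()),
                      _["n_new"] = next_id - start_id);
}
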