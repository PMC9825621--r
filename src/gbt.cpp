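// Histogram-based gradient boosting for binary classification.
//
// Implements the two tree-growth policies used by the package's model
// presets: leaf-wise growth with a leaf-count cap (LightGBM-style) and
// depth-wise growth with a depth cap (XGBoost-style). Row bagging,
// per-tree feature subsampling and all tie-breaks are deterministic for a
// given seed; the engine keeps its own RNG so results do not depend on
// R's RNG state.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// xorshift64* PRNG: deterministic, seedable, independent of R's RNG.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, n)
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

// Sample k distinct integers from [0, n) (partial Fisher-Yates).
std::vector<int> sample_k(int n, int k, Rng& rng) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  for (int i = 0; i < k; ++i) {
    int j = i + rng.below(n - i);
    std::swap(pool[i], pool[j]);
  }
  pool.resize(k);
  std::sort(pool.begin(), pool.end());
  return pool;
}

struct Split {
  double gain = -1.0;
  int feat = -1;
  int bin = -1;       // go left when bin(x) <= bin
  double gl = 0.0, hl = 0.0;
  int nl = 0;
};

struct Node {
  int feat = -1;      // -1 for leaf
  int bin = -1;
  int left = -1, right = -1;
  double value = 0.0; // leaf output (already shrunk)
  double gain = 0.0;
};

struct Params {
  int nrounds, num_leaves, max_depth, min_data, max_bins, bagging_freq;
  double learning_rate, lambda, min_hess, bagging_fraction, feature_fraction;
  bool leafwise;
  uint64_t seed;
};

struct Leaf {
  int lo, hi;         // range in the row-index array
  int depth;
  double gsum, hsum;
  int node_id;
  Split best;
};

class Builder {
public:
  Builder(const std::vector<uint8_t>& bins, int n, int p,
          const std::vector<int>& nbins, const Params& par)
    : bins_(bins), n_(n), p_(p), nbins_(nbins), par_(par) {}

  // Build one tree from gradients/hessians over rows `rows`, using feature
  // subset `feats`. Returns nodes; accumulates per-feature gain.
  std::vector<Node> build(const std::vector<double>& g, const std::vector<double>& h,
                          const std::vector<int>& rows, const std::vector<int>& feats,
                          std::vector<double>& feat_gain) {
    idx_ = rows;
    nodes_.clear();
    double gsum = 0.0, hsum = 0.0;
    for (int r : idx_) { gsum += g[r]; hsum += h[r]; }

    nodes_.push_back(Node());
    std::vector<Leaf> open;
    Leaf root{0, (int)idx_.size(), 0, gsum, hsum, 0, Split()};
    root.best = find_split(root, g, h, feats);
    open.push_back(root);
    int n_leaves = 1;

    while (true) {
      // pick the splittable leaf: highest gain (leaf-wise), or first in
      // FIFO order subject to the depth cap (depth-wise)
      int pick = -1;
      if (par_.leafwise) {
        double bestg = 0.0;
        for (size_t i = 0; i < open.size(); ++i)
          if (open[i].best.gain > bestg + 1e-12) { bestg = open[i].best.gain; pick = (int)i; }
        if (pick < 0 || n_leaves >= par_.num_leaves) break;
      } else {
        for (size_t i = 0; i < open.size(); ++i)
          if (open[i].best.gain > 1e-12 && open[i].depth < par_.max_depth) { pick = (int)i; break; }
        if (pick < 0) break;
      }

      Leaf lf = open[pick];
      open.erase(open.begin() + pick);
      const Split& sp = lf.best;

      // partition rows of this leaf on the chosen split
      int mid = partition(lf.lo, lf.hi, sp.feat, sp.bin);

      Node& nd = nodes_[lf.node_id];
      nd.feat = sp.feat; nd.bin = sp.bin; nd.gain = sp.gain;
      feat_gain[sp.feat] += sp.gain;

      Leaf L{lf.lo, mid, lf.depth + 1, sp.gl, sp.hl, (int)nodes_.size(), Split()};
      nodes_.push_back(Node());
      Leaf R{mid, lf.hi, lf.depth + 1, lf.gsum - sp.gl, lf.hsum - sp.hl,
             (int)nodes_.size(), Split()};
      nodes_.push_back(Node());
      nodes_[lf.node_id].left = L.node_id;
      nodes_[lf.node_id].right = R.node_id;

      L.best = find_split(L, g, h, feats);
      R.best = find_split(R, g, h, feats);
      open.push_back(L);
      open.push_back(R);
      ++n_leaves;
      if (par_.leafwise && n_leaves >= par_.num_leaves) break;
    }

    for (const Leaf& lf : open)
      nodes_[lf.node_id].value = leaf_value(lf.gsum, lf.hsum);
    return nodes_;
  }

private:
  double leaf_value(double gsum, double hsum) const {
    return -par_.learning_rate * gsum / (hsum + par_.lambda);
  }

  inline uint8_t bin_at(int row, int feat) const {
    return bins_[(size_t)feat * n_ + row];
  }

  int partition(int lo, int hi, int feat, int bin) {
    // stable partition keeps row order deterministic
    std::stable_partition(idx_.begin() + lo, idx_.begin() + hi,
                          [&](int r) { return bin_at(r, feat) <= bin; });
    int mid = lo;
    while (mid < hi && bin_at(idx_[mid], feat) <= bin) ++mid;
    return mid;
  }

  Split find_split(const Leaf& lf, const std::vector<double>& g,
                   const std::vector<double>& h, const std::vector<int>& feats) {
    Split best;
    int cnt = lf.hi - lf.lo;
    if (cnt < 2 * par_.min_data) return best;
    double parent = lf.gsum * lf.gsum / (lf.hsum + par_.lambda);

    std::vector<double> hg, hh;
    std::vector<int> hc;
    for (int f : feats) {
      int nb = nbins_[f];
      if (nb < 2) continue;
      hg.assign(nb, 0.0); hh.assign(nb, 0.0); hc.assign(nb, 0);
      for (int i = lf.lo; i < lf.hi; ++i) {
        int r = idx_[i];
        int b = bin_at(r, f);
        hg[b] += g[r]; hh[b] += h[r]; ++hc[b];
      }
      double gl = 0.0, hl = 0.0; int nl = 0;
      for (int b = 0; b < nb - 1; ++b) {
        gl += hg[b]; hl += hh[b]; nl += hc[b];
        if (nl < par_.min_data || hl < par_.min_hess) continue;
        int nr = cnt - nl;
        double hr = lf.hsum - hl;
        if (nr < par_.min_data || hr < par_.min_hess) break;
        double gr = lf.gsum - gl;
        double gain = 0.5 * (gl * gl / (hl + par_.lambda) +
                             gr * gr / (hr + par_.lambda) - parent);
        if (gain > best.gain + 1e-12) {
          best.gain = gain; best.feat = f; best.bin = b;
          best.gl = gl; best.hl = hl; best.nl = nl;
        }
      }
    }
    return best;
  }

  const std::vector<uint8_t>& bins_;
  int n_, p_;
  const std::vector<int>& nbins_;
  const Params& par_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;
};

// quantile bin edges for one feature; bin(x) = #\{e in edges : e <= x\}
std::vector<double> make_edges(const double* x, int n, int max_bins) {
  std::vector<double> v(x, x + n);
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  std::vector<double> edges;
  int nu = (int)v.size();
  if (nu <= 1) return edges;
  if (nu <= max_bins) {
    for (int i = 1; i < nu; ++i) edges.push_back((v[i - 1] + v[i]) / 2.0);
  } else {
    for (int b = 1; b < max_bins; ++b) {
      int i = (int)((double)b * nu / max_bins);
      if (i < 1) i = 1;
      if (i > nu - 1) i = nu - 1;
      double e = (v[i - 1] + v[i]) / 2.0;
      if (edges.empty() || e > edges.back()) edges.push_back(e);
    }
  }
  return edges;
}

inline int bin_value(double x, const std::vector<double>& edges) {
  return (int)(std::upper_bound(edges.begin(), edges.end(), x) - edges.begin());
}

double tree_predict_row(const std::vector<double>& feat, const std::vector<double>& bin,
                        const std::vector<double>& left, const std::vector<double>& right,
                        const std::vector<double>& value, const std::vector<int>& binned_row) {
  int nd = 0;
  while (feat[nd] >= 0) {
    int f = (int)feat[nd];
    nd = (binned_row[f] <= (int)bin[nd]) ? (int)left[nd] : (int)right[nd];
  }
  return value[nd];
}

std::vector<int> all_feats(int p) {
  std::vector<int> f(p);
  for (int i = 0; i < p; ++i) f[i] = i;
  return f;
}

Params read_params(const List& params) {
  Params p;
  p.nrounds = as<int>(params["nrounds"]);
  p.num_leaves = as<int>(params["num_leaves"]);
  p.max_depth = as<int>(params["max_depth"]);
  p.min_data = as<int>(params["min_data_in_leaf"]);
  p.max_bins = as<int>(params["max_bins"]);
  p.bagging_freq = as<int>(params["bagging_freq"]);
  p.learning_rate = as<double>(params["learning_rate"]);
  p.lambda = as<double>(params["lambda_l2"]);
  p.min_hess = as<double>(params["min_sum_hessian"]);
  p.bagging_fraction = as<double>(params["bagging_fraction"]);
  p.feature_fraction = as<double>(params["feature_fraction"]);
  p.leafwise = as<std::string>(params["growth"]) == "leafwise";
  p.seed = (uint64_t)as<double>(params["seed"]);
  return p;
}

} // namespace

// [[Rcpp::export(name = ".gbt_train_cpp")]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, List params) {
  const int n = X.nrow(), p = X.ncol();
  Params par = read_params(params);

  // bin the training matrix
  std::vector<std::vector<double> > edges(p);
  std::vector<int> nbins(p);
  std::vector<uint8_t> bins((size_t)n * p);
  for (int j = 0; j < p; ++j) {
    edges[j] = make_edges(&X(0, j), n, par.max_bins);
    nbins[j] = (int)edges[j].size() + 1;
    for (int i = 0; i < n; ++i)
      bins[(size_t)j * n + i] = (uint8_t)bin_value(X(i, j), edges[j]);
  }

  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<double> score(n, base), g(n), h(n), feat_gain(p, 0.0);
  Rng rng(par.seed * 2654435761ULL + 1ULL);

  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) all_rows[i] = i;
  std::vector<int> bag = all_rows;

  Builder builder(bins, n, p, nbins, par);
  List trees(par.nrounds);
  int n_feat_sub = std::max(1, (int)std::floor(p * par.feature_fraction + 1e-9));
  int n_bag = std::max(2 * par.min_data,
                       (int)std::floor(n * par.bagging_fraction + 1e-9));
  n_bag = std::min(n_bag, n);

  for (int round = 0; round < par.nrounds; ++round) {
    for (int i = 0; i < n; ++i) {
      double pr = 1.0 / (1.0 + std::exp(-score[i]));
      g[i] = pr - y[i];
      h[i] = std::max(pr * (1.0 - pr), 1e-16);
    }
    if (par.bagging_fraction < 1.0 && par.bagging_freq > 0 &&
        round % par.bagging_freq == 0) {
      std::vector<int> rows = sample_k(n, n_bag, rng);
      bag = rows;
    }
    std::vector<int> feats = (n_feat_sub < p) ? sample_k(p, n_feat_sub, rng) : all_feats(p);

    std::vector<Node> nodes = builder.build(g, h, bag, feats, feat_gain);

    // flatten and update scores for all rows
    int m = (int)nodes.size();
    NumericVector tfeat(m), tbin(m), tleft(m), tright(m), tvalue(m);
    for (int k = 0; k < m; ++k) {
      tfeat[k] = nodes[k].feat; tbin[k] = nodes[k].bin;
      tleft[k] = nodes[k].left; tright[k] = nodes[k].right;
      tvalue[k] = nodes[k].value;
    }
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (nodes[nd].feat >= 0) {
        int f = nodes[nd].feat;
        nd = (bins[(size_t)f * n + i] <= (uint8_t)nodes[nd].bin)
               ? nodes[nd].left : nodes[nd].right;
      }
      score[i] += nodes[nd].value;
    }
    trees[round] = List::create(_["feat"] = tfeat, _["bin"] = tbin,
                                _["left"] = tleft, _["right"] = tright,
                                _["value"] = tvalue);
  }

  List edg(p);
  for (int j = 0; j < p; ++j) edg[j] = NumericVector(edges[j].begin(), edges[j].end());

  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["edges"] = edg,
                      _["feature_gain"] = NumericVector(feat_gain.begin(), feat_gain.end()));
}

// [[Rcpp::export(name = ".gbt_predict_cpp")]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  const int n = X.nrow(), p = X.ncol();
  List edg = model["edges"];
  List trees = model["trees"];
  const double base = as<double>(model["base_score"]);

  std::vector<std::vector<double> > edges(p);
  for (int j = 0; j < p; ++j) edges[j] = as<std::vector<double> >(edg[j]);

  // pre-extract trees
  int T = trees.size();
  std::vector<std::vector<double> > tf(T), tb(T), tl(T), tr(T), tv(T);
  for (int t = 0; t < T; ++t) {
    List tree = trees[t];
    tf[t] = as<std::vector<double> >(tree["feat"]);
    tb[t] = as<std::vector<double> >(tree["bin"]);
    tl[t] = as<std::vector<double> >(tree["left"]);
    tr[t] = as<std::vector<double> >(tree["right"]);
    tv[t] = as<std::vector<double> >(tree["value"]);
  }

  NumericVector out(n);
  std::vector<int> row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = bin_value(X(i, j), edges[j]);
    double s = base;
    for (int t = 0; t < T; ++t)
      s += tree_predict_row(tf[t], tb[t], tl[t], tr[t], tv[t], row);
    out[i] = 1.0 / (1.0 + std::exp(-s));
  }
  return out;
}
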