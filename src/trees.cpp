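// Regression-tree ensembles: CART-style greedy trees (decision tree,
// Random Forest) and trees split at uniform-random thresholds on random
// feature subsets (Extremely Randomized Trees). Hand-rolled uniform
// deviates on top of std::mt19937 keep results byte-identical across
// standard library implementations.
#include <Rcpp.h>
#include <vector>
#include <random>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
    std::mt19937 gen;
    explicit Rng(uint32_t seed) : gen(seed) {}
    // uniform in [0, 1) with 53-bit resolution, engine-defined only
    double unif() {
        const uint64_t a = gen() >> 5, b = gen() >> 6;
        return (a * 67108864.0 + b) / 9007199254740992.0;
    }
    int below(int n) { return (int) (unif() * n) % n; } // 0..n-1
};

struct TreeBuilder {
    const NumericMatrix& X;
    const NumericVector& y;
    int p, mtry, min_leaf;
    bool random_threshold;
    Rng rng;

    std::vector<int> feature;
    std::vector<double> threshold;
    std::vector<int> left, right;
    std::vector<double> value;
    std::vector<double>& importance; // accumulated SSE decrease per feature

    std::vector<int> idx;          // row indices, partitioned in place
    std::vector<int> feat_pool;    // scratch for mtry sampling

    TreeBuilder(const NumericMatrix& X_, const NumericVector& y_, int mtry_,
                int min_leaf_, bool random_threshold_, uint32_t seed,
                std::vector<double>& imp)
        : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), min_leaf(min_leaf_),
          random_threshold(random_threshold_), rng(seed), importance(imp) {
        feat_pool.resize(p);
        for (int j = 0; j < p; ++j) feat_pool[j] = j;
    }

    int new_node() {
        feature.push_back(-1); threshold.push_back(NA_REAL);
        left.push_back(-1); right.push_back(-1); value.push_back(0.0);
        return (int) feature.size() - 1;
    }

    double node_sse(int lo, int hi, double& sum_out) const {
        double s = 0, ss = 0;
        for (int i = lo; i < hi; ++i) { const double v = y[idx[i]]; s += v; ss += v * v; }
        sum_out = s;
        const int n = hi - lo;
        return ss - s * s / n;
    }

    int build(int lo, int hi) {
        const int node = new_node();
        const int n = hi - lo;
        double sum;
        const double sse = node_sse(lo, hi, sum);
        value[node] = sum / n;
        if (n < 2 * min_leaf || sse <= 1e-12 * n) return node;

        // draw mtry candidate features (partial Fisher-Yates)
        const int m = std::min(mtry, p);
        for (int j = 0; j < m; ++j)
            std::swap(feat_pool[j], feat_pool[j + rng.below(p - j)]);

        int best_f = -1;
        double best_thr = 0, best_gain = 0;
        std::vector<std::pair<double, double>> xy;

        for (int j = 0; j < m; ++j) {
            const int f = feat_pool[j];
            double xmin = X(idx[lo], f), xmax = xmin;
            for (int i = lo + 1; i < hi; ++i) {
                const double v = X(idx[i], f);
                if (v < xmin) xmin = v;
                if (v > xmax) xmax = v;
            }
            if (!(xmax > xmin)) continue;

            if (random_threshold) {
                const double thr = xmin + rng.unif() * (xmax - xmin);
                double sl = 0, ssl = 0; int nl = 0;
                for (int i = lo; i < hi; ++i) {
                    if (X(idx[i], f) < thr) {
                        const double v = y[idx[i]]; sl += v; ssl += v * v; ++nl;
                    }
                }
                const int nr = n - nl;
                if (nl < min_leaf || nr < min_leaf) continue;
                const double sr = sum - sl;
                const double ssr = (sse + sum * sum / n) - ssl;
                const double gain = sse - (ssl - sl * sl / nl) - (ssr - sr * sr / nr);
                if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = thr; }
            } else {
                xy.clear(); xy.reserve(n);
                for (int i = lo; i < hi; ++i) xy.emplace_back(X(idx[i], f), y[idx[i]]);
                std::sort(xy.begin(), xy.end());
                double sl = 0, ssl = 0;
                for (int i = 0; i < n - 1; ++i) {
                    sl += xy[i].second; ssl += xy[i].second * xy[i].second;
                    const int nl = i + 1, nr = n - nl;
                    if (nl < min_leaf || nr < min_leaf) continue;
                    if (!(xy[i + 1].first > xy[i].first)) continue;
                    const double sr = sum - sl;
                    double ssr = 0; // sse via total sumsq
                    // total sum of squares for the node:
                    // reuse: sse = ss_total - sum^2/n  =>  ss_total = sse + sum^2/n
                    ssr = (sse + sum * sum / n) - ssl;
                    const double gain = sse - (ssl - sl * sl / nl) - (ssr - sr * sr / nr);
                    if (gain > best_gain) {
                        best_gain = gain; best_f = f;
                        best_thr = xy[i].first + 0.5 * (xy[i + 1].first - xy[i].first);
                    }
                }
            }
        }

        if (best_f < 0 || best_gain <= 0) return node;

        // partition idx in place: left = x < thr, matching prediction
        int mid = lo;
        for (int i = lo; i < hi; ++i) {
            if (X(idx[i], best_f) < best_thr) std::swap(idx[i], idx[mid++]);
        }
        if (mid == lo || mid == hi) return node; // degenerate, keep as leaf

        feature[node] = best_f;
        threshold[node] = best_thr;
        importance[best_f] += best_gain;
        left[node] = build(lo, mid);
        right[node] = build(mid, hi);
        return node;
    }
};

double predict_one(const IntegerVector& feature, const NumericVector& threshold,
                   const IntegerVector& left, const IntegerVector& right,
                   const NumericVector& value, const NumericMatrix& X, int row) {
    int node = 0;
    while (feature[node] >= 0) {
        node = (X(row, feature[node]) < threshold[node]) ? left[node] : right[node];
    }
    return value[node];
}

} // namespace

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, int n_trees, int mtry,
                     int min_leaf, bool random_threshold, bool bootstrap,
                     int seed) {
    const int n = X.nrow(), p = X.ncol();
    if (n < 1) stop("empty training matrix");
    if (min_leaf < 1) stop("min_samples_leaf must be >= 1");
    List trees(n_trees);
    std::vector<double> importance(p, 0.0);

    for (int t = 0; t < n_trees; ++t) {
        const uint32_t tree_seed = (uint32_t) seed + 2654435761u * (uint32_t) (t + 1);
        TreeBuilder tb(X, y, mtry, min_leaf, random_threshold, tree_seed, importance);
        tb.idx.resize(n);
        if (bootstrap) {
            Rng brng(tree_seed ^ 0x9e3779b9u);
            for (int i = 0; i < n; ++i) tb.idx[i] = brng.below(n);
        } else {
            for (int i = 0; i < n; ++i) tb.idx[i] = i;
        }
        tb.build(0, n);
        trees[t] = List::create(
            _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
            _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
            _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
            _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
            _["value"] = NumericVector(tb.value.begin(), tb.value.end()));
    }

    NumericVector imp(importance.begin(), importance.end());
    const double tot = Rcpp::sum(imp);
    if (tot > 0) imp = imp / tot;
    return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
    const int n = X.nrow();
    const int T = trees.size();
    NumericVector out(n, 0.0);
    for (int t = 0; t < T; ++t) {
        List tr = trees[t];
        IntegerVector feature = tr["feature"];
        NumericVector threshold = tr["threshold"];
        IntegerVector left = tr["left"], right = tr["right"];
        NumericVector value = tr["value"];
        for (int i = 0; i < n; ++i)
            out[i] += predict_one(feature, threshold, left, right, value, X, i);
    }
    return out / (double) T;
}
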