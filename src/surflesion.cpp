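#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---- connected components on a masked mesh graph (union-find) --------------
//
// Vertices are 1-based; edges is the undirected edge list of the full mesh.
// Unmasked vertices get label 0; masked vertices get component labels
// 1..k, numbered by the smallest vertex index they contain (deterministic).

static int uf_find(std::vector<int> &parent, int x) {
    while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
    }
    return x;
}

// [[Rcpp::export]]
IntegerVector cc_masked(int nv, IntegerVector edge_from, IntegerVector edge_to,
                        LogicalVector mask) {
    std::vector<int> parent(nv + 1);
    for (int i = 0; i <= nv; ++i) parent[i] = i;
    int ne = edge_from.size();
    for (int e = 0; e < ne; ++e) {
        int a = edge_from[e], b = edge_to[e];
        if (mask[a - 1] && mask[b - 1]) {
            int ra = uf_find(parent, a), rb = uf_find(parent, b);
            if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
        }
    }
    IntegerVector lab(nv, 0);
    std::vector<int> compid(nv + 1, 0);
    int k = 0;
    for (int v = 1; v <= nv; ++v) {
        if (!mask[v - 1]) continue;
        int r = uf_find(parent, v);
        if (compid[r] == 0) compid[r] = ++k;  // roots are minimal members
        lab[v - 1] = compid[r];
    }
    return lab;
}

// ---- isolation forest ------------------------------------------------------
//
// Standard isolation forest: each tree is grown on a subsample of size psi
// by splitting a uniformly chosen feature at a uniform point between the
// node minimum and maximum, until singleton nodes or the depth limit
// ceil(log2(psi)) is reached. Anomaly score of a point is
// 2^(-E[h(x)]/c(psi)) with the usual average-path-length normalisation
// c(n) = 2 H(n-1) - 2 (n-1)/n. Uses the R RNG so results follow set.seed().

static double avg_path_length(double n) {
    if (n <= 1.0) return 0.0;
    if (n == 2.0) return 1.0;
    const double euler = 0.5772156649015329;
    return 2.0 * (std::log(n - 1.0) + euler) - 2.0 * (n - 1.0) / n;
}

struct IsoTree {
    std::vector<int> feature;   // -1 for external node
    std::vector<double> split;
    std::vector<int> left, right, size;
};

static int iso_build(const NumericMatrix &X, std::vector<int> &idx,
                     int lo, int hi, int depth, int max_depth, IsoTree &tree) {
    int node = (int) tree.feature.size();
    tree.feature.push_back(-1);
    tree.split.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.size.push_back(hi - lo);
    int n = hi - lo;
    if (n <= 1 || depth >= max_depth) return node;

    int p = X.ncol();
    // pick a feature with spread; try a few random features, then scan
    int q = -1;
    double mn = 0.0, mx = 0.0;
    for (int attempt = 0; attempt < p; ++attempt) {
        int cand = (int) std::floor(unif_rand() * p);
        if (cand >= p) cand = p - 1;
        double cmn = X(idx[lo], cand), cmx = cmn;
        for (int i = lo + 1; i < hi; ++i) {
            double v = X(idx[i], cand);
            if (v < cmn) cmn = v;
            if (v > cmx) cmx = v;
        }
        if (cmx > cmn) { q = cand; mn = cmn; mx = cmx; break; }
    }
    if (q < 0) return node;  // all candidate features constant: external

    double s = mn + unif_rand() * (mx - mn);
    // partition idx[lo..hi) by X[, q] < s
    int i = lo, j = hi - 1;
    while (i <= j) {
        if (X(idx[i], q) < s) { ++i; }
        else { std::swap(idx[i], idx[j]); --j; }
    }
    int mid = i;
    if (mid == lo || mid == hi) return node;  // degenerate split: external

    tree.feature[node] = q;
    tree.split[node] = s;
    int l = iso_build(X, idx, lo, mid, depth + 1, max_depth, tree);
    int r = iso_build(X, idx, mid, hi, depth + 1, max_depth, tree);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
}

// [[Rcpp::export]]
List iso_fit(NumericMatrix X, int n_trees, int psi) {
    int n = X.nrow();
    if (psi > n) psi = n;
    List forest(n_trees);
    for (int t = 0; t < n_trees; ++t) {
        // subsample psi rows without replacement (partial Fisher-Yates)
        std::vector<int> pool(n);
        for (int i = 0; i < n; ++i) pool[i] = i;
        std::vector<int> idx(psi);
        for (int i = 0; i < psi; ++i) {
            int j = i + (int) std::floor(unif_rand() * (n - i));
            if (j >= n) j = n - 1;
            std::swap(pool[i], pool[j]);
            idx[i] = pool[i];
        }
        int max_depth = (int) std::ceil(std::log2((double) std::max(psi, 2)));
        IsoTree tree;
        iso_build(X, idx, 0, psi, 0, max_depth, tree);
        forest[t] = List::create(
            _["feature"] = wrap(tree.feature),
            _["split"] = wrap(tree.split),
            _["left"] = wrap(tree.left),
            _["right"] = wrap(tree.right),
            _["size"] = wrap(tree.size));
    }
    return List::create(_["trees"] = forest, _["psi"] = psi,
                        _["n_trees"] = n_trees, _["n_features"] = X.ncol());
}

// [[Rcpp::export]]
NumericVector iso_score(List model, NumericMatrix X) {
    List forest = model["trees"];
    int psi = as<int>(model["psi"]);
    int n_trees = forest.size();
    int n = X.nrow();
    NumericVector path(n, 0.0);
    for (int t = 0; t < n_trees; ++t) {
        List tr = forest[t];
        IntegerVector feature = tr["feature"];
        NumericVector split = tr["split"];
        IntegerVector left = tr["left"];
        IntegerVector right = tr["right"];
        IntegerVector size = tr["size"];
        for (int i = 0; i < n; ++i) {
            int node = 0, depth = 0;
            while (feature[node] >= 0) {
                node = (X(i, feature[node]) < split[node]) ? left[node]
                                                           : right[node];
                ++depth;
            }
            path[i] += depth + avg_path_length((double) size[node]);
        }
    }
    double cpsi = avg_path_length((double) psi);
    NumericVector score(n);
    for (int i = 0; i < n; ++i)
        score[i] = std::pow(2.0, -(path[i] / n_trees) / cpsi);
    return score;
}
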