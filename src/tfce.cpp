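#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// 3D grid neighbourhood offsets (6- or 26-connectivity).
static std::vector<std::array<int,3>> neighbour_offsets(int connectivity) {
    std::vector<std::array<int,3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                int manhattan = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (connectivity == 6 && manhattan != 1) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

struct UnionFind {
    std::vector<int> parent, sz;
    UnionFind(int n) : parent(n, -1), sz(n, 0) {}
    void make_set(int v) { parent[v] = v; sz[v] = 1; }
    int find(int v) {
        int root = v;
        while (parent[root] != root) root = parent[root];
        while (parent[v] != root) { int next = parent[v]; parent[v] = root; v = next; }
        return root;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (sz[a] < sz[b]) std::swap(a, b);
        parent[b] = a; sz[a] += sz[b];
    }
};

// Threshold-free cluster enhancement of a non-negative statistic map.
// Discrete sum over thresholds h = dh, 2*dh, ..., floor(max/dh)*dh of
// extent(v, h)^E * h^H * dh, where extent is the size of the connected
// component of {x >= h} containing v. Voxels are activated in descending
// order so each threshold step only merges components incrementally; the
// result is exactly the brute-force discrete sum.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector x, IntegerVector dims, double H, double E,
                       double dh, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    if (x.size() != n) stop("map length does not match dims");
    if (dh <= 0) stop("dh must be positive");
    NumericVector out(n);
    double mx = 0;
    for (int i = 0; i < n; ++i) if (x[i] > mx) mx = x[i];
    if (mx <= 0) return out;
    const int K = (int)std::floor(mx / dh + 1e-9);
    if (K < 1) return out;

    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::sort(order.begin(), order.end(),
              [&](int a, int b) { return x[a] > x[b]; });

    auto off = neighbour_offsets(connectivity);
    UnionFind uf(n);
    int ptr = 0;  // voxels order[0..ptr) are active
    for (int k = K; k >= 1; --k) {
        const double h = k * dh;
        while (ptr < n && x[order[ptr]] >= h - 1e-12) {
            const int v = order[ptr];
            uf.make_set(v);
            const int vz = v / (nx * ny), vy = (v / nx) % ny, vx = v % nx;
            for (const auto &d : off) {
                const int ux = vx + d[0], uy = vy + d[1], uz = vz + d[2];
                if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
                    continue;
                const int u = ux + nx * (uy + ny * uz);
                if (uf.parent[u] >= 0) uf.unite(u, v);
            }
            ++ptr;
        }
        const double hH = std::pow(h, H) * dh;
        for (int i = 0; i < ptr; ++i) {
            const int v = order[i];
            out[v] += std::pow((double)uf.sz[uf.find(v)], E) * hH;
        }
    }
    return out;
}

// Label connected components of a logical mask; 0 outside the mask,
// components numbered 1..L in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");
    IntegerVector labels(n, 0);
    auto off = neighbour_offsets(connectivity);
    int next = 0;
    std::vector<int> stack;
    for (int s = 0; s < n; ++s) {
        if (!mask[s] || labels[s] != 0) continue;
        labels[s] = ++next;
        stack.push_back(s);
        while (!stack.empty()) {
            const int v = stack.back(); stack.pop_back();
            const int vz = v / (nx * ny), vy = (v / nx) % ny, vx = v % nx;
            for (const auto &d : off) {
                const int ux = vx + d[0], uy = vy + d[1], uz = vz + d[2];
                if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
                    continue;
                const int u = ux + nx * (uy + ny * uz);
                if (mask[u] && labels[u] == 0) { labels[u] = next; stack.push_back(u); }
            }
        }
    }
    return labels;
}
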