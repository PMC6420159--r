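// Maximal information coefficient via grid search: for every grid shape
// (nx, ny) with nx * ny <= B(n) = n^alpha, one axis is partitioned into
// equal-frequency bins (ties kept together) and the other axis partition
// is optimized by dynamic programming over candidate cut points
// (superclumps of tied/adjacent values).  The normalized maximum over
// shapes and both axis orientations is returned, which makes the
// statistic symmetric in its arguments by construction.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// equal-frequency binning of sorted values into <= nb bins, equal values
// never split; returns bin index per sorted position
static std::vector<int> equiBins(const std::vector<double>& sorted, int nb) {
    int n = sorted.size();
    std::vector<int> bin(n);
    for (int i = 0; i < n; ++i) {
        int b = (int)((long long)i * nb / n);
        if (i > 0 && sorted[i] == sorted[i - 1]) b = bin[i - 1];
        else if (i > 0 && b < bin[i - 1]) b = bin[i - 1];
        bin[i] = b;
    }
    return bin;
}

// DP: maximize sum over x-bins of sum_q (c_bq/n) * log2(c_bq / r_b),
// given cumulative y-bin counts at superclump boundaries.
// cum has T+1 rows (boundary 0..T) and ny columns.
// returns best objective for exactly l bins, l = 1..lmax (index l-1)
static std::vector<double> dpOptimize(const std::vector<std::vector<double> >& cum,
                                      int ny, int lmax, int n) {
    int T = cum.size() - 1;
    const double NEG = -1e100;
    // g(s, t): contribution of an x-bin spanning clumps (s, t]
    std::vector<std::vector<double> > g(T + 1, std::vector<double>(T + 1, 0.0));
    for (int s = 0; s < T; ++s)
        for (int t = s + 1; t <= T; ++t) {
            double tot = 0.0, val = 0.0;
            for (int q = 0; q < ny; ++q) tot += cum[t][q] - cum[s][q];
            if (tot > 0) {
                for (int q = 0; q < ny; ++q) {
                    double c = cum[t][q] - cum[s][q];
                    if (c > 0) val += (c / n) * std::log2(c / tot);
                }
            }
            g[s][t] = val;
        }
    std::vector<std::vector<double> > D(T + 1, std::vector<double>(lmax + 1, NEG));
    D[0][0] = 0.0;
    for (int t = 1; t <= T; ++t)
        for (int l = 1; l <= std::min(t, lmax); ++l)
            for (int s = l - 1; s < t; ++s)
                if (D[s][l - 1] > NEG / 2)
                    D[t][l] = std::max(D[t][l], D[s][l - 1] + g[s][t]);
    std::vector<double> best(lmax, NEG);
    for (int l = 1; l <= lmax; ++l) best[l - 1] = D[T][l];
    return best;
}

// one orientation: y equipartitioned into ny bins, x-axis optimized.
// fills scores[nx] = best MI (bits) for nx x-bins, nx = 2..nxMax
static void axisScores(const std::vector<double>& x,
                       const std::vector<double>& y,
                       int ny, int nxMax, int clumpFactor,
                       std::vector<double>& scores) {
    int n = x.size();
    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    // y bins by rank
    std::vector<int> ordY = ord;
    std::sort(ordY.begin(), ordY.end(),
              [&](int a, int b) { return y[a] < y[b]; });
    std::vector<double> ySorted(n);
    for (int i = 0; i < n; ++i) ySorted[i] = y[ordY[i]];
    std::vector<int> ybinSorted = equiBins(ySorted, ny);
    int nyEff = ybinSorted[n - 1] + 1;
    std::vector<int> ybin(n);
    for (int i = 0; i < n; ++i) ybin[ordY[i]] = ybinSorted[i];
    // H(Y) in bits
    std::vector<double> m(nyEff, 0.0);
    for (int i = 0; i < n; ++i) m[ybin[i]] += 1.0;
    double hy = 0.0;
    for (int q = 0; q < nyEff; ++q)
        if (m[q] > 0) hy -= (m[q] / n) * std::log2(m[q] / n);
    // order by x, build clumps at distinct x values
    std::vector<int> ordX = ord;
    std::sort(ordX.begin(), ordX.end(),
              [&](int a, int b) { return x[a] < x[b]; });
    std::vector<int> clumpEnd;  // exclusive end index (in ordX) per clump
    for (int i = 1; i <= n; ++i)
        if (i == n || x[ordX[i]] != x[ordX[i - 1]]) clumpEnd.push_back(i);
    // merge into superclumps of roughly n / (clumpFactor * nxMax)
    int targetClumps = std::max(2, clumpFactor * nxMax);
    int targetSize = std::max(1, (int)std::ceil((double)n / targetClumps));
    std::vector<int> superEnd;
    int last = 0;
    for (size_t c = 0; c < clumpEnd.size(); ++c) {
        if (clumpEnd[c] - last >= targetSize || c + 1 == clumpEnd.size()) {
            superEnd.push_back(clumpEnd[c]);
            last = clumpEnd[c];
        }
    }
    int T = superEnd.size();
    std::vector<std::vector<double> > cum(T + 1, std::vector<double>(nyEff, 0.0));
    int pos = 0;
    for (int t = 0; t < T; ++t) {
        cum[t + 1] = cum[t];
        for (; pos < superEnd[t]; ++pos) cum[t + 1][ybin[ordX[pos]]] += 1.0;
    }
    std::vector<double> d = dpOptimize(cum, nyEff, nxMax, n);
    for (int nx = 2; nx <= nxMax; ++nx) {
        double v = d[nx - 1];
        if (v > -1e99) {
            double mi = hy + v;  // = H(Y) - H(Y|X-partition)
            if (mi > scores[nx]) scores[nx] = mi;
        }
    }
}

// [[Rcpp::export(name = ".micCpp")]]
double micCpp(NumericVector xr, NumericVector yr, double alpha = 0.6,
              int clumpFactor = 5) {
    int n = xr.size();
    if (n < 4 || yr.size() != n) return NA_REAL;
    std::vector<double> x(xr.begin(), xr.end()), y(yr.begin(), yr.end());
    int B = std::max(4, (int)std::floor(std::pow((double)n, alpha)));
    double mic = 0.0;
    for (int ny = 2; ny <= B / 2; ++ny) {
        int nxMax = B / ny;
        if (nxMax < 2) break;
        std::vector<double> sXopt(nxMax + 1, -1.0), sYopt(nxMax + 1, -1.0);
        axisScores(x, y, ny, nxMax, clumpFactor, sXopt);  // x optimized
        axisScores(y, x, ny, nxMax, clumpFactor, sYopt);  // y optimized
        for (int nx = 2; nx <= nxMax; ++nx) {
            double denom = std::log2((double)std::min(nx, ny));
            double v = std::max(sXopt[nx], sYopt[nx]) / denom;
            if (v > mic) mic = v;
        }
    }
    return std::min(mic, 1.0);
}
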