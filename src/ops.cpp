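// Compiled kernels for the nucleus-segmentation pipeline: flat-disk grayscale
// morphology, geodesic reconstruction, reflect-border convolution, the direct
// bilateral filter, and priority-flood marker-controlled watershed.
//
// Conventions shared with the R layer:
//  * images are H x W numeric matrices, row = y (down), col = x (right);
//  * dilation/erosion at the border use in-image neighbours only
//    (equivalent to padding with -Inf / +Inf);
//  * convolution and the bilateral filter use half-sample symmetric
//    reflection at the border (edge pixel repeated);
//  * all tie-breaks are (value, row, col) lexicographic so every operator is
//    bit-deterministic.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

static std::vector<std::pair<int, int> > disk_offsets(int radius) {
    std::vector<std::pair<int, int> > off;
    for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx)
            if (dy * dy + dx * dx <= radius * radius)
                off.push_back(std::make_pair(dy, dx));
    return off;
}

// half-sample symmetric reflection of index i into [0, n)
static inline int reflect_idx(int i, int n) {
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - 1 - i;
    }
    return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_disk_dilate(NumericMatrix img, int radius) {
    int H = img.nrow(), W = img.ncol();
    std::vector<std::pair<int, int> > off = disk_offsets(radius);
    NumericMatrix out(H, W);
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            double m = R_NegInf;
            for (size_t k = 0; k < off.size(); ++k) {
                int ii = i + off[k].first, jj = j + off[k].second;
                if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
                double v = img(ii, jj);
                if (v > m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disk_erode(NumericMatrix img, int radius) {
    int H = img.nrow(), W = img.ncol();
    std::vector<std::pair<int, int> > off = disk_offsets(radius);
    NumericMatrix out(H, W);
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            double m = R_PosInf;
            for (size_t k = 0; k < off.size(); ++k) {
                int ii = i + off[k].first, jj = j + off[k].second;
                if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
                double v = img(ii, jj);
                if (v < m) m = v;
            }
            out(i, j) = m;
        }
    }
    return out;
}

// Iterate the geodesic step (dilate then clip by mask, or erode then floor by
// mask) until two successive iterates are identical.  `dilation` selects the
// side.  Returns the fixed point and the number of geodesic steps taken.
// [[Rcpp::export]]
List cpp_reconstruct(NumericMatrix marker, NumericMatrix mask, int radius,
                     bool dilation) {
    int H = marker.nrow(), W = marker.ncol();
    long max_iter = (long)H * (long)W;
    NumericMatrix f = clone(marker);
    std::vector<std::pair<int, int> > off = disk_offsets(radius);
    long iter = 0;
    for (;;) {
        ++iter;
        if (iter > max_iter)
            stop("reconstruction failed to stabilise within H*W iterations");
        bool changed = false;
        NumericMatrix nf(H, W);
        for (int j = 0; j < W; ++j) {
            for (int i = 0; i < H; ++i) {
                double m = dilation ? R_NegInf : R_PosInf;
                for (size_t k = 0; k < off.size(); ++k) {
                    int ii = i + off[k].first, jj = j + off[k].second;
                    if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
                    double v = f(ii, jj);
                    if (dilation ? (v > m) : (v < m)) m = v;
                }
                double g = mask(i, j);
                double v = dilation ? std::min(m, g) : std::max(m, g);
                nf(i, j) = v;
                if (v != f(i, j)) changed = true;
            }
        }
        f = nf;
        if (!changed) break;
    }
    return List::create(Named("image") = f, Named("iterations") = (double)iter);
}

// Correlation with reflect border; kernels here are symmetric so this equals
// convolution.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_reflect(NumericMatrix img, NumericMatrix kernel) {
    int H = img.nrow(), W = img.ncol();
    int kh = kernel.nrow(), kw = kernel.ncol();
    int rh = kh / 2, rw = kw / 2;
    NumericMatrix out(H, W);
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            double s = 0.0;
            for (int dj = -rw; dj <= rw; ++dj) {
                int jj = reflect_idx(j + dj, W);
                for (int di = -rh; di <= rh; ++di) {
                    int ii = reflect_idx(i + di, H);
                    s += img(ii, jj) * kernel(di + rh, dj + rw);
                }
            }
            out(i, j) = s;
        }
    }
    return out;
}

// Direct bilateral filter: square window of half-width `radius`, spatial
// Gaussian of scale sigma_s, range Gaussian of scale sigma_r, reflect border.
// [[Rcpp::export]]
NumericMatrix cpp_bilateral(NumericMatrix img, double sigma_s, double sigma_r,
                            int radius) {
    int H = img.nrow(), W = img.ncol();
    double is2 = 1.0 / (2.0 * sigma_s * sigma_s);
    double ir2 = 1.0 / (2.0 * sigma_r * sigma_r);
    NumericMatrix out(H, W);
    for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
            double ip = img(i, j);
            double wsum = 0.0, vsum = 0.0;
            for (int dj = -radius; dj <= radius; ++dj) {
                int jj = reflect_idx(j + dj, W);
                for (int di = -radius; di <= radius; ++di) {
                    int ii = reflect_idx(i + di, H);
                    double iq = img(ii, jj);
                    double d = ip - iq;
                    double w = std::exp(-(double)(di * di + dj * dj) * is2)
                             * std::exp(-d * d * ir2);
                    wsum += w;
                    vsum += w * iq;
                }
            }
            out(i, j) = vsum / wsum;
        }
    }
    return out;
}

// Marker-controlled watershed by priority flooding.  `seeds` uses -1 for
// unseeded pixels, 0 for the background source and 1..N for foreground
// markers.  Pixels are labelled when first reached; the queue pops in
// ascending (relief, row, col) order, so flooding is fully deterministic and
// ridge pixels go to the region that reaches them first.
// [[Rcpp::export]]
IntegerMatrix cpp_marker_watershed(NumericMatrix relief, IntegerMatrix seeds,
                                   int connectivity) {
    int H = relief.nrow(), W = relief.ncol();
    typedef std::pair<double, long> QE; // (relief value, row*W + col)
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
    IntegerMatrix lab(H, W);
    for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
            lab(i, j) = seeds(i, j);
            if (seeds(i, j) >= 0)
                pq.push(std::make_pair(relief(i, j), (long)i * W + j));
        }
    const int di8[8] = {-1, 0, 0, 1, -1, -1, 1, 1};
    const int dj8[8] = {0, -1, 1, 0, -1, 1, -1, 1};
    int nn = (connectivity == 8) ? 8 : 4;
    while (!pq.empty()) {
        QE top = pq.top();
        pq.pop();
        int i = (int)(top.second / W), j = (int)(top.second % W);
        int L = lab(i, j);
        for (int k = 0; k < nn; ++k) {
            int ii = i + di8[k], jj = j + dj8[k];
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (lab(ii, jj) != -1) continue;
            lab(ii, jj) = L;
            pq.push(std::make_pair(relief(ii, jj), (long)ii * W + jj));
        }
    }
    for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
            if (lab(i, j) == -1) lab(i, j) = 0;
    return lab;
}
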