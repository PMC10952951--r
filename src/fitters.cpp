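#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Counter-based per-voxel RNG (splitmix64): estimates for a voxel depend
// only on (seed, voxel index), never on execution order or mask shape.
static inline uint64_t splitmix64(uint64_t &state) {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static inline double unif01(uint64_t &state) {
    return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t voxel_stream(uint64_t seed, uint64_t voxel) {
    // decorrelate the (seed, voxel) pair before drawing
    uint64_t s = seed * 0x9E3779B97F4A7C15ULL + 0x2545F4914F6CDD1DULL;
    s ^= (voxel + 1ULL) * 0xD1342543DE82EF95ULL;
    splitmix64(s);
    return s;
}

struct FitResult {
    double s0, t2, sse;
    bool converged;
};

// Bounded Levenberg-Marquardt for S(TE) = S0 * exp(-TE / T2*).
// Box constraints enforced by clamping after each trial step; convergence
// when an accepted step reduces the SSE by less than tol (relative) or
// moves the parameters by a negligible amount.
static FitResult lm_fit(const double *y, const double *te, int ne,
                        double s0_start, double t2_start,
                        double s0_lo, double s0_hi,
                        double t2_lo, double t2_hi,
                        int max_iter, double tol) {
    double s0 = std::min(std::max(s0_start, s0_lo), s0_hi);
    double t2 = std::min(std::max(t2_start, t2_lo), t2_hi);

    auto sse_at = [&](double a, double b) {
        double s = 0.0;
        for (int i = 0; i < ne; ++i) {
            double r = a * std::exp(-te[i] / b) - y[i];
            s += r * r;
        }
        return s;
    };

    double sse = sse_at(s0, t2);
    double lambda = 1e-3;
    bool converged = false;

    for (int iter = 0; iter < max_iter; ++iter) {
        // J'J and J'r for the 2-parameter model
        double a11 = 0, a12 = 0, a22 = 0, g1 = 0, g2 = 0;
        for (int i = 0; i < ne; ++i) {
            double e = std::exp(-te[i] / t2);
            double r = s0 * e - y[i];
            double j1 = e;                              // d/dS0
            double j2 = s0 * te[i] / (t2 * t2) * e;     // d/dT2*
            a11 += j1 * j1; a12 += j1 * j2; a22 += j2 * j2;
            g1 += j1 * r;   g2 += j2 * r;
        }
        // active-set handling: if S0 sits on a bound with the gradient
        // pointing outward, the joint step degenerates -- optimise T2*
        // alone (1-D damped Newton) with S0 held at the bound
        bool s0_pinned =
            (s0 >= s0_hi * (1.0 - 1e-12) && g1 < 0) ||
            (s0 <= s0_lo * (1.0 + 1e-12) + 1e-300 && g1 > 0);
        bool accepted = false;
        for (int tries = 0; tries < 30; ++tries) {
            double s0_new, t2_new;
            if (s0_pinned) {
                if (a22 <= 0 || !std::isfinite(a22)) break;
                double d2 = -g2 / (a22 * (1.0 + lambda));
                s0_new = s0;
                t2_new = std::min(std::max(t2 + d2, t2_lo), t2_hi);
            } else {
                double b11 = a11 * (1.0 + lambda);
                double b22 = a22 * (1.0 + lambda);
                double det = b11 * b22 - a12 * a12;
                if (det <= 0 || !std::isfinite(det)) { lambda *= 10.0; continue; }
                double d1 = -( b22 * g1 - a12 * g2) / det;
                double d2 = -(-a12 * g1 + b11 * g2) / det;
                s0_new = std::min(std::max(s0 + d1, s0_lo), s0_hi);
                t2_new = std::min(std::max(t2 + d2, t2_lo), t2_hi);
            }
            // S0 is linear given T2*: refine it in closed form (keeps the
            // step inside the box, speeds convergence near clamped bounds)
            double num = 0, den = 0;
            for (int i = 0; i < ne; ++i) {
                double e = std::exp(-te[i] / t2_new);
                num += y[i] * e; den += e * e;
            }
            if (den > 0) {
                double s0_proj = std::min(std::max(num / den, s0_lo), s0_hi);
                if (sse_at(s0_proj, t2_new) <= sse_at(s0_new, t2_new))
                    s0_new = s0_proj;
            }
            double sse_new = sse_at(s0_new, t2_new);
            if (std::isfinite(sse_new) && sse_new <= sse) {
                double drop = sse - sse_new;
                double step = std::fabs(s0_new - s0) / std::max(1.0, std::fabs(s0)) +
                              std::fabs(t2_new - t2) / std::max(1.0, std::fabs(t2));
                s0 = s0_new; t2 = t2_new; sse = sse_new;
                lambda = std::max(lambda / 3.0, 1e-12);
                accepted = true;
                if (drop <= tol * (sse + 1e-300) || step < 1e-12)
                    converged = true;
                break;
            }
            lambda *= 10.0;
        }
        if (!accepted) { converged = true; break; }  // no improving step left
        if (converged) break;
    }
    FitResult res;
    res.s0 = s0; res.t2 = t2; res.sse = sse; res.converged = converged;
    return res;
}

static double median_of(std::vector<double> v) {
    size_t n = v.size();
    std::sort(v.begin(), v.end());
    if (n % 2 == 1) return v[n / 2];
    return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Multi-start fit of a block of voxels.
// signals: nvox x necho matrix; voxelIdx: 0-based linear voxel indices used
// to derive each voxel's RNG substream. Returns nvox x 6 matrix with
// columns t2star, s0, n_converged, residual_rms, at_bound, fit_ok.
// [[Rcpp::export(name = ".fitVoxelsCpp")]]
NumericMatrix fit_voxels_cpp(NumericMatrix signals, NumericVector te,
                             NumericVector voxelIdx, int nInit, double seed,
                             double t2Lo, double t2Hi,
                             double s0LoMult, double s0HiMult,
                             int maxIter, double tol) {
    const int nvox = signals.nrow();
    const int ne = signals.ncol();
    NumericMatrix out(nvox, 6);
    std::vector<double> yv(ne), tev(ne);
    for (int j = 0; j < ne; ++j) tev[j] = te[j];
    const double boundEps = 1e-6;

    for (int v = 0; v < nvox; ++v) {
        for (int j = 0; j < ne; ++j) yv[j] = signals(v, j);
        double ymax = 0.0;
        for (int j = 0; j < ne; ++j) ymax = std::max(ymax, yv[j]);
        if (!(ymax > 0.0)) {            // nothing to fit
            out(v, 0) = NA_REAL; out(v, 1) = NA_REAL;
            out(v, 2) = 0; out(v, 3) = NA_REAL; out(v, 4) = 0; out(v, 5) = 0;
            continue;
        }
        double s0_lo = s0LoMult * ymax, s0_hi = s0HiMult * ymax;
        uint64_t rng = voxel_stream((uint64_t)seed, (uint64_t)voxelIdx[v]);
        std::vector<double> t2s, s0s;
        t2s.reserve(nInit); s0s.reserve(nInit);
        double best_sse = R_PosInf;
        for (int k = 0; k < nInit; ++k) {
            double t2_start = t2Lo + unif01(rng) * (t2Hi - t2Lo);
            double s0_start = s0_lo + unif01(rng) * (s0_hi - s0_lo);
            FitResult fr = lm_fit(yv.data(), tev.data(), ne, s0_start,
                                  t2_start, s0_lo, s0_hi, t2Lo, t2Hi,
                                  maxIter, tol);
            if (fr.converged) {
                t2s.push_back(fr.t2);
                s0s.push_back(fr.s0);
                if (fr.sse < best_sse) best_sse = fr.sse;
            }
        }
        if (t2s.empty()) {
            out(v, 0) = NA_REAL; out(v, 1) = NA_REAL;
            out(v, 2) = 0; out(v, 3) = NA_REAL; out(v, 4) = 0; out(v, 5) = 0;
            continue;
        }
        double t2_med = median_of(t2s);
        double s0_med = median_of(s0s);
        double sse_med = 0.0;
        for (int j = 0; j < ne; ++j) {
            double r = s0_med * std::exp(-tev[j] / t2_med) - yv[j];
            sse_med += r * r;
        }
        bool at_bound = (t2_med <= t2Lo * (1 + boundEps) + boundEps) ||
                        (t2_med >= t2Hi * (1 - boundEps) - boundEps);
        out(v, 0) = t2_med;
        out(v, 1) = s0_med;
        out(v, 2) = (double)t2s.size();
        out(v, 3) = std::sqrt(sse_med / ne);
        out(v, 4) = at_bound ? 1.0 : 0.0;
        out(v, 5) = 1.0;
    }
    return out;
}

// Per-start estimates for one voxel (diagnostics / median-robustness checks).
// Returns nInit x 4: s0, t2star, converged, sse.
// [[Rcpp::export(name = ".fitVoxelStartsCpp")]]
NumericMatrix fit_voxel_starts_cpp(NumericVector signal, NumericVector te,
                                   double voxelIdx, int nInit, double seed,
                                   double t2Lo, double t2Hi,
                                   double s0LoMult, double s0HiMult,
                                   int maxIter, double tol) {
    const int ne = signal.size();
    NumericMatrix out(nInit, 4);
    std::vector<double> yv(ne), tev(ne);
    double ymax = 0.0;
    for (int j = 0; j < ne; ++j) {
        yv[j] = signal[j]; tev[j] = te[j];
        ymax = std::max(ymax, yv[j]);
    }
    if (!(ymax > 0.0)) {
        std::fill(out.begin(), out.end(), NA_REAL);
        return out;
    }
    double s0_lo = s0LoMult * ymax, s0_hi = s0HiMult * ymax;
    uint64_t rng = voxel_stream((uint64_t)seed, (uint64_t)voxelIdx);
    for (int k = 0; k < nInit; ++k) {
        double t2_start = t2Lo + unif01(rng) * (t2Hi - t2Lo);
        double s0_start = s0_lo + unif01(rng) * (s0_hi - s0_lo);
        FitResult fr = lm_fit(yv.data(), tev.data(), ne, s0_start, t2_start,
                              s0_lo, s0_hi, t2Lo, t2Hi, maxIter, tol);
        out(k, 0) = fr.s0; out(k, 1) = fr.t2;
        out(k, 2) = fr.converged ? 1.0 : 0.0; out(k, 3) = fr.sse;
    }
    return out;
}
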