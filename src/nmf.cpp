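#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Kullback-Leibler divergence D(V || WH) up to terms constant in W, H are
// kept so successive values are comparable across iterations.
static double kl_divergence(const NumericMatrix& V,
                            const std::vector<double>& WH,
                            int n, int m) {
    const double eps = 1e-12;
    double d = 0.0;
    for (int j = 0; j < m; ++j) {
        for (int i = 0; i < n; ++i) {
            double v = V(i, j);
            double wh = WH[i + (size_t)j * n] + eps;
            if (v > 0.0) d += v * std::log(v / wh) - v + wh;
            else d += wh;
        }
    }
    return d;
}

static void mat_prod(const std::vector<double>& W, const std::vector<double>& H,
                     std::vector<double>& WH, int n, int k, int m) {
    std::fill(WH.begin(), WH.end(), 0.0);
    for (int j = 0; j < m; ++j) {
        for (int a = 0; a < k; ++a) {
            double h = H[a + (size_t)j * k];
            if (h == 0.0) continue;
            const double* wcol = &W[(size_t)a * n];
            double* out = &WH[(size_t)j * n];
            for (int i = 0; i < n; ++i) out[i] += wcol[i] * h;
        }
    }
}

//' Nonnegative matrix factorization by multiplicative KL-divergence updates.
//'
//' V (n x m, nonnegative counts) is approximated by W (n x k) %*% H (k x m).
//' Initial factors are drawn from R's RNG so results are reproducible under
//' set.seed(). Convergence is declared when the relative change in the KL
//' divergence over a 10-iteration window falls below `tol`.
//'
//' @noRd
// [[Rcpp::export(name = ".nmf_kl")]]
List nmf_kl(NumericMatrix V, int k, int max_iter = 10000, double tol = 1e-6) {
    const int n = V.nrow(), m = V.ncol();
    const double eps = 1e-12;
    if (k < 1) stop("k must be >= 1");

    double total = 0.0;
    for (int j = 0; j < m; ++j) for (int i = 0; i < n; ++i) total += V(i, j);
    // scale initial entries so E[WH] matches the mean of V
    double init_scale = std::sqrt((total / (double)(n * m)) / (double)k);
    if (init_scale <= 0.0) init_scale = 1e-3;

    std::vector<double> W((size_t)n * k), H((size_t)k * m), WH((size_t)n * m);
    std::vector<double> R_((size_t)n * m);
    for (size_t t = 0; t < W.size(); ++t) W[t] = (0.1 + R::unif_rand()) * init_scale;
    for (size_t t = 0; t < H.size(); ++t) H[t] = (0.1 + R::unif_rand()) * init_scale;

    double prev = R_PosInf, div = R_PosInf;
    int it = 0;
    for (it = 1; it <= max_iter; ++it) {
        // W update
        mat_prod(W, H, WH, n, k, m);
        for (int j = 0; j < m; ++j)
            for (int i = 0; i < n; ++i)
                R_[i + (size_t)j * n] = V(i, j) / (WH[i + (size_t)j * n] + eps);
        for (int a = 0; a < k; ++a) {
            double hsum = 0.0;
            for (int j = 0; j < m; ++j) hsum += H[a + (size_t)j * k];
            hsum += eps;
            for (int i = 0; i < n; ++i) {
                double acc = 0.0;
                for (int j = 0; j < m; ++j)
                    acc += H[a + (size_t)j * k] * R_[i + (size_t)j * n];
                W[i + (size_t)a * n] *= acc / hsum;
            }
        }
        // H update
        mat_prod(W, H, WH, n, k, m);
        for (int j = 0; j < m; ++j)
            for (int i = 0; i < n; ++i)
                R_[i + (size_t)j * n] = V(i, j) / (WH[i + (size_t)j * n] + eps);
        for (int a = 0; a < k; ++a) {
            double wsum = 0.0;
            for (int i = 0; i < n; ++i) wsum += W[i + (size_t)a * n];
            wsum += eps;
            for (int j = 0; j < m; ++j) {
                double acc = 0.0;
                const double* wcol = &W[(size_t)a * n];
                const double* rcol = &R_[(size_t)j * n];
                for (int i = 0; i < n; ++i) acc += wcol[i] * rcol[i];
                H[a + (size_t)j * k] *= acc / wsum;
            }
        }
        if (it % 10 == 0 || it == max_iter) {
            mat_prod(W, H, WH, n, k, m);
            div = kl_divergence(V, WH, n, m);
            if (R_finite(prev)) {
                double rel = std::fabs(prev - div) / (std::fabs(prev) + eps);
                if (rel < tol) break;
            }
            prev = div;
        }
    }

    NumericMatrix Wout(n, k), Hout(k, m);
    for (int a = 0; a < k; ++a)
        for (int i = 0; i < n; ++i) Wout(i, a) = W[i + (size_t)a * n];
    for (int j = 0; j < m; ++j)
        for (int a = 0; a < k; ++a) Hout(a, j) = H[a + (size_t)j * k];
    return List::create(_["W"] = Wout, _["H"] = Hout,
                        _["divergence"] = div, _["iterations"] = it);
}
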