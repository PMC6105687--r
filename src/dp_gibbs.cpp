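#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Truncated stick-breaking Dirichlet-process mixture over paired cancer cell
// fractions. Each mutation i contributes, on each timepoint axis t, a
// binomial likelihood Binom(alt[i] | dep[i], zeta[i] * pi_k[t]) where zeta is
// the expected VAF at CCF 1 for that mutation's copy-number/purity context
// and pi_k[t] is the cluster's CCF on axis t. Cluster CCFs carry a uniform
// prior over a fixed grid (griddy Gibbs update); the concentration alpha has
// a Gamma(alpha_a, alpha_b) hyperprior resampled each sweep. zgrp indexes the
// vector of unique zeta values per axis so binomial log-terms are shared.
//
// All randomness flows through R's RNG: results are reproducible under
// set.seed().

static inline double clamp_p(double p) {
    if (p < 1e-9) return 1e-9;
    if (p > 1.0 - 1e-9) return 1.0 - 1e-9;
    return p;
}

static int sample_categorical_log(const std::vector<double>& logw) {
    const int K = (int)logw.size();
    double mx = logw[0];
    for (int k = 1; k < K; ++k) if (logw[k] > mx) mx = logw[k];
    double tot = 0.0;
    std::vector<double> w(K);
    for (int k = 0; k < K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
    double u = R::unif_rand() * tot, acc = 0.0;
    for (int k = 0; k < K; ++k) { acc += w[k]; if (u <= acc) return k; }
    return K - 1;
}

// [[Rcpp::export(name = ".dp_gibbs_2d")]]
List dp_gibbs_2d(IntegerVector alt1, IntegerVector dep1, IntegerVector zgrp1,
                 NumericVector zeta1,
                 IntegerVector alt2, IntegerVector dep2, IntegerVector zgrp2,
                 NumericVector zeta2,
                 int K, NumericVector grid, int n_iter, int burnin, int thin,
                 double alpha_a = 1.0, double alpha_b = 1.0) {
    const int n = alt1.size();
    const int G = grid.size();
    const int G1 = zeta1.size(), G2 = zeta2.size();
    if (n < 1) stop("no mutations supplied");
    if (burnin >= n_iter) stop("burnin must be smaller than the sweep count");

    const int n_keep = (n_iter - burnin + thin - 1) / thin;
    IntegerMatrix z_draws(n, n_keep);
    NumericMatrix pi1_draws(K, n_keep), pi2_draws(K, n_keep);
    IntegerMatrix n_draws(K, n_keep);
    NumericVector alpha_draws(n_keep);

    // state
    std::vector<int> z(n);
    std::vector<double> pi1(K), pi2(K), logw(K);
    double alpha = 1.0;
    for (int i = 0; i < n; ++i) z[i] = (int)(R::unif_rand() * K) % K;
    for (int k = 0; k < K; ++k) {
        pi1[k] = grid[(int)(R::unif_rand() * G) % G];
        pi2[k] = grid[(int)(R::unif_rand() * G) % G];
        logw[k] = -std::log((double)K);
    }

    // per-(component, zeta-group) log terms, refreshed when pi changes
    std::vector<double> lp1((size_t)K * G1), lq1((size_t)K * G1);
    std::vector<double> lp2((size_t)K * G2), lq2((size_t)K * G2);
    auto refresh_axis = [&](int k) {
        for (int g = 0; g < G1; ++g) {
            double p = clamp_p(zeta1[g] * pi1[k]);
            lp1[k + (size_t)g * K] = std::log(p);
            lq1[k + (size_t)g * K] = std::log1p(-p);
        }
        for (int g = 0; g < G2; ++g) {
            double p = clamp_p(zeta2[g] * pi2[k]);
            lp2[k + (size_t)g * K] = std::log(p);
            lq2[k + (size_t)g * K] = std::log1p(-p);
        }
    };
    for (int k = 0; k < K; ++k) refresh_axis(k);

    std::vector<double> ll(K), lpost(G);
    std::vector<int> nk(K);
    // sufficient statistics per component x zeta group
    std::vector<double> A1((size_t)K * G1), D1((size_t)K * G1);
    std::vector<double> A2((size_t)K * G2), D2((size_t)K * G2);

    int keep = 0;
    for (int sweep = 1; sweep <= n_iter; ++sweep) {
        // --- assignments ---
        for (int i = 0; i < n; ++i) {
            int g1 = zgrp1[i], g2 = zgrp2[i];
            double a1 = (double)alt1[i], r1 = (double)(dep1[i] - alt1[i]);
            double a2 = (double)alt2[i], r2 = (double)(dep2[i] - alt2[i]);
            for (int k = 0; k < K; ++k) {
                ll[k] = logw[k]
                    + a1 * lp1[k + (size_t)g1 * K] + r1 * lq1[k + (size_t)g1 * K]
                    + a2 * lp2[k + (size_t)g2 * K] + r2 * lq2[k + (size_t)g2 * K];
            }
            z[i] = sample_categorical_log(ll);
        }

        // --- counts and sufficient statistics ---
        std::fill(nk.begin(), nk.end(), 0);
        std::fill(A1.begin(), A1.end(), 0.0); std::fill(D1.begin(), D1.end(), 0.0);
        std::fill(A2.begin(), A2.end(), 0.0); std::fill(D2.begin(), D2.end(), 0.0);
        for (int i = 0; i < n; ++i) {
            int k = z[i];
            nk[k]++;
            A1[k + (size_t)zgrp1[i] * K] += alt1[i];
            D1[k + (size_t)zgrp1[i] * K] += dep1[i];
            A2[k + (size_t)zgrp2[i] * K] += alt2[i];
            D2[k + (size_t)zgrp2[i] * K] += dep2[i];
        }

        // --- stick weights ---
        double log_stick_left = 0.0, sum_log1mv = 0.0;
        int tail = n;
        for (int k = 0; k < K; ++k) {
            tail -= nk[k];
            double v;
            if (k == K - 1) v = 1.0;
            else v = R::rbeta(1.0 + nk[k], alpha + (double)tail);
            if (v < 1e-12) v = 1e-12;
            if (v > 1.0 - 1e-12) v = 1.0 - 1e-12;
            if (k == K - 1) v = 1.0 - 1e-12;
            logw[k] = log_stick_left + std::log(v);
            log_stick_left += std::log1p(-v);
            if (k < K - 1) sum_log1mv += std::log1p(-v);
        }

        // --- concentration ---
        alpha = R::rgamma(alpha_a + (double)(K - 1), 1.0 / (alpha_b - sum_log1mv));
        if (alpha < 1e-6) alpha = 1e-6;

        // --- cluster CCFs (griddy Gibbs per component per axis) ---
        for (int k = 0; k < K; ++k) {
            if (nk[k] == 0) {
                pi1[k] = grid[(int)(R::unif_rand() * G) % G];
                pi2[k] = grid[(int)(R::unif_rand() * G) % G];
            } else {
                for (int gi = 0; gi < G; ++gi) {
                    double lg = 0.0;
                    for (int g = 0; g < G1; ++g) {
                        double a = A1[k + (size_t)g * K];
                        double d = D1[k + (size_t)g * K];
                        if (d == 0.0) continue;
                        double p = clamp_p(zeta1[g] * grid[gi]);
                        lg += a * std::log(p) + (d - a) * std::log1p(-p);
                    }
                    lpost[gi] = lg;
                }
                pi1[k] = grid[sample_categorical_log(lpost)];
                for (int gi = 0; gi < G; ++gi) {
                    double lg = 0.0;
                    for (int g = 0; g < G2; ++g) {
                        double a = A2[k + (size_t)g * K];
                        double d = D2[k + (size_t)g * K];
                        if (d == 0.0) continue;
                        double p = clamp_p(zeta2[g] * grid[gi]);
                        lg += a * std::log(p) + (d - a) * std::log1p(-p);
                    }
                    lpost[gi] = lg;
                }
                pi2[k] = grid[sample_categorical_log(lpost)];
            }
            refresh_axis(k);
        }

        // --- store ---
        if (sweep > burnin && (sweep - burnin - 1) % thin == 0 && keep < n_keep) {
            for (int i = 0; i < n; ++i) z_draws(i, keep) = z[i] + 1; // 1-based
            for (int k = 0; k < K; ++k) {
                pi1_draws(k, keep) = pi1[k];
                pi2_draws(k, keep) = pi2[k];
                n_draws(k, keep) = nk[k];
            }
            alpha_draws[keep] = alpha;
            ++keep;
        }
    }

    return List::create(_["z"] = z_draws, _["pi1"] = pi1_draws,
                        _["pi2"] = pi2_draws, _["n"] = n_draws,
                        _["alpha"] = alpha_draws, _["n_kept"] = keep);
}
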