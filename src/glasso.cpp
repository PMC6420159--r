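// Graphical lasso (sparse inverse covariance) with an element-wise penalty
// matrix, block coordinate descent over columns with an inner lasso solved
// by coordinate descent.  Per-element penalties are what allows
// testability-based masking: an effectively infinite penalty on a pair
// forces its precision entry to exactly zero.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double softThreshold(double z, double t) {
    if (z > t) return z - t;
    if (z < -t) return z + t;
    return 0.0;
}

// [[Rcpp::export(name = ".glassoCpp")]]
Rcpp::List glassoCpp(const arma::mat& S, const arma::mat& Rho,
                     arma::mat W, arma::mat B,
                     int maxIter = 100, double tol = 1e-4,
                     bool warm = false) {
    const uword p = S.n_rows;
    if (!warm) {
        W = S;
        W.diag() = S.diag() + Rho.diag();
        B.zeros(p, p);
    } else {
        W.diag() = S.diag() + Rho.diag();
    }
    // convergence scale: mean absolute off-diagonal of S
    double sbar = 0.0;
    if (p > 1) {
        sbar = (accu(abs(S)) - accu(abs(S.diag()))) / double(p * (p - 1));
    }
    if (sbar < 1e-12) sbar = 1e-12;
    const double thr = tol * sbar;

    bool converged = false;
    int it = 0;
    uvec all = regspace<uvec>(0, p - 1);
    for (it = 1; it <= maxIter; ++it) {
        double dW = 0.0;
        for (uword j = 0; j < p; ++j) {
            uvec others = find(all != j);
            mat V = W.submat(others, others);
            vec s12 = S.col(j); s12 = s12.elem(others);
            vec r12 = Rho.col(j); r12 = r12.elem(others);
            vec beta = B.col(j); beta = beta.elem(others);
            vec u = V * beta;
            // inner lasso coordinate descent
            for (int inner = 0; inner < 200; ++inner) {
                double dBeta = 0.0;
                for (uword i = 0; i < p - 1; ++i) {
                    double bOld = beta(i);
                    double c = s12(i) - (u(i) - V(i, i) * bOld);
                    double bNew = softThreshold(c, r12(i)) / V(i, i);
                    if (bNew != bOld) {
                        double d = bNew - bOld;
                        u += d * V.col(i);
                        beta(i) = bNew;
                        dBeta = std::max(dBeta, std::fabs(d));
                    }
                }
                if (dBeta < thr * 0.1) break;
            }
            vec w12 = V * beta;
            vec wOld = W.col(j); wOld = wOld.elem(others);
            dW = std::max(dW, abs(w12 - wOld).max());
            for (uword i = 0; i < p - 1; ++i) {
                W(others(i), j) = w12(i);
                W(j, others(i)) = w12(i);
                B(others(i), j) = beta(i);
            }
        }
        if (dW < thr) { converged = true; break; }
    }

    // recover the precision matrix from W and the regression coefficients
    mat Theta(p, p, fill::zeros);
    for (uword j = 0; j < p; ++j) {
        uvec others = find(all != j);
        vec beta = B.col(j); beta = beta.elem(others);
        vec w12 = W.col(j); w12 = w12.elem(others);
        double tjj = 1.0 / (W(j, j) - dot(w12, beta));
        Theta(j, j) = tjj;
        for (uword i = 0; i < p - 1; ++i)
            Theta(others(i), j) = -beta(i) * tjj;
    }
    Theta = 0.5 * (Theta + Theta.t());

    return Rcpp::List::create(Rcpp::Named("precision") = Theta,
                              Rcpp::Named("W") = W,
                              Rcpp::Named("B") = B,
                              Rcpp::Named("iterations") = it,
                              Rcpp::Named("converged") = converged);
}
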