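// Dense-MLP numerical kernels (forward, backprop, Adam) for the
// conditional GAN. Mirrors the list-of-weights representation used on the
// R side: W[[l]] is fan_in x fan_out, b[[l]] a length-fan_out vector.
//
// All kernels use zero-copy views onto the R matrices. cpp_adam_step
// mutates the weight and moment matrices IN PLACE; the R side snapshots
// (deep-copies) any state that must survive later updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat view(SEXP x)
{
    NumericMatrix m(x);
    return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

static arma::vec view_vec(SEXP x)
{
    NumericVector v(x);
    return arma::vec(v.begin(), v.size(), false, true);
}

// out_type: 0 linear, 1 sigmoid
// [[Rcpp::export(name = "cpp_nn_forward")]]
List cpp_nn_forward(const List& W, const List& b, const arma::mat& X,
                    int out_type, bool cache)
{
    const int L = W.size();
    List acts(L);
    arma::mat A = X;
    for (int l = 0; l < L; ++l) {
        if (cache) acts[l] = A;
        arma::mat Wl = view(W[l]);
        arma::vec bl = view_vec(b[l]);
        arma::mat Z = A * Wl;
        Z.each_row() += bl.t();
        if (l < L - 1) {
            A = arma::clamp(std::move(Z), 0.0, arma::datum::inf); // ReLU
        } else if (out_type == 1) {
            A = 1.0 / (1.0 + arma::exp(-Z));
        } else {
            A = std::move(Z);
        }
    }
    if (cache) return List::create(_["out"] = A, _["acts"] = acts);
    return List::create(_["out"] = A);
}

// dZ is dL/d(pre-activation of the output layer)
// [[Rcpp::export(name = "cpp_nn_backward")]]
List cpp_nn_backward(const List& W, const List& acts, const arma::mat& dZ)
{
    const int L = W.size();
    List gW(L), gb(L);
    arma::mat delta = dZ;
    arma::mat dX;
    for (int l = L - 1; l >= 0; --l) {
        arma::mat A = view(acts[l]);
        gW[l] = arma::mat(A.t() * delta);
        gb[l] = arma::vec(arma::sum(delta, 0).t());
        arma::mat Wl = view(W[l]);
        arma::mat dA = delta * Wl.t();
        if (l > 0) {
            delta = dA % (A > 0); // A is the ReLU output feeding layer l
        } else {
            dX = std::move(dA);
        }
    }
    return List::create(_["W"] = gW, _["b"] = gb, _["dX"] = dX);
}

// In-place Adam update of (W, b) and the moment estimates.
// [[Rcpp::export(name = "cpp_adam_step")]]
void cpp_adam_step(List W, List b, List mW, List vW, List mb, List vb,
                   const List& gW, const List& gb, double lr, double beta1,
                   double beta2, int t, double eps = 1e-8)
{
    const int L = W.size();
    const double c1 = 1.0 - std::pow(beta1, t);
    const double c2 = 1.0 - std::pow(beta2, t);
    for (int l = 0; l < L; ++l) {
        arma::mat Wl = view(W[l]), mWl = view(mW[l]), vWl = view(vW[l]);
        arma::mat gWl = view(gW[l]);
        mWl = beta1 * mWl + (1 - beta1) * gWl;
        vWl = beta2 * vWl + (1 - beta2) * arma::square(gWl);
        Wl -= lr * (mWl / c1) / (arma::sqrt(vWl / c2) + eps);

        arma::vec bl = view_vec(b[l]), mbl = view_vec(mb[l]),
                  vbl = view_vec(vb[l]);
        arma::vec gbl = view_vec(gb[l]);
        mbl = beta1 * mbl + (1 - beta1) * gbl;
        vbl = beta2 * vbl + (1 - beta2) * arma::square(gbl);
        bl -= lr * (mbl / c1) / (arma::sqrt(vbl / c2) + eps);
    }
}
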