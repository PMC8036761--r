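#include <Rcpp.h>
#include <vector>

// Backward-Euler time stepping of the 1-D areal heat equation on a chain of
// control volumes with a lumped heater node. All quantities are per unit
// heater area: capacities C [J m^-2 K^-1], interface conductances G
// [W m^-2 K^-1], source flux q [W m^-2] injected at the heater node.
//
// Backward Euler is L-stable, so arbitrarily thin film cells never oscillate,
// and with zero-flux ends it conserves injected energy to roundoff. The
// tridiagonal system is solved with the Thomas algorithm each substep; the
// first output interval may use a graded substep sequence to resolve the
// sqrt(t) startup singularity.
//
// Optional electro-thermal coupling (constant-current drive): the injected
// flux follows the heater resistance, q = q0 * (1 + alpha * T_heater),
// evaluated explicitly at the previous substep (the correction is O(alpha*dT)
// ~ a few percent, so explicit evaluation is ample).

// [[Rcpp::export]]
Rcpp::List fd_step_heater(Rcpp::NumericVector C,
                          Rcpp::NumericVector G,
                          int heater,
                          double q0,
                          int n_out,
                          double dt_out,
                          Rcpp::NumericVector sub_first,
                          int substeps,
                          bool couple,
                          double alpha) {
    const int n = C.size();
    if (G.size() != n - 1)
        Rcpp::stop("length(G) must be length(C) - 1");
    if (heater < 1 || heater > n)
        Rcpp::stop("heater index out of range");
    const int h = heater - 1;

    std::vector<double> T(n, 0.0), Tnew(n, 0.0);
    std::vector<double> cp(n), dp(n); // Thomas workspace
    Rcpp::NumericVector Th_out(n_out);
    double energy_in = 0.0;

    for (int m = 0; m < n_out; ++m) {
        const bool first = (m == 0) && sub_first.size() > 0;
        const int nsub = first ? sub_first.size() : substeps;
        for (int s = 0; s < nsub; ++s) {
            const double dt = first ? sub_first[s] : dt_out / substeps;
            double q = q0;
            if (couple) q = q0 * (1.0 + alpha * T[h]);
            energy_in += q * dt;

            // assemble and solve (C/dt + L) Tnew = C/dt * T + q e_h
            // tridiagonal: lower/upper = -G, diag = C/dt + G_left + G_right
            // Thomas forward sweep
            double diag0 = C[0] / dt + (n > 1 ? G[0] : 0.0);
            double rhs0 = C[0] / dt * T[0] + (h == 0 ? q : 0.0);
            cp[0] = (n > 1) ? (-G[0] / diag0) : 0.0;
            dp[0] = rhs0 / diag0;
            for (int i = 1; i < n; ++i) {
                const double lower = -G[i - 1];
                const double diag = C[i] / dt + G[i - 1] + (i < n - 1 ? G[i] : 0.0);
                const double rhs = C[i] / dt * T[i] + (i == h ? q : 0.0);
                const double denom = diag - lower * cp[i - 1];
                cp[i] = (i < n - 1) ? (-G[i] / denom) : 0.0;
                dp[i] = (rhs - lower * dp[i - 1]) / denom;
            }
            Tnew[n - 1] = dp[n - 1];
            for (int i = n - 2; i >= 0; --i)
                Tnew[i] = dp[i] - cp[i] * Tnew[i + 1];
            T.swap(Tnew);
        }
        Th_out[m] = T[h];
    }

    Rcpp::NumericVector field(n);
    for (int i = 0; i < n; ++i) field[i] = T[i];
    return Rcpp::List::create(Rcpp::Named("dT_heater") = Th_out,
                              Rcpp::Named("field") = field,
                              Rcpp::Named("energy_in") = energy_in);
}
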