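# Conversion constant between eta (1/s) and S2axis*tauc (s):
# (9/10) (mu0/4pi)^2 gammaH^4 hbar^2 P2(cos 90deg)^2 / rHH^6.
# The prefactor is squared in (mu0/4pi): the first-power form is not
# dimensionally consistent with eta in 1/s.
.ccr_eta_const <- function(r_HH = .nmr_const$r_HH_me) {
  0.9 * .nmr_const$mu0_4pi^2 * .nmr_const$gamma_H^4 * .nmr_const$hbar^2 *
    p2(cos(pi / 2))^2 / r_HH^6
}

#' Forward SQ/TQ cross-correlated relaxation ratio curve
#'
#' \eqn{|I_a/I_b| = \frac{3}{4}\,\eta\tanh(\sqrt{\eta^2+\delta^2}\,T) /
#' (\sqrt{\eta^2+\delta^2} - \delta\tanh(\sqrt{\eta^2+\delta^2}\,T))}, where
#' `eta` is the intra-methyl 1H-1H cross-correlated relaxation rate and
#' `delta` accounts for relaxation coupling with external protons.
#'
#' @param T_s Relaxation delays, s.
#' @param eta Cross-correlated rate, 1/s.
#' @param delta External-proton coupling term, 1/s (>= 0).
#' @return Ratio values (dimensionless, >= 0).
#' @export
#' @examples
#' ccr_forward(0.045, eta = 15.5, delta = 0)  # 0.75 * tanh(0.6975)
ccr_forward <- function(T_s, eta, delta = 0) {
  stopifnot(all(T_s > 0), delta >= 0)
  s <- sqrt(eta^2 + delta^2)
  th <- tanh(s * T_s)
  0.75 * eta * th / (s - delta * th)
}

#' Fit an SQ/TQ cross-correlated relaxation ratio curve
#'
#' Least-squares (eta, delta) fit of [ccr_forward()] with delta constrained
#' non-negative; Monte-Carlo uncertainties and the order-parameter/tumbling
#' product via [s2tc_from_eta()].
#'
#' @param T_s Delays, s (>= 5 values).
#' @param ratios Observed |Ia/Ib| values.
#' @param sigma Per-point noise SD (scalar or vector) for Monte-Carlo errors.
#' @param n_mc Monte-Carlo draws (default 200; 0 to skip). @param seed Seed.
#' @return One-row tibble: `eta`, `eta_error`, `delta`, `delta_error`,
#'   `S2_tauc_ns`, `S2_tauc_error_ns`, `flag`.
#' @export
fit_ccr <- function(T_s, ratios, sigma = NULL, n_mc = 200, seed = 1L) {
  stopifnot(length(T_s) >= 5, length(T_s) == length(ratios))
  if (all(ratios == 0)) {
    return(tibble(eta = NA_real_, eta_error = NA_real_, delta = NA_real_,
                  delta_error = NA_real_, S2_tauc_ns = NA_real_,
                  S2_tauc_error_ns = NA_real_, flag = "degenerate"))
  }
  fit1 <- function(y) {
    # initial eta from the early-time slope: ratio ~ (3/4) eta T
    eta0 <- max(y[1] / (0.75 * T_s[1]), 1)
    f <- tryCatch(
      nlminb(c(eta = eta0, delta = 1),
             function(p) sum((y - ccr_forward(T_s, p[1], p[2]))^2),
             lower = c(1e-3, 0), upper = c(500, 100)),
      error = function(e) NULL
    )
    if (is.null(f) || f$convergence > 1) return(NULL)
    c(eta = f$par[[1]], delta = f$par[[2]])
  }
  cf <- fit1(ratios)
  if (is.null(cf)) {
    return(tibble(eta = NA_real_, eta_error = NA_real_, delta = NA_real_,
                  delta_error = NA_real_, S2_tauc_ns = NA_real_,
                  S2_tauc_error_ns = NA_real_, flag = "nonconverged"))
  }
  err <- c(eta = 0, delta = 0)
  if (n_mc > 0 && !is.null(sigma) && any(sigma > 0)) {
    err <- montecarlo_errors(fit1, yhat = ccr_forward(T_s, cf[["eta"]], cf[["delta"]]),
                             sigma = sigma, n_draws = n_mc, seed = seed)
  }
  tibble(
    eta = cf[["eta"]], eta_error = err[["eta"]],
    delta = cf[["delta"]], delta_error = err[["delta"]],
    S2_tauc_ns = s2tc_from_eta(cf[["eta"]]),
    S2_tauc_error_ns = s2tc_from_eta(err[["eta"]]),
    flag = "ok"
  )
}

#' Order-parameter/tumbling product from the cross-correlated rate
#'
#' Linear conversion \eqn{S^2_{axis}\tau_c = \eta / C} with
#' \eqn{C = \frac{9}{10}(\mu_0/4\pi)^2 \gamma_H^4 \hbar^2
#' P_2(\cos 90^\circ)^2 / r_{HH}^6} and \eqn{r_{HH} = 1.813} angstrom.
#'
#' @param eta Cross-correlated rate, 1/s (>= 0).
#' @param r_HH Intra-methyl H-H distance, m.
#' @return S2axis * tau_c in nanoseconds.
#' @export
#' @examples
#' s2tc_from_eta(15.5)  # about 4.3 ns
s2tc_from_eta <- function(eta, r_HH = .nmr_const$r_HH_me) {
  stopifnot(all(eta >= 0))
  eta / .ccr_eta_const(r_HH) * 1e9
}

#' Viscosity correction of a D2O-measured tumbling time
#'
#' Multiplicative correction for comparing a tumbling time determined in
#' (mostly) H2O buffer with methyl data measured in 100% D2O.
#'
#' @param tau_c_ns Measured tumbling time, ns.
#' @param viscosity_ratio D2O/H2O viscosity ratio (default 1.23 at 298 K).
#' @return Corrected tau_c in ns.
#' @export
d2o_tc_correction <- function(tau_c_ns, viscosity_ratio = 1.23) {
  if (any(viscosity_ratio <= 0)) abort("Viscosity ratio must be positive")
  tau_c_ns * viscosity_ratio
}
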