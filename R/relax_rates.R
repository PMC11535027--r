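#' Fit a mono-exponential decay to one intensity series
#'
#' Least-squares fit of \eqn{I(t) = I_0 e^{-R t}} by Levenberg-Marquardt with
#' a log-linear initial guess. If a per-point `sigma` is supplied the fit
#' minimises chi-squared, otherwise unweighted SSE. Uncertainties come from a
#' seeded Monte-Carlo resampling of the residual noise.
#'
#' @param delays Numeric vector of relaxation delays (s), at least 3 values,
#'   strictly increasing and non-negative.
#' @param intensities Signal amplitudes (arbitrary units).
#' @param sigma Noise SD, a scalar or per-point vector; used for weighting and
#'   for Monte-Carlo error estimation. If `NULL`, errors use the residual RMS.
#' @param n_mc Monte-Carlo draws for the uncertainty (default 200); set to 0
#'   to skip.
#' @param seed Seed for the Monte-Carlo resampling.
#' @return One-row tibble: `rate`, `rate_error`, `I0`, `I0_error`,
#'   `residual_rms`, `flag` (`"ok"`, `"degenerate"` or `"negative_rate"`).
#' @export
#' @examples
#' t <- seq(0.1, 1, 0.1)
#' fit_monoexponential(t, 100 * exp(-2 * t), n_mc = 0)
fit_monoexponential <- function(delays, intensities, sigma = NULL,
                                n_mc = 200, seed = 1L) {
  stopifnot(length(delays) >= 3, length(delays) == length(intensities))
  if (any(diff(delays) <= 0) || any(delays < 0)) {
    abort("Delays must be non-negative and strictly increasing")
  }
  if (max(intensities) - min(intensities) == 0) {
    return(tibble(rate = NA_real_, rate_error = NA_real_, I0 = intensities[1],
                  I0_error = NA_real_, residual_rms = 0, flag = "degenerate"))
  }
  fit1 <- function(y) {
    # log-linear start (positive points only), then Levenberg-Marquardt
    pos <- y > 0
    if (sum(pos) >= 2) {
      cf <- coef(lm(log(y[pos]) ~ delays[pos]))
      start <- list(I0 = exp(cf[[1]]), R = max(-cf[[2]], 1e-3))
    } else {
      start <- list(I0 = max(abs(y)), R = 1 / max(delays))
    }
    fit <- tryCatch(
      if (is.null(sigma) || any(sigma <= 0)) {
        minpack.lm::nlsLM(y ~ I0 * exp(-R * delays), start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        w <- 1 / rep(sigma, length.out = length(y))^2
        minpack.lm::nlsLM(y ~ I0 * exp(-R * delays), start = start, weights = w,
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      },
      error = function(e) NULL
    )
    if (is.null(fit)) return(NULL)
    coef(fit)
  }
  cf <- fit1(intensities)
  if (is.null(cf)) abort("Mono-exponential fit failed to converge")
  resid <- intensities - cf[["I0"]] * exp(-cf[["R"]] * delays)
  rms <- sqrt(mean(resid^2))
  sig_mc <- if (!is.null(sigma)) rep(sigma, length.out = length(delays)) else rep(rms, length(delays))
  err <- c(R = 0, I0 = 0)
  if (n_mc > 0 && any(sig_mc > 0)) {
    err <- montecarlo_errors(
      function(y) { p <- fit1(y); if (is.null(p)) NULL else c(R = p[["R"]], I0 = p[["I0"]]) },
      yhat = cf[["I0"]] * exp(-cf[["R"]] * delays),
      sigma = sig_mc, n_draws = n_mc, seed = seed
    )
  }
  tibble(
    rate = cf[["R"]], rate_error = err[["R"]],
    I0 = cf[["I0"]], I0_error = err[["I0"]],
    residual_rms = rms,
    flag = if (cf[["R"]] < 0) "negative_rate" else "ok"
  )
}

#' Fit mono-exponential decays for a table of probes
#'
#' @param decays Long tibble with columns `residue`, `atom`, `delay_s`,
#'   `intensity` and optionally `sigma` (plus any grouping columns named in
#'   `by`).
#' @param by Extra grouping columns (e.g. `"experiment"`, `"field_T"`).
#' @inheritParams fit_monoexponential
#' @return Tibble with one row per probe group and the columns of
#'   [fit_monoexponential()].
#' @export
fit_rates <- function(decays, by = character(0), n_mc = 200, seed = 1L) {
  grp <- c("residue", "atom", by)
  decays |>
    group_by(dplyr::across(dplyr::all_of(grp))) |>
    group_modify(~{
      sg <- if ("sigma" %in% names(.x)) .x$sigma[1] else NULL
      fit_monoexponential(.x$delay_s, .x$intensity, sigma = sg,
                          n_mc = n_mc, seed = seed)
    }) |>
    ungroup()
}

#' R2 from R1rho and R1 with spin-lock offset correction
#'
#' \eqn{R_2 = R_{1\rho}/\sin^2\theta - R_1/\tan^2\theta} with
#' \eqn{\theta = \arctan(\omega/\Omega)}, where \eqn{\omega} is the spin-lock
#' field strength and \eqn{\Omega} the resonance offset from the carrier
#' (both Hz). On resonance (\eqn{\Omega = 0}, \eqn{\theta = 90^\circ}) this
#' reduces exactly to \eqn{R_{1\rho}}. Errors are propagated in quadrature
#' through the two rate terms.
#'
#' @param r1rho,r1 Rates in 1/s (vectors recycle).
#' @param omega_sl Spin-lock field strength, Hz (default 2000).
#' @param offset Offset from the carrier, Hz.
#' @param r1rho_err,r1_err Optional rate uncertainties for propagation.
#' @return Tibble with `R2` and `R2_error`.
#' @export
r2_from_r1rho <- function(r1rho, r1, omega_sl = 2000, offset = 0,
                          r1rho_err = 0, r1_err = 0) {
  if (any(omega_sl == 0 & offset == 0)) {
    abort("Undefined tilt angle: spin-lock field and offset both zero")
  }
  theta <- atan2(omega_sl, offset)
  s2 <- sin(theta)^2
  # R1 coefficient cos^2/sin^2; on resonance cos = 0 exactly
  c2s2 <- cos(theta)^2 / s2
  tibble(
    R2 = r1rho / s2 - r1 * c2s2,
    R2_error = sqrt((r1rho_err / s2)^2 + (r1_err * c2s2)^2)
  )
}

#' Heteronuclear NOE ratio with noise-propagated error
#'
#' @param I_sat,I_ref Peak intensities with and without proton saturation.
#' @param sigma_sat,sigma_ref Spectral noise SDs of the two experiments.
#' @return Tibble with `noe_ratio` and `noe_error`
#'   (\eqn{|ratio|\sqrt{(\sigma_s/I_s)^2 + (\sigma_r/I_r)^2}}).
#' @export
hetnoe <- function(I_sat, I_ref, sigma_sat = 0, sigma_ref = 0) {
  if (any(I_ref == 0)) abort("Division error: reference intensity is zero")
  ratio <- I_sat / I_ref
  tibble(
    noe_ratio = ratio,
    noe_error = abs(ratio) * sqrt((sigma_sat / I_sat)^2 + (sigma_ref / I_ref)^2)
  )
}

#' Effective transverse relaxation rate from constant-time intensities
#'
#' \eqn{R_{2,eff} = -\ln(I/I_0)/T} for a constant-time relaxation period T.
#'
#' @param I Intensity with the CPMG block applied.
#' @param I0 Reference intensity (no relaxation block).
#' @param T_relax Constant-time relaxation period, s (e.g. 0.04).
#' @return R2eff in 1/s.
#' @export
r2eff_from_intensities <- function(I, I0, T_relax) {
  if (any(I <= 0) || any(I0 <= 0)) abort("Domain error: intensities must be positive")
  if (any(T_relax <= 0)) abort("Domain error: T_relax must be positive")
  -log(I / I0) / T_relax
}

#' Dispersion amplitude: R2eff difference between slowest and fastest pulsing
#'
#' @param profile Tibble with `nu_cpmg_Hz` and `R2eff` (any row order).
#' @return `R2eff` at the lowest CPMG frequency minus `R2eff` at the highest.
#' @export
delta_r2eff <- function(profile) {
  stopifnot(nrow(profile) >= 2)
  p <- arrange(profile, .data$nu_cpmg_Hz)
  p$R2eff[1] - p$R2eff[nrow(p)]
}

#' Elementwise R1*R2 product with propagated error
#'
#' Diagnostic product used to separate exchange contributions from diffusion
#' anisotropy: exchange raises R1*R2 while anisotropic tumbling moves R1 and
#' R2 in opposite directions.
#'
#' @param rates Tibble with columns `residue`, `atom`, `R1`, `R2` and
#'   optionally `R1_error`, `R2_error`.
#' @return `rates` with added `r1r2` and `r1r2_error`.
#' @export
r1r2_product <- function(rates) {
  r1e <- rates$R1_error %||% 0
  r2e <- rates$R2_error %||% 0
  mutate(rates,
         r1r2 = .data$R1 * .data$R2,
         r1r2_error = sqrt((r2e * .data$R1)^2 + (r1e * .data$R2)^2))
}

#' Rotational correlation time from TRACT rates
#'
#' The TROSY (R2alpha) and anti-TROSY (R2beta) rates differ by twice the
#' DD/CSA cross-correlation rate eta_xy. For an axially symmetric CSA tensor
#' at angle phi to the N-H bond,
#' \eqn{\eta_{xy} = p\,\delta_N\,P_2(\cos\phi)\,(4 J(0) + 3 J(\omega_N))}
#' with \eqn{p = \mu_0 \gamma_H \gamma_N \hbar / (16\pi\sqrt{2} r_{NH}^3)}
#' and \eqn{\delta_N = \gamma_N B_0 \Delta\sigma_N / (3\sqrt{2})}; tau_c is
#' recovered by root-finding on the rigid-rotor spectral density
#' \eqn{J(\omega) = (2/5)\,\tau_c/(1 + (\omega\tau_c)^2)}.
#'
#' @param r2alpha,r2beta TROSY / anti-TROSY rates, 1/s.
#' @param B0 Field, Tesla.
#' @param r_NH N-H distance, m. @param csa_N 15N CSA (dimensionless, e.g.
#'   -172e-6). @param csa_angle CSA-bond angle, rad.
#' @return One-row tibble: `eta_xy`, `tau_c_ns`, `flag`.
#' @export
tract_tc <- function(r2alpha, r2beta, B0 = 16.4,
                     r_NH = .nmr_const$r_NH, csa_N = .nmr_const$csa_N,
                     csa_angle = .nmr_const$csa_angle) {
  eta <- (r2beta - r2alpha) / 2
  if (eta <= 0) {
    return(tibble(eta_xy = eta, tau_c_ns = NA_real_, flag = "unphysical"))
  }
  wN <- abs(omega_larmor(B0, "15N"))
  # p = (mu0/4pi) gammaH gammaN hbar / (2 sqrt(2) rNH^3)
  p <- .nmr_const$mu0_4pi * .nmr_const$gamma_H * abs(.nmr_const$gamma_N) *
    .nmr_const$hbar / (2 * sqrt(2) * r_NH^3)
  dN <- abs(.nmr_const$gamma_N) * B0 * abs(csa_N) / (3 * sqrt(2))
  eta_of_tc <- function(tc) {
    J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
    p * dN * p2(cos(csa_angle)) * (4 * J(0) + 3 * J(wN))
  }
  root <- uniroot(function(tc) eta_of_tc(tc) - eta,
                  lower = 1e-12, upper = 1e-6, tol = 1e-15)
  tibble(eta_xy = eta, tau_c_ns = root$root * 1e9, flag = "ok")
}

#' Monte-Carlo parameter uncertainties for an arbitrary fitter
#'
#' Perturbs the model-predicted data with Gaussian noise of the stated SD,
#' refits each replicate, and returns the SD of the refit parameters. Fully
#' determined by `seed`.
#'
#' @param refit Function taking a perturbed data vector and returning a named
#'   numeric parameter vector (or `NULL` on non-convergence).
#' @param yhat Model-predicted (noise-free) data vector at the best fit.
#' @param sigma Noise SD (scalar or per-point).
#' @param n_draws Number of replicates (>= 50 recommended; default 200).
#' @param seed Integer seed.
#' @param max_fail_frac Error if more than this fraction of replicates fails
#'   to converge (default 0.1).
#' @return Named vector of parameter SDs.
#' @export
montecarlo_errors <- function(refit, yhat, sigma, n_draws = 200, seed = 1L,
                              max_fail_frac = 0.1) {
  if (n_draws < 1) abort("n_draws must be at least 1")
  sigma <- rep(sigma, length.out = length(yhat))
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_draws), function(i) refit(yhat + rnorm(length(yhat), 0, sigma)))
  })
  ok <- !vapply(draws, is.null, logical(1))
  if (mean(!ok) > max_fail_frac) {
    abort(paste0("Monte-Carlo error estimation failed: ",
                 round(100 * mean(!ok)), "% of replicates did not converge"))
  }
  mat <- do.call(rbind, draws[ok])
  apply(mat, 2, sd)
}
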