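#' Weight-average mass of a fast monomer-dimer equilibrium
#'
#' \eqn{M_W = 2M - M\frac{-K_D + \sqrt{K_D^2 + 8[M]K_D}}{4[M]}} where `M` is
#' the monomer mass and `[M]` the monomer-equivalent molar concentration at
#' the detector. The `[M] -> 0` limit is handled analytically (`M_W = M`).
#'
#' @param conc Monomer-equivalent concentration, M (vectorised).
#' @param M Monomer mass, Da.
#' @param K_D Dimer dissociation constant, M.
#' @return Weight-average mass, Da.
#' @export
#' @examples
#' mw_monomer_dimer(0.013, M = 12100, K_D = 0.013)  # 1.5 * M
mw_monomer_dimer <- function(conc, M, K_D) {
  stopifnot(M > 0, K_D > 0, all(conc >= 0))
  ifelse(conc == 0, M,
         2 * M - M * (-K_D + sqrt(K_D^2 + 8 * conc * K_D)) / (4 * conc))
}

#' Fit a monomer-dimer dissociation constant to a SEC-MALS series
#'
#' Least-squares fit of [mw_monomer_dimer()] with the endpoint masses
#' constrained (monomer mass fixed from sequence; dimer = 2M). The 95%
#' confidence interval comes from the fit covariance; when the upper bound
#' exceeds `lower_limit_factor` times the highest tested concentration the
#' estimate is flagged as a lower limit (solubility-limited series).
#'
#' @param series Tibble with `conc_molar` and `mw_da` (>= 4 points).
#' @param M Monomer mass, Da.
#' @param lower_limit_factor Multiple of the highest concentration beyond
#'   which the upper CI marks a lower-limit estimate (default 10).
#' @return Object of class `dimer_fit`: `K_D`, `K_D_se`, `ci95` (length-2),
#'   `lower_limit` flag, `chi2`.
#' @export
fit_dimer_kd <- function(series, M, lower_limit_factor = 10) {
  stopifnot(nrow(series) >= 4)
  s <- arrange(series, .data$conc_molar)
  if (stats::cor(s$conc_molar, s$mw_da) < 0) {
    warn("Mw decreases with concentration: monomer-dimer model violated")
  }
  # fit on log KD for positivity and a sane error scale
  fit <- minpack.lm::nlsLM(mw_da ~ mw_monomer_dimer(conc_molar, M, exp(lk)),
                           data = s, start = list(lk = log(max(s$conc_molar))),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  lk <- coef(fit)[["lk"]]
  lk_se <- sqrt(vcov(fit)[1, 1])
  K_D <- exp(lk)
  tq <- qt(0.975, df = nrow(s) - 1)
  ci <- exp(lk + c(-1, 1) * tq * lk_se)
  lower_limit <- ci[2] > lower_limit_factor * max(s$conc_molar)
  resid <- s$mw_da - mw_monomer_dimer(s$conc_molar, M, K_D)
  structure(list(
    K_D = K_D, K_D_se = K_D * lk_se, ci95 = ci, lower_limit = lower_limit,
    M = M, chi2 = sum(resid^2), n = nrow(s)
  ), class = "dimer_fit")
}

#' @export
print.dimer_fit <- function(x, ...) {
  cat("Monomer-dimer SEC-MALS fit (monomer ", format(x$M / 1000, digits = 4),
      " kDa, ", x$n, " points)\n", sep = "")
  cat("  K_D = ", format(x$K_D * 1000, digits = 4), " mM  (95% CI ",
      format(x$ci95[1] * 1000, digits = 3), "-",
      format(x$ci95[2] * 1000, digits = 3), " mM)",
      if (x$lower_limit) "  [lower limit: solubility-limited series]",
      "\n", sep = "")
  invisible(x)
}

#' Convert a fluorescence progress curve to product concentration
#'
#' Linear calibration between the uncleaved-substrate control and the
#' fluorescence at complete cleavage:
#' \eqn{[P](t) = S_0 (F(t) - F_{uncleaved}) / (F_{complete} - F_{uncleaved})},
#' clipped to \[0, S0\] with a warning for out-of-band values.
#'
#' @param fluorescence Observed fluorescence trace (a.u.).
#' @param F_uncleaved,F_complete Calibration endpoints (a.u.).
#' @param substrate_total Total substrate concentration, M.
#' @return Product concentration, M.
#' @export
calibrate_fluorescence <- function(fluorescence, F_uncleaved, F_complete,
                                   substrate_total) {
  if (F_complete == F_uncleaved) abort("Zero calibration span")
  p <- substrate_total * (fluorescence - F_uncleaved) / (F_complete - F_uncleaved)
  n_out <- sum(p < -1e-9 * substrate_total | p > substrate_total * (1 + 1e-9))
  if (n_out > 0) {
    warn(paste0(n_out, " point(s) outside the calibration band; clipped"))
  }
  pmin(substrate_total, pmax(0, p))
}

#' Initial reaction rate from a product progress curve
#'
#' Slope of a linear fit over the initial window where conversion is below
#' `max_conversion` of the total substrate. If fewer than `min_points` points
#' qualify the window is widened with a warning.
#'
#' @param time_s Time, s. @param product Product concentration, M.
#' @param substrate_total Total substrate, M.
#' @param max_conversion Initial-window conversion bound (default 0.1).
#' @param min_points Minimum points in the window (default 5).
#' @return One-row tibble: `v0` (M/s), `v0_se`, `n_points`, `window_s`.
#' @export
initial_rate <- function(time_s, product, substrate_total,
                         max_conversion = 0.1, min_points = 5) {
  stopifnot(length(time_s) == length(product))
  ok <- product < max_conversion * substrate_total
  if (sum(ok) < min_points) {
    warn(paste0("Fewer than ", min_points, " points below ",
                100 * max_conversion, "% conversion; window widened"))
    ok <- seq_along(time_s) <= max(min_points, sum(ok))
  }
  x <- time_s[ok]; y <- product[ok]
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - slope * (x - mean(x))
  se <- sqrt(sum(resid^2) / (length(x) - 2) / sxx)
  tibble(v0 = slope, v0_se = se, n_points = sum(ok), window_s = max(x))
}

#' Michaelis-Menten fit with catalytic constants
#'
#' Fits \eqn{v = v_{max}[S]/(K_m + [S])} to initial rates and derives
#' \eqn{k_{cat} = v_{max}/[E]_{trimer}} and \eqn{k_{cat}/K_m}, where the
#' kinetically competent enzyme unit is the trimer (monomer concentration
#' divided by 3).
#'
#' @param substrate Substrate concentrations, M (>= 4 levels).
#' @param rates Initial rates, M/s.
#' @param enzyme_monomer Monomeric enzyme concentration, M.
#' @return Object of class `mm_fit`: `v_max`, `K_m`, standard errors,
#'   `k_cat`, `kcat_over_km`, `enzyme_trimer`, plus a warning flag when K_m
#'   is far above the probed range.
#' @export
fit_michaelis_menten <- function(substrate, rates, enzyme_monomer) {
  stopifnot(length(substrate) >= 4, length(substrate) == length(rates),
            enzyme_monomer > 0)
  df <- tibble(s = substrate, v = rates)
  start <- list(vmax = max(rates) * 1.2, km = median(substrate))
  fit <- minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df, start = start,
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  flag <- if (cf[["km"]] > 5 * max(substrate)) {
    warn("K_m more than 5x above the highest substrate level: poorly constrained")
    "poorly_constrained"
  } else "ok"
  trimer <- enzyme_monomer / 3
  structure(list(
    v_max = cf[["vmax"]], v_max_se = se[[1]],
    K_m = cf[["km"]], K_m_se = se[[2]],
    enzyme_trimer = trimer,
    k_cat = cf[["vmax"]] / trimer,
    kcat_over_km = cf[["vmax"]] / trimer / cf[["km"]],
    flag = flag, n = length(substrate)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten fit (", x$n, " substrate levels)\n", sep = "")
  cat("  v_max = ", format(x$v_max, digits = 4), " M/s;  K_m = ",
      format(x$K_m * 1e6, digits = 4), " uM\n", sep = "")
  cat("  k_cat = ", format(x$k_cat, digits = 4), " 1/s (trimer ",
      format(x$enzyme_trimer * 1e9, digits = 4), " nM);  k_cat/K_m = ",
      format(x$kcat_over_km, digits = 4), " 1/(M s)\n", sep = "")
  invisible(x)
}

#' Activator-binding fit of cleavage rates
#'
#' One-site binding of the activating peptide with a basal rate:
#' \eqn{k = k_{max}[A]/(K_{D,app} + [A]) + k_0}, approximating the free
#' activator concentration by its total.
#'
#' @param activator Activator concentrations, M (>= 5 levels).
#' @param k_obs Observed cleavage rates, 1/s.
#' @param sigma Optional per-point SD for weighting and Monte-Carlo errors.
#' @param n_mc Monte-Carlo error draws (default 200; 0 to skip).
#' @param seed Seed.
#' @return Object of class `activation_fit`: `k_max`, `K_D_app`, `k_0` and
#'   Monte-Carlo errors.
#' @export
fit_activation <- function(activator, k_obs, sigma = NULL, n_mc = 200,
                           seed = 1L) {
  stopifnot(length(activator) >= 5, length(activator) == length(k_obs))
  if (stats::cor(activator, k_obs) < 0) {
    warn("Rates decrease with activator concentration: one-site activation model violated")
  }
  fit1 <- function(y) {
    args <- list(
      y ~ kmax * activator / (kd + activator) + k0,
      start = list(kmax = max(y) - min(y), kd = median(activator),
                   k0 = max(min(y), 1e-12)),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!is.null(sigma)) {
      args$weights <- 1 / rep(sigma, length.out = length(y))^2
    }
    f <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    setNames(coef(f), c("k_max", "K_D_app", "k_0"))
  }
  cf <- fit1(k_obs)
  if (is.null(cf)) {
    warn("Activation fit did not converge; returning NA parameters")
    cf <- c(k_max = NA_real_, K_D_app = NA_real_, k_0 = NA_real_)
    return(structure(c(as.list(cf),
                       list(errors = setNames(rep(NA_real_, 3), names(cf)),
                            n = length(activator))),
                     class = "activation_fit"))
  }
  err <- setNames(rep(NA_real_, 3), names(cf))
  if (n_mc > 0 && !is.null(sigma)) {
    yhat <- cf[["k_max"]] * activator / (cf[["K_D_app"]] + activator) + cf[["k_0"]]
    err <- montecarlo_errors(fit1, yhat, sigma, n_draws = n_mc, seed = seed)
  }
  structure(c(as.list(cf), list(errors = err, n = length(activator))),
            class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat("Activator-binding kinetic fit (", x$n, " levels)\n", sep = "")
  cat("  k_max = ", format(x$k_max, digits = 4), " 1/s;  K_D,app = ",
      format(x$K_D_app * 1e6, digits = 4), " uM;  k_0 = ",
      format(x$k_0, digits = 4), " 1/s\n", sep = "")
  invisible(x)
}

#' Percent substrate cleaved from gel band intensities
#'
#' \eqn{100(1 - I_t/I_{t0})} for the intact-substrate band before and after
#' incubation. Ratios above 1 are clipped to 0% cleaved with a warning.
#'
#' @param I_t0 Intact band intensity at time zero (> 0).
#' @param I_t Intact band intensity after incubation.
#' @return Percent cleaved, 0-100.
#' @export
gel_cleavage_fraction <- function(I_t0, I_t) {
  if (any(I_t0 <= 0)) abort("Time-zero band intensity must be positive")
  if (any(I_t > I_t0)) warn("Band intensity increased; percent cleaved clipped to 0")
  pmax(0, pmin(100, 100 * (1 - I_t / I_t0)))
}
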