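#' Lipari-Szabo model-free spectral density
#'
#' Isotropic form:
#' \eqn{J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_c}{1+(\omega\tau_c)^2} +
#' \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right]} with
#' \eqn{1/\tau' = 1/\tau_c + 1/\tau_e}. The axial form sums three Lorentzian
#' branches with correlation times set by \eqn{D_\parallel, D_\perp} and
#' weights set by the angle `alpha` between the bond vector and the unique
#' axis.
#'
#' @param w Angular frequency, rad/s (vectorised).
#' @param tau_c Overall tumbling time, s (isotropic mode).
#' @param S2 Generalized order parameter in \[0, 1\].
#' @param tau_e Internal correlation time, s (0 disables the internal term).
#' @param D_par,D_perp Axial diffusion constants, 1/s (axial mode; both
#'   `NULL` for isotropic).
#' @param alpha Angle between the bond vector and the unique axis, rad
#'   (axial mode).
#' @return J(w) in s/rad.
#' @export
spectral_density_mf <- function(w, tau_c = NULL, S2 = 1, tau_e = 0,
                                D_par = NULL, D_perp = NULL, alpha = NULL) {
  lorentz_pair <- function(tk) {
    tp <- if (tau_e > 0) 1 / (1 / tk + 1 / tau_e) else 0
    S2 * tk / (1 + (w * tk)^2) +
      (if (tau_e > 0) (1 - S2) * tp / (1 + (w * tp)^2) else 0)
  }
  if (is.null(D_par)) {
    stopifnot(!is.null(tau_c))
    0.4 * lorentz_pair(tau_c)
  } else {
    stopifnot(!is.null(alpha), D_par > 0, D_perp > 0)
    ca2 <- cos(alpha)^2
    A <- c((3 * ca2 - 1)^2 / 4,
           3 * ca2 * (1 - ca2),
           0.75 * (1 - ca2)^2)
    tk <- c(1 / (6 * D_perp),
            1 / (5 * D_perp + D_par),
            1 / (2 * D_perp + 4 * D_par))
    0.4 * (A[1] * lorentz_pair(tk[1]) + A[2] * lorentz_pair(tk[2]) +
             A[3] * lorentz_pair(tk[3]))
  }
}

#' Predict 15N relaxation rates from model-free parameters
#'
#' Standard dipolar + CSA expressions for an amide 15N spin evaluated on the
#' model-free spectral density. `Rex` is added to R2 scaled by
#' `(B0/B0_ref)^2`.
#'
#' @param S2,tau_e,Rex Model-free parameters (tau_e in s, Rex in 1/s at the
#'   reference field).
#' @param B0 Field, Tesla.
#' @param tau_c Isotropic tumbling time, s.
#' @param D_par,D_perp,alpha Axial tensor and bond-vector angle (optional;
#'   see [spectral_density_mf()]).
#' @param B0_ref Reference field for Rex reporting (default 16.4 T).
#' @param r_NH,csa_N Bond length (m) and 15N CSA (dimensionless).
#' @return One-row tibble: `R1`, `R2`, `noe`.
#' @export
predict_rates <- function(S2, tau_e = 0, Rex = 0, B0 = 16.4,
                          tau_c = NULL, D_par = NULL, D_perp = NULL,
                          alpha = NULL, B0_ref = 16.4,
                          r_NH = .nmr_const$r_NH, csa_N = .nmr_const$csa_N) {
  if (!is.null(D_par) && is.null(alpha)) {
    abort("Axial mode requires the bond-vector angle to the unique axis")
  }
  wH <- omega_larmor(B0, "1H"); wN <- omega_larmor(B0, "15N")
  J <- function(w) spectral_density_mf(abs(w), tau_c = tau_c, S2 = S2,
                                       tau_e = tau_e, D_par = D_par,
                                       D_perp = D_perp, alpha = alpha)
  d <- .nmr_const$mu0_4pi * .nmr_const$hbar *
    .nmr_const$gamma_H * .nmr_const$gamma_N / r_NH^3
  d2_4 <- d^2 / 4
  c2 <- (abs(wN) * csa_N)^2 / 3
  JhmN <- J(wH - wN); JN <- J(wN); JhpN <- J(wH + wN)
  R1 <- d2_4 * (JhmN + 3 * JN + 6 * JhpN) + c2 * JN
  R2 <- d2_4 / 2 * (4 * J(0) + JhmN + 3 * JN + 6 * J(wH) + 6 * JhpN) +
    c2 / 6 * (4 * J(0) + 3 * JN) + Rex * (B0 / B0_ref)^2
  # S2 = 0 with tau_e = 0 zeroes the spectral density: NOE limit is 1
  noe <- ifelse(R1 > 0,
                1 + d2_4 * (.nmr_const$gamma_H / .nmr_const$gamma_N) *
                  (6 * JhpN - JhmN) / R1,
                1)
  tibble(R1 = R1, R2 = R2, noe = noe)
}

#' Filter probes by the R2/R1 quotient
#'
#' Probes whose R2/R1 ratio exceeds the cutoff carry exchange contributions
#' (or overlap artefacts) that bias the tumbling-time estimate and are
#' excluded from the diffusion-tensor stage. The boundary is strict: a ratio
#' exactly at the cutoff is retained.
#'
#' @param rates Tibble with `residue`, `atom`, `R1`, `R2` (one row per probe
#'   per field) and optionally `noe`.
#' @param max_ratio R2/R1 cutoff (default 30).
#' @param min_noe Optional hetNOE floor (default `NULL`: off).
#' @return List with tibbles `retained` and `excluded` (the latter with a
#'   `reason` column).
#' @export
filter_probes <- function(rates, max_ratio = 30, min_noe = NULL) {
  stopifnot(all(c("R1", "R2") %in% names(rates)))
  if (nrow(rates) == 0) {
    return(list(retained = rates, excluded = mutate(rates, reason = character(0))))
  }
  if (any(rates$R1 <= 0)) abort("R1 must be positive for ratio filtering")
  bad_ratio <- rates$R2 / rates$R1 > max_ratio
  bad_noe <- if (!is.null(min_noe) && "noe" %in% names(rates)) {
    rates$noe < min_noe
  } else rep(FALSE, nrow(rates))
  excluded <- rates[bad_ratio | bad_noe, , drop = FALSE]
  excluded$reason <- ifelse(bad_ratio[bad_ratio | bad_noe],
                            paste0("R2/R1 > ", max_ratio), "hetNOE floor")
  list(retained = rates[!(bad_ratio | bad_noe), , drop = FALSE],
       excluded = excluded)
}

#' Initial tumbling-time estimate from the R2/R1 ratio
#'
#' Inverts the rigid-rotor (S2 = 1) single-field R2/R1 ratio at the trimmed
#' mean of the per-probe ratios. Used to seed [fit_modelfree()].
#'
#' @param rates Tibble with `residue`, `atom`, `field_T`, `R1`, `R2`.
#' @param trim Fraction trimmed from each tail of the ratio distribution
#'   (default 0.1).
#' @param min_probes Minimum number of probes required (default 5).
#' @return tau_c estimate in seconds. With several fields, the mean of the
#'   per-field estimates.
#' @export
estimate_tc <- function(rates, trim = 0.1, min_probes = 5) {
  per_field <- split(rates, rates$field_T)
  ests <- vapply(per_field, function(df) {
    if (nrow(df) < min_probes) {
      abort(paste0("Need at least ", min_probes, " probes per field, got ", nrow(df)))
    }
    target <- mean(df$R2 / df$R1, trim = trim)
    B0 <- df$field_T[1]
    ratio_of_tc <- function(tc) {
      p <- predict_rates(S2 = 1, tau_c = tc, B0 = B0)
      p$R2 / p$R1
    }
    uniroot(function(tc) ratio_of_tc(tc) - target,
            lower = 5e-10, upper = 1e-7, tol = 1e-14)$root
  }, numeric(1))
  mean(ests)
}

# Per-probe chi2 for one candidate parameter set at fixed global tumbling.
.probe_chi2 <- function(par, obs, tau_c, D_par, D_perp, alpha) {
  tot <- 0
  for (i in seq_len(nrow(obs))) {
    p <- predict_rates(S2 = par[["S2"]], tau_e = par[["tau_e"]] %||% 0,
                       Rex = par[["Rex"]] %||% 0, B0 = obs$field_T[i],
                       tau_c = tau_c, D_par = D_par, D_perp = D_perp,
                       alpha = alpha)
    tot <- tot +
      ((obs$R1[i] - p$R1) / obs$R1_error[i])^2 +
      ((obs$R2[i] - p$R2) / obs$R2_error[i])^2 +
      ((obs$noe[i] - p$noe) / obs$noe_error[i])^2
  }
  tot
}

# Model definitions: free parameters of M1..M4.
.mf_models <- list(
  M1 = c("S2"),
  M2 = c("S2", "tau_e"),
  M3 = c("S2", "Rex"),
  M4 = c("S2", "tau_e", "Rex")
)

.fit_probe_models <- function(obs, tau_c, D_par = NULL, D_perp = NULL,
                              alpha = NULL, criterion = "AICc") {
  n_obs <- 3L * nrow(obs)
  lower <- c(S2 = 0, tau_e = 0, Rex = 0)
  upper <- c(S2 = 1, tau_e = 5e-9, Rex = 50)
  start <- c(S2 = 0.8, tau_e = 2e-11, Rex = 1)
  admissible <- names(.mf_models)[vapply(.mf_models, length, 1L) <= n_obs - 1L]
  # the criterion must be comparable across models: use the small-sample
  # correction only when it is defined for every admissible model, else
  # plain AIC throughout
  k_max <- max(vapply(.mf_models[admissible], length, 1L))
  use_aicc <- criterion == "AICc" && (n_obs - k_max - 1L >= 1L)
  fits <- list()
  for (mid in admissible) {
    pars <- .mf_models[[mid]]
    k <- length(pars)
    obj <- function(v) {
      pv <- setNames(as.list(v), pars)
      .probe_chi2(pv, obs, tau_c, D_par, D_perp, alpha)
    }
    if (k == 1) {
      o <- optimize(function(s) obj(s), interval = c(0, 1), tol = 1e-9)
      est <- c(S2 = o$minimum); chi2 <- o$objective
    } else {
      f <- nlminb(start[pars], obj, lower = lower[pars], upper = upper[pars])
      est <- f$par; chi2 <- f$objective
    }
    crit <- if (use_aicc) {
      chi2 + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1L)
    } else {
      chi2 + 2 * k
    }
    fits[[mid]] <- list(model = mid, est = est, chi2 = chi2, crit = crit, k = k)
  }
  fits[[which.min(vapply(fits, `[[`, numeric(1), "crit"))]]
}

#' Model-free fit of a backbone relaxation dataset
#'
#' Two-stage Lipari-Szabo analysis: (1) estimate the global tumbling from the
#' R2/R1 ratio of the filtered probe set, (2) per-probe model selection among
#' M1 \{S2\}, M2 \{S2, tau_e\}, M3 \{S2, Rex\}, M4 \{S2, tau_e, Rex\}, then
#' re-optimisation of the global tumbling over probes whose selected model
#' carries no Rex, iterated to convergence (relative tau_c change < 0.1%).
#'
#' @param rates Tibble with one row per (probe, field): `residue`, `atom`,
#'   `field_T`, `R1`, `R1_error`, `R2`, `R2_error`, `noe`, `noe_error`.
#' @param mode `"isotropic"` or `"axial"`.
#' @param vectors Bond-vector tibble from [extract_bond_vectors()] (required
#'   for axial mode).
#' @param criterion `"AICc"` (falling back to AIC when a probe has too few
#'   observables for the small-sample correction) or `"AIC"`.
#' @param filter Apply the R2/R1 > 30 probe filter before fitting (default
#'   `TRUE`).
#' @param max_iter Maximum tensor/probe iterations (default 20).
#' @return An object of class `modelfree_fit`: list with `tensor` (tau_c in
#'   ns, and D_par/D_perp/orientation in axial mode), `params` (per-probe
#'   tibble), `excluded`, `converged`, `iterations`, `chi2`.
#' @export
fit_modelfree <- function(rates, mode = c("isotropic", "axial"),
                          vectors = NULL, criterion = c("AICc", "AIC"),
                          filter = TRUE, max_iter = 20) {
  mode <- match.arg(mode); criterion <- match.arg(criterion)
  if (mode == "axial" && is.null(vectors)) {
    abort("Axial mode requires bond vectors")
  }
  flt <- if (filter) filter_probes(rates) else list(retained = rates,
                                                    excluded = rates[0, ])
  ret <- flt$retained
  probes <- ret |> distinct(.data$residue, .data$atom)
  obs_by_probe <- lapply(seq_len(nrow(probes)), function(i) {
    filter(ret, .data$residue == probes$residue[i], .data$atom == probes$atom[i])
  })
  tau_c <- estimate_tc(ret)

  axial_pars <- NULL
  angles <- rep(NA_real_, nrow(probes))
  if (mode == "axial") {
    vkey <- paste(vectors$residue, vectors$atom)
    pkey <- paste(probes$residue, probes$atom)
    miss <- !pkey %in% vkey
    if (any(miss)) {
      abort(paste0("Missing bond vector(s) for probe(s): ",
                   paste(pkey[miss], collapse = ", ")))
    }
    vm <- as.matrix(vectors[match(pkey, vkey), c("x", "y", "z")])
  }

  fit_all_probes <- function(tau_c, D_par = NULL, D_perp = NULL) {
    lapply(seq_along(obs_by_probe), function(i) {
      .fit_probe_models(obs_by_probe[[i]], tau_c, D_par, D_perp,
                        alpha = angles[i], criterion = criterion)
    })
  }
  global_chi2 <- function(tau_c, sel, no_rex_only = TRUE) {
    # the tumbling objective uses exchange-free probes; if model selection
    # assigned Rex everywhere, fall back to all probes rather than an empty
    # (flat) objective
    if (no_rex_only &&
        all(vapply(sel, function(s) "Rex" %in% names(s$est), logical(1)))) {
      no_rex_only <- FALSE
    }
    tot <- 0
    for (i in seq_along(sel)) {
      s <- sel[[i]]
      if (no_rex_only && "Rex" %in% names(s$est)) next
      # refit the probe's selected parameter set at the candidate tau_c
      pars <- .mf_models[[s$model]]
      obj <- function(v) .probe_chi2(setNames(as.list(v), pars),
                                     obs_by_probe[[i]], tau_c, NULL, NULL, NA)
      if (length(pars) == 1) {
        tot <- tot + optimize(obj, c(0, 1), tol = 1e-8)$objective
      } else {
        tot <- tot + nlminb(s$est, obj, lower = c(S2 = 0, tau_e = 0, Rex = 0)[pars],
                            upper = c(S2 = 1, tau_e = 5e-9, Rex = 50)[pars])$objective
      }
    }
    tot
  }

  converged <- FALSE; iter <- 0L; sel <- NULL
  if (mode == "isotropic") {
    repeat {
      iter <- iter + 1L
      sel <- fit_all_probes(tau_c)
      opt <- optimize(function(tc) global_chi2(tc, sel),
                      interval = tau_c * c(0.7, 1.4), tol = tau_c * 1e-5)
      new_tc <- opt$minimum
      if (abs(new_tc - tau_c) / tau_c < 1e-3) {
        tau_c <- new_tc; converged <- TRUE
        sel <- fit_all_probes(tau_c)
        break
      }
      tau_c <- new_tc
      if (iter >= max_iter) break
    }
    tensor <- list(mode = "isotropic", tau_c_ns = tau_c * 1e9)
  } else {
    # axial: optimise (D_iso, ratio, theta, phi) on the filtered set, with
    # per-probe S2-only refits inside the tensor objective, then final
    # per-probe model selection.
    tensor_obj <- function(v) {
      Diso <- v[1]; ratio <- exp(v[2]); th <- v[3]; ph <- v[4]
      Dpar <- 3 * Diso * ratio / (ratio + 2)
      Dper <- 3 * Diso / (ratio + 2)
      axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      angles <<- acos(pmin(1, pmax(-1, as.numeric(vm %*% axis))))
      tot <- 0
      for (i in seq_along(obs_by_probe)) {
        o <- optimize(function(s) .probe_chi2(list(S2 = s), obs_by_probe[[i]],
                                              NULL, Dpar, Dper, angles[i]),
                      c(0, 1), tol = 1e-7)
        tot <- tot + o$objective
      }
      tot
    }
    Diso0 <- 1 / (6 * tau_c)
    tf <- nlminb(c(Diso0, log(1.2), pi / 4, pi / 4), tensor_obj,
                 lower = c(Diso0 / 3, log(1), 0, -pi),
                 upper = c(Diso0 * 3, log(3), pi, pi))
    iter <- 1L; converged <- tf$convergence == 0
    Diso <- tf$par[1]; ratio <- exp(tf$par[2])
    D_par <- 3 * Diso * ratio / (ratio + 2)
    D_perp <- 3 * Diso / (ratio + 2)
    axis <- c(sin(tf$par[3]) * cos(tf$par[4]),
              sin(tf$par[3]) * sin(tf$par[4]), cos(tf$par[3]))
    angles <- acos(pmin(1, pmax(-1, as.numeric(vm %*% axis))))
    sel <- fit_all_probes(NULL, D_par = D_par, D_perp = D_perp)
    tau_c <- 1 / (2 * (D_par + 2 * D_perp))
    tensor <- list(mode = "axial", tau_c_ns = tau_c * 1e9,
                   D_par = D_par, D_perp = D_perp,
                   theta = tf$par[3], phi = tf$par[4],
                   anisotropy = D_par / D_perp)
  }

  params <- list_rbind(lapply(seq_along(sel), function(i) {
    s <- sel[[i]]
    tibble(
      residue = probes$residue[i], atom = probes$atom[i], model = s$model,
      S2 = s$est[["S2"]],
      tau_e_ps = if ("tau_e" %in% names(s$est)) s$est[["tau_e"]] * 1e12 else 0,
      Rex = if ("Rex" %in% names(s$est)) s$est[["Rex"]] else 0,
      chi2 = s$chi2
    )
  }))
  structure(
    list(tensor = tensor, params = params, excluded = flt$excluded,
         converged = converged, iterations = iter, chi2 = sum(params$chi2)),
    class = "modelfree_fit"
  )
}

#' @export
print.modelfree_fit <- function(x, ...) {
  cat("Model-free fit (", x$tensor$mode, " diffusion)\n", sep = "")
  cat("  tau_c: ", format(x$tensor$tau_c_ns, digits = 4), " ns",
      if (x$tensor$mode == "axial")
        paste0("  (D_par/D_perp = ", format(x$tensor$anisotropy, digits = 3), ")"),
      "\n", sep = "")
  cat("  probes: ", nrow(x$params), " fitted, ", nrow(x$excluded),
      " excluded; mean S2 = ", format(mean(x$params$S2), digits = 3), "\n", sep = "")
  cat("  chi2: ", format(x$chi2, digits = 5), "; converged: ", x$converged,
      " (", x$iterations, " iteration(s))\n", sep = "")
  invisible(x)
}
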