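#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model-free fit
#'
#' @param x A `modelfree_fit`. @param ... Unused.
#' @return Per-probe parameter tibble (`residue`, `atom`, `model`, `S2`,
#'   `tau_e_ps`, `Rex`, `chi2`).
#' @export
tidy.modelfree_fit <- function(x, ...) x$params

#' @rdname tidy.modelfree_fit
#' @return For `glance`: a one-row tibble with the diffusion-tensor summary.
#' @export
glance.modelfree_fit <- function(x, ...) {
  tibble(
    mode = x$tensor$mode, tau_c_ns = x$tensor$tau_c_ns,
    anisotropy = x$tensor$anisotropy %||% 1,
    n_probes = nrow(x$params), n_excluded = nrow(x$excluded),
    mean_S2 = mean(x$params$S2), chi2 = x$chi2,
    converged = x$converged, iterations = x$iterations
  )
}

#' Tidy a global dispersion fit
#'
#' @param x A `dispersion_fit`. @param ... Unused.
#' @return Per-probe tibble with fitted shift differences and baselines.
#' @export
tidy.dispersion_fit <- function(x, ...) {
  tidyr::unnest(x$probes, cols = c("field_T", "R2_0"))
}

#' @rdname tidy.dispersion_fit
#' @return For `glance`: one-row tibble with the shared exchange parameters.
#' @export
glance.dispersion_fit <- function(x, ...) {
  tibble(
    coherence = x$coherence, p_B = x$p_B, p_B_error = x$p_B_error,
    k_ex = x$k_ex, k_ex_error = x$k_ex_error,
    tau_ex_ms = x$tau_ex_ms, tau_ex_error_ms = x$tau_ex_error_ms,
    chi2 = x$chi2, n_profiles = x$n_profiles
  )
}

#' Tidy a lineshape titration fit
#'
#' @param x A `lineshape_fit`. @param ... Unused.
#' @return One row per parameter with estimate and Monte-Carlo error.
#' @export
tidy.lineshape_fit <- function(x, ...) {
  tibble(
    term = c("K_D", "k_off"),
    estimate = c(x$K_D, x$k_off),
    std.error = c(x$K_D_error, x$k_off_error)
  )
}

#' @rdname tidy.lineshape_fit
#' @export
glance.lineshape_fit <- function(x, ...) {
  tibble(K_D = x$K_D, k_off = x$k_off, k_on = x$k_on, chi2 = x$chi2,
         n_points = x$n_points, flag = x$flag)
}

#' Tidy a monomer-dimer MALS fit
#'
#' @param x A `dimer_fit`. @param ... Unused.
#' @export
tidy.dimer_fit <- function(x, ...) {
  tibble(term = "K_D", estimate = x$K_D, std.error = x$K_D_se,
         conf.low = x$ci95[1], conf.high = x$ci95[2])
}

#' @rdname tidy.dimer_fit
#' @export
glance.dimer_fit <- function(x, ...) {
  tibble(K_D = x$K_D, conf.low = x$ci95[1], conf.high = x$ci95[2],
         lower_limit = x$lower_limit, chi2 = x$chi2, n = x$n)
}

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`. @param ... Unused.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("v_max", "K_m"),
         estimate = c(x$v_max, x$K_m),
         std.error = c(x$v_max_se, x$K_m_se))
}

#' @rdname tidy.mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble(v_max = x$v_max, K_m = x$K_m, k_cat = x$k_cat,
         kcat_over_km = x$kcat_over_km, enzyme_trimer = x$enzyme_trimer,
         flag = x$flag, n = x$n)
}

#' Tidy an activator-binding fit
#'
#' @param x An `activation_fit`. @param ... Unused.
#' @export
tidy.activation_fit <- function(x, ...) {
  tibble(term = c("k_max", "K_D_app", "k_0"),
         estimate = c(x$k_max, x$K_D_app, x$k_0),
         std.error = unname(x$errors))
}

#' @rdname tidy.activation_fit
#' @export
glance.activation_fit <- function(x, ...) {
  tibble(k_max = x$k_max, K_D_app = x$K_D_app, k_0 = x$k_0, n = x$n)
}
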