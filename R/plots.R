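#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a CSP profile along the sequence
#'
#' Bar plot of chemical-shift perturbations with the significance threshold,
#' the standard presentation for mapping a binding footprint.
#'
#' @param csps Output of [flag_significant()] (or a CSP tibble).
#' @return A ggplot object.
#' @export
plot_csp <- function(csps) {
  thr <- attr(csps, "threshold")
  p <- ggplot(csps, aes(x = .data$residue, y = .data$csp)) +
    geom_col(aes(fill = if ("significant" %in% names(csps))
      .data$significant != "none" else FALSE), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey55", "TRUE" = "firebrick")) +
    labs(x = "Residue", y = "CSP (ppm)") +
    theme_minimal()
  if (!is.null(thr) && !is.na(thr)) {
    p <- p + geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' Plot relaxation dispersion profiles with the global fit
#'
#' @param object A `dispersion_fit`.
#' @param profiles The profile tibble the fit was run on.
#' @param ... Unused.
#' @return A ggplot: R2eff vs CPMG frequency, one panel per probe, points
#'   for data and lines for the fitted model.
#' @export
autoplot.dispersion_fit <- function(object, profiles, ...) {
  fitted <- tidy(object) |>
    mutate(curve = pmap(list(.data$dw_ppm, .data$dw_H_ppm, .data$field_T,
                             .data$R2_0), function(dw, dwh, fT, r20) {
      nu <- seq(25, max(profiles$nu_cpmg_Hz), length.out = 60)
      # a dense display grid need not satisfy the even-echo-count constraint
      suppressWarnings(
        if (object$coherence == "SQ") {
          simulate_cpmg_sq(nu, object$p_B, object$k_ex, dw, B0 = fT,
                           R2_0 = r20, T_relax = object$T_relax)
        } else {
          simulate_cpmg_mq(nu, object$p_B, object$k_ex, dw, dwh, B0 = fT,
                           R2_0 = r20, T_relax = object$T_relax)
        }
      )
    })) |>
    tidyr::unnest("curve")
  ggplot(profiles, aes(x = .data$nu_cpmg_Hz, y = .data$R2eff,
                       colour = factor(.data$field_T))) +
    geom_point() +
    geom_line(data = fitted) +
    facet_wrap(~ residue) +
    labs(x = expression(nu[CPMG] ~ "(Hz)"), y = expression(R[2 * eff] ~ (s^-1)),
         colour = "Field (T)") +
    theme_minimal()
}

#' Plot a lineshape titration series
#'
#' @param spectra Tibble from [simulate_lineshape_titration()] or
#'   [gen_lineshape()].
#' @return A ggplot of the stacked 1D traces coloured by titration point.
#' @export
plot_lineshape_titration <- function(spectra) {
  ggplot(spectra, aes(x = .data$freq_Hz, y = .data$intensity,
                      colour = factor(signif(.data$L_total * 1e6, 3)),
                      group = .data$point)) +
    geom_line() +
    labs(x = "Frequency (Hz)", y = "Intensity (a.u.)",
         colour = "Ligand (uM)") +
    theme_minimal()
}

#' Plot a model-free parameter profile
#'
#' @param object A `modelfree_fit`. @param ... Unused.
#' @return A ggplot of S2 (and Rex where fitted) along the sequence.
#' @export
autoplot.modelfree_fit <- function(object, ...) {
  long <- object$params |>
    select("residue", "S2", "Rex") |>
    tidyr::pivot_longer(c("S2", "Rex"), names_to = "parameter")
  ggplot(long, aes(x = .data$residue, y = .data$value)) +
    geom_point() +
    facet_wrap(~ parameter, ncol = 1, scales = "free_y") +
    labs(x = "Residue", y = NULL) +
    theme_minimal()
}

#' Plot a SEC-MALS monomer-dimer fit
#'
#' @param object A `dimer_fit`.
#' @param series The (conc, Mw) series the fit was run on.
#' @param ... Unused.
#' @return A ggplot of Mw vs concentration with the fitted curve and the
#'   monomer/dimer endpoint masses.
#' @export
autoplot.dimer_fit <- function(object, series, ...) {
  grid <- tibble(conc_molar = seq(min(series$conc_molar),
                                  max(series$conc_molar), length.out = 100))
  grid$mw_da <- mw_monomer_dimer(grid$conc_molar, object$M, object$K_D)
  ggplot(series, aes(x = .data$conc_molar * 1e6, y = .data$mw_da / 1000)) +
    geom_point() +
    geom_line(data = grid) +
    geom_hline(yintercept = c(object$M, 2 * object$M) / 1000,
               linetype = "dotted") +
    labs(x = "Monomer concentration (uM)", y = "Mw (kDa)") +
    theme_minimal()
}

#' Plot a PRE attenuation profile
#'
#' @param profile The `profile` tibble from [attenuation_profile()].
#' @return A ggplot of corrected intensity ratios along the sequence,
#'   coloured by attenuation class.
#' @export
plot_pre_profile <- function(profile) {
  ggplot(profile, aes(x = .data$residue, y = .data$ratio,
                      colour = .data$class)) +
    geom_point() +
    geom_hline(yintercept = 1, linetype = "dotted") +
    labs(x = "Residue", y = "I_para / I_dia (corrected)",
         colour = "Attenuation") +
    theme_minimal()
}
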