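# Seeded generators for every input class the fitters consume. Defaults are
# the study conditions reported for the PDZ-domain system: tumbling 8.2 ns
# with backbone order parameters 0.9 +/- 0.1; backbone exchange on 0.42 ms
# (298 K) with a 15-16% minor state; methyl MQ exchange at 16.6% / 1.19 ms;
# core methyl S2axis*tauc 4.3 ns; monomer-dimer K_D 13 mM for a 12.1 kDa
# monomer; activator binding K_D 3.18 uM with k_off 48.5 1/s; catalytic
# efficiency ~85 1/(M s) at 510 nM monomeric enzyme. Every generator attaches
# its generating parameters as a `manifest` attribute so recovery tests never
# re-derive truth from prose.

.with_manifest <- function(x, ...) {
  structure(x, manifest = list(...))
}

#' Generate mono-exponential intensity decays
#'
#' @param rates Tibble with `residue`, `atom`, `rate` (1/s) and optionally
#'   `I0` (default 100).
#' @param delays Delay grid, s.
#' @param noise Gaussian noise SD as a fraction of I0 (default 0.02).
#' @param seed Integer seed.
#' @return Long tibble (`residue`, `atom`, `delay_s`, `intensity`, `sigma`)
#'   with the generating parameters in `attr(, "manifest")`.
#' @export
gen_decays <- function(rates, delays = c(0.4, 0.6, 0.8, 1.2, 1.6, 1.8, 2.4),
                       noise = 0.02, seed = 1L) {
  stopifnot(all(rates$rate > 0))
  if (!"I0" %in% names(rates)) rates$I0 <- 100
  out <- with_seed(seed, {
    rates |>
      tidyr::crossing(delay_s = delays) |>
      mutate(sigma = noise * .data$I0,
             intensity = .data$I0 * exp(-.data$rate * .data$delay_s) +
               rnorm(dplyr::n(), 0, .data$sigma)) |>
      select("residue", "atom", "delay_s", "intensity", "sigma")
  })
  .with_manifest(out, rates = rates, delays = delays, noise = noise, seed = seed)
}

#' Generate two-site CPMG dispersion profiles
#'
#' Forward-simulates [simulate_cpmg_sq()] or [simulate_cpmg_mq()] for a set
#' of probes at one or more fields and perturbs R2eff with Gaussian noise
#' expressed as a fraction of the baseline rate.
#'
#' @param probes Tibble with `residue`, `atom`, `dw_ppm` and (MQ only)
#'   `dw_H_ppm`.
#' @param p_B,k_ex Shared exchange parameters.
#' @param fields Fields, Tesla.
#' @param nu_cpmg CPMG frequency grid, Hz.
#' @param coherence `"SQ"` or `"MQ"`.
#' @param R2_0 Baseline rate, 1/s. @param T_relax Constant-time period, s.
#' @param noise Noise SD as a fraction of R2_0. @param seed Seed.
#' @return Long tibble (`residue`, `atom`, `field_T`, `nu_cpmg_Hz`, `R2eff`,
#'   `sigma`) with manifest.
#' @export
gen_dispersion <- function(probes, p_B = 0.152, k_ex = 1000 / 0.42,
                           fields = c(16.4, 21.1),
                           nu_cpmg = seq(25, 1500, by = 125),
                           coherence = c("SQ", "MQ"), R2_0 = 10,
                           T_relax = 0.04, noise = 0.02, seed = 1L) {
  coherence <- match.arg(coherence)
  grid <- tidyr::crossing(probes, field_T = fields)
  out <- with_seed(seed, {
    sims <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      prof <- if (coherence == "SQ") {
        simulate_cpmg_sq(nu_cpmg, p_B, k_ex, g$dw_ppm, B0 = g$field_T,
                         R2_0 = R2_0, T_relax = T_relax)
      } else {
        simulate_cpmg_mq(nu_cpmg, p_B, k_ex, g$dw_ppm, g$dw_H_ppm,
                         B0 = g$field_T, R2_0 = R2_0, T_relax = T_relax)
      }
      mutate(prof, residue = g$residue, atom = g$atom, field_T = g$field_T)
    })
    list_rbind(sims) |>
      mutate(sigma = noise * R2_0,
             R2eff = .data$R2eff + rnorm(dplyr::n(), 0, .data$sigma)) |>
      select("residue", "atom", "field_T", "nu_cpmg_Hz", "R2eff", "sigma")
  })
  .with_manifest(out, p_B = p_B, k_ex = k_ex, tau_ex_ms = 1000 / k_ex,
                 fields = fields, coherence = coherence, R2_0 = R2_0,
                 T_relax = T_relax, noise = noise, seed = seed, probes = probes)
}

#' Generate backbone R1/R2/hetNOE triples from the model-free forward model
#'
#' Per-probe order parameters default to a cohort at 0.9 +/- 0.1 (truncated
#' to \[0.5, 1\]) tumbling at 8.2 ns, the study conditions for a rigid small
#' domain.
#'
#' @param n_probes Number of backbone probes (default 80).
#' @param tau_c_ns Global tumbling time, ns (default 8.2).
#' @param S2_mean,S2_sd Order-parameter cohort distribution (defaults 0.9,
#'   0.1).
#' @param S2 Optional explicit per-probe S2 vector overriding the cohort
#'   draw.
#' @param fields Fields, Tesla (default 16.4).
#' @param noise Fractional Gaussian noise on each rate (default 0.02).
#' @param seed Seed.
#' @return Tibble with one row per (probe, field): `residue`, `atom`,
#'   `field_T`, `R1`, `R1_error`, `R2`, `R2_error`, `noe`, `noe_error`;
#'   manifest carries the generating parameters including the drawn S2.
#' @export
gen_relaxation_triples <- function(n_probes = 80, tau_c_ns = 8.2,
                                   S2_mean = 0.9, S2_sd = 0.1, S2 = NULL,
                                   fields = 16.4, noise = 0.02, seed = 1L) {
  out <- with_seed(seed, {
    if (is.null(S2)) {
      S2 <- pmin(1, pmax(0.5, rnorm(n_probes, S2_mean, S2_sd)))
    }
    grid <- tidyr::crossing(tibble(residue = seq_len(length(S2)), S2 = S2),
                            field_T = fields)
    pred <- list_rbind(lapply(seq_len(nrow(grid)), function(i) {
      predict_rates(S2 = grid$S2[i], tau_c = tau_c_ns * 1e-9,
                    B0 = grid$field_T[i])
    }))
    tibble(
      residue = grid$residue, atom = "N-H", field_T = grid$field_T,
      R1 = pred$R1 * (1 + rnorm(nrow(grid), 0, noise)),
      R1_error = noise * pred$R1,
      R2 = pred$R2 * (1 + rnorm(nrow(grid), 0, noise)),
      R2_error = noise * pred$R2,
      noe = pred$noe + rnorm(nrow(grid), 0, noise * abs(pred$noe)),
      noe_error = noise * abs(pred$noe)
    )
  })
  .with_manifest(out, tau_c_ns = tau_c_ns, S2 = S2, fields = fields,
                 noise = noise, seed = seed)
}

#' Generate SQ/TQ cross-correlated relaxation ratio curves
#'
#' A methyl cohort at a common order-parameter/tumbling product (default the
#' core-residue average 4.3 ns) with an external-proton coupling term.
#'
#' @param n_methyls Cohort size (default 20).
#' @param S2_tauc_ns Generating S2axis*tauc, ns (default 4.3).
#' @param delta External-proton term, 1/s (default 2).
#' @param delays Delay grid, s (default 13 values, 2-45 ms).
#' @param noise Fractional noise on the ratios (default 0.02). @param seed
#'   Seed.
#' @return Long tibble (`residue`, `atom`, `T_s`, `ratio`, `sigma`) with
#'   manifest.
#' @export
gen_ccr <- function(n_methyls = 20, S2_tauc_ns = 4.3, delta = 2,
                    delays = seq(0.002, 0.045, length.out = 13),
                    noise = 0.02, seed = 1L) {
  eta <- S2_tauc_ns * 1e-9 * .ccr_eta_const()
  out <- with_seed(seed, {
    tidyr::crossing(tibble(residue = seq_len(n_methyls), atom = "Ile-d1"),
                    T_s = delays) |>
      mutate(clean = ccr_forward(.data$T_s, eta, delta),
             sigma = noise * max(.data$clean),
             ratio = pmax(0, .data$clean + rnorm(dplyr::n(), 0, .data$sigma))) |>
      select("residue", "atom", "T_s", "ratio", "sigma")
  })
  .with_manifest(out, S2_tauc_ns = S2_tauc_ns, eta = eta, delta = delta,
                 delays = delays, noise = noise, seed = seed)
}

#' Generate a two-state lineshape titration series
#'
#' Defaults are the activator-peptide regime: K_D 3.18 uM, k_off 48.5 1/s,
#' 250 uM protein, eight points from 0 to 2 ligand equivalents, a 120 Hz
#' free/bound separation and 20 1/s linewidths in both states.
#'
#' @param K_D,k_off Binding parameters (M, 1/s).
#' @param P_total Protein concentration, M.
#' @param equivalents Ligand equivalents per point.
#' @param freq_Hz Frequency grid, Hz.
#' @param nu_free,nu_bound,R2_free,R2_bound Lineshape parameters.
#' @param noise Noise SD as a fraction of the maximum intensity. @param seed
#'   Seed.
#' @return Spectra tibble as from [simulate_lineshape_titration()] plus
#'   `sigma`; manifest carries all generating parameters.
#' @export
gen_lineshape <- function(K_D = 3.18e-6, k_off = 48.5, P_total = 250e-6,
                          equivalents = c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2),
                          freq_Hz = seq(-120, 240, by = 2),
                          nu_free = 0, nu_bound = 120,
                          R2_free = 20, R2_bound = 20,
                          noise = 0.01, seed = 1L) {
  clean <- simulate_lineshape_titration(K_D, k_off, P_total,
                                        equivalents * P_total, freq_Hz,
                                        nu_free, nu_bound, R2_free, R2_bound)
  out <- with_seed(seed, {
    sg <- noise * max(clean$intensity)
    mutate(clean, sigma = sg,
           intensity = .data$intensity + rnorm(dplyr::n(), 0, sg))
  })
  .with_manifest(out, K_D = K_D, k_off = k_off, P_total = P_total,
                 equivalents = equivalents, nu_free = nu_free,
                 nu_bound = nu_bound, R2_free = R2_free, R2_bound = R2_bound,
                 noise = noise, seed = seed)
}

#' Generate a SEC-MALS monomer-dimer concentration series
#'
#' Defaults are the solubility-limited dimerization scenario: 12.1 kDa
#' monomer, K_D 13 mM, detector concentrations 50-600 uM.
#'
#' @param M Monomer mass, Da. @param K_D Dimer dissociation constant, M.
#' @param conc Concentration grid, M.
#' @param noise Fractional noise on Mw (default 0.01). @param seed Seed.
#' @return Tibble (`conc_molar`, `mw_da`) with manifest.
#' @export
gen_mals <- function(M = 12100, K_D = 0.013,
                     conc = seq(50e-6, 600e-6, length.out = 12),
                     noise = 0.01, seed = 1L) {
  out <- with_seed(seed, {
    mw <- mw_monomer_dimer(conc, M, K_D)
    tibble(conc_molar = conc, mw_da = mw * (1 + rnorm(length(conc), 0, noise)))
  })
  .with_manifest(out, M = M, K_D = K_D, conc = conc, noise = noise, seed = seed)
}

#' Generate Michaelis-Menten initial-rate data
#'
#' Defaults reproduce the standard-buffer catalytic efficiency: K_m 20 uM
#' with v_max chosen so that k_cat/K_m = 85 1/(M s) at a trimer
#' concentration of 170 nM (510 nM monomer), probed at the assay's substrate
#' grid.
#'
#' @param K_m Michaelis constant, M.
#' @param kcat_over_km Catalytic efficiency, 1/(M s).
#' @param enzyme_monomer Monomeric enzyme concentration, M.
#' @param substrate Substrate grid, M.
#' @param noise Fractional noise on the rates (default 0.03). @param seed
#'   Seed.
#' @return Tibble (`substrate_molar`, `rate`, `sigma`) with manifest
#'   including the implied `v_max`.
#' @export
gen_kinetics_mm <- function(K_m = 20e-6, kcat_over_km = 85,
                            enzyme_monomer = 510e-9,
                            substrate = c(0.5, 5, 10, 20, 30) * 1e-6,
                            noise = 0.03, seed = 1L) {
  trimer <- enzyme_monomer / 3
  v_max <- kcat_over_km * K_m * trimer
  out <- with_seed(seed, {
    v <- v_max * substrate / (K_m + substrate)
    tibble(substrate_molar = substrate,
           rate = v * (1 + rnorm(length(v), 0, noise)),
           sigma = noise * v)
  })
  .with_manifest(out, K_m = K_m, v_max = v_max, kcat_over_km = kcat_over_km,
                 enzyme_monomer = enzyme_monomer, noise = noise, seed = seed)
}

#' Generate activator-binding cleavage-rate data
#'
#' Defaults probe the assay's activator grid (5-300 uM) with a one-site
#' activation model.
#'
#' @param k_max,K_D_app,k_0 Activation parameters (1/s, M, 1/s).
#' @param activator Activator grid, M.
#' @param noise Fractional noise (default 0.03). @param seed Seed.
#' @return Tibble (`activator_molar`, `k_obs`, `sigma`) with manifest.
#' @export
gen_kinetics_activation <- function(k_max = 2e-3, K_D_app = 50e-6, k_0 = 1e-4,
                                    activator = c(5, 10, 25, 50, 75, 100,
                                                  150, 200, 300) * 1e-6,
                                    noise = 0.03, seed = 1L) {
  out <- with_seed(seed, {
    k <- k_max * activator / (K_D_app + activator) + k_0
    tibble(activator_molar = activator,
           k_obs = k * (1 + rnorm(length(k), 0, noise)),
           sigma = noise * k)
  })
  .with_manifest(out, k_max = k_max, K_D_app = K_D_app, k_0 = k_0,
                 activator = activator, noise = noise, seed = seed)
}

#' Generate an enzymatic progress curve with fluorescence calibration
#'
#' Integrates the Michaelis-Menten rate law (implicit closed form solved per
#' time point) and maps product concentration onto a fluorescence scale
#' between the uncleaved control and the complete-cleavage plateau.
#'
#' @param v_max,K_m Kinetic parameters (M/s, M).
#' @param substrate_total Initial substrate, M.
#' @param times Time grid, s.
#' @param F_uncleaved,F_complete Fluorescence endpoints, a.u.
#' @param noise Noise SD as a fraction of the fluorescence span. @param seed
#'   Seed.
#' @return Tibble (`time_s`, `fluorescence`, `sigma`) with manifest.
#' @export
gen_progress_curve <- function(v_max, K_m, substrate_total = 20e-6,
                               times = seq(0, 3600, by = 60),
                               F_uncleaved = 1000, F_complete = 5000,
                               noise = 0.005, seed = 1L) {
  S_at <- vapply(times, function(t) {
    if (t == 0) return(substrate_total)
    f <- function(S) K_m * log(substrate_total / S) + (substrate_total - S) -
      v_max * t
    if (f(1e-15 * substrate_total) < 0) return(1e-15 * substrate_total)
    uniroot(f, c(1e-15 * substrate_total, substrate_total), tol = 1e-18)$root
  }, numeric(1))
  product <- substrate_total - S_at
  span <- F_complete - F_uncleaved
  out <- with_seed(seed, {
    fl <- F_uncleaved + span * product / substrate_total
    tibble(time_s = times,
           fluorescence = fl + rnorm(length(fl), 0, noise * abs(span)),
           sigma = noise * abs(span))
  })
  .with_manifest(out, v_max = v_max, K_m = K_m,
                 substrate_total = substrate_total,
                 F_uncleaved = F_uncleaved, F_complete = F_complete,
                 noise = noise, seed = seed)
}

#' Generate a paramagnetic attenuation pattern
#'
#' A flat ratio background with one or more attenuated residue blocks,
#' emulating a contiguous broadened stretch near a bound paramagnetic ion.
#'
#' @param residues Residue range (default 350:458).
#' @param blocks Tibble with `start`, `end`, `ratio` for attenuated
#'   stretches (default one block, residues 412-430 at ratio 0.1).
#' @param background Background ratio (default 1).
#' @param noise Absolute Gaussian noise on the ratio (default 0.02).
#' @param seed Seed.
#' @return Tibble (`residue`, `ratio`) with manifest.
#' @export
gen_pre <- function(residues = 350:458,
                    blocks = tibble(start = 412, end = 430, ratio = 0.1),
                    background = 1, noise = 0.02, seed = 1L) {
  ratio <- rep(background, length(residues))
  for (i in seq_len(nrow(blocks))) {
    sel <- residues >= blocks$start[i] & residues <= blocks$end[i]
    ratio[sel] <- blocks$ratio[i]
  }
  out <- with_seed(seed, {
    tibble(residue = residues,
           ratio = pmax(0, ratio + rnorm(length(ratio), 0, noise)))
  })
  .with_manifest(out, blocks = blocks, background = background,
                 noise = noise, seed = seed)
}
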