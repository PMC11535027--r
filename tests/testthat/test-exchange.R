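dw_rad_at <- function(dw_ppm, B0, gamma = 2.7126e7) {
  dw_ppm * 1e-6 * gamma * B0
}

test_that("the propagator's cycle rate matches Carver-Richards on a grid", {
  nu <- seq(25, 1500, by = 125)
  grid <- expand.grid(p_B = c(0.02, 0.1, 0.166),
                      k_ex = c(300, 1000, 2400, 8000),
                      dw_ppm = c(0.5, 1.5, 3))[1:20, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    dwr <- dw_rad_at(g$dw_ppm, 16.4)
    sim <- simulate_cpmg_sq(nu, g$p_B, g$k_ex, g$dw_ppm, B0 = 16.4,
                            R2_0 = 8, method = "cycle")$R2eff
    cr <- carver_richards(nu, g$p_B, g$k_ex, dwr, R2_0 = 8)
    expect_lt(max(abs(sim - cr) / cr), 0.01)
  }
})

test_that("intensity-detected R2eff matches the closed forms where they hold", {
  nu <- seq(25, 1500, by = 125)
  # fast/intermediate exchange: the finite-T projection term is negligible
  for (k_ex in c(4000, 8000, 16000)) {
    for (dw_ppm in c(0.5, 1.5)) {
      sim <- simulate_cpmg_sq(nu, 0.1, k_ex, dw_ppm, B0 = 16.4,
                              R2_0 = 8)$R2eff
      cr <- carver_richards(nu, 0.1, k_ex, dw_rad_at(dw_ppm, 16.4), R2_0 = 8)
      expect_lt(max(abs(sim - cr) / cr), 0.01)
    }
  }
  # Luz-Meiboom in its fast-exchange validity regime
  sim <- simulate_cpmg_sq(nu, 0.1, 1e4, 0.5, B0 = 16.4, R2_0 = 8)$R2eff
  lm_ <- luz_meiboom(nu, 0.1, 1e4, dw_rad_at(0.5, 16.4), R2_0 = 8)
  expect_lt(max(abs(sim - lm_) / lm_), 0.01)
})

test_that("dispersion is flat without a minor state or shift difference", {
  nu <- seq(25, 1500, by = 125)
  expect_equal(simulate_cpmg_sq(nu, 0, 1000, 2, R2_0 = 9)$R2eff, rep(9, length(nu)))
  expect_equal(simulate_cpmg_sq(nu, 0.1, 1000, 0, R2_0 = 9)$R2eff, rep(9, length(nu)))
  expect_equal(simulate_cpmg_mq(nu[nu <= 750], 0, 1000, 1.5, 0.1,
                                R2_0 = 9)$R2eff,
               rep(9, sum(nu <= 750)))
})

test_that("SQ dispersion decays toward the population-averaged rate", {
  # fast/intermediate regime: R2eff at very high nu approaches R2_0 within 2%
  prof <- simulate_cpmg_sq(c(25, 4000), 0.15, 4000, 1.5, B0 = 16.4, R2_0 = 10)
  expect_gt(prof$R2eff[1], prof$R2eff[2])
  expect_equal(prof$R2eff[2], 10, tolerance = 0.02 * 10)
})

test_that("SQ dispersion is non-increasing in refocusing frequency", {
  nu <- c(25, 50, 100, 200, 400, 800, 1500)
  for (k_ex in c(800, 2400, 8000)) {
    prof <- simulate_cpmg_sq(nu, 0.152, k_ex, 2, B0 = 16.4, R2_0 = 10)
    expect_true(all(diff(prof$R2eff) < 1e-6))
  }
})

test_that("MQ propagation reduces to SQ carbon dispersion when dw_H = 0", {
  nu <- seq(25, 750, by = 75)
  mq <- simulate_cpmg_mq(nu, 0.166, 840, 1.5, 0, B0 = 16.4, R2_0 = 10)$R2eff
  sqc <- simulate_cpmg_sq(nu, 0.166, 840, 1.5, B0 = 16.4, nucleus = "13C",
                          R2_0 = 10)$R2eff
  expect_equal(mq, sqc, tolerance = 1e-8)
})

test_that("the reported methyl exchange regime produces a dispersive profile", {
  nu <- seq(25, 750, by = 75)
  prof <- simulate_cpmg_mq(nu, p_B = 0.166, k_ex = 1000 / 1.19,
                           dw_C_ppm = 1.5, dw_H_ppm = 0.1, B0 = 16.4,
                           R2_0 = 10)
  expect_gt(delta_r2eff(prof), 0)
})

test_that("global SQ fitting is self-consistent on noiseless data", {
  probes <- tibble::tibble(residue = 1:4, atom = "N-H",
                           dw_ppm = c(1, 1.6, 2.2, 3))
  disp <- gen_dispersion(probes, p_B = 0.12, k_ex = 2000,
                         fields = c(16.4, 21.1),
                         nu_cpmg = c(25, 50, 100, 250, 500, 1000, 1500),
                         noise = 0, seed = 1)
  disp$sigma <- 0.1   # nominal weights; data are exact
  fit <- fit_dispersion_global(disp, coherence = "SQ")
  expect_equal(fit$p_B, 0.12, tolerance = 1e-4)
  expect_equal(fit$k_ex, 2000, tolerance = 1e-4)
  expect_equal(sort(tidy(fit)$dw_ppm[!duplicated(tidy(fit)$residue)]),
               probes$dw_ppm, tolerance = 1e-3)
})

test_that("a flat probe does not perturb the shared exchange parameters", {
  probes <- tibble::tibble(residue = 1:4, atom = "N-H",
                           dw_ppm = c(1.5, 2, 2.5, 0))
  disp <- gen_dispersion(probes, p_B = 0.12, k_ex = 2000,
                         fields = c(16.4, 21.1),
                         nu_cpmg = c(25, 50, 100, 250, 500, 1000, 1500),
                         noise = 0.02, seed = 3)
  fit <- fit_dispersion_global(disp, coherence = "SQ")
  flatdw <- dplyr::filter(fit$probes, residue == 4)$dw_ppm
  expect_lt(flatdw, 0.3)
  expect_equal(fit$p_B, 0.12, tolerance = 0.15)
  expect_equal(fit$k_ex, 2000, tolerance = 0.15)
})

test_that("all-flat input triggers a degenerate-fit error", {
  probes <- tibble::tibble(residue = 1:3, atom = "N-H", dw_ppm = 0)
  disp <- gen_dispersion(probes, p_B = 0.1, k_ex = 2000,
                         nu_cpmg = c(25, 100, 500, 1500),
                         noise = 0.01, seed = 2)
  expect_error(fit_dispersion_global(disp, coherence = "SQ"), "Degenerate")
})

test_that("free-ligand equilibria obey their analytic limits", {
  expect_equal(equilibrium_free_ligand(100e-6, 0, 1e-6)$L_free, 0)
  # no binding: L_free -> L_total as K_D -> infinity
  weak <- equilibrium_free_ligand(100e-6, 50e-6, 1e3)
  expect_equal(weak$L_free, 50e-6, tolerance = 1e-6)
  # stoichiometric regime: all ligand bound
  tight <- equilibrium_free_ligand(100e-6, 50e-6, 1e-9)
  expect_lt(tight$L_free / 50e-6, 1e-3)
  expect_equal(tight$f_bound, 0.5, tolerance = 1e-3)
})

test_that("lineshapes obey the fast and slow exchange limits", {
  freq <- seq(-150, 270, by = 0.5)
  # fast exchange: single Lorentzian at the population-weighted shift
  fast <- simulate_lineshape_titration(K_D = 1e-4, k_off = 1e6,
                                       P_total = 100e-6, L_total = 100e-6,
                                       freq_Hz = freq)
  fb <- equilibrium_free_ligand(100e-6, 100e-6, 1e-4)$f_bound
  peak <- freq[which.max(fast$intensity)]
  expect_equal(peak, fb * 120, tolerance = 1)

  # slow exchange: two Lorentzians with areas proportional to populations
  slow <- simulate_lineshape_titration(K_D = 1e-4, k_off = 1e-3,
                                       P_total = 100e-6, L_total = 100e-6,
                                       freq_Hz = freq)
  area_free <- sum(slow$intensity[freq < 60]) * 0.5
  area_bound <- sum(slow$intensity[freq >= 60]) * 0.5
  expect_equal(area_bound / (area_free + area_bound), fb, tolerance = 0.01)
})

test_that("the integrated lineshape intensity is conserved across titration", {
  sp <- simulate_lineshape_titration(K_D = 3.18e-6, k_off = 48.5,
                                     P_total = 250e-6,
                                     L_total = c(0, 125e-6, 250e-6, 500e-6),
                                     freq_Hz = seq(-400, 520, by = 0.5))
  integrals <- sp |>
    dplyr::summarise(int = sum(intensity) * 0.5, .by = point) |>
    dplyr::pull(int)
  expect_lt(max(abs(integrals / integrals[1] - 1)), 1e-3)
})

test_that("lineshape titration fitting is self-consistent without noise", {
  sp <- gen_lineshape(noise = 0, seed = 1)
  fit <- fit_lineshape_titration(sp, P_total = 250e-6)
  expect_equal(fit$K_D, 3.18e-6, tolerance = 1e-3)
  expect_equal(fit$k_off, 48.5, tolerance = 1e-3)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_output(print(fit), "K_D")
})

test_that("saturated titrations raise an identifiability warning", {
  sp <- gen_lineshape(K_D = 1e-9, equivalents = c(10, 20, 40, 60, 80),
                      noise = 0, seed = 1)
  expect_warning(fit <- fit_lineshape_titration(sp, P_total = 250e-6),
                 "saturation")
  expect_equal(fit$flag, "saturated")
})
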