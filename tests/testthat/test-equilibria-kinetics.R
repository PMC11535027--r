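test_that("the monomer-dimer mass relation obeys its analytic limits", {
  M <- 12100
  expect_equal(mw_monomer_dimer(0, M, 0.013), M)
  expect_equal(mw_monomer_dimer(1e4, M, 0.013), 2 * M, tolerance = 1e-3)
  expect_equal(mw_monomer_dimer(0.013, M, 0.013), 1.5 * M, tolerance = 1e-12)
  conc <- 10^seq(-6, 0, length.out = 30)
  expect_true(all(diff(mw_monomer_dimer(conc, M, 0.013)) > 0))
})

test_that("dimer K_D fitting is exact on a well-spanned noiseless series", {
  conc <- 10^seq(log10(0.1 * 0.013), log10(10 * 0.013), length.out = 10)
  series <- tibble::tibble(conc_molar = conc,
                           mw_da = mw_monomer_dimer(conc, 12100, 0.013))
  fit <- fit_dimer_kd(series, M = 12100)
  expect_equal(fit$K_D, 0.013, tolerance = 1e-3)
  expect_false(fit$lower_limit)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("a solubility-limited series flags the estimate as a lower limit", {
  m <- gen_mals(M = 12100, K_D = 0.013, noise = 0.01, seed = 4)
  fit <- fit_dimer_kd(m, M = 12100)
  expect_true(fit$lower_limit)
  expect_equal(fit$K_D, 0.013, tolerance = 0.25)

  # a 50-fold tighter dimerisation on the same concentration range is
  # well-determined: the flag clears
  m2 <- gen_mals(M = 12100, K_D = 0.013 / 50, noise = 0.01, seed = 4)
  fit2 <- fit_dimer_kd(m2, M = 12100)
  expect_false(fit2$lower_limit)
  expect_equal(fit2$K_D, 0.013 / 50, tolerance = 0.25)
})

test_that("decreasing Mw with concentration raises a model warning", {
  bad <- tibble::tibble(conc_molar = c(1, 2, 3, 4) * 1e-4,
                        mw_da = c(14000, 13500, 13000, 12500))
  expect_warning(fit_dimer_kd(bad, M = 12100), "violated")
})

test_that("fluorescence calibration maps the span linearly and clips", {
  expect_equal(calibrate_fluorescence(1000, 1000, 5000, 20e-6), 0)
  expect_equal(calibrate_fluorescence(5000, 1000, 5000, 20e-6), 20e-6)
  expect_equal(calibrate_fluorescence(3000, 1000, 5000, 20e-6), 10e-6)
  expect_warning(p <- calibrate_fluorescence(6000, 1000, 5000, 20e-6),
                 "clipped")
  expect_equal(p, 20e-6)
  expect_error(calibrate_fluorescence(3000, 1000, 1000, 20e-6), "span")
})

test_that("initial rates recover slopes and respect the conversion window", {
  t <- seq(0, 600, 30)
  exact <- initial_rate(t, 1e-9 * t, substrate_total = 20e-6)
  expect_equal(exact$v0, 1e-9, tolerance = 1e-10)

  flat <- initial_rate(t, rep(0, length(t)), substrate_total = 20e-6)
  expect_equal(flat$v0, 0, tolerance = 1e-15)

  # integrated Michaelis-Menten oracle: v0 within 5% of vmax S0 / (Km + S0)
  pc <- gen_progress_curve(v_max = 2.89e-10, K_m = 20e-6,
                           substrate_total = 20e-6,
                           times = seq(0, 20000, 250), noise = 0, seed = 1)
  prod <- calibrate_fluorescence(pc$fluorescence, 1000, 5000, 20e-6)
  ir <- initial_rate(pc$time_s, prod, 20e-6)
  v_true <- 2.89e-10 * 20 / (20 + 20)
  expect_equal(ir$v0, v_true, tolerance = 0.05)
  expect_lte(ir$v0, v_true * 1.001)   # window underestimates, never inflates

  expect_warning(
    initial_rate(seq(0, 100, 25), seq(0, 100, 25) * 1e-7, 20e-6),
    "widened"
  )
})

test_that("Michaelis-Menten fits recover parameters and catalytic constants", {
  s <- c(0.5, 5, 10, 20, 30) * 1e-6
  v <- 3e-10 * s / (20e-6 + s)
  fit <- fit_michaelis_menten(s, v, enzyme_monomer = 510e-9)
  expect_equal(fit$v_max, 3e-10, tolerance = 1e-6)
  expect_equal(fit$K_m, 20e-6, tolerance = 1e-6)
  # the trimer is the kinetically competent unit: kcat * [trimer] = vmax
  expect_equal(fit$k_cat * fit$enzyme_trimer, fit$v_max, tolerance = 1e-12)
  expect_equal(fit$enzyme_trimer, 170e-9)
  # half-saturation identity
  expect_equal(3e-10 * fit$K_m / (fit$K_m + fit$K_m), fit$v_max / 2,
               tolerance = 1e-10)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("activation fits recover the one-site binding parameters", {
  a <- c(5, 10, 25, 50, 75, 100, 150, 200, 300) * 1e-6
  k <- 2e-3 * a / (50e-6 + a) + 1e-4
  fit <- fit_activation(a, k, n_mc = 0)
  expect_equal(fit$k_max, 2e-3, tolerance = 1e-4)
  expect_equal(fit$K_D_app, 50e-6, tolerance = 1e-3)
  expect_equal(fit$k_0, 1e-4, tolerance = 1e-2)

  # endpoints: k(0) = k_0 and k(inf) = k_max + k_0
  expect_equal(fit$k_max * 0 / (fit$K_D_app + 0) + fit$k_0, fit$k_0)
  w <- testthat::capture_warnings(fit_activation(a, rev(k), n_mc = 0))
  expect_match(w, "violated", all = FALSE)
})

test_that("gel cleavage percentages follow the band-intensity ratio", {
  expect_equal(gel_cleavage_fraction(10, 10), 0)
  expect_equal(gel_cleavage_fraction(10, 0), 100)
  expect_equal(gel_cleavage_fraction(10, 4), 60)
  expect_warning(p <- gel_cleavage_fraction(10, 12), "clipped")
  expect_equal(p, 0)
  expect_error(gel_cleavage_fraction(0, 1), "positive")
})
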