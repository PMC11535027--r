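test_that("predict_rates matches the rigid-rotor closed form at S2 = 1", {
  for (B0 in c(14.1, 16.4, 21.1)) {
    oracle <- rigid_rates_oracle(8.2e-9, B0)
    p <- predict_rates(S2 = 1, tau_c = 8.2e-9, B0 = B0)
    expect_equal(p$R1, oracle$R1, tolerance = 1e-10)
    expect_equal(p$R2, oracle$R2, tolerance = 1e-10)
    expect_equal(p$noe, oracle$noe, tolerance = 1e-10)
  }
})

test_that("internal motion reduces to the S2-scaled limit as tau_e -> 0", {
  rigid <- predict_rates(S2 = 1, tau_c = 8.2e-9, B0 = 16.4)
  fast <- predict_rates(S2 = 0.8, tau_e = 1e-15, tau_c = 8.2e-9, B0 = 16.4)
  # with tau_e -> 0 the internal term carries no spectral density: rates are
  # exactly S2-scaled
  expect_equal(fast$R1, 0.8 * rigid$R1, tolerance = 1e-4)
  expect_equal(fast$R2, 0.8 * rigid$R2, tolerance = 1e-4)
})

test_that("a degenerate axial tensor reproduces the isotropic rates", {
  tau_c <- 8.2e-9
  D <- 1 / (6 * tau_c)
  for (alpha in c(0, 0.4, 1.2, pi / 2)) {
    iso <- predict_rates(S2 = 0.85, tau_e = 3e-11, tau_c = tau_c, B0 = 16.4)
    ax <- predict_rates(S2 = 0.85, tau_e = 3e-11, D_par = D, D_perp = D,
                        alpha = alpha, B0 = 16.4)
    expect_equal(ax$R1, iso$R1, tolerance = 1e-10)
    expect_equal(ax$R2, iso$R2, tolerance = 1e-10)
  }
})

test_that("predicted hetNOE stays within the physical 15N bounds", {
  set.seed(3)
  for (i in 1:25) {
    p <- predict_rates(S2 = runif(1, 0.2, 1), tau_e = runif(1, 0, 2e-9),
                       Rex = runif(1, 0, 10), tau_c = runif(1, 1e-9, 2e-8),
                       B0 = 16.4)
    expect_gt(p$noe, -4)
    expect_lt(p$noe, 1)
  }
})

test_that("probes are filtered on a strict R2/R1 > 30 boundary", {
  rates <- tibble::tibble(residue = 1:3, atom = "N-H",
                          R1 = 1, R2 = c(31, 30, 10))
  fl <- filter_probes(rates)
  expect_equal(fl$excluded$residue, 1)
  expect_setequal(fl$retained$residue, c(2, 3))

  empty <- filter_probes(rates[0, ])
  expect_equal(nrow(empty$retained), 0)
})

test_that("tumbling estimate inverts the R2/R1 ratio on synthetic data", {
  rt <- gen_relaxation_triples(n_probes = 12, tau_c_ns = 8.2, noise = 0.01,
                               seed = 4)
  est <- estimate_tc(rt)
  expect_equal(est * 1e9, 8.2, tolerance = 0.1)

  expect_error(estimate_tc(rt[1:3, ]), "at least 5")

  # two fields agree within 5 percent on synthetic data
  rt2 <- gen_relaxation_triples(n_probes = 12, tau_c_ns = 8.2,
                                fields = c(16.4, 21.1), noise = 0.01,
                                seed = 4)
  e1 <- estimate_tc(dplyr::filter(rt2, field_T == 16.4))
  e2 <- estimate_tc(dplyr::filter(rt2, field_T == 21.1))
  expect_equal(e1 / e2, 1, tolerance = 0.05)
})

test_that("noiseless rigid data select M1 everywhere and refit exactly", {
  S2_true <- seq(0.7, 0.95, length.out = 8)
  rt <- gen_relaxation_triples(S2 = S2_true, tau_c_ns = 8.2, noise = 0,
                               seed = 1)
  # noise = 0 leaves zero errors; use nominal 1 percent weights
  rt <- dplyr::mutate(rt, R1_error = 0.01 * R1, R2_error = 0.01 * R2,
                      noe_error = 0.01 * abs(noe))
  fit <- fit_modelfree(rt)
  expect_true(all(fit$params$model == "M1"))
  expect_true(all(fit$params$Rex == 0))
  expect_equal(fit$tensor$tau_c_ns, 8.2, tolerance = 1e-4)
  expect_equal(fit$params$S2, S2_true, tolerance = 1e-4)

  # forward rates from the fitted parameters reproduce the data
  pred <- predict_rates(S2 = fit$params$S2[1],
                        tau_c = fit$tensor$tau_c_ns * 1e-9, B0 = 16.4)
  obs <- dplyr::filter(rt, residue == 1)
  expect_equal(pred$R1, obs$R1, tolerance = 1e-4)
  expect_equal(pred$R2, obs$R2, tolerance = 1e-4)
})

test_that("injected exchange is detected by model selection", {
  S2_true <- rep(0.85, 12)
  rt <- gen_relaxation_triples(S2 = S2_true, tau_c_ns = 8.2,
                               fields = c(16.4, 21.1), noise = 0.02, seed = 8)
  # add Rex = 5 1/s (at 16.4 T reference) to half the probes, field-scaled
  rex_probes <- 1:6
  rt <- dplyr::mutate(rt,
    R2 = R2 + ifelse(residue %in% rex_probes, 5 * (field_T / 16.4)^2, 0))
  fit <- fit_modelfree(rt)
  sel <- dplyr::filter(fit$params, residue %in% rex_probes)
  expect_gte(mean(sel$model %in% c("M3", "M4")), 0.9)
  expect_equal(mean(sel$Rex), 5, tolerance = 0.2)
})

test_that("axial fitting recovers an isotropic truth with unit anisotropy", {
  rt <- gen_relaxation_triples(n_probes = 24, tau_c_ns = 8.2, noise = 0.01,
                               seed = 21)
  set.seed(21)
  vecs <- tibble::tibble(residue = 1:24, atom = "N-H",
                         x = rnorm(24), y = rnorm(24), z = rnorm(24))
  nrm <- sqrt(vecs$x^2 + vecs$y^2 + vecs$z^2)
  vecs <- dplyr::mutate(vecs, x = x / nrm, y = y / nrm, z = z / nrm)
  fit <- fit_modelfree(rt, mode = "axial", vectors = vecs)
  expect_equal(fit$tensor$anisotropy, 1, tolerance = 0.05)
  expect_equal(fit$tensor$tau_c_ns, 8.2, tolerance = 0.05)
})

test_that("tidy and glance summarise model-free fits", {
  rt <- gen_relaxation_triples(n_probes = 8, tau_c_ns = 8.2, noise = 0.02,
                               seed = 12)
  fit <- fit_modelfree(rt)
  td <- tidy(fit)
  expect_true(all(c("residue", "model", "S2", "Rex") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_output(print(fit), "Model-free fit")
})
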