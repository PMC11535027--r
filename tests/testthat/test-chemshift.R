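test_that("amide and methyl CSPs follow the weighted Euclidean forms", {
  ref <- make_shift_table(1:3, h = c(8.0, 8.1, 8.2), x = c(120, 121, 122))
  per <- make_shift_table(1:3, h = c(8.1, 8.1, 8.23),
                          x = c(120, 122, 122.20))
  csp <- compute_csp_amide(ref, per)
  expect_equal(csp$csp, c(0.1, 0.2, 0.05), tolerance = 1e-12)

  refm <- make_shift_table(1:3, h = c(0.8, 0.9, 0.86), x = c(13, 14, 15),
                           x_nucleus = "13C", atom = "Ile-d1")
  perm <- make_shift_table(1:3, h = c(0.8, 0.9, 0.92),
                           x = c(13.4, 14, 15.32),
                           x_nucleus = "13C", atom = "Ile-d1")
  cspm <- compute_csp_methyl(refm, perm)
  expect_equal(cspm$csp, c(0.1, 0, 0.1), tolerance = 1e-12)
})

test_that("CSP is symmetric in table order and errors on empty overlap", {
  ref <- make_shift_table(1:4, h = rnorm(4, 8), x = rnorm(4, 120))
  per <- make_shift_table(1:4, h = rnorm(4, 8), x = rnorm(4, 120))
  expect_equal(compute_csp_amide(ref, per)$csp,
               compute_csp_amide(per, ref)$csp)
  other <- make_shift_table(10:12, h = rnorm(3, 8), x = rnorm(3, 120))
  expect_error(compute_csp_amide(ref, other), "Empty overlap")
})

test_that("significance flagging matches the mean + k SD rule", {
  csps <- tibble::tibble(residue = 1:4, atom = "N-H",
                         delta_H = 0, delta_X = 0, csp = c(0, 0, 0, 1))
  fl <- flag_significant(csps, "1SD")
  # mean 0.25, sd 0.5: only the 1.0 record exceeds 0.75
  expect_equal(fl$significant, c("none", "none", "none", "1SD"))

  same <- dplyr::mutate(csps, csp = 0.3)
  expect_warning(fl2 <- flag_significant(same, "1SD"), "SD = 0")
  expect_true(all(fl2$significant == "none"))
})

test_that("iterative corrected-to-zero flagging converges and flags outliers", {
  csps <- tibble::tibble(residue = 1:10, atom = "N-H", delta_H = 0,
                         delta_X = 0, csp = c(rep(0.01, 9), 0.5))
  fl <- flag_significant(csps, "2SD", corrected_to_zero = TRUE)
  expect_equal(sum(fl$significant == "2SD"), 1)
  expect_equal(fl$significant[10], "2SD")
  # brute-force reference: trimmed stats exclude the flagged record
  thr <- attr(fl, "threshold")
  expect_equal(thr, mean(rep(0.01, 9)) + 2 * sd(rep(0.01, 9)))
})

test_that("secondary shifts apply renormalised 1-2-1 smoothing", {
  obs <- dplyr::bind_rows(
    tibble::tibble(residue = 1:3, nucleus = "CA", shift_ppm = c(50, 54, 50)),
    tibble::tibble(residue = 1:3, nucleus = "CB", shift_ppm = c(30, 30, 30))
  )
  rc <- dplyr::bind_rows(
    tibble::tibble(residue = 1:3, nucleus = "CA", shift_ppm = 50),
    tibble::tibble(residue = 1:3, nucleus = "CB", shift_ppm = 30)
  )
  ss <- secondary_shifts(obs, rc)
  expect_equal(ss$raw, c(0, 4, 0))
  expect_equal(ss$smoothed[2], 2)           # (0 + 8 + 0) / 4
  expect_equal(ss$smoothed[1], 4 / 3)       # terminal: (2*0 + 1*4) / 3

  # zero raw profile stays zero
  ss0 <- secondary_shifts(rc, rc)
  expect_true(all(ss0$smoothed == 0))

  # two-residue flat profile: renormalised weights leave it unchanged
  obs2 <- dplyr::bind_rows(
    tibble::tibble(residue = 1:2, nucleus = "CA", shift_ppm = c(54, 54)),
    tibble::tibble(residue = 1:2, nucleus = "CB", shift_ppm = 30)
  )
  rc2 <- dplyr::filter(rc, residue <= 2)
  ss2 <- secondary_shifts(obs2, rc2)
  expect_equal(ss2$smoothed, c(4, 4))

  # smoothing never amplifies the extreme value
  set.seed(42)
  raw <- rnorm(20)
  obs3 <- dplyr::bind_rows(
    tibble::tibble(residue = 1:20, nucleus = "CA", shift_ppm = 50 + raw),
    tibble::tibble(residue = 1:20, nucleus = "CB", shift_ppm = 30)
  )
  rc3 <- dplyr::bind_rows(
    tibble::tibble(residue = 1:20, nucleus = "CA", shift_ppm = 50),
    tibble::tibble(residue = 1:20, nucleus = "CB", shift_ppm = 30)
  )
  ss3 <- secondary_shifts(obs3, rc3)
  expect_lte(max(abs(ss3$smoothed)), max(abs(ss3$raw)))
})

test_that("rotamer populations invert the 13C shift calibrations", {
  shifts <- tibble::tibble(
    residue = 1:3, atom = c("Met-e", "Ile-d1", "Ile-d1"),
    shift_ppm = c(15.9, 14.8, 12.05)
  )
  rp <- rotamer_population(shifts)
  expect_equal(rp$p_trans, c(0, 1, 0.5), tolerance = 1e-12)
  expect_equal(rp$rotamer_class, c("gauche_minus", "trans", "mixed"))

  expect_warning(
    low <- rotamer_population(tibble::tibble(residue = 1, atom = "Ile-d1",
                                             shift_ppm = 8.0)),
    "clamped"
  )
  expect_equal(low$p_trans, 0)

  expect_error(rotamer_population(tibble::tibble(residue = 1, atom = "Leu-d1",
                                                 shift_ppm = 24)),
               "Ile-d1 and Met-e")

  # calibration round trip is the identity on [0, 1]
  p <- seq(0, 1, 0.05)
  back <- rotamer_population(tibble::tibble(residue = seq_along(p),
                                            atom = "Ile-d1",
                                            shift_ppm = 9.3 + 5.5 * p))
  expect_equal(back$p_trans, p, tolerance = 1e-12)
  backm <- rotamer_population(tibble::tibble(residue = seq_along(p),
                                             atom = "Met-e",
                                             shift_ppm = 15.9 + 3.6 * p))
  expect_equal(backm$p_trans, p, tolerance = 1e-12)
})

test_that("rotamer deltas are signed with direction labels", {
  apo <- rotamer_population(tibble::tibble(residue = c(1, 2), atom = "Ile-d1",
                                           shift_ppm = 9.3 + 5.5 * c(0.8, 0.3)))
  holo <- rotamer_population(tibble::tibble(residue = c(1, 3), atom = "Ile-d1",
                                            shift_ppm = 9.3 + 5.5 * c(0.6, 0.9)))
  rd <- rotamer_delta(holo, apo)
  expect_equal(nrow(rd), 1)
  expect_equal(rd$delta_p_trans, -0.2, tolerance = 1e-12)
  expect_equal(rd$direction, "toward_gauche_minus")
  expect_setequal(attr(rd, "unmatched"), c("2 Ile-d1", "3 Ile-d1"))

  same <- rotamer_delta(apo, apo)
  expect_true(all(same$delta_p_trans == 0))
  expect_true(all(same$direction == "unchanged"))
})

test_that("NOE networks symmetrise peaks and difference by edge identity", {
  peaks <- tibble::tibble(probe_a = c("A", "B"), probe_b = c("B", "A"),
                          intensity = c(2, 4))
  net <- build_noe_network(peaks)
  expect_equal(nrow(net), 1)
  expect_equal(net$n_peaks, 2L)
  expect_equal(net$mean_intensity, 3)

  expect_warning(
    net2 <- build_noe_network(tibble::tibble(probe_a = c("A", "C"),
                                             probe_b = c("A", "D"))),
    "self-pair"
  )
  expect_equal(nrow(net2), 1)

  empty <- build_noe_network(tibble::tibble(probe_a = character(0),
                                            probe_b = character(0)))
  expect_equal(nrow(empty), 0)

  a <- build_noe_network(tibble::tibble(probe_a = c("A", "B"),
                                        probe_b = c("B", "C")))
  b <- build_noe_network(tibble::tibble(probe_a = c("B", "C"),
                                        probe_b = c("C", "D")))
  d <- diff_noe_networks(a, b)
  expect_equal(paste(d$gained$probe_a, d$gained$probe_b), "C D")
  expect_equal(paste(d$lost$probe_a, d$lost$probe_b), "A B")
  expect_equal(paste(d$retained$probe_a, d$retained$probe_b), "B C")

  self_diff <- diff_noe_networks(a, a)
  expect_equal(nrow(self_diff$gained), 0)
  expect_equal(nrow(self_diff$lost), 0)
  expect_equal(nrow(self_diff$retained), nrow(a))
})
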