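# Rate model: closed forms, calibration, and monotonicity contracts.

test_that("effective_bimolecular reproduces its closed form and limits", {
  # the printed upstream rate: 2e6 * 1 / (19 + 1) = 1e5 /M/s (5-nt toehold)
  expect_equal(effective_bimolecular(2e6, 19, 1), 1e5)
  expect_equal(effective_bimolecular(2e6, 0, 1), 2e6)   # no dissociation
  expect_equal(effective_bimolecular(2e6, 19, 0), 0)    # stalled migration
})

test_that("calibration inverts the upstream closed form exactly", {
  m <- calibrated_model()
  expect_equal(m$k_r_ref, 19)
  expect_true(m$calibrated)
  # round trip to the printed value, essentially exactly
  expect_lt(abs(effective_bimolecular(m$k_bind, m$k_r_ref, m$k_i_desired) -
                  1e5) / 1e5, 1e-10)
  # infeasible target: effective rate cannot exceed k_bind
  expect_error(calibrate_rate_model(rate_model(), k_upstream_eff = 3e6),
               "infeasible")
})

test_that("cooperative calibration matches 2e13 /M^2/s within 10% and is idempotent", {
  m <- calibrated_model()
  measured <- tempogate:::.measured_coop_rate(m, 7, 7)
  expect_lt(abs(measured - 2e13) / 2e13, 0.1)
  m2 <- calibrate_rate_model(m)
  expect_equal(m2$k_r_ref, m$k_r_ref)
  expect_equal(m2$coop_scale, m$coop_scale, tolerance = 1e-3)
})

test_that("effective rates give the 20-fold output-vs-memory advantage at c = 100 nM", {
  # (k_coop_eff * c) / k_upstream_eff with the printed lumped rates
  expect_equal(2e13 * 100e-9 / 1e5, 20)
})

test_that("effective_bimolecular is monotone in each argument", {
  kf <- c(1e5, 1e6, 2e6); kr <- c(0.1, 1, 10, 100); ki <- c(0.01, 0.1, 1, 10)
  for (r in kr) for (i in ki)
    expect_false(is.unsorted(effective_bimolecular(kf, r, i)))
  for (f in kf) for (i in ki)
    expect_false(is.unsorted(rev(effective_bimolecular(f, kr, i))))
  for (f in kf) for (r in kr)
    expect_false(is.unsorted(effective_bimolecular(f, r, ki)))
})

test_that("toehold dissociation falls per-nucleotide and rejects bad models", {
  m <- rate_model()
  lens <- 3:8
  ks <- vapply(lens, function(L) toehold_dissociation(m, L), 0)
  expect_false(is.unsorted(rev(ks)))
  expect_equal(ks[1L] / ks[2L], 20)
  expect_error(rate_model(k_i_crosstalk_fwd = 2, k_i_crosstalk_back = 1),
               "not be faster")
})

test_that("rate_bias divides both constants of the disadvantaged pathway", {
  expect_equal(rate_bias(delta_k = 1)$pathway1, rate_bias(delta_k = 1)$pathway2)
  b5 <- rate_bias(1e5, 2e13, 5)
  expect_equal(b5$pathway1$k_s, 2e4)
  expect_equal(b5$pathway1$k_f, 4e12)
  b2 <- rate_bias(1e5, 2e13, 2)
  expect_equal(b2$pathway1$k_f, 1e13)
  expect_error(rate_bias(delta_k = 0.5), ">= 1")
})
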