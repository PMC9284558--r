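# Characterization scans: separation reports, time-resolution, toehold,
# crosstalk-suppression, and rate-bias surveys.

test_that("onoff_separation computes the ratio and pass flag", {
  net <- build_abstract()
  sched <- ab_schedule(1500, c = 100, t_end = 5200)
  traj <- simulate_ode(net, schedule = sched, sample_dt = 5)
  rep <- onoff_separation(traj, on_output = "Y", off_output = "Z",
                          t_mark = 1500 + 3600)
  expect_gt(rep$ratio_1h, 2)
  expect_true(rep$passes)
  expect_equal(rep$ratio_1h, rep$conc_1h[["on"]] / rep$conc_1h[["off"]])
  # symmetric simultaneous injection gives ratio 1, fails the criterion
  sim <- simulate_ode(net, schedule = injection_schedule(
    c("A", "B"), c(0, 0), c(100, 100), t_end = 5000), sample_dt = 5)
  rep_sim <- onoff_separation(sim, "Y", "Z", t_mark = 4000)
  expect_equal(rep_sim$ratio_1h, 1, tolerance = 1e-8)
  expect_false(rep_sim$passes)
  expect_error(onoff_separation(traj, "Y", "Z", t_mark = 100),
               "after the last input")
})

test_that("unequal pathway rates worsen separation versus the balanced circuit", {
  # trimolecular model without the mismatch: the disadvantaged order's
  # separation at delta_k = 5 is worse than at delta_k = 1
  d <- gate_design(mismatch = mismatch_spec(present = FALSE),
                   conc_inputs = 100, conc_gates = 120)
  ratio_for <- function(dk) {
    net <- build_trimolecular(d, delta_k = dk)
    res <- tempogate:::.ordered_separation(net, "A", 900, 100, 3600,
                                           sample_dt = 5)
    res$report$ratio_1h
  }
  expect_lt(ratio_for(5), ratio_for(1))
})

test_that("scan_delta_t returns the smallest delay passing in both orders", {
  net <- build_abstract()
  res <- scan_delta_t(net, c = 100, dt_grid = c(300, 900, 2700),
                      t_mark_after = 3600, sample_dt = 10)
  expect_identical(nrow(res$table), 6L)
  # passing is monotone along this grid and the minimum is consistent
  passing <- with(res$table, tapply(passes, dt, all))
  expect_equal(res$min_passing_dt, min(as.numeric(names(passing))[passing]))
  # relaxing the criterion can only shorten (or keep) the minimum delay
  res_relaxed <- scan_delta_t(net, c = 100, dt_grid = c(300, 900, 2700),
                              t_mark_after = 3600, criterion = 1.2,
                              sample_dt = 10)
  expect_lte(res_relaxed$min_passing_dt, res$min_passing_dt)
  expect_error(scan_delta_t(net, dt_grid = c(0, 60)), "positive")
  expect_error(scan_delta_t(net, dt_grid = c(600, 60)), "ascending")
})

test_that("scans are deterministic: repeated invocation is bit-identical", {
  net <- build_abstract()
  r1 <- scan_delta_t(net, c = 100, dt_grid = c(600, 1800), sample_dt = 20)
  r2 <- scan_delta_t(net, c = 100, dt_grid = c(600, 1800), sample_dt = 20)
  expect_identical(r1, r2)
})

test_that("memory conversion at the trimolecular fidelity takes ~1/(k_s c) = 100 s", {
  # pseudo-first-order regime: upstream gate at c = 100 nM, trace input, so
  # the linearized timescale 1/(k_s c) applies
  tri <- build_trimolecular()
  init <- c(GA = 100, GB = 100, GaB = 100, GbA = 100, RepY = 150, RepZ = 150)
  traj <- simulate_ode(tri, init = init,
                       schedule = injection_schedule("A", 0, 5, t_end = 200),
                       sample_dt = 0.5)
  a_curve <- species_curve(traj, "A")
  t_cross <- traj$times[min(which(a_curve < 5 / exp(1) & traj$times > 0))]
  expect_gt(t_cross, 90)
  expect_lt(t_cross, 110)
})

test_that("toehold survey reproduces the designed trade-offs", {
  tab <- scan_toehold(gate_design(), c(5, 6, 7), calibrated_model(),
                      dt = 600, sample_dt = 10)
  expect_identical(tab$s_star_length, c(5, 6, 7))
  # maximum ON level is nondecreasing in the S* length
  expect_false(is.unsorted(tab$max_on))
  # the immediate-mark OFF level is nondecreasing in S* length (the
  # crosstalk-side monotonicity, read out before memory-depletion feedback)
  expect_false(is.unsorted(tab$conc_off_immediate))
  # right after the second input the computation is correct at every length
  expect_true(all(tab$passes_immediate))
})

test_that("crosstalk suppression scan returns the largest passing rate, monotonely", {
  res <- scan_crosstalk_bm_rate(gate_design(), calibrated_model(),
                                k_grid = c(0.1, 0.001), threshold = 0.05,
                                horizon = 3600, dt = 600, sample_dt = 20)
  tab <- res$table
  # monotone: if a rate suppresses, every smaller grid rate does too
  expect_false(is.unsorted(tab$suppressed[order(-tab$k_bm_fwd)]))
  expect_false(is.unsorted(rev(tab$peak_off_excess)))
  if (any(tab$suppressed))
    expect_equal(res$largest_suppressing, max(tab$k_bm_fwd[tab$suppressed]))
  expect_error(scan_crosstalk_bm_rate(gate_design(), calibrated_model(),
                                      k_grid = c(0.001, 0.1)), "descending")
})

test_that("rate-bias survey degrades the disadvantaged pathway with delta_k", {
  res <- scan_rate_bias(delta_k_grid = c(1, 2, 5), sample_dt = 10)
  tab <- res$table
  expect_identical(nrow(tab), 6L)
  # delta_k = 1: symmetric leak in the two orders
  t1 <- tab[tab$delta_k == 1, ]
  expect_equal(t1$conc_off[1L], t1$conc_off[2L], tolerance = 1e-8)
  # disadvantaged order (A first: ON produced by the slow pathway):
  # separation strictly decreasing, OFF leak strictly increasing in delta_k
  dis <- tab[tab$first_input == "A", ]
  expect_false(is.unsorted(rev(dis$ratio), strictly = TRUE))
  expect_false(is.unsorted(dis$conc_off, strictly = TRUE))
  # four output curves per bias: Y and Z under both orders
  expect_length(res$trajectories, 6L)
})
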