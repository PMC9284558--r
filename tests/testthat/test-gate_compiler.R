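# Abstract gate compilation and temporal truth-table evaluation.

test_that("the two-input abstract gate has the canonical 4-reaction structure", {
  net <- build_abstract()
  expect_length(net$species, 6L)
  expect_length(net$reactions, 4L)
  expect_identical(validate_network(net), character(0))
  # slow conversions are unimolecular at k_slow, output steps bimolecular
  orders <- vapply(net$reactions, function(r) sum(r$reactants), 0L)
  rates <- vapply(net$reactions, `[[`, 0, "rate")
  expect_identical(sort(orders), c(1L, 1L, 2L, 2L))
  expect_equal(sort(unique(rates)), c(0.002, 2e6))
  # fast/slow dominance at operating concentration: (k_f * c) / k_s = 100
  expect_equal(2e6 * 100e-9 / 0.002, 100)
  expect_error(build_abstract(abstract_gate_spec(n_inputs = 3)),
               "build_abstract_n")
})

test_that("a spec with weak fast-pathway dominance warns", {
  expect_warning(abstract_gate_spec(k_fast = 1e4, input_conc = 1),
                 "k_fast")
})

test_that("n-input generalization yields n! outputs and the derived reaction counts", {
  for (n in 2:4) {
    net <- build_abstract_n(n)
    outs <- vapply(net$species, `[[`, "", "role") == "output"
    expect_identical(sum(outs), as.integer(factorial(n)))
    expect_identical(validate_network(net), character(0))
  }
  # n = 3: 3 slow + 6 pair-memory + 6 terminal = 15 reactions; oracle:
  # enumerate ordered prefixes P and extensions x (brute force)
  inputs <- c("A", "B", "C")
  prefixes <- list()
  for (k in 1:2)
    for (p in tempogate:::.permutations(inputs))
      prefixes <- unique(c(prefixes, list(p[seq_len(k)])))
  n_fast <- as.integer(sum(vapply(prefixes, function(p) 3 - length(p), 0)))
  expect_identical(length(build_abstract_n(3)$reactions), 3L + n_fast)
  expect_identical(n_fast, 12L)  # 6 pair-memory + 6 terminal
  expect_error(build_abstract_n(5), "output species")
})

test_that("n = 2 via the generalized builder reproduces build_abstract", {
  expect_equal(build_abstract_n(2), build_abstract())
})

test_that("the simulated truth table reproduces the temporal AND logic", {
  net <- build_abstract()
  tab <- suppressWarnings(
    evaluate_truth_table(net, c = 100, dt_order = 1500, t_mark = 3600,
                         on_threshold = 0.25))
  expect_identical(nrow(tab), 12L)
  expect_true(all(tab$pass))
  # the three relative timings give the three distinct ON patterns
  on_of <- function(cond) tab$observed[tab$condition == cond]
  expect_identical(on_of("A_before_B"), c(TRUE, FALSE))
  expect_identical(on_of("B_before_A"), c(FALSE, TRUE))
  expect_identical(on_of("simultaneous"), c(TRUE, TRUE))
  # missing-input conditions are OFF at exactly zero, threshold-independent
  expect_identical(tab$conc[tab$condition %in% c("none", "A_only", "B_only")],
                   rep(0, 6L))
})

test_that("order fidelity: the permutation-matched output dominates 10-fold", {
  # with dt_order >= 10 / k_slow every prefix commits before the next input
  net <- build_abstract_n(3)
  dt <- 10 / 0.002
  sched <- injection_schedule(c("A", "B", "C"), c(0, dt, 2 * dt),
                              rep(100, 3), t_end = 2 * dt + 3600)
  state <- traj_at(simulate_ode(net, schedule = sched, sample_dt = 10),
                   2 * dt + 3600)
  outs <- state[startsWith(names(state), "O_")]
  expect_gt(outs[["O_ABC"]], 10 * max(outs[names(outs) != "O_ABC"]))
})

test_that("permuting input labels permutes outputs identically", {
  net <- build_abstract()
  c0 <- 100
  sched_ab <- ab_schedule(900, c = c0, t_end = 4500)
  sched_ba <- injection_schedule(c("B", "A"), c(0, 900), c(c0, c0),
                                 t_end = 4500)
  end_ab <- traj_at(simulate_ode(net, schedule = sched_ab), 4500)
  end_ba <- traj_at(simulate_ode(net, schedule = sched_ba), 4500)
  swap <- c(A = "B", B = "A", a = "b", b = "a", Y = "Z", Z = "Y")
  expect_equal(unname(end_ab[names(swap)]), unname(end_ba[unname(swap)]),
               tolerance = 1e-9)
})
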