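# Network data model, validation, conservation laws, and the ODE backend.

test_that("validate_network accepts conserving networks and pinpoints violations", {
  net <- build_abstract()
  expect_identical(validate_network(net), character(0))

  # dropping a strand from a composition breaks conservation in one reaction
  broken <- crn_network(
    species = list(crn_species("A", "input", "A"),
                   crn_species("Y", "output", c("A", "B"))),
    reactions = list(crn_reaction("A", "Y", 0.01, "/s", label = "bad")))
  v <- validate_network(broken)
  expect_length(v, 1L)
  expect_match(v, "strand B not conserved")

  # undeclared species are reported, not raised
  undecl <- crn_network(
    species = list(crn_species("A", "input", "A")),
    reactions = list(crn_reaction("A", "Q", 1, "/s", label = "r")))
  expect_match(validate_network(undecl), "undeclared species Q", all = FALSE)

  # generated detailed network is validator-clean
  det <- build_detailed(gate_design(), calibrated_model())
  expect_identical(validate_network(det), character(0))
})

test_that("reaction constructor enforces order/unit consistency", {
  expect_error(crn_reaction(c("A", "B"), "C", 1, "/s"), "inconsistent")
  expect_error(crn_reaction("A", "B", -1), "positive")
  expect_error(crn_reaction(c("A", "A", "B", "B"), "C", 1), "order")
  # /M2/s is accepted as a synonym and canonicalized
  r <- crn_reaction(c("A", "B", "C"), "D", 1, "/M2/s")
  expect_identical(r$units, "/M^2/s")
})

test_that("conserved_quantities returns one strand total per base strand", {
  net <- build_abstract()
  cq <- conserved_quantities(net)
  expect_setequal(names(cq), c("A", "B"))
  # each combination has zero net change under every reaction
  N <- tempogate:::.net_matrix(net)
  for (w in cq) expect_true(all(abs(t(w) %*% N) == 0))

  # detailed network: the cooperative-gate bottom strand total spans the
  # gate, all its bound intermediates, the open-middle complex, and waste
  det <- build_detailed(gate_design(), calibrated_model())
  cq_det <- conserved_quantities(det)
  expect_true("botAB" %in% names(cq_det))
  carriers <- names(cq_det$botAB)[cq_det$botAB > 0]
  expect_true(all(c("GaB", "a.GaB", "GaB.B", "a.GaB.B", "a.GaB.b",
                    "a.GaBm.b", "GBx", "WaB") %in% carriers))

  expect_identical(conserved_quantities(crn_network()), list())
})

test_that("ODE simulation respects the abstract gate's symmetry and reachability", {
  net <- build_abstract()
  # both inputs together: Y(t) = Z(t) for all t by A<->B, Y<->Z symmetry
  sched <- injection_schedule(c("A", "B"), c(0, 0), c(100, 100), t_end = 2000)
  traj <- simulate_ode(net, schedule = sched)
  expect_lt(max(abs(species_curve(traj, "Y") - species_curve(traj, "Z"))),
            1e-8)
  # a single input cannot produce any output, at any time, exactly
  traj_a <- simulate_ode(net, schedule = injection_schedule("A", 0, 100,
                                                            t_end = 4000))
  expect_identical(max(species_curve(traj_a, "Y")), 0)
  expect_identical(max(species_curve(traj_a, "Z")), 0)
})

test_that("stiff trajectory matches the fixed-step RK4 oracle", {
  net <- build_abstract()
  y0 <- stats::setNames(c(100, 0, 0, 0, 0, 0), species_names(net))
  # segment 1: A alone for 150 s; segment 2: add B, run to 300 s
  y_rk <- rk4_integrate(net, y0, 0, 150, dt = 0.01)
  y_rk["B"] <- y_rk["B"] + 100
  y_rk <- rk4_integrate(net, y_rk, 150, 300, dt = 0.01)

  sched <- injection_schedule(c("A", "B"), c(0, 150), c(100, 100),
                              t_end = 300)
  y_ros <- traj_at(simulate_ode(net, schedule = sched), 300)
  rel <- abs(y_ros - y_rk) / pmax(abs(y_rk), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("ordered injection drives Y toward c while Z stays near zero", {
  # A at t = 0, B at t = 1500 s, c = 100 nM: the committed memory routes
  # essentially all of B into Y
  net <- build_abstract()
  sched <- ab_schedule(1500, c = 100, t_end = 5100)
  y_end <- traj_at(simulate_ode(net, schedule = sched), 5100)
  expect_gt(y_end[["Y"]], 90)
  expect_lt(y_end[["Z"]], 5)
  # cross-check the endpoint against the RK4 oracle at coarse dt
  y0 <- stats::setNames(numeric(6), species_names(net))
  y0["A"] <- 100
  y_rk <- rk4_integrate(net, y0, 0, 1500, dt = 0.05)
  y_rk["B"] <- y_rk["B"] + 100
  y_rk <- rk4_integrate(net, y_rk, 1500, 5100, dt = 0.05)
  expect_lt(max(abs(y_end - y_rk) / pmax(abs(y_rk), 1e-6)), 1e-4)
})

test_that("trajectories record injection jumps and conserve strands", {
  net <- build_trimolecular()
  sched <- ab_schedule(600, c = 90, t_end = 1800)
  traj <- simulate_ode(net, schedule = sched, sample_dt = 5)

  # the injected species jumps by exactly the added concentration
  iB <- which(traj$times == 600)
  expect_length(iB, 2L)
  bcol <- which(traj$species == "B")
  expect_equal(unname(traj$conc[iB[2L], bcol] - traj$conc[iB[1L], bcol]), 90,
               tolerance = 1e-10)

  # strand totals are constant between events up to solver tolerance
  st <- strand_totals(net, traj)
  post <- seq_along(traj$times) >= iB[2L]
  drift <- apply(st[post, , drop = FALSE], 2L, function(x) diff(range(x)))
  expect_lt(max(drift), 10 * traj$rtol * max(st))

  # nonnegativity within solver slack
  expect_gt(min(traj$conc), -100 * traj$atol)
})

test_that("integration reports the failing segment on impossible tolerances", {
  net <- build_abstract()
  sched <- injection_schedule("A", 0, 100, t_end = 10)
  expect_error(
    simulate_ode(net, schedule = sched, rtol = 1e-300, atol = 1e-320),
    "segment")
})
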