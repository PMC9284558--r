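# Strand-displacement model builders: trimolecular network, elementary-step
# expansions, and the detailed model's characteristic behaviors.

test_that("trimolecular network has the enumerated reaction inventory", {
  tri <- build_trimolecular(include_crosstalk = TRUE,
                            include_reporters = TRUE)
  # 2 upstream + 2 cooperative + 4 crosstalk half-reactions + 2 reporter
  expect_length(tri$reactions, 10L)
  expect_identical(validate_network(tri), character(0))
  labs <- vapply(tri$reactions, `[[`, "", "label")
  expect_setequal(labs, c("upstream_A", "upstream_B", "coop_Y", "coop_Z",
                          "crosstalk_Y_fwd", "crosstalk_Y_rev",
                          "crosstalk_Z_fwd", "crosstalk_Z_rev",
                          "report_Y", "report_Z"))
  # crosstalk reversible pairs are linked
  expect_identical(count_reactions(tri), 8L)
  no_x <- build_trimolecular(include_crosstalk = FALSE)
  expect_length(no_x$reactions, 6L)
  expect_error(build_trimolecular(delta_k = 0.5), ">= 1")
})

test_that("balanced pathways leak symmetrically at the trimolecular fidelity", {
  tri <- build_trimolecular(delta_k = 1)
  sched_ab <- ab_schedule(900, c = 90, t_end = 4500)
  sched_ba <- injection_schedule(c("B", "A"), c(0, 900), c(90, 90),
                                 t_end = 4500)
  end_ab <- traj_at(simulate_ode(tri, schedule = sched_ab, sample_dt = 5), 4500)
  end_ba <- traj_at(simulate_ode(tri, schedule = sched_ba, sample_dt = 5), 4500)
  # OFF-output leak identical under pathway exchange
  expect_equal(end_ab[["FluoZ"]], end_ba[["FluoY"]], tolerance = 1e-8)
  expect_equal(end_ab[["FluoY"]], end_ba[["FluoZ"]], tolerance = 1e-8)
})

test_that("desired expansion yields 5 reactions (binding pairs collapsed) and 3 intermediates", {
  tri <- build_trimolecular(include_crosstalk = FALSE,
                            include_reporters = FALSE)
  rxn <- tri$reactions[[which(vapply(tri$reactions, `[[`, "", "label") ==
                                "coop_Y")]]
  ex <- expand_irreversible_trimolecular(
    rxn, tri$species, rates = list(k_f = 2e6, k_r_left = 0.5,
                                   k_r_right = 0.5, k_i = 1))
  expect_length(ex$reactions, 9L)          # unidirectional
  expect_identical(count_reactions(ex$reactions), 5L)  # as drawn
  expect_setequal(vapply(ex$species, `[[`, "", "name"),
                  c("a.GaB", "GaB.B", "a.GaB.B"))
  # the expansion is strand-conserving in context
  net <- crn_network(c(tri$species, ex$species), ex$reactions, "detailed")
  expect_identical(validate_network(net), character(0))
  # only trimolecular reactions expand
  expect_error(expand_irreversible_trimolecular(
    tri$reactions[[1L]], tri$species, list()), "trimolecular")
})

test_that("crosstalk expansion yields 6 reactions with the shared step de-duplicated", {
  tri <- build_trimolecular(include_crosstalk = TRUE,
                            include_reporters = FALSE)
  labs <- vapply(tri$reactions, `[[`, "", "label")
  rxn <- tri$reactions[[which(labs == "crosstalk_Y_fwd")]]
  rates <- list(k_f = 2e6, k_r_left = 0.5, k_r_right = 0.5,
                k_i_fwd = 0.1, k_i_back = 1, k_r_mid = 19)
  ex <- expand_reversible_trimolecular(rxn, tri$species, rates,
                                       first_memory = "a")
  expect_length(ex$reactions, 8L)
  expect_identical(count_reactions(ex$reactions), 6L)
  expect_setequal(vapply(ex$species, `[[`, "", "name"),
                  c("a.GaB", "a.GaB.b", "a.GaBm.b"))

  # assembled detailed network keeps the shared binding reaction exactly once
  det <- build_detailed(gate_design(), calibrated_model())
  det_labs <- vapply(det$reactions, `[[`, "", "label")
  expect_identical(sum(det_labs == "bind_a.GaB"), 1L)
  expect_identical(anyDuplicated(det_labs), 0L)
  # 4 bimolecular kept + 2 x 9 desired + 2 x 6 new crosstalk = 34; drawn:
  # 4 + 2 x 5 + 2 x 5 = 24
  expect_length(det$reactions, 34L)
  expect_identical(count_reactions(det), 24L)
})

test_that("QSS: expansion's lumped rate matches k_f^2 k_i / (k_r_l k_r_r) when dissociation dominates", {
  k_f <- 2e6; k_r <- 100; k_i <- 1  # k_r >> k_i
  qss <- (k_f * 1e-9)^2 * k_i / (k_r * k_r) * 1e18
  measured <- tempogate:::.measured_coop_rate_elem(k_f, k_r, k_r, k_i)
  expect_lt(abs(measured - qss) / qss, 0.05)
})

test_that("severed crosstalk branch migration produces exactly zero OFF output", {
  tri <- build_trimolecular(include_crosstalk = TRUE,
                            include_reporters = FALSE)
  labs <- vapply(tri$reactions, `[[`, "", "label")
  rxn <- tri$reactions[[which(labs == "crosstalk_Y_fwd")]]
  ex <- expand_reversible_trimolecular(
    rxn, tri$species,
    rates = list(k_f = 2e6, k_r_left = 0.5, k_r_right = 0.5,
                 k_i_fwd = 1e-30, k_i_back = 1, k_r_mid = 19),
    first_memory = "a")
  # crosstalk-only network: memories a and b plus the gate, no input B
  net <- crn_network(c(tri$species, ex$species), ex$reactions, "detailed")
  traj <- simulate_ode(net, init = c(a = 50, b = 50, GaB = 100),
                       schedule = injection_schedule(t_end = 2000))
  expect_lt(max(species_curve(traj, "Y")), 1e-20)
})

test_that("shorter S* toeholds dissociate faster on the crosstalk side", {
  m <- calibrated_model()
  expect_gt(toehold_dissociation(m, 5, cooperative = TRUE),
            toehold_dissociation(m, 7, cooperative = TRUE))
  d5 <- gate_design(s_star_length = 5)
  d7 <- gate_design(s_star_length = 7)
  r_of <- function(net, lab) {
    labs <- vapply(net$reactions, `[[`, "", "label")
    net$reactions[[which(labs == lab)]]$rate
  }
  n5 <- build_detailed(d5, m); n7 <- build_detailed(d7, m)
  expect_gt(r_of(n5, "diss_GaB.B"), r_of(n7, "diss_GaB.B"))
})

test_that("a lone input is transiently sequestered on cooperative gates but yields no output", {
  det <- build_detailed(gate_design(), calibrated_model())
  sched <- injection_schedule("A", 0, 90, t_end = 3600)
  traj <- simulate_ode(det, schedule = sched, sample_dt = 5)
  expect_lt(max(species_curve(traj, "FluoY")), 1e-8)
  expect_lt(max(species_curve(traj, "FluoZ")), 1e-8)
  # free A dips below what upstream consumption alone would leave, because
  # some A parks on the far cooperative gate's open toehold
  seq_complex <- species_curve(traj, "GbA.A")
  expect_gt(max(seq_complex), 1)          # nM-scale transient binding
})

test_that("build_detailed demands a calibrated rate model", {
  expect_error(build_detailed(gate_design(), rate_model()), "calibration")
})

test_that("detailed trajectories converge to trimolecular ones when binding equilibrates fast", {
  # same lumped rate, dissociation and binding scaled up 30x: QSS sharpens
  m <- calibrated_model()
  lam <- 100
  fast <- rate_model(k_bind = m$k_bind * lam, per_nt_factor = m$per_nt_factor,
                     k_r_ref = m$k_r_ref * lam,
                     k_i_desired = m$k_i_desired,
                     k_i_crosstalk_fwd = m$k_i_crosstalk_fwd,
                     k_i_crosstalk_back = m$k_i_crosstalk_back,
                     k_r_mid = m$k_r_mid, coop_scale = m$coop_scale)
  fast$calibrated <- TRUE  # same lumped cooperative rate by construction
  d <- gate_design()
  det <- build_detailed(d, fast, include_crosstalk = FALSE)
  tri <- build_trimolecular(d, include_crosstalk = FALSE)
  sched <- ab_schedule(600, c = 90, t_end = 3600)
  tr_det <- simulate_ode(det, schedule = sched, sample_dt = 10)
  tr_tri <- simulate_ode(tri, schedule = sched, sample_dt = 10)
  dev <- max(abs(species_curve(tr_det, "FluoY") -
                   species_curve(tr_tri, "FluoY")))
  expect_lt(dev, 0.05 * 90)
})
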