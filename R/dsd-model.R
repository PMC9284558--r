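#' Compile the trimolecular-fidelity strand-displacement network
#'
#' The two-input gate at the fidelity where cooperative hybridization is a
#' single trimolecular step. Desired pathways: each input displaces its
#' memory strand from an upstream gate (irreversible bimolecular, rates
#' `k_s1 = k_s2/delta_k` and `k_s2`), and a memory strand plus the other
#' input react with a cooperative gate to release an output (irreversible
#' trimolecular, rates `k_f1 = k_f2/delta_k` and `k_f2`). Crosstalk: the two
#' memory strands can reversibly react with either cooperative gate as two
#' cooperative inputs, producing undesired output; the pair on the second
#' gate is generated by symmetry. Reporters irreversibly convert each output
#' into a fluorophore signal.
#'
#' Crosstalk rate constants are not printed at this fidelity; they are
#' derived from the elementary rates by quasi-steady-state lumping: forward
#' = the desired cooperative rate scaled by the branch-migration slowdown
#' `k'_i / k_i` (the mismatch's entire effect), backward =
#' `k_bind * k_i_back / (k_i_back + k_r_mid)`.
#'
#' @param design A [gate_design()].
#' @param k_s2 Upstream displacement rate of pathway 2, /M/s. Default 1e5
#'   (a 5-nt toehold).
#' @param k_f2 Cooperative hybridization rate of pathway 2, /M^2/s. Default
#'   2e13 (a 7-nt toehold).
#' @param delta_k Rate bias between the pathways, `>= 1`; pathway 1 (the
#'   Y-producing one) is the slower.
#' @param include_crosstalk Add the reversible crosstalk reactions?
#' @param include_reporters Add the reporter reactions?
#' @param rmodel Rate model used to derive crosstalk constants.
#' @param reporter_rate Reporter displacement rate, /M/s. Default 1e6.
#' @return A conservation-valid `crn_network` (fidelity `"trimolecular"`)
#'   with gate/reporter initial concentrations in `metadata$init`.
#' @export
build_trimolecular <- function(design = gate_design(), k_s2 = 1e5,
                               k_f2 = 2e13, delta_k = 1,
                               include_crosstalk = TRUE,
                               include_reporters = TRUE,
                               rmodel = rate_model(),
                               reporter_rate = 1e6) {
  stopifnot(inherits(design, "gate_design"), k_s2 > 0, k_f2 > 0)
  if (delta_k < 1)
    stop("delta_k must be >= 1 (pathway 1 is the slower one by convention)")
  bias <- rate_bias(k_s2, k_f2, delta_k)

  species <- list(
    crn_species("A", "input", "A"),
    crn_species("B", "input", "B"),
    crn_species("GA", "gate", c("a", "botA")),
    crn_species("GB", "gate", c("b", "botB")),
    crn_species("a", "memory", "a"),
    crn_species("b", "memory", "b"),
    crn_species("WA", "waste", c("A", "botA")),
    crn_species("WB", "waste", c("B", "botB")),
    crn_species("GaB", "cooperative_gate", c("Y", "botAB")),
    crn_species("GbA", "cooperative_gate", c("Z", "botBA")),
    crn_species("Y", "output", "Y"),
    crn_species("Z", "output", "Z"),
    crn_species("WaB", "waste", c("a", "B", "botAB")),
    crn_species("WbA", "waste", c("b", "A", "botBA")))

  reactions <- list(
    crn_reaction(c("A", "GA"), c("a", "WA"), bias$pathway1$k_s, "/M/s",
                 label = "upstream_A"),
    crn_reaction(c("B", "GB"), c("b", "WB"), bias$pathway2$k_s, "/M/s",
                 label = "upstream_B"),
    crn_reaction(c("a", "GaB", "B"), c("Y", "WaB"), bias$pathway1$k_f,
                 "/M^2/s", label = "coop_Y"),
    crn_reaction(c("b", "GbA", "A"), c("Z", "WbA"), bias$pathway2$k_f,
                 "/M^2/s", label = "coop_Z"))

  init <- c(GA = design$conc_gates, GB = design$conc_gates,
            GaB = design$conc_gates, GbA = design$conc_gates)

  if (include_crosstalk) {
    species <- c(species, list(
      crn_species("GBx", "intermediate", c("a", "b", "botAB")),
      crn_species("GAx", "intermediate", c("a", "b", "botBA"))))
    slow <- .crosstalk_bm_rate(design, rmodel)
    k_x_fwd1 <- bias$pathway1$k_f * slow / rmodel$k_i_desired
    k_x_fwd2 <- bias$pathway2$k_f * slow / rmodel$k_i_desired
    k_x_rev <- rmodel$k_bind * rmodel$k_i_crosstalk_back /
      (rmodel$k_i_crosstalk_back + rmodel$k_r_mid)
    reactions <- c(reactions, list(
      crn_reaction(c("a", "GaB", "b"), c("Y", "GBx"), k_x_fwd1, "/M^2/s",
                   label = "crosstalk_Y_fwd",
                   reversible_partner = "crosstalk_Y_rev"),
      crn_reaction(c("Y", "GBx"), c("a", "GaB", "b"), k_x_rev, "/M/s",
                   label = "crosstalk_Y_rev",
                   reversible_partner = "crosstalk_Y_fwd"),
      crn_reaction(c("b", "GbA", "a"), c("Z", "GAx"), k_x_fwd2, "/M^2/s",
                   label = "crosstalk_Z_fwd",
                   reversible_partner = "crosstalk_Z_rev"),
      crn_reaction(c("Z", "GAx"), c("b", "GbA", "a"), k_x_rev, "/M/s",
                   label = "crosstalk_Z_rev",
                   reversible_partner = "crosstalk_Z_fwd")))
  }

  outputs <- c(Y = "Y", Z = "Z")
  if (include_reporters) {
    species <- c(species, list(
      crn_species("RepY", "reporter", c("fY", "qY")),
      crn_species("RepZ", "reporter", c("fZ", "qZ")),
      crn_species("FluoY", "fluorophore", "fY"),
      crn_species("FluoZ", "fluorophore", "fZ"),
      crn_species("WRepY", "waste", c("Y", "qY")),
      crn_species("WRepZ", "waste", c("Z", "qZ"))))
    reactions <- c(reactions, list(
      crn_reaction(c("Y", "RepY"), c("FluoY", "WRepY"), reporter_rate,
                   "/M/s", label = "report_Y"),
      crn_reaction(c("Z", "RepZ"), c("FluoZ", "WRepZ"), reporter_rate,
                   "/M/s", label = "report_Z")))
    init <- c(init, RepY = design$conc_reporters, RepZ = design$conc_reporters)
    outputs <- c(Y = "FluoY", Z = "FluoZ")
  }

  crn_network(species, reactions, "trimolecular",
              metadata = list(
                inputs = c("A", "B"),
                outputs = outputs,
                output_of_first = c(A = "Y", B = "Z"),
                input_conc = design$conc_inputs,
                init = init,
                memory_timescale = 1 / (bias$pathway1$k_s * 1e-9 *
                                          design$conc_inputs)))
}

# crosstalk forward branch-migration rate implied by the design's mismatch
.crosstalk_bm_rate <- function(design, rmodel) {
  mm <- design$mismatch
  if (!mm$present) return(rmodel$k_i_desired)
  if (!is.null(mm$k_fwd)) mm$k_fwd else rmodel$k_i_crosstalk_fwd
}

.crosstalk_bm_back_rate <- function(design, rmodel) {
  mm <- design$mismatch
  if (!mm$present) return(rmodel$k_i_desired)
  if (!is.null(mm$k_back)) mm$k_back else rmodel$k_i_crosstalk_back
}

# role lookup helper
.role_of <- function(species, name) {
  for (s in species) if (s$name == name) return(s$role)
  NA_character_
}
.species_by_name <- function(species, name) {
  for (s in species) if (s$name == name) return(s)
  stop("species not declared: ", name)
}
.merge_multisets <- function(...) {
  parts <- list(...)
  all <- unlist(lapply(parts, function(m) rep(names(m), m)))
  .as_multiset(all)
}

#' Expand an irreversible trimolecular cooperative reaction
#'
#' Replaces one irreversible cooperative-hybridization step
#' `memory + gate + input -> output + waste` by its elementary-step model:
#' four reversible toehold binding/dissociation reactions (memory on the
#' gate and on the input-bound gate; input on the gate and on the
#' memory-bound gate) and one irreversible unimolecular branch-migration
#' step from the doubly-bound complex. Counted with reversible binding pairs
#' collapsed ([count_reactions()]) this is 5 reactions, and it introduces
#' the three intermediates `m.G`, `G.x`, and `m.G.x`.
#'
#' @param rxn A trimolecular `crn_reaction` with one cooperative-gate, one
#'   memory, and one input reactant.
#' @param species Species declarations used to infer the reactant roles.
#' @param rates List with `k_f` (/M/s), `k_r_left` (memory side, /s),
#'   `k_r_right` (input side, /s), `k_i` (branch migration, /s).
#' @return List with `reactions` (9 unidirectional `crn_reaction`s) and
#'   `species` (the 3 new intermediate declarations).
#' @export
expand_irreversible_trimolecular <- function(rxn, species, rates) {
  stopifnot(inherits(rxn, "crn_reaction"))
  if (sum(rxn$reactants) != 3L)
    stop("expansion applies to trimolecular reactions only (order ",
         sum(rxn$reactants), ")")
  roles <- vapply(names(rxn$reactants), function(n) .role_of(species, n), "")
  gate <- names(roles)[roles == "cooperative_gate"]
  mem <- names(roles)[roles == "memory"]
  inp <- names(roles)[roles == "input"]
  if (length(gate) != 1L || length(mem) != 1L || length(inp) != 1L)
    stop("reaction must have exactly one cooperative-gate, one memory, and ",
         "one input reactant")
  stopifnot(all(c("k_f", "k_r_left", "k_r_right", "k_i") %in% names(rates)))

  g <- .species_by_name(species, gate)
  m <- .species_by_name(species, mem)
  x <- .species_by_name(species, inp)
  mg <- paste(mem, gate, sep = ".")
  gx <- paste(gate, inp, sep = ".")
  mgx <- paste(mem, gate, inp, sep = ".")

  new_species <- list(
    crn_species(mg, "intermediate", .merge_multisets(m$composition, g$composition)),
    crn_species(gx, "intermediate", .merge_multisets(g$composition, x$composition)),
    crn_species(mgx, "intermediate",
                .merge_multisets(m$composition, g$composition, x$composition)))

  products <- rep(names(rxn$products), rxn$products)
  rr <- list(
    crn_reaction(c(mem, gate), mg, rates$k_f, "/M/s",
                 label = paste0("bind_", mg),
                 reversible_partner = paste0("diss_", mg)),
    crn_reaction(mg, c(mem, gate), rates$k_r_left, "/s",
                 label = paste0("diss_", mg),
                 reversible_partner = paste0("bind_", mg)),
    crn_reaction(c(inp, gate), gx, rates$k_f, "/M/s",
                 label = paste0("bind_", gx),
                 reversible_partner = paste0("diss_", gx)),
    crn_reaction(gx, c(inp, gate), rates$k_r_right, "/s",
                 label = paste0("diss_", gx),
                 reversible_partner = paste0("bind_", gx)),
    crn_reaction(c(inp, mg), mgx, rates$k_f, "/M/s",
                 label = paste0("bind_", mgx, "_via_", mg),
                 reversible_partner = paste0("diss_", mgx, "_via_", mg)),
    crn_reaction(mgx, c(inp, mg), rates$k_r_right, "/s",
                 label = paste0("diss_", mgx, "_via_", mg),
                 reversible_partner = paste0("bind_", mgx, "_via_", mg)),
    crn_reaction(c(mem, gx), mgx, rates$k_f, "/M/s",
                 label = paste0("bind_", mgx, "_via_", gx),
                 reversible_partner = paste0("diss_", mgx, "_via_", gx)),
    crn_reaction(mgx, c(mem, gx), rates$k_r_left, "/s",
                 label = paste0("diss_", mgx, "_via_", gx),
                 reversible_partner = paste0("bind_", mgx, "_via_", gx)),
    crn_reaction(mgx, products, rates$k_i, "/s",
                 label = paste0("migrate_", mgx)))
  list(reactions = rr, species = new_species)
}

#' Expand a reversible trimolecular crosstalk reaction
#'
#' Replaces one reversible crosstalk step
#' `memory1 + gate + memory2 <-> output + open-complex` by six elementary
#' reactions, the first of which (memory1 binding the gate) already exists
#' in the desired pathway expansion and is de-duplicated at network
#' assembly: the shared memory binding, second-memory binding/unbinding on
#' the input side, mismatch-creating forward branch migration (`k_i_fwd`),
#' mismatch-eliminating backward branch migration (`k_i_back`), output
#' release by middle-toehold dissociation (`k_r_mid`), and reversible output
#' rebinding to the open-middle complex (`k_f`).
#'
#' @param rxn_fwd The forward crosstalk `crn_reaction`
#'   (`memory1 + gate + memory2 -> output + complex`).
#' @param species Species declarations (the open-middle complex must be
#'   declared, as [build_trimolecular()] does).
#' @param rates List with `k_f`, `k_r_left`, `k_r_right` (second-memory
#'   side), `k_i_fwd`, `k_i_back`, `k_r_mid`.
#' @param first_memory The memory that binds the desired (shared) side;
#'   defaults to the one named in the reaction label-independent convention
#'   that the gate's own pathway memory binds first, which must be supplied
#'   when both reactant memories are plausible.
#' @return List with `reactions` (8 unidirectional `crn_reaction`s, the
#'   shared pair first) and `species` (new intermediates, shared `m.G`
#'   first).
#' @export
expand_reversible_trimolecular <- function(rxn_fwd, species, rates,
                                           first_memory) {
  stopifnot(inherits(rxn_fwd, "crn_reaction"))
  if (sum(rxn_fwd$reactants) != 3L)
    stop("expansion applies to trimolecular reactions only (order ",
         sum(rxn_fwd$reactants), ")")
  roles <- vapply(names(rxn_fwd$reactants), function(n) .role_of(species, n), "")
  gate <- names(roles)[roles == "cooperative_gate"]
  mems <- names(roles)[roles == "memory"]
  if (length(gate) != 1L || length(mems) != 2L)
    stop("crosstalk reaction must have one cooperative-gate and two memory ",
         "reactants")
  if (missing(first_memory)) stop("first_memory must name the shared-side memory")
  stopifnot(first_memory %in% mems)
  second <- setdiff(mems, first_memory)
  prod_roles <- vapply(names(rxn_fwd$products),
                       function(n) .role_of(species, n), "")
  outp <- names(prod_roles)[prod_roles %in% c("output", "fluorophore")]
  openc <- setdiff(names(rxn_fwd$products), outp)
  if (length(outp) != 1L || length(openc) != 1L)
    stop("crosstalk products must be one output and one open-middle complex")
  stopifnot(all(c("k_f", "k_r_left", "k_r_right", "k_i_fwd", "k_i_back",
                  "k_r_mid") %in% names(rates)))

  g <- .species_by_name(species, gate)
  m1 <- .species_by_name(species, first_memory)
  m2 <- .species_by_name(species, second)
  mg <- paste(first_memory, gate, sep = ".")
  mgm <- paste(first_memory, gate, second, sep = ".")
  mgm_mig <- paste(first_memory, paste0(gate, "m"), second, sep = ".")

  new_species <- list(
    crn_species(mg, "intermediate",
                .merge_multisets(m1$composition, g$composition)),
    crn_species(mgm, "intermediate",
                .merge_multisets(m1$composition, g$composition, m2$composition)),
    crn_species(mgm_mig, "intermediate",
                .merge_multisets(m1$composition, g$composition, m2$composition)))

  rr <- list(
    crn_reaction(c(first_memory, gate), mg, rates$k_f, "/M/s",
                 label = paste0("bind_", mg),
                 reversible_partner = paste0("diss_", mg)),
    crn_reaction(mg, c(first_memory, gate), rates$k_r_left, "/s",
                 label = paste0("diss_", mg),
                 reversible_partner = paste0("bind_", mg)),
    crn_reaction(c(second, mg), mgm, rates$k_f, "/M/s",
                 label = paste0("bind_", mgm),
                 reversible_partner = paste0("diss_", mgm)),
    crn_reaction(mgm, c(second, mg), rates$k_r_right, "/s",
                 label = paste0("diss_", mgm),
                 reversible_partner = paste0("bind_", mgm)),
    crn_reaction(mgm, mgm_mig, rates$k_i_fwd, "/s",
                 label = paste0("bm_fwd_", mgm)),
    crn_reaction(mgm_mig, mgm, rates$k_i_back, "/s",
                 label = paste0("bm_back_", mgm)),
    crn_reaction(mgm_mig, c(outp, openc), rates$k_r_mid, "/s",
                 label = paste0("release_", outp, "_", mgm)),
    crn_reaction(c(outp, openc), mgm_mig, rates$k_f, "/M/s",
                 label = paste0("rebind_", outp, "_", openc)))
  list(reactions = rr, species = new_species)
}

#' Compile the detailed (elementary-step) network
#'
#' All four trimolecular reactions of the trimolecular model (two desired,
#' two crosstalk) are replaced by their elementary-step expansions
#' ([expand_irreversible_trimolecular()], 5 reactions each, and
#' [expand_reversible_trimolecular()], 6 reactions each with the shared
#' binding de-duplicated); upstream and reporter reactions stay bimolecular.
#' Elementary rates come from the calibrated [rate_model()] as functions of
#' the design's toehold lengths and mismatch, with the rate bias `delta_k`
#' applied to pathway 1's upstream rate and branch-migration rate.
#'
#' @inheritParams build_trimolecular
#' @param rmodel A calibrated [rate_model()] (see [calibrate_rate_model()]).
#' @return A conservation-valid `crn_network` (fidelity `"detailed"`).
#' @export
build_detailed <- function(design = gate_design(), rmodel, k_s2 = 1e5,
                           delta_k = 1, include_reporters = TRUE,
                           include_crosstalk = TRUE, reporter_rate = 1e6) {
  stopifnot(inherits(design, "gate_design"), inherits(rmodel, "rate_model"))
  if (!isTRUE(rmodel$calibrated))
    stop("calibration required: pass a rate model from calibrate_rate_model()")

  tri <- build_trimolecular(design, k_s2 = k_s2, k_f2 = 2e13,
                            delta_k = delta_k,
                            include_crosstalk = include_crosstalk,
                            include_reporters = include_reporters,
                            rmodel = rmodel, reporter_rate = reporter_rate)
  species <- tri$species
  k_r_left <- toehold_dissociation(rmodel, design$toehold_S$length,
                                   cooperative = TRUE)
  k_r_right <- toehold_dissociation(rmodel, design$s_star_length,
                                    cooperative = TRUE)
  bm_fwd <- .crosstalk_bm_rate(design, rmodel)
  bm_back <- .crosstalk_bm_back_rate(design, rmodel)

  labels <- vapply(tri$reactions, `[[`, "", "label")
  keep <- tri$reactions[labels %in% c("upstream_A", "upstream_B",
                                      "report_Y", "report_Z")]
  expansions <- list()
  # pathway 1 (Y) carries the 1/delta_k bias on its branch-migration rates
  for (spec in list(list(lab = "coop_Y", bias = delta_k),
                    list(lab = "coop_Z", bias = 1))) {
    rxn <- tri$reactions[[which(labels == spec$lab)]]
    expansions[[length(expansions) + 1L]] <- expand_irreversible_trimolecular(
      rxn, species,
      rates = list(k_f = rmodel$k_bind, k_r_left = k_r_left,
                   k_r_right = k_r_right,
                   k_i = rmodel$k_i_desired / spec$bias))
  }
  if (include_crosstalk) {
    for (spec in list(list(lab = "crosstalk_Y_fwd", first = "a", bias = delta_k),
                      list(lab = "crosstalk_Z_fwd", first = "b", bias = 1))) {
      rxn <- tri$reactions[[which(labels == spec$lab)]]
      expansions[[length(expansions) + 1L]] <- expand_reversible_trimolecular(
        rxn, species,
        rates = list(k_f = rmodel$k_bind, k_r_left = k_r_left,
                     k_r_right = k_r_right,
                     k_i_fwd = bm_fwd / spec$bias, k_i_back = bm_back,
                     k_r_mid = rmodel$k_r_mid),
        first_memory = spec$first)
    }
  }

  # assemble with de-duplication of the shared binding reactions/species
  reactions <- keep
  seen_labels <- vapply(reactions, `[[`, "", "label")
  sp_names <- vapply(species, `[[`, "", "name")
  for (ex in expansions) {
    for (s in ex$species) {
      if (!s$name %in% sp_names) {
        species[[length(species) + 1L]] <- s
        sp_names <- c(sp_names, s$name)
      }
    }
    for (r in ex$reactions) {
      if (r$label %in% seen_labels) next  # shared binding step, kept once
      reactions[[length(reactions) + 1L]] <- r
      seen_labels <- c(seen_labels, r$label)
    }
  }

  meta <- tri$metadata
  crn_network(species, reactions, "detailed", metadata = meta)
}
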