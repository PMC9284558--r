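#' Write a network to the plain-text CRN format
#'
#' One declaration per line. Species lines:
#' `species A ; role=input ; composition=A`, with multiset compositions
#' written as `+`-joined strand names (repeated for counts). Reaction lines:
#' `reaction a + B -> Y ; k=2e+06 ; units=/M/s ; label=output_Y`, with an
#' optional `partner=` field linking reversible pairs. `#` starts a comment.
#' Network metadata is preserved verbatim in a `meta` line (serialized JSON),
#' so `read_crn(write_crn(net))` reproduces the network exactly, including
#' species order and units.
#'
#' @param net A `crn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_crn <- function(net, path) {
  stopifnot(inherits(net, "crn_network"))
  lines <- c("# tempogate CRN v1", paste("fidelity", net$fidelity))
  for (s in net$species) {
    comp <- paste(rep(names(s$composition), s$composition), collapse = "+")
    lines <- c(lines, sprintf("species %s ; role=%s ; composition=%s",
                              s$name, s$role, comp))
  }
  for (r in net$reactions) {
    l <- sprintf("reaction %s -> %s ; k=%s ; units=%s",
                 .side_str(r$reactants), .side_str(r$products),
                 formatC(r$rate, format = "g", digits = 17), r$units)
    if (nzchar(r$label)) l <- paste0(l, " ; label=", r$label)
    if (!is.na(r$reversible_partner))
      l <- paste0(l, " ; partner=", r$reversible_partner)
    lines <- c(lines, l)
  }
  if (length(net$metadata))
    lines <- c(lines, paste("meta",
                            as.character(jsonlite::serializeJSON(net$metadata))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from the plain-text CRN format
#'
#' Parse errors (malformed lines, unknown units, rate/order mismatches)
#' carry the offending line number.
#'
#' @param path File written by [write_crn()] or hand-authored in the same
#'   format.
#' @return A `crn_network`.
#' @export
read_crn <- function(path) {
  lines <- readLines(path)
  species <- list(); reactions <- list()
  fidelity <- "abstract"; metadata <- list()
  perr <- function(i, msg) stop(sprintf("%s:%d: %s", path, i, msg),
                                call. = FALSE)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, "fidelity")) {
      fid <- trimws(sub("^fidelity", "", ln))
      if (!fid %in% c("abstract", "trimolecular", "detailed"))
        perr(i, paste("unknown fidelity:", fid))
      fidelity <- fid
    } else if (startsWith(ln, "species")) {
      body <- trimws(sub("^species", "", ln))
      parts <- trimws(strsplit(body, ";", fixed = TRUE)[[1L]])
      name <- parts[1L]
      kv <- .parse_kv(parts[-1L], i, perr)
      comp <- if (!is.null(kv$composition))
        trimws(strsplit(kv$composition, "+", fixed = TRUE)[[1L]]) else NULL
      sp <- tryCatch(crn_species(name, kv$role %||% "other", comp),
                     error = function(e) perr(i, conditionMessage(e)))
      species[[length(species) + 1L]] <- sp
    } else if (startsWith(ln, "reaction")) {
      body <- trimws(sub("^reaction", "", ln))
      parts <- trimws(strsplit(body, ";", fixed = TRUE)[[1L]])
      arrow <- strsplit(parts[1L], "->", fixed = TRUE)[[1L]]
      if (length(arrow) != 2L) perr(i, "reaction line needs exactly one '->'")
      kv <- .parse_kv(parts[-1L], i, perr)
      if (is.null(kv$k)) perr(i, "reaction line missing rate 'k='")
      rate <- suppressWarnings(as.numeric(kv$k))
      if (is.na(rate)) perr(i, paste("malformed rate constant:", kv$k))
      re <- trimws(strsplit(arrow[1L], "+", fixed = TRUE)[[1L]])
      pr <- trimws(strsplit(arrow[2L], "+", fixed = TRUE)[[1L]])
      pr <- pr[pr != "0"]
      rx <- tryCatch(
        crn_reaction(re, pr, rate, units = kv$units,
                     label = kv$label %||% "",
                     reversible_partner = kv$partner %||% NA_character_),
        error = function(e) perr(i, conditionMessage(e)))
      reactions[[length(reactions) + 1L]] <- rx
    } else if (startsWith(ln, "meta")) {
      json <- trimws(sub("^meta", "", ln))
      metadata <- tryCatch(jsonlite::unserializeJSON(json),
                           error = function(e) perr(i, "malformed meta line"))
    } else {
      perr(i, paste("unrecognized directive:", strsplit(ln, " ")[[1L]][1L]))
    }
  }
  crn_network(species, reactions, fidelity, metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_kv <- function(parts, i, perr) {
  out <- list()
  for (p in parts) {
    if (!nzchar(p)) next
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) perr(i, paste("expected key=value, got:", p))
    out[[trimws(substr(p, 1, eq - 1))]] <- trimws(substr(p, eq + 1, nchar(p)))
  }
  out
}

#' Write a trajectory as CSV
#'
#' Header `time_s, <species...>`; concentrations in the trajectory's units
#' (nM for ODE runs).
#'
#' @param traj A `crn_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "crn_trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Deterministic named test networks
#'
#' Small validated networks used across the test-suite and as CLI demo
#' input: the abstract two-input gate, the trimolecular gate with and
#' without crosstalk, the detailed elementary-step gate, and a deliberately
#' conservation-violating network (`broken`) whose single output reaction
#' drops a strand.
#'
#' @return Named list of `crn_network` objects. All entries except `broken`
#'   pass [validate_network()]; `broken` fails with exactly one violation.
#' @export
fixture_networks <- function() {
  rm_cal <- calibrate_rate_model(rate_model())
  broken <- crn_network(
    species = list(crn_species("A", "input", "A"),
                   crn_species("Y", "output", c("A", "B"))),
    reactions = list(crn_reaction("A", "Y", 0.01, "/s", label = "bad")),
    fidelity = "abstract")
  list(abstract = build_abstract(),
       trimolecular = build_trimolecular(include_crosstalk = FALSE),
       trimolecular_crosstalk = build_trimolecular(include_crosstalk = TRUE),
       detailed = build_detailed(gate_design(), rm_cal),
       broken = broken)
}

#' Minimal SBML Level 3 export
#'
#' Writes the network as an SBML Level 3 Version 2 model with mass-action
#' kinetic laws and the rate constants as local parameters (in internal
#' nM/s units, with substance in nM). Intended for interchange with CRN
#' tooling, not as a complete SBML feature surface.
#'
#' @param net A `crn_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  stopifnot(inherits(net, "crn_network"))
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "crn",
                               substanceUnits = "nanomolar",
                               timeUnits = "second")
  comp <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "cell", constant = "true",
                      size = "1")
  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (s in net$species)
    xml2::xml_add_child(los, "species", id = s$name, compartment = "cell",
                        initialConcentration = "0",
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    rx <- xml2::xml_add_child(lor, "reaction", id = sprintf("r%d", j),
                              reversible = "false")
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    for (nm in names(r$reactants))
      xml2::xml_add_child(lre, "speciesReference", species = nm,
                          stoichiometry = as.character(r$reactants[[nm]]),
                          constant = "true")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (nm in names(r$products))
      xml2::xml_add_child(lpr, "speciesReference", species = nm,
                          stoichiometry = as.character(r$products[[nm]]),
                          constant = "true")
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    terms <- unlist(lapply(names(r$reactants), function(nm)
      rep(nm, r$reactants[[nm]])))
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(xml2::xml_add_child(ap, "ci"), xml2::xml_cdata("k"))
    for (tm in terms)
      xml2::xml_add_child(xml2::xml_add_child(ap, "ci"), xml2::xml_cdata(tm))
    lp <- xml2::xml_add_child(kl, "listOfLocalParameters")
    xml2::xml_add_child(lp, "localParameter", id = "k",
                        value = formatC(r$rate * .unit_scale[[r$units]],
                                        format = "g", digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
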