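#' Declare a species of a reaction network
#'
#' A species is a single strand or a complex of strands. The `composition`
#' multiset records which base strands the species contains; it is the basis
#' of the symbolic strand-conservation checks, so every species that takes
#' part in reactions should declare it. Abstract-model signals may use the
#' default composition `{name}`.
#'
#' @param name Species identifier (letters, digits, `_` and `.`).
#' @param role One of `"input"`, `"memory"`, `"gate"`, `"cooperative_gate"`,
#'   `"intermediate"`, `"output"`, `"waste"`, `"reporter"`, `"fluorophore"`,
#'   `"other"`.
#' @param composition Character vector of base-strand names, repeated for
#'   multiple copies, or a named integer vector of counts. Defaults to the
#'   species' own name.
#' @return An object of class `crn_species`.
#' @export
crn_species <- function(name, role = "other", composition = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", name))
    stop("invalid species name: ", name)
  role <- match.arg(role, .species_roles)
  if (is.null(composition)) composition <- name
  comp <- .as_multiset(composition)
  structure(list(name = name, role = role, composition = comp),
            class = "crn_species")
}

# normalize a multiset given as repeated character vector or named counts
.as_multiset <- function(x) {
  if (is.character(x)) {
    tab <- table(x)
    out <- as.integer(tab)
    names(out) <- names(tab)
  } else if (is.numeric(x) && !is.null(names(x))) {
    stopifnot(all(x == as.integer(x)), all(x > 0))
    out <- as.integer(x)
    names(out) <- names(x)
  } else stop("multiset must be a character vector or named integer counts")
  out[order(names(out))]
}

#' Define a mass-action reaction
#'
#' Reactions are unidirectional; a reversible binding/dissociation pair is
#' represented as two reactions linked through `reversible_partner` (the
#' label of the reverse reaction), and [count_reactions()] counts such a pair
#' as a single reaction, matching how reversible arrows are drawn in reaction
#' pathway diagrams.
#'
#' @param reactants,products Character vectors of species names (repeat a name
#'   for stoichiometry > 1). Total reactant stoichiometry must be 1--3.
#' @param rate Positive rate constant in `units`.
#' @param units `"/s"`, `"/M/s"`, or `"/M^2/s"`; must match the reaction order.
#' @param label Free-text label, unique within a network if used for partners.
#' @param reversible_partner Label of the reverse reaction, or `NA`.
#' @return An object of class `crn_reaction`.
#' @export
crn_reaction <- function(reactants, products, rate,
                         units = NULL, label = "",
                         reversible_partner = NA_character_) {
  re <- .as_multiset(reactants)
  pr <- .as_multiset(products)
  ord <- sum(re)
  if (!ord %in% 1:3)
    stop("reaction order must be 1, 2, or 3; got ", ord)
  if (is.null(units)) units <- .unit_for_order[ord]
  units <- .canon_units(units)
  if (units != .unit_for_order[ord])
    stop("units '", units, "' inconsistent with reaction order ", ord,
         " (expected '", .unit_for_order[ord], "')")
  stopifnot(is.numeric(rate), length(rate) == 1L)
  if (!is.finite(rate) || rate <= 0)
    stop("rate constant must be a positive finite number")
  structure(list(reactants = re, products = pr, rate = rate, units = units,
                 label = as.character(label),
                 reversible_partner = as.character(reversible_partner)),
            class = "crn_reaction")
}

.canon_units <- function(u) {
  u <- gsub("\\s", "", u)
  map <- c("/s" = "/s", "/M/s" = "/M/s", "/M2/s" = "/M^2/s",
           "/M^2/s" = "/M^2/s")
  if (!u %in% names(map)) stop("unknown rate units: ", u)
  unname(map[u])
}

#' Assemble a reaction network
#'
#' @param species List of [crn_species()] objects.
#' @param reactions List of [crn_reaction()] objects.
#' @param fidelity `"abstract"`, `"trimolecular"`, or `"detailed"`.
#' @param metadata Free-form provenance list (initial gate concentrations,
#'   output mapping, ...). Kept serializable so CRN files round-trip.
#' @return An object of class `crn_network`.
#' @seealso [validate_network()], [simulate_ode()], [write_crn()]
#' @export
crn_network <- function(species = list(), reactions = list(),
                        fidelity = c("abstract", "trimolecular", "detailed"),
                        metadata = list()) {
  fidelity <- match.arg(fidelity)
  stopifnot(all(vapply(species, inherits, TRUE, "crn_species")),
            all(vapply(reactions, inherits, TRUE, "crn_reaction")))
  structure(list(species = species, reactions = reactions,
                 fidelity = fidelity, metadata = metadata),
            class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  cat(sprintf("<crn_network> fidelity=%s: %d species, %d reactions (%d drawn)\n",
              x$fidelity, length(x$species), length(x$reactions),
              count_reactions(x)))
  for (r in x$reactions) {
    cat(sprintf("  %s -> %s  @ %s %s%s\n",
                .side_str(r$reactants), .side_str(r$products),
                format(r$rate), r$units,
                if (!is.na(r$reversible_partner)) " (reversible)" else ""))
  }
  invisible(x)
}

.side_str <- function(ms) {
  parts <- rep(names(ms), ms)
  if (!length(parts)) "0" else paste(parts, collapse = " + ")
}

#' Species names of a network, in declaration order
#' @param net A `crn_network`.
#' @return Character vector.
#' @export
species_names <- function(net) vapply(net$species, `[[`, "", "name")

#' Count reactions, collapsing linked reversible pairs
#'
#' Reversible binding/dissociation pairs (linked through
#' `reversible_partner`) count as one reaction, as drawn with double-headed
#' arrows in pathway diagrams; all other reactions count individually.
#'
#' @param net A `crn_network` or a list of `crn_reaction`s.
#' @return Integer count.
#' @export
count_reactions <- function(net) {
  rxns <- if (inherits(net, "crn_network")) net$reactions else net
  labs <- vapply(rxns, `[[`, "", "label")
  partners <- vapply(rxns, `[[`, "", "reversible_partner")
  paired <- !is.na(partners) & partners %in% labs
  length(rxns) - sum(paired) %/% 2L
}

# species x reactions reactant stoichiometry (integer matrix)
.reactant_matrix <- function(net) {
  sp <- species_names(net)
  m <- matrix(0L, length(sp), length(net$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(net$reactions)) {
    re <- net$reactions[[j]]$reactants
    m[names(re), j] <- re
  }
  m
}

.product_matrix <- function(net) {
  sp <- species_names(net)
  m <- matrix(0L, length(sp), length(net$reactions),
              dimnames = list(sp, NULL))
  for (j in seq_along(net$reactions)) {
    pr <- net$reactions[[j]]$products
    m[names(pr), j] <- pr
  }
  m
}

.net_matrix <- function(net) .product_matrix(net) - .reactant_matrix(net)

# rate constants in internal nM/s units
.internal_rates <- function(net) {
  vapply(net$reactions, function(r) r$rate * .unit_scale[[r$units]], 0)
}

# base strand count matrix: strands x species
.strand_matrix <- function(net) {
  strands <- sort(unique(unlist(lapply(net$species,
                                       function(s) names(s$composition)))))
  m <- matrix(0L, length(strands), length(net$species),
              dimnames = list(strands, species_names(net)))
  for (s in net$species) m[names(s$composition), s$name] <- s$composition
  m
}

#' Validate a reaction network
#'
#' Checks the structural invariants: unique species names, declared species
#' in every reaction, positive rate constants with units matching the
#' reaction order, non-empty compositions, and exact (integer-arithmetic)
#' strand conservation for every reaction: the strand content of the products
#' must equal that of the reactants for every base strand.
#'
#' @param net A `crn_network`.
#' @return Character vector of violation descriptions; empty if the network
#'   is valid. Violations are returned, never raised.
#' @export
validate_network <- function(net) {
  out <- character()
  sp <- species_names(net)
  dup <- unique(sp[duplicated(sp)])
  for (d in dup) out <- c(out, paste0("duplicate species name: ", d))
  for (s in net$species)
    if (length(s$composition) == 0L)
      out <- c(out, paste0("species ", s$name, " has empty composition"))
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    who <- c(names(r$reactants), names(r$products))
    missing <- setdiff(who, sp)
    for (m in missing)
      out <- c(out, sprintf("reaction %d (%s): undeclared species %s",
                            j, r$label, m))
    ord <- sum(r$reactants)
    if (r$units != .unit_for_order[ord])
      out <- c(out, sprintf("reaction %d (%s): units %s inconsistent with order %d",
                            j, r$label, r$units, ord))
    if (!is.finite(r$rate) || r$rate <= 0)
      out <- c(out, sprintf("reaction %d (%s): non-positive rate constant",
                            j, r$label))
    if (length(missing)) next
    # symbolic strand balance
    comp <- setNames(lapply(net$species, `[[`, "composition"), sp)
    bal <- new.env()
    .acc <- function(side, sign) {
      for (nm in names(side)) {
        cm <- comp[[nm]]
        for (st in names(cm)) {
          cur <- mget(st, envir = bal, ifnotfound = 0L)[[1L]]
          assign(st, cur + sign * side[[nm]] * cm[[st]], envir = bal)
        }
      }
    }
    .acc(r$reactants, -1L)
    .acc(r$products, 1L)
    for (st in ls(bal)) {
      v <- get(st, envir = bal)
      if (v != 0L)
        out <- c(out, sprintf(
          "reaction %d (%s): strand %s not conserved (net change %+d)",
          j, r$label, st, v))
    }
  }
  out
}

#' Conserved strand totals of a network
#'
#' For each base strand appearing in the species compositions, the
#' strand-weighted total concentration is a candidate conserved quantity.
#' Each returned combination has exactly zero net change under every reaction
#' (checked in integer arithmetic on the stoichiometry matrix).
#'
#' @param net A `crn_network`.
#' @return Named list, one entry per conserved base strand, each a named
#'   integer vector of species weights. Empty networks give an empty list.
#' @export
conserved_quantities <- function(net) {
  if (length(net$species) == 0L) return(list())
  W <- .strand_matrix(net)
  if (length(net$reactions) == 0L) {
    return(setNames(lapply(seq_len(nrow(W)), function(i) W[i, ]),
                    rownames(W)))
  }
  N <- .net_matrix(net)
  keep <- apply(W %*% N == 0L, 1L, all)
  out <- lapply(which(keep), function(i) W[i, ])
  setNames(out, rownames(W)[keep])
}
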