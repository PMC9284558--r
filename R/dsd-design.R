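#' Declare a DNA domain
#'
#' @param name Domain identifier (e.g. `"T"`, `"S"`).
#' @param length Domain length in nucleotides. Toeholds must be 3--8 nt,
#'   branch migration domains longer than 10 nt.
#' @param kind `"toehold"`, `"branch"`, or `"clamp"`.
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(name, length, kind = c("toehold", "branch", "clamp")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(length), length == as.integer(length), length > 0)
  if (kind == "toehold" && !(length >= 3 && length <= 8))
    stop("toehold length must be in [3, 8] nt; got ", length)
  if (kind == "branch" && length <= 10)
    stop("branch migration domain must be > 10 nt; got ", length)
  structure(list(name = name, length = as.integer(length), kind = kind),
            class = "domain_spec")
}

#' Mismatch placement in the memory strands
#'
#' A deliberate mismatch near the toehold of each upstream gate slows the
#' mismatch-creating forward branch migration of the crosstalk pathways
#' without affecting memory release: eliminating a mismatch far from the
#' toehold proceeds at roughly the unhindered displacement rate, while
#' creating one near the toehold slows displacement strongly. Only the rate
#' class of the position is modeled, not its geometry.
#'
#' @param present Is a mismatch designed in?
#' @param position_class `"near_toehold"` (slows crosstalk forward branch
#'   migration) or `"distal"`.
#' @param k_fwd Mismatch-creating forward branch-migration rate, /s, or
#'   `NULL` to take the [rate_model()] default.
#' @param k_back Mismatch-eliminating backward rate, /s, or `NULL` for the
#'   rate-model default. Must satisfy `k_fwd <= k_back` when present.
#' @return An object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(present = TRUE,
                          position_class = c("near_toehold", "distal"),
                          k_fwd = NULL, k_back = NULL) {
  position_class <- match.arg(position_class)
  if (present && !is.null(k_fwd) && !is.null(k_back) && k_fwd > k_back)
    stop("mismatch creation (k_fwd) must not be faster than elimination (k_back)")
  structure(list(present = isTRUE(present), position_class = position_class,
                 k_fwd = k_fwd, k_back = k_back),
            class = "mismatch_spec")
}

#' Domain-level design of the two-input strand-displacement gate
#'
#' Defaults follow the characterized circuit: a 5-nt toehold T on the input
#' strands (upstream displacement), a 7-nt toehold S on the memory strands
#' (cooperative hybridization), an S* toehold of the same family on the
#' input side of the cooperative gates whose length is the main robustness
#' knob (5--7 nt), a near-toehold mismatch in each memory strand, and
#' working concentrations of 100 nM gates, 150 nM reporters, and 90 nM
#' inputs.
#'
#' @param toehold_T Input-strand toehold, a [domain_spec()] (default 5 nt).
#' @param toehold_S Memory-strand toehold (default 7 nt).
#' @param s_star_length Length of the cooperative-gate S* toehold on the
#'   input (crosstalk-prone) side, nt; must not exceed `toehold_S$length`.
#' @param mismatch A [mismatch_spec()].
#' @param gate_excess,reporter_excess Fractional excess of gates/reporters
#'   over inputs used when deriving concentrations from an input level.
#' @param conc_gates,conc_reporters,conc_inputs Working concentrations, nM.
#' @return An object of class `gate_design`.
#' @export
gate_design <- function(toehold_T = domain_spec("T", 5, "toehold"),
                        toehold_S = domain_spec("S", 7, "toehold"),
                        s_star_length = 7,
                        mismatch = mismatch_spec(),
                        gate_excess = 0.2, reporter_excess = 0.5,
                        conc_gates = 100, conc_reporters = 150,
                        conc_inputs = 90) {
  stopifnot(inherits(toehold_T, "domain_spec"), inherits(toehold_S, "domain_spec"),
            inherits(mismatch, "mismatch_spec"),
            conc_gates > 0, conc_reporters > 0, conc_inputs > 0)
  if (s_star_length > toehold_S$length)
    stop("s_star_length must not exceed the S toehold length")
  if (!s_star_length %in% 3:8)
    stop("s_star_length must be a toehold length in [3, 8] nt")
  structure(list(toehold_T = toehold_T, toehold_S = toehold_S,
                 s_star_length = as.integer(s_star_length),
                 mismatch = mismatch,
                 gate_excess = gate_excess, reporter_excess = reporter_excess,
                 conc_gates = conc_gates, conc_reporters = conc_reporters,
                 conc_inputs = conc_inputs),
            class = "gate_design")
}
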