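#' Read a run configuration file
#'
#' JSON configuration mirroring the builder arguments. Recognized top-level
#' keys: `fidelity`, `design` (fields of [gate_design()], with toehold
#' lengths as `toehold_T`/`toehold_S` integers and `mismatch` as a nested
#' object), `rate_model` (fields of [rate_model()]), `schedule`
#' (`species`/`time`/`amount` arrays plus `t_end`), `solver` (`rtol`,
#' `atol`, `sample_dt`), and `seed`. Unknown keys anywhere are rejected with
#' their location, so configs round-trip losslessly against the accepted
#' schema.
#'
#' @param path Path to a JSON config file.
#' @return List of class `run_config` with `design`, `rate_model` and
#'   `schedule` materialized as package objects.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("fidelity", "design", "rate_model", "schedule", "solver", "seed")
  .reject_unknown(raw, known, "config")
  out <- list(fidelity = raw$fidelity %||% "trimolecular", seed = raw$seed)
  if (!out$fidelity %in% c("abstract", "trimolecular", "detailed"))
    stop("config: unknown fidelity '", out$fidelity, "'")

  d <- raw$design %||% list()
  .reject_unknown(d, c("toehold_T", "toehold_S", "s_star_length", "mismatch",
                       "gate_excess", "reporter_excess", "conc_gates",
                       "conc_reporters", "conc_inputs"), "config design")
  mm <- d$mismatch %||% list()
  .reject_unknown(mm, c("present", "position_class", "k_fwd", "k_back"),
                  "config design mismatch")
  mismatch <- mismatch_spec(present = mm$present %||% TRUE,
                            position_class = mm$position_class %||% "near_toehold",
                            k_fwd = mm$k_fwd, k_back = mm$k_back)
  out$design <- gate_design(
    toehold_T = domain_spec("T", d$toehold_T %||% 5, "toehold"),
    toehold_S = domain_spec("S", d$toehold_S %||% 7, "toehold"),
    s_star_length = d$s_star_length %||% 7,
    mismatch = mismatch,
    gate_excess = d$gate_excess %||% 0.2,
    reporter_excess = d$reporter_excess %||% 0.5,
    conc_gates = d$conc_gates %||% 100,
    conc_reporters = d$conc_reporters %||% 150,
    conc_inputs = d$conc_inputs %||% 90)

  rm_ <- raw$rate_model %||% list()
  .reject_unknown(rm_, c("k_bind", "per_nt_factor", "k_r_ref", "ref_toehold",
                         "k_i_desired", "k_i_crosstalk_fwd",
                         "k_i_crosstalk_back", "k_r_mid", "coop_scale",
                         "calibrated"), "config rate_model")
  out$rate_model <- do.call(rate_model, rm_)

  if (!is.null(raw$schedule)) {
    s <- raw$schedule
    .reject_unknown(s, c("species", "time", "amount", "t_end"),
                    "config schedule")
    out$schedule <- injection_schedule(s$species %||% character(),
                                       s$time %||% numeric(),
                                       s$amount %||% numeric(), s$t_end)
  }
  sv <- raw$solver %||% list()
  .reject_unknown(sv, c("rtol", "atol", "sample_dt"), "config solver")
  out$solver <- list(rtol = sv$rtol %||% 1e-8, atol = sv$atol %||% 1e-12,
                     sample_dt = sv$sample_dt %||% 1)
  class(out) <- "run_config"
  out
}

.reject_unknown <- function(x, known, where) {
  if (!length(x)) return(invisible())
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop(sprintf("%s: unknown key(s): %s", where, paste(bad, collapse = ", ")))
  invisible()
}
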