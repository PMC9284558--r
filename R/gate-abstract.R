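#' Parameters of the abstract temporal AND gate
#'
#' The abstract chemical reaction network converts each input into a memory
#' species at a slow unimolecular rate and lets a memory react with a
#' later-arriving input at a fast bimolecular rate to produce an
#' order-specific output. Timing discrimination requires the fast pathway to
#' dominate at operating concentration: a warning is given when
#' `k_fast * c < 10 * k_slow`.
#'
#' @param n_inputs Number of inputs (2 for [build_abstract()], up to 4 for
#'   [build_abstract_n()]).
#' @param k_slow Input-to-memory conversion rate, /s. Default 0.002.
#' @param k_fast Memory + input output-production rate, /M/s. Default 2e6.
#' @param input_conc Operating input concentration c, nM. Default 100.
#' @return An object of class `abstract_gate_spec`.
#' @export
abstract_gate_spec <- function(n_inputs = 2, k_slow = 0.002, k_fast = 2e6,
                               input_conc = 100) {
  stopifnot(n_inputs >= 2, k_slow > 0, k_fast > 0, input_conc > 0)
  if (k_fast * input_conc * 1e-9 < 10 * k_slow)
    warning("k_fast * c < 10 * k_slow: output production does not dominate ",
            "memory formation; timing discrimination will be poor")
  structure(list(n_inputs = as.integer(n_inputs), k_slow = k_slow,
                 k_fast = k_fast, input_conc = input_conc),
            class = "abstract_gate_spec")
}

#' Compile the two-input abstract temporal AND network
#'
#' Produces the four-reaction network: `A -> a` and `B -> b` at `k_slow`
#' (memory formation), `a + B -> Y` and `b + A -> Z` at `k_fast`
#' (order-specific output production). Y reports "A before B", Z reports
#' "B before A"; simultaneous arrival turns both on.
#'
#' @param spec An [abstract_gate_spec()] with `n_inputs = 2`.
#' @return A `crn_network` (fidelity `"abstract"`), conservation-valid, with
#'   `metadata$inputs`, `metadata$outputs`, and `metadata$input_conc` set.
#' @export
build_abstract <- function(spec = abstract_gate_spec()) {
  stopifnot(inherits(spec, "abstract_gate_spec"))
  if (spec$n_inputs != 2L)
    stop("build_abstract() compiles the two-input gate only; ",
         "use build_abstract_n() for n >= 3")
  species <- list(
    crn_species("A", "input", "A"),
    crn_species("B", "input", "B"),
    crn_species("a", "memory", "A"),
    crn_species("b", "memory", "B"),
    crn_species("Y", "output", c("A", "B")),
    crn_species("Z", "output", c("A", "B")))
  reactions <- list(
    crn_reaction("A", "a", spec$k_slow, "/s", label = "memory_A"),
    crn_reaction("B", "b", spec$k_slow, "/s", label = "memory_B"),
    crn_reaction(c("a", "B"), "Y", spec$k_fast, "/M/s", label = "output_Y"),
    crn_reaction(c("b", "A"), "Z", spec$k_fast, "/M/s", label = "output_Z"))
  crn_network(species, reactions, "abstract",
              metadata = list(inputs = c("A", "B"),
                              outputs = c(Y = "Y", Z = "Z"),
                              output_of_first = c(A = "Y", B = "Z"),
                              input_conc = spec$input_conc,
                              memory_timescale = 1 / spec$k_slow))
}

# all permutations of a character vector
.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  out
}

#' Compile an n-input abstract temporal AND network
#'
#' Generalizes the two-input gate: memory species encode every ordered prefix
#' of arrivals (first-order memories for single inputs, ordered-pair memories
#' for two, and so on), and each full arrival permutation has its own output
#' species, giving `n!` distinct output decisions. A prefix memory reacts
#' with a not-yet-seen current input at `k_fast` to extend the prefix; the
#' final extension releases the permutation-specific output.
#'
#' @param n Number of inputs, 2--4 (combinatorial growth: the network has
#'   `sum(k=1..n) n!/(n-k)!` memory/output species).
#' @param spec Rate parameters, an [abstract_gate_spec()].
#' @return A `crn_network` with `n!` output species.
#' @export
build_abstract_n <- function(n, spec = abstract_gate_spec(n_inputs = n)) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (n > 4L) {
    n_out <- factorial(n)
    stop(sprintf(paste0(
      "n = %d not supported: the construction needs %d output species and ",
      "%d ordered-prefix memories; networks beyond n = 4 are impractical"),
      n, n_out, sum(vapply(1:(n - 1L), function(k) prod(n:(n - k + 1L)), 0))))
  }
  if (n == 2L) return(build_abstract(abstract_gate_spec(
    2, spec$k_slow, spec$k_fast, spec$input_conc)))

  inputs <- LETTERS[seq_len(n)]
  species <- lapply(inputs, function(i) crn_species(i, "input", i))
  reactions <- list()
  mem_name <- function(p) paste0("m_", paste(p, collapse = ""))
  out_name <- function(p) paste0("O_", paste(p, collapse = ""))

  prefixes <- list()
  for (k in seq_len(n - 1L))
    for (p in .permutations(inputs))
      prefixes[[length(prefixes) + 1L]] <- p[seq_len(k)]
  prefixes <- unique(prefixes)

  for (p in prefixes)
    species[[length(species) + 1L]] <- crn_species(mem_name(p), "memory", p)
  for (p in .permutations(inputs))
    species[[length(species) + 1L]] <- crn_species(out_name(p), "output", p)

  for (i in inputs)
    reactions[[length(reactions) + 1L]] <-
      crn_reaction(i, mem_name(i), spec$k_slow, "/s",
                   label = paste0("memory_", i))
  for (p in prefixes) {
    for (x in setdiff(inputs, p)) {
      ext <- c(p, x)
      prod_name <- if (length(ext) == n) out_name(ext) else mem_name(ext)
      reactions[[length(reactions) + 1L]] <-
        crn_reaction(c(mem_name(p), x), prod_name, spec$k_fast, "/M/s",
                     label = paste0("extend_", paste(ext, collapse = "")))
    }
  }
  outs <- vapply(.permutations(inputs), out_name, "")
  crn_network(species, reactions, "abstract",
              metadata = list(inputs = inputs,
                              outputs = setNames(outs, outs),
                              input_conc = spec$input_conc,
                              memory_timescale = 1 / spec$k_slow))
}

#' Expected truth table of the two-input temporal AND gate
#'
#' Six input conditions: both absent, each alone, and both present with the
#' three relative timings. Output Y is ON only when A arrives no later than
#' B, Z only when B arrives no later than A; simultaneous arrival turns both
#' on, and any missing input keeps both off.
#'
#' @return Data frame with columns `condition`, `output`, `expected`.
#' @export
expected_truth_table <- function() {
  conds <- c("none", "A_only", "B_only", "A_before_B", "B_before_A",
             "simultaneous")
  expect <- list(none = c(Y = FALSE, Z = FALSE),
                 A_only = c(Y = FALSE, Z = FALSE),
                 B_only = c(Y = FALSE, Z = FALSE),
                 A_before_B = c(Y = TRUE, Z = FALSE),
                 B_before_A = c(Y = FALSE, Z = TRUE),
                 simultaneous = c(Y = TRUE, Z = TRUE))
  do.call(rbind, lapply(conds, function(cn)
    data.frame(condition = cn, output = names(expect[[cn]]),
               expected = unname(expect[[cn]]), stringsAsFactors = FALSE)))
}

#' Simulate and classify all six input conditions of a two-input gate
#'
#' Each condition is simulated with the network's default initial state
#' (gates and reporters for strand-displacement fidelities); an output is
#' classified ON when its measured concentration, `t_mark` seconds after the
#' last input addition, reaches `on_threshold * c`. Measured species are the
#' fluorophores when reporters are present, the free outputs otherwise.
#'
#' @param net A network built by [build_abstract()], [build_trimolecular()],
#'   or [build_detailed()] (two-input).
#' @param c Input concentration in nM (default: network metadata).
#' @param dt_order Delay between first and second input for the ordered
#'   conditions, seconds. A warning is given when shorter than five memory
#'   conversion timescales.
#' @param t_mark Classification time after the last input, seconds.
#' @param on_threshold ON classification threshold as a fraction of `c`.
#' @param sample_dt Output grid spacing passed to [simulate_ode()].
#' @return Data frame: `condition`, `output`, `expected`, `observed`,
#'   `conc`, `pass`.
#' @export
evaluate_truth_table <- function(net, c = NULL, dt_order = 1500,
                                 t_mark = 3600, on_threshold = 0.25,
                                 sample_dt = 5) {
  stopifnot(inherits(net, "crn_network"))
  meta <- net$metadata
  if (is.null(meta$inputs) || length(meta$inputs) != 2L)
    stop("evaluate_truth_table() needs a compiled two-input gate network")
  if (is.null(c)) c <- meta$input_conc
  ts <- meta$memory_timescale
  if (!is.null(ts) && dt_order < 5 * ts)
    warning(sprintf(paste0("dt_order = %g s is below five memory-conversion ",
                           "timescales (5 x %g s); the first input may not be ",
                           "committed to memory before the second arrives"),
                    dt_order, ts))
  A <- meta$inputs[1L]; B <- meta$inputs[2L]
  outs <- meta$outputs  # logical name -> measured species

  schedules <- list(
    none = injection_schedule(t_end = t_mark),
    A_only = injection_schedule(A, 0, c, t_end = t_mark),
    B_only = injection_schedule(B, 0, c, t_end = t_mark),
    A_before_B = injection_schedule(c(A, B), c(0, dt_order), c(c, c),
                                    t_end = dt_order + t_mark),
    B_before_A = injection_schedule(c(B, A), c(0, dt_order), c(c, c),
                                    t_end = dt_order + t_mark),
    simultaneous = injection_schedule(c(A, B), c(0, 0), c(c, c),
                                      t_end = t_mark))

  expected <- expected_truth_table()
  rows <- list()
  for (cn in names(schedules)) {
    sched <- schedules[[cn]]
    traj <- tryCatch(simulate_ode(net, schedule = sched, sample_dt = sample_dt),
                     error = function(e)
                       stop(sprintf("condition %s: %s", cn,
                                    conditionMessage(e)), call. = FALSE))
    t_last <- if (nrow(sched$events)) max(sched$events$time) else 0
    state <- traj_at(traj, t_last + t_mark)
    for (on in names(outs)) {
      conc <- unname(state[outs[[on]]])
      exp_row <- expected$expected[expected$condition == cn &
                                     expected$output == on]
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cn, output = on, expected = exp_row,
        observed = conc >= on_threshold * c, conc = conc,
        pass = (conc >= on_threshold * c) == exp_row,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
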