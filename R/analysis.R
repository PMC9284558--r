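#' Measured output levels of a trajectory
#'
#' Outputs are read at the measured species recorded in the network metadata
#' (the fluorophores when reporters are present, otherwise the free output
#' strands).
#'
#' @param traj A `crn_trajectory`.
#' @param net The network the trajectory came from.
#' @param t Time in seconds.
#' @return Named vector of output concentrations, named by logical output
#'   (Y, Z).
#' @export
output_levels <- function(traj, net, t) {
  outs <- net$metadata$outputs
  if (is.null(outs)) stop("network metadata carries no output mapping")
  state <- traj_at(traj, t)
  setNames(unname(state[unname(outs)]), names(outs))
}

#' ON/OFF separation report at the two standard time marks
#'
#' Quantifies timing discrimination the way bar plots of circuit
#' characterizations do: output concentrations immediately after the second
#' input (first sample within 5 min) and at a later mark (1 h by default),
#' plus the ON/OFF ratio at the late mark. The circuit passes when the
#' output that should turn ON is at least `criterion` (2 by default) times
#' the output that should stay OFF.
#'
#' @param traj A `crn_trajectory` from a two-input ordered schedule.
#' @param on_output,off_output Measured species names of the expected-ON and
#'   expected-OFF outputs (the first-arriving input's matched output is ON).
#' @param t_mark Absolute time of the late mark, seconds; must lie after the
#'   last injection and within the trajectory.
#' @param t_immediate_after Offset of the immediate mark after the last
#'   input, seconds. Default 300 (5 min).
#' @param criterion Required ON/OFF ratio. Default 2.
#' @param floor OFF concentrations are floored at this value (default the
#'   solver atol, 1e-12 nM) before forming the ratio.
#' @return List of class `separation_report`: `on_output`, `off_output`,
#'   `conc_immediate` (named pair), `conc_1h` (named pair), `ratio_1h`,
#'   `passes`.
#' @export
onoff_separation <- function(traj, on_output, off_output, t_mark,
                             t_immediate_after = 300, criterion = 2,
                             floor = 1e-12) {
  stopifnot(inherits(traj, "crn_trajectory"))
  ev <- traj$schedule$events
  if (nrow(ev) < 1L) stop("schedule has no input events")
  t_last <- max(ev$time)
  if (t_mark <= t_last)
    stop("t_mark must lie after the last input event")
  s_imm <- traj_at(traj, min(t_last + t_immediate_after, max(traj$times)))
  s_late <- traj_at(traj, t_mark)
  on_late <- unname(s_late[on_output])
  off_late <- unname(s_late[off_output])
  ratio <- on_late / max(off_late, floor)
  structure(list(on_output = on_output, off_output = off_output,
                 conc_immediate = c(on = unname(s_imm[on_output]),
                                    off = unname(s_imm[off_output])),
                 conc_1h = c(on = on_late, off = off_late),
                 ratio_1h = ratio, passes = ratio >= criterion),
            class = "separation_report")
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf(paste0("<separation_report> ON %s / OFF %s: immediate %.2f/%.2f nM, ",
                     "late %.2f/%.2f nM, ratio %.2f (%s)\n"),
              x$on_output, x$off_output,
              x$conc_immediate["on"], x$conc_immediate["off"],
              x$conc_1h["on"], x$conc_1h["off"], x$ratio_1h,
              if (x$passes) "pass" else "fail"))
  invisible(x)
}

# simulate one ordered two-input condition and report separation
.ordered_separation <- function(net, first, dt, c, t_mark_after,
                                criterion = 2, sample_dt = 2) {
  meta <- net$metadata
  inputs <- meta$inputs
  second <- setdiff(inputs, first)
  sched <- .two_input_schedule(first, second, dt, c, c,
                               t_end = dt + t_mark_after + 60)
  traj <- simulate_ode(net, schedule = sched, sample_dt = sample_dt)
  on_logical <- meta$output_of_first[[first]]
  off_logical <- setdiff(names(meta$outputs), on_logical)
  rep <- onoff_separation(traj,
                          on_output = meta$outputs[[on_logical]],
                          off_output = meta$outputs[[off_logical]],
                          t_mark = dt + t_mark_after, criterion = criterion)
  list(report = rep, traj = traj)
}

#' Scan the input time separation for the minimum resolvable delay
#'
#' Simulates the ordered two-input condition for every delay in `dt_grid`,
#' in both input orders, and reports the smallest delay at which both orders
#' achieve the ON/OFF separation criterion (ON at least `criterion` times
#' OFF) at `t_mark_after` seconds (60 min by default) after the second
#' input.
#'
#' @param net A compiled two-input network (any fidelity).
#' @param c Input concentration, nM (default: network metadata).
#' @param dt_grid Ascending vector of delays, seconds; must exclude 0.
#'   Default 1--15 min in 1-min steps.
#' @param t_mark_after Late mark offset after the second input, seconds.
#' @param criterion Required ON/OFF ratio. Default 2.
#' @param sample_dt Output grid spacing, seconds.
#' @return List with `min_passing_dt` (seconds; `NA` with a message when no
#'   grid value passes) and `table` (one row per delay and order with the
#'   concentrations, ratio, and pass flag).
#' @export
scan_delta_t <- function(net, c = NULL, dt_grid = 60 * (1:15),
                         t_mark_after = 3600, criterion = 2, sample_dt = 2) {
  stopifnot(inherits(net, "crn_network"))
  if (is.unsorted(dt_grid, strictly = TRUE))
    stop("dt_grid must be sorted ascending")
  if (any(dt_grid <= 0)) stop("dt_grid must be positive (dt = 0 is the ",
                              "simultaneous condition, handled by the truth table)")
  meta <- net$metadata
  if (is.null(c)) c <- meta$input_conc
  inputs <- meta$inputs
  rows <- list()
  for (dt in dt_grid) {
    for (first in inputs) {
      res <- .ordered_separation(net, first, dt, c, t_mark_after, criterion,
                                 sample_dt)
      rep <- res$report
      rows[[length(rows) + 1L]] <- data.frame(
        dt = dt, first_input = first, on_output = rep$on_output,
        off_output = rep$off_output,
        conc_on = rep$conc_1h[["on"]], conc_off = rep$conc_1h[["off"]],
        ratio = rep$ratio_1h, passes = rep$passes,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  both <- tapply(tab$passes, tab$dt, all)
  passing <- as.numeric(names(both))[both]
  min_pass <- if (length(passing)) min(passing) else NA_real_
  if (is.na(min_pass))
    message("no passing delay in grid [", min(dt_grid), ", ", max(dt_grid),
            "] s")
  list(min_passing_dt = min_pass, table = tab)
}

#' Survey cooperative-gate S* toehold lengths
#'
#' Builds the detailed network for each S* length, simulates the
#' first-input-A ordered schedule, and reports ON/OFF concentrations at the
#' immediate (within 5 min) and late (1 h) marks. Shorter S* toeholds bias
#' against crosstalk (the OFF output stays low) at the cost of a lower
#' maximum ON level; longer toeholds pass immediately after the second input
#' but let the OFF output rise by the late mark.
#'
#' @param design A [gate_design()]; its `s_star_length` is replaced by each
#'   scanned value.
#' @param lengths S* lengths to survey, nt. Default `c(5, 6, 7)`.
#' @param rmodel A calibrated [rate_model()].
#' @param dt Input delay of the schedule, seconds. Default 600.
#' @param t_mark_after Late mark offset after the second input. Default 3600.
#' @param criterion Required ON/OFF ratio. Default 2.
#' @param delta_k Rate bias passed to [build_detailed()].
#' @param sample_dt Output grid spacing, seconds.
#' @return Data frame, one row per length: concentrations at both marks,
#'   ratios, the maximum ON level over the trajectory, pass flags, and
#'   `fails_late_only` (passes immediately but not at the late mark).
#' @export
scan_toehold <- function(design = gate_design(), lengths = c(5, 6, 7),
                         rmodel, dt = 600, t_mark_after = 3600,
                         criterion = 2, delta_k = 1, sample_dt = 2) {
  stopifnot(inherits(rmodel, "rate_model"))
  rows <- list()
  for (L in lengths) {
    d <- design
    d$s_star_length <- as.integer(L)
    net <- build_detailed(d, rmodel, delta_k = delta_k)
    res <- .ordered_separation(net, net$metadata$inputs[1L], dt,
                               d$conc_inputs, t_mark_after, criterion,
                               sample_dt)
    rep <- res$report
    on_col <- which(res$traj$species == rep$on_output)
    imm_ratio <- rep$conc_immediate[["on"]] /
      max(rep$conc_immediate[["off"]], 1e-12)
    rows[[length(rows) + 1L]] <- data.frame(
      s_star_length = L,
      conc_on_immediate = rep$conc_immediate[["on"]],
      conc_off_immediate = rep$conc_immediate[["off"]],
      conc_on_1h = rep$conc_1h[["on"]],
      conc_off_1h = rep$conc_1h[["off"]],
      ratio_immediate = imm_ratio,
      ratio_1h = rep$ratio_1h,
      max_on = max(res$traj$conc[, on_col]),
      passes_immediate = imm_ratio >= criterion,
      passes_1h = rep$passes,
      fails_late_only = (imm_ratio >= criterion) && !rep$passes,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Scan the crosstalk branch-migration rate for full leak suppression
#'
#' Rebuilds the detailed network for each candidate mismatch-slowed forward
#' branch-migration rate and simulates the ordered two-input schedule; a
#' rate achieves suppression when the crosstalk-produced OFF output stays
#' below `threshold * c` over the whole trajectory (second input plus
#' `horizon`). Returns the largest suppressing rate: suppression is monotone
#' in the rate, so every smaller grid value also passes.
#'
#' At finite input delays the desired pathways legitimately produce some OFF
#' output from residual unconverted first input (it arrived, just late), and
#' no branch-migration slowdown can remove that floor. The default
#' `baseline = "crosstalk_free"` therefore measures the OFF output in excess
#' of a crosstalk-free reference build of the same design (the
#' crosstalk-attributable production the mismatch is meant to suppress);
#' `baseline = "none"` measures the absolute OFF level instead.
#'
#' @param design A [gate_design()] (its mismatch rate is overridden by each
#'   grid value).
#' @param rmodel A calibrated [rate_model()].
#' @param k_grid Candidate forward branch-migration rates, /s, positive and
#'   strictly descending. Default `c(0.1, 0.01, 0.001)`.
#' @param threshold Suppression threshold as a fraction of the input
#'   concentration. Default 0.05.
#' @param horizon Simulated time after the second input, seconds. Default
#'   4 h.
#' @param dt Input delay, seconds. Default 600 (10 min).
#' @param delta_k Rate bias passed to [build_detailed()].
#' @param baseline `"crosstalk_free"` (default) or `"none"`, see Details.
#' @param sample_dt Output grid spacing, seconds.
#' @return List with `largest_suppressing` (/s; `NA` with a message if none
#'   suppress) and `table` (rate, peak OFF excess, suppressed flag).
#' @export
scan_crosstalk_bm_rate <- function(design = gate_design(), rmodel,
                                   k_grid = c(0.1, 0.01, 0.001),
                                   threshold = 0.05, horizon = 4 * 3600,
                                   dt = 600, delta_k = 1,
                                   baseline = c("crosstalk_free", "none"),
                                   sample_dt = 5) {
  stopifnot(inherits(rmodel, "rate_model"))
  baseline <- match.arg(baseline)
  if (any(k_grid <= 0) || is.unsorted(rev(k_grid), strictly = TRUE))
    stop("k_grid must be positive and strictly descending")
  c_in <- design$conc_inputs
  first <- "A"; second <- "B"
  sched <- .two_input_schedule(first, second, dt, c_in, c_in,
                               t_end = dt + horizon)
  off_curve <- function(net) {
    traj <- simulate_ode(net, schedule = sched, sample_dt = sample_dt)
    meta <- net$metadata
    off_logical <- setdiff(names(meta$outputs), meta$output_of_first[[first]])
    traj$conc[, which(traj$species == meta$outputs[[off_logical]])]
  }
  ref <- if (baseline == "crosstalk_free")
    off_curve(build_detailed(design, rmodel, delta_k = delta_k,
                             include_crosstalk = FALSE)) else 0
  rows <- list()
  for (kp in k_grid) {
    d <- design
    d$mismatch <- mismatch_spec(present = TRUE, k_fwd = kp,
                                k_back = max(kp, .crosstalk_bm_back_rate(
                                  design, rmodel)))
    off <- off_curve(build_detailed(d, rmodel, delta_k = delta_k))
    peak <- max(off - ref)
    rows[[length(rows) + 1L]] <- data.frame(
      k_bm_fwd = kp, peak_off_excess = peak,
      suppressed = peak < threshold * c_in, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$k_bm_fwd[tab$suppressed]
  largest <- if (length(ok)) max(ok) else NA_real_
  if (is.na(largest))
    message("no rate in the grid suppresses the undesired output below ",
            threshold * c_in, " nM")
  list(largest_suppressing = largest, table = tab)
}

#' Survey the rate bias between the two reaction pathways
#'
#' Reproduces the trimolecular-fidelity crosstalk survey: for each fold bias
#' `delta_k`, both ordered input conditions are simulated with crosstalk and
#' reporters on, and the output trajectories and late-mark separation ratios
#' are collected. Larger biases leave the disadvantaged pathway's ON output
#' lower and its crosstalk-driven OFF leak relatively higher, degrading the
#' separation.
#'
#' @param delta_k_grid Fold biases `>= 1`. Default `c(1, 2, 5)`.
#' @param design A [gate_design()]; the default uses the 100 nM / 20 percent
#'   gate excess / 50 percent reporter excess working condition.
#' @param k_s2,k_f2 Pathway-2 rate constants (see [build_trimolecular()]).
#' @param rmodel Rate model for crosstalk constants.
#' @param dt Input delay, seconds. Default 1500.
#' @param t_mark_after Late mark offset after the second input. Default 3600.
#' @param sample_dt Output grid spacing, seconds.
#' @return List with `table` (one row per bias and order: ON/OFF levels,
#'   ratio, pass) and `trajectories` (named list of `crn_trajectory`, four
#'   output curves per bias: Y and Z under both orders).
#' @export
scan_rate_bias <- function(delta_k_grid = c(1, 2, 5),
                           design = gate_design(conc_inputs = 100,
                                                conc_gates = 120,
                                                conc_reporters = 150),
                           k_s2 = 1e5, k_f2 = 2e13, rmodel = rate_model(),
                           dt = 1500, t_mark_after = 3600, sample_dt = 2) {
  if (any(delta_k_grid < 1)) stop("delta_k must be >= 1")
  rows <- list(); trajs <- list()
  for (dk in delta_k_grid) {
    net <- build_trimolecular(design, k_s2 = k_s2, k_f2 = k_f2,
                              delta_k = dk, include_crosstalk = TRUE,
                              include_reporters = TRUE, rmodel = rmodel)
    for (first in net$metadata$inputs) {
      res <- .ordered_separation(net, first, dt, design$conc_inputs,
                                 t_mark_after, sample_dt = sample_dt)
      rep <- res$report
      trajs[[paste0("dk", dk, "_first", first)]] <- res$traj
      rows[[length(rows) + 1L]] <- data.frame(
        delta_k = dk, first_input = first,
        conc_on = rep$conc_1h[["on"]], conc_off = rep$conc_1h[["off"]],
        ratio = rep$ratio_1h, passes = rep$passes, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), trajectories = trajs)
}
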