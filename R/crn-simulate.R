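#' Deterministic mass-action simulation
#'
#' Integrates the mass-action ODE system of a network piecewise between
#' injection events with an L-stable Rosenbrock 4(3) method (Kaps-Rentrop,
#' Shampine parameters) and an analytic Jacobian. At each event time the
#' injected species jumps by the added concentration and the solver restarts;
#' the trajectory records both the pre- and post-injection state at the event
#' time (duplicate time stamps), so injection jumps are observable.
#'
#' Default tolerances are tight (`rtol = 1e-8`, `atol = 1e-12` nM) because
#' detailed strand-displacement networks combine rate constants spanning many
#' orders of magnitude.
#'
#' @param net A validated `crn_network`.
#' @param init Named numeric vector of initial concentrations in nM. Species
#'   not named start at the network's `metadata$init` value if present, else
#'   at 0.
#' @param schedule An [injection_schedule()].
#' @param rtol,atol Relative / absolute solver tolerances (atol in nM).
#' @param sample_dt Spacing of the output grid in seconds; event times and
#'   `t_end` are always included.
#' @param sample_times Optional explicit output times (overrides
#'   `sample_dt`); event times are still added.
#' @return A `crn_trajectory`: list with `times`, `conc` (time x species
#'   matrix, nM), `schedule`, and solver settings.
#' @export
simulate_ode <- function(net, init = NULL, schedule,
                         rtol = 1e-8, atol = 1e-12,
                         sample_dt = 1, sample_times = NULL) {
  stopifnot(inherits(net, "crn_network"), inherits(schedule, "injection_schedule"))
  viol <- validate_network(net)
  if (length(viol))
    stop("network is invalid:\n  ", paste(viol, collapse = "\n  "))
  sp <- species_names(net)
  y <- .initial_state(net, init)
  bad <- setdiff(schedule$events$species, sp)
  if (length(bad))
    stop("schedule injects undeclared species: ", paste(bad, collapse = ", "))

  Mre <- .reactant_matrix(net)
  Nn <- .net_matrix(net)
  k <- .internal_rates(net)

  t_end <- schedule$t_end
  if (is.null(sample_times))
    sample_times <- seq(0, t_end, by = sample_dt)
  grid <- sort(unique(c(0, sample_times, schedule$events$time, t_end)))
  grid <- grid[grid >= 0 & grid <= t_end]

  ev <- schedule$events
  seg_bounds <- sort(unique(c(0, ev$time, t_end)))

  times_out <- numeric(0)
  states <- list()
  t_cur <- 0

  record <- function(tt, yy) {
    times_out[[length(times_out) + 1L]] <<- tt
    states[[length(states) + 1L]] <<- yy
  }

  # events at t = 0 are applied after recording the pristine state
  record(0, y)
  for (i in which(ev$time == 0)) {
    y[ev$species[i]] <- y[ev$species[i]] + ev$amount[i]
    record(0, y)
  }

  for (s in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    samp <- grid[grid > t0 & grid <= t1]
    if (!length(samp) || tail(samp, 1L) < t1) samp <- c(samp, t1)
    res <- tryCatch(
      .ros_segment(Mre, Nn, k, unname(y), t0, t1, samp, rtol, atol,
                   hmax = max(t1 - t0, 1)),
      error = function(e)
        stop(sprintf("ODE integration failed in segment [%g, %g] s: %s",
                     t0, t1, conditionMessage(e)), call. = FALSE))
    st <- res$states
    for (i in seq_along(samp)) record(samp[i], setNames(st[i, ], sp))
    y <- setNames(res$y_end[, 1L], sp)
    # apply injections scheduled exactly at t1
    for (i in which(ev$time == t1)) {
      y[ev$species[i]] <- y[ev$species[i]] + ev$amount[i]
      record(t1, y)
    }
  }

  conc <- do.call(rbind, states)
  rownames(conc) <- NULL
  structure(list(times = unlist(times_out), conc = conc, schedule = schedule,
                 species = sp, units = "nM", rtol = rtol, atol = atol),
            class = "crn_trajectory")
}

# resolve initial state: explicit init > metadata$init > 0
.initial_state <- function(net, init) {
  sp <- species_names(net)
  y <- setNames(numeric(length(sp)), sp)
  meta <- net$metadata$init
  if (!is.null(meta)) {
    bad <- setdiff(names(meta), sp)
    if (length(bad)) stop("metadata$init names unknown species: ",
                          paste(bad, collapse = ", "))
    y[names(meta)] <- as.numeric(meta)
  }
  if (!is.null(init)) {
    stopifnot(is.numeric(init), !is.null(names(init)))
    bad <- setdiff(names(init), sp)
    if (length(bad)) stop("init names unknown species: ",
                          paste(bad, collapse = ", "))
    y[names(init)] <- as.numeric(init)
  }
  y
}

#' Stochastic simulation (Gillespie direct method)
#'
#' Exact SSA sample path of the network in a fixed volume. Copy numbers and
#' concentrations are related through `omega` = copies per nM =
#' `volume * N_A * 1e-9`. Injection amounts given in nM are converted to
#' copies with `round(amount * omega)`. Runs are reproducible: the sampler
#' draws from R's RNG, so a fixed `seed` gives a bitwise-identical event
#' sequence.
#'
#' @param net A validated `crn_network`.
#' @param init Named vector of initial copy numbers (integral, `>= 0`).
#' @param schedule Optional [injection_schedule()] (amounts in nM). If
#'   omitted, supply `t_end`.
#' @param volume Reaction volume in litres; alternatively give `omega`.
#' @param omega Copies per nM (overrides `volume`).
#' @param t_end End time when no schedule is given.
#' @param seed Optional integer seed.
#' @param sample_dt Output grid spacing in seconds.
#' @return A `crn_trajectory` with `units = "copies"` and the `omega` used.
#' @export
simulate_ssa <- function(net, init, schedule = NULL, volume = NULL,
                         omega = NULL, t_end = NULL, seed = NULL,
                         sample_dt = 1) {
  stopifnot(inherits(net, "crn_network"))
  viol <- validate_network(net)
  if (length(viol))
    stop("network is invalid:\n  ", paste(viol, collapse = "\n  "))
  if (is.null(omega)) {
    if (is.null(volume)) stop("supply either volume (L) or omega (copies/nM)")
    omega <- volume * 6.02214076e23 * 1e-9
  }
  if (is.null(schedule)) {
    stopifnot(!is.null(t_end))
    schedule <- injection_schedule(t_end = t_end)
  }
  if (!is.null(seed)) set.seed(seed)

  sp <- species_names(net)
  x <- setNames(numeric(length(sp)), sp)
  stopifnot(is.numeric(init), !is.null(names(init)))
  if (any(init < 0) || any(init != round(init)))
    stop("initial copy numbers must be non-negative integers")
  bad <- setdiff(names(init), sp)
  if (length(bad)) stop("init names unknown species: ", paste(bad, collapse = ", "))
  x[names(init)] <- init

  Mre <- .reactant_matrix(net)
  Nn <- .net_matrix(net)
  k <- .internal_rates(net)

  t_end <- schedule$t_end
  grid <- sort(unique(c(seq(0, t_end, by = sample_dt),
                        schedule$events$time, t_end)))
  ev <- schedule$events
  seg_bounds <- sort(unique(c(0, ev$time, t_end)))

  times_out <- numeric(0); states <- list()
  record <- function(tt, xx) {
    times_out[[length(times_out) + 1L]] <<- tt
    states[[length(states) + 1L]] <<- xx
  }
  record(0, x)
  for (i in which(ev$time == 0)) {
    x[ev$species[i]] <- x[ev$species[i]] + round(ev$amount[i] * omega)
    record(0, x)
  }
  for (s in seq_len(length(seg_bounds) - 1L)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1L]
    samp <- grid[grid > t0 & grid <= t1]
    if (!length(samp) || tail(samp, 1L) < t1) samp <- c(samp, t1)
    res <- .ssa_segment(Mre, Nn, k, unname(x), omega, t0, t1, samp)
    st <- res$states
    for (i in seq_along(samp)) record(samp[i], setNames(st[i, ], sp))
    x <- setNames(res$x_end[, 1L], sp)
    for (i in which(ev$time == t1)) {
      x[ev$species[i]] <- x[ev$species[i]] + round(ev$amount[i] * omega)
      record(t1, x)
    }
  }
  conc <- do.call(rbind, states)
  rownames(conc) <- NULL
  structure(list(times = unlist(times_out), conc = conc, schedule = schedule,
                 species = sp, units = "copies", omega = omega),
            class = "crn_trajectory")
}

#' @export
print.crn_trajectory <- function(x, ...) {
  cat(sprintf("<crn_trajectory> %d samples x %d species (%s), t in [%g, %g] s\n",
              length(x$times), length(x$species), x$units,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.crn_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, x$conc, check.names = FALSE)
}

#' State of a trajectory at a given time
#'
#' Returns the last recorded state at or before `t` (so at a duplicated
#' injection time stamp the post-injection state is returned).
#'
#' @param traj A `crn_trajectory`.
#' @param t Time in seconds.
#' @return Named concentration vector.
#' @export
traj_at <- function(traj, t) {
  stopifnot(inherits(traj, "crn_trajectory"))
  if (t < traj$times[1L] || t > tail(traj$times, 1L))
    stop(sprintf("time %g s outside trajectory range [%g, %g]",
                 t, traj$times[1L], tail(traj$times, 1L)))
  i <- findInterval(t, traj$times)
  setNames(traj$conc[i, ], traj$species)
}

#' Strand-weighted totals along a trajectory
#'
#' Evaluates each conserved quantity of [conserved_quantities()] at every
#' sample; between injections these totals must be constant.
#'
#' @param net The network the trajectory came from.
#' @param traj A `crn_trajectory`.
#' @return Matrix time x strand of totals.
#' @export
strand_totals <- function(net, traj) {
  cq <- conserved_quantities(net)
  if (!length(cq)) return(matrix(0, length(traj$times), 0))
  W <- do.call(cbind, cq)
  traj$conc[, rownames(W), drop = FALSE] %*% W
}
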