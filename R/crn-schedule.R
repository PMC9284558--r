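#' Timed input additions driving a simulation
#'
#' Inputs are added as instantaneous concentration jumps; the integrator is
#' restarted at each event time. This mirrors manual pipetting of inputs into
#' a well: no mixing model is applied.
#'
#' @param species Character vector of injected species (one entry per event).
#' @param time Numeric vector of event times in seconds, each `>= 0` and
#'   `< t_end`.
#' @param amount Added concentrations in nM, each `> 0`.
#' @param t_end Simulation end time in seconds.
#' @return An object of class `injection_schedule` with events sorted by time.
#' @export
injection_schedule <- function(species = character(), time = numeric(),
                               amount = numeric(), t_end) {
  stopifnot(length(species) == length(time), length(time) == length(amount))
  stopifnot(is.numeric(t_end), length(t_end) == 1L, t_end > 0)
  if (length(time)) {
    stopifnot(all(time >= 0), all(amount > 0))
    if (any(time >= t_end))
      stop("all event times must be < t_end")
    o <- order(time)
    species <- species[o]; time <- time[o]; amount <- amount[o]
  }
  structure(list(events = data.frame(time = as.numeric(time),
                                     species = as.character(species),
                                     amount = as.numeric(amount),
                                     stringsAsFactors = FALSE),
                 t_end = as.numeric(t_end)),
            class = "injection_schedule")
}

#' Inter-input delay of a two-event schedule
#'
#' The input time separation `|t_A - t_B|`, defined when the schedule holds
#' exactly two input events.
#'
#' @param sched An [injection_schedule()].
#' @return `|t_1 - t_2|` in seconds, or `NA` if the schedule does not have
#'   exactly two events.
#' @export
delta_t <- function(sched) {
  stopifnot(inherits(sched, "injection_schedule"))
  if (nrow(sched$events) != 2L) return(NA_real_)
  abs(diff(sched$events$time))
}

#' @export
print.injection_schedule <- function(x, ...) {
  cat(sprintf("<injection_schedule> %d events, t_end = %g s\n",
              nrow(x$events), x$t_end))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

# convenience: two-input schedule with given order and delay
.two_input_schedule <- function(first, second, dt, c_first, c_second = c_first,
                                t_end) {
  injection_schedule(species = c(first, second), time = c(0, dt),
                     amount = c(c_first, c_second), t_end = t_end)
}
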