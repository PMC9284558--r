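#' Elementary-rate model for toehold-mediated strand displacement
#'
#' Maps design features (toehold length, mismatch placement) to the
#' elementary rate constants of the detailed model: a hybridization-limited
#' binding rate `k_bind`, toehold dissociation rates that fall geometrically
#' with toehold length (`k_r(L) = k_r_ref * per_nt_factor^(ref_toehold - L)`,
#' so each added nucleotide slows dissociation by `per_nt_factor`), and
#' lumped branch-migration rates. Crosstalk branch migration creates a
#' mismatch and is slowed (`k_i_crosstalk_fwd < k_i_crosstalk_back`);
#' backward migration eliminates the mismatch at the unhindered rate, and
#' memory release is unaffected by the mismatch.
#'
#' `coop_scale` multiplies the dissociation rates on the two cooperative-gate
#' toeholds; it is the free parameter adjusted by [calibrate_rate_model()] so
#' that the detailed expansion reproduces the printed lumped cooperative
#' hybridization rate.
#'
#' @param k_bind Binding on-rate, /M/s. Default 2e6.
#' @param per_nt_factor Fold-change in dissociation per toehold nucleotide
#'   (> 1). Default 20, consistent with the ~20-fold effective-rate change
#'   between 5-nt and 7-nt toeholds at 100 nM.
#' @param k_r_ref Dissociation rate at the reference toehold length, /s.
#' @param ref_toehold Reference toehold length, nt. Default 5.
#' @param k_i_desired Lumped branch-migration rate of mismatch-free desired
#'   pathways, /s. Default 1.
#' @param k_i_crosstalk_fwd Mismatch-creating forward branch-migration rate
#'   of the crosstalk pathways, /s. Default 0.1.
#' @param k_i_crosstalk_back Mismatch-eliminating backward rate, /s. Default 1.
#' @param k_r_mid Dissociation rate of the middle toehold holding the output
#'   in the crosstalk complex, /s. Defaults to `k_r_ref` (a 5-nt toehold).
#' @param coop_scale Multiplier on cooperative-side dissociation rates.
#' @param calibrated Flag set by [calibrate_rate_model()].
#' @return An object of class `rate_model`.
#' @export
rate_model <- function(k_bind = 2e6, per_nt_factor = 20, k_r_ref = 19,
                       ref_toehold = 5, k_i_desired = 1,
                       k_i_crosstalk_fwd = 0.1, k_i_crosstalk_back = 1,
                       k_r_mid = NULL, coop_scale = 1, calibrated = FALSE) {
  stopifnot(k_bind > 0, per_nt_factor > 1, k_r_ref > 0, k_i_desired > 0,
            k_i_crosstalk_fwd > 0, k_i_crosstalk_back > 0, coop_scale > 0)
  if (k_i_crosstalk_fwd > k_i_crosstalk_back)
    stop("mismatch creation (k_i_crosstalk_fwd) must not be faster than ",
         "mismatch elimination (k_i_crosstalk_back)")
  if (is.null(k_r_mid)) k_r_mid <- k_r_ref
  structure(list(k_bind = k_bind, per_nt_factor = per_nt_factor,
                 k_r_ref = k_r_ref, ref_toehold = ref_toehold,
                 k_i_desired = k_i_desired,
                 k_i_crosstalk_fwd = k_i_crosstalk_fwd,
                 k_i_crosstalk_back = k_i_crosstalk_back,
                 k_r_mid = k_r_mid, coop_scale = coop_scale,
                 calibrated = calibrated),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf(paste0("<rate_model>%s k_bind = %g /M/s, k_r(%d nt) = %g /s, ",
                     "x%g per nt, coop_scale = %g\n",
                     "  branch migration: desired %g /s, crosstalk %g /s ",
                     "(back %g /s), k_r_mid = %g /s\n"),
              if (x$calibrated) " [calibrated]" else "",
              x$k_bind, x$ref_toehold, x$k_r_ref, x$per_nt_factor,
              x$coop_scale, x$k_i_desired, x$k_i_crosstalk_fwd,
              x$k_i_crosstalk_back, x$k_r_mid))
  invisible(x)
}

#' Toehold dissociation rate at a given length
#'
#' Strictly decreasing in toehold length: each added nucleotide divides the
#' rate by `per_nt_factor`.
#'
#' @param model A [rate_model()].
#' @param length Toehold length, nt.
#' @param cooperative Apply the cooperative-side calibration factor?
#' @return Dissociation rate, /s.
#' @export
toehold_dissociation <- function(model, length, cooperative = FALSE) {
  stopifnot(inherits(model, "rate_model"), length >= 1)
  k <- model$k_r_ref * model$per_nt_factor^(model$ref_toehold - length)
  if (cooperative) k <- k * model$coop_scale
  k
}

#' Lumped bimolecular rate of a bind/dissociate/branch-migrate pathway
#'
#' Standard steady-state lumping of toehold-mediated strand displacement:
#' a fraction `k_i / (k_r + k_i)` of binding events commit to branch
#' migration before dissociating, so the effective rate is
#' `k_f * k_i / (k_r + k_i)`.
#'
#' @param k_f Binding rate, /M/s.
#' @param k_r Toehold dissociation rate, /s.
#' @param k_i Branch migration rate, /s.
#' @return Effective bimolecular rate, /M/s.
#' @export
effective_bimolecular <- function(k_f, k_r, k_i) {
  stopifnot(k_f > 0, k_r >= 0, k_i >= 0)
  k_f * k_i / (k_r + k_i)
}

#' Quasi-steady-state lumped trimolecular rate of a cooperative reaction
#'
#' When toehold binding on both sides of a cooperative gate equilibrates fast
#' against branch migration, the doubly-bound complex concentration is
#' `(k_f/k_r_left)(k_f/k_r_right) [m][G][x]` and the lumped trimolecular rate
#' constant is `k_f^2 k_bm / (k_r_left k_r_right)`.
#'
#' @param model A [rate_model()].
#' @param len_left,len_right Toehold lengths of the memory side and the
#'   input (S*) side, nt.
#' @param k_bm Branch migration rate of the lumped step, /s.
#' @return Lumped trimolecular rate, /M^2/s.
#' @export
effective_trimolecular <- function(model, len_left = 7, len_right = 7,
                                   k_bm = model$k_i_desired) {
  kf <- model$k_bind * 1e-9  # /nM/s
  krl <- toehold_dissociation(model, len_left, cooperative = TRUE)
  krr <- toehold_dissociation(model, len_right, cooperative = TRUE)
  (kf^2 * k_bm / (krl * krr)) * 1e18  # back to /M^2/s
}

#' Calibrate the rate model against printed lumped rates
#'
#' Two-stage calibration. First, `k_r_ref` is solved in closed form so the
#' upstream (5-nt toehold) effective displacement rate matches
#' `k_upstream_eff`: `k_r_ref = k_bind * k_i / k_upstream_eff - k_i`.
#' Second, the cooperative-side dissociation scale is fitted numerically so
#' that a simulated elementary-step expansion of one cooperative reaction
#' (memory + gate + input at 10 nM each) reproduces the lumped trimolecular
#' rate `k_coop_eff`: the apparent rate constant is inverted from the
#' third-order integrated rate law at 200 s and matched by root finding.
#'
#' @param model A [rate_model()].
#' @param k_upstream_eff Target effective upstream rate, /M/s. Default 1e5
#'   (a 5-nt toehold).
#' @param k_coop_eff Target lumped cooperative rate, /M^2/s. Default 2e13
#'   (a 7-nt toehold).
#' @param len_left,len_right Cooperative toehold lengths used for the fit.
#' @param tol Relative tolerance on the cooperative match. Default 0.1.
#' @return The calibrated `rate_model` (`calibrated = TRUE`). Calibration is
#'   idempotent: recalibrating a calibrated model returns the same rates.
#' @export
calibrate_rate_model <- function(model = rate_model(),
                                 k_upstream_eff = 1e5, k_coop_eff = 2e13,
                                 len_left = 7, len_right = 7, tol = 0.1) {
  stopifnot(inherits(model, "rate_model"))
  k_r_ref <- model$k_bind * model$k_i_desired / k_upstream_eff -
    model$k_i_desired
  if (k_r_ref <= 0)
    stop(sprintf(paste0("calibration infeasible: k_upstream_eff = %g /M/s ",
                        "requires k_r_ref = %g /s <= 0 ",
                        "(upper bound k_bind * k_i / (k_r + k_i) = %g /M/s)"),
                 k_upstream_eff, k_r_ref, model$k_bind))
  model$k_r_ref <- k_r_ref
  model$k_r_mid <- k_r_ref

  # closed-form QSS seed for the cooperative-side scale
  model$coop_scale <- 1
  seed <- sqrt(effective_trimolecular(model, len_left, len_right) / k_coop_eff)
  if (!is.finite(seed) || seed <= 0)
    stop("calibration infeasible: cooperative target unreachable")

  measure <- function(scale) {
    m <- model; m$coop_scale <- scale
    .measured_coop_rate(m, len_left, len_right)
  }
  m0 <- measure(seed)
  if (abs(m0 - k_coop_eff) / k_coop_eff > tol) {
    f <- function(ls) log(measure(exp(ls))) - log(k_coop_eff)
    # measured rate decreases in the dissociation scale
    root <- uniroot(f, interval = log(c(seed / 20, seed * 20)),
                    tol = 1e-4)
    model$coop_scale <- exp(root$root)
  } else {
    model$coop_scale <- seed
  }
  model$calibrated <- TRUE
  model
}

# apparent lumped trimolecular rate of the simulated detailed expansion,
# inverted from y' = k (c0 - y)^3 at t = Tm: k = (1/(c0-y)^2 - 1/c0^2)/(2 Tm)
.measured_coop_rate <- function(model, len_left, len_right,
                                c0 = 10, Tm = 200) {
  .measured_coop_rate_elem(
    k_f = model$k_bind,
    k_r_left = toehold_dissociation(model, len_left, TRUE),
    k_r_right = toehold_dissociation(model, len_right, TRUE),
    k_i = model$k_i_desired, c0 = c0, Tm = Tm)
}

.measured_coop_rate_elem <- function(k_f, k_r_left, k_r_right, k_i,
                                     c0 = 10, Tm = 200) {
  net <- .coop_test_network(k_f, k_r_left, k_r_right, k_i)
  sched <- injection_schedule(t_end = Tm)
  init <- c(m = c0, G = c0, X = c0)
  traj <- simulate_ode(net, init = init, schedule = sched, sample_dt = Tm / 40)
  y <- unname(traj_at(traj, Tm)[["Yout"]])
  k_nM2 <- (1 / (c0 - y)^2 - 1 / c0^2) / (2 * Tm)
  k_nM2 * 1e18  # /M^2/s
}

# minimal cooperative reaction test system: m + G + X -> Yout + W, expanded
.coop_test_network <- function(k_f, k_r_left, k_r_right, k_i) {
  species <- list(
    crn_species("m", "memory", "m"),
    crn_species("X", "input", "X"),
    crn_species("G", "cooperative_gate", c("Yout", "bot")),
    crn_species("Yout", "output", "Yout"),
    crn_species("W", "waste", c("m", "X", "bot")))
  tri <- crn_reaction(c("m", "G", "X"), c("Yout", "W"), 1e12, "/M^2/s",
                      label = "coop")
  ex <- expand_irreversible_trimolecular(
    tri, species,
    rates = list(k_f = k_f, k_r_left = k_r_left, k_r_right = k_r_right,
                 k_i = k_i))
  crn_network(c(species, ex$species), ex$reactions, "detailed")
}

#' Split rates into a slow and a fast reaction pathway
#'
#' The two reaction pathways of the temporal gate need not have equal rate
#' constants; a bias `delta_k >= 1` divides both the upstream and the
#' cooperative rate constants of pathway 1 (the disadvantaged pathway, by
#' convention) by `delta_k`, leaving pathway 2 at the base rates.
#'
#' @param k_s2 Upstream (input + gate -> memory) rate of pathway 2, /M/s.
#' @param k_f2 Cooperative rate of pathway 2, /M^2/s.
#' @param delta_k Fold bias `>= 1`.
#' @return List with elements `pathway1` and `pathway2`, each `list(k_s, k_f)`.
#' @export
rate_bias <- function(k_s2 = 1e5, k_f2 = 2e13, delta_k = 1) {
  if (delta_k < 1)
    stop("delta_k must be >= 1 (pathway 1 is the slower one by convention)")
  list(pathway1 = list(k_s = k_s2 / delta_k, k_f = k_f2 / delta_k),
       pathway2 = list(k_s = k_s2, k_f = k_f2))
}
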