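## Intracellular apoptosis-signalling modules.
##
## Two interchangeable switches map intracellular drug concentration I to the
## activity R of a signalling intermediate:
##   monostable — first-order relaxation to a Hill function of I; exactly one
##     steady state per input, fully reversible;
##   bistable   — activation with saturated (Michaelis-Menten) degradation and
##     positive feedback catalysed by I; two stable branches coexist over a
##     range of inputs, so a transient input can switch the module permanently.
## Both drive the same downstream effector R1 whose crossing of a threshold
## triggers apoptosis at the population level.
##
## All rate functions are agnostic to the time unit: pass dimensional (hr^-1)
## parameters and rates come back per hour; pass the nondimensionalized set
## and they come back per t_scale.

hill <- function(I, k_h, n) {
  x <- (I / k_h)^n
  x / (1 + x)
}

#' Rate of the monostable switch
#'
#' \code{dR/dt = k (I^n / (k_h^n + I^n) - R)}: first-order relaxation of the
#' intermediate R towards a Hill function of the intracellular drug
#' concentration I.
#'
#' @param R Activity of the intermediate, in [0, 1]. Vectorized.
#' @param I Intracellular drug concentration (I_ref units), >= 0. Vectorized.
#' @param p Monostable parameter list with \code{k}, \code{k_h}, \code{n}.
#' @return \code{dR/dt} in the time unit of \code{p$k}.
#' @export
monostable_rate <- function(R, I, p) {
  if (any(I < 0)) stop("negative intracellular concentration", call. = FALSE)
  if (any(R < 0 | R > 1)) stop("R outside [0,1]", call. = FALSE)
  p$k * (hill(I, p$k_h, p$n) - R)
}

#' Rate of the downstream apoptosis effector
#'
#' \code{dR1/dt = k_f R (1 - R1) - k_r R1}: activation of the effector R1 by
#' the intermediate R, with first-order deactivation.
#'
#' @param R1 Effector activity in [0, 1]. Vectorized.
#' @param R Intermediate activity in [0, 1]. Vectorized.
#' @param p Effector parameter list with \code{k_f}, \code{k_r}.
#' @return \code{dR1/dt} in the time unit of the rate constants.
#' @export
effector_rate <- function(R1, R, p) {
  if (any(R1 < 0 | R1 > 1) || any(R < 0 | R > 1))
    stop("state outside [0,1]", call. = FALSE)
  p$k_f * R * (1 - R1) - p$k_r * R1
}

#' Rate of the bistable switch
#'
#' \code{dR/dt = V_f (1-R)/(K_m1 + (1-R)) + (p + q I) k_fb R (1-R)
#'              - V_r R/(K_m2 + R)}: basal activation, input-catalysed
#' positive feedback, and saturated degradation. With the default parameters
#' the module is bistable for inputs below a saddle-node near I = 1 and
#' monostable (high branch only) above it.
#'
#' @param R Active protein fraction in [0, 1]. Vectorized.
#' @param I Intracellular drug concentration (I_ref units), >= 0. Vectorized.
#' @param p Bistable parameter list with \code{V_f}, \code{V_r}, \code{K_m1},
#'   \code{K_m2}, \code{k_fb}, \code{p}, \code{q}.
#' @return \code{dR/dt} in the time unit of the rate constants.
#' @export
bistable_rate <- function(R, I, p) {
  if (any(I < 0)) stop("negative intracellular concentration", call. = FALSE)
  if (any(R < 0 | R > 1)) stop("R outside [0,1]", call. = FALSE)
  p$V_f * (1 - R) / (p$K_m1 + (1 - R)) +
    (p$p + p$q * I) * p$k_fb * R * (1 - R) -
    p$V_r * R / (p$K_m2 + R)
}

## analytic d(bistable_rate)/dR, used for stability classification
bistable_rate_dR <- function(R, I, p) {
  -p$V_f * p$K_m1 / (p$K_m1 + (1 - R))^2 +
    (p$p + p$q * I) * p$k_fb * (1 - 2 * R) -
    p$V_r * p$K_m2 / (p$K_m2 + R)^2
}

#' Steady state of the monostable module
#'
#' Closed form: \code{R* = I^n/(k_h^n + I^n)} and
#' \code{R1* = R*/(R* + k_r/k_f)}.
#'
#' @param I Intracellular drug concentration, >= 0. Vectorized.
#' @param p Signalling parameter block with \code{monostable} and
#'   \code{effector} components (e.g. \code{default_parameters()$signalling}).
#' @return List with components \code{R} and \code{R1}.
#' @export
monostable_steady_state <- function(I, p) {
  if (any(I < 0)) stop("negative intracellular concentration", call. = FALSE)
  R <- hill(I, p$monostable$k_h, p$monostable$n)
  list(R = R, R1 = R / (R + p$effector$k_r / p$effector$k_f))
}

#' Closed-form transient of the monostable switch
#'
#' For a time-varying input \code{I(t)} the linear ODE of the monostable
#' switch has the explicit solution
#' \deqn{R(t) = R_0 e^{-kt} + \int_0^t k\,h(I(w))\, e^{-k (t - w)} dw}
#' with \code{h} the Hill function; evaluated here by adaptive quadrature
#' with the exponential kept in the shifted form \code{e^{-k(t-w)}} so no
#' overflow occurs for large \code{k t}.
#'
#' @param I_path Function of time returning the input (same time unit as
#'   \code{1/p$k}).
#' @param t Time(s) at which to evaluate R. Vectorized.
#' @param p Monostable parameter list (\code{k}, \code{k_h}, \code{n}).
#' @param R0 Initial value of R at time 0.
#' @param ... Passed to [stats::integrate()] (e.g. \code{subdivisions}).
#' @return R(t), same length as \code{t}.
#' @export
monostable_transient <- function(I_path, t, p, R0 = 0, ...) {
  vapply(t, function(tt) {
    if (tt == 0) return(R0)
    conv <- stats::integrate(
      function(w) p$k * hill(I_path(w), p$k_h, p$n) * exp(-p$k * (tt - w)),
      lower = 0, upper = tt, rel.tol = 1e-10, abs.tol = 1e-12, ...)$value
    R0 * exp(-p$k * tt) + conv
  }, numeric(1))
}

#' Steady states of the bistable switch at a given input
#'
#' Finds every root of [bistable_rate()] in [0, 1] by bracketed bisection on
#' sign changes over a fine fixed grid followed by root polishing, and
#' classifies stability from the sign of the analytic derivative of the rate
#' with respect to R. A fine default grid is used because the saturated
#' degradation term creates a boundary layer of width ~\code{K_m2} near
#' R = 0 where roots can lie close together.
#'
#' @param I Intracellular drug concentration (scalar), >= 0.
#' @param p Bistable parameter list.
#' @param grid_step Spacing of the bracketing grid on [0, 1].
#' @return Data frame (one row per steady state, sorted by R) with columns
#'   \code{I}, \code{R_star} and \code{stability} ("stable", "unstable", or
#'   "degenerate" when |d(rate)/dR| < 1e-10, i.e. at a fold).
#' @export
bistable_steady_states <- function(I, p, grid_step = 1e-4) {
  stopifnot(length(I) == 1, I >= 0)
  g <- seq(0, 1, by = grid_step)
  v <- bistable_rate(g, I, p)
  roots <- g[v == 0]
  idx <- which(v[-1] * v[-length(v)] < 0)
  roots <- c(roots, vapply(idx, function(i)
    stats::uniroot(function(R) bistable_rate(R, I, p),
                   lower = g[i], upper = g[i + 1], tol = 1e-14)$root,
    numeric(1)))
  roots <- sort(unique(roots))
  d <- bistable_rate_dR(roots, I, p)
  stab <- ifelse(abs(d) < 1e-10, "degenerate",
                 ifelse(d < 0, "stable", "unstable"))
  data.frame(I = rep(I, length(roots)), R_star = roots, stability = stab,
             stringsAsFactors = FALSE)
}

#' Saddle-node (fold) inputs of the bistable switch
#'
#' Locates the input values at which the number of steady states changes, by
#' bisection on the branch count over an input interval. With the default
#' parameters the module is bistable at basal input (I = 0), so only the
#' upper fold — the switching threshold at which the lower stable branch
#' disappears — lies in the physical range I >= 0; the lower fold is then
#' reported as \code{NA}.
#'
#' @param p Bistable parameter list.
#' @param I_range Interval of inputs to scan.
#' @param n_scan Number of points of the initial branch-count scan.
#' @param tol Absolute tolerance on the fold locations.
#' @return List with \code{lower}, \code{upper} (fold inputs, \code{NA} when
#'   absent from the range) and \code{bistable} (logical: does any fold
#'   exist in the range). When the branch count never changes the result has
#'   \code{bistable = FALSE} and message attribute
#'   \code{"monostable for all I"} in the scanned range.
#' @export
bistable_fold_inputs <- function(p, I_range = c(0, 5), n_scan = 101,
                                 tol = 1e-8) {
  Is <- seq(I_range[1], I_range[2], length.out = n_scan)
  counts <- vapply(Is, function(I) nrow(bistable_steady_states(I, p)),
                   integer(1))
  changes <- which(diff(counts) != 0)
  bisect <- function(lo, hi, n_lo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (nrow(bistable_steady_states(mid, p)) == n_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  folds <- vapply(changes, function(i)
    bisect(Is[i], Is[i + 1], counts[i]), numeric(1))
  out <- list(lower = NA_real_, upper = NA_real_, bistable = length(folds) > 0)
  if (!out$bistable) {
    attr(out, "message") <- "monostable for all I"
    return(out)
  }
  ## the fold at which the branch count drops (ascending I) is the switching
  ## threshold ("upper" fold of the hysteresis loop)
  ups <- folds[counts[changes] > counts[changes + 1]]
  downs <- folds[counts[changes] < counts[changes + 1]]
  if (length(ups)) out$upper <- max(ups)
  if (length(downs)) out$lower <- min(downs)
  out
}

#' Bifurcation diagram of the bistable switch
#'
#' Tabulates all steady-state branches over a grid of inputs.
#'
#' @param p Bistable parameter list.
#' @param I_values Inputs at which to compute the branches.
#' @return Data frame of class \code{cord_bifurcation} with columns \code{I},
#'   \code{R_star}, \code{stability}, and the fold locations of
#'   [bistable_fold_inputs()] stored in attribute \code{"folds"}.
#' @export
bifurcation_diagram <- function(p, I_values = seq(0, 2, by = 0.01)) {
  tab <- do.call(rbind, lapply(I_values, bistable_steady_states, p = p))
  attr(tab, "folds") <- bistable_fold_inputs(
    p, I_range = range(I_values))
  class(tab) <- c("cord_bifurcation", class(tab))
  tab
}

#' Create or update an apoptosis trigger status
#'
#' Encodes the coupling between effector activity and the population model:
#' in \code{"monostable_latch"} mode the trigger fires when R1 first reaches
#' the threshold and never resets (irreversible commitment); in
#' \code{"bistable_reversible"} mode it simply tracks \code{R1 >= R1_th} at
#' the current instant, irreversibility being supplied by the hysteresis of
#' the bistable switch itself.
#'
#' @param R1 Current effector activity.
#' @param status A trigger status as returned by [trigger_status()] or a
#'   previous call; its mode must match \code{mode} when both are given.
#' @param p Effector parameter list containing \code{R1_th}.
#' @param time Current time, recorded as \code{time_fired} on a new firing.
#' @return Updated status list: \code{fired}, \code{mode}, \code{time_fired}
#'   (\code{NA} until first firing in latch mode).
#' @export
apoptosis_trigger <- function(R1, status, p, time = NA_real_) {
  stopifnot(is.list(status), status$mode %in%
              c("monostable_latch", "bistable_reversible"))
  th <- p$R1_th
  if (status$mode == "monostable_latch") {
    if (!status$fired && R1 >= th) {
      status$fired <- TRUE
      status$time_fired <- time
    }
  } else {
    status$fired <- R1 >= th
    if (status$fired && is.na(status$time_fired)) status$time_fired <- time
  }
  status
}

#' @rdname apoptosis_trigger
#' @param mode Trigger mode, \code{"monostable_latch"} or
#'   \code{"bistable_reversible"}.
#' @export
trigger_status <- function(mode = c("monostable_latch", "bistable_reversible")) {
  list(fired = FALSE, mode = match.arg(mode), time_fired = NA_real_)
}

## integrate one signalling module alone under a constant or piecewise input
## I_fun(t); returns deSolve output with columns t, R, R1
integrate_module <- function(module, p, I_fun, times, R0 = NULL, R1_0 = NULL,
                             rtol = 1e-10, atol = 1e-12) {
  rate_fun <- if (module == "bistable") {
    function(R, I) bistable_rate(R, I, p$bistable)
  } else {
    function(R, I) monostable_rate(R, I, p$monostable)
  }
  if (is.null(R0)) R0 <- basal_switch_state(module, p)$R
  if (is.null(R1_0)) R1_0 <- basal_switch_state(module, p)$R1
  rhs <- function(t, y, parms) {
    R <- min(max(y[1], 0), 1); R1 <- min(max(y[2], 0), 1)
    list(c(rate_fun(R, I_fun(t)), effector_rate(R1, R, p$effector)))
  }
  deSolve::ode(c(R = R0, R1 = R1_0), times, rhs, NULL, method = "lsoda",
               rtol = rtol, atol = atol)
}

## basal (I = 0) state of a module: monostable rests at the origin, bistable
## on its lower stable branch (computed, not hard-coded)
basal_switch_state <- function(module, p) {
  if (module == "bistable") {
    ss <- bistable_steady_states(0, p$bistable)
    R <- min(ss$R_star[ss$stability == "stable"])
  } else {
    R <- 0
  }
  list(R = R, R1 = R / (R + p$effector$k_r / p$effector$k_f))
}

## input at which the monostable steady-state effector reaches the apoptosis
## threshold (closed form by inverting the Hill and effector steady states)
monostable_threshold_input <- function(p) {
  th <- p$effector$R1_th
  kappa <- p$effector$k_r / p$effector$k_f
  R_needed <- th * kappa / (1 - th)
  if (R_needed >= 1) return(Inf)
  p$monostable$k_h * (R_needed / (1 - R_needed))^(1 / p$monostable$n)
}

## time for R1 to first reach the threshold under constant input I, from the
## module's basal state; NA if not reached by t_max (time unit of the rates)
time_to_threshold <- function(module, p, I, t_max = 50) {
  th <- p$effector$R1_th
  rate_fun <- if (module == "bistable") {
    function(R) bistable_rate(R, I, p$bistable)
  } else {
    function(R) monostable_rate(R, I, p$monostable)
  }
  b0 <- basal_switch_state(module, p)
  rhs <- function(t, y, parms) {
    R <- min(max(y[1], 0), 1); R1 <- min(max(y[2], 0), 1)
    list(c(rate_fun(R), effector_rate(R1, R, p$effector)))
  }
  out <- deSolve::lsodar(c(b0$R, b0$R1), seq(0, t_max, length.out = 201), rhs,
                         NULL, rtol = 1e-10, atol = 1e-12,
                         rootfunc = function(t, y, parms) y[2] - th)
  troot <- attr(out, "troot")
  if (length(troot) == 0) NA_real_ else troot[1]
}

#' Check that the two signalling modules are matched
#'
#' The two modules are meant to be interchangeable: their switching
#' thresholds (input at which the monostable steady-state effector reaches
#' the apoptosis threshold; upper fold of the bistable switch) should agree,
#' and the time for the effector to reach the threshold under a common
#' reference input should be comparable.
#'
#' @param p Signalling parameter block (\code{default_parameters()$signalling}).
#' @param I_reference Constant reference input used for the time-to-threshold
#'   comparison; defaults to 2, i.e. twice the common switching threshold.
#' @param tol Relative mismatch above which a ratio is flagged.
#' @return List with \code{threshold} (monostable, bistable, ratio),
#'   \code{time_to_threshold} (same structure, in the time unit of the
#'   rates), and logical flags \code{threshold_matched},
#'   \code{time_matched}.
#' @export
calibrate_module_match <- function(p, I_reference = 2, tol = 0.15) {
  th_mono <- monostable_threshold_input(p)
  th_bi <- bistable_fold_inputs(p$bistable)$upper
  t_mono <- time_to_threshold("monostable", p, I_reference)
  t_bi <- time_to_threshold("bistable", p, I_reference)
  r_th <- th_mono / th_bi
  r_t <- t_mono / t_bi
  list(
    threshold = list(monostable = th_mono, bistable = th_bi, ratio = r_th),
    time_to_threshold = list(monostable = t_mono, bistable = t_bi,
                             ratio = r_t, I_reference = I_reference),
    threshold_matched = is.finite(r_th) && abs(r_th - 1) <= tol,
    time_matched = is.finite(r_t) && abs(r_t - 1) <= tol
  )
}

#' Minimum pulse duration that permanently switches the bistable module
#'
#' Integrates the bistable switch under a rectangular input pulse of a given
#' height, lets it relax at basal input, and tests whether it settled on the
#' upper branch. The critical duration separating return-to-basal from
#' permanent switching is located by bisection. This quantifies the module's
#' transient irreversibility: a supra-threshold pulse must also last long
#' enough to commit the switch.
#'
#' @param p Signalling parameter block.
#' @param height Pulse height (I_ref units); must exceed the upper fold.
#' @param d_range Initial bracket on the duration (time unit of the rates).
#' @param relax Relaxation time at basal input after the pulse.
#' @param tol Absolute tolerance on the critical duration.
#' @return List: \code{critical_duration}, \code{height}, and the bracket
#'   outcomes \code{switched_at_upper}, \code{switched_at_lower}.
#' @export
critical_pulse_duration <- function(p, height = 2, d_range = c(0.01, 20),
                                    relax = 100, tol = 1e-3,
                                    rtol = 1e-10, atol = 1e-12) {
  switched_after <- function(d) {
    I_fun <- function(t) ifelse(t >= 0 & t < d, height, 0)
    out <- integrate_module("bistable", p, I_fun, c(0, d, d + relax),
                            rtol = rtol, atol = atol)
    R_end <- out[nrow(out), "R"]
    ss <- bistable_steady_states(0, p$bistable)
    unstable <- ss$R_star[ss$stability == "unstable"]
    if (length(unstable) == 0) return(TRUE)   # not bistable at basal input
    R_end > unstable[1]
  }
  lo <- d_range[1]; hi <- d_range[2]
  s_lo <- switched_after(lo); s_hi <- switched_after(hi)
  if (s_lo || !s_hi)
    stop("duration bracket does not straddle the switching boundary",
         call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (switched_after(mid)) hi <- mid else lo <- mid
  }
  list(critical_duration = (lo + hi) / 2, height = height,
       switched_at_upper = s_hi, switched_at_lower = s_lo)
}
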