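## Coupled tumour-cord simulator (method of lines).
##
## Per grid node the state carries the free (E) and albumin-bound (B)
## extracellular drug, intracellular drug (I), the signalling intermediate
## (R), the apoptosis effector (R1), the cell density (c, c_ref units) and,
## in the monostable case, the irreversible trigger latch (F). The radial
## diffusion operator couples E and B across nodes; everything else is local.
## Integration is stiff-implicit (deSolve), restarted at every dose-protocol
## edge so concentration discontinuities at the capillary wall are resolved
## exactly, with the monostable latch realized through solver root-finding
## events so the growth-rate collapse takes effect at the crossing time.

## state packing order, fixed for regression tests: columns E,B,I,R,R1,C,F
## flattened column-major over nodes
STATE_FIELDS <- c("E", "B", "I", "R", "R1", "C", "F")

#' Simulate the coupled tumour-cord model over a dosing protocol
#'
#' Integrates interstitial transport, intracellular signalling (monostable
#' or bistable module) and logistic population dynamics on the annular cord
#' domain. Initial conditions are the pre-injection equilibrium: no drug
#' anywhere, cell density at the untreated logistic carrying capacity, and
#' the signalling module at its basal (zero-input) steady state — for the
#' bistable module the lower stable branch, computed at setup.
#'
#' In monostable mode the apoptosis trigger is an irreversible latch: a
#' root-finding event fires at the instant a node's effector R1 first
#' reaches the threshold, and that node's growth rate collapses permanently.
#' In bistable mode the growth collapse tracks \code{R1 >= R1_th}
#' instantaneously (reversible); irreversibility, when it occurs, comes from
#' the hysteresis of the switch itself.
#'
#' @param protocol A [dose_protocol()] (capillary concentration schedule).
#' @param module \code{"bistable"} or \code{"monostable"}.
#' @param params Dimensional parameters ([default_parameters()] or a
#'   modified copy).
#' @param t_end_h End of the simulation, hours.
#' @param n_nodes Number of radial grid nodes.
#' @param times_h Output times (hours); default a uniform grid of
#'   \code{n_out} points on [0, \code{t_end_h}]. Protocol edges are always
#'   added to the output grid.
#' @param n_out Number of output times when \code{times_h} is NULL.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method; the default sparse-Jacobian
#'   BDF solver suits the banded coupling of the method-of-lines system.
#' @param death_rate_variant Passed to [population_rate()].
#' @return Object of class \code{cord_result}; see
#'   [as.data.frame.cord_result()] for the tidy export and
#'   [steady_state_diagnostics()] for end-state checks. Fields are
#'   \code{n_times x n_nodes} matrices; \code{c_norm} is cell density
#'   normalized by the untreated carrying capacity so the basal level is 1.
#' @export
simulate_cord <- function(protocol, module = c("bistable", "monostable"),
                          params = default_parameters(), t_end_h = 12,
                          n_nodes = 61, times_h = NULL, n_out = 201,
                          rtol = 1e-8, atol = 1e-10, method = "lsodes",
                          death_rate_variant = FALSE) {
  module <- match.arg(module)
  stopifnot(inherits(protocol, "cord_protocol"))
  if (!is.numeric(rtol) || rtol <= 0 || rtol >= 1e-2 ||
      !is.numeric(atol) || atol <= 0)
    stop("tolerance misconfiguration: need 0 < rtol < 1e-2 and atol > 0",
         call. = FALSE)
  nd <- nondimensionalize(params)
  grid <- build_grid(nd$rc, n_nodes)
  n <- grid$n_nodes
  sg <- nd$signalling
  th <- sg$effector$R1_th

  if (is.null(times_h)) times_h <- seq(0, t_end_h, length.out = n_out)
  times_h <- sort(unique(c(
    times_h, protocol_edges(protocol)[protocol_edges(protocol) <= t_end_h])))
  if (min(times_h) > 0) times_h <- c(0, times_h)
  tau_out <- times_h / nd$t_scale

  ## initial state: drug-free cord at population carrying capacity, module at
  ## its basal steady state
  basal <- basal_switch_state(module, sg)
  y0 <- c(E = rep(0, n), B = rep(0, n), I = rep(0, n),
          R = rep(basal$R, n), R1 = rep(basal$R1, n),
          C = rep(nd$c_star, n), F = rep(0, n))

  ix <- function(f) (match(f, STATE_FIELDS) - 1L) * n + seq_len(n)
  iE <- ix("E"); iB <- ix("B"); iI <- ix("I")
  iR <- ix("R"); iR1 <- ix("R1"); iC <- ix("C"); iF <- ix("F")

  env <- new.env()
  env$time_fired_tau <- rep(NA_real_, n)

  make_rhs <- function(S) {
    force(S)
    function(t, y, parms) {
      E <- pmax(y[iE], 0); B <- pmax(y[iB], 0); I <- pmax(y[iI], 0)
      R <- pmin(pmax(y[iR], 0), 1); R1 <- pmin(pmax(y[iR1], 0), 1)
      C <- pmax(y[iC], 0)
      tr <- extracellular_rates(E, B, I, C, S, grid, nd)
      dI <- intracellular_rate(E, I, nd)
      dR <- if (module == "bistable") bistable_rate(R, I, sg$bistable)
            else monostable_rate(R, I, sg$monostable)
      dR1 <- effector_rate(R1, R, sg$effector)
      triggered <- if (module == "bistable") R1 >= th else y[iF] > 0.5
      dC <- population_rate(C, triggered, nd,
                            death_rate_variant = death_rate_variant)
      list(c(tr$dE, tr$dB, dI, dR, dR1, dC, rep(0, n)))
    }
  }
  rootfunc <- function(t, y, parms) {
    ## one root component per node: crossing of the latch threshold; already
    ## latched nodes are pinned at +1 so they cannot re-fire
    ifelse(y[iF] > 0.5, 1, y[iR1] - th)
  }
  eventfunc <- function(t, y, parms) {
    newly <- y[iF] < 0.5 & y[iR1] >= th - 1e-12
    y[iF][newly] <- 1
    env$time_fired_tau[newly & is.na(env$time_fired_tau)] <- t
    y
  }

  ## integrate segment by segment between protocol edges
  edges <- protocol_edges(protocol) / nd$t_scale
  breaks <- sort(unique(c(0, edges[edges > 0 & edges < max(tau_out)],
                          max(tau_out))))
  y <- y0
  out_all <- NULL
  nsteps <- 0L
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    tt <- sort(unique(c(t0, tau_out[tau_out >= t0 & tau_out <= t1], t1)))
    ## S is constant inside a segment; sample at the midpoint so rounding of
    ## the tau <-> hours conversion cannot land on the wrong side of an edge
    S <- dose_concentration(protocol, (t0 + t1) / 2 * nd$t_scale)
    args <- list(y = y, times = tt, func = make_rhs(S), parms = NULL,
                 method = method, rtol = rtol, atol = atol)
    if (module == "monostable") {
      args$rootfunc <- rootfunc
      args$events <- list(func = eventfunc, root = TRUE)
    }
    sol <- do.call(deSolve::ode, args)
    if (attr(sol, "istate")[1] < 0)
      stop("solver failure in segment ", s, " (istate = ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    nsteps <- nsteps + attr(sol, "istate")[3]
    y <- as.numeric(sol[nrow(sol), -1])
    names(y) <- names(y0)
    seen <- if (is.null(out_all)) numeric(0) else out_all[, 1]
    keep <- sol[, 1] %in% tau_out & !(sol[, 1] %in% seen)
    out_all <- rbind(out_all, sol[keep, , drop = FALSE])
  }
  out_all <- out_all[order(out_all[, 1]), , drop = FALSE]
  tau <- out_all[, 1]

  field_mat <- function(f) {
    m <- out_all[, 1 + ix(f), drop = FALSE]
    dimnames(m) <- NULL
    m
  }
  fields <- list(E = field_mat("E"), B = field_mat("B"), I = field_mat("I"),
                 R = field_mat("R"), R1 = field_mat("R1"),
                 c = field_mat("C"))
  fields$c_norm <- fields$c / nd$c_star

  if (module == "monostable") {
    tf <- env$time_fired_tau * nd$t_scale
    fired <- outer(tau * nd$t_scale, tf,
                   function(t, f) !is.na(f) & t >= f - 1e-9)
  } else {
    fired <- fields$R1 >= th
    tf <- apply(fired, 2, function(col)
      if (any(col)) tau[which(col)[1]] * nd$t_scale else NA_real_)
  }

  res <- list(
    times_h = tau * nd$t_scale, tau = tau,
    fields = fields, fired = fired, time_fired_h = tf,
    module = module, params = params, nd = nd, grid = grid,
    protocol = protocol,
    solver = list(method = method, rtol = rtol, atol = atol,
                  n_steps = nsteps, n_nodes = n,
                  death_rate_variant = death_rate_variant),
    version = as.character(utils::packageVersion("cordsim"))
  )
  class(res) <- "cord_result"
  res
}

#' @export
print.cord_result <- function(x, ...) {
  cat(sprintf("Tumour-cord simulation (%s module)\n", x$module))
  cat(sprintf("  protocol: %s; t = [0, %.3g] h; %d nodes, %d output times\n",
              attr(x$protocol, "name"), max(x$times_h),
              x$grid$n_nodes, length(x$times_h)))
  nf <- sum(!is.na(x$time_fired_h))
  cat(sprintf("  apoptosis triggered at %d/%d nodes; final mean normalized density %.4g\n",
              nf, x$grid$n_nodes,
              mean(x$fields$c_norm[nrow(x$fields$c_norm), ])))
  invisible(x)
}

#' Tidy export of a simulation result
#'
#' @param x A \code{cord_result}.
#' @param row.names,optional Unused (base generic signature).
#' @param ... Unused.
#' @return Long data frame with one row per (time, node): columns
#'   \code{time_h}, \code{node}, \code{r}, \code{E}, \code{B}, \code{I},
#'   \code{R}, \code{R1}, \code{c}, \code{c_norm}, \code{fired}.
#' @export
as.data.frame.cord_result <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  n <- x$grid$n_nodes
  nt <- length(x$times_h)
  data.frame(
    time_h = rep(x$times_h, times = n),
    node = rep(seq_len(n), each = nt),
    r = rep(x$grid$r, each = nt),
    E = as.vector(x$fields$E), B = as.vector(x$fields$B),
    I = as.vector(x$fields$I), R = as.vector(x$fields$R),
    R1 = as.vector(x$fields$R1), c = as.vector(x$fields$c),
    c_norm = as.vector(x$fields$c_norm),
    fired = as.vector(x$fired)
  )
}

## rhs evaluated at the final state of a result, per hour
final_rates <- function(res) {
  nd <- res$nd
  n <- res$grid$n_nodes
  last <- function(f) res$fields[[f]][length(res$times_h), ]
  E <- last("E"); B <- last("B"); I <- last("I")
  R <- pmin(pmax(last("R"), 0), 1); R1 <- pmin(pmax(last("R1"), 0), 1)
  C <- last("c")
  S <- dose_concentration(res$protocol, max(res$times_h))
  tr <- extracellular_rates(pmax(E, 0), pmax(B, 0), pmax(I, 0), C, S,
                            res$grid, nd)
  sg <- nd$signalling
  dR <- if (res$module == "bistable") bistable_rate(R, I, sg$bistable)
        else monostable_rate(R, I, sg$monostable)
  triggered <- res$fired[length(res$times_h), ]
  rates <- c(tr$dE, tr$dB, intracellular_rate(pmax(E, 0), pmax(I, 0), nd),
             dR, effector_rate(R1, R, sg$effector),
             population_rate(C, triggered, nd))
  rates / nd$t_scale
}

#' Steady-state structure of a finished run
#'
#' Verifies that the trajectory has reached (numerical) steady state and
#' reports the structure the model predicts there: a spatially uniform
#' extracellular concentration, albumin binding at equilibrium
#' (\code{k3 E = k4 B}), the intracellular pump balance, and each node's
#' cell density at either the basal carrying capacity or extinction.
#'
#' @param result A \code{cord_result}.
#' @param tol Maximum allowed |d/dt| (per hour, dimensionless state) at the
#'   final time; above it the function errors with "not at steady state".
#' @param extinction_floor Normalized density below which a node is
#'   classified \code{"extinct"}.
#' @param basal_tol Allowed deviation of normalized density from 1 for the
#'   \code{"basal"} classification.
#' @return List: \code{max_rate} (per hour), \code{E_range} (spatial
#'   max-min of E), \code{E_mean}, \code{binding_residual} (max |k3 E - k4
#'   B| per t_scale), \code{pump_residual} (max |dI/dtau|), and
#'   \code{classification} (per node: basal / extinct / indeterminate).
#' @export
steady_state_diagnostics <- function(result, tol = 1e-5,
                                     extinction_floor = 1e-2,
                                     basal_tol = 1e-2) {
  rates <- final_rates(result)
  max_rate <- max(abs(rates))
  if (max_rate >= tol)
    stop(sprintf("not at steady state: max |d/dt| = %.3g per hour (tol %.3g)",
                 max_rate, tol), call. = FALSE)
  nt <- length(result$times_h)
  E <- result$fields$E[nt, ]; B <- result$fields$B[nt, ]
  I <- result$fields$I[nt, ]
  nd <- result$nd
  cn <- result$fields$c_norm[nt, ]
  cls <- ifelse(cn < extinction_floor, "extinct",
                ifelse(abs(cn - 1) < basal_tol, "basal", "indeterminate"))
  list(
    max_rate = max_rate,
    E_range = max(E) - min(E),
    E_mean = mean(E),
    binding_residual = max(abs(nd$k3 * E - nd$k4 * B)),
    pump_residual = max(abs(intracellular_rate(pmax(E, 0), pmax(I, 0), nd))),
    classification = cls
  )
}
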