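## Scenario library and kill-zone summary metrics.
##
## A "kill zone" is the region, growing outward from the capillary wall, in
## which apoptosis has been committed and the cell population is headed for
## extinction. At finite snapshot times the committed state — the trigger
## latch for the monostable module, effector activity above threshold for
## the bistable module — is the reliable marker, because the logistic
## population decay itself is slow (days) compared with the 12 h snapshots
## used throughout. Density-based detection against an extinction floor is
## also provided for long-time (steady-state) profiles.

#' Locate the kill zone in a nodal profile
#'
#' Accepts either a logical per-node "dead" indicator or a numeric profile
#' (e.g. normalized cell density) with a floor below which a node counts as
#' dead. Contiguous dead runs are reported individually, so disjoint kill
#' regions separated by surviving tissue (which arise, e.g., under
#' monostable second-bolus fractionation) are preserved. For numeric
#' profiles region edges are interpolated linearly between the straddling
#' nodes; for logical input the edge is the midpoint between the last dead
#' and first alive node.
#'
#' @param profile Logical vector (TRUE = dead) or numeric vector per node.
#' @param grid A \code{cord_grid}.
#' @param floor Threshold for numeric profiles: \code{profile < floor} is
#'   dead.
#' @return Object of class \code{kill_zone}: list with
#'   \code{boundary_position} (outer edge of the wall-adjacent dead region,
#'   normalized radius; 0 when no node is dead, 1 when all are),
#'   \code{fraction_dead} (dead arc of the radius, dimensionless),
#'   \code{n_regions}, and \code{regions} (data frame with \code{r_inner},
#'   \code{r_outer} per contiguous dead region).
#' @export
kill_zone_boundary <- function(profile, grid, floor = 1e-2) {
  r <- grid$r
  n <- grid$n_nodes
  stopifnot(length(profile) == n)
  numeric_profile <- !is.logical(profile)
  dead <- if (numeric_profile) profile < floor else profile

  edge <- function(i_dead, i_alive) {
    ## position of the dead/alive interface between two adjacent nodes
    if (numeric_profile) {
      f <- (floor - profile[i_dead]) / (profile[i_alive] - profile[i_dead])
      r[i_dead] + f * (r[i_alive] - r[i_dead])
    } else {
      (r[i_dead] + r[i_alive]) / 2
    }
  }

  regions <- NULL
  if (any(dead)) {
    rl <- rle(dead)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      r_in <- if (i0 == 1) r[1] else edge(i0, i0 - 1)
      r_out <- if (i1 == n) r[n] else edge(i1, i1 + 1)
      regions <- rbind(regions, data.frame(r_inner = r_in, r_outer = r_out))
    }
  } else {
    regions <- data.frame(r_inner = numeric(0), r_outer = numeric(0))
  }

  boundary <- if (nrow(regions) == 0) 0
  else if (regions$r_inner[1] > r[1] + grid$dr / 2) 0   # no wall-adjacent zone
  else if (nrow(regions) == 1 && all(dead)) 1
  else regions$r_outer[1]
  frac <- if (nrow(regions) == 0) 0
  else sum(regions$r_outer - regions$r_inner) / (r[n] - r[1])
  structure(list(boundary_position = boundary, fraction_dead = frac,
                 n_regions = nrow(regions), regions = regions),
            class = "kill_zone")
}

#' @export
print.kill_zone <- function(x, ...) {
  cat(sprintf("kill zone: boundary %.4g, fraction dead %.4g, %d region(s)\n",
              x$boundary_position, x$fraction_dead, x$n_regions))
  invisible(x)
}

#' Kill-zone summary of a simulation at a snapshot time
#'
#' @param result A \code{cord_result}.
#' @param snapshot_h Snapshot time (hours); the nearest output time is used.
#' @param basis \code{"trigger"} (default): a node is dead when its
#'   apoptosis trigger is committed at the snapshot — appropriate at finite
#'   times, before the slow logistic decay has run its course.
#'   \code{"density"}: a node is dead when normalized density is below
#'   \code{floor} — appropriate for long-time profiles.
#' @param floor Extinction floor for the density basis.
#' @return A [kill_zone_boundary()] summary with the snapshot time and basis
#'   attached.
#' @export
summarize_kill_zone <- function(result, snapshot_h = max(result$times_h),
                                basis = c("trigger", "density"),
                                floor = 1e-2) {
  basis <- match.arg(basis)
  it <- which.min(abs(result$times_h - snapshot_h))
  kz <- if (basis == "trigger") {
    if (result$module == "bistable") {
      ## R1 is continuous in r, so interpolate the threshold crossing
      kill_zone_boundary(-(result$fields$R1[it, ]), result$grid,
                         floor = -result$nd$signalling$effector$R1_th)
    } else {
      kill_zone_boundary(result$fired[it, ], result$grid)
    }
  } else {
    kill_zone_boundary(result$fields$c_norm[it, ], result$grid, floor = floor)
  }
  kz$snapshot_h <- result$times_h[it]
  kz$basis <- basis
  kz
}

#' Sweep of bolus pulse heights at fixed duration
#'
#' Runs one simulation per pulse height and tabulates the kill-zone summary
#' at the snapshot time. The kill-zone boundary is a non-decreasing and
#' strongly non-linear function of height: nothing happens below the
#' signalling threshold, a wall-adjacent dead zone opens and broadens above
#' it, and a sufficiently strong pulse kills the whole cord.
#'
#' @param heights Capillary pulse heights (E_ref units).
#' @param duration_h Pulse duration (hours).
#' @param module Signalling module.
#' @param snapshot_h Snapshot time for the summaries (hours).
#' @param params,... Passed to [simulate_cord()].
#' @return Data frame: \code{height}, \code{boundary}, \code{fraction_dead},
#'   \code{n_regions}.
#' @export
pulse_height_sweep <- function(heights, duration_h = 2,
                               module = "bistable", snapshot_h = 12,
                               params = default_parameters(), ...) {
  rows <- lapply(heights, function(h) {
    res <- simulate_cord(protocol_pulse(h, duration_h), module = module,
                         params = params, t_end_h = snapshot_h, ...)
    kz <- summarize_kill_zone(res, snapshot_h)
    data.frame(height = h, boundary = kz$boundary_position,
               fraction_dead = kz$fraction_dead, n_regions = kz$n_regions)
  })
  do.call(rbind, rows)
}

#' Fractionation sweep at fixed total dose
#'
#' Splits a fixed total dose (height x duration) across different infusion
#' times and tabulates the resulting kill zones. Too short an infusion
#' floods the cord only briefly (fast washout back through the wall); too
#' long an infusion stays below the signalling threshold; an intermediate
#' infusion time maximizes killing.
#'
#' @param total_dose Product height x duration (E_ref units x hours).
#' @param durations_h Infusion times to test.
#' @param module,snapshot_h,params,... As in [pulse_height_sweep()].
#' @return Data frame: \code{duration_h}, \code{height}, \code{boundary},
#'   \code{fraction_dead}, \code{n_regions}.
#' @export
fractionation_sweep <- function(total_dose = 7, durations_h,
                                module = "bistable", snapshot_h = 12,
                                params = default_parameters(), ...) {
  stopifnot(all(durations_h > 0))
  rows <- lapply(durations_h, function(d) {
    h <- total_dose / d
    res <- simulate_cord(protocol_pulse(h, d), module = module,
                         params = params,
                         t_end_h = max(snapshot_h, d + 1e-3), ...)
    kz <- summarize_kill_zone(res, snapshot_h)
    data.frame(duration_h = d, height = h, boundary = kz$boundary_position,
               fraction_dead = kz$fraction_dead, n_regions = kz$n_regions)
  })
  do.call(rbind, rows)
}

#' Double-bolus study
#'
#' Compares a single bolus with two identical boluses separated by each of
#' the given start-to-start gaps. Summaries are taken \code{followup_h}
#' hours after the start of the second bolus (and, for the single-bolus
#' reference, after its own start). For each gap the single-bolus run is
#' also continued to the same snapshot, and the study reports how much the
#' second bolus changed the cell density and trigger times of nodes that
#' the first bolus had already committed — quantifying that a second bolus
#' widens the kill zone but barely accelerates death inside the existing
#' one.
#'
#' @param height,duration_h Bolus height and duration.
#' @param gaps_h Start-to-start intervals between the two boluses (hours).
#' @param module,params,... As in [pulse_height_sweep()].
#' @param followup_h Time after each bolus start at which the kill zone is
#'   summarized.
#' @return Data frame with one row for the single bolus (\code{gap_h = NA})
#'   and one per gap: \code{boundary}, \code{fraction_dead},
#'   \code{n_regions}, \code{snapshot_h},
#'   \code{max_density_change_inner} (max |change in normalized density|
#'   at the snapshot over nodes inside the single-bolus kill zone) and
#'   \code{max_tfire_shift_inner_h} (max |change of trigger time| there);
#'   both are \code{NA} when the single bolus killed nothing.
#' @export
double_bolus_study <- function(height = 4, duration_h = 1.5,
                               gaps_h = c(24, 48), module = "bistable",
                               params = default_parameters(),
                               followup_h = 12, ...) {
  single <- simulate_cord(protocol_pulse(height, duration_h), module = module,
                          params = params, t_end_h = followup_h, ...)
  kz1 <- summarize_kill_zone(single, followup_h)
  inner <- !is.na(single$time_fired_h)
  rows <- list(data.frame(
    gap_h = NA_real_, boundary = kz1$boundary_position,
    fraction_dead = kz1$fraction_dead, n_regions = kz1$n_regions,
    snapshot_h = kz1$snapshot_h,
    max_density_change_inner = NA_real_, max_tfire_shift_inner_h = NA_real_))
  for (g in gaps_h) {
    snap <- g + followup_h
    res <- simulate_cord(
      protocol_pulses(height, duration_h, gap_h = g, n_pulses = 2),
      module = module, params = params, t_end_h = snap, ...)
    kz <- summarize_kill_zone(res, snap)
    dens_chg <- tfire_chg <- NA_real_
    if (any(inner)) {
      ref <- simulate_cord(protocol_pulse(height, duration_h),
                           module = module, params = params, t_end_h = snap,
                           ...)
      it <- which.min(abs(res$times_h - snap))
      ir <- which.min(abs(ref$times_h - snap))
      dens_chg <- max(abs(res$fields$c_norm[it, inner] -
                            ref$fields$c_norm[ir, inner]))
      tfire_chg <- max(abs(res$time_fired_h[inner] -
                             ref$time_fired_h[inner]), na.rm = TRUE)
    }
    rows <- c(rows, list(data.frame(
      gap_h = g, boundary = kz$boundary_position,
      fraction_dead = kz$fraction_dead, n_regions = kz$n_regions,
      snapshot_h = kz$snapshot_h,
      max_density_change_inner = dens_chg,
      max_tfire_shift_inner_h = tfire_chg)))
  }
  do.call(rbind, rows)
}

#' Effect of the tumour-cord radius on a fixed bolus
#'
#' Re-nondimensionalizes the model for each cord radius, applies the same
#' capillary-wall protocol, and reports the kill zone in absolute units.
#' A fixed bolus spreads over a larger interstitial volume in a wider cord
#' and is diluted, shrinking the absolute dead-region width; a sustained
#' supra-threshold infusion kills the whole cord regardless of radius.
#'
#' @param radii_um Tumour-cord radii to test (micrometres, all > R_C).
#' @param protocol Dose protocol applied at the wall for every radius.
#' @param module,snapshot_h,params,... As in [pulse_height_sweep()].
#' @return Data frame: \code{R_T_um}, \code{boundary} (normalized),
#'   \code{dead_width_um} (absolute width of the wall-adjacent dead zone),
#'   \code{fraction_dead}.
#' @export
cord_radius_study <- function(radii_um, protocol = protocol_pulse(4, 1.75),
                              module = "bistable", snapshot_h = 12,
                              params = default_parameters(), ...) {
  stopifnot(all(radii_um > params$R_C))
  rows <- lapply(radii_um, function(RT) {
    p <- params
    p$R_T <- RT
    res <- simulate_cord(protocol, module = module, params = p,
                         t_end_h = snapshot_h, ...)
    kz <- summarize_kill_zone(res, snapshot_h)
    rc <- p$R_C / p$R_T
    width <- if (kz$boundary_position > 0)
      (kz$boundary_position - rc) * RT else 0
    data.frame(R_T_um = RT, boundary = kz$boundary_position,
               dead_width_um = width, fraction_dead = kz$fraction_dead)
  })
  do.call(rbind, rows)
}

## ---------------------------------------------------------------------------
## scenario registry

scenario_registry <- function() {
  list(
    constant_infusion_bistable = list(
      description = "sustained capillary concentrations spanning the killing threshold, bistable module",
      module = "bistable", sweep = list(heights = c(0.05, 0.1, 0.3, 1)),
      snapshot_h = 200, t_end_h = 200, representative = "heights"),
    constant_infusion_monostable = list(
      description = "sustained capillary concentrations spanning the killing threshold, monostable module",
      module = "monostable", sweep = list(heights = c(0.05, 0.1, 0.3, 1)),
      snapshot_h = 200, t_end_h = 200, representative = "heights"),
    single_bolus = list(
      description = "reference single bolus: S = 4 for 1.75 h, profiles at 30 min and 12 h, bistable module; partial kill with surviving rear",
      module = "bistable", protocol = protocol_pulse(4, 1.75),
      snapshot_h = 12, profile_times_h = c(0.5, 12), t_end_h = 12),
    single_bolus_monostable = list(
      description = "single bolus inside the monostable partial-kill band: S = 3.2 for 2 h (representative height)",
      module = "monostable", protocol = protocol_pulse(3.2, 2),
      snapshot_h = 12, profile_times_h = c(0.5, 12), t_end_h = 12,
      representative = "height"),
    pulse_height_sweep_bistable = list(
      description = "2 h boluses of increasing height, kill zone at 12 h, bistable module",
      module = "bistable", duration_h = 2, snapshot_h = 12,
      sweep = list(heights = c(1, 2, 3.4, 3.6, 4, 8)),
      representative = "heights"),
    pulse_height_sweep_monostable = list(
      description = "2 h boluses of increasing height, kill zone at 12 h, monostable module",
      module = "monostable", duration_h = 2, snapshot_h = 12,
      sweep = list(heights = c(1, 2, 3.2, 3.3, 4, 8)),
      representative = "heights"),
    fractionation_bistable = list(
      description = "fixed total dose 7 (E_ref x h) split over different infusion times, bistable module",
      module = "bistable", total_dose = 7, snapshot_h = 12,
      sweep = list(durations_h = c(0.05, 0.25, 1, 1.75, 4, 12)),
      representative = "total_dose, durations_h"),
    fractionation_monostable = list(
      description = "fixed total dose 6.5 (E_ref x h) split over different infusion times, monostable module",
      module = "monostable", total_dose = 6.5, snapshot_h = 12,
      sweep = list(durations_h = c(0.02, 0.05, 0.25, 1, 1.75, 4, 12)),
      representative = "total_dose, durations_h"),
    double_bolus_bistable = list(
      description = "two boluses S = 3.7, T = 1.5 h with 24 h and 48 h start-to-start gaps, bistable module; snapshots 12 h after the second bolus",
      module = "bistable", height = 3.7, duration_h = 1.5,
      sweep = list(gaps_h = c(24, 48)), representative = "height"),
    double_bolus_monostable = list(
      description = "two boluses S = 3.2, T = 1.5 h with 24 h and 48 h start-to-start gaps, monostable module",
      module = "monostable", height = 3.2, duration_h = 1.5,
      sweep = list(gaps_h = c(24, 48)), representative = "height"),
    cord_radius = list(
      description = "fixed bolus S = 4, T = 1.75 h applied to cords of increasing radius, bistable module, kill zone at 12 h",
      module = "bistable", protocol = protocol_pulse(4, 1.75),
      snapshot_h = 12, sweep = list(radii_um = c(120, 130, 140)),
      representative = "radii_um"),
    infusion_time_bistable = list(
      description = "kill-zone position vs infusion time at fixed pulse heights, bistable module",
      module = "bistable", snapshot_h = 12,
      sweep = list(heights = c(3.6, 4), durations_h = c(0.5, 1, 1.75, 3)),
      representative = "heights, durations_h"),
    infusion_time_monostable = list(
      description = "kill-zone position vs infusion time at fixed pulse heights, monostable module",
      module = "monostable", snapshot_h = 12,
      sweep = list(heights = c(3.2, 4), durations_h = c(0.5, 1, 1.75, 3)),
      representative = "heights, durations_h"),
    second_bolus_fractionation_bistable = list(
      description = "fixed first bolus (S = 3.7, T = 1.5 h), second dose of equal total size fractionated into 1, 2 or 3 sub-pulses starting 48 h later; profiles at 60 h, bistable module",
      module = "bistable", first = list(S = 3.7, T = 1.5), gap_h = 48,
      snapshot_h = 60, sweep = list(n_fractions = c(1, 2, 3)),
      representative = "first, n_fractions"),
    second_bolus_fractionation_monostable = list(
      description = "fixed first bolus (S = 3.4, T = 1.5 h), second dose fractionated, monostable module; disjoint kill regions can appear",
      module = "monostable", first = list(S = 3.4, T = 1.5), gap_h = 48,
      snapshot_h = 60, sweep = list(n_fractions = c(1, 2, 3)),
      representative = "first, n_fractions")
  )
}

#' Look up a named scenario
#'
#' The package ships a registry of fully resolved study configurations
#' covering the behaviours the simulator is designed to exhibit: constant
#' infusion above/below threshold, the reference single bolus, pulse-height
#' and fractionation sweeps, double-bolus schedules, cord-radius
#' sensitivity, infusion-time dependence and second-bolus fractionation.
#' Sweep values not pinned down by the reference dose (heights, durations,
#' fraction counts) are representative choices spanning the sub-threshold
#' to full-kill range, and are marked as such in the entry.
#'
#' @param name Scenario name; see [scenario_names()].
#' @return The scenario configuration list (module, protocol or sweep
#'   definition, snapshot times).
#' @export
scenario <- function(name) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario: ", name, "; known scenarios: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  c(list(name = name), reg[[name]])
}

#' @rdname scenario
#' @export
scenario_names <- function() names(scenario_registry())

#' Protocol for a fractionated second dose after a fixed first bolus
#'
#' The first bolus is S for T hours at t = 0. A second dose with the same
#' total drug amount (S x T) starts \code{gap_h} later, split into
#' \code{n_fractions} equal sub-pulses of the original height, separated by
#' \code{spacing_h}.
#'
#' @param S,T_h First-bolus height and duration.
#' @param gap_h Start-to-start gap between first bolus and second dose.
#' @param n_fractions Number of equal sub-pulses of the second dose.
#' @param spacing_h Start-to-start spacing of the sub-pulses.
#' @return A \code{cord_protocol}.
#' @export
second_bolus_fractionation_protocol <- function(S = 4, T_h = 1.5, gap_h = 48,
                                                n_fractions = 2,
                                                spacing_h = 4) {
  sub_T <- T_h / n_fractions
  starts <- c(0, gap_h + (seq_len(n_fractions) - 1) * spacing_h)
  ends <- c(T_h, gap_h + (seq_len(n_fractions) - 1) * spacing_h + sub_T)
  dose_protocol(starts, ends, rep(S, n_fractions + 1),
                name = sprintf("bolus + %d-way fractionated second dose",
                               n_fractions))
}

#' Run a registered scenario
#'
#' Dispatches on the scenario type: single runs return the
#' \code{cord_result}; sweeps return their summary table.
#'
#' @param name Scenario name.
#' @param params Dimensional parameters.
#' @param ... Passed to the underlying simulation calls.
#' @return A \code{cord_result} or a summary data frame, depending on the
#'   scenario.
#' @export
run_scenario <- function(name, params = default_parameters(), ...) {
  sc <- scenario(name)
  if (grepl("^constant_infusion", name)) {
    rows <- lapply(sc$sweep$heights, function(S) {
      res <- simulate_cord(sc$protocol_fun(S), module = sc$module,
                           params = params, t_end_h = sc$t_end_h, ...)
      kz <- summarize_kill_zone(res, sc$snapshot_h)
      data.frame(height = S, boundary = kz$boundary_position,
                 fraction_dead = kz$fraction_dead,
                 final_min_c_norm = min(res$fields$c_norm[length(res$times_h), ]),
                 final_max_c_norm = max(res$fields$c_norm[length(res$times_h), ]))
    })
    return(do.call(rbind, rows))
  }
  if (name == "single_bolus")
    return(simulate_cord(sc$protocol, module = sc$module, params = params,
                         t_end_h = sc$t_end_h,
                         times_h = sort(unique(c(sc$profile_times_h,
                                                 seq(0, sc$t_end_h, by = 0.25)))),
                         ...))
  if (grepl("^pulse_height_sweep", name))
    return(pulse_height_sweep(sc$sweep$heights, sc$duration_h, sc$module,
                              sc$snapshot_h, params, ...))
  if (grepl("^fractionation", name))
    return(fractionation_sweep(sc$total_dose, sc$sweep$durations_h,
                               sc$module, sc$snapshot_h, params, ...))
  if (grepl("^double_bolus", name))
    return(double_bolus_study(sc$height, sc$duration_h, sc$sweep$gaps_h,
                              sc$module, params, ...))
  if (name == "cord_radius")
    return(cord_radius_study(sc$sweep$radii_um, sc$protocol, sc$module,
                             sc$snapshot_h, params, ...))
  if (grepl("^infusion_time", name)) {
    rows <- lapply(sc$sweep$heights, function(h) {
      tab <- do.call(rbind, lapply(sc$sweep$durations_h, function(d) {
        res <- simulate_cord(protocol_pulse(h, d), module = sc$module,
                             params = params, t_end_h = sc$snapshot_h, ...)
        kz <- summarize_kill_zone(res, sc$snapshot_h)
        data.frame(height = h, duration_h = d,
                   boundary = kz$boundary_position,
                   fraction_dead = kz$fraction_dead)
      }))
      tab
    })
    return(do.call(rbind, rows))
  }
  if (grepl("^second_bolus_fractionation", name)) {
    rows <- lapply(sc$sweep$n_fractions, function(nf) {
      pr <- second_bolus_fractionation_protocol(
        sc$first$S, sc$first$T, sc$gap_h, n_fractions = nf)
      res <- simulate_cord(pr, module = sc$module, params = params,
                           t_end_h = sc$snapshot_h, ...)
      kz <- summarize_kill_zone(res, sc$snapshot_h)
      data.frame(n_fractions = nf, boundary = kz$boundary_position,
                 fraction_dead = kz$fraction_dead, n_regions = kz$n_regions)
    })
    return(do.call(rbind, rows))
  }
  stop("no runner for scenario: ", name, call. = FALSE)
}
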