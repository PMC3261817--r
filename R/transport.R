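## Interstitial drug transport on the annular cross-section of a tumour cord.
##
## The domain is the dimensionless annulus r in [rc, 1] (rc = R_C/R_T) with
## purely radial variation. Free drug enters through the capillary wall
## (Kedem-Katchalsky flux), diffuses, binds reversibly to albumin, and is
## exchanged with the intracellular compartment by saturable pumps whose
## volumetric effect scales with the local cell density. Bound drug diffuses
## slowly and does not cross the capillary wall. The outer cord boundary is
## a symmetry (zero-flux) boundary shared with neighbouring cords.

#' Build a uniform radial grid on the tumour-cord annulus
#'
#' @param rc Dimensionless capillary radius \code{R_C/R_T}, in (0, 1).
#' @param n_nodes Number of nodes (>= 8), including both boundaries.
#' @return Object of class \code{cord_grid}: node positions \code{r} from
#'   \code{rc} to 1, spacing \code{dr}, \code{n_nodes}, and the face radii
#'   \code{r_half} used by the conservative finite-volume operator.
#' @export
build_grid <- function(rc, n_nodes = 61) {
  if (!is.numeric(rc) || length(rc) != 1 || rc <= 0 || rc >= 1)
    stop("rc must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(n_nodes) || n_nodes < 8 || n_nodes != round(n_nodes))
    stop("n_nodes must be an integer >= 8", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  r <- seq(rc, 1, length.out = n_nodes)
  g <- list(r = r, dr = r[2] - r[1], n_nodes = n_nodes,
            rc = rc, spacing = "uniform",
            r_half = (r[-1] + r[-n_nodes]) / 2)
  class(g) <- "cord_grid"
  g
}

#' Discrete radial Laplacian on the cord grid
#'
#' Second-order conservative finite-volume approximation of the cylindrical
#' radial operator \code{(1/r) d/dr (r dF/dr)} at interior nodes. Boundary
#' rows are returned as 0: boundary fluxes are the responsibility of the
#' boundary-condition handling in [extracellular_rates()].
#'
#' @param field Numeric vector of nodal values, length \code{grid$n_nodes}.
#' @param grid A \code{cord_grid}.
#' @return Vector of the same length; entries 1 and n are 0.
#' @export
radial_laplacian <- function(field, grid) {
  n <- grid$n_nodes
  if (length(field) != n) stop("field length does not match grid", call. = FALSE)
  out <- numeric(n)
  i <- 2:(n - 1)
  out[i] <- (grid$r_half[i] * (field[i + 1] - field[i]) -
               grid$r_half[i - 1] * (field[i] - field[i - 1])) /
    (grid$r[i] * grid$dr^2)
  out
}

#' Transcapillary drug flux (Kedem-Katchalsky)
#'
#' Flux of free drug across the capillary wall into the interstitium:
#' \code{K (S - E_wall) + K1}, a permeability-driven diffusive exchange plus
#' a lumped convective (Starling) term.
#'
#' @param S Capillary drug concentration (E_ref units).
#' @param E_wall Extracellular concentration at the wall node.
#' @param K Wall permeability (dimensionless velocity \code{Kw} of the
#'   nondimensional model, or mm/hr when used dimensionally).
#' @param K1 Constant convective flux term (default 0).
#' @return The wall flux, positive into the interstitium.
#' @export
capillary_flux <- function(S, E_wall, K, K1 = 0) {
  if (any(S < 0) || any(E_wall < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  K * (S - E_wall) + K1
}

#' Rate of change of the intracellular drug concentration
#'
#' \code{dI/dt = V1 E/(k1 + E) - V2 I/(k2 + I)}: saturable pumping in and
#' out per unit of cells. Works on the dimensionless parameter set
#' (\code{v1}, \code{v2}) or any consistently scaled one.
#'
#' @param E Extracellular free-drug concentration (E_ref units). Vectorized.
#' @param I Intracellular concentration (I_ref units). Vectorized.
#' @param p List with \code{v1}, \code{v2}, \code{k1}, \code{k2}.
#' @return \code{dI/dt} in the time unit of \code{v1}.
#' @export
intracellular_rate <- function(E, I, p) {
  if (any(E < 0) || any(I < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  p$v1 * E / (p$k1 + E) - p$v2 * I / (p$k2 + I)
}

#' Rates of change of the extracellular free and bound drug fields
#'
#' Interior nodes: diffusion plus cellular efflux/uptake (scaled by the
#' local cell density) plus albumin binding/unbinding for E; diffusion plus
#' binding/unbinding for B. The inner boundary node receives the
#' Kedem-Katchalsky wall flux for E through a conservative half-cell
#' balance (bound drug does not cross the wall); the outer boundary is
#' zero-flux for both fields.
#'
#' @param E,B,I Nodal fields (E_ref / E_ref / I_ref units).
#' @param c_t Nodal cell density (c_ref units).
#' @param S Current capillary concentration (E_ref units).
#' @param grid A \code{cord_grid}.
#' @param nd Dimensionless model from [nondimensionalize()].
#' @return List with \code{dE} and \code{dB} (per \code{t_scale}).
#' @export
extracellular_rates <- function(E, B, I, c_t, S, grid, nd) {
  if (any(c_t < 0)) stop("cell density must be non-negative", call. = FALSE)
  if (any(E < 0) || any(B < 0) || any(I < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  n <- grid$n_nodes
  exch <- nd$chi * c_t * (nd$v2 * I / (nd$k2 + I) - nd$v1 * E / (nd$k1 + E))
  bind <- nd$k3 * E - nd$k4 * B

  dE <- nd$D_E * radial_laplacian(E, grid) + exch - bind
  dB <- nd$D_B * radial_laplacian(B, grid) + bind

  ## half-cell volumes (per radian, per unit length) at the two boundaries
  dr <- grid$dr
  vol_in <- grid$r[1] * dr / 2 + dr^2 / 8
  vol_out <- grid$r[n] * dr / 2 - dr^2 / 8

  Fw <- capillary_flux(S, E[1], nd$Kw, nd$K1)
  dE[1] <- (grid$r_half[1] * nd$D_E * (E[2] - E[1]) / dr + grid$r[1] * Fw) /
    vol_in + exch[1] - bind[1]
  dB[1] <- (grid$r_half[1] * nd$D_B * (B[2] - B[1]) / dr) / vol_in + bind[1]

  dE[n] <- (-grid$r_half[n - 1] * nd$D_E * (E[n] - E[n - 1]) / dr) / vol_out +
    exch[n] - bind[n]
  dB[n] <- (-grid$r_half[n - 1] * nd$D_B * (B[n] - B[n - 1]) / dr) / vol_out +
    bind[n]
  list(dE = dE, dB = dB)
}

#' Dosing protocols: piecewise-constant capillary drug concentration
#'
#' A dose protocol is an ordered set of non-overlapping segments
#' \code{[start_h, end_h)} during which the capillary concentration equals
#' \code{S} (E_ref units); outside all segments the capillary concentration
#' is 0. Segments are closed on the left and open on the right, and the
#' integrator restarts at every edge so discontinuities are not smoothed.
#'
#' @param start_h,end_h,S Numeric vectors of equal length: segment start and
#'   end times (hours) and capillary concentrations.
#' @param name Label for the protocol.
#' @return Object of class \code{cord_protocol}: data frame with columns
#'   \code{start_h}, \code{end_h}, \code{S}, sorted by start time.
#' @export
#' @examples
#' dose_protocol(0, 1.75, 4, name = "single bolus")
dose_protocol <- function(start_h, end_h, S, name = "protocol") {
  stopifnot(length(start_h) == length(end_h), length(S) == length(start_h))
  if (length(start_h) == 0) {
    seg <- data.frame(start_h = numeric(0), end_h = numeric(0), S = numeric(0))
  } else {
    if (any(start_h < 0) || any(end_h <= start_h))
      stop("segments need 0 <= start_h < end_h", call. = FALSE)
    if (any(S < 0)) stop("capillary concentration must be >= 0", call. = FALSE)
    o <- order(start_h)
    seg <- data.frame(start_h = start_h[o], end_h = end_h[o], S = S[o])
    if (nrow(seg) > 1 && any(seg$start_h[-1] < seg$end_h[-nrow(seg)]))
      stop("protocol segments overlap", call. = FALSE)
  }
  structure(seg, name = name, class = c("cord_protocol", "data.frame"))
}

#' @rdname dose_protocol
#' @param duration_h Total duration of a constant infusion (hours).
#' @export
protocol_constant <- function(S, duration_h = 1e6)
  dose_protocol(0, duration_h, S, name = sprintf("constant S=%g", S))

#' @rdname dose_protocol
#' @export
protocol_pulse <- function(S, duration_h, start_h = 0)
  dose_protocol(start_h, start_h + duration_h, S,
                name = sprintf("pulse S=%g T=%gh", S, duration_h))

#' @rdname dose_protocol
#' @param gap_h Time from the start of one pulse to the start of the next.
#' @param n_pulses Number of identical pulses.
#' @export
protocol_pulses <- function(S, duration_h, gap_h, n_pulses = 2) {
  if (gap_h < duration_h) stop("pulses would overlap: gap_h < duration_h",
                               call. = FALSE)
  starts <- (seq_len(n_pulses) - 1) * gap_h
  dose_protocol(starts, starts + duration_h, rep(S, n_pulses),
                name = sprintf("%d pulses S=%g T=%gh gap=%gh",
                               n_pulses, S, duration_h, gap_h))
}

#' Capillary concentration prescribed by a protocol at a given time
#'
#' @param protocol A \code{cord_protocol}.
#' @param t_h Time(s) in hours. Vectorized.
#' @return Capillary concentration S (E_ref units) at each time; 0 outside
#'   all segments.
#' @export
dose_concentration <- function(protocol, t_h) {
  stopifnot(inherits(protocol, "cord_protocol"))
  if (any(t_h < 0)) stop("time must be non-negative", call. = FALSE)
  out <- numeric(length(t_h))
  for (i in seq_len(nrow(protocol))) {
    hit <- t_h >= protocol$start_h[i] & t_h < protocol$end_h[i]
    out[hit] <- protocol$S[i]
  }
  out
}

## event times (hours) at which the integrator must restart
protocol_edges <- function(protocol)
  sort(unique(c(protocol$start_h, protocol$end_h)))
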