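#' Default model parameters for the tumour-cord drug-response model
#'
#' Returns the dimensional parameter set used throughout the package:
#' interstitial transport and cellular uptake constants for doxorubicin,
#' logistic tumour-cell population rates, cord geometry, and the parameters
#' of both intracellular apoptosis-signalling modules.
#'
#' Units are mixed on purpose, following the conventions in which each
#' constant is usually reported: diffusivities in mm^2/hr, transmembrane
#' transport maxima in ng/(1e5 cells)/min, binding rates in hr^-1, population
#' rates in day^-1, radii in micrometres. [nondimensionalize()] reconciles
#' them into a single dimensionless system.
#'
#' The capillary-wall permeability \code{K} (mm/hr) and the lumped convective
#' transmural flux \code{K1} are not constrained by the tabulated literature
#' values at this level of description. \code{K} defaults to 1.3 mm/hr
#' (3.6e-5 cm/s, within the physiological range of transcapillary
#' permeability for small-molecule chemotherapeutics), a value calibrated
#' once so that the reference bolus (capillary concentration 4 for 1.75 h)
#' produces the model's characteristic partial-kill structure: a dead zone
#' adjacent to the capillary wall with surviving tissue at the cord
#' periphery. \code{K1} defaults to 0 (convective leak off). Both are plain
#' fields and can be overridden.
#'
#' @return An object of class \code{cord_params}: a named list with transport
#'   constants (\code{k_d}, \code{k_db}, \code{V1}, \code{V2}, \code{k1},
#'   \code{k2}, \code{k3}, \code{k4}, \code{K}, \code{K1}), population rates
#'   (\code{a1}, \code{a2}, \code{a1_triggered}, \code{b}), geometry
#'   (\code{R_C}, \code{R_T}, micrometres), reference scales (\code{E_ref}
#'   ug/mm^3, \code{I_ref} ng/(1e5 cells), \code{c_ref} cells/mm^3) and a
#'   \code{signalling} sub-list (see [signalling_parameters()]).
#' @seealso [validate_parameters()], [nondimensionalize()], [read_parameters()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$k_d                      # 0.568 mm^2/hr
#' p$signalling$bistable$k_fb # 2.927 hr^-1
default_parameters <- function() {
  p <- list(
    ## interstitial transport (free / albumin-bound drug)
    k_d  = 0.568,    # free-drug diffusion coefficient, mm^2/hr
    k_db = 0.032,    # bound-drug diffusion coefficient, mm^2/hr
    V1   = 0.28,     # max cellular uptake rate, ng/(1e5 cells)/min
    V2   = 0.28,     # max cellular efflux rate, ng/(1e5 cells)/min
    k1   = 0.219,    # Michaelis constant, extracellular side, ug/ml
    k2   = 1.37,     # Michaelis constant, intracellular side, ng/(1e5 cells)
    k3   = 3000,     # free-drug -> albumin binding rate, hr^-1
    k4   = 1000,     # dissociation rate, hr^-1
    ## capillary wall (Kedem-Katchalsky)
    K    = 1.3,      # wall permeability, mm/hr (calibrated; see Details)
    K1   = 0,        # lumped convective transmural flux, ug/mm^2/hr
    ## population
    a1   = 0.5,      # linear growth rate, day^-1
    a2   = 0.24,     # natural decay rate, day^-1
    a1_triggered = 0,# growth rate once apoptosis has been triggered, day^-1
    b    = 0.02592,  # logistic saturation constant, mm^3/(1e5 cells)/day
    ## geometry
    R_C  = 10,       # capillary radius, um
    R_T  = 120,      # tumour-cord radius, um
    ## reference scales used by the nondimensionalization
    E_ref = 0.001,   # extracellular reference concentration, ug/mm^3 (= 1 ug/ml)
    I_ref = 1,       # intracellular reference, ng/(1e5 cells)
    c_ref = 1e6,     # cell-density reference, cells/mm^3
    signalling = signalling_parameters()
  )
  class(p) <- "cord_params"
  p
}

#' Default parameters of the intracellular signalling modules
#'
#' @return Named list with components \code{monostable} (\code{k} hr^-1,
#'   \code{k_h} ng/(1e5 cells), Hill coefficient \code{n}), \code{effector}
#'   (\code{k_f}, \code{k_r} hr^-1, apoptosis threshold \code{R1_th}) and
#'   \code{bistable} (\code{V_f}, \code{V_r}, \code{k_fb} hr^-1; \code{K_m1},
#'   \code{K_m2}, \code{p} dimensionless; \code{q} per ng/(1e5 cells)).
#' @export
signalling_parameters <- function() {
  list(
    monostable = list(k = 0.432, k_h = 1, n = 10),
    effector   = list(k_f = 3.6, k_r = 0.144, R1_th = 0.9),
    bistable   = list(V_f = 27, V_r = 0.459, K_m1 = 100, K_m2 = 0.01,
                      k_fb = 2.927, p = 0.7, q = 0.3)
  )
}

#' Validate a tumour-cord parameter set
#'
#' Checks the structural invariants of the model: positivity of rates,
#' diffusivities, radii and reference scales; geometry \code{R_C < R_T};
#' untreated growth dominating decay (\code{a1 > a2}); triggered growth below
#' decay (\code{a1_triggered < a2}, so triggered cells die out); apoptosis
#' threshold strictly inside (0, 1); Hill coefficient >= 1; basal feedback
#' factor \code{p} in [0, 1].
#'
#' @param p A \code{cord_params} list as returned by [default_parameters()].
#' @return \code{p}, invisibly unchanged, if all invariants hold.
#'   Otherwise an error naming every violated invariant.
#' @export
validate_parameters <- function(p) {
  errs <- character(0)
  need_pos <- c("k_d", "k_db", "V1", "V2", "k1", "k2", "k3", "k4",
                "a1", "a2", "b", "R_C", "R_T", "E_ref", "I_ref", "c_ref", "K")
  for (nm in need_pos) {
    v <- p[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      errs <- c(errs, sprintf("'%s' must be a single positive number", nm))
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(p$K1)) errs <- c(errs, "'K1' must be a single finite number")
  if (!num1(p$a1_triggered) || p$a1_triggered < 0)
    errs <- c(errs, "'a1_triggered' must be a single non-negative number")
  if (num1(p$R_C) && num1(p$R_T) && p$R_C >= p$R_T)
    errs <- c(errs, "capillary radius must be smaller than cord radius (R_C < R_T)")
  if (num1(p$a1) && num1(p$a2) && p$a1 <= p$a2)
    errs <- c(errs, "growth does not dominate decay (requires a1 > a2)")
  if (num1(p$a1_triggered) && num1(p$a2) && p$a1_triggered >= p$a2)
    errs <- c(errs, "triggered growth must fall below decay (a1_triggered < a2)")

  s <- p$signalling
  if (is.null(s)) {
    errs <- c(errs, "missing 'signalling' parameter block")
  } else {
    for (nm in c("k", "k_h")) if (!num1(s$monostable[[nm]]) || s$monostable[[nm]] <= 0)
      errs <- c(errs, sprintf("monostable '%s' must be positive", nm))
    if (!num1(s$monostable$n) || s$monostable$n < 1)
      errs <- c(errs, "Hill coefficient n must be >= 1")
    for (nm in c("k_f", "k_r")) if (!num1(s$effector[[nm]]) || s$effector[[nm]] <= 0)
      errs <- c(errs, sprintf("effector '%s' must be positive", nm))
    th <- s$effector$R1_th
    if (!num1(th) || th <= 0 || th >= 1)
      errs <- c(errs, "threshold outside (0,1): R1_th must satisfy 0 < R1_th < 1")
    for (nm in c("V_f", "V_r", "K_m1", "K_m2", "k_fb"))
      if (!num1(s$bistable[[nm]]) || s$bistable[[nm]] <= 0)
        errs <- c(errs, sprintf("bistable '%s' must be positive", nm))
    if (!num1(s$bistable$p) || s$bistable$p < 0 || s$bistable$p > 1)
      errs <- c(errs, "basal feedback factor p must lie in [0,1]")
    if (!num1(s$bistable$q) || s$bistable$q < 0)
      errs <- c(errs, "input-coupling factor q must be non-negative")
  }
  if (length(errs))
    stop("invalid parameters:\n  - ", paste(errs, collapse = "\n  - "), call. = FALSE)
  invisible(p)
}

#' Nondimensionalize the model
#'
#' Converts the dimensional parameter set to the dimensionless system the
#' integrator uses. The radial coordinate is scaled by the cord radius
#' \code{R_T}, time by the diffusion time scale \code{t_scale = R_T^2/k_d}
#' (so the dimensionless free-drug diffusivity is exactly 1), extracellular
#' concentrations by \code{E_ref}, intracellular concentration by
#' \code{I_ref} and cell density by \code{c_ref}.
#'
#' Unit reconciliation performed here: \code{V1}, \code{V2} are converted
#' from per-minute to per-hour; population rates from per-day to per-hour;
#' \code{k1} (ug/ml) equals its value in \code{E_ref} units because
#' 1 ug/ml = 0.001 ug/mm^3 = \code{E_ref}. The per-cell membrane fluxes
#' (ng per 1e5 cells) become volumetric extracellular sinks/sources after
#' multiplication by the local cell density in 1e5 cells/mm^3; the
#' ng-to-ug conversion (1e-3) cancels exactly against \code{E_ref}
#' (1e-3 ug/mm^3), leaving the bridge factor
#' \code{chi = c_ref / 1e5} applied in the extracellular equation.
#'
#' @param p A validated \code{cord_params} set.
#' @return Object of class \code{cord_ndim}: all rate constants per
#'   \code{t_scale}, lengths per \code{R_T} (\code{rc = R_C/R_T}, outer
#'   radius 1), plus \code{t_scale} (hr), \code{chi}, the untreated
#'   dimensionless carrying capacity \code{c_star}, and the reference scales
#'   needed by [redimensionalize()].
#' @export
nondimensionalize <- function(p) {
  validate_parameters(p)
  R_T_mm <- p$R_T / 1000
  t_scale <- R_T_mm^2 / p$k_d          # hr
  chi <- p$c_ref / 1e5                 # c_ref in 1e5 cells/mm^3

  per_hr <- function(x) x * t_scale
  s <- p$signalling
  nd <- list(
    t_scale = t_scale,
    R_T_mm  = R_T_mm,
    rc      = p$R_C / p$R_T,
    D_E = 1,
    D_B = p$k_db / p$k_d,
    v1  = per_hr(p$V1 * 60),           # per-minute -> per-hour -> per-t_scale
    v2  = per_hr(p$V2 * 60),
    k1  = p$k1,                        # ug/ml == E_ref units
    k2  = p$k2 / p$I_ref,
    k3  = per_hr(p$k3),
    k4  = per_hr(p$k4),
    Kw  = p$K * t_scale / R_T_mm,      # wall permeability, velocity units
    K1  = p$K1 * t_scale / (R_T_mm * p$E_ref),
    a1  = per_hr(p$a1 / 24),
    a2  = per_hr(p$a2 / 24),
    a1_triggered = per_hr(p$a1_triggered / 24),
    b   = per_hr(p$b / 24) * chi,
    chi = chi,
    signalling = list(
      monostable = list(k = per_hr(s$monostable$k),
                        k_h = s$monostable$k_h / p$I_ref,
                        n = s$monostable$n),
      effector = list(k_f = per_hr(s$effector$k_f),
                      k_r = per_hr(s$effector$k_r),
                      R1_th = s$effector$R1_th),
      bistable = list(V_f = per_hr(s$bistable$V_f),
                      V_r = per_hr(s$bistable$V_r),
                      K_m1 = s$bistable$K_m1, K_m2 = s$bistable$K_m2,
                      k_fb = per_hr(s$bistable$k_fb),
                      p = s$bistable$p,
                      q = s$bistable$q * p$I_ref)
    ),
    E_ref = p$E_ref, I_ref = p$I_ref, c_ref = p$c_ref
  )
  ## untreated logistic steady state in c_ref units
  nd$c_star <- (nd$a1 - nd$a2) / nd$b
  class(nd) <- "cord_ndim"
  nd
}

#' Recover dimensional parameters from a dimensionless model
#'
#' Inverse of [nondimensionalize()]; round-tripping reproduces the original
#' dimensional set to floating-point accuracy.
#'
#' @param nd A \code{cord_ndim} object.
#' @return A \code{cord_params} list.
#' @export
redimensionalize <- function(nd) {
  stopifnot(inherits(nd, "cord_ndim"))
  ts <- nd$t_scale
  s <- nd$signalling
  p <- list(
    k_d  = nd$R_T_mm^2 / ts,
    k_db = nd$D_B * nd$R_T_mm^2 / ts,
    V1 = nd$v1 / ts / 60,
    V2 = nd$v2 / ts / 60,
    k1 = nd$k1,
    k2 = nd$k2 * nd$I_ref,
    k3 = nd$k3 / ts,
    k4 = nd$k4 / ts,
    K  = nd$Kw * nd$R_T_mm / ts,
    K1 = nd$K1 * nd$R_T_mm * nd$E_ref / ts,
    a1 = nd$a1 / ts * 24,
    a2 = nd$a2 / ts * 24,
    a1_triggered = nd$a1_triggered / ts * 24,
    b  = nd$b / nd$chi / ts * 24,
    R_C = nd$rc * nd$R_T_mm * 1000,
    R_T = nd$R_T_mm * 1000,
    E_ref = nd$E_ref, I_ref = nd$I_ref, c_ref = nd$c_ref,
    signalling = list(
      monostable = list(k = s$monostable$k / ts,
                        k_h = s$monostable$k_h * nd$I_ref,
                        n = s$monostable$n),
      effector = list(k_f = s$effector$k_f / ts,
                      k_r = s$effector$k_r / ts,
                      R1_th = s$effector$R1_th),
      bistable = list(V_f = s$bistable$V_f / ts,
                      V_r = s$bistable$V_r / ts,
                      K_m1 = s$bistable$K_m1, K_m2 = s$bistable$K_m2,
                      k_fb = s$bistable$k_fb / ts,
                      p = s$bistable$p,
                      q = s$bistable$q / nd$I_ref)
    )
  )
  class(p) <- "cord_params"
  p
}

## deep merge of override list into defaults; unknown names are an error
merge_params <- function(base, override, path = "") {
  for (nm in names(override)) {
    full <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base))
      stop("unknown parameter field: ", full, call. = FALSE)
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]], full)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a parameter file
#'
#' Reads a YAML or JSON file whose fields mirror [default_parameters()];
#' any omitted field keeps its default value. Unknown field names are
#' rejected rather than silently ignored.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A validated \code{cord_params} list.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  override <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  p <- merge_params(unclass(default_parameters()), override)
  class(p) <- "cord_params"
  validate_parameters(p)
  p
}

#' @export
print.cord_params <- function(x, ...) {
  cat("Tumour-cord model parameters (dimensional)\n")
  cat(sprintf("  geometry: R_C = %g um, R_T = %g um\n", x$R_C, x$R_T))
  cat(sprintf("  transport: k_d = %g, k_db = %g mm^2/hr; K = %g mm/hr, K1 = %g\n",
              x$k_d, x$k_db, x$K, x$K1))
  cat(sprintf("  uptake: V1 = V2 = %g ng/(1e5 cells)/min; k1 = %g ug/ml, k2 = %g ng/1e5 cells\n",
              x$V1, x$k1, x$k2))
  cat(sprintf("  binding: k3 = %g, k4 = %g hr^-1\n", x$k3, x$k4))
  cat(sprintf("  population: a1 = %g, a2 = %g, a1_triggered = %g day^-1; b = %g\n",
              x$a1, x$a2, x$a1_triggered, x$b))
  cat(sprintf("  signalling: monostable k = %g hr^-1 (n = %g), bistable k_fb = %g hr^-1, R1 threshold = %g\n",
              x$signalling$monostable$k, x$signalling$monostable$n,
              x$signalling$bistable$k_fb, x$signalling$effector$R1_th))
  invisible(x)
}

#' @export
print.cord_ndim <- function(x, ...) {
  cat("Dimensionless tumour-cord model\n")
  cat(sprintf("  t_scale = %.6g hr (diffusion time R_T^2/k_d); inner radius rc = %.5g\n",
              x$t_scale, x$rc))
  cat(sprintf("  D_B = %.4g; v1 = v2 = %.4g; k3 = %.4g, k4 = %.4g; Kw = %.4g\n",
              x$D_B, x$v1, x$k3, x$k4, x$Kw))
  cat(sprintf("  carrying capacity c* = %.6g (c_ref units)\n", x$c_star))
  invisible(x)
}
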