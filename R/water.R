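# Water-relations arithmetic and the steady-state solute-deposition
# framework.  Potentials are in MPa with the usual sign convention
# (water potential psi_w and osmotic potential psi_s negative in stressed
# tissue); turgor is psi_p = psi_w - psi_s.

#' Turgor pressure from water and osmotic potentials
#'
#' @param psi_w water potential (MPa).
#' @param psi_s osmotic potential (MPa).
#' @return Turgor `psi_w - psi_s` (MPa).
#' @export
turgor <- function(psi_w, psi_s) {
  if (any(psi_w > 0)) {
    warning("positive water potential is unusual for stressed tissue",
            call. = FALSE)
  }
  psi_w - psi_s
}

#' Tissue water status record
#'
#' @param tissue tissue label (e.g. `"N2 root tip"`).
#' @param treatment treatment label.
#' @param psi_w water potential (MPa).
#' @param psi_s osmotic potential (MPa), optional.
#' @return List of class `tissue_water_status` with derived turgor
#'   `psi_p` when `psi_s` is present.
#' @export
tissue_water_status <- function(tissue, treatment, psi_w, psi_s = NA_real_) {
  psi_p <- if (is.na(psi_s)) NA_real_ else turgor(psi_w, psi_s)
  structure(list(tissue = tissue, treatment = treatment,
                 psi_w = psi_w, psi_s = psi_s, psi_p = psi_p),
            class = "tissue_water_status")
}

#' Osmotic adjustment between two water statuses
#'
#' The drop in osmotic potential from the well-watered to the
#' water-deficit status, and whether it fully compensates the drop in
#' water potential: adjustment is complete when turgor is maintained
#' within `tolerance`.
#'
#' @param ww,wd [tissue_water_status()] records with `psi_s` present.
#' @param tolerance turgor-maintenance tolerance (MPa, default 0.05).
#' @return List with `delta_psi_s` (MPa, positive when the WD osmotic
#'   potential is lower), `delta_psi_p`, and logical `complete`.
#' @export
osmotic_adjustment <- function(ww, wd, tolerance = 0.05) {
  stopifnot(inherits(ww, "tissue_water_status"),
            inherits(wd, "tissue_water_status"))
  if (is.na(ww$psi_s) || is.na(wd$psi_s)) {
    stop("both statuses need an osmotic potential (psi_s)", call. = FALSE)
  }
  dpp <- wd$psi_p - ww$psi_p
  list(delta_psi_s = ww$psi_s - wd$psi_s,
       delta_psi_p = dpp,
       complete = abs(dpp) <= tolerance)
}

#' Net solute-deposition rate profile
#'
#' Under steady state, the net local rate at which solutes are added to
#' the osmotic pool of a growing tissue element is the spatial derivative
#' of the solute flux: `D(x) = d(c A v)/dx`, with concentration `c`,
#' cross-sectional area `A` and displacement velocity `v` on a shared
#' grid.  The derivative uses central differences, optionally after
#' smoothing the flux with a smoothing spline.
#'
#' @param field data frame with columns `position_mm`, `concentration`,
#'   `area_mm2`, `velocity_mm_per_h` (concentration in any consistent
#'   amount per mm^3).
#' @param smooth logical; smooth the flux before differentiating.
#' @param spar smoothing parameter for [stats::smooth.spline()].
#' @param scheme optional region scheme for per-region integrals of `D`.
#' @return Data frame with columns `position_mm`, `flux`, `deposition`;
#'   when `scheme` is given, a `region_integrals` attribute holds
#'   per-region integrated deposition.  The fundamental-theorem identity
#'   (integral of `D` = flux difference) is asserted on every call.
#' @export
deposition_rate <- function(field, smooth = FALSE, spar = 0.5,
                            scheme = NULL) {
  need <- c("position_mm", "concentration", "area_mm2", "velocity_mm_per_h")
  stopifnot(all(need %in% names(field)))
  if (any(field$concentration < 0) || any(field$area_mm2 < 0)) {
    stop("concentration and area must be non-negative", call. = FALSE)
  }
  x <- field$position_mm
  flux <- field$concentration * field$area_mm2 * field$velocity_mm_per_h
  fs <- flux
  if (smooth) fs <- predict(stats::smooth.spline(x, flux, spar = spar), x)$y
  dep <- central_diff(x, fs)
  # discrete fundamental theorem: the midpoint-rule integral of the
  # interior central differences telescopes exactly to a flux difference
  n <- length(x)
  lhs <- sum(dep[2:(n - 1)] * (x[3:n] - x[1:(n - 2)])) / 2
  rhs <- (fs[n] + fs[n - 1]) / 2 - (fs[1] + fs[2]) / 2
  stopifnot(abs(lhs - rhs) <= 1e-9 * max(1, abs(rhs)))
  out <- data.frame(position_mm = x, flux = fs, deposition = dep)
  if (!is.null(scheme)) {
    ints <- vapply(seq_len(nrow(scheme)), function(i) {
      g <- seq(scheme$start_mm[i], scheme$end_mm[i], by = 0.1)
      if (g[length(g)] < scheme$end_mm[i]) g <- c(g, scheme$end_mm[i])
      trapz(g, resample_profile(x, dep, g))
    }, numeric(1))
    attr(out, "region_integrals") <-
      data.frame(region = scheme$region, deposition_integral = ints)
  }
  out
}
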