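# Kinematic growth-zone analysis.  The growing root is treated as a
# material continuum under steady state: a tissue element at position x
# (mm from the root-cap junction) moves basally with displacement velocity
# v(x), whose spatial derivative is the local relative elongation rate.
# Under steady state the cell flux v(x)/l(x) is constant along a cell
# file, which lets v(x) be reconstructed from a cortical cell-length
# profile and the overall elongation rate.

#' Logistic displacement-velocity curve
#'
#' Evaluates `v(x) = a2 + (a1 - a2) / (1 + (x / x0)^p)`: `a1` is the
#' velocity near the tip, `a2` the mature-zone plateau (equal to the
#' overall elongation rate), `x0` the midpoint position and `p` the
#' steepness.
#'
#' @param x positions (mm from the root-cap junction), `x >= 0`.
#' @param a1,a2 tip and plateau velocities (mm/h), `a2 > a1 >= 0`.
#' @param x0 midpoint (mm), `> 0`.
#' @param p steepness, `> 0`.
#' @return Velocities (mm/h).
#' @export
logistic_velocity <- function(x, a1, a2, x0, p) {
  a2 + (a1 - a2) / (1 + (x / x0)^p)
}

# Analytic derivative of the logistic velocity (the REL); vectorised in x.
logistic_rel <- function(x, a1, a2, x0, p) {
  out <- (a2 - a1) * p * (x / x0)^(p - 1) / (x0 * (1 + (x / x0)^p)^2)
  out[x == 0 & p > 1] <- 0
  out
}

#' Overall root elongation rate from a two-day cohort
#'
#' The elongation rate is the difference between mean axial lengths of the
#' plants harvested on the two days, divided by the two-day interval.
#'
#' @param cohort data frame with columns `plant`, `day` (15 or 17),
#'   `treatment`, `length_cm`.
#' @return List with `rate_cm_per_day`, `rate_mm_per_h`, and the two day
#'   means (`mean_day15_cm`, `mean_day17_cm`).
#' @export
elongation_rate <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("day", "length_cm") %in% names(cohort)))
  days <- sort(unique(cohort$day))
  if (!all(c(15, 17) %in% days)) {
    stop("cohort must contain harvests at both day 15 and day 17",
         call. = FALSE)
  }
  m15 <- mean(cohort$length_cm[cohort$day == 15])
  m17 <- mean(cohort$length_cm[cohort$day == 17])
  rate <- (m17 - m15) / 2
  if (rate < 0) {
    warning("computed elongation rate is negative; check the cohort",
            call. = FALSE)
  }
  list(rate_cm_per_day = rate,
       rate_mm_per_h = rate * 10 / 24,
       mean_day15_cm = m15,
       mean_day17_cm = m17)
}

#' Mature cortical cell length
#'
#' Mean cell length over the mature window of the profile (default
#' 10-12 mm from the root-cap junction, where cell elongation has ceased).
#'
#' @param profile data frame with columns `position_mm`, `cell_length_um`.
#' @param window numeric length-2 interval in mm.
#' @return Mature cell length (micrometres).
#' @export
mature_cell_length <- function(profile, window = c(10, 12)) {
  sel <- profile$position_mm >= window[1] & profile$position_mm <= window[2]
  if (sum(sel) < 2L) {
    stop("need at least 2 profile points in the mature window [",
         window[1], ", ", window[2], "] mm", call. = FALSE)
  }
  mean(profile$cell_length_um[sel])
}

#' Cell flux
#'
#' The rate at which fully elongated cells leave the growth zone per cell
#' file; under steady state this equals the rate of cell production from
#' the meristem.  Computed as elongation rate divided by final cell
#' length.
#'
#' @param rate_mm_per_h overall elongation rate (mm/h).
#' @param final_cell_len_um mature cell length (micrometres).
#' @return Cell flux (cells/h).
#' @export
cell_flux <- function(rate_mm_per_h, final_cell_len_um) {
  if (final_cell_len_um <= 0) {
    stop("final cell length must be positive", call. = FALSE)
  }
  rate_mm_per_h / (final_cell_len_um / 1000)
}

#' Displacement-velocity profile from a cell-length profile
#'
#' Under steady state the cell flux `v(x) / l(x)` is constant along the
#' file, so `v(x) = flux * l(x)` with flux = elongation rate / mature cell
#' length.  At mature positions the velocity equals the overall elongation
#' rate.
#'
#' @param profile data frame with columns `position_mm`, `cell_length_um`.
#' @param rate_mm_per_h overall elongation rate (mm/h).
#' @param mature_window window for [mature_cell_length()].
#' @return Data frame with columns `position_mm`, `velocity_mm_per_h`, and
#'   attributes `flux_cells_per_h` and `final_cell_len_um`.
#' @export
velocity_profile <- function(profile, rate_mm_per_h,
                             mature_window = c(10, 12)) {
  l_final <- mature_cell_length(profile, mature_window)
  flux <- cell_flux(rate_mm_per_h, l_final)
  if (any(profile$cell_length_um > l_final * (1 + 0.05))) {
    warning("cell lengths exceed the mature value by more than 5%; ",
            "treating as measurement noise", call. = FALSE)
  }
  vel <- data.frame(position_mm = profile$position_mm,
                    velocity_mm_per_h = flux * profile$cell_length_um / 1000)
  attr(vel, "flux_cells_per_h") <- flux
  attr(vel, "final_cell_len_um") <- l_final
  vel
}

#' Fit the logistic curve to a displacement-velocity profile
#'
#' Least-squares fit of `v(x) = a2 + (a1 - a2)/(1 + (x/x0)^p)` with
#' Levenberg-Marquardt iteration, bounded so that `a1 >= 0`, `x0 > 0`,
#' `p > 0`.  Starting values follow the shape of the data (`a1 = min v`,
#' `a2 = max v`, `x0` at the half-range crossing, `p = 4`), with a fixed
#' restart schedule perturbing `p` and `x0` on non-convergence.  The
#' goodness of fit `R` is the Pearson correlation between observed and
#' fitted velocities.
#'
#' @param vel data frame with columns `position_mm`, `velocity_mm_per_h`.
#' @param init optional named list overriding starting values.
#' @return Object of class `logistic_fit`: list with `a1`, `a2`, `x0`,
#'   `p`, `R`, `converged`, and the `nls` object in `$fit`.
#' @export
fit_logistic <- function(vel, init = NULL) {
  x <- vel$position_mm
  y <- vel$velocity_mm_per_h
  if (length(x) < 5L) {
    stop("need at least 5 velocity points spanning rise and plateau",
         call. = FALSE)
  }
  if (diff(range(y)) < 1e-12) {
    stop("velocity profile is flat; logistic fit is degenerate",
         call. = FALSE)
  }
  half <- min(y) + diff(range(y)) / 2
  above <- which(y >= half)
  start <- list(a1 = max(min(y), 1e-6), a2 = max(y),
                x0 = if (length(above)) max(x[min(above)], 0.1) else
                  stats::median(x),
                p = 4)
  if (!is.null(init)) start <- modifyList(start, init)
  lower <- c(a1 = 0, a2 = 1e-9, x0 = 1e-6, p = 1e-6)
  restarts <- list(c(1, 1, 1, 1), c(1, 1, 0.5, 0.5), c(1, 1, 2, 2),
                   c(1, 1, 1, 0.25), c(1, 1, 0.75, 3))
  fit <- NULL
  for (scal in restarts) {
    st <- list(a1 = start$a1 * scal[1], a2 = start$a2 * scal[2],
               x0 = start$x0 * scal[3], p = start$p * scal[4])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a2 + (a1 - a2) / (1 + (x / x0)^p),
        start = st, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("logistic fit did not converge under the restart schedule",
         call. = FALSE)
  }
  cf <- coef(fit)
  if (cf["a2"] <= cf["a1"]) {
    stop("degenerate logistic fit: plateau a2 not above tip velocity a1",
         call. = FALSE)
  }
  structure(
    list(a1 = unname(cf["a1"]), a2 = unname(cf["a2"]),
         x0 = unname(cf["x0"]), p = unname(cf["p"]),
         R = cor(y, fitted(fit)),
         converged = TRUE,
         fit = fit),
    class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> a1=%.4f a2=%.4f mm/h, x0=%.3f mm, p=%.3f, R=%.5f\n",
    x$a1, x$a2, x$x0, x$p, x$R))
  invisible(x)
}

#' Relative elongation rate profile
#'
#' The first derivative of the fitted displacement velocity with respect
#' to position,
#' `dv/dx = (a2 - a1) p (x/x0)^(p-1) / (x0 (1 + (x/x0)^p)^2)`,
#' evaluated analytically on a position grid.
#'
#' @param fit a `logistic_fit` (or list with `a1`, `a2`, `x0`, `p`).
#' @param grid positions in mm, all `>= 0`.
#' @return Data frame with columns `position_mm`, `rel_per_h`.
#' @export
rel_profile <- function(fit, grid) {
  if (any(grid < 0)) stop("positions must be >= 0", call. = FALSE)
  data.frame(position_mm = grid,
             rel_per_h = logistic_rel(grid, fit$a1, fit$a2, fit$x0, fit$p))
}

#' Growth-zone extent from a relative elongation rate profile
#'
#' The growth zone ends where local elongation has effectively ceased:
#' the smallest position beyond the REL peak at which the rate falls below
#' `frac` of the peak value (linearly interpolated between grid points).
#'
#' @param rel data frame with columns `position_mm`, `rel_per_h`.
#' @param frac cessation threshold as a fraction of the peak REL.
#' @return List with `extent_mm`, `peak_position_mm`, `peak_rel_per_h`.
#' @export
growth_zone_extent <- function(rel, frac = 0.05) {
  x <- rel$position_mm
  y <- rel$rel_per_h
  i_pk <- which.max(y)
  if (i_pk == 1L || i_pk == length(y)) {
    stop("no deceleration phase: REL profile has no interior maximum",
         call. = FALSE)
  }
  thr <- frac * y[i_pk]
  below <- which(y < thr & seq_along(y) > i_pk)
  if (!length(below)) {
    stop("REL does not fall below ", frac, " of its peak within the grid",
         call. = FALSE)
  }
  j <- below[1]
  # linear interpolation of the crossing between j-1 and j
  x_cross <- x[j - 1] + (thr - y[j - 1]) * (x[j] - x[j - 1]) /
    (y[j] - y[j - 1])
  list(extent_mm = x_cross,
       peak_position_mm = x[i_pk],
       peak_rel_per_h = y[i_pk])
}

#' Cross-sectional area profile from a diameter profile
#'
#' Assumes a circular cross-section: `A(x) = pi d(x)^2 / 4`.
#'
#' @param diam data frame with columns `position_mm`, `diameter_mm`.
#' @return Data frame with columns `position_mm`, `area_mm2`.
#' @export
area_profile <- function(diam) {
  if (any(diam$diameter_mm <= 0)) {
    stop("diameters must be positive", call. = FALSE)
  }
  data.frame(position_mm = diam$position_mm,
             area_mm2 = pi * diam$diameter_mm^2 / 4)
}

#' Radial plus tangential expansion rate profile
#'
#' The local fractional rate of cross-sectional-area increase experienced
#' by a tissue element moving at velocity `v(x)`:
#' `r(x) = v(x) d ln A / dx` (1/h).  The logarithmic derivative is taken
#' by central finite differences, optionally after smoothing `ln A` with a
#' smoothing spline (diameter data are noisy and the derivative amplifies
#' that noise).
#'
#' @param vel data frame with `position_mm`, `velocity_mm_per_h`.
#' @param area data frame with `position_mm`, `area_mm2` on the same grid.
#' @param smooth logical; smooth `ln A` with [stats::smooth.spline()]
#'   before differentiating.
#' @param spar smoothing parameter passed to [stats::smooth.spline()].
#' @return Data frame with columns `position_mm`, `radtan_per_h`.
#' @export
radtan_rate <- function(vel, area, smooth = FALSE, spar = 0.5) {
  check_shared_grid(vel$position_mm, area$position_mm,
                    "velocity and area profiles")
  if (any(area$area_mm2 <= 0)) stop("areas must be positive", call. = FALSE)
  x <- vel$position_mm
  lnA <- log(area$area_mm2)
  if (smooth) {
    lnA <- predict(stats::smooth.spline(x, lnA, spar = spar), x)$y
  }
  data.frame(position_mm = x,
             radtan_per_h = vel$velocity_mm_per_h * central_diff(x, lnA))
}

#' Volumetric expansion profiles
#'
#' Combines longitudinal and cross-sectional expansion: the relative
#' volumetric expansion rate is `relvol = rel + radtan` (1/h), and the
#' volumetric expansion rate is `volrate = relvol * A` (mm^3 per mm root
#' length per h), taking root volume per unit length equal to the
#' cross-sectional area of a cylinder.
#'
#' @param rel data frame from [rel_profile()].
#' @param radtan data frame from [radtan_rate()].
#' @param area data frame from [area_profile()], same grid.
#' @return Object of class `expansion_profiles`: data frame with columns
#'   `position_mm`, `rel_per_h`, `radtan_per_h`, `relvol_per_h`,
#'   `area_mm2`, `volrate_mm3_per_mm_h`; attribute `peak_position_mm` is
#'   the grid position of maximal volumetric expansion.
#' @export
volumetric_profiles <- function(rel, radtan, area) {
  check_shared_grid(rel$position_mm, radtan$position_mm,
                    "REL and radial+tangential profiles")
  check_shared_grid(rel$position_mm, area$position_mm,
                    "REL and area profiles")
  relvol <- rel$rel_per_h + radtan$radtan_per_h
  out <- data.frame(position_mm = rel$position_mm,
                    rel_per_h = rel$rel_per_h,
                    radtan_per_h = radtan$radtan_per_h,
                    relvol_per_h = relvol,
                    area_mm2 = area$area_mm2,
                    volrate_mm3_per_mm_h = relvol * area$area_mm2)
  # enforced identities
  stopifnot(
    max(abs(out$relvol_per_h - (out$rel_per_h + out$radtan_per_h))) < 1e-12,
    max(abs(out$volrate_mm3_per_mm_h - out$relvol_per_h * out$area_mm2)) <
      1e-12)
  attr(out, "peak_position_mm") <-
    out$position_mm[which.max(out$volrate_mm3_per_mm_h)]
  class(out) <- c("expansion_profiles", "data.frame")
  out
}

#' Growth-zone region scheme
#'
#' Named sampling regions of the growth zone measured from the root-cap
#' junction: R1 spans 0-3 mm (plus the root cap, which carries no
#' kinematic grid), R2 3-6 mm, R3 6-9.5 mm.
#'
#' @return Data frame with columns `region`, `start_mm`, `end_mm`.
#' @export
region_scheme <- function() {
  data.frame(region = c("R1", "R2", "R3"),
             start_mm = c(0, 3, 6),
             end_mm = c(3, 6, 9.5),
             stringsAsFactors = FALSE)
}

#' Per-region summaries of a profile set
#'
#' Trapezoidal integrals and means of each profile column over the regions
#' of a region scheme, after linear resampling onto a 0.1 mm grid.
#'
#' @param profiles data frame with a `position_mm` column and one or more
#'   numeric profile columns.
#' @param scheme data frame as returned by [region_scheme()].
#' @param dx resampling spacing in mm.
#' @return Data frame with one row per region and, per profile column,
#'   `<name>_integral` and `<name>_mean`.
#' @export
region_summaries <- function(profiles, scheme = region_scheme(), dx = 0.1) {
  x <- profiles$position_mm
  if (min(x) > min(scheme$start_mm) + 1e-9 ||
      max(x) < max(scheme$end_mm) - 1e-9) {
    stop("profile grid does not cover the region scheme [",
         min(scheme$start_mm), ", ", max(scheme$end_mm), "] mm",
         call. = FALSE)
  }
  cols <- setdiff(names(profiles), "position_mm")
  out <- scheme
  for (cn in cols) {
    ints <- numeric(nrow(scheme))
    means <- numeric(nrow(scheme))
    for (i in seq_len(nrow(scheme))) {
      g <- seq(scheme$start_mm[i], scheme$end_mm[i], by = dx)
      if (g[length(g)] < scheme$end_mm[i]) g <- c(g, scheme$end_mm[i])
      yv <- resample_profile(x, profiles[[cn]], g)
      ints[i] <- trapz(g, yv)
      means[i] <- ints[i] / (scheme$end_mm[i] - scheme$start_mm[i])
    }
    out[[paste0(cn, "_integral")]] <- ints
    out[[paste0(cn, "_mean")]] <- means
  }
  out
}
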