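# Scenario configurations: the ground truth driving the synthetic-data
# generators.  A scenario bundles the kinematic truth (overall elongation
# rate, logistic displacement-velocity parameters, mature cell length,
# diameter taper), the cohort design, and the omics effect sizes and noise
# levels for one treatment.

#' Build a synthetic-scenario configuration
#'
#' A scenario is the complete ground truth for one treatment (e.g.
#' well-watered or water-deficit): it fixes the kinematic parameters of the
#' growth zone, the cohort design used to estimate elongation rate, and the
#' effect sizes and noise levels of the synthetic metabolome and
#' transcriptome.  All generators in the package are deterministic
#' functions of a scenario and its seed.
#'
#' @param name treatment label, e.g. `"WW"` or `"WD"`.
#' @param elong_rate_cm_per_day overall root elongation rate (cm/day).
#' @param final_cell_len_um mature cortical cell length (micrometres).
#' @param logistic_truth named numeric vector `c(a1, a2, x0, p)` of the
#'   displacement-velocity logistic
#'   `v(x) = a2 + (a1 - a2) / (1 + (x / x0)^p)`; `a1`, `a2` in mm/h, `x0`
#'   in mm, `p` unitless.
#' @param plateau_start_mm position beyond which cell length is mature
#'   (mm from the root-cap junction).
#' @param diameter_taper named numeric vector
#'   `c(d_tip, d_mature, decay_mm)`: root diameter rises from `d_tip` to
#'   `d_mature` (mm) with exponential length scale `decay_mm`.
#' @param n_plants plants per harvest day in a cohort.
#' @param length_sd_cm plant-to-plant Gaussian SD of axial length (cm).
#' @param met_effects data frame of true WD/WW fold changes with columns
#'   `metabolite`, `region`, `fold_change`.
#' @param met_cv coefficient of variation of replicate metabolite
#'   abundances (lognormal noise).
#' @param met_n_reps replicates per treatment-by-region cell.
#' @param missing_rate probability that a metabolite measurement is
#'   missing at random, in `[0, 1)`.
#' @param dat_proportions data frame with columns `region`, `up_tier2`,
#'   `down_tier2`, `up_tier1`, `down_tier1`, `n_transcripts`; tier-1
#'   fractions are inclusive of tier 2 (thresholds `|log2FC| >= 1` nest
#'   `>= 2`).
#' @param seed integer seed for all generators reading this scenario.
#' @return An object of class `scenario_config`.
#' @seealso [ww_scenario()], [wd_scenario()]
#' @export
scenario_config <- function(name,
                            elong_rate_cm_per_day,
                            final_cell_len_um,
                            logistic_truth,
                            plateau_start_mm = 10,
                            diameter_taper = c(d_tip = 0.85, d_mature = 1.05,
                                               decay_mm = 2),
                            n_plants = 9,
                            length_sd_cm = 1.0,
                            met_effects = default_metabolite_effects(),
                            met_cv = 0.10,
                            met_n_reps = 3,
                            missing_rate = 0,
                            dat_proportions = default_dat_proportions(),
                            seed = 1L) {
  lt <- as.numeric(logistic_truth)
  names(lt) <- c("a1", "a2", "x0", "p")
  dt <- as.numeric(diameter_taper)
  names(dt) <- c("d_tip", "d_mature", "decay_mm")
  cfg <- structure(
    list(name = name,
         elong_rate_cm_per_day = elong_rate_cm_per_day,
         final_cell_len_um = final_cell_len_um,
         logistic_truth = lt,
         plateau_start_mm = plateau_start_mm,
         diameter_taper = dt,
         n_plants = as.integer(n_plants),
         length_sd_cm = length_sd_cm,
         met_effects = met_effects,
         met_cv = met_cv,
         met_n_reps = as.integer(met_n_reps),
         missing_rate = missing_rate,
         dat_proportions = dat_proportions,
         seed = as.integer(seed)),
    class = "scenario_config")
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  lt <- cfg$logistic_truth
  if (!(lt["a2"] > lt["a1"] && lt["a1"] >= 0)) {
    stop("logistic truth requires a2 > a1 >= 0", call. = FALSE)
  }
  if (lt["x0"] <= 0 || lt["p"] <= 0) {
    stop("logistic truth requires x0 > 0 and p > 0", call. = FALSE)
  }
  if (cfg$n_plants <= 0) stop("n_plants must be positive", call. = FALSE)
  if (cfg$length_sd_cm < 0) stop("length_sd_cm must be >= 0", call. = FALSE)
  if (cfg$elong_rate_cm_per_day <= 0) {
    stop("elong_rate_cm_per_day must be positive", call. = FALSE)
  }
  if (cfg$final_cell_len_um <= 0) {
    stop("final_cell_len_um must be positive", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$met_n_reps < 2) stop("met_n_reps must be >= 2", call. = FALSE)
  if (any(cfg$met_effects$fold_change <= 0)) {
    stop("all configured fold changes must be > 0", call. = FALSE)
  }
  dp <- cfg$dat_proportions
  need <- c("region", "up_tier2", "down_tier2", "up_tier1", "down_tier1",
            "n_transcripts")
  if (!all(need %in% names(dp))) {
    stop("dat_proportions must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(dp$up_tier2 > dp$up_tier1) || any(dp$down_tier2 > dp$down_tier1)) {
    stop("tier-2 counts cannot exceed tier-1 counts (tiers are nested)",
         call. = FALSE)
  }
  if (any((dp$up_tier1 + dp$down_tier1) > dp$n_transcripts)) {
    stop("tier-1 proportions exceed 1", call. = FALSE)
  }
  if (cfg$diameter_taper["d_tip"] <= 0 || cfg$diameter_taper["d_mature"] <= 0) {
    stop("diameters must be positive", call. = FALSE)
  }
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  lt <- x$logistic_truth
  cat(sprintf("<scenario_config '%s'>\n", x$name))
  cat(sprintf("  elongation rate : %.2f cm/day (%.4f mm/h)\n",
              x$elong_rate_cm_per_day, x$elong_rate_cm_per_day * 10 / 24))
  cat(sprintf("  velocity truth  : a1=%.3f a2=%.4f x0=%.3f p=%.3f (mm/h, mm)\n",
              lt["a1"], lt["a2"], lt["x0"], lt["p"]))
  cat(sprintf("  mature cells    : %.1f um, plateau beyond %.1f mm\n",
              x$final_cell_len_um, x$plateau_start_mm))
  cat(sprintf("  cohort          : n=%d, length sd=%.2f cm, seed=%d\n",
              x$n_plants, x$length_sd_cm, x$seed))
  invisible(x)
}

#' Packaged true metabolite fold changes
#'
#' The default WD/WW effect sizes for the synthetic metabolome: measured
#' fold changes for 21 metabolites in the three growth-zone regions of the
#' N2 nodal root, shipped as a TSV fixture.
#'
#' @return Data frame with columns `metabolite`, `region`, `fold_change`.
#' @export
default_metabolite_effects <- function() {
  wide <- read.delim(path_extdata("n2_metabolite_fold_changes.tsv"),
                     check.names = FALSE)
  long <- data.frame(
    metabolite = rep(wide$metabolite, times = 3),
    region = rep(c("R1", "R2", "R3"), each = nrow(wide)),
    fold_change = c(wide$R1, wide$R2, wide$R3),
    stringsAsFactors = FALSE)
  long[order(long$metabolite, long$region), , drop = FALSE]
}

#' Packaged transcript-threshold count design
#'
#' Differentially accumulated transcript counts per region at the
#' `|log2FC| >= 2` and `|log2FC| >= 1` tiers (tier 1 inclusive of tier 2),
#' out of 45,764 mapped transcripts, used as the expected-count design of
#' the synthetic transcriptome.
#'
#' @return Data frame with columns `region`, `up_tier2`, `down_tier2`,
#'   `up_tier1`, `down_tier1`, `n_transcripts`.
#' @export
default_dat_proportions <- function() {
  read.delim(path_extdata("dat_tier_counts.tsv"))
}

# Continuous position of the volumetric-expansion-rate peak for a scenario
# truth, computed from the analytic derivative of the exponential taper.
vol_peak_position <- function(a1, a2, x0, p, d_tip, d_mature, decay_mm) {
  f <- function(x) {
    v <- a2 + (a1 - a2) / (1 + (x / x0)^p)
    rel <- (a2 - a1) * p * (x / x0)^(p - 1) /
      (x0 * (1 + (x / x0)^p)^2)
    d <- d_mature - (d_mature - d_tip) * exp(-x / decay_mm)
    dd <- (d_mature - d_tip) / decay_mm * exp(-x / decay_mm)
    area <- pi * d^2 / 4
    (rel + v * 2 * dd / d) * area
  }
  stats::optimize(f, c(0.05, 12), maximum = TRUE)$maximum
}

#' The packaged well-watered scenario
#'
#' Calibrated so that (i) the cohort elongation rate is 3.08 cm/day
#' (1.2833 mm/h), (ii) the relative elongation rate peaks at 2.5 mm from
#' the root-cap junction, (iii) cell elongation falls below 5% of its peak
#' rate at 10 mm (the growth-zone extent), and (iv) the mature cell length
#' of 156.9 um reproduces a cell flux of 8.18 cells/h.
#'
#' @param ... overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
ww_scenario <- function(...) {
  defaults <- list(
    name = "WW",
    elong_rate_cm_per_day = 3.08,
    final_cell_len_um = 156.9,
    # x0 and p solve peak REL at 2.5 mm and 5%-of-peak cessation at 10 mm
    logistic_truth = c(a1 = 0.05, a2 = 3.08 * 10 / 24,
                       x0 = 3.3006, p = 2.7469),
    diameter_taper = c(d_tip = 0.85, d_mature = 1.05, decay_mm = 2),
    seed = 1L)
  do.call(scenario_config, modifyList(defaults, list(...)))
}

#' The packaged water-deficit scenario
#'
#' Calibrated so that the cohort elongation rate is 3.13 cm/day, the mature
#' cell length of 169.8 um reproduces a cell flux of 7.68 cells/h, the root
#' is slightly wider than in the well-watered scenario at every position,
#' and the noiseless volumetric-expansion-rate peak sits `vol_peak_shift_mm`
#' basal of the well-watered peak.  The shift is realised by displacing the
#' velocity midpoint: the offset is solved numerically at construction so
#' that the configured knob is the observable peak displacement itself.
#'
#' @param vol_peak_shift_mm basal displacement (mm) of the volumetric peak
#'   relative to [ww_scenario()]; default 1.5.
#' @param ... overrides passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
wd_scenario <- function(vol_peak_shift_mm = 1.5, ...) {
  ww <- ww_scenario()
  a2 <- 3.13 * 10 / 24
  taper <- c(d_tip = 0.86, d_mature = 1.15, decay_mm = 2)
  ww_peak <- do.call(vol_peak_position,
                     as.list(c(a1 = unname(ww$logistic_truth["a1"]),
                               a2 = unname(ww$logistic_truth["a2"]),
                               x0 = unname(ww$logistic_truth["x0"]),
                               p = unname(ww$logistic_truth["p"]),
                               ww$diameter_taper)))
  p <- unname(ww$logistic_truth["p"])
  target <- ww_peak + vol_peak_shift_mm
  off <- stats::uniroot(function(delta) {
    vol_peak_position(0.05, a2, unname(ww$logistic_truth["x0"]) + delta, p,
                      taper["d_tip"], taper["d_mature"],
                      taper["decay_mm"]) - target
  }, c(0, 6))$root
  defaults <- list(
    name = "WD",
    elong_rate_cm_per_day = 3.13,
    final_cell_len_um = 169.8,
    logistic_truth = c(a1 = 0.05, a2 = a2,
                       x0 = unname(ww$logistic_truth["x0"]) + off,
                       p = p),
    diameter_taper = taper,
    seed = 2L)
  do.call(scenario_config, modifyList(defaults, list(...)))
}
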