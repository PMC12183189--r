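# Synthetic-data generators.  Every input the analysis pipeline consumes
# can be generated from a scenario_config, with the statistical structure
# the analysis assumes: Gaussian plant-to-plant noise on axial lengths,
# multiplicative lognormal noise on strictly positive micro-measurements
# and abundances, and missing-at-random masking of metabolite cells.
# Generators are pure functions of (config, seed): identical seeds give
# identical output.

#' Generate a two-day axial-length cohort
#'
#' Per-plant root lengths at days 15 and 17 after germination.  The day-17
#' population mean exceeds the day-15 mean by two days' growth at the
#' scenario's elongation rate; plant-to-plant variation is Gaussian with
#' the configured SD.
#'
#' @param cfg a [scenario_config()].
#' @param base_length_cm population mean length at day 15 (cm).
#' @return Data frame with columns `plant`, `day`, `treatment`,
#'   `length_cm`.
#' @export
make_cohort <- function(cfg, base_length_cm = 10) {
  stopifnot(inherits(cfg, "scenario_config"))
  n <- cfg$n_plants
  with_seed(cfg$seed, {
    l15 <- rnorm(n, base_length_cm, cfg$length_sd_cm)
    l17 <- rnorm(n, base_length_cm + 2 * cfg$elong_rate_cm_per_day,
                 cfg$length_sd_cm)
    data.frame(
      plant = c(sprintf("p%02d", seq_len(n)), sprintf("p%02d", n + seq_len(n))),
      day = rep(c(15L, 17L), each = n),
      treatment = cfg$name,
      length_cm = c(l15, l17),
      stringsAsFactors = FALSE)
  })
}

#' Generate a cortical cell-length profile
#'
#' Cell lengths consistent with the scenario's logistic velocity truth
#' under flux constancy: `l(x) = l_final * v(x) / E`, clipped to the
#' mature value `l_final` beyond the plateau start.  Optional
#' multiplicative lognormal measurement noise with the configured CV.
#'
#' @param cfg a [scenario_config()].
#' @param grid_mm positions in mm from the root-cap junction, within
#'   `[0, 12]`.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise; 0 gives the noiseless truth.
#' @return Data frame with columns `position_mm`, `cell_length_um` and a
#'   `treatment` attribute.
#' @export
make_cell_profile <- function(cfg, grid_mm = seq(0, 12, by = 0.25),
                              noise_cv = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (any(grid_mm < 0 | grid_mm > 12)) {
    stop("cell-length grid must lie within [0, 12] mm", call. = FALSE)
  }
  lt <- cfg$logistic_truth
  e_mm_h <- cfg$elong_rate_cm_per_day * 10 / 24
  v <- logistic_velocity(grid_mm, lt["a1"], lt["a2"], lt["x0"], lt["p"])
  l <- cfg$final_cell_len_um * v / e_mm_h
  l[grid_mm >= cfg$plateau_start_mm] <- cfg$final_cell_len_um
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    l <- with_seed(cfg$seed + 101L,
                   l * rlnorm(length(l), -sdlog^2 / 2, sdlog))
  }
  out <- data.frame(position_mm = grid_mm, cell_length_um = l)
  attr(out, "treatment") <- cfg$name
  out
}

#' Generate a root-diameter profile
#'
#' Smooth monotone exponential approach from the tip diameter to the
#' mature diameter over the configured decay length:
#' `d(x) = d_mature - (d_mature - d_tip) exp(-x / decay)`.
#'
#' @param cfg a [scenario_config()].
#' @param grid_mm positions in mm.
#' @param noise_cv multiplicative lognormal noise CV; 0 for noiseless.
#' @return Data frame with columns `position_mm`, `diameter_mm`.
#' @export
make_diameter_profile <- function(cfg, grid_mm = seq(0, 12, by = 0.25),
                                  noise_cv = 0) {
  stopifnot(inherits(cfg, "scenario_config"))
  tp <- cfg$diameter_taper
  if (tp["d_tip"] > tp["d_mature"]) {
    warning("tip diameter exceeds mature diameter; profile will narrow",
            call. = FALSE)
  }
  d <- tp["d_mature"] - (tp["d_mature"] - tp["d_tip"]) *
    exp(-grid_mm / tp["decay_mm"])
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    d <- with_seed(cfg$seed + 202L,
                   d * rlnorm(length(d), -sdlog^2 / 2, sdlog))
  }
  data.frame(position_mm = grid_mm, diameter_mm = unname(d))
}

#' Generate a synthetic two-treatment metabolome
#'
#' Raw-scale replicate abundances for every metabolite-by-region
#' combination in the effect table of the water-deficit scenario.
#' Well-watered replicates are lognormal around a per-metabolite baseline
#' with the configured CV; water-deficit replicates carry the configured
#' true fold change on the geometric mean.  Cells are masked missing at
#' random with the configured rate.
#'
#' @param cfg a [scenario_config()] whose `met_effects` holds the true
#'   WD/WW fold changes.
#' @param baseline geometric-mean well-watered abundance (arbitrary area
#'   counts).
#' @return An [abundance_matrix()] with samples
#'   `(treatment x region x replicate)` and one row per metabolite.
#' @export
make_metabolome <- function(cfg, baseline = 1e6) {
  stopifnot(inherits(cfg, "scenario_config"))
  eff <- cfg$met_effects
  if (any(eff$fold_change <= 0)) {
    stop("fold changes must be > 0", call. = FALSE)
  }
  regions <- sort(unique(eff$region))
  mets <- sort(unique(eff$metabolite))
  nrep <- cfg$met_n_reps
  sdlog <- sqrt(log(1 + cfg$met_cv^2))
  samples <- expand.grid(replicate = seq_len(nrep), region = regions,
                         treatment = c("WW", "WD"),
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_%s_rep%d", samples$treatment,
                            samples$region, samples$replicate)
  vals <- matrix(NA_real_, nrow = length(mets), ncol = nrow(samples),
                 dimnames = list(mets, samples$sample))
  with_seed(cfg$seed + 303L, {
    for (i in seq_along(mets)) {
      for (r in regions) {
        fc <- eff$fold_change[eff$metabolite == mets[i] & eff$region == r]
        if (!length(fc)) next
        ww_cols <- samples$treatment == "WW" & samples$region == r
        wd_cols <- samples$treatment == "WD" & samples$region == r
        vals[i, ww_cols] <- rlnorm(nrep, log(baseline), sdlog)
        vals[i, wd_cols] <- rlnorm(nrep, log(baseline * fc), sdlog)
      }
    }
    if (cfg$missing_rate > 0) {
      mask <- matrix(runif(length(vals)) < cfg$missing_rate,
                     nrow = nrow(vals))
      vals[mask] <- NA_real_
    }
  })
  abundance_matrix(vals, samples[, c("sample", "treatment", "region",
                                     "replicate")])
}

#' Generate a synthetic transcript log2 fold-change table
#'
#' Per-transcript, per-region log2 fold changes (water deficit vs
#' well-watered) whose expected counts above the `|log2FC| >= 2` and
#' `>= 1` thresholds match the scenario's tier design.  Each transcript is
#' assigned multinomially to a tier category; magnitudes are drawn beyond
#' the corresponding threshold (tier-2 as 2 plus an exponential tail,
#' tier-1-only uniformly on `[1, 2)`, background uniformly inside
#' `(-1, 1)`).
#'
#' @param cfg a [scenario_config()].
#' @param anchors optional data frame with columns `transcript`, `region`,
#'   `log2fc` of planted transcripts with known effects (appended, or
#'   overriding background rows with the same id).
#' @return Data frame with columns `transcript`, `region`, `log2fc`.
#' @export
make_transcript_log2fc <- function(cfg, anchors = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  dp <- cfg$dat_proportions
  if (any(dp$up_tier2 > dp$up_tier1) || any(dp$down_tier2 > dp$down_tier1)) {
    stop("inconsistent tier proportions: tier-2 exceeds tier-1",
         call. = FALSE)
  }
  out <- with_seed(cfg$seed + 404L, {
    pieces <- lapply(seq_len(nrow(dp)), function(i) {
      n <- dp$n_transcripts[i]
      probs <- c(up2 = dp$up_tier2[i],
                 up1 = dp$up_tier1[i] - dp$up_tier2[i],
                 down2 = dp$down_tier2[i],
                 down1 = dp$down_tier1[i] - dp$down_tier2[i]) / n
      probs <- c(probs, none = 1 - sum(probs))
      cat_idx <- sample.int(5L, n, replace = TRUE, prob = probs)
      lfc <- numeric(n)
      lfc[cat_idx == 1L] <- 2 + rexp(sum(cat_idx == 1L), rate = 1.5)
      lfc[cat_idx == 2L] <- runif(sum(cat_idx == 2L), 1, 2 - 1e-9)
      lfc[cat_idx == 3L] <- -(2 + rexp(sum(cat_idx == 3L), rate = 1.5))
      lfc[cat_idx == 4L] <- -runif(sum(cat_idx == 4L), 1, 2 - 1e-9)
      lfc[cat_idx == 5L] <- runif(sum(cat_idx == 5L), -1 + 1e-9, 1 - 1e-9)
      data.frame(transcript = sprintf("t%05d", seq_len(n)),
                 region = dp$region[i],
                 log2fc = lfc,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, pieces)
  })
  if (!is.null(anchors)) {
    stopifnot(all(c("transcript", "region", "log2fc") %in% names(anchors)))
    key <- paste(out$transcript, out$region)
    akey <- paste(anchors$transcript, anchors$region)
    hit <- key %in% akey
    out <- rbind(out[!hit, , drop = FALSE],
                 anchors[, c("transcript", "region", "log2fc")])
  }
  rownames(out) <- NULL
  out
}

#' Select roots within one SD of the mean axial length
#'
#' Sampling rule for harvesting: keep roots whose axial length lies within
#' one sample standard deviation of the cohort mean.  When all lengths are
#' identical (SD = 0) every root is kept: the boundary counts as within.
#'
#' @param lengths numeric vector of root lengths (>= 2 values).
#' @return Logical vector, `TRUE` for kept roots.
#' @export
select_roots <- function(lengths) {
  if (length(lengths) < 2L) {
    stop("need at least 2 roots to compute a selection band", call. = FALSE)
  }
  abs(lengths - mean(lengths)) <= sd(lengths)
}
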