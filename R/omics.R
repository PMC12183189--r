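# Metabolomic preprocessing and differential-abundance statistics, plus
# transcript threshold counting, the transcription-factor filter, and PCA
# variance partitioning.
#
# The preprocessing chain is order-locked: minimum imputation, then
# per-feature median scaling, then natural-log transform for the test.
# Fold changes are computed on the scaled, imputed (pre-log) data.

#' Construct a feature-by-sample abundance matrix
#'
#' @param values numeric matrix, features in rows (rownames = feature
#'   ids), samples in columns; non-negative, `NA` allowed for missing.
#' @param samples data frame with columns `sample`, `treatment`, `region`,
#'   `replicate` describing the columns of `values`, in order.
#' @return Object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, samples) {
  stopifnot(is.matrix(values), is.data.frame(samples),
            nrow(samples) == ncol(values),
            all(c("sample", "treatment", "region", "replicate") %in%
                  names(samples)))
  if (any(values < 0, na.rm = TRUE)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d features x %d samples (%s; %s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$treatment), collapse = "/"),
              paste(unique(x$samples$region), collapse = "/")))
  cat(sprintf("  missing cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

check_observed <- function(values) {
  bad <- rownames(values)[rowSums(!is.na(values)) == 0L]
  if (length(bad)) {
    stop("feature(s) with no observed values: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Median-scale an abundance matrix
#'
#' Divides each feature's raw area counts by that feature's median over
#' its observed values, so every feature's post-scaling median is 1.
#' Idempotent.
#'
#' @param m an [abundance_matrix()].
#' @return A median-scaled `abundance_matrix`.
#' @export
median_scale <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  check_observed(m$values)
  med <- apply(m$values, 1L, median, na.rm = TRUE)
  m$values <- m$values / med
  m
}

#' Impute missing values with the per-feature observed minimum
#'
#' @param m an [abundance_matrix()].
#' @return An `abundance_matrix` with no missing cells.
#' @export
impute_min <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  check_observed(m$values)
  mins <- apply(m$values, 1L, min, na.rm = TRUE)
  idx <- which(is.na(m$values), arr.ind = TRUE)
  if (nrow(idx)) m$values[idx] <- mins[idx[, 1L]]
  m
}

#' Natural-log transform an abundance matrix
#'
#' @param m an [abundance_matrix()] with strictly positive values
#'   (impute first).
#' @return The log-transformed `abundance_matrix`.
#' @export
ln_transform <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (any(m$values <= 0, na.rm = TRUE)) {
    stop("values must be > 0 before the log transform; run impute_min() ",
         "first", call. = FALSE)
  }
  m$values <- log(m$values)
  m
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided Welch test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric vectors of replicate values (>= 2 each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (var(a) == 0 && var(b) == 0) {
    stop("both groups have zero variance; the Welch test is undefined",
         call. = FALSE)
  }
  ht <- t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement;
#' order-preserving in the input.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Fold change between treatment groups
#'
#' WD/WW ratio computed on the median-scaled, imputed (pre-log) data.
#' Default is the ratio of arithmetic means; a geometric-mean ratio is
#' available.
#'
#' @param wd,ww numeric replicate values for the water-deficit and
#'   well-watered groups.
#' @param method `"arithmetic"` (default) or `"geometric"`.
#' @return The fold change (natural scale).
#' @export
fold_change <- function(wd, ww, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  wd <- wd[!is.na(wd)]
  ww <- ww[!is.na(ww)]
  if (method == "arithmetic") {
    mw <- mean(ww)
    if (mw <= 0) stop("WW mean must be positive", call. = FALSE)
    mean(wd) / mw
  } else {
    exp(mean(log(wd)) - mean(log(ww)))
  }
}

#' Differential-abundance calling for a two-treatment metabolome
#'
#' Runs the full preprocessing and testing chain per region: minimum
#' imputation, median scaling, natural-log transform, Welch test of WD vs
#' WW replicates, Benjamini-Hochberg q-values across the features of each
#' region, and fold change on the scaled pre-log data.  Significance is
#' then assigned by [call_dams()].
#'
#' @param m an [abundance_matrix()] with WW and WD samples.
#' @param p_cut,q_cut,fc_cut significance gates (defaults 0.05, 0.10,
#'   1.5).
#' @param preprocess_order order of the pre-log preprocessing steps;
#'   the locked default imputes before scaling.  Any other order changes
#'   results and raises a warning.
#' @return Data frame (a differential table) with columns `feature`,
#'   `region`, `fold_change`, `log2fc`, `t`, `df`, `p`, `q`,
#'   `significant`.
#' @export
dam_pipeline <- function(m, p_cut = 0.05, q_cut = 0.10, fc_cut = 1.5,
                         preprocess_order = c("impute", "scale")) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (!identical(preprocess_order, c("impute", "scale"))) {
    warning("non-standard preprocessing order ",
            paste(preprocess_order, collapse = " -> "),
            "; results are not comparable with the locked ",
            "impute -> scale -> log chain", call. = FALSE)
  }
  pre <- m
  for (step in preprocess_order) {
    pre <- switch(step, impute = impute_min(pre), scale = median_scale(pre),
                  stop("unknown preprocessing step: ", step, call. = FALSE))
  }
  lg <- ln_transform(pre)
  regions <- unique(pre$samples$region)
  res <- lapply(regions, function(r) {
    ww <- pre$samples$sample[pre$samples$treatment == "WW" &
                               pre$samples$region == r]
    wd <- pre$samples$sample[pre$samples$treatment == "WD" &
                               pre$samples$region == r]
    if (length(ww) < 2L || length(wd) < 2L) {
      stop("region ", r, " needs >= 2 replicates per treatment",
           call. = FALSE)
    }
    feats <- rownames(pre$values)
    stats_list <- lapply(feats, function(f) {
      wt <- tryCatch(welch_test(lg$values[f, wd], lg$values[f, ww]),
                     error = function(e) list(t = NA_real_, df = NA_real_,
                                              p = NA_real_))
      fc <- fold_change(pre$values[f, wd], pre$values[f, ww])
      c(fc = fc, t = wt$t, df = wt$df, p = wt$p)
    })
    sm <- do.call(rbind, stats_list)
    data.frame(feature = feats,
               region = r,
               fold_change = sm[, "fc"],
               log2fc = log2(sm[, "fc"]),
               t = sm[, "t"], df = sm[, "df"], p = sm[, "p"],
               q = bh_fdr(sm[, "p"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  call_dams(out, p_cut = p_cut, q_cut = q_cut, fc_cut = fc_cut)
}

#' Apply the differential-abundance significance gates
#'
#' A feature is significant when `p < p_cut`, `q < q_cut`, and the fold
#' change passes the two-sided gate (`FC >= fc_cut` or
#' `FC <= 1 / fc_cut`).
#'
#' @param diff data frame with columns `p`, `q`, `fold_change`.
#' @param p_cut,q_cut,fc_cut the gates.
#' @return `diff` with a (re)computed logical `significant` column.
#' @export
call_dams <- function(diff, p_cut = 0.05, q_cut = 0.10, fc_cut = 1.5) {
  stopifnot(all(c("p", "q", "fold_change") %in% names(diff)))
  diff$significant <- !is.na(diff$p) & diff$p < p_cut & diff$q < q_cut &
    (diff$fold_change >= fc_cut | diff$fold_change <= 1 / fc_cut)
  diff
}

#' Count transcripts beyond log2 fold-change thresholds
#'
#' Per region and per threshold tier, the number of transcripts with
#' `log2FC >= +tier` (up) and `log2FC <= -tier` (down); tiers are nested,
#' so counts at the lower threshold include the higher one.
#'
#' @param diff data frame with columns `region`, `log2fc`.
#' @param tiers numeric thresholds, default `c(2, 1)`.
#' @return Data frame with columns `region`, `tier`, `up`, `down`,
#'   `total`.
#' @export
count_dats <- function(diff, tiers = c(2, 1)) {
  stopifnot(all(c("region", "log2fc") %in% names(diff)))
  regions <- unique(diff$region)
  rows <- list()
  for (r in regions) {
    lfc <- diff$log2fc[diff$region == r]
    for (tr in tiers) {
      up <- sum(lfc >= tr, na.rm = TRUE)
      down <- sum(lfc <= -tr, na.rm = TRUE)
      rows[[length(rows) + 1L]] <-
        data.frame(region = r, tier = tr, up = up, down = down,
                   total = up + down, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Transcription-factor accumulation filter
#'
#' Keeps features that are both present (maximum mean transcript count
#' over region-by-treatment combinations at least `min_count`) and
#' accumulating beyond the log2 fold-change threshold.  The threshold is
#' two-sided by default (`|log2FC| >= threshold`); set
#' `two_sided = FALSE` to keep only increasing features.
#'
#' @param tbl data frame with columns `feature`, `log2fc`,
#'   `max_mean_count`.
#' @param threshold log2 fold-change gate (default 1.2).
#' @param min_count presence gate (default 5).
#' @param two_sided logical.
#' @return The subset of rows passing both gates.
#' @export
tf_filter <- function(tbl, threshold = 1.2, min_count = 5,
                      two_sided = TRUE) {
  stopifnot(all(c("log2fc", "max_mean_count") %in% names(tbl)))
  pass_fc <- if (two_sided) abs(tbl$log2fc) >= threshold else
    tbl$log2fc >= threshold
  tbl[pass_fc & tbl$max_mean_count >= min_count, , drop = FALSE]
}

#' PCA variance partitioning
#'
#' Centered (optionally unit-scaled) principal components analysis of the
#' samples; constant features are dropped before scaling.
#'
#' @param m an [abundance_matrix()] (impute missing values first).
#' @param n_pc number of leading components to report.
#' @param scale. logical, scale features to unit variance.
#' @return List with `var_frac` (length `n_pc`, fractions of total
#'   variance, non-increasing), `scores` (samples x `n_pc`), and the
#'   sample table.
#' @export
pca_variance <- function(m, n_pc = 2, scale. = FALSE) {
  stopifnot(inherits(m, "abundance_matrix"))
  if (any(is.na(m$values))) {
    stop("matrix contains missing values; impute first", call. = FALSE)
  }
  keep <- apply(m$values, 1L, var) > 0
  if (!any(keep)) stop("matrix is constant; PCA is undefined", call. = FALSE)
  x <- t(m$values[keep, , drop = FALSE])
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  fr <- pc$sdev^2 / sum(pc$sdev^2)
  n_pc <- min(n_pc, length(fr))
  list(var_frac = fr[seq_len(n_pc)],
       scores = pc$x[, seq_len(n_pc), drop = FALSE],
       samples = m$samples)
}
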