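# Metabolomic preprocessing, differential calling, transcript thresholds,
# TF filter and PCA.

toy3 <- function(vals) {
  toy_abundance(matrix(vals, nrow = 1, dimnames = list("m1", NULL)),
                treatments = c("WW", "WW", "WW"),
                regions = rep("R1", 3))
}

test_that("median scaling divides by the per-feature observed median", {
  m <- toy3(c(2, 4, 6))
  expect_equal(unname(median_scale(m)$values[1, ]), c(0.5, 1.0, 1.5))
  # every feature's post-scaling median is 1, and scaling is idempotent
  set.seed(2)
  vals <- matrix(rlnorm(60), nrow = 6,
                 dimnames = list(paste0("f", 1:6), NULL))
  vals[sample(60, 8)] <- NA
  m2 <- toy_abundance(vals, treatments = rep(c("WW", "WD"), each = 5),
                      regions = rep("R1", 10))
  s1 <- median_scale(m2)
  expect_equal(unname(apply(s1$values, 1, median, na.rm = TRUE)),
               rep(1, 6))
  expect_equal(median_scale(s1)$values, s1$values)
  vals[2, ] <- NA
  m3 <- toy_abundance(vals, treatments = rep(c("WW", "WD"), each = 5),
                      regions = rep("R1", 10))
  expect_error(median_scale(m3), "f2")
})

test_that("minimum imputation fills missing cells without changing minima", {
  m <- toy3(c(1, NA, 3))
  expect_equal(unname(impute_min(m)$values[1, ]), c(1, 1, 3))
  full <- toy3(c(1, 2, 3))
  expect_equal(impute_min(full)$values, full$values)
  set.seed(4)
  vals <- matrix(rlnorm(50), nrow = 5,
                 dimnames = list(paste0("f", 1:5), NULL))
  vals[sample(50, 10)] <- NA
  m2 <- toy_abundance(vals, treatments = rep("WW", 10),
                      regions = rep("R1", 10))
  imp <- impute_min(m2)
  expect_false(anyNA(imp$values))
  expect_equal(apply(imp$values, 1, min),
               apply(vals, 1, min, na.rm = TRUE))
})

test_that("natural-log transform requires positive values", {
  m <- toy3(c(exp(1), 1, exp(2)))
  expect_equal(unname(ln_transform(m)$values[1, ]), c(1, 0, 2))
  expect_error(ln_transform(toy3(c(0, 1, 2))), "impute")
})

test_that("Welch test matches the long-hand formula", {
  # equal means give t = 0, p = 1
  w0 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  # long-hand Welch-Satterthwaite oracle
  a <- c(10, 11, 12)
  b <- c(20, 21, 22)
  got <- welch_test(a, b)
  hand <- welch_by_hand(a, b)
  expect_equal(got$t, hand$t, tolerance = 1e-12)
  expect_equal(got$df, hand$df, tolerance = 1e-12)
  expect_equal(got$p, hand$p, tolerance = 1e-12)
  set.seed(8)
  a2 <- rnorm(5, 3, 2)
  b2 <- rnorm(7, 4, 0.5)
  got2 <- welch_test(a2, b2)
  hand2 <- welch_by_hand(a2, b2)
  expect_equal(got2$t, hand2$t, tolerance = 1e-12)
  expect_equal(got2$p, hand2$p, tolerance = 1e-12)
  expect_error(welch_test(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welch_test(1, c(2, 3)), "2 replicates")
})

test_that("the observed 3-vs-3 split is the most extreme permutation", {
  # with groups this separated, every relabelling of the six values gives
  # a smaller |t| than the observed split (and its mirror)
  a <- c(10, 11, 12)
  b <- c(20, 21, 22)
  pool <- c(a, b)
  t_obs <- abs(welch_by_hand(a, b)$t)
  splits <- combn(6, 3)
  t_perm <- apply(splits, 2, function(idx)
    abs(welch_by_hand(pool[idx], pool[-idx])$t))
  expect_equal(sum(t_perm >= t_obs - 1e-12), 2)  # observed + mirror
  expect_lt(welch_test(a, b)$p, 2 / 20)
})

test_that("BH q-values match the hand step-up computation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # hand step-up: p * m / rank with monotone enforcement from the top
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  hand <- rev(cummin(rev(p * length(p) / rank(p))))
  expect_equal(bh_fdr(p), hand)
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change is the WD/WW mean ratio on pre-log data", {
  expect_equal(fold_change(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(fold_change(c(4, 6), c(2, 3)), 2)
  expect_equal(fold_change(c(4, 8), c(2, 4), method = "geometric"), 2)
  expect_error(fold_change(c(1, 2), c(0, 0)), "positive")
})

test_that("significance gates combine p, q and a two-sided fold change", {
  d <- data.frame(p = c(0.01, 0.01, 0.01, 0.2),
                  q = c(0.05, 0.05, 0.05, 0.05),
                  fold_change = c(2.0, 1.2, 0.5, 2.0))
  out <- call_dams(d)
  expect_equal(out$significant, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("threshold counts are nested and match hand counting", {
  d0 <- data.frame(region = "R1", log2fc = rep(0, 5))
  c0 <- count_dats(d0)
  expect_equal(c0$total, c(0, 0))
  d <- data.frame(region = "R1", log2fc = c(2.5, -2.1, 1.2, -0.5))
  cd <- count_dats(d)
  expect_equal(cd[cd$tier == 2, c("total", "up", "down")],
               data.frame(total = 2L, up = 1L, down = 1L),
               ignore_attr = TRUE)
  expect_equal(cd[cd$tier == 1, c("total", "up", "down")],
               data.frame(total = 3L, up = 2L, down = 1L),
               ignore_attr = TRUE)
})

test_that("TF filter combines presence and accumulation gates", {
  tbl <- data.frame(feature = c("a", "b", "c", "d"),
                    log2fc = c(1.3, 1.3, -1.3, 1.1),
                    max_mean_count = c(10, 3, 10, 10))
  expect_equal(tf_filter(tbl)$feature, c("a", "c"))
  expect_equal(tf_filter(tbl, two_sided = FALSE)$feature, "a")
})

test_that("PCA variance fractions behave as eigenvalue shares", {
  # rank-1 data: the first component carries all variance
  v <- outer(c(1, 2, 3), c(1, 4, 2, 5))
  rownames(v) <- paste0("f", 1:3)
  m <- toy_abundance(v, treatments = rep("WW", 4), regions = rep("R1", 4))
  expect_equal(pca_variance(m, 1)$var_frac, 1, tolerance = 1e-12)
  # two features, three samples: fractions are the eigenvalue shares of
  # the hand-computed 2x2 sample covariance
  v2 <- matrix(c(1, 3, 2, 8, 6, 4), nrow = 2,
               dimnames = list(c("f1", "f2"), NULL))
  m2 <- toy_abundance(v2, treatments = c("WW", "WD", "WW"),
                      regions = rep("R1", 3))
  ev <- eigen(stats::cov(t(v2)))$values
  expect_equal(pca_variance(m2, 2)$var_frac, ev / sum(ev),
               tolerance = 1e-12)
  # fractions are non-increasing, sum to <= 1, sample order irrelevant
  set.seed(6)
  v3 <- matrix(rlnorm(40), nrow = 5,
               dimnames = list(paste0("f", 1:5), NULL))
  m3 <- toy_abundance(v3, treatments = rep(c("WW", "WD"), 4),
                      regions = rep("R1", 8))
  fr <- pca_variance(m3, 4)$var_frac
  expect_true(all(diff(fr) <= 1e-12))
  expect_lte(sum(fr), 1 + 1e-12)
  perm <- sample(8)
  m3p <- toy_abundance(v3[, perm],
                       treatments = rep(c("WW", "WD"), 4)[perm],
                       regions = rep("R1", 8))
  expect_equal(pca_variance(m3p, 4)$var_frac, fr, tolerance = 1e-9)
  const <- toy_abundance(matrix(1, 2, 4,
                                dimnames = list(c("f1", "f2"), NULL)),
                         treatments = rep("WW", 4),
                         regions = rep("R1", 4))
  expect_error(pca_variance(const), "constant")
})

test_that("strong true effects are recovered across seeds at n = 3", {
  # features with true fold change >= 1.8 under cv = 0.10 and triplicate
  # sampling should essentially always pass the p/q/FC gates
  eff <- default_metabolite_effects()
  strong <- eff$fold_change >= 1.8 | eff$fold_change <= 1 / 1.8
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    m <- make_metabolome(wd_scenario(seed = 200 + s))
    d <- dam_pipeline(m)
    d <- d[order(d$feature, d$region), ]
    eo <- eff[order(eff$metabolite, eff$region), ]
    stopifnot(identical(d$feature, eo$metabolite))
    total <- total + sum(strong)
    hits <- hits + sum(d$significant[strong])
  }
  expect_gte(hits / total, 0.95)
})

test_that("the preprocessing order is locked", {
  m <- make_metabolome(wd_scenario(missing_rate = 0.1))
  expect_warning(dam_pipeline(m, preprocess_order = c("scale", "impute")),
                 "non-standard preprocessing order")
})
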