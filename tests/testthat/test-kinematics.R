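# Kinematic analysis: rates, flux, velocity reconstruction, logistic
# fitting, REL, expansion profiles and region bookkeeping.

test_that("elongation rate is the two-day mean difference", {
  co <- data.frame(plant = rep(c("a", "b"), each = 2),
                   day = c(15, 15, 17, 17), treatment = "WW",
                   length_cm = c(10, 10, 16.16, 16.16))
  r <- elongation_rate(co)
  expect_equal(r$rate_cm_per_day, 3.08)
  expect_equal(r$rate_mm_per_h, 1.2833333, tolerance = 1e-6)
  co$length_cm <- c(10.5, 10.5, 16.26, 16.26)
  co$length_cm[1:2] <- 10  # means 10.00 and 16.26
  expect_equal(elongation_rate(co)$rate_cm_per_day, 3.13)
  co$length_cm <- rep(12, 4)
  expect_equal(elongation_rate(co)$rate_cm_per_day, 0)
  expect_error(elongation_rate(co[co$day == 15, ]), "both day")
  co$length_cm <- c(16, 16, 10, 10)
  expect_warning(elongation_rate(co), "negative")
})

test_that("mature cell length is the windowed mean", {
  pr <- data.frame(position_mm = c(10, 10.5, 11, 11.5, 12),
                   cell_length_um = rep(150, 5))
  expect_equal(mature_cell_length(pr), 150)
  pr$cell_length_um <- c(150, 160, 170, 150, 170)
  expect_equal(mature_cell_length(pr, window = c(10, 11)), 160)
  expect_error(mature_cell_length(pr, window = c(13, 14)), "mature window")
})

test_that("cell flux reproduces the worked examples to 3 significant figures", {
  expect_equal(signif(cell_flux(1.28333, 156.9), 3), 8.18)
  expect_equal(signif(cell_flux(1.30417, 169.8), 3), 7.68)
  expect_equal(cell_flux(0, 150), 0)
  expect_error(cell_flux(1.28, 0), "positive")
})

test_that("velocity reconstruction obeys flux constancy", {
  # mature cells everywhere: velocity equals the overall rate
  pr <- data.frame(position_mm = seq(0, 12, 0.5),
                   cell_length_um = 150)
  v <- velocity_profile(pr, 1.2)
  expect_equal(v$velocity_mm_per_h, rep(1.2, nrow(pr)))
  # half-length cells move at half the rate
  pr2 <- pr
  pr2$cell_length_um[pr2$position_mm < 10] <- 75
  v2 <- velocity_profile(pr2, 1.2)
  expect_equal(v2$velocity_mm_per_h[pr2$position_mm < 10][1], 0.6)
  # v/l is constant along the profile (machine precision)
  cfg <- ww_scenario()
  cells <- make_cell_profile(cfg, seq(0, 12, 0.1))
  vel <- velocity_profile(cells, cfg$elong_rate_cm_per_day * 10 / 24)
  ratio <- vel$velocity_mm_per_h / (cells$cell_length_um / 1000)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  # round trip: the reconstruction reproduces the scenario truth pointwise
  lt <- cfg$logistic_truth
  keep <- cells$position_mm < cfg$plateau_start_mm
  truth <- logistic_velocity(cells$position_mm[keep], lt["a1"], lt["a2"],
                             lt["x0"], lt["p"])
  expect_equal(vel$velocity_mm_per_h[keep], unname(truth),
               tolerance = 1e-12)
})

test_that("logistic fit recovers exact and noisy curves", {
  x <- seq(0.25, 12, length.out = 25)
  vel <- logistic_samples(x, 0.05, 1.283, 3.0, 4.0)
  fit <- fit_logistic(vel)
  expect_equal(fit$a1, 0.05, tolerance = 1e-6)
  expect_equal(fit$a2, 1.283, tolerance = 1e-6)
  expect_equal(fit$x0, 3.0, tolerance = 1e-6)
  expect_equal(fit$p, 4.0, tolerance = 1e-6)
  expect_equal(fit$R, 1, tolerance = 1e-9)
  # 2% multiplicative noise: fit quality stays above 0.98
  set.seed(3)
  veln <- vel
  veln$velocity_mm_per_h <- veln$velocity_mm_per_h * (1 + 0.02 * rnorm(25))
  expect_gte(fit_logistic(veln)$R, 0.98)
  expect_error(fit_logistic(vel[1:4, ]), "at least 5")
  flat <- data.frame(position_mm = x,
                     velocity_mm_per_h = rep(1, 25))
  expect_error(fit_logistic(flat), "flat")
})

test_that("logistic fit matches an independent grid-search + polish oracle", {
  x <- seq(0.25, 12, length.out = 25)
  set.seed(17)
  y <- logistic_samples(x, 0.05, 1.283, 3.0, 4.0)$velocity_mm_per_h *
    (1 + 0.02 * rnorm(25))
  vel <- data.frame(position_mm = x, velocity_mm_per_h = y)
  sse <- function(th) {
    pred <- th[2] + (th[1] - th[2]) / (1 + (x / th[3])^th[4])
    sum((y - pred)^2)
  }
  # coarse 4-D grid, then Nelder-Mead polish from the best grid point
  grid <- expand.grid(a1 = seq(0, 0.2, 0.05), a2 = seq(1.0, 1.6, 0.1),
                      x0 = seq(1.5, 5, 0.5), p = seq(2, 6, 1))
  vals <- apply(grid, 1L, sse)
  best <- as.numeric(grid[which.min(vals), ])
  polish <- optim(best, sse, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-14))
  fit <- fit_logistic(vel)
  expect_equal(sse(c(fit$a1, fit$a2, fit$x0, fit$p)), polish$value,
               tolerance = 1e-6)
  expect_equal(c(fit$a1, fit$a2, fit$x0, fit$p), polish$par,
               tolerance = 1e-3)
})

test_that("noisy parameter recovery holds across seeded scenarios", {
  # profiles sampled at the package's standard 0.1 mm spacing
  x <- seq(0.25, 12, by = 0.1)
  truth <- c(a1 = 0.05, a2 = 1.2833, x0 = 3.3006, p = 2.7469)
  ok_x0 <- ok_p <- ok_a2 <- logical(50)
  for (s in 1:50) {
    set.seed(1000 + s)
    cv <- if (s %% 2) 0.02 else 0.05
    y <- logistic_samples(x, truth["a1"], truth["a2"], truth["x0"],
                          truth["p"])$velocity_mm_per_h *
      exp(rnorm(length(x), 0, cv))
    fit <- fit_logistic(data.frame(position_mm = x,
                                   velocity_mm_per_h = y))
    ok_x0[s] <- abs(fit$x0 - truth["x0"]) / truth["x0"] < 0.10
    ok_p[s] <- abs(fit$p - truth["p"]) / truth["p"] < 0.10
    ok_a2[s] <- abs(fit$a2 - truth["a2"]) / truth["a2"] < 0.03
  }
  expect_true(all(ok_x0))
  expect_true(all(ok_p))
  expect_true(all(ok_a2))
})

test_that("analytic REL matches the closed form and finite differences", {
  fit <- list(a1 = 0, a2 = 1.28, x0 = 3, p = 4)
  # at the midpoint the derivative is (a2 - a1) p / (4 x0)
  expect_equal(rel_profile(fit, 3)$rel_per_h, 1.28 * 4 / (4 * 3),
               tolerance = 1e-12)
  expect_equal(rel_profile(fit, 3)$rel_per_h, 0.42667, tolerance = 1e-4)
  # vanishes far from the growth zone
  expect_lt(rel_profile(fit, 1e4)$rel_per_h, 1e-10)
  expect_error(rel_profile(fit, c(-0.5, 2)), ">= 0")
  # finite-difference oracle on the fitted curve
  g <- seq(0.1, 12, 0.05)
  h <- 1e-5
  fd <- (logistic_velocity(g + h, fit$a1, fit$a2, fit$x0, fit$p) -
           logistic_velocity(g - h, fit$a1, fit$a2, fit$x0, fit$p)) / (2 * h)
  expect_equal(rel_profile(fit, g)$rel_per_h, fd, tolerance = 1e-6)
})

test_that("growth-zone extent finds the cessation point past the peak", {
  cfg <- ww_scenario()
  lt <- cfg$logistic_truth
  rel <- rel_profile(list(a1 = lt["a1"], a2 = lt["a2"], x0 = lt["x0"],
                          p = lt["p"]), seq(0, 12, 0.1))
  gz <- growth_zone_extent(rel)
  expect_equal(gz$peak_position_mm, 2.5, tolerance = 0.1)
  expect_equal(gz$extent_mm, 10, tolerance = 0.15)
  flatrel <- data.frame(position_mm = 0:10, rel_per_h = rep(1, 11))
  expect_error(growth_zone_extent(flatrel), "no deceleration")
})

test_that("area profile assumes circular cross-sections", {
  d <- data.frame(position_mm = 0:2, diameter_mm = c(1, 2, 1))
  a <- area_profile(d)
  expect_equal(a$area_mm2[1], pi / 4, tolerance = 1e-12)
  expect_equal(a$area_mm2[1], 0.7854, tolerance = 1e-4)
  expect_equal(a$area_mm2[2], pi, tolerance = 1e-12)
  d2 <- d
  d2$diameter_mm <- d$diameter_mm * 2
  expect_equal(area_profile(d2)$area_mm2, 4 * a$area_mm2)
  d$diameter_mm[1] <- 0
  expect_error(area_profile(d), "positive")
})

test_that("radial+tangential rate is v times the log-derivative of area", {
  x <- seq(0, 10, 0.01)
  vel <- data.frame(position_mm = x, velocity_mm_per_h = 0.2 + 0.1 * x)
  # constant area: no cross-sectional expansion
  flat <- data.frame(position_mm = x, area_mm2 = rep(0.8, length(x)))
  expect_equal(radtan_rate(vel, flat)$radtan_per_h, rep(0, length(x)))
  # exponential area: ln A is linear, so central differences are exact
  k <- 0.3
  ea <- data.frame(position_mm = x, area_mm2 = 0.5 * exp(k * x))
  expect_equal(radtan_rate(vel, ea)$radtan_per_h,
               k * vel$velocity_mm_per_h, tolerance = 1e-9)
  # polynomial area against the symbolic product-rule derivative
  pa <- data.frame(position_mm = x, area_mm2 = (1 + 0.1 * x)^2)
  sym <- vel$velocity_mm_per_h * 2 * 0.1 / (1 + 0.1 * x)
  got <- radtan_rate(vel, pa)$radtan_per_h
  interior <- seq(2, length(x) - 1)
  expect_equal(got[interior], sym[interior], tolerance = 1e-4)
  expect_error(radtan_rate(vel, flat[1:5, ]), "grid")
})

test_that("volumetric profiles satisfy the defining identities", {
  x <- seq(0, 9.5, 0.1)
  rel <- data.frame(position_mm = x, rel_per_h = 0.4 * exp(-(x - 2)^2))
  zero <- data.frame(position_mm = x, radtan_per_h = 0)
  area <- data.frame(position_mm = x, area_mm2 = 0.7 + 0.02 * x)
  vp <- volumetric_profiles(rel, zero, area)
  expect_equal(vp$relvol_per_h, rel$rel_per_h)
  expect_equal(vp$volrate_mm3_per_mm_h, rel$rel_per_h * area$area_mm2)
  rt <- data.frame(position_mm = x, radtan_per_h = 0.1 * exp(-x))
  vp2 <- volumetric_profiles(rel, rt, area)
  expect_equal(vp2$relvol_per_h, rel$rel_per_h + rt$radtan_per_h,
               tolerance = 1e-12)
})

test_that("integrated volumetric rate equals the boundary flux difference", {
  # relvol * A = d(vA)/dx when rel = dv/dx and radtan = v dlnA/dx, so the
  # integral telescopes to v(L)A(L) - v(0)A(0)
  cfg <- ww_scenario()
  lt <- cfg$logistic_truth
  x <- seq(0, 9.5, 0.005)
  fit <- list(a1 = lt[["a1"]], a2 = lt[["a2"]], x0 = lt[["x0"]],
              p = lt[["p"]])
  rel <- rel_profile(fit, x)
  v <- logistic_velocity(x, fit$a1, fit$a2, fit$x0, fit$p)
  vel <- data.frame(position_mm = x, velocity_mm_per_h = v)
  area <- area_profile(make_diameter_profile(cfg, x))
  vp <- volumetric_profiles(rel, radtan_rate(vel, area), area)
  got <- sum(diff(x) * (vp$volrate_mm3_per_mm_h[-1] +
                          vp$volrate_mm3_per_mm_h[-length(x)]) / 2)
  expected <- v[length(x)] * area$area_mm2[length(x)] -
    v[1] * area$area_mm2[1]
  expect_equal(got, expected, tolerance = 1e-4)
})

test_that("region summaries integrate and average correctly", {
  x <- seq(0, 9.5, 0.1)
  const <- data.frame(position_mm = x, v = rep(2, length(x)))
  rs <- region_summaries(const)
  expect_equal(rs$v_mean, rep(2, 3))
  expect_equal(sum(rs$v_integral), 2 * 9.5, tolerance = 1e-9)
  # piecewise-linear profile: hand trapezoid over R1 = [0,3]
  tri <- data.frame(position_mm = c(0, 3, 6, 9.5), v = c(0, 3, 0, 0))
  rs2 <- region_summaries(tri)
  expect_equal(rs2$v_integral[1], 4.5, tolerance = 1e-9)  # (3*3)/2
  expect_equal(rs2$v_integral[2], 4.5, tolerance = 1e-9)
  expect_equal(rs2$v_integral[3], 0, tolerance = 1e-9)
  # additivity: region integrals sum to the full-range integral
  set.seed(5)
  wig <- data.frame(position_mm = x, v = abs(rnorm(length(x))) + 0.5)
  rs3 <- region_summaries(wig)
  full <- sum(diff(x) * (wig$v[-1] + wig$v[-length(x)]) / 2)
  expect_equal(sum(rs3$v_integral), full, tolerance = 1e-6)
  short <- data.frame(position_mm = seq(0, 5, 0.1), v = 1)
  expect_error(region_summaries(short), "cover")
})
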