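# Estimators: closed forms, oracle equivalence, invariances.

test_that("the Wald ratio follows the first-order delta method", {
  est <- wald_ratio(make_pairs(0.5, 0.1, 0.02, sx = 0.05))
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)
  expect_equal(est$ci_low, 0.2 - 1.959964 * 0.04, tolerance = 1e-9)
  # null numerator
  est0 <- wald_ratio(make_pairs(0.5, 0, 0.02))
  expect_equal(est0$beta, 0)
  expect_equal(est0$pvalue, 1)
  expect_error(wald_ratio(make_pairs(0, 0.1, 0.02)), "beta_exposure")
})

test_that("the first-order Wald SE tracks a parametric-bootstrap oracle", {
  boot_se <- function(bx, sx, by, sy, n = 1e5) {
    set.seed(55)
    sd(rnorm(n, by, sy) / rnorm(n, bx, sx))
  }
  # strong instrument (F = 625): first-order SE within 10% of the bootstrap
  est <- wald_ratio(make_pairs(0.5, 0.1, 0.02, sx = 0.02))
  expect_lt(abs(est$se - boot_se(0.5, 0.02, 0.1, 0.02)) /
              boot_se(0.5, 0.02, 0.1, 0.02), 0.10)
  # at F = 100 neglecting the exposure-side noise understates the SE by ~11%;
  # the approximation error stays bounded (< 15%)
  est2 <- wald_ratio(make_pairs(0.5, 0.1, 0.02, sx = 0.05))
  rel <- abs(est2$se - boot_se(0.5, 0.05, 0.1, 0.02)) / boot_se(0.5, 0.05, 0.1, 0.02)
  expect_gt(rel, 0.05)
  expect_lt(rel, 0.15)
})

test_that("IVW reproduces a perfectly proportional set exactly", {
  p <- make_pairs(c(0.5, 0.25), c(0.1, 0.05), c(0.02, 0.02))
  est <- ivw(p)
  expect_equal(est$beta, 0.2, tolerance = 1e-14)
  expect_equal(est$q, 0, tolerance = 1e-20)
  expect_equal(est$q_pvalue, 1)
})

test_that("IVW with a single pair collapses to the Wald ratio", {
  p <- make_pairs(0.5, 0.1, 0.02, sx = 0.05)
  expect_equal(ivw(p)$beta, wald_ratio(p)$beta)
  expect_equal(ivw(p)$se, wald_ratio(p)$se)
  expect_equal(ivw(p)$method, "wald_ratio")
})

test_that("IVW and Egger match an independent WLS oracle on random instances", {
  set.seed(501)
  for (rep in 1:40) {
    k <- sample(3:10, 1)
    bx <- runif(k, 0.1, 0.6) * sample(c(-1, 1), k, replace = TRUE)
    by <- 0.2 * bx + rnorm(k, 0, 0.05)
    sy <- runif(k, 0.01, 0.1)
    p <- make_pairs(bx, by, sy)

    est <- ivw(p, effects_model = "fixed")
    o <- wls_oracle(bx, by, sy, intercept = FALSE)
    expect_equal(est$beta, o$coef[1], tolerance = 1e-10)
    expect_equal(est$se, o$se_unscaled[1], tolerance = 1e-10)

    egg <- mr_egger(p)
    flip <- ifelse(bx < 0, -1, 1)
    oe <- wls_oracle(bx * flip, by * flip, sy, intercept = TRUE)
    expect_equal(egg$beta, oe$coef[2], tolerance = 1e-10)
    expect_equal(egg$egger_intercept, oe$coef[1], tolerance = 1e-10)
    expect_equal(egg$se, oe$se_scaled[2], tolerance = 1e-10)
    expect_equal(egg$egger_intercept_se, oe$se_scaled[1], tolerance = 1e-10)
  }
})

test_that("the multiplicative random-effects model never deflates the SE", {
  set.seed(502)
  bx <- runif(6, 0.2, 0.5); by <- 0.2 * bx + rnorm(6, 0, 0.08)
  sy <- rep(0.02, 6)
  p <- make_pairs(bx, by, sy)
  fixed <- ivw(p, "fixed"); mre <- ivw(p, "multiplicative_random")
  expect_equal(mre$beta, fixed$beta)
  expect_gte(mre$se, fixed$se)
  expect_equal(mre$se, fixed$se * sqrt(max(1, fixed$q / (6 - 1))), tolerance = 1e-12)
})

test_that("MR-Egger recovers an exact line through the points", {
  bx <- c(0.2, 0.4, 0.6)
  by <- 0.01 + 0.3 * bx
  est <- mr_egger(make_pairs(bx, by, rep(0.02, 3)))
  expect_equal(est$beta, 0.3, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-12)
  # collinear through the origin: intercept exactly zero
  est0 <- mr_egger(make_pairs(bx, 0.3 * bx, rep(0.02, 3)))
  expect_equal(est0$egger_intercept, 0, tolerance = 1e-12)
})

test_that("methods requiring three variants flag smaller sets", {
  p <- make_pairs(c(0.5, 0.25), c(0.1, 0.05), c(0.02, 0.02))
  expect_warning(expect_null(mr_egger(p)), "not estimable")
  expect_warning(expect_null(weighted_median(p, seed = 1)), "not estimable")
  expect_warning(expect_null(leave_one_out(p)), "not estimable")
})

test_that("the weighted median interpolates the ordered ratios at half weight", {
  # symmetric three-ratio case with equal weights
  p <- make_pairs(c(0.5, 0.5, 0.5), c(0.05, 0.10, 0.15), rep(0.02, 3))
  expect_equal(weighted_median(p, n_boot = 200, seed = 5)$beta, 0.2)
  # equal-weight four-ratio case: hand evaluation of the interpolation at 0.5
  # ratios (0.1, 0.2, 0.4, 0.5), midpoints (0.125, 0.375, 0.625, 0.875)
  # -> 0.2 + (0.5 - 0.375)/0.25 * (0.4 - 0.2) = 0.3
  p4 <- make_pairs(rep(0.5, 4), 0.5 * c(0.1, 0.2, 0.4, 0.5), rep(0.02, 4))
  expect_equal(weighted_median(p4, n_boot = 200, seed = 5)$beta, 0.3,
               tolerance = 1e-12)
})

test_that("the weighted median resists a minority outlier", {
  # outlier ratio 10 carries < 25% of the weight: estimate stays within the
  # range of the well-behaved ratios
  p <- make_pairs(rep(0.5, 4), 0.5 * c(0.1, 0.2, 0.3, 10), rep(0.02, 4))
  est <- weighted_median(p, n_boot = 200, seed = 7)
  expect_gte(est$beta, 0.1)
  expect_lte(est$beta, 0.3)
})

test_that("the weighted-median bootstrap SE is seeded and reproducible", {
  p <- make_pairs(c(0.3, 0.4, 0.5), c(0.06, 0.09, 0.1), rep(0.02, 3))
  e1 <- weighted_median(p, n_boot = 300, seed = 42)
  e2 <- weighted_median(p, n_boot = 300, seed = 42)
  expect_identical(e1$se, e2$se)
  expect_error(weighted_median(p, n_boot = 10), "seed")
})

test_that("Cochran's Q matches its closed form and calibration", {
  # all ratios equal -> Q = 0, p = 1
  p <- make_pairs(c(0.5, 0.25), c(0.1, 0.05), c(0.02, 0.02))
  q0 <- cochran_q(p, beta_ref = 0.2)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$pvalue, 1)
  # two pairs, equal weights 25, ratios 0 and 0.4 about beta_ref = 0.2
  p2 <- make_pairs(c(0.5, 0.5), c(0, 0.2), c(0.1, 0.1))
  q2 <- cochran_q(p2, beta_ref = 0.2)
  expect_equal(q2$q, 2)
  expect_equal(q2$df, 1)
  expect_equal(q2$pvalue, pchisq(2, 1, lower.tail = FALSE))
})

test_that("leave-one-out recomputes IVW on each reduced set", {
  set.seed(503)
  bx <- runif(6, 0.2, 0.6)
  by <- 0.2 * bx + rnorm(6, 0, 0.03)
  p <- make_pairs(bx, by, rep(0.02, 6))
  loo <- leave_one_out(p)
  expect_equal(nrow(loo), 6)
  for (i in 1:6)
    expect_equal(loo$beta[i], ivw(p[-i, ])$beta, tolerance = 1e-12)
  # homogeneous set: every leave-one-out estimate equals the full estimate
  ph <- make_pairs(bx, 0.2 * bx, rep(0.02, 6))
  looh <- leave_one_out(ph)
  expect_equal(looh$beta, rep(0.2, 6), tolerance = 1e-12)
  expect_equal(attr(looh, "max_abs_deviation"), 0, tolerance = 1e-12)
  # a gross outlier is the most influential exclusion
  py <- make_pairs(bx, c(0.2 * bx[-6], 5 * bx[6]), rep(0.02, 6))
  looy <- leave_one_out(py)
  dev <- abs(looy$beta - attr(looy, "full_beta"))
  expect_equal(which.max(dev), 6L)
})

test_that("estimators are sign- and scale-equivariant in the outcome", {
  set.seed(504)
  bx <- runif(5, 0.2, 0.6)
  by <- 0.2 * bx + rnorm(5, 0, 0.03)
  sy <- runif(5, 0.01, 0.05)
  p <- make_pairs(bx, by, sy)
  flip <- make_pairs(bx, -by, sy)
  expect_equal(ivw(flip)$beta, -ivw(p)$beta)
  expect_equal(ivw(flip)$se, ivw(p)$se)
  expect_equal(mr_egger(flip)$beta, -mr_egger(p)$beta)
  expect_equal(mr_egger(flip)$se, mr_egger(p)$se)
  expect_equal(weighted_median(flip, 200, seed = 9)$beta,
               -weighted_median(p, 200, seed = 9)$beta)
  # scaling the outcome by c scales every estimate and SE by c
  c0 <- 3.7
  sc <- make_pairs(bx, c0 * by, c0 * sy)
  expect_equal(ivw(sc)$beta, c0 * ivw(p)$beta, tolerance = 1e-12)
  expect_equal(ivw(sc)$se, c0 * ivw(p)$se, tolerance = 1e-12)
  expect_equal(mr_egger(sc)$beta, c0 * mr_egger(p)$beta, tolerance = 1e-12)
})

test_that("jointly flipping a pair's exposure orientation changes nothing", {
  set.seed(505)
  bx <- runif(5, 0.2, 0.6)
  by <- 0.2 * bx + rnorm(5, 0, 0.03)
  sy <- runif(5, 0.01, 0.05)
  p <- make_pairs(bx, by, sy)
  pf <- p
  pf$beta_exposure[2] <- -pf$beta_exposure[2]
  pf$beta_outcome[2] <- -pf$beta_outcome[2]
  expect_equal(ivw(pf)$beta, ivw(p)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pf)$beta, mr_egger(p)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(pf)$egger_intercept, mr_egger(p)$egger_intercept,
               tolerance = 1e-12)
  expect_equal(weighted_median(pf, 200, seed = 11)$beta,
               weighted_median(p, 200, seed = 11)$beta, tolerance = 1e-12)
  expect_equal(cochran_q(pf, 0.2)$q, cochran_q(p, 0.2)$q, tolerance = 1e-12)
})

test_that("weighted-median breakdown occurs past half the weight", {
  # valid ratios at 0.1, invalid shifted by +0.4; equal weights
  shift <- function(n_invalid) {
    by <- c(rep(0.05, 10 - n_invalid), rep(0.05 + 0.2, n_invalid))
    make_pairs(rep(0.5, 10), by, rep(0.02, 10))
  }
  under <- weighted_median(shift(4), 200, seed = 13)  # 40% invalid weight
  over <- weighted_median(shift(6), 200, seed = 13)   # 60% invalid weight
  expect_equal(under$beta, 0.1, tolerance = 1e-9)
  expect_gt(over$beta, 0.3)  # escapes the valid-ratio range
})
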