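test_that("cumulative measure matches closed forms and quadrature", {
  expect_equal(cumulativeMeasure(rateSpec("constant", r0 = 1), 2), 2)
  expect_equal(cumulativeMeasure(rateSpec("constant", r0 = 3), 0), 0)
  # quadrature oracle for the singular power law r(t) = t^{-1/2}
  spec <- rateSpec("power_law", r0 = 1, gamma = -0.5)
  oracle <- integrate(function(x) x^(-0.5), 0, 1)$value
  expect_equal(cumulativeMeasure(spec, 1), oracle, tolerance = 1e-8)
  expect_equal(cumulativeMeasure(spec, 0), 0)
  # nondecreasing
  tt <- seq(0, 5, by = 0.1)
  expect_true(all(diff(cumulativeMeasure(spec, tt)) >= 0))
  expect_error(cumulativeMeasure(spec, -1), "nonnegative")
})

test_that("tabulated measures interpolate and invert exactly", {
  tb <- cbind(c(0, 1, 2, 4), c(0, 2, 2, 5))   # flat segment on [1, 2]
  spec <- rateSpec("tabulated", table = tb)
  expect_equal(cumulativeMeasure(spec, c(0.5, 1.5, 3)), c(1, 2, 3.5))
  # generalized inverse returns the leftmost time on the flat
  expect_equal(gcbranch:::inverseMeasure(spec, 2), 1)
  expect_equal(gcbranch:::inverseMeasure(spec, 3.5), 3)
})

test_that("arrival sampling is deterministic, empty at horizon 0, and has Poisson mean", {
  spec <- rateSpec("constant", r0 = 10)
  g <- c(0.3, 0.7)
  expect_equal(nrow(sampleArrivals(spec, g, 0, seed = 1)), 0)
  a1 <- sampleArrivals(spec, g, 50, seed = 42)
  a2 <- sampleArrivals(spec, g, 50, seed = 42)
  expect_identical(a1, a2)
  expect_true(all(diff(a1$time) >= 0))
  expect_identical(a1$clone_index, seq_len(nrow(a1)))
  # mean count over 200 replicates within 3 SE of R(50) = 500 (Var = mean)
  counts <- vapply(1:200, function(s)
    nrow(sampleArrivals(spec, g, 50, seed = s)), 0)
  expect_lt(abs(mean(counts) - 500), 3 * sqrt(500 / 200))
})

test_that("first-arrival law matches its closed forms", {
  fe <- firstArrivalLaw(rateSpec("constant", r0 = 1), gk = 0.5)
  expect_equal(fe$family, "exponential")
  expect_equal(fe$median, log(2) / 0.5)
  # gamma = 0 power law degenerates to the exponential branch
  fw0 <- firstArrivalLaw(rateSpec("power_law", r0 = 1, gamma = 0), gk = 0.5)
  expect_equal(fw0$shape, 1)
  expect_equal(fw0$median, fe$median)
  expect_equal(fw0$mean, fe$mean)
  # gamma = 1, gk * r0 = 2: Weibull(shape 2, scale 1); mean by quadrature
  fw <- firstArrivalLaw(rateSpec("power_law", r0 = 2, gamma = 1), gk = 1)
  expect_equal(fw$shape, 2)
  expect_equal(fw$scale, 1)
  dens <- function(t) 2 * t * exp(-t^2)            # f = r e^{-R}
  oracle <- integrate(function(t) t * dens(t), 0, Inf)$value
  expect_equal(fw$mean, oracle, tolerance = 1e-7)
  expect_equal(fw$mean, sqrt(pi) / 2, tolerance = 1e-12)
  expect_error(firstArrivalLaw(rateSpec("tabulated",
                                        table = cbind(c(0, 1), c(0, 1))),
                               gk = 0.5), "closed-form")
})

test_that("sampled first arrivals pass a KS test against the Weibull law", {
  spec <- rateSpec("power_law", r0 = 3, gamma = -0.5)
  gk <- 0.4
  fal <- firstArrivalLaw(spec, gk)
  # type-k stream has measure gk * R(t); first arrival = R^{-1}(E / gk)
  draws <- withr::with_seed(7, {
    gcbranch:::inverseMeasure(spec, rexp(1e5) / gk)
  })
  ks <- suppressWarnings(
    ks.test(draws, pweibull, shape = fal$shape, scale = fal$scale))
  expect_gt(ks$p.value, 0.001)
})

test_that("typed thinning is a superposition of independent typed streams", {
  # merged labeled stream vs independent streams with rates g_k r(t):
  # per-type count means within 3 SE of g_k R(horizon)
  spec <- rateSpec("power_law", r0 = 5, gamma = -0.5)
  g <- c(0.3, 0.7)
  R <- cumulativeMeasure(spec, 10)
  lab <- t(vapply(1:200, function(s)
    tabulate(sampleArrivals(spec, g, 10, seed = s)$type_index, 2), c(0, 0)))
  sep <- t(vapply(1:200, function(s) c(
    nrow(sampleArrivals(rateSpec("power_law", r0 = 5 * g[1], gamma = -0.5),
                        1, 10, seed = 1000 + s)),
    nrow(sampleArrivals(rateSpec("power_law", r0 = 5 * g[2], gamma = -0.5),
                        1, 10, seed = 2000 + s))), c(0, 0)))
  for (k in 1:2) {
    se <- sqrt(g[k] * R / 200)
    expect_lt(abs(mean(lab[, k]) - g[k] * R), 3 * se)
    expect_lt(abs(mean(sep[, k]) - g[k] * R), 3 * se)
  }
})

test_that("waiting-time ratio follows the power-law formula", {
  expect_equal(waitingTimeRatio(2, -1/2), 4)
  expect_equal(waitingTimeRatio(2, 0), 2)
  expect_equal(waitingTimeRatio(1, 0.7), 1)
  expect_error(waitingTimeRatio(2, -1), "gamma")
  expect_error(waitingTimeRatio(-1, 0), "positive")
})

test_that("race pmf is geometric with the right moments and tail", {
  expect_equal(racePmf(0.5, 0.5, 0), 0.5)
  # partial sums to 1e4 reach 1 within 1e-12 whenever p >= 0.01
  expect_equal(sum(racePmf(0.99, 0.01, 0:1e4)), 1, tolerance = 1e-12)
  expect_equal(sum(racePmf(0.3, 0.2, 0:1e4)), 1, tolerance = 1e-12)
  expect_error(racePmf(0.5, 0.5, -1), "nonnegative")
  # Monte-Carlo oracle: two independent thinned Poisson streams
  mc <- withr::with_seed(3, {
    T2 <- rexp(1e5, 0.25)
    rpois(1e5, 0.75 * T2)
  })
  expect_lt(abs(mean(mc) - raceMoments(0.75, 0.25)["mean"]),
            3 * sd(mc) / sqrt(1e5))
  # scaled race count tends to Exp(1) as the rare-set mass vanishes
  eps <- 1e-3
  mc2 <- withr::with_seed(4, {
    T2 <- rexp(1e5, eps)
    rpois(1e5, (1 - eps) * T2)
  })
  scaled <- eps * mc2
  ks <- suppressWarnings(ks.test(scaled, pexp, 1))
  expect_lt(ks$statistic, 0.02)
})
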