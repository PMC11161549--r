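test_that("clone fitness sampling matches the stated laws", {
  # p0 ~ U[0.35, 1]: P(supercritical) = 0.15/0.65 (checked at 1e5 draws here)
  fit <- sampleCloneFitness(fitnessLaw("uniform", 0.35, 1), 1e5, lambda = 1,
                            seed = 2)
  p <- 0.15 / 0.65
  expect_lt(abs(mean(fit$p2 > 0.5) - p), 3 * sqrt(p * (1 - p) / 1e5))
  # fixed p2 = 0.5: every clone critical
  f0 <- sampleCloneFitness(fitnessLaw("fixed", value = 0.5), 100, 1, seed = 1)
  expect_true(all(f0$alpha == 0))
  # p2 ~ U[0, 1] (p0 ~ U[0, 1]): P(alpha <= 0) = H(1/2) = 0.5
  f1 <- sampleCloneFitness(fitnessLaw("uniform", 0, 1), 1e5, 1, seed = 3)
  expect_lt(abs(mean(f1$alpha <= 0) - 0.5), 3 * sqrt(0.25 / 1e5))
  # alpha cdf consistency: P(alpha <= u) = H((lambda + u)/(2 lambda))
  u <- 0.2; lam <- 2
  f2 <- sampleCloneFitness(fitnessLaw("uniform", 0, 1), 1e5, lam, seed = 4)
  target <- (lam + u) / (2 * lam)
  expect_lt(abs(mean(f2$alpha <= u) - target),
            3 * sqrt(target * (1 - target) / 1e5))
})

test_that("mixture extinction probability uses the smallest-root formula", {
  # fixed p2 = 0.6 -> (1 - p2)/p2
  expect_equal(gcbranch:::mixtureExtinctionQ(fitnessLaw("fixed", value = 0.4)),
               2 / 3, tolerance = 1e-9)
  # uniform law: closed-form integral oracle
  law <- fitnessLaw("uniform", 0.35, 1)
  oracle <- (0.5 / 0.65) + (log(0.65 / 0.5) - 0.15) / 0.65
  expect_equal(gcbranch:::mixtureExtinctionQ(law), oracle, tolerance = 1e-8)
})

test_that("dominance trajectories keep fractions, bounds and dominants consistent", {
  tr <- simulateDominance(rateSpec("constant", r0 = 3),
                          fitnessLaw("uniform", 0.35, 1), lambda = 1,
                          horizon = 8, seed = 5)
  pr <- dominanceProfile(tr)
  tot <- rowSums(tr@sizes)
  on <- tot > 0
  # fractions sum to one whenever the GC is populated
  frac <- tr@sizes[on, , drop = FALSE] / tot[on]
  expect_equal(rowSums(frac), rep(1, sum(on)))
  expect_true(all(pr$simpson[on] >= 0 & pr$simpson[on] <= 1))
  expect_true(all(pr$invSimpson[on] >= 1))
  expect_true(all(is.na(pr$dominant[!on])))
  # richness never exceeds the number of arrived clones
  arrived <- vapply(pr$time, function(t) sum(tr@arrivalTimes <= t), 0)
  expect_true(all(pr$richness <= arrived))
  # brute-force argmax oracle at random grid times
  set.seed(31)
  for (t in sample(tr@times, 100, replace = TRUE)) {
    i <- which.min(abs(tr@times - t))
    z <- tr@sizes[i, ]
    expected <- if (all(z == 0)) NA_integer_ else
      min(which(z == max(z)))
    expect_identical(dominantClone(tr, t), expected)
  }
  expect_error(dominantClone(tr, 100), "horizon")
})

test_that("dominant-clone ties break to the earliest clone", {
  tr <- new("DominanceTrajectory", times = c(0, 1),
            sizes = rbind(c(0, 0, 0), c(0, 5, 5)),
            arrivalTimes = c(0.1, 0.2, 0.3), p2 = rep(0.6, 3),
            alpha = rep(0.2, 3), lambda = 1, truncated = rep(FALSE, 3))
  expect_identical(dominantClone(tr, 1), 2L)  # clones 2 and 3 tie -> 2
  expect_identical(dominantClone(tr, 0), NA_integer_)
})

test_that("turnover counting is monotone under grid refinement", {
  args <- list(spec = rateSpec("constant", r0 = 3),
               law = fitnessLaw("uniform", 0.35, 1), lambda = 1,
               horizon = 8, seed = 17)
  coarse <- do.call(simulateDominance, c(args, gridStep = 0.2))
  fine <- do.call(simulateDominance, c(args, gridStep = 0.1))
  expect_gte(turnoverCount(fine), turnoverCount(coarse))
  # a lone clone never turns over
  one <- new("DominanceTrajectory", times = 0:5,
             sizes = matrix(c(0, 1, 2, 4, 4, 8), 6, 1),
             arrivalTimes = 0.5, p2 = 0.7, alpha = 0.4, lambda = 1,
             truncated = FALSE)
  expect_equal(turnoverCount(one), 0L)
})

test_that("differential fitness destabilizes dominance relative to equal fitness", {
  lateTurnovers <- function(law, seed) {
    tr <- simulateDominance(rateSpec("constant", r0 = 3), law, lambda = 1,
                            horizon = 12, seed = seed, cap = 5e4)
    pr <- dominanceProfile(tr)
    half <- pr$dominant[pr$time >= 6]
    ok <- !is.na(half)
    d <- half[ok]
    if (length(d) < 2) 0L else sum(d[-1] != d[-length(d)])
  }
  het <- hom <- numeric(20)
  for (s in 1:20) {
    het[s] <- lateTurnovers(fitnessLaw("uniform", 0.35, 1), seed = s)
    hom[s] <- lateTurnovers(fitnessLaw("fixed", value = 0.3), seed = s)
  }
  expect_gte(median(het), median(hom))
})

test_that("equal-fitness GC Bray-Curtis approaches the clone-level limit", {
  # all clones share p2 = 0.7 (alpha = 0.4); BC_Y(t, t + 1) -> bc(1, 0.4)
  tr <- simulateDominance(rateSpec("constant", r0 = 3),
                          fitnessLaw("fixed", value = 0.3), lambda = 1,
                          horizon = 16, seed = 2, cap = 3e5)
  i1 <- which.min(abs(tr@times - 15))
  i2 <- which.min(abs(tr@times - 16))
  bc <- brayCurtis(tr@sizes[i1, ], tr@sizes[i2, ])
  expect_lt(abs(bc - bcLimit(1, 0.4)), 0.1)
})

test_that("expected clonal richness stays inside the extinction bracket", {
  # E(D0(t)) lies in [(1 - Q) R(t), R(t)]; near-critical clones keep the mean
  # well above the asymptotic slope at moderate horizons
  law <- fitnessLaw("uniform", 0.35, 1)
  Q <- gcbranch:::mixtureExtinctionQ(law)
  r0 <- 2; horizon <- 50
  rich <- numeric(15)
  for (r in 1:15) {
    arr <- sampleArrivals(rateSpec("constant", r0 = r0), "distinct", horizon,
                          seed = 100 + r)
    fit <- sampleCloneFitness(law, nrow(arr), 1, seed = 100 + r)
    alive <- 0
    for (k in seq_len(nrow(arr))) {
      m <- singleTypeModel(fit$p0[k], expLifespan(1))
      tr <- simulateClone(m, 1, horizon - arr$time[k], seed = 1000 * r + k,
                          cap = 5000)
      alive <- alive +
        (tr@truncated || sum(countsAt(tr, tr@horizon)) > 0)
    }
    rich[r] <- alive
  }
  R <- r0 * horizon
  se <- sd(rich) / sqrt(length(rich))
  expect_gt(mean(rich) + 3 * se, (1 - Q) * R)
  expect_lt(mean(rich) - 3 * se, R)
})
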