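test_that("mean matrix follows the offspring formula", {
  expect_equal(meanMatrix(singleTypeModel(0.4)), matrix(1.2, 1, 1))
  # diagonal (non-communicating clones) model: M = diag(2 (1 - p0^k))
  p0 <- c(0.2, 0.5, 0.8)
  off <- lapply(seq_along(p0), function(k) {
    q <- matrix(0, 3, 3); q[k, k] <- 1
    offspringLaw(p0[k], q)
  })
  m3 <- branchingModel(off, expLifespan(1), K = 3)
  expect_equal(meanMatrix(m3), diag(2 * (1 - p0)))
  # 2-type, q^1 concentrated on the pair (1, 2): enumeration oracle
  q1 <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  q2 <- matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE)
  m2 <- branchingModel(list(offspringLaw(0.3, q1), offspringLaw(0.3, q2)),
                       expLifespan(1), K = 2)
  # type 1 divides into exactly one type-1 and one type-2 daughter
  expect_equal(meanMatrix(m2)[1, ], c(0.7, 0.7))
})

test_that("M*(s) is the Laplace-discounted mean matrix", {
  m <- twoTypeModel(rate = 2)
  M <- meanMatrix(m)
  expect_equal(mstarMatrix(m, 0), M)
  s <- 0.7
  expect_equal(mstarMatrix(m, s), 2 / (2 + s) * M)
  # entries nonincreasing in s >= 0
  grid <- seq(0, 3, by = 0.5)
  vals <- sapply(grid, function(x) mstarMatrix(m, x)[1, 2])
  expect_true(all(diff(vals) <= 0))
  expect_error(mstarMatrix(m, -2.5), "abscissa")
})

test_that("malthusian recovers closed-form growth rates", {
  # single type, exponential(1/24), p2 = 0.6 => alpha = (2 p2 - 1) lambda
  mr <- malthusian(singleTypeModel(0.4, expLifespan(1 / 24)))
  expect_equal(mr@alpha, 1 / 120, tolerance = 1e-8)
  expect_equal(mr@criticality, "super")
  # normalizations
  expect_equal(sum(mr@u), 1, tolerance = 1e-10)
  expect_equal(sum(mr@u * mr@v), 1, tolerance = 1e-10)
  # critical
  mc <- malthusian(singleTypeModel(0.5, expLifespan(1)))
  expect_equal(mc@alpha, 0, tolerance = 1e-10)
  expect_equal(mc@criticality, "critical")
  # subcritical single type: alpha = (2 p2 - 1) lambda < 0
  ms <- malthusian(singleTypeModel(0.7, expLifespan(2)))
  expect_equal(ms@alpha, (2 * 0.3 - 1) * 2, tolerance = 1e-8)
  expect_equal(ms@criticality, "sub")
  # type-independent p0, exponential(1), row-stochastic kernel:
  # alpha = G^{*,-1}(1 / (2 (1 - p0))) = 2(1 - p0) - 1
  expect_equal(malthusian(twoTypeModel(p0 = 0.4))@alpha, 0.2,
               tolerance = 1e-8)
  # closed-form grid p2 x lambda
  for (p2 in seq(0.55, 0.95, by = 0.1)) for (lam in c(0.1, 1, 10)) {
    mr <- malthusian(singleTypeModel(1 - p2, expLifespan(lam)))
    expect_equal(mr@alpha, (2 * p2 - 1) * lam, tolerance = 1e-8)
  }
})

test_that("malthusian refuses reducible models", {
  # type 2 only produces type 2: the pattern is reducible
  q1 <- matrix(c(0.5, 0.5, 0, 0), 2, 2, byrow = TRUE)
  q2 <- matrix(c(0, 0, 0, 1), 2, 2, byrow = TRUE)
  m <- branchingModel(list(offspringLaw(0.3, q1), offspringLaw(0.3, q2)),
                      expLifespan(1), K = 2)
  expect_error(malthusian(m), "reducible")
})

test_that("Perron root agrees with a power-iteration oracle on K up to 50", {
  set.seed(21)
  for (K in c(5, 20, 50)) {
    A <- matrix(runif(K * K, 0.01, 1), K, K)
    x <- rep(1, K)
    for (i in 1:500) { x <- A %*% x; x <- x / sum(x) }
    lam <- sum(A %*% x) / sum(x)
    expect_equal(gcbranch:::perronRoot(A), lam, tolerance = 1e-10)
  }
})

test_that("extinction probabilities solve the smallest-root equation", {
  expect_equal(extinctionProbability(singleTypeModel(0.4)), 2 / 3,
               tolerance = 1e-10)
  expect_equal(extinctionProbability(singleTypeModel(0.5)), 1)
  expect_equal(extinctionProbability(singleTypeModel(0.6)), 1)
  expect_equal(extinctionProbability(singleTypeModel(0)), 0)
  # empirical extinction fraction over 3000 clones at a horizon long enough
  # for the extinction probability to have converged (~25 mean lifespans)
  m <- singleTypeModel(0.4, expLifespan(1))
  ext <- vapply(1:3000, function(s) {
    tr <- simulateClone(m, 1, 25, seed = s, cap = 3000)
    !tr@truncated && sum(countsAt(tr, 25)) == 0
  }, TRUE)
  q <- 2 / 3
  expect_lt(abs(mean(ext) - q), 3 * sqrt(q * (1 - q) / 3000))
})

test_that("stationary composition equals the left Perron eigenvector", {
  # symmetric two-type model: (0.5, 0.5) by symmetry
  q <- matrix(c(0.25, 0.5, 0, 0.25), 2, 2, byrow = TRUE)
  msym <- branchingModel(list(offspringLaw(0.3, q), offspringLaw(0.3, q)),
                         expLifespan(1), K = 2)
  expect_equal(stationaryComposition(msym), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(stationaryComposition(singleTypeModel(0.2)), 1)
  expect_error(stationaryComposition(singleTypeModel(0.5)), "supercritical")
  # simulation oracle: long-run type frequencies of a surviving clone
  m <- twoTypeModel()
  v <- stationaryComposition(m)
  tr <- surviveClone(m, 22, minCells = 500)
  z <- as.numeric(countsAt(tr, 22))
  expect_lt(max(abs(z / sum(z) - v)), 0.02)
})
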