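test_that("sequence partitioning matches per-position comparison", {
  p <- partitionFromSequences("AKV", "ARV")
  expect_equal(c(p@L, p@L1, p@L2), c(3, 2, 1))
  expect_equal(p@V1, c(1L, 3L))
  expect_equal(p@V2, 2L)
  expect_equal(partitionFromSequences("AKV", "AKV")@L2, 0)
  expect_equal(partitionFromSequences("AAA", "CCC")@L1, 0)
  expect_error(partitionFromSequences("AKV", "AK"), "equal length")
  expect_error(partitionFromSequences("AK-", "AKV"), "position 3")
})

test_that("BCR classification assigns each position to one compartment", {
  p <- partitionFromSequences("AKV", "ARV")
  # unmutated: state (L1, 0, L2, 0, 0)
  cg <- classifyBcr(p, "AKV", "ARV", "AKV")
  expect_equal(unname(cg$state), c(2, 0, 1, 0, 0))
  expect_equal(c(cg$N, cg$Delta), c(0, 0))
  # perfect convergence to the bnAb
  cb <- classifyBcr(p, "AKV", "ARV", "ARV")
  expect_equal(unname(cb$state), c(2, 0, 0, 1, 0))
  expect_equal(c(cb$N, cb$Delta), c(1, 1))
  # mutate one V1 position away from both references
  cm <- classifyBcr(p, "AKV", "ARV", "CKV")
  expect_equal(unname(cm$state), c(1, 1, 1, 0, 0))
  expect_equal(c(cm$N, cm$Delta), c(1, -1))
  # a V2 mutation matching neither sequence
  c3 <- classifyBcr(p, "AKV", "ARV", "AWV")
  expect_equal(unname(c3$state), c(2, 0, 0, 0, 1))
  expect_equal(c(c3$N, c3$Delta), c(1, 0))
})

test_that("single-position mutations move the state by one kernel increment", {
  fx <- generateFixture(8, 5, nBcr = 0, seed = 3)
  g <- fx$sequences[["germline"]]; b <- fx$sequences[["bnab"]]
  p <- partitionFromSequences(g, b)
  inc <- gcbranch:::.driftIncrements
  aa <- gcbranch:::.AA
  set.seed(5)
  for (i in 1:40) {
    pos <- sample(p@L, 1)
    s0chars <- strsplit(g, "")[[1]]
    # random starting BCR a few mutations in
    for (pp in sample(p@L, 3)) s0chars[pp] <- sample(aa, 1)
    s1chars <- s0chars
    s1chars[pos] <- sample(aa, 1)
    st0 <- classifyBcr(p, g, b, paste(s0chars, collapse = ""))$state
    st1 <- classifyBcr(p, g, b, paste(s1chars, collapse = ""))$state
    d <- st1 - st0
    match <- apply(inc, 1, function(e) all(e == d))
    expect_true(any(match))
  }
})

test_that("case distribution normalizes and matches the V2 mass formula", {
  p <- toyPartition(57, 41)
  cd <- caseDistribution(germlineState(p), p, driftKernel(rho1 = 1))
  expect_equal(unname(cd$conditional["pi2"]), 41 / 98, tolerance = 1e-12)
  expect_equal(sum(cd$probs), 1, tolerance = 1e-12)
  # at the germline state the cases needing prior mutations (a reversion in
  # V1, or any move out of the empty l22/l23 compartments) are impossible
  expect_equal(unname(cd$probs[c("1.2", "2.3", "2.4", "2.5", "2.6")]),
               rep(0, 5))
  expect_true(all(cd$probs[c("1.1", "1.3", "2.1", "2.2", "2.7")] > 0))
  # l11 = 0: case 1.1 structurally impossible
  pz <- toyPartition(2, 2)
  cd0 <- caseDistribution(mutationState(0, 2, 2, 0, 0, pz), pz, driftKernel())
  expect_equal(unname(cd0$probs["1.1"]), 0)
  # l12 = 0 with rho11 < 1: impossible reversion mass folds into case 1.3
  cdf <- caseDistribution(mutationState(2, 0, 2, 0, 0, pz), pz,
                          driftKernel(rho11 = 0.5))
  expect_equal(unname(cdf$probs["1.2"]), 0)
  expect_gt(unname(cdf$probs["1.3"]), 0)
  # property: normalization across random states and kernels
  set.seed(9)
  for (i in 1:25) {
    l11 <- sample(0:2, 1); l21 <- sample(0:2, 1)
    l22 <- sample(0:(2 - l21), 1)
    st <- mutationState(l11, 2 - l11, l21, l22, 2 - l21 - l22, pz)
    kern <- driftKernel(piTilde = runif(1, 0, 0.5),
                        sigma11 = runif(1, 0, 2), sigma21 = runif(1, 0, 2))
    cdr <- caseDistribution(st, pz, kern)
    expect_equal(sum(cdr$probs), 1, tolerance = 1e-12)
    expect_true(all(cdr$probs >= 0))
  }
  # an over-biased kernel implies a negative rho3|2 -> validation error
  expect_error(
    caseDistribution(mutationState(2, 0, 1, 1, 0, pz), pz,
                     driftKernel(rho12 = 1.5, rho22 = 1.5)),
    "rho3\\|2")
})

test_that("one-step transitions follow the case distribution", {
  p <- toyPartition(2, 2)
  st <- mutationState(1, 1, 1, 1, 0, p)
  # no mutation probability: state always unchanged
  k0 <- driftKernel(piTilde = 0)
  for (s in 1:5) expect_equal(stepState(st, p, k0, seed = s), st)
  # empirical one-step frequencies vs the distribution (2e4 draws, 3 SE)
  kern <- driftKernel(piTilde = 0.5)
  cd <- caseDistribution(st, p, kern)
  draws <- vapply(1:20000, function(s)
    paste(stepState(st, p, kern, seed = s), collapse = ","), "")
  targets <- apply(cd$increments, 1, function(e)
    paste(st + e, collapse = ","))
  for (lbl in unique(targets)) {
    pr <- sum(cd$probs[targets == lbl])
    obs <- mean(draws == lbl)
    expect_lt(abs(obs - pr), 3 * sqrt(pr * (1 - pr) / 20000) + 1e-12)
  }
})

test_that("drift simulation conserves compartment totals and tracks rho1", {
  p <- toyPartition(6, 4)
  # piTilde = 0: every live cell stays in the germline state
  pop0 <- simulateDrift(0.3, expLifespan(1), p, driftKernel(piTilde = 0),
                        horizon = 6, seed = 2)
  expect_true(all(pop0$states[, 1] == 6 & pop0$states[, 3] == 4))
  # conservation audit on a mutating population
  pop <- simulateDrift(0.4, expLifespan(1), p, driftKernel(), horizon = 12,
                       seed = 3)
  expect_true(all(pop$states[, 1] + pop$states[, 2] == 6))
  expect_true(all(pop$states[, 3] + pop$states[, 4] + pop$states[, 5] == 4))
  expect_true(all(pop$N == pop$states[, 2] + pop$states[, 4] + pop$states[, 5]))
  expect_true(all(pop$Delta == pop$states[, 4] - pop$states[, 2]))
  expect_true(all(abs(pop$Delta) <= pop$N))
})

test_that("the repertoire drifts away from the bnAb faster as rho1 grows", {
  p <- toyPartition(6, 4)
  meanDelta <- function(rho1) {
    acc <- n <- 0
    for (s in 1:20) {
      pop <- simulateDrift(0.4, expLifespan(1), p, driftKernel(rho1 = rho1),
                           horizon = 25, seed = s, cap = 1e5)
      acc <- acc + sum(pop$Delta); n <- n + length(pop$Delta)
    }
    acc / n
  }
  md <- vapply(c(0.1, 0.5, 1.0), meanDelta, 0)
  expect_lt(md[3], 0)                 # net drift away from the bnAb
  expect_true(all(diff(md) < 0))      # decreasing in rho1
})

test_that("state-space enumeration is complete and duplicate-free", {
  p <- toyPartition(3, 2)
  ss <- enumerateStateSpace(p)
  expect_equal(nrow(ss), 4 * choose(4, 2))  # (L1+1) * C(L2+2, 2) = 24
  expect_equal(anyDuplicated(ss), 0)
  expect_true(all(ss[, 1] + ss[, 2] == 3))
  expect_true(all(ss[, 3] + ss[, 4] + ss[, 5] == 2))
  expect_equal(nrow(enumerateStateSpace(toyPartition(0, 0))), 1)
  expect_error(enumerateStateSpace(toyPartition(400, 400)), "too large")
})

test_that("stationary drift composition solves the eigenproblem", {
  p <- toyPartition(2, 2)
  sc <- stationaryCompositionDrift(p, driftKernel(), 0.4, expLifespan(1))
  expect_true(all(abs(rowSums(sc$Q) - 1) < 1e-12))
  expect_equal(sc$alpha, 0.2, tolerance = 1e-10)
  expect_equal(sum(sc$freq), 1, tolerance = 1e-10)
  # left-eigenvector property: freq' Q = freq'
  expect_lt(max(abs(as.numeric(sc$freq %*% sc$Q) - sc$freq)), 1e-10)
  expect_error(stationaryCompositionDrift(p, driftKernel(), 0.5,
                                          expLifespan(1)), "p0 < 1/2")
  # alpha via the gamma-lifespan Laplace inverse
  sg <- stationaryCompositionDrift(p, driftKernel(), 0.4, gammaLifespan(2, 0.5))
  expect_equal((1 + 0.5 * sg$alpha)^(-2), 1 / 1.2, tolerance = 1e-10)
})

test_that("with rho = 1 the V1 margin is a birth-death chain", {
  # the V1 compartment decouples when rho1 = rho11 = 1: its l11-marginal is a
  # birth-death chain with down rate ~ l11/(1+sigma11) and up rate
  # ~ (1 - l11/L1)/(1+sigma21); compare its product-form stationary law with
  # the dense eigenvector marginal
  p <- toyPartition(3, 2)
  kern <- driftKernel()
  sc <- stationaryCompositionDrift(p, kern, 0.4, expLifespan(1))
  marg <- vapply(0:3, function(l)
    sum(sc$freq[sc$states[, 1] == l]), 0)
  L1 <- 3
  dn <- function(l) (l / L1) / (1 + kern@sigma11)
  up <- function(l) (1 - l / L1) / (1 + kern@sigma21)
  piBD <- numeric(L1 + 1); piBD[1] <- 1
  for (l in 1:L1) piBD[l + 1] <- piBD[l] * up(l - 1) / dn(l)
  piBD <- piBD / sum(piBD)
  expect_lt(max(abs(marg - piBD)), 1e-8)
})
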