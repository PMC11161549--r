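## ---------------------------------------------------------------------------
## Convergent evolution of BCRs relative to a germline / bnAb pair:
## V-segment partition, 5-compartment mutation-count states, the 10-case
## per-division mutation kernel, and the induced branching process.
## ---------------------------------------------------------------------------

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.checkAASeq <- function(x, what = "sequence") {
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% .AA)
  if (length(bad))
    stop(sprintf("%s contains non-amino-acid character '%s' at position %d",
                 what, chars[bad[1]], bad[1]))
  chars
}

#' Partition a V segment relative to a germline/bnAb pair
#'
#' Splits the aligned amino-acid positions into V1 (germline and bnAb
#' identical) and V2 (they differ).  Sequences must be equal-length, gap-free
#' amino-acid strings.
#'
#' @param germline,bnab amino-acid strings of equal length.
#' @return A \linkS4class{SegmentPartition}.
#' @examples
#' partitionFromSequences("AKV", "ARV")  # L1 = 2, L2 = 1
#' @export
partitionFromSequences <- function(germline, bnab) {
  g <- .checkAASeq(toupper(germline), "germline")
  b <- .checkAASeq(toupper(bnab), "bnab")
  if (length(g) != length(b))
    stop("germline and bnab sequences must have equal length")
  V1 <- which(g == b)
  V2 <- which(g != b)
  new("SegmentPartition", L = length(g), L1 = length(V1), L2 = length(V2),
      V1 = as.integer(V1), V2 = as.integer(V2))
}

#' Mutation-count state constructor
#'
#' A state is the 5-vector (l11, l12, l21, l22, l23): within V1 the numbers
#' of unmutated and mutated-away positions; within V2 the numbers matching
#' the germline, matching the bnAb, and matching neither.  States must
#' satisfy l11 + l12 = L1 and l21 + l22 + l23 = L2.
#'
#' @param l11,l12,l21,l22,l23 nonnegative position counts.
#' @param partition optional \linkS4class{SegmentPartition} to validate
#'   against.
#' @return Named integer vector of length 5.
#' @export
mutationState <- function(l11, l12, l21, l22, l23, partition = NULL) {
  s <- as.integer(c(l11 = l11, l12 = l12, l21 = l21, l22 = l22, l23 = l23))
  names(s) <- c("l11", "l12", "l21", "l22", "l23")
  if (any(s < 0)) stop("state counts must be nonnegative")
  if (!is.null(partition)) {
    if (s[1] + s[2] != partition@L1)
      stop("l11 + l12 must equal L1 = ", partition@L1)
    if (s[3] + s[4] + s[5] != partition@L2)
      stop("l21 + l22 + l23 must equal L2 = ", partition@L2)
  }
  s
}

#' @describeIn mutationState unmutated (germline) state (L1, 0, L2, 0, 0).
#' @export
germlineState <- function(partition) {
  mutationState(partition@L1, 0L, partition@L2, 0L, 0L, partition)
}

#' Classify a BCR sequence against a germline/bnAb pair
#'
#' Assigns every aligned position to exactly one of the five compartments
#' and returns the mutation-count state together with the total mutation
#' count \eqn{N = l_{12} + l_{22} + l_{23}} and the net mutational gain
#' toward the bnAb \eqn{\Delta = l_{22} - l_{12}}.
#'
#' @param partition a \linkS4class{SegmentPartition} for the pair.
#' @param germline,bnab,bcr aligned amino-acid strings of equal length.
#' @return list with \code{state}, \code{N}, \code{Delta}.
#' @examples
#' p <- partitionFromSequences("AKV", "ARV")
#' classifyBcr(p, "AKV", "ARV", "ARV")  # N = 1, Delta = +1
#' @export
classifyBcr <- function(partition, germline, bnab, bcr) {
  g <- .checkAASeq(toupper(germline), "germline")
  b <- .checkAASeq(toupper(bnab), "bnab")
  s <- .checkAASeq(toupper(bcr), "bcr")
  if (length(s) != partition@L || length(g) != partition@L ||
      length(b) != partition@L)
    stop("all sequences must have length L = ", partition@L)
  V1 <- partition@V1; V2 <- partition@V2
  l11 <- sum(s[V1] == g[V1])
  l12 <- partition@L1 - l11
  l21 <- sum(s[V2] == g[V2])
  l22 <- sum(s[V2] == b[V2])
  l23 <- partition@L2 - l21 - l22
  st <- mutationState(l11, l12, l21, l22, l23, partition)
  list(state = st, N = unname(st[2] + st[4] + st[5]),
       Delta = unname(st[4] - st[2]))
}

## The 11 outcome labels and their increment vectors (rows).  "none" is the
## no-mutation outcome; cases 1.3 and 2.7 are mutations that leave the state
## unchanged (synonymous or not altering compartment membership).
.driftIncrements <- local({
  inc <- rbind(
    none    = c(0, 0, 0, 0, 0),
    "1.1"   = c(-1, 1, 0, 0, 0),
    "1.2"   = c(1, -1, 0, 0, 0),
    "1.3"   = c(0, 0, 0, 0, 0),
    "2.1"   = c(0, 0, -1, 1, 0),
    "2.2"   = c(0, 0, -1, 0, 1),
    "2.3"   = c(0, 0, 1, -1, 0),
    "2.4"   = c(0, 0, 0, -1, 1),
    "2.5"   = c(0, 0, 1, 0, -1),
    "2.6"   = c(0, 0, 0, 1, -1),
    "2.7"   = c(0, 0, 0, 0, 0))
  colnames(inc) <- c("l11", "l12", "l21", "l22", "l23")
  inc
})

#' Per-division mutation-case distribution
#'
#' Probability of each of the 11 division outcomes for a cell in the given
#' mutation-count state: no mutation (probability \code{1 - piTilde}) plus
#' the 10 mutation cases.  Conditional on a mutation, it lands in V1 with
#' probability \eqn{\pi_1 = \rho_1 L_1 / L} and in V2 otherwise; within each
#' compartment the target sub-compartment is chosen proportionally to its
#' current size (modulated by the rho coefficients) and the outcome of the
#' mutation is split by the sigma odds.  Cases whose source compartment is
#' empty are structurally impossible: their mass is folded into the
#' corresponding no-change case (1.3 or 2.7).
#'
#' @param state mutation-count state (see \code{\link{mutationState}}).
#' @param partition a \linkS4class{SegmentPartition}.
#' @param params a \linkS4class{DriftKernel}.
#' @return list with \code{probs} (named length-11 vector summing to 1),
#'   \code{increments} (11 x 5 matrix) and \code{conditional} =
#'   c(pi1, pi2), the compartment probabilities given a mutation.
#' @examples
#' p <- toyPartition(57, 41)
#' cd <- caseDistribution(germlineState(p), p, driftKernel(rho1 = 1))
#' cd$conditional["pi2"]  # 41/98
#' @export
caseDistribution <- function(state, partition, params) {
  stopifnot(is(partition, "SegmentPartition"), is(params, "DriftKernel"))
  state <- mutationState(state[1], state[2], state[3], state[4], state[5],
                         partition)
  L <- partition@L; L1 <- partition@L1; L2 <- partition@L2
  l11 <- state[1]; l12 <- state[2]
  l21 <- state[3]; l22 <- state[4]; l23 <- state[5]

  pi1 <- if (L1 > 0) params@rho1 * L1 / L else 0
  if (pi1 > 1 + 1e-12)
    stop("invalid kernel: rho1 * L1 / L exceeds 1")
  pi1 <- min(pi1, 1)
  pi2 <- 1 - pi1

  # --- V1 split (conditional on a mutation in V1)
  if (L1 > 0) {
    w11 <- params@rho11 * l11 / L1
    if (w11 > 1 + 1e-12)
      stop("invalid kernel at state (", paste(state, collapse = ","),
           "): rho11 * l11 / L1 exceeds 1")
    p11 <- w11 / (1 + params@sigma11)
    p12 <- (1 - w11) / (1 + params@sigma21)
    if (l12 == 0) p12 <- 0          # impossible case folded into 1.3
    p13 <- 1 - p11 - p12
  } else {
    p11 <- p12 <- p13 <- 0
  }

  # --- V2 split (conditional on a mutation in V2)
  if (L2 > 0) {
    w21 <- params@rho12 * l21 / L2
    w22 <- params@rho22 * l22 / L2
    rho32 <- if (l23 > 0) (L2 / l23) * (1 - w21 - w22) else 0
    if (rho32 < -1e-12 || w21 + w22 > 1 + 1e-12)
      stop("invalid kernel at state (", paste(state, collapse = ","),
           "): implied rho3|2 is negative")
    w23 <- rho32 * l23 / L2
    d1 <- 1 + params@sigma12_2 + params@sigma13_2
    d2 <- 1 + params@sigma21_2 + params@sigma23_2
    d3 <- 1 + params@sigma31_2 + params@sigma32_2
    p21 <- w21 * params@sigma12_2 / d1
    p22 <- w21 * params@sigma13_2 / d1
    p23 <- w22 * params@sigma21_2 / d2
    p24 <- w22 * params@sigma23_2 / d2
    p25 <- w23 * params@sigma31_2 / d3
    p26 <- w23 * params@sigma32_2 / d3
    p27 <- 1 - (p21 + p22 + p23 + p24 + p25 + p26)
  } else {
    p21 <- p22 <- p23 <- p24 <- p25 <- p26 <- p27 <- 0
  }

  pt <- params@piTilde
  probs <- as.numeric(c(1 - pt,
                        pt * pi1 * p11, pt * pi1 * p12, pt * pi1 * p13,
                        pt * pi2 * p21, pt * pi2 * p22, pt * pi2 * p23,
                        pt * pi2 * p24, pt * pi2 * p25, pt * pi2 * p26,
                        pt * pi2 * p27))
  names(probs) <- rownames(.driftIncrements)
  stopifnot(all(probs > -1e-12), abs(sum(probs) - 1) < 1e-12)
  probs <- pmax(probs, 0)
  list(probs = probs, increments = .driftIncrements,
       conditional = c(pi1 = unname(pi1), pi2 = unname(pi2)))
}

#' Draw one division step of the mutation kernel
#'
#' Samples one of the 11 outcomes from \code{\link{caseDistribution}} and
#' applies its increment; conservation of L1 and L2 holds by construction.
#'
#' @inheritParams caseDistribution
#' @param seed integer root seed.
#' @return The post-division mutation-count state.
#' @export
stepState <- function(state, partition, params, seed) {
  cd <- caseDistribution(state, partition, params)
  i <- withSeed(substreamSeed(seed, "stepState"),
                sample.int(length(cd$probs), 1L, prob = cd$probs))
  mutationState(state[1] + cd$increments[i, 1],
                state[2] + cd$increments[i, 2],
                state[3] + cd$increments[i, 3],
                state[4] + cd$increments[i, 4],
                state[5] + cd$increments[i, 5], partition)
}

#' Simulate intra-clonal mutational drift
#'
#' Age-dependent branching process on mutation-count states: every cell has
#' the same death probability \code{p0} and lifespan law; at division, with
#' probability piTilde a single mutation occurs (one of the 10 cases) and
#' both daughters inherit the mother's post-mutation state.  The clone
#' starts from one cell in \code{founderState} (the unmutated germline state
#' by default).
#'
#' @param p0 death probability, in [0, 1).
#' @param lifespan a \linkS4class{LifespanLaw} shared by all cells.
#' @param partition a \linkS4class{SegmentPartition}.
#' @param params a \linkS4class{DriftKernel}.
#' @param horizon simulation end time.
#' @param seed integer root seed.
#' @param cap live-cell cap (overflow flags the trajectory truncated).
#' @param founderState starting state (default \code{germlineState}).
#' @return list with \code{states} (live cells x 5 matrix at the horizon),
#'   \code{N}, \code{Delta} (per live cell), \code{nCells} (total ever
#'   born), \code{truncated}, \code{truncatedAt}.
#' @examples
#' p <- toyPartition(6, 4)
#' pop <- simulateDrift(0.4, expLifespan(1), p, driftKernel(), horizon = 6,
#'                      seed = 1)
#' table(pop$Delta)
#' @export
simulateDrift <- function(p0, lifespan, partition, params, horizon, seed,
                          cap = 1e6, founderState = germlineState(partition)) {
  stopifnot(p0 >= 0, p0 < 1, is(lifespan, "LifespanLaw"), horizon >= 0)
  founderState <- mutationState(founderState[1], founderState[2],
                                founderState[3], founderState[4],
                                founderState[5], partition)
  cache <- new.env(parent = emptyenv())   # case distribution per state
  getDist <- function(st) {
    key <- paste(st, collapse = ",")
    cd <- cache[[key]]
    if (is.null(cd)) {
      cd <- caseDistribution(st, partition, params)
      cache[[key]] <- cd
    }
    cd
  }

  withSeed(substreamSeed(seed, "simulateDrift"), {
    nAlloc <- 256L
    stateM <- matrix(0L, nAlloc, 5L)
    birth <- numeric(nAlloc); endt <- numeric(nAlloc)
    fate <- character(nAlloc)
    n <- 1L
    stateM[1, ] <- founderState
    birth[1] <- 0; endt[1] <- sampleLifespan(lifespan, 1)
    fate[1] <- "alive"

    heapT <- numeric(64L); heapI <- integer(64L); hn <- 0L
    hless <- function(a, b) heapT[a] < heapT[b] ||
      (heapT[a] == heapT[b] && heapI[a] < heapI[b])
    hpush <- function(tm, id) {
      hn <<- hn + 1L
      if (hn > length(heapT)) {
        heapT <<- c(heapT, numeric(length(heapT)))
        heapI <<- c(heapI, integer(length(heapI)))
      }
      heapT[hn] <<- tm; heapI[hn] <<- id
      j <- hn
      while (j > 1L) {
        p <- j %/% 2L
        if (hless(j, p)) {
          tt <- heapT[p]; heapT[p] <<- heapT[j]; heapT[j] <<- tt
          ii <- heapI[p]; heapI[p] <<- heapI[j]; heapI[j] <<- ii
          j <- p
        } else break
      }
    }
    hpop <- function() {
      out <- c(heapT[1], heapI[1])
      heapT[1] <<- heapT[hn]; heapI[1] <<- heapI[hn]; hn <<- hn - 1L
      j <- 1L
      repeat {
        l <- 2L * j; r <- l + 1L; s <- j
        if (l <= hn && hless(l, s)) s <- l
        if (r <= hn && hless(r, s)) s <- r
        if (s == j) break
        tt <- heapT[s]; heapT[s] <<- heapT[j]; heapT[j] <<- tt
        ii <- heapI[s]; heapI[s] <<- heapI[j]; heapI[j] <<- ii
        j <- s
      }
      out
    }
    grow <- function(m) {
      while (n + m > nrow(stateM)) {
        stateM <<- rbind(stateM, matrix(0L, nrow(stateM), 5L))
        birth <<- c(birth, numeric(length(birth)))
        endt <<- c(endt, numeric(length(endt)))
        fate <<- c(fate, character(length(fate)))
      }
    }

    hpush(endt[1], 1L)
    alive <- 1L
    truncated <- FALSE
    truncatedAt <- Inf
    while (hn > 0L) {
      ev <- hpop()
      tm <- ev[1]; i <- as.integer(ev[2])
      if (tm > horizon) break
      if (stats::runif(1) < p0) {
        fate[i] <- "died"
        alive <- alive - 1L
      } else {
        fate[i] <- "divided"
        st <- stateM[i, ]
        cd <- getDist(st)
        j <- sample.int(11L, 1L, prob = cd$probs)
        newSt <- st + cd$increments[j, ]
        grow(2L)
        for (d in 1:2) {
          n <- n + 1L
          stateM[n, ] <- newSt
          birth[n] <- tm
          endt[n] <- tm + sampleLifespan(lifespan, 1)
          fate[n] <- "alive"
          hpush(endt[n], n)
        }
        alive <- alive + 1L
        if (alive > cap) {
          truncated <- TRUE
          truncatedAt <- tm
          break
        }
      }
    }
    live <- which(fate[seq_len(n)] == "alive")
    states <- stateM[live, , drop = FALSE]
    colnames(states) <- c("l11", "l12", "l21", "l22", "l23")
    list(states = states,
         N = states[, 2] + states[, 4] + states[, 5],
         Delta = states[, 4] - states[, 2],
         nCells = n, truncated = truncated, truncatedAt = truncatedAt)
  })
}

#' Enumerate the mutation-count state space
#'
#' All states (l11, l12, l21, l22, l23) with l11 + l12 = L1 and
#' l21 + l22 + l23 = L2, in lexicographic order; there are
#' (L1 + 1)(L2 + 1)(L2 + 2)/2 of them.
#'
#' @param partition a \linkS4class{SegmentPartition}.
#' @return Integer matrix, one state per row.
#' @export
enumerateStateSpace <- function(partition) {
  L1 <- partition@L1; L2 <- partition@L2
  nStates <- (L1 + 1) * (L2 + 1) * (L2 + 2) / 2
  if (nStates > 1e5)
    stop("state space too large to enumerate (", nStates, " states)")
  out <- matrix(0L, nStates, 5L,
                dimnames = list(NULL, c("l11", "l12", "l21", "l22", "l23")))
  r <- 0L
  for (l11 in 0:L1) for (l21 in 0:L2) for (l22 in 0:(L2 - l21)) {
    r <- r + 1L
    out[r, ] <- c(l11, L1 - l11, l21, l22, L2 - l21 - l22)
  }
  out
}

#' Stationary mutation composition and growth rate of a drifting clone
#'
#' Builds the dense one-step state-transition matrix Q from the mutation
#' kernel (row-stochastic over the enumerated state space), returns its left
#' eigenvector for eigenvalue 1 normalized to frequencies, and the
#' Malthusian parameter \eqn{\alpha = G^{*,-1}(1/(2(1-p_0)))} implied by the
#' type-independent death probability and lifespan law (requires
#' \eqn{p_0 < 1/2}).  Conditional on survival, the per-cell mutation
#' compartment counts of an expanding clone settle on these frequencies.
#'
#' @inheritParams simulateDrift
#' @return list with \code{alpha}, \code{states} (enumerated matrix),
#'   \code{freq} (stationary frequencies summing to 1) and \code{Q}.
#' @export
stationaryCompositionDrift <- function(partition, params, p0, lifespan) {
  if (p0 >= 0.5)
    stop("stationary composition requires a supercritical clone (p0 < 1/2)")
  states <- enumerateStateSpace(partition)
  nS <- nrow(states)
  key <- apply(states, 1, paste, collapse = ",")
  lookup <- stats::setNames(seq_len(nS), key)
  Q <- matrix(0, nS, nS)
  for (i in seq_len(nS)) {
    cd <- caseDistribution(states[i, ], partition, params)
    tgt <- sweep(cd$increments, 2, -as.numeric(states[i, ]), "-")  # state+inc
    tk <- apply(tgt, 1, paste, collapse = ",")
    jj <- lookup[tk]
    for (m in seq_along(jj)) Q[i, jj[m]] <- Q[i, jj[m]] + cd$probs[m]
  }
  stopifnot(all(abs(rowSums(Q) - 1) < 1e-10))
  if (!isIrreducible(Q))
    stop("mutation kernel is reducible on this state space")
  ev <- eigen(t(Q))
  iu <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, iu])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-8)) stop("stationary eigenvector not nonnegative")
  v <- pmax(v, 0)
  list(alpha = lifespanLaplaceInverse(lifespan, 1 / (2 * (1 - p0))),
       states = states, freq = v / sum(v), Q = Q)
}
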