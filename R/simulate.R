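## ---------------------------------------------------------------------------
## Event-driven simulation of the multitype age-dependent branching process
## ---------------------------------------------------------------------------

## Core single-clone simulator.  Events (end of a cell's lifespan) are
## processed in time order, ties broken by cell id (birth order), so a given
## RNG substream always yields the same log.  All random draws happen in
## event order: fate, then the daughter type pair, then the two daughter
## lifespans.
.simClone <- function(model, founderType, horizon, streamSeed, cap = 1e6) {
  K <- model@K
  p0 <- vapply(model@offspring, function(o) o@p0, 0)
  # flatten each type's unordered-pair law for fast sampling
  pairIdx <- vector("list", K)
  pairProb <- vector("list", K)
  for (k in seq_len(K)) {
    q <- model@offspring[[k]]@pairProbs
    keep <- which(upper.tri(q, diag = TRUE) & q > 0, arr.ind = TRUE)
    pairIdx[[k]] <- keep
    pairProb[[k]] <- q[keep]
  }
  laws <- model@lifespan

  withSeed(streamSeed, {
    nAlloc <- 256L
    parent <- integer(nAlloc); typev <- integer(nAlloc)
    birth <- numeric(nAlloc); endt <- numeric(nAlloc)
    fate <- character(nAlloc)
    n <- 1L
    parent[1] <- 0L; typev[1] <- as.integer(founderType)
    birth[1] <- 0; endt[1] <- sampleLifespan(laws[[founderType]], 1)
    fate[1] <- "alive"

    # binary min-heap on (event time, cell id)
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
      while (n + m > length(parent)) {
        parent <<- c(parent, integer(length(parent)))
        typev <<- c(typev, integer(length(typev)))
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
      k <- typev[i]
      if (stats::runif(1) < p0[k]) {
        fate[i] <- "died"
        alive <- alive - 1L
      } else {
        fate[i] <- "divided"
        np <- length(pairProb[[k]])
        j <- if (np == 1L) 1L else sample.int(np, 1L, prob = pairProb[[k]])
        ab <- pairIdx[[k]][j, ]
        grow(2L)
        for (d in 1:2) {
          n <- n + 1L
          parent[n] <- i; typev[n] <- as.integer(ab[d]); birth[n] <- tm
          endt[n] <- tm + sampleLifespan(laws[[ab[d]]], 1)
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

    list(cells = data.frame(id = seq_len(n), parent = parent[seq_len(n)],
                            type = typev[seq_len(n)], birth = birth[seq_len(n)],
                            end = endt[seq_len(n)], fate = fate[seq_len(n)],
                            stringsAsFactors = FALSE),
         truncated = truncated, truncatedAt = truncatedAt)
  })
}

#' Simulate one clonal family
#'
#' Event-driven realization of the multitype age-dependent branching process
#' started from a single founder cell at time 0.  Each cell draws a lifespan
#' from its type's law, then either dies (probability p0 of its type) or
#' divides into an unordered pair of daughter types drawn from its type's
#' pair distribution; all cells evolve independently.  If the number of live
#' cells exceeds \code{cap} the trajectory is truncated and flagged rather
#' than silently wrong (supercritical clones grow exponentially).
#'
#' @param model a \linkS4class{BranchingModel}.
#' @param founderType founder type index in 1..K.
#' @param horizon simulation end time (>= 0).
#' @param seed integer root seed.
#' @param cap maximum number of simultaneously live cells (default 1e6).
#' @return A \linkS4class{CloneTrajectory}.
#' @examples
#' m <- singleTypeModel(p0 = 0.3, expLifespan(1))
#' simulateClone(m, 1, horizon = 4, seed = 1)
#' @export
simulateClone <- function(model, founderType, horizon, seed, cap = 1e6) {
  stopifnot(is(model, "BranchingModel"), horizon >= 0, cap >= 1)
  if (founderType < 1 || founderType > model@K)
    stop("founderType must lie in 1..K")
  sim <- .simClone(model, founderType, horizon,
                   substreamSeed(seed, "simulateClone"), cap)
  new("CloneTrajectory", cells = sim$cells,
      founderType = as.integer(founderType), horizon = horizon, K = model@K,
      truncated = sim$truncated, truncatedAt = sim$truncatedAt)
}

#' Simulate a germinal-center reaction
#'
#' Couples the Poisson seeding process with independent clone-level branching:
#' founder arrivals are sampled from \code{spec} and \code{weights}, and the
#' l-th clone evolves as an independent copy of the branching process started
#' at its arrival time with its founder's type.  Each clone draws from its
#' own RNG substream keyed by its clone index, so GC realizations are
#' reproducible regardless of clone interleaving.
#'
#' @inheritParams simulateClone
#' @param spec immigration \linkS4class{RateSpec}.
#' @param weights founder type probabilities (length K).
#' @return A \linkS4class{GCTrajectory}.
#' @examples
#' m <- singleTypeModel(p0 = 0.5, expLifespan(1))
#' simulateGC(m, rateSpec("constant", r0 = 2), 1, horizon = 5, seed = 1)
#' @export
simulateGC <- function(model, spec, weights, horizon, seed, cap = 1e6) {
  stopifnot(is(model, "BranchingModel"), horizon >= 0)
  checkTypeWeights(weights, model@K)
  arr <- sampleArrivals(spec, weights, horizon, seed)
  clones <- vector("list", nrow(arr))
  for (l in seq_len(nrow(arr))) {
    sim <- .simClone(model, arr$type_index[l], horizon - arr$time[l],
                     substreamSeed(seed, "clone", l), cap)
    clones[[l]] <- new("CloneTrajectory", cells = sim$cells,
                       founderType = arr$type_index[l],
                       horizon = horizon - arr$time[l], K = model@K,
                       truncated = sim$truncated, truncatedAt = sim$truncatedAt)
  }
  new("GCTrajectory", arrivals = arr, clones = clones, horizon = horizon,
      K = model@K)
}

#' Type counts along a trajectory
#'
#' Exact per-type counts read off the event log at the requested times.
#' Counts are right-continuous: a cell is present from its birth (inclusive)
#' until its death/division event (exclusive), so the state reported at an
#' event time is the post-event state.
#'
#' @param traj a \linkS4class{CloneTrajectory} or \linkS4class{GCTrajectory}.
#' @param times query times within [0, horizon].
#' @return numeric matrix, \code{length(times)} rows x K type columns.
#' @export
setGeneric("countsAt", function(traj, times) standardGeneric("countsAt"))

#' @rdname countsAt
#' @export
setMethod("countsAt", "CloneTrajectory", function(traj, times) {
  if (any(times < 0) || any(times > traj@horizon))
    stop("times must lie within [0, horizon]")
  if (traj@truncated && any(times > traj@truncatedAt))
    stop("trajectory truncated at t = ", traj@truncatedAt,
         "; counts beyond that time are not available")
  cells <- traj@cells
  out <- matrix(0, length(times), traj@K)
  for (i in seq_along(times)) {
    t <- times[i]
    sel <- cells$birth <= t & cells$end > t
    out[i, ] <- tabulate(cells$type[sel], traj@K)
  }
  dimnames(out) <- list(NULL, paste0("type", seq_len(traj@K)))
  out
})

#' @rdname countsAt
#' @export
setMethod("countsAt", "GCTrajectory", function(traj, times) {
  if (any(times < 0) || any(times > traj@horizon))
    stop("times must lie within [0, horizon]")
  out <- matrix(0, length(times), traj@K,
                dimnames = list(NULL, paste0("type", seq_len(traj@K))))
  for (l in seq_along(traj@clones)) {
    Tl <- traj@arrivals$time[l]
    on <- which(times >= Tl)
    if (length(on))
      out[on, ] <- out[on, , drop = FALSE] +
        countsAt(traj@clones[[l]], times[on] - Tl)
  }
  out
})
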