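## ---------------------------------------------------------------------------
## Infinite-type clonal-dominance model: each founder starts its own type,
## clones draw an i.i.d. division probability (random fitness) and never
## communicate.
## ---------------------------------------------------------------------------

#' Random fitness law for the per-clone death probability
#'
#' Distribution from which each clone's death probability p0 (equivalently
#' division probability p2 = 1 - p0) is drawn independently.
#'
#' @slot type one of \code{"uniform"}, \code{"fixed"}, \code{"tabulated"}.
#' @slot min,max uniform support for p0.
#' @slot value fixed p0.
#' @slot table two-column matrix \code{cbind(p0, prob)} for the tabulated
#'   law.
#' @export
setClass("FitnessLaw",
  representation(type = "character", min = "numeric", max = "numeric",
                 value = "numeric", table = "matrix"),
  prototype(type = "uniform", min = 0.35, max = 1, value = 0.5,
            table = matrix(numeric(0), ncol = 2)))

setValidity("FitnessLaw", function(object) {
  msg <- character(0)
  if (!object@type %in% c("uniform", "fixed", "tabulated"))
    msg <- c(msg, "type must be 'uniform', 'fixed' or 'tabulated'")
  if (object@type == "uniform" &&
      (object@min < 0 || object@max > 1 || object@min >= object@max))
    msg <- c(msg, "uniform support must satisfy 0 <= min < max <= 1")
  if (object@type == "fixed" && (object@value < 0 || object@value > 1))
    msg <- c(msg, "fixed p0 must lie in [0, 1]")
  if (object@type == "tabulated") {
    tb <- object@table
    if (ncol(tb) != 2 || nrow(tb) < 1 || any(tb[, 1] < 0) ||
        any(tb[, 1] > 1) || any(tb[, 2] < 0) ||
        abs(sum(tb[, 2]) - 1) > 1e-12)
      msg <- c(msg, "tabulated law needs p0 values in [0,1] and probabilities summing to 1")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn FitnessLaw constructor.  Defaults to p0 ~ Uniform[0.35, 1],
#'   under which a clone is supercritical (p2 > 1/2) with probability
#'   0.15/0.65.
#' @param type,min,max,value,table see slots.
#' @export
fitnessLaw <- function(type = c("uniform", "fixed", "tabulated"),
                       min = 0.35, max = 1, value = 0.5, table = NULL) {
  type <- match.arg(type)
  if (is.null(table)) table <- matrix(numeric(0), ncol = 2)
  new("FitnessLaw", type = type, min = min, max = max, value = value,
      table = as.matrix(table))
}

setMethod("show", "FitnessLaw", function(object) {
  cat(switch(object@type,
    uniform = sprintf("FitnessLaw: p0 ~ Uniform[%g, %g]\n", object@min,
                      object@max),
    fixed = sprintf("FitnessLaw: p0 = %g\n", object@value),
    tabulated = sprintf("FitnessLaw: tabulated (%d atoms)\n",
                        nrow(object@table))))
})

#' Sample per-clone fitness (division probability and growth rate)
#'
#' Draws i.i.d. death probabilities p0 from the fitness law and converts them
#' to division probabilities p2 = 1 - p0 and, for exponential lifespans with
#' rate \code{lambda}, to per-clone Malthusian parameters
#' \eqn{\alpha_k = (2 p_2^k - 1)\lambda}.
#'
#' @param law a \linkS4class{FitnessLaw}.
#' @param n number of clones.
#' @param lambda exponential lifespan rate shared by all clones.
#' @param seed integer root seed.
#' @return data.frame with columns \code{p0}, \code{p2}, \code{alpha}.
#' @export
sampleCloneFitness <- function(law, n, lambda = 1, seed = 1) {
  stopifnot(is(law, "FitnessLaw"), n >= 1, lambda > 0)
  p0 <- withSeed(substreamSeed(seed, "sampleCloneFitness"),
    switch(law@type,
      uniform   = stats::runif(n, law@min, law@max),
      fixed     = rep(law@value, n),
      tabulated = sample(law@table[, 1], n, replace = TRUE,
                         prob = law@table[, 2])))
  p2 <- 1 - p0
  data.frame(p0 = p0, p2 = p2, alpha = (2 * p2 - 1) * lambda)
}

## Mixture extinction probability Q = integral of min{1, (1-p2)/p2} over the
## fitness law (smallest-root formula), by quadrature / direct sum.
mixtureExtinctionQ <- function(law) {
  qext <- function(p0) {
    p2 <- 1 - p0
    ifelse(p2 <= 0.5, 1, (1 - p2) / p2)
  }
  switch(law@type,
    uniform = stats::integrate(function(x) qext(x) / (law@max - law@min),
                               law@min, law@max,
                               rel.tol = 1e-10)$value,
    fixed = qext(law@value),
    tabulated = sum(qext(law@table[, 1]) * law@table[, 2]))
}

#' Simulate the clonal-dominance model
#'
#' Founder B cells arrive by an (in)homogeneous Poisson process; every
#' arrival starts a brand-new clone whose cells carry a clone-specific
#' division probability drawn from \code{law} and exponential(\code{lambda})
#' lifespans.  Clone sizes are recorded on a uniform reporting grid; clonal
#' fractions, Simpson / inverse-Simpson diversity, richness and the dominant
#' clone are then read off that grid.
#'
#' @param spec immigration \linkS4class{RateSpec}.
#' @param law a \linkS4class{FitnessLaw} for the per-clone death probability.
#' @param lambda exponential lifespan rate (one time unit = one mean mitotic
#'   cycle when lambda = 1).
#' @param horizon simulation end time.
#' @param seed integer root seed.
#' @param cap per-clone live-cell cap.
#' @param gridStep reporting-grid spacing (default 0.1 lifespan units).
#' @return A \linkS4class{DominanceTrajectory}.
#' @examples
#' tr <- simulateDominance(rateSpec("constant", r0 = 3), fitnessLaw(),
#'                         lambda = 1, horizon = 5, seed = 1)
#' dominanceProfile(tr)[1:5, ]
#' @export
simulateDominance <- function(spec, law, lambda = 1, horizon, seed,
                              cap = 1e6, gridStep = 0.1) {
  stopifnot(horizon >= 0)
  arr <- sampleArrivals(spec, "distinct", horizon, seed)
  nClones <- nrow(arr)
  fit <- if (nClones > 0) sampleCloneFitness(law, nClones, lambda, seed)
         else data.frame(p0 = numeric(0), p2 = numeric(0),
                         alpha = numeric(0))
  times <- seq(0, horizon, by = gridStep)
  sizes <- matrix(0, length(times), max(nClones, 1L))[, seq_len(nClones),
                                                      drop = FALSE]
  truncated <- logical(nClones)
  for (k in seq_len(nClones)) {
    model <- singleTypeModel(fit$p0[k], expLifespan(lambda))
    sim <- .simClone(model, 1L, horizon - arr$time[k],
                     substreamSeed(seed, "clone", k), cap)
    truncated[k] <- sim$truncated
    on <- which(times >= arr$time[k] &
                  (!sim$truncated |
                     times - arr$time[k] <= sim$truncatedAt))
    for (i in on) {
      t <- times[i] - arr$time[k]
      sizes[i, k] <- sum(sim$cells$birth <= t & sim$cells$end > t)
    }
  }
  new("DominanceTrajectory", times = times, sizes = sizes,
      arrivalTimes = arr$time, p2 = fit$p2, alpha = fit$alpha,
      lambda = lambda, truncated = truncated)
}

#' Diversity and dominance profile of a dominance trajectory
#'
#' @param traj a \linkS4class{DominanceTrajectory}.
#' @return data.frame with one row per reporting time: total cell count,
#'   clonal richness, Simpson and inverse-Simpson indices, and the dominant
#'   clone index (NA while the GC is empty).
#' @export
dominanceProfile <- function(traj) {
  stopifnot(is(traj, "DominanceTrajectory"))
  total <- rowSums(traj@sizes)
  richness <- rowSums(traj@sizes > 0)
  simpson <- ifelse(total > 0, rowSums((traj@sizes / pmax(total, 1))^2),
                    NA_real_)
  dominant <- apply(traj@sizes, 1, function(z)
    if (all(z == 0)) NA_integer_ else which.max(z))
  data.frame(time = traj@times, total = total, richness = richness,
             simpson = simpson, invSimpson = 1 / simpson,
             dominant = as.integer(dominant))
}

#' Dominant clone at a given time
#'
#' Index of a clone whose size equals or exceeds every other clone's size at
#' the reporting-grid point nearest to \code{t}; ties go to the
#' earliest-arrived (smallest-index) clone, and NA is returned while the GC
#' is empty.
#'
#' @param traj a \linkS4class{DominanceTrajectory}.
#' @param t query time within the simulated horizon.
#' @return Clone index or NA.
#' @export
dominantClone <- function(traj, t) {
  stopifnot(is(traj, "DominanceTrajectory"))
  if (t < 0 || t > max(traj@times)) stop("t outside the simulated horizon")
  i <- which.min(abs(traj@times - t))
  z <- traj@sizes[i, ]
  if (all(z == 0)) return(NA_integer_)
  which.max(z)   # ties -> smallest index
}

#' Number of dominant-clone turnovers
#'
#' Counts reporting-grid steps at which the dominant clone differs from the
#' previous grid point; transitions from an empty GC to the first dominant
#' clone are not counted.
#'
#' @param traj a \linkS4class{DominanceTrajectory}.
#' @return Nonnegative integer turnover count.
#' @export
turnoverCount <- function(traj) {
  dom <- dominanceProfile(traj)$dominant
  ok <- !is.na(dom)
  d <- dom[ok]
  if (length(d) < 2) return(0L)
  sum(d[-1] != d[-length(d)])
}
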