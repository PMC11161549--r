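#' Cumulative immigration measure R(t)
#'
#' Integral of the local seeding intensity, \eqn{R(t) = \int_0^t r(x) dx}.
#' For power-law rates \eqn{r(t) = r_0 t^\gamma} this is
#' \eqn{r_0 t^{\gamma+1}/(\gamma+1)}, finite for every \eqn{\gamma > -1} even
#' though the rate itself is unbounded at 0 when \eqn{\gamma < 0}.
#'
#' @param spec a \linkS4class{RateSpec}.
#' @param t nonnegative time (vectorized).
#' @return R(t), nonnegative and nondecreasing, with R(0) = 0.
#' @examples
#' cumulativeMeasure(rateSpec("power_law", r0 = 1, gamma = -0.5), 1)  # = 2
#' @export
cumulativeMeasure <- function(spec, t) {
  stopifnot(is(spec, "RateSpec"))
  if (any(t < 0)) stop("t must be nonnegative")
  switch(spec@form,
    constant  = spec@r0 * t,
    power_law = spec@r0 * t^(spec@gamma + 1) / (spec@gamma + 1),
    tabulated = {
      tb <- spec@table
      out <- stats::approx(tb[, 1], tb[, 2], xout = pmin(t, max(tb[, 1])),
                           rule = 2, ties = "ordered")$y
      beyond <- t > max(tb[, 1])
      if (any(beyond)) {
        # extrapolate flat beyond the last knot (no further mass specified)
        out[beyond] <- max(tb[, 2])
      }
      out
    })
}

## Generalized inverse R^{-1}(y) = inf{t : R(t) >= y}.  Closed form for the
## analytic families; exact piecewise-linear inversion (leftmost point on flat
## segments) for tabulated measures.
inverseMeasure <- function(spec, y) {
  stopifnot(is(spec, "RateSpec"), all(y >= 0))
  switch(spec@form,
    constant  = y / spec@r0,
    power_law = ((spec@gamma + 1) * y / spec@r0)^(1 / (spec@gamma + 1)),
    tabulated = {
      tb <- spec@table
      Rv <- tb[, 2]; tv <- tb[, 1]
      vapply(y, function(yy) {
        if (yy > Rv[length(Rv)]) return(Inf)
        i <- findInterval(yy, Rv)            # largest i with R[i] <= yy
        if (Rv[i] == yy) return(tv[match(yy, Rv)])  # leftmost time on flats
        tv[i] + (yy - Rv[i]) / (Rv[i + 1] - Rv[i]) * (tv[i + 1] - tv[i])
      }, 0)
    })
}

#' Sample typed founder arrivals on [0, horizon]
#'
#' Generates one realization of the inhomogeneous Poisson seeding process by
#' inversion: with unit-exponential increments \eqn{E_i}, the arrival times
#' are \eqn{T_i = R^{-1}(E_1 + \dots + E_i)}.  Inversion is exact for all
#' supported rate forms, including power laws with a singular rate at 0 where
#' thinning has no finite majorant.  Founder types are i.i.d. with
#' probabilities \code{weights}; with \code{weights = "distinct"} every
#' arrival founds a new type (the infinite-type clonal-dominance mode).
#'
#' @param spec a \linkS4class{RateSpec}.
#' @param weights positive probabilities summing to 1, or \code{"distinct"}.
#' @param horizon nonnegative end of the observation window.
#' @param seed integer root seed (substream key: "sampleArrivals").
#' @return data.frame with columns \code{clone_index}, \code{time},
#'   \code{type_index}, ordered by time.
#' @examples
#' sampleArrivals(rateSpec("constant", r0 = 2), c(0.5, 0.5), horizon = 3,
#'                seed = 1)
#' @export
sampleArrivals <- function(spec, weights, horizon, seed) {
  stopifnot(is(spec, "RateSpec"), horizon >= 0)
  checkTypeWeights(weights)
  Rmax <- cumulativeMeasure(spec, horizon)
  withSeed(substreamSeed(seed, "sampleArrivals"), {
    times <- numeric(0)
    total <- 0
    # draw cumulative exponentials in blocks until R(horizon) is exceeded
    repeat {
      blk <- max(16L, ceiling(1.5 * (Rmax - total)))
      cum <- total + cumsum(stats::rexp(blk))
      total <- cum[length(cum)]
      times <- c(times, cum)
      if (total > Rmax) break
    }
    times <- times[times <= Rmax]
    n <- length(times)
    type <- if (identical(weights, "distinct")) seq_len(n)
            else if (n > 0) sample.int(length(weights), n, replace = TRUE,
                                       prob = weights)
            else integer(0)
    data.frame(clone_index = seq_len(n),
               time = if (n > 0) inverseMeasure(spec, times) else numeric(0),
               type_index = as.integer(type))
  })
}

#' Law of the first arrival of a given founder type
#'
#' Closed-form distribution of \eqn{T_{k1}}, the waiting time until the first
#' type-k founder (precursor frequency \code{gk}) joins the GC.  Under a
#' constant overall rate r0 this is exponential with rate \code{gk * r0};
#' under a power-law rate \eqn{r_0 t^\gamma} it is Weibull with shape
#' \eqn{1+\gamma} and scale \eqn{((1+\gamma)/(g_k r_0))^{1/(1+\gamma)}}, heavy
#' tailed when the seeding slows down (\eqn{\gamma < 0}).
#'
#' @param spec a \linkS4class{RateSpec} (constant or power_law).
#' @param gk precursor frequency in (0, 1].
#' @return list with \code{family}, parameter entries, \code{median} and
#'   \code{mean}.
#' @examples
#' firstArrivalLaw(rateSpec("constant", r0 = 1), gk = 0.5)$median  # log(2)/0.5
#' @export
firstArrivalLaw <- function(spec, gk) {
  stopifnot(is(spec, "RateSpec"), gk > 0, gk <= 1)
  if (spec@form == "tabulated")
    stop("no closed-form first-arrival law for tabulated rates; sample instead")
  if (spec@form == "constant") {
    rate <- gk * spec@r0
    return(list(family = "exponential", rate = rate,
                median = log(2) / rate, mean = 1 / rate))
  }
  shp <- 1 + spec@gamma
  scl <- ((1 + spec@gamma) / (gk * spec@r0))^(1 / (1 + spec@gamma))
  list(family = "weibull", shape = shp, scale = scl,
       median = scl * log(2)^(1 / shp),
       mean = scl * gamma(1 + 1 / shp))
}

#' Waiting-time ratio between two precursor frequencies
#'
#' Ratio of the median (equivalently mean) waiting times until the first
#' founders of two types join the GC, when their precursor frequencies differ
#' by a factor \code{gRatio} under a power-law seeding rate with exponent
#' \code{gamma}: \eqn{(g_k/g_{k'})^{1/(1+\gamma)}}.  With a decelerating rate
#' (\eqn{\gamma = -1/2}) halving the precursor frequency quadruples the wait;
#' with a stationary rate it merely doubles it.
#'
#' @param gRatio positive frequency ratio \eqn{g_k / g_{k'}}.
#' @param gamma power-law exponent, > -1 (0 for a constant rate).
#' @return The multiplicative factor \code{gRatio^(1/(1+gamma))}.
#' @examples
#' waitingTimeRatio(2, -1/2)  # 4
#' waitingTimeRatio(2, 0)     # 2
#' @export
waitingTimeRatio <- function(gRatio, gamma) {
  if (any(gRatio <= 0)) stop("gRatio must be positive")
  if (any(gamma <= -1)) stop("gamma must be > -1")
  gRatio^(1 / (1 + gamma))
}

#' Founder-race probability mass function
#'
#' Probability that exactly \code{n} founders from type set K1 join the GC
#' before the first founder from a disjoint set K2 arrives.  Under
#' proportional seeding the count is geometric with success probability
#' \eqn{p = g_2/(g_1+g_2)} regardless of the shape of r(t):
#' \eqn{P(N = n) = p (1-p)^n}.
#'
#' @param g1Sum,g2Sum total precursor frequencies of the two disjoint sets
#'   (both positive).
#' @param n nonnegative count (vectorized).
#' @return P(N = n).
#' @examples
#' racePmf(0.5, 0.5, 0)           # symmetric race: 1/2
#' sum(racePmf(0.75, 0.25, 0:50)) # ~ 1
#' @export
racePmf <- function(g1Sum, g2Sum, n) {
  stopifnot(g1Sum > 0, g2Sum > 0)
  if (any(n < 0) || any(n != floor(n))) stop("n must be a nonnegative integer")
  p <- g2Sum / (g1Sum + g2Sum)
  p * (1 - p)^n
}

#' @describeIn racePmf mean and variance of the race count:
#'   \eqn{E(N) = g_1/g_2}, \eqn{Var(N) = (g_1/g_2)^2 + g_1/g_2}.
#' @export
raceMoments <- function(g1Sum, g2Sum) {
  stopifnot(g1Sum > 0, g2Sum > 0)
  m <- g1Sum / g2Sum
  c(mean = m, var = m^2 + m)
}
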