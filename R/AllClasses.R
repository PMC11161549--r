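#' @import methods
NULL

## ---------------------------------------------------------------------------
## Immigration: rate specifications and type weights
## ---------------------------------------------------------------------------

#' Immigration rate specification
#'
#' Describes the local intensity r(t) of the Poisson process seeding a
#' germinal center with founder B cells.  Three forms are supported:
#' \describe{
#'   \item{\code{constant}}{r(t) = r0.}
#'   \item{\code{power_law}}{r(t) = r0 * t^gamma with gamma > -1; the rate may
#'     be unbounded at t = 0 (gamma < 0) yet the cumulative measure stays
#'     finite.}
#'   \item{\code{tabulated}}{the cumulative measure R(t) is given at sample
#'     points and interpolated piecewise-linearly.}
#' }
#'
#' @slot form one of \code{"constant"}, \code{"power_law"}, \code{"tabulated"}.
#' @slot r0 positive rate constant (events per unit time).
#' @slot gamma power-law exponent, > -1 (power_law only).
#' @slot table two-column matrix \code{cbind(time, measure)} of nondecreasing
#'   cumulative-measure samples starting at (0, 0) (tabulated only).
#' @export
setClass("RateSpec",
  representation(form = "character", r0 = "numeric", gamma = "numeric",
                 table = "matrix"),
  prototype(form = "constant", r0 = 1, gamma = 0,
            table = matrix(numeric(0), ncol = 2)))

setValidity("RateSpec", function(object) {
  msg <- character(0)
  if (!object@form %in% c("constant", "power_law", "tabulated"))
    msg <- c(msg, "form must be 'constant', 'power_law' or 'tabulated'")
  if (object@form %in% c("constant", "power_law")) {
    if (length(object@r0) != 1 || !is.finite(object@r0) || object@r0 <= 0)
      msg <- c(msg, "r0 must be a single positive number")
  }
  if (object@form == "power_law" &&
      (length(object@gamma) != 1 || !is.finite(object@gamma) ||
       object@gamma <= -1))
    msg <- c(msg, "gamma must be a single number > -1")
  if (object@form == "tabulated") {
    tb <- object@table
    if (ncol(tb) != 2 || nrow(tb) < 2)
      msg <- c(msg, "table must have two columns (time, measure) and >= 2 rows")
    else {
      if (tb[1, 1] != 0 || tb[1, 2] != 0)
        msg <- c(msg, "tabulated measure must start at (0, 0)")
      if (any(diff(tb[, 1]) <= 0))
        msg <- c(msg, "tabulated times must be strictly increasing")
      if (any(diff(tb[, 2]) < 0))
        msg <- c(msg, "tabulated measure must be nondecreasing")
      if (any(!is.finite(tb)))
        msg <- c(msg, "tabulated measure must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RateSpec constructor.
#' @param form,r0,gamma,table see slots.
#' @export
rateSpec <- function(form = c("constant", "power_law", "tabulated"),
                     r0 = 1, gamma = 0, table = NULL) {
  form <- match.arg(form)
  if (is.null(table)) table <- matrix(numeric(0), ncol = 2)
  new("RateSpec", form = form, r0 = r0, gamma = gamma,
      table = as.matrix(table))
}

setMethod("show", "RateSpec", function(object) {
  switch(object@form,
    constant  = cat(sprintf("RateSpec: constant r(t) = %g\n", object@r0)),
    power_law = cat(sprintf("RateSpec: power law r(t) = %g * t^%g\n",
                            object@r0, object@gamma)),
    tabulated = cat(sprintf("RateSpec: tabulated cumulative measure (%d knots, R(%g) = %g)\n",
                            nrow(object@table), max(object@table[, 1]),
                            max(object@table[, 2]))))
})

## Validate a vector of founder type weights (precursor frequencies g_k).
## The reserved value "distinct" encodes the infinite-type mode in which every
## arrival founds a brand-new type (clonal-dominance model).
checkTypeWeights <- function(g, K = NULL) {
  if (identical(g, "distinct")) return(invisible(g))
  if (!is.numeric(g) || length(g) < 1)
    stop("type weights must be a numeric vector or \"distinct\"")
  if (any(g <= 0)) stop("type weights must be strictly positive")
  if (abs(sum(g) - 1) > 1e-12) stop("type weights must sum to 1 (tol 1e-12)")
  if (!is.null(K) && length(g) != K)
    stop("length of type weights must equal the number of types K")
  invisible(g)
}

## ---------------------------------------------------------------------------
## Branching mechanism
## ---------------------------------------------------------------------------

#' Cell lifespan law
#'
#' Lifespan distribution of a cell type.  Analytic families (exponential,
#' gamma, fixed) support the Laplace transform and density needed by the
#' asymptotics and moment modules; an empirical family (resampled values) is
#' accepted for simulation only.
#'
#' @slot family one of \code{"exponential"}, \code{"gamma"}, \code{"fixed"},
#'   \code{"empirical"}.
#' @slot rate exponential rate.
#' @slot shape,scale gamma parameters.
#' @slot value fixed lifespan.
#' @slot samples empirical sample pool.
#' @export
setClass("LifespanLaw",
  representation(family = "character", rate = "numeric", shape = "numeric",
                 scale = "numeric", value = "numeric", samples = "numeric"),
  prototype(family = "exponential", rate = 1, shape = 1, scale = 1,
            value = 1, samples = numeric(0)))

setValidity("LifespanLaw", function(object) {
  msg <- character(0)
  fam <- object@family
  if (!fam %in% c("exponential", "gamma", "fixed", "empirical"))
    msg <- c(msg, "unknown lifespan family")
  if (fam == "exponential" && (object@rate <= 0 || !is.finite(object@rate)))
    msg <- c(msg, "exponential rate must be positive")
  if (fam == "gamma" && (object@shape <= 0 || object@scale <= 0))
    msg <- c(msg, "gamma shape and scale must be positive")
  if (fam == "fixed" && object@value <= 0)
    msg <- c(msg, "fixed lifespan must be positive (G(0) = 0)")
  if (fam == "empirical" &&
      (length(object@samples) < 1 || any(object@samples <= 0)))
    msg <- c(msg, "empirical samples must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn LifespanLaw exponential lifespan with given rate.
#' @param rate exponential rate parameter.
#' @export
expLifespan <- function(rate = 1) new("LifespanLaw", family = "exponential",
                                      rate = rate)

#' @describeIn LifespanLaw gamma lifespan (shape-scale parametrization).
#' @param shape,scale gamma parameters.
#' @export
gammaLifespan <- function(shape, scale) new("LifespanLaw", family = "gamma",
                                            shape = shape, scale = scale)

#' @describeIn LifespanLaw deterministic lifespan (test models only; lattice).
#' @param value the fixed lifespan.
#' @export
fixedLifespan <- function(value) new("LifespanLaw", family = "fixed",
                                     value = value)

#' @describeIn LifespanLaw empirical lifespan resampled from a pool.
#' @param samples positive sample pool for the empirical family.
#' @export
empiricalLifespan <- function(samples) new("LifespanLaw", family = "empirical",
                                           samples = as.numeric(samples))

setMethod("show", "LifespanLaw", function(object) {
  cat(switch(object@family,
    exponential = sprintf("LifespanLaw: exponential(rate = %g)\n", object@rate),
    gamma = sprintf("LifespanLaw: gamma(shape = %g, scale = %g)\n",
                    object@shape, object@scale),
    fixed = sprintf("LifespanLaw: fixed(%g)\n", object@value),
    empirical = sprintf("LifespanLaw: empirical (%d samples)\n",
                        length(object@samples))))
})

#' Offspring law of one cell type
#'
#' At the end of its lifespan a cell either dies (probability \code{p0}) or
#' divides into an unordered pair of daughter types drawn from
#' \code{pairProbs}.  The pair probabilities q_{ij} live on the upper triangle
#' (i <= j) of a K x K matrix and sum to one.
#'
#' @slot p0 death probability in [0, 1].
#' @slot pairProbs K x K matrix of conditional division-pair probabilities;
#'   only entries with row <= col may be nonzero.
#' @export
setClass("OffspringLaw",
  representation(p0 = "numeric", pairProbs = "matrix"))

setValidity("OffspringLaw", function(object) {
  msg <- character(0)
  if (length(object@p0) != 1 || object@p0 < 0 || object@p0 > 1)
    msg <- c(msg, "p0 must be a probability")
  q <- object@pairProbs
  if (nrow(q) != ncol(q)) msg <- c(msg, "pairProbs must be square")
  if (any(q < 0)) msg <- c(msg, "pair probabilities must be >= 0")
  if (any(q[lower.tri(q)] != 0))
    msg <- c(msg, "pairProbs must be upper-triangular (unordered pairs i <= j)")
  if (object@p0 < 1 && abs(sum(q) - 1) > 1e-12)
    msg <- c(msg, "pair probabilities must sum to 1 (tol 1e-12)")
  if (length(msg)) msg else TRUE
})

#' @describeIn OffspringLaw constructor; \code{pairProbs} may be omitted for a
#'   single-type model (self-renewing division).
#' @param p0 death probability.
#' @param pairProbs upper-triangular matrix of pair probabilities.
#' @export
offspringLaw <- function(p0, pairProbs = matrix(1, 1, 1)) {
  new("OffspringLaw", p0 = p0, pairProbs = as.matrix(pairProbs))
}

#' Multitype branching mechanism
#'
#' A K-type age-dependent (Bellman-Harris) branching mechanism: each type has
#' its own lifespan law and offspring law (death or division into an unordered
#' type pair).
#'
#' @slot K number of types.
#' @slot offspring list of \linkS4class{OffspringLaw}, one per type.
#' @slot lifespan list of \linkS4class{LifespanLaw}, one per type.
#' @export
setClass("BranchingModel",
  representation(K = "integer", offspring = "list", lifespan = "list"))

setValidity("BranchingModel", function(object) {
  msg <- character(0)
  K <- object@K
  if (length(object@offspring) != K || length(object@lifespan) != K)
    msg <- c(msg, "need one offspring law and one lifespan law per type")
  for (k in seq_len(K)) {
    o <- object@offspring[[k]]
    if (!is(o, "OffspringLaw")) msg <- c(msg, "offspring must be OffspringLaw")
    else if (nrow(o@pairProbs) != K)
      msg <- c(msg, sprintf("pairProbs of type %d must be %d x %d", k, K, K))
    if (!is(object@lifespan[[k]], "LifespanLaw"))
      msg <- c(msg, "lifespan must be LifespanLaw")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BranchingModel constructor from per-type law lists (laws are
#'   recycled across types when a single one is given).
#' @param offspring an \linkS4class{OffspringLaw} or list of them.
#' @param lifespan a \linkS4class{LifespanLaw} or list of them.
#' @param K number of types; inferred from \code{pairProbs} when missing.
#' @export
branchingModel <- function(offspring, lifespan, K = NULL) {
  if (is(offspring, "OffspringLaw")) offspring <- list(offspring)
  if (is(lifespan, "LifespanLaw")) lifespan <- list(lifespan)
  if (is.null(K)) K <- max(length(offspring),
                           nrow(offspring[[1]]@pairProbs))
  if (length(offspring) == 1 && K > 1) offspring <- rep(offspring, K)
  if (length(lifespan) == 1 && K > 1) lifespan <- rep(lifespan, K)
  new("BranchingModel", K = as.integer(K), offspring = offspring,
      lifespan = lifespan)
}

#' @describeIn BranchingModel convenience constructor for a single-type model
#'   with death probability \code{p0}.
#' @param p0 death probability of the single type.
#' @export
singleTypeModel <- function(p0, lifespan = expLifespan(1)) {
  branchingModel(offspringLaw(p0), lifespan, K = 1)
}

setMethod("show", "BranchingModel", function(object) {
  p0 <- vapply(object@offspring, function(o) o@p0, 0)
  cat(sprintf("BranchingModel with %d type(s)\n", object@K))
  cat("  death probabilities:", paste(signif(p0, 4), collapse = ", "), "\n")
  cat("  lifespans:", paste(vapply(object@lifespan,
                                   function(l) l@family, ""), collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## Trajectories
## ---------------------------------------------------------------------------

#' Event-level realization of a single clone
#'
#' Cell-level log of one simulated clonal family.  \code{cells} has one row
#' per cell ever born: \code{id}, \code{parent} (0 for the founder),
#' \code{type}, \code{birth}, \code{end} (time of its death/division event)
#' and \code{fate} ("died", "divided" or "alive" when the event falls beyond
#' the horizon).  Counts are right-continuous: a cell is present on
#' [birth, end).
#'
#' @slot cells data.frame event log (one row per cell).
#' @slot founderType type index of the founder cell.
#' @slot horizon simulated time horizon.
#' @slot K number of types.
#' @slot truncated TRUE when the live-cell cap was hit.
#' @slot truncatedAt time at which simulation was truncated (Inf otherwise).
#' @export
setClass("CloneTrajectory",
  representation(cells = "data.frame", founderType = "integer",
                 horizon = "numeric", K = "integer", truncated = "logical",
                 truncatedAt = "numeric"))

setMethod("show", "CloneTrajectory", function(object) {
  cat(sprintf("CloneTrajectory: founder type %d, %d cell(s), horizon %g%s\n",
              object@founderType, nrow(object@cells), object@horizon,
              if (object@truncated)
                sprintf(" [TRUNCATED at t = %g]", object@truncatedAt) else ""))
})

#' Germinal-center realization (immigration + clones)
#'
#' Superposition of independently evolving clones, each started at its
#' founder's arrival time: Y(t) = sum over clones of Z^(l)(t - T_l).
#'
#' @slot arrivals data.frame with columns clone_index, time, type_index.
#' @slot clones list of \linkS4class{CloneTrajectory}.
#' @slot horizon simulated horizon.
#' @slot K number of types.
#' @export
setClass("GCTrajectory",
  representation(arrivals = "data.frame", clones = "list",
                 horizon = "numeric", K = "integer"))

setMethod("show", "GCTrajectory", function(object) {
  cat(sprintf("GCTrajectory: %d clone(s) over horizon %g, %d type(s)\n",
              nrow(object@arrivals), object@horizon, object@K))
})

#' Malthusian analysis result
#'
#' @slot alpha Malthusian parameter (root of rho*(alpha) = 1).
#' @slot u right eigenvector of M*(alpha), normalized so sum(u) = 1.
#' @slot v left eigenvector, normalized so u . v = 1.
#' @slot criticality "sub", "critical" or "super".
#' @export
setClass("MalthusResult",
  representation(alpha = "numeric", u = "numeric", v = "numeric",
                 criticality = "character"))

setMethod("show", "MalthusResult", function(object) {
  cat(sprintf("MalthusResult: alpha = %.6g (%scritical)\n", object@alpha,
              switch(object@criticality, sub = "sub", critical = "",
                     super = "super")))
  cat("  v (left eigenvector):", paste(signif(object@v, 4), collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## Clonal dominance
## ---------------------------------------------------------------------------

#' Clone-size paths of the infinite-type dominance model
#'
#' Clone sizes of the infinite-type (one type per clone) model evaluated on a
#' reporting grid.  Column k of \code{sizes} is the size path of the k-th
#' clone (arrival order), zero before its arrival.
#'
#' @slot times reporting grid.
#' @slot sizes length(times) x nClones matrix of clone sizes.
#' @slot arrivalTimes founder arrival times (one per clone).
#' @slot p2 sampled division probabilities, one per clone.
#' @slot alpha per-clone Malthusian parameters (exponential lifespans).
#' @slot lambda lifespan rate shared by all clones.
#' @slot truncated logical vector, per-clone cap overflow flag.
#' @export
setClass("DominanceTrajectory",
  representation(times = "numeric", sizes = "matrix",
                 arrivalTimes = "numeric", p2 = "numeric", alpha = "numeric",
                 lambda = "numeric", truncated = "logical"))

setMethod("show", "DominanceTrajectory", function(object) {
  cat(sprintf(
    "DominanceTrajectory: %d clone(s), grid of %d times on [0, %g]\n",
    ncol(object@sizes), length(object@times), max(object@times)))
  if (any(object@truncated))
    cat(sprintf("  %d clone(s) truncated at the cell cap\n",
                sum(object@truncated)))
})

## ---------------------------------------------------------------------------
## Mutational drift relative to a germline/bnAb pair
## ---------------------------------------------------------------------------

#' Partition of a V segment relative to a germline/bnAb pair
#'
#' Positions of the aligned V segment split into V1 (germline and bnAb agree)
#' and V2 (they differ).
#'
#' @slot L segment length; \code{L1 + L2 = L}.
#' @slot L1,L2 sizes of the matched/mismatched position sets.
#' @slot V1,V2 1-based position index sets.
#' @export
setClass("SegmentPartition",
  representation(L = "integer", L1 = "integer", L2 = "integer",
                 V1 = "integer", V2 = "integer"))

setValidity("SegmentPartition", function(object) {
  msg <- character(0)
  if (object@L1 + object@L2 != object@L) msg <- c(msg, "L1 + L2 must equal L")
  if (length(object@V1) != object@L1 || length(object@V2) != object@L2)
    msg <- c(msg, "V1/V2 sizes must match L1/L2")
  if (length(intersect(object@V1, object@V2)) > 0)
    msg <- c(msg, "V1 and V2 must be disjoint")
  if (!setequal(c(object@V1, object@V2), seq_len(object@L)))
    msg <- c(msg, "V1 and V2 must cover positions 1..L")
  if (length(msg)) msg else TRUE
})

#' @describeIn SegmentPartition construct directly from subset sizes (the
#'   "toy" mode: the first L1 positions are taken as matched).
#' @param L1,L2 subset sizes.
#' @export
toyPartition <- function(L1, L2) {
  new("SegmentPartition", L = as.integer(L1 + L2), L1 = as.integer(L1),
      L2 = as.integer(L2), V1 = seq_len(L1),
      V2 = as.integer(if (L2 > 0) L1 + seq_len(L2) else integer(0)))
}

setMethod("show", "SegmentPartition", function(object) {
  cat(sprintf("SegmentPartition: L = %d (L1 = %d matched, L2 = %d mismatched)\n",
              object@L, object@L1, object@L2))
})

#' Somatic-hypermutation kernel parameters
#'
#' Parameters of the 10-case per-division mutation kernel acting on the
#' 5-compartment mutation-count state (l11, l12, l21, l22, l23).  \code{rho}
#' coefficients modulate per-position mutation rates; \code{sigma}
#' coefficients are odds splitting the outcome of a mutation within a
#' compartment.  Defaults follow the simulation design used to study drift
#' relative to VRC01-class antibodies.
#'
#' @slot piTilde per-division probability that a mutation lands in the V
#'   segment, in [0, 0.5].
#' @slot rho1 bias of mutating in V1 versus V2 (rho1 * L1 / L <= 1).
#' @slot rho11,rho12,rho22 per-position rate modulators within V1 / V2.
#' @slot sigma11,sigma21 odds parameters for V1 outcomes.
#' @slot sigma12_2,sigma13_2,sigma21_2,sigma23_2,sigma31_2,sigma32_2 odds
#'   parameters for V2 outcomes.
#' @export
setClass("DriftKernel",
  representation(piTilde = "numeric", rho1 = "numeric", rho11 = "numeric",
                 rho12 = "numeric", rho22 = "numeric", sigma11 = "numeric",
                 sigma21 = "numeric", sigma12_2 = "numeric",
                 sigma13_2 = "numeric", sigma21_2 = "numeric",
                 sigma23_2 = "numeric", sigma31_2 = "numeric",
                 sigma32_2 = "numeric"))

setValidity("DriftKernel", function(object) {
  msg <- character(0)
  if (object@piTilde < 0 || object@piTilde > 0.5)
    msg <- c(msg, "piTilde must lie in [0, 0.5]")
  pos <- c(object@rho1, object@rho11, object@rho12, object@rho22,
           object@sigma11, object@sigma21, object@sigma12_2,
           object@sigma13_2, object@sigma21_2, object@sigma23_2,
           object@sigma31_2, object@sigma32_2)
  if (any(pos < 0)) msg <- c(msg, "rho and sigma coefficients must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn DriftKernel constructor with field defaults (sigma11 = 1/3,
#'   sigma21 = 1/10, sigma12_2 = 1/10, sigma13_2 = 19/10, sigma21_2 = 1/10,
#'   sigma23_2 = 19/10, sigma31_2 = sigma32_2 = 1/10; neutral rho).
#' @param piTilde,rho1,rho11,rho12,rho22 rate parameters, see slots.
#' @param sigma11,sigma21,sigma12_2,sigma13_2,sigma21_2,sigma23_2,sigma31_2,sigma32_2
#'   odds parameters, see slots.
#' @export
driftKernel <- function(piTilde = 0.25, rho1 = 1, rho11 = 1, rho12 = 1,
                        rho22 = 1, sigma11 = 1 / 3, sigma21 = 1 / 10,
                        sigma12_2 = 1 / 10, sigma13_2 = 19 / 10,
                        sigma21_2 = 1 / 10, sigma23_2 = 19 / 10,
                        sigma31_2 = 1 / 10, sigma32_2 = 1 / 10) {
  new("DriftKernel", piTilde = piTilde, rho1 = rho1, rho11 = rho11,
      rho12 = rho12, rho22 = rho22, sigma11 = sigma11, sigma21 = sigma21,
      sigma12_2 = sigma12_2, sigma13_2 = sigma13_2, sigma21_2 = sigma21_2,
      sigma23_2 = sigma23_2, sigma31_2 = sigma31_2, sigma32_2 = sigma32_2)
}

setMethod("show", "DriftKernel", function(object) {
  cat(sprintf("DriftKernel: piTilde = %g, rho1 = %g (rho11 = %g, rho12 = %g, rho22 = %g)\n",
              object@piTilde, object@rho1, object@rho11, object@rho12,
              object@rho22))
})
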