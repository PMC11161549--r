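## Temporal alpha and beta diversity indices for type-count vectors.
##
## All indices operate on nonnegative count vectors (one entry per type;
## infinite type spaces are represented sparsely by their observed support,
## which is exact because absent types contribute nothing).  Indices that are
## undefined on an empty population return NA_real_ rather than erroring, so
## profiles over a trajectory that starts empty stay well formed.

.checkCounts <- function(c1) {
  if (!is.numeric(c1) || any(c1 < 0) || any(!is.finite(c1)))
    stop("counts must be finite and nonnegative")
}

#' Hill number of order q
#'
#' Alpha-diversity profile
#' \eqn{D^q = (\sum_k p_k^q)^{1/(1-q)}} on relative abundances
#' \eqn{p_k = c_k / \sum c}.  Order 0 is species richness, the q -> 1 limit
#' is the exponential of the Shannon index, and q = 2 is the inverse Simpson
#' index.  The limits at q = 0 and q = 1 are evaluated by their explicit
#' formulas (switch threshold 1e-9) to avoid blow-up of the generic exponent.
#'
#' @param counts nonnegative count vector.
#' @param q diversity order, >= 0.
#' @return The Hill number; NA for an empty population.
#' @examples
#' hillNumber(c(50, 50), 2)   # 2
#' hillNumber(c(25, 75), 1)   # exp(Shannon) ~ 1.7548
#' @export
hillNumber <- function(counts, q) {
  .checkCounts(counts)
  if (length(q) != 1 || q < 0) stop("q must be a single number >= 0")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts[counts > 0] / tot
  if (q < 1e-9) return(length(p))
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Jaccard distance between two type supports
#'
#' Presence/absence beta diversity: one minus the ratio of shared to pooled
#' types, \eqn{1 - |S_1 \cap S_2| / |S_1 \cup S_2|}.
#'
#' @param c1,c2 count vectors over the same type index set.
#' @return Distance in [0, 1]; NA when both populations are empty.
#' @export
jaccardDistance <- function(c1, c2) {
  .checkCounts(c1); .checkCounts(c2)
  stopifnot(length(c1) == length(c2))
  if (sum(c1) == 0 && sum(c2) == 0) return(NA_real_)
  s1 <- c1 > 0; s2 <- c2 > 0
  1 - sum(s1 & s2) / sum(s1 | s2)
}

#' Bray-Curtis temporal dissimilarity
#'
#' Count-based compositional turnover
#' \eqn{\sum_k |c_{1k} - c_{2k}| / (\sum c_1 + \sum c_2)} in [0, 1]; 0 means
#' identical composition, 1 full turnover.  For a surviving supercritical
#' clone compared with itself delta time units later this index converges to
#' \code{\link{bcLimit}}, which depends only on the Malthusian parameter.
#'
#' @inheritParams jaccardDistance
#' @return Dissimilarity in [0, 1]; NA when both populations are empty.
#' @examples
#' brayCurtis(c(2, 1), c(1, 1))  # 1/5
#' @export
brayCurtis <- function(c1, c2) {
  .checkCounts(c1); .checkCounts(c2)
  stopifnot(length(c1) == length(c2))
  tot <- sum(c1) + sum(c2)
  if (tot == 0) return(NA_real_)
  sum(abs(c1 - c2)) / tot
}

#' Bhattacharyya coefficient between two compositions
#'
#' Overlap of relative abundances, \eqn{\sum_k \sqrt{p_{1k} p_{2k}}}: 1 for
#' identical proportions, 0 for disjoint supports.
#'
#' @inheritParams jaccardDistance
#' @return Coefficient in [0, 1]; NA when either population is empty.
#' @export
bhattacharyyaCoef <- function(c1, c2) {
  .checkCounts(c1); .checkCounts(c2)
  stopifnot(length(c1) == length(c2))
  t1 <- sum(c1); t2 <- sum(c2)
  if (t1 == 0 || t2 == 0) return(NA_real_)
  sum(sqrt((c1 / t1) * (c2 / t2)))
}

#' @describeIn bhattacharyyaCoef Hellinger distance
#'   \eqn{\sqrt{1 - B}} on the same pair.
#' @export
hellingerDistance <- function(c1, c2) {
  b <- bhattacharyyaCoef(c1, c2)
  if (is.na(b)) return(NA_real_)
  sqrt(max(0, 1 - b))
}

#' Proportion of similarity
#'
#' \eqn{\sum_k \min(p_{1k}, p_{2k})}, equivalently
#' \eqn{1 - \frac12 \sum_k |p_{1k} - p_{2k}|}; both forms are evaluated and
#' asserted equal.
#'
#' @inheritParams jaccardDistance
#' @return Similarity in [0, 1]; NA when either population is empty.
#' @export
proportionSimilarity <- function(c1, c2) {
  .checkCounts(c1); .checkCounts(c2)
  stopifnot(length(c1) == length(c2))
  t1 <- sum(c1); t2 <- sum(c2)
  if (t1 == 0 || t2 == 0) return(NA_real_)
  p1 <- c1 / t1; p2 <- c2 / t2
  a <- sum(pmin(p1, p2))
  b <- 1 - 0.5 * sum(abs(p1 - p2))
  stopifnot(abs(a - b) < 1e-12)
  a
}

#' Simpson concentration index
#'
#' \eqn{\sum_k p_k^2}: the probability that two cells drawn with replacement
#' belong to the same type.  Its inverse is the order-2 Hill number, used as
#' the clonal alpha-diversity measure.
#'
#' @param counts nonnegative count vector.
#' @return Index in (0, 1]; NA for an empty population.
#' @examples
#' simpsonIndex(c(3, 1))    # 10/16
#' inverseSimpson(c(1, 1))  # 2
#' @export
simpsonIndex <- function(counts) {
  .checkCounts(counts)
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  sum((counts / tot)^2)
}

#' @rdname simpsonIndex
#' @export
inverseSimpson <- function(counts) 1 / simpsonIndex(counts)

#' Asymptotic Bray-Curtis limit of a surviving clone
#'
#' Long-run Bray-Curtis dissimilarity between a supercritical clone and
#' itself \code{delta} time units later:
#' \eqn{bc(\delta, \alpha) = (1 - e^{-\alpha\delta})/(1 + e^{-\alpha\delta})},
#' increasing in \eqn{\alpha\delta} and saturating at 1.
#'
#' @param delta nonnegative time lag.
#' @param alpha Malthusian parameter.
#' @return Limit value in [0, 1).
#' @examples
#' bcLimit(log(3), 1)  # 0.5
#' @export
bcLimit <- function(delta, alpha) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  e <- exp(-alpha * delta)
  (1 - e) / (1 + e)
}

#' Malthusian parameter from a late-time Bray-Curtis value
#'
#' Exact inverse of \code{\link{bcLimit}}:
#' \eqn{\hat\alpha = \delta^{-1} \log((1 + BC)/(1 - BC))}.  Applied to the
#' observed Bray-Curtis dissimilarity of a surviving clone at a large time
#' and lag delta, it is a strongly consistent estimator of the clone's
#' Malthusian parameter.
#'
#' @param bc observed Bray-Curtis value in [0, 1).
#' @param delta positive time lag used for the comparison.
#' @return Estimated growth rate (1/time).
#' @examples
#' estimateMalthusian(bcLimit(2, 0.3), 2)  # 0.3
#' @export
estimateMalthusian <- function(bc, delta) {
  if (any(bc < 0) || any(bc >= 1)) stop("bc must lie in [0, 1)")
  if (any(delta <= 0)) stop("delta must be positive")
  log((1 + bc) / (1 - bc)) / delta
}
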