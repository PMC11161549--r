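#' Mean offspring matrix
#'
#' Entry (i, j) is the expected number of type-j daughters produced by a
#' type-i cell at the end of its lifespan:
#' \eqn{m_{ij} = (1 - p_0^i) \sum_{(a,b)} q^i_{ab} (1_{a=j} + 1_{b=j})}
#' summed over unordered pairs, so row sums equal \eqn{2(1 - p_0^i)}.
#'
#' @param model a \linkS4class{BranchingModel}.
#' @return K x K numeric matrix.
#' @examples
#' meanMatrix(singleTypeModel(0.4))  # 2 * (1 - 0.4) = 1.2
#' @export
meanMatrix <- function(model) {
  stopifnot(is(model, "BranchingModel"))
  K <- model@K
  M <- matrix(0, K, K)
  for (i in seq_len(K)) {
    o <- model@offspring[[i]]
    q <- o@pairProbs
    for (j in seq_len(K)) {
      M[i, j] <- (1 - o@p0) * (sum(q[, j]) + sum(q[j, ]))
    }
  }
  M
}

## Second factorial offspring moments beta^k_{j1 j2} = d^2 h_k / ds_j1 ds_j2
## at s = 1.  For the die-or-divide mechanism with pair probs q:
## beta_{j1 j2} = (1-p0)(q_{j1 j2} + q_{j2 j1}) for j1 != j2 and
## 2 (1-p0) q_{jj} on the diagonal (upper-triangular storage).
offspringSecondMoments <- function(model) {
  K <- model@K
  out <- vector("list", K)
  for (k in seq_len(K)) {
    o <- model@offspring[[k]]
    q <- o@pairProbs
    b <- matrix(0, K, K)
    for (j1 in seq_len(K)) for (j2 in seq_len(K)) {
      b[j1, j2] <- if (j1 == j2) 2 * q[j1, j1] else
        q[min(j1, j2), max(j1, j2)]
    }
    out[[k]] <- (1 - o@p0) * b
  }
  out
}

#' Laplace-weighted mean matrix M*(s)
#'
#' Entry (i, j) is \eqn{G_i^*(s) m_{ij}}: the mean offspring matrix with each
#' row discounted by the Laplace transform of that type's lifespan law.
#' \code{mstarMatrix(model, 0)} equals \code{meanMatrix(model)}, and entries
#' are nonincreasing in s.
#'
#' @param model a \linkS4class{BranchingModel}.
#' @param s real argument; must lie above every lifespan transform's abscissa
#'   of convergence.
#' @return K x K numeric matrix.
#' @export
mstarMatrix <- function(model, s) {
  M <- meanMatrix(model)
  g <- vapply(model@lifespan, lifespanLaplace, 0, s = s)
  g * M   # row scaling
}

## Perron-Frobenius root of a nonnegative matrix: its spectral radius, which
## by Perron-Frobenius theory is itself a (real, nonnegative) eigenvalue.
perronRoot <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

## Irreducibility of the boolean pattern of M via powers up to K.
isIrreducible <- function(M) {
  K <- nrow(M)
  B <- (M > 0) * 1
  acc <- diag(K) + B
  P <- B
  for (i in seq_len(K)) {
    P <- (P %*% B > 0) * 1
    acc <- acc + P
  }
  all(acc > 0)
}

#' Malthusian parameter and Perron eigenvectors
#'
#' Solves \eqn{\rho^*(\alpha) = 1} for the Malthusian parameter, where
#' \eqn{\rho^*(s)} is the Perron-Frobenius root of M*(s).  The map
#' \eqn{s \mapsto \rho^*(s)} is continuous and strictly decreasing, so the
#' root is located by bisection (tolerance 1e-10) inside a bracket grown
#' geometrically above the lifespan transforms' abscissa of convergence.
#' The right (u) and left (v) eigenvectors of M*(alpha) are normalized so
#' that \code{sum(u) == 1} and \code{sum(u * v) == 1}; v (rescaled to sum 1)
#' gives the limiting type composition of a surviving clone.
#'
#' @param model a \linkS4class{BranchingModel} with an irreducible mean
#'   matrix and analytic lifespan laws.
#' @return A \linkS4class{MalthusResult}.
#' @examples
#' malthusian(singleTypeModel(0.4, expLifespan(1/24)))  # alpha = 1/120
#' @export
malthusian <- function(model) {
  stopifnot(is(model, "BranchingModel"))
  M <- meanMatrix(model)
  if (!isIrreducible(M))
    stop("mean offspring matrix is reducible; no joint Malthusian analysis")
  rho <- function(s) perronRoot(mstarMatrix(model, s))
  rho0 <- rho(0)
  crit <- if (rho0 > 1 + 1e-10) "super" else if (rho0 < 1 - 1e-10) "sub"
          else "critical"

  if (crit == "critical") {
    alpha <- 0
  } else {
    lower <- max(vapply(model@lifespan, laplaceLowerBound, 0))
    if (crit == "super") {
      lo <- 0
      hi <- 1
      while (rho(hi) >= 1) hi <- 2 * hi
    } else {
      hi <- 0
      if (is.finite(lower)) {
        lo <- lower + 1e-8 * max(1, abs(lower))
        step <- (hi - lo)
        # approach the abscissa until rho exceeds 1 (root existence check)
        while (rho(lo) < 1) {
          step <- step / 2
          lo <- lo + step
          if (step < 1e-12)
            stop("no Malthusian parameter: rho*(s) stays below 1 on the ",
                 "domain of the lifespan transforms")
        }
      } else {
        lo <- -1
        while (rho(lo) < 1) {
          lo <- 2 * lo
          if (lo < -1e8) stop("no Malthusian parameter found in bracket")
        }
      }
    }
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (rho(mid) >= 1) lo <- mid else hi <- mid
    }
    alpha <- (lo + hi) / 2
  }

  Ms <- mstarMatrix(model, alpha)
  er <- eigen(Ms)
  iu <- which.max(Re(er$values))
  u <- Re(er$vectors[, iu])
  el <- eigen(t(Ms))
  iv <- which.max(Re(el$values))
  v <- Re(el$vectors[, iv])
  if (sum(u) < 0) u <- -u
  if (sum(v) < 0) v <- -v
  if (any(u <= 0) || any(v <= 0))
    stop("Perron eigenvectors not strictly positive; matrix may be reducible")
  u <- u / sum(u)
  v <- v / sum(u * v)
  new("MalthusResult", alpha = alpha, u = u, v = v, criticality = crit)
}

#' Extinction probabilities
#'
#' Smallest nonnegative fixed point of the offspring p.g.f. system
#' \eqn{s = h(s)}, computed by monotone iteration from 0.  For a single type
#' with division probability p2 the fixed point of
#' \eqn{1 - p_2 + p_2 s^2 = s} is \eqn{\min\{1, (1 - p_2)/p_2\}}.
#'
#' @param model a \linkS4class{BranchingModel}.
#' @param tol convergence tolerance (default 1e-12).
#' @return Per-type extinction probability vector (start from one cell of
#'   that type).
#' @examples
#' extinctionProbability(singleTypeModel(0.4))  # (1-0.6)/0.6 = 2/3
#' @export
extinctionProbability <- function(model, tol = 1e-12) {
  stopifnot(is(model, "BranchingModel"))
  K <- model@K
  # (sub)critical processes die out almost surely; the fixed-point iteration
  # converges only algebraically there, so short-circuit to the exact answer
  if (perronRoot(meanMatrix(model)) <= 1 + 1e-12) return(rep(1, K))
  h <- function(s) {
    vapply(seq_len(K), function(k) {
      o <- model@offspring[[k]]
      q <- o@pairProbs
      o@p0 + (1 - o@p0) * sum(q * outer(s, s))
    }, 0)
  }
  s <- rep(0, K)
  repeat {
    s2 <- h(s)
    if (max(abs(s2 - s)) < tol) break
    s <- s2
  }
  pmin(s2, 1)
}

#' Limiting type composition of a surviving clone
#'
#' In the supercritical irreducible case the type frequencies of a clone that
#' escapes extinction converge almost surely to the left Perron eigenvector
#' of M*(alpha), normalized to sum 1.
#'
#' @param model a supercritical, irreducible \linkS4class{BranchingModel}.
#' @return Frequency vector over types (sums to 1).
#' @export
stationaryComposition <- function(model) {
  mr <- malthusian(model)
  if (mr@criticality != "super")
    stop("stationary composition requires a supercritical model")
  mr@v / sum(mr@v)
}
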