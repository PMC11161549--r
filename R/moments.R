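#' Uniform time grid for the moment solvers
#'
#' @param h positive step size (time units).
#' @param horizon end of the grid.
#' @return list with \code{h}, \code{horizon} and the grid \code{times}
#'   \code{(0, h, 2h, ..., horizon)}.
#' @export
timeGrid <- function(h, horizon) {
  stopifnot(h > 0, horizon > 0)
  N <- round(horizon / h)
  if (abs(N * h - horizon) > 1e-9 * max(1, horizon))
    stop("horizon must be an integer multiple of h")
  if (N > 1e7) stop("grid too fine: horizon / h must not exceed 1e7")
  list(h = h, horizon = horizon, times = seq(0, N) * h)
}

## Per-type convolution machinery shared by the first- and second-moment
## solvers.  Density families (exponential, gamma with shape >= 1) use
## trapezoidal product integration; the fixed family contributes an exact
## atom A(t - d), linearly interpolated between grid points.
.checkSolverLifespans <- function(model) {
  for (law in model@lifespan) {
    if (law@family == "empirical")
      stop("the moment solver supports analytic lifespan families only")
    if (law@family == "gamma" && law@shape < 1)
      stop("gamma lifespans with shape < 1 have an unbounded density at 0; ",
           "not supported by the solver")
  }
}

## Linear interpolation of a (N+1) x P path matrix at time x >= 0.
.pathAt <- function(mat, h, x) {
  n <- x / h
  lo <- floor(n + 1e-12)
  w <- n - lo
  if (lo + 2 > nrow(mat)) return(mat[nrow(mat), ])
  if (w < 1e-12) mat[lo + 1, ] else
    (1 - w) * mat[lo + 1, ] + w * mat[lo + 2, ]
}

#' Mean renewal-equation solution A(t)
#'
#' Solves the first-moment Volterra system
#' \deqn{A_{kj}(t) = \sum_l m_{kl} \int_0^t A_{lj}(t-u) dG_k(u) +
#'   \delta_{kj}(1 - G_k(t))}
#' forward in time by trapezoidal product integration (global error O(h^2)).
#' \eqn{A_{kj}(t)} is the expected number of type-j cells at time t in a
#' clone founded by a single type-k cell; A(0) is the identity.
#'
#' @param model a \linkS4class{BranchingModel} with analytic lifespans.
#' @param grid a \code{\link{timeGrid}}.
#' @return list with \code{times} and \code{A}, a K x K x length(times)
#'   array.
#' @examples
#' m <- singleTypeModel(0.4, expLifespan(1))
#' sol <- solveMean(m, timeGrid(0.01, 2))
#' sol$A[1, 1, length(sol$times)]  # ~ exp((2*0.6 - 1) * 2)
#' @export
solveMean <- function(model, grid) {
  stopifnot(is(model, "BranchingModel"))
  .checkSolverLifespans(model)
  K <- model@K
  h <- grid$h
  times <- grid$times
  N <- length(times) - 1L
  M <- meanMatrix(model)

  dens <- vector("list", K)     # density values on the grid, or NULL (atom)
  atom <- rep(NA_real_, K)
  g0 <- numeric(K)
  Gt <- matrix(0, N + 1L, K)
  for (k in seq_len(K)) {
    law <- model@lifespan[[k]]
    Gt[, k] <- lifespanCDF(law, times)
    if (law@family == "fixed") atom[k] <- law@value
    else {
      dens[[k]] <- lifespanDensity(law, times)
      g0[k] <- dens[[k]][1]
    }
  }

  # implicit trapezoid coefficient for the u = 0 endpoint
  C <- matrix(0, K, K)
  for (k in seq_len(K)) if (is.na(atom[k])) C[k, ] <- (h / 2) * g0[k] * M[k, ]
  IC <- diag(K) - C

  Amat <- matrix(0, N + 1L, K * K)        # row n+1 = vec(A(t_n))
  Amat[1, ] <- as.vector(diag(K))
  for (n in seq_len(N)) {
    Rn <- matrix(0, K, K)
    rows <- seq(n + 1L - 1L, 1L)          # indices of A(t_{n-1}) ... A(0)
    for (k in seq_len(K)) {
      if (is.na(atom[k])) {
        w <- dens[[k]][2:(n + 1L)]        # g_k(t_1) ... g_k(t_n)
        w[n] <- w[n] / 2                  # trapezoid endpoint at u = t_n
        convk <- matrix(h * as.vector(crossprod(w, Amat[rows, , drop = FALSE])),
                        K, K)
      } else {
        d <- atom[k]
        convk <- if (times[n + 1L] >= d - 1e-12)
          matrix(.pathAt(Amat, h, times[n + 1L] - d), K, K)
        else matrix(0, K, K)
      }
      Rn[k, ] <- M[k, , drop = FALSE] %*% convk
    }
    Rn <- Rn + diag(1 - Gt[n + 1L, ], nrow = K)
    An <- solve(IC, Rn)
    Amat[n + 1L, ] <- as.vector(An)
  }
  A <- array(t(Amat), dim = c(K, K, N + 1L))
  list(times = times, A = A)
}

#' Second-factorial-moment renewal solution B(t)
#'
#' Solves the second-moment Volterra system with inhomogeneity built from
#' the second factorial offspring moments and the first-moment path:
#' \deqn{B^k_{ij}(t) = \sum_l m_{kl} \int_0^t B^l_{ij}(t-u) dG_k(u) +
#'   \sum_{k_1 k_2} \beta^k_{k_1 k_2} \int_0^t A_{k_1 i}(t-u)
#'   A_{k_2 j}(t-u) dG_k(u),} with B(0) = 0.
#'
#' @inheritParams solveMean
#' @param mean optional precomputed \code{solveMean(model, grid)} output.
#' @return list with \code{times}, \code{A} and \code{B} (a K x K x K x
#'   length(times) array indexed \code{[founder k, i, j, time]}), plus the
#'   variance path \code{V} (\code{[founder k, j, time]}).
#' @export
solveSecond <- function(model, grid, mean = NULL) {
  stopifnot(is(model, "BranchingModel"))
  .checkSolverLifespans(model)
  if (is.null(mean)) mean <- solveMean(model, grid)
  K <- model@K
  h <- grid$h
  times <- mean$times
  N <- length(times) - 1L
  M <- meanMatrix(model)
  beta <- offspringSecondMoments(model)

  dens <- vector("list", K)
  atom <- rep(NA_real_, K)
  g0 <- numeric(K)
  for (k in seq_len(K)) {
    law <- model@lifespan[[k]]
    if (law@family == "fixed") atom[k] <- law@value
    else {
      dens[[k]] <- lifespanDensity(law, times)
      g0[k] <- dens[[k]][1]
    }
  }
  C <- matrix(0, K, K)
  for (k in seq_len(K)) if (is.na(atom[k])) C[k, ] <- (h / 2) * g0[k] * M[k, ]
  IC <- diag(K) - C

  # source paths P_k(x) = A(x)' beta_k A(x), one (N+1) x K^2 matrix per k
  Pmat <- vector("list", K)
  for (k in seq_len(K)) {
    Pk <- matrix(0, N + 1L, K * K)
    for (n in 0:N) {
      Ax <- matrix(mean$A[, , n + 1L], K, K)
      Pk[n + 1L, ] <- as.vector(t(Ax) %*% beta[[k]] %*% Ax)
    }
    Pmat[[k]] <- Pk
  }

  Bmat <- matrix(0, N + 1L, K * K * K)  # row n+1 = vec over (k, i, j)
  idx <- function(k) ((k - 1L) * K * K + 1L):(k * K * K)
  for (n in seq_len(N)) {
    rows <- seq(n, 1L)
    Rn <- matrix(0, K, K * K)            # row k = vec_{ij} of rhs for founder k
    for (k in seq_len(K)) {
      if (is.na(atom[k])) {
        w <- dens[[k]][2:(n + 1L)]
        w[n] <- w[n] / 2
        # convolution of each founder-l B path with g_k
        convB <- matrix(0, K, K * K)
        for (l in seq_len(K)) {
          convB[l, ] <- h * as.vector(
            crossprod(w, Bmat[rows, idx(l), drop = FALSE]))
        }
        wS <- dens[[k]][2:(n + 1L)]
        wS[n] <- wS[n] / 2
        src <- h * (as.vector(crossprod(wS, Pmat[[k]][rows, , drop = FALSE])) +
                    0.5 * g0[k] * Pmat[[k]][n + 1L, ])
      } else {
        d <- atom[k]
        if (times[n + 1L] >= d - 1e-12) {
          x <- times[n + 1L] - d
          convB <- matrix(0, K, K * K)
          for (l in seq_len(K))
            convB[l, ] <- .pathAt(Bmat[, idx(l), drop = FALSE], h, x)
          src <- .pathAt(Pmat[[k]], h, x)
        } else {
          convB <- matrix(0, K, K * K)
          src <- numeric(K * K)
        }
      }
      Rn[k, ] <- as.vector(M[k, , drop = FALSE] %*% convB) + src
    }
    Bn <- solve(IC, Rn)
    for (k in seq_len(K)) Bmat[n + 1L, idx(k)] <- Bn[k, ]
  }

  B <- array(0, dim = c(K, K, K, N + 1L))
  for (k in seq_len(K))
    B[k, , , ] <- array(t(Bmat[, idx(k), drop = FALSE]), dim = c(K, K, N + 1L))
  V <- array(0, dim = c(K, K, N + 1L))   # [founder k, type j, time]
  for (k in seq_len(K)) for (j in seq_len(K))
    V[k, j, ] <- B[k, j, j, ] + mean$A[k, j, ] - mean$A[k, j, ]^2
  list(times = times, A = mean$A, B = B, V = V)
}

#' GC-level moment paths (mean and covariance of Y(t))
#'
#' Convolves the clone-level moment paths with the immigration rate:
#' \deqn{M_j(t) = \int_0^t r(t-x) \bar A_j(x) dx, \quad
#'   C_{jk}(t) = \int_0^t r(t-x) \bar C_{jk}(x) dx,}
#' with \eqn{\bar A_j = \sum_i g_i A_{ij}} and
#' \eqn{\bar C_{jk} = \sum_i g_i B^i_{jk}}.  The quadrature integrates the
#' moment path against increments of the cumulative measure R, so rates that
#' are singular at 0 (power laws with negative exponent) are handled exactly
#' in R.
#'
#' @inheritParams solveMean
#' @param spec immigration \linkS4class{RateSpec}.
#' @param weights founder type probabilities (length K).
#' @param second set TRUE to also return the covariance path (requires the
#'   second-moment solve).
#' @return list with \code{times}, \code{M} (length(times) x K mean path)
#'   and, when \code{second}, \code{C} (K x K x length(times) covariance).
#' @export
gcMoments <- function(model, spec, weights, grid, second = FALSE) {
  checkTypeWeights(weights, model@K)
  K <- model@K
  sol <- if (second) solveSecond(model, grid) else solveMean(model, grid)
  times <- sol$times
  N <- length(times) - 1L
  g <- weights

  Abar <- matrix(0, N + 1L, K)
  for (j in seq_len(K))
    Abar[, j] <- colSums(g * matrix(sol$A[, j, ], K, N + 1L))

  Rt <- cumulativeMeasure(spec, times)
  Mout <- matrix(0, N + 1L, K,
                 dimnames = list(NULL, paste0("type", seq_len(K))))
  for (n in seq_len(N)) {
    # sum_m 0.5 (Abar(x_m) + Abar(x_{m+1})) (R(t_n - x_m) - R(t_n - x_{m+1}))
    dR <- Rt[(n + 1L):2] - Rt[n:1]       # R(t_n - x_m) - R(t_n - x_{m+1})
    mid <- 0.5 * (Abar[1:n, , drop = FALSE] + Abar[2:(n + 1L), , drop = FALSE])
    Mout[n + 1L, ] <- colSums(dR * mid)
  }
  out <- list(times = times, M = Mout)

  if (second) {
    Cbar <- array(0, dim = c(K, K, N + 1L))
    for (i in seq_len(K)) Cbar <- Cbar + g[i] * sol$B[i, , , , drop = TRUE]
    if (K == 1L) Cbar <- array(g[1] * sol$B[1, , , ], dim = c(1, 1, N + 1L))
    Cout <- array(0, dim = c(K, K, N + 1L))
    Cmat <- matrix(Cbar, K * K, N + 1L)
    for (n in seq_len(N)) {
      dR <- Rt[(n + 1L):2] - Rt[n:1]
      mid <- 0.5 * (Cmat[, 1:n, drop = FALSE] +
                    Cmat[, 2:(n + 1L), drop = FALSE])
      Cout[, , n + 1L] <- matrix(mid %*% dR, K, K)
    }
    out$C <- Cout
  }
  out
}
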