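#' Lifespan distribution function G(x)
#' @param law a \linkS4class{LifespanLaw}.
#' @param x nonnegative times (vectorized).
#' @return G(x) = P(lifespan <= x).
#' @export
lifespanCDF <- function(law, x) {
  stopifnot(is(law, "LifespanLaw"))
  switch(law@family,
    exponential = stats::pexp(x, rate = law@rate),
    gamma       = stats::pgamma(x, shape = law@shape, scale = law@scale),
    fixed       = as.numeric(x >= law@value),
    empirical   = stats::ecdf(law@samples)(x))
}

## Density dG/dx for families that have one (used by the moment solver).
lifespanDensity <- function(law, x) {
  switch(law@family,
    exponential = stats::dexp(x, rate = law@rate),
    gamma       = stats::dgamma(x, shape = law@shape, scale = law@scale),
    stop("lifespan family '", law@family, "' has no density usable here"))
}

#' Laplace transform G*(s) of a lifespan law
#'
#' \eqn{G^*(s) = \int_0^\infty e^{-sx} dG(x)}, available analytically for the
#' exponential, gamma and fixed families.  The transform diverges below the
#' abscissa of convergence (-rate for exponential, -1/scale for gamma).
#'
#' @param law a \linkS4class{LifespanLaw}.
#' @param s real argument (vectorized).
#' @return G*(s).
#' @export
lifespanLaplace <- function(law, s) {
  stopifnot(is(law, "LifespanLaw"))
  switch(law@family,
    exponential = {
      if (any(s <= -law@rate)) stop("s below abscissa of convergence")
      law@rate / (law@rate + s)
    },
    gamma = {
      if (any(s <= -1 / law@scale)) stop("s below abscissa of convergence")
      (1 + law@scale * s)^(-law@shape)
    },
    fixed = exp(-s * law@value),
    stop("no analytic Laplace transform for the empirical family"))
}

## Inverse of G* on (0, 1]: the value s with G*(s) = y.  Closed forms.
lifespanLaplaceInverse <- function(law, y) {
  stopifnot(y > 0, y <= 1)
  switch(law@family,
    exponential = law@rate * (1 - y) / y,
    gamma       = (y^(-1 / law@shape) - 1) / law@scale,
    fixed       = -log(y) / law@value,
    stop("no analytic Laplace transform for the empirical family"))
}

## Lower end of the open interval on which G*(s) is finite (plus epsilon).
laplaceLowerBound <- function(law) {
  switch(law@family,
    exponential = -law@rate,
    gamma       = -1 / law@scale,
    fixed       = -Inf,
    stop("no analytic Laplace transform for the empirical family"))
}

## Draw n lifespans (uses the current RNG stream).
sampleLifespan <- function(law, n) {
  switch(law@family,
    exponential = stats::rexp(n, rate = law@rate),
    gamma       = stats::rgamma(n, shape = law@shape, scale = law@scale),
    fixed       = rep(law@value, n),
    empirical   = sample(law@samples, n, replace = TRUE))
}
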