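#' Evaluate code under a fixed RNG seed, restoring the RNG state afterwards
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Next FFT-friendly length (factors 2, 3, 5) at or above n
#' @keywords internal
nextFastLength <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2, 3, 5)) while (k %% p == 0) k <- k / p
    if (k == 1) return(m)
    m <- m + 1
  }
}

#' Sample from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' Used for per-channel phase jitter around a band's common oscillator.
#' For large concentration the wrapped-normal approximation with
#' sd = 1/sqrt(kappa) is used.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0); 0 is uniform on (-pi, pi].
#' @return numeric vector of angles in (-pi, pi].
#' @keywords internal
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  if (kappa > 100) {
    x <- stats::rnorm(n, 0, 1 / sqrt(kappa))
    return(atan2(sin(x), cos(x)))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Concentration parameter giving a target single-channel phasor length
#'
#' Solves I1(kappa)/I0(kappa) = rho for kappa. Two channels jittered
#' independently with concentration kappa around a common phase have
#' expected pairwise phase locking rho^2.
#'
#' @param rho target mean resultant length in [0, 1).
#' @return concentration kappa (Inf for rho >= 0.9999).
#' @keywords internal
kappaForResultant <- function(rho) {
  if (rho <= 0) return(0)
  if (rho >= 0.9999) return(Inf)
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - rho
  stats::uniroot(f, c(1e-6, 5000), tol = 1e-10)$root
}
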