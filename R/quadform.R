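# Tail probabilities of positive mixtures of 1-df chi-square variables,
# P(sum_k lambda_k chi^2_{1,k} > q): the null distribution of every
# quadratic-form score statistic in this package. Primary backend is
# numerical inversion of the characteristic function (Imhof's integral via
# stats::integrate); fallback is 4-moment matching to a scaled
# non-central chi-square (Liu-type), used when the inversion fails or its
# result is not a usable probability.

# Gauss-Legendre nodes/weights on (0, 1) (Golub-Welsch), cached per order
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre_01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- (e$values[ord] + 1) / 2
  weights <- 2 * e$vectors[1, ord]^2 / 2
  .gl_cache[[key]] <- list(nodes = nodes, weights = weights)
  .gl_cache[[key]]
}

imhof_integrand <- function(u, lambda, q) {
  lu <- outer(lambda, u)
  k <- length(lambda)
  theta <- 0.5 * .colSums(atan(lu), k, length(u)) - 0.5 * q * u
  logrho <- 0.25 * .colSums(log1p(lu * lu), k, length(u))
  out <- sin(theta) / (u * exp(logrho))
  out[u == 0] <- 0.5 * (sum(lambda) - q)
  out
}

imhof_tail <- function(q, lambda, tol = 1e-9) {
  res <- tryCatch(
    stats::integrate(imhof_integrand, lower = 0, upper = Inf,
                     lambda = lambda, q = q,
                     subdivisions = 1000L, abs.tol = tol,
                     stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(res) || res$message != "OK") return(NULL)
  p <- 0.5 + res$value / pi
  attr(p, "abs.error") <- res$abs.error
  p
}

# Batch Imhof evaluation: many statistic values against one eigenvalue
# set. Amplitude and base phase are shared across q's, so the inversion
# integral is evaluated once on a common grid (composite Simpson on
# [0, U], U chosen so the amplitude envelope is negligible beyond it).
imhof_tail_multi <- function(qs, lambda, tol = 1e-6) {
  s <- max(lambda)
  l <- lambda / s
  qs <- qs / s
  # truncate where the integrated oscillatory tail (envelope / phase
  # speed, by one integration by parts) is below tol; the leading
  # endpoint term is added back as a correction
  q_min <- max(min(qs), 0.5)
  U <- 1
  env <- function(u) exp(-0.25 * sum(log1p(l^2 * u^2))) / u
  it <- 0
  while (env(U) / (0.5 * q_min) > tol / 5 && it < 200) {
    U <- U * 1.4; it <- it + 1
  }
  # resolve the fastest oscillation 0.5 * max(q) * u
  n_osc <- max(qs, 1) * U / (4 * pi)
  N <- min(max(501L, as.integer(16 * n_osc) %/% 2L * 2L + 1L), 100001L)
  u <- seq(0, U, length.out = N)
  lu <- outer(l, u[-1])
  k <- length(l)
  theta0 <- c(0, 0.5 * .colSums(atan(lu), k, N - 1L))
  amp <- c(0, exp(-0.25 * .colSums(log1p(lu * lu), k, N - 1L)) / u[-1])
  h <- u[2] - u[1]
  wsimp <- rep(c(4, 2), length.out = N - 2L)
  dtheta0_U <- 0.5 * sum(l / (1 + (l * U)^2))
  vapply(qs, function(q) {
    f <- sin(theta0 - 0.5 * q * u) * amp
    f[1] <- 0.5 * (sum(l) - q)
    v <- h / 3 * (f[1] + sum(wsimp * f[2:(N - 1L)]) + f[N])
    # endpoint term of the integrated-by-parts tail beyond U
    v <- v + amp[N] * cos(theta0[N] - 0.5 * q * U) /
      (0.5 * q - dtheta0_U)
    min(max(0.5 + v / pi, 0), 1)
  }, numeric(1))
}

liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2; a <- sqrt(l); d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), l = l, d = d,
       muX = l + d, sigmaX = sqrt(2) * sqrt(l + 2 * d))
}

liu_tail <- function(q, lambda) {
  p <- liu_params(lambda)
  qn <- (q - p$muQ) / p$sigmaQ * p$sigmaX + p$muX
  stats::pchisq(qn, df = p$l, ncp = p$d, lower.tail = FALSE)
}

liu_quantile <- function(prob_tail, lambda) {
  p <- liu_params(lambda)
  q0 <- stats::qchisq(prob_tail, df = p$l, ncp = p$d, lower.tail = FALSE)
  (q0 - p$muX) / p$sigmaX * p$sigmaQ + p$muQ
}

#' Upper tail probability of a weighted chi-square(1) mixture
#'
#' Computes \eqn{P(\sum_k \lambda_k \chi^2_{1,k} > q)} by numerical
#' inversion of the characteristic function, with a 4-moment-matching
#' fallback. The backend actually used is recorded in the
#' \code{"backend"} attribute (\code{"exact-mixture"} or
#' \code{"moment-approx"}).
#'
#' @param lambda nonnegative mixture weights (eigenvalues), not all zero.
#' @param q observed statistic value.
#' @param tol absolute error target for the numerical inversion.
#' @return the tail probability in [0, 1], with attribute \code{backend}.
#' @export
pvalue_quadform <- function(lambda, q, tol = 1e-9) {
  if (any(!is.finite(lambda)) || !is.finite(q))
    stop("non-finite input to pvalue_quadform", call. = FALSE)
  if (any(lambda < -1e-8 * max(abs(lambda))))
    stop("mixture weights must be nonnegative", call. = FALSE)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0)
    stop("all mixture weights are zero", call. = FALSE)
  if (q <= 0) return(structure(1, backend = "exact-mixture"))
  if (length(lambda) == 1) {
    p <- stats::pchisq(q / lambda, df = 1, lower.tail = FALSE)
    return(structure(p, backend = "exact-mixture"))
  }
  p <- imhof_tail(q, lambda, tol = tol)
  usable <- !is.null(p) && is.finite(p) && p > tol && p < 1 + 1e-8 &&
    attr(p, "abs.error") <= max(tol, 0.01 * max(p, .Machine$double.eps))
  if (usable)
    return(structure(min(as.numeric(p), 1), backend = "exact-mixture"))
  # adaptive scheme failed (oscillatory slow decay, e.g. k = 2):
  # fixed-grid inversion before surrendering to the moment approximation
  p2 <- imhof_tail_multi(q, lambda, tol = min(tol * 100, 1e-6))
  if (is.finite(p2) && p2 > 100 * tol && p2 < 1)
    return(structure(p2, backend = "exact-mixture"))
  structure(liu_tail(q, lambda), backend = "moment-approx")
}
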