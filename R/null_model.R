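# Null phenotype model shared by all region and marker tests:
# g(E[Y_i]) = Z_i alpha, i.e. the association model with the genetic term
# left out. Region tests are score tests against this null, so it is
# fitted once per dataset and reused across genes and windows.

#' Fit the phenotype-on-covariates null model
#'
#' Binary phenotypes are fitted by logistic regression (IRLS via
#' \code{stats::glm.fit}); continuous phenotypes by ordinary least squares.
#' The returned object carries the fitted means, residuals, variance
#' weights and covariate projection pieces needed by the score tests.
#'
#' @param phenotype numeric vector; 0/1 for \code{kind = "binary"}.
#' @param covariates optional numeric matrix/data.frame of non-genetic
#'   covariates (an intercept is always added).
#' @param kind \code{"binary"} or \code{"continuous"}.
#' @return an object of class \code{inco_null}.
#' @export
fit_null <- function(phenotype, covariates = NULL,
                     kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  y <- as.numeric(phenotype)
  if (anyNA(y)) stop("missing phenotype values are not allowed", call. = FALSE)
  n <- length(y)
  X <- cbind("(Intercept)" = rep(1, n))
  if (!is.null(covariates)) {
    Z <- as.matrix(covariates)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
    if (anyNA(Z)) stop("missing covariate values are not allowed",
                       call. = FALSE)
    X <- cbind(X, Z)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; redundant column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (kind == "binary") {
    if (!all(y %in% c(0, 1)))
      stop("binary phenotype must be coded 0/1", call. = FALSE)
    if (length(unique(y)) < 2)
      stop("binary phenotype has a single level", call. = FALSE)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    if (!fit$converged)
      stop("logistic null model did not converge", call. = FALSE)
    mu <- fit$fitted.values
    if (any(mu < 1e-10 | mu > 1 - 1e-10))
      stop("fitted probabilities numerically 0 or 1 (separation?)",
           call. = FALSE)
    v <- mu * (1 - mu)
    sigma2 <- NA_real_
  } else {
    fit <- stats::lm.fit(X, y)
    mu <- fit$fitted.values
    sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
    if (sigma2 <= 0) stop("residual variance is zero", call. = FALSE)
    v <- rep(sigma2, n)
  }
  structure(list(kind = kind, y = y, X = X, mu = mu, resid = y - mu,
                 v = v, sigma2 = sigma2,
                 XtVX_inv = solve(crossprod(X, X * v)),
                 coef = fit$coefficients, converged = TRUE, n = n),
            class = "inco_null")
}

#' @export
print.inco_null <- function(x, ...) {
  cat("inco_null (", x$kind, "): n =", x$n, ", covariates =",
      ncol(x$X) - 1, "\n")
  invisible(x)
}

# Score-statistic building blocks for a marker matrix G (n x m):
#   S = G'(y - mu)
#   K = G' P0 G,  P0 = V - V X (X'VX)^{-1} X'V   (V = diag of variance weights)
# K is the null covariance of S; everything downstream (Q statistics,
# mixture weights) is a function of (S, K).
score_prep <- function(null, G) {
  VG <- G * null$v
  XtVG <- crossprod(null$X, VG)
  K <- crossprod(G, VG) - crossprod(XtVG, null$XtVX_inv %*% XtVG)
  S <- drop(crossprod(G, null$resid))
  list(S = S, K = K)
}
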