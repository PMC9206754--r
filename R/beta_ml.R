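#' Variable-dispersion beta regression by maximum likelihood
#'
#' Fits `y ~ Beta(mu * phi, (1 - mu) * phi)` with `logit(mu) = X beta`
#' and `log(phi) = Z gamma`, by BFGS with analytic gradients. Supports
#' observation weights (case weights on the log likelihood) and
#' cluster-robust (sandwich) standard errors for repeatedly sampled
#' hosts. This is the engine behind the per-taxon relative-abundance
#' trend models, the evenness model and the personalization model.
#'
#' @param y response strictly inside (0, 1) (apply
#'   [smithson_transform()] first if boundary values occur).
#' @param X design matrix of the logit-mean submodel (with intercept).
#' @param Z design matrix of the log-precision submodel (default
#'   intercept only).
#' @param weights optional non-negative case weights (internally
#'   normalized to mean 1 so the effective sample size stays `n`).
#' @param cluster optional factor for cluster-robust covariance.
#' @param start optional starting values `c(beta, gamma)`.
#' @param maxit BFGS iteration cap.
#' @return object of class `beta_ml`: coefficients (`mean`,
#'   `precision`), `logLik`, `vcov`, `vcov_cluster`, fitted `mu`/`phi`,
#'   `pearson_dispersion`, `converged`.
#' @export
beta_ml <- function(y, X, Z = NULL, weights = NULL, cluster = NULL,
                    start = NULL, maxit = 1000) {
  n <- length(y)
  X <- as.matrix(X)
  if (is.null(Z)) Z <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Z <- as.matrix(Z)
  if (any(y <= 0 | y >= 1)) stop("responses must lie strictly inside (0, 1)")
  w <- if (is.null(weights)) rep(1, n) else weights * n / sum(weights)
  p <- ncol(X); q <- ncol(Z)
  ylog <- log(y); y1log <- log1p(-y); ystar <- ylog - y1log

  nll <- function(par) {
    eta <- drop(X %*% par[1:p]); zeta <- drop(Z %*% par[p + 1:q])
    mu <- stats::plogis(eta); phi <- exp(zeta)
    a <- mu * phi; b <- (1 - mu) * phi
    ll <- lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * ylog + (b - 1) * y1log
    if (any(!is.finite(ll))) return(1e10)
    -sum(w * ll)
  }
  grad <- function(par) {
    eta <- drop(X %*% par[1:p]); zeta <- drop(Z %*% par[p + 1:q])
    mu <- stats::plogis(eta); phi <- exp(zeta)
    a <- mu * phi; b <- (1 - mu) * phi
    mustar <- digamma(a) - digamma(b)
    gb <- w * phi * (ystar - mustar) * mu * (1 - mu)
    gg <- w * phi * (mu * (ystar - mustar) + y1log - digamma(b) + digamma(phi))
    -c(drop(crossprod(X, gb)), drop(crossprod(Z, gg)))
  }

  if (is.null(start)) {
    b0 <- tryCatch(stats::lm.wfit(X, ystar, w)$coefficients, error = function(e) NULL)
    if (is.null(b0) || any(!is.finite(b0))) b0 <- c(stats::qlogis(mean(y)), rep(0, p - 1))
    mu0 <- stats::plogis(drop(X %*% b0))
    v <- stats::var(y)
    phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-6) - 1, 1.5)
    start <- c(b0, log(phi0), rep(0, q - 1))
  }
  opt <- stats::optim(start, nll, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12), hessian = TRUE)
  par <- opt$par
  eta <- drop(X %*% par[1:p]); zeta <- drop(Z %*% par[p + 1:q])
  mu <- stats::plogis(eta); phi <- exp(zeta)
  gn <- sqrt(sum(grad(par)^2))
  converged <- opt$convergence == 0 && gn < 1e-3 * max(1, abs(opt$value))
  vc <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, p + q, p + q))
  # per-observation score contributions for the sandwich meat
  a <- mu * phi; b <- (1 - mu) * phi
  mustar <- digamma(a) - digamma(b)
  sb <- w * phi * (ystar - mustar) * mu * (1 - mu)
  sg <- w * phi * (mu * (ystar - mustar) + y1log - digamma(b) + digamma(phi))
  S <- cbind(X * sb, Z * sg)
  vcc <- NULL
  if (!is.null(cluster)) {
    cl <- as.factor(cluster)
    Sc <- rowsum(S, cl)
    G <- nlevels(cl)
    meat <- crossprod(Sc) * G / max(G - 1, 1)
    vcc <- vc %*% meat %*% vc
  }
  pear <- sum(w * (y - mu)^2 / (mu * (1 - mu) / (1 + phi))) / (n - p - q)
  nm <- c(colnames(X), paste0("disp_", colnames(Z)))
  dimnames(vc) <- list(nm, nm)
  structure(list(coefficients = list(mean = stats::setNames(par[1:p], colnames(X)),
                                     precision = stats::setNames(par[p + 1:q], colnames(Z))),
                 par = stats::setNames(par, nm),
                 logLik = -opt$value, vcov = vc, vcov_cluster = vcc,
                 mu = mu, phi = phi, y = y, X = X, Z = Z, weights = w,
                 pearson_dispersion = pear, converged = converged,
                 gradient_norm = gn, df = p + q),
            class = "beta_ml")
}

#' @export
logLik.beta_ml <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
coef.beta_ml <- function(object, ...) object$par

#' @export
vcov.beta_ml <- function(object, cluster_robust = FALSE, ...) {
  if (cluster_robust) {
    if (is.null(object$vcov_cluster)) stop("fit carries no cluster structure")
    object$vcov_cluster
  } else object$vcov
}

#' @export
print.beta_ml <- function(x, ...) {
  cat("Variable-dispersion beta regression (ML)\n")
  cat("logLik:", format(x$logLik, digits = 6),
      " converged:", x$converged, "\n")
  vc <- x$vcov_cluster %||% x$vcov
  se <- sqrt(pmax(diag(vc), 0))
  tab <- cbind(Estimate = x$par, `Std.Error` = se,
               z = x$par / se,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(x$par / se)))
  stats::printCoefmat(tab, ...)
  invisible(x)
}

#' Likelihood-ratio test between nested beta fits
#'
#' Optionally corrects the statistic for overdispersion by dividing it by
#' the full model's Pearson chi-square/df ratio when that ratio exceeds 1.
#'
#' @param full,reference nested [beta_ml()] fits (full must nest reference).
#' @param overdispersion_correct apply the Pearson-ratio correction.
#' @return list `statistic, df, p, dispersion_ratio`.
#' @export
lrt_beta_ml <- function(full, reference, overdispersion_correct = TRUE) {
  stat <- 2 * (full$logLik - reference$logLik)
  df <- full$df - reference$df
  if (df <= 0) stop("models are not nested in the expected direction")
  ratio <- if (overdispersion_correct) max(1, full$pearson_dispersion) else 1
  list(statistic = stat, df = df,
       p = stats::pchisq(stat / ratio, df, lower.tail = FALSE),
       dispersion_ratio = ratio)
}

# parametric bootstrap percentile CIs for a beta_ml fit
beta_ml_boot_ci <- function(fit, n_boot = 1000, seed = 1L, level = 0.95) {
  if (n_boot <= 0) return(NULL)
  draws <- withr::with_seed(seed, {
    replicate(n_boot, {
      ystar <- stats::rbeta(length(fit$y), fit$mu * fit$phi, (1 - fit$mu) * fit$phi)
      ystar <- pmin(pmax(ystar, 1e-10), 1 - 1e-10)
      bf <- tryCatch(beta_ml(ystar, fit$X, fit$Z, weights = fit$weights,
                             start = fit$par),
                     error = function(e) NULL)
      if (is.null(bf)) rep(NA_real_, length(fit$par)) else bf$par
    })
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 1, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE))
  rownames(ci) <- names(fit$par)
  ci
}
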