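#' Marginal logistic regression with clustered data (GEE)
#'
#' Fits a population-averaged logistic model by generalized estimating
#' equations with an independence or exchangeable working correlation and
#' reports robust (sandwich) standard errors. Written for cluster-randomized
#' observational structures such as patients nested in providers; with an
#' independence working correlation and singleton clusters the estimates
#' coincide with ordinary logistic maximum likelihood.
#'
#' The exchangeable correlation parameter is re-estimated each iteration by
#' the usual moment estimator on standardized Pearson residuals; cluster
#' inversions use the closed form for `(1-a)I + aJ`, so fits scale to large
#' clusters.
#'
#' @param formula model formula with a 0/1 (or logical) response.
#' @param data data frame; rows with missing values in any model variable
#'   are dropped listwise (count recorded in the fit).
#' @param id cluster identifier: a column name in `data` or a vector.
#' @param corstr working correlation, `"exchangeable"` or `"independence"`.
#' @param maxit,tol iteration cap and convergence tolerance on the maximum
#'   absolute coefficient update.
#' @return object of class `gee_fit` with elements `coefficients`, `vcov`
#'   (robust), `alpha`, `phi`, `n_used`, `n_dropped`, `n_clusters`,
#'   `corstr`, `converged`, `iterations`.
#' @examples
#' d <- data.frame(y = rbinom(200, 1, 0.4), x = rnorm(200),
#'                 g = rep(1:20, each = 10))
#' fit <- gee_logit(y ~ x, d, id = "g")
#' coef(fit)
#' @export
gee_logit <- function(formula, data, id,
                      corstr = c("exchangeable", "independence"),
                      maxit = 50, tol = 1e-10) {
  corstr <- match.arg(corstr)
  if (is.character(id) && length(id) == 1) {
    if (!id %in% names(data)) stop_model("cluster column not found: ", id)
    idv <- data[[id]]
  } else {
    idv <- id
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.pass)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  keep <- stats::complete.cases(X, y, idv)
  n_dropped <- sum(!keep)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  g <- factor(idv[keep])
  n <- length(y)
  p <- ncol(X)
  if (n == 0) stop_model("no complete cases")
  if (!all(y %in% c(0, 1))) stop_model("response must be binary 0/1")
  if (length(unique(y)) < 2) {
    stop_model("degenerate outcome: response is constant")
  }
  if (nlevels(g) < 2) stop_model("need at least 2 clusters; got ",
                                 nlevels(g))

  ni <- as.vector(table(g))
  npair <- sum(ni * (ni - 1)) / 2

  # initialize at the independence (ordinary logistic) solution
  beta <- tryCatch(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients,
    error = function(e) rep(0, p))
  if (any(!is.finite(beta))) beta <- rep(0, p)

  alpha <- 0
  phi <- 1
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    v <- mu * (1 - mu)
    v <- pmax(v, 1e-12)
    sv <- sqrt(v)
    e <- (y - mu) / sv
    phi <- sum(e^2) / (n - p)
    if (corstr == "exchangeable" && npair > p) {
      S <- as.vector(rowsum(e, g))
      Q <- as.vector(rowsum(e^2, g))
      alpha <- sum(S^2 - Q) / 2 / (phi * (npair - p))
      alpha <- min(max(alpha, 0), 0.95)
    } else {
      alpha <- 0
    }
    Z <- X * sv
    ZG <- rowsum(Z, g)                     # cluster sums of Z
    rG <- as.vector(rowsum(e, g))          # cluster sums of residuals
    ci <- alpha / (1 + (ni - 1) * alpha)   # J-term weight per cluster
    B <- (crossprod(Z) - crossprod(ZG * sqrt(ci))) / (1 - alpha)
    G <- (crossprod(Z, e) - crossprod(ZG, ci * rG)) / (1 - alpha)
    delta <- tryCatch(solve(B, G), error = function(e2)
      stop_model("singular working information at iteration ", it))
    beta <- beta + as.vector(delta)
    trace <- c(trace, max(abs(delta)))
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop_model("GEE did not converge in ", maxit,
               " iterations; |update| trace: ",
               paste(signif(utils::tail(trace, 5), 3), collapse = ", "))
  }

  # robust sandwich covariance at the solution
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  sv <- sqrt(pmax(mu * (1 - mu), 1e-12))
  e <- (y - mu) / sv
  Z <- X * sv
  ZG <- rowsum(Z, g)
  rG <- as.vector(rowsum(e, g))
  ci <- alpha / (1 + (ni - 1) * alpha)
  B <- (crossprod(Z) - crossprod(ZG * sqrt(ci))) / (1 - alpha)
  U <- (rowsum(Z * e, g) - ZG * (ci * rG)) / (1 - alpha)  # per-cluster scores
  Binv <- solve(B)
  V <- Binv %*% crossprod(U) %*% Binv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)

  structure(list(coefficients = beta, vcov = V, alpha = alpha, phi = phi,
                 n_used = n, n_dropped = n_dropped, n_clusters = nlevels(g),
                 corstr = corstr, converged = converged, iterations = it,
                 formula = formula),
            class = "gee_fit")
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' @export
print.gee_fit <- function(x, ...) {
  cat("<gee_fit> logit link,", x$corstr, "working correlation\n")
  cat("  n =", x$n_used, "(", x$n_dropped, "dropped ), clusters =",
      x$n_clusters, ", alpha =", signif(x$alpha, 4), "\n")
  print(tidy_gee(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a GEE fit on the odds-ratio scale
#'
#' @param fit a `gee_fit`.
#' @param conf_level confidence level (default 0.95, Wald on the log scale).
#' @return data frame: `term`, `log_or`, `se`, `or`, `ci_low`, `ci_high`,
#'   `p`.
#' @export
tidy_gee <- function(fit, conf_level = 0.95) {
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- b / se
  data.frame(term = names(b), log_or = unname(b), se = unname(se),
             or = exp(unname(b)),
             ci_low = exp(unname(b - zq * se)),
             ci_high = exp(unname(b + zq * se)),
             p = 2 * stats::pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}
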