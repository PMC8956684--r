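#' Ridge-stabilized logistic regression
#'
#' Fits a logistic regression by penalized iteratively reweighted least squares
#' (Newton steps with step-halving). A fixed, very small ridge penalty is put on
#' the slopes (never on the intercept) so that the fit returns finite
#' coefficients even under complete separation, which happens routinely when
#' small models are fitted on highly discriminative expression features. The
#' penalty (default 1e-6 on standardized inputs) is far below the sampling noise
#' of any coefficient reported by the package and does not change 0.5-cutoff
#' classifications.
#'
#' @param x numeric matrix of predictors (n x d); may have zero columns for an
#'   intercept-only model. Columns should be on comparable scales (the package
#'   standardizes upstream).
#' @param y binary response, 0/1 (or logical).
#' @param ridge ridge penalty applied to slopes.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the step size.
#' @return list with `coefficients` (intercept first), `fitted`, `converged`,
#'   `separated` (complete-separation flag), `iterations`.
#' @examples
#' x <- matrix(rnorm(60), 30, 2)
#' y <- rbinom(30, 1, plogis(x[, 1]))
#' fit_logit(x, y)$coefficients
#' @export
fit_logit <- function(x, y, ridge = 1e-6, max_iter = 100L, tol = 1e-9) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  storage.mode(x) <- "double"
  n <- length(y)
  stopifnot(nrow(x) == n)
  d <- ncol(x)
  xd <- cbind(`(Intercept)` = 1, x)
  pen <- c(0, rep(ridge, d))
  beta <- c(qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), rep(0, d))

  pll <- function(b) {
    eta <- drop(xd %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * sum(pen * b^2)
  }
  ll <- pll(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(xd, y - mu)) - pen * beta
    hess <- crossprod(xd * w, xd)
    diag(hess) <- diag(hess) + pen
    step <- solve(hess, grad)
    # step-halving keeps the penalized log-likelihood monotone under separation
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- pll(cand)
      if (llc >= ll - 1e-12 || lam < 1e-4) break
      lam <- lam / 2
    }
    beta <- cand
    moved <- max(abs(lam * step))
    ll <- llc
    if (moved < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(xd %*% beta)
  separated <- d > 0L && any(y == 1) && any(y == 0) &&
    min(eta[y == 1]) > max(eta[y == 0]) &&
    min(plogis(eta[y == 1])) > 1 - 1e-4 && max(plogis(eta[y == 0])) < 1e-4
  names(beta) <- colnames(xd)
  structure(
    list(coefficients = beta, fitted = plogis(eta), converged = converged,
         separated = separated, iterations = it, ridge = ridge),
    class = "sw_logit"
  )
}

#' Predict probabilities from a ridge-stabilized logistic fit
#'
#' @param object a fit from [fit_logit()].
#' @param newx matrix of predictors with the same columns as the training data.
#' @param ... unused.
#' @return vector of probabilities in \[0, 1\].
#' @export
predict.sw_logit <- function(object, newx, ...) {
  b <- object$coefficients
  if (is.null(dim(newx))) newx <- matrix(newx, ncol = length(b) - 1L)
  drop(plogis(b[1L] + newx %*% b[-1L]))
}
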