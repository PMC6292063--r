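#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so that package functions taking
#' a `seed` argument do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Derive a deterministic substream seed
#'
#' One master seed spawns independent per-stage, per-replicate substreams so
#' that adding a method or replicate does not perturb the draws of another.
#' A small integer hash (splitmix-style mixing, reduced mod 2^31 - 1) keyed on
#' the master seed and any number of string/integer labels.
#'
#' @param seed master integer seed.
#' @param ... labels (strings or integers) identifying the substream.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  labs <- unlist(lapply(list(...), as.character))
  h <- as.double(seed) %% 2147483647
  for (lab in labs) {
    for (ch in utf8ToInt(lab)) {
      h <- (h * 31 + ch) %% 2147483647
    }
    h <- (h * 2654435761) %% 2147483647
  }
  as.integer(h %% 2147483645L + 1L)
}

logit <- function(p) log(p / (1 - p))
expit <- function(x) stats::plogis(x)

#' Draw from an inverse-Wishart distribution
#'
#' If `W ~ Wishart(df, S^{-1})` then `W^{-1} ~ InvWishart(df, S)`.
#'
#' @param df degrees of freedom, must be >= nrow(S).
#' @param S positive-definite scale matrix.
#' @return a draw (matrix) from InvWishart(df, S).
#' @keywords internal
rinvwishart <- function(df, S) {
  d <- nrow(S)
  if (df < d) stop("inverse-Wishart degrees of freedom below dimension")
  W <- stats::rWishart(1L, df, chol2inv(chol(S)))[, , 1L]
  chol2inv(chol(W))
}

#' Posterior draw from a Bayesian normal linear regression
#'
#' The standard proper-imputation device: draw sigma^2 from its scaled
#' inverse-chi-square posterior, then coefficients from their conditional
#' normal. A small ridge keeps the cross-product invertible under
#' collinearity.
#'
#' @param X design matrix (complete rows).
#' @param y response vector.
#' @param ridge ridge added to the diagonal of X'X (relative scale).
#' @return list with `beta` (coefficient draw), `sigma` (residual SD draw).
#' @keywords internal
bayes_lm_draw <- function(X, y, ridge = 1e-5) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X)
  diag(XtX) <- diag(XtX) * (1 + ridge) + ridge
  R <- chol(XtX)
  bhat <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  rss <- sum((y - X %*% bhat)^2)
  dfres <- max(n - p, 1L)
  sigma2 <- rss / stats::rchisq(1L, dfres)
  z <- stats::rnorm(p)
  beta <- bhat + sqrt(sigma2) * backsolve(R, z)
  list(beta = drop(beta), sigma = sqrt(sigma2))
}

#' Approximate posterior draw from a ridge-penalised logistic regression
#'
#' Coefficients are the penalised MLE plus a normal perturbation with the
#' asymptotic covariance — the usual chained-equations device for binary
#' targets. The ridge guards against perfect separation.
#'
#' @param X design matrix (complete rows).
#' @param y 0/1 response.
#' @param ridge penalty added to the information diagonal.
#' @param maxit IRLS iteration cap.
#' @param start optional warm-start coefficients.
#' @return list with `beta` (posterior draw), `mle`, and `separation` flag.
#' @keywords internal
bayes_logit_draw <- function(X, y, ridge = 1e-4, maxit = 25L, start = NULL) {
  p <- ncol(X)
  beta <- if (is.null(start)) numeric(p) else start
  separation <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- expit(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-10)) w <- pmax(w, 1e-10)
    info <- crossprod(X * w, X)
    diag(info) <- diag(info) + ridge
    score <- crossprod(X, y - mu) - ridge * beta
    R <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(R)) { separation <- TRUE; break }
    step <- backsolve(R, forwardsolve(t(R), score))
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  if (max(abs(beta)) > 25) separation <- TRUE
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  w <- pmax(expit(eta) * (1 - expit(eta)), 1e-10)
  info <- crossprod(X * w, X)
  diag(info) <- diag(info) + ridge
  R <- chol(info)
  draw <- beta + backsolve(R, stats::rnorm(p))
  list(beta = drop(draw), mle = drop(beta), separation = separation)
}
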