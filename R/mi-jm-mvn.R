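#' Multivariate-normal data augmentation (JM-MVN)
#'
#' Imputation under an unstructured multivariate normal for the wide data
#' matrix, treating repeated measurements as distinct variables and binary
#' variables as continuous. The sampler alternates an I-step — drawing the
#' missing cells of each missingness pattern from their conditional normal
#' given the observed cells and current (mu, Sigma) — with a P-step drawing
#' (mu, Sigma) from the normal-inverse-Wishart posterior under a
#' Jeffreys-type prior: `Sigma ~ IW(n - 1, S)` with S the centred
#' cross-product of the completed data, then `mu ~ N(ybar, Sigma / n)`.
#' Imputations are retained every `between_draws` iterations after
#' `burn_in`, from a single chain.
#'
#' @param cohort an amputed [cohort_table()].
#' @param config an [mi_config()].
#' @param seed integer seed.
#' @return an [imputation_set()].
#' @export
jm_mvn <- function(cohort, config = mi_config("JM-MVN"), seed = 1L) {
  em <- engine_matrix(cohort)
  Y <- em$Y; miss <- em$miss
  n <- nrow(Y); p <- ncol(Y)
  pat_key <- apply(miss, 1L, function(z) paste(as.integer(z), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  pats <- pats[vapply(pats, function(ix) any(miss[ix[1L], ]), logical(1))]

  n_iter <- config$burn_in + config$m * config$between_draws
  keep_at <- config$burn_in + seq_len(config$m) * config$between_draws
  trace <- matrix(NA_real_, n_iter, 2L,
                  dimnames = list(NULL, c("mean_imputed", "logdet_sigma")))
  imps <- vector("list", config$m)

  with_seed(seed, {
    Y <- marginal_fill(Y, miss)
    k <- 0L
    for (it in seq_len(n_iter)) {
      # P-step
      ybar <- colMeans(Y)
      S <- crossprod(sweep(Y, 2L, ybar))
      Sigma <- tryCatch(rinvwishart(n - 1L, S), error = function(e) {
        message("jm_mvn: singular covariance; applying ridge fallback")
        rinvwishart(n - 1L, S + diag(1e-6 * mean(diag(S)), p))
      })
      Rmu <- chol(Sigma)
      mu <- ybar + drop(stats::rnorm(p) %*% Rmu) / sqrt(n)
      # I-step, per missingness pattern
      for (ix in pats) {
        mset <- which(miss[ix[1L], ]); oset <- which(!miss[ix[1L], ])
        Roo <- chol(Sigma[oset, oset, drop = FALSE])
        W <- backsolve(Roo, forwardsolve(t(Roo),
                         Sigma[oset, mset, drop = FALSE]))
        resid <- sweep(Y[ix, oset, drop = FALSE], 2L, mu[oset])
        cmean <- sweep(resid %*% W, 2L, mu[mset], `+`)
        ccov <- Sigma[mset, mset, drop = FALSE] -
          crossprod(Sigma[oset, mset, drop = FALSE], W)
        ccov <- (ccov + t(ccov)) / 2
        Rc <- chol(ccov + diag(1e-12, length(mset)))
        Z <- matrix(stats::rnorm(length(ix) * length(mset)), length(ix))
        Y[ix, mset] <- cmean + Z %*% Rc
      }
      trace[it, ] <- c(mean(Y[miss]), 2 * sum(log(diag(Rmu))))
      if (it %in% keep_at) {
        k <- k + 1L
        imps[[k]] <- rebuild_cohort(cohort, Y)
      }
    }
  })
  imputation_set(imps, cohort, config, seed,
                 diagnostics = as.data.frame(trace))
}
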