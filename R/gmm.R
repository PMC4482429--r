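#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximisation on end-point damage values with `k` components,
#' run to convergence (relative log-likelihood change below `tol`) from
#' `restarts` random initialisations; the best log-likelihood fit is kept.
#' Component variances are floored at `1e-6` times the sample variance so
#' a cluster collapsing onto identical values restarts instead of
#' degenerating. Scores follow the information criteria for a 1-D mixture
#' with `p = 3k - 1` free parameters: `AIC = 2p - 2 lnL`,
#' `BIC = p ln(n) - 2 lnL`.
#'
#' @param values numeric vector of end-point total damages (needs at least
#'   `10 * k` observations).
#' @param k number of Gaussian components.
#' @param tol convergence tolerance on the log-likelihood.
#' @param restarts number of random restarts.
#' @param max_iter EM iteration cap per restart.
#' @param seed seed for the restart initialisations.
#' @return an `outcome_gmm`: weights, means, variances, `loglik`, `aic`,
#'   `bic`, `k`, `n` and the posterior responsibility matrix.
#' @export
fit_gmm <- function(values, k, tol = 1e-8, restarts = 20, max_iter = 500,
                    seed = 1L) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 10 * k)
    stop("need at least 10*k = ", 10 * k, " values to fit k = ", k,
         " components")
  svar <- stats::var(x)
  if (!is.finite(svar) || svar == 0) svar <- 1
  floor_var <- 1e-6 * svar

  em_once <- function(mu0) {
    w <- rep(1 / k, k); mu <- mu0; s2 <- rep(svar, k)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j)
        w[j] * stats::dnorm(x, mu[j], sqrt(s2[j])), numeric(n))
      dens <- matrix(dens, nrow = n)
      rs <- rowSums(dens)
      rs[rs < 1e-300] <- 1e-300
      ll <- sum(log(rs))
      resp <- dens / rs
      nk <- colSums(resp)
      nk[nk < 1e-12] <- 1e-12
      w <- nk / n
      mu <- colSums(resp * x) / nk
      s2 <- vapply(seq_len(k), function(j)
        sum(resp[, j] * (x - mu[j])^2) / nk[j], numeric(1))
      s2 <- pmax(s2, floor_var)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
      ll_old <- ll
    }
    list(w = w, mu = mu, s2 = s2, loglik = ll, resp = resp)
  }

  # seed the restart draws without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- sample(x, k)
    fit <- em_once(mu0)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$mu)
  p <- 3 * k - 1
  structure(list(k = k, n = n,
                 weights = best$w[ord], means = best$mu[ord],
                 variances = best$s2[ord], loglik = best$loglik,
                 aic = 2 * p - 2 * best$loglik,
                 bic = p * log(n) - 2 * best$loglik,
                 posteriors = best$resp[, ord, drop = FALSE]),
            class = "outcome_gmm")
}

#' Select the mixture order by information criteria
#'
#' Fits k = 1..4 components and returns the minimum-BIC model; the result
#' records the AIC-selected order too and whether the two criteria agree.
#'
#' @param values end-point damage values.
#' @param k_range candidate component counts.
#' @param ... passed to [fit_gmm()].
#' @return the selected `outcome_gmm`, with attributes `k_bic`, `k_aic`,
#'   `criteria` (per-k AIC/BIC table) and `agreement`.
#' @export
select_k <- function(values, k_range = 1:4, ...) {
  fits <- lapply(k_range, function(k) fit_gmm(values, k, ...))
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  k_bic <- k_range[which.min(bic)]
  k_aic <- k_range[which.min(aic)]
  out <- fits[[which.min(bic)]]
  attr(out, "criteria") <- data.frame(k = k_range, aic = aic, bic = bic)
  attr(out, "k_bic") <- k_bic
  attr(out, "k_aic") <- k_aic
  attr(out, "agreement") <- k_bic == k_aic
  out
}

#' Label outcomes from a two-component mixture
#'
#' Assigns each run to the component with the larger posterior; the
#' lower-mean component is the "resolved" (low-damage) class, the
#' higher-mean component "ulcerated" (high-damage). Posterior ties go to
#' the lower-mean class.
#'
#' @param values end-point damages to label.
#' @param model a fitted k = 2 `outcome_gmm`.
#' @return factor with levels `resolved`, `ulcerated`.
#' @export
label_outcomes <- function(values, model) {
  stopifnot(inherits(model, "outcome_gmm"))
  if (model$k != 2) stop("outcome labelling requires a k = 2 mixture")
  x <- as.numeric(values)
  d1 <- model$weights[1] * stats::dnorm(x, model$means[1],
                                        sqrt(model$variances[1]))
  d2 <- model$weights[2] * stats::dnorm(x, model$means[2],
                                        sqrt(model$variances[2]))
  factor(ifelse(d2 > d1, "ulcerated", "resolved"),
         levels = c("resolved", "ulcerated"))
}

#' @export
print.outcome_gmm <- function(x, ...) {
  cat("<outcome_gmm> k = ", x$k, ", n = ", x$n, "\n", sep = "")
  cat("  weights:  ", paste(signif(x$weights, 4), collapse = ", "), "\n")
  cat("  means:    ", paste(signif(x$means, 5), collapse = ", "), "\n")
  cat("  sd:       ", paste(signif(sqrt(x$variances), 4), collapse = ", "),
      "\n")
  cat("  logLik ", signif(x$loglik, 6), "; AIC ", signif(x$aic, 6),
      "; BIC ", signif(x$bic, 6), "\n", sep = "")
  invisible(x)
}
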