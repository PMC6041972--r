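# Fixed-variance 1-D Gaussian mixture for meta-QTL detection: each projected
# QTL position x_i is modelled as drawn from one of K true loci, with its
# own known variance s_i^2 derived from its 95% CI. Only the K means and the
# K-1 free mixing weights are estimated (nu = 2K - 1).

#' Per-QTL standard deviation from the 95% CI width
#'
#' A 95% normal interval spans 2 * 1.96 standard deviations, so
#' sd = width / 3.92.
#'
#' @param width 95% CI width(s) in cM, > 0.
#' @return standard deviation(s) in cM.
#' @export
qtl_sd <- function(width) {
  width <- as.numeric(width)
  if (any(!is.na(width) & width <= 0))
    stop("CI width must be > 0")
  width / 3.92
}

# log-sum-exp over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

mixture_loglik <- function(x, s, means, weights) {
  ld <- vapply(seq_along(means), function(k)
    log(weights[k]) + stats::dnorm(x, means[k], s, log = TRUE),
    numeric(length(x)))
  ld <- matrix(ld, nrow = length(x))
  sum(row_logsumexp(ld))
}

# k-means++-style seeding of initial means on the observed positions.
seed_means <- function(x, K) {
  means <- x[sample.int(length(x), 1)]
  while (length(means) < K) {
    d2 <- vapply(x, function(xi) min((xi - means)^2), numeric(1))
    if (all(d2 == 0)) {
      means <- c(means, sample(x, K - length(means), replace = TRUE))
    } else {
      means <- c(means, x[sample.int(length(x), 1, prob = d2)])
    }
  }
  means
}

#' Fit a fixed-variance Gaussian mixture to projected QTL positions
#'
#' Maximizes L = prod_i sum_k p_k * phi(x_i; mu_k, s_i^2) by EM, with the
#' observation variances s_i^2 held fixed (derived from each QTL's CI via
#' [qtl_sd()]); only the means and mixing weights are free, so the model has
#' nu = 2K - 1 parameters. `K = 1` is returned in closed form: the
#' inverse-variance weighted mean. For K > 1 the EM is restarted from
#' multiple seeded initializations and the best log-likelihood kept;
#' results are deterministic under a fixed `seed`.
#'
#' @param positions numeric vector of projected QTL positions (cM).
#' @param sds per-QTL standard deviations (cM), same length, all > 0.
#' @param K number of mixture components, `1 <= K <= length(positions)`.
#' @param restarts number of seeded EM restarts (K > 1).
#' @param max_iter maximum EM iterations per restart.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param seed integer seed for the restart initializations, or `NULL` to
#'   use the current RNG state.
#' @return an object of class `qtl_mixture`: list with `K`, `means`,
#'   `weights`, `loglik`, `responsibilities` (n x K), `trace` (per-iteration
#'   log-likelihood of the best restart), `n_params`, `converged`, `n_iter`,
#'   plus the data (`positions`, `sds`).
#' @examples
#' fit <- fit_qtl_mixture(c(0, 0.2, 49.8, 50), rep(1, 4), K = 2, seed = 1)
#' fit$means
#' @export
fit_qtl_mixture <- function(positions, sds, K, restarts = 10,
                            max_iter = 500, tol = 1e-8, seed = NULL) {
  x <- as.numeric(positions)
  s <- as.numeric(sds)
  n <- length(x)
  if (length(s) != n) stop("positions and sds must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(s)) || any(s <= 0))
    stop("positions must be finite and sds finite and > 0")
  if (K < 1 || K > n) stop("K must satisfy 1 <= K <= number of observations")
  w <- 1 / s^2
  if (K == 1) {
    mu <- sum(w * x) / sum(w)
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    return(structure(list(
      K = 1L, means = mu, weights = 1, loglik = ll,
      responsibilities = matrix(1, n, 1), trace = ll,
      n_params = 1L, converged = TRUE, n_iter = 0L,
      positions = x, sds = s), class = "qtl_mixture"))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    means <- seed_means(x, K)
    weights <- rep(1 / K, K)
    trace <- numeric()
    converged <- FALSE
    resp <- NULL
    for (iter in seq_len(max_iter)) {
      ld <- vapply(seq_len(K), function(k)
        log(weights[k]) + stats::dnorm(x, means[k], s, log = TRUE),
        numeric(n))
      ld <- matrix(ld, nrow = n)
      lse <- row_logsumexp(ld)
      ll <- sum(lse)
      trace <- c(trace, ll)
      resp <- exp(ld - lse)
      if (iter > 1 && abs(ll - trace[iter - 1]) < tol) {
        converged <- TRUE
        break
      }
      # M-step: inverse-variance weighted means, average responsibilities
      wk <- resp * w
      denom <- colSums(wk)
      upd <- denom > 0
      means[upd] <- colSums(wk * x)[upd] / denom[upd]
      weights <- colMeans(resp)
      weights <- pmax(weights, 1e-12)
      weights <- weights / sum(weights)
    }
    cand <- list(means = means, weights = weights,
                 loglik = trace[length(trace)], responsibilities = resp,
                 trace = trace, converged = converged, n_iter = length(trace))
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  ord <- order(best$means)
  structure(list(
    K = as.integer(K),
    means = best$means[ord],
    weights = best$weights[ord],
    loglik = best$loglik,
    responsibilities = best$responsibilities[, ord, drop = FALSE],
    trace = best$trace,
    n_params = 2L * as.integer(K) - 1L,
    converged = best$converged,
    n_iter = best$n_iter,
    positions = x, sds = s), class = "qtl_mixture")
}

#' @export
print.qtl_mixture <- function(x, ...) {
  cat(sprintf("Fixed-variance Gaussian mixture: K = %d, n = %d, logLik = %.4f%s\n",
              x$K, length(x$positions), x$loglik,
              if (x$converged) "" else " (not converged)"))
  cat("means:  ", paste(sprintf("%.3f", x$means), collapse = "  "), "\n")
  cat("weights:", paste(sprintf("%.3f", x$weights), collapse = "  "), "\n")
  invisible(x)
}

#' @export
logLik.qtl_mixture <- function(object, ...) {
  structure(object$loglik, df = object$n_params,
            nobs = length(object$positions), class = "logLik")
}

# Classification log-likelihood: responsibilities hardened to their argmax.
classification_loglik <- function(fit) {
  z <- max.col(fit$responsibilities, ties.method = "first")
  sum(log(fit$weights[z]) +
        stats::dnorm(fit$positions, fit$means[z], fit$sds, log = TRUE))
}

#' Information criteria for a mixture fit
#'
#' AIC = -2 logL + 2 nu; AICc = AIC + 2 nu (nu + 1) / (n - nu - 1)
#' (reported as `Inf` when n <= nu + 1); AIC3 = -2 logL + 3 nu;
#' BIC = -2 logL + nu log n; AWE = -2 logLc + 2 nu (3/2 + log n), where
#' logLc is the classification log-likelihood with each observation hardened
#' to its most probable component (Banfield-Raftery form). nu = 2K - 1.
#'
#' @param fit a [fit_qtl_mixture()] object.
#' @param n observation count (defaults to the fit's own).
#' @return named numeric vector `AIC`, `AICc`, `AIC3`, `BIC`, `AWE`.
#' @export
information_criteria <- function(fit, n = length(fit$positions)) {
  stopifnot(inherits(fit, "qtl_mixture"))
  nu <- fit$n_params
  m2ll <- -2 * fit$loglik
  aic <- m2ll + 2 * nu
  aicc <- if (n > nu + 1) aic + 2 * nu * (nu + 1) / (n - nu - 1) else Inf
  aic3 <- m2ll + 3 * nu
  bic <- m2ll + nu * log(n)
  awe <- -2 * classification_loglik(fit) + 2 * nu * (3 / 2 + log(n))
  c(AIC = aic, AICc = aicc, AIC3 = aic3, BIC = bic, AWE = awe)
}

#' Select the number of meta-QTL by five information criteria
#'
#' Each criterion votes for the K minimizing it (ties toward smaller K). The
#' chosen K is, under the default `"majority"` strategy, the most voted K
#' with ties again broken toward smaller K; `"aicc_only"` follows the AICc
#' vote alone; `"consensus_min"` picks the K with the smallest summed
#' per-criterion rank.
#'
#' @param fits list of [fit_qtl_mixture()] objects for K = 1, 2, ... on the
#'   same data.
#' @param n observation count.
#' @param strategy vote-combination rule.
#' @return object of class `mqtl_selection`: list with `criteria` (matrix,
#'   K rows x 5 criteria), `votes` (named integer vector criterion -> K),
#'   `chosen_K`, `strategy`.
#' @export
select_model <- function(fits, n = length(fits[[1]]$positions),
                         strategy = c("majority", "aicc_only",
                                      "consensus_min")) {
  strategy <- match.arg(strategy)
  Ks <- vapply(fits, function(f) f$K, integer(1))
  stopifnot(!anyDuplicated(Ks))
  crit <- t(vapply(fits, information_criteria, numeric(5), n = n))
  rownames(crit) <- Ks
  votes <- apply(crit, 2, function(v) Ks[which.min(v)])
  chosen <- switch(strategy,
    majority = {
      tab <- table(votes)
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)
    },
    aicc_only = unname(votes["AICc"]),
    consensus_min = {
      ranks <- apply(crit, 2, rank, ties.method = "min")
      Ks[which.min(rowSums(ranks))]
    })
  structure(list(criteria = crit, votes = votes,
                 chosen_K = as.integer(chosen), strategy = strategy),
            class = "mqtl_selection")
}

#' @export
print.mqtl_selection <- function(x, ...) {
  cat(sprintf("Model selection (%s): chosen K = %d\n",
              x$strategy, x$chosen_K))
  cat("votes:", paste(names(x$votes), x$votes, sep = "=", collapse = "  "),
      "\n")
  print(round(x$criteria, 2))
  invisible(x)
}
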