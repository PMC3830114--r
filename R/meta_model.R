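#' Configuration for the mixture meta-model
#'
#' Controls the per-chromosome maximum-likelihood Gaussian mixture fit of
#' projected QTL positions and the selection of the number of meta-QTL.
#'
#' @param kmax Maximum number of mixture components tried (default 10).
#' @param criterion Model-selection criterion: `"AIC"` (default), `"AICc"`
#'   or `"BIC"`.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Iteration cap per EM run.
#' @param restarts Random initializations per K (restart 0 is
#'   deterministic quantile-based; the rest jitter the quantiles).
#' @param seed Integer seed for the jittered restarts.
#' @param k_fixed Optional user-forced K; when set, [select_model()] fits
#'   only this K.
#' @return A `meta_model_config` list.
#' @export
meta_model_config <- function(kmax = 10, criterion = c("AIC", "AICc", "BIC"),
                              tol = 1e-8, max_iter = 500, restarts = 10,
                              seed = 20131111, k_fixed = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(kmax >= 1, tol > 0, max_iter >= 1, restarts >= 1)
  if (!is.null(k_fixed)) stopifnot(k_fixed >= 1)
  structure(list(kmax = as.integer(kmax), criterion = criterion, tol = tol,
                 max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 k_fixed = k_fixed),
            class = "meta_model_config")
}

# one EM run from given component means; per-observation variances are
# fixed (each QTL contributes the variance implied by its CI), so only the
# means and mixing weights are free parameters
em_run <- function(x, s2, mu, tol, max_iter) {
  n <- length(x)
  K <- length(mu)
  pi_k <- rep(1 / K, K)
  s <- sqrt(s2)
  loglik_prev <- -Inf
  converged <- FALSE
  iter <- 0
  resp <- matrix(1 / K, n, K)
  repeat {
    iter <- iter + 1
    # E step (log-sum-exp for stability)
    logd <- vapply(seq_len(K),
                   function(k) dnorm(x, mu[k], s, log = TRUE) + log(pi_k[k]),
                   numeric(n))
    logd <- matrix(logd, nrow = n)
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    loglik <- sum(lse)
    if (loglik < loglik_prev - 1e-8) {
      abort("EM log-likelihood decreased; this is a bug")
    }
    resp <- exp(logd - lse)
    if (abs(loglik - loglik_prev) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    loglik_prev <- loglik
    # M step: precision-weighted means, average responsibilities as weights
    nk <- colSums(resp)
    empty <- nk < 1e-6
    if (any(empty)) {
      # collapse guard: restart empty components at the worst-fit point
      worst <- which.min(lse)
      mu[empty] <- x[worst]
      pi_k[empty] <- 1 / K
      pi_k <- pi_k / sum(pi_k)
      loglik_prev <- -Inf
      next
    }
    pi_k <- nk / n
    w <- resp / s2
    mu <- colSums(w * x) / colSums(w)
  }
  info <- colSums(resp / s2)  # effective precision per component
  list(mu = mu, pi = pi_k, loglik = loglik, resp = resp, info = info,
       converged = converged, iterations = iter)
}

criterion_score <- function(loglik, K, n, criterion) {
  p <- 2 * K - 1  # K means + (K - 1) free weights
  base <- -2 * loglik + 2 * p
  switch(criterion,
         AIC = base,
         AICc = if (n - p - 1 > 0) base + 2 * p * (p + 1) / (n - p - 1) else Inf,
         BIC = -2 * loglik + p * log(n))
}

#' Fit a K-component Gaussian mixture to projected QTL positions
#'
#' Maximizes `sum_i log sum_k pi_k phi(x_i; mu_k, sigma_i^2)` by
#' expectation-maximization, where each QTL contributes a fixed observation
#' variance `sigma_i^2` derived from its confidence interval (see
#' [ci_to_sigma()]); the free parameters are the component means (candidate
#' meta-QTL positions) and mixing weights. The best of several restarts is
#' returned: restart 0 initializes the means at K-quantiles of the
#' positions, further restarts jitter those quantiles reproducibly under
#' `config$seed`. Component means are reported sorted ascending with 95%
#' intervals `mu_k +/- 1.96 / sqrt(sum_i r_ik / sigma_i^2)`.
#'
#' @param positions Numeric vector of QTL positions in cM.
#' @param sigmas Per-QTL standard deviations in cM (same length, all > 0).
#' @param K Number of components (1 <= K <= number of QTL).
#' @param config A [meta_model_config()].
#' @return A `metaqtl_fit` object; see [tidy.metaqtl_fit()] and
#'   [glance.metaqtl_fit()].
#' @export
#' @examples
#' fit <- fit_mixture(c(10, 20), c(1, 2), K = 1)
#' fit$mu  # inverse-variance weighted mean: 12
fit_mixture <- function(positions, sigmas, K, config = meta_model_config()) {
  n <- length(positions)
  if (length(sigmas) != n) abort("positions and sigmas must have equal length")
  if (any(sigmas <= 0)) abort("all sigmas must be > 0")
  if (K > n) abort("K must not exceed the number of QTL")
  s2 <- sigmas^2
  probs <- (seq_len(K) - 0.5) / K
  inits <- list(sort(quantile(positions, probs, names = FALSE, type = 7)))
  if (config$restarts > 1) {
    jitter_sd <- max(sd(positions), min(sigmas)) * 0.25
    if (!is.finite(jitter_sd) || jitter_sd == 0) jitter_sd <- 0.25
    extra <- withr::with_seed(config$seed + K, {
      lapply(seq_len(config$restarts - 1), function(r) {
        sort(inits[[1]] + rnorm(K, 0, jitter_sd))
      })
    })
    inits <- c(inits, extra)
  }
  runs <- lapply(inits, function(mu0) {
    em_run(positions, s2, mu0, config$tol, config$max_iter)
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
  ord <- order(best$mu)
  fit <- list(
    K = as.integer(K),
    mu = best$mu[ord],
    pi = best$pi[ord],
    loglik = best$loglik,
    criterion = config$criterion,
    score = criterion_score(best$loglik, K, n, config$criterion),
    resp = best$resp[, ord, drop = FALSE],
    info = best$info[ord],
    n = n,
    converged = best$converged,
    iterations = best$iterations,
    positions = positions,
    sigmas = sigmas
  )
  class(fit) <- "metaqtl_fit"
  fit
}

#' @export
print.metaqtl_fit <- function(x, ...) {
  cat(sprintf("<metaqtl_fit> K = %d, n = %d, loglik = %.3f, %s = %.3f%s\n",
              x$K, x$n, x$loglik, x$criterion, x$score,
              if (x$converged) "" else " (not converged)"))
  cat("  means (cM):", paste(sprintf("%.2f", x$mu), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn fit_mixture Per-component tibble: mean, 95% interval, weight
#'   and effective number of supporting QTL.
#' @param x A `metaqtl_fit`.
#' @param ... Unused.
#' @method tidy metaqtl_fit
#' @export
tidy.metaqtl_fit <- function(x, ...) {
  half <- 1.96 / sqrt(x$info)
  tibble(
    component = seq_len(x$K),
    mu_cM = x$mu,
    ci_lo_cM = x$mu - half,
    ci_hi_cM = x$mu + half,
    weight = x$pi,
    n_eff = colSums(x$resp)
  )
}

#' @describeIn fit_mixture One-row fit summary.
#' @method glance metaqtl_fit
#' @export
glance.metaqtl_fit <- function(x, ...) {
  tibble(K = x$K, n = x$n, loglik = x$loglik, criterion = x$criterion,
         score = x$score, converged = x$converged,
         iterations = x$iterations)
}

#' Select the number of meta-QTL on a chromosome
#'
#' Fits mixtures with K = 1 .. `min(kmax, n)` components (or only
#' `k_fixed` when set) and returns the fit minimizing the configured
#' information criterion, with ties broken toward smaller K. The full per-K
#' table is retained for reporting.
#'
#' @inheritParams fit_mixture
#' @return A `metaqtl_selection` object: list with elements `best` (a
#'   `metaqtl_fit`), `table` (per-K log-likelihood and criterion score) and
#'   `criterion`.
#' @export
select_model <- function(positions, sigmas, config = meta_model_config()) {
  n <- length(positions)
  if (n == 0) abort("at least one QTL is required")
  ks <- if (!is.null(config$k_fixed)) {
    if (config$k_fixed > n) abort("k_fixed must not exceed the number of QTL")
    config$k_fixed
  } else {
    seq_len(min(config$kmax, n))
  }
  fits <- lapply(ks, function(k) fit_mixture(positions, sigmas, k, config))
  scores <- vapply(fits, `[[`, numeric(1), "score")
  best <- fits[[which.min(scores)]]  # first minimum = smallest K on ties
  table <- purrr::map_dfr(fits, glance)
  structure(list(best = best, table = table, criterion = config$criterion),
            class = "metaqtl_selection")
}

#' @export
print.metaqtl_selection <- function(x, ...) {
  cat(sprintf("<metaqtl_selection> best K = %d by %s over %d candidate(s)\n",
              x$best$K, x$criterion, nrow(x$table)))
  print(x$best)
  invisible(x)
}

#' @describeIn select_model Per-K model table.
#' @param x A `metaqtl_selection`.
#' @param ... Unused.
#' @method tidy metaqtl_selection
#' @export
tidy.metaqtl_selection <- function(x, ...) {
  x$table
}

#' @describeIn select_model One-row summary of the selected model.
#' @method glance metaqtl_selection
#' @export
glance.metaqtl_selection <- function(x, ...) {
  glance(x$best)
}

#' Consensus meta-QTL intervals from a mixture fit
#'
#' Reports each component's mean and 95% interval, sorted by mean and
#' optionally clipped to the chromosome span `[0, chrom_length]`.
#'
#' @param fit A `metaqtl_fit`.
#' @param chrom_length Optional chromosome length in cM used for clipping.
#' @return A tibble with columns `component`, `mu_cM`, `ci_lo_cM`,
#'   `ci_hi_cM`, `weight`, `n_eff`.
#' @export
metaqtl_intervals <- function(fit, chrom_length = NULL) {
  out <- tidy(fit)
  if (!is.null(chrom_length)) {
    out$ci_lo_cM <- pmax(out$ci_lo_cM, 0)
    out$ci_hi_cM <- pmin(out$ci_hi_cM, chrom_length)
  }
  out[order(out$mu_cM), , drop = FALSE]
}
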