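#' Log-likelihood of data under a Gaussian mixture
#'
#' Computes \eqn{\sum_j \log \sum_i \pi_i \phi(x_j; \mu_i, \sigma_i)} with
#' log-sum-exp stabilisation, so points far in the tails of every component
#' do not underflow to `-Inf` prematurely.
#'
#' @param model A [gaussian_mixture()].
#' @param x Nonempty numeric data vector.
#' @return Log-likelihood in nats.
#' @export
loglik_mixture <- function(model, x) {
  check_mixture(model)
  if (length(x) == 0L) abort("`x` must be nonempty")
  loglik_gmm_cpp(as.numeric(x), model$mean, model$sd, model$weight)
}

#' Corrected Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2p + \frac{2p(p+1)}{n - p - 1}}
#' The small-sample correction term requires `n_obs > n_params + 1`.
#'
#' @param loglik Maximised log-likelihood (nats).
#' @param n_params Number of free parameters (for an `n`-component univariate
#'   Gaussian mixture, `3n - 1`).
#' @param n_obs Number of observations.
#' @return AICc in nats.
#' @examples
#' aicc(-650, n_params = 2, n_obs = 144)
#' @export
aicc <- function(loglik, n_params, n_obs) {
  if (n_obs <= n_params + 1)
    abort("AICc undefined: `n_obs` must exceed `n_params` + 1")
  -2 * loglik + 2 * n_params + 2 * n_params * (n_params + 1) / (n_obs - n_params - 1)
}

#' Relative likelihood of a model versus the AICc-optimal one
#'
#' Two conventions are offered. The default, `"exp-delta"`, returns
#' `exp(aicc_best - aicc_i)`, treating the raw AICc difference as a log
#' evidence ratio; this is the convention some mixture-model reports print.
#' `"akaike"` returns the conventional `exp((aicc_best - aicc_i)/2)`.
#'
#' @param aicc_i AICc of the model under comparison.
#' @param aicc_best AICc of the optimal (lowest-AICc) model;
#'   `aicc_best <= aicc_i`.
#' @param mode `"exp-delta"` (default) or `"akaike"`.
#' @return Relative likelihood in (0, 1].
#' @examples
#' relative_likelihood(1247.4, 1245.9) # 0.22
#' @export
relative_likelihood <- function(aicc_i, aicc_best, mode = c("exp-delta", "akaike")) {
  mode <- arg_match(mode)
  if (any(aicc_best > aicc_i + 1e-12))
    abort("`aicc_best` must not exceed `aicc_i`")
  d <- aicc_best - aicc_i
  if (mode == "akaike") d <- d / 2
  exp(d)
}

# First restart: quantile-spaced means. Later restarts: n random data points
# as means (sorted). Narrow jitter around the quantile configuration turned
# out to explore too little of the likelihood surface and systematically
# missed the ML optimum for overlapping components; random-point starts match
# the optima an independent multistart fitter finds.
em_init <- function(x, n, restart) {
  mu0 <- if (restart == 1L)
    as.numeric(quantile(x, probs = (seq_len(n) - 0.5) / n, names = FALSE))
  else sort(sample(x, n))
  list(mu = mu0, sigma = rep(max(sd(x) / sqrt(n), 1), n), pi = rep(1 / n, n))
}

#' Fit an n-component Gaussian mixture by maximum-likelihood EM
#'
#' Runs EM from `restarts` initializations (quantile-spaced means first,
#' then random data points as means; equal weights) and keeps the best
#' non-degenerate run. A run is
#' degenerate when a component SD collapses below `sigma_floor` (a component
#' locking onto near-duplicate points); degenerate runs are discarded. For
#' `n = 1` the closed-form maximum-likelihood estimates are returned (mean
#' and ML standard deviation, i.e. the `1/n` variance convention).
#'
#' @param x Numeric data vector with `length(x) > 3n - 1`.
#' @param n Number of components.
#' @param restarts Number of EM initializations (default 50).
#' @param tol Absolute convergence tolerance on the log-likelihood
#'   (default 1e-8).
#' @param max_iter Iteration cap per restart.
#' @param sigma_floor Lower bound on component SDs in index units
#'   (default 0.5).
#' @param seed Optional integer seed for the initialization jitter.
#' @return A `mixture_fit`: the canonicalized [gaussian_mixture()] plus
#'   `loglik`, `n_params = 3n - 1`, `n_obs`, `aicc`, `converged`,
#'   `n_restarts_used` (non-degenerate restarts) and the data.
#' @examples
#' x <- sample_mixture(hfli_mixture("RH"), 144, seed = 1)
#' fit_mixture(x, 3, seed = 1)
#' @export
fit_mixture <- function(x, n, restarts = 50, tol = 1e-8, max_iter = 1000,
                        sigma_floor = 0.5, seed = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) abort("`x` must not contain missing values")
  n_params <- 3L * n - 1L
  if (length(x) <= n_params)
    abort(sprintf("need more than %d observations to fit %d components",
                  n_params, n))

  if (n == 1L) {
    mu <- mean(x)
    s_ml <- sqrt(sum((x - mu)^2) / length(x))
    if (s_ml < sigma_floor)
      abort("data are (near-)constant: single-component SD below `sigma_floor`")
    model <- gaussian_mixture(mu, s_ml, 1)
    ll <- loglik_mixture(model, x)
    return(new_mixture_fit(model, ll, n_params, length(x), TRUE, 1L, x,
                           monotone = TRUE))
  }

  with_seed(seed, {
    best <- NULL
    used <- 0L
    for (r in seq_len(restarts)) {
      init <- em_init(x, n, restart = r)
      run <- em_gmm_cpp(x, init$mu, init$sigma, init$pi,
                        tol = tol, max_iter = as.integer(max_iter),
                        sigma_floor = sigma_floor)
      if (run$degenerate) next
      used <- used + 1L
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    if (is.null(best))
      return(new_mixture_fit(NULL, NA_real_, n_params, length(x), FALSE, 0L, x,
                             monotone = NA))
    model <- gaussian_mixture(best$mu, best$sigma, best$pi / sum(best$pi))
    new_mixture_fit(model, best$loglik, n_params, length(x),
                    isTRUE(best$converged), used, x,
                    monotone = isTRUE(best$monotone))
  })
}

new_mixture_fit <- function(model, loglik, n_params, n_obs, converged,
                            n_restarts_used, x, monotone) {
  structure(
    list(model = model, loglik = loglik, n_params = n_params, n_obs = n_obs,
         aicc = if (is.finite(loglik) && n_obs > n_params + 1)
           aicc(loglik, n_params, n_obs) else NA_real_,
         converged = converged, n_restarts_used = n_restarts_used,
         monotone = monotone, data = x),
    class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  k <- if (is.null(x$model)) NA_integer_ else nrow(x$model)
  cat(sprintf("Gaussian mixture fit: %s component(s), n = %d\n", k, x$n_obs))
  cat(sprintf("  loglik = %.3f, AICc = %.3f, converged = %s (restarts used: %d)\n",
              x$loglik, x$aicc, x$converged, x$n_restarts_used))
  if (!is.null(x$model)) print(as.data.frame(x$model))
  invisible(x)
}

#' @rdname fit_mixture
#' @param object,x A `mixture_fit`.
#' @param ... Unused.
#' @export
tidy.mixture_fit <- function(x, ...) {
  if (is.null(x$model)) return(tibble(component = integer(0)))
  mutate(as_tibble(x$model), component = dplyr::row_number(), .before = 1)
}

#' @rdname fit_mixture
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble(n_components = if (is.null(x$model)) NA_integer_ else nrow(x$model),
         loglik = x$loglik, n_params = x$n_params, n_obs = x$n_obs,
         aicc = x$aicc, converged = x$converged,
         n_restarts_used = x$n_restarts_used)
}

#' Fit a range of component counts and select by AICc
#'
#' Fits each `n` in `n_range` with [fit_mixture()], ranks the successful fits
#' by AICc, and reports each model's relative likelihood versus the optimal
#' one. Failed fits (all restarts degenerate) are excluded from the ranking
#' with a warning.
#'
#' @inheritParams fit_mixture
#' @param n_range Component counts to try (default `1:5`).
#' @param mode Relative-likelihood convention, see [relative_likelihood()].
#' @return A `mixture_selection`: a tibble (`n`, `loglik`, `n_params`,
#'   `aicc`, `rel_lik`, `converged`) with the fits in `attr(, "fits")` and
#'   the selected count in `$best_n`.
#' @examples
#' x <- sample_mixture(hfli_mixture("RH"), 144, seed = 1)
#' select_mixture(x, 1:3, restarts = 10, seed = 1)
#' @export
select_mixture <- function(x, n_range = 1:5, restarts = 50, tol = 1e-8,
                           max_iter = 1000, sigma_floor = 0.5, seed = NULL,
                           mode = c("exp-delta", "akaike")) {
  mode <- arg_match(mode)
  if (length(n_range) == 0L) abort("`n_range` must be nonempty")
  with_seed(seed, {
    fits <- lapply(n_range, function(n)
      tryCatch(
        fit_mixture(x, n, restarts = restarts, tol = tol, max_iter = max_iter,
                    sigma_floor = sigma_floor, seed = NULL),
        error = function(e) new_mixture_fit(NULL, NA_real_, 3L * n - 1L,
                                            length(x), FALSE, 0L, x, NA)))
    names(fits) <- as.character(n_range)
    tab <- purrr::map_dfr(fits, glance)
    tab <- mutate(tab, n = as.integer(n_range), .before = 1)
    ok <- is.finite(tab$aicc)
    if (!any(ok)) {
      # AICc can be undefined (n_obs <= 3n) even when a lone requested fit
      # succeeded; with nothing to rank, return that fit unranked
      if (length(n_range) == 1L && is.finite(tab$loglik[1])) {
        tab$rel_lik <- 1
        return(structure(list(table = select(tab, -"n_components"),
                              best_n = tab$n[1], fits = fits, mode = mode),
                         class = "mixture_selection"))
      }
      abort("no component count could be fit")
    }
    if (!all(ok))
      warn(sprintf("fit failed for n = %s; excluded from ranking",
                   paste(tab$n[!ok], collapse = ", ")))
    best_aicc <- min(tab$aicc[ok])
    tab$rel_lik <- NA_real_
    tab$rel_lik[ok] <- relative_likelihood(tab$aicc[ok], best_aicc, mode = mode)
    best_n <- tab$n[ok][which.min(tab$aicc[ok])]
    structure(list(table = select(tab, -"n_components"), best_n = best_n,
                   fits = fits, mode = mode),
              class = "mixture_selection")
  })
}

#' @export
print.mixture_selection <- function(x, ...) {
  cat(sprintf("Mixture model selection (AICc, %s relative likelihood)\n", x$mode))
  print(as.data.frame(x$table))
  cat(sprintf("Selected: n = %d components\n", x$best_n))
  invisible(x)
}

#' @rdname select_mixture
#' @param object,x A `mixture_selection`.
#' @param ... Unused.
#' @export
tidy.mixture_selection <- function(x, ...) x$table

#' @rdname select_mixture
#' @export
glance.mixture_selection <- function(x, ...) {
  best <- x$fits[[as.character(x$best_n)]]
  mutate(glance(best), best_n = x$best_n, .before = 1)
}

#' Best fitted model of a selection
#'
#' @param selection A `mixture_selection`.
#' @return The `mixture_fit` with the lowest AICc.
#' @export
best_fit <- function(selection) {
  stopifnot(inherits(selection, "mixture_selection"))
  selection$fits[[as.character(selection$best_n)]]
}

#' Nonparametric bootstrap confidence intervals for mixture parameters
#'
#' Resamples subjects with replacement, refits the `n`-component mixture per
#' resample, matches components across resamples by mean order (descending),
#' and returns percentile intervals for every mean, SD and weight. Resamples
#' whose fit fails (all restarts degenerate) are dropped and counted.
#'
#' @inheritParams fit_mixture
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param restarts EM restarts per resample (default 10; refits start near a
#'   global optimum of a same-sized sample so fewer restarts suffice).
#' @param conf Interval coverage (default 0.95).
#' @return A tibble with one row per (component, parameter): `estimate`,
#'   `lower`, `upper`; the number of failed resamples is in
#'   `attr(, "n_failed")`.
#' @export
mixture_ci <- function(x, n, n_boot = 200, restarts = 10, conf = 0.95,
                       tol = 1e-8, max_iter = 1000, sigma_floor = 0.5,
                       seed = NULL) {
  if (n_boot < 100) abort("`n_boot` must be at least 100")
  fit0 <- fit_mixture(x, n, restarts = max(restarts, 20), tol = tol,
                      max_iter = max_iter, sigma_floor = sigma_floor,
                      seed = seed)
  if (is.null(fit0$model)) abort("full-sample fit failed; no CI available")
  with_seed(seed, {
    draws <- purrr::map(seq_len(n_boot), function(b) {
      xb <- sample(x, length(x), replace = TRUE)
      fb <- tryCatch(
        fit_mixture(xb, n, restarts = restarts, tol = tol, max_iter = max_iter,
                    sigma_floor = sigma_floor, seed = NULL),
        error = function(e) NULL)
      if (is.null(fb) || is.null(fb$model)) return(NULL)
      fb$model # canonicalized: descending mean
    })
    ok <- !vapply(draws, is.null, logical(1))
    if (!any(ok)) abort("all bootstrap refits failed")
    alpha <- (1 - conf) / 2
    boot <- purrr::map_dfr(draws[ok], function(m)
      mutate(as_tibble(m), component = dplyr::row_number()))
    est <- mutate(as_tibble(fit0$model), component = dplyr::row_number())
    out <- tidyr::pivot_longer(boot, c("mean", "sd", "weight"),
                               names_to = "parameter") %>%
      group_by(.data$component, .data$parameter) %>%
      summarise(lower = quantile(.data$value, alpha, names = FALSE),
                upper = quantile(.data$value, 1 - alpha, names = FALSE),
                .groups = "drop")
    est_long <- tidyr::pivot_longer(est, c("mean", "sd", "weight"),
                                    names_to = "parameter",
                                    values_to = "estimate")
    out <- left_join(est_long, out, by = c("component", "parameter")) %>%
      arrange(.data$component, .data$parameter)
    attr(out, "n_failed") <- sum(!ok)
    attr(out, "conf") <- conf
    out
  })
}
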