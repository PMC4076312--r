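test_that("mixture log-likelihood matches closed forms and is additive", {
  m <- gaussian_mixture(0, 1, 1)
  expect_equal(loglik_mixture(m, 0), -0.5 * log(2 * pi))
  mlh <- hfli_mixture("LH")
  x <- sample_mixture(mlh, 100, seed = 1)
  expect_equal(loglik_mixture(mlh, c(x, x)), 2 * loglik_mixture(mlh, x))
  expect_error(loglik_mixture(mlh, numeric(0)), "nonempty")
})

test_that("mean per-point log-likelihood approaches negative entropy", {
  # numerical-integration oracle for the differential entropy of the mixture
  mlh <- hfli_mixture("LH")
  grid <- seq(-160, 160, by = 0.02)
  f <- dmixture(grid, mlh)
  h <- -sum(0.02 * ifelse(f > 0, f * log(f), 0)) # trapezoid to first order
  x <- sample_mixture(mlh, 1e5, seed = 21)
  ll_bar <- loglik_mixture(mlh, x) / length(x)
  lf <- log(dmixture(x, mlh))
  expect_lt(abs(ll_bar + h), 5 * sd(lf) / sqrt(length(x)))
})

test_that("single-component fit is the closed-form ML estimate", {
  x <- as.numeric(scale(rnorm(144))) * 22.7 + 53.5 # exact sample moments
  f <- fit_mixture(x, 1)
  expect_equal(f$model$mean, 53.5, tolerance = 1e-12)
  expect_equal(f$model$sd, 22.7 * sqrt(143 / 144), tolerance = 1e-12)
  expect_equal(f$n_params, 2L)
  expect_true(f$converged)
  # worked AICc example from these moments
  expect_lt(abs(f$aicc - 1311.0), 0.5)
})

test_that("AICc formula behaves at its edges", {
  expect_equal(aicc(-10, 0, 50), 20) # no parameters: plain -2*loglik
  expect_lt(abs(aicc(-10, 3, 1e8) - (20 + 6)), 1e-5) # correction vanishes
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("relative likelihood supports both conventions", {
  expect_equal(relative_likelihood(1245.9, 1245.9), 1.0)
  expect_equal(round(relative_likelihood(1247.4, 1245.9), 2), 0.22)
  expect_equal(relative_likelihood(1247.4, 1245.9, mode = "akaike"),
               sqrt(relative_likelihood(1247.4, 1245.9)))
  expect_error(relative_likelihood(1, 2), "must not exceed")
})

test_that("EM recovers well-separated components and the generating model", {
  # two tight spikes at +-50
  set.seed(4)
  x <- c(rnorm(300, -50, 1), rnorm(300, 50, 1))
  f <- fit_mixture(x, 2, restarts = 10, seed = 2)
  expect_lt(max(abs(sort(f$model$mean) - c(-50, 50))), 1)
  expect_lt(max(abs(f$model$weight - 0.5)), 0.05)
  expect_true(f$monotone)

  # large-sample consistency for the 4-component reference model
  mlh <- hfli_mixture("LH")
  x <- sample_mixture(mlh, 2e4, seed = 8)
  f4 <- fit_mixture(x, 4, restarts = 8, seed = 8)
  expect_lt(max(abs(f4$model$mean - mlh$mean)), 1)
  # the overlapping top-two components trade weight slowly; looser bound
  expect_lt(max(abs(f4$model$weight - mlh$weight)), 0.05)

  # fitted density integrates to one
  dens <- function(t) dmixture(t, f4$model)
  expect_equal(stats::integrate(Vectorize(dens), -200, 200,
                                rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
})

test_that("parameter recovery error shrinks with sample size", {
  m <- gaussian_mixture(c(-30, 30), c(5, 5), c(0.5, 0.5)) # |dmu| = 12 sd
  err <- vapply(c(1e3, 1e4), function(n) {
    x <- sample_mixture(m, n, seed = n)
    f <- fit_mixture(x, 2, restarts = 5, seed = 1)
    max(abs(sort(f$model$mean) - c(-30, 30)))
  }, numeric(1))
  expect_lt(err[1], 1)
  expect_lt(err[2], 0.5)
})

test_that("restart-best EM attains at least an independent fitter's optimum", {
  suppressMessages(library(mclust))
  mlh <- hfli_mixture("LH")
  for (i in 1:3) {
    x <- sample_mixture(mlh, 153, seed = i)
    for (k in 3:4) {
      f <- fit_mixture(x, k, restarts = 50, seed = i)
      mc <- mclust::Mclust(x, G = k, modelNames = "V", verbose = FALSE)
      expect_gte(f$loglik, mc$loglik - 1e-3)
    }
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  for (i in 1:10) {
    x <- sample_mixture(hfli_mixture("LH"), 120, seed = i)
    f <- fit_mixture(x, sample(2:5, 1), restarts = 5, seed = i)
    expect_true(is.na(f$monotone) || f$monotone)
  }
})

test_that("model selection ranks by AICc with unit best relative likelihood", {
  # data truly from one Gaussian: n = 1 wins in most replicates
  wins <- sum(vapply(1:20, function(i) {
    set.seed(i * 7)
    x <- rnorm(1000, 10, 5)
    s <- suppressWarnings(select_mixture(x, 1:3, restarts = 10, seed = i))
    s$best_n == 1L
  }, logical(1)))
  expect_gte(wins, 11)

  x <- sample_mixture(hfli_mixture("LH"), 153, seed = 5)
  s <- select_mixture(x, 1:5, restarts = 25, seed = 5)
  expect_equal(s$table$rel_lik[s$table$n == s$best_n], 1.0)
  expect_true(all(s$table$rel_lik <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(s$table$aicc[s$table$n == s$best_n], min(s$table$aicc, na.rm = TRUE))
  # fits that cannot be run are excluded with a warning, not an error
  xs <- sample_mixture(hfli_mixture("RH"), 12, seed = 1)
  expect_warning(s2 <- select_mixture(xs, c(1, 5), restarts = 5, seed = 1),
                 "excluded")
  expect_equal(s2$best_n, 1L)
})

test_that("bootstrap CIs bracket generating parameters and are stable", {
  # tight two-spike data: mean intervals collapse to near-zero width
  set.seed(6)
  x <- c(rnorm(100, -50, 1), rnorm(100, 50, 1))
  ci <- mixture_ci(x, 2, n_boot = 100, restarts = 3, seed = 1)
  mu_rows <- ci[ci$parameter == "mean", ]
  expect_true(all(mu_rows$upper - mu_rows$lower < 1))
  expect_true(all(mu_rows$lower <= mu_rows$estimate &
                    mu_rows$estimate <= mu_rows$upper))

  # consistency: lowest-mean interval brackets the generating value
  mlh <- hfli_mixture("LH")
  xl <- sample_mixture(mlh, 1500, seed = 12)
  ci4 <- mixture_ci(xl, 4, n_boot = 100, restarts = 3, seed = 2)
  low <- ci4[ci4$component == 4 & ci4$parameter == "mean", ]
  expect_lt(low$lower, -63.6)
  expect_gt(low$upper, -63.6)

  # doubling the bootstrap leaves endpoints within 10% of interval width
  ci_b <- mixture_ci(x, 2, n_boot = 200, restarts = 3, seed = 1)
  a <- ci[ci$parameter == "mean", ]
  b <- ci_b[ci_b$parameter == "mean", ]
  w <- pmax(a$upper - a$lower, 1e-3)
  expect_true(all(abs(a$lower - b$lower) < pmax(0.1 * w, 0.05)))
  expect_true(all(abs(a$upper - b$upper) < pmax(0.1 * w, 0.05)))
  expect_error(mixture_ci(x, 2, n_boot = 50), "at least 100")
})

test_that("tidy and glance expose fit and selection results as tibbles", {
  x <- sample_mixture(hfli_mixture("RH"), 144, seed = 3)
  f <- fit_mixture(x, 3, restarts = 10, seed = 3)
  td <- tidy(f)
  expect_named(td, c("component", "mean", "sd", "weight"))
  expect_equal(nrow(td), 3)
  gl <- glance(f)
  expect_equal(gl$n_obs, 144)
  expect_equal(gl$n_params, 8)
  s <- select_mixture(x, 1:3, restarts = 10, seed = 3)
  expect_equal(nrow(tidy(s)), 3)
  expect_equal(glance(s)$best_n, s$best_n)
  expect_s3_class(best_fit(s), "mixture_fit")
})
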