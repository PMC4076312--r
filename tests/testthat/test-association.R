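test_that("Edinburgh laterality quotient covers pure and mixed tallies", {
  expect_equal(edinburgh_lq(9, 0), 100)
  expect_equal(edinburgh_lq(0, 9), -100)
  expect_equal(edinburgh_lq(6, 3), 100 / 3)
  expect_true(is.na(edinburgh_lq(0, 0)))
  expect_error(edinburgh_lq(-1, 2), "nonnegative")
})

test_that("3-level manual preference categories use the published boundaries", {
  expect_equal(as.character(mps3(c(-100, -55, -54.9, 0, 99, 100))),
               c("Strong L", "Strong L", "Moderate", "Moderate", "Moderate",
                 "Strong R"))
  expect_error(mps3(101), "out of")
})

test_that("7-level categories resolve shared boundaries to the lower category", {
  expect_equal(mps7(c(-100, -99, -75, -25, 0, 25, 75, 99, 100)),
               c(1L, 2L, 2L, 3L, 4L, 4L, 5L, 6L, 7L))
  expect_error(mps7(-150), "out of")
  expect_length(mps7_midvalues(), 7)
  expect_true(all(diff(mps7_midvalues()) > 0))
})

test_that("contingency tables count correctly and tidy to fractions", {
  d <- tibble::tibble(a = "x", b = "y")
  tab1 <- contingency(d, "a", "b")
  expect_equal(unclass(tab1)[1, 1], 1L, ignore_attr = TRUE)
  co <- assign_types(generate_cohort(seed = 3))
  tab <- contingency(co, "handedness", "lat_type")
  expect_equal(sum(tab), nrow(co))
  td <- tidy(tab)
  expect_equal(sum(td$fraction), 1)
  expect_error(contingency(co[0, ], "handedness", "lat_type"), "empty")
})

test_that("dominance collapse reproduces the published 2x2 tables", {
  counts <- tibble::tibble(
    handedness = rep(c("RH", "LH"), each = 3),
    lat_type = rep(c("Typical", "Ambilateral", "Strongly-atypical"), 2),
    n = c(130, 14, 0, 120, 23, 10),
    hfli = c(60, 0, -60, 60, 0, -60))
  co <- cohort_from_counts(counts)
  m <- unclass(collapse_dominance(co))
  expect_equal(m, matrix(c(130L, 120L, 14L, 33L), 2,
                         dimnames = dimnames(m)))
  m2 <- unclass(collapse_dominance(co, exclude_strongly_atypical = TRUE))
  expect_equal(as.vector(m2), c(130L, 120L, 14L, 23L))
  # degenerate single-cell cohort
  solo <- cohort_from_counts(counts[1, ])
  expect_equal(as.vector(unclass(collapse_dominance(solo))), c(130L, 0L, 0L, 0L))
})

test_that("kappa matches hand arithmetic, endpoints and an external check", {
  # diagonal agreement
  expect_equal(cohen_kappa(diag(5L, 3))$kappa, 1)
  # exact independence: rows proportional to column margins
  indep <- outer(c(30, 70), c(0.4, 0.6)) # margins factorize
  expect_equal(cohen_kappa(indep)$kappa, 0)
  # simultaneous row/column permutation leaves kappa unchanged
  set.seed(2)
  m <- matrix(rpois(9, 20), 3)
  p <- sample(3)
  expect_equal(cohen_kappa(m[p, p])$kappa, cohen_kappa(m)$kappa)
  # all-zero matched category contributes nothing
  m4 <- cbind(rbind(m, 0), 0)
  expect_equal(cohen_kappa(m4)$kappa, cohen_kappa(m)$kappa)
  # cross-check against an independent implementation
  expect_equal(cohen_kappa(m)$kappa,
               unname(e1071::classAgreement(m)$kappa))
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
  # degenerate margins flagged
  expect_warning(res <- cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
  expect_true(is.na(res$kappa))
})

test_that("kappa converges to zero under independent hand/language labels", {
  set.seed(8)
  n <- 1e5
  co <- tibble::tibble(
    handedness = sample(c("RH", "LH"), n, TRUE, prob = c(0.9, 0.1)),
    lat_type = factor(sample(c("Typical", "Ambilateral"), n, TRUE,
                             prob = c(0.9, 0.1)),
                      levels = c("Typical", "Ambilateral", "Strongly-atypical")))
  k <- cohen_kappa(collapse_dominance(co))$kappa
  expect_lt(abs(k), 0.01)
})

test_that("Fisher exact p agrees with direct hypergeometric enumeration", {
  tabs <- list(matrix(c(1, 11, 9, 3), 2),
               matrix(c(5, 5, 5, 5), 2),
               matrix(c(12, 2, 3, 17), 2))
  for (tb in tabs)
    expect_equal(fisher_exact(tb)$p.value, oracle_fisher_2x2(tb),
                 tolerance = 1e-10)
  # identical rows: no association, p = 1
  expect_equal(fisher_exact(matrix(c(4, 4, 6, 6), 2))$p.value, 1)
  # removing an all-zero column leaves the r x c p unchanged
  m <- matrix(c(130, 120, 14, 23, 0, 10), 2)
  expect_equal(fisher_exact(cbind(m, 0))$p.value, fisher_exact(m)$p.value)
  expect_error(fisher_exact(matrix(2e4, 1, 1)), "too large")
})

test_that("Spearman association equals a brute-force rank oracle", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  set.seed(13)
  x <- round(rnorm(60), 1) # rounding forces midrank ties
  y <- round(x + rnorm(60), 1)
  got <- spearman_assoc(x, y)
  want <- oracle_spearman(x, y)
  expect_equal(got$rho, want$rho, tolerance = 1e-12)
  expect_equal(got$p.value, want$p, tolerance = 1e-9)
  const <- spearman_assoc(rep(1, 10), 1:10)
  expect_false(const$valid)
  expect_true(is.na(const$rho))
})

test_that("occurrence regression recovers exact and degenerate structure", {
  # flat occurrence: zero slope
  flat <- tibble::tibble(
    mps = rep(mps7_midvalues(), each = 10),
    atypical = rep(c(TRUE, rep(FALSE, 9)), 7))
  expect_equal(glance(occurrence_regression(flat))$slope, 0)
  # occurrence exactly linear in mid-values: OLS recovers it exactly
  mids <- mps7_midvalues()
  lin <- purrr::map_dfr(seq_along(mids), function(i) {
    n_atyp <- 100 + mids[i] # occurrence (%) = (100 + mid)/4 with n = 400
    tibble::tibble(mps = rep(mids[i], 400),
                   atypical = rep(c(TRUE, FALSE), c(n_atyp, 400 - n_atyp)))
  })
  g <- glance(occurrence_regression(lin))
  expect_equal(g$slope, 0.25, tolerance = 1e-9)
  expect_equal(g$intercept, 25, tolerance = 1e-9)
  expect_error(occurrence_regression(tibble::tibble(mps = rep(0, 5),
                                                    atypical = TRUE)),
               "2 nonempty")
})

test_that("synthetic cohorts show the negative occurrence slope", {
  neg <- sum(vapply(1:30, function(i) {
    co <- assign_types(generate_cohort(seed = i))
    glance(occurrence_regression(co))$slope < 0
  }, logical(1)))
  expect_gte(neg, 16) # majority of seeded replicates
})
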