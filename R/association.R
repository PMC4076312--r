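#' Edinburgh handedness laterality quotient
#'
#' \deqn{LQ = 100 (R - L) / (R + L)} from the right- and left-hand tallies
#' of the Edinburgh inventory items: -100 = exclusive left-hand use,
#' +100 = exclusive right-hand use.
#'
#' @param right_tally,left_tally Nonnegative item tallies (vectorized).
#' @return The quotient in `[-100, 100]`; `NA` where both tallies are zero.
#' @examples
#' edinburgh_lq(6, 3) # 33.33
#' @export
edinburgh_lq <- function(right_tally, left_tally) {
  if (any(right_tally < 0) || any(left_tally < 0))
    abort("tallies must be nonnegative")
  tot <- right_tally + left_tally
  out <- 100 * (right_tally - left_tally) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Categorize manual preference strength
#'
#' `mps3()` maps an Edinburgh score to the 3-level scale: `"Strong L"` for
#' scores at or below -55, `"Strong R"` for exactly 100, `"Moderate"`
#' otherwise (boundaries chosen near the terciles of a
#' handedness-balanced cohort). `mps7()` maps to the 7-level ordinal scale
#' with single-point extreme categories (1 at exactly -100, 7 at exactly
#' 100) and interior intervals `(-100,-75], (-75,-25], (-25,25], (25,75],
#' (75,100)` for categories 2-6 (a score at a shared interval boundary falls
#' to the lower category).
#'
#' @param score Edinburgh scores in `[-100, 100]` (vectorized; `NA` allowed).
#' @return `mps3()`: a factor with levels `Strong L < Moderate < Strong R`;
#'   `mps7()`: an integer vector in 1..7.
#' @examples
#' mps3(c(-55, 0, 100))
#' mps7(c(-100, -75, 25, 100))
#' @export
mps3 <- function(score) {
  check_score(score)
  out <- ifelse(score <= -55, "Strong L",
                ifelse(score == 100, "Strong R", "Moderate"))
  factor(out, levels = c("Strong L", "Moderate", "Strong R"), ordered = TRUE)
}

#' @rdname mps3
#' @export
mps7 <- function(score) {
  check_score(score)
  out <- as.integer(cut(score, breaks = c(-100, -75, -25, 25, 75, 100),
                        labels = FALSE, right = TRUE,
                        include.lowest = TRUE)) + 1L
  out[!is.na(score) & score == -100] <- 1L
  out[!is.na(score) & score == 100] <- 7L
  out
}

check_score <- function(score) {
  bad <- !is.na(score) & (score < -100 | score > 100)
  if (any(bad))
    abort(sprintf("scores out of [-100, 100]: %s",
                  paste(utils::head(score[bad], 5), collapse = ", ")))
}

#' Mid-values of the 7-level manual preference categories
#'
#' @return Numeric vector of length 7: -100, -87, -50, 0, 50, 87, 100.
#' @export
mps7_midvalues <- function() c(-100, -87, -50, 0, 50, 87, 100)

#' Cross-tabulate two categorical cohort variables
#'
#' @param data A data frame.
#' @param row,col Column names (strings) of categorical variables.
#' @return A `contingency_table`: an integer matrix with dimnames, keeping
#'   empty levels of factor inputs. `tidy()` returns the long form with
#'   counts and fractions of the total.
#' @examples
#' co <- assign_types(generate_cohort(seed = 1))
#' contingency(co, "handedness", "lat_type")
#' @export
contingency <- function(data, row, col) {
  if (nrow(data) == 0L) abort("empty cohort")
  if (!row %in% names(data) || !col %in% names(data))
    abort("`row` and `col` must name columns of `data`")
  tab <- table(data[[row]], data[[col]], dnn = c(row, col))
  out <- unclass(as.matrix(tab))
  storage.mode(out) <- "integer"
  structure(out, class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  m <- rbind(cbind(m, All = rowSums(m)), All = c(colSums(m), sum(m)))
  print(m)
  invisible(x)
}

#' @rdname contingency
#' @param x A `contingency_table` (or plain matrix).
#' @param ... Unused.
#' @export
tidy.contingency_table <- function(x, ...) {
  m <- unclass(x)
  df <- as.data.frame.table(as.table(m), responseName = "n")
  names(df)[1:2] <- c("row", "col")
  mutate(as_tibble(df), fraction = .data$n / sum(.data$n))
}

#' Collapse a typed cohort to a 2x2 dominance table
#'
#' Rows: hemisphere contralateral to the preferred hand (Left for
#' right-handers, non-Left for left-handers). Columns: language-dominant
#' hemisphere (Left for Typical, non-Left for Ambilateral and
#' Strongly-atypical pooled).
#'
#' @param data A cohort tibble with `handedness` and a type column.
#' @param type_col Type column: `"lat_type"` (default) or `"binary_type"`
#'   (zero-threshold classification, where `"typical"` maps to Left).
#' @param exclude_strongly_atypical Drop Strongly-atypical subjects first
#'   (only meaningful with `type_col = "lat_type"`).
#' @return A 2x2 `contingency_table` (hand x language, Left / non-Left).
#' @export
collapse_dominance <- function(data, type_col = "lat_type",
                               exclude_strongly_atypical = FALSE) {
  stopifnot("handedness" %in% names(data), type_col %in% names(data))
  data <- filter(data, !is.na(.data[[type_col]]))
  if (exclude_strongly_atypical && "lat_type" %in% names(data))
    data <- filter(data, .data$lat_type != "Strongly-atypical")
  left_lang <- if (type_col == "binary_type") "typical" else "Typical"
  d <- mutate(data,
              hand = factor(ifelse(.data$handedness == "RH", "Left", "non-Left"),
                            levels = c("Left", "non-Left")),
              language = factor(ifelse(.data[[type_col]] == left_lang,
                                       "Left", "non-Left"),
                                levels = c("Left", "non-Left")))
  contingency(d, "hand", "language")
}

#' Cohen's kappa for a square contingency table
#'
#' Chance-corrected agreement \eqn{\kappa = (P_o - P_e)/(1 - P_e)} with
#' observed agreement \eqn{P_o} (diagonal fraction) and expected agreement
#' \eqn{P_e} from the margins. Significance uses the Fleiss large-sample
#' standard error of kappa under the null hypothesis of chance agreement,
#' with a two-sided normal test. Rows and columns must carry matched
#' (aligned) categories in the same order.
#'
#' @param tab Square count matrix (e.g. a [contingency()] result).
#' @return A `kappa_result` with `kappa`, `po`, `pe`, `se0`, `statistic`
#'   (z), `p`, `n`; `tidy()`/`glance()` return it as a one-row tibble.
#' @examples
#' cohen_kappa(matrix(c(130, 120, 14, 33), 2))
#' @export
cohen_kappa <- function(tab) {
  m <- unclass(as.matrix(tab))
  if (nrow(m) != ncol(m)) abort("`tab` must be square (matched categories)")
  n <- sum(m)
  if (n <= 0) abort("`tab` has no observations")
  p <- m / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (1 - pe < 1e-12) {
    warn("degenerate margins: expected agreement is 1; kappa undefined")
    return(structure(list(kappa = NA_real_, po = po, pe = pe, se0 = NA_real_,
                          statistic = NA_real_, p = NA_real_, n = n),
                     class = "kappa_result"))
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Levin-Paik null SE of kappa
  se0 <- sqrt(pe + pe^2 - sum(pr * pc * (pr + pc))) / ((1 - pe) * sqrt(n))
  z <- kappa / se0
  structure(list(kappa = kappa, po = po, pe = pe, se0 = se0, statistic = z,
                 p = 2 * pnorm(-abs(z)), n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (Po = %.4f, Pe = %.4f, n = %d)\n",
              x$kappa, x$po, x$pe, x$n))
  cat(sprintf("  z = %.3f, two-sided p = %.4g (Fleiss null SE %.4f)\n",
              x$statistic, x$p, x$se0))
  invisible(x)
}

#' @rdname cohen_kappa
#' @param x A `kappa_result`.
#' @param ... Unused.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble(kappa = x$kappa, po = x$po, pe = x$pe, se0 = x$se0,
         statistic = x$statistic, p.value = x$p, n = x$n)
}

#' @rdname cohen_kappa
#' @export
glance.kappa_result <- function(x, ...) tidy(x)

#' Fisher exact test for an r x c contingency table
#'
#' Uses the exact network algorithm for the table probability ordering; if
#' exact enumeration is infeasible for a larger table, falls back to seeded
#' Monte-Carlo with at least `1e5` sampled tables (reported in `method`).
#'
#' @param tab Count matrix.
#' @param b Monte-Carlo sample size for the fallback (>= 1e5).
#' @param seed Optional seed for the fallback.
#' @return A one-row tibble: `p.value`, `method`.
#' @export
fisher_exact <- function(tab, b = 1e5, seed = NULL) {
  m <- unclass(as.matrix(tab))
  if (sum(m) > 1e4) abort("table total too large for an exact test")
  if (b < 1e5) abort("`b` must be at least 1e5")
  exact <- tryCatch(fisher.test(m), error = function(e) NULL)
  if (!is.null(exact))
    return(tibble(p.value = exact$p.value, method = "exact"))
  mc <- with_seed(seed, fisher.test(m, simulate.p.value = TRUE, B = as.integer(b)))
  tibble(p.value = mc$p.value, method = sprintf("monte-carlo (B = %d)", as.integer(b)))
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman correlation with the asymptotic t-approximation
#' p-value, suitable when either variable departs from normality.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p.value`, `n`, `valid` (`FALSE` with
#'   `rho = NA` for constant input).
#' @export
spearman_assoc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(tibble(rho = NA_real_, p.value = NA_real_, n = length(x),
                  valid = FALSE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x),
         valid = TRUE)
}

#' Atypical-occurrence regression on manual preference categories
#'
#' Computes, per 7-level manual preference category, the percentage of
#' atypically lateralized subjects (Ambilateral and Strongly-atypical
#' pooled), then fits an ordinary least-squares line of that occurrence on
#' the category mid-values ([mps7_midvalues()]). Empty categories are
#' dropped; at least two nonempty categories are required.
#'
#' @param data A cohort tibble with `mps` and either `lat_type` or a logical
#'   `atypical` column.
#' @return An `occurrence_fit`: per-category tibble in `$table`, the `lm`
#'   fit in `$fit`; `glance()` gives `slope`, `intercept`, `p.value`.
#' @export
occurrence_regression <- function(data) {
  stopifnot("mps" %in% names(data))
  if ("atypical" %in% names(data)) {
    atyp <- data$atypical
  } else if ("lat_type" %in% names(data)) {
    atyp <- data$lat_type != "Typical"
  } else abort("`data` needs a `lat_type` or logical `atypical` column")
  d <- tibble(cat = mps7(data$mps), atypical = atyp) %>%
    filter(!is.na(.data$cat), !is.na(.data$atypical))
  tab <- d %>%
    group_by(.data$cat) %>%
    summarise(n = dplyr::n(), occurrence = 100 * mean(.data$atypical),
              .groups = "drop") %>%
    mutate(mid = mps7_midvalues()[.data$cat], .after = "cat")
  if (nrow(tab) < 2) abort("need at least 2 nonempty categories")
  fit <- lm(occurrence ~ mid, data = tab)
  structure(list(table = tab, fit = fit), class = "occurrence_fit")
}

#' @export
print.occurrence_fit <- function(x, ...) {
  cat("Atypical occurrence by manual preference category\n")
  print(as.data.frame(x$table))
  print(glance(x))
  invisible(x)
}

#' @rdname occurrence_regression
#' @param x An `occurrence_fit`.
#' @param ... Unused.
#' @export
tidy.occurrence_fit <- function(x, ...) x$table

#' @rdname occurrence_regression
#' @export
glance.occurrence_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble(slope = unname(coef(x$fit)[2]), intercept = unname(coef(x$fit)[1]),
         p.value = unname(sm$coefficients["mid", "Pr(>|t|)"]),
         r.squared = sm$r.squared, n_categories = nrow(x$table))
}
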