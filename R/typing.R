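#' Locate interior local minima of a mixture density
#'
#' Scans the density derivative on a regular grid for sign changes from
#' negative to positive, then refines each bracketed root by bisection. The
#' mixture density's local minima are natural classification cutpoints for a
#' multimodal laterality index.
#'
#' @param model A [gaussian_mixture()].
#' @param lower,upper Scan range (defaults cover the index range
#'   `[-100, 100]`).
#' @param step Grid step (default 0.1 index units).
#' @param tol Bisection tolerance on the location (default 1e-3).
#' @return Numeric vector of minima locations, ascending (possibly empty).
#' @examples
#' find_density_minima(hfli_mixture("LH"))
#' @export
find_density_minima <- function(model, lower = -100, upper = 100, step = 0.1,
                                tol = 1e-3) {
  check_mixture(model)
  grid_crossings(model, lower, upper, step, tol, from = 1)
}

# Interior local maxima (modes), same scheme with the opposite crossing.
find_density_maxima <- function(model, lower = -100, upper = 100, step = 0.1,
                                tol = 1e-3) {
  grid_crossings(model, lower, upper, step, tol, from = -1)
}

# Locate sign changes of `from * derivative` from - to + on a regular grid
# (from = 1: density minima; from = -1: maxima),
# refined by bisection. The derivative can be exactly zero at a grid point
# (symmetric models) or underflow to zero over a whole stretch between
# far-apart components; zero runs are treated as part of the crossing and
# resolved to their midpoint.
grid_crossings <- function(model, lower, upper, step, tol, from) {
  grid <- seq(lower, upper, by = step)
  s <- sign(from * dmixture_deriv(grid, model)) # want - -> + transitions
  nz <- which(s != 0)
  if (length(nz) < 2) return(numeric(0))
  pre <- nz[-length(nz)]
  post <- nz[-1]
  idx <- which(s[pre] < 0 & s[post] > 0)
  vapply(idx, function(j) {
    i1 <- pre[j]; i2 <- post[j]
    if (i2 > i1 + 1L) return((grid[i1] + grid[i2]) / 2) # flat zero run
    lo <- grid[i1]; hi <- grid[i2]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (from * dmixture_deriv(mid, model) < 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}

type_labels <- function(n_types) {
  base <- c("Typical", "Ambilateral", "Strongly-atypical")
  if (n_types <= 3L) base[seq_len(n_types)]
  else c(base, paste("Group", 4:n_types))
}

#' Typing thresholds
#'
#' A `typing_thresholds` object holds the ordered HFLI cutpoints separating
#' lateralization types, labelled from the highest-HFLI type downward
#' (Typical above the top cutpoint, then Ambilateral, then
#' Strongly-atypical). `hfli_type_cutpoints()` returns the operational
#' preset (-50, 18): Typical for HFLI > 18, Ambilateral for HFLI in
#' `[-50, 18]`, Strongly-atypical for HFLI < -50.
#'
#' @param cutpoints Strictly increasing numeric vector.
#' @param labels Type labels, length `length(cutpoints) + 1`, highest type
#'   first.
#' @return A `typing_thresholds`.
#' @examples
#' hfli_type_cutpoints()
#' @export
typing_thresholds <- function(cutpoints,
                              labels = type_labels(length(cutpoints) + 1L)) {
  cutpoints <- sort(as.numeric(cutpoints))
  if (anyDuplicated(cutpoints)) abort("`cutpoints` must be strictly increasing")
  if (length(labels) != length(cutpoints) + 1L)
    abort("need one more label than cutpoints")
  structure(list(cutpoints = cutpoints, labels = labels),
            class = "typing_thresholds")
}

#' @rdname typing_thresholds
#' @export
hfli_type_cutpoints <- function() typing_thresholds(c(-50, 18))

#' @export
print.typing_thresholds <- function(x, ...) {
  cat("Typing thresholds:\n")
  cuts <- c(Inf, rev(x$cutpoints), -Inf)
  for (i in seq_along(x$labels))
    cat(sprintf("  %-18s (%s, %s%s\n", x$labels[i],
                format(cuts[i + 1]), format(cuts[i]),
                if (i == 1) ")" else "]"))
  invisible(x)
}

#' Derive typing thresholds by pooling overlapping mixture components
#'
#' Each interior density minimum is a candidate cutpoint between its two
#' flanking components. Adjacent components are pooled (their separating
#' minimum dropped) when the dip is shallow: mixture density at the minimum
#' at least `dip_ratio` times the lower of the mixture densities at the two
#' flanking component means (each component's nominal mode). The
#' retained cutpoints define the types, from the highest-mean pool (Typical)
#' downward. In the reference models the two highest-mean components overlap
#' heavily and are pooled, leaving 2 (right-handers) or 3 (left-handers)
#' types.
#'
#' @param model A [gaussian_mixture()].
#' @param minima Candidate cutpoints (default: [find_density_minima()]).
#' @param dip_ratio Pooling threshold in (0, 1) (default 0.8).
#' @return A [typing_thresholds()]; with no retained minima, a single pooled
#'   type (with a warning when no minima existed at all).
#' @examples
#' pool_components(hfli_mixture("LH"))
#' @export
pool_components <- function(model, minima = NULL, dip_ratio = 0.8) {
  check_mixture(model)
  if (is.null(minima)) minima <- find_density_minima(model)
  minima <- sort(minima)
  if (length(minima) == 0L) {
    warn("mixture density has no interior local minima; single pooled type")
    return(typing_thresholds(numeric(0)))
  }
  means <- sort(model$mean)
  keep <- vapply(minima, function(m) {
    lo_mode <- max(means[means < m], -Inf)
    hi_mode <- min(means[means > m], Inf)
    if (!is.finite(lo_mode) || !is.finite(hi_mode)) return(FALSE)
    dip <- dmixture(m, model)
    dip < dip_ratio * min(dmixture(lo_mode, model), dmixture(hi_mode, model))
  }, logical(1))
  typing_thresholds(minima[keep])
}

#' Assign lateralization types from HFLI values
#'
#' Adds the 3-category (or however many the thresholds define) type and the
#' classical binary classification to a cohort table. Boundary rules: the
#' top type requires an HFLI strictly above the top cutpoint and the bottom
#' type strictly below the bottom cutpoint; values exactly at a cutpoint
#' fall to the type between. The binary classification is `"typical"` for
#' strictly positive HFLI, `"atypical"` otherwise (0 is atypical). Subjects
#' with missing HFLI get `NA` types; their count is recorded in
#' `attr(, "n_excluded")`.
#'
#' @param data A data frame with an HFLI column.
#' @param thresholds A [typing_thresholds()] (default the operational preset
#'   [hfli_type_cutpoints()]).
#' @param hfli_col Name of the HFLI column (default `"hfli"`).
#' @return `data` as a tibble with factor columns `lat_type` (levels from
#'   Typical downward) and `binary_type`.
#' @examples
#' assign_types(tibble::tibble(hfli = c(70, 0, -63)))
#' @export
assign_types <- function(data, thresholds = hfli_type_cutpoints(),
                         hfli_col = "hfli") {
  stopifnot(inherits(thresholds, "typing_thresholds"))
  if (!hfli_col %in% names(data))
    abort(sprintf("column `%s` not found", hfli_col))
  x <- data[[hfli_col]]
  if (any(stats::na.omit(x) < -100 | stats::na.omit(x) > 100))
    abort("HFLI values must lie in [-100, 100]")
  cuts <- thresholds$cutpoints
  k <- length(cuts)
  labels <- thresholds$labels
  idx <- vapply(x, function(xi) {
    if (is.na(xi)) return(NA_integer_)
    if (k == 0L) return(1L)
    if (xi > cuts[k]) return(1L)
    pos <- k + 1L - sum(xi >= cuts) # ties at a cutpoint fall to the type above
    max(pos, 2L)
  }, integer(1))
  out <- as_tibble(data)
  out$lat_type <- factor(labels[idx], levels = labels)
  out$binary_type <- factor(ifelse(is.na(x), NA, ifelse(x > 0, "typical", "atypical")),
                            levels = c("typical", "atypical"))
  attr(out, "n_excluded") <- sum(is.na(x))
  out
}

#' Per-type cohort summary
#'
#' Counts, percentages, and HFLI / MPS moments (mean, n-1 SD) per handedness
#' group and lateralization type.
#'
#' @param data A cohort tibble with `handedness`, `lat_type`, `hfli` and
#'   optionally `mps`.
#' @return A tibble, one row per (handedness, type).
#' @export
type_summary <- function(data) {
  stopifnot(all(c("handedness", "lat_type", "hfli") %in% names(data)))
  has_mps <- "mps" %in% names(data)
  data %>%
    filter(!is.na(.data$lat_type)) %>%
    group_by(.data$handedness, .data$lat_type) %>%
    summarise(n = dplyr::n(),
              hfli_mean = mean(.data$hfli), hfli_sd = sd(.data$hfli),
              mps_mean = if (has_mps) mean(.data$mps) else NA_real_,
              mps_sd = if (has_mps) sd(.data$mps) else NA_real_,
              .groups = "drop_last") %>%
    mutate(pct = 100 * .data$n / sum(.data$n), .after = "n") %>%
    dplyr::ungroup()
}
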