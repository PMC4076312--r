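#' Construct a t-map volume with hemisphere masks
#'
#' Container for a 3D t-statistic grid plus left/right hemisphere masks and
#' an optional exclusion mask (regions removed before any voxel counting,
#' e.g. the cerebellum). After applying the exclusion, the two hemisphere
#' masks must be disjoint.
#'
#' @param values 3D numeric array of t-statistics.
#' @param left_mask,right_mask 3D logical (or 0/1) arrays, same dimensions;
#'   nonzero = voxel included.
#' @param exclusion_mask Optional 3D array; nonzero voxels are removed from
#'   both hemispheres before anything else.
#' @return A `tmap_volume`.
#' @export
tmap_volume <- function(values, left_mask, right_mask, exclusion_mask = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) abort("`values` must be a 3D array")
  as_mask <- function(m, what) {
    if (is.null(m)) return(array(FALSE, dim(values)))
    m <- array(as.logical(m != 0), dim(m))
    if (!identical(dim(m), dim(values)))
      abort(sprintf("`%s` dimensions do not match `values`", what))
    m
  }
  left <- as_mask(left_mask, "left_mask")
  right <- as_mask(right_mask, "right_mask")
  excl <- if (is.null(exclusion_mask)) array(FALSE, dim(values))
          else as_mask(exclusion_mask, "exclusion_mask")
  if (any(left & right & !excl))
    abort("hemisphere masks overlap outside the exclusion mask")
  structure(list(values = values, left_mask = left, right_mask = right,
                 exclusion_mask = excl),
            class = "tmap_volume")
}

#' @export
print.tmap_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("t-map volume %dx%dx%d: %d left / %d right / %d excluded voxels\n",
              d[1], d[2], d[3], sum(x$left_mask & !x$exclusion_mask),
              sum(x$right_mask & !x$exclusion_mask), sum(x$exclusion_mask)))
  invisible(x)
}

#' Extract suprathreshold voxel values per hemisphere
#'
#' Removes excluded voxels, then returns the t-values strictly greater than
#' `threshold` within each hemisphere mask ("positive t-map" at the default
#' `threshold = 0`: zeros are excluded). Values are returned sorted
#' (ascending), which makes seeded resampling invariant to voxel storage
#' order.
#'
#' @param volume A [tmap_volume()].
#' @param threshold t-value cutoff (strict inequality).
#' @return A list with numeric vectors `left` and `right` (possibly empty).
#' @export
extract_suprathreshold <- function(volume, threshold = 0) {
  stopifnot(inherits(volume, "tmap_volume"))
  keep <- !volume$exclusion_mask
  l <- volume$values[volume$left_mask & keep]
  r <- volume$values[volume$right_mask & keep]
  list(left = sort(l[l > threshold]), right = sort(r[r > threshold]))
}

#' Laterality index from two activation masses
#'
#' \deqn{LI = 100 (L - R) / (L + R)} so that +100 is purely left and -100
#' purely right activation.
#'
#' @param sum_left,sum_right Nonnegative activation masses (sums of
#'   suprathreshold voxel t-values, or voxel counts). Vectorized.
#' @return The index in `[-100, 100]`; `NA` where both masses are zero.
#' @examples
#' li_value(10, 0) # +100
#' li_value(3, 1)  # 50
#' @export
li_value <- function(sum_left, sum_right) {
  tot <- sum_left + sum_right
  out <- 100 * (sum_left - sum_right) / tot
  out[tot <= 0] <- NA_real_
  out
}

#' Bootstrap hemispheric functional lateralization index (HFLI)
#'
#' Per hemisphere, draws `n_iter` resamples with replacement of size
#' `clamp(round(k * n_voxels), min_sample, max_sample)` from the sorted
#' suprathreshold voxel values, forms all `n_iter * n_iter` pairwise
#' laterality indices from the resample sums ([li_value()]), discards the
#' `trim` fraction of lowest and of highest pairwise values, and returns the
#' mean of the retained ones. The result is the weighted (t-value-magnitude
#' weighted) laterality index; `weighting = "count"` instead returns the
#' index of the raw suprathreshold voxel counts (no bootstrap variability).
#'
#' With a multi-threshold ladder (`thresholds` a vector), the index is the
#' weighted mean of per-threshold indices, weights proportional to the
#' threshold values; this is off by default (single `threshold = 0`).
#'
#' @param volume A [tmap_volume()].
#' @param threshold t-value cutoff (default 0, strict).
#' @param k Resample ratio in (0, 1] (default 0.25).
#' @param min_sample,max_sample Bounds on the resample size in voxels
#'   (defaults 5 and 1000). A hemisphere with fewer than `min_sample`
#'   suprathreshold voxels makes the result invalid, except that a
#'   completely empty hemisphere opposite a well-populated one gives the
#'   exact unilateral index (+100 or -100).
#' @param n_iter Bootstrap resamples per hemisphere (default 100).
#' @param trim Fraction of the pairwise index distribution trimmed per tail
#'   (default 0.25; must be in `[0, 0.5)`).
#' @param seed Optional integer seed. Each hemisphere's resample index
#'   stream is drawn from this same seed, so the schedule depends only on
#'   the seed, the hemisphere's voxel count and the resample size; swapping
#'   the hemisphere masks therefore negates the index exactly.
#' @param weighting `"sum"` (default) or `"count"`.
#' @param thresholds Optional vector of positive thresholds for the ladder
#'   variant; overrides `threshold`.
#' @return A one-row tibble: `hfli`, `n_left`, `n_right`, `valid`, `reason`.
#' @examples
#' tm <- generate_tmap(c(12, 12, 12), effect_left = 3, effect_right = 1,
#'                     noise_sd = 1, seed = 7)
#' compute_hfli(tm, seed = 1)
#' @export
compute_hfli <- function(volume, threshold = 0, k = 0.25, min_sample = 5,
                         max_sample = 1000, n_iter = 100, trim = 0.25,
                         seed = NULL, weighting = c("sum", "count"),
                         thresholds = NULL) {
  weighting <- arg_match(weighting)
  if (k <= 0 || k > 1) abort("`k` must be in (0, 1]")
  if (min_sample > max_sample) abort("`min_sample` must be <= `max_sample`")
  if (trim < 0 || trim >= 0.5) abort("`trim` must be in [0, 0.5)")

  if (!is.null(thresholds)) {
    if (any(thresholds < 0)) abort("ladder `thresholds` must be nonnegative")
    rows <- lapply(thresholds, function(th)
      compute_hfli(volume, threshold = th, k = k, min_sample = min_sample,
                   max_sample = max_sample, n_iter = n_iter, trim = trim,
                   seed = seed, weighting = weighting))
    rows <- bind_rows(rows)
    ok <- rows$valid
    if (!any(ok))
      return(tibble(hfli = NA_real_, n_left = 0L, n_right = 0L, valid = FALSE,
                    reason = "no threshold level yielded a valid index"))
    w <- thresholds[ok]
    if (all(w == 0)) w <- rep(1, sum(ok))
    return(tibble(hfli = sum(rows$hfli[ok] * w) / sum(w),
                  n_left = rows$n_left[which(ok)[1]],
                  n_right = rows$n_right[which(ok)[1]],
                  valid = TRUE, reason = NA_character_))
  }

  supra <- extract_suprathreshold(volume, threshold)
  nl <- length(supra$left); nr <- length(supra$right)
  invalid <- function(reason)
    tibble(hfli = NA_real_, n_left = nl, n_right = nr, valid = FALSE,
           reason = reason)
  # purely unilateral activation: nothing to resample against, the index is
  # exact by definition
  if (nl >= min_sample && nr == 0L)
    return(tibble(hfli = 100, n_left = nl, n_right = nr, valid = TRUE,
                  reason = NA_character_))
  if (nr >= min_sample && nl == 0L)
    return(tibble(hfli = -100, n_left = nl, n_right = nr, valid = TRUE,
                  reason = NA_character_))
  if (nl < min_sample || nr < min_sample)
    return(invalid(sprintf(
      "fewer than %d suprathreshold voxels in %s hemisphere", min_sample,
      if (nl < min_sample && nr < min_sample) "either"
      else if (nl < min_sample) "left" else "right")))

  if (weighting == "count") {
    return(tibble(hfli = li_value(nl, nr), n_left = nl, n_right = nr,
                  valid = TRUE, reason = NA_character_))
  }

  ml <- min(max(as.integer(round(k * nl)), min_sample), max_sample)
  mr <- min(max(as.integer(round(k * nr)), min_sample), max_sample)
  # each hemisphere's index stream is restarted from the same seed, so the
  # schedule depends only on (seed, n_voxels, resample size): swapping the
  # hemisphere masks mirrors the schedule and negates the index exactly
  sums_l <- with_seed(seed, resample_sums(supra$left, ml, n_iter))
  sums_r <- with_seed(seed, resample_sums(supra$right, mr, n_iter))
  li <- li_value(rep(sums_l, times = n_iter),
                 rep(sums_r, each = n_iter))
  li <- sort(li)
  drop <- floor(trim * length(li))
  kept <- if (drop > 0) li[(drop + 1):(length(li) - drop)] else li
  tibble(hfli = mean(kept), n_left = nl, n_right = nr, valid = TRUE,
         reason = NA_character_)
}

# n_iter resample sums of size m with replacement; resample j uses draws
# ((j-1)*m + 1):(j*m) of the index stream.
resample_sums <- function(values, m, n_iter) {
  idx <- sample.int(length(values), m * n_iter, replace = TRUE)
  colSums(matrix(values[idx], nrow = m))
}
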