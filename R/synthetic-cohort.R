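#' Reference manual-preference-score moments by handedness and type
#'
#' Cell means and SDs (Edinburgh units) of the manual preference strength
#' (MPS) score conditional on handedness and language lateralization type,
#' as observed in the 297-subject reference cohort. No right-hander was
#' Strongly-atypical, so that cell has no moments.
#'
#' @return A tibble with columns `handedness`, `lat_type`, `mean`, `sd`.
#' @export
mps_moments <- function() {
  tibble(
    handedness = c("RH", "RH", "LH", "LH", "LH"),
    lat_type = c("Typical", "Ambilateral",
                 "Typical", "Ambilateral", "Strongly-atypical"),
    mean = c(93, 94, -59, -73, -87),
    sd = c(11, 12, 42, 29, 18)
  )
}

# Map mixture components (descending mean) to lateralization types: the two
# highest-mean components jointly form "Typical" (they overlap too much to be
# told apart), then one type per remaining component.
component_types <- function(n_components) {
  if (n_components <= 2L) return(rep("Typical", n_components))
  c("Typical", "Typical", "Ambilateral",
    rep("Strongly-atypical", n_components - 3L))
}

#' Cohort generator configuration
#'
#' Bundles the pieces [generate_cohort()] needs: group sizes, the
#' handedness-specific HFLI mixtures, and the conditional MPS moments.
#' Defaults reproduce the reference study conditions: 144 right-handers and
#' 153 left-handers with the published mixture parameters.
#'
#' @param n_rh,n_lh Nonnegative group sizes.
#' @param rh_mixture,lh_mixture [gaussian_mixture()] models for the HFLI of
#'   each handedness group.
#' @param mps_moments Tibble as returned by [mps_moments()].
#' @param seed Optional integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_rh = 144, n_lh = 153,
                          rh_mixture = hfli_mixture("RH"),
                          lh_mixture = hfli_mixture("LH"),
                          mps_moments = lateralize::mps_moments(),
                          seed = NULL) {
  stopifnot(n_rh >= 0, n_lh >= 0, n_rh == round(n_rh), n_lh == round(n_lh))
  check_mixture(rh_mixture)
  check_mixture(lh_mixture)
  req <- c("handedness", "lat_type", "mean", "sd")
  if (!all(req %in% names(mps_moments)))
    abort("`mps_moments` must have columns handedness, lat_type, mean, sd")
  if (any(abs(mps_moments$mean) > 100))
    abort("MPS cell means must lie in [-100, 100]")
  if (any(mps_moments$sd < 0)) abort("MPS cell SDs must be nonnegative")
  structure(list(n_rh = as.integer(n_rh), n_lh = as.integer(n_lh),
                 rh_mixture = rh_mixture, lh_mixture = lh_mixture,
                 mps_moments = mps_moments, seed = seed),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws one record per subject: HFLI from the handedness-specific Gaussian
#' mixture (clipped to the index range `[-100, 100]`), a lateralization type
#' taken from the mixture component that generated the HFLI (top two
#' components = Typical, next = Ambilateral, lowest = Strongly-atypical),
#' and an MPS score drawn from the (handedness, type)-conditional normal and
#' clipped to `[-100, 100]`. MPS is independent of HFLI within a cell; only
#' the cell moments are emulated.
#'
#' @param config A [cohort_config()]; the remaining arguments override its
#'   fields for convenience.
#' @inheritParams cohort_config
#' @return A tibble with `subject_id`, `handedness`, `mps`, `hfli`, and the
#'   generating `lat_type`, deterministic given `seed`.
#' @examples
#' generate_cohort(seed = 1)
#' @export
generate_cohort <- function(config = cohort_config(), n_rh = NULL, n_lh = NULL,
                            seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(n_rh) || !is.null(n_lh) || !is.null(seed))
    config <- cohort_config(
      n_rh = n_rh %||% config$n_rh, n_lh = n_lh %||% config$n_lh,
      rh_mixture = config$rh_mixture, lh_mixture = config$lh_mixture,
      mps_moments = config$mps_moments, seed = seed %||% config$seed)

  one_group <- function(handedness, n, model) {
    draw <- sample_mixture(model, n, keep_components = TRUE)
    types <- component_types(nrow(model))
    lat_type <- types[draw$component]
    cells <- left_join(tibble(handedness = handedness, lat_type = lat_type),
                       config$mps_moments, by = c("handedness", "lat_type"))
    if (anyNA(cells$mean))
      abort(sprintf("no MPS moments for cell %s / %s", handedness,
                    lat_type[which(is.na(cells$mean))[1]]))
    tibble(handedness = handedness,
           mps = pmin(pmax(rnorm(n, cells$mean, cells$sd), -100), 100),
           hfli = pmin(pmax(draw$value, -100), 100),
           lat_type = lat_type)
  }

  with_seed(config$seed, {
    out <- bind_rows(one_group("RH", config$n_rh, config$rh_mixture),
                     one_group("LH", config$n_lh, config$lh_mixture))
    mutate(out, subject_id = sprintf("S%04d", dplyr::row_number()), .before = 1)
  })
}

#' Generate a synthetic lateralized t-map
#'
#' Builds a [tmap_volume()] whose voxel t-values are
#' `normal(effect, noise_sd)` with a hemisphere-specific effect. The volume
#' is split into hemispheres at the midplane of the first (left-right) axis;
#' with an odd axis the midplane column belongs to neither hemisphere (and
#' carries the average effect, so noiseless symmetric volumes are exactly
#' mirror-symmetric). An exclusion mask covering the first
#' `exclusion_depth` fraction of slices along the second
#' (anterior-posterior) axis stands in for removing the cerebellum.
#'
#' @param dim Integer 3-vector of grid dimensions; the first axis needs at
#'   least 2 voxels.
#' @param effect_left,effect_right Mean t-value per hemisphere.
#' @param noise_sd Voxel noise SD in t-units (>= 0).
#' @param seed Optional integer seed.
#' @param exclusion_depth Fraction of posterior slices excluded
#'   (default 0.15).
#' @return A `tmap_volume`.
#' @examples
#' generate_tmap(c(10, 10, 10), 5, 0, noise_sd = 0)
#' @export
generate_tmap <- function(dim = c(24L, 24L, 24L), effect_left = 3,
                          effect_right = 1, noise_sd = 1, seed = NULL,
                          exclusion_depth = 0.15) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L) || dim[1] < 2L)
    abort("`dim` must be a 3-vector with at least 2 voxels on the first axis")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative")
  nx <- dim[1]
  half <- nx %/% 2L
  xs <- slice.index(array(0, dim), 1)
  left <- xs <= half
  right <- xs > nx - half # leaves the midplane column out when nx is odd
  eff <- array((effect_left + effect_right) / 2, dim)
  eff[left] <- effect_left
  eff[right] <- effect_right
  ny <- dim[2]
  excl_depth <- min(ny, ceiling(exclusion_depth * ny))
  excl <- slice.index(array(0, dim), 2) <= excl_depth
  with_seed(seed, {
    vals <- array(rnorm(prod(dim), mean = eff, sd = noise_sd), dim)
    tmap_volume(vals, left, right, excl)
  })
}

#' Read and write t-map volumes as NIfTI
#'
#' `write_tmap()` writes the t-values and the three masks as four NIfTI
#' files with an identity orientation (`<prefix>_tmap.nii`,
#' `_left.nii`, `_right.nii`, `_excl.nii`); `read_tmap()` assembles a
#' [tmap_volume()] from such files (mask voxels are included where nonzero).
#'
#' @param volume A [tmap_volume()].
#' @param prefix Path prefix for the four files.
#' @param tmap,left_mask,right_mask,exclusion_mask NIfTI file paths;
#'   `exclusion_mask` may be `NULL`.
#' @return `write_tmap()` the file paths, invisibly; `read_tmap()` a
#'   `tmap_volume`.
#' @export
write_tmap <- function(volume, prefix) {
  stopifnot(inherits(volume, "tmap_volume"))
  paths <- paste0(prefix, c("_tmap.nii", "_left.nii", "_right.nii", "_excl.nii"))
  RNifti::writeNifti(volume$values, paths[1])
  RNifti::writeNifti(volume$left_mask * 1, paths[2])
  RNifti::writeNifti(volume$right_mask * 1, paths[3])
  RNifti::writeNifti(volume$exclusion_mask * 1, paths[4])
  invisible(paths)
}

#' @rdname write_tmap
#' @export
read_tmap <- function(tmap, left_mask, right_mask, exclusion_mask = NULL) {
  rd <- function(p) as.array(RNifti::readNifti(p))
  tmap_volume(rd(tmap), rd(left_mask), rd(right_mask),
              if (!is.null(exclusion_mask)) rd(exclusion_mask))
}
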