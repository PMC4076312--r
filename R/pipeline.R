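#' Read and validate a cohort table
#'
#' Reads a tabular text file (TSV or CSV by extension) with a header row and
#' columns `subject_id`, `handedness` (`RH`/`LH`), `mps`, and optionally
#' `hfli` and/or t-map file paths (`tmap`, `left_mask`, `right_mask`,
#' `exclusion_mask`). Malformed rows are rejected with their line numbers;
#' duplicate subject ids are an error listing the ids.
#'
#' @param path File path.
#' @return A validated cohort tibble; `attr(, "hfli_scheduled")` is `TRUE`
#'   when no `hfli` column is present but t-map paths are, meaning an HFLI
#'   computation stage is needed.
#' @export
read_cohort <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv else readr::read_tsv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  req <- c("subject_id", "handedness", "mps")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0)
    abort(sprintf("missing required column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  has_hfli <- "hfli" %in% names(raw)
  has_tmaps <- all(c("tmap", "left_mask", "right_mask") %in% names(raw))
  if (!has_hfli && !has_tmaps)
    abort("cohort needs either an `hfli` column or t-map path columns")

  line <- seq_len(nrow(raw)) + 1L # header is line 1
  problems <- character(0)
  bad <- is.na(raw$subject_id) | !raw$handedness %in% c("RH", "LH")
  if (any(bad, na.rm = TRUE))
    problems <- c(problems, sprintf(
      "line %d: invalid subject_id or handedness", line[which(bad)]))
  bad_mps <- !is.na(raw$mps) & (raw$mps < -100 | raw$mps > 100)
  if (any(bad_mps))
    problems <- c(problems, sprintf("line %d: mps out of [-100, 100]",
                                    line[which(bad_mps)]))
  if (has_hfli) {
    bad_h <- !is.na(raw$hfli) & (raw$hfli < -100 | raw$hfli > 100)
    if (any(bad_h))
      problems <- c(problems, sprintf("line %d: hfli out of [-100, 100]",
                                      line[which(bad_h)]))
  }
  if (length(problems) > 0)
    abort(paste(c("malformed cohort rows:", problems), collapse = "\n"))
  dup <- unique(raw$subject_id[duplicated(raw$subject_id)])
  if (length(dup) > 0)
    abort(sprintf("duplicate subject ids: %s", paste(dup, collapse = ", ")))

  out <- as_tibble(raw)
  attr(out, "hfli_scheduled") <- !has_hfli && has_tmaps
  out
}

#' Write a cohort table
#'
#' @param cohort A cohort tibble.
#' @param path Output path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::write_csv else readr::write_tsv
  writer(cohort, path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' @param input `"synthetic"` (generate a cohort), `"cohort"` (a cohort
#'   tibble or file path in `cohort`), or `"tmaps"` (a cohort file whose
#'   rows point to t-map volumes; HFLI is computed first).
#' @param cohort Cohort tibble or file path (for `input != "synthetic"`).
#' @param cohort_config A [cohort_config()] for synthetic input.
#' @param n_range Component counts for mixture selection (default `1:5`).
#' @param typing `"preset"` (operational cutpoints -50 / 18) or `"derived"`
#'   (cutpoints from the pooled-sample fitted mixture's density minima).
#' @param restarts,tol,sigma_floor EM settings, see [fit_mixture()].
#' @param ci Compute bootstrap CIs for the selected models (default `TRUE`).
#' @param n_boot Bootstrap resamples for CIs.
#' @param hfli_settings Named list of [compute_hfli()] arguments for t-map
#'   input.
#' @param seed Integer seed covering every stochastic stage.
#' @return A `lateralization_config` list.
#' @export
lateralization_config <- function(input = c("synthetic", "cohort", "tmaps"),
                                  cohort = NULL,
                                  cohort_config = lateralize::cohort_config(),
                                  n_range = 1:5,
                                  typing = c("preset", "derived"),
                                  restarts = 50, tol = 1e-8, sigma_floor = 0.5,
                                  ci = TRUE, n_boot = 100,
                                  hfli_settings = list(), seed = 1) {
  input <- arg_match(input)
  typing <- arg_match(typing)
  if (input != "synthetic" && is.null(cohort))
    abort("`cohort` is required unless `input = \"synthetic\"`")
  structure(list(input = input, cohort = cohort, cohort_config = cohort_config,
                 n_range = n_range, typing = typing, restarts = restarts,
                 tol = tol, sigma_floor = sigma_floor, ci = ci,
                 n_boot = n_boot, hfli_settings = hfli_settings, seed = seed),
            class = "lateralization_config")
}

#' Run the full lateralization analysis pipeline
#'
#' Stages, in order: obtain a cohort (synthesize, load, or load plus
#' per-subject bootstrap HFLI from t-maps); fit Gaussian mixtures with AICc
#' selection per handedness group and pooled; derive or apply typing
#' thresholds and assign types; compute the association statistics
#' (contingency tables, kappa with and without Strongly-atypicals and for
#' the zero-threshold classification, Fisher exact tests, Spearman
#' correlations, atypical-occurrence regression). Every stochastic stage is
#' seeded from `config$seed`.
#'
#' @param config A [lateralization_config()].
#' @return A `lateralization_report` list: `cohort`, `selection` (per
#'   group), `models`, `ci`, `thresholds`, `typing_summary`, `tables`,
#'   `stats`, `provenance`.
#' @examples
#' \donttest{
#' cfg <- lateralization_config(input = "synthetic", restarts = 10,
#'                              ci = FALSE, seed = 1)
#' run_lateralization(cfg)
#' }
#' @export
run_lateralization <- function(config) {
  stopifnot(inherits(config, "lateralization_config"))
  seed <- config$seed

  cohort <- switch(config$input,
    synthetic = generate_cohort(config$cohort_config, seed = seed),
    cohort = ,
    tmaps = if (is.character(config$cohort)) read_cohort(config$cohort)
            else as_tibble(config$cohort))
  if ("lat_type" %in% names(cohort))
    cohort <- dplyr::rename(cohort, lat_type_generator = "lat_type")

  if (config$input == "tmaps" ||
      isTRUE(attr(cohort, "hfli_scheduled"))) {
    cohort$hfli <- purrr::pmap_dbl(
      list(cohort$tmap, cohort$left_mask, cohort$right_mask,
           if ("exclusion_mask" %in% names(cohort)) cohort$exclusion_mask
           else rep(list(NULL), nrow(cohort)), seq_len(nrow(cohort))),
      function(tm, lm, rm, ex, i) {
        vol <- read_tmap(tm, lm, rm, ex)
        args <- c(list(volume = vol, seed = seed + i), config$hfli_settings)
        do.call(compute_hfli, args)$hfli
      })
  }

  groups <- list(RH = filter(cohort, .data$handedness == "RH"),
                 LH = filter(cohort, .data$handedness == "LH"),
                 pooled = cohort)
  groups <- groups[vapply(groups, nrow, integer(1)) > 0]
  selection <- purrr::imap(groups, function(g, nm)
    tryCatch(select_mixture(g$hfli, n_range = config$n_range,
                            restarts = config$restarts, tol = config$tol,
                            sigma_floor = config$sigma_floor, seed = seed),
             error = function(e) {
               warn(sprintf("mixture selection failed for group %s: %s",
                            nm, conditionMessage(e)))
               NULL
             }))
  if (all(vapply(selection, is.null, logical(1))))
    abort("no group could be fit")
  models <- purrr::map(purrr::compact(selection), best_fit)
  cis <- if (isTRUE(config$ci)) {
    purrr::imap(purrr::compact(selection), function(s, nm)
      mixture_ci(groups[[nm]]$hfli, n = s$best_n, n_boot = config$n_boot,
                 restarts = 10, tol = config$tol,
                 sigma_floor = config$sigma_floor, seed = seed))
  } else NULL

  if (config$typing == "derived" && is.null(models[["pooled"]]))
    abort("derived typing requires a pooled-sample mixture fit")
  derived <- if (!is.null(models[["pooled"]]))
    tryCatch(pool_components(models[["pooled"]]$model),
             warning = function(w) NULL) else NULL
  thresholds <- if (config$typing == "preset") hfli_type_cutpoints()
                else pool_components(models[["pooled"]]$model)

  cohort <- assign_types(cohort, thresholds)
  tables <- list(
    type_by_handedness = contingency(cohort, "handedness", "lat_type"))
  has_mps <- "mps" %in% names(cohort) && !all(is.na(cohort$mps))
  if (has_mps) {
    cohort$mps3 <- mps3(cohort$mps)
    cohort$mps7 <- mps7(cohort$mps)
    tables$type_by_mps3 <- contingency(cohort, "mps3", "lat_type")
  }

  no_sa <- filter(cohort, .data$lat_type != "Strongly-atypical")
  kappa <- list(
    gmm = cohen_kappa(collapse_dominance(cohort)),
    gmm_excl_sa = cohen_kappa(collapse_dominance(cohort,
                                                 exclude_strongly_atypical = TRUE)),
    zero_thr = cohen_kappa(collapse_dominance(cohort, type_col = "binary_type")),
    zero_thr_excl_sa = cohen_kappa(
      collapse_dominance(no_sa, type_col = "binary_type")))
  if (has_mps) {
    # 3x3 alignment: Typical~Strong R, Ambilateral~Moderate,
    # Strongly-atypical~Strong L
    m3 <- table(factor(cohort$mps3, levels = c("Strong R", "Moderate", "Strong L")),
                cohort$lat_type)
    kappa$type_mps3 <- cohen_kappa(as.matrix(m3))
  }

  safe_fisher <- function(tab) {
    tryCatch(fisher_exact(tab, seed = seed), error = function(e)
      tibble(p.value = NA_real_, method = paste("failed:", conditionMessage(e))))
  }
  stats <- list(
    kappa = kappa,
    fisher = list(
      type_by_handedness = safe_fisher(tables$type_by_handedness),
      type_by_handedness_excl_sa = safe_fisher(
        contingency(no_sa, "handedness", "lat_type")[, colnames(
          tables$type_by_handedness) != "Strongly-atypical", drop = FALSE])))
  if (has_mps) {
    stats$fisher$type_by_mps3 <- safe_fisher(tables$type_by_mps3)
    safe_spearman <- function(x, y) {
      tryCatch(spearman_assoc(x, y), error = function(e)
        tibble(rho = NA_real_, p.value = NA_real_, n = length(x),
               valid = FALSE))
    }
    stats$spearman <- purrr::imap(groups, function(g, nm) {
      g2 <- if (nm == "pooled") cohort else
        filter(cohort, .data$handedness == nm)
      list(all = safe_spearman(g2$mps, g2$hfli),
           excl_sa = safe_spearman(
             g2$mps[g2$lat_type != "Strongly-atypical"],
             g2$hfli[g2$lat_type != "Strongly-atypical"]))
    })
    stats$occurrence <- tryCatch(occurrence_regression(cohort),
                                 error = function(e) NULL)
  }

  structure(list(
    cohort = cohort, selection = selection, models = models, ci = cis,
    thresholds = thresholds, derived_thresholds = derived,
    typing_summary = type_summary(cohort), tables = tables, stats = stats,
    provenance = list(seed = seed, input = config$input,
                      n_range = config$n_range, typing = config$typing,
                      restarts = config$restarts,
                      package_version = as.character(utils::packageVersion("lateralize")))),
    class = "lateralization_report")
}

#' @export
print.lateralization_report <- function(x, ...) {
  cat(sprintf("Lateralization analysis report (n = %d subjects, seed %s)\n",
              nrow(x$cohort), format(x$provenance$seed)))
  for (nm in names(x$selection)) {
    if (is.null(x$selection[[nm]])) next
    cat(sprintf("  %s: %d-component mixture selected (AICc %.1f)\n", nm,
                x$selection[[nm]]$best_n, best_fit(x$selection[[nm]])$aicc))
  }
  cat("Typing summary:\n")
  print(as.data.frame(x$typing_summary))
  cat(sprintf("kappa (hand vs language dominance): %.3f (p = %.3g); excl. Strongly-atypical: %.3f (p = %.3g)\n",
              x$stats$kappa$gmm$kappa, x$stats$kappa$gmm$p,
              x$stats$kappa$gmm_excl_sa$kappa, x$stats$kappa$gmm_excl_sa$p))
  invisible(x)
}

#' Write a report's artifacts to a directory
#'
#' Writes the typed cohort, per-group model-selection tables, fitted model
#' parameters (with CIs when present), the typing summary, contingency
#' tables (TSV), and a machine-readable `stats.json`. Output is
#' deterministic: no timestamps.
#'
#' @param report A `lateralization_report`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "lateralization_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  readr::write_tsv(report$cohort, p("cohort.tsv"))
  for (nm in names(report$selection))
    readr::write_tsv(tidy(report$selection[[nm]]), p(sprintf("selection_%s.tsv", nm)))
  for (nm in names(report$models))
    readr::write_tsv(tidy(report$models[[nm]]), p(sprintf("model_%s.tsv", nm)))
  if (!is.null(report$ci))
    for (nm in names(report$ci))
      readr::write_tsv(report$ci[[nm]], p(sprintf("ci_%s.tsv", nm)))
  readr::write_tsv(report$typing_summary, p("typing_summary.tsv"))
  for (nm in names(report$tables))
    readr::write_tsv(tidy(report$tables[[nm]]), p(sprintf("table_%s.tsv", nm)))
  stats <- list(
    kappa = purrr::map(report$stats$kappa, tidy),
    fisher = report$stats$fisher,
    spearman = report$stats$spearman,
    occurrence = if (!is.null(report$stats$occurrence))
      list(table = tidy(report$stats$occurrence),
           fit = glance(report$stats$occurrence)),
    thresholds = list(cutpoints = report$thresholds$cutpoints,
                      labels = report$thresholds$labels,
                      derived_cutpoints = report$derived_thresholds$cutpoints),
    provenance = report$provenance)
  jsonlite::write_json(stats, p("stats.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}
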