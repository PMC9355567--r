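# End-to-end orchestration: per-assay fitness estimation, clone combination
# into population-timepoint estimates, background fitness, and recovery
# scoring against a synthetic truth table.

#' Estimate fitness effects for every assay of a study
#'
#' Runs [assay_fitness()] on each clone's count table, measures each clone's
#' background fitness from its reference-competition series, combines the two
#' clones of every population-timepoint into inverse-variance weighted
#' estimates (with the pooled-cBC standard error and the neutral floor), and
#' tests each mutation for a nonzero effect with BH correction per
#' environment.
#'
#' @param assays Named list (by `clone_id`) of per-assay count tibbles, or a
#'   `synthetic_study` (whose counts and competition series are used).
#' @param metadata Per-clone tibble with `clone_id`, `environment`,
#'   `population`, `timepoint`, `generation` (ignored when `assays` is a
#'   `synthetic_study`).
#' @param competition Named list of reference-competition series per clone
#'   (optional; enables background-fitness estimation).
#' @param generations_per_cycle,min_total,min_count,spike_timepoint,spike_delta,llr_cutoff,max_cbcs
#'   Passed to [assay_fitness()].
#' @param seed Base seed for the per-assay cBC partitions.
#' @param min_total_cbcs Pooled-cBC floor for a population-timepoint estimate
#'   (default 3).
#' @return List: `estimates` (long tibble: `mutation_id`, `environment`,
#'   `population`, `timepoint`, `generation`, `s`, `sigma_cbc`, `sigma_neut`,
#'   `sigma`, `num_cbcs`, `p`, `significant`), `clone_estimates`,
#'   `background` (per population-timepoint `x`, `x_sd`),
#'   `clone_background`, `exclusions`.
#' @export
study_estimates <- function(assays, metadata = NULL, competition = NULL,
                            generations_per_cycle = 10,
                            min_total = 5000, min_count = 10,
                            spike_timepoint = 2L, spike_delta = 0.5,
                            llr_cutoff = 40, max_cbcs = 5L, seed = 1L,
                            min_total_cbcs = 3L) {
  if (inherits(assays, "synthetic_study")) {
    study <- assays
    metadata <- study$metadata
    competition <- study$competition
    generations_per_cycle <- study$assay$generations_per_cycle
    assays <- lapply(study$assays, `[[`, "counts")
  }
  stopifnot(!is.null(metadata))

  per_assay <- vector("list", length(assays))
  names(per_assay) <- names(assays)
  for (i in seq_along(assays)) {
    per_assay[[i]] <- assay_fitness(
      assays[[i]], generations_per_cycle = generations_per_cycle,
      min_total = min_total, min_count = min_count,
      spike_timepoint = spike_timepoint, spike_delta = spike_delta,
      llr_cutoff = llr_cutoff, max_cbcs = max_cbcs,
      seed = seed + i)
  }

  clone_estimates <- dplyr::bind_rows(lapply(names(per_assay), function(cl) {
    dplyr::bind_cols(tibble::tibble(clone_id = cl),
                     per_assay[[cl]]$clone_summary)
  }))
  clone_estimates <- dplyr::left_join(
    clone_estimates,
    metadata[, c("clone_id", "environment", "population", "timepoint",
                 "generation")],
    by = "clone_id")

  clone_background <- NULL
  background <- NULL
  if (!is.null(competition)) {
    clone_background <- dplyr::bind_rows(lapply(names(competition), function(cl) {
      dplyr::bind_cols(tibble::tibble(clone_id = cl),
                       background_fitness(competition[[cl]],
                                          generations_per_cycle))
    }))
    clone_background <- dplyr::left_join(
      clone_background,
      metadata[, c("clone_id", "environment", "population", "timepoint")],
      by = "clone_id")
    background <- dplyr::summarise(
      dplyr::group_by(clone_background, .data$environment, .data$population,
                      .data$timepoint),
      x_sd = if (dplyr::n() > 1L) sd(.data$x) else NA_real_,
      x = mean(.data$x),
      .groups = "drop")
  }

  # combine clones per population-timepoint
  bg_groups <- dplyr::distinct(metadata, .data$environment, .data$population,
                               .data$timepoint, .data$generation)
  est_rows <- list()
  for (i in seq_len(nrow(bg_groups))) {
    bg <- bg_groups[i, ]
    clones <- metadata$clone_id[
      metadata$environment == bg$environment &
        metadata$population == bg$population &
        metadata$timepoint == bg$timepoint]
    cbc_all <- dplyr::bind_rows(lapply(clones, function(cl) {
      dplyr::bind_cols(tibble::tibble(clone_id = cl),
                       per_assay[[cl]]$cbc_fitness)
    }))
    sigma_neut_pt <- neutral_sigma(cbc_all$s[cbc_all$neutral])
    ce <- clone_estimates[clone_estimates$clone_id %in% clones &
                            !clone_estimates$neutral, ]
    for (mut in unique(ce$mutation_id)) {
      ce_m <- ce[ce$mutation_id == mut, ]
      cbc_m <- cbc_all[cbc_all$mutation_id == mut, ]
      pt <- population_timepoint_fitness(ce_m, cbc_m$s, sigma_neut_pt,
                                         min_total_cbcs = min_total_cbcs)
      if (is.null(pt)) next
      test <- test_nonzero_effect(cbc_m$s, cbc_m$clone_id)
      est_rows[[length(est_rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(mutation_id = mut), bg, pt,
        tibble::tibble(p = test$p))
    }
  }
  estimates <- dplyr::bind_rows(est_rows)
  if (nrow(estimates)) {
    estimates <- dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(estimates, .data$environment),
      significant = bh_significant(.data$p)))
  }

  list(estimates = estimates,
       clone_estimates = clone_estimates,
       background = background,
       clone_background = clone_background,
       exclusions = dplyr::bind_rows(lapply(names(per_assay), function(cl) {
         ex <- per_assay[[cl]]$exclusions
         if (nrow(ex)) dplyr::bind_cols(tibble::tibble(clone_id = cl), ex)
       })))
}

#' Score estimates against the synthetic truth
#'
#' Joins population-timepoint estimates with the generator's true effect
#' surface on (mutation, environment, population, timepoint) and reports the
#' error `s - s_true`, the standardized error `z = (s - s_true) / sigma`, and
#' the fraction of estimates within `3 * sigma` of the truth.
#'
#' @param estimates Estimate table from [study_estimates()].
#' @param truth A `truth_table`.
#' @return List: `joined` (per-estimate tibble with `error`, `z`),
#'   `coverage_3sigma` (fraction with `|z| < 3`), `rmse`.
#' @export
recovery_report <- function(estimates, truth) {
  joined <- dplyr::inner_join(
    estimates, truth$effects,
    by = c("mutation_id", "environment", "population", "timepoint"))
  joined$error <- joined$s - joined$s_true
  joined$z <- joined$error / joined$sigma
  list(joined = tibble::as_tibble(joined),
       coverage_3sigma = mean(abs(joined$z) < 3),
       rmse = sqrt(mean(joined$error^2)))
}

# ---- TSV interfaces ----

#' Read or write the package's tabular interchange files
#'
#' Plain-TSV readers/writers for the pipeline's inputs and outputs: barcode
#' maps, per-assay lineage counts, experiment metadata, and estimate tables.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name barfit_io
NULL

#' @rdname barfit_io
#' @export
read_barcode_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(barcode = "c"))
  validate_barcode_map(map)
  map
}

#' @rdname barfit_io
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname barfit_io
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname barfit_io
#' @export
write_estimates_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname barfit_io
#' @export
read_estimates_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Export per-mutation epistasis fits as JSON
#'
#' @param fits Result of [fit_epistasis_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  payload <- lapply(seq_len(nrow(fits$fits)), function(i) {
    f <- fits$fits$fit[[i]]
    list(environment = fits$fits$environment[i],
         mutation_id = fits$fits$mutation_id[i],
         model = f$model,
         beta = if (is.na(f$beta)) NULL else f$beta,
         alphas = f$alphas,
         r_squared = f$r_squared,
         bic = f$bic,
         n_points = f$n_points)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
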