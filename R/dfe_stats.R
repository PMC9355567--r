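# DFE-level statistics over a measurement matrix of fitness effects.
#
# The measurement matrix is held in long form: one row per measured
# (mutation, background) cell, where a background is one population-timepoint
# (or one clone) in one environment. Required columns: mutation_id,
# environment, population, timepoint, generation, s, sigma_cbc, sigma_neut.

# Internal: background key columns.
bg_key <- c("environment", "population", "timepoint")

#' Mean of the distribution of fitness effects for each background
#'
#' The DFE mean for a background is the mean fitness effect over its measured
#' mutations; backgrounds with fewer than `min_mutations` measurements are
#' dropped. Its standard error combines per-mutation measurement error (scaled
#' by the number of mutations) with the background's neutral-set error, which
#' is shared across mutations and therefore not scaled:
#' `sigma_DFE = sqrt(sum(sigma_cbc^2) / n^2 + sigma_neut^2)`.
#' Filled-in cells (see [fill_in_dfe()]) contribute to the mean but carry no
#' measurement variance (`sigma_cbc` is `NA` and excluded from the sum).
#'
#' @param estimates Long measurement table (see file header); may carry a
#'   logical `filled` column.
#' @param min_mutations Minimum measured mutations per background
#'   (default 60).
#' @return Tibble with one row per retained background: key columns,
#'   `generation`, `dfe_mean`, `sigma_dfe_mean`, `n_mutations`, `n_filled`.
#' @export
dfe_mean <- function(estimates, min_mutations = 60L) {
  if (!"filled" %in% names(estimates)) estimates$filled <- FALSE
  out <- dplyr::summarise(
    dplyr::group_by(estimates, dplyr::across(dplyr::all_of(c(bg_key, "generation")))),
    dfe_mean = mean(.data$s),
    sigma_dfe_mean = sqrt(
      sum(.data$sigma_cbc[!is.na(.data$sigma_cbc)]^2) / dplyr::n()^2 +
        .data$sigma_neut[which(!is.na(.data$sigma_neut))[1]]^2),
    n_mutations = dplyr::n(),
    n_filled = sum(.data$filled),
    .groups = "drop"
  )
  out[out$n_mutations >= min_mutations, , drop = FALSE]
}

#' Mutations measured in every background of each environment
#'
#' @param estimates Long measurement table.
#' @return Tibble `environment`, `mutation_id` for mutations with a
#'   measurement in every background of that environment (possibly empty).
#' @export
shared_mutation_set <- function(estimates) {
  n_bg <- dplyr::summarise(
    dplyr::group_by(estimates, .data$environment),
    n_backgrounds = dplyr::n_distinct(paste(.data$population, .data$timepoint)),
    .groups = "drop")
  per_mut <- dplyr::summarise(
    dplyr::group_by(estimates, .data$environment, .data$mutation_id),
    n_measured = dplyr::n_distinct(paste(.data$population, .data$timepoint)),
    .groups = "drop")
  per_mut <- dplyr::left_join(per_mut, n_bg, by = "environment")
  out <- per_mut[per_mut$n_measured == per_mut$n_backgrounds,
                 c("environment", "mutation_id")]
  tibble::as_tibble(out)
}

#' Greedy largest clone set with a floor on shared mutations
#'
#' Iterates through clones sorted by descending number of measured mutations,
#' adding each to the set as long as the number of mutations measured in
#' every clone of the set stays at or above `min_shared`; stops before the
#' first clone whose addition would drop the intersection below the floor.
#'
#' @param clone_measurements Tibble with columns `clone_id`, `mutation_id`
#'   (one row per measured pair), for one condition.
#' @param min_shared Intersection floor (default 40).
#' @return Character vector of the selected clone ids.
#' @export
largest_clone_set <- function(clone_measurements, min_shared = 40L) {
  sets <- split(unique(clone_measurements[, c("clone_id", "mutation_id")])$mutation_id,
                unique(clone_measurements[, c("clone_id", "mutation_id")])$clone_id)
  ord <- names(sort(vapply(sets, length, integer(1)), decreasing = TRUE))
  chosen <- character(0)
  current <- NULL
  for (cl in ord) {
    candidate <- if (is.null(current)) sets[[cl]] else intersect(current, sets[[cl]])
    if (length(candidate) < min_shared) break
    chosen <- c(chosen, cl)
    current <- candidate
  }
  chosen
}

#' Fill in missing measurements with per-mutation condition means
#'
#' Completes the measurement matrix of each environment: a missing
#' (mutation, background) cell receives the mean fitness effect of that
#' mutation across the backgrounds where it was measured in that environment.
#' Filled cells are flagged and carry no measurement variance (`sigma_cbc =
#' NA`); measured cells are untouched. A mutation with no measurement at all
#' in an environment cannot be filled and is dropped with a warning.
#'
#' @param estimates Long measurement table.
#' @return The completed table with a logical `filled` column.
#' @export
fill_in_dfe <- function(estimates) {
  if (!"filled" %in% names(estimates)) estimates$filled <- FALSE
  backgrounds <- dplyr::distinct(
    estimates, dplyr::across(dplyr::all_of(c(bg_key, "generation"))))
  # per-background neutral error applies to all cells of that background
  bg_neut <- dplyr::distinct(
    estimates[!is.na(estimates$sigma_neut), ],
    dplyr::across(dplyr::all_of(bg_key)), .data$sigma_neut)
  muts <- dplyr::distinct(estimates, .data$environment, .data$mutation_id)
  grid <- dplyr::inner_join(muts, backgrounds, by = "environment",
                            relationship = "many-to-many")
  filled <- dplyr::left_join(
    grid, estimates,
    by = c("environment", "mutation_id", "population", "timepoint", "generation"))
  mut_mean <- dplyr::summarise(
    dplyr::group_by(estimates, .data$environment, .data$mutation_id),
    fill_value = mean(.data$s), .groups = "drop")
  filled <- dplyr::left_join(filled, mut_mean,
                             by = c("environment", "mutation_id"))
  is_missing <- is.na(filled$s)
  filled$filled[is_missing] <- TRUE
  filled$s[is_missing] <- filled$fill_value[is_missing]
  filled$sigma_cbc[is_missing] <- NA_real_
  filled$sigma_neut <- NULL
  filled <- dplyr::left_join(filled, bg_neut, by = bg_key)
  filled$fill_value <- NULL
  dropped <- filled[is.na(filled$s), ]
  if (nrow(dropped)) {
    warning(dplyr::n_distinct(dropped$mutation_id),
            " mutation(s) with no measurement in a condition dropped")
    filled <- filled[!is.na(filled$s), , drop = FALSE]
  }
  tibble::as_tibble(filled)
}

#' Regress the DFE mean against generations evolved
#'
#' Ordinary least squares of the per-background DFE mean on the generation
#' coordinate, with a free intercept; the slope's two-sided Wald test uses the
#' t distribution of the OLS slope. Scope `"pooled"` fits all backgrounds of
#' each environment together; `"per_population"` fits each population
#' separately.
#'
#' @param summaries Output of [dfe_mean()].
#' @param scope `"pooled"` or `"per_population"`.
#' @param weighted If `TRUE`, weight points by `1 / sigma_dfe_mean^2`
#'   (unweighted by default).
#' @return Tibble with `environment` (and `population` for per-population
#'   scope), `slope`, `se`, `p`, `n`.
#' @export
regress_dfe_vs_generation <- function(summaries,
                                      scope = c("pooled", "per_population"),
                                      weighted = FALSE) {
  scope <- match.arg(scope)
  groups <- if (scope == "pooled") "environment" else c("environment", "population")
  fit_one <- function(d) {
    if (nrow(d) < 3L) stop("need at least three backgrounds in scope", call. = FALSE)
    if (length(unique(d$generation)) < 2L) {
      stop("degenerate generation coordinate (all equal)", call. = FALSE)
    }
    w <- if (weighted) 1 / d$sigma_dfe_mean^2 else NULL
    fit <- lm(dfe_mean ~ generation, data = d, weights = w)
    sm <- summary(fit)$coefficients
    tibble::tibble(slope = sm["generation", "Estimate"],
                   se = sm["generation", "Std. Error"],
                   p = sm["generation", "Pr(>|t|)"],
                   n = nrow(d))
  }
  dplyr::reframe(dplyr::group_by(summaries,
                                 dplyr::across(dplyr::all_of(groups))),
                 fit_one(dplyr::pick(dplyr::everything())))
}

#' Count strongly deleterious mutations missing from each background
#'
#' A mutation is strongly deleterious in a condition if its mean fitness
#' effect across all backgrounds of that environment is below `threshold`.
#' For each background, counts how many such mutations lack a measurement
#' there — the census used to judge whether missingness is biased toward
#' strongly deleterious mutations in fit backgrounds.
#'
#' @param estimates Long measurement table.
#' @param threshold Condition-mean cutoff (default -0.05).
#' @return Tibble with background key columns, `generation`, and `n_missing`.
#' @export
count_missing_strong_deleterious <- function(estimates, threshold = -0.05) {
  mut_mean <- dplyr::summarise(
    dplyr::group_by(estimates, .data$environment, .data$mutation_id),
    cond_mean = mean(.data$s), .groups = "drop")
  strong <- mut_mean[mut_mean$cond_mean < threshold, ]
  backgrounds <- dplyr::distinct(
    estimates, dplyr::across(dplyr::all_of(c(bg_key, "generation"))))
  grid <- dplyr::inner_join(strong[, c("environment", "mutation_id")],
                            backgrounds, by = "environment",
                            relationship = "many-to-many")
  measured <- dplyr::mutate(
    estimates[, c("environment", "mutation_id", "population", "timepoint")],
    measured = TRUE)
  grid <- dplyr::left_join(
    grid, measured,
    by = c("environment", "mutation_id", "population", "timepoint"))
  dplyr::summarise(
    dplyr::group_by(grid, dplyr::across(dplyr::all_of(c(bg_key, "generation")))),
    n_missing = sum(is.na(.data$measured)),
    .groups = "drop")
}
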