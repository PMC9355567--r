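# Decomposition of epistasis into a fitness-correlated component and
# idiosyncratic population-specific steps.
#
# Inputs are the long estimate table (mutation_id, environment, population,
# timepoint, s, sigma, num_cbcs, ...) and a background-fitness table
# (environment, population, timepoint, x).

#' Mutations eligible for epistasis modeling
#'
#' Measurements backed by fewer than `min_cbcs` cBCs are dropped first (the
#' modeling is sensitive to outliers); mutations measured in fewer than
#' `min_pts` surviving population-timepoints in an environment are then
#' excluded.
#'
#' @param estimates Long estimate table with a `num_cbcs` column.
#' @param min_pts Minimum population-timepoints per mutation (default 20).
#' @param min_cbcs Minimum cBCs per measurement (default 5).
#' @return The filtered estimate table, with the per-environment survivor
#'   counts in `attr(, "n_eligible")`.
#' @export
eligible_mutations <- function(estimates, min_pts = 20L, min_cbcs = 5L) {
  kept <- estimates[estimates$num_cbcs >= min_cbcs, , drop = FALSE]
  n_bg <- dplyr::summarise(
    dplyr::group_by(kept, .data$environment, .data$mutation_id),
    n_points = dplyr::n(), .groups = "drop")
  ok <- n_bg[n_bg$n_points >= min_pts, c("environment", "mutation_id")]
  out <- dplyr::semi_join(kept, ok, by = c("environment", "mutation_id"))
  attr(out, "n_eligible") <- dplyr::summarise(
    dplyr::group_by(ok, .data$environment),
    n_mutations = dplyr::n(), .groups = "drop")
  out
}

#' Classify the correlation between fitness effect and background fitness
#'
#' Per (mutation, environment): OLS of the fitness effect on background
#' fitness with a free intercept. The mutation is classed `negative` if the
#' slope is below `-slope_cut` with Wald p below `p_cut`, `positive`
#' symmetrically, otherwise `ns`. A second label applies the same slope rule
#' after Benjamini-Hochberg correction of the p-values over each
#' environment's mutation family.
#'
#' @param estimates Long estimate table (one mutation/environment per group;
#'   at least 3 points each).
#' @param background Background-fitness table.
#' @param p_cut Wald p-value threshold (default 0.05).
#' @param slope_cut Absolute slope threshold (default 0.05), filtering for
#'   effect sizes above the typical measurement error across the fitness
#'   range.
#' @return Tibble: `environment`, `mutation_id`, `slope`, `se`, `wald_p`,
#'   `class`, `bh_class`, `n`.
#' @export
classify_fitness_correlation <- function(estimates, background,
                                         p_cut = 0.05, slope_cut = 0.05) {
  estimates <- estimates[, setdiff(names(estimates), "x"), drop = FALSE]
  d <- dplyr::inner_join(estimates, background,
                         by = c("environment", "population", "timepoint"))
  fit_one <- function(g) {
    if (nrow(g) < 3L) {
      return(tibble::tibble(slope = NA_real_, se = NA_real_, wald_p = NA_real_,
                            n = nrow(g)))
    }
    if (length(unique(g$x)) < 2L) {
      warning("zero variance in background fitness; classified ns")
      return(tibble::tibble(slope = 0, se = NA_real_, wald_p = 1, n = nrow(g)))
    }
    fit <- lm(s ~ x, data = g)
    sm <- summary(fit)$coefficients
    tibble::tibble(slope = sm["x", "Estimate"], se = sm["x", "Std. Error"],
                   wald_p = sm["x", "Pr(>|t|)"], n = nrow(g))
  }
  out <- dplyr::reframe(
    dplyr::group_by(d, .data$environment, .data$mutation_id),
    fit_one(dplyr::pick(dplyr::everything())))
  classify <- function(slope, p) {
    dplyr::case_when(
      is.na(slope) | is.na(p) ~ "ns",
      slope < -slope_cut & p < p_cut ~ "negative",
      slope > slope_cut & p < p_cut ~ "positive",
      TRUE ~ "ns")
  }
  out$class <- classify(out$slope, out$wald_p)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$environment),
    bh_p = p.adjust(.data$wald_p, method = "BH"))
  out <- dplyr::ungroup(out)
  out$bh_class <- classify(out$slope, out$bh_p)
  out
}

#' Anchor fitness effects and background fitness at the first timepoint
#'
#' Within each environment, the background fitness is shifted by the mean
#' fitness across all populations at the first timepoint, and each mutation's
#' fitness effect is shifted by its mean effect across all populations at the
#' first timepoint. The anchored variables therefore pass through (0, 0) for
#' the (averaged) ancestral state, and the models are fit without a free
#' intercept. Mutations with no first-timepoint measurement cannot be
#' anchored and are excluded with a message.
#'
#' @param estimates Long estimate table.
#' @param background Background-fitness table.
#' @param first_timepoint First-timepoint label per environment; by default
#'   the smallest timepoint present in `background`.
#' @return List: `anchored` (estimate table with `s_anch`, `x`, `x_anch`
#'   columns), `anchors` (per environment `x_anchor`; per mutation
#'   `s_anchor`), `excluded` (mutations without a first-timepoint
#'   measurement).
#' @export
anchor_estimates <- function(estimates, background, first_timepoint = NULL) {
  estimates <- estimates[, setdiff(names(estimates), "x"), drop = FALSE]
  first_tp <- dplyr::summarise(
    dplyr::group_by(background, .data$environment),
    first_timepoint = if (is.null(first_timepoint)) min(.data$timepoint)
      else first_timepoint,
    .groups = "drop")
  x_anchor <- dplyr::summarise(
    dplyr::group_by(dplyr::inner_join(background, first_tp, by = "environment"),
                    .data$environment),
    x_anchor = mean(.data$x[.data$timepoint == .data$first_timepoint]),
    .groups = "drop")
  d <- dplyr::inner_join(estimates, background,
                         by = c("environment", "population", "timepoint"))
  d <- dplyr::inner_join(d, first_tp, by = "environment")
  s_anchor <- dplyr::summarise(
    dplyr::group_by(d, .data$environment, .data$mutation_id),
    s_anchor = mean(.data$s[.data$timepoint == .data$first_timepoint]),
    .groups = "drop")
  excluded <- s_anchor[is.nan(s_anchor$s_anchor), c("environment", "mutation_id")]
  if (nrow(excluded)) {
    message(nrow(excluded),
            " mutation(s) without a first-timepoint measurement excluded ",
            "from epistasis modeling")
    s_anchor <- s_anchor[!is.nan(s_anchor$s_anchor), , drop = FALSE]
  }
  d <- dplyr::inner_join(d, s_anchor, by = c("environment", "mutation_id"))
  d <- dplyr::inner_join(d, x_anchor, by = "environment")
  d$s_anch <- d$s - d$s_anchor
  d$x_anch <- d$x - d$x_anchor
  d$first_timepoint <- NULL
  list(anchored = tibble::as_tibble(d),
       anchors = list(x = x_anchor, s = s_anchor),
       excluded = excluded)
}

#' Admissible idiosyncratic step indicators for one anchored series
#'
#' For each population, candidate onsets run from its second observed
#' timepoint through its last; an indicator is 1 at observed points with
#' timepoint at or after the onset in that population and 0 elsewhere. Specs
#' covering a single observed point are disallowed (they would fit one point
#' exactly), so only candidates with coverage of at least 2 are returned. An
#' onset at the first timepoint is redundant with the anchor and never a
#' candidate.
#'
#' @param series Anchored series for one (mutation, environment):
#'   tibble with `population`, `timepoint`.
#' @return Tibble: `population`, `onset`, `coverage`.
#' @export
candidate_indicators <- function(series) {
  per_pop <- split(series$timepoint, series$population)
  rows <- lapply(names(per_pop), function(p) {
    tps <- sort(unique(per_pop[[p]]))
    if (length(tps) < 2L) return(NULL)
    onsets <- tps[-1L]
    coverage <- vapply(onsets, function(o) sum(per_pop[[p]] >= o), integer(1))
    tibble::tibble(population = p, onset = onsets, coverage = coverage)
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(tibble::tibble(population = character(0), onset = numeric(0),
                          coverage = integer(0)))
  }
  out[out$coverage >= 2L, , drop = FALSE]
}

# Internal: indicator column for a candidate over the observed points.
indicator_column <- function(series, population, onset) {
  as.numeric(series$population == population & series$timepoint >= onset)
}

# Gaussian OLS BIC for a fixed-intercept (through-origin) fit. k counts the
# slope and step parameters only; the additive constants are kept so that
# dataset-level totals are meaningful. SSR is floored to keep BIC finite on
# degenerate exact fits.
ols_bic <- function(ssr, n, k) {
  n * log(max(ssr, 1e-300) / n) + k * log(n) + n * (1 + log(2 * pi))
}

#' Centered, clamped R-squared
#'
#' Because the fixed (anchored) intercept is considered part of the model,
#' R-squared is computed against the *centered* sum of squares,
#' `1 - SSR / sum((y - mean(y))^2)`; a model explaining less variance than a
#' free-intercept-only model yields a negative value, which is clamped to 0.
#'
#' @param ssr Sum of squared residuals.
#' @param y Response values (anchored fitness effects).
#' @return R-squared in `[0, 1]`.
#' @export
model_r2 <- function(ssr, y) {
  css <- sum((y - mean(y))^2)
  if (css == 0) {
    warning("zero centered sum of squares; R^2 defined as 0")
    return(0)
  }
  max(0, 1 - ssr / css)
}

# Internal: through-origin OLS, returning coefficients and SSR.
fit_ols0 <- function(X, y) {
  if (ncol(X) == 0L) {
    return(list(coef = numeric(0), ssr = sum(y^2), fitted = rep(0, length(y))))
  }
  fit <- lm.fit(X, y)
  list(coef = coef(fit), ssr = sum(fit$residuals^2), fitted = fit$fitted.values)
}

# Internal: residual-based standard error of the first design column's
# coefficient in a through-origin OLS fit.
beta_se_ols0 <- function(X, ssr, n, k) {
  if (n <= k) return(NA_real_)
  xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  if (is.null(xtx_inv)) return(NA_real_)
  sqrt(ssr / (n - k) * xtx_inv[1, 1])
}

# Internal: construct the epistasis_fit record.
new_epistasis_fit <- function(model, series, beta, alphas, ssr, k, bic_path,
                              beta_se = NA_real_) {
  n <- nrow(series)
  structure(list(
    model = model,
    beta = beta,
    beta_se = beta_se,
    alphas = alphas,
    r_squared = model_r2(ssr, series$s_anch),
    bic = ols_bic(ssr, n, k),
    bic_path = bic_path,
    n_points = n,
    k = k,
    ssr = ssr,
    sigma_e = sqrt(ssr / n)
  ), class = "epistasis_fit")
}

#' @export
print.epistasis_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, k = %d, R^2 = %.3f, BIC = %.2f\n",
              x$model, x$n_points, x$k, x$r_squared, x$bic))
  if (!is.na(x$beta)) cat(sprintf("  beta (background-fitness slope): %.4f\n", x$beta))
  if (nrow(x$alphas)) {
    cat("  idiosyncratic steps:\n")
    for (i in seq_len(nrow(x$alphas))) {
      cat(sprintf("    population %s from timepoint %s: %+.4f\n",
                  x$alphas$population[i], x$alphas$onset[i],
                  x$alphas$coefficient[i]))
    }
  }
  invisible(x)
}

#' Fit the fitness (XM) model
#'
#' Through-origin OLS of the anchored fitness effect on the anchored
#' background fitness: epistasis is modeled as strictly fitness-correlated.
#'
#' @param series Anchored series for one (mutation, environment): tibble with
#'   `population`, `timepoint`, `s_anch`, `x_anch` (>= 2 points).
#' @return An `epistasis_fit`.
#' @export
fit_xm <- function(series) {
  stopifnot(nrow(series) >= 2L)
  if (all(series$x_anch == 0)) {
    stop("background fitness has no variation; XM slope undefined", call. = FALSE)
  }
  X <- matrix(series$x_anch, ncol = 1L)
  fit <- fit_ols0(X, series$s_anch)
  new_epistasis_fit("XM", series, beta = unname(fit$coef[1]),
                    alphas = empty_alphas(), ssr = fit$ssr, k = 1L,
                    bic_path = ols_bic(fit$ssr, nrow(series), 1L),
                    beta_se = beta_se_ols0(X, fit$ssr, nrow(series), 1L))
}

empty_alphas <- function() {
  tibble::tibble(population = character(0), onset = numeric(0),
                 coefficient = numeric(0), coverage = integer(0))
}

# Internal: iterative BIC forward selection of step indicators.
# base_cols: list of fixed design columns (e.g. x_anch for FM). At each step
# every admissible candidate (one per population at most) is refit jointly
# with the current design; the candidate with the largest BIC decrease is
# accepted if the decrease strictly exceeds delta_bic. Ties break by larger
# coverage, then earlier onset, then population label order.
forward_select_steps <- function(series, candidates, base_cols, k_base,
                                 delta_bic = 2) {
  y <- series$s_anch
  n <- length(y)
  X_base <- if (length(base_cols)) do.call(cbind, base_cols) else
    matrix(numeric(0), nrow = n, ncol = 0L)
  selected <- empty_alphas()
  sel_cols <- NULL
  fit <- fit_ols0(X_base, y)
  bic <- ols_bic(fit$ssr, n, k_base)
  bic_path <- bic
  repeat {
    if (nrow(selected) > 0L) {
      candidates_open <- candidates[!candidates$population %in% selected$population, ,
                                    drop = FALSE]
    } else {
      candidates_open <- candidates
    }
    if (nrow(candidates_open) == 0L) break
    trial <- vapply(seq_len(nrow(candidates_open)), function(i) {
      col <- indicator_column(series, candidates_open$population[i],
                              candidates_open$onset[i])
      X <- cbind(X_base, sel_cols, col)
      f <- fit_ols0(X, y)
      ols_bic(f$ssr, n, k_base + nrow(selected) + 1L)
    }, numeric(1))
    ord <- order(trial, -candidates_open$coverage, candidates_open$onset,
                 candidates_open$population)
    best <- ord[1]
    if (bic - trial[best] > delta_bic) {
      col <- indicator_column(series, candidates_open$population[best],
                              candidates_open$onset[best])
      sel_cols <- cbind(sel_cols, col)
      selected <- dplyr::bind_rows(selected, tibble::tibble(
        population = candidates_open$population[best],
        onset = candidates_open$onset[best],
        coefficient = NA_real_,
        coverage = candidates_open$coverage[best]))
      bic <- trial[best]
      bic_path <- c(bic_path, bic)
    } else {
      break
    }
  }
  X_final <- cbind(X_base, sel_cols)
  final <- fit_ols0(X_final, y)
  k_sel <- nrow(selected)
  if (k_sel > 0L) {
    selected$coefficient <- unname(final$coef[(k_base + 1L):(k_base + k_sel)])
  }
  list(selected = selected, ssr = final$ssr,
       beta = if (k_base >= 1L) unname(final$coef[1]) else NA_real_,
       beta_se = if (k_base >= 1L)
         beta_se_ols0(X_final, final$ssr, n, k_base + k_sel) else NA_real_,
       bic = bic, bic_path = bic_path, k = k_base + k_sel)
}

#' Fit the idiosyncratic (IM) model
#'
#' Step indicators (one per population at most, onset at an observed
#' timepoint, coverage of at least two points) are added by iterative forward
#' selection, accepting at each step the candidate that decreases the BIC the
#' most, provided the decrease strictly exceeds `delta_bic`. All coefficients
#' are refit jointly at every step. The empty model (zero steps) is a valid
#' outcome.
#'
#' @inheritParams fit_xm
#' @param candidates Candidate set from [candidate_indicators()]; computed
#'   from `series` when `NULL`.
#' @param delta_bic Minimum BIC improvement to accept a step (default 2).
#' @return An `epistasis_fit`.
#' @export
fit_im <- function(series, candidates = NULL, delta_bic = 2) {
  if (is.null(candidates)) candidates <- candidate_indicators(series)
  res <- forward_select_steps(series, candidates, base_cols = list(),
                              k_base = 0L, delta_bic = delta_bic)
  new_epistasis_fit("IM", series, beta = NA_real_, alphas = res$selected,
                    ssr = res$ssr, k = res$k, bic_path = res$bic_path)
}

#' Fit the full (FM) model
#'
#' The background-fitness slope is always present; step indicators are then
#' forward-selected exactly as in [fit_im()], with the slope refit jointly at
#' every step. The selected step set may differ from the IM set (IM is not
#' nested in FM), so FM may explain less variance than IM.
#'
#' @inheritParams fit_im
#' @return An `epistasis_fit`.
#' @export
fit_fm <- function(series, candidates = NULL, delta_bic = 2) {
  if (all(series$x_anch == 0)) {
    stop("background fitness has no variation; FM slope undefined", call. = FALSE)
  }
  if (is.null(candidates)) candidates <- candidate_indicators(series)
  res <- forward_select_steps(series, candidates,
                              base_cols = list(series$x_anch),
                              k_base = 1L, delta_bic = delta_bic)
  new_epistasis_fit("FM", series, beta = res$beta, alphas = res$selected,
                    ssr = res$ssr, k = res$k, bic_path = res$bic_path,
                    beta_se = res$beta_se)
}

#' Select the best model per mutation and for the whole dataset
#'
#' Per mutation the winner is the model with the lowest BIC; ties go to the
#' model with fewer parameters. The dataset-level comparison aggregates each
#' model class over all mutations with a joint Gaussian likelihood using a
#' per-mutation residual variance (sum of the per-mutation `n log(SSR/n)`
#' terms and constants) and the pooled parameter count against the pooled
#' number of points.
#'
#' @param fits Tibble with one row per (mutation, model) carrying list-column
#'   `fit` of `epistasis_fit` objects (as returned by
#'   [fit_epistasis_models()]).
#' @return List: `per_mutation` (tibble `mutation_id`, `environment`, `best`),
#'   `dataset` (tibble `model`, `bic`, `k`, `n`).
#' @export
select_best_model <- function(fits) {
  per_mut <- dplyr::summarise(
    dplyr::group_by(fits, .data$environment, .data$mutation_id),
    best = {
      b <- vapply(.data$fit, function(f) f$bic, numeric(1))
      k <- vapply(.data$fit, function(f) f$k, numeric(1))
      models <- vapply(.data$fit, function(f) f$model, character(1))
      models[order(b, k)][1]
    },
    .groups = "drop")
  stats <- dplyr::mutate(
    fits,
    ssr = vapply(.data$fit, function(f) f$ssr, numeric(1)))
  dataset <- dplyr::summarise(
    dplyr::group_by(stats, .data$environment, .data$model),
    bic = sum(.data$n_points * log(pmax(.data$ssr, 1e-300) / .data$n_points) +
                .data$n_points * (1 + log(2 * pi))) +
      sum(.data$k) * log(sum(.data$n_points)),
    k = sum(.data$k),
    n = sum(.data$n_points),
    .groups = "drop")
  list(per_mutation = per_mut, dataset = dataset)
}

#' Fit XM, IM and FM for every eligible mutation
#'
#' @param estimates Long estimate table (already filtered by
#'   [eligible_mutations()] if desired).
#' @param background Background-fitness table.
#' @param delta_bic Forward-selection acceptance threshold (default 2).
#' @return List: `fits` (tibble `environment`, `mutation_id`, `model`,
#'   `beta`, `r_squared`, `bic`, `n_points`, `k`, list-column `fit`),
#'   `coefficients` (flat tibble of all selected step coefficients),
#'   `anchors`, `excluded`.
#' @export
fit_epistasis_models <- function(estimates, background, delta_bic = 2) {
  anch <- anchor_estimates(estimates, background)
  d <- anch$anchored
  groups <- dplyr::group_split(dplyr::group_by(d, .data$environment,
                                               .data$mutation_id))
  rows <- lapply(groups, function(g) {
    series <- g[order(g$population, g$timepoint), ]
    cand <- candidate_indicators(series)
    fits <- list(fit_xm(series),
                 fit_im(series, cand, delta_bic),
                 fit_fm(series, cand, delta_bic))
    tibble::tibble(
      environment = g$environment[1],
      mutation_id = g$mutation_id[1],
      model = vapply(fits, function(f) f$model, character(1)),
      beta = vapply(fits, function(f) f$beta, numeric(1)),
      r_squared = vapply(fits, function(f) f$r_squared, numeric(1)),
      bic = vapply(fits, function(f) f$bic, numeric(1)),
      n_points = vapply(fits, function(f) f$n_points, numeric(1)),
      k = vapply(fits, function(f) f$k, numeric(1)),
      fit = fits)
  })
  fits <- dplyr::bind_rows(rows)
  coefficients <- dplyr::bind_rows(lapply(seq_len(nrow(fits)), function(i) {
    a <- fits$fit[[i]]$alphas
    if (nrow(a) == 0L) return(NULL)
    tibble::tibble(environment = fits$environment[i],
                   mutation_id = fits$mutation_id[i],
                   model = fits$model[i],
                   population = a$population, onset = a$onset,
                   coefficient = a$coefficient, coverage = a$coverage)
  }))
  if (nrow(coefficients) == 0L) {
    coefficients <- tibble::tibble(environment = character(0),
                                   mutation_id = character(0),
                                   model = character(0),
                                   population = character(0),
                                   onset = numeric(0), coefficient = numeric(0),
                                   coverage = integer(0))
  }
  list(fits = fits, coefficients = coefficients,
       anchors = anch$anchors, excluded = anch$excluded)
}

#' Shuffled null dataset
#'
#' Within each (mutation, environment) set, the fitness effects are randomly
#' permuted over the observed (population, timepoint) cells; the background
#' fitness values and the missingness mask are untouched. By default the
#' standard errors travel with their fitness values so downstream
#' error-dependent steps stay coherent; `s_only = TRUE` permutes the fitness
#' effects alone.
#'
#' @param estimates Long estimate table.
#' @param seed RNG seed.
#' @param s_only Permute only the `s` column (default `FALSE`).
#' @return The permuted estimate table.
#' @export
make_shuffled_dataset <- function(estimates, seed = 1L, s_only = FALSE) {
  cols <- if (s_only) "s" else
    intersect(c("s", "sigma", "sigma_cbc", "num_cbcs"), names(estimates))
  withr::with_seed(seed, {
    out <- dplyr::group_modify(
      dplyr::group_by(estimates, .data$environment, .data$mutation_id),
      function(d, key) {
        idx <- sample.int(nrow(d))
        d[, cols] <- d[idx, cols]  # one permutation carries all columns
        d
      })
    dplyr::ungroup(out)[, names(estimates)]
  })
}

#' Simulated null dataset
#'
#' Within each (mutation, environment) set, the fitness effects are replaced
#' by independent draws from a normal distribution with mean zero and
#' standard deviation equal to the mean standard error of the set; the mask
#' and background fitness are untouched.
#'
#' @param estimates Long estimate table with a `sigma` column.
#' @param seed RNG seed.
#' @return The simulated estimate table.
#' @export
make_simulated_dataset <- function(estimates, seed = 1L) {
  withr::with_seed(seed, {
    dplyr::ungroup(dplyr::mutate(
      dplyr::group_by(estimates, .data$environment, .data$mutation_id),
      s = rnorm(dplyr::n(), mean = 0, sd = mean(.data$sigma))))
  })
}

#' Census of idiosyncratic step coefficients
#'
#' Counts the selected IM and FM step coefficients by sign for each
#' environment and model.
#'
#' @param coefficients Flat coefficient table from [fit_epistasis_models()].
#' @return Tibble: `environment`, `model`, `n_total`, `n_negative`,
#'   `n_positive`.
#' @export
census_coefficients <- function(coefficients) {
  base <- tidyr::crossing(environment = unique(coefficients$environment),
                          model = c("IM", "FM"))
  counts <- dplyr::summarise(
    dplyr::group_by(coefficients, .data$environment, .data$model),
    n_total = dplyr::n(),
    n_negative = sum(.data$coefficient < 0),
    n_positive = sum(.data$coefficient > 0),
    .groups = "drop")
  out <- dplyr::left_join(base, counts, by = c("environment", "model"))
  out[is.na(out)] <- 0L
  out
}
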