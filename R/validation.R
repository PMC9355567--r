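# Seeded validation experiments: parameter-recovery and null-calibration
# studies run entirely on generated data. These back the package's
# correctness claims and are reused by the acceptance script.

# Internal: anchored background-fitness grid from the evolution generator
# (per-population concave trajectories, anchored at the first timepoint).
anchored_background_grid <- function(seed, evo = evolution_config()) {
  bg <- simulate_evolution(evo, seed = seed)
  bg <- dplyr::distinct(bg, .data$environment, .data$population,
                        .data$timepoint, .data$x_pop)
  anchor <- mean(bg$x_pop[bg$timepoint == min(bg$timepoint)])
  bg$x_anch <- bg$x_pop - anchor
  bg
}

#' Idiosyncratic-step and slope recovery experiment
#'
#' Generates `n` mutations with one true idiosyncratic step each (random
#' population, interior onset, magnitude uniform in `alpha_range`, random
#' sign) on anchored background-fitness grids from the evolution generator,
#' fits the idiosyncratic model, and scores whether the injected population
#' carries a selected coefficient with onset within one timepoint of the
#' truth. A second arm generates `n` pure-slope mutations (slope uniform in
#' `beta_range`), fits the full model, and scores the slope error against
#' twice its empirical standard deviation over the arm.
#'
#' @param n Mutations per arm (default 200).
#' @param seed RNG seed.
#' @param noise Per-point measurement noise SD, in fitness units (default
#'   0.005, the typical propagated standard error of a population-timepoint
#'   estimate at the default assay depth).
#' @param alpha_range Absolute step magnitudes, spanning 5-20x `noise`.
#' @param beta_range Slope magnitudes for the full-model arm.
#' @return List: `im` (tibble per mutation: `population`, `onset`,
#'   `magnitude`, `recovered`, `n_coefficients`), `fm` (tibble: `beta_true`,
#'   `beta_hat`, `error`, `within_2sd`), `im_recovery_rate`,
#'   `fm_within_2sd_rate`.
#' @export
step_recovery_experiment <- function(n = 200, seed = 1L, noise = 0.005,
                                     alpha_range = c(0.025, 0.1),
                                     beta_range = c(0.1, 0.6)) {
  grid <- anchored_background_grid(seed)
  pops <- unique(grid$population)
  tps <- sort(unique(grid$timepoint))
  onsets <- tps[-c(1L, length(tps))]
  im_rows <- withr::with_seed(seed + 1L, {
    lapply(seq_len(n), function(i) {
      pop <- sample(pops, 1)
      onset <- sample(onsets, 1)
      mag <- sample(c(-1, 1), 1) * runif(1, alpha_range[1], alpha_range[2])
      d <- grid
      d$s_anch <- rnorm(nrow(d), 0, noise) +
        ifelse(d$population == pop & d$timepoint >= onset, mag, 0)
      fit <- fit_im(d)
      hit <- fit$alphas$population == pop &
        abs(fit$alphas$onset - onset) <= 1
      tibble::tibble(population = pop, onset = onset, magnitude = mag,
                     recovered = any(hit),
                     n_coefficients = nrow(fit$alphas))
    })
  })
  im <- dplyr::bind_rows(im_rows)

  fm_rows <- withr::with_seed(seed + 2L, {
    lapply(seq_len(n), function(i) {
      b <- sample(c(-1, 1), 1) * runif(1, beta_range[1], beta_range[2])
      d <- grid
      d$s_anch <- b * d$x_anch + rnorm(nrow(d), 0, noise)
      fit <- fit_fm(d)
      tibble::tibble(beta_true = b, beta_hat = fit$beta)
    })
  })
  fm <- dplyr::bind_rows(fm_rows)
  fm$error <- fm$beta_hat - fm$beta_true
  fm$within_2sd <- abs(fm$error) < 2 * sd(fm$error)

  list(im = im, fm = fm,
       im_recovery_rate = mean(im$recovered),
       fm_within_2sd_rate = mean(fm$within_2sd))
}

#' Null-calibration experiment for the epistasis machinery
#'
#' Generates `n_mutations` pure-noise mutations (no slope, no steps) on the
#' anchored grid, fits the idiosyncratic model to the empirical null and to
#' its within-set shuffled counterpart, and classifies each mutation's
#' fitness correlation. On data with no true epistasis the selected
#' coefficient counts of the two datasets estimate the same false-selection
#' rate, and the classification should not exceed its nominal type-I level.
#'
#' @param n_mutations Null mutations (default 100).
#' @param seed RNG seed.
#' @param noise Per-point noise SD (default 0.005).
#' @return List: `n_im_null`, `n_im_shuffled` (total selected coefficients),
#'   `type1_rate` (fraction classified non-ns), `type1_p_only` (fraction with
#'   Wald p below 0.05, ignoring the slope criterion), `n_mutations`.
#' @export
null_calibration_experiment <- function(n_mutations = 100, seed = 1L,
                                        noise = 0.005) {
  grid <- anchored_background_grid(seed)
  est <- withr::with_seed(seed + 1L, {
    dplyr::bind_rows(lapply(seq_len(n_mutations), function(i) {
      d <- grid
      d$mutation_id <- sprintf("null%03d", i)
      d$s <- rnorm(nrow(d), 0, noise)
      d$sigma <- noise
      d
    }))
  })
  background <- dplyr::distinct(grid, .data$environment, .data$population,
                                .data$timepoint)
  background$x <- grid$x_pop[match(
    paste(background$population, background$timepoint),
    paste(grid$population, grid$timepoint))]

  count_im <- function(data) {
    vapply(split(data, data$mutation_id), function(g) {
      d <- tibble::tibble(population = g$population, timepoint = g$timepoint,
                          s_anch = g$s - mean(g$s[g$timepoint == min(g$timepoint)]),
                          x_anch = g$x_anch)
      nrow(fit_im(d)$alphas)
    }, numeric(1))
  }
  per_null <- count_im(est)
  shuf <- make_shuffled_dataset(est, seed = seed + 2L)
  per_shuf <- count_im(shuf)
  # sampling SD of the difference of the two totals, from the paired
  # per-mutation counts (the two runs share the underlying draws)
  diff_sd <- sqrt(n_mutations) * sd(per_null - per_shuf)

  cls <- classify_fitness_correlation(est, background)
  list(n_im_null = sum(per_null),
       n_im_shuffled = sum(per_shuf),
       per_mutation_null = per_null,
       per_mutation_shuffled = per_shuf,
       diff_sampling_sd = diff_sd,
       type1_rate = mean(cls$class != "ns"),
       type1_p_only = mean(cls$wald_p < 0.05),
       n_mutations = n_mutations)
}

#' DFE-trend experiment: biased versus balanced idiosyncratic epistasis
#'
#' Generates the true-effect surface for two environments that differ only in
#' the sign bias of their idiosyncratic steps (strongly negative-biased
#' versus balanced), adds measurement noise, and regresses the per-background
#' DFE mean on generations evolved. With negative-biased steps the DFE mean
#' declines during evolution; with balanced steps no consistent trend is
#' expected.
#'
#' @param seed RNG seed.
#' @param noise Per-cell measurement noise SD (default 0.003).
#' @param neg_frac Negative-step fractions per environment (default
#'   `c(biased = 0.9, balanced = 0.5)`).
#' @param step_prob Per-population step probability (default 0.25; high
#'   enough that step effects, not the shared fitness slope, dominate the
#'   contrast between the two environments).
#' @return Tibble per environment: `slope`, `se`, `p`, `n`.
#' @export
dfe_trend_experiment <- function(seed = 1L, noise = 0.003,
                                 neg_frac = c(biased = 0.9, balanced = 0.5),
                                 step_prob = 0.25) {
  evo <- evolution_config(environments = names(neg_frac))
  eff <- effect_config(step_neg_frac = neg_frac, step_prob = step_prob,
                       slope_frac = 0)
  bg <- simulate_evolution(evo, seed = seed)
  truth <- assign_true_effects(bg, eff, seed = seed + 1L)
  est <- truth$effects
  est <- est[!est$mutation_id %in%
               truth$mutations$mutation_id[truth$mutations$neutral], ]
  gen <- dplyr::distinct(bg, .data$environment, .data$population,
                         .data$timepoint, .data$generation)
  est <- dplyr::inner_join(est, gen,
                           by = c("environment", "population", "timepoint"))
  est <- withr::with_seed(seed + 2L, {
    est$s <- est$s_true + rnorm(nrow(est), 0, noise)
    est
  })
  est$sigma_cbc <- noise
  est$sigma_neut <- noise / 3
  summaries <- dfe_mean(est, min_mutations = 60)
  regress_dfe_vs_generation(summaries, scope = "pooled")
}
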