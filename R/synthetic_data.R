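# Seeded synthetic study generator: evolving backgrounds with known fitness,
# a panel of insertion mutations with known epistatic structure, and raw
# barcode-assay count matrices, all reproducible from (config, seed) with an
# exported truth table for recovery scoring.

#' Evolution-experiment configuration
#'
#' Describes the evolved backgrounds the generator emulates: several
#' replicate populations sampled at increasing generation coordinates, with
#' fitness rising along a concave (declining-adaptability) trajectory
#' `x(g) = v * g / (1 + g / tau)`; `tau = Inf` gives a linear gain.
#'
#' @param n_populations Populations per environment (default 6).
#' @param generations Strictly increasing generation coordinates of the
#'   sampled timepoints (default six timepoints spanning ten thousand
#'   generations).
#' @param environments Environment labels (default `"E1"`).
#' @param v Initial fitness gain per generation (default 4e-5).
#' @param tau Saturation scale in generations (default 4000).
#' @param pop_cv Lognormal coefficient of variation of `v` and `tau` across
#'   populations (default 0.1).
#' @param clone_sd Standard deviation of the fitness perturbation between the
#'   two clones of a background (default 0.005).
#' @param x_measure_sd Measurement noise of the reference-competition fitness
#'   assay, per clone replicate (default 0.003).
#' @return An `evolution_config` list.
#' @export
evolution_config <- function(n_populations = 6L,
                             generations = c(1000, 2800, 4600, 6400, 8200, 10000),
                             environments = "E1",
                             v = 4e-5, tau = 4000,
                             pop_cv = 0.1, clone_sd = 0.005,
                             x_measure_sd = 0.003) {
  stopifnot(length(generations) >= 2L, all(diff(generations) > 0),
            n_populations >= 1L, v >= 0, tau > 0)
  structure(as.list(environment()), class = "evolution_config")
}

#' Mutation-effect configuration
#'
#' Defines the generative picture for the panel of insertion mutations: an
#' ancestral effect (mostly deleterious, a few beneficial), an optional linear
#' dependence on background fitness, and idiosyncratic step changes confined
#' to single populations from one timepoint onward. The per-environment sign
#' bias of the steps controls whether the DFE mean drifts during evolution.
#'
#' @param n_mutations Non-neutral mutations in the panel (default 91).
#' @param n_neutral Neutral reference mutations (default 5).
#' @param p_beneficial Probability that a mutation's ancestral effect is
#'   beneficial (default 0.08).
#' @param del_shape,del_scale Gamma parameters of the deleterious ancestral
#'   effect magnitude (default shape 1.5, scale 0.04).
#' @param ben_mean,ben_sd Normal parameters of the beneficial ancestral
#'   effect (default 0.03, 0.01).
#' @param slope_frac Fraction of mutations with a background-fitness slope
#'   (default 0.5).
#' @param slope_mean,slope_sd Normal parameters of that slope
#'   (default -0.35, 0.35).
#' @param step_prob Per-population probability that a mutation carries one
#'   idiosyncratic step (default 0.12).
#' @param step_shape,step_scale Gamma parameters of the step magnitude
#'   (default 2, 0.03).
#' @param step_neg_frac Named (by environment) or scalar fraction of steps
#'   that are negative (default 0.75).
#' @param interior_onsets If `TRUE` (default), onsets are drawn from the
#'   second through the second-to-last timepoint, so every step spans at
#'   least two observed points.
#' @return An `effect_config` list.
#' @export
effect_config <- function(n_mutations = 91L, n_neutral = 5L,
                          p_beneficial = 0.08,
                          del_shape = 1.5, del_scale = 0.04,
                          ben_mean = 0.03, ben_sd = 0.01,
                          slope_frac = 0.5, slope_mean = -0.35, slope_sd = 0.35,
                          step_prob = 0.12, step_shape = 2, step_scale = 0.03,
                          step_neg_frac = 0.75, interior_onsets = TRUE) {
  stopifnot(n_mutations >= 1L, n_neutral >= 1L)
  structure(as.list(environment()), class = "effect_config")
}

#' Barcode-assay configuration
#'
#' Describes one pooled serial-transfer competition assay: barcodes per
#' mutation, transfer cycles, dilution depth, sequencing depth, and the
#' injected artifacts (outlier barcodes, a single-timepoint contamination
#' spike, and missingness biased toward strongly deleterious mutations in fit
#' backgrounds).
#'
#' @param n_barcodes Barcodes per mutation (default 15).
#' @param depth Sequencing reads per timepoint (default 1e5).
#' @param bottleneck Cells transferred at each dilution (default 2e6).
#' @param generations_per_cycle Generations per transfer cycle; 10 emulates a
#'   1/2^10 daily dilution (default 10).
#' @param n_timepoints Sequenced assay timepoints (default 5).
#' @param outlier_rate Per-barcode probability of an outlier fitness offset
#'   (default 0.01).
#' @param outlier_sd Standard deviation of the (wide) outlier offset
#'   (default 0.15).
#' @param outlier_cap Truncation bound on the offset, per generation (default
#'   0.2): pre-existing mutations or co-transformed plasmids perturb a
#'   lineage's fitness substantially but not beyond biologically plausible
#'   per-generation effects.
#' @param spike If `TRUE`, inject a contamination spike at `spike_timepoint`
#'   (default `FALSE`).
#' @param spike_timepoint Assay timepoint receiving the spike (default 2).
#' @param spike_rate Fraction of lineages spiked (default 0.005).
#' @param spike_min,spike_max Range of the log-frequency bump (default
#'   0.8-1.5, comfortably above the 0.5 detection threshold).
#' @param missing_rate Maximum probability that a strongly deleterious
#'   mutation fails transformation in the fittest background (scales linearly
#'   with background fitness rank; default 0.3).
#' @param missing_threshold Fitness-effect threshold defining "strongly
#'   deleterious" for the missingness model (default -0.05).
#' @param initial_cv Lognormal sd of initial barcode frequencies
#'   (default 0.5).
#' @param barcode_length Length of generated barcode sequences (default 10).
#' @return An `assay_config` list.
#' @export
assay_config <- function(n_barcodes = 15L, depth = 1e5, bottleneck = 2e6,
                         generations_per_cycle = 10, n_timepoints = 5L,
                         outlier_rate = 0.01, outlier_sd = 0.15,
                         outlier_cap = 0.2,
                         spike = FALSE, spike_timepoint = 2L,
                         spike_rate = 0.005, spike_min = 0.8, spike_max = 1.5,
                         missing_rate = 0.3, missing_threshold = -0.05,
                         initial_cv = 0.5, barcode_length = 10L) {
  stopifnot(depth > 0, bottleneck > 0, n_timepoints >= 2L, n_barcodes >= 1L)
  structure(as.list(environment()), class = "assay_config")
}

#' Simulate evolving backgrounds
#'
#' Generates, per environment and population, a monotone concave true-fitness
#' trajectory over the configured timepoints (population-level jitter on the
#' trajectory parameters) and two clones per background whose fitness is
#' perturbed around the population value.
#'
#' @param evo An [evolution_config()].
#' @param seed RNG seed.
#' @return Tibble: `environment`, `population`, `timepoint`, `generation`,
#'   `x_pop`, `clone_id`, `clone`, `x_clone`.
#' @export
simulate_evolution <- function(evo, seed = 1L) {
  withr::with_seed(seed, {
    rows <- list()
    for (env in evo$environments) {
      for (p in seq_len(evo$n_populations)) {
        v_p <- evo$v * exp(rnorm(1, 0, evo$pop_cv))
        tau_p <- if (is.finite(evo$tau)) evo$tau * exp(rnorm(1, 0, evo$pop_cv)) else Inf
        g <- evo$generations
        x <- if (is.finite(tau_p)) v_p * g / (1 + g / tau_p) else v_p * g
        pop <- sprintf("P%d", p)
        for (cl in 1:2) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            environment = env, population = pop,
            timepoint = seq_along(g), generation = g, x_pop = x,
            clone = cl,
            clone_id = sprintf("%s_%s_T%d_c%d", env, pop, seq_along(g), cl),
            x_clone = x + rnorm(length(g), 0, evo$clone_sd))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Assign true mutation effects over the backgrounds
#'
#' Builds the ground-truth effect surface
#' `s_true(m, p, t, e) = a_m + b_m * x_pop(p, t, e) + sum(steps active at t)`,
#' with neutral reference mutations pinned at zero (no slope, no steps).
#'
#' @param backgrounds Output of [simulate_evolution()].
#' @param eff An [effect_config()].
#' @param seed RNG seed.
#' @return List of class `truth_table`: `mutations` (tibble `mutation_id`,
#'   `neutral`, `a`, `b`), `steps` (tibble `mutation_id`, `environment`,
#'   `population`, `onset`, `magnitude`), `effects` (tibble `mutation_id`,
#'   `environment`, `population`, `timepoint`, `s_true`).
#' @export
assign_true_effects <- function(backgrounds, eff, seed = 1L) {
  withr::with_seed(seed, {
    n_m <- eff$n_mutations
    ids <- sprintf("mut%03d", seq_len(n_m + eff$n_neutral))
    neutral <- c(rep(FALSE, n_m), rep(TRUE, eff$n_neutral))
    beneficial <- runif(n_m) < eff$p_beneficial
    a <- ifelse(beneficial,
                rnorm(n_m, eff$ben_mean, eff$ben_sd),
                -rgamma(n_m, shape = eff$del_shape, scale = eff$del_scale))
    b <- ifelse(runif(n_m) < eff$slope_frac,
                rnorm(n_m, eff$slope_mean, eff$slope_sd), 0)
    mutations <- tibble::tibble(mutation_id = ids, neutral = neutral,
                                a = c(a, rep(0, eff$n_neutral)),
                                b = c(b, rep(0, eff$n_neutral)))
    tps <- sort(unique(backgrounds$timepoint))
    onset_pool <- if (eff$interior_onsets && length(tps) > 2L) {
      tps[-c(1L, length(tps))]
    } else {
      tps[-1L]
    }
    pops <- dplyr::distinct(backgrounds, .data$environment, .data$population)
    step_rows <- list()
    for (i in seq_len(n_m)) {
      has_step <- runif(nrow(pops)) < eff$step_prob
      if (!any(has_step)) next
      hit <- pops[has_step, , drop = FALSE]
      neg_frac <- if (!is.null(names(eff$step_neg_frac))) {
        unname(eff$step_neg_frac[hit$environment])
      } else {
        rep(eff$step_neg_frac, nrow(hit))
      }
      sign <- ifelse(runif(nrow(hit)) < neg_frac, -1, 1)
      step_rows[[length(step_rows) + 1L]] <- tibble::tibble(
        mutation_id = ids[i],
        environment = hit$environment,
        population = hit$population,
        onset = sample(onset_pool, nrow(hit), replace = TRUE),
        magnitude = sign * rgamma(nrow(hit), shape = eff$step_shape,
                                  scale = eff$step_scale))
    }
    steps <- if (length(step_rows)) dplyr::bind_rows(step_rows) else
      tibble::tibble(mutation_id = character(0), environment = character(0),
                     population = character(0), onset = integer(0),
                     magnitude = numeric(0))

    bgs <- dplyr::distinct(backgrounds, .data$environment, .data$population,
                           .data$timepoint, .data$x_pop)
    effects <- tidyr::crossing(mutation_id = ids, bgs)
    effects <- dplyr::left_join(effects,
                                mutations[, c("mutation_id", "a", "b")],
                                by = "mutation_id")
    effects$s_true <- effects$a + effects$b * effects$x_pop
    if (nrow(steps)) {
      step_sum <- dplyr::summarise(
        dplyr::group_by(
          dplyr::inner_join(steps, bgs,
                            by = c("environment", "population"),
                            relationship = "many-to-many"),
          .data$mutation_id, .data$environment, .data$population,
          .data$timepoint),
        step_total = sum(.data$magnitude[.data$onset <= .data$timepoint[1]]),
        .groups = "drop")
      effects <- dplyr::left_join(
        effects, step_sum,
        by = c("mutation_id", "environment", "population", "timepoint"))
      effects$s_true <- effects$s_true +
        ifelse(is.na(effects$step_total), 0, effects$step_total)
      effects$step_total <- NULL
    }
    effects <- effects[, c("mutation_id", "environment", "population",
                           "timepoint", "s_true")]
    structure(list(mutations = mutations, steps = steps,
                   effects = tibble::as_tibble(effects)),
              class = "truth_table")
  })
}

# Internal: unique random barcode sequences.
random_barcodes <- function(n, length = 10L) {
  draw <- function(k) {
    apply(matrix(sample(c("A", "C", "G", "T"), k * length, replace = TRUE),
                 nrow = k), 1L, paste, collapse = "")
  }
  bcs <- draw(n)
  while (anyDuplicated(bcs)) {
    dup <- which(duplicated(bcs))
    bcs[dup] <- draw(length(dup))
  }
  bcs
}

#' Simulate barcode-assay counts for one clone
#'
#' Propagates lineage frequencies through serial transfer cycles
#' (`f_i(t+1)` proportional to `f_i(t) * exp(s_i * g)`), applies a
#' multinomial bottleneck of `bottleneck` cells at each transfer, and emits
#' multinomial reads at the configured depth at every timepoint. Optional
#' injections: outlier barcodes (a wide fitness offset), a single-timepoint
#' contamination spike, and missingness of strongly deleterious mutations
#' with probability scaled by background-fitness rank.
#'
#' @param s_true Named numeric vector of true per-generation fitness effects,
#'   one per mutation (neutral mutations must be 0).
#' @param neutral Named logical vector over the same mutations.
#' @param assay An [assay_config()].
#' @param x_rank Background-fitness rank in `[0, 1]` used by the missingness
#'   model (0 = least fit background of the condition).
#' @param clone_id,library_id Identifiers for the emitted map rows.
#' @return List: `counts` (per-assay counts tibble), `map` (barcode map
#'   rows), `lineages` (tibble with per-barcode truth: `s_lineage`,
#'   `outlier`, `spiked`), `missing` (mutations dropped by the missingness
#'   model). Uses the current RNG stream; seed at the caller.
#' @export
simulate_assay_counts <- function(s_true, neutral, assay, x_rank = 0,
                                  clone_id = "clone", library_id = "L01") {
  stopifnot(all(s_true[neutral] == 0))
  muts <- names(s_true)
  # biased missingness: strongly deleterious mutations fail transformation
  # more often in fitter backgrounds
  p_miss <- ifelse(!neutral & s_true < assay$missing_threshold,
                   assay$missing_rate * x_rank, 0)
  missing <- muts[runif(length(muts)) < p_miss]
  muts_in <- setdiff(muts, missing)

  per_mut <- rep(assay$n_barcodes, length(muts_in))
  mutation_id <- rep(muts_in, per_mut)
  n_lin <- length(mutation_id)
  outlier <- runif(n_lin) < assay$outlier_rate
  offset <- pmin(pmax(rnorm(n_lin, 0, assay$outlier_sd), -assay$outlier_cap),
                 assay$outlier_cap)
  s_lin <- s_true[mutation_id] + ifelse(outlier, offset, 0)

  f <- exp(rnorm(n_lin, 0, assay$initial_cv))
  f <- f / sum(f)
  g <- assay$generations_per_cycle
  tp_n <- assay$n_timepoints
  reads <- matrix(0L, nrow = n_lin, ncol = tp_n)
  reads[, 1L] <- rmultinom(1L, assay$depth, f)[, 1L]
  for (tp in 2:tp_n) {
    w <- f * exp(s_lin * g)
    f <- w / sum(w)
    cells <- rmultinom(1L, assay$bottleneck, f)[, 1L]
    f <- cells / assay$bottleneck
    reads[, tp] <- rmultinom(1L, assay$depth, f)[, 1L]
  }

  spiked <- rep(FALSE, n_lin)
  if (isTRUE(assay$spike)) {
    spiked <- runif(n_lin) < assay$spike_rate
    bump <- exp(runif(sum(spiked), assay$spike_min, assay$spike_max))
    sp_t <- assay$spike_timepoint
    reads[spiked, sp_t] <- as.integer(round(pmax(reads[spiked, sp_t], 10) * bump))
  }

  barcode <- random_barcodes(n_lin, assay$barcode_length)
  colnames(reads) <- paste0("t", seq_len(tp_n))
  counts <- tibble::tibble(
    barcode = barcode,
    library_id = library_id,
    clone_id = clone_id,
    mutation_id = mutation_id,
    neutral = unname(neutral[mutation_id]))
  counts <- dplyr::bind_cols(counts, tibble::as_tibble(reads))
  list(counts = counts,
       map = counts[, c("barcode", "library_id", "clone_id", "mutation_id",
                        "neutral")],
       lineages = tibble::tibble(barcode = barcode, mutation_id = mutation_id,
                                 s_lineage = unname(s_lin),
                                 outlier = outlier, spiked = spiked),
       missing = missing)
}

#' Generate a complete synthetic study
#'
#' Runs [simulate_evolution()], [assign_true_effects()] and
#' [simulate_assay_counts()] for every clone of every background, plus a
#' simulated reference-competition series per clone for background-fitness
#' estimation. Everything is reproducible from (configs, seed).
#'
#' @param evo,eff,assay Configurations (defaults as documented in their
#'   constructors).
#' @param seed Master RNG seed; per-assay streams are derived from it.
#' @return List of class `synthetic_study`: `backgrounds`, `truth`, `assays`
#'   (list of per-clone lists: `counts`, `lineages`, `missing`), `metadata`
#'   (per-clone tibble), `competition` (per-clone reference-competition
#'   series), and the configs.
#' @export
synthetic_study <- function(evo = evolution_config(),
                            eff = effect_config(),
                            assay = assay_config(),
                            seed = 1L) {
  backgrounds <- simulate_evolution(evo, seed = seed)
  truth <- assign_true_effects(backgrounds, eff, seed = seed + 1L)

  s_by_mut <- setNames(truth$mutations$a, truth$mutations$mutation_id)
  neutral <- setNames(truth$mutations$neutral, truth$mutations$mutation_id)

  # background-fitness rank within each environment (for missingness)
  backgrounds <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(backgrounds, .data$environment),
    x_rank = (rank(.data$x_pop) - 1) / pmax(1, dplyr::n() - 1)))

  assays <- list()
  competition <- list()
  metadata <- list()
  for (i in seq_len(nrow(backgrounds))) {
    row <- backgrounds[i, ]
    eff_here <- truth$effects[
      truth$effects$environment == row$environment &
        truth$effects$population == row$population &
        truth$effects$timepoint == row$timepoint, ]
    s_true <- setNames(eff_here$s_true, eff_here$mutation_id)[names(neutral)]
    lib <- sprintf("L%03d", i)
    res <- withr::with_seed(seed + 100L + i, {
      simulate_assay_counts(s_true, neutral, assay, x_rank = row$x_rank,
                            clone_id = row$clone_id, library_id = lib)
    })
    assays[[row$clone_id]] <- res
    competition[[row$clone_id]] <- withr::with_seed(seed + 5000L + i, {
      simulate_competition_series(row$x_clone, assay$generations_per_cycle,
                                  noise_sd = evo$x_measure_sd)
    })
    metadata[[i]] <- dplyr::bind_cols(row, tibble::tibble(library_id = lib))
  }
  structure(list(backgrounds = backgrounds, truth = truth, assays = assays,
                 metadata = dplyr::bind_rows(metadata),
                 competition = competition,
                 evo = evo, eff = eff, assay = assay, seed = seed),
            class = "synthetic_study")
}

# Internal: duplicate reference-competition frequency series for one clone.
# The log-ratio of clone to reference advances by x * g per cycle, plus
# measurement noise on each flow-cytometry reading.
simulate_competition_series <- function(x_clone, generations_per_cycle,
                                        n_cycles = 4L, noise_sd = 0.003) {
  rows <- lapply(1:2, function(rep_i) {
    lr0 <- 0
    cyc <- 0:(n_cycles - 1L)
    lr <- lr0 + x_clone * generations_per_cycle * cyc +
      rnorm(n_cycles, 0, noise_sd * generations_per_cycle)
    f_clone <- 1 / (1 + exp(-lr))
    tibble::tibble(replicate = rep_i, cycle = cyc,
                   f_clone = f_clone, f_ref = 1 - f_clone)
  })
  dplyr::bind_rows(rows)
}

#' Export the ground truth as TSV files
#'
#' Writes `truth_mutations.tsv`, `truth_steps.tsv` and `truth_effects.tsv`,
#' join-compatible with the pipeline's estimate and fit outputs.
#'
#' @param truth A `truth_table`.
#' @param dir Output directory (created if needed).
#' @return The written paths, invisibly.
#' @export
export_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    mutations = file.path(dir, "truth_mutations.tsv"),
    steps = file.path(dir, "truth_steps.tsv"),
    effects = file.path(dir, "truth_effects.tsv"))
  readr::write_tsv(truth$mutations, paths["mutations"])
  readr::write_tsv(truth$steps, paths["steps"])
  readr::write_tsv(truth$effects, paths["effects"])
  invisible(paths)
}

#' Read an exported truth table
#'
#' @param dir Directory written by [export_truth()].
#' @return A `truth_table`.
#' @export
read_truth <- function(dir) {
  structure(list(
    mutations = readr::read_tsv(file.path(dir, "truth_mutations.tsv"),
                                show_col_types = FALSE),
    steps = readr::read_tsv(file.path(dir, "truth_steps.tsv"),
                            show_col_types = FALSE),
    effects = readr::read_tsv(file.path(dir, "truth_effects.tsv"),
                              show_col_types = FALSE)),
    class = "truth_table")
}
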