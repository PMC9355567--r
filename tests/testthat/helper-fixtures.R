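# Shared fixture builders. Everything is generated in code under fixed seeds.

# A log_freq object built directly from a log-frequency matrix (bypasses
# counts when a test only cares about trajectory shape).
make_lf <- function(logf, totals = rep(10000, ncol(logf)),
                    retained = rep(TRUE, ncol(logf))) {
  if (is.null(rownames(logf))) rownames(logf) <- paste0("bc", seq_len(nrow(logf)))
  structure(list(logf = logf, totals = totals, retained = retained,
                 cycle = seq_len(ncol(logf))),
            class = "log_freq")
}

# Deterministic count trajectories n_t = round(n0 * exp(theta * (t - 1))) for
# building outlier-test fixtures.
exp_counts <- function(n0, theta, n_t = 5L) {
  round(n0 * exp(theta * (seq_len(n_t) - 1L)))
}

# Independent brute-force oracle for the deletion-neighborhood rule.
oracle_neighborhood <- function(x) {
  n <- nchar(x)
  dels <- vapply(seq_len(n), function(i) {
    paste0(substr(x, 1, i - 1), substr(x, i + 1, n))
  }, character(1))
  unique(c(x, dels))
}
oracle_correct <- function(raw, known) {
  if (raw %in% known) return(raw)
  L <- nchar(known[1])
  if (abs(nchar(raw) - L) > 1) return(NA_character_)
  nb_raw <- oracle_neighborhood(raw)
  hits <- known[vapply(known, function(k) {
    length(intersect(nb_raw, oracle_neighborhood(k))) > 0
  }, logical(1))]
  if (length(hits) == 1) hits else NA_character_
}

# Independent Poisson profile-likelihood oracle for the LLR test (grid-search
# maximum, dpois-based likelihood).
oracle_loglik <- function(n, N, t, theta) {
  w <- N * exp(theta * t)
  f0 <- sum(n) / sum(w)
  sum(stats::dpois(n, f0 * w, log = TRUE))
}
oracle_llr <- function(n, N, t, theta0, grid = seq(-3, 3, by = 1e-4)) {
  ll <- vapply(grid, function(th) oracle_loglik(n, N, t, th), numeric(1))
  2 * (max(ll) - oracle_loglik(n, N, t, theta0))
}

# Random anchored series for the epistasis models: n_pops populations over
# timepoints 1..n_tp with anchored background fitness rising ~linearly.
make_series <- function(n_pops = 6, n_tp = 6, noise = 0.005,
                        beta = 0, steps = NULL, x_gain = 0.02, seed = 1) {
  withr::with_seed(seed, {
    d <- tidyr::crossing(population = paste0("P", seq_len(n_pops)),
                         timepoint = seq_len(n_tp))
    d$x_anch <- x_gain * (d$timepoint - 1) + stats::rnorm(nrow(d), 0, 0.002)
    d$s_anch <- beta * d$x_anch + stats::rnorm(nrow(d), 0, noise)
    if (!is.null(steps)) {
      for (i in seq_len(nrow(steps))) {
        on <- d$population == steps$population[i] &
          d$timepoint >= steps$onset[i]
        d$s_anch[on] <- d$s_anch[on] + steps$magnitude[i]
      }
    }
    d
  })
}

# Estimate-level long table for DFE / epistasis tests: backgrounds on a
# pops x timepoints grid with per-cell errors, optional missing cells.
make_estimates <- function(s_matrix, sigma_cbc = 0.01, sigma_neut = 0.005,
                           environment = "E1", num_cbcs = 10) {
  muts <- rownames(s_matrix)
  bgs <- colnames(s_matrix)
  d <- tidyr::crossing(mutation_id = muts, bg = bgs)
  d$s <- as.vector(t(s_matrix))  # crossing sorts; align below instead
  d <- d[order(d$mutation_id, d$bg), ]
  d$s <- s_matrix[cbind(match(d$mutation_id, muts), match(d$bg, bgs))]
  d$environment <- environment
  d$population <- sub("\\.t.*$", "", d$bg)
  d$timepoint <- as.integer(sub("^.*\\.t", "", d$bg))
  d$generation <- d$timepoint * 1000
  d$sigma_cbc <- sigma_cbc
  d$sigma_neut <- sigma_neut
  d$sigma <- sqrt(d$sigma_cbc^2 + d$sigma_neut^2)
  d$num_cbcs <- num_cbcs
  d$bg <- NULL
  d[!is.na(d$s), , drop = FALSE]
}

# Small synthetic study used by the pipeline tests (fast; ~10 s).
small_study <- function(seed = 3) {
  synthetic_study(
    evo = evolution_config(n_populations = 2,
                           generations = c(1000, 5000, 9000)),
    eff = effect_config(n_mutations = 12, n_neutral = 3),
    assay = assay_config(n_barcodes = 6, depth = 3e4, bottleneck = 5e5),
    seed = seed)
}
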