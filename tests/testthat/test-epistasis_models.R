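# Anchored series come from make_series() (helper): populations P1..P6 over
# timepoints 1..6 with x_anch rising ~0.02 per timepoint.

test_that("eligibility drops thin measurements before counting backgrounds", {
  est <- tidyr::crossing(environment = "E1", mutation_id = c("m1", "m2"),
                         population = paste0("P", 1:5), timepoint = 1:4)
  est$num_cbcs <- 10
  # m2 measured in 19 cells after one drop (below a 20-point floor)
  est <- est[!(est$mutation_id == "m2" & est$population == "P1" &
                 est$timepoint == 1), ]
  got <- eligible_mutations(est, min_pts = 20, min_cbcs = 5)
  expect_setequal(unique(got$mutation_id), "m1")
  # low-cBC measurements are removed first and can disqualify a mutation
  est2 <- tidyr::crossing(environment = "E1", mutation_id = "m3",
                          population = paste0("P", 1:5), timepoint = 1:4)
  est2$num_cbcs <- c(4, rep(10, 19))
  got2 <- eligible_mutations(est2, min_pts = 20, min_cbcs = 5)
  expect_equal(nrow(got2), 0)
  expect_equal(nrow(eligible_mutations(est2, min_pts = 19, min_cbcs = 5)), 19)
  # complete set passes through unchanged
  got3 <- eligible_mutations(est[est$mutation_id == "m1", ], 20, 5)
  expect_equal(nrow(got3), 20)
})

test_that("fitness-correlation classes apply both the Wald and slope criteria", {
  bg <- tidyr::crossing(environment = "E1", population = paste0("P", 1:6),
                        timepoint = 1:6)
  bg$x <- 0.02 * (bg$timepoint - 1) + rep(seq(0, 0.01, length.out = 6), each = 6)
  mk_est <- function(id, slope, noise, seed) {
    withr::with_seed(seed, {
      d <- bg
      d$mutation_id <- id
      d$s <- -0.1 + slope * d$x + rnorm(nrow(d), 0, noise)
      d$x <- NULL
      d
    })
  }
  est <- dplyr::bind_rows(
    mk_est("flat", 0, 1e-6, 1),
    mk_est("neg", -0.2, 0.002, 2),
    mk_est("small", -0.04, 1e-6, 3))   # tiny p but sub-threshold slope
  got <- classify_fitness_correlation(est, bg)
  expect_equal(got$class[got$mutation_id == "flat"], "ns")
  expect_equal(got$class[got$mutation_id == "neg"], "negative")
  # significance alone is not enough: |slope| must exceed 0.05
  expect_true(got$wald_p[got$mutation_id == "small"] < 1e-6)
  expect_equal(got$class[got$mutation_id == "small"], "ns")
  expect_true(all(c("bh_class", "slope", "wald_p") %in% names(got)))
})

test_that("anchoring subtracts first-timepoint means and is invertible", {
  bg <- tidyr::crossing(environment = "E1", population = c("P1", "P2"),
                        timepoint = 1:3)
  bg$x <- c(0.00, 0.05, 0.10, 0.02, 0.06, 0.12)
  est <- bg
  est$mutation_id <- "m1"
  est$s <- c(0.00, -0.02, -0.05, 0.02, -0.01, -0.04)
  a <- anchor_estimates(est, bg)
  # anchors are the first-timepoint means across populations
  expect_equal(a$anchors$s$s_anchor, mean(c(0.00, 0.02)))
  expect_equal(a$anchors$x$x_anchor, mean(c(0.00, 0.02)))
  expect_equal(a$anchored$s_anch, est$s - 0.01)
  expect_equal(a$anchored$x_anch, bg$x - 0.01)
  # back-transformation recovers the raw series exactly
  expect_equal(a$anchored$s_anch + a$anchors$s$s_anchor, est$s)
  # an already-centered series is unchanged
  est2 <- est; est2$s <- est$s - 0.01
  bg2 <- bg; bg2$x <- bg$x - 0.01
  a2 <- anchor_estimates(est2, bg2)
  expect_equal(a2$anchored$s_anch, est2$s)
  # a mutation absent from the first timepoint is excluded with a message
  est3 <- dplyr::bind_rows(est, dplyr::mutate(est[est$timepoint > 1, ],
                                              mutation_id = "late"))
  expect_message(a3 <- anchor_estimates(est3, bg), "excluded")
  expect_false("late" %in% a3$anchored$mutation_id)
  expect_equal(a3$excluded$mutation_id, "late")
})

test_that("candidate indicators span observed onsets with coverage >= 2", {
  # fully observed population over 6 timepoints: onsets t2..t5 (t6 covers 1)
  s1 <- tibble::tibble(population = "P1", timepoint = 1:6)
  c1 <- candidate_indicators(s1)
  expect_equal(c1$onset, 2:5)
  expect_equal(c1$coverage, 5:2)
  # last two timepoints missing: onset coverage counts observed points only
  s2 <- tibble::tibble(population = "P1", timepoint = 1:4)
  expect_equal(candidate_indicators(s2)$onset, 2:3)
  # two observed points: single onset of coverage 2 at most
  s3 <- tibble::tibble(population = "P1", timepoint = c(1, 4))
  c3 <- candidate_indicators(s3)
  expect_equal(nrow(c3), 0)  # onset 4 would cover a single point
  s4 <- tibble::tibble(population = "P1", timepoint = c(1, 4, 5))
  c4 <- candidate_indicators(s4)
  expect_equal(c4$onset, 4)
  expect_equal(c4$coverage, 2)
})

test_that("XM is a through-origin fit with centered, clamped R-squared", {
  d <- make_series(n_pops = 2, n_tp = 4, noise = 0, seed = 61)
  d$s_anch <- 0.5 * d$x_anch
  fit <- fit_xm(d)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # orthogonal response with nonzero mean: raw centered R^2 < 0, clamped to 0
  d2 <- tibble::tibble(population = "P1", timepoint = 1:4,
                       x_anch = c(-1, 1, -1, 1), s_anch = c(1, 1, 1.5, 1.5))
  fit2 <- fit_xm(d2)
  raw <- 1 - fit2$ssr / sum((d2$s_anch - mean(d2$s_anch))^2)
  expect_true(raw < 0)
  expect_equal(fit2$r_squared, 0)
  # minimal n = 2 is defined
  expect_s3_class(fit_xm(d[1:2, ]), "epistasis_fit")
  dz <- d; dz$x_anch <- 0
  expect_error(fit_xm(dz), "no variation")
})

test_that("centered R-squared matches hand arithmetic on a 5-point example", {
  y <- c(0.00, 0.01, -0.02, 0.03, 0.04)
  ssr <- 0.0005
  want <- 1 - ssr / sum((y - mean(y))^2)
  expect_equal(model_r2(ssr, y), want, tolerance = 1e-13)
  expect_equal(model_r2(0, y), 1)
  expect_warning(r0 <- model_r2(0.1, rep(1, 4)), "zero centered")
  expect_equal(r0, 0)
})

test_that("IM null behavior: spurious selections are rare (empty model typical)", {
  # scale-invariant BIC selection admits occasional spurious steps on pure
  # noise; the typical null fit is empty and the mean count stays well
  # below one per mutation
  counts <- vapply(1:20, function(i) {
    nrow(fit_im(make_series(noise = 0.003, seed = 200 + i))$alphas)
  }, numeric(1))
  expect_true(mean(counts) < 1)
  expect_true(mean(counts == 0) >= 0.5)
  # the empty model is a valid outcome with k = 0
  empty_seed <- 200 + which(counts == 0)[1]
  fit0 <- fit_im(make_series(noise = 0.003, seed = empty_seed))
  expect_equal(nrow(fit0$alphas), 0)
  expect_equal(fit0$k, 0)
  expect_true(is.finite(fit0$bic))
})

test_that("IM recovers injected steps in the correct population", {
  # one +0.10 step from timepoint 4 in P2, noise 0.005
  d1 <- make_series(noise = 0.005, seed = 63,
                    steps = tibble::tibble(population = "P2", onset = 4,
                                           magnitude = 0.10))
  fit1 <- fit_im(d1)
  hit <- fit1$alphas$population == "P2"
  expect_true(any(hit))
  expect_true(any(hit & abs(fit1$alphas$onset - 4) <= 1))
  expect_true(any(hit & abs(fit1$alphas$coefficient - 0.10) < 0.02))
  # two independent steps in two populations; never two in one population
  d2 <- make_series(noise = 0.005, seed = 64,
                    steps = tibble::tibble(population = c("P1", "P5"),
                                           onset = c(3, 5),
                                           magnitude = c(-0.08, 0.12)))
  fit2 <- fit_im(d2)
  expect_true(all(c("P1", "P5") %in% fit2$alphas$population))
  expect_equal(anyDuplicated(fit2$alphas$population), 0)
})

test_that("IM fitted values are piecewise-constant steps within populations", {
  d <- make_series(noise = 0.004, seed = 65,
                   steps = tibble::tibble(population = "P3", onset = 3,
                                          magnitude = 0.09))
  fit <- fit_im(d)
  pred <- rep(0, nrow(d))
  for (i in seq_len(nrow(fit$alphas))) {
    on <- d$population == fit$alphas$population[i] &
      d$timepoint >= fit$alphas$onset[i]
    pred[on] <- pred[on] + fit$alphas$coefficient[i]
  }
  # populations without a selected step predict the anchored baseline (zero)
  other <- d$population != "P3"
  expect_true(all(pred[other] == 0))
  # residual SSR consistent with the recorded fit
  expect_equal(sum((d$s_anch - pred)^2), fit$ssr, tolerance = 1e-12)
})

test_that("FM keeps the slope, selects steps independently, and tolerates non-nesting", {
  # pure slope: no indicators, slope within 2 SE of truth
  d1 <- make_series(beta = 0.5, noise = 0.004, seed = 66)
  fm1 <- fit_fm(d1)
  expect_true(abs(fm1$beta - 0.5) < 0.05)
  expect_true(fm1$beta_se > 0)
  # pure step: slope near zero, the step recovered
  d2 <- make_series(noise = 0.004, seed = 67,
                    steps = tibble::tibble(population = "P4", onset = 3,
                                           magnitude = 0.1))
  fm2 <- fit_fm(d2)
  expect_equal(fm2$alphas$population, "P4")
  expect_true(abs(fm2$beta) < 0.2)
  # IM not nested in FM: both fits exist and R^2 may order either way
  im2 <- fit_im(d2)
  expect_s3_class(im2, "epistasis_fit")
  expect_s3_class(fm2, "epistasis_fit")
  expect_true(is.finite(im2$bic) && is.finite(fm2$bic))
})

test_that("model selection takes the BIC argmin with a fewer-parameter tie rule", {
  mk_fit <- function(model, bic, k) {
    structure(list(model = model, bic = bic, k = k, n_points = 30,
                   ssr = 0.001, beta = 0, beta_se = 0.1,
                   alphas = tibble::tibble(), r_squared = 0.5),
              class = "epistasis_fit")
  }
  fits <- tibble::tibble(
    environment = "E1", mutation_id = "m1",
    model = c("XM", "IM", "FM"),
    n_points = 30, k = c(1, 2, 3),
    fit = list(mk_fit("XM", 10, 1), mk_fit("IM", 8, 2), mk_fit("FM", 9, 3)))
  sel <- select_best_model(fits)
  expect_equal(sel$per_mutation$best, "IM")
  # tie between IM and FM: IM wins on parameter count
  fits2 <- fits
  fits2$fit <- list(mk_fit("XM", 10, 1), mk_fit("IM", 8, 2), mk_fit("FM", 8, 3))
  expect_equal(select_best_model(fits2)$per_mutation$best, "IM")
})

test_that("dataset-level BIC equals a brute-force joint-likelihood computation", {
  fits <- fit_epistasis_models(
    dplyr::bind_rows(lapply(1:3, function(i) {
      d <- make_series(noise = 0.005, seed = 70 + i,
                       steps = if (i == 1)
                         tibble::tibble(population = "P2", onset = 3,
                                        magnitude = 0.1) else NULL)
      tibble::tibble(environment = "E1", mutation_id = paste0("m", i),
                     population = d$population, timepoint = d$timepoint,
                     s = d$s_anch, x = d$x_anch)
    })) |> (\(d) {
      # raw inputs for fit_epistasis_models: estimates + background
      est <- d[, c("environment", "mutation_id", "population", "timepoint", "s")]
      est
    })(),
    background = {
      d <- make_series(noise = 0, seed = 99)
      tibble::tibble(environment = "E1", population = d$population,
                     timepoint = d$timepoint, x = 0.02 * (d$timepoint - 1))
    })
  sel <- select_best_model(fits$fits)
  for (mod in c("XM", "IM", "FM")) {
    sub <- fits$fits[fits$fits$model == mod, ]
    n <- sum(sub$n_points)
    ssr <- vapply(sub$fit, function(f) f$ssr, numeric(1))
    nn <- sub$n_points
    want <- sum(nn * log(pmax(ssr, 1e-300) / nn) + nn * (1 + log(2 * pi))) +
      sum(sub$k) * log(n)
    expect_equal(sel$dataset$bic[sel$dataset$model == mod], want,
                 tolerance = 1e-10)
  }
})

test_that("shuffled null permutes within sets and preserves everything else", {
  est <- tidyr::crossing(environment = c("E1", "E2"),
                         mutation_id = c("m1", "m2"),
                         population = paste0("P", 1:3), timepoint = 1:3)
  withr::with_seed(72, {
    est$s <- rnorm(nrow(est))
    est$sigma <- runif(nrow(est), 0.001, 0.01)
  })
  shuf <- make_shuffled_dataset(est, seed = 5)
  # multiset of s preserved within each (mutation, environment) set
  for (e in c("E1", "E2")) for (m in c("m1", "m2")) {
    a <- sort(est$s[est$environment == e & est$mutation_id == m])
    b <- sort(shuf$s[shuf$environment == e & shuf$mutation_id == m])
    expect_equal(a, b)
  }
  # mask and keys unchanged
  expect_identical(est[, c("environment", "mutation_id", "population",
                           "timepoint")],
                   shuf[, c("environment", "mutation_id", "population",
                            "timepoint")])
  # sigma travels with s by default
  pairs <- paste(est$s, est$sigma)
  expect_setequal(paste(shuf$s, shuf$sigma), pairs)
  # determinism
  expect_identical(shuf, make_shuffled_dataset(est, seed = 5))
  expect_false(identical(shuf$s, make_shuffled_dataset(est, seed = 6)$s))
  # s-only mode leaves sigma in place
  s_only <- make_shuffled_dataset(est, seed = 5, s_only = TRUE)
  expect_identical(s_only$sigma, est$sigma)
})

test_that("simulated null draws from N(0, mean sigma) per set", {
  est <- tidyr::crossing(environment = "E1", mutation_id = c("tight", "loose"),
                         population = paste0("P", 1:6), timepoint = 1:6)
  est$s <- 1
  est$sigma <- ifelse(est$mutation_id == "tight", 0.01, 0.1)
  # degenerate: zero sigma -> all zeros
  est0 <- est; est0$sigma <- 0
  expect_true(all(make_simulated_dataset(est0, seed = 1)$s == 0))
  # moment check over many replicate draws
  draws_t <- numeric(0); draws_l <- numeric(0)
  for (i in 1:300) {
    sim <- make_simulated_dataset(est, seed = i)
    draws_t <- c(draws_t, sim$s[sim$mutation_id == "tight"])
    draws_l <- c(draws_l, sim$s[sim$mutation_id == "loose"])
  }
  expect_true(abs(mean(draws_t)) < 3 * 0.01 / sqrt(length(draws_t)))
  expect_equal(sd(draws_t), 0.01, tolerance = 0.02)
  # per-set sigma, not global: the loose set is visibly wider
  expect_equal(sd(draws_l), 0.1, tolerance = 0.02)
})

test_that("coefficient census counts signs per environment and model", {
  coefs <- tibble::tibble(
    environment = c("E1", "E1", "E1", "E2"),
    mutation_id = c("m1", "m1", "m2", "m3"),
    model = c("IM", "IM", "IM", "FM"),
    population = "P1", onset = 3,
    coefficient = c(0.1, -0.2, -0.3, 0.05), coverage = 3)
  cen <- census_coefficients(coefs)
  im_e1 <- cen[cen$environment == "E1" & cen$model == "IM", ]
  expect_equal(im_e1$n_total, 3)
  expect_equal(im_e1$n_positive, 1)
  expect_equal(im_e1$n_negative, 2)
  # empty census is all zeros
  expect_equal(cen$n_total[cen$environment == "E1" & cen$model == "FM"], 0)
  # census equals direct re-iteration over the store
  for (i in seq_len(nrow(cen))) {
    sub <- coefs[coefs$environment == cen$environment[i] &
                   coefs$model == cen$model[i], ]
    expect_equal(cen$n_total[i], nrow(sub))
    expect_equal(cen$n_negative[i], sum(sub$coefficient < 0))
  }
})

test_that("forward selection honors its contract on fuzzed inputs", {
  withr::with_seed(80, {
    for (rep in 1:30) {
      n_pops <- sample(2:6, 1)
      n_tp <- sample(3:6, 1)
      steps <- if (runif(1) < 0.5) {
        tibble::tibble(population = paste0("P", sample(n_pops, 1)),
                       onset = sample(2:max(2, n_tp - 1), 1),
                       magnitude = runif(1, -0.15, 0.15))
      } else NULL
      d <- make_series(n_pops = n_pops, n_tp = n_tp,
                       noise = runif(1, 0.002, 0.02),
                       beta = runif(1, -0.5, 0.5), steps = steps,
                       seed = 1000 + rep)
      # randomly drop a few observations
      d <- d[runif(nrow(d)) > 0.1, , drop = FALSE]
      if (length(unique(d$population)) < 2 || nrow(d) < 6) next
      for (fit in list(fit_im(d), fit_fm(d))) {
        # every accepted step decreased BIC by more than 2, strictly
        if (length(fit$bic_path) > 1) {
          expect_true(all(-diff(fit$bic_path) > 2))
        }
        # at most one parameter per population
        expect_equal(anyDuplicated(fit$alphas$population), 0)
        # no indicator fitting a single observed point
        for (i in seq_len(nrow(fit$alphas))) {
          covered <- sum(d$population == fit$alphas$population[i] &
                           d$timepoint >= fit$alphas$onset[i])
          expect_true(covered >= 2)
        }
        expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
        expect_true(is.finite(fit$bic))
      }
    }
  })
})
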