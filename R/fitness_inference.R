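#' @importFrom stats median optimize rnorm runif rgamma rmultinom rbinom
#'   lm coef vcov pt p.adjust sd qnorm complete.cases setNames
#' @importFrom rlang .data
NULL

# Internal: count matrix (lineages x timepoints) from a counts tibble.
counts_matrix <- function(counts) {
  tcols <- grep("^t[0-9]+$", names(counts), value = TRUE)
  m <- as.matrix(counts[, tcols])
  rownames(m) <- counts$barcode
  storage.mode(m) <- "double"
  m
}

#' Convert lineage counts to masked log-frequency trajectories
#'
#' Assay timepoints whose total barcode count is below `min_total` are dropped
#' for all lineages; within retained timepoints, a lineage's log-frequency is
#' defined only where its count is at least `min_count`. Totals are computed
#' before any lineage-level masking.
#'
#' @param counts A per-assay counts tibble (columns `barcode`, `t1`..`tn`, plus
#'   map columns) or a bare count matrix.
#' @param min_total Minimum total reads for a timepoint to be retained
#'   (default 5000).
#' @param min_count Minimum per-lineage count for a log-frequency to be
#'   defined (default 10).
#' @return A list of class `log_freq`: `logf` (matrix, `NA` where undefined),
#'   `totals`, `retained` (logical over timepoints), and `cycle` (the 1-based
#'   timepoint coordinate, in transfer cycles).
#' @export
log_frequencies <- function(counts, min_total = 5000, min_count = 10) {
  m <- if (is.matrix(counts)) counts else counts_matrix(counts)
  if (ncol(m) < 2L) stop("need at least two assay timepoints", call. = FALSE)
  totals <- colSums(m)
  retained <- totals >= min_total
  if (sum(retained) < 2L) {
    stop("fewer than two timepoints pass the total-count threshold (",
         min_total, ")", call. = FALSE)
  }
  logf <- log(sweep(m, 2L, totals, "/"))
  logf[m < min_count] <- NA_real_
  logf[, !retained] <- NA_real_
  structure(list(logf = logf, totals = totals, retained = retained,
                 cycle = seq_len(ncol(m))),
            class = "log_freq")
}

#' Flag single-timepoint contamination spikes
#'
#' A lineage is flagged iff its log-frequency at the spike timepoint exceeds
#' both neighboring timepoints by more than `delta` log-units, the signature
#' of low-level sequencing-library contamination confined to one timepoint.
#' Lineages with an undefined log-frequency at any of the three timepoints are
#' not flagged.
#'
#' @param lf A `log_freq` object.
#' @param spike_timepoint Index (1-based assay timepoint) of the suspect
#'   timepoint; default 2, so neighbors are timepoints 1 and 3.
#' @param delta Excess in natural-log units required on both sides
#'   (default 0.5).
#' @return Logical vector over lineages (`TRUE` = flagged).
#' @export
flag_contamination_spikes <- function(lf, spike_timepoint = 2L, delta = 0.5) {
  tp <- spike_timepoint
  if (tp - 1L < 1L || tp + 1L > ncol(lf$logf)) {
    return(rep(FALSE, nrow(lf$logf)))
  }
  a <- lf$logf[, tp] - lf$logf[, tp - 1L]
  b <- lf$logf[, tp] - lf$logf[, tp + 1L]
  flagged <- !is.na(a) & !is.na(b) & a > delta & b > delta
  unname(flagged)
}

# Internal: per-lineage slopes over consecutive retained timepoint pairs.
# Slopes are per transfer cycle; a gap left by a dropped timepoint divides by
# the cycle distance. Returns a lineages x pairs matrix (NA where undefined).
pair_slopes <- function(lf) {
  keep <- which(lf$retained)
  if (length(keep) < 2L) stop("need two retained timepoints", call. = FALSE)
  from <- keep[-length(keep)]
  to <- keep[-1L]
  slopes <- (lf$logf[, to, drop = FALSE] - lf$logf[, from, drop = FALSE]) /
    rep(lf$cycle[to] - lf$cycle[from], each = nrow(lf$logf))
  colnames(slopes) <- paste0("p", from, "_", to)
  slopes
}

#' Per-barcode fitness from log-frequency slopes
#'
#' For each lineage, the log-frequency slope over every consecutive pair of
#' retained timepoints is normalized against the median slope of the neutral
#' reference lineages for that same pair, the normalized slopes are averaged,
#' and the average is converted to per-generation units.
#'
#' @param lf A `log_freq` object.
#' @param neutral Logical vector over lineages marking neutral-reference
#'   barcodes (used to compute the per-pair median; at least one neutral slope
#'   must be defined for every pair used).
#' @param generations_per_cycle Generations per transfer cycle (e.g. 10 for a
#'   1/2^10 daily dilution).
#' @param normalize `"subtract"` (default; fitness effects are additive on the
#'   log-slope scale) or `"divide"` for sensitivity checks.
#' @return Tibble with columns `barcode`, `s` (per generation), `n_pairs`;
#'   lineages with no valid pair are dropped.
#' @export
barcode_fitness <- function(lf, neutral, generations_per_cycle = 10,
                            normalize = c("subtract", "divide")) {
  normalize <- match.arg(normalize)
  if (!any(neutral)) {
    stop("no neutral reference lineages available for normalization",
         call. = FALSE)
  }
  slopes <- pair_slopes(lf)
  med <- apply(slopes[neutral, , drop = FALSE], 2L, median, na.rm = TRUE)
  norm <- if (normalize == "subtract") {
    sweep(slopes, 2L, med, "-")
  } else {
    sweep(slopes, 2L, med, "/")
  }
  # a pair with no neutral reference slope is unusable
  norm[, is.na(med)] <- NA_real_
  n_pairs <- rowSums(!is.na(norm))
  s <- rowMeans(norm, na.rm = TRUE) / generations_per_cycle
  out <- tibble::tibble(barcode = rownames(slopes), s = unname(s),
                        n_pairs = unname(n_pairs))
  out[out$n_pairs >= 1L, , drop = FALSE]
}

# Internal: Poisson profile log-likelihood for one lineage trajectory.
# Counts n at retained timepoints with totals N and cycle coordinates t are
# modeled as Poisson(N * f0 * exp(theta * t)); f0 is profiled in closed form.
# Constant log(n!) terms are dropped (they cancel in likelihood ratios).
lineage_loglik <- function(n, N, t, theta) {
  w <- N * exp(theta * t)
  tot <- sum(n)
  if (tot == 0) return(0)
  f0 <- tot / sum(w)
  mu <- f0 * w
  sum(n * log(mu)) - tot
}

# Internal: ML raw slope (per cycle) for one lineage trajectory.
lineage_ml_theta <- function(n, N, t, interval = c(-5, 5)) {
  if (sum(n) == 0) return(0)
  optimize(function(th) lineage_loglik(n, N, t, th),
           interval = interval, maximum = TRUE, tol = 1e-6)$maximum
}

#' Log-likelihood ratio of a barcode against a reference fitness
#'
#' Twice the difference between the Poisson profile log-likelihood of the
#' barcode's counts at its own maximum-likelihood log-frequency slope and at
#' the reference slope `theta0`. Used by [exclude_outlier_barcodes()]; exposed
#' so the likelihood model is independently checkable.
#'
#' @param n Counts at retained timepoints.
#' @param N Total assay counts at those timepoints.
#' @param t Cycle coordinates of the timepoints.
#' @param theta0 Reference (null) slope, per cycle.
#' @return List with `llr`, `theta_hat`.
#' @export
barcode_llr <- function(n, N, t, theta0) {
  theta_hat <- lineage_ml_theta(n, N, t)
  llr <- 2 * (lineage_loglik(n, N, t, theta_hat) - lineage_loglik(n, N, t, theta0))
  list(llr = llr, theta_hat = theta_hat)
}

#' Exclude outlier barcodes by iterative log-likelihood ratio test
#'
#' Within one insertion mutation, barcodes whose read-count trajectories are
#' inconsistent with the barcodes near the median fitness are excluded: the
#' barcode with the largest log-likelihood ratio against the median
#' maximum-likelihood slope is removed if its LLR strictly exceeds
#' `llr_cutoff`, the median is recomputed, and the test repeats until no
#' barcode exceeds the cutoff or a single barcode remains.
#'
#' @param counts Count matrix (barcodes of one mutation x timepoints).
#' @param lf The assay-level `log_freq` object (for totals and retained mask).
#' @param llr_cutoff Exclusion threshold (default 40, strict inequality).
#' @return List with `retained` (barcode names), `excluded`, and `llr` (last
#'   computed LLR per barcode).
#' @export
exclude_outlier_barcodes <- function(counts, lf, llr_cutoff = 40) {
  keep_t <- which(lf$retained)
  N <- lf$totals[keep_t]
  t <- lf$cycle[keep_t]
  m <- counts[, keep_t, drop = FALSE]
  bcs <- rownames(m)
  theta_hat <- vapply(seq_len(nrow(m)),
                      function(i) lineage_ml_theta(m[i, ], N, t), numeric(1))
  names(theta_hat) <- bcs
  retained <- bcs
  excluded <- character(0)
  llr <- setNames(rep(NA_real_, length(bcs)), bcs)
  while (length(retained) >= 2L) {
    theta0 <- median(theta_hat[retained])
    llr_now <- vapply(retained, function(b) {
      2 * (lineage_loglik(m[b, ], N, t, theta_hat[b]) -
             lineage_loglik(m[b, ], N, t, theta0))
    }, numeric(1))
    llr[retained] <- llr_now
    worst <- which.max(llr_now)
    if (llr_now[worst] > llr_cutoff) {
      excluded <- c(excluded, retained[worst])
      retained <- retained[-worst]
    } else {
      break
    }
  }
  list(retained = retained, excluded = excluded, llr = llr)
}

#' Randomly combine barcodes into cBCs
#'
#' Partitions the barcodes of one mutation into at most `max_cbcs` groups of
#' sizes differing by at most one (seeded shuffle, then round-robin
#' assignment) and sums their counts element-wise, yielding combined-barcode
#' (cBC) lineages whose pooled trajectory equals the input pool.
#'
#' @param counts Count matrix (retained barcodes of one mutation x
#'   timepoints).
#' @param max_cbcs Maximum number of cBCs (default 5).
#' @param prefix Row-name prefix for the cBC ids.
#' @return List with `counts` (cBC x timepoint matrix) and `members` (list of
#'   barcode names per cBC). Uses the current RNG stream; seed at the caller.
#' @export
combine_barcodes <- function(counts, max_cbcs = 5L, prefix = "cbc") {
  n <- nrow(counts)
  stopifnot(n >= 1L)
  k <- min(n, max_cbcs)
  ord <- sample.int(n)
  group <- rep_len(seq_len(k), n)[order(ord)]
  # equivalent: shuffled barcodes assigned round-robin to groups 1..k
  ids <- paste0(prefix, seq_len(k))
  combined <- matrix(0, nrow = k, ncol = ncol(counts),
                     dimnames = list(ids, colnames(counts)))
  for (g in seq_len(k)) {
    combined[g, ] <- colSums(counts[group == g, , drop = FALSE])
  }
  list(counts = combined,
       members = split(rownames(counts), ids[group]))
}

#' Mean and standard error of cBC fitness values for one mutation in one clone
#'
#' The clone-level fitness effect is the mean over cBCs; its standard error
#' over cBCs is `sqrt(sum((s - mean)^2) / ((n - 1) * n))`, and the combined
#' standard error adds the clone's neutral-set error in quadrature:
#' `sigma = sqrt(sigma_cbc^2 + sigma_neut^2)`. With a single cBC the cBC-level
#' error is undefined (`NA`) and is resolved by the borrowing rule at the
#' population-timepoint level.
#'
#' @param s_cbc Numeric vector of cBC fitness values (length >= 1).
#' @param sigma_neut The clone's neutral-set standard error.
#' @return One-row tibble: `s`, `sigma_cbc`, `sigma_neut`, `sigma`,
#'   `num_cbcs`.
#' @export
clone_mutation_summary <- function(s_cbc, sigma_neut) {
  n <- length(s_cbc)
  if (n < 1L) stop("no cBC fitness values", call. = FALSE)
  m <- mean(s_cbc)
  sigma_cbc <- if (n >= 2L) sqrt(sum((s_cbc - m)^2) / ((n - 1) * n)) else NA_real_
  tibble::tibble(
    s = m,
    sigma_cbc = sigma_cbc,
    sigma_neut = sigma_neut,
    sigma = sqrt(sigma_cbc^2 + sigma_neut^2),
    num_cbcs = n
  )
}

# Internal: neutral-set standard error — SE of the mean over all neutral cBC
# fitness values (mirrors the mutation-level formula).
neutral_sigma <- function(s_neutral_cbcs) {
  n <- length(s_neutral_cbcs)
  if (n < 2L) return(NA_real_)
  sqrt(sum((s_neutral_cbcs - mean(s_neutral_cbcs))^2) / ((n - 1) * n))
}

#' Combine clone estimates into a population-timepoint fitness effect
#'
#' Inverse-variance weighted mean of one or two clone estimates. The
#' cBC-level standard error is recomputed from the pooled cBC fitness values
#' of both clones around the weighted mean (a conservative choice that
#' captures unspecified biological differences between replicates), and the
#' neutral error of both clones' neutral cBCs is added in quadrature. If one
#' clone has a single cBC, its weighting variance borrows `sigma` from the
#' other clone. Returns `NULL` unless the clones contribute at least
#' `min_total_cbcs` cBCs together.
#'
#' @param clone_est Tibble of 1-2 rows from [clone_mutation_summary()] (plus
#'   a `clone_id` column).
#' @param cbc_values Numeric vector of all cBC fitness values for this
#'   mutation across the contributing clones.
#' @param sigma_neut_pt Neutral-set standard error over both clones' neutral
#'   cBCs.
#' @param min_total_cbcs Minimum pooled cBC count (default 3).
#' @return One-row tibble (`s`, `sigma_cbc`, `sigma_neut`, `sigma`,
#'   `num_cbcs`) or `NULL`.
#' @export
population_timepoint_fitness <- function(clone_est, cbc_values, sigma_neut_pt,
                                         min_total_cbcs = 3L) {
  n_total <- sum(clone_est$num_cbcs)
  stopifnot(length(cbc_values) == n_total)
  if (n_total < min_total_cbcs) return(NULL)
  w_sigma <- clone_est$sigma
  if (any(is.na(w_sigma))) {
    # single-cBC clone: borrow the other replicate's sigma for weighting
    if (nrow(clone_est) == 2L && sum(is.na(w_sigma)) == 1L) {
      w_sigma[is.na(w_sigma)] <- w_sigma[!is.na(w_sigma)]
    } else {
      return(NULL)
    }
  }
  w <- 1 / w_sigma^2
  s_pt <- sum(clone_est$s * w) / sum(w)
  sigma_cbc <- sqrt(sum((cbc_values - s_pt)^2) / ((n_total - 1) * n_total))
  tibble::tibble(
    s = s_pt,
    sigma_cbc = sigma_cbc,
    sigma_neut = sigma_neut_pt,
    sigma = sqrt(sigma_cbc^2 + sigma_neut_pt^2),
    num_cbcs = n_total
  )
}

#' Test for a nonzero fitness effect from cBC values
#'
#' Ordinary least squares of the cBC fitness values on a clone-difference
#' regressor (`r = -1/2` for the first clone, `+1/2` for the second, so the
#' intercept is the across-clone mean effect). The two-sided p-value comes
#' from the intercept t-statistic. With all cBCs in one clone the
#' clone-difference term is dropped and noted.
#'
#' @param s_cbc Numeric vector of cBC fitness values (length >= 3).
#' @param clone Vector of clone labels aligned with `s_cbc`.
#' @return One-row tibble: `estimate`, `t`, `p`, `df`, `clone_term` (logical:
#'   was the clone-difference term estimable).
#' @export
test_nonzero_effect <- function(s_cbc, clone) {
  stopifnot(length(s_cbc) >= 3L, length(clone) == length(s_cbc))
  clones <- sort(unique(as.character(clone)))
  if (length(clones) > 2L) stop("at most two clones expected", call. = FALSE)
  if (length(clones) == 2L) {
    r <- ifelse(as.character(clone) == clones[1], -0.5, 0.5)
    fit <- lm(s_cbc ~ r)
    clone_term <- TRUE
  } else {
    fit <- lm(s_cbc ~ 1)
    clone_term <- FALSE
  }
  sm <- summary(fit)$coefficients
  est <- sm["(Intercept)", "Estimate"]
  tval <- sm["(Intercept)", "t value"]
  df <- fit$df.residual
  tibble::tibble(
    estimate = est,
    t = tval,
    p = 2 * pt(abs(tval), df = df, lower.tail = FALSE),
    df = df,
    clone_term = clone_term
  )
}

#' Benjamini-Hochberg significance over a family of mutations
#'
#' @param p Numeric vector of per-mutation p-values (one family, e.g. all
#'   mutations assayed in one environment).
#' @param alpha Family-wise false discovery rate (default 0.05).
#' @return Logical vector: significant after BH correction.
#' @export
bh_significant <- function(p, alpha = 0.05) {
  p.adjust(p, method = "BH") < alpha
}

#' Background fitness from reference-competition frequency series
#'
#' The fitness of a clone versus a fluorescent reference is the least-squares
#' slope of `ln(f_clone / f_ref)` against time over the assay cycles,
#' expressed per generation. Cycles at which either frequency is 0 or 1 are
#' dropped with a warning. Replicate assays are averaged and their standard
#' deviation reported.
#'
#' @param series Tibble with columns `replicate`, `cycle`, `f_clone`, `f_ref`.
#' @param generations_per_cycle Generations per assay cycle.
#' @return One-row tibble: `x` (per-generation fitness), `sd` (`NA` with one
#'   replicate), `n_replicates`.
#' @export
background_fitness <- function(series, generations_per_cycle = 10) {
  usable <- series$f_clone > 0 & series$f_clone < 1 &
    series$f_ref > 0 & series$f_ref < 1
  if (any(!usable)) {
    warning(sum(!usable), " cycle(s) dropped with degenerate frequencies")
    series <- series[usable, , drop = FALSE]
  }
  slopes <- vapply(split(series, series$replicate), function(d) {
    if (nrow(d) < 2L) stop("need at least two usable cycles", call. = FALSE)
    y <- log(d$f_clone / d$f_ref)
    unname(coef(lm(y ~ cycle, data = data.frame(cycle = d$cycle, y = y)))[2])
  }, numeric(1))
  per_gen <- slopes / generations_per_cycle
  tibble::tibble(
    x = mean(per_gen),
    sd = if (length(per_gen) > 1L) sd(per_gen) else NA_real_,
    n_replicates = length(per_gen)
  )
}

#' Full fitness estimation for one barcode assay
#'
#' Runs the complete per-assay chain: log-frequency conversion with count
#' thresholds, contamination-spike exclusion, per-barcode fitness, iterative
#' LLR outlier exclusion per mutation, random combination into cBCs, and
#' re-estimation of fitness on the cBC counts (same thresholds, neutral
#' medians recomputed from the neutral cBCs). Clone-level summaries use the
#' neutral-set standard error of the assay.
#'
#' @param counts Per-assay counts tibble (columns `barcode`, `mutation_id`,
#'   `neutral`, `t1`..`tn`).
#' @param generations_per_cycle Generations per transfer cycle.
#' @param min_total,min_count Count thresholds (see [log_frequencies()]).
#' @param spike_timepoint,spike_delta Contamination-spike heuristic (see
#'   [flag_contamination_spikes()]); `spike_timepoint = NULL` disables it.
#' @param llr_cutoff Outlier LLR cutoff (default 40).
#' @param max_cbcs Maximum cBCs per mutation (default 5).
#' @param seed Seed for the cBC partition (recorded in the result).
#' @param normalize Neutral normalization mode (see [barcode_fitness()]).
#' @return List with `cbc_fitness` (tibble: `mutation_id`, `neutral`,
#'   `cbc_id`, `s`, `n_pairs`, `n_barcodes`), `clone_summary` (tibble:
#'   `mutation_id`, `neutral`, `s`, `sigma_cbc`, `sigma_neut`, `sigma`,
#'   `num_cbcs`), `sigma_neut`, `exclusions` (tibble of lineage-level
#'   exclusions with reasons), and `seed`.
#' @export
assay_fitness <- function(counts, generations_per_cycle = 10,
                          min_total = 5000, min_count = 10,
                          spike_timepoint = 2L, spike_delta = 0.5,
                          llr_cutoff = 40, max_cbcs = 5L, seed = 1L,
                          normalize = "subtract") {
  m <- counts_matrix(counts)
  map <- counts[, c("barcode", "mutation_id", "neutral")]
  lf <- log_frequencies(m, min_total = min_total, min_count = min_count)

  exclusions <- tibble::tibble(barcode = character(0), reason = character(0))
  if (!is.null(spike_timepoint)) {
    spiked <- flag_contamination_spikes(lf, spike_timepoint, spike_delta)
    if (any(spiked)) {
      exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
        barcode = rownames(m)[spiked], reason = "contamination_spike"))
      m <- m[!spiked, , drop = FALSE]
      map <- map[!spiked, , drop = FALSE]
      lf$logf <- lf$logf[!spiked, , drop = FALSE]
    }
  }

  bc_fit <- barcode_fitness(lf, map$neutral, generations_per_cycle,
                            normalize = normalize)
  no_pair <- setdiff(rownames(m), bc_fit$barcode)
  if (length(no_pair)) {
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      barcode = no_pair, reason = "no_valid_pair"))
  }
  measured <- dplyr::inner_join(bc_fit, map, by = "barcode")
  if (nrow(measured) == 0L) {
    stop("no lineage retains a valid consecutive timepoint pair in this assay",
         call. = FALSE)
  }

  # outlier exclusion per mutation, on raw counts
  retained <- character(0)
  for (mut in unique(measured$mutation_id)) {
    bcs <- measured$barcode[measured$mutation_id == mut]
    if (length(bcs) < 2L) {
      retained <- c(retained, bcs)
      next
    }
    res <- exclude_outlier_barcodes(m[bcs, , drop = FALSE], lf, llr_cutoff)
    retained <- c(retained, res$retained)
    if (length(res$excluded)) {
      exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
        barcode = res$excluded, reason = "llr_outlier"))
    }
  }
  measured <- measured[measured$barcode %in% retained, , drop = FALSE]

  # combine into cBCs (seeded), per mutation, then re-measure on cBC counts
  cbc_rows <- list()
  withr::with_seed(seed, {
    for (mut in unique(measured$mutation_id)) {
      bcs <- measured$barcode[measured$mutation_id == mut]
      comb <- combine_barcodes(m[bcs, , drop = FALSE], max_cbcs = max_cbcs,
                               prefix = paste0(mut, ".cbc"))
      cbc_rows[[mut]] <- tibble::tibble(
        barcode = rownames(comb$counts),
        mutation_id = mut,
        neutral = map$neutral[match(mut, map$mutation_id)],
        n_barcodes = lengths(comb$members)[rownames(comb$counts)],
        counts = lapply(seq_len(nrow(comb$counts)), function(i) comb$counts[i, ])
      )
    }
  })
  cbc_tbl <- dplyr::bind_rows(cbc_rows)
  cbc_m <- do.call(rbind, cbc_tbl$counts)
  rownames(cbc_m) <- cbc_tbl$barcode
  colnames(cbc_m) <- colnames(m)

  lf_cbc <- log_frequencies(cbc_m, min_total = min_total, min_count = min_count)
  cbc_fit <- barcode_fitness(lf_cbc, cbc_tbl$neutral, generations_per_cycle,
                             normalize = normalize)
  cbc_fitness <- dplyr::inner_join(
    cbc_fit,
    cbc_tbl[, c("barcode", "mutation_id", "neutral", "n_barcodes")],
    by = "barcode")
  names(cbc_fitness)[names(cbc_fitness) == "barcode"] <- "cbc_id"

  sig_neut <- neutral_sigma(cbc_fitness$s[cbc_fitness$neutral])
  clone_summary <- dplyr::group_by(cbc_fitness, .data$mutation_id, .data$neutral)
  clone_summary <- dplyr::reframe(clone_summary,
                                  clone_mutation_summary(.data$s, sig_neut))
  list(cbc_fitness = cbc_fitness,
       clone_summary = clone_summary,
       sigma_neut = sig_neut,
       exclusions = exclusions,
       seed = seed)
}
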