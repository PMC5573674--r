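#' Scaling scenario: the generating model of a strain panel
#'
#' Bundles the coefficients of both scaling laws and the study-design
#' constants used to generate a synthetic genome-reduction panel. The medium
#' presets carry the regression coefficients of the three growth media:
#' genome-size slope `r` of -14.6 (M63), -10.1 (MAA), -5.1 (LB); growth-rate
#' slope `alpha` of -4.9 (M63), -4.8 (MAA), -2.4 (LB); and mutation capacity
#' `log10_M0` of -6.1 (M63), -4.3 (MAA), -5.4 (LB).
#'
#' The wild-type growth-rate anchor `mu_wt` (1.4, 0.88 and 0.45 1/h in LB,
#' MAA and M63) fixes the genome-size intercept
#' `b = log10_M0 + alpha * mu_wt - r * log10(G_wt)` so that both laws hold
#' simultaneously and strain-wise rates order M63 > MAA > LB, the direction
#' of the nutrition shift. The default panel is a wild type of 4.65 Mb plus
#' nine reduced genomes spanning 4.561 down to 3.62 Mb.
#'
#' @param medium `"M63"`, `"MAA"` or `"LB"` (selects the preset).
#' @param r,alpha,log10_M0 Override the preset coefficients.
#' @param mu_wt Wild-type growth rate anchoring the intercept (1/h).
#' @param genome_sizes_mb Genome sizes, wild type first, descending (Mb).
#' @param noise_sd_log10M Log10-scale sd of per-strain mutation-rate noise.
#' @param noise_sd_mu Sd of per-strain growth-rate noise (1/h).
#' @param n_cultures Parallel cultures per fluctuation assay.
#' @param N_t Final cells per culture at plating.
#' @param target_size_bp Effective mutational target size (bp-equivalents).
#' @param n_growth_replicates Replicate OD curves per strain (the growth
#'   assays were replicated 12-24 times; the generator uses 24).
#' @param seed RNG seed of the scenario.
#' @return A list of class `scaling_scenario`.
#' @export
scaling_scenario <- function(medium = c("M63", "MAA", "LB"), r = NULL,
                             alpha = NULL, log10_M0 = NULL, mu_wt = NULL,
                             genome_sizes_mb = NULL, noise_sd_log10M = 0.1,
                             noise_sd_mu = 0.02, n_cultures = 96,
                             N_t = 1e9, target_size_bp = 1,
                             n_growth_replicates = 24, seed = 1) {
  medium <- match.arg(medium)
  presets <- list(
    M63 = list(r = -14.6, alpha = -4.9, log10_M0 = -6.1, mu_wt = 0.45),
    MAA = list(r = -10.1, alpha = -4.8, log10_M0 = -4.3, mu_wt = 0.88),
    LB  = list(r = -5.1,  alpha = -2.4, log10_M0 = -5.4, mu_wt = 1.4))
  p <- presets[[medium]]
  r <- r %||% p$r
  alpha <- alpha %||% p$alpha
  log10_M0 <- log10_M0 %||% p$log10_M0
  mu_wt <- mu_wt %||% p$mu_wt
  if (alpha == 0) {
    stop("inconsistent presets: alpha = 0 cannot couple the two laws",
         call. = FALSE)
  }
  genome_sizes_mb <- genome_sizes_mb %||%
    c(4.65, seq(4.561, 3.62, length.out = 9))
  stopifnot(all(genome_sizes_mb > 0), !is.unsorted(rev(genome_sizes_mb)),
            noise_sd_log10M >= 0, noise_sd_mu >= 0, n_cultures >= 2,
            N_t > 0, target_size_bp > 0, n_growth_replicates >= 1)
  # b anchors the wild type on both lines simultaneously
  b <- log10_M0 + alpha * mu_wt - r * log10(genome_sizes_mb[1])
  structure(list(medium = medium, r = r, b = b, alpha = alpha,
                 log10_M0 = log10_M0, mu_wt = mu_wt,
                 genome_sizes_mb = genome_sizes_mb,
                 noise_sd_log10M = noise_sd_log10M, noise_sd_mu = noise_sd_mu,
                 n_cultures = n_cultures, N_t = N_t,
                 target_size_bp = target_size_bp,
                 n_growth_replicates = n_growth_replicates, seed = seed),
            class = "scaling_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample mutant counts from the branching fluctuation model
#'
#' Independent brute-force oracle for the Luria-Delbruck distribution:
#' simulates synchronous binary divisions over `n_generations` starting from
#' one cell. Mutations in generation `g` arise as Poisson with mean
#' proportional to the `2^(g-1)` divisions of that generation (normalised so
#' the expected total is `m`), and a generation-`g` mutation is carried by
#' `2^(n_generations - g)` final mutants. Jackpot cultures arise naturally.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param n_cultures Number of parallel cultures to simulate.
#' @param seed RNG seed; `NULL` uses the current RNG state (for callers that
#'   manage their own stream).
#' @param n_generations Number of synchronous doublings.
#' @return Numeric vector of `n_cultures` mutant counts.
#' @examples
#' mean(sample_ld_counts(1, 1e4, seed = 1) == 0)  # about exp(-1)
#' @export
sample_ld_counts <- function(m, n_cultures, seed = NULL,
                             n_generations = 20) {
  stopifnot(m >= 0, n_cultures >= 1, n_generations >= 1)
  draw <- function() {
    counts <- numeric(n_cultures)
    if (m == 0) return(counts)
    g <- seq_len(n_generations)
    lambda <- m * 2^(g - 1) / (2^n_generations - 1)
    for (gg in g) {
      counts <- counts + rpois(n_cultures, lambda[gg]) *
        2^(n_generations - gg)
    }
    counts
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a logistic OD600 growth curve with reader noise
#'
#' `OD(t) = K * od0 * exp(mu t) / (K + od0 * (exp(mu t) - 1))` sampled on a
#' regular grid, plus Gaussian reader noise truncated below at an OD floor.
#' `carrying_capacity = Inf` gives the pure exponential limit.
#'
#' @param mu Growth rate (1/h, >= 0).
#' @param od0 Inoculation OD600.
#' @param carrying_capacity Saturating OD600 (`K`).
#' @param dt_h Sampling interval (hours).
#' @param horizon_h Last sampling time (hours).
#' @param noise_sd Sd of additive reader noise (OD units).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param floor Lower truncation of noisy readings.
#' @return A [growth_curve()] (medium slot set to `"M63"` by default use;
#'   the curve itself is medium-agnostic).
#' @export
gen_growth_curve <- function(mu, od0 = 0.001, carrying_capacity = 1.0,
                             dt_h = 0.25, horizon_h = 16, noise_sd = 0.003,
                             seed = NULL, floor = 1e-4) {
  stopifnot(mu >= 0, od0 > 0, dt_h > 0, horizon_h >= dt_h, noise_sd >= 0)
  t <- seq(0, horizon_h, by = dt_h)
  K <- carrying_capacity
  od <- if (is.infinite(K)) {
    od0 * exp(mu * t)
  } else {
    K * od0 * exp(mu * t) / (K + od0 * (exp(mu * t) - 1))
  }
  add_noise <- function() pmax(od + rnorm(length(od), 0, noise_sd), floor)
  od <- if (noise_sd == 0) pmax(od, floor) else
    if (is.null(seed)) add_noise() else withr::with_seed(seed, add_noise())
  growth_curve(times = t, od = od)
}

#' Generate a synthetic genome-reduction strain panel
#'
#' Draws, for every strain of the scenario, a true mutation rate on the
#' genome-size law (`log10 M = r log10 G + b` plus log-normal strain noise)
#' and the matching true growth rate from the growth-rate law
#' (`mu = (log10 M - log10_M0)/alpha` plus Gaussian noise), so both laws and
#' the genome-size/growth-rate correlation hold simultaneously. It then
#' emits the raw observables: fluctuation mutant counts via
#' [sample_ld_counts()] with `m = M * N_t * target_size_bp`, and replicate
#' logistic OD curves via [gen_growth_curve()] (horizon extended for slow
#' strains so the exponential window is sampled).
#'
#' All output is a pure function of the scenario (including its seed).
#'
#' @param scenario A [scaling_scenario()].
#' @return List of class `strain_panel` with: `observations` (tibble of true
#'   per-strain values: `strain_id`, `medium`, `genome_size_mb`,
#'   `mutation_rate`, `growth_rate`, `m_per_culture`), `counts` (long tibble
#'   `strain_id`, `medium`, `culture_id`, `mutant_count`), `curves` (long
#'   tibble `strain_id`, `medium`, `replicate`, `time_h`, `od600`) and the
#'   `scenario`.
#' @export
gen_strain_panel <- function(scenario) {
  stopifnot(inherits(scenario, "scaling_scenario"))
  sc <- scenario
  n <- length(sc$genome_sizes_mb)
  ids <- sprintf("strain_%02d", seq_len(n) - 1)
  withr::with_seed(sc$seed, {
    log10M <- sc$r * log10(sc$genome_sizes_mb) + sc$b +
      rnorm(n, 0, sc$noise_sd_log10M)
    mu <- (log10M - sc$log10_M0) / sc$alpha + rnorm(n, 0, sc$noise_sd_mu)
    if (any(mu <= 0)) {
      stop("scenario yields non-positive growth rates; raise mu_wt or ",
           "reduce noise", call. = FALSE)
    }
    M <- 10^log10M
    m_pc <- M * sc$N_t * sc$target_size_bp
    counts <- lapply(seq_len(n), function(i) {
      tibble::tibble(strain_id = ids[i], medium = sc$medium,
                     culture_id = seq_len(sc$n_cultures),
                     mutant_count = sample_ld_counts(m_pc[i], sc$n_cultures))
    })
    curves <- lapply(seq_len(n), function(i) {
      horizon <- max(16, ceiling(6.5 / mu[i] / 0.25) * 0.25)
      reps <- lapply(seq_len(sc$n_growth_replicates), function(rep) {
        cv <- gen_growth_curve(mu[i], horizon_h = horizon)
        tibble::tibble(strain_id = ids[i], medium = sc$medium,
                       replicate = rep, time_h = cv$times, od600 = cv$od)
      })
      dplyr::bind_rows(reps)
    })
    structure(
      list(observations = tibble::tibble(
             strain_id = ids, medium = sc$medium,
             genome_size_mb = sc$genome_sizes_mb,
             mutation_rate = M, growth_rate = mu, m_per_culture = m_pc),
           counts = dplyr::bind_rows(counts),
           curves = dplyr::bind_rows(curves),
           scenario = sc),
      class = "strain_panel")
  })
}

#' Estimate strain observations from a panel's raw observables
#'
#' The estimation bridge from raw synthetic (or real, identically shaped)
#' data to the row type the scaling fits consume: per strain, the
#' mutations-per-culture MLE ([estimate_m_mle()]) converted to a per-bp rate
#' with the panel's `N_t` and target size, and the growth rate as the mean
#' [growth_rate()] over replicate curves.
#'
#' The growth fits use a wide window by default (`min_frac = 0.7` of the
#' readings inside `od_range = [0.02, 0.2]`): under plate-reader noise,
#' max-slope selection over many short windows is upward-biased, and the
#' bottom decade of OD carries mostly noise.
#'
#' @param panel A [gen_strain_panel()] result.
#' @param od_range,min_frac,min_points Growth-window settings (see
#'   [growth_rate()]).
#' @param n_max Truncation cap for the mutation MLE.
#' @param compute_ci Compute likelihood-ratio CIs per strain (slower).
#' @return Tibble with one row per strain: `strain_id`, `medium`,
#'   `genome_size_mb`, `mutation_rate`, `growth_rate` (estimated values),
#'   plus `m_hat` and `mu_r2`.
#' @export
analyze_strain_panel <- function(panel, od_range = c(0.02, 0.2),
                                 min_frac = 0.7, min_points = 5,
                                 n_max = 10000, compute_ci = FALSE) {
  stopifnot(inherits(panel, "strain_panel"))
  sc <- panel$scenario
  obs <- panel$observations
  rows <- lapply(seq_len(nrow(obs)), function(i) {
    id <- obs$strain_id[i]
    cts <- panel$counts$mutant_count[panel$counts$strain_id == id]
    est <- estimate_m_mle(cts, n_max = n_max, compute_ci = compute_ci)
    M <- mutation_rate_per_bp(est$m_hat, sc$N_t, sc$target_size_bp)
    cv <- panel$curves[panel$curves$strain_id == id, , drop = FALSE]
    fits <- lapply(split(cv, cv$replicate), function(d) {
      growth_rate(growth_curve(times = d$time_h, od = d$od600),
                  min_points = min_points, od_range = od_range,
                  min_frac = min_frac)
    })
    tibble::tibble(strain_id = id, medium = obs$medium[i],
                   genome_size_mb = obs$genome_size_mb[i],
                   mutation_rate = M,
                   growth_rate = mean(vapply(fits, `[[`, numeric(1), "mu")),
                   m_hat = est$m_hat,
                   mu_r2 = mean(vapply(fits, `[[`, numeric(1), "r2")))
  })
  dplyr::bind_rows(rows)
}

#' Generate a nested deleted-gene table over 23 categories
#'
#' Emulates the structure of a cumulative genome-reduction deletion table:
#' each reduced genome contains all of its predecessor's deletions plus new
#' ones. Category totals are calibrated so that exactly `n_major` of the 23
#' categories exceed 10 cumulative deletions in the most-reduced strain
#' (major categories receive `11 + Poisson` extra genes, the remainder at
#' most 10), matching the 14-of-23 retention of the strict
#' more-than-10-deletions filter.
#'
#' @param n_strains Length of the series including the wild type.
#' @param seed RNG seed.
#' @param categories Category vocabulary (23 codes).
#' @param n_major Number of categories that must pass the >10 filter.
#' @return List of class `deletion_table_sim` with `records` (tibble
#'   `strain_id`, `gene_id`, `category`: the new deletions of each reduced
#'   strain), `series_order`, and `total_genes_per_category`.
#' @export
gen_gene_category_table <- function(n_strains = 10, seed = 1,
                                    categories = gene_categories(),
                                    n_major = 14) {
  stopifnot(n_strains >= 2, n_major <= length(categories))
  series <- sprintf("strain_%02d", seq_len(n_strains) - 1)
  reduced <- series[-1]
  withr::with_seed(seed, {
    major <- sample(categories, n_major)
    totals <- stats::setNames(integer(length(categories)), categories)
    totals[major] <- 11 + rpois(n_major, 25)
    minor <- setdiff(categories, major)
    totals[minor] <- pmin(rpois(length(minor), 4), 10)
    recs <- list()
    gene_counter <- 0
    for (ct in categories) {
      tot <- totals[[ct]]
      if (tot == 0) next
      # spread the category's deletions across the reduced strains
      alloc <- tabulate(sample.int(length(reduced), tot, replace = TRUE),
                        nbins = length(reduced))
      for (si in seq_along(reduced)) {
        if (alloc[si] == 0) next
        ids <- sprintf("gene_%05d", gene_counter + seq_len(alloc[si]))
        gene_counter <- gene_counter + alloc[si]
        recs[[length(recs) + 1]] <- tibble::tibble(
          strain_id = reduced[si], gene_id = ids, category = ct)
      }
    }
    records <- dplyr::bind_rows(recs)
    structure(list(records = records, series_order = series,
                   total_genes_per_category = totals + 5 + rpois(
                     length(categories), 40)),
              class = "deletion_table_sim")
  })
}

#' Generate a log-expression matrix with planted growth correlations
#'
#' Emulates a compendium of expression profiles with known per-sample growth
#' rates: each planted gene's log expression is constructed with a specified
#' population correlation to the drawn growth-rate vector; unplanted genes
#' are uncorrelated. Per-sample offsets make raw column means differ, so the
#' matrix exercises global normalization. The default planted genes carry
#' the mismatch-repair-like correlations 0.39 (`mutL`), -0.06 (`mutH`) and
#' -0.26 (`mutS`).
#'
#' @param n_genes Number of background genes.
#' @param n_samples Number of samples (profiles), default 75.
#' @param planted Named numeric vector of target correlations in `[-1, 1]`.
#' @param seed RNG seed.
#' @return List with `expression` (matrix, genes x samples), `growth`
#'   (per-sample rates, 1/h) and `planted`.
#' @export
gen_expression_table <- function(n_genes = 100, n_samples = 75,
                                 planted = c(mutL = 0.39, mutH = -0.06,
                                             mutS = -0.26), seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 3)
  if (any(abs(planted) > 1)) {
    stop("planted correlations must lie in [-1, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    growth <- pmax(rnorm(n_samples, 0.5, 0.15), 0.05)
    z_mu <- as.numeric(scale(growth))
    gene_ids <- c(names(planted), sprintf("gene_%04d", seq_len(n_genes)))
    expr <- matrix(0, length(gene_ids), n_samples,
                   dimnames = list(gene_ids, sprintf("sample_%02d",
                                                     seq_len(n_samples))))
    for (i in seq_along(planted)) {
      rho <- planted[[i]]
      expr[i, ] <- 8 + rho * z_mu + sqrt(1 - rho^2) * rnorm(n_samples)
    }
    for (i in seq_len(n_genes)) {
      expr[length(planted) + i, ] <- rnorm(n_samples, 8, 1)
    }
    # per-sample offsets: unequal raw column means, removed by normalization
    expr <- sweep(expr, 2, rnorm(n_samples, 0, 0.3), `+`)
    list(expression = expr, growth = growth, planted = planted)
  })
}
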