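#' Mutant-count sample from a fluctuation assay
#'
#' Bundles the mutant colony counts observed across parallel cultures of one
#' strain in one growth medium -- the observable of a Luria-Delbruck
#' fluctuation test.
#'
#' @param strain_id Strain identifier.
#' @param medium Growth medium, one of `"LB"`, `"MAA"`, `"M63"`.
#' @param counts Integer vector of mutant colonies per parallel culture
#'   (length >= 2, all non-negative).
#' @return An object of class `mutant_count_sample` with fields `strain_id`,
#'   `medium`, `counts` and `n_cultures`.
#' @examples
#' s <- mutant_count_sample("wt", "M63", c(0, 1, 0, 5, 0, 2))
#' s$n_cultures
#' @export
mutant_count_sample <- function(strain_id, medium = c("LB", "MAA", "M63"),
                                counts) {
  medium <- match.arg(medium)
  counts <- check_counts(counts)
  if (length(counts) < 2) {
    stop("a fluctuation sample needs at least 2 parallel cultures",
         call. = FALSE)
  }
  structure(
    list(strain_id = as.character(strain_id), medium = medium,
         counts = counts, n_cultures = length(counts)),
    class = "mutant_count_sample"
  )
}

check_counts <- function(counts) {
  if (!is.numeric(counts) || anyNA(counts)) {
    stop("counts must be numeric and free of NA", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  as.numeric(counts)
}

as_counts <- function(sample) {
  if (inherits(sample, "mutant_count_sample")) return(sample$counts)
  check_counts(sample)
}

#' Set of selective-plate colony counts for a CFU assay
#'
#' @param colony_counts Integer vector of colonies per plate (the assay used
#'   9 to 12 plates per culture).
#' @param dilution_factor Fold dilution applied before plating (> 0).
#' @param plated_volume_ml Volume plated per plate in ml (> 0).
#' @return An object of class `plate_count_set`.
#' @seealso [cfu_from_plates()]
#' @export
plate_count_set <- function(colony_counts, dilution_factor = 1,
                            plated_volume_ml = 1) {
  colony_counts <- check_counts(colony_counts)
  if (length(colony_counts) < 1) stop("need at least one plate", call. = FALSE)
  stopifnot(dilution_factor > 0, plated_volume_ml > 0)
  structure(
    list(colony_counts = colony_counts, dilution_factor = dilution_factor,
         plated_volume_ml = plated_volume_ml),
    class = "plate_count_set"
  )
}

#' Lea-Coulson distribution of mutant counts
#'
#' Computes `p0 .. p_nmax` of the Luria-Delbruck mutant-count distribution in
#' the Lea-Coulson parameterisation by the MSS recursion
#' `p0 = exp(-m)`, `p_n = (m/n) * sum_{k<n} p_k / (n - k + 1)`,
#' where `m` is the expected number of mutational events per culture.
#'
#' @param m Expected mutations per culture (>= 0).
#' @param n_max Largest count for which the pmf is returned.
#' @return An object of class `ld_distribution`: a list with `m`, `n_max` and
#'   `pmf` (numeric vector of length `n_max + 1`, `pmf[n + 1] == p_n`).
#' @examples
#' d <- ld_pmf(1, 5)
#' d$pmf[1]  # exp(-1)
#' @export
ld_pmf <- function(m, n_max) {
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 0) {
    stop("m must be a single non-negative number", call. = FALSE)
  }
  n_max <- as.integer(n_max)
  stopifnot(n_max >= 0)
  structure(list(m = m, n_max = n_max, pmf = .ld_pmf_c(m, n_max)),
            class = "ld_distribution")
}

#' P0 estimator of mutations per culture
#'
#' Classical zero-class estimator: inverts `p0 = exp(-m)` to
#' `m = -log(fraction of cultures with zero mutants)`. Usable only when at
#' least one culture has no mutants; serves as a fallback and as a diagnostic
#' cross-check of the maximum-likelihood estimate.
#'
#' @param sample A [mutant_count_sample()] or a raw integer vector of counts.
#' @return The estimate of `m` (a single non-negative number).
#' @export
estimate_m_p0 <- function(sample) {
  counts <- as_counts(sample)
  n0 <- sum(counts == 0)
  if (n0 == 0) {
    stop("P0 inapplicable: no culture has zero mutants", call. = FALSE)
  }
  -log(n0 / length(counts))
}

#' Maximum-likelihood estimate of mutations per culture
#'
#' Fits the Lea-Coulson distribution ([ld_pmf()]) to the observed mutant
#' counts by one-dimensional maximisation of the log-likelihood over `log(m)`,
#' with an explicit boundary at `m = 0` (all-zero samples). The confidence
#' interval is the likelihood-ratio interval (chi-squared, 1 df), which
#' behaves sensibly when the estimate is near the zero boundary.
#'
#' Counts at or above the truncation cap `n_max` are binned into a final
#' `>= n_max` tail cell with probability `1 - sum(pmf)` (jackpot cultures are
#' expected under this distribution). Set `tail_bin = FALSE` to instead treat
#' such counts as an error.
#'
#' @param sample A [mutant_count_sample()] or raw count vector (length >= 2).
#' @param ci_level Confidence level of the likelihood-ratio interval.
#' @param n_max Truncation cap of the pmf used by the likelihood.
#' @param compute_ci Compute the likelihood-ratio CI (adds likelihood
#'   evaluations; can be disabled for bulk point estimation).
#' @param tail_bin Bin counts `>= n_max` into the tail cell (default) instead
#'   of signalling an error.
#' @return An object of class `rate_estimate`: list with `m_hat`, `ci_low`,
#'   `ci_high`, `ci_level`, `loglik`, `n_cultures` and `boundary` (TRUE when
#'   the estimate sits at `m = 0`).
#' @examples
#' counts <- sample_ld_counts(m = 1, n_cultures = 200, seed = 1)
#' estimate_m_mle(counts)$m_hat
#' @export
estimate_m_mle <- function(sample, ci_level = 0.95, n_max = 10000,
                           compute_ci = TRUE, tail_bin = TRUE) {
  counts <- as_counts(sample)
  if (length(counts) < 2) {
    stop("need at least 2 parallel cultures", call. = FALSE)
  }
  if (!tail_bin && any(counts > n_max)) {
    stop("truncation limit exceeded: counts above n_max = ", n_max,
         "; raise the cap (n_max) or enable tail binning", call. = FALSE)
  }
  n <- length(counts)
  capped <- as.integer(pmin(counts, n_max))

  if (all(counts == 0)) {
    # boundary: ll(m) = -n * m, maximised at 0
    ci_high <- if (compute_ci) qchisq(ci_level, 1) / (2 * n) else NA_real_
    return(new_rate_estimate(0, 0, ci_high, ci_level, 0, n, boundary = TRUE))
  }

  ll <- function(m) .ld_loglik_c(m, capped, as.integer(n_max))
  hi <- log(2 * max(counts) + 2)
  opt <- optimize(function(lm) ll(exp(lm)), interval = c(log(1e-4), hi),
                  maximum = TRUE, tol = 1e-4)
  m_hat <- exp(opt$maximum)
  ll_hat <- opt$objective

  ci_low <- ci_high <- NA_real_
  if (compute_ci) {
    drop <- qchisq(ci_level, 1) / 2
    g <- function(m) ll_hat - ll(m) - drop
    # lower bound: g(m_hat) < 0, g -> +Inf as m -> 0 unless 0 is in the CI
    if (ll_hat - ll(1e-8) < drop) {
      ci_low <- 0
    } else {
      ci_low <- uniroot(g, c(1e-8, m_hat), tol = m_hat * 1e-4)$root
    }
    up <- m_hat * 2
    while (g(up) < 0 && up < exp(hi) * 10) up <- up * 2
    ci_high <- uniroot(g, c(m_hat, up), tol = m_hat * 1e-4)$root
  }
  new_rate_estimate(m_hat, ci_low, ci_high, ci_level, ll_hat, n,
                    boundary = FALSE)
}

new_rate_estimate <- function(m_hat, ci_low, ci_high, ci_level, loglik,
                              n_cultures, boundary) {
  structure(
    list(m_hat = m_hat, ci_low = ci_low, ci_high = ci_high,
         ci_level = ci_level, loglik = loglik, n_cultures = n_cultures,
         boundary = boundary),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Lea-Coulson MLE: m = %.4g [%.4g, %.4g] (%d cultures)\n",
              x$m_hat, x$ci_low, x$ci_high, x$n_cultures))
  invisible(x)
}

#' Cell density from selective-free plate counts
#'
#' Averages the reliable plate counts -- those in the closed interval
#' `[10, 500]` colonies per plate, the range treated as countable in the CFU
#' protocol -- and converts to cells per ml using the dilution factor and
#' plated volume.
#'
#' @param plates A [plate_count_set()].
#' @param reliable_range Closed interval of countable colonies per plate.
#' @return A list of class `cfu_estimate` with `cells_per_ml`, `n_reliable`
#'   (plates passing the filter) and `reliable_counts`.
#' @examples
#' p <- plate_count_set(c(8, 52, 187, 540), dilution_factor = 1e6,
#'                      plated_volume_ml = 0.1)
#' cfu_from_plates(p)$cells_per_ml
#' @export
cfu_from_plates <- function(plates, reliable_range = c(10, 500)) {
  stopifnot(inherits(plates, "plate_count_set"))
  ok <- plates$colony_counts >= reliable_range[1] &
    plates$colony_counts <= reliable_range[2]
  if (!any(ok)) {
    stop("no countable plates: all counts outside [",
         reliable_range[1], ", ", reliable_range[2], "]", call. = FALSE)
  }
  reliable <- plates$colony_counts[ok]
  structure(
    list(cells_per_ml = mean(reliable) * plates$dilution_factor /
           plates$plated_volume_ml,
         n_reliable = length(reliable), reliable_counts = reliable),
    class = "cfu_estimate"
  )
}

#' Per-base-pair, per-division mutation rate
#'
#' Converts a mutations-per-culture estimate into the mutation rate
#' `M = m_hat / (N_t * target_size_bp)`, the per-bp per-division rate used by
#' both scaling laws. The effective target size of the selectable phenotype
#' defaults to 1 bp-equivalent, i.e. a per-target rate.
#'
#' @param m_hat Estimated mutations per culture (>= 0).
#' @param N_t Final number of cells per culture at plating (> 0).
#' @param target_size_bp Effective mutational target size in bp (> 0).
#' @return The mutation rate `M` (single number).
#' @export
mutation_rate_per_bp <- function(m_hat, N_t, target_size_bp = 1) {
  if (!is.numeric(m_hat) || any(m_hat < 0)) {
    stop("m_hat must be non-negative", call. = FALSE)
  }
  if (!is.numeric(N_t) || any(N_t <= 0)) {
    stop("N_t must be positive", call. = FALSE)
  }
  if (!is.numeric(target_size_bp) || any(target_size_bp <= 0)) {
    stop("target_size_bp must be positive", call. = FALSE)
  }
  m_hat / (N_t * target_size_bp)
}
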