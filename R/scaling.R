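#' Spearman rank correlation (mid-ranks)
#'
#' Pearson product-moment correlation of mid-ranks, averaging ranks over
#' ties. Returns `NA` with a warning when either argument has zero rank
#' variance (correlation undefined).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A single correlation in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' spearman_rho(1:5, 5:1)          # -1
#' spearman_rho(c(1, 2, 3), c(2, 2, 3))
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("spearman rho undefined: zero rank variance", call. = FALSE)
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper that flags the zero-variance (undefined) case with
#' `NA` and a warning instead of propagating `NaN`.
#'
#' @inheritParams spearman_rho
#' @return A single correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("pearson r undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)
}

# all permutations of 1..n as a matrix (n! rows); used for exact tests, n <= 8
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[pos] <- n
      perm[-pos] <- sub[r, ]
      out[row, ] <- perm
      row <- row + 1
    }
  }
  out
}

#' Permutation p-value for a correlation statistic
#'
#' Permutes `y` against `x`. For `n <= 8` every one of the `n!` permutations
#' is enumerated and the p-value is the exact fraction; for larger `n` a
#' seeded Monte-Carlo sample of `n_perm` permutations is drawn and the
#' add-one corrected estimate `(b + 1) / (n_perm + 1)` is returned, which also
#' floors the p-value at `1 / (n_perm + 1)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param statistic `"spearman"` (mid-rank) or `"pearson"`.
#' @param n_perm Number of Monte-Carlo permutations (ignored when exact).
#' @param seed RNG seed for the Monte-Carlo branch.
#' @param alternative `"two-sided"` (on `|statistic|`), `"less"` or
#'   `"greater"`.
#' @return A single p-value in `(0, 1]`.
#' @examples
#' permutation_pvalue(1:3, 1:3, "spearman", alternative = "greater")  # 1/6
#' @export
permutation_pvalue <- function(x, y, statistic = c("spearman", "pearson"),
                               n_perm = 10000, seed = 1,
                               alternative = c("two-sided", "less",
                                               "greater")) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y), n_perm >= 1)
  n <- length(x)
  stat_fun <- if (statistic == "spearman") {
    function(a, b) suppressWarnings(spearman_rho(a, b))
  } else {
    function(a, b) suppressWarnings(pearson_r(a, b))
  }
  obs <- stat_fun(x, y)
  if (is.na(obs)) return(NA_real_)
  eps <- 1e-12
  tail_count <- function(stats) {
    switch(alternative,
           "two-sided" = sum(abs(stats) >= abs(obs) - eps, na.rm = TRUE),
           "greater"   = sum(stats >= obs - eps, na.rm = TRUE),
           "less"      = sum(stats <= obs + eps, na.rm = TRUE))
  }
  if (n <= 8) {
    perms <- all_permutations(n)
    stats <- apply(perms, 1, function(p) stat_fun(x, y[p]))
    tail_count(stats) / nrow(perms)
  } else {
    stats <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) stat_fun(x, sample(y)), numeric(1))
    })
    (tail_count(stats) + 1) / (n_perm + 1)
  }
}

check_obs <- function(obs, cols) {
  stopifnot(is.data.frame(obs))
  missing <- setdiff(cols, names(obs))
  if (length(missing) > 0) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if ("medium" %in% names(obs) && length(unique(obs$medium)) > 1) {
    stop("observations mix media; fit one medium at a time", call. = FALSE)
  }
  if (nrow(obs) < 3) stop("insufficient observations (< 3)", call. = FALSE)
  obs
}

#' Fit the genome-size scaling law of the mutation rate
#'
#' Ordinary least squares of `log10(M)` on `log10(G)`:
#' `log10(M_i) = r * log10(G_i) + b`, where `M_i` is the mutation rate
#' (per bp per division) and `G_i` the genome size in Mb. A Spearman rank
#' correlation between `M` and `G` with a permutation p-value is attached.
#'
#' @param obs Data frame of strain observations with columns
#'   `genome_size_mb` and `mutation_rate` (and optionally a single-valued
#'   `medium`); one row per strain.
#' @param n_perm,seed,alternative Passed to [permutation_pvalue()].
#' @return An object of class `genome_scaling_fit`: list with `r` (slope),
#'   `b` (intercept), `r2`, `spearman_rho`, `p_value`, `rho_flagged`, `n`.
#' @export
fit_genome_scaling <- function(obs, n_perm = 10000, seed = 1,
                               alternative = "two-sided") {
  obs <- check_obs(obs, c("genome_size_mb", "mutation_rate"))
  stopifnot(all(obs$genome_size_mb > 0), all(obs$mutation_rate > 0))
  lx <- log10(obs$genome_size_mb)
  ly <- log10(obs$mutation_rate)
  fit <- lm(ly ~ lx)
  rho <- suppressWarnings(spearman_rho(obs$mutation_rate, obs$genome_size_mb))
  flagged <- is.na(rho)
  p <- if (flagged) NA_real_ else {
    permutation_pvalue(obs$genome_size_mb, obs$mutation_rate, "spearman",
                       n_perm = n_perm, seed = seed,
                       alternative = alternative)
  }
  structure(
    list(r = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r2 = summary(fit)$r.squared,
         spearman_rho = if (flagged) 0 else rho,
         p_value = p, rho_flagged = flagged, n = nrow(obs)),
    class = "genome_scaling_fit"
  )
}

#' Fit the growth-rate scaling law of the mutation rate
#'
#' Ordinary least squares of `log10(M)` on the growth rate `mu` (1/h):
#' `log10(M_i) = log10(M0) + alpha * mu_i`. The intercept is the mutation
#' capacity: `M0`, the extrapolated mutation rate at zero growth, is reported
#' both as `log10_M0` and as `M0 = 10^log10_M0`.
#'
#' @param obs Data frame with columns `growth_rate` and `mutation_rate`
#'   (single medium); one row per strain.
#' @inheritParams fit_genome_scaling
#' @return An object of class `growth_mutation_fit`: list with `alpha`,
#'   `log10_M0`, `M0`, `r2`, `spearman_rho`, `p_value`, `rho_flagged`, `n`.
#' @export
fit_growth_mutation <- function(obs, n_perm = 10000, seed = 1,
                                alternative = "two-sided") {
  obs <- check_obs(obs, c("growth_rate", "mutation_rate"))
  stopifnot(all(obs$mutation_rate > 0))
  if (sd(obs$growth_rate) == 0) {
    stop("degenerate predictor: growth rate constant across observations",
         call. = FALSE)
  }
  ly <- log10(obs$mutation_rate)
  fit <- lm(ly ~ obs$growth_rate)
  rho <- suppressWarnings(spearman_rho(obs$mutation_rate, obs$growth_rate))
  flagged <- is.na(rho)
  p <- if (flagged) NA_real_ else {
    permutation_pvalue(obs$growth_rate, obs$mutation_rate, "spearman",
                       n_perm = n_perm, seed = seed,
                       alternative = alternative)
  }
  icpt <- unname(coef(fit)[1])
  structure(
    list(alpha = unname(coef(fit)[2]), log10_M0 = icpt, M0 = 10^icpt,
         r2 = summary(fit)$r.squared,
         spearman_rho = if (flagged) 0 else rho,
         p_value = p, rho_flagged = flagged, n = nrow(obs)),
    class = "growth_mutation_fit"
  )
}

#' @export
print.genome_scaling_fit <- function(x, ...) {
  cat(sprintf(
    "log10(M) = %.3f * log10(G) + %.3f  (r2 = %.3f, rho = %.3f, p = %.3g)\n",
    x$r, x$b, x$r2, x$spearman_rho, x$p_value))
  invisible(x)
}

#' @export
print.growth_mutation_fit <- function(x, ...) {
  cat(sprintf(
    "log10(M) = %.3f + %.3f * mu  (M0 = %.3g, r2 = %.3f, rho = %.3f, p = %.3g)\n",
    x$log10_M0, x$alpha, x$M0, x$r2, x$spearman_rho, x$p_value))
  invisible(x)
}

#' Paired test for a mutation-rate shift between media
#'
#' Exact one-sided Wilcoxon signed-rank test on paired `log10` mutation
#' rates, testing whether rates in the poorer medium are shifted above those
#' in the richer medium for the same strains. Strains with identical rates in
#' both media drop out (signed-rank convention); if all pairs are ties the
#' test is flagged and `p = 1`.
#'
#' @param rates_poor,rates_rich Positive mutation rates in the two media,
#'   paired by strain (equal length >= 5).
#' @param alternative Passed to [stats::wilcox.test()]; default `"greater"`
#'   (poorer medium above richer).
#' @return List of class `media_shift_test` with `p_value`, `direction`
#'   (median paired log10 difference), `n_pairs`, `n_nonzero`, `flagged`.
#' @export
media_shift_test <- function(rates_poor, rates_rich,
                             alternative = "greater") {
  stopifnot(length(rates_poor) == length(rates_rich),
            length(rates_poor) >= 5,
            all(rates_poor > 0), all(rates_rich > 0))
  d <- log10(rates_poor) - log10(rates_rich)
  nz <- d != 0
  if (!any(nz)) {
    return(structure(list(p_value = 1, direction = 0,
                          n_pairs = length(d), n_nonzero = 0L,
                          flagged = TRUE),
                     class = "media_shift_test"))
  }
  wt <- suppressWarnings(
    wilcox.test(d[nz], alternative = alternative, exact = TRUE)
  )
  structure(
    list(p_value = unname(wt$p.value), direction = stats::median(d),
         n_pairs = length(d), n_nonzero = sum(nz), flagged = FALSE),
    class = "media_shift_test"
  )
}

#' @export
print.media_shift_test <- function(x, ...) {
  cat(sprintf(
    "media shift: p = %.4g (%d/%d informative pairs, median shift %.3f log10)\n",
    x$p_value, x$n_nonzero, x$n_pairs, x$direction))
  invisible(x)
}
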