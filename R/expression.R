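#' Global normalization of a log-expression matrix
#'
#' Shifts every sample column additively so that all column means equal the
#' grand mean of the input (global normalization of logarithmic values).
#' When `replicate_groups` is supplied, biological replicate columns of the
#' same condition are then averaged into one representative column per
#' condition.
#'
#' @param log_expr Numeric genes x samples matrix of log-scale expression,
#'   finite throughout.
#' @param replicate_groups Optional vector (length `ncol(log_expr)`) labelling
#'   replicate columns of the same condition.
#' @return The normalized matrix; columns are conditions when
#'   `replicate_groups` is given, samples otherwise.
#' @export
normalize_expression <- function(log_expr, replicate_groups = NULL) {
  log_expr <- as.matrix(log_expr)
  if (!all(is.finite(log_expr))) {
    stop("expression matrix must be finite", call. = FALSE)
  }
  grand <- mean(log_expr)
  shifted <- sweep(log_expr, 2, colMeans(log_expr) - grand)
  if (is.null(replicate_groups)) return(shifted)
  stopifnot(length(replicate_groups) == ncol(shifted))
  groups <- unique(replicate_groups)
  out <- vapply(groups, function(g) {
    rowMeans(shifted[, replicate_groups == g, drop = FALSE])
  }, numeric(nrow(shifted)))
  colnames(out) <- as.character(groups)
  rownames(out) <- rownames(log_expr)
  out
}

#' Correlate gene expression with growth rate
#'
#' Pearson correlation between each gene's log expression profile and the
#' per-sample growth rates, with a seeded permutation p-value (the growth
#' vector is permuted once per draw and reused across genes). Genes with
#' constant expression have undefined correlation and are flagged.
#'
#' @param expr Normalized genes x samples log-expression matrix (see
#'   [normalize_expression()]); row names identify genes.
#' @param growth Growth rates (1/h), one per sample column.
#' @param n_perm Number of permutations for the p-values.
#' @param seed RNG seed for the permutations.
#' @param alternative `"two-sided"`, `"less"` or `"greater"`.
#' @return A tibble with one row per gene: `gene`, `r`, `p_value`, `flagged`.
#' @export
correlate_expression_growth <- function(expr, growth, n_perm = 1000,
                                        seed = 1,
                                        alternative = c("two-sided", "less",
                                                        "greater")) {
  alternative <- match.arg(alternative)
  expr <- as.matrix(expr)
  stopifnot(ncol(expr) == length(growth), n_perm >= 1)
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("gene_", seq_len(nrow(expr)))
  n <- length(growth)
  gene_sd <- apply(expr, 1, sd)
  flagged <- gene_sd == 0 | sd(growth) == 0
  r <- rep(NA_real_, nrow(expr))
  p <- rep(NA_real_, nrow(expr))
  ok <- !flagged
  if (any(ok)) {
    z_expr <- t(scale(t(expr[ok, , drop = FALSE])))  # row-standardized
    z_mu <- as.numeric(scale(growth))
    r_ok <- as.numeric(z_expr %*% z_mu) / (n - 1)
    # permutation null: same permuted growth vector applied to every gene
    perm_z <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) sample(z_mu), numeric(n))
    })
    r_null <- (z_expr %*% perm_z) / (n - 1)  # genes x n_perm
    eps <- 1e-12
    b <- switch(alternative,
                "two-sided" = rowSums(abs(r_null) >= abs(r_ok) - eps),
                "greater"   = rowSums(r_null >= r_ok - eps),
                "less"      = rowSums(r_null <= r_ok + eps))
    r[ok] <- r_ok
    p[ok] <- (b + 1) / (n_perm + 1)
  }
  tibble::tibble(gene = genes, r = r, p_value = p, flagged = flagged)
}
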