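#' Default 23-code gene-category vocabulary
#'
#' Functional category codes in the style of the 23-class Riley annotation of
#' the E. coli genome, including the transporter (`t`), predicted transporter
#' (`pt`), predicted membrane (`pm`) and partial-information (`d`) classes.
#' The vocabulary is configuration, not hard-coded biology: supply your own
#' 23 codes to the table constructors to match a different annotation.
#'
#' @return Character vector of 23 category codes.
#' @export
gene_categories <- function() {
  c("c", "ce", "cp", "d", "e", "f", "h", "l", "lp", "m", "o", "pc", "pd",
    "pe", "pf", "ph", "pl", "pm", "pr", "pt", "r", "s", "t")
}

#' Cumulative deleted-gene counts per category along a reduction series
#'
#' Counts, for every strain of an ordered genome-reduction series (wild type
#' first), the number of distinct genes of each functional category deleted
#' in that strain or any earlier strain of the series. Deletions are nested
#' in the engineered series, so the counts accumulate monotonically.
#'
#' @param records Data frame of deletion records with columns `strain_id`,
#'   `gene_id`, `category`. Duplicate (strain, gene) pairs are deduplicated
#'   with a warning; unknown category codes are an error.
#' @param series_order Character vector of strain ids, wild type first, in
#'   reduction order. Strains without records contribute no new deletions.
#' @param categories Category vocabulary (23 codes by default).
#' @param total_genes Optional named vector of per-category totals in the
#'   wild-type genome; when supplied, cumulative counts must not exceed it.
#' @return An object of class `gene_category_table`: list with `strains`,
#'   `categories`, `cumulative_counts` (strains x categories matrix) and
#'   `total_genes_per_category` (or `NULL`).
#' @export
cumulative_deletion_counts <- function(records, series_order,
                                       categories = gene_categories(),
                                       total_genes = NULL) {
  stopifnot(is.data.frame(records),
            all(c("strain_id", "gene_id", "category") %in% names(records)))
  series_order <- as.character(series_order)
  bad <- setdiff(unique(records$category), categories)
  if (length(bad) > 0) {
    stop("unknown gene category code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unknown_strains <- setdiff(unique(records$strain_id), series_order)
  if (length(unknown_strains) > 0) {
    stop("deletion records name strain(s) absent from series_order: ",
         paste(unknown_strains, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(records[, c("strain_id", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (strain, gene) deletion record(s) dropped",
            call. = FALSE)
    records <- records[!dup, , drop = FALSE]
  }
  n_s <- length(series_order)
  counts <- matrix(0, n_s, length(categories),
                   dimnames = list(series_order, categories))
  if (nrow(records) > 0) {
    # a gene counts from the first strain of the series that deletes it
    first_idx <- vapply(split(match(records$strain_id, series_order),
                              records$gene_id), min, numeric(1))
    gene_cat <- records$category[match(names(first_idx), records$gene_id)]
    inc <- table(factor(first_idx, levels = seq_len(n_s)),
                 factor(gene_cat, levels = categories))
    counts <- apply(inc, 2, cumsum)
    dimnames(counts) <- list(series_order, categories)
  }
  if (!is.null(total_genes)) {
    total_genes <- total_genes[categories]
    if (any(sweep(counts, 2, total_genes) > 0)) {
      stop("cumulative deletions exceed wild-type per-category totals",
           call. = FALSE)
    }
  }
  structure(list(strains = series_order, categories = categories,
                 cumulative_counts = counts,
                 total_genes_per_category = total_genes),
            class = "gene_category_table")
}

#' Retain gene categories with more than `min_deleted` deleted genes
#'
#' Keeps categories whose cumulative deleted-gene count in the final
#' (most-reduced) strain strictly exceeds `min_deleted` ("more than 10
#' deleted genes" read strictly: a category with exactly 10 is dropped).
#'
#' @param table A [cumulative_deletion_counts()] result.
#' @param min_deleted Strict lower bound on final cumulative deletions.
#' @return Character vector of retained category codes.
#' @export
filter_categories <- function(table, min_deleted = 10) {
  stopifnot(inherits(table, "gene_category_table"))
  final <- table$cumulative_counts[nrow(table$cumulative_counts), ]
  names(final)[final > min_deleted]
}

#' Correlate category deletion counts with mutation rates
#'
#' For every retained gene category and every medium, the Pearson correlation
#' (Spearman via `method`) between `log10` mutation rate and the cumulative
#' deleted-gene count across the strain series, with a seeded permutation
#' p-value, floored at `1 / (n_perm + 1)` by the add-one correction. The
#' result carries the heat-map quantity `-log10(p)`. Categories whose count
#' column is constant have undefined correlation and are flagged (excluded
#' from the heat map).
#'
#' @param table A [cumulative_deletion_counts()] result.
#' @param obs Data frame of strain observations with columns `strain_id`,
#'   `medium`, `mutation_rate`; strains must cover the table's series.
#' @param categories Categories to analyse (default: all of the table's;
#'   typically pre-filtered with [filter_categories()]).
#' @param n_perm,seed Permutation settings (see [permutation_pvalue()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param include_wild_type Include the zero-deletion wild-type row (the
#'   first strain of the series) in the correlation. Default `TRUE`.
#' @return A tibble with one row per (category, medium): `category`,
#'   `medium`, `correlation`, `p_value`, `neg_log10_p`, `flagged`.
#' @export
category_correlation <- function(table, obs, categories = NULL,
                                 n_perm = 2000, seed = 1,
                                 method = c("pearson", "spearman"),
                                 include_wild_type = TRUE) {
  stopifnot(inherits(table, "gene_category_table"))
  method <- match.arg(method)
  if (is.null(categories)) categories <- table$categories
  stopifnot(all(categories %in% table$categories))
  stopifnot(all(c("strain_id", "medium", "mutation_rate") %in% names(obs)))
  strains <- table$strains
  if (!include_wild_type) strains <- strains[-1]
  media <- unique(obs$medium)
  res <- list()
  for (med in media) {
    sub <- obs[obs$medium == med, , drop = FALSE]
    idx <- match(strains, sub$strain_id)
    if (anyNA(idx)) {
      stop("medium ", med, " lacks observations for strain(s): ",
           paste(strains[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    ly <- log10(sub$mutation_rate[idx])
    for (ct in categories) {
      cc <- table$cumulative_counts[strains, ct]
      if (sd(cc) == 0) {
        res[[length(res) + 1]] <- tibble::tibble(
          category = ct, medium = med, correlation = NA_real_,
          p_value = NA_real_, neg_log10_p = NA_real_, flagged = TRUE)
        next
      }
      rr <- if (method == "pearson") pearson_r(ly, cc) else
        suppressWarnings(spearman_rho(ly, cc))
      pp <- permutation_pvalue(cc, ly, statistic = method, n_perm = n_perm,
                               seed = seed, alternative = "two-sided")
      res[[length(res) + 1]] <- tibble::tibble(
        category = ct, medium = med, correlation = rr, p_value = pp,
        neg_log10_p = -log10(pp), flagged = FALSE)
    }
  }
  dplyr::bind_rows(res)
}
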