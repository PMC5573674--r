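#' Read a tab-separated analysis table
#'
#' Strict TSV dialect shared by all pipeline stages: header row mandatory,
#' UTF-8, `.` decimal separator, no thousands separators. Unknown columns are
#' preserved. Schema violations (missing columns, malformed numeric cells)
#' are reported with their location.
#'
#' @param path File path.
#' @param required Character vector of column names that must be present.
#' @param numeric_cols Columns that must parse as numbers.
#' @return A tibble.
#' @export
read_table_tsv <- function(path, required = NULL, numeric_cols = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  prob <- readr::problems(x)
  if (nrow(prob) > 0) {
    stop("malformed cell in ", path, " at row ", prob$row[1], ", column ",
         prob$col[1], ": expected ", prob$expected[1], call. = FALSE)
  }
  empty <- vapply(x, function(cl) is.logical(cl) && all(is.na(cl)),
                  logical(1))
  if (nrow(x) > 0 && any(empty)) {
    stop("column(s) without parseable values in ", path, ": ",
         paste(names(x)[empty], collapse = ", "), call. = FALSE)
  }
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(x))) {
    if (!is.numeric(x[[cl]])) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(x[[cl]]))))[1]
      stop("malformed numeric cell in ", path, ", column ", cl, ", row ",
           bad_row, call. = FALSE)
    }
  }
  x
}

#' Write a tab-separated analysis table
#'
#' Numeric columns are serialised with `%.10g`, so a read/write round trip is
#' byte-stable modulo that float formatting.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  y <- x
  for (cl in names(y)) {
    if (is.numeric(y[[cl]]) && !is.integer(y[[cl]])) {
      y[[cl]] <- sprintf("%.10g", y[[cl]])
    }
  }
  readr::write_tsv(y, path, progress = FALSE)
  invisible(path)
}

#' Write a full set of synthetic pipeline inputs
#'
#' Generates one strain panel per requested medium plus the deletion table
#' and expression compendium, and writes them in the exact TSV dialects the
#' analysis stages read: `fluctuation.tsv`, `plates.tsv`, `od.tsv`,
#' `observations.tsv` (true values), `deletions.tsv`, `expression.tsv` and
#' `expression_growth.tsv`.
#'
#' @param outdir Output directory (created if absent).
#' @param media Media to simulate (one panel each, same genome series).
#' @param seed Master seed; per-medium panel seeds are derived from it.
#' @param noise_sd_log10M,noise_sd_mu Strain-noise overrides passed to
#'   [scaling_scenario()] (set both 0 for the noise-free identity check).
#' @param deletions,expression Generate the deletion table / expression
#'   compendium.
#' @return Invisibly, the list of written paths.
#' @export
simulate_inputs <- function(outdir, media = c("M63", "MAA", "LB"), seed = 42,
                            noise_sd_log10M = 0.1, noise_sd_mu = 0.02,
                            deletions = TRUE, expression = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  obs <- fluct <- od <- plates <- list()
  for (i in seq_along(media)) {
    sc <- scaling_scenario(media[i], noise_sd_log10M = noise_sd_log10M,
                           noise_sd_mu = noise_sd_mu, seed = seed + i)
    panel <- gen_strain_panel(sc)
    obs[[i]] <- panel$observations
    fluct[[i]] <- panel$counts
    od[[i]] <- panel$curves
    plates[[i]] <- withr::with_seed(seed + 100 + i, {
      dplyr::bind_rows(lapply(panel$observations$strain_id, function(id) {
        n_plates <- sample(9:12, 1)
        tibble::tibble(
          strain_id = id, medium = media[i], plate_id = seq_len(n_plates),
          colony_count = rpois(n_plates, sc$N_t * 0.1 / 1e6),
          dilution_factor = 1e6, plated_volume_ml = 0.1)
      }))
    })
  }
  w <- function(x, name) {
    p <- file.path(outdir, name)
    write_table_tsv(x, p)
    p
  }
  paths <- c(paths,
             w(dplyr::bind_rows(obs), "observations.tsv"),
             w(dplyr::bind_rows(fluct), "fluctuation.tsv"),
             w(dplyr::bind_rows(od), "od.tsv"),
             w(dplyr::bind_rows(plates), "plates.tsv"))
  if (deletions) {
    dt <- gen_gene_category_table(
      n_strains = length(scaling_scenario(media[1])$genome_sizes_mb),
      seed = seed + 200)
    paths <- c(paths, w(dt$records, "deletions.tsv"))
  }
  if (expression) {
    ex <- gen_expression_table(seed = seed + 300)
    wide <- tibble::as_tibble(ex$expression, rownames = "gene")
    paths <- c(paths, w(wide, "expression.tsv"),
               w(tibble::tibble(sample = colnames(ex$expression),
                                growth_rate = ex$growth),
                 "expression_growth.tsv"))
  }
  invisible(paths)
}

fit_row <- function(medium, model, slope, intercept, fit) {
  tibble::tibble(medium = medium, model = model, slope = slope,
                 intercept = intercept, r2 = fit$r2,
                 spearman_rho = fit$spearman_rho, p_value = fit$p_value,
                 n = fit$n)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates fluctuation-rate estimation, growth-rate estimation, the two
#' scaling-law fits per medium, the media-shift test, and (when inputs are
#' provided) the gene-category correlation, expression correlation and
#' serial-transfer stages. Writes `rates.tsv`, `growth.tsv`, `fits.tsv`,
#' `heatmap.tsv`, `expression_corr.tsv`, `trajectory.tsv` as applicable plus
#' a machine-readable `summary.json` holding every fitted coefficient and
#' p-value, the parameters and the seeds.
#'
#' The scaling fits consume `observations` when given (e.g. the true-value
#' table written by [simulate_inputs()], or a curated table of measured
#' rates); otherwise they are assembled from the estimation stages, in which
#' case a `strains` table with `strain_id`, `medium`, `genome_size_mb` must
#' be provided.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `outdir` (required); input paths `observations`, `fluctuation`,
#'   `plates`, `od`, `deletions`, `expression`, `expression_growth`,
#'   `strains` (all optional); `params` (optional list: `n_perm`, `seed`,
#'   `N_t`, `target_size_bp`, `culture_volume_ml`, `od_range`, `min_frac`,
#'   `n_max`, `poor_medium`, `rich_medium`); `transfer` (optional list:
#'   `n_days`, `od_noise_sd`, `mu_start`, `mu_max`,
#'   `half_saturation_generations`, `alpha`, `log10_M0`).
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$outdir))
  p <- config$params %||% list()
  n_perm <- p$n_perm %||% 10000
  seed <- p$seed %||% 1
  target_size_bp <- p$target_size_bp %||% 1
  od_range <- p$od_range %||% c(0.02, 0.2)
  min_frac <- p$min_frac %||% 0.7
  n_max <- p$n_max %||% 10000

  inputs <- c("observations", "fluctuation", "plates", "od", "deletions",
              "expression", "expression_growth", "strains")
  for (nm in inputs) {
    if (!is.null(config[[nm]]) && !file.exists(config[[nm]])) {
      stop("missing input file for '", nm, "': ", config[[nm]],
           call. = FALSE)
    }
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(params = list(n_perm = n_perm, seed = seed,
                                target_size_bp = target_size_bp,
                                od_range = od_range, min_frac = min_frac,
                                n_max = n_max))

  # --- CFU / final population sizes -----------------------------------
  nt_lookup <- NULL
  if (!is.null(config$plates)) {
    pl <- read_table_tsv(config$plates,
                         required = c("strain_id", "medium", "colony_count",
                                      "dilution_factor", "plated_volume_ml"),
                         numeric_cols = c("colony_count", "dilution_factor",
                                          "plated_volume_ml"))
    vol <- p$culture_volume_ml %||% 1
    nt_lookup <- dplyr::bind_rows(lapply(
      split(pl, paste(pl$strain_id, pl$medium, sep = "\r")), function(d) {
        cfu <- cfu_from_plates(plate_count_set(
          d$colony_count, d$dilution_factor[1], d$plated_volume_ml[1]))
        tibble::tibble(strain_id = d$strain_id[1], medium = d$medium[1],
                       N_t = cfu$cells_per_ml * vol,
                       n_reliable_plates = cfu$n_reliable)
      }))
  }

  # --- fluctuation stage ----------------------------------------------
  rates <- NULL
  if (!is.null(config$fluctuation)) {
    fl <- read_table_tsv(config$fluctuation,
                         required = c("strain_id", "medium", "mutant_count"),
                         numeric_cols = "mutant_count")
    rates <- dplyr::bind_rows(lapply(
      split(fl, paste(fl$strain_id, fl$medium, sep = "\r")), function(d) {
        est <- estimate_m_mle(d$mutant_count, n_max = n_max,
                              compute_ci = FALSE)
        nt <- if (!is.null(nt_lookup)) {
          nt_lookup$N_t[nt_lookup$strain_id == d$strain_id[1] &
                          nt_lookup$medium == d$medium[1]][1]
        } else p$N_t %||% 1e9
        tibble::tibble(strain_id = d$strain_id[1], medium = d$medium[1],
                       m_hat = est$m_hat, N_t = nt,
                       mutation_rate = mutation_rate_per_bp(
                         est$m_hat, nt, target_size_bp))
      }))
    write_table_tsv(rates, file.path(config$outdir, "rates.tsv"))
  }

  # --- growth stage ----------------------------------------------------
  growth <- NULL
  if (!is.null(config$od)) {
    odt <- read_table_tsv(config$od,
                          required = c("strain_id", "medium", "replicate",
                                       "time_h", "od600"),
                          numeric_cols = c("time_h", "od600"))
    growth <- dplyr::bind_rows(lapply(
      split(odt, paste(odt$strain_id, odt$medium, sep = "\r")), function(d) {
        mus <- vapply(split(d, d$replicate), function(r) {
          growth_rate(growth_curve(times = r$time_h, od = r$od600),
                      od_range = od_range, min_frac = min_frac)$mu
        }, numeric(1))
        tibble::tibble(strain_id = d$strain_id[1], medium = d$medium[1],
                       growth_rate = mean(mus),
                       n_replicates = length(mus))
      }))
    write_table_tsv(growth, file.path(config$outdir, "growth.tsv"))
  }

  # --- observations for the fits --------------------------------------
  obs <- NULL
  if (!is.null(config$observations)) {
    obs <- read_table_tsv(config$observations,
                          required = c("strain_id", "medium",
                                       "genome_size_mb", "mutation_rate",
                                       "growth_rate"),
                          numeric_cols = c("genome_size_mb", "mutation_rate",
                                           "growth_rate"))
  } else if (!is.null(rates) && !is.null(growth)) {
    if (is.null(config$strains)) {
      stop("assembling observations from estimates needs a 'strains' table ",
           "with genome sizes", call. = FALSE)
    }
    st <- read_table_tsv(config$strains,
                         required = c("strain_id", "medium",
                                      "genome_size_mb"),
                         numeric_cols = "genome_size_mb")
    obs <- dplyr::inner_join(rates, growth, by = c("strain_id", "medium"))
    obs <- dplyr::inner_join(obs, st, by = c("strain_id", "medium"))
  }

  # --- scaling fits + media shift -------------------------------------
  if (!is.null(obs)) {
    fits <- list()
    for (med in unique(obs$medium)) {
      sub <- obs[obs$medium == med, , drop = FALSE]
      gfit <- fit_genome_scaling(sub, n_perm = n_perm, seed = seed)
      mfit <- fit_growth_mutation(sub, n_perm = n_perm, seed = seed)
      fits[[length(fits) + 1]] <- fit_row(med, "genome_size", gfit$r,
                                          gfit$b, gfit)
      fits[[length(fits) + 1]] <- fit_row(med, "growth_rate", mfit$alpha,
                                          mfit$log10_M0, mfit)
      summary$fits[[med]] <- list(
        genome_size = list(r = gfit$r, b = gfit$b, r2 = gfit$r2,
                           spearman_rho = gfit$spearman_rho,
                           p_value = gfit$p_value),
        growth_rate = list(alpha = mfit$alpha, log10_M0 = mfit$log10_M0,
                           M0 = mfit$M0, r2 = mfit$r2,
                           spearman_rho = mfit$spearman_rho,
                           p_value = mfit$p_value))
    }
    write_table_tsv(dplyr::bind_rows(fits),
                    file.path(config$outdir, "fits.tsv"))

    poor <- p$poor_medium %||% "M63"
    rich <- p$rich_medium %||% "LB"
    if (all(c(poor, rich) %in% obs$medium)) {
      a <- obs[obs$medium == poor, ]
      b <- obs[obs$medium == rich, ]
      common <- intersect(a$strain_id, b$strain_id)
      if (length(common) >= 5) {
        sh <- media_shift_test(
          a$mutation_rate[match(common, a$strain_id)],
          b$mutation_rate[match(common, b$strain_id)])
        summary$media_shift <- list(poor = poor, rich = rich,
                                    p_value = sh$p_value,
                                    median_log10_shift = sh$direction,
                                    n_pairs = sh$n_pairs)
      }
    }
  }

  # --- gene-category stage --------------------------------------------
  if (!is.null(config$deletions) && !is.null(obs)) {
    recs <- read_table_tsv(config$deletions,
                           required = c("strain_id", "gene_id", "category"))
    series <- config$series_order %||% unique(obs$strain_id)
    tab <- cumulative_deletion_counts(recs, series_order = series)
    kept <- filter_categories(tab, min_deleted = p$min_deleted %||% 10)
    heat <- category_correlation(tab, obs, categories = kept,
                                 n_perm = p$n_perm_categories %||% 2000,
                                 seed = seed)
    write_table_tsv(heat, file.path(config$outdir, "heatmap.tsv"))
    summary$gene_categories <- list(
      retained = kept, n_retained = length(kept),
      n_categories = length(tab$categories))
  }

  # --- expression stage ------------------------------------------------
  if (!is.null(config$expression) && !is.null(config$expression_growth)) {
    ex <- read_table_tsv(config$expression, required = "gene")
    gr <- read_table_tsv(config$expression_growth,
                         required = c("sample", "growth_rate"),
                         numeric_cols = "growth_rate")
    mat <- as.matrix(ex[, gr$sample, drop = FALSE])
    rownames(mat) <- ex$gene
    corr <- correlate_expression_growth(normalize_expression(mat),
                                        gr$growth_rate,
                                        n_perm = p$n_perm_expression %||%
                                          1000,
                                        seed = seed)
    write_table_tsv(corr, file.path(config$outdir, "expression_corr.tsv"))
  }

  # --- serial transfer (optional) -------------------------------------
  if (!is.null(config$transfer)) {
    tc <- config$transfer
    proto <- transfer_protocol(
      n_days = tc$n_days %||% 50,
      od_noise_sd = tc$od_noise_sd %||% 0)
    adapt <- adaptation_model(
      mu_start = tc$mu_start %||% (8 * log(2) / 24),
      mu_max = tc$mu_max %||% tc$mu_start %||% (8 * log(2) / 24),
      half_saturation_generations = tc$half_saturation_generations %||% 150,
      alpha = tc$alpha %||% -4.9, log10_M0 = tc$log10_M0 %||% -6.1)
    traj <- run_serial_transfer(proto, adapt, seed = seed)
    write_table_tsv(traj, file.path(config$outdir, "trajectory.tsv"))
    summary$transfer <- list(
      cumulative_generations = tail(traj$cumulative_generations, 1),
      mu_fold_change = attr(traj, "mu_fold_change"),
      log10_M_change = attr(traj, "log10_M_change"))
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
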