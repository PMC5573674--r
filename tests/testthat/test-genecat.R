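test_that("cumulative counts accumulate distinct genes down the series", {
  tab <- cumulative_deletion_counts(nested_t_records(),
                                    c("wt", "red1", "red2", "red3"))
  expect_equal(unname(tab$cumulative_counts[, "t"]), c(0, 2, 5, 10))
  expect_true(all(tab$cumulative_counts[1, ] == 0))
  # empty records give an all-zero table
  empty <- tibble::tibble(strain_id = character(), gene_id = character(),
                          category = character())
  tab0 <- cumulative_deletion_counts(empty, c("wt", "red1"))
  expect_true(all(tab0$cumulative_counts == 0))
})

test_that("bad category codes error and duplicates are deduplicated", {
  bad <- tibble::tibble(strain_id = "red1", gene_id = "g1", category = "zz")
  expect_error(cumulative_deletion_counts(bad, c("wt", "red1")),
               "unknown gene category code")
  dup <- nested_t_records()[c(1, 1, 2), ]
  expect_warning(
    tab <- cumulative_deletion_counts(dup, c("wt", "red1", "red2", "red3")),
    "duplicate")
  expect_equal(unname(tab$cumulative_counts[, "t"]), c(0, 2, 2, 2))
})

test_that("category filter is strict and filter at 0 keeps any deletion", {
  recs <- tibble::tibble(
    strain_id = "red1",
    gene_id = sprintf("g%03d", 1:77),
    category = rep(c("d", "k", "t"), c(44, 8, 25)))
  recs$category[recs$category == "k"] <- "m"  # keep vocabulary valid
  tab <- cumulative_deletion_counts(recs, c("wt", "red1"))
  expect_setequal(filter_categories(tab), c("d", "t"))
  expect_setequal(filter_categories(tab, 0), c("d", "m", "t"))
  # a category with exactly min_deleted genes is excluded
  ten <- tibble::tibble(strain_id = "red1", gene_id = sprintf("h%02d", 1:10),
                        category = "pt")
  tab10 <- cumulative_deletion_counts(ten, c("wt", "red1"))
  expect_length(filter_categories(tab10), 0)
})

test_that("category correlation finds proportional counts and flags ties", {
  series <- sprintf("s%d", 0:4)
  log10M <- seq(-9, -7, length.out = 5)
  obs <- tibble::tibble(strain_id = series, medium = "M63",
                        mutation_rate = 10^log10M)
  # category t: counts proportional to log10 M; category m: constant 0
  counts <- round((log10M - log10M[1]) * 10)
  recs <- dplyr::bind_rows(lapply(2:5, function(i) {
    new <- counts[i] - counts[i - 1]
    if (new == 0) return(NULL)
    tibble::tibble(strain_id = series[i],
                   gene_id = sprintf("t%d_%d", i, seq_len(new)),
                   category = "t")
  }))
  tab <- cumulative_deletion_counts(recs, series)
  res <- category_correlation(tab, obs, categories = c("t", "m"),
                              n_perm = 200, seed = 1)
  rt <- res[res$category == "t", ]
  expect_equal(rt$correlation, 1, tolerance = 1e-9)
  expect_equal(rt$neg_log10_p, -log10(rt$p_value))
  rm_ <- res[res$category == "m", ]
  expect_true(rm_$flagged)
  expect_true(is.na(rm_$correlation))
})

test_that("correlations are invariant under consistent strain relabeling", {
  sim <- gen_gene_category_table(seed = 4)
  panel <- gen_strain_panel(scaling_scenario("M63", seed = 4))
  obs <- panel$observations
  tab <- cumulative_deletion_counts(sim$records, sim$series_order)
  kept <- filter_categories(tab)
  r1 <- category_correlation(tab, obs, categories = kept, n_perm = 100,
                             seed = 9)
  # relabel strains consistently in both inputs
  relab <- stats::setNames(sprintf("x%02d", seq_along(sim$series_order)),
                           sim$series_order)
  recs2 <- sim$records
  recs2$strain_id <- unname(relab[recs2$strain_id])
  obs2 <- obs
  obs2$strain_id <- unname(relab[obs2$strain_id])
  tab2 <- cumulative_deletion_counts(recs2, unname(relab[sim$series_order]))
  r2 <- category_correlation(tab2, obs2, categories = kept, n_perm = 100,
                             seed = 9)
  expect_equal(r1$correlation, r2$correlation, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("generated deletion tables are nested and calibrated", {
  for (s in c(1, 7, 23)) {
    sim <- gen_gene_category_table(seed = s)
    tab <- cumulative_deletion_counts(sim$records, sim$series_order)
    expect_true(all(apply(tab$cumulative_counts, 2, diff) >= 0))
    expect_length(filter_categories(tab), 14)
    expect_true(all(tab$cumulative_counts[nrow(tab$cumulative_counts), ] <=
                      sim$total_genes_per_category))
  }
  # determinism
  a <- gen_gene_category_table(seed = 3)
  b <- gen_gene_category_table(seed = 3)
  expect_identical(a, b)
})
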