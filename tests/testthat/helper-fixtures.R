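# Collinear strain observations placed exactly on both scaling laws.
collinear_obs <- function(r = -14.6, b = 2.5, alpha = -4.9, log10_M0 = -6.1,
                          genome_sizes = c(4.65, 4.4, 4.2, 3.9, 3.62),
                          medium = "M63") {
  log10M <- r * log10(genome_sizes) + b
  tibble::tibble(
    strain_id = sprintf("s%02d", seq_along(genome_sizes)),
    medium = medium,
    genome_size_mb = genome_sizes,
    mutation_rate = 10^log10M,
    growth_rate = (log10M - log10_M0) / alpha)
}

# Inverse-cdf sampler from the Lea-Coulson pmf itself: used to test the MLE
# under its own model, independently of the branching oracle.
sample_lc_direct <- function(m, n, seed, n_max = 5000) {
  p <- ld_pmf(m, n_max)$pmf
  cdf <- cumsum(p)
  withr::with_seed(seed, {
    u <- runif(n)
    findInterval(u, cdf)  # counts above n_max land in the tail bin
  })
}

# Small deletion-record table: three reduced strains with nested t-category
# deletions of 2, 3 and 5 new genes.
nested_t_records <- function() {
  tibble::tibble(
    strain_id = rep(c("red1", "red2", "red3"), c(2, 3, 5)),
    gene_id = sprintf("g%02d", 1:10),
    category = "t")
}
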