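# Shared in-code fixtures: small hand-built fraction tables and random
# table generators used across test files.

# A normalized table where per-OTU abundances are set directly; columns are
# padded with a filler OTU so each sums to 1.
make_scaled_table <- function(values, densities, missing = rep(FALSE, length(densities))) {
  filler <- 1 - colSums(values)
  stopifnot(all(filler >= -1e-12))
  vals <- rbind(values, filler = pmax(filler, 0))
  vals[, missing] <- NA_real_
  fraction_table(vals, densities, missing = missing, normalized = TRUE)
}

# Random raw count table for property checks.
random_count_table <- function(n_otu = 6, n_frac = 8, seed = 1) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_otu * n_frac, lambda = 50), n_otu, n_frac,
                     dimnames = list(paste0("OTU", seq_len(n_otu)),
                                     sprintf("F%02d", seq_len(n_frac))))
    dens <- sort(runif(n_frac, 1.66, 1.83), decreasing = TRUE)
    fraction_table(counts, dens, total_mass = colSums(counts))
  })
}

# Four-fraction DNA-style grid: two heavy (>= 1.702), two light.
dna4_densities <- c(1.720, 1.710, 1.695, 1.685)

# Independent quadrature of a Gaussian density over (lower, upper).
# stats::integrate() diverges on semi-infinite intervals whose mass is far in
# a tail, so the bounds are clipped to center +/- 15 sd, beyond which the
# mass is < 1e-50.
gaussian_quadrature <- function(lower, upper, center, sigma) {
  lo <- max(lower, center - 15 * sigma)
  hi <- min(upper, center + 15 * sigma)
  if (lo >= hi) return(0)
  stats::integrate(stats::dnorm, lo, hi, mean = center, sd = sigma,
                   rel.tol = 1e-10)$value
}
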