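# Shared builders for small test problems.

toy_sources_2 <- function() {
  source_spec(name = c("A", "B"),
              mean_d13C = c(-30, -20), sd_d13C = 1,
              mean_d15N = c(2, 8), sd_d15N = 1)
}

toy_sources_3 <- function() {
  # well-separated, non-collinear triangle in isotope space
  source_spec(name = c("A", "B", "C"),
              mean_d13C = c(-32, -18, -26), sd_d13C = 0.5,
              mean_d15N = c(2, 4, 12), sd_d15N = 0.5)
}

# Consumer samples drawn from the mixture forward model for given diet p.
draw_consumers <- function(sources, p, n = 20, residual = 0.5, seed = 1) {
  truth <- community_truth(sources, list(Cons = p))
  cfg <- sim_config(n_sources = nrow(sources), n_consumers = 1,
                    samples_per_taxon = n,
                    source_sd = c(d13C = sources$sd_d13C[1],
                                  d15N = sources$sd_d15N[1]),
                    residual_sd = c(d13C = residual, d15N = residual),
                    seed = seed)
  set.seed(seed)
  iso <- sample_isotopes(truth, cfg)
  iso[iso$type == "consumer", c("d13C", "d15N")]
}

quick_settings <- function(seed = 1, iterations = 4000, burn_in = 1000,
                           chains = 2, thin = 5) {
  mcmc_settings(iterations = iterations, burn_in = burn_in, chains = chains,
                thin = thin, seed = seed)
}

# Welch two-sample t-test p-value from first principles (test oracle).
welch_p <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Four-source problem with one planted zero contributor (for pruning).
# Z sits far above the consumer on the d15N axis while the consumer lies
# close to the A-B edge of the true mixing triangle, so any appreciable Z
# contribution would push the implied remainder outside the triangle: the
# zero contributor is identifiable, not aliased into the simplex null space.
planted_zero_problem <- function(seed = 1) {
  src <- source_spec(name = c("A", "B", "C", "Z"),
                     mean_d13C = c(-32, -18, -27, -27), sd_d13C = 0.5,
                     mean_d15N = c(2, 4, 8, 16), sd_d15N = 0.5)
  truth <- community_truth(src, list(Cons = c(A = 0.5, B = 0.3, C = 0.2,
                                              Z = 0)))
  cfg <- sim_config(n_sources = 4, n_consumers = 1, samples_per_taxon = 30,
                    source_sd = c(d13C = 0.5, d15N = 0.5),
                    tef_d13C = c(mean = 0, sd = 0),
                    tef_d15N = c(mean = 0, sd = 0),
                    residual_sd = c(d13C = 0.5, d15N = 0.5), seed = seed)
  set.seed(seed)
  iso <- sample_isotopes(truth, cfg)
  list(y = iso[iso$type == "consumer", c("d13C", "d15N")], src = src,
       truth = c(A = 0.5, B = 0.3, C = 0.2))
}
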