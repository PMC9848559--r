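test_that("log posterior matches an independently coded density sum", {
  set.seed(9)
  src <- source_spec(name = c("A", "B", "C"),
                     mean_d13C = runif(3, -32, -20), sd_d13C = runif(3, 0.3, 1),
                     mean_d15N = runif(3, 2, 10), sd_d15N = runif(3, 0.3, 1),
                     tef_d13C = 0.4, tef_sd_d13C = 1.3,
                     tef_d15N = 2.5, tef_sd_d15N = 0.6,
                     conc_C = runif(3, 0.2, 0.6), conc_N = runif(3, 0.05, 0.2))
  y <- data.frame(d13C = rnorm(5, -26), d15N = rnorm(5, 7))
  prob <- mixing_problem(y, src, concentration_dependent = TRUE)
  p <- c(0.5, 0.3, 0.2); sig <- c(0.7, 0.4)
  got <- log_posterior(p, sig, prob, sigma_prior_sd = 10)
  # independent implementation: explicit loops, no shared helpers
  want <- lgamma(3)
  for (k in 1:2) {
    mu <- if (k == 1) src$mean_d13C else src$mean_d15N
    om <- if (k == 1) src$sd_d13C else src$sd_d15N
    de <- if (k == 1) src$tef_d13C else src$tef_d15N
    ta <- if (k == 1) src$tef_sd_d13C else src$tef_sd_d15N
    q <- if (k == 1) src$conc_C else src$conc_N
    yk <- if (k == 1) y$d13C else y$d15N
    denom <- 0; num <- 0; v <- 0
    for (i in 1:3) denom <- denom + p[i] * q[i]
    for (i in 1:3) num <- num + p[i] * q[i] * (mu[i] + de[i])
    for (i in 1:3) v <- v + p[i]^2 * q[i]^2 * (om[i]^2 + ta[i]^2)
    mmean <- num / denom
    mvar <- v / denom^2 + sig[k]^2
    for (j in seq_along(yk)) {
      want <- want - 0.5 * log(2 * pi * mvar) -
        (yk[j] - mmean)^2 / (2 * mvar)
    }
    want <- want + log(2) - 0.5 * log(2 * pi * 100) - sig[k]^2 / 200
  }
  expect_equal(got, want, tolerance = 1e-10)
  expect_error(log_posterior(c(0.5, 0.4), sig, prob), "sum to 1|length")
  expect_error(log_posterior(p, c(-1, 1), prob), "positive")
})

test_that("a single source collapses the mixture mean to mu + tef", {
  src <- source_spec(name = "A", mean_d13C = -25, sd_d13C = 1,
                     mean_d15N = 5, sd_d15N = 1,
                     tef_d13C = 0.4, tef_d15N = 3)
  y <- data.frame(d13C = c(-24.6, -24.6, -24.6), d15N = c(8, 8, 8))
  prob <- mixing_problem(y, src)
  lp1 <- log_posterior(1, c(0.5, 0.5), prob)
  # data sit exactly at mu + tef, so shifting them off-centre lowers density
  y2 <- data.frame(d13C = y$d13C + 1, d15N = y$d15N)
  expect_gt(lp1, log_posterior(1, c(0.5, 0.5), mixing_problem(y2, src)))
})

test_that("equal concentrations cancel out of the mixture", {
  src <- toy_sources_2()
  y <- data.frame(d13C = rnorm(5, -25), d15N = rnorm(5, 5))
  src_c <- src; src_c$conc_C <- 0.37; src_c$conc_N <- 0.08
  p <- c(0.6, 0.4); sig <- c(0.5, 0.5)
  expect_equal(
    log_posterior(p, sig, mixing_problem(y, src)),
    log_posterior(p, sig, mixing_problem(y, src_c,
                                         concentration_dependent = TRUE)),
    tolerance = 1e-12)
})

test_that("two equidistant sources give a posterior median near one half", {
  src <- source_spec(name = c("A", "B"), mean_d13C = c(-30, -20),
                     sd_d13C = 0.5, mean_d15N = c(0, 0), sd_d15N = 0.5)
  set.seed(4)
  y <- data.frame(d13C = rnorm(10, -25, 0.3), d15N = rnorm(10, 0, 0.3))
  dr <- run_mcmc(mixing_problem(y, src), quick_settings(seed = 4))
  s <- posterior_summary(dr)
  expect_lt(abs(s$median[s$source == "A"] - 0.5), 0.05)
})

test_that("the sampler recovers a known three-source diet", {
  ref <- reference_community(seed = 1)
  set.seed(1)
  iso <- sample_isotopes(ref$truth, ref$config)
  y <- iso[iso$type == "consumer", c("d13C", "d15N")]
  prob <- mixing_problem(y, ref$truth$source_specs)
  dr <- run_mcmc(prob, quick_settings(seed = 1, iterations = 8000,
                                      burn_in = 2000))
  s <- posterior_summary(dr)
  expect_true(all(abs(s$median - ref$true_diet[s$source]) < 0.1))
  expect_true(all(dr$acceptance > 0.15 & dr$acceptance < 0.55))
})

test_that("MCMC is seed-deterministic and draws stay on the simplex", {
  src <- toy_sources_2()
  y <- draw_consumers(src, c(A = 0.4, B = 0.6), n = 8, seed = 2)
  prob <- mixing_problem(y, src)
  d1 <- run_mcmc(prob, quick_settings(seed = 5))
  d2 <- run_mcmc(prob, quick_settings(seed = 5))
  expect_identical(d1$chains, d2$chains)
  pooled <- do.call(rbind, d1$chains)
  expect_true(all(abs(rowSums(pooled[, c("A", "B")]) - 1) < 1e-9))
  expect_true(all(pooled[, c("sigma_d13C", "sigma_d15N")] > 0))
  s <- posterior_summary(d1)
  expect_lt(abs(sum(s$median_renorm) - 1), 1e-9)
})

test_that("Gelman-Rubin matches the textbook formula and flags divergence", {
  set.seed(6)
  chains <- lapply(1:3, function(i) {
    m <- cbind(rnorm(50, 0, 1), rnorm(50, i / 10, 2))
    colnames(m) <- c("A", "B")
    m
  })
  draws <- structure(list(chains = chains, source_names = c("A", "B")),
                     class = "posterior_draws")
  rhat <- gelman_rubin(draws)
  # independent textbook computation
  for (par in c("A", "B")) {
    x <- sapply(chains, function(ch) ch[, par])
    n <- nrow(x); m <- ncol(x)
    W <- mean(apply(x, 2, var))
    B <- n * var(colMeans(x))
    vhat <- (n - 1) / n * W + B / n
    expect_equal(unname(rhat[par]), sqrt(vhat / W), tolerance = 1e-8)
  }
  # two chains around 0 and 100 must be flagged
  far <- structure(list(chains = list(cbind(A = rnorm(50, 0, 1)),
                                      cbind(A = rnorm(50, 100, 1))),
                        source_names = "A"),
                   class = "posterior_draws")
  r <- gelman_rubin(far)
  expect_gt(r["A"], 1.1)
  expect_true("A" %in% attr(r, "flagged"))
  expect_error(gelman_rubin(structure(list(chains = far$chains[1]),
                                      class = "posterior_draws")),
               "2 chains")
})

test_that("splitting one well-mixed run gives R-hat near 1", {
  set.seed(7)
  long <- rnorm(4000)
  halves <- list(cbind(A = long[1:2000]), cbind(A = long[2001:4000]))
  draws <- structure(list(chains = halves, source_names = "A"),
                     class = "posterior_draws")
  expect_lt(abs(gelman_rubin(draws)["A"] - 1), 0.01)
})

test_that("posterior summaries equal independent percentile computations", {
  set.seed(8)
  draws_m <- cbind(A = rbeta(1000, 2, 3), sigma_d13C = 1, sigma_d15N = 1)
  draws_m <- cbind(draws_m[, 1, drop = FALSE],
                   B = 1 - draws_m[, "A"],
                   draws_m[, 2:3])
  obj <- structure(list(chains = list(draws_m[1:500, ], draws_m[501:1000, ]),
                        source_names = c("A", "B")),
                   class = "posterior_draws")
  s <- posterior_summary(obj)
  # independent type-7 percentile: linear interpolation of order statistics
  manual_q <- function(x, prob) {
    x <- sort(x); h <- (length(x) - 1) * prob + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  a <- draws_m[, "A"]
  expect_equal(s$median[s$source == "A"], manual_q(a, 0.5), tolerance = 1e-12)
  expect_equal(s$q2.5[s$source == "A"], manual_q(a, 0.025), tolerance = 1e-12)
  expect_equal(s$q97.5[s$source == "A"], manual_q(a, 0.975),
               tolerance = 1e-12)
  # degenerate draws give a zero-width interval
  const <- matrix(rep(c(0.6, 0.4, 1, 1), each = 20), 20,
                  dimnames = list(NULL, c("A", "B", "sigma_d13C",
                                          "sigma_d15N")))
  cobj <- structure(list(chains = list(const, const),
                         source_names = c("A", "B")),
                    class = "posterior_draws")
  cs <- posterior_summary(cobj)
  expect_equal(cs$median, c(0.6, 0.4))
  expect_equal(cs$q2.5, cs$q97.5)
})

test_that("with an uninformative likelihood the grid oracle returns the prior", {
  # two coincident sources: the likelihood cannot separate them
  src <- source_spec(name = c("A", "B"), mean_d13C = c(-25, -25),
                     sd_d13C = 1, mean_d15N = c(5, 5), sd_d15N = 1)
  y <- data.frame(d13C = -25, d15N = 5)
  suppressWarnings(prob <- mixing_problem(y, src))
  or <- grid_posterior_oracle(prob)
  expect_equal(unname(or$mean), c(0.5, 0.5), tolerance = 0.01)
})

test_that("refining the oracle grid barely moves the posterior means", {
  src <- toy_sources_2()
  y <- draw_consumers(src, c(A = 0.3, B = 0.7), n = 10, seed = 3)
  prob <- mixing_problem(y, src)
  coarse <- grid_posterior_oracle(prob, resolution = 0.01)
  fine <- grid_posterior_oracle(prob, resolution = 0.005)
  expect_lt(max(abs(coarse$mean - fine$mean)), 0.005)
})

test_that("MCMC means agree with the grid oracle on two-source problems", {
  src <- toy_sources_2()
  for (seed in 1:3) {
    y <- draw_consumers(src, c(A = 0.35, B = 0.65), n = 10, seed = seed)
    prob <- mixing_problem(y, src)
    or <- grid_posterior_oracle(prob)
    dr <- run_mcmc(prob, quick_settings(seed = seed, iterations = 12000,
                                        burn_in = 3000, chains = 3))
    pooled <- do.call(rbind, dr$chains)
    expect_lt(max(abs(colMeans(pooled[, c("A", "B")]) - or$mean)), 0.02)
  }
})

test_that("credible intervals cover the truth at roughly nominal rate", {
  src <- toy_sources_3()
  set.seed(10)
  hits <- 0L; total <- 0L
  for (i in 1:50) {
    g <- rgamma(3, 1); p <- g / sum(g); names(p) <- src$name
    y <- draw_consumers(src, p, n = 15, seed = 100 + i)
    dr <- run_mcmc(mixing_problem(y, src),
                   quick_settings(seed = 100 + i, iterations = 3000,
                                  burn_in = 1000))
    s <- posterior_summary(dr)
    hits <- hits + sum(p[s$source] >= s$q2.5 & p[s$source] <= s$q97.5)
    total <- total + 3L
  }
  expect_gte(hits / total, 0.85)
})

test_that("duplicating a source preserves the duplicated pair's summed share", {
  src2 <- toy_sources_2()
  y <- draw_consumers(src2, c(A = 0.6, B = 0.4), n = 20, seed = 11)
  base <- run_mcmc(mixing_problem(y, src2),
                   quick_settings(seed = 11, iterations = 10000,
                                  burn_in = 3000))
  base_med <- posterior_summary(base)
  dup <- source_spec(name = c("A", "B", "A2"),
                     mean_d13C = c(-30, -20, -30), sd_d13C = 1,
                     mean_d15N = c(2, 8, 2), sd_d15N = 1)
  dupped <- run_mcmc(mixing_problem(y, dup),
                     quick_settings(seed = 11, iterations = 10000,
                                    burn_in = 3000))
  pooled <- do.call(rbind, dupped$chains)
  pair_share <- median(pooled[, "A"] + pooled[, "A2"])
  expect_lt(abs(pair_share - base_med$median[base_med$source == "A"]), 0.08)
})

test_that("degenerate MCMC settings are rejected", {
  expect_error(mcmc_settings(iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(chains = 1), "chains")
  expect_error(mcmc_settings(iterations = 101, burn_in = 100, thin = 10),
               "zero post-thinning")
})
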