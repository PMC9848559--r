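test_that("config validation rejects impossible communities", {
  expect_error(sim_config(n_sources = 0), "n_sources")
  expect_error(sim_config(source_sd = c(d13C = -1, d15N = 1)), "source_sd")
  expect_error(sim_config(n_sources = 2,
                          source_mean_ranges = list(d13C = c(-20, -20),
                                                    d15N = c(0, 10))),
               "degenerate")
  expect_error(sim_config(diet_concentration = 0), "diet_concentration")
})

test_that("a single-source community has the degenerate diet (1)", {
  truth <- generate_community(sim_config(n_sources = 1, n_consumers = 1))
  expect_identical(unname(truth$true_diets$Consumer1), 1)
})

test_that("community generation is deterministic given the seed", {
  cfg <- sim_config(n_sources = 4, n_consumers = 5, seed = 99)
  expect_identical(generate_community(cfg), generate_community(cfg))
  sim1 <- simulate_community(cfg)
  sim2 <- simulate_community(cfg)
  expect_identical(sim1$isotopes, sim2$isotopes)
  expect_identical(sim1$guts, sim2$guts)
})

test_that("true diets reproduce an independent Dirichlet-by-gammas draw", {
  cfg <- sim_config(n_sources = 3, n_consumers = 1, diet_concentration = 1,
                    seed = 7)
  truth <- generate_community(cfg)
  # independent re-implementation of the documented draw order:
  # source means (2 x K uniforms) then K gammas per consumer
  set.seed(7)
  runif(3, -34, -18)
  runif(3, 0, 12)
  g <- rgamma(3, shape = 1, rate = 1)
  expect_equal(unname(truth$true_diets$Consumer1), g / sum(g),
               tolerance = 1e-12)
})

test_that("every generated diet and gut composition lies on the simplex", {
  sim <- simulate_community(sim_config(n_sources = 5, n_consumers = 8,
                                       gut_samples_per_consumer = 6,
                                       seed = 3))
  for (p in sim$truth$true_diets) expect_lt(abs(sum(p) - 1), 1e-9)
  comp <- as.matrix(sim$guts[, sim$truth$source_names])
  expect_true(all(comp >= 0))
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
})

test_that("degenerate mixtures collapse to the source mean", {
  src <- source_spec(name = "only", mean_d13C = -25, sd_d13C = 0,
                     mean_d15N = 5, sd_d15N = 0)
  truth <- community_truth(src, list(C1 = c(only = 1)))
  cfg <- sim_config(n_sources = 1, n_consumers = 1, samples_per_taxon = 5,
                    source_sd = c(d13C = 0, d15N = 0),
                    tef_d13C = c(mean = 0, sd = 0),
                    tef_d15N = c(mean = 0, sd = 0),
                    residual_sd = c(d13C = 0, d15N = 0), seed = 1)
  set.seed(1)
  iso <- sample_isotopes(truth, cfg)
  cons <- iso[iso$type == "consumer", ]
  expect_equal(cons$d13C, rep(-25, 5))
  expect_equal(cons$d15N, rep(5, 5))
})

test_that("a symmetric two-source diet centres consumers at the midpoint", {
  src <- source_spec(name = c("A", "B"), mean_d13C = c(-30, -20),
                     sd_d13C = 0.5, mean_d15N = c(0, 0), sd_d15N = 0.5)
  truth <- community_truth(src, list(C1 = c(A = 0.5, B = 0.5)))
  cfg <- sim_config(n_sources = 2, n_consumers = 1,
                    samples_per_taxon = 4000,
                    source_sd = c(d13C = 0.5, d15N = 0.5),
                    tef_d13C = c(mean = 0, sd = 0),
                    tef_d15N = c(mean = 0, sd = 0),
                    residual_sd = c(d13C = 0, d15N = 0), seed = 2)
  set.seed(2)
  iso <- sample_isotopes(truth, cfg)
  cons <- iso[iso$type == "consumer", ]
  expect_lt(abs(mean(cons$d13C) - (-25)), 3 * 0.5 / sqrt(4000) * 2)
})

test_that("simulated consumer moments match the closed-form mixture", {
  src <- toy_sources_3()
  src$tef_d13C <- 0.4; src$tef_sd_d13C <- 1.3
  src$tef_d15N <- 2.5; src$tef_sd_d15N <- 0.8
  p <- c(A = 0.6, B = 0.3, C = 0.1)
  truth <- community_truth(src, list(C1 = p))
  cfg <- sim_config(n_sources = 3, n_consumers = 1, samples_per_taxon = 500,
                    source_sd = c(d13C = 0.5, d15N = 0.5),
                    tef_d13C = c(mean = 0.4, sd = 1.3),
                    tef_d15N = c(mean = 2.5, sd = 0.8),
                    residual_sd = c(d13C = 0.5, d15N = 0.5), seed = 4)
  set.seed(4)
  iso <- sample_isotopes(truth, cfg)
  cons <- iso[iso$type == "consumer", ]
  # closed-form moments written out independently here
  mu_c <- sum(p * (src$mean_d13C + 0.4))
  var_c <- sum(p^2 * (0.5^2 + 1.3^2)) + 0.5^2
  mu_n <- sum(p * (src$mean_d15N + 2.5))
  var_n <- sum(p^2 * (0.5^2 + 0.8^2)) + 0.5^2
  n <- 500
  expect_lt(abs(mean(cons$d13C) - mu_c), 3 * sqrt(var_c / n))
  expect_lt(abs(mean(cons$d15N) - mu_n), 3 * sqrt(var_n / n))
  # variance of a sample variance ~ 2 var^2 / (n-1)
  expect_lt(abs(var(cons$d13C) - var_c), 3 * sqrt(2 * var_c^2 / (n - 1)))
  expect_lt(abs(var(cons$d15N) - var_n), 3 * sqrt(2 * var_n^2 / (n - 1)))
})

test_that("gut compositions concentrate on the true diet", {
  src <- toy_sources_3()
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  truth <- community_truth(src, list(C1 = p))
  # sharp Dirichlet limit: compositions approach the true diet
  cfg <- sim_config(n_sources = 3, n_consumers = 1,
                    gut_samples_per_consumer = 20,
                    diet_concentration = 1e6, gut_drop_prob = 0, seed = 5)
  set.seed(5)
  guts <- sample_guts(truth, cfg)
  comp <- as.matrix(guts[, names(p)])
  expect_true(all(abs(sweep(comp, 2, p)) < 0.01))
  # Monte-Carlo mean of per-gut proportions matches the diet
  cfg2 <- sim_config(n_sources = 3, n_consumers = 1,
                     gut_samples_per_consumer = 1000,
                     diet_concentration = 5, gut_drop_prob = 0, seed = 6)
  set.seed(6)
  guts2 <- sample_guts(truth, cfg2)
  comp2 <- as.matrix(guts2[, names(p)])
  se <- apply(comp2, 2, sd) / sqrt(1000)
  expect_true(all(abs(colMeans(comp2) - p) < 3 * se + 0.02))
})

test_that("single-item diets give guts that are 100% that item", {
  src <- source_spec(name = "A", mean_d13C = -25, sd_d13C = 1,
                     mean_d15N = 5, sd_d15N = 1)
  truth <- community_truth(src, list(C1 = c(A = 1)))
  cfg <- sim_config(n_sources = 1, n_consumers = 1,
                    gut_samples_per_consumer = 10, seed = 1)
  set.seed(1)
  guts <- sample_guts(truth, cfg)
  expect_true(all(guts$A == 1))
  ov <- occurrence_and_volume(guts, "C1")
  expect_equal(unname(ov$fo["A"]), 1)
})

test_that("fixtures round-trip through the dialect readers", {
  sim <- simulate_community(sim_config(n_sources = 3, n_consumers = 2,
                                       seed = 21))
  d <- withr::local_tempdir()
  files <- write_fixture(sim$truth, sim$isotopes, sim$guts, d)
  # 2 consumers -> 2x2 taxa CSVs + 1 diet CSV
  expect_length(files, 5)
  y <- read_consumer_file(file.path(d, "Consumer1.csv"))
  orig <- sim$isotopes[sim$isotopes$taxon == "Consumer1", ]
  expect_equal(y$d13C, orig$d13C, tolerance = 1e-9)
  src <- read_sources_file(file.path(d, "Consumer1.Sources.csv"))
  expect_setequal(src$name, names(sim$truth$true_diets$Consumer1))
  expect_equal(src$tef_d13C, rep(0.4, 3))
  expect_equal(src$tef_sd_d13C, rep(1.3, 3))
  diet <- read_diet_table(file.path(d, "diet_composition.csv"))
  expect_equal(nrow(diet), 2)
  expect_false(any(diet$flagged_sum))
})

test_that("the sources fixture header is the eleven-column dialect verbatim", {
  sim <- simulate_community(sim_config(n_sources = 2, n_consumers = 1,
                                       seed = 8))
  d <- withr::local_tempdir()
  write_fixture(sim$truth, sim$isotopes, sim$guts, d)
  header <- readLines(file.path(d, "Consumer1.Sources.csv"), n = 1)
  expect_identical(
    gsub('"', "", header),
    paste(c("Sources", "Meand13C", "SDd13C", "Meand15N", "SDd15N",
            "tefd13C", "tefSDd13C", "tefd15N", "tefSDd15N",
            "conc13C", "conc15N"), collapse = ","))
})

test_that("identical configs produce byte-identical fixtures", {
  cfg <- sim_config(n_sources = 3, n_consumers = 2, seed = 13)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_community(cfg)
  write_fixture(s1$truth, s1$isotopes, s1$guts, d1)
  s2 <- simulate_community(cfg)
  write_fixture(s2$truth, s2$isotopes, s2$guts, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
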