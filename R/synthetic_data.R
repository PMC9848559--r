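# Synthetic reservoir communities with known true diets.
#
# The generator emulates the study design end to end: isotopically distinct
# basal/prey sources, consumers whose tissue isotope values follow the
# concentration-dependent mixing forward model with known diet proportions and
# TEFs, and per-gut volumetric compositions that are noisy around the true
# diet. All draws come from R's global RNG, seeded once per run, in documented
# order, so fixtures are byte-reproducible.

#' Configuration for a synthetic community
#'
#' @param n_sources Number of prey/resource taxa.
#' @param n_consumers Number of consumer (fish) taxa.
#' @param samples_per_taxon Tissue samples drawn per taxon (sources and
#'   consumers alike).
#' @param gut_samples_per_consumer Guts examined per consumer species.
#' @param source_mean_ranges List with elements `d13C` and `d15N`, each a
#'   length-2 interval (permil) from which source means are drawn uniformly.
#' @param source_sd Within-source signature SD per isotope (permil).
#' @param tef_d13C,tef_d15N Length-2 `c(mean, sd)` trophic enrichment factors
#'   (permil). The d13C default is the generic literature value 0.4 +/- 1.3.
#' @param residual_sd Consumer residual SD per isotope (permil), added on top
#'   of propagated source/TEF variance.
#' @param diet_concentration Symmetric Dirichlet concentration for the true
#'   diet vectors; also scales the precision of per-gut compositions around
#'   the true diet (larger = guts closer to the diet).
#' @param gut_drop_prob Probability that a diet item is absent from any one
#'   gut (the remainder is renormalised), so frequency of occurrence can be
#'   below 1.
#' @param use_concentration_dependence Use elemental concentrations in the
#'   mixture weights.
#' @param conc_C,conc_N Elemental concentrations given to every source when
#'   concentration dependence is on.
#' @param seed Integer seed for the whole run.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(n_sources = 3L, n_consumers = 3L,
                       samples_per_taxon = 10L,
                       gut_samples_per_consumer = 10L,
                       source_mean_ranges = list(d13C = c(-34, -18),
                                                 d15N = c(0, 12)),
                       source_sd = c(d13C = 1, d15N = 1),
                       tef_d13C = c(mean = 0.4, sd = 1.3),
                       tef_d15N = c(mean = 3.4, sd = 1.0),
                       residual_sd = c(d13C = 0.5, d15N = 0.5),
                       diet_concentration = 1,
                       gut_drop_prob = 0.3,
                       use_concentration_dependence = FALSE,
                       conc_C = 1, conc_N = 1,
                       seed = 1L) {
  cfg <- list(
    n_sources = assert_scalar_count(n_sources, "n_sources"),
    n_consumers = assert_scalar_count(n_consumers, "n_consumers"),
    samples_per_taxon = assert_scalar_count(samples_per_taxon,
                                            "samples_per_taxon"),
    gut_samples_per_consumer = assert_scalar_count(gut_samples_per_consumer,
                                                   "gut_samples_per_consumer"),
    source_mean_ranges = source_mean_ranges,
    source_sd = assert_nonneg(source_sd, "source_sd"),
    tef_d13C = tef_d13C, tef_d15N = tef_d15N,
    residual_sd = assert_nonneg(residual_sd, "residual_sd"),
    diet_concentration = diet_concentration,
    gut_drop_prob = gut_drop_prob,
    use_concentration_dependence = isTRUE(use_concentration_dependence),
    conc_C = conc_C, conc_N = conc_N,
    seed = as.integer(seed)
  )
  for (iso in isotope_names()) {
    rng <- source_mean_ranges[[iso]]
    if (is.null(rng) || length(rng) != 2L || any(is.na(rng))) {
      stop("source_mean_ranges must give a length-2 interval for ", iso,
           call. = FALSE)
    }
    if (cfg$n_sources > 1L && diff(range(rng)) <= 0) {
      stop("source_mean_ranges for ", iso,
           " is degenerate but n_sources > 1", call. = FALSE)
    }
  }
  if (cfg$diet_concentration <= 0) {
    stop("diet_concentration must be positive", call. = FALSE)
  }
  if (cfg$gut_drop_prob < 0 || cfg$gut_drop_prob >= 1) {
    stop("gut_drop_prob must be in [0, 1)", call. = FALSE)
  }
  assert_nonneg(cfg$tef_d13C[["sd"]], "tef_d13C sd")
  assert_nonneg(cfg$tef_d15N[["sd"]], "tef_d15N sd")
  if (cfg$conc_C < 0 || cfg$conc_N < 0) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Diet categories a synthetic source can stand for; recycled when
# n_sources exceeds the list. Keeps fixtures within the DS1 vocabulary.
source_category_rotation <- function() {
  c("periphyton", "phytoplankton", "plant", "zooplankton", "insect",
    "decapod", "mollusc", "fish", "hirudinea")
}

#' Assemble a community ground truth
#'
#' @param source_specs A [source_spec()] table.
#' @param true_diets Named list, one element per consumer: a named simplex
#'   vector over (a subset of) the source names.
#' @return A list with class `community_truth`.
#' @export
community_truth <- function(source_specs, true_diets) {
  source_specs <- validate_source_spec(source_specs)
  if (is.null(names(true_diets)) || any(names(true_diets) == "")) {
    stop("true_diets must be a named list (one element per consumer)",
         call. = FALSE)
  }
  for (cons in names(true_diets)) {
    p <- true_diets[[cons]]
    if (is.null(names(p))) {
      stop("diet vector for ", cons, " must be named by source", call. = FALSE)
    }
    unknown <- setdiff(names(p), source_specs$name)
    if (length(unknown)) {
      stop("diet of ", cons, " references unknown sources: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    assert_simplex(p, paste0("true_diets$", cons), tol = 1e-12)
  }
  structure(list(source_specs = source_specs,
                 true_diets = true_diets,
                 consumer_names = names(true_diets),
                 source_names = source_specs$name),
            class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat("Synthetic community truth:",
      length(x$source_names), "sources,",
      length(x$consumer_names), "consumers\n")
  invisible(x)
}

#' Generate a synthetic community with known diets
#'
#' Seeds the global RNG from `config$seed` and draws, in order: source d13C
#' means (uniform in range), source d15N means, then one Dirichlet diet per
#' consumer (via `n_sources` gamma draws each). Deterministic given the
#' config.
#'
#' @param config A [sim_config()].
#' @return A [community_truth()] object. Each source also carries a diet
#'   `category` attribute (column `category`) used when writing gut fixtures.
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  K <- config$n_sources
  mu_c <- stats::runif(K, config$source_mean_ranges$d13C[1],
                       config$source_mean_ranges$d13C[2])
  mu_n <- stats::runif(K, config$source_mean_ranges$d15N[1],
                       config$source_mean_ranges$d15N[2])
  src_names <- sprintf("Source%d", seq_len(K))
  conc_C <- if (config$use_concentration_dependence) config$conc_C else 1
  conc_N <- if (config$use_concentration_dependence) config$conc_N else 1
  specs <- source_spec(
    name = src_names,
    mean_d13C = mu_c, sd_d13C = config$source_sd[["d13C"]],
    mean_d15N = mu_n, sd_d15N = config$source_sd[["d15N"]],
    tef_d13C = config$tef_d13C[["mean"]],
    tef_sd_d13C = config$tef_d13C[["sd"]],
    tef_d15N = config$tef_d15N[["mean"]],
    tef_sd_d15N = config$tef_d15N[["sd"]],
    conc_C = conc_C, conc_N = conc_N
  )
  specs$category <- rep_len(source_category_rotation(), K)
  diets <- vector("list", config$n_consumers)
  names(diets) <- sprintf("Consumer%d", seq_len(config$n_consumers))
  for (i in seq_len(config$n_consumers)) {
    if (K == 1L) {
      p <- 1
    } else {
      g <- stats::rgamma(K, shape = config$diet_concentration, rate = 1)
      # guard against an all-zero gamma vector at tiny concentrations
      if (sum(g) == 0) g <- rep(1, K)
      p <- g / sum(g)
    }
    names(p) <- src_names
    diets[[i]] <- p
  }
  community_truth(specs, diets)
}

# Closed-form moments of the consumer mixture for one isotope.
# w_i = p_i q_i; mu = sum w (mu+tef) / sum w;
# var = sum w^2 (omega^2 + tau^2) / (sum w)^2  (+ residual added by caller).
mixture_moments_1d <- function(p, mu, omega, tef, tau, q) {
  w <- p * q
  s <- sum(w)
  if (s <= 0) stop("mixture weights sum to zero", call. = FALSE)
  list(mean = sum(w * (mu + tef)) / s,
       var = sum(w^2 * (omega^2 + tau^2)) / s^2)
}

#' Draw tissue isotope samples for every taxon
#'
#' Source taxa are sampled from their signature Normal; consumer taxa from
#' `Normal(mu_mix, sigma_mix)` of the concentration-dependent mixture forward
#' model with the residual SD folded in. Draws consume the current global RNG
#' stream (sources first in order, d13C then d15N per taxon, then consumers).
#'
#' @param truth A [community_truth()].
#' @param config The matching [sim_config()].
#' @return A `data.frame` with columns taxon, type ("source"/"consumer"),
#'   d13C, d15N.
#' @export
sample_isotopes <- function(truth, config) {
  stopifnot(inherits(truth, "community_truth"), inherits(config, "sim_config"))
  sp <- truth$source_specs
  if (any(sp$conc_C < 0) || any(sp$conc_N < 0)) {
    stop("negative elemental concentrations", call. = FALSE)
  }
  n <- config$samples_per_taxon
  out <- list()
  for (i in seq_len(nrow(sp))) {
    out[[length(out) + 1L]] <- data.frame(
      taxon = sp$name[i], type = "source",
      d13C = stats::rnorm(n, sp$mean_d13C[i], sp$sd_d13C[i]),
      d15N = stats::rnorm(n, sp$mean_d15N[i], sp$sd_d15N[i]),
      stringsAsFactors = FALSE
    )
  }
  for (cons in truth$consumer_names) {
    p <- truth$true_diets[[cons]]
    idx <- match(names(p), sp$name)
    mc <- mixture_moments_1d(p, sp$mean_d13C[idx], sp$sd_d13C[idx],
                             sp$tef_d13C[idx], sp$tef_sd_d13C[idx],
                             sp$conc_C[idx])
    mn <- mixture_moments_1d(p, sp$mean_d15N[idx], sp$sd_d15N[idx],
                             sp$tef_d15N[idx], sp$tef_sd_d15N[idx],
                             sp$conc_N[idx])
    out[[length(out) + 1L]] <- data.frame(
      taxon = cons, type = "consumer",
      d13C = stats::rnorm(n, mc$mean,
                          sqrt(mc$var + config$residual_sd[["d13C"]]^2)),
      d15N = stats::rnorm(n, mn$mean,
                          sqrt(mn$var + config$residual_sd[["d15N"]]^2)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Draw per-gut volumetric compositions for every consumer
#'
#' Each gut is a Dirichlet draw centred on the consumer's true diet with
#' precision `diet_concentration * n_items`; each item is then independently
#' dropped (set to zero volume) with probability `gut_drop_prob` and the rest
#' renormalised, so frequency of occurrence can fall below 1. Items with zero
#' true proportion get exact zero volume.
#'
#' @param truth A [community_truth()].
#' @param config The matching [sim_config()].
#' @return A `data.frame` with columns species, gut_id and one volumetric
#'   proportion column per source taxon.
#' @export
sample_guts <- function(truth, config) {
  stopifnot(inherits(truth, "community_truth"), inherits(config, "sim_config"))
  n_guts <- config$gut_samples_per_consumer
  items <- truth$source_names
  rows <- list()
  for (cons in truth$consumer_names) {
    p_full <- stats::setNames(numeric(length(items)), items)
    p_full[names(truth$true_diets[[cons]])] <- truth$true_diets[[cons]]
    alpha <- config$diet_concentration * length(items) * p_full
    for (g in seq_len(n_guts)) {
      x <- numeric(length(items))
      pos <- alpha > 0
      x[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
      drop <- stats::runif(length(items)) < config$gut_drop_prob
      x[drop] <- 0
      if (sum(x) == 0) {
        # keep the dominant true item rather than emit an empty gut
        x[which.max(p_full)] <- 1
      }
      comp <- stats::setNames(x / sum(x), items)
      rows[[length(rows) + 1L]] <- c(list(species = cons,
                                          gut_id = sprintf("%s_g%d", cons, g)),
                                     as.list(comp))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  names(out) <- c("species", "gut_id", items)
  out
}

#' Generate a full synthetic community in one call
#'
#' Convenience wrapper: seeds once, then runs [generate_community()],
#' [sample_isotopes()] and [sample_guts()] on the same stream.
#'
#' @param config A [sim_config()].
#' @return List with elements truth, isotopes, guts, config.
#' @export
simulate_community <- function(config) {
  truth <- generate_community(config)  # seeds the RNG
  isotopes <- sample_isotopes(truth, config)
  guts <- sample_guts(truth, config)
  list(truth = truth, isotopes = isotopes, guts = guts, config = config)
}

#' The reference synthetic community for parameter-recovery checks
#'
#' One consumer with true diet (0.7, 0.2, 0.1) over three well-separated,
#' non-collinear sources (the situation the study engineers by pooling taxa
#' into isotopically distinct units), with the study's generic d13C TEF
#' (0.4 +/- 1.3 permil), a fish-type d15N TEF (3.4 +/- 1.0 permil), source
#' SD 0.5 permil and residual SD 0.5 permil, and 30 tissue samples per
#' taxon.
#'
#' @param seed Seed stored in the configuration.
#' @return List: `truth` ([community_truth()]), `config` ([sim_config()]),
#'   `true_diet` (named vector).
#' @export
reference_community <- function(seed = 1L) {
  config <- sim_config(
    n_sources = 3L, n_consumers = 1L, samples_per_taxon = 30L,
    source_sd = c(d13C = 0.5, d15N = 0.5),
    tef_d13C = c(mean = 0.4, sd = 1.3),
    tef_d15N = c(mean = 3.4, sd = 1.0),
    residual_sd = c(d13C = 0.5, d15N = 0.5),
    seed = seed
  )
  src <- source_spec(
    name = c("SourceA", "SourceB", "SourceC"),
    mean_d13C = c(-32, -18, -26), sd_d13C = 0.5,
    mean_d15N = c(2, 4, 12), sd_d15N = 0.5,
    tef_d13C = 0.4, tef_sd_d13C = 1.3,
    tef_d15N = 3.4, tef_sd_d15N = 1.0
  )
  src$category <- source_category_rotation()[1:3]
  p <- c(SourceA = 0.7, SourceB = 0.2, SourceC = 0.1)
  truth <- community_truth(src, list(RefConsumer = p))
  list(truth = truth, config = config, true_diet = p)
}

#' Write a synthetic community in the study's file dialects
#'
#' Emits, per consumer, `<name>.csv` (columns D13C, D15N) and
#' `<name>.Sources.csv` with the eleven-column source dialect, plus one
#' flattened diet-composition CSV with the standard header (Reservoir,
#' Latitude, Longitude, Sampling period, Fish species, Replicates, and the
#' twelve diet-category columns). Source rows hold empirical mean/SD of the
#' generated source samples and the configured TEFs; gut compositions are
#' aggregated to species-level mean volumetric proportions under each
#' source's diet category.
#'
#' @param truth,isotopes,guts Output pieces of [simulate_community()].
#' @param dir Output directory (created if needed).
#' @param reservoir Label written in the diet table's Reservoir column.
#' @return Invisibly, the character vector of files written.
#' @export
write_fixture <- function(truth, isotopes, guts, dir,
                          reservoir = "SyntheticRes") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir,
                                      call. = FALSE)
  }
  sp <- truth$source_specs
  src_samples <- split(isotopes[isotopes$type == "source", ],
                       isotopes$taxon[isotopes$type == "source"])
  emp <- do.call(rbind, lapply(sp$name, function(nm) {
    s <- src_samples[[nm]]
    data.frame(name = nm,
               mean_d13C = mean(s$d13C), sd_d13C = stats::sd(s$d13C),
               mean_d15N = mean(s$d15N), sd_d15N = stats::sd(s$d15N),
               stringsAsFactors = FALSE)
  }))
  files <- character(0)
  for (cons in truth$consumer_names) {
    cs <- isotopes[isotopes$taxon == cons & isotopes$type == "consumer", ]
    f1 <- file.path(dir, paste0(cons, ".csv"))
    write_consumer_file(data.frame(D13C = cs$d13C, D15N = cs$d15N), f1)
    pool <- names(truth$true_diets[[cons]])
    idx <- match(pool, sp$name)
    eidx <- match(pool, emp$name)
    specs <- source_spec(
      name = pool,
      mean_d13C = emp$mean_d13C[eidx], sd_d13C = emp$sd_d13C[eidx],
      mean_d15N = emp$mean_d15N[eidx], sd_d15N = emp$sd_d15N[eidx],
      tef_d13C = sp$tef_d13C[idx], tef_sd_d13C = sp$tef_sd_d13C[idx],
      tef_d15N = sp$tef_d15N[idx], tef_sd_d15N = sp$tef_sd_d15N[idx],
      conc_C = sp$conc_C[idx], conc_N = sp$conc_N[idx]
    )
    f2 <- file.path(dir, paste0(cons, ".Sources.csv"))
    write_sources_file(specs, f2)
    files <- c(files, f1, f2)
  }
  diet <- fixture_diet_table(truth, guts, reservoir)
  f3 <- file.path(dir, "diet_composition.csv")
  write_diet_table(diet, f3)
  invisible(c(files, f3))
}

# Species-level mean volumetric proportions per diet category, in the
# twelve-column dialect, from gut-level records over source taxa.
fixture_diet_table <- function(truth, guts, reservoir) {
  cats <- diet_categories()
  sp <- truth$source_specs
  cat_of <- stats::setNames(sp$category %||% rep_len(source_category_rotation(),
                                                     nrow(sp)),
                            sp$name)
  rows <- lapply(truth$consumer_names, function(cons) {
    g <- guts[guts$species == cons, truth$source_names, drop = FALSE]
    vo <- colMeans(g)
    by_cat <- stats::setNames(numeric(length(cats)), cats)
    for (nm in names(vo)) {
      by_cat[cat_of[[nm]]] <- by_cat[cat_of[[nm]]] + vo[[nm]]
    }
    c(list(Reservoir = reservoir, Latitude = "1.21", Longitude = "103.49",
           `Sampling period` = "synthetic", `Fish species` = cons,
           Replicates = sum(guts$species == cons)),
      as.list(by_cat))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  names(out) <- c("Reservoir", "Latitude", "Longitude", "Sampling period",
                  "Fish species", "Replicates", cats)
  out
}
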