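# Bayesian two-isotope concentration-dependent mixing model (the
# SIAR/simmr model class), written out in full: likelihood, priors, an
# adaptive random-walk Metropolis sampler on transformed parameters,
# Gelman-Rubin convergence diagnostics, posterior summaries, and a
# simplex-grid integration oracle used for testing.

#' Set up a mixing problem
#'
#' @param consumers Consumer tissue samples: `data.frame` (or matrix) with
#'   columns `d13C`, `d15N`.
#' @param sources A [source_spec()] table (at least 2 rows for inference).
#' @param concentration_dependent Weight sources by elemental concentration.
#' @return List with class `mixing_problem`.
#' @export
mixing_problem <- function(consumers, sources,
                           concentration_dependent = FALSE) {
  sources <- validate_source_spec(sources)
  y <- as.matrix(as.data.frame(consumers)[, c("d13C", "d15N")])
  if (nrow(y) < 1L || any(!is.finite(y))) {
    stop("consumer samples must be finite and non-empty", call. = FALSE)
  }
  if (nrow(y) < 3L) {
    warning("fewer than 3 consumer samples: the residual SD is poorly ",
            "informed", call. = FALSE)
  }
  mu <- cbind(sources$mean_d13C, sources$mean_d15N)
  omega <- cbind(sources$sd_d13C, sources$sd_d15N)
  delta <- cbind(sources$tef_d13C, sources$tef_d15N)
  tau <- cbind(sources$tef_sd_d13C, sources$tef_sd_d15N)
  if (any(!is.finite(mu)) || any(!is.finite(omega))) {
    stop("source signatures must be finite", call. = FALSE)
  }
  q <- if (concentration_dependent) {
    cbind(sources$conc_C, sources$conc_N)
  } else {
    matrix(1, nrow(sources), 2)
  }
  if (any(q <= 0)) {
    stop("concentration dependence requires positive concentrations",
         call. = FALSE)
  }
  structure(list(y = y, mu = mu, omega = omega, delta = delta, tau = tau,
                 q = q, source_names = sources$name,
                 n_sources = nrow(sources),
                 concentration_dependent = concentration_dependent),
            class = "mixing_problem")
}

#' @export
print.mixing_problem <- function(x, ...) {
  cat("Mixing problem:", nrow(x$y), "consumer samples,",
      x$n_sources, "sources",
      if (x$concentration_dependent) "(concentration-dependent)" else "",
      "\n")
  invisible(x)
}

# Mixture mean and source+TEF variance per isotope for one p.
problem_moments <- function(p, problem) {
  w <- p * problem$q                       # N x 2
  s <- colSums(w)
  mu_mix <- colSums(w * (problem$mu + problem$delta)) / s
  var_mix <- colSums(w^2 * (problem$omega^2 + problem$tau^2)) / s^2
  list(mean = mu_mix, var = var_mix)
}

#' Log posterior density of the mixing model
#'
#' Gaussian likelihood with mixture mean
#' `mu_k = sum_i p_i q_ik (mu_ik + tef_ik) / sum_i p_i q_ik` and variance
#' `sum_i p_i^2 q_ik^2 (omega_ik^2 + tau_ik^2) / (sum_i p_i q_ik)^2 +
#' sigma_k^2` per isotope k; a flat Dirichlet(1,...,1) prior on the diet
#' proportions and independent half-Normal(0, `sigma_prior_sd`) priors on
#' the residual SDs.
#'
#' @param p Diet-proportion simplex vector over the problem's sources.
#' @param sigma Length-2 positive residual SDs (d13C, d15N).
#' @param problem A [mixing_problem()].
#' @param sigma_prior_sd Scale of the half-Normal prior (permil).
#' @return Log density (finite for all valid inputs).
#' @export
log_posterior <- function(p, sigma, problem, sigma_prior_sd = 10) {
  assert_simplex(p, "p")
  if (length(p) != problem$n_sources) {
    stop("p has length ", length(p), " but the problem has ",
         problem$n_sources, " sources", call. = FALSE)
  }
  if (length(sigma) != 2L || any(sigma <= 0)) {
    stop("sigma must be two positive residual SDs", call. = FALSE)
  }
  mm <- problem_moments(p, problem)
  sdk <- sqrt(mm$var + sigma^2)
  ll <- sum(stats::dnorm(problem$y[, 1], mm$mean[1], sdk[1], log = TRUE)) +
    sum(stats::dnorm(problem$y[, 2], mm$mean[2], sdk[2], log = TRUE))
  lp_prior <- lgamma(problem$n_sources) +  # Dirichlet(1,...,1) density
    sum(stats::dnorm(sigma, 0, sigma_prior_sd, log = TRUE) + log(2))
  ll + lp_prior
}

#' MCMC settings
#'
#' Defaults follow the study protocol: 30,000 iterations per model with a
#' burn-in of 10,000, four chains (at least two are needed for the
#' Gelman-Rubin check), thinning by 10.
#'
#' @param iterations,burn_in,chains,thin Integer MCMC controls.
#' @param seed Integer seed; each chain uses a distinct stream derived from
#'   it.
#' @param proposal_scale Initial random-walk scale, adapted during burn-in.
#' @param sigma_prior_sd Half-Normal prior scale for residual SDs (permil).
#' @return List with class `mcmc_settings`.
#' @export
mcmc_settings <- function(iterations = 30000L, burn_in = 10000L,
                          chains = 4L, thin = 10L, seed = 1L,
                          proposal_scale = 0.5, sigma_prior_sd = 10) {
  s <- list(iterations = assert_scalar_count(iterations, "iterations"),
            burn_in = assert_scalar_count(burn_in, "burn_in", min = 0L),
            chains = assert_scalar_count(chains, "chains", min = 2L),
            thin = assert_scalar_count(thin, "thin"),
            seed = as.integer(seed),
            proposal_scale = proposal_scale,
            sigma_prior_sd = sigma_prior_sd)
  if (s$burn_in >= s$iterations) {
    stop("burn_in must be smaller than iterations", call. = FALSE)
  }
  if ((s$iterations - s$burn_in) %/% s$thin < 1L) {
    stop("settings leave zero post-thinning draws", call. = FALSE)
  }
  class(s) <- "mcmc_settings"
  s
}

# theta = (z_1..z_{N-1}, log sigma_1, log sigma_2); p = alr^{-1}(z).
theta_to_state <- function(theta, N) {
  if (N > 1L) {
    z <- theta[seq_len(N - 1L)]
    e <- exp(c(z, 0))
    p <- e / sum(e)
  } else {
    p <- 1
  }
  sigma <- exp(theta[N:(N + 1L)])
  list(p = p, sigma = sigma)
}

# log posterior in theta space: adds the ALR log-Jacobian sum(log p) and the
# log-sigma Jacobians.
log_posterior_theta <- function(theta, problem, sigma_prior_sd) {
  st <- theta_to_state(theta, problem$n_sources)
  if (any(st$p <= 0) || any(!is.finite(st$sigma))) return(-Inf)
  lp <- log_posterior(st$p, st$sigma, problem, sigma_prior_sd)
  jac <- if (problem$n_sources > 1L) sum(log(st$p)) else 0
  lp + jac + sum(log(st$sigma))
}

#' Run the adaptive Metropolis sampler
#'
#' Random-walk Metropolis on the additive log-ratio transform of the diet
#' proportions and the log residual SDs, with the transform Jacobians in the
#' target. The proposal scale adapts in batches of 50 during burn-in towards
#' an acceptance rate of roughly 0.2-0.4 and is frozen afterwards. Each chain
#' runs on its own seeded stream, so output is deterministic given the
#' settings.
#'
#' @param problem A [mixing_problem()].
#' @param settings An [mcmc_settings()].
#' @return `posterior_draws` object: per-chain matrices of retained draws
#'   (diet proportions by source plus `sigma_d13C`, `sigma_d15N`), post
#'   burn-in acceptance rates, and the settings used.
#' @export
run_mcmc <- function(problem, settings = mcmc_settings()) {
  stopifnot(inherits(problem, "mixing_problem"),
            inherits(settings, "mcmc_settings"))
  N <- problem$n_sources
  d <- (N - 1L) + 2L
  n_keep <- (settings$iterations - settings$burn_in) %/% settings$thin
  par_names <- c(problem$source_names, "sigma_d13C", "sigma_d15N")
  # data-driven deterministic init for the residual SDs
  sd0 <- apply(problem$y, 2, stats::sd)
  sd0[!is.finite(sd0) | sd0 < 0.1] <- 1
  chains <- vector("list", settings$chains)
  acc_rates <- numeric(settings$chains)
  for (ch in seq_len(settings$chains)) {
    set.seed(settings$seed + 7919L * (ch - 1L))
    theta <- c(rep(0, N - 1L), log(sd0))
    scale <- settings$proposal_scale
    lp_cur <- log_posterior_theta(theta, problem, settings$sigma_prior_sd)
    draws <- matrix(NA_real_, n_keep, N + 2L,
                    dimnames = list(NULL, par_names))
    kept <- 0L
    acc_batch <- 0L
    acc_post <- 0L
    n_post <- 0L
    for (it in seq_len(settings$iterations)) {
      prop <- theta + scale * stats::rnorm(d)
      lp_prop <- log_posterior_theta(prop, problem, settings$sigma_prior_sd)
      if (log(stats::runif(1)) < lp_prop - lp_cur) {
        theta <- prop
        lp_cur <- lp_prop
        acc_batch <- acc_batch + 1L
        if (it > settings$burn_in) acc_post <- acc_post + 1L
      }
      if (it > settings$burn_in) n_post <- n_post + 1L
      if (it <= settings$burn_in && it %% 50L == 0L) {
        rate <- acc_batch / 50
        if (rate > 0.35) scale <- scale * exp(0.2)
        if (rate < 0.20) scale <- scale * exp(-0.2)
        acc_batch <- 0L
      }
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0L) {
        kept <- kept + 1L
        st <- theta_to_state(theta, N)
        draws[kept, ] <- c(st$p, st$sigma)
      }
    }
    chains[[ch]] <- draws[seq_len(kept), , drop = FALSE]
    acc_rates[ch] <- acc_post / n_post
  }
  structure(list(chains = chains, acceptance = acc_rates,
                 source_names = problem$source_names,
                 settings = settings),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chains x",
      nrow(x$chains[[1]]), "retained draws over",
      length(x$source_names), "sources; mean acceptance",
      sprintf("%.2f", mean(x$acceptance)), "\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance diagnostic: with m chains of n
#' draws, `W` the mean within-chain variance and `B/n` the variance of chain
#' means, `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Parameters with
#' `Rhat > threshold` are flagged. Constant parameters (zero variance
#' everywhere) report 1.
#'
#' @param draws A `posterior_draws` object (>= 2 chains, >= 10 draws each).
#' @param threshold Flagging threshold (default 1.1).
#' @return Named Rhat vector with attribute `flagged`.
#' @export
gelman_rubin <- function(draws, threshold = 1.1) {
  chains <- draws$chains
  if (length(chains) < 2L) {
    stop("Gelman-Rubin requires at least 2 chains", call. = FALSE)
  }
  n <- min(vapply(chains, nrow, integer(1)))
  if (n < 10L) stop("need at least 10 draws per chain", call. = FALSE)
  pars <- colnames(chains[[1]])
  rhat <- vapply(pars, function(par) {
    x <- vapply(chains, function(ch) ch[seq_len(n), par], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B_over_n <- stats::var(colMeans(x))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  attr(rhat, "flagged") <- names(rhat)[rhat > threshold]
  rhat
}

#' Summarise posterior diet proportions
#'
#' Chains are pooled; per source the posterior median and central 95%
#' credible interval are reported, plus medians renormalised to sum to 1
#' (the value entered in the predation matrix).
#'
#' @param draws A `posterior_draws` object.
#' @return `data.frame`: source, median, q2.5, q97.5, median_renorm, rhat.
#' @export
posterior_summary <- function(draws) {
  pooled <- do.call(rbind, draws$chains)
  rhat <- tryCatch(gelman_rubin(draws), error = function(e) NULL)
  src <- draws$source_names
  med <- apply(pooled[, src, drop = FALSE], 2, stats::median)
  qs <- apply(pooled[, src, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975))
  data.frame(source = src,
             median = unname(med),
             q2.5 = unname(qs[1, ]),
             q97.5 = unname(qs[2, ]),
             median_renorm = unname(med / sum(med)),
             rhat = if (is.null(rhat)) NA_real_ else unname(rhat[src]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Posterior means by brute-force grid integration
#'
#' Evaluates the exact unnormalised posterior on a simplex lattice of diet
#' proportions crossed with a residual-SD grid and returns normalised
#' posterior means of the proportions. Because the likelihood factorises
#' over isotopes and each residual SD touches one isotope only, the SD grid
#' is integrated out per isotope before combining. Supports 2 or 3 sources.
#'
#' @param problem A [mixing_problem()] with <= 3 sources.
#' @param resolution Simplex grid step (cell midpoints; default 0.005 for 2
#'   sources, 0.02 for 3).
#' @param sigma_grid Residual-SD grid (permil).
#' @param sigma_prior_sd Half-Normal prior scale, matching [log_posterior()].
#' @return List: `mean` (named posterior means), `n_grid` (lattice size).
#' @export
grid_posterior_oracle <- function(problem, resolution = NULL,
                                  sigma_grid = seq(0.02, 6, length.out = 80),
                                  sigma_prior_sd = 10) {
  N <- problem$n_sources
  if (N > 3L) stop("grid oracle supports at most 3 sources", call. = FALSE)
  if (N < 2L) stop("grid oracle needs at least 2 sources", call. = FALSE)
  h <- resolution %||% if (N == 2L) 0.005 else 0.02
  mids <- seq(h / 2, 1 - h / 2, by = h)
  if (N == 2L) {
    P <- cbind(mids, 1 - mids)
  } else {
    g <- expand.grid(p1 = mids, p2 = mids)
    g <- g[g$p1 + g$p2 < 1, ]
    P <- cbind(g$p1, g$p2, 1 - g$p1 - g$p2)
  }
  colnames(P) <- problem$source_names
  # per-isotope marginal log-likelihood over the sigma grid
  log_prior_sigma <- stats::dnorm(sigma_grid, 0, sigma_prior_sd, log = TRUE) +
    log(2)
  total <- numeric(nrow(P))
  for (k in 1:2) {
    qk <- problem$q[, k]
    s <- as.numeric(P %*% qk)
    mu_mix <- as.numeric(P %*% (qk * (problem$mu[, k] + problem$delta[, k]))) / s
    var_src <- as.numeric(P^2 %*% (qk^2 * (problem$omega[, k]^2 +
                                             problem$tau[, k]^2))) / s^2
    yk <- problem$y[, k]
    nk <- length(yk)
    ss <- nk * mu_mix^2 - 2 * mu_mix * sum(yk) + sum(yk^2)
    ll_sig <- matrix(NA_real_, nrow(P), length(sigma_grid))
    for (j in seq_along(sigma_grid)) {
      v <- var_src + sigma_grid[j]^2
      ll_sig[, j] <- -0.5 * nk * log(2 * pi * v) - ss / (2 * v) +
        log_prior_sigma[j]
    }
    total <- total + apply(ll_sig, 1, log_sum_exp)
  }
  w <- exp(total - log_sum_exp(total))
  means <- colSums(P * w)
  list(mean = stats::setNames(means, problem$source_names), n_grid = nrow(P))
}
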