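# Feasibility screening with simulated mixing polygons, threshold-based
# source pruning, and assembly of the prey x predator predation matrix.

# TEF-adjusted source means and propagated SDs in (d13C, d15N) space.
adjusted_source_geometry <- function(sources) {
  list(mean = cbind(sources$mean_d13C + sources$tef_d13C,
                    sources$mean_d15N + sources$tef_d15N),
       sd = cbind(sqrt(sources$sd_d13C^2 + sources$tef_sd_d13C^2),
                  sqrt(sources$sd_d15N^2 + sources$tef_sd_d15N^2)))
}

# Are points inside (or on the boundary of) the convex hull of `verts`?
# `verts` are hull vertices in order (output of chull). Degenerate hulls
# (all vertices collinear) fall back to a distance-to-segment test.
points_in_hull <- function(pts, verts, segment_tol = 0.5) {
  nv <- nrow(verts)
  if (nv >= 3L) {
    # check the hull really is 2-D (chull output can still be collinear
    # only when all input points are; guard anyway)
    area2 <- 0
    for (i in seq_len(nv)) {
      j <- i %% nv + 1L
      area2 <- area2 + verts[i, 1] * verts[j, 2] - verts[j, 1] * verts[i, 2]
    }
    if (abs(area2) > 1e-12) {
      inside <- rep(TRUE, nrow(pts))
      orient <- sign(area2)
      for (i in seq_len(nv)) {
        j <- i %% nv + 1L
        ex <- verts[j, 1] - verts[i, 1]
        ey <- verts[j, 2] - verts[i, 2]
        cross <- ex * (pts[, 2] - verts[i, 2]) - ey * (pts[, 1] - verts[i, 1])
        inside <- inside & (orient * cross >= -1e-12)
      }
      return(inside)
    }
  }
  # collinear / two-point case: distance to the spanning segment
  d2 <- as.matrix(stats::dist(verts))
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  a <- verts[ij[1], ]
  b <- verts[ij[2], ]
  ab <- b - a
  len2 <- sum(ab^2)
  t <- if (len2 == 0) rep(0, nrow(pts)) else
    pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                       (pts[, 2] - a[2]) * ab[2]) / len2))
  dx <- pts[, 1] - (a[1] + t * ab[1])
  dy <- pts[, 2] - (a[2] + t * ab[2])
  sqrt(dx^2 + dy^2) <= segment_tol
}

#' Monte-Carlo mixing-polygon feasibility check
#'
#' Per iterate, each source's TEF-adjusted mean is resampled from
#' `Normal(mu + tef, sqrt(omega^2 + tau^2))` per isotope, the convex hull of
#' the resampled sources is formed, and each consumer point is tested for
#' containment (boundary counts as inside). A sample's inside-probability is
#' the fraction of iterates containing it; the consumer passes when the mean
#' probability over samples (or the probability of the sample mean, mode
#' `"per_mean"`) reaches `min_prob`. Two-source or collinear geometries
#' degrade to a distance-to-segment test with tolerance `segment_tol`.
#'
#' @param consumers Consumer samples (columns `d13C`, `d15N`).
#' @param sources A [source_spec()] table (>= 2 rows).
#' @param mc_iters Monte-Carlo iterates (< 100 warns).
#' @param seed Seed for the resampling.
#' @param min_prob Acceptance level on the inside-probability (default 0.05).
#' @param mode `"per_sample"` (default) or `"per_mean"`.
#' @param segment_tol Permil tolerance for degenerate (segment) geometries.
#' @return List with class `mixing_polygon_report`: per-sample
#'   probabilities, the mean probability, and the pass flag.
#' @export
mixing_polygon_check <- function(consumers, sources, mc_iters = 1000L,
                                 seed = 1L, min_prob = 0.05,
                                 mode = c("per_sample", "per_mean"),
                                 segment_tol = 0.5) {
  mode <- match.arg(mode)
  sources <- validate_source_spec(sources)
  if (nrow(sources) < 2L) {
    stop("mixing polygon needs at least 2 sources", call. = FALSE)
  }
  if (mc_iters < 100L) {
    warning("fewer than 100 Monte-Carlo iterates gives a coarse ",
            "inside-probability", call. = FALSE)
  }
  y <- as.matrix(as.data.frame(consumers)[, c("d13C", "d15N")])
  pts <- if (mode == "per_mean") matrix(colMeans(y), 1) else y
  geo <- adjusted_source_geometry(sources)
  K <- nrow(sources)
  set.seed(seed)
  hits <- numeric(nrow(pts))
  for (it in seq_len(mc_iters)) {
    sim <- matrix(stats::rnorm(2L * K, mean = geo$mean, sd = geo$sd), K, 2)
    verts <- sim[grDevices::chull(sim), , drop = FALSE]
    hits <- hits + points_in_hull(pts, verts, segment_tol)
  }
  prob <- hits / mc_iters
  structure(list(probability = prob, mean_probability = mean(prob),
                 pass = mean(prob) >= min_prob, mode = mode,
                 mc_iters = mc_iters, min_prob = min_prob),
            class = "mixing_polygon_report")
}

#' @export
print.mixing_polygon_report <- function(x, ...) {
  cat(sprintf("Mixing polygon check (%s): mean inside-probability %.3f -> %s\n",
              x$mode, x$mean_probability, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Sequentially prune unimportant sources from a consumer's model
#'
#' Repeats: fit the mixing model, compute the threshold `0.25 / N` for the
#' current source count N, and collect sources whose renormalised posterior
#' median falls below it. If any, the single lowest contributor is removed,
#' provided the reduced source set still passes the mixing-polygon check —
#' otherwise that source is restored, marked protected, and the next-lowest
#' candidate is tried. After each removal the model is refitted (the
#' threshold depends on N). The loop refuses to go below `min_sources`
#' sources and records every decision in an audit trail.
#'
#' @param consumers Consumer samples (columns `d13C`, `d15N`).
#' @param sources Initial [source_spec()] pool (must pass the polygon
#'   check).
#' @param settings [mcmc_settings()] used for every fit.
#' @param concentration_dependent Passed to [mixing_problem()].
#' @param polygon_args List of arguments for [mixing_polygon_check()]
#'   (mc_iters, seed, min_prob, mode, segment_tol).
#' @param min_sources Smallest admissible source count (default 2).
#' @return List with class `prune_result`: final `sources`, final `draws`,
#'   final `summary`, and the `audit` data.frame (step, action, source,
#'   median, threshold, n_sources).
#' @export
prune_sources <- function(consumers, sources, settings = mcmc_settings(),
                          concentration_dependent = FALSE,
                          polygon_args = list(), min_sources = 2L) {
  sources <- validate_source_spec(sources)
  poly <- function(src) {
    do.call(mixing_polygon_check,
            c(list(consumers = consumers, sources = src), polygon_args))
  }
  if (!poly(sources)$pass) {
    stop("initial source pool fails the mixing-polygon feasibility check",
         call. = FALSE)
  }
  audit <- list()
  protected <- character(0)
  step <- 0L
  repeat {
    problem <- mixing_problem(consumers, sources, concentration_dependent)
    draws <- run_mcmc(problem, settings)
    summ <- posterior_summary(draws)
    N <- nrow(sources)
    threshold <- 0.25 / N
    below <- summ[summ$median_renorm < threshold &
                    !summ$source %in% protected, ]
    if (N <= min_sources || nrow(below) == 0L) break
    below <- below[order(below$median_renorm), ]
    removed <- FALSE
    for (i in seq_len(nrow(below))) {
      cand <- below$source[i]
      reduced <- sources[sources$name != cand, , drop = FALSE]
      step <- step + 1L
      if (poly(reduced)$pass) {
        audit[[length(audit) + 1L]] <- data.frame(
          step = step, action = "removed", source = cand,
          median = below$median_renorm[i], threshold = threshold,
          n_sources = N, stringsAsFactors = FALSE)
        sources <- validate_source_spec(reduced)
        removed <- TRUE
        break
      } else {
        audit[[length(audit) + 1L]] <- data.frame(
          step = step, action = "protected", source = cand,
          median = below$median_renorm[i], threshold = threshold,
          n_sources = N, stringsAsFactors = FALSE)
        protected <- c(protected, cand)
      }
    }
    if (!removed) break
  }
  audit_df <- if (length(audit)) do.call(rbind, audit) else
    data.frame(step = integer(0), action = character(0),
               source = character(0), median = numeric(0),
               threshold = numeric(0), n_sources = integer(0))
  structure(list(sources = sources, draws = draws, summary = summ,
                 audit = audit_df, protected = protected),
            class = "prune_result")
}

#' Replay a pruning audit trail
#'
#' Applies the recorded removals to the initial pool and refits once with
#' the same settings; with identical seeds this reproduces the final
#' posterior summary exactly.
#'
#' @param audit Audit `data.frame` from [prune_sources()].
#' @param consumers,sources,settings,concentration_dependent As in the
#'   original call.
#' @return The refitted [posterior_summary()] on the final source set.
#' @export
replay_audit <- function(audit, consumers, sources,
                         settings = mcmc_settings(),
                         concentration_dependent = FALSE) {
  removed <- audit$source[audit$action == "removed"]
  final <- sources[!sources$name %in% removed, , drop = FALSE]
  problem <- mixing_problem(consumers, validate_source_spec(final),
                            concentration_dependent)
  posterior_summary(run_mcmc(problem, settings))
}

#' Assemble the prey x predator predation matrix
#'
#' One column per consumer, holding its renormalised posterior medians over
#' its surviving sources; absent links are exact zeros. Rows cover the union
#' of all sources plus any extra registry taxa (e.g. pure producers that
#' survive in no model).
#'
#' @param summaries Named list: consumer -> [posterior_summary()]
#'   `data.frame`.
#' @param taxa Optional character registry of all taxa; every consumer
#'   source must resolve to it.
#' @return Numeric matrix with class `predation_matrix` (rows prey, columns
#'   predators).
#' @export
assemble_matrix <- function(summaries, taxa = NULL) {
  if (is.null(names(summaries)) || anyDuplicated(names(summaries))) {
    stop("summaries must be uniquely named by consumer", call. = FALSE)
  }
  all_sources <- unique(unlist(lapply(summaries, `[[`, "source")))
  if (is.null(taxa)) {
    taxa <- union(all_sources, names(summaries))
  } else {
    if (anyDuplicated(taxa)) stop("duplicate taxon labels", call. = FALSE)
    unresolved <- setdiff(all_sources, taxa)
    if (length(unresolved)) {
      stop("sources not in the taxon registry: ",
           paste(unresolved, collapse = ", "), call. = FALSE)
    }
  }
  prey <- intersect(taxa, union(all_sources, setdiff(taxa, names(summaries))))
  mat <- matrix(0, nrow = length(prey), ncol = length(summaries),
                dimnames = list(prey, names(summaries)))
  for (cons in names(summaries)) {
    s <- summaries[[cons]]
    mat[s$source, cons] <- s$median_renorm
  }
  validate_predation_matrix(mat)
}

validate_predation_matrix <- function(mat, tol = 1e-6) {
  if (!is.matrix(mat) || is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("predation matrix must have row (prey) and column (predator) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat))) {
    stop("duplicate taxon labels in the predation matrix", call. = FALSE)
  }
  if (any(mat < -tol) || any(mat > 1 + tol)) {
    stop("predation matrix entries must lie in [0, 1]", call. = FALSE)
  }
  cs <- colSums(mat)
  bad <- cs > tol & abs(cs - 1) > tol
  if (any(bad)) {
    stop("consumer columns must sum to 1: ",
         paste(colnames(mat)[bad], collapse = ", "), call. = FALSE)
  }
  class(mat) <- c("predation_matrix", class(unclass(mat)))
  mat
}
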