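# Isotope sample preparation: lipid normalisation, TEF attachment,
# statistical pooling of isotopically indistinct taxa, source summaries,
# and the imputed "unknown producer" basal node.

#' Lipid-normalise whole-body d13C values
#'
#' Whole-body samples (small invertebrates analysed whole) are enriched in
#' lipids, which are depleted in 13C. The arithmetic normalisation for
#' aquatic animals, `d13C' = d13C - 3.32 + 0.99 * C:N`, is applied when the
#' sample's C:N ratio exceeds 3.5; below that, tissue is lean enough to leave
#' unchanged. d15N is never altered and the correction is applied at most
#' once (tracked in the `lipid_corrected` column).
#'
#' @param samples `data.frame` with columns `d13C`, `d15N`, and logical
#'   `whole_body`; `c_to_n` required (non-NA) wherever `whole_body` is TRUE.
#' @return The samples with corrected `d13C` and a `lipid_corrected` column.
#' @export
lipid_correct <- function(samples) {
  if (is.null(samples$whole_body)) samples$whole_body <- FALSE
  if (is.null(samples$c_to_n)) samples$c_to_n <- NA_real_
  if (is.null(samples$lipid_corrected)) samples$lipid_corrected <- FALSE
  bad <- samples$whole_body & is.na(samples$c_to_n)
  if (any(bad)) {
    stop("whole-body samples without a C:N ratio (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  if (any(samples$c_to_n <= 0, na.rm = TRUE)) {
    stop("C:N ratios must be positive", call. = FALSE)
  }
  sel <- samples$whole_body & !samples$lipid_corrected &
    !is.na(samples$c_to_n) & samples$c_to_n > 3.5
  samples$d13C[sel] <- samples$d13C[sel] - 3.32 + 0.99 * samples$c_to_n[sel]
  samples$lipid_corrected[sel] <- TRUE
  samples
}

#' Default taxon-group d15N trophic enrichment factors
#'
#' Literature-style per-trophic-step d15N discrimination values (permil),
#' used when no study-specific table is supplied: fish 3.4 +/- 1.0,
#' invertebrates 2.5 +/- 1.0, primary consumers of algae 2.2 +/- 1.0.
#'
#' @return `data.frame` with columns taxon_group, tef_d15N_mean, tef_d15N_sd.
#' @export
default_tef_table <- function() {
  data.frame(
    taxon_group = c("fish", "invertebrate", "primary_consumer"),
    tef_d15N_mean = c(3.4, 2.5, 2.2),
    tef_d15N_sd = c(1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
}

#' Attach trophic enrichment factors to source summaries
#'
#' d15N TEFs are taxon-group specific (looked up per source); d13C uses the
#' generic 0.4 +/- 1.3 permil unless overridden.
#'
#' @param source_summaries `data.frame` with columns name, mean_d13C,
#'   sd_d13C, mean_d15N, sd_d15N (e.g. from [summarize_sources()]).
#' @param groups Named character vector: source name -> taxon group.
#' @param tef_table TEF lookup (see [default_tef_table()]).
#' @param generic_d13C Length-2 `c(mean, sd)` d13C TEF.
#' @param fallback_group Group used for sources missing from `groups`;
#'   `NULL` makes a missing entry an error.
#' @param conc_C,conc_N Elemental concentrations attached to every source.
#' @return A [source_spec()] table.
#' @export
attach_tefs <- function(source_summaries, groups,
                        tef_table = default_tef_table(),
                        generic_d13C = c(mean = 0.4, sd = 1.3),
                        fallback_group = NULL,
                        conc_C = 1, conc_N = 1) {
  nm <- source_summaries$name
  grp <- groups[nm]
  if (!is.null(fallback_group)) grp[is.na(grp)] <- fallback_group
  if (any(is.na(grp))) {
    stop("no taxon group (and no fallback) for sources: ",
         paste(nm[is.na(grp)], collapse = ", "), call. = FALSE)
  }
  idx <- match(grp, tef_table$taxon_group)
  if (any(is.na(idx))) {
    stop("taxon groups missing from the TEF table: ",
         paste(unique(grp[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  source_spec(
    name = nm,
    mean_d13C = source_summaries$mean_d13C,
    sd_d13C = source_summaries$sd_d13C,
    mean_d15N = source_summaries$mean_d15N,
    sd_d15N = source_summaries$sd_d15N,
    tef_d13C = generic_d13C[["mean"]], tef_sd_d13C = generic_d13C[["sd"]],
    tef_d15N = tef_table$tef_d15N_mean[idx],
    tef_sd_d15N = tef_table$tef_d15N_sd[idx],
    conc_C = conc_C, conc_N = conc_N
  )
}

# Per-isotope p-value for a set of taxa: Welch t-test for pairs,
# one-way ANOVA for larger sets.
isotope_test_p <- function(values, taxa) {
  k <- length(unique(taxa))
  if (k == 2L) {
    stats::t.test(values ~ factor(taxa))$p.value
  } else {
    fit <- stats::aov(values ~ factor(taxa))
    summary(fit)[[1]][["Pr(>F)"]][1]
  }
}

#' Pool isotopically indistinct taxa
#'
#' For each candidate set (e.g. congeneric fishes, to be pooled to genus), a
#' two-sample Welch t-test (pairs) or one-way ANOVA (larger sets) is run per
#' isotope. Under the default rule `"pool_unless_distinct"`, the set is
#' pooled when neither isotope differs significantly (p >= alpha on both) —
#' the taxa cannot be statistically separated. The alternative literal rule
#' `"pool_if_overlap"` pools when both isotope tests are significant.
#' Pooling relabels taxa; it never drops samples.
#'
#' @param samples `data.frame` with columns taxon, d13C, d15N.
#' @param candidate_sets Named list: pooled label -> character vector of
#'   member taxa.
#' @param alpha Significance level (default 0.05).
#' @param rule Pooling decision rule (see above).
#' @return List: `samples` (with pooled taxon labels), `assignment` (named
#'   vector old -> new label), `report` (per-set p-values and decision).
#' @export
pool_taxa <- function(samples, candidate_sets, alpha = 0.05,
                      rule = c("pool_unless_distinct", "pool_if_overlap")) {
  rule <- match.arg(rule)
  assignment <- stats::setNames(unique(samples$taxon), unique(samples$taxon))
  report <- list()
  for (label in names(candidate_sets)) {
    members <- intersect(candidate_sets[[label]], samples$taxon)
    counts <- table(samples$taxon[samples$taxon %in% members])
    small <- names(counts)[counts < 2]
    if (length(small)) {
      warning("excluding taxa with < 2 samples from pooling set '", label,
              "': ", paste(small, collapse = ", "), call. = FALSE)
      members <- setdiff(members, small)
    }
    if (length(members) < 2L) next
    sub <- samples[samples$taxon %in% members, ]
    p13 <- isotope_test_p(sub$d13C, sub$taxon)
    p15 <- isotope_test_p(sub$d15N, sub$taxon)
    pooled <- switch(rule,
                     pool_unless_distinct = (p13 >= alpha && p15 >= alpha),
                     pool_if_overlap = (p13 < alpha && p15 < alpha))
    if (pooled) assignment[members] <- label
    report[[length(report) + 1L]] <- data.frame(
      set = label, members = paste(members, collapse = ";"),
      p_d13C = p13, p_d15N = p15, pooled = pooled,
      stringsAsFactors = FALSE
    )
  }
  samples$taxon <- unname(assignment[samples$taxon])
  list(samples = samples, assignment = assignment,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(set = character(0), members = character(0),
                    p_d13C = numeric(0), p_d15N = numeric(0),
                    pooled = logical(0)))
}

#' Summarise source taxa to per-isotope mean and SD
#'
#' Arithmetic mean and sample SD (n-1 denominator) per taxon. Taxa with a
#' single sample are an error unless whitelisted (the field exception for
#' abundant taxa that are hard to isolate, e.g. Copepoda), in which case the
#' SD is set to `sd_floor`. Taxa below `min_samples_warn` samples warn.
#'
#' @param samples `data.frame` with columns taxon, d13C, d15N.
#' @param single_sample_whitelist Taxa allowed a single sample.
#' @param sd_floor SD (permil) assigned to whitelisted single-sample taxa,
#'   and the minimum SD for any taxon (a zero SD would make the mixing
#'   likelihood degenerate).
#' @param min_samples_warn Warning threshold on per-taxon sample count.
#' @return `data.frame`: name, n, mean_d13C, sd_d13C, mean_d15N, sd_d15N.
#' @export
summarize_sources <- function(samples, single_sample_whitelist = character(0),
                              sd_floor = 0.5, min_samples_warn = 3L) {
  taxa <- unique(samples$taxon)
  out <- lapply(taxa, function(tx) {
    s <- samples[samples$taxon == tx, ]
    n <- nrow(s)
    if (n == 1L && !tx %in% single_sample_whitelist) {
      stop("taxon '", tx, "' has a single sample and is not whitelisted",
           call. = FALSE)
    }
    if (n < min_samples_warn) {
      warning("taxon '", tx, "' has only ", n, " sample(s)", call. = FALSE)
    }
    sdc <- if (n > 1L) stats::sd(s$d13C) else sd_floor
    sdn <- if (n > 1L) stats::sd(s$d15N) else sd_floor
    data.frame(name = tx, n = n,
               mean_d13C = mean(s$d13C), sd_d13C = max(sdc, 0),
               mean_d15N = mean(s$d15N), sd_d15N = max(sdn, 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Impute an "unknown producer" basal node from zooplankton
#'
#' Where a primary producer could not be sampled (e.g. phytoplankton too
#' scarce for isotope analysis), a basal node is imputed by stepping the
#' zooplankton signature down one trophic level: producer mean = zooplankton
#' sample mean minus the zooplankton TEF mean, per isotope; SDs are the
#' zooplankton sample SDs.
#'
#' @param zoop_samples Zooplankton isotope samples (columns d13C, d15N).
#' @param tef_d13C,tef_d15N Zooplankton TEF means (permil).
#' @param name Label for the node.
#' @return One-row source summary `data.frame` with a `provenance` attribute
#'   of "synthetic".
#' @export
make_unknown_producer <- function(zoop_samples, tef_d13C = 0.4,
                                  tef_d15N = 2.2,
                                  name = "unknown producer") {
  if (is.null(zoop_samples) || nrow(zoop_samples) == 0L) {
    stop("no zooplankton samples: cannot impute an unknown producer",
         call. = FALSE)
  }
  n <- nrow(zoop_samples)
  out <- data.frame(
    name = name, n = n,
    mean_d13C = mean(zoop_samples$d13C) - tef_d13C,
    sd_d13C = if (n > 1L) stats::sd(zoop_samples$d13C) else 0,
    mean_d15N = mean(zoop_samples$d15N) - tef_d15N,
    sd_d15N = if (n > 1L) stats::sd(zoop_samples$d15N) else 0,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- "synthetic"
  out
}
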