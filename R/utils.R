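#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Controlled vocabulary of gut-content diet categories
#'
#' The twelve volumetric diet categories used in the flattened diet-composition
#' table: the ten microscopy categories plus detritus and hirudinea.
#'
#' @return Character vector of category names.
#' @export
diet_categories <- function() {
  c("substrate", "unidentified.animal.matter", "plant", "periphyton",
    "phytoplankton", "zooplankton", "insect", "decapod", "mollusc",
    "fish", "detritus", "hirudinea")
}

isotope_names <- function() c("d13C", "d15N")

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(sprintf("`%s` must be non-negative and finite", name), call. = FALSE)
  }
  x
}

assert_simplex <- function(p, name = "p", tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < -tol)) {
    stop(sprintf("`%s` must be a non-negative numeric vector", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Construct a table of source specifications
#'
#' A source specification carries everything the mixing model needs for one
#' candidate prey/resource: per-isotope mean and SD of its signature, the
#' trophic enrichment factor (TEF) mean and SD applied when a consumer eats
#' it, and its elemental C and N concentrations (used only when the model is
#' run concentration-dependent).
#'
#' @param name Source taxon labels.
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N Source signature moments (permil).
#' @param tef_d13C,tef_sd_d13C,tef_d15N,tef_sd_d15N TEF moments (permil).
#' @param conc_C,conc_N Elemental concentrations; 1 gives the
#'   concentration-independent model.
#' @return A `data.frame` with class `source_spec`, one row per source.
#' @export
source_spec <- function(name, mean_d13C, sd_d13C, mean_d15N, sd_d15N,
                        tef_d13C = 0, tef_sd_d13C = 0,
                        tef_d15N = 0, tef_sd_d15N = 0,
                        conc_C = 1, conc_N = 1) {
  df <- data.frame(
    name = as.character(name),
    mean_d13C = mean_d13C, sd_d13C = sd_d13C,
    mean_d15N = mean_d15N, sd_d15N = sd_d15N,
    tef_d13C = tef_d13C, tef_sd_d13C = tef_sd_d13C,
    tef_d15N = tef_d15N, tef_sd_d15N = tef_sd_d15N,
    conc_C = conc_C, conc_N = conc_N,
    stringsAsFactors = FALSE
  )
  validate_source_spec(df)
}

validate_source_spec <- function(df) {
  needed <- c("name", "mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N",
              "tef_d13C", "tef_sd_d13C", "tef_d15N", "tef_sd_d15N",
              "conc_C", "conc_N")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("source specification is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate source names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  sds <- c("sd_d13C", "sd_d15N", "tef_sd_d13C", "tef_sd_d15N")
  for (col in sds) assert_nonneg(df[[col]], col)
  if (any(df$conc_C < 0) || any(df$conc_N < 0)) {
    stop("elemental concentrations must be non-negative", call. = FALSE)
  }
  class(df) <- c("source_spec", "data.frame")
  df
}
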