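# Readers and writers for every file dialect the pipeline touches, the
# food-web plot, and the end-to-end pipeline driver.

ds4_source_columns <- function() {
  c("Sources", "Meand13C", "SDd13C", "Meand15N", "SDd15N",
    "tefd13C", "tefSDd13C", "tefd15N", "tefSDd15N", "conc13C", "conc15N")
}

read_strict_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

check_numeric_column <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) {
    suppressWarnings(num <- as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' of ", path,
           " (row ", bad[1], ")", call. = FALSE)
    }
    v <- num
  }
  v
}

#' Read a consumer isotope file (D13C/D15N dialect)
#'
#' @param path CSV with header columns `D13C` and `D15N` (exact case; extra
#'   columns are ignored with a warning).
#' @return `data.frame` with columns d13C, d15N and a `row` provenance
#'   column.
#' @export
read_consumer_file <- function(path) {
  df <- read_strict_csv(path)
  for (col in c("D13C", "D15N")) {
    if (!col %in% names(df)) {
      stop("missing header '", col, "' in ", path,
           " (headers are case-sensitive)", call. = FALSE)
    }
  }
  extra <- setdiff(names(df), c("D13C", "D15N"))
  if (length(extra)) {
    warning("ignoring extra columns in ", basename(path), ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  data.frame(d13C = check_numeric_column(df, "D13C", path),
             d15N = check_numeric_column(df, "D15N", path),
             row = seq_len(nrow(df)))
}

#' @rdname read_consumer_file
#' @param samples `data.frame` with columns `D13C`, `D15N` (or `d13C`,
#'   `d15N`).
#' @export
write_consumer_file <- function(samples, path) {
  if (all(c("d13C", "d15N") %in% names(samples))) {
    samples <- data.frame(D13C = samples$d13C, D15N = samples$d15N)
  }
  utils::write.csv(samples[, c("D13C", "D15N")], path, row.names = FALSE)
  invisible(path)
}

#' Read a source file (eleven-column Sources dialect)
#'
#' The concentration columns are optional; when absent every concentration
#' defaults to 1 (concentration-independent model) with a message.
#'
#' @param path CSV with columns Sources, Meand13C, SDd13C, Meand15N, SDd15N,
#'   tefd13C, tefSDd13C, tefd15N, tefSDd15N and optionally conc13C,
#'   conc15N.
#' @return A [source_spec()] table.
#' @export
read_sources_file <- function(path) {
  df <- read_strict_csv(path)
  required <- setdiff(ds4_source_columns(), c("conc13C", "conc15N"))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing source columns in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(col) check_numeric_column(df, col, path)
  has_conc <- all(c("conc13C", "conc15N") %in% names(df))
  if (!has_conc) {
    message("no concentration columns in ", basename(path),
            "; defaulting all concentrations to 1")
  }
  if (any(num("SDd13C") < 0) || any(num("SDd15N") < 0) ||
      any(num("tefSDd13C") < 0) || any(num("tefSDd15N") < 0)) {
    stop("negative SD in ", path, call. = FALSE)
  }
  source_spec(
    name = as.character(df$Sources),
    mean_d13C = num("Meand13C"), sd_d13C = num("SDd13C"),
    mean_d15N = num("Meand15N"), sd_d15N = num("SDd15N"),
    tef_d13C = num("tefd13C"), tef_sd_d13C = num("tefSDd13C"),
    tef_d15N = num("tefd15N"), tef_sd_d15N = num("tefSDd15N"),
    conc_C = if (has_conc) num("conc13C") else 1,
    conc_N = if (has_conc) num("conc15N") else 1
  )
}

#' @rdname read_sources_file
#' @param sources A [source_spec()] table.
#' @export
write_sources_file <- function(sources, path) {
  out <- data.frame(
    Sources = sources$name,
    Meand13C = sources$mean_d13C, SDd13C = sources$sd_d13C,
    Meand15N = sources$mean_d15N, SDd15N = sources$sd_d15N,
    tefd13C = sources$tef_d13C, tefSDd13C = sources$tef_sd_d13C,
    tefd15N = sources$tef_d15N, tefSDd15N = sources$tef_sd_d15N,
    conc13C = sources$conc_C, conc15N = sources$conc_N,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read the flattened diet-composition table
#'
#' Expects the study's column layout: Reservoir, Latitude, Longitude,
#' Sampling period, Fish species, Replicates, then the twelve diet-category
#' columns. Rows whose diet columns sum outside [0.98, 1.02] are flagged,
#' and species with fewer than `min_guts` replicates are marked below the
#' gut-count minimum.
#'
#' @param path CSV path.
#' @param min_guts Minimum replicate count (default 4).
#' @return The table with logical columns `flagged_sum` and
#'   `below_min_guts` appended.
#' @export
read_diet_table <- function(path, min_guts = 4L) {
  df <- read_strict_csv(path)
  meta <- c("Reservoir", "Latitude", "Longitude", "Sampling period",
            "Fish species", "Replicates")
  missing <- setdiff(c(meta, diet_categories()), names(df))
  if (length(missing)) {
    stop("missing diet-table columns in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in diet_categories()) df[[col]] <- check_numeric_column(df, col,
                                                                   path)
  sums <- rowSums(df[, diet_categories()])
  df$flagged_sum <- sums < 0.98 | sums > 1.02
  df$below_min_guts <- df$Replicates < min_guts
  df
}

#' @rdname read_diet_table
#' @param diet Diet table in the same layout.
#' @export
write_diet_table <- function(diet, path) {
  keep <- c("Reservoir", "Latitude", "Longitude", "Sampling period",
            "Fish species", "Replicates", diet_categories())
  utils::write.csv(diet[, keep], path, row.names = FALSE)
  invisible(path)
}

#' Read or write a predation matrix CSV
#'
#' First column `taxon` holds the prey labels; remaining columns are
#' consumers.
#'
#' @param path CSV path.
#' @return A `predation_matrix`.
#' @export
read_predation_matrix <- function(path) {
  df <- read_strict_csv(path)
  if (names(df)[1] != "taxon") {
    stop("first column of a predation matrix CSV must be 'taxon'",
         call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$taxon
  validate_predation_matrix(mat)
}

#' @rdname read_predation_matrix
#' @param mat A predation matrix.
#' @export
write_predation_matrix <- function(mat, path) {
  df <- data.frame(taxon = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a TEF lookup table (CSV or YAML)
#'
#' @param path File with fields taxon_group, tef_d15N_mean, tef_d15N_sd.
#' @return `data.frame` in the [default_tef_table()] layout.
#' @export
read_tef_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext %in% c("yml", "yaml")) {
    as.data.frame(do.call(rbind, lapply(yaml::read_yaml(path), as.data.frame)))
  } else {
    read_strict_csv(path)
  }
  needed <- c("taxon_group", "tef_d15N_mean", "tef_d15N_sd")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("TEF table is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$tef_d15N_mean <- as.numeric(df$tef_d15N_mean)
  df$tef_d15N_sd <- as.numeric(df$tef_d15N_sd)
  df[, needed]
}

#' Read a taxon-presence table
#'
#' Tab-separated table with columns `taxon`, `group` (basal, invertebrate or
#' fish) and one 0/1 presence column per reservoir; the layout of the
#' study's presence records.
#'
#' @param path TSV path. Defaults to the copy shipped with the package.
#' @return The presence `data.frame`.
#' @export
read_presence_table <- function(path = system.file("extdata",
                                                   "taxa_presence_12res.tsv",
                                                   package = "reswebr")) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df))) {
    stop("presence table needs 'taxon' and 'group' columns", call. = FALSE)
  }
  df
}

#' Count taxa per structural group in a presence table
#'
#' @param presence Output of [read_presence_table()].
#' @return Named integer vector of group sizes.
#' @export
presence_group_counts <- function(presence) {
  vapply(split(presence$taxon, presence$group), length, integer(1))
}

#' Read the per-category tissue-sample counts
#'
#' @param path CSV with columns `category`, `count`. Defaults to the copy
#'   shipped with the package.
#' @return `data.frame` with the counts.
#' @export
read_tissue_counts <- function(path = system.file("extdata",
                                                  "tissue_sample_counts.csv",
                                                  package = "reswebr")) {
  df <- read_strict_csv(path)
  df$count <- as.numeric(df$count)
  df
}

#' Draw the food-web graph
#'
#' Directed graph with an edge prey -> predator per positive matrix entry.
#' Node size grows with total degree and edge width with the diet
#' contribution; the layout is seeded, so identical matrix and seed give
#' identical coordinates.
#'
#' @param mat A predation matrix.
#' @param file Optional PNG path; when `NULL` nothing is rendered and only
#'   the graph structure is returned.
#' @param seed Layout seed.
#' @param link_threshold Entries above this form edges.
#' @return Invisibly, a list: `graph` (igraph object), `layout`
#'   (coordinates), `node_size`, `edge_width`.
#' @export
plot_web <- function(mat, file = NULL, seed = 1L, link_threshold = 0) {
  if (length(mat) == 0L) stop("empty predation matrix", call. = FALSE)
  idx <- which(unclass(mat) > link_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rownames(mat)[idx[, 1]],
                      to = colnames(mat)[idx[, 2]],
                      weight = mat[idx], stringsAsFactors = FALSE)
  nodes <- union(rownames(mat), colnames(mat))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  deg <- igraph::degree(g, mode = "all")
  node_size <- 6 + 3 * deg
  edge_width <- 0.5 + 4 * edges$weight
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
    igraph::plot.igraph(g, layout = lay, vertex.size = node_size,
                        edge.width = edge_width,
                        edge.arrow.size = 0.5,
                        vertex.label.cex = 0.8)
  }
  invisible(list(graph = g, layout = lay, node_size = node_size,
                 edge_width = edge_width))
}

#' Pipeline run configuration
#'
#' @param input_dir Directory holding per-consumer `<name>.csv` /
#'   `<name>.Sources.csv` pairs and optionally `diet_composition.csv`.
#' @param output_dir Directory for all outputs (created if needed).
#' @param settings [mcmc_settings()] for every consumer model.
#' @param concentration_dependent Use elemental concentrations.
#' @param polygon_args Arguments for [mixing_polygon_check()] during
#'   pruning.
#' @param link_threshold Link threshold for the indices.
#' @param plot Render the web PNG.
#' @param seed Master seed; per-consumer MCMC and polygon seeds are derived
#'   from it (seed + consumer index, seed + 1000 + consumer index).
#' @return List with class `run_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            settings = mcmc_settings(),
                            concentration_dependent = FALSE,
                            polygon_args = list(),
                            link_threshold = 0,
                            plot = TRUE, seed = 1L) {
  if (!dir.exists(input_dir)) {
    stop("input directory does not exist: ", input_dir, call. = FALSE)
  }
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 settings = settings,
                 concentration_dependent = concentration_dependent,
                 polygon_args = polygon_args,
                 link_threshold = link_threshold,
                 plot = plot, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised fields: input_dir, output_dir, seed, link_threshold, plot,
#' concentration_dependent, and an `mcmc` block (iterations, burn_in,
#' chains, thin, seed).
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  mc <- y$mcmc %||% list()
  settings <- do.call(mcmc_settings, mc)
  pipeline_config(
    input_dir = y$input_dir, output_dir = y$output_dir,
    settings = settings,
    concentration_dependent = isTRUE(y$concentration_dependent),
    link_threshold = y$link_threshold %||% 0,
    plot = y$plot %||% TRUE,
    seed = y$seed %||% 1L
  )
}

discover_consumers <- function(input_dir) {
  src_files <- list.files(input_dir, pattern = "\\.Sources\\.csv$")
  consumers <- sub("\\.Sources\\.csv$", "", src_files)
  keep <- file.exists(file.path(input_dir, paste0(consumers, ".csv")))
  sort(consumers[keep])
}

#' Run the full food-web pipeline on a directory of inputs
#'
#' For every consumer with a `<name>.csv` / `<name>.Sources.csv` pair:
#' feasibility check, source pruning with refits, posterior summary. The
#' per-consumer summaries are assembled into the predation matrix, network
#' indices are computed, the web is drawn, and a machine-readable manifest
#' is written. Any stage failure aborts with the stage and consumer named.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: matrix, indices, summaries, audits, manifest,
#'   output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  consumers <- discover_consumers(config$input_dir)
  if (length(consumers) == 0L) {
    stop("no consumer file pairs found in ", config$input_dir, call. = FALSE)
  }
  diet_path <- file.path(config$input_dir, "diet_composition.csv")
  diet <- if (file.exists(diet_path)) read_diet_table(diet_path) else NULL
  summaries <- list()
  audits <- list()
  rhat_max <- numeric(0)
  for (i in seq_along(consumers)) {
    cons <- consumers[i]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed for consumer '%s': %s",
                     what, cons, conditionMessage(e)), call. = FALSE)
      })
    }
    y <- stage("read", read_consumer_file(
      file.path(config$input_dir, paste0(cons, ".csv"))))
    src <- stage("read", read_sources_file(
      file.path(config$input_dir, paste0(cons, ".Sources.csv"))))
    settings <- config$settings
    settings$seed <- config$seed + i
    poly_args <- utils::modifyList(list(seed = config$seed + 1000L + i),
                                   config$polygon_args)
    pr <- stage("prune", prune_sources(
      y, src, settings = settings,
      concentration_dependent = config$concentration_dependent,
      polygon_args = poly_args))
    summaries[[cons]] <- pr$summary
    audits[[cons]] <- pr$audit
    rhat_max[cons] <- max(pr$summary$rhat, na.rm = TRUE)
    utils::write.csv(pr$summary,
                     file.path(config$output_dir,
                               paste0("posterior_", cons, ".csv")),
                     row.names = FALSE)
  }
  mat <- assemble_matrix(summaries)
  matrix_path <- file.path(config$output_dir, "predation_matrix.csv")
  write_predation_matrix(mat, matrix_path)
  idx <- web_indices(mat, link_threshold = config$link_threshold)
  idx_df <- data.frame(S = idx$S, L = idx$L,
                       link_density = idx$link_density,
                       connectance = idx$connectance,
                       frac_basal = idx$frac_basal,
                       frac_intermediate = idx$frac_intermediate,
                       frac_top = idx$frac_top,
                       mean_pianka = idx$mean_pianka,
                       mean_levins_b = idx$mean_levins_b)
  utils::write.csv(idx_df, file.path(config$output_dir, "web_indices.csv"),
                   row.names = FALSE)
  audit_all <- do.call(rbind, lapply(names(audits), function(cons) {
    a <- audits[[cons]]
    if (nrow(a)) cbind(consumer = cons, a) else NULL
  }))
  if (is.null(audit_all)) {
    audit_all <- data.frame(consumer = character(0), step = integer(0),
                            action = character(0), source = character(0),
                            median = numeric(0), threshold = numeric(0),
                            n_sources = integer(0))
  }
  utils::write.csv(audit_all,
                   file.path(config$output_dir, "pruning_audit.csv"),
                   row.names = FALSE)
  if (isTRUE(config$plot)) {
    plot_web(mat, file = file.path(config$output_dir, "food_web.png"),
             seed = config$seed)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("reswebr")),
    input_dir = config$input_dir,
    consumers = consumers,
    seed = config$seed,
    mcmc = config$settings[c("iterations", "burn_in", "chains", "thin")],
    concentration_dependent = config$concentration_dependent,
    link_threshold = config$link_threshold,
    rhat_max = as.list(rhat_max),
    pruning_removals = as.list(vapply(audits, function(a) {
      sum(a$action == "removed")
    }, numeric(1))),
    diet_table_rows = if (is.null(diet)) 0L else nrow(diet)
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(matrix = mat, indices = idx, summaries = summaries,
                 audits = audits, manifest = manifest,
                 files = list(matrix = matrix_path,
                              manifest = manifest_path)))
}
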