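# Gut-content analysis: frequency of occurrence, volumetric contribution,
# the feeding index, and the GCA-restricted candidate-source pool.

gut_item_columns <- function(guts) {
  setdiff(names(guts), c("species", "gut_id"))
}

#' Frequency of occurrence and volumetric contribution for one species
#'
#' `FO_i` is the fraction of the species' guts in which item i occurs
#' (any strictly positive volume counts); `VO_i` is the mean volumetric
#' proportion of item i across all guts, guts without the item contributing
#' zero.
#'
#' @param guts Gut-level records: a `data.frame` with columns `species`,
#'   `gut_id` and one volumetric-proportion column per diet item.
#' @param species Species to summarise.
#' @return List with named vectors `fo` and `vo` and the gut count `n_guts`.
#' @export
occurrence_and_volume <- function(guts, species) {
  items <- gut_item_columns(guts)
  g <- guts[guts$species == species, items, drop = FALSE]
  if (nrow(g) == 0L) {
    stop("no gut records for species: ", species, call. = FALSE)
  }
  m <- as.matrix(g)
  list(fo = colMeans(m > 0), vo = colMeans(m), n_guts = nrow(g))
}

#' Feeding index
#'
#' `FI_i = FO_i * VO_i / sum_j FO_j * VO_j`: the normalised product of an
#' item's frequency of occurrence and mean volumetric contribution.
#'
#' @param fo,vo Named vectors over the same items.
#' @return Named FI vector summing to 1.
#' @export
feeding_index <- function(fo, vo) {
  if (length(fo) != length(vo)) {
    stop("fo and vo must have the same length", call. = FALSE)
  }
  if (!is.null(names(fo)) && !is.null(names(vo)) &&
      !identical(names(fo), names(vo))) {
    vo <- vo[names(fo)]
  }
  prod <- fo * vo
  tot <- sum(prod)
  if (tot <= 0) {
    stop("empty diet: all FO x VO products are zero", call. = FALSE)
  }
  prod / tot
}

#' Per-species feeding-index table
#'
#' @param guts Gut-level records (see [occurrence_and_volume()]).
#' @return Long `data.frame`: species, n_guts, item, fo, vo, fi.
#' @export
feeding_index_table <- function(guts) {
  out <- lapply(unique(guts$species), function(sp) {
    ov <- occurrence_and_volume(guts, sp)
    fi <- feeding_index(ov$fo, ov$vo)
    data.frame(species = sp, n_guts = ov$n_guts, item = names(fi),
               fo = unname(ov$fo), vo = unname(ov$vo), fi = unname(fi),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' GCA-restricted candidate-source pool per consumer
#'
#' The mixing-model source pool for a consumer is the union of the taxa
#' mapped from every diet category with positive feeding index. Consumers
#' with fewer than `min_guts` examined guts (the study's minimum of four)
#' are flagged and given the literature-based pool instead.
#'
#' @param fi_table Output of [feeding_index_table()].
#' @param category_map Named list: diet category -> character vector of
#'   source taxa.
#' @param min_guts Minimum gut count for a GCA-informed pool (default 4).
#' @param literature_pools Optional named list: species -> character vector,
#'   used for flagged consumers.
#' @return Named list per species: `pool` (character) and `literature_based`
#'   (logical).
#' @export
candidate_sources <- function(fi_table, category_map, min_guts = 4L,
                              literature_pools = NULL) {
  out <- list()
  for (sp in unique(fi_table$species)) {
    tab <- fi_table[fi_table$species == sp, ]
    if (tab$n_guts[1] < min_guts) {
      out[[sp]] <- list(pool = as.character(literature_pools[[sp]] %||%
                                              character(0)),
                        literature_based = TRUE)
      next
    }
    nonzero <- tab$item[tab$fi > 0]
    unmapped <- nonzero[!nonzero %in% names(category_map)]
    if (length(unmapped)) {
      stop("no source mapping for diet categories with positive FI: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    pool <- sort(unique(unlist(category_map[nonzero], use.names = FALSE)))
    out[[sp]] <- list(pool = pool, literature_based = FALSE)
  }
  out
}
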