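# Food-web summary indices computed from a predation matrix.

#' Topology indices of a predation matrix
#'
#' A link is any entry above `link_threshold`. `S` counts the distinct taxa
#' (union of row and column labels); link density is `L/S`; directed
#' connectance is `L/S^2` (or `L/(S(S-1))` with
#' `connectance_denominator = "S_S-1"`). Nodes with no prey are basal
#' (isolated nodes — possible after pruning — count as basal), nodes with
#' prey and no predators are top, nodes with both are intermediate. Mean
#' Pianka overlap and mean Levins niche breadth are attached when at least
#' two consumers exist.
#'
#' @param mat A predation matrix (rows prey, columns predators).
#' @param link_threshold Minimum contribution for an entry to count as a
#'   link (default 0: any positive entry).
#' @param connectance_denominator `"S2"` (default) or `"S_S-1"`.
#' @return List with class `web_indices`: S, L, link_density, connectance,
#'   frac_basal, frac_intermediate, frac_top, mean_pianka, mean_levins_b,
#'   niche_breadth (per-consumer table).
#' @export
web_indices <- function(mat, link_threshold = 0,
                        connectance_denominator = c("S2", "S_S-1")) {
  connectance_denominator <- match.arg(connectance_denominator)
  if (is.null(dim(mat)) || length(mat) == 0L) {
    stop("empty predation matrix", call. = FALSE)
  }
  if (link_threshold < 0) stop("link_threshold must be >= 0", call. = FALSE)
  nodes <- union(rownames(mat), colnames(mat))
  S <- length(nodes)
  links <- mat > link_threshold
  L <- sum(links)
  has_prey <- stats::setNames(rep(FALSE, S), nodes)
  has_pred <- stats::setNames(rep(FALSE, S), nodes)
  for (cons in colnames(mat)) {
    if (any(links[, cons])) has_prey[cons] <- TRUE
  }
  for (prey in rownames(mat)) {
    if (any(links[prey, ])) has_pred[prey] <- TRUE
  }
  basal <- !has_prey
  top <- has_prey & !has_pred
  intermediate <- has_prey & has_pred
  denom <- if (connectance_denominator == "S2") S^2 else S * (S - 1)
  nb <- niche_breadth(mat)
  n_cons <- sum(colSums(mat) > 0)
  mp <- if (n_cons >= 2L) pianka_overlap(mat)$mean else NA_real_
  structure(list(S = S, L = L,
                 link_density = L / S,
                 connectance = L / denom,
                 frac_basal = sum(basal) / S,
                 frac_intermediate = sum(intermediate) / S,
                 frac_top = sum(top) / S,
                 mean_pianka = mp,
                 mean_levins_b = mean(nb$B),
                 niche_breadth = nb,
                 link_threshold = link_threshold,
                 connectance_denominator = connectance_denominator),
            class = "web_indices")
}

#' @export
print.web_indices <- function(x, ...) {
  cat(sprintf(
    paste0("Food web: S = %d, L = %d, link density %.3f, connectance %.3f\n",
           "fractions basal/intermediate/top: %.3f / %.3f / %.3f\n",
           "mean Pianka overlap %.3f, mean Levins B %.3f\n"),
    x$S, x$L, x$link_density, x$connectance,
    x$frac_basal, x$frac_intermediate, x$frac_top,
    x$mean_pianka, x$mean_levins_b))
  invisible(x)
}

#' Pianka's pairwise niche overlap
#'
#' `O_jk = sum_i p_ij p_ik / sqrt(sum_i p_ij^2 * sum_i p_ik^2)` over the
#' shared prey index set. Consumers whose column is all zero are excluded
#' with a warning. The mean is over unordered consumer pairs (diagonal
#' excluded).
#'
#' @param mat A predation matrix.
#' @return List: `overlap` (symmetric matrix, unit diagonal), `mean`.
#' @export
pianka_overlap <- function(mat) {
  zero <- colSums(mat != 0) == 0
  if (any(zero)) {
    warning("excluding all-zero consumer columns: ",
            paste(colnames(mat)[zero], collapse = ", "), call. = FALSE)
    mat <- mat[, !zero, drop = FALSE]
  }
  nc <- ncol(mat)
  if (nc < 2L) stop("Pianka overlap needs at least 2 consumers",
                    call. = FALSE)
  m <- unclass(mat)
  norms <- sqrt(colSums(m^2))
  O <- crossprod(m) / outer(norms, norms)
  diag(O) <- 1
  mean_ov <- mean(O[upper.tri(O)])
  list(overlap = O, mean = mean_ov)
}

#' Levins' niche breadth per consumer
#'
#' `B_j = 1 / sum_i p_ij^2`; the standardised form
#' `B_A = (B - 1) / (N_j - 1)` uses the consumer's count of positive prey
#' entries and is defined only for diets with more than one prey.
#'
#' @param mat A predation matrix with consumer columns summing to 1.
#' @return `data.frame`: consumer, B, n_prey, B_A.
#' @export
niche_breadth <- function(mat) {
  m <- unclass(mat)
  out <- lapply(colnames(m), function(cons) {
    p <- m[, cons]
    n_prey <- sum(p > 0)
    B <- if (sum(p^2) > 0) 1 / sum(p^2) else NA_real_
    BA <- if (n_prey > 1L) (B - 1) / (n_prey - 1) else NA_real_
    data.frame(consumer = cons, B = B, n_prey = n_prey, B_A = BA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
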