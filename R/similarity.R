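# Pairwise structural similarity between regions: connectivity matching
# index (CMI), generalized topological overlap (GTOM), directed graph
# distances and spatial distances, and the combined ranked pair table used to
# relate lesioned regions to functionally defined regions.

#' Connectivity matching index of a region pair
#'
#' Normalized overlap of two regions' connections:
#' `CMI_all(i,j) = sum_k (A_ik A_jk + A_ki A_kj) /
#'                sum_k (max(A_ik, A_jk) + max(A_ki, A_kj))`,
#' over all third regions `k != i, j`. A value of 1 means region i's
#' afferents and efferents coincide exactly with region j's; disjoint
#' neighbourhoods give 0. `mode = "in"` / `"out"` restricts to the afferent /
#' efferent half.
#'
#' @param c a connectome.
#' @param i,j region abbreviations (or indices), `i != j`.
#' @param mode `"all"` (default), `"in"` or `"out"`.
#' @param weighted use numeric weights inside the products and maxima
#'   instead of the 0/1 adjacency.
#' @return ratio in \[0, 1\]; 0 with attribute `defined = FALSE` when both
#'   regions are isolated (zero denominator).
#' @export
cmi <- function(c, i, j, mode = c("all", "in", "out"), weighted = FALSE) {
  mode <- match.arg(mode)
  A <- adjacency_matrix(c, weighted = weighted)
  if (!weighted) A <- (A > 0) + 0
  ab <- region_abbrev(c)
  ii <- if (is.character(i)) match(i, ab) else as.integer(i)
  jj <- if (is.character(j)) match(j, ab) else as.integer(j)
  if (is.na(ii) || is.na(jj)) stop("unknown region in cmi()")
  if (ii == jj) stop("cmi is undefined for i == j")
  cmi_pair(A, ii, jj, mode)
}

cmi_pair <- function(A, ii, jj, mode = "all") {
  k <- setdiff(seq_len(nrow(A)), c(ii, jj))
  num <- den <- 0
  if (mode %in% c("all", "out")) {
    num <- num + sum(A[ii, k] * A[jj, k])
    den <- den + sum(pmax(A[ii, k], A[jj, k]))
  }
  if (mode %in% c("all", "in")) {
    num <- num + sum(A[k, ii] * A[k, jj])
    den <- den + sum(pmax(A[k, ii], A[k, jj]))
  }
  if (den == 0) return(structure(0, defined = FALSE))
  num / den
}

#' Connectivity matching matrix between two region sets
#'
#' @param c a connectome.
#' @param rows,cols region abbreviation vectors (default: all regions).
#' @param mode,weighted see [cmi()].
#' @return matrix of CMI values with `NA` on cells where row and column name
#'   the same region; symmetric when `rows == cols`.
#' @export
cmi_matrix <- function(c, rows = region_abbrev(c), cols = region_abbrev(c),
                       mode = c("all", "in", "out"), weighted = FALSE) {
  mode <- match.arg(mode)
  if (!length(rows) || !length(cols)) stop("rows and cols must be non-empty")
  A <- adjacency_matrix(c, weighted = weighted)
  if (!weighted) A <- (A > 0) + 0
  ab <- region_abbrev(c)
  ri <- match(rows, ab); ci <- match(cols, ab)
  if (anyNA(ri) || anyNA(ci)) stop("unknown region in cmi_matrix()")
  out <- matrix(NA_real_, length(ri), length(ci), dimnames = list(rows, cols))
  for (a in seq_along(ri)) for (b in seq_along(ci)) {
    if (ri[a] == ci[b]) next
    out[a, b] <- as.numeric(cmi_pair(A, ri[a], ci[b], mode))
  }
  out
}

#' Generalized topological overlap matrix
#'
#' Counts the m-step neighbours two regions share on the symmetrized graph
#' and normalizes to \[0, 1\]:
#' `GTOM_m(i,j) = (|N_m(i) ∩ N_m(j)| + a_ij) / (min(|N_m(i)|, |N_m(j)|) + 1 - a_ij)`
#' where `N_m` is the set of regions reachable within m undirected steps
#' (excluding the region itself) and `a_ij` indicates a direct edge. Directly
#' linked pairs with identical neighbourhoods score 1.
#'
#' @param c a connectome.
#' @param m neighbourhood depth, `m >= 1`.
#' @return symmetric matrix with unit diagonal.
#' @export
gtom <- function(c, m = 1L) {
  if (m < 1L) stop("m must be >= 1")
  U <- (adjacency_matrix(c, weighted = FALSE) > 0)
  U <- U | t(U)
  diag(U) <- FALSE
  S <- U
  if (m > 1L) {
    P <- U
    for (step in 2:m) {
      P <- (P %*% U) > 0
      S <- S | P
    }
    diag(S) <- FALSE
  }
  Sn <- S + 0
  k <- rowSums(Sn)
  shared <- Sn %*% t(Sn)
  aij <- U + 0
  den <- outer(k, k, pmin) + 1 - aij
  out <- (shared + aij) / den
  out[den <= 0] <- 0
  diag(out) <- 1
  dimnames(out) <- list(region_abbrev(c), region_abbrev(c))
  out
}

#' Directed shortest-path distance matrices
#'
#' @param c a connectome.
#' @return list with `D_out` (`D_out[i, j]` = hops on the shortest directed
#'   path i -> j) and `D_in = t(D_out)`; unreachable pairs are `Inf`.
#' @export
graph_distances <- function(c) {
  g <- as_igraph(c, weighted = FALSE)
  D <- igraph::distances(g, mode = "out", weights = NA)
  dimnames(D) <- list(region_abbrev(c), region_abbrev(c))
  list(D_out = D, D_in = t(D))
}

#' Euclidean distance matrix between region coordinates (mm)
#'
#' @param c a connectome with `x`, `y`, `z` coordinates.
#' @return symmetric matrix; rows/columns of regions without coordinates are
#'   `NA`.
#' @export
spatial_distance <- function(c) {
  xyz <- as.matrix(c$regions[, c("x", "y", "z")])
  if (all(is.na(xyz))) stop("connectome has no region coordinates")
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- list(region_abbrev(c), region_abbrev(c))
  D
}

#' Ranked pair table of lesioned versus functional regions
#'
#' One row per (non-lesioned region, lesioned region) pair, carrying the five
#' pairwise statistics — directed graph distances `D_out` / `D_in` (hops from
#' the region to the lesioned region and back), spatial distance `D_spat`
#' (mm), `CMI_All` and a model coactivation value — plus a per-column rank
#' (1 = best: smallest distance, largest similarity; ties averaged). The
#' `marker` column is 2 for motor, 3 for learning and 0 for other regions.
#' Re-sorting the table by any column reproduces the usual similarity
#' screening workflow.
#'
#' @param c control connectome with functional groups assigned.
#' @param lesion a [lesion_model()] or character vector.
#' @param coactivation optional symmetric region-by-region coactivation
#'   matrix (e.g. from [coactivation()] of an FHN run on `c`).
#' @param include `"all"` non-lesioned regions, or `"functional"` only.
#' @return data.frame of class `pair_table`.
#' @export
pair_rank_table <- function(c, lesion, coactivation = NULL,
                            include = c("all", "functional")) {
  include <- match.arg(include)
  les <- resolve_lesion(c, lesion)
  grp <- setNames(c$regions$functional_group, c$regions$abbrev)
  others <- setdiff(region_abbrev(c), les)
  if (include == "functional") others <- others[grp[others] %in% c("motor", "learning")]
  if (!length(others) || !length(les)) stop("empty region or lesion set")
  gd <- graph_distances(c)
  ds <- if (!all(is.na(c$regions$x))) spatial_distance(c) else NULL
  cm <- cmi_matrix(c, rows = others, cols = les)
  marker <- ifelse(grp[others] == "motor", 2L, ifelse(grp[others] == "learning", 3L, 0L))
  out <- expand.grid(functional_region = others, lesioned_region = les,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$marker <- marker[match(out$functional_region, others)]
  idx <- cbind(match(out$functional_region, rownames(gd$D_out)),
               match(out$lesioned_region, colnames(gd$D_out)))
  out$D_out <- gd$D_out[idx]
  out$D_in <- gd$D_in[idx]
  out$D_spat <- if (!is.null(ds)) ds[cbind(match(out$functional_region, rownames(ds)),
                                           match(out$lesioned_region, colnames(ds)))]
                else NA_real_
  out$CMI_All <- cm[cbind(match(out$functional_region, rownames(cm)),
                          match(out$lesioned_region, colnames(cm)))]
  out$coactivation <- if (!is.null(coactivation))
    coactivation[cbind(match(out$functional_region, rownames(coactivation)),
                       match(out$lesioned_region, colnames(coactivation)))]
    else NA_real_
  out$rank_D_out <- rank(out$D_out, ties.method = "average", na.last = "keep")
  out$rank_D_in <- rank(out$D_in, ties.method = "average", na.last = "keep")
  out$rank_D_spat <- rank(out$D_spat, ties.method = "average", na.last = "keep")
  out$rank_CMI <- rank(-out$CMI_All, ties.method = "average", na.last = "keep")
  out$rank_coactivation <- rank(-out$coactivation, ties.method = "average",
                                na.last = "keep")
  out <- out[, c("functional_region", "marker", "lesioned_region",
                 "D_out", "D_in", "D_spat", "CMI_All", "coactivation",
                 "rank_D_out", "rank_D_in", "rank_D_spat", "rank_CMI",
                 "rank_coactivation")]
  class(out) <- c("pair_table", "data.frame")
  out
}
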