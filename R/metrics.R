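# Global and local network parameters for directed weighted connectomes.
# Path-based quantities are computed on the unweighted digraph; clustering and
# transitivity on the underlying undirected simple graph, following the
# triplet-based definitions used in tract-tracing connectomics.

undirected_of <- function(c) {
  igraph::as_undirected(as_igraph(c, weighted = FALSE), mode = "collapse")
}

#' Reciprocal-edge count and reciprocity ratio
#'
#' An edge is reciprocal when its reverse edge also exists. The reciprocity
#' of a digraph is the number of such edges over the total edge count.
#'
#' @param c a connectome.
#' @return list with `count` (edges whose reverse exists) and `ratio`
#'   (`NA` for an edgeless graph).
#' @export
reciprocity_stats <- function(c) {
  m <- nrow(c$edges)
  if (!m) return(list(count = 0L, ratio = NA_real_))
  key <- paste(c$edges$from, c$edges$to, sep = "\r")
  rev <- paste(c$edges$to, c$edges$from, sep = "\r")
  count <- sum(rev %in% key)
  list(count = as.integer(count), ratio = count / m)
}

#' Average shortest-path length (hops)
#'
#' Mean of the unweighted shortest-path lengths over all reachable ordered
#' region pairs (i != j). Unreachable pairs are excluded from the mean but
#' counted and reported, so disconnection is visible rather than silently
#' absorbed.
#'
#' @param c a connectome.
#' @return list with `value` (mean hops; `NA` if no pair is reachable),
#'   `n_pairs` (reachable ordered pairs) and `n_unreachable`.
#' @export
avg_path_length <- function(c) {
  g <- as_igraph(c, weighted = FALSE)
  D <- igraph::distances(g, mode = "out", weights = NA)
  diag(D) <- NA
  fin <- is.finite(D)
  n_reach <- sum(fin, na.rm = TRUE)
  n_unreach <- sum(!fin & !is.na(D))
  list(value = if (n_reach) mean(D[which(fin)]) else NA_real_,
       n_pairs = n_reach, n_unreachable = n_unreach)
}

#' Average local clustering coefficient
#'
#' Mean of the per-region local clustering coefficients of the underlying
#' undirected simple graph; regions with fewer than two neighbours
#' contribute zero.
#'
#' @param c a connectome.
#' @return numeric in \[0, 1\].
#' @export
avg_clustering <- function(c) {
  lc <- igraph::transitivity(undirected_of(c), type = "local")
  lc[is.nan(lc) | is.na(lc)] <- 0
  mean(lc)
}

#' Transitivity (global clustering coefficient)
#'
#' Ratio of closed triplets to all connected triplets of the underlying
#' undirected simple graph.
#'
#' @param c a connectome.
#' @return numeric in \[0, 1\] (`NaN` when no triplet exists).
#' @export
transitivity_coef <- function(c) {
  igraph::transitivity(undirected_of(c), type = "global")
}

#' Small-worldness index
#'
#' `S = (T / <T_rand>) / (L / <L_rand>)`: transitivity normalized by its
#' null-ensemble mean, over the average shortest-path length normalized the
#' same way.
#'
#' @param c a connectome.
#' @param ensemble list of null-model connectomes (see [er_ensemble()] and
#'   [rewire_ensemble()]); passing `list(c)` gives 1 by construction.
#' @return list with `value`, the empirical `transitivity` and `path_length`,
#'   their ensemble means and the ensemble size.
#' @export
small_worldness <- function(c, ensemble) {
  if (!length(ensemble)) stop("ensemble must contain at least one network")
  T_obs <- transitivity_coef(c)
  L_obs <- avg_path_length(c)$value
  T_r <- mean(vapply(ensemble, transitivity_coef, numeric(1)))
  L_r <- mean(vapply(ensemble, function(x) avg_path_length(x)$value, numeric(1)))
  val <- if (is.na(T_r) || T_r == 0 || is.na(L_r) || L_r == 0) NA_real_
         else (T_obs / T_r) / (L_obs / L_r)
  list(value = val, transitivity = T_obs, path_length = L_obs,
       transitivity_rand = T_r, path_length_rand = L_r,
       ensemble_size = length(ensemble))
}

kc_score <- function(A01, bc, share_total, idx) {
  s <- length(idx)
  if (s < 2L) return(0)
  dens <- sum(A01[idx, idx]) / (s * (s - 1))
  dens * sum(bc[idx]) / share_total
}

#' Knotty-centrality of a connectome
#'
#' Scores a region subset S by the product of its internal directed edge
#' density and its share of total betweenness centrality,
#' `KC(S) = density(S) * sum(BC_S) / sum(BC)`, and reports the maximizing
#' subset. Graphs with at most `exhaustive_max` regions are searched
#' exhaustively; larger graphs use deterministic greedy ascent seeded from
#' the top-betweenness regions.
#'
#' @param c a connectome.
#' @param exhaustive_max exhaustive-search cutoff (subset enumeration is
#'   exponential).
#' @param max_seeds number of nested top-betweenness seed sets for the
#'   greedy search.
#' @return list with `score` (in \[0, 1\]) and `subset` (region abbreviations).
#' @export
knotty_centrality <- function(c, exhaustive_max = 12L, max_seeds = 20L) {
  n <- n_regions(c)
  if (n < 2L) stop("knotty-centrality needs at least 2 regions")
  A01 <- adjacency_matrix(c, weighted = FALSE)
  g <- as_igraph(c, weighted = FALSE)
  bc <- igraph::betweenness(g, directed = TRUE, weights = NA)
  tot <- sum(bc)
  if (tot == 0) return(list(score = 0, subset = character()))
  ab <- region_abbrev(c)
  best <- list(score = -Inf, idx = integer())
  if (n <= exhaustive_max) {
    for (s in 2:n) {
      cmb <- utils::combn(n, s)
      for (k in seq_len(ncol(cmb))) {
        idx <- cmb[, k]
        sc <- kc_score(A01, bc, tot, idx)
        if (sc > best$score) best <- list(score = sc, idx = idx)
      }
    }
  } else {
    ord <- order(bc, decreasing = TRUE)
    for (k in 2:min(max_seeds, n)) {
      idx <- sort(ord[seq_len(k)])
      sc <- kc_score(A01, bc, tot, idx)
      repeat {
        improved <- FALSE
        # best single add or drop
        cand_add <- setdiff(seq_len(n), idx)
        sc_add <- vapply(cand_add, function(v) kc_score(A01, bc, tot, c(idx, v)),
                         numeric(1))
        sc_drop <- if (length(idx) > 2L)
          vapply(seq_along(idx), function(j) kc_score(A01, bc, tot, idx[-j]),
                 numeric(1)) else numeric(0)
        ba <- if (length(sc_add)) max(sc_add) else -Inf
        bd <- if (length(sc_drop)) max(sc_drop) else -Inf
        if (ba >= bd && ba > sc) {
          idx <- sort(c(idx, cand_add[which.max(sc_add)])); sc <- ba; improved <- TRUE
        } else if (bd > sc) {
          idx <- idx[-which.max(sc_drop)]; sc <- bd; improved <- TRUE
        }
        if (!improved) break
      }
      if (sc > best$score) best <- list(score = sc, idx = idx)
    }
  }
  list(score = best$score, subset = ab[best$idx])
}

# ---- local parameters ------------------------------------------------------

katz_centrality <- function(c, attenuation = NULL) {
  A <- adjacency_matrix(c, weighted = FALSE)
  n <- nrow(A)
  if (is.null(attenuation)) {
    lam <- max(Mod(eigen(A, only.values = TRUE)$values))
    attenuation <- if (lam > 0) 0.85 / lam else 0
  }
  # status from incoming walks: x = sum_{k>=1} alpha^k (A')^k 1
  solve(diag(n) - attenuation * t(A), rep(1, n)) - 1
}

leverage_centrality <- function(gu) {
  k <- igraph::degree(gu)
  adj <- igraph::as_adj_list(gu)
  vapply(seq_along(k), function(i) {
    nb <- as.integer(adj[[i]])
    if (!length(nb)) return(NA_real_)
    mean((k[i] - k[nb]) / (k[i] + k[nb]))
  }, numeric(1))
}

locality_index <- function(gu) {
  A <- igraph::as_adjacency_matrix(gu, sparse = FALSE) > 0
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nbh <- c(i, which(A[i, ]))
    if (length(nbh) == 1L) return(0)
    intra <- sum(A[nbh, nbh]) / 2
    incident <- sum(A[nbh, ]) - intra
    if (incident == 0) return(0)
    intra / incident
  }, numeric(1))
}

flow_coefficient <- function(c) {
  A <- adjacency_matrix(c, weighted = FALSE) > 0
  U <- A | t(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    k <- sum(U[i, ])
    if (k < 2L) return(0)
    into <- which(A[, i]); out <- which(A[i, ])
    paths <- length(into) * length(out) - length(intersect(into, out))
    paths / (k * (k - 1))
  }, numeric(1))
}

#' Monte-Carlo Shapley rating of regions
#'
#' Shapley value of the neighbourhood-coverage game: a coalition's worth is
#' the number of regions it dominates (members plus regions adjacent to a
#' member in either direction). Estimated by averaging marginal
#' contributions over random permutations.
#'
#' @param c a connectome.
#' @param n_perm number of sampled permutations.
#' @param seed RNG seed.
#' @return numeric vector of per-region ratings (sums to `n_regions`).
#' @export
shapley_rating <- function(c, n_perm = 500L, seed = 1L) {
  A <- adjacency_matrix(c, weighted = FALSE) > 0
  U <- A | t(A)
  diag(U) <- TRUE
  n <- nrow(U)
  with_seed(seed, {
    val <- numeric(n)
    for (p in seq_len(n_perm)) {
      perm <- sample.int(n)
      covered <- rep(FALSE, n)
      for (i in perm) {
        gain <- sum(U[i, ] & !covered)
        val[i] <- val[i] + gain
        covered <- covered | U[i, ]
      }
    }
    val / n_perm
  })
}

shapley_exact_coverage <- function(c) {
  # closed form for the coverage game: each region j distributes 1/(deg(j)+1)
  # to every member of its closed neighbourhood
  A <- adjacency_matrix(c, weighted = FALSE) > 0
  U <- A | t(A)
  diag(U) <- TRUE
  colSums(U / rowSums(U))
}

#' Default local-parameter registry
#'
#' Thirteen per-region network parameters with an explicit orientation flag
#' (`higher_better`): degrees, Katz status, local clustering, leverage,
#' locality, local efficiency, betweenness, eigenvector centrality, flow
#' coefficient, Shapley rating and harmonic closeness (in and out).
#'
#' @return data.frame with columns `name` and `higher_better`.
#' @export
default_local_registry <- function() {
  data.frame(
    name = c("degree_all", "degree_in", "degree_out", "katz", "clustering",
             "leverage", "locality", "local_efficiency", "betweenness",
             "eigenvector", "flow_coefficient", "shapley",
             "closeness_in", "closeness_out"),
    higher_better = TRUE,
    stringsAsFactors = FALSE)
}

#' Local network parameters of every region
#'
#' @param c a connectome.
#' @param registry subset of [default_local_registry()] to compute.
#' @param shapley_perm,seed Monte-Carlo settings for the Shapley rating.
#' @return object of class `local_param_matrix`: list with `values`
#'   (regions x parameters matrix) and `registry`.
#' @export
local_parameters <- function(c, registry = default_local_registry(),
                             shapley_perm = 500L, seed = 1L) {
  g <- as_igraph(c, weighted = FALSE)
  gu <- undirected_of(c)
  n <- n_regions(c)
  compute <- function(name) {
    switch(name,
      degree_all = igraph::degree(g, mode = "all"),
      degree_in = igraph::degree(g, mode = "in"),
      degree_out = igraph::degree(g, mode = "out"),
      katz = katz_centrality(c),
      clustering = {
        lc <- igraph::transitivity(gu, type = "local")
        lc[is.nan(lc) | is.na(lc)] <- 0
        lc
      },
      leverage = leverage_centrality(gu),
      locality = locality_index(gu),
      local_efficiency = igraph::local_efficiency(gu),
      betweenness = igraph::betweenness(g, directed = TRUE, weights = NA),
      eigenvector = igraph::eigen_centrality(gu)$vector,
      flow_coefficient = flow_coefficient(c),
      shapley = shapley_rating(c, n_perm = shapley_perm, seed = seed),
      closeness_in = igraph::harmonic_centrality(g, mode = "in"),
      closeness_out = igraph::harmonic_centrality(g, mode = "out"),
      stop("unknown local parameter: ", name))
  }
  vals <- vapply(registry$name, compute, numeric(n))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = n)
  dimnames(vals) <- list(region_abbrev(c), registry$name)
  structure(list(values = vals, registry = registry),
            class = "local_param_matrix")
}

#' Average rank of each region over local parameters
#'
#' Each parameter column is ranked with 1 = most important according to its
#' orientation flag (ties receive the average rank); the per-region mean over
#' parameters is the region's importance score — low average rank means high
#' importance.
#'
#' @param m a [local_parameters()] result.
#' @return named numeric vector of average ranks.
#' @export
average_rank <- function(m) {
  stopifnot(inherits(m, "local_param_matrix"))
  rk <- vapply(seq_len(ncol(m$values)), function(j) {
    x <- m$values[, j]
    if (m$registry$higher_better[j]) x <- -x
    rank(x, ties.method = "average", na.last = "keep")
  }, numeric(nrow(m$values)))
  out <- rowMeans(rk, na.rm = TRUE)
  names(out) <- rownames(m$values)
  out
}

#' One-row table of global network metrics
#'
#' @param c a connectome.
#' @param ensemble optional null ensemble for [small_worldness()]; when
#'   `NULL` the small-worldness column is `NA`.
#' @return one-row data.frame.
#' @export
global_metrics <- function(c, ensemble = NULL) {
  rec <- reciprocity_stats(c)
  apl <- avg_path_length(c)
  sw <- if (!is.null(ensemble)) small_worldness(c, ensemble)$value else NA_real_
  kc <- if (n_regions(c) >= 2) knotty_centrality(c)$score else NA_real_
  data.frame(n_regions = n_regions(c), n_links = n_edges(c),
             reciprocal_edges = rec$count, reciprocity = rec$ratio,
             avg_path_length = apl$value, n_unreachable_pairs = apl$n_unreachable,
             avg_clustering = avg_clustering(c),
             transitivity = transitivity_coef(c),
             small_worldness = sw, knotty_centrality = kc)
}
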