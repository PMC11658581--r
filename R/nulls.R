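# Null-model ensembles and permutation tests for control-vs-lesioned
# comparisons. Randomization relies on igraph's G(n,m) sampler and directed
# degree-preserving edge swaps.

#' Null-ensemble specification
#'
#' @param kind `"erdos_renyi"` (G(n,m): same region and edge count) or
#'   `"degree_preserving_rewire"` (directed double-edge swaps preserving
#'   every region's in- and out-degree).
#' @param size number of sampled networks.
#' @param n_swaps_per_edge swap attempts per edge for rewiring mixing.
#' @param seed RNG seed.
#' @return an `ensemble_spec` list.
#' @export
ensemble_spec <- function(kind = c("degree_preserving_rewire", "erdos_renyi"),
                          size = 100L, n_swaps_per_edge = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 1L) stop("ensemble size must be >= 1")
  structure(list(kind = kind, size = as.integer(size),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

edges_from_igraph <- function(g, template) {
  el <- igraph::as_edgelist(g, names = FALSE)
  ab <- region_abbrev(template)
  m <- nrow(el)
  src <- template$edges
  # carry edge attributes over positionally: the null models randomize
  # topology, not the weight distribution
  idx <- if (nrow(src) >= m) seq_len(m) else rep_len(seq_len(max(1L, nrow(src))), m)
  data.frame(from = ab[el[, 1]], to = ab[el[, 2]],
             weight_category = if (nrow(src)) src$weight_category[idx] else "light",
             weight = if (nrow(src)) src$weight[idx] else 1,
             observations = if (nrow(src)) src$observations[idx] else 1L,
             stringsAsFactors = FALSE)
}

#' Erdos-Renyi G(n,m) ensemble matched to a connectome
#'
#' Each sample is a uniform simple digraph with the same region set and
#' exactly the same number of directed edges as the input.
#'
#' @param c a connectome with at least one edge.
#' @param spec an [ensemble_spec()] (the `kind` field is ignored here).
#' @return list of connectomes of length `spec$size`.
#' @export
er_ensemble <- function(c, spec = ensemble_spec("erdos_renyi")) {
  if (!n_edges(c)) stop("er_ensemble needs a connectome with edges")
  n <- n_regions(c); m <- n_edges(c)
  with_seed(spec$seed, {
    lapply(seq_len(spec$size), function(k) {
      g <- igraph::sample_gnm(n, m, directed = TRUE)
      connectome(c$regions, edges_from_igraph(g, c), meta = list(null = "erdos_renyi"))
    })
  })
}

#' Degree-preserving rewiring ensemble
#'
#' Directed double-edge swaps that preserve each region's in-degree and
#' out-degree exactly while avoiding self-loops and multi-edges.
#'
#' @param c a connectome with at least two edges.
#' @param spec an [ensemble_spec()].
#' @return list of connectomes of length `spec$size`.
#' @export
rewire_ensemble <- function(c, spec = ensemble_spec("degree_preserving_rewire")) {
  if (n_edges(c) < 2L) stop("rewire_ensemble needs at least two edges")
  g0 <- as_igraph(c, weighted = FALSE)
  niter <- spec$n_swaps_per_edge * n_edges(c)
  with_seed(spec$seed, {
    lapply(seq_len(spec$size), function(k) {
      g <- igraph::rewire(g0, igraph::keeping_degseq(loops = FALSE, niter = niter))
      connectome(c$regions, edges_from_igraph(g, c),
                 meta = list(null = "degree_preserving_rewire"))
    })
  })
}

#' Build an ensemble according to its spec
#' @param c a connectome.
#' @param spec an [ensemble_spec()].
#' @return list of connectomes.
#' @export
build_ensemble <- function(c, spec) {
  switch(spec$kind,
         erdos_renyi = er_ensemble(c, spec),
         degree_preserving_rewire = rewire_ensemble(c, spec),
         stop("unknown ensemble kind: ", spec$kind))
}

# fast adjacency-matrix metric implementations used inside permutation loops
fast_metric <- function(name) {
  switch(name,
    n_links = function(A) sum(A > 0),
    reciprocal_edges = function(A) sum(A > 0 & t(A) > 0),
    reciprocity = function(A) {
      m <- sum(A > 0)
      if (!m) return(NA_real_)
      sum(A > 0 & t(A) > 0) / m
    },
    transitivity = function(A) {
      U <- (A > 0 | t(A) > 0) + 0
      k <- rowSums(U)
      den <- sum(k * (k - 1))
      if (!den) return(NaN)
      sum(diag(U %*% U %*% U)) / den
    },
    avg_clustering = function(A) {
      U <- (A > 0 | t(A) > 0) + 0
      k <- rowSums(U)
      tri <- diag(U %*% U %*% U)
      lc <- ifelse(k < 2, 0, tri / (k * (k - 1)))
      mean(lc)
    },
    avg_path_length = function(A) {
      g <- igraph::graph_from_adjacency_matrix((A > 0) + 0, mode = "directed")
      D <- igraph::distances(g, mode = "out", weights = NA)
      diag(D) <- NA
      fin <- which(is.finite(D))
      if (!length(fin)) return(NA_real_)
      mean(D[fin])
    },
    stop("unknown metric name: ", name,
         " (use one of n_links, reciprocal_edges, reciprocity, transitivity,",
         " avg_clustering, avg_path_length, or pass a function)"))
}

resolve_metric <- function(metric) {
  if (is.character(metric)) {
    f <- fast_metric(metric)
    list(fn_A = f, label = metric)
  } else if (is.function(metric)) {
    list(fn_A = NULL, fn_c = metric, label = "custom")
  } else stop("metric must be a registry name or a function(connectome)")
}

#' Permutation test for a lesion-induced metric change
#'
#' The observed statistic is `delta_obs = metric(control) - metric(lesioned)`.
#' The null distribution removes a random lesion of matching size from either
#' the control connectome itself (`null_mode = "lesion"`) or from a freshly
#' drawn null network of the control (`null_mode = "graph"`, using
#' `spec$kind`). The two-sided empirical p-value uses the add-one estimator
#' `p = (1 + #{|delta*| >= |delta_obs|}) / (1 + n_perm)`.
#'
#' @param metric registry name (`"reciprocal_edges"`, `"reciprocity"`,
#'   `"transitivity"`, `"avg_clustering"`, `"avg_path_length"`, `"n_links"`)
#'   or a `function(connectome) -> numeric`.
#' @param c_control,c_lesioned control and lesioned connectomes
#'   (`c_lesioned` must be an induced subnetwork of the control).
#' @param spec an [ensemble_spec()]; supplies the null-graph kind and seed.
#' @param n_perm number of permutations.
#' @param null_mode `"lesion"` or `"graph"` (see above).
#' @return list with `p_value`, `delta_obs`, `null` (the permuted deltas),
#'   `metric` and `null_mode`.
#' @export
permutation_test <- function(metric, c_control, c_lesioned,
                             spec = ensemble_spec(), n_perm = 999L,
                             null_mode = c("lesion", "graph")) {
  null_mode <- match.arg(null_mode)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  mt <- resolve_metric(metric)
  lesion_size <- n_regions(c_control) - n_regions(c_lesioned)
  if (lesion_size < 0L) stop("lesioned connectome has more regions than control")
  eval_c <- function(x) {
    if (!is.null(mt$fn_A)) mt$fn_A(adjacency_matrix(x, weighted = FALSE)) else mt$fn_c(x)
  }
  obs <- eval_c(c_control) - eval_c(c_lesioned)
  A_ctrl <- adjacency_matrix(c_control, weighted = FALSE)
  n <- nrow(A_ctrl)
  sub_metric <- function(A, drop_idx) {
    Asub <- if (length(drop_idx)) A[-drop_idx, -drop_idx, drop = FALSE] else A
    if (!is.null(mt$fn_A)) mt$fn_A(Asub)
    else mt$fn_c(subnetwork_by_index(c_control, drop_idx))
  }
  null_delta <- with_seed(spec$seed, {
    if (null_mode == "lesion") {
      base <- if (!is.null(mt$fn_A)) mt$fn_A(A_ctrl) else mt$fn_c(c_control)
      vapply(seq_len(n_perm), function(k) {
        drop_idx <- if (lesion_size) sample.int(n, lesion_size) else integer()
        base - sub_metric(A_ctrl, drop_idx)
      }, numeric(1))
    } else {
      nulls <- build_ensemble(c_control,
                              ensemble_spec(spec$kind, size = n_perm,
                                            n_swaps_per_edge = spec$n_swaps_per_edge,
                                            seed = spec$seed))
      vapply(nulls, function(gnull) {
        An <- adjacency_matrix(gnull, weighted = FALSE)
        drop_idx <- if (lesion_size) sample.int(n, lesion_size) else integer()
        f0 <- if (!is.null(mt$fn_A)) mt$fn_A(An) else mt$fn_c(gnull)
        f0 - (if (!is.null(mt$fn_A)) mt$fn_A(
          if (length(drop_idx)) An[-drop_idx, -drop_idx, drop = FALSE] else An)
          else mt$fn_c(subnetwork(gnull, setdiff(region_abbrev(gnull),
                                                 region_abbrev(gnull)[drop_idx]))))
      }, numeric(1))
    }
  })
  keep <- !is.na(null_delta)
  p <- (1 + sum(abs(null_delta[keep]) >= abs(obs))) / (1 + sum(keep))
  list(p_value = p, delta_obs = obs, null = null_delta,
       metric = mt$label, null_mode = null_mode)
}

subnetwork_by_index <- function(c, drop_idx) {
  if (!length(drop_idx)) return(c)
  subnetwork(c, region_abbrev(c)[-drop_idx])
}
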