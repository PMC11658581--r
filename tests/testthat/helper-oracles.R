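# Independent brute-force oracles used to validate the package's graph
# metrics, plus small fixture builders. Everything here is deliberately
# naive (loops, enumeration) and shares no code with the implementation.

toy_connectome <- function(edges, n = NULL, abbrev = NULL, coords = NULL) {
  if (is.null(abbrev)) {
    nn <- if (is.null(n)) max(edges) else n
    abbrev <- paste0("N", seq_len(nn))
  }
  regions <- data.frame(abbrev = abbrev, stringsAsFactors = FALSE)
  if (!is.null(coords)) {
    regions$x <- coords[, 1]; regions$y <- coords[, 2]; regions$z <- coords[, 3]
  }
  ed <- if (length(edges)) {
    data.frame(from = abbrev[edges[, 1]], to = abbrev[edges[, 2]],
               stringsAsFactors = FALSE)
  } else NULL
  connectome(regions, ed)
}

random_digraph_matrix <- function(n, m, seed) {
  set.seed(seed)
  slots <- which(matrix(TRUE, n, n) & !diag(TRUE, n))
  A <- matrix(0, n, n)
  A[sample(slots, m)] <- 1
  dimnames(A) <- list(paste0("N", seq_len(n)), paste0("N", seq_len(n)))
  A
}

connectome_from_matrix <- function(A) {
  idx <- which(A > 0, arr.ind = TRUE)
  ab <- rownames(A)
  toy_connectome(idx, abbrev = ab)
}

oracle_reciprocal_count <- function(A) {
  cnt <- 0L
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] > 0 && A[j, i] > 0) cnt <- cnt + 1L
  }
  cnt
}

oracle_distances <- function(A) {
  # Floyd-Warshall, row/column relaxation per intermediate node
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_avg_path_length <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- NA
  v <- D[is.finite(D) & !is.na(D)]
  if (!length(v)) NA_real_ else mean(v)
}

oracle_transitivity <- function(A) {
  U <- (A > 0 | t(A) > 0) + 0
  n <- nrow(U)
  closed <- 0; total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    if (U[i, j] && U[j, k]) {           # path i-j-k centred at j
      total <- total + 1
      if (U[i, k]) closed <- closed + 1
    }
  }
  if (!total) NaN else closed / total
}

oracle_avg_clustering <- function(A) {
  U <- (A > 0 | t(A) > 0) + 0
  n <- nrow(U)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(U[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in nb) for (b in nb) if (a < b && U[a, b]) links <- links + 1
    2 * links / (k * (k - 1))
  }, numeric(1)))
}

# betweenness via shortest-path counting with matrix powers
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  maxd <- max(D[is.finite(D)])
  Pk <- vector("list", max(maxd, 1))
  Pk[[1]] <- (A > 0) + 0
  if (maxd >= 2) for (k in 2:maxd) Pk[[k]] <- Pk[[k - 1]] %*% Pk[[1]]
  sigma <- function(s, t) if (D[s, t] == 0) 1 else Pk[[D[s, t]]][s, t]
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(D[s, t]) || D[s, t] == 0) next
    st <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / st
      }
    }
  }
  bc
}

# set-overlap CMI oracle for binary graphs
oracle_cmi_all <- function(A, i, j) {
  others <- setdiff(seq_len(nrow(A)), c(i, j))
  out_i <- intersect(which(A[i, ] > 0), others)
  out_j <- intersect(which(A[j, ] > 0), others)
  in_i <- intersect(which(A[, i] > 0), others)
  in_j <- intersect(which(A[, j] > 0), others)
  num <- length(intersect(out_i, out_j)) + length(intersect(in_i, in_j))
  den <- length(union(out_i, out_j)) + length(union(in_i, in_j))
  if (!den) 0 else num / den
}

# exhaustive knotty-centrality via bitmask enumeration
oracle_knotty <- function(A, bc) {
  n <- nrow(A)
  tot <- sum(bc)
  if (tot == 0) return(list(score = 0, subset = integer()))
  best <- 0; best_set <- integer()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    s <- length(idx)
    if (s < 2) next
    val <- (sum(A[idx, idx] > 0) / (s * (s - 1))) * sum(bc[idx]) / tot
    if (val > best) { best <- val; best_set <- idx }
  }
  list(score = best, subset = best_set)
}
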