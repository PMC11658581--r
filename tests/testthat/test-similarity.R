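test_that("CMI matches direct evaluation on constructed cases", {
  # identical in/out neighbourhoods -> 1
  cc <- toy_connectome(rbind(c(1, 3), c(2, 3), c(4, 1), c(4, 2)), n = 4)
  expect_equal(cmi(cc, "N1", "N2"), 1)
  # disjoint neighbourhoods -> 0
  cc2 <- toy_connectome(rbind(c(1, 3), c(2, 4)), n = 4)
  expect_equal(cmi(cc2, "N1", "N2"), 0)
  # i->k, j->k, j->l: num 1, den max(1,1)+max(0,1) = 2 -> 0.5
  cc3 <- toy_connectome(rbind(c(1, 3), c(2, 3), c(2, 4)), n = 4)
  expect_equal(cmi(cc3, "N1", "N2", mode = "out"), 0.5)
  # isolated pair: defined-flag
  cc4 <- toy_connectome(rbind(c(3, 4)), n = 4)
  v <- cmi(cc4, "N1", "N2")
  expect_equal(as.numeric(v), 0)
  expect_false(attr(v, "defined"))
  expect_error(cmi(cc, "N1", "N1"), "i == j")
})

test_that("CMI is symmetric and equals the set-overlap oracle on binary graphs", {
  for (seed in 1:6) {
    A <- random_digraph_matrix(20, 70, seed)
    cc <- connectome_from_matrix(A)
    pairs <- cbind(sample(20, 8), sample(20, 8))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      v <- as.numeric(cmi(cc, i, j))
      expect_equal(v, as.numeric(cmi(cc, j, i)))
      expect_equal(v, oracle_cmi_all(A, i, j), tolerance = 1e-12)
    }
  }
})

test_that("cmi_matrix is consistent with elementwise calls", {
  cc <- generate_connectome(generator_config(n_regions = 16, n_links = 60,
                                             seed = 4))
  rows <- region_abbrev(cc)[1:4]
  cols <- region_abbrev(cc)[3:8]
  M <- cmi_matrix(cc, rows, cols)
  expect_true(is.na(M["R003_R", "R003_R"]))
  for (r in rows) for (cl in setdiff(cols, r)) {
    expect_equal(M[r, cl], as.numeric(cmi(cc, r, cl)))
  }
  # symmetric when rows = cols
  S <- cmi_matrix(cc, rows, rows)
  expect_equal(S, t(S))
})

test_that("GTOM follows the neighbourhood-overlap formula", {
  # adjacent pair with identical residual neighbourhoods scores 1
  cc <- toy_connectome(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1),
                             c(2, 3), c(3, 2), c(1, 4), c(4, 1),
                             c(2, 4), c(4, 2)), n = 4)
  G <- gtom(cc, 1)
  expect_equal(G["N1", "N2"], 1)
  # no shared neighbours, no direct edge -> 0
  cc2 <- toy_connectome(rbind(c(1, 3), c(3, 1), c(2, 4), c(4, 2)), n = 4)
  expect_equal(gtom(cc2, 1)["N1", "N2"], 0)
  # hand-built 5-node: N(1)={2,3}, N(5)={3,4}; shared {3};
  # min(2,2)+1-0 = 3 -> 1/3
  cc3 <- toy_connectome(rbind(c(1, 2), c(1, 3), c(5, 3), c(5, 4)), n = 5)
  expect_equal(gtom(cc3, 1)["N1", "N5"], 1 / 3)
  expect_error(gtom(cc3, 0), "m must be")
})

test_that("GTOM deepening saturates toward full overlap", {
  cc <- generate_connectome(generator_config(n_regions = 20, n_links = 90,
                                             seed = 8))
  g1 <- gtom(cc, 1); g2 <- gtom(cc, 2); g5 <- gtom(cc, 5)
  for (g in list(g1, g2, g5)) {
    expect_true(all(g >= 0 & g <= 1 + 1e-12))
    expect_equal(g, t(g))
  }
  # overlap predominantly grows with depth (the min-based normalization
  # allows occasional small dips) and saturates once the neighbourhoods
  # span the connected component
  expect_true(all(g2 - g1 >= -1e-12))
  expect_gt(mean(g5), mean(g1))
  comp <- igraph::components(as_igraph(cc), mode = "weak")
  if (comp$no == 1) expect_gt(min(g5), 0.8)
})

test_that("graph distances are directed, dual and match Floyd-Warshall", {
  cc <- toy_connectome(rbind(c(1, 2), c(2, 3)))
  gd <- graph_distances(cc)
  expect_equal(gd$D_out["N1", "N2"], 1)
  expect_equal(gd$D_out["N1", "N3"], 2)
  expect_equal(gd$D_in, t(gd$D_out))
  expect_true(is.infinite(gd$D_out["N3", "N1"]))
  for (seed in 1:4) {
    A <- random_digraph_matrix(30, 120, seed)
    ccr <- connectome_from_matrix(A)
    expect_equal(unname(graph_distances(ccr)$D_out), oracle_distances(A))
  }
})

test_that("spatial distances are Euclidean and symmetric", {
  coords <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  cc <- toy_connectome(rbind(c(1, 2)), n = 3, coords = coords)
  D <- spatial_distance(cc)
  expect_equal(D["N1", "N2"], 5)
  expect_equal(D["N1", "N3"], 0)
  expect_equal(D, t(D))
})

test_that("pair tables carry all statistics with coherent ranks", {
  cc <- generate_connectome(generator_config(n_regions = 20, n_links = 120,
                                             seed = 6))
  cc <- assign_groups(cc, motor = "R001_R", learning = c("R002_R", "R002_L"))
  les <- lesion_model("toy", c("R005_R", "R006_R"))
  pt <- pair_rank_table(cc, les)
  expect_equal(nrow(pt), (20 - 2) * 2)
  expect_setequal(unique(pt$marker), c(0L, 2L, 3L))
  # best CMI pair carries CMI rank 1
  expect_equal(pt$rank_CMI[which.max(pt$CMI_All)], 1)
  # ranks are tie-averaged permutations of 1..n
  expect_equal(sort(unique(round(pt$rank_D_spat, 6))),
               sort(unique(round(rank(pt$D_spat), 6))))
  # sorting by marker then spatial distance is reproducible
  ord <- order(pt$marker, pt$D_spat)
  expect_equal(pt$D_spat[ord][1:2], sort(pt$D_spat[pt$marker == 0])[1:2])
  # a supplied coactivation matrix is picked up
  co <- matrix(0.5, 20, 20, dimnames = list(region_abbrev(cc),
                                            region_abbrev(cc)))
  pt2 <- pair_rank_table(cc, les, coactivation = co)
  expect_true(all(pt2$coactivation == 0.5))
})
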