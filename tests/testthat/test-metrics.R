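test_that("reciprocity handles pure, absent and mixed cases", {
  expect_equal(reciprocity_stats(toy_connectome(rbind(c(1, 2), c(2, 1)))),
               list(count = 2L, ratio = 1))
  expect_equal(reciprocity_stats(toy_connectome(rbind(c(1, 2), c(2, 3))))$ratio, 0)
  mix <- reciprocity_stats(toy_connectome(rbind(c(1, 2), c(2, 1), c(2, 3))))
  expect_equal(mix$count, 2L)
  expect_equal(mix$ratio, 2 / 3)
  empty <- reciprocity_stats(connectome(data.frame(abbrev = "A")))
  expect_true(is.na(empty$ratio))
})

test_that("average path length matches hand cases and never grows with edges", {
  # complete digraph on 3 nodes
  cc <- toy_connectome(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  expect_equal(avg_path_length(cc)$value, 1)
  # 1 <-> 2, 2 -> 3: reachable distances {1,2,1,1}
  cc2 <- toy_connectome(rbind(c(1, 2), c(2, 1), c(2, 3)))
  apl2 <- avg_path_length(cc2)
  expect_equal(apl2$value, 1.25)
  expect_equal(apl2$n_unreachable, 2L)
  # adding an edge cannot increase the mean over a superset of pairs
  cc3 <- toy_connectome(rbind(c(1, 2), c(2, 1), c(2, 3), c(1, 3)))
  expect_lte(avg_path_length(cc3)$value, apl2$value)
})

test_that("path length and triplet metrics agree with brute-force oracles", {
  for (seed in 1:8) {
    A <- random_digraph_matrix(25, 90, seed)
    cc <- connectome_from_matrix(A)
    expect_equal(avg_path_length(cc)$value, oracle_avg_path_length(A),
                 tolerance = 1e-12)
    expect_equal(transitivity_coef(cc), oracle_transitivity(A),
                 tolerance = 1e-12)
    expect_equal(avg_clustering(cc), oracle_avg_clustering(A),
                 tolerance = 1e-12)
  }
})

test_that("clustering and transitivity are 1 on a triangle and 0 on a path", {
  tri <- toy_connectome(rbind(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(avg_clustering(tri), 1)
  expect_equal(transitivity_coef(tri), 1)
  path <- toy_connectome(rbind(c(1, 2), c(2, 3)))
  expect_equal(avg_clustering(path), 0)
  expect_equal(transitivity_coef(path), 0)
})

test_that("small-worldness is self-normalizing and label-invariant", {
  cc <- generate_connectome(generator_config(n_regions = 30, n_links = 200,
                                             seed = 4))
  expect_equal(small_worldness(cc, list(cc))$value, 1)
  # a clustered ring-like graph against an ER ensemble scores above 1
  n <- 30
  ring <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(c(i, i %% n + 1), c(i, (i + 1) %% n + 1))))
  rc <- toy_connectome(ring, n = n)
  sw <- small_worldness(rc, er_ensemble(rc, ensemble_spec("erdos_renyi",
                                                          size = 30, seed = 9)))
  expect_gt(sw$value, 1)
  # permuting region labels does not change the score
  perm <- sample(region_abbrev(cc))
  ccp <- connectome(cc$regions[match(perm, cc$regions$abbrev), ], cc$edges)
  expect_equal(small_worldness(ccp, list(ccp))$value, 1)
})

test_that("knotty-centrality matches exhaustive enumeration on small graphs", {
  for (seed in 1:6) {
    A <- random_digraph_matrix(8, 18, seed)
    cc <- connectome_from_matrix(A)
    bc <- igraph::betweenness(as_igraph(cc, weighted = FALSE),
                              directed = TRUE, weights = NA)
    got <- knotty_centrality(cc, exhaustive_max = 12)
    want <- oracle_knotty(A, bc)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_true(got$score >= 0 && got$score <= 1)
  }
  # greedy search on a larger graph stays within the oracle bound on a
  # small instance (greedy <= exhaustive optimum)
  A <- random_digraph_matrix(10, 30, 42)
  cc <- connectome_from_matrix(A)
  bc <- igraph::betweenness(as_igraph(cc, weighted = FALSE),
                            directed = TRUE, weights = NA)
  greedy <- knotty_centrality(cc, exhaustive_max = 2)  # force greedy path
  expect_lte(greedy$score,
             oracle_knotty(A, bc)$score + 1e-12)
})

test_that("a dense core with a periphery is recovered as the knotty subset", {
  # complete digraph on 4 core nodes plus 4 pendant nodes
  core <- as.matrix(expand.grid(1:4, 1:4))
  core <- core[core[, 1] != core[, 2], c(1, 2)]
  pend <- rbind(c(5, 1), c(1, 5), c(6, 2), c(2, 6), c(7, 3), c(3, 7),
                c(8, 4), c(4, 8))
  cc <- toy_connectome(rbind(core, pend), n = 8)
  kc <- knotty_centrality(cc)
  expect_setequal(kc$subset, paste0("N", 1:4))
  expect_gt(kc$score, 0.9)
})

test_that("local parameters behave on a star and match the betweenness oracle", {
  # star: center 1 connected bidirectionally to 5 leaves
  star <- do.call(rbind, lapply(2:6, function(i) rbind(c(1, i), c(i, 1))))
  cc <- toy_connectome(star, n = 6)
  lp <- local_parameters(cc, shapley_perm = 200)
  v <- lp$values
  expect_equal(unname(which.max(v[, "degree_all"])), 1L)
  expect_equal(unname(which.max(v[, "betweenness"])), 1L)
  expect_equal(unname(which.max(v[, "shapley"])), 1L)
  for (seed in 1:4) {
    A <- random_digraph_matrix(10, 25, seed)
    ccr <- connectome_from_matrix(A)
    lpr <- local_parameters(ccr, registry = data.frame(
      name = "betweenness", higher_better = TRUE))
    expect_equal(unname(lpr$values[, "betweenness"]), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("Katz with zero attenuation is uniform and Shapley matches its closed form", {
  cc <- generate_connectome(generator_config(n_regions = 20, n_links = 80,
                                             seed = 5))
  expect_equal(unname(lesionconn:::katz_centrality(cc, attenuation = 0)),
               rep(0, 20))
  mc <- shapley_rating(cc, n_perm = 4000, seed = 3)
  exact <- lesionconn:::shapley_exact_coverage(cc)
  expect_lt(max(abs(mc - unname(exact))), 0.2)
  expect_equal(sum(mc), 20, tolerance = 1e-9)
})

test_that("average ranks follow manual ranking and are scale invariant", {
  vals <- matrix(c(3, 2, 1,    # param A, higher better: ranks 1,2,3
                   10, 30, 20),# param B, higher better: ranks 3,1,2
                 ncol = 2, dimnames = list(c("r1", "r2", "r3"), c("A", "B")))
  m <- structure(list(values = vals,
                      registry = data.frame(name = c("A", "B"),
                                            higher_better = TRUE)),
                 class = "local_param_matrix")
  expect_equal(average_rank(m), c(r1 = 2, r2 = 1.5, r3 = 2.5))
  # positive rescaling of a column changes nothing
  m2 <- m; m2$values[, 2] <- m2$values[, 2] * 17
  expect_equal(average_rank(m2), average_rank(m))
  # a region best in every parameter has rank 1; ties share ranks
  vals3 <- matrix(c(5, 1, 1, 9, 2, 2), ncol = 2,
                  dimnames = list(c("r1", "r2", "r3"), c("A", "B")))
  m3 <- m; m3$values <- vals3
  ar <- average_rank(m3)
  expect_equal(unname(ar["r1"]), 1)
  expect_equal(unname(ar["r2"]), unname(ar["r3"]))
})

test_that("global metric table is permutation invariant", {
  cc <- generate_connectome(generator_config(n_regions = 24, n_links = 120,
                                             seed = 8))
  g1 <- global_metrics(cc)
  set.seed(1)
  perm <- sample(region_abbrev(cc))
  ccp <- connectome(cc$regions[match(perm, cc$regions$abbrev), ], cc$edges)
  g2 <- global_metrics(ccp)
  expect_equal(g1$reciprocity, g2$reciprocity)
  expect_equal(g1$avg_path_length, g2$avg_path_length)
  expect_equal(g1$transitivity, g2$transitivity)
  expect_equal(g1$knotty_centrality, g2$knotty_centrality, tolerance = 1e-9)
})
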