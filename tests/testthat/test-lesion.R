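test_that("lesion application removes regions and incident edges", {
  cc <- generate_connectome(generator_config(n_regions = 60, n_links = 400,
                                             seed = 2))
  les <- sample_lesion_set(cc, 6, "right", seed = 1)
  lc <- apply_lesion(cc, les)
  expect_equal(n_regions(lc), 54L)
  # conservation: removed links are exactly those incident to the lesion set
  incident <- sum(cc$edges$from %in% les$regions | cc$edges$to %in% les$regions)
  expect_equal(n_edges(lc) + incident, n_edges(cc))
  # empty lesion is the identity
  expect_equal(apply_lesion(cc, character())$edges, cc$edges)
  expect_error(apply_lesion(cc, "NOT_A_REGION"), "NOT_A_REGION")
})

test_that("sequential lesions compose like their union", {
  cc <- generate_connectome(generator_config(n_regions = 40, n_links = 300,
                                             seed = 3))
  l1 <- sample_lesion_set(cc, 5, "right", seed = 4)$regions
  l2 <- sample_lesion_set(cc, 5, "left", seed = 5)$regions
  seq_les <- apply_lesion(apply_lesion(cc, l1), l2)
  union_les <- apply_lesion(cc, union(l1, l2))
  expect_equal(seq_les$regions$abbrev, union_les$regions$abbrev)
  expect_equal(seq_les$edges, union_les$edges)
})

test_that("differential report matches hand enumeration on a toy digraph", {
  # 1 <-> 2, 2 -> 3, 3 -> 4; lesioning {4} leaves the reciprocal pair intact
  cc <- toy_connectome(rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 4)))
  rep <- differential_report(cc, "N4", sw_spec = NULL)
  expect_equal(rep$n_regions_lesioned, 3L)
  expect_equal(rep$n_links_lesioned, 3L)
  expect_equal(rep$reciprocal_edges_control, 2L)
  expect_equal(rep$reciprocal_edges_lesioned, 2L)
  expect_equal(rep$pct_reduction_reciprocal, 0)
  # empty lesion: all deltas zero
  rep0 <- differential_report(cc, character(), sw_spec = NULL)
  expect_equal(rep0$pct_reduction_reciprocal, 0)
  expect_equal(rep0$pct_increase_path_length, 0)
  expect_equal(rep0$pct_reduction_cluster_coeff, 0)
})

test_that("reciprocal-edge accounting matches a brute-force pair scan", {
  for (seed in 1:5) {
    A <- random_digraph_matrix(50, 300, seed)
    cc <- connectome_from_matrix(A)
    expect_equal(reciprocity_stats(cc)$count, oracle_reciprocal_count(A))
  }
})

test_that("functional loss percentages follow hand counts", {
  # M1 has 4 connections, exactly 1 to the lesioned region
  cc <- toy_connectome(rbind(c(1, 2), c(2, 1), c(1, 3), c(1, 4)),
                       abbrev = c("M1_R", "X_R", "Y_R", "L_R"))
  cc <- assign_groups(cc, motor = "M1_R")
  fl <- functional_loss(cc, "L_R", "motor")
  expect_equal(fl$n_connections, 4L)
  expect_equal(fl$n_lost, 1L)
  expect_equal(fl$pct_loss, 25)
  # region connected only to lesioned regions loses everything
  cc2 <- toy_connectome(rbind(c(1, 2), c(2, 1)), abbrev = c("M1_R", "L_R"))
  cc2 <- assign_groups(cc2, motor = "M1_R")
  expect_equal(functional_loss(cc2, "L_R", "motor")$pct_loss, 100)
  # no lesion contact
  cc3 <- toy_connectome(rbind(c(1, 2)), abbrev = c("M1_R", "X_R", "L_R"))
  cc3 <- assign_groups(cc3, motor = "M1_R")
  expect_equal(functional_loss(cc3, "L_R", "motor")$pct_loss, 0)
  expect_error(functional_loss(cc3, "L_R", "learning"), "learning")
})

test_that("connection census splits lesion links by functional group", {
  # 3 lesion-motor links, 1 lesion-learning link
  cc <- toy_connectome(rbind(c(1, 2), c(2, 1), c(1, 3), c(1, 4)),
                       abbrev = c("LES_R", "M1_R", "M2_R", "CA1_R"))
  cc <- assign_groups(cc, motor = c("M1_R", "M2_R"), learning = "CA1_R")
  cen <- connection_census(cc, "LES_R")
  expect_equal(unname(cen$counts), c(3L, 1L))
  expect_equal(unname(cen$percentages), c(75, 25))
  expect_true(cen$defined)
  # no lesion-group links: counts zero, percentages flagged undefined
  cc0 <- toy_connectome(rbind(c(1, 2)), abbrev = c("A_R", "B_R", "M1_R"))
  cc0 <- assign_groups(cc0, motor = "M1_R")
  cen0 <- connection_census(cc0, "A_R")
  expect_equal(sum(cen0$counts), 0L)
  expect_false(cen0$defined)
})

test_that("the MCRD triple filter applies RELi, MULi and NETi as specified", {
  # two lesioned regions (L1, L2) and three partners with controlled
  # observation counts and ranks
  regions <- data.frame(abbrev = c("L1", "L2", "P1", "P2", "P3"))
  edges <- data.frame(
    from = c("L1", "P1", "L2", "L1", "L1"),
    to   = c("P1", "L1", "P1", "P2", "P3"),
    observations = c(3L, 2L, 2L, 1L, 5L))
  cc <- connectome(regions, edges)
  ranks <- c(L1 = 4, L2 = 5, P1 = 1, P2 = 2, P3 = 3)
  # no-op filter keeps every lesion-touching pair record
  all_rec <- mcrd_filter(cc, c("L1", "L2"), reli = 1, muli = 0, neti = 1,
                         ranks = ranks)
  expect_equal(nrow(all_rec), 4L)
  expect_equal(all_rec$direction[all_rec$lesioned_region == "L1" &
                                 all_rec$partner_region == "P1"], "reciprocal")
  # RELi = 2 drops the single-observation connection (L1-P2)
  r2 <- mcrd_filter(cc, c("L1", "L2"), reli = 2, muli = 0, neti = 1,
                    ranks = ranks)
  expect_false(any(r2$partner_region == "P2"))
  # MULi = 2 keeps only P1 (touches both lesioned regions)
  rm_ <- mcrd_filter(cc, c("L1", "L2"), reli = 1, muli = 2, neti = 1,
                     ranks = ranks)
  expect_equal(unique(rm_$partner_region), "P1")
  # NETi = 0.2 keeps only the best-ranked 20% of regions: rank cutoff
  # excludes P3 (ranked in the worst 80%)
  rn <- mcrd_filter(cc, c("L1", "L2"), reli = 1, muli = 0, neti = 0.2,
                    ranks = ranks)
  expect_false(any(rn$partner_region == "P3"))
  expect_error(mcrd_filter(cc, "L1", neti = 0, ranks = ranks), "neti")
})

test_that("the MCRD filter is monotone in its three parameters", {
  cc <- generate_connectome(generator_config(n_regions = 40, n_links = 400,
                                             seed = 6))
  les <- sample_lesion_set(cc, 6, "right", seed = 2)
  ranks <- average_rank(local_parameters(cc, shapley_perm = 50))
  n_at <- function(reli, muli, neti)
    nrow(mcrd_filter(cc, les, reli, muli, neti, ranks))
  expect_gte(n_at(1, 0, 1), n_at(2, 0, 1))
  expect_gte(n_at(2, 0, 1), n_at(3, 0, 1))
  expect_gte(n_at(1, 0, 1), n_at(1, 2, 1))
  expect_gte(n_at(1, 0, 1), n_at(1, 0, 0.5))
  expect_gte(n_at(1, 0, 0.5), n_at(1, 0, 0.2))
})
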