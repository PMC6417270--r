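scheme <- scoring_scheme()

test_that("greedy clustering handles the elementary cases", {
  set.seed(51)
  s <- rand_seq(100)
  two_same <- protein_records(c("b", "a"), c(s, s))
  cs <- greedy_identity_cluster(two_same, scheme = scheme)
  expect_length(cs$clusters, 1L)
  expect_equal(cs$representative, "a")  # tie on length -> id order

  half <- paste0(substr(s, 1, 50), rand_seq(50))
  cs2 <- greedy_identity_cluster(protein_records(c("a", "b"), c(s, half)),
                                 scheme = scheme)
  expect_length(cs2$clusters, 2L)

  expect_error(greedy_identity_cluster(two_same, identity_threshold = 0),
               "identity_threshold")
})

test_that("greedy clustering satisfies the representative property and
           the word prefilter is inert", {
  set.seed(52)
  # mixed collection: 10 seed sequences, each with close (join) and
  # distant (split) variants
  seeds <- replicate(10, rand_seq(100))
  recs <- list()
  k <- 0
  for (i in seq_along(seeds)) {
    for (v in 1:4) {
      k <- k + 1
      rate <- if (v <= 2) 0.04 else 0.5
      recs[[k]] <- mutate_variant(seeds[i], rate)
    }
  }
  col <- protein_records(sprintf("s%02d", seq_len(k)), unlist(recs))
  with_pf <- greedy_identity_cluster(col, scheme = scheme)
  without_pf <- greedy_identity_cluster(col, scheme = scheme,
                                        use_prefilter = FALSE)
  expect_identical(canon_partition(with_pf$clusters),
                   canon_partition(without_pf$clusters))
  expect_identical(with_pf$representative, without_pf$representative)

  # partition property: disjoint cover
  all_ids <- sort(unlist(with_pf$clusters))
  expect_identical(all_ids, sort(col$id))

  # every member >= 0.90 identity to its representative (all-pairs
  # identity oracle via direct alignment)
  for (ci in seq_along(with_pf$clusters)) {
    rep_id <- with_pf$representative[ci]
    rep_rec <- col[col$id == rep_id, , drop = FALSE]
    for (mem in with_pf$clusters[[ci]]) {
      mrec <- col[col$id == mem, , drop = FALSE]
      hit <- local_align(mrec, rep_rec, scheme)
      ident <- hit$nident / min(nchar(mrec$seq), nchar(rep_rec$seq))
      expect_gte(ident, 0.90)
    }
  }
})

test_that("MCL separates disconnected parts and keeps cliques together", {
  tri2 <- similarity_graph(
    c("a", "b", "c", "d", "e", "f"),
    data.frame(from = c("a", "b", "c", "d", "e", "f"),
               to = c("b", "c", "a", "e", "f", "d"),
               weight = 1))
  cs <- mcl_cluster(tri2)
  expect_length(cs$clusters, 2L)
  expect_identical(canon_partition(cs$clusters), "a,b,c|d,e,f")

  k4 <- similarity_graph(
    letters[1:4],
    data.frame(from = c("a", "a", "a", "b", "b", "c"),
               to = c("b", "c", "d", "c", "d", "d"), weight = 1))
  expect_length(mcl_cluster(k4)$clusters, 1L)
})

test_that("MCL matches a long-run fixed-point oracle on random small graphs", {
  set.seed(53)
  for (i in 1:60) {
    g <- random_graph(sample(3:6, 1), p_edge = stats::runif(1, 0.3, 0.9))
    sg <- similarity_graph(g$nodes, g$edges)
    cs <- mcl_cluster(sg, inflation = 1.4)
    oracle <- mcl_oracle_partition(g$nodes, g$edges, inflation = 1.4)
    expect_identical(canon_partition(cs$clusters),
                     canon_partition(oracle), info = i)
    # every cluster is contained in one connected component
    ig <- igraph::graph_from_data_frame(
      g$edges, directed = FALSE,
      vertices = data.frame(name = g$nodes))
    comp <- igraph::components(ig)$membership
    for (cl in cs$clusters) {
      expect_length(unique(comp[cl]), 1L)
    }
    # partition property
    expect_identical(sort(unlist(cs$clusters)), sort(g$nodes))
  }
})

test_that("MCL is invariant to node input order", {
  set.seed(54)
  g <- random_graph(6, 0.6)
  sg1 <- similarity_graph(g$nodes, g$edges)
  perm <- sample(length(g$nodes))
  sg2 <- similarity_graph(g$nodes[perm],
                          g$edges[sample(nrow(g$edges)), , drop = FALSE])
  expect_identical(canon_partition(mcl_cluster(sg1)$clusters),
                   canon_partition(mcl_cluster(sg2)$clusters))
})

test_that("similarity graphs validate their input", {
  expect_error(similarity_graph("a", data.frame(from = "a", to = "b",
                                                weight = 1)),
               "endpoints")
  expect_error(similarity_graph(c("a", "b"),
                                data.frame(from = c("a", "b"),
                                           to = c("b", "a"),
                                           weight = 1)),
               "duplicate")
  expect_error(similarity_graph(c("a", "b"),
                                data.frame(from = "a", to = "b",
                                           weight = -1)),
               "non-negative")
})

test_that("the seed cluster is retained and a missing seed is an error", {
  cs <- cluster_set(list(c("a", "b"), "q"), c("a", "q"), "mcl")
  expect_identical(retain_seed_cluster(cs, "q"), "q")
  expect_identical(retain_seed_cluster(cs, "b"), c("a", "b"))
  expect_error(retain_seed_cluster(cs, "zz"), "zz")
})
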