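test_that("modularity matches closed forms", {
  A <- withr::with_seed(1, random_graph(7))
  net <- as_network(A)
  # all nodes in one community
  expect_equal(newman_girvan_modularity(net, rep(1, 7)), 0)

  # two disjoint unit edges, partitioned by edge: Q = 2 * (1/2 - 1/4) = 0.5
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 1
  A2[3, 4] <- A2[4, 3] <- 1
  expect_equal(newman_girvan_modularity(as_network(A2), c(1, 1, 2, 2)), 0.5)

  # all-singleton partition on a loop-free graph is negative
  expect_true(newman_girvan_modularity(net, 1:7) < 0)

  expect_error(newman_girvan_modularity(as_network(matrix(0, 3, 3)),
                                        c(1, 1, 2)), "zero total weight")
})

test_that("modularity agrees with igraph and the pairwise-sum oracle on random graphs", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(5:12, 1)
      A <- random_graph(n)
      labels <- sample(1:3, n, replace = TRUE)
      net <- as_network(A)
      q <- newman_girvan_modularity(net, labels)
      expect_equal(q, modularity_pairsum(A, labels))
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                               weighted = TRUE)
      expect_equal(q, igraph::modularity(g, labels,
                                         weights = igraph::E(g)$weight))
    }
  })
})

test_that("Louvain recovers two disjoint cliques and matches the exhaustive optimum", {
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1
  A[5:8, 5:8] <- 1
  diag(A) <- 0
  net <- as_network(A)
  part <- louvain_partition(net, seed = 1)
  expect_equal(length(part$sizes), 2L)
  expect_equal(unname(part$labels[1:4]), rep(part$labels[[1]], 4))
  expect_equal(unname(part$labels[5:8]), rep(part$labels[[5]], 4))
  expect_equal(part$Q, max_modularity_exhaustive(A), tolerance = 1e-12)
})

test_that("a complete uniform graph admits no positive split and stays whole", {
  A <- matrix(1, 6, 6); diag(A) <- 0
  expect_equal(max_modularity_exhaustive(A), 0, tolerance = 1e-12)
  part <- louvain_partition(as_network(A), seed = 1)
  expect_equal(length(part$sizes), 1L)
  expect_equal(part$Q, 0)
})

test_that("Louvain attains the exhaustive-partition modularity maximum (N <= 8)", {
  withr::with_seed(2025, {
    for (rep in 1:20) {
      n <- sample(5:8, 1)
      A <- random_graph(n)
      qmax <- max_modularity_exhaustive(A)
      net <- as_network(A)
      qbest <- -Inf
      for (s in 1:10) {
        qbest <- max(qbest, louvain_partition(net, seed = s)$Q)
        if (qbest >= qmax - 1e-12) break
      }
      expect_gte(qbest, qmax - 1e-12)
      # whenever a positive-Q partition exists, the returned Q is >= 0
      if (qmax > 1e-12) expect_gte(qbest, 0)
    }
  })
})

test_that("Louvain is deterministic under a fixed seed", {
  prof <- withr::with_seed(5, random_profiles(30, 6, 4))
  net <- build_similarity_matrix(prof)
  p1 <- louvain_partition(net, seed = 42)
  p2 <- louvain_partition(net, seed = 42)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$Q, p2$Q)
})

test_that("small communities are unretained but keep their labels", {
  bl <- block_network(c(12, 11, 3), w_in = 10, w_out = 1)
  part <- louvain_partition(bl$network, seed = 1)
  expect_equal(sort(unname(part$sizes)), c(3L, 11L, 12L))

  filt <- filter_small(part, min_size = 10)
  expect_equal(length(filt$retained), 2L)
  expect_equal(sum(filt$flagged), 3L)
  expect_identical(filt$labels, part$labels)   # labels preserved
  expect_identical(filter_small(part, 1)$retained,
                   sort(as.integer(names(part$sizes))))
  expect_warning(filter_small(part, min_size = 50), "empty")
})

test_that("subtype profiles follow the normalized-average definition", {
  # community of 2 with both affected at baseline, U = 0.5 -> S = 2, fraction = 1
  arr <- array(0, c(4, 2, 2))
  arr[1:2, 1, ] <- 1                      # members of the community
  prof <- as_profiles(arr)
  U <- c(c1 = 0.5, c2 = 0.25)
  sp <- subtype_profile(prof, U, members = 1:2, community_id = 1L)
  expect_equal(sp$S["c1", 1], 2)
  expect_equal(sp$affected_fraction["c1", 1], 1)
  # all-zero column with positive U -> S = 0
  expect_equal(sp$S["c2", 1], 0)
  expect_equal(sp$N_l, 2L)

  # community = entire population at baseline -> S = 1 wherever U > 0
  arr2 <- withr::with_seed(8, array(rbinom(24, 1, 0.6), c(4, 3, 2)))
  prof2 <- as_profiles(arr2)
  U2 <- baseline_normalizers(prof2)
  sp2 <- subtype_profile(prof2, U2, members = 1:4)
  expect_equal(unname(sp2$S[U2 > 0, 1]), rep(1, sum(U2 > 0)))

  # U = 0 columns are undefined and flagged
  arr3 <- arr2; arr3[, 2, 1] <- 0
  prof3 <- as_profiles(arr3)
  U3 <- baseline_normalizers(prof3)
  sp3 <- subtype_profile(prof3, U3, members = 1:3)
  expect_equal(sp3$undefined_columns, "c2")
  expect_true(all(is.na(sp3$S["c2", ])))
})

test_that("S * U * N_l recovers integer affected counts", {
  withr::with_seed(9, {
    prof <- random_profiles(20, 5, 3)
    labels <- sample(1:3, 20, replace = TRUE)
    U <- baseline_normalizers(prof)
    for (cid in 1:3) {
      sp <- subtype_profile(prof, U, members = which(labels == cid),
                            community_id = cid)
      counts <- sp$S * U * sp$N_l   # U recycles over columns of S
      counts <- counts[U > 0, ]
      expect_true(all(abs(counts - round(counts)) < 1e-9))
    }
  })
})
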