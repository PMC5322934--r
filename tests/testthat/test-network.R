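# Network construction, transient flags and betweenness centrality.

test_that("edges require both the correlation and the contact threshold", {
  md <- diag(1, 3)
  md[1, 2] <- md[2, 1] <- 0.6   # passes mDCC, in contact
  md[1, 3] <- md[3, 1] <- 0.6   # passes mDCC, too far
  md[2, 3] <- md[3, 2] <- 0.45  # fails mDCC at any distance
  dd <- ifelse(row(md) != col(md), 10, 0)
  dd[1, 2] <- dd[2, 1] <- 4
  net <- build_network(as_mdcc_matrix(md, md, dd))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(c(net$edges$a, net$edges$b), c(1L, 2L))
  expect_false(net$edges$transient)
})

test_that("transient edges are flagged when DCC stays below threshold", {
  md <- diag(1, 2)
  md[1, 2] <- md[2, 1] <- 0.6
  dc <- diag(1, 2)
  dc[1, 2] <- dc[2, 1] <- 0.3
  dd <- matrix(4, 2, 2); diag(dd) <- 0
  net <- build_network(as_mdcc_matrix(md, dc, dd))
  expect_equal(nrow(net$edges), 1L)
  expect_true(net$edges$transient)
})

test_that("closed-form betweenness: path, star and 4-cycle", {
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  b <- residue_betweenness(network_from_adjacency(path3))
  expect_equal(unname(b), c(0, 1, 0))

  star <- matrix(0L, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1L
  b <- residue_betweenness(network_from_adjacency(star))
  expect_equal(unname(b), c(3, 0, 0, 0))

  cyc4 <- matrix(0L, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; cyc4[i, j] <- cyc4[j, i] <- 1L }
  b <- residue_betweenness(network_from_adjacency(cyc4))
  expect_equal(unname(b), rep(0.5, 4))
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  set.seed(12)
  for (r in 1:30) {
    n <- sample(4:12, 1)
    adj <- random_connected_graph(n, p = runif(1, 0.2, 0.5))
    b <- residue_betweenness(network_from_adjacency(adj))
    expect_equal(unname(b), brute_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("disconnected components score independently", {
  adj <- matrix(0L, 6, 6)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- 1L  # path 1-2-3
  adj[4, 5] <- adj[5, 4] <- 1L                            # pair 4-5; 6 isolated
  b <- residue_betweenness(network_from_adjacency(adj))
  expect_equal(unname(b), c(0, 1, 0, 0, 0, 0))
})

test_that("removing an edge never increases shortest-path counts", {
  set.seed(13)
  for (r in 1:10) {
    adj <- random_connected_graph(7, 0.4)
    edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    e <- edges[sample(nrow(edges), 1), ]
    adj2 <- adj
    adj2[e[1], e[2]] <- adj2[e[2], e[1]] <- 0L
    for (s in 1:6) for (t in (s + 1):7) {
      s1 <- brute_sigma(adj, s, t)
      s2 <- brute_sigma(adj2, s, t)
      # only compare at equal path length; a removed edge can lengthen paths
      p1 <- enum_shortest_paths(adj, s, t)
      p2 <- enum_shortest_paths(adj2, s, t)
      if (length(p1) > 0 && length(p2) > 0 &&
          length(p1[[1]]) == length(p2[[1]])) {
        expect_lte(s2, s1)
      }
    }
  }
})

test_that("tree betweenness sums to the total intermediate-node count", {
  set.seed(14)
  for (r in 1:10) {
    n <- sample(5:12, 1)
    adj <- random_tree(n)
    b <- residue_betweenness(network_from_adjacency(adj))
    total <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      p <- enum_shortest_paths(adj, s, t)[[1]]  # unique path in a tree
      total <- total + (length(p) - 2)
    }
    expect_equal(sum(b), total, tolerance = 1e-12)
  }
})

test_that("raising the mDCC threshold never adds edges", {
  set.seed(15)
  n <- 8
  md <- matrix(0, n, n)
  md[upper.tri(md)] <- runif(n * (n - 1) / 2, -1, 1)
  md <- md + t(md); diag(md) <- 1
  dd <- matrix(0, n, n)
  dd[upper.tri(dd)] <- runif(n * (n - 1) / 2, 1, 8)
  dd <- dd + t(dd)
  m <- as_mdcc_matrix(md, md, dd)
  e1 <- build_network(m, mdcc_threshold = 0.3)$edges
  e2 <- build_network(m, mdcc_threshold = 0.6)$edges
  k1 <- paste(e1$a, e1$b)
  k2 <- paste(e2$a, e2$b)
  expect_true(all(k2 %in% k1))
})

test_that("per-molecule rankings partition nodes with deterministic ties", {
  path4 <- matrix(0L, 4, 4)
  for (i in 1:3) path4[i, i + 1] <- path4[i + 1, i] <- 1L
  net <- network_from_adjacency(path4, molecule = c("A", "A", "B", "B"))
  tb <- top_betweenness(net, per_molecule = 15)
  expect_equal(sort(unique(tb$molecule)), c("A", "B"))
  expect_equal(sum(tb$molecule == "A"), 2L)
  # all-equal betweenness falls back to node order
  iso <- network_from_adjacency(matrix(0L, 3, 3))
  tb0 <- top_betweenness(iso, per_molecule = 2)
  expect_equal(tb0$residue, iso$nodes$key[1:2])
  expect_equal(tb0$rank, 1:2)
})

test_that("the any-mode-pair rule can draw edges the provenance rule misses", {
  # provenance pair: mdcc 0.9 at 6 A (no contact); second candidate pair:
  # mdcc 0.6 at 4 A (contact) -> edge only under any_mode_pair = TRUE
  m <- as_mdcc_matrix(diag(1, 2) + 0.9 - 0.9 * diag(1, 2),
                      diag(1, 2), matrix(6, 2, 2))
  extra <- data.frame(a = 1L, b = 2L, atom_i = NA_integer_,
                      atom_j = NA_integer_, k = 2L, l = 2L, mdcc = 0.6,
                      mean_weight = 0.5, center_distance = 4)
  m$candidates <- rbind(m$candidates, extra)
  expect_equal(nrow(build_network(m)$edges), 0L)
  net <- build_network(m, any_mode_pair = TRUE)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$mdcc, 0.6)
})

test_that("network exports write edge list, GraphML and rankings", {
  path3 <- matrix(0L, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1L
  net <- network_from_adjacency(path3)
  e <- withr::local_tempfile(fileext = ".tsv")
  g <- withr::local_tempfile(fileext = ".graphml")
  b <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, edges_tsv = e, graphml = g, betweenness_tsv = b)
  expect_equal(nrow(read.table(e, sep = "\t", header = TRUE)), 2L)
  expect_true(any(grepl("graphml", readLines(g))))
  expect_equal(nrow(read.table(b, sep = "\t", header = TRUE)), 3L)
})
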