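path_edges <- data.frame(from = c("a", "b"), to = c("b", "c"))

test_that("hub classification is inclusive at the degree boundary", {
  star <- data.frame(from = "hub", to = paste0("leaf", 1:3))
  expect_setequal(classify_hubs(star, 3), "hub")            # degree exactly k
  expect_length(classify_hubs(star, 4), 0)                  # degree k - 1
  expect_error(classify_hubs(star, 0), ">= 1")
  empty <- data.frame(from = character(0), to = character(0))
  expect_length(classify_hubs(empty, 1, nodes = c("x", "y")), 0)
})

test_that("hub sets are nested as the threshold rises", {
  e <- random_connected_edges(30, 0.2, seed = 3)
  for (k in 1:6)
    expect_true(all(classify_hubs(e, k + 1) %in% classify_hubs(e, k)))
})

test_that("clustering coefficients match exhaustive triangle counting", {
  tri <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"))
  expect_equal(unname(clustering_coefficients(tri)), rep(1, 3))
  star <- data.frame(from = "c0", to = paste0("l", 1:4))
  cc <- clustering_coefficients(star)
  expect_equal(unname(cc["c0"]), 0)
  expect_equal(unname(cc[paste0("l", 1:4)]), rep(0, 4))  # degree < 2
  # brute-force oracle on a random graph
  e <- random_connected_edges(8, 0.5, seed = 7)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  cc <- clustering_coefficients(e)
  for (v in rownames(a)) {
    nb <- names(which(a[v, ] == 1))
    deg <- length(nb)
    tri_n <- 0
    if (deg >= 2)
      for (i in seq_along(nb)) for (j in seq_along(nb))
        if (i < j && a[nb[i], nb[j]] == 1) tri_n <- tri_n + 1
    expected <- if (deg < 2) 0 else 2 * tri_n / (deg * (deg - 1))
    expect_equal(unname(cc[v]), expected, tolerance = 1e-12)
  }
})

test_that("mean shortest paths follow the reachable-only convention", {
  msp <- mean_shortest_paths(path_edges)
  expect_equal(unname(msp["b"]), 1.0)
  expect_equal(unname(msp[c("a", "c")]), c(1.5, 1.5))
  k4 <- t(combn(paste0("v", 1:4), 2))
  expect_equal(unname(mean_shortest_paths(
    data.frame(from = k4[, 1], to = k4[, 2]))), rep(1, 4))
  two <- data.frame(from = c("a", "c"), to = c("b", "d"))
  expect_equal(unname(mean_shortest_paths(two)), rep(1, 4))
  iso <- mean_shortest_paths(path_edges, nodes = c("a", "b", "c", "z"))
  expect_true(is.na(iso["z"]))
})

# independent information-centrality oracle: resistance distances from the
# Moore-Penrose pseudoinverse of the Laplacian
ic_oracle <- function(edges, nodes = NULL) {
  g <- senescnet:::as_undirected_graph(edges, nodes)
  a <- as.matrix(igraph::as_adjacency_matrix(g))
  l <- diag(rowSums(a)) - a
  gamma <- MASS::ginv(l)
  n <- nrow(a)
  r <- outer(diag(gamma), diag(gamma), "+") - 2 * gamma
  out <- n / rowSums(r)
  names(out) <- rownames(a)
  out
}

test_that("information centrality is vertex-symmetric on complete graphs", {
  k4 <- t(combn(paste0("v", 1:4), 2))
  ic <- information_centrality(data.frame(from = k4[, 1], to = k4[, 2]))
  expect_equal(max(ic) - min(ic), 0, tolerance = 1e-12)
  expect_true(all(ic > 0))
})

test_that("star centers carry more information centrality than leaves", {
  star <- data.frame(from = "c0", to = paste0("l", 1:4))
  ic <- information_centrality(star)
  expect_gt(ic["c0"], ic["l1"])
  expect_equal(max(ic[paste0("l", 1:4)]) - min(ic[paste0("l", 1:4)]), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(ic), as.numeric(ic_oracle(star)[names(ic)]),
               tolerance = 1e-8)
})

test_that("information centrality equals the matrix-inversion oracle on random graphs", {
  for (seed in 1:5) {
    e <- random_connected_edges(30, 0.15, seed)
    ic <- information_centrality(e)
    orc <- ic_oracle(e)
    expect_equal(as.numeric(ic), as.numeric(orc[names(ic)]),
                 tolerance = 1e-8)
  }
})

test_that("adding an edge never decreases its endpoints' centrality", {
  for (seed in 1:5) {
    e <- random_connected_edges(10, 0.3, seed)
    g <- igraph::graph_from_data_frame(e, directed = FALSE)
    a <- as.matrix(igraph::as_adjacency_matrix(g))
    miss <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
    if (!nrow(miss)) next
    pick <- miss[1, ]
    v1 <- rownames(a)[pick[1]]; v2 <- rownames(a)[pick[2]]
    before <- information_centrality(e)
    after <- information_centrality(rbind(e, data.frame(from = v1, to = v2)))
    expect_gte(after[v1], before[v1] - 1e-10)
    expect_gte(after[v2], before[v2] - 1e-10)
  }
})

test_that("singleton components yield missing centrality with a warning", {
  expect_warning(ic <- information_centrality(path_edges,
                                              nodes = c("a", "b", "c", "z")),
                 "singleton")
  expect_true(is.na(ic["z"]))
  expect_true(all(!is.na(ic[c("a", "b", "c")])))
})

test_that("module-versus-network centrality comparison detects planted shifts", {
  set.seed(21)
  ic <- setNames(rnorm(60, 10, 1), paste0("g", 1:60))
  part <- setNames(rep("grey", 60), names(ic))
  part[1:10] <- "turquoise"
  ic[1:10] <- ic[1:10] + 10   # +10 sigma shift
  out <- compare_module_centrality(ic, part)
  expect_lt(out$p[out$module == "turquoise"], 1e-10)
  part2 <- part; part2[11] <- "blue"  # singleton module
  expect_error(compare_module_centrality(ic, part2), "fewer than 2")
})

test_that("a module drawn from the network distribution is rarely called different", {
  set.seed(22)
  extreme <- 0
  for (i in 1:20) {
    ic <- setNames(rnorm(200, 5, 1), paste0("g", 1:200))
    part <- setNames(rep("grey", 200), names(ic))
    part[sample(200, 30)] <- "turquoise"
    out <- compare_module_centrality(ic, part)
    if (out$p < 0.01) extreme <- extreme + 1
  }
  expect_lte(extreme, 1)  # >= 95% of replicates non-extreme
})

test_that("hypergeometric enrichment is exact", {
  expect_equal(hypergeom_enrichment(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-15)
  expect_equal(hypergeom_enrichment(10, 5, 5, 0), 1)
  expect_error(hypergeom_enrichment(10, 5, 5, 6), "overlap")
  expect_error(hypergeom_enrichment(10, 12, 5, 2), "universe")
  expect_error(hypergeom_enrichment(10, 5, 5, -1), "non-negative")
})

test_that("topology report is internally consistent", {
  e <- random_connected_edges(25, 0.2, seed = 11)
  rep_ <- topology_report(e, hub_k = 5)
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  expect_setequal(rep_$node, igraph::V(g)$name)
  expect_identical(rep_$is_hub, rep_$degree >= 5)
  expect_true(all(rep_$information_centrality > 0))
  expect_true(all(rep_$clustering >= 0 & rep_$clustering <= 1))
})
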