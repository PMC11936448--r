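graph_from_edges <- function(n, edges) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

test_that("correlation matrix honours duplication, independence, and symmetry", {
  # two regions with identical counts correlate perfectly
  subj <- sprintf("s%d", 1:10)
  set.seed(1)
  v <- rnorm(10, 100, 10)
  tbl <- dplyr::bind_rows(
    tibble::tibble(subject_id = subj, group = "15min", region_id = 1L,
                   region_abbrev = "A", count = v),
    tibble::tibble(subject_id = subj, group = "15min", region_id = 2L,
                   region_abbrev = "B", count = v),
    tibble::tibble(subject_id = subj, group = "15min", region_id = 3L,
                   region_abbrev = "C", count = rnorm(10, 100, 10)))
  cm <- correlation_matrix(tbl)
  expect_equal(cm$r[1, 2], 1)
  expect_equal(cm$r, t(cm$r))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)

  # independent noise at large n: mean |r| near zero
  big <- simulate_count_table(count_table_spec(
    n_regions = 50, n_communities = 1,
    groups = tibble::tibble(label = "15min", n_female = 50L, n_male = 50L),
    fold_change = c("15min" = 1), latent_loading = 0, dispersion = 0.5,
    seed = 2))
  r <- correlation_matrix(big)$r
  expect_lt(mean(abs(r[upper.tri(r)])), 0.12)
})

test_that("density thresholding keeps the top |r| edges with signed weights", {
  r <- toy_corr_4()
  full <- threshold_at_density(r, 1)
  expect_equal(full$n_edges, 6L)

  # strongest entry negative: present with its sign at any density
  rn <- r; rn[1, 2] <- rn[2, 1] <- -0.95
  bg <- threshold_at_density(rn, 1 / 6)
  edges <- tidy(bg)
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$weight, -0.95)
  expect_equal(edges$sign, "negative")

  # 143-node budget: round(rho * 10153)
  set.seed(3)
  m <- matrix(rnorm(143^2), 143); m <- (m + t(m)) / 2; diag(m) <- 1
  m <- m / max(abs(m[upper.tri(m)]))
  expect_equal(threshold_at_density(m, 0.025)$n_edges, round(0.025 * 10153))
  expect_true(threshold_at_density(m, 0.025)$n_edges %in% 253:256)
  expect_equal(threshold_at_density(m, 256 / 10153)$n_edges, 256L)

  # deterministic lexicographic tie-break among equal |r|
  tie <- diag(4)
  tie[1, 2] <- tie[2, 1] <- 0.5
  tie[3, 4] <- tie[4, 3] <- 0.5
  tie[1, 3] <- tie[3, 1] <- -0.5
  kept <- tidy(threshold_at_density(tie, 1 / 6))
  expect_equal(nrow(kept), 1L)
  expect_equal(abs(kept$weight), 0.5)
  # earliest (row, col) pair wins: edge 1-2
  expect_setequal(c(kept$from, kept$to), c("R001", "R002"))

  # undefined entries are never selected
  nau <- diag(3); nau[1, 2] <- nau[2, 1] <- NA; nau[1, 3] <- nau[3, 1] <- 0.4
  nau[2, 3] <- nau[3, 2] <- 0.2
  expect_equal(threshold_at_density(nau, 1)$n_edges, 2L)
})

test_that("efficiencies match hand enumeration on canonical small graphs", {
  k3 <- graph_from_edges(3, c(1, 2, 2, 3, 1, 3))
  expect_equal(global_efficiency(k3), 1)
  expect_equal(local_efficiency(k3), 1)
  path3 <- graph_from_edges(3, c(1, 2, 2, 3))
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(local_efficiency(path3), 0)
  expect_equal(global_efficiency(graph_from_edges(2, integer(0))), 0)
  k4 <- graph_from_edges(4, c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4))
  expect_equal(local_efficiency(k4), 1)
})

test_that("ECO selection equals brute-force maximisation of (Eg+El)/rho", {
  r <- toy_corr_4()
  grid <- (1:6) / 6
  eco <- eco_select_density(r, grid)
  expect_equal(eco$best_density, 0.5)
  expect_equal(max(eco$curve$J), 2.5)
  expect_equal(eco$best_graph$n_edges, 3L)

  # brute-force oracle over the same grid using the independent oracles
  ord <- order(-abs(r[upper.tri(r)]))
  pairs <- which(upper.tri(r), arr.ind = TRUE)[ord, ]
  oracle_J <- vapply(1:6, function(k) {
    adj <- matrix(0, 4, 4)
    for (e in seq_len(k)) adj[pairs[e, 1], pairs[e, 2]] <-
        adj[pairs[e, 2], pairs[e, 1]] <- 1
    (global_efficiency_oracle(adj) + local_efficiency_oracle(adj)) / (k / 6)
  }, numeric(1))
  expect_equal(eco$curve$J, oracle_J)
  expect_equal(eco$best_density, grid[which.max(oracle_J)])

  # two-node system: one nontrivial density
  r2 <- diag(2); r2[1, 2] <- r2[2, 1] <- 0.4
  eco2 <- eco_select_density(r2, 1)
  expect_equal(eco2$best_graph$n_edges, 1L)
  expect_error(eco_select_density(r, numeric(0)),
               class = "fishmap_error_validation")
})

test_that("giant component follows the size-then-first-vertex tie rule", {
  full <- igraph::make_full_graph(5)
  expect_equal(igraph::vcount(giant_component(full)), 5L)
  edgeless <- graph_from_edges(3, integer(0))
  gc <- giant_component(edgeless)
  expect_equal(igraph::vcount(gc), 1L)
  two_tri <- graph_from_edges(8, c(1, 2, 2, 3, 1, 3,       # triangle
                                   4, 5, 5, 6, 4, 6, 4, 7, # 4-clique-ish
                                   7, 8))
  igraph::V(two_tri)$name <- as.character(1:8)
  gc2 <- giant_component(two_tri)
  expect_setequal(igraph::V(gc2)$name, as.character(4:8))
})

test_that("centralities match a power-iteration oracle and obvious symmetries", {
  star <- igraph::make_star(5, mode = "undirected")
  cent <- centralities(star)
  expect_equal(which.max(cent$degree), 1L)
  expect_equal(which.max(cent$eigenvector), 1L)

  ring <- igraph::make_ring(6)
  cr <- centralities(ring)
  expect_true(all(abs(cr$degree - 2) < 1e-12))
  expect_true(all(abs(cr$eigenvector - 1) < 1e-9))

  set.seed(4)
  g <- igraph::sample_gnp(20, 0.3)
  while (igraph::components(g)$no > 1) g <- igraph::sample_gnp(20, 0.3)
  ev <- centralities(g)$eigenvector
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  v <- rep(1, 20)
  for (i in 1:10000) v <- adj %*% v / sqrt(sum((adj %*% v)^2))
  v <- as.numeric(v / max(v))
  expect_equal(ev, v, tolerance = 1e-8)

  # disconnected: eigenvector on giant component, others zero, with warning
  dis <- igraph::disjoint_union(igraph::make_full_graph(4),
                                igraph::make_full_graph(2))
  expect_warning(cd <- centralities(dis), "disconnected")
  expect_true(all(cd$eigenvector[5:6] == 0))
})

test_that("Louvain recovers planted cliques and is seed-reproducible", {
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(5),
                                        igraph::make_full_graph(5))
  two_cliques <- igraph::add_edges(two_cliques, c(1, 6))
  part <- louvain_partition(two_cliques, seed = 1)
  memb <- tidy(part)$community
  expect_equal(part$n_communities, 2L)
  expect_true(all(memb[1:5] == memb[1]) && all(memb[6:10] == memb[6]))
  expect_false(memb[1] == memb[6])

  expect_equal(louvain_partition(igraph::make_full_graph(6),
                                 seed = 2)$n_communities, 1L)

  p1 <- louvain_partition(two_cliques, seed = 9, restarts = 5)
  p2 <- louvain_partition(two_cliques, seed = 9, restarts = 5)
  expect_identical(p1$membership, p2$membership)
  expect_error(louvain_partition(graph_from_edges(3, integer(0))),
               class = "fishmap_error_validation")
})

test_that("node roles reproduce hand-computed z and participation values", {
  # community 1: star on nodes 1-4 (1 is centre); community 2: triangle 5-7;
  # plus one bridge 2-5
  g <- graph_from_edges(7, c(1, 2, 1, 3, 1, 4, 5, 6, 6, 7, 5, 7, 2, 5))
  part <- tibble::tibble(region = as.character(1:7),
                         community = c(1, 1, 1, 1, 2, 2, 2))
  igraph::V(g)$name <- as.character(1:7)
  roles <- node_roles(g, part)

  # star community: centre z = +1.732, leaves z = -0.577 (population SD)
  expect_equal(roles$z[1], 1.5 / sqrt(0.75), tolerance = 1e-12)
  expect_equal(roles$z[3], -0.5 / sqrt(0.75), tolerance = 1e-12)
  # all-internal node: P = 0
  expect_equal(roles$participation[1], 0)
  # node 2: degree 2, 1 edge in community, 1 outside -> P = 1/2
  expect_equal(roles$participation[2], 0.5)
  # node 5: degree 3, 2 in its community, 1 outside -> P = 1 - (2/3)^2 - (1/3)^2
  expect_equal(roles$participation[5], 4 / 9)

  # K_is sums to degree; z has mean 0 and population SD 1 per community
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  expect_equal(roles$degree, rowSums(adj), ignore_attr = TRUE)
  # community 1 has spread: z standardised to mean 0, population SD 1
  zs <- roles$z[roles$community == 1]
  expect_equal(mean(zs), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zs^2)), 1, tolerance = 1e-12)
  # community 2 is a clique: zero spread collapses every z to 0
  expect_true(all(roles$z[roles$community == 2] == 0))
})

test_that("role labels follow the hub/connector thresholds", {
  # large star: centre z well above 2.5
  n <- 30
  g <- igraph::make_star(n, mode = "undirected")
  igraph::V(g)$name <- as.character(1:n)
  part <- tibble::tibble(region = as.character(1:n),
                         community = rep(1, n))
  roles <- node_roles(g, part)
  expect_gt(roles$z[1], 2.5)
  expect_equal(roles$role[1], "provincial hub")   # P = 0 inside one community
  expect_true(all(roles$role[-1] == "peripheral"))
  # degree-zero flag
  g2 <- graph_from_edges(3, c(1, 2))
  igraph::V(g2)$name <- as.character(1:3)
  r2 <- node_roles(g2, tibble::tibble(region = as.character(1:3),
                                      community = c(1, 1, 2)))
  expect_true(r2$degree_zero[3])
  expect_equal(r2$participation[3], 0)
})

test_that("small-worldness is ~1 against its own null and >1 for a lattice", {
  set.seed(6)
  g <- igraph::sample_gnm(100, 600)
  sw <- small_worldness(g, n_rand = 200, seed = 2)
  expect_equal(sw$sigma, 1, tolerance = 0.15)

  lattice <- igraph::make_lattice(20, nei = 2, periodic = TRUE)
  # ring lattice with 4 neighbours: local clustering exactly 0.5
  expect_equal(fishmap:::mean_local_clustering(lattice), 0.5)
  swl <- small_worldness(lattice, n_rand = 200, seed = 3)
  expect_gt(swl$sigma, 1)
})

test_that("ER ensemble clustering converges to the edge probability", {
  ns <- er_null_stats(60, 150, n_rand = 300, seed = 4)
  p_edge <- 150 / choose(60, 2)
  expect_lt(abs(ns$C_rand - p_edge), 3 * ns$C_se + 0.002)
  # "zero" convention shrinks the mean by the isolate fraction
  ns0 <- er_null_stats(60, 150, n_rand = 100, seed = 4,
                       clustering_isolates = "zero")
  expect_lt(ns0$C_rand, ns$C_rand)
})

test_that("sigma equals the ratio-of-ratios of its printed components", {
  expect_equal((0.42 / 0.025) / (5.3 / 3.9), 12.36, tolerance = 1e-3)
})
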