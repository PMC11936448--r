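#' Cross-animal regional correlation matrix
#'
#' Pearson correlations between regional c-fos counts across the animals
#' of one group (classically the 15-min post-behaviour group, where
#' induction peaks). Entries are computed over pairwise-complete
#' observations so that masked regions (failed registrations) shrink only
#' the affected pairs. Pairs with fewer than `min_n` complete animals, and
#' all pairs of a zero-variance region, are undefined (`NA`) and are never
#' eligible for network edges.
#'
#' @param table Regional count table.
#' @param group Group label whose animals enter the correlation (default
#'   `"15min"`).
#' @param value Value column (default `"count"`).
#' @param min_n Minimum pairwise-complete n for a defined entry (default 3).
#' @return A `corr_matrix` object: list with `r` (region x region matrix,
#'   unit diagonal), `n` (pairwise-complete counts) and `regions` (tibble of
#'   `region_id`, `region_abbrev`).
#' @export
correlation_matrix <- function(table, group = "15min", value = "count",
                               min_n = 3) {
  table <- as_tibble(table)
  sub <- table[table$group == group, ]
  if (nrow(sub) == 0) abort("group not found in table", class = "fishmap_error_validation")
  wide <- sub |>
    dplyr::select(dplyr::all_of(c("subject_id", "region_id", value))) |>
    tidyr::pivot_wider(names_from = "region_id", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  region_ids <- as.integer(colnames(m))

  r <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(m))
  low_n <- nmat < min_n
  if (any(low_n[upper.tri(low_n)] & !is.na(r[upper.tri(r)]))) {
    warn("some region pairs have fewer complete animals than min_n; set to NA")
  }
  r[low_n] <- NA
  diag(r) <- 1

  abbrevs <- sub$region_abbrev[match(region_ids, sub$region_id)]
  regions <- tibble(region_id = region_ids,
                    region_abbrev = abbrevs %||% sprintf("R%03d", region_ids))
  dimnames(r) <- dimnames(nmat) <- list(regions$region_abbrev, regions$region_abbrev)
  structure(list(r = r, n = nmat, regions = regions, group = group),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix> %d regions, group '%s', %d defined pairs\n",
              nrow(x$r), x$group,
              sum(!is.na(x$r[upper.tri(x$r)]))))
  invisible(x)
}

#' Threshold a correlation matrix at a target density
#'
#' Builds the functional network by treating the correlation matrix as an
#' adjacency matrix and retaining the top `round(density * n*(n-1)/2)`
#' region pairs ranked by absolute correlation. Signed correlations are
#' kept as edge weights for reporting; all topology metrics operate on the
#' unsigned binarized view. Ties in |r| are broken by ascending region-id
#' pair, so the graph is deterministic. Undefined entries are never
#' selected.
#'
#' @param corr A `corr_matrix` (or plain symmetric matrix).
#' @param density Target edge density in (0, 1].
#' @return A `brain_graph`: list with `graph` (igraph, vertex name =
#'   region abbreviation, edge attribute `weight` = signed r), `density`
#'   (realised), `target_density`, `n_edges`, `regions`.
#' @export
threshold_at_density <- function(corr, density) {
  if (!is.numeric(density) || length(density) != 1 || density <= 0 || density > 1) {
    abort("density must be in (0, 1]", class = "fishmap_error_validation")
  }
  r <- if (inherits(corr, "corr_matrix")) corr$r else as.matrix(corr)
  regions <- if (inherits(corr, "corr_matrix")) corr$regions else
    tibble(region_id = seq_len(nrow(r)),
           region_abbrev = colnames(r) %||% sprintf("R%03d", seq_len(nrow(r))))
  n <- nrow(r)
  if (n < 2) abort("need at least two regions", class = "fishmap_error_validation")

  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[upper.tri(r)]
  ok <- !is.na(vals)
  ut <- ut[ok, , drop = FALSE]; vals <- vals[ok]
  n_pairs <- n * (n - 1) / 2
  budget <- min(round(density * n_pairs), length(vals))
  ord <- order(-abs(vals), ut[, 1], ut[, 2])
  pick <- ord[seq_len(budget)]

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::V(g)$name <- regions$region_abbrev
  igraph::V(g)$region_id <- regions$region_id
  if (budget > 0) {
    g <- igraph::add_edges(g, t(ut[pick, , drop = FALSE]))
    igraph::E(g)$weight <- vals[pick]
    igraph::E(g)$sign <- ifelse(vals[pick] >= 0, "positive", "negative")
  }
  structure(list(graph = g, density = budget / n_pairs,
                 target_density = density, n_edges = budget,
                 regions = regions),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d regions, %d edges (density %.4f, mean degree %.2f)\n",
              igraph::vcount(x$graph), x$n_edges, x$density,
              2 * x$n_edges / igraph::vcount(x$graph)))
  invisible(x)
}

#' @rdname threshold_at_density
#' @param x A `brain_graph`.
#' @param ... Unused.
#' @exportS3Method
glance.brain_graph <- function(x, ...) {
  g <- as_binary_igraph(x)
  tibble(n_nodes = igraph::vcount(g), n_edges = x$n_edges,
         density = x$density,
         mean_degree = 2 * x$n_edges / igraph::vcount(g),
         E_g = global_efficiency(x), E_l = local_efficiency(x),
         J = (global_efficiency(x) + local_efficiency(x)) / x$density)
}

#' Edge list of a brain graph
#'
#' @param x A `brain_graph`.
#' @param ... Unused.
#' @return Tibble `from`, `to` (region abbreviations), `weight` (signed r),
#'   `sign`.
#' @exportS3Method
tidy.brain_graph <- function(x, ...) {
  if (x$n_edges == 0) {
    return(tibble(from = character(), to = character(),
                  weight = numeric(), sign = character()))
  }
  el <- igraph::as_edgelist(x$graph)
  tibble(from = el[, 1], to = el[, 2],
         weight = igraph::E(x$graph)$weight,
         sign = igraph::E(x$graph)$sign)
}

as_binary_igraph <- function(g) {
  if (inherits(g, "brain_graph")) g$graph
  else if (igraph::is_igraph(g)) g
  else abort("expected a brain_graph or igraph object", class = "fishmap_error_validation")
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length on the
#' unweighted (binarized) graph; unreachable pairs contribute 0. Equals 1
#' for a complete graph.
#'
#' @param graph A `brain_graph` or igraph object.
#' @return Efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(graph) {
  g <- as_binary_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2) abort("need at least two nodes", class = "fishmap_error_validation")
  d <- igraph::distances(g, weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on
#' each node's neighbours; nodes with fewer than two neighbours contribute
#' 0. Captures fault-tolerant local (clustered) connectivity.
#'
#' @inheritParams global_efficiency
#' @return Efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(graph) {
  g <- as_binary_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 1) abort("need at least one node", class = "fishmap_error_validation")
  eff <- vapply(seq_len(n), function(v) {
    nb <- igraph::neighbors(g, v)
    if (length(nb) < 2) return(0)
    global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  mean(eff)
}

#' Select network density by efficiency-cost optimization
#'
#' Scans a grid of candidate densities; at each, thresholds the
#' correlation matrix, binarizes on |r|, and evaluates the quality
#' function `J = (E_g + E_l) / rho` -- combined global and local
#' efficiency per unit connection cost. Returns the full curve and the
#' argmax (ties resolved toward the sparser network). Functional brain
#' networks selected this way typically land at mean degree 2-5.
#'
#' @param corr A `corr_matrix` or symmetric matrix.
#' @param densities Numeric grid of densities in (0, 1]. The default scans
#'   steps of 0.005 up to 0.30, starting at the density giving mean degree
#'   1 (`2 / (n - 1)`): below that the thresholded graph is fragmentary
#'   and efficiency-per-cost degenerates toward whichever few edges first
#'   close a triangle.
#' @return An `eco_curve`: list with `curve` (tibble `density`,
#'   `n_edges`, `E_g`, `E_l`, `J`), `best_density`, `best_graph`.
#' @export
eco_select_density <- function(corr, densities = NULL) {
  if (is.null(densities)) {
    n <- if (inherits(corr, "corr_matrix")) nrow(corr$r) else nrow(corr)
    lo <- 0.005 * ceiling(2 / (n - 1) / 0.005)
    densities <- seq(min(lo, 0.30), 0.30, by = 0.005)
  }
  if (length(densities) == 0) abort("empty density grid", class = "fishmap_error_validation")
  if (any(densities <= 0 | densities > 1)) {
    abort("densities must lie in (0, 1]", class = "fishmap_error_validation")
  }
  densities <- sort(unique(densities))
  rows <- purrr::map_dfr(densities, function(rho) {
    bg <- threshold_at_density(corr, rho)
    eg <- global_efficiency(bg)
    el <- local_efficiency(bg)
    tibble(density = rho, n_edges = bg$n_edges, E_g = eg, E_l = el,
           J = (eg + el) / rho)
  })
  best <- which.max(rows$J)   # which.max takes the first (sparsest) maximum
  structure(list(curve = rows, best_density = rows$density[best],
                 best_graph = threshold_at_density(corr, rows$density[best])),
            class = "eco_curve")
}

#' @export
print.eco_curve <- function(x, ...) {
  cat(sprintf("<eco_curve> %d densities scanned; J* = %.3f at density %.4f (%d edges)\n",
              nrow(x$curve), max(x$curve$J), x$best_density,
              x$best_graph$n_edges))
  invisible(x)
}

#' @rdname eco_select_density
#' @param x An `eco_curve`.
#' @param ... Unused.
#' @exportS3Method
tidy.eco_curve <- function(x, ...) x$curve

#' Giant component of a network
#'
#' Largest connected component of the binarized graph. Size ties are
#' broken toward the component containing the smallest vertex index.
#'
#' @inheritParams global_efficiency
#' @return An igraph subgraph.
#' @export
giant_component <- function(graph) {
  g <- as_binary_igraph(graph)
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_vertex <- vapply(best, function(k) min(which(comp$membership == k)),
                           integer(1))
    best <- best[which.min(first_vertex)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Degree and eigenvector centrality
#'
#' Degree on the binarized graph; eigenvector centrality as the principal
#' eigenvector of the binary adjacency, scaled so the maximum is 1. On a
#' disconnected graph the eigenvector step runs on the giant component
#' (other nodes get 0) with a warning.
#'
#' @inheritParams global_efficiency
#' @return Tibble `region`, `degree`, `eigenvector`, sorted by input
#'   vertex order.
#' @export
centralities <- function(graph) {
  g <- as_binary_igraph(graph)
  deg <- igraph::degree(g)
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  ev <- rep(0, igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warn("graph disconnected: eigenvector centrality computed on the giant component")
    gc <- giant_component(g)
    sub_ev <- igraph::eigen_centrality(gc, weights = NA)$vector
    sub_ev <- sub_ev / max(sub_ev)
    ev[match(igraph::V(gc)$name, nm)] <- sub_ev
  } else {
    ev <- igraph::eigen_centrality(g, weights = NA)$vector
    ev <- ev / max(ev)
  }
  tibble(region = nm, degree = as.numeric(deg), eigenvector = as.numeric(ev))
}

#' Louvain community detection with restarts
#'
#' Louvain modularity optimisation on the binarized giant component, run
#' `restarts` times under distinct seeds; the partition with the highest
#' modularity is kept. Community counts from Louvain are restart-dependent
#' on real data, which is why the best-of-restarts partition (not a
#' specific community count) is the reproducible object.
#'
#' @inheritParams global_efficiency
#' @param seed Base RNG seed.
#' @param restarts Number of seeded runs (default 20).
#' @param giant_only Partition only the giant component (default), as
#'   node-role analyses do; `FALSE` partitions the whole graph, which a
#'   planted-structure evaluation needs when the thresholded graph splits
#'   into one component per community.
#' @return A `community_partition`: list with `membership` (tibble
#'   `region`, `community`; ids contiguous from 1), `modularity`, `seed`,
#'   `restarts`.
#' @export
louvain_partition <- function(graph, seed = 1L, restarts = 20L,
                              giant_only = TRUE) {
  g0 <- as_binary_igraph(graph)
  if (igraph::ecount(g0) < 1) abort("graph has no edges", class = "fishmap_error_validation")
  g <- if (giant_only) giant_component(g0) else g0
  best <- NULL
  for (i in seq_len(restarts)) {
    cl <- with_preserved_seed(seed + i - 1L,
                              igraph::cluster_louvain(g, weights = NA))
    if (is.null(best) || igraph::modularity(cl) > igraph::modularity(best)) {
      best <- cl
    }
  }
  memb <- igraph::membership(best)
  memb <- as.integer(factor(memb, levels = unique(sort(memb))))
  structure(list(
    membership = tibble(region = igraph::V(g)$name %||%
                          as.character(seq_len(igraph::vcount(g))),
                        community = memb),
    modularity = igraph::modularity(best),
    n_communities = max(memb),
    seed = seed, restarts = restarts),
    class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, modularity %.3f (%d restarts)\n",
              x$n_communities, x$modularity, x$restarts))
  invisible(x)
}

#' @rdname louvain_partition
#' @param x A `community_partition`.
#' @param ... Unused.
#' @exportS3Method
tidy.community_partition <- function(x, ...) x$membership

#' Node roles from within-module degree and participation
#'
#' For each node of the partitioned (giant-component) graph, computes the
#' within-module degree z-score
#' `z_i = (kappa_i - mean(kappa_s)) / sd(kappa_s)` (population SD over the
#' node's community; communities with zero SD give z = 0) and the
#' participation coefficient `P_i = 1 - sum_s (K_is / K_i)^2`
#' (0 for a node whose edges all stay in its own community; degree-0 nodes
#' get P = 0 with a flag). Roles follow the hub/connector taxonomy:
#' nodes with `z >= z_hub` are hubs, split into connector hubs
#' (`P >= p_hub_connector`) and provincial hubs; non-hubs are nonhub
#' connectors (`P >= p_nonhub_connector`) or peripheral.
#'
#' @inheritParams global_efficiency
#' @param partition A `community_partition` (or tibble `region`,
#'   `community` covering the graph's vertices).
#' @param z_hub Hub threshold on z (default 2.5).
#' @param p_hub_connector Connector threshold on P among hubs (default 0.30).
#' @param p_nonhub_connector Connector threshold on P among non-hubs
#'   (default 0.62).
#' @return Tibble `region`, `community`, `degree`, `within_degree`, `z`,
#'   `participation`, `role`, `degree_zero`.
#' @export
node_roles <- function(graph, partition, z_hub = 2.5,
                       p_hub_connector = 0.30, p_nonhub_connector = 0.62) {
  g <- as_binary_igraph(graph)
  memb_tbl <- if (inherits(partition, "community_partition"))
    partition$membership else as_tibble(partition)
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!all(nm %in% memb_tbl$region)) {
    # restrict to the partitioned subgraph (typically the giant component)
    g <- igraph::induced_subgraph(g, which(nm %in% memb_tbl$region))
    nm <- igraph::V(g)$name
  }
  comm <- memb_tbl$community[match(nm, memb_tbl$region)]
  n <- igraph::vcount(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- rowSums(adj)

  # K_is: edges from node i into community s
  ncomm <- max(comm)
  Kis <- sapply(seq_len(ncomm), function(s) rowSums(adj[, comm == s, drop = FALSE]))
  Kis <- matrix(Kis, nrow = n)
  kappa <- Kis[cbind(seq_len(n), comm)]

  z <- numeric(n)
  for (s in seq_len(ncomm)) {
    idx <- comm == s
    ks <- kappa[idx]
    mu <- mean(ks)
    sig <- sqrt(mean((ks - mu)^2))  # population SD
    z[idx] <- if (sig > 0) (ks - mu) / sig else 0
  }
  P <- unname(ifelse(deg > 0, 1 - rowSums((Kis / pmax(deg, 1))^2), 0))

  role <- ifelse(z >= z_hub,
                 ifelse(P >= p_hub_connector, "connector hub", "provincial hub"),
                 ifelse(P >= p_nonhub_connector, "nonhub connector", "peripheral"))
  tibble(region = nm, community = comm, degree = as.numeric(deg),
         within_degree = as.numeric(kappa), z = z, participation = P,
         role = role, degree_zero = deg == 0)
}

#' Erdos-Renyi null ensemble statistics
#'
#' Draws `n_rand` G(n, M) graphs and returns the ensemble means of the
#' clustering coefficient (mean local clustering) and the mean shortest
#' path over reachable ordered pairs of each draw's giant component --
#' the reference values for small-worldness.
#'
#' Nodes of degree < 2 have no defined local clustering; by default they
#' are excluded from each graph's average (`clustering_isolates =
#' "exclude"`), which makes the ensemble mean of a sparse G(n, M) ensemble
#' converge to the edge probability M / (n(n-1)/2). Setting `"zero"`
#' counts them as 0 instead, shrinking the mean by the isolate fraction.
#'
#' @param n_nodes,n_edges Size of each random graph.
#' @param n_rand Number of draws (default 1000).
#' @param seed RNG seed.
#' @param clustering_isolates `"exclude"` (default) or `"zero"`: how
#'   degree-<2 nodes enter the mean local clustering.
#' @return Tibble with `C_rand`, `L_rand`, `n_rand`, and Monte-Carlo
#'   standard errors `C_se`, `L_se`.
#' @export
er_null_stats <- function(n_nodes, n_edges, n_rand = 1000, seed = 1L,
                          clustering_isolates = c("exclude", "zero")) {
  clustering_isolates <- match.arg(clustering_isolates)
  set.seed(seed)
  cs <- numeric(n_rand); ls <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    cs[i] <- mean_local_clustering(g, clustering_isolates)
    ls[i] <- mean_giant_path_length(g)
  }
  tibble(C_rand = mean(cs), L_rand = mean(ls), n_rand = n_rand,
         C_se = sd(cs) / sqrt(n_rand), L_se = sd(ls) / sqrt(n_rand))
}

mean_local_clustering <- function(g, isolates = "exclude") {
  ct <- igraph::transitivity(g, type = "local",
                             isolates = if (isolates == "zero") "zero" else "NaN")
  mean(ct, na.rm = isolates != "zero")
}

mean_giant_path_length <- function(g) {
  gc <- giant_component(g)
  if (igraph::vcount(gc) < 2) return(NaN)
  d <- igraph::distances(gc, weights = NA)
  mean(d[row(d) != col(d)])
}

#' Small-worldness against an Erdos-Renyi ensemble
#'
#' Computes `sigma = (C_g / C_rand) / (L_g / L_rand)`, where `C_g` is the
#' network's mean local clustering coefficient, `L_g` its mean shortest
#' path over the giant component, and the `_rand` terms are means over
#' `n_rand` Erdos-Renyi G(n, M) graphs with the same node and edge counts.
#' `sigma` well above 1 marks the small-world regime: lattice-like
#' clustering with random-like path lengths.
#'
#' The same clustering convention (see [er_null_stats()]) is applied to
#' the real network and every null draw.
#'
#' @inheritParams global_efficiency
#' @inheritParams er_null_stats
#' @param n_rand Number of null draws (default 1000).
#' @param seed RNG seed for the ensemble.
#' @return A `small_world` object (also a one-row tibble): `sigma`, `C_g`,
#'   `L_g`, `C_rand`, `L_rand`, `n_rand`.
#' @export
small_worldness <- function(graph, n_rand = 1000, seed = 1L,
                            clustering_isolates = c("exclude", "zero")) {
  clustering_isolates <- match.arg(clustering_isolates)
  g <- as_binary_igraph(graph)
  if (igraph::ecount(g) < 1) abort("graph has no edges", class = "fishmap_error_validation")
  C_g <- mean_local_clustering(g, clustering_isolates)
  L_g <- mean_giant_path_length(g)
  nulls <- er_null_stats(igraph::vcount(g), igraph::ecount(g),
                         n_rand = n_rand, seed = seed,
                         clustering_isolates = clustering_isolates)
  if (!is.finite(nulls$C_rand) || nulls$C_rand <= 0 || !is.finite(nulls$L_rand)) {
    abort("null ensemble clustering or path length undefined",
          class = "fishmap_error_validation")
  }
  out <- tibble(sigma = (C_g / nulls$C_rand) / (L_g / nulls$L_rand),
                C_g = C_g, L_g = L_g, C_rand = nulls$C_rand,
                L_rand = nulls$L_rand, n_rand = n_rand)
  class(out) <- c("small_world", class(out))
  out
}
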