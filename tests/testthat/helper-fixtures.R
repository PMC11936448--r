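# shared fixtures and small independent oracles, computed lazily and cached
# for the whole test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  ct <- table(a, b)
  n <- sum(ct)
  si <- sum(choose(rowSums(ct), 2))
  sj <- sum(choose(colSums(ct), 2))
  sij <- sum(choose(ct, 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force greedy dedup oracle: O(n^2), same first-come-first-kept order
dedup_oracle <- function(candidates, geometry, min_dist_um) {
  g <- as.numeric(geometry)
  pos <- cbind(candidates$z * g[1], candidates$y * g[2], candidates$x * g[3])
  keep <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < min_dist_um) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  which(keep)
}

# Floyd-Warshall shortest paths on an adjacency matrix (independent of igraph)
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

global_efficiency_oracle <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

local_efficiency_oracle <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    global_efficiency_oracle(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

# 4-region toy correlation matrix: strong triangle + weak spokes
toy_corr_4 <- function() {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- 0.8
  r[1, 3] <- r[3, 1] <- 0.7
  r[1, 4] <- r[4, 1] <- 0.10
  r[2, 4] <- r[4, 2] <- 0.05
  r[3, 4] <- r[4, 3] <- 0.02
  dimnames(r) <- list(letters[1:4], letters[1:4])
  r
}

# planted-structure table used by recovery checks: 40 regions, 4 planted
# communities, region 1 a cross-community hub; one 30-animal group
recovery_spec <- function(seed = 1L) {
  count_table_spec(
    n_regions = 40, n_communities = 4,
    hub_regions = 1L, hub_loading = 1.0,
    groups = tibble::tibble(label = "15min", n_female = 15L, n_male = 15L),
    fold_change = c("15min" = 1),
    latent_loading = 0.8, dispersion = 0.4, seed = seed
  )
}

recovery_table <- function() cached("recovery_table",
                                    simulate_count_table(recovery_spec()))

# synthetic separable volume -> labeled cubes, split, trained classifier
stain_cubes <- function() cached("stain_cubes", {
  vol <- simulate_volume(volume_spec(shape = c(60, 80, 80), n_cells = 120,
                                     fraction_punctate = 0.5, seed = 3))
  extract_cubes(vol$intensity, vol$cells)
})

stain_split <- function() cached("stain_split",
                                 split_cubes(stain_cubes(), 0.8, seed = 1))

trained_classifier <- function() cached("trained_classifier", {
  train_stain_classifier(augment_cubes(stain_split()$train),
                         stain_train_config(epochs = 20, seed = 1))
})
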