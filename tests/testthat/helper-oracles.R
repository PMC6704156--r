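# Independent brute-force oracles. Everything here works on plain vectors and
# adjacency matrices, deliberately avoiding the code paths (stats::cor with
# method = "spearman", igraph, hclust) that the package itself uses.

# Spearman as mid-ranks followed by an explicitly coded Pearson sum formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

oracle_spearman_matrix <- function(mat) {
  p <- nrow(mat)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) out[i, j] <- out[j, i] <- oracle_spearman(mat[i, ], mat[j, ])
  }
  dimnames(out) <- list(rownames(mat), rownames(mat))
  out
}

# BFS distances from source `s` on a logical adjacency matrix.
oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      nb <- which(adj[u, ] & is.infinite(d))
      d[nb] <- d[u] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

# Count shortest paths between all pairs by DP over BFS layers.
oracle_path_counts <- function(adj) {
  n <- nrow(adj)
  d <- t(vapply(seq_len(n), function(s) oracle_bfs_dist(adj, s), numeric(n)))
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (v in which(d[s, ] == dist)) {
        preds <- which(adj[v, ] & d[s, ] == dist - 1)
        sigma[s, v] <- sum(sigma[s, preds])
      }
    }
  }
  list(d = d, sigma = sigma)
}

# Unnormalized node betweenness over unordered pairs, endpoints excluded.
oracle_node_betweenness <- function(adj) {
  n <- nrow(adj)
  pc <- oracle_path_counts(adj)
  bt <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(pc$d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(pc$d[s, v]) && is.finite(pc$d[v, t]) &&
          pc$d[s, v] + pc$d[v, t] == pc$d[s, t]) {
        bt[v] <- bt[v] + pc$sigma[s, v] * pc$sigma[v, t] / pc$sigma[s, t]
      }
    }
  }
  bt
}

# Edge betweenness over unordered pairs for edge (u, v).
oracle_edge_betweenness <- function(adj, u, v) {
  n <- nrow(adj)
  pc <- oracle_path_counts(adj)
  total <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(pc$d[s, t])) next
    cnt <- 0
    if (is.finite(pc$d[s, u]) && is.finite(pc$d[v, t]) &&
        pc$d[s, u] + 1 + pc$d[v, t] == pc$d[s, t]) {
      cnt <- cnt + pc$sigma[s, u] * pc$sigma[v, t]
    }
    if (is.finite(pc$d[s, v]) && is.finite(pc$d[u, t]) &&
        pc$d[s, v] + 1 + pc$d[u, t] == pc$d[s, t]) {
      cnt <- cnt + pc$sigma[s, v] * pc$sigma[u, t]
    }
    total <- total + cnt / pc$sigma[s, t]
  }
  total
}

oracle_connected <- function(adj, nodes = seq_len(nrow(adj))) {
  if (length(nodes) == 0) return(FALSE)
  d <- oracle_bfs_dist(adj, nodes[1])
  all(is.finite(d[nodes]))
}

# Exhaustive grid scan for the highest non-fragmenting threshold.
oracle_threshold_scan <- function(rho, grid_step = 0.01, policy = "nonisolated") {
  grid <- round(seq(grid_step, 1, by = grid_step), 10)
  best <- NA_real_
  for (t in grid) {
    adj <- abs(rho) >= t
    diag(adj) <- FALSE
    deg <- rowSums(adj)
    ok <- if (policy == "strict") {
      all(deg > 0) && oracle_connected(adj)
    } else {
      any(deg > 0) && oracle_connected(adj, which(deg > 0))
    }
    if (ok) best <- t
  }
  best
}

# Ward agglomeration by the Lance-Williams update on squared dissimilarities
# (the ward.D2 criterion: heights are square roots of the merge cost).
# Returns cluster memberships after each merge and the merge heights.
oracle_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- d^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii < jj) {
        i <- active[ii]; j <- active[jj]
        if (s[i, j] < best_val) { best_val <- s[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_val))
    new <- max(c(active, length(members))) + 1
    members[[new]] <- c(members[[i]], members[[j]])
    sizes[new] <- sizes[i] + sizes[j]
    s <- rbind(cbind(s, 0), 0)
    for (k in active) {
      if (k == i || k == j) next
      s[new, k] <- s[k, new] <-
        ((sizes[i] + sizes[k]) * s[i, k] + (sizes[j] + sizes[k]) * s[j, k] -
           sizes[k] * s[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    active <- c(setdiff(active, c(i, j)), new)
    partitions[[length(partitions) + 1]] <-
      lapply(active, function(a) sort(members[[a]]))
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a partition for comparison.
partition_key <- function(parts) {
  paste(sort(vapply(parts, function(p) paste(sort(p), collapse = ","),
                    character(1))), collapse = " | ")
}

# Partition sequence implied by an hclust tree (memberships after each merge).
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  lapply(seq_len(n - 1), function(k) {
    grp <- stats::cutree(hc, k = n - k)
    unname(lapply(split(seq_len(n), grp), sort))
  })
}
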