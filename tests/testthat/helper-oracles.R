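# Independent oracles used across the suite.  These deliberately use naive,
# exhaustive algorithms so they stay independent of the package's code paths.

# --- graphs ----------------------------------------------------------------

# all shortest paths between s and t by explicit enumeration on the BFS DAG
enum_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] == 1)
      new <- nb[dist[nb] == Inf]
      dist[new] <- dist[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  if (!is.finite(dist[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- which(adj[v, ] == 1 & dist == dist[v] - 1)
    out <- list()
    for (u in preds) {
      for (p in walk(u)) out[[length(out) + 1L]] <- c(p, v)
    }
    out
  }
  walk(t)
}

# betweenness by exhaustive path enumeration over unordered pairs
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  g <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enum_shortest_paths(adj, s, t)
      sigma <- length(paths)
      if (sigma == 0) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        cnt <- sum(vapply(paths, function(p) i %in% p, logical(1)))
        g[i] <- g[i] + cnt / sigma
      }
    }
  }
  g
}

graph_is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

random_connected_graph <- function(n, p = 0.3) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- which(upper.tri(adj))
    adj[up] <- as.integer(runif(length(up)) < p)
    adj <- adj + t(adj)
    if (graph_is_connected(adj)) return(adj)
  }
}

random_tree <- function(n) {
  adj <- matrix(0L, n, n)
  for (v in 2:n) {
    u <- sample.int(v - 1L, 1L)
    adj[u, v] <- adj[v, u] <- 1L
  }
  adj
}

# wrap an adjacency matrix into the package's network representation:
# mdcc 0.9 / distance 4 where an edge exists, else mdcc 0 / distance 10
network_from_adjacency <- function(adj, molecule = NULL) {
  n <- nrow(adj)
  md <- ifelse(adj == 1, 0.9, 0)
  dd <- ifelse(adj == 1, 4, 10)
  diag(md) <- 1
  build_network(as_mdcc_matrix(md, md, dd, molecule = molecule))
}

# sigma_st path counts for the monotonicity check
brute_sigma <- function(adj, s, t) length(enum_shortest_paths(adj, s, t))

# --- correlations ----------------------------------------------------------

# mDCC with known (planted) mode memberships and centers: hard indicator
# weights from the true switch schedule
oracle_mdcc_planted <- function(xi, xj, in_k, in_l, mu_k, mu_l) {
  w <- as.numeric(in_k & in_l)
  di <- sweep(xi, 2, mu_k)
  dj <- sweep(xj, 2, mu_l)
  num <- mean(w * rowSums(di * dj))
  d1 <- mean(w * rowSums(di * di))
  d2 <- mean(w * rowSums(dj * dj))
  num / sqrt(d1 * d2)
}

# naive DCC straight from the definition
oracle_dcc <- function(xi, xj) {
  di <- sweep(xi, 2, colMeans(xi))
  dj <- sweep(xj, 2, colMeans(xj))
  mean(rowSums(di * dj)) /
    sqrt(mean(rowSums(di * di)) * mean(rowSums(dj * dj)))
}

# exhaustive residue-matrix oracle: enumerate every atom pair and mode pair,
# apply the rare-pair floor, take the max (ties: mean weight, then distance)
oracle_residue_matrix <- function(traj, modes, sel, weight_floor = 0.1) {
  top <- traj$topology
  res_of <- top$atoms$residue[sel]
  nres <- max(top$atoms$residue)
  M <- matrix(NA_real_, nres, nres)
  best_mw <- matrix(-Inf, nres, nres)
  best_cd <- matrix(Inf, nres, nres)
  for (ii in seq_along(sel)) {
    for (jj in seq_along(sel)) {
      a <- res_of[ii]; b <- res_of[jj]
      if (a >= b) next
      xi <- atom_coords(traj, sel[ii])
      xj <- atom_coords(traj, sel[jj])
      Pi <- mode_posterior(modes[[ii]], xi)
      Pj <- mode_posterior(modes[[jj]], xj)
      for (k in seq_len(modes[[ii]]$K)) {
        for (l in seq_len(modes[[jj]]$K)) {
          w <- Pi[, k] * Pj[, l]
          if (mean(w) <= weight_floor) next
          di <- sweep(xi, 2, modes[[ii]]$centers[k, ])
          dj <- sweep(xj, 2, modes[[jj]]$centers[l, ])
          d1 <- mean(w * rowSums(di * di))
          d2 <- mean(w * rowSums(dj * dj))
          if (d1 < 1e-24 || d2 < 1e-24) next
          val <- mean(w * rowSums(di * dj)) / sqrt(d1 * d2)
          cd <- sqrt(sum((modes[[ii]]$centers[k, ] - modes[[jj]]$centers[l, ])^2))
          better <- is.na(M[a, b]) || val > M[a, b] ||
            (val == M[a, b] && (mean(w) > best_mw[a, b] ||
              (mean(w) == best_mw[a, b] && cd < best_cd[a, b])))
          if (better) {
            M[a, b] <- M[b, a] <- val
            best_mw[a, b] <- mean(w)
            best_cd[a, b] <- cd
          }
        }
      }
    }
  }
  M
}

# --- geometry --------------------------------------------------------------

random_proper_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# best selection RMSD achievable over proper rotations, by random search
brute_min_rmsd <- function(P, Q, n_try = 20000) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (i in seq_len(n_try)) {
    R <- random_proper_rotation()
    d <- Pc %*% t(R) - Qc
    best <- min(best, sqrt(mean(rowSums(d * d))))
  }
  best
}

# --- misc builders ---------------------------------------------------------

# tiny glycine-fragment PDB text (3 atoms, 1 residue)
toy_pdb_lines <- function() {
  c("ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "END")
}

# small trajectory with arbitrary coordinates, one CA atom per residue
make_toy_traj <- function(coord_list) {
  # coord_list: list of n x 3 matrices, one per atom
  nat <- length(coord_list)
  n <- nrow(coord_list[[1]])
  top <- mdccr:::synth_topology(c(A = nat))
  arr <- array(NA_real_, dim = c(n, nat, 3))
  for (a in seq_len(nat)) arr[, a, ] <- coord_list[[a]]
  trajectory(arr, top, box_warn_threshold = Inf)
}
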