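# RMSD, RMSF, Cartesian PCA, distances, density clustering.

test_that("rmsd_series matches hand-computed values", {
  sys <- generate_unimodal_system(4, 3, sigma = 1, seed = 1)
  tr <- sys$trajectory
  # identical to itself -> 0
  expect_equal(rmsd_series(tr, frame_coords(tr, 2), "all")[2], 0)
  # uniform (1,0,0) displacement, no fit -> exactly 1 A
  arr <- tr$coords
  arr[2, , 1] <- arr[1, , 1] + 1
  arr[2, , 2:3] <- arr[1, , 2:3]
  tr2 <- trajectory(arr, tr$topology, box_warn_threshold = Inf)
  expect_equal(rmsd_series(tr2, 1L, "all")[2], 1)
  # 4-atom direct arithmetic oracle
  ref <- frame_coords(tr, 1)
  x <- frame_coords(tr, 3)
  expect_equal(rmsd_series(tr, 1L, "all")[3],
               sqrt(mean(rowSums((x - ref)^2))))
  expect_error(rmsd_series(tr, 1L, "none"), class = "mdccr_selection_error")
})

test_that("rmsf reproduces closed forms", {
  # immobile atom -> 0; alternating +/-d -> d
  still <- matrix(5, 40, 3)
  alt <- cbind(rep(c(2, -2), 20), 0, 0)
  tr <- make_toy_traj(list(still, alt))
  v <- rmsf(tr, "all", fit = "none")
  expect_equal(unname(v[1]), 0)
  expect_equal(unname(v[2]), 2)
  # isotropic Gaussian, sigma = 1: E||dr||^2 = 3 sigma^2 -> rmsf = sqrt(3)
  sys <- generate_unimodal_system(3, 100000, sigma = 1, seed = 11)
  v <- rmsf(sys$trajectory, "all", fit = "none")
  expect_equal(unname(v), rep(sqrt(3), 3), tolerance = 0.01)
  expect_error(rmsf(make_toy_traj(list(matrix(0, 1, 3))), "all"),
               class = "mdccr_validation_error")
})

test_that("rmsf squared equals the trace of the per-atom covariance", {
  sys <- generate_two_state_pair(500, seed = 9)
  tr <- sys$trajectory
  v <- rmsf(tr, "all", fit = "none")
  for (a in 1:2) {
    X <- atom_coords(tr, a)
    n <- nrow(X)
    tr_cov <- sum(diag(cov(X))) * (n - 1) / n  # population covariance
    expect_equal(unname(v[a])^2, tr_cov, tolerance = 1e-10)
  }
})

test_that("per-molecule rmsf ignores relative motion of other molecules", {
  # two rigid 4-atom molecules; molecule B translates over time.
  set.seed(31)
  base <- matrix(rnorm(12, sd = 2), 4, 3)
  n <- 50
  top <- mdccr:::synth_topology(c(A = 4L, B = 4L))
  arr <- array(NA_real_, dim = c(n, 8, 3))
  for (f in seq_len(n)) {
    arr[f, 1:4, ] <- base
    arr[f, 5:8, ] <- sweep(base, 2, c(f * 0.5, 0, 0), "+")
  }
  tr <- trajectory(arr, top, box_warn_threshold = Inf)
  v <- rmsf(tr, "all", fit = "molecule", fit_selection = "heavy")
  expect_lt(max(v), 1e-8)  # internally rigid => no fluctuation per molecule
  vg <- rmsf(tr, "all", fit = "global", fit_selection = "heavy")
  expect_gt(max(vg), 1)    # global fit sees the drift
})

test_that("PCA recovers planted structure and conserves variance", {
  # single planted 3N direction + tiny noise -> PC1 rate >= 0.99
  set.seed(5)
  nat <- 4; n <- 2000
  dir <- rnorm(3 * nat); dir <- dir / sqrt(sum(dir^2))
  amp <- rnorm(n, sd = 3)
  X <- outer(amp, dir) + matrix(rnorm(n * 3 * nat, sd = 0.05), n)
  arr <- array(NA_real_, dim = c(n, nat, 3))
  for (a in seq_len(nat)) arr[, a, ] <- X[, (3 * a - 2):(3 * a)]
  tr <- trajectory(arr, mdccr:::synth_topology(c(A = nat)),
                   box_warn_threshold = Inf)
  p <- pca_cartesian(tr, "all")
  expect_gte(p$contribution_rates[1], 0.99)
  # rates sum to 1, all non-negative
  expect_equal(sum(p$contribution_rates), 1, tolerance = 1e-9)
  expect_true(all(p$contribution_rates >= 0))
  # components orthonormal
  G <- crossprod(p$components)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-9)
  # eigenvalue sum equals total population variance
  Xc <- scale(X, scale = FALSE)
  expect_equal(sum(p$eigenvalues), sum(Xc^2) / n, tolerance = 1e-9)
  # reconstruction from all components reproduces centered data
  rec <- p$projections %*% t(p$components)
  expect_lt(max(abs(rec - Xc)), 1e-8)
})

test_that("two equal-variance planted directions split 50/50", {
  set.seed(6)
  nat <- 3; n <- 50000
  d1 <- rnorm(3 * nat); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(3 * nat); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  X <- outer(rnorm(n, sd = 2), d1) + outer(rnorm(n, sd = 2), d2)
  arr <- array(NA_real_, dim = c(n, nat, 3))
  for (a in seq_len(nat)) arr[, a, ] <- X[, (3 * a - 2):(3 * a)]
  tr <- trajectory(arr, mdccr:::synth_topology(c(A = nat)),
                   box_warn_threshold = Inf)
  p <- suppressWarnings(pca_cartesian(tr, "all"))
  expect_equal(p$contribution_rates[1], 0.5, tolerance = 0.02)
  expect_equal(p$contribution_rates[2], 0.5, tolerance = 0.02)
})

test_that("distance series is exact and rigid-transform invariant", {
  a1 <- matrix(0, 10, 3)
  a2 <- matrix(rep(c(3, 4, 0), each = 10), 10, 3)
  tr <- make_toy_traj(list(a1, a2))
  expect_equal(distance_series(tr, 1, 2), rep(5, 10))
  expect_equal(distance_series(tr, 1, 1), rep(0, 10))
  expect_error(distance_series(tr, 1, 99), class = "mdccr_lookup_error")
  sys <- generate_unimodal_system(4, 100, sigma = 0.5, seed = 8, tumble = TRUE)
  d0 <- distance_series(sys$trajectory, 1, 2)
  d1 <- distance_series(superpose(sys$trajectory, 1L, "all"), 1, 2)
  expect_lt(max(abs(d0 - d1)), 1e-8)
})

test_that("density clustering resolves separated blobs and merges close ones", {
  set.seed(21)
  n <- 1000
  blob <- function(cx, cy, s) cbind(rnorm(n, cx, s), rnorm(n, cy, s))
  # three well-separated tight blobs
  P <- rbind(blob(0, 0, 0.1), blob(5, 0, 0.1), blob(0, 5, 0.1))
  planted <- rep(1:3, each = n)
  cl <- density_cluster_2d(P)
  expect_equal(cl$n_clusters, 3L)
  # majority-map labels onto planted ones, then score
  correct <- 0
  for (k in 1:3) {
    lab <- cl$labels[planted == k]
    correct <- correct + max(table(lab))
  }
  expect_gte(correct / length(planted), 0.99)
  # single blob
  expect_equal(density_cluster_2d(blob(0, 0, 1))$n_clusters, 1L)
  # two blobs too close to resolve at default bandwidth
  P2 <- rbind(blob(0, 0, 1), blob(0.1, 0, 1))
  expect_equal(density_cluster_2d(P2)$n_clusters, 1L)
  # degenerate: identical points -> one cluster
  expect_equal(density_cluster_2d(matrix(1, 5, 2))$n_clusters, 1L)
})
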