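# DCC, mode-pair mDCC, and the residue-level summary matrix.

test_that("dcc reproduces closed-form cases", {
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3)
  tr <- make_toy_traj(list(x, -x, x + 5))
  expect_equal(dcc(tr, 1, 1), 1)
  # point reflection through a fixed origin: dr_j = -dr_i -> -1
  expect_equal(dcc(tr, 1, 2), -1)
  expect_equal(dcc(tr, 1, 3), 1)   # rigid shift preserves deviations
  expect_equal(dcc(tr, 1, 2), dcc(tr, 2, 1))
})

test_that("orthogonal deviation patterns give dcc of exactly zero", {
  a <- cbind(c(1, -1, 1, -1), 0, 0)
  b <- cbind(c(1, 1, -1, -1), 0, 0)
  tr <- make_toy_traj(list(a, b))
  # per-frame dot products (1,-1,-1,1) average to 0
  expect_equal(dcc(tr, 1, 2), 0)
})

test_that("zero-variance atoms make dcc an explicit error, not a zero", {
  tr <- make_toy_traj(list(matrix(0, 10, 3),
                           matrix(rnorm(30), 10, 3)))
  expect_error(dcc(tr, 1, 2), class = "mdccr_undefined_correlation_error")
})

test_that("uni-modal mdcc collapses to dcc", {
  sys <- generate_unimodal_system(4, 500, sigma = 1, seed = 3)
  tr <- sys$trajectory
  modes <- lapply(1:4, function(a) fit_modes(tr, a, max_modes = 1, seed = a))
  for (i in 1:3) {
    mp <- mdcc_mode_pair(tr, i, i + 1, modes[[i]], modes[[i + 1]], 1, 1)
    expect_equal(mp$value, dcc(tr, i, i + 1), tolerance = 1e-9)
    expect_equal(mp$mean_weight, 1)
  }
})

test_that("fitted-mode mdcc matches the planted-assignment oracle", {
  sys <- generate_two_state_pair(20000, occupancy = 0.5, rho = 0.9,
                                 jitter_sigma = 1, seed = 17)
  tr <- sys$trajectory
  truth <- sys$truth
  # oracle with the true switch schedule and planted centers, matched state 1
  o <- oracle_mdcc_planted(atom_coords(tr, 1), atom_coords(tr, 2),
                           truth$states == 1L, truth$states == 1L,
                           truth$modes[[1]]$centers[1, ],
                           truth$modes[[2]]$centers[1, ])
  expect_equal(o, 0.9, tolerance = 0.05)
  mi <- fit_modes(tr, 1, seed = 21)
  mj <- fit_modes(tr, 2, seed = 22)
  best <- -Inf
  for (k in seq_len(mi$K)) for (l in seq_len(mj$K)) {
    mp <- mdcc_mode_pair(tr, 1, 2, mi, mj, k, l)
    if (!is.na(mp$value) && mp$mean_weight > 0.1) best <- max(best, mp$value)
  }
  expect_equal(best, o, tolerance = 0.05)
})

test_that("a never-jointly-occupied mode pair is reported undefined", {
  two <- function(c1, c2) structure(
    list(atom = "x", K = 2L, weights = c(0.5, 0.5),
         centers = rbind(c1, c2),
         covariances = list(diag(0.01, 3), diag(0.01, 3)),
         loglik = NA_real_, bic = NA_real_, seed = 1L, n_frames = 0L,
         trace = numeric(0)), class = "atom_modes")
  # both atoms flip together between basins; modes (1 of i, 2 of j) never co-occur
  s <- rep(c(1, 2), each = 50)
  xi <- rbind(matrix(0, 50, 3), matrix(10, 50, 3)) +
    matrix(rnorm(300, sd = 0.1), 100, 3)
  xj <- xi + 2
  tr <- make_toy_traj(list(xi, xj))
  mi <- two(c(0, 0, 0), c(10, 10, 10))
  mj <- two(c(2, 2, 2), c(12, 12, 12))
  mp <- mdcc_mode_pair(tr, 1, 2, mi, mj, 1, 2)
  expect_lt(mp$mean_weight, 1e-6)
  expect_true(is.na(mp$value))
})

test_that("residue matrix equals the exhaustive enumeration oracle", {
  # 3 residues; two atoms bimodal with independent switches (so some joint
  # mode pairs are rare and must be filtered), one atom unimodal
  set.seed(55)
  mk_two_state <- function(q, c1, c2, n) {
    s <- 1L + (runif(n) > q)
    rbind(c1, c2)[s, ] + matrix(rnorm(3 * n, sd = 0.3), n, 3)
  }
  n <- 2000
  x1 <- mk_two_state(0.3, c(0, 0, 0), c(4, 0, 0), n)
  x2 <- mk_two_state(0.7, c(0, 3, 0), c(4, 3, 0), n)
  x3 <- matrix(rnorm(3 * n, sd = 0.3), n, 3) + 8
  tr <- make_toy_traj(list(x1, x2, x3))
  modes <- lapply(1:3, function(a) fit_modes(tr, a, max_modes = 3, seed = a))
  m <- residue_matrix(tr, modes, selection = "all", weight_floor = 0.1)
  oracle <- oracle_residue_matrix(tr, modes, 1:3, weight_floor = 0.1)
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(m$mdcc[a, b], oracle[a, b], tolerance = 1e-12)
  }
  # the rare-pair filter bit: joint occupancy ~0.3*0.3 = 0.09 <= 0.1 for the
  # (mode1, mode1) pair of atoms 1 and 2, so it cannot be the provenance pair
  prov12 <- m$provenance[m$provenance$a == 1 & m$provenance$b == 2, ]
  expect_gt(prov12$mean_weight, 0.1)
  # candidates below the floor were dropped entirely
  expect_true(all(m$candidates$mean_weight > 0.1))
})

test_that("rare but strong mode pairs are excluded and the next best kept", {
  # hand-built posteriors via mode geometry: the strongly-correlated joint
  # basin is occupied only 5% of the time
  set.seed(66)
  n <- 4000
  s <- 1L + (runif(n) > 0.05)      # state 1 rare (5%)
  e <- matrix(rnorm(3 * n, sd = 0.2), n, 3)
  eta <- matrix(rnorm(3 * n, sd = 0.2), n, 3)
  # in rare state 1 the two atoms are perfectly coupled; in state 2 uncoupled
  x1 <- rbind(c(0, 0, 0), c(6, 0, 0))[s, ] + e
  x2 <- rbind(c(0, 2, 0), c(6, 2, 0))[s, ]
  x2 <- x2 + ifelse(s == 1L, 1, 0) * e + ifelse(s == 1L, 0, 1) * eta
  tr <- make_toy_traj(list(x1, x2))
  modes <- lapply(1:2, function(a) fit_modes(tr, a, max_modes = 3, seed = a))
  m <- residue_matrix(tr, modes, selection = "all", weight_floor = 0.1)
  prov <- m$provenance[m$provenance$a == 1 & m$provenance$b == 2, ]
  # the maximizing pair must be a well-populated one, not the rare basin
  expect_gt(prov$mean_weight, 0.1)
  expect_lt(m$mdcc[1, 2], 0.9)   # the rho = 1 rare-basin value was filtered
})

test_that("forcing K = 1 makes the residue mDCC equal the DCC matrix", {
  sys <- generate_two_state_pair(1000, seed = 23)
  m <- mdcc(sys$trajectory, selection = "all", max_modes = 1, seed = 1)
  off <- upper.tri(m$mdcc)
  expect_lt(max(abs(m$mdcc[off] - m$dcc[off])), 1e-9)
})

test_that("random trajectories stay in range with symmetric matrices", {
  for (r in 1:5) {
    set.seed(700 + r)
    coords <- lapply(1:6, function(a) {
      drift <- outer(sin(seq_len(300) / (10 + a)), rnorm(3), "*")
      drift + matrix(rnorm(900, sd = runif(1, 0.2, 2)), 300, 3) + 10 * a
    })
    tr <- make_toy_traj(coords)
    m <- mdcc(tr, selection = "all", max_modes = 3, seed = r, restarts = 2)
    vals <- c(m$mdcc[upper.tri(m$mdcc)], m$dcc[upper.tri(m$dcc)])
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
    expect_lt(max(abs(m$mdcc - t(m$mdcc)), na.rm = TRUE), 1e-12)
    expect_lt(max(abs(m$dcc - t(m$dcc)), na.rm = TRUE), 1e-12)
    expect_equal(unname(diag(m$mdcc)), rep(1, 6))
  }
})

test_that("residues whose only atoms are frozen yield missing cells", {
  tr <- make_toy_traj(list(matrix(0, 100, 3),
                           matrix(rnorm(300), 100, 3)))
  modes <- lapply(1:2, function(a) fit_modes(tr, a, max_modes = 2, seed = a))
  m <- residue_matrix(tr, modes, selection = "all")
  expect_true(is.na(m$mdcc[1, 2]))
  expect_true(is.na(m$dcc[1, 2]))
  expect_true(is.na(m$mdcc[1, 1]))  # no motion: self-cell undefined too
})

test_that("matrix and provenance exports round-trip through files", {
  sys <- generate_two_state_pair(500, seed = 29)
  m <- mdcc(sys$trajectory, selection = "all", max_modes = 2, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_mdcc(m, tsv, provenance_json = jl)
  back <- as.matrix(read.table(tsv, sep = "\t", header = TRUE, row.names = 1,
                               check.names = FALSE))
  expect_equal(unname(back), unname(m$mdcc), tolerance = 1e-12)
  recs <- lapply(readLines(jl), jsonlite::fromJSON)
  expect_equal(length(recs), nrow(m$provenance))
})
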