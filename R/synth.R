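# Seeded synthetic trajectories with planted ground truth.
#
# The generators emit point-atom systems (one CA-named atom per residue,
# alanine bookkeeping) whose per-atom coordinate distributions have known
# Gaussian-mixture structure: planted mode centers and jitter, a shared
# two-state latent switch with Markov dwell times, and within-mode jitter
# correlated across coupled atoms.  Coordinates are emitted already
# superposed (no global rigid motion) unless `tumble = TRUE`.

synth_topology <- function(chain_residues, molecules = NULL) {
  # chain_residues: named integer vector, chain id -> residue count
  rows <- list()
  serial <- 0L
  for (ch in names(chain_residues)) {
    for (r in seq_len(chain_residues[[ch]])) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(serial = serial, name = "CA",
                                   element = "C", chain = ch, resno = r,
                                   insert = "", resname = "ALA",
                                   stringsAsFactors = FALSE)
    }
  }
  topology(do.call(rbind, rows), molecules = molecules)
}

# two-state latent schedule; dwell <= 1 means independent draws per frame
markov_states <- function(n, occupancy, dwell) {
  if (dwell <= 1) {
    return(1L + (runif(n) > occupancy))
  }
  d1 <- max(2 * occupancy * dwell, 1.0000001)
  d2 <- max(2 * (1 - occupancy) * dwell, 1.0000001)
  p12 <- 1 / d1
  p21 <- 1 / d2
  s <- integer(n)
  s[1] <- 1L + (runif(1) > occupancy)
  u <- runif(n)
  for (t in 2:n) {
    flip <- if (s[t - 1] == 1L) u[t] < p12 else u[t] < p21
    s[t] <- if (flip) 3L - s[t - 1] else s[t - 1]
  }
  s
}

random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_tumble <- function(coords) {
  for (f in seq_len(dim(coords)[1])) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 5)
    coords[f, , ] <- sweep(matrix(coords[f, , ], ncol = 3) %*% t(R), 2, tr, "+")
  }
  coords
}

new_ground_truth <- function(seed, modes, states = NULL, couplings = NULL,
                             mapping = NULL, intended_edges = NULL,
                             intended_top = NULL) {
  structure(list(seed = seed, modes = modes, states = states,
                 couplings = couplings, mapping = mapping,
                 intended_edges = intended_edges,
                 intended_top = intended_top),
            class = "synthetic_ground_truth")
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth (seed %d): %d atoms\n",
              x$seed, length(x$modes)))
  if (!is.null(x$states)) {
    cat(sprintf("  shared two-state switch: %d frames, state-1 fraction %.3f\n",
                length(x$states), mean(x$states == 1L)))
  }
  if (!is.null(x$intended_edges)) {
    cat(sprintf("  intended edges: %d\n", nrow(x$intended_edges)))
  }
  invisible(x)
}

#' Draw iid samples from a planted Gaussian mixture
#'
#' @param n sample count.
#' @param weights mixture weights (sum to 1).
#' @param centers `K x 3` matrix of mode centers, Angstrom.
#' @param sigma isotropic per-mode jitter s.d. (scalar or length K).
#' @param seed integer seed.
#' @return List: `coords` (`n x 3`), `component` (planted assignment).
#' @export
sample_mixture <- function(n, weights, centers, sigma, seed) {
  if (abs(sum(weights) - 1) > 1e-9 || any(weights <= 0)) {
    mdccr_stop("mixture weights must be positive and sum to 1",
               "mdccr_parameter_error")
  }
  centers <- matrix(centers, ncol = 3)
  K <- length(weights)
  sigma <- rep_len(sigma, K)
  if (any(sigma <= 0)) {
    mdccr_stop("sigma must be positive", "mdccr_parameter_error")
  }
  with_seed(seed, {
    comp <- sample.int(K, n, replace = TRUE, prob = weights)
    coords <- centers[comp, , drop = FALSE] +
      matrix(rnorm(3 * n), n, 3) * sigma[comp]
    list(coords = coords, component = comp)
  })
}

#' Generate a uni-modal (single-basin) synthetic system
#'
#' Independent isotropic Gaussian jitter per atom about fixed, well-separated
#' centers; every atom is its own residue.  Ground truth: K = 1 everywhere,
#' no couplings.
#'
#' @param n_atoms atom (= residue) count.
#' @param n_frames frame count (>= 2).
#' @param sigma isotropic jitter s.d., Angstrom.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param spacing center-to-center spacing along x, Angstrom.
#' @param tumble add a random global rigid motion per frame (exercises the
#'   superposition stage).
#' @return List: `trajectory`, `truth` (a `"synthetic_ground_truth"`).
#' @export
generate_unimodal_system <- function(n_atoms, n_frames, sigma = 1, seed = 1,
                                     spacing = 10, tumble = FALSE) {
  if (n_frames < 2L) mdccr_stop("n_frames must be >= 2", "mdccr_parameter_error")
  if (sigma <= 0) mdccr_stop("sigma must be positive", "mdccr_parameter_error")
  top <- synth_topology(c(A = n_atoms))
  centers <- cbind((seq_len(n_atoms) - 1) * spacing, 0, 0)
  coords <- with_seed(seed, {
    arr <- array(rnorm(n_frames * n_atoms * 3, sd = sigma),
                 dim = c(n_frames, n_atoms, 3))
    for (a in seq_len(n_atoms)) {
      arr[, a, ] <- sweep(arr[, a, , drop = TRUE], 2, centers[a, ], "+")
    }
    if (tumble) arr <- apply_tumble(arr)
    arr
  })
  modes <- lapply(seq_len(n_atoms), function(a) {
    list(weights = 1, centers = matrix(centers[a, ], 1, 3), sigma = sigma)
  })
  list(trajectory = trajectory(coords, top, box_warn_threshold = Inf),
       truth = new_ground_truth(seed, modes,
                                mapping = residue_table(top)))
}

#' Generate a coupled two-state atom pair
#'
#' Two atoms share one latent two-state (Markov) switch selecting each atom's
#' active mode center; within-mode displacements are correlated across the
#' atoms with coefficient `rho` along matched axes.  `geometry` controls how
#' the two atoms' inter-center vectors relate: with `"anti-aligned"` vectors
#' the mode-switch contribution to the naive covariance opposes the jitter
#' correlation, so conventional DCC is small or negative while the
#' matched-mode mDCC stays near `rho` — the scenario in which averaging over
#' a multi-modal distribution hides a real, transiently formed interaction.
#'
#' @param n_frames frame count.
#' @param centers_i,centers_j optional `2 x 3` matrices of the two atoms'
#'   mode centers (Angstrom); defaults are built from `separation`,
#'   `contact_distance` and `geometry`.
#' @param occupancy stationary fraction of state 1, in (0,1).
#' @param rho within-mode jitter correlation, `|rho| <= 1`.
#' @param jitter_sigma within-mode isotropic jitter s.d., Angstrom.
#' @param separation distance between each atom's two centers (default
#'   `6 * jitter_sigma`).
#' @param contact_distance distance between the atoms' state-1 centers
#'   (default 4 A, i.e. in contact).
#' @param geometry `"anti-aligned"`, `"aligned"` or `"orthogonal"`.
#' @param dwell mean dwell time of the switch, frames; `<= 1` gives
#'   independent per-frame states.
#' @param seed integer seed.
#' @param tumble add global rigid motion per frame.
#' @return List: `trajectory` (2 atoms, chains A and B), `truth`.
#' @export
generate_two_state_pair <- function(n_frames, centers_i = NULL,
                                    centers_j = NULL, occupancy = 0.5,
                                    rho = 0.9, jitter_sigma = 1,
                                    separation = 6 * jitter_sigma,
                                    contact_distance = 4,
                                    geometry = c("anti-aligned", "aligned",
                                                 "orthogonal"),
                                    dwell = 100, seed = 1, tumble = FALSE) {
  geometry <- match.arg(geometry)
  if (occupancy <= 0 || occupancy >= 1) {
    mdccr_stop("occupancy must lie in (0,1)", "mdccr_parameter_error")
  }
  if (abs(rho) > 1) mdccr_stop("|rho| must be <= 1", "mdccr_parameter_error")
  if (jitter_sigma <= 0) {
    mdccr_stop("jitter_sigma must be positive", "mdccr_parameter_error")
  }
  if (is.null(centers_i)) {
    centers_i <- rbind(c(0, 0, 0), c(0, separation, 0))
  }
  if (is.null(centers_j)) {
    step <- switch(geometry,
                   "aligned" = c(0, separation, 0),
                   "anti-aligned" = c(0, -separation, 0),
                   "orthogonal" = c(0, 0, separation))
    centers_j <- rbind(c(contact_distance, 0, 0),
                       c(contact_distance, 0, 0) + step)
  }
  centers_i <- matrix(centers_i, 2, 3)
  centers_j <- matrix(centers_j, 2, 3)
  if (sum((centers_i[1, ] - centers_i[2, ])^2) < 1e-12 ||
      sum((centers_j[1, ] - centers_j[2, ])^2) < 1e-12) {
    mdccr_stop("each atom needs two distinct mode centers",
               "mdccr_parameter_error")
  }
  top <- synth_topology(c(A = 1L, B = 1L))
  out <- with_seed(seed, {
    s <- markov_states(n_frames, occupancy, dwell)
    ei <- matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3)
    ej <- rho * ei + sqrt(1 - rho^2) *
      matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3)
    arr <- array(NA_real_, dim = c(n_frames, 2L, 3L))
    arr[, 1, ] <- centers_i[s, ] + ei
    arr[, 2, ] <- centers_j[s, ] + ej
    if (tumble) arr <- apply_tumble(arr)
    list(arr = arr, s = s)
  })
  modes <- list(
    list(weights = c(occupancy, 1 - occupancy), centers = centers_i,
         sigma = jitter_sigma),
    list(weights = c(occupancy, 1 - occupancy), centers = centers_j,
         sigma = jitter_sigma))
  truth <- new_ground_truth(seed, modes, states = out$s,
                            couplings = data.frame(atom_i = 1L, atom_j = 2L,
                                                   rho = rho),
                            mapping = residue_table(top))
  truth$geometry <- geometry
  list(trajectory = trajectory(out$arr, top, box_warn_threshold = Inf),
       truth = truth)
}

#' Generate a planted allosteric chain
#'
#' Three molecules — A, a bridge, and B — whose residues form one coupling
#' path: consecutive path residues share a two-state switch, have correlated
#' within-mode jitter (`rho`) and sit within contact range of each other,
#' while all other residue pairs are either uncoupled, out of contact, or
#' both.  Alternating inter-center geometry keeps the conventional DCC of
#' consecutive pairs low (transient edges).  Decoy residues per molecule are
#' uni-modal, uncoupled and far from everything.  The ground truth records
#' the intended edge set (consecutive path pairs) and the intended
#' top-betweenness residue (the middle of the path, a bridge residue).
#'
#' @param n_frames frame count.
#' @param n_a,n_bridge,n_b path residues per molecule.
#' @param n_decoy decoy residues added to each molecule.
#' @param rho within-mode jitter correlation of consecutive path residues.
#' @param jitter_sigma within-mode jitter s.d., Angstrom.
#' @param spacing distance between consecutive path residues' base
#'   positions, Angstrom (must stay in contact range, < 5).
#' @param separation distance between each path residue's two mode centers
#'   (default `6 * jitter_sigma`).
#' @param occupancy,dwell switch parameters (see
#'   [generate_two_state_pair()]).
#' @param break_link optional path position `m`: decouple and separate path
#'   residues `m` and `m + 1` (the network then falls apart into two
#'   components).
#' @param seed integer seed.
#' @return List: `trajectory`, `truth` (with `intended_edges` and
#'   `intended_top`).
#' @export
generate_allosteric_chain <- function(n_frames = 5000, n_a = 4, n_bridge = 5,
                                      n_b = 4, n_decoy = 2, rho = 0.9,
                                      jitter_sigma = 0.25, spacing = 3.5,
                                      separation = 6 * jitter_sigma,
                                      occupancy = 0.5, dwell = 100,
                                      break_link = NULL, seed = 1) {
  if (n_bridge < 1L || n_a < 1L || n_b < 1L) {
    mdccr_stop("each molecule needs at least one path residue",
               "mdccr_parameter_error")
  }
  # intended edges must be geometrically realisable: both matched-mode
  # center distances have to be inside the 5 A contact rule
  if (spacing >= 5 || sqrt(spacing^2 + (2 * separation)^2) >= 5) {
    mdccr_stop(paste0("inconsistent chain spec: coupled consecutive residues",
                      " would not be in contact (< 5 A) for this spacing/",
                      "separation"), "mdccr_spec_error")
  }
  M <- n_a + n_bridge + n_b
  chain_of <- rep(c("A", "X", "B"), times = c(n_a, n_bridge, n_b))
  counts <- c(A = n_a + n_decoy, X = n_bridge + n_decoy, B = n_b + n_decoy)
  top <- synth_topology(counts,
                        molecules = c(A = "A", X = "bridge", B = "B"))
  rtab <- residue_table(top)
  # atom index of path position m: decoys are appended within each chain,
  # so chain A holds residues 1..n_a then decoys, etc.
  path_atom <- integer(M)
  m <- 1L
  for (ch in c("A", "X", "B")) {
    n_path <- c(A = n_a, X = n_bridge, B = n_b)[[ch]]
    idx <- which(top$atoms$chain == ch)
    path_atom[m:(m + n_path - 1L)] <- idx[seq_len(n_path)]
    m <- m + n_path
  }
  decoy_atom <- setdiff(seq_len(n_atoms(top)), path_atom)

  base <- cbind((seq_len(M) - 1) * spacing, 0, 0)
  offs <- cbind(0, (-1)^(seq_len(M)) * separation, 0)
  shift_z <- rep(0, M)
  if (!is.null(break_link)) {
    if (break_link < 1L || break_link >= M) {
      mdccr_stop("break_link must name a path link (1 .. path length - 1)",
                 "mdccr_parameter_error")
    }
    shift_z[(break_link + 1L):M] <- 30
  }
  coords <- with_seed(seed, {
    s <- markov_states(n_frames, occupancy, dwell)
    arr <- array(0, dim = c(n_frames, n_atoms(top), 3L))
    eps <- matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3)
    for (mm in seq_len(M)) {
      if (mm > 1L) {
        fresh <- !is.null(break_link) && mm == break_link + 1L
        eps <- if (fresh) {
          matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3)
        } else {
          rho * eps + sqrt(1 - rho^2) *
            matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3)
        }
      }
      ctr1 <- base[mm, ] + c(0, 0, shift_z[mm])
      ctr2 <- ctr1 + offs[mm, ]
      centers <- rbind(ctr1, ctr2)
      arr[, path_atom[mm], ] <- centers[s, ] + eps
    }
    for (d in seq_along(decoy_atom)) {
      ctr <- c(12 * d, 60, 0)
      arr[, decoy_atom[d], ] <-
        sweep(matrix(rnorm(3 * n_frames, sd = jitter_sigma), n_frames, 3),
              2, ctr, "+")
    }
    attr(arr, "states") <- s
    arr
  })
  states <- attr(coords, "states")
  attr(coords, "states") <- NULL

  links <- cbind(seq_len(M - 1L), 2:M)
  if (!is.null(break_link)) links <- links[links[, 1] != break_link, , drop = FALSE]
  intended_edges <- data.frame(
    a = rtab$key[top$atoms$residue[path_atom[links[, 1]]]],
    b = rtab$key[top$atoms$residue[path_atom[links[, 2]]]],
    stringsAsFactors = FALSE)
  mid <- path_atom[ceiling(M / 2)]
  intended_top <- if (is.null(break_link)) {
    rtab$key[top$atoms$residue[mid]]
  } else NA_character_

  modes <- vector("list", n_atoms(top))
  for (mm in seq_len(M)) {
    ctr1 <- base[mm, ] + c(0, 0, shift_z[mm])
    modes[[path_atom[mm]]] <- list(weights = c(occupancy, 1 - occupancy),
                                   centers = rbind(ctr1, ctr1 + offs[mm, ]),
                                   sigma = jitter_sigma)
  }
  for (d in seq_along(decoy_atom)) {
    modes[[decoy_atom[d]]] <- list(weights = 1,
                                   centers = matrix(c(12 * d, 60, 0), 1, 3),
                                   sigma = jitter_sigma)
  }
  couplings <- data.frame(atom_i = path_atom[links[, 1]],
                          atom_j = path_atom[links[, 2]], rho = rho)
  truth <- new_ground_truth(seed, modes, states = states,
                            couplings = couplings, mapping = rtab,
                            intended_edges = intended_edges,
                            intended_top = intended_top)
  list(trajectory = trajectory(coords, top, box_warn_threshold = Inf),
       truth = truth)
}
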