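# Standard trajectory descriptors: RMSD, RMSF, Cartesian PCA, interatomic
# distance series, and density-based clustering of PC score clouds.

#' Per-frame RMSD against a reference
#'
#' `value[t] = sqrt(mean over selected atoms of squared deviation)` from the
#' reference, optionally after fitting each frame onto the reference on the
#' same selection.
#'
#' @param traj a `"trajectory"`.
#' @param reference frame index, `n_atoms x 3` matrix, or `"trajectory"`
#'   (first frame).
#' @param selection atoms entering the RMSD (see [select_atoms()]).
#' @param fit if `TRUE`, superpose each frame onto the reference (on the same
#'   selection) before measuring.  Default `FALSE`: measure as-is.
#' @return Numeric vector, one value per frame, in Angstrom.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "all", fit = FALSE) {
  sel <- which(select_atoms(traj$topology, selection))
  if (length(sel) == 0L) {
    mdccr_stop("empty selection for RMSD", "mdccr_selection_error")
  }
  ref <- if (inherits(reference, "trajectory")) frame_coords(reference, 1L)
         else if (is.matrix(reference)) reference
         else frame_coords(traj, as.integer(reference))
  if (fit) traj <- superpose(traj, ref, sel)
  refs <- ref[sel, , drop = FALSE]
  vapply(seq_len(n_frames(traj)), function(f) {
    d <- matrix(traj$coords[f, sel, ], ncol = 3) - refs
    sqrt(mean(rowSums(d * d)))
  }, numeric(1))
}

#' Root-mean-square fluctuation per atom
#'
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)` after removing global rigid
#' motion.  By default each molecule is superposed independently on its own
#' backbone (other molecules ignored), which isolates internal fluctuations
#' from inter-molecular tumbling; `fit = "global"` superposes all molecules
#' together, `fit = "none"` uses the coordinates as given.
#'
#' @param traj a `"trajectory"` (>= 2 frames).
#' @param selection atoms to report (see [select_atoms()]).
#' @param fit `"molecule"`, `"global"` or `"none"`.
#' @param fit_selection atoms used for the superposition fit
#'   (default `"backbone"`; intersected with each molecule under
#'   `fit = "molecule"`).
#' @param by_residue if `TRUE`, average atom RMSF within each residue and
#'   return one value per residue (named by residue key).
#' @return Named numeric vector (Angstrom), per atom or per residue.
#' @export
rmsf <- function(traj, selection = "heavy",
                 fit = c("molecule", "global", "none"),
                 fit_selection = "backbone", by_residue = FALSE) {
  fit <- match.arg(fit)
  if (n_frames(traj) < 2L) {
    mdccr_stop("RMSF needs at least 2 frames", "mdccr_validation_error")
  }
  top <- traj$topology
  sel <- which(select_atoms(top, selection))
  if (length(sel) == 0L) {
    mdccr_stop("empty selection for RMSF", "mdccr_selection_error")
  }
  fitmask <- select_atoms(top, fit_selection)

  vals <- rep(NA_real_, length(sel))
  mol_of_atom <- unname(top$molecules[top$atoms$chain])
  groups <- if (fit == "molecule") split(seq_along(sel), mol_of_atom[sel])
            else list(all = seq_along(sel))
  for (g in groups) {
    atoms_g <- sel[g]
    work <- traj
    if (fit != "none") {
      fmask <- fitmask
      if (fit == "molecule") {
        fmask <- fmask & mol_of_atom == mol_of_atom[atoms_g[1]]
      }
      if (sum(fmask) < 3L) {
        fmask <- select_atoms(top, "heavy") &
          (fit != "molecule" | mol_of_atom == mol_of_atom[atoms_g[1]])
      }
      if (sum(fmask) < 3L) {
        # too few atoms to define a rigid fit (e.g. point-atom molecules):
        # fall back to the coordinates as given
        warning(sprintf(paste0("molecule '%s' has fewer than 3 fit atoms; ",
                               "RMSF computed without superposition"),
                        mol_of_atom[atoms_g[1]]))
      } else {
        work <- superpose(traj, 1L, fmask)
      }
    }
    for (i in seq_along(atoms_g)) {
      X <- atom_coords(work, atoms_g[i])
      d <- sweep(X, 2, colMeans(X))
      vals[g[i]] <- sqrt(mean(rowSums(d * d)))
    }
  }
  names(vals) <- paste0(residue_keys(top$atoms)[sel], ":", top$atoms$name[sel])
  if (by_residue) {
    rk <- residue_keys(top$atoms)[sel]
    vals <- vapply(split(vals, factor(rk, levels = unique(rk))), mean,
                   numeric(1))
  }
  vals
}

#' Cartesian principal component analysis
#'
#' Eigen-decomposition of the population covariance (1/n normalisation) of
#' the flattened 3N coordinate vectors of the selected atoms.  The trajectory
#' is assumed superposed already.
#'
#' @param traj a superposed `"trajectory"`.
#' @param selection atoms entering the PCA.
#' @return `"traj_pca"` object: `mean_structure` (n_sel x 3), `components`
#'   (3N x n_comp, orthonormal columns), `eigenvalues` (A^2, non-increasing),
#'   `contribution_rates` (sum to 1), `projections` (frames x n_comp),
#'   `atoms` (selected indices).
#' @export
pca_cartesian <- function(traj, selection = "all") {
  sel <- which(select_atoms(traj$topology, selection))
  if (length(sel) == 0L) {
    mdccr_stop("empty selection for PCA", "mdccr_selection_error")
  }
  m <- n_frames(traj)
  if (m <= 3L * length(sel)) {
    warning(sprintf("only %d frames for %d coordinates; PCA may be noisy",
                    m, 3L * length(sel)))
  }
  X <- array_to_xyz(traj$coords[, sel, , drop = FALSE])  # frames x 3N
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc, nu = 0)
  ev <- s$d^2 / m                       # population covariance eigenvalues
  tot <- sum(ev)
  if (tot < 1e-300) {
    mdccr_stop("zero total variance; PCA undefined", "mdccr_validation_error")
  }
  keep <- seq_len(min(m, ncol(X)))
  structure(list(mean_structure = matrix(mu, ncol = 3, byrow = TRUE),
                 components = s$v[, keep, drop = FALSE],
                 eigenvalues = ev[keep],
                 contribution_rates = ev[keep] / tot,
                 projections = Xc %*% s$v[, keep, drop = FALSE],
                 atoms = sel),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("Cartesian PCA: %d atoms, %d frames\n",
              nrow(x$mean_structure), nrow(x$projections)))
  cat("  contribution rates:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$contribution_rates[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.traj_pca <- function(x, ...) {
  plot(x$projections[, 1], x$projections[, 2],
       xlab = sprintf("PC1 (%.1f%%)", 100 * x$contribution_rates[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * x$contribution_rates[2]),
       pch = 20, cex = 0.4, ...)
  invisible(x)
}

#' Interatomic distance time series
#'
#' Euclidean distance between two atoms in every frame; no superposition is
#' applied (distances are rigid-transform invariant anyway).
#'
#' @param traj a `"trajectory"`.
#' @param atom_a,atom_b atom indices (topology order).
#' @return Numeric vector per frame, Angstrom.
#' @export
distance_series <- function(traj, atom_a, atom_b) {
  d <- atom_coords(traj, atom_a) - atom_coords(traj, atom_b)
  sqrt(rowSums(d * d))
}

#' Density-based clustering of a 2-D score cloud
#'
#' Kernel-density contouring of (PC1, PC2) scores: the density is estimated
#' on a grid ([MASS::kde2d]), cells above `threshold` times the peak density
#' are kept, and 8-connected super-threshold regions become clusters.  Each
#' point is assigned the label of its grid cell; sub-threshold points are
#' assigned the nearest labelled cell (set `assign_all = FALSE` to keep them
#' as noise, label 0).
#'
#' @param projections two-column matrix (or `"traj_pca"`, using PC1/PC2).
#' @param n_grid grid resolution per axis.
#' @param bandwidth optional length-2 bandwidth for [MASS::kde2d]; default
#'   normal-reference bandwidth per axis.
#' @param threshold density cutoff as a fraction of the peak density.
#' @param assign_all assign sub-threshold points to the nearest cluster?
#' @return `"density_clusters"`: `labels` (per point), `n_clusters`,
#'   `centers` (cluster density-peak coordinates), plus the grid.
#' @export
density_cluster_2d <- function(projections, n_grid = 100, bandwidth = NULL,
                               threshold = 0.05, assign_all = TRUE) {
  if (inherits(projections, "traj_pca")) {
    projections <- projections$projections[, 1:2, drop = FALSE]
  }
  P <- as.matrix(projections)[, 1:2, drop = FALSE]
  if (nrow(P) < 2L) {
    mdccr_stop("need at least 2 points to cluster", "mdccr_validation_error")
  }
  if (max(abs(sweep(P, 2, P[1, ]))) < 1e-12) {  # degenerate: all identical
    return(structure(list(labels = rep(1L, nrow(P)), n_clusters = 1L,
                          centers = matrix(P[1, ], ncol = 2), grid = NULL),
                     class = "density_clusters"))
  }
  if (is.null(bandwidth)) {
    bw1 <- MASS::bandwidth.nrd(P[, 1])
    bw2 <- MASS::bandwidth.nrd(P[, 2])
    if (bw1 <= 0) bw1 <- max(diff(range(P[, 1])) / n_grid, 1e-6)
    if (bw2 <= 0) bw2 <- max(diff(range(P[, 2])) / n_grid, 1e-6)
    bandwidth <- c(bw1, bw2)
  }
  pad <- bandwidth
  kd <- MASS::kde2d(P[, 1], P[, 2], h = bandwidth, n = n_grid,
                    lims = c(range(P[, 1]) + c(-1, 1) * pad[1],
                             range(P[, 2]) + c(-1, 1) * pad[2]))
  keep <- kd$z >= threshold * max(kd$z)
  lab <- label_components(keep)
  nclu <- max(lab)

  # map each point to its grid cell
  gi <- findInterval(P[, 1], kd$x, all.inside = TRUE)
  gj <- findInterval(P[, 2], kd$y, all.inside = TRUE)
  # snap to nearer grid node
  gi <- gi + (abs(kd$x[pmin(gi + 1L, n_grid)] - P[, 1]) < abs(kd$x[gi] - P[, 1]))
  gj <- gj + (abs(kd$y[pmin(gj + 1L, n_grid)] - P[, 2]) < abs(kd$y[gj] - P[, 2]))
  labels <- lab[cbind(gi, gj)]

  if (assign_all && any(labels == 0L) && nclu > 0L) {
    lab_cells <- which(lab > 0L, arr.ind = TRUE)
    cellxy <- cbind(kd$x[lab_cells[, 1]], kd$y[lab_cells[, 2]])
    for (p in which(labels == 0L)) {
      d2 <- (cellxy[, 1] - P[p, 1])^2 + (cellxy[, 2] - P[p, 2])^2
      labels[p] <- lab[lab_cells[which.min(d2), , drop = FALSE]]
    }
  }
  centers <- t(vapply(seq_len(max(nclu, 1L)), function(k) {
    cells <- which(lab == k, arr.ind = TRUE)
    if (nrow(cells) == 0L) return(c(NA_real_, NA_real_))
    peak <- cells[which.max(kd$z[cells]), ]
    c(kd$x[peak[1]], kd$y[peak[2]])
  }, numeric(2)))
  structure(list(labels = labels, n_clusters = nclu, centers = centers,
                 grid = kd), class = "density_clusters")
}

#' @export
print.density_clusters <- function(x, ...) {
  cat(sprintf("Density clustering: %d cluster(s), %d points (%d noise)\n",
              x$n_clusters, length(x$labels), sum(x$labels == 0L)))
  invisible(x)
}

# label 8-connected TRUE regions of a logical matrix (iterative flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      cell <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((cell - 1L) %% nr) + 1L
      j <- ((cell - 1L) %/% nr) + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          nb <- (jj - 1L) * nr + ii
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}
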