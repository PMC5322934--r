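# Trajectory container and rigid-body superposition.

#' Construct a trajectory
#'
#' @param coords numeric array `n_frames x n_atoms x 3`, in Angstrom.
#' @param top the `"topology"` the atom axis refers to (same order).
#' @param frame_times optional numeric vector of frame times (ps).
#' @param box_warn_threshold warn if any frame's bounding-box diagonal exceeds
#'   this many Angstrom (likely un-imaged periodic coordinates); `Inf` disables.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(coords, top, frame_times = NULL,
                       box_warn_threshold = 1000) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    mdccr_stop("coords must be an n_frames x n_atoms x 3 array",
               "mdccr_shape_error")
  }
  if (dim(coords)[2] != n_atoms(top)) {
    mdccr_stop(sprintf("coords have %d atoms but topology has %d",
                       dim(coords)[2], n_atoms(top)), "mdccr_shape_error")
  }
  if (!all(is.finite(coords))) {
    mdccr_stop("non-finite coordinates in trajectory", "mdccr_validation_error")
  }
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[1]) {
    mdccr_stop("frame_times length must equal n_frames", "mdccr_shape_error")
  }
  if (is.finite(box_warn_threshold)) {
    rng <- apply(coords, 3, range)  # 2 x 3 over all frames/atoms: cheap proxy
    diag_len <- sqrt(sum((rng[2, ] - rng[1, ])^2))
    if (diag_len > box_warn_threshold) {
      warning(sprintf(paste0("bounding box diagonal %.0f A exceeds %.0f A; ",
                             "coordinates may not be re-imaged"),
                      diag_len, box_warn_threshold))
    }
  }
  structure(list(coords = coords, topology = top, frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d atoms\n", d[1], d[2]))
  print(x$topology)
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one atom across frames
#'
#' @param traj a `"trajectory"`.
#' @param atom atom index (topology order).
#' @return `n_frames x 3` matrix.
#' @export
atom_coords <- function(traj, atom) {
  na <- dim(traj$coords)[2]
  if (length(atom) != 1L || atom < 1L || atom > na) {
    mdccr_stop(paste0("unknown atom index: ", atom), "mdccr_lookup_error")
  }
  traj$coords[, atom, , drop = TRUE]
}

#' Single frame as an atom x 3 matrix
#' @param traj a `"trajectory"`.
#' @param frame frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, frame) {
  if (frame < 1L || frame > n_frames(traj)) {
    mdccr_stop(paste0("frame out of range: ", frame), "mdccr_lookup_error")
  }
  matrix(traj$coords[frame, , ], ncol = 3)
}

xyz_to_array <- function(xyz) {
  # bio3d xyz matrix (frames x 3N, columns x1,y1,z1,...) -> frames x N x 3
  m <- nrow(xyz)
  nat <- ncol(xyz) / 3L
  aperm(array(t(xyz), dim = c(3L, nat, m)), c(3L, 2L, 1L))
}

array_to_xyz <- function(coords) {
  m <- dim(coords)[1]
  nat <- dim(coords)[2]
  matrix(aperm(coords, c(3L, 2L, 1L)), nrow = m, ncol = 3L * nat, byrow = TRUE)
}

#' Read a trajectory
#'
#' Multi-model PDB and DCD are supported.  Every frame must contain exactly
#' the topology's atoms, in topology order; a mismatch raises a shape error
#' naming the offending frame.  Coordinates are in Angstrom (the native unit
#' of both formats).
#'
#' @param path trajectory file.
#' @param format `"pdb"` (multi-model) or `"dcd"`; `"xtc"` is recognised but
#'   not implemented.
#' @param top the matching `"topology"`.
#' @return A `"trajectory"`.
#' @export
read_trajectory <- function(path, format = c("pdb", "dcd", "xtc"), top) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    mdccr_stop(paste0("file not found: ", path), "mdccr_io_error")
  }
  if (format == "xtc") {
    mdccr_stop("XTC reading is not implemented; convert to DCD or multi-model PDB",
               "mdccr_format_error")
  }
  nat <- n_atoms(top)
  if (format == "pdb") {
    # per-model atom-count scan first, for a precise shape diagnostic
    lines <- readLines(path)
    model_starts <- grep("^MODEL", lines)
    if (length(model_starts) > 0) {
      model_ends <- grep("^ENDMDL", lines)
      counts <- vapply(seq_along(model_starts), function(i) {
        blk <- lines[model_starts[i]:model_ends[i]]
        sum(grepl("^(ATOM  |HETATM)", blk))
      }, integer(1))
      bad <- which(counts != nat)
      if (length(bad) > 0) {
        mdccr_stop(sprintf("frame %d has %d atoms but topology has %d",
                           bad[1], counts[bad[1]], nat), "mdccr_shape_error")
      }
    }
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE))
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
    if (ncol(xyz) != 3L * nat) {
      mdccr_stop(sprintf("DCD frames have %d atoms but topology has %d",
                         ncol(xyz) / 3L, nat), "mdccr_shape_error")
    }
  }
  if (ncol(xyz) != 3L * nat) {
    mdccr_stop(sprintf("frames have %d atoms but topology has %d",
                       ncol(xyz) / 3L, nat), "mdccr_shape_error")
  }
  trajectory(xyz_to_array(xyz), top)
}

fmt_pdb_name <- function(name) {
  # atom names shorter than 4 characters start in column 14
  ifelse(nchar(name) >= 4L, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj a `"trajectory"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  a <- traj$topology$atoms
  nm <- fmt_pdb_name(a$name)
  con <- file(path, "w")
  on.exit(close(con))
  m <- n_frames(traj)
  for (f in seq_len(m)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, nm, substr(a$resname, 1, 3), a$chain,
      a$resno %% 10000L, a$insert, xyz[, 1], xyz[, 2], xyz[, 3],
      1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Kabsch: proper rotation (det = +1) and translation minimising RMSD of P
# onto Q (both n x 3).  Returns R (3x3) and centers; apply as
# (X - cp) %*% t(R) + cq.
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

check_fit_selection <- function(X) {
  if (nrow(X) < 3L) {
    mdccr_stop("superposition needs at least 3 selected atoms",
               "mdccr_degenerate_fit_error")
  }
  sv <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    mdccr_stop("selected atoms are (nearly) collinear; rotation is not determined",
               "mdccr_degenerate_fit_error")
  }
  invisible(TRUE)
}

#' Superpose a trajectory onto a reference frame
#'
#' Each frame is rigid-body fitted (rotation with determinant +1, plus
#' translation; the classic SVD solution with reflection correction) so that
#' the selected atoms minimise RMSD to the reference; the fitted transform is
#' applied to all atoms of the frame.
#'
#' @param traj a `"trajectory"`.
#' @param reference reference coordinates: a frame index into `traj`
#'   (default 1), an `n_atoms x 3` matrix, or another `"trajectory"` (its
#'   first frame is used).
#' @param selection atoms to fit on (see [select_atoms()]); default
#'   `"backbone"`.
#' @return The superposed `"trajectory"`.
#' @export
superpose <- function(traj, reference = 1L, selection = "backbone") {
  sel <- which(select_atoms(traj$topology, selection))
  if (length(sel) == 0L) {
    mdccr_stop("empty superposition selection", "mdccr_selection_error")
  }
  ref <- if (inherits(reference, "trajectory")) {
    frame_coords(reference, 1L)
  } else if (is.matrix(reference)) {
    reference
  } else {
    frame_coords(traj, as.integer(reference))
  }
  if (nrow(ref) != n_atoms(traj$topology)) {
    mdccr_stop("reference must have the topology's atom count", "mdccr_shape_error")
  }
  Qs <- ref[sel, , drop = FALSE]
  check_fit_selection(Qs)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    X <- matrix(traj$coords[f, , ], ncol = 3)
    fit <- kabsch_fit(X[sel, , drop = FALSE], Qs)
    out[f, , ] <- sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, fit$cq, "+")
  }
  trajectory(out, traj$topology, traj$frame_times, box_warn_threshold = Inf)
}
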