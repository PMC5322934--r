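# Dynamic cross-correlation (DCC) and its multi-modal generalisation (mDCC).
#
# DCC(i,j)            = <dri . drj>_t / sqrt(<|dri|^2> <|drj|^2>),
#                       dri(t) = ri(t) - <ri>_t.
# mDCC(i,j;k,l)       = <w (dri_k . drj_l)>_t /
#                       sqrt(<w |dri_k|^2>_t <w |drj_l|^2>_t),
#                       dri_k(t) = ri(t) - mu_k,  w(t) = p_k(ri(t)) p_l(rj(t)).
# Residue summary     : mDCC(a,b) = max over atoms i in a, j in b and mode
#                       pairs (k,l) of mDCC(i,j;k,l), restricted to pairs
#                       whose time-averaged joint probability exceeds the
#                       rare-pair floor (default 0.1).

dcc_xy <- function(xi, xj) {
  di <- sweep(xi, 2, colMeans(xi))
  dj <- sweep(xj, 2, colMeans(xj))
  vi <- mean(rowSums(di * di))
  vj <- mean(rowSums(dj * dj))
  if (vi < 1e-24 || vj < 1e-24) {
    mdccr_stop("DCC undefined: atom with zero positional variance",
               "mdccr_undefined_correlation_error")
  }
  mean(rowSums(di * dj)) / sqrt(vi * vj)
}

#' Conventional dynamic cross-correlation of two atoms
#'
#' Normalized time-averaged dot product of the two atoms' deviations from
#' their mean positions, in `[-1, 1]`.  The trajectory should be superposed
#' first so that global rigid motion does not masquerade as correlation.
#'
#' @param traj a superposed `"trajectory"`.
#' @param atom_i,atom_j atom indices.
#' @return Scalar correlation.
#' @export
dcc <- function(traj, atom_i, atom_j) {
  dcc_xy(atom_coords(traj, atom_i), atom_coords(traj, atom_j))
}

mdcc_xy <- function(xi, xj, pi_k, pj_l, mu_k, mu_l) {
  w <- pi_k * pj_l
  mw <- mean(w)
  di <- sweep(xi, 2, mu_k)
  dj <- sweep(xj, 2, mu_l)
  d1 <- mean(w * rowSums(di * di))
  d2 <- mean(w * rowSums(dj * dj))
  val <- if (d1 < 1e-24 || d2 < 1e-24) NA_real_
         else mean(w * rowSums(di * dj)) / sqrt(d1 * d2)
  list(value = val, mean_weight = mw)
}

#' Mode-pair mDCC between two atoms
#'
#' Correlation between mode `k` of atom `i` and mode `l` of atom `j`:
#' deviations are taken from the mode centers and every frame is weighted by
#' the joint mode-membership probability `w(t) = p_k(r_i(t)) p_l(r_j(t))`.
#' When both atoms are uni-modal this reduces exactly to the conventional
#' DCC.
#'
#' @param traj a superposed `"trajectory"`.
#' @param atom_i,atom_j atom indices.
#' @param modes_i,modes_j `"atom_modes"` fits for the two atoms.
#' @param k,l mode indices.
#' @param posterior_i,posterior_j optional precomputed [mode_posterior()]
#'   matrices (recomputed when omitted).
#' @return List of class `"mode_pair_correlation"`: `atom_i`, `atom_j`, `k`,
#'   `l`, `value` (`NA` when the weighted variances vanish, e.g. the mode
#'   pair is never jointly occupied), `mean_weight` (time-averaged joint
#'   probability) and `center_distance` (Angstrom).
#' @export
mdcc_mode_pair <- function(traj, atom_i, atom_j, modes_i, modes_j, k, l,
                           posterior_i = NULL, posterior_j = NULL) {
  if (k < 1L || k > modes_i$K || l < 1L || l > modes_j$K) {
    mdccr_stop("mode index out of range", "mdccr_lookup_error")
  }
  xi <- atom_coords(traj, atom_i)
  xj <- atom_coords(traj, atom_j)
  if (is.null(posterior_i)) posterior_i <- mode_posterior(modes_i, xi)
  if (is.null(posterior_j)) posterior_j <- mode_posterior(modes_j, xj)
  res <- mdcc_xy(xi, xj, posterior_i[, k], posterior_j[, l],
                 modes_i$centers[k, ], modes_j$centers[l, ])
  structure(list(atom_i = atom_i, atom_j = atom_j, k = k, l = l,
                 value = res$value, mean_weight = res$mean_weight,
                 center_distance = mode_center_distance(modes_i, k, modes_j, l)),
            class = "mode_pair_correlation")
}

#' Residue-level mDCC/DCC correlation matrix
#'
#' Evaluates the mode-pair mDCC for every atom pair (and every mode pair)
#' across residues, drops rare pairs whose time-averaged joint probability is
#' at or below `weight_floor`, and keeps per residue pair the largest mDCC
#' value along with the provenance of the maximizing atom/mode pair (ties:
#' larger mean weight, then smaller center distance).  A companion
#' conventional-DCC matrix stores, per residue pair, the largest atom-pair
#' DCC.  The minimum mDCC per residue pair is also recorded for diagnostics.
#'
#' @param traj a superposed `"trajectory"`.
#' @param modes list of `"atom_modes"`, named/indexed by the atoms in
#'   `selection` order (as produced by [mdcc()]); one per analysed atom.
#' @param selection atoms analysed (default `"heavy"`).
#' @param weight_floor rare-pair filter on the time-averaged joint mode
#'   probability (default 0.1).
#' @param keep_candidates retain all floor-passing mode-pair candidates per
#'   residue pair (needed for the "any mode pair" network rule; costs
#'   memory on large systems).
#' @return An `"mdcc_matrix"` (see [mdcc()]).
#' @export
residue_matrix <- function(traj, modes, selection = "heavy",
                           weight_floor = 0.1, keep_candidates = TRUE) {
  top <- traj$topology
  sel <- which(select_atoms(top, selection))
  if (length(sel) != length(modes)) {
    mdccr_stop(sprintf("%d mode fits supplied for %d selected atoms",
                       length(modes), length(sel)), "mdccr_shape_error")
  }
  rtab <- residue_table(top)
  nres <- nrow(rtab)
  res_of <- top$atoms$residue[sel]

  # per-atom precomputation: coords, posterior, per-mode deviations
  prep <- lapply(seq_along(sel), function(ii) {
    X <- atom_coords(traj, sel[ii])
    m <- modes[[ii]]
    P <- mode_posterior(m, X)
    devs <- lapply(seq_len(m$K), function(k) sweep(X, 2, m$centers[k, ]))
    sqs <- lapply(devs, function(D) rowSums(D * D))
    Xc <- sweep(X, 2, colMeans(X))
    list(m = m, P = P, devs = devs, sqs = sqs, Xc = Xc,
         var = mean(rowSums(Xc * Xc)))
  })

  mmat <- matrix(NA_real_, nres, nres)
  dmat <- matrix(NA_real_, nres, nres)
  minmat <- matrix(NA_real_, nres, nres)
  prov <- list()
  cand <- if (keep_candidates) list() else NULL

  na_sel <- length(sel)
  for (ii in seq_len(na_sel)) {
    pi_ <- prep[[ii]]
    for (jj in ii:na_sel) {
      a <- res_of[ii]; b <- res_of[jj]
      if (a == b) next  # self-residue cells handled below
      pj_ <- prep[[jj]]

      # conventional DCC (max over atom pairs)
      if (pi_$var > 1e-24 && pj_$var > 1e-24) {
        dval <- mean(rowSums(pi_$Xc * pj_$Xc)) / sqrt(pi_$var * pj_$var)
        if (is.na(dmat[a, b]) || dval > dmat[a, b]) {
          dmat[a, b] <- dmat[b, a] <- dval
        }
      }

      key <- paste0(min(a, b), "_", max(a, b))
      for (k in seq_len(pi_$m$K)) {
        for (l in seq_len(pj_$m$K)) {
          w <- pi_$P[, k] * pj_$P[, l]
          mw <- mean(w)
          if (mw <= weight_floor) next
          d1 <- mean(w * pi_$sqs[[k]])
          d2 <- mean(w * pj_$sqs[[l]])
          if (d1 < 1e-24 || d2 < 1e-24) next
          val <- mean(w * rowSums(pi_$devs[[k]] * pj_$devs[[l]])) / sqrt(d1 * d2)
          cdist <- sqrt(sum((pi_$m$centers[k, ] - pj_$m$centers[l, ])^2))
          if (keep_candidates) {
            cand[[key]] <- rbind(cand[[key]],
              data.frame(a = min(a, b), b = max(a, b), atom_i = sel[ii],
                         atom_j = sel[jj], k = k, l = l, mdcc = val,
                         mean_weight = mw, center_distance = cdist))
          }
          cur <- prov[[key]]
          better <- is.null(cur) || val > cur$mdcc ||
            (val == cur$mdcc && (mw > cur$mean_weight ||
              (mw == cur$mean_weight && cdist < cur$center_distance)))
          if (better) {
            prov[[key]] <- data.frame(a = min(a, b), b = max(a, b),
                                      atom_i = sel[ii], atom_j = sel[jj],
                                      k = k, l = l, mdcc = val,
                                      mean_weight = mw,
                                      center_distance = cdist)
            mmat[a, b] <- mmat[b, a] <- val
          }
          if (is.na(minmat[a, b]) || val < minmat[a, b]) {
            minmat[a, b] <- minmat[b, a] <- val
          }
        }
      }
    }
  }

  # self-pairs: representative correlation is 1 wherever the residue moves
  moving <- rep(FALSE, nres)
  for (ii in seq_len(na_sel)) {
    if (prep[[ii]]$var > 1e-24) moving[res_of[ii]] <- TRUE
  }
  diag(mmat) <- ifelse(moving, 1, NA_real_)
  diag(dmat) <- ifelse(moving, 1, NA_real_)

  provenance <- if (length(prov) > 0) do.call(rbind, prov) else
    data.frame(a = integer(), b = integer(), atom_i = integer(),
               atom_j = integer(), k = integer(), l = integer(),
               mdcc = numeric(), mean_weight = numeric(),
               center_distance = numeric())
  rownames(provenance) <- NULL
  candidates <- if (keep_candidates && length(cand) > 0) {
    out <- do.call(rbind, cand); rownames(out) <- NULL; out
  } else NULL

  dimnames(mmat) <- dimnames(dmat) <- dimnames(minmat) <-
    list(rtab$key, rtab$key)
  structure(list(residues = rtab, mdcc = mmat, dcc = dmat,
                 min_mdcc = minmat, provenance = provenance,
                 candidates = candidates,
                 params = list(weight_floor = weight_floor,
                               selection = selection)),
            class = "mdcc_matrix")
}

#' Multi-modal dynamic cross-correlation analysis
#'
#' One-stop analysis: fits Gaussian-mixture modes to every selected atom
#' ([fit_modes()]), computes all-against-all mode-pair correlations, and
#' summarises them into a residue-level matrix ([residue_matrix()]).
#' The trajectory must be superposed beforehand (see [superpose()]).
#'
#' @param traj a superposed `"trajectory"`.
#' @param selection atoms to analyse (default `"heavy"`).
#' @param max_modes largest mixture size per atom (default 6).
#' @param seed integer seed controlling the (otherwise deterministic) fits.
#' @param weight_floor rare-pair filter (default 0.1).
#' @param restarts EM restarts per candidate K.
#' @param keep_candidates see [residue_matrix()].
#' @param modes optional precomputed list of `"atom_modes"` (selection order);
#'   when supplied, fitting is skipped.
#' @return `"mdcc_matrix"` with elements `residues` (residue table), `mdcc`
#'   and `dcc` (symmetric residue x residue matrices), `min_mdcc`
#'   (diagnostic minimum), `provenance` (maximizing atom/mode pair per
#'   residue pair), `modes`, and `params`.
#' @examples
#' \dontrun{
#' sys <- generate_two_state_pair(n_frames = 5000, seed = 1)
#' m <- mdcc(sys$trajectory, seed = 1)
#' print(m)
#' net <- build_network(m)
#' }
#' @export
mdcc <- function(traj, selection = "heavy", max_modes = 6, seed = 1,
                 weight_floor = 0.1, restarts = 5, keep_candidates = TRUE,
                 modes = NULL) {
  sel <- which(select_atoms(traj$topology, selection))
  if (length(sel) == 0L) {
    mdccr_stop("empty analysis selection", "mdccr_selection_error")
  }
  if (is.null(modes)) {
    modes <- lapply(seq_along(sel), function(ii) {
      fit_modes(traj, sel[ii], max_modes = max_modes,
                seed = seed + 31L * ii, restarts = restarts)
    })
  }
  out <- residue_matrix(traj, modes, selection = selection,
                        weight_floor = weight_floor,
                        keep_candidates = keep_candidates)
  out$modes <- modes
  out$params$max_modes <- max_modes
  out$params$seed <- seed
  out
}

#' Assemble a residue correlation matrix from plain matrices
#'
#' Builds an `"mdcc_matrix"` directly from residue-level values — useful for
#' constructing small test systems by hand or for importing matrices computed
#' elsewhere.  The provenance entries carry the supplied center distances;
#' atom/mode ids are unknown (`NA`/1).
#'
#' @param mdcc symmetric residue-by-residue representative mDCC matrix
#'   (dimnames, if present, become residue keys).
#' @param dcc symmetric companion conventional-DCC matrix (same shape).
#' @param center_distance symmetric matrix of mode-center distances, Angstrom.
#' @param molecule molecule label per residue (default one molecule `"A"`).
#' @param mean_weight time-averaged joint mode probability per cell
#'   (default 1).
#' @return An `"mdcc_matrix"`.
#' @export
as_mdcc_matrix <- function(mdcc, dcc, center_distance, molecule = NULL,
                           mean_weight = NULL) {
  n <- nrow(mdcc)
  stopifnot(ncol(mdcc) == n, all(dim(dcc) == n), all(dim(center_distance) == n))
  if (max(abs(mdcc - t(mdcc)), na.rm = TRUE) > 1e-12 ||
      max(abs(dcc - t(dcc)), na.rm = TRUE) > 1e-12) {
    mdccr_stop("mdcc/dcc matrices must be symmetric", "mdccr_validation_error")
  }
  keys <- rownames(mdcc)
  if (is.null(keys)) keys <- paste0("A:", seq_len(n), ":RES")
  if (is.null(molecule)) molecule <- rep("A", n)
  rtab <- data.frame(residue = seq_len(n), key = keys,
                     chain = molecule, resno = seq_len(n), insert = "",
                     resname = "RES", molecule = molecule,
                     stringsAsFactors = FALSE)
  if (is.null(mean_weight)) mean_weight <- matrix(1, n, n)
  ut <- which(upper.tri(mdcc) & !is.na(mdcc), arr.ind = TRUE)
  provenance <- data.frame(a = ut[, 1], b = ut[, 2],
                           atom_i = NA_integer_, atom_j = NA_integer_,
                           k = 1L, l = 1L, mdcc = mdcc[ut],
                           mean_weight = mean_weight[ut],
                           center_distance = center_distance[ut])
  dimnames(mdcc) <- dimnames(dcc) <- list(keys, keys)
  structure(list(residues = rtab, mdcc = mdcc, dcc = dcc,
                 min_mdcc = mdcc, provenance = provenance,
                 candidates = provenance,
                 params = list(weight_floor = NA_real_, selection = NA)),
            class = "mdcc_matrix")
}

#' @export
print.mdcc_matrix <- function(x, ...) {
  n <- nrow(x$mdcc)
  off <- x$mdcc[upper.tri(x$mdcc)]
  cat(sprintf("mDCC residue correlation matrix: %d residues\n", n))
  if (any(!is.na(off))) {
    cat(sprintf("  off-diagonal mDCC: min %.3f, median %.3f, max %.3f (%d defined)\n",
                min(off, na.rm = TRUE), stats::median(off, na.rm = TRUE),
                max(off, na.rm = TRUE), sum(!is.na(off))))
  }
  cat(sprintf("  rare-pair weight floor: %g\n", x$params$weight_floor))
  invisible(x)
}

#' @export
summary.mdcc_matrix <- function(object, mdcc_threshold = 0.5, ...) {
  off <- object$mdcc[upper.tri(object$mdcc)]
  doff <- object$dcc[upper.tri(object$dcc)]
  structure(list(n_residues = nrow(object$mdcc),
                 n_defined = sum(!is.na(off)),
                 n_high_mdcc = sum(off >= mdcc_threshold, na.rm = TRUE),
                 n_transient = sum(off >= mdcc_threshold &
                                   doff < mdcc_threshold, na.rm = TRUE),
                 mdcc_threshold = mdcc_threshold),
            class = "summary.mdcc_matrix")
}

#' @export
print.summary.mdcc_matrix <- function(x, ...) {
  cat(sprintf(paste0("mDCC summary: %d residues, %d residue pairs defined\n",
                     "  pairs with mDCC >= %.2f: %d (of which %d transient:",
                     " DCC < %.2f)\n"),
              x$n_residues, x$n_defined, x$mdcc_threshold, x$n_high_mdcc,
              x$n_transient, x$mdcc_threshold))
  invisible(x)
}

#' @export
as.matrix.mdcc_matrix <- function(x, which = c("mdcc", "dcc", "min_mdcc"),
                                  ...) {
  x[[match.arg(which)]]
}

#' @export
plot.mdcc_matrix <- function(x, which = c("mdcc", "dcc"), ...) {
  M <- x[[match.arg(which)]]
  n <- nrow(M)
  pal <- hcl.colors(101, "Blue-Red 3")
  image(seq_len(n), seq_len(n), t(M[n:1, , drop = FALSE]),
        zlim = c(-1, 1), col = pal, axes = FALSE,
        xlab = "residue", ylab = "residue", ...)
  axis(1, at = seq_len(n), labels = colnames(M), las = 2, cex.axis = 0.6)
  axis(2, at = seq_len(n), labels = rev(rownames(M)), las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write the residue matrix and provenance to disk
#'
#' @param x an `"mdcc_matrix"`.
#' @param matrix_tsv path for the residue-by-residue mDCC matrix (TSV with
#'   residue labels).
#' @param dcc_tsv optional path for the companion DCC matrix.
#' @param provenance_json optional path for per-cell provenance
#'   (JSON lines, one record per residue pair).
#' @return Invisibly, `x`.
#' @export
write_mdcc <- function(x, matrix_tsv, dcc_tsv = NULL, provenance_json = NULL) {
  write.table(x$mdcc, matrix_tsv, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(dcc_tsv)) {
    write.table(x$dcc, dcc_tsv, sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(provenance_json)) {
    con <- file(provenance_json, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(x$provenance))) {
      writeLines(jsonlite::toJSON(as.list(x$provenance[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(x)
}
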