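# Gaussian-mixture "modes" of per-atom coordinate distributions.
#
# Each atom's sampled 3-D coordinates are modelled as a mixture of full-
# covariance Gaussians.  Fitting is expectation-maximization with seeded
# k-means initialisation and multiple restarts; the number of components K
# is chosen by BIC over 1..max_modes.  Components are regularized by a small
# diagonal floor so frozen atoms do not produce singular fits.

LOG2PI <- log(2 * pi)

# per-component log pi_k + log N(x | mu_k, Sigma_k); X is n x 3
gmm_log_weighted_dens <- function(X, weights, centers, covs) {
  n <- nrow(X)
  K <- length(weights)
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    R <- chol(covs[[k]])
    logdet <- 2 * sum(log(diag(R)))
    Y <- sweep(X, 2, centers[k, ]) %*% backsolve(R, diag(3))
    maha <- rowSums(Y * Y)
    out[, k] <- log(weights[k]) - 0.5 * (3 * LOG2PI + logdet + maha)
  }
  out
}

row_log_sum_exp <- function(M) {
  mx <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) mx <- pmax(mx, M[, k])
  mx + log(rowSums(exp(M - mx)))
}

# one EM run from a hard initial assignment (or soft responsibilities);
# returns NULL on degeneracy
gmm_em_run <- function(X, assign0, K, reg, maxit, tol) {
  n <- nrow(X)
  if (is.matrix(assign0)) {
    resp <- assign0
  } else {
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), assign0)] <- 1
  }
  ll_trace <- numeric(0)
  ll <- -Inf
  weights <- NULL; centers <- NULL; covs <- NULL
  for (it in seq_len(maxit)) {
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    weights <- nk / n
    centers <- crossprod(resp, X) / nk
    covs <- lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2, centers[k, ])
      S <- crossprod(Xc, Xc * resp[, k]) / nk[k] + diag(reg, 3)
      (S + t(S)) / 2
    })
    lw <- tryCatch(gmm_log_weighted_dens(X, weights, centers, covs),
                   error = function(e) NULL)
    if (is.null(lw)) return(NULL)
    lse <- row_log_sum_exp(lw)
    ll_new <- sum(lse)
    ll_trace <- c(ll_trace, ll_new)
    resp <- exp(lw - lse)
    if (is.finite(ll) && abs(ll_new - ll) < tol * (1 + abs(ll_new))) {
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(weights = weights, centers = centers, covs = covs,
       loglik = ll, trace = ll_trace)
}

# multi-restart fit for one K: each seeded k-means start gets a short EM
# run, then the best short run is polished to full convergence
gmm_fit_k <- function(X, K, seed, restarts, reg, maxit, tol) {
  n <- nrow(X)
  ux <- unique(X)
  if (nrow(ux) < K) return(NULL)
  if (K == 1L) return(gmm_em_run(X, rep(1L, n), 1L, reg, maxit, tol))
  best <- NULL
  for (r in seq_len(restarts)) {
    assign0 <- with_seed(seed + 7919L * r, {
      ctr <- ux[sample.int(nrow(ux), K), , drop = FALSE]
      km <- suppressWarnings(tryCatch(
        kmeans(X, centers = ctr, iter.max = 10),
        error = function(e) NULL))
      if (is.null(km)) {
        d2 <- vapply(seq_len(K), function(k)
          rowSums(sweep(X, 2, ctr[k, ])^2), numeric(nrow(X)))
        max.col(-d2)
      } else km$cluster
    })
    if (length(unique(assign0)) < K) next
    fit <- gmm_em_run(X, assign0, K, reg, maxit = 25L, tol = 1e-4)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best)) return(NULL)
  # polish: resume EM from the best short run's responsibilities
  lw <- gmm_log_weighted_dens(X, best$weights, best$centers, best$covs)
  resp <- exp(lw - row_log_sum_exp(lw))
  fit <- gmm_em_run(X, resp, K, reg, maxit, tol)
  if (is.null(fit)) return(best)
  fit$trace <- c(best$trace, fit$trace)
  fit
}

# sort modes by weight desc, ties by lexicographic center
mode_order <- function(weights, centers) {
  order(-weights, centers[, 1], centers[, 2], centers[, 3])
}

#' Fit Gaussian-mixture modes to one atom's coordinate distribution
#'
#' Decomposes the spatial distribution of an atom over the trajectory into
#' Gaussian "modes" (conformational substates, e.g. rotamer basins).
#' Candidate component counts K = 1..`max_modes` are each fitted by EM with
#' `restarts` seeded k-means initialisations, and K is chosen by BIC.
#' Components whose converged weight falls below `prune` are removed and the
#' remaining weights renormalised.  Modes are reported sorted by
#' non-increasing weight (ties: lexicographic center).
#'
#' @param x a `"trajectory"` (then `atom` names the atom) or an `n x 3`
#'   coordinate matrix.
#' @param atom atom index when `x` is a trajectory.
#' @param max_modes largest K considered (default 6).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param restarts EM restarts per K (default 5).
#' @param reg diagonal covariance floor, A^2 (default 1e-6).
#' @param prune weight floor below which converged components are dropped.
#' @param maxit,tol EM iteration cap and relative log-likelihood tolerance.
#' @return `"atom_modes"`: `K`, `weights`, `centers` (K x 3), `covariances`
#'   (list of 3 x 3), `loglik`, `bic` (per candidate K; NA where a candidate
#'   was infeasible), `seed`, `n_frames`, `atom`, and the selected fit's
#'   log-likelihood `trace`.
#' @export
fit_modes <- function(x, atom = NULL, max_modes = 6, seed = 1,
                      restarts = 5, reg = 1e-6, prune = 0.01,
                      maxit = 200, tol = 1e-6) {
  X <- if (inherits(x, "trajectory")) {
    if (is.null(atom)) mdccr_stop("atom index required", "mdccr_lookup_error")
    atom_coords(x, atom)
  } else as.matrix(x)
  if (ncol(X) != 3L) mdccr_stop("coordinates must be n x 3", "mdccr_shape_error")
  n <- nrow(X)
  if (n < 50L) warning(sprintf("only %d frames; mode fit may be unstable", n))

  label <- if (inherits(x, "trajectory")) {
    a <- x$topology$atoms
    paste0(residue_keys(a)[atom], ":", a$name[atom])
  } else if (!is.null(atom)) as.character(atom) else "coords"

  # degenerate: (numerically) frozen atom -> single mode at that point
  if (max(abs(sweep(X, 2, X[1, ]))) < 1e-12) {
    return(structure(list(atom = label, K = 1L, weights = 1,
                          centers = matrix(X[1, ], 1, 3),
                          covariances = list(diag(reg, 3)),
                          loglik = NA_real_, bic = NA_real_, seed = seed,
                          n_frames = n, trace = numeric(0)),
                     class = "atom_modes"))
  }

  bics <- rep(NA_real_, max_modes)
  fits <- vector("list", max_modes)
  for (K in seq_len(max_modes)) {
    fit <- gmm_fit_k(X, K, seed, restarts, reg, maxit, tol)
    if (is.null(fit)) next
    npar <- (K - 1) + 3 * K + 6 * K
    bics[K] <- fit$loglik - 0.5 * npar * log(n)  # larger is better
    fits[[K]] <- fit
  }
  if (all(is.na(bics))) {
    mdccr_stop("mixture fitting failed for every candidate K", "mdccr_fit_error")
  }
  Kbest <- which.max(bics)
  fit <- fits[[Kbest]]

  keep <- fit$weights >= prune
  if (!any(keep)) keep <- which.max(fit$weights)
  w <- fit$weights[keep] / sum(fit$weights[keep])
  ctr <- fit$centers[keep, , drop = FALSE]
  cv <- fit$covs[keep]
  o <- mode_order(w, ctr)
  structure(list(atom = label, K = length(w), weights = w[o],
                 centers = ctr[o, , drop = FALSE], covariances = cv[o],
                 loglik = fit$loglik, bic = bics, seed = seed, n_frames = n,
                 trace = fit$trace),
            class = "atom_modes")
}

#' @export
print.atom_modes <- function(x, ...) {
  cat(sprintf("Atom modes [%s]: K = %d (n = %d frames)\n", x$atom, x$K,
              x$n_frames))
  for (k in seq_len(x$K)) {
    cat(sprintf("  mode %d: weight %.3f, center (%.2f, %.2f, %.2f) A\n",
                k, x$weights[k], x$centers[k, 1], x$centers[k, 2],
                x$centers[k, 3]))
  }
  invisible(x)
}

#' Per-frame mode-membership probabilities
#'
#' Standard mixture responsibilities: the probability that the atom belongs
#' to each of its modes at each frame, given its coordinates there.  Rows
#' sum to 1.
#'
#' @param modes an `"atom_modes"` fit.
#' @param x a `"trajectory"` plus `atom`, or an `n x 3` coordinate matrix
#'   (same coordinate frame the modes were fitted in).
#' @param atom atom index when `x` is a trajectory.
#' @return `n_frames x K` matrix of probabilities.
#' @export
mode_posterior <- function(modes, x, atom = NULL) {
  X <- if (inherits(x, "trajectory")) {
    if (is.null(atom)) mdccr_stop("atom index required", "mdccr_lookup_error")
    atom_coords(x, atom)
  } else as.matrix(x)
  if (modes$K == 1L) return(matrix(1, nrow(X), 1))
  lw <- gmm_log_weighted_dens(X, modes$weights, modes$centers,
                              modes$covariances)
  exp(lw - row_log_sum_exp(lw))
}

#' Distance between two mode centers
#'
#' @param modes_i,modes_j `"atom_modes"` objects.
#' @param k,l mode indices into `modes_i` and `modes_j`.
#' @return Euclidean distance in Angstrom.
#' @export
mode_center_distance <- function(modes_i, k, modes_j, l) {
  if (k < 1L || k > modes_i$K) {
    mdccr_stop(paste0("mode index out of range: k = ", k), "mdccr_lookup_error")
  }
  if (l < 1L || l > modes_j$K) {
    mdccr_stop(paste0("mode index out of range: l = ", l), "mdccr_lookup_error")
  }
  sqrt(sum((modes_i$centers[k, ] - modes_j$centers[l, ])^2))
}

#' Serialize mode fits to JSON
#'
#' @param modes a single `"atom_modes"` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_modes <- function(modes, path) {
  if (inherits(modes, "atom_modes")) modes <- list(modes)
  payload <- lapply(modes, function(m) {
    list(atom = m$atom, K = m$K, weights = m$weights,
         centers = m$centers, covariances = m$covariances,
         fit = list(seed = m$seed, n_frames = m$n_frames,
                    criterion = "BIC", bic = m$bic, loglik = m$loglik))
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read mode fits from JSON written by [write_modes()]
#'
#' @param path JSON file.
#' @return List of `"atom_modes"` objects.
#' @export
read_modes <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(p) {
    centers <- do.call(rbind, lapply(p$centers, function(r) unlist(r)))
    covs <- lapply(p$covariances, function(cv)
      do.call(rbind, lapply(cv, function(r) unlist(r))))
    structure(list(atom = p$atom, K = as.integer(p$K),
                   weights = unlist(p$weights),
                   centers = matrix(centers, ncol = 3),
                   covariances = covs,
                   loglik = null2na(p$fit$loglik), bic = unlist(p$fit$bic),
                   seed = p$fit$seed, n_frames = p$fit$n_frames,
                   trace = numeric(0)),
              class = "atom_modes")
  })
}

null2na <- function(x) if (is.null(x)) NA_real_ else x
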