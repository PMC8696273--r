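#' Split subjects into four groups for reproducibility analysis
#'
#' With two acquisition sites, subjects within each site are randomly halved,
#' giving four independent groups; with a single site (or no site labels)
#' subjects are randomly split into four groups directly.
#'
#' @param subject_ids Vector of subject identifiers.
#' @param site_labels Optional vector (same length) with at most two distinct
#'   values.
#' @param seed Integer seed.
#' @return List of four character vectors of subject ids (disjoint, covering
#'   all subjects).
#' @export
split_groups <- function(subject_ids, site_labels = NULL, seed = 1L) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  halve <- function(ids) {
    k <- floor(length(ids) / 2)
    first <- sample(ids, k)
    list(first, setdiff(ids, first))
  }
  groups <- with_seed(seed, {
    if (is.null(site_labels)) {
      parts <- halve(subject_ids)
      c(halve(parts[[1]]), halve(parts[[2]]))
    } else {
      stopifnot(length(site_labels) == n)
      sites <- unique(site_labels)
      if (length(sites) > 2) stop("at most two site labels supported")
      if (length(sites) == 1) {
        parts <- halve(subject_ids)
        c(halve(parts[[1]]), halve(parts[[2]]))
      } else {
        c(halve(subject_ids[site_labels == sites[1]]),
          halve(subject_ids[site_labels == sites[2]]))
      }
    }
  })
  if (any(lengths(groups) < 2)) {
    stop("too few subjects to split into four groups of at least 2")
  }
  names(groups) <- paste0("group", 1:4)
  groups
}

#' Semi-nonnegative CP decomposition of a coupling tensor
#'
#' Canonical polyadic decomposition by alternating least squares with a
#' nonnegativity constraint on selected modes (by default mode 3, the
#' individual/subject mode, whose loadings act as nonnegative mixture
#' weights). Unconstrained modes are updated by exact least squares;
#' constrained modes by hierarchical (column-wise) nonnegative least-squares
#' updates. Both updates are exact block minimizers, so the reconstruction
#' error is non-increasing across iterations. The best of `n_restarts`
#' random initializations (seeds derived from `seed`) is kept.
#'
#' @param tensor A `"coupling_tensor"` (see [build_coupling_tensor()]) or a
#'   plain 3-way numeric array (gene x connection x subject).
#' @param rank Number of components (default 10).
#' @param constraint_modes Integer vector of modes constrained to be
#'   nonnegative (default 3).
#' @param seed Integer seed for the restarts.
#' @param tol Convergence tolerance on the change in relative fit.
#' @param max_iter Maximum ALS iterations per restart.
#' @param n_restarts Number of random restarts (default 5).
#' @return An object of class `"cp_decomposition"`: list with `scales`
#'   (component scores, descending), `gene_weights`, `connection_weights`
#'   (unit-norm columns, one per component), `individual_weights`
#'   (nonnegative, unit-norm columns), `fit` (relative reconstruction
#'   error), `fit_trace` (per-iteration, best restart), `converged`,
#'   `n_iterations`, `rank`.
#' @export
cp_decompose_seminonneg <- function(tensor, rank = 10, constraint_modes = 3,
                                    seed = 1L, tol = 1e-8, max_iter = 500,
                                    n_restarts = 5) {
  X <- if (inherits(tensor, "coupling_tensor")) tensor$values else tensor
  if (length(dim(X)) != 3) stop("tensor must be a 3-way array")
  if (anyNA(X) || any(!is.finite(X))) stop("tensor contains NA or non-finite values")
  d <- dim(X)
  if (rank < 1 || rank > min(d)) {
    stop("rank must be between 1 and the smallest mode dimension (", min(d), ")")
  }
  normX <- sqrt(sum(X^2))
  if (normX == 0) stop("all-zero tensor cannot be decomposed")
  # precomputed unfoldings
  X1 <- X; dim(X1) <- c(d[1], d[2] * d[3])
  X2 <- aperm(X, c(2, 1, 3)); dim(X2) <- c(d[2], d[1] * d[3])
  X3 <- aperm(X, c(3, 1, 2)); dim(X3) <- c(d[3], d[1] * d[2])
  unf <- list(X1, X2, X3)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    res <- with_seed(seed + rs - 1L, {
      cp_als_run(unf, d, rank, constraint_modes, tol, max_iter, normX)
    })
    if (is.null(best) || res$fit < best$fit) best <- res
  }
  out <- cp_finalize(best, d, rank)
  if (!out$converged) {
    warning("CP decomposition did not converge within ", max_iter,
            " iterations (fit ", format(out$fit, digits = 4), ")")
  }
  if (all(out$scales <= .Machine$double.eps * normX)) {
    warning("all component scales are numerically zero (degenerate tensor)")
  }
  out
}

khatri_rao <- function(A, B) {
  # column-wise Kronecker product; rows ordered with B's index fastest
  vapply(seq_len(ncol(A)), function(r) kronecker(A[, r], B[, r]),
         numeric(nrow(A) * nrow(B)))
}

cp_als_run <- function(unf, d, rank, constraint_modes, tol, max_iter, normX) {
  Fs <- lapply(d, function(n) matrix(stats::rnorm(n * rank), n, rank))
  for (m in constraint_modes) Fs[[m]] <- abs(Fs[[m]])
  gram <- lapply(Fs, crossprod)
  fit_trace <- numeric(0)
  fit_old <- Inf
  converged <- FALSE
  it <- 0
  others <- list(c(3L, 2L), c(3L, 1L), c(2L, 1L))
  for (it in seq_len(max_iter)) {
    for (m in 1:3) {
      o <- others[[m]]
      Z <- khatri_rao(Fs[[o[1]]], Fs[[o[2]]])
      G <- gram[[o[1]]] * gram[[o[2]]]
      W <- unf[[m]] %*% Z
      if (m %in% constraint_modes) {
        Fm <- Fs[[m]]
        for (pass in 1:3) {
          for (r in seq_len(rank)) {
            if (G[r, r] <= .Machine$double.eps) next
            num <- W[, r] - Fm %*% G[, r] + Fm[, r] * G[r, r]
            Fm[, r] <- pmax(0, num / G[r, r])
          }
        }
        Fs[[m]] <- Fm
      } else {
        ridge <- diag(rank) * .Machine$double.eps * max(diag(G), 1)
        Fs[[m]] <- t(solve(G + ridge, t(W)))
      }
      gram[[m]] <- crossprod(Fs[[m]])
    }
    # relative reconstruction error without forming the reconstruction:
    # ||X - Xhat||^2 = ||X||^2 - 2 <X, Xhat> + ||Xhat||^2, with the inner
    # product available from the last mode's MTTKRP
    cross <- sum(W * Fs[[3]])
    normXhat2 <- sum(gram[[1]] * gram[[2]] * gram[[3]])
    err2 <- max(0, normX^2 - 2 * cross + normXhat2)
    fit <- sqrt(err2) / normX
    fit_trace <- c(fit_trace, fit)
    if (is.finite(fit_old) && abs(fit_old - fit) < tol) {
      converged <- TRUE
      break
    }
    fit_old <- fit
  }
  list(factors = Fs, fit = fit_trace[length(fit_trace)], fit_trace = fit_trace,
       converged = converged, n_iterations = it)
}

cp_finalize <- function(res, d, rank) {
  Fs <- res$factors
  nrm <- lapply(Fs, function(M) {
    n <- sqrt(colSums(M^2))
    n[n == 0] <- 1
    n
  })
  lambda <- nrm[[1]] * nrm[[2]] * nrm[[3]]
  Fs <- lapply(1:3, function(m) sweep(Fs[[m]], 2, nrm[[m]], `/`))
  # sign convention: gene and connection factors may carry sign; flip the
  # pair jointly so the largest-magnitude gene weight is positive
  for (r in seq_len(rank)) {
    if (Fs[[1]][which.max(abs(Fs[[1]][, r])), r] < 0) {
      Fs[[1]][, r] <- -Fs[[1]][, r]
      Fs[[2]][, r] <- -Fs[[2]][, r]
    }
  }
  ord <- order(lambda, decreasing = TRUE)
  structure(list(
    scales = lambda[ord],
    gene_weights = Fs[[1]][, ord, drop = FALSE],
    connection_weights = Fs[[2]][, ord, drop = FALSE],
    individual_weights = Fs[[3]][, ord, drop = FALSE],
    fit = res$fit,
    fit_trace = res$fit_trace,
    converged = res$converged,
    n_iterations = res$n_iterations,
    rank = rank
  ), class = "cp_decomposition")
}

#' @export
print.cp_decomposition <- function(x, ...) {
  cat("Semi-nonnegative CP decomposition, rank ", x$rank, "\n", sep = "")
  cat("  component scores: ", paste(format(x$scales, digits = 3),
                                    collapse = ", "), "\n", sep = "")
  cat("  relative reconstruction error: ", format(x$fit, digits = 4),
      if (x$converged) " (converged)" else " (not converged)", "\n", sep = "")
  invisible(x)
}

#' Leading component of a CP decomposition
#'
#' Returns the component with the largest score and the dominance ratio to
#' the runner-up; a tie (within `tol_ratio`) triggers a warning and the
#' first component in stable order is returned.
#'
#' @param result A `"cp_decomposition"`.
#' @param tol_ratio Relative tolerance for declaring a tie (default 1e-8).
#' @return List with `scale`, `gene_weights`, `connection_weights`,
#'   `individual_weights`, `dominance_ratio`.
#' @export
select_leading_component <- function(result, tol_ratio = 1e-8) {
  if (length(result$scales) == 0) stop("empty decomposition")
  s <- result$scales
  if (length(s) > 1 && s[2] > 0 && (s[1] - s[2]) <= tol_ratio * s[1]) {
    warning("leading component score tied with runner-up; taking the first")
  }
  list(
    scale = s[1],
    gene_weights = result$gene_weights[, 1],
    connection_weights = result$connection_weights[, 1],
    individual_weights = result$individual_weights[, 1],
    dominance_ratio = if (length(s) > 1 && s[2] > 0) s[1] / s[2] else Inf
  )
}

#' Mean + SD selection on absolute weight scores
#'
#' Selects items whose absolute weight exceeds mean(|w|) + SD(|w|) (sample
#' SD, strict inequality); the rule used for both gene and connection
#' weights.
#'
#' @param weights Numeric vector (may carry sign).
#' @return Integer indices of selected items (named if `weights` is named).
#' @export
weight_threshold_select <- function(weights) {
  if (length(weights) < 2) stop("need at least 2 items")
  a <- abs(weights)
  thr <- mean_plus_sd(a)
  if (stats::sd(a) == 0) {
    warning("constant weights: empty selection")
    return(integer(0))
  }
  sel <- which(a > thr)
  sel
}

# align signs of gene-weight vectors to a reference (CP sign indeterminacy)
align_sign <- function(ref, v) if (stats::cor(ref, v) < 0) -v else v

#' Cross-group consistency of leading components
#'
#' Correspondence is the mean over the six group pairs of the absolute
#' Pearson correlation between gene-weight vectors (sign-aligned);
#' the mismatch rate is the Jaccard distance
#' 1 - |intersection| / |union| of the per-group mean + SD gene selections.
#'
#' @param components List of four leading components (as returned by
#'   [select_leading_component()]) over the same gene universe.
#' @return List with `mismatch_rate`, `mean_correspondence`, and
#'   `selections` (per-group selected gene indices).
#' @export
cross_group_consistency <- function(components) {
  stopifnot(length(components) >= 2)
  W <- lapply(components, `[[`, "gene_weights")
  n <- unique(lengths(W))
  if (length(n) != 1) stop("gene-weight vectors differ in length")
  pairs <- utils::combn(length(W), 2)
  cors <- apply(pairs, 2, function(p) abs(stats::cor(W[[p[1]]], W[[p[2]]])))
  sels <- lapply(W, weight_threshold_select)
  uni <- Reduce(union, sels)
  inter <- Reduce(intersect, sels)
  mismatch <- if (length(uni) == 0) 0 else 1 - length(inter) / length(uni)
  list(mismatch_rate = mismatch, mean_correspondence = mean(cors),
       selections = sels)
}

#' Genes selected in all four groups
#'
#' The 100\% repeated-rate criterion: the intersection of the per-group
#' mean + SD gene selections.
#'
#' @param selections List of per-group selections (indices or names).
#' @return The intersection.
#' @export
repeated_gene_selection <- function(selections) {
  Reduce(intersect, selections)
}
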