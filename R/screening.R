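#' Per-gene correlation between one subject's connectivity and gene
#' co-expression contributions
#'
#' For each gene a, the Pearson correlation across connections between the
#' subject's FC vector and the gene's co-expression contribution
#' E_ia x E_ja, with a two-sided p-value from the t distribution on S - 2
#' degrees of freedom. Genes whose product vector has zero variance are
#' flagged degenerate (r = NA, p = 1) with a warning rather than an error:
#' near-constant genes occur in real expression matrices.
#'
#' @param expr Normalized region x gene expression matrix.
#' @param fc_subject Connection vector for one subject (any linear scale;
#'   Pearson correlation is scale-invariant).
#' @return data.frame with columns `gene`, `r`, `p`, `degenerate`.
#' @export
per_gene_correlation <- function(expr, fc_subject) {
  R <- nrow(expr)
  ci <- connection_index(R)
  S <- nrow(ci)
  if (length(fc_subject) != S) {
    stop("fc_subject has length ", length(fc_subject), ", expected ", S)
  }
  P <- expr[ci$i, , drop = FALSE] * expr[ci$j, , drop = FALSE] # S x genes
  pv <- sqrt(colMeans(P^2) - colMeans(P)^2)
  degenerate <- pv == 0
  r <- rep(NA_real_, ncol(P))
  if (any(!degenerate)) {
    r[!degenerate] <- as.vector(stats::cor(fc_subject,
                                           P[, !degenerate, drop = FALSE]))
  }
  if (any(degenerate)) {
    warning(sum(degenerate), " gene(s) with constant co-expression products",
            " recorded as non-significant")
  }
  p <- rep(1, ncol(P))
  ok <- !degenerate
  tstat <- r[ok] * sqrt((S - 2) / pmax(1 - r[ok]^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(abs(tstat), df = S - 2, lower.tail = FALSE)
  data.frame(gene = colnames(expr), r = r, p = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_genes Number of tests.
#' @return alpha / n_genes.
#' @export
bonferroni_threshold <- function(alpha, n_genes) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_genes < 1) stop("n_genes must be >= 1")
  alpha / n_genes
}

#' Prevalence filter for per-subject significance calls
#'
#' A gene enters the pool when it is significant in strictly more than
#' `threshold` of subjects ("more than 80\%" read as a strict inequality).
#'
#' @param significance Subject x gene logical matrix.
#' @param threshold Prevalence fraction in (0, 1); default 0.8.
#' @return Character vector of selected gene identifiers (column indices if
#'   the matrix has no column names).
#' @export
prevalence_filter <- function(significance, threshold = 0.8) {
  if (nrow(significance) == 0) stop("no subjects in significance matrix")
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  prev <- colMeans(significance)
  sel <- prev > threshold
  if (is.null(colnames(significance))) which(sel) else colnames(significance)[sel]
}

#' Individual-level screening of connectivity-related genes
#'
#' Runs [per_gene_correlation()] for every subject, applies the
#' Bonferroni-corrected per-gene threshold `alpha / n_genes` within each
#' subject, and retains genes significant in more than `prevalence` of
#' subjects.
#'
#' @param expr Normalized region x gene expression matrix.
#' @param conn Subject x connection matrix (raw or normalized; screening is
#'   invariant to per-subject linear rescaling).
#' @param alpha Family-wise error rate per subject (default 0.05).
#' @param prevalence Prevalence threshold (default 0.8).
#' @return An object of class `"screening_result"`: list with `r` and
#'   `significant` (subject x gene matrices), `prevalence` (per-gene
#'   fraction), `pool` (selected gene ids), `p_threshold`.
#' @export
screen_genes <- function(expr, conn, alpha = 0.05, prevalence = 0.8) {
  R <- nrow(expr)
  ci <- connection_index(R)
  if (ncol(conn) != nrow(ci)) {
    stop("connectivity/expression dimension mismatch")
  }
  p_thr <- bonferroni_threshold(alpha, ncol(expr))
  n_sub <- nrow(conn)
  rmat <- matrix(NA_real_, n_sub, ncol(expr),
                 dimnames = list(rownames(conn), colnames(expr)))
  sig <- matrix(FALSE, n_sub, ncol(expr),
                dimnames = dimnames(rmat))
  for (k in seq_len(n_sub)) {
    tab <- per_gene_correlation(expr, conn[k, ])
    rmat[k, ] <- tab$r
    sig[k, ] <- !tab$degenerate & tab$p < p_thr
  }
  prev <- colMeans(sig)
  pool <- prevalence_filter(sig, prevalence)
  structure(list(
    r = rmat, significant = sig, prevalence = prev, pool = pool,
    p_threshold = p_thr, alpha = alpha, prevalence_threshold = prevalence
  ), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Individual-level gene screening\n")
  cat("  subjects: ", nrow(x$significant), ", genes: ", ncol(x$significant),
      "\n", sep = "")
  cat("  per-subject Bonferroni threshold: P < ",
      format(x$p_threshold, digits = 3), "\n", sep = "")
  cat("  pool (> ", 100 * x$prevalence_threshold, "% of subjects): ",
      length(x$pool), " genes\n", sep = "")
  invisible(x)
}
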