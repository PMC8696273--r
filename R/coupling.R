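#' Normalize a region x gene expression matrix
#'
#' Produces the normalized expression values E_ia used by all coupling
#' statistics. Two conventions are supported:
#'
#' * `method = "pearson"` (default): gene columns are z-scored across regions
#'   and region rows are standardized across genes, alternating until both
#'   constraints hold to within `tol`. Under this normalization the mean
#'   product (1/N) sum_a E_ia E_ja equals the Pearson correlation between the
#'   two regions' expression profiles, so the CGE statistic is both a mean of
#'   per-gene co-expression contributions and a correlation coefficient.
#' * `method = "zscore"`: the literal convention -- each gene column z-scored
#'   across regions (population SD) and nothing else.
#'
#' All z-scoring uses the population variance (divisor R), so that means of
#' products equal correlation coefficients exactly.
#'
#' @param raw Numeric region x gene matrix. Row names are region identifiers,
#'   column names gene identifiers (defaults are generated if absent).
#' @param method `"pearson"` or `"zscore"`; see above.
#' @param tol Convergence tolerance for the alternating standardization.
#' @param max_iter Maximum alternating sweeps.
#' @return A numeric matrix of class `"expression_matrix"` with attribute
#'   `method`.
#' @export
normalize_expression <- function(raw, method = c("pearson", "zscore"),
                                 tol = 1e-12, max_iter = 200) {
  method <- match.arg(method)
  raw <- as.matrix(raw)
  if (nrow(raw) < 3) stop("need at least 3 regions")
  if (anyNA(raw)) stop("expression matrix contains missing values")
  if (is.null(colnames(raw))) colnames(raw) <- paste0("gene", seq_len(ncol(raw)))
  if (is.null(rownames(raw))) rownames(raw) <- paste0("region", seq_len(nrow(raw)))
  csd <- sqrt(colMeans(raw^2) - colMeans(raw)^2)
  if (any(csd == 0)) {
    stop("constant expression column(s): ",
         paste(colnames(raw)[csd == 0], collapse = ", "))
  }
  E <- scale_cols_pop(raw)
  if (method == "pearson") {
    if (ncol(raw) < 2) stop("method 'pearson' needs at least 2 genes")
    for (it in seq_len(max_iter)) {
      E <- t(scale_cols_pop(t(E)))  # standardize rows across genes
      E <- scale_cols_pop(E)        # restore column z-scores
      rm <- rowMeans(E)
      rs <- rowMeans(E^2) - rm^2
      if (max(abs(rm)) < tol && max(abs(rs - 1)) < tol) break
    }
  }
  structure(E, class = c("expression_matrix", class(E)), method = method)
}

# population z-score of each column; input must have no constant columns
scale_cols_pop <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(x^2) - m^2)
  if (any(s == 0)) stop("constant column encountered during normalization")
  t((t(x) - m) / s)
}

#' Correlated gene expression (CGE) between two regions
#'
#' CGE_ij = (1/N) sum_a E_ia E_ja, the mean per-gene co-expression
#' contribution between regions i and j. With the `"pearson"` normalization
#' of [normalize_expression()] this equals the Pearson correlation of the two
#' regions' expression profiles across genes.
#'
#' @param expr Normalized expression matrix (see [normalize_expression()]).
#' @param i,j Region indices (i != j).
#' @return A single CGE value.
#' @export
compute_cge <- function(expr, i, j) {
  if (i == j) stop("CGE is undefined for a self-connection (i == j)")
  mean(expr[i, ] * expr[j, ])
}

#' CGE for every connection
#'
#' @param expr Normalized expression matrix.
#' @return Numeric vector of raw CGE values over all R(R-1)/2 connections in
#'   canonical order.
#' @export
cge_vector <- function(expr) {
  ci <- connection_index(nrow(expr))
  rowMeans(expr[ci$i, , drop = FALSE] * expr[ci$j, , drop = FALSE])
}

#' Normalize per-subject functional connectivity
#'
#' Per subject: an optional Fisher r-to-z transform (for raw correlation
#' input) followed by a z-score across the S connections using the population
#' SD, so that the mean product of two normalized connection vectors is their
#' Pearson correlation.
#'
#' @param raw Subject x connection numeric matrix.
#' @param fisher If `TRUE`, apply atanh() first; requires all |r| < 1. Set to
#'   `FALSE` for input already on an unbounded (e.g. z) scale.
#' @return Subject x connection matrix of class `"connectivity_set"`.
#' @export
normalize_connectivity <- function(raw, fisher = TRUE) {
  raw <- as.matrix(raw)
  if (ncol(raw) < 3) stop("need at least 3 connections per subject")
  if (anyNA(raw)) stop("connectivity matrix contains missing values")
  if (fisher) {
    if (any(abs(raw) >= 1)) {
      stop("Fisher transform requires |r| < 1 for all entries; ",
           "use fisher = FALSE for already-transformed input")
    }
    raw <- atanh(raw)
  }
  out <- t(apply(raw, 1, zscore_pop, what = "connectivity row"))
  dimnames(out) <- dimnames(raw)
  structure(out, class = c("connectivity_set", class(out)), fisher = fisher)
}

#' Global connectivity-expression coupling (CEC) of one subject
#'
#' CEC = (1/S) sum_s FC_s * CGE_s over connections. When both inputs are
#' z-scored across connections (population SD) this is the Pearson
#' correlation between the subject's connectivity profile and the CGE
#' profile.
#'
#' @param fc Normalized per-subject connection vector.
#' @param cge Normalized (z-scored) CGE connection vector.
#' @return A single coupling value.
#' @export
compute_global_cec <- function(fc, cge) {
  if (length(fc) != length(cge)) {
    stop("fc and cge must have the same length (", length(fc), " vs ",
         length(cge), ")")
  }
  mean(fc * cge)
}

#' Per-gene contribution to the coupling at one connection
#'
#' C_sa = (FC_s x CGE_s) x (E_ia x E_ja): the connection-level coupling term
#' times gene a's co-expression contribution at that connection. Vectorized
#' over its arguments.
#'
#' @param fc_s Normalized connectivity at connection s.
#' @param cge_s Normalized CGE at connection s.
#' @param e_ia,e_ja Normalized expression of gene a in the two end regions.
#' @return C_sa value(s).
#' @export
compute_csa <- function(fc_s, cge_s, e_ia, e_ja) {
  (fc_s * cge_s) * (e_ia * e_ja)
}

#' Build the gene x connection x subject coupling tensor
#'
#' Assembles C_sa for every gene, connection and subject, together with the
#' population-averaged gene x connection matrix (mean over subjects) and the
#' population- and connection-averaged per-gene vector. The per-connection
#' CGE is z-scored across connections (population SD) before entering the
#' coupling term; the raw CGE is retained for the mean-over-genes identity
#' (1/N) sum_a C_sa = (FC_s CGE_s^norm) CGE_s^raw.
#'
#' @param expr Normalized region x gene expression matrix.
#' @param conn Normalized subject x connection matrix
#'   ([normalize_connectivity()]); its column count must equal
#'   R(R-1)/2 for the region count of `expr`.
#' @param genes Optional gene subset (names or indices) to restrict the
#'   tensor to, e.g. a screened gene pool. The restricted set is the gene
#'   universe of the tensor: CGE and all derived quantities are computed
#'   over these genes only.
#' @return An object of class `"coupling_tensor"`: a list with `values`
#'   (gene x connection x subject array), `avg_csa` (gene x connection),
#'   `gene_means` (per gene), `cge_raw`, `cge_norm`, `gene_ids`,
#'   `n_regions`.
#' @export
build_coupling_tensor <- function(expr, conn, genes = NULL) {
  R <- nrow(expr)
  S <- n_connections(R)
  if (ncol(conn) != S) {
    stop("connectivity has ", ncol(conn), " connections but expression ",
         "implies R(R-1)/2 = ", S, " for ", R, " regions")
  }
  if (!is.null(genes)) expr <- expr[, genes, drop = FALSE]
  cge_raw <- cge_vector(expr)
  cge_norm <- zscore_pop(cge_raw, what = "CGE vector")
  ci <- connection_index(R)
  P <- t(expr[ci$i, , drop = FALSE] * expr[ci$j, , drop = FALSE]) # gene x S
  n_sub <- nrow(conn)
  vals <- array(0, dim = c(nrow(P), S, n_sub),
                dimnames = list(rownames(P), NULL, rownames(conn)))
  for (k in seq_len(n_sub)) {
    vals[, , k] <- P * rep(conn[k, ] * cge_norm, each = nrow(P))
  }
  avg <- rowMeans(vals, dims = 2)
  structure(list(
    values = vals,
    avg_csa = avg,
    gene_means = rowMeans(avg),
    cge_raw = cge_raw,
    cge_norm = cge_norm,
    gene_ids = rownames(P),
    n_regions = R
  ), class = "coupling_tensor")
}

#' @export
print.coupling_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat("Coupling tensor (C_sa): ", d[1], " genes x ", d[2], " connections x ",
      d[3], " subjects\n", sep = "")
  invisible(x)
}

#' Population-averaged per-connection coupling (CEC_s)
#'
#' Mean over subjects of FC_s x CGE_s at each connection; the connection-level
#' coupling profile used to select gene-related connections.
#'
#' @param conn Normalized subject x connection matrix.
#' @param cge_norm CGE vector z-scored across connections.
#' @return Per-connection vector of population-averaged CEC values.
#' @export
connection_cec <- function(conn, cge_norm) {
  if (ncol(conn) != length(cge_norm)) stop("dimension mismatch")
  colMeans(conn) * cge_norm
}
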