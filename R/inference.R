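#' Permutation null for population- and connection-averaged gene
#' contributions
#'
#' Each permutation shuffles all entries of the population-averaged C_sa
#' matrix jointly (flatten, permute, reshape -- destroying both gene and
#' connection structure; `mode = "column"` instead permutes within each
#' connection, preserving per-connection marginals) and recomputes every
#' gene's connection-averaged mean. A gene is significant when its observed
#' mean exceeds all permutation-derived means for that gene (one-sided,
#' P < 1 / n_perm).
#'
#' @param avg_csa Gene x connection matrix of population-averaged C_sa.
#' @param n_perm Number of permutations (default 1000; fewer than 1000
#'   triggers a warning that P < 0.001 is unattainable).
#' @param seed Integer seed.
#' @param mode `"full"` (default) or `"column"`.
#' @return An object of class `"permutation_result"`: list with `observed`
#'   (per-gene means), `null_max`, `n_exceeded`, `p` (empirical, (k+1)/(n+1)
#'   convention), `significant` (observed greater than every null value),
#'   `n_perm`.
#' @export
permutation_null_gene_means <- function(avg_csa, n_perm = 1000, seed = 1L,
                                        mode = c("full", "column")) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm < 1000) {
    warning("fewer than 1000 permutations: the P < 0.001 criterion ",
            "is unattainable")
  }
  avg_csa <- as.matrix(avg_csa)
  G <- nrow(avg_csa)
  v <- as.vector(avg_csa)
  observed <- rowMeans(avg_csa)
  n_exceeded <- integer(G)
  null_max <- rep(-Inf, G)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      null_means <- rowMeans(matrix(
        if (mode == "full") sample(v)
        else as.vector(apply(avg_csa, 2, sample)),
        nrow = G))
      n_exceeded <- n_exceeded + (null_means >= observed)
      null_max <- pmax(null_max, null_means)
    }
  })
  p <- (n_exceeded + 1) / (n_perm + 1)
  structure(list(
    observed = observed, null_max = null_max, n_exceeded = n_exceeded,
    p = p, significant = n_exceeded == 0, n_perm = n_perm, mode = mode,
    gene_ids = rownames(avg_csa)
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test on per-gene mean contributions (",
      x$n_perm, " permutations, ", x$mode, " shuffle)\n", sep = "")
  cat("  significant genes: ", sum(x$significant), " / ",
      length(x$observed), "\n", sep = "")
  invisible(x)
}

#' Intersection of tensor- and permutation-selected genes
#'
#' Genes identified by both routes are the high- and reliable-association
#' set.
#'
#' @param tensor_genes,permutation_genes Gene identifier vectors over the
#'   same universe.
#' @return Their intersection.
#' @export
reliable_gene_intersection <- function(tensor_genes, permutation_genes) {
  intersect(tensor_genes, permutation_genes)
}

#' Select gene-related connections from population-averaged coupling
#'
#' Connections whose absolute population-averaged CEC_s exceeds
#' mean(|CEC|) + SD(|CEC|) over all connections (sample SD, strict
#' inequality). Set `use_abs = FALSE` to threshold the signed values
#' instead.
#'
#' @param cec_s Per-connection population-averaged CEC values.
#' @param use_abs Threshold absolute values (default TRUE).
#' @return Integer indices of selected connections.
#' @export
cec_connection_select <- function(cec_s, use_abs = TRUE) {
  if (length(cec_s) < 2) stop("need at least 2 connections")
  x <- if (use_abs) abs(cec_s) else cec_s
  if (stats::sd(x) == 0) {
    warning("constant CEC values: empty selection")
    return(integer(0))
  }
  which(x > mean_plus_sd(x))
}

#' Combine the two connection-selection routes
#'
#' The final gene-related connection set is the intersection of the
#' CEC-threshold route and the tensor connection-weight route; the fraction
#' of the tensor route contained in the CEC route is reported as a
#' consistency diagnostic.
#'
#' @param cec_route,tensor_route Integer connection index sets.
#' @return An object of class `"connection_selection"`: list with
#'   `cec_route`, `tensor_route`, `final`, `containment`.
#' @export
connection_selection_combine <- function(cec_route, tensor_route) {
  final <- intersect(cec_route, tensor_route)
  containment <- if (length(tensor_route) == 0) NA_real_
                 else length(final) / length(tensor_route)
  structure(list(
    cec_route = cec_route, tensor_route = tensor_route,
    final = final, containment = containment
  ), class = "connection_selection")
}

#' @export
print.connection_selection <- function(x, ...) {
  cat("Gene-related connection selection\n")
  cat("  CEC route: ", length(x$cec_route), ", tensor route: ",
      length(x$tensor_route), ", final (intersection): ",
      length(x$final), "\n", sep = "")
  cat("  tensor-route containment in CEC route: ",
      format(x$containment, digits = 3), "\n", sep = "")
  invisible(x)
}
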