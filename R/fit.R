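#' Control parameters for a coupling analysis
#'
#' Collects every tunable constant of the pipeline with the conventional
#' defaults: per-subject family-wise error 0.05, prevalence threshold 80\%,
#' CP rank 10, 1000 permutations, mean + SD selection thresholds.
#'
#' @param alpha Family-wise error rate for per-subject screening and for the
#'   ANOVA / post hoc stages.
#' @param prevalence Prevalence-filter threshold (strict inequality).
#' @param rank CP decomposition rank.
#' @param n_perm Permutations for the gene-mean and SI nulls.
#' @param tol ALS convergence tolerance.
#' @param max_iter Maximum ALS iterations.
#' @param n_restarts ALS random restarts.
#' @param fisher Apply the Fisher r-to-z transform when normalizing
#'   connectivity (set `FALSE` for input already on an unbounded scale, e.g.
#'   the synthetic generator's output).
#' @param expression_method Normalization convention for expression (see
#'   [normalize_expression()]).
#' @param seed Integer seed governing group splitting, restarts and
#'   permutations.
#' @return A list of class `"cgc_control"`.
#' @export
cgc_control <- function(alpha = 0.05, prevalence = 0.8, rank = 10,
                        n_perm = 1000, tol = 1e-8, max_iter = 500,
                        n_restarts = 5, fisher = FALSE,
                        expression_method = "pearson", seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, prevalence > 0, prevalence < 1,
            rank >= 1, n_perm >= 1, tol > 0, max_iter >= 1, n_restarts >= 1)
  structure(list(alpha = alpha, prevalence = prevalence, rank = rank,
                 n_perm = n_perm, tol = tol, max_iter = max_iter,
                 n_restarts = n_restarts, fisher = fisher,
                 expression_method = expression_method,
                 seed = as.integer(seed)),
            class = "cgc_control")
}

#' Fit the full connectivity-expression coupling analysis
#'
#' Runs the four-step procedure end to end: (1) individual-level screening
#' of connectivity-related genes (per-gene correlation, Bonferroni,
#' prevalence filter); (2) construction of the gene x connection x subject
#' coupling tensor over the screened pool and semi-nonnegative CP
#' decomposition in four subject groups; (3) selection of
#' connectivity-related genes (tensor mean + SD intersection across groups,
#' permutation test, and their intersection) and of gene-related
#' connections (CEC threshold route intersected with the tensor
#' connection-weight route); (4) network-level dissection into
#' network-shared (ANOVA) and network-specific (four-criterion) genes.
#'
#' @param expression Raw region x gene matrix (or a path handled by
#'   [read_expression_tsv()]).
#' @param connectivity Raw subject x connection matrix in canonical
#'   upper-triangle order (or a TSV path).
#' @param atlas A `"network_atlas"` data.frame (or a TSV path).
#' @param control A [cgc_control()] list.
#' @param site_labels Optional per-subject acquisition-site labels for the
#'   four-group split.
#' @param tensor_scope `"pool"` (default) restricts the coupling tensor --
#'   and therefore the CGE entering the coupling term -- to the screened
#'   gene pool, mirroring the restriction of the analysis to
#'   connectivity-related genes; `"all"` keeps the full gene universe.
#'   Note that when screening is sharp the pool can consist almost entirely
#'   of truly coupled genes, in which case the within-pool mean + SD and
#'   permutation refinements have little contrast left to work with and
#'   select few or no genes; that is the expected behavior of those rules
#'   on a homogeneous pool, not a failure.
#' @return An object of class `"cgc_fit"`; see Details. Stage results live
#'   in `$screening`, `$tensor` (full-cohort coupling tensor),
#'   `$group_decompositions`, `$consistency`, `$gene_selection`,
#'   `$connection_selection`, `$network` (shared set, specificity report),
#'   and `$manifest` records configuration, per-stage counts and timing.
#' @export
cgc_fit <- function(expression, connectivity, atlas,
                    control = cgc_control(), site_labels = NULL,
                    tensor_scope = c("pool", "all")) {
  tensor_scope <- match.arg(tensor_scope)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(connectivity)) connectivity <- read_connectivity_tsv(connectivity)
  if (is.character(atlas)) atlas <- read_atlas_tsv(atlas)
  stopifnot(inherits(control, "cgc_control"))
  t_all <- list()
  tic <- function() proc.time()[["elapsed"]]
  # -- stage 1: screening ---------------------------------------------------
  t0 <- tic()
  expr <- normalize_expression(expression, method = control$expression_method)
  conn <- normalize_connectivity(connectivity, fisher = control$fisher)
  screening <- screen_genes(expr, conn, alpha = control$alpha,
                            prevalence = control$prevalence)
  pool <- screening$pool
  t_all$screening <- tic() - t0
  if (length(pool) < 2) {
    stop("screening pool has fewer than 2 genes; cannot continue ",
         "(", length(pool), " selected)")
  }
  # -- stage 2: coupling tensor + grouped decompositions --------------------
  t0 <- tic()
  tensor <- build_coupling_tensor(
    expr, conn, genes = if (tensor_scope == "pool") pool else NULL)
  universe <- tensor$gene_ids
  groups <- split_groups(rownames(conn), site_labels, seed = control$seed)
  eff_rank <- min(control$rank, length(universe), ncol(tensor$avg_csa),
                  min(lengths(groups)))
  if (eff_rank < control$rank) {
    warning("CP rank reduced to ", eff_rank, " to fit the tensor dimensions")
  }
  decs <- lapply(seq_along(groups), function(gi) {
    sub <- tensor$values[, , groups[[gi]], drop = FALSE]
    cp_decompose_seminonneg(sub, rank = eff_rank,
                            seed = control$seed + 100L * gi,
                            tol = control$tol, max_iter = control$max_iter,
                            n_restarts = control$n_restarts)
  })
  leads <- lapply(decs, select_leading_component)
  consistency <- cross_group_consistency(leads)
  t_all$tensor <- tic() - t0
  # -- stage 3: gene and connection selection -------------------------------
  t0 <- tic()
  tensor_genes <- universe[repeated_gene_selection(consistency$selections)]
  perm <- permutation_null_gene_means(tensor$avg_csa, n_perm = control$n_perm,
                                      seed = control$seed + 7L)
  perm_genes <- universe[perm$significant]
  reliable <- reliable_gene_intersection(tensor_genes, perm_genes)
  cec_s <- connection_cec(conn, tensor$cge_norm)
  cec_route <- cec_connection_select(cec_s)
  # connection weights: sign-align the group components to the first group,
  # average, then apply the mean + SD rule
  ref <- leads[[1]]$gene_weights
  cw <- vapply(leads, function(l) {
    if (stats::cor(ref, l$gene_weights) < 0) -l$connection_weights
    else l$connection_weights
  }, numeric(length(leads[[1]]$connection_weights)))
  tensor_route <- weight_threshold_select(rowMeans(cw))
  conn_sel <- connection_selection_combine(cec_route, tensor_route)
  t_all$selection <- tic() - t0
  # -- stage 4: network dissection ------------------------------------------
  t0 <- tic()
  classification <- classify_connections(atlas)
  shared <- network_shared_anova(tensor$avg_csa, classification,
                                 alpha = control$alpha)
  specific <- network_specific_pipeline(tensor, classification,
                                        rank = control$rank,
                                        n_perm = control$n_perm,
                                        alpha = control$alpha,
                                        seed = control$seed + 13L,
                                        tol = control$tol,
                                        max_iter = control$max_iter,
                                        n_restarts = control$n_restarts)
  t_all$network <- tic() - t0
  manifest <- list(
    control = unclass(control),
    n_regions = nrow(expr), n_genes = ncol(expr), n_subjects = nrow(conn),
    counts = c(pool = length(pool),
               tensor_genes = length(tensor_genes),
               permutation_genes = length(perm_genes),
               reliable_genes = length(reliable),
               cec_connections = length(cec_route),
               tensor_connections = length(tensor_route),
               final_connections = length(conn_sel$final),
               shared_genes = length(shared$shared),
               specific_genes = length(specific$labels)),
    timing_sec = unlist(t_all)
  )
  structure(list(
    screening = screening,
    tensor = tensor,
    group_decompositions = decs,
    consistency = consistency,
    gene_selection = list(tensor_genes = tensor_genes,
                          permutation_genes = perm_genes,
                          reliable_genes = reliable,
                          permutation = perm),
    connection_selection = conn_sel,
    cec_s = cec_s,
    network = list(shared = shared, specific = specific,
                   classification = classification),
    atlas = atlas,
    expr = expr,
    conn = conn,
    control = control,
    manifest = manifest
  ), class = "cgc_fit")
}

#' @export
print.cgc_fit <- function(x, ...) {
  cts <- x$manifest$counts
  cat("Connectivity-expression coupling analysis\n")
  cat("  ", x$manifest$n_regions, " regions, ", x$manifest$n_genes,
      " genes, ", x$manifest$n_subjects, " subjects\n", sep = "")
  cat("  screened pool:        ", cts[["pool"]], " genes\n", sep = "")
  cat("  reliable genes:       ", cts[["reliable_genes"]],
      " (", cts[["tensor_genes"]], " by tensor, ",
      cts[["permutation_genes"]], " by permutation)\n", sep = "")
  cat("  gene-related connections: ", cts[["final_connections"]],
      " (", cts[["cec_connections"]], " by CEC, ",
      cts[["tensor_connections"]], " by tensor)\n", sep = "")
  cat("  network-shared genes: ", cts[["shared_genes"]],
      ";  network-specific genes: ", cts[["specific_genes"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.cgc_fit <- function(object, ...) {
  cl <- object$network$classification
  final <- object$connection_selection$final
  intra <- cl$type[final] == "intra"
  hom <- cl$homologous
  out <- list(
    counts = object$manifest$counts,
    consistency = object$consistency[c("mismatch_rate", "mean_correspondence")],
    connection_breakdown = c(
      intra = sum(intra), inter = sum(!intra),
      pct_intra = round(100 * mean(intra), 1)),
    homolog_recovery = c(
      n_homologous = sum(hom),
      selected = sum(hom[final]),
      pct = round(100 * sum(final %in% which(hom)) / max(sum(hom), 1), 1)),
    intra_table = intra_network_table(cl, selected = final),
    stage_counts = object$network$specific$stage_counts,
    timing_sec = object$manifest$timing_sec
  )
  class(out) <- "summary.cgc_fit"
  out
}

#' @export
print.summary.cgc_fit <- function(x, ...) {
  cat("== Coupling analysis summary ==\n\nStage counts:\n")
  print(x$counts)
  cat("\nCross-group component consistency: mismatch ",
      format(x$consistency$mismatch_rate, digits = 3), ", correspondence ",
      format(x$consistency$mean_correspondence, digits = 4), "\n", sep = "")
  cat("\nGene-related connections: ", x$connection_breakdown[["intra"]],
      " intra (", x$connection_breakdown[["pct_intra"]], "%), ",
      x$connection_breakdown[["inter"]], " inter\n", sep = "")
  cat("Homologous connections selected: ", x$homolog_recovery[["selected"]],
      " / ", x$homolog_recovery[["n_homologous"]],
      " (", x$homolog_recovery[["pct"]], "%)\n", sep = "")
  cat("\nIntra-network connection accounting:\n")
  print(x$intra_table, row.names = FALSE)
  cat("\nNetwork-specific survivor counts:\n")
  print(x$stage_counts, row.names = FALSE)
  invisible(x)
}

#' Per-gene coefficient table of a coupling fit
#'
#' @param object A `"cgc_fit"`.
#' @param ... Unused.
#' @return data.frame over the tensor gene universe: mean contribution
#'   (population- and connection-averaged C_sa), screening prevalence, pool
#'   membership, and logical columns for the tensor, permutation, reliable,
#'   shared and specific selections (with the assigned network where
#'   applicable).
#' @export
coef.cgc_fit <- function(object, ...) {
  genes <- object$tensor$gene_ids
  labels <- object$network$specific$labels
  data.frame(
    gene = genes,
    mean_csa = object$tensor$gene_means,
    prevalence = object$screening$prevalence[genes],
    in_pool = genes %in% object$screening$pool,
    tensor_selected = genes %in% object$gene_selection$tensor_genes,
    permutation_selected = genes %in% object$gene_selection$permutation_genes,
    reliable = genes %in% object$gene_selection$reliable_genes,
    shared = genes %in% object$network$shared$shared,
    specific_network = ifelse(genes %in% names(labels),
                              labels[genes], NA_character_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Plot method for a coupling fit
#'
#' Left: per-connection absolute population-averaged CEC with the mean + SD
#' selection threshold, colored by intra/inter-network status. Right:
#' population- and connection-averaged C_sa per gene with the reliable
#' genes highlighted.
#'
#' @param x A `"cgc_fit"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cgc_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cl <- x$network$classification
  a <- abs(x$cec_s)
  graphics::plot(a, col = ifelse(cl$type == "intra", "firebrick", "grey60"),
                 pch = 16, cex = 0.6, xlab = "connection",
                 ylab = "|population-averaged CEC|", ...)
  graphics::abline(h = mean_plus_sd(a), lty = 2)
  gm <- x$tensor$gene_means
  rel <- x$screening$pool %in% x$gene_selection$reliable_genes
  graphics::plot(gm, col = ifelse(rel, "darkorange", "grey40"), pch = 16,
                 xlab = "gene (pool)", ylab = "mean C_sa", ...)
  invisible(x)
}
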