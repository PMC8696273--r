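#' Classify connections by network membership and homology
#'
#' Labels every connection (canonical order) as intra- or inter-network,
#' records the network (for intra) or network pair (for inter), and flags
#' homologous connections (mutual contralateral homologs).
#'
#' @param atlas A `"network_atlas"` data.frame (columns `network`,
#'   `hemisphere`, `homolog_id`).
#' @return An object of class `"connection_classification"`: data.frame with
#'   columns `s`, `i`, `j`, `type` ("intra"/"inter"), `network` (network
#'   name or "pair:A-B"), `homologous`.
#' @export
classify_connections <- function(atlas) {
  need <- c("network", "homolog_id")
  if (!all(need %in% names(atlas))) {
    stop("atlas must carry network and homolog_id columns")
  }
  if (anyNA(atlas$network)) {
    stop("unmapped region(s): ",
         paste(atlas$region_id[is.na(atlas$network)], collapse = ", "))
  }
  ci <- connection_index(nrow(atlas))
  ni <- atlas$network[ci$i]
  nj <- atlas$network[ci$j]
  intra <- ni == nj
  hom <- atlas$homolog_id[ci$i] == atlas$homolog_id[ci$j]
  out <- data.frame(
    s = ci$s, i = ci$i, j = ci$j,
    type = ifelse(intra, "intra", "inter"),
    network = ifelse(intra, ni, paste0("pair:", pmin(ni, nj), "-", pmax(ni, nj))),
    homologous = hom,
    stringsAsFactors = FALSE
  )
  class(out) <- c("connection_classification", "data.frame")
  out
}

#' Per-network intra-connection accounting
#'
#' Counts intra-network connections per network and, when a selected
#' connection set is supplied, the per-network number of selected
#' connections with the two percentage columns: A\% (share of all selected
#' intra-network connections) and B\% (share of the network's own
#' connections).
#'
#' @param classification From [classify_connections()].
#' @param selected Optional integer vector of selected connection indices.
#' @return data.frame, one row per network plus a "Sum" row.
#' @export
intra_network_table <- function(classification, selected = NULL) {
  cl <- classification[classification$type == "intra", ]
  nets <- unique(cl$network)
  n_conn <- vapply(nets, function(n) sum(cl$network == n), integer(1))
  out <- data.frame(network = nets, n_connections = n_conn,
                    stringsAsFactors = FALSE)
  if (!is.null(selected)) {
    sel_cl <- cl[cl$s %in% selected, ]
    n_sel <- vapply(nets, function(n) sum(sel_cl$network == n), integer(1))
    out$n_selected <- n_sel
    out$pct_of_selected <- round(100 * n_sel / max(sum(n_sel), 1), 1)
    out$pct_of_network <- round(100 * n_sel / n_conn, 1)
  }
  sum_row <- data.frame(network = "Sum",
                        n_connections = sum(out$n_connections),
                        stringsAsFactors = FALSE)
  if (!is.null(selected)) {
    sum_row$n_selected <- sum(out$n_selected)
    sum_row$pct_of_selected <- 100
    sum_row$pct_of_network <- round(100 * sum(out$n_selected) /
                                      sum(out$n_connections), 1)
  }
  rbind(out, sum_row)
}

# per-gene network grouping of intra-network connections; networks need
# >= min_size connections to enter group statistics
intra_groups <- function(classification, min_size = 2) {
  cl <- classification[classification$type == "intra", ]
  counts <- table(cl$network)
  usable <- names(counts)[counts >= min_size]
  dropped <- setdiff(names(counts), usable)
  list(connections = cl$s, networks = cl$network, usable = usable,
       dropped = dropped)
}

#' Network-shared genes by one-way ANOVA
#'
#' For each gene, a one-way ANOVA compares the population-averaged C_sa
#' values among the groups of intra-network connections from the different
#' networks; genes without a significant difference (P >= alpha) are
#' network-shared. Networks with fewer than two intra-network connections
#' are excluded from the grouping with a warning.
#'
#' @param avg_csa Gene x connection matrix of population-averaged C_sa.
#' @param classification From [classify_connections()].
#' @param alpha Significance level (default 0.05).
#' @return List with `shared` (gene ids with P >= alpha), `p` (per-gene
#'   ANOVA p-values), `networks_used`.
#' @export
network_shared_anova <- function(avg_csa, classification, alpha = 0.05) {
  grp <- intra_groups(classification)
  if (length(grp$dropped)) {
    warning("network(s) with < 2 intra-network connections excluded from ",
            "ANOVA: ", paste(grp$dropped, collapse = ", "))
  }
  keep <- grp$networks %in% grp$usable
  if (length(unique(grp$networks[keep])) < 2) {
    stop("fewer than 2 usable network groups")
  }
  g <- factor(grp$networks[keep])
  cols <- grp$connections[keep]
  p <- apply(avg_csa[, cols, drop = FALSE], 1, function(x) {
    # degenerate cases: a constant gene has F = 0 (no group differences,
    # p = 1); zero residual variance with differing group means is a
    # certain rejection
    if (stats::var(x) == 0) return(1)
    pv <- stats::oneway.test(x ~ g, var.equal = TRUE)$p.value
    if (is.na(pv)) {
      means <- tapply(x, g, mean)
      pv <- if (max(means) - min(means) > 0) 0 else 1
    }
    pv
  })
  shared <- rownames(avg_csa)[p >= alpha]
  list(shared = shared, p = p, networks_used = grp$usable)
}

#' Per-network tensor-decomposition gene candidates
#'
#' For each network, the coupling tensor restricted to that network's
#' intra-network connections is decomposed (nonnegative individual mode,
#' leading component) and genes are selected by the mean + SD rule on
#' absolute gene weights. Returns the per-network sets and their union (the
#' candidate pool for network-specific analysis). The requested rank is
#' reduced to the number of available connections where necessary (with a
#' warning).
#'
#' @param tensor A `"coupling_tensor"`.
#' @param classification From [classify_connections()].
#' @param rank Target CP rank (default 10).
#' @param seed,tol,max_iter,n_restarts Passed to
#'   [cp_decompose_seminonneg()].
#' @return List with `per_network` (named list of gene-id vectors),
#'   `union`, `components` (leading components per network).
#' @export
per_network_tensor_candidates <- function(tensor, classification, rank = 10,
                                          seed = 1L, tol = 1e-8,
                                          max_iter = 500, n_restarts = 5) {
  cl <- classification[classification$type == "intra", ]
  nets <- sort(unique(cl$network))
  gene_ids <- tensor$gene_ids
  per_network <- list()
  components <- list()
  for (nw in nets) {
    cols <- cl$s[cl$network == nw]
    sub <- tensor$values[, cols, , drop = FALSE]
    if (all(sub == 0)) {
      warning("all-zero sub-tensor for network ", nw, ": empty selection")
      per_network[[nw]] <- character(0)
      next
    }
    r_eff <- min(rank, dim(sub))
    if (r_eff < rank) {
      warning("network ", nw, ": rank reduced to ", r_eff,
              " (only ", length(cols), " intra-network connections)")
    }
    dec <- cp_decompose_seminonneg(sub, rank = r_eff, seed = seed, tol = tol,
                                   max_iter = max_iter,
                                   n_restarts = n_restarts)
    lead <- select_leading_component(dec)
    components[[nw]] <- lead
    per_network[[nw]] <- gene_ids[weight_threshold_select(lead$gene_weights)]
  }
  list(per_network = per_network,
       union = sort(unique(unlist(per_network, use.names = FALSE))),
       components = components)
}

#' Network specificity index (SI) with a permutation null
#'
#' SI of a gene for a target network is the mean population-averaged C_sa
#' over the target network's intra-network connections minus the pooled mean
#' over all other networks' intra-network connections. The null reassigns
#' network labels to intra-network connections at random (preserving group
#' sizes); the gene is significant for the network when the observed SI
#' exceeds all permuted values.
#'
#' Networks with fewer than two intra-network connections are excluded from
#' both the target and the rest pool (the same usability rule applied to the
#' ANOVA and post hoc stages: a single connection supports no within-network
#' statistic).
#'
#' @param avg_csa_gene Per-connection vector of population-averaged C_sa for
#'   one gene (full connection universe, canonical order).
#' @param classification From [classify_connections()].
#' @param target_network Network name.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `si`, `p` ((k+1)/(n+1) convention), `significant`.
#' @export
specificity_index <- function(avg_csa_gene, classification, target_network,
                              n_perm = 1000, seed = 1L) {
  if (n_perm < 1000) {
    warning("fewer than 1000 permutations: the P < 0.001 criterion ",
            "is unattainable")
  }
  grp <- intra_groups(classification)
  keep <- grp$networks %in% grp$usable
  if (!target_network %in% grp$networks[keep]) {
    stop("target network has fewer than 2 intra-network connections")
  }
  x <- avg_csa_gene[grp$connections[keep]]
  in_target <- grp$networks[keep] == target_network
  si_of <- function(ind) mean(x[ind]) - mean(x[!ind])
  si <- si_of(in_target)
  k <- sum(in_target)
  exceeded <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      ind <- seq_along(x) %in% sample(seq_along(x), k)
      si_of(ind) >= si
    }, logical(1)))
  })
  list(si = si, p = (exceeded + 1) / (n_perm + 1), significant = exceeded == 0)
}

#' Post hoc specificity comparison of the two top networks
#'
#' Ranks the networks by the gene's connection-averaged mean C_sa, then
#' requires the first network's mean to be at least twice the second's and a
#' Welch two-sample t-test on the two networks' per-connection values to
#' reject at `alpha`. When the two means differ in sign the fold criterion
#' is evaluated on absolute values with a warning. Only networks with at
#' least two intra-network connections enter the ranking (a singleton
#' network cannot support the t-test, so it could never pass and would only
#' displace genuine top networks).
#'
#' @param avg_csa_gene Per-connection vector for one gene.
#' @param classification From [classify_connections()].
#' @param alpha t-test level (default 0.05).
#' @param fold Required fold ratio (default 2).
#' @return List with `first_network`, `second_network`, `fold_ratio`, `t_p`,
#'   `passes`.
#' @export
posthoc_specificity <- function(avg_csa_gene, classification, alpha = 0.05,
                                fold = 2) {
  grp <- intra_groups(classification)
  keep <- grp$networks %in% grp$usable
  if (length(grp$usable) < 2) stop("fewer than 2 usable networks")
  x <- avg_csa_gene[grp$connections[keep]]
  g <- grp$networks[keep]
  means <- tapply(x, g, mean)
  ord <- order(means, decreasing = TRUE)
  first <- names(means)[ord[1]]
  second <- names(means)[ord[2]]
  m1 <- means[ord[1]]
  m2 <- means[ord[2]]
  if (sign(m1) != sign(m2) && m2 != 0) {
    warning("top-two network means differ in sign; fold ratio computed on ",
            "absolute values")
  }
  fold_ratio <- if (m2 == 0) Inf else abs(m1) / abs(m2)
  x1 <- x[g == first]
  x2 <- x[g == second]
  if (length(x1) < 2 || length(x2) < 2) {
    warning("a top network has a single connection; t-test skipped, ",
            "criterion fails")
    t_p <- NA_real_
  } else {
    t_p <- stats::t.test(x1, x2)$p.value
  }
  passes <- isTRUE(fold_ratio >= fold && !is.na(t_p) && t_p < alpha &&
                     m1 > 0)
  list(first_network = first, second_network = second,
       fold_ratio = unname(fold_ratio), t_p = t_p, passes = passes)
}

#' Four-criterion network-specific gene identification
#'
#' Applies, in order: (1) per-network tensor candidacy (mean + SD gene
#' weights on each network's intra-connection sub-tensor); (2) SI
#' permutation significance for the candidate network; (3) one-way ANOVA
#' across the network groups at the Bonferroni level alpha / (number of
#' criterion-2 survivors); (4) the post hoc fold-and-t-test comparison of
#' the two top networks, which must also agree with the candidate network.
#' A gene is labeled with a network only when all four criteria pass.
#'
#' @param tensor A `"coupling_tensor"`.
#' @param classification From [classify_connections()].
#' @param rank CP rank for per-network decompositions (default 10).
#' @param n_perm SI permutations (default 1000).
#' @param alpha Base level for criteria 3 and 4 (default 0.05).
#' @param seed Integer seed.
#' @param tol,max_iter,n_restarts Passed to CP decomposition.
#' @return An object of class `"network_specificity"`: list with `labels`
#'   (named character vector gene -> network for genes passing all
#'   criteria), `report` (per-gene data.frame of stage outcomes),
#'   `stage_counts` (per-network survivor counts after criterion 1,
#'   criteria 1-2, and criteria 1-4), `candidates` (criterion-1 sets).
#' @export
network_specific_pipeline <- function(tensor, classification, rank = 10,
                                      n_perm = 1000, alpha = 0.05, seed = 1L,
                                      tol = 1e-8, max_iter = 500,
                                      n_restarts = 5) {
  cand <- per_network_tensor_candidates(tensor, classification, rank = rank,
                                        seed = seed, tol = tol,
                                        max_iter = max_iter,
                                        n_restarts = n_restarts)
  avg <- tensor$avg_csa
  gene_ids <- tensor$gene_ids
  # criterion 2: SI per candidate (gene, network); label permutations are
  # drawn once per network and shared by that network's candidate genes
  grp <- intra_groups(classification)
  keep <- grp$networks %in% grp$usable
  icols <- grp$connections[keep]
  inets <- grp$networks[keep]
  rows <- list()
  for (nw in names(cand$per_network)) {
    genes_nw <- cand$per_network[[nw]]
    if (!length(genes_nw)) next
    if (!nw %in% inets) {
      warning("network ", nw, " has fewer than 2 intra-network connections;",
              " SI not evaluable, its candidates are dropped")
      next
    }
    Tm <- avg[genes_nw, icols, drop = FALSE]
    in_t <- inets == nw
    k <- sum(in_t)
    n <- length(inets)
    obs <- rowMeans(Tm[, in_t, drop = FALSE]) -
      rowMeans(Tm[, !in_t, drop = FALSE])
    tot <- rowSums(Tm)
    exceeded <- with_seed(seed + match(nw, names(cand$per_network)), {
      ex <- integer(length(genes_nw))
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n, k)
        mt <- rowMeans(Tm[, idx, drop = FALSE])
        sip <- mt - (tot - mt * k) / (n - k)
        ex <- ex + (sip >= obs)
      }
      ex
    })
    rows[[length(rows) + 1]] <- data.frame(
      gene = genes_nw, network = nw, si = unname(obs),
      si_p = (exceeded + 1) / (n_perm + 1),
      si_pass = exceeded == 0, stringsAsFactors = FALSE)
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), network = character(0), si = numeric(0),
               si_p = numeric(0), si_pass = logical(0))
  si_survivors <- report[report$si_pass, , drop = FALSE]
  # criteria 3 + 4 on the SI survivors (unique genes)
  genes34 <- unique(si_survivors$gene)
  n_cand <- length(genes34)
  labels <- character(0)
  report$anova_p <- NA_real_
  report$posthoc_pass <- NA
  report$first_network <- NA_character_
  if (n_cand > 0) {
    bon <- alpha / n_cand
    shared <- network_shared_anova(avg[genes34, , drop = FALSE],
                                   classification, alpha = alpha)
    for (gene in genes34) {
      p_anova <- shared$p[gene]
      idx <- report$gene == gene
      report$anova_p[idx] <- p_anova
      if (is.na(p_anova) || p_anova >= bon) next
      ph <- posthoc_specificity(avg[gene, ], classification, alpha = alpha)
      report$posthoc_pass[idx] <- ph$passes
      report$first_network[idx] <- ph$first_network
      cand_nets <- si_survivors$network[si_survivors$gene == gene]
      if (ph$passes && ph$first_network %in% cand_nets) {
        labels[gene] <- ph$first_network
      }
    }
  }
  nets <- names(cand$per_network)
  stage_counts <- data.frame(
    network = nets,
    criterion1 = vapply(nets, function(n) length(cand$per_network[[n]]),
                        integer(1)),
    criteria12 = vapply(nets, function(n)
      sum(si_survivors$network == n), integer(1)),
    criteria1234 = vapply(nets, function(n) sum(labels == n), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(labels = labels, report = report,
                 stage_counts = stage_counts,
                 candidates = cand$per_network,
                 n_anova_candidates = n_cand),
            class = "network_specificity")
}

#' @export
print.network_specificity <- function(x, ...) {
  cat("Network-specific gene identification (four criteria)\n")
  print(x$stage_counts, row.names = FALSE)
  cat("labeled genes: ", length(x$labels), "\n", sep = "")
  invisible(x)
}
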