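test_that("the 90-region atlas reproduces the published connection counts", {
  atlas <- aal_like_atlas()
  expect_equal(nrow(atlas), 90)
  expect_equal(length(unique(atlas$network)), 8)
  expect_equal(length(unique(atlas$homolog_id)), 45)
  cl <- classify_connections(atlas)
  expect_equal(nrow(cl), 4005)
  counts <- table(cl$network[cl$type == "intra"])
  expect_equal(unname(counts[paste0("N", 1:8)]),
               c(91, 91, 6, 6, 153, 45, 153, 28), ignore_attr = TRUE)
  expect_equal(sum(counts), 573)
  expect_equal(sum(cl$homologous), 45)
  # every homologous connection is intra-network by construction
  expect_true(all(cl$type[cl$homologous] == "intra"))
})

test_that("toy atlases classify correctly and errors are raised", {
  cl <- classify_connections(generate_atlas(c(2)))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$type, "intra")
  expect_true(cl$homologous)
  atlas <- generate_atlas(c(4, 4))
  cl2 <- classify_connections(atlas)
  expect_equal(unname(table(cl2$network[cl2$type == "intra"])), c(6L, 6L),
               ignore_attr = TRUE)
  expect_equal(sum(cl2$type == "inter") + sum(cl2$type == "intra"),
               n_connections(8))
  bad <- atlas
  bad$network[3] <- NA
  expect_error(classify_connections(bad), "unmapped")
})

test_that("intra-network accounting reports the two percentage columns", {
  atlas <- aal_like_atlas()
  cl <- classify_connections(atlas)
  # select the visual-analog network's intra connections plus a few others
  n1 <- cl$s[cl$type == "intra" & cl$network == "N1"][1:44]
  rest <- cl$s[cl$type == "intra" & cl$network == "N2"][1:20]
  tab <- intra_network_table(cl, selected = c(n1, rest))
  row1 <- tab[tab$network == "N1", ]
  expect_equal(row1$n_connections, 91)
  expect_equal(row1$n_selected, 44)
  expect_equal(row1$pct_of_selected, round(100 * 44 / 64, 1))
  expect_equal(row1$pct_of_network, round(100 * 44 / 91, 1))
  expect_equal(tab$n_connections[tab$network == "Sum"], 573)
})

test_that("network-shared ANOVA separates flat from shifted genes", {
  atlas <- generate_atlas(c(6, 6, 4, 4))
  cl <- classify_connections(atlas)
  n_intra <- sum(cl$type == "intra")
  S <- nrow(cl)
  set.seed(50)
  avg <- matrix(rnorm(3 * S), 3, S,
                dimnames = list(c("flat", "shifted", "noise"), NULL))
  avg["flat", ] <- 1 # identical in all groups
  idx4 <- cl$s[cl$type == "intra" & cl$network == "N4"]
  avg["shifted", idx4] <- avg["shifted", idx4] + 10
  res <- network_shared_anova(avg, cl)
  expect_true("flat" %in% res$shared)     # F = 0 -> shared
  expect_false("shifted" %in% res$shared) # 10 SD shift -> rejected
  expect_lt(res$p["shifted"], 1e-6)
  # type-I calibration: random genes shared at about 1 - alpha
  avg2 <- matrix(rnorm(400 * S), 400, S,
                 dimnames = list(paste0("g", 1:400), NULL))
  res2 <- network_shared_anova(avg2, cl)
  rate <- length(res2$shared) / 400
  expect_lt(abs(rate - 0.95), 3 * sqrt(0.95 * 0.05 / 400) + 0.01)
})

test_that("specificity index is maximal for a clean indicator gene", {
  atlas <- generate_atlas(c(6, 6, 4, 4))
  cl <- classify_connections(atlas)
  x <- numeric(nrow(cl))
  x[cl$s[cl$type == "intra" & cl$network == "N2"]] <- 1
  si <- specificity_index(x, cl, "N2", n_perm = 1000, seed = 3)
  expect_equal(si$p, 1 / 1001)
  expect_true(si$significant)
  expect_equal(si$si, 1 - 0) # mean 1 in target, 0 elsewhere
  # constant gene: SI 0, never significant
  si0 <- suppressWarnings(
    specificity_index(rep(2, nrow(cl)), cl, "N2", n_perm = 200, seed = 3))
  expect_equal(si0$si, 0)
  expect_false(si0$significant)
  expect_error(specificity_index(x, cl, "N9", n_perm = 1000), "network")
})

test_that("specificity index is calibrated on exchangeable data", {
  atlas <- generate_atlas(c(6, 6, 4, 4))
  cl <- classify_connections(atlas)
  set.seed(55)
  hits <- 0
  n_genes <- 300
  for (g in seq_len(n_genes)) {
    x <- rnorm(nrow(cl))
    si <- suppressWarnings(
      specificity_index(x, cl, "N1", n_perm = 100, seed = 1000 + g))
    hits <- hits + si$significant
  }
  p0 <- 1 / 101
  expect_lt(abs(hits / n_genes - p0), 3 * sqrt(p0 * (1 - p0) / n_genes))
})

test_that("post hoc comparison enforces fold ratio and t-test jointly", {
  atlas <- generate_atlas(c(6, 6, 4, 4))
  cl <- classify_connections(atlas)
  set.seed(60)
  x <- rnorm(nrow(cl), 0, 0.3)
  i1 <- cl$s[cl$type == "intra" & cl$network == "N1"]
  i2 <- cl$s[cl$type == "intra" & cl$network == "N2"]
  # means 10 vs 4 with tight spread: ratio 2.5 and significant
  x[i1] <- 10 + rnorm(length(i1), 0, 0.3)
  x[i2] <- 4 + rnorm(length(i2), 0, 0.3)
  ph <- posthoc_specificity(x, cl)
  expect_equal(ph$first_network, "N1")
  expect_equal(ph$second_network, "N2")
  expect_gte(ph$fold_ratio, 2)
  expect_lt(ph$t_p, 0.05)
  expect_true(ph$passes)
  # means 10 vs 6: ratio below 2 fails regardless of the t-test
  x2 <- x
  x2[i2] <- 6 + rnorm(length(i2), 0, 0.3)
  ph2 <- posthoc_specificity(x2, cl)
  expect_lt(ph2$fold_ratio, 2)
  expect_false(ph2$passes)
})

test_that("per-network candidates react to sub-tensor structure", {
  atlas <- generate_atlas(c(4, 4))
  cl <- classify_connections(atlas)
  S <- nrow(cl)
  set.seed(65)
  vals <- array(rnorm(30 * S * 5, 0, 0.1), c(30, S, 5))
  # gene 3 dominates N1's intra connections
  i1 <- cl$s[cl$type == "intra" & cl$network == "N1"]
  vals[3, i1, ] <- vals[3, i1, ] + 5
  tens <- structure(list(values = vals, avg_csa = rowMeans(vals, dims = 2),
                         gene_ids = paste0("g", 1:30)),
                    class = "coupling_tensor")
  cand <- suppressWarnings(
    per_network_tensor_candidates(tens, cl, rank = 2, seed = 2,
                                  n_restarts = 2))
  expect_true("g3" %in% cand$per_network$N1)
  expect_false("g3" %in% cand$per_network$N2)
  expect_true(all(unlist(cand$per_network) %in% cand$union))
  # all-zero sub-tensor yields an empty selection with a warning
  vals2 <- vals
  vals2[, cl$s[cl$network == "N2" & cl$type == "intra"], ] <- 0
  tens2 <- structure(list(values = vals2,
                          avg_csa = rowMeans(vals2, dims = 2),
                          gene_ids = paste0("g", 1:30)),
                     class = "coupling_tensor")
  expect_warning(
    cand2 <- per_network_tensor_candidates(tens2, cl, rank = 2, seed = 2,
                                           n_restarts = 2),
    "all-zero")
  expect_length(cand2$per_network$N2, 0)
})

test_that("survivor counts are non-increasing through the criteria", {
  ds <- generate_dataset(synthetic_config(seed = 8))
  expr <- normalize_expression(ds$expression)
  conn <- normalize_connectivity(ds$connectivity, fisher = FALSE)
  cl <- classify_connections(ds$atlas)
  tens <- build_coupling_tensor(expr, conn)
  sp <- suppressWarnings(
    network_specific_pipeline(tens, cl, n_perm = 200, seed = 4,
                              max_iter = 200, n_restarts = 2))
  sc <- sp$stage_counts
  expect_true(all(sc$criteria12 <= sc$criterion1))
  expect_true(all(sc$criteria1234 <= sc$criteria12))
  # labels only ever point to the gene's own candidate network
  for (g in names(sp$labels)) {
    expect_true(sp$labels[g] %in%
                  sp$report$network[sp$report$gene == g & sp$report$si_pass])
  }
})
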