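test_that("atlas generation follows the homolog and network conventions", {
  atlas <- aal_like_atlas()
  expect_equal(nrow(atlas), 90)
  expect_equal(length(unique(atlas$network)), 8)
  expect_equal(length(unique(atlas$homolog_id)), 45)
  # homolog pairs partition regions, are adjacent, share a network and
  # cross hemispheres
  for (h in unique(atlas$homolog_id)) {
    pair <- atlas[atlas$homolog_id == h, ]
    expect_equal(nrow(pair), 2)
    expect_equal(diff(pair$region_id), 1)
    expect_equal(pair$network[1], pair$network[2])
    expect_setequal(pair$hemisphere, c("L", "R"))
  }
  expect_equal(nrow(generate_atlas(c(2))), 2)
  expect_error(generate_atlas(c(3, 4)), "even")
})

test_that("connectivity template encodes the configured boosts", {
  cfg <- synthetic_config(seed = 1)
  atlas <- generate_atlas(cfg)
  out <- generate_connectivity(cfg, atlas)
  cl <- classify_connections(atlas)
  intra_nonhom <- cl$type == "intra" & !cl$homologous
  expect_equal(unique(out$template[cl$type == "inter"]), cfg$base_fc)
  expect_equal(unique(out$template[intra_nonhom]),
               cfg$base_fc + cfg$intra_network_fc_boost)
  expect_equal(unique(out$template[cl$homologous]),
               cfg$base_fc + cfg$intra_network_fc_boost +
                 cfg$homolog_fc_boost)
  # zero noise -> all subjects equal the template
  cfg0 <- synthetic_config(subject_noise_sd = 0, n_subjects = 3)
  out0 <- generate_connectivity(cfg0, generate_atlas(cfg0))
  for (k in 1:3) expect_equal(unname(out0$connectivity[k, ]), out0$template)
})

test_that("homolog boost alone puts homologs at the top of the template", {
  cfg <- synthetic_config(n_regions = 90,
                          network_sizes = c(14, 14, 4, 4, 18, 10, 18, 8),
                          intra_network_fc_boost = 0, homolog_fc_boost = 2,
                          base_fc = 0)
  atlas <- generate_atlas(cfg)
  out <- generate_connectivity(cfg, atlas)
  cl <- classify_connections(atlas)
  top45 <- order(out$template, decreasing = TRUE)[1:45]
  expect_setequal(top45, which(cl$homologous))
})

test_that("subject averaging concentrates on the template", {
  cfg <- synthetic_config(n_subjects = 50, subject_noise_sd = 0.1, seed = 5)
  out <- generate_connectivity(cfg, generate_atlas(cfg))
  expect_gt(cor(colMeans(out$connectivity), out$template), 0.99)
})

test_that("planted expression aligns with the template factor", {
  # deterministic case: full coupling, products equal the factor products
  cfg1 <- synthetic_config(coupling_effect = 1, n_genes = 30,
                           n_coupling_genes = 5,
                           network_specific_map = integer(0),
                           network_coexpression = 0)
  atlas <- generate_atlas(cfg1)
  conn <- generate_connectivity(cfg1, atlas)
  E <- generate_expression(cfg1, atlas, conn$template)
  ci <- connection_index(cfg1$n_regions)
  P <- E[ci$i, 1] * E[ci$j, 1]
  expect_equal(cor(P, E[ci$i, 2] * E[ci$j, 2]), 1, tolerance = 1e-8)
  # columns are population z-scores
  expect_lt(max(abs(colMeans(E))), 1e-12)
  expect_lt(max(abs(colMeans(E^2) - 1)), 1e-12)
  # null case: no coupling leaves planted genes indistinguishable
  cfg0 <- synthetic_config(coupling_effect = 0, seed = 6)
  ds0 <- generate_dataset(cfg0)
  E0 <- ds0$expression
  P0 <- E0[ci$i, ] * E0[ci$j, ]
  r0 <- as.vector(cor(ds0$template, P0))
  planted <- seq_len(cfg0$n_coupling_genes)
  expect_lt(abs(mean(abs(r0[planted])) - mean(abs(r0[-planted]))), 0.02)
  # degenerate template rejected
  expect_error(generate_expression(cfg1, atlas,
                                   rep(0, n_connections(30))), "degenerate")
})

test_that("planted genes carry detectably stronger template correlation", {
  ds <- generate_dataset(synthetic_config(seed = 19))
  ci <- connection_index(nrow(ds$expression))
  P <- ds$expression[ci$i, ] * ds$expression[ci$j, ]
  r <- abs(as.vector(cor(ds$template, P)))
  planted <- seq_along(ds$truth$coupling_genes)
  bg <- setdiff(seq_len(ncol(P)),
                c(planted, match(names(ds$truth$network_specific),
                                 colnames(ds$expression))))
  expect_gt(mean(r[planted]), quantile(r[bg], 0.95))
})

test_that("dataset generation is a pure function of its configuration", {
  a <- generate_dataset(synthetic_config(seed = 4))
  b <- generate_dataset(synthetic_config(seed = 4))
  expect_identical(a$expression, b$expression)
  expect_identical(a$connectivity, b$connectivity)
  expect_identical(a$truth, b$truth)
  c_ <- generate_dataset(synthetic_config(seed = 5))
  expect_false(identical(a$expression, c_$expression))
  # shapes under the default configuration
  expect_equal(dim(a$expression), c(30, 300))
  expect_equal(dim(a$connectivity), c(40, n_connections(30)))
  expect_length(a$truth$coupling_genes, 20)
  expect_length(a$truth$network_specific, 10)
  expect_true(all(a$truth$strong_connections %in%
                    a$truth$coupled_connections))
})

test_that("datasets round-trip through the plain-text writers", {
  ds <- generate_dataset(synthetic_config(n_regions = 8, n_genes = 12,
                                          n_subjects = 3,
                                          network_sizes = c(4, 4),
                                          n_coupling_genes = 2,
                                          network_specific_map = integer(0),
                                          seed = 2))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_equal(read_expression_tsv(paths["expression"]), ds$expression,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(read_connectivity_tsv(paths["connectivity"]),
               ds$connectivity, ignore_attr = TRUE, tolerance = 1e-12)
  atlas2 <- read_atlas_tsv(paths["atlas"])
  expect_equal(atlas2$network, ds$atlas$network)
  expect_equal(atlas2$homolog_id, ds$atlas$homolog_id)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$coupling_genes, ds$truth$coupling_genes)
})
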