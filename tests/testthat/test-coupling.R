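test_that("expression normalization matches population z-scores", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 1, 1))
  z <- normalize_expression(m, method = "zscore")
  expect_equal(z[, "a"], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(colMeans(z^2), c(a = 1, b = 1))
  # idempotence
  expect_equal(unclass(normalize_expression(z, method = "zscore")), unclass(z),
               ignore_attr = TRUE)
})

test_that("pearson normalization standardizes both margins", {
  set.seed(7)
  m <- matrix(rnorm(30 * 40), 30, 40)
  z <- normalize_expression(m, method = "pearson")
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(colMeans(z^2) - 1)), 1e-10)
  expect_lt(max(abs(rowMeans(z))), 1e-10)
  expect_lt(max(abs(rowMeans(z^2) - 1)), 1e-10)
})

test_that("constant gene columns are rejected by name", {
  m <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  expect_error(normalize_expression(m), "g2")
})

test_that("CGE equals the Pearson correlation of regional profiles", {
  set.seed(11)
  m <- matrix(rnorm(8 * 50), 8, 50)
  z <- normalize_expression(m, method = "pearson")
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    expect_equal(compute_cge(z, pair[1], pair[2]),
                 cor(z[pair[1], ], z[pair[2], ]), tolerance = 1e-10)
  }
  # symmetry and self-connection
  expect_equal(compute_cge(z, 2, 5), compute_cge(z, 5, 2))
  expect_error(compute_cge(z, 3, 3), "self-connection")
  # bounds under the chosen normalization
  expect_true(all(abs(cge_vector(z)) <= 1 + 1e-12))
})

test_that("identical and opposite profiles give CGE of 1 and -1", {
  # a doubly standardized matrix built from balanced +/-1 rows: region 2
  # duplicates region 1 up to sign, region 4 duplicates region 3
  set.seed(3)
  G <- 40
  r <- rep(c(1, -1), G / 2)
  s <- sample(r)
  m <- rbind(r, -r, s, -s)
  z <- normalize_expression(m, method = "pearson")
  expect_equal(unclass(z), m, ignore_attr = TRUE) # already a fixed point
  expect_equal(compute_cge(z, 1, 2), -1)
  expect_equal(compute_cge(z, 3, 4), -1)
  expect_equal(compute_cge(rbind(z, z)[c(1, 5, 2, 3), ], 1, 2), 1)
})

test_that("connectivity normalization applies Fisher z then z-scores", {
  row <- c(0.1, 0.2, 0.3, 0.4)
  out <- normalize_connectivity(rbind(row), fisher = TRUE)
  manual <- atanh(row)
  manual <- (manual - mean(manual)) / sqrt(mean((manual - mean(manual))^2))
  expect_equal(as.vector(out), manual, tolerance = 1e-10)
  expect_equal(mean(out), 0, tolerance = 1e-12)
  expect_equal(mean(out^2), 1, tolerance = 1e-12)
  # identical subjects stay identical; |r| = 1 rejected
  two <- normalize_connectivity(rbind(row, row))
  expect_equal(two[1, ], two[2, ])
  expect_error(normalize_connectivity(rbind(c(0.5, 1, 0.2))), "Fisher")
})

test_that("global CEC equals the Pearson correlation across connections", {
  set.seed(5)
  S <- 200
  fc <- rnorm(S)
  fc <- (fc - mean(fc)) / sqrt(mean((fc - mean(fc))^2))
  cge <- rnorm(S)
  cge <- (cge - mean(cge)) / sqrt(mean((cge - mean(cge))^2))
  expect_equal(compute_global_cec(fc, cge), cor(fc, cge), tolerance = 1e-10)
  expect_equal(compute_global_cec(fc, fc), 1, tolerance = 1e-12)
  # constructed orthogonal pair
  orth <- cge - fc * mean(fc * cge)
  expect_equal(compute_global_cec(fc, orth), 0, tolerance = 1e-12)
  expect_error(compute_global_cec(fc, cge[-1]), "length")
})

test_that("per-entry coupling contribution is the stated product", {
  expect_equal(compute_csa(2.0, 1.0, 0.5, 1.0), 1.0)
  expect_equal(compute_csa(3, -2, 0, 5), 0)
  expect_equal(compute_csa(c(1, 2), c(3, 4), c(1, 1), c(2, 0.5)),
               c(6, 4))
})

test_that("coupling tensor entries match hand-computed products", {
  d <- tiny_dataset(seed = 21, n_regions = 3, n_genes = 2, n_subjects = 1)
  tens <- build_coupling_tensor(d$expr, d$conn)
  ci <- connection_index(3)
  cge_raw <- cge_vector(d$expr)
  cge_nrm <- (cge_raw - mean(cge_raw)) /
    sqrt(mean((cge_raw - mean(cge_raw))^2))
  for (a in 1:2) {
    for (s in 1:3) {
      expect_equal(unname(tens$values[a, s, 1]),
                   unname(d$conn[1, s] * cge_nrm[s] *
                            d$expr[ci$i[s], a] * d$expr[ci$j[s], a]),
                   tolerance = 1e-12)
    }
  }
})

test_that("tensor identity links the three coupling statistics", {
  d <- tiny_dataset(seed = 9, n_regions = 8, n_genes = 30, n_subjects = 3)
  tens <- build_coupling_tensor(d$expr, d$conn)
  for (k in 1:3) {
    lhs <- colMeans(tens$values[, , k]) # mean over genes at each connection
    rhs <- d$conn[k, ] * tens$cge_norm * tens$cge_raw
    expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("tensor averaging is order-independent and consistent", {
  d <- tiny_dataset(seed = 13, n_regions = 6, n_genes = 10, n_subjects = 5)
  tens <- build_coupling_tensor(d$expr, d$conn)
  expect_equal(tens$avg_csa, rowMeans(tens$values, dims = 2))
  bygene1 <- rowMeans(tens$avg_csa)              # subjects then connections
  bygene2 <- apply(tens$values, 1, mean)         # all at once
  expect_equal(bygene1, bygene2, tolerance = 1e-12)
  expect_equal(tens$gene_means, bygene1)
  # two identical subjects average to either one
  conn2 <- d$conn[c(1, 1), ]
  t2 <- build_coupling_tensor(d$expr, conn2)
  expect_equal(t2$avg_csa, t2$values[, , 1])
  # dimension mismatch errors
  expect_error(build_coupling_tensor(d$expr, d$conn[, -1]), "connections")
})

test_that("gene restriction defines the CGE universe", {
  d <- tiny_dataset(seed = 17, n_regions = 7, n_genes = 12, n_subjects = 2)
  sub <- build_coupling_tensor(d$expr, d$conn, genes = 1:5)
  direct <- build_coupling_tensor(d$expr[, 1:5], d$conn)
  expect_equal(sub$cge_raw, direct$cge_raw)
  expect_equal(sub$values, direct$values)
})
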