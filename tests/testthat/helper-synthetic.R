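# shared small fixtures built in code

# tiny normalized dataset for coupling arithmetic tests
tiny_dataset <- function(seed = 42, n_regions = 10, n_genes = 25,
                         n_subjects = 4) {
  set.seed(seed)
  raw_expr <- matrix(rnorm(n_regions * n_genes), n_regions, n_genes,
                     dimnames = list(paste0("r", seq_len(n_regions)),
                                     paste0("g", seq_len(n_genes))))
  S <- n_connections(n_regions)
  raw_conn <- matrix(rnorm(n_subjects * S, 0, 0.5), n_subjects, S,
                     dimnames = list(paste0("s", seq_len(n_subjects)), NULL))
  list(expr = normalize_expression(raw_expr),
       conn = normalize_connectivity(raw_conn, fisher = FALSE))
}

# exact rank-1 tensor lambda * g o c o h with nonnegative h
rank1_tensor <- function(g, cvec, h, lambda = 1) {
  lambda * outer(g, cvec) %o% h
}

# atlas mirroring the 90-region AAL-style layout used in the source tables
aal_like_atlas <- function() {
  generate_atlas(c(14, 14, 4, 4, 18, 10, 18, 8))
}
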