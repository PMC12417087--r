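# Small in-code fixtures shared across test files.

# 5-gene expression matrix over 2 stages (3 + 2 samples), values chosen so
# genes span the activity bands.
toy_expr <- function() {
  m <- rbind(
    ga = c(1.0, 2.0, 3.0, 8.0, 9.0),
    gb = c(5.0, 5.0, 5.0, 5.0, 5.0),
    gc = c(0.0, 0.1, 0.2, 4.0, 4.1),
    gd = c(2.0, 1.0, 2.0, 1.0, 2.0),
    ge = c(10.0, 0.0, 10.0, 0.0, 10.0))
  colnames(m) <- c("s1", "s2", "s3", "s4", "s5")
  m
}

toy_stages <- function() {
  stage_partition(
    setNames(c("early", "early", "early", "late", "late"),
             paste0("s", 1:5)),
    stage_order = c("early", "late"))
}

# 5-gene chain-plus-triangle background with weights in (0, 1]
toy_background <- function() {
  background_network(
    from = c("ga", "ga", "gb", "gc", "gd"),
    to   = c("gb", "gc", "gc", "gd", "ge"),
    weight = c(0.9, 0.5, 0.8, 0.4, 1.0),
    genes = c("ga", "gb", "gc", "gd", "ge"))
}

# independently coded classical RWR on a dense matrix: column-normalizes
# with dangling columns sent to the seed, then iterates plain base-R
# arithmetic. Used as the oracle for the static-only ablation.
rwr_oracle <- function(adj_dense, seed_vec, gamma, tol = 1e-12,
                       max_iter = 100000L) {
  w <- as.matrix(adj_dense)
  seed_vec <- seed_vec / sum(seed_vec)
  for (j in seq_len(ncol(w))) {
    cs <- sum(w[, j])
    w[, j] <- if (cs > 0) w[, j] / cs else seed_vec
  }
  p <- seed_vec
  for (i in seq_len(max_iter)) {
    p_new <- (1 - gamma) * (w %*% p)[, 1] + gamma * seed_vec
    if (sum(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("oracle did not converge")
}

# random column-substochastic multilayer-like instance for solver oracles
random_instance <- function(n_genes, s_stages, seed) {
  set.seed(seed)
  genes <- sprintf("r%03d", seq_len(n_genes))
  n_edges <- max(n_genes, rpois(1, 2 * n_genes))
  from <- sample(genes, n_edges, replace = TRUE)
  to <- sample(genes, n_edges, replace = TRUE)
  keep <- from != to
  bg <- background_network(from[keep], to[keep],
                           runif(sum(keep)), genes = genes)
  stage_nets <- lapply(seq_len(s_stages), function(s) {
    ap <- sample(c(0, 0.68, 0.95, 0.99), n_genes, replace = TRUE)
    reweight_sample(bg, ap)
  })
  prs_raw <- runif(n_genes * (s_stages + 1))
  ml <- assemble_multilayer(bg, stage_nets, delta = runif(1), mu = runif(1))
  list(ml = ml, prs = prs_raw / sum(prs_raw))
}
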