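test_that("gene statistics match direct evaluation of the k-sigma formulas", {
  ex <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(ex) <- paste0("s", 1:3)
  st <- gene_stats(ex)
  # mean 2, unbiased variance 1 -> damping 1 - 1/2
  expect_equal(st["g1", "mean"], 2)
  expect_equal(st["g1", "sd"], 1)
  expect_equal(st["g1", "th1"], 2 + 1 * 1 * (1 - 1 / 2))
  expect_equal(st["g1", "th3"], 2 + 3 * 1 * (1 - 1 / 2))
  # constant gene: sd 0 collapses all thresholds onto the mean
  expect_equal(st["g2", "sd"], 0)
  expect_equal(unlist(st["g2", c("th1", "th2", "th3")], use.names = FALSE),
               c(5, 5, 5))
  expect_error(gene_stats(ex[, 1, drop = FALSE]), "2 genes and 2 samples")
})

test_that("thresholds are monotone in k and approach mean + k*sigma for large sigma", {
  set.seed(7)
  for (i in 1:20) {
    ex <- matrix(rnorm(40, sd = runif(1, 0.01, 10)), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
    st <- gene_stats(ex)
    expect_true(all(st$th1 <= st$th2 & st$th2 <= st$th3))
    expect_true(all(st$th1 >= st$mean))
  }
  # damping factor tends to 1 as sigma grows
  big <- matrix(c(-1, 1) * 1e3, 2, 10, byrow = TRUE,
                dimnames = list(c("flat", "wide"), paste0("s", 1:10)))
  big["wide", ] <- seq(-1e3, 1e3, length.out = 10) * sqrt(12) / 2
  st <- gene_stats(big)
  sigma <- st["wide", "sd"]
  for (k in 1:3)
    expect_equal(st["wide", paste0("th", k)],
                 st["wide", "mean"] + k * sigma,
                 tolerance = 1e-4)
})

test_that("active probabilities land exactly on the four band constants", {
  st <- data.frame(mean = 2, sd = 1, th1 = 2.5, th2 = 3.0, th3 = 3.5,
                   row.names = "g")
  ex <- matrix(c(3.5, 10, 3.0, 3.49, 2.5, 2.99, 2.49, -5), 1,
               dimnames = list("g", paste0("s", 1:8)))
  ap <- active_probabilities(ex, st)
  expect_identical(as.numeric(ap),
                   c(0.99, 0.99, 0.95, 0.95, 0.68, 0.68, 0, 0))
})

test_that("sample reweighting is a two-sided activity product", {
  net <- background_network("a", "b", 1, genes = c("a", "b", "c"))
  am <- reweight_sample(net, c(0.99, 0.95, 0))
  expect_equal(am["a", "b"], 0.99 * 1 * 0.95)
  expect_equal(am["b", "a"], am["a", "b"])
  # inactive gene zeroes its row and column
  net2 <- toy_background()
  am2 <- reweight_sample(net2, c(0, 1, 1, 1, 1))
  expect_true(all(am2["ga", ] == 0) && all(am2[, "ga"] == 0))
  # all-active identity
  am3 <- reweight_sample(net2, rep(1, 5))
  expect_equal(as.matrix(am3), as.matrix(net2$adjacency))
  expect_error(reweight_sample(net2, c(1, 1)), "length")
})

test_that("stage adjacency is the entrywise mean of its sample networks", {
  a1 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 0.4, dims = c(2, 2))
  a2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 0.6, dims = c(2, 2))
  expect_equal(stage_adjacency(list(a1, a2))[1, 2], 0.5)
  expect_equal(as.matrix(stage_adjacency(list(a1))), as.matrix(a1))
  expect_error(stage_adjacency(list()), "no sample networks")
})

test_that("dynamic networks compose correctly on a hand-computed toy", {
  ex <- toy_expr(); sp <- toy_stages(); net <- toy_background()
  nets <- build_dynamic_networks(ex, sp, net)
  expect_named(nets, c("early", "late"))

  # independent recomputation with plain loops
  m <- rowMeans(ex)
  v <- apply(ex, 1, function(x) sum((x - mean(x))^2) / (length(x) - 1))
  th <- sapply(1:3, function(k) m + k * sqrt(v) * (1 - 1 / (1 + v)))
  ap <- ex * 0
  for (g in rownames(ex)) for (s in colnames(ex)) {
    x <- ex[g, s]
    ap[g, s] <- if (x >= th[g, 3]) 0.99 else if (x >= th[g, 2]) 0.95
    else if (x >= th[g, 1]) 0.68 else 0
  }
  b <- as.matrix(net$adjacency)
  for (stage in c("early", "late")) {
    ids <- names(sp$assignment)[sp$assignment == stage]
    expected <- Reduce(`+`, lapply(ids, function(mm)
      outer(ap[, mm], ap[, mm]) * b)) / length(ids)
    expect_equal(as.matrix(nets[[stage]]), expected, ignore_attr = TRUE)
    # entrywise bound: stage weight never exceeds the static weight
    expect_true(all(as.matrix(nets[[stage]]) <= b + 1e-15))
  }

  # permuting samples within a stage leaves the stage network unchanged
  perm <- c("s3", "s1", "s2", "s4", "s5")
  nets_p <- build_dynamic_networks(ex[, perm], toy_stages(), net)
  expect_equal(as.matrix(nets_p$early), as.matrix(nets$early))
})

test_that("constant expression puts every sample in the top band", {
  ex <- matrix(5, 3, 4, dimnames = list(c("ga", "gb", "gc"), paste0("s", 1:4)))
  sp <- stage_partition(setNames(rep(c("x", "y"), each = 2), paste0("s", 1:4)),
                        c("x", "y"))
  net <- background_network(c("ga", "gb"), c("gb", "gc"), c(0.5, 0.2),
                            genes = c("ga", "gb", "gc"))
  nets <- build_dynamic_networks(ex, sp, net)
  expect_equal(nets$x["ga", "gb"], 0.99 * 0.5 * 0.99)
  expect_equal(nets$y["gb", "gc"], 0.99 * 0.2 * 0.99)
})
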