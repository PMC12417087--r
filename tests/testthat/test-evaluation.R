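ranked_fixture <- function(genes, scores) {
  rank_genes(setNames(scores, genes))
}

test_that("control-set schemes build the documented sets", {
  universe <- sprintf("g%03d", 1:100)
  test <- gene_set(universe[1:10], "disease")

  wg <- build_control_set(test, "WG", universe)
  expect_length(wg$controls, 90)
  expect_length(intersect(wg$controls, wg$test), 0)

  rc <- build_control_set(test$members[1:2], "RC", universe,
                          n_controls = 99, seed = 4)
  expect_lte(length(rc$controls), 2 * 99)
  expect_length(intersect(rc$controls, test$members[1:2]), 0)
  rc2 <- build_control_set(test$members[1:2], "RC", universe,
                           n_controls = 99, seed = 4)
  expect_identical(rc$controls, rc2$controls)   # same seed, same draw
  rc3 <- build_control_set(test$members[1:2], "RC", universe,
                           n_controls = 99, seed = 5)
  expect_false(identical(rc$controls, rc3$controls))

  expect_error(build_control_set(gene_set("absent"), "WG", universe),
               "no test gene")
})

test_that("ALI controls are the nearest same-chromosome genes by midpoint", {
  genes <- sprintf("p%02d", 1:10)
  ann <- data.frame(gene = genes, chrom = "chr1",
                    start = (1:10) * 1000, end = (1:10) * 1000 + 100,
                    stringsAsFactors = FALSE)
  cand <- build_control_set(genes[5], "ALI", universe = genes,
                            annotation = ann, n_controls = 4)
  expect_setequal(cand$controls, genes[c(4, 6, 3, 7)])
  # brute-force check of the distance ordering with symbol tie-break
  mid <- (ann$start + ann$end) / 2
  d <- abs(mid - mid[5]); names(d) <- genes
  expect_identical(sort(cand$controls),
                   sort(names(sort(d[-5]))[1:4]))
  # short chromosome: take all available with a message
  expect_message(
    small <- build_control_set(genes[5], "ALI", universe = genes[4:6],
                               annotation = ann, n_controls = 4),
    "only 2")
  expect_setequal(small$controls, genes[c(4, 6)])
  expect_error(build_control_set(genes[5], "ALI", universe = genes),
               "coordinates")
})

test_that("top-k precision and recall count hits in the restricted list", {
  rk <- ranked_fixture(letters[1:10], 10:1)
  cand <- structure(list(test = c("a", "f"), controls = letters[2:5],
                         scheme = "WG", seed = NULL),
                    class = "candidate_set")
  # restricted list is a,b,c,d,e,f; top-5 holds 1 of the 2 test genes
  tk <- topk_metrics(rk, cand, ks = c(5L))
  expect_equal(tk$precision, 1 / 5)
  expect_equal(tk$recall, 1 / 2)
  # perfect ranking at k = |test|
  cand2 <- structure(list(test = c("a", "b"), controls = c("c", "d"),
                          scheme = "WG", seed = NULL),
                     class = "candidate_set")
  tk2 <- topk_metrics(rk, cand2, ks = 2L)
  expect_equal(tk2$precision, 1)
  expect_equal(tk2$recall, 1)
  # no test genes in top-k
  cand3 <- structure(list(test = "f", controls = letters[1:5],
                          scheme = "WG", seed = NULL),
                     class = "candidate_set")
  tk3 <- topk_metrics(rk, cand3, ks = 3L)
  expect_equal(tk3$precision, 0)
  expect_equal(tk3$recall, 0)
  expect_warning(topk_metrics(rk, cand3, ks = 50L), "truncated")
})

test_that("recall is monotone in k and the hit identity holds", {
  set.seed(21)
  for (i in 1:5) {
    genes <- sprintf("g%03d", 1:60)
    rk <- ranked_fixture(genes, runif(60))
    test <- sample(genes, 8)
    cand <- build_control_set(test, "WG", genes)
    tk <- topk_metrics(rk, cand, ks = c(5L, 10L, 20L, 40L, 60L))
    expect_true(all(diff(tk$recall) >= 0))
    expect_equal(tk$precision * tk$k, tk$hits)
    expect_equal(tk$recall * length(cand$test), tk$hits)
  }
})

test_that("AUROC and AUPRC match hand-derived and brute-force values", {
  # perfect separation
  rk <- ranked_fixture(c("t1", "t2", "c1", "c2"), c(4, 3, 2, 1))
  cand <- structure(list(test = c("t1", "t2"), controls = c("c1", "c2"),
                         scheme = "WG", seed = NULL),
                    class = "candidate_set")
  cm <- curve_metrics(rk, cand)
  expect_equal(cm$auroc, 1)
  expect_equal(cm$auprc, 1)

  # interleaved (+,-,+,-): 3 of 4 (positive, control) pairs concordant
  rk2 <- ranked_fixture(c("t1", "c1", "t2", "c2"), c(4, 3, 2, 1))
  expect_equal(curve_metrics(rk2, cand)$auroc, 0.75)

  # brute-force Mann-Whitney oracle on random instances with ties
  set.seed(33)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    genes <- sprintf("g%04d", 1:n)
    scores <- sample(round(runif(n), 2))          # rounded -> frequent ties
    rk3 <- ranked_fixture(genes, scores)
    test <- sample(genes, sample(3:10, 1))
    cand3 <- build_control_set(test, "WG", genes)
    s <- setNames(scores, genes)
    u <- 0
    for (p in cand3$test) for (q in cand3$controls)
      u <- u + unname((s[p] > s[q]) + 0.5 * (s[p] == s[q]))
    expect_equal(curve_metrics(rk3, cand3)$auroc,
                 u / (length(cand3$test) * length(cand3$controls)))
  }

  # label-independent scores give AUROC near 1/2
  genes <- sprintf("g%04d", 1:2000)
  rk4 <- ranked_fixture(genes, runif(2000))
  cand4 <- build_control_set(sample(genes, 200), "WG", genes)
  expect_lt(abs(curve_metrics(rk4, cand4)$auroc - 0.5), 0.05)

  expect_error(
    curve_metrics(rk, structure(list(test = c("t1", "t2", "c1", "c2"),
                                     controls = "zz", scheme = "WG"),
                                class = "candidate_set")),
    "both test and control")
})
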