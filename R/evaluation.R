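#' Build a control gene set for benchmarking
#'
#' Constructs the control set `Setc` complementing a test set of known
#' disease genes under one of three schemes:
#' * `ALI` (artificial linked interval): for each test gene, the `n_controls`
#'   genes nearest on the same chromosome by midpoint distance, excluding all
#'   test genes — emulates linkage/association candidate intervals.
#' * `RC` (randomized control): `n_controls` genes drawn uniformly without
#'   replacement per test gene from the universe minus the test set —
#'   emulates exome-sequencing candidate lists.
#' * `WG` (whole genome): every universe gene outside the test set.
#'
#' Controls drawn for different test genes may coincide; the pooled control
#' set is deduplicated, and a gene in the test set is never a control.
#'
#' @param test A `gene_set` (or character vector) of known disease genes;
#'   only members present in `universe` are used.
#' @param scheme One of `"ALI"`, `"RC"`, `"WG"`.
#' @param universe Character vector of ranked genes (the candidate pool).
#' @param annotation Gene coordinate data.frame (see
#'   [read_gene_coordinates()]); required for `ALI`.
#' @param n_controls Controls per test gene (ALI, RC); default 99.
#' @param seed Integer seed for the RC draw; required for reproducibility.
#' @return A `candidate_set`: list with `test`, `controls`, `scheme`, `seed`.
#' @export
build_control_set <- function(test, scheme = c("WG", "RC", "ALI"),
                              universe, annotation = NULL,
                              n_controls = 99L, seed = NULL) {
  scheme <- match.arg(scheme)
  members <- if (inherits(test, "gene_set")) test$members else
    unique(as.character(test))
  test_in <- intersect(members, universe)
  if (!length(test_in)) stop("no test gene present in the ranking universe")
  pool <- setdiff(universe, test_in)
  controls <- switch(scheme,
    WG = pool,
    RC = {
      if (!is.null(seed)) {
        old <- get_rng_state()
        on.exit(restore_rng_state(old), add = TRUE)
        set.seed(seed)
      }
      unique(unlist(lapply(test_in, function(g)
        sample(pool, min(n_controls, length(pool))))))
    },
    ALI = {
      if (is.null(annotation)) stop("ALI scheme requires gene coordinates")
      ann <- annotation[annotation$gene %in% universe, , drop = FALSE]
      mid <- setNames((ann$start + ann$end) / 2, ann$gene)
      chrom <- setNames(ann$chrom, ann$gene)
      unique(unlist(lapply(test_in, function(g) {
        if (!g %in% names(mid)) {
          warning("test gene '", g, "' has no coordinates; skipped for ALI")
          return(character())
        }
        cand <- setdiff(names(chrom)[chrom == chrom[g]], test_in)
        if (length(cand) < n_controls)
          message("ALI: only ", length(cand), " same-chromosome control(s) ",
                  "available for test gene '", g, "'")
        d <- abs(mid[cand] - mid[g])
        cand[order(d, cand, method = "radix")][seq_len(min(n_controls,
                                                           length(cand)))]
      })))
    })
  if (!length(controls)) stop("empty control set under scheme ", scheme)
  structure(list(test = test_in, controls = controls, scheme = scheme,
                 seed = seed),
            class = "candidate_set")
}

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

# restrict a ranking to the candidate set, preserving rank order
restrict_ranking <- function(ranking, cand) {
  set_all <- c(cand$test, cand$controls)
  df <- as.data.frame(ranking)
  df <- df[df$gene %in% set_all, , drop = FALSE]
  if (!nrow(df)) stop("ranking contains no candidate gene")
  df
}

#' Top-k precision and recall over a candidate set
#'
#' The ranking is first restricted to the candidate set (test plus
#' controls); the top-k slice `Rk` of that restricted list then gives
#' `Topk_Precision = |Rk n test| / k` and `Topk_Recall = |Rk n test| / |test|`.
#'
#' @param ranking A `ranked_gene_list`.
#' @param cand A `candidate_set`.
#' @param ks Integer vector of cutoffs; default `c(5, 10, 50, 100, 200)`.
#' @return data.frame with columns `k`, `hits`, `precision`, `recall`.
#' @export
topk_metrics <- function(ranking, cand, ks = c(5L, 10L, 50L, 100L, 200L)) {
  df <- restrict_ranking(ranking, cand)
  n_test <- length(cand$test)
  res <- lapply(ks, function(k) {
    if (k > nrow(df)) {
      warning("k = ", k, " exceeds candidate-set size ", nrow(df),
              "; truncated")
      k <- nrow(df)
    }
    hits <- sum(df$gene[seq_len(k)] %in% cand$test)
    data.frame(k = k, hits = hits, precision = hits / k,
               recall = hits / n_test)
  })
  do.call(rbind, res)
}

#' AUROC and AUPRC over a candidate set
#'
#' Restricts the ranking to the candidate set, labels test genes positive,
#' and computes the area under the ROC curve (rank-sum form, equivalent to
#' the normalized Mann-Whitney U, with tied scores contributing half) and
#' the area under the precision-recall curve (step interpolation over
#' distinct score thresholds).
#'
#' @param ranking A `ranked_gene_list`.
#' @param cand A `candidate_set`.
#' @return List with `auroc` and `auprc`.
#' @export
curve_metrics <- function(ranking, cand) {
  df <- restrict_ranking(ranking, cand)
  pos <- df$gene %in% cand$test
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("candidate set must contain both test and control genes")
  r <- rank(df$score)                       # ties share average rank
  auroc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # PR curve over distinct thresholds, descending score
  o <- order(-df$score)
  sc <- df$score[o]; lab <- pos[o]
  cut <- sort(unique(c(which(diff(sc) != 0), length(sc))))
  tp <- cumsum(lab)[cut]
  fp <- cumsum(!lab)[cut]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  auprc <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, auprc = auprc)
}

#' Full evaluation report for one ranking and scheme
#'
#' Convenience wrapper combining [build_control_set()], [topk_metrics()] and
#' [curve_metrics()].
#'
#' @inheritParams build_control_set
#' @inheritParams topk_metrics
#' @param ranking A `ranked_gene_list`.
#' @return An `evaluation_report`: list with `scheme`, `topk` (data.frame),
#'   `auroc`, `auprc`, `n_test`, `n_controls_total`, `seed`.
#' @export
evaluate_ranking <- function(ranking, test, scheme = c("WG", "RC", "ALI"),
                             annotation = NULL, n_controls = 99L,
                             seed = NULL, ks = c(5L, 10L, 50L, 100L, 200L)) {
  scheme <- match.arg(scheme)
  cand <- build_control_set(test, scheme, universe = ranking$gene,
                            annotation = annotation,
                            n_controls = n_controls, seed = seed)
  curves <- curve_metrics(ranking, cand)
  structure(list(scheme = scheme,
                 topk = topk_metrics(ranking, cand, ks),
                 auroc = curves$auroc, auprc = curves$auprc,
                 n_test = length(cand$test),
                 n_controls_total = length(cand$controls),
                 seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (scheme=", x$scheme, "): ", x$n_test, " test vs ",
      x$n_controls_total, " control genes\n", sep = "")
  cat(sprintf("AUROC = %.4f, AUPRC = %.4f\n", x$auroc, x$auprc))
  print(x$topk, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as tab-separated text
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  lines <- c(sprintf("# scheme\t%s", report$scheme),
             sprintf("# n_test\t%d", report$n_test),
             sprintf("# n_controls\t%d", report$n_controls_total),
             sprintf("AUROC\t%s", fmt_num(report$auroc)),
             sprintf("AUPRC\t%s", fmt_num(report$auprc)),
             sprintf("Top%d_Precision\t%s", report$topk$k,
                     fmt_num(report$topk$precision)),
             sprintf("Top%d_Recall\t%s", report$topk$k,
                     fmt_num(report$topk$recall)))
  writeLines(lines, path)
  invisible(path)
}
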