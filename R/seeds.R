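#' Stage-wise differential-expression scores
#'
#' For each stage, compares the stage's samples against all other samples
#' with a two-sample test per gene and returns the absolute test statistic.
#' Genes that change most sharply at a given stage thus receive the most
#' seed mass in that stage's layer. The default statistic is the Welch
#' two-sample t; `score_fun` accepts any drop-in replacement (e.g. a
#' moderated t computed externally) with the same signature, and
#' `precomputed` accepts a ready-made gene x stage score table.
#'
#' Genes whose two group variances are both zero are scored 0 rather than
#' infinite: with no within-group variation the statistic is undefined and
#' such genes carry no usable evidence.
#'
#' @param expr Expression matrix.
#' @param stages A `stage_partition`.
#' @param score_fun Function `(x_in, x_out) -> numeric` taking the two
#'   gene-row submatrices (in-stage, out-of-stage) and returning one
#'   statistic per gene. Default: vectorized Welch t.
#' @param precomputed Optional numeric matrix (genes x stages, dimnames
#'   matching) of externally computed statistics; absolute values are taken.
#' @return Numeric matrix, genes x stages, of non-negative scores.
#' @export
stage_differential_scores <- function(expr, stages, score_fun = welch_t,
                                      precomputed = NULL) {
  if (!is.null(precomputed)) {
    stopifnot(identical(rownames(precomputed), rownames(expr)),
              identical(colnames(precomputed), stages$stage_labels))
    return(abs(precomputed))
  }
  out <- vapply(stages$stage_labels, function(s) {
    inset <- stages$assignment == s
    if (sum(inset) < 2L || sum(!inset) < 2L)
      stop("stage '", s, "' or its complement has fewer than 2 samples")
    abs(score_fun(expr[, inset, drop = FALSE], expr[, !inset, drop = FALSE]))
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Vectorized Welch two-sample t statistic
#'
#' One statistic per gene (row) for in-group versus out-group samples, with
#' unpooled variances. Rows with zero denominator return 0.
#'
#' @param x_in,x_out Numeric matrices (same genes in rows).
#' @return Numeric vector of t statistics (signed).
#' @export
welch_t <- function(x_in, x_out) {
  n1 <- ncol(x_in); n2 <- ncol(x_out)
  m1 <- rowMeans(x_in); m2 <- rowMeans(x_out)
  v1 <- rowSums((x_in - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x_out - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- numeric(length(m1))
  pos <- se2 > 0
  t[pos] <- (m1[pos] - m2[pos]) / sqrt(se2[pos])
  t
}

#' Background-layer seed: across-stage mean score
#'
#' The background layer has no stage of its own; its seed is the arithmetic
#' mean of the per-stage scores, so genes differential in any stage
#' contribute, with persistent signals weighted most.
#'
#' @param stage_scores Genes x stages score matrix.
#' @return Numeric vector (one mean score per gene).
#' @export
background_seed <- function(stage_scores) {
  rowMeans(as.matrix(stage_scores))
}

#' Assemble the normalized restart vector
#'
#' Stacks the seed scores in the multilayer block order — background mean
#' first, then the S stage vectors in temporal order — and divides by the
#' grand total so the restart vector is a probability distribution over all
#' multilayer nodes. `static_only` mode uses the normalized background mean
#' alone; `dynamic_only` stacks only the stage vectors.
#'
#' @param stage_scores Genes x stages score matrix (non-negative).
#' @param smean Background seed; defaults to [background_seed()] of
#'   `stage_scores`.
#' @param mode One of `"full"`, `"static_only"`, `"dynamic_only"`.
#' @return A `restart_vector`: list with `prs` (normalized stacked vector),
#'   `mode`, `n`, `s`.
#' @export
assemble_restart <- function(stage_scores, smean = NULL,
                             mode = c("full", "static_only", "dynamic_only")) {
  mode <- match.arg(mode)
  stage_scores <- as.matrix(stage_scores)
  if (any(stage_scores < 0)) stop("seed scores must be non-negative")
  if (is.null(smean)) smean <- background_seed(stage_scores)
  raw <- switch(mode,
    full = c(smean, as.numeric(stage_scores)),
    static_only = smean,
    dynamic_only = as.numeric(stage_scores))
  total <- sum(raw)
  if (total <= 0)
    stop("all seed scores are zero: no restart information")
  structure(list(prs = unname(raw) / total, mode = mode,
                 n = nrow(stage_scores),
                 s = if (mode == "static_only") 0L else ncol(stage_scores)),
            class = "restart_vector")
}
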