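#' Per-gene activity statistics and k-sigma thresholds
#'
#' For each gene, computes the mean and unbiased standard deviation of its
#' expression over all samples, and the three k-sigma activity thresholds
#'
#' \deqn{Th_k = \bar{G} + k \sigma \left(1 - \frac{1}{1+\sigma^2}\right),
#'       \quad k = 1, 2, 3.}
#'
#' The damping factor `1 - 1/(1+sigma^2)` shrinks the thresholds of
#' low-variance genes toward their mean, so that noisy flat profiles are not
#' declared active by chance; as the variance grows the factor approaches 1
#' and the rule becomes the classical k-sigma cut.
#'
#' Statistics are computed jointly over all M samples (not per stage) so that
#' activity calls are comparable across stages.
#'
#' @param expr Expression matrix (genes x samples), M >= 2.
#' @return A data.frame with one row per gene: `mean`, `sd`, `th1`, `th2`,
#'   `th3`.
#' @export
gene_stats <- function(expr) {
  expr <- validate_expression(expr)
  m <- rowMeans(expr)
  # unbiased variance, denominator M - 1
  v <- rowSums((expr - m)^2) / (ncol(expr) - 1L)
  s <- sqrt(v)
  damp <- 1 - 1 / (1 + v)
  out <- data.frame(mean = m, sd = s,
                    th1 = m + 1 * s * damp,
                    th2 = m + 2 * s * damp,
                    th3 = m + 3 * s * damp)
  rownames(out) <- rownames(expr)
  out
}

#' Gene active probabilities per sample
#'
#' Maps each expression value onto one of four activity levels by its
#' position relative to the gene's k-sigma thresholds:
#' value >= Th3 gives 0.99; \[Th2, Th3) gives 0.95; \[Th1, Th2) gives 0.68;
#' below Th1 gives 0. For a constant gene (sd 0) all thresholds collapse to
#' the mean, so every sample lands in the top band.
#'
#' @param expr Expression matrix.
#' @param stats Output of [gene_stats()] computed from the same matrix.
#' @return Numeric matrix of the same shape as `expr` with entries in
#'   \{0, 0.68, 0.95, 0.99\}.
#' @export
active_probabilities <- function(expr, stats) {
  stopifnot(identical(rownames(expr), rownames(stats)))
  ap <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  ap[expr >= stats$th1] <- 0.68
  ap[expr >= stats$th2] <- 0.95
  ap[expr >= stats$th3] <- 0.99
  ap
}

#' Reweight the static network by one sample's active probabilities
#'
#' Each edge weight is scaled by the active probabilities of both endpoint
#' genes: `A'[i, j] = ap[i] * A[i, j] * ap[j]` (a two-sided broadcasting
#' product). An inactive gene (probability 0) disconnects entirely in that
#' sample.
#'
#' @param background A `background_network`.
#' @param ap_m Numeric vector of active probabilities aligned with
#'   `background$genes`.
#' @return Sparse symmetric adjacency matrix of the sample network.
#' @export
reweight_sample <- function(background, ap_m) {
  if (length(ap_m) != length(background$genes))
    stop("active-probability vector length (", length(ap_m),
         ") does not match network size (", length(background$genes), ")")
  d <- Diagonal(x = as.numeric(ap_m))
  out <- d %*% background$adjacency %*% d
  dimnames(out) <- dimnames(background$adjacency)
  out
}

#' Stage adjacency as the mean of its sample networks
#'
#' The dynamic network of a stage averages the reweighted adjacencies of the
#' stage's samples entrywise, so an edge's stage weight reflects how
#' consistently both endpoints are active across the stage's patients.
#'
#' @param sample_networks Non-empty list of same-shaped sparse adjacencies.
#' @return Sparse symmetric stage adjacency.
#' @export
stage_adjacency <- function(sample_networks) {
  if (!length(sample_networks)) stop("stage has no sample networks")
  Reduce(`+`, sample_networks) / length(sample_networks)
}

#' Build the ordered per-stage dynamic networks
#'
#' Composes [gene_stats()], [active_probabilities()], [reweight_sample()] and
#' [stage_adjacency()]: activity statistics are computed once over all
#' samples, every sample's network is reweighted from the shared static
#' adjacency, and sample networks are averaged within each stage.
#'
#' @param expr Expression matrix, genes aligned with `background$genes`.
#' @param stages A `stage_partition` over the samples of `expr`.
#' @param background A `background_network`.
#' @return Named list of S sparse stage adjacencies in temporal order.
#' @export
build_dynamic_networks <- function(expr, stages, background) {
  if (!identical(rownames(expr), background$genes))
    stop("expression matrix and background network must share gene order; ",
         "see align_universe()")
  ap <- active_probabilities(expr, gene_stats(expr))
  out <- lapply(stages$stage_labels, function(s) {
    ids <- names(stages$assignment)[stages$assignment == s]
    stage_adjacency(lapply(ids, function(m) reweight_sample(background, ap[, m])))
  })
  names(out) <- stages$stage_labels
  out
}
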