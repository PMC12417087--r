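#' Random walk with restart to convergence
#'
#' Iterates `P_{t+1} = (1 - gamma) * TLc %*% P_t + gamma * PRS` from
#' `P_0 = PRS` until the L1 difference between successive iterates falls
#' below `tol`. With a column-stochastic transition matrix and a normalized
#' restart vector every iterate is a probability distribution, and for
#' `gamma > 0` the iteration contracts at rate `1 - gamma` toward the unique
#' stationary vector.
#'
#' @param tlc Column-stochastic (sparse) transition matrix.
#' @param prs Restart vector (a `restart_vector` or bare numeric summing
#'   to 1).
#' @param gamma Restart probability in (0, 1\]; default 0.1.
#' @param tol L1 convergence tolerance; default 1e-6.
#' @param max_iter Iteration cap; default 1000.
#' @return A `propagation_state`: list with `p_inf` (stationary vector),
#'   `iterations`, `residual`, `gamma`, and the layout fields `mode`, `n`,
#'   `s` when `prs` carries them.
#' @export
propagate <- function(tlc, prs, gamma = 0.1, tol = 1e-6, max_iter = 1000L) {
  layout <- NULL
  if (inherits(prs, "restart_vector")) {
    layout <- prs[c("mode", "n", "s")]
    prs <- prs$prs
  }
  if (!is.numeric(gamma) || gamma <= 0 || gamma > 1)
    stop("gamma must lie in (0, 1]")
  if (abs(sum(prs) - 1) > 1e-8) stop("restart vector must sum to 1")
  if (nrow(tlc) != length(prs))
    stop("transition matrix and restart vector dimensions differ")
  p <- prs
  it <- 0L
  residual <- Inf
  while (it < max_iter) {
    p_next <- as.numeric((1 - gamma) * (tlc %*% p)) + gamma * prs
    residual <- sum(abs(p_next - p))
    p <- p_next
    it <- it + 1L
    if (residual < tol) break
  }
  if (residual >= tol)
    stop("propagation did not converge in ", max_iter,
         " iterations (final L1 residual ", signif(residual, 4), ")")
  structure(c(list(p_inf = p, iterations = it, residual = residual,
                   gamma = gamma), layout),
            class = "propagation_state")
}

#' Extract the background-layer scores
#'
#' Slices the first N entries (the background block) out of the stationary
#' vector; these are the method's final gene scores. In `static_only` mode
#' the whole vector is the background layer. `dynamic_only` mode has no
#' background layer; set `aggregate = TRUE` to get the per-gene mean over
#' the stage layers instead.
#'
#' @param state A `propagation_state` from [propagate()].
#' @param network The `multilayer_network` the walk ran on (provides gene
#'   names and layout when the state lacks them).
#' @param aggregate For `dynamic_only` mode, average the stage layers.
#' @return Named numeric vector of length N.
#' @export
background_scores <- function(state, network, aggregate = FALSE) {
  mode <- state$mode %||% network$mode
  n <- network$n
  p <- state$p_inf
  sc <- switch(mode,
    static_only = p,
    full = p[seq_len(n)],
    dynamic_only = {
      if (!aggregate)
        stop("dynamic_only mode has no background layer; ",
             "set aggregate = TRUE for the mean over stage layers")
      rowMeans(matrix(p, nrow = n))
    })
  setNames(sc, network$genes)
}

#' Rank genes by descending score
#'
#' Removes excluded genes (known disease genes, housekeeping genes, ...),
#' then sorts by descending score with ties broken by ascending gene symbol
#' so repeated runs are byte-identical.
#'
#' @param scores Named numeric vector of finite gene scores.
#' @param exclusions List of `gene_set`s (or character vectors) to drop.
#' @return A `ranked_gene_list`: data.frame with columns `gene`, `score`.
#' @export
rank_genes <- function(scores, exclusions = list()) {
  if (!all(is.finite(scores))) stop("gene scores must be finite")
  if (is.null(names(scores))) stop("scores must be a named vector")
  drop <- unique(unlist(lapply(exclusions, function(e)
    if (inherits(e, "gene_set")) e$members else as.character(e))))
  keep <- setdiff(names(scores), drop)
  if (!length(keep)) stop("no genes left after applying exclusion lists")
  sc <- scores[keep]
  ord <- order(-sc, names(sc), method = "radix")
  structure(data.frame(gene = names(sc)[ord], score = unname(sc[ord]),
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat("ranked_gene_list:", nrow(x), "genes; top of list:\n")
  print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
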