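#' Temporal transition matrix over the stage layers
#'
#' Assembles the block-tridiagonal transition structure of the S stage
#' layers: diagonal blocks `(1 - mu) * A[s]` (movement within a stage
#' network) and identity blocks `mu * I` between temporally adjacent stages
#' only (a walker may step to the same gene's counterpart in the previous or
#' next stage). Non-adjacent stage pairs are not connected.
#'
#' @param stage_networks Ordered list of S same-shaped stage adjacencies.
#' @param mu Inter-stage jump weight in \[0, 1\].
#' @return Sparse (S*N) x (S*N) matrix.
#' @export
temporal_transition <- function(stage_networks, mu) {
  if (!length(stage_networks)) stop("need at least one stage network")
  if (!is.numeric(mu) || mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  s <- length(stage_networks)
  n <- nrow(stage_networks[[1L]])
  blocks <- matrix(list(NULL), s, s)
  zero <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                       dims = c(n, n))
  eye <- Diagonal(n)
  for (a in seq_len(s)) {
    for (b in seq_len(s)) {
      blocks[[a, b]] <- if (a == b) (1 - mu) * stage_networks[[a]]
      else if (abs(a - b) == 1L) mu * eye
      else zero
    }
  }
  rows <- lapply(seq_len(s), function(a) do.call(cbind, blocks[a, ]))
  out <- do.call(rbind, rows)
  genes <- rownames(stage_networks[[1L]])
  if (!is.null(genes)) {
    lab <- paste(rep(names(stage_networks) %||% paste0("stage", seq_len(s)),
                     each = n), genes, sep = ".")
    dimnames(out) <- list(lab, lab)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full transition matrix of the background-temporal multilayer network
#'
#' Couples the static background layer B to the S-layer temporal transition
#' matrix TS in the block layout
#'
#' \deqn{T_L = \begin{pmatrix} (1-\delta) B & \delta J^\top \\
#'       \delta J & T_S \end{pmatrix}, \qquad
#'       J = \tfrac{1}{S}\, e \otimes I,}
#'
#' with `e` the all-ones S-vector and `I` the N x N identity: the background
#' copy of a gene feeds each of its S stage counterparts with weight
#' `delta / S`, and each stage copy feeds the background copy back. The TS
#' block is used as printed, not rescaled by `(1 - delta)`; column
#' normalization absorbs the resulting non-uniform column sums (set
#' `scale_ts = TRUE` for the rescaled variant).
#'
#' @param background A `background_network` (adjacency B).
#' @param ts Temporal transition matrix from [temporal_transition()].
#' @param delta Layer-type jump weight in \[0, 1\].
#' @param n_stages Number of stage layers S.
#' @param scale_ts If `TRUE`, use `(1 - delta) * TS` in the bottom-right
#'   block. Off by default.
#' @return Sparse (N*(S+1)) x (N*(S+1)) matrix; background block first.
#' @export
full_transition <- function(background, ts, delta, n_stages,
                            scale_ts = FALSE) {
  if (!is.numeric(delta) || delta < 0 || delta > 1)
    stop("delta must lie in [0, 1]")
  n <- length(background$genes)
  if (nrow(ts) != n * n_stages)
    stop("TS dimension does not match N * S")
  jt <- do.call(cbind, rep(list(Diagonal(n) / n_stages), n_stages)) # N x NS
  ts_block <- if (scale_ts) (1 - delta) * ts else ts
  out <- rbind(cbind((1 - delta) * background$adjacency, delta * jt),
               cbind(delta * Matrix::t(jt), ts_block))
  lab <- c(paste("background", background$genes, sep = "."),
           rownames(ts) %||% paste0("dyn", seq_len(n * n_stages)))
  dimnames(out) <- list(lab, lab)
  out
}

#' Column-normalize a transition matrix
#'
#' Divides every column by its sum so columns are probability distributions.
#' All-zero ("dangling") columns — a gene inactive in every sample of a stage
#' with no interlayer mass — are replaced by the teleport distribution, the
#' standard PageRank fix, so that total probability is conserved during
#' propagation.
#'
#' @param m Non-negative (sparse) matrix.
#' @param teleport Distribution used for dangling columns; `NULL` for
#'   uniform. Typically the restart vector.
#' @return Column-stochastic sparse matrix.
#' @export
column_normalize <- function(m, teleport = NULL) {
  cs <- Matrix::colSums(m)
  if (any(cs < 0)) stop("transition matrix must be non-negative")
  dangling <- which(cs == 0)
  scale <- numeric(length(cs))
  scale[cs > 0] <- 1 / cs[cs > 0]
  out <- m %*% Diagonal(x = scale)
  dimnames(out) <- dimnames(m)
  if (length(dangling)) {
    if (is.null(teleport)) teleport <- rep(1 / nrow(m), nrow(m))
    if (length(teleport) != nrow(m))
      stop("teleport vector length does not match matrix dimension")
    teleport <- teleport / sum(teleport)
    out[, dangling] <- matrix(teleport, nrow(m), length(dangling))
  }
  out
}

#' Assemble the multilayer network
#'
#' Builds the propagation substrate for one of three modes:
#' * `full` — background layer coupled to the S stage layers (the method's
#'   default substrate).
#' * `static_only` — the background network alone; propagation on it is a
#'   classical single-network random walk with restart (ablation).
#' * `dynamic_only` — the S-layer temporal network alone (ablation).
#'
#' @param background A `background_network`.
#' @param stage_networks Ordered list of stage adjacencies (may be `NULL`
#'   for `static_only`).
#' @param delta Background/stage coupling weight, default 0.5.
#' @param mu Adjacent-stage coupling weight, default 0.5.
#' @param mode One of `"full"`, `"static_only"`, `"dynamic_only"`.
#' @param scale_ts Passed to [full_transition()].
#' @return A `multilayer_network`: list with the unnormalized `transition`
#'   matrix, `mode`, `genes`, `n`, `s`, `delta`, `mu`.
#' @export
assemble_multilayer <- function(background, stage_networks = NULL,
                                delta = 0.5, mu = 0.5,
                                mode = c("full", "static_only", "dynamic_only"),
                                scale_ts = FALSE) {
  mode <- match.arg(mode)
  n <- length(background$genes)
  s <- length(stage_networks)
  if (mode != "static_only" && s == 0L)
    stop("mode '", mode, "' requires at least one stage network")
  transition <- switch(mode,
    static_only = background$adjacency,
    dynamic_only = temporal_transition(stage_networks, mu),
    full = full_transition(background, temporal_transition(stage_networks, mu),
                           delta, s, scale_ts = scale_ts))
  structure(list(transition = transition, mode = mode,
                 genes = background$genes, n = n,
                 s = if (mode == "static_only") 0L else s,
                 delta = delta, mu = mu),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat("multilayer_network (mode=", x$mode, "): N=", x$n, ", S=", x$s,
      ", total nodes=", nrow(x$transition), "\n", sep = "")
  invisible(x)
}
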