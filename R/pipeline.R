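#' Rank genes end to end
#'
#' Runs the full prioritization pipeline: align the gene universe, build the
#' per-stage dynamic networks, assemble the multilayer transition matrix,
#' compute differential-expression seeds, propagate to the stationary
#' distribution, and rank genes by their background-layer scores.
#'
#' Inputs may be in-memory objects or file paths (dispatched by type);
#' file inputs use the readers of this package.
#'
#' @param expr Expression matrix or path to an expression TSV.
#' @param stages A `stage_partition` or path to a stage-annotation TSV.
#' @param network A `background_network` or path to an edge-list TSV.
#' @param delta,mu Multilayer coupling weights in \[0, 1\]; defaults 0.5.
#' @param gamma Restart probability; default 0.1.
#' @param tol,max_iter Convergence controls; defaults 1e-6 and 1000.
#' @param mode `"full"`, `"static_only"` (classical single-network walk) or
#'   `"dynamic_only"`.
#' @param exclusions List of `gene_set`s / character vectors to drop from
#'   the final ranking (e.g. housekeeping genes).
#' @param score_divisor Edge-score divisor when `network` is a path.
#' @param scale_ts Passed to [full_transition()].
#' @param out Optional path; when set, the ranking is written with a
#'   provenance header via [write_ranking()].
#' @return A `ranked_gene_list` with a `params` attribute recording all
#'   parameters and the aligned universe size, plus a `state` attribute
#'   with the converged `propagation_state`.
#' @export
run_rank <- function(expr, stages, network,
                     delta = 0.5, mu = 0.5, gamma = 0.1,
                     tol = 1e-6, max_iter = 1000L,
                     mode = c("full", "static_only", "dynamic_only"),
                     exclusions = list(), score_divisor = 1000,
                     scale_ts = FALSE, out = NULL) {
  mode <- match.arg(mode)
  if (is.character(expr)) expr <- read_expression(expr)
  if (is.character(network)) network <- read_edge_list(network, score_divisor)
  if (is.character(stages)) stages <- read_stage_annotation(stages, expr)
  aligned <- align_universe(expr, network)
  expr <- aligned$expr; network <- aligned$network
  stage_nets <- if (mode == "static_only") NULL else
    build_dynamic_networks(expr, stages, network)
  ml <- assemble_multilayer(network, stage_nets, delta = delta, mu = mu,
                            mode = mode, scale_ts = scale_ts)
  scores <- stage_differential_scores(expr, stages)
  rs <- assemble_restart(scores, mode = mode)
  tlc <- column_normalize(ml$transition, teleport = rs$prs)
  state <- propagate(tlc, rs, gamma = gamma, tol = tol, max_iter = max_iter)
  gene_scores <- background_scores(state, ml,
                                   aggregate = (mode == "dynamic_only"))
  ranking <- rank_genes(gene_scores, exclusions)
  params <- list(delta = delta, mu = mu, gamma = gamma, tol = tol,
                 max_iter = max_iter, mode = mode,
                 universe_size = length(network$genes),
                 stages = stages$stage_labels,
                 iterations = state$iterations)
  attr(ranking, "params") <- params
  attr(ranking, "state") <- state
  if (!is.null(out)) {
    hdr <- sprintf("%s=%s", names(params),
                   vapply(params, function(p) paste(p, collapse = ","),
                          character(1)))
    write_ranking(ranking, out, header = hdr)
  }
  ranking
}

#' Evaluate a ranking against known disease genes
#'
#' Wrapper over [evaluate_ranking()] accepting file paths, writing a
#' tab-separated report when `out` is given.
#'
#' @param ranking A `ranked_gene_list` or path to a ranking file.
#' @param disease_genes A `gene_set` or path to a one-symbol-per-line list.
#' @param scheme Control-set scheme (`"WG"`, `"RC"`, `"ALI"`).
#' @param coords Coordinate data.frame or path (required for ALI).
#' @param n_controls Controls per test gene; default 99.
#' @param seed RC sampling seed.
#' @param ks Top-k cutoffs.
#' @param out Optional report path.
#' @return An `evaluation_report`.
#' @export
run_evaluate <- function(ranking, disease_genes,
                         scheme = c("WG", "RC", "ALI"), coords = NULL,
                         n_controls = 99L, seed = NULL,
                         ks = c(5L, 10L, 50L, 100L, 200L), out = NULL) {
  scheme <- match.arg(scheme)
  if (is.character(ranking)) ranking <- read_ranking(ranking)
  if (is.character(disease_genes)) disease_genes <- read_gene_list(disease_genes)
  if (is.character(coords)) coords <- read_gene_coordinates(coords)
  if (scheme == "ALI" && is.null(coords))
    stop("ALI scheme requires a gene coordinate table")
  report <- evaluate_ranking(ranking, disease_genes, scheme,
                             annotation = coords, n_controls = n_controls,
                             seed = seed, ks = ks)
  if (!is.null(out)) write_report(report, out)
  report
}
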