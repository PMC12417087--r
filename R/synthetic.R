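#' Configuration for the synthetic staged-expression benchmark
#'
#' Defines the statistical structure the ranking method assumes: a sparse
#' interaction network with a planted disease module whose genes show a
#' stage-progressive mean shift in expression. Defaults emulate a
#' desk-scale, log2-microarray-like staged case/control design: 500 genes on
#' a preferential-attachment network (3 edges per new node), a 20-gene
#' module, 3 disease stages with 8 samples each, and a non-decreasing effect
#' schedule of 0.5 / 1.5 / 3 within-gene standard deviations.
#'
#' @param n_genes Number of genes/nodes.
#' @param network_model `"preferential_attachment"` (connected, scale-free)
#'   or `"two_cluster"` (two dense blocks joined by weak bridges).
#' @param edges_per_node Attachment edges per new node (PA model).
#' @param module_size Planted module size (< n_genes).
#' @param s_stages Number of disease stages S.
#' @param samples_per_stage Samples per stage.
#' @param baseline_mean,baseline_sd Mean and between-gene sd of per-gene
#'   baseline expression (log2-like scale).
#' @param effect_schedule Non-decreasing per-stage mean shift of module
#'   genes, in units of `noise_sd`.
#' @param noise_sd Within-gene, per-sample noise sd.
#' @param module_adjacency Fraction of the module grown as a connected
#'   neighborhood (the rest drawn at random), so network propagation has
#'   topological signal to exploit.
#' @param inter_cluster_weight Bridge-edge weight for the two-cluster model.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 500L,
                             network_model = c("preferential_attachment",
                                               "two_cluster"),
                             edges_per_node = 3L,
                             module_size = 20L,
                             s_stages = 3L,
                             samples_per_stage = 8L,
                             baseline_mean = 7,
                             baseline_sd = 1,
                             effect_schedule = c(0.5, 1.5, 3.0),
                             noise_sd = 1,
                             module_adjacency = 0.8,
                             inter_cluster_weight = 1e-3,
                             seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(module_size < n_genes, baseline_sd > 0, noise_sd > 0,
            length(effect_schedule) == s_stages,
            samples_per_stage >= 2L, s_stages >= 2L || s_stages == 1L)
  if (is.unsorted(effect_schedule))
    stop("effect_schedule must be non-decreasing across stages")
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate the synthetic background network and gene coordinates
#'
#' Builds a connected undirected weighted network over `g1 ... g<n>` with
#' edge weights uniform in (0, 1), plus sequential gene coordinates on two
#' synthetic chromosomes (for artificial-linked-interval control sets).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A `synthetic_config`.
#' @return List with `network` (a `background_network`) and `annotation`
#'   (coordinate data.frame).
#' @export
generate_background <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  g <- switch(cfg$network_model,
    preferential_attachment =
      igraph::sample_pa(n, m = cfg$edges_per_node, directed = FALSE),
    two_cluster = {
      h <- n %/% 2L
      g1 <- igraph::sample_pa(h, m = cfg$edges_per_node, directed = FALSE)
      g2 <- igraph::sample_pa(n - h, m = cfg$edges_per_node, directed = FALSE)
      igraph::add_edges(igraph::disjoint_union(g1, g2), c(1L, h + 1L))
    })
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- runif(nrow(el))
  if (cfg$network_model == "two_cluster") {
    h <- n %/% 2L
    bridge <- (el[, 1L] <= h) != (el[, 2L] <= h)
    w[bridge] <- cfg$inter_cluster_weight
  }
  network <- background_network(genes[el[, 1L]], genes[el[, 2L]], w,
                                genes = genes)
  half <- ceiling(n / 2)
  idx_on_chrom <- c(seq_len(half), seq_len(n - half))
  annotation <- data.frame(
    gene = genes,
    chrom = rep(c("chr1", "chr2"), c(half, n - half)),
    start = idx_on_chrom * 10000 + 1,
    end = idx_on_chrom * 10000 + 5000,
    stringsAsFactors = FALSE)
  list(network = network, annotation = annotation)
}

#' Pick the planted disease module
#'
#' Grows `module_adjacency * module_size` genes as a connected patch around
#' a random start node, expanding the frontier with inverse-degree weighting
#' so the module is topologically coherent without being biased toward hub
#' genes (a hub-heavy truth set would look enriched to any degree-driven
#' ranking even with no expression signal). The remaining genes are drawn at
#' random elsewhere.
#'
#' @param cfg A `synthetic_config`.
#' @param network The generated `background_network`.
#' @return A `gene_set` named `"planted_module"`.
#' @export
generate_module <- function(cfg, network) {
  set.seed(cfg$seed + 1L)
  g <- igraph::graph_from_adjacency_matrix(network$adjacency,
                                           mode = "undirected",
                                           weighted = TRUE)
  deg <- igraph::degree(g)
  start <- sample(length(network$genes), 1L, prob = 1 / deg)
  n_adj <- min(cfg$module_size, ceiling(cfg$module_adjacency * cfg$module_size))
  core <- start
  frontier <- setdiff(as.integer(igraph::neighbors(g, start)), core)
  while (length(core) < n_adj && length(frontier)) {
    nxt <- if (length(frontier) == 1L) frontier else
      sample(frontier, 1L, prob = 1 / deg[frontier])
    core <- c(core, nxt)
    frontier <- setdiff(union(frontier,
                              as.integer(igraph::neighbors(g, nxt))), core)
  }
  rest <- sample(setdiff(seq_len(cfg$n_genes), core),
                 cfg$module_size - n_adj)
  gene_set(network$genes[sort(c(core, rest))], "planted_module")
}

#' Generate the staged expression matrix with the planted module
#'
#' Each gene gets a baseline level drawn from
#' `Normal(baseline_mean, baseline_sd)`; every sample value adds
#' `Normal(0, noise_sd)` noise, and module genes in stage s are additionally
#' shifted by `effect_schedule[s] * noise_sd`. Non-module genes are thus
#' exchangeable across stages (null genes), while module genes show a
#' monotone stage-progressive shift.
#'
#' @param cfg A `synthetic_config`.
#' @param network The generated `background_network` (fixes gene order).
#' @param module A `gene_set` of planted module genes.
#' @return List with `expr` (matrix), `stages` (a `stage_partition`) and
#'   `module` (the truth `gene_set`).
#' @export
generate_expression <- function(cfg, network, module) {
  set.seed(cfg$seed + 2L)
  genes <- network$genes
  n <- length(genes)
  s <- cfg$s_stages
  m_per <- cfg$samples_per_stage
  stage_labels <- sprintf("stage%d", seq_len(s))
  sample_ids <- as.vector(vapply(seq_len(s), function(k)
    sprintf("%s_rep%02d", stage_labels[k], seq_len(m_per)),
    character(m_per)))
  assignment <- setNames(rep(stage_labels, each = m_per), sample_ids)
  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  expr <- baseline + matrix(rnorm(n * s * m_per, 0, cfg$noise_sd), n)
  in_module <- genes %in% module$members
  shift <- rep(cfg$effect_schedule * cfg$noise_sd, each = m_per)
  expr[in_module, ] <- expr[in_module, ] +
    matrix(shift, sum(in_module), s * m_per, byrow = TRUE)
  dimnames(expr) <- list(genes, sample_ids)
  list(expr = validate_expression(expr),
       stages = stage_partition(assignment, stage_labels),
       module = module)
}

#' Generate and optionally write a complete synthetic dataset
#'
#' Runs [generate_background()], [generate_module()] and
#' [generate_expression()]; with `out_dir` set, writes `expr.tsv`,
#' `stages.tsv`, `network.tsv`, `coords.tsv` and `truth.txt` in the formats
#' the readers in this package expect.
#'
#' @param cfg A `synthetic_config`.
#' @param out_dir Optional output directory (created if missing).
#' @return List with `expr`, `stages`, `network`, `annotation`, `module`,
#'   `cfg`, invisibly when writing.
#' @export
simulate_dataset <- function(cfg = synthetic_config(), out_dir = NULL) {
  bg <- generate_background(cfg)
  module <- generate_module(cfg, bg$network)
  ex <- generate_expression(cfg, bg$network, module)
  out <- list(expr = ex$expr, stages = ex$stages, network = bg$network,
              annotation = bg$annotation, module = module, cfg = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    expr_df <- data.frame(gene = rownames(ex$expr), ex$expr,
                          check.names = FALSE)
    write.table(expr_df, file.path(out_dir, "expr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = names(ex$stages$assignment),
                           stage = unname(ex$stages$assignment)),
                file.path(out_dir, "stages.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_edge_list(bg$network$adjacency, file.path(out_dir, "network.tsv"))
    write.table(bg$annotation, file.path(out_dir, "coords.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(module$members, file.path(out_dir, "truth.txt"))
    return(invisible(out))
  }
  out
}
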