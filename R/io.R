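#' Read a gene-by-sample expression matrix
#'
#' Reads a tab-separated table whose first column holds gene symbols and whose
#' header row holds sample identifiers. Values must be finite numbers.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (genes in rows, samples in columns) with unique
#'   row and column names, validated by [validate_expression()].
#' @export
read_expression <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("expression table at '", path, "' is empty or has no sample columns")
  genes <- tab[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene identifier(s) in expression table: ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite expression value at gene '",
         genes[bad[1L, 1L]], "', sample '", colnames(tab)[-1L][bad[1L, 2L]],
         "' (row ", bad[1L, 1L], ", column ", bad[1L, 2L], ")")
  }
  dimnames(num) <- list(genes, colnames(tab)[-1L])
  validate_expression(num)
}

#' Validate an expression matrix
#'
#' Checks the invariants required downstream: unique gene and sample
#' identifiers, all values finite, at least 2 genes and 2 samples.
#'
#' @param x A numeric matrix with gene rownames and sample colnames.
#' @return `x`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("expression matrix needs at least 2 genes and 2 samples")
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  x
}

#' Read a sample-to-stage annotation table
#'
#' Two tab-separated columns (`sample`, `stage`), optionally a third numeric
#' `order` column giving the temporal position of each stage. Without an
#' order column, stage temporal order is the order of first appearance.
#'
#' @param path Path to the annotation file.
#' @param expr Expression matrix whose samples the annotation must cover.
#' @return A `stage_partition`: list with `stage_labels` (ordered), `assignment`
#'   (named character vector sample -> stage) and `counts` (samples per stage).
#' @export
read_stage_annotation <- function(path, expr) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("stage annotation at '", path, "' is empty or malformed")
  samples <- as.character(tab[[1L]])
  stage <- as.character(tab[[2L]])
  if (ncol(tab) >= 3L) {
    ord <- as.numeric(tab[[3L]])
    levels <- unique(stage[order(ord)])
  } else {
    levels <- unique(stage)
  }
  stage_partition(setNames(stage, samples), stage_order = levels, expr = expr)
}

#' Construct and validate a stage partition
#'
#' @param assignment Named character vector mapping sample id to stage label.
#' @param stage_order Stage labels in temporal order; defaults to order of
#'   first appearance in `assignment`.
#' @param expr Optional expression matrix; when given, the partition must
#'   cover exactly its samples.
#' @return A `stage_partition` object.
#' @export
stage_partition <- function(assignment, stage_order = unique(unname(assignment)),
                            expr = NULL) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("assignment must be a named vector with unique sample names")
  if (!setequal(stage_order, unique(assignment)))
    stop("stage_order must contain exactly the stages present in assignment")
  if (!is.null(expr)) {
    missing <- setdiff(colnames(expr), names(assignment))
    if (length(missing))
      stop("sample(s) missing from stage annotation: ",
           paste(missing, collapse = ", "))
    unknown <- setdiff(names(assignment), colnames(expr))
    if (length(unknown))
      stop("annotation contains unknown sample(s): ",
           paste(unknown, collapse = ", "))
    assignment <- assignment[colnames(expr)]
  }
  counts <- vapply(stage_order, function(s) sum(assignment == s), integer(1))
  if (any(counts < 2L))
    stop("every stage needs at least 2 samples; offending stage(s): ",
         paste(stage_order[counts < 2L], collapse = ", "))
  if (length(stage_order) < 2L) stop("at least 2 stages are required")
  structure(list(stage_labels = stage_order,
                 assignment = assignment,
                 counts = setNames(counts, stage_order)),
            class = "stage_partition")
}

#' @export
print.stage_partition <- function(x, ...) {
  cat("stage_partition:", length(x$stage_labels), "stages,",
      length(x$assignment), "samples\n")
  print(x$counts)
  invisible(x)
}

#' Read a weighted undirected edge list into a background network
#'
#' Three tab-separated columns (gene1, gene2, score). Scores are divided by
#' `score_divisor` so that STRING-style combined scores (0-1000) land in
#' \[0, 1\]. Duplicate undirected edges collapse to their maximum weight;
#' self-edges are dropped with a warning.
#'
#' @param path Path to the edge-list file.
#' @param score_divisor Positive scale divisor; 1000 for STRING scores,
#'   1 for already-scaled weights.
#' @return A `background_network`: list with `genes` (ordered node names) and
#'   `adjacency` (symmetric sparse weight matrix, zero diagonal).
#' @export
read_edge_list <- function(path, score_divisor = 1000) {
  stopifnot(is.numeric(score_divisor), score_divisor > 0)
  tab <- read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 3L)
    stop("edge list at '", path, "' is empty or has fewer than 3 columns")
  background_network(as.character(tab[[1L]]), as.character(tab[[2L]]),
                     as.numeric(tab[[3L]]) / score_divisor)
}

#' Construct and validate a background network from edge vectors
#'
#' @param from,to Character vectors of endpoint gene symbols.
#' @param weight Numeric edge weights, required to lie in \[0, 1\].
#' @param genes Optional node universe (ordered); defaults to the sorted
#'   union of endpoints.
#' @return A `background_network` object.
#' @export
background_network <- function(from, to, weight, genes = NULL) {
  stopifnot(length(from) == length(to), length(to) == length(weight))
  if (any(!is.finite(weight) | weight < 0))
    stop("edge weights must be finite and non-negative")
  if (any(weight > 1 + 1e-12))
    stop("edge weight ", max(weight), " exceeds 1 after scaling; ",
         "check score_divisor")
  self <- from == to
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped")
    from <- from[!self]; to <- to[!self]; weight <- weight[!self]
  }
  if (is.null(genes)) genes <- sort(unique(c(from, to)))
  if (anyDuplicated(genes)) stop("duplicate gene in node universe")
  i <- match(from, genes); j <- match(to, genes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint outside the node universe")
  n <- length(genes)
  # canonicalize undirected pairs and collapse duplicates by maximum weight
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- (lo - 1) * n + hi
  keep <- order(key, -weight)
  keep <- keep[!duplicated(key[keep])]
  lo <- lo[keep]; hi <- hi[keep]; w <- weight[keep]
  adj <- sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = rep(w, 2L),
                      dims = c(n, n), dimnames = list(genes, genes))
  structure(list(genes = genes, adjacency = adj), class = "background_network")
}

#' @export
print.background_network <- function(x, ...) {
  cat("background_network:", length(x$genes), "genes,",
      Matrix::nnzero(x$adjacency) / 2, "undirected edges\n")
  invisible(x)
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines ignored; duplicates collapsed.
#'
#' @param path Path to the list file.
#' @param name Optional set name (defaults to the file name).
#' @return A `gene_set`: list with `name` and `members` (unique symbols).
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- readLines(path)
  members <- unique(trimws(lines[nzchar(trimws(lines))]))
  if (!length(members)) stop("gene list at '", path, "' is empty")
  gene_set(members, name)
}

#' @rdname read_gene_list
#' @param members Character vector of gene symbols.
#' @export
gene_set <- function(members, name = "gene_set") {
  structure(list(name = name, members = unique(as.character(members))),
            class = "gene_set")
}

#' Read a gene coordinate table
#'
#' Four tab-separated columns with header: gene, chromosome, start, end
#' (integer base pairs, start <= end). Used to build artificial-linked-interval
#' control sets.
#'
#' @param path Path to the coordinate file.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_coordinates <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 4L)
    stop("coordinate table at '", path, "' is empty or has fewer than 4 columns")
  ann <- data.frame(gene = as.character(tab[[1L]]),
                    chrom = as.character(tab[[2L]]),
                    start = as.numeric(tab[[3L]]),
                    end = as.numeric(tab[[4L]]),
                    stringsAsFactors = FALSE)
  bad <- which(!is.finite(ann$start) | !is.finite(ann$end) |
                 ann$start < 0 | ann$end < 0 | ann$start > ann$end)
  if (length(bad))
    stop("malformed coordinate row for gene '", ann$gene[bad[1L]],
         "' (row ", bad[1L], "): need 0 <= start <= end")
  if (anyDuplicated(ann$gene)) stop("duplicate gene in coordinate table")
  ann
}

# full float precision, no padding: round trips are bit-identical
fmt_num <- function(x) trimws(formatC(x, digits = 17, format = "g"))

#' Write / read a gene ranking
#'
#' `write_ranking()` writes `rank<TAB>gene<TAB>score` with full floating-point
#' precision (17 significant digits) so that a write/read round trip is
#' bit-identical; `read_ranking()` parses it back.
#'
#' @param ranking A `ranked_gene_list` (see [rank_genes()]) or a data.frame
#'   with columns `gene` and `score`.
#' @param path Output path.
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`), used for run provenance.
#' @return `write_ranking()` returns `path` invisibly; `read_ranking()`
#'   returns a `ranked_gene_list`.
#' @export
write_ranking <- function(ranking, path, header = NULL) {
  df <- as.data.frame(ranking)
  if (nrow(df) == 0L) stop("refusing to write an empty ranking")
  lines <- c(if (length(header)) paste0("# ", header),
             "rank\tgene\tscore",
             sprintf("%d\t%s\t%s", seq_len(nrow(df)), df$gene,
                     fmt_num(df$score)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ranking
#' @export
read_ranking <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("ranking file at '", path, "' is empty")
  structure(data.frame(gene = as.character(tab$gene),
                       score = as.numeric(tab$score),
                       stringsAsFactors = FALSE),
            class = c("ranked_gene_list", "data.frame"))
}

#' Write a weighted adjacency matrix as a tab-separated edge list
#'
#' Emits one line per undirected edge (`gene1<TAB>gene2<TAB>weight`), upper
#' triangle only, for inspection of per-stage dynamic networks.
#'
#' @param adjacency Symmetric (sparse) matrix with gene dimnames.
#' @param path Output path.
#' @export
write_edge_list <- function(adjacency, path) {
  idx <- Matrix::which(adjacency != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  genes <- rownames(adjacency)
  lines <- sprintf("%s\t%s\t%s", genes[idx[, 1L]], genes[idx[, 2L]],
                   fmt_num(adjacency[idx]))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict expression and network to their common gene universe
#'
#' The activity model needs an expression profile for every network node, so
#' the working universe is the intersection of the expression gene set and
#' the network gene set. Genes outside the intersection are dropped with a
#' logged count.
#'
#' @param expr Expression matrix.
#' @param network A `background_network`.
#' @return List with aligned `expr` and `network` (identical gene order,
#'   taken from the network's ordering restricted to the intersection).
#' @export
align_universe <- function(expr, network) {
  common <- intersect(network$genes, rownames(expr))
  if (length(common) < 2L)
    stop("fewer than 2 genes shared between expression matrix and network")
  dropped <- (length(network$genes) - length(common)) +
    (nrow(expr) - length(common))
  if (dropped > 0)
    message("align_universe: dropped ", length(network$genes) - length(common),
            " network-only and ", nrow(expr) - length(common),
            " expression-only gene(s); universe size ", length(common))
  network$adjacency <- network$adjacency[common, common, drop = FALSE]
  network$genes <- common
  list(expr = expr[common, , drop = FALSE], network = network)
}
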