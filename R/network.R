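#' Edge-rule configuration for co-expression network construction
#'
#' Two genes are linked when at least one of two rank-and-threshold
#' conditions holds: (1) their Pearson correlation is at least
#' `base_threshold` and one gene ranks within the other's top
#' `top_k_strict` most-correlated genes; (2) their correlation is at least
#' the high threshold `t` and one gene ranks within the other's top
#' `top_k_relaxed`. Thresholds are inclusive (`>=`): the rule's own worked
#' example links a gene at exactly the base threshold.
#'
#' @param base_threshold Correlation floor for the strict-rank condition
#'   (default 0.3).
#' @param top_k_strict Rank cutoff for condition 1 (default 3).
#' @param high_threshold High correlation threshold `t` for condition 2;
#'   0.7 or 0.8 in typical use (default 0.7).
#' @param top_k_relaxed Rank cutoff for condition 2 (default 50).
#' @param use_absolute_correlation Rank and threshold on `|r|` instead of
#'   signed `r` (default `FALSE`; negative correlation then never links).
#' @return An `edge_rule_config` list, stored in each network as its
#'   configuration fingerprint.
#' @export
edge_rule_config <- function(base_threshold = 0.3, top_k_strict = 3,
                             high_threshold = 0.7, top_k_relaxed = 50,
                             use_absolute_correlation = FALSE) {
  stopifnot(base_threshold > 0, base_threshold <= high_threshold,
            high_threshold < 1, top_k_strict >= 1, top_k_relaxed >= 1)
  structure(list(base_threshold = base_threshold,
                 top_k_strict = as.integer(top_k_strict),
                 high_threshold = high_threshold,
                 top_k_relaxed = as.integer(top_k_relaxed),
                 use_absolute_correlation = isTRUE(use_absolute_correlation)),
            class = "edge_rule_config")
}

#' Construct a gene network from a binary adjacency matrix
#'
#' A `gene_network` is an undirected simple graph over an ordered gene list,
#' stored as a symmetric binary adjacency matrix with zero diagonal.
#'
#' @param adjacency Square 0/1 (or logical) matrix; symmetrized state is
#'   validated, not repaired.
#' @param gene_ids Node identifiers; defaults to `rownames(adjacency)`.
#' @param config Optional `edge_rule_config` fingerprint recording how the
#'   network was built.
#' @return A `gene_network` with elements `gene_ids`, `adjacency`
#'   (integer 0/1 with dimnames) and `config`.
#' @export
gene_network <- function(adjacency, gene_ids = NULL, config = NULL) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("`adjacency` must be a square matrix")
  if (is.null(gene_ids)) gene_ids <- rownames(adjacency)
  if (is.null(gene_ids)) stop("gene identifiers are required")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (length(gene_ids) != nrow(adjacency))
    stop("gene_ids length does not match adjacency dimension")
  A <- matrix(as.integer(adjacency != 0), nrow(adjacency))
  if (!all(A == t(A))) stop("adjacency must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency must have zero diagonal")
  dimnames(A) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = as.character(gene_ids), adjacency = A,
                 config = config),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d edges\n",
              length(x$gene_ids), n_edges(x)))
  invisible(x)
}

#' Per-gene degree and edge count of a network
#'
#' @param net A `gene_network`.
#' @return `degrees`: named integer vector of node degrees; `n_edges`: the
#'   number of undirected edges.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  stats::setNames(as.integer(rowSums(net$adjacency)), net$gene_ids)
}

#' @rdname degrees
#' @export
n_edges <- function(net) sum(net$adjacency) %/% 2L

#' Pearson correlation matrix of an expression matrix
#'
#' Correlations are computed gene-by-gene across all samples present in
#' `em` (subset samples first with [subset_expression()] to restrict to one
#' group).
#'
#' @param em An `expression_matrix` with at least 3 samples.
#' @return Symmetric correlation matrix with unit diagonal, gene identifiers
#'   as dimnames.
#' @export
correlation_matrix <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (ncol(em$values) < 3L) stop("need at least 3 samples for correlation")
  sds <- apply(em$values, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene: ", rownames(em$values)[sds == 0][1L])
  r <- stats::cor(t(em$values))
  diag(r) <- 1
  r
}

# Rank matrix under the edge rules: rank_mat(r)[i, j] is the rank of gene j
# among gene i's correlations (1 = most correlated), self excluded, ties
# broken by ascending gene identifier so construction is deterministic.
.rank_matrix <- function(r) {
  m <- nrow(r)
  ids <- rownames(r)
  out <- matrix(NA_integer_, m, m, dimnames = dimnames(r))
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    ord <- others[order(-r[i, others], ids[others])]
    out[i, ord] <- seq_along(ord)
  }
  out
}

#' Neighbours of a gene ordered by decreasing correlation
#'
#' Ties are broken by ascending gene identifier; the gene itself is excluded.
#'
#' @param r Correlation matrix with gene identifiers as dimnames.
#' @param gene Gene identifier or index.
#' @return Character vector of the other genes, most correlated first.
#' @export
rank_neighbours <- function(r, gene) {
  ids <- rownames(r)
  i <- if (is.character(gene)) match(gene, ids) else as.integer(gene)
  if (is.na(i) || i < 1L || i > nrow(r)) stop("unknown gene: ", gene)
  others <- setdiff(seq_len(nrow(r)), i)
  ids[others][order(-r[i, others], ids[others])]
}

#' Build a co-expression network from a correlation matrix
#'
#' Applies the two edge conditions described in [edge_rule_config()] to a
#' precomputed correlation matrix. An undirected edge (i, j) exists iff
#' either condition holds in at least one direction.
#'
#' @param r Symmetric correlation matrix with gene identifiers as dimnames.
#' @param config An `edge_rule_config`.
#' @return A `gene_network` carrying `config` as its fingerprint.
#' @export
network_from_correlation <- function(r, config = edge_rule_config()) {
  stopifnot(inherits(config, "edge_rule_config"))
  if (is.null(rownames(r))) stop("correlation matrix needs gene identifiers")
  if (nrow(r) < 2L) stop("need at least 2 genes to build a network")
  if (config$use_absolute_correlation) r <- abs(r)
  rk <- .rank_matrix(r)
  in_top <- function(k) {T <- rk <= k; T[is.na(T)] <- FALSE; T}
  t3 <- in_top(config$top_k_strict)
  t50 <- in_top(config$top_k_relaxed)
  cond1 <- (r >= config$base_threshold) & (t3 | t(t3))
  cond2 <- (r >= config$high_threshold) & (t50 | t(t50))
  A <- cond1 | cond2
  diag(A) <- FALSE
  gene_network(A + 0L, rownames(r), config = config)
}

#' Build a region's co-expression network from expression data
#'
#' Convenience wrapper: restricts `em` to `genes` (typically the
#' intersection DE genes of a region pair) and to the requested sample
#' group, computes the Pearson correlation matrix, and applies the edge
#' rules.
#'
#' @param em An `expression_matrix`.
#' @param config An `edge_rule_config`.
#' @param genes Optional gene subset (order preserved).
#' @param samples `"affected"` (default), `"control"`, or `"all"`; which
#'   samples feed the correlations. Disease-state networks use affected
#'   samples only.
#' @return A `gene_network`.
#' @export
build_network <- function(em, config = edge_rule_config(), genes = NULL,
                          samples = "affected") {
  if (!is.null(genes) && length(genes) == 0L)
    stop("empty gene set: no network to build")
  sub <- subset_expression(em, genes = genes, samples = samples)
  network_from_correlation(correlation_matrix(sub), config)
}

#' Read / write a network as a canonical two-column edge list
#'
#' Each undirected edge appears once as `geneA<TAB>geneB` with the
#' lexicographically smaller identifier first, rows sorted, so files diff
#' cleanly.
#'
#' @param net A `gene_network`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency == 1L, arr.ind = TRUE)
  a <- net$gene_ids[idx[, 1L]]
  b <- net$gene_ids[idx[, 2L]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  ord <- order(lo, hi)
  writeLines(if (length(ord)) paste(lo[ord], hi[ord], sep = "\t") else
               character(0), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param gene_ids Full node set (isolated genes carry no edges, so the
#'   edge list alone cannot recover them).
#' @return `read_edge_list`: a `gene_network` on `gene_ids`.
#' @export
read_edge_list <- function(path, gene_ids) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  m <- length(gene_ids)
  A <- matrix(0L, m, m, dimnames = list(gene_ids, gene_ids))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("malformed edge-list line: ", lines[lengths(parts) != 2L][1L])
    a <- vapply(parts, `[[`, "", 1L)
    b <- vapply(parts, `[[`, "", 2L)
    unknown <- setdiff(c(a, b), gene_ids)
    if (length(unknown))
      stop("edge names unknown gene: ", unknown[1L])
    ia <- match(a, gene_ids); ib <- match(b, gene_ids)
    A[cbind(ia, ib)] <- 1L
    A[cbind(ib, ia)] <- 1L
  }
  diag(A) <- 0L
  gene_network(A, gene_ids)
}
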