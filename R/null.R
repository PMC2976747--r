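# zero-TO count straight from two adjacency matrices (hot path of the null)
.zero_to_count <- function(A1, A2) {
  d1 <- rowSums(A1); d2 <- rowSums(A2)
  sum(rowSums(A1 * A2) == 0 & (d1 > 0 | d2 > 0))
}

#' Degree-preserving random rewiring of a network
#'
#' Randomizes which genes are connected while keeping every gene's degree
#' exactly equal to the original, via repeated double-edge swaps (two
#' disjoint edges (a,b), (c,d) are replaced by (a,d), (c,b) when this
#' creates no self-loop or duplicate edge). The number of attempted swaps is
#' `swap_factor` times the edge count.
#'
#' @param net A `gene_network` with at least 2 edges.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param swap_factor Attempted swaps per edge (default 10).
#' @return A rewired `gene_network` on the same gene set with identical
#'   per-gene degrees. A graph admitting no valid swap (e.g. a triangle,
#'   the unique simple graph on its degree sequence) is returned unchanged
#'   with a warning.
#' @export
rewire_network <- function(net, seed = NULL, swap_factor = 10) {
  stopifnot(inherits(net, "gene_network"))
  ne <- n_edges(net)
  if (ne < 2L) stop("need at least 2 edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected")
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                 niter = swap_factor * ne))
  A <- as.matrix(igraph::as_adjacency_matrix(g2, type = "both"))
  A <- matrix(as.integer(A), nrow(A), dimnames = list(net$gene_ids,
                                                      net$gene_ids))
  if (identical(A, net$adjacency) && ne >= 2L)
    warning("rewiring left the network unchanged (no valid swap found)")
  out <- gene_network(A, net$gene_ids, config = net$config)
  if (!identical(degrees(out), degrees(net)))
    stop("internal error: rewiring changed the degree sequence")
  out
}

#' Null distribution of the zero-overlap gene count
#'
#' For each replicate the networks are rewired (independently sub-seeded)
#' with [rewire_network()] and the number of genes with zero cross-network
#' neighbourhood overlap between the rewired pair is recorded. By default
#' both networks are rewired, so the null randomizes topology on both
#' sides while preserving every degree.
#'
#' @param net1,net2 `gene_network`s on the same gene set.
#' @param n_random Number of random network pairs (default 1000).
#' @param seed Integer seed for the whole run.
#' @param rewire `"both"` (default) or `"second"` (network 1 held fixed).
#' @param swap_factor Passed to [rewire_network()].
#' @return Integer vector of `n_random` zero-overlap counts.
#' @export
null_distribution <- function(net1, net2, n_random = 1000, seed = 1,
                              rewire = c("both", "second"),
                              swap_factor = 10) {
  rewire <- match.arg(rewire)
  stopifnot(inherits(net1, "gene_network"), inherits(net2, "gene_network"))
  if (!identical(net1$gene_ids, net2$gene_ids))
    stop("networks must share an identical ordered gene set")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_random)
  vapply(seq_len(n_random), function(b) {
    set.seed(sub_seeds[b])
    r1 <- if (rewire == "both")
      suppressWarnings(rewire_network(net1)) else net1
    r2 <- suppressWarnings(rewire_network(net2))
    .zero_to_count(r1$adjacency, r2$adjacency)
  }, integer(1L))
}

#' t-statistic comparing the observed zero-overlap count with its null
#'
#' Computes `t = |mu1 - mu2| / (SD * sqrt(1/n1 + 1/n2))` where `mu1` is the
#' observed count (a single real-network pair, `n2 = 1`), `mu2` and `SD`
#' are the mean and sample standard deviation of the `n1` null counts, with
#' a two-sided p-value on `n1 + n2 - 2` degrees of freedom (999 at the
#' default 1000 randomizations).
#'
#' @param observed Observed zero-overlap gene count.
#' @param null_counts Zero-overlap counts from [null_distribution()]
#'   (length >= 2, non-degenerate).
#' @param seed Optional seed to record in the summary.
#' @return A `null_summary` list: `observed_zero_to`, `null_counts`,
#'   `mu1`, `mu2`, `sd`, `n1`, `n2`, `t_stat`, `df`, `p_value`, `seed`.
#' @export
to_t_statistic <- function(observed, null_counts, seed = NULL) {
  n1 <- length(null_counts)
  if (n1 < 2L) stop("need at least 2 null counts")
  mu2 <- mean(null_counts)
  sd_null <- stats::sd(null_counts)
  if (sd_null == 0) stop("degenerate null: all null counts identical")
  n2 <- 1L
  t_stat <- abs(observed - mu2) / (sd_null * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2L
  p <- 2 * stats::pt(t_stat, df = df, lower.tail = FALSE)
  structure(list(observed_zero_to = observed,
                 null_counts = as.integer(null_counts),
                 mu1 = observed, mu2 = mu2, sd = sd_null,
                 n1 = n1, n2 = n2,
                 t_stat = t_stat, df = df, p_value = p, seed = seed),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(
    "null_summary: observed %d zero-TO genes vs null mean %.2f (sd %.2f, n = %d)\n  t = %.3f on %d df, two-sided p = %.3g\n",
    x$observed_zero_to, x$mu2, x$sd, x$n1, x$t_stat, x$df, x$p_value))
  invisible(x)
}
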