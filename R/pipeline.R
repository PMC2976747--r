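#' Run the full differential-topology workflow for a region pair
#'
#' Orchestrates the pipeline: differential expression in each region (or
#' externally supplied DE lists), intersection genes, one co-expression
#' network per region over the intersection, the cross-network topological
#' overlap profile, zero-overlap gene selection, the degree-preserving
#' rewiring null with its t-statistic, a per-gene connectivity report, and
#' optional gene-set enrichment of the zero-overlap genes against a GMT
#' collection (universe = the intersection genes).
#'
#' @param expr_a,expr_b `expression_matrix` objects for regions A and B.
#' @param config An `edge_rule_config`.
#' @param de_lists Optional `list(a =, b =)` of precomputed DE gene
#'   identifier vectors (e.g. from an external SAM run); when given, the
#'   internal DE stage is skipped.
#' @param fdr_threshold Permutation-FDR cutoff for DE calling
#'   (default 0.005).
#' @param n_permutations Label permutations per region (default 1000).
#' @param samples Sample group feeding each region's network
#'   (default `"affected"`).
#' @param n_random Rewiring null replicates (default 1000).
#' @param rewire `"both"` or `"second"`; see [null_distribution()].
#' @param to_threshold Topological-overlap cutoff (default 0).
#' @param gmt Optional `gene_set_collection` for enrichment of the
#'   zero-overlap genes.
#' @param seed Master seed; DE permutations and the null are sub-seeded
#'   from it.
#' @param outdir Optional directory; when given, every stage output is
#'   written there (gene lists, edge lists, TSV tables, JSON manifest).
#' @return A `pair_result` list with elements `de_a`, `de_b` (NULL when
#'   external lists are used), `intersection`, `net_a`, `net_b`,
#'   `profile`, `zero_to`, `null_summary`, `degree_report`, `enrichment`
#'   and `manifest` (stage counts, seeds and configuration fingerprint).
#' @export
run_pair <- function(expr_a, expr_b, config = edge_rule_config(),
                     de_lists = NULL, fdr_threshold = 0.005,
                     n_permutations = 1000, samples = "affected",
                     n_random = 1000, rewire = c("both", "second"),
                     to_threshold = 0, gmt = NULL, seed = 1,
                     outdir = NULL) {
  rewire <- match.arg(rewire)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, 3L)

  if (is.null(de_lists)) {
    de_a <- permutation_fdr(expr_a, n_permutations, seed = sub_seeds[1L],
                            fdr_threshold = fdr_threshold)
    de_b <- permutation_fdr(expr_b, n_permutations, seed = sub_seeds[2L],
                            fdr_threshold = fdr_threshold)
    list_a <- de_a$called_genes
    list_b <- de_b$called_genes
    de_source <- "internal permutation FDR"
  } else {
    if (!all(c("a", "b") %in% names(de_lists)))
      stop("de_lists must have elements 'a' and 'b'")
    de_a <- de_b <- NULL
    list_a <- de_lists$a
    list_b <- de_lists$b
    de_source <- "external DE lists"
  }
  intersection <- intersect_de(list_a, list_b)
  if (length(intersection) < 2L)
    stop(sprintf(
      "intersection of DE lists too small to build networks (|A| = %d, |B| = %d, |A ∩ B| = %d)",
      length(list_a), length(list_b), length(intersection)))

  message(sprintf("DE (%s): |A| = %d, |B| = %d; intersection = %d genes",
                  de_source, length(list_a), length(list_b),
                  length(intersection)))

  net_a <- build_network(expr_a, config, genes = intersection,
                         samples = samples)
  net_b <- build_network(expr_b, config, genes = intersection,
                         samples = samples)
  message(sprintf("networks: A %d edges, B %d edges over %d genes",
                  n_edges(net_a), n_edges(net_b), length(intersection)))

  profile <- to_profile(net_a, net_b)
  zero_to <- zero_to_genes(profile, to_threshold = to_threshold)
  observed <- length(zero_to)
  null_counts <- null_distribution(net_a, net_b, n_random = n_random,
                                   seed = sub_seeds[3L], rewire = rewire)
  null_summary <- to_t_statistic(observed, null_counts,
                                 seed = sub_seeds[3L])
  message(sprintf(
    "zero-TO genes: %d observed vs null mean %.1f (t = %.2f, p = %.3g)",
    observed, null_summary$mu2, null_summary$t_stat, null_summary$p_value))

  deg_report <- degree_report(net_a, net_b, genes = as.character(zero_to))
  enrichment <- if (!is.null(gmt))
    enrich(as.character(zero_to), gmt, universe = intersection) else NULL

  manifest <- list(
    de_source = de_source,
    counts = list(de_a = length(list_a), de_b = length(list_b),
                  intersection = length(intersection),
                  edges_a = n_edges(net_a), edges_b = n_edges(net_b),
                  zero_to = observed,
                  isolated = length(attr(zero_to, "isolated"))),
    config = unclass(config),
    samples = samples, to_threshold = to_threshold,
    n_permutations = if (is.null(de_lists)) n_permutations else NULL,
    fdr_threshold = if (is.null(de_lists)) fdr_threshold else NULL,
    n_random = n_random, rewire = rewire,
    seed = seed, stage_seeds = as.list(sub_seeds),
    null = list(mu2 = null_summary$mu2, sd = null_summary$sd,
                t_stat = null_summary$t_stat, df = null_summary$df,
                p_value = null_summary$p_value))

  result <- structure(list(de_a = de_a, de_b = de_b,
                           intersection = intersection,
                           net_a = net_a, net_b = net_b, profile = profile,
                           zero_to = zero_to, null_summary = null_summary,
                           degree_report = deg_report,
                           enrichment = enrichment, manifest = manifest),
                      class = "pair_result")
  if (!is.null(outdir)) write_pair_result(result, outdir)
  result
}

#' @export
print.pair_result <- function(x, ...) {
  cts <- x$manifest$counts
  cat(sprintf(
    "pair_result: %d intersection genes, %d zero-TO (null mean %.1f, p = %.3g)\n",
    cts$intersection, cts$zero_to, x$manifest$null$mu2,
    x$manifest$null$p_value))
  invisible(x)
}

#' Write every stage output of a pair run to a directory
#'
#' @param result A `pair_result` from [run_pair()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, `outdir`.
#' @export
write_pair_result <- function(result, outdir) {
  stopifnot(inherits(result, "pair_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  if (!is.null(result$de_a)) {
    utils::write.table(result$de_a$table, p("de_region_a.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(result$de_b$table, p("de_region_b.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_gene_list(result$intersection, p("intersection_genes.txt"))
  write_edge_list(result$net_a, p("network_a_edges.tsv"))
  write_edge_list(result$net_b, p("network_b_edges.tsv"))
  utils::write.table(result$profile, p("to_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_list(as.character(result$zero_to), p("zero_to_genes.txt"))
  utils::write.table(result$degree_report, p("degree_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(null_count = result$null_summary$null_counts),
    p("null_counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$enrichment))
    utils::write.table(result$enrichment, p("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
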