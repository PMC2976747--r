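#' Cross-network topological overlap profile
#'
#' For each gene `i` present in two networks on the same ordered node set,
#' let `X` and `Y` be its neighbour sets in network 1 and network 2 and
#' `d1`, `d2` its degrees. The topological overlap is
#' `TO_i = |X intersect Y| / max(d1, d2)`, reported rounded to 4 decimal
#' places. The larger degree is used as denominator to reduce false
#' negatives: a gene with 200 neighbours in one network and 10 in the other,
#' all 10 shared, truly shares only 5% of its larger neighbourhood, and the
#' min-degree convention (`to_min`, also reported) would score it 1. Genes
#' isolated in both networks get `TO = 0` and are flagged `isolated`.
#'
#' @param net1,net2 `gene_network`s on identical ordered gene sets.
#' @return Data frame with one row per gene: `gene_id`, `d1`, `d2`,
#'   `overlap` (integer neighbourhood intersection size), `to` (max-degree
#'   denominator, 4 dp), `to_min` (min-degree denominator, 4 dp),
#'   `isolated`.
#' @export
to_profile <- function(net1, net2) {
  stopifnot(inherits(net1, "gene_network"), inherits(net2, "gene_network"))
  if (!identical(net1$gene_ids, net2$gene_ids))
    stop("networks must share an identical ordered gene set")
  A1 <- net1$adjacency; A2 <- net2$adjacency
  d1 <- as.integer(rowSums(A1))
  d2 <- as.integer(rowSums(A2))
  overlap <- as.integer(rowSums(A1 * A2))
  dmax <- pmax(d1, d2)
  dmin <- pmin(d1, d2)
  isolated <- dmax == 0L
  to <- ifelse(isolated, 0, round(overlap / pmax(dmax, 1L), 4L))
  to_min <- ifelse(dmin == 0L, 0, round(overlap / pmax(dmin, 1L), 4L))
  data.frame(gene_id = net1$gene_ids, d1 = d1, d2 = d2, overlap = overlap,
             to = to, to_min = to_min, isolated = isolated,
             stringsAsFactors = FALSE)
}

#' Topological overlap of a single gene between two networks
#'
#' @inheritParams to_profile
#' @param gene Gene identifier.
#' @param denominator `"max"` (the statistic proper) or `"min"` (the
#'   alternative convention, for comparison).
#' @return The rounded overlap ratio for `gene`.
#' @export
topological_overlap <- function(net1, net2, gene, denominator = c("max", "min")) {
  denominator <- match.arg(denominator)
  prof <- to_profile(net1, net2)
  row <- prof[prof$gene_id == gene, ]
  if (nrow(row) == 0L) stop("unknown gene: ", gene)
  if (denominator == "max") row$to else row$to_min
}

#' Genes with zero topological overlap
#'
#' Selection is on the exact integer neighbourhood intersection
#' (`overlap == 0`), so the 4-decimal rounding of the reported ratio is
#' purely cosmetic. Genes isolated in both networks are excluded (their
#' neighbourhoods are vacuously disjoint) and returned in the
#' `"isolated"` attribute. A positive `to_threshold` instead selects genes
#' with `to <= to_threshold`; divergence cutoffs other than exact zero can
#' be justified for specific analyses.
#'
#' @param profile A profile from [to_profile()].
#' @param to_threshold Topological-overlap cutoff (default 0: exact zero
#'   overlap).
#' @return Character vector of gene identifiers in profile order, with the
#'   isolated genes as attribute `"isolated"`.
#' @export
zero_to_genes <- function(profile, to_threshold = 0) {
  stopifnot(is.data.frame(profile), to_threshold >= 0)
  active <- !profile$isolated
  sel <- if (to_threshold == 0) profile$overlap == 0L else
    profile$to <= to_threshold
  structure(profile$gene_id[active & sel],
            isolated = profile$gene_id[profile$isolated])
}

#' Per-gene connectivity differences between two networks
#'
#' Descriptive companion to the zero-overlap selection: a large degree
#' contrast between regions is read as a change in the gene's co-expression
#' activity between them.
#'
#' @inheritParams to_profile
#' @param genes Optional subset of genes to report (default all).
#' @return Data frame of `gene_id`, `d1`, `d2`, `abs_diff`, sorted by
#'   descending `abs_diff` (ties by gene identifier).
#' @export
degree_report <- function(net1, net2, genes = NULL) {
  prof <- to_profile(net1, net2)
  if (!is.null(genes)) {
    unknown <- setdiff(genes, prof$gene_id)
    if (length(unknown)) stop("unknown gene: ", unknown[1L])
    prof <- prof[match(genes, prof$gene_id), ]
  }
  out <- data.frame(gene_id = prof$gene_id, d1 = prof$d1, d2 = prof$d2,
                    abs_diff = abs(prof$d1 - prof$d2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_diff, out$gene_id), ]
  rownames(out) <- NULL
  out
}
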