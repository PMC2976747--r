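#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Members are deduplicated; members
#' outside the universe are retained in storage but do not count towards a
#' set's effective size.
#'
#' @param path Path to the GMT file.
#' @param universe Gene identifiers defining the enrichment universe.
#' @return A `gene_set_collection`: list with `sets` (named list of
#'   `list(description, genes)`) and `universe`.
#' @export
read_gmt <- function(path, universe) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  sets <- lapply(parts, function(p)
    list(description = p[[2L]], genes = unique(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate set name: ", names(sets)[duplicated(names(sets))][1L])
  structure(list(sets = sets, universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation test against gene-set collections
#'
#' For each set, the one-sided hypergeometric tail probability of drawing
#' at least the observed overlap when `|query|` genes are sampled from the
#' universe and the set's in-universe members are the successes, with
#' Benjamini-Hochberg correction across sets. The natural universe for
#' zero-overlap gene lists is the intersection gene set of the comparison
#' (the pool the query was drawn from), not the whole genome.
#'
#' @param genes Query gene identifiers. Genes outside the universe are
#'   dropped with a warning.
#' @param collection A `gene_set_collection` (or the result of
#'   [read_gmt()]).
#' @param universe Optional universe override; defaults to the
#'   collection's.
#' @param fdr_threshold BH-FDR cutoff for the `significant` flag
#'   (default 0.05).
#' @return Data frame of `set_name`, `set_size` (in-universe), `overlap`,
#'   `p_value`, `bh_fdr`, `significant`, ordered by ascending p-value.
#' @export
enrich <- function(genes, collection, universe = NULL,
                   fdr_threshold = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(universe)) universe <- collection$universe
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    genes <- intersect(genes, universe)
  }
  n_univ <- length(universe)
  n_query <- length(genes)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]]$genes, universe)
    k <- length(intersect(genes, members))
    p <- if (length(members) == 0L || n_query == 0L) 1 else
      stats::phyper(k - 1L, length(members), n_univ - length(members),
                    n_query, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(members), overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$bh_fdr <= fdr_threshold
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}
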