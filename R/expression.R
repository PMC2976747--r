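#' Construct a validated expression matrix
#'
#' An `expression_matrix` bundles a genes x samples numeric matrix of
#' summarized expression values with a group label (`"affected"` or
#' `"control"`) per sample. It is the substrate for differential expression
#' and for co-expression network construction.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are taken as gene and sample identifiers unless `gene_ids` /
#'   `sample_ids` are given.
#' @param groups Named character vector mapping every sample identifier to
#'   `"affected"` or `"control"`.
#' @param gene_ids,sample_ids Optional identifier vectors overriding dimnames.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (named numeric matrix) and `groups` (named character vector
#'   aligned with the matrix columns).
#' @examples
#' vals <- matrix(rnorm(12), 3, 4,
#'                dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' grp <- setNames(rep(c("affected", "control"), 2), colnames(vals))
#' em <- expression_matrix(vals, grp)
#' @export
expression_matrix <- function(values, groups, gene_ids = NULL,
                              sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x samples)")
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ",
         gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifier: ",
         sample_ids[duplicated(sample_ids)][1L])
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]))
  }
  groups <- unlist(groups)
  missing_grp <- setdiff(sample_ids, names(groups))
  if (length(missing_grp))
    stop("sample missing from group labels: ", missing_grp[1L])
  groups <- groups[sample_ids]
  bad_lab <- setdiff(unique(groups), c("affected", "control"))
  if (length(bad_lab))
    stop("unknown group label: ", bad_lab[1L],
         " (expected 'affected' or 'control')")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d affected, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "affected"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Gene identifiers of a coexdiff object
#'
#' @param x An `expression_matrix` or `gene_network`.
#' @return Character vector of gene identifiers in stored order.
#' @export
gene_ids <- function(x) {
  if (inherits(x, "expression_matrix")) return(rownames(x$values))
  if (inherits(x, "gene_network")) return(x$gene_ids)
  stop("no gene identifiers for class ", paste(class(x), collapse = "/"))
}

#' Subset an expression matrix by genes and/or samples
#'
#' @param em An `expression_matrix`.
#' @param genes Optional gene identifiers to keep (in the given order).
#' @param samples Either sample identifiers, or one of `"affected"`,
#'   `"control"`, `"all"` to select by group label.
#' @return A new `expression_matrix`.
#' @export
subset_expression <- function(em, genes = NULL, samples = "all") {
  stopifnot(inherits(em, "expression_matrix"))
  vals <- em$values
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(vals))
    if (length(unknown))
      stop("unknown gene identifier: ", unknown[1L])
    vals <- vals[genes, , drop = FALSE]
  }
  keep <- colnames(vals)
  if (length(samples) == 1L && samples %in% c("affected", "control")) {
    keep <- keep[em$groups[keep] == samples]
  } else if (!(length(samples) == 1L && samples == "all")) {
    unknown <- setdiff(samples, keep)
    if (length(unknown))
      stop("unknown sample identifier: ", unknown[1L])
    keep <- samples
  }
  expression_matrix(vals[, keep, drop = FALSE], em$groups[keep])
}

#' Read an expression matrix and its sample groups from disk
#'
#' The expression file is tab-separated with a header row of sample
#' identifiers and a first column of gene identifiers. The groups file is a
#' two-column tab-separated table `sample_id<TAB>label` with labels
#' `affected` or `control`, no header.
#'
#' @param path Path to the expression TSV.
#' @param groups_path Path to the two-column groups TSV.
#' @return An `expression_matrix`; gene order is preserved from the file.
#' @export
read_expression <- function(path, groups_path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(tab) < 2L) stop("expression file needs gene IDs plus >=1 sample")
  genes <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(num) | vals == "")) {
    bad <- which(is.na(num) | vals == "", arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(num) <- list(genes, sample_ids)
  grp <- utils::read.delim(groups_path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(grp) < 2L) stop("groups file must have two tab-separated columns")
  groups <- stats::setNames(grp[[2L]], grp[[1L]])
  expression_matrix(num, groups)
}

#' Write an expression matrix (and optionally its groups) to disk
#'
#' @param em An `expression_matrix`.
#' @param path Output path for the expression TSV.
#' @param groups_path Optional output path for the two-column groups TSV.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(em, path, groups_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    utils::write.table(
      data.frame(names(em$groups), unname(em$groups)),
      groups_path, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write one-per-line gene lists
#'
#' Blank lines are skipped; duplicates are an error on read.
#'
#' @param path File path.
#' @return `read_gene_list`: character vector of gene identifiers in file
#'   order.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids))
    stop("duplicate gene identifier in ", path, ": ",
         ids[duplicated(ids)][1L])
  ids
}

#' @rdname read_gene_list
#' @param ids Character vector of gene identifiers.
#' @export
write_gene_list <- function(ids, path) {
  if (anyDuplicated(ids))
    stop("refusing to write duplicate gene identifiers")
  writeLines(as.character(ids), path)
  invisible(path)
}
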