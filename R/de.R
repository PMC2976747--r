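#' SAM-style moderated difference statistic
#'
#' For each gene, `d = (mean_affected - mean_control) / (s + s0)` where `s`
#' is the two-group pooled standard error of the mean difference and the
#' exchangeability constant `s0` is the median of all per-gene `s`. The
#' fudge factor keeps genes with tiny variance from dominating the ranking,
#' in the spirit of the SAM modified t-statistic.
#'
#' @param em An `expression_matrix` with at least 2 samples per group.
#' @return Named numeric vector of per-gene d-statistics.
#' @export
de_statistic <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  aff <- em$groups == "affected"
  .de_stat_core(em$values, aff)
}

# core: d-statistics for an arbitrary affected-indicator, reused by the
# label permutations
.de_stat_core <- function(vals, aff) {
  n1 <- sum(aff); n2 <- sum(!aff)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (affected: ", n1,
         ", control: ", n2, ")")
  xa <- vals[, aff, drop = FALSE]
  xc <- vals[, !aff, drop = FALSE]
  ma <- rowMeans(xa); mc <- rowMeans(xc)
  ssa <- rowSums((xa - ma)^2)
  ssc <- rowSums((xc - mc)^2)
  pooled_var <- (ssa + ssc) / (n1 + n2 - 2L)
  s <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  s0 <- stats::median(s)
  stats::setNames((ma - mc) / (s + s0), rownames(vals))
}

#' Permutation-FDR differential expression call
#'
#' Group labels are permuted (all distinct labelings are enumerated exactly
#' when there are no more of them than `n_permutations`, otherwise
#' `n_permutations` random labelings are drawn) and each gene's q-value is
#' the expected number of permutation scores at least as extreme as its own,
#' divided by the observed count at least as extreme, clipped to \[0, 1\]
#' and made monotone non-increasing in `|d|`.
#'
#' @param em An `expression_matrix`.
#' @param n_permutations Number of label permutations (>= 100).
#' @param seed Integer seed; the call is fully reproducible.
#' @param fdr_threshold q-value cutoff for calling a gene differentially
#'   expressed (default 0.005, i.e. a relaxed FDR of 0.5%).
#' @return A `de_result`: a list with `table` (data.frame of `gene_id`,
#'   `d_statistic`, `q_value`, `called`), `called_genes`,
#'   `fdr_threshold`, `n_permutations` (as used) and `seed`.
#' @export
permutation_fdr <- function(em, n_permutations = 1000, seed = 1,
                            fdr_threshold = 0.005) {
  stopifnot(inherits(em, "expression_matrix"))
  if (n_permutations < 100) stop("n_permutations must be >= 100")
  aff <- em$groups == "affected"
  n <- length(aff); n1 <- sum(aff)
  d_obs <- .de_stat_core(em$values, aff)

  n_distinct <- choose(n, n1)
  if (n_distinct <= n_permutations) {
    if (n_distinct < n_permutations)
      warning(sprintf(
        "only %d distinct labelings exist; using all of them instead of %d permutations",
        n_distinct, n_permutations))
    combs <- utils::combn(n, n1)
    perm_sets <- lapply(seq_len(ncol(combs)), function(j) combs[, j])
  } else {
    set.seed(seed)
    perm_sets <- lapply(seq_len(n_permutations),
                        function(j) sample.int(n, n1))
  }

  abs_obs <- abs(d_obs)
  perm_abs <- unlist(lapply(perm_sets, function(idx) {
    lab <- rep(FALSE, n); lab[idx] <- TRUE
    abs(.de_stat_core(em$values, lab))
  }), use.names = FALSE)
  n_perm_used <- length(perm_sets)

  sorted_perm <- sort(perm_abs)
  sorted_obs <- sort(abs_obs)
  # #{perm >= x} and #{obs >= x}, vectorized over thresholds x
  ge_perm <- length(sorted_perm) -
    findInterval(abs_obs, sorted_perm, left.open = TRUE)
  ge_obs <- length(sorted_obs) -
    findInterval(abs_obs, sorted_obs, left.open = TRUE)
  q <- (ge_perm / n_perm_used) / ge_obs
  q <- pmin(pmax(q, 0), 1)
  # enforce monotonicity: a larger |d| never gets a larger q
  ord <- order(abs_obs, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  tab <- data.frame(gene_id = names(d_obs), d_statistic = unname(d_obs),
                    q_value = unname(q),
                    called = unname(q) <= fdr_threshold,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 called_genes = tab$gene_id[tab$called],
                 fdr_threshold = fdr_threshold,
                 n_permutations = n_perm_used,
                 seed = seed),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d/%d genes called at FDR %g (%d permutations)\n",
              length(x$called_genes), nrow(x$table), x$fdr_threshold,
              x$n_permutations))
  invisible(x)
}

#' Intersection genes of two differential-expression calls
#'
#' The genes differentially expressed in both regions of a pair form the
#' shared node set over which both regional co-expression networks are
#' built.
#'
#' @param list_a,list_b Gene identifier vectors (each duplicate-free).
#' @return Genes present in both lists, ordered by `list_a`'s order.
#' @export
intersect_de <- function(list_a, list_b) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b))
    stop("gene lists must be duplicate-free")
  list_a[list_a %in% list_b]
}
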