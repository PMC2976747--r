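# Shared fixtures and independent oracles. The oracles are deliberately
# naive (per-pair loops, explicit set operations) so they stay independent
# of the vectorized implementation they check.

random_expression <- function(m = 8, n = 10, seed = 1, prefix = "g") {
  set.seed(seed)
  vals <- matrix(rnorm(m * n), m, n,
                 dimnames = list(sprintf("%s%03d", prefix, seq_len(m)),
                                 sprintf("s%02d", seq_len(n))))
  groups <- setNames(rep(c("affected", "control"), length.out = n),
                     colnames(vals))
  expression_matrix(vals, groups)
}

random_gene_network <- function(m = 30, p = 0.15, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(m))
  A <- matrix(0L, m, m, dimnames = list(ids, ids))
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < p]
  A[on] <- 1L
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  gene_network(A, ids)
}

# adjacency from a network built directly from a neighbour list
network_from_neighbours <- function(ids, edges) {
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  gene_network(A, ids)
}

# toy pair realizing the asymmetric-degree scenario: gene "hub" has
# degree d1 in net1 and d2 in net2 with `shared` common neighbours
asymmetric_pair <- function(d1 = 200, d2 = 10, shared = 10) {
  m <- d1 + d2 - shared + 1
  ids <- c("hub", sprintf("v%03d", seq_len(m - 1)))
  n1 <- network_from_neighbours(
    ids, lapply(ids[2:(d1 + 1)], function(v) c("hub", v)))
  n2 <- network_from_neighbours(
    ids, lapply(ids[2:(d2 + 1)], function(v) c("hub", v)))
  list(n1 = n1, n2 = n2)
}

# exhaustive pairwise oracle for the two edge conditions, both directions
oracle_network <- function(r, base = 0.3, t_high = 0.7, k1 = 3, k2 = 50) {
  ids <- rownames(r)
  m <- nrow(r)
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(m), i)
    ord <- others[order(-r[i, others], ids[others])]
    match(j, ord)
  }
  A <- matrix(0L, m, m, dimnames = list(ids, ids))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    c1 <- r[i, j] >= base && (rank_of(i, j) <= k1 || rank_of(j, i) <= k1)
    c2 <- r[i, j] >= t_high && (rank_of(i, j) <= k2 || rank_of(j, i) <= k2)
    if (c1 || c2) A[i, j] <- A[j, i] <- 1L
  }
  A
}

# per-gene set-operations oracle for the cross-network overlap
oracle_to <- function(net1, net2, gene) {
  X <- names(which(net1$adjacency[gene, ] == 1L))
  Y <- names(which(net2$adjacency[gene, ] == 1L))
  list(d1 = length(X), d2 = length(Y),
       overlap = length(intersect(X, Y)),
       to = if (max(length(X), length(Y)) == 0) 0 else
         round(length(intersect(X, Y)) / max(length(X), length(Y)), 4),
       to_min = if (min(length(X), length(Y)) == 0) 0 else
         round(length(intersect(X, Y)) / min(length(X), length(Y)), 4))
}

# correlation matrix realizing the worked edge-rule scenarios: gene A's
# three candidates at the given correlations, candidates near-uncorrelated
# with each other
toy_corr <- function(r_candidates, off = 0.05) {
  ids <- c("A", "B", "C", "D")
  r <- matrix(off, 4, 4, dimnames = list(ids, ids))
  r["A", c("B", "C", "D")] <- r_candidates
  r[c("B", "C", "D"), "A"] <- r_candidates
  diag(r) <- 1
  r
}
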