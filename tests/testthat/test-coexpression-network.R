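test_that("correlation matrix matches the textbook formula and flags degeneracy", {
  em <- random_expression(m = 5, n = 6, seed = 21)
  r <- correlation_matrix(em)

  # direct covariance / (sd * sd) evaluation
  for (i in 1:4) for (j in (i + 1):5) {
    x <- em$values[i, ]; y <- em$values[j, ]
    expect_equal(r[i, j],
                 sum((x - mean(x)) * (y - mean(y))) / ((length(x) - 1) *
                   sd(x) * sd(y)),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(r)), rep(1, 5))

  # duplicated gene and negated gene
  em2 <- em
  em2$values[2, ] <- em2$values[1, ]
  em2$values[3, ] <- -em2$values[1, ]
  r2 <- correlation_matrix(em2)
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)

  em$values[4, ] <- 7
  expect_error(correlation_matrix(em), "zero-variance gene: g004")
})

test_that("neighbour ranking is by decreasing correlation with identifier tie-break", {
  r <- toy_corr(c(0.3, 0.32, 0.4))  # B = 0.3, C = 0.32, D = 0.4
  expect_identical(rank_neighbours(r, "A"), c("D", "C", "B"))

  tied <- matrix(0.5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(tied) <- 1
  expect_identical(rank_neighbours(tied, "C"), c("A", "B", "D"))

  set.seed(4)
  ids <- sprintf("g%02d", 1:12)
  rr <- matrix(runif(144, -1, 1), 12, 12, dimnames = list(ids, ids))
  rr[lower.tri(rr)] <- t(rr)[lower.tri(rr)]
  diag(rr) <- 1
  for (g in ids) {
    others <- setdiff(ids, g)
    expect_identical(rank_neighbours(rr, g),
                     others[order(-rr[g, others], others)])
  }
})

test_that("the strict-rank condition links exactly the above-threshold top-3", {
  cfg <- edge_rule_config()

  # three candidates at 0.3, 0.32, 0.4: all three link
  net <- network_from_correlation(toy_corr(c(0.3, 0.32, 0.4)), cfg)
  expect_equal(unname(degrees(net)["A"]), 3L)

  # candidates at 0.3, 0.28, 0.29: only the gene at the threshold links
  net2 <- network_from_correlation(toy_corr(c(0.3, 0.28, 0.29)), cfg)
  expect_equal(unname(degrees(net2)["A"]), 1L)
  expect_equal(net2$adjacency["A", "B"], 1L)
})

test_that("built networks equal the exhaustive two-condition oracle", {
  for (seed in 1:25) {
    em <- random_expression(m = 8, n = 10, seed = seed)
    r <- correlation_matrix(em)
    net <- network_from_correlation(r, edge_rule_config())
    expect_identical(net$adjacency, oracle_network(r),
                     info = paste("seed", seed))
  }
  # a configuration where the relaxed condition matters
  for (seed in 26:35) {
    em <- random_expression(m = 8, n = 5, seed = seed)
    r <- correlation_matrix(em)
    cfg <- edge_rule_config(base_threshold = 0.5, top_k_strict = 2,
                            high_threshold = 0.7, top_k_relaxed = 5)
    net <- network_from_correlation(r, cfg)
    expect_identical(net$adjacency,
                     oracle_network(r, base = 0.5, t_high = 0.7,
                                    k1 = 2, k2 = 5),
                     info = paste("seed", seed))
  }
})

test_that("networks are simple and monotone in the high threshold", {
  em <- random_expression(m = 30, n = 8, seed = 99)
  r <- correlation_matrix(em)
  net <- network_from_correlation(r, edge_rule_config(high_threshold = 0.6))
  A <- net$adjacency
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A %in% c(0L, 1L)))

  # raising t never adds edges; both conditions never remove condition-1 edges
  for (t_high in c(0.7, 0.8, 0.9)) {
    tighter <- network_from_correlation(
      r, edge_rule_config(high_threshold = t_high))
    expect_true(all(tighter$adjacency <= A))
    A <- tighter$adjacency
  }
  cond1_only <- network_from_correlation(
    r, edge_rule_config(high_threshold = 0.999, top_k_relaxed = 1))
  both <- network_from_correlation(r, edge_rule_config(high_threshold = 0.6))
  expect_true(all(cond1_only$adjacency <= both$adjacency))
})

test_that("minimum degree reaches the strict rank cutoff when top-3 clear the base threshold", {
  gen <- generate_pair(synthetic_spec(m_genes = 200, n_affected = 10,
                                      n_control = 10, de_fraction = 0,
                                      n_blocks = 10, block_size = 20,
                                      loading = 0.45, noise_sd = 0.89,
                                      n_planted_diff = 0, seed = 17))
  r <- correlation_matrix(subset_expression(gen$region1, samples = "all"))
  third_best <- apply(r - diag(2, nrow(r)), 1,
                      function(x) sort(x, decreasing = TRUE)[3])
  expect_true(all(third_best >= 0.3))
  net <- network_from_correlation(r, edge_rule_config())
  expect_gte(min(degrees(net)), 3L)
})

test_that("build_network restricts genes and samples and rejects empty input", {
  em <- random_expression(m = 12, n = 10, seed = 31)
  keep <- rownames(em$values)[1:6]
  net <- build_network(em, genes = keep, samples = "all")
  expect_identical(net$gene_ids, keep)
  expect_error(build_network(em, genes = character(0)), "empty gene set")

  aff <- build_network(em, genes = keep, samples = "affected")
  r_aff <- correlation_matrix(subset_expression(em, keep, "affected"))
  expect_identical(aff$adjacency,
                   network_from_correlation(r_aff)$adjacency)
})
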