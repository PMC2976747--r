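test_that("a 200-vs-10 degree gene with 10 shared neighbours scores 0.05 (max) and 1 (min)", {
  p <- asymmetric_pair()
  expect_equal(topological_overlap(p$n1, p$n2, "hub"), 0.05)
  expect_equal(topological_overlap(p$n1, p$n2, "hub", denominator = "min"), 1)
  prof <- to_profile(p$n1, p$n2)
  hub <- prof[prof$gene_id == "hub", ]
  expect_equal(c(hub$d1, hub$d2, hub$overlap), c(200, 10, 10))
})

test_that("identical networks give unit overlap and an empty zero-overlap set", {
  net <- random_gene_network(m = 25, p = 0.2, seed = 6)
  prof <- to_profile(net, net)
  active <- !prof$isolated
  expect_true(all(prof$to[active] == 1))
  expect_length(as.character(zero_to_genes(prof)), 0)
  expect_true(all(degree_report(net, net)$abs_diff == 0))
})

test_that("overlap profiles match the per-gene set-operations oracle", {
  for (seed in 1:20) {
    n1 <- random_gene_network(m = 30, p = 0.12, seed = seed)
    n2 <- random_gene_network(m = 30, p = 0.12, seed = seed + 1000)
    n2$gene_ids <- n1$gene_ids
    dimnames(n2$adjacency) <- dimnames(n1$adjacency)
    prof <- to_profile(n1, n2)
    for (g in sample(n1$gene_ids, 8)) {
      o <- oracle_to(n1, n2, g)
      row <- prof[prof$gene_id == g, ]
      expect_equal(unname(unlist(row[c("d1", "d2", "overlap", "to",
                                       "to_min")])),
                   unname(unlist(o)), info = paste(seed, g))
    }
    # whole zero-overlap set equals the brute-force filter
    brute <- vapply(n1$gene_ids, function(g) {
      o <- oracle_to(n1, n2, g)
      o$overlap == 0 && (o$d1 > 0 || o$d2 > 0)
    }, logical(1))
    expect_identical(as.character(zero_to_genes(prof)),
                     n1$gene_ids[brute])
    # invariants: bounded, symmetric in network order, max <= min convention
    expect_true(all(prof$to >= 0 & prof$to <= 1))
    expect_true(all(prof$to <= prof$to_min + 1e-12))
    swapped <- to_profile(n2, n1)
    expect_equal(prof$to, swapped$to)
  }
})

test_that("disjoint neighbourhoods score zero and isolated genes are flagged, not selected", {
  ids <- c("g", "a", "b", "c", "d", "lone")
  n1 <- network_from_neighbours(ids, list(c("g", "a"), c("g", "b"),
                                          c("a", "b"), c("c", "d")))
  n2 <- network_from_neighbours(ids, list(c("g", "c"), c("g", "d"),
                                          c("c", "d"), c("a", "b")))
  prof <- to_profile(n1, n2)
  expect_equal(prof$to[prof$gene_id == "g"], 0)
  z <- zero_to_genes(prof)
  expect_true("g" %in% z)
  expect_false("lone" %in% as.character(z))
  expect_identical(attr(z, "isolated"), "lone")
  expect_true(prof$isolated[prof$gene_id == "lone"])

  # adding a shared edge can only increase a gene's overlap
  n2b <- n2
  n2b$adjacency["g", "a"] <- n2b$adjacency["a", "g"] <- 1L
  expect_gte(topological_overlap(n1, n2b, "g"),
             topological_overlap(n1, n2, "g"))
})

test_that("a positive overlap survives 4-decimal rounding at realistic sizes", {
  # smallest positive ratio with <= 5000 genes is 1/4999 > 0.00005
  p <- asymmetric_pair(d1 = 4999, d2 = 1, shared = 1)
  expect_gt(topological_overlap(p$n1, p$n2, "hub"), 0)
  prof <- to_profile(p$n1, p$n2)
  expect_false("hub" %in% as.character(zero_to_genes(prof)))
})

test_that("a relaxed overlap threshold widens the selection monotonically", {
  n1 <- random_gene_network(m = 40, p = 0.15, seed = 3)
  n2 <- random_gene_network(m = 40, p = 0.15, seed = 4)
  n2$gene_ids <- n1$gene_ids
  dimnames(n2$adjacency) <- dimnames(n1$adjacency)
  prof <- to_profile(n1, n2)
  z0 <- as.character(zero_to_genes(prof))
  z1 <- as.character(zero_to_genes(prof, to_threshold = 0.2))
  expect_true(all(z0 %in% z1))
  expect_identical(z1, prof$gene_id[!prof$isolated & prof$to <= 0.2])
})

test_that("degree reports surface the largest connectivity changes first", {
  ids <- c("g", sprintf("x%02d", 1:30))
  n1 <- network_from_neighbours(ids, lapply(ids[2:4], function(v) c("g", v)))
  n2 <- network_from_neighbours(ids, lapply(ids[2:25],
                                            function(v) c("g", v)))
  rep_ <- degree_report(n1, n2)
  expect_identical(rep_$gene_id[1], "g")
  expect_equal(unlist(rep_[1, c("d1", "d2", "abs_diff")], use.names = FALSE),
               c(3, 24, 21))

  n3 <- random_gene_network(m = 30, p = 0.2, seed = 11)
  n4 <- random_gene_network(m = 30, p = 0.2, seed = 12)
  n4$gene_ids <- n3$gene_ids
  dimnames(n4$adjacency) <- dimnames(n3$adjacency)
  rep2 <- degree_report(n3, n4)
  naive <- abs(degrees(n3) - degrees(n4))
  expect_equal(rep2$abs_diff, unname(sort(naive, decreasing = TRUE)))

  expect_error(to_profile(n3, random_gene_network(m = 10, seed = 1)),
               "identical ordered gene set")
})
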