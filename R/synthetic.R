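#' Specification for the two-region synthetic expression generator
#'
#' The generator emulates the statistical structure the differential
#' topology analysis assumes: a latent-factor model where genes in the same
#' co-expression block share a per-sample factor (so within-block Pearson
#' correlations are controlled analytically as
#' `loading^2 / (loading^2 + noise_sd^2)`), a group mean-shift for
#' differentially expressed genes, and planted differential-topology genes
#' that load on one block in region 1 and a disjoint block in region 2, so
#' their true network neighbourhoods share no members.
#'
#' The differentially expressed genes are drawn once and shared by both
#' regions, and planted genes are always included among them, so the truth
#' differential-expression intersection is well-defined and planted genes
#' survive the intersection stage by construction.
#'
#' @param m_genes Total genes per region (default 300).
#' @param n_affected,n_control Samples per group per region (defaults 10
#'   and 13, typical of laser-capture microarray region cohorts).
#' @param de_fraction Fraction of genes given a group mean shift
#'   (default 0.5).
#' @param effect_size Mean shift for affected samples, in units of a
#'   gene's total (factor + noise) standard deviation (default 1.5).
#' @param n_blocks,block_size Latent co-expression blocks partitioning the
#'   genes (defaults 15 blocks of 20); genes beyond
#'   `n_blocks * block_size` are pure-noise background.
#' @param loading Factor loading of block genes (default 0.8).
#' @param noise_sd Independent noise standard deviation (default 0.6;
#'   with the default loading, within-block correlation is 0.64).
#' @param n_planted_diff Planted differential-topology genes, at most one
#'   per block (default 10).
#' @param seed Integer seed making generation fully deterministic.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(m_genes = 300, n_affected = 10, n_control = 13,
                           de_fraction = 0.5, effect_size = 1.5,
                           n_blocks = 15, block_size = 20, loading = 0.8,
                           noise_sd = 0.6, n_planted_diff = 10, seed = 1) {
  stopifnot(m_genes >= 2, n_affected >= 2, n_control >= 2,
            de_fraction >= 0, de_fraction <= 1, n_blocks >= 1,
            block_size >= 2, loading >= 0, noise_sd >= 0,
            loading + noise_sd > 0,
            n_planted_diff >= 0, n_planted_diff <= n_blocks)
  if (n_blocks * block_size > m_genes)
    stop("blocks cover more genes than m_genes (",
         n_blocks * block_size, " > ", m_genes, ")")
  if (n_planted_diff > 0 && n_blocks < 2)
    stop("planting differential-topology genes needs at least 2 blocks")
  structure(list(m_genes = as.integer(m_genes),
                 n_affected = as.integer(n_affected),
                 n_control = as.integer(n_control),
                 de_fraction = de_fraction, effect_size = effect_size,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 loading = loading, noise_sd = noise_sd,
                 n_planted_diff = as.integer(n_planted_diff),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# one region's matrix given per-gene block assignment (NA = background)
.generate_region <- function(spec, blocks, de_idx, region_tag) {
  m <- spec$m_genes
  n <- spec$n_affected + spec$n_control
  total_sd <- sqrt(spec$loading^2 + spec$noise_sd^2)
  factors <- matrix(stats::rnorm(spec$n_blocks * n), spec$n_blocks, n)
  X <- spec$noise_sd * matrix(stats::rnorm(m * n), m, n)
  in_block <- !is.na(blocks)
  X[in_block, ] <- spec$loading * factors[blocks[in_block], , drop = FALSE] +
    X[in_block, , drop = FALSE]
  # background genes get matched marginal variance
  if (any(!in_block)) {
    if (spec$noise_sd == 0)
      stop("background genes need noise_sd > 0")
    X[!in_block, ] <- X[!in_block, , drop = FALSE] * (total_sd / spec$noise_sd)
  }
  aff_cols <- seq_len(spec$n_affected)
  X[de_idx, aff_cols] <- X[de_idx, aff_cols] + spec$effect_size * total_sd
  sample_ids <- c(sprintf("%s_A%02d", region_tag, aff_cols),
                  sprintf("%s_C%02d", region_tag, seq_len(spec$n_control)))
  dimnames(X) <- list(sprintf("g%04d", seq_len(m)), sample_ids)
  groups <- stats::setNames(rep(c("affected", "control"),
                                c(spec$n_affected, spec$n_control)),
                            sample_ids)
  expression_matrix(X, groups)
}

#' Generate a two-region synthetic expression pair with ground truth
#'
#' @param spec A `synthetic_spec`.
#' @return List with `region1`, `region2` (each an `expression_matrix` on
#'   the same genes) and `truth`: `de_genes`, `planted` (the
#'   differential-topology genes), `blocks_region1`, `blocks_region2`
#'   (named block indices, `NA` for background genes), and `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  m <- spec$m_genes
  genes <- sprintf("g%04d", seq_len(m))
  covered <- spec$n_blocks * spec$block_size
  blocks1 <- c(rep(seq_len(spec$n_blocks), each = spec$block_size),
               rep(NA_integer_, m - covered))
  # one planted gene per block for the first n_planted_diff blocks; in
  # region 2 it loads on the block half a turn away, so its true
  # neighbourhoods are disjoint between regions
  planted_idx <- integer(0)
  blocks2 <- blocks1
  if (spec$n_planted_diff > 0) {
    planted_idx <- match(seq_len(spec$n_planted_diff), blocks1)
    shift <- max(1L, spec$n_blocks %/% 2L)
    blocks2[planted_idx] <-
      ((blocks1[planted_idx] - 1L + shift) %% spec$n_blocks) + 1L
  }
  n_de <- round(spec$de_fraction * m)
  de_idx <- sort(unique(c(planted_idx, sample.int(m, n_de))))
  region1 <- .generate_region(spec, blocks1, de_idx, "R1")
  region2 <- .generate_region(spec, blocks2, de_idx, "R2")
  list(region1 = region1, region2 = region2,
       truth = list(de_genes = genes[de_idx],
                    planted = genes[planted_idx],
                    blocks_region1 = stats::setNames(blocks1, genes),
                    blocks_region2 = stats::setNames(blocks2, genes),
                    spec = spec))
}

#' Planted-gene recovery of the zero-overlap selection
#'
#' Runs the network-building and zero-overlap stages on a generated pair,
#' restricted to the truth differential-expression intersection, and scores
#' recovery of the planted differential-topology genes.
#'
#' @param spec A `synthetic_spec`.
#' @param config An `edge_rule_config` for network construction.
#' @param samples Sample group feeding the correlations (default
#'   `"affected"`, matching the generator's design).
#' @return List with `sensitivity` (planted genes recovered / planted; `NA`
#'   if none were planted), `false_discovery_proportion` (non-planted
#'   fraction of the zero-overlap output; 0 if that output is empty),
#'   `zero_to` (the selected genes) and `planted`.
#' @export
recovery_test <- function(spec, config = edge_rule_config(),
                          samples = "affected") {
  gen <- generate_pair(spec)
  genes <- gen$truth$de_genes
  if (length(genes) < 2L) stop("truth DE intersection has fewer than 2 genes")
  net1 <- build_network(gen$region1, config, genes = genes, samples = samples)
  net2 <- build_network(gen$region2, config, genes = genes, samples = samples)
  z <- zero_to_genes(to_profile(net1, net2))
  planted <- gen$truth$planted
  sens <- if (length(planted)) length(intersect(planted, z)) / length(planted)
          else NA_real_
  fdp <- if (length(z)) length(setdiff(z, planted)) / length(z) else 0
  list(sensitivity = sens, false_discovery_proportion = fdp,
       zero_to = as.character(z), planted = planted)
}
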