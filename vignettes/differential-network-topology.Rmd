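---
title: "Differential topology of gene co-expression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential topology of gene co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(coexdiff)
```

## The question

When the same genes are expressed in two tissues — say two brain regions
sampled from diseased and healthy subjects — a gene can keep its expression
level yet change *who it is co-expressed with*. coexdiff quantifies that
change. For a pair of regions it builds one co-expression network per
region over a shared node set (the genes differentially expressed in both
regions), and then compares, gene by gene, the two network neighbourhoods.
Genes whose neighbourhoods share no members at all are the output of
interest: their co-expression context has been completely rewired between
the regions, which is read as a change in the gene's activity between the
two conditions the regions represent.

## The procedure

1. **Differential expression per region.** Affected and control samples
   are compared with a moderated difference statistic
   $d_i = (\bar{x}^{\text{aff}}_i - \bar{x}^{\text{ctl}}_i)/(s_i + s_0)$,
   where $s_i$ is the pooled standard error and $s_0$ the median of all
   $s_i$, with a label-permutation FDR (q-value). The default calling
   threshold is a relaxed FDR of 0.5% — relaxed deliberately, because the
   DE stage only selects the node set and downstream stages provide their
   own control. Externally computed DE lists can be supplied instead and
   bypass this stage.
2. **Intersection genes.** Genes called in both regions form the common
   node set, so the two networks are defined over identical genes and
   differ only in their edges.
3. **Co-expression networks.** Genes $i$ and $j$ are linked when, in that
   region's samples, either (1) their Pearson correlation is at least
   0.3 *and* one ranks within the other's top-3 most-correlated genes, or
   (2) their correlation is at least a high threshold $t$ (0.7 by
   default, 0.8 also customary) *and* one ranks within the other's
   top-50. Condition 1 gives every gene a local neighbourhood (minimum
   connectivity 3 when the top-3 correlations clear the floor); condition
   2 lets strongly correlated hubs exceed the rank limit. The result is a
   sparse, simple, undirected binary network.
4. **Cross-network topological overlap.** For gene $i$ with neighbour
   sets $X$ (network 1) and $Y$ (network 2) and degrees $d1_i$, $d2_i$:
   $$\mathrm{TO}_i = \frac{|X \cap Y|}{\max(d1_i, d2_i)}$$
   The *larger* degree is the denominator: a gene with 200 neighbours in
   one region and 10 in the other, all 10 shared, truly shares only 5% of
   its larger neighbourhood, and dividing by the smaller degree would
   score it a misleading 1. Values are reported rounded to 4 decimal
   places.
5. **Zero-overlap selection.** Genes with $|X \cap Y| = 0$ (tested on
   the exact integer count, so the rounding is cosmetic) and at least one
   positive degree are selected. Other cutoffs can be justified and are
   available via `to_threshold`.
6. **Randomization null.** Is the observed zero-overlap count explicable
   by degree structure alone? Both networks are rewired by double edge
   swaps — every gene keeps its exact degree while the wiring randomizes —
   1000 times by default, the zero-overlap count recorded each time, and
   the observed count compared with the null by
   $t = |\mu_1 - \mu_2| / (SD\sqrt{1/n_1 + 1/n_2})$ with $\mu_1$ the
   observed count ($n_2 = 1$ real network pair), $\mu_2$ and $SD$ the
   null mean and standard deviation over $n_1$ replicates, and a
   two-sided p on $n_1 + n_2 - 2$ degrees of freedom (999 at the
   default). In structured data the real pair has *fewer* zero-overlap
   genes than its rewired null, because genuine shared co-expression
   structure survives in both regions.
7. **Descriptive follow-up.** `degree_report()` ranks genes by
   cross-region connectivity change, and `enrich()` runs a one-sided
   hypergeometric over-representation test of the zero-overlap genes
   against user GMT gene sets, BH-corrected, with the *intersection
   genes* as universe — the selection was drawn from that pool, so
   conditioning on it is the honest null; padding the universe with genes
   that could never have been selected only inflates significance.

## A worked run

```{r, eval = FALSE}
spec <- synthetic_spec(seed = 4)
gen <- generate_pair(spec)
res <- run_pair(gen$region1, gen$region2,
                fdr_threshold = 0.05, n_permutations = 200,
                n_random = 100, seed = 3)
#> DE (internal permutation FDR): |A| = 134, |B| = 146; intersection = 124 genes
#> networks: A 349 edges, B 406 edges over 124 genes
#> zero-TO genes: 27 observed vs null mean 93.0 (t = 11.29, p = 1.75e-19)
```

The pair shares most of its co-expression structure, so only 27 of 124
genes have fully disjoint neighbourhoods where degree-matched random
wiring would produce about 93.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `base_threshold` | 0.3 | correlation floor for the top-3 rule |
| `top_k_strict` | 3 | rank cutoff of condition 1 |
| `high_threshold` (t) | 0.7 | correlation floor for the top-50 rule |
| `top_k_relaxed` | 50 | rank cutoff of condition 2 |
| `fdr_threshold` | 0.005 | DE calling q-value cutoff |
| `n_random` | 1000 | rewiring null replicates |
| `swap_factor` | 10 | attempted swaps per edge per rewiring |
| `to_threshold` | 0 | overlap cutoff for selection |

Both correlation thresholds are **inclusive** (`>=`). The defining
example of condition 1 links a candidate at exactly $r = 0.3$, so a
strict inequality would contradict the rule's own illustration; the same
convention is applied to $t$ for consistency. Rank ties are broken by
ascending gene identifier, making network construction deterministic
across platforms. Signed correlation is used — negative correlation never
links — with `use_absolute_correlation` available as an explicit opt-in.

Two genuinely open design points were resolved as follows. *Which samples
feed the correlations*: the `samples` selector is explicit and recorded;
the default is affected-only, since the networks are interpreted as
disease-state co-expression (the generator mirrors this default so truth
maps cleanly). *Whether to rewire one or both networks in the null*: both,
independently (`rewire = "both"`), since the null should randomize
topology on both sides of the comparison; `"second"` is available.

## Numerical and degenerate-input choices

- Genes isolated in both networks have vacuously disjoint neighbourhoods;
  they get TO = 0 with an `isolated` flag and are *excluded* from the
  zero-overlap output (reported separately), since the statistic presumes
  active neighbourhoods. Under condition 1 with adequate correlations
  they cannot occur, but synthetic edge cases can produce them.
- Zero-overlap selection compares the integer intersection size with 0,
  never the rounded ratio. With up to 5000 genes the smallest positive
  ratio, $1/4999$, still rounds to a positive 4-decimal value, so the
  rounding cannot silently zero a true overlap (guarded by a test).
- A rewiring target that admits no valid swap (e.g. a triangle, uniquely
  determined by its degree sequence) is returned unchanged with a
  warning; an all-identical null distribution is an error rather than a
  zero-division.
- With small cohorts the permutation test enumerates all distinct label
  assignments exactly (with a warning) instead of resampling; q-values
  are clipped to [0, 1] and forced monotone in $|d|$.
- Missing or non-finite expression values are rejected at load, never
  imputed; zero-variance genes are an error naming the gene.

## What the synthetic generator emulates — and what it does not

`generate_pair()` draws a two-region dataset from a latent-factor model:
genes in block $b$ are `loading * factor_b + noise`, so within-block
correlation is exactly $\ell^2/(\ell^2+\sigma^2)$ (0.64 at the defaults
$\ell = 0.8$, $\sigma = 0.6$) and between-block correlation is 0 in
population. Cohort sizes default to 10 affected / 13 control per region,
typical of laser-capture microdissection microarray studies. DE genes
(default half the genes, 1.5 total-SD mean shift in affected samples) are
drawn once and shared by both regions, so the truth DE intersection is
well-defined; planted differential-topology genes (default 10) are forced
into the DE set and load on one block in region 1 and a disjoint block in
region 2, so their true neighbourhoods share no members and, in the
noiseless limit, their overlap is exactly zero.

The generator controls Pearson correlation analytically, which is exactly
the quantity the edge rules consume — that is why a factor model was
chosen over copula or graph-conditioned samplers. It does **not** emulate
probe-level noise, summarization artefacts, batch structure, outlier
samples, heavy-tailed expression, or correlated noise between blocks.
Passing recovery tests therefore shows the pipeline correctly inverts its
own generative assumptions, not that it is robust to everything real
microarrays do.

One behaviour worth knowing: as `noise_sd` grows past the
signal-dominated range, sample correlations become chance-driven, the
zero-overlap set balloons, and planted genes get swept in along with
everything else — *sensitivity* can rebound while the *false discovery
proportion* of the selection climbs towards 1. Sensitivity alone is only
meaningful while the networks are signal-dominated; the test suite checks
the monotone sensitivity decline in that range and the monotone FDP
growth across the whole sweep.

## Problem sizes used by the test suite

The suite favours many small seeded replicates over few large ones:
8-gene expression fixtures (100 seeds) against an exhaustive edge-rule
oracle, 30-node network pairs (100 seeds) against a set-operations
overlap oracle, 50-node rewiring degree checks (100 seeds), 20 runs of
the default 300-gene generator with a 50-replicate null for the
direction check, and 10 seeds for planted-gene recovery. The minimum
connectivity scenario uses 200 genes over 20 samples with weak blocks
(loading 0.45, noise 0.89), tuned so every gene's top-3 correlations
clear 0.3; at that sample size the extreme tail of ~20k pairwise sample
correlations occasionally exceeds $t$, which adds condition-2 edges but
cannot lower the minimum degree.

## Known limitations

- Pearson correlation only; rank-based similarity would need a different
  edge-rule calibration and is not provided.
- The DE stage is a self-contained SAM-style statistic, not the SAM
  package; with precomputed SAM lists the pipeline reproduces the
  original workflow faithfully, and exact q-value agreement with SAM is
  not a goal.
- The null preserves each network's degree sequence but not, e.g., its
  clustering coefficient; significance is relative to degree structure
  only.
- No within-network topological overlap matrices or module detection:
  the statistic here compares a gene's neighbourhood *across* two
  networks, which is a different object from WGCNA-style TOM.
- Multi-region studies are handled as independent pairwise comparisons;
  no cross-pair statistic is defined.
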