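---
title: "Signal diagnostics for phylogenomic supermatrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal diagnostics for phylogenomic supermatrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quartetdiag)
```

## The problem this package addresses

Concatenated multi-gene ("supermatrix") phylogenomics routinely produces
trees with maximal support at every node, yet contested placements — for
example, which lineage of apoid wasps is the extant sister group of the
bees — can rest on signal that has little to do with shared ancestry.
Standard substitution models assume globally stationary, reversible and
homogeneous (SRH) sequence evolution; real lineages drift in base and
amino acid composition, and target-enrichment datasets carry large,
non-random blocks of missing data. Both can masquerade as phylogenetic
signal. quartetdiag implements the diagnostic toolkit used to interrogate
such placements:

1. **Bowker's matched-pairs test of symmetry** screens every taxon pair
   for violations of the SRH assumptions.
2. **Four-cluster likelihood mapping (FcLM)** asks, for every quartet of
   taxa drawn one-per-group from four predefined clusters, which of the
   three resolved quartet topologies the data support.
3. **Three permutation schemes** rebuild the supermatrix into null
   matrices that retain progressively less structure, so that residual
   quartet support on randomized data exposes confounding
   (non-phylogenetic) signal.
4. A **supermatrix assembly** stage builds the protein-domain-based data
   blocks these analyses partition over, and a **simulator** generates
   study-shaped data on which every stage is validated.

## Models and statistics

### Bowker's test

For a pair of aligned sequences, restricted to columns where both carry
data, let $n_{ij}$ count columns with state $i$ in one sequence and $j$
in the other. Under SRH evolution the expected divergence table is
symmetric. Bowker's statistic

$$B = \sum_{i<j,\; n_{ij}+n_{ji}>0} \frac{(n_{ij}-n_{ji})^2}{n_{ij}+n_{ji}}$$

is referred to the upper tail of a $\chi^2$ distribution with one degree
of freedom per contributing pair. A pair with no off-diagonal
disagreement ($\mathrm{df}=0$) is assigned $p=1$: there is no evidence
against symmetry, and the convention keeps the all-pairs heat map total.
The pass/fail boundary is strict — $p > \alpha$ passes (the "white cell"
of the heat map), $p \le \alpha$ fails.

### Quartet likelihoods and likelihood mapping

For each quartet the three unrooted topologies $T_1=(12|34)$,
$T_2=(13|24)$, $T_3=(14|23)$ (indices in the hypothesis's group order)
are scored by exact Felsenstein pruning on the four-leaf tree, under
GTR+$\Gamma$ (nucleotide) or LG+$\Gamma$ (amino acid, published LG
exchangeabilities). Rate matrices are scaled to one expected substitution
per site per unit branch length; discrete-gamma rates use
equal-probability categories with mean-of-category rates (mean 1; four
categories by default). Columns missing in any of the four taxa are
excluded partition-wise; a quartet with no usable site is reported as
*undetermined* and excluded from proportions.

The five branch lengths are optimized per topology by round-robin Brent
search on $[10^{-8}, 10]$, iterated until the log-likelihood improves by
less than $10^{-6}$ or 100 rounds. The optimized log-likelihoods map to
simplex weights $p_i \propto e^{\ell_i}$ (computed via log-sum-exp), a
point in the equilateral triangle, and one of seven regions: corner
$C_i$ when $p_i > 2/3$, an edge when the smallest weight is below $1/6$,
otherwise the center. The corner and edge constants are configurable:
they approximate the canonical likelihood-mapping partition, and all
package-level conclusions are proportions robust to their exact values.

### Model parameters for FcLM

Model parameters are estimated once per partition on the full matrix —
empirical frequencies, and gamma shape (plus GTR exchangeabilities for
nucleotide data) maximized on a small fixed sample of quartets with
star-like fixed branch lengths — then held fixed across all quartets.
Per-quartet re-estimation would be unstable on sparse partitions, and a
fixed global model mirrors how partitioned supermatrix analyses are run
in practice. Branch lengths are shared across partitions within a
quartet: a quartet has only five branches, and per-partition branch sets
overfit small domain blocks.

### Permutation schemes

Scheme I permutes observed residues within each partition, across taxa
and sites; it destroys phylogenetic signal while preserving each
partition's residue multiset and the exact missing-data mask. (The
permutation is cell-wise within the partition; a column-wise variant
would retain per-column composition, which is part of what the scheme is
meant to destroy.) Scheme II replaces observed cells with i.i.d. draws —
LG frequencies for amino acid matrices, per-partition empirical
frequencies for nucleotide matrices by default — additionally destroying
among-taxon compositional heterogeneity; the mask is still preserved.
Scheme III finally permutes the missing/observed indicator uniformly
within each partition, destroying the missing-data geometry while
conserving per-partition missing-cell counts. When a permuted amino acid
matrix is analyzed by FcLM, a single LG model is applied across all
partitions, since partition-specific structure no longer exists.
Corrected support compares original and permuted region proportions as
$\max(0, \text{orig}_i - \text{perm}_i)$; the subtraction floor keeps
proportions interpretable.

### Supermatrix assembly

Gene alignments arrive masked (ambiguously aligned amino acid columns,
removed together with their codons) and annotated with protein domains.
Columns inside a domain annotation are pooled across genes into one
block per domain identifier; non-domain columns form one residual block
per gene (pooling residual regions across genes is an alternative the
package does not implement). Blocks with fewer than four data-bearing
taxa or no parsimony-informative column are dropped — an explicitly
stated proxy for "no phylogenetic information content", not a MARE
information score. The required-groups rule keeps a block only if every
named group contributes at least one taxon with actual sequence data
(presence of a fully gapped taxon does not count). Blocks concatenate in
lexicographic name order, missing-filled, with 1-based inclusive
coordinates; codon partition schemes model each position of each block
separately (NT123) or drop third positions (NT12). The MCMC bookkeeping
helper computes retained posterior sample counts
(runs × (generations/interval − burn-in)); with three runs of three
million generations sampled every 500 and 25% burn-in it returns 13,500.

## The simulator, and what passing tests do and do not show

The simulator evolves sites down a tree by standard CTMC sampling: root
states from the stationary frequencies, per-edge transition matrices,
per-site discrete-gamma rate categories. Lineage-heterogeneous
composition — the violation the Bowker screen exists to catch — is
induced by rebuilding the rate matrix with override frequencies on
flagged subtrees, making the process non-stationary across the tree.
Amino acid and nucleotide tracks are simulated independently on the same
tree under their own models; the 3:1 column correspondence is
bookkeeping, as every downstream analysis treats the tracks separately.
Missingness is block-structured by default (whole gene × taxon dropout),
matching target-enrichment data geometry. Defaults are chosen as
realistic study conditions: occupancy 0.9, 20% masked columns, one to
two annotated domains per gene, and a `paper_shaped` layout of 183 taxa
/ 195 genes whose four-cluster hypothesis groups have sizes 2, 5, 42 and
134, mirroring the published bee-sister-group design.

The simulator does **not** generate indels, codon-linked substitution,
alignment error beyond the mask annotations, or rate variation across
genes beyond length differences. Passing diagnostics on simulated data
therefore validate the statistical machinery — calibration of the
symmetry test, topology recovery and star-signal detection by FcLM, the
conservation contracts of the permutation schemes — not the biological
correctness of any particular empirical result.

## Numerical choices and degenerate inputs

* Transition matrices come from the spectral decomposition of the
  symmetrized reversible rate matrix; rows are renormalized and clipped
  at zero against rounding.
* Four-taxon site likelihoods are computed in probability space (no
  per-node scaling is needed at this tree size); a site whose likelihood
  underflows to zero is floored at the smallest positive double, so an
  "impossible" column yields a large negative contribution rather than
  $-\infty$.
* Pattern compression makes nucleotide quartets cheap (at most 256
  distinct fully observed patterns), and per-branch partial products are
  cached during optimization so each Brent evaluation rebuilds a single
  transition matrix.
* Ties in region classification break toward the lower region index;
  weight vectors are deterministic functions of the data, so fixed seed
  plus fixed inputs give byte-identical reports.
* All randomness flows through a single seed per entry point; internal
  RNG use saves and restores the caller's RNG state.

## Problem sizes used in validation

The shipped validation suite runs the Bowker calibration on 2,000
simulated homogeneous pairs of 10,000 sites (rejection expected in
[0.03, 0.07] at $\alpha = 0.05$) and 200 heterogeneous pairs (power
above 0.5); FcLM recovery on 200 quartets from the 183-taxon
`paper_shaped` layout at 5,000 nucleotide sites (at least 95% of
quartets in the generating corner, and a star-tree control whose modal
region is the center); pruning-versus-enumeration agreement on 200
random model draws; permutation contracts plus corner-support erasure on
an eight-taxon, 6,000-site simulation; and supermatrix algebra on 100
randomized gene sets. These sizes were chosen so the whole suite runs on
a laptop-class single core in minutes while keeping the binomial error
of every rate estimate well inside the asserted bands.

## Known limitations

* FcLM here is a diagnostic, not a tree builder: only four-taxon
  likelihoods are implemented, and only the three resolved topologies of
  a four-group hypothesis are compared.
* The information-content filter is a stated proxy; it will not
  reproduce MARE scores on real data.
* Quartet totals of the original study (58,050 and 103,320) depend on
  group memberships not published in machine-readable form; the package
  reproduces the method, not those counts.
* The LG-frequency option of permutation scheme II applies to amino
  acid matrices only; nucleotide nulls use empirical or uniform
  frequencies.
* No NEXUS dialect, no invariant-sites category, no codon models.
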