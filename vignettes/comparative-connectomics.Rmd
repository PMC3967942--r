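---
title: "Comparing labeled connectomes: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing labeled connectomes: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comparanet)
```

## The setting

Two whole-brain structural networks are expressed in one parcellation of
assumed homologue regions, so that row *i* of one adjacency matrix and row
*i* of the other describe "the same" region in two species (or cohorts, or
modalities). The canonical use case is a bilateral map of 82 regions, with
a tract-tracing-derived matrix on one side and a tractography-derived one
on the other. Because the two sides are measured with incommensurable
weight scales, the main analysis is **binary at matched density**: the
weighted side is averaged over subjects and only its top-*L* weights are
kept, with *L* the reference side's edge count, and then binarized. Every
similarity statement is then assessed against explicit null ensembles
rather than taken at face value.

## The statistics

**Intersection ratio.** With edge sets $E_A$, $E_B$ and common edge count
$L$, the ratio $L_x/L = |E_A \cap E_B| / L$ in $[0,1]$ summarizes
whole-network wiring agreement.

**Homologue connectivity similarity (HCS).** For region $i$,
$\mathrm{HCS}_i = |\Gamma_A(i) \cap \Gamma_B(i)| /
|\Gamma_A(i) \cup \Gamma_B(i)|$ — the Jaccard similarity of its neighbor
sets. First-order: do the same partners connect to $i$ in both networks?

**Matching index and HMIS.** Within one network, the matching index
$MI(i,j) = |(\Gamma(i) \cap \Gamma(j)) \setminus \{i,j\}| /
|(\Gamma(i) \cup \Gamma(j)) \setminus \{i,j\}|$ measures how similar two
regions' neighborhoods are, with **both endpoints excluded from both
neighbor sets** before intersecting. Row $i$ of the MI matrix is region
$i$'s connectivity-similarity profile; the homologue matching index
similarity $\mathrm{HMIS}_i$ is the Pearson correlation of that row across
the two networks (diagonal excluded). Second-order: does region $i$ keep
the same "connectivity coalitions", even if individual edges moved?

The endpoint-exclusion convention is load-bearing. On the four-node toy
pair built by `fig1d_toy()` (network 1: A–B, A–C, A–D, B–C; network 2:
A–B, A–C, A–D, C–D), region A has identical neighbors in both networks
(HCS = 1), yet its MI rows are $(0.5, 0.5, 0)$ and $(0, 0.5, 0.5)$, whose
correlation is exactly $-0.5$. Only the exclude-both-endpoints rule
reproduces this analytic value; excluding neither, or only one, does not.
The package therefore applies it everywhere, including the weighted cosine
variant below.

**Weighted variants.** Hemisphere-wise networks are so dense (~0.79) that
binary statistics saturate against rewired nulls, so the within-hemisphere
arm uses weighted metrics that never compare weights *across* the two
matrices: the weighted matching index is the cosine similarity of weight
rows with positions $i$ and $j$ zeroed in both rows, and the weighted HMIS
correlates its rows. The intersection ratio and HCS are deliberately
absent from that arm.

**Rich club.** $\phi(k) = 2E_{>k} / (N_{>k}(N_{>k}-1))$ over the regions
with degree *strictly* greater than $k$; the weighted form divides the
club's weight sum $W_{>k}$ by the sum of the $E_{>k}$ largest weights in
the whole network. Raw coefficients rise mechanically with $k$, so they
are normalized by the mean coefficient of degree-matched nulls;
$\phi_{norm}(k) > 1$ over a range of $k$, with small per-level empirical
p, indicates a club beyond what the degree sequence explains.

## Null models and p-values

* **Degree-preserving rewiring** (binary): repeated double-edge swaps, 10
  attempted swaps per edge by default (a standard mixing heuristic; the
  package asserts exact degree conservation on every draw rather than
  proving mixing). Backed by igraph's C implementation.
* **Link-and-weight reshuffle** (weighted): rewire the support as above,
  then permute the weight multiset over the new edges. Weights are
  conserved exactly as a multiset; strengths are not.
* **Region draws** (rich-club overlap): member-set sizes drawn uniformly
  without replacement, independently per network — the null overlap is
  hypergeometric, and the Monte-Carlo draw is checked against that closed
  form in the tests.
* For region-wise cross-network statistics (HCS, HMIS), each null draw
  rewires **both** networks independently. Rewiring only one side would
  hold the other side's idiosyncrasies fixed and shift the null mean; the
  both-sides choice is symmetric and is the package default (documented
  here because the underlying convention is genuinely open).

Empirical p-values use $(1 + \#\{\text{null at least as extreme}\}) /
(1 + n)$, never $0$; with $n = 10000$ the smallest attainable value is
$\approx 10^{-4}$. z-scores use the sample SD of the nulls. Bonferroni
correction tests $p < \alpha/m$ with $m$ the number of defined
region-tests (82 in the canonical setting); Benjamini–Hochberg step-up is
available for the weighted arm, where discovery-rate control is the more
common reporting convention.

**Empirical vs z-score p at reduced ensemble size.** The two conventions
interact: with $n_{null} = 1000$, the empirical floor $1/1001$ is *larger*
than $0.05/82$, so no region can ever pass Bonferroni regardless of
effect size. At full $n_{null} = 10000$ this cannot happen. For
scaled-down runs the pipeline therefore offers
`p_method = "zscore"` — the Gaussian tail of the null z-score — as the
operative region-wise p; preserved regions in the synthetic world sit at
$z \approx 15$ and scrambled ones at $z \approx 0$, so the choice never
decides borderline cases there. The default remains `"empirical"`.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_null` | 10000 | ensemble size; governs the empirical p floor |
| `alpha` | 0.05 | significance level after correction |
| `correction` | bonferroni | `fdr_bh` for the weighted arm |
| `n_swap_per_edge` | 10 | attempted double-edge swaps per edge |
| `rewire_prob` | 0.1 | per-edge probability of entering a swap (robustness control) |
| `insert_fraction` | 0.1 | fraction of L inserted into empty pairs (robustness control) |
| `hub rule` | mean + 1 SD | flag threshold for central regions |

Thresholding ties are broken deterministically (weight descending, then
lexicographic label pair), so density matching is seed-free and
reproducible; real tractography weights rarely tie, but the synthetic
worlds and rounded inputs do.

## The synthetic worlds

`generate_planted_pair()` emulates the *structure of the comparison*, not
brain biology: two binary networks with exactly equal edge count, a
planted shared-edge fraction (realized within ±2 edges), a set of regions
whose neighborhoods are forced identical (their HCS is exactly 1 by
construction) and a set scrambled by degree-preserving swaps confined to
their incident edges. Defaults mirror the canonical setting: 82 regions,
1857 edges (density 0.559, i.e. 1857/3321), overlap 0.754. The generator
starts from an Erdős–Rényi G(n, L) graph, so it reproduces *densities and
overlaps* but **not** the heavy-tailed degree structure, spatial
embedding, hemispheric symmetry or genuine rich-club organization of real
connectomes — a green planted-pair test certifies the statistics'
calibration and recovery behavior, not neuroanatomical realism. (One
visible consequence: the null intersection ratio of ER pairs equals the
density, ≈ 0.559, whereas degree-heterogeneous real connectomes push it
higher, ≈ 0.6.) Planted rich clubs for testing the club machinery are
built explicitly in the test suite as clique-plus-periphery graphs.

`generate_subjects()` adds independent symmetric Gaussian noise (clipped
at zero) to a shared weighted backbone. The default `noise_sd = 0.7`
against log-normal(0, 1) weights puts pairwise inter-subject correlations
in the mid-0.8s, the regime reported for small tractography cohorts; it
emulates between-subject measurement variability only, not systematic
individual differences in topology.

## Numerical choices and degenerate inputs

* Self-connections are forbidden; nonzero diagonals are zeroed on ingest
  with a warning.
* Undefined values are `NA` and propagate: a region isolated in both
  networks has undefined HCS (not 0); an MI pair with empty union after
  exclusion, a cosine row that is zero after exclusion, and a correlation
  over a constant row are all undefined. Row correlations drop undefined
  entries pairwise and require at least 3 valid pairs. Nothing is silently
  imputed — notably, with unit weights the cosine MI is *not* numerically
  identical to the binary Jaccard MI, and on very sparse graphs the
  NA rules can leave weighted HMIS undefined where binary HMIS is not;
  the package treats the stated conventions as authoritative.
* Eigenvector centrality is the principal eigenvector of the dense
  symmetric matrix (unit Euclidean norm, nonnegative); on disconnected
  graphs the dominant component carries the mass and a warning lists the
  component count. Weighted betweenness uses lengths $1/w$; weighted
  clustering uses the Onnela geometric-mean form with degrees on the
  binary support; degree-<2 regions get clustering 0 by convention.
* Spearman p-values use the t approximation (appropriate at n = 82 and
  standard in the field's toolboxes); exact enumeration is not attempted.
* Rich-club curves are reported for $k = 0, \dots, \max(d) - 1$;
  $\phi$ is undefined for clubs of fewer than two members, and the
  reporting peak is the $k$ maximizing $\phi_{norm}$ among levels with at
  least 3 members and a defined null mean.
* The rewire-probability robustness control pairs pooled edges with a
  feasible partner (searching the pool), so the expected fraction of
  displaced edges is close to the nominal probability even at density
  0.56, where blind double-edge swaps fail two times in three.

## Known limitations

* The degree-preserving rewiring is the standard swap-chain heuristic;
  uniformity over the fixed-degree-sequence ensemble is assumed, not
  proven.
* The planted-pair generator treats "maximally scrambled" as a target
  subject to the overlap budget; when overlap and rewiring constraints
  collide it scrambles less rather than missing the planted overlap, and
  raises an error only when the overlap itself is unattainable.
* The weighted arm's reshuffle null conserves topology-degree structure
  and the weight multiset but not strengths; analyses whose null should
  conserve strength sequences need a different model.
* No spatial information is modeled anywhere: distance-dependent
  connection costs, geometric nulls and surface renderings are out of
  scope.
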