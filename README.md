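# comparanet

Comparative analysis of labeled brain connectomes in R.

## The problem

Macroscale connectomes from two species (or two cohorts, or two mapping
modalities) can be compared directly when their regions are expressed in a
shared parcellation of assumed homologues — e.g. a bilateral regional map of
82 regions (41 per hemisphere), with one binary undirected adjacency matrix
per species built at matched density. `comparanet` implements the full
analysis stack for such comparisons, for network neuroscientists who have
two labeled adjacency matrices and want defensible statistics rather than
ad-hoc scripts:

- **Construction** — symmetrize/binarize a directed tract-tracing matrix;
  average per-subject tractography weight matrices; threshold the average to
  a reference edge count *L* (density matching, deterministic tie-break);
  split by hemisphere.
- **Whole-network similarity** — the edge intersection ratio
  *L<sub>x</sub>/L* of the two networks.
- **Region-wise similarity** — the *homologue connectivity similarity*
  HCS<sub>i</sub> = |Γ<sub>A</sub>(i) ∩ Γ<sub>B</sub>(i)| /
  |Γ<sub>A</sub>(i) ∪ Γ<sub>B</sub>(i)| (Jaccard of neighbor sets), and the
  *homologue matching index similarity* HMIS<sub>i</sub> = r(MI<sub>A</sub>[i,·],
  MI<sub>B</sub>[i,·]) — the Pearson correlation of region *i*'s
  matching-index row across species, where
  MI(i,j) = |(Γ(i)∩Γ(j))∖{i,j}| / |(Γ(i)∪Γ(j))∖{i,j}|. Weighted variants
  use the endpoint-excluded cosine similarity of weight rows.
- **Topology** — betweenness centrality, eigenvector centrality, clustering
  coefficient (binary and weighted forms), cross-species Spearman rank
  correlations, mean + 1 SD hub flagging.
- **Rich club** — φ(k) = 2E<sub>&gt;k</sub> /
  (N<sub>&gt;k</sub>(N<sub>&gt;k</sub>−1)), its weighted ranked-sum analogue
  φ<sub>w</sub>(k) = W<sub>&gt;k</sub> / Σ<sup>E&gt;k</sup> w<sup>rank</sup>,
  normalization against degree-matched nulls, member extraction at the
  normalized peak, a cross-species membership overlap permutation test, and
  rich vs non-rich permutation contrasts.
- **Statistics** — degree-preserving rewiring and link-and-weight-reshuffle
  null ensembles, empirical z-scores and p-values with the
  (1 + count)/(1 + n) convention, Bonferroni and Benjamini–Hochberg
  correction, and perturbation / random-insertion robustness controls.
- **Synthetic data** — a planted-pair generator (exact edge count,
  controllable edge overlap, regions with forced-identical or scrambled
  neighborhoods) and a multi-subject weighted-matrix generator, so every
  part of the pipeline is testable without any external data.

## Worked example

```r
library(comparanet)

## the two four-region toy "brains" that dissociate HCS from HMIS
toy <- fig1d_toy()
intersection_ratio(toy[[1]], toy[[2]])
#> [1] 0.75
hcs(toy[[1]], toy[[2]])["A"]      # region A keeps exactly neighbors B, C, D
#> A
#> 1
hmis(toy[[1]], toy[[2]])["A"]     # ... yet its similarity profile flips
#>    A
#> -0.5

## a full synthetic study: 82 regions, 1857 edges (density 0.559),
## 75.4% planted edge overlap, 10 preserved and 5 rewired regions
sp <- planted_pair_spec(82, 1857, 0.754, preserved_regions = 1:10,
                        rewired_regions = 11:15, seed = 5)
pp <- generate_planted_pair(sp)
cfg <- analysis_config(species_a = pp$a, species_b = pp$b,
                       arm = "whole_brain_binary", n_null = 1000,
                       p_method = "zscore", seed = 1)
rep <- run_whole_brain(cfg, verbose = FALSE)
rep
#> <comparative_report: whole_brain_binary arm>
#>   intersection ratio 0.754 (z = 24.34, p = 0.000999)
#>   significant HCS regions: 56 / 82
#>   significant HMIS regions: 7 / 82
#>   rich-club overlap 3/4 at k = 51/52 (p = 0.002997)
write_report(rep, "results/run1")
```

The intersection ratio sits ~24 null standard deviations above
degree-matched chance (the null mean is the density, ≈ 0.559). At 75.4%
planted overlap most regions share well over half of their neighbors, so
56 of 82 clear the Bonferroni bar for HCS — among them all 10 regions whose
neighborhoods were planted identical (HCS = 1 exactly) — while none of the
5 deliberately rewired regions does. HMIS, the stricter "second-order"
profile correlation, flags only 7 regions on this unstructured
Erdős–Rényi-style world. The rich-club members at the normalized peak are
the handful of highest-degree nodes; a planted pair has no engineered club,
and the rich-club machinery is exercised against planted club structures in
the test suite.

## Command line

```sh
Rscript inst/cli/comparanet.R toy-fig1d --out fixtures/
Rscript inst/cli/comparanet.R simulate --n-regions 82 --n-edges 1857 \
        --edge-overlap 0.754 --seed 1 --out fixtures/
Rscript inst/cli/comparanet.R run --a fixtures/pair_a.tsv \
        --b fixtures/pair_b.tsv --arm whole_brain_binary \
        --n-null 1000 --seed 1 --out results/
```

All inputs and outputs are plain TSV: dense labeled matrices (header row +
label column), 3-column edge lists (optional `# labels:` header preserving
isolated regions), and per-region/per-k result tables.

## Further documentation

`vignettes/comparative-connectomics.Rmd` describes the model and every
convention choice (endpoint exclusion, tie-breaks, NA discipline, p-value
conventions, what the synthetic worlds do and do not emulate).
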