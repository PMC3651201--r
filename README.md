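# sitematch

Enzyme function prediction by catalytic-site template matching. Given a
query protein structure, sitematch searches a library of catalytic-site
templates — one centroid per critical residue, ion, or cofactor, plus
their pairwise-distance matrix — for residue subsets of the query whose
geometry reproduces a template, then re-ranks the candidate matches with
geometric and physical descriptors combined in a size-partitioned logistic
score. It is aimed at structural bioinformaticians annotating structures of
unknown function against curated site libraries, and at method developers
who need a fully seeded synthetic benchmark for site-matching pipelines.

## Method

A template is a small complete graph: nodes are residue centroids (Cα for
amino acids, the single atom for ions, a curated atom for cofactors) and
edges are distances d_T,ij. Matching is a pruned subgraph-isomorphism
search over the query's candidate residues:

- candidate pools per template position admit the template's residue type,
  any substitution allowed by the template-specific binary substitution
  matrix (derived from homolog sites with matching residue count and EC
  number), and any-ion-for-any-ion wildcarding;
- paths are grown position by position in canonical residue order; every
  new edge must agree with the template edge within 1.5 Å, partial paths
  are ranked by the running distance-matrix RMSD, and the best P_max = 100
  survive each step (the first pair screen is never pruned) — quadratic
  cost in target size, linear in template size;
- each complete match m is described by
  rmsddm(d_T, d_S) = sqrt( Σ_(i<j) (d_T,ij − d_S,ij)² / m ) with
  m = n_T(n_T−1)/2, the count e_inc of edges within 0.5 Å, the estimated
  fraction f of correctly placed residues obtained from the quadratic
  edge-loss model n_exc = ((2n_T−1) − sqrt((2n_T−1)² − 8·E_exc))/2,
  the removed-standard-residue count, the quaternion-superposition
  backbone RMSD, the mean distance d_c to the nearest pocket center
  (entering as (d_c + 0.1)^−1), and the interaction term
  f·e_inc·(d_c + 0.1)^−1;
- a logistic model with size-binned coefficients (bins 2, 3, 4–7) maps the
  descriptors to a probability; hits are labeled positive on exact
  four-field EC agreement, deduplicated per (target, family, label), and
  evaluated by ROC/AUC, TPR, and Matthews correlation sweeps.

Four published coefficient sets are bundled (`bundled_model()`);
`fit_logistic()` refits by unregularized maximum likelihood on your own
hit tables.

## Worked example

Generate a 4-residue template, plant a jittered copy among 30 decoy
residues, and search:

```r
library(sitematch)

tpl <- generate_template(4, seed = 42, ec = "3.4.21.4", site_id = "F001-0")
pl  <- plant_in_decoy(tpl, jitter_sigma = 0.15, n_decoys = 30,
                      seed = 7, target_id = "query")
pool <- build_candidate_pool(pl$target, tpl)
hits <- search_template(pool)
hits_table(hits)
#> # A tibble: 1 × 7
#>   site_id target_id  rank rmsddm residues          n_substitutions substitutions
#>   <chr>   <chr>     <int>  <dbl> <chr>                       <int> <chr>
#> 1 F001-0  query         1  0.203 ASP A 1; CYS A 2…               0 ""
```

The one complete match is the planted site: its distance matrix deviates
from the template by 0.203 Å RMS, consistent with the 0.15 Å per-coordinate
jitter. Its descriptor vector confirms a clean hit — all 6 edges inside the
0.5 Å inclusion threshold (`e_inc = 6`, `f = 1`) and a 0.22 Å backbone
superposition residual:

```r
dv <- compute_descriptors(tpl, hits, find_pockets(pl$target))
dplyr::select(dv, rank, rmsddm, e_inc, f, backbone_rmsd, d_c)
#> # A tibble: 1 × 6
#>    rank rmsddm e_inc     f backbone_rmsd   d_c
#>   <int>  <dbl> <int> <dbl>         <dbl> <dbl>
#> 1     1  0.203     6     1         0.219    50
```

(`d_c = 50` is the documented no-pocket sentinel: a scattered decoy target
has no real surface concavity.)

End to end, on a seeded synthetic benchmark the full descriptor set
separates true from cross-family hits where the search's raw rmsddm alone
cannot:

```r
bench <- generate_benchmark(benchmark_spec(n_families = 10, seed = 3))
hits  <- benchmark_hits(bench, use_pockets = FALSE)
ev    <- benchmark_evaluation(hits)
c(full = ev$full$auc, rmsddm_only = ev$minimal$auc)
#>        full rmsddm_only
#>           1         0.4
```

`evaluate_hits()` objects support `tidy()`, `glance()`, and `autoplot()`
(ROC, TPR-vs-threshold, MCC-vs-threshold panels). A thin command-line
front end over the same functions lives at `inst/cli/sitematch.R`
(subcommands `simulate`, `build-catalog`, `search`, `score`), and every
command writes a JSON manifest sufficient to reproduce its output.

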