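# rgranule

Sequence-based prediction of RNA granule proteomes and analysis of their
protein–protein-interaction (PPI) network grammar.

## What it does

Stress granules and P-bodies are membraneless condensates of RNA and
RNA-binding proteins. Their catalogued proteomes are small and graded by
evidence strength (tier 1 = strongest, tier 4 = weakest), which makes a
proteome-wide view hard to get experimentally. `rgranule` takes the
machine-learning route:

1. **Features.** Every protein sequence becomes a 139-dimensional vector:
   19 physicochemical descriptors (length, molecular weight, pI, GRAVY,
   low-complexity-region fraction, charge and composition statistics,
   Vihinen flexibility, ...), 20 amino-acid composition fractions, and the
   fractions of the 50 most abundant 2-mers and 50 most abundant 3-mers of
   the positive training set (overlapping counts over L − k + 1 windows).
2. **Classifier.** A balanced learning set (tier-filtered positives plus
   catalogue-excluded random negatives) trains a seeded random forest
   (500 trees, √p features per split). Stratified 10-fold cross-validation
   reports AUC and PR-AUC as mean ± SEM, with per-fold re-selection of the
   k-mer vocabulary so feature selection never sees test data, and averaged
   Gini importances normalized to sum 1. Each protein receives a granule
   propensity p ∈ [0, 1]; p > 0.7 is flagged high-confidence.
3. **Profiles.** A sliding window (50 residues, step 5) scored by the model
   yields per-residue propensity tracks and peak calls, annotated with
   windowed GRAVY and cysteine fraction.
4. **Network grammar.** From a STRING-style edge list (combined score ≥ 400)
   the predicted proteome's graph is built, and per node seven metrics are
   computed — degree, betweenness, eigenvector, PageRank, closeness
   (Wasserman–Faust), clustering coefficient, degree centrality — each with
   mid-rank percentile ranks. Propensity bins ([0.5,0.6) ... [0.9,1.0]) are
   compared by adjacent-bin one-way ANOVA; seeded Louvain clustering
   extracts dense communities summarized over their high-confidence members;
   multi-list Venn accounting and a seeded 2D layout round out the toolkit.
5. **Synthetic data.** A seeded generator emits FASTA proteomes with planted
   compositional signal (RGG motifs, hydrophilicity tilt, low-complexity
   stretches, cysteine depletion, decaying by tier), tier tables, and
   block-structured PPI edge lists with propensity-coupled density — so the
   entire pipeline is testable offline.

## Worked example

```r
library(rgranule)

cfg <- granule_sim_config()                      # default study conditions
pr  <- generate_proteome(cfg, seed = 1)
ls  <- assemble_learning_set(pr$tiers, pr$records, "PBSG", "==1", seed = 2)
recs <- pr$records[c(ls$positives, ls$negatives)]
labs <- rep(c(1L, 0L), each = length(ls$positives))

cv <- granule_cv(labels = labs, records = recs, k = 10, seed = 3)
cv
#> 10-fold cross-validation (strict vocabulary)
#>   AUC:    1.000 +/- 0.000 (mean +/- SEM)
#>   PR-AUC: 1.000 +/- 0.000

head(sort(cv$importance, decreasing = TRUE), 5)
#>           k3_RGG            gravy mean_flexibility            k2_GG
#>       0.11779531       0.11237192       0.10146808       0.07591907
#>            k2_RG
#>       0.07390458
```

The planted discriminators — RGG content, low GRAVY — top the importance
ranking, and cross-validation separates the planted classes essentially
perfectly. Training a full model and scoring the catalogue tiers:

```r
vocab <- build_vocabulary(recs[labs == 1])
feats <- build_feature_table(recs, vocab)
fit   <- granule_fit(feats, labs, vocabulary = vocab, seed = 4)
fbt   <- lapply(split(pr$tiers$accession, pr$tiers$tier),
                function(a) build_feature_table(pr$records[a], vocab))
round(tier_identification_rates(fit, fbt), 1)
#>     1     2     3     4
#> 100.0  95.0  61.7  21.7
```

Identification rates decay with evidence tier, mirroring the decaying
planted signal. On the network side:

```r
ed   <- generate_ppi(cfg, seed = 5)               # planted 3-block model
g    <- ppi_graph(ed, vertices = names(attr(ed, "blocks")))
part <- louvain_partition(g, seed = 6)
part
#> Louvain partition: 3 clusters, modularity 0.600 (resolution 1, seed 6)
#>   sizes: 60, 60, 60
adjusted_rand_index(part$membership[names(attr(ed, "blocks"))],
                    attr(ed, "blocks"))
#> [1] 1
```

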