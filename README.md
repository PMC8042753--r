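# dupdiverge

Scoring the degree of functional divergence of duplicate gene pairs, and
asking what that divergence did to their subsequent evolution.

After a gene duplication, some pairs of copies diverge into distinct
functions (knocking out either copy gives an abnormal phenotype), while
others stay largely redundant (only the double knockout is abnormal). Given
a set of pairs with phenotype-derived *high* / *low* diversification labels,
`dupdiverge` builds the two features that discriminate the classes —

- **K\_A/K\_S** — nonsynonymous over synonymous substitutions per site
  between the two coding sequences (protein divergence per unit of
  duplication age), estimated by Nei–Gojobori (1986) counting with a
  Jukes–Cantor correction on a back-translated codon alignment;
- **Re/K\_S** — Spearman correlation of the two genes' expression profiles
  across a condition compendium, normalised by K\_S (expression similarity
  per unit of age);

and fits a binomial GLM for the **degree of functional divergence**,

```
logit(DFD) = b0 + b1 * KA/KS + b2 * Re/KS
```

so that DFD is the probability that a pair is highly diversified.
Classification thresholds are calibrated at a 5% false-positive rate from
the class-conditional score percentiles, giving a three-way call
(high / low / unclassified). Downstream modules test the functional
correlates of the calls (shared GO terms and domains, core-gene status, PPI
degree, expression breadth, tandem vs whole-genome duplication mechanism),
compare ortholog retention rates in two related species, and estimate
branch-specific K\_A/K\_S with positive/purifying selection calls on a
three-taxon star (A. thaliana / A. lyrata / B. rapa), with bootstrap
support for the observed trends. A fully seeded synthetic-data generator
produces every input the pipeline consumes — codon pairs evolved under a
chosen selection intensity ω, expression profiles with targeted Spearman
correlations, annotations, and ortholog triplets with class-dependent
retention — so every stage is testable end to end without downloads.

## Worked example

Estimate divergence for one simulated pair evolved at ω = 0.2:

```r
library(dupdiverge)

pair <- simulate_codon_pair(n_codons = 300, t = 0.3, omega = 0.2, seed = 7)
estimate_pair_divergence(pair$cds_a, pair$cds_b, aligned = TRUE)
#> NG86 divergence over 300 codons: Ka = 0.1308, Ks = 0.5434, Ka/Ks = 0.2408
```

The estimate recovers the planted ω ≈ 0.2 at the planted synonymous
divergence 2t ≈ 0.6. Run the whole pipeline on a simulated input bundle:

```r
dir <- tempfile()
simulate_dataset(sim_config(n_high = 150, n_low = 100, seed = 7), out_dir = dir)
res <- run_full_pipeline(run_config(input_dir = dir, out_dir = tempfile(),
                                    aligned_orthologs = TRUE, seed = 7))
str(res$manifest)
#> $ n_pairs_in    : int 250
#> $ n_kept        : int 109     # identity >= 30%, coverage >= 50%, Ks <= 3
#> $ n_rejected    : int 141
#> $ n_high        : int 39
#> $ n_low         : int 70
#> $ n_unclassified: int 0
#> $ roc_auc       : num 0.998
#> $ thr_low       : num 0.811
#> $ thr_high      : num 0.128
```

Counts are conserved across stages (`kept + rejected = input`,
`high + low + unclassified = classified`). Note the thresholds: with the
generator's default class contrasts the two classes separate almost
completely, so the 5th percentile of the high-class scores lies *above* the
95th percentile of the low-class scores, the model is flagged
`non_separating`, and no pair is left unclassified — on real, overlapping
data the thresholds order the other way and an unclassified middle band
appears. See `vignette("dfd-methods")` for why, and for every default.

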