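# tscpath

Pathway-level transcriptional similarity for drug-response classification
in bulk transcriptomics.

## What this package is for

In neoadjuvant HER2+ breast cancer trials, many patients do not reach
pathological complete response (pCR) even under combination anti-HER2
therapy, and single-gene expression biomarkers of response are weak —
tumor expression profiles are so similar between patients (most sample
pairs correlate above 0.9) that little gene-level variance is
response-linked. `tscpath` is for analysts who want to use *pathways* as
the predictive features instead: it scores how similar a patient's
gene–gene co-expression pattern within a pathway is to that of responders
versus non-responders, and builds biomarker discovery and a
cross-validated classifier on top of that score.

## The statistic at the core

For a pathway expression matrix $P$ (genes × samples), define the
diagonal-deleted Gram matrix

$$P_0 = P P' - \mathrm{Diagonal}(P P').$$

The **transcriptional similarity coefficient (TSC)** between two sample
populations $P_1$ and $P_2$ over the same genes is the cosine similarity
of their off-diagonal Grams:

$$\mathrm{TSC}(P_1,P_2)=\frac{\sum_{ij}(P_{10})_{ij}(P_{20})_{ij}}
 {\sqrt{\sum_{ij}(P_{10})_{ij}^2}\sqrt{\sum_{ij}(P_{20})_{ij}^2}} \in [-1,1].$$

Deleting the Gram diagonal removes each gene's own squared magnitude, which
makes the coefficient exactly invariant to the number of samples compared
(duplicating all samples of a population changes nothing). On top of the
TSC the package provides:

* **delta-TSC profiles** — per sample and pathway, TSC against the
  remaining responders minus TSC against the remaining non-responders;
* **pathway and gene biomarkers** — concordance index (AUC) against the
  binary response with permutation significance and BH adjustment;
* **a responder classifier** — subsampled leave-one-out cross-validation:
  100 draws of 5 responders and 5 non-responders per held-out sample,
  per-side medians over pathways, majority vote;
* **cohort structure** — Spearman sample similarity, Ward clustering and
  adjusted-Rand concordance with the response labels;
* **a synthetic trial generator** — three-arm cohorts with configurable
  pCR rates, very high inter-sample correlation, and response signal
  injected into pathway gene–gene covariance, with ground truth for
  testing every stage;
* **I/O** for expression tables (TSV/CSV), GMT gene-set files and clinical
  response tables, plus a config-driven `run_pipeline()` over arm × ER
  groups.

## Worked example

Generate a default synthetic cohort and check it reproduces the trial-like
cohort properties:

```r
library(tscpath)

co <- generate_cohort(cohort_config(n_per_arm = 40, seed = 42))
emulation_report(co$expression, co$response, co$gene_sets)
#> fraction of sample pairs with Pearson r > 0.90: 1.000 (7140 pairs)
#> responder fraction by arm:
#>          arm responder_fraction  n
#>  combination              0.400 40
#>    lapatinib              0.350 40
#>  trastuzumab              0.275 40
#> pathway sizes: 10 - 30 (n = 100 )
```

All sample pairs sit above Pearson 0.9 (the high-correlation regime that
defeats univariate biomarkers), and the per-arm responder fractions scatter
around the configured pCR rates (0.513 / 0.247 / 0.295) as binomial draws
at n = 40 should.

Now a single-arm cohort with a strong covariance signal in 10 of its 100
pathways, scored by delta-TSC biomarkers and the classifier:

```r
co <- generate_cohort(cohort_config(n_per_arm = 60, arms = "combination",
                                    pcr_rate_by_arm = c(combination = 0.513),
                                    effect_size = 3, seed = 42))
sets <- filter_sets_by_size(co$gene_sets, 10, 30, co$expression)
prof <- delta_tsc_profile(co$expression, co$response, sets)
pw   <- pathway_biomarkers(prof, co$response, n_perm = 1000, seed = 42)
head(pw, 5)
#>  feature cindex perm_frac bh_adjusted n_samples group
#>  PWY_003  0.958         0           0        60   all
#>  PWY_001  0.938         0           0        60   all
#>  PWY_007  0.881         0           0        60   all
#>  PWY_002  0.880         0           0        60   all
#>  PWY_004  0.867         0           0        60   all

co$ground_truth$signal_pathways
#> "PWY_001" ... "PWY_010"
```

The five top-ranked pathways are all injected signal pathways: a C-index of
0.958 means a randomly chosen responder has a higher delta-TSC than a
randomly chosen non-responder 95.8% of the time, and no label permutation
out of 1000 beat it.

```r
pred <- loocv_predict(co$expression, co$response, sets, seed = 42)
y <- co$response$response[match(pred$sample_id, co$response$sample_id)]
mean(pred$predicted == y)
#> [1] 0.8666667

head(pred, 3)
#>  sample_id votes_responder votes_total predicted vote_fraction
#>      S0001               9         100         0          0.09
#>      S0002              34         100         0          0.34
#>      S0003              71         100         1          0.71
```

Each held-out sample received 100 subsampled votes; sample `S0003` was
called a responder by 71 of them and is predicted 1. Overall accuracy is
86.7% on this cohort, against a 50%-ish chance level.

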