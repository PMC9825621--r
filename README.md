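# somaticsieve

Somatic-vs-germline classification for **tumor-only** whole-exome
sequencing, and the TMB correction that follows from it.

When no matched normal is available, variant calls that survive database
filtering (population allele frequency < 0.01 across eight germline
databases), an artifact filter, and a leave-one-out panel of normals are
still dominated by the patient's *rare* germline variants. Tumor
mutational burden (TMB) computed from them is inflated severalfold, and
inflated most for patients from ancestries under-represented in germline
databases. somaticsieve trains gradient-boosted decision trees to classify
each remaining variant as somatic or germline from 53 tumor-only features:

* `pop_max` (max allele frequency over the databases), per-sample variant
  `count`, `t_alt_freq`, `t_maj_allele`, `max_cosmic_count`;
* `snp_vaf_bin_00..19` — a 20-bin VAF histogram of the *informative SNPs*
  (common heterozygous SNPs) sharing the variant's copy-number segment,
  which encodes local copy state and purity;
* coding-ontology one-hot, the six pyrimidine-centered substitution
  classes, and the 16 trinucleotide flank pairs (+ non-SBS flags).

Truth labels for training come from a matched-normal pipeline run in
parallel: kept tumor-only variants called somatic there are labeled 1,
everything else 0. Corrected TMB counts variants with somatic posterior
&ge; 0.5, divided by the capture footprint in Mb (the pooled-cohort
constant is the patient-weighted kit average, 41).

Because the real benchmark cohorts are controlled-access, the package
bundles a synthetic cohort simulator (`simulate_cohort()`) that emulates
purity, copy-number segments, clonal/subclonal somatic VAFs with binomial
read noise, rare het/hom germline variants with ancestry-dependent
database representation, informative SNPs, COSMIC counts, and
mutational-spectrum differences — so every stage is testable end to end.
The gradient-boosting engine itself (leaf-wise "lgbm" preset with
`num_leaves = 30`, bagging 0.7/5, feature fraction 0.7, bagging seed 2018;
depth-wise "xgb" preset with depth 6) is implemented in the package in
C++, since no boosting library is available in the target environment.

## Worked example

```r
library(somaticsieve)

# simulate a training cohort and a held-out cohort
train <- simulate_cohort(cohort_config(n_patients = c(low = 7, mid = 7, high = 7)),
                         seed = 7)
train_an <- analyze_cohort(train)      # PoN -> prefilter -> features -> labels
suite <- train_suite(train_an$fm, train_an$labels, nrounds = 150)

test <- simulate_cohort(cohort_config(n_patients = c(low = 3, mid = 4, high = 3)),
                        seed = 99)
test_an <- analyze_cohort(test)
post <- predict_suite(suite, test_an$fm)

y <- test_an$labels$label
calls <- as.integer(post$ensemble >= 0.5)
m <- binary_metrics(confusion_counts(calls, y),
                    auc = exact_auc(post$ensemble, y), call_rate = 100)
tt <- tmb_table(test_an, post["ensemble"], norm_mb = 41)
```

Output (verbatim):

```
held-out AUC 0.992  MCC 0.909  TPR 0.948  TNR 0.971
naive TMB fit:     R2 0.050  slope 0.093
corrected TMB fit: R2 0.981  slope 0.996
        feature importance
1:   t_alt_freq 0.48756979
2: t_maj_allele 0.15294273
3:      pop_max 0.04361333
4:      sub_C>A 0.04103561
5:        count 0.02668192
```

Reading this: the ensemble separates somatic from germline on held-out
patients (AUC 0.992, every variant receives a posterior — call rate 100%).
Regressing true TMB on the naive tumor-only estimate gives a slope near 0
(germline leakage variance swamps the signal); after classification the
corrected estimate tracks truth with slope ~1 and R² 0.98. The most
informative features are the read-fraction statistics, with the database
and per-sample count features next — the same ordering class the benchmark
reports.

The same pipeline runs file-based from the command line:

```sh
for stage in simulate build-pon filter featurize train predict evaluate tmb bias-report; do
  Rscript exec/somaticsieve "$stage" --out run1 --seed 7
done
# run1/metrics.json, run1/tmb.tsv, run1/bias_report.tsv, logs + resolved configs
```

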