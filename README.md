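# diagentropy

Quantifies how much **diagnostic uncertainty** a clinical feature — a
symptom, demographic trait, lab test or imaging finding — actually
removes, alongside the conventional 2×2 accuracy metrics that describe
how well it discriminates.

Accuracy metrics (sensitivity, specificity, Youden's J) summarize a
test's discrimination but not its effect on uncertainty: a highly
accurate test applied at very low prevalence may barely narrow the
differential. `diagentropy` treats a dichotomous feature as a
decision-tree split of the patient population into test-positive and
test-negative nodes and measures the **entropy removal**

> ER = H(parent) − (n₊/N)·H(test⁺) − (n₋/N)·H(test⁻)

where H is Shannon entropy over disease status (bits), the parent node
is the whole sample and the children are the test-positive (TP + FP)
and test-negative (FN + TN) groups. ER equals the mutual information
between test and disease indicators; the headline quantity is the
fraction ER / H(parent), the share of baseline uncertainty removed
(0–100%). The intended users are clinical-epidemiology researchers
evaluating features extracted from systematic reviews of diagnostic
accuracy.

The package provides:

* count ↔ performance-parameter conversion for 2×2 tables
  (`derive_counts()`, `counts_to_performance()`), accuracy metrics with
  a Haldane–Anscombe-corrected diagnostic odds ratio
  (`accuracy_metrics()`);
* the entropy decomposition (`entropy_removal()`,
  `shannon_entropy()`, plus `mutual_information()` as an independent
  cross-check);
* the accuracy-vs-information **quadrant framework**
  (`classify_quadrant()`, `quadrant_summary()`, `quadrant_plot()`) with
  cutoffs J ≥ 0.60 / ER ≥ 0.40;
* Pearson **correlation reports** relating the ER fraction to each
  accuracy metric (`correlation_report()`);
* CSV ingestion/export with header aliases and per-row diagnostics
  (`read_feature_table()`, `write_results()`);
* a **synthetic cohort generator** with planted ground-truth controls
  (`generate_cohort()`, `ground_truth_check()`);
* a subcommand **CLI** (`compute`, `quadrant`, `correlate`, `plot`,
  `simulate`, `replicate`).

## Worked example

A feature with prevalence 0.20, sensitivity 0.80 and specificity 0.90
in a sample of 1000 patients gives the table TP = 160, FP = 80,
FN = 40, TN = 720:

```r
library(diagentropy)
cts <- diagnostic_counts(160, 80, 40, 720)
accuracy_metrics(cts)
#> <accuracy_metrics>
#>   sensitivity = 0.8000  specificity = 0.9000
#>   ppv = 0.6667  npv = 0.9474  youden_j = 0.7000
#>   dor = 36 (log 3.584)
entropy_removal(cts)
#> <entropy_result>
#>   H(parent) = 0.7219 bits; H(test+) = 0.9183; H(test-) = 0.2975
#>   weighted child entropy = 0.4465 bits
#>   entropy removed = 0.2755 bits (38.16% of parent)
```

The sample started with 0.72 bits of uncertainty about disease status
(prevalence 0.20); splitting on the feature leaves a weighted 0.45
bits, so the feature removes 38% of the baseline uncertainty. With
J = 0.70 but ER < 40% it lands in the High Accuracy / Low Information
quadrant — accurate, yet less informative than its J suggests.

The same pipeline over a whole table:

```r
ft  <- read_feature_table(system.file("extdata", "example_features.csv",
                                      package = "diagentropy"))
res <- compute_feature_table(ft)
quadrant_summary(res)
#> <quadrant_summary>  n = 6  (J cut = 0.6, ER cut = 0.4)
#>   HIGH_ACC_HIGH_INFO   1
#>   HIGH_ACC_LOW_INFO    3
#>   LOW_ACC_HIGH_INFO    0
#>   LOW_ACC_LOW_INFO     2
#>   categories:
#>     Demographics             1
#>     Imaging                  2
#>     Lab/Diagnostic Tests     2
#>     Signs/Symptoms/History   1
```

From a shell, the installed CLI chains the same steps:

```sh
cli=$(Rscript -e 'cat(system.file("cli", "diagentropy", package = "diagentropy"))')
Rscript "$cli" simulate --seed 9 --n-features 405 --output cohort.csv
Rscript "$cli" compute  --input cohort.csv  --output results.csv
Rscript "$cli" quadrant --input results.csv --output quadrants.json
Rscript "$cli" correlate --input results.csv
Rscript "$cli" plot     --input results.csv --output quadrants.png
```

Every command writes a JSON run manifest next to its output; logs go to
stderr, machine-readable output to files/stdout.

## Replicating the published 405-feature analysis

The quadrant counts, category counts and correlation values of the
published analysis this package accompanies were computed from a
source-data table distributed as supplementary material; it is not
bundled here. After downloading it:

```r
options(diagentropy.source_data = "/path/to/source_table.csv")
replicate_study(source_data_path())   # or: diagentropy replicate --input ...
```

prints each computed quantity next to its published value
(`published_reference()`). The acceptance tests in
`tests/testthat/test-acceptance.R` run the same checks when that
option is set.

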