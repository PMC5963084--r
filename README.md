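# pktem

Rule-based therapy-efficacy modeling from tumor pharmacokinetic (PK) gene
expression, with survival validation.

## What problem this solves

Whether a chemotherapy works in a given tumor depends not only on its
target but on the tumor's pharmacokinetics: influx transporters must bring
the drug in, efflux transporters (ABC family) can pump it out, and
metabolic enzymes (CYPs, UGTs, nucleotide-processing enzymes) can degrade
it — or must first activate it, for prodrugs. A tumor that somatically
over-expresses an exporter of a drug the patient is receiving is a tumor
in which that drug is plausibly ineffective.

`pktem` is for computational oncology / pharmacogenomics analysts who want
to evaluate administered therapies against a patient's tumor expression
profile with transparent rules, and to validate the resulting risk
classification with survival analysis. It implements:

* a **composite normal reference**: per-gene median `m_g` and median
  absolute difference `s_g` pooled over *all* normal-tissue samples, and
  robust Z-scores `Z = (x - m_g) / s_g` with calls `high` (`Z >= 2`) and
  `low` (`Z <= -2`);
* a **drug–gene PK knowledge base** (CSV of `drug,gene,role` with roles
  `import/export/metabolize/activate/target`) plus therapy-name
  normalization for raw clinical records;
* a **rule engine** over three tumor-genomics features (transport,
  metabolism, target). The therapy-efficacy model (TEM) predicts a
  therapy ineffective when *any export gene is high or at least two
  drug-degrading enzymes are high*; patients who received an ineffective
  therapy within 1.5 years of diagnosis are **high-risk**;
* **survival validation**: gated per-cancer and cancer-type-stratified
  pan-cancer Cox models (univariate and covariate-adjusted, HR > 1 = worse
  survival for high-risk), likelihood-ratio tests, Kaplan–Meier and
  covariate-adjusted survival curves, threshold sweeps, repeated k-fold
  cross-validation, and **DerSimonian–Laird random-effects meta-analysis**
  pooling per-cancer hazard ratios:
  `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
  inverse-variance weights on the log-HR scale;
* a **synthetic cohort generator** with planted alterations and known
  ground truth, so the entire pipeline is testable end to end without any
  patient data.

## Worked example

```r
library(pktem)

sim <- simulate_cohort(sim_config(seed = 42))
#> Synthetic cohort: 2868 tumors / 295 normals, 73 genes, 6227 therapy
#> records; 149 planted high-risk patients (5.2%)

ref <- build_reference(sim$normal)
#> Composite normal reference: 73 genes from 295 normal samples (73 callable)
z     <- zscore(sim$tumor, ref)
calls <- expression_calls(z)          # high / normal / low at |Z| >= 2

kb <- read_kb(example_kb_path())
nm <- read_name_map(example_name_map_path())
verdicts <- evaluate_cohort(sim$therapy, calls, kb, rule_spec("tem"), nm)
risk     <- classify_patients(verdicts, patients = sim$clinical$patient_id)
table(risk$status)
#> high  low
#>  149 2719

cohort <- risk_cohort(sim$clinical, risk)
fit_risk_cox(cohort, covariates = c("age", "stage", "grade"),
             stratify_by = "cancer_type")
#> OS multivariate Cox model: HR = 1.54 [1.23, 1.94], p = 0.00022
#> (2719 low / 149 high, 1104 events)

pc <- per_cancer_survival(cohort)
ok <- pc$effects$converged
pool_hr(pc$effects$hr[ok], pc$effects$ci_low[ok], pc$effects$ci_high[ok],
        pc$effects$cancer_type[ok])
#> Random-effects pooled HR = 1.63 [1.30, 2.05], p = 2.8e-05
#> (k = 8, tau2 = 0, Q = 4.24)
```

The generator planted a true hazard ratio of 1.47 on ~5% of patients; the
classifier recovers exactly the planted patients (149/149 here), the
stratified multivariate Cox model estimates HR 1.54 with the truth inside
its CI, and meta-analytic pooling of the eight per-cancer fits agrees with
no detected heterogeneity (`tau2 = 0`).

`run_tem_pipeline()` orchestrates the whole analysis (all rules, both
endpoints, gate reports, meta-analysis, sweeps, cross-validation) from a
YAML config; `inst/scripts/run_pipeline.R` is a command-line wrapper.

## Files

* `R/` — knowledge base, expression normalization, rule engine, survival
  validation, meta-analysis, synthetic data, pipeline orchestration
* `inst/extdata/pk_kb.csv`, `inst/extdata/therapy_names.tsv` — bundled
  example knowledge base and therapy-name map (intentionally partial;
  bring your own curation for real cohorts)
* `vignettes/therapy-efficacy-modeling.Rmd` — the model, its assumptions,
  parameter choices, generator design, and limitations
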