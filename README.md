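# matchscore

Rules-based quantification of how completely a drug regimen targets a
tumour's deleterious molecular alterations and immune biomarkers — the
**Matching Score** — together with the cohort-level outcome analysis that
accompanies it, and a synthetic cohort generator for testing the whole
pipeline without patient data.

The intended users are precision-oncology analysts working with molecularly
complex tumours (the motivating setting is carcinoma of unknown primary,
CUP), where patients typically carry several deleterious alterations and
receive individualized drug combinations. The question the score answers is
not "was the patient matched?" but "*how much* of the tumour's biology did
the regimen address?".

## The score

Raw assay calls (tissue NGS and/or blood cfDNA; variants of unknown
significance excluded upstream) are pooled into countable units: same gene +
same alteration class collapse within an assay result, structurally distinct
alterations of one gene count separately, and each assay result is counted
on its own. Against a drug–target knowledge base, a unit is *matched* when
any regimen drug's effective target set contains its gene, where effective
targets encode the field's matching conventions:

- anti-VEGF/VEGFR drugs additionally match *TP53*;
- PARP inhibitors and platinum cytotoxics match *BRCA*-related genes;
- synergy pairs (dabrafenib + trametinib via *BRAF*, pertuzumab +
  trastuzumab via *ERBB2*) count their shared unit twice in numerator and
  denominator when both partners are given;
- ER/AR IHC positivity targeted by a hormone modulator adds one to both
  sides.

With targeted fraction n/d and an immune checkpoint component cc (full for
MSI-high, TMB ≥ 20 mut/Mb or high PD-L1 with a checkpoint inhibitor; half
for TMB-intermediate or low-positive PD-L1):

    MS = 100            if cc = full
       = 50 + 100·n/(2d)  if cc = half
       = 100·n/d          otherwise        (capped at 100; 0 when d = 0)

Patients are stratified at a cutoff (default 50, strict `>`), selected in
the original procedure by ROC/Youden analysis against clinical benefit
(CR/PR or stable disease ≥ 6 months) — `roc_cutoff()` reproduces that step.

## Worked example

```r
library(matchscore)
kb <- default_kb()

profile <- patient_profile(
  "CUP-017",
  rbind(
    alteration_table("FM-1", "tissue_ngs",
                     c("BRAF", "TP53", "CDKN2A", "MYC"), "mutation"),
    alteration_table("GH-1", "cfdna", "BRAF", "mutation")),
  immune_biomarkers(tmb_mut_per_mb = 4.1, msi_status = "stable",
                    pdl1_percent = 0))

compute_matching_score(profile, c("dabrafenib", "trametinib", "bevacizumab"), kb)
#> <matching_score> CUP-017: 71.4% (matched)
#>   targeted fraction: 5 / 7; checkpoint component: absent
#>   * BRAF [mutation, FM-1]              w=2  synergy pair dabrafenib+trametinib (counted twice in numerator and denominator)
#>     CDKN2A [mutation, FM-1]            w=1  untargeted
#>     MYC [mutation, FM-1]               w=1  untargeted
#>   * TP53 [mutation, FM-1]              w=1  targeted by regimen
#>   * BRAF [mutation, GH-1]              w=2  synergy pair dabrafenib+trametinib (counted twice in numerator and denominator)
```

Reading the ledger: the *BRAF* mutation appears in both the tissue and the
cfDNA report, so it contributes one unit per assay result; each is doubled
because both synergy partners are in the regimen. *TP53* is matched through
bevacizumab's anti-VEGF rule. CDKN2A and MYC are untargeted. Hence 5/7 =
71.4%, which `dichotomize_score()` places in the high (> 50%) group.

The cohort level runs the same way on data frames:

```r
coh <- simulate_cohort(sim_config(n_patients = 300), seed = 2026)
d <- cbind(coh$scores,
           coh$outcomes[match(coh$scores$patient_id,
                              coh$outcomes$patient_id), -1])
analyze_cohort(d, cutoff = 50)
#> <cohort_analysis> 300 patients (300 response-evaluable), cutoff 50%
#> Progression-free survival:
#>   matched          7.2 vs 4.3 mo; HR 0.76 (0.31-1.85); log-rank p = 0.541
#>   ms_high          11.1 vs 3.8 mo; HR 0.33 (0.24-0.44); log-rank p = 5.2e-15
#> Clinical benefit (SD >= 6 months / PR / CR):
#>   matched          56% (164/291) vs 11% (1/9); OR 10.33; Fisher p = 0.0124
#>   ms_high          71% (140/196) vs 24% (25/104); OR 7.90; Fisher p = 3.16e-15
```

The simulated cohort is generated with PFS medians of 10.4 vs 2.8 months
and benefit probabilities 0.71 vs 0.24 by score group, and the analysis
recovers them — being merely *matched* (score > 0) separates outcomes far
less than a *high degree* of matching, which is the score's central point.
`vignettes/matching-score-methods.Rmd` documents the model, every rule and
threshold, the simulator's calibration, and its limitations.

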