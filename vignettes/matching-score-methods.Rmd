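---
title: "The Matching Score: model, rules, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Matching Score: model, rules, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matchscore)
```

## The problem

Precision-oncology programmes for molecularly complex tumours — carcinoma of
unknown primary (CUP) being the motivating case — rarely face a single
actionable alteration. A typical CUP tumour carries a median of about four
deleterious alterations on tissue NGS, no two patients alike. Whether a
*regimen* (often an individualized combination) addresses *most* of a
tumour's biology, rather than whether any single drug is "matched", is the
quantity of interest. The Matching Score (MS) formalizes this as a percent:
roughly, the number of deleterious alterations targeted by the administered
drugs divided by the total number of deleterious alterations found, with
immune biomarkers folded in through fixed tiers.

This package implements the score as a rules engine over an explicit
drug–target knowledge base, together with the cohort-level outcome analysis
that accompanies it (Kaplan–Meier / log-rank / Cox for PFS and OS,
Fisher / odds-ratio contingency analysis of clinical benefit, a univariate
screen feeding multivariate models, ROC-based cutoff selection), and a
synthetic cohort generator so the whole pipeline is testable without patient
data.

## The score

### Countable units

Raw assay calls are first pooled into *countable units*
(`pool_countable_alterations()`):

* within one assay result, calls sharing gene and alteration class collapse
  to one unit (two *KRAS* point mutations count once);
* the same gene altered in structurally distinct ways — say amplification
  and mutation — yields two units;
* alterations reported by different assay results (e.g. a tissue panel and a
  cfDNA panel) are counted separately, reflecting genuine spatial and
  temporal heterogeneity between samples.

Only deleterious calls enter the model; variants of unknown significance
must be excluded upstream, and no driver/passenger distinction is made.
Two points here were genuinely open and are exposed as options rather than
buried:

* **Cross-assay duplicates.** Counting "each test result" literally means a
  *TP53* mutation seen in both tissue and blood contributes two units. That
  literal reading is the default; `dedup_across_assays = TRUE` gives the
  union-with-deduplication alternative, and a test pins the difference.
* **Pathway-level collapsing.** "Same signalling pathway" collapsing is
  approximated by same-gene-and-class collapsing, because no pathway
  ontology is part of the score's definition. A user-supplied
  `pathway_map` (gene → pathway label) enables cross-gene collapsing for
  users who want one.

### The knowledge base

`matching_kb` objects map drugs to the gene sets they are considered matched
to. Matching conventions are data, not code:

* antibodies match the gene product they bind; small molecules match genes
  curated for low IC50 (curation happens when the KB is written, not at
  runtime) or for direct downstream effectors — a MEK inhibitor lists
  *BRAF* (and *RAS* genes) among its targets for exactly this reason;
* drugs with anti-VEGF/VEGFR activity additionally match *TP53* (motivated
  by the association between *TP53* loss and VEGFA overexpression); the rule
  is a KB flag, and disabling it removes exactly *TP53* from those drugs;
* PARP inhibitors and platinum cytotoxics match any *BRCA*-related gene; the
  membership of that list is a configurable KB field (default BRCA1/2,
  PALB2, ATM, BARD1, BRIP1, RAD51C/D) since no canonical enumeration exists;
* *synergy pairs* (dabrafenib + trametinib via *BRAF*; pertuzumab +
  trastuzumab via *ERBB2*): when **both** partners appear in the regimen,
  the shared unit is counted twice in both numerator and denominator. One
  partner alone scores once.

The shipped default KB (19 drugs) is illustrative: large enough to express
every rule, small enough to audit by eye. It is not a reconstruction of any
particular programme's curation, which is exactly why `load_kb()`/`write_kb()`
round-trip user KBs through JSON or YAML with full validation.

### Checkpoint inhibitors and biomarkers

Checkpoint inhibitors are scored against immune biomarkers, not genomic
units. With a checkpoint drug in the regimen the component is **full**
(score 100%) for MSI-high, TMB ≥ 20 mutations/Mb, or high PD-L1; **half**
(50%) for TMB-intermediate (6–19) or low-positive PD-L1. TMB bins follow the
printed clinical convention (low ≤ 5, intermediate 6–19, high ≥ 20); the
numerically open interval (5, 6) is assigned to low. PD-L1 positivity is
≥ 1%; the "high" threshold is nowhere defined in the source convention, so
the package defaults to 50% — the standard tumour-proportion-score cut for
strong expression — and exposes it (`pdl1_high`).

Three unstated corner cases were decided as follows:

* a checkpoint drug with *no* qualifying biomarker contributes a **zero**
  component — it behaves like any other unmatched drug;
* two half-tier biomarkers (TMB-intermediate *and* PD-L1 low-positive) do
  **not** stack to 100;
* when the half tier applies, the genomic fraction is computed over
  non-checkpoint targets only.

Hormone-receptor IHC positivity (ER or AR) targeted by a hormone modulator
adds one to both numerator and denominator; with no genomic units at all,
ER+ plus letrozole is 1/1 = 100%.

### The combination formula

With countable units giving a targeted fraction $n/d$ and checkpoint
component $cc$:

$$
\mathrm{MS} =
\begin{cases}
100 & cc = \text{full}\\[2pt]
50 + 100\,\dfrac{n}{2d} & cc = \text{half}\\[2pt]
100\,\dfrac{n}{d} & \text{otherwise,}
\end{cases}
$$

with the fraction taken as 0 when $d = 0$, and the result capped at 100.
A patient is *matched* when the score is positive. The engine emits a
per-unit audit ledger (which rule fired, with what weight), and the ledger
totals are asserted to reconcile with $n$ and $d$ — the score is never
reported without its decomposition.

Scores are dichotomized at a cutoff with strict inequality: the default 50
gives groups "> 50%" vs "0–50%", the boundary belonging to low and unmatched
patients (score 0) always low. `roc_cutoff()` reproduces the cutoff-selection
procedure: candidate cutoffs (by default the observed scores) are ranked by
the Youden index against clinical benefit, ties broken toward the larger
cutoff; maximizing the between-group benefit-rate difference is available as
an alternative criterion, since the original procedure's exact objective is
not documented.

## Outcome analysis

Clinical benefit is CR, PR, or stable disease lasting ≥ 6 months
(inclusive); non-evaluable responses are excluded from benefit analyses
only. The analysis pipeline (`analyze_cohort()`) mirrors standard practice
for small retrospective cohorts: per covariate, KM medians (median defined
as the smallest time with survival ≤ 0.5), a two-group log-rank test, and a
univariate Cox hazard ratio for PFS and OS; Fisher's exact test and a sample
odds ratio with Woolf CI (Haldane–Anscombe 0.5 correction on zero cells) for
benefit; covariates with univariate p < 0.1 enter multivariate Cox /
logistic models, and the multivariate step is skipped when fewer than two
pass — a single survivor has nothing to be adjusted for. Age is dichotomized
at the cohort median. Reported percentages round half-up, matching how
clinical tables print 71% and 24%.

Standard estimators are delegated to the `survival` package and `stats`
(`survfit`, `survdiff`, `coxph`, `glm`, `fisher.test`); the test suite
checks them against independent re-derivations — grid-search partial
likelihood maximization, direct observed-minus-expected log-rank
tabulation, full hypergeometric enumeration — rather than trusting either
implementation alone. Ties use Efron's method by default; Breslow (the SPSS
default, hence what legacy analyses most often used) is an explicit toggle,
and a test documents that the two differ on tied data.

Monotone likelihood in Cox fits and separation in logistic fits are
detected and flagged, with the affected confidence interval reported as
unbounded rather than as a spuriously finite Wald interval.

## The synthetic cohort generator

`simulate_cohort()` emulates the *marginal* structure of a CUP cohort so
that every pipeline stage has realistic input:

* **Assay presence**: 76% of patients have tissue NGS, 74% cfDNA (at least
  one is forced).
* **Alteration counts**: each calibrated gene is present independently with
  its marginal frequency (tissue: *TP53* 0.554, *CDKN2A* 0.243, *KRAS*
  0.203; cfDNA: *TP53* 0.611, *KRAS* 0.208, *PIK3CA* 0.167), plus a
  negative-binomial count of filler genes drawn from a pool of genes
  recurrently altered in CUP. The filler parameters (tissue size 2, mean
  3.4; cfDNA size 1.5, mean 1.0) were calibrated once, numerically, so the
  truncated per-assay totals have median 4 (max 25) and 2 (max 9). Only
  median and range are published for these counts; the negative binomial is
  a modelling choice for overdispersed counts, not an estimate.
* **Biomarkers**: TMB category probabilities 0.625/0.281/0.094 with values
  drawn uniformly within each band; MSI-high 3.6%; PD-L1 positive 30.9%
  (positives uniform on 1–100%, so roughly half are "high"). ER/AR IHC
  positivity is not published for this setting; 10% and 5% were chosen as
  plausible for a mixed-histology CUP cohort and are config fields.
* **Regimens**: `matched_rich` greedily picks up to three KB drugs covering
  the patient's genes and adds a checkpoint inhibitor half the time when a
  biomarker qualifies; `unmatched` draws non-targeting cytotoxics; `random`
  samples the KB uniformly.
* **Outcomes**: given each patient's score group, PFS is exponential with
  the group median (defaults 10.4 / 2.8 months — implying a generating
  hazard ratio of 2.8/10.4 ≈ 0.27); OS is PFS plus an independent
  exponential post-progression time whose rate is solved numerically
  (uniroot on the hypoexponential median) so the OS median hits its target
  (15.8 / 6.9); best response is drawn to hit the group's benefit
  probability (0.71 / 0.24), with SD-driven benefit only when PFS ≥ 6
  months so the endpoints never contradict. Censoring is by an independent
  exponential censoring time with rate $c = a f/(1-f)$, which makes the
  expected censored fraction exactly $f$ (default 20%) while keeping the
  censoring non-informative — the property Cox estimation needs.

What the generator deliberately does **not** model: gene co-occurrence and
mutual exclusivity (draws are independent), clonal structure, panel
composition differences between vendors, correlation between TMB and
alteration counts, and any real link between molecular profile and outcome
beyond the score group. Passing pipeline tests on this generator therefore
demonstrates that the software recovers what it simulates — calibration,
internal consistency, estimator correctness — and says nothing about
real-patient effect sizes, which require actual cohorts.

## Numerical and testing choices

* The worked-example surfaces (30% for 3 of 10; 75% for TMB-intermediate +
  checkpoint + one matched target of two; 100% for MSI-high + checkpoint)
  are exact identities of the formula and are tested exactly.
* The scoring engine is fuzz-tested against a brute-force scorer that
  re-transcribes every rule literally from the KB structures; the two must
  agree exactly on random small profiles.
* Dichotomization uses strict `>`. A score can land on the default boundary
  only as `100 * (n/d)` with `n/d = 1/2`, or as the bare half tier — both
  exactly representable in floating point (IEEE division of `n` by `d = 2n`
  yields exactly 0.5) — so 50 vs "> 50" is never a rounding accident.
* Statistical calibration is tested by simulation at deliberately moderate
  sizes — log-rank type-I error over 1000 null replicates at n = 200/arm
  must land in [0.03, 0.07]; Cox Wald CI coverage over 500 replicates at
  n = 500 in [0.90, 0.98]; parameter recovery uses 10,000 draws for KM
  medians (±5%) and the geometric mean over 10 replicate cohorts of 500/arm
  for the hazard ratio (±15%). Replicate-averaging for the HR isolates
  estimator accuracy from single-draw Monte-Carlo noise, whose standard
  deviation at that cohort size is itself ≈ 7% of the true value.
* All randomness flows from explicit seeds; the same seed reproduces a
  cohort byte-for-byte.

## Limitations

The default KB is a teaching-sized stand-in: real use requires a curated KB
reflecting current approvals and one's own IC50/downstream-effector
judgments, which is why validation and round-tripping get as much code as
scoring. The score itself is retrospective and descriptive — the package
deliberately contains no regimen recommendation logic. And the outcome
analysis implements the small-cohort retrospective toolkit (no competing
risks, no time-varying covariates, no RECIST re-adjudication); its results
are only as interpretable as those designs allow.
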