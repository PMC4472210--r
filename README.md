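# txpredict

Transcriptome-guided drug prediction and molecular tumor board toolkit.

`txpredict` implements, as a tested and reusable R pipeline, the analysis
platform used in molecular-guided therapy studies of relapsed pediatric
solid tumors (the motivating setting is refractory/recurrent
neuroblastoma): a tumor biopsy's genome-wide expression profile is
compared against a whole-body panel of normal tissues, five independent
scoring engines nominate drugs, and tumor-board decision rules turn the
ranked report into a treatment plan of at most four agents. The package
also provides the study-level bookkeeping (sample QC gates, the 21-day
feasibility ledger, response tallies) and the reproducibility analyses
(replicate-biopsy PERMANOVA, principal coordinates, drug-set
reproducibility sweeps, microarray-vs-RNA-seq concordance). A
synthetic-data module generates every input with the statistical
structure the analyses assume, so everything runs and is testable with no
external downloads.

## The model in brief

**Preprocessing.** For gene *g* with linear-scale expression *x_g*, the
relative expression against a normal reference with per-gene location
*μ_g* and scale *σ_g* (mean/SD of log2 expression over 45 normal
tissues) is

    z_g = (log2(x_g + 1) − μ_g) / σ_g

**Five scoring engines**, each emitting per-drug evidence on a
comparable 0–10 scale:

1. *Biomarker rules* — curated Z-predicates on marker genes that predict
   drug sensitivity **or resistance**; evidence is |z| of the marker.
2. *Drug target expression* — drugs with an inhibitor mechanism against
   a gene with z ≥ +3; evidence is the maximum qualifying z.
3. *Network hidden nodes* — hypergeometric enrichment of differentially
   expressed genes in bounded directed reachability neighborhoods of a
   protein–protein interaction network (drivers = divergence, effectors
   = convergence), BH-corrected; drugs inhibiting significant nodes get
   evidence −log10(q), capped at 10. Significant regulators need not be
   differentially expressed themselves.
4. *Drug response signatures* — the Connectivity-Map KS rank statistic
   of the patient's up/down gene sets (|z| ≥ 1.5, up to 500 genes each)
   against drug perturbation rankings; significant *inverse* connectivity
   (permutation p ≤ 0.05) yields evidence −score × 10.
5. *Drug sensitivity signatures* — Parametric Gene Set Enrichment
   (PAGE): z_set = (S_m − μ)·√m/δ of drug-sensitivity gene sets derived
   from a cell-line panel (expression–IC50 correlations replicated in ≥2
   cell contexts) against the full Z-profile.

**Report and tumor board.** Aggregate score = weighted sum of sensitive
evidence (resistance evidence flags but never subtracts); drugs are
dense-ranked; the board excludes drugs without FDA approval or pediatric
dosing, demotes previously failed and resistance-flagged drugs, and
selects up to four agents.

**Concordance.** Distance-based PERMANOVA with pseudo-F
(SS_A/(g−1))/(SS_W/(N−g)) and add-one-smoothed permutation p (floor
1/(n_perm+1) = 0.001 at 999 permutations); classical MDS; drug-set
reproducibility = fraction of replicate pairs agreeing on each
above-threshold drug, averaged over drugs then patients.

## Worked example

```r
library(txpredict)

cfg <- sim_config(n_genes = 300, n_patients = 2, n_drugs = 20, seed = 1)
ref <- gen_normal_reference(cfg)
kbb <- gen_drug_knowledge_base(cfg, names(ref$location))
cohort <- gen_tumor_cohort(ref, cfg, kb = kbb$kb)

z <- compute_zscores(cohort$profiles[[1]], ref)
scores <- rbind(
  apply_biomarker_rules(z, kbb$rules),
  score_target_expression(z, kbb$kb),
  score_network_drugs(hidden_nodes(kbb$network, overexpressed_targets(z)), kbb$kb),
  score_connectivity(select_differential_sets(z), kbb$signatures,
                     n_perm = 200, seed = 1),
  score_sensitivity(z, derive_sensitivity_signatures(kbb$panel)))
report <- aggregate_report(scores, kbb$kb)
print(report, n = 4)
#> <drug_report> 10 drugs with predicted efficacy
#>   drug_id     score rank resistance_flag                                     methods
#> 1    D013 11.873235    1           FALSE biomarker,sensitivity_signature,target_expression
#> 2    D019  7.162397    2           FALSE           sensitivity_signature,target_expression
#> 3    D016  6.857933    3           FALSE                    connectivity,target_expression
#> 4    D005  5.734044    4           FALSE           sensitivity_signature,target_expression

tumor_board_filter(report, kb = kbb$kb)
#> <treatment_plan> 4 agent(s); interactions: not evaluated
cohort$truth$beneficial[[1]]
#> [1] "D005" "D007" "D013" "D016" "D019"
```

The four chosen agents are drawn from the five ground-truth beneficial
drugs (inhibitors of the patient's planted overexpressed targets); the
aggregate scores combine target overexpression, inverse connectivity,
sensitivity-signature enrichment, and a fired biomarker rule.

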