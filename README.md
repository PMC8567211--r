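# hehprofile

Trisomy-based risk stratification for high hyperdiploid childhood
B-cell precursor acute lymphoblastic leukaemia (ALL).

High hyperdiploidy (51–65 chromosomes) is the most common genetic subtype
of childhood ALL. It carries a good prognosis on average, yet — being so
common — contributes a large share of all relapses, and chromosome count
alone does not isolate a uniformly low-risk group. The signal is in the
*pattern* of whole-chromosome gains. This package implements, as reusable
and tested components, the full analysis chain behind a trisomy-pattern
risk profile:

* **ISCN karyotype parsing** — gains/losses with multiplicity, modal
  number or range, fusion and masked-hypodiploidy screens
  (`parse_iscn`, `screen_cohort`, `gains_table`).
* **Risk classifiers** — the UKALL high-hyperdiploid profile
  (good risk ⇔ (+17 ∧ +18) ∨ (exactly one of +17/+18 ∧ ¬+5 ∧ ¬+20)),
  COG double (+4,+10) and triple (+4,+10,+17) trisomies, modal-number
  categories, NCI groups (`classify_ukall_heh`, `classify_cog`,
  `classify_cohort`).
* **Survival machinery** — Kaplan-Meier with log(−log) intervals, rates at
  a horizon, log-rank tests, Efron-tie Cox models, Harrell's C
  (`km_fit`, `rate_at`, `logrank`, `cox_fit`, `concordance_index`).
* **Profile discovery** — univariate screening, phi-correlation
  clustering of gains, exhaustive subset search with a C-index plateau
  rule, Mallows' Cp and forward-stepwise Cox BIC, and derivation of the
  decision rule as a minimal penalized DNF over the gain indicators
  (`discover_profile` and friends).
* **MRD analysis** — clinical category bins, hazard per log reduction,
  and a log-rank threshold scan for the optimal discriminative cutoff
  (`categorize_mrd`, `mrd_log_hr`, `scan_thresholds`).
* **Synthetic cohorts** — a Gaussian-copula generator of correlated
  chromosome gains with proportional-hazards endpoints and log-normal
  MRD, so the whole chain is testable without patient-level trial data
  (`default_config`, `generate_cohort`).

## Worked example

```r
library(hehprofile)

k <- parse_iscn("55,XY,+4,+6,+10,+14,+17,+18,+21,+21,+X")
k
#> <heh_karyotype> modal 55, gains {4,6,10,14,17,18,21,21,X}, losses {}
modal_category(k)
#> [1] "54-57"
classify_ukall_heh(unique(k$gains))
#> <risk_call> UKALL_HEH: GOOD (basis: +17, +18)
```

The modal number 55 places the karyotype in the middle high-hyperdiploid
band; the joint gain of +17 and +18 makes the call good risk regardless of
+5/+20 status.

```r
cohort <- generate_cohort(default_config(), n = 725, seed = 2003)
table(cohort$true_risk)
#> GOOD POOR
#>  588  137

cohort <- classify_cohort(cohort)
compare_classifiers(cohort)
#>   classifier n_good pct_good relapse_rate_10y hr_vs_rest hr_vs_rest_p hr_mrd_adjusted c_index   auc
#> 1  UKALL_HEH    588       81           0.0415      0.214     5.24e-08           0.208   0.657 0.663
#> 2     COG_TT    347       48           0.0499      0.552     4.63e-02           0.503   0.564 0.557
#> 3     COG_DT    449       62           0.0609      0.771     3.61e-01           0.698   0.526 0.515
```

On a simulated validation-scale cohort (n = 725), the profile assigns ~81%
of patients to the good-risk group, whose 10-year relapse rate is ~4%;
membership is strongly protective (hazard ratio ~0.21 against the rest,
essentially unchanged after adjusting for minimal residual disease), and
the profile out-discriminates the double/triple-trisomy definitions
(C-index 0.66 vs 0.56/0.53) while covering a much larger share of
patients.

Rediscovering the profile from data alone:

```r
big <- generate_cohort(default_config(), n = 5000, seed = 1)
g <- as.matrix(big[, paste0("gain_", CHROM_LABELS)]); colnames(g) <- CHROM_LABELS
disc <- discover_profile(g, big$time_relapse, big$ind_relapse)
disc$selection
#> <subset_selection> chosen k = 4 -> 5, 17, 18, 20
#>  k          subset   c_index        cp      bic
#>  1              17 0.5949829 60.206537 6681.371
#>  2           17,18 0.6187567 38.033777 6667.339
#>  3        17,18,20 0.6326506 25.527042 6659.923
#>  4      5,17,18,20 0.6433580  7.313285 6647.424
#>  5    5,8,17,18,20 0.6482199  7.596044 6651.868
#>  6 5,8,17,18,19,20 0.6499778  7.775714 6656.379
rule_to_string(disc$rule)
#> [1] "(+17 & +18) | (+17 & no+5 & no+20) | (+18 & no+5 & no+20)"
```

The C-index plateaus at four chromosomes (adding a fifth gains < 0.005),
Cp and BIC both bottom out at {5, 17, 18, 20}, and the derived decision
rule is exactly the published profile.

A command-line front end over the same functions ships in
`inst/cli/heh.R` (subcommands `simulate`, `parse`, `classify`, `discover`,
`mrd-scan`, `report`).

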