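# misinfoK

Rubric-based scoring of misinformation vulnerability from messaging-platform
survey data, with demographic subgroup inference and a message-credibility
analysis.

## The problem

During a health crisis, peer-to-peer messaging platforms (WhatsApp and
similar) carry both accurate guidance and misinformation. Survey studies of
this problem ask respondents about their usage, trust, forwarding and
fact-checking habits, have them judge real and fabricated messages, and ask
which unverified remedies they acted on. `misinfoK` turns such questionnaire
data into a per-respondent **vulnerability index** and answers two
questions:

1. Which demographic subgroups (age, occupation) are most vulnerable?
2. Does attaching *background evidence* (a link or named source) to a false
   message make people more likely to believe it?

Because raw responses from such studies are typically not deposited, the
package also includes a synthetic-cohort generator that emulates the study
conditions with planted, known effects, so the entire pipeline can be
validated by parameter recovery.

## The model

Each respondent's answers are scored against a YAML-configured rubric of
nine question groups (usage duration, communication/news priority, reliance
for pandemic updates, trust, forwarding, fact-checking, message discernment,
and actions on unverified remedies). Twelve items are scored directly; the
discernment score is derived by counting incorrect judgments over a bank of
10 true/false messages and binning the count. The scores sum to `S_cal`, and

```
K = S_cal / S_max
```

where `S_max` is the rubric's maximum achievable sum (46 for the default
rubric). Higher K means higher vulnerability; only relative comparisons
within a sample are meaningful.

Subgroup inference follows the classical chain for unequal group sizes:
one-way ANOVA on K, Hartley's F-max variance-homogeneity screen with a
Monte-Carlo calibrated p-value (the textbook tables assume balanced groups),
and Hochberg's GT2 post hoc procedure, whose familywise-adjusted p-values
are upper tails of the studentized maximum modulus distribution, evaluated
by adaptive quadrature.

For credibility, the 8 false messages in the bank are split by whether they
carry background evidence. Over all retained respondents, the rates of
marking a false message true — `a_s/N_s` with evidence versus `a_x/N_x`
without — are compared by a pooled two-proportion z-test, and their ratio
summarizes the credibility boost.

The methods vignette (`vignettes/vulnerability-scoring.Rmd`) documents every
modelling and numerical decision, including the generator's calibration and
its stated limitations.

## Worked example

Generate a study-scale synthetic cohort (1,191 records, 54 planted filter
violators), apply the exclusion filters, score everyone, and run the
subgroup and credibility analyses:

```r
library(misinfoK)

cfg <- simulation_config(seed = 1)
cohort <- generate_cohort(cfg)
part <- apply_exclusions(cohort$records)
part
#> Cohort partition: 1137 retained, 54 excluded
#>
#> non_whatsapp_user      not_in_india
#>                27                27

scored <- score_survey(part$retained, cohort$rubric, cohort$bank)
subgroup_summary(scored$k, factor(scored$age_group, age_group_levels()))
#>   group_id   n    k_mean    ci_low   ci_high
#> 1 under_18  26 0.2851171 0.2480860 0.3221481
#> 2    19_25 395 0.3207485 0.3116926 0.3298044
#> 3    26_35 163 0.3274206 0.3130639 0.3417774
#> 4    36_50 297 0.3397014 0.3293630 0.3500398
#> 5    51_65 225 0.3522705 0.3397334 0.3648077
#> 6  over_65  31 0.3927069 0.3607489 0.4246649

one_way_anova(scored$k, scored$age_group)
#> One-way ANOVA: F(5, 1131) = 7.7777, p = 3.306e-07, MSE = 0.00848957

gt2 <- hochberg_gt2(scored$k, factor(scored$age_group, age_group_levels()))
posthoc_matrix(gt2, digits = 3)
#>          under_18 19_25  26_35  36_50  51_65  over_65
#> under_18 ">.99"   ".580" ".365" ".056" ".007" ".000"
#> 19_25    "-"      ">.99" ">.99" ".107" ".001" ".000"
#> 26_35    "-"      "-"    ">.99" ".940" ".125" ".005"
#> 36_50    "-"      "-"    "-"    ">.99" ".859" ".035"
#> 51_65    "-"      "-"    "-"    "-"    ">.99" ".285"
#> over_65  "-"      "-"    "-"    "-"    "-"    ">.99"

credibility_analysis(part$retained, cohort$bank)
#> False-message credibility: a_s/N_s = 1394/4548 = 0.307, a_x/N_x = 222/4548 = 0.049
#> Evidence raises the marked-true rate 6.3-fold
#> Two-proportion z-test (pooled): p1 = 0.3065, p2 = 0.0488, z = 32.150, p = 8.824e-227
```

Vulnerability rises monotonically with age in this cohort (the generator
plants that gradient), the omnibus test detects it, GT2 localizes it to the
contrasts involving the oldest respondents, and false messages carrying
evidence are believed about six times as often as those without.

`run_pipeline()` runs the same chain from either a survey CSV or a
simulation config and writes a full report bundle (demographic and usage
tables, subgroup K series, post hoc matrices, credibility table, JSON
report, run log) to a directory. `recover_parameters()` compares every
recovered quantity against what the generator planted. A command-line
wrapper with `simulate`, `score` and `run` verbs is installed at
`system.file("scripts", "misinfok.R", package = "misinfoK")`.

## Package layout

- `R/` — rubric engine, survey I/O and exclusion filters, statistics
  (ANOVA, SMM/GT2, Hartley F-max, two-proportion z-test), credibility
  analysis, synthetic generator, reporting pipeline.
- `inst/extdata/` — default rubric (`rubric_default.yaml`), a four-item
  sensitivity variant (`rubric_four_actions.yaml`), the synthetic message
  bank, and the occupation keyword table.
- `tests/testthat/` — unit and property tests plus end-to-end acceptance
  tests (hand-computed oracles, Monte-Carlo cross-checks, parameter
  recovery).
- `vignettes/vulnerability-scoring.Rmd` — methods and design decisions.
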