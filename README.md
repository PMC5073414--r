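# reglink

Deterministic + probabilistic record linkage of administrative registries,
with linked-versus-unlinked bias assessment and a ground-truthed synthetic
registry generator.

## What this is for

Population-health research links person-level source extracts — immigration
landing records, vital-statistics death registrations — to a population
registry of insured residents. The files share no unique identifier, so
records are matched on names, sex, dates and geography, all of which carry
typos, phonetic misspellings, transposed day/month fields and missing
values. `reglink` implements the standard multi-stage strategy end to end:

1. **Standardize**: clean names, NYSIIS phonetic surname codes,
   postal-code-derived city codes.
2. **Block**: partition both files into mutually exclusive, exhaustive
   subsets so only within-block pairs are compared.
3. **Deterministic cascade**: ordered exact-match passes from strict
   (surname + given + birth date + sex) to lenient (phonetic, sex-free);
   ambiguous matches defer rather than tie-break.
4. **Probabilistic passes**: Fellegi–Sunter log-odds weights
   `w = log2(m/u)` on agreement, `log2((1-m)/(1-u))` on disagreement, 0 on
   missing; definite links above `t_upper`, a grey zone above `t_lower`;
   m/u estimable by EM (`em_estimate()`).
5. **Review and resolution**: a rule-based reviewer adjudicates the grey
   zone using city agreement; duplicates resolve by linkage quality and
   event-date rules; linked persons get opaque surrogate keys.
6. **Evaluate**: linkage rates, method mix, standardized differences
   `|p1-p2| / sqrt((p1(1-p1)+p2(1-p2))/2)` between linked and unlinked
   files, era series, and precision/recall against synthetic ground truth.

Because real registry holdings are confidential, the package ships a seeded
synthetic generator that emulates their error structure (skewed surnames
with a very-common-short-surname pool, per-field corruption scaled by
era-dependent quality, unlinkable records, within-source duplicates) so the
whole pipeline is verifiable against ground truth.

## Worked example

```r
library(reglink)

pt  <- read_postal_city_table(system.file("extdata", "postal_city_demo.csv",
                                          package = "reglink"))
cfg <- synthetic_config(n_registry = 2000, n_source = 600, seed = 42)
sim <- simulate_registries(cfg)

out <- run_pipeline(run_config(sim$registry, sim$source,
                               source_kind = "immigration",
                               postal_table = pt, seed = 7))
out$pass_log
#>    pass_id          mode  n_in n_candidates n_linked n_review
#> 1:       1 deterministic   600        18996      384        0
#> 2:       2 deterministic   216         4925       50        0
#> 3:       3 deterministic   166          136       49        0
#> 4:       4 probabilistic   117        31215       39       22
#> 5:       5 probabilistic    56         4689       32        4
out$method_mix
#> $pct_deterministic 80.5   $pct_probabilistic 13   $pct_unlinked 6.5
truth_metrics(out$decisions, sim$truth)[c("precision", "recall")]
#> $precision 0.9964   $recall 0.9790
```

Read: of 600 source records, 483 (80.5%) linked across the three
deterministic passes, 78 (13%) linked probabilistically or after review,
and 39 (6.5%) stayed unlinked; against ground truth, 99.6% of links are
correct and 97.9% of truly linkable records were found. Stratified
linked-versus-unlinked tables (`build_stratum_table()`), era series
(`rates_by_period()`) and the run log reproduce the standard reporting
format for linkage studies.

The package also ships the published stratified linked/unlinked counts of
two large Ontario registry linkages (`published_count_table()`); feeding
them through the evaluation module reproduces every printed linkage rate
and standardized difference of those tables to printed precision — e.g.

```r
standardized_difference(279144/2692178, 89577/425156)  # 0.30
linkage_rate(405039, 36974)                            # 91.6
```

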