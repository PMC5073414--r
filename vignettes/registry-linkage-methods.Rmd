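---
title: "Linking administrative registries: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking administrative registries: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Health-administrative research routinely needs to attach person-level
source extracts — immigration landing records, vital-statistics death
registrations — to a population registry of insured residents, when the
files share no unique identifier. Records must be matched on names, sex,
dates and geography, all of which are corrupted in practice: typos,
phonetic misspellings, transposed day/month fields, missing values, and
data quality that varies by era. The fraction of source records that can
be attached is the *linkage rate*, and because failure to link is not
random (very common short surnames, sparse infant death registrations),
analyses restricted to linked records can be biased. This package
implements the full linkage strategy — deterministic passes, then
Fellegi–Sunter probabilistic scoring, then rule-based review — together
with the linked-versus-unlinked bias evaluation, and a ground-truthed
synthetic registry generator so every stage is testable end to end.

## The linkage model

### Standardization

Names are uppercased, diacritics mapped to ASCII, punctuation removed
(`clean_name()`), and surnames are coded with the original (1970) NYSIIS
phonetic algorithm (`nysiis()`), so that BROWN/BRAUN or
MACDONALD/MCDONALD standardize to one code and can share a block. We use
the original rule set rather than the later "modified" variant because
that is the system named by the linkage processes this package models;
codes are uncapped by default (truncation to 6 characters loses
discrimination among long surnames and is available as a flag). Only
surnames are phonetically coded; given names are cleaned but compared as
text, with the full given-name list retained and the first given name
used for matching (`nysiis_given = TRUE` turns coding on for given names
if wanted). Postal codes map to city codes by longest-prefix lookup
(`city_of()`), emulating a postal-code conversion file; an unknown or
missing postal code yields `UNKNOWN`, which downstream review treats as
*absence of evidence*, never as agreement.

### Blocking

Comparing all pairs is infeasible — the pair count is the product of the
file sizes — so both files are partitioned into mutually exclusive and
exhaustive blocks keyed on standardized fields (`block_scheme()`,
`build_blocks()`), and only within-block pairs are compared. With the
default `own_block` policy a record missing a key field falls into a
missing-value block, preserving the partition property (asserted on every
run). The `broadcast` policy instead compares such records against every
value of that field; it is the default for sex in the probabilistic
passes, because records with missing sex otherwise have no chance to link
while sex stratification keeps its benefit for complete records.

### Deterministic cascade

Ordered exact-match passes progress from strict to lenient: (1) exact
cleaned surname + first given name + full birth date + sex; (2) NYSIIS
surname + given initial + full birth date + sex; (3) exact surname + full
birth date without sex, catching miscoded sex. A record links only when
*exactly one* registry record in its block agrees on every compared
field; missing counts as disagreement, and records with two or more fully
agreeing candidates are deliberately left for later passes rather than
tie-broken — the conservative choice for very common surnames, where
arbitrary tie-breaks manufacture false links. For death files, the death
date can be compared against the registry date of last contact within a
configurable window (default 30 days) as an additional pass-1 field.
These defaults are declared configuration, not a claim about any
production system's unpublished pass parameters; every pass is
user-overridable via `pass_spec()`.

### Probabilistic scoring

Surviving records are scored with Fellegi–Sunter log-odds weights. Each
field carries an *m*-probability (agreement given a true match) and a
*u*-probability (agreement given a non-match); a pair's weight is

$$ W = \sum_j w_j,\qquad
   w_j = \begin{cases}
     \log_2 (m_j/u_j) & \text{field agrees}\\
     \log_2\!\big((1-m_j)/(1-u_j)\big) & \text{field disagrees}\\
     0 & \text{field missing,}
   \end{cases} $$

the overall log-odds in favour of a true match under conditional
independence. Base 2 is conventional (weights in bits) and only rescales
thresholds. Missing contributes zero rather than a disagreement penalty:
death registrations legally require only sex and dates, and penalizing
sparse records would re-create the very bias the evaluation is meant to
measure. Weights at or above `t_upper` are definite; weights in
`[t_lower, t_upper)` form the grey zone of possible matches. The default
thresholds (4 and 8 bits) are explicit, overridable stand-ins — the
production systems this models do not publish theirs, so structural
fidelity, not numerical equivalence, is the claim. Per source record the
highest-weight candidate is taken; a definite candidate must also beat
the runner-up by `delta` (default 1 bit) to link outright, otherwise it
joins the grey zone. Two probabilistic passes with different blocking
(NYSIIS surname within sex, then birth year within sex) give records a
second chance when one blocking key is corrupted.

The m/u defaults shipped in `default_field_models()` are round,
deliberately generic starting values. When training data are available,
`em_estimate()` fits them by the classical two-class EM under conditional
independence, with missing cells contributing no information, and
relabels the classes if the fit converges label-swapped. The
parameter-recovery suite checks all six parameters of a three-field model
are recovered within ±0.02 from 50,000 simulated vectors.

### Review, uniqueness, deduplication, keys

Grey-zone pairs go to a deterministic rule-based reviewer
(`auto_review()`) standing in for manual clerical review: accept iff the
weight reaches `min_weight` (validated to be at least `t_lower`), the
postal-derived city codes agree (unless city evidence is waived; `UNKNOWN`
never agrees), and the best candidate beats its runner-up by the
configured margin. Whether review could also overturn definite matches is
left out: here review only adjudicates the grey zone.

"Best record linkage quality" is operationalized as
deterministic > probabilistic > review, then weight — respecting the
deterministic-first hierarchy — and drives both optional one-to-one
enforcement (`enforce_one_to_one()`) and deduplication: duplicate death
records of one person keep the best-quality match, then the death date
closest to the registry last-contact date (`dedup_death()`); repeat
immigration records keep the earliest landing date
(`dedup_immigration()`). By default the pipeline leaves genuine
within-source duplicates to the dedup rules rather than one-to-one
enforcement, mirroring the study flow those rules come from. Linked
persons then receive opaque surrogate link keys (`assign_link_keys()`) —
per-run counters, or salted hashes when cross-run stability is needed;
derivation of real identifiers from health numbers is out of scope, so a
surrogate is the honest artifact.

## Evaluation

`linkage_rate()` reports `100·n_linked/(n_linked+n_unlinked)` to one
decimal, half-up. Linked/unlinked composition is contrasted with the
two-proportion standardized difference

$$ d = \frac{|p_1 - p_2|}{\sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}}, $$

reported to two decimals, with 0.2 / 0.5 / 0.8 read as small / moderate /
large. The source the formula models prints no formula, only values; this
pooled two-proportion form reproduces every printed standardized
difference of both published tables from their printed counts, which is
the strongest available evidence it is the right one (the test suite
recomputes all of them, and the continuous overload documents its
unpooled-variance choice). Percentages within a file are computed over
the *full* file — missing is a stratum like any other. On synthetic runs,
`truth_metrics()` adds precision and recall against ground truth, where a
link to the wrong person counts against both; with no links at all,
precision is undefined and rendered as 1 with a warning.

## The synthetic generator

`synthetic_config()` + `simulate_registries()` emulate, with ground
truth: a Zipf-weighted surname distribution overlaid with a pool of very
common surnames of at most four letters (the short-surname failure mode,
encoded without reference to ethnicity); per-field corruption operators —
one-edit typos, same-NYSIIS misspellings from a shipped variant table
(checked exhaustively for code equality), day/month transposition where
defined, and dropped values; era-dependent quality multipliers scaling
all corruption rates; a fraction of source records with freshly invented
identifiers and no registry counterpart (e.g. neonatal deaths never
issued a registration number) so no accidental true match exists; and
within-source duplicates differing in event date. All randomness flows
from one seed through named substreams, so adding a generator does not
perturb the draws of another and runs are bit-reproducible.

Defaults (per-field rates: typo 0.05, phonetic swap 0.03, date
transposition 0.02, missing 0.03; unlinkable fraction 0.05; duplication
0.03; common-surname fraction 0.15; era multipliers 2.0 / 1.5 / 1.0 over
1985–1994 / 1995–2004 / 2005 onward) were chosen once as plausible
magnitudes for administrative data of this kind. No public estimates of
the real databases' corruption rates exist, and these values must not be
read as such; they are the package's declared simulation conditions. The
registry generator additionally enforces uniqueness of the identifying
tuple (surname, first given name, sex, birth date) — a real registry
separates such persons by registration number, and unique tuples keep
ground truth unambiguous.

What the generator does *not* emulate: household structure and realistic
demography, migration dynamics, non-Latin scripts, and correlated
corruption across fields. Passing tests therefore demonstrate the
pipeline's correctness and its qualitative failure modes, not performance
guarantees on any real database.

## Numerical and design choices

- **Rounding** is half-up (rates 1 dp, standardized differences 2 dp),
  matching tabular presentation conventions; R's default half-to-even
  would flip printed digits.
- **Boundary conventions**: `weight >= t_upper` is definite;
  `weight == t_lower` is possible; ties among equally good candidates go
  to review, never to arbitrary choice. Dedup ties fall back to earliest
  event date, then stable input order, so runs are deterministic.
- **Degenerate inputs**: empty pass lists, empty blocking schemes,
  thresholds out of order, m/u outside (0,1) and unknown fields or
  comparators are configuration errors naming the offending key;
  `em_estimate()` refuses single-field (unidentifiable) or all-identical
  (degenerate) input with a diagnostic.
- **Problem sizes** used by the shipped checks: oracle-equivalence
  fixtures of at most 200 records (where brute force is exact and cheap),
  corruption and era properties on 10,000-record derivations, EM recovery
  on 50,000 vectors, and a full 50,000 × 10,000 end-to-end run in the
  acceptance script — sizes at which the binomial noise of the checked
  quantities is far smaller than the effects being demonstrated.
- **Interface**: the package's functions and scripts are the interface;
  runs are driven from R (`run_config()` + `run_pipeline()`) or from a
  YAML configuration (`config_from_yaml()`), with subcommand-like stages
  (simulate / link / evaluate) exposed as composable functions rather
  than a shell binary, which suits an analysis package.

## Known limitations

String-similarity partial agreement (e.g. Jaro–Winkler bands), Bayesian
linkage with priors, prior-informed imputation and any correction of
estimates for linkage error are out of scope — the evaluation layer
measures linked-versus-unlinked differences, it does not correct them.
Thresholds and m/u values equivalent to any production AutoMatch-style
deployment cannot be claimed, only the same structure. The rule-based
reviewer is a deterministic stand-in for human clerical review: it makes
review reproducible and testable, at the cost of human judgment on edge
cases.
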