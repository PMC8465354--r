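---
title: "Methods: consensus indices and association tests for ethnomedicinal surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus indices and association tests for ethnomedicinal surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoindex)
```

## The data model

A quantitative ethnobotanical survey has three tables: an informant
roster (age, gender, education, community, village), a taxon register
(botanical name, family, life form, parts used, preparation, route,
nativity, voucher), and the use-reports. One use-report is one citation
of one taxon by one informant for one ailment. Everything downstream —
every index in this package — is a function of use-report counts and a
handful of denominators, which is why the model supports two levels:

* **informant level**: one row per citation, `count = 1`, informant ids
  present. Required for knowledge dichotomization and the age
  regression, because those need per-informant tallies.
* **aggregate level**: rows are (taxon, category, village) counts with
  an explicit `n_informants`. This is the shape published surveys
  print, and every index (UV, Fq, Rf, FUV, ICF, RI) is computable from
  it. `aggregate_survey()` is the lossy bridge from the first level to
  the second; the total citation count is conserved by construction and
  asserted by tests.

Vocabulary columns are controlled. Readers accept both full words and
the single-letter dialect of printed field tables (`H`/`S`/`T`/`L`/`P`
for life forms, `Wp`/`Lv`/`Rt`/... for parts, `N`/`E` for nativity),
case-insensitively; unknown tokens are rejected by name rather than
passed through, since a silent `"herb "`/`"Herb"` split would corrupt
every percentage downstream. The part vocabulary includes `Stem` and
`Latex`, which field tables use alongside the classical twelve codes.

## The indices and their assumptions

**Use value** `UV = ΣU/n` counts *use-reports*, not distinct
informants. The distinction matters for taxa cited by one informant for
several disease categories: each citation counts. This is the counting
rule under which the shipped register's printed use frequencies
(`Fq = 100·UV`) reproduce, and it implies UV can in principle exceed 1
in heavily multi-use registers even though the classical description
calls 1 the "cited by everyone" ceiling.

**Family use value** is the plain mean of member UVs. It is bounded by
the member minimum and maximum (asserted as a property test), so a
monotypic family inherits its single member's UV exactly.

**ICF** `(N_ur − N_t)/(N_ur − 1)` is computed per disease category.
With `N_ur ≤ 1` the formula divides by zero; such categories are
returned with `icf = NA` and `defined = FALSE` rather than being forced
to 0 or 1, because a category with a single citation carries no
consensus information in either direction. Within its domain ICF lies
in [0, 1], equals 1 exactly when one taxon carries all citations, and is
strictly decreasing in `N_t` at fixed `N_ur` — all property-tested
against a loop-level oracle.

**Relative importance** needs per-taxon counts of pharmacological
functions (PH) and body systems treated (BS). These are almost never
published per taxon, so `relative_importance()` takes an explicit
annotation table instead of pretending to infer them; the shipped
register carries the source's printed RI values for display only. RI is
invariant under rescaling all PH or all BS by a constant (the maxima
normalize it away), ranges in (0, 100], and hits 100 exactly at the
joint maxima.

**Relative frequency** per village needs village-localized reports.
The shipped register does not localize citations, so `relative_frequency()`
also accepts the pre-tabulated distinct-taxa-per-village counts of a
site table, with the register size as denominator.

## Association tests

Knowledge is dichotomized at ≤5 vs >5 *distinct taxa* per informant —
the convention of published knowledge tables — while the age regression
uses *total use-reports* as the response; the two metrics are related
but not interchangeable, and both are implemented under separate names.

The chi-square is the plain Pearson statistic with expected counts from
the marginals and **no continuity correction**: the printed education
(13.734) and age-band (25.673) statistics of the packaged survey
reproduce exactly only without it. Expected counts below 5 trigger a
warning, never an error; a zero row/column marginal is a degenerate
table and errors, so simulation code drops empty factor levels first.
The analytic p-value is validated against a label-shuffling permutation
oracle in the suite, on a table whose cell expectations are large
enough (≥16) that the asymptotic approximation error is itself within
the Monte-Carlo band; on very small tables the two legitimately differ
by more than Monte-Carlo noise.

The packaged education factor has six levels: postgraduates are folded
into the graduate row, which is how the published 102-informant table is
laid out. The roster vocabulary keeps all seven levels.

## The category map

Free-text ailments are normalized (lowercase, trimmed) and looked up in
an ailment → category map of 85 entries across the 15 categories.
Compound printed strings ("constipation/indigestion") are stored as
separate entries because interview answers arrive one ailment at a
time. Two curation choices keep the map a partition: ethnoveterinary
uses are namespaced ("veterinary wounds"), since "wounds" otherwise
belongs to dermatology; and "bronchitis" is respiratory only, although
the source lists it under ear/nose/throat as well. Unmapped strings
either leave the report unassigned (with a warning) or reject the
batch, by policy.

## The shipped survey and its inconsistencies

The fixture transcribes a published 102-informant, 107-taxon,
15-category survey at aggregate level — the informant-level interview
data were never published, which is also why the fixture cannot support
dichotomization directly (its contingency tables are packaged as
printed instead). The transcription preserves the source's internal
disagreements rather than repairing them:

* a few taxa print an Fq inconsistent with their own use-report count
  (`validate_consistency()` flags exactly these);
* the register's per-category splits sum to 1636 citations while the
  category table sums to the published 1631, and several category
  totals differ between the two tables;
* the register's per-category ICF range therefore starts at 0.84 where
  the category table gives 0.85;
* the prose claims 52 families; the register contains 55;
* the per-taxon administration route is not published and is carried as
  a uniform `Oral` placeholder, clearly not data.

Tests assert what the computation gives on the stored counts, and the
acceptance values are computed from the table each published value was
actually derived from.

## The simulator: what it emulates, and what it does not

`generator_config()` defaults restate the surveyed world: 102
informants aged 21–80 in eight villages with the published informant
weights, a 25/102 female share, the published education and community
margins, and 107 taxa in 52 families. The knowledge model is a
truncated-at-1 Poisson for the distinct-taxa count with log-linear mean:

```
log mu = log(base_rate) + age_coef·(age−50)/10
         + education_coef·(level−Middle) + community_offset
```

Defaults: `base_rate = 5` taxa for the reference informant (the
published ≤5/>5 split puts about two-thirds of informants at or below
five taxa), `age_coef = 0.3` per decade (knowledge grows with age, the
direction the survey's age table shows), `education_coef = −0.2` per
level (schooling displaces traditional knowledge), community offsets
`(0, +0.25, −0.05)` making the nomadic community the most knowledgeable.
Truncation at 1 encodes that every interviewed informant cited
something. Feasibility is checked against the *expected* mean over the
configured demographics, not a worst-case informant, so small synthetic
registers remain usable.

Taxon popularity is a Dirichlet draw (concentration 0.3: a few
blockbuster taxa, a long tail, as real citation tables show), each
taxon's distribution over the 15 categories is another Dirichlet draw
(0.3: taxa are specialists but not monothematic), and each known taxon
yields `1 + Poisson(reports_per_taxon_mean − 1)` citations
(`reports_per_taxon_mean = 3`, putting the expected total near the
published 16 citations per informant). The pseudo-random draw order is
fixed — demographics, knowledge, register, popularity, profiles,
reports — so extending a later stage never reshuffles earlier draws
under the same seed.

What a green simulation test does **not** establish: the generator has
no interviewer effects, no village-level floristic differences (taxa
are equally available everywhere), no correlation between a taxon's
popularity and its category profile, and independent informants — no
household or snowball-sampling clustering. Recovery of the age and
education coefficients uses an untruncated Poisson regression, a
deliberate approximation that is negligible at the default mean
(P(0) ≈ 0.7%) but biased for `base_rate` near 1.

## Numerical conventions

* Percentages and index values are rounded **half away from zero** to
  2 decimals at presentation only (`round_half_up()`); base R's
  banker's rounding would print 0.845 as 0.84 where published tables
  print 0.85. Unrounded values are retained internally.
* Comparisons with printed values use ±0.01 after rounding: the source
  itself rounds inconsistently at the last digit.
* Ranking ties are broken by botanical name ascending, making reports
  reproducible across platforms.
* The analysis path contains no randomness at all; all stochastic code
  lives in the generator behind a single seed.

## Limitations

Only the six indices above are provided — no fidelity level, cultural
importance, or citation-RFC variants. There is no biomedical ontology
behind the category map, no taxonomic name resolution, and no Fisher
exact test or multiple-testing correction (the analysis convention this
package reproduces applies none). The fixture is aggregate-level;
claims that need informant-level data can only be exercised on
simulated surveys.
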