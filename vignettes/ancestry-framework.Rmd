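---
title: "Standardized ancestry categories: model, cascade, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized ancestry categories: model, cascade, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestrycat)
```

## The representation

`ancestrycat` represents the ancestry of every analyzed sample in two
forms. The *detailed description* is free text and should be as granular
as the source allows ("Yoruban", "Old Order Amish population isolate
individuals of European descent"). The *ancestry category* is one of 17
controlled labels describing regional population groupings with
characteristic patterns of genetic variation. The two forms are
complementary: the description preserves information, the category makes
samples comparable, searchable and countable.

```{r}
ancestry_categories()$name
```

Three categories describe admixed populations (`African American or
Afro-Caribbean`, `Hispanic or Latin American`, `Other admixed ancestry`);
`Other` means a descriptor is known but cannot be placed; `Not reported`
means no ancestry or recruitment information exists at all. Where
possible, categories are anchored to reference populations of the 1000
Genomes and HapMap projects — 27 codes in total, pairwise disjoint across
categories — so that a sample shown (e.g. by principal component analysis)
to cluster with CEU can be categorized as European without any verbal
description. Several groupings (Central Asian, Greater Middle Eastern,
Native American, Oceanian) currently lack a suitable reference population;
their `reference_populations` sets are empty.

Supergroups such as "Asian" and "African" are *display-time aggregations*,
not categories: analyses accept a configurable map
(`default_supergroup_map()`) and collapse labels only when percentaging.
The default map places the five Asian categories under "Asian" and
Sub-Saharan African, African unspecified and African American or
Afro-Caribbean under "African". Whether the two admixed/unspecified African
groups belong in the "African" display aggregate is a judgement call; we
include them by default because they are the categories a reader scanning
for African-ancestry representation would want counted, and the map is an
explicit argument for anyone who disagrees.

The hierarchy (root, supergroups, categories, synonyms) is exportable as
OBO 1.4 via `export_obo()`. Term ids are assigned in a fixed namespace by
sorting on term name, which keeps them stable across exports; they are
artifact-defined and deliberately do not imitate any public ontology's
identifiers.

## The classification cascade

`classify_sample()` turns raw sample metadata into a category assignment
with provenance. Evidence is consulted in decreasing order of trust:

1. **reference-population codes** (`tier = "reference-population"`) —
   genomic clustering evidence outranks everything, including the
   author's own label; where both are present and disagree, the genomic
   call wins and the tier records that this rung decided;
2. **author-stated category** (`"author-stated"`);
3. **descriptor lexicon** (`"lexicon"`) — longest-match scanning of the
   normalized description;
4. **country of recruitment** (`"country-inferred"`) — a
   demographic-majority fallback;
5. otherwise **`Not reported`** (`"not-reported"`).

The cascade is total and deterministic: an unresolvable rung falls through
rather than erroring, and the same inputs always give the same result. A
property test verifies that adding a population code can never *lower* the
tier.

### Descriptor matching

Descriptors are normalized (case-folded, punctuation stripped, whitespace
collapsed) and scanned left-to-right with longest-match n-grams capped at
four tokens. The cap covers the longest shipped terms while keeping
matching cheap; the left-to-right greedy rule resolves overlaps
deterministically. Longest-match is what makes "African American" a match
for the admixed category rather than "African" + a leftover token, and
"Pima Indian" Native American rather than South Asian. Matches are looked
up against, in priority order, the descriptor lexicon (including the
category table's example descriptors), category names and synonyms, and
reference-population codes. Disjoint matches produce a multi-category
result ("European and Japanese" → European + East Asian).

A non-empty descriptor in which *nothing* matches raises an
`ancestrycat_unclassified` error instead of being silently filed under
`Other`: `Other` is defined as "descriptor known but unclassifiable",
which is a curator judgement that an automatic matcher must not fake.
Empty input is different — it is the absence of information, and yields
`Not reported`.

No fuzzy matching (edit distance, stemming) is attempted; the lexicon and
synonym tables are plain TSVs under `inst/extdata/` and extending them is
the supported way to cover new descriptors. The shipped lexicon and
country tables are curated seed subsets (about 80 descriptors and 95
countries) chosen to cover the vocabulary's own examples and common cases,
not a reproduction of any complete curation database.

### Admixture

If the description signals admixture ("admixed", "admixture", "mixed
ancestry"): a result that already is a defined admixed category is kept,
and any plain categories matched in the text are recorded as
`admixture_components`; otherwise the sample becomes
`Other admixed ancestry` with those matched categories as components. Two
boundary decisions are worth stating. First, reference-population evidence
is never overridden by the keyword — a sample that genetically clusters
with CEU stays European whatever the prose says. Second, a description
that says "admixed" but matches nothing else still becomes
`Other admixed ancestry` (with no components) rather than `Not reported`,
because the statement of admixture is itself ancestry information.

### Country inference

When the only information is where participants were recruited, the
country's demographic-majority category is used, following UN M49 regions
and national demographic compendia. Countries whose resident populations
are too heterogeneous for a majority call (United States, Canada,
Australia, New Zealand, South Africa, Singapore, …) map to `Not reported`
by design: recruitment in such a country tells you essentially nothing
about ancestry. Latin American countries map to `Hispanic or Latin
American`, whose definition is itself an admixed regional grouping. Multiple recruitment
countries with conflicting inferred categories likewise fall through to
`Not reported`.

## The TSV dialects

`read_ancestry_tsv()` / `write_ancestry_tsv()` pin a column order
(`study_accession`, `pubmed_id`, `publication_date`, `stage`,
`number_of_individuals`, `broad_ancestral_category`,
`detailed_ancestry_description`, `country_of_recruitment`,
`country_of_origin`, `additional_ancestry_description`, `confidential`).
Files are unquoted TSV — commas in free text are data, not delimiters —
with UTF-8 and Unix newlines; the writer refuses tabs/newlines inside
fields rather than escaping them. Round-tripping is exact and
property-tested on 1,000 random records.

Multi-valued cells (categories, countries) are comma-separated, with
`" and "` additionally accepted on read. One category name legitimately
contains commas ("Greater Middle Eastern (Middle Eastern, North African,
or Persian)"), so category cells are parsed greedily: the longest run of
comma-separated segments that resolves as a single label is consumed
first. Dates are ISO-8601 with a day-month-year fallback. A row with an
empty category cell is classified through the cascade from its description
and recruitment country (the pinned rule "empty category + empty
description → Not reported" is the degenerate case). The `confidential`
flag models an explicit statement that ancestry cannot be disclosed; it
suppresses the linter's missing-data rules (R8–R10) for that record.

## The linter

The ten rules in `lint_rules()` encode reporting recommendations for
authors: granularity (R1), country-as-ancestry (R2), cohort-name-as-
ancestry (R3, against an extensible cohort list), ethnocultural terms
without a genetic qualifier (R4), isolates without their broader ancestry
(R5), admixture without components (R6), missing ascertainment method
(R7), and the hard completeness rules — category (R8), sample size (R9),
recruitment country (R10). R6 fires on an explicit admixture signal (the
keyword, or the `Other admixed ancestry` category) with fewer than two
component categories recoverable from the text; the two well-defined
admixed categories do not trigger it by themselves, since their admixture
is part of their definition. `lint_catalog()` also reports the fraction of
studies with no ancestry information at all — a corpus-quality metric, not
a threshold: the linter measures, it does not judge.

## The synthetic generator

`generate_catalog()` draws studies of three kinds: *not-reported* (one
sample, `Not reported`), *single-category* (one initial sample, sometimes
a replication sample of the same category), and *multi-ancestry* (two
distinct categories, one initial sample each, plus one jointly annotated
replication sample, which is what produces `multiple`-label individuals).
Defaults emulate a European-dominant corpus: 4% not-reported studies, 25%
multi-ancestry, single-category weights led by European (0.62) and East
Asian (0.15), publication years 2005–2016, and sample sizes from a shifted
negative binomial (mean 2,000, dispersion 0.8) to mimic heavy-tailed GWAS
cohort sizes, for which no canonical distribution exists. Associations are
a shifted Poisson per study (mean 5); in multi-ancestry studies each
association carries its own single-category annotation with probability
0.5. These values were chosen once, as plausible corpus conditions, and
the tests are built around them rather than the other way around.

The generator bookkeeps exact per-label counts at all three levels *as it
generates*, independently of the analysis code, and
`expected_distribution()` gives the closed-form expectation implied by a
configuration (using the exact inclusion probability of a category in the
two-category draw: first category from the weights, second from the
renormalized remainder). Pipeline-closure tests require the analysis of
the written-and-reread catalog to match the ground truth *exactly*;
Monte-Carlo tests require the closed form to match the mean over 200 seeds
within three standard errors.

What the generator does **not** emulate: individuals recurring across
studies (real cohorts are reused, which skews real corpora toward
well-studied populations), correlation between trait and ancestry, trends
over time within a configuration, realistic accession/PubMed structure, or
free-text noise in descriptors (synthetic descriptions are drawn from the
category table's own example descriptors). Passing the recovery tests
therefore demonstrates that the *pipeline* is correct and unbiased under
known conditions — not that any particular real corpus looks like the
defaults.

## Statistical conventions in validation

- **Counting.** Individuals are summed over both stages and across studies
  without deduplication; a sample annotated with several categories
  contributes its whole size to `multiple` (no fractional splitting);
  `Not reported` is excluded from the distinct-category count that decides
  whether a unit is `multiple`; windows are inclusive publication-year
  ranges.
- **Recovery intervals.** At the study level, shares are exactly binomial
  and tested against exact 99% quantile intervals (n = 1,000 studies). At
  the individuals and associations levels the shares are cluster-ratio
  estimators — a sample's whole size, and all unannotated associations of
  a study, share one label — so a binomial interval on the raw totals
  would be anti-conservative; the tests use delta-method intervals with
  the sample/study count as the effective n, widened by the design effect
  computed in closed form from the generator's size and association-count
  distributions.
- **Fold changes.** `compare_windows()` reports `pct_b / pct_a`, with `NA`
  (undefined) rather than infinity when a label is absent from the first
  window. Fold estimates on rare categories are noisy — the validation
  design (a category rising from 1% to 3% of studies) is tested within
  three delta-method standard errors, and the acceptance script uses
  4,000-study windows to report a stable estimate.
- **Problem sizes.** The default test run uses catalogs of up to 1,000
  studies and 200-seed Monte-Carlo batches of 150 studies; these sizes
  make every stochastic check stable at the stated interval widths while
  the whole suite stays interactive.

## Known limitations

Classification is lexical and tabular by design: no inference is performed
from genotype data, and descriptors outside the seed tables raise rather
than guess. Conflicts between author-stated labels and genomic clustering
are resolved by a fixed precedence (genomic first) rather than curator
review; the tier in every result makes this auditable. The country table's
majority-category calls are coarse national-level judgements and are
deliberately conservative for settler and multi-ethnic countries.
Diversity statistics inherit the biases of their inputs — repeated cohorts
inflate well-studied categories, and the `multiple` label absorbs
associations from multi-ancestry studies that single-category accounting
cannot attribute.
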