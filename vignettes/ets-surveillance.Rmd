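---
title: "Mapping emulsifier, thickener and stabilizer co-occurrence in packaged foods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping emulsifier, thickener and stabilizer co-occurrence in packaged foods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etscan)
library(dplyr)
```

## The problem

Emulsifiers, thickeners and stabilizers (ETSs) — the E400–E499 class of
food additives — modify texture, viscosity and phase stability of packaged
foods. Several of them (carrageenan E407, carboxymethylcellulose E466,
polysorbate 80 E433, the gums E410–E427) have drawn attention because they
reach the colon largely undigested and may perturb the gut microbiota.
Mechanistic work almost always studies one additive at a time, yet
manufacturers combine them systematically. Before interaction effects can
be studied, one needs a *basemap*: which additives appear where, how often,
in what combinations, and in which kinds of products.

`etscan` provides that basemap machinery for any tabular product database
carrying free-text ingredient lists and declared nutrition per 100 g. The
pipeline is: additive detection in ingredient text → eligibility screening
and deduplication → energy shares and hyper-palatability classification →
prevalence, count-distribution and co-occurrence statistics, including an
exact two-sided test of combination enrichment.

## Additive detection

Ingredient lists mix E-number tokens (`E 407`, `e-472a`), legal plaintext
names in several languages, and misspellings. The lexicon assigns each of
the 59 main-class E400–E499 additives a compiled case-insensitive regular
expression covering (i) the E-number with an optional space or hyphen and
an optional subclass letter, with word-boundary guards so `E4070` is not
`E407`; (ii) a curated set of plaintext names and spellings. The
carrageenan entry, for instance, matches `(c|k)ar*age*nan` as well as the
E-number forms. Sub-classes (E472a–f, E470a/b, E407a, E479b) are reported
as their main class, and an additive listed in two sub-ingredient lists is
counted once.

The exact inventory of names and misspellings a given national market uses
is not published anywhere; our table curates EU Annex II names plus common
Norwegian and English spellings, and is a versioned, overridable data file
(`ets_definitions()`). `compile_lexicon(validate = TRUE)` checks the
round-trip contract: every stored spelling is matched by its own entry and
by no other.

```{r}
lex <- ets_lexicon()
lex
detect_ets("emulsifier (E472a), stabiliser (E472b), guar gum", lex)[[1]]
```

One genuine ambiguity deserves a flag: the lump groups used for
enrichment merge near-identical additives, and the package uses
E40x = E400–E404 (alginates), E42x = E420–E422, E45x = E450–E452,
E47x = E470–E477, with pectin (E440) kept separate. An alternative reading
would fold E440–E444 into E40x; we reject it because alginates and pectin
are discussed — and behave — as distinct classes, and keeping pectin
separate is the only choice consistent with reporting pectin-specific
results. `lump_ets()` is a projection (idempotent), applied before
enrichment testing only; exact-combination reporting stays unlumped.

## Eligibility screening

Raw records from heterogeneous sources are screened in a fixed order:
non-food items, products without ingredient lists, implausible declared
nutrition, then duplicates. The nutrition checks are: any single nutrient
above 100 g/100 g; sugar above total carbohydrate; saturated above total
fat; no declared energy; more than 4,200 kJ/100 g; and a kJ/kcal ratio
outside [3.984, 4.384] (4.184 kJ per kcal ± 0.2, inclusive), skipped for
low-energy products (kJ < 10 and kcal < 2) where label rounding makes the
ratio meaningless. Duplicates are detected on exact GTIN or case-folded,
whitespace-collapsed name; fuzzy name matching is deliberately not
attempted — distinct products genuinely differ in additive content while
sharing near-identical names, so fuzzy matching would create false merges.

Where a record violates several rules, it is tallied under the first
triggered reason, in the order the rules are listed above; a linear
flowchart is the only reporting shape whose tallies add up to the input
count (`n_input = n_eligible + sum(tallies)`, asserted in code). The order
of checks *within* the nutrition block is a free choice; we fix it
document-side rather than leave it implementation-defined.

## Energy shares and hyper-palatability

Declared energy is authoritative and never recomputed. Fat contributes
37 kJ/g, carbohydrate and sugar 17 kJ/g; each macronutrient's share is its
energy divided by declared total energy (kJ/100 g) × 100. Sodium is
estimated as 40% of declared salt.

A product is *hyper-palatable* when it meets at least one of three
criteria: fat + sodium (fat > 5 E% and sodium ≥ 0.30 g/100 g), fat + sugar
(both > 20 E%), carbohydrate + sodium (non-sugar carbohydrate > 40 E% and
sodium ≥ 0.20 g/100 g). Share thresholds are strict, sodium thresholds
non-strict. Products meeting two or more criteria form their own class;
beverages are excluded from the classification. The fat threshold of the
first criterion defaults to 5 E% here; the original operational definition
by Fazzino and colleagues uses 25 E%, and the discrepancy cannot be
resolved from the surveillance literature alone, so the value is exposed as
`hp_thresholds(fat_sodium_fat_epct = )` with the default documented.

## The co-occurrence model

Within a food group of `N` products, let `n_c` be the number of products
carrying additive `c`. For a combination `S` (at-least semantics: the
product carries every code in `S`, possibly others), the expected count
under independence conditional on the marginals is

`E[S] = N * prod_{c in S} (n_c / N)`

and *fold enrichment* is `FE = observed / expected`. The null distribution
of the observed count is that of the intersection of |S| independent,
uniformly random fixed-size subsets of `N` — a chained (multiset)
hypergeometric. `null_intersection_distribution()` computes it exactly by
dynamic programming: the running intersection size `s` maps to `k` with
probability `dhyper(k, s, N - s, n_j)` when the `j`-th subset is added.
Each DP step is evaluated column-wise from the hypergeometric ratio
recurrence on the log scale; this is numerically robust in the far tails
and fast enough for supports of a thousand states. The distribution's mean
equals `E[S]` exactly (a property asserted in the tests), and for two sets
the DP reduces to the ordinary hypergeometric.

Because both over- and under-representation are of interest, two-sided
p-values use Blaker's acceptability construction: with
`gamma(x) = min(P(X <= x), P(X >= x))`, the p-value is the null probability
of all outcomes whose acceptability does not exceed that of the observed
count. A `1 + 1e-7` multiplier on the comparison absorbs floating-point
ties in the acceptability ordering. The resulting p always lies between
the smaller tail probability and twice it.

The null has no free deviation parameter, so conventional confidence
intervals are undefined; instead `bootstrap_ci_logfe()` resamples products
(rows) with replacement within the food group and returns percentile
2.5/97.5 bounds of log fold enrichment (via `boot`). Replicates with zero
observed count or an empty marginal have undefined log FE; they are
excluded from the percentiles and their count is reported — silently
imputing them would bias the interval toward the defined region, and at the
sample sizes where they are common the interval is not trustworthy anyway.

`enrichment_scan()` applies two printed filters before testing: additives
below 1% within-group prevalence are dropped, and combinations (sizes 2–4)
with expected count below 10 are not tested. Benjamini–Hochberg q-values
per food group are emitted as an *additional* column: the two-sided
p-values and bootstrap intervals are the core contract, and no multiplicity
correction is part of it.

Two combination semantics coexist and are never mixed:
`exact_combination_counts()` counts products whose additive set *equals*
the combination (intersection-plot reporting, unlumped, default threshold
50 products), while enrichment uses at-least semantics on lumped codes.

## The synthetic market

Real national product databases are proprietary, so validation runs on a
synthetic market whose statistical structure is known exactly. Additive
inclusion within a food group follows a *Bernoulli archetype mixture*: a
product draws an archetype `a` (weight `w_a`), then includes each code `c`
independently with probability `p_{a,c}`. This mechanism was chosen over
copulas because it yields closed forms for everything the analysis
estimates: marginals `P(c) = sum_a w_a p_{a,c}`, at-least combination
probabilities `P(S) = sum_a w_a prod_{c in S} p_{a,c}`, and hence analytic
fold enrichments `FE(S) = P(S) / prod P(c)`. A single archetype gives
exact independence (`FE = 1`); two archetypes with weights (0.5, 0.5) and
inclusion probabilities (0.8, 0.8) vs (0.1, 0.1) give the hand-derivable
pair FE of `(0.5·0.64 + 0.5·0.01) / 0.45² ≈ 1.605` used in the recovery
tests.

Ingredient texts render each true code in one of four styles (E-number
with random spacing/hyphen/case, plaintext name or synonym, stored
misspelling, subclass token) among benign filler ingredients, with a
round-trip guarantee `detect_ets(render(S)) = S` enforced by lexicon
validation and tested over all styles. Declared nutrition is drawn from
per-group truncated log-normals with sugar ≤ carbohydrate and saturated ≤
total fat by construction; the declared kcal label is an integer and kJ is
derived as `round(4.184 · kcal)`, so clean records always pass the ratio
screen (including the low-energy corner, where integer labels genuinely
sit). Ineligible and duplicate records are injected at configurable rates,
each built to trigger exactly one exclusion reason, so the eligibility
report can be compared to the generator's ground truth *exactly*.

The bundled `default_market_config()` ("norway-like", a versioned YAML) has
sixteen food groups with sizes and additive prevalences loosely shaped on a
national packaged-food market: meat & poultry the largest group with a
phosphate-heavy processed archetype, desserts and bakery the most
additive-dense, infant food nearly additive-free with at most one additive
per product, and the eight additives that real surveys fail to find
(E426, E427, E479, E483, E493–E495, E499) at probability zero. These
defaults are scenery for exercising the pipeline, not reference values; in
particular the synthetic market is saltier and fattier than a real market,
so its hyper-palatability shares run higher than survey figures. What
passing tests demonstrate is that the *machinery* is correct under known
truth — detection inverts rendering, tallies match injected defects,
estimated fold enrichments cover analytic ones — not that the synthetic
market reproduces any real market's headline numbers. Features of real
data the generator does not emulate include brand-level name collisions,
multilingual label mixtures beyond the stored synonyms, and correlation
between nutrition and additive content within a group.

## Numerical and design choices

* **Rounding of printed percentages** is half-up at the reported precision
  (`summarize_shares()`), matching how summary tables round 27.502% to 28%.
* **Blaker ties**: the `1 + 1e-7` acceptability multiplier; without it,
  equal-probability outcomes can drop out of the sum on some platforms.
* **DP size order**: sizes are processed smallest-first so the support
  never exceeds the smallest marginal.
* **Degenerate bootstrap replicates** are counted, not imputed (above).
* **Additive count cap**: counts are pooled at 10+ before tabulation and
  before Spearman ranking (ties get average ranks via the standard
  `cor.test` machinery).
* **Deduplication order**: survivors are sorted by (source, GTIN) and the
  first occurrence kept, making the filter deterministic and monotone
  (adding records never evicts a previously eligible one).
* **Problem sizes in the test-suite**: the simulation studies run at the
  sizes the validation design calls for — type-I calibration on twenty
  independent groups of 5,000 products, interval coverage on fifty markets
  of 2,000 products with 500 bootstrap replicates, a 200,000-draw
  Monte-Carlo check of the null distribution — which keeps the full suite
  near two minutes on a single core.

## Worked example

```{r example, fig.width = 6, fig.height = 4}
cfg <- default_market_config(n_total = 2000, seed = 42)
market <- generate_market(cfg)
res <- suppressWarnings(
  run_pipeline(market$records, B = 200, seed = 42, min_products = 10)
)
res$report
res$count_distribution
tidy(res$enrichment) |>
  arrange(p_two_sided) |>
  select(group, combo, observed, expected, fold_enrichment, p_two_sided) |>
  head(5)
glance(res$enrichment)
autoplot(res$count_distribution)
```

## Known limitations

* The plaintext synonym inventory is a curation; a market using spellings
  outside it will under-detect until the lexicon file is extended.
* Name-based deduplication is exact-match only; real databases contain
  near-duplicate names that survive it (a documented property, not a bug).
* Eligibility attribution is first-reason along a fixed order; datasets
  screened with a different rule order will report different per-reason
  tallies for multi-violation records (the eligible set is unaffected).
* The enrichment scan is exhaustive over retained codes and sizes 2–4;
  with many prevalent additives per group the number of tested
  combinations grows combinatorially, and `expected_min` is then the main
  cost control.
* Beverages are excluded from hyper-palatability but retained everywhere
  else; group-level comparisons across the two analyses therefore use
  different denominators.
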