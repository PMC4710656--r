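---
title: "Weighted-reasons preference analysis for pastoral sheep surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-reasons preference analysis for pastoral sheep surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewepref)
library(dplyr)
```

## The problem and the data

Participatory definition of breeding objectives asks the livestock keepers
themselves which traits matter. In the survey design this package
implements, each farmer classifies the ewes of each breed group
(Red Maasai, Dorper, and their crosses) in their own flock into a Best, an
Average and a Poor quality ewe, and gives three reasons, in order of
importance, for every classification. Each ewe is also measured (body
weight, body length, heart girth, body condition score, estimated daily
milk yield) and valued (the price, in Kenya Shillings, the farmer would
pay for her as a breeding ewe). Finally the farmer ranks all ewes on the
farm across breed groups from 1 (most preferred) downwards.

Two tables drive everything: an ewe table (one row per surveyed ewe) and a
reason table (up to three ordered free-text reasons per ewe). `ewepref`
validates both on entry — invalid rows are quarantined with a reason, not
silently dropped — and all downstream analyses are plain functions of
tibbles.

## The weighted-reasons index

Free-text reasons are first mapped to seven trait groups (body size and
growth, condition, milk production, reproduction and mothering ability,
drought tolerance, disease resistance, breed attributes) through a keyword
lexicon. The lexicon is data, not code: transcribing and grouping open
interview answers is a judgement call, so the bundled vocabulary can be
replaced by a two-column CSV. Matching is longest-pattern-first on
normalized (case-folded, whitespace-collapsed) text, and anything
unmatched is reported rather than guessed.

Within a stratum (site by breed by quality class), let $X_{ji}$ be the
number of order-$j$ reasons given to trait group $i$. The weighted-reasons
index is

$$
\mathrm{WR}_i \;=\; \frac{\sum_{j=1}^{3} r_j X_{ji}}
{\sum_i \sum_{j=1}^{3} r_j X_{ji}},
\qquad r_1 = 3,\; r_2 = 2,\; r_3 = 1 .
$$

The weights assume farmers value their first, second and third reasons on
an even step; they are a convention, so `weight_scheme()` accepts
alternatives (equal `c(1,1,1)`, steeper `c(5,3,1)`) for sensitivity
checks, and the index always renormalizes to one. With the default integer
weights all arithmetic before the final division is exact.

Published tables of this kind print the *weighted* contributions
$r_j X_{ji}$, not the raw counts — their row sums equal the plain sum of
the printed triple and the WR column equals that sum over the stratum
total. `wr_from_contributions()` therefore ingests contribution columns
directly (this is how the bundled `study_contributions()` table is
analysed), while `contributions_to_counts()` inverts the weighting and
insists on exact divisibility.

### Clustered categories

For an overview, the seven groups condense to four: body size and growth;
condition; reproduction and milk (milk production merged with reproduction
and mothering ability); and adaptation (drought tolerance merged with
disease resistance). Breed attributes is excluded because its responses
are few and heterogeneous. After exclusion the clustered index is
**renormalized over the remaining groups**. That renormalization is a
deliberate design choice: it is the only convention under which the
clustered values are internally consistent with the per-trait table
(e.g. a condition score of 13 out of a post-exclusion total of 38 gives
0.34), and `cluster_scheme(renormalize = FALSE)` exposes the alternative
for anyone who wants the original denominator.

### Display rounding

Report rendering uses half-up rounding to two decimals (`round_half_up()`),
so 1/8 prints as 0.13 — banker's rounding would print 0.12 and disagree
with the published convention. The implementation guards the binary
representation with a `1e-9` nudge, which is eleven orders of magnitude
below the rounding step and cannot affect genuine survey ratios.

## Across-breed ranks

On farms with all three breed groups a farmer ranks nine ewes (1–9); with
two groups, six. Six-ewe ranks are stretched onto the nine-ewe scale with
the affine, endpoint-exact map `new = 1 + (old − 1) × 1.6`, kept as reals
(2.6, 4.2, …) with no re-rounding. `summarize_breed_ranks()` averages the
rescaled ranks per breed and site over ewes (a per-farm averaging option
exists, since the convention is not fixed by the field), excluding missing
ranks pairwise and reporting the exclusions.

## The trait model

Each measured trait is analysed with the fixed-effects linear model

$$
y_{ijkl} = \mu + \mathrm{Site}_i + \mathrm{Farmer}_j(\mathrm{Site}_i)
 + \mathrm{Breed}_k + \mathrm{Rank}_l
 + (\mathrm{Breed}\times\mathrm{Site})_{ki} + e_{ijkl},
$$

with farmer a *fixed* effect nested within site and rank the quality
class. Price is modelled on its raw KES scale. Candidate terms — ewe age
from dentition and the rank-by-breed and rank-by-site interactions — are
screened one at a time against the base model and retained only below the
chosen significance level (`screen_terms()`, default 0.05).

### Encoding and testing choices

A plain `farmer` factor would alias `site` (its dummies span the site
indicator), so the design is built explicitly: treatment coding for site,
breed and quality, and **sum-to-zero contrasts within each site** for the
farmer deviations. This keeps the site contrast estimable, identifies
farmer effects inside their own site, and yields a full-rank matrix whose
rank deficiencies (if a user supplies a degenerate design) are reported as
errors naming the aliased columns, while single-level factors are dropped
with a warning.

ANOVA uses type II (marginal) tests by default: each term is compared
against the model containing all terms that do not contain it, with the
full-model residual mean square as denominator. `site` is therefore never
tested in the presence of `breed:site`; the farmer deviations, being
within-site contrasts rather than a term containing `site`, remain in both
models of every comparison. Sequential (type I) tests are available and
agree with type II on balanced orthogonal designs, which the test suite
checks. Residual normality is summarised numerically (skewness, excess
kurtosis, Shapiro–Wilk) instead of by eye.

### Least-squares means and letters

LS-means average model predictions over the levels of the non-target
factors with equal weights, hierarchically for the nested factor: farmers
equal **within their site**, sites equal. This matters because the default
survey has ten farmers at one site and nine at the other; flat averaging
over site-farmer cells would weight sites 10:9. Because of that
convention the contrasts are built in-package rather than delegated;
`emmeans` reproduces the estimates and standard errors exactly on designs
without the nesting asymmetry, and the test suite uses it as an
independent cross-check there, alongside a brute-force normal-equations
oracle on random instances. If an age covariate is retained, means are
evaluated at its sample mean.

Pairwise comparisons of LS-means are unadjusted t tests at the stated
significance level (the publication convention for such tables says only
"significantly different at p < 0.05"); a Tukey-style adjustment sits
behind `letter_groups(adjust = "tukey")`. Letters come from the
insert-and-absorb algorithm — start with one set holding every level;
for each significant pair split every set containing both; absorb subsets;
letter the surviving sets in descending-mean order — which guarantees that
significantly different levels never share a letter and non-different
levels always do.

## The synthetic generator

`flock_design()` and `generate_flocks()` emulate the study so that every
pipeline stage can be exercised without field data: 19 farmers (10 + 9
across the two sites), 11 farms with all three breed groups and 9 ewes,
6 with Red Maasai and Crosses, 2 with Dorper and Crosses (6 ewes each) —
147 ewes. The split of the two-group farm types across sites is not fixed
by the study description; the default places 3 Red-Maasai-and-Cross farms
and 1 Dorper-and-Cross farm at each site, consistent with the published
totals.

Traits are drawn from normal distributions per breed-by-quality stratum
using the published means and SDs, shifted by breed-specific
Isinya-minus-Amboseli deltas read from the breed-by-site LS-means (half
the delta on each side of the pooled mean). A farmer effect shared by all
ewes on a farm takes 40% of the stratum SD, with the residual scaled so
the total SD is preserved; the true within-farm correlation is unknown in
the field, so this is a free parameter, not an estimate. BCS is snapped
to the half-point grid and clipped to [1, 5]; milk is truncated at zero
(zero is a real value: no milk left after the lambs); price is a positive
whole number. Ages 1–9 are drawn with mean about 3.6 years. Across-breed
ranks order a latent preference score (breed-by-site preference shift,
quality-class pull, Gaussian noise), so the generator's preference
ordering is recoverable from the rank summaries.

Ordered reasons are drawn from stratum profiles proportional to the
bundled contribution table. The default mechanism draws the three ordered
reasons **independently from the pooled profile** $p_i \propto S_i$. This
is deliberate: it makes the expected order-weighted shares equal the
design WR exactly, so the preference index closes the loop on generated
data. Sampling *without* replacement (a natural first thought, offered as
`reason_mode = "sequential"`) systematically depresses concentrated
categories — for a stratum with a 0.53-probability category the expected
weighted share drops below 0.40 — and per-order profiles with exclusion
have the same defect; neither can reproduce its own design profile.
Allowing a repeated trait group within one ewe is also defensible on
field grounds: two distinct phrases ("big body", "fast growth") map to
one group. Every latent draw (farmer effects, stratum means, latent
preference scores, reason categories) is recorded in a generation ledger
keyed to the emitted records, which is what the recovery tests compare
against. The phrases attached to drawn categories are chosen so the
bundled lexicon maps them back deterministically — positive wording for
Best and Average ewes, negative for Poor.

What the generator does **not** emulate: transcription noise and unmapped
vocabulary, missing measurements, within-farm trait correlations beyond
the single shared farmer effect, non-normal trait tails, and any temporal
flock dynamics. Passing closed-loop tests therefore demonstrate the
pipeline's internal consistency, not robustness to messy field data.

## Orchestration

`run_pipeline()` drives the stages end to end from a `run_config()` (or a
YAML file): load or simulate, map reasons, build the preference and
clustered tables, summarise ranks, and fit, screen and letter every
requested trait, writing CSVs plus a JSON manifest with an MD5 checksum
per file. Identical configurations give identical manifests. Status codes
distinguish validation (2) from estimation (3) failures, and partial
outputs survive a failed stage with the failure point recorded.

## Problem sizes and verification

The package's own checks run at these sizes, chosen to keep Monte-Carlo
error well inside the asserted bands: oracle equivalence against a
normal-equations solver on 100 random designs of at most 60 records
(agreement to 1e-8 relative); 95% CI coverage of the breed-by-site gap
over 1,000 simulated surveys at the study's n = 147 (covering 95% ± 2%);
empirical size of the age screening over 1,000 null surveys (5% ± 1.5%);
and closed-loop WR recovery with 1,000 ewes per stratum (within ±0.03 of
the design profile). `scripts/acceptance.R` recomputes all of these, plus
the published-table reproductions, from scratch at every run.

## Known limitations

* The lexicon covers the vocabulary named in the study; real transcripts
  will need extension, and unmapped phrases block the tally on purpose.
* Farmer(site) is fixed, exactly as the model equation writes it; there
  is no random-effects machinery, so inference is conditional on the
  sampled farmers.
* The weighted-reasons values are preference summaries, not selection
  index weights; turning them into economic weights is out of scope.
* Whether published rank means were averaged over ewes or farms is not
  determinable; both are offered, ewes being the default.
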