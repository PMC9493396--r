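---
title: "Methods: the intersubjective agreement index and its pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the intersubjective agreement index and its pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wordia)
```

## The measurement problem

Free-report paradigms ask participants to describe a briefly flashed image
in their own words, with a confidence rating per word. Because no answer
key exists, `wordia` scores each word against what *other participants*
reported: a word is informative about an image exactly insofar as people
who saw that image produce it and people who saw other images do not. This
vignette documents the model, its assumptions, the tunable parameters, the
numerical choices, and what the synthetic tests do and do not establish.

## The study design the package assumes

The analyses presume a blocked cohort design: the image set is partitioned
into blocks; a fixed cohort of participants sees one block, each image
once, at one of several SOAs (stimulus onset asynchronies — the time from
image onset to the first mask); the SOA rotation gives every (image, SOA)
cell the same number of participants (10 in the default design; the
package infers or accepts `n_per_cell`). Within each cell, participants
get an **order position**. The order concept matters because the pooled
analysis and all baselines remove participants *by order position* to keep
denominators equal. The design never states how order should be derived
from a raw file, so the package makes it explicit: order is the rank of
first appearance in the input, overridable by an explicit order column
(`build_cohorts(order_col = ...)`). Any deposit-specific column semantics
should be confirmed against the file itself via the configurable
`column_map` of `read_responses()`; nothing is hard-coded.

## Word IA

For reporter $r$ of word $w$ on image $i$:

* per-SOA scope: the within fraction is $t = k/9$ where $k$ counts the
  other 9 cell members who reported $w$; each other image contributes a
  baseline fraction $b_j = k_j/9$ over its cell minus the participant at
  $r$'s order position.
* pooled scope: the comparison set is the 30 participants of $i$ minus the
  reporter minus the same-order participant in each of the other two SOA
  cells (27); baselines likewise use 27 order-matched participants.

Criteria are the descending union of the observed fractions with the
endpoints 1 and 0 — no binning, so the cumulative curves are exact step
functions. The ROC plots target cumulative against baseline cumulative
across criteria, anchored at the origin, and the AUC is the trapezoidal
area. On this criteria grid the trapezoid is *exactly* the
rank-comparison form

$$\mathrm{AUC} = P(b < t) + \tfrac12 P(b = t),$$

which the test suite verifies against an independent pairwise-comparison
oracle on over a thousand random instances. Word IA is the mean AUC over
the word's reporters. A word reported by a single participant has no
defined IA; the package represents this as an explicit `NA` with a status
(`"rare"` vs `"unreported"`), never as 0, so summaries cannot silently
absorb undefined values.

**Similar-pair exclusion.** When two nearly identical images are both in
the set, a word genuinely specific to their shared content is reported
under both, inflating the baseline and depressing IA for no good reason.
Registered partners are therefore dropped from each other's baselines
(419 → 418 comparison images in the full design). Directionally, removing
a baseline image whose fraction strictly exceeds the within fraction can
only raise the AUC; the property test encodes exactly that. One subtlety
found while proving it: removing an image whose fraction exactly *ties*
the within fraction can lower an AUC that is already below chance (the tie
contributes score ½, above a sub-0.5 mean), so the guarantee is stated for
strict exceedance plus ties at or above chance.

**Image IA** is the mean of the image's defined pooled Word IAs (`NA` if
it has none), reported with `prop_rare`, the fraction of the image's word
groups that were single-reporter.

## Cleaning pipeline

The pipeline is deliberately minimal and fully deterministic:

1. lowercase; internal whitespace becomes a hyphen; characters outside
   letters/digits/hyphens are dropped (the response UI allows only those);
2. spell correction: a manual two-column map is consulted first; otherwise
   a dictionary speller proposes known words at edit distance 1 and a
   correction is accepted **only when the suggestion is unique**. Words
   containing digits or hyphens are never "corrected". Semi-automatic
   human adjudication is irreproducible, so ambiguity always resolves to
   "keep the word";
3. lemmatization by a fixed lookup table shipped as a versioned asset
   (`children → child`, `walked → walk`, ...). Base forms are never keys,
   which makes the whole normalization a fixed point: cleaning twice
   equals cleaning once (tested);
4. within-trial deduplication *after* normalization, keeping the earliest
   slot and its confidence — so `cats`/`cat` in one trial collapse to one
   row, matching the intent of "the same word".

Placeholder words (`na`, `none`, `arbitrary`, ...) are retained with their
confidence: they are data (typed under instruction when nothing more could
be reported), and their low specificity is informative. No synonym merging
is attempted; `boat` and `speedboat` stay distinct words.

## SSE and its bootstrap null

Two similar images shown to disjoint cohorts should elicit similar word
frequencies. Over the union of words, with $f_A, f_B$ the counts of
distinct participants reporting each word, the package sums squared
distances of the points $(f_A, f_B)$ to the identity line. The literal
perpendicular distance gives $\sum (f_A - f_B)^2 / 2$ and is the default;
the vertical convention $\sum (f_A - f_B)^2$ differs by the factor 2 and
is exposed as a switch (`convention = "vertical"`) rather than silently
rescaled, because published values do not always state which was used.
Deciding between them against a particular deposit is a one-line check
once that deposit is present.

The null asks what mean SSE random pairings produce: each iteration picks
one image from every registered pair and re-pairs it with a uniform draw
from the whole pool excluding itself — self-pairing would contribute SSE 0
and bias the null toward consistency, so it is disallowed. 100 iterations
of 24 pairs are the default; the interval reported is a percentile
interval (99% by default). Image trios should be reduced to pairs upstream
(which member to drop is a user choice; the registry format takes pairs).

## Correlation analyses

Confidence–IA association is computed at two levels: one point per defined
pooled (word, image) group (mean reporter confidence vs pooled IA), and
one point per individual response against its group's per-SOA IA,
optionally per SOA. Confidence-1 ("Don't Know") responses are included by
default — they were typed under instruction and carry signal — with an
`exclude_dont_know` flag for sensitivity analyses. All correlations are
Pearson via `stats::cor.test` (df = n − 2, Fisher-z 95% CI); degenerate
inputs (under 3 points, or a constant variable such as an all-equal
`prop_rare`) raise classed conditions instead of returning `NA`s.
Multilevel (mixed-model) analyses are intentionally out of scope; the
model-ready response-level table (`ia_point_table()`) exports everything
such software needs.

## The synthetic generator

`simulate_reports()` emulates the full design: 20 blocks × 21 images × 30
participants, 7 trials per SOA via a cyclic rotation that lands exactly 10
participants in every (image, SOA) cell, 5 words per trial — 63,000 rows.
Words come from a three-class mixture whose defaults were chosen once as
plausible study conditions:

| parameter | default | rationale |
|---|---|---|
| specific lexicon / image | 20 tokens | enough distinct local content that most reports repeat across 30 viewers without saturating |
| generic lexicon | 60 shared words | coarse scene vocabulary any image can elicit |
| `p_specific` by SOA | 0.45 / 0.55 / 0.65 | longer exposure yields more detail; plants the SOA effect to be recovered |
| noise rate | 0.05 | matches the ~5% of "Don't Know" placeholder entries such paradigms elicit |
| confidence by class | specific high, generic mid, noise ≡ 1 | encodes the confidence–specificity link as a controllable effect size |
| misspelling / inflection rates | 0.02 / 0.05 | typing-error scale; planted **only** from the shipped manual map and lemma table so cleaning recovery is exactly checkable |
| similar pairs | 24 natural + 4 artificial, overlap 0.8 | mirrors the registered-pair bookkeeping; overlap 1 makes a pair generatively identical |

Ground-truth labels (specific/generic/noise) accompany every dataset for
parameter-recovery tests. What passing on synthetic data shows: the
estimator recovers planted specificity structure, order-based exclusions
balance the counts, and the statistics separate signal from a calibrated
null. What it does not show: robustness to natural-language phenomena —
synonymy, compositional phrases, idiosyncratic vocabulary — which the
generator deliberately does not model (words are tokens), nor the exact
outcome of any historical semi-automatic spell-correction pass.

Three canned fixtures pin the arithmetic analytically: a landmark word
reported by 6/10 in one cell and nowhere else (within fraction 5/9,
baseline all zero, IA exactly 1); a word reported by the first five order
positions of every cell (baseline everywhere equals the within fraction,
IA exactly 0.5); and a letter-array world of image-unique tokens reported
by everyone (every Word IA and Image IA exactly 1, no rare words).

## Numerical and scale choices

* Exact fractions are kept throughout; percentages are rounded only for
  display.
* Ties in image rankings break by IA (desc), then report frequency (desc),
  then alphabetically — deterministic output.
* Degenerate inputs fail loudly with classed conditions
  (`wordia_empty_summary`, `wordia_too_few_points`,
  `wordia_degenerate_cor`) rather than propagating `NA`.
* Perfectly linear correlation inputs return r = 1 with a collapsed
  [1, 1] interval (the Fisher transform is infinite there); callers should
  treat the CI as degenerate.
* The test suite exercises the full 63,000-row design once for structural
  counts and parameter recovery (tens of seconds) and otherwise uses a
  2-block × 6-image × 12-participant design, which preserves every
  structural property (cells of 4, three SOAs, similar pairs) at a
  fraction of the cost.

## Known limitations

* The shipped dictionary and lemma table are small, curated assets meant
  for synthetic and demonstration corpora; real deposits need a fuller
  dictionary (any word list can be passed to `dictionary_speller()`) and
  possibly a corpus-specific manual map.
* IA assumes exact, balanced cohorts; off-size cells are flagged and the
  analysis proceeds with the nominal denominators, which slightly biases
  fractions in flagged cells.
* The bootstrap null follows the registered-pair pool construction; with
  few pairs the null distribution is coarse and its percentile interval
  should be read accordingly.
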