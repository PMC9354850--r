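---
title: "Methods: scoring, networks and the synthetic-corpus design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, networks and the synthetic-corpus design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infodemix)
```

`infodemix` analyzes corpora of government social-media posts published
during a public-health emergency: per-post communication-power scores,
cross-account content-duplication networks, co-word networks over post
titles, content-type distributions, and the temporal coupling between
posting volume and the epidemic curve. This vignette explains each model,
the tunable parameters and their defaults, the numerical conventions, and
what the synthetic-corpus generator does and does not emulate.

## The data model

A `corpus` holds one row per post with the nine crawled attributes (title,
originality flag, read count, posting time, watch/like/comment counts,
article and cover links), the posting account, and an optional content-type
label, together with the *collection date* — the day engagement counts were
read off the platform. Engagement metrics are cumulative at collection
time, so any score built on them depends on post age; that is why the
collection date is part of the container rather than an argument.

Read counts come with a platform quirk: above a display cap (100,000 on
WeChat) the exact number is no longer shown. We store such values as
`(cap, censored = TRUE)`, i.e. an explicit lower bound, and propagate the
flag. No imputation is attempted: every downstream statistic that touches
reads (STCI, the reads-over-10,000 rate) uses the displayed bound, which
makes censored scores conservative lower bounds. Watch counts ("in-views")
are carried through I/O but used by no metric — no published convention
assigns them a role in the index family — so they remain available to
users without influencing results.

## STCI: the Single Tweets Communication Index

The score of a post with cumulative reads $R$, cumulative likes $Z$ and age
$d$ days is

$$\mathrm{STCI} = 10\left[\,0.6\big(0.2\ln(R/d+1) + 0.8\ln(R+1)\big) +
 0.4\big(0.2\ln(10Z/d+1) + 0.8\ln(10Z+1)\big)\right]^2 .$$

The structure is the WCI family's: reads carry 60% of the weight and likes
40%; within each block the *daily-average* term ($R/d$, $10Z/d$) carries
20% and the *cumulative* term 80%; likes are multiplied by 10 so that like
and read magnitudes contribute on comparable log scales; the weighted sum
is squared and scaled by 10. Published renderings of this formula are
typographically damaged (missing division signs, a bare "40", detached
exponent); the reading above is the one under which plausible inputs
($R \in [10^4, 10^5]$, $Z \in [10^2, 10^4]$, $d \le 30$) produce scores in
the several-hundred-to-1,100 band that published high-score tables show,
while the literal readings explode or collapse the scale. All four
interpretation choices are isolated in the single function `stci()`.

Numerical conventions:

- $d$ is the day difference between collection and posting, floored at 1,
  so same-day collection never divides by zero.
- The score is exactly 0 iff $R = Z = 0$, strictly increasing in $R$ and
  $Z$, non-increasing in $d$ (property-tested on a grid).
- The high-communication screen `high_stci_filter()` uses a *strict*
  inequality (score > 800 by default), matching the conventional
  "STCI > 800" phrasing.
- Censored reads are scored at the cap; the resulting score is a lower
  bound and the flag travels with the row.

## Independence (duplication) networks

Cross-posting the same article is common among sibling government
accounts; the *less* two accounts duplicate each other, the more
independent their output. `duplication_matrix()` counts, for each account
pair, matched title pairs: titles are canonicalized (case-folded,
punctuation and whitespace collapsed) and matched exactly by default, or by
token Jaccard similarity above a threshold. Each post can be matched at
most once per counterpart account — a greedy maximum matching by
similarity, which for exact matching reduces to summing
$\min(n_i(t), n_j(t))$ over shared titles $t$.

Because the counted quantity is *overlap*, the package names the row sums
`overlap strength`; independence is its inverse ranking. The field's
terminology ("independence strength") labels the same numbers.

`valued_density()` is the mean of the $n(n-1)$ off-diagonal tie values —
the UCINET convention for valued (weighted) networks, and the only reading
under which a count-valued 10-node duplication network can have a density
in the hundreds. A binary mode (share of nonzero ties) is available behind
the `mode` argument. For the co-word network the same function applies; on
a $[0,1]$-valued Ochiai matrix the valued density is necessarily $\le 1$,
so published co-word densities above 1 must come from raw-count or
rescaled matrices — both are computable here, neither is asserted as the
"right" one.

Matrices export to UCINET DL full-matrix format and CSV edge lists for
external sociometric tools.

## Co-word networks

Titles are tokenized (default: canonicalize, split on whitespace, drop
stoplist words; any segmenter with the same one-string-to-tokens contract
can be plugged in, e.g. for Chinese). `term_frequencies()` counts *token
occurrences*, not document frequencies. `select_high_freq()` keeps terms
with frequency strictly above `min_freq` (default 60) truncated to `top_k`
(default 100), ties broken lexicographically so selection is
deterministic.

`cooccurrence_matrix()` counts, for each term pair, the number of titles
containing both (presence per title). The Ochiai transform

$$y_{AB} = \frac{X_{AB}}{\sqrt{X_A X_B}}$$

normalizes by the geometric mean of the marginal frequencies. We follow
the mixed convention in which $X_A, X_B$ are total occurrence frequencies
while $X_{AB}$ is per-title presence; since per-title presence is bounded
by document frequency, $X_{AB} \le \min(X_A, X_B)$ and $y \in [0,1]$ holds
under the mixture (property-tested over random corpora). Degree centrality
comes in binary (share of nonzero neighbors) and valued (row-sum) modes.

## Content typing

The six-type emergency taxonomy — overview releases, prevention/control
measures, science and disinformation, line-assistance stories, epidemic
impact, negative impact — is assigned by a rule-based lexicon classifier:
the type with the most keyword hits in the title wins, ties break by a
configurable priority order, zero hits follow a fallback policy
(`unclassified` or a default type). This is a transparent stand-in for
manual coding; no published codebook exists, so accuracy claims are only
meaningful on synthetic corpora with disjoint lexicons, where agreement
with the planted type is exact by construction (and verified). Titles, not
article bodies, are classified — the body text is not part of the corpus
schema.

Weekly type proportions use 7-day bins anchored at the corpus start, with
the final partial week retained (a 75-day window yields ten full weeks and
a stub), since dropping it would silently discard posts.

## Temporal dynamics

`daily_counts()` zero-fills missing days so series are contiguous;
`correlate_series()` aligns two series on their common dates and computes
the product-moment correlation with the two-sided $t$-based p-value
($t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, via `stats::cor.test`), on raw
(unsmoothed) daily counts. `period_summary()` gives per-period five-number
summaries using inclusive linear-interpolation quartiles
(`stats::quantile` type 7) — box-plot conventions differ, so the choice is
fixed and stated.

## The synthetic-corpus generator

The generator's defaults encode the study conditions the package is built
around: 10 health-commission accounts posting 2020-01-17 to 2020-03-31
(75 days) with per-account weights proportional to the published account
totals (6,612 posts overall); an epidemic curve that is Poisson noise
around a log-normal-shaped expectation peaking at day 28 (height 4,000
cases/day, log-width 0.45) — a single rapid-rise/slow-decay wave; a target
posting-volume/case Pearson correlation of 0.721; an hour profile nearly
silent from 00:00 to 07:00 with its maximum at 08:00 and smaller
afternoon/late-evening modes; a week-varying type mixture in which
science/disinformation declines, assistance stories rise, and impact
coverage appears from week 6; a planted duplicate rate of 5 shared titles
per account pair (a modest ~7% of posts); and log-normal reads
(meanlog 7.56, sdlog 1.8, mean ≈ 9,680 — matching the published overall
average read count — with ~1.4% of posts censored at the 100,000 cap) with
likes binomially thinned from *uncensored* reads at 0.005 per read, since
like counts are not capped. No engagement distribution is published;
log-normal reads are a modeling choice, flagged as such.

**Correlation planting.** Posting totals must correlate with the epidemic
curve on the *count* scale, but both marginals are discrete and the
curve's variation is mostly deterministic shape, so a textbook bivariate
copula on two independent marginals would attenuate badly. Instead, daily
posts are $\mathrm{qpois}(\Phi(g_t), \lambda)$ where the latent
$g_t = (a\,s_t + \varepsilon_t)/\sqrt{a^2+1}$ blends the standardized
log-curve shape $s_t$ with white noise. The coupling $a$ is calibrated so
that the Monte-Carlo mean of the realized count-scale Pearson $r$ equals
the target: 40 simulated replicates with common random numbers under a
fixed internal calibration seed make the objective smooth and monotone in
$a$, and a root-finder solves it. The calibrated $a$ is therefore a
deterministic property of the config (and cached), not of the run seed.
$|\rho| = 1$ bypasses the latent path: posts are an exact integer multiple
of the (possibly reflected) case counts, so sample $r$ is exactly
$\pm 1$.

**Duplication planting.** For each account pair, a Poisson number of
duplicate pairs (mean = the configured rate) *overwrites* the titles of
already-drawn posts, one in each account, with a fresh shared title. Since
no posts are added or removed, daily totals — and hence the planted
correlation — are untouched. Each post participates in at most one planted
pair, so measured matrix entries equal planted counts up to rare chance
title collisions.

**What the generator does not emulate.** Titles are whitespace-joined
keyword-plus-Zipf-filler token strings, not natural language: co-word
ground truth is exact, but nothing about real lexical statistics,
segmentation ambiguity or semantic drift transfers. There is no retweet or
propagation structure, no account-specific posting-hour signatures, no
engagement dependence on content type or posting hour, and duplicate
engagement counts are drawn independently for the two copies. Passing
recovery tests therefore validates the *computations*, not claims about
real corpora.

## Problem sizes and test design

The suite validates each stage against an independent oracle or planted
truth at sizes chosen to keep the whole run inside a couple of minutes on
one core: correlation recovery uses a 365-day window and 200 seeds (mean
sample $r$ within ±0.03 of the 0.721 target); duplication recovery uses 50
seeds of a 4-account, 1,200-post config at rate 10 (entry means within
15%); scoring is compared to a straight-line formula evaluation on a full
default corpus at $10^{-9}$; co-occurrence is compared to brute-force
enumeration over 200 random titles; classifier and hour-peak recovery use
1,000- and 10,000-post corpora. The hour-profile total-variation check
(≤ 0.02 at 10,000 posts) sits about three standard errors above the
multinomial sampling noise of the planted profile.

## Known limitations

- Censored reads make STCI a lower bound for capped posts; rankings among
  capped posts are driven by likes and age only.
- The lexicon classifier has no notion of polysemy or context; on real
  text it is a baseline, not a validated coder.
- The duplication matcher's similarity mode is token Jaccard with greedy
  matching; near-duplicates below the threshold, paraphrases, and
  cross-language duplicates are out of scope.
- Valued density of a count matrix grows with corpus size; compare
  densities only across corpora of comparable scale.
- The copula calibration targets the *mean* sample correlation; any single
  seed's realized $r$ scatters around the target (sd ≈ 0.014 at 365 days).
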