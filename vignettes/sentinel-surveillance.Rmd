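---
title: "Sentinel surveillance of online communities: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sentinel surveillance of online communities: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`sentinelnet` monitors how topical content circulates within and between
online communities without collecting a platform-scale corpus. The idea is
borrowed from epidemiological sentinel surveillance: rather than testing
the whole population, one watches a small number of carefully chosen sites
whose data are of known, consistent quality. Here the "sites" are a
handful of highly retweeted accounts per community, followed
longitudinally. This vignette records the models the package implements,
the conventions and defaults it fixes, and the reasoning behind the design
choices that were genuinely open.

## The retweet network and directed modularity

A corpus of tweets induces a weighted directed graph in which the arc from
original poster $i$ to retweeter $j$ carries weight $A_{ij}$, the number
of times $j$ retweeted $i$. The weighted in-degree of an account is the
number of times it was retweeted — its amplification — and the out-degree
the number of times it amplified others. Self-retweets are excluded
entirely: they neither create arcs nor introduce nodes.

Analysis restricts to the largest *weakly* connected component. Retweet
graphs are nearly acyclic, so strongly connected components would be tiny
and would discard almost all structure; a retweet in either direction is
evidence that two accounts sit in the same conversation. Size ties (which
essentially never occur beyond toy data) are broken toward the component
whose sorted account ids come first lexicographically, to keep every
operation deterministic.

Communities maximize the directed, weighted modularity

$$Q = \frac{1}{w}\sum_{i}\sum_{j}\Bigl(A_{ij} -
  \frac{w_i^{in}\,w_j^{out}}{w}\Bigr)\,\delta(C_i, C_j),$$

with $w$ the total arc weight. The diagonal null-model terms ($i = j$) are
kept even though $A_{ii} = 0$; they are part of the quality function, and
dropping them would shift $Q$ by a partition-dependent constant.

`louvain_communities()` maximizes $Q$ in the generalized-Louvain style:
the full modularity matrix $B_{ij} = A_{ij} - w_i^{in} w_j^{out}/w$ is
formed explicitly and symmetrized as $(B + B^\top)/2$, which leaves $Q$
unchanged for every partition while making the greedy node-move gains
well-defined. Node visitation order is shuffled deterministically from the
seed; moves are accepted only for gains above $10^{-10}$, communities are
then aggregated and the process repeats. Five restarts (seeds
`seed + 0..4`) are run by default and the best modularity wins — the
number of restarts is exposed because plain modularity maximization is
degenerate near its optimum. The resolution parameter multiplying the null
model defaults to 1 (plain modularity) and is exposed in the
configuration.

The dense-matrix formulation is faithful to the directed null model and
simple to reason about, but quadratic in nodes; it is intended for the
network sizes the sentinel approach targets (up to a few thousand
accounts), not platform-scale graphs.

## Partition stability: Rand and z-Rand

Robustness of the community structure is assessed by re-collecting a
second corpus and comparing partitions on the common node set. The Rand
index is the fraction of node pairs classified consistently. Its
significance is judged by the z-Rand score: the number of pairs
co-assigned in both partitions, $w_{12}$, standardized by its exact mean
and standard deviation under the null in which one partition's labels are
uniformly permuted across nodes, keeping both partitions' group sizes
fixed. The mean is $M_1 M_2 / M$ (with $M$ the number of node pairs and
$M_k$ the within-group pair counts); the variance is computed in closed
form by splitting ordered pairs of node-pairs by whether they share a
node. A naive hypergeometric variance that treats pair memberships as
independent draws ignores this dependence and disagrees with the
permutation null, so the package implements the exact second moment; the
unit tests verify it against a brute-force permutation oracle. Degenerate
nulls (for example one partition all-together and the other all-apart)
have zero variance and yield a missing z-score with a warning, never an
infinity.

## Sentinels, activity, and attrition

From every community at least `min_size` nodes large, the `k = 15` most
retweeted accounts are selected as sentinels, ties broken toward the
lexicographically smaller id. The in-degree distribution of retweet
networks is heavy-tailed, so a small `k` typically accounts for most of a
community's amplification; `sentinel_coverage()` reports that fraction per
community with mean, median and interquartile range. Screening communities
for language or geography requires external services, so
`select_sentinels()` takes an injectable predicate instead; the default
keeps every community.

Longitudinal monitoring suffers attrition (deletion, suspension). An
account is *active* on a day if a tweet from it is observed on that day or
later; its *active account days* within a window therefore equal
last-tweet-day − window-start + 1. Per-capita rates divide topical tweet
counts by active account days, which removes the mechanical decline a
fixed denominator would impose. Day bucketing uses a configurable
timezone, defaulting to UTC; analyses anchored to the US news cycle
should set `"America/New_York"`, and window demarcations quoted in
Eastern time require it to reproduce exactly.

## The linked domain score

Communities are characterized by where they link. URLs reduce to
lowercased registered domains ("www.foxnews.com" → "foxnews.com"); links
to twitter.com and to URL shorteners (bit.ly, t.co, ...; the list is
configurable) are tagged and excluded but counted, so the accounting
identity `total = twitter + shortened + retained` is always available.
Domains shared fewer than 10 times in total across all communities are
dropped. The retention sentence admits a second reading — at least 10
shares by some single community — so that variant sits behind
`per_community = TRUE`; the total-across-communities rule is the default
because it matches the exclusion phrasing. Row entries are fractions of
the community's links to *retained* domains, making rows sum to one and
comparable across communities with different twitter/shortener mixes.

The score is the first principal component of this matrix with columns
mean-centered but **not** variance-scaled: the rows are compositions on a
common scale, and unit-variance scaling would inflate rare domains into
the leading component. Principal axes are defined only up to sign, so the
orientation is fixed by an anchor domain whose loading is forced positive
(by default the largest-magnitude loading). Scoring the conservative pole
positive is a matter of anchoring on a conservative outlet's domain.

Communities are then clustered on the one-dimensional scores.
Agglomerative clustering with centroid linkage is the default and average
linkage is available behind a flag; the two descriptions appear in
different places in the literature this package follows, so both are
provided rather than silently reconciled — on one-dimensional data the
difference is minor. Silhouette scores are reported for every cut from 2
to `max_k`; the silhouette-optimal cut is chosen unless the caller forces
`k` (forcing a cut below the optimum is sometimes warranted by domain
knowledge, and the object records that the cut was forced). Cluster labels
are ordered by increasing mean score so that label 1 is the most negative
pole. An optional join against a user-supplied media-bias table groups
domain loadings by category and computes the Pearson correlation between
loading and ordinal political tilt (Left = 1 ... Right = 5); the package
ships no bias data.

## Keyword topics, rates, and coded content

Topic identification is deliberately simple: case-insensitive substring
containment against editable keyword lists, with nested topics gated on a
parent (a vaccine-hesitancy tweet must first be a vaccine tweet, which
must first be a COVID tweet). Plain containment means "mask" matches
"masks" and also "unmasked" — that is the faithful behavior, and a
word-boundary mode exists behind a flag for callers who want it. The
shipped lists under `inst/extdata/topics/` reproduce the quoted anchor
phrases of each topic family; where full lists were not quoted, the
remainder is a clearly marked reconstruction, and the code treats the
lists purely as data.

Scaled per-capita rates divide each community's tweets-per-active-account-
day by the sum across communities, so they sum to one. The daily display
normalization is tweets per 15 active accounts.

For human coding, `stratified_sample()` draws up to `n` tweets per
(cluster, topic) stratum with communities represented as equally as
possible: an equal share per community with largest-remainder rounding,
communities that cannot fill their share contribute everything, and the
shortfall is re-split among the rest (so availabilities 500/30/500 at
`n = 100` yield 35/30/35). Chi-square tests on coded contingency tables
use Pearson's statistic without continuity correction; reconstructing
counts from published sample sizes and percentages rounds each cell to
the nearest integer. Inter-coder reliability is Krippendorff's alpha in
the nominal coincidence-matrix formulation, with units coded by fewer
than two coders dropped and the all-codes-identical degenerate case
returning 1 with a warning.

## Burst detection

For each community and day, the "document" is the set of that day's
topical tweets, cleaned (lowercase; URLs and @-mentions stripped;
punctuation-delimited tokens; a fixed shipped English stopword list) and
reduced to a trigram count vector; trigrams never span tweet boundaries,
and tweets shorter than three tokens contribute nothing. The similarity
between clusters $A$ and $B$ on day $t$ is the arithmetic mean of cosine
similarities over all community pairs $(a \in A, b \in B)$; a
within-cluster variant over distinct unordered pairs is available for
diagnostics. A community that posts nothing contributes an empty document
whose pairs score 0 and remain in the mean — silence is informative — with
the count of such pairs reported.

The burst score standardizes the day against its own history:

$$H(A,B,t) = \frac{s_t - \operatorname{mean}_{\tau<t}\{s_\tau\}}
  {\operatorname{SD}_{\tau<t}\{s_\tau\}}.$$

The history is *expanding* — all observed days strictly before $t$, with
the baseline period seeding it — rather than a rolling window, matching
the notion of "historical" similarity. The standard deviation is the
sample SD (ddof = 1) by default with the population convention exposed,
since the source description is silent on the point. $H$ is undefined
(missing, never infinite) while fewer than `burn_in = 7` prior days have
been observed or when the historical SD is zero. Days with $H \ge 2$ are
flagged.

Standardizing against history presumes the series is stationary around a
constant level, so `adf_check()` runs the Dickey–Fuller regression with a
constant and zero lagged differences, $\Delta s_t = \alpha + \rho s_{t-1}
+ \varepsilon_t$. The null distribution of the t-statistic is nonstandard;
the p-value comes from a seeded Monte-Carlo simulation of driftless random
walks of the same length (4000 replicates by default), which keeps the
check self-contained and exact at any sample size. The verdict is a logged
diagnostic gate, not a hard stop.

## Burst attribution via latent semantic analysis

For a flagged day and cluster pair, each cluster's tweets form a
tweet-by-trigram matrix whose truncated SVD is computed; the document
(left) singular vectors of the five largest singular values are examined.
"A sharp drop" in component magnitude is formalized as the largest ratio
between consecutive sorted absolute components, searched over the top
`min(50, n)` positions, with at least one tweet always selected; the rule
is deterministic and configurable because the qualitative description
admits many formalizations, and this one is presented as the package's
choice, not anyone else's. Signs of singular vectors are arbitrary, so
only magnitudes are used.

Tweets "common to both clusters" are formalized as near-duplicate pairs
across the two clusters' topical sets — trigram-support Jaccard at least
0.5 by default — because identical retweet text is the dominant mechanism
by which the same content appears in two clusters, yet exact string
equality would be too brittle. Matched tweets are removed from both
clusters' documents, the day's similarity and burst score are recomputed
against the unchanged history, and the flag is marked attributed exactly
when the recomputed score falls below the flagging threshold. A flag with
no cross-cluster matches is reported unattributed with nothing removed.

## The synthetic corpus generator

`generate_corpus()` exists so that every pipeline stage can be exercised
offline against known ground truth. It emulates the statistical structure
the analysis assumes:

- **Assortative retweeting.** A retweet stays within its community with
  probability `p_in = 0.95`; targets are drawn by preferential attachment
  on current in-degree, producing the heavy-tailed amplification profile
  that sentinel coverage relies on.
- **Domain poles.** The first half of the communities links only to one
  pool of synthetic domains, the second half to another (the pools are
  named `leftnews*.org` / `rightnews*.org` and are labelled synthetic
  throughout); disjoint supports make pole recovery by the domain score a
  sharp, testable prediction.
- **Community vocabularies with a shared news cycle.** Background tokens
  are drawn from community-specific Zipf-like vocabularies, so baseline
  trigram overlap between communities comes only from a shared daily
  "news" channel: each day carries a handful of fresh news phrases, and a
  deterministic quota of each community's COVID tweets carries one,
  with the quota following a weekly sinusoid
  (`news_base * (1 + news_amplitude * sin(2π day/7))`). Weekly posting
  and news cycles are a well-documented feature of social platforms, and
  a cycle-dominated baseline keeps the burst score of ordinary days
  bounded (the standardized extreme of a sinusoid is √2), which is the
  low-baseline regime the detector is meant for.
- **Planted topics and events.** Keyword topics are emitted within COVID
  tweets at per-community rates; virality events inject verbatim copies
  of a fixed text into chosen communities on known days, with the
  injected tweet ids recorded in the truth object.

The generator is deterministic given its seed. Default dimensions are 4
communities × 25 accounts × 42 days with ~3 tweets per account-day, which
keeps a full end-to-end run around two seconds.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real data: natural language (texts are token
templates, so cleaning and tokenization edge cases are exercised by
dedicated unit fixtures instead), duplicated text between a retweet and
its source (retweet arcs and tweet texts are generated independently),
bot-like coordination, account churn mid-window, multilingual content,
and cross-platform spread. Real similarity baselines are also noisier
than a quota-driven news cycle; the bounded-baseline design makes the
planted-event tests sharp, not representative of every empirical series.

## Problem sizes and numerical conventions

The test suite and the acceptance script run entirely on synthetic or
constructed data, at sizes chosen to make the checked properties sharp:
exhaustive partition enumeration up to 5 nodes, 20-node partitions against
a 10,000-permutation null, planted-recovery corpora of 100 accounts over
14 days across 5 seeds, and full pipeline runs of 100 accounts over 42
days across 5 seeds. Key numerical conventions collected in one place:
Louvain move tolerance $10^{-10}$ with best-of-5 restarts; PCA via SVD of
the centered matrix with a rank-0 result reported as all-zero scores;
silhouette cuts skipped when distances degenerate; cosine similarity of
an empty document defined as 0; burst scores missing (not infinite) under
short or constant history; sample-SD convention throughout with the
population variant exposed; all randomness routed through explicit seeds
and `withr::with_seed`, so every result in the package is reproducible
bit-for-bit given the seed.

## Limitations

The dense modularity matrix bounds community detection to networks of a
few thousand nodes. Trigram cosine similarity captures lexical overlap
only; paraphrased content with disjoint wording is invisible to it, and
embedding-based similarity is an explicit non-goal here. URL shorteners
are tagged, not resolved, so content behind them is excluded from domain
profiles. The language/geography screen is an injectable predicate, not a
detector. Sentinel monitoring detects presence and patterns of
cross-community spread; it is not designed to reconstruct diffusion
pathways in detail, for which the small monitored account set is
insufficient by construction.
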