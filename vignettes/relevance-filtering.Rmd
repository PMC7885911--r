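---
title: "Iterative topic-model relevance filtering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative topic-model relevance filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicsift)
```

## The problem

Social-media corpora collected around a health emergency are dominated by
noise. Posts by healthcare professionals (HCPs) that characterize, prevent,
diagnose, or treat the disease — the clinically relevant minority — share
much of their surface vocabulary with mundane posts, jokes, politics, and
misinformation, so no keyword query isolates them, and at the scale of
millions of posts manual labeling is not an option. `topicsift` implements
an unsupervised route: alternate a topic model, which groups documents
without supervision, with a clinical-concept relevance score, which ranks
what the groups talk about. Each pass removes documents associated with
irrelevant topics; the next pass estimates relevance on a cleaner corpus.
Neither component needs labels, and each compensates for the other's
weaknesses — concept annotation is noisy at the document level but
informative in aggregate, while topic models represent everything,
relevant or not, unless something ranks their topics.

## The model

Write $D^{(0)}$ for the raw corpus. A keyword heuristic over author
profiles (27 credential patterns such as "MD", "Dr", "epidemiolog\*",
"public health") keeps documents by self-identified HCPs, giving
$D^{(1)}$. This filter is deliberately sensitive rather than precise:
credentialed authors posting noise pass it, and the iterative stage exists
to remove them. The exact published credential list is not public, so the
default lexicon shipped here is a documented, overridable stand-in.

Each filtering iteration $i \ge 1$ then performs four steps on the current
corpus $D^{(i)}$ of $M^{(i)}$ documents.

**1. Topic generation.** A $k$-topic LDA model is fitted by collapsed
Gibbs sampling, giving the document–topic matrix
$\theta^{(i)} \in \mathbb{R}^{k \times M^{(i)}}$, where
$\theta^{(i)}_{t,m}$ estimates the probability that a word of document $m$
was sampled from topic $t$, and topic–word distributions $\beta^{(i)}$.
The model is refitted from scratch each iteration: the corpus changes, and
a fresh fit keeps iterations independent and reproducible.

**2. Concept scoring.** Every document carries a multiset of concept
mentions $C(m)$ — trigger words matched against a clinical lexicon (or
read from a precomputed annotation file). For corpora $A \subset B$, a
trigger $c$ scores

$$\mathrm{Rel}(c; A, B) =
  \frac{f_A(c)/|A| + \epsilon}
       {\bigl(f_B(c) - f_A(c)\bigr)/\bigl(|B| - |A|\bigr) + \epsilon},$$

the ratio of its per-document occurrence rate among kept documents to its
rate among discarded ones ($f$ counts occurrences, $|\cdot|$ counts
documents, $\epsilon$ prevents division by zero). The reference pair
follows a fixed schedule: $(A,B) = (D^{(1)}, D^{(0)})$ at $i = 1$ —
HCP-authored against everything else — and $(D^{(i)}, D^{(1)})$ afterwards,
holding $D^{(1)}$ as a stable baseline so scores do not collapse onto a
single topic. Before the first iteration, concepts with
$\mathrm{Rel}(c; D^{(1)}, D^{(0)}) < 1$ (more frequent per document
*outside* the HCP set) are removed once and stay removed.

**3. Topic scoring and selection.** Topic $t$ scores the
$\theta$-weighted mean of its documents' total concept relevance,

$$\mathrm{Score}^{(i)}(t) =
  \frac{\sum_m \theta^{(i)}_{t,m} \sum_{c \in C(m)} \mathrm{Rel}^{(i)}(c)}
       {\sum_m \theta^{(i)}_{t,m}},$$

and the relevant set $R^{(i)}$ keeps topics with
$\mathrm{Score}^{(i)}(t) \ge (S^{(i)}_{\max} - S^{(i)}_{\min})\,\tau +
S^{(i)}_{\min}$. Note the topic's own word list plays no role in its score,
so clinically relevant words absent from the concept lexicon (too new, for
instance) can still dominate a high-scoring topic.

**4. Document filtering.** Document $m$ survives iff its relevant-topic
mass meets the uniform baseline,
$\sum_{t \in R^{(i)}} \theta^{(i)}_{t,m} \ge r^{(i)}/k$ with
$r^{(i)} = |R^{(i)}|$. The loop stops after a fixed number of rounds or
early once $r^{(i)}$ reaches a configured fraction of $k$, the sign that
little irrelevant material remains.

## Parameters

* `k` (default 100): topic count. 100 balances granularity against
  summarizability on corpora of $10^5$–$10^6$ short documents; the
  package's small-corpus demonstrations use 10–20, and filtering behavior
  is comparable across this range.
* `tau` (default 0.25): position of the relevance cutoff between the
  minimum and maximum topic score, in [0, 1]. Values near 1 keep only the
  most concept-dense topics; 0.25 keeps a diverse relevant set. Choose it
  by inspecting the topic-score distribution of an initial model.
* `eps` (default 0.001): relevance smoothing. It appears in numerator and
  denominator alike, so a term unseen in both corpora scores exactly 1
  (neutral), and terms seen only in the kept corpus get large finite
  scores that grow as `eps` shrinks.
* `max_iterations` (default 3) and `stop_topic_fraction` (default 0.5):
  three rounds suffice in practice; by the round where more than half the
  topics qualify as relevant, filtering has little left to remove. The
  early stop is a heuristic scaled to `k`; analyses that prescribe an
  exact round count disable it by setting `stop_topic_fraction = 1`.
* `relevance_basis`: `"concepts"` scores concept triggers only;
  `"all_words"` scores every token, the ablation that measures what
  concept annotation adds. Both run through identical machinery.
* Sampler controls: symmetric priors `alpha = 5/k` and `eta = 0.01`, 1000
  Gibbs sweeps, and an explicit seed. The sampler uses its own
  Mersenne–Twister stream, so a fixed seed gives identical fits regardless
  of the caller's R RNG state; iteration $i$ uses `seed + i - 1`, and
  window $w$ of a windowed analysis uses `seed + 1000w`.

## Preprocessing contract

Text is normalized in a fixed order: strip HTML tags; drop URLs and
@-mentions (platform boilerplate, removable by configuration); expand
contractions from a fixed table; remove emoji by Unicode block; lowercase;
reduce "#tag" to "tag"; split on non-alphanumerics; lemmatize; drop
stopwords, the corpus query terms, and single characters. Lowercasing
precedes lemmatization by design. The lemmatizer is a small
rule-plus-exception dictionary honoring the contract the pipeline needs —
plural nouns to singular, inflected verbs to base form, noun reading
preferred when ambiguous, unknown words unchanged — and it is idempotent
on its own output, which makes re-tokenization of cached token streams a
no-op. It is deliberately not a full morphological analyzer; tokens it
leaves imperfect (e.g. rare gerunds) are scored consistently on both sides
of every relevance ratio, which is what matters here.

Concept annotation is greedy longest-match (up to 3 tokens)
left-to-right, one mention per matched occurrence, no negation or
word-sense disambiguation: false positive mentions are tolerated because
relevance ratios, not single mentions, drive filtering. Scoring keys on
the normalized *trigger string* with the concept identifier carried as
metadata, and the inner sum of the topic score treats $C(m)$ as a
multiset — a document mentioning "fever" three times contributes three
times the trigger's relevance. Mentions of the same concept in one
document are therefore counted per occurrence; this is a documented
choice, and set semantics can be had by deduplicating the mention table.

## The synthetic evaluation corpus

The real corpora this method targets have no ground truth, so the package
ships a generator whose output does. It emulates the statistical structure
the method assumes:

* $K$ planted topics over a vocabulary split into clinical words (each
  mapped to a synthetic concept identifier in the bundled lexicon) and
  general words; topic–word distributions are heavy-tailed Dirichlet
  draws.
* Each document draws a topic mixture; the intended-relevant share (25%
  by default) leans on the clinical topics and is drawn conditional on
  clinical mass $\ge 0.5$, the noise share conditional on $< 0.5$, so the
  label ("relevant" iff majority clinical mass) is consistent and its
  empirical share concentrates on the target.
* A configurable fraction of clinical words (default 20%) also receives
  mass in noise topics — mundane posts reusing clinical vocabulary, which
  is precisely what makes this filtering problem non-trivial.
* Author bios carry credential keywords at class-dependent rates (0.9
  relevant, 0.2 noise), chosen so the author-filtered corpus is only
  ~60% relevant, mirroring how imprecise profile heuristics are in
  practice.
* Credentialed authors additionally emit a few community-jargon tokens
  regardless of what they post about, and every document may carry
  idiosyncratic rare tokens (typos, fragments). Neither is in the concept
  lexicon. These two features are what give concept-based scoring its
  measurable edge over the all-words ablation: author-correlated and rare
  tokens acquire large, noisy relevance ratios that only the all-words
  basis consumes.
* Optional trend events hold every document that drew tokens from a given
  topic until after an onset date, for testing windowed micro-trend
  detection.

What the generator does *not* emulate: natural language (tokens are
synthetic symbols), document-length heterogeneity beyond Poisson,
author-level post correlation, threads, retweet dynamics, multilinguality,
or adversarial content. Passing tests on generated corpora therefore
demonstrate that the machinery implements the method and that the method
recovers planted structure under realistic noise — not performance on any
real platform.

## Numerical choices and degenerate inputs

* All boundary comparisons use $\ge$: the topic-score cutoff, the
  document filter (a uniform $\theta$ column survives), and the concept
  pre-filter (a trigger with equal rates is retained). The document
  filter's comparison carries a $10^{-12}$ float tolerance so that
  uniform columns pass equality exactly.
* $\theta$ and $\beta$ come from the final Gibbs state smoothed by their
  priors, so columns/rows sum to 1 and no entry is zero; topics can
  therefore always be score-normalized.
* Zero-token documents are excluded from sampling, flagged, and given
  uniform $\theta$ columns — under the document filter they sit exactly
  on the boundary and survive.
* Top-word lists order ties by vocabulary order, making reports and
  coherence deterministic.
* UMass coherence uses the standard $+1$ co-document smoothing; a
  reference word with zero document frequency contributes through a
  1-document floor.
* Note that growing the relevant set does not monotonically grow the kept
  set: each added topic raises the threshold $r/k$ by $1/k$ but adds only
  $\theta_{t,m}$ to a document's mass. The boundary facts that do hold
  ($\tau = 0$ keeps everything; $R$ = all topics keeps everything) are
  tested instead.
* Iteration-1 relevance compares the author-filtered corpus against what
  the filter discarded, so the pipeline refuses corpora where the filter
  discards nothing — there would be no reference set.
* Threads are carried as grouping metadata only; documents are always
  scored individually (thread concatenation would entangle the
  document-topic unit the filter operates on).
* Time windows are half-open `[start, start + 14d)` UTC at 7-day stride,
  anchored at the user's start date; a boundary-day document belongs to
  the window opening that day.

## Problem sizes in the shipped checks

The package's tests and the `scripts/acceptance.R` report run the full
pipeline on generated corpora of 2,000 documents (vocabulary 600 + jargon
and rare tokens, mean length 18, five replicate corpora) at $k = 20$ with
three iterations, plus a seven-window trend analysis at two iterations per
window — sizes chosen so the whole evaluation completes in minutes on one
core while leaving each LDA fit enough data to recover the planted
structure. The same code paths scale to the million-document regime the
method was designed for; only the topic count ($k = 100$) and wall-clock
budget change.

## Known limitations

* The credential lexicon is a heuristic stand-in; sensitivity and
  precision on a real platform depend on profile conventions the package
  cannot know.
* The dictionary annotator matches surface phrases only — no negation,
  hedging, or sense disambiguation — and inherits every bias of the
  lexicon it is given.
* Relevance ratios are descriptive statistics, not tests; no uncertainty
  is attached, and rare terms have high-variance scores by construction
  (mitigated, not removed, by `eps`).
* Topic-count sensitivity: very small $k$ merges relevant and irrelevant
  content into shared topics, weakening the filter; the early-stop
  fraction is scaled to $k$ but remains a heuristic.
* The method surfaces what credentialed authors discuss; silence on a
  topic is not evidence of clinical irrelevance, and discussion intensity
  is an imperfect proxy for importance.
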