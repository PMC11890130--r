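---
title: "Evidence-based fact-checking of health web pages: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-based fact-checking of health web pages: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medfactcheck)
```

## The problem and the pipeline's stance

Manually verifying the claims on a health web page against the scientific
literature is slow expert work. This package automates the retrieval side
of that process: it does not decide whether a claim is *true*, it measures
whether a claim has a close counterpart in peer-reviewed literature and
hands the evidence (sentence, article, link) to a human. The unit of
analysis is the sentence; the unit of reporting is the page, summarised as
the fraction of claim-bearing sentences with literature support.

The pipeline rests on three modelling assumptions worth stating plainly:

* **Claims are identifiable by theme.** A sentence is worth verifying if it
  is about a disease's statistics (*epidemiology*), its signs and symptoms
  (*semiology*), or its treatment, prevention and diagnosis (*management*).
  Everything else is *neutral* and skipped. This four-way scheme also
  scopes the search and the comparison: evidence for an epidemiological
  claim is only sought among epidemiological sentences.
* **PubMed is the source of truth**, approached through boolean queries
  built from MeSH descriptors and keyphrases, restricted to freely
  available systematic reviews and meta-analyses — the publication types
  that aggregate evidence rather than report single studies.
* **High vector similarity is a usable proxy for semantic support.** A web
  sentence counts as credible when some same-category literature sentence
  scores at or above a similarity threshold. This proxy has a known
  failure mode, discussed under Limitations.

## Sentence classification

`train_classifier()` is the package's fitted-model core: it returns a
classed object with `predict`, `print` and `summary` methods. Two backends
are built in.

The **keyword backend** is a per-class term-frequency scorer. For token
$t$ and class $c$, the smoothed class-conditional frequency
$p(t\mid c) = (n_{tc} + \alpha)/(N_c + \alpha V)$ (with $\alpha = 0.5$,
$V$ the vocabulary size) is normalised across classes into a vote
$v(t,c) = p(t\mid c)/\sum_{c'} p(t\mid c')$; a sentence's class score is
the sum of its tokens' votes, and the reported confidence is the chosen
class's share of the total. Class-specific vocabulary votes near 1 for its
class; ubiquitous words split their vote evenly and cancel out. The
backend has no random state at all, which is why the test suite and the
offline pipeline default to it.

The **multinomial backend** hashes the token bag into 256 signed features
(see *Embeddings* below) and fits a ridge-penalised multinomial logistic
model with `nnet::multinom`. It is the package's trainable route for
corpora where plain term frequencies are not separable. Transformer
classifiers are deliberately out of the package: where one is available it
can be wrapped as an external scorer, and the configuration object keeps
the fine-tuning hyperparameters (learning rate 3e-5, weight decay 1e-3,
3 epochs, batch size 32, maximum sequence length 128 tokens) that such a
backend would consume.

Decisions taken where the design was open:

* Sentences longer than `max_seq_len` tokens are truncated, never
  rejected — a long sentence is still classifiable from its head.
* Ties in the class scores break by the fixed label order
  neutral < semiology < epidemiology < management, so prediction is
  deterministic and order-invariant.
* The train/validation split is 80/20, stratified by class, under a fixed
  seed (`split_corpus()`).
* Evaluation follows the usual conventions: precision is 0 (and flagged)
  for a class with no predicted positives, so degenerate predictors
  produce defined numbers rather than NaNs.
* Cohen's κ uses the marginal-product chance correction
  $\kappa = (p_o - p_e)/(1 - p_e)$,
  $p_e = \sum_i p_A(i)\,p_B(i)$. When $p_e = 1$ both annotators used a
  single identical category, agreement is total, and κ is defined as 1.
  Note a consequence of the formula that is often mis-stated: two
  annotators who each use a *single, different* category have $p_e = 0$
  and κ = 0, not −1; κ = −1 requires total disagreement with balanced
  marginals (e.g. alternating x/y against y/x).

## Term extraction and query assembly

Per page and category, the category's sentences are concatenated and two
ingredient sets extracted.

**MeSH terms** come from a dictionary matcher over a loaded vocabulary
(descriptor → tree numbers → lowercase entry terms). An exact phrase hit
scores 1, a plural-stemmed hit 0.9, and the default threshold 0.5 keeps
both; every returned descriptor is guaranteed to be in the vocabulary, so
it always carries tree numbers. The packaged vocabulary
(`inst/extdata/mesh_mini.tsv`, ~50 descriptors) is a miniature test
fixture covering the seven example diseases; a full MeSH export in the
same three-column layout drops in unchanged. A tagging model can be
supplied as a function backend; its proposals are resolved against the
vocabulary and unknown descriptors dropped with a warning.

**Keyphrases** come from a term-frequency ranker over stopword-free
1–3-grams, weighted frequency × length so a phrase seen as often as its
constituent words outranks them, ties broken alphabetically. The default
`top_n = 5` is a pragmatic cap: the phrases are AND-joined in their
subquery, and AND-ing many phrases quickly empties a PubMed result set.
Keyphrases that duplicate an extracted MeSH descriptor or entry term are
dropped (case-insensitively, logged) so a concept is not required twice.

The query is a three-level boolean tree. MeSH terms are grouped by the
leading letter of each tree number — a descriptor whose tree numbers span
several letters appears in every one of its groups, once per group — then
OR-ed within a group, AND-ed across groups, with the `[MeSH Terms]` field
tag and double quotes around multi-word terms. Keyphrases are AND-ed
untagged. The final query ORs the non-empty subqueries, each
parenthesised. Groups are keyed by the letter actually observed rather
than a hard-coded category count, so the builder is indifferent to how
many top-level MeSH branches the vocabulary edition has. Field-tag syntax
is this package's choice of concrete PubMed serialisation. A round-trip
parser (`parse_query`) ships with the builder; the suite checks on
randomized term sets that every emitted string re-parses to the builder's
tree and that a subquery with $g$ groups of sizes $n_i$ contains exactly
$g-1$ ANDs and $\sum_i (n_i - 1)$ ORs.

## Retrieval

Live mode appends `free full text[Filter]` and the systematic-review /
meta-analysis publication-type clause, submits via E-utilities esearch in
relevance order, and retries with exponential backoff; email and API key
are configurable, and the open-access clause can be swapped (PMC OA users
may prefer a different filter). "Top 20" is interpreted as the first 20
of PubMed's relevance ranking. The manual relevance screen that a human
would apply to retrieved titles is mechanised as an exclusion list
(`apply_exclusions`): listed PMIDs are flagged, not deleted, so survivor
ranks are stable and the decision is auditable.

Fixture mode — the path every test exercises — scores each article of a
JSONL store by the number of distinct query terms found in its title,
text, or MeSH annotations, ranks by score with ties broken by ascending
PMID, and is a pure function of (query, store). Fetched article text is
segmented with the same rule-based segmenter used for web pages, and the
article sentences are then categorized by the same classifier that
labelled the page, keeping the comparison within-theme by construction.

## Embeddings, matching and the page score

The default sentence embedder is 256-dimensional signed feature hashing
of the lowercase token bag: each token's integer hash (31-ary rolling
hash mod 2³¹, pure integer arithmetic, so identical on every platform)
selects a coordinate and a sign. Word order is ignored by construction;
two sentences sharing no tokens are near-orthogonal at this dimension.
It gives the pipeline meaningful cosine geometry with zero pretrained
weights. A transformer encoder can be passed anywhere an `embedder`
argument appears (mean pooling is the conventional choice there); the
hashing embedder is the default because it is deterministic and
dependency-free, not because it rivals learned semantics.

Matching compares each categorized web sentence against every
same-category article sentence and keeps pairs scoring at or above the
threshold, default **0.87** — applied to cosine on its raw scale (87% ⇒
0.87) and to Jaccard likewise. Cosine is the default metric; Jaccard is
retained for comparison runs. Degenerate inputs are defined, not fatal:
an empty article side yields an empty match list (a page without evidence
is a result), a zero vector is a cosine error (its direction is
undefined), and the Jaccard of two empty token sets is 1 (identical
emptiness, reported via a message). Match tables report scores to 4
decimals; report percentages round half-even to the integer.

A page's report counts its non-neutral sentences (`n_categorized`), those
with at least one match (`n_credible`), and their ratio
(`credible_fraction`, defined as 0 for a page with no categorized
sentences), with each credible sentence linked to its best-scoring
evidence sentence and PubMed URL.

## Corpus ingestion

HTML is parsed with libxml2 (tag soup tolerated). After removing script,
style, nav, header, footer, aside and form subtrees, block elements are
kept when they read like prose: at least 25 characters with a stopword
density of at least 0.25, or at least 150 characters regardless; blocks
whose anchor text exceeds half their characters are discarded as link
lists. All four cut-offs are arguments. Pages from which nothing can be
extracted yield an empty string — an extraction failure is a reportable
outcome, never an exception.

Segmentation is rule-based for determinism: a run of `.!?` ends a
sentence when followed by whitespace and an upper-case letter, digit or
opening quote, unless the preceding word is on the packaged abbreviation
list; decimals never split because no whitespace follows the dot.
Fragments under 3 characters merge forward, so concatenating the
sentences recovers every non-whitespace character exactly once. Spans are
0-based half-open into the cleaned text, and all ids derive from
(document id, ordinal). Documents serialise to a canonical JSONL (fixed
field order), making save → load → save byte-identical.

## The synthetic generator: what it does and does not show

`generate_labeled_corpus()` instantiates five templates per class with
seven disease names and numeric slots; `generate_article_store()`
additionally builds an article store in which a chosen fraction of a
companion web-sentence set has a same-category near-duplicate planted at
a known position, with the ground-truth key returned. Planting is
deterministic (the first ⌈fraction·n⌉ sentences in corpus order), filler
sentences carry an extra pooled-analysis clause so they cannot collide
with web sentences, and the whole store is a pure function of the spec.
Noise is within-sentence token shuffling at the spec's `noise_rate`;
because the default embedder and Jaccard are bag-of-token measures,
shuffling leaves their scores unchanged, so recovery is anti-monotone in
noise only in the non-strict sense — a stricter noise model (token
dropout or substitution) would be needed to make that inequality strict,
and would change what "planted" means.

The templates are *lexically separable by construction*: each class has
content words the others lack. A term-frequency classifier therefore
reaches accuracy 1.0 on the noiseless corpus, and planted duplicates are
recovered exactly. That is the point — these are correctness fixtures
with known answers, not difficulty benchmarks. Passing them shows the
machinery (ids, spans, grouping, thresholds, determinism) is right; it
says nothing about performance on real annotated web pages, where
classes share vocabulary, paraphrase replaces duplication, and reported
credible fractions are far below 1.

Problem sizes used by the suite and the acceptance script — 200
randomized term sets for query round-trips, 50 random fixtures of up to
10³ sentence pairs for matcher/oracle agreement, 400 sentences per class
for classification, 5 pages for the end-to-end demo — were chosen so each
property is exercised well past its edge cases while the whole suite
stays comfortably interactive.

## Known limitations

* **Syntactic similarity is not semantic support.** Near-identical
  surface forms can differ in meaning (timescales, negation, populations);
  pairs above the threshold still need human review, which is why reports
  link the evidence rather than asserting truth.
* An unmatched sentence is not thereby false: the 20-article window is
  small relative to the literature, and paraphrase defeats both metrics.
* The dictionary MeSH matcher does no synonym expansion beyond its entry
  terms and plural stemming; the packaged vocabulary is a test miniature.
* Retrieved-article quality (journal, recency, retraction status) is not
  scored.
* Live retrieval depends on NCBI service behaviour and is intentionally
  untested offline; fixture mode is the reproducible path.
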