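# medfactcheck

Evidence-based fact-checking of online health information, against PubMed
as the source of truth.

Health websites mix verifiable medical claims with filler prose. This
package automates the evidence-retrieval side of checking them: it reduces
a page to sentences, decides which sentences carry claims worth verifying
and of what kind, finds related peer-reviewed literature, and reports which
claims have close counterparts in that literature. It is aimed at people
building health-information quality tools — the output is evidence for a
human judgment, not a verdict.

## The method

Four stages, run per page:

1. **Thematic classification.** Every sentence gets one of four labels —
   *neutral*, *semiology* (signs and symptoms), *epidemiology* (statistics,
   prevalence, risk factors), *management* (treatment, prevention,
   diagnosis). Non-neutral sentences are the claims; the label also scopes
   the later comparison so that, say, a prevalence figure is only checked
   against epidemiological statements.
2. **Query generation.** For each non-neutral category of the page, MeSH
   descriptors and keyphrases are extracted from the category's text and
   assembled into a boolean PubMed query:

   ```
   (  (m11 OR m12 ...) AND (m21 OR ...) AND ...   # MeSH terms, OR-ed within
                                                  # a tree category, AND-ed across
   ) OR ( k1 AND k2 AND ... )                     # keyphrases
   ```

   where the MeSH grouping follows the leading letter of each descriptor's
   tree number.
3. **Retrieval.** The query runs against PubMed (NCBI E-utilities, filtered
   to free full text and systematic reviews / meta-analyses) or against an
   offline JSONL fixture store; the top 20 articles are kept and their text
   segmented into sentences, which the *same* classifier then categorizes.
4. **Similarity matching.** Sentences are embedded and compared with cosine
   similarity (or token-set Jaccard) within each thematic category. A web
   sentence with at least one literature sentence scoring ≥ 0.87 counts as
   *credible*; the page report gives the credible fraction and, per credible
   sentence, its best evidence sentence with a PubMed link.

For a sentence pair with embeddings u, v the score is cos(u,v) = u·v/(‖u‖‖v‖);
Jaccard is |A∩B|/|A∪B| over lowercased token sets. Annotation agreement is
measured with Cohen's κ = (p₀ − pₑ)/(1 − pₑ).

Every model-backed step has a deterministic backend that ships with the
package and runs offline: a per-class term-frequency keyword classifier and
a ridge-penalised multinomial logistic classifier (hashed bag-of-words
features), a dictionary MeSH matcher over a packaged mini-vocabulary, a
term-frequency keyphrase ranker, and a 256-dimensional signed
feature-hashing sentence embedder. Transformer encoders can be plugged in
as function backends where they are available.

## Worked example

Entirely offline: a synthetic template corpus trains the classifier, and a
generated article store with planted evidence stands in for PubMed.

```r
library(medfactcheck)

corpus <- generate_labeled_corpus(generator_spec(n_per_class = 100, seed = 7))
model  <- train_classifier(corpus, classifier_config(backend = "keyword"))

st   <- generate_article_store(generator_spec(n_per_class = 6, seed = 2),
                               overlap_fraction = 0.5)
page <- new_document("demo-page",
                     text = paste(st$web$text[seq(1, 18, 2)], collapse = " "))

cfg <- pipeline_config(
  model     = model,
  retrieval = retrieval_config(mode = "fixture",
                               fixture_path = st$store_path),
  metric = "cosine", threshold = 0.87)
reports <- run_pipeline(list(page), cfg)
reports[["demo-page"]]
```

```
<page_report demo-page>
  categorized sentences: 9
  credible: 5 (56%)
  best evidence per credible sentence:
    demo-page-s1 -> pmid100001-s1 (score 1.0000) https://pubmed.ncbi.nlm.nih.gov/100001/
    demo-page-s2 -> pmid100001-s3 (score 1.0000) https://pubmed.ncbi.nlm.nih.gov/100001/
    demo-page-s3 -> pmid100001-s5 (score 1.0000) https://pubmed.ncbi.nlm.nih.gov/100001/
    demo-page-s4 -> pmid100002-s2 (score 1.0000) https://pubmed.ncbi.nlm.nih.gov/100002/
    demo-page-s5 -> pmid100002-s4 (score 1.0000) https://pubmed.ncbi.nlm.nih.gov/100002/
```

All 9 sentences of the page carried claims; the store was built so that
half the web sentences have a planted near-duplicate, and the matcher found
evidence for 5 of 9 (56%). Each credible sentence links to the article
sentence that supports it. `attr(reports, "queries")` holds the PubMed
query issued per page and category, e.g.

```
((Arthritis[MeSH Terms] OR "Arthritis, Rheumatoid"[MeSH Terms] OR ...
 OR "Pulmonary Disease, Chronic Obstructive"[MeSH Terms]) AND Pain[MeSH Terms])
OR ("breath severe fatigue" AND "chronic obstructive pulmonary" AND ...)
```

A thin command-line wrapper lives at `inst/scripts/factcheck.R`
(`Rscript factcheck.R --input pages.jsonl --store articles.jsonl ...`).

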