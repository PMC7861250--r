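---
title: "Pattern-based extraction of tumor entities from Chinese radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pattern-based extraction of tumor entities from Chinese radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(onconer)
library(dplyr)
```

## The extraction problem

Chinese diagnostic-imaging conclusions are short, formulaic free-text
documents. For oncology reporting three entity classes matter: the **primary
tumor site** (the organ of cancer origin — the first anatomic site associated
with a malignancy description and not with metastasis), the **primary tumor
size** (measurement expressions such as `1.3CM × 1.7CM`), and the
**metastatic sites** (anatomic positions co-occurring with 转移 "metastasis"
and its variants). Annotated corpora in this domain are small — hundreds of
reports — which makes heavily parameterized sequence labelers hard to train
and favors a pattern-based pipeline that encodes the discourse regularities
of radiology writing directly. `onconer` implements such a pipeline, plus the
entity-level weighted evaluation used to score it and a synthetic report
generator so that every stage is testable end to end without access to
restricted clinical data.

## The pipeline

All stages share three primitives:

* **Sentence decomposition.** Sentences split on 。；;！？ and newline, with
  the delimiter kept on the preceding sentence. Commas deliberately do *not*
  split: a measurement and its anatomic context routinely share a comma-joined
  clause (`...软组织密度灶,大小约1.3CM × 1.7CM,...`) and must stay in one
  sentence context. Spans are code-point offsets into the unmodified original
  text, and concatenating the sentences reconstructs the document exactly.
* **Dictionary segmentation.** A greedy longest-match tokenizer over the
  anatomy dictionary guarantees that every dictionary term in a sentence
  surfaces as one unbroken token (左肺门 wins over the nested 肺门). The
  contract — terms unbroken, token concatenation equals the input — is what
  matters; any segmenter honoring it can be substituted.
* **Width folding.** Full-width ASCII (１.３ＣＭ) folds to half-width before
  any matching, one code point to one code point, so spans remain valid in
  the original surface. Case is preserved; the Latin malignancy abbreviations
  MT/CA are matched case-insensitively.

### Primary sites

Sentences containing a malignancy indicator (癌, 恶性, 瘤, MT, CA) are kept;
those also containing a metastasis keyword are discarded, because a site
described as metastatic cannot be the primary. Anatomy mentions are matched
in the survivors and the first mention in document order is taken. Since 肺癌
only pins the organ, a refinement pass then scans the document for an anatomy
mention that is a *proper part* of the approximate site (左肺上叶 for 肺) and
substitutes the first one found. Part-of is string containment with two
guards: laterality spelling variants (左肺门 / 左侧肺门 — the same site) are
never parts of each other, and a part must have a strictly longer name, so
refinement can only move toward specificity. Refinement also skips
metastasis sentences by default (`skip_metastasis`), keeping the exclusion
consistent across the stage.

One site per report is returned by default; reports with two independent
primaries therefore lose the second one, a documented limitation that the
regression suite pins down. `multi_primary = TRUE` returns the first site of
every surviving indicator sentence instead, as a clearly-marked extension.

### Tumor sizes

Measurement expressions are highly regular, so the stage is grammar-driven:

1. **Detect** sentences matching the size grammar — 1–3 dimensions, each an
   integer or decimal with optional CM/MM unit in any case and width, joined
   by `×`, `X`, `x` or `*` with optional spaces, optionally preceded by the
   qualifiers 不足 ("less than") or 约 ("about"). A bare number with neither
   a second dimension nor a unit (a date, a count) is not a match and does
   not consume characters. DM is not accepted as a unit: no decimeter-scale
   lesion measurement occurs in this genre, and admitting it would let
   ordinary digits-plus-D strings through.
2. **Filter** to sentences related to the primary tumor: the sentence must
   contain a laterality variant of a primary site (左肺门 matches 左侧肺门 —
   the only rewriting applied; no fuzzy matching) or be the primary mention's
   own sentence. Among survivors, sentences carrying a density indicator
   (高密度影, 低密度影, 不规则团块, ...) rank first, since such wording
   correlates with lesion-size statements. With no primary site the stage
   returns nothing: size extraction is defined relative to a primary.
3. **Extract** all leftmost-longest non-overlapping grammar matches from the
   survivors. Matching is deterministic; ties are impossible under the
   grammar.

Normalization renders `v1UNITxv2UNIT...` with a lowercase `x` and uppercase
units; under the default `propagate` policy a trailing unit fills unit-less
dimensions to its left (`5x4x3CM` → `5CMx4CMx3CM`), values stay exactly as
written (`2.0` is not rewritten to `2`). Deduplication keys on this
normalized form. Parsing, normalizing and re-parsing is a fixed point, and an
independent brute-force scanner (every substring, anchored full-match,
leftmost-longest assembly) agrees with the production matcher on generated
strings — both properties are in the test suite.

### Metastatic sites

Sentences containing a metastasis keyword are the key sentences. Within
each, the extractor collects maximal anatomy-bearing phrases: contiguous
token runs of anatomy terms, descriptor terms, conjunction tokens (、 及 与)
and the locative characters 内/部/旁, trimmed to end at the last anatomy
token; any other character terminates a run. Each phrase is then
descriptor-stripped (纵隔内多发肿大淋巴结 → 纵隔内淋巴结; longest descriptor
first, iterated to a fixed point so stripping is idempotent) and
coordination-completed: 肺门及前纵隔淋巴结 splits into 肺门 and 前纵隔淋巴结,
the elided head 淋巴结 is identified as the longest anatomy term that is a
*proper* suffix of the last conjunct, and appended to every conjunct not
already carrying it. When the last conjunct is itself a complete site name
(肝、骨 — nothing elided) no suffix is appended; the literal trailing-token
fallback would otherwise manufacture 肝骨. Deduplication folds laterality
variants.

Two deliberate behaviors: compound phrases *without* conjunctions
(右肺门纵隔多发肿大淋巴结) are emitted un-split — the surface text does not
carry the information needed to divide them, and the regression suite pins
the un-split output. And the default `substring` negation policy treats
double negatives (转移不除外, "metastasis not excluded") as positive
mentions, which is the clinically correct reading; a `drop-negated` policy is
available that discards simply negated sentences (未见/无 ... 转移), a
behavior some corpora may prefer but which is not the default.

## Evaluation

Scoring is entity-level under exact matching of normalized strings with set
semantics. Per document, TP = |pred ∩ gold|, FP = |pred \\ gold|,
FN = |gold \\ pred|; counts pool over documents (micro average — the
convention for entity-level scoring; macro is a flag) and

$$P = \frac{TP}{TP+FP},\qquad R = \frac{TP}{TP+FN},\qquad
F_1 = \frac{2PR}{P+R}.$$

Boundary conventions: an empty denominator yields 0, and when prediction and
gold are empty for every document all three metrics are 1 (vacuous
perfection). True negatives are never computed — extraction has no closed
universe of negatives and the formulas never use them.

The **weighted overall** score combines the three tasks with weights 0.2
(primary site), 0.3 (size) and 0.5 (metastatic site). Two inequivalent
aggregations are defensible and both are implemented: `metric` mode (the
default) takes the weight-dot-product of the per-task metrics, and `count`
mode weight-scales the TP/FP/FN counts before applying the formulas. The two
disagree whenever task difficulty differs, and published overall rows in this
task family are not always consistent with either; making the mode explicit
is the honest resolution.

The **robustness experiment** draws, for each subsample size, `repeats`
uniform random document subsets, scores the weighted overall on each and
reports mean ± sd per metric. At the full corpus size every draw is the
whole corpus, so sd is exactly 0 — a useful self-check that the suite
asserts. `autoplot()` renders the curve.

```{r robustness, fig.width = 6, fig.height = 3.5}
corp <- generate_corpus(generator_config(n_docs = 100, seed = 42))
pred <- extract_entities(corp$documents)
curve <- robustness_curve(pred, corp$gold, sizes = seq(20, 100, 20),
                          repeats = 10, seed = 1)
autoplot(curve)
```

## The synthetic generator

Restricted clinical corpora cannot ship with a package, so the generator
emulates the *structure* the rules depend on: multi-sentence reports (5–25
sentences, matching reported corpus means of roughly 14–25 per text) holding
one primary clause (directly specific, or an approximate organ clause plus a
later finer sentence so refinement is exercised), a size clause in 60% of
reports (matching a reported 0.60 size entities per text) that pairs a
grammar-sampled measurement with a density indicator and a laterality
variant of the primary site, metastasis clauses totalling 0–5 gold entities
(mean 2.5, against a reported 2.46 per text) with descriptor padding and
coordinated lymph-node lists, and neutral filler sentences. Sentence shapes
live in a packaged TSV template file, not in code, so users can extend them.

Adversarial switches, all defaulting to 0, inject the documented hard cases
and tag the affected documents: `compound` (conjunction-free compound
phrases whose gold lists the true split sites the extractor is expected to
miss), `double_negation` (转移不除外 clauses — recoverable under the default
policy), and `unknown_anatomy` (sites absent from the dictionary, yielding
pure misses). Gold always records the *true* entities; for in-grammar
documents those coincide with what the rules return, which is what the
recall = precision = 1 end-to-end assertion checks.

What passing on synthetic text does **not** show: real reports contain
abbreviations (T4胸椎), compound anatomic phrases, out-of-dictionary sites,
typos and idiosyncratic phrasing at rates the generator does not model.
In-grammar perfection validates the machinery, not clinical performance;
dictionary coverage in particular is a data concern — the shipped ~150-term
anatomy lexicon is a seed, and the loader accepts a replacement TSV.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| task weights | 0.2 / 0.3 / 0.5 | standard weighting for this task family; must sum to 1 |
| `average` | micro | convention for entity-level P/R/F1; macro by flag |
| `mode` | metric | see aggregation discussion above |
| `negation_policy` | substring | double negatives are positive mentions |
| `multi_primary` | FALSE | one primary per report; TRUE is an extension |
| unit policy | propagate | trailing unit fills unit-less dimensions |
| variant expansion | on | applied when matching sites into size sentences and when deduplicating metastatic sites |
| sentence delimiters | 。；;！？ + newline | commas never split (see above) |

## Numerical and design choices

* Descriptor stripping is plain longest-first removal; a surface that is
  itself a dictionary anatomy term is protected from stripping (小脑 is not
  reduced to 脑), but descriptor characters inside undictionaried anatomy can
  still be removed — a known sharp edge inherited from string-level rules.
* The tie-break for several candidate sites in one malignancy sentence is
  leftmost; for several surviving sentences, first in document order.
* Degenerate inputs are defined, not errors: empty text → no sentences; no
  malignancy indicator → no primary; no primary → no sizes; `n_docs = 0` →
  empty corpus.
* Determinism throughout: extraction has no randomness; generation and
  subsampling are seeded and leave the global RNG untouched.
* Test problem sizes: unit fixtures are single sentences; end-to-end checks
  use 200-document corpora, the distributional check of the generator 600,
  chosen to mirror the train/test sizes typical of this task while keeping
  the suite quick.

## Limitations

Beyond the tagged adversarial cases: no abbreviation resolution, no
ontology-based normalization (UMLS/MeSH), no splitting of compound anatomic
phrases lacking conjunctions, no certainty grading (考虑转移 and 转移 are
treated identically), no cross-document inference, and long compound site
names are truncated to their longest dictionary suffix (胸下段食管 → 食管)
unless the dictionary is extended — which is the intended fix.
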