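---
title: "Aspect-level sentiment analysis for diabetes tweets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aspect-level sentiment analysis for diabetes tweets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspectsent)
```

## The problem and the model

A tweet about living with diabetes rarely carries one opinion. "Glucose
tablets might be a better option than a sugary food" is positive about
glucose tablets and lukewarm about sugary food; a document-level classifier
collapses that distinction. `aspectsent` assigns a polarity to each *aspect*
— each mention of a domain concept such as a drug, symptom, complication or
laboratory test — rather than to the whole message.

The method is lexicon-based (a semantic-orientation approach, not a trained
classifier). For an aspect mention $a_i$ and the set $w_{f_i}$ of words
selected near it, the aggregate scores are plain sums of the per-word prior
polarities from a SentiWordNet-style lexicon:

$$\mathrm{ScorePos}(a_i) = \sum_{w \in w_{f_i}} \mathrm{ScorePos}_{SWN}(w),$$

and likewise for $\mathrm{ScoreNeg}$ and $\mathrm{ScoreNeu}$. The aspect is
labelled **positive** when $\mathrm{ScorePos}$ strictly exceeds both other
aggregates, **negative** and **neutral** symmetrically. The three strict
inequalities leave ties undefined; we close the rule by mapping every tie —
including the empty window, whose sums are all zero — to *neutral*. That is
the conservative choice: a tie is exactly the situation in which the lexicon
offers no directional evidence.

Words that cannot be looked up (no mappable POS category, or absent from the
lexicon) contribute $(0, 0, 0)$, not a neutral prior of $(1/3, 1/3, 1/3)$:
the sums above range only over lexicon-returned scores, so an unknown word
should not manufacture neutral mass that could outvote a genuinely polar
neighbour.

## Pipeline stages and the choices inside them

### Preprocessing

Normalization removes whole `@`-mention tokens (removing only the `@` would
leave usernames behind as noise words), removes URL tokens — `http://`,
`https://` and bare `t.co/` shorteners, since modern tweets overwhelmingly
use https — and strips the `#` of hashtags while keeping the body, which is
often a content word ("#diabetes"). CamelCase hashtag bodies are kept as
single tokens; splitting them is a known limitation. Abbreviations are then
expanded token-wise and case-insensitively from two dictionaries (domain
jargon first, then SMS shorthand, longest key first), and only afterwards
are remaining words offered to the spell corrector. The order matters:
expanding first protects domain shorthand like "Hypo" (hypoglycemia) from
being "corrected" into an unrelated English word. The corrector itself is an
interface; the default does nothing, and the bundled dictionary corrector is
deterministic (minimal edit distance, cap 1, lexicographically first
suggestion), so no external spell-check engine is required or bundled.

Every normalization edit is logged with its offset, original and
replacement; replaying the log over the raw text reproduces the normalized
text exactly, which is what makes the stage auditable and testable.

Tokenization, sentence splitting (a sentence ends at a free-standing `.`,
`!` or `?`), Penn-Treebank POS tagging and lemmatization run behind a
pluggable backend contract. The default backend is a deterministic
rule-and-lexicon tagger written for this package: a closed-class lexicon,
a small open-class override list, suffix rules (`-ly` adverbs, `-ing`/`-ed`
verbs, adjectival suffixes, plural `-s`), and noun as the default category.
It is context-free, so it cannot disambiguate noun/verb homographs the way
a statistical tagger would; it is, however, byte-for-byte reproducible and
covers the tag inventory the scorer consumes (only `NN*`, `VB*`, `JJ*` and
`RB*` reach the lexicon). Any richer tagger can be supplied through the same
`list(name, tag)` contract.

### Aspect detection

The gazetteer maps lemmatized term sequences to concept identifiers. The
canonical source is a flat `concept_id <TAB> term` file;
`owl_to_gazetteer()` flattens an OWL ontology's `rdfs:label`s plus any
annotation property whose local name contains "synonym" into that format, so
the runtime pipeline never needs an OWL parser. Everything else in the
ontology — axioms, hierarchy, object properties — is deliberately ignored:
the method uses the ontology purely as a term source, and detection is flat.

Matching is on lemma sequences, not surfaces, so "glucose tablets" finds a
"glucose tablet" term: lemmatization exists in the pipeline precisely to
make that possible. Whether to match on surface or lemma was an open call;
lemma was chosen and is exercised throughout the tests. Overlaps resolve
leftmost-longest (ties on length to the smaller start), matches never
overlap, and matching is tweet-wide rather than per-sentence (windows may
also cross sentence boundaries — the unit of context is the tweet). A term
claimed by two concepts resolves to the lexicographically smallest concept
id, with a build warning.

### Context windows

`before`, `after` and `around` select up to $N$ word tokens on the
respective side(s) of the mention; `around` is always the disjoint union of
the other two, an identity the tests assert exactly. Windows are counted in
word tokens and punctuation is skipped *without* consuming a slot — a comma
adjacent to an aspect should not cost a context word. Tokens of a
neighbouring aspect count as ordinary context. The supported API accepts any
$N \ge 1$; the pipeline's conventional range is 2–6, and 3 is the default
because both-side context at width three is the configuration the approach
is known to do best with.

### Scoring and sense selection

The lexicon parser accepts the standard SentiWordNet 3.0 tab-separated
format and recomputes the neutral score as $1 - \mathrm{pos} -
\mathrm{neg}$ on every line rather than trusting a stored column, enforcing
the sum-to-one contract at the boundary (a line whose positive and negative
scores already exceed 1 is rejected with its line number). A lemma can have
many senses; sense choice is a pluggable strategy. The default is the
most-frequent-sense baseline (smallest sense rank, ties to the smaller
synset id), which is deterministic and needs no network service; an adapter
for an external word-sense-disambiguation service can be plugged in through
the same interface. Lookup is by lemma and mapped POS category only —
no surface-form fallback.

### Evaluation

Identification and polarity are scored with precision, recall and F-measure
(harmonic mean), reported as percentages; zero denominators yield 0 with a
warning instead of NaN so sweep grids never crash. Span matching is
configurable: `exact` (identical token span, the default) or `overlap`
(at least one shared token, greedy leftmost one-to-one). Polarity metrics
are computed one-vs-rest per class over the identification-matched aspects;
the *macro* average is the unweighted mean over the classes present in gold
or predictions — so a perfect prediction scores 100 on any corpus — and
*micro* pools counts (for single-label decisions micro P = R = F =
accuracy). Both are always reported, and macro is the default headline:
with per-class averaging the aggregate F is generally *not* the harmonic
mean of the aggregate P and R, which is worth knowing when comparing
reports. Neither the matching criterion nor the averaging is baked in,
because published evaluations frequently leave both unstated.

## The synthetic corpus generator

Real annotated health-tweet corpora are not redistributable, so the package
carries a seeded generator that emulates the statistical structure the
method relies on: polar words concentrated near aspect terms. Each
generated tweet embeds one gazetteer term (single- or two-word), flanked on
each side by 1–3 words drawn from the gold label's polarity vocabulary,
padded with out-of-lexicon filler, optionally decorated with a mention,
URL, hashtag or abbreviation to exercise preprocessing, and optionally
followed by a near-miss decoy phrase absent from the gazetteer. Generated
vocabulary is nonsense syllabograms whose endings avoid every suffix the
default tagger treats specially, so each word is tagged `NN` with itself as
lemma and the lexicon lookup path is fully under the generator's control.

Label planting is margin-based rather than score-targeted: positive words
carry triples like $(0.75, 0, 0.25)$, so any nonempty same-polarity context
leaves the top aggregate at least 0.1 clear of the runner-up and the strict
inequalities decide correctly. Consequently a noiseless corpus is recovered
at exactly 100% macro P/R/F by `around`/$N{=}3$ — that is a designed
parameter-recovery property, not an empirical finding. The `noise`
parameter replaces planted polar words with out-of-lexicon filler (gold
unchanged), degrading recovery monotonically in expectation; `decoys`
plant near-miss phrases that must *not* be detected. A fraction of polar
words receives a second, neutral, higher-rank sense so the
most-frequent-sense fallback is exercised on every run.

Defaults are the corpus conditions the pipeline targets: 900 tweets, one
annotated aspect each, balanced labels, context width 1–3 per side, no
noise or decoys. The generator does **not** attempt realistic Twitter
language (burstiness, code-switching, emoji); passing tests on synthetic
corpora demonstrates the pipeline's contracts — detection, windowing,
aggregation, evaluation — not performance on real tweets, which depends on
the quality of the real ontology, lexicon and tagger supplied.

Everything is drawn from a single RNG stream under the configured seed and
the seed is recorded in the manifest; regeneration is byte-identical.

## Numerical and degenerate-input conventions

* Token indices and character offsets are 0-based; spans are half-open.
* Percentages are kept at full precision internally and rounded only for
  display. Note that the harmonic mean of *rounded* P and R can differ from
  the F computed from raw counts by a hundredth.
* Empty tweet, empty window, empty gazetteer scan: all return empty
  structures or zero triples, never errors. Zero *extractable terms* when
  building a gazetteer or lexicon is an error, since the pipeline cannot do
  anything meaningful without them.
* Lexicon sense triples must sum to 1 within $10^{-9}$; aggregates over
  windows are unbounded above.

## Problem sizes used in the tests

The shipped test-suite and acceptance runs use corpora of 25–300 tweets and
20-seed replicates for the stochastic degradation checks; these sizes give
the properties under test no room to pass by accident while keeping a full
run comfortable on a single CPU. The generator reaches the default
900-tweet scale in the same code path.

## Known limitations

* The default tagger is context-free; noun/verb homographs default to noun.
  Swap in a statistical backend for real corpora.
* Hashtag bodies are not case-split; negation and intensifiers are not
  modelled; emoji are ignored.
* The Turtle reader covers the label/synonym subset of the syntax (prefix
  declarations, `;`/`,` continuation, plain and tagged literals), not blank
  nodes or multi-line literals; RDF/XML input has no such restriction.
* Aggregate scores are raw sums, not length-normalized, so larger windows
  can only accumulate evidence, never dilute it.
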