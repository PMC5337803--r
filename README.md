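# aspectsent

Aspect-level sentiment analysis for short health-related social-media texts,
built around the diabetes domain. Instead of labelling a whole tweet
positive or negative, `aspectsent` finds each mention of a domain *aspect*
(a drug, symptom, complication, lab test, ...) via an ontology-derived
gazetteer and assigns a polarity to that mention from the words around it.

The package is for text-mining researchers and health-informatics
practitioners who need a fully offline, deterministic, testable
implementation of the lexicon-based (semantic-orientation) approach:
no web services, no pretrained models, no downloads required to run or test.

## The method

For each aspect mention $a_i$, a context word set $w_{f_i}$ is selected by
one of three proximity methods — the $N$ words before the mention, the $N$
words after it, or both sides (*around*), with $N$ conventionally 2–6.
Each context word $w$ contributes its prior-polarity triple from a
SentiWordNet-style lexicon (one sense per word, chosen by a pluggable
selector whose default is the most-frequent-sense baseline), and the
aggregates are plain sums:

```
ScorePos(a_i) = Σ_{w ∈ wf_i} ScorePosSWN(w)      (likewise Neg, Neu)
```

The mention is **positive** if `ScorePos` strictly exceeds both other
aggregates, **negative** or **neutral** symmetrically; ties (including the
empty window) are neutral. Evaluation reports span-level precision, recall
and F-measure (harmonic mean) for aspect identification, and macro/micro
averaged P/R/F for 3-class polarity, over a `method × N` sweep grid.

A seeded synthetic-corpus generator produces miniature tweets, gold
annotations, a lexicon and a gazetteer with known structure (polar words
planted around aspects with a guaranteed decision margin), so the entire
pipeline is verifiable end to end without any external corpus.

## Worked example

```r
library(aspectsent)
d   <- system.file("extdata", package = "aspectsent")
gaz <- build_gazetteer(file.path(d, "gazetteer-fixture.tsv"))
lex <- load_lexicon(file.path(d, "swn-fixture.txt"))

tw <- preprocess_tweet("t1", paste(
  "When people with diabetes experience a dangerous drop in blood sugar ,",
  "glucose tablets might be a better option than a sugary food or drink"))
mentions <- detect_aspects(tw, gaz)
mentions
#>   tweet_id start end concept_id         surface sentence_index
#> 1       t1     3   4   DDO:0001        diabetes              0
#> 2       t1     9  11   DDO:0002     blood sugar              0
#> 3       t1    12  14   DDO:0003 glucose tablets              0

for (i in seq_len(nrow(mentions))) {
  w <- extract_window(tw, mentions[i, ], method = "around", n = 4)
  print(score_aspect(w, tw, lex))
}
#> <aspect_sentiment t1 [3,4) around n=4> pos=0.000 neg=1.125 neu=0.875 -> negative
#> <aspect_sentiment t1 [9,11) around n=4> pos=0.000 neg=1.125 neu=0.875 -> negative
#> <aspect_sentiment t1 [12,14) around n=4> pos=0.875 neg=0.500 neu=0.625 -> positive
```

Reading the output: the gazetteer finds three aspects by lemma matching
("glucose tablets" matches the term "glucose tablet"; spans are 0-based,
half-open token ranges). For *blood sugar*, the window words "dangerous"
(0, 0.625, 0.375) and "drop" (0, 0.5, 0.5) sum to (0, 1.125, 0.875), and
negative strictly dominates, so the aspect is negative. For *glucose
tablets*, "better" (0.875, 0, 0.125) outweighs "drop", so the aspect is
positive — the message is negative about the glycemic drop yet positive
about the tablets, which is exactly the distinction aspect-level analysis
exists to make.

Abbreviation expansion, mention/URL/hashtag stripping and the rest of the
normalization stage are exercised the same way:

```r
dom <- read_abbreviations(file.path(d, "abbrev-diabetes.tsv"), source = "domain")
normalize_tweet("@user1 my carbs spiked http://t.co/xyz #diabetes",
                dicts = list(dom))$text
#> [1] "my carbohydrates spiked diabetes"
```

## Command line

A thin CLI over the same functions is installed as `exec/aspectsent`:

```sh
aspectsent preprocess --in tweets.jsonl --abbrev sms.tsv --abbrev diabetes.tsv --out tokens.jsonl
aspectsent owl2gazetteer --in ddo.owl --out gaz.tsv
aspectsent annotate --in tweets.jsonl --gazetteer gaz.tsv --lexicon swn.txt \
                    --method around --n 3 --out aspects.jsonl
aspectsent evaluate --pred aspects.jsonl --gold gold.jsonl
aspectsent sweep --in tweets.jsonl --gold gold.jsonl --lexicon swn.txt --gazetteer gaz.tsv
aspectsent simulate --seed 42 --n-tweets 100 --out-dir fixtures/
```

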