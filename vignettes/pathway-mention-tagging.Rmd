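---
title: "Recognizing named pathway mentions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing named pathway mentions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtag)
```

## The task

A *named pathway mention* is a text span that refers to a biological pathway
by name — "MAPK signalling pathway", "Calcium signalling", "RNA
degradation" — rather than describing its molecular constituents. Two
properties make the task awkward for the two obvious approaches. Exact
dictionary lookup fails on routine name variation: stop-word insertion and
deletion, permutation through prepositions ("p53 signalling pathway" vs
"signalling pathway of p53"), spelling variants ("signalling"/"signaling")
and alternative keywords ("MAPK pathway" vs "MAPK signalling pathway").
Purely lexical keyword spotting fails on ambiguity: "the diagnostic pathway"
contains the strongest pathway keyword and is not a biological pathway,
while many genuine pathway names ("RNA degradation") contain no keyword at
all. `pathtag` therefore combines two complementary detectors and merges
their output.

## Soft dictionary matching

### The SoftTFIDF score

Both a candidate text window and a dictionary name are treated as bags of
lowercased tokens. Each bag is weighted by TFIDF over the dictionary: with
`N` entries and `df_w` the number of entries containing token `w`, the raw
weight is `log(TF_w + 1) * log(N / df_w)`, scaled to unit Euclidean norm.
Unseen tokens receive a smoothed document frequency `df_floor = 1`, which
keeps rare-token weights high without infinities. For each query token `w`
the best Jaro-Winkler partner `v*(w)` in the name is found; pairs at or
above the inner threshold `θ_jw = 0.9` contribute
`V_S(w) · V_T(v*(w)) · JW(w, v*(w))`, and the sum is clamped to `[0, 1]`
(several query tokens may map onto one name token). The TFIDF form and the
Jaro-Winkler constants (prefix scale 0.1, prefix cap 4, inner threshold
0.9) follow the established string-metric toolkit conventions for this
hybrid; all are configurable through `metric_config()`.

Two details are fixed for determinism. Ties for `v*(w)` are broken toward
the larger name-side weight, then lexicographically. Comparison is on
lowercased tokens, consistent with dictionary indexing; original casing is
preserved in all reported surfaces.

This construction is exactly why the score absorbs the variation typology:
an inserted stop-word appears in many dictionary names, so its weight is
small and the score stays high; a permuted name is the same bag; a spelling
variant is caught by the character-level inner metric; a swapped keyword
("cascade" for "pathway") loses only the small weight such ubiquitous
keywords carry. By the same mechanism the score is honest about its
weaknesses: inserting a word the dictionary has *never* seen carries a large
smoothed weight and can push a long name below threshold.

### Scanning documents

Scoring every window against every entry is unnecessary. A token is a
*start point* only if a single-token lookup at the lower threshold (0.40)
returns anything; from each start point, windows of length 1 to 25 tokens
are scored, a run of more than four consecutive empty lengths aborts the
check, and the longest window reaching the upper threshold (0.90) becomes
one annotation with that score and entry id. The dual thresholds trade
speed and recall (lower) against precision and recall (upper) and are
exposed in `matcher_config()`. Candidate entries are restricted through an
inverted token index extended with Jaro-Winkler-close vocabulary tokens;
because an entry with no close token pair scores zero, the restriction is
exact, and the test suite verifies equality with brute-force scoring of
every entry.

Three boundary decisions were open and are fixed as follows. Windows are
anchored at the start point and extend rightward only. Windows never cross
sentence boundaries — pathway names do not span sentences. Windows also stop
at separator tokens (comma, period, semicolon, colon): without this, a long
rare-token name followed by a clause separator can keep a swallowed
separator above the upper threshold under the longest-match rule. Overlaps
from different start points are resolved by score, then span length, then
leftmost position.

Two consequences are worth knowing. First, a dictionary name headed by a
very rare token (a gene symbol) can match on that token alone with a score
just below 1 — useful for lenient recall on permuted mentions, and a genuine
source of the soft matcher's precision limits. Second, a name whose *first*
token is common across the dictionary (e.g. "Metabolism of …") may fall
under the lower threshold at its start point and be missed entirely; real
dictionaries mitigate this by also containing short entries that keep such
tokens informative, and the synthetic dictionary mirrors that structure
(see below).

## Rule-based recognition

Keyword anchors are found token-wise and case-insensitively; multi-token
combinations ("signal transduction pathway") win over their parts at a
position, and consumed tokens are not rematched. The base set covers
"pathway", "signalling"/"signaling", "transduction", "cascade" and
"network" with plural forms; the combination list is generated from
spelling × head-noun products plus "signal transduction" forms, and both
are user-extensible — the phenomenon is open-ended.

From each anchor, the backward rule scans left and stops at the first
determiner, separator, clausal preposition/subordinating conjunction,
wh-word or verb (Penn tags DT/PDT, the four separator punctuations, IN,
WDT/WP/WP$/WRB, VB\*), i.e. at tokens that cannot occur inside a pathway
name. One preposition is deliberately exempt: "of" is noun-phrase-internal
and ubiquitous *inside* pathway names ("Activation of the Rac signalling
pathway", "mammalian target of rapamycin (mTOR) signalling pathways"), so
stopping at it would truncate exactly the complex coordinated mentions the
rules exist to capture; the transparent set defaults to `{"of"}` and is
configurable. The forward rule extends the segment through pathway verb
phrases ("induced by", "regulated by", "mediated through", …) up to the
first punctuation token.

A segment becomes a mention only if a gene/protein mention lies *fully
inside* it — this gate is what separates "the p53 signalling pathway" from
"the diagnostic pathway". Gene recognition is an interface: any function
from a document to gene-mention annotations, or precomputed standoff
annotations imported from an external tagger. The bundled recognizer is
deterministic — case-sensitive token-sequence lookup in a synthetic lexicon
plus a morphology heuristic (tokens mixing uppercase letters and digits,
length ≥ 2, stop-listed words excluded) — chosen for reproducibility: no
model downloads, identical output everywhere. It is a stand-in with the
obvious limits of lexicon lookup (no context, no disambiguation), which is
why the interface accepts real taggers.

Part-of-speech tags come from the same philosophy: the default backend is a
rule tagger over closed-class lexicons with generated verb inflections and
noun-biased defaults ("signalling" is never a verb), sufficient for the
five stop classes the rules consume; any Penn-Treebank tagger can be
plugged in via `pos_tag(doc, backend = fun)`.

Tokenization splits on every non-alphanumeric character, so slash chains
("ras/raf/MAPK") and hyphenated forms ("Wnt-signalling") expose their parts
to keyword anchoring and gene lookup. Offsets are 0-based, half-open,
counted in Unicode code points everywhere.

## Merging and evaluation

Mentions found by only one component pass through; overlapping annotations
are replaced by one annotation covering the group. Overlap grouping is
closed transitively (a chain a–b–c merges into one span) over the union of
both input sets: the rule engine may legitimately emit overlapping segments
from adjacent anchors, and transitive closure is the only policy that
guarantees a pairwise non-overlapping final set. A merged annotation keeps
the maximum member score and the dictionary id when exactly one distinct id
is present.

Evaluation counts TP/FP/FN with `P = TP/(TP+FP)`, `R = TP/(TP+FN)`,
`F1 = 2PR/(P+R)`, all defined as 0 on empty denominators. Strict matching
requires identical spans; lenient matching pairs predictions in offset
order with the first unmatched overlapping gold span. Lenient pairing is
deliberately one-to-one: a single prediction overlapping two gold mentions
counts once, preventing double-counting inflation. Gold corpora are read
from inline XML (annotation elements embedded in the text; the element name
marking a pathway mention is a config value, since label conventions vary
between corpora) or from standoff `.txt`/`.ann` pairs. "Unique" mentions in
corpus summaries are exact case-sensitive surface strings, with a
case-insensitive option.

## The synthetic data generator

The generator defines the study conditions under which the pipeline is
tested; it is deliberately a pure function of (dictionary, configuration,
seed).

`synthetic_dictionary()` (default 250 entries) emulates the lexical
composition of public pathway databases: gene-headed signalling names
("<GENE> signalling pathway/network", "<GENE> pathway/cascade"),
regulation/activation phrasings ("Regulation of <process> by <GENE>",
"Activation of the <GENE> cascade") that give "of", "the" and "by"
realistic document frequencies, short "<modifier> activation/regulation"
entries of the kind process-oriented databases curate, metabolic names
("<compound> metabolism/biosynthesis/degradation") and keyword-free process
names ("Apoptosis"). The proportions matter: they keep every template's
leading token informative enough to pass the start-point threshold (the
weakest, "Activation"/"Regulation", sit near 0.44 against the 0.40
threshold), which is precisely the property real dictionaries need for this
scanning strategy to achieve full recall on verbatim names. Gene symbols
are generated three-consonant + digit strings, disjoint from the symbols
used in carrier sentences, so corpus text never contains a dictionary gene
outside an embedded name.

`generate_synthetic_corpus()` embeds one (possibly perturbed) dictionary
name per non-distractor sentence in carrier templates whose content words
are disjoint from dictionary vocabulary and whose mentions are followed by
punctuation, records exact gold spans and a per-sentence manifest, and
packs sentences into documents of ten. Perturbations apply independently
per mention: stop-word insertion at an interior position (drawn from a
shipped standard English closed-class list), stop-word deletion,
permutation into prepositional form, keyword swap among
pathway/cascade/network, and spelling swap. Distractor sentences carry a
pathway keyword but no pathway and no gene ("The diagnostic pathway was
followed…"). Switches select rule-only mentions (keyword + gene names
absent from the dictionary), keyword-free dictionary mentions, carrier gene
symbols, and sampling without replacement — these isolate each component
for the union-effect and gating analyses.

What passing on this corpus does *not* show: robustness to real abstracts'
tokenization noise, to trained-tagger gene errors, to dictionary coverage
gaps, or to nested/discontinuous mentions; absolute benchmark numbers on
published gold corpora additionally depend on the original dictionary,
preprocessing stack and gene tagger and are out of scope here — the
evaluation machinery produces the same-shaped tables when such corpora are
supplied.

## Numerical choices and degenerate inputs

* Jaro similarity is 0 when either string is empty (including both empty);
  `jaro(s, s) = 1` for non-empty `s`. The Winkler boost
  `J + ℓ·p·(1−J)` is applied unconditionally with `p ≤ 0.25`, so values
  stay in `[0, 1]`.
* A token bag whose raw TFIDF weights are all zero (every token in every
  entry) has an all-zero weight vector and similarity 0 to everything —
  single-entry dictionaries are degenerate for TFIDF (`log N = 0`).
* "More than four consecutive empty window lengths" aborts a check on the
  fifth consecutive empty lookup (`miss_limit + 1`).
* Duplicate `(id, name)` dictionary lines collapse; variant expansion never
  removes the original entry; variants carry `parent_id` provenance and a
  `#v` suffix on their id, and annotations always report the parent id.
* Scale: the suite and the acceptance script run corpora of 200–500
  sentences against 250-entry dictionaries — sizes chosen so every
  distribution-level claim (recall comparisons, oracle agreement over
  thousands of random pairs) is measured on hundreds of events.

## Known limitations

Mentions whose names share no informative token with the dictionary are
invisible to the soft matcher, and keyword-free, gene-free names
("microglial activation") are invisible to the rules — the union narrows
but does not close this gap. The bundled gene stand-in under-recognizes
compared to trained taggers, which weakens rule recall on real text.
Acronym expansion linking ("T cell receptor (TCR) signalling") and
normalization of mentions to database entries are out of scope.
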