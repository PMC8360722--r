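---
title: "Methods: text-derived drug networks and overlapping core-drug communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: text-derived drug networks and overlapping core-drug communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cddf)
```

`cddf` infers core drugs of traditional Chinese medicine prescriptions from
unstructured literature. This vignette explains the model behind each stage,
the parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic benchmark does and does not
demonstrate.

## Corpus construction

The cleaning pipeline is `split_sentences()` → `retain_cjk()` →
`to_simplified()` → `segment_words()`.

A deliberate ordering choice: sentences are split on terminators
(`。！？!?；;` and newlines) **before** any non-CJK stripping. Stripping
first would delete the terminators and fuse unrelated sentences, and the
skip-gram objective downstream defines context windows that must not cross
sentence boundaries — so boundary information is preserved first, then each
span is reduced to the CJK range `[U+4E00, U+9FA5]` (both ends inclusive).

Segmentation is dictionary-based forward maximum matching (FMM): at each
position the longest lexicon word matching a prefix is taken, with a
single-character fallback. FMM is transparent, deterministic, and exactly
reproducible from a lexicon alone; it is deliberately pluggable (any
function producing token vectors can feed `new_corpus()`) so a statistical
segmenter can be substituted when higher accuracy matters more than
auditability. Concatenating the output tokens always reproduces the input
span — a property the test suite checks against a brute-force oracle.

Traditional→simplified conversion is a per-character table lookup. The
packaged table (`simplify_map_demo.tsv`, ~50 pairs) is a demonstration
fixture, not a complete font-conversion database; production use should
load a full mapping with `read_simplify_map()`.

`min_count` (default 1) removes rare tokens from the *vocabulary* only:
they stay in the sentences, where they still occupy window positions. This
matters — deleting them would silently shorten distances between their
neighbours and distort the context distribution.

## The subword embedding

Each character carries three code strings from the SSP2VEC code book:
stroke order (digits, e.g. 太 → `1344`), structure class (two digits,
opaque), and pinyin with an uppercase tone letter (`taiD`). A word's code
sequence is the per-character concatenation stroke+structure+pinyin in
word order with **no boundary markers**: 太阳 →
`134496taiD52251166yangB`. (The per-character codes are taken as
authoritative for 阳 — `522511`, consistent with its radical appearing as
the substring `52`.) Feature substrings are all sliding windows of length
`n_min` to `n_max` over that sequence; with the full range a sequence of
length *L* yields *L(L+1)/2* substrings.

Substrings are hashed into `B` buckets by 32-bit FNV-1a over their UTF-8
bytes. Hashing makes the parameter matrix a fixed size at the cost of
collisions, which subword embedding practice accepts; `B = 2^21` by
default, and much smaller values (2^15) are fine for small vocabularies.
The word representation is the **mean** of its substring-bucket rows.
Mean rather than sum keeps the representation's scale independent of word
length, so a fixed learning rate behaves uniformly across short and long
words; `aggregate = "sum"` is available for comparison.

Training is skip-gram: for each target position, every context word within
`window` (= *c*, default 2, truncated at sentence edges) is predicted from
the target representation. The output layer is a softmax over the
vocabulary; since exact softmax is intractable at scale it is optimised by
negative sampling (`negative = 5` draws from the unigram distribution
raised to 0.75), while the exact-softmax path (`negative = 0`) is retained
and its analytic gradient is verified against central finite differences
in the tests. Learning rate decays linearly from `alpha = 0.025` to
`alpha/10^4`. Words containing characters absent from the feature table
are not dropped — each gets a dedicated whole-word input row, because its
neighbours still need it as a context. With `buckets = 0` every word falls
back this way, which reproduces the continuous skip-gram baseline
(`mode = "csg"`) bitwise at equal seeds — a wiring check in the suite.

Two outputs exist per word; **the context-matrix rows are the semantic
vectors** used downstream (`output_vectors()`), with the input side
available via `side = "input"` for comparison experiments.

The reference implementation is single-threaded and bitwise-deterministic
given the seed (one `mt19937` stream drives initialisation and negative
sampling); there is intentionally no multi-worker mode, whose lock-free
updates would make runs irreproducible.

## Drug network

Drugs are the corpus∩thesaurus intersection after alias normalisation.
Pairwise similarity is cosine; the network has an edge wherever similarity
is **strictly** greater than `s`, stored as edge weight. Untrained or
all-zero vectors are defined to have similarity 0 to everything and so
become isolated nodes, which the community stage treats as singletons.

No principled value of `s` exists independent of the corpus; it is a
required parameter (default 0.5). Because context vectors of words trained
on a common corpus are often globally correlated, absolute thresholds
transfer poorly — `target_edges` instead scans the sorted similarity list
for the threshold whose edge count is closest to a budget, which is how
the synthetic benchmark pins its network density (3 edges per drug). The
pairwise computation is exact O(n²); drug vocabularies are hundreds of
names, so approximate nearest-neighbour search would add risk without
benefit.

## COPRA community detection

Each node starts with its own label at coefficient 1. One update pools the
neighbours' label maps (unit contributions per neighbour — edge weights do
not enter the pooling by default, matching the worked arithmetic of the
method's illustration; `weighted = TRUE` scales contributions by weight),
normalises coefficients to sum 1, deletes labels strictly below `1/r`, and
renormalises. The canonical six-neighbour example — labels yellow×3,
pink×2, green×1, `r = 2` — normalises to 3/6, 2/6, 1/6 and retains only
yellow. If *every* label falls below `1/r`, one maximal-coefficient label
is kept, chosen uniformly at random among ties, following the original
algorithm. Since surviving coefficients are ≥ 1/r and sum to 1, a node
holds at most `r` labels, which is exactly the overlap bound.

Sweeps are asynchronous (updates visible within a sweep) over a fresh
seeded random node order each sweep — the scheme under which label
propagation is known to behave well, and the one a node-at-a-time
narration implies. Termination is when no node's label *set* changes over
a full sweep; coefficient oscillation is tolerated. This is simpler than
the original minimum-label-count criterion (available as
`stop_rule = "counts"`) and, combined with `max_iter = 100`, terminates on
all graphs tried; non-convergence returns the current state with a
warning rather than failing.

Communities are labels' holder sets, so overlap falls out naturally: a
node with two surviving labels is a member of both communities.
Communities with more than `min_size = 3` members are flagged *major* for
reporting; all communities (including singletons from isolated nodes)
remain in the data and in the size distribution. An optional
post-processing step (`split = TRUE`) splits communities that are
disconnected in the induced subgraph; it is off by default since the
base algorithm does not prescribe it.

Core drugs are a community's top-10 members by degree **in the full
network**, not the community subgraph — the reason an overlapping drug
shows the same degree in both of its communities. Ties break by larger
summed incident edge weight, then C-locale lexicographic name, making the
ranking fully deterministic.

## Analytics

Closeness uses the Wasserman–Faust composition: with `R` the reachable set
of a node (excluded itself) and `n` the network size,
`(|R|/Σd) · (|R|/(n−1))`, and 0 for isolated nodes. Plain within-component
closeness is misleading on drug networks, which are typically
disconnected: a two-node component would score its members 1.0, above
every node of the giant component. The component-size scaling keeps
values in `[0, 1]` and comparable across components; the unscaled variant
remains available (`scaled = FALSE`). Degree and closeness are computed
once per node on the full network. Distributions are reported as
histograms: community sizes and degrees unbinned, closeness binned at
0.01.

## The synthetic benchmark

`gen_planted_corpus()` emulates the statistical structure the embedding
stage assumes: words with similar meanings occur in similar contexts. Each
sentence draws a group, samples 3 of its 8 drugs and interleaves them with
group-specific context words (`c1 d1 c2 d2 c3 d3 c4`), so that drugs of a
group share both their context distribution and window-mate drugs;
`noise_rate` replaces one drug per sentence with a cross-group drug at the
given probability. The companion `gen_feature_table()` gives same-group
characters a shared two-digit stroke prefix — a synthetic radical — so the
subword channel also carries group signal. Token names come from a
reserved CJK block (U+7A00 onward) that cannot collide with the packaged
real-character fixtures.

Defaults — 3 groups × 8 drugs × 10 contexts, 500 sentences, 3 drugs per
sentence, zero noise — are the validation conditions used by the test
suite and the acceptance script. The embedding runs at `dim = 16`,
`window = 2`, `epochs = 20`, `buckets = 2^15`; these sizes give a
sub-second training run while leaving the recovery task non-trivial
(54-word vocabulary, 24 drugs, ~11 000 pairs per epoch). The benchmark
network pins density at 3 edges per drug via `target_edges`, and recovery
is scored as best-match purity over major communities: Σ max-overlap with
a planted group / Σ community sizes.

What passing shows: the whole chain — cleaning conventions, substring
hashing, SGD, thresholding, label propagation — preserves planted
co-occurrence structure well enough to recover it (purity ≥ 0.9). What it
does not show: performance on real literature, where group structure is
soft, frequencies are Zipfian, segmentation errs, drug names alias, and
polysemy exists. The generator makes none of those effects; claims about
real corpora need real corpora.

## Numerical choices and degenerate inputs

* Strict inequalities follow the method's statements: edges need
  similarity *greater than* `s`; labels are deleted when *strictly below*
  `1/r` (two labels at exactly 1/2 with `r = 2` both survive).
* Coefficient normalisation tolerance is 1e-9 in the invariant tests;
  renormalisation after deletion keeps sums exactly 1 in exact arithmetic.
* `n_max` defaults to 12 as a cost cap on long words (full-length windows
  are quadratic in sequence length); sequences shorter than the cap use
  their full length, and `feature_substrings()` clamps with a message.
* Empty corpora warn and return empty objects; empty vocabularies after
  `min_count` are an error at training time; networks with fewer than two
  drugs are returned edgeless; `max_iter = 0` label propagation returns
  the initial state with a warning.
* Zero-vector cosine is defined as 0 (logged), never NaN.
* word2vec text export rounds to six decimals; re-import is exact to 1e-6.

## Known limitations

* FMM segmentation has no disambiguation; garden-path segmentations are
  possible and lexicon-dependent.
* The packaged character/simplification tables are fixtures covering the
  documented examples plus synthetic entries; they make the package
  self-testing, not production-complete.
* Hash collisions can merge unrelated substrings at small `B`; this is by
  construction and unmonitored.
* COPRA's result depends on sweep order; determinism is per-seed, not
  per-graph. On graphs with weak community structure different seeds can
  give different (all defensible) partitions.
* Thesaurus matching is exact post-normalisation; multi-word drug names
  split by segmentation are not re-joined.
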