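---
title: "Methods: mapping a literature landscape with litscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a literature landscape with litscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

litscape turns a corpus of time-stamped scientific abstracts into a
quantitative map of a research field: which themes exist, how they wax and
wane, how they co-occur, how documents cluster into subfields, and where the
vocabulary of one subfield does or does not penetrate another. This vignette
is the package's own account of the underlying models, the tunable
parameters, the numerical choices, and the limits of what its tests
demonstrate.

## The corpus model

The unit of analysis is an abstract with a stable identifier, a title, and a
publication year, stored as one JSON object per line (JSONL). Everything
downstream consumes this format, so corpora can come from a live PubMed
query (`fetch_pubmed()`), from disk, or from the synthetic generator.
Deduplication treats two records as duplicates when they share an identifier
or when their case- and whitespace-normalized title + abstract pair is
identical; the first occurrence in corpus order survives. The text half of
the rule catches re-fetched records that reappear under fresh accession ids;
no fuzzy matching is attempted.

## Preprocessing

`tokenize()` applies, in order: markup stripping, punctuation stripping,
whitespace collapsing, removal of standalone numeric tokens, lowercasing,
stopword removal, removal of tokens shorter than three characters, and
Porter stemming. Two details deserve note.

* **Numeric stripping** removes tokens that are entirely digits ("25") but
  keeps digits embedded in alphanumeric tokens. This keeps synthetic stems
  such as `w0001` intact, which the offline validation framework depends
  on: because synthetic tokens are already stems, the stemmer is a no-op on
  them and downstream stages can be tested in isolation from stemmer
  behavior.
* **Stemming** is the classic Porter (1980) algorithm, implemented in the
  package and verified in the test suite against the worked examples
  published with the algorithm itself. Domain stems come out as expected:
  *senescence* → `senesc`, *mitochondrial* → `mitochondri`, *telomeres* →
  `telomer`.

Documents are then filtered by post-preprocessing token count with
**inclusive** bounds, default [30, 500] — short abstracts carry too little
signal for stable topic inference, and very long ones are usually
non-standard formats. The vocabulary is pruned by document frequency: a
token must appear in at least `ceiling(min_doc_fraction * n_docs)` documents
(default fraction 0.011, the desk-scale generalization of an absolute
5,000-document floor on a ~460k corpus; an absolute `min_doc_count` override
reproduces the original rule exactly) and in at most 30% of documents.
Pruning is order-independent and ids are assigned in lexicographic token
order, so the vocabulary is a pure function of the document multiset.

## Topic model

Latent Dirichlet allocation with symmetric priors `alpha = eta = 1/K`.
Inference is collapsed Gibbs sampling implemented in C++ with a
package-internal RNG, which makes a fit bit-reproducible for a fixed seed,
corpus order, and single thread. One *pass* is one full sweep of the sampler
over the token stream; the topic-word matrix `phi` and document-topic matrix
`theta` are posterior-mean estimates from the final state. `theta` entries
below 1e-8 are floored and rows renormalized so entropies and log-ratios
stay finite. The default 20 passes is enough for the well-separated-topic
recovery experiments in the test suite to reach matched cosines above 0.99;
real corpora with diffuse topics may need more.

The number of topics is selected by **c_v coherence**: for each candidate
K, a model is trained and its topics scored with the published c_v
configuration — top 20 words per topic, boolean sliding window of 110
tokens (documents shorter than the window contribute one window), NPMI with
epsilon 1e-12, and indirect cosine similarity under one-set segmentation —
then averaged over topics. Ties go to the smaller K.

One design choice departs from the common library default of scanning with
reduced effort. A variational "pass" hides ~50 inner per-document
iterations, so five such passes are nearly converged; five Gibbs sweeps are
not, and under-converged scan models systematically *inflate* coherence at
larger K, because fragments of a true topic remain internally coherent
while merged models (K too small) are penalized. Since a Gibbs sweep at
desk scale costs ~10 ms, the scan simply uses the same 20 sweeps as the
final model (`scan_passes`, configurable).

## Topic-level statistics

* **TF-IDF** uses one convention everywhere:
  `weight(t, d) = tf(t, d) * log2(N / df_t)`, rows L2-normalized. Tokens in
  every document get weight zero.
* **Topic-word importance** aggregates TF-IDF by topic responsibility:
  `score(k, t) = sum_d theta[d, k] * tfidf[d, t]`.
* **Yearly topic proportions** average `theta` over each year's documents
  (so each year's proportions sum to 1), with a trailing 5-year moving
  average. Averaging `theta` was chosen over counting dominant topics as the
  smoother, information-preserving reading; dominant-topic counting is
  available by computing on `dominant_topic()` output directly.
* **Shannon entropy** of each document's topic mixture is reported in nats
  (`0 ln 0 := 0`), averaged per year, with a trailing 10-year rolling mean.
  Bounds: 0 to `ln K`.
* **Co-occurrence** takes each document's top-5 topics (ties toward the
  lower index) and counts unordered pairs, normalized by the number of
  documents. Chord-diagram edges are the pairs strictly above 0.033; the
  package emits the table, not the figure.
* **Sentiment** is a pluggable valence-lexicon scorer. The compound score is
  the standard normalization `S / sqrt(S^2 + 15)` of the summed valences
  `S`, clipped to [-1, 1]. The bundled lexicon is a compact general-purpose
  list of Porter-stemmed scientific-register words with hand-assigned
  valences on the usual [-4, 4] scale; any published lexicon in the same
  two-column format can be substituted. Keywords are the top 500 corpus
  features; a keyword's score is the mean compound over documents containing
  it.

All moving averages in the package are trailing (past-inclusive) and
undefined until a full window exists — no lookahead, no partial windows.
Years with no documents are omitted, never interpolated, and consecutive-year
comparisons skip pairs that span a gap.

## The document landscape

Documents are re-vectorized with a capped vocabulary: the 500 tokens with
the highest corpus-wide count (ties lexicographic), document frequencies
recomputed on the restriction, TF-IDF, L2 normalization. PCA (default 50
components, mean-centered, component signs fixed so the largest-magnitude
loading is positive) feeds two consumers:

1. **Clustering**: a k-nearest-neighbor graph (k = 5, Euclidean, union-
   symmetrized) partitioned by the Leiden algorithm optimizing
   RB-configuration modularity at resolution 0.7. Labels are relabeled by
   descending cluster size from 0.
2. **Visualization**: a seeded force-directed (Fruchterman–Reingold) layout
   of the same graph, with disconnected components tiled side by side. The
   embedding is deliberately non-load-bearing: every statistic reads labels,
   TF-IDF, or PCA coordinates, never the 2-D layout, and a test asserts
   that clustering is unchanged when computed without it.

The *refocus* operation (`refocus_subcorpus()`) retains documents whose
dominant topic falls in a chosen set — e.g. the molecular/cell-biology
topics of an aging-literature corpus — and reruns the whole
vectorize/PCA/cluster pipeline on the subcorpus with its own parameters
(default 30 PCs), with features and document frequencies recomputed on the
subcorpus.

## Cluster-level statistics

* **Cosine similarity** between per-cluster mean TF-IDF vectors; zero
  profiles are flagged and score 0 against everything.
* **Differential words**: a token's mean TF-IDF in a cluster minus the
  maximum of its means over the other clusters. A difference rather than a
  ratio: scale-stable and defined when the other side is zero.
* **Topic enrichment**: observed topic mass per cluster versus the
  corpus-wide mass scaled by cluster size, as
  `log2((obs + eps) / (exp + eps))` with `eps = 1e-9`; the pseudocount
  implements the otherwise unspecified guard against division by zero.
  Observed mass is soft `theta` mass, consistent with the aggregation used
  everywhere else; a counts-based variant is one `dominant_topic()` call
  away. Rows are z-scored before UPGMA hierarchical clustering (Euclidean,
  average linkage) so clusters group by enrichment *shape*, not magnitude.
* **Evolution**: per-cluster mean publication year, and yearly cluster
  shares (summing to 1 per year) with trailing smoothing.
* **Thematic stability**: per cluster, the cosine between consecutive
  years' mean topic vectors, smoothed over 5 years, with an OLS slope per
  cluster; clusters are ranked by slope. A stationary cluster has all
  cosines exactly 1 and slope 0; converging clusters have positive slopes.
* **Hallmark presence**: the proportion of documents per cluster containing
  each of fourteen hallmark-of-aging stems ('oxid', 'inflamm', 'senesc',
  'mitochondri', 'genom', 'stem', 'insulin', 'metabol', 'telomer',
  'epigenet', 'autophagi', 'nutrient', 'microbi', 'intercellular'), matched
  as prefixes of stemmed tokens — the reading of "regular expression
  matching" consistent with stem semantics.
* **Semantic overlap**: each source cluster's top-20 words by mean TF-IDF,
  scored by their mean TF-IDF within every target cluster. Off-diagonal
  entries, symmetrized by averaging both directions, rank unordered cluster
  pairs from most- to least-studied connection — the package's gap-discovery
  statistic.

## The synthetic generator and what passing tests show

`generate_corpus()` draws from a Dirichlet-multinomial model: per-year
topic concentrations (`alpha_by_year`, with `alpha_trajectory()` builders
for constant, drifting, and converging prevalence), topic-word rows from a
symmetric Dirichlet with concentration `beta`, uniform document lengths
(default 40–200 tokens, inside the retention window), planted clusters with
cluster-exclusive marker stems replacing tokens at `marker_rate`, optional
hallmark-style stems targeted at chosen clusters, and duplicates re-emitted
under fresh ids. One global seed drives a fixed draw order (years, topic
mixtures, lengths, tokens, markers, duplicates), so generation is
byte-reproducible.

Default study conditions, chosen once as representative of a desk-scale
recovery experiment: 5 topics over 300 stems at `beta = 0.05`
(well-separated topics with ~15-word effective support), 100 documents per
year over 20 years, 4 clusters, `marker_rate = 0.1`. Recovery experiments in
the test suite run at these conditions: topic recovery at 2,000 documents,
coherence-based selection of K over {2, 5, 10} across 10 seeds, and cluster
recovery at 1,200 documents with `marker_rate = 0.2`.

Each recovery experiment isolates the planted structure it probes:

* **Topic recovery and model selection use marker-free corpora**
  (`marker_rate = 0`). Marker stems are high-frequency vocabulary drawn
  independently of topic assignments, so they enter every topic's top-word
  list while co-occurring only within their own cluster's documents; that
  penalizes a correctly sized model's coherence more than a fragmented
  larger one's, confounding the selection experiment with cluster
  machinery. (Parameter recovery itself is robust — matched topic cosines
  stay above 0.99 with markers present — but the c_v comparison across K
  is not.)
* **Cluster recovery uses a single-topic base corpus.** With a topic
  overlay, the TF-IDF/PCA geometry genuinely contains both structures, and
  Leiden resolves the finer topic-by-cluster product partition — a correct
  refinement (its communities map near-purely onto the planted clusters,
  which is itself asserted as a property test), but not the partition the
  adjusted-Rand comparison targets. Setting `K_true = 1` makes the planted
  clusters the only multivariate structure, which is the standard design
  for testing partition recovery.
* **What passing does not show.** The generator emits exchangeable stems,
  not language: no syntax, collocations, polysemy, rare-word tails, or
  citation structure. Recovery under these conditions validates the
  machinery — the estimators, statistics, and their wiring — not the claim
  that any particular real corpus has recoverable structure at these
  parameter values.

## Degenerate inputs and numerical conventions

Empty abstracts tokenize to empty lists; documents with no in-vocabulary
tokens get zero count rows, prior-mean topic distributions (flagged), and
zero TF-IDF rows. Ties are broken deterministically everywhere: argmax to
the lower index, token orderings lexicographically, coherence ties to the
smaller K, cluster labels by size then first appearance. Oracle comparisons
in the test suite are at 1e-12 for deterministic algebra (TF-IDF, topic
importance, differential scores, overlap), 1e-9 for enrichment, and 1e-8
for row-stochasticity of fitted matrices.

## Limitations

The kNN graph is built from a dense distance matrix, fine to tens of
thousands of documents but not to half a million; at that scale the
landscape stage needs an approximate-neighbor backend, though every
statistic downstream of the labels is scale-indifferent. The bundled
stopword list and valence lexicon are compact defaults, both replaceable by
study-specific files. Coherence-based model selection inherits c_v's known
preference structure — it rewards topics whose top words co-occur in
windows, which on heterogeneous real corpora can plateau over a range of K
rather than peak sharply; the scan reports the full curve, not just the
argmax, for exactly this reason.
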