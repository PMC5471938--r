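---
title: "Hidden-knowledge generation and filtering: methods and design"
author: "lbdiscovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden-knowledge generation and filtering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdiscovery)
```

## The problem

Several thousand biomedical articles are indexed every day, and no reader
can follow more than a sliver of them. Literature-based discovery (LBD)
automates the inference Swanson performed by hand: if one paper links
concept A to concept B and another links B to C, while A and C are never
directly related anywhere in the literature, the pair (A, C) is *hidden
knowledge* — a candidate connection worth investigating (new treatments,
drug repurposing, side-effect prediction). The classic example links
fish oil to Raynaud disease through terms such as blood viscosity and
platelet aggregation.

`lbdiscovery` implements this A-B-C model and its multi-step
generalization over a concept-relation graph built from *predications*:
subject-predicate-object triples (e.g. `C0019134 TREATS C0030705`)
extracted from documents by tools such as SemRep, with concepts
identified by CUIs (Concept Unique Identifiers) and annotated with
semantic types from the UMLS Semantic Network. The package does not run
any relation extractor; it consumes tabular exports of their output.

## The inference model

Let `M` be the square concept matrix with `m[i, j]` the number of
predication instances relating concepts i and j. Only *positive*
relations populate `M`: negated predications are parsed and retained in
the data model but excluded from the graph. Self-relations are excluded,
and the matrix is symmetrized — a relation in either direction makes the
two concepts related.

With `norm` the binarization operator (positive entries become 1),
connections through exactly one linking term are the strictly positive,
off-diagonal entries of

    norm(M^2) - norm(M)

and, generally, connections through exactly k linking terms are the
strictly positive entries of

    norm(M^(k+1)) - sum_{j=1..k} norm(M^j)

`hiddenPairs(matrix, k)` evaluates this expression. On an undirected
graph it is equivalent to: (A, C) is hidden at depth k iff the BFS
shortest-path distance between A and C is exactly k + 1. The test suite
checks this equivalence against an independent BFS oracle (igraph) on
one hundred seeded random graphs; the implementation itself never uses
igraph.

Numerical choices worth knowing:

* powers are computed on the **binarized** matrix with the result
  re-binarized after every multiplication. Only positivity matters in the
  formulas, and boolean semantics cannot overflow on literature-scale
  counts;
* the diagonal is always excluded — a walk returning to its origin is not
  a discovery;
* the strictly-positive test is applied uniformly at every depth;
* the matrix is undirected by design. Predication triples are directed,
  but relatedness in the discovery model is symmetric; a directed mode is
  deliberately out of scope;
* the default depth ceiling is 4. The evaluation protocols stop at two
  steps; deeper expressions are permitted but combinatorial.

`linkingChains()` returns the human-readable justification: all *simple*
paths (no repeated CUIs) of k linking terms between two concepts, each
hop annotated with its supporting PMIDs. Matrix powers count walks, not
simple paths, but at pair level the two coincide (a pair at distance
k + 1 has a simple shortest path), so the chain enumeration and the
matrix formula agree on *which* pairs are hidden; chains with repeated
CUIs would not be interpretable evidence and are never produced.
`openDiscovery()` (only A given) ranks all hidden targets by chain
count; `closedDiscoveryBackoff()` (A and C given) returns chains at the
smallest productive depth, reporting depth 0 for directly connected
pairs and NA when nothing is found — multi-step chains as a backoff for
failed single-step discovery.

## Filtering

Unfiltered hidden-knowledge generation at scale is unusable, so the
package layers four filters. All except synonym merging are contractions
(outputs are subsets of inputs), and every step appends a row to the
predication set's filter log, from which percent-remaining reports are
derived.

**Synonym merging (`sy`).** Thesauri assembled from many source
vocabularies split senses inconsistently (Raynaud *disease* and Raynaud
*phenomenon* carry different CUIs). `buildSynonymClasses()` keeps
unordered CUI pairs asserted synonymous by at least `minSources`
*distinct* source vocabularies (default 2), takes connected components
(synonyms of synonyms), and discards components larger than
`maxClassSize` (default 5) wholesale — oversized components are chaining
noise, and the size filter is applied after closure, so a 6-member
component is dropped entirely rather than trimmed. Each class is
represented by its lexicographically smallest CUI; the choice of
representative is not semantically motivated, it is simply deterministic
and stable. `applySynonymMerge()` rewrites a predication set onto
representatives, dropping (and counting) predications that collapse into
self-relations; it is idempotent, and the vocabulary shrinks by exactly
the sum of (class size − 1) when no predication collapses.

**Semantic-type filtering (`st`).** Every CUI carries one or more
semantic types. Named presets: `obvious` excludes five groups that
rarely appear in useful relations (activities & behaviours, geographic
areas, occupations, organizations, procedures); `half` excludes those
plus anatomy, concepts & ideas, devices, living beings and objects;
`manual` is a user-maintained expert list shipped as an empty template;
`yyp` is an *inclusion* preset restricting the vocabulary to chemicals &
drugs, genes & molecular sequences, disorders, physiology and anatomy
members. The group-to-type table is a reconstructed snapshot of the
public Semantic Network grouping and is user-replaceable. Two open
choices were settled as follows: for multi-typed concepts in exclude
mode the default rule is `any` (one excluded type disqualifies the
concept — this produces the large reductions such filters are used for),
with `all` configurable; and the `yyp` disorders contribution omits the
finding and sign-or-symptom types, which are observation categories
rather than disorder entities. Filters apply to the whole vocabulary,
not per role (linking vs target); per-role filtering is a non-goal. CUIs
absent from the concept table are retained with a warning (fail-open
keeps pipeline composition predictable); `strict = TRUE` drops them.

**Common-linking-term stoplist (`clt`).** A CUI that acts as a linking
term for very many hidden pairs (patient, study, week) is unlikely to be
informative. `buildCltStoplist()` counts, for every CUI in a training
segment (typically a historical date range), the number of distinct
one-step hidden pairs it links, then stoplists CUIs with count at least
`minCount`, truncated to the top `topFraction` by count (ties at the cut
keep the lexicographically smaller CUI). The counting unit — hidden
pairs, rather than documents or relation instances — and the two
thresholds are exposed as parameters because the technique admits
several reasonable instantiations; counting hidden pairs measures
exactly the quantity the filter is meant to control.

**Degree-based connection breaking (`break`).** Rather than deleting
general terms outright, their connections can be broken at
matrix-creation time. With `C(A)` the number of CUIs linked to A, the
`node` variant removes every edge incident to a CUI with
`C(A) > threshold`; the `pair` variant removes the edge (A, B) only when
`min(C(A), C(B)) > threshold`, so hubs keep their ties to rare concepts.
Degrees are computed once on the input matrix and edges removed in a
single pass — no cascading recomputation, because the rule is a test at
matrix-creation time, not a fixed point. The pair variant never removes
more edges than the node variant, breaking is anti-monotone in the
threshold, and a threshold at or above the maximum degree is the
identity (all property-tested). Thresholds are corpus-dependent and must
be supplied explicitly; the package ships no default.

## Evaluation protocols

**Replication.** Seven classic discoveries (Raynaud disease-fish oil,
somatomedin C-arginine, migraine-magnesium, magnesium
deficiency-neurologic disease, Alzheimer's-indomethacin,
Alzheimer's-estrogen, schizophrenia-calcium-independent phospholipase
A2) ship as editable fixtures with their literature segments.
`replicateDiscovery()` restricts the corpus to the segment, removes
every *document* containing a direct link between the endpoints (the
whole PMID is dropped, not just the offending row), applies the filter
pipeline, and reports the number of distinct linking CUIs per depth.
The direct link is read as between the two discovery endpoints, which is
what keeps the discovery itself out of its own evidence.

**Timeslicing.** `buildGoldStandard()` treats knowledge first published
after a cutoff date as what a system run on the pre-cutoff literature
should have predicted: gold = unordered pairs of positive post-cutoff
predications minus every pair present pre-cutoff (any pre-cutoff
predication, negated included, disqualifies a pair — it was not new).
Overlapping slices are a configuration error. `timesliceEvaluate()`
reports total generated pairs, correct (in gold), precision, recall,
F = 2PR/(P+R) (0 when P + R = 0; empty gold is flagged and reported as
recall 0), and the average number of pairs per term seen pre-cutoff —
the user-burden statistic, whose denominator is the count of distinct
CUIs in at least one positive pre-cutoff predication. Pairs are
unordered and predicate-agnostic throughout; a "both depths" run pools
depths 1 and 2. Precision in this protocol is structurally low even for
a correct system: much generated knowledge is either not yet published
or too obvious to publish.

## The synthetic corpus generator

No licensed predication database can be assumed, so every component is
exercised on synthetic corpora from `generateCorpus()`. A spec fixes the
vocabulary size, the degree model, document counts, the date range and
timeslice cutoff, the negation rate, a semantic-type palette, synonym
cliques, and optional planted discovery chains; a single mandatory seed
drives all sampling, with per-section sub-seeds at fixed offsets so
adding a feature never perturbs earlier draws. Same seed, same corpus,
byte for byte.

Defaults were chosen once as the package's study conditions: 500
concepts, hub-structured edges (endpoints drawn with power-law weights,
exponent 2.5, mean degree 4 — reproducing the heavy-tailed, hub-heavy
shape that motivates degree-based breaking), 400 documents of 1-5
predications dated 1980-2015 around a 2005-12-31 cutoff (mirroring the
classic end-of-2005 timeslice design), 10% negated predications, and 10
synonym cliques of 2-4 CUIs with 1-3 asserting sources per pair. Dates
are uniform per document at day granularity; concepts receive 1-3
semantic types by palette weight.

Planted chains use *reserved* CUIs that take part in no random edge, so
the source-target distance equals the chain length by construction; the
planter verifies this by BFS after insertion and fails loudly rather
than accept a shortcut. The `both-split` placement writes the chain
before the cutoff and a direct source-target predication after it — the
ground truth for timeslice recall. Acceptance-style checks run twenty
200-concept corpora with planted chains of lengths 2 and 3 and require
exact-depth recovery and full planted-pair recall.

What the generator does *not* emulate: extractor error modes (SemRep's
precision is far from perfect), realistic MeSH/date distributions,
correlated predicates, or vocabulary growth over time. Passing tests
therefore demonstrate the algebra, the contracts and the protocol
plumbing — not performance on real literature, whose headline numbers
require full-scale licensed snapshots.

## Worked example

The four relations extracted from the sentence *"We used hemofiltration
to treat a patient with digoxin overdose that was complicated by
refractory hyperkalemia"* form a 4-concept graph:

```{r worked}
ps <- PredicationSet(data.frame(
  pmid = "PM0001", date = "2000-06-15",
  subject_cui = c("C0001", "C0003", "C0004", "C0001"),
  predicate = c("TREATS", "PROCESS_OF", "COMPLICATES", "TREATS"),
  object_cui = c("C0002", "C0002", "C0003", "C0003"),
  negated = FALSE))
mat <- buildAdjacency(ps)
hiddenPairTable(hiddenPairs(mat, 1))
formatChain(linkingChains(mat, ps, "C0001", "C0004", 1)[[1]])
```

Hemofiltration (C0001) and patients (C0002) are each hidden from
hyperkalemia (C0004) through the single linking term digoxin overdose
(C0003); at depth 2 nothing further is hidden.

## Scale, determinism and limitations

The test suite and the acceptance script run on corpora of 100-500
concepts and a few hundred documents — sizes at which the sparse-matrix
expressions, chain enumeration and brute-force oracles all complete in
seconds and every expected value can be verified independently. The
sparse representation (`Matrix`) is the same one that carries the method
to larger corpora.

All randomness flows from explicit seeds; CLI runs write no timestamps,
so a fixed-seed invocation is byte-identical when repeated. Known
limitations: no ranking of hidden pairs beyond chain counts, no directed
mode, no relation-type (predicate) filtering beyond negation exclusion,
no per-role semantic-type filtering, and open discovery at depth 3+ is
combinatorial on hub-heavy graphs.
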