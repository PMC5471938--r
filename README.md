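# lbdiscovery

Hidden-knowledge generation and filtering for literature-based discovery
(LBD) in R.

Biomedical literature grows by thousands of articles a day, and
connections that are never stated in any single paper — a drug that
should treat a disease because both relate to the same physiology — go
unnoticed. In Swanson's A-B-C model, a *hidden* connection between
concepts A and C is proposed when some linking term B relates to both
while A and C are never directly related anywhere in the corpus.
`lbdiscovery` implements this model and its multi-step generalization
over concept-relation graphs built from *predications*
(subject-predicate-object triples with UMLS CUIs, as produced by
SemRep-style extractors), together with the filtering and evaluation
machinery needed to make the output usable and measurable.

## The model

Let `M` be the symmetric concept matrix with `m[i,j] > 0` iff a positive
relation between concepts i and j is attested. With `norm` binarizing
positive entries to 1, the pairs hidden at linking depth k are the
strictly positive off-diagonal entries of

    norm(M^(k+1)) − Σ_{j=1..k} norm(M^j)

so depth 1 is the classic `norm(M²) − norm(M)`. Equivalently: (A, C) is
hidden at depth k iff their shortest-path distance is exactly k + 1 —
the package's test suite verifies this equivalence against an
independent BFS oracle on hundreds of random graphs.

Around the inference core:

* **four filters** — source-asserted synonym merging into disjoint
  classes (support ≥ 2 sources, class size ≤ 5 by default);
  semantic-type exclusion/inclusion presets; an automatic
  common-linking-term stoplist; and degree-based connection breaking
  (whole-node or per-edge `min(C(A), C(B)) > threshold`);
* **two evaluation protocols** — replication of seven classic
  discoveries (with document-level removal of direct links), and
  timeslicing (precision / recall / F against knowledge first published
  after a cutoff, plus pairs-per-term burden);
* **a seeded synthetic corpus generator** with hub-heavy degree
  structure, synonym cliques, negation, dates, and plantable discovery
  chains whose depth is guaranteed by construction — so everything is
  testable without licensed SemMedDB/UMLS data;
* **a CLI** (`inst/scripts/lbd`) with subcommands `simulate`,
  `synmerge`, `filter`, `stoplist`, `matrix`, `discover`, `replicate`,
  `timeslice`, a machine-readable run log per invocation, and the exit
  codes 0 (ok) / 1 (input) / 2 (configuration) / 3 (internal).

## Worked example

The four relations SemRep extracts from *"We used hemofiltration to
treat a patient with digoxin overdose that was complicated by refractory
hyperkalemia"*:

```r
library(lbdiscovery)
ps <- PredicationSet(data.frame(
  pmid = "PM0001", date = "2000-06-15",
  subject_cui = c("C0001", "C0003", "C0004", "C0001"),   # H, D, Y, H
  predicate = c("TREATS", "PROCESS_OF", "COMPLICATES", "TREATS"),
  object_cui = c("C0002", "C0002", "C0003", "C0003"),    # P, P, D, D
  negated = FALSE))
mat <- buildAdjacency(ps)
hiddenPairTable(hiddenPairs(mat, 1))
#>   cui_a cui_b depth
#> 1 C0001 C0004     1
#> 2 C0002 C0004     1
formatChain(linkingChains(mat, ps, "C0001", "C0004", 1)[[1]])
#> [1] "C0001>C0003>C0004"
nrow(hiddenPairTable(hiddenPairs(mat, 2)))
#> [1] 0
```

Hemofiltration (C0001) and patients (C0002) are each hidden from
hyperkalemia (C0004) via the single linking term digoxin overdose
(C0003); nothing further is hidden at depth 2. Closed discovery with
backoff returns the same chain at the smallest productive depth:

```r
closedDiscoveryBackoff(mat, ps, "C0001", "C0004", maxDepth = 2)$depth
#> [1] 1
```

## Package layout

| Where | What |
|---|---|
| `R/relations-io.R` | readers/writers for the predication, concept, synonym and hidden-pair dialects |
| `R/inference.R` | adjacency matrix, `norm` powers, hidden pairs, chains, open/closed discovery |
| `R/synonyms.R` | synonym classes, statistics, merge |
| `R/filters.R` | semantic-type filters, `clt` stoplist, degree breaking |
| `R/evaluation.R` | replication and timeslicing protocols |
| `R/synthetic-corpus.R` | seeded corpus generator and discovery planting |
| `R/cli.R`, `inst/scripts/lbd` | command-line interface |
| `vignettes/hidden-knowledge.Rmd` | methods: model, assumptions, parameters, design choices |
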