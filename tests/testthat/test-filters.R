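test_that("semantic-type exclusion honors the multi-ST rule", {
  ps <- edgePreds(c("C0001", "C0002"), c("C0009", "C0009"))
  ct <- conceptsFor(c("C0001", "C0002", "C0009"),
                    list("geoa", c("geoa", "dsyn"), "phsu"))
  fAny <- semanticTypeFilter("exclude", "geoa", "any")
  out <- filterSemanticTypes(ps, ct, fAny)
  # both subjects carry geoa, so under "any" everything is dropped
  expect_equal(nrow(predications(out)), 0)

  # multi-ST concept {geoa, dsyn}: any removes it, all keeps it
  fAll <- semanticTypeFilter("exclude", "geoa", "all")
  multi <- edgePreds("C0002", "C0009")
  expect_equal(nrow(predications(filterSemanticTypes(multi, ct, fAny))), 0)
  expect_equal(nrow(predications(filterSemanticTypes(multi, ct, fAll))), 1)
})

test_that("the inclusion preset removes a sign-or-symptom-only concept", {
  yyp <- stPreset("yyp")
  expect_equal(yyp$mode, "include")
  ps <- edgePreds(c("C0001", "C0002"), c("C0009", "C0009"))
  ct <- conceptsFor(c("C0001", "C0002", "C0009"),
                    list("dsyn", "sosy", "phsu"))
  out <- filterSemanticTypes(ps, ct, yyp)
  expect_equal(predications(out)$subject_cui, "C0001")
})

test_that("preset expansion and unknown-CUI handling behave as configured", {
  obvious <- stPreset("obvious")
  expect_true(all(c("geoa", "ocac", "topp") %in% obvious$stSet))
  expect_false("dsyn" %in% obvious$stSet)
  half <- stPreset("half")
  expect_true(all(obvious$stSet %in% half$stSet))
  expect_true("bpoc" %in% half$stSet)
  expect_error(stPreset("manual"), class = "lbd_config_error")  # empty template

  ps <- edgePreds("C0001", "C0042")   # C0042 not in the table
  ct <- conceptsFor("C0001", list("dsyn"))
  f <- semanticTypeFilter("exclude", "geoa")
  expect_warning(kept <- filterSemanticTypes(ps, ct, f), "absent")
  expect_equal(nrow(predications(kept)), 1)
  expect_warning(strict <- filterSemanticTypes(ps, ct, f, strict = TRUE),
                 "absent")
  expect_equal(nrow(predications(strict)), 0)
})

test_that("common-linking-term stoplists count linked hidden pairs", {
  # A-B, B-C, A-E, E-D: every CUI links at most one hidden pair
  ps <- edgePreds(c("C000A", "C000B", "C000A", "C000E"),
                  c("C000B", "C000C", "C000E", "C000D"))
  expect_equal(length(cuis(buildCltStoplist(ps, 1, minCount = 2))), 0)
  expect_setequal(cuis(buildCltStoplist(ps, 1, minCount = 1)),
                  c("C000A", "C000B", "C000E"))

  # hub with 6 leaves links choose(6,2) = 15 hidden pairs
  hub <- edgePreds(rep("C000X", 6), sprintf("C00%02d", 1:6))
  expect_equal(cuis(buildCltStoplist(hub, 1, minCount = 2)), "C000X")

  expect_error(buildCltStoplist(PredicationSet(), 1, 1),
               class = "lbd_config_error")
  # a clique yields no hidden pairs at all
  cl <- utils::combn(sprintf("C%04d", 1:4), 2)
  expect_warning(sl <- buildCltStoplist(edgePreds(cl[1, ], cl[2, ]), 1, 1),
                 "no hidden pairs")
  expect_equal(length(cuis(sl)), 0)
})

test_that("top-fraction truncation keeps the highest counts, smaller CUI on ties", {
  # two hubs with different fan-outs plus a minor linker
  hubA <- edgePreds(rep("C0900", 6), sprintf("C01%02d", 1:6))
  hubB <- edgePreds(rep("C0800", 4), sprintf("C02%02d", 1:4))
  ps <- PredicationSet(rbind(predications(hubA), predications(hubB)))
  full <- buildCltStoplist(ps, 1, minCount = 1)
  expect_setequal(cuis(full), c("C0900", "C0800"))
  top <- buildCltStoplist(ps, 0.5, minCount = 1)
  expect_equal(cuis(top), "C0900")   # 15 pairs beats 6

  # equal counts: the lexicographically smaller CUI survives the cut
  hubC <- edgePreds(rep("C0700", 4), sprintf("C03%02d", 1:4))
  tie <- PredicationSet(rbind(predications(hubB), predications(hubC)))
  expect_equal(cuis(buildCltStoplist(tie, 0.5, minCount = 1)), "C0700")
})

test_that("stoplist application drops touching predications", {
  ps <- edgePreds(c("C000X", "C000A"), c("C000C", "C000B"))
  sl <- new("Stoplist", cuis = "C000X", provenance = list())
  out <- applyStoplist(ps, sl)
  expect_equal(predications(out)$subject_cui, "C000A")

  id <- applyStoplist(ps, new("Stoplist"))
  expect_identical(predications(id), predications(ps))

  all <- new("Stoplist", cuis = cuis(ps), provenance = list())
  expect_warning(none <- applyStoplist(ps, all), "every predication")
  expect_equal(nrow(predications(none)), 0)
})

test_that("node degree counts distinct neighbors", {
  mat <- buildAdjacency(workedSentencePreds())
  expect_equal(nodeDegree(mat, D), 3)
  expect_equal(nodeDegree(mat, Y), 1)
  expect_error(nodeDegree(mat, "C9999"), class = "lbd_input_error")

  # isolated CUI, constructed directly
  m <- Matrix::Matrix(0, 2, 2, sparse = TRUE,
                      dimnames = list(c("C1", "C2"), c("C1", "C2")))
  iso <- new("AdjacencyMatrix",
             counts = methods::as(methods::as(m, "CsparseMatrix"),
                                  "generalMatrix"), symmetric = TRUE)
  expect_equal(nodeDegree(iso, "C1"), 0)
})

test_that("connection breaking distinguishes the node and pair variants", {
  star <- buildAdjacency(edgePreds(rep("C0010", 5), sprintf("C000%d", 1:5)))
  node <- breakConnections(star, "node", 4)
  expect_equal(Matrix::nnzero(adjacencyCounts(node)), 0)
  pair <- breakConnections(star, "pair", 4)
  expect_equal(Matrix::nnzero(adjacencyCounts(pair)),
               Matrix::nnzero(adjacencyCounts(star)))

  # 6-clique: every degree is 5, the pair rule removes all 15 edges
  cl <- utils::combn(sprintf("C%04d", 1:6), 2)
  clique <- buildAdjacency(edgePreds(cl[1, ], cl[2, ]))
  expect_equal(Matrix::nnzero(adjacencyCounts(
    breakConnections(clique, "pair", 4))), 0)

  # threshold at or above the maximum degree is the identity
  for (v in c("node", "pair"))
    expect_equal(as.matrix(adjacencyCounts(breakConnections(clique, v, 5))),
                 as.matrix(adjacencyCounts(clique)))
  expect_error(breakConnections(star, "pair", 0), class = "lbd_config_error")
})

test_that("breaking is anti-monotone in threshold and pair removes a subset of node", {
  for (seed in 1:5) {
    g <- randomGraphPreds(60, 0.06, seed = seed)
    mat <- buildAdjacency(g$preds)
    prevNode <- -1
    for (thr in c(1, 2, 4, 8)) {
      node <- Matrix::nnzero(adjacencyCounts(breakConnections(mat, "node", thr)))
      pair <- Matrix::nnzero(adjacencyCounts(breakConnections(mat, "pair", thr)))
      expect_gte(pair, node)               # pair removes no more than node
      expect_gte(node, prevNode)           # higher threshold keeps more
      prevNode <- node
    }
  }
})

test_that("filters commute with CUI relabeling", {
  g <- randomGraphPreds(40, 0.08, seed = 3)
  mat <- buildAdjacency(g$preds)
  vocab <- cuis(mat)
  # bijective relabeling that preserves lexicographic comparability only
  # of matrix structure, not order: permute digits
  relabel <- stats::setNames(sprintf("C9%04d", seq_along(vocab)),
                             sample(vocab))
  permDf <- predications(g$preds)
  permDf$subject_cui <- relabel[permDf$subject_cui]
  permDf$object_cui <- relabel[permDf$object_cui]
  permPs <- PredicationSet(permDf)
  permMat <- buildAdjacency(permPs)
  for (v in c("node", "pair")) {
    kept <- breakConnections(mat, v, 3)
    permKept <- breakConnections(permMat, v, 3)
    edgeSet <- function(m) {
      t <- methods::as(methods::as(adjacencyCounts(m), "CsparseMatrix"),
                       "TsparseMatrix")
      vs <- cuis(m)
      sort(paste(pmin(vs[t@i + 1], vs[t@j + 1]),
                 pmax(vs[t@i + 1], vs[t@j + 1])))
    }
    orig <- edgeSet(kept)
    relabeled <- vapply(strsplit(orig, " "), function(p)
      paste(sort(relabel[p]), collapse = " "), "")
    expect_identical(sort(relabeled), edgeSet(permKept))
  }
})

test_that("predication-level filters are contractions", {
  g <- randomGraphPreds(50, 0.05, seed = 17)
  ps <- g$preds
  sl <- buildCltStoplist(ps, 0.5, minCount = 1)
  stopped <- applyStoplist(ps, sl)
  expect_true(all(predications(stopped)$pmid %in% predications(ps)$pmid))
  expect_lte(nrow(predications(stopped)), nrow(predications(ps)))
  broken <- applyBreakFilter(ps, "pair", 3)
  expect_lte(nrow(predications(broken)), nrow(predications(ps)))
  # stage log is monotone non-increasing across contraction filters
  both <- applyBreakFilter(stopped, "pair", 3)
  log <- filterLog(both)
  expect_true(all(log$n_after <= log$n_before))
  expect_true(all(diff(log$n_after) <= 0))
})
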