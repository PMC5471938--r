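test_that("adjacency construction symmetrizes, excludes negations and self-relations", {
  ps <- PredicationSet(data.frame(
    pmid = c("PM1", "PM2"), date = "2000-01-01",
    subject_cui = c("C0001", "C0002"), predicate = c("TREATS", "AFFECTS"),
    object_cui = c("C0002", "C0001"), negated = FALSE,
    stringsAsFactors = FALSE))
  m <- adjacencyCounts(buildAdjacency(ps))
  expect_equal(m["C0001", "C0002"], 2)
  expect_equal(m["C0002", "C0001"], 2)

  selfrel <- PredicationSet(data.frame(
    pmid = "PM1", date = "2000-01-01", subject_cui = "C0001",
    predicate = "TREATS", object_cui = "C0001", negated = FALSE,
    stringsAsFactors = FALSE))
  expect_warning(empty <- buildAdjacency(selfrel), "empty")
  expect_equal(length(cuis(empty)), 0)

  negmix <- PredicationSet(data.frame(
    pmid = c("PM1", "PM2"), date = "2000-01-01",
    subject_cui = "C0001", predicate = "TREATS", object_cui = "C0002",
    negated = c(FALSE, TRUE), stringsAsFactors = FALSE))
  expect_equal(adjacencyCounts(buildAdjacency(negmix))["C0001", "C0002"], 1)

  # presence/absence mode caps entries at 1
  expect_equal(adjacencyCounts(
    buildAdjacency(ps, countDuplicates = FALSE))["C0001", "C0002"], 1)
})

test_that("normBinarize maps positives to one and is idempotent", {
  m <- Matrix::Matrix(c(0, 3, 3, 0), 2, 2, sparse = TRUE)
  b <- normBinarize(m)
  expect_equal(as.matrix(b), matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  expect_equal(as.matrix(normBinarize(b)), as.matrix(b))
  z <- Matrix::Matrix(0, 3, 3, sparse = TRUE)
  expect_equal(Matrix::nnzero(normBinarize(z)), 0)
  neg <- Matrix::Matrix(c(0, -1, -1, 0), 2, 2, sparse = TRUE)
  expect_error(normBinarize(neg), "negative")
})

test_that("hidden pairs on the worked-sentence and path graphs match hand enumeration", {
  mat <- buildAdjacency(workedSentencePreds())
  hp1 <- hiddenPairTable(hiddenPairs(mat, 1))
  expect_equal(hp1$cui_a, c(H, P))
  expect_equal(hp1$cui_b, c(Y, Y))
  expect_equal(nrow(hiddenPairTable(hiddenPairs(mat, 2))), 0)

  # path A - b1 - b2 - C
  path <- edgePreds(c("C0100", "C0200", "C0300"),
                    c("C0200", "C0300", "C0400"))
  pmat <- buildAdjacency(path)
  h1 <- hiddenPairTable(hiddenPairs(pmat, 1))
  expect_setequal(paste(h1$cui_a, h1$cui_b),
                  c("C0100 C0300", "C0200 C0400"))
  h2 <- hiddenPairTable(hiddenPairs(pmat, 2))
  expect_equal(paste(h2$cui_a, h2$cui_b), "C0100 C0400")

  # complete graph: nothing is hidden at any depth
  ids <- sprintf("C%04d", 1:5)
  cmb <- utils::combn(ids, 2)
  kmat <- buildAdjacency(edgePreds(cmb[1, ], cmb[2, ]))
  for (k in 1:3)
    expect_equal(nrow(hiddenPairTable(hiddenPairs(kmat, k))), 0)

  expect_error(hiddenPairs(mat, 5), class = "lbd_config_error")
  expect_equal(nrow(hiddenPairTable(hiddenPairs(mat, 5, maxDepth = 6))), 0)
})

test_that("hidden pairs at depth k are exactly the BFS distance-(k+1) pairs", {
  configs <- expand.grid(n = c(60, 150), density = c(0.01, 0.04))
  for (i in seq_len(nrow(configs))) {
    for (seed in 1:4) {
      g <- randomGraphPreds(configs$n[i], configs$density[i],
                            seed = 1000 * i + seed)
      mat <- buildAdjacency(g$preds)
      for (k in 1:3) {
        got <- hiddenPairTable(hiddenPairs(mat, k))
        want <- pairsAtDistance(g$edges, k + 1)
        expect_identical(pairSetKey(got), pairSetKey(want))
      }
    }
  }
})

test_that("direct pairs and per-depth hidden pairs partition disjointly", {
  g <- randomGraphPreds(80, 0.03, seed = 99)
  mat <- buildAdjacency(g$preds)
  tkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  direct <- tkey(g$edges$a, g$edges$b)
  layers <- lapply(1:3, function(k) {
    df <- hiddenPairTable(hiddenPairs(mat, k))
    tkey(df$cui_a, df$cui_b)
  })
  all <- c(list(direct), layers)
  for (i in seq_along(all))
    for (j in seq_along(all))
      if (i < j) expect_equal(length(intersect(all[[i]], all[[j]])), 0)
})

test_that("linking chains enumerate simple paths with per-hop evidence", {
  ps <- workedSentencePreds()
  mat <- buildAdjacency(ps)
  ch <- linkingChains(mat, ps, H, Y, 1)
  expect_equal(length(ch), 1)
  expect_equal(ch[[1]]$links, D)
  expect_equal(formatChain(ch[[1]]), paste(H, D, Y, sep = ">"))
  expect_equal(ch[[1]]$evidence, list("PM0001", "PM0001"))

  path <- edgePreds(c("C0100", "C0200", "C0300"),
                    c("C0200", "C0300", "C0400"))
  pmat <- buildAdjacency(path)
  ch2 <- linkingChains(pmat, path, "C0100", "C0400", 2)
  expect_equal(length(ch2), 1)
  expect_equal(ch2[[1]]$links, c("C0200", "C0300"))

  # square A-B-C-D-A: two depth-1 chains A->C, via B and via D
  sq <- edgePreds(c("C0001", "C0002", "C0003", "C0004"),
                  c("C0002", "C0003", "C0004", "C0001"))
  smat <- buildAdjacency(sq)
  ch3 <- linkingChains(smat, sq, "C0001", "C0003", 1)
  expect_equal(vapply(ch3, function(x) x$links, ""), c("C0002", "C0004"))

  expect_error(linkingChains(mat, ps, H, H, 1), class = "lbd_input_error")
  expect_error(linkingChains(mat, ps, H, "C9999", 1),
               class = "lbd_input_error")
  expect_warning(linkingChains(mat, ps, H, P, 1), "directly connected")
})

test_that("depth-1 chain count equals the common-neighbor count", {
  g <- randomGraphPreds(70, 0.05, seed = 5)
  mat <- buildAdjacency(g$preds)
  nbr <- function(v) unique(c(g$edges$b[g$edges$a == v],
                              g$edges$a[g$edges$b == v]))
  hp <- hiddenPairTable(hiddenPairs(mat, 1))
  for (r in seq_len(min(nrow(hp), 20))) {
    chains <- linkingChains(mat, g$preds, hp$cui_a[r], hp$cui_b[r], 1)
    expect_equal(length(chains),
                 length(intersect(nbr(hp$cui_a[r]), nbr(hp$cui_b[r]))))
  }
})

test_that("open discovery ranks hidden targets by chain count", {
  star <- edgePreds(rep("C0010", 4), sprintf("C000%d", 1:4))
  smat <- buildAdjacency(star)
  res <- openDiscovery(smat, "C0001", 1)
  expect_equal(res, c(C0002 = 1L, C0003 = 1L, C0004 = 1L))

  ps <- workedSentencePreds()
  mat <- buildAdjacency(ps)
  expect_equal(openDiscovery(mat, P, 1), stats::setNames(1L, Y))

  # isolated source: indexed in the matrix but with no edges
  m <- Matrix::sparseMatrix(i = 1, j = 2, x = 1, dims = c(3, 3),
                            dimnames = list(c("C1", "C2", "C3"),
                                            c("C1", "C2", "C3")),
                            symmetric = FALSE)
  m <- Matrix::drop0(m + Matrix::t(m))
  iso <- new("AdjacencyMatrix",
             counts = methods::as(methods::as(m, "CsparseMatrix"),
                                  "generalMatrix"),
             symmetric = TRUE)
  expect_equal(length(openDiscovery(iso, "C3", 1)), 0)
  expect_error(openDiscovery(mat, "C9999", 1), class = "lbd_input_error")
})

test_that("closed discovery backs off to the smallest productive depth", {
  path <- edgePreds(c("C0100", "C0200", "C0300"),
                    c("C0200", "C0300", "C0400"))
  pmat <- buildAdjacency(path)
  bk <- closedDiscoveryBackoff(pmat, path, "C0100", "C0400", 2)
  expect_equal(bk$depth, 2L)
  expect_equal(length(bk$chains), 1)

  ps <- workedSentencePreds()
  mat <- buildAdjacency(ps)
  bk2 <- closedDiscoveryBackoff(mat, ps, H, Y, 2)
  expect_equal(bk2$depth, 1L)
  expect_equal(bk2$chains[[1]]$links, D)
  # direct connection: depth 0, nothing hidden
  expect_equal(closedDiscoveryBackoff(mat, ps, H, P, 2)$depth, 0L)

  # two components: no depth works
  two <- edgePreds(c("C0001", "C0003"), c("C0002", "C0004"))
  tmat <- buildAdjacency(two)
  bk3 <- closedDiscoveryBackoff(tmat, two, "C0001", "C0004", 3)
  expect_true(is.na(bk3$depth))
  expect_equal(length(bk3$chains), 0)
})
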