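#' Build the concept adjacency matrix from predications
#'
#' Populates the sparse symmetric matrix M at the heart of the discovery
#' system: `m[i, j]` is the number of predication instances supporting a
#' relation between concepts i and j. Following the positive-relations rule,
#' negated predications are excluded, as are self-relations (subject equal
#' to object). The matrix is undirected: a relation in either direction
#' contributes to both `m[i, j]` and `m[j, i]`.
#'
#' @param preds a [PredicationSet-class].
#' @param countDuplicates when TRUE (default) every supporting instance is
#'   counted; when FALSE entries are capped at 1 (presence/absence). Only
#'   positivity matters for hidden-knowledge generation, so the choice
#'   affects reporting, not discovery.
#' @return an [AdjacencyMatrix-class].
#' @export
buildAdjacency <- function(preds, countDuplicates = TRUE) {
  stopifnot(is(preds, "PredicationSet"))
  df <- predications(preds)
  df <- df[!df$negated & df$subject_cui != df$object_cui, , drop = FALSE]
  if (nrow(df) == 0) {
    warning("no positive non-self predications; adjacency matrix is empty")
    m <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(0L, 0L))
    return(new("AdjacencyMatrix", counts = m, symmetric = TRUE))
  }
  vocab <- sort(unique(c(df$subject_cui, df$object_cui)))
  i <- match(df$subject_cui, vocab)
  j <- match(df$object_cui, vocab)
  m <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(1, 2 * length(i)),
                            dims = c(length(vocab), length(vocab)),
                            dimnames = list(vocab, vocab))
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  if (!countDuplicates) m@x[m@x > 0] <- 1
  new("AdjacencyMatrix", counts = m, symmetric = TRUE)
}

#' Binarize a matrix of relation counts
#'
#' The `norm` operator of the discovery formulas: positive entries map to 1,
#' zeros stay 0. Idempotent.
#'
#' @param matrix a sparse (or dense) numeric matrix with entries >= 0.
#' @return a sparse 0/1 matrix of the same shape and dimnames.
#' @export
normBinarize <- function(matrix) {
  m <- methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  m <- Matrix::drop0(m)
  if (length(m@x) > 0 && any(m@x < 0))
    stop("normBinarize: negative entries are not count data")
  m@x[] <- 1
  m
}

#' Hidden concept pairs at a given linking depth
#'
#' A pair (A, C) is hidden at depth k when A and C are connected through a
#' chain of exactly k linking terms but by nothing shorter — i.e. the
#' strictly positive off-diagonal entries of
#' \deqn{\mathrm{norm}(M^{k+1}) - \sum_{j=1}^{k} \mathrm{norm}(M^{j})}
#' where `norm` binarizes positive entries (so k = 1 is
#' `norm(M^2) - norm(M)`, k = 2 is `norm(M^3) - norm(M^2) - norm(M)`, and
#' so on). Powers are taken on the binarized matrix — only positivity
#' matters, and boolean semantics avoid count overflow on literature-scale
#' corpora. The diagonal (walks returning to origin) is always excluded.
#'
#' @param matrix an [AdjacencyMatrix-class].
#' @param k linking depth (number of intermediate terms), >= 1.
#' @param maxDepth configured ceiling for k (default 4; deeper expressions
#'   are combinatorial and must be asked for explicitly).
#' @return a [HiddenPairSet-class] with every pair labelled depth k.
#' @export
hiddenPairs <- function(matrix, k, maxDepth = 4L) {
  stopifnot(is(matrix, "AdjacencyMatrix"))
  k <- as.integer(k)
  if (k < 1L) stopConfig("linking depth k must be >= 1")
  if (k > maxDepth)
    stopConfig("linking depth k=%d exceeds configured maximum %d", k, maxDepth)
  emptyPairs <- new("HiddenPairSet")
  m <- adjacencyCounts(matrix)
  if (nrow(m) == 0 || Matrix::nnzero(m) == 0) return(emptyPairs)

  B <- normBinarize(m)
  walk <- B              # norm(M^j) for the current j
  reached <- B           # sum of norm(M^1..j), reduced to its support
  if (k > 1) {
    for (j in 2:k) {
      walk <- normBinarize(walk %*% B)
      reached <- normBinarize(reached + walk)
    }
  }
  top <- normBinarize(walk %*% B)    # norm(M^{k+1})
  expr <- Matrix::drop0(top - reached) # strictly positive <=> new at k+1
  exprT <- methods::as(expr, "TsparseMatrix")
  pos <- exprT@x > 0
  ii <- exprT@i[pos] + 1L
  jj <- exprT@j[pos] + 1L
  keep <- ii < jj                      # off-diagonal, unordered
  ii <- ii[keep]; jj <- jj[keep]
  if (length(ii) == 0) return(emptyPairs)
  vocab <- rownames(m)
  p <- orderPair(vocab[ii], vocab[jj])
  df <- data.frame(cui_a = p$a, cui_b = p$b, depth = k,
                   stringsAsFactors = FALSE)
  df <- df[order(df$cui_a, df$cui_b), , drop = FALSE]
  rownames(df) <- NULL
  new("HiddenPairSet", pairs = df)
}

# internal: neighbor index list of the binarized matrix, diagonal excluded
neighborList <- function(mat) {
  B <- methods::as(normBinarize(adjacencyCounts(mat)), "TsparseMatrix")
  n <- nrow(B)
  keep <- B@i != B@j
  i <- B@i[keep] + 1L
  j <- B@j[keep] + 1L
  out <- vector("list", n)
  idx <- split(j, factor(i, levels = seq_len(n)))
  for (v in seq_len(n)) out[[v]] <- sort(unique(idx[[v]]))
  out
}

# internal: enumerate all simple paths of `len` edges from src (index) to
# tgt (index, or NA for "any endpoint"), lexicographic DFS order.
simplePaths <- function(nbrs, src, tgt, len) {
  paths <- list()
  path <- integer(len + 1)
  path[1] <- src
  visit <- function(v, depth) {
    for (w in nbrs[[v]]) {
      if (w %in% path[seq_len(depth)]) next
      if (depth == len) {
        if (is.na(tgt) || w == tgt) {
          path[depth + 1L] <<- w
          paths[[length(paths) + 1L]] <<- path[seq_len(depth + 1L)]
        }
      } else {
        # prune: endpoints are fixed, intermediate must not be tgt
        if (!is.na(tgt) && w == tgt) next
        path[depth + 1L] <<- w
        visit(w, depth + 1L)
      }
    }
  }
  if (len >= 1) visit(src, 1L)
  paths
}

# internal: supporting PMIDs for the (undirected, positive) relation a--b
edgeEvidence <- function(predDf, a, b) {
  hit <- !predDf$negated &
    ((predDf$subject_cui == a & predDf$object_cui == b) |
     (predDf$subject_cui == b & predDf$object_cui == a))
  sort(unique(predDf$pmid[hit]))
}

#' Enumerate linking chains between two concepts
#'
#' All simple paths (no repeated CUIs) of exactly `k` linking terms between
#' `source` and `target`, each hop annotated with the PMIDs of the
#' predications supporting it. For k = 1 the chains' middle elements are the
#' classic linking terms B of the A-B-C model. Chains are returned in
#' lexicographic order of their linking-CUI sequence.
#'
#' Matrix powers count walks, but a chain with a repeated CUI is not
#' human-interpretable evidence, so chains are restricted to simple paths;
#' at the pair level the two notions coincide (a pair hidden at depth k has
#' a shortest path, hence a simple path, of length k + 1).
#'
#' @param matrix an [AdjacencyMatrix-class].
#' @param preds the [PredicationSet-class] the matrix was built from (for
#'   per-hop PMID evidence).
#' @param source,target CUIs, both indexed in the matrix.
#' @param k linking depth (number of intermediate CUIs), >= 1.
#' @return a list of chains, each a list with elements `source`, `links`
#'   (character vector of k CUIs), `target`, and `evidence` (a list of k + 1
#'   PMID vectors, one per hop).
#' @export
linkingChains <- function(matrix, preds, source, target, k) {
  stopifnot(is(matrix, "AdjacencyMatrix"), is(preds, "PredicationSet"))
  k <- as.integer(k)
  if (k < 1L) stopConfig("linking depth k must be >= 1")
  vocab <- cuis(matrix)
  if (source == target) stopInput("source and target must differ: %s", source)
  for (cui in c(source, target))
    if (!cui %in% vocab) stopInput("CUI not in adjacency matrix: %s", cui)
  si <- match(source, vocab)
  ti <- match(target, vocab)
  nbrs <- neighborList(matrix)
  if (ti %in% nbrs[[si]])
    warning(sprintf("%s and %s are directly connected; chains are not hidden knowledge",
                    source, target))
  paths <- simplePaths(nbrs, si, ti, k + 1L)
  if (length(paths) == 0) return(list())
  # deterministic: lexicographic on the linking CUI sequence
  keys <- vapply(paths, function(p) paste(vocab[p], collapse = "\r"), "")
  paths <- paths[order(keys)]
  predDf <- predications(preds)
  lapply(paths, function(p) {
    pc <- vocab[p]
    ev <- lapply(seq_len(length(pc) - 1L), function(h)
      edgeEvidence(predDf, pc[h], pc[h + 1L]))
    list(source = pc[1], links = pc[-c(1, length(pc))],
         target = pc[length(pc)], evidence = ev)
  })
}

# internal: BFS distances (in edges) from a source index; Inf if unreachable
bfsDistances <- function(nbrs, src) {
  n <- length(nbrs)
  dist <- rep(Inf, n)
  dist[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(nbrs[frontier]))
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Open discovery: all hidden targets of a source concept
#'
#' Finds every concept hidden from `source` at linking depth `k` (shortest
#' connection uses exactly k intermediate terms) and counts its distinct
#' depth-k linking chains (simple paths).
#'
#' @param matrix an [AdjacencyMatrix-class].
#' @param source a CUI indexed in the matrix.
#' @param k linking depth, >= 1.
#' @return named integer vector, target CUI -> chain count, sorted by count
#'   descending then CUI.
#' @export
openDiscovery <- function(matrix, source, k) {
  stopifnot(is(matrix, "AdjacencyMatrix"))
  k <- as.integer(k)
  if (k < 1L) stopConfig("linking depth k must be >= 1")
  vocab <- cuis(matrix)
  if (!source %in% vocab) stopInput("CUI not in adjacency matrix: %s", source)
  si <- match(source, vocab)
  nbrs <- neighborList(matrix)
  dist <- bfsDistances(nbrs, si)
  hiddenIdx <- which(dist == k + 1L)
  if (length(hiddenIdx) == 0) return(stats::setNames(integer(), character()))
  paths <- simplePaths(nbrs, si, NA_integer_, k + 1L)
  ends <- vapply(paths, function(p) p[length(p)], 1L)
  counts <- table(factor(ends, levels = hiddenIdx))
  out <- stats::setNames(as.integer(counts), vocab[hiddenIdx])
  out <- out[out > 0]
  out[order(-out, names(out))]
}

#' Closed discovery with multi-step backoff
#'
#' The single-step A-B-C search sometimes fails (rare concepts may have no
#' common linking term); multi-step chains then serve as a backoff. Returns
#' the chains at the smallest depth k <= `maxDepth` with a non-empty result.
#' Directly connected pairs report depth 0 (there is nothing hidden to
#' discover); unreachable pairs report depth `NA`.
#'
#' @param matrix an [AdjacencyMatrix-class].
#' @param preds the underlying [PredicationSet-class] (chain evidence).
#' @param source,target CUIs indexed in the matrix.
#' @param maxDepth deepest k to try, >= 1.
#' @return list with `depth` (0, the k used, or NA) and `chains` (as
#'   [linkingChains()]; empty for depth 0 or NA).
#' @export
closedDiscoveryBackoff <- function(matrix, preds, source, target,
                                   maxDepth = 2L) {
  stopifnot(is(matrix, "AdjacencyMatrix"))
  maxDepth <- as.integer(maxDepth)
  if (maxDepth < 1L) stopConfig("maxDepth must be >= 1")
  vocab <- cuis(matrix)
  if (source == target) stopInput("source and target must differ: %s", source)
  for (cui in c(source, target))
    if (!cui %in% vocab) stopInput("CUI not in adjacency matrix: %s", cui)
  nbrs <- neighborList(matrix)
  si <- match(source, vocab)
  ti <- match(target, vocab)
  if (ti %in% nbrs[[si]])
    return(list(depth = 0L, chains = list()))
  for (k in seq_len(maxDepth)) {
    chains <- linkingChains(matrix, preds, source, target, k)
    if (length(chains) > 0) return(list(depth = k, chains = chains))
  }
  list(depth = NA_integer_, chains = list())
}
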