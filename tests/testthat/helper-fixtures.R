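# Fixtures are built in code; no stored data files.

# Predication set from an undirected edge list (one row per edge).
edgePreds <- function(a, b, pmid = NULL, date = "2000-06-15",
                      predicate = "ASSOCIATED_WITH", negated = FALSE) {
  n <- length(a)
  if (is.null(pmid)) pmid <- sprintf("PM%04d", seq_len(n))
  PredicationSet(data.frame(
    pmid = pmid, date = date, subject_cui = a, predicate = predicate,
    object_cui = b, negated = negated, stringsAsFactors = FALSE))
}

# The worked-sentence graph: hemofiltration (C0001) treats patients
# (C0002); digoxin overdose (C0003) is a process of patients; hyperkalemia
# (C0004) complicates digoxin overdose; hemofiltration treats (inferred)
# digoxin overdose.
H <- "C0001"; P <- "C0002"; D <- "C0003"; Y <- "C0004"
workedSentencePreds <- function() {
  PredicationSet(data.frame(
    pmid = c("PM0001", "PM0001", "PM0001", "PM0001"),
    date = "2000-06-15",
    subject_cui = c(H, D, Y, H),
    predicate = c("TREATS", "PROCESS_OF", "COMPLICATES", "TREATS"),
    object_cui = c(P, P, D, D),
    negated = FALSE, stringsAsFactors = FALSE))
}

# Random sparse undirected graph as a predication set; returns the edge
# list too so oracles can be built independently of buildAdjacency().
randomGraphPreds <- function(nNodes, density, seed) {
  set.seed(seed)
  cuiIds <- sprintf("C%05d", seq_len(nNodes))
  pairs <- utils::combn(nNodes, 2L)
  keep <- stats::runif(ncol(pairs)) < density
  idx <- pairs[, keep, drop = FALSE]
  if (ncol(idx) == 0) idx <- pairs[, 1, drop = FALSE]
  list(preds = edgePreds(cuiIds[idx[1, ]], cuiIds[idx[2, ]]),
       edges = data.frame(a = cuiIds[idx[1, ]], b = cuiIds[idx[2, ]],
                          stringsAsFactors = FALSE))
}

# Independent BFS oracle: pairs of CUIs at shortest-path distance exactly
# d, computed with igraph on the raw edge list (never via the package's
# matrix machinery).
pairsAtDistance <- function(edges, d) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  dm <- igraph::distances(g)
  vs <- rownames(dm)
  hit <- which(dm == d & upper.tri(dm), arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(cui_a = character(), cui_b = character(),
                      stringsAsFactors = FALSE))
  a <- vs[hit[, 1]]; b <- vs[hit[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(cui_a = a, cui_b = b, stringsAsFactors = FALSE)
  out[order(out$cui_a, out$cui_b), , drop = FALSE]
}

pairSetKey <- function(df) sort(paste(df$cui_a, df$cui_b))

# Brute-force synonym-class oracle: keep pairs with enough distinct
# sources, then repeatedly union intersecting sets until a fixed point,
# then apply the size window. Independent of the union-find implementation.
bruteForceSynClasses <- function(assertions, minSources, maxClassSize) {
  key <- paste(pmin(assertions$cui_a, assertions$cui_b),
               pmax(assertions$cui_a, assertions$cui_b))
  support <- tapply(assertions$source, key, function(s) length(unique(s)))
  kept <- names(support)[support >= minSources]
  sets <- lapply(strsplit(kept, " "), identity)
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  sets <- Filter(function(s) length(s) >= 2 && length(s) <= maxClassSize, sets)
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, `[`, "", 1L))]
}

randomAssertions <- function(nCuis, nRows, seed) {
  set.seed(seed)
  ids <- sprintf("C%04d", seq_len(nCuis))
  a <- sample(ids, nRows, replace = TRUE)
  b <- sample(ids, nRows, replace = TRUE)
  keep <- a != b
  data.frame(cui_a = pmin(a[keep], b[keep]), cui_b = pmax(a[keep], b[keep]),
             source = sample(paste0("SRC", 1:4), sum(keep), replace = TRUE),
             stringsAsFactors = FALSE)
}

# Small concept table covering a CUI vector with chosen semantic types.
conceptsFor <- function(cui, sts) {
  ConceptTable(cui = cui, name = paste("concept", seq_along(cui)),
               semTypes = sts)
}
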