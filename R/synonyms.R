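#' Build disjoint synonym classes from source-asserted synonymy
#'
#' Thesauri assembled from many source vocabularies split senses
#' inconsistently, so the same clinical concept can carry several CUIs
#' (Raynaud disease vs Raynaud phenomenon being the classic case). This
#' builds merge classes from source-asserted synonym pairs in three steps:
#'
#' 1. keep only unordered CUI pairs asserted by at least `minSources`
#'    *distinct* source vocabularies (assertion rows from one source count
#'    once);
#' 2. gather synonyms-of-synonyms: take connected components (transitive
#'    closure) of the kept pairs;
#' 3. discard components larger than `maxClassSize` wholesale — their
#'    members stay unmerged (oversized classes are dominated by chaining
#'    noise rather than genuine synonymy).
#'
#' Each retained class is represented by its lexicographically smallest CUI.
#'
#' @param assertions data.frame as from [readSynonymAssertions()]
#'   (`cui_a`, `cui_b`, `source`).
#' @param minSources minimum number of distinct sources per pair (>= 1).
#' @param maxClassSize largest component retained (>= 2).
#' @return a [SynonymClasses-class].
#' @export
buildSynonymClasses <- function(assertions, minSources = 2L,
                                maxClassSize = 5L) {
  minSources <- as.integer(minSources)
  maxClassSize <- as.integer(maxClassSize)
  if (minSources < 1L) stopConfig("minSources must be >= 1")
  if (maxClassSize < 2L) stopConfig("maxClassSize must be >= 2")
  empty <- new("SynonymClasses", classes = list(),
               canonicalMap = character(),
               minSources = minSources, maxClassSize = maxClassSize)
  if (is.null(assertions) || nrow(assertions) == 0) return(empty)

  key <- pairKey(assertions$cui_a, assertions$cui_b)
  support <- tapply(assertions$source, key,
                    function(s) length(unique(s)))
  kept <- names(support)[support >= minSources]
  if (length(kept) == 0) return(empty)
  ends <- strsplit(kept, "\r", fixed = TRUE)
  a <- vapply(ends, `[`, "", 1L)
  b <- vapply(ends, `[`, "", 2L)

  # union-find over the qualifying pairs
  nodes <- sort(unique(c(a, b)))
  parent <- seq_along(nodes)
  names(parent) <- nodes
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  for (e in seq_along(ia)) {
    ra <- find(ia[e]); rb <- find(ib[e])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(nodes), find, 1L)
  comps <- split(nodes, roots)
  comps <- comps[lengths(comps) >= 2 & lengths(comps) <= maxClassSize]
  comps <- lapply(unname(comps), sort)
  if (length(comps) == 0) return(empty)
  comps <- comps[order(vapply(comps, `[`, "", 1L))]
  cmap <- unlist(lapply(comps, function(m) {
    stats::setNames(rep(m[1], length(m)), m)
  }))
  new("SynonymClasses", classes = comps, canonicalMap = cmap,
      minSources = minSources, maxClassSize = maxClassSize)
}

#' Descriptive statistics of synonym classes
#'
#' Mirrors the usual reporting for merged-synonym vocabularies: number of
#' classes (size >= 2), largest class, counts of classes with strictly more
#' than 20/10/7/5/3 members, and mean class size.
#'
#' @param classes a [SynonymClasses-class].
#' @return a list with `numClasses`, `maxSize`, `countsOver` (named integer
#'   vector for thresholds 20, 10, 7, 5, 3), `meanSize`, and `degenerate`
#'   (TRUE when there are no classes and the mean is reported as 0).
#' @export
classStatistics <- function(classes) {
  stopifnot(is(classes, "SynonymClasses"))
  sizes <- lengths(synClasses(classes))
  thr <- c(20L, 10L, 7L, 5L, 3L)
  if (length(sizes) == 0) {
    return(list(numClasses = 0L, maxSize = 0L,
                countsOver = stats::setNames(rep(0L, 5), thr),
                meanSize = 0, degenerate = TRUE))
  }
  list(numClasses = length(sizes),
       maxSize = max(sizes),
       countsOver = stats::setNames(
         vapply(thr, function(t) sum(sizes > t), 1L), thr),
       meanSize = mean(sizes),
       degenerate = FALSE)
}

#' Rewrite a PredicationSet onto canonical synonym representatives
#'
#' Every subject/object CUI is replaced by its class representative
#' (identity for unclassed CUIs). Predications whose two endpoints collapse
#' onto the same representative become self-relations and are dropped (and
#' counted in the filter log). Idempotent: merging twice equals merging once.
#'
#' @param preds a [PredicationSet-class].
#' @param classes a [SynonymClasses-class].
#' @return the rewritten [PredicationSet-class].
#' @export
applySynonymMerge <- function(preds, classes) {
  stopifnot(is(preds, "PredicationSet"), is(classes, "SynonymClasses"))
  df <- predications(preds)
  nBefore <- nrow(df)
  if (nBefore == 0 || length(synClasses(classes)) == 0)
    return(logFilterStep(preds, "synonym_merge", "no-op (empty input or classes)",
                         nBefore, nBefore))
  df$subject_cui <- canonicalCui(classes, df$subject_cui)
  df$object_cui <- canonicalCui(classes, df$object_cui)
  selfPair <- df$subject_cui == df$object_cui
  df <- df[!selfPair, , drop = FALSE]
  out <- PredicationSet(df, provenance = preds@provenance,
                        filterLog = filterLog(preds))
  logFilterStep(out, "synonym_merge",
                sprintf("classes=%d self_pairs_dropped=%d",
                        length(synClasses(classes)), sum(selfPair)),
                nBefore, nrow(df))
}
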