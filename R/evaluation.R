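#' A replication case: one known discovery to re-derive
#'
#' @param name short label (e.g. `"RD-fsh"`).
#' @param sourceCui,targetCui the discovery's endpoint CUIs.
#' @param startYear,endYear the literature segment used for the original
#'   discovery (inclusive years).
#' @param expectedDirectConnections optionally, the number of
#'   direct-connection documents the original protocol reports removing.
#' @return a classed list.
#' @export
replicationCase <- function(name, sourceCui, targetCui, startYear, endYear,
                            expectedDirectConnections = NA_integer_) {
  startYear <- as.integer(startYear)
  endYear <- as.integer(endYear)
  if (startYear > endYear) stopConfig("case %s: start year after end year", name)
  structure(list(name = name, sourceCui = sourceCui, targetCui = targetCui,
                 startYear = startYear, endYear = endYear,
                 expectedDirectConnections = as.integer(expectedDirectConnections)),
            class = "ReplicationCase")
}

#' Read replication cases from a YAML file
#'
#' The package ships the seven classic discovery cases (Raynaud
#' disease/fish oil and friends) as
#' `system.file("extdata", "replication_cases.yaml", package = "lbdiscovery")`;
#' the file is user-editable (CUIs can be remapped to a local vocabulary).
#'
#' @param path YAML file; each entry needs `name`, `source_cui`,
#'   `target_cui`, `start_year`, `end_year` and optionally
#'   `direct_connections`.
#' @return named list of `ReplicationCase` objects.
#' @export
readReplicationCases <- function(path = system.file("extdata",
                                                    "replication_cases.yaml",
                                                    package = "lbdiscovery")) {
  if (!file.exists(path)) stopInput("cases file not found: %s", path)
  raw <- yaml::read_yaml(path)
  cases <- lapply(raw$cases, function(x) {
    replicationCase(x$name, x$source_cui, x$target_cui,
                    x$start_year, x$end_year,
                    if (is.null(x$direct_connections)) NA_integer_
                    else x$direct_connections)
  })
  stats::setNames(cases, vapply(cases, `[[`, "", "name"))
}

#' Remove documents containing a direct link between two concepts
#'
#' Replication must not be contaminated by the discovery itself: every
#' document (PMID) containing a positive predication directly linking `a`
#' and `c` (either direction) is identified and ALL its predications are
#' dropped — removal is document-level, not row-level.
#'
#' @param preds a [PredicationSet-class].
#' @param a,c the discovery endpoint CUIs.
#' @return list with `preds` (the reduced set) and `removedDocuments`
#'   (count of removed PMIDs).
#' @export
removeDirectDocuments <- function(preds, a, c) {
  stopifnot(is(preds, "PredicationSet"))
  df <- predications(preds)
  nBefore <- nrow(df)
  direct <- !df$negated &
    ((df$subject_cui == a & df$object_cui == c) |
     (df$subject_cui == c & df$object_cui == a))
  badPmids <- unique(df$pmid[direct])
  keep <- !(df$pmid %in% badPmids)
  out <- PredicationSet(df[keep, , drop = FALSE],
                        provenance = preds@provenance,
                        filterLog = filterLog(preds))
  out <- logFilterStep(out, "remove_direct_documents",
                       sprintf("pair=%s/%s documents=%d", a, c,
                               length(badPmids)),
                       nBefore, sum(keep))
  list(preds = out, removedDocuments = length(badPmids))
}

#' Restrict a PredicationSet to a date range
#'
#' @param preds a [PredicationSet-class].
#' @param start,end inclusive bounds (`Date` or ISO/year strings).
#' @return the restricted [PredicationSet-class] (logged).
#' @export
selectDateRange <- function(preds, start, end) {
  stopifnot(is(preds, "PredicationSet"))
  start <- if (inherits(start, "Date")) start else normalizeDate(start)
  end <- if (inherits(end, "Date")) end else normalizeDate(end)
  if (is.na(start) || is.na(end)) stopConfig("unparseable date bound")
  if (start > end) stopConfig("date range start after end")
  df <- predications(preds)
  nBefore <- nrow(df)
  keep <- df$date >= start & df$date <= end
  out <- PredicationSet(df[keep, , drop = FALSE],
                        provenance = preds@provenance,
                        filterLog = filterLog(preds))
  logFilterStep(out, "date_range",
                sprintf("%s..%s", format(start), format(end)),
                nBefore, sum(keep))
}

#' Replicate a known discovery
#'
#' Runs the replication protocol for one case: restrict the corpus to the
#' case's literature segment, remove every document containing a direct
#' link between the endpoints, apply the filter pipeline in order, build
#' the adjacency matrix, and report — for each depth 1..`maxDepth` — the
#' number of distinct CUIs appearing in linking positions of any
#' source-to-target chain at that depth.
#'
#' @param case a `ReplicationCase`.
#' @param preds the full [PredicationSet-class] corpus.
#' @param filters ordered list of functions `PredicationSet ->
#'   PredicationSet` (e.g. partially applied [applySynonymMerge()],
#'   [filterSemanticTypes()], [applyStoplist()]); applied in order.
#' @param maxDepth deepest chain length to enumerate.
#' @param breakVariant,breakThreshold optional degree-based connection
#'   breaking applied to the matrix after the predication filters.
#' @return list with `case`, `found` (were both CUIs in the filtered
#'   vocabulary?), `directConnections` (documents removed), and
#'   `linkingTerms` (integer vector, one entry per depth).
#' @export
replicateDiscovery <- function(case, preds, filters = list(), maxDepth = 2L,
                               breakVariant = NULL, breakThreshold = NULL) {
  stopifnot(inherits(case, "ReplicationCase"), is(preds, "PredicationSet"))
  seg <- selectDateRange(preds, sprintf("%04d-01-01", case$startYear),
                         sprintf("%04d-12-31", case$endYear))
  rd <- removeDirectDocuments(seg, case$sourceCui, case$targetCui)
  ps <- rd$preds
  for (f in filters) ps <- f(ps)
  counts <- stats::setNames(rep(0L, maxDepth), paste0("depth", seq_len(maxDepth)))
  vocabOk <- all(c(case$sourceCui, case$targetCui) %in% cuis(ps))
  if (!vocabOk || nrow(predications(ps)) == 0)
    return(list(case = case$name, found = FALSE,
                directConnections = rd$removedDocuments,
                linkingTerms = counts))
  mat <- buildAdjacency(ps)
  if (!is.null(breakVariant))
    mat <- breakConnections(mat, breakVariant, breakThreshold)
  if (!all(c(case$sourceCui, case$targetCui) %in% cuis(mat)))
    return(list(case = case$name, found = FALSE,
                directConnections = rd$removedDocuments,
                linkingTerms = counts))
  for (k in seq_len(maxDepth)) {
    chains <- suppressWarnings(
      linkingChains(mat, ps, case$sourceCui, case$targetCui, k))
    counts[k] <- length(unique(unlist(lapply(chains, `[[`, "links"))))
  }
  list(case = case$name, found = TRUE,
       directConnections = rd$removedDocuments, linkingTerms = counts)
}

#' Build a timeslicing gold standard
#'
#' Knowledge that first appears after the cutoff is what a discovery system
#' run on the pre-cutoff literature should have predicted. The gold
#' standard is the set of unordered CUI pairs attested by positive
#' post-cutoff predications, minus every pair already present before the
#' cutoff (in any predication — a relation that was merely renegotiated is
#' not new knowledge).
#'
#' @param preCutoff,postCutoff [PredicationSet-class] objects with disjoint
#'   date ranges (validated; overlap is a configuration error).
#' @return character vector of pair keys; use [goldPairTable()] for a
#'   two-column data.frame.
#' @export
buildGoldStandard <- function(preCutoff, postCutoff) {
  stopifnot(is(preCutoff, "PredicationSet"), is(postCutoff, "PredicationSet"))
  preDf <- predications(preCutoff)
  postDf <- predications(postCutoff)
  if (nrow(postDf) == 0) {
    warning("post-cutoff set is empty; gold standard is empty")
    return(character())
  }
  if (nrow(preDf) > 0 && max(preDf$date) >= min(postDf$date))
    stopConfig("pre- and post-cutoff date ranges overlap (%s >= %s)",
               format(max(preDf$date)), format(min(postDf$date)))
  pos <- postDf[!postDf$negated & postDf$subject_cui != postDf$object_cui, ]
  postPairs <- unique(pairKey(pos$subject_cui, pos$object_cui))
  prePairs <- if (nrow(preDf) > 0)
    unique(pairKey(preDf$subject_cui, preDf$object_cui)) else character()
  setdiff(postPairs, prePairs)
}

#' Expand pair keys into a two-column data.frame
#'
#' @param keys pair keys as returned by [buildGoldStandard()].
#' @return data.frame with columns `cui_a`, `cui_b` (`cui_a < cui_b`).
#' @export
goldPairTable <- function(keys) {
  if (length(keys) == 0)
    return(data.frame(cui_a = character(), cui_b = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(cui_a = vapply(parts, `[`, "", 1L),
             cui_b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Score generated hidden pairs against a timeslicing gold standard
#'
#' Computes the standard bundle: total pairs generated, pairs found in the
#' gold standard ("correct"), precision = correct/total, recall =
#' correct/|gold|, F = 2PR/(P+R), and the average number of hidden pairs
#' generated per term seen in the pre-cutoff segment (the burden a user
#' faces per query concept).
#'
#' @param hidden a [HiddenPairSet-class] (all depths pooled unless `depths`
#'   restricts them).
#' @param gold pair keys from [buildGoldStandard()].
#' @param preCutoffVocabSize number of distinct CUIs in at least one
#'   positive pre-cutoff predication (> 0).
#' @param depths optional integer vector restricting which depths count.
#' @return a [TimesliceResult-class].
#' @export
timesliceEvaluate <- function(hidden, gold, preCutoffVocabSize,
                              depths = NULL) {
  stopifnot(is(hidden, "HiddenPairSet"))
  preCutoffVocabSize <- as.integer(preCutoffVocabSize)
  if (preCutoffVocabSize <= 0L)
    stopConfig("preCutoffVocabSize must be positive")
  df <- hiddenPairTable(hidden)
  if (!is.null(depths)) df <- df[df$depth %in% depths, , drop = FALSE]
  total <- nrow(df)
  keys <- pairKey(df$cui_a, df$cui_b)
  correct <- sum(keys %in% gold)
  flags <- character()
  precision <- if (total == 0) 0 else correct / total
  if (length(gold) == 0) {
    recall <- 0
    flags <- c(flags, "empty_gold")
  } else {
    recall <- correct / length(gold)
  }
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  new("TimesliceResult", total = as.integer(total),
      correct = as.integer(correct), precision = precision, recall = recall,
      fMeasure = f, averagePerTerm = total / preCutoffVocabSize,
      flags = flags)
}

#' Count the terms seen in a predication segment
#'
#' The denominator of the average-pairs-per-term statistic: distinct CUIs
#' appearing in at least one positive predication of the segment.
#'
#' @param preds a [PredicationSet-class].
#' @return integer count.
#' @export
segmentVocabularySize <- function(preds) {
  stopifnot(is(preds, "PredicationSet"))
  df <- predications(preds)
  df <- df[!df$negated, , drop = FALSE]
  length(unique(c(df$subject_cui, df$object_cui)))
}
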