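#' Semantic-type filter specification
#'
#' Concepts carry one or more semantic-type (ST) codes from the UMLS
#' Semantic Network (e.g. `dsyn` = disease or syndrome). A filter either
#' excludes concepts whose STs fall in `stSet`, or includes only concepts
#' with at least one ST in `stSet`. For multi-ST concepts in exclude mode,
#' `multiStRule` decides whether any single excluded ST disqualifies the
#' concept (`"any"`, the default — a lone excluded type is enough) or all
#' of its STs must be excluded (`"all"`).
#'
#' @param mode `"exclude"` or `"include"`.
#' @param stSet non-empty character vector of ST codes.
#' @param multiStRule `"any"` or `"all"` (exclude mode only).
#' @return a classed list usable with [filterSemanticTypes()].
#' @export
semanticTypeFilter <- function(mode = c("exclude", "include"), stSet,
                               multiStRule = c("any", "all")) {
  mode <- match.arg(mode)
  multiStRule <- match.arg(multiStRule)
  stSet <- unique(as.character(stSet))
  if (length(stSet) == 0) stopConfig("stSet must be non-empty")
  structure(list(mode = mode, stSet = stSet, multiStRule = multiStRule),
            class = "SemanticTypeFilter")
}

#' The bundled semantic-group table
#'
#' Maps semantic-group names (activities & behaviours, anatomy, ...) to
#' their member ST codes. Reconstructed snapshot of the public Semantic
#' Network grouping; user-replaceable.
#'
#' @return data.frame with columns `group_id`, `group_name`, `st`.
#' @export
stGroupTable <- function() {
  utils::read.delim(system.file("extdata", "st_groups.tsv",
                                package = "lbdiscovery"),
                    comment.char = "#", colClasses = "character",
                    stringsAsFactors = FALSE)
}

# groups whose STs rarely appear in useful relations
obviousGroups <- c("activities & behaviors", "geographic areas",
                   "occupations", "organizations", "procedures")
# supertypes for which at least half the subtypes fall in the manual list
halfGroups <- c(obviousGroups, "anatomy", "concepts & ideas", "devices",
                "living beings", "objects")

#' Named semantic-type filter presets
#'
#' * `obvious` — exclude the five groups that rarely appear in useful
#'   relations (activities & behaviours, geographic areas, occupations,
#'   organizations, procedures).
#' * `half` — exclude those five plus anatomy, concepts & ideas, devices,
#'   living beings and objects.
#' * `manual` — a user-editable 70-type expert exclusion list; ships as an
#'   empty template (`st_exclude_manual.txt`) to be filled in locally.
#' * `yyp` — the inclusion preset restricting the vocabulary to chemicals &
#'   drugs, genes & molecular sequences, disorders, physiology and anatomy
#'   members (`st_include_yyp.txt`).
#'
#' @param name one of `"obvious"`, `"half"`, `"manual"`, `"yyp"`.
#' @param multiStRule passed through to [semanticTypeFilter()].
#' @return a `SemanticTypeFilter`.
#' @export
stPreset <- function(name = c("obvious", "half", "manual", "yyp"),
                     multiStRule = "any") {
  name <- match.arg(name)
  groups <- stGroupTable()
  if (name %in% c("obvious", "half")) {
    wanted <- if (name == "obvious") obviousGroups else halfGroups
    sts <- groups$st[groups$group_name %in% wanted]
    return(semanticTypeFilter("exclude", sts, multiStRule))
  }
  file <- if (name == "manual") "st_exclude_manual.txt" else "st_include_yyp.txt"
  sts <- readStList(system.file("extdata", file, package = "lbdiscovery"))
  if (length(sts) == 0)
    stopConfig("preset '%s' has no ST codes configured (template not filled in)",
               name)
  semanticTypeFilter(if (name == "manual") "exclude" else "include",
                     sts, multiStRule)
}

#' Read a plain-text ST list (one code per line, `#` comments)
#'
#' @param path file path.
#' @return character vector of ST codes (possibly empty).
#' @export
readStList <- function(path) {
  if (!file.exists(path)) stopInput("ST list not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  unique(lines)
}

#' Filter predications by concept semantic type
#'
#' Determines the set of removed CUIs from the concept table and the filter
#' specification, then drops every predication touching a removed CUI.
#' CUIs absent from the concept table are retained with a warning (fail-open
#' keeps filter composition predictable); `strict = TRUE` drops them
#' instead.
#'
#' @param preds a [PredicationSet-class].
#' @param concepts a [ConceptTable-class].
#' @param filter a `SemanticTypeFilter` from [semanticTypeFilter()] or
#'   [stPreset()].
#' @param strict drop unknown CUIs instead of retaining them.
#' @return the filtered [PredicationSet-class].
#' @export
filterSemanticTypes <- function(preds, concepts, filter, strict = FALSE) {
  stopifnot(is(preds, "PredicationSet"), is(concepts, "ConceptTable"),
            inherits(filter, "SemanticTypeFilter"))
  df <- predications(preds)
  nBefore <- nrow(df)
  vocab <- cuis(preds)
  known <- vocab[vocab %in% cuis(concepts)]
  unknown <- setdiff(vocab, known)
  if (length(unknown) > 0)
    warning(sprintf("%d CUI(s) absent from the concept table (%s)",
                    length(unknown),
                    if (strict) "dropped: strict mode" else "retained"))
  sts <- semanticTypes(concepts)[known]
  inSet <- lapply(sts, function(s) s %in% filter$stSet)
  removed <- if (filter$mode == "exclude") {
    if (filter$multiStRule == "any") {
      known[vapply(inSet, any, TRUE)]
    } else {
      known[vapply(inSet, all, TRUE)]
    }
  } else {
    known[!vapply(inSet, any, TRUE)]   # include: keep when any ST matches
  }
  if (strict) removed <- c(removed, unknown)
  keep <- !(df$subject_cui %in% removed) & !(df$object_cui %in% removed)
  out <- PredicationSet(df[keep, , drop = FALSE],
                        provenance = preds@provenance,
                        filterLog = filterLog(preds))
  logFilterStep(out, "semantic_type",
                sprintf("mode=%s rule=%s sts=%d cuis_removed=%d unknown=%d",
                        filter$mode, filter$multiStRule,
                        length(filter$stSet), length(removed),
                        length(unknown)),
                nBefore, sum(keep))
}

# internal: per-CUI count of distinct hidden pairs the CUI links at depth 1,
# i.e. non-adjacent pairs among its neighbors.
linkingCounts <- function(mat) {
  nbrs <- neighborList(mat)
  vocab <- cuis(mat)
  counts <- integer(length(nbrs))
  for (v in seq_along(nbrs)) {
    nb <- nbrs[[v]]
    if (length(nb) < 2) next
    cnt <- 0L
    for (a in seq_len(length(nb) - 1L)) {
      rest <- nb[(a + 1L):length(nb)]
      cnt <- cnt + sum(!(rest %in% nbrs[[nb[a]]]))
    }
    counts[v] <- cnt
  }
  stats::setNames(counts, vocab)
}

#' Build a stoplist of common linking terms
#'
#' A CUI that links very many hidden pairs is almost certainly a general,
#' uninformative term (patient, study, ...). From a training predication
#' segment this generates the one-step hidden pairs, counts for every CUI
#' the number of distinct hidden pairs it acts as a linking term for, and
#' stoplists the CUIs with count >= `minCount`, truncated to the top
#' `topFraction` by count. Ties at the truncation cut keep the
#' lexicographically smaller CUI.
#'
#' @param training a non-empty [PredicationSet-class] (e.g. a historical
#'   date segment of the corpus).
#' @param topFraction fraction of qualifying CUIs to keep, in (0, 1].
#' @param minCount minimum number of linked hidden pairs, >= 1.
#' @return a [Stoplist-class]; empty (with a warning) when the training
#'   segment yields no hidden pairs.
#' @export
buildCltStoplist <- function(training, topFraction = 1, minCount = 2L) {
  stopifnot(is(training, "PredicationSet"))
  if (nrow(predications(training)) == 0)
    stopConfig("training predication set is empty")
  if (topFraction <= 0 || topFraction > 1)
    stopConfig("topFraction must be in (0, 1]")
  minCount <- as.integer(minCount)
  if (minCount < 1L) stopConfig("minCount must be >= 1")
  dateRange <- range(predications(training)$date)
  prov <- list(training_start = format(dateRange[1]),
               training_end = format(dateRange[2]),
               top_fraction = topFraction, min_count = minCount)
  mat <- buildAdjacency(training)
  counts <- linkingCounts(mat)
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    warning("training segment yields no hidden pairs; stoplist is empty")
    return(new("Stoplist", cuis = character(), provenance = prov))
  }
  qual <- counts[counts >= minCount]
  if (length(qual) == 0)
    return(new("Stoplist", cuis = character(), provenance = prov))
  ord <- order(-qual, names(qual))       # count desc, then smaller CUI first
  keepN <- ceiling(topFraction * length(qual))
  new("Stoplist", cuis = sort(names(qual)[ord][seq_len(keepN)]),
      provenance = prov)
}

#' Apply a stoplist to a PredicationSet
#'
#' Drops every predication touching a stoplisted CUI.
#'
#' @param preds a [PredicationSet-class].
#' @param stoplist a [Stoplist-class].
#' @return the filtered [PredicationSet-class].
#' @export
applyStoplist <- function(preds, stoplist) {
  stopifnot(is(preds, "PredicationSet"), is(stoplist, "Stoplist"))
  df <- predications(preds)
  nBefore <- nrow(df)
  bad <- cuis(stoplist)
  keep <- !(df$subject_cui %in% bad) & !(df$object_cui %in% bad)
  if (nBefore > 0 && sum(keep) == 0)
    warning("stoplist removed every predication")
  out <- PredicationSet(df[keep, , drop = FALSE],
                        provenance = preds@provenance,
                        filterLog = filterLog(preds))
  logFilterStep(out, "stoplist",
                sprintf("cuis=%d", length(bad)), nBefore, sum(keep))
}

#' Apply degree-based connection breaking at the predication level
#'
#' Convenience wrapper for pipelines that operate on predication sets:
#' builds the adjacency matrix, breaks connections with
#' [breakConnections()], and drops the positive predications whose
#' (subject, object) edge was removed. Negated predications are untouched
#' (they are not edges).
#'
#' @param preds a [PredicationSet-class].
#' @param variant,threshold as [breakConnections()].
#' @return the filtered [PredicationSet-class].
#' @export
applyBreakFilter <- function(preds, variant, threshold) {
  stopifnot(is(preds, "PredicationSet"))
  df <- predications(preds)
  nBefore <- nrow(df)
  if (nBefore == 0)
    return(logFilterStep(preds, "break", "no-op (empty input)", 0L, 0L))
  mat <- buildAdjacency(preds)
  kept <- breakConnections(mat, variant, threshold)
  km <- methods::as(methods::as(adjacencyCounts(kept), "CsparseMatrix"),
                    "TsparseMatrix")
  vocab <- cuis(kept)
  keptKeys <- unique(pairKey(vocab[km@i + 1L], vocab[km@j + 1L]))
  isEdgeRow <- !df$negated & df$subject_cui != df$object_cui
  rowKeys <- pairKey(df$subject_cui, df$object_cui)
  keep <- !isEdgeRow | rowKeys %in% keptKeys
  out <- PredicationSet(df[keep, , drop = FALSE],
                        provenance = preds@provenance,
                        filterLog = filterLog(preds))
  logFilterStep(out, "break",
                sprintf("variant=%s threshold=%d", variant,
                        as.integer(threshold)),
                nBefore, sum(keep))
}

#' Degree of a concept in the adjacency matrix
#'
#' The number of distinct CUIs with a nonzero connection to `cui`
#' (the C(A) of degree-based connection breaking), self excluded.
#'
#' @param matrix an [AdjacencyMatrix-class].
#' @param cui a CUI indexed in the matrix.
#' @return integer degree.
#' @export
nodeDegree <- function(matrix, cui) {
  stopifnot(is(matrix, "AdjacencyMatrix"))
  vocab <- cuis(matrix)
  if (!cui %in% vocab) stopInput("CUI not in adjacency matrix: %s", cui)
  i <- match(cui, vocab)
  row <- adjacencyCounts(matrix)[i, ]
  as.integer(sum(row != 0) - (row[i] != 0))
}

# internal: all node degrees at once
allDegrees <- function(matrix) {
  B <- normBinarize(adjacencyCounts(matrix))
  Matrix::diag(B) <- 0
  stats::setNames(Matrix::rowSums(B), rownames(B))
}

#' Break connections of highly connected concepts
#'
#' Highly connected concepts tend to be general, uninformative terms;
#' instead of stoplisting them outright, their connections can be broken at
#' matrix-creation time. Degrees C(.) are computed once on the input matrix
#' and edges are removed in a single pass (no cascading recomputation):
#'
#' * `variant = "node"` — every edge incident to a CUI A with
#'   C(A) > `threshold` is removed (the CUI is disconnected entirely).
#' * `variant = "pair"` — the edge (A, B) is removed iff
#'   min(C(A), C(B)) > `threshold`; edges to low-degree partners survive,
#'   so a hub keeps its ties to rare concepts.
#'
#' The pair variant never removes more edges than the node variant at equal
#' threshold. Thresholds are corpus-dependent and must be chosen
#' empirically; no default is provided.
#'
#' @param matrix an [AdjacencyMatrix-class] (left unchanged).
#' @param variant `"node"` or `"pair"`.
#' @param threshold positive integer degree cutoff.
#' @return a new [AdjacencyMatrix-class] with the surviving counts.
#' @export
breakConnections <- function(matrix, variant = c("node", "pair"), threshold) {
  stopifnot(is(matrix, "AdjacencyMatrix"))
  variant <- match.arg(variant)
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L)
    stopConfig("break threshold must be a positive integer")
  m <- adjacencyCounts(matrix)
  if (nrow(m) == 0) return(matrix)
  deg <- allDegrees(matrix)
  high <- deg > threshold
  mt <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  i <- mt@i + 1L
  j <- mt@j + 1L
  drop <- if (variant == "node") {
    high[i] | high[j]
  } else {
    high[i] & high[j]     # min(C(i), C(j)) > threshold
  }
  keep <- !drop
  out <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = mt@x[keep],
                              dims = dim(m), dimnames = dimnames(m))
  out <- methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
  new("AdjacencyMatrix", counts = out, symmetric = matrix@symmetric)
}
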