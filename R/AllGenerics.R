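#' Extract the predication table
#'
#' @param x a [PredicationSet-class].
#' @return data.frame of predications.
#' @export
setGeneric("predications", function(x) standardGeneric("predications"))

#' @describeIn PredicationSet-class the predication rows as a data.frame.
#' @param x a `PredicationSet`.
#' @export
setMethod("predications", "PredicationSet", function(x) x@predications)

#' Extract the append-only filter log
#'
#' @param x a [PredicationSet-class].
#' @return data.frame of applied steps with before/after counts.
#' @export
setGeneric("filterLog", function(x) standardGeneric("filterLog"))

#' @rdname filterLog
#' @export
setMethod("filterLog", "PredicationSet", function(x) x@filterLog)

#' The set of concept identifiers carried by an object
#'
#' @param x a `PredicationSet`, `ConceptTable`, `AdjacencyMatrix` or
#'   `Stoplist`.
#' @return character vector of CUIs.
#' @export
setGeneric("cuis", function(x) standardGeneric("cuis"))

#' @rdname cuis
#' @export
setMethod("cuis", "PredicationSet", function(x) {
  df <- x@predications
  if (nrow(df) == 0) return(character())
  sort(unique(c(df$subject_cui, df$object_cui)))
})

#' @rdname cuis
#' @export
setMethod("cuis", "ConceptTable", function(x) x@concepts$cui)

#' @rdname cuis
#' @export
setMethod("cuis", "AdjacencyMatrix", function(x) rownames(x@counts))

#' @rdname cuis
#' @export
setMethod("cuis", "Stoplist", function(x) x@cuis)

#' Semantic types of one or all concepts
#'
#' @param x a [ConceptTable-class].
#' @param cui optional CUI (or vector); when missing, the full named list.
#' @return character vector of ST codes (or named list when `cui` missing).
#' @export
semanticTypes <- function(x, cui) {
  stopifnot(is(x, "ConceptTable"))
  if (missing(cui)) return(x@semTypes)
  x@semTypes[cui]
}

#' The disjoint classes of a SynonymClasses object
#'
#' @param x a [SynonymClasses-class].
#' @return list of character vectors.
#' @export
synClasses <- function(x) {
  stopifnot(is(x, "SynonymClasses"))
  x@classes
}

#' Canonicalize CUIs through a synonym-class map
#'
#' Maps every classed CUI to its class representative; unclassed CUIs map to
#' themselves (the identity extension of the stored map).
#'
#' @param x a [SynonymClasses-class].
#' @param cui character vector of CUIs.
#' @return character vector of the same length.
#' @export
canonicalCui <- function(x, cui) {
  stopifnot(is(x, "SynonymClasses"))
  hit <- x@canonicalMap[cui]
  unname(ifelse(is.na(hit), cui, hit))
}

#' The sparse count matrix of an AdjacencyMatrix
#'
#' @param x an [AdjacencyMatrix-class].
#' @return a sparse `Matrix` with CUI dimnames.
#' @export
adjacencyCounts <- function(x) {
  stopifnot(is(x, "AdjacencyMatrix"))
  x@counts
}

#' The hidden pairs as a data.frame
#'
#' @param x a [HiddenPairSet-class].
#' @return data.frame with columns `cui_a`, `cui_b`, `depth`.
#' @export
hiddenPairTable <- function(x) {
  stopifnot(is(x, "HiddenPairSet"))
  x@pairs
}

setMethod("show", "PredicationSet", function(object) {
  df <- object@predications
  cat(sprintf("PredicationSet with %d predications over %d concepts\n",
              nrow(df), length(cuis(object))))
  if (nrow(df) > 0) {
    cat(sprintf("  dates: %s .. %s | negated: %d\n",
                format(min(df$date)), format(max(df$date)),
                sum(df$negated)))
  }
  if (nrow(object@filterLog) > 0)
    cat(sprintf("  filter log: %d step(s), last: %s\n",
                nrow(object@filterLog),
                utils::tail(object@filterLog$step, 1)))
})

setMethod("show", "ConceptTable", function(object) {
  cat(sprintf("ConceptTable with %d concepts, %d distinct semantic types\n",
              nrow(object@concepts),
              length(unique(unlist(object@semTypes)))))
})

setMethod("show", "SynonymClasses", function(object) {
  cat(sprintf(
    "SynonymClasses: %d classes over %d CUIs (min_sources=%d, max_class_size=%d)\n",
    length(object@classes), length(object@canonicalMap),
    object@minSources, object@maxClassSize))
})

setMethod("show", "AdjacencyMatrix", function(object) {
  m <- object@counts
  nEdges <- Matrix::nnzero(m)
  if (object@symmetric) nEdges <- nEdges / 2
  cat(sprintf("AdjacencyMatrix: %d concepts, %d %s edges\n",
              nrow(m), nEdges,
              if (object@symmetric) "undirected" else "directed"))
})

setMethod("show", "HiddenPairSet", function(object) {
  df <- object@pairs
  cat(sprintf("HiddenPairSet with %d pairs\n", nrow(df)))
  if (nrow(df) > 0) {
    tab <- table(df$depth)
    cat(sprintf("  by depth: %s\n",
                paste(sprintf("k=%s: %d", names(tab), as.integer(tab)),
                      collapse = ", ")))
  }
})

setMethod("show", "Stoplist", function(object) {
  cat(sprintf("Stoplist with %d CUIs\n", length(object@cuis)))
})

setMethod("show", "TimesliceResult", function(object) {
  cat("Timeslice evaluation\n")
  cat(sprintf("  total: %d  correct: %d\n", object@total, object@correct))
  cat(sprintf("  precision: %.4g  recall: %.4g  F: %.4g  avg/term: %.4g\n",
              object@precision, object@recall, object@fMeasure,
              object@averagePerTerm))
  if (length(object@flags) > 0)
    cat(sprintf("  flags: %s\n", paste(object@flags, collapse = ", ")))
})

# internal: append one step to a PredicationSet's filter log
logFilterStep <- function(ps, step, detail, nBefore, nAfter) {
  ps@filterLog <- rbind(ps@filterLog, data.frame(
    step = step, detail = detail,
    n_before = as.integer(nBefore), n_after = as.integer(nAfter),
    stringsAsFactors = FALSE))
  ps
}
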