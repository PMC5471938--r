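#' @import methods
#' @importClassesFrom Matrix Matrix
NULL

predicationColumns <- c("pmid", "date", "subject_cui", "predicate",
                        "object_cui", "negated")

#' PredicationSet: a collection of extracted relation instances
#'
#' One row per predication (who-said-what-where-when): document identifier,
#' publication date, subject CUI, predicate name, object CUI and a negation
#' flag. Negated rows are retained at read time and only excluded when the
#' adjacency matrix is built, so no information is silently dropped on input.
#' The append-only filter log records every transformation applied to the
#' set together with before/after row counts, which is what makes
#' "percent of relations remaining" reports possible after any pipeline.
#'
#' @slot predications data.frame with columns `pmid`, `date` (Date),
#'   `subject_cui`, `predicate`, `object_cui`, `negated` (logical).
#' @slot provenance character vector of input paths this set was read from.
#' @slot filterLog data.frame of applied steps (`step`, `detail`,
#'   `n_before`, `n_after`), append-only.
#' @exportClass PredicationSet
setClass("PredicationSet",
  representation(predications = "data.frame",
                 provenance = "character",
                 filterLog = "data.frame"),
  prototype(predications = data.frame(), provenance = character(),
            filterLog = data.frame(step = character(), detail = character(),
                                   n_before = integer(), n_after = integer(),
                                   stringsAsFactors = FALSE))
)

setValidity("PredicationSet", function(object) {
  df <- object@predications
  if (nrow(df) == 0 && ncol(df) == 0) return(TRUE)
  missing <- setdiff(predicationColumns, names(df))
  if (length(missing) > 0)
    return(paste("missing predication columns:", paste(missing, collapse = ", ")))
  if (!inherits(df$date, "Date")) return("date column must be of class Date")
  if (!is.logical(df$negated)) return("negated column must be logical")
  if (nrow(df) > 0) {
    if (any(is.na(df$date))) return("all dates must be parseable (no NA)")
    if (any(df$subject_cui == "" | df$object_cui == ""))
      return("subject and object CUIs must be non-empty")
    if (any(df$predicate == "")) return("predicates must be non-empty")
  }
  TRUE
})

#' Construct a PredicationSet
#'
#' @param predications data.frame with the predication columns (see
#'   [PredicationSet-class]); a `date` column of strings is normalized.
#' @param provenance character vector of originating paths.
#' @param filterLog an existing filter log to carry over.
#' @return a [PredicationSet-class] object.
#' @export
PredicationSet <- function(predications = data.frame(),
                           provenance = character(),
                           filterLog = emptyFilterLog()) {
  if (nrow(predications) == 0) {
    predications <- data.frame(
      pmid = character(), date = as.Date(character()),
      subject_cui = character(), predicate = character(),
      object_cui = character(), negated = logical(),
      stringsAsFactors = FALSE)
  }
  if (nrow(predications) > 0) {
    if (!inherits(predications$date, "Date"))
      predications$date <- normalizeDate(predications$date)
    predications$pmid <- as.character(predications$pmid)
    predications$subject_cui <- as.character(predications$subject_cui)
    predications$object_cui <- as.character(predications$object_cui)
    predications$predicate <- as.character(predications$predicate)
    predications$negated <- as.logical(predications$negated)
    predications <- predications[predicationColumns]
    rownames(predications) <- NULL
  }
  new("PredicationSet", predications = predications,
      provenance = provenance, filterLog = filterLog)
}

#' ConceptTable: CUI metadata (preferred name + semantic types)
#'
#' @slot concepts data.frame with columns `cui`, `name`.
#' @slot semTypes named list: CUI -> character vector of semantic-type codes
#'   (each entry non-empty; every CUI carries at least one semantic type).
#' @exportClass ConceptTable
setClass("ConceptTable",
  representation(concepts = "data.frame", semTypes = "list"),
  prototype(concepts = data.frame(cui = character(), name = character(),
                                  stringsAsFactors = FALSE),
            semTypes = list())
)

setValidity("ConceptTable", function(object) {
  df <- object@concepts
  if (!all(c("cui", "name") %in% names(df)))
    return("concepts needs columns cui, name")
  if (anyDuplicated(df$cui)) return("every CUI must appear once")
  if (!setequal(names(object@semTypes), df$cui))
    return("semTypes must be keyed by exactly the table's CUIs")
  if (length(object@semTypes) > 0 &&
      any(vapply(object@semTypes, length, 1L) == 0))
    return("every CUI must have at least one semantic type")
  TRUE
})

#' Construct a ConceptTable
#'
#' @param cui character vector of concept identifiers (unique).
#' @param name preferred names, parallel to `cui`.
#' @param semTypes list of character vectors of ST codes, parallel to `cui`.
#' @return a [ConceptTable-class] object.
#' @export
ConceptTable <- function(cui = character(), name = character(),
                         semTypes = list()) {
  names(semTypes) <- cui
  new("ConceptTable",
      concepts = data.frame(cui = as.character(cui), name = as.character(name),
                            stringsAsFactors = FALSE),
      semTypes = semTypes)
}

#' SynonymClasses: disjoint synonym classes with canonical representatives
#'
#' Built by [buildSynonymClasses()] from source-asserted synonymy. Classes
#' are pairwise disjoint CUI sets of size >= 2; each class is represented by
#' its lexicographically smallest member. CUIs not in any class implicitly
#' map to themselves.
#'
#' @slot classes list of character vectors (the disjoint classes).
#' @slot canonicalMap named character: classed CUI -> representative.
#' @slot minSources support threshold used (distinct sources per pair).
#' @slot maxClassSize size cutoff used (larger components are discarded).
#' @exportClass SynonymClasses
setClass("SynonymClasses",
  representation(classes = "list", canonicalMap = "character",
                 minSources = "integer", maxClassSize = "integer"),
  prototype(classes = list(), canonicalMap = character(),
            minSources = 1L, maxClassSize = 2L)
)

setValidity("SynonymClasses", function(object) {
  cls <- object@classes
  if (length(cls) > 0) {
    sizes <- lengths(cls)
    if (any(sizes < 2)) return("every class must have size >= 2")
    if (any(sizes > object@maxClassSize))
      return("class exceeds maxClassSize")
    all <- unlist(cls)
    if (anyDuplicated(all)) return("classes must be pairwise disjoint")
    reps <- vapply(cls, function(m) min(m), "")
    if (!setequal(names(object@canonicalMap), all))
      return("canonicalMap must cover exactly the classed CUIs")
    for (i in seq_along(cls)) {
      if (!all(object@canonicalMap[cls[[i]]] == reps[i]))
        return("each classed CUI must map to its class representative")
    }
  }
  TRUE
})

#' AdjacencyMatrix: CUI-indexed sparse relation-count matrix
#'
#' The square sparse matrix M whose entry m[i, j] counts the predication
#' instances supporting a relation between concepts i and j (zero where no
#' relation is attested). Row/column names carry the CUI <-> index map.
#' The matrix is symmetrized at construction (a relation in either direction
#' connects both concepts) and has a zero diagonal.
#'
#' @slot counts a sparse `Matrix` with identical row and column CUI names.
#' @slot symmetric logical flag; when TRUE the counts are symmetric.
#' @exportClass AdjacencyMatrix
setClass("AdjacencyMatrix",
  representation(counts = "Matrix", symmetric = "logical"),
  prototype(symmetric = TRUE)
)

setValidity("AdjacencyMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (nrow(m) > 0) {
    if (is.null(rownames(m)) || is.null(colnames(m)))
      return("counts must carry CUI dimnames")
    if (!identical(rownames(m), colnames(m)))
      return("row and column CUI names must match")
    if (any(Matrix::diag(m) != 0)) return("diagonal must be zero")
    if (object@symmetric && !Matrix::isSymmetric(m, check.attributes = FALSE))
      return("counts flagged symmetric but are not")
    if (length(m@x) > 0 && any(m@x < 0)) return("counts must be non-negative")
  }
  TRUE
})

#' HiddenPairSet: hidden concept pairs labelled with linking depth
#'
#' Unordered CUI pairs with no direct relation in the corpus, labelled with
#' the smallest linking depth k at which they appear (k = 1 is the classic
#' one-linking-term A-B-C case). A pair never appears at two depths and
#' never coincides with a direct connection.
#'
#' @slot pairs data.frame with columns `cui_a`, `cui_b` (with
#'   `cui_a < cui_b` lexicographically) and integer `depth`.
#' @exportClass HiddenPairSet
setClass("HiddenPairSet",
  representation(pairs = "data.frame"),
  prototype(pairs = data.frame(cui_a = character(), cui_b = character(),
                               depth = integer(), stringsAsFactors = FALSE))
)

setValidity("HiddenPairSet", function(object) {
  df <- object@pairs
  if (!all(c("cui_a", "cui_b", "depth") %in% names(df)))
    return("pairs needs columns cui_a, cui_b, depth")
  if (nrow(df) > 0) {
    if (any(df$cui_a >= df$cui_b))
      return("pairs must satisfy cui_a < cui_b")
    if (anyDuplicated(paste(df$cui_a, df$cui_b)))
      return("no pair may appear at two depths")
    if (any(df$depth < 1)) return("depth must be >= 1")
  }
  TRUE
})

#' Stoplist: CUIs barred from the discovery graph
#'
#' @slot cuis character set of stoplisted CUIs (no duplicates).
#' @slot provenance list describing how the stoplist was built (training
#'   date range, thresholds).
#' @exportClass Stoplist
setClass("Stoplist",
  representation(cuis = "character", provenance = "list"),
  prototype(cuis = character(), provenance = list())
)

setValidity("Stoplist", function(object) {
  if (anyDuplicated(object@cuis)) return("stoplist CUIs must be unique")
  TRUE
})

#' TimesliceResult: the metric bundle of a timeslicing evaluation
#'
#' @slot total hidden pairs generated.
#' @slot correct generated pairs found in the gold standard.
#' @slot precision correct / total (0 when total = 0).
#' @slot recall correct / |gold| (0, flagged, when gold is empty).
#' @slot fMeasure harmonic mean 2PR/(P+R), 0 when P + R = 0.
#' @slot averagePerTerm total / (number of terms seen pre-cutoff).
#' @slot flags character vector of degeneracy flags (e.g. `empty_gold`).
#' @exportClass TimesliceResult
setClass("TimesliceResult",
  representation(total = "integer", correct = "integer",
                 precision = "numeric", recall = "numeric",
                 fMeasure = "numeric", averagePerTerm = "numeric",
                 flags = "character"),
  prototype(flags = character())
)

setValidity("TimesliceResult", function(object) {
  if (object@correct > object@total) return("correct must be <= total")
  if (object@precision < 0 || object@precision > 1) return("precision in [0,1]")
  if (object@recall < 0 || object@recall > 1) return("recall in [0,1]")
  TRUE
})
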