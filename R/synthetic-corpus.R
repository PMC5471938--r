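defaultStPalette <- c(dsyn = 3, phsu = 3, orch = 2, gngm = 2, aapp = 2,
                      sosy = 1.5, topp = 1.5, celf = 1, bpoc = 1,
                      ftcn = 0.8, geoa = 0.5, humn = 0.5, acty = 0.5)

#' Specification of a synthetic predication corpus
#'
#' The generator emulates the three input file kinds of a predication-based
#' discovery pipeline — a predication table, a concept table with semantic
#' types, and source-asserted synonym assertions — with controllable
#' structure. Defaults describe a mid-sized literature segment: 500
#' concepts wired by a hub-heavy (power-law weight, exponent 2.5) graph of
#' mean degree 4, 400 documents of 1-5 predications each, dated 1980-2015
#' around a 2005-12-31 timeslice cutoff, 10% negated predications, and 10
#' synonym cliques of 2-4 CUIs asserted by 1-3 sources per pair.
#'
#' @param nConcepts vocabulary size (>= 4).
#' @param degreeModel list: `model = "hub"` with `exponent` (> 1) and
#'   `meanDegree`, or `model = "uniform"` with edge probability `p`.
#' @param nDocuments number of documents.
#' @param predicationsPerDocument length-2 integer range.
#' @param dateRange length-2 character/Date range of publication dates.
#' @param cutoff timeslice cutoff date inside `dateRange`.
#' @param negatedFraction fraction of negated predications in [0, 1).
#' @param stPalette named numeric vector: semantic-type code -> sampling
#'   weight (1-3 types per concept).
#' @param synonymCliques list with `count`, `size` (length-2 range) and
#'   `sourcesPerPair` (length-2 range).
#' @param plantedChains list of lists `list(length = k, placement =
#'   "pre"|"post"|"both-split")`; chain CUIs are reserved out of the random
#'   graph so the planted distance is exact.
#' @param seed mandatory integer seed; the corpus is a pure function of it.
#' @return a classed list (`CorpusSpec`).
#' @export
corpusSpec <- function(nConcepts = 500L,
                       degreeModel = list(model = "hub", exponent = 2.5,
                                          meanDegree = 4),
                       nDocuments = 400L,
                       predicationsPerDocument = c(1L, 5L),
                       dateRange = c("1980-01-01", "2015-12-31"),
                       cutoff = "2005-12-31",
                       negatedFraction = 0.1,
                       stPalette = defaultStPalette,
                       synonymCliques = list(count = 10L, size = c(2L, 4L),
                                             sourcesPerPair = c(1L, 3L)),
                       plantedChains = list(),
                       seed) {
  if (missing(seed)) stopConfig("corpusSpec: seed is mandatory")
  nConcepts <- as.integer(nConcepts)
  if (nConcepts < 4L) stopConfig("nConcepts must be >= 4")
  if (negatedFraction < 0 || negatedFraction >= 1)
    stopConfig("negatedFraction must be in [0, 1)")
  if (!degreeModel$model %in% c("hub", "uniform"))
    stopConfig("degreeModel$model must be 'hub' or 'uniform'")
  dateRange <- normalizeDate(dateRange)
  cutoff <- normalizeDate(cutoff)
  if (any(is.na(dateRange)) || is.na(cutoff))
    stopConfig("unparseable dateRange/cutoff")
  if (cutoff < dateRange[1] || cutoff > dateRange[2])
    stopConfig("cutoff must lie inside dateRange")
  reserved <- sum(vapply(plantedChains,
                         function(ch) as.integer(ch$length) + 1L, 1L))
  if (reserved > nConcepts - 3L)
    stopConfig("infeasible spec: %d reserved chain CUIs for %d concepts",
               reserved, nConcepts)
  structure(list(nConcepts = nConcepts, degreeModel = degreeModel,
                 nDocuments = as.integer(nDocuments),
                 predicationsPerDocument = as.integer(predicationsPerDocument),
                 dateRange = dateRange, cutoff = cutoff,
                 negatedFraction = negatedFraction, stPalette = stPalette,
                 synonymCliques = synonymCliques,
                 plantedChains = plantedChains,
                 seed = as.integer(seed)),
            class = "CorpusSpec")
}

predicatePalette <- c("TREATS", "AFFECTS", "CAUSES", "COEXISTS_WITH",
                      "ASSOCIATED_WITH", "INTERACTS_WITH", "PROCESS_OF",
                      "INHIBITS")

# sample() treats a length-1 vector as 1:n; this draws from an inclusive
# integer range safely even when lo == hi
sampleRange <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(lo:hi, 1L)
}

# Sub-seeds are derived from the master seed by fixed offsets, one per
# sampling section, so adding a later feature never perturbs earlier draws.
sectionSeed <- function(spec, section) {
  offsets <- c(concepts = 0L, edges = 1L, documents = 2L,
               synonyms = 3L, planting = 4L)
  (spec$seed + offsets[[section]]) %% .Machine$integer.max
}

#' Generate a synthetic predication corpus
#'
#' Fully reproducible from the spec's seed: the same spec yields
#' byte-identical output files. The hub degree model draws edge endpoints
#' with power-law weights (weight of the i-th concept proportional to
#' i^(-1/(exponent-1))), producing the heavy-tailed degree distribution
#' that motivates degree-based connection breaking. Planted discovery
#' chains use reserved CUIs that take part in no random edge, so their
#' source-target distance is exactly the chain length by construction
#' (verified by BFS at planting time, which fails loudly otherwise).
#'
#' @param spec a `CorpusSpec` from [corpusSpec()].
#' @return a classed list (`lbdCorpus`) with elements `predications`
#'   ([PredicationSet-class]), `concepts` ([ConceptTable-class]),
#'   `synonyms` (assertion data.frame), `manifest` (every planted chain and
#'   sampled parameter), and `spec`.
#' @export
generateCorpus <- function(spec) {
  stopifnot(inherits(spec, "CorpusSpec"))
  n <- spec$nConcepts
  allCui <- sprintf("C%07d", seq_len(n))
  nReserved <- sum(vapply(spec$plantedChains,
                          function(ch) as.integer(ch$length) + 1L, 1L))
  freeCui <- allCui[seq_len(n - nReserved)]
  reservedCui <- if (nReserved > 0) allCui[(n - nReserved + 1L):n] else character()

  # concepts & semantic types
  set.seed(sectionSeed(spec, "concepts"))
  pal <- spec$stPalette
  sts <- lapply(seq_len(n), function(i) {
    kst <- sample(1:3, 1)
    sort(sample(names(pal), min(kst, length(pal)), prob = pal))
  })
  concepts <- ConceptTable(cui = allCui,
                           name = paste("synthetic concept", seq_len(n)),
                           semTypes = sts)

  # relation graph over the free vocabulary
  set.seed(sectionSeed(spec, "edges"))
  nf <- length(freeCui)
  dm <- spec$degreeModel
  if (dm$model == "uniform") {
    idx <- utils::combn(nf, 2L)
    keep <- stats::runif(ncol(idx)) < dm$p
    edges <- idx[, keep, drop = FALSE]
  } else {
    w <- seq_len(nf)^(-1 / (dm$exponent - 1))
    m <- round(dm$meanDegree * nf / 2)
    ei <- integer(0); ej <- integer(0)
    seen <- character(0)
    tries <- 0L
    while (length(ei) < m && tries < 50L) {
      need <- m - length(ei)
      a <- sample.int(nf, 2L * need, replace = TRUE, prob = w)
      b <- sample.int(nf, 2L * need, replace = TRUE, prob = w)
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      lo <- pmin(a, b); hi <- pmax(a, b)
      key <- paste(lo, hi)
      new <- !(key %in% seen) & !duplicated(key)
      lo <- lo[new]; hi <- hi[new]; key <- key[new]
      take <- seq_len(min(length(lo), need))
      ei <- c(ei, lo[take]); ej <- c(ej, hi[take])
      seen <- c(seen, key[take])
      tries <- tries + 1L
    }
    edges <- rbind(ei, ej)
  }
  nEdges <- ncol(edges)
  if (nEdges == 0) stopConfig("degree model produced no edges")

  # documents
  set.seed(sectionSeed(spec, "documents"))
  nDays <- as.integer(spec$dateRange[2] - spec$dateRange[1])
  rows <- list()
  ppd <- spec$predicationsPerDocument
  for (d in seq_len(spec$nDocuments)) {
    pmid <- sprintf("PM%06d", d)
    date <- spec$dateRange[1] + sample.int(nDays + 1L, 1L) - 1L
    np <- sampleRange(ppd[1], ppd[2])
    eidx <- sample.int(nEdges, np, replace = TRUE)
    flip <- stats::runif(np) < 0.5
    si <- ifelse(flip, edges[2, eidx], edges[1, eidx])
    oi <- ifelse(flip, edges[1, eidx], edges[2, eidx])
    rows[[d]] <- data.frame(
      pmid = pmid, date = date,
      subject_cui = freeCui[si],
      predicate = sample(predicatePalette, np, replace = TRUE),
      object_cui = freeCui[oi],
      negated = stats::runif(np) < spec$negatedFraction,
      stringsAsFactors = FALSE)
  }
  predDf <- do.call(rbind, rows)
  preds <- PredicationSet(predDf, provenance = "synthetic")

  # synonym assertions: cliques of distinct free CUIs (kept off the graph's
  # hub end to avoid degenerate merges of the same high-degree concepts)
  set.seed(sectionSeed(spec, "synonyms"))
  sc <- spec$synonymCliques
  sources <- paste0("SRC", LETTERS[1:5])
  synRows <- list()
  pool <- sample(freeCui)
  used <- 0L
  for (q in seq_len(sc$count)) {
    size <- sampleRange(sc$size[1], sc$size[2])
    if (used + size > length(pool)) break
    members <- sort(pool[(used + 1L):(used + size)])
    used <- used + size
    pr <- utils::combn(members, 2L)
    for (e in seq_len(ncol(pr))) {
      nSrc <- sampleRange(sc$sourcesPerPair[1], sc$sourcesPerPair[2])
      for (s in sample(sources, nSrc)) {
        synRows[[length(synRows) + 1L]] <- data.frame(
          cui_a = pr[1, e], cui_b = pr[2, e], source = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  synonyms <- if (length(synRows) > 0) do.call(rbind, synRows) else
    data.frame(cui_a = character(), cui_b = character(),
               source = character(), stringsAsFactors = FALSE)
  rownames(synonyms) <- NULL

  corpus <- structure(
    list(predications = preds, concepts = concepts, synonyms = synonyms,
         manifest = list(seed = spec$seed, n_concepts = n,
                         n_edges = nEdges, n_documents = spec$nDocuments,
                         n_predications = nrow(predDf),
                         degree_model = spec$degreeModel,
                         reserved_cuis = reservedCui,
                         planted_chains = list()),
         spec = spec),
    class = "lbdCorpus")

  # planted discovery chains on reserved CUIs
  if (length(spec$plantedChains) > 0) {
    set.seed(sectionSeed(spec, "planting"))
    at <- 1L
    for (ch in spec$plantedChains) {
      L <- as.integer(ch$length)
      members <- reservedCui[at:(at + L)]
      at <- at + L + 1L
      corpus <- plantDiscovery(corpus,
                               source = members[1],
                               links = members[seq_len(L - 1L) + 1L],
                               target = members[L + 1L],
                               placement = ch$placement)
    }
  }
  corpus
}

# internal: BFS distance between two CUIs on the positive relation graph of
# a predication data.frame; Inf when unreachable or either CUI is isolated
sliceDistance <- function(predDf, a, b) {
  df <- predDf[!predDf$negated & predDf$subject_cui != predDf$object_cui, ]
  if (nrow(df) == 0) return(Inf)
  vocab <- sort(unique(c(df$subject_cui, df$object_cui)))
  if (!(a %in% vocab) || !(b %in% vocab)) return(Inf)
  ps <- PredicationSet(df)
  mat <- buildAdjacency(ps)
  nbrs <- neighborList(mat)
  dist <- bfsDistances(nbrs, match(a, cuis(mat)))
  dist[match(b, cuis(mat))]
}

#' Plant a discovery chain into a corpus
#'
#' Inserts the chain source - links[1] - ... - links[k] - target, one hop
#' per fresh document, dated inside the requested slice:
#'
#' * `"pre"` — all hops before the cutoff;
#' * `"post"` — all hops after the cutoff;
#' * `"both-split"` — the chain before the cutoff plus a *direct*
#'   source-target predication after it (the planted ground truth for
#'   timeslicing: the pre slice can infer what the post slice publishes).
#'
#' Planting guarantees the source-target distance in the chain's slice is
#' exactly the chain length: if a shorter (or equal) connection already
#' exists, or the inserted hops create a shortcut, it fails loudly rather
#' than silently producing an off-depth chain.
#'
#' @param corpus an `lbdCorpus` (or compatible list with `predications`,
#'   `concepts`, `spec`, `manifest`).
#' @param source,target endpoint CUIs (must exist in the concept table).
#' @param links character vector of intermediate CUIs (possibly empty for a
#'   direct plant).
#' @param placement `"pre"`, `"post"` or `"both-split"`.
#' @return the corpus with the inserted predications and an updated
#'   manifest entry.
#' @export
plantDiscovery <- function(corpus, source, links, target,
                           placement = c("pre", "post", "both-split")) {
  placement <- match.arg(placement)
  stopifnot(is(corpus$predications, "PredicationSet"))
  chain <- c(source, links, target)
  if (anyDuplicated(chain)) stopConfig("planted chain repeats a CUI")
  known <- cuis(corpus$concepts)
  missing <- setdiff(chain, known)
  if (length(missing) > 0)
    stopInput("planted chain CUIs not in concept table: %s",
              paste(missing, collapse = ", "))
  L <- length(chain) - 1L
  spec <- corpus$spec
  cutoff <- spec$cutoff
  chainSlice <- if (placement == "post") "post" else "pre"
  predDf <- predications(corpus$predications)

  sliceDf <- if (chainSlice == "pre") predDf[predDf$date <= cutoff, ]
             else predDf[predDf$date > cutoff, ]
  existing <- sliceDistance(sliceDf, source, target)
  if (existing < L)
    stop(structure(
      class = c("lbd_planting_error", "lbd_config_error", "lbd_error",
                "error", "condition"),
      list(message = sprintf(
        "planting %s-...-%s (length %d): a connection of length %g already exists",
        source, target, L, existing), call = sys.call())))

  chainDate <- if (chainSlice == "pre") max(spec$dateRange[1], cutoff - 60)
               else min(spec$dateRange[2], cutoff + 60)
  nExisting <- length(grep("^PL", predDf$pmid))
  newRows <- data.frame(
    pmid = sprintf("PL%06d", nExisting + seq_len(L)),
    date = chainDate,
    subject_cui = chain[-length(chain)],
    predicate = "ASSOCIATED_WITH",
    object_cui = chain[-1],
    negated = FALSE, stringsAsFactors = FALSE)
  if (placement == "both-split") {
    newRows <- rbind(newRows, data.frame(
      pmid = sprintf("PL%06d", nExisting + L + 1L),
      date = min(spec$dateRange[2], cutoff + 120),
      subject_cui = source, predicate = "ASSOCIATED_WITH",
      object_cui = target, negated = FALSE, stringsAsFactors = FALSE))
  }
  allDf <- rbind(predDf, newRows)

  # verify the realized distance in the chain's slice
  checkDf <- if (chainSlice == "pre") allDf[allDf$date <= cutoff, ]
             else allDf[allDf$date > cutoff, ]
  realized <- sliceDistance(checkDf, source, target)
  if (!identical(as.numeric(realized), as.numeric(L)))
    stop(structure(
      class = c("lbd_planting_error", "lbd_config_error", "lbd_error",
                "error", "condition"),
      list(message = sprintf(
        "planting %s-...-%s: realized distance %g != chain length %d",
        source, target, realized, L), call = sys.call()))) # shortcut crept in

  corpus$predications <- PredicationSet(
    allDf, provenance = corpus$predications@provenance,
    filterLog = filterLog(corpus$predications))
  corpus$manifest$planted_chains <-
    c(corpus$manifest$planted_chains,
      list(list(source = source, links = as.character(links),
                target = target, length = L, placement = placement,
                depth = L - 1L,
                documents = newRows$pmid,
                dates = format(unique(newRows$date)))))
  corpus
}

#' Write a corpus's three input files plus manifest
#'
#' Emits `predications.tsv`, `concepts.tsv`, `synonyms.tsv` (the simple-tsv
#' dialects) and `manifest.json` into `dir`. Output is deterministic given
#' the corpus (no timestamps).
#'
#' @param corpus an `lbdCorpus`.
#' @param dir output directory (created if missing).
#' @return (invisibly) the four file paths.
#' @export
writeCorpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pPath <- file.path(dir, "predications.tsv")
  cPath <- file.path(dir, "concepts.tsv")
  sPath <- file.path(dir, "synonyms.tsv")
  mPath <- file.path(dir, "manifest.json")
  writePredications(corpus$predications, pPath)
  ct <- corpus$concepts
  utils::write.table(
    data.frame(cui = cuis(ct), name = ct@concepts$name,
               semantic_types = vapply(semanticTypes(ct), paste,
                                       "", collapse = "|"),
               stringsAsFactors = FALSE),
    cPath, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  utils::write.table(corpus$synonyms, sPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(corpus$manifest, mPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(predications = pPath, concepts = cPath,
              synonyms = sPath, manifest = mPath))
}
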